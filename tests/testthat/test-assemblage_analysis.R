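test_that("ecoregion collapse merges the arctic and boreal components", {
  expect_equal(collapse_ecoregions("Tundra"), "Arctic")
  expect_equal(collapse_ecoregions("Arctic Cordillera"), "Arctic")
  expect_equal(collapse_ecoregions(c("Taiga", "Hudson Plains",
                                     "Northern Forests")),
               rep("Boreal", 3))
  expect_equal(collapse_ecoregions("Great Plains"), "Great Plains")
  expect_equal(collapse_ecoregions("Boreal"), "Boreal")  # pass-through
  expect_true(is.na(collapse_ecoregions(NA)))
  expect_error(collapse_ecoregions("Atlantis"), "Atlantis.*valid labels")
})

test_that("latitude and longitude bands use lower-inclusive edges", {
  expect_equal(latitude_band(52.1), "50-55")
  expect_equal(latitude_band(25.0), "25-30")
  expect_equal(latitude_band(24.99), "<25")
  expect_equal(latitude_band(57), ">55")
  expect_equal(longitude_band(-100.0), "95-105")
  expect_equal(longitude_band(-74.9), "<75")
  expect_equal(longitude_band(-140), ">135")
  expect_true(is.na(longitude_band(10)))   # eastern records excluded
  expect_true(is.na(latitude_band(NA)))
})

test_that("single-partition summaries equal the continental audit", {
  coll <- planted_library()
  coll$meta$ecoregion <- "Great Plains"
  audit <- audit_library(coll)
  summ <- partition_and_summarize(coll, "ecoregion")
  row <- summ[summ$partition == "Great Plains", ]
  s <- audit$species
  expect_equal(row$n_species, nrow(s))
  expect_equal(row$mean_nnd, mean(s$nn_distance))
  expect_equal(row$n_sharing, sum(s$sharing))
  expect_equal(row$id_success_pct, identification_success(s))
  # idempotence: the pooled Total row is the same single assemblage
  tot <- summ[summ$partition == "Total", ]
  expect_equal(row$mean_nnd, tot$mean_nnd)
  expect_equal(row$n_sharing, tot$n_sharing)
})

# Two species share a haplotype continentally but never co-occur in a
# region: regional resolution removes the sharing.
two_region_library <- function() {
  west <- with_transitions(TPL, seq(4, 120, by = 4))
  east <- with_transitions(TPL, seq(7, 203, by = 7))
  seqs <- c(x1 = TPL, x2 = TPL,
            y1 = TPL, y2 = TPL,
            w1 = west, w2 = west,
            e1 = east, e2 = east)
  make_collection(
    c("Xa xa", "Xa xa", "Yb yb", "Yb yb", "Wc wc", "Wc wc", "Ed ed",
      "Ed ed"),
    seqs,
    ecoregion = c("Great Plains", "Great Plains",
                  "North American Deserts", "North American Deserts",
                  "Great Plains", "Great Plains",
                  "North American Deserts", "North American Deserts"))
}

test_that("regional restriction removes cross-region sharing", {
  coll <- two_region_library()
  continental <- audit_library(coll)
  n_cont <- sum(continental$species$sharing)
  expect_equal(n_cont, 2)   # Xa and Yb share the template haplotype

  summ <- partition_and_summarize(coll, "ecoregion")
  regional <- summ[summ$partition != "Total", ]
  expect_true(all(regional$n_sharing < n_cont))
  expect_true(all(regional$n_sharing == 0))
  # and every regionally sharing species must share continentally
  for (p in regional$partition) {
    ids <- coll$meta$specimen_id[coll$meta$ecoregion == p]
    sub <- audit_library(subset_collection(coll, ids))
    reg_sharing <- sub$species$species[sub$species$sharing]
    expect_true(all(reg_sharing %in%
                      continental$species$species[
                        continental$species$sharing]))
  }
})

test_that("per-band summaries equal brute-force recomputation", {
  set.seed(9)
  lib <- generate_library(sim_config(seed = 9, n_species = 30,
                                     n_genera = 10, specimens_mean = 4,
                                     n_sharing_pairs = 3, n_deep_splits = 3,
                                     n_low_div_pairs = 3, n_introduced = 2,
                                     n_neotropical = 1))
  coll <- lib$collection
  summ <- partition_and_summarize(coll, "lat_band")
  bands <- latitude_band(coll$meta$latitude)
  for (b in setdiff(summ$partition, "Total")) {
    ids <- coll$meta$specimen_id[!is.na(bands) & bands == b]
    row <- summ[summ$partition == b, ]
    expect_equal(row$n_sequences, length(ids))
    sub <- subset_collection(coll, ids)
    expect_equal(row$n_species, length(unique(sub$meta$species)))
    if (row$n_species >= 2 && length(ids) >= 2) {
      oracle <- audit_library(sub)$species
      expect_equal(row$mean_nnd, mean(oracle$nn_distance[oracle$assessed]))
      expect_equal(row$n_sharing, sum(oracle$sharing))
    }
  }
})

test_that("presence/absence matrix is consistent with the summaries", {
  coll <- two_region_library()
  coll$meta$latitude <- c(40, 40, 40, 40, 40, 40, 40, NA)
  pa <- presence_absence_matrix(coll, "ecoregion")
  expect_equal(sort(rownames(pa)),
               sort(unique(coll$meta$species)))
  expect_equal(unname(rowSums(pa)[c("Xa xa", "Wc wc")]), c(1, 1))
  summ <- partition_and_summarize(coll, "ecoregion")
  for (p in setdiff(summ$partition, "Total")) {
    expect_equal(unname(colSums(pa)[p]),
                 summ$n_species[summ$partition == p])
  }
  pa2 <- presence_absence_matrix(coll, "lat_band")
  expect_equal(attr(pa2, "n_skipped"), 1)
})

test_that("region overlap recovers a planted three-region design", {
  meta <- data.frame(
    specimen_id = sprintf("s%d", 1:6),
    species = c("A a", "A a", "B b", "B b", "C c", "C c"),
    family = c("FamA", "FamA", "FamA", "FamA", "FamB", "FamB"),
    bin_id = c("c1", "c1", "c2", "c2", "c3", "c3"),
    zoogeo_region = c("Nearctic", "Nearctic",
                      "Nearctic", "Neotropical",
                      "Neotropical", "Neotropical"))
  coll <- specimen_collection(meta, stats::setNames(rep(TPL, 6),
                                                    meta$specimen_id))
  ov <- region_overlap(supplied_bins(coll), coll)
  expect_equal(dim(ov$matrix), c(3, 2))
  expect_true(all(rowSums(ov$matrix) >= 1))
  expect_equal(unname(ov$matrix["c1", ]), c(TRUE, FALSE))
  expect_equal(unname(ov$matrix["c2", ]), c(TRUE, TRUE))
  expect_equal(unname(ov$matrix["c3", ]), c(FALSE, TRUE))
  expect_equal(ov$endemic$n, 1)   # c1 only
  expect_identical(ov$endemic$pct, percentage(1, 3))
  tot <- ov$family_table[ov$family_table$family == "Total", ]
  expect_equal(tot$Nearctic_n, 2)
  expect_equal(tot$Neotropical_n, 2)
  fa <- ov$family_table[ov$family_table$family == "FamA", ]
  expect_equal(fa$n_clusters, 2)
  expect_identical(fa$Nearctic_pct, 100.0)
})
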