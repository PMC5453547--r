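test_that("single linkage joins below threshold and chains", {
  pct <- matrix(NA_real_, 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  pct["a", "b"] <- pct["b", "a"] <- 2.0
  pct["b", "c"] <- pct["c", "b"] <- 2.0
  pct["a", "c"] <- pct["c", "a"] <- 4.0
  part <- single_linkage_clusters(fake_dist(pct), threshold = 2.2)
  expect_equal(length(unique(part$assignment$cluster)), 1)  # chaining

  pct2 <- matrix(c(NA, 1, 1, NA), 2, 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
  part2 <- single_linkage_clusters(fake_dist(pct2), threshold = 2.2)
  expect_equal(unique(part2$assignment$cluster), "a")  # smallest-id label
})

test_that("single linkage equals brute-force connected components", {
  skip_if_not_installed("igraph")
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30
    pct <- matrix(NA_real_, n, n)
    pct[upper.tri(pct)] <- runif(n * (n - 1) / 2, 0, 5)
    pct[upper.tri(pct)][sample(n * (n - 1) / 2, 40)] <- NA  # undefined pairs
    pct[lower.tri(pct)] <- t(pct)[lower.tri(pct)]
    rownames(pct) <- colnames(pct) <- sprintf("s%02d", 1:n)
    dm <- fake_dist(pct)
    part <- single_linkage_clusters(dm, threshold = 2.2)

    edges <- which(upper.tri(pct) & !is.na(pct) & pct <= 2.2, arr.ind = TRUE)
    g <- igraph::graph_from_edgelist(cbind(edges[, 1], edges[, 2]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
    ref <- igraph::components(g)$membership
    got <- as.integer(factor(part$assignment$cluster,
                             levels = unique(part$assignment$cluster)))
    # same partition up to relabelling
    expect_equal(length(unique(paste(ref, got))),
                 length(unique(ref)))
    expect_equal(length(unique(got)), length(unique(ref)))
  }
})

test_that("cluster count is monotone in the threshold, with known extremes", {
  set.seed(42)
  seqs <- stats::setNames(c(TPL, TPL, vapply(1:10, function(i) {
    mutate_sequence(TPL, rpois(1, 20))
  }, character(1))), sprintf("s%02d", 1:12))
  dm <- pairwise_matrix(seqs)
  thresholds <- c(0.05, 0.5, 1, 2.2, 4, 8, 100)
  sizes <- vapply(thresholds, function(th) {
    length(unique(single_linkage_clusters(dm, th)$assignment$cluster))
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[length(sizes)], 1L)  # above max distance: one cluster
  # below the smallest positive distance: haplotype-identity components
  hap <- collapse_haplotypes(dm, haplotype_min_overlap = 500)
  expect_equal(sizes[1], length(unique(hap$membership)))
})

test_that("isolated specimens become flagged singletons", {
  pct <- matrix(NA_real_, 3, 3,
                dimnames = list(c("a", "b", "z"), c("a", "b", "z")))
  pct["a", "b"] <- pct["b", "a"] <- 1.0
  part <- single_linkage_clusters(fake_dist(pct), 2.2)
  asg <- part$assignment
  expect_true(asg$isolated[asg$specimen_id == "z"])
  expect_equal(asg$cluster[asg$specimen_id == "z"], "z")
})

test_that("concordance categories follow the invariant table", {
  sp <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B", s5 = "C", s6 = "D",
          s7 = "D", s8 = "D")
  cl <- c(s1 = "c1", s2 = "c1",             # A: MATCH
          s3 = "c2", s4 = "c3",             # B: SPLIT (2 clusters)
          s5 = "c4", s6 = "c4",             # C: MERGE (shares c4 with D)
          s7 = "c4", s8 = "c5")             # D: MIXTURE
  part <- structure(list(assignment = data.frame(specimen_id = names(cl),
                                                 cluster = unname(cl),
                                                 isolated = FALSE),
                         source = "supplied_bins", threshold = NA_real_),
                    class = "cluster_partition")
  rec <- concordance_classify(sp, part)
  expect_equal(stats::setNames(rec$category, rec$species),
               c(A = "MATCH", B = "SPLIT", C = "MERGE", D = "MIXTURE"))
  cnt <- concordance_counts(rec)
  expect_equal(cnt$n_match + cnt$n_split + cnt$n_merge + cnt$n_mixture,
               cnt$n_species)
  expect_equal(unname(cnt$histogram), c(2, 0, 0))
})

test_that("concordance on generated data equals the recorded truth", {
  lib <- generate_library(sim_config(seed = 3, n_species = 40,
                                     specimens_mean = 5))
  dm <- pairwise_matrix(lib$collection)
  part <- single_linkage_clusters(dm, 2.2)
  rec <- concordance_classify(lib$collection, part)
  cmp <- merge(lib$truth, rec, by = "species")
  expect_equal(cmp$category, cmp$expected_category)
  cnt <- concordance_counts(rec)
  expect_equal(cnt$n_match + cnt$n_split + cnt$n_merge + cnt$n_mixture,
               nrow(lib$truth))
})

test_that("supplied BINs pass through and drive cluster-vs-species counts", {
  meta <- data.frame(
    specimen_id = sprintf("s%03d", 1:110),
    species = c(sprintf("Sp %03d", 1:100), sprintf("Sp %03d", 1:10)),
    bin_id = sprintf("BIN%03d", 1:110))
  seqs <- stats::setNames(rep(TPL, 110), meta$specimen_id)
  coll <- specimen_collection(meta, seqs)
  part <- supplied_bins(coll)
  expect_equal(part$source, "supplied_bins")
  # 10 planted splits over 100 species: cluster excess is exactly 10%
  res <- bin_count_vs_species(part, coll)
  expect_equal(res$n_clusters, 110)
  expect_equal(res$n_species, 100)
  expect_identical(res$excess_pct, 10.0)

  meta$bin_id[1] <- NA
  expect_error(supplied_bins(specimen_collection(meta, seqs)), "bin_id")
})
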