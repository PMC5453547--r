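test_that("K2P matches the closed form on a constructed pair", {
  a <- frag(TPL, 1, 20)
  b <- with_transversions(with_transitions(a, c(3, 6)), 9)
  res <- k2p_distance(a, b, min_overlap = 1)
  expect_equal(res$overlap, 20)
  expect_equal(res$P, 0.10)
  expect_equal(res$Q, 0.05)
  # independently frozen: -1/2 ln(1 - 2/10 - 1/20) - 1/4 ln(1 - 1/10)
  expect_equal(res$distance, 0.17018116514034704, tolerance = 1e-12)
})

test_that("identity, thresholds, and degenerate input behave", {
  res <- k2p_distance(TPL, TPL)
  expect_equal(res$distance, 0)
  expect_equal(res$P + res$Q, 0)
  expect_true(res$defined)

  short <- frag(TPL, 1, 120)
  res2 <- k2p_distance(short, TPL, min_overlap = 200)
  expect_false(res2$defined)
  expect_true(is.na(res2$distance))

  expect_error(k2p_distance(substr(TPL, 1, 100), TPL), "unequal frame")
})

test_that("K2P is symmetric, dominates the p-distance, and reduces with Q=0", {
  set.seed(11)
  for (k in 1:15) {
    a <- mutate_sequence(TPL, rpois(1, 30))
    b <- mutate_sequence(TPL, rpois(1, 30))
    ab <- k2p_distance(a, b)
    ba <- k2p_distance(b, a)
    expect_identical(ab$distance, ba$distance)
    expect_gte(ab$distance, ab$P + ab$Q - 1e-12)
  }
  # transitions only: d = -1/2 ln(1 - 2P)
  ti_only <- with_transitions(TPL, seq(3, 90, by = 3))
  res <- k2p_distance(TPL, ti_only)
  expect_equal(res$Q, 0)
  expect_equal(res$distance, -0.5 * log(1 - 2 * res$P), tolerance = 1e-12)
})

test_that("pairwise matrix equals per-pair oracles (pure R and ape)", {
  set.seed(12)
  seqs <- c(
    stats::setNames(vapply(1:8, function(i) {
      mutate_sequence(TPL, rpois(1, 25))
    }, character(1)), sprintf("r%02d", 1:8)),
    fragN = sub_at(frag(TPL, 30, 620), 100:110, "N"),
    fragS = frag(TPL, 1, 450))
  dm <- pairwise_matrix(seqs, min_overlap = 300)
  m <- as.matrix(dm)
  for (i in 1:(length(seqs) - 1)) {
    for (j in (i + 1):length(seqs)) {
      o <- oracle_k2p(seqs[[i]], seqs[[j]], min_overlap = 300)
      if (o$defined) {
        expect_equal(m[i, j], o$distance, tolerance = 1e-12)
      } else {
        expect_true(is.na(m[i, j]))
      }
    }
  }
  # second, library-independent oracle on the clean full-length subset
  skip_if_not_installed("ape")
  clean <- seqs[1:8]
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(clean), "")))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(as.matrix(pairwise_matrix(clean))[1:8, 1:8]),
               unname(ref), tolerance = 1e-10)
})

test_that("pairwise matrix rejects a single specimen", {
  expect_error(pairwise_matrix(c(a = TPL)), "at least 2")
})

test_that("haplotype collapse uses zero mismatches over sufficient overlap", {
  seqs <- c(full1 = TPL, full2 = TPL,
            sub550 = frag(TPL, 1, 550),
            sub450 = frag(TPL, 1, 450),
            diff1 = with_transitions(TPL, 300))
  dm <- pairwise_matrix(seqs, min_overlap = 300)
  hap <- collapse_haplotypes(dm, haplotype_min_overlap = 500)
  mem <- hap$membership
  expect_identical(mem[["full1"]], mem[["full2"]])
  expect_identical(mem[["full1"]], mem[["sub550"]])   # zero-mismatch rule
  expect_false(mem[["sub450"]] == mem[["full1"]])     # overlap below 500
  expect_false(mem[["diff1"]] == mem[["full1"]])      # one-site difference
})

test_that("haplotype groups are the component closure of the relation", {
  # A and C differ at position 600; B is a fragment identical to both over
  # its 520-position window, so A-B and B-C link even though A-C do not.
  seqs <- c(A = TPL, B = frag(TPL, 1, 520),
            C = with_transitions(TPL, 600))
  dm <- pairwise_matrix(seqs)
  hap <- collapse_haplotypes(dm, 500)
  expect_equal(length(unique(hap$membership)), 1)
})

test_that("species NN and intraspecific summaries match brute force", {
  coll <- planted_library()
  dm <- pairwise_matrix(coll)
  sp <- stats::setNames(coll$meta$species, coll$meta$specimen_id)
  nn <- species_nn(dm, sp)

  # brute-force oracle over all pairs
  ids <- names(coll$sequences)
  for (s in unique(sp)) {
    mine <- ids[sp[ids] == s]
    other <- ids[sp[ids] != s]
    inter <- c()
    inter_sp <- c()
    for (x in mine) {
      for (y in other) {
        o <- oracle_k2p(coll$sequences[[x]], coll$sequences[[y]])
        if (o$defined) {
          inter <- c(inter, o$distance)
          inter_sp <- c(inter_sp, unname(sp[y]))
        }
      }
    }
    row <- nn[nn$species == s, ]
    expect_equal(row$nn_distance, 100 * min(inter), tolerance = 1e-12)
    expect_equal(row$nn_species, inter_sp[which.min(inter)])
    intra <- c()
    if (length(mine) > 1) {
      for (i in 1:(length(mine) - 1)) {
        for (j in (i + 1):length(mine)) {
          o <- oracle_k2p(coll$sequences[[mine[i]]],
                          coll$sequences[[mine[j]]])
          if (o$defined) intra <- c(intra, o$distance)
        }
      }
    }
    if (length(intra) > 0) {
      expect_equal(row$intra_mean, 100 * mean(intra), tolerance = 1e-12)
      expect_equal(row$intra_max, 100 * max(intra), tolerance = 1e-12)
    } else {
      expect_true(is.na(row$intra_mean))
    }
  }
  # haplotype sharers sit at NN distance zero
  expect_equal(nn$nn_distance[nn$species == "Alpha two"], 0)
})
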