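# Seeded synthetic barcode libraries with planted truth.  The generator is
# phenomenological: it targets the realized percent divergences a reference
# library exhibits (intraspecific scale, nearest-neighbor scale) directly via
# substitution counts rather than simulating a coalescent.  Every emitted
# sequence stays stop-free in frame 1 of the invertebrate mitochondrial code,
# so the reading-frame QC always passes by construction.

# Fixed stop-free 658-position COI-like template (frame 1 has no TAA/TAG).
.coi_template_chunks <- c(
  "GTATCTACGCACTGTGCTAATTACTCTCAGTGTGAAGACACTATAATGTTTAAGATCTCTCAATGGAACT",
  "GTGACCGTTGATTACAATCCAATTACACTGAGAAATTTTATCAAATAGGCGTTCGACAGTGACGATTGAG",
  "TTTGCTAAATAGTCTACTGGAATATTCAAGAAGTGTTTTATGCAACATCTCCGTTTTAGAACGCATTCTT",
  "CGTGTGCGAAAACGGATCCATTCCCATACATGTGTAACCACTGATATCAAGGAGAGATATTCCCTGGTAA",
  "TAGGTTGCGATCCGGCGAAGAGAGACAGACGTTTTCATCGAGGTTGTTACGCTCATAAAGGAGCCCAATT",
  "TTTTAAGCTCGACAGAAGCAGAACAGGAGAAAGCTCCATCTCCTTACGCGTGATCGTTGTATCAAGTGCT",
  "GGACAACACGCAGAACCAAATCTTCGTGAACCAAAGCTAATAAGCGACGACAAACGCGCCTATATTTGGC",
  "GTCATACTCAAAGTAACGTCACGATGAGTGAAGATGGTCAGTGAGCTATTTACCTAACAATAAACCTGCA",
  "CGGCATGTGTGTTGATGCCGCTAATCTAAAAAGCAAGCCCCCATTGCAGTGTAAATCTGCAAATAACGTT",
  "ACTAAAATATACACTTTAGAAAGATATA")

#' The fixed 658-position template sequence
#' @return a 658-character A/C/G/T string, stop-free in frame 1.
#' @export
coi_template <- function() paste(.coi_template_chunks, collapse = "")

.transition_of <- c(A = "G", G = "A", C = "T", T = "C")
.transversions_of <- list(A = c("C", "T"), G = c("C", "T"),
                          C = c("A", "G"), T = c("A", "G"))

# Would substituting position `pos` of `ch` with `base` create a frame-1 stop?
.makes_stop <- function(ch, pos, base) {
  ci <- (pos - 1) %/% 3
  start <- ci * 3 + 1
  if (start + 2 > length(ch)) return(FALSE)  # dangling partial codon
  cod <- ch[start:(start + 2)]
  cod[pos - start + 1] <- base
  paste(cod, collapse = "") %in% .mito_stops
}

#' Mutate a sequence by an exact number of substitutions
#'
#' Substitutes exactly `n_substitutions` distinct positions.  Each site is a
#' transition with probability `ti_tv / (ti_tv + 1)`; site choice is biased
#' toward third codon positions (weight `third_pos_weight` vs 1).  A
#' substitution that would create a frame-1 stop codon is re-drawn (another
#' base at the site, then another site); exhausting all sites raises an
#' error (infeasible request).
#'
#' @param seq A/C/G/T string (positions with other characters are never
#'   touched).
#' @param n_substitutions exact Hamming distance to the output.
#' @param ti_tv transition:transversion ratio (default 3).
#' @param third_pos_weight sampling weight of third codon positions
#'   (default 4).
#' @return the mutated sequence string.
#' @export
mutate_sequence <- function(seq, n_substitutions, ti_tv = 3,
                            third_pos_weight = 4) {
  if (n_substitutions == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  sites <- which(ch %in% c("A", "C", "G", "T"))
  if (n_substitutions > length(sites)) {
    stop("requested ", n_substitutions, " substitutions but only ",
         length(sites), " defined positions")
  }
  w <- ifelse(sites %% 3 == 0, third_pos_weight, 1)
  order <- sample(sites, length(sites), prob = w)
  p_ti <- ti_tv / (ti_tv + 1)
  done <- 0L
  for (pos in order) {
    orig <- ch[pos]
    first <- if (stats::runif(1) < p_ti) .transition_of[[orig]] else
      sample(.transversions_of[[orig]], 1)
    candidates <- c(first, sample(setdiff(c("A", "C", "G", "T"),
                                          c(orig, first))))
    placed <- FALSE
    for (base in candidates) {
      if (!.makes_stop(ch, pos, base)) {
        ch[pos] <- base
        placed <- TRUE
        break
      }
    }
    if (placed) done <- done + 1L
    if (done == n_substitutions) break
  }
  if (done < n_substitutions) {
    stop("could not place ", n_substitutions,
         " substitutions without creating a stop codon")
  }
  paste(ch, collapse = "")
}

#' Configuration of the synthetic library generator
#'
#' Defaults are the generator's stated world: specimens per species follow a
#' truncated geometric with mean 19.46 on \[1, 614\]; the intraspecific
#' scale targets a mean within-species divergence of 0.45% and the
#' interspecific scale a congeneric nearest-neighbor distance around 2.7%;
#' introduced species get their intraspecific scale shrunk by 0.45 and their
#' NN scale stretched by 1.6.  Planted features (identical shared
#' haplotypes, deep intraspecific splits of 2.5–8%, low-divergence neighbor
#' pairs of 0.2–0.9%) are recorded in the returned truth.
#'
#' @param seed integer RNG seed.
#' @param n_families,n_genera,n_species taxonomy sizes.
#' @param specimens_mean mean of the truncated geometric specimen count.
#' @param specimens_max truncation ceiling (default 614).
#' @param mean_intra,mean_nnd divergence scales in percent.
#' @param ti_tv transition:transversion ratio.
#' @param n_sharing_pairs,n_deep_splits,n_low_div_pairs,n_introduced planted
#'   feature counts.
#' @param deep_split_range,low_div_range planted depth / NN ranges in
#'   percent.
#' @param introduced_intra_factor,introduced_nnd_factor introduced-species
#'   scale multipliers.
#' @param n_neotropical native species also given Neotropical records (for
#'   overlap analysis).
#' @param regions named list of region -> c(latitude, longitude) centres.
#' @param occupancy_lam Poisson rate of extra regions occupied per species.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_families = 4L, n_genera = 30L, n_species = 120L,
                       specimens_mean = 19.46, specimens_max = 614L,
                       mean_intra = 0.45, mean_nnd = 2.7, ti_tv = 3,
                       n_sharing_pairs = 5L, n_deep_splits = 6L,
                       n_low_div_pairs = 5L, n_introduced = 5L,
                       deep_split_range = c(2.5, 8),
                       low_div_range = c(0.2, 0.9),
                       introduced_intra_factor = 0.45,
                       introduced_nnd_factor = 1.6,
                       n_neotropical = 3L,
                       regions = NULL,
                       occupancy_lam = 1) {
  if (is.null(regions)) {
    regions <- list(
      "Tundra" = c(68, -110),
      "Taiga" = c(58, -100),
      "Northwestern Forested Mountains" = c(50, -118),
      "Eastern Temperate Forests" = c(38, -84),
      "Great Plains" = c(41, -100),
      "North American Deserts" = c(36, -112))
  }
  cfg <- list(seed = as.integer(seed), n_families = n_families,
              n_genera = n_genera, n_species = n_species,
              specimens_mean = specimens_mean,
              specimens_max = as.integer(specimens_max),
              mean_intra = mean_intra, mean_nnd = mean_nnd, ti_tv = ti_tv,
              n_sharing_pairs = n_sharing_pairs,
              n_deep_splits = n_deep_splits,
              n_low_div_pairs = n_low_div_pairs,
              n_introduced = n_introduced,
              deep_split_range = deep_split_range,
              low_div_range = low_div_range,
              introduced_intra_factor = introduced_intra_factor,
              introduced_nnd_factor = introduced_nnd_factor,
              n_neotropical = n_neotropical,
              regions = regions, occupancy_lam = occupancy_lam)
  stopifnot(cfg$mean_intra > 0, cfg$mean_nnd > 0, cfg$specimens_mean >= 1)
  planted <- 2 * n_sharing_pairs + n_deep_splits + 2 * n_low_div_pairs +
    n_introduced + n_neotropical
  if (planted > n_species) {
    stop("planted feature species (", planted, ") exceed n_species (",
         n_species, ")")
  }
  if (round(low_div_range[1] / 100 * .frame_length) < 1) {
    stop("low_div_range lower bound is below one substitution's resolution")
  }
  structure(cfg, class = "sim_config")
}

# Truncated geometric specimen counts with the configured mean.
.r_specimens <- function(n, mean, max) {
  pmin(1L + stats::rgeom(n, 1 / mean), max)
}

#' Per-species mean intraspecific divergences for contrast simulations
#'
#' Draws right-skewed per-species mean divergences (gamma, shape 2) around a
#' target mean, the distributional shape the generator assumes for
#' intraspecific COI variation.
#'
#' @param n number of species.
#' @param mean_pct target mean in percent.
#' @param shape gamma shape (default 2).
#' @return numeric vector of divergences (percent).
#' @export
sample_species_intra_means <- function(n, mean_pct, shape = 2) {
  stats::rgamma(n, shape = shape, rate = shape / mean_pct)
}

#' Generate a synthetic barcode library with planted truth
#'
#' Builds genus founders from the fixed template, species founders from
#' genus founders, and specimens from species founders, with substitution
#' counts targeting the configured divergence scales.  Sharing pairs copy an
#' identical haplotype into two species; deep splits place a second founder
#' at the planted depth inside one species; low-divergence pairs separate
#' two founders by a planted handful of substitutions.  Every species' first
#' specimen carries its founder haplotype unmutated.  Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list: `collection` (a `specimen_collection`) and `truth` (data
#'   frame of per-species planted flags and the expected cluster-concordance
#'   category at the 2.2% surrogate threshold).
#' @export
generate_library <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- .frame_length
  tpl <- coi_template()

  families <- sprintf("Family%02d", seq_len(config$n_families))
  genus_family <- sample(families, config$n_genera, replace = TRUE)
  genera <- sprintf("Genus%03d", seq_len(config$n_genera))
  # Uneven genus sizes: exponential weights give monotypic through large
  # genera, which the genus-size profile and the Spearman contrast need.
  gw <- stats::rexp(config$n_genera)
  sp_genus_idx <- sample(config$n_genera, config$n_species, replace = TRUE,
                         prob = gw)
  species <- sprintf("%s sp%03d", genera[sp_genus_idx],
                     seq_len(config$n_species))

  lam_intra <- config$mean_intra / 100 * L / 2
  s_mean <- config$mean_nnd / 100 * L / 2
  s_min <- 4L
  s_lam <- max(s_mean - s_min, 0.5)

  genus_founders <- vapply(genera, function(g) {
    mutate_sequence(tpl, stats::rpois(1, 33), config$ti_tv)
  }, character(1))

  n_sp <- config$n_species
  roles <- rep("background", n_sp)
  avail <- seq_len(n_sp)
  take <- function(k) {
    picked <- avail[sample.int(length(avail), k)]
    avail <<- setdiff(avail, picked)
    picked
  }
  sharing_a <- take(config$n_sharing_pairs)
  sharing_b <- take(config$n_sharing_pairs)
  deep_idx <- take(config$n_deep_splits)
  lowdiv_a <- take(config$n_low_div_pairs)
  lowdiv_b <- take(config$n_low_div_pairs)
  introduced_idx <- take(config$n_introduced)
  neotrop_idx <- take(config$n_neotropical)

  introduced <- seq_len(n_sp) %in% introduced_idx
  founders <- character(n_sp)
  for (i in seq_len(n_sp)) {
    s <- s_min + stats::rpois(1, s_lam)
    if (introduced[i]) s <- round(s * config$introduced_nnd_factor)
    founders[i] <- mutate_sequence(genus_founders[[sp_genus_idx[i]]], s,
                                   config$ti_tv)
  }
  # Planted haplotype sharing: identical founders.
  founders[sharing_b] <- founders[sharing_a]
  # Planted low-divergence neighbors: a handful of substitutions apart.
  lowdiv_subs <- integer(config$n_low_div_pairs)
  if (config$n_low_div_pairs > 0) {
    sub_lo <- max(1L, round(config$low_div_range[1] / 100 * L))
    sub_hi <- max(sub_lo, floor(config$low_div_range[2] / 100 * L))
    for (k in seq_len(config$n_low_div_pairs)) {
      lowdiv_subs[k] <- sub_lo + sample.int(sub_hi - sub_lo + 1L, 1L) - 1L
      founders[lowdiv_b[k]] <- mutate_sequence(founders[lowdiv_a[k]],
                                               lowdiv_subs[k], config$ti_tv)
    }
  }
  # Planted deep splits: second founder at the planted depth.
  deep_depth <- rep(NA_real_, n_sp)
  founder2 <- rep(NA_character_, n_sp)
  for (i in deep_idx) {
    depth <- stats::runif(1, config$deep_split_range[1],
                          config$deep_split_range[2])
    deep_depth[i] <- depth
    founder2[i] <- mutate_sequence(founders[i], round(depth / 100 * L),
                                   config$ti_tv)
  }

  n_regions <- length(config$regions)
  region_names <- names(config$regions)
  occupancy <- lapply(seq_len(n_sp), function(i) {
    k <- min(1 + stats::rpois(1, config$occupancy_lam), n_regions)
    sample(region_names, k)
  })

  counts <- .r_specimens(n_sp, config$specimens_mean, config$specimens_max)
  counts[deep_idx] <- pmax(counts[deep_idx], 2L)

  seqs <- vector("list", n_sp)
  meta_rows <- vector("list", n_sp)
  next_id <- 1L
  for (i in seq_len(n_sp)) {
    m <- counts[i]
    lam <- lam_intra *
      (if (introduced[i]) config$introduced_intra_factor else 1)
    sub2 <- rep(FALSE, m)
    if (i %in% deep_idx) sub2[seq(2, m, by = 2)] <- TRUE
    sp_seqs <- character(m)
    for (k in seq_len(m)) {
      base <- if (sub2[k]) founder2[i] else founders[i]
      nmut <- if (k == 1 || (i %in% deep_idx && k == 2)) 0L else
        stats::rpois(1, lam)
      sp_seqs[k] <- if (nmut == 0) base else
        mutate_sequence(base, nmut, config$ti_tv)
    }
    ids <- sprintf("SP%05d", next_id:(next_id + m - 1))
    next_id <- next_id + m
    names(sp_seqs) <- ids
    seqs[[i]] <- sp_seqs

    reg <- sample(occupancy[[i]], m, replace = TRUE)
    centers <- do.call(rbind, config$regions[reg])
    zoo <- rep("Nearctic", m)
    if (introduced[i]) zoo[1] <- "Palaearctic"
    if (i %in% neotrop_idx) zoo[m] <- "Neotropical"
    meta_rows[[i]] <- data.frame(
      specimen_id = ids,
      species = species[i],
      genus = genera[sp_genus_idx[i]],
      family = genus_family[sp_genus_idx[i]],
      bin_id = NA_character_,
      latitude = round(centers[, 1] + stats::rnorm(m, sd = 1.5), 4),
      longitude = round(centers[, 2] + stats::rnorm(m, sd = 2), 4),
      ecoregion = reg,
      zoogeo_region = zoo,
      status = if (introduced[i]) "introduced" else "native",
      stringsAsFactors = FALSE)
  }

  meta <- do.call(rbind, meta_rows)
  sequences <- unlist(seqs)
  collection <- specimen_collection(meta, sequences)

  # Expected concordance category under the generator's own single-linkage
  # clustering at the 2.2% surrogate threshold.  Computed, not assumed:
  # background congeners may legitimately fall below the threshold and
  # merge, exactly as real libraries do.
  dm <- pairwise_matrix(collection)
  part <- single_linkage_clusters(dm, 2.2)
  rec <- concordance_classify(collection, part)
  expected <- rec$category[match(species, rec$species)]
  partner <- rep(NA_character_, n_sp)
  partner[sharing_a] <- species[sharing_b]
  partner[sharing_b] <- species[sharing_a]
  lowdiv_partner <- rep(NA_character_, n_sp)
  lowdiv_partner[lowdiv_a] <- species[lowdiv_b]
  lowdiv_partner[lowdiv_b] <- species[lowdiv_a]
  truth <- data.frame(
    species = species, genus = genera[sp_genus_idx],
    family = genus_family[sp_genus_idx],
    n_specimens = counts, introduced = introduced,
    sharing_partner = partner,
    low_div_partner = lowdiv_partner,
    deep_split_depth = deep_depth,
    neotropical = seq_len(n_sp) %in% neotrop_idx,
    expected_category = expected,
    stringsAsFactors = FALSE)

  .verify_truth(collection, truth, config)
  list(collection = collection, truth = truth, config = config)
}

# Generator self-check: planted structure must be present in the emitted
# sequences, and everything must pass the reading-frame QC.
.verify_truth <- function(collection, truth, config) {
  seqs <- collection$sequences
  meta <- collection$meta
  first_of <- function(sp) {
    seqs[[meta$specimen_id[meta$species == sp][1]]]
  }
  share <- truth[!is.na(truth$sharing_partner), ]
  for (i in seq_len(nrow(share))) {
    if (!identical(first_of(share$species[i]),
                   first_of(share$sharing_partner[i]))) {
      stop("internal error: planted sharing pair is not identical")
    }
  }
  deep <- truth[!is.na(truth$deep_split_depth), ]
  for (i in seq_len(nrow(deep))) {
    ids <- meta$specimen_id[meta$species == deep$species[i]][1:2]
    d <- k2p_distance(seqs[[ids[1]]], seqs[[ids[2]]])
    if (!d$defined || 100 * d$distance <= 2) {
      stop("internal error: planted deep split below 2%")
    }
  }
  rfc <- reading_frame_check(seqs)
  if (!all(rfc$pass, na.rm = TRUE)) {
    stop("internal error: generated sequence failed the reading-frame check")
  }
  invisible(TRUE)
}

#' Write a generated library to disk
#'
#' Emits the FASTA + TSV dialect the readers consume, plus `truth.json`.
#'
#' @param library output of [generate_library()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_library <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "library.fasta")
  tsv <- file.path(dir, "specimens.tsv")
  truth <- file.path(dir, "truth.json")
  write_barcode_fasta(library$collection$sequences, fasta)
  meta <- library$collection$meta
  meta$has_sequence <- NULL
  utils::write.table(meta, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  jsonlite::write_json(library$truth, truth, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(fasta, tsv, truth))
}
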