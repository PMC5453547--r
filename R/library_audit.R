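# Species-level diagnosability audit: category classification (sharing /
# low-divergence / deep-split / diagnostic), identification success, family
# summary table, and the genus-size sharing profile.

#' One-decimal percentage with half-up rounding
#'
#' Printed percentages round half-up (so 96.25 -> 96.3), not to even;
#' `decimals` defaults to the one-decimal convention of the summary tables.
#'
#' @param count numerator.
#' @param total denominator, must be positive.
#' @param decimals digits after the point.
#' @return rounded percentage (may be negative when `count` is).
#' @export
percentage <- function(count, total, decimals = 1L) {
  if (any(total <= 0)) stop("percentage(): total must be > 0")
  x <- 100 * count / total
  f <- 10^decimals
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

#' Classify species into diagnosability categories
#'
#' Categories follow the audit's definitions: `SHARING` when the species
#' belongs to a haplotype group with at least one other species;
#' `LOW_DIVERGENCE` when not sharing and the NN distance lies strictly
#' between 0 and `low_div_max` percent; `DEEP_SPLIT` when the maximum
#' intraspecific divergence exceeds `deep_split_min` percent (independent of
#' the other flags); `DIAGNOSTIC` is the complement of `SHARING` (deep-split
#' species stay diagnostic).  Species whose NN distance is undefined are
#' `UNASSESSED` and excluded from percentage denominators.
#'
#' @param nn_distance NN distance(s) in percent (`NA` = undefined).
#' @param sharing_flag logical, haplotype shared with another species.
#' @param intra_max maximum intraspecific divergence in percent (`NA` for
#'   singletons).
#' @param low_div_max,deep_split_min thresholds in percent (defaults 1.0
#'   and 2.0).
#' @return data frame of logical columns `sharing`, `low_divergence`,
#'   `deep_split`, `diagnostic`, `assessed`.
#' @export
classify_species <- function(nn_distance, sharing_flag, intra_max,
                             low_div_max = 1.0, deep_split_min = 2.0) {
  assessed <- !is.na(nn_distance)
  sharing <- assessed & sharing_flag
  low_div <- assessed & !sharing & !is.na(nn_distance) &
    nn_distance > 0 & nn_distance < low_div_max
  deep <- !is.na(intra_max) & intra_max > deep_split_min
  diagnostic <- assessed & !sharing
  data.frame(sharing = sharing, low_divergence = low_div,
             deep_split = deep, diagnostic = diagnostic,
             assessed = assessed)
}

#' Category set of one classified species
#' @param flags one row of [classify_species()] output.
#' @return character vector of category names.
#' @export
category_set <- function(flags) {
  if (!flags$assessed) return("UNASSESSED")
  out <- c(if (flags$sharing) "SHARING",
           if (flags$low_divergence) "LOW_DIVERGENCE",
           if (flags$deep_split) "DEEP_SPLIT",
           if (flags$diagnostic) "DIAGNOSTIC")
  out
}

# Species sharing a haplotype group with >= 1 other species.
.sharing_species <- function(haplotypes, species_by_id) {
  shared <- character(0)
  for (g in haplotypes$groups) {
    sp <- unique(species_by_id[g])
    if (length(sp) >= 2) shared <- c(shared, sp)
  }
  unique(shared)
}

# Species-level value of a per-specimen metadata column (modal value,
# alphabetical tie-break).
.species_field <- function(meta, field) {
  vapply(split(meta[[field]], meta$species), function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_character_)
    tab <- sort(table(v), decreasing = TRUE)
    names(tab)[1]
  }, character(1))
}

#' Run the continental diagnosability audit
#'
#' Computes the distance matrix, haplotype groups, per-species NN and
#' intraspecific summaries, and the category flags, for the sequenced
#' specimens of a collection.
#'
#' @param collection a `specimen_collection` with at least 2 sequenced
#'   species.
#' @param min_overlap minimum overlap for a defined distance (default 300).
#' @param haplotype_min_overlap minimum overlap for a sharing call
#'   (default 500).
#' @param low_div_max,deep_split_min category thresholds in percent.
#' @return list of class `library_audit`: `species` (the SpeciesSummary data
#'   frame), `distance` (`k2p_dist`), `haplotypes`, and the thresholds used.
#' @export
audit_library <- function(collection, min_overlap = 300L,
                          haplotype_min_overlap = 500L,
                          low_div_max = 1.0, deep_split_min = 2.0) {
  meta <- collection$meta[collection$meta$has_sequence, , drop = FALSE]
  if (nrow(meta) < 2) stop("need at least 2 sequenced specimens")
  dm <- pairwise_matrix(collection, min_overlap = min_overlap)
  hap <- collapse_haplotypes(dm, haplotype_min_overlap)
  species_by_id <- stats::setNames(meta$species, meta$specimen_id)
  nn <- species_nn(dm, species_by_id)

  shared_sp <- .sharing_species(hap, species_by_id)
  n_hap <- vapply(split(hap$membership[meta$specimen_id], meta$species),
                  function(g) length(unique(g)), integer(1))

  flags <- classify_species(nn$nn_distance, nn$species %in% shared_sp,
                            nn$intra_max, low_div_max, deep_split_min)
  genus <- .species_field(meta, "genus")
  family <- .species_field(meta, "family")
  status <- .species_field(meta, "status")

  species <- cbind(
    data.frame(species = nn$species,
               genus = as.character(genus[nn$species]),
               family = as.character(family[nn$species]),
               status = as.character(status[nn$species]),
               n_specimens = nn$n_specimens,
               n_haplotypes = as.integer(n_hap[nn$species]),
               intra_mean = nn$intra_mean, intra_max = nn$intra_max,
               nn_species = nn$nn_species, nn_distance = nn$nn_distance,
               stringsAsFactors = FALSE),
    flags)
  rownames(species) <- NULL
  structure(list(species = species, distance = dm, haplotypes = hap,
                 min_overlap = min_overlap,
                 haplotype_min_overlap = haplotype_min_overlap,
                 low_div_max = low_div_max,
                 deep_split_min = deep_split_min),
            class = "library_audit")
}

#' @export
print.library_audit <- function(x, ...) {
  s <- x$species
  ok <- sum(s$assessed)
  cat(sprintf(paste0("library_audit: %d species assessed; sharing %d, ",
                     "low-divergence %d, deep-split %d; ID success %.1f%%\n"),
              ok, sum(s$sharing), sum(s$low_divergence), sum(s$deep_split),
              identification_success(s)))
  invisible(x)
}

#' Identification success of an audited assemblage
#'
#' The percentage of assessed species that are diagnostic (do not share
#' their barcode), i.e. `100 - sharing percentage` before rounding.
#'
#' @param summaries SpeciesSummary data frame (from [audit_library()]) or a
#'   `library_audit`.
#' @param decimals rounding digits (default 1).
#' @return rounded percentage, or `NA` (with a warning) when no species is
#'   assessed.
#' @export
identification_success <- function(summaries, decimals = 1L) {
  if (inherits(summaries, "library_audit")) summaries <- summaries$species
  n <- sum(summaries$assessed)
  if (n == 0) {
    warning("no assessed species; identification success undefined")
    return(NA_real_)
  }
  percentage(sum(summaries$diagnostic & summaries$assessed), n, decimals)
}

#' Family-level summary table
#'
#' One row per family plus a `Total` row: species totals and barcode
#' coverage (counting sequence-less specimens toward "no barcodes"),
#' sequence and cluster counts, mean NN / intraspecific divergence over
#' assessed species, identification success and sharing count.
#'
#' @param collection the full `specimen_collection` (sequence-less records
#'   included).
#' @param summaries SpeciesSummary data frame from [audit_library()].
#' @param partition optional `cluster_partition` for per-family cluster
#'   counts.
#' @return data frame of family rows.
#' @export
family_table <- function(collection, summaries, partition = NULL) {
  meta <- collection$meta
  fam_all <- .species_field(meta, "family")
  fam_all[is.na(fam_all)] <- "Unknown"
  sp_all <- names(fam_all)
  barcoded <- sp_all %in% summaries$species
  seq_fam <- meta$family[meta$has_sequence]
  seq_fam[is.na(seq_fam)] <- "Unknown"
  cluster_by_id <- NULL
  if (!is.null(partition)) {
    cluster_by_id <- stats::setNames(partition$assignment$cluster,
                                     partition$assignment$specimen_id)
  }

  one <- function(fam, species_set, seq_count) {
    s <- summaries[summaries$species %in% species_set, , drop = FALSE]
    assessed <- s[s$assessed, , drop = FALSE]
    n_clusters <- NA_integer_
    if (!is.null(cluster_by_id)) {
      ids <- meta$specimen_id[meta$has_sequence &
                                meta$species %in% species_set]
      n_clusters <- length(unique(cluster_by_id[ids]))
    }
    data.frame(
      family = fam,
      species_total = length(species_set),
      species_barcoded = sum(species_set %in% summaries$species),
      coverage_pct = percentage(sum(species_set %in% summaries$species),
                                length(species_set)),
      n_sequences = seq_count,
      n_clusters = n_clusters,
      mean_nnd = if (nrow(assessed)) mean(assessed$nn_distance) else NA_real_,
      mean_intra = if (any(!is.na(assessed$intra_mean))) {
        mean(assessed$intra_mean, na.rm = TRUE)
      } else NA_real_,
      id_success_pct = if (nrow(assessed)) {
        percentage(sum(assessed$diagnostic), nrow(assessed))
      } else NA_real_,
      n_sharing = sum(s$sharing),
      stringsAsFactors = FALSE)
  }

  fams <- sort(unique(fam_all))
  rows <- lapply(fams, function(f) {
    one(f, sp_all[fam_all == f], sum(seq_fam == f))
  })
  total <- one("Total", sp_all, sum(meta$has_sequence))
  out <- do.call(rbind, c(rows, list(total)))
  rownames(out) <- NULL
  out
}

# Fig-2-style log2 size category: {1}, {2-3}, {4-7}, {8-15}, {16-31},
# {32-63}, {>=64}.
.log2_bin <- function(n) pmin(floor(log2(pmax(n, 1))) + 1L, 7L)

#' Genus-size sharing profile
#'
#' Bins genera by species count on a log2 scale and pools barcode-sharing
#' incidence per bin.
#'
#' @param summaries SpeciesSummary data frame.
#' @return list: `genera` (genus, n_species, n_sharing, log2_bin) and `bins`
#'   (bin, n_genera, n_species, n_sharing, sharing_pct).
#' @export
genus_sharing_profile <- function(summaries) {
  s <- summaries[!is.na(summaries$genus), , drop = FALSE]
  gen <- data.frame(
    genus = sort(unique(s$genus)),
    stringsAsFactors = FALSE)
  gen$n_species <- as.integer(table(s$genus)[gen$genus])
  gen$n_sharing <- as.integer(tapply(s$sharing, s$genus, sum)[gen$genus])
  gen$log2_bin <- .log2_bin(gen$n_species)

  bins <- data.frame(bin = 1:7)
  bins$n_genera <- vapply(bins$bin, function(b) {
    sum(gen$log2_bin == b)
  }, integer(1))
  bins$n_species <- vapply(bins$bin, function(b) {
    sum(gen$n_species[gen$log2_bin == b])
  }, integer(1))
  bins$n_sharing <- vapply(bins$bin, function(b) {
    sum(gen$n_sharing[gen$log2_bin == b])
  }, integer(1))
  bins$sharing_pct <- ifelse(bins$n_species > 0,
                             percentage(bins$n_sharing,
                                        pmax(bins$n_species, 1)), NA_real_)
  list(genera = gen, bins = bins)
}
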