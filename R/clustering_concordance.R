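# Cluster assignment (supplied BIN labels or a single-linkage surrogate) and
# species <-> cluster concordance.  The single-linkage clustering is a
# documented surrogate for the registry-based BIN algorithm: supplied labels
# are always preferred when available.

.new_partition <- function(assignment, source, threshold = NA_real_) {
  structure(list(assignment = assignment, source = source,
                 threshold = threshold),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("cluster_partition (%s%s): %d specimens in %d clusters\n",
              x$source,
              if (!is.na(x$threshold)) sprintf(", threshold %.2f%%",
                                               x$threshold) else "",
              nrow(x$assignment), length(unique(x$assignment$cluster))))
  invisible(x)
}

#' Single-linkage OTU clustering at a distance threshold
#'
#' Clusters are the connected components of the graph joining specimen pairs
#' whose defined K2P distance is at most `threshold` percent.  Labels are
#' deterministic: the lexicographically smallest member id.  Specimens with
#' no defined comparison become flagged singletons.
#'
#' @param matrix a `k2p_dist`.
#' @param threshold linkage threshold in percent (default 2.2, the usual
#'   seed threshold for barcode OTUs).
#' @return a `cluster_partition` whose `assignment` has columns
#'   `specimen_id`, `cluster`, `isolated`.
#' @export
single_linkage_clusters <- function(matrix, threshold = 2.2) {
  stopifnot(threshold > 0)
  x <- matrix
  idx <- .pair_indices(x$n)
  edge <- x$defined & x$distance <= threshold / 100
  comp <- .uf_components(x$n, idx$i[edge], idx$j[edge])
  label <- vapply(split(x$ids, comp), function(g) sort(g)[1], character(1))
  has_def <- logical(x$n)
  sel <- x$defined
  has_def[unique(c(idx$i[sel], idx$j[sel]))] <- TRUE
  assignment <- data.frame(
    specimen_id = x$ids,
    cluster = as.character(label[as.character(comp)]),
    isolated = !has_def,
    stringsAsFactors = FALSE)
  .new_partition(assignment, "single_linkage", threshold)
}

#' Partition from externally supplied BIN labels
#'
#' @param collection a `specimen_collection` whose sequenced specimens all
#'   carry a `bin_id`.
#' @return a `cluster_partition` with `source = "supplied_bins"`.
#' @export
supplied_bins <- function(collection) {
  meta <- collection$meta[collection$meta$has_sequence, , drop = FALSE]
  if (any(is.na(meta$bin_id))) {
    stop(sum(is.na(meta$bin_id)),
         " sequenced specimen(s) lack a bin_id; cannot use supplied BINs")
  }
  assignment <- data.frame(specimen_id = meta$specimen_id,
                           cluster = meta$bin_id, isolated = FALSE,
                           stringsAsFactors = FALSE)
  .new_partition(assignment, "supplied_bins")
}

#' Classify species-to-cluster concordance
#'
#' `MATCH`: one cluster, not shared with another species; `SPLIT`: several
#' clusters, none shared; `MERGE`: one cluster, shared; `MIXTURE`: several
#' clusters, at least one shared.
#'
#' @param species_map named character vector, specimen id -> species, or a
#'   `specimen_collection`.
#' @param partition a `cluster_partition` covering the same specimens.
#' @return data frame: `species`, `n_clusters`, `clusters`,
#'   `shares_cluster`, `category`.
#' @export
concordance_classify <- function(species_map, partition) {
  if (inherits(species_map, "specimen_collection")) {
    meta <- species_map$meta[species_map$meta$has_sequence, , drop = FALSE]
    species_map <- stats::setNames(meta$species, meta$specimen_id)
  }
  asg <- partition$assignment
  if (!all(asg$specimen_id %in% names(species_map))) {
    stop("partition contains specimens absent from the species map")
  }
  sp <- species_map[asg$specimen_id]
  cl_species <- lapply(split(sp, asg$cluster), unique)
  shared_cluster <- names(cl_species)[lengths(cl_species) >= 2]
  sp_clusters <- lapply(split(asg$cluster, sp), unique)

  species <- sort(names(sp_clusters))
  n_cl <- lengths(sp_clusters)[species]
  shares <- vapply(sp_clusters[species], function(cl) {
    any(cl %in% shared_cluster)
  }, logical(1))
  category <- ifelse(n_cl == 1,
                     ifelse(shares, "MERGE", "MATCH"),
                     ifelse(shares, "MIXTURE", "SPLIT"))
  data.frame(
    species = species,
    n_clusters = as.integer(n_cl),
    clusters = vapply(sp_clusters[species], function(cl) {
      paste(sort(cl), collapse = ",")
    }, character(1)),
    shares_cluster = shares,
    category = category,
    stringsAsFactors = FALSE,
    row.names = NULL)
}

#' Summary counts of concordance categories
#'
#' @param records output of [concordance_classify()].
#' @return list: `n_match`, `n_split`, `n_merge`, `n_mixture`, `n_species`,
#'   `pct_match`, and `histogram` of split multiplicities (species occupying
#'   2 / 3 / >=4 clusters).
#' @export
concordance_counts <- function(records) {
  stopifnot(nrow(records) >= 1)
  cat_n <- function(x) sum(records$category == x)
  multi <- records$n_clusters[records$n_clusters >= 2]
  list(n_match = cat_n("MATCH"), n_split = cat_n("SPLIT"),
       n_merge = cat_n("MERGE"), n_mixture = cat_n("MIXTURE"),
       n_species = nrow(records),
       pct_match = percentage(cat_n("MATCH"), nrow(records)),
       histogram = c(`2` = sum(multi == 2), `3` = sum(multi == 3),
                     `>=4` = sum(multi >= 4)))
}

#' Cluster count versus species count
#'
#' @param partition a `cluster_partition`.
#' @param species_map named specimen id -> species vector or a
#'   `specimen_collection`.
#' @return list: `n_clusters`, `n_species`, `excess_pct` (signed percentage
#'   of the cluster excess over the species count).
#' @export
bin_count_vs_species <- function(partition, species_map) {
  if (inherits(species_map, "specimen_collection")) {
    meta <- species_map$meta[species_map$meta$has_sequence, , drop = FALSE]
    species_map <- stats::setNames(meta$species, meta$specimen_id)
  }
  n_clusters <- length(unique(partition$assignment$cluster))
  n_species <- length(unique(species_map[partition$assignment$specimen_id]))
  list(n_clusters = n_clusters, n_species = n_species,
       excess_pct = percentage(n_clusters - n_species, n_species))
}

#' Write partition and concordance artifacts
#' @param partition a `cluster_partition`.
#' @param records optional concordance records.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_concordance <- function(partition, records = NULL, dir = ".") {
  paths <- character(0)
  p <- file.path(dir, "partition.tsv")
  asg <- partition$assignment
  asg$source <- partition$source
  utils::write.table(asg, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(records)) {
    p <- file.path(dir, "concordance.tsv")
    utils::write.table(records, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
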