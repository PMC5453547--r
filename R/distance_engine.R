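# Kimura-2-parameter distances under pairwise deletion, haplotype collapse,
# and per-species intraspecific / nearest-neighbor summaries.  Distances are
# fractions internally; reporting boundaries multiply by 100.

#' Encode aligned sequences as an integer matrix
#'
#' @param seqs character vector of equal-length aligned sequences.
#' @return integer matrix, one column per sequence (positions x specimens);
#'   0 marks positions excluded by pairwise deletion (N, gaps).
#' @keywords internal
encode_sequences <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    stop("sequences are not in a common frame (lengths ",
         paste(unique(lens), collapse = ", "), ")")
  }
  ch <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
               nrow = lens[1])
  codes <- .base_codes[ch]
  codes[is.na(codes)] <- 0L
  m <- matrix(as.integer(codes), nrow = lens[1])
  colnames(m) <- names(seqs)
  m
}

.k2p_from_counts <- function(overlap, ti, tv, min_overlap) {
  P <- ifelse(overlap > 0, ti / overlap, NA_real_)
  Q <- ifelse(overlap > 0, tv / overlap, NA_real_)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  defined <- overlap >= min_overlap & !is.na(w1) & w1 > 0 & w2 > 0
  d <- rep(NA_real_, length(overlap))
  d[defined] <- -0.5 * log(w1[defined]) - 0.25 * log(w2[defined])
  list(P = P, Q = Q, distance = d, defined = defined)
}

#' Kimura-2-parameter distance between two aligned sequences
#'
#' Pairwise deletion: only positions where both sequences have A/C/G/T count
#' toward the overlap.  With transition proportion P and transversion
#' proportion Q over the overlap, the distance is
#' \deqn{d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q).}
#' The comparison is flagged undefined when the overlap is below
#' `min_overlap` or either log argument is non-positive (saturation).
#'
#' @param a,b aligned sequences in the same frame.
#' @param min_overlap minimum comparable positions (default 300).
#' @return list: `overlap`, `transitions`, `transversions`, `P`, `Q`,
#'   `distance` (fraction), `defined`.
#' @export
k2p_distance <- function(a, b, min_overlap = 300L) {
  stopifnot(min_overlap >= 1)
  if (nchar(a) != nchar(b)) {
    stop("sequences of unequal frame length (", nchar(a), " vs ", nchar(b),
         ")")
  }
  codes <- encode_sequences(c(x = a, y = b))
  cnt <- pair_counts_cpp(codes)
  res <- .k2p_from_counts(cnt$overlap, cnt$transitions, cnt$transversions,
                          min_overlap)
  list(overlap = cnt$overlap[1], transitions = cnt$transitions[1],
       transversions = cnt$transversions[1], P = res$P[1], Q = res$Q[1],
       distance = res$distance[1], defined = res$defined[1])
}

#' All-pairs K2P distance matrix for a collection
#'
#' @param collection a `specimen_collection` (or a named character vector of
#'   aligned sequences).
#' @param min_overlap minimum comparable positions per pair (default 300).
#' @return object of class `k2p_dist`: ids plus condensed (lower-triangle,
#'   [stats::dist] order) vectors `overlap`, `transitions`, `transversions`,
#'   `distance` (fraction, `NA` when undefined) and `defined`.
#' @export
pairwise_matrix <- function(collection, min_overlap = 300L) {
  seqs <- if (inherits(collection, "specimen_collection")) {
    collection$sequences
  } else {
    collection
  }
  if (length(seqs) < 2) stop("need at least 2 sequenced specimens")
  codes <- encode_sequences(seqs)
  cnt <- pair_counts_cpp(codes)
  res <- .k2p_from_counts(cnt$overlap, cnt$transitions, cnt$transversions,
                          min_overlap)
  structure(list(ids = names(seqs), n = length(seqs),
                 overlap = cnt$overlap, transitions = cnt$transitions,
                 transversions = cnt$transversions,
                 P = res$P, Q = res$Q,
                 distance = res$distance, defined = res$defined,
                 min_overlap = min_overlap),
            class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat(sprintf("k2p_dist: %d specimens, %d pairs (%d undefined)\n",
              x$n, length(x$distance), sum(!x$defined)))
  invisible(x)
}

# Row/column indices of the condensed pair vectors, dist order (i < j).
.pair_indices <- function(n) {
  i <- rep.int(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n),
              use.names = FALSE)
  list(i = i, j = j)
}

#' Convert a `k2p_dist` to a full symmetric matrix
#' @param x a `k2p_dist`.
#' @param ... unused.
#' @return numeric matrix of distances (fractions); undefined pairs `NA`,
#'   diagonal 0.
#' @method as.matrix k2p_dist
#' @export
as.matrix.k2p_dist <- function(x, ...) {
  d <- x$distance
  attributes(d) <- list(Size = x$n, Labels = x$ids, Diag = FALSE,
                        Upper = FALSE, class = "dist")
  as.matrix(d)
}

#' Export a distance matrix
#'
#' `phylip`: square PHYLIP matrix (undefined pairs printed as -1).
#' `long`: TSV with columns id1, id2, overlap, P, Q, distance, defined.
#'
#' @param x a `k2p_dist`.
#' @param path output path.
#' @param format `"phylip"` or `"long"`.
#' @return `path`, invisibly.
#' @export
export_distances <- function(x, path, format = c("long", "phylip")) {
  format <- match.arg(format)
  if (format == "phylip") {
    m <- as.matrix(x)
    m[is.na(m)] <- -1
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", x$n), con)
    for (k in seq_len(x$n)) {
      writeLines(paste(c(formatC(x$ids[k], width = -10),
                         sprintf("%.6f", m[k, ])), collapse = " "), con)
    }
  } else {
    idx <- .pair_indices(x$n)
    df <- data.frame(id1 = x$ids[idx$i], id2 = x$ids[idx$j],
                     overlap = x$overlap, P = x$P, Q = x$Q,
                     distance = x$distance, defined = x$defined)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

# Minimal union-find (path halving, union to smaller root) used for
# haplotype groups and single-linkage clusters.
.uf_components <- function(n, edges_i, edges_j) {
  parent <- seq_len(n)
  find <- function(x) {
    root <- x
    while (parent[root] != root) root <- parent[root]
    while (parent[x] != root) {
      nxt <- parent[x]
      parent[x] <<- root
      x <- nxt
    }
    root
  }
  for (k in seq_along(edges_i)) {
    ri <- find(edges_i[k])
    rj <- find(edges_j[k])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  vapply(seq_len(n), find, integer(1))
}

#' Collapse identical haplotypes
#'
#' Two specimens share a haplotype when their comparison is defined, has zero
#' mismatches over the overlap, and the overlap is at least
#' `haplotype_min_overlap`.  Haplotype groups are the connected components of
#' this relation (the relation itself is not transitive for partial
#' fragments, so the component closure is taken).
#'
#' @param matrix a `k2p_dist`.
#' @param haplotype_min_overlap minimum overlap for a sharing call
#'   (default 500).
#' @return list: `membership` (named integer, group per specimen) and
#'   `groups` (list of specimen-id vectors, labelled by their
#'   lexicographically smallest member).
#' @export
collapse_haplotypes <- function(matrix, haplotype_min_overlap = 500L) {
  x <- matrix
  idx <- .pair_indices(x$n)
  same <- x$defined & (x$transitions + x$transversions) == 0L &
    x$overlap >= haplotype_min_overlap
  comp <- .uf_components(x$n, idx$i[same], idx$j[same])
  groups <- split(x$ids, comp)
  labels <- vapply(groups, function(g) sort(g)[1], character(1))
  names(groups) <- labels
  membership <- stats::setNames(labels[match(comp, names(labels))], x$ids)
  list(membership = membership, groups = groups[order(labels)])
}

#' Per-species intraspecific and nearest-neighbor distances
#'
#' For every species, the nearest-neighbor (NN) distance is the minimum
#' defined interspecific specimen-pair distance and `nn_species` the species
#' attaining it; `intra_mean`/`intra_max` summarize defined within-species
#' pairs (missing for singletons).  Distances are reported in percent.
#'
#' @param matrix a `k2p_dist`.
#' @param species character vector of species labels, one per specimen, in
#'   matrix order (or named by specimen id).
#' @return data frame with one row per species: `species`, `n_specimens`,
#'   `intra_mean`, `intra_max`, `nn_species`, `nn_distance`, `nn_defined`.
#' @export
species_nn <- function(matrix, species) {
  x <- matrix
  if (!is.null(names(species))) species <- species[x$ids]
  stopifnot(length(species) == x$n)
  sp_levels <- sort(unique(species))
  if (length(sp_levels) < 2) stop("need at least 2 species")
  fac <- match(species, sp_levels)
  idx <- .pair_indices(x$n)
  fi <- fac[idx$i]; fj <- fac[idx$j]
  def <- x$defined
  d <- x$distance

  intra <- fi == fj & def
  intra_mean <- tapply(d[intra], fi[intra], mean)
  intra_max <- tapply(d[intra], fi[intra], max)

  inter <- fi != fj & def
  lo <- pmin(fi, fj)[inter]
  hi <- pmax(fi, fj)[inter]
  key <- (lo - 1) * length(sp_levels) + hi
  pair_min <- tapply(d[inter], key, min)
  key_vals <- as.numeric(names(pair_min))
  pair_lo <- (key_vals - 1) %/% length(sp_levels) + 1
  pair_hi <- (key_vals - 1) %% length(sp_levels) + 1

  nn_dist <- rep(NA_real_, length(sp_levels))
  nn_sp <- rep(NA_character_, length(sp_levels))
  for (s in seq_along(sp_levels)) {
    sel <- pair_lo == s | pair_hi == s
    if (!any(sel)) next
    dmin <- pair_min[sel]
    other <- ifelse(pair_lo[sel] == s, pair_hi[sel], pair_lo[sel])
    best <- which.min(dmin)  # ties: first (alphabetical partner) wins
    nn_dist[s] <- dmin[best]
    nn_sp[s] <- sp_levels[other[best]]
  }

  data.frame(
    species = sp_levels,
    n_specimens = as.integer(table(factor(fac, levels =
                                            seq_along(sp_levels)))),
    intra_mean = 100 * as.numeric(intra_mean[as.character(
      seq_along(sp_levels))]),
    intra_max = 100 * as.numeric(intra_max[as.character(
      seq_along(sp_levels))]),
    nn_species = nn_sp,
    nn_distance = 100 * nn_dist,
    nn_defined = !is.na(nn_dist),
    stringsAsFactors = FALSE)
}
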