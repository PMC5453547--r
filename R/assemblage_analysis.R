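# Assemblage-level re-analysis: partition the library by ecoregion,
# latitude/longitude band or zoogeographic region, recompute the audit inside
# each partition, and measure cross-region cluster overlap / endemism.

# The 15-region terrestrial scheme and its collapse to the 12 analysis
# regions (Arctic Cordillera + Tundra -> Arctic; Taiga + Hudson Plain +
# Northern Forests -> Boreal).
.ecoregion_collapse <- c(
  "arctic cordillera" = "Arctic",
  "tundra" = "Arctic",
  "taiga" = "Boreal",
  "hudson plain" = "Boreal",
  "hudson plains" = "Boreal",
  "northern forests" = "Boreal",
  "northwestern forested mountains" = "Northwestern Forested Mountains",
  "marine west coast forests" = "Marine West Coast Forests",
  "eastern temperate forests" = "Eastern Temperate Forests",
  "great plains" = "Great Plains",
  "north american deserts" = "North American Deserts",
  "mediterranean california" = "Mediterranean California",
  "southern semi-arid highlands" = "Southern Semi-Arid Highlands",
  "temperate sierras" = "Temperate Sierras",
  "tropical dry forests" = "Tropical Dry Forests",
  "tropical wet forests" = "Tropical Wet Forests",
  # already-collapsed labels pass through
  "arctic" = "Arctic",
  "boreal" = "Boreal")

#' Collapse raw ecoregion labels to the 12 analysis regions
#'
#' Arctic Cordillera and Tundra merge into `Arctic`; Taiga, Hudson Plain and
#' Northern Forests merge into `Boreal`; the other labels are unchanged.
#' Matching is case-insensitive and already-collapsed labels pass through.
#'
#' @param labels character vector of ecoregion labels (`NA` allowed).
#' @return character vector of analysis-region labels.
#' @export
collapse_ecoregions <- function(labels) {
  key <- tolower(trimws(labels))
  out <- .ecoregion_collapse[key]
  bad <- !is.na(labels) & is.na(out)
  if (any(bad)) {
    stop("unknown ecoregion label(s): ",
         paste(unique(labels[bad]), collapse = ", "),
         "; valid labels: ",
         paste(sort(unique(.ecoregion_collapse)), collapse = ", "),
         " (or the raw 15-region names)")
  }
  unname(out)
}

.band_label <- function(x, edges, prefix_lt, prefix_gt) {
  labs <- c(prefix_lt,
            paste0(edges[-length(edges)], "-", edges[-1]),
            prefix_gt)
  idx <- findInterval(x, edges, left.open = FALSE) + 1L  # lower-inclusive
  out <- labs[idx]
  out[is.na(x)] <- NA_character_
  out
}

#' Latitude band of a coordinate
#'
#' 5-degree bands with edges 25..55, lower-inclusive / upper-exclusive,
#' open extremes (`"<25"`, `">55"`).
#'
#' @param lat latitude in signed decimal degrees.
#' @return band labels.
#' @export
latitude_band <- function(lat) {
  .band_label(lat, seq(25, 55, by = 5), "<25", ">55")
}

#' Longitude band of a coordinate
#'
#' 10-degree bands over the absolute value of western longitudes (edges
#' 75..135), lower-inclusive.  Eastern (positive) longitudes return `NA`:
#' the east-west analysis is Nearctic-only.
#'
#' @param lon longitude in signed decimal degrees (western negative).
#' @return band labels, `NA` for missing or eastern coordinates.
#' @export
longitude_band <- function(lon) {
  out <- .band_label(abs(lon), seq(75, 135, by = 10), "<75", ">135")
  out[!is.na(lon) & lon > 0] <- NA_character_
  out
}

.partition_keys <- c("ecoregion", "lat_band", "lon_band", "zoogeo_region")

# Per-specimen partition label for a key; NA = excluded from that analysis.
.partition_labels <- function(meta, key) {
  switch(key,
         ecoregion = collapse_ecoregions(meta$ecoregion),
         lat_band = latitude_band(meta$latitude),
         lon_band = longitude_band(meta$longitude),
         zoogeo_region = meta$zoogeo_region,
         stop("unknown partition key '", key, "'; valid keys: ",
              paste(.partition_keys, collapse = ", ")))
}

.assemblage_row <- function(label, collection, min_overlap,
                            haplotype_min_overlap, low_div_max,
                            deep_split_min, cluster_threshold) {
  meta <- collection$meta[collection$meta$has_sequence, , drop = FALSE]
  n_seq <- nrow(meta)
  base <- data.frame(
    partition = label, n_sequences = n_seq,
    n_clusters = NA_integer_,
    n_species = length(unique(meta$species)),
    n_genera = length(unique(meta$genus)),
    mean_nnd = NA_real_, max_nnd = NA_real_,
    mean_intra = NA_real_, max_intra = NA_real_,
    id_success_pct = NA_real_, n_sharing = NA_integer_,
    stringsAsFactors = FALSE)
  if (n_seq < 2) {
    base$n_clusters <- n_seq
    base$n_sharing <- 0L
    return(base)
  }
  dm <- pairwise_matrix(collection, min_overlap = min_overlap)
  part <- single_linkage_clusters(dm, cluster_threshold)
  base$n_clusters <- length(unique(part$assignment$cluster))
  if (base$n_species < 2) {
    base$n_sharing <- 0L
    intra <- dm$defined
    if (any(intra)) {
      base$mean_intra <- 100 * mean(dm$distance[intra])
      base$max_intra <- 100 * max(dm$distance[intra])
    }
    return(base)
  }
  audit <- audit_library(collection, min_overlap = min_overlap,
                         haplotype_min_overlap = haplotype_min_overlap,
                         low_div_max = low_div_max,
                         deep_split_min = deep_split_min)
  s <- audit$species
  assessed <- s[s$assessed, , drop = FALSE]
  base$mean_nnd <- if (nrow(assessed)) mean(assessed$nn_distance) else
    NA_real_
  base$max_nnd <- if (nrow(assessed)) max(assessed$nn_distance) else NA_real_
  if (any(!is.na(s$intra_mean))) {
    base$mean_intra <- mean(s$intra_mean, na.rm = TRUE)
    base$max_intra <- max(s$intra_max, na.rm = TRUE)
  }
  base$id_success_pct <- if (nrow(assessed)) {
    percentage(sum(assessed$diagnostic), nrow(assessed))
  } else NA_real_
  base$n_sharing <- sum(s$sharing)
  base
}

#' Partition the library and recompute the audit per assemblage
#'
#' Within each partition (ecoregion, latitude band, longitude band or
#' zoogeographic region) the distances, clusters, sharing and identification
#' success are recomputed from only that partition's specimens.  A pooled
#' `Total` row (all specimens carrying the key) is appended.
#'
#' @param collection a `specimen_collection`.
#' @param key one of `"ecoregion"`, `"lat_band"`, `"lon_band"`,
#'   `"zoogeo_region"`.
#' @param min_overlap,haplotype_min_overlap,low_div_max,deep_split_min audit
#'   settings, as in [audit_library()].
#' @param cluster_threshold single-linkage threshold in percent.
#' @return data frame of assemblage rows; attribute `n_skipped` counts
#'   specimens lacking the key.
#' @export
partition_and_summarize <- function(collection, key,
                                    min_overlap = 300L,
                                    haplotype_min_overlap = 500L,
                                    low_div_max = 1.0, deep_split_min = 2.0,
                                    cluster_threshold = 2.2) {
  labels <- .partition_labels(collection$meta, key)
  skipped <- sum(is.na(labels))
  if (skipped > 0) {
    message(skipped, " specimen(s) lack '", key, "' and were skipped")
  }
  keep <- !is.na(labels)
  parts <- sort(unique(labels[keep]))
  rows <- lapply(parts, function(p) {
    ids <- collection$meta$specimen_id[keep & labels == p]
    .assemblage_row(p, subset_collection(collection, ids), min_overlap,
                    haplotype_min_overlap, low_div_max, deep_split_min,
                    cluster_threshold)
  })
  total <- .assemblage_row(
    "Total", subset_collection(collection,
                               collection$meta$specimen_id[keep]),
    min_overlap, haplotype_min_overlap, low_div_max, deep_split_min,
    cluster_threshold)
  out <- do.call(rbind, c(rows, list(total)))
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}

#' Species-by-partition presence/absence matrix
#'
#' @param collection a `specimen_collection`.
#' @param key partition key as in [partition_and_summarize()].
#' @return logical matrix, species rows by partition columns; attribute
#'   `n_skipped` counts specimens lacking the key.
#' @export
presence_absence_matrix <- function(collection, key) {
  labels <- .partition_labels(collection$meta, key)
  keep <- !is.na(labels)
  sp <- sort(unique(collection$meta$species[keep]))
  parts <- sort(unique(labels[keep]))
  m <- matrix(FALSE, nrow = length(sp), ncol = length(parts),
              dimnames = list(sp, parts))
  pairs <- unique(data.frame(sp = collection$meta$species[keep],
                             part = labels[keep]))
  m[cbind(pairs$sp, pairs$part)] <- TRUE
  attr(m, "n_skipped") <- sum(!keep)
  m
}

#' Cluster overlap among zoogeographic regions and endemism
#'
#' For every cluster, the set of zoogeographic regions of its member
#' specimens; per family and overall, the count and percentage of clusters
#' present in each region.  Endemics are clusters present in the home region
#' (default `Nearctic`) only.
#'
#' @param partition a `cluster_partition`.
#' @param collection a `specimen_collection` providing `zoogeo_region` and
#'   `family` per specimen.
#' @param home_region endemism reference region.
#' @return list: `matrix` (clusters x regions logical), `family_table`
#'   (per-family counts and percentages per region), `endemic`
#'   (`n`, `pct`), `n_clusters`.
#' @export
region_overlap <- function(partition, collection, home_region = "Nearctic") {
  meta <- collection$meta
  asg <- partition$assignment
  reg <- stats::setNames(meta$zoogeo_region, meta$specimen_id)[
    asg$specimen_id]
  fam <- stats::setNames(meta$family, meta$specimen_id)[asg$specimen_id]
  has_reg <- !is.na(reg)
  if (!all(has_reg)) {
    message(sum(!has_reg),
            " specimen(s) lack zoogeo_region and were skipped")
  }
  cl <- asg$cluster[has_reg]
  cl_regions <- lapply(split(reg[has_reg], cl), unique)
  regions <- .zoogeo_regions[.zoogeo_regions %in% unlist(cl_regions)]
  extra <- setdiff(sort(unique(unlist(cl_regions))), .zoogeo_regions)
  regions <- c(regions, extra)
  clusters <- sort(names(cl_regions))
  m <- matrix(FALSE, nrow = length(clusters), ncol = length(regions),
              dimnames = list(clusters, regions))
  for (cname in clusters) m[cname, cl_regions[[cname]]] <- TRUE

  cl_family <- vapply(split(fam[has_reg], cl), function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return("Unknown")
    names(sort(table(v), decreasing = TRUE))[1]
  }, character(1))[clusters]

  fam_rows <- function(fam_name, rows) {
    counts <- colSums(m[rows, , drop = FALSE])
    pcts <- percentage(counts, length(rows))
    df <- data.frame(family = fam_name, n_clusters = length(rows),
                     stringsAsFactors = FALSE)
    for (r in regions) {
      df[[paste0(r, "_n")]] <- counts[[r]]
      df[[paste0(r, "_pct")]] <- pcts[[r]]
    }
    df
  }
  fams <- sort(unique(cl_family))
  tab <- do.call(rbind, c(
    lapply(fams, function(f) fam_rows(f, which(cl_family == f))),
    list(fam_rows("Total", seq_along(clusters)))))
  rownames(tab) <- NULL

  endemic_n <- if (home_region %in% regions) {
    sum(m[, home_region] & rowSums(m) == 1)
  } else 0L
  list(matrix = m, family_table = tab,
       endemic = list(region = home_region, n = endemic_n,
                      pct = percentage(endemic_n, length(clusters))),
       n_clusters = length(clusters))
}
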