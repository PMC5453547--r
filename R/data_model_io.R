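# Input/output and validation for the two library artifacts: an aligned COI
# FASTA in the fixed 658-position barcode frame, and a tab-separated specimen
# table.  All downstream analysis consumes the specimen_collection built here.

.valid_status <- c("native", "introduced", "extraterritorial", "unknown")
.zoogeo_regions <- c("Nearctic", "Neotropical", "Palaearctic", "Ethiopian",
                     "Oriental", "Australian")
.iupac_ambiguity <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

.empty_report <- function() {
  data.frame(specimen_id = character(), field = character(),
             issue = character(), detail = character(),
             stringsAsFactors = FALSE)
}

.report_row <- function(id, field, issue, detail = "") {
  data.frame(specimen_id = id, field = field, issue = issue,
             detail = detail, stringsAsFactors = FALSE)
}

.make_report <- function(rows, n_accepted, n_rejected) {
  rep <- do.call(rbind, c(list(.empty_report()), rows))
  structure(rep, class = c("validation_report", "data.frame"),
            n_accepted = n_accepted, n_rejected = n_rejected)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report: %d accepted, %d rejected, %d issue(s)\n",
              attr(x, "n_accepted"), attr(x, "n_rejected"), nrow(x)))
  if (nrow(x) > 0) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write a validation report as TSV and JSON
#'
#' @param report a `validation_report` as attached by the readers.
#' @param tsv,json output paths; either may be `NULL` to skip that format.
#' @return the report, invisibly.
#' @export
write_validation_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(as.data.frame(report), tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(n_accepted = attr(report, "n_accepted"),
           n_rejected = attr(report, "n_rejected"),
           issues = as.data.frame(report)),
      json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

# Upper-case, U->T, '.'/'~' -> '-', non-N IUPAC ambiguity -> N.  Returns the
# normalized string plus counts used for report entries.
.normalize_sequence <- function(seq) {
  s <- gsub("[.~]", "-", chartr("U", "T", toupper(seq)))
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  ambiguous <- ch %in% .iupac_ambiguity
  unknown <- !(ch %in% c("A", "C", "G", "T", "N", "-")) & !ambiguous
  ch[ambiguous] <- "N"
  list(seq = paste(ch, collapse = ""),
       n_ambiguous = sum(ambiguous),
       unknown_chars = unique(ch[unknown]))
}

# Right-pad to the 658-position frame; positions outside the sequenced
# fragment are '-'.
.pad_to_frame <- function(seq, frame_length = .frame_length) {
  n <- nchar(seq)
  if (n >= frame_length) return(seq)
  paste0(seq, strrep("-", frame_length - n))
}

#' Count defined (A/C/G/T) positions of aligned sequences
#'
#' @param seqs character vector of aligned sequences.
#' @return integer vector of defined lengths.
#' @export
defined_length <- function(seqs) {
  vapply(seqs, function(s) sum(strsplit(s, "", fixed = TRUE)[[1]] %in%
                                 c("A", "C", "G", "T")),
         integer(1), USE.NAMES = FALSE)
}

#' Read an aligned barcode FASTA
#'
#' Reads a FASTA of COI barcodes pre-aligned to the common 658-position frame.
#' Sequence text is upper-cased; `U` becomes `T`; `.` and `~` become `-`;
#' IUPAC ambiguity codes other than `N` are mapped to `N` (reported).
#' Sequences shorter than the frame are right-padded with `-`.  The specimen
#' id is the header text up to the first `header_delimiter`.
#'
#' @param path FASTA file path.
#' @param header_delimiter character separating the id from trailing header
#'   fields (default `"|"`).
#' @param frame_length the common frame length (default 658).
#' @return list with `sequences` (named character vector) and `report`
#'   (a `validation_report`).
#' @export
read_barcode_fasta <- function(path, header_delimiter = "|",
                               frame_length = .frame_length) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), header_delimiter, fixed = TRUE),
                function(x) trimws(x[[1]]), character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate specimen id(s) in FASTA: ",
         paste(unique(dup), collapse = ", "),
         " (each appears in more than one record)")
  }
  raw <- as.character(set)
  rows <- list()
  keep <- rep(TRUE, length(ids))
  out <- character(length(ids))
  for (i in seq_along(ids)) {
    if (nchar(raw[i]) == 0) {
      keep[i] <- FALSE
      rows[[length(rows) + 1]] <- .report_row(ids[i], "sequence",
                                              "empty_sequence")
      next
    }
    norm <- .normalize_sequence(raw[i])
    if (length(norm$unknown_chars) > 0) {
      keep[i] <- FALSE
      rows[[length(rows) + 1]] <- .report_row(
        ids[i], "sequence", "unknown_character",
        paste(norm$unknown_chars, collapse = ","))
      next
    }
    if (nchar(norm$seq) > frame_length) {
      keep[i] <- FALSE
      rows[[length(rows) + 1]] <- .report_row(
        ids[i], "sequence", "too_long",
        sprintf("%d > frame %d", nchar(norm$seq), frame_length))
      next
    }
    if (norm$n_ambiguous > 0) {
      rows[[length(rows) + 1]] <- .report_row(
        ids[i], "sequence", "ambiguity_to_N", as.character(norm$n_ambiguous))
    }
    out[i] <- .pad_to_frame(norm$seq, frame_length)
  }
  sequences <- stats::setNames(out[keep], ids[keep])
  list(sequences = sequences,
       report = .make_report(rows, sum(keep), sum(!keep)))
}

#' Write aligned barcode sequences as FASTA
#'
#' @param sequences named character vector of aligned sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_barcode_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a specimen metadata table and attach sequences
#'
#' The table is UTF-8 TSV with a header row.  `specimen_id` and `species` are
#' required; `genus`, `family`, `bin_id`, `latitude`, `longitude`,
#' `ecoregion`, `zoogeo_region` and `status` are optional.  `genus` defaults
#' to the first token of the binomial.  Rows without a matching sequence are
#' kept and flagged sequence-less so species without barcodes still count in
#' coverage reporting.  Out-of-range or unparseable coordinates are cleared to
#' `NA` with a report entry; unrecognized status values become `"unknown"`.
#'
#' @param path TSV path.
#' @param sequences named character vector from [read_barcode_fasta()], or
#'   `NULL` for a metadata-only collection.
#' @return list with `collection` (a `specimen_collection`) and `report`.
#' @export
read_specimen_table <- function(path, sequences = NULL) {
  if (!file.exists(path)) stop("specimen table not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = c("NA", ""),
                           check.names = FALSE, fileEncoding = "UTF-8")
  required <- c("specimen_id", "species")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("specimen table lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  optional <- c("genus", "family", "bin_id", "latitude", "longitude",
                "ecoregion", "zoogeo_region", "status")
  for (col in setdiff(optional, names(tab))) tab[[col]] <- NA_character_
  rows <- list()
  keep <- rep(TRUE, nrow(tab))

  bad_species <- is.na(tab$species) | trimws(tab$species) == ""
  for (i in which(bad_species)) {
    rows[[length(rows) + 1]] <- .report_row(tab$specimen_id[i], "species",
                                            "empty_species")
  }
  keep[bad_species] <- FALSE

  dup <- tab$specimen_id[keep][duplicated(tab$specimen_id[keep])]
  if (length(dup) > 0) {
    stop("duplicate specimen id(s) in table: ",
         paste(unique(dup), collapse = ", "))
  }

  parse_coord <- function(values, field, lo, hi) {
    num <- suppressWarnings(as.numeric(values))
    bad <- (!is.na(values)) & (is.na(num) | num < lo | num > hi)
    for (i in which(bad & keep)) {
      rows[[length(rows) + 1]] <<- .report_row(tab$specimen_id[i], field,
                                               "bad_coordinate", values[i])
    }
    num[bad] <- NA_real_
    num
  }
  lat <- parse_coord(tab$latitude, "latitude", -90, 90)
  lon <- parse_coord(tab$longitude, "longitude", -180, 180)

  status <- tolower(ifelse(is.na(tab$status), "unknown", tab$status))
  bad_status <- !(status %in% .valid_status)
  for (i in which(bad_status & keep)) {
    rows[[length(rows) + 1]] <- .report_row(tab$specimen_id[i], "status",
                                            "unknown_status", tab$status[i])
  }
  status[bad_status] <- "unknown"

  genus <- tab$genus
  derive <- is.na(genus) | trimws(genus) == ""
  first_token <- vapply(strsplit(trimws(tab$species), "\\s+"),
                        function(x) x[[1]], character(1))
  genus[derive] <- first_token[derive]

  meta <- data.frame(
    specimen_id = tab$specimen_id[keep],
    species = trimws(tab$species[keep]),
    genus = genus[keep],
    family = tab$family[keep],
    bin_id = tab$bin_id[keep],
    latitude = lat[keep],
    longitude = lon[keep],
    ecoregion = tab$ecoregion[keep],
    zoogeo_region = tab$zoogeo_region[keep],
    status = status[keep],
    stringsAsFactors = FALSE)

  coll <- specimen_collection(meta, sequences)
  list(collection = coll,
       report = .make_report(rows, sum(keep), sum(!keep)))
}

#' Construct a specimen collection
#'
#' Binds specimen metadata to aligned sequences.  Sequences whose id is
#' absent from `meta` are dropped; specimens without a sequence are kept and
#' flagged via `has_sequence`.
#'
#' @param meta data frame with at least `specimen_id` and `species`.
#' @param sequences named character vector of aligned sequences (may be
#'   `NULL`).
#' @return object of class `specimen_collection`: list with `meta` and
#'   `sequences`.
#' @export
specimen_collection <- function(meta, sequences = NULL) {
  stopifnot(is.data.frame(meta), all(c("specimen_id", "species") %in%
                                       names(meta)))
  if (anyDuplicated(meta$specimen_id)) {
    stop("duplicate specimen id(s) in metadata")
  }
  for (col in c("genus", "family", "bin_id", "ecoregion", "zoogeo_region")) {
    if (is.null(meta[[col]])) meta[[col]] <- NA_character_
  }
  if (is.null(meta$status)) meta$status <- "unknown"
  for (col in c("latitude", "longitude")) {
    if (is.null(meta[[col]])) meta[[col]] <- NA_real_
  }
  if (is.null(sequences)) sequences <- stats::setNames(character(0),
                                                       character(0))
  sequences <- sequences[names(sequences) %in% meta$specimen_id]
  meta$has_sequence <- meta$specimen_id %in% names(sequences)
  structure(list(meta = meta, sequences = sequences),
            class = "specimen_collection")
}

#' @export
print.specimen_collection <- function(x, ...) {
  cat(sprintf(
    "specimen_collection: %d specimens (%d sequenced), %d species, %d families\n",
    nrow(x$meta), sum(x$meta$has_sequence),
    length(unique(x$meta$species)),
    length(unique(x$meta$family[!is.na(x$meta$family)]))))
  invisible(x)
}

#' Subset a collection by specimen ids
#' @param collection a `specimen_collection`.
#' @param ids specimen ids to keep.
#' @return a `specimen_collection`.
#' @export
subset_collection <- function(collection, ids) {
  meta <- collection$meta[collection$meta$specimen_id %in% ids, ,
                          drop = FALSE]
  rownames(meta) <- NULL
  meta$has_sequence <- NULL
  specimen_collection(meta, collection$sequences)
}

#' Filter short sequence records
#'
#' Drops sequenced records whose defined length (A/C/G/T positions) is below
#' `min_len`, except ids in `whitelist` (retained short-but-diagnostic
#' fragments).  Sequence-less records are untouched.
#'
#' @param collection a `specimen_collection`.
#' @param min_len minimum defined length (default 500, the record floor).
#' @param whitelist specimen ids exempt from the filter.
#' @return list with the filtered `collection` and a `report` listing
#'   removals.
#' @export
length_filter <- function(collection, min_len = 500L,
                          whitelist = character()) {
  stopifnot(min_len >= 1)
  seqs <- collection$sequences
  dl <- defined_length(seqs)
  drop <- names(seqs)[dl < min_len & !(names(seqs) %in% whitelist)]
  rows <- lapply(drop, function(id) {
    .report_row(id, "sequence", "below_min_length",
                sprintf("%d < %d", dl[[which(names(seqs) == id)]], min_len))
  })
  keep_ids <- setdiff(collection$meta$specimen_id, drop)
  out <- subset_collection(collection, keep_ids)
  list(collection = out,
       report = .make_report(rows, length(keep_ids), length(drop)))
}

#' Reading-frame check under the invertebrate mitochondrial code
#'
#' Translates the defined region of each sequence in all three frames and
#' keeps the frame with the fewest stop codons (ties broken by the lowest
#' frame).  A sequence passes when that minimum is zero.  Codons containing
#' `N` are skipped; a `-` strictly inside the sequenced region counts as a
#' frameshift failure.  Sequences with fewer than 30 defined positions give
#' an indeterminate (flagged, non-failing) result.
#'
#' @param seqs character vector of normalized aligned sequences.
#' @return data frame with one row per sequence: `frame` (1-3), `stop_codons`,
#'   `pass`, `frameshift`, `indeterminate`.
#' @export
reading_frame_check <- function(seqs) {
  one <- function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    if (sum(ch %in% c("A", "C", "G", "T")) < 30) {
      return(data.frame(frame = NA_integer_, stop_codons = NA_integer_,
                        pass = NA, frameshift = FALSE, indeterminate = TRUE))
    }
    span <- range(which(ch != "-"))
    region <- ch[span[1]:span[2]]
    if (any(region == "-")) {
      return(data.frame(frame = NA_integer_, stop_codons = NA_integer_,
                        pass = FALSE, frameshift = TRUE,
                        indeterminate = FALSE))
    }
    stops <- vapply(0:2, function(off) {
      sub <- region[(off + 1):length(region)]
      nc <- length(sub) %/% 3
      if (nc == 0) return(0L)
      cod <- matrix(sub[seq_len(nc * 3)], nrow = 3)
      has_n <- colSums(cod == "N") > 0
      codons <- apply(cod[, !has_n, drop = FALSE], 2, paste, collapse = "")
      sum(codons %in% .mito_stops)
    }, integer(1))
    best <- which.min(stops)  # ties -> lowest frame index
    data.frame(frame = best, stop_codons = stops[best],
               pass = stops[best] == 0L, frameshift = FALSE,
               indeterminate = FALSE)
  }
  out <- do.call(rbind, lapply(unname(seqs), one))
  if (!is.null(names(seqs))) out$specimen_id <- names(seqs)
  out
}
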