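# Fixture builders and independent oracles.  The oracles are deliberately
# pure-R, character-level reimplementations so they share no code with the
# compiled pair-counting path they check.

TPL <- coi_template()

# Substitute explicit positions/bases.
sub_at <- function(seq, pos, base) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch[pos] <- base
  paste(ch, collapse = "")
}

base_at <- function(seq, pos) substr(seq, pos, pos)

transition_base <- function(b) c(A = "G", G = "A", C = "T", T = "C")[[b]]
transversion_base <- function(b) {
  if (b %in% c("A", "G")) "C" else "A"
}

# Apply k transitions (and optionally transversions) at chosen positions.
with_transitions <- function(seq, pos) {
  for (p in pos) seq <- sub_at(seq, p, transition_base(base_at(seq, p)))
  seq
}
with_transversions <- function(seq, pos) {
  for (p in pos) seq <- sub_at(seq, p, transversion_base(base_at(seq, p)))
  seq
}

# A fragment of the frame: positions [from, to] kept, the rest gapped.
frag <- function(seq, from, to) {
  paste0(strrep("-", from - 1), substr(seq, from, to),
         strrep("-", nchar(seq) - to))
}

# Independent K2P oracle (character level, pairwise deletion).
oracle_k2p <- function(a, b, min_overlap = 300L) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  n <- sum(ok)
  ti <- sum(ok & ((ca == "A" & cb == "G") | (ca == "G" & cb == "A") |
                    (ca == "C" & cb == "T") | (ca == "T" & cb == "C")))
  tv <- sum(ok & ca != cb) - ti
  P <- ti / n
  Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  defined <- n >= min_overlap && w1 > 0 && w2 > 0
  list(overlap = n, transitions = ti, transversions = tv, P = P, Q = Q,
       distance = if (defined) -0.5 * log(w1) - 0.25 * log(w2) else
         NA_real_,
       defined = defined)
}

# Collection from named sequences plus parallel metadata vectors.
make_collection <- function(species, seqs, genus = NULL, family = "FamA",
                            ...) {
  meta <- data.frame(specimen_id = names(seqs), species = species,
                     stringsAsFactors = FALSE)
  meta$genus <- if (is.null(genus)) {
    vapply(strsplit(species, " "), `[[`, character(1), 1)
  } else genus
  meta$family <- family
  extra <- list(...)
  for (nm in names(extra)) meta[[nm]] <- extra[[nm]]
  specimen_collection(meta, seqs)
}

# Hand-built k2p_dist for clustering tests: `pct` is a symmetric matrix of
# percent distances (NA = undefined pair).
fake_dist <- function(pct, ids = rownames(pct)) {
  n <- nrow(pct)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(n))
  i <- rep.int(seq_len(n - 1), (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n))
  d <- pct[cbind(i, j)] / 100
  structure(list(ids = ids, n = n,
                 overlap = rep(658L, length(d)),
                 transitions = ifelse(!is.na(d) & d == 0, 0L, 1L),
                 transversions = 0L,
                 P = d, Q = rep(0, length(d)),
                 distance = d, defined = !is.na(d),
                 min_overlap = 300L),
            class = "k2p_dist")
}

# Small deterministic multi-species library used by several tests:
#   Alpha one:   2 identical specimens (tpl)
#   Alpha two:   shares tpl haplotype with "Alpha one" (1 specimen)
#   Beta one:    20 substitutions away; second specimen 3 further
#   Gamma one:   60 substitutions away (own genus)
planted_library <- function() {
  beta <- with_transitions(TPL, seq(3, 60, by = 3))
  seqs <- c(a1 = TPL, a2 = TPL, s1 = TPL,
            b1 = beta, b2 = with_transitions(beta, c(100, 103, 106)),
            g1 = with_transitions(TPL, seq(3, 180, by = 3)))
  make_collection(c("Alpha one", "Alpha one", "Alpha two",
                    "Beta one", "Beta one", "Gamma one"),
                  seqs,
                  genus = c("Alpha", "Alpha", "Alpha", "Beta", "Beta",
                            "Gamma"))
}
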