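---
title: "Auditing a COI barcode reference library: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing a COI barcode reference library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeaudit)
```

## The problem

A barcode reference library is useful exactly insofar as species in it are
*diagnosable*: an unknown COI sequence must land unambiguously on one
species. This package quantifies diagnosability for a library of aligned
658-position COI barcodes with specimen metadata, classifies every species
into the standard failure categories, scores species against sequence
clusters, and re-runs the whole audit inside geographic partitions. This
vignette records the model, the defaults, and the design decisions that
were genuinely open — in enough detail that a maintainer can predict the
package's behaviour at every edge.

## Distance model

Distances are Kimura-2-parameter. For a pair of sequences, only positions
where **both** have A/C/G/T count (pairwise deletion of N and gaps); over
that overlap, with transition proportion $P$ and transversion proportion
$Q$:

$$ d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q). $$

A comparison is *undefined* when the overlap is below `min_overlap`
(default **300** positions) or a log argument is non-positive
(saturation). Undefined pairs are excluded from every summary and counted
in reports. Distances are fractions internally and become percentages only
at reporting boundaries.

Why 300? The library's record floor is 500 defined positions, but retained
short diagnostic fragments go down to ~307 bp; 300 keeps those fragments
comparable to full-length records while refusing distances estimated from
trivially short overlaps. Haplotype *sharing* is a stronger claim than a
distance, so it uses its own floor (below).

## Haplotype sharing

Two specimens share a haplotype when their comparison is defined, has
**zero mismatches** over the overlap, and the overlap is at least
`haplotype_min_overlap` (default **500**, the record floor). For fragments
of unequal length this relation is not transitive (a short fragment can
match two full-length sequences that differ outside its window), so
haplotype groups are defined as the **connected components** of the
relation. That closure is a deliberate choice: it is conservative in the
direction that matters for an audit, since it can only *add* sharing
calls, never hide one.

## Species categories

For each species with a defined nearest-neighbor (NN) distance:

| Category | Rule | Default threshold |
|---|---|---|
| `SHARING` | in a haplotype group with ≥2 species | — |
| `DIAGNOSTIC` | not `SHARING` | — |
| `LOW_DIVERGENCE` | not sharing, $0 < \mathrm{NN} <$ `low_div_max` | 1.0% |
| `DEEP_SPLIT` | max intraspecific divergence > `deep_split_min` | 2.0% |

Categories are a **set**, not a partition: a deep-split species stays
diagnostic, and can simultaneously be sharing or low-divergence.
Identification success is $100 \times$ diagnostic/assessed, so it is
exactly the complement of the sharing percentage before rounding. Species
whose every interspecific comparison is undefined are `UNASSESSED` and
excluded from denominators. Singletons have no intraspecific values but
are still assessed for sharing and low divergence.

**Rounding.** Printed percentages round *half-up* at one decimal
(`percentage()`), because summary tables in this field print one-decimal
percentages and banker's rounding would disagree on `.x5` boundaries.

**Averaging convention.** Family and assemblage means average *per-species*
values (each species' NN distance, each species' mean intraspecific
divergence), not pooled specimen pairs. Whether reference implementations
average over pairs or species first is not documented anywhere we could
check; the per-species convention is flagged here rather than asserted as
anyone else's.

## Clusters and concordance

The registry-based BIN algorithm is not reimplemented. When specimens
carry externally assigned `bin_id` labels those are always preferred
(`supplied_bins()`); otherwise `single_linkage_clusters()` provides a
documented surrogate: connected components of the graph joining pairs with
defined distance ≤ `threshold` (default **2.2%**, the usual seed threshold
for barcode OTUs). Labels are deterministic (lexicographically smallest
member id) so runs diff cleanly. A consequence of the surrogate worth
stating: it cannot split a species whose internal divergence lies below
the threshold, so multi-cluster species in the 0.7–2.0% range are only
detectable with supplied labels.

Concordance per species: `MATCH` (one unshared cluster), `SPLIT` (≥2
clusters, none shared), `MERGE` (one shared cluster), `MIXTURE` (≥2
clusters, ≥1 shared). These four always partition the species set.

## Assemblage analysis

Partition keys: `ecoregion` (the 15-label terrestrial scheme collapsed to
12 — Arctic Cordillera + Tundra → Arctic; Taiga + Hudson Plain + Northern
Forests → Boreal), `lat_band` (5° bands, edges 25–55°), `lon_band` (10°
bands over |longitude|, edges 75–135°), and `zoogeo_region`. Band
intervals are lower-inclusive/upper-exclusive with open extremes; the
table headers this mirrors ("50° & 55°") are ambiguous, so the convention
is fixed here once. Eastern-hemisphere longitudes are excluded from the
east–west analysis with a log note, since it is defined over western
longitudes. Specimens lacking the key are skipped and counted.

Within each partition everything — distances, clusters, sharing,
identification success — is recomputed from only that partition's
specimens (not from continental species ranges; this choice is flagged as
such). A pooled `Total` row uses all specimens carrying the key.

One invariant deserves care. Restricting to a region can only *remove*
co-occurrence, so any species sharing within a region also shares
continentally, and every per-region sharing count is ≤ the continental
count. The *sum* of per-region counts, however, can exceed the continental
count when a sharing pair co-occurs in several regions — the per-region
form is what the package tests.

GIS is out of scope: ecoregion and zoogeographic labels are inputs; the
only coordinate arithmetic performed is the band assignment.

## Sequence quality rules

Records need ≥ `min_len` (default **500**) defined positions, with an
explicit whitelist for short-but-diagnostic fragments. The reading-frame
check translates the defined region in all three frames under the
invertebrate mitochondrial code (stops TAA/TAG only; TGA is Trp, AGA/AGG
are Ser) and keeps the frame with the fewest stops, ties to the lowest
frame; pass means zero stops. Codons containing N are skipped; a gap
strictly inside the sequenced region is a frameshift failure; fewer than
30 defined positions give an indeterminate, non-failing result. The
amplicon's frame offset is not assumed — the minimum-stop rule replaces a
hard-coded offset.

Sequences are assumed pre-aligned to the common 658-position frame (the
group this models shows no indels), so no aligner is included; shorter
fragments are padded with `-`. How sub-500-bp fragments are placed in the
frame by upstream pipelines is not documented, so the padding convention
is an assumption of this package. IUPAC ambiguity codes other than N are
mapped to N with a report entry.

## The synthetic generator, and what a green test establishes

`generate_library()` is *phenomenological*: real audits report realized
percent divergences, so the generator targets those directly with
substitution counts rather than simulating a coalescent. Defaults are the
stated world: specimens per species truncated-geometric with mean 19.46 on
[1, 614]; intraspecific scale 0.45% (per-specimen Poisson substitutions);
congeneric founder separation targeting ~2.7% NN distances; 3:1
transition:transversion ratio with third-codon-position bias; introduced
species get intraspecific scale ×0.45 and NN scale ×1.6. Planted features:
sharing pairs copy one founder haplotype into two species; deep splits
place a second founder at a depth drawn from 2.5–8%; low-divergence pairs
separate founders by substitutions equivalent to 0.2–0.9%. Every species'
first specimen is its unmutated founder, which pins planted NN distances
to their design values within one mutation step. Infeasible plantings
(e.g. a low-divergence request below one substitution's resolution) fail
before generation.

The recorded truth distinguishes *design-level* flags (who was planted to
share, split, or be introduced — these are asserted at 100% / ≥95%
recovery) from the *expected concordance category*, which is computed by
running the generator's own single-linkage clustering on the emitted
sequences. The latter is deliberately computed rather than assumed:
background congeners legitimately fall below 2.2% and merge, exactly as
most species in a real library do, and pretending they would all `MATCH`
would make the truth wrong by construction.

For the introduced-vs-native contrast, per-species mean divergences are
drawn from a gamma with shape 2 (right-skewed, strictly positive — the
usual shape of intraspecific COI divergence distributions). With means
0.20% vs 0.44% at n = 30/300 this implies an expected Welch statistic
around 7.5, consonant with what continental libraries report for this
contrast.

What the generator does **not** emulate: coalescent genealogies,
selection, introgression, endosymbiont sweeps, sequencing error, and
geographic autocorrelation of haplotypes. A green planted-truth test
therefore establishes that the *audit machinery* is correct, not that the
generator is a faithful model of noctuid evolution.

## Numerical and degenerate-input choices

- K2P becomes undefined (not clamped) on saturated pairs; they are counted.
- `distance = 0` iff both P and Q are 0; zero-distance ties in NN partner
  selection break alphabetically.
- Single specimens, single-species partitions, and empty partitions
  degrade to `NA` fields rather than errors; hard errors are reserved for
  contract violations (duplicate ids, missing required columns, unequal
  frame lengths, unknown region labels).
- All clustering and labelling is deterministic; the CLI logs a config
  hash and the package version for reproducible diffs.

## Known limitations

- The single-linkage surrogate under-splits relative to registry BIN
  assignments below its threshold (see above).
- Longitude bands assume a Nearctic library (western longitudes).
- The chi-square homogeneity test is the standard r×2 Pearson test; no
  claim is made to reproduce any particular published statistic whose
  underlying table is unpublished.
- Assemblage identification success uses in-region specimens only; a
  range-based assignment could differ for wide-ranging species.
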