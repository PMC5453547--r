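# barcodeaudit

Diagnosability audit of COI DNA barcode reference libraries.

## What it is for

A DNA barcode reference library assigns unknown specimens to species by
comparing their mitochondrial COI barcode (the standard 658-bp fragment) to
curated sequences of known species. Whether that works depends on the
library's *diagnosability structure*: species whose haplotypes are shared
with another species cannot be identified by distance at all, species whose
nearest neighbor sits below ~1% divergence are fragile, and species with
deep (>2%) internal divergence may hide cryptic diversity. `barcodeaudit`
measures all of this for a library of aligned COI sequences plus specimen
metadata, the way large continental-scale moth libraries are audited:

- **Distances.** Kimura-2-parameter distances under pairwise deletion.
  With transition proportion *P* and transversion proportion *Q* over the
  comparable positions of a pair,

  *d* = −½ ln(1 − 2*P* − *Q*) − ¼ ln(1 − 2*Q*).

- **Haplotype sharing.** Two specimens share a haplotype when they have
  zero mismatches over ≥500 comparable positions; groups are the connected
  components of that relation. A species that co-occurs in a group with
  another species is `SHARING`, otherwise `DIAGNOSTIC`.
- **Categories.** `LOW_DIVERGENCE`: not sharing, nearest-neighbor distance
  in (0, 1%); `DEEP_SPLIT`: maximum intraspecific divergence > 2%
  (independent of the others — deep-split species remain diagnostic).
- **Identification success** = 100 × diagnostic / assessed species.
- **Cluster concordance.** Species are scored against sequence clusters
  (supplied BIN labels, or a single-linkage surrogate at 2.2%) as
  `MATCH` / `SPLIT` / `MERGE` / `MIXTURE`.
- **Assemblages.** The whole audit is recomputed inside ecoregions,
  5° latitude bands, 10° longitude bands, or zoogeographic regions, plus
  cluster overlap/endemism across regions.
- **Comparative statistics.** Welch's unequal-variance t test, Spearman
  rank correlation, and the r×2 Pearson chi-square homogeneity test.
- **Synthetic libraries.** A seeded generator plants known sharing pairs,
  deep splits, low-divergence pairs and introduced species into a COI-like
  template, so every stage is testable with full ground truth and no
  downloads.

## Worked example

```r
library(barcodeaudit)
lib   <- generate_library(sim_config(seed = 7, n_species = 60,
                                     n_genera = 15, specimens_mean = 6))
audit <- audit_library(lib$collection)
print(audit)
#> library_audit: 60 species assessed; sharing 10, low-divergence 10,
#>   deep-split 6; ID success 83.3%

part <- single_linkage_clusters(audit$distance, threshold = 2.2)
cnt  <- concordance_counts(concordance_classify(lib$collection, part))
#> MATCH 26 / SPLIT 4 / MERGE 28 / MIXTURE 2 (43.3% match)

summ <- partition_and_summarize(lib$collection, "ecoregion")
summ[, c("partition", "n_species", "id_success_pct", "n_sharing")]
#>                         partition n_species id_success_pct n_sharing
#> 1                          Arctic        29          100.0         0
#> 2                          Boreal        16          100.0         0
#> ...
#> 7                           Total        60           83.3        10
```

Reading the numbers: the generator planted 5 sharing pairs (10 species),
6 deep splits and 4 low-divergence pairs into 60 species; the audit flags
all 10 planted sharers (`SHARING`, hence ID success 100 × 50/60 = 83.3%).
Because the shared haplotypes mostly involve species pairs that do not
co-occur regionally, per-ecoregion sharing collapses (0–2 species per
region versus 10 continentally) — regional restriction improves
resolution, the central assemblage phenomenon the package measures.

## Command line

```sh
Rscript inst/scripts/barcodeaudit.R simulate --seed 5 --n-species 60 --out sim/
Rscript inst/scripts/barcodeaudit.R audit       --fasta sim/library.fasta --meta sim/specimens.tsv --out out/
Rscript inst/scripts/barcodeaudit.R concordance --fasta sim/library.fasta --meta sim/specimens.tsv --out out/
Rscript inst/scripts/barcodeaudit.R assemblages --key lat_band --fasta sim/library.fasta --meta sim/specimens.tsv --out out/
Rscript inst/scripts/barcodeaudit.R overlap     --fasta sim/library.fasta --meta sim/specimens.tsv --out out/
```

Defaults reproduce the standard audit thresholds (low divergence < 1%,
deep split > 2%, clusters at 2.2%, 500-bp record floor). All artifacts are
TSV with JSON mirrors; a `run.log` records the package version and a
config hash.

## Vignette

`vignettes/barcode-library-audit.Rmd` documents the model and its
assumptions, every tunable threshold, what the synthetic generator does
and does not emulate, and the numerical conventions (half-up rounding,
pairwise deletion, component closures, band edges).
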