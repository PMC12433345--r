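# entropeaks

Downstream analysis of multi-tissue bulk ATAC-seq in R: from per-sample
MACS2 peak calls to tissue-specific regulatory regions, the transcription
factors that plausibly drive them, and the genes whose expression tracks
their promoter accessibility.

The package targets study designs like a six-tissue panel spanning the
limbic system and the HPA stress axis — amygdala (Amy), hippocampus
(Hip), hypothalamus (HT), thalamus (Tal), adrenal gland (AG) and
pituitary gland (PG) — with eight biological replicates per tissue, but
every design parameter (tissue set, replicate count, thresholds) is
configurable.

## What it computes

1. **Consensus peaks** — per-sample narrowPeak summits are extended to
   fixed-width windows (summit ± 75 bp), clustered across samples by
   single-linkage overlap, and kept when supported by ≥ 2 peak sets.
   Fragments are counted per region by midpoint containment, and regions
   are filtered (count ≥ 10 in ≥ 75% of some tissue's replicates; total
   ≥ 100 reads) before reads-per-million (RPM) normalization.

2. **Tissue specificity by Shannon entropy** — for each region, the
   per-tissue mean RPM *Eᵢ* gives relative accessibilities
   *Rᵢ = Eᵢ / ΣE* and the entropy

   *H = −Σᵢ Rᵢ log₂ Rᵢ*,  0 ≤ *H* ≤ log₂ *N*,

   low when accessibility concentrates in one tissue. A region is called
   tissue-specific when *H* < 2 bits and max *Rᵢ* ≥ 0.33, and is labeled
   with its argmax tissue.

3. **Known-motif enrichment** — tissue-specific regions are scanned with
   a HOMER-format PWM library (log-odds scoring, both strands); each
   motif is tested against GC-matched background windows drawn from the
   genome (2:1, 0.05-wide GC bins) with the upper-tail hypergeometric
   probability, significant at *p* < 0.001. Reporting layers: the
   motif × tissue p-value matrix, coefficient-of-variation ranking of
   −log₁₀ *p* scores, tissue-unique motif sets and UpSet intersection
   counts.

4. **Cis correlation with expression** — regions whose midpoint lies
   within ± 3 kb of a transcript's TSS are paired with that gene; RPM
   and expression are Pearson-correlated across each tissue's
   replicates; positive pairs with *p* < 0.05 are kept, one best pair
   per gene and tissue. Tissue-unique motifs are cross-checked against
   expression of their transcription factor (expressed in the tissue,
   and significantly higher there than in every other tissue by
   one-sided Welch tests).

5. **Synthetic data with ground truth** — a deterministic generator
   (`simulate_bundle()`) emulates the full design: a random genome and
   annotation, 3,000 shared plus 100-per-tissue specific loci with
   negative-binomial counts, planted motif instances in specific
   regions, and expression planted to correlate (ρ = 0.9) with promoter
   accessibility for 30% of genes. Every pipeline claim is validated
   against this truth table in the test suite.

## Worked example

```r
library(entropeaks)

cfg <- sim_config(seed = 3, n_shared = 80, n_specific = 10,
                  chrom_len = 250000L, n_genes = 40L)
bundle <- simulate_bundle(cfg)
res <- run_pipeline(bundle, out_dir = NULL,
                    config = pipeline_config(seed = 3))
print(res)
#> <pipeline_result>
#>   consensus: 140 regions (140 before filters)
#>   tissue-specific regions: 45
#>   significant motifs: 5 (5 tissue-unique)
#>   cis pairs: 77 (of 486 tested)

table(res$specificity$classified$label, useNA = "ifany")
#>   AG  Amy  Hip   HT   PG  Tal <NA>
#>    8    5    8    9    8    7   95

round(res$motifs$pmat["TF_AG", ], 4)
#>   Amy   Hip    HT   Tal    AG    PG
#> 1e+00 1e+00 1e+00 1e+00 2e-04 1e+00
```

All 140 planted loci (80 shared + 60 specific) are recovered as
consensus regions; 45 of the 60 tissue-specific loci pass the entropy
and accessibility thresholds with the correct label and no false calls;
the motif planted in adrenal-specific regions is significant in AG only
(*p* = 2 × 10⁻⁴) — at this toy scale the weakest of the six planted
motifs falls short of *p* < 0.001, which is why 5 of 6 are significant.
With the full default design (100 specific loci per tissue) all six are
recovered with *p* < 10⁻³⁹.

A command-line front end with `simulate`, `consensus`, `specificity`,
`motifs`, `integrate`, `qc` and `all` subcommands is installed at
`system.file("cli", "entropeaks.R", package = "entropeaks")`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/entropeaks.R", package="entropeaks"))') \
    all --simulate --seed 7 --out results/
```

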