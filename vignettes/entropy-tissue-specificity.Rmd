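---
title: "Entropy-based tissue specificity of chromatin accessibility: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based tissue specificity of chromatin accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entropeaks)
```

# Scope

`entropeaks` implements the downstream arm of a multi-tissue bulk
ATAC-seq study: it consumes per-sample MACS2 narrowPeak calls, fragment
intervals, a genome, a transcript annotation, a known-motif library and
an expression matrix, and produces consensus peaks, entropy-based
tissue-specificity calls, known-motif enrichment in tissue-specific
regions, and promoter-accessibility–expression cis correlations.
Upstream read processing (trimming, alignment, duplicate marking, peak
calling) and differential-accessibility testing are out of scope; peaks
are consumed, never produced.

All internal coordinates are 0-based half-open, the native convention of
BED and narrowPeak; GTF input is converted on read and back on write.
That single convention removes an entire class of off-by-one errors at
the cost of one conversion at each boundary.

# Consensus peak construction

Each peak contributes a fixed-width window centred on its summit — the
base of maximal signal — extended by `flank` bp on each side (default
75, giving 151-bp windows). Fixed widths make counts comparable across
regions and keep motif scanning windows homogeneous. Windows from all
samples are clustered by single-linkage overlap (at least 1 bp; abutting
windows do not merge), and a cluster becomes a consensus region when it
contains windows from at least `min_overlap` distinct samples (default
2, the weakest reproducibility requirement that still discards
single-sample noise).

The cluster's representative summit is the **median member summit**,
with ties resolved to the lower coordinate. The median is deterministic,
robust to a single outlying sample, and keeps the consensus window
inside the cluster hull, which guarantees that consensus regions never
overlap each other. The mean would have the same determinism but can be
dragged by stragglers at the cluster edge.

Counting assigns each fragment to the region containing its midpoint
(`floor((start + end) / 2)`). Midpoint assignment partitions fragments —
no fragment is counted twice — which keeps library sizes additive and
makes RPM normalization self-consistent.

Three inclusion filters follow:

* **Representation**: a region must have a count of at least
  `min_count` (default 10 reads) in at least
  `ceiling(group_frac * n_replicates)` samples of *some* tissue
  (default 75%). "Represented" is deliberately defined by the same
  10-read minimum rather than a second threshold.
* **Total**: the summed count across all samples must reach `min_total`
  (default 100 reads). The total is interpreted per region across the
  whole matrix; a per-sample reading of 100 would contradict the
  10-read representation rule.
* Both filters are monotone: raising a threshold can only shrink the
  region set (a property the test suite asserts).

RPM uses the **in-matrix library size** — reads assigned to consensus
regions, not total sequenced reads — so the pipeline is self-contained
from its own inputs. The fraction of reads in peaks (FRiP) is reported
separately as a QC metric, so no information is lost by this choice.

# The specificity index

For region *r*, let *Eᵢ* be the mean RPM over tissue *i*'s replicates
(the arithmetic mean matches the entropy framework's use of a
per-tissue expectation; summing would weight tissues by replicate
count). Relative accessibility and entropy are

$$R_i = \frac{E_i}{\sum_j E_j}, \qquad
  H = -\sum_i R_i \log_2 R_i \in [0, \log_2 N],$$

with the convention $0 \log_2 0 = 0$. $H = 0$ means all accessibility
sits in one tissue; $H = \log_2 N$ (≈ 2.585 bits for six tissues) means
a perfectly uniform profile. A region is called **tissue-specific**
when

* $H < h_{max}$ (default 2 bits, strict inequality, matching the
  "less than" phrasing of the rule), and
* $\max_i R_i \ge r_{min}$ (default 0.33, inclusive — "at least a
  third of the signal in one tissue"),

and it is labeled with the argmax tissue, ties resolved by the
configured tissue order. Classification depends only on the *Rᵢ*, so it
is invariant to uniform rescaling of the profile. Regions with
$\sum E = 0$ are reported as *unclassifiable* rather than silently
dropped: they are visible in the output with `H = NA`.

# Motif enrichment

Scanning uses standard log-odds scores
$s(b, j) = \log_2(p_{bj} / q_b)$ against a background base composition
$q$ estimated from the background sequence set. Two numerical choices
matter:

* PWM probabilities are floored at $10^{-3}$ before the ratio, so
  motif positions with zero probability stay finite (≈ −8 bits against
  a uniform background) instead of vetoing a window outright.
* Ambiguous bases (N) score a flat −10 bits at any position — low
  enough that a single N rejects a window at any realistic threshold,
  without special-casing masked sequence in the parser.

Both strands are scanned (the reverse strand scores the reverse
complement with the same matrix); hit positions are reported
forward-strand leftmost, and overlapping hits on either strand count
once toward the per-sequence "contains the motif" indicator. Per-motif
thresholds come from the motif file; when a file provides none, the
threshold defaults to 80% of the motif's maximal attainable score — a
deterministic fallback that admits near-exact matches only.

Background windows are drawn from the genome to match the target
windows' lengths exactly and their GC distribution per 0.05-wide bin
(largest-remainder apportionment of the 2:1 background:target ratio
across bins). Windows overlap neither the targets nor each other, and
the draw is deterministic given a seed. A bin that cannot be filled
after bounded oversampling is topped up from the nearest bin with a
warning. This is plain GC matching: it deliberately does not reproduce
the additional CpG and autonormalization corrections some scanning
suites apply internally, which is worth remembering when comparing
absolute p-values across tools.

Enrichment is tested with the upper-tail hypergeometric probability:
drawing the target set (size $n_t$) from the pooled target + background
population, with motif-containing sequences as successes,

$$p = P(X \ge k_t), \quad X \sim
  \mathrm{Hypergeom}(M = n_t + n_b,\; K = k_t + k_b,\; n = n_t).$$

The hypergeometric (rather than binomial) tail is exact at these set
sizes; it is evaluated through R's numerically stable distribution
function and verified in the tests against full combinatorial
enumeration for all populations up to 25. Significance uses raw
$p < 0.001$. Fold enrichment $(k_t/n_t)/(k_b/n_b)$ is reported
alongside; when no background sequence contains the motif the fold is
infinite and reported as the capped sentinel $10^6$.

Reporting follows three layers: the motif × tissue p-value matrix; a
coefficient-of-variation ranking of $-\log_{10} p$ scores (motifs with
mean score above 20, top 50 by CV) highlighting motifs whose enrichment
varies most across tissues; and tissue-unique sets (significant in
exactly one tissue) plus all $2^N - 1$ intersection counts for UpSet
displays. The "enrichment score" of the CV layer is $-\log_{10} p$;
the significance filter always uses the p-value itself.

# Accessibility–expression integration

A region pairs with a transcript when the region midpoint lies within
±`promoter_window` bp of the TSS (default 3 kb, inclusive at both
edges, strand-agnostic — the window is symmetric). One region may pair
with many transcripts and vice versa.

Correlations are computed **within tissue across its replicates**
(n = 8 in the default design): Pearson's r with the two-sided t-test
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ degrees of freedom. Per-tissue
testing is what makes the per-tissue gene counts and their
intersections meaningful. At n = 8 the weakest correlation reaching
p < 0.05 is r ≈ 0.707, so a "significant positive cis pair" here is
always a strong correlation; the package applies only positivity and
p < 0.05 and reports r, rather than imposing a separate r cutoff.
Perfect correlations report p = 0 as a sentinel; zero-variance vectors
make r undefined and are reported missing. A Benjamini–Hochberg
adjusted p-value within each tissue is emitted alongside the raw one,
but the headline filter uses the raw p < 0.05. Per gene and tissue,
only the pair with the highest r is retained.

The TF expression-support filter asks, for each tissue-unique motif:
is the motif's transcription factor *expressed* in that tissue (mean
expression ≥ `expr_min`, default 1.0 in the units of the supplied
matrix — the floor is intentionally permissive and exists only to
exclude silent genes), and is that expression *tissue-specific*? The
location test is a one-sided Welch two-sample t-test of the motif's
tissue against every other tissue separately, all comparisons required
to reject at `tf_alpha` (default 0.05), plus the requirement that the
tissue has the maximal mean. Requiring every pairwise rejection is the
strictest reading of "significantly higher than all others"; a pooled
or rank-based alternative would be less sensitive to unequal variances
across tissues, which the Welch form already accommodates. TF names
are mapped to expression rows through an explicit map when given, with
a case-insensitive symbol match as fallback; unmapped TFs are listed
as skipped, never silently dropped.

# The synthetic-data generator

`simulate_bundle()` produces every pipeline input with a known truth
table. It emulates the default study shape — 6 tissues × 8 replicates,
3,000 shared plus 100-per-tissue specific loci on 2 × 1 Mb chromosomes
with 500 genes — at roughly 1/1000 of a mammalian genome's scale,
chosen so a full end-to-end run with all 48 samples completes in well
under a minute on one CPU while keeping per-sample counts at realistic
ATAC depths for the regions it models.

* **Counts**: per locus and sample, negative binomial with mean
  `nb_mean × N × share` and dispersion 0.2 in the standard
  var = μ + 0.2 μ² sense (biological coefficient of variation ≈ 0.45,
  typical of bulk chromatin replicates). Shared loci split their signal
  uniformly (share 1/6, so 50 reads/sample at defaults); specific loci
  give their target tissue share f = 0.6 and (1−f)/5 to the rest.
* **Placement**: summits sit on a jittered grid with a 300-bp minimum
  spacing, so consensus windows never collide; about 30% of shared loci
  are relocated into ±2.5 kb promoter windows so the integration stage
  has promoter-proximal signal to find.
* **Motifs**: each tissue has one planted 10-mer consensus, written
  (random strand, random offset within ±40 bp of the summit, hence
  always inside the 151-bp consensus window) into exactly 80% of that
  tissue's specific loci, and into shared loci at a 2% background rate.
* **Expression**: 30% of genes with a promoter-proximal locus track
  that locus's RPM within each tissue at correlation ρ = 0.9
  (standardized-accessibility mixing with Gaussian noise); other genes
  are independent log-normal baseline noise; one designated TF gene per
  tissue is strongly over-expressed there to exercise the
  expression-support filter.
* **Determinism**: each stage draws from its own stream seeded as
  master seed + a fixed stage offset, so stages are independently
  reproducible and inserting a stage never reshuffles later ones.

Choosing f = 0.6 puts the planted specific profile comfortably above
the R ≥ 0.33 criterion, but close to the entropy threshold: its
expected entropy is H(0.6, 0.08×5) ≈ 1.90 bits, only ≈ 0.1 bits under
the 2-bit cutoff, while replicate noise at these settings propagates to
a standard deviation of roughly 0.12 bits on H. A nontrivial fraction
of truly specific loci therefore fluctuates past the threshold, and
classification sensitivity at these exact settings sits around 0.8
rather than near 1 — the false-discovery side is essentially clean
because shared loci sit ≈ 0.5 bits above the cutoff with the same
noise. The test suite measures both against the truth table; the
sensitivity this design actually achieves is a property of the planted
margin, not of the classifier implementation, and raising f or the
replicate count (or lowering the dispersion) moves it toward 1.

What the generator does **not** emulate, and what passing tests
therefore do not show: Tn5 insertion-sequence bias, nucleosomal
fragment-length periodicity, copy-number or mappability artifacts,
overdispersion structure that varies by locus, off-peak background
fragments (FRiP is 1.0 by construction on simulated data), correlated
motif co-occurrence, and trans or enhancer-distance regulation. Results
on real data depend on upstream peak calling quality in ways no
simulation exercises.

# Degenerate inputs and numerical conventions

* Peaks without a called summit (`summit_offset = -1`) use the interval
  midpoint.
* All-zero accessibility profiles: unclassifiable, `H = NA`, label
  `NA`.
* `0 log 0 = 0` in the entropy; `H` is clamped against IEEE negative
  zero so the one-hot case prints exactly 0.
* Argmax ties in classification resolve to the configured tissue
  order; median ties in consensus resolve to the lower coordinate;
  both are deterministic.
* Parsers reject structural problems (wrong column counts, non-integer
  coordinates, summit outside its peak, probability rows off unity by
  more than $10^{-3}$) with the offending line number; they never
  repair silently.
* Sample correlation uses $\log_{10}(\mathrm{RPM} + 1)$; the
  pseudo-count handles the zeros that sparse regions produce.
* The TSS QC window is −1000..+100 bp strand-oriented; the promoter
  context window is 3 kb upstream; the integration window is ±3 kb
  symmetric. The three windows serve different questions and are
  separately configurable.

# Problem sizes in the test suite

Unit tests run on a down-scaled design (120 shared + 15-per-tissue
specific loci on 2 × 300 kb chromosomes, 60 genes) that preserves the
6 × 8 sample structure; the end-to-end recovery checks run the full
default design (3,600 loci, 48 samples, ~8.6 M fragments), which takes
about half a minute. Oracle checks are exhaustive where feasible
(hypergeometric tails for all populations to M = 25) and sampled
elsewhere (1,000 random simplex vectors for the entropy, 100 random
sequences for the scanner, 1,000 random vector pairs for the
correlation test).

# Known limitations

* Single-linkage clustering can chain peaks across samples into long
  clusters when summits drift; the fixed re-extension around the median
  summit bounds the output width but a chain wider than 151 bp loses
  its tails.
* UTR annotation is collapsed into exon context unless the GTF provides
  explicit UTR features; first/other exon and intron sub-categories are
  not distinguished.
* The hypergeometric test treats sequences as exchangeable; GC matching
  removes the largest composition bias but repeat content and CpG
  islands are not separately controlled.
* Annotation versions are taken as given: the package accepts one GTF
  and leaves reconciliation of annotation releases between assays to
  the user.
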