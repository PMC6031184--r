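---
title: "High-accuracy targeted bisulfite sequencing: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-accuracy targeted bisulfite sequencing: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hamtbs)
```

## The measurement model

Bisulfite treatment deaminates unmethylated cytosine to uracil (sequenced
as T) while 5-methylcytosine is protected and reads C. After PCR
enrichment of target amplicons and paired-end sequencing, the methylation
level of a cytosine is estimated by the fraction of informative read bases
showing C:

$$\hat{m} = \frac{n_C}{n_C + n_T}.$$

Only C and T bases at or above a Phred quality of 20 are informative;
G/A bases (sequencing error or an underlying variant) are ignored, the
standard bisulfite convention. Each amplicon assays one bisulfite strand;
bottom-strand amplicons are handled on the reverse complement so all
internal logic is top-strand-like, and positions are mapped back to
1-based genomic coordinates on output.

Cytosine context is taken from the two reference bases following the
cytosine on the assayed strand: `CG` → CpG, `C[ACT]G` → CHG,
`C[ACT][ACT]` → CHH. Human CHH cytosines are essentially unmethylated, so
the retained-C fraction at CHH sites measures bisulfite conversion
*failure*: the per-unit conversion rate is
$\sum n_T / \sum (n_C + n_T)$ over the CHH sites of a
sample × amplicon unit. CHG sites are enumerated and reported but do not
enter the conversion denominator; the protocol's conversion statement is
made on CHH, and restricting to it keeps the estimate interpretable if
residual CHG methylation exists. Primer-footprint positions are synthetic
oligonucleotide, not template, and are masked from both methylation
calling and conversion denominators.

## Read-evidenced CpGs, artifacts, and SNP-CpGs

The analysis is not restricted to reference CpGs: at any assayed-strand
reference cytosine that is not a reference CpG, a read showing `C`
immediately followed by `G` evidences a CpG absent from the reference.
Two processes create such signals — PCR errors (artifacts) and genuine
variants in the following base (SNP-CpGs) — and they separate cleanly:
artifacts ride on a few aberrant amplicons, so they present at very low
coverage with ~0% or ~100% methylation, while a SNP-CpG is present in the
template and appears at full coverage with an ordinary methylation level.
At a read-evidenced CpG, `CG` reads count as methylated and `TG` reads as
unmethylated, and the CpG interpretation supersedes the position's
reference context so that a SNP-CpG's protected cytosines do not deflate
the CHH conversion rate. Candidates are restricted to reference
cytosines because at a genomic T an observed C is indistinguishable from
a conversion failure.

The artifact rule quantifies "very low coverage" as less than `cov_frac`
(default 5%) of the unit's *median reference-CpG coverage* and "extreme"
as within `extremity` (default 5%) of 0 or 1. The protocol describes only
the qualitative signature; both knobs are exposed and the defaults were
calibrated on the simulator's injected artifacts, not on cohort data.
Reference CpGs are never artifact-flagged.

## The three QC filters

1. **Conversion**: a sample × amplicon unit fails when its CHH conversion
   rate is *strictly below* 0.95 (exactly 0.95 passes, matching the
   "lower than" exclusion wording); a unit with no CHH coverage cannot be
   certified and fails with an explicit reason.
2. **Artifacts**: flagged non-reference CpG sites are removed; retained
   ones are reported as candidate SNP-CpGs.
3. **Coverage**: CpG sites supported by fewer than 1000 informative reads
   are removed (exactly 1000 is retained).

All flags are computed from the input table and then intersected, which
makes the filters commute — in particular the artifact rule's median
coverage is never affected by the coverage filter having run first. A
unit "passes QC" when its conversion passes and at least one of its
reference CpGs survives the coverage cutoff; survival fractions count
units, matching how panel dropout is reported in practice.

## Overlap trimming

Amplicons shorter than twice the read length yield mates whose inner ends
overlap; counting both would double-weight the lowest-quality part of the
fragment. For each overlapping pair the mate with the lower *mean Phred
quality over the intersection* is hard-trimmed (bases removed), with ties
trimming mate 2 — a deterministic, order-independent rule. Hard trimming
(rather than quality masking) keeps downstream counting free of special
cases; afterwards each reference position is covered at most once per
pair, and the operation is idempotent. Whether the original protocol
trimmed per base or per end is not documented; trimming the whole overlap
from one mate is implemented. Pairs with indels or clipping (rare in
amplicon data) pass through untrimmed with a warning rather than risking
silent miscounts.

## The read simulator

`simulate_sample()` draws `depth` independent full-length fragments per
amplicon. Per fragment, each reference-CpG cytosine is methylated with
its profile probability (independently per site and fragment — no
haplotype correlation, which no statistic here depends on); unmethylated
and non-CpG cytosines convert to T independently with probability
`conversion`, modelling incomplete conversion as i.i.d. per cytosine
where the laboratory protocol only constrains the aggregate rate.
Uniform base errors substitute one of the three other bases. Paired
reads cover the fragment from both ends, are emitted pre-aligned to the
amplicon reference (SAM) or in sequencing orientation (FASTQ), carry
constant Q37 qualities by default (optionally a lower quality on mate 2's
overlap, to exercise trimming), and a fixed seed makes output
byte-identical. Injected PCR artifacts are fully converted fragments
differing from the reference only by the artifact `CG` dinucleotide —
the simplest construction with the observed signature (low coverage,
100% apparent methylation).

What the simulator does *not* emulate: PCR duplicates and per-cycle error
profiles, indels, adapter read-through, index hopping, haplotype
structure, and coverage imbalance between amplicons. Passing tests
therefore certify the *statistical* pipeline — counting, filtering,
regression, subsampling — under a clean error model, not robustness to
every artefact of real libraries.

## Titration statistics

Titration profiles (`mix_titration()`) set every reference CpG to the
same level, the in-silico analogue of mixing 0% and 100% methylated
control DNA to 0/25/50/75/100%. Statistics are on the percent scale
throughout. Per CpG, ordinary least squares of observed on expected
methylation gives slope, intercept and R²; zero-variance observations
make R² undefined (reported missing, excluded from the per-amplicon
mean). An amplicon is flagged nonlinear when its mean R² falls below 0.98
or its mean slope leaves [0.9, 1.1] — explicit, configurable thresholds
standing in for a qualitative exclusion decision. Condition comparisons
report the mean |difference| in percentage points per amplicon × level
and per amplicon over an inner join of sites. Replicate SDs use the
sample SD (n−1) per CpG × level cell and aggregate as the mean and max
over cells — the most granular consistent aggregation, since finer
conventions are not documented.

## The coverage bootstrap

Sequencing part of a library is subsampling without replacement: from a
population of `N = 100{,}000` fragments at level `p` (`round(pN)` C's),
draw `c` fragments and estimate $\hat m$. The bootstrap draws 1000 such
subsets per grid cell (hypergeometric counts via `rhyper`) and reports
the sample SD in percentage points; the closed form
$100\sqrt{p(1-p)/c \cdot (N-c)/(N-1)}$ serves as the independent oracle
in the tests. The level grid runs 0–100% in 10-point steps and the
coverage grid is 100, 200–2000 in steps of 200, then 3000, 4000, 5000 —
the package's reading of the protocol's abbreviated grid listing; both
are configurable. Per-cell seeds derive deterministically from the master
seed, so grids are reproducible cell by cell.

The cost proxy divides the combined SD (sum over levels) by the
coverage. Since combined SD decays as $k/\sqrt{c}$, the relative SD
reduction per additional 100× is $50/c$ independent of $k$; the cutoff
recommendation returns the smallest grid coverage where this marginal
gain is ≤ 5%, i.e. 1000×. The 5% criterion is an explicit calibration
chosen to make the qualitative "gain above this threshold is low"
argument reproducible; the $k/\sqrt{c}$ fit itself is used as a
diagnostic that rejects non-monotone curves beyond Monte-Carlo
tolerance.

```{r covsim, eval = FALSE}
cc <- cost_curve(build_grid(seed = 1))
plot(cc)
recommend_cutoff(cc)          # 1000
recommend_cutoff(cc, 0.025)   # 2000
```

## Numerical and interface choices

* **Coordinates**: BED input is 0-based half-open; all reported site
  positions are 1-based genomic, the common cytosine-report convention.
* **Boundaries** are inclusive-pass throughout (conversion ≥ 0.95,
  coverage ≥ 1000), per the strict "lower/less than" exclusion wording.
* **Amplicon lengths** outside 200–450 bp warn rather than fail; panels
  exist outside the typical range and a hard error would block them.
* **Degenerate inputs**: zero depth yields empty reads with a complete
  truth table; empty BED yields an empty panel; a unit without CHH
  coverage is an explicit undefined-rate failure, never a silent pass;
  `meth_fraction` is `NA` at zero coverage.
* **SAM I/O** reads through Rsamtools (temporary BAM); writing emits SAM
  text directly. Fully trimmed mates are kept as zero-length records
  in memory and skipped on write.

## Problem sizes used in the shipped checks

The package's own validation runs at desk scale, chosen to make the
statistics decisive yet quick: titration linearity on a synthetic
7-amplicon × 5-CpG panel at 2000× per level (post-filter coverage
≥ 1000×, conversion 99%, base error 10⁻³); the pooled-versus-triplicate
comparison at 3 × 1000× against 1 × 3000× over the same truth; parameter
recovery on 7 × 20 CpGs across 21 levels at 225× with perfect conversion
(2940 calls against exact binomial intervals); and the full default
bootstrap grid. Under these conditions the observed margins are wide:
per-amplicon mean R² ≈ 0.9995 against the 0.99 bound and condition
differences ≈ 0.5–0.7 pp against the 1 pp bound.

## Known limitations

* The caller assumes pure-`M` alignments (amplicon reads); indel-bearing
  reads are ignored in calling, with a warning.
* Conversion is estimated on CHH only; assays on genuinely
  CHH-methylated material (e.g. plants) would need a different QC signal.
* The artifact rule needs reference CpGs in the amplicon to calibrate its
  median coverage; CpG-free amplicons skip artifact detection with a
  warning.
* Replicate-SD aggregates depend on the chosen per-cell granularity;
  published aggregate values from other datasets may average differently.
* The simulator's clean error model (see above) bounds what green tests
  prove about messy real-world libraries.
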