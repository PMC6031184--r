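# hamtbs

Post-sequencing analysis for **targeted amplicon bisulfite sequencing
(TBS)** panels — the class of assays that PCR-amplify a handful of
bisulfite-converted regions (e.g. regulatory regions of a candidate gene
such as *FKBP5*) and sequence them to very high depth to quantify CpG
methylation with sub-percent accuracy in large sample cohorts.

The package is aimed at groups running such panels (or designing one) who
need the *analysis* side of the protocol after adapter trimming and
bisulfite alignment:

* **Panel model** — amplicons from BED + FASTA, cytosine context
  enumeration (CpG/CHG/CHH) on the assayed strand, in-silico bisulfite
  conversion, and multiplexing capacity arithmetic
  (`loading factor = samples x amplicons`, region covered =
  `amplicons x mean length`).
* **Read simulator** — paired bisulfite amplicon reads (SAM/FASTQ) with
  known per-CpG methylation, conversion efficiency, base-call error, depth
  and injected PCR artifacts, plus a truth table, so every downstream step
  is testable without sequencing data.
* **Overlap trimming** — paired-end mates of amplicons shorter than twice
  the read length overlap; the lower-quality mate loses the overlap so no
  template base is counted twice.
* **Methylation calling** — per-site counts of C (methylated) vs T
  (unmethylated) at base quality ≥ 20, in CpG and CHH context, including
  *read-evidenced* CpGs at non-reference positions (every read showing a
  CpG is considered, so SNP-created CpGs are not lost).
* **The three QC filters** — bisulfite conversion rate ≥ 95% per
  sample x amplicon (from CHH sites), PCR-artifact removal (non-reference
  CpGs at very low coverage *and* ~0/~100% methylation), and a minimum
  coverage of 1000x per CpG; plus survival summaries.
* **Titration validation** — per-CpG ordinary least squares of observed
  vs expected methylation across a 0/25/50/75/100% titration (slope,
  intercept, R²; mean R² per amplicon), condition comparisons
  (pooled vs replicated bisulfite/PCR designs) and replicate SDs.
* **Coverage bootstrap** — the subsampling experiment behind the 1000x
  rule: SD of estimated methylation over 1000 random subsets of a
  100,000-fragment population per level, the combined-SD cost proxy, and a
  marginal-gain cutoff recommendation.

## The statistics at the core

A site's methylation is estimated as `n_C / (n_C + n_T)` over
quality-passing informative bases. Sequencing at coverage `c` from a
library of `N` fragments methylated at level `p` is subsampling without
replacement, so the estimate's standard deviation follows the
hypergeometric law

    SD(p, c) = 100 * sqrt( p(1-p)/c * (N-c)/(N-1) )   [percentage points]

which the bootstrap module reproduces empirically. Summing SD over
methylation levels gives the combined SD per coverage; under the fitted
`k / sqrt(c)` decay the relative accuracy gain of 100 extra reads is
`50 / c`, which drops to 5% at `c = 1000` — the recommended minimum
coverage. Assay linearity is summarized per CpG by the coefficient of
determination R² of observed (%) on expected (%) methylation across the
titration, averaged per amplicon.

## Worked example

The package ships a small synthetic two-amplicon panel
(`inst/extdata/example_panel.{bed,fa}`, generated by `synthetic_panel()`).
The full in-silico titration — simulate five levels, trim overlaps, call,
QC, fit — runs in seconds:

```r
library(hamtbs)
bed <- system.file("extdata", "example_panel.bed", package = "hamtbs")
fa  <- system.file("extdata", "example_panel.fa",  package = "hamtbs")
pnl <- load_panel(bed, fa)
print(pnl)
#> TBS amplicon panel: 2 amplicon(s)
#>   amp01        amp01:0-250 (top strand, 250 bp, primers 20/20)
#>   amp02        amp02:0-250 (top strand, 250 bp, primers 20/20)

ex <- titration_experiment(pnl, depth = 1500, conversion = 0.99,
                           seed = 42, min_cov = 1000)
print(ex$qc)
#> TBS quality control
#>   sample x amplicon units: 10, passing all filters: 10 (100.0%)
#>   PCR-artifact sites flagged: 1
#>   sites retained: 674 of 675 (min coverage 1000)
print(ex$fit)
#> TBS titration linearity: 8 CpG(s), 2 amplicon(s)
#>  amplicon n_cpg mean_r_squared mean_slope nonlinear
#>     amp01     4      0.9997257  0.9922090     FALSE
#>     amp02     4      0.9996129  0.9910607     FALSE

cc <- cost_curve(build_grid(seed = 1))
recommend_cutoff(cc)
#> [1] 1000
```

Reading the output: all 10 sample x amplicon units passed conversion,
artifact and coverage filtering (one spurious read-evidenced CpG — a
sequencing-error artifact — was flagged and removed); each amplicon's
methylation signal is linear across the titration (mean R² > 0.999 with
slope ≈ 1); and the bootstrap cost curve flattens at 1000x coverage.

A command-line front end over the same functions is installed as
`exec/hamtbs` (`hamtbs simulate`, `trim-overlap`, `call`, `qc`,
`titrate`, `covsim`, `capacity`, ...).

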