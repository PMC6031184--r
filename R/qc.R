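#' Conversion-rate filter (QC step 1)
#'
#' A sample x amplicon unit fails when its CHH-derived bisulfite conversion
#' rate is *lower than* the threshold (a rate exactly at the threshold
#' passes); all its sites are excluded downstream. Units without any CHH
#' coverage cannot be certified and are marked failed with reason
#' `"no CHH coverage"`.
#'
#' @param calls A `tbs_calls` table.
#' @param threshold Minimum acceptable conversion rate.
#' @return data.frame per unit: `sample`, `amplicon`, `rate`, `pass`,
#'   `reason`.
#' @export
filter_conversion <- function(calls, threshold = 0.95) {
  units <- conversion_rates(calls)
  if (!nrow(units)) {
    units$pass <- logical(0)
    units$reason <- character(0)
    return(units)
  }
  units$pass <- !is.na(units$rate) & units$rate >= threshold
  units$reason <- ifelse(is.na(units$rate), "no CHH coverage",
                         ifelse(units$pass, "",
                                sprintf("conversion %.4f < %.2f",
                                        units$rate, threshold)))
  units
}

#' PCR-artifact detection (QC step 2)
#'
#' PCR errors occasionally fabricate CpG dinucleotides absent from the
#' reference; these read-evidenced sites surface at very low coverage and
#' extreme (~0% or ~100%) methylation. Rather than restricting analysis to
#' reference CpGs — which would also discard genuine SNP-created CpGs — a
#' non-reference CpG site is flagged as artifact only when its coverage is
#' below `cov_frac` of the amplicon's median reference-CpG coverage *and*
#' its methylation is within `extremity` of 0 or 1. Reference CpGs are never
#' flagged; a retained non-reference CpG is a candidate SNP-CpG.
#'
#' @param calls A `tbs_calls` table.
#' @param cov_frac "Very low coverage" cutoff, as a fraction of the unit's
#'   median reference-CpG coverage.
#' @param extremity "Extreme methylation" band half-width (fraction).
#' @return data.frame of the non-reference CpG sites with their coverage,
#'   methylation, the unit's median reference-CpG coverage and the
#'   `artifact` flag.
#' @export
detect_artifacts <- function(calls, cov_frac = 0.05, extremity = 0.05) {
  cand <- calls[calls$context == "CpG" & !calls$is_reference_cpg, ,
                drop = FALSE]
  out <- data.frame(sample = character(0), amplicon = character(0),
                    pos = integer(0), coverage = integer(0),
                    meth_fraction = numeric(0), median_ref_cov = numeric(0),
                    artifact = logical(0))
  if (!nrow(cand)) return(out)
  res <- lapply(seq_len(nrow(cand)), function(i) {
    s <- cand$sample[i]; a <- cand$amplicon[i]
    refcov <- calls$coverage[calls$sample == s & calls$amplicon == a &
                               calls$is_reference_cpg]
    if (!length(refcov)) {
      warning("amplicon '", a, "' (sample '", s,
              "') has no reference CpG; artifact detection skipped")
      med <- NA_real_
    } else med <- stats::median(refcov)
    mf <- cand$meth_fraction[i]
    flag <- !is.na(med) && cand$coverage[i] < cov_frac * med &&
      !is.na(mf) && (mf <= extremity || mf >= 1 - extremity)
    data.frame(sample = s, amplicon = a, pos = cand$pos[i],
               coverage = cand$coverage[i], meth_fraction = mf,
               median_ref_cov = med, artifact = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Minimum-coverage filter (QC step 3)
#'
#' Removes CpG-context sites supported by fewer than `min_cov` informative
#' reads (a site at exactly `min_cov` is retained). Non-CpG context sites
#' (the conversion-rate evidence) are left untouched.
#'
#' @param calls A `tbs_calls` table.
#' @param min_cov Minimum coverage.
#' @return The filtered `tbs_calls` table.
#' @export
filter_coverage <- function(calls, min_cov = 1000L) {
  drop <- calls$context == "CpG" & calls$coverage < min_cov
  out <- calls[!drop, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tbs_calls", "data.frame")
  out
}

#' Apply all three QC filters and summarize survival
#'
#' Runs the conversion-rate, PCR-artifact and minimum-coverage filters on a
#' calls table. All flags are computed from the *input* table, then
#' intersected, so the filters commute. A sample x amplicon unit "passes"
#' when its conversion rate passes and at least one of its reference CpGs
#' survives the coverage cutoff.
#'
#' @param calls A `tbs_calls` table (possibly several samples combined with
#'   `rbind`).
#' @param min_conversion Conversion-rate threshold (fraction).
#' @param min_cov Minimum CpG coverage.
#' @param cov_frac,extremity Artifact-detection knobs, see
#'   [detect_artifacts()].
#' @return An object of class `tbs_qc`: list with `calls` (retained sites),
#'   `units` (per-unit conversion/coverage/pass table), `artifacts`
#'   (non-reference CpG site flags), and `summary` (unit survival fraction,
#'   artifact and site counts).
#' @export
apply_qc <- function(calls, min_conversion = 0.95, min_cov = 1000L,
                     cov_frac = 0.05, extremity = 0.05) {
  conv <- filter_conversion(calls, min_conversion)
  art <- detect_artifacts(calls, cov_frac, extremity)
  qc_summary(calls, conv, art, min_cov = min_cov)
}

#' Summarize QC survival
#'
#' @param calls The unfiltered `tbs_calls` table.
#' @param conversion Output of [filter_conversion()].
#' @param artifacts Output of [detect_artifacts()].
#' @param min_cov Minimum CpG coverage.
#' @return A `tbs_qc` object (see [apply_qc()]).
#' @export
qc_summary <- function(calls, conversion = filter_conversion(calls),
                       artifacts = detect_artifacts(calls),
                       min_cov = 1000L) {
  art_key <- with(artifacts[artifacts$artifact, , drop = FALSE],
                  paste(sample, amplicon, pos))
  key <- paste(calls$sample, calls$amplicon, calls$pos)
  conv_key <- paste(conversion$sample, conversion$amplicon)[conversion$pass]
  unit_key <- paste(calls$sample, calls$amplicon)

  keep <- unit_key %in% conv_key &
    !(key %in% art_key) &
    !(calls$context == "CpG" & calls$coverage < min_cov)
  retained <- calls[keep, , drop = FALSE]
  rownames(retained) <- NULL
  class(retained) <- c("tbs_calls", "data.frame")

  units <- conversion
  rk <- paste(retained$sample, retained$amplicon)[retained$is_reference_cpg]
  units$coverage_pass <- paste(units$sample, units$amplicon) %in% rk
  units$pass <- units$pass & units$coverage_pass
  n_units <- nrow(units)
  structure(
    list(calls = retained, units = units, artifacts = artifacts,
         summary = list(
           n_units = n_units,
           n_units_pass = sum(units$pass),
           unit_pass_fraction = if (n_units) sum(units$pass) / n_units else NA_real_,
           n_artifact_sites = sum(artifacts$artifact),
           n_sites_in = nrow(calls),
           n_sites_retained = nrow(retained),
           min_cov = min_cov)),
    class = "tbs_qc")
}

#' @export
print.tbs_qc <- function(x, ...) {
  s <- x$summary
  cat("TBS quality control\n")
  cat(sprintf("  sample x amplicon units: %d, passing all filters: %d (%.1f%%)\n",
              s$n_units, s$n_units_pass, 100 * s$unit_pass_fraction))
  cat(sprintf("  PCR-artifact sites flagged: %d\n", s$n_artifact_sites))
  cat(sprintf("  sites retained: %d of %d (min coverage %d)\n",
              s$n_sites_retained, s$n_sites_in, s$min_cov))
  invisible(x)
}
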