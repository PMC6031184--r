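#' Build a titration observation table from calls and a sample sheet
#'
#' Joins a (QC-filtered) calls table with a sample sheet assigning each
#' sample its expected titration level, yielding the long-format percent
#' table used by [fit_titration()], [compare_conditions()] and
#' [replicate_sd()].
#'
#' @param calls A `tbs_calls` table (CpG-context sites are used).
#' @param sheet data.frame with columns `sample`, `expected_level` (percent,
#'   0-100) and optionally `condition` and `replicate`.
#' @return data.frame `amplicon`, `pos`, `level` (%), `meth` (%), plus
#'   `sample` and any `condition`/`replicate` columns present.
#' @export
titration_table <- function(calls, sheet) {
  stopifnot(all(c("sample", "expected_level") %in% names(sheet)))
  cpg <- calls[calls$context == "CpG", , drop = FALSE]
  i <- match(cpg$sample, sheet$sample)
  if (anyNA(i))
    stop("sample(s) missing from sheet: ",
         paste(unique(cpg$sample[is.na(i)]), collapse = ", "))
  out <- data.frame(amplicon = cpg$amplicon, pos = cpg$pos,
                    level = sheet$expected_level[i],
                    meth = 100 * cpg$meth_fraction,
                    sample = cpg$sample, stringsAsFactors = FALSE)
  for (col in c("condition", "replicate"))
    if (col %in% names(sheet)) out[[col]] <- sheet[[col]][i]
  out
}

#' Read a sample sheet TSV
#'
#' @param path TSV with header columns `sample`, `expected_level` and
#'   optionally `condition`, `replicate`.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "expected_level") %in% names(sheet)))
  sheet
}

#' Per-CpG titration linearity
#'
#' For each CpG, ordinary least squares of observed methylation (%) on the
#' expected titration level (%): slope, intercept and the coefficient of
#' determination R-squared. R-squared measures linearity of amplification of
#' the methylation signal; per amplicon the mean R-squared over its CpGs is
#' reported, and an amplicon is flagged nonlinear when that mean falls below
#' `r2_threshold` or its mean slope leaves `slope_range`. CpGs with zero
#' variance in the observations are degenerate: their R-squared is missing
#' and excluded from the amplicon mean.
#'
#' @param observed data.frame `amplicon`, `pos`, `level` (%), `meth` (%) as
#'   from [titration_table()] (replicate rows per level are pooled into the
#'   fit).
#' @param min_levels Minimum number of distinct levels per CpG.
#' @param r2_threshold,slope_range Nonlinearity flag knobs.
#' @return An object of class `tbs_titration`: list with `per_cpg` (slope,
#'   intercept, r_squared, n_levels) and `per_amplicon` (mean R-squared,
#'   mean slope, n CpGs, nonlinear flag).
#' @export
fit_titration <- function(observed, min_levels = 3L, r2_threshold = 0.98,
                          slope_range = c(0.9, 1.1)) {
  stopifnot(all(c("amplicon", "pos", "level", "meth") %in% names(observed)))
  observed <- observed[!is.na(observed$meth), , drop = FALSE]
  keyf <- interaction(observed$amplicon, observed$pos, drop = TRUE)
  per_cpg <- lapply(split(observed, keyf), function(d) {
    nl <- length(unique(d$level))
    if (nl < min_levels)
      stop("CpG ", d$amplicon[1], ":", d$pos[1], " observed at only ", nl,
           " level(s); need >= ", min_levels)
    if (stats::var(d$meth) == 0) {
      return(data.frame(amplicon = d$amplicon[1], pos = d$pos[1],
                        slope = 0, intercept = d$meth[1],
                        r_squared = NA_real_, n_levels = nl,
                        stringsAsFactors = FALSE))
    }
    fit <- stats::lm(meth ~ level, data = d)
    # R^2 computed directly (summary.lm warns on noise-free fits)
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((d$meth - mean(d$meth))^2)
    data.frame(amplicon = d$amplicon[1], pos = d$pos[1],
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = r2, n_levels = nl,
               stringsAsFactors = FALSE)
  })
  per_cpg <- do.call(rbind, per_cpg)
  per_cpg <- per_cpg[order(per_cpg$amplicon, per_cpg$pos), , drop = FALSE]
  rownames(per_cpg) <- NULL
  per_amp <- lapply(split(per_cpg, per_cpg$amplicon), function(d) {
    mr2 <- if (all(is.na(d$r_squared))) NA_real_
    else mean(d$r_squared, na.rm = TRUE)
    ms <- mean(d$slope)
    data.frame(amplicon = d$amplicon[1], n_cpg = nrow(d),
               mean_r_squared = mr2, mean_slope = ms,
               nonlinear = !is.na(mr2) &
                 (mr2 < r2_threshold | ms < slope_range[1] | ms > slope_range[2]),
               stringsAsFactors = FALSE)
  })
  per_amp <- do.call(rbind, per_amp)
  rownames(per_amp) <- NULL
  structure(list(per_cpg = per_cpg, per_amplicon = per_amp,
                 r2_threshold = r2_threshold, slope_range = slope_range),
            class = "tbs_titration")
}

#' @export
print.tbs_titration <- function(x, ...) {
  cat("TBS titration linearity:", nrow(x$per_cpg), "CpG(s),",
      nrow(x$per_amplicon), "amplicon(s)\n")
  print(x$per_amplicon, row.names = FALSE)
  invisible(x)
}

#' Compare methylation between two conditions
#'
#' Mean absolute methylation difference (percentage points) between a test
#' condition and a reference condition, per amplicon x level and per
#' amplicon, over the sites present in both tables (inner join on
#' amplicon/pos/level).
#'
#' @param test,reference data.frames with `amplicon`, `pos`, `level`, `meth`
#'   (%), one observation per site x level (average replicates beforehand).
#' @return An object of class `tbs_condcmp`: list with `per_cell` (amplicon
#'   x level mean |difference|), `per_amplicon`, and `overall` (mean of the
#'   per-amplicon means).
#' @export
compare_conditions <- function(test, reference) {
  m <- merge(test[, c("amplicon", "pos", "level", "meth")],
             reference[, c("amplicon", "pos", "level", "meth")],
             by = c("amplicon", "pos", "level"),
             suffixes = c("_test", "_ref"))
  m <- m[!is.na(m$meth_test) & !is.na(m$meth_ref), , drop = FALSE]
  if (!nrow(m))
    stop("no shared (amplicon, pos, level) sites between the two conditions")
  m$absdiff <- abs(m$meth_test - m$meth_ref)
  per_cell <- stats::aggregate(absdiff ~ amplicon + level, data = m, FUN = mean)
  names(per_cell)[3] <- "mean_abs_diff"
  per_amp <- stats::aggregate(absdiff ~ amplicon, data = m, FUN = mean)
  names(per_amp)[2] <- "mean_abs_diff"
  structure(list(per_cell = per_cell[order(per_cell$amplicon, per_cell$level), ],
                 per_amplicon = per_amp,
                 overall = mean(per_amp$mean_abs_diff),
                 n_sites = nrow(m)),
            class = "tbs_condcmp")
}

#' @export
print.tbs_condcmp <- function(x, ...) {
  cat(sprintf(
    "TBS condition comparison over %d site x level observation(s)\n", x$n_sites))
  print(x$per_amplicon, row.names = FALSE)
  cat(sprintf("overall mean |difference|: %.3f percentage points\n", x$overall))
  invisible(x)
}

#' Replicate standard deviations
#'
#' Technical-variability summary over replicate measurements: the sample SD
#' (n-1 denominator, percentage points) per CpG x level cell, aggregated as
#' the mean and maximum over all cells. Cells with fewer than two replicates
#' are excluded with a warning.
#'
#' @param replicates data.frame `amplicon`, `pos`, `level`, `replicate`,
#'   `meth` (%).
#' @return An object of class `tbs_repstats`: list with `per_cell` (SD per
#'   CpG x level), `mean_sd`, `max_sd`, `n_cells`.
#' @export
replicate_sd <- function(replicates) {
  stopifnot(all(c("amplicon", "pos", "level", "meth") %in% names(replicates)))
  keyf <- interaction(replicates$amplicon, replicates$pos, replicates$level,
                      drop = TRUE)
  cells <- lapply(split(replicates, keyf), function(d) {
    data.frame(amplicon = d$amplicon[1], pos = d$pos[1], level = d$level[1],
               n = nrow(d),
               sd = if (nrow(d) >= 2L) stats::sd(d$meth) else NA_real_,
               stringsAsFactors = FALSE)
  })
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  dropped <- sum(cells$n < 2L)
  if (dropped)
    warning(dropped, " cell(s) with < 2 replicates excluded")
  ok <- cells[cells$n >= 2L, , drop = FALSE]
  structure(list(per_cell = ok,
                 mean_sd = if (nrow(ok)) mean(ok$sd) else NA_real_,
                 max_sd = if (nrow(ok)) max(ok$sd) else NA_real_,
                 n_cells = nrow(ok)),
            class = "tbs_repstats")
}

#' @export
print.tbs_repstats <- function(x, ...) {
  cat(sprintf(
    "TBS replicate SD over %d CpG x level cell(s): mean %.2f%%, max %.2f%%\n",
    x$n_cells, x$mean_sd, x$max_sd))
  invisible(x)
}
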