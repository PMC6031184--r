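#' Bootstrap SD of methylation estimates at one level and coverage
#'
#' A sequencing run observes a random subset of the amplicon library, so
#' methylation quantification at coverage `c` is subsampling `c` fragments
#' without replacement from a finite population of `N` fragments of which
#' `round(p * N)` carry C (methylated) and the rest T. This draws `n_boot`
#' such subsets, estimates methylation in each, and returns the sample SD of
#' the estimates in percentage points. The closed-form counterpart is the
#' hypergeometric SD `100 * sqrt(p(1-p)/c * (N-c)/(N-1))`.
#'
#' @param p Methylation level (fraction in `[0,1]`).
#' @param coverage Subset size `c` (must not exceed `N`).
#' @param N Fragment population size.
#' @param n_boot Number of bootstrap subsets.
#' @param seed Optional RNG seed.
#' @return SD of the estimated methylation level, percentage points.
#' @export
subsample_sd <- function(p, coverage, N = 100000L, n_boot = 1000L,
                         seed = NULL) {
  stopifnot(p >= 0, p <= 1, coverage >= 0, n_boot >= 2)
  if (coverage > N)
    stop("coverage (", coverage, ") exceeds the fragment population (", N, ")")
  if (!is.null(seed)) set.seed(seed)
  if (coverage == 0L) return(NA_real_)
  m <- round(p * N)
  draws <- stats::rhyper(n_boot, m, N - m, coverage)
  stats::sd(draws / coverage) * 100
}

#' Default coverage grid
#'
#' `100, 200, 400, ..., 2000` in steps of 200, then `3000, 4000, 5000`.
#' @return Integer vector of coverages.
#' @export
default_coverages <- function() {
  as.integer(c(100, seq(200, 2000, by = 200), 3000, 4000, 5000))
}

#' Simulate the SD grid over methylation levels and coverages
#'
#' Fills an SD table over the (level, coverage) grid with [subsample_sd()],
#' one deterministic per-cell seed derived from the master seed, so the grid
#' is reproducible cell by cell.
#'
#' @param levels Methylation levels in percent (default 0-100 by 10).
#' @param coverages Coverage grid (default [default_coverages()]).
#' @param N Fragment population size per level.
#' @param n_boot Bootstrap subsets per cell (a value below 100 triggers a
#'   high-variance warning).
#' @param seed Master RNG seed.
#' @return An object of class `tbs_simgrid`: data.frame `level` (%),
#'   `coverage`, `sd` (pp), with the grid parameters as attributes.
#' @export
build_grid <- function(levels = seq(0, 100, by = 10),
                       coverages = default_coverages(),
                       N = 100000L, n_boot = 1000L, seed = 1L) {
  if (!length(levels) || !length(coverages))
    stop("empty level or coverage grid")
  if (n_boot < 100L)
    warning("n_boot = ", n_boot, " gives a high-variance SD table")
  grid <- expand.grid(level = levels, coverage = coverages,
                      KEEP.OUT.ATTRS = FALSE)
  grid$sd <- vapply(seq_len(nrow(grid)), function(i) {
    cell_seed <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    subsample_sd(grid$level[i] / 100, grid$coverage[i], N = N,
                 n_boot = n_boot, seed = cell_seed)
  }, numeric(1))
  structure(grid, class = c("tbs_simgrid", "data.frame"),
            N = N, n_boot = n_boot, seed = seed)
}

#' Accuracy-versus-cost curve from an SD grid
#'
#' Per coverage, the combined SD is the sum of the per-level SDs — the
#' grid's one-number accuracy summary — and the cost proxy divides the
#' combined SD by the sequencing depth, trading accuracy gained against
#' reads spent.
#'
#' @param grid A `tbs_simgrid`.
#' @return An object of class `tbs_costcurve`: data.frame `coverage`,
#'   `combined_sd` (pp), `cost`.
#' @export
cost_curve <- function(grid) {
  stopifnot(inherits(grid, "tbs_simgrid"))
  agg <- stats::aggregate(sd ~ coverage, data = grid, FUN = sum)
  names(agg)[2] <- "combined_sd"
  agg <- agg[order(agg$coverage), , drop = FALSE]
  agg$cost <- agg$combined_sd / agg$coverage
  rownames(agg) <- NULL
  structure(agg, class = c("tbs_costcurve", "data.frame"))
}

#' Recommend a minimum-coverage cutoff
#'
#' Under binomial/hypergeometric subsampling the combined SD decays as
#' `k / sqrt(c)`, so the relative SD reduction gained by 100 further reads
#' is `50 / c` regardless of `k`. The recommended cutoff is the smallest
#' grid coverage at which that marginal gain drops to `marginal_gain` or
#' less — past it, extra depth buys little accuracy. The `k / sqrt(c)` model
#' is fitted to the curve and used as a diagnostic: a curve that *rises*
#' with coverage beyond Monte-Carlo tolerance is rejected.
#'
#' @param curve A `tbs_costcurve`.
#' @param marginal_gain Relative SD reduction per additional 100x coverage
#'   below which more depth is not worthwhile.
#' @return The recommended coverage (an element of the grid).
#' @export
recommend_cutoff <- function(curve, marginal_gain = 0.05) {
  stopifnot(inherits(curve, "tbs_costcurve"))
  if (nrow(curve) < 3L)
    stop("need at least 3 grid coverages to recommend a cutoff")
  if (all(curve$combined_sd == 0))
    stop("flat zero SD curve: no finite coverage recommendation")
  fit <- stats::lm(combined_sd ~ 0 + I(1 / sqrt(coverage)), data = curve)
  k <- unname(stats::coef(fit)[1])
  # diagnostic: the combined SD must not increase with coverage beyond
  # Monte-Carlo noise (10% of the fitted value)
  rises <- diff(curve$combined_sd) > 0.10 * (k / sqrt(curve$coverage[-nrow(curve)]))
  if (any(rises))
    stop("combined SD increases with coverage beyond Monte-Carlo tolerance; ",
         "check n_boot or the grid")
  ok <- curve$coverage[50 / curve$coverage <= marginal_gain]
  if (!length(ok)) {
    warning("no grid coverage reaches the requested marginal gain; ",
            "returning the largest")
    return(max(curve$coverage))
  }
  min(ok)
}

#' @export
print.tbs_simgrid <- function(x, ...) {
  cat(sprintf(
    "TBS coverage-accuracy grid: %d level(s) x %d coverage(s), N = %d, %d bootstrap subsets\n",
    length(unique(x$level)), length(unique(x$coverage)),
    attr(x, "N"), attr(x, "n_boot")))
  print(utils::head(as.data.frame(x), 8), row.names = FALSE)
  if (nrow(x) > 8) cat("  ...", nrow(x) - 8, "more row(s)\n")
  invisible(x)
}

#' @export
print.tbs_costcurve <- function(x, ...) {
  cat("TBS coverage cost curve\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
plot.tbs_costcurve <- function(x, ...) {
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(x$coverage, x$combined_sd, type = "b", log = "x",
                 xlab = "coverage", ylab = "combined SD (pp)", ...)
  graphics::plot(x$coverage, x$cost, type = "b", log = "xy",
                 xlab = "coverage", ylab = "combined SD / coverage", ...)
  invisible(x)
}
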