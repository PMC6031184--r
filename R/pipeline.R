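#' Simulate, trim and call one titration series
#'
#' Runs the full in-silico titration validation: for each expected level, a
#' sample is simulated over the panel, overlap-trimmed and called; the
#' per-level call tables are combined and QC-filtered, and per-CpG
#' linearity is fitted across levels. This is the desk-scale analogue of
#' sequencing 0/25/50/75/100% methylated control DNA over a panel.
#'
#' @param pnl A `tbs_panel`.
#' @param levels_pct Expected methylation levels in percent.
#' @param depth Fragments per amplicon per level.
#' @param conversion,base_error,read_length Passed to [sim_config()].
#' @param seed Master seed; per-level seeds are derived from it.
#' @param min_cov Coverage filter applied before fitting.
#' @param sample_prefix Prefix for the per-level sample names.
#' @return List with `calls` (combined raw calls), `qc` (the `tbs_qc`),
#'   `table` (titration observation table) and `fit` (`tbs_titration`).
#' @export
titration_experiment <- function(pnl, levels_pct = c(0, 25, 50, 75, 100),
                                 depth = 2000L, conversion = 0.99,
                                 base_error = 0.001, read_length = 250L,
                                 seed = 1L, min_cov = 1000L,
                                 sample_prefix = "titr") {
  profiles <- mix_titration(pnl, levels_pct / 100)
  calls <- vector("list", length(levels_pct))
  sheet <- data.frame(sample = sprintf("%s_L%03d", sample_prefix, levels_pct),
                      expected_level = levels_pct, stringsAsFactors = FALSE)
  for (i in seq_along(levels_pct)) {
    cfg <- sim_config(depth = depth, conversion = conversion,
                      base_error = base_error, read_length = read_length,
                      seed = (as.integer(seed) + 1009L * i) %% .Machine$integer.max)
    sim <- simulate_sample(pnl, profiles[[i]], cfg, sample = sheet$sample[i])
    sim <- trim_overlap(sim)
    calls[[i]] <- call_sites(sim, pnl)
  }
  calls <- do.call(rbind, calls)
  class(calls) <- c("tbs_calls", "data.frame")
  qc <- apply_qc(calls, min_cov = min_cov)
  tab <- titration_table(qc$calls, sheet)
  list(calls = calls, qc = qc, table = tab, fit = fit_titration(tab))
}

#' Simulate and compare replicate versus pooled conditions
#'
#' In-silico version of the condition comparison used to validate pooling
#' strategies: the reference condition (C1) is three independent samples at
#' `depth_ref` each, with per-site methylation taken as the mean of the
#' three estimates; the test condition (C2) is a single pooled sample at
#' `n_rep * depth_ref` (by default 3000x), simulated from the same truth.
#' The two are compared as mean absolute methylation difference per
#' amplicon.
#'
#' @param pnl A `tbs_panel`.
#' @param levels_pct Titration levels in percent.
#' @param depth_ref Per-replicate depth of the reference condition.
#' @param n_rep Number of reference replicates (and the pooling factor of
#'   the test condition).
#' @param conversion,base_error,read_length Passed to [sim_config()].
#' @param seed Master seed.
#' @param min_cov Coverage filter.
#' @return List with `reference` and `test` titration tables, `replicates`
#'   (the per-replicate reference table, suitable for [replicate_sd()]) and
#'   `comparison` (a `tbs_condcmp`).
#' @export
condition_experiment <- function(pnl, levels_pct = c(0, 25, 50, 75, 100),
                                 depth_ref = 1000L, n_rep = 3L,
                                 conversion = 0.99, base_error = 0.001,
                                 read_length = 250L, seed = 1L,
                                 min_cov = NULL) {
  if (is.null(min_cov)) min_cov <- depth_ref %/% 2L
  profiles <- mix_titration(pnl, levels_pct / 100)
  sim_call <- function(profile, depth, sample, sub_seed) {
    cfg <- sim_config(depth = depth, conversion = conversion,
                      base_error = base_error, read_length = read_length,
                      seed = sub_seed)
    sim <- trim_overlap(simulate_sample(pnl, profile, cfg, sample = sample))
    call_sites(sim, pnl)
  }
  rep_tabs <- list(); c2_tabs <- list()
  s <- as.integer(seed)
  for (i in seq_along(levels_pct)) {
    lvl <- levels_pct[i]
    for (r in seq_len(n_rep)) {
      nm <- sprintf("C1_L%03d_r%d", lvl, r)
      calls <- sim_call(profiles[[i]], depth_ref, nm,
                        (s + 2003L * i + 101L * r) %% .Machine$integer.max)
      calls <- filter_coverage(calls, min_cov)
      tab <- titration_table(calls, data.frame(sample = nm,
                                               expected_level = lvl))
      tab$replicate <- r
      rep_tabs[[nm]] <- tab
    }
    nm <- sprintf("C2_L%03d", lvl)
    calls <- sim_call(profiles[[i]], n_rep * depth_ref, nm,
                      (s + 2003L * i + 577L) %% .Machine$integer.max)
    calls <- filter_coverage(calls, n_rep * min_cov)
    c2_tabs[[nm]] <- titration_table(calls, data.frame(sample = nm,
                                                       expected_level = lvl))
  }
  replicates <- do.call(rbind, rep_tabs)
  rownames(replicates) <- NULL
  # reference methylation = mean of the replicate estimates per site x level
  reference <- stats::aggregate(meth ~ amplicon + pos + level,
                                data = replicates, FUN = mean)
  test <- do.call(rbind, c2_tabs)
  rownames(test) <- NULL
  list(reference = reference, test = test, replicates = replicates,
       comparison = compare_conditions(test, reference))
}
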