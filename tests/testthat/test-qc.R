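# a unit with an exact CHH conversion rate and one CpG site
unit_rows <- function(sample, amp, n_unconv, n_conv, cpg_cov = 1500,
                      cpg_meth = 0.5) {
  rbind(site_row(sample, amp, 10, "CHH", FALSE, n_unconv, n_conv),
        site_row(sample, amp, 20, "CpG", TRUE, round(cpg_cov * cpg_meth),
                 cpg_cov - round(cpg_cov * cpg_meth)))
}

test_that("conversion filter excludes rates strictly below threshold", {
  calls <- as_calls(rbind(
    unit_rows("s1", "a1", 10, 990),    # 0.99  -> pass
    unit_rows("s2", "a1", 50, 950),    # 0.95  -> pass (boundary)
    unit_rows("s3", "a1", 51, 949)))   # 0.949 -> fail
  fc <- filter_conversion(calls)
  expect_equal(fc$pass[match(c("s1", "s2", "s3"), fc$sample)],
               c(TRUE, TRUE, FALSE))
  # a unit without CHH coverage cannot be certified
  calls2 <- as_calls(site_row("s4", "a1", 20, "CpG", TRUE, 5, 5))
  fc2 <- filter_conversion(calls2)
  expect_false(fc2$pass)
  expect_equal(fc2$reason, "no CHH coverage")
  empty <- as_calls(site_row("x", "y", 1, "CpG", TRUE, 1, 1)[0, ])
  expect_equal(nrow(filter_conversion(empty)), 0L)
})

test_that("artifact detection follows the low-coverage extreme-level rule", {
  base <- rbind(
    site_row("s1", "a1", seq(30, 70, 10), "CpG", TRUE, 1000, 1000),  # median 2000
    site_row("s1", "a1", 11, "CpG", FALSE, 12, 0),      # low cov, 100% -> artifact
    site_row("s1", "a1", 12, "CpG", FALSE, 0, 30),      # low cov, 0%  -> artifact
    site_row("s1", "a1", 13, "CpG", FALSE, 893, 1007),  # SNP-CpG, 47% -> keep
    site_row("s1", "a1", 14, "CpG", FALSE, 120, 0))     # extreme but 6% of median: keep
  art <- detect_artifacts(as_calls(base))
  expect_equal(art$artifact[match(c(11, 12, 13, 14), art$pos)],
               c(TRUE, TRUE, FALSE, FALSE))
  # reference CpGs are never artifact-flagged, however extreme
  ref_ext <- as_calls(rbind(base,
                            site_row("s1", "a1", 15, "CpG", TRUE, 5, 0)))
  art2 <- detect_artifacts(ref_ext)
  expect_false(15 %in% art2$pos)
  # an amplicon with no reference CpG cannot calibrate the rule
  lonely <- as_calls(site_row("s9", "a9", 5, "CpG", FALSE, 3, 0))
  expect_warning(detect_artifacts(lonely), "no reference CpG")
})

test_that("coverage filter boundary is exactly 1000", {
  calls <- as_calls(rbind(
    site_row("s1", "a1", 1, "CpG", TRUE, 500, 500),   # 1000 -> retained
    site_row("s1", "a1", 2, "CpG", TRUE, 499, 500),   # 999  -> removed
    site_row("s1", "a1", 3, "CHH", FALSE, 1, 50)))    # CHH untouched
  kept <- filter_coverage(calls, 1000)
  expect_equal(sort(kept$pos), c(1, 3))
  expect_equal(nrow(filter_coverage(calls[0, ], 1000)), 0L)
  full <- as_calls(site_row("s1", "a1", 1:3, "CpG", TRUE, 600, 600))
  expect_equal(nrow(filter_coverage(full, 1000)), 3L)
})

test_that("raising the coverage cutoff never retains more sites", {
  pnl <- synthetic_panel(2, amp_len = 220, n_cpg = 4, seed = 40)
  sim <- simulate_sample(pnl, mix_titration(pnl, 0.4)[[1]],
                         sim_config(depth = 300, seed = 41))
  calls <- call_sites(trim_overlap(sim), pnl)
  n_prev <- Inf
  for (mc in c(0, 100, 250, 290, 301)) {
    n <- nrow(filter_coverage(calls, mc))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("the three filters commute", {
  calls <- as_calls(rbind(
    unit_rows("s1", "a1", 10, 990, cpg_cov = 1500),
    unit_rows("s2", "a1", 80, 920, cpg_cov = 1500),   # conversion fail
    unit_rows("s1", "a2", 5, 995, cpg_cov = 800),     # coverage fail
    site_row("s1", "a1", 77, "CpG", FALSE, 8, 0)))    # artifact
  qc <- apply_qc(calls, min_cov = 1000)
  key <- function(df) sort(paste(df$sample, df$amplicon, df$pos))
  # order 1: conversion, artifacts, coverage; order 2: coverage first
  conv <- filter_conversion(calls)
  art <- detect_artifacts(calls)
  ck <- paste(conv$sample, conv$amplicon)[conv$pass]
  ak <- with(art[art$artifact, ], paste(sample, amplicon, pos))
  o1 <- calls[paste(calls$sample, calls$amplicon) %in% ck, ]
  o1 <- o1[!paste(o1$sample, o1$amplicon, o1$pos) %in% ak, ]
  o1 <- filter_coverage(as_calls(o1), 1000)
  o2 <- filter_coverage(calls, 1000)
  o2 <- o2[!paste(o2$sample, o2$amplicon, o2$pos) %in% ak, ]
  o2 <- o2[paste(o2$sample, o2$amplicon) %in% ck, ]
  expect_equal(key(qc$calls), key(o1))
  expect_equal(key(qc$calls), key(o2))
})

test_that("injected artifacts are flagged and SNP-CpGs survive, across seeds", {
  for (seed in c(51, 52, 53)) {
    pnl <- synthetic_panel(1, amp_len = 250, n_cpg = 4, seed = seed)
    ctx <- enumerate_contexts(pnl)
    chh <- ctx[ctx$context == "CHH" & !ctx$in_primer, ]
    sim <- simulate_sample(pnl, mix_titration(pnl, 0.5)[[1]],
                           sim_config(depth = 2000, base_error = 0,
                                      seed = seed + 100))
    sim <- inject_artifacts(sim, pnl,
                            data.frame(amplicon = "amp01",
                                       pos = chh$pos[c(2, 6)]), 15)
    calls <- call_sites(trim_overlap(sim), pnl)
    art <- detect_artifacts(calls)
    flagged <- art$pos[art$artifact]
    expect_setequal(flagged, chh$pos[c(2, 6)])
  }
  # full-coverage intermediate-methylation SNP-CpG is never flagged
  pnl <- synthetic_panel(1, amp_len = 250, n_cpg = 4, seed = 54)
  ctx <- enumerate_contexts(pnl)
  chh <- ctx[ctx$context == "CHH" & !ctx$in_primer, ]
  var_seq <- pnl[["amp01"]]$ref_seq
  substr(var_seq, chh$offset[4] + 1L, chh$offset[4] + 1L) <- "G"
  vpnl <- panel(amplicon("amp01", var_seq, len_range = c(50, 600),
                         fwd_primer_len = 20, rev_primer_len = 20))
  sim <- simulate_sample(vpnl, mix_titration(vpnl, 0.5)[[1]],
                         sim_config(depth = 2000, base_error = 0, seed = 55))
  calls <- call_sites(trim_overlap(sim), pnl)
  art <- detect_artifacts(calls)
  expect_true(chh$pos[4] %in% art$pos)
  expect_false(art$artifact[art$pos == chh$pos[4]])
})

test_that("QC survival fractions count sample x amplicon units", {
  # 10 units, one failing conversion
  calls <- as_calls(do.call(rbind, lapply(1:10, function(i)
    unit_rows(sprintf("s%02d", i), "a1",
              n_unconv = if (i == 1) 80 else 10,
              n_conv = if (i == 1) 920 else 990))))
  qc <- apply_qc(calls, min_cov = 1000)
  expect_equal(qc$summary$unit_pass_fraction, 0.9)
  qc_all <- apply_qc(as_calls(calls[calls$sample != "s01", ]),
                     min_cov = 1000)
  expect_equal(qc_all$summary$unit_pass_fraction, 1.0)
})

test_that("a cohort-scale fixture yields the exact survival fraction", {
  # 95 samples x 29 amplicons, 9 units failing conversion
  samples <- sprintf("s%02d", 1:95)
  amps <- sprintf("a%02d", 1:29)
  grid <- expand.grid(sample = samples, amplicon = amps,
                      stringsAsFactors = FALSE)
  fail <- paste(grid$sample, grid$amplicon) %in%
    paste(sprintf("s%02d", 1:9), "a07")
  chh <- site_row(grid$sample, grid$amplicon, 10, "CHH", FALSE,
                  ifelse(fail, 80, 10), ifelse(fail, 920, 990))
  cpg <- site_row(grid$sample, grid$amplicon, 20, "CpG", TRUE, 800, 800)
  qc <- apply_qc(as_calls(rbind(chh, cpg)), min_cov = 1000)
  expect_equal(qc$summary$n_units, 2755)
  expect_equal(qc$summary$unit_pass_fraction, (2755 - 9) / 2755)
})
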