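test_that("titration mixing yields one uniform profile per level", {
  pnl <- synthetic_panel(2, amp_len = 200, n_cpg = 4, seed = 2)
  profs <- mix_titration(pnl, c(0, 0.25, 0.5, 0.75, 1))
  expect_length(profs, 5)
  for (i in seq_along(profs)) {
    expect_equal(nrow(profs[[i]]), 8)  # 2 amplicons x 4 CpGs
    expect_true(all(profs[[i]]$meth == c(0, 0.25, 0.5, 0.75, 1)[i]))
  }
  expect_length(mix_titration(pnl, numeric(0)), 0)
  expect_true(all(mix_titration(pnl, 0.1)[[1]]$meth == 0.1))
  expect_error(mix_titration(pnl, 1.2), "\\[0, 1\\]")
})

test_that("a fixed seed makes simulation output byte-identical", {
  pnl <- synthetic_panel(2, amp_len = 200, n_cpg = 3, seed = 3)
  prof <- mix_titration(pnl, 0.3)[[1]]
  cfg <- sim_config(depth = 50, seed = 99)
  s1 <- simulate_sample(pnl, prof, cfg)
  s2 <- simulate_sample(pnl, prof, cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_sample(pnl, prof, sim_config(depth = 50, seed = 100))
  expect_false(identical(s1$records$seq, s3$records$seq))
})

test_that("zero depth yields an empty read set but a complete truth table", {
  pnl <- synthetic_panel(2, amp_len = 200, n_cpg = 3, seed = 3)
  sim <- simulate_sample(pnl, mix_titration(pnl, 0.5)[[1]],
                         sim_config(depth = 0, seed = 1))
  expect_equal(nrow(sim$records), 0L)
  expect_equal(nrow(sim$truth), 6L)
  expect_true(all(!sim$truth$artifact))
})

test_that("simulated reads use the DNA alphabet and respect coordinates", {
  pnl <- synthetic_panel(2, amp_len = 220, n_cpg = 3, seed = 4)
  sim <- simulate_sample(pnl, mix_titration(pnl, 0.5)[[1]],
                         sim_config(depth = 30, read_length = 120, seed = 5))
  expect_false(any(grepl("[^ACGTN]", sim$records$seq)))
  ends <- sim$records$pos + nchar(sim$records$seq) - 1L
  expect_true(all(sim$records$pos >= 1L & ends <= 220L))
  # with no base errors and full conversion, non-cytosine reference bases
  # are reproduced verbatim
  sim0 <- simulate_sample(pnl, mix_titration(pnl, 1)[[1]],
                          sim_config(depth = 5, conversion = 1,
                                     base_error = 0, seed = 6))
  for (i in seq_len(nrow(sim0$records))) {
    r <- sim0$records[i, ]
    ref <- substr(hamtbs:::working_seq(pnl[[r$rname]]), r$pos,
                  r$pos + nchar(r$seq) - 1L)
    # every C is a CpG-protected or reference C; T may replace C only
    expect_equal(gsub("C", "T", r$seq), gsub("C", "T", ref))
  }
})

test_that("simulated methylation matches the profile binomially", {
  pnl <- synthetic_panel(1, amp_len = 250, n_cpg = 5, seed = 8)
  sim <- simulate_sample(pnl, mix_titration(pnl, 0.5)[[1]],
                         sim_config(depth = 5000, conversion = 1,
                                    base_error = 0, seed = 9))
  calls <- call_sites(trim_overlap(sim), pnl)
  cpg <- calls[calls$is_reference_cpg, ]
  expect_equal(nrow(cpg), 5L)
  expect_true(all(cpg$coverage == 5000L))
  lo <- qbinom(0.0005, 5000, 0.5); hi <- qbinom(0.9995, 5000, 0.5)
  expect_true(all(cpg$n_meth >= lo & cpg$n_meth <= hi))
})

test_that("incomplete conversion leaves the expected CHH residue", {
  pnl <- synthetic_panel(1, amp_len = 250, n_cpg = 3, seed = 10)
  sim <- simulate_sample(pnl, mix_titration(pnl, 0)[[1]],
                         sim_config(depth = 400, conversion = 0.95,
                                    base_error = 0, seed = 11))
  calls <- call_sites(trim_overlap(sim), pnl)
  chh <- calls[calls$context == "CHH", ]
  n <- sum(chh$coverage)
  frac_uncov <- sum(chh$n_meth) / n
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(frac_uncov - 0.05), 3 * se)
})

test_that("a profile missing a reference CpG is rejected", {
  pnl <- synthetic_panel(1, amp_len = 200, n_cpg = 3, seed = 12)
  prof <- mix_titration(pnl, 0.5)[[1]][-1, ]
  expect_error(simulate_sample(pnl, prof, sim_config(depth = 5, seed = 1)),
               "missing")
})

test_that("artifact injection creates spurious low-coverage CpG signals", {
  pnl <- synthetic_panel(1, amp_len = 250, n_cpg = 4, seed = 13)
  ctx <- enumerate_contexts(pnl)
  chh <- ctx[ctx$context == "CHH" & !ctx$in_primer, ]
  sim <- simulate_sample(pnl, mix_titration(pnl, 0.5)[[1]],
                         sim_config(depth = 2000, base_error = 0, seed = 14))
  pos1 <- data.frame(amplicon = "amp01", pos = chh$pos[3])
  simA <- inject_artifacts(sim, pnl, pos1, n_reads = 10)
  calls <- call_sites(trim_overlap(simA), pnl)
  art <- calls[!calls$is_reference_cpg & calls$pos == chh$pos[3], ]
  expect_equal(nrow(art), 1L)
  expect_equal(art$n_meth, 10)
  expect_equal(art$coverage, 10)
  expect_equal(art$meth_fraction, 1.0)

  # bookkeeping: zero reads is a no-op; two positions flag two truth rows
  expect_identical(inject_artifacts(sim, pnl, pos1, 0), sim)
  sim2 <- inject_artifacts(sim, pnl,
                           data.frame(amplicon = "amp01",
                                      pos = chh$pos[c(4, 5)]), 5)
  expect_equal(sum(sim2$truth$artifact), 2L)

  # a reference CpG is not a legal artifact target
  cpg_pos <- ctx$pos[ctx$is_reference_cpg][1]
  expect_error(inject_artifacts(sim, pnl,
                                data.frame(amplicon = "amp01", pos = cpg_pos),
                                5),
               "reference CpG")
})
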