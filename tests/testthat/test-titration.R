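obs_df <- function(meth, levels = c(0, 25, 50, 75, 100), amp = "a1", pos = 1) {
  data.frame(amplicon = amp, pos = pos, level = levels, meth = meth,
             stringsAsFactors = FALSE)
}

test_that("per-CpG least squares recovers slope, intercept and R-squared", {
  fit <- fit_titration(obs_df(c(0, 25, 50, 75, 100)))
  expect_equal(fit$per_cpg$slope, 1)
  expect_equal(fit$per_cpg$intercept, 0)
  expect_equal(fit$per_cpg$r_squared, 1)

  fit <- fit_titration(obs_df(c(0, 20, 40, 60, 80)))
  expect_equal(fit$per_cpg$slope, 0.8)
  expect_equal(fit$per_cpg$intercept, 0)
  expect_equal(fit$per_cpg$r_squared, 1)

  # degenerate: constant observations have no defined R-squared
  fit <- fit_titration(obs_df(rep(50, 5)))
  expect_equal(fit$per_cpg$slope, 0)
  expect_true(is.na(fit$per_cpg$r_squared))
  expect_true(is.na(fit$per_amplicon$mean_r_squared))

  expect_error(fit_titration(obs_df(c(1, 2), levels = c(0, 100))),
               "level")
})

test_that("R-squared equals the squared Pearson correlation", {
  set.seed(60)
  for (i in 1:5) {
    meth <- c(0, 25, 50, 75, 100) * runif(1, 0.8, 1.1) + rnorm(5, 0, 3)
    fit <- fit_titration(obs_df(meth))
    expect_equal(fit$per_cpg$r_squared,
                 cor(meth, c(0, 25, 50, 75, 100))^2)
  }
})

test_that("amplicon means skip degenerate CpGs and flag nonlinearity", {
  obs <- rbind(obs_df(c(0, 25, 50, 75, 100), pos = 1),
               obs_df(rep(50, 5), pos = 2),
               obs_df(c(0, 10, 60, 90, 100), pos = 3))
  fit <- fit_titration(obs)
  r3 <- fit$per_cpg$r_squared[fit$per_cpg$pos == 3]
  expect_equal(fit$per_amplicon$mean_r_squared, mean(c(1, r3)))
  # a slope far from unity is flagged even with perfect linearity
  fit2 <- fit_titration(obs_df(c(0, 20, 40, 60, 80)))
  expect_true(fit2$per_amplicon$nonlinear)
  fit3 <- fit_titration(obs_df(c(0, 25, 50, 75, 100)))
  expect_false(fit3$per_amplicon$nonlinear)
})

test_that("noise-free titrations are perfectly linear at every CpG", {
  pnl <- synthetic_panel(3, amp_len = 220, n_cpg = 4, seed = 61)
  profs <- mix_titration(pnl, c(0, 0.25, 0.5, 0.75, 1))
  obs <- do.call(rbind, lapply(names(profs), function(l) {
    p <- profs[[l]]
    data.frame(amplicon = p$amplicon, pos = p$pos,
               level = as.numeric(l) * 100, meth = p$meth * 100)
  }))
  fit <- fit_titration(obs)
  expect_true(all(abs(fit$per_cpg$r_squared - 1) < 1e-12))
  expect_true(all(abs(fit$per_cpg$slope - 1) < 1e-12))
})

test_that("condition comparison averages absolute differences", {
  ref <- rbind(obs_df(c(1, 26, 51, 74, 99)),
               obs_df(c(0, 24, 50, 76, 100), pos = 2))
  expect_equal(compare_conditions(ref, ref)$overall, 0)
  shift <- ref; shift$meth <- shift$meth + 1
  cmp <- compare_conditions(shift, ref)
  expect_equal(cmp$overall, 1)
  expect_true(all(cmp$per_cell$mean_abs_diff == 1))

  a <- obs_df(c(10, 20, 30), levels = c(0, 50, 100))
  b <- obs_df(c(10.2, 19.6, 30.9), levels = c(0, 50, 100))
  expect_equal(compare_conditions(b, a)$overall, mean(c(0.2, 0.4, 0.9)))
  # symmetric in absolute value
  expect_equal(compare_conditions(a, b)$overall,
               compare_conditions(b, a)$overall)
  other <- obs_df(c(1, 2, 3), levels = c(0, 50, 100), amp = "zz")
  expect_error(compare_conditions(a, other), "no shared")
})

test_that("replicate SD uses the sample SD and aggregates over cells", {
  reps <- data.frame(amplicon = "a1", pos = 1, level = 50,
                     replicate = 1:3, meth = c(50, 50, 50))
  expect_equal(replicate_sd(reps)$mean_sd, 0)
  reps$meth <- c(49, 50, 51)
  expect_equal(replicate_sd(reps)$mean_sd, 1)
  # cells with SDs exactly 0.5 and 1.5 -> mean 1.0, max 1.5
  cells <- rbind(
    data.frame(amplicon = "a1", pos = 1, level = 0, replicate = 1:3,
               meth = c(9.5, 10, 10.5)),
    data.frame(amplicon = "a1", pos = 2, level = 0, replicate = 1:3,
               meth = c(48.5, 50, 51.5)))
  rs <- replicate_sd(cells)
  expect_equal(rs$per_cell$sd, c(0.5, 1.5), tolerance = 1e-12)
  expect_equal(rs$mean_sd, 1.0)
  expect_equal(rs$max_sd, 1.5)
  # cells with a single replicate are excluded with a warning
  lone <- rbind(cells,
                data.frame(amplicon = "a1", pos = 3, level = 0,
                           replicate = 1, meth = 5))
  expect_warning(rs2 <- replicate_sd(lone), "excluded")
  expect_equal(rs2$n_cells, 2)
})

test_that("calls join with a sample sheet into the titration table", {
  pnl <- synthetic_panel(1, amp_len = 200, n_cpg = 3, seed = 62)
  sims <- lapply(c(0, 50, 100), function(l)
    call_sites(trim_overlap(simulate_sample(
      pnl, mix_titration(pnl, l / 100)[[1]],
      sim_config(depth = 50, seed = 63 + l))),
      pnl, sample = paste0("L", l)))
  calls <- as_calls(do.call(rbind, sims))
  sheet <- data.frame(sample = paste0("L", c(0, 50, 100)),
                      expected_level = c(0, 50, 100))
  tab <- titration_table(calls, sheet)
  expect_true(all(tab$level %in% c(0, 50, 100)))
  expect_equal(nrow(tab), sum(calls$context == "CpG"))
  expect_error(titration_table(calls, sheet[1:2, ]), "missing from sheet")
})
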