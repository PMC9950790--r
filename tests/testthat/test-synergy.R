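# Median-effect fitting, effect-dose inversion and combination index.

test_that("noiseless median-effect data are refit exactly", {
  dr <- simulate_dose_response(m = 1, dm = 10, doses = c(1, 10, 100))
  fit <- fit_median_effect(dr$dose, dr$fa)
  expect_equal(fit$m, 1, tolerance = 1e-9)
  expect_equal(fit$dm, 10, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)

  # steeper curve, uneven dose ladder (doses keep fa off the clip boundary)
  dr2 <- simulate_dose_response(m = 2.5, dm = 3.7,
                                doses = c(1, 2, 5, 8))
  fit2 <- fit_median_effect(dr2$dose, dr2$fa)
  expect_equal(fit2$m, 2.5, tolerance = 1e-9)
  expect_equal(fit2$dm, 3.7, tolerance = 1e-9)
})

test_that("median dose is the fa = 0.5 dose and IC50 equals Dm", {
  dr <- simulate_dose_response(m = 1.8, dm = 23.93, doses = c(5, 12, 25, 80))
  fit <- fit_median_effect(dr$dose, dr$fa)
  expect_equal(dose_for_effect(fit, 0.5), fit$dm, tolerance = 1e-12)
  expect_equal(ic50_of(fit)$ic50, fit$dm)
  expect_equal(ic50_of(fit, max_dose = 100)$label, "23.93")
})

test_that("dose-response handling of replicates, zero doses and boundaries", {
  # replicate wells averaged before fitting
  doses <- c(1, 1, 10, 10, 100, 100)
  fa <- 1 / (1 + (10 / doses)^1) + c(-0.01, 0.01, -0.02, 0.02, -0.005, 0.005)
  fit <- fit_median_effect(doses, fa)
  ref <- fit_median_effect(c(1, 10, 100), 1 / (1 + (10 / c(1, 10, 100))^1))
  expect_equal(fit$m, ref$m, tolerance = 0.05)
  # dose-0 rows dropped; all-saturated data flagged degenerate
  expect_error(fit_median_effect(c(0, 0, 1, 10), c(0, 0, 0.2, 0.6)),
               class = "degenerate_input_error")
  expect_warning(f <- fit_median_effect(c(1, 10, 100), c(1, 1, 1)))
  expect_true(f$degenerate)
})

test_that("dose_for_effect inverts the median-effect equation", {
  fit <- fit_median_effect(c(1, 10, 100), 1 / (1 + (10 / c(1, 10, 100))))
  expect_equal(dose_for_effect(fit, 0.8), 40, tolerance = 1e-6)
  # strictly increasing in fa
  fas <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(dose_for_effect(fit, fas)) > 0))
  expect_error(dose_for_effect(fit, 1), class = "degenerate_input_error")
  expect_error(dose_for_effect(fit, 0), class = "degenerate_input_error")
})

test_that("one-drug limit of the combination index is additive", {
  fit_a <- fit_median_effect(c(1, 10, 100), 1 / (1 + (10 / c(1, 10, 100))))
  fit_b <- fit_median_effect(c(2, 20, 200), 1 / (1 + (20 / c(2, 20, 200))))
  fa <- 0.7
  res <- combination_index(fit_a, fit_b, d_a = dose_for_effect(fit_a, fa),
                           d_b = 0, fa_combo = fa)
  expect_equal(res$ci, 1, tolerance = 1e-9)
  expect_equal(res$verdict, "additive")
})

test_that("Loewe-additive mixtures give CI = 1 across dose ratios", {
  fit_a <- fit_median_effect(c(1, 10, 100), 1 / (1 + (10 / c(1, 10, 100))))
  fit_b <- fit_median_effect(c(2, 20, 200), 1 / (1 + (20 / c(2, 20, 200))))
  ratios <- c(0.1, 0.2, 0.5, 1, 2, 5, 10)
  grid <- data.frame(dose_a = 5 * ratios, dose_b = 10 / ratios)
  mix <- simulate_combination(fit_a, fit_b, grid, mode = "loewe_additive")
  expect_equal(nrow(mix), nrow(grid))
  for (i in seq_len(nrow(mix))) {
    res <- combination_index(fit_a, fit_b, mix$dose_a[i], mix$dose_b[i], mix$fa[i])
    expect_equal(res$ci, 1, tolerance = 1e-6)
  }
})

test_that("fixed-CI construction is recovered by combination_index", {
  fit_a <- fit_median_effect(c(1, 10, 100), 1 / (1 + (10 / c(1, 10, 100))))
  fit_b <- fit_median_effect(c(1, 20, 400), 1 / (1 + (20 / c(1, 20, 400))^0.8))
  grid <- data.frame(dose_a = c(2, 5, 10), dose_b = c(8, 4, 12))
  for (target in c(0.4, 1.7)) {
    mix <- simulate_combination(fit_a, fit_b, grid, mode = "fixed_ci", ci = target)
    for (i in seq_len(nrow(mix))) {
      res <- combination_index(fit_a, fit_b, mix$dose_a[i], mix$dose_b[i], mix$fa[i])
      expect_equal(res$ci, target, tolerance = 1e-6)
      expect_equal(res$verdict, if (target < 1) "synergistic" else "antagonistic")
    }
  }
  expect_error(simulate_combination(fit_a, fit_b, grid, mode = "fixed_ci", ci = -1),
               class = "format_error")
})

test_that("CI is strictly increasing in each combination dose", {
  fit_a <- fit_median_effect(c(1, 10, 100), 1 / (1 + (10 / c(1, 10, 100))))
  fit_b <- fit_median_effect(c(2, 20, 200), 1 / (1 + (20 / c(2, 20, 200))))
  cis_a <- vapply(c(1, 2, 4, 8), function(d)
    combination_index(fit_a, fit_b, d, 5, 0.6)$ci, numeric(1))
  cis_b <- vapply(c(1, 2, 4, 8), function(d)
    combination_index(fit_a, fit_b, 5, d, 0.6)$ci, numeric(1))
  expect_true(all(diff(cis_a) > 0))
  expect_true(all(diff(cis_b) > 0))
})

test_that("dose scaling scales Dm and leaves m invariant", {
  doses <- c(0.5, 2, 9, 40)
  fa <- 1 / (1 + (6 / doses)^1.4)
  f1 <- fit_median_effect(doses, fa)
  f2 <- fit_median_effect(doses * 3, fa)
  expect_equal(f2$m, f1$m, tolerance = 1e-9)
  expect_equal(f2$dm, 3 * f1$dm, tolerance = 1e-9)
})

test_that("Dm recovery under 5% multiplicative noise stays within 15%", {
  rel_err <- vapply(1:200, function(s) {
    dr <- simulate_dose_response(m = 1.2, dm = 10,
                                 doses = c(0.8, 2, 4, 10, 20, 50, 100),
                                 noise_sd = 0.05, seed = s)
    fit <- fit_median_effect(dr$dose, dr$fa)
    abs(fit$dm - 10) / 10
  }, numeric(1))
  expect_lt(median(rel_err), 0.15)
})

test_that("ci_table reports per-row CI and per-pair minima", {
  fit_a <- fit_median_effect(c(1, 10, 100), 1 / (1 + (10 / c(1, 10, 100))))
  fit_b <- fit_median_effect(c(2, 20, 200), 1 / (1 + (20 / c(2, 20, 200))))
  combos <- data.frame(agent_a = "a", agent_b = "b",
                       dose_a = c(2, 5), dose_b = c(3, 30), fa = c(0.4, 0.6))
  tab <- ci_table(combos, list(a = fit_a, b = fit_b))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$pair_min_ci, rep(min(tab$ci), 2))
  expect_error(ci_table(combos, list(a = fit_a)), class = "format_error")
})
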