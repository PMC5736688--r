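make_trace <- function(times, migration, proliferation, degradation) {
  structure(list(times = times, migration = migration,
                 proliferation = proliferation, degradation = degradation),
            class = "cell_response_trace")
}

test_that("cell responses are weighted sums; degradation is the c-Cbl trace", {
  p <- two_adapter_params() # w_mig = (1, 0.5), w_prol = (0.2, 1), degr = A1
  res <- simulate_network(build_specific_network(p), t_end = 600, n_points = 61)
  tr <- compute_responses(res, p)
  t1 <- phospho_trace(res, "A1"); t2 <- phospho_trace(res, "A2")
  expect_equal(tr$migration, 1 * t1 + 0.5 * t2)
  expect_equal(tr$proliferation, 0.2 * t1 + 1 * t2)
  expect_identical(tr$degradation, t1) # bit-identical
  # all-zero weights null out the weighted responses
  p0 <- p
  for (i in 1:2) p0$adapters[[i]]$weights[] <- 0
  tr0 <- compute_responses(res, p0)
  expect_identical(max(abs(tr0$migration)), 0)
  expect_identical(max(abs(tr0$proliferation)), 0)
})

test_that("summaries: trapezoid AUC, peak amplitude, relative shares", {
  tt <- seq(0, 10, length.out = 11)
  s <- summarize_responses(make_trace(tt, rep(1, 11), rep(0, 11), rep(0, 11)))
  expect_equal(unname(s$integrated["migration"]), 10)
  expect_equal(unname(s$amplitude["migration"]), 1)
  # closed-form integral of exp(-t) on [0, 10]
  tt <- seq(0, 10, length.out = 2001)
  s <- summarize_responses(make_trace(tt, exp(-tt), rep(0, 2001), rep(0, 2001)))
  expect_equal(unname(s$integrated["migration"]), 1 - exp(-10), tolerance = 1e-3)
  # relative shares
  tt <- c(0, 1)
  s <- summarize_responses(make_trace(tt, c(3, 3), c(1, 1), c(0, 0)))
  expect_equal(unname(s$relative_integrated),
               c(0.75, 0.25, 0))
  expect_equal(sum(s$relative_integrated), 1)
  expect_error(summarize_responses(make_trace(0, 1, 1, 1)), "2 time points")
})

test_that("complete inhibition silences the target and keeps it competing", {
  p <- two_adapter_params()
  p_inh <- apply_inhibitor(p, "A2")
  res <- simulate_network(build_specific_network(p_inh), t_end = 600, n_points = 61)
  expect_lt(max(abs(phospho_trace(res, "A2"))), 1e-9)
  # binding retained: the inhibited adapter still occupies receptor states
  bound <- adapter_total_trace(res, "A2") - res$trajectories[, "A2"] -
    res$trajectories[, "A2:PTPN"]
  expect_gt(max(bound), 0)
  # competition: inhibiting A2 changes A1 phosphorylation
  res0 <- simulate_network(build_specific_network(p), t_end = 600, n_points = 61)
  expect_false(isTRUE(all.equal(phospho_trace(res, "A1"),
                                phospho_trace(res0, "A1"))))
  # inhibiting the degradation adapter nulls the degradation response
  p_deg <- apply_inhibitor(p, "A1")
  res_d <- simulate_network(build_specific_network(p_deg), t_end = 600, n_points = 61)
  expect_lt(max(abs(compute_responses(res_d, p_deg)$degradation)), 1e-9)
  # deplete mode zeroes the pool instead
  p_dep <- apply_inhibitor(p, "A2", mode = "deplete")
  expect_identical(p_dep$adapters[[2]]$concentration, 0)
  expect_error(apply_inhibitor(p, "A9"), "unknown adapter")
})

test_that("percent reduction is a ratio of integrated responses", {
  tt <- c(0, 1)
  base <- summarize_responses(make_trace(tt, c(4, 4), c(2, 2), c(0, 0)))
  treat <- summarize_responses(make_trace(tt, c(1, 1), c(2, 2), c(0, 0)))
  expect_equal(percent_reduction(base, treat, "migration"), 75)
  expect_equal(percent_reduction(base, base, "migration"), 0)
  zero <- summarize_responses(make_trace(tt, c(0, 0), c(0, 0), c(0, 0)))
  expect_equal(percent_reduction(base, zero, "migration"), 100)
  expect_error(percent_reduction(zero, base, "migration"), "positive")
  # invariant under common rescaling
  base2 <- base; treat2 <- treat
  base2$integrated <- base$integrated * 7.3
  treat2$integrated <- treat$integrated * 7.3
  expect_equal(percent_reduction(base2, treat2, "migration"),
               percent_reduction(base, treat, "migration"))
})

test_that("significance band is +/-10 percent with inclusive bounds", {
  tt <- c(0, 1)
  base <- summarize_responses(make_trace(tt, c(100, 100), c(1, 1), c(0, 0)))
  band <- significance_band(base, "migration")
  expect_equal(as.numeric(band), c(90, 110))
  expect_true(outside_band(band, 89))
  expect_false(outside_band(band, 110)) # inclusive
  expect_false(outside_band(band, 90))
  expect_true(outside_band(band, 110.0001))
})

test_that("chi-square gof matches an independent quantile computation", {
  expect_s3_class(chi2_gof(1:4, 1:4, rep(1, 4)), "gof_report")
  g0 <- chi2_gof(1:4, 1:4, rep(1, 4))
  expect_equal(g0$chi2, 0)
  expect_true(g0$passed)
  g1 <- chi2_gof(rep(0, 5), rep(1, 5), rep(1, 5))
  expect_equal(g1$chi2, 5)
  expect_identical(g1$dof, 4L)
  # oracle: solve P(X <= x) = 0.95 by integrating the chi-square density
  cdf <- function(x) stats::integrate(stats::dchisq, 0, x, df = 4,
                                      rel.tol = 1e-10)$value
  crit <- stats::uniroot(function(x) cdf(x) - 0.95, c(1, 30), tol = 1e-9)$root
  expect_equal(g1$critical, crit, tolerance = 1e-6)
  expect_equal(round(g1$critical, 3), 9.488)
  expect_true(g1$passed) # 5 < 9.488
  expect_false(chi2_gof(rep(0, 5), rep(2, 5), rep(1, 5))$passed) # chi2 = 20
  # residual scaling by SEM
  g2 <- chi2_gof(c(0, 0), c(1, 1), c(0.5, 0.5))
  expect_equal(g2$chi2, 8)
  # pearson variant uses sqrt(expected)
  g3 <- chi2_gof(c(4, 4), c(2, 2), pearson = TRUE)
  expect_equal(g3$chi2, 2 * (2 - 4)^2 / 4)
  expect_error(chi2_gof(1:3, 1:4, rep(1, 4)), "lengths differ")
  expect_error(chi2_gof(1:4, 1:4, c(1, 1, 0, 1)), "positive")
})

test_that("receptor fold is 1 for symmetric receptors and monotone in abundance", {
  mk <- function(conc1, conc2) {
    sites <- list(R1 = c("Ya", "Yb"), R2 = c("Ya", "Yb"))
    model_parameters(
      receptors = list(std_receptor("R1", conc = conc1),
                       std_receptor("R2", conc = conc2)),
      adapters = list(std_adapter("A1", sites = sites),
                      std_adapter("A2", sites = sites, koff = 0.3)),
      phosphatase = std_phosphatase(), degradation_adapter = "A1")
  }
  p_sym <- mk(4000, 4000)
  f_sym <- receptor_fold(p_sym, "migration", t_end = 600, n_points = 61)
  expect_equal(f_sym, 1, tolerance = 1e-6)
  f_hi <- receptor_fold(mk(8000, 4000), "migration", t_end = 600, n_points = 61)
  expect_gt(f_hi, f_sym)
  expect_warning(f_inf <- receptor_fold(mk(4000, 0), "migration",
                                        t_end = 600, n_points = 61),
                 "degenerate")
  expect_identical(f_inf, Inf)
  p1 <- mk(4000, 4000); p1$receptors <- p1$receptors[1]
  expect_error(receptor_fold(p1, "migration"), "exactly two")
})

test_that("inhibitor panel reports reductions and significance per target", {
  p <- two_adapter_params()
  pan <- inhibitor_panel(p, c("A1", "A2"), t_end = 600, n_points = 61)
  expect_identical(nrow(pan), 4L) # 2 inhibitors x 2 responses
  expect_true(all(pan$reduction_pct <= 100))
  expect_error(inhibitor_panel(p, character()), "empty")
  expect_error(inhibitor_panel(p, "A9"), "unknown inhibitor")
})
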