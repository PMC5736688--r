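test_that("kp = 0 produces identically zero phospho traces", {
  p <- two_adapter_params(kp = 0)
  for (variant in c("nonspecific", "specific")) {
    res <- simulate_network(build_network(p, variant), t_end = 600, n_points = 61)
    # zero up to solver absolute tolerance
    expect_lt(max(abs(phospho_trace(res, "A1"))), 1e-9)
    expect_lt(max(abs(phospho_trace(res, "A2"))), 1e-9)
  }
})

test_that("without VEGF the system stays at its initial state", {
  p <- two_adapter_params()
  p$ligand <- ligand_spec(0)
  res <- simulate_network(build_specific_network(p), t_end = 600, n_points = 61)
  dev <- max(abs(t(res$trajectories) - res$trajectories[1, ]))
  expect_lt(dev, 1e-9)
})

test_that("single-adapter binding settles on the closed-form isotherm", {
  # kp = 0, pure binding; the closed-form equilibrium couples the ligand
  # equilibrium (constant VEGF) to the receptor-adapter quadratic
  p <- model_parameters(
    receptors = list(std_receptor()),
    adapters = list(std_adapter("A1")),
    phosphatase = std_phosphatase(), kp = 0)
  a <- p$adapters[[1]]; r <- p$receptors[[1]]
  res <- simulate_network(build_nonspecific_network(p),
                          t_end = 100 / a$koff, n_points = 201)
  VEGF <- ligand_molecules(p$ligand)
  alpha <- r$kon_vegf * VEGF / r$koff_vegf
  RT <- r$concentration; AT <- a$concentration
  Kd <- a$koff / a$kon
  # C = P*A/Kd with A = AT - C, P = (RT - C)/(1 + 1/alpha)
  f <- function(C) (RT - C) / (1 + 1 / alpha) * (AT - C) / Kd - C
  C_eq <- stats::uniroot(f, c(0, min(AT, RT) * (1 - 1e-12)), tol = 1e-12)$root
  C_sim <- unname(res$trajectories[nrow(res$trajectories), "[pR1:A1]"])
  expect_equal(C_sim, C_eq, tolerance = 1e-3)
})

test_that("moiety totals are conserved along every fixture trajectory", {
  for (s in c(2, 5, 13)) {
    p <- generate_fixture_parameters(s, n_adapters = 2, n_receptors = 1,
                                     n_sites = 2)
    res <- simulate_network(build_specific_network(p), t_end = 1200,
                            n_points = 121)
    expect_lt(max(res$conservation_error), 1e-6)
    # bookkeeping oracle: total adapter amount from the conservation vector
    tot <- adapter_total_trace(res, "A1")
    expect_equal(max(abs(tot - tot[1])) / tot[1], 0, tolerance = 1e-6)
  }
})

test_that("phospho trace equals manual summation over species compositions", {
  p <- two_adapter_params()
  res <- simulate_network(build_specific_network(p), t_end = 600, n_points = 61)
  net <- res$network
  manual <- numeric(length(res$times))
  for (i in seq_len(nrow(net$species))) {
    ph <- net$species$phospho[[i]]
    if ("A1" %in% names(ph)) {
      manual <- manual + ph[["A1"]] * res$trajectories[, net$species$id[i]]
    }
  }
  expect_equal(phospho_trace(res, "A1"), manual, tolerance = 1e-12)
  # bounded by the conserved total at all times
  expect_true(all(phospho_trace(res, "A1") <=
                    adapter_total_trace(res, "A1") + 1e-9))
  expect_error(phospho_trace(res, "nope"), "unknown adapter")
})

test_that("refining the output grid leaves summary metrics stable", {
  p <- two_adapter_params()
  net <- build_specific_network(p)
  s1 <- summarize_responses(compute_responses(
    simulate_network(net, t_end = 1800, n_points = 301), p))
  s2 <- summarize_responses(compute_responses(
    simulate_network(net, t_end = 1800, n_points = 601), p))
  expect_equal(s1$integrated, s2$integrated, tolerance = 1e-3)
  expect_equal(s1$amplitude, s2$amplitude, tolerance = 1e-3)
})

test_that("receptor contribution isolates one receptor over shared pools", {
  p <- generate_fixture_parameters(4, n_adapters = 2, n_receptors = 2,
                                   n_sites = 2)
  # single-receptor params: contribution equals the full simulation
  p1 <- p; p1$receptors <- p1$receptors[1]
  for (i in seq_along(p1$adapters)) p1$adapters[[i]]$site_names$R2 <- NULL
  full <- simulate_network(build_specific_network(p1), t_end = 600, n_points = 61)
  only <- receptor_contribution(p1, "R1", t_end = 600, n_points = 61)
  expect_equal(phospho_trace(only, "A1"), phospho_trace(full, "A1"),
               tolerance = 1e-10)
  # two receptors: contributions are not additive (shared adapter pools)
  fullres <- simulate_network(build_specific_network(p), t_end = 600, n_points = 61)
  c1 <- receptor_contribution(p, "R1", t_end = 600, n_points = 61)
  c2 <- receptor_contribution(p, "R2", t_end = 600, n_points = 61)
  sum_traces <- phospho_trace(c1, "A1") + phospho_trace(c2, "A1")
  expect_gt(max(abs(sum_traces - phospho_trace(fullres, "A1"))), 1e-6)
  # zeroing all receptors: flat zero phospho
  p0 <- p
  for (i in seq_along(p0$receptors)) p0$receptors[[i]]$concentration <- 0
  res0 <- simulate_network(build_specific_network(p0), t_end = 600, n_points = 61)
  expect_lt(max(abs(phospho_trace(res0, "A1"))), 1e-9)
  expect_error(receptor_contribution(p, "R9"), "unknown receptor")
})

test_that("tidy trajectory export preserves every value", {
  p <- two_adapter_params()
  res <- simulate_network(build_nonspecific_network(p), t_end = 60, n_points = 7)
  long <- trajectories_long(res)
  expect_identical(nrow(long), 7L * ncol(res$trajectories))
  sub <- long[long$species == "A1", ]
  expect_identical(sub$value, unname(res$trajectories[, "A1"]))
})
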