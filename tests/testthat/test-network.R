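test_that("one receptor, one adapter: the scheme's six steps, nine species", {
  p <- model_parameters(
    receptors = list(std_receptor()),
    adapters = list(std_adapter("A1")),
    phosphatase = std_phosphatase())
  net <- build_nonspecific_network(p)
  # VEGF, R1, pR1, A1, [pR1:A1], [pR1:pA1], [pR1:pA1:PTPN], A1:PTPN, PTPN
  expect_identical(nrow(net$species), 9L)
  # 3 reversible pairs + phosphorylation + catalysis + recycling
  expect_identical(nrow(net$reactions), 9L)
})

test_that("zero adapters leaves only ligand-receptor activation", {
  p <- model_parameters(receptors = list(std_receptor()), adapters = list(),
                        phosphatase = std_phosphatase())
  net <- build_nonspecific_network(p)
  expect_identical(sort(net$species$id),
                   sort(c("VEGF", "PTPN", "R1", "pR1")))
  expect_identical(nrow(net$reactions), 2L)
})

test_that("nonspecific reaction count scales as receptors x adapters", {
  count_for <- function(n_rec, n_ad) {
    recs <- lapply(seq_len(n_rec), function(i) {
      std_receptor(paste0("R", i))
    })
    site_map <- stats::setNames(
      rep(list(c("Ya", "Yb")), n_rec), paste0("R", seq_len(n_rec)))
    ads <- lapply(seq_len(n_ad), function(i) {
      std_adapter(paste0("A", i), sites = site_map)
    })
    p <- model_parameters(receptors = recs, adapters = ads,
                          phosphatase = std_phosphatase())
    nrow(build_nonspecific_network(p)$reactions)
  }
  # 2 VEGF steps per receptor + 6 steps per receptor-adapter pair
  # + 1 recycling step per adapter
  expect_identical(count_for(2, 3), 2L * 2L + 6L * 2L * 3L + 3L)
  expect_identical(count_for(1, 2), 2L + 6L * 2L + 2L)
})

test_that("stoichiometry columns of a reversible pair negate each other", {
  p <- model_parameters(
    receptors = list(std_receptor()),
    adapters = list(std_adapter("A1")),
    phosphatase = std_phosphatase())
  net <- build_nonspecific_network(p)
  S <- stoichiometry_matrix(net)
  j_f <- which(net$reactions$label == "VEGF binding R1")
  j_r <- which(net$reactions$label == "VEGF release R1")
  expect_identical(S[, j_f], -S[, j_r])
})

test_that("adapter and receptor moieties lie in the left null space", {
  for (build in list(build_nonspecific_network, build_specific_network)) {
    p <- generate_fixture_parameters(5, n_adapters = 2, n_receptors = 2,
                                     n_sites = 2)
    net <- build(p)
    S <- stoichiometry_matrix(net)
    for (m in c("A1", "A2", "R1", "R2")) {
      w <- conservation_vector(net, m)
      expect_equal(max(abs(w %*% S)), 0, info = m)
    }
  }
})

test_that("network construction is canonical: same inputs, identical network", {
  p <- generate_fixture_parameters(9, n_adapters = 3, n_receptors = 1, n_sites = 3)
  expect_identical(build_specific_network(p), build_specific_network(p))
  expect_identical(build_nonspecific_network(p), build_nonspecific_network(p))
})

test_that("specific model on a single shared exclusive site reduces to nonspecific", {
  p <- two_adapter_params()
  pc <- collapse_to_single_site(p)
  ns <- build_nonspecific_network(p)
  sc <- build_specific_network(pc)
  # isomorphic: same sizes and identical dynamics
  expect_identical(nrow(ns$species), nrow(sc$species))
  expect_identical(nrow(ns$reactions), nrow(sc$reactions))
  expect_identical(sort(ns$reactions$rate), sort(sc$reactions$rate))
  r_ns <- simulate_network(ns, t_end = 600, n_points = 121,
                           rtol = 1e-10, atol = 1e-12)
  r_sc <- simulate_network(sc, t_end = 600, n_points = 121,
                           rtol = 1e-10, atol = 1e-12)
  s_ns <- summarize_responses(compute_responses(r_ns, p))
  s_sc <- summarize_responses(compute_responses(r_sc, pc))
  expect_equal(s_sc$integrated, s_ns$integrated, tolerance = 1e-8)
  expect_equal(s_sc$amplitude, s_ns$amplitude, tolerance = 1e-8)
})

test_that("specific state space equals feasible configs x phospho-flag states", {
  p <- generate_fixture_parameters(7, n_adapters = 3, n_receptors = 1,
                                   n_sites = 3)
  net <- build_specific_network(p)
  cfgs <- enumerate_configurations("R1", p)
  expected_states <- sum(vapply(cfgs, function(cf) 3^length(cf$occupancy), 0))
  n_receptor_states <- sum(net$species$kind == "phospho_receptor_complex")
  expect_identical(n_receptor_states, as.integer(expected_states))
  # no receptor state exceeds the steric occupancy bound
  mo <- as.integer(max_occupancy("R1", p))
  bound_counts <- vapply(net$species$adapters[net$species$kind ==
                                                "phospho_receptor_complex"],
                         sum, 0)
  expect_true(max(bound_counts) == mo)
})

test_that("steric limits shape the reference VEGFR1 state space", {
  p <- reference_parameters("HUVEC")
  mo <- max_occupancy("VEGFR1", p)
  expect_identical(as.integer(mo), 2L)
  expect_identical(attr(mo, "shared_sites"), "Y794")
  net <- build_specific_network(p)
  v1 <- net$species$kind == "phospho_receptor_complex" &
    net$species$receptor == "VEGFR1"
  expect_true(max(vapply(net$species$adapters[v1], sum, 0)) == 2)
  # every doubly-occupied VEGFR1 state involves Y794
  pairs <- net$species$id[v1][vapply(net$species$adapters[v1], sum, 0) == 2]
  expect_true(all(grepl("Y794:", pairs)))
})

test_that("species and reaction tables export the network faithfully", {
  p <- two_adapter_params()
  net <- build_nonspecific_network(p)
  st <- species_table(net)
  rt <- reactions_table(net)
  expect_identical(nrow(st), nrow(net$species))
  expect_identical(nrow(rt), nrow(net$reactions))
  expect_true(all(c("PTPN", "VEGF") %in% st$id[st$constant]))
  expect_match(rt$reactants[rt$label == "A1 binding R1"], "pR1 \\+ A1")
})
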