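#' Synthetic reference parameterization for VEGFR1/VEGFR2 signaling
#'
#' A complete, ready-to-run parameter set for the five VEGFR1-associated
#' adapters (PLCg, PI3K, Src, Abl, c-Cbl) on VEGFR1 and VEGFR2. It is a
#' *synthetic stand-in*: structural facts stated in the primary literature
#' are encoded exactly — VEGFR1 carboxy-terminal tyrosine sites Tyr794,
#' Tyr1169, Tyr1213, Tyr1242, Tyr1333 at 0.171 Angstrom/amino-acid spacing;
#' the shared adapter phosphorylation rate kp = 0.01/s; the 1 pL cell
#' volume; a 50 ng/mL VEGF-A164 dose; PLCg and PI3K as the only Tyr794
#' binders; and adapter sizes such that at most two adapters occupy VEGFR1
#' simultaneously, one of them at Tyr794 — while quantities not printed in
#' the main text (adapter concentrations, binding kinetics, response
#' weights, VEGFR2 site spacing) are filled with literature-plausible
#' values and flagged `provenance = "synthetic"`. Predictions from this set
#' are structurally faithful but not numerically calibrated.
#'
#' Two cell contexts are provided: `"HUVEC"` (endothelial; low VEGFR1,
#' higher VEGFR2) and `"RAW"` (macrophage; high VEGFR1, low VEGFR2).
#'
#' @param cell `"HUVEC"` or `"RAW"`.
#' @return A validated `model_parameters` object.
#' @export
reference_parameters <- function(cell = c("HUVEC", "RAW")) {
  cell <- match.arg(cell)
  vol <- 1e-12
  pm <- function(k) per_molar_to_per_molecule(k, vol)

  rec_conc <- switch(cell,
    HUVEC = c(VEGFR1 = 1800, VEGFR2 = 4900),
    RAW = c(VEGFR1 = 20000, VEGFR2 = 3000))

  receptors <- list(
    receptor_spec("VEGFR1", rec_conc[["VEGFR1"]],
                  kon_vegf = pm(3e7), koff_vegf = 3e-4,
                  sites = c(Y794 = 794, Y1169 = 1169, Y1213 = 1213,
                            Y1242 = 1242, Y1333 = 1333),
                  aa_spacing = 0.171),
    receptor_spec("VEGFR2", rec_conc[["VEGFR2"]],
                  kon_vegf = pm(1e7), koff_vegf = 1e-3,
                  sites = c(Y951 = 951, Y1059 = 1059, Y1175 = 1175,
                            Y1214 = 1214),
                  aa_spacing = 0.171))

  ad_conc <- switch(cell,
    HUVEC = c(PLCg = 2.6e4, PI3K = 4.2e4, Src = 1.1e4, Abl = 4.0e3, cCbl = 8.0e3),
    RAW = c(PLCg = 1.4e4, PI3K = 3.0e4, Src = 8.0e3, Abl = 2.5e3, cCbl = 6.0e3))

  # kon (1/(M s)), koff (1/s): SH2-domain/phospho-peptide scale kinetics
  kin <- list(
    PLCg = c(kon = 1.2e6, koff = 0.12),
    PI3K = c(kon = 2.4e6, koff = 0.12),
    Src = c(kon = 1.0e6, koff = 0.50),
    Abl = c(kon = 8.0e5, koff = 0.40),
    cCbl = c(kon = 1.0e6, koff = 0.20))

  # y-extent of the adapter crystal structures (Angstrom); halves must sum
  # below 64.1 A (Tyr794 to its nearest neighbour) but above 28.0 A (the
  # widest gap among the four C-terminal sites), making Tyr794-plus-one the
  # only multi-adapter pattern on VEGFR1
  sizes <- c(PLCg = 60, PI3K = 58, Src = 52, Abl = 54, cCbl = 62)

  site_map <- list(
    PLCg = list(VEGFR1 = c("Y794", "Y1169"), VEGFR2 = "Y1175"),
    PI3K = list(VEGFR1 = c("Y794", "Y1213"), VEGFR2 = "Y1175"),
    Src = list(VEGFR1 = c("Y1169", "Y1213"), VEGFR2 = c("Y951", "Y1214")),
    Abl = list(VEGFR1 = c("Y1213", "Y1242"), VEGFR2 = "Y951"),
    cCbl = list(VEGFR1 = "Y1333", VEGFR2 = "Y1059"))

  weights <- list(
    PLCg = c(migration = 1.0, proliferation = 1.0),
    PI3K = c(migration = 0.7, proliferation = 0.25),
    Src = c(migration = 0.4, proliferation = 0.35),
    Abl = c(migration = 0.05, proliferation = 0.05),
    cCbl = c(migration = 0, proliferation = 0))

  adapters <- lapply(names(ad_conc), function(a) {
    adapter_spec(a, ad_conc[[a]],
                 kon = pm(kin[[a]][["kon"]]), koff = kin[[a]][["koff"]],
                 size_y = sizes[[a]], site_names = site_map[[a]],
                 weights = weights[[a]], provenance = "synthetic")
  })

  phosphatase <- phosphatase_spec(kon = pm(1e6), koff = 0.1, kd = 1,
                                  reservoir = 1e5)

  model_parameters(receptors = receptors, adapters = adapters,
                   phosphatase = phosphatase,
                   ligand = ligand_spec(50, 38200),
                   kp = 0.01, cell_volume = vol,
                   degradation_adapter = "cCbl")
}
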