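# Hand-built minimal parameter sets with fully controlled geometry, plus a
# brute-force steric oracle. Everything is constructed in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

std_phosphatase <- function() {
  phosphatase_spec(kon = per_molar_to_per_molecule(1e6), koff = 0.1, kd = 1,
                   reservoir = 1e5)
}

std_receptor <- function(name = "R1", sites = c(Ya = 100, Yb = 300),
                         conc = 5000, aa_spacing = 0.171) {
  receptor_spec(name, conc, kon_vegf = per_molar_to_per_molecule(1e7),
                koff_vegf = 1e-3, sites = sites, aa_spacing = aa_spacing)
}

std_adapter <- function(name, sites = list(R1 = c("Ya", "Yb")), conc = 1e4,
                        size_y = 20, kon_M = 1e6, koff = 0.1,
                        weights = c(migration = 1, proliferation = 0.5)) {
  adapter_spec(name, conc, kon = per_molar_to_per_molecule(kon_M),
               koff = koff, size_y = size_y, site_names = sites,
               weights = weights)
}

# one receptor with two sites 34.2 A apart, two adapters that can co-occupy
two_adapter_params <- function(kp = 0.01, degradation_adapter = "A1") {
  model_parameters(
    receptors = list(std_receptor()),
    adapters = list(
      std_adapter("A1", conc = 8e3, koff = 0.1,
                  weights = c(migration = 1, proliferation = 0.2)),
      std_adapter("A2", conc = 2e4, koff = 0.3,
                  weights = c(migration = 0.5, proliferation = 1))),
    phosphatase = std_phosphatase(), kp = kp,
    degradation_adapter = degradation_adapter)
}

# exhaustive assignment filter; independent of enumerate_configurations()
brute_force_configs <- function(receptor_name, params) {
  r <- vegfrsim:::get_receptor(params, receptor_name)
  sites <- names(r$sites)
  ad <- vapply(params$adapters, function(a) a$name, "")
  choices <- c(NA_character_, ad)
  grids <- do.call(expand.grid,
                   c(rep(list(choices), length(sites)), stringsAsFactors = FALSE))
  keys <- character()
  for (i in seq_len(nrow(grids))) {
    row <- as.character(grids[i, ])
    occ <- stats::setNames(row, sites)
    occ <- occ[!is.na(occ)]
    cf <- binding_configuration(receptor_name, occ)
    if (is_feasible(cf, params)) keys <- c(keys, config_key(cf))
  }
  sort(unique(keys))
}

config_key <- function(cf) {
  if (!length(cf$occupancy)) return("")
  paste(sort(paste0(names(cf$occupancy), "=", cf$occupancy)), collapse = ";")
}

enumerated_keys <- function(receptor_name, params) {
  sort(vapply(enumerate_configurations(receptor_name, params), config_key, ""))
}
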