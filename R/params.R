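#' Convert a molar concentration to molecules per cell
#'
#' Concentrations and bimolecular rate constants are expressed in
#' molecules/cell inside the model; conversion from molar units assumes a
#' fixed cell volume (1 pL by default).
#'
#' @param concentration Concentration in mol/L (nonnegative).
#' @param volume Cell volume in litres (default `1e-12`, i.e. 1 pL).
#' @return Molecules per cell (numeric).
#' @examples
#' molar_to_molecules(1e-9) # 1 nM in a 1 pL cell, ~602 molecules
#' @export
molar_to_molecules <- function(concentration, volume = 1e-12) {
  if (any(concentration < 0)) stop_user("concentration must be nonnegative")
  if (any(volume <= 0)) stop_user("volume must be positive")
  concentration * AVOGADRO * volume
}

#' Convert molecules per cell back to molar concentration
#'
#' Inverse of [molar_to_molecules()]; the composition of the two round-trips
#' to relative error below 1e-12.
#'
#' @param molecules Molecules per cell (nonnegative).
#' @inheritParams molar_to_molecules
#' @return Concentration in mol/L.
#' @export
molecules_to_molar <- function(molecules, volume = 1e-12) {
  if (any(molecules < 0)) stop_user("molecules must be nonnegative")
  if (any(volume <= 0)) stop_user("volume must be positive")
  molecules / (AVOGADRO * volume)
}

#' Convert a bimolecular rate constant from 1/(M s) to 1/(molecule s)
#'
#' @param k Rate constant in 1/(M s).
#' @inheritParams molar_to_molecules
#' @return Rate constant in 1/(molecule s) for the given cell volume.
#' @export
per_molar_to_per_molecule <- function(k, volume = 1e-12) {
  if (any(k < 0)) stop_user("rate constant must be nonnegative")
  k / (AVOGADRO * volume)
}

#' Ligand specification
#'
#' Describes the VEGF dose applied to the cells. Doses are given as mass
#' concentrations (ng/mL), the unit used for bath application, and converted
#' to molar via the ligand molecular weight. VEGF binds its receptors as a
#' homodimer, so the default molecular weight is the ~38.2 kDa dimer mass of
#' VEGF-A164; it is a field precisely so it can be overridden.
#'
#' @param concentration_mass Dose in ng/mL (nonnegative).
#' @param molecular_weight Molecular weight in g/mol (positive).
#' @param depletable If `FALSE` (default) the ligand is a boundary species
#'   held constant during simulation (bath application vastly exceeds
#'   receptor numbers); if `TRUE` it is consumed by binding.
#' @return An object of class `ligand_spec`.
#' @export
ligand_spec <- function(concentration_mass = 50, molecular_weight = 38200,
                        depletable = FALSE) {
  if (concentration_mass < 0) stop_user("ligand concentration_mass must be nonnegative")
  if (molecular_weight <= 0) stop_user("ligand molecular_weight must be positive")
  structure(list(concentration_mass = concentration_mass,
                 molecular_weight = molecular_weight,
                 depletable = isTRUE(depletable)),
            class = "ligand_spec")
}

#' Ligand molar concentration
#'
#' Converts the ng/mL dose to mol/L: `mass * 1e-6 / molecular_weight`
#' (1 ng/mL = 1e-6 g/L).
#'
#' @param ligand A [ligand_spec()].
#' @return Concentration in mol/L.
#' @examples
#' ligand_molar(ligand_spec(50, 38200)) # ~1.31 nM
#' @export
ligand_molar <- function(ligand) {
  stopifnot(inherits(ligand, "ligand_spec"))
  if (ligand$molecular_weight <= 0) stop_user("ligand molecular_weight must be positive")
  ligand$concentration_mass * 1e-6 / ligand$molecular_weight
}

#' Ligand amount in molecules/cell model units
#'
#' @inheritParams ligand_molar
#' @param volume Cell volume in litres.
#' @return Molecules per cell-volume equivalent.
#' @export
ligand_molecules <- function(ligand, volume = 1e-12) {
  molar_to_molecules(ligand_molar(ligand), volume)
}

#' Adapter specification
#'
#' An intracellular SH2-domain adapter (e.g. PLCg, PI3K, Src, Abl, c-Cbl)
#' that binds receptor phospho-tyrosine sites and is itself phosphorylated.
#' Interaction kinetics are shared across receptors and across the adapter's
#' tyrosine sites.
#'
#' @param name Adapter identifier (unique within a parameter set).
#' @param concentration Molecules/cell (nonnegative).
#' @param kon Association rate, 1/(molecule s) (volume-converted).
#' @param koff Dissociation rate, 1/s.
#' @param size_y Total extent of the adapter along the receptor axis, in
#'   Angstroms; half of it is the one-sided footprint toward a neighbouring
#'   site because the adapter's centre engages the phospho-tyrosine.
#' @param site_names Named list mapping receptor name to a character vector
#'   of tyrosine-site names this adapter can bind on that receptor.
#' @param weights Named nonnegative numeric vector with elements
#'   `migration` and `proliferation`: the adapter's calibrated contribution
#'   to each weighted cell response.
#' @param provenance Free-text origin flag for the values, e.g. `"SI"`,
#'   `"fixture"` or `"synthetic"`.
#' @param inhibited Logical; if `TRUE` this adapter's phosphorylation step is
#'   removed from generated networks (see [apply_inhibitor()]).
#' @return An object of class `adapter_spec`.
#' @export
adapter_spec <- function(name, concentration, kon, koff, size_y,
                         site_names = list(),
                         weights = c(migration = 0, proliferation = 0),
                         provenance = "synthetic", inhibited = FALSE) {
  if (!nzchar(name)) stop_user("adapter name must be non-empty")
  if (concentration < 0) stop_user("adapter '", name, "': concentration must be nonnegative")
  if (kon <= 0 || koff <= 0) stop_user("adapter '", name, "': kon and koff must be positive")
  if (size_y <= 0) stop_user("adapter '", name, "': size_y must be positive")
  weights <- unlist(weights)
  if (any(weights < 0)) stop_user("adapter '", name, "': weights must be nonnegative")
  for (w in c("migration", "proliferation")) {
    if (!w %in% names(weights)) weights[w] <- 0
  }
  structure(list(name = name, concentration = concentration,
                 kon = kon, koff = koff, size_y = size_y,
                 site_names = site_names, weights = weights,
                 provenance = provenance, inhibited = isTRUE(inhibited)),
            class = "adapter_spec")
}

#' Receptor specification
#'
#' A VEGF receptor with its carboxy-terminal tyrosine sites. Inter-site
#' distances follow from the residue separation times the average Angstrom
#' per amino-acid spacing measured on the receptor crystal structure.
#'
#' @param name Receptor identifier (e.g. `"VEGFR1"`).
#' @param concentration Surface receptors per cell (nonnegative).
#' @param kon_vegf VEGF association rate, 1/(molecule s).
#' @param koff_vegf VEGF dissociation rate, 1/s.
#' @param sites Named numeric vector mapping site name to residue index
#'   (e.g. `c(Y794 = 794, ...)`); residue indices must be distinct.
#' @param aa_spacing Angstroms per amino acid along the carboxy terminus
#'   (0.171 for VEGFR1).
#' @return An object of class `receptor_spec`; sites are stored sorted by
#'   residue index.
#' @export
receptor_spec <- function(name, concentration, kon_vegf, koff_vegf,
                          sites, aa_spacing = 0.171) {
  if (!nzchar(name)) stop_user("receptor name must be non-empty")
  if (concentration < 0) stop_user("receptor '", name, "': concentration must be nonnegative")
  if (kon_vegf <= 0 || koff_vegf <= 0) {
    stop_user("receptor '", name, "': kon_vegf and koff_vegf must be positive")
  }
  if (aa_spacing <= 0) stop_user("receptor '", name, "': aa_spacing must be positive")
  sites <- unlist(sites)
  if (length(sites) < 1) stop_user("receptor '", name, "': at least one tyrosine site required")
  if (is.null(names(sites)) || any(!nzchar(names(sites)))) {
    stop_user("receptor '", name, "': sites must be a named vector site -> residue")
  }
  sites <- sites[order(sites)]
  if (any(diff(sites) <= 0)) {
    stop_user("receptor '", name, "': residue indices must be strictly increasing")
  }
  structure(list(name = name, concentration = concentration,
                 kon_vegf = kon_vegf, koff_vegf = koff_vegf,
                 sites = sites, aa_spacing = aa_spacing),
            class = "receptor_spec")
}

#' Phosphatase specification
#'
#' A generalized protein tyrosine phosphatase (PTPN) that binds and
#' dephosphorylates all phospho-adapters with shared kinetics. PTPN is an
#' inexhaustible reservoir: its concentration is held constant during
#' simulation.
#'
#' @param kon Association rate with phospho-adapters, 1/(molecule s).
#' @param koff Dissociation rate, 1/s.
#' @param kd Catalytic dephosphorylation rate, 1/s.
#' @param reservoir Effective constant PTPN level, molecules/cell.
#' @return An object of class `phosphatase_spec`.
#' @export
phosphatase_spec <- function(kon, koff, kd, reservoir) {
  if (kon <= 0 || koff <= 0 || kd <= 0) stop_user("phosphatase rates must be positive")
  if (reservoir < 0) stop_user("phosphatase reservoir must be nonnegative")
  structure(list(kon = kon, koff = koff, kd = kd, reservoir = reservoir),
            class = "phosphatase_spec")
}

#' Assemble a complete model parameterization
#'
#' @param receptors List of [receptor_spec()] objects.
#' @param adapters List of [adapter_spec()] objects (names unique).
#' @param phosphatase A [phosphatase_spec()].
#' @param ligand A [ligand_spec()].
#' @param kp Adapter phosphorylation rate, 1/s; shared by all adapters so
#'   phosphorylation differences arise from receptor interaction kinetics
#'   only. Default 0.01/s. Zero is permitted (phosphorylation switched off).
#' @param cell_volume Cell volume in litres used for unit conversions;
#'   default 1e-12 L (1 pL).
#' @param degradation_adapter Name of the adapter whose phosphorylation
#'   trace *is* the degradation cell response (c-Cbl), or `NULL` if absent.
#' @return A validated object of class `model_parameters`.
#' @export
model_parameters <- function(receptors, adapters, phosphatase,
                             ligand = ligand_spec(), kp = 0.01,
                             cell_volume = 1e-12,
                             degradation_adapter = NULL) {
  params <- structure(list(receptors = receptors, adapters = adapters,
                           phosphatase = phosphatase, ligand = ligand,
                           kp = kp, cell_volume = cell_volume,
                           degradation_adapter = degradation_adapter),
                      class = "model_parameters")
  validate_parameters(params)
  params
}

#' Validate a model parameterization
#'
#' Checks every structural invariant: positivity constraints, unique adapter
#' names, and that every site an adapter claims to bind exists on the
#' referenced receptor. Errors name the offending record.
#'
#' @param params A `model_parameters` object.
#' @return Invisibly `TRUE`; otherwise an error.
#' @export
validate_parameters <- function(params) {
  if (!inherits(params, "model_parameters")) stop_user("not a model_parameters object")
  if (params$kp < 0) stop_user("kp must be nonnegative")
  if (params$cell_volume <= 0) stop_user("cell_volume must be positive")
  stopifnot(inherits(params$phosphatase, "phosphatase_spec"),
            inherits(params$ligand, "ligand_spec"))
  rec_names <- vapply(params$receptors, function(r) r$name, "")
  if (anyDuplicated(rec_names)) stop_user("receptor names must be unique")
  ad_names <- vapply(params$adapters, function(a) a$name, "")
  if (anyDuplicated(ad_names)) stop_user("adapter names must be unique")
  for (a in params$adapters) {
    for (rn in names(a$site_names)) {
      r <- params$receptors[[match(rn, rec_names)]]
      if (is.null(r)) stop_user("adapter '", a$name, "' references unknown receptor '", rn, "'")
      bad <- setdiff(a$site_names[[rn]], names(r$sites))
      if (length(bad)) {
        stop_user("adapter '", a$name, "' references unknown site(s) ",
                  paste(bad, collapse = ", "), " on receptor '", rn, "'")
      }
    }
  }
  if (!is.null(params$degradation_adapter) &&
      !params$degradation_adapter %in% ad_names) {
    stop_user("degradation_adapter '", params$degradation_adapter,
              "' is not among the adapters")
  }
  invisible(TRUE)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("model_parameters:", length(x$receptors), "receptor(s),",
      length(x$adapters), "adapter(s)\n")
  cat("  receptors:", paste(vapply(x$receptors, `[[`, "", "name"), collapse = ", "), "\n")
  cat("  adapters: ", paste(vapply(x$adapters, `[[`, "", "name"), collapse = ", "), "\n")
  cat("  kp =", x$kp, "1/s, cell volume =", x$cell_volume, "L\n")
  invisible(x)
}

# ---- helpers -----------------------------------------------------------

receptor_names <- function(params) vapply(params$receptors, `[[`, "", "name")
adapter_names <- function(params) vapply(params$adapters, `[[`, "", "name")

get_receptor <- function(params, name) {
  i <- match(name, receptor_names(params))
  if (is.na(i)) stop_user("unknown receptor '", name, "'")
  params$receptors[[i]]
}

get_adapter <- function(params, name) {
  i <- match(name, adapter_names(params))
  if (is.na(i)) stop_user("unknown adapter '", name, "'")
  params$adapters[[i]]
}

# ---- file I/O ----------------------------------------------------------

#' Save a parameter set to a directory of plain-text tables
#'
#' Writes `receptors.csv`, `sites.csv`, `adapters.csv`, `weights.csv` and a
#' `config.json` holding the scalar fields (kp, cell volume, ligand,
#' phosphatase, degradation adapter). Numerics are written with 17
#' significant digits so that [load_parameters()] round-trips all fields
#' exactly.
#'
#' In `adapters.csv` the `sites` column encodes the binding map as
#' semicolon-separated `receptor:site` tokens.
#'
#' @param params A `model_parameters` object.
#' @param path Directory to create/write into.
#' @return Invisibly, `path`.
#' @export
save_parameters <- function(params, path) {
  validate_parameters(params)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)

  rec <- data.frame(
    name = vapply(params$receptors, `[[`, "", "name"),
    concentration = fmt_full(vapply(params$receptors, `[[`, 0, "concentration")),
    kon_vegf = fmt_full(vapply(params$receptors, `[[`, 0, "kon_vegf")),
    koff_vegf = fmt_full(vapply(params$receptors, `[[`, 0, "koff_vegf")),
    aa_spacing = fmt_full(vapply(params$receptors, `[[`, 0, "aa_spacing")),
    stringsAsFactors = FALSE)
  utils::write.csv(rec, file.path(path, "receptors.csv"), row.names = FALSE)

  sites <- do.call(rbind, lapply(params$receptors, function(r) {
    data.frame(receptor = r$name, site = names(r$sites),
               residue = fmt_full(unname(r$sites)), stringsAsFactors = FALSE)
  }))
  utils::write.csv(sites, file.path(path, "sites.csv"), row.names = FALSE)

  encode_sites <- function(a) {
    toks <- unlist(lapply(names(a$site_names), function(rn) {
      paste0(rn, ":", a$site_names[[rn]])
    }))
    paste(toks, collapse = ";")
  }
  ad <- data.frame(
    name = vapply(params$adapters, `[[`, "", "name"),
    concentration = fmt_full(vapply(params$adapters, `[[`, 0, "concentration")),
    kon = fmt_full(vapply(params$adapters, `[[`, 0, "kon")),
    koff = fmt_full(vapply(params$adapters, `[[`, 0, "koff")),
    size_y = fmt_full(vapply(params$adapters, `[[`, 0, "size_y")),
    sites = vapply(params$adapters, encode_sites, ""),
    provenance = vapply(params$adapters, `[[`, "", "provenance"),
    inhibited = vapply(params$adapters, `[[`, TRUE, "inhibited"),
    stringsAsFactors = FALSE)
  utils::write.csv(ad, file.path(path, "adapters.csv"), row.names = FALSE)

  wt <- do.call(rbind, lapply(params$adapters, function(a) {
    data.frame(adapter = a$name, response = names(a$weights),
               weight = fmt_full(unname(a$weights)), stringsAsFactors = FALSE)
  }))
  if (is.null(wt)) {
    wt <- data.frame(adapter = character(), response = character(),
                     weight = character())
  }
  utils::write.csv(wt, file.path(path, "weights.csv"), row.names = FALSE)

  cfg <- list(kp = params$kp, cell_volume = params$cell_volume,
              degradation_adapter = params$degradation_adapter,
              ligand = unclass(params$ligand),
              phosphatase = unclass(params$phosphatase))
  # digits = I(17): full IEEE double precision so load round-trips exactly
  jsonlite::write_json(cfg, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

read_param_csv <- function(path, file, required) {
  fp <- file.path(path, file)
  if (!file.exists(fp)) stop_user("parameter file missing: ", fp)
  df <- tryCatch(utils::read.csv(fp, stringsAsFactors = FALSE),
                 error = function(e) stop_user("cannot parse ", fp, ": ", conditionMessage(e)))
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop_user(file, ": missing required column(s) ", paste(miss, collapse = ", "))
  }
  df
}

#' Load a parameter set from a directory of plain-text tables
#'
#' Reads the layout written by [save_parameters()]. Missing optional scalars
#' are filled with their documented defaults (kp = 0.01/s, cell volume =
#' 1 pL). All structural invariants are validated; violations raise errors
#' naming the offending record.
#'
#' @param path Directory containing the parameter tables.
#' @return A validated `model_parameters` object.
#' @export
load_parameters <- function(path) {
  if (!dir.exists(path)) stop_user("parameter directory does not exist: ", path)
  rec_df <- read_param_csv(path, "receptors.csv",
                           c("name", "concentration", "kon_vegf", "koff_vegf", "aa_spacing"))
  site_df <- read_param_csv(path, "sites.csv", c("receptor", "site", "residue"))
  ad_df <- read_param_csv(path, "adapters.csv",
                          c("name", "concentration", "kon", "koff", "size_y", "sites"))

  wt_path <- file.path(path, "weights.csv")
  wt_df <- if (file.exists(wt_path)) {
    read_param_csv(path, "weights.csv", c("adapter", "response", "weight"))
  } else NULL

  cfg_path <- file.path(path, "config.json")
  cfg <- if (file.exists(cfg_path)) {
    tryCatch(jsonlite::read_json(cfg_path, simplifyVector = TRUE),
             error = function(e) stop_user("cannot parse config.json: ", conditionMessage(e)))
  } else list()

  receptors <- lapply(seq_len(nrow(rec_df)), function(i) {
    row <- rec_df[i, ]
    srows <- site_df[site_df$receptor == row$name, , drop = FALSE]
    if (nrow(srows) == 0) stop_user("receptor '", row$name, "' has no sites in sites.csv")
    receptor_spec(name = row$name, concentration = row$concentration,
                  kon_vegf = row$kon_vegf, koff_vegf = row$koff_vegf,
                  sites = stats::setNames(as.numeric(srows$residue), srows$site),
                  aa_spacing = row$aa_spacing)
  })

  adapters <- lapply(seq_len(nrow(ad_df)), function(i) {
    row <- ad_df[i, ]
    site_names <- list()
    if (nzchar(row$sites)) {
      toks <- strsplit(row$sites, ";", fixed = TRUE)[[1]]
      for (tok in toks) {
        parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
        if (length(parts) != 2) {
          stop_user("adapters.csv row ", i, " ('", row$name,
                    "'): malformed sites token '", tok, "'")
        }
        site_names[[parts[1]]] <- c(site_names[[parts[1]]], parts[2])
      }
    }
    weights <- c(migration = 0, proliferation = 0)
    if (!is.null(wt_df)) {
      wrows <- wt_df[wt_df$adapter == row$name, , drop = FALSE]
      if (nrow(wrows)) {
        weights[wrows$response] <- as.numeric(wrows$weight)
      }
    }
    adapter_spec(name = row$name, concentration = row$concentration,
                 kon = row$kon, koff = row$koff, size_y = row$size_y,
                 site_names = site_names, weights = weights,
                 provenance = if ("provenance" %in% names(ad_df)) row$provenance else "file",
                 inhibited = if ("inhibited" %in% names(ad_df)) row$inhibited else FALSE)
  })

  ph <- cfg$phosphatase %||% list()
  phosphatase <- phosphatase_spec(
    kon = ph$kon %||% per_molar_to_per_molecule(1e6),
    koff = ph$koff %||% 0.1, kd = ph$kd %||% 1,
    reservoir = ph$reservoir %||% 1e5)
  lg <- cfg$ligand %||% list()
  ligand <- ligand_spec(
    concentration_mass = lg$concentration_mass %||% 50,
    molecular_weight = lg$molecular_weight %||% 38200,
    depletable = lg$depletable %||% FALSE)

  model_parameters(receptors = receptors, adapters = adapters,
                   phosphatase = phosphatase, ligand = ligand,
                   kp = cfg$kp %||% 0.01,
                   cell_volume = cfg$cell_volume %||% 1e-12,
                   degradation_adapter = cfg$degradation_adapter)
}

# ---- fixture generator -------------------------------------------------

#' Generate a randomized fixture parameter set
#'
#' Produces a complete, valid `model_parameters` object with randomized but
#' physiologically scaled values: adapter concentrations log-uniform on
#' \[1e2, 1e5\] molecules/cell (the range used for concentration sweeps),
#' dissociation constants between 1 and 1000 nM, and adapter sizes adjusted
#' so that at least one steric co-occupancy constraint is active. Generation
#' is bitwise reproducible for a fixed seed and does not disturb the
#' caller's random number generator state.
#'
#' @param seed Integer seed.
#' @param n_adapters Number of adapters (>= 1).
#' @param n_receptors Number of receptors (default 2).
#' @param n_sites Tyrosine sites per receptor (default 3).
#' @return A validated `model_parameters` object with
#'   `provenance = "fixture"` adapters; the first adapter is designated the
#'   degradation channel.
#' @export
generate_fixture_parameters <- function(seed, n_adapters, n_receptors = 2,
                                        n_sites = 3) {
  if (n_adapters < 1) stop_user("n_adapters must be >= 1")
  if (n_receptors < 1 || n_sites < 1) stop_user("need at least one receptor and site")
  withr::with_seed(seed, {
    vol <- 1e-12
    receptors <- lapply(seq_len(n_receptors), function(i) {
      residues <- sort(sample(700:1400, n_sites))
      receptor_spec(
        name = paste0("R", i),
        concentration = 10^stats::runif(1, 3.0, 4.3),
        kon_vegf = per_molar_to_per_molecule(10^stats::runif(1, 6.5, 7.5), vol),
        koff_vegf = 10^stats::runif(1, -4, -3),
        sites = stats::setNames(residues, paste0("Y", residues)),
        aa_spacing = 0.171)
    })
    rec_names <- vapply(receptors, `[[`, "", "name")

    adapters <- lapply(seq_len(n_adapters), function(i) {
      kon_M <- 10^stats::runif(1, 5.5, 6.5)
      kd_nM <- 10^stats::runif(1, 0, 3)
      site_names <- list()
      for (r in receptors) {
        k <- sample(seq_along(r$sites), 1)
        site_names[[r$name]] <- sort(names(r$sites)[sample(seq_along(r$sites), k)])
      }
      adapter_spec(
        name = paste0("A", i),
        concentration = 10^stats::runif(1, 2, 5),
        kon = per_molar_to_per_molecule(kon_M, vol),
        koff = kd_nM * 1e-9 * kon_M,
        size_y = 1, # provisional; rescaled below
        site_names = site_names,
        weights = c(migration = stats::runif(1), proliferation = stats::runif(1)),
        provenance = "fixture")
    })

    # size draws on the scale of inter-site gaps, then force at least one
    # active co-occupancy constraint on the first receptor's closest pair
    gaps <- unlist(lapply(receptors, function(r) diff(r$sites) * r$aa_spacing))
    for (i in seq_along(adapters)) {
      adapters[[i]]$size_y <- stats::runif(1, 0.8 * min(gaps), 1.6 * max(gaps))
    }
    r1 <- receptors[[1]]
    d1 <- diff(r1$sites) * r1$aa_spacing
    j <- which.min(d1)
    pair <- names(r1$sites)[c(j, j + 1)]
    a1 <- 1; a2 <- if (n_adapters >= 2) 2 else 1
    adapters[[a1]]$site_names[[r1$name]] <-
      sort(unique(c(adapters[[a1]]$site_names[[r1$name]], pair[1])))
    adapters[[a2]]$site_names[[r1$name]] <-
      sort(unique(c(adapters[[a2]]$site_names[[r1$name]], pair[2])))
    if (adapters[[a1]]$size_y / 2 + adapters[[a2]]$size_y / 2 < d1[j]) {
      adapters[[a1]]$size_y <- 2.2 * d1[j]
    }

    phosphatase <- phosphatase_spec(
      kon = per_molar_to_per_molecule(1e6, vol), koff = 0.1, kd = 1,
      reservoir = 1e5)

    model_parameters(receptors = receptors, adapters = adapters,
                     phosphatase = phosphatase, ligand = ligand_spec(),
                     kp = 0.01, cell_volume = vol,
                     degradation_adapter = adapters[[1]]$name)
  })
}
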