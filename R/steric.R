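#' Distance between two tyrosine sites along the receptor
#'
#' The carboxy terminus is treated as a one-dimensional chain with a fixed
#' average spacing per amino acid, so the distance between two sites is the
#' residue separation times that spacing (e.g. 0.171 Angstrom/aa for
#' VEGFR1).
#'
#' @param receptor A [receptor_spec()].
#' @param site_a,site_b Site names present on the receptor.
#' @return Distance in Angstroms.
#' @examples
#' r1 <- receptor_spec("VEGFR1", 1800, 1e-5, 1e-3,
#'                     sites = c(Y1242 = 1242, Y1333 = 1333), aa_spacing = 0.171)
#' site_distance(r1, "Y1242", "Y1333") # 15.6 A
#' @export
site_distance <- function(receptor, site_a, site_b) {
  stopifnot(inherits(receptor, "receptor_spec"))
  for (s in c(site_a, site_b)) {
    if (!s %in% names(receptor$sites)) {
      stop_user("unknown site '", s, "' on receptor '", receptor$name, "'")
    }
  }
  abs(receptor$sites[[site_a]] - receptor$sites[[site_b]]) * receptor$aa_spacing
}

#' One-sided steric footprint of an adapter
#'
#' The adapter's centre binds the phospho-tyrosine, so the space it occupies
#' toward a neighbouring site is half its total extent along the receptor
#' axis.
#'
#' @param adapter An [adapter_spec()].
#' @return Footprint in Angstroms (`size_y / 2`).
#' @export
adapter_footprint <- function(adapter) {
  stopifnot(inherits(adapter, "adapter_spec"))
  adapter$size_y / 2
}

#' Construct a binding configuration
#'
#' @param receptor Receptor name.
#' @param occupancy Named character vector mapping site name to adapter
#'   name; unoccupied sites are simply absent. May be empty.
#' @return An object of class `binding_configuration`.
#' @export
binding_configuration <- function(receptor, occupancy = character()) {
  occupancy <- unlist(occupancy)
  if (length(occupancy) && (is.null(names(occupancy)) || anyDuplicated(names(occupancy)))) {
    stop_user("occupancy must map each site at most once")
  }
  structure(list(receptor = receptor,
                 occupancy = if (length(occupancy)) occupancy else character()),
            class = "binding_configuration")
}

#' Test whether a binding configuration is sterically feasible
#'
#' A configuration is feasible iff every assigned adapter may bind its site
#' (the site is in the adapter's site map for this receptor) and, for every
#' pair of occupied sites, the sum of the two one-sided footprints is
#' strictly smaller than the inter-site distance. Ties are infeasible. The
#' empty configuration and every single-adapter configuration on an allowed
#' site are always feasible.
#'
#' @param config A [binding_configuration()].
#' @param params A `model_parameters` object resolving receptor and
#'   adapters.
#' @return Logical scalar.
#' @export
is_feasible <- function(config, params) {
  stopifnot(inherits(config, "binding_configuration"))
  receptor <- get_receptor(params, config$receptor)
  occ <- config$occupancy
  if (!length(occ)) return(TRUE)
  for (s in names(occ)) {
    if (!s %in% names(receptor$sites)) {
      stop_user("unknown site '", s, "' on receptor '", receptor$name, "'")
    }
    a <- get_adapter(params, occ[[s]])
    allowed <- a$site_names[[receptor$name]] %||% character()
    if (!s %in% allowed) return(FALSE)
  }
  if (length(occ) >= 2) {
    sn <- names(occ)
    for (i in seq_len(length(occ) - 1)) {
      for (j in seq(i + 1, length(occ))) {
        fi <- adapter_footprint(get_adapter(params, occ[[sn[i]]]))
        fj <- adapter_footprint(get_adapter(params, occ[[sn[j]]]))
        if (fi + fj >= site_distance(receptor, sn[i], sn[j])) return(FALSE)
      }
    }
  }
  TRUE
}

#' Enumerate all sterically feasible binding configurations of a receptor
#'
#' Walks the receptor's sites in residue order, extending partial
#' configurations with every adapter allowed at the site and pruning
#' extensions that violate a pairwise steric constraint. Because pairwise
#' feasibility is monotone under removal of an adapter, pruning is exact:
#' the result equals a brute-force filter of all site-to-adapter
#' assignments.
#'
#' @param receptor A [receptor_spec()] or receptor name.
#' @param params A `model_parameters` object.
#' @return List of [binding_configuration()] objects, beginning with the
#'   empty configuration; order is deterministic (sites in residue order,
#'   adapters in parameter order).
#' @export
enumerate_configurations <- function(receptor, params) {
  if (is.character(receptor)) receptor <- get_receptor(params, receptor)
  stopifnot(inherits(receptor, "receptor_spec"))
  rn <- receptor$name
  site_names <- names(receptor$sites)
  ad_names <- adapter_names(params)
  allowed_at <- lapply(site_names, function(s) {
    ad_names[vapply(params$adapters, function(a) {
      s %in% (a$site_names[[rn]] %||% character())
    }, TRUE)]
  })
  names(allowed_at) <- site_names

  results <- list()
  extend <- function(occ, idx) {
    results[[length(results) + 1L]] <<- binding_configuration(rn, occ)
    if (idx > length(site_names)) return(invisible())
    for (k in seq(idx, length(site_names))) {
      s <- site_names[k]
      for (a in allowed_at[[s]]) {
        cand <- c(occ, stats::setNames(a, s))
        ok <- TRUE
        if (length(occ)) {
          fa <- adapter_footprint(get_adapter(params, a))
          for (s0 in names(occ)) {
            f0 <- adapter_footprint(get_adapter(params, occ[[s0]]))
            if (fa + f0 >= site_distance(receptor, s0, s)) { ok <- FALSE; break }
          }
        }
        if (ok) extend(cand, k + 1L)
      }
    }
  }
  extend(character(), 1L)
  results
}

#' Tabulate feasible configurations across all receptors
#'
#' @param params A `model_parameters` object.
#' @return A data frame with columns `receptor`, `n_bound`, `sites`,
#'   `adapters` (site and adapter lists `|`-separated), one row per
#'   feasible configuration.
#' @export
configurations_table <- function(params) {
  rows <- list()
  for (r in params$receptors) {
    cfgs <- enumerate_configurations(r, params)
    for (cf in cfgs) {
      rows[[length(rows) + 1L]] <- data.frame(
        receptor = r$name, n_bound = length(cf$occupancy),
        sites = paste(names(cf$occupancy), collapse = "|"),
        adapters = paste(unname(cf$occupancy), collapse = "|"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Maximum simultaneous adapter occupancy of a receptor
#'
#' @param receptor Receptor name or [receptor_spec()].
#' @param params A `model_parameters` object.
#' @return Integer maximum number of simultaneously bound adapters, with
#'   attribute `shared_sites`: the site names present in *every* maximal
#'   configuration (empty if none).
#' @export
max_occupancy <- function(receptor, params) {
  cfgs <- enumerate_configurations(receptor, params)
  n <- vapply(cfgs, function(cf) length(cf$occupancy), 0L)
  m <- max(n)
  shared <- character()
  if (m > 0) {
    maxi <- cfgs[n == m]
    shared <- Reduce(intersect, lapply(maxi, function(cf) names(cf$occupancy)))
  }
  structure(m, shared_sites = shared)
}
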