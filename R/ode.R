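#' Integrate a reaction network
#'
#' Solves `dx/dt = S v(x)` with mass-action rates using a stiff-capable
#' integrator (deSolve `lsoda`). Boundary species (the ligand unless
#' depletable, and the PTPN reservoir) are held constant. After
#' integration, tiny negative excursions (> -1e-9 molecules) are zeroed and
#' every adapter and receptor moiety total is verified to be conserved over
#' the whole grid; a breach beyond `conservation_tol` relative error raises
#' an integrity error.
#'
#' @param network A `reaction_network`.
#' @param t_end Simulation horizon in seconds (default 3600 s with 601
#'   output points, on the order of the phospho-ELISA observation window;
#'   both are configurable).
#' @param n_points Number of output grid points (>= 2).
#' @param rtol,atol Relative/absolute solver tolerances (defaults 1e-8 and
#'   1e-10).
#' @param conservation_tol Maximum tolerated relative drift of any moiety
#'   total (default 1e-6).
#' @param method deSolve integration method.
#' @return An object of class `simulation_result`: list with `times`,
#'   `trajectories` (matrix time x species, columns named by species id),
#'   `network`, and `params_digest`.
#' @export
simulate_network <- function(network, t_end = 3600, n_points = 601,
                             rtol = 1e-8, atol = 1e-10,
                             conservation_tol = 1e-6, method = "lsoda") {
  stopifnot(inherits(network, "reaction_network"))
  if (t_end <= 0) stop_user("t_end must be positive")
  if (n_points < 2) stop_user("n_points must be >= 2")

  sp <- network$species
  ids <- sp$id
  n_sp <- length(ids)
  S <- stoichiometry_matrix(network)
  storage.mode(S) <- "double"

  # reactant index pairs (0 = absent); mass-action reactions here have at
  # most two reactants
  n_rx <- nrow(network$reactions)
  i1 <- integer(n_rx); i2 <- integer(n_rx)
  for (j in seq_len(n_rx)) {
    re <- match(network$reactions$reactants[[j]], ids)
    if (anyNA(re)) stop("reaction references unknown species")
    if (length(re) > 2) stop("more than two reactants in a mass-action step")
    i1[j] <- if (length(re) >= 1) re[1] else 0L
    i2[j] <- if (length(re) >= 2) re[2] else 0L
  }
  k <- network$reactions$rate
  const_idx <- which(sp$constant)

  rhs <- function(t, y, p) {
    y[y < 0] <- 0
    xx <- c(1, y)
    v <- k * xx[i1 + 1L] * xx[i2 + 1L]
    dy <- as.vector(S %*% v)
    dy[const_idx] <- 0
    list(dy)
  }

  y0 <- stats::setNames(sp$initial, ids)
  times <- seq(0, t_end, length.out = n_points)
  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  ist <- attributes(out)$istate
  if (!is.null(ist) && ist[1] < 0) {
    stop("ODE solver failed (istate = ", ist[1], ")")
  }
  if (nrow(out) < n_points) stop("ODE solver returned an incomplete grid")

  traj <- unname(out[, -1, drop = FALSE])
  colnames(traj) <- ids
  if (any(traj < -1e-6)) {
    stop("integration produced significantly negative amounts (min ",
         format(min(traj)), ")")
  }
  traj[traj < 0] <- 0

  # moiety conservation over the whole grid
  moieties <- c(adapter_names_network(network), receptor_names_network(network))
  cons <- vapply(moieties, function(m) {
    w <- conservation_vector(network, m)
    tot <- as.vector(traj %*% w)
    ref <- max(abs(tot[1]), 1)
    max(abs(tot - tot[1])) / ref
  }, 0)
  if (length(cons) && max(cons) > conservation_tol) {
    stop("conservation integrity error: moiety '",
         names(cons)[which.max(cons)], "' drifts by relative error ",
         format(max(cons)))
  }

  structure(list(times = times, trajectories = traj, network = network,
                 conservation_error = cons,
                 params_digest = network$params_digest),
            class = "simulation_result")
}

adapter_names_network <- function(network) {
  unique(unlist(lapply(network$species$adapters, names)))
}

receptor_names_network <- function(network) {
  r <- network$species$receptor
  unique(r[!is.na(r) & nzchar(r)])
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("simulation_result: ", length(x$times), " time points over [0, ",
      max(x$times), "] s, ", ncol(x$trajectories), " species\n", sep = "")
  invisible(x)
}

#' Phosphorylated-adapter time course
#'
#' Sums, over all species, the number of phosphorylated copies of the named
#' adapter each species contains. PTPN-bound phospho intermediates are
#' included (the adapter remains chemically phosphorylated until the
#' catalytic dephosphorylation step fires); the post-catalysis
#' adapter-phosphatase complex is not.
#'
#' @param result A `simulation_result`.
#' @param adapter Adapter name.
#' @return Numeric vector (molecules/cell) over the simulation grid.
#' @export
phospho_trace <- function(result, adapter) {
  stopifnot(inherits(result, "simulation_result"))
  net <- result$network
  if (!adapter %in% adapter_names_network(net)) {
    stop_user("unknown adapter '", adapter, "' in network")
  }
  w <- vapply(net$species$phospho, function(p) {
    if (adapter %in% names(p)) p[[adapter]] else 0
  }, 0)
  as.vector(result$trajectories %*% w)
}

#' Total (bound + free, any state) adapter time course
#'
#' @inheritParams phospho_trace
#' @return Numeric vector over the grid; constant up to solver error.
#' @export
adapter_total_trace <- function(result, adapter) {
  stopifnot(inherits(result, "simulation_result"))
  w <- conservation_vector(result$network, adapter)
  as.vector(result$trajectories %*% w)
}

#' Simulate the contribution of a single receptor
#'
#' Re-simulates the model with every other receptor's surface concentration
#' set to zero while all adapter pools are unchanged, isolating the signal
#' transduced through the named receptor. Because adapters are shared,
#' single-receptor contributions are not additive in general.
#'
#' @param params A `model_parameters` object.
#' @param receptor Receptor name to retain.
#' @param variant Model variant (`"specific"` or `"nonspecific"`).
#' @param ... Passed to [simulate_network()].
#' @return A `simulation_result`.
#' @export
receptor_contribution <- function(params, receptor,
                                  variant = c("specific", "nonspecific"), ...) {
  variant <- match.arg(variant)
  rn <- receptor_names(params)
  if (!receptor %in% rn) stop_user("unknown receptor '", receptor, "'")
  p <- params
  for (i in seq_along(p$receptors)) {
    if (p$receptors[[i]]$name != receptor) p$receptors[[i]]$concentration <- 0
  }
  simulate_network(build_network(p, variant), ...)
}

#' Trajectories in long (tidy) form
#'
#' @param result A `simulation_result`.
#' @return Data frame with columns `time`, `species`, `value`.
#' @export
trajectories_long <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  ids <- colnames(result$trajectories)
  data.frame(
    time = rep(result$times, times = length(ids)),
    species = rep(ids, each = length(result$times)),
    value = as.vector(result$trajectories),
    stringsAsFactors = FALSE)
}
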