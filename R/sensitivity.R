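#' Sweep one adapter's concentration
#'
#' Runs one simulation per grid point with only the named adapter's
#' concentration changed, on a log-spaced grid spanning 1e2 to 1e5
#' molecules/cell by default (the physiological sweep range), recording the
#' response summary and every adapter's phospho integrated response and
#' amplitude at each point.
#'
#' @param params A `model_parameters` object.
#' @param adapter Adapter whose concentration is swept.
#' @param n_grid Number of grid points (>= 2); the endpoints are exactly
#'   the range bounds.
#' @param range Length-2 concentration range in molecules/cell.
#' @param variant Model variant.
#' @param ... Passed to [simulate_network()].
#' @return Object of class `sweep_result`: list with `adapter`, `grid`,
#'   `responses` (data frame: concentration, response, integrated,
#'   amplitude, relative_integrated) and `adapters` (data frame:
#'   concentration, adapter, integrated, amplitude).
#' @export
sweep_concentration <- function(params, adapter, n_grid = 7,
                                range = c(1e2, 1e5), variant = "specific",
                                ...) {
  if (n_grid < 2) stop_user("n_grid must be >= 2")
  if (!adapter %in% adapter_names(params)) stop_user("unknown adapter '", adapter, "'")
  grid <- 10^seq(log10(range[1]), log10(range[2]), length.out = n_grid)
  resp_rows <- list(); ad_rows <- list()
  for (g in grid) {
    p <- params
    i <- match(adapter, adapter_names(p))
    p$adapters[[i]]$concentration <- g
    res <- simulate_network(build_network(p, variant), ...)
    summ <- summarize_responses(compute_responses(res, p))
    for (r in RESPONSES) {
      resp_rows[[length(resp_rows) + 1L]] <- data.frame(
        concentration = g, response = r,
        integrated = summ$integrated[[r]], amplitude = summ$amplitude[[r]],
        relative_integrated = summ$relative_integrated[[r]],
        stringsAsFactors = FALSE)
    }
    for (a in adapter_names(p)) {
      tr <- phospho_trace(res, a)
      ad_rows[[length(ad_rows) + 1L]] <- data.frame(
        concentration = g, adapter = a,
        integrated = auc_trapezoid(res$times, tr), amplitude = max(tr),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(adapter = adapter, grid = grid,
                 responses = do.call(rbind, resp_rows),
                 adapters = do.call(rbind, ad_rows)),
            class = "sweep_result")
}

#' Perturbation specification for Monte Carlo sampling
#'
#' Default scheme: each adapter's kon and koff are independently multiplied
#' by log-uniform factors spanning one decade either way around nominal
#' (`10^U(-decades, decades)`). The `"concentrations"` target perturbs
#' adapter concentrations instead.
#'
#' @param target `"kinetics"` or `"concentrations"`.
#' @param decades Half-width of the log10-uniform multiplier (default 1;
#'   0 gives a zero-width, deterministic perturbation).
#' @return A `perturbation_spec` list.
#' @export
perturbation_spec <- function(target = c("kinetics", "concentrations"),
                              decades = 1) {
  target <- match.arg(target)
  if (decades < 0) stop_user("decades must be nonnegative")
  structure(list(target = target, decades = decades),
            class = "perturbation_spec")
}

#' Draw Monte Carlo perturbation multipliers
#'
#' @param params A `model_parameters` object (defines how many factors are
#'   needed per draw).
#' @param n_draws Number of draws (>= 1).
#' @param seed Integer seed; draws are bitwise reproducible and the
#'   caller's RNG state is untouched.
#' @param perturbation A [perturbation_spec()].
#' @return Numeric matrix `n_draws` x n_factors with named columns
#'   (`<adapter>.kon`, `<adapter>.koff` for kinetics;
#'   `<adapter>.concentration` for concentrations).
#' @export
draw_perturbations <- function(params, n_draws, seed,
                               perturbation = perturbation_spec()) {
  if (n_draws < 1) stop_user("n_draws must be >= 1")
  stopifnot(inherits(perturbation, "perturbation_spec"))
  ad <- adapter_names(params)
  cols <- if (perturbation$target == "kinetics") {
    as.vector(t(outer(ad, c("kon", "koff"), paste, sep = ".")))
  } else {
    paste0(ad, ".concentration")
  }
  d <- perturbation$decades
  withr::with_seed(seed, {
    m <- matrix(10^stats::runif(n_draws * length(cols), -d, d),
                nrow = n_draws, dimnames = list(NULL, cols))
    m
  })
}

apply_perturbation <- function(params, multipliers, perturbation) {
  p <- params
  for (i in seq_along(p$adapters)) {
    a <- p$adapters[[i]]
    if (perturbation$target == "kinetics") {
      p$adapters[[i]]$kon <- a$kon * multipliers[[paste0(a$name, ".kon")]]
      p$adapters[[i]]$koff <- a$koff * multipliers[[paste0(a$name, ".koff")]]
    } else {
      p$adapters[[i]]$concentration <-
        a$concentration * multipliers[[paste0(a$name, ".concentration")]]
    }
  }
  p
}

#' Monte Carlo uncertainty propagation
#'
#' Draws parameter perturbations, simulates each draw, and returns per-
#' output means and standard deviations over draws. Outputs are the
#' integrated response and amplitude of each cell response and of each
#' adapter's phospho trace. Deterministic for a fixed seed.
#'
#' @param params A `model_parameters` object.
#' @param n_draws Number of Monte Carlo draws (>= 1). The published
#'   analysis style uses thousands of draws; smaller counts are appropriate
#'   for routine testing.
#' @param seed Integer seed.
#' @param perturbation A [perturbation_spec()].
#' @param variant Model variant.
#' @param ... Passed to [simulate_network()].
#' @return Object of class `mc_result`: list with `mean`, `sd` (named
#'   vectors), `draws` (data frame, one row per draw), `perturbation`,
#'   `seed`, `n_draws`.
#' @export
monte_carlo <- function(params, n_draws = 200, seed = 1,
                        perturbation = perturbation_spec(),
                        variant = "specific", ...) {
  mult <- draw_perturbations(params, n_draws, seed, perturbation)
  rows <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    p <- apply_perturbation(params, mult[i, , drop = TRUE], perturbation)
    res <- simulate_network(build_network(p, variant), ...)
    summ <- summarize_responses(compute_responses(res, p))
    out <- c(stats::setNames(summ$integrated, paste0(RESPONSES, ".integrated")),
             stats::setNames(summ$amplitude, paste0(RESPONSES, ".amplitude")))
    for (a in adapter_names(p)) {
      tr <- phospho_trace(res, a)
      out[paste0(a, ".integrated")] <- auc_trapezoid(res$times, tr)
      out[paste0(a, ".amplitude")] <- max(tr)
    }
    rows[[i]] <- out
  }
  draws <- as.data.frame(do.call(rbind, rows))
  sd_fun <- if (n_draws == 1) function(x) 0 else stats::sd
  structure(list(mean = vapply(draws, mean, 0),
                 sd = vapply(draws, sd_fun, 0),
                 draws = draws, perturbation = perturbation,
                 seed = seed, n_draws = n_draws),
            class = "mc_result")
}
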