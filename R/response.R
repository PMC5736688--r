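#' Map phospho-adapter traces to cell responses
#'
#' Migration and proliferation are weighted sums of adapter phosphorylation
#' (`sum_i w_i pA_i(t)` with calibrated nonnegative weights); the
#' degradation response is identical to the phosphorylation trace of the
#' designated degradation adapter (c-Cbl), taken bit-for-bit.
#'
#' @param result A `simulation_result`.
#' @param params The `model_parameters` the simulation was built from; every
#'   adapter present must carry `migration` and `proliferation` weights.
#' @return Object of class `cell_response_trace`: list with `times`,
#'   `migration`, `proliferation`, `degradation`.
#' @export
compute_responses <- function(result, params) {
  stopifnot(inherits(result, "simulation_result"))
  net_adapters <- adapter_names_network(result$network)
  n <- length(result$times)
  migration <- numeric(n); proliferation <- numeric(n)
  for (a in params$adapters) {
    if (!a$name %in% net_adapters) next
    w <- a$weights
    if (!all(c("migration", "proliferation") %in% names(w))) {
      stop_user("adapter '", a$name, "' is missing migration/proliferation weights")
    }
    tr <- phospho_trace(result, a$name)
    migration <- migration + w[["migration"]] * tr
    proliferation <- proliferation + w[["proliferation"]] * tr
  }
  degradation <- if (!is.null(params$degradation_adapter) &&
                     params$degradation_adapter %in% net_adapters) {
    phospho_trace(result, params$degradation_adapter)
  } else numeric(n)
  structure(list(times = result$times, migration = migration,
                 proliferation = proliferation, degradation = degradation),
            class = "cell_response_trace")
}

RESPONSES <- c("migration", "proliferation", "degradation")

#' Summarize a cell-response trace
#'
#' Integrated response is the area under the response-time curve (trapezoid
#' rule on the stored grid); amplitude is the peak value; the relative
#' integrated response is each response's share of the three-response
#' integrated total (zeros if the total is zero).
#'
#' @param trace A `cell_response_trace` (>= 2 time points).
#' @return Object of class `response_summary` with named vectors
#'   `integrated`, `amplitude`, `relative_integrated`.
#' @export
summarize_responses <- function(trace) {
  stopifnot(inherits(trace, "cell_response_trace"))
  if (length(trace$times) < 2) stop_user("need at least 2 time points")
  integrated <- vapply(RESPONSES, function(r) {
    auc_trapezoid(trace$times, trace[[r]])
  }, 0)
  amplitude <- vapply(RESPONSES, function(r) max(trace[[r]]), 0)
  total <- sum(integrated)
  relative <- if (total > 0) integrated / total else stats::setNames(rep(0, 3), RESPONSES)
  structure(list(integrated = integrated, amplitude = amplitude,
                 relative_integrated = relative),
            class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  m <- rbind(integrated = x$integrated, amplitude = x$amplitude,
             relative = x$relative_integrated)
  print(signif(m, 4))
  invisible(x)
}

#' Apply an adapter-targeted inhibitor
#'
#' Complete inhibition of an adapter's signal: by default the adapter's
#' phosphorylation step is removed from generated networks (`block_kp`),
#' while its receptor binding is retained so competition for sites
#' persists — the catalytic inhibitors used experimentally (Wortmannin,
#' U73122, Imatinib) block activity, not expression. The alternative
#' `deplete` mode zeroes the adapter's concentration instead.
#'
#' @param params A `model_parameters` object.
#' @param adapter Adapter name to inhibit.
#' @param mode `"block_kp"` (default) or `"deplete"`.
#' @return Modified `model_parameters`.
#' @export
apply_inhibitor <- function(params, adapter, mode = c("block_kp", "deplete")) {
  mode <- match.arg(mode)
  i <- match(adapter, adapter_names(params))
  if (is.na(i)) stop_user("unknown adapter '", adapter, "'")
  if (mode == "block_kp") {
    params$adapters[[i]]$inhibited <- TRUE
  } else {
    params$adapters[[i]]$concentration <- 0
  }
  params
}

#' Percent reduction of an integrated response under treatment
#'
#' `100 * (1 - treated/baseline)` on the integrated response; invariant
#' under rescaling both summaries by a common factor.
#'
#' @param baseline,treated `response_summary` objects.
#' @param response One of `"migration"`, `"proliferation"`,
#'   `"degradation"`.
#' @return Percent reduction (negative if the treatment increases the
#'   response).
#' @export
percent_reduction <- function(baseline, treated, response) {
  response <- match.arg(response, RESPONSES)
  b <- baseline$integrated[[response]]
  if (b <= 0) stop_user("baseline integrated ", response, " must be positive")
  100 * (1 - treated$integrated[[response]] / b)
}

#' Model-significance band around an untreated response
#'
#' The interval covering a 10% variation of the baseline integrated
#' response (`[0.9 b, 1.1 b]` by default). A treated value strictly outside
#' the band is flagged as model-significant; the bounds themselves are
#' inside the band (inclusive).
#'
#' @param baseline A `response_summary`.
#' @param response Response name.
#' @param width Half-width as a fraction of baseline (default 0.10).
#' @return Numeric length-2 vector `c(lower, upper)` with attribute
#'   `baseline`.
#' @export
significance_band <- function(baseline, response, width = 0.10) {
  response <- match.arg(response, RESPONSES)
  b <- baseline$integrated[[response]]
  if (b <= 0) stop_user("baseline integrated ", response, " must be positive")
  structure(c(lower = (1 - width) * b, upper = (1 + width) * b), baseline = b)
}

#' Is a treated value outside a significance band?
#'
#' @param band Output of [significance_band()].
#' @param value Treated integrated response.
#' @return Logical; `TRUE` iff strictly outside the (inclusive) bounds.
#' @export
outside_band <- function(band, value) {
  value < band[["lower"]] || value > band[["upper"]]
}

#' Chi-square goodness of fit of a predicted time course
#'
#' Scores predictions against an observed time series using the measurement
#' SEM as the scale: `chi2 = sum(((obs - scale*pred)/sem)^2)` with
#' `dof = n - 1`; the fit passes when the statistic is below the chi-square
#' critical value at significance level `alpha`. Pearson scaling (expected
#' value in the denominator) is available behind a flag. An optional scale
#' factor maps model molecules/cell onto the measured phospho/total signal
#' units.
#'
#' @param predicted,observed Equal-length numeric vectors (n >= 2).
#' @param sem Positive measurement standard errors, same length (ignored
#'   when `pearson = TRUE`).
#' @param alpha Significance level (default 0.05).
#' @param scale Multiplier applied to `predicted` before comparison
#'   (default 1).
#' @param pearson If `TRUE`, use `sqrt(scale*pred)` as the denominator.
#' @return Object of class `gof_report`: `chi2`, `dof`, `critical`,
#'   `passed`, `residuals`.
#' @export
chi2_gof <- function(predicted, observed, sem = NULL, alpha = 0.05,
                     scale = 1, pearson = FALSE) {
  n <- length(observed)
  if (length(predicted) != n) stop_user("predicted and observed lengths differ")
  if (n < 2) stop_user("need at least 2 points")
  expected <- scale * predicted
  denom <- if (pearson) {
    if (any(expected <= 0)) stop_user("Pearson scaling requires positive expected values")
    sqrt(expected)
  } else {
    if (is.null(sem)) stop_user("sem is required unless pearson = TRUE")
    if (length(sem) != n) stop_user("sem length differs from observed")
    if (any(sem <= 0)) stop_user("sem must be positive")
    sem
  }
  resid <- (observed - expected) / denom
  chi2 <- sum(resid^2)
  dof <- as.integer(n - 1)
  critical <- stats::qchisq(1 - alpha, dof)
  structure(list(chi2 = chi2, dof = dof, critical = critical,
                 passed = chi2 < critical, residuals = resid),
            class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf("chi2 = %.4g on %d dof (critical %.4g): %s\n",
              x$chi2, x$dof, x$critical, if (x$passed) "PASS" else "FAIL"))
  invisible(x)
}

#' Fold difference of integrated responses between two receptors
#'
#' Runs a single-receptor contribution simulation for each of exactly two
#' receptors and returns the ratio of integrated responses (first receptor
#' over second).
#'
#' @param params A `model_parameters` object with exactly two receptors.
#' @param response Response name.
#' @param variant Model variant.
#' @param ... Passed to [simulate_network()].
#' @return The fold (numeric); `Inf` with a warning when the denominator is
#'   zero (degenerate, e.g. the second receptor absent).
#' @export
receptor_fold <- function(params, response, variant = "specific", ...) {
  response <- match.arg(response, RESPONSES)
  rn <- receptor_names(params)
  if (length(rn) != 2) stop_user("receptor_fold requires exactly two receptors")
  ints <- vapply(rn, function(r) {
    res <- receptor_contribution(params, r, variant = variant, ...)
    summarize_responses(compute_responses(res, params))$integrated[[response]]
  }, 0)
  if (ints[2] == 0) {
    warning("degenerate fold: zero integrated ", response, " for ", rn[2])
    return(Inf)
  }
  unname(ints[1] / ints[2])
}

#' Compare the specific and nonspecific model variants
#'
#' Simulates both variants from the same parameters and reports response
#' summaries, per-adapter phospho metrics (integrated and amplitude), and
#' the percent changes from nonspecific to specific: on the *relative*
#' integrated response fractions (the specific model's migration share gain
#' is quoted relative to proliferation and degradation) and on the raw
#' amplitudes.
#'
#' @param params A `model_parameters` object.
#' @param ... Passed to [simulate_network()].
#' @return List with elements `nonspecific`, `specific` (each: `summary`,
#'   `adapters` data frame), `relative_integrated_change_pct`,
#'   `amplitude_change_pct`, `adapter_integrated_change_pct`,
#'   `adapter_amplitude_change_pct`.
#' @export
compare_models <- function(params, ...) {
  run <- function(variant) {
    res <- simulate_network(build_network(params, variant), ...)
    summ <- summarize_responses(compute_responses(res, params))
    ad <- do.call(rbind, lapply(adapter_names(params), function(a) {
      tr <- phospho_trace(res, a)
      data.frame(adapter = a,
                 integrated = auc_trapezoid(res$times, tr),
                 amplitude = max(tr), stringsAsFactors = FALSE)
    }))
    list(summary = summ, adapters = ad)
  }
  ns <- run("nonspecific"); spc <- run("specific")
  pct <- function(new, old) ifelse(old > 0, 100 * (new - old) / old, NA_real_)
  list(
    nonspecific = ns, specific = spc,
    relative_integrated_change_pct = stats::setNames(
      pct(spc$summary$relative_integrated, ns$summary$relative_integrated), RESPONSES),
    amplitude_change_pct = stats::setNames(
      pct(spc$summary$amplitude, ns$summary$amplitude), RESPONSES),
    adapter_integrated_change_pct = stats::setNames(
      pct(spc$adapters$integrated, ns$adapters$integrated), ns$adapters$adapter),
    adapter_amplitude_change_pct = stats::setNames(
      pct(spc$adapters$amplitude, ns$adapters$amplitude), ns$adapters$adapter))
}

#' Predicted maximum response reductions for a panel of inhibitors
#'
#' For each listed adapter, simulates complete inhibition (phosphorylation
#' blocked, binding retained) and reports the percent reduction in each
#' requested integrated response together with the model-significance
#' verdict against a 10% variation band around the untreated response.
#'
#' @param params A `model_parameters` object.
#' @param inhibitors Character vector of adapter names (non-empty).
#' @param variant Model variant.
#' @param responses Responses to report (default migration and
#'   proliferation).
#' @param ... Passed to [simulate_network()].
#' @return Data frame: `inhibitor`, `response`, `baseline`, `treated`,
#'   `reduction_pct`, `significant`.
#' @export
inhibitor_panel <- function(params, inhibitors, variant = "specific",
                            responses = c("migration", "proliferation"), ...) {
  if (!length(inhibitors)) stop_user("inhibitor list is empty")
  unknown <- setdiff(inhibitors, adapter_names(params))
  if (length(unknown)) stop_user("unknown inhibitor target(s): ",
                                 paste(unknown, collapse = ", "))
  base <- summarize_responses(compute_responses(
    simulate_network(build_network(params, variant), ...), params))
  rows <- list()
  for (inh in inhibitors) {
    p2 <- apply_inhibitor(params, inh)
    treat <- summarize_responses(compute_responses(
      simulate_network(build_network(p2, variant), ...), p2))
    for (resp in responses) {
      band <- significance_band(base, resp)
      rows[[length(rows) + 1L]] <- data.frame(
        inhibitor = inh, response = resp,
        baseline = base$integrated[[resp]],
        treated = treat$integrated[[resp]],
        reduction_pct = percent_reduction(base, treat, resp),
        significant = outside_band(band, treat$integrated[[resp]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
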