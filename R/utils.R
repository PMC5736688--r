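# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Avogadro constant (1/mol)
#' @keywords internal
AVOGADRO <- 6.02214076e23

# Weak but stable content digest used to label outputs with the generating
# inputs. Not cryptographic; only needs to distinguish parameterizations.
content_digest <- function(x) {
  b <- as.double(serialize(x, NULL, version = 2))
  i <- seq_along(b)
  s1 <- sum(b * ((i %% 97) + 1)) %% 4294967291
  s2 <- sum(b * ((i %% 89) + 7)) %% 4294967279
  sprintf("%.0f-%.0f", s1, s2)
}

# trapezoid rule on an arbitrary grid
auc_trapezoid <- function(times, values) {
  stopifnot(length(times) == length(values), length(times) >= 2)
  sum(diff(times) * (values[-length(values)] + values[-1]) / 2)
}

# format numerics for CSV so that read.csv round-trips them exactly
fmt_full <- function(x) {
  if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
}

stop_user <- function(...) {
  stop(structure(class = c("vegfrsim_user_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
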