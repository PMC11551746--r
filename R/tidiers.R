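#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy strand-exchange fit results
#'
#' `tidy()` returns one row per estimated parameter with columns `term`,
#' `estimate`, `std.error` and `unit`; `glance()` returns a one-row fit
#' summary.
#'
#' @param x A fitted object (`exchange_fit`, `hill_fit`, `assoc_fit`,
#'   `dissoc_fit` or `model_comparison`).
#' @param ... Unused.
#' @return A tibble.
#' @name strandex-tidiers
NULL

rate_units <- function(rates) {
  scheme <- as_reaction_scheme(attr(rates, "scheme"))
  ifelse(scheme$bimolecular[names(rates)], "nM^-1 s^-1", "s^-1")
}

#' @rdname strandex-tidiers
#' @method tidy exchange_fit
#' @export
tidy.exchange_fit <- function(x, ...) {
  eq <- x$equilibrium
  eq_units <- if (ncol(eq) == 4) c("nM^-1", "", "nM", "") else c("nM^-1", "nM", "")
  bind_rows(
    tibble(term = names(x$rates), estimate = as.numeric(x$rates),
           std.error = unname(x$se), unit = unname(rate_units(x$rates))),
    tibble(term = names(eq), estimate = as.numeric(eq[1, ]),
           std.error = NA_real_, unit = eq_units)
  )
}

#' @rdname strandex-tidiers
#' @method glance exchange_fit
#' @export
glance.exchange_fit <- function(x, ...) {
  m <- length(x$residuals); p <- length(x$rates)
  tibble(ssr = x$ssr, n = m, n_parameters = p,
         aic = m * log(x$ssr / m) + 2 * p,
         runs_p = runs_test(x$residuals)$p.value,
         converged = x$converged, n_evaluations = x$n_evaluations)
}

#' @rdname strandex-tidiers
#' @method tidy hill_fit
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(term = c("K_D", "n", "baseline", "amplitude"),
         estimate = c(x$K_D, x$n, x$baseline, x$amplitude),
         std.error = unname(x$se[c("K_D", "n", "baseline", "amplitude")]),
         unit = c("uM", "", "anisotropy", "anisotropy"))
}

#' @rdname strandex-tidiers
#' @method glance hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(ssr = x$ssr, n = nrow(x$data), converged = x$converged)
}

#' @rdname strandex-tidiers
#' @method tidy assoc_fit
#' @export
tidy.assoc_fit <- function(x, ...) {
  tibble(term = c("V_N", "V_E", "T_half", "baseline", "amplitude", "n"),
         estimate = c(x$V_N, x$V_E, x$T_half, x$baseline, x$amplitude, x$n),
         std.error = c(NA_real_, NA_real_,
                       unname(x$se[c("T_half", "baseline", "amplitude", "n")])),
         unit = c("anisotropy s^-1", "anisotropy s^-1", "s",
                  "anisotropy", "anisotropy", ""))
}

#' @rdname strandex-tidiers
#' @method glance assoc_fit
#' @export
glance.assoc_fit <- function(x, ...) {
  tibble(ssr = x$ssr, n = nrow(x$data),
         nucleation_window = x$nucleation_window,
         ve_halfwidth = x$ve_halfwidth)
}

#' @rdname strandex-tidiers
#' @method tidy dissoc_fit
#' @export
tidy.dissoc_fit <- function(x, ...) {
  tibble(term = c("k_off", "amplitude", "baseline"),
         estimate = c(x$k_off, x$amplitude, x$baseline),
         std.error = unname(x$se[c("k_off", "amplitude", "baseline")]),
         unit = c("s^-1", "anisotropy", "anisotropy"))
}

#' @rdname strandex-tidiers
#' @method glance dissoc_fit
#' @export
glance.dissoc_fit <- function(x, ...) {
  tibble(ssr = x$ssr, n = nrow(x$data), converged = x$converged)
}

#' @rdname strandex-tidiers
#' @method tidy model_comparison
#' @export
tidy.model_comparison <- function(x, ...) {
  tibble(scheme = names(x$aic), ssr = unname(x$ssr), aic = unname(x$aic),
         runs_p = unname(x$runs_p), selected = names(x$aic) == x$selected)
}

#' @rdname strandex-tidiers
#' @method glance model_comparison
#' @export
glance.model_comparison <- function(x, ...) {
  tibble(selected = x$selected, n = x$m,
         delta_aic = abs(diff(unname(x$aic))))
}
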