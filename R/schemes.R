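#' Reaction schemes for DNA strand exchange
#'
#' The three-step scheme treats strand exchange as
#' A + B <-> C1 <-> C2 <-> D + E, where A is the presynaptic filament
#' (one kinetic species regardless of ssDNA length), B the donor dsDNA,
#' C1 and C2 two topologically distinct three-stranded intermediates, D the
#' heteroduplex product and E the displaced donor strand.  The two-step
#' alternative collapses C1 and C2 into a single intermediate.
#'
#' @param name `"three_step"` or `"two_step"`.
#' @return A `reaction_scheme` object: a list with the scheme name, the
#'   species it tracks and the names of its rate constants.
#' @examples
#' reaction_scheme("three_step")
#' @export
reaction_scheme <- function(name = c("three_step", "two_step")) {
  name <- match.arg(name)
  if (name == "three_step") {
    out <- list(
      name = name,
      species = c("A", "B", "C1", "C2", "D", "E"),
      rate_names = c("k1", "k_m1", "k2", "k_m2", "k3", "k_m3"),
      # TRUE where the rate is bimolecular (nM^-1 s^-1)
      bimolecular = c(k1 = TRUE, k_m1 = FALSE, k2 = FALSE,
                      k_m2 = FALSE, k3 = FALSE, k_m3 = TRUE)
    )
  } else {
    out <- list(
      name = name,
      species = c("A", "B", "C1", "D", "E"),
      rate_names = c("k1", "k_m1", "k2", "k_m2"),
      bimolecular = c(k1 = TRUE, k_m1 = FALSE, k2 = FALSE, k_m2 = TRUE)
    )
  }
  structure(out, class = "reaction_scheme")
}

as_reaction_scheme <- function(scheme) {
  if (inherits(scheme, "reaction_scheme")) return(scheme)
  reaction_scheme(scheme)
}

#' @export
print.reaction_scheme <- function(x, ...) {
  arrows <- if (x$name == "three_step") {
    "A + B <-> C1 <-> C2 <-> D + E"
  } else {
    "A + B <-> C1 <-> D + E"
  }
  cat("<reaction_scheme> ", x$name, ": ", arrows, "\n", sep = "")
  cat("rate constants:", paste(x$rate_names, collapse = ", "), "\n")
  invisible(x)
}

#' Rate constants of a strand-exchange scheme
#'
#' Bimolecular constants (`k1`, and `k_m3` in the three-step scheme or `k_m2`
#' in the two-step scheme) are in nM^-1 s^-1; all others are first-order
#' (s^-1).  All must be finite and non-negative.
#'
#' @param k1,k_m1,k2,k_m2 Forward/reverse constants of steps 1 and 2.
#' @param k3,k_m3 Forward/reverse constants of step 3 (three-step scheme
#'   only; leave `NULL` for two-step).
#' @param scheme Scheme name or [reaction_scheme()] object.
#' @return A named numeric vector of class `rate_constants` with a
#'   `scheme` attribute.
#' @examples
#' rate_constants(1e-3, 1e-2, 5e-3, 1e-3, 2e-3, 1e-4)
#' @export
rate_constants <- function(k1, k_m1, k2, k_m2, k3 = NULL, k_m3 = NULL,
                           scheme = if (is.null(k3)) "two_step" else "three_step") {
  scheme <- as_reaction_scheme(scheme)
  vals <- if (scheme$name == "three_step") {
    if (is.null(k3) || is.null(k_m3)) {
      abort("three_step scheme needs all six rate constants", class = "strandex_invalid_parameter")
    }
    c(k1 = unname(k1), k_m1 = unname(k_m1), k2 = unname(k2),
      k_m2 = unname(k_m2), k3 = unname(k3), k_m3 = unname(k_m3))
  } else {
    if (!is.null(k3) || !is.null(k_m3)) {
      abort("two_step scheme takes only four rate constants", class = "strandex_invalid_parameter")
    }
    c(k1 = unname(k1), k_m1 = unname(k_m1), k2 = unname(k2), k_m2 = unname(k_m2))
  }
  validate_rates(vals, scheme)
  structure(vals, scheme = scheme$name, class = "rate_constants")
}

validate_rates <- function(vals, scheme) {
  scheme <- as_reaction_scheme(scheme)
  if (length(vals) != length(scheme$rate_names)) {
    abort(sprintf("%s scheme needs %d rate constants, got %d",
                  scheme$name, length(scheme$rate_names), length(vals)),
          class = "strandex_invalid_parameter")
  }
  if (anyNA(vals) || any(!is.finite(vals)) || any(vals < 0)) {
    abort("rate constants must be finite and >= 0",
          class = "strandex_invalid_parameter")
  }
  invisible(vals)
}

as_rate_constants <- function(rates, scheme = NULL) {
  if (inherits(rates, "rate_constants")) return(rates)
  scheme <- as_reaction_scheme(scheme %||% if (length(rates) == 6) "three_step" else "two_step")
  rates <- unlist(rates)
  if (is.null(names(rates)) || !all(scheme$rate_names %in% names(rates))) {
    names(rates) <- scheme$rate_names
  }
  vals <- rates[scheme$rate_names]
  validate_rates(vals, scheme)
  structure(vals, scheme = scheme$name, class = "rate_constants")
}

#' Initial reaction state
#'
#' Concentrations in nM.  In the two-step scheme `C2` must stay 0 and the
#' single intermediate is carried as `C1`.
#'
#' @param A Presynaptic filament (nM).
#' @param B Donor dsDNA (nM).
#' @param C1,C2 Intermediates (nM).
#' @param D Heteroduplex product (nM).
#' @param E Displaced donor strand (nM).
#' @param scheme Scheme name or object.
#' @return Named numeric vector over the scheme's species.
#' @export
reaction_state <- function(A, B, C1 = 0, C2 = 0, D = 0, E = 0,
                           scheme = "three_step") {
  scheme <- as_reaction_scheme(scheme)
  full <- c(A = A, B = B, C1 = C1, C2 = C2, D = D, E = E)
  if (scheme$name == "two_step" && C2 != 0) {
    abort("two_step scheme has no C2 species", class = "strandex_invalid_parameter")
  }
  state <- full[scheme$species]
  if (anyNA(state) || any(!is.finite(state)) || any(state < 0)) {
    abort("concentrations must be finite and >= 0", class = "strandex_invalid_parameter")
  }
  state
}

#' Mass-action derivatives of a strand-exchange state
#'
#' Instantaneous rates of change (nM/s) of each species under mass action.
#' For the three-step scheme the fluxes are v1 = k1*A*B - k_m1*C1,
#' v2 = k2*C1 - k_m2*C2, v3 = k3*C2 - k_m3*D*E; step 3 reverse is treated as
#' bimolecular (D + E -> C2) so K3 = k3/k_m3 carries units of nM.
#'
#' @param rates [rate_constants()].
#' @param state Named state vector as from [reaction_state()].
#' @param scheme Scheme name or object; defaults to the scheme of `rates`.
#' @return Named numeric vector of derivatives, one per species.
#' @examples
#' r <- rate_constants(1e-3, 0, 0, 0, 0, 0)
#' mass_action_derivatives(r, reaction_state(36, 36))
#' @export
mass_action_derivatives <- function(rates, state, scheme = NULL) {
  scheme <- as_reaction_scheme(scheme %||% attr(rates, "scheme") %||% "three_step")
  rates <- as_rate_constants(rates, scheme)
  state <- state[scheme$species]
  if (anyNA(state)) abort("state is missing species", class = "strandex_invalid_parameter")
  if (scheme$name == "three_step") {
    v1 <- rates[["k1"]] * state[["A"]] * state[["B"]] - rates[["k_m1"]] * state[["C1"]]
    v2 <- rates[["k2"]] * state[["C1"]] - rates[["k_m2"]] * state[["C2"]]
    v3 <- rates[["k3"]] * state[["C2"]] - rates[["k_m3"]] * state[["D"]] * state[["E"]]
    c(A = -v1, B = -v1, C1 = v1 - v2, C2 = v2 - v3, D = v3, E = v3)
  } else {
    v1 <- rates[["k1"]] * state[["A"]] * state[["B"]] - rates[["k_m1"]] * state[["C1"]]
    v2 <- rates[["k2"]] * state[["C1"]] - rates[["k_m2"]] * state[["D"]] * state[["E"]]
    c(A = -v1, B = -v1, C1 = v1 - v2, D = v2, E = v2)
  }
}

#' Stepwise and total equilibrium constants
#'
#' K1 = k1/k_m1 (nM^-1), K2 = k2/k_m2 (dimensionless), K3 = k3/k_m3 (nM) and
#' K_total = K1 * K2 * K3 for the three-step scheme.  For the two-step scheme
#' K1 = k1/k_m1, K2 = k2/k_m2 (nM) and K_total = K1 * K2.
#'
#' @param rates [rate_constants()].
#' @return One-row tibble with columns `K1`, `K2`, (`K3`,) `K_total`.
#' @examples
#' equilibrium_constants(rate_constants(1e-3, 1e-2, 5e-3, 1e-3, 2e-3, 1e-4))
#' @export
equilibrium_constants <- function(rates) {
  rates <- as_rate_constants(rates)
  scheme <- as_reaction_scheme(attr(rates, "scheme"))
  rev_names <- grep("^k_m", scheme$rate_names, value = TRUE)
  if (any(rates[rev_names] == 0)) {
    abort("equilibrium constants undefined: a reverse rate is zero",
          class = "strandex_undefined_equilibrium")
  }
  if (scheme$name == "three_step") {
    K1 <- rates[["k1"]] / rates[["k_m1"]]
    K2 <- rates[["k2"]] / rates[["k_m2"]]
    K3 <- rates[["k3"]] / rates[["k_m3"]]
    tibble(K1 = K1, K2 = K2, K3 = K3, K_total = K1 * K2 * K3)
  } else {
    K1 <- rates[["k1"]] / rates[["k_m1"]]
    K2 <- rates[["k2"]] / rates[["k_m2"]]
    tibble(K1 = K1, K2 = K2, K_total = K1 * K2)
  }
}

#' Fold change in equilibrium constants between two conditions
#'
#' Componentwise ratio of equilibrium constants measured with a cofactor or
#' mediator present over a baseline condition (e.g. with/without Swi5-Sfr1),
#' the conventional way of expressing a mediator's effect on each reaction
#' step.
#'
#' @param with_factor,baseline One-row tibbles (or named vectors/lists) of
#'   equilibrium constants as returned by [equilibrium_constants()].
#' @return One-row tibble of fold ratios for each shared constant.
#' @export
relative_equilibrium_change <- function(with_factor, baseline) {
  wf <- unlist(with_factor)
  bl <- unlist(baseline)
  keys <- intersect(names(wf), names(bl))
  if (length(keys) == 0) abort("no shared equilibrium constants to compare")
  if (any(!is.finite(bl[keys])) || any(bl[keys] <= 0)) {
    abort("baseline equilibrium constants must be positive",
          class = "strandex_division_error")
  }
  as_tibble(as.list(wf[keys] / bl[keys]))
}
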