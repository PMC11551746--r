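#' Simulate a strand-exchange time course
#'
#' Integrates the mass-action ODE system of the chosen scheme with a
#' stiff-capable solver ([deSolve::lsoda()] driving a compiled
#' right-hand side).  Concentrations are in nM, time in seconds.  Small
#' negative excursions below the absolute solver tolerance are clamped to 0.
#'
#' @param rates [rate_constants()].
#' @param state0 Initial state from [reaction_state()] (defaults to 36 nM
#'   filament and donor dsDNA, the standard assay condition).
#' @param times Strictly increasing sample times (s) starting at 0.
#' @param rtol,atol Relative/absolute solver tolerances.
#' @return A tibble of class `exchange_trajectory` with a `time_s` column and
#'   one column per species, plus attributes `rates`, `scheme`, `A0`, `B0`
#'   and `initial_state`.
#' @examples
#' r <- rate_constants(2e-4, 2e-3, 5e-3, 2e-3, 1e-3, 5e-5)
#' traj <- simulate_exchange(r, times = seq(0, 100, by = 10))
#' @export
simulate_exchange <- function(rates, state0 = NULL, times = seq(0, 1000, by = 5),
                              rtol = 1e-8, atol = 1e-10) {
  rates <- as_rate_constants(rates)
  scheme <- as_reaction_scheme(attr(rates, "scheme"))
  if (is.null(state0)) state0 <- reaction_state(36, 36, scheme = scheme)
  state0 <- state0[scheme$species]
  if (anyNA(state0) || any(state0 < 0)) {
    abort("initial state must cover all species with non-negative values",
          class = "strandex_invalid_parameter")
  }
  if (length(times) < 2 || any(diff(times) <= 0) || times[1] != 0) {
    abort("times must be strictly increasing and start at 0",
          class = "strandex_invalid_parameter")
  }
  if (scheme$name == "three_step") {
    func <- "strandex_deriv3"; initfunc <- "strandex_init3"
  } else {
    func <- "strandex_deriv2"; initfunc <- "strandex_init2"
  }
  sol <- try(deSolve::lsoda(
    y = unname(state0), times = times, func = func,
    parms = unname(rates), dllname = "strandex", initfunc = initfunc,
    rtol = rtol, atol = atol
  ), silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(times) ||
      anyNA(sol[, -1])) {
    abort(sprintf(
      "ODE integration failed for rates [%s]",
      paste(sprintf("%s=%.3g", names(rates), rates), collapse = ", ")),
      class = "strandex_integration_failure")
  }
  conc <- sol[, -1, drop = FALSE]
  # clamp sub-tolerance negative excursions
  conc[conc < 0 & conc > -atol * 10] <- 0
  colnames(conc) <- scheme$species
  out <- as_tibble(cbind(data.frame(time_s = sol[, 1]), conc))
  structure(out,
            rates = rates, scheme = scheme$name,
            A0 = unname(state0[["A"]]), B0 = unname(state0[["B"]]),
            initial_state = state0,
            class = c("exchange_trajectory", class(out)))
}

#' Algebraic equilibrium of a strand-exchange scheme
#'
#' Solves the mass-action equilibrium directly, without integration.  The
#' reversible chain has no cycles, so at equilibrium every step is
#' individually balanced; the state is parameterised by free filament
#' concentration and the single conservation residual is solved with
#' [stats::uniroot()].  Used as an independent check that long-time
#' simulations relax to the true equilibrium.
#'
#' @param rates [rate_constants()]; all reverse rates must be positive.
#' @param state0 Initial state (sets the conserved totals).
#' @param tol Root-finding tolerance on the conservation residual (nM).
#' @return One-row tibble with the equilibrium concentrations (nM).
#' @export
algebraic_equilibrium <- function(rates, state0 = NULL, tol = 1e-12) {
  rates <- as_rate_constants(rates)
  scheme <- as_reaction_scheme(attr(rates, "scheme"))
  if (is.null(state0)) state0 <- reaction_state(36, 36, scheme = scheme)
  state0 <- state0[scheme$species]
  rev_names <- grep("^k_m", scheme$rate_names, value = TRUE)
  if (any(rates[rev_names] == 0)) {
    abort("algebraic equilibrium needs positive reverse rates",
          class = "strandex_undefined_equilibrium")
  }
  three <- scheme$name == "three_step"
  K1 <- rates[["k1"]] / rates[["k_m1"]]
  K2 <- rates[["k2"]] / rates[["k_m2"]]
  K3 <- if (three) rates[["k3"]] / rates[["k_m3"]] else NA_real_
  # conserved totals: filament strand, donor complementary strand, E - D
  inter <- if (three) state0[["C1"]] + state0[["C2"]] else state0[["C1"]]
  TA <- state0[["A"]] + inter + state0[["D"]]
  TB <- state0[["B"]] + inter + state0[["D"]]
  delta <- state0[["E"]] - state0[["D"]]

  state_at <- function(a) {
    b <- TB - TA + a
    C1 <- K1 * a * b
    if (three) {
      C2 <- K2 * C1
      DE <- K3 * C2        # D * E at equilibrium
    } else {
      C2 <- 0
      DE <- K2 * C1
    }
    D <- if (DE <= 0) 0 else (-delta + sqrt(delta^2 + 4 * DE)) / 2
    c(A = a, B = b, C1 = C1, C2 = C2, D = D, E = D + delta)
  }
  resid <- function(a) {
    s <- state_at(a)
    s[["A"]] + s[["C1"]] + s[["C2"]] + s[["D"]] - TA
  }
  lo <- max(0, TA - TB)
  if (resid(lo) > 0 || resid(TA) < 0) {
    abort("no positive equilibrium root found", class = "strandex_numerical_error")
  }
  a <- uniroot(resid, c(lo, TA), tol = tol)$root
  s <- state_at(a)
  if (!three) s <- s[c("A", "B", "C1", "D", "E")]
  as_tibble(as.list(s))
}

#' @export
print.exchange_trajectory <- function(x, ...) {
  cat(sprintf("<exchange_trajectory> %s scheme, A0 = %g nM, B0 = %g nM, %d time points\n",
              attr(x, "scheme"), attr(x, "A0"), attr(x, "B0"), nrow(x)))
  NextMethod()
}
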