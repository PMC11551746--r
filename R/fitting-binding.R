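# Levenberg-Marquardt wrapper shared by the closed-form model fits.
# Returns estimates, standard errors from the Jacobian-based covariance at
# the optimum, fitted values and residuals.
lm_least_squares <- function(par0, residual_fn, lower = NULL, upper = NULL,
                             maxiter = 1000) {
  p <- length(par0)
  fit <- minpack.lm::nls.lm(
    par = par0, fn = residual_fn,
    lower = lower %||% rep(-Inf, p), upper = upper %||% rep(Inf, p),
    control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                         ftol = 1e-15, ptol = 1e-15)
  )
  res <- fit$fvec
  m <- length(res)
  ssr <- sum(res^2)
  se <- rep(NA_real_, p)
  if (m > p) {
    cov <- try(chol2inv(chol(fit$hessian)) * ssr / (m - p), silent = TRUE)
    if (!inherits(cov, "try-error")) se <- sqrt(pmax(diag(cov), 0))
  }
  names(se) <- names(fit$par)
  list(par = fit$par, se = se, ssr = ssr, residuals = res,
       converged = fit$info %in% 1:4, niter = fit$niter, info = fit$info)
}

#' Hill binding curve
#'
#' Steady-state anisotropy as a function of recombinase concentration:
#' `baseline + amplitude * conc^n / (K_D^n + conc^n)`.  Total recombinase is
#' treated as free ligand (no depletion correction).
#'
#' @param conc Recombinase concentration (uM).
#' @param baseline Minimum anisotropy.
#' @param amplitude Amplitude of the anisotropy change.
#' @param K_D Dissociation constant (uM).
#' @param n Hill coefficient.
#' @return Anisotropy values.
#' @export
hill_curve <- function(conc, baseline, amplitude, K_D, n) {
  baseline + amplitude * conc^n / (K_D^n + conc^n)
}

#' Fit the Hill equation to a steady-state binding titration
#'
#' Nonlinear least squares for (baseline, amplitude, K_D, n) on an
#' anisotropy-vs-concentration titration; K_D and n are searched in log
#' space to keep them positive.  At `conc = K_D` the fitted curve passes
#' through `baseline + amplitude / 2`.
#'
#' @param data Data frame with columns `concentration_uM` and `anisotropy`
#'   (at least 5 points spanning the transition).
#' @return A `hill_fit` object; see [generics::tidy()] and
#'   [generics::glance()] methods.
#' @examples
#' d <- generate_titration(K_D = 1.0, n = 1, noise = noise_model(sd = 0))
#' fit_hill(d)
#' @export
fit_hill <- function(data) {
  conc <- data$concentration_uM
  y <- data$anisotropy
  if (length(conc) < 5) {
    abort("need at least 5 titration points", class = "strandex_invalid_input")
  }
  if (any(conc <= 0)) abort("concentrations must be > 0", class = "strandex_invalid_input")
  b0 <- min(y); a0 <- max(y) - min(y)
  if (a0 <= 0) a0 <- max(abs(y)) * 0.1 + 1e-6
  kd0 <- conc[which.min(abs(y - (b0 + a0 / 2)))]
  par0 <- c(baseline = b0, amplitude = a0, logK = log(kd0), logn = 0)
  fn <- function(p) {
    hill_curve(conc, p[["baseline"]], p[["amplitude"]],
               exp(p[["logK"]]), exp(p[["logn"]])) - y
  }
  fit <- lm_least_squares(par0, fn)
  if (!fit$converged) {
    abort("Hill fit did not converge", class = "strandex_fit_failure")
  }
  K_D <- exp(fit$par[["logK"]]); n <- exp(fit$par[["logn"]])
  se <- c(baseline = fit$se[["baseline"]], amplitude = fit$se[["amplitude"]],
          K_D = K_D * fit$se[["logK"]], n = n * fit$se[["logn"]])
  if (K_D < min(conc) || K_D > max(conc)) {
    warn("fitted K_D outside the sampled concentration range (extrapolation)",
         class = "strandex_extrapolation_warning")
  }
  structure(list(
    K_D = K_D, n = n,
    baseline = fit$par[["baseline"]], amplitude = fit$par[["amplitude"]],
    se = se, ssr = fit$ssr, residuals = fit$residuals,
    fitted = y + fit$residuals,
    converged = fit$converged, data = as_tibble(data)
  ), class = "hill_fit")
}

#' Sigmoid filament-association curve
#'
#' Anisotropy during filament assembly:
#' `baseline + amplitude * t^n / (T_half^n + t^n)`, where `T_half` is the
#' half-occupancy time.
#'
#' @param t Time (s).
#' @param baseline Minimum anisotropy.
#' @param amplitude Amplitude of the anisotropy change.
#' @param T_half Half-occupancy time (s).
#' @param n Sigmoid steepness exponent.
#' @export
association_curve <- function(t, baseline, amplitude, T_half, n) {
  baseline + amplitude * t^n / (T_half^n + t^n)
}

#' Nucleation and elongation kinetics of filament association
#'
#' From a real-time anisotropy association trace: the nucleation velocity
#' `V_N` is the ordinary least-squares slope over the first
#' `nucleation_window` seconds after protein injection (10 s for Dmc1, 5 s
#' for Rad51); `T_half` comes from a sigmoid fit of the full trace; and the
#' elongation velocity `V_E` is the least-squares slope over all samples
#' with `t` in `[T_half - ve_halfwidth, T_half + ve_halfwidth]` (9 samples
#' at 0.5 s sampling with the default 2 s half-width).
#'
#' @param data Data frame with columns `time_s` and `anisotropy`, sampled at
#'   2 Hz or faster over the sigmoid rise.
#' @param nucleation_window Seconds after injection used for `V_N`.
#' @param ve_halfwidth Half-width (s) of the window around `T_half` for `V_E`.
#' @return An `assoc_fit` object with `V_N`, `V_E`, `T_half` and the sigmoid
#'   parameters.  If the sigmoid fit fails or `T_half` falls outside the
#'   observed times (e.g. on a purely linear rise), `T_half` and `V_E` are
#'   `NA` with a warning and `V_N` is still returned.
#' @export
association_kinetics <- function(data, nucleation_window = 10, ve_halfwidth = 2) {
  t <- data$time_s; y <- data$anisotropy
  idx <- t <= nucleation_window + 1e-9
  if (sum(idx) < 2) abort("too few points in the nucleation window",
                          class = "strandex_invalid_input")
  vn_fit <- lm(y[idx] ~ t[idx])
  V_N <- unname(coef(vn_fit)[2])

  b0 <- min(y); a0 <- max(y) - min(y)
  th0 <- t[which.min(abs(y - (b0 + a0 / 2)))]
  if (!is.finite(th0) || th0 <= 0) th0 <- max(t) / 4
  par0 <- c(baseline = b0, amplitude = max(a0, 1e-6),
            logT = log(th0), logn = log(2))
  fn <- function(p) {
    association_curve(t, p[["baseline"]], p[["amplitude"]],
                      exp(p[["logT"]]), exp(p[["logn"]])) - y
  }
  fit <- try(lm_least_squares(par0, fn), silent = TRUE)
  sigmoid_ok <- !inherits(fit, "try-error") && fit$converged
  T_half <- if (sigmoid_ok) exp(fit$par[["logT"]]) else NA_real_
  if (!sigmoid_ok || T_half > max(t) || T_half < min(t[t > 0])) {
    warn("T_half outside the observed time range; V_E not estimated",
         class = "strandex_thalf_warning")
    V_E <- NA_real_
    if (!sigmoid_ok) T_half <- NA_real_
  } else {
    widx <- abs(t - T_half) <= ve_halfwidth + 1e-9
    if (sum(widx) < 3) {
      abort("too few points in the elongation-velocity window",
            class = "strandex_invalid_input")
    }
    V_E <- unname(coef(lm(y[widx] ~ t[widx]))[2])
  }
  pars <- if (sigmoid_ok) fit$par else par0 * NA
  se <- if (sigmoid_ok) {
    c(baseline = fit$se[["baseline"]], amplitude = fit$se[["amplitude"]],
      T_half = T_half * fit$se[["logT"]],
      n = exp(fit$par[["logn"]]) * fit$se[["logn"]])
  } else c(baseline = NA_real_, amplitude = NA_real_,
           T_half = NA_real_, n = NA_real_)
  structure(list(
    V_N = V_N, V_E = V_E, T_half = T_half,
    baseline = unname(pars[["baseline"]]), amplitude = unname(pars[["amplitude"]]),
    n = if (sigmoid_ok) exp(pars[["logn"]]) else NA_real_,
    se = se, ssr = if (sigmoid_ok) fit$ssr else NA_real_,
    nucleation_window = nucleation_window, ve_halfwidth = ve_halfwidth,
    data = as_tibble(data)
  ), class = "assoc_fit")
}

#' Fit a single-exponential filament dissociation decay
#'
#' Least-squares fit of `amplitude * exp(-k_off * t) + baseline` to a
#' decaying anisotropy trace; `k_off` is bounded below by 0.  The value at
#' `t = 0` equals `amplitude + baseline`.
#'
#' @param data Data frame with columns `time_s` and `anisotropy`.
#' @return A `dissoc_fit` object with `k_off` (1/s), `amplitude`, `baseline`
#'   and standard errors.  Non-decaying input yields `k_off` near 0 with a
#'   warning.
#' @export
fit_dissociation <- function(data) {
  t <- data$time_s; y <- data$anisotropy
  if (length(t) < 4) abort("too few points", class = "strandex_invalid_input")
  if (sd(y) == 0) {
    warn("constant trace: no decay to fit", class = "strandex_nondecay_warning")
    return(structure(list(
      k_off = 0, amplitude = 0, baseline = mean(y),
      se = c(baseline = NA_real_, amplitude = NA_real_, k_off = NA_real_),
      ssr = 0, residuals = rep(0, length(y)), converged = TRUE,
      data = as_tibble(data)
    ), class = "dissoc_fit"))
  }
  ntail <- max(5L, length(y) %/% 20L)
  b0 <- mean(tail(y, ntail))
  a0 <- y[1] - b0
  decaying <- a0 > 0 && unname(coef(lm(y ~ t))[2]) < 0
  half <- t[which.min(abs((y - b0) - a0 / 2))]
  k0 <- if (is.finite(half) && half > 0) log(2) / half else 1 / max(t)
  par0 <- c(baseline = b0, amplitude = a0, k_off = max(k0, 1e-8))
  fn <- function(p) p[["amplitude"]] * exp(-p[["k_off"]] * t) + p[["baseline"]] - y
  fit <- lm_least_squares(par0, fn, lower = c(-Inf, -Inf, 0))
  if (!fit$converged) abort("dissociation fit did not converge",
                            class = "strandex_fit_failure")
  if (!decaying || fit$par[["k_off"]] < 1e-10) {
    warn("trace is not decaying: k_off is approximately 0",
         class = "strandex_nondecay_warning")
  }
  structure(list(
    k_off = unname(fit$par[["k_off"]]),
    amplitude = unname(fit$par[["amplitude"]]),
    baseline = unname(fit$par[["baseline"]]),
    se = c(baseline = fit$se[["baseline"]], amplitude = fit$se[["amplitude"]],
           k_off = fit$se[["k_off"]]),
    ssr = fit$ssr, residuals = fit$residuals, converged = fit$converged,
    data = as_tibble(data)
  ), class = "dissoc_fit")
}

#' Recombinase concentration needed to saturate an ssDNA substrate
#'
#' One recombinase monomer covers `nt_per_monomer` nucleotides (3 for
#' RecA-family filaments), so saturating `fragment_conc` nM of a
#' `length_nt`-mer requires `length_nt * fragment_conc / nt_per_monomer` of
#' protein; `excess` scales this (2 for the standard condition of twice the
#' saturating amount).
#'
#' @param length_nt ssDNA length (nucleotides).
#' @param fragment_conc Fragment concentration (nM).
#' @param nt_per_monomer Nucleotides covered per monomer.
#' @param excess Fold excess over saturation.
#' @return Protein concentration in uM.
#' @examples
#' stoichiometric_concentration(83, 36, excess = 2) # ~2 uM
#' @export
stoichiometric_concentration <- function(length_nt, fragment_conc,
                                         nt_per_monomer = 3, excess = 1) {
  stopifnot(length_nt > 0, fragment_conc > 0, nt_per_monomer > 0, excess > 0)
  excess * length_nt * fragment_conc / nt_per_monomer / 1000
}

#' Protein concentration from A280 by Beer-Lambert
#'
#' @param a280 Absorbance at 280 nm.
#' @param epsilon Molar extinction coefficient (1/M/cm), e.g. 1.23e4 for
#'   Dmc1, 1.44e4 for Swi5-Sfr1, 1.86e4 for Rad51.
#' @param path_cm Path length (cm).
#' @return Concentration in M.
#' @export
concentration_from_absorbance <- function(a280, epsilon, path_cm = 1) {
  if (!is.finite(epsilon) || epsilon <= 0) {
    abort("epsilon must be > 0", class = "strandex_invalid_parameter")
  }
  a280 / (epsilon * path_cm)
}

#' Mean and standard deviation over replicate estimates
#'
#' @param x Numeric vector of per-replicate estimates (length >= 2).
#' @return One-row tibble with `mean`, `sd` (n-1 denominator) and `n`.
#' @export
aggregate_replicates <- function(x) {
  if (length(x) < 2) abort("need at least 2 replicates", class = "strandex_invalid_input")
  tibble(mean = mean(x), sd = sd(x), n = length(x))
}
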