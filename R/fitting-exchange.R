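#' Configuration for rate-constant fitting
#'
#' Rate constants are searched in log10 space under box bounds.  The search
#' is global-then-local: a seeded log-uniform screen of `n_screen` candidate
#' parameter sets is ranked by residual sum of squares, Levenberg-Marquardt
#' refinement runs from the best `n_starts`, and `n_hops` basin hops
#' (LM restarts from the incumbent jittered by up to 0.6 decades) polish the
#' result.  Default bounds are 1e-7 to 1e-1 nM^-1 s^-1 for bimolecular
#' constants and 1e-6 to 1 s^-1 for unimolecular ones.  All draws come from
#' `seed`, so fits are reproducible.
#'
#' @param scheme `"three_step"` or `"two_step"`.
#' @param n_starts Number of LM multistarts (>= 1).
#' @param seed Seed for the screen, start and hop draws.
#' @param n_screen Size of the screening sample.
#' @param n_hops Number of basin hops after the multistart.
#' @param lower,upper Optional named per-parameter bounds (linear scale);
#'   defaults depend on molecularity.
#' @param rtol,atol ODE solver tolerances passed to [simulate_exchange()].
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @return A `fit_config` list.
#' @export
fit_config <- function(scheme = "three_step", n_starts = 8, seed = 1,
                       n_screen = 250, n_hops = 10,
                       lower = NULL, upper = NULL,
                       rtol = 1e-8, atol = 1e-10, maxiter = 200) {
  scheme <- as_reaction_scheme(scheme)
  if (n_starts < 1) abort("n_starts must be >= 1", class = "strandex_invalid_parameter")
  bim <- scheme$bimolecular
  def_lower <- ifelse(bim, 1e-7, 1e-6)
  def_upper <- ifelse(bim, 1e-1, 1)
  names(def_lower) <- names(def_upper) <- scheme$rate_names
  if (!is.null(lower)) def_lower[names(lower)] <- unlist(lower)
  if (!is.null(upper)) def_upper[names(upper)] <- unlist(upper)
  if (any(def_lower >= def_upper) || any(def_lower <= 0)) {
    abort("bounds must satisfy 0 < lower < upper", class = "strandex_invalid_parameter")
  }
  structure(list(scheme = scheme, n_starts = as.integer(n_starts),
                 seed = as.integer(seed),
                 n_screen = as.integer(max(n_screen, n_starts)),
                 n_hops = as.integer(n_hops),
                 lower = def_lower, upper = def_upper,
                 rtol = rtol, atol = atol, maxiter = maxiter),
            class = "fit_config")
}

# residual closure for one time course under one scheme
exchange_residual_fn <- function(data, config) {
  scheme <- config$scheme
  assay <- attr(data, "assay") %||% "pairing"
  A0 <- attr(data, "A0") %||% 36
  B0 <- attr(data, "B0") %||% 36
  t_data <- data$time_s
  y <- data$value
  sim_times <- if (t_data[1] == 0) t_data else c(0, t_data)
  keep <- if (t_data[1] == 0) seq_along(sim_times) else -1L
  state0 <- reaction_state(A0, B0, scheme = scheme)
  function(logk) {
    traj <- try(simulate_exchange(
      as_rate_constants(10^logk, scheme), state0, sim_times,
      rtol = config$rtol, atol = config$atol), silent = TRUE)
    if (inherits(traj, "try-error")) return(rep(1e4, length(y)))
    trajectory_to_percent(traj, assay)$percent[keep] - y
  }
}

lm_from <- function(fn, start, config) {
  llo <- log10(config$lower); lhi <- log10(config$upper)
  minpack.lm::nls.lm(
    par = pmin(pmax(start, llo), lhi), fn = fn, lower = llo, upper = lhi,
    control = minpack.lm::nls.lm.control(maxiter = config$maxiter,
                                         ftol = 1e-12, ptol = 1e-12))
}

# screen -> multistart -> basin hops; returns the best nls.lm object and the
# total number of LM iterations spent
run_search <- function(fn, config) {
  llo <- log10(config$lower); lhi <- log10(config$upper)
  p <- length(llo)
  best <- NULL
  n_eval <- 0L
  with_local_seed(config$seed, {
    cand <- matrix(runif(config$n_screen * p), ncol = p)
    cand <- sweep(sweep(cand, 2, lhi - llo, `*`), 2, llo, `+`)
    colnames(cand) <- names(config$lower)
    ssr0 <- apply(cand, 1, function(q) sum(fn(q)^2))
    for (i in order(ssr0)[seq_len(config$n_starts)]) {
      f <- try(lm_from(fn, cand[i, ], config), silent = TRUE)
      if (inherits(f, "try-error")) next
      n_eval <- n_eval + f$niter
      if (is.null(best) || f$deviance < best$deviance) best <- f
    }
    if (!is.null(best) && config$n_hops > 0) {
      for (h in seq_len(config$n_hops)) {
        f <- try(lm_from(fn, best$par + runif(p, -0.6, 0.6), config),
                 silent = TRUE)
        if (inherits(f, "try-error")) next
        n_eval <- n_eval + f$niter
        if (f$deviance < best$deviance) best <- f
      }
    }
  })
  if (is.null(best)) {
    abort("no multistart converged; check data scale and bounds",
          class = "strandex_fit_failure")
  }
  list(best = best, n_eval = n_eval)
}

# package an nls.lm optimum into an exchange_fit
finalize_exchange_fit <- function(best, n_eval, data, config) {
  scheme <- config$scheme
  llo <- log10(config$lower); lhi <- log10(config$upper)
  logk <- best$par
  at_bound <- logk <= llo + 1e-6 | logk >= lhi - 1e-6
  if (any(at_bound)) {
    warn(paste("parameter(s) at bound:",
               paste(names(config$lower)[at_bound], collapse = ", ")),
         class = "strandex_boundary_warning")
  }
  rates <- as_rate_constants(10^as.numeric(logk), scheme)
  res <- best$fvec
  y <- data$value
  m <- length(res); p <- length(logk)
  ssr <- sum(res^2)
  se_log <- rep(NA_real_, p)
  if (m > p) {
    cov <- try(chol2inv(chol(best$hessian)) * ssr / (m - p), silent = TRUE)
    if (!inherits(cov, "try-error")) se_log <- sqrt(pmax(diag(cov), 0))
  }
  se <- setNames(as.numeric(rates) * log(10) * se_log, names(rates))
  structure(list(
    rates = rates,
    equilibrium = equilibrium_constants(rates),
    fitted = y + res, residuals = res, ssr = ssr,
    se = se, converged = best$info %in% 1:4,
    n_evaluations = n_eval, at_bound = at_bound,
    assay = attr(data, "assay") %||% "pairing",
    A0 = attr(data, "A0") %||% 36, B0 = attr(data, "B0") %||% 36,
    config = config, data = as_tibble(data)
  ), class = "exchange_fit")
}

#' Fit strand-exchange rate constants to an assay time course
#'
#' Least-squares estimation of the scheme's rate constants from a percent
#' time course (pairing substrate% by default; displacement product% is also
#' supported), minimising the sum of squared residuals between the data and
#' the ODE-simulated observable.  The global-then-local search described in
#' [fit_config()] makes the fit deterministic given (data, config).
#'
#' @param data A [time_course()] (or data frame with columns `time_s`,
#'   `value` plus `assay`, `A0`, `B0` attributes) on the percent scale.
#' @param config A [fit_config()].
#' @return An `exchange_fit` object with linear-scale `rates`, their
#'   `equilibrium` constants, residual diagnostics, Jacobian-based standard
#'   errors and convergence info.  A parameter ending on a bound triggers a
#'   boundary warning.
#' @export
fit_time_course <- function(data, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  if (any(diff(data$time_s) <= 0) || anyNA(data$value)) {
    abort("time course must have strictly increasing times and finite values",
          class = "strandex_invalid_input")
  }
  fn <- exchange_residual_fn(data, config)
  out <- run_search(fn, config)
  # three-step landscapes benefit from a start embedded from a quick
  # two-step pre-fit (fit the simpler scheme, lift its optimum)
  if (config$scheme$name == "three_step" && config$n_hops > 0) {
    cfg2 <- fit_config("two_step",
                       n_starts = min(3L, config$n_starts),
                       seed = config$seed + 1L,
                       n_screen = max(50L, config$n_screen %/% 2L),
                       n_hops = min(3L, config$n_hops),
                       rtol = config$rtol, atol = config$atol,
                       maxiter = config$maxiter)
    fn2 <- exchange_residual_fn(data, cfg2)
    pre <- try(run_search(fn2, cfg2), silent = TRUE)
    if (!inherits(pre, "try-error")) {
      out$n_eval <- out$n_eval + pre$n_eval
      w <- try(lm_from(fn, three_from_two(pre$best$par), config), silent = TRUE)
      if (!inherits(w, "try-error")) {
        out$n_eval <- out$n_eval + w$niter
        if (w$deviance < out$best$deviance) {
          out$best <- w
          # re-hop around the improved optimum
          with_local_seed(config$seed + 2L, {
            for (h in seq_len(config$n_hops)) {
              f <- try(lm_from(fn, out$best$par +
                                 runif(length(out$best$par), -0.6, 0.6), config),
                       silent = TRUE)
              if (inherits(f, "try-error")) next
              out$n_eval <- out$n_eval + f$niter
              if (f$deviance < out$best$deviance) out$best <- f
            }
          })
        }
      }
    }
  }
  finalize_exchange_fit(out$best, out$n_eval, data, config)
}

# embed a two-step optimum in three-step space: make the C1<->C2 exchange
# fast and symmetric so the intermediate pair behaves as one pool
three_from_two <- function(logk2) {
  k <- 10^logk2
  log10(c(k1 = k[1], k_m1 = 2 * k[2], k2 = 0.5, k_m2 = 0.5,
          k3 = 2 * k[3], k_m3 = k[4]))
}

# lump a three-step optimum into two-step space assuming fast C1<->C2
# pre-equilibrium with occupancy fraction f = K2 / (1 + K2) in C2
two_from_three <- function(logk3) {
  k <- 10^logk3
  f <- (k[3] / k[4]) / (1 + k[3] / k[4])
  log10(pmax(c(k1 = k[1], k_m1 = k[2] * (1 - f), k2 = k[5] * f,
               k_m2 = k[6]), 1e-10))
}

#' Wald-Wolfowitz runs test on residual signs
#'
#' Tests whether the signs of a residual series are randomly ordered
#' (normal approximation).  A small p-value flags systematic deviation of a
#' fitted model from the data, the diagnostic used to discriminate the
#' three-step from the two-step exchange scheme.
#'
#' @param x Residual series; zeros are dropped.
#' @return An object of class `htest` with the z statistic and two-sided
#'   p-value.
#' @export
runs_test <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  if (n1 == 0 || n2 == 0 || n < 2) {
    z <- NA_real_; pval <- NA_real_; runs <- if (n > 0) 1 else 0
  } else {
    runs <- 1 + sum(diff(s) != 0)
    mu <- 2 * n1 * n2 / n + 1
    v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
    if (v <= 0) { z <- NA_real_; pval <- NA_real_ }
    else {
      z <- (runs - mu) / sqrt(v)
      pval <- 2 * pnorm(-abs(z))
    }
  }
  structure(list(
    statistic = c(z = z), p.value = pval,
    estimate = c(runs = runs, n_positive = n1, n_negative = n2),
    method = "Wald-Wolfowitz runs test (normal approximation)",
    data.name = deparse(substitute(x)),
    alternative = "non-random sign ordering"
  ), class = "htest")
}

#' Compare two-step and three-step exchange schemes on one time course
#'
#' Fits both schemes and compares them by AIC (`m * log(SSR / m) + 2p`) and
#' by a runs test on the residual signs; the runs test quantifies systematic
#' deviation, AIC decides the selection.  After the independent searches,
#' each scheme is additionally warm-started from the other's optimum (a
#' fast-pre-equilibrium embedding in one direction, intermediate lumping in
#' the other), which stabilises the SSR gap between the nested-like models.
#'
#' @param data A [time_course()] on the percent scale.
#' @param config A [fit_config()]; its scheme-specific bounds are rebuilt
#'   per fitted scheme.  `config_two` optionally overrides the search
#'   settings for the two-step fit (defaults to a lighter search, since the
#'   4-parameter landscape is easier).
#' @param config_two Optional [fit_config()] for the two-step fit.
#' @return A `model_comparison` object with both fits, their SSR/AIC and
#'   runs-test p-values, and the selected scheme.
#' @export
compare_models <- function(data, config = fit_config(), config_two = NULL) {
  cfg3 <- config
  if (cfg3$scheme$name != "three_step") {
    cfg3 <- fit_config("three_step", n_starts = config$n_starts,
                       seed = config$seed, n_screen = config$n_screen,
                       n_hops = config$n_hops, rtol = config$rtol,
                       atol = config$atol, maxiter = config$maxiter)
  }
  cfg2 <- config_two %||% fit_config(
    "two_step", n_starts = max(4L, cfg3$n_starts %/% 2L),
    seed = cfg3$seed + 1L, n_screen = max(150L, cfg3$n_screen %/% 2L),
    n_hops = max(4L, cfg3$n_hops %/% 2L),
    rtol = cfg3$rtol, atol = cfg3$atol, maxiter = cfg3$maxiter)
  if (cfg2$scheme$name != "two_step") {
    abort("config_two must use the two_step scheme",
          class = "strandex_invalid_parameter")
  }

  fn3 <- exchange_residual_fn(data, cfg3)
  fn2 <- exchange_residual_fn(data, cfg2)
  s3 <- run_search(fn3, cfg3)
  s2 <- run_search(fn2, cfg2)
  # cross warm starts
  w3 <- try(lm_from(fn3, three_from_two(s2$best$par), cfg3), silent = TRUE)
  if (!inherits(w3, "try-error") && w3$deviance < s3$best$deviance) s3$best <- w3
  w2 <- try(lm_from(fn2, two_from_three(s3$best$par), cfg2), silent = TRUE)
  if (!inherits(w2, "try-error") && w2$deviance < s2$best$deviance) s2$best <- w2

  quiet_finalize <- function(best, n_eval, cfg) {
    withCallingHandlers(
      finalize_exchange_fit(best, n_eval, data, cfg),
      warning = function(w) {
        if (inherits(w, "strandex_boundary_warning")) invokeRestart("muffleWarning")
      })
  }
  fits <- list(two_step = quiet_finalize(s2$best, s2$n_eval, cfg2),
               three_step = quiet_finalize(s3$best, s3$n_eval, cfg3))
  m <- nrow(data)
  aic <- vapply(fits, function(f) {
    m * log(f$ssr / m) + 2 * length(f$rates)
  }, numeric(1))
  runs_p <- vapply(fits, function(f) runs_test(f$residuals)$p.value, numeric(1))
  selected <- names(which.min(aic))
  structure(list(
    fits = fits,
    ssr = vapply(fits, `[[`, numeric(1), "ssr"),
    aic = aic, runs_p = runs_p, selected = selected, m = m
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  tab <- data.frame(scheme = names(x$aic), ssr = x$ssr, aic = x$aic,
                    runs_p = x$runs_p, row.names = NULL)
  print(tab, digits = 4)
  cat("selected:", x$selected, "\n")
  invisible(x)
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat(sprintf("<exchange_fit> %s scheme on %s assay (%d points)\n",
              attr(x$rates, "scheme"), x$assay, length(x$residuals)))
  tab <- data.frame(estimate = as.numeric(x$rates), std.error = unname(x$se),
                    row.names = names(x$rates))
  print(tab, digits = 4)
  cat(sprintf("SSR = %.4g; converged: %s\n", x$ssr, x$converged))
  invisible(x)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> K_D = %.4g uM (se %.2g), n = %.3g (se %.2g)\n",
              x$K_D, x$se[["K_D"]], x$n, x$se[["n"]]))
  invisible(x)
}

#' @export
print.assoc_fit <- function(x, ...) {
  cat(sprintf("<assoc_fit> V_N = %.4g /s, T_half = %.4g s, V_E = %.4g /s\n",
              x$V_N, x$T_half, x$V_E))
  invisible(x)
}

#' @export
print.dissoc_fit <- function(x, ...) {
  cat(sprintf("<dissoc_fit> k_off = %.4g /s (se %.2g), amplitude = %.4g, baseline = %.4g\n",
              x$k_off, x$se[["k_off"]], x$amplitude, x$baseline))
  invisible(x)
}
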