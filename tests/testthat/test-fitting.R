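test_that("Hill fit recovers generating parameters and honours the midpoint", {
  d <- generate_titration(K_D = 1.0, n = 1, baseline = 0.05, amplitude = 0.10,
                          noise = noise_model(sd = 0))
  fit <- fit_hill(d)
  expect_rel_equal(fit$K_D, 1.0, 1e-6)
  expect_rel_equal(fit$n, 1.0, 1e-6)
  expect_rel_equal(fit$baseline, 0.05, 1e-6)
  expect_rel_equal(fit$amplitude, 0.10, 1e-6)
  # at [R] = K_D the curve passes through baseline + amplitude / 2 exactly
  expect_equal(hill_curve(fit$K_D, fit$baseline, fit$amplitude, fit$K_D, fit$n),
               fit$baseline + fit$amplitude / 2)

  expect_error(fit_hill(d[1:4, ]), class = "strandex_invalid_input")
  far <- generate_titration(K_D = 40, n = 1, conc = seq(0.1, 2, length.out = 8),
                            noise = noise_model(sd = 0))
  expect_warning(fit_hill(far), class = "strandex_extrapolation_warning")
})

test_that("association kinetics: slopes, T_half and degenerate linear traces", {
  # a pure line over the nucleation window returns its slope exactly
  lin <- tibble::tibble(time_s = seq(0, 10, 0.5),
                        anisotropy = 0.15 + 4e-3 * seq(0, 10, 0.5))
  fit <- suppressWarnings(association_kinetics(lin, nucleation_window = 10))
  expect_rel_equal(fit$V_N, 4e-3, 1e-10)
  expect_true(is.na(fit$V_E))

  # V_N equals the closed-form OLS slope
  d <- generate_association(T_half = 20.7, noise = noise_model(sd = 0.002, seed = 4))
  fit <- association_kinetics(d, nucleation_window = 10)
  idx <- d$time_s <= 10
  x <- d$time_s[idx]; y <- d$anisotropy[idx]
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_rel_equal(fit$V_N, slope, 1e-12)

  # noiseless sigmoid: T_half and midpoint identity
  d0 <- generate_association(T_half = 20.7, n = 3, baseline = 0.15,
                             amplitude = 0.10, noise = noise_model(sd = 0))
  fit0 <- association_kinetics(d0, nucleation_window = 10)
  expect_rel_equal(fit0$T_half, 20.7, 1e-6)
  expect_equal(association_curve(fit0$T_half, fit0$baseline, fit0$amplitude,
                                 fit0$T_half, fit0$n),
               fit0$baseline + fit0$amplitude / 2)
  expect_true(is.finite(fit0$V_E) && fit0$V_E > fit0$V_N)

  # too sparse sampling around T_half cannot support the elongation slope
  sparse <- generate_association(T_half = 20.7, times = seq(0, 120, 3),
                                 noise = noise_model(sd = 0))
  expect_error(association_kinetics(sparse), class = "strandex_invalid_input")
})

test_that("dissociation fit matches the generator and a log-linear oracle", {
  d <- generate_dissociation(k_off = 0.02, amplitude = 0.12, baseline = 0.18,
                             times = seq(0, 300, 0.5), noise = noise_model(sd = 0))
  fit <- fit_dissociation(d)
  expect_rel_equal(fit$k_off, 0.02, 1e-8)
  expect_rel_equal(fit$amplitude, 0.12, 1e-8)
  expect_rel_equal(fit$baseline, 0.18, 1e-8)
  # value at t = 0 is amplitude + baseline
  expect_rel_equal(fit$amplitude + fit$baseline, d$anisotropy[1], 1e-8)

  # baseline-free decay: log-linear regression is an independent oracle
  t <- seq(0, 100, 0.5)
  y <- 0.25 * exp(-0.05 * t)
  ll <- stats::lm(log(y) ~ t)
  fit2 <- fit_dissociation(tibble::tibble(time_s = t, anisotropy = y))
  expect_rel_equal(fit2$k_off, -unname(coef(ll)[2]), 1e-8)

  expect_warning(
    flat <- fit_dissociation(tibble::tibble(time_s = t, anisotropy = rep(0.2, length(t)))),
    class = "strandex_nondecay_warning")
  expect_equal(flat$k_off, 0)
  expect_equal(flat$amplitude, 0)
})

test_that("stoichiometric and Beer-Lambert helpers do their arithmetic", {
  expect_equal(stoichiometric_concentration(83, 36, 3, 2), 1.992)
  expect_equal(stoichiometric_concentration(3, 1000, 3, 1), 1)
  expect_equal(stoichiometric_concentration(30, 100, 3, 2), 2)

  expect_equal(concentration_from_absorbance(1.23, 1.23e4), 1e-4)
  expect_equal(concentration_from_absorbance(0, 1.23e4), 0)
  expect_equal(concentration_from_absorbance(0.186, 1.86e4), 1e-5)
  expect_error(concentration_from_absorbance(1, 0), class = "strandex_invalid_parameter")
})

test_that("replicate aggregation gives sample mean and n-1 standard deviation", {
  expect_equal(unlist(aggregate_replicates(c(1, 1, 1))), c(mean = 1, sd = 0, n = 3))
  expect_equal(unlist(aggregate_replicates(c(1, 2, 3))), c(mean = 2, sd = 1, n = 3))
  expect_equal(aggregate_replicates(c(3, 1, 2)), aggregate_replicates(c(1, 2, 3)))
  expect_error(aggregate_replicates(5), class = "strandex_invalid_input")
})

test_that("runs test flags systematic residual structure and passes random signs", {
  too_many <- runs_test(rep(c(1, -1), 40))
  expect_lt(too_many$p.value, 1e-6)
  too_few <- runs_test(c(rep(1, 40), rep(-1, 40)))
  expect_lt(too_few$p.value, 1e-6)
  set.seed(11)
  random <- runs_test(rnorm(200))
  expect_gt(random$p.value, 0.01)
})

test_that("time-course fitting is deterministic and flags flat data at the bound", {
  flat <- time_course(seq(0, 500, 10), rep(100, 51))
  expect_warning(
    fit <- fit_time_course(flat, fit_config(n_screen = 60, n_starts = 2,
                                            n_hops = 0, seed = 1)),
    class = "strandex_boundary_warning")
  expect_equal(fit$rates[["k1"]], 1e-7)

  tc <- generate_exchange_course(standard_rates("two_step"),
                                 times = seq(0, 1000, 10),
                                 noise = noise_model(sd = 0.5, seed = 9))
  cfg <- fit_config("two_step", n_screen = 60, n_starts = 2, n_hops = 2, seed = 5)
  f1 <- fit_time_course(tc, cfg)
  f2 <- fit_time_course(tc, cfg)
  expect_identical(unclass(f1$rates), unclass(f2$rates))
  expect_identical(f1$ssr, f2$ssr)
})

test_that("doubling substrate concentrations leaves recovered constants in tolerance", {
  r <- standard_rates()
  truth <- equilibrium_constants(r)
  tc72 <- generate_exchange_course(r, A0 = 72, B0 = 72,
                                   times = seq(0, 1000, 4),
                                   noise = noise_model(sd = 0))
  fit <- fit_time_course(tc72, fit_config(n_screen = 600, n_starts = 12,
                                          n_hops = 25, seed = 3))
  expect_rel_equal(unlist(fit$equilibrium), unlist(truth), 0.05)
})
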