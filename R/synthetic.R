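#' Reference rate constants for the standard pairing condition
#'
#' A rate set chosen so that the simulated standard condition (36 nM
#' filament and donor dsDNA, 0-1000 s) reproduces the qualitative behaviour
#' of the real assay: roughly 40% of substrate converted within 1000 s with
#' about half of the converted material carried through to the final
#' product, and -- for the three-step set -- residual structure that a
#' two-step fit cannot absorb, mirroring the systematic two-step residuals
#' seen with real pairing data.  Used as the default ground truth by the
#' generators and recovery studies.
#'
#' @param scheme `"three_step"` (default) or `"two_step"` (reference truth
#'   for scheme-selection studies).
#' @return A [rate_constants()] object.
#' @export
standard_rates <- function(scheme = c("three_step", "two_step")) {
  scheme <- match.arg(scheme)
  if (scheme == "three_step") {
    rate_constants(k1 = 1.1e-4, k_m1 = 4.7e-2, k2 = 2.5e-2, k_m2 = 3.1e-3,
                   k3 = 3.2e-3, k_m3 = 1.3e-4)
  } else {
    rate_constants(k1 = 1e-4, k_m1 = 2e-2, k2 = 3e-3, k_m2 = 2e-4)
  }
}

#' Additive Gaussian instrument-noise model
#'
#' Homoscedastic Gaussian noise on the reported signal; `sd` is in the
#' signal's own units (percentage points for percent series, anisotropy
#' units for anisotropy series).  All generator randomness flows through
#' `seed`.
#'
#' @param sd Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return A `noise_model` list.
#' @export
noise_model <- function(sd = 1, seed = 1) {
  if (!is.finite(sd) || sd < 0) abort("sd must be >= 0", class = "strandex_invalid_parameter")
  structure(list(sd = sd, seed = as.integer(seed)), class = "noise_model")
}

add_noise <- function(x, noise) {
  if (noise$sd == 0) return(x)
  with_local_seed(noise$seed, x + rnorm(length(x), sd = noise$sd))
}

#' Generate a synthetic FRET strand-exchange time course
#'
#' Emulates the pairing or displacement assay: simulate the mass-action
#' scheme, convert to percent, map to fluorescence through the inverse
#' calibration, add seeded Gaussian noise on the fluorescence (with sd
#' scaled so the percent-scale noise has the requested sd), and convert
#' back.  Noise sd defaults to 1 percentage point, about 1% of the dynamic
#' range.
#'
#' @param rates Generating [rate_constants()] (default [standard_rates()]).
#' @param A0,B0 Initial filament / donor concentrations (nM).
#' @param times Sampling grid (s).
#' @param calib [fret_calibration()].
#' @param assay `"pairing"` or `"displacement"`.
#' @param noise [noise_model()] on the percent scale.
#' @param condition Free-text condition metadata.
#' @return A [time_course()] with columns `time_s`, `value` (noisy percent)
#'   and `fluorescence` (noisy raw signal), carrying a `truth` attribute
#'   with the generating rates and the noiseless percent series.
#' @export
generate_exchange_course <- function(rates = standard_rates(), A0 = 36, B0 = 36,
                                     times = seq(0, 1000, by = 2),
                                     calib = fret_calibration(),
                                     assay = c("pairing", "displacement"),
                                     noise = noise_model(),
                                     condition = "standard") {
  assay <- match.arg(assay)
  rates <- as_rate_constants(rates)
  scheme <- attr(rates, "scheme")
  traj <- simulate_exchange(rates, reaction_state(A0, B0, scheme = scheme), times)
  clean_pct <- trajectory_to_percent(traj, assay)$percent
  f_clean <- percent_to_fluorescence(clean_pct, calib, assay)
  # affine map: percent-scale sd translates to a fluorescence-scale sd
  slope <- abs(percent_to_fluorescence(1, calib, assay) -
                 percent_to_fluorescence(0, calib, assay))
  f_noisy <- add_noise(f_clean, noise_model(noise$sd * slope, noise$seed))
  pct_noisy <- if (noise$sd == 0) clean_pct
               else fluorescence_to_percent(f_noisy, calib, assay, clip = FALSE)
  out <- time_course(times, pct_noisy, assay = assay, A0 = A0, B0 = B0,
                     condition = condition)
  out$fluorescence <- f_noisy
  attr(out, "truth") <- list(rates = rates, percent = clean_pct,
                             fluorescence = f_clean, noise = noise)
  out
}

#' Generate a synthetic SDS-quench abortive experiment
#'
#' At each quench time SDS collapse is instantaneous: C1 reverts to free
#' substrates and C2 proceeds to final products, after which the signal is
#' flat; the post-SDS value is read `readout_delay` seconds later (a
#' sampling offset only).  Both assay modes are emitted with shared ground
#' truth from [predict_intermediates()].
#'
#' @param rates Generating [rate_constants()] (three-step).
#' @param A0,B0 Initial concentrations (nM).
#' @param quench_times SDS addition times (s); default 150, 300, 600, 900.
#' @param readout_delay Seconds between SDS addition and readout.
#' @param noise [noise_model()] applied to every reported percent.
#' @return List with tibbles `dsp` (`quench_time_s`, `substrate_before_pct`,
#'   `substrate_after_pct`), `dsd` (`quench_time_s`, `substrate_before_pct`,
#'   `product_after_pct`) and `truth` (`quench_time_s`, `C1_pct`,
#'   `C2_plus_product_pct`).
#' @export
generate_abortive_experiment <- function(rates = standard_rates(), A0 = 36, B0 = 36,
                                         quench_times = c(150, 300, 600, 900),
                                         readout_delay = 150,
                                         noise = noise_model(sd = 0)) {
  rates <- as_rate_constants(rates)
  if (attr(rates, "scheme") != "three_step") {
    abort("abortive experiment needs the three_step scheme",
          class = "strandex_invalid_parameter")
  }
  times <- sort(unique(c(0, quench_times)))
  traj <- simulate_exchange(rates, reaction_state(A0, B0), times)
  idx <- match(quench_times, traj$time_s)
  substrate_before <- 100 * traj$A[idx] / A0
  inter <- predict_intermediates(traj)[idx, ]
  # instantaneous collapse: C1 -> substrates, C2 -> products
  substrate_after <- substrate_before + inter$C1_pct
  product_after <- inter$C2_plus_product_pct
  nz <- function(x, k) add_noise(x, noise_model(noise$sd, noise$seed + k))
  list(
    dsp = tibble(quench_time_s = quench_times,
                 readout_time_s = quench_times + readout_delay,
                 substrate_before_pct = nz(substrate_before, 0L),
                 substrate_after_pct = nz(substrate_after, 1L)),
    dsd = tibble(quench_time_s = quench_times,
                 readout_time_s = quench_times + readout_delay,
                 substrate_before_pct = nz(substrate_before, 0L),
                 product_after_pct = nz(product_after, 2L)),
    truth = tibble(quench_time_s = quench_times,
                   C1_pct = inter$C1_pct,
                   C2_plus_product_pct = inter$C2_plus_product_pct)
  )
}

#' Generate a synthetic steady-state binding titration
#'
#' Noiseless values follow [hill_curve()]; seeded Gaussian noise is added on
#' the anisotropy.
#'
#' @param K_D Dissociation constant (uM).
#' @param n Hill coefficient.
#' @param baseline,amplitude Anisotropy floor and dynamic range.
#' @param conc Concentration grid (uM); default 12 log-spaced points from
#'   0.05 to 5 uM.
#' @param noise [noise_model()] in anisotropy units.
#' @return Tibble (`concentration_uM`, `anisotropy`) with a `truth` attribute.
#' @export
generate_titration <- function(K_D = 1.22, n = 3, baseline = 0.05,
                               amplitude = 0.10,
                               conc = exp(seq(log(0.05), log(5), length.out = 12)),
                               noise = noise_model(sd = 0.002)) {
  clean <- hill_curve(conc, baseline, amplitude, K_D, n)
  out <- tibble(concentration_uM = conc, anisotropy = add_noise(clean, noise))
  attr(out, "truth") <- list(K_D = K_D, n = n, baseline = baseline,
                             amplitude = amplitude, anisotropy = clean)
  out
}

#' Generate a synthetic filament-association trace
#'
#' Noiseless values follow [association_curve()]; anisotropy is sampled
#' every 0.5 s by default.
#'
#' @param T_half Half-occupancy time (s).
#' @param n Sigmoid exponent.
#' @param baseline,amplitude Anisotropy floor and dynamic range.
#' @param times Sampling grid (s).
#' @param noise [noise_model()] in anisotropy units.
#' @return Tibble (`time_s`, `anisotropy`) with a `truth` attribute.
#' @export
generate_association <- function(T_half = 20.7, n = 3, baseline = 0.15,
                                 amplitude = 0.10,
                                 times = seq(0, 120, by = 0.5),
                                 noise = noise_model(sd = 0.002)) {
  clean <- association_curve(times, baseline, amplitude, T_half, n)
  out <- tibble(time_s = times, anisotropy = add_noise(clean, noise))
  attr(out, "truth") <- list(T_half = T_half, n = n, baseline = baseline,
                             amplitude = amplitude, anisotropy = clean)
  out
}

#' Generate a synthetic filament-dissociation decay
#'
#' Noiseless values follow `amplitude * exp(-k_off * t) + baseline`.
#'
#' @param k_off Dissociation rate constant (1/s).
#' @param amplitude,baseline Anisotropy decay amplitude and floor.
#' @param times Sampling grid (s); default every 0.5 s over 0-600 s.
#' @param noise [noise_model()] in anisotropy units.
#' @return Tibble (`time_s`, `anisotropy`) with a `truth` attribute.
#' @export
generate_dissociation <- function(k_off = 0.133, amplitude = 0.10,
                                  baseline = 0.20,
                                  times = seq(0, 600, by = 0.5),
                                  noise = noise_model(sd = 0.002)) {
  clean <- amplitude * exp(-k_off * times) + baseline
  out <- tibble(time_s = times, anisotropy = add_noise(clean, noise))
  attr(out, "truth") <- list(k_off = k_off, amplitude = amplitude,
                             baseline = baseline, anisotropy = clean)
  out
}
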