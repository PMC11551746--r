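#' FRET signal calibration
#'
#' Maximum FRET efficiency `E_max` anchors the affine map between donor
#' fluorescence and percent substrate/product: the fully complexed state
#' emits `(1 - E_max) * F0` in the pairing assay, while in the displacement
#' assay the fully displaced state emits `F0 / (1 - E_max)` relative to the
#' quenched start `F0`.
#'
#' @param E_max Maximum FRET efficiency, in (0, 1].
#' @param F0 Initial fluorescence (arbitrary units, > 0): the unquenched
#'   filament signal in pairing, the fully quenched duplex signal in
#'   displacement.
#' @return A `fret_calibration` object.
#' @export
fret_calibration <- function(E_max = 0.6, F0 = 1) {
  if (!is.finite(E_max) || E_max <= 0 || E_max > 1) {
    abort("E_max must be in (0, 1]", class = "strandex_calibration_error")
  }
  if (!is.finite(F0) || F0 <= 0) {
    abort("F0 must be > 0", class = "strandex_calibration_error")
  }
  structure(list(E_max = E_max, F0 = F0), class = "fret_calibration")
}

#' Convert a simulated trajectory to an assay percent series
#'
#' The pairing assay reports percent free substrate, 100 * A(t) / A0 (the
#' heteroduplex product retains the acceptor-labelled strand and stays
#' quenched); the displacement assay reports percent displaced product,
#' 100 * E(t) / B0.
#'
#' @param traj An [simulate_exchange()] trajectory.
#' @param assay `"pairing"` or `"displacement"`.
#' @return Tibble with columns `time_s`, `percent` and an `assay` attribute.
#' @export
trajectory_to_percent <- function(traj, assay = c("pairing", "displacement")) {
  assay <- match.arg(assay)
  A0 <- attr(traj, "A0"); B0 <- attr(traj, "B0")
  if (is.null(A0) || is.null(B0) || A0 <= 0 || B0 <= 0) {
    abort("trajectory must carry positive A0 and B0", class = "strandex_invalid_input")
  }
  pct <- if (assay == "pairing") 100 * traj$A / A0 else 100 * traj$E / B0
  structure(tibble(time_s = traj$time_s, percent = pct), assay = assay)
}

#' Convert fluorescence to percent substrate or product
#'
#' Affine calibration through `E_max`: in pairing,
#' substrate% = 100 * (F/F0 - (1 - E_max)) / E_max, so F = F0 maps to 100%
#' and the fully complexed signal (1 - E_max) * F0 maps to 0%.  In
#' displacement, product% = 100 * (F/F0 - 1) * (1 - E_max) / E_max with F0
#' the fully quenched starting emission.
#'
#' @param f Fluorescence values (> 0).
#' @param calib [fret_calibration()].
#' @param assay `"pairing"` or `"displacement"`.
#' @param clip Clip the result to \[0, 100\] (default); generators disable
#'   this to keep additive noise Gaussian at the range edges.
#' @return Numeric percent series.
#' @examples
#' fluorescence_to_percent(0.7, fret_calibration(E_max = 0.6), "pairing")
#' @export
fluorescence_to_percent <- function(f, calib = fret_calibration(),
                                    assay = c("pairing", "displacement"),
                                    clip = TRUE) {
  assay <- match.arg(assay)
  stopifnot(inherits(calib, "fret_calibration"))
  rel <- f / calib$F0
  pct <- if (assay == "pairing") {
    100 * (rel - (1 - calib$E_max)) / calib$E_max
  } else {
    100 * (rel - 1) * (1 - calib$E_max) / calib$E_max
  }
  if (clip) pct <- pmin(pmax(pct, 0), 100)
  pct
}

#' Inverse of [fluorescence_to_percent()]
#'
#' @inheritParams fluorescence_to_percent
#' @param percent Percent substrate (pairing) or product (displacement).
#' @return Fluorescence in the units of `calib$F0`.
#' @export
percent_to_fluorescence <- function(percent, calib = fret_calibration(),
                                    assay = c("pairing", "displacement")) {
  assay <- match.arg(assay)
  stopifnot(inherits(calib, "fret_calibration"))
  rel <- if (assay == "pairing") {
    (1 - calib$E_max) + calib$E_max * percent / 100
  } else {
    1 + calib$E_max / (1 - calib$E_max) * percent / 100
  }
  rel * calib$F0
}

#' Convert 2-aminopurine fluorescence to percent substrate
#'
#' Heteroduplex formation quenches 2AP emission to a fixed fraction of the
#' filament signal (60.1% under the standard calibration), so
#' substrate% = 100 * (F_rel - q) / (1 - q) where `F_rel` is fluorescence
#' relative to the initial filament and `q` the quench fraction.  The map is
#' affine and strictly increasing; inputs above 1 are clipped to 1.
#'
#' @param f_rel Fluorescence relative to the initial filament signal.
#' @param quench_fraction Fully quenched relative level, in (0, 1).
#' @return Percent substrate.
#' @examples
#' two_ap_to_substrate_percent(c(1, 0.8005, 0.601))
#' @export
two_ap_to_substrate_percent <- function(f_rel, quench_fraction = 0.601) {
  if (!is.finite(quench_fraction) || quench_fraction <= 0 || quench_fraction >= 1) {
    abort("quench_fraction must be in (0, 1)", class = "strandex_calibration_error")
  }
  if (any(f_rel <= 0, na.rm = TRUE)) {
    abort("relative fluorescence must be > 0", class = "strandex_invalid_input")
  }
  f_rel <- pmin(f_rel, 1)
  100 * (f_rel - quench_fraction) / (1 - quench_fraction)
}

#' Quantify intermediates from an SDS-quench abortive assay
#'
#' SDS collapses C1 back to free substrates and C2 to final products.  In
#' the pairing-initiated mode (DSP) the post-SDS substrate gain reveals C1
#' and `C2 + product = 100 - substrate_after`; in the displacement-initiated
#' mode (DSD) the post-SDS product% is `C2 + product` directly.  Both modes
#' share the C1 rule.  Two readings of the C1 equation are exposed:
#' `"mass_balance"` (default) takes C1 as the complexed fraction not
#' accounted for by C2 + product, `(100 - substrate_before) - (C2 + product)`,
#' which closes substrate% + C1% + (C2+product)% to 100 and equals the
#' substrate gain across SDS addition; `"printed"` subtracts from the free
#' substrate% instead, `substrate_before - (C2 + product)`, which does not
#' close.
#'
#' @param substrate_before Percent substrate just before SDS addition.
#' @param after In DSP mode, percent substrate after SDS; in DSD mode,
#'   percent product after SDS.
#' @param mode `"DSP"` or `"DSD"`.
#' @param c1_rule `"mass_balance"` or `"printed"`.
#' @param clamp_tol Negative C1 within this many percentage points is
#'   clamped to 0 (measurement noise); larger inconsistencies warn.
#' @return Tibble with columns `C1_pct` and `C2_plus_product_pct`.
#' @examples
#' abortive_quantify(60, 70, mode = "DSP")
#' @export
abortive_quantify <- function(substrate_before, after, mode = c("DSP", "DSD"),
                              c1_rule = c("mass_balance", "printed"),
                              clamp_tol = 2) {
  mode <- match.arg(mode)
  c1_rule <- match.arg(c1_rule)
  chk <- c(substrate_before, after)
  if (any(!is.finite(chk)) || any(chk < -clamp_tol) || any(chk > 100 + clamp_tol)) {
    warn("abortive-assay percentages outside [0, 100]",
         class = "strandex_inconsistent_measurement")
  }
  c2p <- if (mode == "DSP") 100 - after else after
  c1 <- if (c1_rule == "mass_balance") {
    (100 - substrate_before) - c2p
  } else {
    substrate_before - c2p
  }
  bad <- c1 < -clamp_tol
  if (any(bad, na.rm = TRUE)) {
    warn("negative C1 beyond clamp tolerance: inconsistent measurement",
         class = "strandex_inconsistent_measurement")
  }
  c1[c1 < 0 & c1 >= -clamp_tol] <- 0
  tibble(C1_pct = c1, C2_plus_product_pct = c2p)
}

#' Predicted intermediate percentages along a trajectory
#'
#' From a simulated three-step trajectory, the model-predicted abortive-assay
#' readout: C1% = 100 * C1(t)/A0 and (C2 + product)% = 100 * (C2(t)+D(t))/A0.
#' Together with substrate% these close to 100 at every time.
#'
#' @param traj A three-step [simulate_exchange()] trajectory.
#' @return Tibble with `time_s`, `C1_pct`, `C2_plus_product_pct`.
#' @export
predict_intermediates <- function(traj) {
  if (!identical(attr(traj, "scheme"), "three_step")) {
    abort("predict_intermediates needs a three_step trajectory",
          class = "strandex_invalid_input")
  }
  A0 <- attr(traj, "A0")
  if (is.null(A0) || A0 <= 0) abort("trajectory must carry positive A0",
                                    class = "strandex_invalid_input")
  tibble(time_s = traj$time_s,
         C1_pct = 100 * traj$C1 / A0,
         C2_plus_product_pct = 100 * (traj$C2 + traj$D) / A0)
}
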