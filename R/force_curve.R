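#' A single approach force curve
#'
#' One force-vs-piezo-displacement record at one grid pixel of a force
#' volume. `z` is piezo displacement in nm (strictly monotone; stored
#' internally increasing towards the sample), `force` the vertical force in
#' nN. The setpoint is the maximum force the controller applies; curves are
#' validated against it with a 5% allowance.
#'
#' @param z piezo displacement, nm; strictly monotone, length >= 8.
#' @param force vertical force, nN; same length as `z`.
#' @param setpoint maximum applied force, nN.
#' @param pixel integer `(row, col)` grid index.
#' @param meta free-form list of acquisition tags.
#' @return an object of class `"force_curve"`.
#' @export
force_curve <- function(z, force, setpoint = 150,
                        pixel = c(NA_integer_, NA_integer_), meta = list()) {
  if (!is.numeric(z) || !is.numeric(force) || length(z) != length(force))
    cm_abort("'z' and 'force' must be numeric vectors of equal length",
             "cm_data_error")
  if (length(z) < 8L)
    cm_abort("a force curve needs at least 8 samples", "cm_data_error")
  dz <- diff(z)
  if (any(!is.finite(z)) || !(all(dz > 0) || all(dz < 0)))
    cm_abort("'z' must be strictly monotone", "cm_data_error")
  if (all(dz < 0)) { z <- rev(z); force <- rev(force) }
  stopifnot_scalar(setpoint, "setpoint", 0, Inf, open_lower = TRUE)
  if (max(force) > setpoint * 1.05)
    cm_abort(sprintf("max force %.3g nN exceeds setpoint %.3g nN by > 5%%",
                     max(force), setpoint), "cm_data_error")
  structure(
    list(z = as.numeric(z), force = as.numeric(force), setpoint = setpoint,
         pixel = as.integer(pixel), meta = meta),
    class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf(
    "Force curve: %d samples, z %.1f..%.1f nm, force %.3g..%.3g nN (setpoint %g nN), pixel (%s, %s)\n",
    length(x$z), min(x$z), max(x$z), min(x$force), max(x$force),
    x$setpoint, x$pixel[1], x$pixel[2]))
  invisible(x)
}

baseline_window <- function(curve, baseline_fraction) {
  stopifnot_scalar(baseline_fraction, "baseline_fraction", 0, 1,
                   open_lower = TRUE, open_upper = TRUE)
  n <- floor(baseline_fraction * length(curve$z))
  if (n < 4L)
    cm_abort("baseline window has fewer than 4 samples", "cm_data_error")
  seq_len(n)
}

#' Remove baseline offset and tilt from a force curve
#'
#' Fits a straight line to the pre-contact region (the first
#' `baseline_fraction` of samples along `z`) and subtracts it from the
#' whole curve, removing detector offset and linear drift. Must be applied
#' before contact detection or any Hertz fit.
#'
#' @param curve a [force_curve()].
#' @param baseline_fraction fraction of samples taken as pre-contact.
#' @return the corrected `force_curve`; the fitted intercept/slope are
#'   recorded in `meta$baseline`.
#' @export
correct_baseline <- function(curve, baseline_fraction = 0.3) {
  stopifnot(inherits(curve, "force_curve"))
  idx <- baseline_window(curve, baseline_fraction)
  co <- stats::lm.fit(cbind(1, curve$z[idx]), curve$force[idx])$coefficients
  curve$force <- curve$force - (co[1] + co[2] * curve$z)
  curve$meta$baseline <- list(intercept = unname(co[1]), slope = unname(co[2]),
                              fraction = baseline_fraction)
  curve
}

#' Estimate the force-noise level from the pre-contact baseline
#'
#' @inheritParams correct_baseline
#' @return standard deviation of the detrended baseline force, nN.
#' @export
estimate_noise_sigma <- function(curve, baseline_fraction = 0.3) {
  stopifnot(inherits(curve, "force_curve"))
  idx <- baseline_window(curve, baseline_fraction)
  r <- stats::lm.fit(cbind(1, curve$z[idx]), curve$force[idx])$residuals
  stats::sd(r)
}

#' Detect the tip--sample contact point
#'
#' Finds the first sustained rise of the (baseline-corrected) force above
#' `threshold * noise_sigma` over at least `sustain` consecutive samples,
#' then walks back to the last preceding sample whose force is within one
#' noise standard deviation of zero. That sample is the contact point from
#' which indentation depth is measured.
#'
#' @param curve a baseline-corrected [force_curve()].
#' @param noise_sigma force-noise SD in nN; estimated from the baseline
#'   window when `NULL`.
#' @param threshold detection threshold in units of `noise_sigma`.
#' @param sustain number of consecutive supra-threshold samples required.
#' @param baseline_fraction pre-contact fraction used for the noise
#'   estimate and for the too-early guard.
#' @return list with `contact_z` (nm) and `contact_index`.
#' @export
detect_contact_point <- function(curve, noise_sigma = NULL, threshold = 3,
                                 sustain = 3, baseline_fraction = 0.3) {
  stopifnot(inherits(curve, "force_curve"))
  if (is.null(noise_sigma))
    noise_sigma <- estimate_noise_sigma(curve, baseline_fraction)
  if (!is_scalar_number(noise_sigma) || noise_sigma <= 0)
    cm_abort("'noise_sigma' must be a positive scalar", "cm_domain_error")
  f <- curve$force
  n <- length(f)
  above <- f > threshold * noise_sigma
  # first index starting a run of `sustain` supra-threshold samples
  run <- which(stats::filter(as.numeric(above), rep(1, sustain),
                             sides = 1) == sustain)
  if (length(run) == 0L)
    cm_abort("no sustained force rise above threshold: no contact found",
             "cm_no_contact")
  rise <- run[1L] - sustain + 1L
  j <- rise
  while (j > 1L && f[j] > noise_sigma) j <- j - 1L
  n_base <- length(baseline_window(curve, baseline_fraction))
  if (j <= n_base)
    cm_abort(sprintf(
      "contact at sample %d lies inside the %d-sample baseline window", j,
      n_base), "cm_contact_too_early")
  list(contact_z = curve$z[j], contact_index = j)
}

#' Convert a force curve to an indentation curve
#'
#' Re-references the depth axis to the contact point and, when a cantilever
#' spring constant is supplied, subtracts the cantilever deflection:
#' \eqn{\delta = (z - z_0) - F/k}. With `spring_constant = NULL` the data
#' are taken as pre-converted and \eqn{\delta = z - z_0}. Samples with
#' negative depth are dropped and the grid is sorted to be monotone
#' non-decreasing from 0.
#'
#' @param curve a baseline-corrected [force_curve()].
#' @param contact_z contact position in piezo coordinates, nm.
#' @param spring_constant cantilever spring constant, nN/nm, or `NULL`.
#' @return an object of class `"indentation_curve"` with fields `delta`
#'   (nm), `force` (nN), `contact_z`, `contact_index`.
#' @export
to_indentation <- function(curve, contact_z, spring_constant = NULL) {
  stopifnot(inherits(curve, "force_curve"))
  if (!is_scalar_number(contact_z) ||
      contact_z < min(curve$z) || contact_z > max(curve$z))
    cm_abort("'contact_z' outside the z-range of the curve", "cm_domain_error")
  post <- curve$z >= contact_z
  delta <- curve$z[post] - contact_z
  force <- curve$force[post]
  if (!is.null(spring_constant)) {
    stopifnot_scalar(spring_constant, "spring_constant", 0, Inf,
                     open_lower = TRUE)
    delta <- delta - force / spring_constant
  }
  keep <- delta >= 0
  delta <- delta[keep]; force <- force[keep]
  ord <- order(delta)
  delta <- delta[ord]; force <- force[ord]
  if (length(delta) == 0L || delta[1L] > 0) {
    ci <- which(curve$z >= contact_z)[1L]
    delta <- c(0, delta); force <- c(curve$force[ci], force)
  }
  delta[1L] <- 0
  if (length(delta) < 6L)
    cm_abort(sprintf("only %d post-contact samples (need >= 6)",
                     length(delta)), "cm_insufficient_indentation")
  structure(
    list(delta = delta, force = force, contact_z = contact_z,
         contact_index = which(curve$z >= contact_z)[1L],
         pixel = curve$pixel, setpoint = curve$setpoint),
    class = "indentation_curve")
}

#' @export
print.indentation_curve <- function(x, ...) {
  cat(sprintf(
    "Indentation curve: %d samples, depth 0..%.1f nm, force up to %.3g nN (contact at z = %.1f nm)\n",
    length(x$delta), max(x$delta), max(x$force), x$contact_z))
  invisible(x)
}
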