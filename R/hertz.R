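#' Fit the Hertz--Sneddon model over a depth window
#'
#' The central estimator of the package. Over the indentation window
#' `depth_range` \eqn{= [\delta_{lo}, \delta_{hi}]} the model
#' \deqn{F = F_0 + C \tan(\theta) \frac{E_a}{1-\nu^2}
#'       (\delta^2 - \delta_{lo}^2)}
#' is fitted by ordinary least squares; the free offset \eqn{F_0} absorbs
#' force accumulated above the window so each window estimates a local
#' apparent modulus. The fit is linear in \eqn{\delta^2 - \delta_{lo}^2},
#' so it is exact on noiseless model curves.
#'
#' @param ind an [to_indentation()] result (`"indentation_curve"`).
#' @param tip a [tip_geometry()].
#' @param depth_range numeric length-2, fit window in nm.
#' @param min_points minimum number of samples required in the window.
#' @return an object of class `"hertz_fit"` with components `ea` (MPa),
#'   `f_offset` (nN), `fit_r2`, `n_points`, `depth_lo`, `depth_hi`,
#'   `depth_effective` (depth actually covered by data), `tip`, and the
#'   windowed data. Methods: [print()], [summary()], [coef()],
#'   [predict()], [fitted()], [residuals()], [plot()], [simulate()].
#' @seealso [fit_segment()], [fit_apparent_modulus()]
#' @export
fit_hertz <- function(ind, tip = tip_geometry(), depth_range = c(0, 50),
                      min_points = 3L) {
  stopifnot(inherits(ind, "indentation_curve"), inherits(tip, "tip_geometry"))
  if (length(depth_range) != 2L || !is.numeric(depth_range) ||
      depth_range[2] <= depth_range[1] || depth_range[1] < 0)
    cm_abort("'depth_range' must be an increasing non-negative pair",
             "cm_domain_error")
  lo <- depth_range[1]; hi <- depth_range[2]
  sel <- ind$delta >= lo & ind$delta <= hi
  n <- sum(sel)
  if (n < min_points)
    cm_abort(sprintf("segment [%g, %g] nm holds %d samples (need >= %d)",
                     lo, hi, n, min_points),
             "cm_segment_underfilled")
  delta <- ind$delta[sel]; force <- ind$force[sel]
  x <- delta^2 - lo^2
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, x = x), force)
  slope <- unname(fit$coefficients["x"])
  pref <- tip_prefactor(tip)
  ea <- slope / pref
  rss <- sum(fit$residuals^2)
  tss <- sum((force - mean(force))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  if (!is.finite(ea) || ea <= 0)
    cm_abort(sprintf(
      "non-positive fitted modulus (%.3g MPa) over [%g, %g] nm; n = %d, R^2 = %.3f, force range %.3g..%.3g nN",
      ea, lo, hi, n, r2, min(force), max(force)),
      "cm_fit_failed", ea = ea, n_points = n, fit_r2 = r2)
  structure(
    list(ea = ea, f_offset = unname(fit$coefficients[1]),
         fit_r2 = r2, n_points = n,
         depth_lo = lo, depth_hi = hi,
         depth_effective = c(min(delta), max(delta)),
         residual_sd = if (n > 2) sqrt(rss / (n - 2)) else NA_real_,
         tip = tip, delta = delta, force = force,
         fitted = unname(fit$fitted.values)),
    class = "hertz_fit")
}

#' Fit one tomography segment
#'
#' Windowed Hertz--Sneddon fit used for stiffness tomography; segments are
#' conventionally 5 nm wide between 0 and 50 nm.
#'
#' @inheritParams fit_hertz
#' @param depth_lo,depth_hi segment bounds, nm.
#' @return a `"hertz_fit"` (see [fit_hertz()]).
#' @export
fit_segment <- function(ind, depth_lo, depth_hi, tip = tip_geometry(),
                        min_points = 3L) {
  fit_hertz(ind, tip, depth_range = c(depth_lo, depth_hi),
            min_points = min_points)
}

#' Fit the full-range apparent elastic modulus
#'
#' Single Hertz--Sneddon fit from contact down to `max_depth` (default
#' 50 nm); this is the per-curve headline value that enters cell and
#' subject aggregation. Curves ending shallower than `max_depth` are
#' fitted over their available range, recorded in `depth_effective`.
#'
#' @inheritParams fit_hertz
#' @param max_depth maximum indentation depth used, nm.
#' @return a `"hertz_fit"` (see [fit_hertz()]).
#' @export
fit_apparent_modulus <- function(ind, tip = tip_geometry(), max_depth = 50) {
  fit_hertz(ind, tip, depth_range = c(0, max_depth), min_points = 6L)
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf(
    "Hertz-Sneddon fit [%g, %g] nm: Ea = %.4g MPa (n = %d, R^2 = %.4f)\n",
    x$depth_lo, x$depth_hi, x$ea, x$n_points, x$fit_r2))
  invisible(x)
}

#' @export
summary.hertz_fit <- function(object, ...) {
  cat("Hertz-Sneddon windowed fit\n")
  cat(sprintf("  window:          [%g, %g] nm (data %.2f..%.2f nm)\n",
              object$depth_lo, object$depth_hi,
              object$depth_effective[1], object$depth_effective[2]))
  cat(sprintf("  apparent modulus: %.4g MPa\n", object$ea))
  cat(sprintf("  force offset:     %.4g nN\n", object$f_offset))
  cat(sprintf("  n, R^2, sd(res):  %d, %.4f, %.3g nN\n",
              object$n_points, object$fit_r2, object$residual_sd))
  print(object$tip)
  invisible(object)
}

#' @export
coef.hertz_fit <- function(object, ...) {
  c(ea = object$ea, f_offset = object$f_offset)
}

#' @export
fitted.hertz_fit <- function(object, ...) object$fitted

#' @export
residuals.hertz_fit <- function(object, ...) object$force - object$fitted

#' Predict force from a fitted Hertz--Sneddon model
#'
#' @param object a `"hertz_fit"`.
#' @param newdata optional data frame (or list) with a `delta` column, nm;
#'   defaults to the depths used in the fit.
#' @param ... unused.
#' @return predicted force, nN.
#' @export
predict.hertz_fit <- function(object, newdata = NULL, ...) {
  delta <- if (is.null(newdata)) object$delta else newdata$delta
  if (is.null(delta)) cm_abort("'newdata' needs a 'delta' column",
                               "cm_domain_error")
  object$f_offset +
    tip_prefactor(object$tip) * object$ea * (delta^2 - object$depth_lo^2)
}

#' Simulate noisy force data from a fitted Hertz--Sneddon model
#'
#' Draws `nsim` replicates of the windowed force data with Gaussian noise
#' at the fit's residual standard deviation.
#'
#' @param object a `"hertz_fit"`.
#' @param nsim number of replicates.
#' @param seed integer seed.
#' @param ... unused.
#' @return data frame with columns `delta` and `sim_1 ... sim_nsim`.
#' @export
simulate.hertz_fit <- function(object, nsim = 1, seed = 1L, ...) {
  mu <- stats::predict(object)
  sd <- object$residual_sd
  if (!is.finite(sd)) sd <- 0
  with_seed(seed, {
    out <- replicate(nsim, mu + stats::rnorm(length(mu), 0, sd))
    out <- as.data.frame(out)
    names(out) <- paste0("sim_", seq_len(nsim))
    cbind(data.frame(delta = object$delta), out)
  })
}

#' @export
plot.hertz_fit <- function(x, ...) {
  graphics::plot(x$delta, x$force, pch = 16, cex = 0.5,
                 xlab = "indentation depth (nm)", ylab = "force (nN)",
                 main = sprintf("Ea = %.3g MPa over [%g, %g] nm",
                                x$ea, x$depth_lo, x$depth_hi), ...)
  ord <- order(x$delta)
  graphics::lines(x$delta[ord], x$fitted[ord], col = "red3", lwd = 2)
  invisible(x)
}
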