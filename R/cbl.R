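# Concentration boundary layer thickness: log-linear fit of the profile and
# extrapolation to the independently measured bulk concentration.

#' Ordinary least squares fit of log10 concentration against height
#'
#' Fits `log10(conc) = alpha + beta * height` over the points falling inside
#' `fit_range` (inclusive). This is the descriptive model whose inversion at
#' the bulk concentration gives the boundary layer thickness.
#'
#' @param cp a `conc_profile` (see [to_concentration()]).
#' @param fit_range numeric `c(lo, hi)` in micrometres, or `NULL` to use the
#'   default range: from the surface up to the first height whose
#'   concentration is within `bulk_frac` of the bulk value (always at least
#'   three points).
#' @param bulk_frac fraction of the bulk concentration used by the default
#'   range rule (default 0.05, i.e. within 5 percent of bulk).
#' @return A list with `alpha` (log10 umol L-1), `beta` (log10 umol L-1 per
#'   um), `r_squared`, `n_points`, `fit_range` and the underlying `lm` fit.
#' @export
fit_log_profile <- function(cp, fit_range = NULL, bulk_frac = 0.05) {
  stopifnot(inherits(cp, "conc_profile"))
  if (is.null(fit_range)) fit_range <- default_fit_range(cp, bulk_frac)
  idx <- which(cp$heights >= fit_range[1] & cp$heights <= fit_range[2])
  if (length(idx) < 3L)
    stop("fit_log_profile: need >= 3 points in fit range [",
         fit_range[1], ", ", fit_range[2], "] um", call. = FALSE)
  conc <- cp$conc[idx]
  if (any(conc <= 0))
    stop("fit_log_profile: non-positive concentrations in fit range",
         call. = FALSE)
  d <- data.frame(height = cp$heights[idx], logc = log10(conc))
  fit <- stats::lm(logc ~ height, data = d)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((d$logc - mean(d$logc))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(alpha = unname(stats::coef(fit)[1]),
       beta = unname(stats::coef(fit)[2]),
       r_squared = r2, n_points = length(idx),
       fit_range = range(cp$heights[idx]), model = fit)
}

# Default range: surface up to the first height within bulk_frac of bulk,
# extended to at least 3 points.
default_fit_range <- function(cp, bulk_frac = 0.05) {
  near_bulk <- abs(cp$conc - cp$bulk_conc) <= bulk_frac * cp$bulk_conc
  hi_idx <- if (any(near_bulk)) which(near_bulk)[1L] else length(cp$heights)
  hi_idx <- max(hi_idx, min(3L, length(cp$heights)))
  c(cp$heights[1L], cp$heights[hi_idx])
}

#' Concentration boundary layer thickness by log-linear extrapolation
#'
#' Fits [fit_log_profile()] and extrapolates the height at which the fitted
#' log-linear profile reaches the independently measured bulk concentration:
#' `delta_cbl = (log10(bulk_conc) - alpha) / beta`. A negative extrapolation
#' (the fitted line reaches bulk below the surface) is reported with a flag,
#' not clipped. A slope indistinguishable from zero means the profile cannot
#' be told apart from bulk and the thickness is undefined.
#'
#' @inheritParams fit_log_profile
#' @param beta_tol minimum absolute slope (log10 units per um) for a defined
#'   thickness; the default 1e-6 is below instrument resolution over a
#'   4500 um profile.
#' @return An object of class `cbl_fit` with the fit coefficients, the
#'   extrapolated `delta_cbl` in micrometres, `bulk_conc`, fit diagnostics
#'   and a `flag` (`"ok"` or `"negative_extrapolation"`).
#' @section Errors: signals a condition of class `cblflux_undefined_thickness`
#'   when `abs(beta) < beta_tol`.
#' @examples
#' cp <- structure(list(heights = seq(0, 2500, 100),
#'                      conc = 10^(2 + 5e-4 * seq(0, 2500, 100)),
#'                      bulk_conc = 1000, analyte = "oxygen",
#'                      meta = list(profile_id = "ex")),
#'                 class = "conc_profile")
#' cbl_thickness(cp)  # delta = (3 - 2) / 5e-4 = 2000 um
#' @export
cbl_thickness <- function(cp, fit_range = NULL, bulk_frac = 0.05,
                          beta_tol = 1e-6) {
  fit <- fit_log_profile(cp, fit_range = fit_range, bulk_frac = bulk_frac)
  if (!is.finite(fit$beta) || abs(fit$beta) < beta_tol) {
    cond <- structure(
      class = c("cblflux_undefined_thickness", "error", "condition"),
      list(message = paste0(
             "cbl_thickness: |beta| = ", format(abs(fit$beta)),
             " < tolerance ", beta_tol,
             "; profile indistinguishable from bulk"),
           call = sys.call(-1)))
    stop(cond)
  }
  delta <- (log10(cp$bulk_conc) - fit$alpha) / fit$beta
  structure(
    list(profile_id = cp$meta$profile_id, analyte = cp$analyte,
         alpha = fit$alpha, beta = fit$beta, delta_cbl = delta,
         bulk_conc = cp$bulk_conc, r_squared = fit$r_squared,
         n_points = fit$n_points, fit_range = fit$fit_range,
         flag = if (delta < 0) "negative_extrapolation" else "ok",
         model = fit$model),
    class = "cbl_fit")
}

#' @export
print.cbl_fit <- function(x, ...) {
  cat("CBL log-linear fit (", x$analyte, ", profile '", x$profile_id,
      "')\n", sep = "")
  cat(sprintf("  alpha = %.6g, beta = %.6g per um (R^2 = %.4f, n = %d)\n",
              x$alpha, x$beta, x$r_squared, x$n_points))
  cat(sprintf("  delta_CBL = %.1f um at bulk %.4g umol/L  [%s]\n",
              x$delta_cbl, x$bulk_conc, x$flag))
  invisible(x)
}

#' @export
summary.cbl_fit <- function(object, ...) {
  s <- summary(object$model)
  cat(sprintf(
    "delta_CBL = %.1f um; fit range %g-%g um; flag: %s\n\n",
    object$delta_cbl, object$fit_range[1], object$fit_range[2],
    object$flag))
  print(s$coefficients)
  invisible(s)
}

#' @export
coef.cbl_fit <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}

#' @export
residuals.cbl_fit <- function(object, ...) stats::residuals(object$model)

#' Predicted concentration from a CBL fit
#'
#' @param object a `cbl_fit`.
#' @param heights heights in micrometres at which to evaluate the fitted
#'   log-linear profile.
#' @param ... unused.
#' @return Predicted concentrations in umol L-1.
#' @export
predict.cbl_fit <- function(object, heights, ...) {
  10^(object$alpha + object$beta * heights)
}

#' @export
plot.cbl_fit <- function(x, ...) {
  h <- seq(x$fit_range[1], max(x$fit_range[2], x$delta_cbl, na.rm = TRUE),
           length.out = 100)
  graphics::plot(h, log10(predict(x, h)), type = "l",
                 xlab = "distance from surface (um)",
                 ylab = "log10 concentration (umol/L)",
                 main = sprintf("%s: delta_CBL = %.0f um", x$profile_id,
                                x$delta_cbl), ...)
  graphics::points(x$model$model$height, x$model$model$logc)
  graphics::abline(h = log10(x$bulk_conc), lty = 2)
  graphics::abline(v = x$delta_cbl, lty = 3)
  invisible(x)
}
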