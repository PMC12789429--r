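# Fick's-first-law flux from the upper linear gradient of a concentration
# profile, with deterministic automatic gradient-window selection.

#' Diffusion coefficients for protons and oxygen in seawater
#'
#' Defaults are the molecular diffusion coefficients at salinity 35 and
#' 26.5 degrees C: D_H+ = 9.31e-5 cm2 s-1 and D_O2 = 2.20e-5 cm2 s-1.
#'
#' @param D_H proton diffusion coefficient, cm2 s-1.
#' @param D_O2 oxygen diffusion coefficient, cm2 s-1.
#' @param reference_salinity,reference_temp conditions the defaults refer to.
#' @return An object of class `diffusion_constants`.
#' @export
diffusion_constants <- function(D_H = 9.31e-5, D_O2 = 2.20e-5,
                                reference_salinity = 35,
                                reference_temp = 26.5) {
  stopifnot(D_H > 0, D_O2 > 0)
  structure(list(D_H = D_H, D_O2 = D_O2,
                 reference_salinity = reference_salinity,
                 reference_temp = reference_temp),
            class = "diffusion_constants")
}

#' @export
print.diffusion_constants <- function(x, ...) {
  cat(sprintf("Diffusion coefficients at S = %g, T = %g C:\n",
              x$reference_salinity, x$reference_temp))
  cat(sprintf("  D_H+  = %g cm2/s\n  D_O2 = %g cm2/s\n", x$D_H, x$D_O2))
  invisible(x)
}

# slope and R^2 of conc ~ height for every contiguous window, via prefix
# sums; rows = start index, cols = end index
window_stats <- function(h, y, min_points) {
  n <- length(h)
  starts <- integer(0); ends <- integer(0)
  slope <- numeric(0); r2 <- numeric(0)
  for (i in seq_len(n - min_points + 1L)) {
    for (j in seq.int(i + min_points - 1L, n)) {
      hi <- h[i:j]; yi <- y[i:j]
      sxx <- sum((hi - mean(hi))^2)
      sxy <- sum((hi - mean(hi)) * (yi - mean(yi)))
      syy <- sum((yi - mean(yi))^2)
      b <- sxy / sxx
      r <- if (syy > 0) sxy^2 / (sxx * syy) else NA_real_
      starts <- c(starts, i); ends <- c(ends, j)
      slope <- c(slope, b); r2 <- c(r2, r)
    }
  }
  data.frame(start = starts, end = ends, slope = slope, r2 = r2)
}

#' Select the gradient window of a profile
#'
#' Finds the contiguous window of heights used for the Fick's-law linear
#' fit: among all windows with at least `min_points` points that contain the
#' steepest surface-ward gradient segment, the one maximizing the linear-fit
#' R^2 is chosen; ties (within 1e-9) are broken toward the window nearer the
#' surface, then the longer window. Complex and S-shaped profiles thereby
#' resolve to their upper (surface-adjacent) linear limb. The rule is
#' deterministic for a given profile.
#'
#' @param cp a `conc_profile`.
#' @param min_points minimum number of points in the window (>= 3).
#' @param r2_floor if the best window's R^2 falls below this value the
#'   window is still returned but flagged `"low_r2"` (default 0.8).
#' @return A list of class `gradient_window` with `window` (`c(lo, hi)` in
#'   micrometres), `idx`, `r_squared` and `flag` (`"ok"`, `"low_r2"`, or
#'   `"flat"` for a profile with no resolvable gradient, in which case the
#'   window spans the whole profile).
#' @export
select_gradient_window <- function(cp, min_points = 4, r2_floor = 0.8) {
  stopifnot(inherits(cp, "conc_profile"), min_points >= 3)
  h <- cp$heights; y <- cp$conc
  n <- length(h)
  if (n < min_points)
    stop("select_gradient_window: profile has fewer than min_points (",
         min_points, ") heights", call. = FALSE)
  if (stats::sd(y) <= 1e-12 * max(abs(mean(y)), 1)) {
    return(structure(list(window = c(h[1L], h[n]), idx = c(1L, n),
                          r_squared = NA_real_, flag = "flat"),
                     class = "gradient_window"))
  }
  seg <- abs(diff(y) / diff(h))
  k <- which.max(seg)   # steepest segment; which.max takes the first
  st <- window_stats(h, y, min_points)
  st <- st[st$start <= k & st$end >= k + 1L, , drop = FALSE]
  st$r2[is.na(st$r2)] <- -Inf
  best <- max(st$r2)
  cand <- st[st$r2 >= best - 1e-9, , drop = FALSE]
  cand <- cand[order(cand$start, -(cand$end - cand$start)), , drop = FALSE]
  w <- cand[1L, ]
  structure(list(window = c(h[w$start], h[w$end]),
                 idx = c(w$start, w$end),
                 r_squared = if (is.finite(w$r2)) w$r2 else NA_real_,
                 flag = if (is.finite(w$r2) && w$r2 >= r2_floor) "ok"
                        else "low_r2"),
            class = "gradient_window")
}

#' @export
print.gradient_window <- function(x, ...) {
  cat(sprintf("Gradient window %g-%g um (R^2 = %s) [%s]\n",
              x$window[1], x$window[2], format(x$r_squared), x$flag))
  invisible(x)
}

#' Material flux from Fick's first law
#'
#' Fits an ordinary least squares line to concentration (umol L-1) against
#' height (um) inside `window` and converts the slope `m` to a flux
#' `J = -D * m`, expressed in umol m-2 s-1:
#' `J = -(D [cm2 s-1] * 1e-4 [m2 cm-2]) * (m * 1e9 [umol m-4 per (umol L-1 um-1)])`.
#' Positive J is efflux away from the coral surface, negative J is influx.
#'
#' @param cp a `conc_profile`.
#' @param window `c(lo, hi)` in micrometres, a `gradient_window`, or `NULL`
#'   to select automatically with [select_gradient_window()].
#' @param D diffusion coefficient in cm2 s-1; defaults to the analyte's
#'   entry in `constants`.
#' @param constants a [diffusion_constants()] object.
#' @param min_points minimum points for automatic window selection.
#' @return An object of class `flux_fit` with `slope_m` (umol L-1 per um),
#'   `diffusion_coeff`, `flux_J` (umol m-2 s-1), `flux_x1e4` (the same flux
#'   scaled by 1e4, the conventional proton-flux display scale), `window`,
#'   `r_squared`, `n_points` and `flag`.
#' @examples
#' cp <- structure(list(heights = seq(0, 1000, 100),
#'                      conc = 200 + 0.2 * seq(0, 1000, 100),
#'                      bulk_conc = 400, analyte = "oxygen",
#'                      meta = list(profile_id = "ex")),
#'                 class = "conc_profile")
#' fick_flux(cp, window = c(0, 1000))  # J = -0.44 umol m-2 s-1 (influx)
#' @export
fick_flux <- function(cp, window = NULL, D = NULL,
                      constants = diffusion_constants(), min_points = 4) {
  stopifnot(inherits(cp, "conc_profile"))
  flag <- "ok"
  if (is.null(window)) {
    window <- select_gradient_window(cp, min_points = min_points)
  }
  if (inherits(window, "gradient_window")) {
    flag <- window$flag
    wr2 <- window$r_squared
    window <- window$window
  }
  if (window[1] < min(cp$heights) || window[2] > max(cp$heights))
    stop("fick_flux: window outside the profile's height range",
         call. = FALSE)
  if (is.null(D))
    D <- switch(cp$analyte, pH_total = constants$D_H,
                oxygen = constants$D_O2)
  idx <- which(cp$heights >= window[1] & cp$heights <= window[2])
  if (length(idx) < 3L)
    stop("fick_flux: need >= 3 points in the window", call. = FALSE)
  h <- cp$heights[idx]; y <- cp$conc[idx]
  sxx <- sum((h - mean(h))^2)
  sxy <- sum((h - mean(h)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  m <- sxy / sxx
  r2 <- if (syy > 0) sxy^2 / (sxx * syy) else NA_real_
  if (syy <= (1e-12 * max(abs(mean(y)), 1))^2 * (length(y) - 1))
    flag <- "flat"
  if (flag == "flat") m <- 0
  J <- -(D * 1e-4) * (m * 1e9)
  structure(
    list(profile_id = cp$meta$profile_id, analyte = cp$analyte,
         slope_m = m, diffusion_coeff = D, flux_J = J,
         flux_x1e4 = J * 1e4, window = as.numeric(window),
         r_squared = r2, n_points = length(idx), flag = flag,
         heights = h, conc = y),
    class = "flux_fit")
}

#' @export
print.flux_fit <- function(x, ...) {
  dir <- if (x$flux_J > 0) "efflux" else if (x$flux_J < 0) "influx"
         else "no net flux"
  cat("Fick flux (", x$analyte, ", profile '", x$profile_id, "')\n",
      sep = "")
  cat(sprintf("  gradient m = %.4g umol/L/um over %g-%g um (R^2 = %s, n = %d)\n",
              x$slope_m, x$window[1], x$window[2], format(x$r_squared),
              x$n_points))
  cat(sprintf("  J = %.4g umol m-2 s-1 (%s; x1e4 scale: %.4g)  [%s]\n",
              x$flux_J, dir, x$flux_x1e4, x$flag))
  invisible(x)
}

#' @export
coef.flux_fit <- function(object, ...) {
  c(slope_m = object$slope_m, flux_J = object$flux_J)
}

#' @export
residuals.flux_fit <- function(object, ...) {
  fitted <- mean(object$conc) + object$slope_m *
    (object$heights - mean(object$heights))
  object$conc - fitted
}

#' @export
plot.flux_fit <- function(x, ...) {
  graphics::plot(x$heights, x$conc,
                 xlab = "distance from surface (um)",
                 ylab = "concentration (umol/L)",
                 main = sprintf("%s: J = %.3g umol m-2 s-1", x$profile_id,
                                x$flux_J), ...)
  graphics::abline(mean(x$conc) - x$slope_m * mean(x$heights), x$slope_m,
                   lty = 2)
  invisible(x)
}

#' Full per-profile analysis pipeline
#'
#' Runs the standard processing chain on one raw profile: replicate
#' averaging, bulk standardization, unit conversion, CBL thickness fit and
#' Fick's-law flux on the automatically selected gradient window. All
#' intermediates are retained. An undefined boundary layer thickness
#' (profile indistinguishable from bulk) is reported as a flagged `NA`, not
#' an error; other stage failures propagate with the stage name.
#'
#' @param p a raw [micro_profile()].
#' @param constants a [diffusion_constants()] object.
#' @param tail_from,density,fit_range,bulk_frac,beta_tol,min_points passed
#'   to the corresponding stages.
#' @return An object of class `profile_result` with elements `profile` (the
#'   averaged, standardized profile), `conc`, `cbl` (a `cbl_fit`, possibly
#'   flagged), and `flux` (a `flux_fit`).
#' @export
profile_pipeline <- function(p, constants = diffusion_constants(),
                             tail_from = 2500, density = 1.025,
                             fit_range = NULL, bulk_frac = 0.05,
                             beta_tol = 1e-6, min_points = 4) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "cblflux_undefined_thickness")) stop(e)
      stop("pipeline stage '", name, "' failed for profile '",
           p$profile_id, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  pav <- stage("average", average_heights(p))
  pst <- stage("standardize", standardize_to_bulk(pav, tail_from = tail_from))
  cp <- stage("convert", to_concentration(pst, density = density))
  cbl <- tryCatch(
    cbl_thickness(cp, fit_range = fit_range, bulk_frac = bulk_frac,
                  beta_tol = beta_tol),
    cblflux_undefined_thickness = function(e) {
      structure(list(profile_id = cp$meta$profile_id, analyte = cp$analyte,
                     alpha = NA_real_, beta = NA_real_,
                     delta_cbl = NA_real_, bulk_conc = cp$bulk_conc,
                     r_squared = NA_real_, n_points = NA_integer_,
                     fit_range = c(NA_real_, NA_real_),
                     flag = "undefined_thickness", model = NULL),
                class = "cbl_fit")
    })
  flux <- stage("flux", fick_flux(cp, constants = constants,
                                  min_points = min_points))
  structure(list(profile = pst, conc = cp, cbl = cbl, flux = flux),
            class = "profile_result")
}

#' @export
print.profile_result <- function(x, ...) {
  print(x$cbl)
  print(x$flux)
  invisible(x)
}

#' Analyze a batch of profiles into a results table
#'
#' Applies [profile_pipeline()] to each profile and assembles one row per
#' profile with metadata, CBL and flux results, matching the CSV layout the
#' `profile` command writes.
#'
#' @param profiles list of [micro_profile()] objects.
#' @param ... passed to [profile_pipeline()].
#' @return A data frame with columns `profile_id`, `analyte`, `species`,
#'   `genotype`, `treatment`, `condition`, `alpha`, `beta`, `cbl_r_squared`,
#'   `delta_cbl_um`, `cbl_flag`, `window_lo_um`, `window_hi_um`, `slope`,
#'   `flux_umol_m2_s`, `flux_x1e4`, `flux_r_squared`, `flux_flag`,
#'   `surface_value`.
#' @export
analyze_profiles <- function(profiles, ...) {
  if (inherits(profiles, "micro_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    r <- profile_pipeline(p, ...)
    data.frame(
      profile_id = p$profile_id, analyte = p$analyte, species = p$species,
      genotype = p$genotype, treatment = p$treatment,
      condition = p$condition,
      alpha = r$cbl$alpha, beta = r$cbl$beta,
      cbl_r_squared = r$cbl$r_squared, delta_cbl_um = r$cbl$delta_cbl,
      cbl_flag = r$cbl$flag,
      window_lo_um = r$flux$window[1], window_hi_um = r$flux$window[2],
      slope = r$flux$slope_m, flux_umol_m2_s = r$flux$flux_J,
      flux_x1e4 = r$flux$flux_x1e4, flux_r_squared = r$flux$r_squared,
      flux_flag = r$flux$flag,
      surface_value = r$profile$readings[[1L]][1L],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
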