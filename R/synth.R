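# Seeded generator of synthetic microsensor profiles with known ground
# truth (imposed flux, boundary layer thickness, group effect sizes),
# emulating the instrument's sampling scheme.

#' Default instrument sampling heights
#'
#' The canonical scheme: from the surface every 100 um up to 2500 um, then
#' a 2000 um tailing region at 500 um intervals (30 heights in total).
#'
#' @return Numeric vector of heights in micrometres.
#' @export
default_heights <- function() c(seq(0, 2500, by = 100),
                                seq(3000, 4500, by = 500))

#' Configuration for the synthetic profile generator
#'
#' Defaults mirror the measured study conditions: bulk oxygen 6.99 mg L-1
#' and bulk pH_T 7.97 (morning control seawater), a boundary layer of
#' 800 um, ten readings per height on the canonical height scheme, and
#' per-reading sensor noise of 0.01 pH units / 0.05 mg O2 L-1 (typical
#' microelectrode and optode precision).
#'
#' @param geometry `"linear"` (steady-state Fick profile: constant gradient
#'   inside the boundary layer, bulk beyond), `"loglinear"` (log10
#'   concentration linear in height up to the boundary layer), or
#'   `"s_shaped"` (surface plateau, a linear limb carrying the imposed
#'   gradient, then a smooth approach to bulk — the complex geometry seen
#'   over rough coral surfaces).
#' @param analyte `"pH_total"` or `"oxygen"`.
#' @param imposed_flux flux in umol m-2 s-1 (positive = efflux) carried by
#'   the linear gradient (`linear` and `s_shaped` geometries).
#' @param delta_cbl_true boundary layer thickness, um; must lie inside the
#'   sampled height range.
#' @param bulk bulk value in raw sensor units (pH_T or mg O2 L-1).
#' @param surface surface value in raw sensor units (`loglinear` geometry
#'   only).
#' @param limb for `s_shaped`: `c(lo, hi)` um, the linear limb carrying the
#'   imposed gradient (default 100-600 um).
#' @param noise_sd per-reading Gaussian noise in sensor units; default
#'   0.01 (pH) or 0.05 (O2 mg L-1).
#' @param drift constant sensor offset added to every reading (not to the
#'   independent external bulk), removed downstream by
#'   [standardize_to_bulk()].
#' @param heights sampling heights, um.
#' @param reads_per_height replicate readings per height (default 10).
#' @param density seawater density (kg L-1) for the pH/proton conversion.
#' @param constants [diffusion_constants()] used to translate flux to a
#'   gradient.
#' @param species,treatment,condition,genotype metadata for the emitted
#'   profile.
#' @param temperature,salinity water conditions.
#' @param n_per_cell colonies per design cell for factorial datasets.
#' @param bio_cv between-colony biological coefficient of variation of the
#'   imposed flux within a cell (default 0.15); colony noise proportional
#'   to the cell mean.
#' @param bio_sd if non-`NULL`, overrides `bio_cv` with additive Gaussian
#'   colony noise of this absolute standard deviation (same in every
#'   cell). Proportional noise emulates biological spread that scales with
#'   flux magnitude; the absolute mode produces the exchangeable,
#'   homoscedastic errors under which the factorial F-test is calibrated,
#'   and is the appropriate null for type-I-error simulations.
#' @param base_means for factorial datasets: data frame with columns
#'   `species`, `condition`, `analyte`, `flux` giving the per-cell baseline
#'   flux; defaults to the generator's proton/oxygen baseline table.
#' @param multipliers data frame with columns `species`, `treatment`,
#'   `condition`, `mult`; cells not listed default to a multiplier of 1.
#' @param seed integer RNG seed; each profile uses a stream derived from
#'   `(seed, profile index)`.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(geometry = c("linear", "loglinear", "s_shaped"),
                         analyte = c("oxygen", "pH_total"),
                         imposed_flux = NULL, delta_cbl_true = 800,
                         bulk = NULL, surface = NULL, limb = c(100, 600),
                         noise_sd = NULL, drift = 0,
                         heights = default_heights(),
                         reads_per_height = 10, density = 1.025,
                         constants = diffusion_constants(),
                         species = "M_capitata", treatment = "control",
                         condition = "light", genotype = "G1",
                         temperature = 26.5, salinity = 35,
                         n_per_cell = 3, bio_cv = 0.15, bio_sd = NULL,
                         base_means = NULL, multipliers = NULL,
                         seed = 1) {
  geometry <- match.arg(geometry)
  analyte <- match.arg(analyte)
  if (is.null(bulk)) bulk <- switch(analyte, oxygen = 6.99,
                                    pH_total = 7.97)
  if (is.null(noise_sd)) noise_sd <- switch(analyte, oxygen = 0.05,
                                            pH_total = 0.01)
  if (delta_cbl_true <= 0 || delta_cbl_true > max(heights))
    stop("synth_config: delta_cbl_true must lie within the sampled ",
         "height range (0, ", max(heights), "]", call. = FALSE)
  if (geometry %in% c("linear", "s_shaped") && is.null(imposed_flux))
    stop("synth_config: imposed_flux is required for ", geometry,
         " geometry", call. = FALSE)
  if (geometry == "loglinear" && is.null(surface))
    stop("synth_config: surface value is required for loglinear geometry",
         call. = FALSE)
  if (reads_per_height < 1)
    stop("synth_config: reads_per_height must be >= 1", call. = FALSE)
  structure(
    list(geometry = geometry, analyte = analyte,
         imposed_flux = imposed_flux, delta_cbl_true = delta_cbl_true,
         bulk = bulk, surface = surface, limb = limb, noise_sd = noise_sd,
         drift = drift, heights = sort(unique(heights)),
         reads_per_height = reads_per_height, density = density,
         constants = constants, species = species, treatment = treatment,
         condition = condition, genotype = genotype,
         temperature = temperature, salinity = salinity,
         n_per_cell = n_per_cell, bio_cv = bio_cv, bio_sd = bio_sd,
         base_means = base_means, multipliers = multipliers, seed = seed),
    class = "synth_config")
}

# raw sensor units -> umol/L, and back
sensor_to_conc <- function(x, analyte, density) {
  switch(analyte,
         pH_total = 10^(-x) * density * 1e6,
         oxygen = x / O2_MOLAR_MASS * 1e3)
}
conc_to_sensor <- function(c_umol, analyte, density) {
  switch(analyte,
         pH_total = -log10(c_umol / (density * 1e6)),
         oxygen = c_umol * O2_MOLAR_MASS / 1e3)
}

# derived stream seed below 2^31, reproducible per (seed, index)
profile_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 77003 * as.numeric(index)) %% 2147483647L)
}

# latent noiseless concentration (umol/L) at given heights
latent_profile <- function(cfg) {
  h <- cfg$heights
  bulk_conc <- sensor_to_conc(cfg$bulk, cfg$analyte, cfg$density)
  D <- switch(cfg$analyte, pH_total = cfg$constants$D_H,
              oxygen = cfg$constants$D_O2)
  delta <- cfg$delta_cbl_true
  truth <- list(geometry = cfg$geometry, analyte = cfg$analyte,
                bulk_conc = bulk_conc, delta_cbl_true = delta,
                drift = cfg$drift)
  if (cfg$geometry == "linear") {
    m <- -cfg$imposed_flux / (D * 1e5)    # umol/L per um
    conc <- ifelse(h < delta, bulk_conc + m * (h - delta), bulk_conc)
    truth$slope_m <- m
    truth$imposed_flux <- cfg$imposed_flux
    truth$window_true <- c(0, delta)
  } else if (cfg$geometry == "loglinear") {
    surf_conc <- sensor_to_conc(cfg$surface, cfg$analyte, cfg$density)
    beta <- (log10(bulk_conc) - log10(surf_conc)) / delta
    alpha <- log10(surf_conc)
    conc <- ifelse(h < delta, 10^(alpha + beta * h), bulk_conc)
    truth$alpha <- alpha
    truth$beta <- beta
    truth$surface_conc <- surf_conc
  } else {                                 # s_shaped
    m <- -cfg$imposed_flux / (D * 1e5)
    lo <- cfg$limb[1]; hi <- cfg$limb[2]
    if (hi >= delta || lo < 0 || hi <= lo)
      stop("synth_config: limb must satisfy 0 <= lo < hi < delta_cbl_true",
           call. = FALSE)
    # limb ends half a linear continuation short of bulk, so the
    # transition is shallower than the limb and the limb stays steepest
    v_hi <- bulk_conc - m * (delta - hi) / 2
    v_lo <- v_hi - m * (hi - lo)
    conc <- numeric(length(h))
    conc[h <= lo] <- v_lo
    mid <- h > lo & h <= hi
    conc[mid] <- v_lo + m * (h[mid] - lo)
    tr <- h > hi & h < delta
    t <- (h[tr] - hi) / (delta - hi)
    conc[tr] <- v_hi + (bulk_conc - v_hi) * (1 - cos(pi * t)) / 2
    conc[h >= delta] <- bulk_conc
    truth$slope_m <- m
    truth$imposed_flux <- cfg$imposed_flux
    truth$window_true <- c(lo, hi)
  }
  if (any(conc <= 0))
    stop("synth_config: geometry drives concentrations non-positive; ",
         "reduce |imposed_flux| or delta, or raise the bulk value",
         call. = FALSE)
  truth$conc <- conc
  truth
}

#' Generate one synthetic microsensor profile with ground truth
#'
#' Builds the noiseless latent concentration profile for the configured
#' geometry (steady-state Fick diffusion for the linear geometry), converts
#' it to raw sensor units (proton profiles are generated in H+
#' concentration space and emitted as pH readings), then adds the
#' configured constant drift and per-reading Gaussian noise. The
#' independent external bulk reading is exact (drift- and noise-free).
#'
#' @param cfg a [synth_config()].
#' @param index profile index; the RNG stream is derived from
#'   `(cfg$seed, index)` so profiles are individually reproducible.
#' @return A list of class `synth_profile` with `profile` (a
#'   [micro_profile()]) and `truth` (geometry, imposed flux/gradient,
#'   boundary layer thickness, bulk and latent concentrations, drift).
#' @export
make_profile <- function(cfg, index = 1) {
  stopifnot(inherits(cfg, "synth_config"))
  truth <- latent_profile(cfg)
  sensor <- conc_to_sensor(truth$conc, cfg$analyte, cfg$density)
  set.seed(profile_seed(cfg$seed, index))
  readings <- lapply(sensor, function(v)
    v + cfg$drift + stats::rnorm(cfg$reads_per_height, 0, cfg$noise_sd))
  if (cfg$analyte == "oxygen")
    readings <- lapply(readings, function(v) pmax(v, 0))
  p <- micro_profile(
    profile_id = sprintf("sim_%s_%03d", substr(cfg$analyte, 1, 2), index),
    analyte = cfg$analyte, heights = cfg$heights, readings = readings,
    species = cfg$species, genotype = cfg$genotype,
    treatment = cfg$treatment, condition = cfg$condition,
    temperature = cfg$temperature, salinity = cfg$salinity,
    external_bulk = cfg$bulk)
  structure(list(profile = p, truth = truth), class = "synth_profile")
}

# baseline flux table (umol m-2 s-1) per species x condition; proton dark
# values follow the observed group means (2.5 and 0.29 on the x1e4 scale),
# light proton influx and oxygen values are representative magnitudes
default_base_means <- function(analyte) {
  if (analyte == "pH_total")
    data.frame(
      species = rep(c("P_acuta", "M_capitata"), each = 2),
      condition = rep(c("dark", "light"), 2),
      flux = c(2.5e-4, -0.7e-4, 0.29e-4, -0.5e-4),
      stringsAsFactors = FALSE)
  else
    data.frame(
      species = rep(c("P_acuta", "M_capitata"), each = 2),
      condition = rep(c("dark", "light"), 2),
      flux = c(-0.5, 1.0, -0.4, 0.8),
      stringsAsFactors = FALSE)
}

#' Generate a factorial dataset of synthetic profiles with a truth table
#'
#' Emulates the 2 species x 2 treatment x 2 condition design: each cell's
#' imposed mean flux is a species-by-condition baseline scaled by the
#' cell's multiplier (default 1), each colony draws its own flux with a
#' between-colony coefficient of variation `cfg$bio_cv`, and (optionally)
#' a full synthetic profile is generated per colony.
#'
#' @param cfg a [synth_config()]; `base_means`, `multipliers`,
#'   `n_per_cell`, `bio_cv` and `seed` control the design.
#' @param emit `"profiles"` (default) to generate full microsensor
#'   profiles, or `"responses"` to return only the per-colony imposed flux
#'   values (fast path for statistical simulations that do not need the
#'   measurement layer).
#' @return A list of class `synth_dataset` with `truth` (one row per cell:
#'   imposed mean flux), `colonies` (one row per colony: drawn flux), and,
#'   when `emit = "profiles"`, `profiles` (list of [micro_profile()]s).
#' @export
make_factorial_dataset <- function(cfg, emit = c("profiles", "responses")) {
  stopifnot(inherits(cfg, "synth_config"))
  emit <- match.arg(emit)
  base <- cfg$base_means
  if (is.null(base)) base <- default_base_means(cfg$analyte)
  cells <- expand.grid(species = unique(base$species),
                       treatment = c("control", "high_pCO2"),
                       condition = unique(base$condition),
                       stringsAsFactors = FALSE)
  cells$mult <- 1
  if (!is.null(cfg$multipliers)) {
    mm <- cfg$multipliers
    for (i in seq_len(nrow(mm))) {
      j <- cells$species == mm$species[i] &
        cells$treatment == mm$treatment[i] &
        cells$condition == mm$condition[i]
      cells$mult[j] <- mm$mult[i]
    }
  }
  cells$base_flux <- base$flux[match(paste(cells$species, cells$condition),
                                     paste(base$species, base$condition))]
  cells$imposed_mean <- cells$base_flux * cells$mult
  colonies <- cells[rep(seq_len(nrow(cells)), each = cfg$n_per_cell), ]
  colonies$genotype <- paste0("G", sequence(rep(cfg$n_per_cell,
                                                nrow(cells))))
  rownames(colonies) <- NULL
  set.seed(profile_seed(cfg$seed, 0L))
  colonies$flux <- if (!is.null(cfg$bio_sd))
    colonies$imposed_mean + stats::rnorm(nrow(colonies), 0, cfg$bio_sd)
  else colonies$imposed_mean *
    (1 + stats::rnorm(nrow(colonies), 0, cfg$bio_cv))
  out <- list(truth = cells, colonies = colonies)
  if (emit == "profiles") {
    profiles <- vector("list", nrow(colonies))
    for (i in seq_len(nrow(colonies))) {
      ci <- colonies[i, ]
      pcfg <- cfg
      pcfg$geometry <- if (cfg$geometry == "loglinear") "linear"
                       else cfg$geometry
      pcfg$imposed_flux <- ci$flux
      pcfg$species <- ci$species
      pcfg$treatment <- ci$treatment
      pcfg$condition <- ci$condition
      pcfg$genotype <- ci$genotype
      pr <- make_profile(pcfg, index = i)
      pr$profile$profile_id <- sprintf("sim_%s_%s_%s_%s", ci$species,
                                       ci$treatment, ci$condition,
                                       ci$genotype)
      profiles[[i]] <- pr$profile
    }
    out$profiles <- profiles
  }
  structure(out, class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("Synthetic factorial dataset: %d cells, %d colonies%s\n",
              nrow(x$truth), nrow(x$colonies),
              if (is.null(x$profiles)) " (responses only)"
              else sprintf(", %d profiles", length(x$profiles))))
  print(x$truth, row.names = FALSE)
  invisible(x)
}
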