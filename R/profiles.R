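# Microsensor profile data model: replicate readings by height, with the
# colony/treatment metadata needed downstream.

O2_MOLAR_MASS <- 31.998 # g mol-1

#' Construct a microsensor profile
#'
#' A `micro_profile` holds one vertical profile measured above a coral
#' surface: sensor heights (micrometres, 0 = coral surface), the replicate
#' raw readings collected at each height, and the metadata (species,
#' genotype, treatment, light/dark condition, temperature, salinity) plus
#' the independent bulk reading from the external probe.
#'
#' Raw readings are in native sensor units: pH on the total scale for
#' `analyte = "pH_total"`, dissolved oxygen in mg per litre for
#' `analyte = "oxygen"`.
#'
#' @param profile_id character identifier.
#' @param analyte `"pH_total"` or `"oxygen"`.
#' @param heights numeric vector of distances from the surface in
#'   micrometres; strictly increasing, starting at 0.
#' @param readings list of numeric vectors, one per height, each with at
#'   least one replicate reading (the canonical instrument scheme records
#'   ten readings per height).
#' @param species `"M_capitata"` or `"P_acuta"`.
#' @param genotype character genotype / colony label.
#' @param treatment `"control"` or `"high_pCO2"`.
#' @param condition `"light"` or `"dark"`.
#' @param temperature water temperature, degrees C.
#' @param salinity practical salinity.
#' @param external_bulk bulk reading from the independent external probe,
#'   in raw sensor units.
#' @param averaged,standardized logical processing-state flags; set by
#'   [average_heights()] and [standardize_to_bulk()].
#' @return An object of class `micro_profile`.
#' @export
micro_profile <- function(profile_id, analyte, heights, readings,
                          species = "M_capitata", genotype = "G1",
                          treatment = "control", condition = "light",
                          temperature = 26.5, salinity = 35,
                          external_bulk = NA_real_,
                          averaged = FALSE, standardized = FALSE) {
  analyte <- match.arg(analyte, c("pH_total", "oxygen"))
  species <- match.arg(species, c("M_capitata", "P_acuta"))
  treatment <- match.arg(treatment, c("control", "high_pCO2"))
  condition <- match.arg(condition, c("light", "dark"))
  p <- structure(
    list(profile_id = as.character(profile_id), analyte = analyte,
         heights = as.numeric(heights), readings = readings,
         species = species, genotype = as.character(genotype),
         treatment = treatment, condition = condition,
         temperature = temperature, salinity = salinity,
         external_bulk = external_bulk,
         averaged = isTRUE(averaged), standardized = isTRUE(standardized)),
    class = "micro_profile")
  validate_micro_profile(p)
  p
}

validate_micro_profile <- function(p) {
  h <- p$heights
  if (length(h) < 1L || any(h < 0))
    stop("profile '", p$profile_id, "': heights must be non-negative",
         call. = FALSE)
  if (h[1] != 0)
    stop("profile '", p$profile_id, "': first height must be 0 (the surface)",
         call. = FALSE)
  if (length(h) > 1L && any(diff(h) <= 0))
    stop("profile '", p$profile_id, "': heights must be strictly increasing",
         call. = FALSE)
  if (!is.list(p$readings) || length(p$readings) != length(h))
    stop("profile '", p$profile_id,
         "': readings must be a list with one vector per height",
         call. = FALSE)
  n <- lengths(p$readings)
  if (any(n < 1L))
    stop("profile '", p$profile_id, "': every height needs >= 1 reading",
         call. = FALSE)
  v <- unlist(p$readings, use.names = FALSE)
  if (anyNA(v) || !all(is.finite(v)))
    stop("profile '", p$profile_id, "': readings must be finite",
         call. = FALSE)
  if (p$analyte == "pH_total" && (any(v <= 0) || any(v >= 14)))
    stop("profile '", p$profile_id, "': pH readings must be in (0, 14)",
         call. = FALSE)
  if (p$analyte == "oxygen" && any(v < 0))
    stop("profile '", p$profile_id, "': oxygen readings must be >= 0",
         call. = FALSE)
  invisible(p)
}

#' @export
print.micro_profile <- function(x, ...) {
  cat("Microsensor profile '", x$profile_id, "' (", x$analyte, ")\n",
      sep = "")
  cat(sprintf("  %s, genotype %s, %s, %s\n", x$species, x$genotype,
              x$treatment, x$condition))
  cat(sprintf("  %d heights: %g-%g um; readings per height: %s\n",
              length(x$heights), min(x$heights), max(x$heights),
              paste(range(lengths(x$readings)), collapse = "-")))
  cat(sprintf("  external bulk: %s; averaged: %s; standardized: %s\n",
              format(x$external_bulk), x$averaged, x$standardized))
  invisible(x)
}

profile_columns <- c("profile_id", "analyte", "height_um", "reading",
                     "species", "genotype", "treatment", "condition",
                     "temp_c", "salinity", "external_bulk")

#' Read microsensor profiles from a long-format CSV file
#'
#' One row per replicate reading. Required columns: `profile_id`, `analyte`,
#' `height_um`, `reading`, `species`, `genotype`, `treatment`, `condition`,
#' `temp_c`, `salinity`, `external_bulk`. Rows belonging to one profile must
#' appear as contiguous height blocks in increasing height order.
#'
#' @param path path to a comma-delimited UTF-8 file with a header row.
#' @return A list of [micro_profile()] objects, one per `profile_id`, in
#'   order of first appearance. An empty file (header only) gives an empty
#'   list.
#' @seealso [write_profiles()] for the inverse operation.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(profile_columns, names(df))
  if (length(missing))
    stop("profile table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) return(list())
  ids <- unique(df$profile_id)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    rows <- df[df$profile_id == id, , drop = FALSE]
    # heights in file order; collapse contiguous runs into height blocks
    r <- rle(rows$height_um)
    h <- r$values
    if (anyDuplicated(h))
      stop("profile '", id, "': duplicated height blocks out of order",
           call. = FALSE)
    if (length(h) > 1L && any(diff(h) <= 0))
      stop("profile '", id, "': heights must be strictly increasing",
           call. = FALSE)
    idx <- rep(seq_along(h), r$lengths)
    readings <- split(rows$reading, idx)
    names(readings) <- NULL
    meta <- rows[1L, ]
    out[[id]] <- micro_profile(
      profile_id = id, analyte = meta$analyte, heights = h,
      readings = readings, species = meta$species, genotype = meta$genotype,
      treatment = meta$treatment, condition = meta$condition,
      temperature = meta$temp_c, salinity = meta$salinity,
      external_bulk = meta$external_bulk)
  }
  out
}

#' Write microsensor profiles to a long-format CSV file
#'
#' @param profiles a `micro_profile` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "micro_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    n <- lengths(p$readings)
    data.frame(profile_id = p$profile_id, analyte = p$analyte,
               height_um = rep(p$heights, n),
               reading = unlist(p$readings, use.names = FALSE),
               species = p$species, genotype = p$genotype,
               treatment = p$treatment, condition = p$condition,
               temp_c = p$temperature, salinity = p$salinity,
               external_bulk = p$external_bulk,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Average replicate readings at each height
#'
#' Collapses the replicate readings at every height (ten per height under
#' the canonical instrument scheme) to their arithmetic mean. Idempotent.
#'
#' @param p a [micro_profile()].
#' @return The profile with a single mean value per height and
#'   `averaged = TRUE`; metadata unchanged.
#' @export
average_heights <- function(p) {
  stopifnot(inherits(p, "micro_profile"))
  p$readings <- lapply(p$readings, function(v) mean(v))
  p$averaged <- TRUE
  validate_micro_profile(p)
  p
}

#' Standardize a profile to the external bulk probe
#'
#' Applies a single additive offset (in raw sensor units) to every reading
#' so that the mean of the averaged readings in the tailing region (heights
#' `>= tail_from`, outside the boundary layer) equals the independent
#' external bulk reading exactly. This removes constant sensor drift
#' relative to the reference probe.
#'
#' @param p a [micro_profile()] with a finite `external_bulk`.
#' @param tail_from start of the tailing bulk region, micrometres. The
#'   default 2500 is where the canonical sampling scheme switches from
#'   100 um to 500 um steps.
#' @return The shifted profile with `standardized = TRUE`.
#' @export
standardize_to_bulk <- function(p, tail_from = 2500) {
  stopifnot(inherits(p, "micro_profile"))
  if (!is.finite(p$external_bulk))
    stop("profile '", p$profile_id, "': external_bulk is required",
         call. = FALSE)
  tail_idx <- which(p$heights >= tail_from)
  if (!length(tail_idx))
    stop("profile '", p$profile_id, "': no heights >= tail_from (",
         tail_from, " um)", call. = FALSE)
  height_means <- vapply(p$readings, mean, numeric(1))
  offset <- p$external_bulk - mean(height_means[tail_idx])
  p$readings <- lapply(p$readings, function(v) v + offset)
  p$standardized <- TRUE
  validate_micro_profile(p)
  p
}

#' Convert a processed profile to concentration units
#'
#' Converts the averaged, bulk-standardized sensor readings to analyte
#' concentrations in umol per litre. pH (total scale) becomes proton
#' concentration, 10^(-pH) mol per kg seawater, scaled by the seawater
#' density; dissolved oxygen in mg per litre is divided by the molar mass
#' of O2 (31.998 g per mol). The external bulk reading is converted
#' identically.
#'
#' @param p an averaged, standardized [micro_profile()].
#' @param density seawater density in kg per litre used for the
#'   mol per kg -> mol per litre step of the proton channel. The default
#'   1.025 is representative of the study's temperature/salinity range,
#'   over which density varies by < 0.3 percent.
#' @return An object of class `conc_profile` with fields `heights`, `conc`
#'   (umol L-1), `bulk_conc`, `analyte` and the carried metadata.
#' @export
to_concentration <- function(p, density = 1.025) {
  stopifnot(inherits(p, "micro_profile"))
  if (!p$averaged || !p$standardized)
    stop("profile '", p$profile_id,
         "': average_heights() and standardize_to_bulk() must be applied ",
         "before unit conversion", call. = FALSE)
  vals <- vapply(p$readings, function(v) v[[1L]], numeric(1))
  conv <- switch(p$analyte,
    pH_total = function(x) 10^(-x) * density * 1e6,   # umol L-1 of H+
    oxygen   = function(x) x / O2_MOLAR_MASS * 1e3)   # mg L-1 -> umol L-1
  cp <- structure(
    list(heights = p$heights, conc = conv(vals),
         bulk_conc = conv(p$external_bulk), analyte = p$analyte,
         meta = p[c("profile_id", "species", "genotype", "treatment",
                    "condition", "temperature", "salinity")]),
    class = "conc_profile")
  validate_conc_profile(cp)
  cp
}

validate_conc_profile <- function(cp) {
  if (length(cp$heights) != length(cp$conc))
    stop("conc_profile: heights and conc lengths differ", call. = FALSE)
  if (cp$analyte == "pH_total" && any(cp$conc <= 0))
    stop("conc_profile: proton concentrations must be positive",
         call. = FALSE)
  if (cp$analyte == "oxygen" && any(cp$conc < 0))
    stop("conc_profile: oxygen concentrations must be >= 0", call. = FALSE)
  if (!is.finite(cp$bulk_conc) || cp$bulk_conc <= 0)
    stop("conc_profile: bulk concentration must be positive", call. = FALSE)
  invisible(cp)
}

#' @export
print.conc_profile <- function(x, ...) {
  cat("Concentration profile '", x$meta$profile_id, "' (", x$analyte,
      ")\n", sep = "")
  cat(sprintf("  %d heights, conc %.4g-%.4g umol/L, bulk %.4g umol/L\n",
              length(x$heights), min(x$conc), max(x$conc), x$bulk_conc))
  invisible(x)
}

#' @export
plot.conc_profile <- function(x, ...) {
  graphics::plot(x$heights, x$conc, xlab = "distance from surface (um)",
                 ylab = "concentration (umol/L)",
                 main = x$meta$profile_id, ...)
  graphics::abline(h = x$bulk_conc, lty = 2)
  invisible(x)
}
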