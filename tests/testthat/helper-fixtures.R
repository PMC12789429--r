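# Fixtures are built in code: direct constructors for profiles and
# concentration profiles, and the study's reported bottle-chemistry
# values used to validate the carbonate solver.

# micro_profile from one value (or replicate vector) per height
mk_profile <- function(heights, values, analyte = "oxygen",
                       external_bulk = NA_real_, reps = 1, ...) {
  readings <- if (is.list(values)) values
              else lapply(values, function(v) rep(v, reps))
  micro_profile(profile_id = "test", analyte = analyte, heights = heights,
                readings = readings, external_bulk = external_bulk, ...)
}

# conc_profile built directly, bypassing the sensor layer
mk_conc <- function(heights, conc, bulk, analyte = "oxygen",
                    profile_id = "test") {
  cp <- structure(list(heights = heights, conc = conc, bulk_conc = bulk,
                       analyte = analyte,
                       meta = list(profile_id = profile_id,
                                   species = "M_capitata", genotype = "G1",
                                   treatment = "control",
                                   condition = "light",
                                   temperature = 26.5, salinity = 35)),
                  class = "conc_profile")
  cp
}

# mesocosm/flume bottle chemistry: measured inputs and the derived values
# reported alongside them (morning and mid-day rows)
bottle_chemistry_rows <- function() {
  data.frame(
    row = c("holding_morning_control", "holding_morning_highCO2",
            "midday_control", "midday_highCO2",
            "flume_morning_control", "flume_morning_highCO2"),
    temp = c(26.80, 26.83, 27.28, 27.25, 26.58, 26.13),
    sal = c(35.52, 35.56, 35.39, 35.39, 35.55, 35.61),
    pH = c(7.97, 7.67, 8.10, 7.83, 7.96, 7.66),
    AT = c(2179, 2178, 2168, 2174, 2178, 2179),
    HCO3 = c(1714, 1916, 1584, 1811, 1722, 1927),
    CO3 = c(187, 106, 234, 146, 184, 102),
    DIC = c(1914, 2050, 1827, 1975, 1918, 2057),
    pCO2 = c(461, 1030, 319, 670, 470, 1047),
    omega = c(2.99, 1.69, 3.75, 2.34, 2.93, 1.62),
    stringsAsFactors = FALSE)
}
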