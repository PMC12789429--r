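test_that("profile CSV writer and reader round-trip is the identity", {
  cfg <- synth_config("linear", "oxygen", imposed_flux = 0.5,
                      delta_cbl_true = 800, seed = 42)
  p <- make_profile(cfg)$profile
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles(p, path)
  back <- read_profiles(path)
  expect_length(back, 1)
  q <- back[[1]]
  expect_identical(q$profile_id, p$profile_id)
  expect_equal(q$heights, p$heights)
  expect_equal(q$readings, p$readings)
  for (f in c("analyte", "species", "genotype", "treatment", "condition",
              "temperature", "salinity", "external_bulk"))
    expect_equal(q[[f]], p[[f]])
  # 30 heights x 10 readings survives intact
  expect_length(q$heights, 30)
  expect_true(all(lengths(q$readings) == 10))
})

test_that("reader rejects malformed tables", {
  path <- withr::local_tempfile(fileext = ".csv")
  # out-of-order duplicated height blocks
  df <- data.frame(profile_id = "p1", analyte = "oxygen",
                   height_um = c(0, 0, 100, 100, 0, 0),
                   reading = rep(6, 6), species = "M_capitata",
                   genotype = "G1", treatment = "control",
                   condition = "light", temp_c = 26.5, salinity = 35,
                   external_bulk = 6.9)
  write.csv(df, path, row.names = FALSE)
  expect_error(read_profiles(path), "p1")
  # missing required column
  write.csv(df[setdiff(names(df), "reading")], path, row.names = FALSE)
  expect_error(read_profiles(path), "reading")
  # header-only file gives an empty list
  write.csv(df[0, ], path, row.names = FALSE)
  expect_identical(read_profiles(path), list())
})

test_that("profile invariants are enforced", {
  expect_error(mk_profile(c(100, 200), c(6, 6)), "first height")
  expect_error(mk_profile(c(0, 200, 100), c(6, 6, 6)), "increasing")
  expect_error(mk_profile(c(0, 100), c(6, 15), analyte = "pH_total"),
               "pH readings")
  expect_error(mk_profile(c(0, 100), c(6, -1)), "oxygen readings")
})

test_that("average_heights takes arithmetic means and is idempotent", {
  p <- mk_profile(c(0, 100, 200),
                  list(rep(7, 10), as.numeric(1:10), c(2, 4)),
                  analyte = "pH_total")
  a <- average_heights(p)
  expect_equal(vapply(a$readings, unlist, numeric(1)), c(7, 5.5, 3))
  expect_true(a$averaged)
  expect_equal(average_heights(a)$readings, a$readings)
  # seeded replicate draws recover their own hand-computed mean
  set.seed(311)
  draws <- rnorm(10, mean = 8, sd = 0.01)
  p2 <- mk_profile(c(0, 100, 200), list(draws, draws, draws),
                   analyte = "pH_total")
  m <- unlist(average_heights(p2)$readings[1])
  expect_equal(m, sum(draws) / 10)
  expect_lt(abs(m - 8), 0.01)
})

test_that("bulk standardization applies the additive offset exactly", {
  heights <- c(0, 100, 200, 2500, 3000)
  p <- mk_profile(heights, c(7.5, 7.6, 7.8, 7.9, 7.9),
                  analyte = "pH_total", external_bulk = 7.97)
  s <- standardize_to_bulk(average_heights(p), tail_from = 2500)
  # tail mean was 7.90 -> every reading shifted by +0.07
  expect_equal(unlist(s$readings), c(7.57, 7.67, 7.87, 7.97, 7.97))
  tail_mean <- mean(unlist(s$readings[heights >= 2500]))
  expect_equal(tail_mean, 7.97, tolerance = 1e-15)
  # tail already at bulk -> unchanged
  p0 <- mk_profile(heights, c(7.5, 7.6, 7.8, 7.97, 7.97),
                   analyte = "pH_total", external_bulk = 7.97)
  s0 <- standardize_to_bulk(average_heights(p0))
  expect_equal(unlist(s0$readings), c(7.5, 7.6, 7.8, 7.97, 7.97))
  expect_error(standardize_to_bulk(average_heights(p), tail_from = 9000),
               "tail_from")
})

test_that("injected constant sensor drift is removed against the bulk probe", {
  cfg <- synth_config("linear", "oxygen", imposed_flux = 0.5,
                      delta_cbl_true = 800, noise_sd = 0, drift = -0.2,
                      seed = 9)
  sp <- make_profile(cfg)
  s <- standardize_to_bulk(average_heights(sp$profile))
  surface_truth <- sp$truth$conc[1] * 31.998 / 1e3   # mg/L, drift-free
  expect_equal(unlist(s$readings[1]), surface_truth, tolerance = 1e-10)
})

test_that("unit conversion maps sensor readings to umol/L", {
  heights <- c(0, 100, 2500)
  mk_ready <- function(vals, analyte, bulk) {
    p <- mk_profile(heights, vals, analyte = analyte,
                    external_bulk = bulk)
    p$averaged <- TRUE; p$standardized <- TRUE
    p
  }
  cp <- to_concentration(mk_ready(c(8, 8, 8), "pH_total", 8))
  expect_equal(cp$conc, rep(1.025e-2, 3), tolerance = 1e-12)
  cp2 <- to_concentration(mk_ready(c(6.99, 6.99, 6.99), "oxygen", 6.99))
  expect_equal(cp2$conc, rep(6.99 / 31.998 * 1000, 3))
  expect_equal(cp2$conc[1], 218.45, tolerance = 1e-4)
  expect_equal(cp2$bulk_conc, cp2$conc[1])
  # one pH unit is exactly a factor of ten in proton concentration
  cp7 <- to_concentration(mk_ready(c(7, 7, 7), "pH_total", 7))
  expect_equal(cp7$conc[1] / cp$conc[1], 10)
  # strictly monotone decreasing in pH
  phs <- seq(7, 8.5, by = 0.1)
  concs <- vapply(phs, function(v)
    to_concentration(mk_ready(rep(v, 3), "pH_total", v))$conc[1],
    numeric(1))
  expect_true(all(diff(concs) < 0))
  # conversion refuses unprocessed profiles
  raw <- mk_profile(heights, c(8, 8, 8), analyte = "pH_total",
                    external_bulk = 8)
  expect_error(to_concentration(raw), "average_heights")
})
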