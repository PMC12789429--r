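test_that("Fick flux matches hand dimensional analysis", {
  h <- seq(0, 1000, 100)
  # O2 rising toward the surface sensor end: influx of -0.44
  cp <- mk_conc(h, 200 + 0.2 * h, bulk = 400, analyte = "oxygen")
  f <- fick_flux(cp, window = c(0, 1000))
  expect_equal(f$slope_m, 0.2, tolerance = 1e-12)
  expect_equal(f$flux_J, -2.20e-5 * 1e-4 * 0.2 * 1e9, tolerance = 1e-12)
  expect_equal(f$flux_J, -0.44, tolerance = 1e-12)
  # protons decaying from 0.10 to 0.01 umol/L over 1000 um: efflux
  cph <- mk_conc(h, 0.10 - 9e-5 * h, bulk = 0.01, analyte = "pH_total")
  fh <- fick_flux(cph, window = c(0, 1000))
  expect_equal(fh$slope_m, -9e-5, tolerance = 1e-12)
  expect_equal(fh$flux_J, 8.379e-4, tolerance = 1e-10)
  expect_equal(fh$flux_x1e4, 8.379, tolerance = 1e-6)
  # zero gradient gives zero flux
  f0 <- fick_flux(mk_conc(h, rep(7, 11), bulk = 7), window = c(0, 1000))
  expect_equal(f0$flux_J, 0)
  expect_identical(f0$flag, "flat")
})

test_that("flux is linear in D and reverses sign with the gradient", {
  h <- seq(0, 1000, 100)
  cp <- mk_conc(h, 200 + 0.2 * h, bulk = 400)
  f1 <- fick_flux(cp, window = c(0, 1000), D = 2.2e-5)
  f2 <- fick_flux(cp, window = c(0, 1000), D = 4.4e-5)
  expect_equal(f2$flux_J, 2 * f1$flux_J, tolerance = 1e-12)
  rev <- mk_conc(h, 400 - 0.2 * h, bulk = 200)
  fr <- fick_flux(rev, window = c(0, 1000), D = 2.2e-5)
  expect_equal(fr$flux_J, -f1$flux_J, tolerance = 1e-12)
  # sign convention: sign(J) = -sign(m)
  expect_equal(sign(fr$flux_J), -sign(fr$slope_m))
})

test_that("window selection finds the linear limb", {
  # globally linear: the full profile is selected
  h <- seq(0, 1000, 100)
  w <- select_gradient_window(mk_conc(h, 10 + 0.05 * h, bulk = 60))
  expect_equal(w$window, c(0, 1000))
  expect_identical(w$flag, "ok")
  # linear limb 0-500 um then flat at bulk: window stays inside the limb
  h2 <- seq(0, 2000, 100)
  conc <- ifelse(h2 < 500, 100 + 0.1 * (h2 - 500), 100)
  w2 <- select_gradient_window(mk_conc(h2, conc, bulk = 100))
  expect_gte(w2$window[1], 0)
  expect_lte(w2$window[2], 500)
  expect_gte(diff(w2$window), 300)   # uses the limb, not a sliver
})

test_that("selected window overlaps the true limb of S-shaped profiles", {
  for (seed in c(1, 2, 3)) {
    cfg <- synth_config("s_shaped", "oxygen", imposed_flux = -0.3,
                        delta_cbl_true = 900, limb = c(100, 600),
                        seed = seed)
    sp <- make_profile(cfg)
    cp <- to_concentration(standardize_to_bulk(
      average_heights(sp$profile)))
    w <- select_gradient_window(cp)
    overlap <- min(w$window[2], 600) - max(w$window[1], 100)
    expect_gte(overlap / 500, 0.8)
  }
})

test_that("window selection is deterministic and respects min_points", {
  cfg <- synth_config("s_shaped", "oxygen", imposed_flux = -0.3,
                      delta_cbl_true = 900, limb = c(100, 600), seed = 4)
  cp <- to_concentration(standardize_to_bulk(
    average_heights(make_profile(cfg)$profile)))
  w1 <- select_gradient_window(cp, min_points = 5)
  w2 <- select_gradient_window(cp, min_points = 5)
  expect_identical(w1, w2)
  idx <- which(cp$heights >= w1$window[1] & cp$heights <= w1$window[2])
  expect_gte(length(idx), 5)
})

test_that("pipeline recovers imposed flux exactly on noiseless profiles", {
  for (J in c(0.5, -0.2)) {
    cfg <- synth_config("linear", "oxygen", imposed_flux = J,
                        delta_cbl_true = 800, noise_sd = 0, seed = 1)
    r <- profile_pipeline(make_profile(cfg)$profile)
    expect_equal(r$flux$flux_J, J, tolerance = 1e-6)
  }
  cfgp <- synth_config("linear", "pH_total", imposed_flux = 2.5e-4,
                       delta_cbl_true = 800, noise_sd = 0, seed = 1)
  rp <- profile_pipeline(make_profile(cfgp)$profile)
  expect_equal(rp$flux$flux_J, 2.5e-4, tolerance = 2.5e-4 * 0.01)
})

test_that("a profile sitting at bulk yields ~zero flux and an undefined CBL", {
  cfg <- synth_config("linear", "oxygen", imposed_flux = 0,
                      delta_cbl_true = 800, noise_sd = 0, seed = 1)
  r <- profile_pipeline(make_profile(cfg)$profile)
  expect_equal(r$flux$flux_J, 0)
  expect_identical(r$flux$flag, "flat")
  expect_identical(r$cbl$flag, "undefined_thickness")
  expect_true(is.na(r$cbl$delta_cbl))
})

test_that("pipeline stage errors carry the stage name", {
  p <- mk_profile(c(0, 100, 200), c(6, 6, 6))   # no external bulk
  expect_error(profile_pipeline(p), "standardize")
})
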