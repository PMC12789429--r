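mk_surface <- function(value, condition, analyte = "pH_total",
                       species = "P_acuta", genotype = "G1",
                       treatment = "control") {
  structure(list(profile_id = paste0("p_", condition), species = species,
                 genotype = genotype, treatment = treatment,
                 condition = condition, analyte = analyte, value = value),
            class = "surface_record")
}

test_that("diel surface oscillation is light minus dark", {
  d <- diel_delta(mk_surface(8.12, "light"), mk_surface(7.10, "dark"))
  expect_equal(d$delta, 1.02)
  expect_equal(diel_delta(mk_surface(7.5, "light"),
                          mk_surface(7.5, "dark"))$delta, 0)
  expect_error(diel_delta(mk_surface(8.1, "light", species = "P_acuta"),
                          mk_surface(7.1, "dark",
                                     species = "M_capitata")),
               "species")
  expect_error(diel_delta(mk_surface(8.1, "dark"),
                          mk_surface(7.1, "dark")), "pair")
})

test_that("an imposed diel surface oscillation survives the pipeline", {
  # dark surface pH 7.10 vs light 7.64: imposed delta = 0.54
  mk <- function(surface, condition, seed) {
    cfg <- synth_config("loglinear", "pH_total", surface = surface,
                        delta_cbl_true = 800, bulk = 7.97,
                        condition = condition, species = "P_acuta",
                        seed = seed)
    surface_record(profile_pipeline(make_profile(cfg)$profile))
  }
  deltas <- vapply(1:5, function(s)
    diel_delta(mk(7.64, "light", s), mk(7.10, "dark", s + 500))$delta,
    numeric(1))
  expect_lt(abs(mean(deltas) - 0.54), 0.05)
})

test_that("calcification rate is buoyant weight change over days", {
  expect_equal(calcification_rate(108, 110.09, 19), 0.11)
  expect_equal(calcification_rate(200, 200, 19), 0)
  # group means: a 0.11 g/d offset between groups is recovered exactly
  g1 <- calcification_rate(c(108, 252, 177), c(110.09, 254.09, 179.09), 19)
  g2 <- calcification_rate(c(108, 252, 177), c(108, 252, 177), 19)
  expect_equal(mean(g1) - mean(g2), 0.11)
  expect_error(calcification_rate(108, 110, 0), "days")
  expect_error(calcification_rate(-1, 110, 19), "weights")
})

test_that("Yeo-Johnson transform matches its analytic special cases", {
  x <- c(-2.5, -0.3, 0, 0.4, 3)
  expect_equal(as.numeric(yeo_johnson(c(0, 0.4, 3), lambda = 1)),
               c(0, 0.4, 3))
  for (l in c(-1, 0, 0.5, 2))
    expect_equal(as.numeric(yeo_johnson(0, lambda = l)), 0)
  expect_equal(as.numeric(yeo_johnson(c(0.5, 2), lambda = 0)),
               log(c(1.5, 3)))
  expect_equal(as.numeric(yeo_johnson(c(-0.5, -2), lambda = 2)),
               -log(c(1.5, 3)))
})

test_that("Yeo-Johnson agrees with the car implementation", {
  x <- c(-3.2, -1.1, -0.01, 0, 0.2, 1.7, 4.4)
  for (l in c(-0.5, 0, 0.7, 1, 2, 2.3))
    expect_equal(as.numeric(yeo_johnson(x, lambda = l)),
                 car::yjPower(x, l), tolerance = 1e-10)
  # ML lambda on near-normal data stays near the identity transform
  set.seed(42)
  z <- rnorm(200, mean = 1)
  expect_lt(abs(attr(yeo_johnson(z), "lambda") - 1), 0.5)
})

test_that("null data yields no significant terms or contrasts", {
  df <- expand.grid(species = c("A", "B"), treatment = c("c", "t"),
                    condition = c("l", "d"), rep = 1:3,
                    stringsAsFactors = FALSE)
  df$y <- 5
  fc <- factorial_compare(df, "y")
  expect_true(all(fc$anova_table$F[fc$anova_table$term != "Residuals"]
                  == 0))
  expect_true(all(fc$anova_table$p[fc$anova_table$term != "Residuals"]
                  == 1))
  expect_true(all(fc$contrasts$adjusted_p == 1))
})

test_that("two balanced groups give F equal to the squared t statistic", {
  set.seed(7)
  df <- data.frame(treatment = rep(c("control", "high_pCO2"), each = 8),
                   y = rnorm(16, mean = rep(c(0, 1), each = 8)))
  fc <- factorial_compare(df, "y", factors = "treatment")
  t2 <- unname(t.test(y ~ treatment, data = df, var.equal = TRUE)
               $statistic^2)
  F <- fc$anova_table$F[fc$anova_table$term == "treatment"]
  expect_lt(abs(F / t2 - 1), 1e-8)
})

test_that("Bonferroni adjustment dominates raw p-values and caps at one", {
  set.seed(21)
  df <- expand.grid(species = c("A", "B"), treatment = c("c", "t"),
                    condition = c("l", "d"), rep = 1:3,
                    stringsAsFactors = FALSE)
  df$y <- rnorm(nrow(df))
  fc <- factorial_compare(df, "y")
  raw <- summary(emmeans::contrast(
    emmeans::emmeans(fc$model, ~ species * treatment * condition),
    method = "pairwise", adjust = "none"))$p.value
  expect_true(all(fc$contrasts$adjusted_p >= raw - 1e-12))
  expect_true(all(fc$contrasts$adjusted_p <= 1))
  expect_equal(fc$contrasts$adjusted_p,
               pmin(1, raw * length(raw)), tolerance = 1e-10)
})

test_that("the ANOVA table is invariant to factor-level relabeling", {
  set.seed(33)
  df <- expand.grid(species = c("A", "B"), treatment = c("c", "t"),
                    condition = c("l", "d"), rep = 1:3,
                    stringsAsFactors = FALSE)
  df$y <- rnorm(nrow(df), mean = as.integer(df$species == "A"))
  f1 <- factorial_compare(df, "y")
  df2 <- df
  df2$species <- c(A = "Zspecies1", B = "species2")[df2$species]
  f2 <- factorial_compare(df2, "y")
  expect_equal(f1$anova_table$F, f2$anova_table$F, tolerance = 1e-10)
  expect_equal(f1$anova_table$p, f2$anova_table$p, tolerance = 1e-10)
})

test_that("empty design cells are reported by name", {
  df <- expand.grid(species = c("A", "B"), treatment = c("c", "t"),
                    rep = 1:2, stringsAsFactors = FALSE)
  df$y <- rnorm(nrow(df))
  df <- df[!(df$species == "B" & df$treatment == "t"), ]
  expect_error(factorial_compare(df, "y",
                                 factors = c("species", "treatment")),
               "B:t")
})

test_that("the Yeo-Johnson option records its fitted lambda", {
  set.seed(5)
  df <- expand.grid(species = c("A", "B"), treatment = c("c", "t"),
                    rep = 1:6, stringsAsFactors = FALSE)
  df$y <- exp(rnorm(nrow(df))) - 0.5   # skewed, mixed sign
  fc <- factorial_compare(df, "y", factors = c("species", "treatment"),
                          transform = "yeo_johnson")
  expect_identical(fc$transformation_used$name, "yeo_johnson")
  expect_true(is.finite(fc$transformation_used$lambda))
})
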