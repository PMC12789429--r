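# Surface diel-oscillation metrics, buoyant-weight calcification rates, and
# factorial linear-model comparisons with Bonferroni pairwise contrasts.

#' Extract the surface record of a processed profile
#'
#' The surface value is the averaged, bulk-standardized reading at height 0
#' (raw sensor units: pH_T or O2 mg L-1), with the metadata needed to pair
#' light and dark measurements.
#'
#' @param p an averaged, standardized [micro_profile()], or a
#'   `profile_result` from [profile_pipeline()].
#' @return An object of class `surface_record` with `profile_id`,
#'   `species`, `genotype`, `treatment`, `condition`, `analyte`, `value`.
#' @export
surface_record <- function(p) {
  if (inherits(p, "profile_result")) p <- p$profile
  stopifnot(inherits(p, "micro_profile"))
  if (!p$averaged || !p$standardized)
    stop("surface_record: profile must be averaged and standardized",
         call. = FALSE)
  structure(list(profile_id = p$profile_id, species = p$species,
                 genotype = p$genotype, treatment = p$treatment,
                 condition = p$condition, analyte = p$analyte,
                 value = p$readings[[1L]][1L]),
            class = "surface_record")
}

#' @export
print.surface_record <- function(x, ...) {
  cat(sprintf("Surface (0 um) %s = %.4g  [%s %s %s %s]\n", x$analyte,
              x$value, x$species, x$genotype, x$treatment, x$condition))
  invisible(x)
}

#' Diel surface oscillation between paired light and dark profiles
#'
#' Computes `delta = light value - dark value` for a pair of surface
#' records sharing species, genotype, treatment and analyte.
#'
#' @param light,dark [surface_record()]s measured under light and dark
#'   conditions respectively.
#' @return A list with `analyte` and `delta` (pH_T units or O2 mg L-1).
#' @export
diel_delta <- function(light, dark) {
  stopifnot(inherits(light, "surface_record"),
            inherits(dark, "surface_record"))
  for (f in c("species", "genotype", "treatment", "analyte"))
    if (!identical(light[[f]], dark[[f]]))
      stop("diel_delta: light/dark records differ in ", f, " ('",
           light[[f]], "' vs '", dark[[f]], "')", call. = FALSE)
  if (light$condition != "light" || dark$condition != "dark")
    stop("diel_delta: records must be a (light, dark) pair; got ('",
         light$condition, "', '", dark$condition, "')", call. = FALSE)
  list(analyte = light$analyte, delta = light$value - dark$value)
}

#' Calcification rate from buoyant weights
#'
#' @param w_initial,w_final buoyant weights in g at the start and end of
#'   the exposure.
#' @param days exposure duration in days (the study design uses 19).
#' @return Calcification rate in g CaCO3 per day,
#'   `(w_final - w_initial) / days`. Vectorized.
#' @export
calcification_rate <- function(w_initial, w_final, days = 19) {
  if (any(!is.finite(days)) || any(days <= 0))
    stop("calcification_rate: days must be positive", call. = FALSE)
  if (any(w_initial < 0) || any(w_final < 0))
    stop("calcification_rate: weights must be >= 0", call. = FALSE)
  (w_final - w_initial) / days
}

#' Yeo-Johnson power transformation
#'
#' The Yeo-Johnson family extends the Box-Cox transformation to negative
#' values: for `x >= 0`, `((x+1)^lambda - 1)/lambda` (or `log(x+1)` at
#' `lambda = 0`); for `x < 0`, `-(((1-x)^(2-lambda) - 1)/(2-lambda))` (or
#' `-log(1-x)` at `lambda = 2`). When `lambda` is not supplied it is
#' estimated by maximizing the normal profile log-likelihood over
#' `[-3, 3]`.
#'
#' @param x numeric vector of finite values.
#' @param lambda transformation parameter, or `NULL` to estimate it.
#' @return The transformed vector, with the lambda used attached as
#'   attribute `"lambda"`.
#' @export
yeo_johnson <- function(x, lambda = NULL) {
  if (!all(is.finite(x))) stop("yeo_johnson: x must be finite",
                               call. = FALSE)
  if (is.null(lambda)) {
    ll <- function(l) {
      z <- yj_apply(x, l)
      n <- length(x)
      -n / 2 * log(sum((z - mean(z))^2) / n) +
        (l - 1) * sum(sign(x) * log(abs(x) + 1))
    }
    lambda <- stats::optimize(ll, c(-3, 3), maximum = TRUE)$maximum
  }
  if (!is.finite(lambda)) stop("yeo_johnson: lambda must be finite",
                               call. = FALSE)
  structure(yj_apply(x, lambda), lambda = lambda)
}

yj_apply <- function(x, l) {
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- if (abs(l) < 1e-10) log(x[pos] + 1)
              else ((x[pos] + 1)^l - 1) / l
  out[!pos] <- if (abs(l - 2) < 1e-10) -log(1 - x[!pos])
               else -(((1 - x[!pos])^(2 - l) - 1) / (2 - l))
  out
}

#' Factorial linear-model comparison with Bonferroni pairwise contrasts
#'
#' Fits an ordinary least squares model of a response on up to three
#' crossed factors (species, treatment, light/dark condition), produces an
#' ANOVA table (Type II sums of squares by default) and all pairwise
#' contrasts between factor-level cells via estimated marginal means with
#' Bonferroni adjustment. Genotype is not modelled (no random effects); it
#' can be kept in `data` for external checks.
#'
#' @param data data frame holding the response and factor columns.
#' @param response name of the response column.
#' @param factors character vector of factor column names (each with >= 2
#'   levels present).
#' @param interactions logical; fit the full factorial (`TRUE`, default)
#'   or the additive model.
#' @param ss_type ANOVA sum-of-squares type, 2 (default) or 3.
#' @param transform `"none"` or `"yeo_johnson"`; the latter applies
#'   [yeo_johnson()] with maximum-likelihood lambda to the response before
#'   fitting, as is conventional when flux residuals (which span both
#'   signs) deviate from normality.
#' @param alpha significance level recorded on the result (default 0.05).
#' @return An object of class `factorial_comparison` with elements `model`,
#'   `anova_table` (term, df, F, p), `emmeans` (cell estimated marginal
#'   means), `contrasts` (pairwise contrasts with Bonferroni-adjusted p),
#'   `transformation_used`, `ss_type`, `alpha`.
#' @export
factorial_compare <- function(data, response,
                              factors = c("species", "treatment",
                                          "condition"),
                              interactions = TRUE, ss_type = 2,
                              transform = c("none", "yeo_johnson"),
                              alpha = 0.05) {
  transform <- match.arg(transform)
  stopifnot(is.data.frame(data), response %in% names(data))
  missing_f <- setdiff(factors, names(data))
  if (length(missing_f))
    stop("factorial_compare: factor column(s) not in data: ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  df <- data
  for (f in factors) {
    df[[f]] <- factor(df[[f]])
    if (nlevels(df[[f]]) < 2)
      stop("factorial_compare: factor '", f, "' has fewer than 2 levels",
           call. = FALSE)
  }
  if (interactions && length(factors) > 1) {
    cells <- table(df[factors])
    if (any(cells == 0)) {
      empty <- which(cells == 0, arr.ind = TRUE)
      lab <- apply(empty, 1L, function(i)
        paste(mapply(function(f, j) dimnames(cells)[[f]][j],
                     seq_along(factors), i), collapse = ":"))
      stop("factorial_compare: empty design cell(s) with interactions: ",
           paste(lab, collapse = ", "), call. = FALSE)
    }
  }
  lambda <- NULL
  if (transform == "yeo_johnson") {
    yj <- yeo_johnson(df[[response]])
    lambda <- attr(yj, "lambda")
    df[[response]] <- as.numeric(yj)
  }
  op <- if (interactions) " * " else " + "
  fml <- stats::as.formula(paste(response, "~",
                                 paste(factors, collapse = op)))
  contr <- if (ss_type == 3)
    stats::setNames(rep(list("contr.sum"), length(factors)), factors)
  else NULL
  # fit on a unit-variance response so that tiny absolute scales (proton
  # flux is ~1e-5) do not trip rank/rounding checks; F, t and p are
  # invariant, and estimates are rescaled back below
  scale_y <- stats::sd(df[[response]])
  const_y <- !is.finite(scale_y) || scale_y == 0   # degenerate response
  if (const_y) scale_y <- 1
  df[[response]] <- df[[response]] / scale_y
  fit <- stats::lm(fml, data = df, contrasts = contr)
  quiet <- if (const_y) suppressWarnings else identity
  an <- quiet(tryCatch(car::Anova(fit, type = ss_type),
                       error = function(e) stats::anova(fit)))
  anova_table <- data.frame(term = rownames(an), df = an$Df,
                            sum_sq = an$`Sum Sq` * scale_y^2,
                            F = an$`F value`,
                            p = an$`Pr(>F)`, stringsAsFactors = FALSE)
  # a perfectly constant response has F = 0/0 (up to floating-point noise
  # from the QR decomposition); report it as no evidence
  degen <- anova_table$term != "Residuals" &
    (const_y | (!is.finite(anova_table$F) &
                  anova_table$sum_sq <= 1e-12))
  anova_table$F[degen] <- 0
  anova_table$p[degen] <- 1
  spec <- stats::as.formula(paste("~", paste(factors, collapse = " * ")))
  emm <- quiet(emmeans::emmeans(fit, spec))
  emm_df <- as.data.frame(emm)
  for (col in c("emmean", "SE", "lower.CL", "upper.CL"))
    if (col %in% names(emm_df)) emm_df[[col]] <- emm_df[[col]] * scale_y
  ctr <- quiet(summary(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "bonferroni")))
  contrasts <- data.frame(pair = as.character(ctr$contrast),
                          estimate = ctr$estimate * scale_y,
                          se = ctr$SE * scale_y,
                          df = ctr$df, t = ctr$t.ratio,
                          adjusted_p = ctr$p.value,
                          stringsAsFactors = FALSE)
  dctr <- const_y |
    (!is.finite(contrasts$adjusted_p) & abs(contrasts$estimate) <=
       1e-12 & contrasts$se <= 1e-12)
  contrasts$estimate[dctr & abs(contrasts$estimate) <= 1e-12] <- 0
  contrasts$t[dctr] <- 0
  contrasts$adjusted_p[dctr] <- 1
  structure(
    list(model = fit, formula = fml, anova_table = anova_table,
         emmeans = emm_df, contrasts = contrasts,
         transformation_used = if (is.null(lambda)) "none"
           else list(name = "yeo_johnson", lambda = lambda),
         ss_type = ss_type, alpha = alpha),
    class = "factorial_comparison")
}

#' @export
print.factorial_comparison <- function(x, ...) {
  cat("Factorial comparison: ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("Type %s ANOVA; alpha = %g; transformation: %s\n",
              x$ss_type, x$alpha,
              if (is.character(x$transformation_used)) "none"
              else sprintf("Yeo-Johnson (lambda = %.3f)",
                           x$transformation_used$lambda)))
  tab <- x$anova_table
  tab$F <- signif(tab$F, 4); tab$p <- signif(tab$p, 4)
  print(tab, row.names = FALSE)
  sig <- x$contrasts[!is.na(x$contrasts$adjusted_p) &
                       x$contrasts$adjusted_p < x$alpha, , drop = FALSE]
  cat(sprintf("%d of %d Bonferroni pairwise contrasts significant at alpha = %g\n",
              nrow(sig), nrow(x$contrasts), x$alpha))
  invisible(x)
}

#' @export
summary.factorial_comparison <- function(object, ...) {
  print(object)
  cat("\nEstimated marginal means:\n")
  print(object$emmeans, row.names = FALSE)
  cat("\nPairwise contrasts (Bonferroni):\n")
  ctr <- object$contrasts
  ctr$estimate <- signif(ctr$estimate, 4)
  ctr$adjusted_p <- signif(ctr$adjusted_p, 4)
  print(ctr[c("pair", "estimate", "adjusted_p")], row.names = FALSE)
  invisible(object)
}
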