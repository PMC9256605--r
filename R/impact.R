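#' Relative potential impact
#'
#' Combines community sensitivity and exposure into the exposure-sensitivity
#' part of the vulnerability framework: each component is placed on \[0, 1\]
#' and the potential impact is the Euclidean distance of the pair from the
#' origin. Exposure is first converted to a loss (`max(0, -E)`, so projected
#' gains contribute zero harm) and each component min-max scaled across the
#' community set, unless explicit bounds are supplied.
#'
#' @param sensitivity Numeric vector of sensitivity scores, one per community.
#' @param exposure Numeric vector of percent changes (negative = loss).
#' @param bounds Optional list with `sensitivity = c(lo, hi)` and
#'   `loss = c(lo, hi)` fixing the scaling instead of the observed min-max.
#'   Required when fewer than 2 communities are scored, or when a component
#'   has zero range.
#' @param scale If `"minmax"` (default) components are rescaled as described;
#'   `"none"` uses the raw values (sensitivity as-is, loss = `max(0, -E)`).
#' @return Data frame: `scaled_sensitivity`, `scaled_exposure_loss`,
#'   `potential_impact` (in \[0, sqrt(2)\] under min-max scaling).
#' @examples
#' potential_impact(0.3, -40, bounds = list(sensitivity = c(0, 1),
#'                                          loss = c(0, 100)))
#' @export
potential_impact <- function(sensitivity, exposure, bounds = NULL,
                             scale = c("minmax", "none")) {
  scale <- match.arg(scale)
  stopifnot(length(sensitivity) == length(exposure))
  loss <- pmax(0, -exposure)
  rescale <- function(x, b) {
    if (!is.null(b)) return(pmin(1, pmax(0, (x - b[1]) / (b[2] - b[1]))))
    if (length(x) < 2L)
      stop("min-max scaling needs >= 2 communities; supply `bounds`")
    rng <- range(x)
    if (diff(rng) == 0)
      stop("component has zero range across communities; supply `bounds`")
    (x - rng[1]) / diff(rng)
  }
  if (scale == "minmax") {
    s <- rescale(sensitivity, bounds$sensitivity)
    l <- rescale(loss, bounds$loss)
  } else {
    s <- sensitivity; l <- loss
  }
  data.frame(scaled_sensitivity = s, scaled_exposure_loss = l,
             potential_impact = sqrt(s^2 + l^2))
}

#' Double burden of simultaneous sector losses
#'
#' A community bears a double burden when both its fisheries and agriculture
#' exposures are projected losses (both strictly negative).
#'
#' @param e_a,e_f Signed percent changes for agriculture and fisheries.
#' @return Logical vector.
#' @export
double_burden <- function(e_a, e_f) (e_a < 0) & (e_f < 0)

#' @rdname double_burden
#' @param flags Logical vector of double-burden flags.
#' @return `double_burden_rate`: fraction of communities flagged.
#' @export
double_burden_rate <- function(flags) mean(flags)

#' Mixed-effects mean with a country random intercept
#'
#' Estimates the average of a community-level quantity across countries with a
#' random-intercept model `value ~ 1 + (1 | country)` (REML), reporting the
#' fixed intercept, its standard error, and the Satterthwaite t-test of the
#' intercept against zero. Singular or failed fits fall back to the mean of
#' country means with a t-test across countries (with a warning).
#'
#' @param values Numeric vector (one per community).
#' @param country Grouping labels.
#' @return List of class `mixed_mean`: `estimate`, `se`, `t`, `df`, `p`,
#'   `sd_country`, `sd_resid`, `method`.
#' @export
mixed_mean <- function(values, country) {
  country <- as.factor(country)
  if (nlevels(country) < 2L) stop("need communities from at least 2 countries")
  d <- data.frame(y = values, country = country)
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lmerTest::lmer(y ~ 1 + (1 | country), data = d))),
    error = function(e) NULL)
  if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
    co <- suppressWarnings(stats::coef(summary(fit)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    return(structure(list(estimate = co[1, "Estimate"],
                          se = co[1, "Std. Error"], t = co[1, "t value"],
                          df = co[1, "df"], p = co[1, "Pr(>|t|)"],
                          sd_country = vc$sdcor[vc$grp == "country"],
                          sd_resid = vc$sdcor[vc$grp == "Residual"],
                          method = "lmm"), class = "mixed_mean"))
  }
  warning("singular or failed mixed-model fit; using mean of country means")
  cm <- tapply(d$y, d$country, mean)
  k <- length(cm)
  se <- stats::sd(cm) / sqrt(k)
  est <- mean(cm)
  t <- if (se > 0) est / se else NA_real_
  structure(list(estimate = est, se = se, t = t, df = k - 1,
                 p = if (is.na(t)) NA_real_ else
                   2 * stats::pt(-abs(t), k - 1),
                 sd_country = stats::sd(cm), sd_resid = NA_real_,
                 method = "country_means"), class = "mixed_mean")
}

#' @export
print.mixed_mean <- function(x, ...) {
  cat(sprintf("mixed mean: %.4g +/- %.4g (SE); t = %.3g, df = %.3g, p = %.3g [%s]\n",
              x$estimate, x$se, x$t, x$df, x$p, x$method))
  invisible(x)
}

#' Paired difference between sector exposures
#'
#' Tests whether fisheries and agriculture exposure differ while keeping the
#' paired structure: the per-community difference (`e_f - e_a`) is the
#' response of a country random-intercept model, and the intercept is tested
#' against zero.
#'
#' @param e_f,e_a Per-community percent changes (aligned).
#' @param country Grouping labels.
#' @return A `mixed_mean` result for the difference.
#' @export
paired_sector_difference <- function(e_f, e_a, country) {
  stopifnot(length(e_f) == length(e_a))
  mixed_mean(e_f - e_a, country)
}

#' Cohen's D standardized mean difference
#'
#' `(mean(a) - mean(b)) / s_pooled`, with the pooled SD weighting each group's
#' variance by its degrees of freedom.
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @return Scalar effect size (positive when `a` has the larger mean).
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 values")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) stop("pooled standard deviation is zero")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Random sample of populated coastal cells
#'
#' Filters the population grid to coastal cells with density strictly above
#' the threshold and draws a fixed fraction of them without replacement,
#' reproducibly by seed. Mirrors the reference-site construction used to test
#' whether surveyed sites are exposure-biased relative to the coast at large.
#'
#' @param pop A population grid (see [generate_population_grid()]) or any list
#'   with `lat`, `lon`, `density`, `coastal`.
#' @param threshold Minimum density, exclusive (default 25 people/km^2).
#' @param fraction Fraction of eligible cells to draw (default 0.1).
#' @param seed Integer seed.
#' @return Data frame `site_id`, `lat`, `lon`, `density`; attribute
#'   `"n_eligible"` records the eligible-cell count.
#' @export
random_coastal_sample <- function(pop, threshold = 25, fraction = 0.1, seed = 1L) {
  elig <- which(pop$coastal & pop$density > threshold, arr.ind = TRUE)
  if (nrow(elig) == 0L) stop("no coastal cells exceed the density threshold")
  n <- floor(fraction * nrow(elig))
  if (n < 1L) stop("fraction too small: no cells drawn")
  pick <- with_seed(seed, sample.int(nrow(elig), n))
  out <- data.frame(site_id = sprintf("R%05d", seq_len(n)),
                    lat = pop$lat[elig[pick, 1]], lon = pop$lon[elig[pick, 2]],
                    density = pop$density[elig[pick, , drop = FALSE]])
  attr(out, "n_eligible") <- nrow(elig)
  out
}

# Internal: Nakagawa variance-decomposition R2 for a gaussian lmer fit.
nakagawa_r2 <- function(fit) {
  var_f <- stats::var(as.vector(stats::model.matrix(fit) %*% lme4::fixef(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_r <- sum(vc$vcov[vc$grp != "Residual"])
  var_e <- vc$vcov[vc$grp == "Residual"]
  c(marginal = var_f / (var_f + var_r + var_e),
    conditional = (var_f + var_r) / (var_f + var_r + var_e))
}

#' Wealth-impact mixed regression with bootstrap standard errors
#'
#' Regresses potential impact on the scaled material-style-of-life score with
#' a country random intercept; the slope's standard error comes from a
#' nonparametric bootstrap that resamples communities within country
#' (stratified, so every resample retains all countries). Marginal and
#' conditional R-squared follow the standard variance-decomposition
#' definitions for mixed models.
#'
#' @param msl Scaled community wealth scores.
#' @param impact Potential-impact scores (or any community response).
#' @param country Grouping labels.
#' @param n_boot Bootstrap replications (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return List of class `impact_regression`: `slope`, `intercept`, `se_boot`,
#'   `p`, `r2_marginal`, `r2_conditional`, `n_boot`.
#' @export
msl_impact_regression <- function(msl, impact, country, n_boot = 1000, seed = 1L) {
  country <- as.factor(country)
  if (nlevels(country) < 2L) stop("need at least 2 countries")
  if (length(msl) < 10L) stop("need at least 10 communities")
  d <- data.frame(y = impact, x = msl, country = country)
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(y ~ x + (1 | country), data = d)))
  slope <- lme4::fixef(fit)[["x"]]
  intercept <- lme4::fixef(fit)[["(Intercept)"]]
  r2 <- nakagawa_r2(fit)

  idx_by_country <- split(seq_len(nrow(d)), d$country)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- unlist(lapply(idx_by_country, function(ix)
      ix[sample.int(length(ix), length(ix), replace = TRUE)]))
    bf <- tryCatch(suppressMessages(suppressWarnings(
      lme4::lmer(y ~ x + (1 | country), data = d[idx, ]))),
      error = function(e) NULL)
    if (is.null(bf)) NA_real_ else lme4::fixef(bf)[["x"]]
  }, numeric(1)))
  se <- stats::sd(boots, na.rm = TRUE)
  z <- slope / se
  structure(list(slope = slope, intercept = intercept, se_boot = se,
                 p = 2 * stats::pnorm(-abs(z)),
                 r2_marginal = unname(r2["marginal"]),
                 r2_conditional = unname(r2["conditional"]),
                 n_boot = sum(!is.na(boots))),
            class = "impact_regression")
}

#' @export
print.impact_regression <- function(x, ...) {
  cat(sprintf("slope %.4g +/- %.4g (bootstrap SE, n = %d); p = %.3g; R2 m = %.3f, c = %.3f\n",
              x$slope, x$se_boot, x$n_boot, x$p, x$r2_marginal,
              x$r2_conditional))
  invisible(x)
}
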