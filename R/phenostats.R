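.trait_column <- function(trait) {
  switch(trait,
         heading = "heading_days",
         aftermath = "aftermath_score",
         stop("unknown trait: ", trait))
}

.pheno_records <- function(pheno, trait) {
  col <- .trait_column(trait)
  df <- data.frame(genotype_id = pheno$genotype_id,
                   year = pheno$year,
                   replicate = pheno$replicate,
                   value = pheno[[col]])
  df[!is.na(df$value), , drop = FALSE]
}

#' Variance components for a trait
#'
#' One-random-effect mixed model with genotype random and year fixed
#' (year is dropped automatically when the trait was scored in a single
#' year, as aftermath heading was), fitted by REML with \pkg{lme4}.
#' `n_bar` is the harmonic mean of per-genotype record counts, the
#' effective replication entering line-mean heritability.
#'
#' @param pheno a `phenotype_table`
#' @param trait `"heading"` or `"aftermath"`
#' @return a `variance_components` list: `sigma2_g`, `sigma2_e`,
#'   `fixed_effects`, `n_bar`, `n_genotypes`, `model`
#' @export
variance_components <- function(pheno, trait = "heading") {
  df <- .pheno_records(pheno, trait)
  counts <- table(df$genotype_id)
  if (max(counts) < 2) {
    stop("sigma2_g is unidentifiable: no genotype has more than one record")
  }
  multi_year <- length(unique(df$year)) > 1
  form <- if (multi_year) value ~ 1 + factor(year) + (1 | genotype_id) else
    value ~ 1 + (1 | genotype_id)
  fit <- lme4::lmer(form, data = df, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2_g <- vc$vcov[vc$grp == "genotype_id"]
  sigma2_e <- vc$vcov[vc$grp == "Residual"]
  structure(list(sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 fixed_effects = lme4::fixef(fit),
                 n_bar = length(counts) / sum(1 / as.numeric(counts)),
                 n_genotypes = length(counts),
                 model = fit),
            class = "variance_components")
}

#' Line-mean heritability
#'
#' `H2 = sigma2_g / (sigma2_g + sigma2_e / n_bar)`: the repeatability of
#' genotype means over `n_bar` records.
#'
#' @param vc a `variance_components` object (or a list with `sigma2_g`,
#'   `sigma2_e`, `n_bar`)
#' @return heritability in `[0, 1]`
#' @export
line_mean_h2 <- function(vc) {
  if (vc$sigma2_g + vc$sigma2_e <= 0) {
    stop("heritability undefined: both variance components are zero")
  }
  vc$sigma2_g / (vc$sigma2_g + vc$sigma2_e / vc$n_bar)
}

#' Conditional means (BLUPs) per genotype
#'
#' Fixed-effect-adjusted best linear unbiased predictions of the
#' genotype effects plus the intercept level: the shrunken genotype
#' means used as the per-genotype phenotype in the marker scans. Year
#' effects are averaged over the scored years.
#'
#' @param pheno a `phenotype_table`
#' @param trait `"heading"` or `"aftermath"`
#' @return named numeric vector keyed by genotype id
#' @export
conditional_means <- function(pheno, trait = "heading") {
  vc <- variance_components(pheno, trait)
  fe <- vc$fixed_effects
  year_terms <- grep("^factor\\(year\\)", names(fe))
  # treatment contrasts: reference year contributes 0
  mu <- fe[["(Intercept)"]] +
    if (length(year_terms) > 0) sum(fe[year_terms]) / (length(year_terms) + 1)
    else 0
  re <- lme4::ranef(vc$model)$genotype_id
  stats::setNames(mu + re[["(Intercept)"]], rownames(re))
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param x,y numeric vectors; incomplete pairs are dropped
#' @param level confidence level, default 0.95
#' @return list with `r`, `ci_low`, `ci_high`, `n`
#' @export
pearson_with_ci <- function(x, y, level = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for zero-variance input")
  }
  ct <- stats::cor.test(x, y, conf.level = level)
  list(r = unname(ct$estimate), ci_low = ct$conf.int[1],
       ci_high = ct$conf.int[2], n = length(x))
}

#' Between-year correlation of a trait
#'
#' Pearson correlation of genotype values between the first and last
#' scored year, either on genotype means over replicates (default, the
#' scale of the published estimate) or on plant-level records matched by
#' genotype and replicate.
#'
#' @param pheno a `phenotype_table`
#' @param trait trait name
#' @param level confidence level
#' @param scale `"genotype_mean"` or `"plant"`
#' @return list as in [pearson_with_ci()]
#' @export
year_correlation <- function(pheno, trait = "heading", level = 0.95,
                             scale = c("genotype_mean", "plant")) {
  scale <- match.arg(scale)
  df <- .pheno_records(pheno, trait)
  years <- sort(unique(df$year))
  if (length(years) < 2) stop("trait was scored in a single year")
  y1 <- df[df$year == years[1], ]
  y2 <- df[df$year == years[length(years)], ]
  if (scale == "genotype_mean") {
    m1 <- tapply(y1$value, y1$genotype_id, mean)
    m2 <- tapply(y2$value, y2$genotype_id, mean)
    ids <- intersect(names(m1), names(m2))
    pearson_with_ci(m1[ids], m2[ids], level)
  } else {
    k1 <- paste(y1$genotype_id, y1$replicate)
    k2 <- paste(y2$genotype_id, y2$replicate)
    ids <- intersect(k1, k2)
    pearson_with_ci(y1$value[match(ids, k1)], y2$value[match(ids, k2)], level)
  }
}

#' One-way ANOVA F-test
#'
#' Standard one-way decomposition (used for the replicate-effect check
#' on aftermath scores).
#'
#' @param values numeric response
#' @param groups group labels (at least 2 non-empty groups)
#' @return list with `F`, `df1`, `df2`, `MSE` (residual mean square), `p`
#' @export
oneway_f_test <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(factor(groups[ok]))
  if (nlevels(groups) < 2) stop("need at least two non-empty groups")
  a <- stats::anova(stats::lm(values ~ groups))
  list(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
       MSE = a$`Mean Sq`[2], p = a$`Pr(>F)`[1])
}

#' Simple linear regression with a slope t-test
#'
#' Ordinary least squares of `y` on `x` (e.g. aftermath heading on
#' heading date, where a negative slope means earlier-heading plants
#' show stronger aftermath heading).
#'
#' @param y response
#' @param x predictor
#' @return list with `slope`, `intercept`, `se_slope`, `p_slope`, `n`
#' @export
regress <- function(y, x) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("constant predictor")
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  list(slope = cf["x", "Estimate"], intercept = cf["(Intercept)", "Estimate"],
       se_slope = cf["x", "Std. Error"], p_slope = cf["x", "Pr(>|t|)"],
       n = length(x))
}
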