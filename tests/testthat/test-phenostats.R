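# balanced records: n_genotypes genotypes x 2 years x 2 reps with known
# variance components
sim_balanced_pheno <- function(n_genotypes, sigma_g = 1, sigma_e = 1,
                               year_gap = 2, seed = 1) {
  set.seed(seed)
  gval <- rnorm(n_genotypes, 55, sigma_g)
  recs <- expand.grid(replicate = 1:2, year = c(2014, 2015),
                      genotype = seq_len(n_genotypes))
  out <- data.frame(
    genotype_id = sprintf("g%04d", recs$genotype),
    family_id = "F",
    replicate = recs$replicate,
    year = recs$year,
    heading_days = gval[recs$genotype] +
      ifelse(recs$year == 2015, year_gap, 0) +
      rnorm(nrow(recs), 0, sigma_e),
    aftermath_score = NA_integer_)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

test_that("variance components recover the generating values on balanced data", {
  est <- t(sapply(1:11, function(r) {
    ph <- sim_balanced_pheno(360, sigma_g = 1, sigma_e = 1, seed = 130 + r)
    vc <- variance_components(ph, "heading")
    c(vc$sigma2_g, vc$sigma2_e, vc$n_bar)
  }))
  expect_lt(abs(median(est[, 1]) - 1), 0.15)
  expect_lt(abs(median(est[, 2]) - 1), 0.15)
  expect_equal(est[1, 3], 4)  # harmonic mean of 4 records per genotype

  single <- sim_balanced_pheno(50, seed = 131)
  single <- single[single$replicate == 1 & single$year == 2014, ]
  expect_error(variance_components(single, "heading"), "unidentifiable")
})

test_that("line-mean heritability follows its closed form and bounds", {
  vc <- list(sigma2_g = 1, sigma2_e = 1, n_bar = 4)
  expect_equal(line_mean_h2(vc), 0.8)
  expect_equal(line_mean_h2(list(sigma2_g = 1, sigma2_e = 0, n_bar = 2)), 1)
  expect_error(line_mean_h2(list(sigma2_g = 0, sigma2_e = 0, n_bar = 4)),
               "undefined")
  # monotone: increasing sigma2_g raises H2, increasing sigma2_e lowers it
  h <- sapply(c(0.5, 1, 2, 4), function(sg)
    line_mean_h2(list(sigma2_g = sg, sigma2_e = 1, n_bar = 4)))
  expect_false(is.unsorted(h))
  h2 <- sapply(c(0.5, 1, 2, 4), function(se)
    line_mean_h2(list(sigma2_g = 1, sigma2_e = se, n_bar = 4)))
  expect_false(is.unsorted(rev(h2)))
})

test_that("conditional means shrink toward the year-adjusted grand mean", {
  # near-zero residual: conditional means approach raw genotype means
  ph <- sim_balanced_pheno(80, sigma_g = 2, sigma_e = 0.01, seed = 132)
  cm <- suppressWarnings(conditional_means(ph, "heading"))
  raw <- tapply(ph$heading_days - ifelse(ph$year == 2015, 2, 0),
                ph$genotype_id, mean)
  expect_equal(unname(cm[names(raw)]), as.numeric(raw), tolerance = 0.05)

  # near-zero genetic variance: strong shrinkage toward the grand mean
  ph0 <- sim_balanced_pheno(80, sigma_g = 0, sigma_e = 1, seed = 133)
  cm0 <- suppressWarnings(conditional_means(ph0, "heading"))
  raw0 <- tapply(ph0$heading_days - ifelse(ph0$year == 2015, 2, 0),
                 ph0$genotype_id, mean)
  expect_lt(var(cm0), 0.25 * var(as.numeric(raw0)))

  # shrinkage preserves the ranking of raw means
  ph1 <- sim_balanced_pheno(60, sigma_g = 1, sigma_e = 1, seed = 134)
  cm1 <- conditional_means(ph1, "heading")
  raw1 <- tapply(ph1$heading_days - ifelse(ph1$year == 2015, 2, 0),
                 ph1$genotype_id, mean)
  expect_equal(order(cm1[names(raw1)]), order(raw1))
})

test_that("Pearson correlation with Fisher-z interval behaves at the extremes", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_with_ci(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_with_ci(x, -x)$r, -1)
  expect_error(pearson_with_ci(x, rep(2, 5)), "zero-variance")
  expect_error(pearson_with_ci(1:3, 3:1), "4 complete pairs")

  # CI coverage near nominal for rho = 0.8
  set.seed(135)
  cover <- mean(replicate(400, {
    z <- rnorm(300)
    x <- z + rnorm(300, 0, sqrt(1 / 0.8^2 - 1))
    ci <- pearson_with_ci(z, x)
    rho <- 0.8
    ci$ci_low <= rho && rho <= ci$ci_high
  }))
  expect_gt(cover, 0.91)
  expect_lt(cover, 0.99)
})

test_that("between-year correlation reflects the heritable signal scale", {
  ph <- sim_balanced_pheno(300, sigma_g = 2, sigma_e = 1, seed = 136)
  yc <- year_correlation(ph, "heading")
  # genotype means over 2 reps: expected r = 4 / (4 + 1/2)
  expect_lt(abs(yc$r - 4 / 4.5), 0.05)
  expect_lt(yc$ci_low, yc$r)
  expect_gt(yc$ci_high, yc$r)
  yp <- year_correlation(ph, "heading", scale = "plant")
  expect_lt(yp$r, yc$r)  # plant-level records are noisier
})

test_that("one-way ANOVA matches its permutation oracle and the t-test identity", {
  set.seed(137)
  values <- rnorm(24, rep(c(0, 0.7), each = 12))
  groups <- rep(c("r1", "r2"), each = 12)
  ft <- oneway_f_test(values, groups)
  expect_equal(ft$df1, 1)
  expect_equal(ft$df2, 22)
  tt <- t.test(values ~ groups, var.equal = TRUE)
  expect_equal(ft$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(ft$p, tt$p.value, tolerance = 1e-10)

  perm <- replicate(10000, {
    oneway_f_test(values, sample(groups))$F
  })
  p_perm <- mean(perm >= ft$F - 1e-12)
  se <- sqrt(p_perm * (1 - p_perm) / 10000)
  expect_lt(abs(ft$p - p_perm), 3 * se + 5e-3)

  sym <- c(1, 2, 3, 1, 2, 3)
  ft0 <- oneway_f_test(sym, rep(c("a", "b"), each = 3))
  expect_equal(ft0$F, 0)
  expect_equal(ft0$p, 1)
  expect_error(oneway_f_test(1:4, rep("a", 4)), "two non-empty")
})

test_that("the regression slope is exact on noiseless data and detects coupling", {
  x <- c(0, 1, 2, 3, 4)
  fit <- suppressWarnings(regress(2 * x + 1, x))  # perfect-fit warning
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(suppressWarnings(regress(2 * x + 100, x))$slope, 2,
               tolerance = 1e-12)
  expect_error(regress(1:5, rep(1, 5)), "constant")

  # negative aftermath-on-heading coupling is recovered from the generator
  g <- sim_testcross_family(n_markers = 30, n_offspring = 60, seed = 138)
  spec <- qtl_spec(effects = data.frame(lg = 1, pos_cm = 50,
                                        additive_effect = 4,
                                        trait = "heading"),
                   residual_sd = 1, aftermath_coupling = -0.6,
                   aftermath_mean = 5, aftermath_sd = 1)
  neg <- sum(replicate(20, {
    ph <- simulate_phenotypes(g, spec, seed = sample.int(1e6, 1))
    d <- ph[!is.na(ph$aftermath_score), ]
    regress(d$aftermath_score, d$heading_days)$slope < 0
  }))
  expect_gte(neg, 19)
})

test_that("estimation error shrinks with more genotypes", {
  err_at <- function(n, seeds) {
    median(sapply(seeds, function(s) {
      vc <- variance_components(sim_balanced_pheno(n, seed = s), "heading")
      abs(vc$sigma2_g - 1)
    }))
  }
  expect_lt(err_at(360, 201:207), err_at(45, 201:207) + 0.02)
})
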