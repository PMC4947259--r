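test_that("genetic maps are bounded, sorted per linkage group and deterministic", {
  m1 <- make_genetic_map(1, 100, 2, seed = 1)
  expect_equal(nrow(m1), 2)
  expect_true(all(m1$pos_cm >= 0 & m1$pos_cm <= 100))

  m7 <- make_genetic_map(7, 100, 700, seed = 7)
  expect_equal(as.integer(table(m7$lg)), rep(100, 7))
  for (lg in 1:7) {
    expect_false(is.unsorted(m7$pos_cm[m7$lg == lg]))
  }
  expect_identical(m7, make_genetic_map(7, 100, 700, seed = 7))

  expect_error(make_genetic_map(7, -1, 700), "n_lgs")
  expect_error(make_genetic_map(2, 100, 3), "n_lgs")
})

test_that("scaffold assignment keeps physical positions strictly increasing", {
  map <- assign_scaffolds(make_genetic_map(2, 100, 80, seed = 3),
                          scaffolds_per_lg = 5, bp_per_cm = 1e6)
  expect_true(all(c("scaffold", "pos_bp") %in% names(map)))
  for (sc in unique(map$scaffold)) {
    expect_true(all(diff(map$pos_bp[map$scaffold == sc]) > 0))
  }
  # 1 Mb/cM scaling: a 20 cM scaffold spans at most ~20 Mb
  spans <- tapply(map$pos_bp, map$scaffold, function(p) diff(range(p)))
  expect_true(all(spans <= 20e6))
})

test_that("offspring of a hom x het locus segregate ~1:1 het:hom with only two classes", {
  map <- assign_scaffolds(make_genetic_map(1, 50, 10, seed = 2))
  par <- make_parents(map, "F1", cross_mode = "F1_fullsib",
                      config_probs = c(testcross = 1, het_het = 0,
                                       hom_hom = 0), seed = 4)
  g <- simulate_family(par, map, 400, seed = 5)
  for (i in seq_len(n_sites(g))) {
    cnt <- tabulate(g$calls[i, ] + 1L, 3)
    # exactly two classes: one homozygote plus the heterozygote
    expect_equal(sum(cnt > 0), 2)
    expect_true(cnt[2] > 0)
    # binomial(400, 1/2): het fraction within a generous 99.9% band
    expect_gt(cnt[2] / 400, 0.5 - 3.29 * sqrt(0.25 / 400))
    expect_lt(cnt[2] / 400, 0.5 + 3.29 * sqrt(0.25 / 400))
  }
})

test_that("recombination between loci follows Haldane's map function", {
  # two loci 10 cM apart: r = (1 - exp(-0.2)) / 2 = 0.0906
  loci <- data.frame(marker_id = c("a", "b"), lg = 1, pos_cm = c(20, 30),
                     scaffold = "scf_1_01", pos_bp = c(1L, 2L))
  class(loci) <- c("genetic_map", "data.frame")
  par <- make_parents(loci, "F1", cross_mode = "F1_fullsib", seed = 1)
  par$p1 <- matrix(c(1L, 1L, 0L, 0L), 2, 2, byrow = TRUE)  # coupling phase
  par$p2 <- matrix(0L, 2, 2)
  g <- simulate_family(par, loci, 5000, seed = 6)
  h <- attr(g, "haplotypes")$h1  # gametes transmitted by parent 1
  rec <- mean(h[1, ] != h[2, ])
  r_true <- 0.5 * (1 - exp(-0.2))
  se <- sqrt(r_true * (1 - r_true) / 5000)
  expect_lt(abs(rec - r_true), 3 * se)
})

test_that("F2 sib-mated offspring are products of distinct F1 matings", {
  map <- assign_scaffolds(make_genetic_map(1, 60, 30, seed = 9))
  par <- make_parents(map, "F2", cross_mode = "F2_sibmated", seed = 10)
  g <- simulate_family(par, map, 50, seed = 11, n_f1 = 10)
  expect_equal(n_samples(g), 50)
  expect_true(all(g$calls %in% 0:2))
  expect_identical(g$calls,
                   simulate_family(par, map, 50, seed = 11, n_f1 = 10)$calls)
})

test_that("phenotypes are additive in QTL dosage with fixed year effects", {
  calls <- rbind(c(0L, 1L, 2L, 2L, 0L))
  gm <- toy_matrix(calls)
  gm$sites$lg <- 1
  gm$sites$pos_cm <- 10
  # no QTL, no residual: every record is family_mean + year_effect
  spec0 <- qtl_spec(family_mean = 50,
                    year_effects = c(`2014` = 0, `2015` = 3),
                    residual_sd = 0)
  ph0 <- simulate_phenotypes(gm, spec0, years = c(2014, 2015), reps = 2,
                             seed = 1)
  expect_true(all(ph0$heading_days[ph0$year == 2014] == 50))
  expect_true(all(ph0$heading_days[ph0$year == 2015] == 53))

  # one QTL, effect 5 days per allele: dosage 2 minus dosage 0 is 10
  spec1 <- qtl_spec(effects = data.frame(lg = 1, pos_cm = 10,
                                         additive_effect = 5,
                                         trait = "heading"),
                    family_mean = 50, year_effects = c(`2014` = 0),
                    residual_sd = 0)
  ph1 <- simulate_phenotypes(gm, spec1, years = 2014, reps = 1, seed = 1)
  v <- setNames(ph1$heading_days, ph1$genotype_id)
  expect_equal(unname(v["G01_03"] - v["G01_01"]), 10)
  expect_equal(unname(v["G01_02"] - v["G01_01"]), 5)

  expect_error(simulate_phenotypes(gm, spec1, years = numeric(0)), "year")
})

test_that("aftermath scores stay on the 1-9 scale and follow negative coupling", {
  g <- sim_testcross_family(n_markers = 40, n_offspring = 200, seed = 20)
  spec <- qtl_spec(effects = data.frame(lg = 1, pos_cm = 50,
                                        additive_effect = 4,
                                        trait = "heading"),
                   family_mean = 55, year_effects = c(`2014` = 0, `2015` = 3),
                   residual_sd = 1, aftermath_coupling = -0.8,
                   aftermath_mean = 5, aftermath_sd = 0.5)
  ph <- simulate_phenotypes(g, spec, seed = 21)
  aft <- ph$aftermath_score[!is.na(ph$aftermath_score)]
  expect_true(all(aft >= 1 & aft <= 9))
  truth <- attr(ph, "truth")
  expect_lt(cor(truth$g_heading, truth$g_aftermath_latent), -0.5)
})

test_that("generator variance decomposition matches its configured components", {
  # 500 genotypes x 2 years x 2 reps, no QTL: the pooled within-genotype-year
  # replicate variance estimates residual_sd^2 with df = n_genotypes * years
  gm <- toy_matrix(matrix(1L, 1, 500))
  gm$sites$lg <- 1
  gm$sites$pos_cm <- 1
  spec <- qtl_spec(family_mean = 50, year_effects = c(`2014` = 0, `2015` = 2),
                   residual_sd = 3)
  ph <- simulate_phenotypes(gm, spec, years = c(2014, 2015), reps = 2,
                            seed = 31)
  d <- ph[order(ph$genotype_id, ph$year, ph$replicate), ]
  v1 <- d$heading_days[d$replicate == 1]
  v2 <- d$heading_days[d$replicate == 2]
  ss <- sum((v1 - v2)^2 / 2)  # chi-square, df = 1000
  df <- length(v1)
  expect_gt(ss / 9, qchisq(0.005, df))
  expect_lt(ss / 9, qchisq(0.995, df))
})

test_that("GBS noise injection respects its rates and is reversible at zero", {
  g <- sim_testcross_family(n_markers = 50, n_offspring = 60, seed = 40)
  clean <- apply_gbs_noise(g, 0, 0, seed = 41)
  expect_identical(clean$calls, g$calls)
  allmiss <- apply_gbs_noise(g, 1, 0, seed = 42)
  expect_true(all(is.na(allmiss$calls)))

  big <- sim_testcross_family(n_markers = 100, n_offspring = 100, seed = 43)
  noisy <- apply_gbs_noise(big, 0.3, 0, seed = 44)
  frac <- mean(is.na(noisy$calls))
  half <- 2.576 * sqrt(0.3 * 0.7 / 10000)
  expect_gt(frac, 0.3 - half)
  expect_lt(frac, 0.3 + half)

  # perturbed calls are flagged by a sub-threshold GQ
  err <- apply_gbs_noise(g, 0, 0.2, seed = 45)
  changed <- which(err$calls != g$calls)
  expect_gt(length(changed), 0)
  expect_true(all(err$gq[changed] < 30))
  expect_true(all(err$gq[-changed][!is.na(err$gq[-changed])] >= 30))
  expect_error(apply_gbs_noise(g, -0.1, 0), "rates")
})

test_that("zipper tables anchor every scaffold unless a fraction is dropped", {
  map <- assign_scaffolds(make_genetic_map(2, 100, 100, seed = 50),
                          scaffolds_per_lg = 10)
  z0 <- make_zipper(map, 0, seed = 51)
  expect_setequal(z0$scaffold, unique(map$scaffold))
  expect_identical(z0, make_zipper(map, 0, seed = 51))
  z3 <- make_zipper(map, 0.3, seed = 52)
  expect_equal(nrow(z3), nrow(z0) - floor(0.3 * nrow(z0)))
  expect_error(make_zipper(map, 1), "unanchored_fraction")
})
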