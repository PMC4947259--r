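test_that("quality filtering is inclusive at the GQ/MQ thresholds", {
  calls <- rbind(c(0L, 1L, 2L), c(1L, 1L, 0L), c(2L, 0L, 1L))
  gq <- rbind(c(29L, 30L, 31L), c(40L, NA, 40L), c(35L, 35L, 35L))
  gm <- toy_matrix(calls, gq = gq, mq = c(45, 30, 29))
  out <- site_quality_filter(gm, min_gq = 30, min_mq = 30)
  # MQ 29 site dropped, MQ 30 retained (boundary inclusive)
  expect_equal(n_sites(out), 2)
  # GQ 29 call set missing, GQ 30 kept, absent GQ passes
  expect_true(is.na(out$calls[1, 1]))
  expect_equal(out$calls[1, 2:3], c(1L, 2L))
  expect_equal(out$calls[2, ], calls[2, ])

  clean <- toy_matrix(calls, gq = matrix(50L, 3, 3))
  expect_identical(site_quality_filter(clean)$calls, clean$calls)
})

test_that("presence and MAF boundaries are inclusive", {
  # 60 samples, 18 missing: presence = 42/60 = 0.70 exactly
  v <- c(rep(NA_integer_, 18), counts_vector(21, 21, 0))
  # MAF site: dosages 54 zeros + 6 hets = 6/120 = 0.05 exactly
  w <- c(counts_vector(54, 6, 0))
  gm <- toy_matrix(rbind(v, w))
  out <- presence_maf_filter(gm, min_presence = 0.70, min_maf = 0.05)
  expect_equal(n_sites(out), 2)
  out2 <- presence_maf_filter(gm, min_presence = 0.71, min_maf = 0.05)
  expect_equal(n_sites(out2), 1)
  out3 <- presence_maf_filter(gm, min_presence = 0.70, min_maf = 0.051)
  expect_equal(out3$sites$pos_bp, gm$sites$pos_bp[1])
})

test_that("a hand-enumerated 10-site fixture yields the exact survivor set", {
  n <- 20  # samples
  sites <- list(
    counts_vector(10, 10, 0),            # MAF 0.25          keep
    counts_vector(20, 0, 0),             # monomorphic       drop
    counts_vector(18, 2, 0),             # MAF 0.05          keep at 0.05
    counts_vector(19, 1, 0),             # MAF 0.025         drop
    counts_vector(0, 4, 16),             # MAF 0.10          keep
    c(rep(NA_integer_, 7), counts_vector(6, 7, 0)),  # presence 0.65 drop
    c(rep(NA_integer_, 6), counts_vector(7, 7, 0)),  # presence 0.70 keep
    counts_vector(5, 10, 5),             # MAF 0.50          keep
    rep(NA_integer_, 20),                # no calls          drop
    counts_vector(17, 3, 0))             # MAF 0.075         keep
  gm <- toy_matrix(do.call(rbind, sites))
  out <- presence_maf_filter(gm, min_presence = 0.70, min_maf = 0.05)
  expect_equal(out$sites$pos_bp, gm$sites$pos_bp[c(1, 3, 5, 7, 8, 10)])
})

test_that("segregation classification follows the third-class tolerance rule", {
  a <- classify_segregation(counts_vector(29, 31, 0))
  expect_equal(a$class, "TESTCROSS_HOMREF_HET")
  expect_equal(c(a$n1, a$n2), c(29, 31))

  b <- classify_segregation(counts_vector(20, 20, 20))
  expect_equal(b$class, "OTHER")

  # 2/60 = 0.033 <= 0.05: the rare hom-ref class is tolerated as error
  d <- classify_segregation(counts_vector(2, 30, 28))
  expect_equal(d$class, "TESTCROSS_HOMALT_HET")
  expect_equal(c(d$n1, d$n2), c(28, 30))

  # below the call floor the site is not classified
  e <- classify_segregation(counts_vector(5, 5, 0), min_calls = 20)
  expect_equal(e$class, "OTHER")
  expect_match(e$reason, "non-missing")
})

test_that("classification is invariant to allele relabeling", {
  set.seed(80)
  for (i in 1:20) {
    v <- sample(c(0L, 1L, 2L, NA), 60, replace = TRUE,
                prob = c(0.4, 0.45, 0.05, 0.1))
    orig <- classify_segregation(v)
    swap <- classify_segregation(2L - v)
    expect_equal(swap$n1, orig$n1)
    expect_equal(swap$n2, orig$n2)
    flip <- c(TESTCROSS_HOMREF_HET = "TESTCROSS_HOMALT_HET",
              TESTCROSS_HOMALT_HET = "TESTCROSS_HOMREF_HET",
              OTHER = "OTHER")
    expect_equal(swap$class, unname(flip[orig$class]))
  }
})

test_that("the 1:1 chi-square statistic and elimination match hand arithmetic", {
  expect_equal(chi_square_1to1(30, 30)$statistic, 0)
  expect_equal(chi_square_1to1(30, 30)$p, 1)
  cs <- chi_square_1to1(40, 20)
  expect_equal(cs$statistic, 400 / 60, tolerance = 1e-12)
  expect_lt(cs$p, 0.05)  # eliminated at alpha = 0.05
  cs2 <- chi_square_1to1(34, 26)
  expect_equal(cs2$statistic, 64 / 60, tolerance = 1e-12)
  expect_gt(cs2$p, 0.05)  # retained
  expect_error(chi_square_1to1(-1, 5), "non-negative")
  expect_error(chi_square_1to1(0, 0), "positive")
})

test_that("testcross selection produces a monotone stage report and drops het x het sites", {
  g <- sim_testcross_family(n_markers = 200, n_offspring = 60, seed = 81)
  sel <- select_testcross_markers(g)
  expect_equal(sel$report$stage,
               c("input", "presence_maf", "testcross", "chi_square"))
  expect_true(all(diff(sel$report$n_sites) <= 0))
  expect_equal(sel$report$n_sites[1], 200)
  # noise-free true testcross sites all survive to the chi-square stage
  expect_equal(sel$report$n_sites[3], 200)
  # chi-square eliminates about alpha of true 1:1 sites (binomial 99.9% band)
  elim <- sel$report$n_sites[3] - sel$report$n_sites[4]
  expect_lt(abs(elim / 200 - 0.05), 3.29 * sqrt(0.05 * 0.95 / 200))

  # het x het family: nothing reaches the testcross stage
  map <- assign_scaffolds(make_genetic_map(1, 50, 50, seed = 82))
  par <- make_parents(map, "HH", cross_mode = "F1_fullsib",
                      config_probs = c(testcross = 0, het_het = 1,
                                       hom_hom = 0), seed = 83)
  hh <- simulate_family(par, map, 60, seed = 84)
  sel_hh <- select_testcross_markers(hh)
  expect_equal(sel_hh$report$n_sites[3], 0)
  expect_equal(n_sites(sel_hh$matrix), 0)
})

test_that("segregation-distorted sites are eliminated and third-class calls masked", {
  g <- sim_testcross_family(n_markers = 50, n_offspring = 60, seed = 85)
  # inject a 45:15 distorted site and a site with 2 third-class calls
  calls <- rbind(counts_vector(45, 15, 0),
                 counts_vector(28, 30, 2),
                 g$calls)
  gm <- toy_matrix(calls)
  sel <- select_testcross_markers(gm)
  kept_pos <- sel$matrix$sites$pos_bp
  expect_false(gm$sites$pos_bp[1] %in% kept_pos)  # chi-square 15 > 3.8415
  expect_true(gm$sites$pos_bp[2] %in% kept_pos)
  row2 <- which(sel$matrix$sites$pos_bp == gm$sites$pos_bp[2])
  expect_false(any(sel$matrix$calls[row2, ] == 2, na.rm = TRUE))
  mixed <- gm
  mixed$samples$family_id[1:10] <- "OTHERFAM"
  expect_error(select_testcross_markers(mixed), "several families")
})
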