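# fixture builders shared across test files; everything is generated in code

# wrap a sites x samples dosage matrix into a genotype_matrix
toy_matrix <- function(calls, scaffold = "scf_1", family = "G01",
                       pos = NULL, mq = 60, gq = NULL) {
  calls <- as.matrix(calls)
  if (is.null(pos)) pos <- seq_len(nrow(calls)) * 100L
  sites <- data.frame(scaffold = scaffold, pos_bp = as.integer(pos),
                      ref = "A", alt = "G", mq = mq)
  samples <- data.frame(
    sample_id = sprintf("%s_%02d", family, seq_len(ncol(calls))),
    family_id = family)
  genotype_matrix(sites, samples, calls, gq)
}

# a dosage vector with exact class counts, in fixed order
counts_vector <- function(n0, n1, n2) {
  c(rep(0L, n0), rep(1L, n1), rep(2L, n2))
}

# one simulated testcross-only family on a single linkage group
sim_testcross_family <- function(n_markers = 100, n_offspring = 60,
                                 seed = 1, lg_length = 100,
                                 scaffolds_per_lg = 20) {
  map <- assign_scaffolds(
    make_genetic_map(1, lg_length, n_markers, seed = seed),
    scaffolds_per_lg = scaffolds_per_lg)
  par <- make_parents(map, "FAM", cross_mode = "F1_fullsib",
                      config_probs = c(testcross = 1, het_het = 0,
                                       hom_hom = 0),
                      seed = seed + 1)
  simulate_family(par, map, n_offspring, seed = seed + 2)
}

# six-family panel on a shared map (used by GWAS tests)
sim_panel <- function(n_markers = 600, n_offspring = 60, seed = 5,
                      cross_mode = "F2_sibmated") {
  map <- assign_scaffolds(make_genetic_map(7, 100, n_markers, seed = seed),
                          scaffolds_per_lg = 20)
  fams <- study_families()
  gs <- lapply(seq_len(nrow(fams)), function(i) {
    par <- make_parents(map, fams$family_id[i], cross_mode = cross_mode,
                        seed = seed + 100 + i)
    simulate_family(par, map, n_offspring, seed = seed + 200 + i)
  })
  list(map = map, genotypes = bind_families(gs))
}

# independent step-up BH oracle (straight from the step-up definition)
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# grid-search oracle for the two-locus haplotype-frequency likelihood
ld_grid_oracle <- function(tab, step = 1e-6) {
  n <- sum(tab)
  p_a <- (2 * sum(tab[3, ]) + sum(tab[2, ])) / (2 * n)
  p_b <- (2 * sum(tab[, 3]) + sum(tab[, 2])) / (2 * n)
  k <- list(AB = 2 * tab[3, 3] + tab[3, 2] + tab[2, 3],
            Ab = 2 * tab[3, 1] + tab[3, 2] + tab[2, 1],
            aB = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
            ab = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1],
            dh = tab[2, 2])
  lo <- max(0, p_a + p_b - 1)
  hi <- min(p_a, p_b)
  grid <- seq(lo, hi, by = step)
  pAb <- p_a - grid
  paB <- p_b - grid
  pab <- 1 - p_a - p_b + grid
  safe_log <- function(x) log(pmax(x, 1e-300))
  loglik <- k$AB * safe_log(grid) + k$Ab * safe_log(pAb) +
    k$aB * safe_log(paB) + k$ab * safe_log(pab) +
    k$dh * safe_log(grid * pab + pAb * paB)
  loglik[!is.finite(loglik)] <- -Inf
  list(p_AB = grid[which.max(loglik)], loglik = max(loglik))
}

# empirical silhouette of a 1-d embedding against labels
silhouette_1d <- function(x, labels) {
  labs <- unique(labels)
  s <- vapply(seq_along(x), function(i) {
    own <- labels[i]
    a <- mean(abs(x[i] - x[labels == own & seq_along(x) != i]))
    b <- min(vapply(setdiff(labs, own), function(l)
      mean(abs(x[i] - x[labels == l])), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
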