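#' Cross-tabulate two loci into a 3x3 dosage table
#'
#' Complete-pairs analysis: an individual contributes only when called at
#' both loci.
#'
#' @param ga,gb dosage vectors (0/1/2/NA) for loci A and B
#' @return 3x3 integer matrix; entry `[i+1, j+1]` counts individuals
#'   with dosage `i` at A and `j` at B
#' @export
two_locus_counts <- function(ga, gb) {
  ok <- !is.na(ga) & !is.na(gb)
  tab <- matrix(0L, 3, 3, dimnames = list(A = 0:2, B = 0:2))
  if (any(ok)) {
    t0 <- table(factor(ga[ok], levels = 0:2), factor(gb[ok], levels = 0:2))
    tab[] <- as.integer(t0)
  }
  tab
}

# log-likelihood of the unobserved AB haplotype frequency given the 3x3
# dosage table; allele frequencies are fixed at their sample values
.ld_loglik <- function(p_ab, p_a, p_b, k) {
  pAb <- p_a - p_ab
  paB <- p_b - p_ab
  pab <- 1 - p_a - p_b + p_ab
  xlogy <- function(x, y) {  # x scalar count, y (possibly vector) frequency
    if (x <= 0) return(rep(0, length(y)))
    x * log(pmax(y, 1e-300))
  }
  dh <- p_ab * pab + pAb * paB
  xlogy(k$AB, p_ab) + xlogy(k$Ab, pAb) + xlogy(k$aB, paB) +
    xlogy(k$ab, pab) + xlogy(k$dh, dh)
}

#' Maximum-likelihood two-locus LD from unphased diplotypes
#'
#' Estimates the frequency of the AB haplotype from a 3x3 genotype table
#' with allele frequencies fixed at their observed values, so the only
#' unknown is how the double heterozygotes split between the coupling
#' (AB/ab) and repulsion (Ab/aB) phases -- the classic cubic-equation
#' likelihood. The estimate is found by EM (E-step: coupling fraction
#' `f = pAB*pab / (pAB*pab + pAb*paB)`; M-step:
#' `pAB = (known_AB + f * n_dh) / (2n)`), run from three starts (just
#' inside both admissible bounds, and linkage equilibrium), tolerance
#' 1e-10, at most 1000 iterations; the best log-likelihood wins and ties
#' resolve to the smaller `|D|`.
#'
#' @param counts 3x3 matrix from [two_locus_counts()]; here allele "A"
#'   ("B") is the dosage-counted allele at each locus
#' @param tol EM convergence tolerance on `p_AB`
#' @param max_iter maximum EM iterations per start
#' @return an `ld_pair_estimate` list: `p_A`, `p_B`, `p_AB`, `D`,
#'   `D_prime`, `r2`, `loglik`, `converged`, `n`
#' @export
haplotype_freq_ml <- function(counts, tol = 1e-10, max_iter = 1000) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3, 3)), all(counts >= 0))
  n <- sum(counts)
  if (n < 1) stop("empty genotype table")
  # dosage i = count of the A (resp. B) allele; R indices are dosage + 1
  p_a <- (2 * sum(counts[3, ]) + sum(counts[2, ])) / (2 * n)
  p_b <- (2 * sum(counts[, 3]) + sum(counts[, 2])) / (2 * n)
  if (p_a <= 0 || p_a >= 1 || p_b <= 0 || p_b >= 1) {
    stop("LD undefined: at least one locus is monomorphic in the sample")
  }
  k <- list(
    AB = 2 * counts[3, 3] + counts[3, 2] + counts[2, 3],
    Ab = 2 * counts[3, 1] + counts[3, 2] + counts[2, 1],
    aB = 2 * counts[1, 3] + counts[1, 2] + counts[2, 3],
    ab = 2 * counts[1, 1] + counts[1, 2] + counts[2, 1],
    dh = counts[2, 2])
  lo <- max(0, p_a + p_b - 1)
  hi <- min(p_a, p_b)
  eps <- 1e-6 * (hi - lo) + 1e-12
  starts <- unique(pmin(pmax(c(lo + eps, p_a * p_b, hi - eps), lo), hi))

  run_em <- function(p0) {
    p <- p0
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      pAb <- p_a - p
      paB <- p_b - p
      pab <- 1 - p_a - p_b + p
      denom <- p * pab + pAb * paB
      f <- if (k$dh > 0 && denom > 0) p * pab / denom else 0.5
      p_new <- (k$AB + f * k$dh) / (2 * n)
      p_new <- pmin(pmax(p_new, lo), hi)
      if (abs(p_new - p) < tol) {
        p <- p_new
        conv <- TRUE
        break
      }
      p <- p_new
    }
    list(p = p, loglik = .ld_loglik(p, p_a, p_b, k), converged = conv)
  }

  fits <- lapply(starts, run_em)
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  ps <- vapply(fits, `[[`, numeric(1), "p")
  best_ll <- max(ll)
  cand <- which(ll >= best_ll - 1e-9)
  # tie between stationary points: keep the smaller |D| (conservative)
  p_ab <- ps[cand][which.min(abs(ps[cand] - p_a * p_b))]
  conv <- any(vapply(fits[cand], `[[`, logical(1), "converged"))
  D <- p_ab - p_a * p_b
  d_max <- if (D >= 0) min(p_a * (1 - p_b), (1 - p_a) * p_b) else
    min(p_a * p_b, (1 - p_a) * (1 - p_b))
  structure(list(
    p_A = p_a, p_B = p_b, p_AB = p_ab, D = D,
    D_prime = if (d_max > 0) D / d_max else 0,
    r2 = D^2 / (p_a * (1 - p_a) * p_b * (1 - p_b)),
    loglik = .ld_loglik(p_ab, p_a, p_b, k),
    converged = conv, n = n), class = "ld_pair_estimate")
}

#' Enumerate all within-scaffold site pairs
#'
#' LD is evaluated in base pairs within scaffolds only, never across.
#'
#' @param x a `genotype_matrix` (sites sorted within scaffold)
#' @return data.frame with site indices `site_i`, `site_j`, `scaffold`
#'   and `distance_bp`
#' @export
enumerate_scaffold_pairs <- function(x) {
  out <- lapply(split(seq_len(n_sites(x)), x$sites$scaffold), function(idx) {
    if (length(idx) < 2) return(NULL)
    pr <- utils::combn(idx, 2)
    data.frame(site_i = pr[1, ], site_j = pr[2, ],
               scaffold = x$sites$scaffold[pr[1, ]],
               distance_bp = abs(x$sites$pos_bp[pr[2, ]] -
                                   x$sites$pos_bp[pr[1, ]]))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(site_i = integer(0), site_j = integer(0),
                      scaffold = character(0), distance_bp = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Estimate r-squared for every within-scaffold pair
#'
#' Runs [haplotype_freq_ml()] on each pair from
#' [enumerate_scaffold_pairs()]. Pairs where a locus is monomorphic among
#' complete observations, or where the EM did not converge, are dropped
#' and counted.
#'
#' @param x a `genotype_matrix`
#' @return data.frame of pairs with `r2`, `D`, `D_prime`, `distance_bp`,
#'   `n`; attribute `"n_dropped"` counts unusable pairs
#' @export
ld_scan <- function(x) {
  pairs <- enumerate_scaffold_pairs(x)
  res <- vector("list", nrow(pairs))
  dropped <- 0L
  for (p in seq_len(nrow(pairs))) {
    est <- tryCatch(
      haplotype_freq_ml(two_locus_counts(x$calls[pairs$site_i[p], ],
                                         x$calls[pairs$site_j[p], ])),
      error = function(e) NULL)
    if (is.null(est) || !est$converged) {
      dropped <- dropped + 1L
      next
    }
    res[[p]] <- data.frame(site_i = pairs$site_i[p], site_j = pairs$site_j[p],
                           scaffold = pairs$scaffold[p],
                           distance_bp = pairs$distance_bp[p],
                           r2 = est$r2, D = est$D, D_prime = est$D_prime,
                           n = est$n)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(site_i = integer(0), site_j = integer(0),
                      scaffold = character(0), distance_bp = numeric(0),
                      r2 = numeric(0), D = numeric(0), D_prime = numeric(0),
                      n = integer(0))
  }
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

#' Bin LD estimates into a decay curve
#'
#' Pairs are sorted by inter-marker distance and chunked into consecutive
#' bins of `bin_size` estimates (1000 in the published decay plot); each
#' bin reports the mean r-squared and mean distance. The final partial
#' bin is retained and flagged.
#'
#' @param pairs data.frame with `r2` and `distance_bp` (e.g. from
#'   [ld_scan()])
#' @param bin_size estimates per bin, default 1000
#' @return data.frame of `ld_bin` rows: `mean_distance_bp`, `mean_r2`,
#'   `n_pairs`, `partial`
#' @export
bin_ld_decay <- function(pairs, bin_size = 1000) {
  stopifnot(bin_size >= 1)
  if (nrow(pairs) == 0) {
    return(data.frame(mean_distance_bp = numeric(0), mean_r2 = numeric(0),
                      n_pairs = integer(0), partial = logical(0)))
  }
  ok <- is.finite(pairs$r2) & is.finite(pairs$distance_bp)
  pairs <- pairs[ok, , drop = FALSE]
  ord <- order(pairs$distance_bp)
  r2 <- pairs$r2[ord]
  d <- pairs$distance_bp[ord]
  bin <- ceiling(seq_along(r2) / bin_size)
  out <- data.frame(
    mean_distance_bp = as.numeric(tapply(d, bin, mean)),
    mean_r2 = as.numeric(tapply(r2, bin, mean)),
    n_pairs = as.integer(tapply(r2, bin, length)))
  out$partial <- out$n_pairs < bin_size
  rownames(out) <- NULL
  out
}
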