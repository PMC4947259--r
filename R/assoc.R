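#' Tie-corrected Kruskal-Wallis test
#'
#' Rank-based k-sample test. With midranks for ties,
#' `H = [12 / (N (N + 1))] * sum(R_j^2 / n_j) - 3 (N + 1)` divided by the
#' tie correction `1 - sum(t^3 - t) / (N^3 - N)`; the p-value is the
#' chi-square upper tail on `k - 1` degrees of freedom. When all values
#' are tied the correction denominator vanishes and the test returns
#' `H = 0`, `p = 1`.
#'
#' @param values numeric phenotype vector
#' @param groups group labels (here: the two genotype classes of a
#'   pseudo-testcross marker); pairs with a missing value or group are
#'   dropped
#' @return list with `H`, `df`, `p`, `n`, and `skipped`/`reason` when
#'   fewer than two groups remain
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  groups <- droplevels(groups)
  n <- length(values)
  k <- nlevels(groups)
  if (k < 2) {
    return(list(H = NA_real_, df = NA_integer_, p = NA_real_, n = n,
                skipped = TRUE,
                reason = "fewer than two groups with non-missing data"))
  }
  r <- rank(values)  # midranks
  rank_sums <- tapply(r, groups, sum)
  n_j <- tabulate(groups)
  H <- 12 / (n * (n + 1)) * sum(rank_sums^2 / n_j) - 3 * (n + 1)
  ties <- table(r)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (correction <= 0) {
    # every value identical: no evidence against the null
    return(list(H = 0, df = k - 1L, p = 1, n = n, skipped = FALSE))
  }
  H <- H / correction
  list(H = H, df = k - 1L,
       p = stats::pchisq(H, df = k - 1, lower.tail = FALSE),
       n = n, skipped = FALSE)
}

#' Chi-square upper-tail probability
#'
#' Survival function of the chi-square distribution, used to reproduce
#' scan p-values from printed test statistics.
#'
#' @param x non-negative quantile (the test statistic)
#' @param df degrees of freedom (1 for a two-class marker test)
#' @return upper-tail probability
#' @export
chisq_sf <- function(x, df = 1) {
  if (any(x < 0)) stop("x must be non-negative")
  if (any(df < 1)) stop("df must be >= 1")
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjusted p-values,
#' `q_(i) = min_{j >= i} p_(j) m / j` capped at 1, returned in the input
#' order. Delegates to [stats::p.adjust()] with `method = "BH"`.
#'
#' @param pvals p-values in `[0, 1]`
#' @return q-values of the same length
#' @export
bh_qvalues <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Single-marker Kruskal-Wallis scan over one family
#'
#' Runs one Kruskal-Wallis test per marker against the supplied
#' per-genotype phenotype (for heading: the conditional means from
#' [conditional_means()]; for aftermath: replicate scores averaged per
#' genotype) and computes Benjamini-Hochberg q-values over the markers of
#' this family-by-trait scan.
#'
#' @param x a testcross-selected `genotype_matrix` for one family
#' @param phenotype named numeric vector keyed by genotype id
#' @param trait label recorded in the result, e.g. `"heading"`
#' @return a `marker_test_result` data.frame with one row per marker:
#'   `marker_id` (when available), `scaffold`, `pos_bp`, `family_id`,
#'   `trait`, `n`, `H`, `df`, `p_value`, `q_value`
#' @export
run_family_scan <- function(x, phenotype, trait = "heading") {
  ids <- x$samples$sample_id
  missing_ids <- setdiff(ids, names(phenotype))
  if (length(missing_ids) > 0) {
    stop("phenotype vector is missing genotype id(s): ",
         paste(utils::head(missing_ids, 10), collapse = ", "),
         if (length(missing_ids) > 10) " ...")
  }
  y <- phenotype[ids]
  res <- lapply(seq_len(n_sites(x)), function(i)
    kruskal_wallis(y, x$calls[i, ]))
  out <- data.frame(
    marker_id = if ("marker_id" %in% names(x$sites)) x$sites$marker_id else
      NA_character_,
    scaffold = x$sites$scaffold,
    pos_bp = x$sites$pos_bp,
    family_id = x$samples$family_id[1],
    trait = trait,
    n = vapply(res, `[[`, numeric(1), "n"),
    H = vapply(res, `[[`, numeric(1), "H"),
    df = vapply(res, function(r) as.numeric(r$df), numeric(1)),
    p_value = vapply(res, `[[`, numeric(1), "p"))
  out$q_value <- NA_real_
  tested <- !is.na(out$p_value)
  out$q_value[tested] <- bh_qvalues(out$p_value[tested])
  if ("lg" %in% names(x$sites)) out$true_lg <- x$sites$lg
  if ("pos_cm" %in% names(x$sites)) out$true_pos_cm <- x$sites$pos_cm
  class(out) <- c("marker_test_result", "data.frame")
  out
}
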