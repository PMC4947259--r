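#' Site-level quality filter
#'
#' Genotype calls with GQ below `min_gq` are set missing; sites with mean
#' mapping quality below `min_mq` are dropped. Boundaries are inclusive
#' (a call with GQ exactly 30 and a site with MQ exactly 30 are kept).
#' Absent GQ/MQ values pass.
#'
#' @param x a `genotype_matrix`
#' @param min_gq minimum genotype quality (phred), default 30
#' @param min_mq minimum per-site mean mapping quality, default 30
#' @return a filtered `genotype_matrix`
#' @export
site_quality_filter <- function(x, min_gq = 30, min_mq = 30) {
  calls <- x$calls
  if (!is.null(x$gq)) {
    low <- !is.na(x$gq) & x$gq < min_gq
    calls[low] <- NA_integer_
  }
  keep <- is.na(x$sites$mq) | x$sites$mq >= min_mq
  gq <- if (!is.null(x$gq)) {
    g <- x$gq
    g[is.na(calls)] <- NA_integer_
    g
  }
  genotype_matrix(x$sites[keep, , drop = FALSE], x$samples,
                  calls[keep, , drop = FALSE],
                  if (!is.null(gq)) gq[keep, , drop = FALSE])
}

#' Presence and minor-allele-frequency filter
#'
#' Keeps sites called in at least `min_presence` of samples and with a
#' minor allele frequency (from non-missing allele counts) of at least
#' `min_maf`. Both boundaries are inclusive. Sites with no non-missing
#' calls are dropped.
#'
#' @param x a `genotype_matrix`
#' @param min_presence minimum fraction of samples with a call, default
#'   0.70
#' @param min_maf minimum minor allele frequency, default 0.05 for the
#'   across-family panel (0.10 is used within each family)
#' @return a filtered `genotype_matrix`
#' @export
presence_maf_filter <- function(x, min_presence = 0.70, min_maf = 0.05) {
  if (min_presence < 0 || min_presence > 1 || min_maf < 0 || min_maf > 0.5) {
    stop("min_presence must be in [0,1] and min_maf in [0, 0.5]")
  }
  called <- rowSums(!is.na(x$calls))
  presence <- called / n_samples(x)
  maf <- site_maf(x)
  keep <- called > 0 & presence >= min_presence & !is.na(maf) & maf >= min_maf
  subset_sites(x, keep)
}

#' Classify the segregation pattern of one site in a full-sib family
#'
#' A pseudo-testcross site is homozygous in one (ungenotyped) parent and
#' heterozygous in the other, so offspring fall into one homozygous class
#' and the heterozygous class in a 1:1 ratio. The class is inferred from
#' offspring counts: a site is `TESTCROSS_HOMREF_HET` or
#' `TESTCROSS_HOMALT_HET` when one homozygous class plus the heterozygote
#' account for at least `1 - third_class_tolerance` of the non-missing
#' calls (the rare third class is attributed to genotyping error);
#' otherwise `OTHER`.
#'
#' @param site_calls integer vector of dosages (0/1/2/NA) for one site
#' @param third_class_tolerance maximum fraction for the rare third
#'   class, default 0.05
#' @param min_calls minimum non-missing calls to attempt classification
#' @return list with `class`, `n1` (homozygous class count), `n2`
#'   (heterozygous count), `n_other`, `n_called`, and `reason` when the
#'   site is `OTHER`
#' @export
classify_segregation <- function(site_calls, third_class_tolerance = 0.05,
                                 min_calls = 20) {
  calls <- site_calls[!is.na(site_calls)]
  n <- length(calls)
  cnt <- tabulate(calls + 1L, nbins = 3L)  # counts of dosage 0, 1, 2
  if (n < min_calls) {
    return(list(class = "OTHER", n1 = NA_integer_, n2 = NA_integer_,
                n_other = NA_integer_, n_called = n,
                reason = sprintf("only %d non-missing calls (< %d)", n,
                                 min_calls)))
  }
  # the heterozygote must be a major class; the rarer homozygote is the
  # candidate error class
  third_is_homalt <- cnt[1] >= cnt[3]
  hom <- if (third_is_homalt) cnt[1] else cnt[3]
  third <- if (third_is_homalt) cnt[3] else cnt[1]
  if (third / n <= third_class_tolerance && hom + cnt[2] >= n - third) {
    cls <- if (third_is_homalt) "TESTCROSS_HOMREF_HET" else
      "TESTCROSS_HOMALT_HET"
    return(list(class = cls, n1 = hom, n2 = cnt[2], n_other = third,
                n_called = n, reason = NULL))
  }
  list(class = "OTHER", n1 = hom, n2 = cnt[2], n_other = third, n_called = n,
       reason = "third genotype class above tolerance")
}

#' Chi-square test for 1:1 segregation
#'
#' Pearson statistic for observed counts `n1`, `n2` against equal
#' expectation: `(n1 - n2)^2 / (n1 + n2)` on 1 degree of freedom, no
#' continuity correction. Sites with `p < alpha` (statistic above 3.8415
#' at the default 0.05) deviate significantly from 1:1 and are
#' eliminated from the scan.
#'
#' @param n1,n2 class counts (homozygous and heterozygous class)
#' @return list with `statistic` and `p`
#' @export
chi_square_1to1 <- function(n1, n2) {
  if (n1 < 0 || n2 < 0) stop("counts must be non-negative")
  if (n1 + n2 == 0) stop("n1 + n2 must be positive")
  stat <- (n1 - n2)^2 / (n1 + n2)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Select pseudo-testcross markers for one family
#'
#' Applies, in order: presence/MAF filtering (within-family 10% MAF
#' default), segregation classification, and the 1:1 chi-square
#' elimination. Residual third-class calls at accepted testcross sites
#' are set missing so downstream tests see two genotype classes.
#'
#' @param x a `genotype_matrix` restricted to one family
#' @param min_presence minimum call fraction, default 0.70
#' @param min_maf within-family minor allele frequency floor, default 0.10
#' @param alpha per-site chi-square elimination level, default 0.05
#' @param third_class_tolerance passed to [classify_segregation()]
#' @param min_calls passed to [classify_segregation()]
#' @return list with `matrix` (surviving `genotype_matrix`, whose site
#'   table gains `seg_class`, `n1`, `n2`, `chisq`, `chisq_p` columns) and
#'   `report` (a `filter_report` data.frame of stage counts)
#' @export
select_testcross_markers <- function(x, min_presence = 0.70, min_maf = 0.10,
                                     alpha = 0.05,
                                     third_class_tolerance = 0.05,
                                     min_calls = 20) {
  if (length(unique(x$samples$family_id)) > 1) {
    stop("matrix spans several families; use subset_family() first")
  }
  n_input <- n_sites(x)
  x1 <- presence_maf_filter(x, min_presence = min_presence, min_maf = min_maf)
  n_maf <- n_sites(x1)

  seg <- lapply(seq_len(n_sites(x1)), function(i)
    classify_segregation(x1$calls[i, ], third_class_tolerance, min_calls))
  cls <- vapply(seg, `[[`, character(1), "class")
  is_tc <- cls != "OTHER"
  x2 <- subset_sites(x1, is_tc)
  seg <- seg[is_tc]
  n_tc <- n_sites(x2)

  # third-class calls at accepted sites are treated as genotyping errors
  calls <- x2$calls
  for (i in seq_len(n_tc)) {
    err_dose <- if (seg[[i]]$class == "TESTCROSS_HOMREF_HET") 2L else 0L
    calls[i, which(calls[i, ] == err_dose)] <- NA_integer_
  }
  gq <- x2$gq
  if (!is.null(gq)) gq[is.na(calls)] <- NA_integer_

  chs <- lapply(seg, function(s) chi_square_1to1(s$n1, s$n2))
  stat <- vapply(chs, `[[`, numeric(1), "statistic")
  pval <- vapply(chs, `[[`, numeric(1), "p")
  keep <- pval >= alpha

  sites <- x2$sites
  sites$seg_class <- vapply(seg, `[[`, character(1), "class")
  sites$n1 <- vapply(seg, function(s) as.integer(s$n1), integer(1))
  sites$n2 <- vapply(seg, function(s) as.integer(s$n2), integer(1))
  sites$chisq <- stat
  sites$chisq_p <- pval
  out <- genotype_matrix(sites[keep, , drop = FALSE], x2$samples,
                         calls[keep, , drop = FALSE],
                         if (!is.null(gq)) gq[keep, , drop = FALSE])
  report <- data.frame(
    stage = c("input", "presence_maf", "testcross", "chi_square"),
    n_sites = c(n_input, n_maf, n_tc, sum(keep)))
  class(report) <- c("filter_report", "data.frame")
  list(matrix = out, report = report)
}
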