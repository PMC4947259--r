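#' Genotype matrix container
#'
#' Holds diploid dosage calls (count of alternate alleles, `NA` = missing)
#' for a set of variant sites by a set of individuals, together with
#' per-site metadata (scaffold, 1-based physical position, alleles, mean
#' mapping quality and, for simulated data, linkage-group/cM coordinates)
#' and per-call genotype quality (phred GQ).
#'
#' @param sites data.frame with at least `scaffold`, `pos_bp`, `ref`,
#'   `alt`, `mq`. Simulated data additionally carries `marker_id`, `lg`,
#'   `pos_cm`. Positions must be strictly increasing within a scaffold.
#' @param samples data.frame with `sample_id` and `family_id`.
#' @param calls integer matrix, sites x samples, values in `{0, 1, 2, NA}`.
#' @param gq optional integer matrix of the same shape; `NA` means no GQ
#'   was recorded for that call (treated as passing quality filters).
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, samples, calls, gq = NULL) {
  stopifnot(is.data.frame(sites), is.data.frame(samples))
  req <- c("scaffold", "pos_bp", "ref", "alt", "mq")
  missing_cols <- setdiff(req, names(sites))
  if (length(missing_cols) > 0) {
    stop("sites is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(c("sample_id", "family_id") %in% names(samples))) {
    stop("samples must have columns sample_id and family_id")
  }
  calls <- as.matrix(calls)
  if (nrow(calls) != nrow(sites) || ncol(calls) != nrow(samples)) {
    stop("calls must be a sites x samples matrix (",
         nrow(sites), " x ", nrow(samples), ")")
  }
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) stop("dosage calls must be 0, 1, 2 or NA")
  if (!is.null(gq)) {
    gq <- as.matrix(gq)
    if (!identical(dim(gq), dim(calls))) stop("gq must match calls in shape")
  }
  # positions strictly increasing within each scaffold
  for (sc in unique(sites$scaffold)) {
    p <- sites$pos_bp[sites$scaffold == sc]
    if (any(diff(p) <= 0)) {
      stop("pos_bp must be strictly increasing within scaffold ", sc)
    }
  }
  rownames(calls) <- NULL
  structure(list(sites = sites, samples = samples, calls = calls, gq = gq),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples (%d scaffolds, %.1f%% missing)\n",
              n_sites(x), n_samples(x),
              length(unique(x$sites$scaffold)),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Number of sites / samples in a genotype matrix
#' @param x a `genotype_matrix`
#' @return integer count
#' @export
n_sites <- function(x) nrow(x$sites)

#' @rdname n_sites
#' @export
n_samples <- function(x) nrow(x$samples)

#' Subset a genotype matrix by site or sample index
#'
#' @param x a `genotype_matrix`
#' @param idx integer or logical index vector
#' @return a `genotype_matrix` restricted to the selection
#' @export
subset_sites <- function(x, idx) {
  genotype_matrix(x$sites[idx, , drop = FALSE],
                  x$samples,
                  x$calls[idx, , drop = FALSE],
                  if (!is.null(x$gq)) x$gq[idx, , drop = FALSE])
}

#' @rdname subset_sites
#' @export
subset_samples <- function(x, idx) {
  genotype_matrix(x$sites,
                  x$samples[idx, , drop = FALSE],
                  x$calls[, idx, drop = FALSE],
                  if (!is.null(x$gq)) x$gq[, idx, drop = FALSE])
}

#' Restrict a genotype matrix to one family
#' @param x a `genotype_matrix`
#' @param family family id to keep
#' @return a `genotype_matrix` with only that family's samples
#' @export
subset_family <- function(x, family) {
  keep <- x$samples$family_id == family
  if (!any(keep)) stop("no samples with family_id ", family)
  subset_samples(x, keep)
}

#' Per-site minor allele frequency from non-missing dosage calls
#' @param x a `genotype_matrix`
#' @return numeric vector, `NA` for sites with no calls
#' @export
site_maf <- function(x) {
  alt <- rowSums(x$calls, na.rm = TRUE)
  n_called <- rowSums(!is.na(x$calls))
  p <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  pmin(p, 1 - p)
}

#' Combine genotype matrices over samples (same sites, e.g. several families)
#' @param ... `genotype_matrix` objects sharing an identical site table
#' @return a single `genotype_matrix`
#' @export
bind_families <- function(...) {
  gms <- list(...)
  if (length(gms) == 1 && is.list(gms[[1]]) &&
      !inherits(gms[[1]], "genotype_matrix")) {
    gms <- gms[[1]]
  }
  ref <- gms[[1]]$sites
  for (g in gms[-1]) {
    if (!identical(g$sites$scaffold, ref$scaffold) ||
        !identical(g$sites$pos_bp, ref$pos_bp)) {
      stop("all matrices must share the same site table")
    }
  }
  genotype_matrix(
    ref,
    do.call(rbind, lapply(gms, function(g) g$samples)),
    do.call(cbind, lapply(gms, function(g) g$calls)),
    if (!is.null(gms[[1]]$gq)) do.call(cbind, lapply(gms, function(g) g$gq))
  )
}
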