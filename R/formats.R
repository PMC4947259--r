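#' Write a genotype matrix as VCF v4.2
#'
#' Emits one record per site with scaffold as CHROM, 1-based POS, GT and
#' (when present) GQ per call, and per-site mean mapping quality in
#' INFO/MQ. Dosage 0/1/2 maps to `0/0`, `0/1`, `1/1`; missing calls are
#' written `./.` with GQ `.`.
#'
#' @param x a `genotype_matrix`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_vcf <- function(x, path) {
  has_gq <- !is.null(x$gq)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sibscan",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mean mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_gq)
      "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples$sample_id), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (n_sites(x) == 0) return(invisible(path))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  ids <- if ("marker_id" %in% names(x$sites)) x$sites$marker_id else "."
  fmt <- if (has_gq) "GT:GQ" else "GT"
  lines <- vapply(seq_len(n_sites(x)), function(i) {
    d <- x$calls[i, ]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    if (has_gq) {
      q <- x$gq[i, ]
      gt <- paste(gt, ifelse(is.na(q), ".", as.character(q)), sep = ":")
    }
    paste(c(x$sites$scaffold[i], x$sites$pos_bp[i],
            if (length(ids) > 1) ids[i] else ".",
            x$sites$ref[i], x$sites$alt[i], ".", "PASS",
            sprintf("MQ=%g", x$sites$mq[i]), fmt, gt), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Parsing is delegated to \pkg{vcfR}. Dosage is the count of alternate
#' alleles in GT (phased or unphased separators accepted); `./.` is
#' missing. Multiallelic sites are skipped and counted. Absent GQ or
#' INFO/MQ is recorded as `NA` and treated as passing downstream quality
#' filters.
#'
#' @param path VCF file (plain text or gzipped)
#' @param samples optional data.frame (`sample_id`, `family_id`) giving
#'   family membership; by default the family is taken as the part of the
#'   sample id before the last underscore (ids written by [write_vcf()]
#'   follow this convention), or `NA` if there is none.
#' @return a `genotype_matrix`; attribute `"n_skipped_multiallelic"`
#'   reports skipped sites
#' @export
read_vcf <- function(path, samples = NULL) {
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF ", path, ": ",
                             conditionMessage(e)))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    sample_ids <- colnames(v@gt)[-1]
    if (is.null(sample_ids)) sample_ids <- character(0)
    smp <- .default_samples(sample_ids, samples)
    gm <- genotype_matrix(
      data.frame(scaffold = character(0), pos_bp = integer(0),
                 ref = character(0), alt = character(0), mq = numeric(0)),
      smp, matrix(integer(0), 0, nrow(smp)))
    attr(gm, "n_skipped_multiallelic") <- 0L
    return(gm)
  }
  multi <- grepl(",", fix$ALT)
  n_skip <- sum(multi)
  if (n_skip > 0) {
    message("read_vcf: skipped ", n_skip, " multiallelic site(s)")
  }
  keep <- which(!multi)
  gt <- vcfR::extract.gt(v, element = "GT")
  gq <- if (any(grepl("GQ", v@gt[, "FORMAT"]))) {
    suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  } else NULL
  gt <- gt[keep, , drop = FALSE]
  if (!is.null(gq)) gq <- gq[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  mq <- suppressWarnings(
    as.numeric(sub(".*MQ=([0-9.eE+-]+).*", "\\1", fix$INFO)))
  mq[!grepl("MQ=", fix$INFO)] <- NA_real_
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- gsub("\\|", "/", gt)
  dosage[clean %in% c("0/0")] <- 0L
  dosage[clean %in% c("0/1", "1/0")] <- 1L
  dosage[clean %in% c("1/1")] <- 2L
  sample_ids <- colnames(gt)
  smp <- .default_samples(sample_ids, samples)
  sites <- data.frame(scaffold = fix$CHROM, pos_bp = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, mq = mq)
  if (!all(fix$ID == ".") && !anyNA(fix$ID)) sites$marker_id <- fix$ID
  ord <- order(sites$scaffold, sites$pos_bp)
  gm <- genotype_matrix(sites[ord, , drop = FALSE], smp,
                        dosage[ord, , drop = FALSE],
                        if (!is.null(gq)) gq[ord, , drop = FALSE])
  attr(gm, "n_skipped_multiallelic") <- n_skip
  gm
}

.default_samples <- function(sample_ids, samples) {
  if (!is.null(samples)) {
    stopifnot(all(c("sample_id", "family_id") %in% names(samples)))
    m <- match(sample_ids, samples$sample_id)
    if (anyNA(m)) stop("samples table is missing ids: ",
                       paste(sample_ids[is.na(m)], collapse = ", "))
    return(data.frame(sample_id = sample_ids,
                      family_id = samples$family_id[m]))
  }
  fam <- ifelse(grepl("_", sample_ids),
                sub("_[^_]*$", "", sample_ids), NA_character_)
  data.frame(sample_id = sample_ids, family_id = fam)
}

#' Read and validate a phenotype table
#'
#' Expects a delimited file with header columns `genotype_id`,
#' `family_id`, `replicate`, `year`, `heading_days` and optionally
#' `aftermath_score`. Rows with an aftermath score outside 1..9 or a
#' negative heading value are rejected with a warning; the number of
#' rejected rows is reported in attribute `"n_rejected"`.
#'
#' @param path CSV file path
#' @return a `phenotype_table` data.frame
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("genotype_id", "family_id", "replicate", "year", "heading_days")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop("phenotype file missing column(s): ",
                             paste(miss, collapse = ", "))
  if (!"aftermath_score" %in% names(df)) df$aftermath_score <- NA_integer_
  bad_aft <- !is.na(df$aftermath_score) &
    (df$aftermath_score < 1 | df$aftermath_score > 9 |
       df$aftermath_score != round(df$aftermath_score))
  bad_head <- !is.na(df$heading_days) & df$heading_days < 0
  bad <- bad_aft | bad_head
  if (any(bad)) {
    warning("rejected ", sum(bad), " phenotype row(s) with out-of-range values")
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("phenotype_table", "data.frame")
  attr(df, "n_rejected") <- sum(bad)
  df
}

#' Write a phenotype table as CSV
#' @param x a `phenotype_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_phenotypes <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read a genome-zipper anchoring table
#'
#' Tab-separated with header columns `scaffold`, `lg`, `pos_cm`. A
#' scaffold may be anchored only once: on duplicates the first row wins
#' and a warning reports how many were dropped.
#'
#' @param path TSV file path
#' @return a `zipper_table` data.frame
#' @export
read_zipper <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("scaffold", "lg", "pos_cm"), names(df))
  if (length(miss) > 0) stop("zipper file missing column(s): ",
                             paste(miss, collapse = ", "))
  dup <- duplicated(df$scaffold)
  if (any(dup)) {
    warning("zipper table: dropped ", sum(dup),
            " duplicate scaffold anchor(s); first occurrence kept")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("zipper_table", "data.frame")
  attr(df, "n_duplicates") <- sum(dup)
  df
}

#' Write a zipper table as TSV
#' @param x a `zipper_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_zipper <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a genetic linkage map
#'
#' Tab-separated with header columns `marker_id`, `lg`, `pos_cm`;
#' rows are sorted by (`lg`, `pos_cm`) and marker ids must be unique.
#'
#' @param path TSV file path
#' @return a `genetic_map` data.frame
#' @export
read_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("marker_id", "lg", "pos_cm"), names(df))
  if (length(miss) > 0) stop("map file missing column(s): ",
                             paste(miss, collapse = ", "))
  if (anyDuplicated(df$marker_id)) stop("map has duplicate marker ids")
  df <- df[order(df$lg, df$pos_cm), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' Write a genetic map as TSV
#' @param x a `genetic_map`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_map <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
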