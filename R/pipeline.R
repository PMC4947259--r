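#' Pipeline configuration
#'
#' Collects every stage parameter with defaults mirroring the study's
#' printed thresholds: GQ 30, MQ 30, presence 0.70, MAF 0.05 across
#' families / 0.10 within a family, chi-square alpha 0.05, FDR 0.05,
#' LD bins of 1000. One global seed is fanned out to fixed per-stage
#' sub-seeds so stages can be rerun independently.
#'
#' @param n_families number of full-sib families
#' @param n_offspring offspring per family (60 in the study)
#' @param n_markers simulated marker count
#' @param n_lgs linkage groups (7)
#' @param lg_length_cm linkage-group length
#' @param scaffolds_per_lg physical scaffolds per linkage group
#' @param bp_per_cm physical scale (1 Mb/cM)
#' @param cross_mode `"F2_sibmated"` or `"F1_fullsib"`
#' @param missing_rate,genotype_error_rate GBS noise rates
#' @param unanchored_fraction zipper scaffolds left unanchored
#' @param min_gq,min_mq quality thresholds
#' @param min_presence presence threshold
#' @param maf_global,maf_family MAF thresholds
#' @param chisq_alpha 1:1 elimination level
#' @param fdr_alpha FDR level for scans and GWAS
#' @param ld_bin_size LD decay bin size
#' @param n_pcs principal components used as GWAS covariates
#' @param seed global seed
#' @return a validated `pipeline_config` list
#' @export
pipeline_config <- function(n_families = 6, n_offspring = 60,
                            n_markers = 1400, n_lgs = 7, lg_length_cm = 100,
                            scaffolds_per_lg = 20, bp_per_cm = 1e6,
                            cross_mode = "F2_sibmated",
                            missing_rate = 0.2, genotype_error_rate = 0.01,
                            unanchored_fraction = 0.1,
                            min_gq = 30, min_mq = 30, min_presence = 0.70,
                            maf_global = 0.05, maf_family = 0.10,
                            chisq_alpha = 0.05, fdr_alpha = 0.05,
                            ld_bin_size = 1000, n_pcs = 3, seed = 1) {
  cfg <- as.list(environment())
  rates <- c(missing_rate, genotype_error_rate, unanchored_fraction,
             min_presence, maf_global, maf_family, chisq_alpha, fdr_alpha)
  if (any(rates < 0 | rates > 1)) stop("rates and thresholds must be in [0,1]")
  if (n_families < 1 || n_offspring < 1 || n_markers < 2 * n_lgs) {
    stop("invalid design sizes")
  }
  if (!cross_mode %in% c("F2_sibmated", "F1_fullsib")) {
    stop("cross_mode must be F2_sibmated or F1_fullsib")
  }
  if (abs(seed) > 2^31 - 2e6) stop("seed too large")
  class(cfg) <- "pipeline_config"
  cfg
}

.stage_seed <- function(cfg, stage) {
  offsets <- c(map = 1L, parents = 2L, family = 3L, noise = 4L, pheno = 5L,
               zipper = 6L)
  as.integer(cfg$seed) + unname(offsets[stage]) * 1000L
}

#' Run the full analysis pipeline on simulated study data
#'
#' Chains every stage: simulate six full-sib families over a shared
#' genetic map, write genotypes (VCF), phenotypes (CSV), map and zipper
#' (TSV); estimate phenotype variance components, heritability and
#' conditional means; select pseudo-testcross markers and run the
#' per-family Kruskal-Wallis scans; anchor results through the zipper
#' and bin them over map intervals; estimate LD decay within scaffolds;
#' and run the mixed-model GWAS across all families. A manifest
#' (parameters, seed, stage summaries) is written as JSON.
#'
#' @param config a `pipeline_config`
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output
#' @param qtl optional `qtl_spec` shared across families (family means
#'   still differ per [study_families()]); `NULL` uses a default with
#'   heading QTL on linkage groups 4 and 7 and an aftermath QTL on 2
#' @return a `pipeline_run` list with elements `genotypes` (clean and
#'   noisy), `phenotypes`, `map`, `zipper`, `phenostats`, `scans`,
#'   `anchored`, `ld`, `gwas`, `manifest`
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         qtl = NULL) {
  cfg <- config
  fams <- utils::head(study_families(), cfg$n_families)
  map <- make_genetic_map(cfg$n_lgs, cfg$lg_length_cm, cfg$n_markers,
                          seed = .stage_seed(cfg, "map"))
  map_sc <- assign_scaffolds(map, cfg$scaffolds_per_lg, cfg$bp_per_cm)
  zipper <- make_zipper(map_sc, cfg$unanchored_fraction,
                        seed = .stage_seed(cfg, "zipper"))
  if (is.null(qtl)) {
    qtl_eff <- data.frame(
      lg = c(4, 4, 7, 2, 6),
      pos_cm = c(31.4, 98.2, 43.6, 79.8, 52.5),
      additive_effect = c(3, 2, 2.5, 1.2, 1.0),
      trait = c("heading", "heading", "heading",
                "aftermath_latent", "aftermath_latent"))
  } else {
    qtl_eff <- qtl$effects
  }
  # jittered maps can end short of the nominal length; keep QTL on the map
  for (k in seq_len(nrow(qtl_eff))) {
    ext <- range(map_sc$pos_cm[map_sc$lg == qtl_eff$lg[k]])
    qtl_eff$pos_cm[k] <- min(max(qtl_eff$pos_cm[k], ext[1]), ext[2])
  }

  clean <- vector("list", nrow(fams))
  noisy <- vector("list", nrow(fams))
  pheno <- vector("list", nrow(fams))
  for (i in seq_len(nrow(fams))) {
    par <- make_parents(map_sc, family_id = fams$family_id[i],
                        cross_mode = cfg$cross_mode,
                        seed = .stage_seed(cfg, "parents") + i)
    g <- simulate_family(par, map_sc, cfg$n_offspring,
                         seed = .stage_seed(cfg, "family") + i)
    spec <- qtl_spec(effects = qtl_eff, family_mean = fams$family_mean[i],
                     aftermath_mean = fams$aftermath_mean[i],
                     residual_sd = if (is.null(qtl)) 5 else qtl$residual_sd)
    ph <- simulate_phenotypes(g, spec, seed = .stage_seed(cfg, "pheno") + i)
    clean[[i]] <- g
    noisy[[i]] <- apply_gbs_noise(g, cfg$missing_rate, cfg$genotype_error_rate,
                                  seed = .stage_seed(cfg, "noise") + i)
    pheno[[i]] <- ph
  }
  names(clean) <- names(noisy) <- names(pheno) <- fams$family_id
  all_noisy <- bind_families(noisy)
  pheno_all <- do.call(rbind, lapply(pheno, as.data.frame))
  rownames(pheno_all) <- NULL
  class(pheno_all) <- c("phenotype_table", "data.frame")

  # phenotype statistics
  vc <- variance_components(pheno_all, "heading")
  ph_stats <- list(
    variance_components = list(sigma2_g = vc$sigma2_g,
                               sigma2_e = vc$sigma2_e, n_bar = vc$n_bar),
    h2_line_mean = line_mean_h2(vc),
    year_correlation = year_correlation(pheno_all, "heading"),
    replicate_f_test = with(
      pheno_all[!is.na(pheno_all$aftermath_score), ],
      oneway_f_test(aftermath_score, replicate)))
  cmeans <- conditional_means(pheno_all, "heading")

  # per-family quality filtering, testcross selection, scans
  q_all <- site_quality_filter(all_noisy, cfg$min_gq, cfg$min_mq)
  scans <- list()
  reports <- list()
  for (f in fams$family_id) {
    fam_m <- subset_family(q_all, f)
    sel <- select_testcross_markers(fam_m, cfg$min_presence, cfg$maf_family,
                                    cfg$chisq_alpha)
    reports[[f]] <- sel$report
    scans[[f]] <- run_family_scan(sel$matrix, cmeans, trait = "heading")
  }
  anchored <- lapply(scans, anchor_markers, zipper = zipper)

  # LD decay across the combined panel
  panel <- presence_maf_filter(q_all, cfg$min_presence, cfg$maf_global)
  ld_pairs <- ld_scan(panel)
  ld_bins <- bin_ld_decay(ld_pairs, cfg$ld_bin_size)

  # mixed-model GWAS across all families
  y <- cmeans[panel$samples$sample_id]
  K <- vanraden_kinship(panel)
  pcs <- genotype_pca(panel, k = cfg$n_pcs)
  gwas <- mlm_scan(y, pcs$scores, K, panel, maf_floor = cfg$maf_global)
  thr <- significance_thresholds(gwas$p_value, alpha = cfg$fdr_alpha)

  manifest <- list(
    package_version = as.character(utils::packageVersion("sibscan")),
    seed = cfg$seed,
    parameters = unclass(cfg),
    n_sites_simulated = n_sites(all_noisy),
    n_sites_panel = n_sites(panel),
    n_samples = n_samples(all_noisy),
    stage_reports = lapply(reports, function(r)
      stats::setNames(as.list(r$n_sites), r$stage)),
    gwas_lambda = genomic_inflation(gwas$p_value),
    gwas_n_significant_fdr = sum(thr$fdr_flags),
    bonferroni_cut = thr$bonferroni_cut)

  run <- list(genotypes = list(clean = clean, noisy = noisy,
                               panel = panel),
              phenotypes = pheno_all, map = map_sc, zipper = zipper,
              phenostats = ph_stats, conditional_means = cmeans,
              scans = scans, reports = reports, anchored = anchored,
              ld = list(pairs = ld_pairs, bins = ld_bins),
              gwas = list(result = gwas, thresholds = thr,
                          pca = pcs, qq = qq_data(gwas$p_value)),
              manifest = manifest)
  class(run) <- "pipeline_run"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_vcf(all_noisy, file.path(out_dir, "genotypes.vcf"))
    write_phenotypes(pheno_all, file.path(out_dir, "phenotypes.csv"))
    write_map(map_sc, file.path(out_dir, "genetic_map.tsv"))
    write_zipper(zipper, file.path(out_dir, "zipper.tsv"))
    for (f in names(anchored)) {
      utils::write.table(as.data.frame(anchored[[f]]),
                         file.path(out_dir, sprintf("scan_%s.tsv", f)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    utils::write.table(ld_bins, file.path(out_dir, "ld_bins.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(as.data.frame(gwas),
                       file.path(out_dir, "gwas.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run:\n")
  cat(sprintf("  %d families, %d samples, %d simulated sites (%d in panel)\n",
              length(x$genotypes$clean), x$manifest$n_samples,
              x$manifest$n_sites_simulated, x$manifest$n_sites_panel))
  cat(sprintf("  heading H2 (line mean) = %.3f, between-year r = %.3f\n",
              x$phenostats$h2_line_mean, x$phenostats$year_correlation$r))
  cat(sprintf("  GWAS lambda = %.3f, FDR hits = %d\n",
              x$manifest$gwas_lambda, x$manifest$gwas_n_significant_fdr))
  invisible(x)
}
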