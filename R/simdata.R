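#' Build a genetic linkage map
#'
#' Markers are spread evenly along each linkage group with uniform jitter
#' of up to a quarter of the nominal spacing, then sorted, so the map is
#' approximately uniform but not gridded. Deterministic for a fixed seed.
#'
#' @param n_lgs number of linkage groups (perennial ryegrass has 7)
#' @param lg_length_cm length of each linkage group in centimorgans
#' @param n_markers total marker count, split as evenly as possible over
#'   linkage groups; must be at least `2 * n_lgs`
#' @param seed integer seed
#' @return a `genetic_map`: data.frame with `marker_id`, `lg`, `pos_cm`,
#'   sorted by (`lg`, `pos_cm`)
#' @export
make_genetic_map <- function(n_lgs = 7, lg_length_cm = 100, n_markers = 700,
                             seed = 1) {
  if (n_lgs < 1 || lg_length_cm <= 0 || n_markers < 2 * n_lgs) {
    stop("need n_lgs >= 1, lg_length_cm > 0 and n_markers >= 2 * n_lgs")
  }
  set.seed(seed)
  per_lg <- rep(n_markers %/% n_lgs, n_lgs)
  extra <- n_markers %% n_lgs
  if (extra > 0) per_lg[seq_len(extra)] <- per_lg[seq_len(extra)] + 1
  out <- lapply(seq_len(n_lgs), function(lg) {
    m <- per_lg[lg]
    grid <- seq(0, lg_length_cm, length.out = m)
    spacing <- lg_length_cm / max(m - 1, 1)
    pos <- grid + runif(m, -spacing / 4, spacing / 4)
    pos <- sort(pmin(pmax(pos, 0), lg_length_cm))
    data.frame(marker_id = sprintf("lg%d_m%04d", lg, seq_len(m)),
               lg = lg, pos_cm = pos)
  })
  map <- do.call(rbind, out)
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Assign map loci to physical scaffolds
#'
#' Each linkage group is chopped into `scaffolds_per_lg` equal centimorgan
#' segments; every marker inherits the scaffold of its segment, and its
#' physical coordinate within the scaffold is the cM offset scaled by a
#' fixed bp-per-cM constant (default 1 Mb/cM). Positions are forced to be
#' strictly increasing within a scaffold.
#'
#' @param map a `genetic_map`
#' @param scaffolds_per_lg segments per linkage group
#' @param bp_per_cm physical scale, base pairs per centimorgan
#' @return the map with added `scaffold` and `pos_bp` columns
#' @export
assign_scaffolds <- function(map, scaffolds_per_lg = 20, bp_per_cm = 1e6) {
  stopifnot(scaffolds_per_lg >= 1, bp_per_cm > 0)
  out <- map
  out$scaffold <- NA_character_
  out$pos_bp <- NA_integer_
  for (lg in unique(map$lg)) {
    i <- which(map$lg == lg)
    len <- max(map$pos_cm[i])
    seg_len <- max(len, 1e-9) / scaffolds_per_lg
    seg <- pmin(floor(map$pos_cm[i] / seg_len), scaffolds_per_lg - 1)
    out$scaffold[i] <- sprintf("scf_%d_%02d", lg, seg + 1)
    bp <- round((map$pos_cm[i] - seg * seg_len) * bp_per_cm) + 1L
    # break ties so positions are strictly increasing within a scaffold
    for (sc in unique(out$scaffold[i])) {
      j <- which(out$scaffold[i] == sc)
      b <- bp[j]
      for (k in seq_along(b)[-1]) if (b[k] <= b[k - 1]) b[k] <- b[k - 1] + 1L
      out$pos_bp[i[j]] <- as.integer(b)
    }
  }
  out
}

#' Simulate a phased parent pair for one family
#'
#' The real parents of the study families were never genotyped, so
#' parental truth exists only in simulation. Each locus is assigned a
#' cross configuration at random: testcross (homozygous in one parent,
#' heterozygous in the other, the informative 1:1 class), intercross
#' (het x het), or uninformative (both homozygous).
#'
#' @param loci a `genetic_map` (with or without scaffold columns)
#' @param family_id family label, e.g. `"G11"`
#' @param cross_mode `"F2_sibmated"` (pair cross, then random mating among
#'   the F1; the default, matching seed multiplication in isolation) or
#'   `"F1_fullsib"` (offspring drawn directly from the pair cross)
#' @param config_probs probabilities for the per-locus parental
#'   configurations `testcross`, `het_het`, `hom_hom` (renormalised)
#' @param seed integer seed
#' @return a `parent_pair`: list with phased haplotype matrices `p1`, `p2`
#'   (2 x n_loci, alleles 0/1), `loci`, `family_id`, `cross_mode`
#' @export
make_parents <- function(loci, family_id = "G01",
                         cross_mode = c("F2_sibmated", "F1_fullsib"),
                         config_probs = c(testcross = 0.5, het_het = 0.3,
                                          hom_hom = 0.2),
                         seed = 1) {
  cross_mode <- match.arg(cross_mode)
  set.seed(seed)
  L <- nrow(loci)
  probs <- config_probs / sum(config_probs)
  conf <- sample(names(probs), L, replace = TRUE, prob = probs)
  p1 <- matrix(0L, 2, L)
  p2 <- matrix(0L, 2, L)
  for (k in seq_len(L)) {
    if (conf[k] == "testcross") {
      hom_allele <- rbinom(1, 1, 0.5)
      het_in_p1 <- rbinom(1, 1, 0.5) == 1
      if (het_in_p1) {
        p1[, k] <- sample(0:1)
        p2[, k] <- hom_allele
      } else {
        p1[, k] <- hom_allele
        p2[, k] <- sample(0:1)
      }
    } else if (conf[k] == "het_het") {
      p1[, k] <- sample(0:1)
      p2[, k] <- sample(0:1)
    } else {
      a <- rbinom(1, 1, 0.5)
      p1[, k] <- a
      p2[, k] <- rbinom(1, 1, 0.5)
    }
  }
  structure(list(p1 = p1, p2 = p2, loci = loci, family_id = family_id,
                 cross_mode = cross_mode, config = conf),
            class = "parent_pair")
}

# One gamete from a phased diplotype. Crossovers follow Haldane's
# no-interference model: between consecutive loci d cM apart the parental
# phase switches with probability r = (1 - exp(-2 d / 100)) / 2, which is
# the Markov chain induced by a Poisson crossover process on the cM scale.
.meiosis_gamete <- function(hap, lg, pos_cm) {
  L <- length(lg)
  gam <- integer(L)
  for (g in unique(lg)) {
    i <- which(lg == g)
    d <- diff(pos_cm[i])
    r <- 0.5 * (1 - exp(-2 * d / 100))
    switches <- c(rbinom(1, 1, 0.5), rbinom(length(d), 1, r))
    phase <- cumsum(switches) %% 2 + 1
    gam[i] <- hap[cbind(phase, i)]
  }
  gam
}

#' Simulate offspring genotypes for one full-sib family
#'
#' Offspring are formed by one gamete per parent, with crossovers placed
#' under Haldane's map function (no interference). In `F2_sibmated` mode
#' an F1 cohort is produced from the pair cross first and each offspring
#' is the product of a random mating between two distinct F1 plants.
#'
#' @param parents a `parent_pair` from [make_parents()]; its loci must
#'   carry `scaffold` and `pos_bp` columns (see [assign_scaffolds()])
#' @param map the `genetic_map` the parents were phased over
#' @param n_offspring offspring count (60 in the study families)
#' @param seed integer seed
#' @param n_f1 F1 cohort size for `F2_sibmated` mode
#' @return a `genotype_matrix` of dosages (0/1/2, no missing data yet);
#'   attribute `"haplotypes"` holds the two transmitted gametes per
#'   offspring (list of two loci x offspring 0/1 matrices) for LD checks
#' @export
simulate_family <- function(parents, map, n_offspring = 60, seed = 1,
                            n_f1 = 20) {
  if (nrow(parents$loci) != nrow(map) ||
      !all(parents$loci$marker_id == map$marker_id)) {
    stop("parents are not phased over the loci of this map")
  }
  if (n_offspring < 1) stop("n_offspring must be >= 1")
  loci <- if (all(c("scaffold", "pos_bp") %in% names(parents$loci))) {
    parents$loci
  } else if (all(c("scaffold", "pos_bp") %in% names(map))) {
    map
  } else {
    stop("loci need scaffold/pos_bp columns; run assign_scaffolds() first")
  }
  set.seed(seed)
  lg <- loci$lg
  pos <- loci$pos_cm
  L <- nrow(loci)

  draw_pair_cross <- function(n) {
    h1 <- vapply(seq_len(n), function(i) .meiosis_gamete(parents$p1, lg, pos),
                 integer(L))
    h2 <- vapply(seq_len(n), function(i) .meiosis_gamete(parents$p2, lg, pos),
                 integer(L))
    list(h1 = h1, h2 = h2)
  }

  if (parents$cross_mode == "F1_fullsib") {
    hp <- draw_pair_cross(n_offspring)
    h1 <- hp$h1; h2 <- hp$h2
  } else {
    f1 <- draw_pair_cross(n_f1)
    f1_dip <- lapply(seq_len(n_f1), function(i) rbind(f1$h1[, i], f1$h2[, i]))
    h1 <- matrix(0L, L, n_offspring)
    h2 <- matrix(0L, L, n_offspring)
    for (i in seq_len(n_offspring)) {
      mates <- sample(n_f1, 2, replace = FALSE)
      h1[, i] <- .meiosis_gamete(f1_dip[[mates[1]]], lg, pos)
      h2[, i] <- .meiosis_gamete(f1_dip[[mates[2]]], lg, pos)
    }
  }
  calls <- h1 + h2
  storage.mode(calls) <- "integer"
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  sites <- data.frame(marker_id = loci$marker_id, lg = loci$lg,
                      pos_cm = loci$pos_cm, scaffold = loci$scaffold,
                      pos_bp = loci$pos_bp, ref = ref, alt = alt, mq = 60)
  ord <- order(sites$scaffold, sites$pos_bp)
  samples <- data.frame(
    sample_id = sprintf("%s_%02d", parents$family_id, seq_len(n_offspring)),
    family_id = parents$family_id)
  gm <- genotype_matrix(sites[ord, ], samples, calls[ord, , drop = FALSE])
  attr(gm, "haplotypes") <- list(h1 = h1[ord, , drop = FALSE],
                                 h2 = h2[ord, , drop = FALSE])
  gm
}

#' Specify the trait truth model for phenotype simulation
#'
#' @param effects data.frame with `lg`, `pos_cm`, `additive_effect` (days
#'   per alternate allele for heading; latent units for aftermath) and
#'   `trait` in `{"heading", "aftermath_latent"}`. Each QTL is attached to
#'   the nearest simulated marker on its linkage group.
#' @param family_mean baseline days to heading (days from April 1st)
#' @param year_effects named numeric vector of fixed year offsets in days
#' @param residual_sd residual standard deviation for heading, days
#' @param aftermath_coupling slope of the aftermath latent trait on the
#'   heading genetic value (negative: earlier-heading genotypes head more
#'   strongly in the aftermath)
#' @param aftermath_mean latent baseline for the aftermath score
#' @param aftermath_sd residual sd of the aftermath latent trait
#' @return a `qtl_spec` list
#' @export
qtl_spec <- function(effects = NULL,
                     family_mean = 55,
                     year_effects = c(`2014` = 0, `2015` = 3),
                     residual_sd = 5,
                     aftermath_coupling = -0.5,
                     aftermath_mean = 2.5,
                     aftermath_sd = 1.5) {
  if (is.null(effects)) {
    effects <- data.frame(lg = integer(), pos_cm = numeric(),
                          additive_effect = numeric(), trait = character())
  }
  stopifnot(all(c("lg", "pos_cm", "additive_effect", "trait") %in%
                  names(effects)),
            all(effects$trait %in% c("heading", "aftermath_latent")),
            residual_sd >= 0, aftermath_sd >= 0)
  structure(list(effects = effects, family_mean = family_mean,
                 year_effects = year_effects, residual_sd = residual_sd,
                 aftermath_coupling = aftermath_coupling,
                 aftermath_mean = aftermath_mean, aftermath_sd = aftermath_sd),
            class = "qtl_spec")
}

# nearest marker on the requested linkage group
.match_qtl_sites <- function(sites, effects) {
  if (nrow(effects) == 0) return(integer(0))
  vapply(seq_len(nrow(effects)), function(k) {
    i <- which(sites$lg == effects$lg[k])
    if (length(i) == 0) stop("QTL on lg ", effects$lg[k],
                             " but no simulated markers on that lg")
    ext <- range(sites$pos_cm[i])
    if (effects$pos_cm[k] < ext[1] - 1e-9 || effects$pos_cm[k] > ext[2] + 1e-9) {
      stop("QTL position ", effects$pos_cm[k], " cM outside map extent of lg ",
           effects$lg[k])
    }
    i[which.min(abs(sites$pos_cm[i] - effects$pos_cm[k]))]
  }, integer(1))
}

#' Simulate heading-date and aftermath-heading phenotypes
#'
#' Heading (days from April 1st) is additive: family mean + QTL dosage
#' effects + fixed year effect + Gaussian residual, recorded per plant,
#' year and replicate. Aftermath heading is a latent Gaussian (its own
#' QTL plus a configurable negative regression on the heading genetic
#' value) cut into the ordinal 1-9 scale at fixed half-integer thresholds,
#' scored in the final year only, per replicate.
#'
#' @param genotypes a noise-free `genotype_matrix` from [simulate_family()]
#' @param qtl a `qtl_spec`
#' @param years vector of year labels (default two years, as scored)
#' @param reps replicates per year (default 2)
#' @param seed integer seed
#' @return a `phenotype_table` data.frame with columns `genotype_id`,
#'   `family_id`, `replicate`, `year`, `heading_days`, `aftermath_score`
#'   (aftermath only in the last year); attribute `"truth"` holds the
#'   per-genotype genetic values
#' @export
simulate_phenotypes <- function(genotypes, qtl = qtl_spec(),
                                years = c(2014, 2015), reps = 2, seed = 1) {
  if (length(years) < 1 || reps < 1) stop("need at least one year and one rep")
  ye <- qtl$year_effects[as.character(years)]
  if (any(is.na(ye))) stop("year_effects must name every simulated year")
  set.seed(seed)
  n <- n_samples(genotypes)
  eff_h <- qtl$effects[qtl$effects$trait == "heading", , drop = FALSE]
  eff_a <- qtl$effects[qtl$effects$trait == "aftermath_latent", , drop = FALSE]
  dose_at <- function(eff) {
    idx <- .match_qtl_sites(genotypes$sites, eff)
    if (length(idx) == 0) return(rep(0, n))
    d <- genotypes$calls[idx, , drop = FALSE]
    d[is.na(d)] <- 1  # QTL genotypes should be noise-free; fallback to mean
    as.numeric(t(d) %*% eff$additive_effect)
  }
  g_head <- qtl$family_mean + dose_at(eff_h)
  g_after <- qtl$aftermath_mean + dose_at(eff_a) +
    qtl$aftermath_coupling * (g_head - mean(g_head))

  recs <- expand.grid(rep_i = seq_len(reps), year = years,
                      plant = seq_len(n), KEEP.OUT.ATTRS = FALSE)
  heading <- g_head[recs$plant] + ye[as.character(recs$year)] +
    rnorm(nrow(recs), 0, qtl$residual_sd)
  last_year <- years[length(years)]
  aft <- rep(NA_integer_, nrow(recs))
  is_last <- recs$year == last_year
  latent <- g_after[recs$plant[is_last]] +
    rnorm(sum(is_last), 0, qtl$aftermath_sd)
  aft[is_last] <- as.integer(pmin(9, pmax(1, round(latent))))
  out <- data.frame(
    genotype_id = genotypes$samples$sample_id[recs$plant],
    family_id = genotypes$samples$family_id[recs$plant],
    replicate = recs$rep_i,
    year = recs$year,
    heading_days = heading,
    aftermath_score = aft)
  class(out) <- c("phenotype_table", "data.frame")
  attr(out, "truth") <- data.frame(
    genotype_id = genotypes$samples$sample_id,
    g_heading = g_head, g_aftermath_latent = g_after)
  out
}

#' Inject GBS-like missingness and genotype error
#'
#' Each call is independently set missing with `missing_rate`; each
#' surviving call is perturbed to a uniformly chosen different dosage
#' with `genotype_error_rate`. GQ is assigned so erroneous calls can be
#' flagged: clean calls draw GQ in 30-60, perturbed calls in 3-29.
#'
#' @param genotypes a `genotype_matrix`
#' @param missing_rate per-call missing probability in `[0, 1]`
#' @param genotype_error_rate per-call error probability in `[0, 1]`
#' @param seed integer seed
#' @return a `genotype_matrix` with `NA` calls and a populated `gq` slot
#' @export
apply_gbs_noise <- function(genotypes, missing_rate = 0.2,
                            genotype_error_rate = 0.01, seed = 1) {
  if (missing_rate < 0 || missing_rate > 1 ||
      genotype_error_rate < 0 || genotype_error_rate > 1) {
    stop("rates must be in [0, 1]")
  }
  set.seed(seed)
  calls <- genotypes$calls
  nc <- length(calls)
  gq <- matrix(sample(30:60, nc, replace = TRUE), nrow(calls), ncol(calls))
  miss <- matrix(runif(nc) < missing_rate, nrow(calls), ncol(calls))
  err <- matrix(runif(nc) < genotype_error_rate, nrow(calls), ncol(calls))
  err <- err & !miss & !is.na(calls)
  if (any(err)) {
    old <- calls[err]
    shift <- sample(1:2, sum(err), replace = TRUE)
    calls[err] <- (old + shift) %% 3L
    gq[err] <- sample(3:29, sum(err), replace = TRUE)
  }
  calls[miss] <- NA_integer_
  gq[is.na(calls)] <- NA_integer_
  genotype_matrix(genotypes$sites, genotypes$samples, calls, gq)
}

#' Build a genome-zipper anchoring table from simulated scaffolds
#'
#' Each scaffold is anchored at the mean cM position of its markers
#' (rounded to 0.1 cM, the resolution of published zipper coordinates); a
#' random fraction of scaffolds is left out of the table to emulate
#' unanchored scaffolds.
#'
#' @param map a `genetic_map` with scaffold assignments
#' @param unanchored_fraction fraction of scaffolds omitted, in `[0, 1)`
#' @param seed integer seed
#' @return a `zipper_table` data.frame (`scaffold`, `lg`, `pos_cm`)
#' @export
make_zipper <- function(map, unanchored_fraction = 0.1, seed = 1) {
  if (unanchored_fraction < 0 || unanchored_fraction >= 1) {
    stop("unanchored_fraction must be in [0, 1)")
  }
  if (!"scaffold" %in% names(map)) {
    stop("map has no scaffold column; run assign_scaffolds() first")
  }
  set.seed(seed)
  agg <- aggregate(pos_cm ~ scaffold + lg, data = map, FUN = mean)
  agg$pos_cm <- round(agg$pos_cm, 1)
  agg <- agg[order(agg$lg, agg$pos_cm), c("scaffold", "lg", "pos_cm")]
  n_drop <- floor(unanchored_fraction * nrow(agg))
  if (n_drop > 0) {
    drop <- sample(nrow(agg), n_drop)
    agg <- agg[-drop, , drop = FALSE]
  }
  rownames(agg) <- NULL
  class(agg) <- c("zipper_table", "data.frame")
  agg
}

#' Default six-family study design
#'
#' Family labels, cross types and baseline heading means emulating six
#' pair-cross full-sib families with contrasting primary heading dates:
#' one early x late cross, two involving intermediate parents, three
#' late x late crosses with a narrow range in days to heading.
#'
#' @return data.frame with `family_id`, `cross`, `family_mean` (days from
#'   April 1st) and `aftermath_mean` (latent scale; one family segregates
#'   strongly for aftermath heading)
#' @export
study_families <- function() {
  data.frame(
    family_id = c("G11", "G12", "G15", "G16", "G17", "G18"),
    cross = c("Late x Early", "Inter x Late", "Late x Late",
              "Late x Late", "Late x Late", "Inter x Inter"),
    family_mean = c(48, 56, 64, 63, 65, 52),
    aftermath_mean = c(2, 2, 1.5, 1.5, 1.5, 4))
}
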