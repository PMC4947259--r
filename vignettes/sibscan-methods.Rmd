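---
title: "Models and methods behind sibscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sibscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sibscan)
```

`sibscan` analyses marker–trait association in small collections of
full-sib families genotyped by sequencing, the design used for heading
date and aftermath heading in perennial ryegrass breeding material. This
vignette describes the statistical models, the defaults and why they were
chosen, the numerical decisions, and what the synthetic-data generator
does and does not emulate.

## Why per-family scans

In a panel assembled from a few pair-cross families, population-level LD
decays extremely fast (recurrent-selection ancestry), so genome-wide
mixed-model association at tens of thousands of markers has little power;
within one full-sib family, a single meiosis generation leaves LD blocks
of centimorgan scale. The package therefore implements both analyses: the
mixed-model GWAS (as the negative control it typically is at these
densities) and the per-family pseudo-testcross scan that carries the
signal.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions the
rest of the package is validated under.

**Study design.** Six full-sib families of 60 offspring each
(`study_families()`), giving 360 genotypes scored in two years and two
replicates for heading (days from April 1st) and once, in the final year,
for aftermath heading on the ordinal 1–9 scale. Baseline family means
(48–65 days) emulate one early-by-late cross, two crosses involving
intermediate parents, and three late-by-late crosses with a narrow range.

**Meiosis.** Crossovers follow Haldane's map function with no
interference: between consecutive loci separated by *d* cM the parental
phase switches with probability `r = (1 − exp(−2d/100))/2`, the Markov
chain of a Poisson crossover process. This is the simplest model
consistent with a cM map; nothing in the analysis depends on
interference.

**Cross modes.** The study families descend from a single pair cross
followed by seed multiplication in isolation, so the default
`F2_sibmated` mode crosses the two parents, raises an F1 cohort (default
20 plants) and draws each offspring from a random mating of two distinct
F1 individuals. `F1_fullsib` mode draws offspring directly from the pair
cross; it is the mode used in parameter-recovery tests because every
simulated testcross locus then segregates exactly 1:1. The real parents
were never genotyped, so parental truth exists only in simulation:
`make_parents()` assigns each locus a testcross, het-by-het or
uninformative configuration with configurable probabilities.

**Phenotypes.** Heading is additive:
`y = family_mean + Σ dosage·effect + year_effect + N(0, σ²)` per
plant-year-replicate record. The default residual SD is 5 days: combined
with the between- and within-family genetic variance of the default
six-family design this implies a line-mean heritability near 0.88 and a
between-year genotype-mean correlation near 0.8, the scales reported for
this trait in multi-year field scoring. Aftermath heading is a latent
Gaussian with its own QTL plus a negative regression on the heading
genetic value (earlier-heading genotypes head more strongly in regrowth;
the slope is configurable), cut into scores 1–9 at fixed half-integer
thresholds.

**GBS noise.** Calls are set missing independently (default 20 %,
motivating the 70 % presence filter) and surviving calls are perturbed to
a different dosage with probability 1 % ; perturbed calls receive GQ in
3–29 and clean calls GQ in 30–60, so the GQ ≥ 30 filter can (optionally)
flag exactly the injected errors.

**Physical coordinates.** Each linkage group is chopped into equal-cM
scaffolds and positions scale at 1 Mb/cM, so LD decay has physical
distances. The zipper table anchors each scaffold at the mean cM of its
markers, rounded to 0.1 cM; a configurable fraction of scaffolds is
omitted to emulate unanchored scaffolds (rendered `--` in output tables).

**What is not emulated:** read-level sequencing, alignment and variant
calling; allele-specific error structure; segregation distortion from
selection; genotype-by-environment interaction; spatial field trends
(the real trial's block design is not modelled — the analysis model has
only genotype and year). Passing tests therefore demonstrate correctness
of the statistics under Mendelian segregation with independent noise,
not robustness to these real-data features.

## Filtering and pseudo-testcross selection

Thresholds default to GQ ≥ 30, site mean MQ ≥ 30, presence ≥ 70 %, MAF ≥
5 % across the panel and ≥ 10 % within a family; every boundary is
inclusive. A site is accepted as a pseudo-testcross when one homozygous
class plus the heterozygote account for at least 95 % of non-missing
calls (at least 20 by default) — the residual third class, attributed to
genotyping error, is set missing rather than rejecting the site, because
a strict two-class requirement would discard nearly everything at
realistic GBS error rates; the 5 % tolerance is configurable. The 1:1
check is the plain Pearson statistic `(n₁−n₂)²/(n₁+n₂)` on 1 df with no
continuity correction, applied per site at α = 0.05 without
multiple-testing correction — the goal is marker QC, not inference, and
a corrected threshold would retain heavily distorted markers.

## The Kruskal–Wallis scan

Markers surviving selection have two genotype classes, so each test is a
rank test with midranks for ties:

    H = [12 / (N(N+1))] Σ R_j²/n_j − 3(N+1),  divided by
    1 − Σ(t³−t)/(N³−N)

with p from the χ²₁ upper tail. When every value is tied the correction
denominator vanishes and the test returns H = 0, p = 1. The phenotype
entering the heading scan is the per-genotype conditional mean (BLUP)
from the mixed model below; aftermath, scored in a single year, can use
replicate means directly. Benjamini–Hochberg q-values are computed within
each family-by-trait scan — the only scope consistent with reporting a
single family's table — via `stats::p.adjust`. The implementation of H is
the package's own (cross-checked against `stats::kruskal.test` in the
test suite) because the scan needs the guarded degenerate cases and
per-marker bookkeeping.

## Maximum-likelihood LD from unphased diplotypes

For two biallelic loci the 3×3 dosage table determines all haplotype
counts except the split of double heterozygotes between coupling (AB/ab)
and repulsion (Ab/aB). With allele frequencies fixed at their sample
values — the classical cubic-equation formulation, which keeps the
optimisation one-dimensional — the log-likelihood in the single unknown
p(AB) is maximised by EM: the E-step assigns double heterozygotes the
coupling fraction `f = p_AB p_ab / (p_AB p_ab + p_Ab p_aB)` and the
M-step updates `p_AB = (known_AB + f n_dh)/(2n)`. The EM runs from three
starts (just inside both admissible bounds `[max(0, p_A+p_B−1),
min(p_A, p_B)]`, and linkage equilibrium `p_A p_B`), tolerance 1e-10, at
most 1000 iterations; the best log-likelihood wins, and a tie between
stationary points resolves to the smaller |D| (the conservative choice).
The test suite verifies every returned optimum against a 1e-6-step grid
search of the same likelihood. Individuals contribute to a pair only if
called at both loci; monomorphic loci raise an error (r² undefined);
non-converged pairs are dropped from decay bins and counted.

Pairs are enumerated within scaffolds only — distances across scaffolds
are unknown — and the decay curve sorts pairs by distance and averages
r² in consecutive bins of 1000 estimates, retaining and flagging the
final partial bin.

One accuracy limit is intrinsic: at n = 60 diplotypes, the phase
information lost at double heterozygotes bounds how closely any
estimator can track the r² computed from the true phased gametes. The
package's estimator agrees with a phase-known count estimator to ~0.01
(median absolute error) with a tail reaching ~0.1 for uninformative
tables; its RMSE against phased truth is about 0.03 at this sample size,
which is the likelihood's own floor, not an optimisation error.

## Mixed-model GWAS

The kinship matrix is VanRaden's `K = WWᵀ / (2Σ p_k(1−p_k))` with W the
dosage matrix centered by twice the allele frequency; missing dosages
are mean-imputed for K and PCA only. Structure covariates are the first
principal components of the centered dosage matrix (default 3 — the
number is configurable since no single value is canonical for six
families; signs follow the largest-|loading|-positive convention so
results are platform-deterministic).

Variance components of `y = Xβ + u + e`, `var(u) = σ²_g K`, come from
restricted maximum likelihood profiled over `δ = σ²_e/σ²_g` on the
spectrum of K projected off X (one eigendecomposition, then Brent search
of log δ on [−12, 12] with an explicit boundary check — `σ²_g → 0`
appears as δ at the upper bound). Per-marker tests fix the variance
components at this null optimum (the P3D/EMMAX approximation, standard
practice and accurate when no single marker explains much variance) and
compute generalized least squares in the whitened coordinates
`V^{−1/2} = D^{−1/2}Uᵀ`, with a Wald t-test on n − p − 1 degrees of
freedom. Markers with missing calls are tested on their complete cases
with V restricted to those individuals — slower but exact, rather than
imputing the tested marker. With K = I and no covariates the scan reduces
exactly to per-marker ordinary least squares (verified to 1e-8), and
under a kinship-drawn polygenic null with six families its genomic
inflation stays within [0.9, 1.1] while naive regression inflates
several-fold. Bonferroni thresholds are the exact quotient α/m; with
α = 0.05 and m = 51,864 markers this is 9.64×10⁻⁷ (the arithmetic
quotient, even where published roundings differ).

## Anchoring and heatmap binning

Scan results join the zipper table by scaffold: all markers on a
scaffold inherit its (LG, cM); scaffolds missing from the zipper are
flagged unanchored and survive into output tables as `--`. Heatmap cells
are the gaps between consecutive linkage-map markers: intervals are
half-open `[m_i, m_{i+1})` with the final interval closed, so a marker
anchored exactly on an interior map position goes to the right interval
— the boundary membership has to be decided somewhere, and half-open
intervals make the tiling exact. Positions outside the map extent clamp
to the terminal intervals with a warning. Each cell reports the median H
of its markers (absent when empty); per-family rows assemble into a
families × intervals matrix with colour bounds [0, max median].

## Phenotype statistics

Variance components use `lme4::lmer` with genotype random and year fixed
(the year term is dropped automatically for single-year traits such as
aftermath); replicate is not modelled as an effect for heading — it
enters only as replication within genotype-year, matching the stated
analysis model. `n̄` is the harmonic mean of per-genotype record counts,
which handles unbalanced records conservatively. Line-mean heritability
is `σ²_g/(σ²_g + σ²_e/n̄)`; conditional means are the fixed-effect-
adjusted BLUPs (intercept plus the average year effect plus the genotype
effect). The between-year correlation defaults to genotype means over
replicates — plant-level matching is available but noisier, and the
genotype-mean scale is the one a line-mean heritability refers to.
Pearson intervals use the Fisher z transform; the replicate check is a
one-way ANOVA F-test.

## Pipeline, determinism, problem sizes

`run_pipeline()` chains simulation → quality filtering → phenotype
statistics → per-family testcross selection and scans → zipper anchoring
→ LD decay → mixed-model GWAS, writing VCF/CSV/TSV artifacts and a JSON
manifest (parameters, seed, stage counts, inflation). One global seed
fans out to fixed per-stage sub-seeds, so any stage can be reproduced
independently and a rerun under the same configuration is bit-identical.
Default problem sizes — 6 × 60 genotypes, 1,400 markers over 7 linkage
groups, 20 scaffolds per group — were chosen so the full pipeline and
the complete test suite run comfortably on a single desktop core while
keeping every per-family scan at the study's 60-offspring sample size;
the default QTL set places heading QTL on linkage groups 4 and 7 and
aftermath QTL on 2 and 6, regions repeatedly implicated for these traits.

## Known limitations

- Only two-class (1:1) markers are scanned; 1:2:1 het-by-het markers are
  excluded by design, as are interval-mapping refinements.
- The LD estimator assumes random union of gametes; within an F1
  full-sib family the two parental gamete pools violate this, which is
  one reason family LD estimates are noisier than their population
  counterparts.
- The MLM supports one random effect; no GxE, no multi-trait models.
- BCF, indexed VCF access and phased input are out of scope; the VCF
  reader skips multiallelic sites (with a count) rather than decomposing
  them.
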