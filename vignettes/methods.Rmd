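---
title: "Methods: PRS construction and symptom-association scanning in prsScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PRS construction and symptom-association scanning in prsScan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`prsScan` implements a polygenic-risk-score (PRS) association analysis
for binary psychiatric and cognitive symptoms in Huntington's disease
(HD) cohorts: clumped multi-threshold scoring from external GWAS summary
statistics, principal-component (PC) adjustment, logistic scans with
two-level Bonferroni control, conditional multi-PRS models, and
descriptive cohort statistics. A synthetic cohort generator supplies
genotypes, training GWAS and phenotypes of the same shape as the real
(access-controlled) inputs, so every stage is exercised by tests without
any download.

# The scoring model

A PRS is a weighted sum of allele dosages. For individual $i$ and
training p-value cutoff $t$:

$$\mathrm{PRS}_t(i) = \sum_{j \,:\, p_j < t} \beta_j \, d_{ij},$$

over clumped index SNPs $j$, with $\beta_j$ the training-GWAS effect of
the counted allele and $d_{ij} \in [0,2]$ the dosage. Decisions baked
into the implementation:

* **Strict cutoff comparison.** A SNP with $p_j$ exactly equal to the
  cutoff is excluded, following the usual "$p < 0.05$" notation of
  threshold grids. The grid default is `1e-4, 1e-3, 0.01, 0.05, 0.5, 1`;
  sets are nested, so the variant count per cutoff is non-decreasing.
* **Effect-allele counting.** Whether one counts minor alleles or effect
  alleles changes each raw score by a per-variant constant
  ($d \mapsto 2-d$, $\beta \mapsto -\beta$). Because adjusted scores are
  residualized on an intercept and standardized, they are invariant to
  this choice (verified to 1e-10 by the flip-invariance tests), and the
  package counts effect alleles.
* **Clumping.** Greedy by ascending training p-value: the most
  significant remaining SNP becomes an index; all SNPs on the same
  chromosome within 500 kb (inclusive window boundary) with dosage
  $r^2 > 0.1$ (strict) are removed and attributed to that index. Ties in
  p-value are broken by (chromosome, position, variant id) so runs are
  reproducible. LD is computed from the analysis cohort's own dosages —
  the single-dataset setting — rather than an external reference panel.
  A brute-force reference that re-sorts and rescans after every removal
  is kept in the test suite and must agree exactly on random instances
  up to 50 SNPs.
* **Missing dosages** are mean-imputed at $2\times$ the effect-allele
  frequency, keeping the analysed $n$ constant across cutoffs.

## Harmonization and QC

Training records are matched to target variants on chromosome:position
(robust to rsID drift); duplicated positions are dropped entirely. If
the training allele pair equals (alt, ref) the effect is carried; if
(ref, alt), its sign is flipped; strand-complement matches are resolved
by complementing first. Strand-ambiguous A/T and C/G SNPs are dropped by
default — the standard guard against silent sign errors — and can
instead be oriented by allele-frequency concordance
($|\Delta f| < 0.2$). QC keeps variants with target MAF $> 0.01$ and
imputation quality $> 0.9$ on both datasets, with the training-side
check applied only where the column exists; comparisons are strictly
greater. The major histocompatibility complex is excluded (default
chr6:25–34 Mb, closed interval, configurable) from scores where
long-range LD would otherwise dominate, conventionally the
schizophrenia-derived score. Every exclusion at every stage carries a
reason, and record counts satisfy input = retained + dropped.

## Ancestry adjustment

Dosages are centered by $2\hat p$ and scaled by
$\sqrt{2\hat p(1-\hat p)}$; monomorphic variants are skipped. The PCs
are left singular vectors of the standardized sample-by-variant matrix —
orthonormal over samples (Gram matrix within 1e-8 of identity). Each raw
score is regressed by OLS on an intercept plus 20 PCs (default; capped
below the sample count), and residuals are divided by their $n-1$
standard deviation. Adjusted scores therefore have mean 0, variance 1,
and correlation $< 10^{-8}$ with every PC; logistic slopes read as
log-odds per SD. A residual variance below $10^{-12}$ (e.g. a score that
is an exact linear function of a PC) is refused with a "degenerate
variance" error rather than standardized into noise. Constant PC columns
are dropped as no-op regressors, so an all-zero PC matrix reduces to
plain centering and scaling.

# Inference

Logistic models are fit by iteratively reweighted least squares
(`glm.fit`, at most 100 iterations, relative log-likelihood tolerance
1e-10) behind a wrapper that adds Wald statistics
($\mathrm{CI} = \exp(\hat\beta \pm 1.96\,\mathrm{SE})$), Nagelkerke
$R^2$ (Cox–Snell rescaled by its maximum), and the Mann–Whitney AUC with
mid-ranks for ties. Possible complete separation (a fitted probability
within 1e-10 of 0/1 together with a coefficient above 15) flags the fit
as non-converged instead of reporting diverged estimates; no Firth
penalty is applied by default, so rare outcomes such as psychosis are
flagged rather than silently shrunk.

The scan fits every (PRS, symptom, cutoff) combination with per-symptom
case-wise deletion of missing endorsements. Two Bonferroni tiers
annotate results: level 1 at $\alpha / (\text{PRS} \times
\text{symptoms})$ — $0.05/63 = 7.94\times10^{-4}$ in the 9x7 layout —
and level 2 additionally dividing by the cutoff count
($0.05/378 = 1.32\times10^{-4}$). Level 1 deliberately ignores cutoff
multiplicity (the cutoffs are strongly correlated nested scores); level
2 is the conservative bound over all fits. The type-I-error test
therefore evaluates the level-1 family at each fixed cutoff and the
level-2 family over the whole grid. 27 PRS-symptom pairs with prior
population-level evidence are tracked as primary hypotheses so that
nominal hits among them can be reported separately.

Conditional models follow the published workflow: per symptom, all PRS
nominally significant alone enter one logistic fit at their
most-significant cutoff (taken at face value, without winner's-curse
adjustment), with the six other symptom endorsements as covariates; a
design with condition number above $10^8$ is refused rather than
ridge-stabilized. Symptom-count regressions (OLS of adjusted PRS on the
0–7 count, missing endorsements counted as non-endorsed) and
sex-stratified fits with the normal heterogeneity test
$z = (\log\mathrm{OR}_F - \log\mathrm{OR}_M)/\sqrt{SE_F^2 + SE_M^2}$
complete the inference layer. The CAG-corrected onset residual uses a
log-linear regression of age at motor onset on CAG repeat length; the
published analyses delegate the exact functional form to an external
reference, so the log-linear form here is a declared stand-in.

## Cohort structure

Exclusions run in the narrative order of the clinical workflow: keep
individuals with at least one non-missing endorsement (positive or
negative), remove comorbid psychiatric diagnoses, then prune
relatedness. Relatedness uses a genomic-relationship (GRM) estimator,
$\mathrm{mean}_j\,(d_{aj}-2p_j)(d_{bj}-2p_j)/(2p_j(1-p_j))$, on whose
scale duplicates score ~1, parent-offspring ~0.5 and second-degree
relatives ~0.25 — matching the identity-by-descent scale at which the
0.25 cutoff is defined. Which member of a pair to drop is not specified
in the source workflow; the package removes greedily by highest degree
in the relatedness graph, breaking ties by fewer non-missing
endorsements then lexicographic id, and verifies post hoc that no
retained pair exceeds the threshold. PCs are computed after relative
removal, on the analysis cohort. Two practical caveats discovered during
design and now encoded in defaults: the GRM noise SE is roughly
$1/\sqrt{M_\mathrm{eff}}$, so fixtures need a few hundred effectively
independent markers before a 0.25 threshold is meaningful; and sampling
genotypes with replacement from a small haplotype panel manufactures
genuine cryptic relatives (shared haplotypes), so default panels are
large (20,000 haplotypes).

# The synthetic cohort generator

The generator emulates the *structure* of the study inputs, not human
genetics:

* **Haplotypes.** Within a block, a latent AR(1) Gaussian is thresholded
  at each variant's allele frequency. The latent step correlation is
  calibrated per adjacent pair (via the tetrachoric relation, solved by
  quadrature and root-finding) so the realized allele correlation equals
  the requested `within_block_corr`; correlation decays with distance
  and blocks are independent. Because the attainable binary correlation
  is bounded by the frequency margins, the default `maf_range` is
  (0.2, 0.5), which keeps targets up to ~0.7 attainable. The default
  inter-block gap (600 kb) exceeds the 500 kb clumping window, so
  cross-block co-clumping by distance is impossible by construction.
* **Training GWAS.** True effects on `n_causal` variants are scaled so
  their liability variance $\sum_j 2f_j(1-f_j)\beta_j^2$ equals
  `h2_liability` (a bookkeeping exact under linkage equilibrium of the
  causal set); reported effects add noise with variance
  $1/(N\,2f(1-f))$ and p-values are the two-sided normal tests. The
  training trait's scale is irrelevant downstream — the pipeline
  consumes only (effect, p) — so reported effects are treated as
  log-odds directly.
* **Symptoms.** Symptom $j$ is a Bernoulli draw with logit
  $c_j + \beta_{\mathrm{prs},j}\,s_i + \text{covariate terms} +
  \lambda_j u_i$, where $u_i$ is a shared standard-normal factor. One
  factor with non-negative loadings is the smallest parameterization
  that reproduces uniformly positive symptom correlations. Intercepts
  are found by root-finding on the realized linear predictor so marginal
  frequencies hit configured targets (defaults: 66.0, 60.3, 10.8, 31.2,
  53.8, 37.5, 57.5 percent) within Monte-Carlo error; default covariate
  effects (sex, CAG, onset age, duration, study) take the published
  adjusted odds ratios as their log-odds. Sex is balanced; CAG is drawn
  on 40–55; onset age declines log-linearly with CAG; duration is
  gamma with study-specific means (6.54 vs 8.14 years); 6.8% of
  individuals carry no questionnaire, 2.3% a comorbid flag.
* **Relatives** are embedded as parent-offspring-like duos sharing one
  haplotype.

What it does **not** emulate: realistic human LD maps and allele
frequency spectra, imputation error structure, X-chromosome dosages,
ascertainment, site effects, or family structure beyond duos. Passing
tests therefore demonstrate the *software* recovers what it simulates
under the stated model — parameter recovery, error control, invariances
— not that the model captures the real cohort. The study's own LD and
symptom-correlation magnitudes are unpublished; the generator's values
are calibration knobs, not estimates.

# Numerical choices and degenerate inputs

* LD $r^2$ of a constant dosage vector is defined as 0 with a warning (a
  monomorphic variant cannot be in LD).
* `p = 0` summary rows are rejected (outside the domain of the ranking),
  as are rows with non-finite effects or identical alleles; every
  rejection is counted.
* Zero cells in a 2x2 sex table trigger the flagged Haldane–Anscombe 0.5
  correction; a zero margin is an error. The chi-square test is Pearson
  without continuity correction, consistent with the Woolf CI
  arithmetic.
* An empty clump input yields an empty index set with a message, not an
  error; a cutoff column with no variants is constant and is refused at
  standardization.
* All tie-breaks (clump order, relative removal) are total orders, and
  the only randomness anywhere is the explicit seeds, so pipeline reruns
  are byte-identical (asserted by SHA-equal output files in tests).

# Problem sizes

The shipped configurations are sized for interactive use and continuous
testing: default pipeline fixture 500 individuals, 500 variants in 100
blocks, three training GWAS (~15 s end to end); calibration suites use
200 replicates at n = 2000–5000 with reduced scan grids, 100 random
clumping instances of 20–50 SNPs, and 10,000 individuals for the
liability bookkeeping check. Real-data scale (thousands of samples,
millions of variants) is outside the design envelope of the in-memory
LD search, which is quadratic per window; the module boundaries
(harmonize → clump → score → adjust → scan) are the natural seams for
swapping in an out-of-core implementation.

# Known limitations

* The GRM approximates IBD; at the 0.25 decision scale they agree for
  the targeted degrees of relatedness, but no pedigree inference is
  attempted.
* No Firth or exact logistic fallback: separated fits are flagged, left
  out of tier annotation, and reported.
* Winner's-curse in "best cutoff" selection is inherited from the
  published design, not corrected.
* Indels, multiallelic variants and genome-build liftover are out of
  scope; multiallelic VCF rows are rejected with a count.
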