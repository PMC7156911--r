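## Synthetic cohort generator: block-LD haplotypes via a thresholded Gaussian
## copula, genotype sampling, a training GWAS over the same variants, and
## correlated binary symptoms under a logistic liability model with a shared
## latent factor. Every downstream stage of the package is testable on its
## output without any external data.

SYMPTOMS <- c("DEP", "IRR", "PSY", "VAB", "APT", "POB", "COG")

## Table-1-style marginal endorsement frequencies used as the generator's
## default calibration targets (percent).
DEFAULT_SYMPTOM_FREQ <- c(DEP = 66.0, IRR = 60.3, PSY = 10.8, VAB = 31.2,
                          APT = 53.8, POB = 37.5, COG = 57.5)

#' Specify the LD-block structure of a haplotype panel
#'
#' Variants are organised into physically separated blocks. Within a block,
#' adjacent variants have a target allele correlation `within_block_corr`
#' (decaying with distance, first-order autoregressive on the latent scale);
#' variants in different blocks are independent. The default
#' `inter_block_gap_bp` (600 kb) exceeds the 500 kb clumping window, so
#' variants in different blocks can never be co-clumped by distance.
#'
#' The generator realises alleles by thresholding a Gaussian copula at the
#' allele frequency. The allele-scale (phi) correlation attainable between
#' two binary variants is bounded by their frequency margins, so the default
#' `maf_range` of (0.2, 0.5) keeps correlations up to ~0.7 attainable.
#'
#' @param n_blocks number of LD blocks.
#' @param snps_per_block variants per block.
#' @param within_block_corr target allele correlation between adjacent
#'   within-block variants, in \[0, 1\].
#' @param block_span_bp physical length of one block, base pairs.
#' @param inter_block_gap_bp gap between consecutive blocks, base pairs.
#' @param maf_range length-2 interval in (0, 0.5\] from which alternate
#'   allele frequencies are drawn uniformly.
#' @return An object of class `LDBlockSpec` (a validated list).
#' @export
ldBlockSpec <- function(n_blocks = 4L, snps_per_block = 50L,
                        within_block_corr = 0.6, block_span_bp = 200000L,
                        inter_block_gap_bp = 600000L,
                        maf_range = c(0.2, 0.5)) {
    if (!is.numeric(n_blocks) || n_blocks < 1)
        stop("invalid LDBlockSpec field 'n_blocks': must be >= 1")
    if (!is.numeric(snps_per_block) || snps_per_block < 1)
        stop("invalid LDBlockSpec field 'snps_per_block': must be >= 1")
    if (!is.numeric(within_block_corr) || within_block_corr < 0 ||
        within_block_corr > 1)
        stop("invalid LDBlockSpec field 'within_block_corr': must be in [0, 1]")
    if (!is.numeric(block_span_bp) || block_span_bp <= 0)
        stop("invalid LDBlockSpec field 'block_span_bp': must be positive")
    if (!is.numeric(inter_block_gap_bp) || inter_block_gap_bp <= 0)
        stop("invalid LDBlockSpec field 'inter_block_gap_bp': must be positive")
    if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2])
        stop("invalid LDBlockSpec field 'maf_range': need 0 < low <= high <= 0.5")
    structure(list(n_blocks = as.integer(n_blocks),
                   snps_per_block = as.integer(snps_per_block),
                   within_block_corr = within_block_corr,
                   block_span_bp = as.integer(block_span_bp),
                   inter_block_gap_bp = as.integer(inter_block_gap_bp),
                   maf_range = maf_range),
              class = "LDBlockSpec")
}

## Standard bivariate normal CDF P(Z1 <= h, Z2 <= k) with correlation rho,
## by one-dimensional quadrature over the conditional normal.
pbvn <- function(h, k, rho) {
    if (abs(rho) >= 1) {
        if (rho >= 1) return(stats::pnorm(min(h, k)))
        return(max(0, stats::pnorm(h) - stats::pnorm(-k)))
    }
    f <- function(x) stats::dnorm(x) *
        stats::pnorm((k - rho * x) / sqrt(1 - rho^2))
    stats::integrate(f, -8, h, rel.tol = 1e-9)$value
}

## Latent Gaussian correlation inducing allele (phi) correlation `phi`
## between binary variants with frequencies f1, f2. Capped at the
## margin-attainable maximum.
latentRho <- function(f1, f2, phi) {
    if (phi <= 0) return(0)
    h <- stats::qnorm(f1); k <- stats::qnorm(f2)
    p11_target <- f1 * f2 + phi * sqrt(f1 * (1 - f1) * f2 * (1 - f2))
    p11_max <- min(f1, f2)
    if (p11_target >= p11_max - 1e-10) return(1)
    g <- function(r) pbvn(h, k, r) - p11_target
    if (g(0.99995) <= 0) return(0.99995)
    stats::uniroot(g, c(0, 0.99995), tol = 1e-7)$root
}

#' Simulate a phased haplotype reference panel with block LD
#'
#' @param spec an [ldBlockSpec()].
#' @param n_haplotypes number of phased haplotypes (rows).
#' @param seed integer seed; identical seeds give identical panels.
#' @return A list of class `HaplotypePanel` with `haplotypes` (0/1 matrix,
#'   haplotypes x variants), `variants` (data.frame: `variant_id`, `chr`,
#'   `pos`, `ref`, `alt`, `freq` — the target alternate-allele frequency)
#'   and the `spec`.
#' @export
simulateHaplotypePanel <- function(spec, n_haplotypes = 4000L, seed = 1L) {
    stopifnot(inherits(spec, "LDBlockSpec"))
    set.seed(seed)
    m_total <- spec$n_blocks * spec$snps_per_block
    freqs <- stats::runif(m_total, spec$maf_range[1], spec$maf_range[2])
    ## non-ambiguous ref/alt pairs only, so default fixtures survive
    ## strand-aware harmonization untouched
    pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                      "G", "A", "C", "A", "G", "T", "C", "T"),
                    ncol = 2, byrow = TRUE)
    pick <- sample.int(nrow(pairs), m_total, replace = TRUE)
    H <- matrix(0L, n_haplotypes, m_total)
    pos <- integer(m_total)
    stride <- spec$block_span_bp + spec$inter_block_gap_bp
    for (b in seq_len(spec$n_blocks)) {
        idx <- (b - 1L) * spec$snps_per_block + seq_len(spec$snps_per_block)
        m <- spec$snps_per_block
        start <- (b - 1L) * stride + 1L
        pos[idx] <- if (m == 1) start else
            start + round((seq_len(m) - 1) * spec$block_span_bp / (m - 1))
        z <- matrix(0, n_haplotypes, m)
        z[, 1] <- stats::rnorm(n_haplotypes)
        if (m > 1) {
            for (j in 2:m) {
                f1 <- freqs[idx[j - 1]]; f2 <- freqs[idx[j]]
                rho <- latentRho(f1, f2, spec$within_block_corr)
                z[, j] <- if (rho >= 1) z[, j - 1] else
                    rho * z[, j - 1] +
                        sqrt(1 - rho^2) * stats::rnorm(n_haplotypes)
            }
        }
        H[, idx] <- 1L * (z < matrix(stats::qnorm(freqs[idx]),
                                     n_haplotypes, m, byrow = TRUE))
    }
    variants <- data.frame(
        variant_id = sprintf("snp%05d", seq_len(m_total)),
        chr = "1", pos = pos,
        ref = pairs[pick, 1], alt = pairs[pick, 2],
        freq = freqs, stringsAsFactors = FALSE)
    colnames(H) <- variants$variant_id
    structure(list(haplotypes = H, variants = variants, spec = spec),
              class = "HaplotypePanel")
}

#' Sample diploid genotype dosages from a haplotype panel
#'
#' Each individual receives two haplotypes drawn with replacement; the
#' dosage is their sum. With `dosage_noise = TRUE`, truncated Gaussian
#' noise emulates imputed (non-integer) dosages while keeping entries
#' in \[0, 2\].
#'
#' @param panel a `HaplotypePanel`.
#' @param n_individuals number of individuals to draw.
#' @param seed integer seed.
#' @param dosage_noise add truncated noise to emulate imputed dosages.
#' @param noise_sd standard deviation of the dosage noise.
#' @param hap_index optional `n_individuals x 2` matrix of haplotype row
#'   indices, overriding the random draw (used to construct relatives).
#' @return A [DosageMatrix-class]; attribute `"hap_index"` records the
#'   haplotypes drawn for each individual.
#' @export
sampleGenotypes <- function(panel, n_individuals, seed = 1L,
                            dosage_noise = FALSE, noise_sd = 0.05,
                            hap_index = NULL) {
    stopifnot(inherits(panel, "HaplotypePanel"))
    if (n_individuals <= 0) stop("n_individuals must be positive")
    set.seed(seed)
    nh <- nrow(panel$haplotypes)
    if (is.null(hap_index))
        hap_index <- matrix(sample.int(nh, 2 * n_individuals, replace = TRUE),
                            ncol = 2)
    D <- panel$haplotypes[hap_index[, 1], , drop = FALSE] +
         panel$haplotypes[hap_index[, 2], , drop = FALSE]
    storage.mode(D) <- "double"
    if (dosage_noise) {
        D <- D + matrix(stats::rnorm(length(D), 0, noise_sd),
                        nrow(D), ncol(D))
        D <- pmin(pmax(D, 0), 2)
    }
    p <- colMeans(D) / 2
    variants <- panel$variants
    variants$maf <- pmin(p, 1 - p)
    variants$info <- if (dosage_noise)
        pmax(0, 1 - noise_sd^2 / pmax(2 * p * (1 - p), 1e-6)) else 1
    dm <- DosageMatrix(t(D), variants,
                       sample_ids = sprintf("ID%05d", seq_len(n_individuals)))
    attr(dm, "hap_index") <- hap_index
    dm
}

#' Specify a synthetic training GWAS
#'
#' @param n_causal number of causal variants.
#' @param h2_liability variance of the training trait's liability explained
#'   by the causal variants, in \[0, 1\].
#' @param n_training effective training-GWAS sample size (controls the
#'   sampling noise of reported effects).
#' @param seed integer seed.
#' @return An object of class `TrainingGwasSpec`.
#' @export
trainingGwasSpec <- function(n_causal = 100L, h2_liability = 0.3,
                             n_training = 50000L, seed = 1L) {
    if (h2_liability < 0 || h2_liability > 1)
        stop("invalid TrainingGwasSpec field 'h2_liability': must be in [0, 1]")
    if (n_causal < 0) stop("invalid TrainingGwasSpec field 'n_causal'")
    if (n_training <= 0) stop("invalid TrainingGwasSpec field 'n_training'")
    structure(list(n_causal = as.integer(n_causal),
                   h2_liability = h2_liability,
                   n_training = n_training, seed = as.integer(seed)),
              class = "TrainingGwasSpec")
}

#' Simulate training-GWAS summary statistics over a panel's variants
#'
#' True effects are drawn for `n_causal` variants and scaled so that their
#' liability-scale variance contribution, `sum(2 f (1-f) beta^2)`, equals
#' `h2_liability`. The reported effect adds estimation noise with variance
#' `1 / (n_training * 2 f (1-f))`; the p-value is the two-sided normal test
#' of the reported effect against that standard error.
#'
#' @param panel a `HaplotypePanel`.
#' @param gwas_spec a [trainingGwasSpec()].
#' @param info imputation-quality values for the INFO column (recycled).
#' @return A data.frame of summary-statistic records with columns
#'   `variant_id`, `chr`, `pos`, `effect_allele`, `other_allele`, `effect`,
#'   `p_value`, `eaf`, `info`, and `true_effect` (the simulation truth;
#'   not written by [writeSummaryStats()]).
#' @export
simulateTrainingGwas <- function(panel, gwas_spec, info = 1.0) {
    stopifnot(inherits(panel, "HaplotypePanel"),
              inherits(gwas_spec, "TrainingGwasSpec"))
    if (gwas_spec$n_causal > nrow(panel$variants))
        stop("n_causal exceeds the panel's variant count")
    set.seed(gwas_spec$seed)
    m <- nrow(panel$variants)
    f <- colMeans(panel$haplotypes)      # realized alt-allele frequency
    f <- pmin(pmax(f, 1e-4), 1 - 1e-4)
    b <- numeric(m)
    if (gwas_spec$n_causal > 0) {
        causal <- sort(sample.int(m, gwas_spec$n_causal))
        raw <- stats::rnorm(gwas_spec$n_causal)
        vg <- sum(2 * f[causal] * (1 - f[causal]) * raw^2)
        if (vg > 0 && gwas_spec$h2_liability > 0)
            raw <- raw * sqrt(gwas_spec$h2_liability / vg)
        else raw <- raw * 0
        b[causal] <- raw
    }
    se <- 1 / sqrt(gwas_spec$n_training * 2 * f * (1 - f))
    beta_hat <- b + stats::rnorm(m, 0, se)
    p <- 2 * stats::pnorm(-abs(beta_hat) / se)
    p <- pmax(p, .Machine$double.xmin)   # p = 0 is outside the domain
    data.frame(variant_id = panel$variants$variant_id,
               chr = panel$variants$chr, pos = panel$variants$pos,
               effect_allele = panel$variants$alt,
               other_allele = panel$variants$ref,
               effect = beta_hat, p_value = p, eaf = f,
               info = rep_len(info, m), true_effect = b,
               stringsAsFactors = FALSE)
}

#' True polygenic score of each individual under a simulated GWAS
#'
#' @param dosage_matrix a [DosageMatrix-class].
#' @param gwas output of [simulateTrainingGwas()] (must carry `true_effect`).
#' @param standardize return the score in cohort standard-deviation units.
#' @return Numeric vector, one score per sample.
#' @export
trueScores <- function(dosage_matrix, gwas, standardize = TRUE) {
    stopifnot("true_effect" %in% names(gwas))
    D <- dosages(dosage_matrix)
    b <- gwas$true_effect[match(rownames(D), gwas$variant_id)]
    b[is.na(b)] <- 0
    g <- as.numeric(crossprod(D, b))
    if (standardize && stats::sd(g) > 0) g <- (g - mean(g)) / stats::sd(g)
    g
}

#' Specify the symptom liability model
#'
#' Symptom `j` is endorsed when a Bernoulli draw with success probability
#' `plogis(intercept_j + beta_prs_j * score + covariate terms +
#' loading_j * U)` succeeds, where `U` is a standard-normal latent factor
#' shared by all symptoms of one individual — inducing uniformly positive
#' pairwise symptom correlations. Scalar parameters are recycled over the
#' 7 symptoms (DEP, IRR, PSY, VAB, APT, POB, COG).
#'
#' @param intercepts liability-scale intercepts; ignored when `target_freq`
#'   is given (they are then solved by intercept search).
#' @param beta_prs log-odds per SD of the true polygenic score.
#' @param sex_effect,cag_effect,amo_effect,duration_effect,study_effect
#'   log-odds covariate effects (sex is female vs male; CAG, age at motor
#'   onset and duration enter centered; study is Enroll vs REGISTRY).
#' @param loading shared-latent-factor loading (>= 0).
#' @param missing_rate per-symptom probability an endorsement is missing.
#' @param all_missing_rate probability an individual has no questionnaire
#'   at all (all 7 symptoms missing).
#' @param comorbid_rate probability of a comorbid exclusion diagnosis.
#' @param target_freq target marginal frequencies in percent (named or in
#'   symptom order); `NULL` to use `intercepts` directly.
#' @param seed integer seed.
#' @return An object of class `SymptomModelSpec`.
#' @export
symptomModelSpec <- function(intercepts = 0, beta_prs = 0,
                             sex_effect = log(c(1.77, 0.77, 0.96, 0.70,
                                                1.04, 0.99, 1.10)),
                             cag_effect = log(c(0.95, 0.94, 1.02, 1.00,
                                                1.02, 1.02, 1.05)),
                             amo_effect = log(c(0.98, 0.98, 1.01, 0.99,
                                                1.00, 1.00, 1.01)),
                             duration_effect = log(c(1.01, 1.02, 1.06, 1.04,
                                                     1.04, 1.05, 1.10)),
                             study_effect = log(c(1.09, 1.06, 0.88, 0.97,
                                                  1.06, 1.52, 0.96)),
                             loading = 0.8, missing_rate = 0.03,
                             all_missing_rate = 0.068,
                             comorbid_rate = 0.0227,
                             target_freq = DEFAULT_SYMPTOM_FREQ,
                             seed = 1L) {
    rec <- function(x) stats::setNames(rep_len(x, 7L), SYMPTOMS)
    loading <- rec(loading)
    if (any(loading < 0))
        stop("invalid SymptomModelSpec field 'loading': must be >= 0 ",
             "(symptom correlations are positive)")
    if (!is.null(target_freq)) {
        target_freq <- rec(target_freq)
        if (any(target_freq <= 0 | target_freq >= 100))
            stop("invalid SymptomModelSpec field 'target_freq'")
    }
    structure(list(intercepts = rec(intercepts), beta_prs = rec(beta_prs),
                   sex_effect = rec(sex_effect), cag_effect = rec(cag_effect),
                   amo_effect = rec(amo_effect),
                   duration_effect = rec(duration_effect),
                   study_effect = rec(study_effect), loading = loading,
                   missing_rate = rec(missing_rate),
                   all_missing_rate = all_missing_rate,
                   comorbid_rate = comorbid_rate,
                   target_freq = target_freq, seed = as.integer(seed)),
              class = "SymptomModelSpec")
}

#' Simulate clinical covariates for a synthetic HD cohort
#'
#' Sex is balanced; CAG repeat length is drawn on 40–55 (disease-causing,
#' >= 36); age at motor onset declines log-linearly with CAG; disease
#' duration is gamma-distributed with study-specific means (Enroll-HD
#' shorter than REGISTRY); age at last visit = onset + duration.
#'
#' @param n number of individuals.
#' @param seed integer seed.
#' @return data.frame with `ID`, `SEX` ("F"/"M"), `CAG`, `AMO`, `AGE_LAST`,
#'   `STUDY` ("REGISTRY"/"ENROLL"), `DURATION`.
#' @export
simulateCovariates <- function(n, seed = 1L) {
    set.seed(seed)
    sex <- ifelse(stats::rbinom(n, 1, 0.5) == 1, "F", "M")
    cag <- pmin(pmax(round(stats::rnorm(n, 44, 3)), 40L), 55L)
    amo <- exp(5.6 - 0.045 * cag + stats::rnorm(n, 0, 0.15))
    study <- ifelse(stats::rbinom(n, 1, 0.22) == 1, "ENROLL", "REGISTRY")
    dur_mean <- ifelse(study == "ENROLL", 6.54, 8.14)
    duration <- stats::rgamma(n, shape = 2, scale = dur_mean / 2)
    data.frame(ID = sprintf("ID%05d", seq_len(n)), SEX = sex,
               CAG = as.integer(cag), AMO = round(amo, 1),
               AGE_LAST = round(amo + duration, 1), STUDY = study,
               DURATION = round(duration, 2), stringsAsFactors = FALSE)
}

## Solve per-symptom intercepts so that mean plogis(c + eta) hits the
## target marginal frequency, given the realized non-intercept liability.
solveIntercept <- function(eta, target) {
    f <- function(c0) mean(stats::plogis(c0 + eta)) - target
    stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Simulate correlated binary symptom endorsements
#'
#' @param true_scores numeric vector of per-individual polygenic scores
#'   (standard-deviation units).
#' @param covariates data.frame from [simulateCovariates()] (or `NULL` to
#'   generate one internally with the model's seed).
#' @param model a [symptomModelSpec()].
#' @return A phenotype data.frame: `ID`, `SEX`, `CAG`, `AMO`, `AGE_LAST`,
#'   `STUDY`, `COMORBID`, and the 7 symptom columns coded 1/0/NA.
#' @export
simulateSymptoms <- function(true_scores, covariates = NULL, model) {
    stopifnot(inherits(model, "SymptomModelSpec"))
    n <- length(true_scores)
    if (is.null(covariates))
        covariates <- simulateCovariates(n, seed = model$seed + 1000L)
    if (nrow(covariates) != n)
        stop("dimension mismatch: ", n, " scores vs ",
             nrow(covariates), " covariate rows")
    set.seed(model$seed)
    u <- stats::rnorm(n)                       # shared latent factor
    sexF <- as.numeric(covariates$SEX == "F")
    cag_c <- covariates$CAG - mean(covariates$CAG)
    amo_c <- covariates$AMO - mean(covariates$AMO)
    dur <- covariates$AGE_LAST - covariates$AMO
    dur_c <- dur - mean(dur)
    stE <- as.numeric(covariates$STUDY == "ENROLL")
    stE_c <- stE - mean(stE)
    Y <- matrix(NA_integer_, n, 7, dimnames = list(NULL, SYMPTOMS))
    for (j in seq_along(SYMPTOMS)) {
        s <- SYMPTOMS[j]
        eta <- model$beta_prs[s] * true_scores +
            model$sex_effect[s] * sexF + model$cag_effect[s] * cag_c +
            model$amo_effect[s] * amo_c +
            model$duration_effect[s] * dur_c +
            model$study_effect[s] * stE_c + model$loading[s] * u
        c0 <- if (!is.null(model$target_freq))
            solveIntercept(eta, model$target_freq[s] / 100)
        else model$intercepts[s]
        Y[, j] <- stats::rbinom(n, 1, stats::plogis(c0 + eta))
        miss <- stats::runif(n) < model$missing_rate[s]
        Y[miss, j] <- NA_integer_
    }
    none <- stats::runif(n) < model$all_missing_rate
    Y[none, ] <- NA_integer_
    comorbid <- as.integer(stats::runif(n) < model$comorbid_rate)
    cbind(covariates[c("ID", "SEX", "CAG", "AMO", "AGE_LAST", "STUDY")],
          data.frame(COMORBID = comorbid), as.data.frame(Y))
}

#' Generate a complete synthetic cohort in one call
#'
#' Simulates a haplotype panel, genotype dosages (optionally with related
#' pairs sharing one haplotype, emulating parent-offspring duos), one or
#' more training GWAS, and symptom phenotypes driven by the true polygenic
#' score of the first ("causal") GWAS.
#'
#' @param n_individuals cohort size.
#' @param panel_spec an [ldBlockSpec()].
#' @param gwas_specs named list of [trainingGwasSpec()]; the first one's
#'   true score drives the symptoms. The default makes 20% of the panel's
#'   variants causal with liability heritability 0.3.
#' @param symptom_model a [symptomModelSpec()].
#' @param n_relative_pairs number of parent-offspring-like pairs to embed.
#' @param n_haplotypes reference-panel size.
#' @param dosage_noise passed to [sampleGenotypes()].
#' @param seed master integer seed.
#' @return list with `panel`, `dosages` ([DosageMatrix-class]), `gwas`
#'   (named list of summary-stat data.frames), `phenotypes`, `true_scores`.
#' @export
simulateCohort <- function(n_individuals = 500L,
                           panel_spec = ldBlockSpec(),
                           gwas_specs = NULL,
                           symptom_model = symptomModelSpec(beta_prs = 0.15),
                           n_relative_pairs = 0L,
                           n_haplotypes = 4000L,
                           dosage_noise = FALSE, seed = 1L) {
    panel <- simulateHaplotypePanel(panel_spec, n_haplotypes, seed = seed)
    if (is.null(gwas_specs)) {
        m <- nrow(panel$variants)
        gwas_specs <- list(MDD = trainingGwasSpec(
            n_causal = max(1L, round(0.2 * m))))
    }
    dm <- sampleGenotypes(panel, n_individuals, seed = seed + 1L,
                          dosage_noise = dosage_noise)
    if (n_relative_pairs > 0) {
        hi <- attr(dm, "hap_index")
        k <- n_relative_pairs
        if (2L * k > n_individuals) stop("too many relative pairs requested")
        set.seed(seed + 2L)
        ## last k individuals become children of the first k: one haplotype
        ## copied from the parent, the other drawn fresh
        child <- n_individuals - k + seq_len(k)
        hi[child, 1] <- hi[cbind(seq_len(k),
                                 sample(c(1L, 2L), k, replace = TRUE))]
        hi[child, 2] <- sample.int(nrow(panel$haplotypes), k, replace = TRUE)
        dm <- sampleGenotypes(panel, n_individuals, seed = seed + 1L,
                              dosage_noise = dosage_noise, hap_index = hi)
    }
    gwas <- vector("list", length(gwas_specs))
    names(gwas) <- names(gwas_specs)
    for (i in seq_along(gwas_specs)) {
        gs <- gwas_specs[[i]]
        gs$seed <- gs$seed + seed * 1000L
        gwas[[i]] <- simulateTrainingGwas(panel, gs)
    }
    scores <- trueScores(dm, gwas[[1]])
    model <- symptom_model
    model$seed <- model$seed + seed
    covs <- simulateCovariates(n_individuals, seed = seed + 3L)
    pheno <- simulateSymptoms(scores, covs, model)
    list(panel = panel, dosages = dm, gwas = gwas, phenotypes = pheno,
         true_scores = scores)
}

#' Write genotype dosages as VCF 4.2 with FORMAT field DS
#'
#' @param dosage_matrix a [DosageMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDosageVcf <- function(dosage_matrix, path) {
    vi <- variantInfo(dosage_matrix)
    D <- dosages(dosage_matrix)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##source=prsScan",
        paste0("##contig=<ID=", paste(unique(vi$chr)), ">"),
        "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation quality r-squared\">",
        "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Expected alternate allele dosage\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", sampleIds(dosage_matrix)),
              collapse = "\t")), con)
    body <- paste(vi$chr, vi$pos, vi$variant_id, vi$ref, vi$alt, ".", "PASS",
                  sprintf("INFO=%.4f", vi$info), "DS",
                  apply(matrix(sprintf("%.3f", D), nrow(D)), 1, paste,
                        collapse = "\t"),
                  sep = "\t")
    writeLines(body, con)
    invisible(path)
}

#' Write summary statistics as tab-separated text
#'
#' Header: `SNP CHR BP A1 A2 BETA P FRQ INFO` (A1 is the effect allele).
#'
#' @param sumstats data.frame from [simulateTrainingGwas()] or
#'   [readSummaryStats()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSummaryStats <- function(sumstats, path) {
    out <- data.frame(SNP = sumstats$variant_id, CHR = sumstats$chr,
                      BP = sumstats$pos, A1 = sumstats$effect_allele,
                      A2 = sumstats$other_allele, BETA = sumstats$effect,
                      P = sumstats$p_value, FRQ = sumstats$eaf,
                      INFO = sumstats$info)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a phenotype table as tab-separated text
#'
#' Header: `ID SEX CAG AMO AGE_LAST STUDY COMORBID DEP IRR PSY VAB APT POB
#' COG`; symptoms coded 1/0/NA.
#'
#' @param phenotypes phenotype data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePhenotypes <- function(phenotypes, path) {
    cols <- c("ID", "SEX", "CAG", "AMO", "AGE_LAST", "STUDY", "COMORBID",
              SYMPTOMS)
    utils::write.table(phenotypes[cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}
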