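## Shared fixture builders. Everything is generated in code; nothing binary.

SYM <- c("DEP", "IRR", "PSY", "VAB", "APT", "POB", "COG")

## Published symptom-by-sex 2x2 counts used by the descriptive tests.
sexCountsTable <- function() {
    read.delim(system.file("extdata", "symptom_sex_counts.tsv",
                           package = "prsScan"))
}

## A hand-built haplotype panel with explicit haplotypes and frequencies.
manualPanel <- function(H, pos = NULL, chr = "1") {
    m <- ncol(H)
    if (is.null(pos)) pos <- seq_len(m) * 1000L
    variants <- data.frame(
        variant_id = sprintf("snp%05d", seq_len(m)), chr = chr, pos = pos,
        ref = "A", alt = "G", freq = colMeans(H), stringsAsFactors = FALSE)
    colnames(H) <- variants$variant_id
    structure(list(haplotypes = H, variants = variants,
                   spec = ldBlockSpec(1, m, 0)),
              class = "HaplotypePanel")
}

## DosageMatrix with iid binomial dosages at given allele frequencies.
randomDosageMatrix <- function(n_variants, n_samples, freq = 0.3,
                               seed = 1) {
    set.seed(seed)
    freq <- rep_len(freq, n_variants)
    D <- matrix(rbinom(n_variants * n_samples, 2, rep(freq, n_samples)),
                n_variants, n_samples)
    DosageMatrix(D, data.frame(
        variant_id = sprintf("v%04d", seq_len(n_variants)), chr = "1",
        pos = seq_len(n_variants) * 1000L, ref = "A", alt = "G"),
        sprintf("S%04d", seq_len(n_samples)))
}

## Minimal phenotype table wrapper.
makePheno <- function(symptoms, sex = NULL, comorbid = 0L, seed = 1) {
    n <- nrow(symptoms)
    set.seed(seed)
    if (is.null(sex)) sex <- ifelse(rbinom(n, 1, 0.5) == 1, "F", "M")
    cag <- as.integer(pmin(pmax(round(rnorm(n, 44, 3)), 40), 55))
    amo <- round(exp(5.6 - 0.045 * cag + rnorm(n, 0, 0.15)), 1)
    cbind(data.frame(ID = sprintf("ID%05d", seq_len(n)), SEX = sex,
                     CAG = cag, AMO = amo,
                     AGE_LAST = round(amo + rgamma(n, 2, scale = 4), 1),
                     STUDY = ifelse(rbinom(n, 1, 0.22) == 1, "ENROLL",
                                    "REGISTRY"),
                     COMORBID = rep_len(as.integer(comorbid), n),
                     stringsAsFactors = FALSE),
          as.data.frame(symptoms))
}

## A ScoreSet whose adjusted scores are given directly (standardized here).
scoreSetFromMatrix <- function(adj, sample_id = NULL, thresholds = NULL) {
    adj <- as.matrix(adj)
    if (is.null(sample_id)) sample_id <- sprintf("ID%05d", seq_len(nrow(adj)))
    if (is.null(thresholds))
        thresholds <- if (ncol(adj) == 1) 1 else
            sort(c(1, 0.5^(seq_len(ncol(adj) - 1))))
    adj <- apply(adj, 2, function(x) (x - mean(x)) / sd(x))
    prsScan:::ScoreSet(sample_id = sample_id, raw = adj,
                       thresholds = thresholds,
                       n_variants = seq_len(ncol(adj)), adjusted = adj)
}

## Independent brute-force clumping reference: after every removal pass,
## re-sort the survivors by p and rescan from scratch.
bruteForceClump <- function(weights, D, window_bp = 500000, r2_max = 0.1) {
    w <- weights[weights$dropped_reason == "none", , drop = FALSE]
    index <- character()
    repeat {
        if (nrow(w) == 0) break
        w <- w[order(w$p_value, w$chr, w$pos, w$variant_id), , drop = FALSE]
        top <- w[1, ]
        index <- c(index, top$variant_id)
        keep <- rep(TRUE, nrow(w))
        for (j in seq_len(nrow(w))[-1]) {
            if (w$chr[j] == top$chr &&
                abs(w$pos[j] - top$pos) <= window_bp) {
                r2 <- suppressWarnings(
                    cor(D[top$variant_id, ], D[w$variant_id[j], ])^2)
                if (!is.na(r2) && r2 > r2_max) keep[j] <- FALSE
            }
        }
        keep[1] <- FALSE
        w <- w[keep, , drop = FALSE]
    }
    sort(index)
}

## Random clumping instance: blocks of correlated dosages, random p-values.
randomClumpInstance <- function(seed, n_snps = NULL, n_samples = 60) {
    set.seed(seed)
    if (is.null(n_snps)) n_snps <- sample(20:50, 1)
    pos <- sort(sample.int(2000000L, n_snps))
    D <- matrix(0, n_snps, n_samples)
    base <- rbinom(n_samples, 2, 0.4)
    for (i in seq_len(n_snps)) {
        if (runif(1) < 0.5) base <- rbinom(n_samples, 2, runif(1, 0.2, 0.5))
        flip <- runif(n_samples) < 0.15
        d <- base
        d[flip] <- rbinom(sum(flip), 2, 0.4)
        D[i, ] <- d
    }
    ids <- sprintf("s%03d", seq_len(n_snps))
    rownames(D) <- ids
    dm <- DosageMatrix(D, data.frame(variant_id = ids, chr = "1",
                                     pos = pos, ref = "A", alt = "G"))
    weights <- data.frame(variant_id = ids, chr = "1", pos = pos,
                          aligned_effect = rnorm(n_snps),
                          p_value = runif(n_snps),
                          eaf = rowMeans(D) / 2, flip_applied = FALSE,
                          dropped_reason = "none",
                          stringsAsFactors = FALSE)
    list(weights = weights, dm = dm)
}
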