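## The PRS engine: greedy LD clumping by ascending training p-value,
## multi-threshold scoring of harmonized weights against dosages, and
## principal-component residualization with standardization.

#' Clumping parameters
#'
#' @param window_bp physical window around the index variant (inclusive
#'   boundary; default 500 kb).
#' @param r2_max variants with dosage r-squared strictly above this value
#'   to the index variant are removed (default 0.1).
#' @return list of class `ClumpParams`.
#' @export
clumpParams <- function(window_bp = 500000L, r2_max = 0.1) {
    stopifnot(window_bp > 0, r2_max > 0, r2_max < 1)
    structure(list(window_bp = as.integer(window_bp), r2_max = r2_max),
              class = "ClumpParams")
}

#' The default p-value cutoff grid
#'
#' Six nested training-GWAS significance levels defining the score's SNP
#' sets; the last cutoff (1) uses every index variant.
#'
#' @param thresholds strictly increasing cutoffs ending at 1.
#' @return numeric vector of class `CutoffGrid`.
#' @export
cutoffGrid <- function(thresholds = c(1e-4, 1e-3, 0.01, 0.05, 0.5, 1)) {
    if (length(thresholds) < 1 || any(diff(thresholds) <= 0))
        stop("cutoff grid must be strictly increasing")
    if (thresholds[length(thresholds)] != 1)
        stop("the last cutoff must be 1")
    structure(as.numeric(thresholds), class = "CutoffGrid")
}

#' Squared dosage correlation between two variants
#'
#' @param dosage_a,dosage_b numeric vectors of equal length >= 2.
#' @return Squared Pearson correlation in \[0, 1\]; a constant vector
#'   cannot be in LD and returns 0 with a warning.
#' @export
ldR2 <- function(dosage_a, dosage_b) {
    stopifnot(length(dosage_a) == length(dosage_b), length(dosage_a) >= 2)
    if (stats::sd(dosage_a) == 0 || stats::sd(dosage_b) == 0) {
        warning("constant dosage vector: r2 defined as 0")
        return(0)
    }
    stats::cor(dosage_a, dosage_b)^2
}

#' Greedy LD clumping of harmonized weights
#'
#' Selects the most significant remaining variant, removes all variants on
#' the same chromosome within `window_bp` (inclusive) whose dosage
#' r-squared with it strictly exceeds `r2_max`, and repeats. Equal
#' p-values are broken by (chromosome, position, variant id), making the
#' result deterministic. LD is computed from the analysis cohort's own
#' dosages.
#'
#' @param weights harmonized weight data.frame ([harmonizeWeights()]),
#'   restricted to rows with `dropped_reason == "none"` (rows with other
#'   reasons are ignored).
#' @param dosage_matrix a [DosageMatrix-class] covering the weight variants.
#' @param params a [clumpParams()].
#' @return list with `index` — the index-variant data.frame sorted by
#'   genomic coordinate — and `assignment`, a data.frame mapping each
#'   removed variant to the index variant that absorbed it.
#' @export
clumpVariants <- function(weights, dosage_matrix, params = clumpParams()) {
    w <- weights[weights$dropped_reason == "none", , drop = FALSE]
    if (nrow(w) == 0) {
        message("clump: no scorable weights; empty index set")
        return(list(index = w, assignment = data.frame(
            variant_id = character(), index_id = character())))
    }
    D <- dosages(dosage_matrix)
    if (!all(w$variant_id %in% rownames(D)))
        stop("dosage matrix does not cover all weight variants")
    ord <- order(w$p_value, w$chr, w$pos, w$variant_id)
    w <- w[ord, , drop = FALSE]
    alive <- rep(TRUE, nrow(w))
    is_index <- rep(FALSE, nrow(w))
    assigned_to <- rep(NA_character_, nrow(w))
    for (i in seq_len(nrow(w))) {
        if (!alive[i]) next
        alive[i] <- FALSE
        is_index[i] <- TRUE
        cand <- which(alive & w$chr == w$chr[i] &
                      abs(w$pos - w$pos[i]) <= params$window_bp)
        if (length(cand)) {
            di <- D[w$variant_id[i], ]
            for (j in cand) {
                r2 <- suppressWarnings(ldR2(di, D[w$variant_id[j], ]))
                if (r2 > params$r2_max) {
                    alive[j] <- FALSE
                    assigned_to[j] <- w$variant_id[i]
                }
            }
        }
    }
    index <- w[is_index, , drop = FALSE]
    index <- index[order(index$chr, index$pos, index$variant_id), ,
                   drop = FALSE]
    rownames(index) <- NULL
    removed <- !is_index
    list(index = index,
         assignment = data.frame(variant_id = w$variant_id[removed],
                                 index_id = assigned_to[removed],
                                 stringsAsFactors = FALSE))
}

#' Multi-threshold raw PRS
#'
#' For each cutoff `t`, the raw score of individual `i` is the sum over
#' index variants with training p-value strictly below `t` of
#' `aligned_effect * dosage`. Sporadically missing dosages are imputed as
#' twice the effect-allele frequency.
#'
#' @param dosage_matrix a [DosageMatrix-class].
#' @param index_weights index-variant data.frame from [clumpVariants()].
#' @param grid a [cutoffGrid()].
#' @return A [ScoreSet-class] with raw scores (adjusted slot empty).
#' @export
scorePrs <- function(dosage_matrix, index_weights, grid = cutoffGrid()) {
    if (length(grid) == 0) stop("threshold grid is empty")
    D <- dosages(dosage_matrix)
    ids <- index_weights$variant_id
    if (!all(ids %in% rownames(D)))
        stop("dosage matrix does not cover all index variants")
    X <- D[ids, , drop = FALSE]
    if (anyNA(X)) {
        fill <- 2 * index_weights$eaf
        for (r in which(rowSums(is.na(X)) > 0))
            X[r, is.na(X[r, ])] <- fill[r]
    }
    raw <- matrix(0, ncol(D), length(grid))
    nv <- integer(length(grid))
    for (t in seq_along(grid)) {
        sel <- index_weights$p_value < grid[t]
        nv[t] <- sum(sel)
        if (nv[t] > 0)
            raw[, t] <- as.numeric(crossprod(X[sel, , drop = FALSE],
                                   index_weights$aligned_effect[sel]))
    }
    ScoreSet(sample_id = colnames(D), raw = raw, thresholds = grid,
             n_variants = nv)
}

#' Residualize scores on principal components and standardize
#'
#' Per cutoff, the raw score is regressed (ordinary least squares, with
#' intercept) on the genotype principal components; the residuals are
#' divided by their standard deviation (denominator n - 1), giving
#' adjusted scores with mean 0 and variance 1 over the cohort.
#'
#' @param score_set a [ScoreSet-class] with raw scores.
#' @param pcs PC projections from [computePcs()] (or a data.frame with
#'   `sample_id` + component columns); must cover every scored sample.
#' @return The `ScoreSet` with the adjusted slot filled.
#' @export
adjustScores <- function(score_set, pcs) {
    proj <- if (is.list(pcs) && !is.data.frame(pcs)) pcs$projections else pcs
    m <- match(sampleIds(score_set), proj$sample_id)
    if (anyNA(m))
        stop("PCs missing for ",
             paste(utils::head(sampleIds(score_set)[is.na(m)], 5),
                   collapse = ", "))
    P <- as.matrix(proj[m, grep("^PC", names(proj)), drop = FALSE])
    n <- nrow(P)
    if (n <= ncol(P) + 1)
        stop("fewer samples than regressors in PC adjustment")
    raw <- score_set@raw
    adj <- matrix(NA_real_, nrow(raw), ncol(raw))
    ## drop constant PC columns (a zero PC is a no-op regressor)
    keep <- apply(P, 2, stats::sd) > 0
    P <- P[, keep, drop = FALSE]
    for (t in seq_len(ncol(raw))) {
        fit <- stats::lm.fit(cbind(1, P), raw[, t])
        r <- fit$residuals
        s <- stats::sd(r)
        if (!is.finite(s) || s < 1e-12)
            stop("degenerate variance: residual score at cutoff ",
                 score_set@thresholds[t], " is constant")
        adj[, t] <- r / s
        adj[, t] <- adj[, t] - mean(adj[, t])   # guard rounding drift
        adj[, t] <- adj[, t] / stats::sd(adj[, t])
    }
    methods::initialize(score_set, adjusted = adj)
}
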