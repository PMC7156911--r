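#' DosageMatrix: expected allele counts with variant metadata
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding
#' one assay `"DS"` of expected alternate-allele counts in \[0, 2\]
#' (variants in rows, samples in columns) plus per-variant metadata in
#' `rowData`: `variant_id`, `chr`, `pos` (1-based), `ref`, `alt`, `maf`,
#' `info` (imputation quality, r-squared between dosage and true genotype).
#'
#' @aliases DosageMatrix-class
#' @exportClass DosageMatrix
setClass("DosageMatrix", contains = "SummarizedExperiment")

setValidity("DosageMatrix", function(object) {
    msg <- character()
    if (!("DS" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'DS' is required")
    else {
        ds <- SummarizedExperiment::assay(object, "DS")
        bad <- !is.na(ds) & (ds < 0 | ds > 2)
        if (any(bad))
            msg <- c(msg, "dosages must lie in [0, 2]")
    }
    need <- c("variant_id", "chr", "pos", "ref", "alt")
    miss <- setdiff(need, colnames(SummarizedExperiment::rowData(object)))
    if (length(miss))
        msg <- c(msg, paste0("rowData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Construct a DosageMatrix
#'
#' @param dosages numeric matrix, variants x samples, entries in \[0, 2\].
#' @param variants data.frame with columns `variant_id`, `chr`, `pos`,
#'   `ref`, `alt` and optionally `maf`, `info`.
#' @param sample_ids character vector of sample identifiers; defaults to
#'   the column names of `dosages`.
#' @return A [DosageMatrix-class] object.
#' @examples
#' d <- matrix(c(0, 1, 2, 1), 2, 2)
#' v <- data.frame(variant_id = c("v1", "v2"), chr = "1", pos = c(100L, 200L),
#'                 ref = "A", alt = "G")
#' dm <- DosageMatrix(d, v, c("s1", "s2"))
#' dosages(dm)
#' @export
DosageMatrix <- function(dosages, variants, sample_ids = colnames(dosages)) {
    dosages <- as.matrix(dosages)
    if (is.null(sample_ids))
        sample_ids <- paste0("S", seq_len(ncol(dosages)))
    if (nrow(dosages) != nrow(variants))
        stop("nrow(dosages) must equal nrow(variants)")
    if (length(sample_ids) != ncol(dosages))
        stop("length(sample_ids) must equal ncol(dosages)")
    p <- rowMeans(dosages, na.rm = TRUE) / 2
    if (!("alt_freq" %in% names(variants))) variants$alt_freq <- p
    if (!("maf" %in% names(variants))) variants$maf <- pmin(p, 1 - p)
    if (!("info" %in% names(variants))) variants$info <- 1
    dimnames(dosages) <- list(variants$variant_id, sample_ids)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(DS = dosages),
        rowData = S4Vectors::DataFrame(variants),
        colData = S4Vectors::DataFrame(sample_id = sample_ids,
                                       row.names = sample_ids))
    methods::new("DosageMatrix", se)
}

#' @rdname DosageMatrix
#' @param x,object a `DosageMatrix`.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname DosageMatrix
#' @export
setMethod("dosages", "DosageMatrix", function(x)
    SummarizedExperiment::assay(x, "DS"))

#' @rdname DosageMatrix
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname DosageMatrix
#' @export
setMethod("variantInfo", "DosageMatrix", function(x)
    as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname DosageMatrix
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname DosageMatrix
#' @export
setMethod("sampleIds", "DosageMatrix", function(x) colnames(x))

setMethod("show", "DosageMatrix", function(object) {
    cat("DosageMatrix:", nrow(object), "variants x", ncol(object),
        "samples\n")
    vi <- variantInfo(object)
    cat("  chromosomes:", paste(unique(vi$chr), collapse = ", "), "\n")
    cat("  MAF range: [", sprintf("%.3f", min(vi$maf)), ", ",
        sprintf("%.3f", max(vi$maf)), "]\n", sep = "")
})

#' ScoreSet: per-individual polygenic risk scores across p-value cutoffs
#'
#' Raw scores are weighted dosage sums over clumped index variants whose
#' training-GWAS p-value falls strictly below each cutoff. Adjusted scores
#' are the residuals of the raw scores on genotype principal components,
#' standardized to mean 0 / variance 1 over the cohort so logistic slopes
#' read as log-odds per standard deviation.
#'
#' @slot sample_id character vector of sample identifiers.
#' @slot raw numeric matrix, samples x thresholds.
#' @slot adjusted numeric matrix (samples x thresholds) or a 0-row matrix
#'   before [adjustScores()] has been applied.
#' @slot thresholds numeric vector of p-value cutoffs (strictly increasing).
#' @slot n_variants integer vector, variants contributing at each cutoff.
#' @aliases ScoreSet-class
#' @exportClass ScoreSet
setClass("ScoreSet",
    representation(sample_id = "character", raw = "matrix",
                   adjusted = "matrix", thresholds = "numeric",
                   n_variants = "integer"))

setValidity("ScoreSet", function(object) {
    msg <- character()
    k <- length(object@thresholds)
    if (k < 1) msg <- c(msg, "at least one threshold required")
    if (any(diff(object@thresholds) <= 0))
        msg <- c(msg, "thresholds must be strictly increasing")
    if (ncol(object@raw) != k)
        msg <- c(msg, "raw score matrix must have one column per threshold")
    if (nrow(object@raw) != length(object@sample_id))
        msg <- c(msg, "one raw score row per sample required")
    if (length(object@n_variants) != k)
        msg <- c(msg, "n_variants must have one entry per threshold")
    if (any(diff(object@n_variants) < 0))
        msg <- c(msg, "n_variants must be non-decreasing across thresholds")
    if (nrow(object@adjusted) > 0) {
        if (!all(dim(object@adjusted) == dim(object@raw)))
            msg <- c(msg, "adjusted scores must match raw score dimensions")
        mu <- colMeans(object@adjusted)
        v <- apply(object@adjusted, 2, stats::var)
        if (any(abs(mu) > 1e-8) || any(abs(v - 1) > 1e-6))
            msg <- c(msg, "adjusted scores must be standardized (mean 0, var 1)")
    }
    if (length(msg)) msg else TRUE
})

ScoreSet <- function(sample_id, raw, thresholds, n_variants,
                     adjusted = matrix(numeric(), 0, 0)) {
    methods::new("ScoreSet", sample_id = as.character(sample_id),
                 raw = as.matrix(raw), adjusted = adjusted,
                 thresholds = as.numeric(thresholds),
                 n_variants = as.integer(n_variants))
}

#' @rdname ScoreSet-class
#' @param x,object a `ScoreSet`.
#' @export
setGeneric("rawScores", function(x) standardGeneric("rawScores"))

#' @rdname ScoreSet-class
#' @export
setMethod("rawScores", "ScoreSet", function(x) {
    m <- x@raw
    dimnames(m) <- list(x@sample_id, as.character(x@thresholds))
    m
})

#' @rdname ScoreSet-class
#' @export
setGeneric("adjustedScores", function(x) standardGeneric("adjustedScores"))

#' @rdname ScoreSet-class
#' @export
setMethod("adjustedScores", "ScoreSet", function(x) {
    if (nrow(x@adjusted) == 0)
        stop("scores have not been adjusted; run adjustScores() first")
    m <- x@adjusted
    dimnames(m) <- list(x@sample_id, as.character(x@thresholds))
    m
})

#' @rdname ScoreSet-class
#' @export
setGeneric("scoreThresholds", function(x) standardGeneric("scoreThresholds"))

#' @rdname ScoreSet-class
#' @export
setMethod("scoreThresholds", "ScoreSet", function(x) x@thresholds)

#' @rdname ScoreSet-class
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname ScoreSet-class
#' @export
setMethod("nVariants", "ScoreSet", function(x)
    stats::setNames(x@n_variants, as.character(x@thresholds)))

#' @rdname ScoreSet-class
#' @export
setMethod("sampleIds", "ScoreSet", function(x) x@sample_id)

setMethod("show", "ScoreSet", function(object) {
    cat("ScoreSet:", length(object@sample_id), "samples,",
        length(object@thresholds), "p-value cutoffs\n")
    cat("  cutoffs:", paste(format(object@thresholds, trim = TRUE),
                            collapse = " "), "\n")
    cat("  variants/cutoff:", paste(object@n_variants, collapse = " "), "\n")
    cat("  adjusted:", if (nrow(object@adjusted)) "yes" else "no", "\n")
})
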