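## Cohort-level exclusions (questionnaire endorsement, comorbid psychiatric
## diagnoses, relatedness pruning) and genotype principal components for
## population-stratification adjustment.

#' Apply cohort exclusions in narrative order
#'
#' Retains individuals with at least one non-missing symptom endorsement
#' (positive or negative), then removes individuals carrying the comorbid
#' psychiatric-diagnosis flag. Relatedness pruning is applied afterwards
#' via [pruneRelatives()]'s keep-list.
#'
#' @param phenotypes phenotype data.frame with the 7 symptom columns and
#'   `COMORBID`.
#' @param keep_ids optional keep-list from [pruneRelatives()], applied as
#'   the final (relatedness) stage.
#' @return list with `phenotypes` (filtered) and `log` — a data.frame of
#'   stages (`endorsement`, `comorbid`, `relatedness`) with `n_removed`
#'   and `n_remaining` in application order.
#' @export
applyCohortExclusions <- function(phenotypes, keep_ids = NULL) {
    miss <- setdiff(c(SYMPTOMS, "COMORBID"), names(phenotypes))
    if (length(miss))
        stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
    n0 <- nrow(phenotypes)
    any_endorse <- rowSums(!is.na(phenotypes[SYMPTOMS])) > 0
    ph <- phenotypes[any_endorse, , drop = FALSE]
    n1 <- nrow(ph)
    ph <- ph[ph$COMORBID == 0, , drop = FALSE]
    n2 <- nrow(ph)
    if (!is.null(keep_ids)) ph <- ph[ph$ID %in% keep_ids, , drop = FALSE]
    n3 <- nrow(ph)
    rownames(ph) <- NULL
    log <- data.frame(
        stage = c("endorsement", "comorbid", "relatedness"),
        n_removed = c(n0 - n1, n1 - n2, n2 - n3),
        n_remaining = c(n1, n2, n3), stringsAsFactors = FALSE)
    list(phenotypes = ph, log = log)
}

#' Estimate pairwise relatedness from genotype dosages
#'
#' Genomic-relationship (GRM) estimator: the mean over variants of
#' `(d_a - 2p)(d_b - 2p) / (2p(1-p))`. On this scale duplicates score ~1,
#' parent-offspring ~0.5, second-degree relatives ~0.25 and unrelated
#' pairs ~0, matching the identity-by-descent scale at which the 0.25
#' pruning cutoff operates.
#'
#' @param dosage_matrix a [DosageMatrix-class].
#' @param maf_min variants below this MAF are excluded (default 0.05).
#' @param min_report only pairs with relatedness above this value are
#'   returned (keeps the pair list small for large cohorts).
#' @return data.frame `id_a`, `id_b`, `relatedness` (each unordered pair
#'   once, id_a < id_b).
#' @export
estimateRelatedness <- function(dosage_matrix, maf_min = 0.05,
                                min_report = -Inf) {
    D <- dosages(dosage_matrix)                 # variants x samples
    p <- rowMeans(D) / 2
    keep <- pmin(p, 1 - p) > maf_min
    if (sum(keep) < 100)
        stop("too few variants after MAF filter (", sum(keep),
             "); need at least 100 for relatedness estimation")
    D <- D[keep, , drop = FALSE]
    p <- p[keep]
    X <- (D - 2 * p) / sqrt(2 * p * (1 - p))    # standardized, variants x n
    A <- crossprod(X) / nrow(X)                 # n x n GRM
    ids <- colnames(D)
    ut <- which(upper.tri(A), arr.ind = TRUE)
    rel <- A[ut]
    sel <- rel > min_report
    data.frame(id_a = ids[ut[sel, 1]], id_b = ids[ut[sel, 2]],
               relatedness = rel[sel], stringsAsFactors = FALSE)
}

#' Prune one member of each related pair
#'
#' Builds the graph of pairs whose relatedness exceeds `threshold` and
#' greedily removes the highest-degree individual until no edge remains.
#' Ties are broken by fewer non-missing symptom endorsements, then by
#' lexicographically smallest id — making runs reproducible. The result is
#' verified post hoc: no retained pair exceeds the threshold.
#'
#' @param kinship data.frame from [estimateRelatedness()].
#' @param phenotypes phenotype table (endorsement counts for tie-breaks);
#'   `NULL` treats all individuals as equally endorsed.
#' @param threshold relatedness cutoff (default 0.25, second-degree).
#' @param all_ids full sample id universe for the keep-list; defaults to
#'   ids appearing in `kinship` plus `phenotypes$ID`.
#' @return character vector of retained sample ids.
#' @export
pruneRelatives <- function(kinship, phenotypes = NULL, threshold = 0.25,
                           all_ids = NULL) {
    if (is.null(all_ids))
        all_ids <- unique(c(kinship$id_a, kinship$id_b,
                            if (!is.null(phenotypes)) phenotypes$ID))
    edges <- kinship[kinship$relatedness > threshold, c("id_a", "id_b")]
    removed <- character()
    endorse <- if (!is.null(phenotypes))
        stats::setNames(rowSums(!is.na(phenotypes[SYMPTOMS])),
                        phenotypes$ID)
    else stats::setNames(rep(0, length(all_ids)), all_ids)
    while (nrow(edges) > 0) {
        deg <- table(c(edges$id_a, edges$id_b))
        cand <- names(deg)[deg == max(deg)]
        if (length(cand) > 1) {
            e <- endorse[cand]; e[is.na(e)] <- 0
            cand <- cand[e == min(e)]
            cand <- sort(cand)[1]
        }
        removed <- c(removed, cand)
        edges <- edges[edges$id_a != cand & edges$id_b != cand, ,
                       drop = FALSE]
    }
    keep <- setdiff(all_ids, removed)
    bad <- kinship$relatedness > threshold &
        kinship$id_a %in% keep & kinship$id_b %in% keep
    stopifnot("pruning failed to break all related pairs" = !any(bad))
    keep
}

#' Genotype principal components
#'
#' Dosages are centered by twice the allele frequency and scaled by
#' `sqrt(2p(1-p))`; monomorphic variants are skipped. Components are the
#' left singular vectors of the standardized sample-by-variant matrix —
#' mutually orthogonal and unit-normalized over samples — ordered by
#' decreasing explained variance.
#'
#' @param dosage_matrix a [DosageMatrix-class].
#' @param n_components number of components (default 20).
#' @return list with `projections` (data.frame: `sample_id` + `PC1..PCk`)
#'   and `explained` (variance share per component).
#' @export
computePcs <- function(dosage_matrix, n_components = 20L) {
    D <- dosages(dosage_matrix)
    p <- rowMeans(D) / 2
    poly <- p > 0 & p < 1
    if (sum(poly) < 2) stop("degenerate dosage matrix: too few polymorphic variants")
    X <- t((D[poly, , drop = FALSE] - 2 * p[poly]) /
           sqrt(2 * p[poly] * (1 - p[poly])))    # samples x variants
    X <- sweep(X, 2, colMeans(X))                # exact column centering
    k <- as.integer(n_components)
    if (k >= min(dim(X)))
        stop("n_components must be smaller than min(samples, variants)")
    sv <- svd(X, nu = k, nv = 0)
    proj <- as.data.frame(sv$u)
    names(proj) <- paste0("PC", seq_len(k))
    proj <- cbind(data.frame(sample_id = colnames(D),
                             stringsAsFactors = FALSE), proj)
    list(projections = proj,
         explained = (sv$d^2 / sum(sv$d^2))[seq_len(k)])
}
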