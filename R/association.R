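## Inferential statistics: logistic PRS-symptom scans across cutoffs with
## two-level Bonferroni control, clinical-covariate models, joint multi-PRS
## conditional fits, symptom-count regressions, sex-stratified heterogeneity
## and the CAG-corrected residual of age at motor onset.

#' Logistic regression with convergence and separation diagnostics
#'
#' Maximum-likelihood fit by iteratively reweighted least squares (at most
#' 100 iterations, relative log-likelihood tolerance 1e-10). Complete or
#' quasi-complete separation is flagged (`converged = FALSE`) rather than
#' silently returning diverged estimates.
#'
#' @param outcome binary 0/1 vector containing both classes.
#' @param design numeric covariate matrix (no intercept column; one is
#'   added) or `NULL` for an intercept-only model.
#' @return list: `coef`, `se`, `z`, `p` (Wald), `or`, `ci_low`, `ci_high`
#'   (exp(b +/- 1.96 se)), `loglik`, `loglik_null`, `n`, `n_cases`,
#'   `n_controls`, `converged`, `diagnostic`.
#' @export
fitLogistic <- function(outcome, design = NULL) {
    y <- as.numeric(outcome)
    if (anyNA(y)) stop("outcome contains missing values; delete case-wise first")
    if (length(unique(y)) < 2) stop("outcome has a single class")
    X <- if (is.null(design)) matrix(1, length(y), 1)
         else cbind(`(Intercept)` = 1, as.matrix(design))
    if (nrow(X) != length(y)) stop("design row count must match outcome length")
    fit <- suppressWarnings(
        stats::glm.fit(X, y, family = stats::binomial(),
                       control = list(epsilon = 1e-10, maxit = 100)))
    mu <- fit$fitted.values
    ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
    p0 <- mean(y)
    ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
    b <- fit$coefficients
    w <- mu * (1 - mu)
    covmat <- tryCatch(solve(crossprod(X, w * X)),
                       error = function(e)
                           matrix(NA_real_, ncol(X), ncol(X)))
    se <- sqrt(diag(covmat))
    separated <- any(mu < 1e-10 | mu > 1 - 1e-10) &&
        max(abs(b), na.rm = TRUE) > 15
    converged <- isTRUE(fit$converged) && !separated && !anyNA(se)
    z <- b / se
    nm <- colnames(X)
    list(coef = stats::setNames(b, nm), se = stats::setNames(se, nm),
         z = z, p = 2 * stats::pnorm(-abs(z)),
         or = exp(b), ci_low = exp(b - 1.96 * se),
         ci_high = exp(b + 1.96 * se),
         loglik = ll, loglik_null = ll0, n = length(y),
         n_cases = sum(y == 1), n_controls = sum(y == 0),
         converged = converged,
         diagnostic = if (separated) "possible complete separation" else "ok")
}

#' Nagelkerke pseudo-R-squared
#'
#' Cox-Snell `1 - exp(2 (ll0 - ll1) / n)` rescaled by its maximum
#' `1 - exp(2 ll0 / n)` so a saturated fit reaches 1.
#'
#' @param loglik_full,loglik_null log-likelihoods of the full and null
#'   models (`loglik_full >= loglik_null`).
#' @param n number of observations.
#' @return Nagelkerke R-squared in \[0, 1\].
#' @export
nagelkerkeR2 <- function(loglik_full, loglik_null, n) {
    if (n <= 0) stop("n must be positive")
    if (loglik_full < loglik_null - 1e-8)
        stop("loglik_full must be >= loglik_null")
    cs <- 1 - exp(2 * (loglik_null - loglik_full) / n)
    cs_max <- 1 - exp(2 * loglik_null / n)
    if (cs_max <= 0) return(0)
    max(0, min(1, cs / cs_max))
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' `(sum of case ranks - n_case (n_case + 1) / 2) / (n_case n_control)`,
#' with tied scores sharing mid-ranks.
#'
#' @param scores numeric predictor (higher = more case-like).
#' @param outcome binary 0/1 vector with both classes present.
#' @return AUC in \[0, 1\].
#' @export
aucStatistic <- function(scores, outcome) {
    y <- as.numeric(outcome)
    if (length(unique(y)) < 2) stop("outcome has a single class")
    r <- rank(scores)
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Two-level Bonferroni correction for the PRS-symptom scan
#'
#' Level 1 corrects for every PRS-symptom pair; level 2 additionally for
#' the cutoff grid. With the study layout (9 PRS x 7 symptoms x 6 cutoffs,
#' alpha 0.05) the thresholds are 0.05/63 = 7.94e-4 and
#' 0.05/378 = 1.32e-4.
#'
#' @param n_prs,n_symptoms,n_cutoffs scan dimensions.
#' @param alpha family-wise error rate.
#' @return list of class `ScanCorrection` with `level1_threshold` and
#'   `level2_threshold`.
#' @export
scanCorrection <- function(n_prs = 9L, n_symptoms = 7L, n_cutoffs = 6L,
                           alpha = 0.05) {
    l1 <- alpha / (n_prs * n_symptoms)
    l2 <- alpha / (n_prs * n_symptoms * n_cutoffs)
    stopifnot(l2 <= l1, l1 < alpha)   # equal only when n_cutoffs = 1
    structure(list(n_prs = n_prs, n_symptoms = n_symptoms,
                   n_cutoffs = n_cutoffs, alpha = alpha,
                   level1_threshold = l1, level2_threshold = l2),
              class = "ScanCorrection")
}

#' The 27 primary PRS-symptom hypotheses
#'
#' PRS-symptom pairs with prior evidence of association in the general
#' population, tracked so nominally significant results among them can be
#' distinguished from opportunistic hits.
#'
#' @return data.frame with columns `prs` and `symptom` (27 rows).
#' @export
primaryHypotheses <- function() {
    pairs <- list(
        MDD = c("DEP", "IRR", "APT"),
        BPD = c("DEP", "IRR"),
        SCZ = c("DEP", "IRR", "PSY", "APT", "VAB"),
        ADHD = c("IRR", "VAB", "COG"),
        ASD = c("IRR", "PSY", "POB"),
        OCD = "POB",
        AD = c("DEP", "IRR", "APT", "VAB", "COG"),
        PD = c("DEP", "IRR", "APT", "COG"),
        INT = "COG")
    out <- data.frame(
        prs = rep(names(pairs), lengths(pairs)),
        symptom = unlist(pairs, use.names = FALSE),
        stringsAsFactors = FALSE)
    stopifnot(nrow(out) == 27L, !anyNA(match(out$symptom, SYMPTOMS)))
    out
}

## Clinical covariate design: sex (F vs M), CAG, age at motor onset,
## disease duration, study (Enroll vs REGISTRY).
clinicalDesign <- function(phenotypes) {
    cbind(sexF = as.numeric(phenotypes$SEX == "F"),
          CAG = phenotypes$CAG, AMO = phenotypes$AMO,
          DURATION = phenotypes$AGE_LAST - phenotypes$AMO,
          studyE = as.numeric(phenotypes$STUDY == "ENROLL"))
}

#' Scan all PRS x symptom x cutoff associations
#'
#' One logistic fit per combination, with per-symptom case-wise deletion
#' of missing endorsements. Each converged fit is annotated with its
#' significance tier under the two-level Bonferroni correction
#' (`level2` < alpha/(tests x cutoffs) < `level1` < alpha/tests,
#' `nominal` < 0.05, else `none`), whether the pair is a primary
#' hypothesis, and whether the row is the pair's best (minimum-p) cutoff.
#'
#' @param phenotypes phenotype data.frame (analysis cohort).
#' @param score_sets named list of adjusted [ScoreSet-class] objects, one
#'   per PRS; sample order must cover `phenotypes$ID`.
#' @param correction a [scanCorrection()]; defaults to the scan's own
#'   dimensions at alpha 0.05.
#' @param covariate_mode `"none"`, `"clinical"` (sex, CAG, age at motor
#'   onset, duration, study), or `"symptom_count"` (number of other
#'   endorsed symptoms as covariate).
#' @param primary primary-hypothesis pairs ([primaryHypotheses()] by
#'   default).
#' @param symptoms symptom columns to scan.
#' @return data.frame with one row per (PRS, symptom, cutoff): `or`,
#'   `ci_low`, `ci_high`, `p_value`, `nagelkerke_r2`, `auc`, `n_cases`,
#'   `n_controls`, `converged`, `tier`, `is_primary`, `best_cutoff`.
#' @export
scanAssociations <- function(phenotypes, score_sets,
                             correction = NULL,
                             covariate_mode = c("none", "clinical",
                                                "symptom_count"),
                             primary = primaryHypotheses(),
                             symptoms = SYMPTOMS) {
    covariate_mode <- match.arg(covariate_mode)
    stopifnot(length(score_sets) > 0, !is.null(names(score_sets)))
    grid <- scoreThresholds(score_sets[[1]])
    if (is.null(correction))
        correction <- scanCorrection(length(score_sets), length(symptoms),
                                     length(grid))
    rows <- list()
    for (prs in names(score_sets)) {
        adj <- adjustedScores(score_sets[[prs]])
        m <- match(phenotypes$ID, rownames(adj))
        if (anyNA(m))
            stop("scores missing for some phenotype ids (PRS ", prs, ")")
        for (sym in symptoms) {
            y_all <- phenotypes[[sym]]
            ok <- !is.na(y_all)
            base_design <- switch(covariate_mode,
                none = NULL,
                clinical = clinicalDesign(phenotypes),
                symptom_count = {
                    cnt <- rowSums(phenotypes[SYMPTOMS] == 1, na.rm = TRUE)
                    this <- as.numeric(phenotypes[[sym]] == 1)
                    this[is.na(this)] <- 0
                    cbind(other_count = cnt - this)
                })
            for (t in seq_along(grid)) {
                s <- adj[m, t]
                design <- if (is.null(base_design)) cbind(PRS = s)
                          else cbind(PRS = s, base_design)
                fit <- fitLogistic(y_all[ok], design[ok, , drop = FALSE])
                ## variance explained by the PRS over the covariate-only model
                r2 <- if (fit$converged) {
                    ll_red <- if (is.null(base_design)) fit$loglik_null
                    else fitLogistic(y_all[ok],
                                     base_design[ok, , drop = FALSE])$loglik
                    nagelkerkeR2(fit$loglik, ll_red, fit$n)
                } else NA_real_
                rows[[length(rows) + 1L]] <- data.frame(
                    prs = prs, symptom = sym, threshold = grid[t],
                    or = fit$or[["PRS"]], ci_low = fit$ci_low[["PRS"]],
                    ci_high = fit$ci_high[["PRS"]],
                    p_value = fit$p[["PRS"]], nagelkerke_r2 = r2,
                    auc = aucStatistic(s[ok], y_all[ok]),
                    n_cases = fit$n_cases, n_controls = fit$n_controls,
                    converged = fit$converged, stringsAsFactors = FALSE)
            }
        }
    }
    res <- do.call(rbind, rows)
    res$tier <- "none"
    conv <- res$converged
    res$tier[conv & res$p_value < 0.05] <- "nominal"
    res$tier[conv & res$p_value < correction$level1_threshold] <- "level1"
    res$tier[conv & res$p_value < correction$level2_threshold] <- "level2"
    res$is_primary <- paste(res$prs, res$symptom) %in%
        paste(primary$prs, primary$symptom)
    res$best_cutoff <- FALSE
    for (key in unique(paste(res$prs, res$symptom))) {
        i <- which(paste(res$prs, res$symptom) == key & res$converged)
        if (length(i))
            res$best_cutoff[i[which.min(res$p_value[i])]] <- TRUE
    }
    attr(res, "correction") <- correction
    res
}

#' Joint logistic model of one symptom on several PRS simultaneously
#'
#' Fits the symptom on all candidate PRS (each at its chosen cutoff) at
#' once, including the 6 other symptom endorsements as covariates, so each
#' PRS effect is adjusted for the other scores and for symptom
#' correlation. Candidates are conventionally the PRS nominally
#' significant in the single-PRS scan, at their best cutoff.
#'
#' @param symptom symptom column name.
#' @param phenotypes phenotype data.frame.
#' @param score_sets named list of adjusted [ScoreSet-class] objects.
#' @param candidates data.frame with columns `prs` and `threshold`.
#' @param include_symptom_covariates adjust for the 6 other symptom
#'   endorsements (default `TRUE`); `FALSE` reduces the single-candidate
#'   case to the plain single-PRS fit.
#' @param max_kappa condition-number bound; a design exceeding it is
#'   refused rather than ridge-stabilized.
#' @return data.frame: one row per candidate PRS with `or`, `ci_low`,
#'   `ci_high`, `p_value`, plus the fit's `n`.
#' @export
jointMultiPrs <- function(symptom, phenotypes, score_sets, candidates,
                          include_symptom_covariates = TRUE,
                          max_kappa = 1e8) {
    stopifnot(nrow(candidates) >= 1)
    y <- phenotypes[[symptom]]
    others <- setdiff(SYMPTOMS, symptom)
    S <- sapply(seq_len(nrow(candidates)), function(i) {
        ss <- score_sets[[candidates$prs[i]]]
        adj <- adjustedScores(ss)
        ti <- match(candidates$threshold[i], scoreThresholds(ss))
        if (is.na(ti)) stop("cutoff ", candidates$threshold[i],
                            " absent from ScoreSet ", candidates$prs[i])
        adj[match(phenotypes$ID, rownames(adj)), ti]
    })
    S <- matrix(S, ncol = nrow(candidates),
                dimnames = list(NULL, candidates$prs))
    O <- if (include_symptom_covariates) as.matrix(phenotypes[others])
         else matrix(numeric(), nrow(phenotypes), 0)
    ok <- !is.na(y) & stats::complete.cases(S) &
        (ncol(O) == 0 | stats::complete.cases(O))
    design <- cbind(S, O)[ok, , drop = FALSE]
    kp <- kappa(cbind(1, design), exact = TRUE)
    if (!is.finite(kp) || kp > max_kappa)
        stop("collinear PRS set refused: design condition number ",
             format(kp, digits = 3))
    fit <- fitLogistic(y[ok], design)
    sel <- candidates$prs
    data.frame(symptom = symptom, prs = sel,
               threshold = candidates$threshold,
               or = fit$or[sel], ci_low = fit$ci_low[sel],
               ci_high = fit$ci_high[sel], p_value = fit$p[sel],
               n = fit$n, converged = fit$converged,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Linear regression of adjusted PRS on symptom count
#'
#' Symptom count (0-7) is the number of positive endorsements; missing
#' endorsements count as non-endorsed (documented choice). One ordinary
#' least-squares fit per cutoff of the given score set.
#'
#' @param score_set adjusted [ScoreSet-class].
#' @param phenotypes phenotype data.frame.
#' @return data.frame per cutoff: `threshold`, `slope`, `se`, `p_value`,
#'   `n`.
#' @export
symptomCountRegression <- function(score_set, phenotypes) {
    cnt <- rowSums(phenotypes[SYMPTOMS] == 1, na.rm = TRUE)
    if (stats::var(cnt) == 0) stop("symptom count has zero variance")
    adj <- adjustedScores(score_set)
    m <- match(phenotypes$ID, rownames(adj))
    out <- lapply(seq_along(scoreThresholds(score_set)), function(t) {
        fit <- stats::lm(adj[m, t] ~ cnt)
        sm <- summary(fit)$coefficients
        data.frame(threshold = scoreThresholds(score_set)[t],
                   slope = sm["cnt", 1], se = sm["cnt", 2],
                   p_value = sm["cnt", 4], n = length(cnt))
    })
    do.call(rbind, out)
}

#' Sex-stratified PRS-symptom association with heterogeneity test
#'
#' Separate logistic fits in female and male strata; the difference of
#' log odds ratios is tested with
#' `z = (logOR_F - logOR_M) / sqrt(SE_F^2 + SE_M^2)` against a standard
#' normal (two-sided).
#'
#' @param symptom symptom column name.
#' @param scores named numeric vector of adjusted PRS (names = sample id).
#' @param phenotypes phenotype data.frame.
#' @return list with `female`, `male` (each `or`, `ci_low`, `ci_high`,
#'   `p_value`, `n` or `NULL` if the stratum is unusable) and
#'   `heterogeneity_p`.
#' @export
sexStratified <- function(symptom, scores, phenotypes) {
    fitStratum <- function(sex) {
        sel <- phenotypes$SEX == sex & !is.na(phenotypes[[symptom]])
        y <- phenotypes[[symptom]][sel]
        s <- scores[match(phenotypes$ID[sel], names(scores))]
        if (length(unique(y)) < 2) {
            warning("stratum ", sex, " lacks both outcome classes; skipped")
            return(NULL)
        }
        fit <- fitLogistic(y, cbind(PRS = s))
        list(or = fit$or[["PRS"]], log_or = fit$coef[["PRS"]],
             se = fit$se[["PRS"]], ci_low = fit$ci_low[["PRS"]],
             ci_high = fit$ci_high[["PRS"]], p_value = fit$p[["PRS"]],
             n = fit$n)
    }
    f <- fitStratum("F"); m <- fitStratum("M")
    het <- if (!is.null(f) && !is.null(m)) {
        z <- (f$log_or - m$log_or) / sqrt(f$se^2 + m$se^2)
        2 * stats::pnorm(-abs(z))
    } else NA_real_
    list(female = f, male = m, heterogeneity_p = het)
}

#' CAG-corrected residual of age at motor onset
#'
#' Residuals of `log(age at motor onset)` regressed on CAG repeat length
#' within the analysis cohort; an individual with a negative residual had
#' earlier-than-expected onset given their repeat length. Offered as an
#' optional covariate or predictor in symptom models.
#'
#' @param amo age at motor onset (years).
#' @param cag CAG repeat length (disease-causing range, >= 36).
#' @return numeric residual vector (sums to zero by construction).
#' @export
amoResidual <- function(amo, cag) {
    if (length(amo) < 10) stop("need at least 10 individuals")
    if (any(cag < 36)) stop("CAG repeat lengths below 36 are not disease-causing")
    stats::residuals(stats::lm(log(amo) ~ cag))
}
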