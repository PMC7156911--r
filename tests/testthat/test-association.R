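test_that("logistic fits agree with closed forms", {
    ## intercept-only: logit of the case fraction
    y <- rep(c(1, 0), c(30, 70))
    fit <- fitLogistic(y)
    expect_equal(unname(fit$coef[1]), log(30 / 70), tolerance = 1e-8)

    ## single binary covariate: slope equals the 2x2 log cross-product
    x <- rep(c(1, 1, 0, 0), c(20, 30, 10, 40))
    y2 <- rep(c(1, 0, 1, 0), c(20, 30, 10, 40))
    fit2 <- fitLogistic(y2, cbind(x = x))
    expect_equal(unname(fit2$coef["x"]), log(20 * 40 / (30 * 10)),
                 tolerance = 1e-6)
    ## agreement with glm() on coefficients and standard errors
    g <- glm(y2 ~ x, family = binomial())
    expect_equal(unname(fit2$coef), unname(coef(g)), tolerance = 1e-8)
    expect_equal(unname(fit2$se),
                 unname(summary(g)$coefficients[, 2]), tolerance = 1e-6)
    expect_equal(fit2$loglik, as.numeric(logLik(g)), tolerance = 1e-8)

    expect_error(fitLogistic(rep(1, 10)), "single class")

    ## complete separation is flagged, not silently reported
    ys <- rep(c(0, 1), each = 20)
    xs <- c(rnorm(20, -3), rnorm(20, 3))
    fit3 <- fitLogistic(ys, cbind(x = xs))
    expect_false(fit3$converged)
    expect_match(fit3$diagnostic, "separation")
})

test_that("Wald p-values are calibrated under the null", {
    set.seed(111)
    p <- vapply(1:500, function(i) {
        x <- rnorm(300)
        y <- rbinom(300, 1, 0.4)
        fitLogistic(y, cbind(x = x))$p[["x"]]
    }, numeric(1))
    rej <- mean(p < 0.05)
    expect_gt(rej, 0.02)
    expect_lt(rej, 0.08)
})

test_that("Nagelkerke R2 matches its definition", {
    expect_equal(nagelkerkeR2(-50, -50, 100), 0)
    expect_equal(nagelkerkeR2(0, -69.31, 100), 1)
    ## plug-in arithmetic: CS = 0.1699, max = 0.75, ratio = 0.2265
    expect_equal(nagelkerkeR2(-60, -69.31, 100), 0.2265, tolerance = 1e-3)
    expect_error(nagelkerkeR2(-60, -69.31, 0), "positive")
    expect_error(nagelkerkeR2(-70, -69.31, 100))
})

test_that("AUC follows the Mann-Whitney formulation", {
    expect_equal(aucStatistic(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
    expect_equal(aucStatistic(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)
    expect_equal(aucStatistic(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
    ## independent check against pROC on a random fixture
    skip_if_not_installed("pROC")
    set.seed(121)
    s <- rnorm(200); y <- rbinom(200, 1, plogis(s))
    expect_equal(aucStatistic(s, y),
                 as.numeric(suppressMessages(pROC::auc(y, s))),
                 tolerance = 1e-10)
})

test_that("scan correction reproduces the two-level thresholds", {
    corr <- scanCorrection()
    expect_equal(signif(corr$level1_threshold, 3), 7.94e-4)
    expect_equal(signif(corr$level2_threshold, 3), 1.32e-4)
    expect_lt(corr$level2_threshold, corr$level1_threshold)
    expect_equal(nrow(primaryHypotheses()), 27)
    expect_true(all(table(primaryHypotheses()$prs)[c("OCD", "INT")] == 1))
})

test_that("the scan annotates tiers, primaries and best cutoffs", {
    set.seed(131)
    n <- 1500
    s_mdd <- rnorm(n)
    model <- symptomModelSpec(beta_prs = c(0.5, rep(0, 6)), loading = 0,
                              sex_effect = 0, cag_effect = 0,
                              amo_effect = 0, duration_effect = 0,
                              study_effect = 0, missing_rate = 0.02,
                              all_missing_rate = 0, comorbid_rate = 0,
                              seed = 132)
    ph <- simulateSymptoms(s_mdd, model = model)
    sets <- list(MDD = scoreSetFromMatrix(
                     sapply(1:3, function(k) s_mdd + rnorm(n, 0, 0.2 * k)),
                     sample_id = ph$ID),
                 SCZ = scoreSetFromMatrix(matrix(rnorm(3 * n), n),
                                          sample_id = ph$ID))
    scan <- scanAssociations(ph, sets)
    expect_equal(nrow(scan), 2 * 7 * 3)
    top <- scan[which.min(scan$p_value), ]
    expect_equal(top$prs, "MDD")
    expect_equal(top$symptom, "DEP")
    expect_equal(top$tier, "level2")
    expect_true(top$is_primary)
    expect_equal(sum(scan$best_cutoff), 14)      # one per pair
    expect_true(all(scan$n_cases + scan$n_controls <= n))
    ## per-symptom case-wise deletion only drops that symptom's missing
    expect_true(all(scan$n_cases + scan$n_controls >= n - 3 * 50))
    ## an OR above 1 has a CI straddling it
    expect_true(all(scan$ci_low < scan$or & scan$or < scan$ci_high))
})

test_that("clinical covariates can be conditioned on", {
    set.seed(141)
    cohort <- simulateCohort(n_individuals = 400,
                             panel_spec = ldBlockSpec(20, 4, 0.3),
                             n_haplotypes = 2000, seed = 142)
    ph <- cohort$phenotypes
    ph <- applyCohortExclusions(ph)$phenotypes
    s <- rnorm(nrow(ph))
    sets <- list(X = scoreSetFromMatrix(cbind(s), sample_id = ph$ID))
    scan_n <- scanAssociations(ph, sets, covariate_mode = "none")
    scan_c <- scanAssociations(ph, sets, covariate_mode = "clinical")
    scan_k <- scanAssociations(ph, sets, covariate_mode = "symptom_count")
    expect_true(all(scan_c$converged))
    ## a null PRS stays null whatever the conditioning
    expect_gt(min(scan_n$p_value), 1e-4)
    expect_gt(min(scan_c$p_value), 1e-4)
    expect_gt(min(scan_k$p_value), 1e-4)
})

test_that("joint multi-PRS fits reduce, adjust and refuse correctly", {
    set.seed(151)
    n <- 2000
    s1 <- rnorm(n)
    s2 <- 0.5 * s1 + sqrt(0.75) * rnorm(n)    # r = 0.5 with s1
    model <- symptomModelSpec(beta_prs = c(0.3, rep(0, 6)), loading = 0,
                              sex_effect = 0, cag_effect = 0,
                              amo_effect = 0, duration_effect = 0,
                              study_effect = 0, missing_rate = 0,
                              all_missing_rate = 0, comorbid_rate = 0,
                              seed = 152)
    ph <- simulateSymptoms(s1, model = model)
    sets <- list(A = scoreSetFromMatrix(cbind(s1), sample_id = ph$ID),
                 B = scoreSetFromMatrix(cbind(s2), sample_id = ph$ID))

    ## single-candidate reduction equals the plain single-PRS fit
    jr <- jointMultiPrs("DEP", ph, sets, data.frame(prs = "A", threshold = 1),
                        include_symptom_covariates = FALSE)
    single <- fitLogistic(ph$DEP, cbind(A = adjustedScores(sets$A)[, 1]))
    expect_equal(jr$or, unname(single$or["A"]), tolerance = 1e-6)
    expect_equal(jr$p_value, unname(single$p["A"]), tolerance = 1e-6)

    ## the causal PRS survives joint adjustment, the proxy attenuates
    jb <- jointMultiPrs("DEP", ph, sets,
                        data.frame(prs = c("A", "B"), threshold = 1))
    expect_lt(jb$p_value[jb$prs == "A"], 0.05)
    expect_gt(jb$p_value[jb$prs == "B"],
              jb$p_value[jb$prs == "A"])

    ## covariate order invariance
    ph_perm <- ph[, c(setdiff(names(ph), SYM), rev(SYM))]
    jb2 <- jointMultiPrs("DEP", ph_perm, sets,
                         data.frame(prs = c("A", "B"), threshold = 1))
    expect_equal(jb2$or, jb$or, tolerance = 1e-10)

    ## perfectly collinear candidate set is refused with a diagnostic
    sets_dup <- list(A = sets$A, A2 = sets$A)
    expect_error(jointMultiPrs("DEP", ph, sets_dup,
                               data.frame(prs = c("A", "A2"),
                                          threshold = 1)),
                 "condition number")
})

test_that("symptom-count regression recovers a constructed slope", {
    set.seed(161)
    n <- 5000
    model <- symptomModelSpec(beta_prs = 0, loading = 0.8,
                              missing_rate = 0, all_missing_rate = 0,
                              comorbid_rate = 0, seed = 162)
    ph <- simulateSymptoms(rnorm(n), model = model)
    cnt <- rowSums(ph[SYM] == 1, na.rm = TRUE)
    expect_equal(range(cnt), c(0, 7))
    prs <- 0.1 * cnt + rnorm(n)
    ss <- scoreSetFromMatrix(cbind(prs), sample_id = ph$ID)
    res <- symptomCountRegression(ss, ph)
    slope_raw <- res$slope[1] * sd(prs)      # undo standardization
    expect_gt(slope_raw, 0.07)
    expect_lt(slope_raw, 0.13)

    ## null PRS: slope indistinguishable from zero
    ss0 <- scoreSetFromMatrix(cbind(rnorm(n)), sample_id = ph$ID)
    expect_gt(symptomCountRegression(ss0, ph)$p_value[1], 0.001)
})

test_that("sex-stratified fits and heterogeneity behave", {
    set.seed(171)
    n <- 1200
    Y <- matrix(rbinom(n * 7, 1, 0.4), n, 7, dimnames = list(NULL, SYM))
    ph <- makePheno(Y, sex = rep(c("F", "M"), each = n / 2))
    ## identical strata: duplicate the female half into the male half
    ph[SYM][(n / 2 + 1):n, ] <- ph[SYM][1:(n / 2), ]
    s <- rnorm(n / 2)
    scores <- setNames(c(s, s), ph$ID)
    res <- sexStratified("DEP", scores, ph)
    expect_equal(res$heterogeneity_p, 1)
    expect_equal(res$female$or, res$male$or)

    ## simulated differential effect is detectable
    set.seed(172)
    hits <- vapply(1:10, function(i) {
        sF <- rnorm(2000); sM <- rnorm(2000)
        yF <- rbinom(2000, 1, plogis(log(1.4) * sF))
        yM <- rbinom(2000, 1, plogis(0 * sM))
        Y2 <- matrix(0L, 4000, 7, dimnames = list(NULL, SYM))
        Y2[, "DEP"] <- c(yF, yM)
        ph2 <- makePheno(Y2, sex = rep(c("F", "M"), each = 2000),
                         seed = i)
        sc <- setNames(c(sF, sM), ph2$ID)
        sexStratified("DEP", sc, ph2)$heterogeneity_p < 0.05
    }, logical(1))
    expect_gt(mean(hits), 0.5)

    ## empty stratum is skipped with a warning
    ph3 <- ph[ph$SEX == "F", ]
    expect_warning(res3 <- sexStratified("DEP",
                                         scores[ph3$ID], ph3), "stratum")
    expect_null(res3$male)
})

test_that("age-at-onset residuals are centered and carry signal", {
    cov <- simulateCovariates(500, seed = 181)
    r <- amoResidual(cov$AMO, cov$CAG)
    expect_equal(sum(r), 0, tolerance = 1e-8)

    ## exact log-linear onset leaves zero residuals
    amo_exact <- exp(5.6 - 0.045 * cov$CAG)
    expect_equal(max(abs(amoResidual(amo_exact, cov$CAG))), 0,
                 tolerance = 1e-10)
    expect_error(amoResidual(cov$AMO[1:5], cov$CAG[1:5]), "at least 10")
    expect_error(amoResidual(cov$AMO, rep(20, 500)), "36")

    ## earlier-than-expected onset coupled to depression is recovered
    set.seed(182)
    hits <- vapply(1:10, function(i) {
        cv <- simulateCovariates(2000, seed = 1000 + i)
        res <- amoResidual(cv$AMO, cv$CAG)
        z <- scale(res)[, 1]
        y <- rbinom(2000, 1, plogis(qlogis(0.3) - 0.3 * z))
        fitLogistic(y, cbind(r = z))$p[["r"]] < 0.05
    }, logical(1))
    expect_gte(mean(hits), 0.7)
})
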