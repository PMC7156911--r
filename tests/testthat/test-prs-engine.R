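test_that("LD r2 follows the squared-correlation definition", {
    a <- c(0, 1, 2, 0); b <- c(0, 1, 1, 1)
    ## oracle: direct Pearson formula on the 4-point vectors
    r_direct <- sum((a - mean(a)) * (b - mean(b))) /
        sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(ldR2(a, b), r_direct^2)
    expect_equal(ldR2(a, b), 3 / 11, tolerance = 1e-12)

    expect_equal(ldR2(a, a), 1)
    expect_equal(ldR2(a, 2 - a), 1)        # sign-invariance of r2
    expect_warning(r0 <- ldR2(c(1, 1, 1), c(0, 1, 2)), "constant")
    expect_equal(r0, 0)
})

test_that("greedy clumping follows the hand-traced example", {
    set.seed(61)
    n <- 400
    v1 <- rbinom(n, 2, 0.4)
    v2 <- v1; swap <- runif(n) < 0.25
    v2[swap] <- rbinom(sum(swap), 2, 0.4)   # r2(1,2) well above 0.1
    v3 <- rbinom(n, 2, 0.3)
    v4 <- rbinom(n, 2, 0.3)                  # r2(3,4) ~ 0
    D <- rbind(v1, v2, v3, v4)
    rownames(D) <- paste0("SNP", 1:4)
    expect_gt(cor(v1, v2)^2, 0.1)
    expect_lt(cor(v3, v4)^2, 0.1)
    dm <- DosageMatrix(D, data.frame(
        variant_id = paste0("SNP", 1:4), chr = "1",
        pos = c(100000, 200000, 800000, 900000), ref = "A", alt = "G"))
    w <- data.frame(variant_id = paste0("SNP", 1:4), chr = "1",
                    pos = c(100000, 200000, 800000, 900000),
                    aligned_effect = 0.1,
                    p_value = c(1e-8, 1e-6, 1e-7, 1e-3),
                    eaf = 0.3, dropped_reason = "none")
    cl <- clumpVariants(w, dm)
    expect_equal(cl$index$variant_id, c("SNP1", "SNP3", "SNP4"))
    expect_equal(cl$assignment$variant_id, "SNP2")
    expect_equal(cl$assignment$index_id, "SNP1")
})

test_that("clumping edge cases: empty input, unlinked variants", {
    inst <- randomClumpInstance(1, n_snps = 10)
    empty <- inst$weights
    empty$dropped_reason <- "qc_fail"
    expect_message(cl0 <- clumpVariants(empty, inst$dm), "empty")
    expect_equal(nrow(cl0$index), 0)

    ## far-apart variants all become index variants
    w <- inst$weights
    w$pos <- seq_len(10) * 600000L
    vi <- variantInfo(inst$dm)
    vi$pos <- w$pos
    dm <- DosageMatrix(dosages(inst$dm), vi)
    cl <- clumpVariants(w, dm)
    expect_equal(nrow(cl$index), 10)
    expect_equal(cl$index$pos, sort(cl$index$pos))
})

test_that("greedy clump matches the brute-force reference", {
    for (seed in 1:20) {
        inst <- randomClumpInstance(seed)
        cl <- clumpVariants(inst$weights, inst$dm)
        expect_equal(sort(cl$index$variant_id),
                     bruteForceClump(inst$weights, dosages(inst$dm)),
                     info = paste("seed", seed))
    }
})

test_that("scoring sums weighted dosages below each cutoff", {
    D <- rbind(c(0, 1), c(2, 1))            # variants x samples
    rownames(D) <- c("a", "b")
    dm <- DosageMatrix(D, data.frame(variant_id = c("a", "b"), chr = "1",
                                     pos = c(1000, 700000), ref = "A",
                                     alt = "G"), c("S1", "S2"))
    w <- data.frame(variant_id = c("a", "b"), chr = "1",
                    pos = c(1000, 700000), aligned_effect = c(0.5, -0.25),
                    p_value = c(0.001, 0.02), eaf = c(0.25, 0.75),
                    dropped_reason = "none")
    ss <- scorePrs(dm, w, cutoffGrid(c(0.01, 1)))
    expect_equal(unname(rawScores(ss)[, "1"]), c(-0.5, 0.25))
    ## only variant "a" passes p < 0.01
    expect_equal(unname(rawScores(ss)[, 2 - 1]), c(0, 0.5))
    expect_equal(unname(nVariants(ss)), c(1, 2))

    ## boundary: p exactly at the cutoff is excluded (strict <)
    wb <- w; wb$p_value <- c(0.01, 0.02)
    ssb <- scorePrs(dm, wb, cutoffGrid(c(0.01, 1)))
    expect_equal(unname(nVariants(ssb)), c(0, 2))
    expect_true(all(rawScores(ssb)[, 1] == 0))

    ## zero weights give zero scores
    w0 <- w; w0$aligned_effect <- 0
    expect_true(all(rawScores(scorePrs(dm, w0, cutoffGrid(c(0.01, 1)))) == 0))

    ## missing dosages imputed at 2 x effect-allele frequency
    Dna <- D; Dna[1, 2] <- NA
    dmna <- DosageMatrix(Dna, variantInfo(dm), c("S1", "S2"))
    ssna <- scorePrs(dmna, w, cutoffGrid(c(0.01, 1)))
    expect_equal(unname(rawScores(ssna)["S2", "1"]),
                 0.5 * (2 * 0.25) - 0.25 * 1)
})

test_that("index sets are nested across increasing cutoffs", {
    inst <- randomClumpInstance(71, n_snps = 40)
    cl <- clumpVariants(inst$weights, inst$dm)
    ss <- scorePrs(inst$dm, cl$index)
    expect_true(all(diff(nVariants(ss)) >= 0))
    grid <- scoreThresholds(ss)
    for (t in seq_len(length(grid) - 1)) {
        inner <- cl$index$variant_id[cl$index$p_value < grid[t]]
        outer <- cl$index$variant_id[cl$index$p_value < grid[t + 1]]
        expect_true(all(inner %in% outer))
    }
})

test_that("PC adjustment standardizes and orthogonalizes the scores", {
    set.seed(81)
    cohort <- simulateCohort(n_individuals = 150,
                             panel_spec = ldBlockSpec(30, 4, 0.4),
                             n_haplotypes = 2000, seed = 82)
    vi <- variantInfo(cohort$dosages)
    gw <- cohort$gwas[[1]]
    hw <- harmonizeWeights(gw, vi)
    cl <- clumpVariants(hw, cohort$dosages)
    ss <- scorePrs(cohort$dosages, cl$index)
    pcs <- computePcs(cohort$dosages, 20)
    adj <- adjustScores(ss, pcs)
    A <- adjustedScores(adj)
    expect_lt(max(abs(colMeans(A))), 1e-8)
    expect_lt(max(abs(apply(A, 2, var) - 1)), 1e-6)
    U <- as.matrix(pcs$projections[, -1])
    expect_lt(max(abs(cor(A, U))), 1e-8)

    ## all-zero PCs reduce to plain centering and scaling
    pcs0 <- pcs
    pcs0$projections[, -1] <- 0
    A0 <- adjustedScores(adjustScores(ss, pcs0))
    raw <- rawScores(ss)
    expect_equal(unname(A0[, 6]),
                 unname((raw[, 6] - mean(raw[, 6])) / sd(raw[, 6])),
                 tolerance = 1e-10)

    ## collinear limit is refused, not silently standardized
    ss_lin <- prsScan:::ScoreSet(
        sample_id = pcs$projections$sample_id,
        raw = cbind(3 + 2 * pcs$projections$PC1), thresholds = 1,
        n_variants = 1L)
    expect_error(adjustScores(ss_lin, pcs), "degenerate variance")

    ## doubling raw scores changes nothing downstream
    ss2 <- prsScan:::ScoreSet(sample_id = sampleIds(ss),
                              raw = 2 * rawScores(ss),
                              thresholds = scoreThresholds(ss),
                              n_variants = ss@n_variants)
    expect_equal(adjustedScores(adjustScores(ss2, pcs)), A,
                 tolerance = 1e-10)
})

test_that("allele re-coding leaves adjusted scores unchanged", {
    cohort <- simulateCohort(n_individuals = 120,
                             panel_spec = ldBlockSpec(25, 4, 0.3),
                             n_haplotypes = 1500, seed = 91)
    vi <- variantInfo(cohort$dosages)
    gw <- cohort$gwas[[1]]
    pcs <- computePcs(cohort$dosages, 10)
    hw <- harmonizeWeights(gw, vi)
    cl <- clumpVariants(hw, cohort$dosages)
    base <- adjustedScores(adjustScores(scorePrs(cohort$dosages, cl$index),
                                        pcs))
    ## re-code a subset of index variants: d -> 2 - d, w -> -w
    set.seed(92)
    flip_ids <- sample(cl$index$variant_id,
                       ceiling(nrow(cl$index) / 3))
    D2 <- dosages(cohort$dosages)
    D2[flip_ids, ] <- 2 - D2[flip_ids, ]
    dm2 <- DosageMatrix(D2, vi)
    idx2 <- cl$index
    sel <- idx2$variant_id %in% flip_ids
    idx2$aligned_effect[sel] <- -idx2$aligned_effect[sel]
    idx2$eaf[sel] <- 1 - idx2$eaf[sel]
    recoded <- adjustedScores(adjustScores(scorePrs(dm2, idx2), pcs))
    expect_equal(recoded, base, tolerance = 1e-10)
})

test_that("score information is monotone toward the optimal cutoff", {
    cohort <- simulateCohort(n_individuals = 400,
                             panel_spec = ldBlockSpec(80, 4, 0.3),
                             gwas_specs = list(T1 = trainingGwasSpec(
                                 60, 0.4, 20000)),
                             n_haplotypes = 3000, seed = 101)
    vi <- variantInfo(cohort$dosages)
    hw <- harmonizeWeights(cohort$gwas[[1]], vi)
    cl <- clumpVariants(hw, cohort$dosages)
    pcs <- computePcs(cohort$dosages, 10)
    A <- adjustedScores(adjustScores(scorePrs(cohort$dosages, cl$index),
                                     pcs))
    info <- abs(cor(A, cohort$true_scores))
    ## allow small Monte-Carlo dips between neighbouring cutoffs
    expect_true(all(diff(as.numeric(info)) > -0.05))
    expect_gt(info[length(info)], info[1] - 0.05)
    expect_gt(max(info), 0.3)
})
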