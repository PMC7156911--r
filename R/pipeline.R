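## Orchestration: simulate/ingest -> QC + harmonize -> cohort structure ->
## PRS -> association scan -> descriptive report, driven by a YAML config,
## with a machine-readable manifest and deterministic, re-runnable outputs.

#' Default pipeline configuration
#'
#' Returns the configuration list [runPipeline()] consumes; any field can
#' be overridden in a user YAML. With `simulate` present the pipeline
#' generates its own inputs, writes them to disk, and reads them back
#' through the same parsers used for real data.
#'
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function() {
    list(
        seed = 1L,
        simulate = list(
            ## 100 well-separated blocks keep the genomic-relationship
            ## noise SE (~1/sqrt(M_eff)) well below the 0.25 pruning
            ## cutoff; a 20k-haplotype panel keeps chance haplotype
            ## sharing (cryptic relatedness) rare at n = 500
            n_individuals = 500L, n_haplotypes = 20000L,
            n_blocks = 100L, snps_per_block = 5L, within_block_corr = 0.6,
            maf_range = c(0.2, 0.5),
            gwas = list(
                MDD = list(n_causal = 60L, h2_liability = 0.3,
                           n_training = 50000L),
                SCZ = list(n_causal = 60L, h2_liability = 0.3,
                           n_training = 50000L),
                INT = list(n_causal = 60L, h2_liability = 0.3,
                           n_training = 50000L)),
            beta_prs = 0.15, n_relative_pairs = 10L),
        paths = NULL,
        clump = list(window_bp = 500000L, r2_max = 0.1),
        thresholds = c(1e-4, 1e-3, 0.01, 0.05, 0.5, 1),
        qc = list(maf_min = 0.01, info_min = 0.9),
        n_pcs = 20L,
        relatedness_threshold = 0.25,
        mhc = list(chr = "6", start = 25000000, end = 34000000,
                   apply_to = "SCZ"),
        covariate_mode = "none",
        alpha = 0.05)
}

validatePipelineConfig <- function(config) {
    if (is.null(config$simulate)) {
        p <- config$paths
        if (is.null(p)) stop("config requires either 'simulate' or 'paths'")
        for (f in c("vcf", "phenotypes", "sumstats"))
            if (is.null(p[[f]]))
                stop("config validation error: missing path field '", f, "'")
        for (f in c("vcf", "phenotypes"))
            if (!file.exists(p[[f]]))
                stop("config path '", f, "' does not exist: ", p[[f]])
        if (is.null(names(p$sumstats)) || any(names(p$sumstats) == ""))
            stop("config 'sumstats' must be a named list (label = path)")
        if (anyDuplicated(names(p$sumstats)))
            stop("config 'sumstats' labels must be unique")
        for (s in p$sumstats)
            if (!file.exists(s)) stop("sumstats path does not exist: ", s)
    }
    invisible(TRUE)
}

writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    path
}

#' Run the full pipeline
#'
#' Stages, in fixed order: (1) simulate or load inputs; (2) parse summary
#' statistics, dosages and phenotypes; (3) QC filter, harmonize alleles,
#' exclude the MHC from configured scores; (4) endorsement/comorbid
#' exclusions, relatedness pruning, principal components; (5) clump,
#' score, adjust each PRS; (6) association scan, joint multi-PRS models,
#' symptom-count regression; (7) descriptive tables. Every stage's
#' parameters and row counts are recorded in `manifest.json`; re-running
#' with the same config and seed reproduces byte-identical tables.
#'
#' @param config configuration list or path to a YAML file
#'   (see [defaultPipelineConfig()]).
#' @param out_dir output directory (created if absent).
#' @param seed overrides `config$seed` when given.
#' @return Invisibly, a list with the principal results (`scan`, `joint`,
#'   `descriptive`, `exclusion_log`, `score_sets`, `manifest`).
#' @export
runPipeline <- function(config = defaultPipelineConfig(), out_dir,
                        seed = NULL) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    base <- defaultPipelineConfig()
    ## a config that supplies paths (and no simulate block) runs on real
    ## inputs; the simulate defaults must not resurrect themselves
    if (!is.null(config$paths) && is.null(config$simulate))
        base$simulate <- NULL
    user_gwas <- config$simulate$gwas
    config <- utils::modifyList(base, config)
    if (!is.null(user_gwas)) config$simulate$gwas <- user_gwas
    if (!is.null(seed)) config$seed <- as.integer(seed)
    validatePipelineConfig(config)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(config = config, stages = list())
    note <- function(stage, ...) {
        manifest$stages[[stage]] <<- list(...)
        message("[", stage, "] ", paste(names(list(...)),
                unlist(list(...)), sep = "=", collapse = " "))
    }

    ## stage 1: inputs
    if (!is.null(config$simulate)) {
        sim <- config$simulate
        spec <- ldBlockSpec(n_blocks = sim$n_blocks,
                            snps_per_block = sim$snps_per_block,
                            within_block_corr = sim$within_block_corr,
                            maf_range = unlist(sim$maf_range))
        gspecs <- lapply(seq_along(sim$gwas), function(i) {
            g <- sim$gwas[[i]]
            trainingGwasSpec(g$n_causal, g$h2_liability, g$n_training,
                             seed = i)
        })
        names(gspecs) <- names(sim$gwas)
        cohort <- simulateCohort(
            n_individuals = sim$n_individuals, panel_spec = spec,
            gwas_specs = gspecs,
            symptom_model = symptomModelSpec(beta_prs = sim$beta_prs),
            n_relative_pairs = sim$n_relative_pairs,
            n_haplotypes = sim$n_haplotypes, seed = config$seed)
        in_dir <- file.path(out_dir, "inputs")
        dir.create(in_dir, showWarnings = FALSE)
        vcf_path <- file.path(in_dir, "dosages.vcf")
        writeDosageVcf(cohort$dosages, vcf_path)
        ss_paths <- lapply(names(cohort$gwas), function(nm) {
            p <- file.path(in_dir, paste0("sumstats_", nm, ".tsv"))
            writeSummaryStats(cohort$gwas[[nm]], p)
            p
        })
        names(ss_paths) <- names(cohort$gwas)
        ph_path <- file.path(in_dir, "phenotypes.tsv")
        writePhenotypes(cohort$phenotypes, ph_path)
        config$paths <- list(vcf = vcf_path, phenotypes = ph_path,
                             sumstats = ss_paths)
        note("simulate", n_individuals = sim$n_individuals,
             n_variants = nrow(cohort$panel$variants),
             n_gwas = length(ss_paths), seed = config$seed)
    }

    ## stage 2: parse
    dm <- readDosages(config$paths$vcf)
    pheno <- readPhenotypes(config$paths$phenotypes)
    sumstats <- lapply(config$paths$sumstats, readSummaryStats)
    note("parse", n_variants = nrow(dm), n_samples = ncol(dm),
         n_phenotypes = nrow(pheno))

    ## stage 3: QC + harmonize (+ MHC exclusion where configured)
    audit <- list(attr(dm, "rejects"))
    vi <- variantInfo(dm)
    weights <- list()
    for (nm in names(sumstats)) {
        qc <- qcFilterVariants(vi, sumstats[[nm]],
                               maf_min = config$qc$maf_min,
                               info_min = config$qc$info_min)
        hw <- harmonizeWeights(sumstats[[nm]], vi, retain_ids = qc$keep)
        if (nm %in% config$mhc$apply_to) {
            hw <- excludeRegion(hw, config$mhc$chr, config$mhc$start,
                                config$mhc$end)
        }
        drops <- hw$dropped_reason != "none"
        audit[[length(audit) + 1L]] <- data.frame(
            variant_id = hw$variant_id[drops],
            stage = rep(paste0("harmonize_", nm), sum(drops)),
            reason = hw$dropped_reason[drops], stringsAsFactors = FALSE)
        weights[[nm]] <- hw
    }
    note("harmonize",
         scorable = paste(names(weights), vapply(weights, function(w)
             sum(w$dropped_reason == "none"), 0L), collapse = ", "))

    ## stage 4: cohort structure
    excl <- applyCohortExclusions(pheno)
    ids1 <- excl$phenotypes$ID
    kin <- estimateRelatedness(dm[, ids1], min_report = 0.05)
    keep <- pruneRelatives(kin, excl$phenotypes,
                           threshold = config$relatedness_threshold,
                           all_ids = ids1)
    excl <- applyCohortExclusions(pheno, keep_ids = keep)
    cohort_pheno <- excl$phenotypes
    dm_final <- dm[, cohort_pheno$ID]
    n_pcs <- min(config$n_pcs,
                 ncol(dm_final) - 2L, nrow(dm_final) - 1L)
    pcs <- computePcs(dm_final, n_pcs)
    note("structure", n_final = nrow(cohort_pheno), n_pcs = n_pcs,
         n_removed_related = excl$log$n_removed[3])

    ## stage 5: PRS per training GWAS
    grid <- cutoffGrid(config$thresholds)
    cp <- clumpParams(config$clump$window_bp, config$clump$r2_max)
    score_sets <- list()
    clump_report <- list()
    for (nm in names(weights)) {
        cl <- clumpVariants(weights[[nm]], dm_final, cp)
        ss <- scorePrs(dm_final, cl$index, grid)
        score_sets[[nm]] <- adjustScores(ss, pcs)
        clump_report[[nm]] <- data.frame(
            prs = nm, n_index = nrow(cl$index),
            n_removed = nrow(cl$assignment))
    }
    note("prs", cutoffs = length(grid),
         index_counts = paste(vapply(clump_report, function(x)
             x$n_index, 0L), collapse = ","))

    ## stage 6: association
    correction <- scanCorrection(length(score_sets), length(SYMPTOMS),
                                 length(grid), config$alpha)
    scan <- scanAssociations(cohort_pheno, score_sets, correction,
                             covariate_mode = config$covariate_mode)
    joint <- list()
    for (sym in SYMPTOMS) {
        cand <- scan[scan$symptom == sym & scan$converged &
                     scan$p_value < 0.05 & scan$best_cutoff, , drop = FALSE]
        if (nrow(cand) == 0) next
        joint[[sym]] <- jointMultiPrs(sym, cohort_pheno, score_sets,
                                      data.frame(prs = cand$prs,
                                                 threshold = cand$threshold))
    }
    joint <- if (length(joint)) do.call(rbind, c(joint, make.row.names = FALSE))
             else data.frame()
    counts <- do.call(rbind, lapply(names(score_sets), function(nm)
        cbind(prs = nm, symptomCountRegression(score_sets[[nm]],
                                               cohort_pheno))))
    note("associate", n_scan_rows = nrow(scan),
         n_joint_rows = nrow(joint))

    ## stage 7: descriptive
    desc <- symptomSummaryTable(cohort_pheno)
    corr <- symptomCorrelationMatrix(cohort_pheno)

    ## outputs
    writeTsv(scan, file.path(out_dir, "scan.tsv"))
    if (nrow(joint)) writeTsv(joint, file.path(out_dir, "joint.tsv"))
    writeTsv(counts, file.path(out_dir, "symptom_count.tsv"))
    writeTsv(desc, file.path(out_dir, "descriptive.tsv"))
    writeTsv(excl$log, file.path(out_dir, "exclusions.tsv"))
    writeTsv(do.call(rbind, audit), file.path(out_dir, "audit.tsv"))
    writeTsv(pcs$projections, file.path(out_dir, "pcs.tsv"))
    for (nm in names(score_sets)) {
        adj <- adjustedScores(score_sets[[nm]])
        writeTsv(data.frame(ID = rownames(adj), adj, check.names = FALSE),
                 file.path(out_dir, paste0("scores_", nm, ".tsv")))
    }
    manifest$correction <- list(
        level1_threshold = correction$level1_threshold,
        level2_threshold = correction$level2_threshold)
    manifest$row_counts <- list(scan = nrow(scan), joint = nrow(joint),
                                descriptive = nrow(desc),
                                cohort = nrow(cohort_pheno))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    invisible(list(scan = scan, joint = joint, descriptive = desc,
                   symptom_correlation = corr,
                   exclusion_log = excl$log, score_sets = score_sets,
                   pcs = pcs, manifest = manifest))
}

#' Render a human-readable run report
#'
#' @param run_dir directory produced by [runPipeline()].
#' @param path output file (default `report.txt` inside `run_dir`).
#' @return the report lines, invisibly; also written to `path`.
#' @export
makeReport <- function(run_dir, path = file.path(run_dir, "report.txt")) {
    mf <- file.path(run_dir, "manifest.json")
    if (!file.exists(mf)) stop("manifest not found in ", run_dir)
    manifest <- jsonlite::read_json(mf)
    lines <- c("PRS-symptom association run report",
               strrep("=", 40))
    l1 <- manifest$correction$level1_threshold
    l2 <- manifest$correction$level2_threshold
    lines <- c(lines, sprintf(
        "Bonferroni thresholds: level 1 %.3g (per PRS-symptom pair), level 2 %.3g (pairs x cutoffs)",
        l1, l2))
    scan_path <- file.path(run_dir, "scan.tsv")
    if (file.exists(scan_path)) {
        scan <- utils::read.delim(scan_path)
        sig <- scan[scan$tier %in% c("level1", "level2"), , drop = FALSE]
        lines <- c(lines, "", sprintf("Scan: %d fits; %d at level 1+, %d at level 2",
                                      nrow(scan), sum(scan$tier %in% c("level1", "level2")),
                                      sum(scan$tier == "level2")))
        if (nrow(sig) == 0) {
            lines <- c(lines, sprintf(
                "No association survives correction (thresholds %.3g / %.3g).",
                l1, l2))
        } else {
            lines <- c(lines, apply(sig, 1, function(r) sprintf(
                "  %s ~ %s @ p<%s: OR %.3f, p %.3g [%s]",
                r[["symptom"]], r[["prs"]], r[["threshold"]],
                as.numeric(r[["or"]]), as.numeric(r[["p_value"]]),
                r[["tier"]])))
        }
    } else warning("scan.tsv missing; partial report")
    joint_path <- file.path(run_dir, "joint.tsv")
    if (file.exists(joint_path)) {
        joint <- utils::read.delim(joint_path)
        lines <- c(lines, "", sprintf("Joint multi-PRS fits: %d rows", nrow(joint)))
    }
    desc_path <- file.path(run_dir, "descriptive.tsv")
    if (file.exists(desc_path)) {
        desc <- utils::read.delim(desc_path)
        lines <- c(lines, "", "Symptom frequencies (% endorsed) and sex odds ratios:",
                   sprintf("  %-4s %5.1f%%  OR %.2f (%.2f-%.2f)",
                           desc$symptom, desc$freq_pct, desc$or,
                           desc$ci_low, desc$ci_high))
    } else warning("descriptive.tsv missing; partial report")
    writeLines(lines, path)
    invisible(lines)
}
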