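## Reading and validation of summary statistics, VCF dosages and phenotype
## tables, plus allele harmonization of training-GWAS weights to the target
## cohort. Every exclusion is carried explicitly (dropped_reason / audit
## rows) so that input count = retained + sum of per-reason drops.

CANONICAL_SUMSTAT_COLS <- c(variant_id = "SNP", chr = "CHR", pos = "BP",
                            effect_allele = "A1", other_allele = "A2",
                            effect = "BETA", p_value = "P",
                            eaf = "FRQ", info = "INFO")

#' Read GWAS summary statistics from delimited text
#'
#' @param path file path (tab- or whitespace-delimited, with header).
#' @param column_map named character vector mapping canonical fields
#'   (`variant_id`, `chr`, `pos`, `effect_allele`, `other_allele`,
#'   `effect`, `p_value`, and optionally `eaf`, `info`) to the file's
#'   column names. Defaults to the `SNP CHR BP A1 A2 BETA P FRQ INFO`
#'   convention.
#' @return data.frame of records in canonical column order. Malformed rows
#'   (non-finite effect, p-value outside (0, 1\]) are dropped and reported
#'   in `attr(, "rejects")`; duplicated variant ids are flagged in
#'   `attr(, "duplicates")`.
#' @export
readSummaryStats <- function(path, column_map = CANONICAL_SUMSTAT_COLS) {
    if (!file.exists(path)) stop("summary-statistics file not found: ", path)
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             check.names = FALSE)
    cm <- CANONICAL_SUMSTAT_COLS
    cm[names(column_map)] <- column_map
    required <- c("variant_id", "chr", "pos", "effect_allele",
                  "other_allele", "effect", "p_value")
    miss <- required[!(cm[required] %in% names(raw))]
    if (length(miss))
        stop("summary-statistics schema error: missing column(s) ",
             paste(sprintf("%s (mapped from '%s')", cm[miss], miss),
                   collapse = ", "))
    rec <- data.frame(variant_id = as.character(raw[[cm["variant_id"]]]),
                      chr = as.character(raw[[cm["chr"]]]),
                      pos = as.integer(raw[[cm["pos"]]]),
                      effect_allele = toupper(raw[[cm["effect_allele"]]]),
                      other_allele = toupper(raw[[cm["other_allele"]]]),
                      effect = as.numeric(raw[[cm["effect"]]]),
                      p_value = as.numeric(raw[[cm["p_value"]]]),
                      stringsAsFactors = FALSE)
    rec$eaf <- if (cm["eaf"] %in% names(raw))
        as.numeric(raw[[cm["eaf"]]]) else NA_real_
    rec$info <- if (cm["info"] %in% names(raw))
        as.numeric(raw[[cm["info"]]]) else NA_real_
    bad_p <- is.na(rec$p_value) | rec$p_value <= 0 | rec$p_value > 1
    bad_eff <- !is.finite(rec$effect)
    bad_pos <- is.na(rec$pos) | rec$pos < 1
    bad_allele <- rec$effect_allele == rec$other_allele |
        rec$effect_allele == "" | rec$other_allele == ""
    reason <- rep(NA_character_, nrow(rec))
    reason[bad_allele] <- "invalid_alleles"
    reason[bad_pos] <- "invalid_position"
    reason[bad_eff] <- "invalid_effect"
    reason[bad_p] <- "invalid_p"
    keep <- is.na(reason)
    rejects <- data.frame(variant_id = rec$variant_id[!keep],
                          stage = rep("read_summary_stats", sum(!keep)),
                          reason = reason[!keep], stringsAsFactors = FALSE)
    out <- rec[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "rejects") <- rejects
    attr(out, "duplicates") <-
        unique(out$variant_id[duplicated(out$variant_id)])
    out
}

#' Read genotype dosages from a VCF
#'
#' Uses the `DS` FORMAT field when present, otherwise converts `GT` to an
#' alternate-allele count. Biallelic SNVs only; multiallelic rows are
#' rejected and counted. Per-variant MAF is computed from the dosages and
#' imputation quality taken from the `INFO=` key when present.
#'
#' @param vcf_path path to a VCF 4.x file.
#' @param sample_subset optional character vector of sample ids to keep;
#'   ids absent from the VCF raise an error listing them.
#' @return A [DosageMatrix-class]; rejected rows in `attr(, "rejects")`.
#' @export
readDosages <- function(vcf_path, sample_subset = NULL) {
    if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
    vcf <- suppressWarnings(VariantAnnotation::readVcf(vcf_path))
    rr <- SummarizedExperiment::rowRanges(vcf)
    n_alt <- lengths(VariantAnnotation::alt(vcf))
    multi <- n_alt != 1L
    g <- VariantAnnotation::geno(vcf)
    if ("DS" %in% names(g)) {
        D <- g$DS
        storage.mode(D) <- "double"
    } else if ("GT" %in% names(g)) {
        gt <- g$GT
        D <- matrix(vapply(gt, function(s) {
            if (is.na(s) || grepl("\\.", s)) return(NA_real_)
            sum(as.integer(strsplit(s, "[/|]")[[1]]) > 0)
        }, numeric(1)), nrow(gt), ncol(gt), dimnames = dimnames(gt))
    } else stop("VCF carries neither DS nor GT genotype fields")
    samples <- colnames(D)
    if (!is.null(sample_subset)) {
        missing_ids <- setdiff(sample_subset, samples)
        if (length(missing_ids))
            stop("samples absent from VCF: ",
                 paste(missing_ids, collapse = ", "))
        D <- D[, sample_subset, drop = FALSE]
        samples <- sample_subset
    }
    ids <- names(rr)
    alt_chr <- vapply(seq_along(n_alt), function(i) {
        a <- VariantAnnotation::alt(vcf)[[i]]
        if (length(a)) as.character(a[1]) else NA_character_
    }, character(1))
    info_df <- VariantAnnotation::info(vcf)
    qual <- if ("INFO" %in% names(info_df))
        as.numeric(info_df$INFO) else rep(NA_real_, length(ids))
    qual[is.na(qual)] <- 1
    rejects <- data.frame(variant_id = ids[multi],
                          stage = rep("read_dosages", sum(multi)),
                          reason = rep("multiallelic", sum(multi)),
                          stringsAsFactors = FALSE)
    keep <- !multi
    variants <- data.frame(
        variant_id = ids[keep],
        chr = as.character(GenomeInfoDb::seqnames(rr))[keep],
        pos = BiocGenerics::start(rr)[keep],
        ref = as.character(VariantAnnotation::ref(vcf))[keep],
        alt = alt_chr[keep],
        info = qual[keep], stringsAsFactors = FALSE)
    dm <- DosageMatrix(D[keep, , drop = FALSE], variants, samples)
    attr(dm, "rejects") <- rejects
    dm
}

#' QC filter on target-cohort variants
#'
#' A variant is retained iff its target MAF is strictly greater than
#' `maf_min`, its target imputation quality strictly greater than
#' `info_min`, and — when the matching summary record carries an
#' imputation quality — that value is also strictly greater than
#' `info_min`.
#'
#' @param variants target-variant data.frame (e.g. [variantInfo()]) with
#'   `variant_id`, `chr`, `pos`, `maf`, `info`.
#' @param summary optional summary-statistics data.frame; matched to
#'   targets by chromosome:position.
#' @param maf_min minor-allele-frequency threshold (default 0.01).
#' @param info_min imputation-quality threshold (default 0.9).
#' @return list with `keep` (retained variant ids) and `drops`
#'   (data.frame `variant_id`, `stage`, `reason`).
#' @export
qcFilterVariants <- function(variants, summary = NULL, maf_min = 0.01,
                             info_min = 0.9) {
    stopifnot(maf_min > 0, maf_min < 1, info_min > 0, info_min < 1)
    reason <- rep(NA_character_, nrow(variants))
    s_info <- rep(NA_real_, nrow(variants))
    if (!is.null(summary)) {
        key_t <- paste(variants$chr, variants$pos, sep = ":")
        key_s <- paste(summary$chr, summary$pos, sep = ":")
        s_info <- summary$info[match(key_t, key_s)]
    }
    reason[!is.na(s_info) & s_info <= info_min] <- "low_training_info"
    reason[variants$info <= info_min] <- "low_info"
    reason[variants$maf <= maf_min] <- "low_maf"
    drops <- data.frame(variant_id = variants$variant_id[!is.na(reason)],
                        stage = rep("qc_filter", sum(!is.na(reason))),
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
    list(keep = variants$variant_id[is.na(reason)], drops = drops)
}

ALLELE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

isAmbiguous <- function(a1, a2) {
    (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize training-GWAS weights to the target cohort's counted allele
#'
#' Records are matched to target variants on chromosome:position. If the
#' (effect, other) allele pair equals the target's (alt, ref), the effect
#' is carried as is; if it equals (ref, alt), the effect's sign is flipped.
#' Strand-complement matches are resolved by complementing both alleles
#' first. Strand-ambiguous (A/T, C/G) variants are dropped by default;
#' with `drop_ambiguous = FALSE` they are oriented by allele-frequency
#' concordance (|difference| < `freq_tol`) and dropped when frequencies
#' cannot decide. Positions hosting duplicate records are dropped entirely.
#'
#' @param summary summary-statistics data.frame ([readSummaryStats()]).
#' @param variants target-variant data.frame with `variant_id`, `chr`,
#'   `pos`, `ref`, `alt` and `alt_freq` (as from [variantInfo()]).
#' @param drop_ambiguous drop A/T and C/G variants (default `TRUE`).
#' @param freq_tol frequency-concordance tolerance for ambiguous variants.
#' @param retain_ids optional set of QC-passing target variant ids; matched
#'   records outside it get `dropped_reason = "qc_fail"`.
#' @return data.frame with one row per summary record: `variant_id` (the
#'   target id when matched), `chr`, `pos`, `aligned_effect`, `p_value`,
#'   `eaf` (aligned to the target alt allele), `flip_applied`,
#'   `dropped_reason` (`"none"` for records that participate in scoring).
#' @export
harmonizeWeights <- function(summary, variants, drop_ambiguous = TRUE,
                             freq_tol = 0.2, retain_ids = NULL) {
    key_s <- paste(summary$chr, summary$pos, sep = ":")
    key_t <- paste(variants$chr, variants$pos, sep = ":")
    dup_s <- key_s %in% key_s[duplicated(key_s)]
    dup_t <- key_t %in% key_t[duplicated(key_t)]
    idx <- match(key_s, key_t)
    n <- nrow(summary)
    out <- data.frame(variant_id = summary$variant_id,
                      chr = summary$chr, pos = summary$pos,
                      aligned_effect = NA_real_,
                      p_value = summary$p_value,
                      eaf = NA_real_, flip_applied = FALSE,
                      dropped_reason = "none", stringsAsFactors = FALSE)
    has_eaf <- "eaf" %in% names(summary)
    alt_freq <- if ("alt_freq" %in% names(variants)) variants$alt_freq
                else rep(NA_real_, nrow(variants))
    for (i in seq_len(n)) {
        if (dup_s[i] || (!is.na(idx[i]) && dup_t[idx[i]])) {
            out$dropped_reason[i] <- "duplicate"; next
        }
        if (is.na(idx[i])) {
            out$dropped_reason[i] <- "allele_mismatch"; next
        }
        j <- idx[i]
        ea <- summary$effect_allele[i]; oa <- summary$other_allele[i]
        ref <- variants$ref[j]; alt <- variants$alt[j]
        ambiguous <- isAmbiguous(ea, oa)
        flip <- NA
        if (ambiguous) {
            if (drop_ambiguous) {
                out$dropped_reason[i] <- "strand_ambiguous"; next
            }
            pair_ok <- (ea == alt && oa == ref) || (ea == ref && oa == alt)
            eafi <- if (has_eaf) summary$eaf[i] else NA_real_
            if (!pair_ok || is.na(eafi) || is.na(alt_freq[j])) {
                out$dropped_reason[i] <- "strand_ambiguous"; next
            }
            if (abs(eafi - alt_freq[j]) < freq_tol) flip <- FALSE
            else if (abs((1 - eafi) - alt_freq[j]) < freq_tol) flip <- TRUE
            else { out$dropped_reason[i] <- "strand_ambiguous"; next }
        } else {
            if (ea == alt && oa == ref) flip <- FALSE
            else if (ea == ref && oa == alt) flip <- TRUE
            else {
                cea <- unname(ALLELE_COMPLEMENT[ea])
                coa <- unname(ALLELE_COMPLEMENT[oa])
                if (!is.na(cea) && !is.na(coa)) {
                    if (cea == alt && coa == ref) flip <- FALSE
                    else if (cea == ref && coa == alt) flip <- TRUE
                }
            }
            if (is.na(flip)) {
                out$dropped_reason[i] <- "allele_mismatch"; next
            }
        }
        if (!is.null(retain_ids) &&
            !(variants$variant_id[j] %in% retain_ids)) {
            out$dropped_reason[i] <- "qc_fail"; next
        }
        out$variant_id[i] <- variants$variant_id[j]
        out$flip_applied[i] <- flip
        out$aligned_effect[i] <- if (flip) -summary$effect[i]
                                 else summary$effect[i]
        out$eaf[i] <- if (has_eaf && !is.na(summary$eaf[i])) {
            if (flip) 1 - summary$eaf[i] else summary$eaf[i]
        } else alt_freq[j]
    }
    out
}

#' Remove a genomic region from a weight table
#'
#' Removes every variant on `chromosome` with `start_bp <= pos <= end_bp`
#' (closed interval, 1-based as in VCF). The default interval is the
#' extended MHC, chr6:25,000,000-34,000,000, conventionally excluded from
#' schizophrenia-derived scores because of long-range LD.
#'
#' @param weights data.frame with `chr` and `pos` columns (e.g. the output
#'   of [harmonizeWeights()]).
#' @param chromosome chromosome label to match.
#' @param start_bp,end_bp closed-interval bounds in base pairs.
#' @return `weights` without the region; `attr(, "n_removed")` reports the
#'   count and `attr(, "removed_ids")` the ids.
#' @export
excludeRegion <- function(weights, chromosome = "6",
                          start_bp = 25000000, end_bp = 34000000) {
    stopifnot(start_bp < end_bp)
    inside <- weights$chr == as.character(chromosome) &
        weights$pos >= start_bp & weights$pos <= end_bp
    out <- weights[!inside, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_removed") <- sum(inside)
    attr(out, "removed_ids") <- weights$variant_id[inside]
    out
}

#' Read a phenotype table written by [writePhenotypes()]
#'
#' @param path tab-separated file with header `ID SEX CAG AMO AGE_LAST
#'   STUDY COMORBID DEP IRR PSY VAB APT POB COG`.
#' @return data.frame with symptoms as integer 1/0/NA.
#' @export
readPhenotypes <- function(path) {
    if (!file.exists(path)) stop("phenotype file not found: ", path)
    ph <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("ID", "SEX", "CAG", "AMO", "AGE_LAST", "STUDY", "COMORBID",
              SYMPTOMS)
    miss <- setdiff(need, names(ph))
    if (length(miss))
        stop("phenotype schema error: missing column(s) ",
             paste(miss, collapse = ", "))
    for (s in SYMPTOMS) ph[[s]] <- as.integer(ph[[s]])
    ph
}
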