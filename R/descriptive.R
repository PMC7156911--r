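## Descriptive cohort statistics: symptom frequencies, female-vs-male 2x2
## odds ratios with Woolf confidence intervals and chi-square tests, and
## the pairwise symptom phi-correlation matrix.

#' A 2x2 symptom-by-sex table
#'
#' @param f_pos,f_neg,m_pos,m_neg non-negative counts: females/males
#'   with/without the symptom.
#' @return list of class `TwoByTwo` (`a` = f_pos, `b` = f_neg, `c` = m_pos,
#'   `d` = m_neg).
#' @export
twoByTwo <- function(f_pos, f_neg, m_pos, m_neg) {
    cells <- c(f_pos, f_neg, m_pos, m_neg)
    if (any(cells < 0) || sum(cells) == 0)
        stop("counts must be non-negative with positive total")
    structure(list(a = f_pos, b = f_neg, c = m_pos, d = m_neg),
              class = "TwoByTwo")
}

#' Symptom frequency from a 2x2 table
#'
#' `100 (a + c) / (a + b + c + d)`: percent endorsing among individuals
#' with a recorded diagnosis of that symptom.
#'
#' @param table a [twoByTwo()].
#' @param digits decimals to round to (default 1, as conventionally
#'   reported).
#' @return percentage.
#' @export
symptomFrequency <- function(table, digits = 1) {
    stopifnot(inherits(table, "TwoByTwo"))
    tot <- table$a + table$b + table$c + table$d
    round(100 * (table$a + table$c) / tot, digits)
}

#' Female-vs-male odds ratio with Woolf CI and chi-square p
#'
#' `OR = (a/b) / (c/d)`; 95% CI `exp(log OR +/- 1.96 sqrt(1/a + 1/b +
#' 1/c + 1/d))`; p from the Pearson chi-square without continuity
#' correction. A zero cell triggers the Haldane-Anscombe correction
#' (0.5 added to every cell), flagged in the result.
#'
#' @param table a [twoByTwo()].
#' @return list: `or`, `ci_low`, `ci_high`, `p_value`,
#'   `haldane_corrected`.
#' @export
sexOddsRatio <- function(table) {
    stopifnot(inherits(table, "TwoByTwo"))
    a <- table$a; b <- table$b; cc <- table$c; d <- table$d
    if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0)
        stop("zero margin: odds ratio undefined")
    corrected <- any(c(a, b, cc, d) == 0)
    if (corrected) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
    or <- (a / b) / (cc / d)
    se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
    p <- suppressWarnings(
        stats::chisq.test(matrix(c(table$a, table$b, table$c, table$d),
                                 2, byrow = TRUE),
                          correct = FALSE)$p.value)
    list(or = or, ci_low = exp(log(or) - 1.96 * se),
         ci_high = exp(log(or) + 1.96 * se), p_value = p,
         haldane_corrected = corrected)
}

#' Pairwise symptom phi-correlation matrix
#'
#' Phi coefficient (Pearson correlation of the 1/0 indicators) per symptom
#' pair on pairwise-complete cases, with chi-square p-values. A constant
#' symptom yields an undefined (NA) row, flagged.
#'
#' @param phenotypes phenotype data.frame with the 7 symptom columns.
#' @param min_pairs minimum pairwise-complete observations (default 30).
#' @return list with `phi` (7x7 symmetric, unit diagonal), `p` (7x7),
#'   `undefined` (character vector of degenerate symptoms).
#' @export
symptomCorrelationMatrix <- function(phenotypes, min_pairs = 30L) {
    k <- length(SYMPTOMS)
    phi <- matrix(NA_real_, k, k, dimnames = list(SYMPTOMS, SYMPTOMS))
    pm <- phi
    diag(phi) <- 1
    undefined <- character()
    for (i in seq_len(k)) {
        xi <- phenotypes[[SYMPTOMS[i]]]
        if (stats::var(xi, na.rm = TRUE) == 0) {
            undefined <- c(undefined, SYMPTOMS[i]); next
        }
        for (j in seq_len(k)) {
            if (j <= i) next
            xj <- phenotypes[[SYMPTOMS[j]]]
            ok <- !is.na(xi) & !is.na(xj)
            if (sum(ok) < min_pairs)
                stop("fewer than ", min_pairs,
                     " pairwise-complete cases for ",
                     SYMPTOMS[i], "-", SYMPTOMS[j])
            if (stats::var(xj[ok]) == 0) next
            r <- stats::cor(xi[ok], xj[ok])
            phi[i, j] <- phi[j, i] <- r
            chi2 <- r^2 * sum(ok)
            pm[i, j] <- pm[j, i] <- stats::pchisq(chi2, 1,
                                                  lower.tail = FALSE)
        }
    }
    list(phi = phi, p = pm, undefined = undefined)
}

#' Descriptive symptom summary table
#'
#' One row per symptom: endorsement frequency among recorded diagnoses,
#' sex-split 2x2 counts, female-vs-male odds ratio with Woolf 95% CI and
#' chi-square p-value.
#'
#' @param phenotypes phenotype data.frame.
#' @return data.frame: `symptom`, `freq_pct`, `f_pos`, `f_neg`, `m_pos`,
#'   `m_neg`, `or`, `ci_low`, `ci_high`, `p_value`.
#' @export
symptomSummaryTable <- function(phenotypes) {
    rows <- lapply(SYMPTOMS, function(s) {
        y <- phenotypes[[s]]
        f <- phenotypes$SEX == "F"
        tab <- twoByTwo(sum(y == 1 & f, na.rm = TRUE),
                        sum(y == 0 & f, na.rm = TRUE),
                        sum(y == 1 & !f, na.rm = TRUE),
                        sum(y == 0 & !f, na.rm = TRUE))
        orr <- sexOddsRatio(tab)
        data.frame(symptom = s, freq_pct = symptomFrequency(tab),
                   f_pos = tab$a, f_neg = tab$b, m_pos = tab$c,
                   m_neg = tab$d, or = orr$or, ci_low = orr$ci_low,
                   ci_high = orr$ci_high, p_value = orr$p_value,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
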