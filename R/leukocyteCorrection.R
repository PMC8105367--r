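## Leukocyte-fraction correction: immune-related genes are those whose
## expression tracks the leukocyte fraction and anti-tracks tumor purity;
## their expression is rescaled by the leukocyte fraction.

#' Select immune-related genes by fraction/purity correlation
#'
#' A gene is selected iff Pearson r(expression, leukocyte fraction) >=
#' \code{cutoff} AND Pearson r(expression, tumor purity) <= -\code{cutoff}
#' across all samples with both fractions available. Zero-variance genes
#' are excluded (correlation undefined).
#'
#' @param cohort an \linkS4class{IpmgCohort} carrying
#'   \code{leukocyte_fraction} and \code{tumor_purity} columns.
#' @param cutoff correlation magnitude cutoff (default 0.3).
#' @return data.frame with \code{gene}, \code{r_fraction}, \code{r_purity},
#'   \code{selected}.
#' @export
selectImmuneGenes <- function(cohort, cutoff = 0.3) {
    cd <- clinicalTable(cohort)
    if (!all(c("leukocyte_fraction", "tumor_purity") %in% colnames(cd)))
        stop("cohort carries no leukocyte fraction / tumor purity")
    ok <- !is.na(cd$leukocyte_fraction) & !is.na(cd$tumor_purity)
    if (sum(ok) < 3) stop("need >= 3 samples with both fractions")
    m <- exprMatrix(cohort)[, ok, drop = FALSE]
    fr <- cd$leukocyte_fraction[ok]
    pu <- cd$tumor_purity[ok]
    sds <- apply(m, 1L, stats::sd)
    rf <- rep(NA_real_, nrow(m)); rp <- rep(NA_real_, nrow(m))
    nz <- sds > 0
    rf[nz] <- as.vector(stats::cor(t(m[nz, , drop = FALSE]), fr))
    rp[nz] <- as.vector(stats::cor(t(m[nz, , drop = FALSE]), pu))
    out <- data.frame(gene = rownames(m), r_fraction = rf, r_purity = rp)
    out$selected <- !is.na(rf) & !is.na(rp) &
        rf >= cutoff & rp <= -cutoff
    out
}

#' Rescale immune-gene expression by leukocyte fraction
#'
#' For the selected immune genes, expression is divided by
#' \code{max(leukocyte_fraction, floor)}; other genes pass through
#' unchanged. Samples lacking a fraction are dropped from the corrected
#' cohort with a warning.
#'
#' @param cohort an \linkS4class{IpmgCohort}.
#' @param immuneGenes character vector of genes to correct.
#' @param floor lower bound applied to the fraction before division
#'   (default 0.01) to keep near-zero fractions from inflating values.
#' @return cohort at stage \code{"fraction_corrected"}.
#' @export
correctByFraction <- function(cohort, immuneGenes, floor = 0.01) {
    cd <- clinicalTable(cohort)
    miss <- is.na(cd$leukocyte_fraction)
    if (any(miss)) {
        warning(sum(miss), " samples without leukocyte fraction dropped")
        cohort <- cohort[, !miss]
        cd <- clinicalTable(cohort)
    }
    m <- exprMatrix(cohort)
    immuneGenes <- intersect(immuneGenes, rownames(m))
    f <- pmax(cd$leukocyte_fraction, floor)
    m[immuneGenes, ] <- sweep(m[immuneGenes, , drop = FALSE], 2L, f, "/")
    setExprMatrix(cohort, m, stage = "fraction_corrected")
}

#' Run the whole leukocyte-fraction correction stage
#'
#' @param cohort normalized \linkS4class{IpmgCohort} with fractions.
#' @param cutoff correlation cutoff.
#' @param floor fraction floor before division.
#' @return list: \code{immuneGenes} (selection table), \code{genes}
#'   (selected ids), \code{cohort} (corrected).
#' @export
fractionCorrect <- function(cohort, cutoff = 0.3, floor = 0.01) {
    sel <- selectImmuneGenes(cohort, cutoff = cutoff)
    genes <- sel$gene[sel$selected]
    list(immuneGenes = sel, genes = genes,
         cohort = correctByFraction(cohort, genes, floor = floor))
}
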