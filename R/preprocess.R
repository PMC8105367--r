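## Expression-table preparation: per-cancer-type mean imputation, low
## expression filtering, log2(x + 1) transform and quantile normalization.

#' Impute missing expression by cancer-type mean
#'
#' Each missing cell is replaced by the mean of the non-missing values of
#' that gene within the same cancer type; if a gene is entirely missing
#' within a type, the gene's global mean is used instead. A gene missing
#' everywhere is an error.
#'
#' @param cohort an \linkS4class{IpmgCohort}.
#' @return cohort at stage \code{"imputed"} with no remaining NA.
#' @export
imputeByCancerType <- function(cohort) {
    m <- exprMatrix(cohort)
    if (!anyNA(m)) return(setExprMatrix(cohort, m, stage = "imputed"))
    type <- clinicalTable(cohort)$cancer_type
    allNA <- rowSums(!is.na(m)) == 0
    if (any(allNA))
        stop("gene(s) missing in every sample: ",
             paste(utils::head(rownames(m)[allNA], 3), collapse = ", "))
    globalMean <- rowMeans(m, na.rm = TRUE)
    for (t in unique(type)) {
        cols <- which(type == t)
        sub <- m[, cols, drop = FALSE]
        nas <- which(is.na(sub), arr.ind = TRUE)
        if (!nrow(nas)) next
        typeMean <- rowMeans(sub, na.rm = TRUE)   # NaN if all-NA in type
        fill <- typeMean[nas[, 1]]
        nanIdx <- is.nan(fill)
        fill[nanIdx] <- globalMean[nas[nanIdx, 1]]
        sub[nas] <- fill
        m[, cols] <- sub
    }
    setExprMatrix(cohort, m, stage = "imputed")
}

#' Drop genes below an expression floor in every sample
#'
#' A gene is retained iff at least one sample reaches \code{threshold}.
#'
#' @param cohort an \linkS4class{IpmgCohort} (imputed).
#' @param threshold minimum expression (default 1).
#' @return cohort at stage \code{"filtered"}.
#' @export
filterLowExpression <- function(cohort, threshold = 1) {
    m <- exprMatrix(cohort)
    keep <- apply(m, 1L, function(x) any(x >= threshold, na.rm = TRUE))
    out <- cohort[keep, ]
    S4Vectors::metadata(out)$stage <- "filtered"
    out
}

#' Quantile normalization with mean-of-rank-range ties
#'
#' Internal reference implementation of the classic algorithm: each
#' sample's values are replaced by the cross-sample mean of the sorted
#' columns at the value's (average) rank, interpolating between the two
#' neighboring order statistics for fractional average ranks.
.quantileNormalize <- function(m) {
    if (ncol(m) == 1L) return(m)
    sortedMeans <- rowMeans(apply(m, 2L, sort))
    out <- m
    for (j in seq_len(ncol(m))) {
        r <- rank(m[, j], ties.method = "average")
        lo <- sortedMeans[floor(r)]
        hi <- sortedMeans[ceiling(r)]
        out[, j] <- (lo + hi) / 2
    }
    out
}

#' log2 transform and quantile-normalize
#'
#' Values become \code{log2(x + 1)} and are then quantile normalized
#' across samples (rank within sample mapped to the mean of the sorted
#' columns at that rank; ties receive the mean of their rank range).
#' A single-sample matrix is only log-transformed. Negative input is an
#' error.
#'
#' @param cohort an \linkS4class{IpmgCohort} (filtered).
#' @return cohort at stage \code{"normalized"}.
#' @export
log2QuantileNormalize <- function(cohort) {
    m <- exprMatrix(cohort)
    if (any(m < 0, na.rm = TRUE)) stop("expression values must be >= 0")
    lg <- log2(m + 1)
    norm <- .quantileNormalize(lg)
    setExprMatrix(cohort, norm, stage = "normalized")
}

#' Full expression preprocessing
#'
#' Imputation, low-expression filtering, log2 + quantile normalization.
#'
#' @param cohort raw \linkS4class{IpmgCohort}.
#' @param threshold low-expression floor.
#' @return cohort at stage \code{"normalized"}.
#' @export
preprocessExpression <- function(cohort, threshold = 1) {
    log2QuantileNormalize(filterLowExpression(imputeByCancerType(cohort),
                                              threshold = threshold))
}
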