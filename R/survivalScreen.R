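## Genome-wide survival screen: 3-year administrative censoring,
## per-cancer-type top/bottom 30% expression grouping pooled across
## types, and one-tailed log-rank tests in both directions.

#' Survival-screen settings
#'
#' @param capYears administrative censoring horizon in years (default 3).
#' @param quantile per-type high/low group fraction (default 0.30; must
#'   lie in (0, 0.5]).
#' @param cohortFilter treatment class to screen
#'   (\code{"immunotherapy"}, \code{"non_immunotherapy"} or \code{"all"}).
#' @param minTypeSize cancer types with fewer filtered samples are
#'   skipped per gene (default 4).
#' @return list of class \code{SurvivalSpec}.
#' @export
survivalSpec <- function(capYears = 3, quantile = 0.30,
                         cohortFilter = "immunotherapy", minTypeSize = 4L) {
    if (quantile <= 0 || quantile > 0.5)
        stop("quantile must lie in (0, 0.5]")
    stopifnot(cohortFilter %in% c("immunotherapy", "non_immunotherapy", "all"))
    structure(list(capYears = capYears, quantile = quantile,
                   cohortFilter = cohortFilter,
                   minTypeSize = as.integer(minTypeSize)),
              class = "SurvivalSpec")
}

#' Administratively censor survival beyond a cap
#'
#' Times beyond \code{capYears} are set to the cap with the event flag
#' cleared; shorter follow-up is untouched.
#'
#' @param clinical clinical data.frame.
#' @param capYears horizon in years (365 days/year).
#' @return clinical data.frame with capped \code{time_days}/\code{event}.
#' @export
capSurvival <- function(clinical, capYears) {
    capDays <- capYears * .DAYS_PER_YEAR
    over <- clinical$time_days > capDays
    clinical$event[over] <- 0L
    clinical$time_days[over] <- capDays
    clinical
}

#' High/low expression groups stratified by cancer type
#'
#' Per cancer type with at least \code{minTypeSize} samples, the top
#' \code{floor(q * n)} samples (minimum 1) by the gene's expression form
#' the high group and the bottom \code{floor(q * n)} the low group; the
#' per-type groups are pooled. Expression ties are broken by sample id,
#' and the low group is taken from the tail of the same descending
#' ordering, so high and low never overlap.
#'
#' @param exprRow named numeric vector (expression over the cohort).
#' @param clinical clinical data.frame for the same samples.
#' @param quantile group fraction.
#' @param minTypeSize minimum per-type sample count.
#' @return list with \code{high} and \code{low} sample-id vectors.
#' @export
stratifiedGroups <- function(exprRow, clinical, quantile = 0.30,
                             minTypeSize = 4L) {
    high <- character(0); low <- character(0)
    for (t in unique(clinical$cancer_type)) {
        ids <- clinical$sample_id[clinical$cancer_type == t]
        n <- length(ids)
        if (n < minTypeSize) {
            warning("cancer type ", t, " skipped (", n, " samples)")
            next
        }
        k <- max(1L, floor(quantile * n))
        x <- exprRow[ids]
        perm <- ids[order(-x, ids)]
        high <- c(high, perm[seq_len(k)])
        low <- c(low, perm[seq.int(n - k + 1L, n)])
    }
    list(high = high, low = low)
}

#' One-tailed log-rank test between two patient groups
#'
#' The standard log-rank chi-square is halved onto the hypothesized
#' direction: with z the signed statistic (positive when the high group
#' dies more than expected), the \code{"high_worse"} p is
#' \code{P(Z >= z)} and the \code{"high_better"} p is \code{P(Z <= z)}.
#' With no usable events the p-value is 1 with a warning.
#'
#' @param clinHigh,clinLow clinical data.frames of the two groups.
#' @param direction \code{"high_better"} or \code{"high_worse"}.
#' @return one-tailed p-value.
#' @export
oneTailedLogrank <- function(clinHigh, clinLow, direction = "high_better") {
    time <- c(clinHigh$time_days, clinLow$time_days)
    event <- c(clinHigh$event, clinLow$event)
    n <- length(time)
    isHigh <- c(rep(1, nrow(clinHigh)), rep(0, nrow(clinLow)))
    res <- .logrankVec(time, event,
                       incl = matrix(1, n, 1), high = matrix(isHigh, n, 1))
    if (is.na(res$z)) warning("no usable events; p = 1")
    .logrankOneTailed(res$z, direction)
}

## Per-type descending orderings of every gene's expression, restricted
## later to arbitrary sample subsets. ord[[type]] is a genes x n_type
## matrix of column indices into expr (ties broken by sample id).
.precomputeTypeOrders <- function(expr, clinical) {
    types <- unique(clinical$cancer_type)
    out <- list()
    for (t in types) {
        cols <- which(clinical$cancer_type == t)
        ids <- clinical$sample_id[cols]
        sub <- expr[, cols, drop = FALSE]
        ord <- t(apply(sub, 1L, function(x) order(-x, ids)))
        if (nrow(sub) == 1L) ord <- matrix(ord, nrow = 1L)
        out[[t]] <- matrix(cols[ord], nrow = nrow(expr))
    }
    out
}

#' Genome-wide survival screen
#'
#' Applies the survival cap, builds per-gene stratified high/low groups,
#' and computes both one-tailed log-rank p-values for every gene with a
#' vectorized log-rank core (one pass over all genes). Genes whose test
#' is degenerate (no events) receive p = 1.
#'
#' @param cohort an \linkS4class{IpmgCohort}.
#' @param spec a \code{\link{survivalSpec}}.
#' @param sampleSubset optional character vector restricting the cohort
#'   (applied after the treatment-class filter); used by the resampling
#'   nulls.
#' @param typeOrders optional precomputed ordering structure (internal
#'   reuse across resamples; must match \code{exprMatrix(cohort)} and the
#'   unfiltered clinical table).
#' @return list with \code{high_better} and \code{high_worse}
#'   \linkS4class{RankedGeneList}s.
#' @export
screenGenome <- function(cohort, spec = survivalSpec(),
                         sampleSubset = NULL, typeOrders = NULL) {
    .countHit("screen_calls")
    expr <- exprMatrix(cohort)
    clin <- clinicalTable(cohort)
    keep <- rep(TRUE, nrow(clin))
    if (spec$cohortFilter != "all")
        keep <- clin$treatment_class == spec$cohortFilter
    if (!is.null(sampleSubset))
        keep <- keep & clin$sample_id %in% sampleSubset
    if (is.null(typeOrders))
        typeOrders <- .precomputeTypeOrders(expr, clin)
    G <- nrow(expr)
    n <- nrow(clin)
    H <- matrix(FALSE, n, G)
    L <- matrix(FALSE, n, G)
    for (t in names(typeOrders)) {
        ord <- typeOrders[[t]]                       # G x n_type col indices
        inSub <- matrix(keep[ord], nrow = G)
        nc <- ncol(inSub)
        cnt <- inSub %*% (upper.tri(matrix(0, nc, nc), diag = TRUE) + 0)
        nt <- cnt[, ncol(cnt)]
        if (!any(nt >= 1L)) next
        k <- pmax(1L, floor(spec$quantile * nt))
        okGene <- nt >= spec$minTypeSize
        selHigh <- inSub & cnt <= k & okGene
        selLow <- inSub & (nt - cnt) < k & okGene     # last k included
        hi <- which(selHigh)
        lo <- which(selLow)
        H[cbind(ord[hi], ((hi - 1L) %% G) + 1L)] <- TRUE
        L[cbind(ord[lo], ((lo - 1L) %% G) + 1L)] <- TRUE
    }
    capped <- capSurvival(clin, spec$capYears)
    incl <- H | L
    res <- .logrankVec(capped$time_days, capped$event, incl, H)
    pWorse <- .logrankOneTailed(res$z, "high_worse")
    pBetter <- .logrankOneTailed(res$z, "high_better")
    names(pWorse) <- names(pBetter) <- rownames(expr)
    list(high_better = RankedGeneList(pBetter, "high_better"),
         high_worse = RankedGeneList(pWorse, "high_worse"))
}

#' Null screens over non-immunotherapy resamples
#'
#' Draws \code{B} subsamples of non-immunotherapy patients of the size of
#' the immunotherapy arm (without replacement, unconstrained by cancer
#' type), runs the genome screen on each, and returns the per-gene
#' one-tailed p-values as a genes x B matrix for the requested direction.
#' One screen per resample, shared by every downstream pathway.
#'
#' @param cohort an \linkS4class{IpmgCohort}.
#' @param spec a \code{\link{survivalSpec}} (its \code{cohortFilter} is
#'   ignored; resamples always come from the non-immunotherapy arm).
#' @param B number of resamples.
#' @param seed RNG seed.
#' @param direction which one-tailed ranking to collect.
#' @return genes x B matrix of p-values.
#' @export
resampleScreens <- function(cohort, spec = survivalSpec(), B = 1000L,
                            seed = 1L, direction = "high_better") {
    clin <- clinicalTable(cohort)
    nonIds <- clin$sample_id[clin$treatment_class == "non_immunotherapy"]
    nImm <- sum(clin$treatment_class == "immunotherapy")
    if (length(nonIds) < nImm)
        stop("non-immunotherapy cohort smaller than immunotherapy cohort")
    expr <- exprMatrix(cohort)
    typeOrders <- .precomputeTypeOrders(expr, clin)
    subSpec <- spec
    subSpec$cohortFilter <- "non_immunotherapy"
    out <- matrix(NA_real_, nrow(expr), B,
                  dimnames = list(rownames(expr), NULL))
    set.seed(seed)
    for (b in seq_len(B)) {
        sub <- sample(nonIds, nImm)
        scr <- screenGenome(cohort, subSpec, sampleSubset = sub,
                            typeOrders = typeOrders)
        tb <- rankedTable(scr[[direction]])
        out[tb$gene, b] <- tb$p
    }
    out
}
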