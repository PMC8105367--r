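## ssGSEA-based patient stratification on the IPMG panel, the
## resampling-controlled survival contrast and the between-group
## differential expression + GSEA characterization.

#' Group patients by panel ssGSEA score
#'
#' All patients are scored by \code{\link{ssgseaScore}} on the gene
#' panel; the group boundaries are placed at the scores that split the
#' immunotherapy-treated patients into \code{k} blocks of equal size
#' (within one: remainders go to the higher-score groups). Every
#' patient is then assigned by score; ties resolve deterministically by
#' sample id. Group 1 holds the lowest scores.
#'
#' @param cohort an \linkS4class{IpmgCohort}.
#' @param panel character vector of panel genes (>= 2 in the cohort).
#' @param k number of groups (default 3).
#' @param alpha ssGSEA exponent.
#' @return list: \code{groups} (named integer vector over all samples),
#'   \code{scores}, \code{boundaries}, \code{immunoPerGroup}.
#' @export
groupByPanelScore <- function(cohort, panel, k = 3L, alpha = 0.25) {
    if (length(intersect(panel, rownames(exprMatrix(cohort)))) < 2L)
        stop("panel must intersect >= 2 cohort genes")
    clin <- clinicalTable(cohort)
    immuno <- clin$sample_id[clin$treatment_class == "immunotherapy"]
    if (length(immuno) < k) stop("fewer immunotherapy patients than groups")
    scores <- ssgseaScore(cohort, panel, alpha = alpha)
    ids <- names(scores)
    ## order everyone by (score, id); group = position of the immuno
    ## boundary patients in that ordering
    ordAll <- order(scores, ids)
    rankAll <- stats::setNames(seq_along(ordAll), ids[ordAll])
    immRank <- sort(rankAll[immuno])
    sizes <- diff(floor(seq(0, length(immuno), length.out = k + 1)))
    cutPos <- immRank[cumsum(sizes)]   # global rank of each block's last member
    grp <- rep(k, length(ids))
    names(grp) <- ids
    r <- rankAll[ids]
    for (g in rev(seq_len(k)))
        grp[r <= cutPos[g]] <- g
    grp <- stats::setNames(as.integer(grp), ids)
    bounds <- scores[names(rankAll)[cutPos]]
    list(groups = grp, scores = scores,
         boundaries = unname(bounds[seq_len(k - 1)]),
         immunoPerGroup = as.integer(table(grp[immuno])))
}

## k-group log-rank p via survival::survdiff
.kGroupLogrankP <- function(time, event, group) {
    if (length(unique(group)) < 2L) return(NA_real_)
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    df <- length(unique(group)) - 1L
    stats::pchisq(sd$chisq, df = df, lower.tail = FALSE)
}

#' Group-wise survival contrast with a resampling control
#'
#' Computes the k-group log-rank p-value among immunotherapy patients
#' (capped at \code{capYears}); then, for each of \code{nResample}
#' draws, samples per group the same number of non-immunotherapy
#' patients (without replacement, unconstrained by cancer type) and
#' computes the control k-group log-rank p. Reports the immunotherapy p,
#' the median control p and the fraction of resamples whose control p is
#' smaller than the immunotherapy p.
#'
#' @param groups output of \code{\link{groupByPanelScore}} (or a named
#'   integer vector of group labels).
#' @param clinical clinical data.frame.
#' @param capYears survival cap (default 3).
#' @param nResample control draws (default 5000).
#' @param seed RNG seed.
#' @return list: \code{immunoP}, \code{controlMedianP},
#'   \code{fracControlSmaller}, \code{controlP} (vector).
#' @export
groupSurvivalContrast <- function(groups, clinical, capYears = 3,
                                  nResample = 5000L, seed = 1L) {
    grp <- if (is.list(groups)) groups$groups else groups
    clin <- capSurvival(clinical, capYears)
    gi <- grp[clin$sample_id]
    imm <- clin$treatment_class == "immunotherapy"
    non <- which(!imm)
    immunoP <- .kGroupLogrankP(clin$time_days[imm], clin$event[imm], gi[imm])
    ks <- sort(unique(gi[imm]))
    perGroupN <- vapply(ks, function(g) sum(gi[imm] == g), 1L)
    nonByGroup <- lapply(ks, function(g) non[gi[non] == g])
    if (any(lengths(nonByGroup) < perGroupN))
        stop("insufficient non-immunotherapy patients in some group")
    set.seed(seed)
    controlP <- vapply(seq_len(nResample), function(b) {
        idx <- unlist(lapply(seq_along(ks), function(j)
            sample(nonByGroup[[j]], perGroupN[j])))
        .kGroupLogrankP(clin$time_days[idx], clin$event[idx], gi[idx])
    }, 0)
    list(immunoP = immunoP,
         controlMedianP = stats::median(controlP, na.rm = TRUE),
         fracControlSmaller = mean(controlP < immunoP, na.rm = TRUE),
         controlP = controlP)
}

#' Identify the best- and worst-surviving groups (immunotherapy arm)
#'
#' Best = highest Kaplan-Meier survival at the cap among immunotherapy
#' patients; worst = lowest.
#'
#' @param groups group labels (list or named vector).
#' @param clinical clinical data.frame.
#' @param capYears evaluation horizon.
#' @return list with \code{best} and \code{worst} group labels.
#' @export
extremeGroups <- function(groups, clinical, capYears = 3) {
    grp <- if (is.list(groups)) groups$groups else groups
    clin <- capSurvival(clinical, capYears)
    imm <- clin[clin$treatment_class == "immunotherapy", ]
    gi <- grp[imm$sample_id]
    surv <- vapply(sort(unique(gi)), function(g) {
        sub <- imm[gi == g, ]
        fit <- survival::survfit(survival::Surv(time_days, event) ~ 1,
                                 data = sub)
        s <- summary(fit, times = capYears * .DAYS_PER_YEAR, extend = TRUE)
        s$surv[1]
    }, 0)
    labs <- sort(unique(gi))
    list(best = labs[which.max(surv)], worst = labs[which.min(surv)])
}

#' Between-group differential expression and GSEA
#'
#' One-tailed Mann-Whitney U test per gene (alternative: greater in the
#' best-surviving group) between the two extreme groups; genes are
#' ranked by ascending p and fed to pre-ranked GSEA. Zero-variance genes
#' receive p = 1.
#'
#' @param cohort an \linkS4class{IpmgCohort}.
#' @param groups group labels (list or named vector).
#' @param db a \linkS4class{PathwayCollection}.
#' @param best,worst extreme group labels (default from
#'   \code{\link{extremeGroups}}).
#' @param nPerm gene permutations for GSEA.
#' @param seed RNG seed.
#' @return list: \code{de} (per-gene p, ordered), \code{ranking}
#'   (\linkS4class{RankedGeneList}), \code{gsea} (data.frame).
#' @export
groupDeGsea <- function(cohort, groups, db, best = NULL, worst = NULL,
                        nPerm = 1000L, seed = 1L) {
    grp <- if (is.list(groups)) groups$groups else groups
    clin <- clinicalTable(cohort)
    if (is.null(best) || is.null(worst)) {
        eg <- extremeGroups(groups, clin)
        best <- eg$best; worst <- eg$worst
    }
    gi <- grp[clin$sample_id]
    bIds <- clin$sample_id[gi == best]
    wIds <- clin$sample_id[gi == worst]
    m <- exprMatrix(cohort)
    p <- apply(m, 1L, function(x) {
        xb <- x[bIds]; xw <- x[wIds]
        if (stats::sd(c(xb, xw)) == 0) return(1)
        stats::wilcox.test(xb, xw, alternative = "greater",
                           exact = NULL)$p.value
    })
    ranking <- RankedGeneList(p, "high_better")
    gsea <- prerankedGsea(ranking, db, nPerm = nPerm, seed = seed)
    list(de = rankedTable(ranking), ranking = ranking, gsea = gsea,
         best = best, worst = worst)
}
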