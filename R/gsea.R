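## Pre-ranked gene set enrichment: weighted Kolmogorov-Smirnov running
## sum, gene-permutation p-values, the resampling-based immunotherapy
## specificity test and the three-series quantile-quantile construction.

#' Enrichment score of one gene set on a ranked statistic
#'
#' The classic weighted running sum: walking down the ranking, hits
#' increment by \code{|stat|^weight} (normalized over the set) and misses
#' decrement uniformly; the enrichment score is the maximum deviation
#' from zero (sign preserved). Computed from the hit positions only, so
#' cost is O(set size) after ranking.
#'
#' @param stat named statistic vector, sorted in ranking order
#'   (descending significance).
#' @param set character vector of member genes.
#' @param weight hit-weight exponent (default 1).
#' @return enrichment score in [-1, 1].
#' @export
enrichmentScore <- function(stat, set, weight = 1) {
    pos <- which(names(stat) %in% set)
    .esFromPositions(stat, pos, weight)
}

.esFromPositions <- function(stat, pos, weight = 1) {
    N <- length(stat)
    m <- length(pos)
    if (m == 0L || m == N) stop("set must hit a proper subset of the ranking")
    pos <- sort(pos)
    w <- abs(stat[pos])^weight
    tot <- sum(w)
    cumHit <- if (tot > 0) cumsum(w) / tot else seq_len(m) / m
    missStep <- 1 / (N - m)
    atHit <- cumHit - (pos - seq_len(m)) * missStep            # after hit i
    beforeHit <- c(0, cumHit[-m]) - (pos - 1 - (seq_len(m) - 1)) * missStep
    maxDev <- max(atHit)
    minDev <- min(beforeHit)
    ## magnitude ties (within numerical precision) resolve positive
    if (maxDev + 1e-12 >= -minDev) unname(maxDev) else unname(minDev)
}

#' Pre-ranked GSEA with gene-permutation p-values
#'
#' For each pathway intersected with the ranking universe (at least
#' \code{minSize} genes), computes the enrichment score and a
#' Monte-Carlo p-value against random same-size gene sets using the
#' +1/+1 estimator, \code{p = (1 + #\{null ES >= ES\}) / (1 + nPerm)}.
#' Null scores are drawn once per distinct set size and shared across
#' pathways of that size.
#'
#' @param ranking a \linkS4class{RankedGeneList}.
#' @param db a \linkS4class{PathwayCollection}.
#' @param nPerm number of gene permutations (default 1000).
#' @param weight hit-weight exponent.
#' @param minSize minimum post-intersection set size (default 3).
#' @param seed RNG seed.
#' @return data.frame with \code{pathway}, \code{size}, \code{es},
#'   \code{p}.
#' @export
prerankedGsea <- function(ranking, db, nPerm = 1000L, weight = 1,
                          minSize = 3L, seed = 1L) {
    stat <- rankingStat(ranking)
    N <- length(stat)
    sets <- pathwaySets(db)
    posList <- lapply(sets, function(s) which(names(stat) %in% s))
    sizes <- lengths(posList)
    keep <- sizes >= minSize & sizes < N
    if (any(!keep))
        warning(sum(!keep), " pathways skipped (too small after intersection)")
    posList <- posList[keep]
    sizes <- sizes[keep]
    if (!length(posList))
        return(data.frame(pathway = character(0), size = integer(0),
                          es = numeric(0), p = numeric(0)))
    obs <- vapply(posList, function(p) .esFromPositions(stat, p, weight), 0)
    set.seed(seed)
    nullBySize <- lapply(unique(sizes), function(m) {
        vapply(seq_len(nPerm), function(i)
            .esFromPositions(stat, sample.int(N, m), weight), 0)
    })
    names(nullBySize) <- as.character(unique(sizes))
    p <- vapply(seq_along(obs), function(i) {
        nl <- nullBySize[[as.character(sizes[i])]]
        .mcPvalue(sum(nl >= obs[i]), nPerm)
    }, 0)
    data.frame(pathway = names(posList), size = as.integer(sizes),
               es = unname(obs), p = p, row.names = NULL)
}

#' Immunotherapy-specificity test for pathways
#'
#' The observed pathway p-value comes from pre-ranked GSEA on the
#' immunotherapy-arm survival ranking. The null draws \code{B} random
#' non-immunotherapy subsamples of the immunotherapy arm's size, reruns
#' the genome screen once per resample, and collects each pathway's GSEA
#' p-value on every null ranking. A pathway is flagged immunotherapy
#' specific when its observed p sits below the 5th percentile of its own
#' null p distribution (the 95th-percentile rank rule).
#'
#' @param cohort an \linkS4class{IpmgCohort}.
#' @param db a \linkS4class{PathwayCollection}.
#' @param spec a \code{\link{survivalSpec}}.
#' @param B number of resamples (>= 20; default 1000).
#' @param nPerm gene permutations inside each GSEA.
#' @param direction which one-tailed ranking feeds GSEA.
#' @param seed RNG seed.
#' @param nullGeneP optional precomputed genes x B null p matrix from
#'   \code{\link{resampleScreens}} (reused by the QQ construction).
#' @return list: \code{table} (per-pathway observed p, null percentile,
#'   specific flag), \code{nullP} (pathways x B null GSEA p matrix),
#'   \code{observed} (observed GSEA table), \code{nullGeneP}.
#' @export
specificityTest <- function(cohort, db, spec = survivalSpec(), B = 1000L,
                            nPerm = 1000L, direction = "high_better",
                            seed = 1L) {
    if (B < 20L) stop("B must be >= 20 for a meaningful percentile")
    seeds <- .childSeeds(seed, 3L)
    obsScreen <- screenGenome(cohort, spec)
    obsGsea <- prerankedGsea(obsScreen[[direction]], db, nPerm = nPerm,
                             seed = seeds[1])
    nullGeneP <- resampleScreens(cohort, spec, B = B, seed = seeds[2],
                                 direction = direction)
    paths <- obsGsea$pathway
    nullP <- matrix(NA_real_, length(paths), B,
                    dimnames = list(paths, NULL))
    gseaSeeds <- .childSeeds(seeds[3], B)
    for (b in seq_len(B)) {
        rk <- RankedGeneList(nullGeneP[, b], direction)
        g <- suppressWarnings(
            prerankedGsea(rk, db, nPerm = nPerm, seed = gseaSeeds[b]))
        nullP[g$pathway, b] <- g$p
    }
    perc <- vapply(seq_along(paths), function(i) {
        nl <- nullP[i, ]
        (sum(nl < obsGsea$p[i]) + 0.5 * sum(nl == obsGsea$p[i])) / B
    }, 0)
    tab <- data.frame(pathway = paths, size = obsGsea$size,
                      es = obsGsea$es, p_obs = obsGsea$p,
                      null_percentile = perc,
                      specific = perc <= 0.05)
    list(table = tab, nullP = nullP, observed = obsGsea,
         nullGeneP = nullGeneP)
}

#' Three-series QQ construction for one pathway
#'
#' Series 1: the sorted survival-screen p-values of the pathway's genes
#' on the immunotherapy ranking. Series 2: at each order-statistic
#' position, the 95th quantile of significance (-log10 p; the 5th
#' percentile on the p scale) over \code{nDraws} random same-size gene
#' draws from the immunotherapy p list. Series 3: the same envelope over
#' the pathway genes' sorted p-values across the non-immunotherapy
#' resample screens. A pathway passes when series 1 sits below each
#' 95%-significance envelope over most positions -- a deliberately
#' strict criterion.
#'
#' @param rankingImmuno immunotherapy-arm \linkS4class{RankedGeneList}.
#' @param nullGeneP genes x B null p matrix from
#'   \code{\link{resampleScreens}}.
#' @param pathway character vector of member genes.
#' @param nDraws random draws for series 2 (default 1000; must be > 1).
#' @param seed RNG seed.
#' @return list: \code{series} (data.frame position x three series),
#'   \code{fracBelowRandom}, \code{fracBelowControl}, \code{pass}.
#' @export
buildQQ <- function(rankingImmuno, nullGeneP, pathway, nDraws = 1000L,
                    seed = 1L) {
    if (nDraws <= 1L) stop("nDraws must be > 1 (quantile of one draw)")
    tb <- rankedTable(rankingImmuno)
    pAll <- stats::setNames(tb$p, tb$gene)
    genes <- intersect(pathway, names(pAll))
    m <- length(genes)
    if (m < 3L) stop("pathway smaller than 3 after intersection; skipped")
    s1 <- sort(unname(pAll[genes]))
    set.seed(seed)
    draws <- matrix(NA_real_, nDraws, m)
    for (i in seq_len(nDraws))
        draws[i, ] <- sort(sample(unname(pAll), m))
    s2 <- apply(draws, 2L, stats::quantile, probs = 0.05, names = FALSE)
    nullSub <- nullGeneP[genes, , drop = FALSE]
    nullSorted <- apply(nullSub, 2L, sort)
    s3 <- apply(nullSorted, 1L, stats::quantile, probs = 0.05,
                names = FALSE)
    f2 <- mean(s1 < s2)
    f3 <- mean(s1 < s3)
    list(series = data.frame(position = seq_len(m), pathway_p = s1,
                             random_q95 = s2, control_q95 = s3),
         fracBelowRandom = f2, fracBelowControl = f3,
         pass = f2 > 0.5 && f3 > 0.5)
}
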