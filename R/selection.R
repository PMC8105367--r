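## Feature selection and the survival-status classifier: single-sample
## GSEA scoring, random survival forest importance with permutation
## p-values, pathway intersection and gene picking, SMOTE balancing and
## the SMOTE-balanced elastic net evaluated on balanced validation draws.

#' Single-sample GSEA score
#'
#' Barbie-style per-sample enrichment: genes are ranked by expression
#' (descending, ties broken by gene id); the score is the sum over all
#' rank positions of the difference between the rank-weighted in-set
#' empirical CDF (weights \code{rank^alpha}) and the uniform out-of-set
#' CDF. Depends only on each sample's gene ordering, so it is invariant
#' to monotone transforms.
#'
#' @param cohort an \linkS4class{IpmgCohort} (or a plain genes x samples
#'   matrix).
#' @param geneSet character vector; must hit >= 1 gene and leave a
#'   non-empty complement.
#' @param alpha rank-weight exponent (default 0.25).
#' @return named numeric vector of per-sample scores.
#' @export
ssgseaScore <- function(cohort, geneSet, alpha = 0.25) {
    m <- if (is(cohort, "IpmgCohort")) exprMatrix(cohort) else cohort
    inSet <- rownames(m) %in% geneSet
    if (!any(inSet)) stop("gene set does not intersect the expression genes")
    if (all(inSet)) stop("gene set covers all genes (empty complement)")
    N <- nrow(m)
    ids <- rownames(m)
    apply(m, 2L, function(x) {
        ord <- order(-x, ids)
        hit <- inSet[ord]
        w <- (N - seq_len(N) + 1)^alpha    # rank weight, top gets N^alpha
        wIn <- cumsum(ifelse(hit, w, 0)) / sum(w[hit])
        pOut <- cumsum(!hit) / (N - sum(hit))
        sum(wIn - pOut)
    })
}

#' Random survival forest feature importance with permutation p-values
#'
#' Fits a random survival forest (log-rank splitting, permutation
#' importance) on the features against survival capped at
#' \code{capYears}, then derives a per-feature p-value by refitting on
#' \code{nNull} response-permuted datasets (Altmann scheme):
#' \code{p = (1 + #\{null importance >= observed\}) / (1 + nNull)}.
#'
#' @param features patients x features numeric matrix or data.frame.
#' @param clinical clinical data.frame for the same patients (rows
#'   matched by \code{sample_id} to \code{rownames(features)}).
#' @param capYears survival cap (default 1).
#' @param nNull response permutations (default 100).
#' @param nTrees forest size (default 1000).
#' @param alpha selection threshold on the p-value (default 0.05).
#' @param seed RNG seed.
#' @return data.frame with \code{feature}, \code{importance}, \code{p},
#'   \code{selected}, ordered by decreasing importance.
#' @export
rsfRank <- function(features, clinical, capYears = 1, nNull = 100L,
                    nTrees = 1000L, alpha = 0.05, seed = 1L) {
    features <- as.data.frame(features)
    if (ncol(features) < 2L) stop("need >= 2 features")
    idx <- match(rownames(features), clinical$sample_id)
    if (anyNA(idx)) stop("features rows must match clinical sample ids")
    clin <- capSurvival(clinical[idx, ], capYears)
    if (nrow(features) < 20L) stop("need >= 20 patients")
    if (sum(clin$event) < 3L) stop("need >= 3 events after the cap")
    d <- data.frame(time = pmax(clin$time_days, 0.5), status = clin$event,
                    features, check.names = FALSE)
    seeds <- .childSeeds(seed, nNull + 1L)
    ## with few events a tree ensemble can return undefined (NA)
    ## permutation importances for some RNG streams; retry
    ## deterministically on a shifted seed
    fitOnce <- function(dd, s) {
        for (k in 0:4) {
            f <- ranger::ranger(survival::Surv(time, status) ~ .,
                                data = dd, num.trees = nTrees,
                                importance = "permutation",
                                splitrule = "logrank",
                                seed = (s + k * 1000003L) %% .Machine$integer.max,
                                num.threads = 1L)
            if (!anyNA(f$variable.importance)) return(f)
        }
        f
    }
    fit <- fitOnce(d, seeds[1])
    obs <- fit$variable.importance
    nullImp <- matrix(NA_real_, nNull, length(obs),
                      dimnames = list(NULL, names(obs)))
    set.seed(seed + 1L)
    for (b in seq_len(nNull)) {
        perm <- sample.int(nrow(d))
        db <- d
        db$time <- d$time[perm]; db$status <- d$status[perm]
        fb <- fitOnce(db, seeds[b + 1L])
        nullImp[b, ] <- fb$variable.importance[names(obs)]
    }
    p <- vapply(seq_along(obs), function(i)
        .mcPvalue(sum(nullImp[, i] >= obs[i], na.rm = TRUE), nNull), 0)
    p[is.na(obs)] <- 1          # degenerate feature: never selected
    out <- data.frame(feature = names(obs), importance = unname(obs),
                      p = p, selected = p < alpha)
    out <- out[order(-out$importance, out$feature), ]
    rownames(out) <- NULL
    out
}

#' Intersect pathway selections and pick candidate IPMGs
#'
#' Pathways selected under both the mutation-corrected and the
#' fraction-corrected analyses are intersected; candidate genes are the
#' members of those pathways whose immunotherapy survival-screen
#' one-tailed p-value is below \code{geneP} under either correction.
#' Candidates are returned ordered by gene-level RSF importance when a
#' gene ranking is supplied, otherwise by their best screen p.
#'
#' @param selMut,selFrac RSF rankings (data.frames from
#'   \code{\link{rsfRank}}) for the two corrections.
#' @param rankingsMut,rankingsFrac \linkS4class{RankedGeneList}s from the
#'   immunotherapy screens on the two corrected tables.
#' @param db a \linkS4class{PathwayCollection}.
#' @param geneP per-gene significance threshold (default 0.05).
#' @param geneRsf optional gene-level RSF ranking used for the final
#'   ordering.
#' @return list: \code{pathways} (intersection), \code{candidates}
#'   (ordered character vector), \code{table} (per-candidate detail).
#' @export
intersectAndPickGenes <- function(selMut, selFrac, rankingsMut,
                                  rankingsFrac, db, geneP = 0.05,
                                  geneRsf = NULL) {
    pathways <- intersect(selMut$feature[which(selMut$selected)],
                          selFrac$feature[which(selFrac$selected)])
    if (!length(pathways)) {
        warning("no pathway selected under both corrections")
        return(list(pathways = character(0), candidates = character(0),
                    table = data.frame()))
    }
    members <- unique(unlist(pathwaySets(db)[pathways]))
    pm <- stats::setNames(rankedTable(rankingsMut)$p,
                          rankedTable(rankingsMut)$gene)
    pf <- stats::setNames(rankedTable(rankingsFrac)$p,
                          rankedTable(rankingsFrac)$gene)
    tab <- data.frame(gene = members,
                      p_mut = unname(pm[members]),
                      p_frac = unname(pf[members]))
    tab$pass <- (!is.na(tab$p_mut) & tab$p_mut < geneP) |
        (!is.na(tab$p_frac) & tab$p_frac < geneP)
    cand <- tab$gene[tab$pass]
    if (!is.null(geneRsf)) {
        imp <- stats::setNames(geneRsf$importance, geneRsf$feature)
        cand <- cand[order(-imp[cand], cand)]
    } else {
        best <- pmin(tab$p_mut[tab$pass], tab$p_frac[tab$pass], na.rm = TRUE)
        cand <- cand[order(best, cand)]
    }
    list(pathways = pathways, candidates = cand, table = tab)
}

#' SMOTE minority oversampling
#'
#' Synthesizes minority-class points as convex combinations
#' \code{x + u (x_nn - x)} (u uniform on [0, 1]) of a minority point and
#' one of its \code{k} minority-class nearest neighbors (Euclidean),
#' until the classes are balanced. Already-balanced input is returned
#' unchanged; a minority class of one is an error.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y binary labels (0/1 or logical).
#' @param k neighbors (default 5; capped at minority size - 1).
#' @param seed RNG seed.
#' @return list with balanced \code{x} and \code{y} (original rows
#'   first).
#' @export
smoteOversample <- function(x, y, k = 5L, seed = 1L) {
    x <- as.matrix(x)
    y <- as.integer(y)
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    if (n1 == n0) return(list(x = x, y = y))
    minLab <- if (n1 < n0) 1L else 0L
    minIdx <- which(y == minLab)
    if (length(minIdx) < 2L) stop("minority class of 1: no neighbor for SMOTE")
    nNew <- abs(n0 - n1)
    xm <- x[minIdx, , drop = FALSE]
    D <- as.matrix(stats::dist(xm))
    diag(D) <- Inf
    k <- min(k, length(minIdx) - 1L)
    nn <- t(apply(D, 1L, function(d) order(d)[seq_len(k)]))
    if (k == 1L) nn <- matrix(nn, ncol = 1L)
    set.seed(seed)
    base <- sample(seq_along(minIdx), nNew, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k, nNew, replace = TRUE))]
    u <- stats::runif(nNew)
    synth <- xm[base, , drop = FALSE] +
        u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
    rownames(synth) <- paste0("smote_", seq_len(nNew))
    list(x = rbind(x, synth), y = c(y, rep(minLab, nNew)))
}

#' One-year survival-status labels
#'
#' Deceased = event within \code{horizonYears}; alive = followed at
#' least that long without an event; patients censored earlier are
#' excluded (label NA).
#'
#' @param clinical clinical data.frame.
#' @param horizonYears label horizon (default 1).
#' @return integer vector (1 deceased, 0 alive, NA excluded) named by
#'   sample id.
#' @export
survivalStatusLabels <- function(clinical, horizonYears = 1) {
    h <- horizonYears * .DAYS_PER_YEAR
    lab <- ifelse(clinical$event == 1L & clinical$time_days <= h, 1L,
           ifelse(clinical$time_days >= h, 0L, NA_integer_))
    stats::setNames(as.integer(lab), clinical$sample_id)
}

#' Train and evaluate the SMOTE-balanced elastic-net classifier
#'
#' For each panel size: the labeled patients are split 2/3 training :
#' 1/3 validation stratified by label, the training set is SMOTE
#' balanced, an elastic-net logistic regression (mixing 0.5, penalty by
#' internal cross-validation maximizing AUC) is fitted on the top genes
#' of the panel, and performance is averaged over \code{nVal} balanced
#' validation subsets (all deceased patients plus an equal-size random
#' draw of alive patients).
#'
#' @param cohort an \linkS4class{IpmgCohort} (features are taken from its
#'   expression matrix).
#' @param genePanel ordered candidate gene vector (most important first).
#' @param panelSizes feature counts to sweep (default
#'   \code{c(64, 50, 40, 30, 20, 10)}; sizes beyond the panel are
#'   truncated).
#' @param horizonYears label horizon (default 1).
#' @param nVal balanced validation draws (default 1000).
#' @param cohortFilter treatment class used for the labels (default
#'   immunotherapy).
#' @param seed RNG seed.
#' @return data.frame, one row per panel size: \code{size},
#'   \code{accuracy}, \code{sensitivity}, \code{specificity}, \code{auc}.
#' @export
trainEvalElasticNet <- function(cohort, genePanel,
                                panelSizes = c(64, 50, 40, 30, 20, 10),
                                horizonYears = 1, nVal = 1000L,
                                cohortFilter = "immunotherapy",
                                seed = 1L) {
    clin <- clinicalTable(cohort)
    if (cohortFilter != "all")
        clin <- clin[clin$treatment_class == cohortFilter, ]
    lab <- survivalStatusLabels(clin, horizonYears)
    lab <- lab[!is.na(lab)]
    genePanel <- intersect(genePanel, rownames(exprMatrix(cohort)))
    expr <- t(exprMatrix(cohort)[genePanel, names(lab), drop = FALSE])
    panelSizes <- unique(pmin(panelSizes, length(genePanel)))
    seeds <- .childSeeds(seed, length(panelSizes))
    out <- vector("list", length(panelSizes))
    for (si in seq_along(panelSizes)) {
        sz <- panelSizes[si]
        x <- expr[, seq_len(sz), drop = FALSE]
        met <- .fitEvalOnce(x, lab, nVal = nVal, seed = seeds[si])
        out[[si]] <- data.frame(size = sz, t(met))
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

.fitEvalOnce <- function(x, lab, nVal, seed) {
    set.seed(seed)
    dIdx <- which(lab == 1); aIdx <- which(lab == 0)
    if (length(dIdx) < 3L) stop("fewer than 3 deceased patients with labels")
    trD <- sample(dIdx, round(2 / 3 * length(dIdx)))
    trA <- sample(aIdx, round(2 / 3 * length(aIdx)))
    tr <- sort(c(trD, trA)); va <- setdiff(seq_along(lab), tr)
    if (sum(lab[va] == 1) < 2L) stop("fewer than 2 deceased in validation split")
    bal <- smoteOversample(x[tr, , drop = FALSE], lab[tr], seed = seed)
    ## repeated 5-fold CV: the penalty choice on ~100 training points is
    ## noisy, so predictions are averaged over independent fold splits
    prob <- rowMeans(vapply(1:3, function(r) {
        foldid <- sample(rep_len(1:5, length(bal$y)))
        cvfit <- glmnet::cv.glmnet(bal$x, bal$y, family = "binomial",
                                   alpha = 0.5, type.measure = "auc",
                                   foldid = foldid)
        as.vector(stats::predict(cvfit, newx = x[va, , drop = FALSE],
                                 s = "lambda.min", type = "response"))
    }, numeric(length(va))))
    yv <- lab[va]
    vd <- which(yv == 1); vaAlive <- which(yv == 0)
    nD <- length(vd)
    acc <- sen <- spe <- auc <- numeric(nVal)
    for (b in seq_len(nVal)) {
        drawA <- sample(vaAlive, min(nD, length(vaAlive)))
        idx <- c(vd, drawA)
        p <- prob[idx]; y <- yv[idx]
        pred <- as.integer(p >= 0.5)
        acc[b] <- mean(pred == y)
        sen[b] <- mean(pred[y == 1] == 1)
        spe[b] <- mean(pred[y == 0] == 0)
        auc[b] <- .aucScore(p, y)
    }
    c(accuracy = mean(acc), sensitivity = mean(sen),
      specificity = mean(spe), auc = mean(auc))
}
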