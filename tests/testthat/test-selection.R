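test_that("ssGSEA scores follow the rank-weighted ECDF difference", {
    ## 3-gene patient, set = top gene, alpha = 0: hand enumeration
    m <- matrix(c(9, 5, 1), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
    clin <- data.frame(sample_id = "s1", cancer_type = "T",
                       treatment_class = "immunotherapy",
                       time_days = 1, event = 0L)
    sc <- ssgseaScore(m, "a", alpha = 0)
    ## positions: hit at 1; wIn = 1,1,1; pOut = 0, 1/2, 1
    expect_equal(unname(sc), (1 - 0) + (1 - 0.5) + (1 - 1),
                 tolerance = 1e-12)

    ## identical rank order across patients -> identical scores;
    ## monotone-transform invariance
    set.seed(12)
    m2 <- matrix(rexp(40), 20, 2,
                 dimnames = list(sprintf("g%02d", 1:20), c("p1", "p2")))
    m2[, 2] <- rank(m2[, 1]) * 3 + 100        # same ordering as p1
    set <- c("g03", "g07", "g11")
    sc2 <- ssgseaScore(m2, set)
    expect_equal(sc2[["p1"]], sc2[["p2"]], tolerance = 1e-12)
    expect_equal(unname(ssgseaScore(m2, set)),
                 unname(ssgseaScore(exp(m2 / 10), set)), tolerance = 1e-12)

    ## top-ranked set scores strictly above the same-size bottom set
    ordG <- rownames(m2)[order(-m2[, 1])]
    expect_gt(ssgseaScore(m2[, 1, drop = FALSE], ordG[1:4])[[1]],
              ssgseaScore(m2[, 1, drop = FALSE], rev(ordG)[1:4])[[1]])

    expect_error(ssgseaScore(m2, rownames(m2)), "complement")
    expect_error(ssgseaScore(m2, "nope"), "intersect")
})

test_that("SMOTE keeps synthetic points on minority segments and balances", {
    ## 1-D minority {0, 1}: every synthetic point lies in [0, 1]
    x <- matrix(c(0, 1, 5, 6, 7, 8), ncol = 1)
    y <- c(1, 1, 0, 0, 0, 0)
    out <- smoteOversample(x, y, k = 1, seed = 3)
    expect_identical(sum(out$y == 1), sum(out$y == 0))
    synth <- out$x[-(1:6), , drop = FALSE]
    expect_true(all(synth >= 0 & synth <= 1))

    ## balanced input returned unchanged
    xb <- matrix(rnorm(8), 4, 2); yb <- c(0, 0, 1, 1)
    ob <- smoteOversample(xb, yb, seed = 1)
    expect_identical(ob$x, xb)

    ## determinism
    set.seed(99)
    x2 <- matrix(rnorm(40), 20, 2)
    y2 <- rep(c(0, 1), c(15, 5))
    a <- smoteOversample(x2, y2, seed = 7)
    b <- smoteOversample(x2, y2, seed = 7)
    expect_identical(a, b)

    ## synthetic points lie on segments between minority neighbors
    minIdx <- which(y2 == 1)
    sN <- a$x[-(1:20), , drop = FALSE]
    onSegment <- apply(sN, 1, function(p) {
        any(apply(utils::combn(minIdx, 2), 2, function(pr) {
            a1 <- x2[pr[1], ]; b1 <- x2[pr[2], ]
            d <- b1 - a1
            t <- if (sum(d^2) == 0) 0 else sum((p - a1) * d) / sum(d^2)
            t >= -1e-9 && t <= 1 + 1e-9 &&
                sqrt(sum((a1 + t * d - p)^2)) < 1e-8
        }))
    })
    expect_true(all(onSegment))

    expect_error(smoteOversample(x2, rep(c(0, 1), c(19, 1))), "minority")
})

test_that("1-year status labels exclude early-censored patients", {
    clin <- data.frame(sample_id = paste0("s", 1:4), cancer_type = "T",
                       treatment_class = "immunotherapy",
                       time_days = c(100, 100, 400, 365),
                       event = c(1L, 0L, 0L, 0L))
    lab <- survivalStatusLabels(clin, 1)
    expect_identical(unname(lab), c(1L, NA_integer_, 0L, 0L))
})

test_that("the elastic-net evaluator is calibrated on separable and null toys", {
    set.seed(31)
    n <- 120
    genes <- sprintf("g%02d", 1:12)
    samples <- sprintf("s%03d", 1:n)
    lab <- rep(c(0L, 1L), c(80, 40))
    m <- matrix(rnorm(12 * n), 12, n, dimnames = list(genes, samples))
    ## perfectly separable: g01 carries the label
    m[1, ] <- lab * 4 + seq(0, 0.1, length.out = n)
    clin <- data.frame(sample_id = samples, cancer_type = "T",
                       treatment_class = "immunotherapy",
                       time_days = ifelse(lab == 1, 200, 400),
                       event = lab)
    co <- IpmgCohort(m, clin, stage = "normalized")
    res <- trainEvalElasticNet(co, genes, panelSizes = 12, nVal = 50,
                               seed = 5)
    expect_equal(res$auc, 1, tolerance = 1e-9)
    expect_gt(res$accuracy, 0.95)

    ## labels independent of features -> AUC near 1/2
    aucs <- numeric(6)
    for (s in 1:6) {
        set.seed(600 + s)
        m0 <- matrix(rnorm(12 * n), 12, n,
                     dimnames = list(genes, samples))
        lab0 <- sample(lab)
        clin0 <- data.frame(sample_id = samples, cancer_type = "T",
                            treatment_class = "immunotherapy",
                            time_days = ifelse(lab0 == 1, 200, 400),
                            event = lab0)
        co0 <- IpmgCohort(m0, clin0, stage = "normalized")
        aucs[s] <- trainEvalElasticNet(co0, genes, panelSizes = 12,
                                       nVal = 50, seed = s)$auc
    }
    expect_gt(mean(aucs), 0.4)
    expect_lt(mean(aucs), 0.6)
})

test_that("pathway intersection and gene picking follow the either-correction rule", {
    selA <- data.frame(feature = c("P1", "P2", "P3"),
                       importance = c(3, 2, 1), p = c(0.01, 0.01, 0.5),
                       selected = c(TRUE, TRUE, FALSE))
    selB <- data.frame(feature = c("P1", "P3"), importance = c(2, 1),
                       p = c(0.02, 0.6), selected = c(TRUE, FALSE))
    db <- PathwayCollection(list(P1 = c("gA", "gB", "gC"),
                                 P2 = c("gD", "gE"),
                                 P3 = c("gF", "gG")))
    pm <- stats::setNames(c(0.04, 0.5, 0.9, 0.001, 0.2, 0.3, 0.4),
                          c("gA", "gB", "gC", "gD", "gE", "gF", "gG"))
    pf <- stats::setNames(c(0.8, 0.03, 0.9, 0.5, 0.2, 0.3, 0.4),
                          names(pm))
    rkM <- RankedGeneList(pm, "high_better")
    rkF <- RankedGeneList(pf, "high_better")
    out <- intersectAndPickGenes(selA, selB, rkM, rkF, db)
    ## P2 selected under one correction only -> excluded
    expect_identical(out$pathways, "P1")
    ## gA passes via mutation side, gB via fraction side, gC fails both
    expect_setequal(out$candidates, c("gA", "gB"))

    selB0 <- transform(selB, selected = FALSE)
    expect_warning(out0 <- intersectAndPickGenes(selA, selB0, rkM, rkF, db),
                   "no pathway")
    expect_length(out0$candidates, 0L)
})

test_that("RSF importance separates an informative feature from noise", {
    ## planted feature: direct linear driver of the hazard
    set.seed(77)
    n <- 100
    feats <- matrix(rnorm(n * 6), n, 6,
                    dimnames = list(sprintf("s%03d", 1:n),
                                    c("signal", paste0("noise", 1:5))))
    haz <- exp(-1.2 * feats[, "signal"])
    ti <- round(rexp(n, haz / 300))
    clin <- data.frame(sample_id = rownames(feats), cancer_type = "T",
                       treatment_class = "immunotherapy",
                       time_days = pmax(ti, 1), event = 1L)
    r <- rsfRank(feats, clin, capYears = 1, nNull = 30, nTrees = 300,
                 seed = 2)
    expect_identical(r$feature[1], "signal")
    expect_lt(r$p[r$feature == "signal"], 0.05)

    ## duplicated feature keeps a similar rank
    feats2 <- cbind(feats, signal2 = feats[, "signal"])
    r2 <- rsfRank(feats2, clin, capYears = 1, nNull = 30, nTrees = 300,
                  seed = 2)
    expect_lte(abs(which(r2$feature == "signal") -
                   which(r2$feature == "signal2")), 2L)

    expect_error(rsfRank(feats[, 1, drop = FALSE], clin), ">= 2 features")
    expect_error(rsfRank(feats, transform(clin, event = 0L)), "events")
})
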