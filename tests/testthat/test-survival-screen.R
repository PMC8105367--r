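test_that("survival capping censors administratively beyond the horizon", {
    clin <- data.frame(sample_id = sprintf("s%02d", 1:10),
                       cancer_type = "T1",
                       treatment_class = "immunotherapy",
                       time_days = c(4, 2, 3.5, 5, 1, 0.5, 2.5, 2.99,
                                     4.5, 2.2) * 365,
                       event = rep(1L, 10))
    out <- capSurvival(clin, 3)
    over <- clin$time_days > 3 * 365
    expect_identical(sum(over), 4L)                 # exactly the 4 beyond cap
    expect_true(all(out$time_days[over] == 3 * 365))
    expect_true(all(out$event[over] == 0L))
    expect_identical(out$time_days[!over], clin$time_days[!over])
    expect_identical(out$event[!over], clin$event[!over])
})

test_that("stratified groups take floor(q n) per type and pool", {
    clin <- data.frame(sample_id = sprintf("s%02d", 1:20),
                       cancer_type = rep(c("A", "B"), each = 10),
                       treatment_class = "immunotherapy",
                       time_days = 100, event = 0L)
    x <- stats::setNames(c(10:1, 20:11), clin$sample_id)
    g1 <- stratifiedGroups(x[1:10], clin[1:10, ], quantile = 0.3)
    expect_identical(length(g1$high), 3L)
    expect_identical(length(g1$low), 3L)
    expect_identical(g1$high, c("s01", "s02", "s03"))
    expect_identical(g1$low, c("s08", "s09", "s10"))

    g2 <- stratifiedGroups(x, clin, quantile = 0.3)
    expect_identical(length(g2$high), 6L)
    expect_identical(length(g2$low), 6L)
    expect_length(intersect(g2$high, g2$low), 0L)

    ## ties at the boundary resolve by sample id, deterministically
    xt <- stats::setNames(rep(c(5, 3, 1), c(4, 3, 3)), clin$sample_id[1:10])
    gt1 <- stratifiedGroups(xt, clin[1:10, ], quantile = 0.3)
    gt2 <- stratifiedGroups(xt[sample(10)], clin[sample(10), ][
        order(sample(10)), ], quantile = 0.3)
    expect_identical(gt1$high, c("s01", "s02", "s03"))
    perm <- sample(10)
    gt3 <- stratifiedGroups(xt[perm], clin[perm, ], quantile = 0.3)
    expect_identical(sort(gt3$high), sort(gt1$high))
    expect_identical(sort(gt3$low), sort(gt1$low))

    expect_warning(stratifiedGroups(x[1:3], clin[1:3, ], quantile = 0.3),
                   "skipped")
})

test_that("one-tailed log-rank halves onto the hypothesized direction", {
    ## identical survival in both groups -> p ~ 0.5 each side
    clinA <- data.frame(sample_id = paste0("a", 1:10), cancer_type = "T",
                        treatment_class = "immunotherapy",
                        time_days = seq(100, 1000, length.out = 10),
                        event = rep(c(1L, 0L), 5))
    clinB <- clinA; clinB$sample_id <- paste0("b", 1:10)
    pEq <- oneTailedLogrank(clinA, clinB, "high_better")
    expect_gt(pEq, 0.4); expect_lt(pEq, 0.6)

    ## high group dies early: high_worse small, high_better its complement
    set.seed(4)
    early <- data.frame(sample_id = paste0("e", 1:20), cancer_type = "T",
                        treatment_class = "immunotherapy",
                        time_days = runif(20, 30, 200), event = 1L)
    late <- data.frame(sample_id = paste0("l", 1:20), cancer_type = "T",
                       treatment_class = "immunotherapy",
                       time_days = runif(20, 500, 1500), event = 1L)
    pw <- oneTailedLogrank(early, late, "high_worse")
    pb <- oneTailedLogrank(early, late, "high_better")
    expect_lt(pw, 0.05)
    expect_gt(pb, 0.95)
    expect_equal(pw + pb, 1, tolerance = 1e-12)

    expect_warning(
        p0 <- oneTailedLogrank(transform(clinA, event = 0L),
                               transform(clinB, event = 0L)),
        "no usable events")
    expect_identical(p0, 1)
})

test_that("the vectorized log-rank matches survival::survdiff on random fixtures", {
    set.seed(11)
    for (i in 1:50) {
        n <- sample(16:60, 1)
        ti <- sample(1:400, n, replace = TRUE)  # ties included
        ev <- rbinom(n, 1, 0.6)
        g <- rbinom(n, 1, 0.5)
        if (length(unique(g)) < 2 || sum(ev) == 0) next
        r <- IPMGfinder:::.logrankVec(ti, ev, matrix(TRUE, n, 1),
                                      matrix(g == 1, n, 1))
        ref <- survival::survdiff(survival::Surv(ti, ev) ~ g)
        expect_equal(unname(r$chisq), ref$chisq, tolerance = 1e-6)
        pTwo <- pchisq(r$chisq, 1, lower.tail = FALSE)
        refP <- pchisq(ref$chisq, 1, lower.tail = FALSE)
        expect_equal(unname(pTwo), refP, tolerance = 1e-6)
    }
})

test_that("the genome screen is calibrated on null genes and both lists align", {
    b <- generateCohort(cohortSpec(seed = 41, mutRate = 0, hyperExtra = 0,
                                   hazardRatioImmuno = 1,
                                   hazardRatioAll = 1, snpLogHazard = 0))
    norm <- preprocessExpression(b$cohort)
    scr <- screenGenome(norm, survivalSpec())
    tb <- rankedTable(scr$high_better)
    tw <- rankedTable(scr$high_worse)
    expect_setequal(tb$gene, tw$gene)
    ## one-tailed pair sums to 1 (normal construction)
    pw <- stats::setNames(tw$p, tw$gene)
    expect_lt(max(abs(tb$p + pw[tb$gene] - 1)), 1e-9)
    ## null p-values approximately uniform
    ks <- suppressWarnings(ks.test(tb$p, "punif"))
    expect_gt(ks$p.value, 0.01)
    ## ordering is by ascending p with gene-id tie-break
    expect_false(is.unsorted(tb$p))
})

test_that("the screen recovers planted immunotherapy-specific genes", {
    medRank <- minRank <- nonImmunoMed <- numeric(0)
    for (s in 1:8) {
        b <- generateCohort(cohortSpec(seed = 500 + s, mutRate = 0,
                                       hyperExtra = 0))
        norm <- preprocessExpression(b$cohort)
        scr <- screenGenome(norm, survivalSpec())
        rk <- match(b$truth$specific_genes,
                    rankedTable(scr$high_better)$gene)
        scrN <- screenGenome(norm,
                             survivalSpec(cohortFilter = "non_immunotherapy"))
        rkN <- match(b$truth$specific_genes,
                     rankedTable(scrN$high_better)$gene)
        medRank <- c(medRank, median(rk))
        minRank <- c(minRank, min(rk))
        nonImmunoMed <- c(nonImmunoMed, median(rkN))
    }
    G <- 1500 * 0.99            # post low-expression filtering
    ## a planted gene reaches the top decile in (essentially) every seed
    expect_gte(mean(minRank <= G / 10), 0.9)
    ## and the planted set as a whole ranks far better on the
    ## immunotherapy arm than on the control arm
    expect_gt(mean(nonImmunoMed - medRank > 0), 0.85)
})
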