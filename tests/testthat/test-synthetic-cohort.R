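test_that("cohort generation is deterministic and internally consistent", {
    sp <- cohortSpec(seed = 77, nGenes = 300L, nPathways = 12L,
                     samplesPerType = 30L, nCodons = 30L)
    a <- generateCohort(sp)
    b <- generateCohort(sp)
    expect_identical(exprMatrix(a$cohort), exprMatrix(b$cohort))
    expect_identical(mutationRecords(a$muts), mutationRecords(b$muts))
    expect_identical(a$genotype$dosage, b$genotype$dosage)
    expect_identical(a$truth, b$truth)

    ## fraction/purity constraints
    fr <- a$fractions
    expect_true(all(fr$leukocyte_fraction > 0 & fr$leukocyte_fraction <= 1))
    expect_true(all(fr$tumor_purity > 0 & fr$tumor_purity <= 1))
    expect_true(all(fr$leukocyte_fraction + fr$tumor_purity <= 1))
    expect_true(all(a$clinical$time_days > 0))

    ## every planted identifier exists in the generated tables
    tr <- a$truth
    genes <- rownames(exprMatrix(a$cohort))
    expect_true(all(c(tr$specific_genes, tr$general_genes,
                      tr$immune_genes, tr$hyper_genes) %in% genes))
    expect_true(tr$specific_pathway %in% names(pathwaySets(a$db)))
    expect_true(tr$causal_snp %in% colnames(a$genotype$dosage))
    expect_true(tr$causal_gene %in% a$genotype$genes$gene_id)

    ## planted role sets are disjoint
    expect_length(intersect(tr$specific_genes, tr$immune_genes), 0L)
    expect_length(intersect(tr$immune_genes, tr$hyper_genes), 0L)

    ## infeasible specs fail before generation
    expect_error(cohortSpec(nGenes = 100L, nPathways = 3L,
                            genesPerPathway = 25L), "must equal")
    expect_error(cohortSpec(nImmuneGenes = 3000L), "planted")
    expect_error(cohortSpec(fracImmunotherapy = 0), "\\(0, 1\\)")
})

test_that("hyper-mutated genes carry an excess non-synonymous burden", {
    b <- generateCohort(cohortSpec(seed = 5, nGenes = 300L,
                                   nPathways = 12L))
    r <- mutationRecords(b$muts)
    snv <- r[r$class %in% c("missense", "nonsense", "silent"), ]
    ratio <- function(g) {
        s <- snv[snv$gene %in% g, ]
        sum(s$class != "silent") / max(1, sum(s$class == "silent"))
    }
    bgRatio <- ratio(setdiff(unique(snv$gene), b$truth$hyper_genes))
    expect_gte(ratio(b$truth$hyper_genes), 3 * bgRatio)
})

test_that("survival marginals match the Weibull model under the null", {
    sp <- cohortSpec(seed = 13, nCancerTypes = 4L, samplesPerType = 500L,
                     nGenes = 60L, nPathways = 4L, genesPerPathway = 15L,
                     nSpecificGenes = 2L, nGeneralGenes = 2L,
                     nImmuneGenes = 10L, nHyperGenes = 2L,
                     hazardRatioImmuno = 1, hazardRatioAll = 1,
                     snpLogHazard = 0, mutRate = 0, hyperExtra = 0,
                     naRate = 0, lowExprFrac = 0)
    b <- generateCohort(sp)
    clin <- b$clinical
    k <- sp$weibullShape
    b0 <- 720 / log(2)^(1 / k)
    ## parametric fit recovers the shape
    fit <- survival::survreg(survival::Surv(time_days, event) ~ 1,
                             data = clin, dist = "weibull")
    expect_lt(abs(1 / fit$scale - k) / k, 0.1)
    ## Kaplan-Meier curve tracks the closed-form survivor function
    km <- survival::survfit(survival::Surv(time_days, event) ~ 1,
                            data = clin)
    grid <- seq(100, 1500, by = 100)
    s <- summary(km, times = grid)$surv
    expect_lt(max(abs(s - exp(-(grid / b0)^k))), 0.05)
})

test_that("planted tertile hazard ratios are realized among treated patients", {
    ## single planted effect: the marginal tertile hazard ratio then
    ## equals the planted conditional one (no frailty attenuation)
    hrs <- numeric(5)
    for (s in 1:5) {
        b <- generateCohort(cohortSpec(seed = 60 + s, mutRate = 0,
                                       hyperExtra = 0, naRate = 0,
                                       nSpecificGenes = 1L,
                                       hazardRatioAll = 1,
                                       snpLogHazard = 0))
        clin <- b$clinical
        imm <- clin$treatment_class == "immunotherapy"
        g <- b$truth$specific_genes[1]
        x <- exprMatrix(b$cohort)[g, clin$sample_id]
        ter <- cut(x[imm], quantile(x[imm], c(0, 1/3, 2/3, 1)),
                   labels = FALSE, include.lowest = TRUE)
        sub <- clin[imm, ][ter != 2, ]
        hi <- ter[ter != 2] == 3
        cx <- survival::coxph(survival::Surv(time_days, event) ~ hi,
                              data = sub)
        hrs[s] <- exp(-unname(coef(cx)))   # bottom-vs-top hazard ratio
    }
    ## protective effect: bottom tertile hazard ~ hazardRatioImmuno x top
    expect_gt(exp(mean(log(hrs))), 4)
    expect_lt(exp(mean(log(hrs))), 9)
})

test_that("the cohort bundle round-trips through standard-format files", {
    sp <- cohortSpec(seed = 21, nGenes = 100L, nPathways = 4L,
                     samplesPerType = 12L, nCodons = 20L, naRate = 0.02)
    b <- generateCohort(sp)
    d <- tempfile()
    paths <- writeCohort(b, d)
    expect_true(all(file.exists(paths)))

    m2 <- readExpression(paths["expression"])
    m1 <- exprMatrix(b$cohort)
    expect_identical(dimnames(m2), dimnames(m1))
    expect_lt(max(abs(m2 - m1), na.rm = TRUE), 1e-9)
    expect_identical(is.na(m2), is.na(m1))

    clin2 <- readClinical(paths["clinical"])
    expect_identical(clin2$sample_id, b$clinical$sample_id)
    muts2 <- readMaf(paths["maf"], cds = b$cds)
    expect_identical(nrow(mutationRecords(muts2)),
                     nrow(mutationRecords(b$muts)))
    db2 <- readGmt(paths["gmt"], dropKeywords = NULL)
    expect_identical(pathwaySets(db2), pathwaySets(b$db))
    gt2 <- readGenotypes(paths["dosage"], paths["snps"], paths["genes"])
    expect_identical(gt2$dosage, b$genotype$dosage)
    truth2 <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
    expect_identical(truth2$causal_snp, b$truth$causal_snp)
})

test_that("the codon fixture covers the documented event classes", {
    fx <- generateCodonFixture()
    expect_identical(names(fx$cds), c("geneA", "geneB", "geneC"))
    ## geneA codon list = single ATG; flanks present
    expect_identical(nchar(as.character(fx$cds[["geneA"]])), 5L)
    r <- mutationRecords(fx$muts)
    expect_setequal(r$class, c("missense", "silent", "nonsense",
                               "frameshift"))
    ## the silent record really is synonymous (CTG -> CTA)
    expect_identical(r$context[r$class == "silent"], "TGC")
})
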