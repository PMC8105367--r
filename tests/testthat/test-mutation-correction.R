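test_that("the substitution-category space has exactly 192 keys (96 collapsed)", {
    keys <- categoryKeys()
    expect_identical(length(keys), 192L)
    expect_identical(anyDuplicated(keys), 0L)
    parsed <- IPMGfinder:::.parseKeys(keys)
    expect_true(all(parsed$ref != parsed$alt))

    ## integer indexing agrees with key order
    bi <- stats::setNames(1:4, c("A", "C", "G", "T"))
    idx <- IPMGfinder:::.categoryIndex(bi[parsed$ref], bi[parsed$alt],
                                       bi[parsed$fp], bi[parsed$tp])
    expect_identical(unname(idx), seq_len(192L))

    ## strand collapse: 96 keys, each the sum of its two orientations
    fr <- uniformFreqs()
    f <- categoryFreq(fr)
    f[] <- seq_len(192) / sum(seq_len(192))
    fr2 <- new("CategoryFrequencies", freq = f,
               nSamples = typeSampleCounts(fr))
    cl <- collapseCategories(fr2)
    expect_identical(nrow(cl), 96L)
    expect_equal(sum(cl), 1, tolerance = 1e-12)
    expect_equal(cl["A[C>T]G", 1],
                 f["A[C>T]G", 1] + f["C[G>A]T", 1], tolerance = 1e-15)
})

test_that("category frequencies count SNVs per cancer type", {
    ## 10 SNVs over 3 categories (5/3/2)
    ctx <- c(rep("ACA", 5), rep("TGT", 3), rep("GCG", 2))
    alt <- c(rep("T", 5), rep("C", 3), rep("A", 2))
    recs <- data.frame(gene = "g", sample = paste0("s", 1:10),
                       class = "missense", ref = substr(ctx, 2, 2),
                       alt = alt, cds_pos = 1L, context = ctx)
    clin <- data.frame(sample_id = paste0("s", 1:10), cancer_type = "T1",
                       treatment_class = "immunotherapy",
                       time_days = 1, event = 0L)
    fr <- buildCategoryFrequencies(MutationSet(recs), clin)
    f <- categoryFreq(fr)
    expect_equal(f["A[C>T]A", "T1"], 0.5, tolerance = 1e-15)
    expect_equal(f["T[G>C]T", "T1"], 0.3, tolerance = 1e-15)
    expect_equal(f["G[C>A]G", "T1"], 0.2, tolerance = 1e-15)
    expect_equal(sum(f), 1, tolerance = 1e-12)

    ## degenerate: all SNVs in one category
    r1 <- recs[1:4, ]
    fr1 <- buildCategoryFrequencies(MutationSet(r1), clin[1:4, ])
    expect_equal(categoryFreq(fr1)["A[C>T]A", "T1"], 1, tolerance = 1e-15)
    expect_equal(sum(categoryFreq(fr1) > 0), 1L)
})

test_that("each codon enumerates 9 substitutions; ATG and CTG match the code", {
    expect_identical(nrow(codonSubstitutions("ATG")), 9L)
    expect_true(all(!codonSubstitutions("ATG")$syn))     # Met: all non-syn
    ctg <- codonSubstitutions("CTG")
    expect_identical(sum(ctg$syn), 4L)                   # CTA/CTC/CTT/TTG
    expect_identical(sum(!ctg$syn), 5L)
    synCodons <- apply(ctg[ctg$syn, ], 1, function(r) {
        cd <- "CTG"; substr(cd, as.integer(r["pos"]),
                            as.integer(r["pos"])) <- r["alt"]; cd
    })
    expect_setequal(synCodons, c("CTA", "CTC", "CTT", "TTG"))
})

test_that("codon backgrounds match the brute-force enumeration oracle", {
    fx <- generateCodonFixture()
    fr <- uniformFreqs()
    u <- 1 / 192
    bg <- computeCodonBackground(fx$cds, fr, "toy", perCodon = TRUE)
    ## ATG codon under uniform frequencies: n_i = 9u, s_i = 0
    gA <- bg$codons[bg$codons$gene == "geneA", ]
    expect_equal(gA$n_i, 9 * u, tolerance = 1e-15)
    expect_equal(gA$s_i, 0, tolerance = 1e-15)
    ## CTG codon: 5 non-synonymous, 4 synonymous
    gB2 <- bg$codons[bg$codons$gene == "geneB" & bg$codons$codon == 2, ]
    expect_equal(gB2$n_i, 5 * u, tolerance = 1e-15)
    expect_equal(gB2$s_i, 4 * u, tolerance = 1e-15)

    ## full agreement with the independent oracle, uniform and random freqs
    for (freqs in list(uniformFreqs(), local({
        set.seed(8)
        f <- matrix(rgamma(192, 1), 192, 1,
                    dimnames = list(categoryKeys(), "toy"))
        f <- f / sum(f)
        new("CategoryFrequencies", freq = f,
            nSamples = c(toy = 10L))
    }))) {
        bgX <- computeCodonBackground(fx$cds, freqs, "toy", perCodon = TRUE)
        fv <- categoryFreq(freqs)[, "toy"]
        for (g in names(fx$cds)) {
            oracle <- bruteForceBackground(as.character(fx$cds[[g]]), fv)
            got <- bgX$codons[bgX$codons$gene == g, ]
            expect_equal(got$n_i, oracle$n_i, tolerance = 1e-12)
            expect_equal(got$s_i, oracle$s_i, tolerance = 1e-12)
            gg <- bgX$genes[bgX$genes$gene == g, ]
            expect_equal(gg$N, oracle$N, tolerance = 1e-12)
            expect_equal(gg$S, oracle$S, tolerance = 1e-12)
        }
    }

    ## conservation: n_i + s_i equals the sum of the 9 category freqs
    set.seed(2)
    fv <- rgamma(192, 1); fv <- fv / sum(fv)
    frR <- new("CategoryFrequencies",
               freq = matrix(fv, 192, 1,
                             dimnames = list(categoryKeys(), "toy")),
               nSamples = c(toy = 10L))
    bgR <- computeCodonBackground(fx$cds, frR, "toy", perCodon = TRUE)
    oracleB <- bruteForceBackground(as.character(fx$cds[["geneB"]]),
                                    categoryFreq(frR)[, "toy"])
    expect_equal(bgR$codons$n_i[bgR$codons$gene == "geneB"] +
                 bgR$codons$s_i[bgR$codons$gene == "geneB"],
                 oracleB$n_i + oracleB$s_i, tolerance = 1e-12)

    ## malformed CDS errors name the gene
    bad <- Biostrings::DNAStringSet(c(geneX = "TATGAC"))  # cds len 4
    expect_error(computeCodonBackground(bad, fr, "toy"), "geneX")
    stopGene <- Biostrings::DNAStringSet(c(geneY = "TTAAGGGC"))  # TAA GGG
    expect_error(computeCodonBackground(stopGene, fr, "toy"), "geneY")
})

test_that("dN/dS follows the regularized ratio and its monotonicity", {
    mk <- function(C, Cs, N, S)
        computeDnds(data.frame(gene = "g", cancer_type = "T1",
                               C = C, Cs = Cs),
                    data.frame(gene = "g", cancer_type = "T1",
                               N = N, S = S))$dnds
    expect_equal(mk(0, 0, 0.5, 0.5), 1, tolerance = 1e-15)
    expect_equal(mk(2, 1, 0.6, 0.3), 1, tolerance = 1e-12)
    expect_equal(mk(3, 0, 0.5, 0.5), 7, tolerance = 1e-12)
    ## monotone in C, antitone in Cs
    v <- vapply(0:6, function(C) mk(C, 2, 0.5, 0.4), 0)
    expect_true(all(diff(v) > 0))
    v2 <- vapply(0:6, function(Cs) mk(3, Cs, 0.5, 0.4), 0)
    expect_true(all(diff(v2) < 0))
    ## zero synonymous background -> excluded with warning
    expect_warning(
        out <- computeDnds(data.frame(gene = "g", cancer_type = "T1",
                                      C = 1, Cs = 0),
                           data.frame(gene = "g", cancer_type = "T1",
                                      N = 0.5, S = 0)),
        "zero background")
    expect_identical(nrow(out), 0L)
})

test_that("binomial calling matches the exact tail and the union rule", {
    ## exact tail oracle via binom.test on a grid of counts
    set.seed(5)
    for (i in 1:25) {
        C <- rpois(1, 4); Cs <- rpois(1, 2); p0 <- runif(1, 0.2, 0.9)
        if (C + Cs == 0) C <- 1
        expect_equal(binomTailP(C, C + Cs, p0),
                     binom.test(C, C + Cs, p0,
                                alternative = "greater")$p.value,
                     tolerance = 1e-12)
    }
    expect_equal(binomTailP(10, 10, 0.75), 0.75^10, tolerance = 1e-15)
    expect_equal(binomTailP(0, 5, 0.3), 1, tolerance = 1e-15)

    ## union over cancer types; p ~ 0.0563 not flagged at 0.05
    dnds <- data.frame(gene = c("g1", "g1", "g2"),
                       cancer_type = c("A", "B", "A"),
                       C = c(10L, 1L, 10L), Cs = c(0L, 5L, 0L),
                       N = c(0.75, 0.5, 0.6), S = c(0.25, 0.5, 0.4),
                       dnds = c(2, 0.5, 3))
    sig <- callSignificantGenes(dnds)
    expect_false("g1" %in% sig$genes)     # p = 0.75^10 ~ 0.0563
    expect_true("g2" %in% sig$genes)      # p = 0.6^10 < 0.05 in type A only
    expect_identical(sig$genes, "g2")
})

test_that("codon indexes scale min-max with the event-weighting rules", {
    fr <- uniformFreqs(nSamples = 10L)    # pan-cancer weight u * 10
    u <- 10 / 192
    mk <- function(recs) computeCodonIndexes(MutationSet(recs), fr,
                                             unique(recs$gene))
    base <- data.frame(gene = "g", sample = "s1", class = "missense",
                       ref = "C", alt = "T", cds_pos = 1L, context = "ACA")
    ## single tabulated codon -> scaled 1
    one <- mk(base)
    expect_equal(one$scaledIndex, 1)
    expect_equal(one$r, u, tolerance = 1e-12)
    expect_identical(one$T, 1L)

    ## codon hit twice vs once at equal r -> half the raw index; min-max
    two <- mk(rbind(base,
                    transform(base, sample = "s2", cds_pos = 4L),
                    transform(base, sample = "s3", cds_pos = 4L)))
    expect_equal(two$rawIndex[two$codon == 2],
                 two$rawIndex[two$codon == 1] / 2, tolerance = 1e-12)
    expect_equal(sort(two$scaledIndex), c(0, 1))

    ## synonymous-only codons are not tabulated
    silent <- transform(base, class = "silent", cds_pos = 7L)
    three <- mk(rbind(base, silent))
    expect_identical(nrow(three), 1L)
    expect_identical(three$codon, 1L)
})

test_that("activity scores honor the no-mutation/LoF/product contract", {
    m <- matrix(1:12 + 0.5, 3, 4,
                dimnames = list(c("gS", "gT", "gU"), paste0("s", 1:4)))
    clin <- data.frame(sample_id = paste0("s", 1:4), cancer_type = "T1",
                       treatment_class = "immunotherapy",
                       time_days = 1:4, event = 0L)
    co <- IpmgCohort(m, clin, stage = "normalized")
    idx <- data.frame(gene = "gS", codon = c(1L, 2L), r = c(1, 2),
                      T = c(1L, 1L), rawIndex = c(1, 2),
                      scaledIndex = c(0.5, 0.8))
    recs <- data.frame(
        gene   = c("gS", "gS", "gS"),
        sample = c("s1", "s1", "s2"),
        class  = c("missense", "missense", "frameshift"),
        ref = "C", alt = c("T", "T", NA),
        cds_pos = c(1L, 4L, 2L),
        context = c("ACA", "ACA", NA))
    out <- scoreAndCorrect(co, idx, MutationSet(recs), "gS")
    ## two mutated codons, scaled 0.5 and 0.8 -> product 0.4
    expect_equal(out$scores["gS", "s1"], 0.4, tolerance = 1e-12)
    expect_equal(exprMatrix(out$cohort)["gS", "s1"], 0.4 * m["gS", "s1"],
                 tolerance = 1e-12)
    ## frameshift -> 0
    expect_identical(out$scores["gS", "s2"], 0)
    expect_identical(exprMatrix(out$cohort)["gS", "s2"], 0)
    ## unmutated sample of the significant gene -> 1, expression unchanged
    expect_identical(out$scores["gS", "s3"], 1)
    ## genes outside sigGenes pass through exactly
    expect_identical(exprMatrix(out$cohort)["gT", ], m["gT", ])
    expect_identical(exprMatrix(out$cohort)["gU", ], m["gU", ])
    expect_identical(cohortStage(out$cohort), "mutation_corrected")

    ## unknown gene/sample references warn and are skipped
    recs2 <- rbind(recs, data.frame(gene = "nope", sample = "s1",
                                    class = "missense", ref = "C",
                                    alt = "T", cds_pos = 1L,
                                    context = "ACA"))
    expect_warning(scoreAndCorrect(co, idx, MutationSet(recs2), "gS"),
                   "unknown")
})

test_that("null mutation data flags few genes; hypermutators are recovered", {
    flagged <- numeric(6)
    hyperRec <- numeric(6)
    for (s in 1:6) {
        b <- generateCohort(cohortSpec(seed = 900 + s, nGenes = 300L,
                                       nPathways = 12L, nCodons = 40L,
                                       naRate = 0, lowExprFrac = 0))
        clin <- b$clinical
        fr <- buildCategoryFrequencies(b$muts, clin)
        types <- colnames(categoryFreq(fr))
        genes <- intersect(names(b$cds), unique(mutationRecords(b$muts)$gene))
        struct <- IPMGfinder:::.codonSubStructure(b$cds[genes])
        bg <- do.call(rbind, lapply(types, function(t) {
            x <- computeCodonBackground(b$cds[genes], fr, t,
                                        structure = struct)
            x$cancer_type <- t
            x
        }))
        counts <- computeMutationCounts(b$muts, clin)
        dnds <- computeDnds(counts, bg)
        sig <- callSignificantGenes(dnds)
        nullGenes <- setdiff(unique(dnds$gene), b$truth$hyper_genes)
        flagged[s] <- mean(nullGenes %in% sig$genes)
        hyperRec[s] <- mean(b$truth$hyper_genes %in% sig$genes)
    }
    ## uniform placement: non-planted flag rate stays near/below nominal
    expect_lt(mean(flagged), 0.075)
    expect_gt(mean(hyperRec), 0.7)
})
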