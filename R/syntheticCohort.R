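## Synthetic TCGA-shaped cohort with planted ground truth: expression,
## somatic mutations, clinical records, leukocyte fractions, pathways,
## coding sequences and genotypes, all generated from one seed so every
## pipeline stage has a known acceptance surface.

#' Cohort generation settings
#'
#' Defaults describe the desk-scale study conditions: 6 cancer types of
#' 60 samples, 1500 genes partitioned into 60 pathways of 25 genes, a
#' 30% immunotherapy arm (about 108 treated patients, the scale of a
#' pooled pan-cancer immunotherapy cohort), one immunotherapy-specific
#' pathway (12 planted survival genes) and one general-prognostic
#' pathway (5 genes), 40 immune genes tracking the leukocyte fraction at
#' r = 0.6, 5 hyper-mutated genes and one causal SNP that is also an
#' eQTL of its gene.
#'
#' @param nCancerTypes,samplesPerType,nGenes,nPathways,genesPerPathway
#'   cohort dimensions (\code{nPathways * genesPerPathway} must equal
#'   \code{nGenes}).
#' @param fracImmunotherapy fraction of immunotherapy-treated samples.
#' @param nSpecificGenes,nGeneralGenes planted survival genes inside the
#'   specific/general pathway.
#' @param nImmuneGenes planted immune genes.
#' @param nHyperGenes planted hyper-mutated genes.
#' @param hazardRatioImmuno top-vs-bottom expression-tertile hazard
#'   ratio of a specific gene among immunotherapy patients (protective:
#'   high expression lowers hazard).
#' @param hazardRatioAll same for general-prognostic genes, all patients.
#' @param corrLeuko target Pearson correlation of immune genes with the
#'   leukocyte fraction.
#' @param snpLogHazard per-allele log hazard ratio of the causal SNP
#'   (immunotherapy patients). Negative by default: the
#'   expression-raising allele is protective, consistent with the SNP
#'   being an eQTL of a protective gene.
#' @param eqtlR target genotype-expression correlation of the causal SNP
#'   with its gene.
#' @param nCodons codons per synthetic CDS.
#' @param mutRate expected SNVs per sample.
#' @param hyperExtra expected extra non-synonymous events per
#'   hyper-mutated gene.
#' @param lofRate fraction of events emitted as frameshift/splice-site.
#' @param naRate missing-cell rate in the raw expression table.
#' @param lowExprFrac fraction of genes kept below the expression floor
#'   in every sample (exercises filtering).
#' @param nSnps genotyped SNPs.
#' @param weibullShape Weibull shape of the survival model (1 recovers
#'   the exponential; the default 2.2 gives the rising hazard typical of
#'   late-stage cohorts and a sharper 1-year outcome).
#' @param seed master seed.
#' @return validated list of class \code{CohortSpec}.
#' @export
cohortSpec <- function(nCancerTypes = 6L, samplesPerType = 60L,
                       nGenes = 1500L, nPathways = 60L,
                       genesPerPathway = 25L, fracImmunotherapy = 0.3,
                       nSpecificGenes = 12L, nGeneralGenes = 5L,
                       nImmuneGenes = 40L, nHyperGenes = 5L,
                       hazardRatioImmuno = 6, hazardRatioAll = 4,
                       corrLeuko = 0.6, snpLogHazard = -2.6, eqtlR = 0.4,
                       nCodons = 60L, mutRate = 20, hyperExtra = 120,
                       lofRate = 0.05, naRate = 0.01, lowExprFrac = 0.01,
                       nSnps = 40L, weibullShape = 2.2, seed = 1L) {
    if (weibullShape <= 0) stop("weibullShape must be positive")
    if (nPathways * genesPerPathway != nGenes)
        stop("nPathways * genesPerPathway must equal nGenes")
    if (fracImmunotherapy <= 0 || fracImmunotherapy >= 1)
        stop("fracImmunotherapy must lie in (0, 1)")
    if (hazardRatioImmuno <= 0 || hazardRatioAll <= 0)
        stop("hazard ratios must be positive")
    if (nSpecificGenes > genesPerPathway || nGeneralGenes > genesPerPathway)
        stop("more planted genes than pathway members")
    if (nImmuneGenes + nHyperGenes + 2L * genesPerPathway > nGenes)
        stop("more planted genes than genes")
    as.list(environment()) |>
        structure(class = "CohortSpec")
}

## tertile contrast of a standard normal: E[X | top 1/3] - E[X | bottom 1/3]
.TERTILE_CONTRAST <- 2 * stats::dnorm(stats::qnorm(2 / 3)) / (1 / 3)

#' Generate the synthetic cohort
#'
#' Expression follows a log-normal model (gene baselines plus
#' cancer-type offsets plus unit noise); immune genes mix the
#' standardized leukocyte fraction into the noise at the target
#' correlation; survival is proportional-hazards Weibull with
#' multiplicative effects of the planted genes (specific genes act only
#' in immunotherapy-treated patients), censored uniformly on [0, 5]
#' years; mutations are placed
#' uniformly over codons with per-cancer-type Dirichlet substitution
#' spectra; hyper-mutated genes receive extra non-synonymous events;
#' genotypes are binomial dosages with one causal, eQTL-linked SNP.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @return list: \code{cohort} (raw \linkS4class{IpmgCohort} with
#'   missing cells), \code{clinical}, \code{fractions}, \code{muts},
#'   \code{cds}, \code{db}, \code{genotype} (dosage/snps/genes) and
#'   \code{truth} (planted ground truth).
#' @export
generateCohort <- function(spec) {
    stopifnot(inherits(spec, "CohortSpec"))
    set.seed(spec$seed)
    nT <- spec$nCancerTypes; nS <- spec$samplesPerType
    n <- nT * nS; G <- spec$nGenes
    types <- sprintf("CT%02d", seq_len(nT))
    sampleIds <- sprintf("S%04d", seq_len(n))
    cancerType <- rep(types, each = nS)
    geneIds <- sprintf("G%04d", seq_len(G))

    ## pathway partition; planted gene roles
    pwIds <- sprintf("PW%02d", seq_len(spec$nPathways))
    membership <- split(geneIds, rep(pwIds, each = spec$genesPerPathway))
    db <- PathwayCollection(membership[pwIds])
    specificPw <- pwIds[1]; generalPw <- pwIds[2]
    specificGenes <- membership[[specificPw]][seq_len(spec$nSpecificGenes)]
    generalGenes <- membership[[generalPw]][seq_len(spec$nGeneralGenes)]
    otherGenes <- setdiff(geneIds, c(membership[[specificPw]],
                                     membership[[generalPw]]))
    immuneGenes <- otherGenes[seq_len(spec$nImmuneGenes)]
    hyperGenes <- otherGenes[spec$nImmuneGenes + seq_len(spec$nHyperGenes)]
    nLow <- round(spec$lowExprFrac * G)
    lowGenes <- if (nLow > 0)
        otherGenes[spec$nImmuneGenes + spec$nHyperGenes + seq_len(nLow)]
    else character(0)

    ## treatment assignment: spread within each cancer type
    nImm <- round(spec$fracImmunotherapy * n)
    imm <- rep(FALSE, n)
    perType <- round(spec$fracImmunotherapy * nS)
    for (t in seq_len(nT))
        imm[(t - 1L) * nS + seq_len(perType)] <- TRUE
    treatment <- ifelse(imm, "immunotherapy", "non_immunotherapy")

    ## leukocyte fraction and tumor purity (fraction + purity <= 1)
    fraction <- 0.05 + 0.55 * stats::rbeta(n, 2, 5)
    purity <- (1 - fraction) * stats::rbeta(n, 20, 2)
    zF <- as.vector(scale(fraction))

    ## genotypes (needed before expression for the eQTL)
    nSnps <- spec$nSnps
    snpIds <- sprintf("SNP%03d", seq_len(nSnps))
    af <- stats::runif(nSnps, 0.1, 0.5)
    af[1] <- 0.35                        # causal SNP: common variant
    af[nSnps - (0:2)] <- 0.02            # rare: MAF filter fodder
    dosage <- vapply(af, function(a) stats::rbinom(n, 2L, a), integer(n))
    dimnames(dosage) <- list(sampleIds, snpIds)
    causalSnp <- snpIds[1]
    causalGene <- specificGenes[1]
    ## gene bodies on one chromosome; SNPs near the first genes except a
    ## deliberately distant tail
    genesBed <- data.frame(chrom = "chr1",
                           start = seq_len(G) * 500000L,
                           end = seq_len(G) * 500000L + 2000L,
                           gene_id = geneIds)
    panelRows <- match(c(causalGene, specificGenes[-1], generalGenes),
                       geneIds)
    nearRows <- rep_len(panelRows, nSnps)
    pos <- genesBed$start[nearRows] +
        sample(-90000:90000, nSnps, replace = TRUE)
    farIdx <- (nSnps - 5L):(nSnps - 3L)  # > 100 kb from every gene body
    pos[farIdx] <- genesBed$start[nearRows[farIdx]] + 250000L
    snpsBed <- data.frame(chrom = "chr1", pos = as.integer(pos),
                          snp_id = snpIds)
    snpsBed$pos[1] <- genesBed$start[panelRows[1]] + 500L  # causal in-body
    zG <- dosage[, causalSnp]
    zG <- if (stats::sd(zG) > 0) as.vector(scale(zG)) else rep(0, n)

    ## expression on the log2 scale
    mu <- stats::rnorm(G, 5, 1)
    names(mu) <- geneIds
    mu[lowGenes] <- -2                    # raw < 1 everywhere
    typeOffset <- matrix(stats::rnorm(G * nT, 0, 0.5), G, nT,
                         dimnames = list(geneIds, types))
    ## planted survival genes reflect the immune state, which the whole
    ## design treats as independent of the tissue of origin: no
    ## cancer-type offsets for them
    typeOffset[c(specificGenes, generalGenes), ] <- 0
    L <- matrix(stats::rnorm(G * n), G, n,
                dimnames = list(geneIds, sampleIds))
    r <- spec$corrLeuko
    L[immuneGenes, ] <- r * matrix(zF, length(immuneGenes), n, byrow = TRUE) +
        sqrt(1 - r^2) * L[immuneGenes, , drop = FALSE]
    re <- spec$eqtlR
    L[causalGene, ] <- re * zG + sqrt(1 - re^2) * L[causalGene, ]
    Lz <- L                               # standardized effects drive hazards
    L <- L + mu + typeOffset[, match(cancerType, types)]

    ## survival: proportional-hazards Weibull (shape k; k = 1 recovers
    ## the exponential), baseline median 720 days, uniform censoring on
    ## [0, 5y]. T = b0 * (X * e^-eta)^(1/k) with X ~ Exp(1) gives
    ## S(t | eta) = exp(-e^eta (t/b0)^k): hazard ratios are e^eta.
    bImm <- -log(spec$hazardRatioImmuno) / .TERTILE_CONTRAST
    bAll <- -log(spec$hazardRatioAll) / .TERTILE_CONTRAST
    eta <- rep(0, n)
    for (g in specificGenes)
        eta <- eta + bImm * Lz[g, ] * imm
    for (g in generalGenes)
        eta <- eta + bAll * Lz[g, ]
    eta <- eta + spec$snpLogHazard * dosage[, causalSnp] * imm
    k <- spec$weibullShape
    b0 <- 720 / log(2)^(1 / k)
    tDeath <- b0 * (stats::rexp(n) * exp(-eta))^(1 / k)
    cTime <- stats::runif(n, 0, 5 * .DAYS_PER_YEAR)
    timeDays <- pmin(tDeath, cTime)
    event <- as.integer(tDeath <= cTime)
    clinical <- data.frame(sample_id = sampleIds, cancer_type = cancerType,
                           treatment_class = treatment,
                           time_days = round(timeDays, 2), event = event)
    fractions <- data.frame(sample_id = sampleIds,
                            leukocyte_fraction = round(fraction, 4),
                            tumor_purity = round(purity, 4))

    ## coding sequences (no stop codons) with 1-nt flanks
    gc0 <- Biostrings::GENETIC_CODE
    sense <- names(gc0)[gc0 != "*"]
    cdsStr <- vapply(seq_len(G), function(i)
        paste0(sample(.BASES, 1),
               paste(sample(sense, spec$nCodons, replace = TRUE),
                     collapse = ""),
               sample(.BASES, 1)), "")
    cds <- Biostrings::DNAStringSet(cdsStr)
    names(cds) <- geneIds

    ## per-type substitution spectra and mutation events
    spectra <- matrix(stats::rgamma(192 * nT, 1), 192, nT,
                      dimnames = list(categoryKeys(), types))
    spectra <- sweep(spectra, 2L, colSums(spectra), "/")
    muts <- .simulateMutations(spec, cds, clinical, spectra,
                               hyperGenes, geneIds)

    ## raw expression: invert the downstream log2(x + 1), sprinkle NA
    raw <- 2^L - 1
    raw[raw < 0] <- 0
    nNA <- round(spec$naRate * length(raw))
    if (nNA > 0) {
        naIdx <- sample.int(length(raw), nNA)
        ## keep at least one observed value per gene per type
        raw[naIdx] <- NA
        allNA <- rowSums(!is.na(raw)) == 0
        raw[allNA, 1] <- 2^mu[allNA] - 1
    }
    cohort <- IpmgCohort(raw, clinical, fractions, stage = "raw")

    truth <- list(specific_pathway = specificPw,
                  general_pathway = generalPw,
                  specific_genes = specificGenes,
                  general_genes = generalGenes,
                  immune_genes = immuneGenes,
                  hyper_genes = hyperGenes,
                  low_genes = lowGenes,
                  causal_snp = causalSnp,
                  causal_gene = causalGene,
                  hazard_ratio_immuno = spec$hazardRatioImmuno,
                  hazard_ratio_all = spec$hazardRatioAll,
                  snp_log_hazard = spec$snpLogHazard,
                  corr_leuko = spec$corrLeuko,
                  eqtl_r = spec$eqtlR,
                  seed = spec$seed)
    list(cohort = cohort, clinical = clinical, fractions = fractions,
         muts = muts, cds = cds, db = db,
         genotype = list(dosage = dosage, snps = snpsBed, genes = genesBed),
         truth = truth)
}

## Place SNV events uniformly over codons; substitution among a codon's
## nine options weighted by the cancer type's category spectrum; hyper
## genes get extra non-synonymous-only events; a small fraction of
## records are emitted as frameshift/splice-site.
.simulateMutations <- function(spec, cds, clinical, spectra, hyperGenes,
                               geneIds) {
    emptyRecs <- data.frame(gene = character(0), sample = character(0),
                            class = character(0), ref = character(0),
                            alt = character(0), cds_pos = integer(0),
                            context = character(0))
    if (spec$mutRate <= 0 && spec$hyperExtra <= 0)
        return(MutationSet(emptyRecs))
    struct <- .codonSubStructure(cds)
    gc0 <- Biostrings::GENETIC_CODE
    seqs <- as.character(cds)
    keys <- categoryKeys()
    nCod <- as.integer(vapply(struct$entries, function(e)
        as.numeric(e$nCodons), 1))
    names(nCod) <- struct$geneIds
    catMat <- lapply(struct$entries, `[[`, "cat")    # codon-major, 9/codon
    synMat <- lapply(struct$entries, `[[`, "syn")

    ## event skeleton: (sample, gene, nonsyn-only flag)
    nPer <- stats::rpois(nrow(clinical), spec$mutRate)
    evSample <- rep(clinical$sample_id, nPer)
    evGene <- sample(geneIds, sum(nPer), replace = TRUE)
    evForce <- rep(FALSE, sum(nPer))
    for (g in hyperGenes) {
        nEv <- stats::rpois(1, spec$hyperExtra)
        if (nEv == 0) next
        evSample <- c(evSample, sample(clinical$sample_id, nEv,
                                       replace = TRUE))
        evGene <- c(evGene, rep(g, nEv))
        evForce <- c(evForce, rep(TRUE, nEv))
    }
    nEv <- length(evGene)
    if (nEv == 0L) return(MutationSet(emptyRecs))
    evType <- clinical$cancer_type[match(evSample, clinical$sample_id)]
    gi <- match(evGene, struct$geneIds)
    ## codon uniform over the gene; substitution among its 9 options
    ## weighted by the cancer type's category spectrum
    codon <- 1L + floor(stats::runif(nEv) * nCod[gi])
    base9 <- (codon - 1L) * 9L
    cat9 <- t(vapply(seq_len(nEv), function(e)
        catMat[[gi[e]]][base9[e] + 1:9], integer(9)))
    syn9 <- t(vapply(seq_len(nEv), function(e)
        synMat[[gi[e]]][base9[e] + 1:9], logical(9)))
    W <- matrix(spectra[cbind(as.vector(cat9),
                              rep(match(evType, colnames(spectra)), 9))],
                nEv, 9)
    W[evForce & syn9] <- 0
    cw <- W %*% upper.tri(matrix(0, 9, 9), diag = TRUE)
    u <- stats::runif(nEv) * cw[, 9]
    within <- 10L - rowSums(cw >= u)     # first column with cumsum >= u
    pick <- cbind(seq_len(nEv), within)
    cat <- cat9[pick]
    syn <- syn9[pick]
    cdsP <- (codon - 1L) * 3L + (within - 1L) %/% 3L + 1L
    s <- seqs[evGene]
    ctx <- substring(s, cdsP, cdsP + 2L)
    ref <- substr(ctx, 2, 2)
    alt <- substr(keys[cat], 5, 5)
    ## classify: silent / missense / nonsense
    codStart <- (codon - 1L) * 3L + 2L
    cod <- substring(s, codStart, codStart + 2L)
    inCodPos <- (cdsP - 1L) %% 3L + 1L
    newcod <- paste0(ifelse(inCodPos == 1L, alt, substr(cod, 1, 1)),
                     ifelse(inCodPos == 2L, alt, substr(cod, 2, 2)),
                     ifelse(inCodPos == 3L, alt, substr(cod, 3, 3)))
    cls <- ifelse(syn, "silent",
                  ifelse(gc0[newcod] == "*", "nonsense", "missense"))
    ## a slice of the background events becomes structural loss of function
    lof <- !evForce & stats::runif(nEv) < spec$lofRate
    cls[lof] <- sample(c("frameshift", "splice_site"), sum(lof),
                       replace = TRUE)
    r <- data.frame(gene = evGene, sample = evSample, class = cls,
                    ref = ref, alt = alt, cds_pos = cdsP, context = ctx)
    MutationSet(r)
}

#' Hand-enumerable codon fixture
#'
#' A 3-gene toy: gene A is a single ATG codon (every single-base change
#' is non-synonymous), gene B is ATG + CTG (the Leu codon CTG has 4
#' synonymous and 5 non-synonymous single-base outcomes), gene C has 4
#' codons and carries a nonsense and a frameshift record. Sequences
#' carry 1-nt flanks; the mutation list covers missense, silent,
#' nonsense and frameshift.
#'
#' @return list with \code{cds} (\link[Biostrings]{DNAStringSet}),
#'   \code{muts} (\linkS4class{MutationSet}) and \code{clinical} (toy
#'   3-sample table).
#' @export
generateCodonFixture <- function() {
    cds <- Biostrings::DNAStringSet(c(
        geneA = "TATGC",                  # flank T | ATG | flank C
        geneB = "AATGCTGT",               # flank A | ATG CTG | flank T
        geneC = "GATGAAACCCGGGT"))        # flank G | ATG AAA CCC GGG | T
    recs <- data.frame(
        gene   = c("geneA", "geneB", "geneC", "geneC"),
        sample = c("s1", "s1", "s2", "s3"),
        class  = c("missense", "silent", "nonsense", "frameshift"),
        ref    = c("T", "G", "A", "C"),
        alt    = c("C", "A", "T", NA),
        cds_pos = c(2L, 6L, 4L, 8L),
        context = c("ATG", "TGC", "GAA", NA))
    clinical <- data.frame(sample_id = c("s1", "s2", "s3"),
                           cancer_type = "toy",
                           treatment_class = "immunotherapy",
                           time_days = c(100, 200, 300),
                           event = c(1L, 0L, 1L))
    list(cds = cds, muts = MutationSet(recs), clinical = clinical)
}

#' Write a generated cohort bundle to standard-format files
#'
#' Expression/clinical/fraction TSVs, MAF-dialect TSV, GMT, flanked CDS
#' FASTA, genotype + BED-like coordinate TSVs and \code{truth.json}.
#'
#' @param bundle output of \code{\link{generateCohort}}.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of file paths.
#' @export
writeCohort <- function(bundle, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- c(expression = file.path(dir, "expression.tsv"),
           clinical = file.path(dir, "clinical.tsv"),
           fractions = file.path(dir, "fractions.tsv"),
           maf = file.path(dir, "mutations.maf.tsv"),
           gmt = file.path(dir, "pathways.gmt"),
           cds = file.path(dir, "cds_flanked.fa"),
           dosage = file.path(dir, "genotypes.tsv"),
           snps = file.path(dir, "snps.bed.tsv"),
           genes = file.path(dir, "genes.bed.tsv"),
           truth = file.path(dir, "truth.json"))
    writeExpression(exprMatrix(bundle$cohort), p["expression"])
    writeClinical(bundle$clinical, p["clinical"])
    utils::write.table(bundle$fractions, p["fractions"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeMaf(bundle$muts, p["maf"])
    writeGmt(bundle$db, p["gmt"])
    Biostrings::writeXStringSet(bundle$cds, p["cds"])
    utils::write.table(data.frame(sample_id = rownames(bundle$genotype$dosage),
                                  bundle$genotype$dosage,
                                  check.names = FALSE),
                       p["dosage"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(bundle$genotype$snps, p["snps"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(bundle$genotype$genes, p["genes"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(bundle$truth, p["truth"], auto_unbox = TRUE)
    invisible(p)
}
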