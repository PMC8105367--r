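## SNP association near candidate genes: region + minor allele frequency
## filtering, a score test of genotype dosage against 1-year survival
## status with a per-SNP permutation cutoff, and the genotype-expression
## correlation (eQTL) step.

#' @importFrom GenomicRanges GRanges findOverlaps resize
#' @importFrom IRanges IRanges
NULL

#' Minor allele frequency of dosage vectors
#'
#' @param dosage samples x SNPs matrix of 0/1/2 dosages (or a vector).
#' @return numeric vector of per-SNP MAF (allele count over 2n, folded).
#' @export
minorAlleleFreq <- function(dosage) {
    if (is.null(dim(dosage))) dosage <- matrix(dosage, ncol = 1L)
    af <- colSums(dosage) / (2 * nrow(dosage))
    pmin(af, 1 - af)
}

#' Filter SNPs by region and minor allele frequency
#'
#' Retains SNPs lying within a gene body extended by \code{windowKb}
#' kilobases on both sides, with MAF >= \code{mafMin}. SNPs with missing
#' coordinates are dropped with a warning.
#'
#' @param geno list from \code{\link{readGenotypes}} (\code{dosage},
#'   \code{snps}, \code{genes}) or a dosage matrix plus explicit
#'   coordinate frames.
#' @param snps data.frame \code{chrom}, \code{pos}, \code{snp_id}.
#' @param genes data.frame \code{chrom}, \code{start}, \code{end},
#'   \code{gene_id}.
#' @param windowKb flanking window in kb (default 100).
#' @param mafMin MAF floor (default 0.05).
#' @return list: \code{dosage} (filtered), \code{snps} (with a
#'   \code{nearest_gene} column of the first overlapping panel gene).
#' @export
filterSnps <- function(geno, snps = NULL, genes = NULL, windowKb = 100,
                       mafMin = 0.05) {
    if (is.list(geno) && !is.null(geno$dosage)) {
        snps <- geno$snps; genes <- geno$genes; geno <- geno$dosage
    }
    miss <- is.na(snps$chrom) | is.na(snps$pos)
    if (any(miss)) {
        warning(sum(miss), " SNPs without coordinates dropped")
        snps <- snps[!miss, , drop = FALSE]
    }
    geno <- geno[, snps$snp_id, drop = FALSE]
    snpGr <- GRanges(snps$chrom, IRanges(snps$pos, width = 1L))
    w <- as.integer(windowKb * 1000)
    geneGr <- GRanges(genes$chrom,
                      IRanges(pmax(1L, genes$start - w), genes$end + w))
    ov <- findOverlaps(snpGr, geneGr)
    inRegion <- seq_len(nrow(snps)) %in% S4Vectors::queryHits(ov)
    gene1 <- rep(NA_character_, nrow(snps))
    gene1[S4Vectors::queryHits(ov)] <-
        genes$gene_id[S4Vectors::subjectHits(ov)]
    maf <- minorAlleleFreq(geno)
    keep <- inRegion & maf >= mafMin
    snpsOut <- snps[keep, , drop = FALSE]
    snpsOut$nearest_gene <- gene1[keep]
    snpsOut$maf <- maf[keep]
    list(dosage = geno[, keep, drop = FALSE], snps = snpsOut)
}

## Vectorized score (trend) test of binary labels on dosage columns:
## U = g'(y - ybar), V = ybar(1-ybar) * sum((g - gbar)^2);
## chi = U^2/V ~ chisq(1) under the null.
.scoreTestP <- function(dosage, y) {
    yc <- y - mean(y)
    U <- as.vector(crossprod(dosage, yc))
    gc <- sweep(dosage, 2L, colMeans(dosage))
    V <- mean(y) * (1 - mean(y)) * colSums(gc^2)
    p <- rep(1, length(U))
    ok <- V > 0
    p[ok] <- stats::pchisq(U[ok]^2 / V[ok], df = 1, lower.tail = FALSE)
    p
}

#' Associate SNP dosages with 1-year survival status
#'
#' Per SNP: a single-marker score test of the binary status on additive
#' dosage. The per-SNP significance cutoff is the 5th percentile of the
#' p-values from \code{nShuffle} genotype permutations; a SNP is flagged
#' when \code{p < alpha} AND \code{p < cutoff}.
#'
#' @param dosage samples x SNPs matrix (rows named by sample id).
#' @param labels binary 1-year status named by sample id (NA excluded).
#' @param nShuffle genotype permutations (default 1000).
#' @param alpha nominal threshold (default 0.05).
#' @param seed RNG seed.
#' @return data.frame: \code{snp_id}, \code{p}, \code{cutoff},
#'   \code{significant}.
#' @export
associateSnps <- function(dosage, labels, nShuffle = 1000L, alpha = 0.05,
                          seed = 1L) {
    common <- intersect(rownames(dosage), names(labels)[!is.na(labels)])
    d <- dosage[common, , drop = FALSE]
    y <- as.numeric(labels[common])
    if (length(unique(y)) < 2L) stop("constant label vector")
    pObs <- .scoreTestP(d, y)
    set.seed(seed)
    nullP <- matrix(NA_real_, nShuffle, ncol(d))
    for (b in seq_len(nShuffle)) {
        ## permuting rows of the dosage matrix == shuffling each SNP's
        ## genotype against the fixed labels
        nullP[b, ] <- .scoreTestP(d[sample.int(nrow(d)), , drop = FALSE], y)
    }
    cutoff <- apply(nullP, 2L, stats::quantile, probs = 0.05, names = FALSE)
    data.frame(snp_id = colnames(d), p = pObs, cutoff = cutoff,
               significant = pObs < alpha & pObs < cutoff)
}

#' Genotype-expression correlation (eQTL step)
#'
#' For each SNP-gene pair: Pearson correlation between the gene's
#' expression and the SNP dosage, its p-value, and a per-pair
#' permutation cutoff (5th percentile of the correlation p over
#' \code{nPerm} genotype permutations). A pair is flagged an eQTL when
#' \code{r > rMin}, \code{p < alpha} and \code{p < cutoff}.
#'
#' @param dosage samples x SNPs matrix.
#' @param cohort an \linkS4class{IpmgCohort} (expression source).
#' @param pairs data.frame \code{snp_id}, \code{gene_id}.
#' @param nPerm permutations (default 1000).
#' @param rMin correlation floor (default 0.2).
#' @param alpha nominal threshold (default 0.05).
#' @param seed RNG seed.
#' @return data.frame: \code{snp_id}, \code{gene_id}, \code{r}, \code{p},
#'   \code{cutoff}, \code{eqtl}.
#' @export
snpExpressionCorrelation <- function(dosage, cohort, pairs, nPerm = 1000L,
                                     rMin = 0.2, alpha = 0.05, seed = 1L) {
    expr <- exprMatrix(cohort)
    common <- intersect(rownames(dosage), colnames(expr))
    if (length(common) < 10L) stop("need >= 10 paired samples")
    seeds <- .childSeeds(seed, nrow(pairs))
    out <- pairs
    out$r <- NA_real_; out$p <- NA_real_; out$cutoff <- NA_real_
    out$eqtl <- FALSE
    n <- length(common)
    corP <- function(r) {
        tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
        2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    }
    for (i in seq_len(nrow(pairs))) {
        sid <- pairs$snp_id[i]; gid <- pairs$gene_id[i]
        if (!sid %in% colnames(dosage) || !gid %in% rownames(expr)) next
        g <- dosage[common, sid]
        if (stats::sd(g) == 0) next    # zero-variance genotype: skipped
        e <- expr[gid, common]
        r <- stats::cor(e, g)
        p <- corP(r)
        set.seed(seeds[i])
        nullR <- vapply(seq_len(nPerm), function(b)
            stats::cor(e, g[sample.int(n)]), 0)
        cutoff <- stats::quantile(corP(nullR), probs = 0.05, names = FALSE)
        out$r[i] <- r; out$p[i] <- p; out$cutoff[i] <- cutoff
        out$eqtl[i] <- r > rMin && p < alpha && p < cutoff
    }
    out
}
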