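## Mutation correction: trinucleotide substitution-category backgrounds,
## codon-level synonymous/non-synonymous expectation, dN/dS, significantly
## mutated gene calling, codon indexes and per-sample protein-activity
## scores used to rescale expression.

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Enumerate the substitution-category key space
#'
#' The default scheme distinguishes all 12 ref>alt base pairs crossed
#' with the 16 immediate 5'/3' flanking contexts, i.e. exactly 192
#' categories, written as e.g. \code{"A[C>T]G"}.
#'
#' @return character vector of 192 keys in canonical order.
#' @export
categoryKeys <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        g <- expand.grid(tp = .BASES, fp = .BASES, alt = .BASES,
                         ref = .BASES, stringsAsFactors = FALSE)
        g <- g[g$ref != g$alt, ]
        keys <- paste0(g$fp, "[", g$ref, ">", g$alt, "]", g$tp)
        ## canonical order: ref, alt, 5', 3'
        cache <<- keys[order(g$ref, g$alt, g$fp, g$tp)]
        cache
    }
})

.categoryKey <- function(fp, ref, alt, tp) paste0(fp, "[", ref, ">", alt, "]", tp)

#' Collapse 192 categories onto the 96 pyrimidine-reference view
#'
#' Each purine-reference key is mapped to its reverse-complement
#' (pyrimidine-reference) key; collapsed frequencies are the sum of the
#' two strand orientations.
#'
#' @param x a \linkS4class{CategoryFrequencies} object.
#' @return matrix of 96 collapsed categories x cancer types.
#' @export
collapseCategories <- function(x) {
    keys <- categoryKeys()
    parse <- .parseKeys(keys)
    purine <- parse$ref %in% c("A", "G")
    collapsed <- keys
    collapsed[purine] <- .categoryKey(.COMP[parse$tp[purine]],
                                      .COMP[parse$ref[purine]],
                                      .COMP[parse$alt[purine]],
                                      .COMP[parse$fp[purine]])
    rowsum(categoryFreq(x), collapsed)
}

.parseKeys <- function(keys) {
    list(fp = substr(keys, 1, 1), ref = substr(keys, 3, 3),
         alt = substr(keys, 5, 5), tp = substr(keys, 7, 7))
}

#' Per-cancer-type substitution-category background frequencies
#'
#' Counts single-nucleotide substitutions (missense, nonsense, silent)
#' per category within each cancer type and divides by the type's total
#' SNV count. Records without a resolvable trinucleotide context are
#' excluded from frequency counting (they still contribute to mutation
#' counts elsewhere). Cancer types with zero usable SNVs are excluded
#' with a warning.
#'
#' @param muts a \linkS4class{MutationSet}.
#' @param clinical clinical data.frame (maps samples to cancer types and
#'   supplies per-type sample counts).
#' @return a \linkS4class{CategoryFrequencies}.
#' @export
buildCategoryFrequencies <- function(muts, clinical) {
    clinical <- validateClinical(clinical)
    r <- mutationRecords(muts)
    r <- r[r$class %in% c("missense", "nonsense", "silent"), , drop = FALSE]
    r$cancer_type <- clinical$cancer_type[match(r$sample, clinical$sample_id)]
    r <- r[!is.na(r$cancer_type), , drop = FALSE]
    usable <- !is.na(r$context) & nchar(r$context) == 3L & !is.na(r$alt)
    r <- r[usable, , drop = FALSE]
    keys <- categoryKeys()
    key <- .categoryKey(substr(r$context, 1, 1), substr(r$context, 2, 2),
                        r$alt, substr(r$context, 3, 3))
    ok <- key %in% keys
    r <- r[ok, , drop = FALSE]; key <- key[ok]
    types <- sort(unique(clinical$cancer_type))
    tab <- table(factor(key, levels = keys),
                 factor(r$cancer_type, levels = types))
    tot <- colSums(tab)
    if (any(tot == 0)) {
        warning("cancer types with zero usable SNVs excluded: ",
                paste(types[tot == 0], collapse = ", "))
        tab <- tab[, tot > 0, drop = FALSE]
        types <- types[tot > 0]
        tot <- tot[tot > 0]
    }
    freq <- sweep(unclass(tab), 2L, tot, "/")
    dimnames(freq) <- list(keys, types)
    nSamp <- vapply(types, function(t)
        sum(clinical$cancer_type == t), 1L)
    new("CategoryFrequencies", freq = freq, nSamples = nSamp)
}

## Lookup: for each of the 64 codons, the 9 single-base variants with
## their within-codon position, alt base and synonymous flag (relative to
## the standard genetic code; changes to stop are non-synonymous).
.codonSubTable <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        gc0 <- Biostrings::GENETIC_CODE
        codons <- names(gc0)
        out <- vector("list", length(codons))
        names(out) <- codons
        for (cd in codons) {
            rows <- list(); k <- 1L
            for (pos in 1:3) {
                refb <- substr(cd, pos, pos)
                for (alt in setdiff(.BASES, refb)) {
                    newcd <- cd
                    substr(newcd, pos, pos) <- alt
                    rows[[k]] <- data.frame(pos = pos, ref = refb, alt = alt,
                                            syn = unname(gc0[newcd] == gc0[cd]))
                    k <- k + 1L
                }
            }
            out[[cd]] <- do.call(rbind, rows)
        }
        cache <<- out
        cache
    }
})

#' Enumerate the 9 single-base substitutions of one codon
#'
#' @param codon 3-base string.
#' @return data.frame with columns \code{pos}, \code{ref}, \code{alt},
#'   \code{syn} (synonymous under the standard genetic code; nonsense
#'   counts as non-synonymous).
#' @export
codonSubstitutions <- function(codon) .codonSubTable()[[toupper(codon)]]

## Integer index of a category in categoryKeys() order (ref, alt, 5', 3').
## Base coding A=1, C=2, G=3, T=4; alt ranked among the 3 non-ref bases.
.categoryIndex <- function(refI, altI, fpI, tpI) {
    altRank <- altI - (altI > refI)
    ((refI - 1L) * 3L + (altRank - 1L)) * 16L + (fpI - 1L) * 4L + tpI
}

## Flatten every (codon, substitution) pair of every CDS into parallel
## vectors: gene index, codon index, category index, synonymous flag.
## The structure depends only on the sequences and is reused across
## cancer types.
.codonSubStructure <- function(cds) {
    gc0 <- Biostrings::GENETIC_CODE
    stops <- names(which(gc0 == "*"))
    codons64 <- names(gc0)
    ## 64 x 9 lookup matrices
    POS <- matrix(0L, 64, 9); ALT <- matrix(0L, 64, 9)
    SYN <- matrix(FALSE, 64, 9)
    for (k in seq_along(codons64)) {
        st <- .codonSubTable()[[codons64[k]]]
        POS[k, ] <- st$pos
        ALT[k, ] <- match(st$alt, .BASES)
        SYN[k, ] <- st$syn
    }
    baseI <- stats::setNames(1:4, .BASES)
    geneIds <- names(cds)
    seqs <- as.character(cds)
    out <- vector("list", length(geneIds))
    for (gi in seq_along(geneIds)) {
        s <- seqs[[gi]]
        L <- nchar(s)
        if ((L - 2) %% 3 != 0)
            stop("CDS length not divisible by 3 for gene ", geneIds[gi])
        nc <- (L - 2) %/% 3
        starts <- seq(1L, by = 3L, length.out = nc)
        codons <- substring(s, starts + 1L, starts + 3L)
        if (nc > 0 && codons[nc] %in% stops) {
            codons <- codons[-nc]; starts <- starts[-nc]; nc <- nc - 1L
        }
        if (any(codons %in% stops))
            stop("internal stop codon in gene ", geneIds[gi])
        ci <- match(codons, codons64)
        chI <- unname(baseI[strsplit(s, "", fixed = TRUE)[[1]]])
        pos <- as.vector(t(POS[ci, , drop = FALSE]))      # codon-major
        altI <- as.vector(t(ALT[ci, , drop = FALSE]))
        syn <- as.vector(t(SYN[ci, , drop = FALSE]))
        cdsP <- rep(starts, each = 9L) + pos - 1L
        ## flanked seq: cds position p sits at seq position p + 1
        fpI <- chI[cdsP]; refI <- chI[cdsP + 1L]; tpI <- chI[cdsP + 2L]
        out[[gi]] <- list(codon = rep(seq_len(nc), each = 9L),
                          cat = .categoryIndex(refI, altI, fpI, tpI),
                          syn = syn, nCodons = nc)
    }
    list(geneIds = geneIds, entries = out)
}

#' Codon-level mutation background for one cancer type
#'
#' For every codon of every gene, enumerates its 9 possible single-base
#' substitutions, classifies each as synonymous or non-synonymous via the
#' standard genetic code, looks up the substitution-category frequency of
#' that change in its genomic trinucleotide context, and accumulates the
#' per-codon non-synonymous (\code{n_i}) and synonymous (\code{s_i})
#' expectations and their per-gene sums \code{N_j}, \code{S_j}.
#'
#' @param cds \link[Biostrings]{DNAStringSet} of coding sequences with one
#'   flanking base at each end; a trailing stop codon, if present, is
#'   excluded from the codon list.
#' @param freqs a \linkS4class{CategoryFrequencies}.
#' @param cancerType which type's frequency column to use.
#' @param perCodon if TRUE, also return the per-codon table.
#' @param structure optional precomputed \code{.codonSubStructure(cds)}
#'   (internal reuse across cancer types).
#' @return data.frame with \code{gene}, \code{N}, \code{S}; when
#'   \code{perCodon}, a list with \code{genes} and \code{codons}.
#' @export
computeCodonBackground <- function(cds, freqs, cancerType, perCodon = FALSE,
                                   structure = NULL) {
    fr <- categoryFreq(freqs)
    if (!cancerType %in% colnames(fr))
        stop("no frequencies for cancer type ", cancerType)
    fvec <- unname(fr[, cancerType])
    if (is.null(structure)) structure <- .codonSubStructure(cds)
    geneIds <- structure$geneIds
    N <- numeric(length(geneIds)); S <- numeric(length(geneIds))
    codonsOut <- if (perCodon) vector("list", length(geneIds)) else NULL
    for (gi in seq_along(geneIds)) {
        e <- structure$entries[[gi]]
        f <- fvec[e$cat]
        ni <- rowsum(f * !e$syn, e$codon, reorder = TRUE)
        si <- rowsum(f * e$syn, e$codon, reorder = TRUE)
        N[gi] <- sum(ni); S[gi] <- sum(si)
        if (perCodon)
            codonsOut[[gi]] <- data.frame(gene = geneIds[gi],
                                          codon = seq_len(e$nCodons),
                                          n_i = as.numeric(ni),
                                          s_i = as.numeric(si))
    }
    genesDf <- data.frame(gene = geneIds, N = N, S = S)
    if (perCodon)
        list(genes = genesDf, codons = do.call(rbind, codonsOut))
    else genesDf
}

#' Per-gene, per-cancer-type mutation counts
#'
#' \code{C} = non-synonymous SNV count (missense + nonsense), \code{Cs} =
#' synonymous SNV count (silent). Frameshift/splice-site/other events are
#' tracked separately as loss-of-function or unclassified and do not
#' enter the counts.
#'
#' @param muts a \linkS4class{MutationSet}.
#' @param clinical clinical data.frame.
#' @return data.frame with \code{gene}, \code{cancer_type}, \code{C},
#'   \code{Cs}.
#' @export
computeMutationCounts <- function(muts, clinical) {
    clinical <- validateClinical(clinical)
    r <- mutationRecords(muts)
    r$cancer_type <- clinical$cancer_type[match(r$sample, clinical$sample_id)]
    r <- r[!is.na(r$cancer_type), , drop = FALSE]
    snv <- r[r$class %in% c("missense", "nonsense", "silent"), , drop = FALSE]
    if (!nrow(snv))
        return(data.frame(gene = character(0), cancer_type = character(0),
                          C = integer(0), Cs = integer(0)))
    key <- interaction(snv$gene, snv$cancer_type, drop = TRUE)
    agg <- data.frame(gene = tapply(snv$gene, key, `[`, 1),
                      cancer_type = tapply(snv$cancer_type, key, `[`, 1),
                      C = as.integer(tapply(snv$class != "silent", key, sum)),
                      Cs = as.integer(tapply(snv$class == "silent", key, sum)))
    rownames(agg) <- NULL
    agg
}

#' Regularized dN/dS per gene and cancer type
#'
#' \code{dNdS = (C/N + 1) / (Cs/S + 1)}: the +1 regularizers keep the
#' ratio defined (and equal to 1) for genes without observed SNVs.
#' Genes whose synonymous background \code{S} is zero are excluded with a
#' warning.
#'
#' @param counts output of \code{\link{computeMutationCounts}}.
#' @param bg per-type backgrounds: data.frame with \code{gene},
#'   \code{cancer_type}, \code{N}, \code{S} (stack per-type outputs of
#'   \code{\link{computeCodonBackground}}).
#' @return data.frame with \code{gene}, \code{cancer_type}, \code{C},
#'   \code{Cs}, \code{N}, \code{S}, \code{dnds}.
#' @export
computeDnds <- function(counts, bg) {
    m <- merge(bg, counts, by = c("gene", "cancer_type"), all.x = TRUE)
    m$C[is.na(m$C)] <- 0L
    m$Cs[is.na(m$Cs)] <- 0L
    bad <- m$S <= 0 | m$N <= 0
    if (any(bad)) {
        warning(sum(bad), " gene/type pairs with zero background excluded")
        m <- m[!bad, , drop = FALSE]
    }
    m$dnds <- (m$C / m$N + 1) / (m$Cs / m$S + 1)
    rownames(m) <- NULL
    m
}

#' Exact one-sided binomial tail P(X >= c | n, p)
#' @param c observed successes
#' @param n trials
#' @param p success probability
#' @return upper-tail probability (1 when \code{c == 0})
#' @export
binomTailP <- function(c, n, p) {
    stats::pbinom(c - 1, n, p, lower.tail = FALSE)
}

#' Call significantly mutated genes
#'
#' Per cancer type, a one-sided binomial test of the non-synonymous count
#' \code{C} in \code{C + Cs} SNVs against the background probability
#' \code{N/(N+S)}; a gene is flagged in that type iff \code{p < alpha}
#' AND \code{dN/dS > 1}. The final set is the union over cancer types.
#' Gene/type pairs with \code{C + Cs == 0} are skipped.
#'
#' @param dnds output of \code{\link{computeDnds}}.
#' @param alpha significance threshold (default 0.05).
#' @return list with \code{genes} (character union set) and \code{table}
#'   (per gene/type p-values and flags).
#' @export
callSignificantGenes <- function(dnds, alpha = 0.05) {
    d <- dnds[dnds$C + dnds$Cs > 0, , drop = FALSE]
    d$p <- binomTailP(d$C, d$C + d$Cs, d$N / (d$N + d$S))
    d$flagged <- d$p < alpha & d$dnds > 1
    list(genes = sort(unique(d$gene[d$flagged])), table = d)
}

#' Codon indexes for significantly mutated genes
#'
#' For every codon of a significant gene carrying at least one
#' non-synonymous SNV: \code{r} is the sample-weighted pan-cancer
#' frequency of the observed substitution category (per-type frequency
#' times per-type sample count, summed over types; multiple distinct
#' categories at one codon are pooled by the event-weighted mean),
#' \code{T} the pan-cancer non-synonymous event count at the codon, the
#' raw index \code{I = r / T}, min-max scaled to [0, 1] across all
#' tabulated codons (all-equal raw indexes map to 1). Codons with only
#' synonymous events are not tabulated.
#'
#' @param muts a \linkS4class{MutationSet}.
#' @param freqs a \linkS4class{CategoryFrequencies}.
#' @param sigGenes character vector of significantly mutated genes.
#' @return data.frame with \code{gene}, \code{codon}, \code{r}, \code{T},
#'   \code{rawIndex}, \code{scaledIndex}.
#' @export
computeCodonIndexes <- function(muts, freqs, sigGenes) {
    if (!length(sigGenes)) stop("sigGenes must be non-empty")
    r <- mutationRecords(muts)
    r <- r[r$gene %in% sigGenes &
           r$class %in% c("missense", "nonsense") &
           !is.na(r$cds_pos) & !is.na(r$context) & !is.na(r$alt), ,
           drop = FALSE]
    if (!nrow(r))
        return(data.frame(gene = character(0), codon = integer(0),
                          r = numeric(0), T = integer(0),
                          rawIndex = numeric(0), scaledIndex = numeric(0)))
    fr <- categoryFreq(freqs)
    nSamp <- typeSampleCounts(freqs)[colnames(fr)]
    ## sample-weighted pan-cancer frequency per category
    panW <- as.vector(fr %*% nSamp)
    names(panW) <- rownames(fr)
    key <- .categoryKey(substr(r$context, 1, 1), substr(r$context, 2, 2),
                        r$alt, substr(r$context, 3, 3))
    r$w <- panW[key]
    r <- r[!is.na(r$w), , drop = FALSE]
    r$codon <- as.integer(ceiling(r$cds_pos / 3))
    grp <- interaction(r$gene, r$codon, drop = TRUE)
    tab <- data.frame(gene = tapply(r$gene, grp, `[`, 1),
                      codon = as.integer(tapply(r$codon, grp, `[`, 1)),
                      r = as.numeric(tapply(r$w, grp, mean)),
                      T = as.integer(tapply(r$w, grp, length)))
    tab$rawIndex <- tab$r / tab$T
    rng <- range(tab$rawIndex)
    tab$scaledIndex <- if (diff(rng) == 0) rep(1, nrow(tab)) else
        (tab$rawIndex - rng[1]) / diff(rng)
    tab <- tab[order(tab$gene, tab$codon), , drop = FALSE]
    rownames(tab) <- NULL
    tab
}

#' Protein-activity scores and mutation-corrected expression
#'
#' Per (significant gene, sample): no mutation observed gives score 1;
#' any frameshift or splice-site event gives score 0 (loss of function);
#' otherwise the product of the scaled indexes of the distinct codons
#' carrying non-synonymous SNVs in that sample. The corrected expression
#' is score times the (normalized) expression; genes outside
#' \code{sigGenes} pass through with score 1.
#'
#' @param cohort an \linkS4class{IpmgCohort} at the normalized stage.
#' @param idx codon-index table from \code{\link{computeCodonIndexes}}.
#' @param muts a \linkS4class{MutationSet}.
#' @param sigGenes significantly mutated genes.
#' @return list with \code{scores} (genes x samples matrix over
#'   \code{sigGenes}) and \code{cohort} (stage
#'   \code{"mutation_corrected"}).
#' @export
scoreAndCorrect <- function(cohort, idx, muts, sigGenes) {
    expr <- exprMatrix(cohort)
    sigGenes <- intersect(sigGenes, rownames(expr))
    scores <- matrix(1, nrow = length(sigGenes), ncol = ncol(expr),
                     dimnames = list(sigGenes, colnames(expr)))
    r <- mutationRecords(muts)
    known <- r$gene %in% rownames(expr) & r$sample %in% colnames(expr)
    if (any(!known))
        warning(sum(!known), " mutation records reference unknown gene/sample; skipped")
    r <- r[known & r$gene %in% sigGenes, , drop = FALSE]
    if (nrow(r)) {
        ## product of scaled indexes over distinct mutated codons
        ns <- r[r$class %in% c("missense", "nonsense") & !is.na(r$cds_pos), ,
                drop = FALSE]
        if (nrow(ns)) {
            ns$codon <- as.integer(ceiling(ns$cds_pos / 3))
            ns <- unique(ns[, c("gene", "sample", "codon")])
            ii <- match(paste(ns$gene, ns$codon),
                        paste(idx$gene, idx$codon))
            ns$si <- idx$scaledIndex[ii]
            ns <- ns[!is.na(ns$si), , drop = FALSE]
            if (nrow(ns)) {
                grp <- paste(ns$gene, ns$sample, sep = "\r")
                prod <- tapply(ns$si, grp, prod)
                gs <- strsplit(names(prod), "\r", fixed = TRUE)
                gi <- match(vapply(gs, `[[`, "", 1L), sigGenes)
                si <- match(vapply(gs, `[[`, "", 2L), colnames(expr))
                scores[cbind(gi, si)] <- as.numeric(prod)
            }
        }
        lof <- r[r$class %in% c("frameshift", "splice_site"), , drop = FALSE]
        if (nrow(lof))
            scores[cbind(match(lof$gene, sigGenes),
                         match(lof$sample, colnames(expr)))] <- 0
    }
    corrected <- expr
    corrected[sigGenes, ] <- scores * expr[sigGenes, , drop = FALSE]
    list(scores = scores,
         cohort = setExprMatrix(cohort, corrected,
                                stage = "mutation_corrected"))
}

#' Run the whole mutation-correction stage
#'
#' Frequencies, per-type codon backgrounds, counts, dN/dS, significant
#' gene calling, codon indexes and the corrected cohort in one call.
#'
#' @param cohort normalized \linkS4class{IpmgCohort}.
#' @param muts a \linkS4class{MutationSet}.
#' @param cds flanked CDS \link[Biostrings]{DNAStringSet}.
#' @param alpha binomial significance threshold.
#' @return list: \code{freqs}, \code{dnds}, \code{sigGenes}, \code{idx},
#'   \code{scores}, \code{cohort}.
#' @export
mutationCorrect <- function(cohort, muts, cds, alpha = 0.05) {
    clin <- clinicalTable(cohort)
    freqs <- buildCategoryFrequencies(muts, clin)
    types <- colnames(categoryFreq(freqs))
    genesInData <- intersect(names(cds),
                             unique(mutationRecords(muts)$gene))
    struct <- .codonSubStructure(cds[genesInData])
    bg <- do.call(rbind, lapply(types, function(t) {
        b <- computeCodonBackground(cds[genesInData], freqs, t,
                                    structure = struct)
        b$cancer_type <- t
        b
    }))
    counts <- computeMutationCounts(muts, clin)
    dnds <- computeDnds(counts, bg)
    sig <- callSignificantGenes(dnds, alpha = alpha)
    if (length(sig$genes)) {
        idx <- computeCodonIndexes(muts, freqs, sig$genes)
        sc <- scoreAndCorrect(cohort, idx, muts, sig$genes)
    } else {
        idx <- computeCodonIndexes(muts, freqs, "none__placeholder")
        sc <- list(scores = matrix(numeric(0), 0, ncol(cohort)),
                   cohort = setExprMatrix(cohort, exprMatrix(cohort),
                                          stage = "mutation_corrected"))
    }
    list(freqs = freqs, dnds = dnds, sigGenes = sig$genes,
         sigTable = sig$table, idx = idx, scores = sc$scores,
         cohort = sc$cohort)
}
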