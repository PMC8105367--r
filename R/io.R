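#' Run configuration
#'
#' Central knobs of the pipeline with the study's default constants: the
#' 3-year survival cap for the genome-wide screen, the 1-year horizon for
#' the prediction model, 1000 specificity resamples, 5000 stratification
#' resamples, 1000 balanced validation sets, the 0.3 immune-gene
#' correlation cutoff, the 0.05 significance thresholds and the 5% minor
#' allele frequency floor.
#'
#' @param seed master seed; every random stage derives a child seed from it.
#' @param survivalCapYearsScreen cap (years) for the survival screen.
#' @param survivalCapYearsModel horizon (years) for status labels.
#' @param nSpecificityResamples non-immunotherapy resamples (specificity null).
#' @param nClusterResamples stratification control resamples.
#' @param nValidationSets balanced validation draws for the classifier.
#' @param thresholds named list: \code{corr_cutoff}, \code{rsf_p},
#'   \code{gene_p}, \code{maf}.
#' @return validated list of class \code{RunConfig}.
#' @export
runConfig <- function(seed = 1L,
                      survivalCapYearsScreen = 3,
                      survivalCapYearsModel = 1,
                      nSpecificityResamples = 1000L,
                      nClusterResamples = 5000L,
                      nValidationSets = 1000L,
                      thresholds = list(corr_cutoff = 0.3, rsf_p = 0.05,
                                        gene_p = 0.05, maf = 0.05)) {
    counts <- c(nSpecificityResamples, nClusterResamples, nValidationSets)
    if (any(counts < 1)) stop("all resample counts must be >= 1")
    if (survivalCapYearsScreen <= 0 || survivalCapYearsModel <= 0)
        stop("survival caps must be positive")
    th <- unlist(thresholds)
    if (any(th <= 0 | th >= 1)) stop("thresholds must lie in (0, 1)")
    structure(list(seed = as.integer(seed),
                   survivalCapYearsScreen = survivalCapYearsScreen,
                   survivalCapYearsModel = survivalCapYearsModel,
                   nSpecificityResamples = as.integer(nSpecificityResamples),
                   nClusterResamples = as.integer(nClusterResamples),
                   nValidationSets = as.integer(nValidationSets),
                   thresholds = thresholds),
              class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the \code{\link{runConfig}} arguments
#' (\code{seed}, \code{survival_cap_years_screen},
#' \code{survival_cap_years_model}, \code{n_specificity_resamples},
#' \code{n_cluster_resamples}, \code{n_validation_sets},
#' \code{thresholds}); absent keys keep their defaults.
#'
#' @param path YAML file.
#' @return a \code{RunConfig}.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    d <- runConfig()
    pick <- function(key, default) if (!is.null(y[[key]])) y[[key]] else default
    th <- d$thresholds
    if (!is.null(y$thresholds)) th[names(y$thresholds)] <- y$thresholds
    runConfig(seed = pick("seed", d$seed),
              survivalCapYearsScreen = pick("survival_cap_years_screen",
                                            d$survivalCapYearsScreen),
              survivalCapYearsModel = pick("survival_cap_years_model",
                                           d$survivalCapYearsModel),
              nSpecificityResamples = pick("n_specificity_resamples",
                                           d$nSpecificityResamples),
              nClusterResamples = pick("n_cluster_resamples",
                                       d$nClusterResamples),
              nValidationSets = pick("n_validation_sets",
                                     d$nValidationSets),
              thresholds = th)
}

#' Read an expression matrix from TSV
#'
#' Genes in rows, samples in columns; the first column holds gene ids.
#' Empty cells and \code{NA} are kept as missing values.
#'
#' @param path TSV file.
#' @return numeric matrix with unique row/column names.
#' @export
readExpression <- function(path) {
    d <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    genes <- as.character(d[[1]])
    if (anyDuplicated(genes))
        stop("duplicate gene ids in expression table: ",
             paste(unique(genes[duplicated(genes)])[1:1], collapse = ", "))
    if (anyDuplicated(colnames(d)[-1]))
        stop("duplicate sample ids in expression table")
    m <- as.matrix(d[, -1, drop = FALSE])
    if (!is.numeric(m)) {
        bad <- which(!vapply(d[-1], is.numeric, TRUE))[1]
        col <- colnames(d)[-1][bad]
        row <- genes[which(is.na(suppressWarnings(
            as.numeric(d[[bad + 1L]]))) & !is.na(d[[bad + 1L]]))[1]]
        stop("non-numeric expression cell at gene '", row,
             "', sample '", col, "'")
    }
    rownames(m) <- genes
    m
}

#' Write an expression matrix to TSV
#'
#' @param m numeric matrix (genes x samples).
#' @param path output path.
#' @export
writeExpression <- function(m, path) {
    d <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

## MAF variant-classification dialect -> internal classes
.VARIANT_CLASS_MAP <- c(
    Missense_Mutation = "missense",
    Nonsense_Mutation = "nonsense",
    Silent            = "silent",
    Frame_Shift_Del   = "frameshift",
    Frame_Shift_Ins   = "frameshift",
    Splice_Site       = "splice_site",
    missense = "missense", nonsense = "nonsense", silent = "silent",
    frameshift = "frameshift", splice_site = "splice_site")

#' Read somatic mutations from a MAF-dialect TSV
#'
#' Required columns: \code{gene}, \code{sample},
#' \code{variant_classification}, \code{ref}, \code{alt}; optional
#' \code{cds_pos} (1-based position within the coding frame) and
#' \code{context} (trinucleotide 5'-ref-3'). When \code{context} is
#' absent it is reconstructed from \code{cds_pos} against \code{cds}
#' (coding sequences carrying one flanking base on each side). Rows with
#' \code{ref == alt} are rejected; unknown classifications are bucketed
#' as \code{"other"}; both are counted in the drop/remap counters.
#'
#' @param path TSV file.
#' @param cds optional \link[Biostrings]{DNAStringSet} of flanked CDS.
#' @return a \linkS4class{MutationSet}.
#' @export
readMaf <- function(path, cds = NULL) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene", "sample", "variant_classification", "ref", "alt")
    miss <- setdiff(need, colnames(d))
    if (length(miss)) stop("MAF missing columns: ", paste(miss, collapse = ", "))
    nRefEqAlt <- sum(!is.na(d$ref) & !is.na(d$alt) & d$ref == d$alt)
    if (nRefEqAlt > 0) {
        warning(nRefEqAlt, " MAF rows with ref == alt dropped")
        d <- d[is.na(d$ref) | is.na(d$alt) | d$ref != d$alt, , drop = FALSE]
    }
    cls <- .VARIANT_CLASS_MAP[d$variant_classification]
    nUnknown <- sum(is.na(cls))
    if (nUnknown > 0)
        warning(nUnknown, " MAF rows with unknown variant class mapped to 'other'")
    cls[is.na(cls)] <- "other"
    r <- data.frame(gene = as.character(d$gene),
                    sample = as.character(d$sample),
                    class = unname(cls),
                    ref = as.character(d$ref),
                    alt = as.character(d$alt),
                    cds_pos = if ("cds_pos" %in% colnames(d))
                        as.integer(d$cds_pos) else NA_integer_,
                    context = if ("context" %in% colnames(d))
                        as.character(d$context) else NA_character_,
                    stringsAsFactors = FALSE)
    needCtx <- is.na(r$context) & !is.na(r$cds_pos) &
        r$class %in% c("missense", "nonsense", "silent")
    if (any(needCtx) && !is.null(cds))
        r$context[needCtx] <- contextFromCds(cds, r$gene[needCtx],
                                             r$cds_pos[needCtx])
    MutationSet(r, dropped = c(ref_eq_alt = as.integer(nRefEqAlt),
                               unknown_class = as.integer(nUnknown)))
}

#' Trinucleotide context from flanked coding sequences
#'
#' @param cds \link[Biostrings]{DNAStringSet}; each record is a CDS with a
#'   single flanking base on both ends, named by gene id.
#' @param gene,cdsPos parallel vectors: gene id and 1-based CDS position.
#' @return character vector of 3-base contexts (NA where unresolvable).
#' @export
contextFromCds <- function(cds, gene, cdsPos) {
    out <- rep(NA_character_, length(gene))
    idx <- match(gene, names(cds))
    ok <- !is.na(idx) & !is.na(cdsPos)
    w <- Biostrings::width(cds)[idx]
    ## seq position p..p+2 spans cds positions (p-1, p, p+1) via the flanks
    ok <- ok & cdsPos >= 1 & (cdsPos + 2) <= w
    if (any(ok))
        out[ok] <- as.character(Biostrings::subseq(cds[idx[ok]],
                                                   start = cdsPos[ok],
                                                   width = 3L))
    out
}

#' Write mutation records to a MAF-dialect TSV
#' @param muts a \linkS4class{MutationSet}
#' @param path output path
#' @export
writeMaf <- function(muts, path) {
    r <- mutationRecords(muts)
    inv <- c(missense = "Missense_Mutation", nonsense = "Nonsense_Mutation",
             silent = "Silent", frameshift = "Frame_Shift_Del",
             splice_site = "Splice_Site", other = "Other")
    d <- data.frame(gene = r$gene, sample = r$sample,
                    variant_classification = unname(inv[r$class]),
                    ref = r$ref, alt = r$alt, cds_pos = r$cds_pos,
                    context = r$context)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT (name, description, members). Member genes are
#' deduplicated within each set; sets whose name matches any keyword
#' (case-insensitive) are removed; sets with fewer than 2 members after
#' deduplication are excluded with a warning.
#'
#' @param path GMT file.
#' @param dropKeywords character vector of name keywords to remove
#'   (default \code{c("cancer", "disease")}); \code{NULL} disables the filter.
#' @return a \linkS4class{PathwayCollection}.
#' @export
readGmt <- function(path, dropKeywords = c("cancer", "disease")) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nm <- vapply(parts, `[[`, "", 1L)
    desc <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "", "")
    sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
    names(sets) <- nm
    if (length(dropKeywords)) {
        pat <- paste(dropKeywords, collapse = "|")
        keep <- !grepl(pat, nm, ignore.case = TRUE)
        sets <- sets[keep]; desc <- desc[keep]
    }
    small <- lengths(sets) < 2L
    if (any(small)) {
        warning(sum(small), " gene sets with < 2 members excluded")
        sets <- sets[!small]; desc <- desc[!small]
    }
    names(desc) <- names(sets)
    PathwayCollection(sets, desc)
}

#' Write gene sets to GMT
#' @param db a \linkS4class{PathwayCollection}
#' @param path output path
#' @export
writeGmt <- function(db, path) {
    sets <- pathwaySets(db)
    desc <- db@description
    lines <- vapply(names(sets), function(nm) {
        d <- if (nm %in% names(desc)) desc[[nm]] else "na"
        paste(c(nm, d, sets[[nm]]), collapse = "\t")
    }, "")
    writeLines(lines, path)
    invisible(path)
}

#' Read a clinical table from TSV
#'
#' @param path TSV with columns \code{sample_id}, \code{cancer_type},
#'   \code{treatment_class}, \code{time_days}, \code{event}.
#' @return validated data.frame.
#' @export
readClinical <- function(path) {
    validateClinical(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a clinical table to TSV
#' @param clinical data.frame
#' @param path output path
#' @export
writeClinical <- function(clinical, path) {
    utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read per-sample leukocyte fraction and tumor purity
#'
#' @param path TSV with columns \code{sample_id},
#'   \code{leukocyte_fraction}, \code{tumor_purity}.
#' @return data.frame.
#' @export
readFractions <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "leukocyte_fraction", "tumor_purity")
    miss <- setdiff(need, colnames(d))
    if (length(miss)) stop("fraction table missing: ", paste(miss, collapse = ", "))
    bad <- d$leukocyte_fraction < 0 | d$leukocyte_fraction > 1 |
        d$tumor_purity < 0 | d$tumor_purity > 1
    if (any(bad, na.rm = TRUE)) stop("fractions must lie in [0, 1]")
    d
}

#' Read a genotype dosage matrix plus coordinates
#'
#' @param genoPath TSV, samples in rows (first column \code{sample_id}),
#'   SNP dosages 0/1/2 in the remaining columns.
#' @param snpBedPath BED-like TSV: \code{chrom}, \code{pos}, \code{snp_id}.
#' @param geneBedPath BED-like TSV: \code{chrom}, \code{start}, \code{end},
#'   \code{gene_id}.
#' @return list with \code{dosage} (samples x SNPs integer matrix),
#'   \code{snps}, \code{genes} data.frames.
#' @export
readGenotypes <- function(genoPath, snpBedPath, geneBedPath) {
    g <- utils::read.delim(genoPath, check.names = FALSE,
                           stringsAsFactors = FALSE)
    m <- as.matrix(g[, -1, drop = FALSE])
    rownames(m) <- g[[1]]
    storage.mode(m) <- "integer"
    if (any(!m %in% c(0L, 1L, 2L)))
        stop("dosages must be 0, 1 or 2")
    snps <- utils::read.delim(snpBedPath, stringsAsFactors = FALSE)
    genes <- utils::read.delim(geneBedPath, stringsAsFactors = FALSE)
    list(dosage = m, snps = snps, genes = genes)
}
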