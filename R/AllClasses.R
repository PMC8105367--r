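#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

.COHORT_STAGES <- c("raw", "imputed", "filtered", "normalized",
                    "mutation_corrected", "fraction_corrected")

.TREATMENT_CLASSES <- c("immunotherapy", "non_immunotherapy")

#' Pan-cancer cohort container
#'
#' \code{IpmgCohort} extends \linkS4class{SummarizedExperiment}: one assay
#' named \code{"expr"} (genes x samples) plus per-sample clinical columns
#' (\code{cancer_type}, \code{treatment_class}, \code{time_days},
#' \code{event}) and, optionally, \code{leukocyte_fraction} and
#' \code{tumor_purity}. A stage tag in \code{metadata()} records which
#' preprocessing/correction steps the expression values have passed.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}
#' @export
setClass("IpmgCohort", contains = "SummarizedExperiment")

setValidity("IpmgCohort", function(object) {
    msg <- character(0)
    if (!"expr" %in% names(assays(object)))
        msg <- c(msg, "assay 'expr' is required")
    cd <- colData(object)
    need <- c("cancer_type", "treatment_class", "time_days", "event")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("missing clinical columns: ",
                             paste(miss, collapse = ", ")))
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be unique")
    if (!length(miss)) {
        if (!all(cd$treatment_class %in% .TREATMENT_CLASSES))
            msg <- c(msg, "treatment_class must be 'immunotherapy' or 'non_immunotherapy'")
        if (any(cd$time_days < 0, na.rm = TRUE))
            msg <- c(msg, "time_days must be non-negative")
        if (!all(cd$event %in% c(0L, 1L)))
            msg <- c(msg, "event must be 0 (alive/censored) or 1 (deceased)")
        if (any(is.na(cd$cancer_type)))
            msg <- c(msg, "every sample needs a cancer_type")
    }
    st <- metadata(object)$stage
    if (is.null(st) || !st %in% .COHORT_STAGES)
        msg <- c(msg, paste0("metadata stage must be one of: ",
                             paste(.COHORT_STAGES, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Construct an IpmgCohort
#'
#' @param expr numeric matrix, genes x samples, dimnames required.
#' @param clinical data.frame with columns \code{sample_id},
#'   \code{cancer_type}, \code{treatment_class}, \code{time_days},
#'   \code{event}; one row per sample in \code{expr}.
#' @param fractions optional data.frame with \code{sample_id},
#'   \code{leukocyte_fraction}, \code{tumor_purity}.
#' @param stage processing stage tag (default \code{"raw"}).
#' @return an \linkS4class{IpmgCohort}.
#' @export
IpmgCohort <- function(expr, clinical, fractions = NULL, stage = "raw") {
    stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
    clinical <- validateClinical(clinical)
    idx <- match(colnames(expr), clinical$sample_id)
    if (anyNA(idx))
        stop("samples missing from clinical table: ",
             paste(colnames(expr)[is.na(idx)][1:min(3, sum(is.na(idx)))],
                   collapse = ", "))
    cd <- clinical[idx, setdiff(colnames(clinical), "sample_id"), drop = FALSE]
    rownames(cd) <- colnames(expr)
    if (!is.null(fractions)) {
        fi <- match(colnames(expr), fractions$sample_id)
        cd$leukocyte_fraction <- fractions$leukocyte_fraction[fi]
        cd$tumor_purity <- fractions$tumor_purity[fi]
    }
    se <- SummarizedExperiment(assays = list(expr = expr),
                               colData = DataFrame(cd))
    metadata(se)$stage <- stage
    new("IpmgCohort", se)
}

#' Validate a clinical table
#'
#' Checks the contract of the per-sample clinical table: unique sample ids,
#' non-negative survival times, binary event codes, a cancer type for every
#' sample and a recognized treatment class.
#'
#' @param clinical data.frame.
#' @return the validated data.frame (character/integer columns coerced).
#' @export
validateClinical <- function(clinical) {
    need <- c("sample_id", "cancer_type", "treatment_class",
              "time_days", "event")
    miss <- setdiff(need, colnames(clinical))
    if (length(miss))
        stop("clinical table missing columns: ", paste(miss, collapse = ", "))
    if (anyDuplicated(clinical$sample_id))
        stop("duplicate sample ids in clinical table")
    if (any(is.na(clinical$cancer_type)))
        stop("every sample needs a cancer_type")
    if (!all(clinical$treatment_class %in% .TREATMENT_CLASSES))
        stop("treatment_class must be 'immunotherapy' or 'non_immunotherapy'")
    if (any(clinical$time_days < 0, na.rm = TRUE))
        stop("time_days must be non-negative")
    if (!all(clinical$event %in% c(0, 1)))
        stop("event must be coded 0/1")
    clinical$sample_id <- as.character(clinical$sample_id)
    clinical$cancer_type <- as.character(clinical$cancer_type)
    clinical$event <- as.integer(clinical$event)
    clinical
}

#' @describeIn IpmgCohort expression matrix accessor
#' @param x an \code{IpmgCohort}
#' @export
exprMatrix <- function(x) assay(x, "expr")

#' @describeIn IpmgCohort clinical table accessor (data.frame with
#'   \code{sample_id} column restored)
#' @export
clinicalTable <- function(x) {
    cd <- as.data.frame(colData(x))
    cd$sample_id <- colnames(x)
    rownames(cd) <- NULL
    cd[, c("sample_id", setdiff(colnames(cd), "sample_id")), drop = FALSE]
}

#' @describeIn IpmgCohort processing stage tag
#' @export
cohortStage <- function(x) metadata(x)$stage

#' @describeIn IpmgCohort set the processing stage tag
#' @param value new stage tag
#' @export
`cohortStage<-` <- function(x, value) {
    stopifnot(value %in% .COHORT_STAGES)
    metadata(x)$stage <- value
    x
}

#' @describeIn IpmgCohort replace the expression assay (stage must be
#'   updated by the caller)
#' @param m replacement matrix with identical dimnames
#' @export
setExprMatrix <- function(x, m, stage = cohortStage(x)) {
    stopifnot(identical(dim(m), dim(exprMatrix(x))) ||
              identical(colnames(m), colnames(x)))
    if (!identical(rownames(m), rownames(x))) {
        x <- x[rownames(m), ]
    }
    SummarizedExperiment::assay(x, "expr") <- m
    metadata(x)$stage <- stage
    x
}

setMethod("show", "IpmgCohort", function(object) {
    cd <- colData(object)
    cat("IpmgCohort:", nrow(object), "genes x", ncol(object), "samples\n")
    cat("  stage:", metadata(object)$stage, "\n")
    cat("  cancer types:", length(unique(cd$cancer_type)),
        "| immunotherapy:", sum(cd$treatment_class == "immunotherapy"),
        "| events:", sum(cd$event), "\n")
})

#' Somatic mutation records
#'
#' One row per mutation event: \code{gene}, \code{sample}, \code{class}
#' (one of missense, nonsense, silent, frameshift, splice_site, other),
#' \code{ref}, \code{alt}, \code{cds_pos} (1-based position within the
#' coding frame; NA if unknown) and \code{context} (trinucleotide
#' 5'-ref-3'; NA if not resolvable). Drop/remap counters from parsing are
#' kept alongside.
#'
#' @slot records data.frame of mutation events
#' @slot dropped named integer vector of parser counters
#' @export
setClass("MutationSet",
         representation(records = "data.frame", dropped = "integer"))

.MUTATION_CLASSES <- c("missense", "nonsense", "silent", "frameshift",
                       "splice_site", "other")

setValidity("MutationSet", function(object) {
    r <- object@records
    need <- c("gene", "sample", "class", "ref", "alt", "cds_pos", "context")
    if (!all(need %in% colnames(r)))
        return(paste0("records must have columns: ", paste(need, collapse = ", ")))
    if (!all(r$class %in% .MUTATION_CLASSES))
        return("unknown mutation class present")
    ok <- is.na(r$ref) | is.na(r$alt) | r$ref != r$alt
    if (!all(ok)) return("ref == alt records must be rejected at read time")
    TRUE
})

#' @describeIn MutationSet construct from a records data.frame
#' @param records data.frame of mutation events
#' @param dropped named integer vector of counters
#' @export
MutationSet <- function(records, dropped = c(ref_eq_alt = 0L, unknown_class = 0L)) {
    new("MutationSet", records = records, dropped = dropped)
}

#' @describeIn MutationSet records accessor
#' @param x a MutationSet
#' @export
mutationRecords <- function(x) x@records

#' @describeIn MutationSet parser counters accessor
#' @export
droppedCounts <- function(x) x@dropped

setMethod("show", "MutationSet", function(object) {
    r <- object@records
    cat("MutationSet:", nrow(r), "events |", length(unique(r$gene)),
        "genes |", length(unique(r$sample)), "samples\n")
    print(table(r$class))
    if (any(object@dropped > 0))
        cat("  dropped:", paste(names(object@dropped), object@dropped,
                                sep = "=", collapse = ", "), "\n")
})

#' Named gene sets (pathway collection)
#'
#' @slot sets named list of character vectors (deduplicated members)
#' @slot description named character vector of set descriptions
#' @export
setClass("PathwayCollection",
         representation(sets = "list", description = "character"))

setValidity("PathwayCollection", function(object) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
        return("sets must be uniquely named")
    if (any(vapply(object@sets, anyDuplicated, 1L) > 0))
        return("member genes must be deduplicated within a set")
    TRUE
})

#' @describeIn PathwayCollection construct from a named list
#' @param sets named list of character vectors
#' @param description optional named descriptions
#' @export
PathwayCollection <- function(sets, description = character(0)) {
    sets <- lapply(sets, unique)
    new("PathwayCollection", sets = sets, description = description)
}

#' @describeIn PathwayCollection gene set list accessor
#' @param x a PathwayCollection
#' @export
pathwaySets <- function(x) x@sets

setMethod("show", "PathwayCollection", function(object) {
    sz <- lengths(object@sets)
    cat("PathwayCollection:", length(object@sets), "sets; sizes",
        min(sz), "-", max(sz), "\n")
})

setMethod("length", "PathwayCollection", function(x) length(x@sets))

#' Per-cancer-type trinucleotide substitution-category frequencies
#'
#' Holds the background frequency of each of the 192 substitution
#' categories (12 ref>alt base pairs x 16 flanking contexts) in every
#' cancer type, plus the number of samples per type used for
#' sample-weighted pan-cancer pooling.
#'
#' @slot freq numeric matrix, 192 categories x cancer types; each column
#'   sums to 1
#' @slot nSamples named integer vector of per-type sample counts
#' @export
setClass("CategoryFrequencies",
         representation(freq = "matrix", nSamples = "integer"))

setValidity("CategoryFrequencies", function(object) {
    if (nrow(object@freq) != 192L)
        return("frequency matrix must have exactly 192 category rows")
    if (!identical(rownames(object@freq), categoryKeys()))
        return("category rows must follow categoryKeys() order")
    cs <- colSums(object@freq)
    if (any(abs(cs - 1) > 1e-9))
        return("per-type frequencies must sum to 1")
    if (any(object@freq < 0)) return("frequencies must be non-negative")
    if (!identical(sort(colnames(object@freq)), sort(names(object@nSamples))))
        return("nSamples must be named by the same cancer types")
    TRUE
})

#' @describeIn CategoryFrequencies frequency matrix accessor
#' @param x a CategoryFrequencies object
#' @export
categoryFreq <- function(x) x@freq

#' @describeIn CategoryFrequencies per-type sample counts
#' @export
typeSampleCounts <- function(x) x@nSamples

setMethod("show", "CategoryFrequencies", function(object) {
    cat("CategoryFrequencies: 192 categories x", ncol(object@freq),
        "cancer types\n")
})

#' Genome-wide survival-screen ranking
#'
#' Genes ordered by ascending one-tailed log-rank p-value under a stated
#' direction hypothesis; the ranking statistic is -log10(p). Ties are
#' broken by gene id so the ordering is deterministic.
#'
#' @slot table data.frame with columns \code{gene}, \code{p}, \code{stat}
#' @slot direction \code{"high_better"} or \code{"high_worse"}
#' @export
setClass("RankedGeneList",
         representation(table = "data.frame", direction = "character"))

setValidity("RankedGeneList", function(object) {
    t <- object@table
    if (!all(c("gene", "p", "stat") %in% colnames(t)))
        return("table needs columns gene, p, stat")
    if (is.unsorted(t$p)) return("table must be ordered by ascending p")
    if (!object@direction %in% c("high_better", "high_worse"))
        return("direction must be high_better or high_worse")
    TRUE
})

#' @describeIn RankedGeneList construct from per-gene p-values
#' @param p named numeric vector of one-tailed p-values
#' @param direction hypothesis direction label
#' @export
RankedGeneList <- function(p, direction) {
    ord <- order(p, names(p))
    t <- data.frame(gene = names(p)[ord], p = unname(p[ord]),
                    stat = -log10(pmax(unname(p[ord]), .Machine$double.xmin)))
    new("RankedGeneList", table = t, direction = direction)
}

#' @describeIn RankedGeneList ranking table accessor
#' @param x a RankedGeneList
#' @export
rankedTable <- function(x) x@table

#' @describeIn RankedGeneList named ranking statistic (-log10 p), in rank
#'   order, as fed to pre-ranked GSEA
#' @export
rankingStat <- function(x) {
    s <- x@table$stat
    names(s) <- x@table$gene
    s
}

setMethod("show", "RankedGeneList", function(object) {
    cat("RankedGeneList (", object@direction, "): ",
        nrow(object@table), " genes; top: ",
        paste(utils::head(object@table$gene, 3), collapse = ", "), "\n",
        sep = "")
})

setMethod("length", "RankedGeneList", function(x) nrow(x@table))
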