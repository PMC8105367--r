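## End-to-end orchestration: simulate (or load) -> preprocess -> both
## corrections -> survival screens -> enrichment + specificity ->
## selection -> prediction model -> stratification -> SNP association,
## with a manifest of every stage.

#' Run the full IPMG discovery pipeline
#'
#' Executes every stage in dependency order on a synthetic cohort (or a
#' pre-generated bundle) and returns the results plus a run manifest.
#' One master seed fans out to per-stage child seeds so stages are
#' individually reproducible; rerunning with the same configuration and
#' seed yields identical results and manifests (timing aside).
#'
#' @param config a \code{\link{runConfig}}.
#' @param spec a \code{\link{cohortSpec}} used to simulate the inputs
#'   (its seed is taken from \code{config$seed}), or \code{NULL} when
#'   \code{bundle} is supplied.
#' @param bundle optional pre-generated cohort bundle
#'   (\code{\link{generateCohort}} output).
#' @param gseaPerm gene permutations inside each GSEA (default 500).
#' @param rsfTrees,rsfNull random survival forest size and null refits.
#' @param panelSizes classifier feature-count sweep.
#' @param k stratification group count.
#' @return list with per-stage results and \code{manifest}.
#' @export
runPipeline <- function(config = runConfig(), spec = NULL, bundle = NULL,
                        gseaPerm = 500L, rsfTrees = 300L, rsfNull = 50L,
                        panelSizes = c(64, 50, 40, 30, 20, 10), k = 3L) {
    t0 <- proc.time()[["elapsed"]]
    manifest <- list(config_hash = .hashObject(config[names(config) != "seed"]),
                     seed = config$seed, stages = list())
    stamp <- function(name, ...) {
        info <- list(...)
        info$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 2)
        manifest$stages[[name]] <<- info
        .msg("stage ", name, " done")
    }
    seeds <- .childSeeds(config$seed, 10L)

    if (is.null(bundle)) {
        if (is.null(spec)) spec <- cohortSpec()
        spec$seed <- config$seed
        bundle <- generateCohort(spec)
    }
    ## pre-flight: every stage input must be present before anything runs
    needed <- c("cohort", "clinical", "muts", "cds", "db", "genotype",
                "truth")
    missing <- setdiff(needed, names(bundle))
    if (length(missing))
        stop("pipeline inputs missing: ", paste(missing, collapse = ", "))
    stamp("simulate", n_samples = ncol(bundle$cohort),
          n_genes = nrow(bundle$cohort),
          n_mutations = nrow(mutationRecords(bundle$muts)))

    norm <- preprocessExpression(bundle$cohort)
    stamp("preprocess", n_genes = nrow(norm))

    mut <- mutationCorrect(norm, bundle$muts, bundle$cds,
                           alpha = config$thresholds$gene_p)
    stamp("mutation_correction", n_sig_genes = length(mut$sigGenes))

    frac <- fractionCorrect(norm, cutoff = config$thresholds$corr_cutoff)
    stamp("fraction_correction", n_immune_genes = length(frac$genes))

    sspec <- survivalSpec(capYears = config$survivalCapYearsScreen)
    scrMut <- screenGenome(mut$cohort, sspec)
    scrFrac <- screenGenome(frac$cohort, sspec)
    stamp("survival_screen", n_genes = length(scrMut$high_better))

    spMut <- specificityTest(mut$cohort, bundle$db, sspec,
                             B = config$nSpecificityResamples,
                             nPerm = gseaPerm, seed = seeds[1])
    spFrac <- specificityTest(frac$cohort, bundle$db, sspec,
                              B = config$nSpecificityResamples,
                              nPerm = gseaPerm, seed = seeds[2])
    stamp("specificity",
          n_specific_mut = sum(spMut$table$specific),
          n_specific_frac = sum(spFrac$table$specific))

    ## ssGSEA features over the survival-related pathways, RSF ranking,
    ## intersection and gene picking
    clin <- clinicalTable(norm)
    immuno <- clin[clin$treatment_class == "immunotherapy", ]
    selOne <- function(corr, sp, seed) {
        paths <- sp$table$pathway[sp$table$specific]
        if (length(paths) < 2L)
            paths <- utils::head(sp$table$pathway[
                order(sp$table$null_percentile)], 5L)
        feats <- vapply(paths, function(pw)
            ssgseaScore(corr[, immuno$sample_id], pathwaySets(bundle$db)[[pw]]),
            numeric(nrow(immuno)))
        rownames(feats) <- immuno$sample_id
        rsfRank(feats, immuno, capYears = config$survivalCapYearsModel,
                nNull = rsfNull, nTrees = rsfTrees,
                alpha = config$thresholds$rsf_p, seed = seed)
    }
    selMut <- selOne(mut$cohort, spMut, seeds[3])
    selFrac <- selOne(frac$cohort, spFrac, seeds[4])
    picked <- intersectAndPickGenes(selMut, selFrac,
                                    scrMut$high_better, scrFrac$high_better,
                                    bundle$db,
                                    geneP = config$thresholds$gene_p)
    ipmgs <- picked$candidates
    stamp("selection", n_pathways = length(picked$pathways),
          n_candidates = length(ipmgs))

    ## downstream panel: the candidate IPMGs; when the intersection is
    ## empty at desk scale, fall back to the members of the top-ranked
    ## pathway so the model/stratification/SNP stages stay exercised
    panel <- if (length(ipmgs) >= 2L) ipmgs else {
        topPw <- selMut$feature[1]
        intersect(pathwaySets(bundle$db)[[topPw]], rownames(norm))
    }
    model <- trainEvalElasticNet(norm, panel,
                                 panelSizes = panelSizes,
                                 horizonYears = config$survivalCapYearsModel,
                                 nVal = config$nValidationSets,
                                 seed = seeds[5])
    stamp("model", best_auc = max(model$auc))
    groups <- groupByPanelScore(norm, panel, k = k)
    contrast <- groupSurvivalContrast(groups, clin,
                                      capYears = config$survivalCapYearsScreen,
                                      nResample = config$nClusterResamples,
                                      seed = seeds[6])
    stamp("stratification", immuno_p = contrast$immunoP,
          control_median_p = contrast$controlMedianP)

    panelBed <- bundle$genotype$genes[
        bundle$genotype$genes$gene_id %in% panel, , drop = FALSE]
    flt <- filterSnps(bundle$genotype$dosage, bundle$genotype$snps,
                      panelBed, mafMin = config$thresholds$maf)
    labels <- survivalStatusLabels(immuno, config$survivalCapYearsModel)
    snpRes <- if (ncol(flt$dosage) > 0L)
        associateSnps(flt$dosage, labels, nShuffle = 1000L,
                      seed = seeds[7])
    else NULL
    eqtl <- if (!is.null(snpRes) && any(snpRes$significant)) {
        sig <- snpRes$snp_id[snpRes$significant]
        pairs <- data.frame(snp_id = sig,
                            gene_id = flt$snps$nearest_gene[
                                match(sig, flt$snps$snp_id)])
        snpExpressionCorrelation(bundle$genotype$dosage, norm, pairs,
                                 seed = seeds[8])
    } else NULL
    stamp("snp",
          n_filtered = if (is.null(snpRes)) 0L else nrow(snpRes),
          n_significant = if (is.null(snpRes)) 0L else
              sum(snpRes$significant),
          n_eqtl = if (is.null(eqtl)) 0L else sum(eqtl$eqtl))

    list(bundle = bundle, normalized = norm, mutation = mut,
         fraction = frac, screens = list(mut = scrMut, frac = scrFrac),
         specificity = list(mut = spMut, frac = spFrac),
         selection = list(mut = selMut, frac = selFrac, picked = picked),
         ipmgs = ipmgs, panel = panel, model = model, groups = groups,
         contrast = contrast, snp = list(assoc = snpRes, eqtl = eqtl),
         manifest = manifest)
}

#' Strip timing from a manifest (for determinism comparisons)
#' @param manifest a pipeline manifest
#' @return the manifest with elapsed-time fields removed
#' @export
manifestFingerprint <- function(manifest) {
    manifest$stages <- lapply(manifest$stages, function(s) {
        s$elapsed_s <- NULL
        s
    })
    manifest
}
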