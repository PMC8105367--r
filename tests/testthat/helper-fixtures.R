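# Shared in-code fixtures. Everything is built programmatically; the
# synthetic cohort generator provides the large inputs.

# small deterministic cohort matrix + clinical table
toyCohort <- function(nGenes = 8, nSamples = 10, seed = 42,
                      nTypes = 2, immFrac = 0.5) {
    set.seed(seed)
    genes <- sprintf("g%02d", seq_len(nGenes))
    samples <- sprintf("s%02d", seq_len(nSamples))
    m <- matrix(round(rexp(nGenes * nSamples, 0.2), 3), nGenes, nSamples,
                dimnames = list(genes, samples))
    clin <- data.frame(
        sample_id = samples,
        cancer_type = rep(sprintf("T%d", seq_len(nTypes)),
                          length.out = nSamples),
        treatment_class = rep(c("immunotherapy", "non_immunotherapy"),
                              times = round(c(immFrac, 1 - immFrac) *
                                            nSamples))[seq_len(nSamples)],
        time_days = sample(50:1500, nSamples),
        event = rbinom(nSamples, 1, 0.6))
    IpmgCohort(m, clin)
}

# uniform substitution-category frequencies for one pseudo cancer type
uniformFreqs <- function(type = "toy", nSamples = 10L) {
    f <- matrix(1 / 192, 192, 1,
                dimnames = list(categoryKeys(), type))
    new("CategoryFrequencies", freq = f,
        nSamples = stats::setNames(as.integer(nSamples), type))
}

# brute-force GSEA running sum (independent oracle)
bruteForceES <- function(stat, setIdx, weight = 1) {
    N <- length(stat)
    hit <- seq_len(N) %in% setIdx
    w <- abs(stat)^weight
    tot <- sum(w[hit])
    inc <- if (tot > 0) ifelse(hit, w / tot, 0) else
        ifelse(hit, 1 / sum(hit), 0)
    dec <- ifelse(hit, 0, 1 / (N - sum(hit)))
    run <- cumsum(inc - dec)
    ## magnitude ties (within numerical precision) resolve positive
    if (max(run) + 1e-12 >= -min(run)) max(run) else min(run)
}

# brute-force codon background oracle: enumerate every (codon,
# substitution) pair of a flanked CDS string against a frequency vector
bruteForceBackground <- function(flankedSeq, freqByKey) {
    gc0 <- Biostrings::GENETIC_CODE
    chars <- strsplit(flankedSeq, "")[[1]]
    L <- length(chars)
    nc <- (L - 2) %/% 3
    cods <- vapply(seq_len(nc), function(i)
        paste(chars[(i - 1) * 3 + 2:4], collapse = ""), "")
    if (gc0[cods[nc]] == "*") {
        cods <- cods[-nc]; nc <- nc - 1
    }
    n_i <- numeric(nc); s_i <- numeric(nc)
    for (ci in seq_len(nc)) {
        for (pos in 1:3) {
            p <- (ci - 1) * 3 + pos          # cds position
            ref <- chars[p + 1]
            for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
                key <- paste0(chars[p], "[", ref, ">", alt, "]",
                              chars[p + 2])
                newcod <- cods[ci]
                substr(newcod, pos, pos) <- alt
                if (gc0[newcod] == gc0[cods[ci]])
                    s_i[ci] <- s_i[ci] + freqByKey[key]
                else n_i[ci] <- n_i[ci] + freqByKey[key]
            }
        }
    }
    list(n_i = n_i, s_i = s_i, N = sum(n_i), S = sum(s_i))
}
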