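## Internal numerics shared across stages.

.DAYS_PER_YEAR <- 365

## counters used to audit how often expensive cores are invoked
.ipmgCounters <- new.env(parent = emptyenv())

.countHit <- function(name) {
    cur <- get0(name, envir = .ipmgCounters, ifnotfound = 0L)
    assign(name, cur + 1L, envir = .ipmgCounters)
    invisible(NULL)
}

.resetCounters <- function() {
    rm(list = ls(.ipmgCounters), envir = .ipmgCounters)
    invisible(NULL)
}

.getCounter <- function(name) get0(name, envir = .ipmgCounters, ifnotfound = 0L)

## Column-wise cumulative sums via one flat cumsum (O(rows x cols)).
.colCumsum <- function(M) {
    raw <- matrix(cumsum(M), nrow(M), ncol(M))
    if (ncol(M) > 1L)
        raw <- sweep(raw, 2L, c(0, raw[nrow(M), -ncol(M)]))
    raw
}

.revColCumsum <- function(M) {
    n <- nrow(M)
    .colCumsum(M[n:1, , drop = FALSE])[n:1, , drop = FALSE]
}

## Vectorized two-group log-rank over many group assignments at once.
##
## time, event: length-n survival data. incl, high: n x G indicator
## matrices; column g defines one test comparing samples with high[,g]==1
## against incl[,g]==1 & high[,g]==0 (rows outside incl are ignored).
## Returns z = (observed - expected deaths in the high group)/sqrt(V):
## positive z means the high group died more than expected.
.logrankVec <- function(time, event, incl, high) {
    stopifnot(nrow(incl) == length(time), identical(dim(incl), dim(high)))
    storage.mode(incl) <- "logical"
    storage.mode(high) <- "logical"
    ord <- order(time)
    time <- time[ord]
    grp <- cumsum(c(TRUE, diff(time) > 0)) - 1L     # 0-based tied groups
    sw <- .logrankSweep(grp, max(grp) + 1L, as.integer(event[ord]),
                        incl[ord, , drop = FALSE],
                        high[ord, , drop = FALSE])
    U <- sw$U; V <- sw$V
    z <- ifelse(V > 0, U / sqrt(V), NA_real_)
    list(z = z, U = U, V = V,
         chisq = ifelse(V > 0, U^2 / V, NA_real_))
}

## One-tailed p-values from a log-rank z; direction is the hypothesis.
## V == 0 (no usable events) yields p = 1 in both directions.
.logrankOneTailed <- function(z, direction) {
    p <- switch(direction,
                high_worse  = stats::pnorm(z, lower.tail = FALSE),
                high_better = stats::pnorm(z, lower.tail = TRUE),
                stop("direction must be high_better or high_worse"))
    p[is.na(p)] <- 1
    p
}

## Rank-based AUC (Wilcoxon statistic); labels coded 0/1.
.aucScore <- function(scores, labels) {
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    if (n1 == 0L || n0 == 0L) return(NA_real_)
    r <- rank(scores)
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Monte-Carlo p with the +1/+1 estimator (never 0).
.mcPvalue <- function(nullGeq, B) (1 + nullGeq) / (1 + B)

## Derive independent child seeds from one master seed (kept < 2^31).
.childSeeds <- function(seed, n) {
    set.seed(seed)
    sample.int(.Machine$integer.max - 1L, n)
}

## md5 of an object's canonical JSON; used for config hashing.
.hashObject <- function(x) {
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                force = TRUE), f)
    unname(tools::md5sum(f))
}

.msg <- function(...) message("[IPMGfinder] ", ...)
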