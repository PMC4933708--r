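#' Median-of-ratios size factors
#'
#' Per-sample scale factors s_j = median over features of K_ij / g_i, where
#' g_i is the geometric mean of feature i across samples and the median runs
#' over features positive in every sample; factors are then rescaled to unit
#' geometric mean so that normalized counts stay on the scale of the raw
#' library.
#'
#' @param x a [MatExperiment-class] or counts matrix.
#' @return named numeric vector of positive size factors (geometric mean 1).
#' @examples
#' m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
#' sizeFactorsMedianOfRatios(m) # 1/sqrt(2), sqrt(2)
#' @export
sizeFactorsMedianOfRatios <- function(x) {
    m <- .countsOf(x)
    allPos <- rowSums(m > 0) == ncol(m)
    if (!any(allPos)) {
        stop(
            "no feature has positive counts in every sample; ",
            "consider a pseudo-reference fallback",
            call. = FALSE
        )
    }
    logGeo <- rowMeans(log(m[allPos, , drop = FALSE]))
    sf <- apply(log(m[allPos, , drop = FALSE]), 2, function(col) {
        exp(median(col - logGeo))
    })
    sf <- sf / exp(mean(log(sf)))
    setNames(sf, colnames(m))
}

#' Method-of-moments dispersion estimates
#'
#' Per-feature negative-binomial dispersion alpha estimated from size-factor
#' normalized counts: alpha = max((v - m)/m^2, floor), with m the grand mean
#' of the normalized counts and v the within-group pooled variance (so that
#' real group differences do not inflate the dispersion). No shrinkage is
#' applied; at small n these raw estimates are noisy (see the package
#' vignette).
#'
#' @param x a [MatExperiment-class] or counts matrix.
#' @param groups per-sample labels (>= 2 samples per group); taken from `x`
#'   when it is a `MatExperiment`.
#' @param sf size factors (default [sizeFactorsMedianOfRatios()]).
#' @param floor lower bound for the estimate (default 1e-8).
#' @return named numeric vector of dispersions, one per feature.
#' @export
estimateDispersionsMoM <- function(x, groups = NULL, sf = NULL, floor = 1e-8) {
    m <- .countsOf(x)
    groups <- .groupsOf(x, groups)
    if (any(table(groups) < 2)) {
        stop("every group needs >= 2 samples", call. = FALSE)
    }
    if (is.null(sf)) sf <- sizeFactorsMedianOfRatios(m)
    norm <- sweep(m, 2, sf, "/")
    grandMean <- rowMeans(norm)
    num <- 0
    df <- 0
    for (g in unique(groups)) {
        i <- groups == g
        ng <- sum(i)
        num <- num + apply(norm[, i, drop = FALSE], 1, var) * (ng - 1)
        df <- df + (ng - 1)
    }
    pooledVar <- num / df
    alpha <- ifelse(
        grandMean > 0,
        (pooledVar - grandMean) / grandMean^2,
        floor
    )
    setNames(pmax(alpha, floor), rownames(m))
}

# Newton fit of one NB group mean on the log scale with fixed dispersion and
# size-factor offsets. Returns the ML log-mean and the observed information.
.nbGroupFit <- function(k, s, alpha) {
    q0 <- mean(k / s)
    if (q0 == 0) {
        # all-zero group: 0.5 pseudo-count on the normalized group mean
        mu <- s * 0.5
        return(c(
            beta = log(0.5),
            info = sum(mu / (1 + alpha * mu)^2)
        ))
    }
    beta <- log(q0)
    for (it in seq_len(100L)) {
        mu <- s * exp(beta)
        score <- sum((k - mu) / (1 + alpha * mu))
        info <- sum(mu * (1 + alpha * k) / (1 + alpha * mu)^2)
        step <- score / info
        step <- max(min(step, 5), -5)
        beta <- beta + step
        if (abs(step) < 1e-12) break
    }
    mu <- s * exp(beta)
    c(beta = beta, info = sum(mu * (1 + alpha * k) / (1 + alpha * mu)^2))
}

#' Negative-binomial Wald test for two-group differential abundance
#'
#' Per feature, group means are fitted by maximum likelihood under a
#' negative-binomial model with fixed per-feature dispersion and per-sample
#' size-factor offsets. The reported log2 fold change is
#' log2(mean_focal / mean_other) (positive = enriched in the focal group),
#' its standard error comes from the inverse observed information mapped to
#' the log2 scale, wald = log2fc/se, and p is the two-sided standard-normal
#' tail. When one group is all-zero a 0.5 pseudo-count on its normalized
#' group mean keeps the fold change finite; features all-zero in both groups
#' are emitted with log2fc = 0 and p = 1. Benjamini-Hochberg adjusted
#' p-values are attached via [bhAdjust()].
#'
#' This is a deliberately transparent NB Wald stage: no empirical-Bayes
#' dispersion shrinkage, fold-change shrinkage, independent filtering or
#' outlier handling.
#'
#' @param x a [MatExperiment-class] or counts matrix (raw counts).
#' @param groups per-sample labels; exactly two groups, each >= 2 samples.
#' @param focalGroup the group whose enrichment gets positive log2fc
#'   (default: first group label in order of appearance).
#' @param sf size factors (default [sizeFactorsMedianOfRatios()]).
#' @param dispersions per-feature dispersions (default
#'   [estimateDispersionsMoM()]).
#' @return data.frame with columns `feature`, `baseMean`, `log2fc`, `se`,
#'   `wald`, `p`, `padj`, `enrichedIn` (all `"none"`; set by
#'   [enrichmentFilter()]); the focal group is recorded in
#'   `attr(, "focalGroup")`.
#' @export
nbWaldTest <- function(x, groups = NULL, focalGroup = NULL, sf = NULL,
                       dispersions = NULL) {
    m <- .countsOf(x)
    groups <- .groupsOf(x, groups)
    lev <- unique(groups)
    if (length(lev) != 2L) {
        stop("exactly two groups are required", call. = FALSE)
    }
    if (any(table(groups) < 2)) {
        stop("every group needs >= 2 samples", call. = FALSE)
    }
    if (is.null(focalGroup)) focalGroup <- lev[1]
    if (!focalGroup %in% lev) {
        stop("'focalGroup' is not one of the group labels", call. = FALSE)
    }
    otherGroup <- setdiff(lev, focalGroup)
    if (is.null(sf)) sf <- sizeFactorsMedianOfRatios(m)
    if (is.null(dispersions)) {
        dispersions <- estimateDispersionsMoM(m, groups, sf)
    }
    dispersions <- rep_len(dispersions, nrow(m))

    iF <- groups == focalGroup
    iO <- groups == otherGroup
    norm <- sweep(m, 2, sf, "/")
    baseMean <- rowMeans(norm)

    nfeat <- nrow(m)
    log2fc <- numeric(nfeat)
    se <- rep(NA_real_, nfeat)
    wald <- rep(NA_real_, nfeat)
    p <- rep(1, nfeat)
    ln2 <- log(2)
    for (i in seq_len(nfeat)) {
        k <- m[i, ]
        if (all(k == 0)) next
        a <- max(dispersions[i], 0)
        fF <- .nbGroupFit(k[iF], sf[iF], a)
        fO <- .nbGroupFit(k[iO], sf[iO], a)
        log2fc[i] <- (fF["beta"] - fO["beta"]) / ln2
        se[i] <- sqrt(1 / fF["info"] + 1 / fO["info"]) / ln2
        wald[i] <- log2fc[i] / se[i]
        p[i] <- 2 * pnorm(-abs(wald[i]))
    }
    res <- data.frame(
        feature = rownames(m), baseMean = baseMean,
        log2fc = log2fc, se = se, wald = wald, p = p,
        padj = bhAdjust(p), enrichedIn = "none",
        stringsAsFactors = FALSE, row.names = NULL
    )
    attr(res, "focalGroup") <- focalGroup
    attr(res, "otherGroup") <- otherGroup
    res
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (via [stats::p.adjust()]), with input
#' validation: padj_(i) = min over j >= i of (m/j) p_(j), capped at 1, in the
#' original order.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.04))
#' @export
bhAdjust <- function(p) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
        stop("p-values must lie in [0, 1]", call. = FALSE)
    }
    p.adjust(p, method = "BH")
}

#' Enrichment filter on differential-abundance records
#'
#' Keeps records that satisfy all of: padj < alpha, |log2fc| strictly greater
#' than `minAbsLog2fc` (i.e. more than a twofold difference at the default),
#' and baseMean strictly greater than `minBaseMean`; annotates the direction
#' of enrichment (focal when log2fc > 0, other when < 0).
#'
#' @param records data.frame from [nbWaldTest()] (columns `padj`, `log2fc`,
#'   `baseMean`).
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @param minAbsLog2fc strict lower bound on |log2fc| (default 1).
#' @param minBaseMean strict lower bound on baseMean (default 2000).
#' @return the retained records with `enrichedIn` set to `"focal"` or
#'   `"other"`; a subset of the input (idempotent).
#' @export
enrichmentFilter <- function(records, alpha = 0.05, minAbsLog2fc = 1,
                             minBaseMean = 2000) {
    need <- c("padj", "log2fc", "baseMean")
    if (!all(need %in% names(records))) {
        stop(
            "records lack column(s): ",
            paste(setdiff(need, names(records)), collapse = ", "),
            call. = FALSE
        )
    }
    keep <- !is.na(records$padj) & records$padj < alpha &
        abs(records$log2fc) > minAbsLog2fc &
        records$baseMean > minBaseMean
    out <- records[keep, , drop = FALSE]
    out$enrichedIn <- ifelse(out$log2fc > 0, "focal", "other")
    out
}

#' Full differential-abundance stage
#'
#' Convenience wrapper running size factors, dispersion estimation, the NB
#' Wald test with BH adjustment, and the enrichment filter in one call.
#'
#' @inheritParams nbWaldTest
#' @inheritParams enrichmentFilter
#' @param dispersions optional per-feature dispersions; estimated by
#'   [estimateDispersionsMoM()] when `NULL`.
#' @return list with `results` (all records), `filtered` (enrichment-filter
#'   survivors), `sizeFactors`, `dispersions`.
#' @export
diffAbundance <- function(x, groups = NULL, focalGroup = NULL,
                          dispersions = NULL,
                          alpha = 0.05, minAbsLog2fc = 1, minBaseMean = 2000) {
    m <- .countsOf(x)
    groups <- .groupsOf(x, groups)
    sf <- sizeFactorsMedianOfRatios(m)
    if (is.null(dispersions)) {
        dispersions <- estimateDispersionsMoM(m, groups, sf)
    }
    res <- nbWaldTest(m, groups, focalGroup, sf, dispersions)
    flt <- enrichmentFilter(res, alpha, minAbsLog2fc, minBaseMean)
    list(
        results = res, filtered = flt,
        sizeFactors = sf, dispersions = dispersions
    )
}
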