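#' Normalize samples to a common sequencing depth
#'
#' Deterministic total-sum scaling (default): every sample is rescaled so its
#' column total equals `depth`. Alternatively `method = "rarefy"` randomly
#' subsamples each column without replacement to exactly `depth` reads
#' (requires integer counts and `depth` no larger than any sample total;
#' seeded for reproducibility).
#'
#' @param x a [MatExperiment-class] or counts matrix.
#' @param depth target per-sample total (default 221168 sequences/sample).
#' @param method `"scale"` (deterministic) or `"rarefy"` (random subsample).
#' @param seed integer seed used by `"rarefy"`.
#' @return same container class as `x`, with normalized counts.
#' @examples
#' m <- matrix(c(2, 4, 6, 3, 0, 9), 3, 2, dimnames = list(1:3, c("a", "b")))
#' normalizeDepth(m, depth = 12)
#' @export
normalizeDepth <- function(x, depth = 221168, method = c("scale", "rarefy"),
                           seed = NULL) {
    method <- match.arg(method)
    m <- .countsOf(x)
    tot <- colSums(m)
    if (any(tot == 0)) {
        stop(
            "sample(s) with zero total counts: ",
            paste(colnames(m)[tot == 0], collapse = ", "),
            call. = FALSE
        )
    }
    if (method == "scale") {
        norm <- sweep(m, 2, depth / tot, "*")
    } else {
        if (any(m != round(m))) {
            stop("'rarefy' requires integer counts", call. = FALSE)
        }
        if (any(tot < depth)) {
            stop("'rarefy' requires depth <= every sample total", call. = FALSE)
        }
        if (!is.null(seed)) set.seed(seed)
        # vegan advises against large minimum counts; harmless here
        norm <- t(suppressWarnings(vegan::rrarefy(t(m), sample = depth)))
        dimnames(norm) <- dimnames(m)
    }
    if (is(x, "MatExperiment")) MatExperiment(norm, groupLabels(x)) else norm
}

#' Per-sample relative abundances
#'
#' @param x a [MatExperiment-class] or counts matrix.
#' @return matrix of proportions; each column sums to 1.
#' @export
relativeAbundance <- function(x) {
    m <- .countsOf(x)
    tot <- colSums(m)
    if (any(tot == 0)) {
        stop(
            "sample(s) with zero total counts: ",
            paste(colnames(m)[tot == 0], collapse = ", "),
            call. = FALSE
        )
    }
    sweep(m, 2, tot, "/")
}

#' Retain features above a relative-abundance cutoff
#'
#' Keeps features whose mean (or maximum) per-sample proportion strictly
#' exceeds `minFrac`; the conventional display cutoff is > 0.5%.
#'
#' @param proportions matrix of per-sample proportions
#'   (see [relativeAbundance()]), or a counts container which is converted.
#' @param minFrac strict lower bound on the summary proportion (default 0.005).
#' @param stat `"mean"` or `"max"` summary across samples.
#' @return the retained rows of `proportions` (possibly 0-row).
#' @export
abundanceFilter <- function(proportions, minFrac = 0.005,
                            stat = c("mean", "max")) {
    stat <- match.arg(stat)
    p <- .countsOf(proportions)
    s <- if (stat == "mean") rowMeans(p) else apply(p, 1, max)
    p[s > minFrac, , drop = FALSE]
}

#' Analytic rarefaction curves
#'
#' Expected number of observed features in a random subsample of n reads,
#' E\[S_n\] = sum_i (1 - C(N - N_i, n)/C(N, n)), evaluated per sample at each
#' requested depth (the exact hypergeometric expectation, via
#' [vegan::rarefy()]).
#'
#' @param x a [MatExperiment-class] or integer counts matrix.
#' @param depths integer subsample depths; each must not exceed any chosen
#'   sample's total.
#' @return long data.frame with columns `sample`, `depth`,
#'   `expectedFeatures`.
#' @examples
#' m <- matrix(c(5, 5), 2, 1, dimnames = list(c("f1", "f2"), "s1"))
#' rarefactionCurve(m, depths = c(1, 2, 10))
#' @export
rarefactionCurve <- function(x, depths) {
    m <- .countsOf(x)
    if (any(m != round(m)) || any(m < 0)) {
        stop("rarefaction requires non-negative integer counts", call. = FALSE)
    }
    depths <- as.integer(depths)
    if (any(depths < 1)) stop("depths must be >= 1", call. = FALSE)
    tot <- colSums(m)
    bad <- depths > min(tot)
    if (any(bad)) {
        stop(
            "depth(s) exceed the smallest sample total (", min(tot), "): ",
            paste(depths[bad], collapse = ", "),
            call. = FALSE
        )
    }
    out <- lapply(seq_len(ncol(m)), function(j) {
        data.frame(
            sample = colnames(m)[j],
            depth = depths,
            # suppress vegan's advisory about non-singleton minimum counts;
            # the hypergeometric expectation is exact for any integer table
            expectedFeatures = as.numeric(suppressWarnings(
                vegan::rarefy(t(m[, j, drop = FALSE]), sample = depths)
            ))
        )
    })
    do.call(rbind, out)
}

#' Bray-Curtis dissimilarity matrix between samples
#'
#' BC(u, v) = sum |u_i - v_i| / sum (u_i + v_i) on the per-sample abundance
#' vectors (columns). Computed with [vegan::vegdist()].
#'
#' @param x a [MatExperiment-class] or non-negative matrix (features x
#'   samples).
#' @return symmetric numeric matrix with zero diagonal, entries in \[0, 1\],
#'   sample ids as dimnames.
#' @examples
#' m <- cbind(u = c(1, 2), v = c(3, 0))
#' brayCurtis(m) # 4/6
#' @export
brayCurtis <- function(x) {
    m <- .countsOf(x)
    if (any(m < 0)) stop("abundances must be non-negative", call. = FALSE)
    tot <- colSums(m)
    if (any(tot == 0)) {
        stop(
            "Bray-Curtis is undefined for all-zero sample(s): ",
            paste(colnames(m)[tot == 0], collapse = ", "),
            call. = FALSE
        )
    }
    as.matrix(vegan::vegdist(t(m), method = "bray"))
}

#' Principal coordinates analysis of a distance matrix
#'
#' Gower double-centering of -d^2/2 followed by eigendecomposition (via
#' [stats::cmdscale()]). Coordinates are returned for positive-eigenvalue
#' axes only, scaled by the square roots of the eigenvalues; negative
#' eigenvalues are retained and reported but excluded from the variance
#' denominator (no Lingoes/Cailliez correction).
#'
#' @param d symmetric distance matrix (or `dist`).
#' @return list with `coordinates` (samples x axes, ordered by decreasing
#'   eigenvalue), `eigenvalues` (all), and `varianceExplained` (fractions of
#'   the positive-eigenvalue sum, one per returned axis).
#' @export
pcoaOrdination <- function(d) {
    d <- as.matrix(d)
    n <- nrow(d)
    if (n < 2L) stop("at least two samples are required", call. = FALSE)
    fit <- suppressWarnings(
        cmdscale(as.dist(d), k = n - 1L, eig = TRUE)
    )
    eig <- fit$eig
    tol <- max(abs(eig)) * 1e-10
    npos <- sum(eig > tol)
    coords <- fit$points[, seq_len(min(npos, ncol(fit$points))), drop = FALSE]
    colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
    list(
        coordinates = coords,
        eigenvalues = eig,
        varianceExplained = eig[seq_len(ncol(coords))] / sum(eig[eig > tol])
    )
}

#' UPGMA (average-linkage) clustering of a distance matrix
#'
#' Agglomerative average-linkage clustering; in the returned ultrametric tree
#' each internal node sits at half the merge distance, so cophenetic
#' tip-to-tip distances reproduce the merge heights.
#'
#' @param d symmetric distance matrix (or `dist`) over >= 2 samples.
#' @return an [ape::phylo] rooted ultrametric tree (serialize with
#'   [ape::write.tree()]).
#' @export
upgmaTree <- function(d) {
    d <- as.matrix(d)
    if (nrow(d) < 2L) stop("at least two samples are required", call. = FALSE)
    hc <- hclust(as.dist(d), method = "average")
    ape::as.phylo(hc)
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: with N samples and a
#' groups, SS_total = sum_{i<j} d_ij^2 / N, SS_within is the analogous
#' within-group sum with per-group divisors, pseudo-F =
#' (SS_between/(a-1)) / (SS_within/(N-a)) and R^2 = SS_between/SS_total.
#' Significance is assessed by permuting group labels; p = (1 + #\{F_perm >=
#' F_obs\}) / (1 + nPerm), so p has resolution exactly 1/(nPerm + 1). When
#' all distances are zero the partition is degenerate and R^2 = 0, p = 1 by
#' convention.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param groups per-sample labels (>= 2 groups, each >= 1 sample).
#' @param nPerm number of label permutations (default 999).
#' @param seed optional integer seed for the permutations.
#' @return list with `f`, `r2`, `p`, `nPerm`, `seed` (class
#'   `"permanova_result"`).
#' @export
permanovaTest <- function(d, groups, nPerm = 999, seed = NULL) {
    d <- as.matrix(d)
    n <- nrow(d)
    groups <- as.character(groups)
    if (length(groups) != n) {
        stop("'groups' must have one label per sample", call. = FALSE)
    }
    a <- length(unique(groups))
    if (a < 2L) stop("at least two groups are required", call. = FALSE)
    if (nPerm < 1L) stop("'nPerm' must be >= 1", call. = FALSE)
    if (nPerm < 19L) {
        warning("nPerm < 19: p-value resolution is coarser than 0.05")
    }

    d2 <- d^2
    ssTotal <- sum(d2) / (2 * n)
    ssWithin <- function(lab) {
        s <- 0
        for (g in unique(lab)) {
            i <- lab == g
            s <- s + sum(d2[i, i]) / (2 * sum(i))
        }
        s
    }
    if (ssTotal <= .Machine$double.eps) {
        res <- list(
            f = NaN, r2 = 0, p = 1, nPerm = as.integer(nPerm),
            seed = seed
        )
        class(res) <- "permanova_result"
        return(res)
    }
    fStat <- function(lab) {
        ssw <- ssWithin(lab)
        ((ssTotal - ssw) / (a - 1)) / (ssw / (n - a))
    }
    fObs <- fStat(groups)
    if (!is.null(seed)) set.seed(seed)
    fPerm <- vapply(
        seq_len(nPerm),
        function(i) fStat(sample(groups)), numeric(1)
    )
    res <- list(
        f = fObs,
        r2 = (ssTotal - ssWithin(groups)) / ssTotal,
        p = (1 + sum(fPerm >= fObs)) / (1 + nPerm),
        nPerm = as.integer(nPerm),
        seed = seed
    )
    class(res) <- "permanova_result"
    res
}

#' @export
print.permanova_result <- function(x, ...) {
    cat("One-way PERMANOVA\n")
    cat(sprintf(
        "  pseudo-F = %.4g, R2 = %.4f, p = %.4g (%d permutations)\n",
        x$f, x$r2, x$p, x$nPerm
    ))
    invisible(x)
}
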