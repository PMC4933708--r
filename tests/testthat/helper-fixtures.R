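# Shared fixture builders; everything is generated in code.

# small labelled count matrix
toyCounts <- function(nf = 6, ns = 4, seed = 11, lambda = 30) {
    set.seed(seed)
    m <- matrix(rpois(nf * ns, lambda), nf, ns)
    dimnames(m) <- list(paste0("f", seq_len(nf)), paste0("s", seq_len(ns)))
    m
}

toyExperiment <- function(nf = 6, ns = 4, seed = 11) {
    MatExperiment(toyCounts(nf, ns, seed), rep(c("thrombolite", "sediment"),
        each = ns / 2
    ))
}

# Euclidean distance matrix of random points (embeddable by construction)
euclideanDistanceFixture <- function(n = 4, dim = 2, seed = 5) {
    set.seed(seed)
    pts <- matrix(rnorm(n * dim), n, dim)
    rownames(pts) <- paste0("s", seq_len(n))
    list(points = pts, d = as.matrix(dist(pts)))
}

# Independent speciation oracle: direct mass-action evaluation with
# independently retyped temperature polynomials for the dissociation
# constants (dilute-solution parameterization).
oracleSpeciation <- function(ph, tc) {
    tk <- tc + 273.15
    k1 <- 10^(-356.3094 - 0.06091964 * tk + 21834.37 / tk +
        126.8339 * log10(tk) - 1684915 / tk^2)
    k2 <- 10^(-107.8871 - 0.03252849 * tk + 5151.79 / tk +
        38.92561 * log10(tk) - 563713.9 / tk^2)
    ah <- 10^(-ph)
    co2 <- 1
    hco3 <- k1 * co2 / ah
    co3 <- k2 * hco3 / ah
    tot <- co2 + hco3 + co3
    c(co2, hco3, co3) / tot
}

# Exhaustive-enumeration PERMANOVA oracle for tiny balanced designs:
# p = fraction of all distinct labelings (including the observed one) whose
# pseudo-F is >= the observed pseudo-F.
oraclePermanovaExact <- function(d, groups) {
    d2 <- as.matrix(d)^2
    n <- nrow(d2)
    a <- length(unique(groups))
    fOf <- function(lab) {
        ssTot <- sum(d2) / (2 * n)
        ssw <- 0
        for (g in unique(lab)) {
            i <- lab == g
            ssw <- ssw + sum(d2[i, i]) / (2 * sum(i))
        }
        ((ssTot - ssw) / (a - 1)) / (ssw / (n - a))
    }
    fObs <- fOf(groups)
    perms <- gtoolsPerms(groups)
    fAll <- apply(perms, 1, fOf)
    mean(fAll >= fObs - 1e-12)
}

# all distinct orderings of a label vector (tiny n only)
gtoolsPerms <- function(x) {
    n <- length(x)
    idx <- NULL
    rec <- function(prefix, rest) {
        if (!length(rest)) {
            idx[[length(idx) + 1L]] <<- prefix
            return(invisible())
        }
        for (i in seq_along(rest)) {
            rec(c(prefix, rest[i]), rest[-i])
        }
    }
    idx <- list()
    rec(character(0), x)
    unique(do.call(rbind, idx))
}
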