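test_that("depth normalization scales every sample to the target total", {
    m <- toyCounts(8, 5)
    norm <- normalizeDepth(m, depth = 1000)
    expect_true(all(abs(colSums(norm) - 1000) < 1e-9))

    # sample already at depth is unchanged; doubled totals are halved
    atDepth <- m
    atDepth[, 1] <- c(500, 100, 100, 100, 100, 50, 25, 25)
    norm2 <- normalizeDepth(atDepth, depth = 1000)
    expect_equal(norm2[, 1], atDepth[, 1])
    doubled <- normalizeDepth(2 * atDepth[, 1, drop = FALSE], depth = 1000)
    expect_equal(doubled[, 1], atDepth[, 1])

    z <- m
    z[, 2] <- 0
    expect_error(normalizeDepth(z, 1000), "s2")
})

test_that("rarefying normalization subsamples to exact integer depth", {
    m <- toyCounts(10, 4, lambda = 100)
    r1 <- normalizeDepth(m, depth = 200, method = "rarefy", seed = 7)
    expect_true(all(colSums(r1) == 200))
    expect_true(all(r1 == round(r1)))
    r2 <- normalizeDepth(m, depth = 200, method = "rarefy", seed = 7)
    expect_identical(r1, r2)
})

test_that("relative abundance and the >0.5% filter behave on toys", {
    one <- matrix(5, 1, 2, dimnames = list("only", c("a", "b")))
    expect_true(all(relativeAbundance(one) == 1))

    # 3-feature hand computation
    m <- matrix(c(10, 30, 60), 3, 1, dimnames = list(c("x", "y", "z"), "s"))
    expect_equal(as.numeric(relativeAbundance(m)), c(0.1, 0.3, 0.6))

    # feature at exactly 0.5% is excluded (strict >)
    m2 <- rbind(rare = c(5, 5), common = c(995, 995))
    colnames(m2) <- c("a", "b")
    kept <- abundanceFilter(relativeAbundance(m2), minFrac = 0.005)
    expect_identical(rownames(kept), "common")
})

test_that("analytic rarefaction matches closed form, endpoints, and Monte Carlo", {
    m <- matrix(c(5, 5), 2, 1, dimnames = list(c("f1", "f2"), "s1"))
    # E[S_2] = 2 (1 - C(5,2)/C(10,2)) = 14/9
    expect_equal(
        rarefactionCurve(m, depths = 2)$expectedFeatures, 14 / 9
    )
    expect_equal(rarefactionCurve(m, depths = 1)$expectedFeatures, 1)
    expect_equal(rarefactionCurve(m, depths = 10)$expectedFeatures, 2)
    expect_error(rarefactionCurve(m, depths = 11), "exceed")

    # Monte-Carlo subsampling oracle at a skewed composition
    counts <- c(12, 4, 2, 1, 1)
    mm <- matrix(counts, ncol = 1, dimnames = list(paste0("f", 1:5), "s"))
    n <- 7
    set.seed(123)
    reads <- rep(seq_along(counts), counts)
    draws <- replicate(4e4, length(unique(sample(reads, n))))
    mc <- mean(draws)
    se <- sd(draws) / sqrt(length(draws))
    analytic <- rarefactionCurve(mm, depths = n)$expectedFeatures
    expect_lt(abs(analytic - mc), 3 * se)

    # curves are non-decreasing in depth
    curve <- rarefactionCurve(mm, depths = 1:20)
    expect_true(all(diff(curve$expectedFeatures) >= 0))
})

test_that("Bray-Curtis reproduces hand values and metric properties", {
    expect_equal(brayCurtis(cbind(u = c(1, 2), v = c(3, 0)))["u", "v"], 4 / 6)
    same <- cbind(a = c(1, 2, 3), b = c(1, 2, 3))
    expect_equal(brayCurtis(same)["a", "b"], 0)
    disjoint <- cbind(a = c(1, 0), b = c(0, 5))
    expect_equal(brayCurtis(disjoint)["a", "b"], 1)

    m <- toyCounts(12, 5)
    d <- brayCurtis(m)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
    # invariance under joint feature permutation
    set.seed(3)
    expect_equal(brayCurtis(m[sample(nrow(m)), ]), d)

    expect_error(brayCurtis(cbind(a = c(0, 0), b = c(1, 1))), "all-zero")
})

test_that("PCoA recovers planted geometry", {
    # two samples at distance d: single axis at +-d/2 with all the variance
    d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
    ord <- pcoaOrdination(d2)
    expect_equal(sort(abs(as.numeric(ord$coordinates[, 1]))), c(1.5, 1.5))
    expect_equal(ord$varianceExplained[1], 1)

    # Euclidean-embeddable 4x4 round trip to 1e-8
    fx <- euclideanDistanceFixture(n = 4, dim = 2)
    ord4 <- pcoaOrdination(fx$d)
    rt <- as.matrix(dist(ord4$coordinates))
    expect_equal(unname(rt), unname(fx$d), tolerance = 1e-8)
    expect_true(all(diff(ord4$eigenvalues) <= 1e-8))

    # collinear points embed on one axis
    line <- as.matrix(dist(cbind(c(0, 1, 3.5))))
    dimnames(line) <- list(c("a", "b", "c"), c("a", "b", "c"))
    ordLine <- pcoaOrdination(line)
    expect_equal(ncol(ordLine$coordinates), 1L)
})

test_that("UPGMA yields ultrametric trees with half-merge-distance heights", {
    lab <- c("A", "B")
    d2 <- matrix(c(0, 6, 6, 0), 2, dimnames = list(lab, lab))
    tr2 <- upgmaTree(d2)
    expect_equal(unname(cophenetic(tr2)["A", "B"]), 6)
    expect_equal(tr2$edge.length, c(3, 3))

    lab3 <- c("A", "B", "C")
    d3 <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, dimnames = list(lab3, lab3))
    tr3 <- upgmaTree(d3)
    coph <- cophenetic(tr3)
    expect_equal(unname(coph["A", "B"]), 2) # join height 1
    expect_equal(unname(coph["A", "C"]), 8) # root height 4
    expect_true(ape::is.ultrametric(tr3))

    big <- brayCurtis(toyCounts(10, 6))
    expect_true(ape::is.ultrametric(upgmaTree(big), tol = 1e-8))
    expect_error(upgmaTree(matrix(0, 1, 1)), "at least two")
})

test_that("PERMANOVA matches vegan's partition and the exact-enumeration oracle", {
    m <- toyCounts(10, 8, seed = 21)
    g <- rep(c("thr", "sed"), each = 4)
    d <- brayCurtis(m)
    fit <- permanovaTest(d, g, nPerm = 999, seed = 1)
    ad <- vegan::adonis2(as.dist(d) ~ g, permutations = 199)
    expect_equal(fit$f, ad$F[1], tolerance = 1e-10)
    expect_equal(fit$r2, ad$R2[1], tolerance = 1e-10)

    # exact enumeration on a 2+2 toy
    m4 <- toyCounts(6, 4, seed = 33)
    g4 <- c("x", "x", "y", "y")
    d4 <- brayCurtis(m4)
    pExact <- oraclePermanovaExact(d4, g4)
    fit4 <- permanovaTest(d4, g4, nPerm = 4999, seed = 2)
    expect_lt(
        abs(fit4$p - pExact),
        3 * sqrt(pExact * (1 - pExact) / 4999) + 1 / 5000
    )
})

test_that("PERMANOVA p-values are seeded, resolution-exact, and label-consistent", {
    m <- toyCounts(10, 8, seed = 8)
    g <- rep(c("a", "b"), each = 4)
    d <- brayCurtis(m)
    f1 <- permanovaTest(d, g, nPerm = 99, seed = 7)
    f2 <- permanovaTest(d, g, nPerm = 99, seed = 7)
    expect_identical(f1, f2)
    expect_equal((f1$p * 100) %% 1, 0) # multiples of 1/(nPerm+1)

    # R2 invariant under a consistent permutation of samples and labels
    set.seed(14)
    pi <- sample(8)
    f3 <- permanovaTest(d[pi, pi], g[pi], nPerm = 99, seed = 7)
    expect_equal(f3$r2, f1$r2, tolerance = 1e-12)

    # degenerate all-identical samples
    z <- matrix(0, 4, 4, dimnames = list(NULL, paste0("s", 1:4)))
    fz <- permanovaTest(z, c("a", "a", "b", "b"), nPerm = 99)
    expect_equal(fz$r2, 0)
    expect_equal(fz$p, 1)

    expect_warning(permanovaTest(d, g, nPerm = 9), "resolution")
    expect_error(permanovaTest(d, rep("a", 8), nPerm = 99), "two groups")
})

test_that("null PERMANOVA p-values are calibrated at the 5% level", {
    set.seed(77)
    nrep <- 400
    rej <- 0
    g <- rep(c("a", "b"), each = 5)
    for (i in seq_len(nrep)) {
        pts <- matrix(rnorm(10 * 3), 10, 3)
        rownames(pts) <- paste0("s", 1:10)
        d <- as.matrix(dist(pts))
        if (permanovaTest(d, g, nPerm = 199)$p <= 0.05) rej <- rej + 1
    }
    rate <- rej / nrep
    expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / nrep))
})
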