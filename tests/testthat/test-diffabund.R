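test_that("median-of-ratios size factors solve the closed-form cases", {
    ident <- cbind(s1 = c(10, 20, 30), s2 = c(10, 20, 30), s3 = c(10, 20, 30))
    expect_equal(unname(sizeFactorsMedianOfRatios(ident)), rep(1, 3))

    doubled <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
    expect_equal(
        unname(sizeFactorsMedianOfRatios(doubled)),
        c(1 / sqrt(2), sqrt(2))
    )

    # unit geometric mean, and column scaling moves only that factor
    m <- toyCounts(20, 4, lambda = 50) + 1
    sf <- sizeFactorsMedianOfRatios(m)
    expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-9)
    m2 <- m
    m2[, 2] <- m2[, 2] * 3
    sf2 <- sizeFactorsMedianOfRatios(m2)
    expect_equal(sf2[2] / sf2[1], 3 * sf[2] / sf[1], tolerance = 1e-9)

    noRef <- cbind(s1 = c(0, 5), s2 = c(5, 0))
    expect_error(sizeFactorsMedianOfRatios(noRef), "pseudo-reference")
})

test_that("method-of-moments dispersions recover simulated regimes", {
    # Poisson counts: estimates pile up near the floor
    set.seed(101)
    mp <- matrix(rpois(500 * 20, 100), 500, 20,
        dimnames = list(paste0("f", 1:500), paste0("s", 1:20))
    )
    g <- rep(c("a", "b"), each = 10)
    dPois <- estimateDispersionsMoM(mp, g, sf = rep(1, 20))
    expect_lt(mean(dPois), 0.01)

    # NB alpha = 0.2 with n = 20 per group: mean estimate in [0.1, 0.3]
    set.seed(102)
    mn <- matrix(rnbinom(500 * 40, mu = 1000, size = 5), 500, 40,
        dimnames = list(paste0("f", 1:500), paste0("s", 1:40))
    )
    g2 <- rep(c("a", "b"), each = 20)
    dNb <- estimateDispersionsMoM(mn, g2, sf = rep(1, 40))
    expect_gt(mean(dNb), 0.1)
    expect_lt(mean(dNb), 0.3)

    # constant feature sits at the floor
    mc <- rbind(const = rep(7, 6), varies = c(1, 9, 4, 8, 2, 6))
    colnames(mc) <- paste0("s", 1:6)
    dc <- estimateDispersionsMoM(mc, rep(c("a", "b"), each = 3),
        sf = rep(1, 6)
    )
    expect_equal(unname(dc["const"]), 1e-8)

    # group differences must not inflate the within-group estimate
    shifted <- rbind(f1 = c(rep(100, 3), rep(10000, 3)))
    colnames(shifted) <- paste0("s", 1:6)
    dShift <- estimateDispersionsMoM(shifted, rep(c("a", "b"), each = 3),
        sf = rep(1, 6)
    )
    expect_lt(unname(dShift["f1"]), 0.05)
})

test_that("the NB Wald test is symmetric under label swap and handles zeros", {
    sim <- simulateCountTable(countSimConfig(
        nFeatures = 120, nDiff = 20, seed = 5
    ))
    me <- sim$experiment
    resT <- nbWaldTest(me, focalGroup = "thrombolite")
    resS <- nbWaldTest(me, focalGroup = "sediment")
    expect_equal(resS$log2fc, -resT$log2fc, tolerance = 1e-9)
    expect_equal(resS$p, resT$p, tolerance = 1e-9)

    # baseMean equals mean of size-factor-normalized counts
    sf <- sizeFactorsMedianOfRatios(counts(me))
    expect_equal(
        resT$baseMean,
        unname(rowMeans(sweep(counts(me), 2, sf, "/")))
    )

    # all-zero feature and one-group-zero feature
    m <- counts(me)[1:10, ]
    m["feat0001", ] <- 0
    m["feat0002", ] <- c(0, 0, 0, 40, 55, 60)
    res0 <- nbWaldTest(m, groupLabels(me), focalGroup = "thrombolite")
    expect_equal(res0$p[1], 1)
    expect_equal(res0$log2fc[1], 0)
    expect_true(is.finite(res0$log2fc[2]) && res0$log2fc[2] < 0)
    expect_lt(res0$padj[2], 0.05)
    expect_true(all(res0$padj >= res0$p))
})

test_that("the Wald stage recovers a true twofold-change regime", {
    set.seed(201)
    nfeat <- 200
    alpha <- 0.1
    mu <- 5000
    m <- matrix(0L, nfeat, 6,
        dimnames = list(sprintf("f%03d", 1:nfeat), paste0("s", 1:6))
    )
    for (i in seq_len(nfeat)) {
        m[i, 1:3] <- rnbinom(3, mu = mu * 2, size = 1 / alpha)
        m[i, 4:6] <- rnbinom(3, mu = mu / 2, size = 1 / alpha)
    }
    g <- rep(c("focal", "other"), each = 3)
    res <- nbWaldTest(m, g,
        focalGroup = "focal", sf = rep(1, 6),
        dispersions = rep(alpha, nfeat)
    )
    expect_gt(mean(res$log2fc), 1.7)
    expect_lt(mean(res$log2fc), 2.3)
})

test_that("our Wald fold changes track DESeq2 on the same table", {
    skip_if_not_installed("DESeq2")
    sim <- simulateCountTable(countSimConfig(
        nFeatures = 150, nDiff = 30, meanLog = 5, sdLog = 1.5, seed = 31
    ))
    m <- counts(sim$experiment)
    keep <- rowSums(m > 0) == ncol(m)
    m <- m[keep, ]
    grp <- factor(groupLabels(sim$experiment), levels = c("sediment", "thrombolite"))
    res <- nbWaldTest(m, as.character(grp), focalGroup = "thrombolite")
    suppressMessages({
        dds <- DESeq2::DESeqDataSetFromMatrix(
            m, S4Vectors::DataFrame(condition = grp), ~condition
        )
        dds <- DESeq2::DESeq(dds, quiet = TRUE)
        dres <- DESeq2::results(dds)
    })
    cc <- cor(res$log2fc, dres$log2FoldChange)
    expect_gt(cc, 0.95)
    # strong calls agree in direction
    strong <- which(!is.na(dres$padj) & dres$padj < 0.01)
    expect_true(all(sign(res$log2fc[strong]) == sign(dres$log2FoldChange[strong])))
})

test_that("BH adjustment matches the hand step-up and validates input", {
    expect_equal(bhAdjust(0.2), 0.2)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    set.seed(4)
    p <- runif(50)
    expect_true(all(bhAdjust(p) >= p))
    expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
    expect_error(bhAdjust(c(0.5, -0.1)), "0, 1")
})

test_that("the enrichment filter keeps exactly the hand-selected subset", {
    recs <- data.frame(
        feature = paste0("f", 1:6),
        baseMean = c(5000, 5000, 5000, 1500, 2000, 9000),
        log2fc = c(1.5, 1.0, -2.2, 3.0, 1.4, 1.01),
        se = 0.2, wald = 5, p = 0.001,
        padj = c(0.01, 0.01, 0.04, 0.01, 0.01, 0.06),
        enrichedIn = "none"
    )
    kept <- enrichmentFilter(recs)
    # f1 passes; f2 fails strict |lfc| > 1; f3 passes (other direction);
    # f4 fails baseMean; f5 fails strict > 2000; f6 fails padj
    expect_identical(kept$feature, c("f1", "f3"))
    expect_identical(kept$enrichedIn, c("focal", "other"))
    # subset + idempotence
    expect_identical(enrichmentFilter(kept), kept)
    expect_true(all(kept$feature %in% recs$feature))
})
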