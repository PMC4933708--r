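#' Configuration for the count-table simulator
#'
#' Describes a two-group feature-by-sample count experiment with known truth,
#' emulating a post-annotation metagenomic count table: log-normal feature
#' mean abundances, negative-binomial sampling noise with common dispersion,
#' a subset of differential features whose group means are split
#' mean * 2^(+lfc/2) vs mean * 2^(-lfc/2), and per-sample depth multipliers.
#' Defaults mirror a 3 + 3 mat-type design with thousands of features whose
#' abundances span the baseMean > 2000 filter regime.
#'
#' @param nFeatures number of features (default 2000).
#' @param nPerGroup samples per group (default 3; >= 2 required).
#' @param meanLog,sdLog log-normal parameters of the feature mean abundances
#'   (defaults 6 and 2).
#' @param dispersion common NB dispersion alpha (0 = Poisson; default 0.1).
#' @param nDiff number of differential features (default 200).
#' @param log2fc true |log2 fold change| of differential features (scalar or
#'   length `nDiff`; default 2). Signs are assigned randomly.
#' @param depthRange range of the uniform per-sample depth multipliers
#'   (default \[0.5, 2\]).
#' @param groups labels for (focal, other) group (default
#'   `c("thrombolite", "sediment")`).
#' @param seed integer seed; the generator is a pure function of the config.
#' @return validated config list (class `"count_sim_config"`).
#' @export
countSimConfig <- function(nFeatures = 2000, nPerGroup = 3, meanLog = 6,
                           sdLog = 2, dispersion = 0.1, nDiff = 200,
                           log2fc = 2, depthRange = c(0.5, 2),
                           groups = c("thrombolite", "sediment"), seed = 1) {
    stopifnot(
        nFeatures >= 1, nPerGroup >= 2, sdLog >= 0, dispersion >= 0,
        nDiff >= 0, nDiff <= nFeatures, all(log2fc >= 0),
        length(depthRange) == 2, depthRange[1] > 0,
        depthRange[1] <= depthRange[2], length(groups) == 2
    )
    cfg <- list(
        nFeatures = as.integer(nFeatures), nPerGroup = as.integer(nPerGroup),
        meanLog = meanLog, sdLog = sdLog, dispersion = dispersion,
        nDiff = as.integer(nDiff), log2fc = log2fc,
        depthRange = depthRange, groups = groups, seed = as.integer(seed)
    )
    class(cfg) <- "count_sim_config"
    cfg
}

#' Simulate a two-group count table with known truth
#'
#' Draws the experiment described by a [countSimConfig()]: feature means from
#' a log-normal, a random subset of differential features with the configured
#' true log2 fold changes (randomly signed), NB (or Poisson when
#' dispersion = 0) counts at mean = group mean x depth multiplier.
#'
#' @param config a [countSimConfig()].
#' @return list with `experiment` (a [MatExperiment-class]) and `truth`
#'   (data.frame: `feature`, `meanAbundance`, `log2fc` as focal-over-other,
#'   `differential` flag).
#' @examples
#' sim <- simulateCountTable(countSimConfig(nFeatures = 50, seed = 7))
#' sim$experiment
#' @export
simulateCountTable <- function(config) {
    stopifnot(inherits(config, "count_sim_config"))
    set.seed(config$seed)
    nf <- config$nFeatures
    npg <- config$nPerGroup
    means <- rlnorm(nf, config$meanLog, config$sdLog)
    lfc <- numeric(nf)
    if (config$nDiff > 0) {
        idx <- sample(nf, config$nDiff)
        signs <- sample(c(-1, 1), config$nDiff, replace = TRUE)
        lfc[idx] <- signs * rep_len(config$log2fc, config$nDiff)
    }
    muFocal <- means * 2^(lfc / 2)
    muOther <- means * 2^(-lfc / 2)
    depth <- runif(2 * npg, config$depthRange[1], config$depthRange[2])
    mu <- cbind(
        matrix(muFocal, nf, npg), matrix(muOther, nf, npg)
    ) * rep(depth, each = nf)
    k <- if (config$dispersion == 0) {
        rpois(length(mu), lambda = mu)
    } else {
        rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    }
    m <- matrix(k, nf, 2 * npg)
    rownames(m) <- sprintf("feat%04d", seq_len(nf))
    colnames(m) <- c(
        sprintf("%s%d", config$groups[1], seq_len(npg)),
        sprintf("%s%d", config$groups[2], seq_len(npg))
    )
    grp <- rep(config$groups, each = npg)
    list(
        experiment = MatExperiment(m, grp),
        truth = data.frame(
            feature = rownames(m), meanAbundance = means,
            log2fc = lfc, differential = lfc != 0,
            stringsAsFactors = FALSE
        )
    )
}

#' Configuration for the isotope-study simulator
#'
#' Describes a synthetic water + carbonate dataset: lake and groundwater DIC
#' delta-13C drawn within the configured ranges (defaults span the measured
#' lake -4.30 to 1.55 permil and groundwater -13.35 to -7.97 permil windows),
#' pH and specific conductance within the observed lake ranges, and carbonate
#' samples generated at the model's own maximum equilibrium prediction plus a
#' known photoautotrophic offset and Gaussian measurement noise, subsampled
#' from cores in 5-cm depth intervals.
#'
#' @param nLake,nGroundwater numbers of water samples per source.
#' @param nCarbonate number of carbonate subsamples (default 18).
#' @param lakeD13cRange,groundwaterD13cRange permil VPDB ranges for DIC.
#' @param phRange pH range (default \[7.18, 7.63\]).
#' @param temperatureRange degrees C range of collection temperatures.
#' @param scRange specific-conductance range, mS/cm.
#' @param trueOffset injected biosignature offset, permil (default +4.0).
#' @param noiseSd Gaussian measurement noise sd, permil (default 0.3).
#' @param tRange temperature window for the equilibrium prediction.
#' @param seed integer seed.
#' @return validated config list (class `"isotope_sim_config"`).
#' @export
isotopeSimConfig <- function(nLake = 4, nGroundwater = 4, nCarbonate = 18,
                             lakeD13cRange = c(-4.30, 1.55),
                             groundwaterD13cRange = c(-13.35, -7.97),
                             phRange = c(7.18, 7.63),
                             temperatureRange = c(15, 30),
                             scRange = c(121.4, 188.2),
                             trueOffset = 4.0, noiseSd = 0.3,
                             tRange = c(10, 40), seed = 1) {
    rngOk <- function(r) length(r) == 2 && r[1] <= r[2]
    stopifnot(
        nLake + nGroundwater >= 1, nCarbonate >= 1, noiseSd >= 0,
        rngOk(lakeD13cRange), rngOk(groundwaterD13cRange), rngOk(phRange),
        rngOk(temperatureRange), rngOk(scRange), rngOk(tRange)
    )
    cfg <- list(
        nLake = as.integer(nLake), nGroundwater = as.integer(nGroundwater),
        nCarbonate = as.integer(nCarbonate),
        lakeD13cRange = lakeD13cRange,
        groundwaterD13cRange = groundwaterD13cRange,
        phRange = phRange, temperatureRange = temperatureRange,
        scRange = scRange, trueOffset = trueOffset, noiseSd = noiseSd,
        tRange = tRange, seed = as.integer(seed)
    )
    class(cfg) <- "isotope_sim_config"
    cfg
}

#' Simulate a water + carbonate isotope study with known truth
#'
#' Water chemistry is drawn within the configured ranges; the equilibrium
#' prediction is then computed through the package's own isotope model
#' ([maxEquilibriumPrediction()]) and the carbonate delta-13C values are that
#' prediction plus the injected offset plus Gaussian noise, so the recovered
#' offsets close exactly on the truth in expectation.
#'
#' @param config an [isotopeSimConfig()].
#' @return list with `water` and `carbonates` (validated sample tables),
#'   `truth` (list: `offset`, `noiseSd`), and `prediction` (the
#'   [EquilibriumPrediction-class] used to generate the carbonates).
#' @examples
#' sim <- simulateIsotopeStudy(isotopeSimConfig(seed = 3))
#' sim$prediction
#' @export
simulateIsotopeStudy <- function(config) {
    stopifnot(inherits(config, "isotope_sim_config"))
    set.seed(config$seed)
    nw <- config$nLake + config$nGroundwater
    src <- c(
        rep("lake", config$nLake), rep("groundwater", config$nGroundwater)
    )
    d13c <- c(
        runif(config$nLake, config$lakeD13cRange[1], config$lakeD13cRange[2]),
        runif(
            config$nGroundwater,
            config$groundwaterD13cRange[1], config$groundwaterD13cRange[2]
        )
    )
    water <- waterSamples(
        id = sprintf("W%02d", seq_len(nw)),
        source = src,
        temperature = runif(
            nw, config$temperatureRange[1], config$temperatureRange[2]
        ),
        ph = runif(nw, config$phRange[1], config$phRange[2]),
        conductance = runif(nw, config$scRange[1], config$scRange[2]),
        d13cDic = d13c
    )
    pred <- maxEquilibriumPrediction(water, tRange = config$tRange)
    nc <- config$nCarbonate
    slot <- (seq_len(nc) - 1) %% 8
    carb <- carbonateSamples(
        id = sprintf("CB%02d", seq_len(nc)),
        core = c("core1", "core2")[((seq_len(nc) - 1) %/% 8) %% 2 + 1],
        depthTop = slot * 5,
        depthBottom = slot * 5 + 5,
        d13cCaco3 = pred@delta13cAragEq + config$trueOffset +
            rnorm(nc, 0, config$noiseSd)
    )
    list(
        water = water, carbonates = carb,
        truth = list(offset = config$trueOffset, noiseSd = config$noiseSd),
        prediction = pred
    )
}
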