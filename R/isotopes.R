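#' Construct and validate a water-sample table
#'
#' A water sample carries the field measurements the isotope model consumes:
#' source class (lake or groundwater), temperature, pH, specific conductance
#' and the measured delta-13C of bulk DIC.
#'
#' @param id character sample ids.
#' @param source `"lake"` or `"groundwater"`.
#' @param temperature degrees C in \[0, 50\], `NA` when not measured.
#' @param ph pH in \[2, 12\].
#' @param conductance specific conductance at 25 C, mS/cm (> 0), `NA` allowed.
#' @param d13cDic delta-13C of DIC, permil VPDB.
#' @return validated data.frame with those columns.
#' @examples
#' waterSamples("LW1", "lake", 22, 7.54, 121.4, 1.55)
#' @export
waterSamples <- function(id, source, temperature = NA_real_, ph,
                         conductance = NA_real_, d13cDic) {
    df <- data.frame(
        id = as.character(id), source = as.character(source),
        temperature = as.numeric(temperature), ph = as.numeric(ph),
        conductance = as.numeric(conductance), d13cDic = as.numeric(d13cDic),
        stringsAsFactors = FALSE
    )
    validateWaterSamples(df)
}

#' @rdname waterSamples
#' @param df data.frame with the `waterSamples()` columns.
#' @export
validateWaterSamples <- function(df) {
    need <- c("id", "source", "temperature", "ph", "conductance", "d13cDic")
    if (!all(need %in% names(df))) {
        stop(
            "water-sample table lacks column(s): ",
            paste(setdiff(need, names(df)), collapse = ", "),
            call. = FALSE
        )
    }
    if (anyDuplicated(df$id)) stop("duplicate water-sample ids", call. = FALSE)
    if (!all(df$source %in% c("lake", "groundwater"))) {
        stop("'source' must be 'lake' or 'groundwater'", call. = FALSE)
    }
    tt <- df$temperature[!is.na(df$temperature)]
    if (any(tt < 0 | tt > 50)) {
        stop("'temperature' must lie in [0, 50] degrees C", call. = FALSE)
    }
    if (any(is.na(df$ph)) || any(df$ph < 2 | df$ph > 12)) {
        stop("'ph' must be present and lie in [2, 12]", call. = FALSE)
    }
    sc <- df$conductance[!is.na(df$conductance)]
    if (any(sc <= 0)) stop("'conductance' must be > 0", call. = FALSE)
    df[need]
}

#' Construct and validate a carbonate-sample table
#'
#' One row per carbonate subsample from a thrombolite core: core id, depth
#' interval (cm) and the measured delta-13C of the CaCO3.
#'
#' @param id character sample ids.
#' @param core character core ids.
#' @param depthTop,depthBottom depth interval in cm, `depthTop < depthBottom`.
#' @param d13cCaco3 delta-13C of the carbonate, permil VPDB.
#' @return validated data.frame with those columns.
#' @examples
#' carbonateSamples("C1-00", "C1", 0, 5, 9.02)
#' @export
carbonateSamples <- function(id, core, depthTop, depthBottom, d13cCaco3) {
    df <- data.frame(
        id = as.character(id), core = as.character(core),
        depthTop = as.numeric(depthTop), depthBottom = as.numeric(depthBottom),
        d13cCaco3 = as.numeric(d13cCaco3), stringsAsFactors = FALSE
    )
    validateCarbonateSamples(df)
}

#' @rdname carbonateSamples
#' @param df data.frame with the `carbonateSamples()` columns.
#' @export
validateCarbonateSamples <- function(df) {
    need <- c("id", "core", "depthTop", "depthBottom", "d13cCaco3")
    if (!all(need %in% names(df))) {
        stop(
            "carbonate-sample table lacks column(s): ",
            paste(setdiff(need, names(df)), collapse = ", "),
            call. = FALSE
        )
    }
    if (anyDuplicated(df$id)) {
        stop("duplicate carbonate-sample ids", call. = FALSE)
    }
    if (any(is.na(df$depthTop)) || any(is.na(df$depthBottom)) ||
        any(df$depthTop < 0) || any(df$depthTop >= df$depthBottom)) {
        stop("depth intervals must satisfy 0 <= depthTop < depthBottom",
            call. = FALSE
        )
    }
    if (any(!is.finite(df$d13cCaco3))) {
        stop("'d13cCaco3' must be finite", call. = FALSE)
    }
    df[need]
}

#' Bicarbonate delta-13C from bulk DIC delta-13C by isotope mass balance
#'
#' Solves the species mass balance delta_DIC = x_a delta_a + x_b delta_b +
#' x_c delta_c for delta_b (bicarbonate), with each species tied to
#' bicarbonate through its equilibrium enrichment at temperature T in exact
#' multiplicative alpha form, delta_species = alpha (delta_b + 1000) - 1000,
#' alpha = 1 + eps/1000. Because CO2(aq) is the 13C-depleted species, the
#' resulting delta_b exceeds delta_DIC whenever the CO2(aq) fraction is
#' non-negligible.
#'
#' @param delta13cDic numeric delta-13C of bulk DIC, permil VPDB.
#' @param speciation a [DICSpeciation-class].
#' @param fr a [FractionationSet-class]; default [fractionationSet()].
#' @param temperature degrees C at which the enrichments are evaluated;
#'   defaults to the speciation temperature.
#' @return numeric delta-13C of HCO3-, permil VPDB.
#' @examples
#' sp <- speciateDIC(7.54, 25)
#' hco3DeltaFromDic(1.55, sp)
#' @export
hco3DeltaFromDic <- function(delta13cDic, speciation,
                             fr = fractionationSet(),
                             temperature = NULL) {
    stopifnot(is(speciation, "DICSpeciation"), is(fr, "FractionationSet"))
    if (is.null(temperature)) temperature <- speciation@temperature
    xs <- moleFractions(speciation)
    if (any(rowSums(xs) < 1e-6)) {
        stop("degenerate speciation: all mole fractions are zero",
            call. = FALSE
        )
    }
    aAB <- 1 + fr@epsCO2aqHCO3(temperature) / 1000
    aCB <- 1 + fr@epsCO3HCO3(temperature) / 1000
    denom <- xs[, "xCO2aq"] * aAB + xs[, "xHCO3"] + xs[, "xCO3"] * aCB
    unname((delta13cDic + 1000) / denom - 1000)
}

#' Theoretical equilibrium aragonite delta-13C from bicarbonate delta-13C
#'
#' Applies the aragonite-bicarbonate equilibrium enrichment at temperature T
#' in exact alpha form: delta_arag = alpha (delta_b + 1000) - 1000 with
#' alpha = 1 + eps(arag - HCO3)(T)/1000.
#'
#' @param delta13cHco3 numeric delta-13C of HCO3-, permil VPDB.
#' @param temperature degrees C.
#' @param fr a [FractionationSet-class].
#' @return numeric theoretical equilibrium aragonite delta-13C, permil VPDB.
#' @examples
#' equilibriumAragoniteDelta(0, 25) # about +2.7 permil
#' @export
equilibriumAragoniteDelta <- function(delta13cHco3, temperature,
                                      fr = fractionationSet()) {
    stopifnot(is(fr, "FractionationSet"))
    alpha <- 1 + fr@epsAragHCO3(temperature) / 1000
    alpha * (delta13cHco3 + 1000) - 1000
}

#' Maximum theoretical equilibrium aragonite delta-13C for a water dataset
#'
#' For each water sample, computes the bicarbonate delta-13C over a
#' temperature grid (the sample's own temperature when measured, otherwise a
#' scan of `tRange`), takes the dataset-wide maximum, then applies the
#' aragonite-bicarbonate enrichment at the grid temperature that maximizes the
#' final value. The result is the most 13C-enriched aragonite that could
#' precipitate in equilibrium with the measured DIC pool, the reference
#' against which measured carbonate is scored by [biosignatureOffsets()].
#'
#' @param water data.frame from [waterSamples()] / [readWaterSamples()].
#' @param tRange numeric length-2 temperature window, degrees C (within
#'   \[0, 50\]); default 10-40 C.
#' @param tStep grid step in degrees C (endpoints always included).
#' @param fr a [FractionationSet-class].
#' @param variant constants variant for [speciateDIC()].
#' @param useSampleTemperature if `TRUE` (default) a sample's measured
#'   temperature fixes its speciation temperature instead of scanning.
#' @return an [EquilibriumPrediction-class].
#' @examples
#' w <- waterSamples("LW1", "lake", NA, 7.54, 121.4, 1.55)
#' maxEquilibriumPrediction(w)
#' @export
maxEquilibriumPrediction <- function(water, tRange = c(10, 40), tStep = 0.1,
                                     fr = fractionationSet(),
                                     variant = c("freshwater", "saline"),
                                     useSampleTemperature = TRUE) {
    variant <- match.arg(variant)
    water <- validateWaterSamples(water)
    if (nrow(water) == 0L) {
        stop("at least one water sample is required", call. = FALSE)
    }
    if (length(tRange) != 2L || tRange[1] > tRange[2] ||
        tRange[1] < 0 || tRange[2] > 50) {
        stop("'tRange' must be an ordered interval within [0, 50]",
            call. = FALSE
        )
    }
    grid <- unique(c(seq(tRange[1], tRange[2], by = tStep), tRange[2]))

    bestDb <- -Inf
    bestIdx <- NA_integer_
    for (i in seq_len(nrow(water))) {
        tcs <- if (useSampleTemperature && !is.na(water$temperature[i])) {
            water$temperature[i]
        } else {
            grid
        }
        sp <- speciateDIC(water$ph[i], tcs, variant = variant)
        db <- hco3DeltaFromDic(water$d13cDic[i], sp, fr)
        if (max(db) > bestDb) {
            bestDb <- max(db)
            bestIdx <- i
        }
    }
    darag <- equilibriumAragoniteDelta(bestDb, grid, fr)
    j <- which.max(darag)
    new("EquilibriumPrediction",
        delta13cHCO3 = bestDb,
        delta13cAragEq = darag[j],
        temperature = grid[j],
        pH = water$ph[bestIdx],
        sourceSampleId = water$id[bestIdx]
    )
}

setMethod("show", "EquilibriumPrediction", function(object) {
    cat("EquilibriumPrediction\n")
    cat(sprintf("  delta13C(HCO3-)    : %.3f permil VPDB\n", object@delta13cHCO3))
    cat(sprintf("  delta13C(aragonite): %.3f permil VPDB (equilibrium)\n", object@delta13cAragEq))
    cat(sprintf(
        "  at T = %.1f degC, pH = %.2f, from sample '%s'\n",
        object@temperature, object@pH, object@sourceSampleId
    ))
})

#' Score measured carbonate delta-13C as biosignature offsets
#'
#' For each carbonate sample computes offset = measured delta-13C minus the
#' maximum theoretical equilibrium aragonite delta-13C, and classifies the
#' sign: positive offsets indicate photoautotrophic 12C drawdown from the
#' local DIC reservoir (the precipitated carbonate is 13C-enriched relative
#' to equilibrium), negative offsets heterotrophic 12C addition, and offsets
#' within `tolerance` of zero are called equilibrium.
#'
#' @param carbonates data.frame from [carbonateSamples()] /
#'   [readCarbonateSamples()].
#' @param prediction an [EquilibriumPrediction-class].
#' @param tolerance permil half-width of the equilibrium class (default 0.1,
#'   comfortably above the 0.01-0.03 permil analytical reproducibility of the
#'   measurements).
#' @return a [BiosignatureResult-class].
#' @examples
#' w <- waterSamples("LW1", "lake", NA, 7.54, 121.4, 1.55)
#' pred <- maxEquilibriumPrediction(w)
#' cb <- carbonateSamples(c("a", "b"), "C1", c(0, 5), c(5, 10), c(9.02, 12.31))
#' biosignatureOffsets(cb, pred)
#' @export
biosignatureOffsets <- function(carbonates, prediction, tolerance = 0.1) {
    stopifnot(is(prediction, "EquilibriumPrediction"))
    carbonates <- validateCarbonateSamples(carbonates)
    if (nrow(carbonates) == 0L) {
        stop("at least one carbonate sample is required", call. = FALSE)
    }
    if (!is.finite(tolerance) || tolerance < 0) {
        stop("'tolerance' must be a non-negative number", call. = FALSE)
    }
    off <- carbonates$d13cCaco3 - prediction@delta13cAragEq
    cls <- ifelse(off > tolerance, "photoautotrophic",
        ifelse(off < -tolerance, "heterotrophic", "equilibrium")
    )
    tab <- data.frame(
        id = carbonates$id, core = carbonates$core,
        depthTop = carbonates$depthTop, depthBottom = carbonates$depthBottom,
        delta13cCaco3 = carbonates$d13cCaco3,
        offset = off, classification = cls,
        stringsAsFactors = FALSE
    )
    new("BiosignatureResult",
        offsets = tab,
        summary = c(
            min = min(off), max = max(off),
            mean = mean(off), sd = if (length(off) > 1L) sd(off) else NA_real_
        ),
        tolerance = tolerance,
        prediction = prediction
    )
}

#' @rdname offsets
#' @export
setMethod("offsets", "BiosignatureResult", function(x) x@offsets)

setMethod("show", "BiosignatureResult", function(object) {
    n <- nrow(object@offsets)
    cat(sprintf(
        "BiosignatureResult: %d carbonate sample(s) vs equilibrium %.3f permil\n",
        n, object@prediction@delta13cAragEq
    ))
    s <- object@summary
    cat(sprintf(
        "  offsets: min %.2f / mean %.2f / max %.2f permil (sd %.2f)\n",
        s["min"], s["mean"], s["max"], s["sd"]
    ))
    print(table(object@offsets$classification))
})
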