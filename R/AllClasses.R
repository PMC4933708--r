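#' @title Core S4 classes
#' @name thromboSig-classes
#' @description S4 containers used across the package: DIC speciation results,
#'   temperature-dependent fractionation sets, equilibrium predictions,
#'   biosignature scoring results, and the count-table experiment container.
NULL

# ---------------------------------------------------------------------------
# DICSpeciation: mole fractions of the three DIC species at given pH and T.
# Vectorized over observations; all slots have equal length.

#' @rdname thromboSig-classes
#' @slot xCO2aq,xHCO3,xCO3 numeric mole fractions of DIC (sum to 1).
#' @slot k1,k2 numeric apparent dissociation constants of carbonic acid used.
#' @slot temperature,pH numeric conditions of the speciation.
#' @exportClass DICSpeciation
setClass("DICSpeciation",
    representation(
        xCO2aq = "numeric", xHCO3 = "numeric", xCO3 = "numeric",
        k1 = "numeric", k2 = "numeric",
        temperature = "numeric", pH = "numeric"
    )
)

setValidity("DICSpeciation", function(object) {
    n <- length(object@xCO2aq)
    lens <- c(
        length(object@xHCO3), length(object@xCO3), length(object@k1),
        length(object@k2), length(object@temperature), length(object@pH)
    )
    if (any(lens != n)) {
        return("all slots must have equal length")
    }
    fr <- cbind(object@xCO2aq, object@xHCO3, object@xCO3)
    if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1)) {
        return("mole fractions must be finite and in [0, 1]")
    }
    if (any(abs(rowSums(fr) - 1) > 1e-12)) {
        return("mole fractions must sum to 1 within 1e-12")
    }
    TRUE
})

# ---------------------------------------------------------------------------
# FractionationSet: named temperature-dependent enrichment functions, each
# mapping T (degrees C) to an enrichment epsilon in permil.

#' @rdname thromboSig-classes
#' @slot epsAragHCO3 function(T degC) -> permil enrichment of aragonite over
#'   HCO3-.
#' @slot epsCO2aqHCO3 function(T degC) -> permil enrichment of CO2(aq) over
#'   HCO3- (negative: CO2(aq) is the 13C-depleted species).
#' @slot epsCO3HCO3 function(T degC) -> permil enrichment of CO3(2-) over
#'   HCO3-.
#' @slot provenance character tag naming the coefficient sources.
#' @exportClass FractionationSet
setClass("FractionationSet",
    representation(
        epsAragHCO3 = "function",
        epsCO2aqHCO3 = "function",
        epsCO3HCO3 = "function",
        provenance = "character"
    )
)

setValidity("FractionationSet", function(object) {
    grid <- c(0, 10, 25, 40, 50)
    for (nm in c("epsAragHCO3", "epsCO2aqHCO3", "epsCO3HCO3")) {
        v <- tryCatch(slot(object, nm)(grid), error = function(e) NA_real_)
        if (length(v) != length(grid) || any(!is.finite(v))) {
            return(sprintf("%s must return finite values on [0, 50] degC", nm))
        }
    }
    if (length(object@provenance) != 1L) {
        return("provenance must be a single string")
    }
    TRUE
})

# ---------------------------------------------------------------------------
# EquilibriumPrediction: bicarbonate delta-13C and the theoretical equilibrium
# aragonite delta-13C derived from it.

#' @rdname thromboSig-classes
#' @slot delta13cHCO3 numeric delta-13C of HCO3- (permil VPDB).
#' @slot delta13cAragEq numeric theoretical equilibrium aragonite delta-13C.
#' @slot sourceSampleId character id of the water sample the maximum traces to.
#' @exportClass EquilibriumPrediction
setClass("EquilibriumPrediction",
    representation(
        delta13cHCO3 = "numeric",
        delta13cAragEq = "numeric",
        temperature = "numeric",
        pH = "numeric",
        sourceSampleId = "character"
    )
)

setValidity("EquilibriumPrediction", function(object) {
    if (length(object@delta13cHCO3) != 1L || length(object@delta13cAragEq) != 1L) {
        return("delta13cHCO3 and delta13cAragEq must be scalars")
    }
    if (!is.finite(object@delta13cHCO3) || !is.finite(object@delta13cAragEq)) {
        return("prediction values must be finite")
    }
    TRUE
})

# ---------------------------------------------------------------------------
# BiosignatureResult: per-carbonate-sample offsets vs the equilibrium
# prediction, with sign-based classification and summary statistics.

#' @rdname thromboSig-classes
#' @slot offsets data.frame with one row per carbonate sample (id, core,
#'   depths, measured delta-13C, offset, classification).
#' @slot summary named numeric: min, max, mean, sd of the offsets.
#' @slot tolerance numeric permil half-width of the "equilibrium" class.
#' @slot prediction the [EquilibriumPrediction-class] scored against.
#' @exportClass BiosignatureResult
setClass("BiosignatureResult",
    representation(
        offsets = "data.frame",
        summary = "numeric",
        tolerance = "numeric",
        prediction = "EquilibriumPrediction"
    )
)

setValidity("BiosignatureResult", function(object) {
    need <- c("id", "delta13cCaco3", "offset", "classification")
    if (!all(need %in% names(object@offsets))) {
        return("offsets table lacks required columns")
    }
    ok <- c("photoautotrophic", "equilibrium", "heterotrophic")
    if (!all(object@offsets$classification %in% ok)) {
        return("unknown classification label")
    }
    TRUE
})

# ---------------------------------------------------------------------------
# MatExperiment: feature-by-sample count container with mat-type labels.
# Extends SummarizedExperiment; the "counts" assay holds non-negative values
# (integers for raw tables; depth normalization yields non-negative reals).

#' @rdname thromboSig-classes
#' @exportClass MatExperiment
setClass("MatExperiment", contains = "SummarizedExperiment")

setValidity("MatExperiment", function(object) {
    if (!"counts" %in% assayNames(object)) {
        return("a 'counts' assay is required")
    }
    m <- assay(object, "counts")
    if (any(!is.finite(m)) || any(m < 0)) {
        return("counts must be finite and non-negative")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object))) {
        return("feature ids must be present and unique")
    }
    if (is.null(colnames(object)) || anyDuplicated(colnames(object))) {
        return("sample ids must be present and unique")
    }
    if (!"group" %in% names(colData(object))) {
        return("colData must contain a 'group' column")
    }
    g <- colData(object)$group
    if (any(is.na(g)) || any(!nzchar(as.character(g)))) {
        return("every sample must carry a non-missing group label")
    }
    TRUE
})
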