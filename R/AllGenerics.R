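#' Group labels of a MatExperiment
#'
#' @param x a [MatExperiment-class].
#' @return character vector of per-sample group labels (e.g. `"thrombolite"`,
#'   `"sediment"`), named by sample id.
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' Mole fractions of the DIC species
#'
#' @param x a [DICSpeciation-class].
#' @return numeric matrix with columns `xCO2aq`, `xHCO3`, `xCO3`, one row per
#'   speciated condition.
#' @export
setGeneric("moleFractions", function(x) standardGeneric("moleFractions"))

#' Evaluate the enrichment functions of a FractionationSet
#'
#' @param x a [FractionationSet-class].
#' @param temperature numeric temperature(s) in degrees C.
#' @return data.frame with the three enrichments (permil) at each temperature.
#' @export
setGeneric("epsilons", function(x, temperature) standardGeneric("epsilons"))

#' Per-sample biosignature offsets
#'
#' @param x a [BiosignatureResult-class].
#' @return the per-sample offsets table (data.frame).
#' @export
setGeneric("offsets", function(x) standardGeneric("offsets"))
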