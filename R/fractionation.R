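#' Temperature-dependent carbon-isotope fractionation set
#'
#' Bundles the equilibrium enrichment factors (permil) that tie the delta-13C
#' of each DIC species and of aragonite to the delta-13C of bicarbonate, each
#' as a function of temperature in degrees C. The default coefficient set is:
#'
#' * aragonite - CO2(g): 13.88 - 0.13 T (Romanek, Grossman & Morse 1992,
#'   linear in degrees C);
#' * HCO3- - CO2(g): 9483/T_K - 23.89 (Mook, Bommerson & Staverman 1974,
#'   hyperbolic in kelvin);
#' * CO2(aq) - HCO3-: -9866/T_K + 24.12 (Mook 1986 compilation);
#' * CO3(2-) - HCO3-: -867/T_K + 2.52 (Mook 1986 compilation);
#'
#' with the aragonite-bicarbonate enrichment formed as the difference of the
#' first two, eps(arag - HCO3)(T) = eps(arag - CO2 g)(T) - eps(HCO3 - CO2 g)(T).
#' At 25 C this evaluates to 2.71 permil, the anchor value against which any
#' alternative coefficient set should be validated. Custom enrichment
#' functions may be supplied (e.g. identically zero for closure tests).
#'
#' @param epsAragHCO3,epsCO2aqHCO3,epsCO3HCO3 optional replacement functions
#'   of temperature (degrees C) returning permil enrichments.
#' @param provenance character tag recording the coefficient source set.
#' @return a [FractionationSet-class].
#' @examples
#' fr <- fractionationSet()
#' epsilons(fr, c(10, 25, 40))
#' @export
fractionationSet <- function(epsAragHCO3 = NULL,
                             epsCO2aqHCO3 = NULL,
                             epsCO3HCO3 = NULL,
                             provenance = "romanek1992-aragonite + mook1974/1986-DIC") {
    if (is.null(epsAragHCO3)) {
        epsAragHCO3 <- function(temperature) {
            (13.88 - 0.13 * temperature) -
                (9483 / (temperature + 273.15) - 23.89)
        }
    }
    if (is.null(epsCO2aqHCO3)) {
        epsCO2aqHCO3 <- function(temperature) {
            -9866 / (temperature + 273.15) + 24.12
        }
    }
    if (is.null(epsCO3HCO3)) {
        epsCO3HCO3 <- function(temperature) {
            -867 / (temperature + 273.15) + 2.52
        }
    }
    new("FractionationSet",
        epsAragHCO3 = epsAragHCO3,
        epsCO2aqHCO3 = epsCO2aqHCO3,
        epsCO3HCO3 = epsCO3HCO3,
        provenance = provenance
    )
}

#' @rdname epsilons
#' @export
setMethod("epsilons", "FractionationSet", function(x, temperature) {
    data.frame(
        temperature = temperature,
        epsAragHCO3 = x@epsAragHCO3(temperature),
        epsCO2aqHCO3 = x@epsCO2aqHCO3(temperature),
        epsCO3HCO3 = x@epsCO3HCO3(temperature)
    )
})

setMethod("show", "FractionationSet", function(object) {
    cat("FractionationSet [", object@provenance, "]\n", sep = "")
    e <- epsilons(object, 25)
    cat(sprintf(
        "  at 25 degC: eps(arag-HCO3) = %.2f, eps(CO2aq-HCO3) = %.2f, eps(CO3-HCO3) = %.2f permil\n",
        e$epsAragHCO3, e$epsCO2aqHCO3, e$epsCO3HCO3
    ))
})
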