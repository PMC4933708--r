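#' Apparent dissociation constants of carbonic acid
#'
#' First and second apparent dissociation constants K1, K2 of carbonic acid as
#' a function of temperature. Two parameterizations are available:
#'
#' * `"freshwater"` (default): the Plummer & Busenberg (1982) temperature
#'   polynomials for the thermodynamic constants in dilute solution
#'   (molal, activity convention). pK1(25 C) = 6.352, pK2(25 C) = 10.329.
#' * `"saline"`: apparent (stoichiometric) seawater constants from the
#'   Dickson & Millero (1987) refit of Mehrbach's measurements, as a function
#'   of temperature and salinity (default S = 35). Activity coefficients of
#'   the carbonate species are absorbed into the constants; no Pitzer model
#'   is attempted.
#'
#' @param temperature numeric, degrees C in \[0, 50\].
#' @param variant `"freshwater"` or `"saline"`.
#' @param salinity practical salinity used by the `"saline"` variant.
#' @return list with numeric vectors `k1` and `k2` (same length as
#'   `temperature`).
#' @examples
#' carbonicAcidConstants(25)
#' @export
carbonicAcidConstants <- function(temperature,
                                  variant = c("freshwater", "saline"),
                                  salinity = 35) {
    variant <- match.arg(variant)
    if (any(!is.finite(temperature)) ||
        any(temperature < 0) || any(temperature > 50)) {
        stop("'temperature' must lie in [0, 50] degrees C", call. = FALSE)
    }
    tk <- temperature + 273.15
    if (variant == "freshwater") {
        logk1 <- -356.3094 - 0.06091964 * tk + 21834.37 / tk +
            126.8339 * log10(tk) - 1684915 / tk^2
        logk2 <- -107.8871 - 0.03252849 * tk + 5151.79 / tk +
            38.92561 * log10(tk) - 563713.9 / tk^2
        list(k1 = 10^logk1, k2 = 10^logk2)
    } else {
        s <- salinity
        pk1 <- 3670.7 / tk - 62.008 + 9.7944 * log(tk) -
            0.0118 * s + 0.000116 * s^2
        pk2 <- 1394.7 / tk + 4.777 - 0.0184 * s + 0.000118 * s^2
        list(k1 = 10^(-pk1), k2 = 10^(-pk2))
    }
}

#' Estimate salinity (TDS) from specific conductance
#'
#' Log-log conductivity-salinity power-law regression for Australian salt
#' lakes (Williams 1986): TDS (g/L) = 0.4665 * SC^1.0878 with SC the specific
#' conductance in mS/cm at 25 C. Appropriate for hypersaline lake waters well
#' above the dilute range.
#'
#' @param sc numeric specific conductance, mS/cm (must be > 0).
#' @return numeric estimated total dissolved solids, g/L.
#' @examples
#' salinityFromConductance(c(121.4, 188.2))
#' @export
salinityFromConductance <- function(sc) {
    if (any(!is.finite(sc)) || any(sc <= 0)) {
        stop("'sc' (specific conductance) must be positive and finite",
            call. = FALSE
        )
    }
    0.4665 * sc^1.0878
}
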