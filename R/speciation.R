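#' Speciate dissolved inorganic carbon from pH and temperature
#'
#' Partitions DIC into mole fractions of CO2(aq), HCO3- and CO3(2-) by mass
#' action: x_CO2aq : x_HCO3 : x_CO3 = 1 : K1/aH : K1 K2 / aH^2 with
#' aH = 10^(-pH), normalized to sum to one. pH is treated as hydrogen-ion
#' activity; the apparent constants absorb activity coefficients of the
#' carbonate species (see [carbonicAcidConstants()]).
#'
#' @param ph numeric pH in \[2, 12\] (activity scale).
#' @param temperature numeric degrees C in \[0, 50\]. Recycled against `ph`.
#' @param variant constants variant passed to [carbonicAcidConstants()].
#' @param k1,k2 optional numeric overrides for the dissociation constants
#'   (e.g. `k2 = 0` to collapse the carbonate branch in limiting-case checks).
#' @param salinity salinity for the `"saline"` variant.
#' @return a [DICSpeciation-class] (vectorized over the inputs).
#' @examples
#' sp <- speciateDIC(ph = 7.54, temperature = 25)
#' moleFractions(sp)
#' @export
speciateDIC <- function(ph, temperature,
                        variant = c("freshwater", "saline"),
                        k1 = NULL, k2 = NULL, salinity = 35) {
    variant <- match.arg(variant)
    if (any(!is.finite(ph)) || any(ph < 2) || any(ph > 12)) {
        stop("'ph' must lie in [2, 12]", call. = FALSE)
    }
    if (any(!is.finite(temperature)) ||
        any(temperature < 0) || any(temperature > 50)) {
        stop("'temperature' must lie in [0, 50] degrees C", call. = FALSE)
    }
    n <- max(length(ph), length(temperature))
    ph <- rep_len(ph, n)
    temperature <- rep_len(temperature, n)
    ks <- carbonicAcidConstants(temperature, variant, salinity)
    if (!is.null(k1)) ks$k1 <- rep_len(k1, n)
    if (!is.null(k2)) ks$k2 <- rep_len(k2, n)
    ah <- 10^(-ph)
    r1 <- rep_len(1, n)
    r2 <- ks$k1 / ah
    r3 <- ks$k1 * ks$k2 / ah^2
    tot <- r1 + r2 + r3
    new("DICSpeciation",
        xCO2aq = r1 / tot, xHCO3 = r2 / tot, xCO3 = r3 / tot,
        k1 = ks$k1, k2 = ks$k2,
        temperature = temperature, pH = ph
    )
}

#' @rdname moleFractions
#' @export
setMethod("moleFractions", "DICSpeciation", function(x) {
    cbind(xCO2aq = x@xCO2aq, xHCO3 = x@xHCO3, xCO3 = x@xCO3)
})

setMethod("show", "DICSpeciation", function(object) {
    n <- length(object@pH)
    cat(sprintf("DICSpeciation with %d condition(s)\n", n))
    k <- min(n, 5L)
    df <- data.frame(
        pH = object@pH[seq_len(k)],
        temperature = object@temperature[seq_len(k)],
        round(moleFractions(object)[seq_len(k), , drop = FALSE], 5)
    )
    print(df, row.names = FALSE)
    if (n > k) cat("  ...", n - k, "more\n")
})
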