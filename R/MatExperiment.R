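#' Feature-by-sample count container with mat-type labels
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding a
#' non-negative `counts` assay (taxa at a chosen rank, or KEGG orthologs, by
#' sample) and a per-sample `group` label (e.g. `"thrombolite"` vs
#' `"sediment"`). Raw tables are integer; depth-normalized tables may hold
#' non-negative reals.
#'
#' @param counts numeric matrix, features x samples, non-negative, with row
#'   and column names.
#' @param group character/factor of per-sample group labels (length =
#'   `ncol(counts)`).
#' @return a [MatExperiment-class].
#' @examples
#' m <- matrix(rpois(20, 10), 5, 4,
#'     dimnames = list(paste0("f", 1:5), paste0("s", 1:4))
#' )
#' me <- MatExperiment(m, rep(c("thrombolite", "sediment"), each = 2))
#' groupLabels(me)
#' @export
MatExperiment <- function(counts, group) {
    counts <- as.matrix(counts)
    if (length(group) != ncol(counts)) {
        stop("'group' must have one label per sample", call. = FALSE)
    }
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        colData = DataFrame(group = as.character(group), row.names = colnames(counts))
    )
    new("MatExperiment", se)
}

#' @rdname groupLabels
#' @export
setMethod("groupLabels", "MatExperiment", function(x) {
    setNames(as.character(colData(x)$group), colnames(x))
})

#' Counts assay of a MatExperiment
#'
#' @param object a [MatExperiment-class].
#' @return the `counts` assay matrix.
#' @export
setMethod("counts", "MatExperiment", function(object) {
    assay(object, "counts")
})

setMethod("show", "MatExperiment", function(object) {
    callNextMethod()
    g <- table(groupLabels(object))
    cat(
        "group:",
        paste(sprintf("%s (n=%d)", names(g), as.integer(g)), collapse = ", "),
        "\n"
    )
})

# Internal: accept MatExperiment or plain matrix in stage functions.
.countsOf <- function(x) {
    if (is(x, "MatExperiment")) counts(x) else as.matrix(x)
}

.groupsOf <- function(x, groups = NULL) {
    if (is.null(groups)) {
        if (!is(x, "MatExperiment")) {
            stop("'groups' is required when 'x' is not a MatExperiment",
                call. = FALSE
            )
        }
        groups <- groupLabels(x)
    }
    as.character(groups)
}
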