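#' Read a water-sample TSV
#'
#' Expected columns: `id`, `source` (lake|groundwater), `temperature_c`
#' (may be empty), `ph`, `sc_ms_cm` (may be empty), `d13c_dic_permil`.
#' Empty fields become `NA`.
#'
#' @param path TSV file path.
#' @return validated water-sample data.frame (see [waterSamples()]).
#' @export
readWaterSamples <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
    need <- c("id", "source", "temperature_c", "ph", "sc_ms_cm", "d13c_dic_permil")
    if (!all(need %in% names(df))) {
        stop(
            "water TSV lacks column(s): ",
            paste(setdiff(need, names(df)), collapse = ", "),
            call. = FALSE
        )
    }
    waterSamples(
        id = df$id, source = df$source, temperature = df$temperature_c,
        ph = df$ph, conductance = df$sc_ms_cm, d13cDic = df$d13c_dic_permil
    )
}

#' Write a water-sample table as TSV
#'
#' @param water data.frame from [waterSamples()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeWaterSamples <- function(water, path) {
    water <- validateWaterSamples(water)
    out <- data.frame(
        id = water$id, source = water$source,
        temperature_c = water$temperature, ph = water$ph,
        sc_ms_cm = water$conductance, d13c_dic_permil = water$d13cDic
    )
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    invisible(path)
}

#' Read a carbonate-sample TSV
#'
#' Expected columns: `id`, `core`, `depth_top_cm`, `depth_bottom_cm`,
#' `d13c_caco3_permil`.
#'
#' @param path TSV file path.
#' @return validated carbonate-sample data.frame (see [carbonateSamples()]).
#' @export
readCarbonateSamples <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
    need <- c("id", "core", "depth_top_cm", "depth_bottom_cm", "d13c_caco3_permil")
    if (!all(need %in% names(df))) {
        stop(
            "carbonate TSV lacks column(s): ",
            paste(setdiff(need, names(df)), collapse = ", "),
            call. = FALSE
        )
    }
    carbonateSamples(
        id = df$id, core = df$core, depthTop = df$depth_top_cm,
        depthBottom = df$depth_bottom_cm, d13cCaco3 = df$d13c_caco3_permil
    )
}

#' Write a carbonate-sample table as TSV
#'
#' @param carbonates data.frame from [carbonateSamples()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeCarbonateSamples <- function(carbonates, path) {
    carbonates <- validateCarbonateSamples(carbonates)
    out <- data.frame(
        id = carbonates$id, core = carbonates$core,
        depth_top_cm = carbonates$depthTop,
        depth_bottom_cm = carbonates$depthBottom,
        d13c_caco3_permil = carbonates$d13cCaco3
    )
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    invisible(path)
}

#' Read a count table + sample metadata into a MatExperiment
#'
#' The count TSV has the feature id in the first column and one column per
#' sample (header row required). The metadata TSV has columns `sample_id`
#' and `group`; every count-table sample must appear in it.
#'
#' @param countsPath count-table TSV path.
#' @param metadataPath sample-metadata TSV path.
#' @return a [MatExperiment-class].
#' @export
readCountTable <- function(countsPath, metadataPath) {
    df <- read.delim(countsPath, stringsAsFactors = FALSE, check.names = FALSE)
    if (ncol(df) < 2L) {
        stop("count TSV needs a feature-id column plus >= 1 sample column",
            call. = FALSE
        )
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    storage.mode(m) <- "numeric"
    meta <- read.delim(metadataPath, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "group") %in% names(meta))) {
        stop("metadata TSV needs columns 'sample_id' and 'group'",
            call. = FALSE
        )
    }
    missing <- setdiff(colnames(m), meta$sample_id)
    if (length(missing)) {
        stop(
            "sample(s) missing from metadata: ",
            paste(missing, collapse = ", "),
            call. = FALSE
        )
    }
    grp <- meta$group[match(colnames(m), meta$sample_id)]
    MatExperiment(m, grp)
}

#' Write a MatExperiment (or counts matrix) and its metadata as TSV
#'
#' @param x a [MatExperiment-class].
#' @param countsPath output count-table TSV path.
#' @param metadataPath optional output metadata TSV path.
#' @return `countsPath`, invisibly.
#' @export
writeCountTable <- function(x, countsPath, metadataPath = NULL) {
    m <- .countsOf(x)
    out <- data.frame(feature = rownames(m), m, check.names = FALSE)
    write.table(out, countsPath,
        sep = "\t", quote = FALSE, row.names = FALSE
    )
    if (!is.null(metadataPath)) {
        if (!is(x, "MatExperiment")) {
            stop("metadata can only be written from a MatExperiment",
                call. = FALSE
            )
        }
        meta <- data.frame(
            sample_id = colnames(m), group = unname(groupLabels(x))
        )
        write.table(meta, metadataPath,
            sep = "\t", quote = FALSE, row.names = FALSE
        )
    }
    invisible(countsPath)
}

#' Write a square distance matrix as TSV
#'
#' @param d symmetric distance matrix with sample-id dimnames.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeDistanceMatrix <- function(d, path) {
    d <- as.matrix(d)
    out <- data.frame(sample = rownames(d), d, check.names = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
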