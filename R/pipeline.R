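#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates the three analysis stages from TSV inputs and writes a report
#' bundle to `outDir`:
#'
#' * geochemistry (needs `waterTsv` + `carbonateTsv`): equilibrium prediction
#'   and biosignature offsets -> `biosignature_report.tsv`,
#'   `biosignature_summary.tsv` (key/value);
#' * community ecology (needs `countsTsv` + `metadataTsv`): depth
#'   normalization, Bray-Curtis, PCoA, UPGMA, PERMANOVA ->
#'   `bray_curtis_distance.tsv`, `pcoa_coordinates.tsv`,
#'   `pcoa_variance.tsv`, `upgma.nwk`, `permanova.tsv`;
#' * differential abundance (same count inputs, raw counts): NB Wald + BH +
#'   enrichment filter -> `diffabund_results.tsv`, `diffabund_filtered.tsv`.
#'
#' Stages whose inputs are absent are skipped with a logged notice, never
#' silently fabricated. A `run_log.txt` records package version, seed and
#' parameters. Reruns with the same config and seed are numerically
#' identical.
#'
#' @param config named list, or path to a YAML file with the same structure.
#'   Recognized entries: `waterTsv`, `carbonateTsv`, `countsTsv`,
#'   `metadataTsv`, `outDir` (required), `seed` (default 1), and the stage
#'   parameters `tRange`, `constantsVariant`, `tolerance`, `depth`, `nPerm`,
#'   `focalGroup`, `alpha`, `minAbsLog2fc`, `minBaseMean`.
#' @return invisible list with the stage results (`biosignature`,
#'   `ecology`, `diffabund`; absent stages are `NULL`).
#' @export
runPipeline <- function(config) {
    if (is.character(config) && length(config) == 1L) {
        config <- yaml::read_yaml(config)
    }
    stopifnot(is.list(config))
    defaults <- list(
        seed = 1L, tRange = c(10, 40), constantsVariant = "freshwater",
        tolerance = 0.1, depth = 221168, nPerm = 999,
        focalGroup = NULL, alpha = 0.05, minAbsLog2fc = 1, minBaseMean = 2000
    )
    cfg <- modifyList(defaults, config)
    if (is.null(cfg$outDir)) stop("'outDir' is required", call. = FALSE)
    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
    logLines <- c(
        sprintf("thromboSig %s", as.character(packageVersion("thromboSig"))),
        sprintf("seed: %d", as.integer(cfg$seed)),
        sprintf(
            "params: tRange=[%s], constantsVariant=%s, depth=%s, nPerm=%d, alpha=%g, minAbsLog2fc=%g, minBaseMean=%g",
            paste(cfg$tRange, collapse = ", "), cfg$constantsVariant,
            format(cfg$depth), cfg$nPerm, cfg$alpha, cfg$minAbsLog2fc,
            cfg$minBaseMean
        )
    )
    note <- function(msg) {
        logLines <<- c(logLines, msg)
        message(msg)
    }
    inStage <- function(stage, expr) {
        tryCatch(expr, error = function(e) {
            stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
        })
    }
    out <- list(biosignature = NULL, ecology = NULL, diffabund = NULL)

    # --- geochemistry ------------------------------------------------------
    if (!is.null(cfg$waterTsv) && !is.null(cfg$carbonateTsv)) {
        out$biosignature <- inStage("geochem", {
            water <- readWaterSamples(cfg$waterTsv)
            carb <- readCarbonateSamples(cfg$carbonateTsv)
            pred <- maxEquilibriumPrediction(
                water,
                tRange = cfg$tRange, variant = cfg$constantsVariant
            )
            bio <- biosignatureOffsets(carb, pred, tolerance = cfg$tolerance)
            write.table(offsets(bio),
                file.path(cfg$outDir, "biosignature_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE
            )
            summ <- c(
                delta13c_hco3_max = pred@delta13cHCO3,
                delta13c_arag_eq_max = pred@delta13cAragEq,
                prediction_temperature_c = pred@temperature,
                prediction_ph = pred@pH,
                offset_min = unname(bio@summary["min"]),
                offset_max = unname(bio@summary["max"]),
                offset_mean = unname(bio@summary["mean"]),
                offset_sd = unname(bio@summary["sd"])
            )
            write.table(
                data.frame(key = names(summ), value = unname(summ)),
                file.path(cfg$outDir, "biosignature_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE
            )
            note("geochem: biosignature report written")
            bio
        })
    } else {
        note("geochem: skipped (no water/carbonate inputs)")
    }

    # --- community ecology + differential abundance ------------------------
    if (!is.null(cfg$countsTsv) && !is.null(cfg$metadataTsv)) {
        me <- inStage("ecology", readCountTable(cfg$countsTsv, cfg$metadataTsv))
        out$ecology <- inStage("ecology", {
            norm <- normalizeDepth(me, depth = cfg$depth)
            d <- brayCurtis(norm)
            ord <- pcoaOrdination(d)
            tree <- upgmaTree(d)
            pmv <- permanovaTest(
                d, groupLabels(me),
                nPerm = cfg$nPerm, seed = cfg$seed
            )
            writeDistanceMatrix(
                d, file.path(cfg$outDir, "bray_curtis_distance.tsv")
            )
            write.table(
                data.frame(
                    sample = rownames(ord$coordinates), ord$coordinates,
                    check.names = FALSE
                ),
                file.path(cfg$outDir, "pcoa_coordinates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE
            )
            write.table(
                data.frame(
                    axis = colnames(ord$coordinates),
                    varianceExplained = ord$varianceExplained
                ),
                file.path(cfg$outDir, "pcoa_variance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE
            )
            ape::write.tree(tree, file.path(cfg$outDir, "upgma.nwk"))
            write.table(
                data.frame(
                    pseudoF = pmv$f, r2 = pmv$r2, p = pmv$p, nPerm = pmv$nPerm
                ),
                file.path(cfg$outDir, "permanova.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE
            )
            note(sprintf(
                "ecology: PERMANOVA R2 = %.3f, p = %.4g", pmv$r2, pmv$p
            ))
            list(distance = d, ordination = ord, tree = tree, permanova = pmv)
        })
        out$diffabund <- inStage("diffabund", {
            da <- diffAbundance(
                me,
                focalGroup = cfg$focalGroup, alpha = cfg$alpha,
                minAbsLog2fc = cfg$minAbsLog2fc, minBaseMean = cfg$minBaseMean
            )
            write.table(da$results,
                file.path(cfg$outDir, "diffabund_results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE
            )
            write.table(da$filtered,
                file.path(cfg$outDir, "diffabund_filtered.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE
            )
            note(sprintf(
                "diffabund: %d/%d features pass the enrichment filter",
                nrow(da$filtered), nrow(da$results)
            ))
            da
        })
    } else {
        note("ecology/diffabund: skipped (no count-table inputs)")
    }

    writeLines(logLines, file.path(cfg$outDir, "run_log.txt"))
    invisible(out)
}
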