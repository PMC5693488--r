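# Plain-text interchange: TSV count/annotation tables and JSON for
# configurations, models and truth records.

#' Read and write count matrices as TSV
#'
#' Counts are exchanged as tab-separated text with genes as rows: the first
#' column (\code{gene_id}) holds gene identifiers, remaining columns are
#' samples with integer cells.
#'
#' @param x integer matrix (genes x samples) or a
#'   \code{SummarizedExperiment} with a \code{"counts"} assay.
#' @param path file path.
#' @return \code{readCounts} returns an integer matrix with gene row names.
#' @export
writeCounts <- function(x, path) {
    if (is(x, "SummarizedExperiment"))
        x <- SummarizedExperiment::assay(x, "counts")
    df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeCounts
#' @export
readCounts <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- df[[1]]
    m
}

#' Read and write sample annotation tables as TSV
#'
#' One row per sample; columns follow the sample-annotation contract
#' (sample_id, subject_id, class_label, tissue_role, lab_id, run_id,
#' replicate_index, input_mass_ng, storage_days_cold, dv200).
#'
#' @param ann data.frame of annotations.
#' @param path file path.
#' @return \code{readAnnotations} returns a data.frame.
#' @export
writeAnnotations <- function(ann, path) {
    utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeAnnotations
#' @export
readAnnotations <- function(path) {
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a transformed (VST) matrix as TSV
#'
#' Floating-point values are written with six significant digits, genes as
#' rows.
#'
#' @param x numeric matrix.
#' @param path file path.
#' @export
writeTransformed <- function(x, path) {
    df <- data.frame(gene_id = rownames(x),
                     signif(x, 6), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Serialize a generator configuration to JSON
#'
#' The JSON document mirrors the \code{GeneratorConfig} slot names, so a
#' configuration round-trips exactly.
#'
#' @param config a \code{GeneratorConfig}.
#' @param path file path.
#' @return \code{readGeneratorConfig} returns a \code{GeneratorConfig}.
#' @export
writeGeneratorConfig <- function(config, path) {
    sl <- slotNames(config)
    v <- lapply(sl, function(s) slot(config, s))
    names(v) <- sl
    jsonlite::write_json(v, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeGeneratorConfig
#' @export
readGeneratorConfig <- function(path) {
    v <- jsonlite::read_json(path, simplifyVector = TRUE)
    do.call(generatorConfig, lapply(v, as.numeric))
}

#' Serialize a simulation truth record to JSON
#'
#' Truth records (the injected subject/lab/run/residual effect values of a
#' simulated study) are written with full floating-point precision so they
#' round-trip bit-identically.
#'
#' @param truth truth-record list from \code{\link{simulateStudy}} metadata.
#' @param path file path.
#' @return \code{readTruthRecord} returns the truth list.
#' @export
writeTruthRecord <- function(truth, path) {
    jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeTruthRecord
#' @export
readTruthRecord <- function(path) {
    jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Serialize a locked classifier model to JSON
#'
#' Weights, intercept, calibration, frozen preprocessing parameters and
#' training metadata are written with full precision; a model read back
#' scores identically to the original.
#'
#' @param model a \code{ClassifierModel}.
#' @param path file path.
#' @return \code{readClassifierModel} returns a \code{ClassifierModel}.
#' @export
writeClassifierModel <- function(model, path) {
    v <- list(
        genes = names(model@weights),
        weights = unname(model@weights),
        intercept = model@intercept,
        scale = model@scale,
        boundary = model@boundary,
        refLogMeans = unname(model@refLogMeans),
        dispersion = model@dispersion,
        metadata = model@metadata)
    jsonlite::write_json(v, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeClassifierModel
#' @export
readClassifierModel <- function(path) {
    v <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("ClassifierModel",
        weights = setNames(as.numeric(v$weights), v$genes),
        intercept = as.numeric(v$intercept),
        scale = as.numeric(v$scale),
        boundary = as.numeric(v$boundary),
        refLogMeans = setNames(as.numeric(v$refLogMeans), v$genes),
        dispersion = as.numeric(v$dispersion),
        metadata = as.list(v$metadata))
}
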