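#' @rdname GenePanel-class
#' @param object,x a \code{GenePanel}
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GenePanel-class
#' @export
setMethod("geneIds", "GenePanel", function(x) x@geneIds)

#' @rdname GenePanel-class
#' @export
setGeneric("markerGene", function(x) standardGeneric("markerGene"))

#' @rdname GenePanel-class
#' @export
setMethod("markerGene", "GenePanel", function(x) x@markerGene)

#' @rdname GenePanel-class
#' @export
setGeneric("exonicLength", function(x) standardGeneric("exonicLength"))

#' @rdname GenePanel-class
#' @export
setMethod("exonicLength", "GenePanel",
    function(x) setNames(x@exonicLength, x@geneIds))

setMethod("show", "GenePanel", function(object) {
    cat("GenePanel with", length(object@geneIds), "genes\n")
    cat("  marker gene:", object@markerGene, "\n")
    cat("  exonic length: median",
        round(median(object@exonicLength)), "bases\n")
})

#' @rdname ExpressionProfile-class
#' @param x an \code{ExpressionProfile}
#' @export
setGeneric("abundance", function(x) standardGeneric("abundance"))

#' @rdname ExpressionProfile-class
#' @export
setMethod("abundance", "ExpressionProfile", function(x) x@abundance)

#' @rdname ExpressionProfile-class
#' @export
setGeneric("dispersion", function(x) standardGeneric("dispersion"))

#' @rdname ExpressionProfile-class
#' @export
setMethod("dispersion", "ExpressionProfile", function(x) x@dispersion)

#' @rdname ExpressionProfile-class
#' @export
setGeneric("profileName", function(x) standardGeneric("profileName"))

#' @rdname ExpressionProfile-class
#' @export
setMethod("profileName", "ExpressionProfile", function(x) x@name)

setMethod("show", "ExpressionProfile", function(object) {
    cat("ExpressionProfile '", object@name, "' over ",
        length(object@abundance), " genes\n", sep = "")
    cat("  dispersion alpha:", object@dispersion, "\n")
    top <- sort(object@abundance, decreasing = TRUE)[1:3]
    cat("  top genes:", paste(names(top), signif(top, 3), collapse = ", "),
        "\n")
})

setMethod("show", "GeneratorConfig", function(object) {
    cat("GeneratorConfig:", object@nGenes, "genes,",
        object@nDiscriminating, "discriminating (|logFC|",
        object@logFoldChange, ")\n")
    cat("  depth", format(object@depth, scientific = TRUE),
        " dispersion", object@dispersion, "\n")
    cat("  technical SDs (run/lab/residual):",
        paste(signif(c(object@runEffectSD, object@labEffectSD,
                       object@residualSD), 3), collapse = "/"), "\n")
    cat("  marker fractions (blood/tissue):",
        object@pureBloodMarkerFraction, "/",
        object@baselineMarkerFraction, "\n")
})

#' @rdname ClassifierModel-class
#' @param x a \code{ClassifierModel}
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))

#' @rdname ClassifierModel-class
#' @export
setMethod("modelWeights", "ClassifierModel", function(x) x@weights)

#' @rdname ClassifierModel-class
#' @export
setGeneric("decisionBoundary", function(x) standardGeneric("decisionBoundary"))

#' @rdname ClassifierModel-class
#' @export
setMethod("decisionBoundary", "ClassifierModel", function(x) x@boundary)

setMethod("show", "ClassifierModel", function(object) {
    md <- object@metadata
    cat("Locked linear ClassifierModel on", length(object@weights),
        "VST features\n")
    cat("  boundary", object@boundary, "on display scale; calibration x",
        signif(object@scale, 4), "\n")
    if (length(md))
        cat("  trained on", md$nUIP, "UIP +", md$nNonUIP,
            "non-UIP samples (penalty", md$penalty, ")\n")
})

#' @rdname LODEstimate-class
#' @param x an \code{LODEstimate}
#' @export
setGeneric("lodValue", function(x) standardGeneric("lodValue"))

#' @rdname LODEstimate-class
#' @export
setMethod("lodValue", "LODEstimate", function(x) x@estimate)

#' @rdname LODEstimate-class
#' @export
setGeneric("lodCI", function(x) standardGeneric("lodCI"))

#' @rdname LODEstimate-class
#' @export
setMethod("lodCI", "LODEstimate", function(x) c(lower = x@lower,
                                                upper = x@upper))

setMethod("show", "LODEstimate", function(object) {
    cat("LODEstimate (", object@method, "): f = ",
        signif(object@estimate, 4), sep = "")
    if (is.finite(object@lower) || is.finite(object@upper))
        cat(" [", signif(object@lower, 4), ", ",
            signif(object@upper, 4), "]", sep = "")
    cat("  flag:", object@flag, "\n")
})

#' @rdname VarianceComponents-class
#' @param x a \code{VarianceComponents}
#' @export
setGeneric("componentSDs", function(x) standardGeneric("componentSDs"))

#' @rdname VarianceComponents-class
#' @export
setMethod("componentSDs", "VarianceComponents", function(x)
    c(within_run = x@withinRunSD, run_to_run = x@runToRunSD,
      interlab = x@interlabSD, interclass = x@interclassSD))

setMethod("show", "VarianceComponents", function(object) {
    sds <- componentSDs(object)
    cat("Score variance components (SD):\n")
    for (nm in names(sds)) {
        ci <- if (nm %in% rownames(object@ci)) object@ci[nm, ] else c(NA, NA)
        cat(sprintf("  %-11s %6s", nm, signif(sds[[nm]], 3)))
        if (all(is.finite(ci)))
            cat(sprintf("  [%s, %s]", signif(ci[1], 3), signif(ci[2], 3)))
        cat("\n")
    }
})
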