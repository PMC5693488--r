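#' @import methods
#' @importFrom stats median rnorm rpois rnbinom rlnorm rbinom rmultinom
#'   quantile sd var lm anova aov pnorm qnorm smooth.spline predict uniroot
#'   isoreg coef setNames rgamma runif complete.cases
NULL

#' GenePanel: the gene content of an expression panel
#'
#' A \code{GenePanel} holds the identifiers of the genes measured by a
#' targeted RNA-seq panel, the per-gene exonic length (in bases, used to
#' allocate reads contributed by contaminating genomic DNA), and the identity
#' of the blood marker gene whose read-count proportion quantifies blood
#' contamination (the hemoglobin-beta role).
#'
#' @slot geneIds character vector of unique gene identifiers.
#' @slot markerGene identifier of the blood marker gene; must be a panel member.
#' @slot exonicLength numeric vector of positive exonic lengths (bases),
#'   parallel to \code{geneIds}.
#'
#' @seealso \code{\link{makePanel}}
#' @export
setClass("GenePanel",
    representation(
        geneIds = "character",
        markerGene = "character",
        exonicLength = "numeric"
    )
)

setValidity("GenePanel", function(object) {
    msg <- character()
    if (length(object@geneIds) < 2L)
        msg <- c(msg, "panel must contain at least 2 genes")
    if (anyDuplicated(object@geneIds))
        msg <- c(msg, "gene identifiers must be unique")
    if (length(object@exonicLength) != length(object@geneIds))
        msg <- c(msg, "exonicLength must be parallel to geneIds")
    if (any(!is.finite(object@exonicLength)) || any(object@exonicLength <= 0))
        msg <- c(msg, "all exonic lengths must be positive and finite")
    if (length(object@markerGene) != 1L ||
        !(object@markerGene %in% object@geneIds))
        msg <- c(msg, "markerGene must be a single member of geneIds")
    if (length(msg)) msg else TRUE
})

#' ExpressionProfile: relative gene abundances for one tissue or contaminant
#'
#' An \code{ExpressionProfile} is the generative unit for every material the
#' verification battery touches: pooled transbronchial-biopsy (TBB) RNA of
#' either class, surgical-lung-biopsy (SLB) RNA, whole-blood RNA, adjacent
#' normal lung tissue, and genomic DNA background. It stores per-gene relative
#' abundances on the unit simplex plus the negative-binomial dispersion used
#' when counts are drawn from it.
#'
#' @slot name profile role label, e.g. \code{"uip_tbb"} or \code{"blood"}.
#' @slot abundance named nonnegative numeric vector summing to 1.
#' @slot dispersion negative-binomial dispersion alpha (>= 0) for counts drawn
#'   from this profile.
#'
#' @seealso \code{\link{makeProfiles}}, \code{\link{simulateCounts}}
#' @export
setClass("ExpressionProfile",
    representation(
        name = "character",
        abundance = "numeric",
        dispersion = "numeric"
    )
)

setValidity("ExpressionProfile", function(object) {
    msg <- character()
    if (length(object@name) != 1L)
        msg <- c(msg, "name must be a single string")
    if (is.null(names(object@abundance)))
        msg <- c(msg, "abundance must be named by gene")
    if (any(object@abundance < 0))
        msg <- c(msg, "abundances must be nonnegative")
    if (abs(sum(object@abundance) - 1) > 1e-9)
        msg <- c(msg, "abundances must sum to 1 within 1e-9")
    if (length(object@dispersion) != 1L || object@dispersion < 0)
        msg <- c(msg, "dispersion must be a single value >= 0")
    if (length(msg)) msg else TRUE
})

#' GeneratorConfig: parameters of the synthetic study generator
#'
#' Bundles every tunable of the synthetic-data generator: panel size, the
#' class-separation signature (number of discriminating genes and their
#' log-fold change), sequencing depth, negative-binomial dispersion, the
#' score-scale technical effect SDs (run, lab, residual replicate), the
#' mixing-fraction jitter of in silico mixtures, and the marker-fraction
#' anchors for blood contamination (pure-blood marker fraction 0.3075 and
#' baseline tissue marker fraction 0.003, the values implied by linear mixing
#' of a 0.3\% baseline to 7\% at 22\% blood).
#'
#' @slot nGenes panel size (default 190).
#' @slot nDiscriminating even number of class-discriminating genes.
#' @slot logFoldChange log-fold change (natural log) separating the classes on
#'   each discriminating gene.
#' @slot depth expected total read count per sample at nominal input mass.
#' @slot dispersion negative-binomial dispersion alpha for tissue profiles.
#' @slot bloodDispersion dispersion for the pooled whole-blood profile
#'   (pooled donor material is more homogeneous than individual biopsies).
#' @slot technicalDispersion dispersion used when re-drawing libraries from
#'   the same pooled RNA material (technical replicates): library-level
#'   overdispersion only, far below the between-subject value.
#' @slot runEffectSD,labEffectSD,residualSD score-scale SDs of run, lab and
#'   replicate-residual technical effects.
#' @slot fractionJitterSD SD of the Gaussian jitter on mixture mass fractions.
#' @slot pureBloodMarkerFraction marker-gene abundance of pure blood.
#' @slot baselineMarkerFraction marker-gene abundance of tissue profiles.
#' @slot massRefNg nominal RNA input mass (ng); effective depth scales as
#'   \code{(mass/massRefNg)^massDepthExponent}.
#' @slot massDepthExponent exponent of the mass-to-depth scaling; 0 gives a
#'   null generator in which input mass has no effect at all.
#' @slot massJitterSD lognormal depth-jitter SD at the reference mass; jitter
#'   grows as \code{sqrt(massRefNg/mass)} for lower inputs.
#' @slot classScoreGap score units spanned by the UIP vs non-UIP profile axis;
#'   converts score-scale technical effects into count-level tilts.
#' @slot seed base random seed fixing all downstream randomness.
#'
#' @seealso \code{\link{generatorConfig}}
#' @export
setClass("GeneratorConfig",
    representation(
        nGenes = "integer",
        nDiscriminating = "integer",
        logFoldChange = "numeric",
        depth = "numeric",
        dispersion = "numeric",
        bloodDispersion = "numeric",
        technicalDispersion = "numeric",
        runEffectSD = "numeric",
        labEffectSD = "numeric",
        residualSD = "numeric",
        fractionJitterSD = "numeric",
        pureBloodMarkerFraction = "numeric",
        baselineMarkerFraction = "numeric",
        massRefNg = "numeric",
        massDepthExponent = "numeric",
        massJitterSD = "numeric",
        classScoreGap = "numeric",
        seed = "integer"
    )
)

setValidity("GeneratorConfig", function(object) {
    msg <- character()
    if (object@nGenes < 2L)
        msg <- c(msg, "nGenes must be >= 2")
    if (object@nDiscriminating < 0L || object@nDiscriminating > object@nGenes - 1L)
        msg <- c(msg, "nDiscriminating must lie in [0, nGenes - 1]")
    if (object@nDiscriminating %% 2L != 0L)
        msg <- c(msg, "nDiscriminating must be even (balanced up/down signature)")
    if (object@depth <= 0)
        msg <- c(msg, "depth must be positive")
    sds <- c(object@runEffectSD, object@labEffectSD, object@residualSD,
             object@fractionJitterSD, object@massJitterSD)
    if (any(sds < 0))
        msg <- c(msg, "all SDs must be >= 0")
    fracs <- c(object@pureBloodMarkerFraction, object@baselineMarkerFraction)
    if (any(fracs < 0 | fracs > 1))
        msg <- c(msg, "marker fractions must lie in [0, 1]")
    if (object@dispersion < 0 || object@bloodDispersion < 0 ||
        object@technicalDispersion < 0)
        msg <- c(msg, "dispersions must be >= 0")
    if (object@massRefNg <= 0)
        msg <- c(msg, "massRefNg must be positive")
    if (object@classScoreGap <= 0)
        msg <- c(msg, "classScoreGap must be positive")
    if (length(msg)) msg else TRUE
})

#' ClassifierModel: a locked linear classifier on VST counts
#'
#' A surrogate for a locked classification algorithm: a linear decision
#' function on variance-stabilized normalized counts, an affine calibration
#' mapping the raw linear score onto a ~7-unit display scale with the decision
#' boundary at 0, and the frozen preprocessing parameters (per-gene reference
#' log geometric means for single-sample size factors, and the dispersion used
#' by the VST) that make scoring of raw counts self-contained. Once trained
#' the model is locked: scoring never mutates it.
#'
#' @slot weights named numeric vector of per-gene weights on the VST scale.
#' @slot intercept raw-scale intercept.
#' @slot scale multiplier of the affine calibration to the display scale.
#' @slot boundary decision boundary on the display scale (0); scores strictly
#'   above it call UIP, ties call non-UIP.
#' @slot refLogMeans per-gene reference log geometric means of normalized
#'   training counts (single-sample median-of-ratios reference).
#' @slot dispersion VST dispersion frozen at training.
#' @slot metadata list of training metadata (class sizes, penalty, seed).
#'
#' @seealso \code{\link{trainClassifier}}, \code{\link{scoreCounts}}
#' @export
setClass("ClassifierModel",
    representation(
        weights = "numeric",
        intercept = "numeric",
        scale = "numeric",
        boundary = "numeric",
        refLogMeans = "numeric",
        dispersion = "numeric",
        metadata = "list"
    )
)

setValidity("ClassifierModel", function(object) {
    msg <- character()
    if (is.null(names(object@weights)))
        msg <- c(msg, "weights must be named by gene")
    if (length(object@refLogMeans) != length(object@weights))
        msg <- c(msg, "refLogMeans must be parallel to weights")
    if (length(object@scale) != 1L || !is.finite(object@scale) ||
        object@scale <= 0)
        msg <- c(msg, "scale must be a single positive number")
    if (length(object@dispersion) != 1L || object@dispersion < 0)
        msg <- c(msg, "dispersion must be a single value >= 0")
    if (length(msg)) msg else TRUE
})

#' LODEstimate: a limit-of-detection estimate
#'
#' The most diluted mixture proportion at which a sample still classifies
#' concordantly with its parent, estimated either by the 90\%-concordance rule
#' on a simulated concordance curve or by the boundary crossing of a smoothing
#' spline fitted to scores, with an optional bootstrap percentile confidence
#' interval.
#'
#' @slot estimate point estimate of the diluent mass fraction (NA if flagged).
#' @slot lower,upper bootstrap 95\% CI bounds (NA when not computed).
#' @slot threshold concordance threshold used (concordance method).
#' @slot method \code{"concordance"} or \code{"spline"}.
#' @slot nBootstrap number of bootstrap replicates (0 when none).
#' @slot flag \code{"ok"}, \code{"none_above_threshold"}, \code{"saturated"}
#'   or \code{"no_crossing"}.
#'
#' @seealso \code{\link{estimateLod}}, \code{\link{splineCrossing}}
#' @export
setClass("LODEstimate",
    representation(
        estimate = "numeric",
        lower = "numeric",
        upper = "numeric",
        threshold = "numeric",
        method = "character",
        nBootstrap = "integer",
        flag = "character"
    )
)

setValidity("LODEstimate", function(object) {
    msg <- character()
    if (!object@method %in% c("concordance", "spline"))
        msg <- c(msg, "method must be 'concordance' or 'spline'")
    if (object@method == "concordance" &&
        (object@threshold <= 0.5 || object@threshold >= 1))
        msg <- c(msg, "threshold must lie in (0.5, 1)")
    est <- c(object@lower, object@estimate, object@upper)
    est <- est[is.finite(est)]
    if (length(est) > 1L && is.unsorted(est))
        msg <- c(msg, "CI must bracket the point estimate")
    if (length(msg)) msg else TRUE
})

#' VarianceComponents: nested technical variance components of scores
#'
#' Within-run, run-to-run (nested total), pooled inter-laboratory, and
#' inter-class standard deviations of classifier scores estimated from a
#' replicated study design, with optional bootstrap confidence intervals.
#'
#' @slot withinRunSD pooled SD of replicates about their sample-by-run cell
#'   means.
#' @slot runToRunSD pooled SD of replicates about per-sample means (nested
#'   total: includes the within-run component).
#' @slot interlabSD pooled SD about per-sample means across laboratories
#'   (NA when a single laboratory was used).
#' @slot interclassSD SD of per-sample mean scores across class-labelled
#'   samples (biological plus technical spread between classes).
#' @slot ci numeric matrix of 95\% CI bounds, rows named by component
#'   (NA until \code{\link{sdBootstrapCi}} fills them in).
#' @slot n integer vector: observations used per component.
#'
#' @seealso \code{\link{estimateVarianceComponents}}
#' @export
setClass("VarianceComponents",
    representation(
        withinRunSD = "numeric",
        runToRunSD = "numeric",
        interlabSD = "numeric",
        interclassSD = "numeric",
        ci = "matrix",
        n = "integer"
    )
)

setValidity("VarianceComponents", function(object) {
    msg <- character()
    sds <- c(object@withinRunSD, object@runToRunSD, object@interlabSD,
             object@interclassSD)
    if (any(sds[is.finite(sds)] < 0))
        msg <- c(msg, "all SDs must be >= 0")
    if (length(msg)) msg else TRUE
})
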