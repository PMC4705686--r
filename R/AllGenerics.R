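#' @include AllClasses.R
NULL

#' @rdname ExpressionCompendium-class
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname ExpressionCompendium-class
#' @export
setGeneric("sampleContexts", function(x) standardGeneric("sampleContexts"))

#' @rdname ExpressionCompendium-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname ExpressionCompendium-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname ExpressionCompendium-class
#' @export
setGeneric("platformTag", function(x) standardGeneric("platformTag"))

#' @rdname GeneSet-class
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))

#' @rdname GeneSet-class
#' @export
setGeneric("geneWeights", function(x) standardGeneric("geneWeights"))

#' @rdname ActivityMatrix-class
#' @export
setGeneric("activityValues", function(x) standardGeneric("activityValues"))

#' @rdname ActivityMatrix-class
#' @export
setGeneric("geneSetNames", function(x) standardGeneric("geneSetNames"))

#' @rdname ActivityMatrix-class
#' @export
setGeneric("usageReport", function(x) standardGeneric("usageReport"))

#' Evaluate a pattern of interest against an activity matrix
#'
#' Returns a logical mask over samples: `TRUE` where the sample's gene-set
#' activities satisfy the pattern. All interval comparisons are strict
#' (open intervals); polygon boundaries count as inside.
#'
#' @param poi a [POI-class] object.
#' @param act an [ActivityMatrix-class].
#' @return named logical vector, one entry per sample in `act`.
#' @export
setGeneric("matchSamples", function(poi, act) standardGeneric("matchSamples"))

#' Resolve all statistical cutoffs of a POI into raw activity values
#'
#' @param poi a [POI-class] object.
#' @param act the [ActivityMatrix-class] the cutoffs refer to.
#' @return a POI of the same kind whose cutoffs are raw numeric bounds.
#' @export
setGeneric("resolvePOI", function(poi, act) standardGeneric("resolvePOI"))

# internal: POI -> plain list ready for JSON serialization
setGeneric("poiToList", function(poi, act = NULL) standardGeneric("poiToList"))

#' @rdname EnrichmentResult-class
#' @export
setGeneric("rankingTable", function(x) standardGeneric("rankingTable"))

#' @rdname EnrichmentResult-class
#' @export
setGeneric("fullTable", function(x) standardGeneric("fullTable"))
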