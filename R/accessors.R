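#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname ExpressionCompendium-class
setMethod("scoreMatrix", "ExpressionCompendium",
          function(x) assay(x, "scores"))

#' @rdname ExpressionCompendium-class
setMethod("sampleContexts", "ExpressionCompendium", function(x) {
  stats::setNames(as.character(colData(x)$context), colnames(x))
})

#' @rdname ExpressionCompendium-class
setMethod("geneIds", "ExpressionCompendium", function(x) rownames(x))

#' @rdname ExpressionCompendium-class
setMethod("sampleIds", "ExpressionCompendium", function(x) colnames(x))

#' @rdname ExpressionCompendium-class
setMethod("platformTag", "ExpressionCompendium", function(x) {
  p <- metadata(x)$platform
  if (is.null(p)) "" else p
})

setMethod("show", "ExpressionCompendium", function(object) {
  ctx <- sampleContexts(object)
  cat("ExpressionCompendium:", nrow(object), "genes x", ncol(object),
      "samples\n")
  cat("  contexts:", length(unique(ctx)), "distinct\n")
  if (nzchar(platformTag(object)))
    cat("  platform:", platformTag(object), "\n")
  invisible(object)
})

#' @rdname GeneSet-class
setMethod("setName", "GeneSet", function(x) x@name)

#' @rdname GeneSet-class
setMethod("geneIds", "GeneSet", function(x) x@geneIds)

#' @rdname GeneSet-class
setMethod("geneWeights", "GeneSet",
          function(x) stats::setNames(x@weights, x@geneIds))

setMethod("show", "GeneSet", function(object) {
  w <- object@weights
  cat("GeneSet '", object@name, "': ", length(object@geneIds), " genes (",
      sum(w > 0), " positive, ", sum(w < 0), " negative weights)\n",
      sep = "")
  invisible(object)
})

#' @rdname ActivityMatrix-class
setMethod("activityValues", "ActivityMatrix", function(x) x@values)

#' @rdname ActivityMatrix-class
setMethod("geneSetNames", "ActivityMatrix", function(x) rownames(x@values))

#' @rdname ActivityMatrix-class
setMethod("sampleIds", "ActivityMatrix", function(x) colnames(x@values))

#' @rdname ActivityMatrix-class
setMethod("usageReport", "ActivityMatrix", function(x) x@usage)

setMethod("show", "ActivityMatrix", function(object) {
  cat("ActivityMatrix:", nrow(object@values), "gene set(s) x",
      ncol(object@values), "samples\n")
  for (s in rownames(object@values)) {
    u <- object@usage[[s]]
    cat("  ", s, ": ", length(u$used), " genes used, ",
        length(u$missing), " missing\n", sep = "")
  }
  invisible(object)
})

setMethod("show", "SyntheticDesign", function(object) {
  cat("SyntheticDesign:", object@nGenes, "genes,",
      sum(object@contexts$size), "samples in", nrow(object@contexts),
      "contexts,", length(object@implants), "implant(s), seed",
      object@seed, "\n")
  invisible(object)
})

.boundLabel <- function(b) {
  if (is.numeric(b)) format(b)
  else paste0(b@mode, "(", format(b@value), ")")
}

setMethod("show", "IntervalPOI", function(object) {
  cat("IntervalPOI over", length(object@sets), "set(s):\n")
  for (i in seq_along(object@sets))
    cat("  ", object@sets[i], " in (", .boundLabel(object@lower[[i]]),
        ", ", .boundLabel(object@upper[[i]]), ")\n", sep = "")
  invisible(object)
})

setMethod("show", "UnionIntervalPOI", function(object) {
  cat("UnionIntervalPOI on '", object@set, "': union of ",
      length(object@intervals), " interval(s)\n", sep = "")
  invisible(object)
})

setMethod("show", "PolygonPOI", function(object) {
  cat("PolygonPOI on (", object@xSet, ", ", object@ySet, "): ",
      length(object@polygons), " polygon(s)\n", sep = "")
  invisible(object)
})

setMethod("show", "FormulaPOI", function(object) {
  cat("FormulaPOI:", object@expression, "\n")
  invisible(object)
})

#' @rdname EnrichmentResult-class
setMethod("rankingTable", "EnrichmentResult", function(x) x@reported)

#' @rdname EnrichmentResult-class
setMethod("fullTable", "EnrichmentResult", function(x) x@full)

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult: N =", object@nTotal, ", K =", object@nSelected,
      "selected, C =", object@nContexts, "contexts tested;",
      nrow(object@reported), "reported\n")
  if (nrow(object@reported))
    print(utils::head(object@reported, 10), row.names = FALSE)
  invisible(object)
})
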