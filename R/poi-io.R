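#' @include AllClasses.R AllGenerics.R poi.R
NULL

# JSON schema (poi_version 1): a top-level object with fields
#   poi_version, type ("interval" | "union" | "polygon" | "formula"),
#   and per-type payload. Infinite bounds are encoded as the strings
#   "Inf" / "-Inf" (JSON has no infinities). When an activity matrix is
#   supplied at save time, resolved numeric cutoffs are stored alongside
#   their specs so a saved POI documents the exact mask it produced on
#   that matrix.

.boundToList <- function(b) {
  if (is.numeric(b)) {
    v <- if (is.finite(b)) unname(b) else as.character(b)
    list(kind = "raw", value = v)
  } else {
    list(kind = "spec", mode = b@mode, value = unname(b@value),
         side = b@side)
  }
}

.boundFromList <- function(x) {
  .stopIf(is.null(x$kind), "POI bound is missing its 'kind' field")
  if (x$kind == "raw") {
    v <- x$value
    if (is.character(v)) v <- as.numeric(v)  # "Inf" / "-Inf"
    .stopIf(is.na(v), "unreadable raw bound in POI file")
    v
  } else if (x$kind == "spec") {
    cutoffSpec(x$mode, x$value, x$side)
  } else {
    stop("unknown POI bound kind '", x$kind, "'", call. = FALSE)
  }
}

setMethod("poiToList", "IntervalPOI", function(poi, act = NULL) {
  out <- list(poi_version = 1L, type = "interval",
              sets = as.list(poi@sets),
              lower = lapply(poi@lower, .boundToList),
              upper = lapply(poi@upper, .boundToList))
  if (!is.null(act)) {
    r <- resolvePOI(poi, act)
    out$resolved <- list(
      lower = lapply(r@lower, function(b)
        if (is.finite(b)) b else as.character(b)),
      upper = lapply(r@upper, function(b)
        if (is.finite(b)) b else as.character(b)))
  }
  out
})

setMethod("poiToList", "UnionIntervalPOI", function(poi, act = NULL) {
  out <- list(poi_version = 1L, type = "union", set = poi@set,
              intervals = lapply(poi@intervals, function(iv)
                list(lower = .boundToList(iv$lower),
                     upper = .boundToList(iv$upper))))
  if (!is.null(act)) {
    r <- resolvePOI(poi, act)
    out$resolved <- lapply(r@intervals, function(iv)
      list(lower = if (is.finite(iv$lower)) iv$lower else
             as.character(iv$lower),
           upper = if (is.finite(iv$upper)) iv$upper else
             as.character(iv$upper)))
  }
  out
})

setMethod("poiToList", "PolygonPOI", function(poi, act = NULL) {
  list(poi_version = 1L, type = "polygon",
       x_set = poi@xSet, y_set = poi@ySet,
       polygons = lapply(poi@polygons, function(p)
         lapply(seq_len(nrow(p)), function(i) c(p[i, 1], p[i, 2]))))
})

setMethod("poiToList", "FormulaPOI", function(poi, act = NULL) {
  list(poi_version = 1L, type = "formula", expression = poi@expression)
})

#' Save / load a pattern of interest as JSON
#'
#' A POI saved with `savePOI()` and reloaded with `loadPOI()` produces the
#' identical sample mask on the same activity matrix. When `act` is given,
#' statistical cutoffs (SD / quantile / normal-tail specs) are additionally
#' resolved and their raw values stored in the document for the record.
#'
#' @param poi a [POI-class] object.
#' @param path file path of the JSON document.
#' @param act optional [ActivityMatrix-class] used to embed resolved
#'   cutoff values.
#' @return `savePOI()` invisibly returns `path`; `loadPOI()` returns the
#'   reconstructed [POI-class] (errors on an unknown `type` tag or schema
#'   violation).
#' @examples
#' poi <- defaultPOI(c("MYC", "MYC_TG"))
#' f <- tempfile(fileext = ".json")
#' savePOI(poi, f)
#' loadPOI(f)
#' @export
savePOI <- function(poi, path, act = NULL) {
  stopifnot(is(poi, "POI"))
  validObject(poi)
  json <- jsonlite::toJSON(poiToList(poi, act), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname savePOI
#' @export
loadPOI <- function(path) {
  .stopIf(!file.exists(path), "POI file not found: ", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("cannot parse POI file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  .stopIf(is.null(doc$type), "POI file has no 'type' field: ", path)
  ver <- doc$poi_version
  .stopIf(!is.null(ver) && !identical(as.integer(ver), 1L),
          "unsupported poi_version in ", path)
  switch(as.character(doc$type),
    interval = {
      .stopIf(is.null(doc$sets) || is.null(doc$lower) ||
                is.null(doc$upper), "interval POI needs sets/lower/upper")
      new("IntervalPOI",
          sets = vapply(doc$sets, as.character, character(1)),
          lower = lapply(doc$lower, .boundFromList),
          upper = lapply(doc$upper, .boundFromList))
    },
    union = {
      .stopIf(is.null(doc$set) || is.null(doc$intervals),
              "union POI needs set/intervals")
      new("UnionIntervalPOI", set = as.character(doc$set),
          intervals = lapply(doc$intervals, function(iv)
            list(lower = .boundFromList(iv$lower),
                 upper = .boundFromList(iv$upper))))
    },
    polygon = {
      .stopIf(is.null(doc$x_set) || is.null(doc$y_set) ||
                is.null(doc$polygons), "polygon POI needs x_set/y_set/polygons")
      polys <- lapply(doc$polygons, function(p)
        do.call(rbind, lapply(p, function(v)
          c(as.numeric(v[[1]]), as.numeric(v[[2]])))))
      polygonPOI(doc$x_set, doc$y_set, polys)
    },
    formula = {
      .stopIf(is.null(doc$expression), "formula POI needs an expression")
      formulaPOI(doc$expression)
    },
    stop("unknown POI type '", doc$type, "' in ", path, call. = FALSE))
}
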