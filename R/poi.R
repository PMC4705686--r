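#' @include AllClasses.R AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# cutoff resolution
# ---------------------------------------------------------------------------

#' Resolve a statistical cutoff against observed activities
#'
#' Turns a [cutoffSpec()] into a raw activity value for one gene set:
#' `raw` returns the value itself; `sd` returns mean + value * SD of the
#' set's activities; `quantile` the linearly interpolated empirical
#' quantile; `normal_p` the point whose tail probability under a
#' Normal(mean, sd) fitted to the activities equals the value (the spec's
#' `side` picks the tail, so `normal_p` 0.5 on either side is the fitted
#' mean).
#'
#' @param spec a [cutoffSpec()].
#' @param act an [ActivityMatrix-class].
#' @param setName the gene set whose activities calibrate the cutoff.
#' @return a single numeric cutoff (activity units).
#' @export
resolveCutoff <- function(spec, act, setName) {
  stopifnot(is(spec, "CutoffSpec"))
  validObject(spec)
  if (spec@mode == "raw") return(unname(spec@value))
  .stopIf(!(setName %in% geneSetNames(act)),
          "unknown gene set '", setName, "'")
  y <- activityValues(act)[setName, ]
  switch(spec@mode,
    sd = {
      mean(y) + spec@value * stats::sd(y)
    },
    quantile = {
      unname(stats::quantile(y, spec@value, type = 7))
    },
    normal_p = {
      m <- mean(y); s <- stats::sd(y)
      if (spec@side == "upper")
        stats::qnorm(spec@value, m, s, lower.tail = FALSE)
      else
        stats::qnorm(spec@value, m, s)
    })
}

.resolveBound <- function(b, act, setName, side) {
  if (is.numeric(b)) unname(b) else resolveCutoff(b, act, setName)
}

# ---------------------------------------------------------------------------
# default POI
# ---------------------------------------------------------------------------

#' The default pattern of interest: all sets highly active
#'
#' One-sided constraint `activity > mean + 1 SD` for every set — the
#' "all gene sets highly active" pattern used when no POI is given.
#'
#' @param sets character vector of gene-set names (or a list of
#'   [GeneSet-class] objects / an [ActivityMatrix-class], from which names
#'   are taken).
#' @return an [IntervalPOI-class] with lower bound `cutoffSpec("sd", 1)`
#'   and upper bound `Inf` per set.
#' @export
defaultPOI <- function(sets) {
  if (is(sets, "ActivityMatrix")) sets <- geneSetNames(sets)
  if (is.list(sets)) sets <- vapply(sets, setName, character(1))
  .stopIf(length(sets) == 0L, "at least one gene set required")
  intervalPOI(sets,
              lower = lapply(sets, function(s) cutoffSpec("sd", 1, "lower")),
              upper = rep(Inf, length(sets)))
}

# ---------------------------------------------------------------------------
# formula machinery
# ---------------------------------------------------------------------------

#' Sanitize gene-set names into formula identifiers
#'
#' Non-alphanumeric characters become `_`; a name that does not start with
#' a letter is prefixed with `g`. Distinct set names that collide after
#' sanitization are an error.
#'
#' @param setNames character vector.
#' @return character vector of identifiers, named by the original names.
#' @export
sanitizeSetNames <- function(setNames) {
  ids <- gsub("[^A-Za-z0-9]", "_", setNames)
  ids <- ifelse(grepl("^[A-Za-z]", ids), ids, paste0("g", ids))
  if (anyDuplicated(ids)) {
    d <- ids[duplicated(ids)][1]
    stop("set names collide after sanitization: ",
         paste(setNames[ids == d], collapse = ", "), call. = FALSE)
  }
  stats::setNames(ids, setNames)
}

.formulaOps <- c("+", "-", "*", "/", "^", "(",
                 "<", ">", "<=", ">=", "&", "|")

.parseFormula <- function(expression) {
  e <- tryCatch(str2lang(expression), error = function(err)
    stop("cannot parse formula '", expression, "': ",
         conditionMessage(err), call. = FALSE))
  .stopIf(!(is.call(e) || is.name(e) || is.numeric(e)),
          "formula must be an expression")
  e
}

# collect identifiers while verifying only whitelisted operators appear
.formulaIdentifiers <- function(e) {
  if (is.numeric(e)) return(character())
  if (is.name(e)) return(as.character(e))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    .stopIf(!(length(op) == 1L && op %in% .formulaOps),
            "operator or function '", op, "' is not allowed in a POI formula")
    return(unique(unlist(lapply(as.list(e)[-1], .formulaIdentifiers))))
  }
  stop("unsupported token in POI formula", call. = FALSE)
}

#' Evaluate a POI formula over an activity matrix
#'
#' Internal workhorse behind `matchSamples()` for [formulaPOI()]: checks
#' the expression against the operator whitelist, maps each identifier to
#' a sanitized set name, and evaluates vectorized over samples.
#' @noRd
.evalFormula <- function(expression, act) {
  e <- .parseFormula(expression)
  ids <- .formulaIdentifiers(e)
  lookup <- sanitizeSetNames(geneSetNames(act))
  unknown <- setdiff(ids, lookup)
  .stopIf(length(unknown) > 0, "formula references unknown gene set(s): ",
          paste(unknown, collapse = ", "))
  v <- activityValues(act)
  env <- new.env(parent = baseenv())
  for (orig in names(lookup)) assign(lookup[[orig]], v[orig, ], envir = env)
  res <- eval(e, envir = env)
  .stopIf(!is.logical(res), "POI formula must evaluate to a condition ",
          "(use a comparator such as '<' or '>')")
  if (length(res) == 1L) res <- rep(res, ncol(v))
  .stopIf(length(res) != ncol(v), "formula evaluation length mismatch")
  res & !is.na(res)
}

# ---------------------------------------------------------------------------
# polygon machinery
# ---------------------------------------------------------------------------

# orientation of the triple (a, b, c); 0 = collinear (within tolerance)
.orient <- function(ax, ay, bx, by, cx, cy) {
  v <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  scale <- max(abs(c(ax, ay, bx, by, cx, cy, 1)))
  ifelse(abs(v) <= 1e-12 * scale * scale, 0, sign(v))
}

.segmentsIntersect <- function(p1, p2, p3, p4) {
  d1 <- .orient(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
  d2 <- .orient(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
  d3 <- .orient(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
  d4 <- .orient(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  onSeg <- function(px, py, qx, qy, rx, ry) {
    min(px, qx) - 1e-12 <= rx && rx <= max(px, qx) + 1e-12 &&
      min(py, qy) - 1e-12 <= ry && ry <= max(py, qy) + 1e-12
  }
  (d1 == 0 && onSeg(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])) ||
    (d2 == 0 && onSeg(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])) ||
    (d3 == 0 && onSeg(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])) ||
    (d4 == 0 && onSeg(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2]))
}

# a polygon is simple if non-adjacent edges never intersect and no edge
# degenerates to a point
.polygonIsSimple <- function(poly) {
  n <- nrow(poly)
  edges <- lapply(seq_len(n), function(i)
    list(a = poly[i, ], b = poly[if (i == n) 1L else i + 1L, ]))
  for (e in edges)
    if (all(e$a == e$b)) return(FALSE)
  if (n <= 3L) return(TRUE)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      if (adjacent) next
      if (.segmentsIntersect(edges[[i]]$a, edges[[i]]$b,
                             edges[[j]]$a, edges[[j]]$b)) return(FALSE)
    }
  }
  TRUE
}

#' Point-in-polygon test (ray casting, boundary counted inside)
#'
#' Even-odd crossing test with an explicit on-boundary check; points on an
#' edge or vertex are inside.
#'
#' @param px,py point coordinates (vectors of equal length).
#' @param poly n x 2 vertex matrix of a simple polygon (vertices in order,
#'   first vertex not repeated).
#' @return logical vector.
#' @export
pointInPolygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  stopifnot(ncol(poly) == 2L, nrow(poly) >= 3L, length(px) == length(py))
  n <- nrow(poly)
  inside <- logical(length(px))
  onEdge <- logical(length(px))
  eps <- 1e-12 * max(1, max(abs(poly)))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    onSeg <- abs(cross) <= eps * max(1, abs(xj - xi) + abs(yj - yi)) &
      px >= pmin(xi, xj) - eps & px <= pmax(xi, xj) + eps &
      py >= pmin(yi, yj) - eps & py <= pmax(yi, yj) + eps
    onEdge <- onEdge | onSeg
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      crosses <- crosses & (px < xint)
    }
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onEdge
}

# ---------------------------------------------------------------------------
# matchSamples methods
# ---------------------------------------------------------------------------

.intervalMask <- function(act, set, lower, upper) {
  .stopIf(!(set %in% geneSetNames(act)), "unknown gene set '", set, "'")
  lo <- .resolveBound(lower, act, set, "lower")
  hi <- .resolveBound(upper, act, set, "upper")
  .stopIf(!(lo < hi), "empty interval for set '", set, "': lower bound ",
          format(lo), " not below upper bound ", format(hi))
  y <- activityValues(act)[set, ]
  y > lo & y < hi   # open interval: ties at a cutoff are excluded
}

#' @rdname matchSamples
setMethod("matchSamples", signature("IntervalPOI", "ActivityMatrix"),
  function(poi, act) {
    validObject(poi)
    mask <- rep(TRUE, ncol(activityValues(act)))
    for (i in seq_along(poi@sets))
      mask <- mask & .intervalMask(act, poi@sets[i],
                                   poi@lower[[i]], poi@upper[[i]])
    stats::setNames(mask, sampleIds(act))
  })

#' @rdname matchSamples
setMethod("matchSamples", signature("UnionIntervalPOI", "ActivityMatrix"),
  function(poi, act) {
    validObject(poi)
    mask <- rep(FALSE, ncol(activityValues(act)))
    for (iv in poi@intervals)
      mask <- mask | .intervalMask(act, poi@set, iv$lower, iv$upper)
    stats::setNames(mask, sampleIds(act))
  })

#' @rdname matchSamples
setMethod("matchSamples", signature("PolygonPOI", "ActivityMatrix"),
  function(poi, act) {
    validObject(poi)
    for (s in c(poi@xSet, poi@ySet))
      .stopIf(!(s %in% geneSetNames(act)), "unknown gene set '", s, "'")
    v <- activityValues(act)
    px <- v[poi@xSet, ]; py <- v[poi@ySet, ]
    mask <- rep(FALSE, length(px))
    for (p in poi@polygons) mask <- mask | pointInPolygon(px, py, p)
    stats::setNames(mask, sampleIds(act))
  })

#' @rdname matchSamples
setMethod("matchSamples", signature("FormulaPOI", "ActivityMatrix"),
  function(poi, act) {
    stats::setNames(.evalFormula(poi@expression, act), sampleIds(act))
  })

# ---------------------------------------------------------------------------
# resolvePOI methods (statistical cutoffs -> raw numbers)
# ---------------------------------------------------------------------------

#' @rdname resolvePOI
setMethod("resolvePOI", signature("IntervalPOI", "ActivityMatrix"),
  function(poi, act) {
    lo <- lapply(seq_along(poi@sets), function(i)
      .resolveBound(poi@lower[[i]], act, poi@sets[i], "lower"))
    hi <- lapply(seq_along(poi@sets), function(i)
      .resolveBound(poi@upper[[i]], act, poi@sets[i], "upper"))
    new("IntervalPOI", sets = poi@sets, lower = lo, upper = hi)
  })

#' @rdname resolvePOI
setMethod("resolvePOI", signature("UnionIntervalPOI", "ActivityMatrix"),
  function(poi, act) {
    ivs <- lapply(poi@intervals, function(iv)
      list(lower = .resolveBound(iv$lower, act, poi@set, "lower"),
           upper = .resolveBound(iv$upper, act, poi@set, "upper")))
    new("UnionIntervalPOI", set = poi@set, intervals = ivs)
  })

#' @rdname resolvePOI
setMethod("resolvePOI", signature("PolygonPOI", "ActivityMatrix"),
  function(poi, act) poi)

#' @rdname resolvePOI
setMethod("resolvePOI", signature("FormulaPOI", "ActivityMatrix"),
  function(poi, act) poi)
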