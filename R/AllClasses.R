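#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
NULL

# ---------------------------------------------------------------------------
# ExpressionCompendium
# ---------------------------------------------------------------------------

#' ExpressionCompendium: annotated expression score matrix
#'
#' A genes x samples matrix of consistently normalized expression scores
#' (z-score-like: values near zero mean absent/low expression) together with
#' a biological-context label for every sample. Built on
#' [SummarizedExperiment::SummarizedExperiment]: the scores live in the
#' `"scores"` assay and the context labels in `colData(x)$context`.
#'
#' Every sample carries exactly one context label; gene and sample
#' identifiers are unique; all scores are finite.
#'
#' @param scores numeric matrix, genes x samples, with unique non-empty
#'   rownames (gene IDs) and colnames (sample IDs).
#' @param contexts character vector of context labels, either named by
#'   sample ID or given in column order of `scores`.
#' @param platform free-text platform tag (e.g. an array platform accession).
#' @param x an `ExpressionCompendium`.
#'
#' @return `ExpressionCompendium()` returns a validated object.
#'   `scoreMatrix()` the numeric matrix; `sampleContexts()` a named character
#'   vector sample -> context; `geneIds()`/`sampleIds()` the dimnames;
#'   `platformTag()` the platform string.
#'
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' comp <- ExpressionCompendium(m, c(s1 = "liver", s2 = "brain"))
#' sampleContexts(comp)
#'
#' @aliases scoreMatrix sampleContexts geneIds sampleIds platformTag
#' @export
setClass("ExpressionCompendium", contains = "SummarizedExperiment")

.validExpressionCompendium <- function(object) {
  msg <- character()
  if (!("scores" %in% assayNames(object)))
    msg <- c(msg, "assay 'scores' is missing")
  else {
    sc <- assay(object, "scores")
    if (!is.numeric(sc))
      msg <- c(msg, "scores must be numeric")
    else if (!all(is.finite(sc)))
      msg <- c(msg, "scores contain non-finite values")
  }
  if (nrow(object) < 1L || ncol(object) < 1L)
    msg <- c(msg, "compendium needs at least one gene and one sample")
  rn <- rownames(object); cn <- colnames(object)
  if (is.null(rn) || anyNA(rn) || any(rn == ""))
    msg <- c(msg, "gene IDs must be non-empty")
  else if (anyDuplicated(rn))
    msg <- c(msg, paste0("duplicate gene IDs: ",
                         paste(unique(rn[duplicated(rn)]), collapse = ", ")))
  if (is.null(cn) || anyNA(cn) || any(cn == ""))
    msg <- c(msg, "sample IDs must be non-empty")
  else if (anyDuplicated(cn))
    msg <- c(msg, paste0("duplicate sample IDs: ",
                         paste(unique(cn[duplicated(cn)]), collapse = ", ")))
  if (!("context" %in% colnames(colData(object))))
    msg <- c(msg, "colData must carry a 'context' column")
  else {
    ctx <- colData(object)$context
    if (anyNA(ctx) || any(ctx == ""))
      msg <- c(msg, "every sample needs exactly one non-empty context label")
    if (any(grepl("[\t\n\r]", ctx)))
      msg <- c(msg, "context labels must not contain tabs or newlines")
  }
  if (length(msg)) msg else TRUE
}

setValidity("ExpressionCompendium", .validExpressionCompendium)

#' @rdname ExpressionCompendium-class
#' @export
ExpressionCompendium <- function(scores, contexts, platform = "") {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  cn <- colnames(scores)
  if (!is.null(names(contexts))) {
    missing <- setdiff(cn, names(contexts))
    if (length(missing))
      stop("no context annotation for sample(s): ",
           paste(missing, collapse = ", "))
    contexts <- contexts[cn]
  } else if (length(contexts) != ncol(scores)) {
    stop("'contexts' must be named by sample or match the number of columns")
  }
  se <- SummarizedExperiment(
    assays  = list(scores = scores),
    colData = DataFrame(context = as.character(unname(contexts)),
                        row.names = cn))
  metadata(se)$platform <- as.character(platform)[1]
  new("ExpressionCompendium", se)
}

# ---------------------------------------------------------------------------
# GeneSet
# ---------------------------------------------------------------------------

#' GeneSet: gene identifiers with signed real weights
#'
#' A named gene set whose members carry user-specified weights. Weights may
#' be any finite positive or negative real numbers (not necessarily
#' integers); negative weights mark genes expected to be anti-correlated
#' with the set's activity (e.g. repressed targets of a transcription
#' factor). At least one member, no duplicated gene IDs, and the weights may
#' not all be zero (the activity denominator is the sum of absolute
#' weights).
#'
#' @param name set name (non-empty string).
#' @param geneIds character vector of gene identifiers (e.g. ENTREZ IDs).
#' @param weights numeric weights, recycled from 1 if omitted.
#' @param x a `GeneSet`.
#'
#' @return `GeneSet()` a validated object; `setName()` its name;
#'   `geneIds()` the member IDs; `geneWeights()` a named numeric vector.
#'
#' @examples
#' gs <- GeneSet("MYC_TG", c("4609", "7078"), c(1, -1))
#' geneWeights(gs)
#'
#' @aliases setName geneWeights
#' @export
setClass("GeneSet",
  representation(name = "character", geneIds = "character",
                 weights = "numeric"))

.validGeneSet <- function(object) {
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name) || object@name == "")
    msg <- c(msg, "set name must be a single non-empty string")
  n <- length(object@geneIds)
  if (n < 1L)
    msg <- c(msg, "a gene set needs at least one member")
  if (anyDuplicated(object@geneIds))
    msg <- c(msg, paste0("duplicate gene IDs in set: ",
      paste(unique(object@geneIds[duplicated(object@geneIds)]), collapse = ", ")))
  if (length(object@weights) != n)
    msg <- c(msg, "one weight per gene required")
  else {
    if (!all(is.finite(object@weights)))
      msg <- c(msg, "weights must be finite")
    else if (sum(abs(object@weights)) == 0)
      msg <- c(msg, "weights must not all be zero")
  }
  if (length(msg)) msg else TRUE
}

setValidity("GeneSet", .validGeneSet)

#' @rdname GeneSet-class
#' @export
GeneSet <- function(name, geneIds, weights = rep(1, length(geneIds))) {
  new("GeneSet", name = as.character(name),
      geneIds = as.character(geneIds), weights = as.numeric(weights))
}

# ---------------------------------------------------------------------------
# ActivityMatrix
# ---------------------------------------------------------------------------

#' ActivityMatrix: gene-set activities per sample
#'
#' The sets x samples matrix of weighted-average gene-set activities
#' produced by [computeActivity()], plus a per-set usage report recording
#' which member genes were present in the compendium and which were
#' missing (and therefore excluded from both numerator and denominator).
#' Sample order is identical to the source compendium.
#'
#' @param x an `ActivityMatrix`.
#' @return `activityValues()` the numeric matrix; `geneSetNames()` and
#'   `sampleIds()` its dimnames; `usageReport()` a list per set with
#'   elements `used` and `missing` (character vectors of gene IDs).
#' @aliases activityValues geneSetNames usageReport
#' @export
setClass("ActivityMatrix",
  representation(values = "matrix", usage = "list"))

.validActivityMatrix <- function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v) || !all(is.finite(v)))
    msg <- c(msg, "activity values must be finite numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "activity matrix needs set and sample names")
  else {
    if (anyDuplicated(rownames(v)))
      msg <- c(msg, "duplicate set names")
    if (!identical(sort(names(object@usage)), sort(rownames(v))))
      msg <- c(msg, "usage report must cover exactly the sets in the matrix")
  }
  if (length(msg)) msg else TRUE
}

setValidity("ActivityMatrix", .validActivityMatrix)

# ---------------------------------------------------------------------------
# SyntheticDesign
# ---------------------------------------------------------------------------

#' SyntheticDesign: blueprint for a synthetic annotated compendium
#'
#' Describes a simulated compendium: a gene universe of `nGenes` genes,
#' biological contexts with stated sample counts, and "implants" — context
#' restricted additive shifts (`delta`, in score units) applied to a listed
#' subset of genes, emulating a gene set that is concordantly active in one
#' context. Baseline scores are i.i.d. Normal(0, baselineSd^2), mirroring
#' normalized compendium z-scores whose values sit near zero for
#' unexpressed genes. The same seed always reproduces the same compendium
#' bit for bit.
#'
#' @param nGenes number of genes in the universe (IDs `g1..g<nGenes>`).
#' @param contexts data.frame with columns `label` and `size` (positive
#'   sample counts), one row per context.
#' @param implants list of `list(context=, genes=, delta=)` entries; `genes`
#'   must be IDs from the generated universe and `context` a design label.
#' @param baselineSd baseline standard deviation of the scores (default 1).
#' @param seed integer seed owning all randomness of the generator.
#' @return a validated `SyntheticDesign`.
#' @examples
#' des <- syntheticDesign(
#'   nGenes = 100,
#'   contexts = data.frame(label = c("A", "B"), size = c(5, 5)),
#'   implants = list(list(context = "A", genes = paste0("g", 1:10), delta = 2)),
#'   seed = 1)
#' @export
setClass("SyntheticDesign",
  representation(nGenes = "integer", contexts = "data.frame",
                 implants = "list", baselineSd = "numeric", seed = "integer"))

.validSyntheticDesign <- function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  cx <- object@contexts
  if (!all(c("label", "size") %in% colnames(cx)))
    msg <- c(msg, "contexts needs 'label' and 'size' columns")
  else {
    if (nrow(cx) < 1L) msg <- c(msg, "at least one context required")
    if (anyDuplicated(cx$label)) msg <- c(msg, "duplicate context labels")
    if (any(cx$size < 1L)) msg <- c(msg, "context sizes must be positive")
  }
  universe <- paste0("g", seq_len(object@nGenes))
  for (imp in object@implants) {
    if (!all(c("context", "genes", "delta") %in% names(imp))) {
      msg <- c(msg, "each implant needs context, genes, delta")
      next
    }
    if (!(imp$context %in% cx$label))
      msg <- c(msg, paste0("implant references unknown context '",
                           imp$context, "'"))
    bad <- setdiff(imp$genes, universe)
    if (length(bad))
      msg <- c(msg, paste0("implant references unknown gene(s): ",
                           paste(utils::head(bad, 5), collapse = ", ")))
    if (!is.finite(imp$delta))
      msg <- c(msg, "implant delta must be finite")
  }
  if (!is.finite(object@baselineSd) || object@baselineSd < 0)
    msg <- c(msg, "baselineSd must be a nonnegative number")
  if (length(msg)) msg else TRUE
}

setValidity("SyntheticDesign", .validSyntheticDesign)

#' @rdname SyntheticDesign-class
#' @export
syntheticDesign <- function(nGenes, contexts, implants = list(),
                            baselineSd = 1, seed = 1L) {
  contexts$label <- as.character(contexts$label)
  contexts$size <- as.integer(contexts$size)
  new("SyntheticDesign", nGenes = as.integer(nGenes), contexts = contexts,
      implants = implants, baselineSd = as.numeric(baselineSd),
      seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# POI hierarchy
# ---------------------------------------------------------------------------

#' Patterns of interest over gene-set activity space
#'
#' A POI is a predicate over the activity space of one or more gene sets;
#' samples satisfying it are "selected" and fed to context enrichment. Four
#' kinds are supported, all evaluated by [matchSamples()] and serializable
#' to JSON with [savePOI()]/[loadPOI()]:
#'
#' * `IntervalPOI` — a conjunction of per-set open intervals
#'   `activity in (lower, upper)`, where each bound is a raw number
#'   (`-Inf`/`Inf` for one-sided constraints) or a [cutoffSpec()].
#' * `UnionIntervalPOI` — a disjunction of open intervals for one set.
#' * `PolygonPOI` — one or more simple polygons in the plane spanned by two
#'   sets' activities; a sample is selected if it falls inside (boundary
#'   included) any polygon.
#' * `FormulaPOI` — an arithmetic/logical expression over set names, e.g.
#'   `"(MYC+2)^2+(MYC_TG-2)^2*10 < 4"` (an ellipse). Set names are
#'   sanitized to identifiers: non-alphanumeric characters become `_`.
#'
#' @name POI-class
#' @aliases IntervalPOI-class UnionIntervalPOI-class PolygonPOI-class
#'   FormulaPOI-class CutoffSpec-class
NULL

#' @export
setClass("POI", representation("VIRTUAL"))

#' Statistical cutoff specification
#'
#' A cutoff on one gene set's activity, resolvable against an activity
#' matrix by [resolveCutoff()]. Modes:
#' * `raw` — the value itself (activity units);
#' * `sd` — mean + value * SD of the set's activities (value in SD units;
#'   may be negative);
#' * `quantile` — empirical quantile, linearly interpolated (value in
#'   \[0,1\]);
#' * `normal_p` — the point whose tail probability under a
#'   Normal(mean, sd) fit to the activities equals `value` (value in
#'   (0,1)); the `side` decides which tail (`upper`: P(Y > c) = value,
#'   `lower`: P(Y < c) = value).
#'
#' @param mode one of `"raw"`, `"sd"`, `"quantile"`, `"normal_p"`.
#' @param value numeric cutoff parameter, interpreted per mode.
#' @param side `"lower"` or `"upper"`; only consulted by `normal_p`.
#' @return a `CutoffSpec`.
#' @examples
#' cutoffSpec("sd", 1)          # one SD above the mean
#' cutoffSpec("quantile", 0.9)  # 90th percentile
#' @export
setClass("CutoffSpec",
  representation(mode = "character", value = "numeric", side = "character"))

.validCutoffSpec <- function(object) {
  msg <- character()
  if (!(object@mode %in% c("raw", "sd", "quantile", "normal_p")))
    msg <- c(msg, paste0("unknown cutoff mode '", object@mode, "'"))
  if (!(object@side %in% c("lower", "upper")))
    msg <- c(msg, "side must be 'lower' or 'upper'")
  v <- object@value
  if (length(v) != 1L || is.na(v))
    msg <- c(msg, "value must be a single number")
  else {
    if (object@mode == "quantile" && (v < 0 || v > 1))
      msg <- c(msg, "quantile value must lie in [0, 1]")
    if (object@mode == "normal_p" && (v <= 0 || v >= 1))
      msg <- c(msg, "normal_p value must lie in (0, 1)")
    if (object@mode %in% c("raw", "sd") && !is.finite(v))
      msg <- c(msg, "raw/sd cutoff value must be finite")
  }
  if (length(msg)) msg else TRUE
}

setValidity("CutoffSpec", .validCutoffSpec)

#' @rdname CutoffSpec-class
#' @export
cutoffSpec <- function(mode, value, side = "lower") {
  new("CutoffSpec", mode = mode, value = as.numeric(value), side = side)
}

# a bound is either a raw number (possibly infinite) or a CutoffSpec
setClassUnion("CutoffBound", c("numeric", "CutoffSpec"))

#' @export
setClass("IntervalPOI", contains = "POI",
  representation(sets = "character", lower = "list", upper = "list"))

.checkBounds <- function(bounds, what) {
  msg <- character()
  for (b in bounds) {
    if (is.numeric(b)) {
      if (length(b) != 1L || is.na(b))
        msg <- c(msg, paste0(what, " bounds must be single numbers"))
    } else if (!is(b, "CutoffSpec")) {
      msg <- c(msg, paste0(what, " bounds must be numeric or CutoffSpec"))
    }
  }
  msg
}

setValidity("IntervalPOI", function(object) {
  msg <- character()
  if (length(object@sets) < 1L) msg <- c(msg, "at least one set required")
  if (anyDuplicated(object@sets)) msg <- c(msg, "duplicate set names")
  if (length(object@lower) != length(object@sets) ||
      length(object@upper) != length(object@sets))
    msg <- c(msg, "one lower and one upper bound per set required")
  msg <- c(msg, .checkBounds(object@lower, "lower"),
           .checkBounds(object@upper, "upper"))
  if (length(msg)) msg else TRUE
})

#' @rdname POI-class
#' @param sets character vector of gene-set names.
#' @param lower,upper per-set bounds: a list (or vector) of raw numbers
#'   and/or [cutoffSpec()] objects; `-Inf`/`Inf` leave a side unconstrained.
#' @export
intervalPOI <- function(sets, lower = rep(-Inf, length(sets)),
                        upper = rep(Inf, length(sets))) {
  asBoundList <- function(b) {
    if (is(b, "CutoffSpec")) list(b)
    else if (is.numeric(b)) as.list(as.numeric(b))
    else as.list(b)
  }
  new("IntervalPOI", sets = as.character(sets),
      lower = asBoundList(lower), upper = asBoundList(upper))
}

#' @export
setClass("UnionIntervalPOI", contains = "POI",
  representation(set = "character", intervals = "list"))

setValidity("UnionIntervalPOI", function(object) {
  msg <- character()
  if (length(object@set) != 1L) msg <- c(msg, "exactly one set name required")
  if (length(object@intervals) < 1L)
    msg <- c(msg, "at least one interval required")
  for (iv in object@intervals) {
    if (!is.list(iv) || !all(c("lower", "upper") %in% names(iv)))
      msg <- c(msg, "each interval needs 'lower' and 'upper'")
    else
      msg <- c(msg, .checkBounds(iv["lower"], "lower"),
               .checkBounds(iv["upper"], "upper"))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname POI-class
#' @param set single gene-set name (union-of-intervals form).
#' @param intervals list of `list(lower=, upper=)` pairs (raw numbers or
#'   [cutoffSpec()]s); the POI is the union of these open intervals.
#' @export
unionIntervalPOI <- function(set, intervals) {
  new("UnionIntervalPOI", set = as.character(set), intervals = intervals)
}

#' @export
setClass("PolygonPOI", contains = "POI",
  representation(xSet = "character", ySet = "character", polygons = "list"))

setValidity("PolygonPOI", function(object) {
  msg <- character()
  if (length(object@xSet) != 1L || length(object@ySet) != 1L)
    msg <- c(msg, "xSet and ySet must be single set names")
  if (length(object@polygons) < 1L)
    msg <- c(msg, "at least one polygon required")
  for (p in object@polygons) {
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L ||
        !all(is.finite(p))) {
      msg <- c(msg, "each polygon must be a finite n x 2 matrix, n >= 3")
    } else if (!.polygonIsSimple(p)) {
      msg <- c(msg, "polygon is degenerate or self-intersecting")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname POI-class
#' @param xSet,ySet names of the sets spanning the scatter plane.
#' @param polygons list of n x 2 numeric matrices (vertices in order,
#'   not repeated at the end); each polygon must be simple.
#' @export
polygonPOI <- function(xSet, ySet, polygons) {
  if (is.matrix(polygons)) polygons <- list(polygons)
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    dimnames(p) <- NULL
    p
  })
  new("PolygonPOI", xSet = as.character(xSet), ySet = as.character(ySet),
      polygons = polygons)
}

#' @export
setClass("FormulaPOI", contains = "POI",
  representation(expression = "character"))

setValidity("FormulaPOI", function(object) {
  if (length(object@expression) != 1L || is.na(object@expression) ||
      object@expression == "")
    return("expression must be a single non-empty string")
  ok <- tryCatch({
    .formulaIdentifiers(.parseFormula(object@expression))
    TRUE
  }, error = function(e) conditionMessage(e))
  if (isTRUE(ok)) TRUE else ok
})

#' @rdname POI-class
#' @param expression formula string over set-name identifiers, numeric
#'   literals, `+ - * / ^` (with `^` right-associative and binding
#'   tightest), comparators `< > <= >=`, logical `&` `|`, and parentheses.
#' @export
formulaPOI <- function(expression) {
  new("FormulaPOI", expression = as.character(expression))
}

# ---------------------------------------------------------------------------
# EnrichmentResult
# ---------------------------------------------------------------------------

#' EnrichmentResult: per-context enrichment of the selected samples
#'
#' Holds the complete per-context table (every annotated context is tested)
#' and the reported subset passing the significance and fold-change filter,
#' ranked by ascending adjusted P, ties broken by descending fold change,
#' then label. Columns: `context`, `n_c` (context size), `k_c` (selected in
#' context), `fold_change`, `p_raw`, `p_adj` (Bonferroni, factor = number
#' of contexts).
#'
#' @param x an `EnrichmentResult`.
#' @return `rankingTable()` the filtered, ranked data.frame;
#'   `fullTable()` the unfiltered table (same columns, same ranking).
#' @aliases rankingTable fullTable
#' @export
setClass("EnrichmentResult",
  representation(full = "data.frame", reported = "data.frame",
                 nTotal = "integer", nSelected = "integer",
                 nContexts = "integer"))
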