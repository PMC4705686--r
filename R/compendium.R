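#' @include AllClasses.R AllGenerics.R
NULL

#' Read an annotated expression compendium from TSV files
#'
#' The matrix file is tab-delimited with a header row of sample IDs and the
#' gene IDs in the first column; the annotation file is 2-column
#' tab-delimited (`sample_id<TAB>context`), headerless (a literal
#' `sample_id  context` first line is tolerated and skipped). Every matrix
#' sample must be annotated; unannotated samples are an error that names
#' the offenders.
#'
#' @param matrixPath path to the score matrix TSV.
#' @param annotationPath path to the sample-annotation TSV.
#' @return a validated [ExpressionCompendium-class].
#' @seealso [writeCompendium()]
#' @export
readCompendium <- function(matrixPath, annotationPath) {
  .stopIf(!file.exists(matrixPath), "matrix file not found: ", matrixPath)
  .stopIf(!file.exists(annotationPath),
          "annotation file not found: ", annotationPath)
  tab <- utils::read.delim(matrixPath, header = TRUE, check.names = FALSE,
                           quote = "", comment.char = "",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  .stopIf(ncol(tab) < 2L, "matrix file needs a gene-ID column and at least ",
          "one sample column: ", matrixPath)
  genes <- tab[[1]]
  .stopIf(anyDuplicated(genes) > 0, "duplicate gene IDs in ", matrixPath,
          ": ", paste(unique(genes[duplicated(genes)]), collapse = ", "))
  cells <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(scores <- matrix(as.numeric(cells), nrow = nrow(cells)))
  if (anyNA(scores)) {
    bad <- which(is.na(scores), arr.ind = TRUE)[1, ]
    stop("non-numeric cell at gene '", genes[bad[1]], "', sample '",
         colnames(cells)[bad[2]], "' in ", matrixPath, call. = FALSE)
  }
  dimnames(scores) <- list(genes, colnames(cells))
  .stopIf(anyDuplicated(colnames(scores)) > 0,
          "duplicate sample IDs in ", matrixPath)

  ann <- utils::read.delim(annotationPath, header = FALSE,
                           check.names = FALSE, quote = "",
                           comment.char = "", colClasses = "character",
                           stringsAsFactors = FALSE)
  .stopIf(ncol(ann) != 2L,
          "annotation file must have exactly 2 tab-separated columns: ",
          annotationPath)
  if (nrow(ann) && identical(unname(unlist(ann[1, ])),
                             c("sample_id", "context")))
    ann <- ann[-1, , drop = FALSE]
  .stopIf(anyDuplicated(ann[[1]]) > 0, "duplicate sample IDs in ",
          annotationPath)
  ctx <- stats::setNames(ann[[2]], ann[[1]])
  missing <- setdiff(colnames(scores), names(ctx))
  .stopIf(length(missing) > 0,
          "sample(s) present in the matrix but missing from annotations: ",
          paste(missing, collapse = ", "))
  ExpressionCompendium(scores, ctx[colnames(scores)])
}

#' Write an expression compendium to TSV files
#'
#' Inverse of [readCompendium()]: scores are written with 12 significant
#' digits (so a read/write round trip reproduces them to at least 10
#' significant digits) and context labels bit-identically. Context labels
#' containing tabs or newlines are rejected by the compendium validity and
#' re-checked here for delimiter safety.
#'
#' @param comp an [ExpressionCompendium-class].
#' @param matrixPath,annotationPath output paths.
#' @return invisibly, `comp`.
#' @export
writeCompendium <- function(comp, matrixPath, annotationPath) {
  stopifnot(is(comp, "ExpressionCompendium"))
  validObject(comp)
  sc <- scoreMatrix(comp)
  ids <- c(rownames(sc), colnames(sc))
  .stopIf(any(grepl("[\t\n\r]", ids)),
          "gene/sample IDs must not contain tabs or newlines")
  con <- file(matrixPath, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste(c("gene_id", colnames(sc)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(sc)), function(i) {
    paste(c(rownames(sc)[i], .fmtNum(sc[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  ctx <- sampleContexts(comp)
  writeLines(paste(names(ctx), ctx, sep = "\t"), annotationPath)
  invisible(comp)
}

#' Tabulate biological contexts of a compendium
#'
#' @param comp an [ExpressionCompendium-class].
#' @return data.frame with columns `context` and `n_samples`, one row per
#'   distinct label in lexicographic order; the sizes sum to the number of
#'   samples.
#' @export
summarizeContexts <- function(comp) {
  stopifnot(is(comp, "ExpressionCompendium"))
  tab <- table(sampleContexts(comp))
  data.frame(context = names(tab)[order(names(tab))],
             n_samples = as.integer(tab[order(names(tab))]),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic annotated compendium from a design
#'
#' Baseline scores are drawn i.i.d. Normal(0, baselineSd^2); each implant
#' adds its `delta` to the listed genes in that context's samples. All
#' randomness is owned by the design's seed: the same design reproduces the
#' same compendium bit for bit, and the caller's RNG state is untouched.
#'
#' @param design a [syntheticDesign()].
#' @return an [ExpressionCompendium-class] with sample IDs `s1..sN`
#'   assigned to contexts in design order and platform tag `"synthetic"`.
#' @export
synthesizeCompendium <- function(design) {
  stopifnot(is(design, "SyntheticDesign"))
  validObject(design)
  genes <- paste0("g", seq_len(design@nGenes))
  nPer <- design@contexts$size
  n <- sum(nPer)
  samples <- paste0("s", seq_len(n))
  ctx <- rep(design@contexts$label, nPer)
  scores <- withSeed(design@seed,
    matrix(stats::rnorm(design@nGenes * n, sd = design@baselineSd),
           nrow = design@nGenes, dimnames = list(genes, samples)))
  for (imp in design@implants) {
    cols <- which(ctx == imp$context)
    scores[imp$genes, cols] <- scores[imp$genes, cols] + imp$delta
  }
  ExpressionCompendium(scores, stats::setNames(ctx, samples),
                       platform = "synthetic")
}

#' Gene sets implanted by a synthetic design
#'
#' One unit-weight [GeneSet-class] per implant, named
#' `implant_<context>`, handy for end-to-end recovery experiments.
#'
#' @param design a [syntheticDesign()].
#' @return list of [GeneSet-class] objects (possibly empty).
#' @export
implantGeneSets <- function(design) {
  stopifnot(is(design, "SyntheticDesign"))
  lapply(design@implants, function(imp)
    GeneSet(paste0("implant_", imp$context), imp$genes))
}

#' Order samples by hierarchical clustering of their activity profiles
#'
#' Agglomerative clustering with Euclidean distances between sample
#' activity vectors and complete linkage, as used to arrange heat-map
#' columns; returns the dendrogram leaf order.
#'
#' @param act an [ActivityMatrix-class] with at least 2 samples.
#' @return integer permutation of `seq_along(sampleIds(act))`.
#' @export
clusterSampleOrder <- function(act) {
  stopifnot(is(act, "ActivityMatrix"))
  v <- activityValues(act)
  .stopIf(ncol(v) < 2L, "sample clustering needs at least 2 samples")
  hc <- stats::hclust(stats::dist(t(v), method = "euclidean"),
                      method = "complete")
  hc$order
}
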