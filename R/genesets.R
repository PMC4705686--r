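#' @include AllClasses.R AllGenerics.R
NULL

#' Read weighted gene sets from a 3-column TSV file
#'
#' Each data row is `set_name<TAB>gene_id<TAB>weight`; one row per
#' (set, gene) pair. The file may contain multiple sets; sets are returned
#' in first-appearance order. No header is required, but a first row whose
#' third field is non-numeric is treated as a header and skipped with a
#' notice. Weights may be any finite positive or negative reals.
#'
#' @param path path to the gene-set file.
#' @return list of [GeneSet-class] objects, named by set.
#' @seealso [writeGeneSetFile()], [readGmt()]
#' @export
readGeneSetFile <- function(path) {
  .stopIf(!file.exists(path), "gene-set file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  .stopIf(length(lines) == 0L, "empty gene-set file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  .stopIf(length(bad) > 0, "line ", bad[1],
          " does not have 3 tab-separated fields in ", path)
  w1 <- suppressWarnings(as.numeric(fields[[1]][3]))
  if (is.na(w1)) {
    message("skipping header row of ", path, ": '", lines[1], "'")
    fields <- fields[-1]
    .stopIf(length(fields) == 0L, "gene-set file holds only a header: ", path)
  }
  m <- do.call(rbind, fields)
  setNamesCol <- m[, 1]; genes <- m[, 2]
  w <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(w))
    stop("non-numeric weight '", m[which(is.na(w))[1], 3],
         "' for gene '", genes[which(is.na(w))[1]], "' in ", path,
         call. = FALSE)
  key <- paste(setNamesCol, genes, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop("duplicate (set, gene) pair: ('", setNamesCol[d], "', '",
         genes[d], "') in ", path, call. = FALSE)
  }
  out <- lapply(unique(setNamesCol), function(s) {
    i <- setNamesCol == s
    GeneSet(s, genes[i], w[i])
  })
  stats::setNames(out, unique(setNamesCol))
}

#' Write gene sets to the 3-column TSV format
#'
#' @param sets a [GeneSet-class] or list of them.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeGeneSetFile <- function(sets, path) {
  if (is(sets, "GeneSet")) sets <- list(sets)
  rows <- unlist(lapply(sets, function(gs) {
    stopifnot(is(gs, "GeneSet"))
    paste(setName(gs), geneIds(gs), .fmtNum(gs@weights), sep = "\t")
  }))
  writeLines(rows, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: `name<TAB>description<TAB>gene1<TAB>gene2...`. All members
#' receive unit weight.
#'
#' @param path path to the GMT file.
#' @return named list of [GeneSet-class] objects, unit weights.
#' @export
readGmt <- function(path) {
  .stopIf(!file.exists(path), "GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  .stopIf(length(lines) == 0L, "empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  .stopIf(length(bad) > 0, "malformed GMT line ", bad[1],
          " (fewer than 3 fields) in ", path)
  nm <- vapply(fields, `[[`, character(1), 1)
  .stopIf(anyDuplicated(nm) > 0, "gene set '", nm[duplicated(nm)][1],
          "' listed twice in ", path)
  out <- lapply(fields, function(f) GeneSet(f[1], unique(f[-(1:2)])))
  stats::setNames(out, nm)
}

#' Build a gene set from typed positive/negative gene lists
#'
#' Mirrors keyboard entry of gene IDs: IDs in the positive list receive
#' weight +1 and IDs in the negative list weight -1. The lists must be
#' disjoint and their union nonempty.
#'
#' @param name set name.
#' @param positiveIds,negativeIds character vectors of gene IDs.
#' @return a [GeneSet-class].
#' @export
keyboardGeneSet <- function(name, positiveIds, negativeIds = character()) {
  positiveIds <- as.character(positiveIds)
  negativeIds <- as.character(negativeIds)
  both <- intersect(positiveIds, negativeIds)
  .stopIf(length(both) > 0, "gene(s) in both positive and negative lists: ",
          paste(both, collapse = ", "))
  .stopIf(length(positiveIds) + length(negativeIds) == 0L,
          "at least one gene ID required")
  GeneSet(name, c(positiveIds, negativeIds),
          c(rep(1, length(positiveIds)), rep(-1, length(negativeIds))))
}

#' Read a 2-column homolog mapping table
#'
#' `source_gene_id<TAB>target_gene_id`, headerless; one source may map to
#' several targets. Exact duplicate pairs are an error.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `source` and `target`.
#' @export
readHomologMap <- function(path) {
  .stopIf(!file.exists(path), "homolog map not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  .stopIf(ncol(tab) != 2L, "homolog map must have exactly 2 columns: ", path)
  map <- data.frame(source = tab[[1]], target = tab[[2]],
                    stringsAsFactors = FALSE)
  .stopIf(anyDuplicated(paste(map$source, map$target, sep = "\r")) > 0,
          "duplicate homolog pairs in ", path)
  map
}

#' Convert a gene set to another species via a homolog table
#'
#' Each member is replaced by all of its mapped homologs, every target
#' inheriting the source weight (one-to-many expansion). When two sources
#' map to the same target, the first-seen weight is kept and the conflict
#' logged. Unmapped genes are dropped and listed in the report. The
#' converted set must stay valid: conversion that empties the set (or
#' zeroes the sum of absolute weights) is an error.
#'
#' @param gs a [GeneSet-class].
#' @param map data.frame with columns `source`, `target`
#'   (see [readHomologMap()]).
#' @return list with elements `geneSet` (converted [GeneSet-class]),
#'   `dropped` (unmapped source IDs) and `conflicts` (data.frame of target,
#'   kept and discarded weights; zero rows if none).
#' @export
convertSpecies <- function(gs, map) {
  stopifnot(is(gs, "GeneSet"),
            all(c("source", "target") %in% colnames(map)))
  outIds <- character(); outW <- numeric()
  dropped <- character()
  conflicts <- list()
  w <- geneWeights(gs)
  for (g in geneIds(gs)) {
    targets <- map$target[map$source == g]
    if (length(targets) == 0L) {
      dropped <- c(dropped, g)
      next
    }
    for (t in targets) {
      i <- match(t, outIds)
      if (is.na(i)) {
        outIds <- c(outIds, t)
        outW <- c(outW, unname(w[g]))
      } else if (outW[i] != w[g]) {
        conflicts[[length(conflicts) + 1L]] <-
          data.frame(target = t, kept = outW[i], discarded = unname(w[g]))
      }
    }
  }
  .stopIf(length(outIds) == 0L,
          "conversion dropped every gene of set '", setName(gs), "'")
  .stopIf(sum(abs(outW)) == 0,
          "conversion left set '", setName(gs), "' with all-zero weights")
  if (length(dropped))
    message("convertSpecies: dropped ", length(dropped),
            " unmapped gene(s) from '", setName(gs), "'")
  conflicts <- if (length(conflicts)) do.call(rbind, conflicts) else
    data.frame(target = character(), kept = numeric(),
               discarded = numeric())
  if (nrow(conflicts))
    message("convertSpecies: ", nrow(conflicts),
            " weight conflict(s); first-seen weight kept")
  list(geneSet = GeneSet(setName(gs), outIds, outW),
       dropped = dropped, conflicts = conflicts)
}

#' Replace a fraction of a gene set by random genes
#'
#' Robustness utility: exactly `round(fraction * size)` members, chosen
#' uniformly at random under the given seed, are replaced by distinct
#' random genes from the universe that are not already members. Replaced
#' members' weights carry over to their replacements, so the set size and
#' the multiset of weights are preserved at every fraction.
#'
#' @param gs a [GeneSet-class].
#' @param fraction fraction of members to replace, in \[0, 1\].
#' @param geneUniverse character vector of candidate gene IDs.
#' @param seed integer seed.
#' @return a perturbed [GeneSet-class] of identical size.
#' @export
perturbGeneSet <- function(gs, fraction, geneUniverse, seed) {
  stopifnot(is(gs, "GeneSet"))
  .stopIf(!is.finite(fraction) || fraction < 0 || fraction > 1,
          "fraction must lie in [0, 1]")
  ids <- geneIds(gs)
  m <- length(ids)
  r <- round(fraction * m)
  if (r == 0L) return(gs)
  pool <- setdiff(geneUniverse, ids)
  .stopIf(length(pool) < r, "gene universe too small: need ", r,
          " replacement genes outside the set, have ", length(pool))
  withSeed(seed, {
    victims <- sample.int(m, r)
    repl <- sample(pool, r)
    ids[victims] <- repl
  })
  GeneSet(setName(gs), ids, gs@weights)
}

#' Drop genes shared by two or more gene sets
#'
#' Optional utility for analyses that require disjoint sets: removes every
#' gene occurring in more than one of the given sets from all of them.
#' Never applied silently by other functions.
#'
#' @param sets list of [GeneSet-class] objects.
#' @return list of [GeneSet-class] objects with shared genes removed;
#'   errors if removal would empty a set.
#' @export
removeSharedGenes <- function(sets) {
  stopifnot(length(sets) >= 2L)
  allIds <- unlist(lapply(sets, geneIds))
  shared <- unique(allIds[duplicated(allIds)])
  lapply(sets, function(gs) {
    keep <- !(geneIds(gs) %in% shared)
    .stopIf(!any(keep), "removing shared genes empties set '",
            setName(gs), "'")
    GeneSet(setName(gs), geneIds(gs)[keep], gs@weights[keep])
  })
}
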