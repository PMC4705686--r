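#' @include AllClasses.R AllGenerics.R
NULL

#' Compute weighted gene-set activities across a compendium
#'
#' The activity of gene set s in sample i is the weighted average
#' \deqn{y_{si} = \frac{\sum_{g \in s} w_g x_{gi}}{\sum_{g \in s} |w_g|}}
#' over the member genes present in the compendium. With all weights 1
#' this is the mean expression of the member genes; negative weights let
#' repressed targets pull the score down, so the activity tracks a
#' regulator's output rather than mean target expression. Member genes
#' absent from the compendium are excluded from both numerator and
#' denominator (the denominator renormalizes naturally) and recorded in
#' the usage report; sets with no present member, or whose present members
#' all have zero weight, are an error.
#'
#' @param comp an [ExpressionCompendium-class].
#' @param sets a [GeneSet-class] or list of them; names must be unique.
#' @return an [ActivityMatrix-class], sets x samples, sample order
#'   identical to the compendium.
#' @examples
#' m <- matrix(c(10, -2, 1, 9), 2, 2,
#'             dimnames = list(c("pos", "neg"), c("i", "k")))
#' comp <- ExpressionCompendium(m, c(i = "tumor", k = "normal"))
#' tg <- GeneSet("TG", c("pos", "neg"), c(1, -1))
#' activityValues(computeActivity(comp, tg))  # 6 and -4
#' @export
computeActivity <- function(comp, sets) {
  stopifnot(is(comp, "ExpressionCompendium"))
  if (is(sets, "GeneSet")) sets <- list(sets)
  .stopIf(length(sets) == 0L, "at least one gene set required")
  nm <- unname(vapply(sets, setName, character(1)))
  .stopIf(anyDuplicated(nm) > 0, "duplicate gene-set names: ",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sc <- scoreMatrix(comp)
  usage <- vector("list", length(sets))
  vals <- matrix(NA_real_, length(sets), ncol(sc),
                 dimnames = list(nm, colnames(sc)))
  for (j in seq_along(sets)) {
    gs <- sets[[j]]
    present <- geneIds(gs) %in% rownames(sc)
    used <- geneIds(gs)[present]
    w <- gs@weights[present]
    .stopIf(length(used) == 0L, "no member gene of set '", nm[j],
            "' is present in the compendium")
    denom <- sum(abs(w))
    .stopIf(denom == 0, "present member genes of set '", nm[j],
            "' all have zero weight")
    vals[j, ] <- as.numeric(w %*% sc[used, , drop = FALSE]) / denom
    usage[[j]] <- list(used = used, missing = geneIds(gs)[!present])
    if (any(!present))
      message("computeActivity: set '", nm[j], "' missing ",
              sum(!present), "/", length(present),
              " gene(s) from the compendium")
  }
  new("ActivityMatrix", values = vals, usage = stats::setNames(usage, nm))
}

#' Mean and standard deviation of a gene set's activity
#'
#' Sample mean and sample SD (denominator N-1) of one set's activities
#' across all samples; the moments behind SD-based and normal-tail
#' cutoffs.
#'
#' @param act an [ActivityMatrix-class].
#' @param setName name of a set in `act`.
#' @return named numeric vector `c(mean=, sd=)`.
#' @export
activityMoments <- function(act, setName) {
  stopifnot(is(act, "ActivityMatrix"))
  .stopIf(!(setName %in% geneSetNames(act)), "unknown gene set '",
          setName, "'")
  y <- activityValues(act)[setName, ]
  .stopIf(length(y) < 2L, "standard deviation needs at least 2 samples")
  c(mean = mean(y), sd = stats::sd(y))
}

#' Write / read an activity matrix as TSV
#'
#' Sets x samples with a header row of sample IDs and set names in the
#' first column; values carry 12 significant digits.
#'
#' @param act an [ActivityMatrix-class].
#' @param path file path.
#' @return `writeActivity()` invisibly returns `path`; `readActivity()`
#'   returns an [ActivityMatrix-class] (usage report empty: the file does
#'   not carry one).
#' @export
writeActivity <- function(act, path) {
  stopifnot(is(act, "ActivityMatrix"))
  v <- activityValues(act)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste(c("gene_set", colnames(v)), collapse = "\t"), con)
  writeLines(vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], .fmtNum(v[i, ])), collapse = "\t"),
    character(1)), con)
  invisible(path)
}

#' @rdname writeActivity
#' @export
readActivity <- function(path) {
  .stopIf(!file.exists(path), "activity file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  v <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- tab[[1]]
  usage <- lapply(seq_len(nrow(v)),
                  function(i) list(used = character(),
                                   missing = character()))
  new("ActivityMatrix", values = v,
      usage = stats::setNames(usage, rownames(v)))
}
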