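#' @include AllClasses.R AllGenerics.R
NULL

#' One-sided Fisher enrichment P-value for a context
#'
#' P-value of a one-sided (enrichment) Fisher's exact test that context
#' membership is over-represented among the selected samples: with X
#' hypergeometric (drawing the `K` selected samples from `N`, of which
#' `n_c` belong to the context), P = P(X >= k_c). Vectorized over the
#' first two arguments.
#'
#' @param k_c selected samples in the context.
#' @param n_c context size.
#' @param K total selected samples.
#' @param N total compendium samples.
#' @return P-value(s) in \[0, 1\]; an empty context (`n_c = 0`) gives 1.
#' @export
fisherEnrichmentP <- function(k_c, n_c, K, N) {
  .stopIf(any(n_c > N) || K > N, "counts exceed the compendium size")
  .stopIf(any(k_c < 0) || any(k_c > pmin(n_c, K)),
          "k_c must lie in [0, min(n_c, K)]")
  stats::phyper(k_c - 1, K, N - K, n_c, lower.tail = FALSE)
}

#' Pseudocounted POI fold change for a context
#'
#' Ratio of the context's pseudocounted selection rate to the global
#' selection rate:
#' \deqn{f_c = \frac{(k_c + K/N) / (n_c + 1)}{K/N}}
#' The pseudocounts keep the ratio finite for empty contexts (an
#' unselected, empty context has fold change exactly 1) and shrink small
#' contexts toward 1. Strictly increasing in `k_c`. Vectorized over the
#' first two arguments.
#'
#' @inheritParams fisherEnrichmentP
#' @return positive fold change(s); requires `K >= 1` (an empty selection
#'   has no rate to compare against).
#' @export
poiFoldChange <- function(k_c, n_c, K, N) {
  .stopIf(K < 1, "fold change needs at least one selected sample (K >= 1)")
  .stopIf(any(k_c < 0) || any(k_c > n_c), "k_c must lie in [0, n_c]")
  rate <- K / N
  ((k_c + rate) / (n_c + 1)) / rate
}

#' Bonferroni adjustment over C hypothesis tests
#'
#' @param pValues raw P-values in \[0, 1\].
#' @param C number of tests (at least `length(pValues)`; in context
#'   enrichment, the number of distinct annotated contexts).
#' @return `pmin(1, C * pValues)`.
#' @export
adjustBonferroni <- function(pValues, C) {
  .stopIf(any(pValues < 0) || any(pValues > 1),
          "P-values must lie in [0, 1]")
  .stopIf(C < length(pValues),
          "C must be at least the number of P-values")
  pmin(1, C * pValues)
}

#' Context enrichment of POI-selected samples
#'
#' Selects samples with [matchSamples()], then tests every annotated
#' context for over-representation among the selected samples with a
#' one-sided Fisher's exact test, Bonferroni-corrects across the C
#' contexts, computes the pseudocounted fold change, and ranks. Reported
#' contexts pass `p_adj < pCutoff` and `fold_change > fcCutoff` (strict,
#' defaults 0.05 and 1.5); ranking is by ascending `p_adj`, ties broken by
#' descending fold change, then label. A POI matching no samples is not an
#' error: it is logged and an empty result returned.
#'
#' @param comp an [ExpressionCompendium-class] supplying the context
#'   annotations.
#' @param act the [ActivityMatrix-class] computed from `comp`.
#' @param poi a [POI-class].
#' @param pCutoff adjusted-P threshold (report if below; default 0.05).
#' @param fcCutoff fold-change threshold (report if above; default 1.5).
#' @return an [EnrichmentResult-class].
#' @export
runEnrichment <- function(comp, act, poi, pCutoff = 0.05, fcCutoff = 1.5) {
  stopifnot(is(comp, "ExpressionCompendium"), is(act, "ActivityMatrix"),
            is(poi, "POI"))
  .stopIf(!identical(sampleIds(act), sampleIds(comp)),
          "activity matrix and compendium sample order differ")
  .stopIf(!is.finite(pCutoff) || pCutoff <= 0 || pCutoff > 1,
          "pCutoff must lie in (0, 1]")
  .stopIf(!is.finite(fcCutoff) || fcCutoff < 0,
          "fcCutoff must be nonnegative")
  mask <- matchSamples(poi, act)
  ctx <- sampleContexts(comp)
  labels <- sort(unique(ctx))
  C <- length(labels)
  N <- length(ctx)
  K <- sum(mask)
  emptyTab <- data.frame(context = character(), n_c = integer(),
                         k_c = integer(), fold_change = numeric(),
                         p_raw = numeric(), p_adj = numeric(),
                         stringsAsFactors = FALSE)
  if (K == 0L) {
    message("runEnrichment: POI matches no samples")
    return(new("EnrichmentResult", full = emptyTab, reported = emptyTab,
               nTotal = as.integer(N), nSelected = 0L,
               nContexts = as.integer(C)))
  }
  n_c <- as.integer(table(ctx)[labels])
  k_c <- as.integer(vapply(labels, function(l) sum(mask[ctx == l]),
                           numeric(1)))
  p_raw <- fisherEnrichmentP(k_c, n_c, K, N)
  tab <- data.frame(context = labels, n_c = n_c, k_c = k_c,
                    fold_change = poiFoldChange(k_c, n_c, K, N),
                    p_raw = p_raw,
                    p_adj = adjustBonferroni(p_raw, C),
                    stringsAsFactors = FALSE)
  ord <- order(tab$p_adj, -tab$fold_change, tab$context)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  rep <- tab[tab$p_adj < pCutoff & tab$fold_change > fcCutoff, ,
             drop = FALSE]
  rownames(rep) <- NULL
  message("runEnrichment: N = ", N, ", K = ", K, ", C = ", C, "; ",
          nrow(rep), " context(s) reported")
  new("EnrichmentResult", full = tab, reported = rep,
      nTotal = as.integer(N), nSelected = as.integer(K),
      nContexts = as.integer(C))
}

#' Write a context ranking table as TSV
#'
#' Columns `context`, `n_c`, `k_c`, `fold_change`, `p_raw`, `p_adj` in
#' ranked order; floating-point columns carry 8 significant digits.
#'
#' @param results an [EnrichmentResult-class] (its reported table is
#'   written) or a data.frame with the six columns above.
#' @param path output path.
#' @param full if `TRUE` and `results` is an [EnrichmentResult-class],
#'   write the complete unfiltered table instead of the reported subset.
#' @return invisibly, `path`.
#' @export
writeRankingTable <- function(results, path, full = FALSE) {
  tab <- if (is(results, "EnrichmentResult")) {
    if (full) fullTable(results) else rankingTable(results)
  } else results
  cols <- c("context", "n_c", "k_c", "fold_change", "p_raw", "p_adj")
  .stopIf(!all(cols %in% colnames(tab)),
          "ranking table needs columns: ", paste(cols, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(tab))
    writeLines(paste(tab$context, tab$n_c, tab$k_c,
                     .fmtNum(tab$fold_change, 8L),
                     .fmtNum(tab$p_raw, 8L),
                     .fmtNum(tab$p_adj, 8L), sep = "\t"), con)
  invisible(path)
}

#' Fraction of reported contexts lacking independent support
#'
#' Literature-validation summary: of `nReported` reported contexts,
#' `nSupported` have independent experimental support; the remainder,
#' expressed as a percentage of the reported contexts, is a conservative
#' estimate of the false discovery rate (unstudied contexts may yet prove
#' true).
#'
#' @param nReported number of reported contexts (>= 1).
#' @param nSupported number with independent support (0..nReported).
#' @return percentage in \[0, 100\].
#' @examples
#' estimateUnsupportedFraction(30, 21)  # 30
#' @export
estimateUnsupportedFraction <- function(nReported, nSupported) {
  .stopIf(nReported < 1, "nReported must be at least 1")
  .stopIf(nSupported < 0 || nSupported > nReported,
          "nSupported must lie in [0, nReported]")
  100 * (nReported - nSupported) / nReported
}
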