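---
title: "Linking gene-set activity patterns to biological contexts with setquery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking gene-set activity patterns to biological contexts with setquery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(setquery)
```

## The problem

Public expression databases hold hundreds of thousands of samples spanning
cells, tissues, diseases and treatments. Once a platform's samples have been
consistently normalized into z-score-like values and each sample annotated
with a single biological-context label, a simple but powerful query becomes
possible: *in which biological contexts does my gene set show a particular
activity pattern?* A researcher with a fresh gene set — say, targets of a
transcription factor from a ChIP experiment — can screen a whole compendium
for contexts where that set is concordantly active, and obtain a ranked,
statistically screened list of candidate contexts for follow-up.

`setquery` implements that engine: weighted gene-set activity scoring,
flexible sample selection by a *pattern of interest* (POI), and per-context
enrichment testing, together with the file formats, cross-species
conversion, robustness utilities and a synthetic-compendium generator for
validation.

## Gene-set activity

For gene $g$ with expression score $x_{gi}$ in sample $i$, the activity of
gene set $s$ with user weights $w_g$ is the weighted average

$$y_{si} = \frac{\sum_{g \in s} w_g\, x_{gi}}{\sum_{g \in s} |w_g|}.$$

With all $w_g = 1$ (the default) this is simply the mean expression of the
member genes. Negative weights encode anti-correlated members: for a
transcription factor's target set, activated targets take $w_g = +1$ and
repressed targets $w_g = -1$, so the score tracks the factor's *regulatory
output* rather than mean target expression. A two-gene illustration — one
activated target scoring 10 and one repressed target scoring −2 — gives
$y = (1\cdot 10 + (-1)(-2))/2 = 6$, whereas the unit-weight mean of the
same sample is 4 and inverts the intended ordering across samples:

```{r}
comp <- ExpressionCompendium(
  matrix(c(10, -2, 1, 9), nrow = 2,
         dimnames = list(c("pos", "neg"), c("active", "inactive"))),
  c(active = "ctxA", inactive = "ctxB"))
act <- computeActivity(comp, list(
  GeneSet("signed", c("pos", "neg"), c(1, -1)),
  GeneSet("unit",   c("pos", "neg"))))
activityValues(act)
```

The denominator $\sum |w_g|$ makes the score invariant to positive
rescaling of a set's weights, and renormalizes automatically when member
genes are absent from a compendium. That missing-gene policy — exclude
absent genes from numerator and denominator, log the count, and record the
identities in the activity object's usage report — is deliberate: partial
overlap is routine in cross-platform and cross-species use, and the
renormalized weighted average remains a comparable activity score. A set
with *no* member present (or only zero-weight members present) has no
defined activity and is an error rather than a silent `NA`.

## Patterns of interest

A POI is a predicate over activity space; `matchSamples()` turns it into a
logical mask over samples. Four kinds cover the practical spectrum:

* **Interval POI** — a conjunction of per-set open intervals
  $y_{si} \in (c_{s1}, c_{s2})$; infinite bounds give one-sided
  constraints. The default POI (`defaultPOI()`) demands every set exceed
  one SD above its mean activity — "all sets highly active".
* **Union-interval POI** — a union of intervals for a single set, for
  selections like "low or high but not intermediate".
* **Polygon POI** — one or more simple polygons in the plane of two sets'
  activities, the programmatic equivalent of lassoing a region of a
  scatter plot; vertex lists are data, so saved selections are
  reproducible.
* **Formula POI** — an expression over set names, e.g.
  `"(MYC+2)^2 + (MYC_TG-2)^2*10 < 4"` (an ellipse), combining arithmetic
  (`+ - * / ^`), comparators (`< > <= >=`) and logic (`& |`).

Cutoffs need not be raw numbers: a `cutoffSpec()` expresses a bound as SDs
from the mean, as an empirical quantile, or as a normal-tail probability
under a Normal fit to the observed activities, and is resolved against the
activity matrix at match time. Every POI serializes to a small versioned
JSON document (`savePOI()`/`loadPOI()`); saving with the activity matrix at
hand additionally records the resolved numeric cutoffs, documenting exactly
which thresholds produced a reported selection.

Three conventions are fixed here because the underlying choice is genuinely
open, and recorded so results are deterministic:

* Interval bounds are **strict** (open intervals): the interval and
  greater-than notations agree on open bounds, and a sample tied exactly
  at a cutoff is excluded.
* Polygon boundaries count as **inside**: a vertex-snapped selection then
  selects the clicked points, and the mask is closed under taking limits
  onto the boundary.
* Formula operator precedence is `^` (right-associative), then unary
  minus, `* /`, `+ -`, comparators, `&`, `|`. This is exactly R's own
  precedence, so formulas are parsed with R's parser and then checked
  against a strict whitelist of operators and known set identifiers —
  nothing else (no function calls) can appear, which makes evaluating
  user-supplied formulas safe. Set names are sanitized into identifiers by
  replacing non-alphanumeric characters with `_` (prefixing `g` if needed);
  a collision between sanitized names is an error rather than a silent
  merge.

## Context enrichment

Let $N$ be the number of compendium samples, $K$ of them selected by the
POI, and let context $c$ contain $n_c$ samples of which $k_c$ are selected.
`runEnrichment()` asks, for every annotated context, whether the context is
over-represented in the selection, using the one-sided Fisher's exact
(hypergeometric tail) probability $P(X \ge k_c)$. A one-sided test is used
deliberately: the ranking reports *enriched* contexts, and a two-sided test
would also flag depletion, which the table does not report.

Raw P-values are Bonferroni-adjusted with factor $C$ equal to the number of
distinct annotated contexts — all contexts are tested, not only those with
$k_c > 0$. Each context also receives a pseudocounted fold change

$$f_c = \frac{(k_c + K/N)/(n_c + 1)}{K/N},$$

the ratio of the context's (pseudocounted) selection rate to the global
rate: an empty, unselected context has $f_c = 1$ exactly, $f_c$ is strictly
increasing in $k_c$, and small contexts are shrunk toward 1. Contexts with
adjusted $P < 0.05$ **and** fold change $> 1.5$ (both strict, both
user-adjustable) are reported, ranked by adjusted P, ties broken by
descending fold change and then label — the tie-break is fixed purely for
reproducibility. No minimum context size is imposed; size-1 contexts are
tested and are naturally hard to call significant. A POI that matches no
samples is not an exception in batch use: it is logged and an empty table
returned.

The adjusted P-values assume independent samples, and they measure
significance only for a POI fixed *before* inspecting results;
interactively re-tuning a POI until something passes turns the analysis
exploratory, and the P-values then serve only to rank contexts.
Correlation-aware inference across samples is out of scope.

## Synthetic compendia and what the tests show

`synthesizeCompendium()` generates the validation substrate: i.i.d.
Normal(0, `baselineSd`²) scores — emulating consistently normalized
compendium z-scores, which sit near zero for unexpressed genes — with
"implants" that add a constant `delta` to a listed gene subset within one
context's samples, i.e. a gene set concordantly shifted in one context. All
randomness derives from the design's seed; generation is bit-reproducible
and leaves the caller's RNG untouched.

The package's recovery experiments use a design of 1000 genes and 1000
samples in 20 contexts of 50, with a single 50-gene implant at `delta = 1`
(one baseline SD) — an effect size at which single genes are far from
separable and only aggregation over the set makes the context detectable.
The 1000-gene universe was chosen as the same order of magnitude as the
sample count; the remaining design values follow the recovery experiment's
specification. Across 100 seeds the implanted context ranks first under
the default POI in ≥95 runs, and still passes the default reporting
cutoffs in ≥80 runs after half the set's genes are replaced by random
genes (`perturbGeneSet()`, which preserves set size and the multiset of
weights so that $\sum|w|$ stays comparable across noise levels). These
numbers are properties of the synthetic model: independent Gaussian
scores, a single clean implant, equal-sized contexts. Real compendia have
correlated genes and samples, heterogeneous context sizes, and annotation
noise, so passing these tests demonstrates the engine's correctness and
qualitative noise-robustness, not field performance on real data.

## Numerical conventions

* Activity SD uses the sample (N−1) denominator; either convention is
  defensible, this one is recorded for determinism.
* Empirical quantiles interpolate linearly between order statistics
  (R type 7).
* `perturbGeneSet()` replaces `round(fraction * size)` members.
* Heat-map sample ordering uses complete-linkage clustering on Euclidean
  distances (`stats::hclust`), whose deterministic tie handling fixes the
  leaf order.
* TSV writers emit 12 significant digits, so write/read round trips
  preserve scores to at least 10 significant digits; identical inputs give
  byte-identical outputs.
* Matrices are oriented genes × samples with a mandatory header; missing
  values are rejected, not imputed (normalized compendia are complete);
  context labels are case-sensitive opaque strings and may not contain
  tabs or newlines (delimiter safety).

## Other design decisions

Cross-species conversion (`convertSpecies()`) expands each gene to *all*
its homologs, every target inheriting the source weight; one-to-many
expansion preserves information, and when two sources collide on a target
the first-seen weight is kept and the conflict reported. Genes shared
between input sets are never removed silently — `removeSharedGenes()` is
provided as an explicit utility for analyses that require disjoint sets.
Weighted gene-set files are 3-column TSV (`set`, `gene`, `weight`), GMT is
accepted with unit weights, and keyboard-style entry assigns +1/−1 to
positive/negative gene lists.

## Limitations

Compendia from different platforms are not directly comparable and must be
analysed separately; no normalization is performed here — inputs are
consumed pre-normalized. Sample independence is assumed by the test;
contexts are free-text labels with no ontology mapping; and the synthetic
generator's additive Gaussian model is a deliberately simple stand-in for
real compendium structure.
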