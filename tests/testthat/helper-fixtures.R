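# small in-code fixtures shared across test files

# 2-gene compendium carrying the signed-weight worked example:
# positive target expressed (10, 1), negative target (-2, 9)
toyCompendium <- function() {
  m <- matrix(c(10, -2, 1, 9), nrow = 2,
              dimnames = list(c("pos", "neg"), c("i", "k")))
  ExpressionCompendium(m, c(i = "tumor", k = "normal"))
}

# random annotated compendium, labels cycled over contexts
randomCompendium <- function(nGenes = 20, nSamples = 12, nContexts = 3,
                             seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(nGenes * nSamples), nGenes,
              dimnames = list(paste0("g", seq_len(nGenes)),
                              paste0("s", seq_len(nSamples))))
  ctx <- rep(paste0("ctx", seq_len(nContexts)), length.out = nSamples)
  ExpressionCompendium(m, stats::setNames(ctx, colnames(m)))
}

# ActivityMatrix built directly from a values matrix (empty usage report)
makeActivity <- function(values) {
  usage <- lapply(rownames(values),
                  function(s) list(used = character(),
                                   missing = character()))
  new("ActivityMatrix", values = values,
      usage = stats::setNames(usage, rownames(values)))
}

# one-set activity matrix from a numeric vector
activityFromVector <- function(y, set = "A") {
  v <- matrix(y, nrow = 1,
              dimnames = list(set, paste0("s", seq_along(y))))
  makeActivity(v)
}

# random star-shaped (hence simple) polygon around the origin: jittered
# even angular spacing keeps every angular gap below pi, so the origin is
# interior and the boundary is single-valued in angle
randomSimplePolygon <- function(nVertices = 6) {
  spacing <- 2 * pi / nVertices
  theta <- spacing * (seq_len(nVertices) - 1) +
    runif(nVertices, 0, 0.4 * spacing)
  r <- runif(nVertices, 0.5, 2)
  cbind(r * cos(theta), r * sin(theta))
}

# recovery design used by the parameter-recovery experiments: 1000 genes,
# 20 contexts of 50 samples, one 50-gene implant in ctx01
recoveryDesign <- function(seed, delta = 1) {
  syntheticDesign(
    nGenes = 1000,
    contexts = data.frame(label = sprintf("ctx%02d", 1:20),
                          size = rep(50L, 20)),
    implants = list(list(context = "ctx01",
                         genes = paste0("g", 1:50),
                         delta = delta)),
    baselineSd = 1, seed = seed)
}

# exhaustive hypergeometric upper-tail probability by direct enumeration
# with binomial coefficients — independent of the implementation under test
enumTailP <- function(k, n, K, N) {
  j <- seq(k, min(n, K))
  if (length(j) == 0) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

writeLinesTo <- function(lines, dir = tempdir(), ext = ".tsv") {
  f <- tempfile(tmpdir = dir, fileext = ext)
  writeLines(lines, f)
  f
}
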