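test_that("a hand-written matrix + annotation round-trips through the reader", {
  mfile <- writeLinesTo(c("gene_id\tS1\tS2",
                          "g1\t0.5\t-1.25",
                          "g2\t2\t0",
                          "g3\t-3.5\t1e-3"))
  afile <- writeLinesTo(c("S1\tliver", "S2\tbrain"))
  comp <- readCompendium(mfile, afile)
  expect_s4_class(comp, "ExpressionCompendium")
  expect_identical(dim(scoreMatrix(comp)), c(3L, 2L))
  expect_identical(geneIds(comp), c("g1", "g2", "g3"))
  expect_identical(unname(sampleContexts(comp)), c("liver", "brain"))
  expect_equal(scoreMatrix(comp)["g3", "S2"], 1e-3)
})

test_that("reader rejects unannotated samples, duplicates and bad cells", {
  mfile <- writeLinesTo(c("gene_id\tS1\tS2", "g1\t1\t2"))
  aMissing <- writeLinesTo("S1\tliver")
  expect_error(readCompendium(mfile, aMissing), "S2")

  aBoth <- writeLinesTo(c("S1\tliver", "S2\tbrain"))
  mDup <- writeLinesTo(c("gene_id\tS1\tS2", "g1\t1\t2", "g1\t3\t4"))
  expect_error(readCompendium(mDup, aBoth), "duplicate gene")

  mBad <- writeLinesTo(c("gene_id\tS1\tS2", "g1\t1\tNA?"))
  expect_error(readCompendium(mBad, aBoth), "non-numeric")
})

test_that("write/read is the identity on scores and labels", {
  comp <- randomCompendium(nGenes = 15, nSamples = 8, seed = 42)
  mf <- tempfile(); af <- tempfile()
  writeCompendium(comp, mf, af)
  back <- readCompendium(mf, af)
  expect_equal(scoreMatrix(back), scoreMatrix(comp), tolerance = 1e-10)
  expect_identical(sampleContexts(back), sampleContexts(comp))
})

test_that("compendium validity enforces shape, labels and finiteness", {
  m <- matrix(1, 1, 1, dimnames = list("g1", "s1"))
  expect_error(ExpressionCompendium(m[0, , drop = FALSE], c(s1 = "a")),
               "at least one gene")
  expect_error(ExpressionCompendium(m, c(s1 = "a\tb")), "tabs")
  mInf <- m; mInf[1, 1] <- Inf
  expect_error(ExpressionCompendium(mInf, c(s1 = "a")), "finite")
  expect_error(writeCompendium(
    ExpressionCompendium(matrix(1, 1, 1, dimnames = list("g\t1", "s1")),
                         c(s1 = "a")), tempfile(), tempfile()))
})

test_that("context summaries count each label once and sum to N", {
  m <- matrix(0.5, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  comp <- ExpressionCompendium(m, c(s1 = "A", s2 = "A", s3 = "B"))
  s <- summarizeContexts(comp)
  expect_identical(s$context, c("A", "B"))
  expect_identical(s$n_samples, c(2L, 1L))
  expect_identical(sum(s$n_samples), 3L)

  one <- ExpressionCompendium(m, c(s1 = "X", s2 = "X", s3 = "X"))
  s1 <- summarizeContexts(one)
  expect_identical(nrow(s1), 1L)
  expect_identical(s1$n_samples, 3L)
})

test_that("synthetic compendia recover the designed context sizes", {
  des <- syntheticDesign(nGenes = 30,
                         contexts = data.frame(label = c("B", "A", "C"),
                                               size = c(4, 7, 2)),
                         seed = 7)
  comp <- synthesizeCompendium(des)
  s <- summarizeContexts(comp)
  expect_identical(s$context, c("A", "B", "C"))
  expect_identical(s$n_samples, c(7L, 4L, 2L))
})

test_that("null synthetic scores average near zero and implants shift means", {
  des0 <- syntheticDesign(nGenes = 400,
                          contexts = data.frame(label = "A", size = 25),
                          baselineSd = 1, seed = 11)
  comp0 <- synthesizeCompendium(des0)
  bound <- 4 * 1 / sqrt(400)
  expect_true(all(abs(colMeans(scoreMatrix(comp0))) < bound))

  genes <- paste0("g", 1:50)
  des <- syntheticDesign(nGenes = 200,
                         contexts = data.frame(label = c("A", "B"),
                                               size = c(10, 10)),
                         implants = list(list(context = "A", genes = genes,
                                              delta = 3)),
                         baselineSd = 1, seed = 12)
  comp <- synthesizeCompendium(des)
  ctx <- sampleContexts(comp)
  mA <- mean(scoreMatrix(comp)[genes, ctx == "A"])
  mB <- mean(scoreMatrix(comp)[genes, ctx == "B"])
  err <- 4 * 1 / sqrt(50 * 10)
  expect_lt(abs(mA - 3), err)
  expect_lt(abs(mB - 0), err)
})

test_that("the generator is bit-reproducible and leaves the caller's RNG alone", {
  des <- syntheticDesign(nGenes = 50,
                         contexts = data.frame(label = "A", size = 5),
                         seed = 99)
  c1 <- synthesizeCompendium(des)
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(synthesizeCompendium(des)); after <- rnorm(3)
  c2 <- synthesizeCompendium(des)
  expect_identical(scoreMatrix(c1), scoreMatrix(c2))
  expect_identical(before, after)
})

test_that("designs referencing unknown contexts or genes are rejected", {
  expect_error(syntheticDesign(
    nGenes = 10, contexts = data.frame(label = "A", size = 2),
    implants = list(list(context = "Z", genes = "g1", delta = 1)),
    seed = 1), "unknown context")
  expect_error(syntheticDesign(
    nGenes = 10, contexts = data.frame(label = "A", size = 2),
    implants = list(list(context = "A", genes = "g999", delta = 1)),
    seed = 1), "unknown gene")
})

test_that("complete-linkage sample ordering places close samples together", {
  # 1-D activities 0, 1, 11: the pair at distance 1 must merge first
  act <- activityFromVector(c(0, 1, 11))
  ord <- clusterSampleOrder(act)
  pos <- match(1:2, ord)
  expect_equal(abs(pos[1] - pos[2]), 1L)

  # identical samples are adjacent leaves
  v <- matrix(c(0, 0, 5, 0, 0, 9), nrow = 2,
              dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  ord2 <- clusterSampleOrder(makeActivity(v))
  expect_equal(abs(match(1, ord2) - match(2, ord2)), 1L)

  expect_error(clusterSampleOrder(activityFromVector(1)), "at least 2")
})

test_that("sample ordering is equivariant under column permutation", {
  set.seed(5)
  v <- matrix(rnorm(3 * 8), nrow = 3,
              dimnames = list(c("A", "B", "C"), paste0("s", 1:8)))
  act <- makeActivity(v)
  ord <- clusterSampleOrder(act)
  perm <- sample(8)
  actP <- makeActivity(v[, perm, drop = FALSE])
  ordP <- clusterSampleOrder(actP)
  # same dendrogram: cophenetic distances agree after permutation
  coph <- function(m) {
    hc <- stats::hclust(stats::dist(t(m)), "complete")
    as.matrix(stats::cophenetic(hc))
  }
  cO <- coph(v)[perm, perm]
  cP <- coph(v[, perm, drop = FALSE])
  dimnames(cO) <- NULL; dimnames(cP) <- NULL
  expect_equal(cO, cP)
  # the globally closest pair stays adjacent in both leaf orders
  d <- as.matrix(stats::dist(t(v))); diag(d) <- Inf
  pair <- which(d == min(d), arr.ind = TRUE)[1, ]
  expect_equal(abs(match(pair[1], ord) - match(pair[2], ord)), 1L)
  pairP <- match(colnames(v)[pair], colnames(v)[perm])
  expect_equal(abs(match(pairP[1], ordP) - match(pairP[2], ordP)), 1L)
})
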