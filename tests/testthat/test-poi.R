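test_that("cutoffs resolve to means, SD offsets and interpolated quantiles", {
  act <- activityFromVector(1:10)
  m <- mean(1:10); s <- sd(1:10)
  expect_equal(resolveCutoff(cutoffSpec("raw", 3.25), act, "A"), 3.25)
  expect_equal(resolveCutoff(cutoffSpec("sd", 0), act, "A"), m)
  expect_equal(resolveCutoff(cutoffSpec("sd", 1.5), act, "A"), m + 1.5 * s)
  # interpolated 90th percentile of 1..10: between the 9th and 10th order
  # statistics, 9 + 0.1 * (10 - 9)
  expect_equal(resolveCutoff(cutoffSpec("quantile", 0.9), act, "A"), 9.1)
  # the median tail point of the fitted normal is its mean, on both sides
  expect_equal(resolveCutoff(cutoffSpec("normal_p", 0.5, "upper"), act, "A"), m)
  expect_equal(resolveCutoff(cutoffSpec("normal_p", 0.5, "lower"), act, "A"), m)
  # symmetric tails straddle the mean symmetrically
  up <- resolveCutoff(cutoffSpec("normal_p", 0.05, "upper"), act, "A")
  lo <- resolveCutoff(cutoffSpec("normal_p", 0.05, "lower"), act, "A")
  expect_equal(up - m, m - lo)
  expect_gt(up, m)

  expect_error(cutoffSpec("circle", 1), "unknown cutoff mode")
  expect_error(cutoffSpec("quantile", 1.2), "\\[0, 1\\]")
  expect_error(cutoffSpec("normal_p", 0), "\\(0, 1\\)")
  expect_error(resolveCutoff(cutoffSpec("sd", 1), act, "nope"), "unknown")
})

test_that("the default POI is one SD above the mean for every set", {
  poi <- defaultPOI(c("A", "B"))
  expect_s4_class(poi, "IntervalPOI")
  expect_identical(poi@sets, c("A", "B"))
  expect_true(all(vapply(poi@upper, function(b) is.numeric(b) && b == Inf,
                         logical(1))))
  expect_error(defaultPOI(character()), "at least one")

  # on ~N(0,1) activities it selects about the upper 16% of samples
  set.seed(10)
  act <- activityFromVector(rnorm(20000))
  frac <- mean(matchSamples(defaultPOI("A"), act))
  expect_lt(abs(frac - pnorm(1, lower.tail = FALSE)), 0.02)
})

test_that("interval masks use strict open bounds and conjoin across sets", {
  v <- matrix(c(1, 2, 3, 10, 20, 30), nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  act <- makeActivity(v)
  # tie at the cutoff is excluded
  m1 <- matchSamples(intervalPOI("A", lower = 2), act)
  expect_identical(unname(m1), c(FALSE, FALSE, TRUE))
  # conjunction across sets
  m2 <- matchSamples(intervalPOI(c("A", "B"), lower = c(1, 0),
                                 upper = c(3, 25)), act)
  expect_identical(unname(m2), c(FALSE, TRUE, FALSE))
  expect_error(matchSamples(intervalPOI("A", lower = 5, upper = 2), act),
               "empty interval")
  expect_error(matchSamples(intervalPOI("Z", lower = 0), act), "unknown")
})

test_that("relaxing an interval cutoff never deselects a sample", {
  set.seed(11)
  act <- makeActivity(matrix(rnorm(2 * 200), nrow = 2,
                             dimnames = list(c("A", "B"),
                                             paste0("s", 1:200))))
  for (i in 1:20) {
    lo <- runif(2, -1, 0.5)
    hi <- runif(2, 0.6, 2)
    tight <- matchSamples(intervalPOI(c("A", "B"), lo, hi), act)
    eps <- runif(2, 0, 0.5)
    loose <- matchSamples(intervalPOI(c("A", "B"), lo - eps, hi + eps), act)
    expect_true(all(loose[tight]))
  }
})

test_that("a union-of-intervals POI is the disjunction of its intervals", {
  act <- activityFromVector(c(-2, -0.5, 0, 0.5, 2))
  poi <- unionIntervalPOI("A", list(list(lower = -Inf, upper = -1),
                                    list(lower = 1, upper = Inf)))
  expect_identical(unname(matchSamples(poi, act)),
                   c(TRUE, FALSE, FALSE, FALSE, TRUE))
  m1 <- matchSamples(intervalPOI("A", upper = -1), act)
  m2 <- matchSamples(intervalPOI("A", lower = 1), act)
  expect_identical(matchSamples(poi, act), m1 | m2)
})

test_that("polygon membership counts the boundary as inside", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_true(pointInPolygon(0.5, 0.5, square))
  expect_false(pointInPolygon(2, 2, square))
  expect_true(pointInPolygon(0, 0.5, square))   # edge
  expect_true(pointInPolygon(1, 1, square))     # vertex

  v <- matrix(c(0.5, 2, 0.25, 0.5, 2, -0.25), nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  act <- makeActivity(v)
  poi <- polygonPOI("A", "B", square)
  expect_identical(unname(matchSamples(poi, act)),
                   c(TRUE, FALSE, FALSE))
})

test_that("multi-polygon masks equal the union of per-polygon masks", {
  set.seed(12)
  act <- makeActivity(matrix(runif(2 * 300, -2, 2), nrow = 2,
                             dimnames = list(c("A", "B"),
                                             paste0("s", 1:300))))
  p1 <- randomSimplePolygon(5)
  p2 <- randomSimplePolygon(7) + 1.5
  both <- matchSamples(polygonPOI("A", "B", list(p1, p2)), act)
  expect_identical(both,
                   matchSamples(polygonPOI("A", "B", p1), act) |
                     matchSamples(polygonPOI("A", "B", p2), act))
})

test_that("self-intersecting polygons are rejected", {
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(polygonPOI("A", "B", bowtie), "self-intersecting")
  expect_error(polygonPOI("A", "B", rbind(c(0, 0), c(0, 0), c(1, 1))))
})

test_that("the elliptical formula selects the centre and excludes the boundary", {
  v <- matrix(c(-2, 0, 2, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("MYC", "MYC_TG"), c("s1", "s2")))
  act <- makeActivity(v)
  poi <- formulaPOI("(MYC+2)^2+(MYC_TG-2)^2*10 < 4")
  m <- matchSamples(poi, act)
  expect_true(m[["s1"]])    # centre: 0 < 4
  expect_false(m[["s2"]])   # boundary: 4 < 4 is false
})

test_that("formula one-sided constraints agree with interval masks", {
  set.seed(13)
  act <- makeActivity(matrix(rnorm(2 * 500), nrow = 2,
                             dimnames = list(c("A", "B_x"),
                                             paste0("s", 1:500))))
  for (cutoff in c(-1, 0, 0.7)) {
    expect_identical(
      matchSamples(formulaPOI(paste0("A > ", cutoff)), act),
      matchSamples(intervalPOI("A", lower = cutoff), act))
  }
  # compound logic evaluates with R precedence
  mix <- matchSamples(formulaPOI("A > 0 & B_x < 0 | A < -1"), act)
  v <- activityValues(act)
  expect_identical(unname(mix),
                   unname(v["A", ] > 0 & v["B_x", ] < 0 | v["A", ] < -1))
})

test_that("formulas are validated against known sets and a safe grammar", {
  act <- activityFromVector(1:5)
  expect_error(matchSamples(formulaPOI("NOPE > 1"), act), "unknown gene set")
  expect_error(formulaPOI("system('ls') > 1"), "not allowed")
  expect_error(formulaPOI("sin(A) < 1"), "not allowed")
  expect_error(matchSamples(formulaPOI("A + 1"), act), "comparator")
  expect_error(formulaPOI("A >"), "cannot parse")
  expect_error(sanitizeSetNames(c("a b", "a.b")), "collide")
})

test_that("every POI kind survives a JSON round trip with an identical mask", {
  set.seed(14)
  act <- makeActivity(matrix(rnorm(2 * 100), nrow = 2,
                             dimnames = list(c("A", "B"),
                                             paste0("s", 1:100))))
  pois <- list(
    intervalPOI(c("A", "B"),
                lower = list(cutoffSpec("sd", 1), cutoffSpec("quantile", 0.2)),
                upper = list(Inf, cutoffSpec("normal_p", 0.1, "upper"))),
    unionIntervalPOI("A", list(list(lower = -Inf, upper = -1),
                               list(lower = cutoffSpec("sd", 1),
                                    upper = Inf))),
    polygonPOI("A", "B", randomSimplePolygon(6)),
    formulaPOI("(A+0.5)^2 + B^2 < 1.5 | A > 1.2"))
  for (poi in pois) {
    f <- tempfile(fileext = ".json")
    savePOI(poi, f, act = act)
    back <- loadPOI(f)
    expect_identical(matchSamples(back, act), matchSamples(poi, act))
  }
})

test_that("POI files tolerate whitespace edits but reject unknown types", {
  f <- tempfile(fileext = ".json")
  savePOI(defaultPOI("A"), f)
  txt <- readLines(f)
  edited <- tempfile(fileext = ".json")
  writeLines(c("", gsub("  ", "    ", txt), ""), edited)
  expect_s4_class(loadPOI(edited), "IntervalPOI")

  bad <- tempfile(fileext = ".json")
  writeLines('{"poi_version": 1, "type": "circle", "radius": 2}', bad)
  expect_error(loadPOI(bad), "unknown POI type 'circle'")
  broken <- tempfile(fileext = ".json")
  writeLines('{"poi_version": 1, "type": "interval"}', broken)
  expect_error(loadPOI(broken), "interval POI needs")
})
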