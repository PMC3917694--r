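test_that("calibration densities match their closed forms", {
  ## the reference root window: Uniform(52, 85)
  root <- uniformCalibration(52, 85)
  expect_equal(calibrationLogDensity(root, 60), log(1 / 33))
  expect_identical(calibrationLogDensity(root, 51.9), -Inf)
  expect_identical(calibrationLogDensity(root, 85.1), -Inf)
  ## offset-exponential: density 1/(mean-offset) at the offset, -Inf below
  oe <- offsetExpCalibration(18, 58)
  expect_equal(calibrationLogDensity(oe, 18), log(1 / 40))
  expect_identical(calibrationLogDensity(oe, 17), -Inf)
  ## integrates to one above the offset
  expect_equal(integrate(function(a) exp(calibrationLogDensity(oe, a)),
                         18, Inf)$value, 1, tolerance = 1e-4)
  ## reversed uniform window is normalised with a warning
  expect_warning(rev <- uniformCalibration(85, 52), "reversed")
  expect_equal(c(rev@minAge, rev@maxAge), c(52, 85))
})

test_that("branch-rate priors honour each clock's density contract", {
  tree <- balanced4(10, 4, 6)
  strict <- clockModel("strict")
  expect_equal(branchRatesLogPrior(strict, tree, rep(1, 6)), 0)
  expect_identical(branchRatesLogPrior(strict, tree, c(1, 1, 1.2, 1, 1, 1)),
                   -Inf)
  ## IGR: product of Gamma(mean 1, var nu/duration) densities
  igr <- clockModel("IGR", nu = 0.2)
  r <- c(0.9, 1.1, 1.05, 0.8, 1.3, 1.0)
  dur <- branchDurations(tree)
  sh <- dur / 0.2
  expect_equal(branchRatesLogPrior(igr, tree, r),
               sum(dgamma(r, sh, rate = sh, log = TRUE)))
  expect_identical(branchRatesLogPrior(igr, tree, replace(r, 2, -0.1)), -Inf)
  ## TK02 with nu -> 0 concentrates at the parent rate
  tk <- clockModel("TK02", nu = 1e-8)
  expect_gt(branchRatesLogPrior(tk, tree, rep(1, 6)),
            branchRatesLogPrior(tk, tree, c(1, 1, 1, 1, 1.05, 1)))
})

test_that("IGR rate draws reproduce the density's moments", {
  ## one fixed branch: 50,000 draws vs mean 1, var nu/t within 3 SE
  tree <- triplet3(40, 20)
  igr <- clockModel("IGR", nu = 0.5)
  set.seed(42)
  draws <- replicate(12500, sampleBranchRates(igr, tree))
  dur <- branchDurations(tree)
  for (e in c(1, 3)) {
    x <- draws[e, ]
    v <- 0.5 / dur[e]
    expect_lt(abs(mean(x) - 1), 3 * sqrt(v / length(x)))
    se_var <- sqrt(2 / (length(x) - 1)) * v  # normal-ish approx
    expect_lt(abs(var(x) - v), 4 * se_var)
  }
  ## degenerate limit: variance vanishes with nu
  tiny <- sampleBranchRates(clockModel("IGR", nu = 1e-10), tree, seed = 1)
  expect_equal(tiny, rep(1, 4), tolerance = 1e-4)
  ## Monte-Carlo draws score finite under the density and the density
  ## cross-check: empirical mean of draws maximises near 1
  lp <- branchRatesLogPrior(igr, tree, draws[, 1])
  expect_true(is.finite(lp))
})

test_that("effective branch lengths are rate times duration", {
  tree <- triplet3(100, 50)
  strict <- clockModel("strict", rate = 0.01)
  len <- effectiveBranchLengths(strict, tree, rep(1, 4))
  expect_equal(unname(len[branchDurations(tree) == 50][1]), 0.5)
  ## ultrametricity in substitutions under a strict clock
  phyS <- asPhylo(tree, useRates = TRUE, rate = 0.01)
  depths <- ape::node.depth.edgelength(phyS)[1:3]
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-12)
  ## zero-duration branch gives zero length
  t0 <- balanced4(10, 4, 10)  # cd clade as old as the root
  expect_true(any(effectiveBranchLengths(strict, t0, rep(1, 6)) == 0))
})

test_that("tree-age prior matches closed forms on small trees", {
  cal <- calibrationSet(uniformCalibration(52, 85))
  ## 3 taxa, root at t_R: free-node density 1/t_R (times the root density)
  t3 <- triplet3(60, 25)
  expect_equal(treeAgeLogPrior(t3, cal), log(1 / 33) + log(1 / 60))
  ## 4-taxon caterpillar, root fixed: joint density 2/t_R^2
  cat4 <- caterpillar4(60, 30, 12)
  expect_equal(treeAgeLogPrior(cat4, cal), log(1 / 33) + log(2 / 60^2))
  ## age-order violations are unrepresentable (class validity) and window
  ## violations score -Inf
  expect_error(caterpillar4(60, 12, 30), "older than its child")
  expect_identical(treeAgeLogPrior(caterpillar4(40, 30, 12), cal), -Inf)
  ## monophyly violation
  calc <- calibrationSet(uniformCalibration(52, 85),
                         nodes = list(offsetExpCalibration(5, 58,
                                                           clade = c("a", "c"))))
  expect_identical(treeAgeLogPrior(caterpillar4(60, 30, 12), calc), -Inf)
})

test_that("free-age density integrates to the calibration product", {
  ## 5-taxon tree with one internal calibration: integrating
  ## exp(treeAgeLogPrior) over the free ages recovers root x node densities
  edge <- matrix(c(6, 1, 6, 7, 7, 8, 7, 9, 8, 2, 8, 3, 9, 4, 9, 5),
                 ncol = 2, byrow = TRUE)
  labs <- c("a", "b", "c", "d", "e")
  cal <- calibrationSet(uniformCalibration(52, 85),
                        nodes = list(offsetExpCalibration(10, 58,
                                                          clade = c("b", "c"))))
  rootA <- 70; calA <- 25
  mk <- function(t7, t9) timeTree(edge, labs, c(0, 0, 0, 0, 0,
                                                rootA, t7, calA, t9))
  f <- function(t7, t9) {
    tt <- tryCatch(mk(t7, t9), error = function(e) NULL)
    if (is.null(tt)) return(0)
    exp(treeAgeLogPrior(tt, cal))
  }
  ## 2-D quadrature over the free ages t7 (parent of cal node and t9), t9
  grid <- 120
  t7s <- seq(calA, rootA, length.out = grid + 1)
  total <- 0
  for (t7 in t7s[-1] - diff(t7s)[1] / 2) {
    t9s <- seq(0, t7, length.out = grid + 1)
    vals <- vapply(t9s[-1] - diff(t9s)[1] / 2, function(t9) f(t7, t9), 0)
    total <- total + sum(vals) * diff(t9s)[1] * diff(t7s)[1]
  }
  expected <- exp(calibrationLogDensity(cal@root, rootA) +
                  calibrationLogDensity(cal@nodes[[1]], calA))
  expect_equal(total, expected, tolerance = 1e-3)
})

test_that("calibrated-tree sampling matches a rejection-sampling oracle", {
  ## 4-taxon balanced topology, root age fixed by a narrow window:
  ## the two free ages are iid Uniform(0, root) - compare marginals with a
  ## rejection oracle drawing uniforms in the bounding box
  cal <- calibrationSet(uniformCalibration(59.99, 60.01))
  topo <- balanced4(60, 20, 30)
  set.seed(314)
  draws <- replicate(1500, {
    tt <- sampleCalibratedTree(cal, topology = topo)
    tt@ages[6:7]
  })
  set.seed(315)
  oracle <- matrix(runif(2 * 1500, 0, 60), 2)  # box sampler; all accepted
  expect_gt(ks.test(draws[1, ], oracle[1, ])$p.value, 0.01)
  expect_gt(ks.test(c(draws), punif, 0, 60)$p.value, 0.01)
  ## caterpillar: ordered pair (t7 < t6 < root); rejection oracle keeps
  ## order-consistent vectors
  topoC <- caterpillar4(60, 30, 12)
  set.seed(316)
  drawsC <- replicate(2000, {
    tt <- sampleCalibratedTree(cal, topology = topoC)
    tt@ages[6:7]
  })
  expect_true(all(drawsC[1, ] > drawsC[2, ]))
  set.seed(317)
  box <- matrix(runif(2 * 8000, 0, 60), 2)
  keep <- box[, box[1, ] > box[2, ]]
  expect_gt(ks.test(drawsC[1, ], keep[1, ])$p.value, 0.01)
  expect_gt(ks.test(drawsC[2, ], keep[2, ])$p.value, 0.01)
})

test_that("root-age draws recover the configured uniform window", {
  cal <- calibrationSet(uniformCalibration(52, 85))
  set.seed(99)
  tt0 <- sampleCalibratedTree(cal, nTaxa = 6)
  roots <- replicate(5000, rootAge(sampleCalibratedTree(cal, topology = tt0)))
  expect_gt(suppressWarnings(ks.test(roots, punif, 52, 85))$p.value, 0.01)
})

test_that("incompatible constraints are rejected", {
  ## overlapping, non-nested clades fail CalibrationSet validity
  expect_error(calibrationSet(uniformCalibration(52, 85),
    nodes = list(A = offsetExpCalibration(10, 58, clade = c("t01", "t02")),
                 B = offsetExpCalibration(10, 58, clade = c("t02", "t03")))),
    "nested or disjoint")
  ## a topology that breaks a calibrated clade raises a constraint conflict
  cal <- calibrationSet(uniformCalibration(52, 85),
    nodes = list(A = offsetExpCalibration(5, 58, clade = c("a", "c"))))
  expect_error(sampleCalibratedTree(cal, topology = caterpillar4()),
               "constraint-conflict")
})
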