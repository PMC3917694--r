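test_that("chain heat follows the Metropolis-coupling schedule", {
  expect_equal(heat(1, 0.1), 1)
  expect_equal(heat(4, 0.1), 1 / 1.3)
  expect_equal(vapply(1:4, heat, 0, temperature = 0), rep(1, 4))
})

test_that("data-free MCMC recovers the uniform root prior", {
  fx <- makePasserineFixture(scale = 0.05, seed = 3, nTaxa = 14)
  cal0 <- calibrationSet(uniformCalibration(52, 85))
  tr <- runMcmc(fx$alignment, fx$scheme, cal0, clockModel("strict"),
                mcmcConfig(nGenerations = 60000L, sampleEvery = 30L,
                           priorOnly = TRUE, seed = 7))[[1]]
  r <- tr@params$rootAge
  expect_equal(length(r), 2000L)
  expect_gt(suppressWarnings(ks.test(r, punif, 52, 85))$p.value, 0.01)
  ## likelihood really is switched off
  expect_true(all(tr@params$logLik == 0))
})

test_that("data-free marginals reproduce scalar-parameter priors", {
  ## detailed-balance check: every kernel leaves its prior invariant
  d <- tinyDataset(5, nTaxa = 6, nSites = 60, clock = clockModel("IGR"))
  ## ages frozen so the scalar kernels get most of the proposal budget
  tr <- runMcmc(d$aln, d$scheme, d$cals, clockModel("IGR", nu = 0.1),
                mcmcConfig(nGenerations = 80000L, sampleEvery = 80L,
                           priorOnly = TRUE, seed = 11, fixAges = TRUE),
                tree = d$tree)[[1]]
  ## thin to near-independence before the KS comparisons
  p <- tr@params[seq(1, nrow(tr@params), by = 5), ]
  expect_gt(suppressWarnings(  # clock rate ~ lognormal(log 0.0025, 1)
    ks.test(p$clockRate, plnorm, log(0.0025), 1))$p.value, 0.01)
  expect_gt(suppressWarnings(  # nu ~ Exp(10)
    ks.test(p$nu, pexp, 10))$p.value, 0.01)
  expect_gt(suppressWarnings(  # alpha ~ Exp(1)
    ks.test(p$alpha1, pexp, 1))$p.value, 0.01)
  expect_gt(suppressWarnings(  # pInv ~ U(0, 1)
    ks.test(p$pinv1, punif))$p.value, 0.01)
})

test_that("posterior matches a fine-grid oracle on a conjugate-style target", {
  ## fixed tree and substitution model, strict clock: the single free
  ## parameter is the clock rate c; compare with 1-D grid integration
  d <- tinyDataset(9, nTaxa = 5, nSites = 300)
  mod <- d$spec$model
  tr <- runMcmc(d$aln, d$scheme, d$cals, clockModel("strict", rate = 0.0025),
                mcmcConfig(nGenerations = 30000L, sampleEvery = 10L,
                           seed = 13, fixSubstModel = TRUE, fixAges = TRUE),
                tree = d$tree, models = mod)[[1]]
  cs <- tr@params$clockRate[-(1:750)]
  phyT <- asPhylo(d$tree)
  Lc <- function(cv) vapply(cv, function(ci) {
    p <- phyT; p$edge.length <- p$edge.length * ci
    logLikelihood(p, mod, d$aln)
  }, 0)
  xs <- exp(seq(log(0.0025) - 3, log(0.0025) + 3, length.out = 600))
  ly <- Lc(xs) + dlnorm(xs, log(0.0025), 1, log = TRUE)
  wy <- exp(ly - max(ly)); wy <- wy / sum(wy)
  gridMean <- sum(xs * wy)
  gridSd <- sqrt(sum((xs - gridMean)^2 * wy))
  mcse <- gridSd / sqrt(50)  # conservative effective sample size
  expect_lt(abs(mean(cs) - gridMean), 4 * mcse)
})

test_that("ASDSF matches a brute-force split tally", {
  mkTrace <- function(splitSets, runId) {
    trees <- lapply(splitSets, function(s)
      list(splits = s, ages = rep(1, length(s))))
    new("Trace", params = data.frame(logLik = numeric(length(trees))),
        trees = trees, tipLabels = c("a", "b", "c", "d"),
        generations = seq_along(trees), runId = as.integer(runId),
        info = list())
  }
  full <- "a|b|c|d"
  t1 <- mkTrace(list(c(full, "a|b"), c(full, "a|b")), 1L)
  t2 <- mkTrace(list(c(full, "a|b"), c(full, "c|d")), 2L)
  ## identical traces: 0
  expect_equal(asdsf(list(t1, t1)), 0)
  ## split at frequencies 1.0 and 0.5 -> SD 0.25 (population denominator);
  ## split at 0 and 0.5 -> 0.25; average 0.25
  expect_equal(asdsf(list(t1, t2)), 0.25)
  ## two runs, one split at 1.0 vs 0.0 -> that split contributes SD 0.5
  t3 <- mkTrace(list(c(full, "a|b")), 1L)
  t4 <- mkTrace(list(c(full, "c|d")), 2L)
  expect_equal(asdsf(list(t3, t4)), 0.5)
  ## random traces vs independent tally oracle
  set.seed(12)
  pool <- c("a|b", "c|d", "a|c", "b|d", "a|d")
  rnd <- function(runId) mkTrace(replicate(30, c(full,
    sample(pool, 2)), simplify = FALSE), runId)
  tra <- rnd(1L); trb <- rnd(2L)
  oracle <- {
    f <- function(tr) table(factor(unlist(lapply(tr@trees, `[[`, "splits")),
                                   levels = c(full, pool))) / 30
    fa <- f(tra); fb <- f(trb)
    keep <- setdiff(names(fa)[pmax(fa, fb) > 0.1], full)
    mean(vapply(keep, function(s)
      sqrt(((fa[[s]] - fb[[s]]) / 2)^2), 0))
  }
  expect_equal(asdsf(list(tra, trb)), oracle)
  expect_error(asdsf(list(t1)), "two")
})

test_that("empirical-Bayes clock prior is height over mean root age", {
  pr <- empiricalBayesClockPrior(heightSubs = 0.685,
                                 rootCal = uniformCalibration(52, 85))
  expect_equal(pr$medianRate, 0.01)
  expect_equal(pr$sdlog, 1)
  ## 2.5-97.5% quantile ratio of the lognormal ~ e^{2*1.96}
  q <- qlnorm(c(0.025, 0.975), pr$meanlog, pr$sdlog)
  expect_equal(q[2] / q[1], exp(2 * qnorm(0.975)), tolerance = 1e-9)
  expect_error(empiricalBayesClockPrior(heightSubs = 0,
                                        rootCal = uniformCalibration(52, 85)),
               "degenerate")
})

test_that("MC3 with swap moves leaves the target invariant", {
  ## prior-only 4-chain run still recovers the root window
  fx <- makePasserineFixture(scale = 0.03, seed = 4, nTaxa = 13)
  cal0 <- calibrationSet(uniformCalibration(52, 85))
  tr <- runMcmc(fx$alignment, fx$scheme, cal0, clockModel("strict"),
                mcmcConfig(nGenerations = 40000L, sampleEvery = 40L,
                           nChains = 3L, temperature = 0.1,
                           priorOnly = TRUE, seed = 21))[[1]]
  r <- tr@params$rootAge
  expect_gt(suppressWarnings(ks.test(r, punif, 52, 85))$p.value, 0.01)
})

test_that("runs are reproducible and independent across seeds", {
  d <- tinyDataset(2, nTaxa = 6, nSites = 80)
  cfg <- mcmcConfig(nGenerations = 500L, sampleEvery = 10L, seed = 5,
                    priorOnly = TRUE)
  a <- runMcmc(d$aln, d$scheme, d$cals, clockModel("strict"), cfg)
  b <- runMcmc(d$aln, d$scheme, d$cals, clockModel("strict"), cfg)
  expect_identical(a[[1]]@params, b[[1]]@params)
  two <- runMcmc(d$aln, d$scheme, d$cals, clockModel("strict"),
                 mcmcConfig(nGenerations = 500L, sampleEvery = 10L,
                            seed = 5, nRuns = 2L, priorOnly = TRUE))
  expect_false(identical(two[[1]]@params$rootAge, two[[2]]@params$rootAge))
})
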