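mkTrace <- function(trees, runId = 1L, labs = c("a", "b", "c", "d")) {
  new("Trace",
      params = data.frame(logLik = rnorm(length(trees)),
                          rootAge = vapply(trees, function(t)
                            max(t$ages), 0)),
      trees = trees, tipLabels = labs,
      generations = seq_along(trees), runId = as.integer(runId),
      info = list())
}

balTree <- function(rootAge, tAB) list(
  splits = c("a|b|c|d", "a|b", "c|d"),
  ages = c(rootAge, tAB, rootAge / 2))

catTree <- function(rootAge) list(
  splits = c("a|b|c|d", "b|c|d", "c|d"),
  ages = c(rootAge, rootAge * 0.7, rootAge * 0.3))

test_that("run concatenation removes burn-in and pools samples", {
  t1 <- mkTrace(lapply(seq(50, 69), balTree, tAB = 10), 1L)
  t2 <- mkTrace(lapply(seq(70, 89), balTree, tAB = 10), 2L)
  ## one run, no burn-in: identity
  p0 <- concatRuns(list(t1), burnIn = 0)
  expect_equal(nrow(p0@params), 20L)
  ## two runs of n samples at 25% burn-in: pooled size 1.5n
  p <- concatRuns(list(t1, t2), burnIn = 0.25)
  expect_equal(nrow(p@params), 30L)
  expect_equal(sum(p@params$run == 1), 15L)
  ## pooled summary equals a weighted recomputation from per-run tallies
  pooledMean <- mean(p@params$rootAge)
  perRun <- c(mean(t1@params$rootAge[-(1:5)]), mean(t2@params$rootAge[-(1:5)]))
  expect_equal(pooledMean, mean(perRun))
  ## incompatible taxa rejected
  t3 <- mkTrace(list(balTree(60, 10)), 3L, labs = c("a", "b", "c", "e"))
  expect_error(concatRuns(list(t1, t3)), "incompatible")
})

test_that("majority consensus keeps splits above half with their PP", {
  ## identical trees: full topology, all PP 1
  tr <- mkTrace(lapply(rep(60, 5), balTree, tAB = 10))
  cons <- majorityConsensus(tr)
  expect_setequal(cons$split, c("a|b|c|d", "a|b", "c|d"))
  expect_true(all(cons$pp == 1))
  ## split in 2 of 3 trees: PP 2/3
  tr2 <- mkTrace(list(balTree(60, 10), balTree(61, 11), catTree(62)))
  cons2 <- majorityConsensus(tr2)
  expect_equal(cons2$pp[cons2$split == "a|b"], 2 / 3)
  ## cd appears in all three
  expect_equal(cons2$pp[cons2$split == "c|d"], 1)
  ## split table equals a brute-force bipartition count
  set.seed(8)
  trees <- replicate(40, if (runif(1) < 0.6) balTree(runif(1, 52, 85), 10)
                         else catTree(runif(1, 52, 85)), simplify = FALSE)
  tr3 <- mkTrace(trees)
  tab <- table(unlist(lapply(trees, `[[`, "splits"))) / 40
  cons3 <- majorityConsensus(tr3)
  for (s in cons3$split)
    expect_equal(cons3$pp[cons3$split == s], unname(tab[[s]]))
  expect_true(all(tab[setdiff(names(tab), cons3$split)] <= 0.5))
})

test_that("node-age summaries use the central-percentile rule", {
  tr <- mkTrace(lapply(rep(50, 4), balTree, tAB = 20))
  s <- nodeAgeSummary(tr, c("a", "b", "c", "d"))
  expect_equal(c(s$mean, s$median, s$lower, s$upper), rep(50, 4))
  ## ages 1..100: CI (3.475, 97.525) under linear interpolation
  tr2 <- mkTrace(lapply(1:100, balTree, tAB = 0.5))
  s2 <- nodeAgeSummary(tr2, c("a", "b", "c", "d"))
  expect_equal(c(s2$lower, s2$upper), c(3.475, 97.525))
  expect_gte(s2$width, 0)
  ## conditioning on the split: ages collected only from samples with it
  mix <- mkTrace(c(lapply(c(10, 20), balTree, tAB = 5),
                   list(catTree(60))))
  sAB <- nodeAgeSummary(mix, c("a", "b"))
  expect_equal(sAB$pp, 2 / 3)
  expect_equal(sAB$median, 5)
  ## absent split: NA with pp 0 (how missing gene nodes are detected)
  gone <- nodeAgeSummary(mix, c("a", "d"))
  expect_equal(gone$pp, 0)
  expect_true(is.na(gone$median))
})

test_that("chronograms round-trip through write and read", {
  set.seed(5)
  trees <- lapply(runif(60, 55, 80), balTree, tAB = 12)
  tr <- mkTrace(trees)
  cons <- majorityConsensus(tr)
  ages <- nodeAgeTable(tr, cons)
  f <- withr::local_tempfile(fileext = ".nex")
  writeChronogram(cons, ages, f, tr@tipLabels)
  back <- readChronogram(f)
  m <- merge(ages, back$summaries, by = "split")
  expect_equal(nrow(m), nrow(ages))
  expect_equal(m$median.x, m$median.y, tolerance = 1e-8)
  expect_equal(m$pp.x, m$pp.y, tolerance = 1e-8)
  expect_equal(m$lower.x, m$lower.y, tolerance = 1e-8)
  ## ultrametric: tip depths equal the root median age
  expect_false(is.null(back$tree))
  expect_equal(rootAge(back$tree),
               ages$median[ages$split == "a|b|c|d"], tolerance = 1e-8)
  ## empty annotation set: plain newick without lengths still parses
  na_ages <- ages
  na_ages$median <- na_ages$lower <- na_ages$upper <- NA_real_
  f2 <- withr::local_tempfile(fileext = ".nex")
  writeChronogram(cons, na_ages, f2, tr@tipLabels)
  back2 <- readChronogram(f2)
  expect_s3_class(back2$phylo, "phylo")
})

test_that("consensus of a consensus is itself (idempotence)", {
  set.seed(9)
  trees <- replicate(30, if (runif(1) < 0.8) balTree(runif(1, 52, 85), 10)
                         else catTree(70), simplify = FALSE)
  tr <- mkTrace(trees)
  cons <- majorityConsensus(tr)
  again <- mkTrace(list(list(splits = cons$split,
                             ages = rep(60, length(cons$split)))))
  cons2 <- majorityConsensus(again)
  expect_setequal(cons2$split, cons$split)
  expect_true(all(cons2$pp == 1))
})

test_that("prior-only credibility intervals cover the root prior mass", {
  fx <- makePasserineFixture(scale = 0.03, seed = 6, nTaxa = 13)
  cal0 <- calibrationSet(uniformCalibration(52, 85))
  tr <- runMcmc(fx$alignment, fx$scheme, cal0, clockModel("strict"),
                mcmcConfig(nGenerations = 40000L, sampleEvery = 20L,
                           priorOnly = TRUE, seed = 31))[[1]]
  s <- nodeAgeSummary(tr, fx$alignment@taxa)
  ## central 95% of Uniform(52, 85): (52.825, 84.175)
  expect_lt(abs(s$lower - 52.825), 1)
  expect_lt(abs(s$upper - 84.175), 1)
})

test_that("trace logs round-trip through write and read", {
  fx <- makePasserineFixture(scale = 0.03, seed = 19, nTaxa = 13)
  tr <- runMcmc(fx$alignment, fx$scheme, fx$calibrations,
                clockModel("strict"),
                mcmcConfig(nGenerations = 400L, sampleEvery = 20L,
                           priorOnly = TRUE, seed = 2))[[1]]
  fp <- withr::local_tempfile(fileext = ".tsv")
  ft <- withr::local_tempfile(fileext = ".trees")
  writeTrace(tr, fp, ft)
  back <- readTrace(fp, ft)
  expect_equal(back@params$rootAge, tr@params$rootAge, tolerance = 1e-9)
  expect_identical(back@generations, tr@generations)
  expect_setequal(back@trees[[1]]$splits, tr@trees[[1]]$splits)
  i <- match(tr@trees[[1]]$splits, back@trees[[1]]$splits)
  expect_equal(back@trees[[1]]$ages[i], tr@trees[[1]]$ages, tolerance = 1e-6)
})
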