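test_that("Kendall's tau matches a brute-force pair count", {
  x <- c(10, 20, 30, 40, 50)
  expect_equal(kendallTau(x, x)$tau, 1)
  expect_equal(kendallTau(x, rev(x))$tau, -1)
  ## random vectors: O(n^2) concordant/discordant oracle (no ties)
  set.seed(4)
  a <- rnorm(8); b <- rnorm(8)
  pairs <- combn(8, 2)
  s <- sum(sign(a[pairs[1, ]] - a[pairs[2, ]]) *
           sign(b[pairs[1, ]] - b[pairs[2, ]]))
  expect_equal(kendallTau(a, b)$tau, s / choose(8, 2), tolerance = 1e-12)
  expect_lte(kendallTau(a, b)$p, 1)
  expect_error(kendallTau(1, 1), "at least 2")
})

test_that("CI width table averages over recovered nodes only", {
  gs <- list(
    g1 = data.frame(split = c("n1", "n2", "n3"), width = c(10, 12, 14)),
    g2 = data.frame(split = c("n1", "n3"), width = c(8, 9)))
  cw <- ciWidthTable(gs)
  expect_equal(unname(cw$means["g1"]), 12)
  expect_equal(unname(cw$means["g2"]), 8.5)   # missing n2 excluded
  expect_true(is.na(cw$widths["n2", "g2"]))
  ## single node CI (40, 50) has width 10 by construction upstream
  one <- data.frame(split = "n", lower = 40, upper = 50, width = 10)
  expect_equal(ciWidthTable(list(g = one))$means[["g"]], 10)
})

test_that("Kruskal-Wallis matches the rank-sum formula", {
  ## worked example: {1,2} vs {3,4} -> H = (12/20)(4.5+24.5) - 15 = 2.4
  kw <- kruskalWallis(list(c(1, 2), c(3, 4)))
  expect_equal(kw$H, 2.4)
  expect_equal(kw$df, 1L)
  ## label permutation of identical groups leaves H unchanged
  g <- list(a = c(5, 7, 7), b = c(7, 5, 5), c = c(6, 6, 8))
  expect_equal(kruskalWallis(g)$H, kruskalWallis(rev(g))$H)
  ## direct tie-corrected formula oracle
  set.seed(2)
  gr <- list(rnorm(6), rnorm(4), rnorm(5))
  x <- unlist(gr); n <- length(x); r <- rank(x)
  Rg <- tapply(r, rep(seq_along(gr), lengths(gr)), sum)
  H <- 12 / (n * (n + 1)) * sum(Rg^2 / lengths(gr)) - 3 * (n + 1)
  ties <- table(x)
  H <- H / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(kruskalWallis(gr)$H, H, tolerance = 1e-12)
  ## all identical observations: H = 0 by convention
  expect_equal(kruskalWallis(list(c(1, 1), c(1, 1)))$H, 0)
})

test_that("credibility-interval overlap is intersection over union", {
  same <- ciOverlap(list(c(0, 10), c(0, 10)))
  expect_true(all(same$pairwise == 1))
  expect_true(same$joint)
  disj <- ciOverlap(list(c(0, 10), c(20, 30)))
  expect_equal(disj$pairwise[1, 2], 0)
  expect_false(disj$joint)
  part <- ciOverlap(list(c(0, 10), c(5, 15)))
  expect_equal(part$pairwise[1, 2], 1 / 3)
  expect_true(part$joint)
  three <- ciOverlap(list(c(0, 10), c(5, 15), c(12, 20)))
  expect_false(three$joint)  # no common intersection
})

test_that("gene-combined node matching flags missing nodes", {
  comb <- data.frame(split = c("n1", "n2", "n3"), pp = 1,
                     median = c(70, 40, 20), lower = c(60, 30, 15),
                     upper = c(80, 50, 25), width = c(20, 20, 10))
  gene <- data.frame(split = c("n1", "n3"), pp = c(0.9, 0.8),
                     median = c(72, 18), lower = c(55, 10),
                     upper = c(88, 26), width = c(33, 16))
  gc <- geneComparison(gene, comb, "MYC")
  expect_equal(gc$missing, "n2")
  expect_equal(nrow(gc$matched), 2L)
  expect_setequal(gc$matched$split, c("n1", "n3"))
})

test_that("saturation tables pair MRCA ages with p-distances", {
  tt <- balanced4(60, 20, 30)
  m <- rbind(a = c("A", "A", "C", "T"), b = c("A", "A", "C", "C"),
             c = c("A", "T", "G", "T"), d = c("A", "T", "G", "C"))
  aln <- multiGeneAlignment(list(g = m))
  st <- saturationTable(aln, "g", tt)
  expect_equal(nrow(st), 6L)
  getAge <- function(x, y) st$age[(st$taxonA == x & st$taxonB == y) |
                                  (st$taxonA == y & st$taxonB == x)]
  expect_equal(getAge("a", "b"), 20)
  expect_equal(getAge("c", "d"), 30)
  expect_equal(getAge("a", "c"), 60)
  expect_equal(st$pDistance[st$taxonA == "b" & st$taxonB == "a" |
                            st$taxonA == "a" & st$taxonB == "b"],
               pDistance(m, "a", "b"))
  ## duplicate taxa at age zero: identical sequences give (0-age, 0-dist)
  ## is approximated by the youngest pair here; chronogram-missing taxa warn
  aln2 <- multiGeneAlignment(list(g = rbind(m, e = c("A", "A", "C", "T"))))
  expect_warning(saturationTable(aln2, "g", tt), "skipped: e")
})

test_that("a saturated gene flattens distance growth at old ages", {
  ## same tree, slow vs fast gene: at large MRCA ages the fast gene's
  ## p-distance gains per My shrink (saturation)
  cal <- calibrationSet(uniformCalibration(150, 160))
  set.seed(17)
  tree <- sampleCalibratedTree(cal, nTaxa = 12)
  spec <- fixtureSpec(c(g = 3000L), FALSE, model = substitutionModel())
  slow <- simulateAlignment(tree, rep(1, 22), spec, clockRate = 0.0005,
                            seed = 1)
  fast <- simulateAlignment(tree, rep(1, 22), spec, clockRate = 0.02,
                            seed = 1)
  stS <- saturationTable(slow, "g", tree)
  stF <- saturationTable(fast, "g", tree)
  old <- stS$age > median(stS$age)
  slopeAt <- function(st, sel) coef(lm(pDistance ~ age, st[sel, ]))[2]
  ## normalise by the young-age slope of each gene
  ratioS <- slopeAt(stS, old) / slopeAt(stS, !old)
  ratioF <- slopeAt(stF, old) / slopeAt(stF, !old)
  expect_lt(ratioF, ratioS)
})

test_that("rate-based root ages back-calculate with interval propagation", {
  expect_equal(rateBasedRootAge(0.5, 1, 0.01)$age, 50)
  iv <- rateBasedRootAge(0.5, 1, 0.01, rateInterval = c(0.008, 0.0125))
  expect_equal(c(iv$lower, iv$upper), c(40, 62.5))
  expect_equal(rateBasedRootAge(0.5, 2, 0.01)$age,
               2 * rateBasedRootAge(0.5, 1, 0.01)$age)
  expect_error(rateBasedRootAge(0.5, 1, 0), "positive")
})

test_that("more sites per gene yield tighter node-age intervals", {
  ## monotone precision trend over three site-count levels x five seeds
  cal0 <- calibrationSet(uniformCalibration(52, 85))
  levels <- c(150L, 600L, 2400L)
  widths <- matrix(NA_real_, 5, 3)
  for (s in 1:5) {
    set.seed(600 + s)
    tree <- sampleCalibratedTree(cal0, nTaxa = 10)
    for (k in seq_along(levels)) {
      spec <- fixtureSpec(stats::setNames(levels[k], "g"), FALSE,
                          model = substitutionModel(alpha = 0.7, pInv = 0.1))
      aln <- simulateAlignment(tree, rep(1, 18), spec, clockRate = 0.0025,
                               seed = 700 + s)
      tr <- runMcmc(aln, spec$scheme, cal0, clockModel("strict"),
                    mcmcConfig(nGenerations = 3000L, sampleEvery = 10L,
                               seed = s, fixSubstModel = TRUE),
                    tree = tree, models = spec$model)[[1]]
      pooled <- concatRuns(list(tr))
      widths[s, k] <- mean(nodeAgeTable(pooled)$width, na.rm = TRUE)
    }
  }
  avg <- colMeans(widths)
  expect_true(all(diff(avg) < 0))
})
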