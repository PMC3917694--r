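test_that("discrete-gamma category rates follow the mean-of-bin rule", {
  ## any alpha: category mean is exactly 1
  for (a in c(0.1, 0.5, 1, 5)) {
    r <- discretizeGamma(a)
    expect_equal(mean(r), 1, tolerance = 1e-9)
    expect_true(all(diff(r) > 0))
  }
  ## alpha -> Inf: all categories -> 1
  expect_equal(discretizeGamma(1e8), rep(1, 4), tolerance = 1e-3)
  ## alpha = 0.5: quadrature oracle per bin
  a <- 0.5
  q <- qgamma(0:4 / 4, a, a)
  oracle <- vapply(1:4, function(k)
    4 * integrate(function(x) x * dgamma(x, a, a), q[k], q[k + 1],
                  rel.tol = 1e-10)$value, 0)
  expect_equal(discretizeGamma(a), oracle / mean(oracle), tolerance = 1e-6)
})

test_that("two-taxon Jukes-Cantor likelihoods match closed forms", {
  jc <- substitutionModel(alpha = 1e9)
  ## pattern (A,A) at zero length: site likelihood 1/4
  expect_equal(logLikelihood(phy("(a:0,b:0);"), jc, aln2("A", "A")),
               log(0.25), tolerance = 1e-9)
  ## pattern (A,T) over path b: (1/4) P_AT(b), and 1/16 at b -> Inf
  b <- 0.3
  pd <- 0.25 * (1 - exp(-4 * b / 3))
  expect_equal(logLikelihood(phy("(a:0.15,b:0.15);"), jc, aln2("A", "T")),
               log(0.25 * pd), tolerance = 1e-8)
  expect_equal(logLikelihood(phy("(a:200,b:200);"), jc, aln2("A", "T")),
               log(1 / 16), tolerance = 1e-6)
})

test_that("pruning equals exhaustive internal-state enumeration (GTR+G4+I)", {
  ## brute-force oracle: sum over all internal-state assignments x categories
  bruteForce <- function(phy4, mod, m) {
    eig <- passerclock:::.gtrEigen(mod)
    catR <- discretizeGamma(mod@alpha)
    mask <- passerclock:::.iupacMask
    n <- length(phy4$tip.label)
    edge <- phy4$edge; len <- phy4$edge.length
    nNode <- max(edge)
    total <- 0
    for (s in seq_len(ncol(m))) {
      obs <- mask[toupper(m[phy4$tip.label, s])]
      var <- 0
      for (cat in 1:4) {
        P <- lapply(len * catR[cat], function(t) passerclock:::.gtrP(eig, t))
        nInt <- nNode - n
        lik <- 0
        for (assign in seq_len(4^nInt) - 1L) {
          states <- integer(nNode)
          a <- assign
          for (j in seq_len(nInt)) { states[n + j] <- a %% 4 + 1; a <- a %/% 4 }
          pr <- mod@baseFreqs[states[n + 1]]
          for (e in seq_len(nrow(edge))) {
            par <- states[edge[e, 1]]; ch <- edge[e, 2]
            if (ch <= n) {
              sel <- which(bitwAnd(2^(0:3), obs[ch]) > 0)
              pr <- pr * sum(P[[e]][par, sel])
            } else {
              pr <- pr * P[[e]][par, states[ch]]
            }
          }
          lik <- lik + pr
        }
        var <- var + lik / 4
      }
      inv <- Reduce(bitwAnd, obs)
      pinvterm <- if (inv > 0) sum(mod@baseFreqs[bitwAnd(2^(0:3), inv) > 0]) else 0
      total <- total + log(mod@pInv * pinvterm + (1 - mod@pInv) * var)
    }
    unname(total)
  }
  mod <- substitutionModel(c(1.2, 3.4, 0.8, 1.1, 4.2, 1),
                           c(0.31, 0.19, 0.22, 0.28), alpha = 0.6, pInv = 0.15)
  phy4 <- phy("((a:0.1,b:0.3):0.2,(c:0.15,d:0.25):0.05);")
  set.seed(7)
  m <- matrix(sample(c("A", "C", "G", "T", "-", "R", "N"), 4 * 8, TRUE), 4, 8,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  ll <- logLikelihood(phy4, mod, multiGeneAlignment(list(g = m)))
  expect_equal(ll, bruteForce(phy4, mod, m), tolerance = 1e-8)
  ## and on a 5-taxon tree
  phy5 <- phy("(((a:0.12,b:0.07):0.1,c:0.2):0.05,(d:0.3,e:0.02):0.18);")
  m5 <- matrix(sample(c("A", "C", "G", "T"), 5 * 6, TRUE), 5, 6,
               dimnames = list(letters[1:5], NULL))
  ll5 <- logLikelihood(phy5, mod, multiGeneAlignment(list(g = m5)))
  expect_equal(ll5, bruteForce(phy5, mod, m5), tolerance = 1e-8)
})

test_that("likelihood is invariant to root placement (pulley principle)", {
  skip_if_not_installed("phytools")
  mod <- substitutionModel(c(1.5, 4, 1, 1, 5, 1), c(0.3, 0.2, 0.2, 0.3),
                           alpha = 0.8, pInv = 0.1)
  set.seed(11)
  tre <- ape::rtree(5, rooted = TRUE)
  tre$edge.length <- runif(nrow(tre$edge), 0.02, 0.3)
  m <- matrix(sample(c("A", "C", "G", "T"), 5 * 50, TRUE), 5, 50,
              dimnames = list(tre$tip.label, NULL))
  aln <- multiGeneAlignment(list(g = m))
  ll0 <- logLikelihood(tre, mod, aln)
  unr <- ape::unroot(tre)
  for (k in 1:10) {
    e <- sample(nrow(unr$edge), 1)
    pos <- runif(1, 0.2, 0.8) * unr$edge.length[e]
    rerooted <- phytools::reroot(unr, node.number = unr$edge[e, 2],
                                 position = pos)
    expect_equal(logLikelihood(rerooted, mod, aln), ll0, tolerance = 1e-8)
  }
})

test_that("pruning agrees with an independent likelihood implementation", {
  skip_if_not_installed("phangorn")
  set.seed(3)
  tre <- ape::rtree(6, rooted = TRUE)
  tre$edge.length <- runif(nrow(tre$edge), 0.05, 0.4)
  m <- matrix(sample(c("A", "C", "G", "T"), 6 * 80, TRUE), 6, 80,
              dimnames = list(tre$tip.label, NULL))
  mod <- substitutionModel(alpha = 0.7)  # JC + gamma
  ll <- logLikelihood(tre, mod, multiGeneAlignment(list(g = m)))
  pd <- phangorn::phyDat(m)
  fit <- phangorn::pml(tre, pd, k = 4, shape = 0.7)
  expect_equal(ll, as.numeric(fit$logLik), tolerance = 1e-6)
})

test_that("partitioned likelihood composes partition terms correctly", {
  fx <- makePasserineFixture(scale = 0.03, seed = 8, nTaxa = 13)
  phyF <- asPhylo(fx$tree, useRates = TRUE, rate = fx$clock@rate)
  mods <- rep(list(fx$spec$model), length(fx$scheme@sites))
  ## all multipliers 1: equals the sum of per-partition likelihoods
  ll1 <- partitionedLogLikelihood(phyF, mods, 1, fx$alignment, fx$scheme)
  by1 <- attr(ll1, "byPartition")
  solo <- vapply(seq_along(fx$scheme@sites), function(p)
    logLikelihood(phyF, fx$spec$model, fx$alignment,
                  sites = fx$scheme@sites[[p]]), 0)
  expect_equal(unname(by1), unname(solo), tolerance = 1e-9)
  ## single partition with m = 2 equals doubled branch lengths
  g <- multiGeneAlignment(fx$alignment@genes["MB"], taxa = fx$alignment@taxa)
  sch <- buildPartitionScheme(c(MB = ncol(g@genes$MB)), FALSE)
  l2 <- partitionedLogLikelihood(phyF, list(fx$spec$model), 2, g, sch)
  phy2 <- phyF; phy2$edge.length <- 2 * phy2$edge.length
  expect_equal(as.numeric(l2), logLikelihood(phy2, fx$spec$model, g),
               tolerance = 1e-9)
  ## pattern compression exactness: site-by-site (no shared columns) oracle
  sub <- fx$alignment@genes$RAG1[, 1:40]
  alnS <- multiGeneAlignment(list(r = sub), taxa = fx$alignment@taxa)
  full <- logLikelihood(phyF, fx$spec$model, alnS)
  persite <- sum(vapply(seq_len(ncol(sub)), function(j)
    logLikelihood(phyF, fx$spec$model, alnS, sites = j), 0))
  expect_equal(full, persite, tolerance = 1e-10)
})
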