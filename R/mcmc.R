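#' Chain heat for Metropolis coupling
#'
#' Chain \code{i} (1-based) runs at inverse temperature
#' \code{1/(1 + (i-1) * T)}; the cold chain (i = 1) has heat 1.
#'
#' @param i Chain index, >= 1.
#' @param temperature Heating constant T >= 0.
#' @return Inverse temperature in (0, 1].
#' @examples
#' heat(4, 0.1)  # 1/1.3
#' @export
heat <- function(i, temperature) {
  stopifnot(i >= 1, temperature >= 0)
  1 / (1 + (i - 1) * temperature)
}

## log Dirichlet density (used by Dirichlet proposal Hastings ratios)
.ldirichlet <- function(x, alpha)
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

## ---- state construction ------------------------------------------------

.newState <- function(bundle, config) {
  n <- bundle$nTip
  tree <- if (!is.null(bundle$initTree)) {
    if (bundle$fixAges) bundle$initTree
    else
    ## keep the supplied topology but overdisperse: draw starting ages
    ## from the calibrated prior on that topology
    tryCatch(sampleCalibratedTree(bundle$cals, topology = bundle$initTree),
             error = function(e) bundle$initTree)
  } else {
    sampleCalibratedTree(bundle$cals, tipLabels = bundle$tipLabels)
  }
  st <- list()
  st$edge <- tree@edge
  st$ages <- tree@ages
  st$relRates <- if (bundle$clockKind == "strict") NULL
                 else sampleBranchRates(clockModel(bundle$clockKind, 1,
                                                   bundle$nu0), tree)
  st$c <- bundle$c0
  st$nu <- bundle$nu0
  st$groups <- bundle$groups0      # list per group: er, bf, alpha, pinv
  st$x <- bundle$w                 # weighted multiplier simplex (m = x/w)
  .refreshStructure(st, bundle)
}

## recompute topology-derived fields (after init or an accepted NNI)
.refreshStructure <- function(st, bundle) {
  n <- bundle$nTip
  nNode <- 2L * n - 1L
  topo <- .topoContext(st$edge, n)
  st$kids <- topo$kids; st$postorder <- topo$postorder
  st$parent <- .parentVec(st$edge, nNode)
  st$edgeOfChild <- integer(nNode)
  st$edgeOfChild[st$edge[, 2L]] <- seq_len(nrow(st$edge))
  tipSets <- .cladeTips(st$edge, n)
  keys <- vapply((n + 1L):nNode, function(v)
    .splitKey(bundle$tipLabels[tipSets[[v]]]), "")
  names(keys) <- (n + 1L):nNode
  st$splitKeys <- keys
  st$calNodes <- vapply(bundle$calKeys, function(k) {
    id <- match(k, keys); if (is.na(id)) NA_integer_ else as.integer(n + id)
  }, 0L)
  st$consOK <- !anyNA(vapply(bundle$consKeys, function(k)
    match(k, keys), 0L)) && !anyNA(st$calNodes)
  st$freeNodes <- setdiff((n + 2L):nNode, st$calNodes)
  st
}

## durations per edge from ages
.durations <- function(st)
  st$ages[st$edge[, 1L]] - st$ages[st$edge[, 2L]]

## substitution branch length above each node (length 2n-1)
.lenNode <- function(st, bundle) {
  out <- numeric(2L * bundle$nTip - 1L)
  rel <- if (is.null(st$relRates)) 1 else st$relRates
  out[st$edge[, 2L]] <- st$c * rel * .durations(st)
  out
}

## ---- prior components --------------------------------------------------

.priorTree <- function(st, bundle) {
  n <- bundle$nTip
  if (!st$consOK) return(list(dens = -Inf, logVol = NA_real_))
  rootA <- st$ages[n + 1L]
  lp <- calibrationLogDensity(bundle$cals@root, rootA)
  if (!is.finite(lp)) return(list(dens = -Inf, logVol = NA_real_))
  fixed <- rep(NA_real_, 2L * n - 1L)
  fixed[seq_len(n)] <- st$ages[seq_len(n)]
  fixed[n + 1L] <- rootA
  cals <- bundle$cals@nodes
  for (i in seq_along(cals)) {
    v <- st$calNodes[i]
    d <- calibrationLogDensity(cals[[i]], st$ages[v])
    if (!is.finite(d)) return(list(dens = -Inf, logVol = NA_real_))
    lp <- lp + d
    fixed[v] <- st$ages[v]
  }
  lv <- .ageLogVolume(st$kids, st$postorder, n, fixed)
  if (!is.finite(lv)) return(list(dens = -Inf, logVol = NA_real_))
  list(dens = lp - lv, logVol = lv)
}

.priorRates <- function(st, bundle) {
  if (is.null(st$relRates)) return(0)
  dur <- .durations(st)
  if (any(st$relRates <= 0)) return(-Inf)
  if (bundle$clockKind == "IGR") {
    shape <- dur / st$nu
    sum(stats::dgamma(st$relRates, shape = shape, rate = shape, log = TRUE))
  } else {
    pr <- .parentEdgeRatesFast(st, bundle)
    v <- st$nu * dur
    sum(stats::dlnorm(st$relRates, meanlog = log(pr) - v / 2,
                      sdlog = sqrt(v), log = TRUE))
  }
}

.parentEdgeRatesFast <- function(st, bundle) {
  n <- bundle$nTip
  parentNode <- st$edge[, 1L]
  pe <- st$edgeOfChild[parentNode]           # 0 where parent is root
  out <- ifelse(parentNode == n + 1L, 1, st$relRates[pmax(pe, 1L)])
  out[parentNode == n + 1L] <- 1
  out
}

.priorScalars <- function(st, bundle) {
  lp <- stats::dlnorm(st$c, bundle$ratePriorMeanlog, bundle$ratePriorSdlog,
                      log = TRUE)
  if (!is.null(st$relRates)) lp <- lp + stats::dexp(st$nu, 10, log = TRUE)
  for (g in st$groups)
    lp <- lp + stats::dexp(g$alpha, 1, log = TRUE)  # pinv ~ U(0,1): 0
  lp
}

## ---- likelihood --------------------------------------------------------

.groupTabs <- function(group) {
  mod <- substitutionModel(group$er, group$bf, group$alpha, group$pinv)
  eig <- .gtrEigen(mod)
  list(U = eig$U, Uinv = eig$Uinv, lambda = eig$lambda,
       catRates = discretizeGamma(group$alpha, 4L),
       pinv = group$pinv, freqs = mod@baseFreqs)
}

.likTabs <- function(st, bundle, gt = lapply(st$groups, .groupTabs)) {
  pg <- bundle$pg
  list(Us = lapply(gt[pg], `[[`, "U"),
       Uinvs = lapply(gt[pg], `[[`, "Uinv"),
       lambdas = lapply(gt[pg], `[[`, "lambda"),
       catRates = vapply(gt[pg], `[[`, numeric(4), "catRates"),
       pinv = vapply(gt[pg], `[[`, 0, "pinv"),
       freqs = vapply(gt[pg], `[[`, numeric(4), "freqs"))
}

.stateLik <- function(st, bundle, tabs, partIdx = NULL) {
  if (bundle$power == 0)
    return(rep(0, if (is.null(partIdx)) bundle$ctx$nPart else length(partIdx)))
  m <- st$x / bundle$w
  lenByNode <- outer(.lenNode(st, bundle), m)
  .evalLoglik(bundle$nTip, list(postorder = st$postorder, kids = st$kids),
              lenByNode, bundle$ctx, tabs, partIdx)
}

## full evaluation of all cached quantities
.evalState <- function(st, bundle) {
  st$groupTabs <- lapply(st$groups, .groupTabs)
  st$tabs <- .likTabs(st, bundle, st$groupTabs)
  tp <- .priorTree(st, bundle)
  st$lpTree <- tp$dens; st$logVol <- tp$logVol
  st$lpRates <- .priorRates(st, bundle)
  st$lpScalar <- .priorScalars(st, bundle)
  st$partLL <- if (bundle$power == 0) rep(0, bundle$ctx$nPart)
    else if (is.finite(st$lpTree + st$lpRates))
      .stateLik(st, bundle, st$tabs)
    else rep(-Inf, bundle$ctx$nPart)
  st
}

.logPrior <- function(st) st$lpTree + st$lpRates + st$lpScalar
.logKernel <- function(st, bundle)
  bundle$power * sum(st$partLL) + .logPrior(st)

## ---- the engine --------------------------------------------------------

.moveTable <- function(bundle, st) {
  if (bundle$power == 0) {
    ## data-free runs: age moves dominate (the realized prior on node ages
    ## is the quantity of interest); all kernels stay active so prior-only
    ## sampling still exercises every proposal for detailed-balance checks
    mv <- c(ageFree = if (length(st$freeNodes)) 24 else 0,
            ageRoot = 12,
            ageCal = if (length(st$calNodes)) 8 else 0,
            rate = if (!is.null(st$relRates)) 4 else 0,
            cRate = 1,
            rescale = 2,
            nu = if (!is.null(st$relRates)) 2 else 0,
            alpha = 3, pinv = 3, er = 1, bf = 1,
            mult = if (bundle$ctx$nPart > 1) 1 else 0,
            nni = if (bundle$topologyMoves) 6 else 0)
  } else {
    mv <- c(ageFree = if (length(st$freeNodes)) 12 else 0,
            ageRoot = 6,
            ageCal = if (length(st$calNodes)) 3 else 0,
            rate = if (!is.null(st$relRates)) 8 else 0,
            cRate = 3,
            rescale = 12,
            nu = if (!is.null(st$relRates)) 2 else 0,
            alpha = 2, pinv = 2, er = 2, bf = 2,
            mult = if (bundle$ctx$nPart > 1) 3 else 0,
            nni = if (bundle$topologyMoves) 6 else 0)
  }
  if (bundle$fixSubstModel)
    mv[c("alpha", "pinv", "er", "bf")] <- 0
  if (bundle$fixAges)
    mv[c("ageFree", "ageRoot", "ageCal", "rescale", "nni")] <- 0
  if (bundle$fixNu) mv["nu"] <- 0
  mv / sum(mv)
}

#' Run Metropolis-coupled MCMC
#'
#' Samples node ages, branch rates, clock and substitution parameters and
#' partition multipliers (and, optionally, the topology under constrained
#' NNI moves) from the posterior \code{likelihood^power * prior}.
#' \code{priorOnly} (power 0) performs the data-free run used to inspect
#' realized calibration priors.  Each of \code{config$nRuns} runs gets an
#' independent seed stream derived from the master seed.
#'
#' @param aln A \linkS4class{MultiGeneAlignment}.
#' @param scheme A \linkS4class{PartitionScheme}.
#' @param cals A \linkS4class{CalibrationSet}.
#' @param clock A \linkS4class{ClockModel} giving the clock kind and the
#'   initial rate and variance values.
#' @param config An \code{\link{mcmcConfig}}.
#' @param tree Optional initial \linkS4class{TimeTree} (also the fixed
#'   topology when \code{config$topologyMoves} is FALSE).
#' @param models Optional initial substitution model(s).
#' @return List of \linkS4class{Trace} objects, one per run.
#' @export
runMcmc <- function(aln, scheme, cals, clock, config = mcmcConfig(),
                    tree = NULL, models = NULL) {
  bundle <- .mcmcBundle(aln, scheme, cals, clock, config, tree, models)
  set.seed(config$seed)
  runSeeds <- sample.int(.Machine$integer.max - 1L, config$nRuns)
  traces <- vector("list", config$nRuns)
  for (r in seq_len(config$nRuns)) {
    set.seed(runSeeds[r])
    traces[[r]] <- .runOne(bundle, config, r)
  }
  if (config$nRuns >= 2L && config$topologyMoves) {
    a <- try(asdsf(traces), silent = TRUE)
    if (!inherits(a, "try-error") && is.finite(a) && a > 0.01)
      warning(sprintf("ASDSF %.4f above the 0.01 convergence threshold", a))
  }
  traces
}

.mcmcBundle <- function(aln, scheme, cals, clock, config, tree, models) {
  tipLabels <- if (!is.null(tree)) tree@tipLabels else aln@taxa
  nPart <- length(scheme@sites)
  pg <- if (config$linkModels) rep(1L, nPart) else seq_len(nPart)
  if (is.null(models)) models <- substitutionModel(alpha = 0.5, pInv = 0.1)
  if (is(models, "SubstitutionModel")) models <- list(models)
  nGroups <- max(pg)
  if (length(models) == 1L) models <- rep(models, nGroups)
  if (length(models) != nGroups) stop("need one model per model group")
  groups0 <- lapply(models, function(m)
    list(er = as.numeric(m@exchangeabilities), bf = as.numeric(m@baseFreqs),
         alpha = m@alpha, pinv = m@pInv))
  w <- vapply(scheme@sites, length, 0L)
  calKeys <- vapply(cals@nodes, function(cl)
    .splitKey(intersect(tipLabels, cl@clade)), "")
  consKeys <- vapply(cals@constraints, function(cl) {
    cl <- intersect(tipLabels, cl)
    .splitKey(cl)
  }, "")
  consKeys <- consKeys[vapply(cals@constraints, function(cl)
    length(intersect(tipLabels, cl)) >= 2, TRUE)]
  consKeys <- setdiff(consKeys, .splitKey(tipLabels))
  list(nTip = length(tipLabels), tipLabels = tipLabels,
       ctx = .likContext(aln, scheme, tipLabels),
       pg = pg, w = w / sum(w), cals = cals,
       calKeys = calKeys, consKeys = consKeys,
       clockKind = clock@kind, c0 = clock@rate,
       nu0 = if (clock@kind == "strict") 0 else clock@nu,
       groups0 = groups0, power = config$power,
       topologyMoves = config$topologyMoves,
       ratePriorMeanlog = config$ratePriorMeanlog,
       ratePriorSdlog = config$ratePriorSdlog,
       fixSubstModel = isTRUE(config$fixSubstModel),
       fixAges = isTRUE(config$fixAges),
       fixNu = isTRUE(config$fixNu),
       initTree = tree)
}

.runOne <- function(bundle, config, runId) {
  nChains <- config$nChains
  heats <- vapply(seq_len(nChains), heat, 0, temperature = config$temperature)
  chains <- vector("list", nChains)
  for (i in seq_len(nChains)) {
    for (try in 1:20) {
      st <- .evalState(.newState(bundle, config), bundle)
      if (is.finite(.logKernel(st, bundle))) break
      if (try == 20) stop("initialization error: no finite starting state")
    }
    chains[[i]] <- st
  }
  nSamp <- config$nGenerations %/% config$sampleEvery
  parNames <- c("logLik", "logPrior", "rootAge", "clockRate", "nu",
                "alpha1", "pinv1", "heightSubs", "treeLengthSubs")
  P <- matrix(NA_real_, nSamp, length(parNames),
              dimnames = list(NULL, parNames))
  trees <- vector("list", nSamp)
  gens <- integer(nSamp)
  k <- 0L
  mvProbs <- .moveTable(bundle, chains[[1]])
  mvNames <- names(mvProbs)
  for (gen in seq_len(config$nGenerations)) {
    for (ci in seq_len(nChains))
      chains[[ci]] <- .oneMove(chains[[ci]], bundle, heats[ci],
                               sample(mvNames, 1L, prob = mvProbs))
    if (nChains > 1L) {
      pr <- sample.int(nChains, 2L)
      ki <- .logKernel(chains[[pr[1]]], bundle)
      kj <- .logKernel(chains[[pr[2]]], bundle)
      if (log(stats::runif(1)) <
          (heats[pr[1]] - heats[pr[2]]) * (kj - ki)) {
        tmp <- chains[[pr[1]]]; chains[[pr[1]]] <- chains[[pr[2]]]
        chains[[pr[2]]] <- tmp
      }
    }
    if (gen %% config$sampleEvery == 0L) {
      k <- k + 1L
      st <- chains[[1L]]
      n <- bundle$nTip
      dur <- .durations(st)
      rel <- if (is.null(st$relRates)) rep(1, length(dur)) else st$relRates
      P[k, ] <- c(sum(st$partLL), .logPrior(st), st$ages[n + 1L], st$c,
                  st$nu, st$groups[[1]]$alpha, st$groups[[1]]$pinv,
                  st$ages[n + 1L] * st$c, sum(dur * rel * st$c))
      trees[[k]] <- list(splits = unname(st$splitKeys),
                         ages = unname(st$ages[as.integer(names(st$splitKeys))]))
      gens[k] <- gen
    }
  }
  new("Trace", params = as.data.frame(P), trees = trees,
      tipLabels = bundle$tipLabels, generations = gens,
      runId = as.integer(runId),
      info = list(clockKind = bundle$clockKind, power = bundle$power,
                  essLogLik = .ess(P[, "logLik"])))
}

## simple initial-positive-sequence ESS estimate
.ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (r in ac) { if (r < 0) break; s <- s + r }
  n / (1 + 2 * s)
}

## ---- proposal kernels --------------------------------------------------

.oneMove <- function(st, bundle, h, mv) {
  switch(mv,
    ageFree = .mvAgeFree(st, bundle, h),
    ageRoot = .mvAgeRoot(st, bundle, h),
    ageCal  = .mvAgeCal(st, bundle, h),
    rate    = .mvRate(st, bundle, h),
    cRate   = .mvC(st, bundle, h),
    rescale = .mvRescale(st, bundle, h),
    nu      = .mvNu(st, bundle, h),
    alpha   = .mvAlpha(st, bundle, h),
    pinv    = .mvPinv(st, bundle, h),
    er      = .mvEr(st, bundle, h),
    bf      = .mvBf(st, bundle, h),
    mult    = .mvMult(st, bundle, h),
    nni     = .mvNni(st, bundle, h))
}

## accept/reject helper comparing full kernels of old and proposed states
.mhAccept <- function(st, prop, bundle, h, logHastings) {
  dk <- .logKernel(prop, bundle) - .logKernel(st, bundle)
  acc <- h * dk + logHastings
  if (is.nan(acc)) return(st)
  if (log(stats::runif(1)) < acc) prop else st
}

.mvAgeFree <- function(st, bundle, h) {
  v <- if (length(st$freeNodes) == 1L) st$freeNodes else sample(st$freeNodes, 1L)
  lo <- max(st$ages[st$kids[v, ]])
  hi <- st$ages[st$parent[v]]
  prop <- st
  prop$ages[v] <- stats::runif(1, lo, hi)
  prop$lpRates <- .priorRates(prop, bundle)
  prop$partLL <- .stateLik(prop, bundle, prop$tabs)
  .mhAccept(st, prop, bundle, h, 0)
}

.mvAgeRoot <- function(st, bundle, h) {
  n <- bundle$nTip
  prop <- st
  if (stats::runif(1) < 0.5) {
    ## independent draw in the admissible part of the calibration window
    lo <- max(max(st$ages[st$kids[n + 1L, ]]), bundle$cals@root@minAge)
    hi <- bundle$cals@root@maxAge
    if (hi <= lo) return(st)
    prop$ages[n + 1L] <- stats::runif(1, lo, hi)
    lh <- 0
  } else {
    ## tree stretch: scale every internal age, keeping relative structure
    f <- exp(stats::runif(1, -0.15, 0.15))
    ids <- (n + 1L):(2L * n - 1L)
    prop$ages[ids] <- st$ages[ids] * f
    lh <- length(ids) * log(f)
  }
  if (prop$ages[n + 1L] <= max(prop$ages[st$kids[n + 1L, ]])) return(st)
  tp <- .priorTree(prop, bundle)
  if (!is.finite(tp$dens)) return(st)
  prop$lpTree <- tp$dens; prop$logVol <- tp$logVol
  prop$lpRates <- .priorRates(prop, bundle)
  prop$partLL <- .stateLik(prop, bundle, prop$tabs)
  .mhAccept(st, prop, bundle, h, lh)
}

.mvAgeCal <- function(st, bundle, h) {
  i <- if (length(st$calNodes) == 1L) 1L else sample(length(st$calNodes), 1L)
  v <- st$calNodes[i]
  lo <- max(st$ages[st$kids[v, ]])
  hi <- st$ages[st$parent[v]]
  prop <- st
  prop$ages[v] <- stats::runif(1, lo, hi)
  tp <- .priorTree(prop, bundle)
  if (!is.finite(tp$dens)) return(st)
  prop$lpTree <- tp$dens; prop$logVol <- tp$logVol
  prop$lpRates <- .priorRates(prop, bundle)
  prop$partLL <- .stateLik(prop, bundle, prop$tabs)
  .mhAccept(st, prop, bundle, h, 0)
}

.mvRate <- function(st, bundle, h) {
  e <- sample.int(length(st$relRates), 1L)
  f <- exp(stats::runif(1, -0.5, 0.5))
  prop <- st
  prop$relRates[e] <- st$relRates[e] * f
  prop$lpRates <- .priorRates(prop, bundle)
  prop$partLL <- .stateLik(prop, bundle, prop$tabs)
  .mhAccept(st, prop, bundle, h, log(f))
}

.mvC <- function(st, bundle, h) {
  f <- exp(stats::runif(1, -0.4, 0.4))
  prop <- st
  prop$c <- st$c * f
  prop$lpScalar <- .priorScalars(prop, bundle)
  prop$partLL <- .stateLik(prop, bundle, prop$tabs)
  .mhAccept(st, prop, bundle, h, log(f))
}

## draw branch rates from their conditional prior given nu (used by the
## joint nu/rates kernel that defeats the nu-rates funnel)
.drawRates <- function(st, bundle, nu) {
  dur <- .durations(st)
  if (bundle$clockKind == "IGR") {
    shape <- dur / nu
    stats::rgamma(length(dur), shape = shape, rate = shape)
  } else {
    n <- bundle$nTip
    ord <- order(st$ages[st$edge[, 1L]], decreasing = TRUE)
    rates <- numeric(length(dur))
    for (i in ord) {
      par <- st$edge[i, 1L]
      pr <- if (par == n + 1L) 1 else rates[st$edgeOfChild[par]]
      v <- nu * dur[i]
      rates[i] <- stats::rlnorm(1, meanlog = log(pr) - v / 2, sdlog = sqrt(v))
    }
    rates
  }
}

.mvNu <- function(st, bundle, h) {
  f <- exp(stats::runif(1, -0.8, 0.8))
  prop <- st
  prop$nu <- st$nu * f
  if (stats::runif(1) < 0.5) {
    ## plain scale move on nu
    prop$lpScalar <- .priorScalars(prop, bundle)
    prop$lpRates <- .priorRates(prop, bundle)
    .mhAccept(st, prop, bundle, h, log(f))
  } else {
    ## joint move: redraw every branch rate from its conditional prior at
    ## the new nu; the conditional densities cancel in the Green ratio, so
    ## the Hastings term transfers the old/new rate-prior difference
    prop$relRates <- .drawRates(st, bundle, prop$nu)
    if (any(!is.finite(prop$relRates)) || any(prop$relRates <= 0))
      return(st)  # zero-density draw (gamma underflow): always rejected
    prop$lpScalar <- .priorScalars(prop, bundle)
    prop$lpRates <- .priorRates(prop, bundle)
    if (!is.finite(prop$lpRates)) return(st)
    prop$partLL <- .stateLik(prop, bundle, prop$tabs)
    lh <- log(f) + st$lpRates - prop$lpRates
    .mhAccept(st, prop, bundle, h, lh)
  }
}

.mvGroupUpdate <- function(st, bundle, h, g, newGroup, logHastings) {
  prop <- st
  prop$groups[[g]] <- newGroup
  prop$lpScalar <- .priorScalars(prop, bundle)
  prop$groupTabs[[g]] <- .groupTabs(newGroup)
  prop$tabs <- .likTabs(prop, bundle, prop$groupTabs)
  parts <- which(bundle$pg == g)
  newLL <- st$partLL
  newLL[parts] <- .stateLik(prop, bundle, prop$tabs, parts)
  prop$partLL <- newLL
  .mhAccept(st, prop, bundle, h, logHastings)
}

.mvAlpha <- function(st, bundle, h) {
  g <- sample.int(length(st$groups), 1L)
  f <- exp(stats::runif(1, -1, 1))
  ng <- st$groups[[g]]; ng$alpha <- ng$alpha * f
  .mvGroupUpdate(st, bundle, h, g, ng, log(f))
}

.mvPinv <- function(st, bundle, h) {
  g <- sample.int(length(st$groups), 1L)
  p <- st$groups[[g]]$pinv + stats::runif(1, -0.25, 0.25)
  ## reflect into [0, 1)
  if (p < 0) p <- -p
  if (p >= 1) p <- 2 - p
  if (p < 0 || p >= 1) return(st)
  ng <- st$groups[[g]]; ng$pinv <- p
  .mvGroupUpdate(st, bundle, h, g, ng, 0)
}

.mvSimplex <- function(cur, eps) {
  prop <- .rdirichlet(eps * cur)
  if (any(prop <= 0)) return(NULL)
  list(value = prop,
       logHastings = .ldirichlet(cur, eps * prop) -
                     .ldirichlet(prop, eps * cur))
}

.mvEr <- function(st, bundle, h) {
  g <- sample.int(length(st$groups), 1L)
  sp <- .mvSimplex(st$groups[[g]]$er, 1500)
  if (is.null(sp)) return(st)
  ng <- st$groups[[g]]; ng$er <- sp$value
  .mvGroupUpdate(st, bundle, h, g, ng, sp$logHastings)
}

.mvBf <- function(st, bundle, h) {
  g <- sample.int(length(st$groups), 1L)
  sp <- .mvSimplex(st$groups[[g]]$bf, 3000)
  if (is.null(sp)) return(st)
  ng <- st$groups[[g]]; ng$bf <- sp$value
  .mvGroupUpdate(st, bundle, h, g, ng, sp$logHastings)
}

.mvMult <- function(st, bundle, h) {
  sp <- .mvSimplex(st$x, 2000)
  if (is.null(sp)) return(st)
  prop <- st
  prop$x <- sp$value
  prop$partLL <- .stateLik(prop, bundle, prop$tabs)
  .mhAccept(st, prop, bundle, h, sp$logHastings)
}

## joint rescale along the rate-time ridge: all internal ages times f,
## clock rate divided by f; substitution branch lengths (and hence the
## likelihood) are unchanged, so this explores the age/rate ridge cheaply
.mvRescale <- function(st, bundle, h) {
  n <- bundle$nTip
  f <- exp(stats::runif(1, -0.2, 0.2))
  ids <- (n + 1L):(2L * n - 1L)
  prop <- st
  prop$ages[ids] <- st$ages[ids] * f
  prop$c <- st$c / f
  tp <- .priorTree(prop, bundle)
  if (!is.finite(tp$dens)) return(st)
  prop$lpTree <- tp$dens; prop$logVol <- tp$logVol
  prop$lpRates <- .priorRates(prop, bundle)
  prop$lpScalar <- .priorScalars(prop, bundle)
  .mhAccept(st, prop, bundle, h, (length(ids) - 1L) * log(f))
}

## constrained NNI: exchange an internal node's sibling with one of its
## children, rejecting exchanges that violate age order or monophyly
.mvNni <- function(st, bundle, h) {
  n <- bundle$nTip
  internal <- setdiff((n + 2L):(2L * n - 1L), integer(0))
  if (!length(internal)) return(st)
  v <- if (length(internal) == 1L) internal else sample(internal, 1L)
  u <- st$parent[v]
  sib <- setdiff(st$kids[u, ], v)
  child <- st$kids[v, sample.int(2L, 1L)]
  if (st$ages[v] <= st$ages[sib]) return(st)  # sib must fit under v
  prop <- st
  iChild <- st$edgeOfChild[child]
  iSib <- st$edgeOfChild[sib]
  prop$edge[iChild, 1L] <- u
  prop$edge[iSib, 1L] <- v
  prop <- .refreshStructure(prop, bundle)
  if (!prop$consOK) return(st)
  tp <- .priorTree(prop, bundle)
  if (!is.finite(tp$dens)) return(st)
  prop$lpTree <- tp$dens; prop$logVol <- tp$logVol
  prop$lpRates <- .priorRates(prop, bundle)
  prop$partLL <- .stateLik(prop, bundle, prop$tabs)
  .mhAccept(st, prop, bundle, h, 0)
}
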