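#' Stepping-stone power schedule
#'
#' Returns \code{nSteps} power values descending from 1 to 0, placed at the
#' quantiles of a Beta(shape, 1) distribution; \code{shape = 1} gives an
#' evenly spaced ladder, the default \code{shape = 0.4} concentrates steps
#' near the prior where the integrand changes fastest.
#'
#' @param nSteps Number of ladder values, >= 2.
#' @param shape Beta shape parameter, > 0.
#' @return Strictly decreasing numeric vector, first 1, last 0.
#' @examples
#' betaSchedule(4, 1)  # 1, 2/3, 1/3, 0
#' @export
betaSchedule <- function(nSteps, shape = 0.4) {
  stopifnot(nSteps >= 2L, shape > 0)
  K <- nSteps - 1L
  stats::qbeta((K:0) / K, shape, 1)
}

.logMeanExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

#' Stepping-stone log marginal likelihood
#'
#' Estimates \eqn{\log m(D)} by bridging posterior and prior through a
#' ladder of power posteriors \eqn{L^\beta \pi}: the chain is run
#' sequentially down the \code{\link{betaSchedule}} ladder (warm starts),
#' with an initial warm-up phase at power 1 discarded as burn-in, and each
#' rung contributes \eqn{\log \frac1n \sum_j e^{(\beta_{k-1}-\beta_k)\,
#' \ell_j}} from log-likelihood samples \eqn{\ell_j} drawn at the lower
#' power \eqn{\beta_k} (log-sum-exp stabilised).
#'
#' @param aln,scheme,cals,clock,tree,models As in \code{\link{runMcmc}}.
#' @param ss A \code{\link{steppingStoneConfig}}.
#' @param config An \code{\link{mcmcConfig}} supplying move settings
#'   (\code{priorOnly = TRUE} makes the likelihood identically 1, giving a
#'   log marginal likelihood of exactly 0).
#' @return The log marginal likelihood, with attribute \code{"table"}: a
#'   data.frame of per-step beta, mean log-likelihood, step contribution
#'   and running total.
#' @export
steppingStoneLogml <- function(aln, scheme, cals, clock,
                               ss = steppingStoneConfig(),
                               config = mcmcConfig(), tree = NULL,
                               models = NULL) {
  set.seed(ss$seed)
  bundle <- .mcmcBundle(aln, scheme, cals, clock, config, tree, models)
  dataFree <- config$priorOnly
  bundle$power <- if (dataFree) 0 else 1
  for (try in 1:20) {
    st <- .evalState(.newState(bundle, config), bundle)
    if (is.finite(.logKernel(st, bundle))) break
    if (try == 20) stop("initialization error: no finite starting state")
  }
  mvProbs <- .moveTable(bundle, st)
  mvNames <- names(mvProbs)
  stepGen <- function(st) .oneMove(st, bundle, 1,
                                   sample(mvNames, 1L, prob = mvProbs))
  ## first step treated as burn-in: warm-up at the posterior
  for (g in seq_len(ss$burnInGenerations)) st <- stepGen(st)
  betas <- betaSchedule(ss$nSteps, ss$shape)
  K <- length(betas) - 1L
  meanLL <- contrib <- numeric(K)
  bundleFull <- bundle; bundleFull$power <- 1
  for (k in seq_len(K)) {
    bLow <- betas[k + 1L]
    bundle$power <- if (dataFree) 0 else bLow
    for (g in seq_len(ss$burnInGenerations)) st <- stepGen(st)
    ll <- numeric(ss$sampleCount)
    for (j in seq_len(ss$sampleCount)) {
      for (g in seq_len(ss$sampleEvery)) st <- stepGen(st)
      ll[j] <- if (dataFree) 0
               else if (bLow > 0) sum(st$partLL)
               else sum(.stateLik(st, bundleFull, st$tabs))
    }
    meanLL[k] <- mean(ll)
    contrib[k] <- .logMeanExp((betas[k] - bLow) * ll)
    if (!is.finite(contrib[k]))
      stop(sprintf("numerical error: non-finite contribution at step %d", k))
  }
  logml <- sum(contrib)
  attr(logml, "table") <- data.frame(beta = betas[-1L], meanLogL = meanLL,
                                     contribution = contrib,
                                     running = cumsum(contrib))
  logml
}

#' Twice the log Bayes factor
#'
#' \code{2 * (logmlA - logmlB)}, the scale on which values above 2, 6 and
#' 10 are conventionally read as positive, strong and very strong evidence
#' for model A (Kass-Raftery bands, attached as an attribute).
#'
#' @param logmlA,logmlB Log marginal likelihoods of models A and B.
#' @return Numeric; attribute \code{"interpretation"} gives the band.
#' @export
bayesFactor2ln <- function(logmlA, logmlB) {
  v <- 2 * (as.numeric(logmlA) - as.numeric(logmlB))
  band <- cut(abs(v), c(-Inf, 2, 6, 10, Inf),
              labels = c("not worth more than a bare mention", "positive",
                         "strong", "very strong"))
  attr(v, "interpretation") <- as.character(band)
  v
}
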