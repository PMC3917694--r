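#' Log-density of a node-age calibration
#'
#' Uniform calibrations return \code{log(1/(max-min))} inside the window and
#' \code{-Inf} outside.  Offset-exponential calibrations return
#' \code{log(lambda) - lambda*(age - offset)} for ages at or above the
#' offset (with \code{lambda = 1/(mean - offset)}) and \code{-Inf} below
#' the hard minimum.
#'
#' @param cal A \linkS4class{Calibration}.
#' @param age Node age(s) in Mya.
#' @return Log-density, vectorised over \code{age}.
#' @examples
#' calibrationLogDensity(uniformCalibration(52, 85), 60)  # log(1/33)
#' calibrationLogDensity(offsetExpCalibration(18, 58), 18)  # log(1/40)
#' @export
calibrationLogDensity <- function(cal, age) {
  if (cal@kind == "uniform") {
    ifelse(age >= cal@minAge & age <= cal@maxAge,
           -log(cal@maxAge - cal@minAge), -Inf)
  } else {
    lam <- 1 / (cal@meanAge - cal@offset)
    ifelse(age >= cal@offset, log(lam) - lam * (age - cal@offset), -Inf)
  }
}

#' Log-prior of branch rates under a clock model
#'
#' Rates are relative to the base clock rate (the tree's \code{rates} slot).
#' Strict: zero when every rate is 1 (all branches at the base rate), else
#' \code{-Inf}.  IGR (white noise): each branch's rate is an independent
#' Gamma draw with mean 1 and variance \code{nu/duration}, so longer
#' branches have less rate noise.  TK02: each branch's rate is lognormal
#' with expectation equal to its parent branch's rate (the base rate for
#' the two root branches) and log-variance \code{nu*duration}.
#'
#' @param clock A \linkS4class{ClockModel}.
#' @param tree A \linkS4class{TimeTree} with positive branch durations.
#' @param rates Per-edge relative rates (default: the tree's own).
#' @return Log joint density; \code{-Inf} for non-positive rates under a
#'   relaxed clock.
#' @export
branchRatesLogPrior <- function(clock, tree, rates = branchRates(tree)) {
  if (is.null(rates)) stop("tree carries no branch rates")
  dur <- branchDurations(tree)
  if (any(dur <= 0)) stop("branch durations must be positive")
  switch(clock@kind,
    strict = if (all(abs(rates - 1) < 1e-12)) 0 else -Inf,
    IGR = {
      if (clock@nu <= 0) stop("IGR requires a positive variance parameter")
      if (any(rates <= 0)) return(-Inf)
      shape <- dur / clock@nu           # mean 1, variance nu/duration
      sum(stats::dgamma(rates, shape = shape, rate = shape, log = TRUE))
    },
    TK02 = {
      if (clock@nu <= 0) stop("TK02 requires a positive variance parameter")
      if (any(rates <= 0)) return(-Inf)
      parentRate <- .parentEdgeRates(tree, rates)
      v <- clock@nu * dur               # log-variance grows with duration
      ## lognormal with E[r] = parentRate: meanlog = log(parent) - v/2
      sum(stats::dlnorm(rates, meanlog = log(parentRate) - v / 2,
                        sdlog = sqrt(v), log = TRUE))
    })
}

## rate of each edge's parent edge; base rate (1) for root-adjacent edges
.parentEdgeRates <- function(tree, rates) {
  n <- nTip(tree)
  edgeOfChild <- integer(2L * n - 1L)
  edgeOfChild[tree@edge[, 2L]] <- seq_len(nrow(tree@edge))
  parentNode <- tree@edge[, 1L]
  out <- numeric(nrow(tree@edge))
  for (i in seq_len(nrow(tree@edge))) {
    pe <- if (parentNode[i] == n + 1L) 0L else edgeOfChild[parentNode[i]]
    out[i] <- if (pe == 0L) 1 else rates[pe]
  }
  out
}

#' Effective branch lengths in substitutions per site
#'
#' Multiplies each branch's duration (My) by its effective rate
#' (base clock rate times the branch's relative rate) to produce the branch
#' lengths the likelihood consumes.
#'
#' @param clock A \linkS4class{ClockModel}.
#' @param tree A \linkS4class{TimeTree}.
#' @param rates Per-edge relative rates (default: the tree's own; a strict
#'   clock uses 1 everywhere).
#' @return Numeric per-edge lengths (expected substitutions/site).
#' @export
effectiveBranchLengths <- function(clock, tree, rates = branchRates(tree)) {
  dur <- branchDurations(tree)
  if (clock@kind == "strict" || is.null(rates)) rates <- rep(1, length(dur))
  if (any(rates < 0)) stop("rates must be non-negative")
  clock@rate * rates * dur
}
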