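#' Average standard deviation of split frequencies
#'
#' The topological convergence diagnostic compared across independent
#' runs: for every non-trivial split whose frequency exceeds
#' \code{minFreq} in at least one run, the standard deviation (population,
#' i.e. n-denominator) of its per-run frequencies is computed; the average
#' over those splits is returned.  Values below 0.01 are conventionally
#' taken to indicate good topological convergence.
#'
#' @param traces List of at least two \linkS4class{Trace} objects sharing
#'   taxa.
#' @param minFreq Minimum split frequency for inclusion (default 0.1).
#' @return The ASDSF (a single number; 0 when runs agree exactly).
#' @export
asdsf <- function(traces, minFreq = 0.1) {
  if (length(traces) < 2L) stop("asdsf needs at least two traces")
  labs <- traces[[1]]@tipLabels
  for (tr in traces) if (!setequal(tr@tipLabels, labs))
    stop("traces must share the same taxa")
  trivial <- .splitKey(labs)
  freq <- lapply(traces, function(tr) {
    n <- length(tr@trees)
    tab <- table(unlist(lapply(tr@trees, `[[`, "splits")))
    tab <- tab[names(tab) != trivial]
    tab / n
  })
  splits <- unique(unlist(lapply(freq, names)))
  keep <- splits[vapply(splits, function(s)
    any(vapply(freq, function(f) (if (s %in% names(f)) f[[s]] else 0) > minFreq,
               TRUE)), TRUE)]
  if (!length(keep)) return(0)
  sds <- vapply(keep, function(s) {
    fs <- vapply(freq, function(f) if (s %in% names(f)) f[[s]] else 0, 0)
    sqrt(mean((fs - mean(fs))^2))  # population (n) denominator
  }, 0)
  mean(sds)
}

#' Empirical-Bayes lognormal prior for the clock rate
#'
#' Divides the posterior median tree height in substitution units from a
#' strict-clock, effectively-uncalibrated run by the mean root age under
#' the root calibration, and uses the quotient as the median of a
#' lognormal prior with a log standard deviation of 1 (weakly
#' informative).
#'
#' @param strictTrace A \linkS4class{Trace} from a strict-clock run (its
#'   \code{heightSubs} column is used), or NULL when \code{heightSubs}
#'   is given directly.
#' @param rootCal The uniform root \linkS4class{Calibration} of the dating
#'   analysis.
#' @param heightSubs Optional tree height in substitutions/site, bypassing
#'   the trace.
#' @param sdlog Log standard deviation of the returned prior (default 1).
#' @return List with \code{meanlog}, \code{sdlog}, \code{medianRate}.
#' @examples
#' empiricalBayesClockPrior(heightSubs = 0.685,
#'                          rootCal = uniformCalibration(52, 85))
#' @export
empiricalBayesClockPrior <- function(strictTrace = NULL, rootCal,
                                     heightSubs = NULL, sdlog = 1) {
  if (is.null(heightSubs)) {
    if (is.null(strictTrace)) stop("need a strict-clock trace or heightSubs")
    heightSubs <- stats::median(strictTrace@params$heightSubs)
  }
  if (!is.finite(heightSubs) || heightSubs <= 0)
    stop("degenerate tree height")
  meanRootAge <- (rootCal@minAge + rootCal@maxAge) / 2
  med <- heightSubs / meanRootAge
  list(meanlog = log(med), sdlog = sdlog, medianRate = med)
}
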