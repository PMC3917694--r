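#' Construct a substitution model
#'
#' @param exchangeabilities Six positive GTR exchangeabilities in the order
#'   AC, AG, AT, CG, CT, GT.  Normalised to sum to one.
#' @param baseFreqs Four stationary base frequencies (A, C, G, T).
#' @param alpha Gamma shape of among-site rate variation (default 1).
#' @param pInv Proportion of invariant sites (default 0).
#' @return A \linkS4class{SubstitutionModel}.
#' @examples
#' substitutionModel()            # Jukes-Cantor
#' substitutionModel(alpha = 0.5, pInv = 0.2)
#' @export
substitutionModel <- function(exchangeabilities = rep(1, 6),
                              baseFreqs = rep(0.25, 4),
                              alpha = 1, pInv = 0) {
  ex <- as.numeric(exchangeabilities)
  names(ex) <- c("AC", "AG", "AT", "CG", "CT", "GT")
  bf <- as.numeric(baseFreqs)
  names(bf) <- c("A", "C", "G", "T")
  new("SubstitutionModel",
      exchangeabilities = ex / sum(ex),
      baseFreqs = bf / sum(bf),
      alpha = as.numeric(alpha), pInv = as.numeric(pInv), nCat = 4L)
}

#' Construct a clock model
#'
#' @param kind "strict", "IGR" or "TK02".
#' @param rate Base clock rate in substitutions/site/My.
#' @param nu Variance parameter of the relaxed clock (ignored for strict).
#' @return A \linkS4class{ClockModel}.
#' @export
clockModel <- function(kind = c("strict", "IGR", "TK02"), rate = 0.0025, nu = 0.1) {
  kind <- match.arg(kind)
  if (kind != "strict" && nu <= 0)
    stop("relaxed clock requires a positive variance parameter nu")
  new("ClockModel", kind = kind, rate = as.numeric(rate),
      nu = if (kind == "strict") 0 else as.numeric(nu))
}

#' Construct a uniform node-age calibration
#' @param minAge,maxAge Window bounds in Mya.
#' @param clade Taxon labels of the calibrated clade (empty = root).
#' @export
uniformCalibration <- function(minAge, maxAge, clade = character()) {
  if (maxAge < minAge) {
    warning("calibration window reversed; swapping bounds")
    tmp <- minAge; minAge <- maxAge; maxAge <- tmp
  }
  new("Calibration", kind = "uniform", minAge = as.numeric(minAge),
      maxAge = as.numeric(maxAge), offset = NA_real_, meanAge = NA_real_,
      clade = as.character(clade))
}

#' Construct an offset-exponential (fossil minimum) calibration
#'
#' The density is \eqn{\lambda e^{-\lambda (a - x_0)}} for ages
#' \eqn{a \ge x_0}, with \eqn{\lambda = 1/(\mu - x_0)} so that \code{meanAge}
#' is the mean of the full distribution.
#'
#' @param offset Hard minimum age \eqn{x_0} (the fossil's youngest bound), Mya.
#' @param meanAge Mean \eqn{\mu} of the full distribution, Mya.
#' @param clade Taxon labels of the calibrated clade.
#' @export
offsetExpCalibration <- function(offset, meanAge, clade = character()) {
  new("Calibration", kind = "offset_exponential", minAge = NA_real_,
      maxAge = NA_real_, offset = as.numeric(offset),
      meanAge = as.numeric(meanAge), clade = as.character(clade))
}

#' Bundle calibrations and monophyly constraints
#'
#' @param root Uniform \linkS4class{Calibration} on the root age.
#' @param nodes List of internal \linkS4class{Calibration}s (each with a clade).
#' @param constraints Named list of extra monophyletic taxon sets (the clades
#'   of \code{nodes} are added automatically).
#' @return A \linkS4class{CalibrationSet}.
#' @export
calibrationSet <- function(root, nodes = list(), constraints = list()) {
  cons <- constraints
  for (i in seq_along(nodes)) {
    cal <- nodes[[i]]
    if (!length(cal@clade)) stop("internal calibrations must name a clade")
    nm <- names(nodes)[i]
    if (is.null(nm) || !nzchar(nm)) nm <- paste0("cal", i)
    cons[[nm]] <- cal@clade
  }
  new("CalibrationSet", root = root, nodes = nodes, constraints = cons)
}

#' Construct a time tree
#'
#' @param edge Integer edge matrix (parent, child), ape numbering.
#' @param tipLabels Taxon labels.
#' @param ages Node ages in Mya (length 2n-1).
#' @param rates Optional per-edge relative rates.
#' @return A \linkS4class{TimeTree}.
#' @export
timeTree <- function(edge, tipLabels, ages, rates = numeric()) {
  new("TimeTree", edge = matrix(as.integer(edge), ncol = 2L),
      tipLabels = as.character(tipLabels), ages = as.numeric(ages),
      rates = as.numeric(rates))
}

#' Construct a multi-gene alignment
#'
#' @param genes Named list of character matrices (taxa x sites); rownames
#'   identify taxa.  A taxon present in one gene but absent from another is
#'   filled in with '?' for the gene it lacks.
#' @param taxa Optional explicit taxon ordering (default: union in order of
#'   first appearance).
#' @return A \linkS4class{MultiGeneAlignment}.
#' @export
multiGeneAlignment <- function(genes, taxa = NULL) {
  if (is.null(names(genes)) || any(!nzchar(names(genes))))
    stop("genes must be a named list")
  if (is.null(taxa))
    taxa <- unique(unlist(lapply(genes, rownames)))
  genes <- lapply(genes, function(m) {
    m[] <- toupper(m)
    miss <- setdiff(taxa, rownames(m))
    if (length(miss)) {
      fill <- matrix("?", nrow = length(miss), ncol = ncol(m),
                     dimnames = list(miss, NULL))
      m <- rbind(m, fill)
    }
    m[taxa, , drop = FALSE]
  })
  new("MultiGeneAlignment", taxa = taxa, genes = genes)
}

#' MCMC run configuration
#'
#' @param nGenerations Number of MCMC generations (one proposal each).
#' @param sampleEvery Sampling interval in generations.
#' @param nChains Number of Metropolis-coupled chains (1 = plain MCMC).
#' @param temperature Heating constant T; chain i has heat 1/(1+(i-1)T).
#' @param nRuns Number of independent runs.
#' @param seed Master seed; per-run streams are derived from it.
#' @param burnInFrac Fraction of samples discarded when runs are combined.
#' @param priorOnly If TRUE the likelihood is switched off (power 0).
#' @param power Likelihood power beta (stepping-stone reuse); priorOnly
#'   forces 0.
#' @param topologyMoves Enable constrained NNI topology proposals.
#' @param linkModels Share one substitution model across partitions
#'   (default FALSE: models unlinked across partitions).
#' @param ratePriorMeanlog,ratePriorSdlog Lognormal prior on the base clock
#'   rate (the empirical-Bayes prior; sd defaults to 1).
#' @param fixSubstModel Freeze the substitution model(s) at their initial
#'   values (no alpha/pInv/frequency/exchangeability moves).
#' @param fixAges Freeze the tree (no node-age, rescale or topology moves);
#'   useful for conjugate checks with a single free parameter.
#' @param fixNu Freeze the relaxed-clock variance parameter at its initial
#'   value (used by the clock-model recovery experiment, where letting nu
#'   collapse towards zero makes the IGR and strict marginals merge).
#' @return A classed list of settings.
#' @export
mcmcConfig <- function(nGenerations = 10000L, sampleEvery = 10L, nChains = 1L,
                       temperature = 0.1, nRuns = 1L, seed = 1L,
                       burnInFrac = 0.25, priorOnly = FALSE, power = 1,
                       topologyMoves = FALSE, linkModels = FALSE,
                       ratePriorMeanlog = log(0.0025), ratePriorSdlog = 1,
                       fixSubstModel = FALSE, fixAges = FALSE,
                       fixNu = FALSE) {
  stopifnot(nChains >= 1L, sampleEvery > 0L, sampleEvery <= nGenerations,
            temperature >= 0, burnInFrac >= 0, burnInFrac < 1)
  structure(list(nGenerations = as.integer(nGenerations),
                 sampleEvery = as.integer(sampleEvery),
                 nChains = as.integer(nChains), temperature = temperature,
                 nRuns = as.integer(nRuns), seed = as.integer(seed),
                 burnInFrac = burnInFrac, priorOnly = priorOnly,
                 power = if (priorOnly) 0 else power,
                 topologyMoves = topologyMoves, linkModels = linkModels,
                 ratePriorMeanlog = ratePriorMeanlog,
                 ratePriorSdlog = ratePriorSdlog,
                 fixSubstModel = fixSubstModel, fixAges = fixAges,
                 fixNu = fixNu),
            class = "McmcConfig")
}

#' Stepping-stone configuration
#'
#' @param nSteps Number of power-posterior steps (default 49, the reference
#'   configuration); the first step is discarded as burn-in via an initial
#'   warm-up phase at power 1.
#' @param shape Beta(shape, 1) quantile schedule shape (default 0.4).
#' @param burnInGenerations Within-step burn-in generations.
#' @param sampleCount Samples drawn per step.
#' @param sampleEvery Generations between retained samples within a step.
#' @param seed Seed for the whole ladder.
#' @export
steppingStoneConfig <- function(nSteps = 49L, shape = 0.4,
                                burnInGenerations = 200L, sampleCount = 100L,
                                sampleEvery = 5L, seed = 1L) {
  stopifnot(nSteps >= 2L, shape > 0)
  structure(list(nSteps = as.integer(nSteps), shape = shape,
                 burnInGenerations = as.integer(burnInGenerations),
                 sampleCount = as.integer(sampleCount),
                 sampleEvery = as.integer(sampleEvery), seed = as.integer(seed)),
            class = "SteppingStoneConfig")
}
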