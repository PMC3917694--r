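#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib passerclock, .registration = TRUE
NULL

#' Nucleotide substitution model (GTR + Gamma(4) + I)
#'
#' A general time-reversible model with discrete-gamma rate variation over
#' four equal-probability categories and a proportion of invariant sites.
#' Branch lengths are expected substitutions per site: the rate matrix is
#' normalised so that the mean substitution rate at stationarity is one.
#'
#' @slot exchangeabilities Named numeric of length 6
#'   (AC, AG, AT, CG, CT, GT), positive; normalised to sum 1 on construction.
#' @slot baseFreqs Numeric of length 4 (A, C, G, T) on the simplex.
#' @slot alpha Gamma shape (> 0) of among-site rate variation.
#' @slot pInv Proportion of invariant sites in [0, 1).
#' @slot nCat Number of discrete gamma categories (4).
#' @export
setClass("SubstitutionModel", representation(
  exchangeabilities = "numeric",
  baseFreqs = "numeric",
  alpha = "numeric",
  pInv = "numeric",
  nCat = "integer"
))

setValidity("SubstitutionModel", function(object) {
  msg <- character()
  if (length(object@exchangeabilities) != 6L || any(object@exchangeabilities <= 0))
    msg <- c(msg, "exchangeabilities must be 6 positive values")
  if (length(object@baseFreqs) != 4L || any(object@baseFreqs <= 0) ||
      abs(sum(object@baseFreqs) - 1) > 1e-8)
    msg <- c(msg, "baseFreqs must be 4 positive values summing to 1")
  if (length(object@alpha) != 1L || object@alpha <= 0)
    msg <- c(msg, "alpha must be a single positive number")
  if (length(object@pInv) != 1L || object@pInv < 0 || object@pInv >= 1)
    msg <- c(msg, "pInv must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Molecular clock model
#'
#' One of three clocks: \code{strict} (a single rate on every branch),
#' \code{IGR} (independent gamma rates, a white-noise uncorrelated clock:
#' each branch carries a relative rate drawn independently from a gamma
#' distribution with mean 1 and variance \code{nu / duration}, so longer
#' branches have less rate noise), or \code{TK02} (autocorrelated lognormal:
#' a branch's relative rate is lognormal with expectation equal to its
#' parent branch's rate and log-variance \code{nu * duration}).  Effective
#' substitution rates are \code{rate * relative rate}, in expected
#' substitutions per site per My.
#'
#' @slot kind One of "strict", "IGR", "TK02".
#' @slot rate Base clock rate c (substitutions/site/My), > 0.
#' @slot nu Variance parameter (dimensionless; unused for strict), >= 0.
#' @export
setClass("ClockModel", representation(
  kind = "character",
  rate = "numeric",
  nu = "numeric"
))

setValidity("ClockModel", function(object) {
  msg <- character()
  if (!object@kind %in% c("strict", "IGR", "TK02"))
    msg <- c(msg, "kind must be strict, IGR or TK02")
  if (length(object@rate) != 1L || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (length(object@nu) != 1L || object@nu < 0)
    msg <- c(msg, "nu must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Node-age calibration
#'
#' A probability density on the age (Mya) of the most recent common ancestor
#' of a clade.  \code{uniform} calibrations are hard windows (used for the
#' root / vicariance events); \code{offset_exponential} calibrations encode
#' a fossil minimum age \code{offset} with an exponential tail whose rate is
#' \code{1 / (mean - offset)} so that \code{mean} is the mean of the full
#' distribution.
#'
#' @slot kind "uniform" or "offset_exponential".
#' @slot minAge,maxAge Window bounds for uniform calibrations (Mya).
#' @slot offset Hard minimum age for offset-exponential calibrations (Mya).
#' @slot meanAge Mean of the full offset-exponential distribution (Mya).
#' @slot clade Character vector of taxon labels whose MRCA is calibrated.
#' @export
setClass("Calibration", representation(
  kind = "character",
  minAge = "numeric",
  maxAge = "numeric",
  offset = "numeric",
  meanAge = "numeric",
  clade = "character"
))

setValidity("Calibration", function(object) {
  msg <- character()
  if (!object@kind %in% c("uniform", "offset_exponential"))
    msg <- c(msg, "kind must be uniform or offset_exponential")
  if (object@kind == "uniform" && !(object@maxAge > object@minAge))
    msg <- c(msg, "uniform calibration needs maxAge > minAge")
  if (object@kind == "offset_exponential" && !(object@meanAge > object@offset))
    msg <- c(msg, "offset_exponential calibration needs meanAge > offset")
  if (length(msg)) msg else TRUE
})

#' A set of calibrations and monophyly constraints
#'
#' Bundles the root calibration (a uniform window on the age of the whole
#' tree), any internal node calibrations (offset-exponential fossil minima
#' in the reference configuration), and the monophyly constraints that pin
#' each calibration to a clade.  Every calibrated clade is automatically a
#' constraint; extra unconstrained-age monophyly statements (such as the
#' rooting constraint that one taxon is sister to all others) may be added.
#'
#' @slot root A uniform \linkS4class{Calibration} on the root age.
#' @slot nodes List of internal \linkS4class{Calibration}s.
#' @slot constraints Named list of taxon-label vectors (monophyletic clades).
#' @export
setClass("CalibrationSet", representation(
  root = "Calibration",
  nodes = "list",
  constraints = "list"
))

setValidity("CalibrationSet", function(object) {
  msg <- character()
  if (object@root@kind != "uniform")
    msg <- c(msg, "root calibration must be uniform")
  for (cal in object@nodes)
    if (!is(cal, "Calibration")) msg <- c(msg, "nodes must hold Calibration objects")
  cl <- lapply(object@constraints, sort)
  for (i in seq_along(cl)) for (j in seq_len(i - 1L)) {
    ov <- intersect(cl[[i]], cl[[j]])
    if (length(ov) && !setequal(ov, cl[[i]]) && !setequal(ov, cl[[j]]))
      msg <- c(msg, "constraints must be nested or disjoint")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' Rooted time tree (chronogram)
#'
#' A rooted binary topology with node ages in My before present.  Node
#' numbering follows \pkg{ape}: tips are 1..n, the root is n+1, internal
#' nodes n+1..2n-1.  Branch durations are parent age minus child age; an
#' optional per-edge relative rate vector carries a relaxed-clock draw.
#'
#' @slot edge Integer matrix (2n-2 x 2), parent in column 1, child in 2.
#' @slot tipLabels Character vector of n taxon labels.
#' @slot ages Numeric vector of 2n-1 node ages (Mya, tips usually 0).
#' @slot rates Numeric per-edge relative rates (length 2n-2, or 0 if unset).
#' @export
setClass("TimeTree", representation(
  edge = "matrix",
  tipLabels = "character",
  ages = "numeric",
  rates = "numeric"
))

setValidity("TimeTree", function(object) {
  n <- length(object@tipLabels)
  msg <- character()
  if (n < 2) msg <- c(msg, "need at least 2 tips")
  if (nrow(object@edge) != 2L * n - 2L) msg <- c(msg, "edge must have 2n-2 rows")
  if (length(object@ages) != 2L * n - 1L) msg <- c(msg, "ages must have 2n-1 entries")
  else {
    dur <- object@ages[object@edge[, 1L]] - object@ages[object@edge[, 2L]]
    if (any(dur < 0)) msg <- c(msg, "every parent must be older than its child")
    if (object@ages[n + 1L] <= 0) msg <- c(msg, "root age must be positive")
  }
  if (length(object@rates) && length(object@rates) != nrow(object@edge))
    msg <- c(msg, "rates must be empty or one per edge")
  if (length(msg)) msg else TRUE
})

#' Multi-gene nucleotide alignment
#'
#' An ordered taxon set with one character matrix per gene.  Characters are
#' upper-case IUPAC nucleotide codes plus '-' (gap) and '?' (missing); gaps
#' and '?' are both treated as fully ambiguous by the likelihood but kept
#' distinct for round-tripping.  All genes share the same taxon rows; a
#' taxon without data for a gene carries a row of '?'.
#'
#' @slot taxa Ordered character vector of taxon labels.
#' @slot genes Named list of character matrices (taxa x sites).
#' @export
setClass("MultiGeneAlignment", representation(
  taxa = "character",
  genes = "list"
))

setValidity("MultiGeneAlignment", function(object) {
  msg <- character()
  if (anyDuplicated(object@taxa)) msg <- c(msg, "duplicate taxon labels")
  if (!length(object@genes)) msg <- c(msg, "at least one gene required")
  for (g in names(object@genes)) {
    m <- object@genes[[g]]
    if (!is.matrix(m) || nrow(m) != length(object@taxa))
      msg <- c(msg, sprintf("gene %s: matrix rows must match taxa", g))
    else if (!identical(rownames(m), object@taxa))
      msg <- c(msg, sprintf("gene %s: rownames must equal taxa", g))
  }
  if (length(msg)) msg else TRUE
})

#' Partition scheme over a multi-gene alignment
#'
#' Coding genes contribute two partitions (codon positions 1+2 and 3),
#' non-coding genes one; partitions are disjoint and cover every site of
#' the concatenated alignment.
#'
#' @slot table data.frame with columns partition, gene, multiplierIndex.
#' @slot sites List (one per partition) of global 1-based site indices.
#' @slot nSites Total concatenated alignment length.
#' @export
setClass("PartitionScheme", representation(
  table = "data.frame",
  sites = "list",
  nSites = "integer"
))

setValidity("PartitionScheme", function(object) {
  all_sites <- sort(unlist(object@sites))
  if (!identical(all_sites, seq_len(object@nSites)))
    "partition site sets must be a set-partition of 1..nSites"
  else TRUE
})

#' MCMC trace
#'
#' Sampled states from one MCMC run: a data.frame of scalar parameters
#' (log-likelihood, log-prior, root age, clock rate, ...) and, per sample,
#' the tree encoded as its internal-node bipartitions with matching ages,
#' which is the representation the consensus and node-age summaries consume.
#'
#' @slot params data.frame, one row per sample.
#' @slot trees List, one element per sample: list(splits=character, ages=numeric).
#' @slot tipLabels Taxon labels shared by all sampled trees.
#' @slot generations Integer vector of generation indices (strictly increasing).
#' @slot runId Integer run identifier.
#' @slot info List of model/run metadata.
#' @export
setClass("Trace", representation(
  params = "data.frame",
  trees = "list",
  tipLabels = "character",
  generations = "integer",
  runId = "integer",
  info = "list"
))

setValidity("Trace", function(object) {
  msg <- character()
  if (nrow(object@params) != length(object@trees))
    msg <- c(msg, "params rows and trees must have equal length")
  if (length(object@generations) != nrow(object@params))
    msg <- c(msg, "generations must match sample count")
  if (length(object@generations) > 1 && any(diff(object@generations) <= 0))
    msg <- c(msg, "generations must be strictly increasing")
  if (length(msg)) msg else TRUE
})
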