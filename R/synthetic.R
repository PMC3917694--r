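#' Draw a time tree from the calibrated uniform tree prior
#'
#' Samples a rooted binary chronogram whose node ages follow the calibrated
#' uniform tree prior: the root age from its uniform window, calibrated
#' node ages from their calibration densities (re-drawn until jointly
#' order-feasible), and the remaining internal ages uniformly over the
#' order-constrained feasible region, by exact top-down inverse-CDF
#' sampling from the recursive subtree-volume polynomials.
#'
#' @param cals A \linkS4class{CalibrationSet}.
#' @param nTaxa Number of tips (ignored when \code{tipLabels} given).
#' @param seed Optional integer seed.
#' @param tipLabels Explicit taxon labels; must contain every calibrated
#'   clade's taxa.  Defaults to \code{t01..tNN} when no clades are named.
#' @param topology Optional fixed topology: a \linkS4class{TimeTree} whose
#'   edge matrix and labels are reused (ages ignored).
#' @return A \linkS4class{TimeTree}.
#' @export
sampleCalibratedTree <- function(cals, nTaxa = NULL, seed = NULL,
                                 tipLabels = NULL, topology = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(topology)) {
    edge <- topology@edge
    tipLabels <- topology@tipLabels
  } else {
    if (is.null(tipLabels)) {
      if (is.null(nTaxa)) stop("give nTaxa, tipLabels or a topology")
      tipLabels <- sprintf("t%02d", seq_len(nTaxa))
    }
    claded <- unlist(cals@constraints)
    if (!all(claded %in% tipLabels))
      stop("calibrated clade taxa missing from tip labels: ",
           paste(setdiff(claded, tipLabels), collapse = ", "))
    edge <- .sampleConstrainedTopology(tipLabels, cals@constraints)
  }
  n <- length(tipLabels)
  if (n < 3L) stop("need at least 3 taxa")
  topo <- .topoContext(edge, n)
  parent <- .parentVec(edge, 2L * n - 1L)
  tipSets <- .cladeTips(edge, n)
  keys <- vapply((n + 1L):(2L * n - 1L), function(v)
    .splitKey(tipLabels[tipSets[[v]]]), "")
  calNodes <- vapply(cals@nodes, function(cal) {
    id <- match(.splitKey(intersect(tipLabels, cal@clade)), keys)
    if (is.na(id)) NA_integer_ else as.integer(n + id)
  }, 0L)
  if (anyNA(calNodes))
    stop("constraint-conflict: a calibrated clade is not monophyletic in the topology")

  for (try in seq_len(1000L)) {
    rootAge <- stats::runif(1, cals@root@minAge, cals@root@maxAge)
    fixed <- rep(NA_real_, 2L * n - 1L)
    fixed[seq_len(n)] <- 0
    fixed[n + 1L] <- rootAge
    ok <- TRUE
    for (i in seq_along(calNodes)) {
      cal <- cals@nodes[[i]]
      a <- if (cal@kind == "uniform") stats::runif(1, cal@minAge, cal@maxAge)
           else cal@offset + stats::rexp(1, 1 / (cal@meanAge - cal@offset))
      if (calNodes[i] == n + 1L) { ok <- FALSE; break }  # root handled above
      fixed[calNodes[i]] <- a
    }
    if (!ok) stop("internal calibration attached to the root; use the root slot")
    S <- rootAge
    pps <- .ageVolumePPs(topo$kids, topo$postorder, n, fixed / S)
    if (.ppEval(pps[[n + 1L]], 1) <= 0) next  # order-infeasible draw
    ages <- fixed
    agesScaled <- fixed / S
    for (v in rev(topo$postorder)) {
      if (!is.na(agesScaled[v])) next
      tPar <- agesScaled[parent[v]]
      prod <- .ppMul(pps[[topo$kids[v, 1L]]], pps[[topo$kids[v, 2L]]])
      FF <- .ppIntegrate(prod)
      Fmax <- .ppEval(FF, tPar)
      if (Fmax <= 0) { agesScaled[v] <- NA; break }
      u <- stats::runif(1) * Fmax
      lo <- FF$breaks[1]
      agesScaled[v] <- stats::uniroot(function(s) .ppEval(FF, s) - u,
                                      lower = lo, upper = tPar,
                                      tol = 1e-12)$root
    }
    if (anyNA(agesScaled)) next
    ages <- agesScaled * S
    ages[seq_len(n)] <- 0
    return(timeTree(edge, tipLabels, ages))
  }
  stop("constraint-conflict: could not draw order-feasible calibrated ages")
}

#' Draw per-branch relative rates under a clock model
#'
#' Strict: every branch at relative rate 1.  IGR: independent
#' \code{Gamma(mean 1, var nu/duration)} draws.  TK02: lognormal rates with
#' expectation equal to the parent branch's rate, log-variance
#' \code{nu*duration}, evolving root-to-tips (root-adjacent branches start
#' from the base rate).
#'
#' @param clock A \linkS4class{ClockModel}.
#' @param tree A \linkS4class{TimeTree} with positive branch durations.
#' @param seed Optional integer seed.
#' @return Numeric per-edge relative rates (multiply by \code{clock@rate}
#'   for absolute rates).
#' @export
sampleBranchRates <- function(clock, tree, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dur <- branchDurations(tree)
  if (any(dur <= 0)) stop("branch durations must be positive")
  nE <- length(dur)
  switch(clock@kind,
    strict = rep(1, nE),
    IGR = {
      if (clock@nu <= 0) stop("IGR requires positive nu")
      shape <- dur / clock@nu
      stats::rgamma(nE, shape = shape, rate = shape)
    },
    TK02 = {
      if (clock@nu <= 0) stop("TK02 requires positive nu")
      n <- nTip(tree)
      edgeOfChild <- integer(2L * n - 1L)
      edgeOfChild[tree@edge[, 2L]] <- seq_len(nE)
      rates <- numeric(nE)
      ## preorder over edges: parents before children
      ord <- order(tree@ages[tree@edge[, 1L]], decreasing = TRUE)
      for (i in ord) {
        par <- tree@edge[i, 1L]
        pr <- if (par == n + 1L) 1 else rates[edgeOfChild[par]]
        v <- clock@nu * dur[i]
        rates[i] <- stats::rlnorm(1, meanlog = log(pr) - v / 2,
                                  sdlog = sqrt(v))
      }
      rates
    })
}

#' Fixture specification for forward simulation
#'
#' @param geneLengths Named integer vector of gene lengths (bp).
#' @param codingFlags Logical per gene (codon-partitioned or not).
#' @param model A \linkS4class{SubstitutionModel} shared by all partitions
#'   (or a list, one per partition).
#' @param multipliers Per-partition rate multipliers; normalised to
#'   length-weighted mean 1.  Default 1 everywhere.
#' @param readingFrames Codon position of each coding gene's first site.
#' @return A classed list; the partition scheme is attached.
#' @export
fixtureSpec <- function(geneLengths, codingFlags, model = substitutionModel(),
                        multipliers = NULL, readingFrames = NULL) {
  stopifnot(all(geneLengths > 0))
  scheme <- buildPartitionScheme(geneLengths, codingFlags, readingFrames)
  nPart <- length(scheme@sites)
  if (is.null(multipliers)) multipliers <- rep(1, nPart)
  if (length(multipliers) != nPart) stop("need one multiplier per partition")
  if (any(multipliers <= 0)) stop("multipliers must be positive")
  w <- vapply(scheme@sites, length, 0L)
  multipliers <- multipliers / sum(multipliers * w / sum(w))
  structure(list(geneLengths = geneLengths, codingFlags = codingFlags,
                 scheme = scheme, model = model, multipliers = multipliers),
            class = "FixtureSpec")
}

#' Simulate a partitioned alignment along a time tree
#'
#' Forward simulation under GTR+Gamma(4)+I: each site draws a rate category
#' (or is invariant with probability \code{pInv}), the root state comes
#' from the stationary frequencies, and states evolve down the tree with
#' branch-specific transition matrices whose lengths are
#' \code{rate * clockRate * duration * multiplier}.
#'
#' @param tree A \linkS4class{TimeTree}.
#' @param rates Per-edge relative rates (e.g. from
#'   \code{\link{sampleBranchRates}}).
#' @param spec A \code{\link{fixtureSpec}}.
#' @param clockRate Base clock rate c in subs/site/My.
#' @param seed Optional integer seed.
#' @return A \linkS4class{MultiGeneAlignment}.
#' @export
simulateAlignment <- function(tree, rates, spec, clockRate = 0.0025,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nTip(tree)
  dur <- branchDurations(tree)
  if (length(rates) != length(dur)) stop("one rate per edge required")
  scheme <- spec$scheme
  nPart <- length(scheme@sites)
  models <- if (is(spec$model, "SubstitutionModel"))
    rep(list(spec$model), nPart) else spec$model
  concat <- matrix(NA_character_, n, scheme@nSites,
                   dimnames = list(tree@tipLabels, NULL))
  nuc <- c("A", "C", "G", "T")
  ord <- order(tree@ages[tree@edge[, 1L]], decreasing = TRUE)  # preorder
  for (p in seq_len(nPart)) {
    sites <- scheme@sites[[p]]
    L <- length(sites)
    mod <- models[[p]]
    eig <- .gtrEigen(mod)
    catR <- discretizeGamma(mod@alpha, mod@nCat)
    inv <- stats::runif(L) < mod@pInv
    cat <- sample.int(mod@nCat, L, replace = TRUE)
    siteRate <- ifelse(inv, 0, catR[cat])
    states <- matrix(0L, 2L * n - 1L, L)
    states[n + 1L, ] <- sample.int(4L, L, replace = TRUE,
                                   prob = mod@baseFreqs)
    for (i in ord) {
      par <- tree@edge[i, 1L]; ch <- tree@edge[i, 2L]
      bl <- clockRate * rates[i] * dur[i] * spec$multipliers[p]
      childStates <- states[par, ]
      if (bl > 0) {
        for (k in unique(siteRate[siteRate > 0])) {
          P <- .gtrP(eig, bl * k)
          idx <- which(siteRate == k)
          for (s in 1:4) {
            ii <- idx[childStates[idx] == s]
            if (length(ii))
              childStates[ii] <- sample.int(4L, length(ii), replace = TRUE,
                                            prob = P[s, ])
          }
        }
      }
      states[ch, ] <- childStates
    }
    concat[, sites] <- matrix(nuc[states[seq_len(n), ]], n, L)
  }
  lens <- spec$geneLengths
  ends <- cumsum(lens); starts <- ends - lens + 1L
  genes <- stats::setNames(lapply(seq_along(lens), function(g)
    concat[, starts[g]:ends[g], drop = FALSE]), names(lens))
  multiGeneAlignment(genes, taxa = tree@tipLabels)
}

#' Reference seven-gene passerine fixture
#'
#' Emits a synthetic bundle emulating the reference supermatrix: seven
#' genes of lengths \code{scale * (622, 504, 419, 800, 749, 2947, 1152)}
#' (MOS, MYC, GAPDH, MB, ODC1, RAG1, RAG2; half-up rounding), codon
#' partitioning for the four coding genes (MOS, MYC, RAG1, RAG2), a root
#' calibration Uniform(52, 85) Mya, five offset-exponential fossil
#' calibrations (minima 10.4, 16.3, 16.3, 16.3, 18.0 Mya, mean 58), the
#' rooting constraint (Acanthisitta sister to all others), and the true
#' generating chronogram, clock and rates for recovery tests.
#'
#' @param scale Fraction in (0, 1] scaling every gene length.
#' @param seed Integer seed; the same seed reproduces the bundle exactly.
#' @param nTaxa Number of taxa (>= 14; default 20, scalable towards the
#'   55-taxon reference).
#' @param clock Generating \linkS4class{ClockModel} (default IGR with
#'   c = 0.0025 subs/site/My and nu = 0.1, the mean of the Exp(10)
#'   variance prior used in inference, so recovery experiments draw the
#'   generating clock from a configuration the analysis priors support).
#' @return List with elements \code{alignment}, \code{tree} (rates
#'   attached), \code{clock}, \code{calibrations}, \code{spec},
#'   \code{scheme}, \code{rates}.
#' @export
makePasserineFixture <- function(scale = 1, seed = 1L, nTaxa = 20L,
                                 clock = clockModel("IGR", rate = 0.0025,
                                                    nu = 0.1)) {
  stopifnot(scale > 0, scale <= 1, nTaxa >= 13L)
  set.seed(seed)
  full <- c(MOS = 622L, MYC = 504L, GAPDH = 419L, MB = 800L,
            ODC1 = 749L, RAG1 = 2947L, RAG2 = 1152L)
  lens <- as.integer(floor(full * scale + 0.5))  # half-up
  names(lens) <- names(full)
  coding <- c(MOS = TRUE, MYC = TRUE, GAPDH = FALSE, MB = FALSE,
              ODC1 = FALSE, RAG1 = TRUE, RAG2 = TRUE)

  nSub <- max(2L, min(round((nTaxa - 1L) * 0.3), nTaxa - 11L))
  taxa <- c("Acanthisitta", sprintf("Suboscine%02d", seq_len(nSub)))
  nOsc <- nTaxa - length(taxa)
  taxa <- c(taxa, sprintf("Oscine%02d", seq_len(nOsc)))
  osc <- grep("^Oscine", taxa, value = TRUE)
  sub <- grep("^Suboscine", taxa, value = TRUE)
  cladeNames <- c("Meliphagidae", "Orthonychidae", "Cracticidae",
                  "Oriolidae", "Certhioidea")
  offsets <- c(10.4, 16.3, 16.3, 16.3, 18.0)
  cals <- list()
  for (i in seq_along(cladeNames))
    cals[[cladeNames[i]]] <- offsetExpCalibration(offsets[i], 58,
                                                  clade = osc[(2 * i - 1):(2 * i)])
  calset <- calibrationSet(
    root = uniformCalibration(52, 85),
    nodes = cals,
    constraints = list(Passeres = setdiff(taxa, "Acanthisitta"),
                       Suboscines = sub, Oscines = osc))

  tree <- sampleCalibratedTree(calset, tipLabels = taxa)
  rates <- sampleBranchRates(clock, tree)
  tree@rates <- rates

  mult <- numeric(0)
  model <- substitutionModel(
    exchangeabilities = c(1.3, 5.4, 0.9, 1.1, 6.8, 1.0),
    baseFreqs = c(0.28, 0.22, 0.23, 0.27), alpha = 0.45, pInv = 0.2)
  sp0 <- buildPartitionScheme(lens, coding)
  mult <- vapply(seq_len(nrow(sp0@table)), function(i) {
    id <- sp0@table$partition[i]
    if (grepl("_pos3$", id)) 2.5 else if (grepl("_pos12$", id)) 0.4 else 1.3
  }, 0)
  spec <- fixtureSpec(lens, coding, model = model, multipliers = mult)
  aln <- simulateAlignment(tree, rates, spec, clockRate = clock@rate)
  list(alignment = aln, tree = tree, rates = rates, clock = clock,
       calibrations = calset, spec = spec, scheme = spec$scheme)
}
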