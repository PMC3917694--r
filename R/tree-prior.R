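## ---- piecewise polynomials --------------------------------------------
## f(t) = 0 for t < breaks[1]; on [breaks[i], breaks[i+1]) a polynomial in
## (t - breaks[i]) with coefficients coefs[[i]] (ascending powers).  The
## last piece extends to +Inf.  Local shifted bases keep the coefficients
## well-conditioned; node ages are rescaled to O(1) before use.

.ppStep <- function(a, value = 1)
  list(breaks = a, coefs = list(value))

.polyHorner <- function(coef, x) {
  out <- 0
  for (j in rev(seq_along(coef))) out <- out * x + coef[j]
  out
}

.ppEval <- function(f, t) {
  vapply(t, function(tt) {
    if (tt < f$breaks[1]) return(0)
    j <- findInterval(tt, f$breaks)
    .polyHorner(f$coefs[[j]], tt - f$breaks[j])
  }, 0)
}

## coefficients of p(x + delta) given those of p(x)
.polyShift <- function(coef, delta) {
  d <- length(coef)
  if (d == 1L || delta == 0) return(coef)
  out <- numeric(d)
  pow <- 1
  ## out_k = sum_j choose(j, k) c_j delta^(j-k)
  for (k in seq_len(d)) {
    j <- k:d
    out[k] <- sum(coef[j] * choose(j - 1L, k - 1L) * delta^(j - k))
  }
  out
}

.polyMul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

.ppMul <- function(f, g) {
  start <- max(f$breaks[1], g$breaks[1])
  br <- sort(unique(c(start, f$breaks[f$breaks > start],
                      g$breaks[g$breaks > start])))
  coefs <- vector("list", length(br))
  for (i in seq_along(br)) {
    jf <- findInterval(br[i], f$breaks)
    jg <- findInterval(br[i], g$breaks)
    cf <- .polyShift(f$coefs[[jf]], br[i] - f$breaks[jf])
    cg <- .polyShift(g$coefs[[jg]], br[i] - g$breaks[jg])
    coefs[[i]] <- .polyMul(cf, cg)
  }
  list(breaks = br, coefs = coefs)
}

## antiderivative with F(breaks[1]) = 0, continuous across pieces
.ppIntegrate <- function(f) {
  k <- length(f$breaks)
  coefs <- vector("list", k)
  C <- 0
  for (i in seq_len(k)) {
    ci <- f$coefs[[i]]
    anti <- c(C, ci / seq_along(ci))
    coefs[[i]] <- anti
    if (i < k) C <- .polyHorner(anti, f$breaks[i + 1L] - f$breaks[i])
  }
  list(breaks = f$breaks, coefs = coefs)
}

## ---- subtree age-volume recursion -------------------------------------
## Given fixed (scaled) ages for tips, calibrated nodes and the root (NA
## for free internal nodes), compute for every node v the function
## V_v(t) = volume of order-consistent assignments of the free ages in v's
## subtree, all younger than t.  Tips and fixed nodes contribute step
## functions; a free node integrates the product of its children.

.ageVolumePPs <- function(kids, postorder, nTip, fixedAges) {
  nNode <- 2L * nTip - 1L
  pps <- vector("list", nNode)
  for (i in seq_len(nTip)) pps[[i]] <- .ppStep(fixedAges[i], 1)
  for (v in postorder) {
    prod <- .ppMul(pps[[kids[v, 1L]]], pps[[kids[v, 2L]]])
    if (is.na(fixedAges[v])) {
      pps[[v]] <- .ppIntegrate(prod)
    } else {
      val <- .ppEval(prod, fixedAges[v])
      ## a fixed node's own age must clear its subtree: val = 0 otherwise
      pps[[v]] <- .ppStep(fixedAges[v], val)
    }
  }
  pps
}

## log feasible-region volume for free internal ages, given fixed root and
## calibrated ages (unscaled input; rescaled internally).  Returns -Inf
## when the configuration is infeasible.
.ageLogVolume <- function(kids, postorder, nTip, fixedAges) {
  root <- nTip + 1L
  S <- fixedAges[root]
  if (is.na(S) || S <= 0) stop("root age must be fixed and positive")
  k <- sum(is.na(fixedAges))
  lv <- cpp_age_log_volume(postorder, kids, nTip, fixedAges / S)
  if (!is.finite(lv)) return(-Inf)
  lv + k * log(S)
}

## map constraint clades to tree nodes; NA where not monophyletic
.matchCladeNodes <- function(tree, clades) {
  keys <- treeSplits(tree)
  vapply(clades, function(cl)
    {
      k <- .splitKey(intersect(tree@tipLabels, cl))
      id <- names(keys)[match(k, keys)]
      if (is.na(id)) NA_integer_ else as.integer(id)
    }, 0L)
}

#' Does a tree satisfy a set of monophyly constraints?
#'
#' @param tree A \linkS4class{TimeTree}.
#' @param constraints List of taxon-label vectors.
#' @return Logical: every constraint clade is monophyletic in the tree.
#' @export
satisfiesConstraints <- function(tree, constraints) {
  if (!length(constraints)) return(TRUE)
  !anyNA(.matchCladeNodes(tree, constraints))
}

#' Log-density of the calibrated uniform tree prior
#'
#' The joint prior on node ages is the root calibration density times the
#' internal calibration densities times a uniform density over the
#' order-constrained feasible region of the remaining (free) node ages,
#' conditional on the root and calibrated ages.  The feasible-region
#' volume is computed exactly by recursive piecewise-polynomial
#' integration over the tree, so the conditional density is properly
#' normalised.  Trees violating a monophyly constraint, a calibration's
#' hard bound, or parent-older-than-child ordering score \code{-Inf}.
#'
#' @param tree A \linkS4class{TimeTree}.
#' @param cals A \linkS4class{CalibrationSet}.
#' @return Log prior density of the tree's node ages.
#' @export
treeAgeLogPrior <- function(tree, cals) {
  n <- nTip(tree)
  ages <- tree@ages
  if (any(ages[tree@edge[, 1L]] <= ages[tree@edge[, 2L]])) return(-Inf)
  if (!satisfiesConstraints(tree, cals@constraints)) return(-Inf)
  lp <- calibrationLogDensity(cals@root, ages[n + 1L])
  if (!is.finite(lp)) return(-Inf)
  fixed <- rep(NA_real_, 2L * n - 1L)
  fixed[seq_len(n)] <- ages[seq_len(n)]
  fixed[n + 1L] <- ages[n + 1L]
  for (cal in cals@nodes) {
    v <- .matchCladeNodes(tree, list(cal@clade))
    if (is.na(v)) return(-Inf)
    if (v != n + 1L) {
      d <- calibrationLogDensity(cal, ages[v])
      if (!is.finite(d)) return(-Inf)
      lp <- lp + d
      fixed[v] <- ages[v]
    }
  }
  topo <- .topoContext(tree@edge, n)
  lv <- .ageLogVolume(topo$kids, topo$postorder, n, fixed)
  if (!is.finite(lv)) return(-Inf)
  lp - lv
}
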