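#' Discrete-gamma category rates
#'
#' Splits a Gamma(alpha, alpha) density (mean 1) into \code{nCat}
#' equal-probability bins and returns the mean rate of each bin, rescaled
#' so the category mean is exactly 1.  This is the mean-of-bin rule (not
#' the median rule).
#'
#' @param alpha Gamma shape, > 0.
#' @param nCat Number of categories (default 4).
#' @return Numeric vector of \code{nCat} category rates with mean 1.
#' @examples
#' discretizeGamma(0.5)
#' @export
discretizeGamma <- function(alpha, nCat = 4L) {
  stopifnot(alpha > 0, nCat >= 1L)
  if (nCat == 1L) return(1)
  ## mean of Gamma(a, a) over the quantile bin [q_{k-1}, q_k], prob 1/nCat:
  ## nCat * (F_{a+1}(q_k) - F_{a+1}(q_{k-1})) using the incomplete-gamma identity
  q <- stats::qgamma(seq(0, 1, length.out = nCat + 1L), shape = alpha, rate = alpha)
  Fup <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
  r <- nCat * diff(Fup)
  r / mean(r)
}

## GTR rate matrix, rows A C G T, normalised so mean rate at stationarity = 1
.gtrQ <- function(model) {
  ex <- model@exchangeabilities
  pi <- model@baseFreqs
  Q <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  pairs <- rbind(c(1,2), c(1,3), c(1,4), c(2,3), c(2,4), c(3,4))
  for (k in 1:6) {
    i <- pairs[k,1]; j <- pairs[k,2]
    Q[i,j] <- ex[k] * pi[j]
    Q[j,i] <- ex[k] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

## Eigen-decomposition of the (reversible) GTR generator via the symmetric
## similarity transform; returns U, Uinv, lambda with Q = U diag(lambda) Uinv
.gtrEigen <- function(model) {
  Q <- .gtrQ(model)
  pi <- model@baseFreqs
  D <- diag(sqrt(pi)); Dinv <- diag(1 / sqrt(pi))
  S <- D %*% Q %*% Dinv
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  list(U = Dinv %*% es$vectors, Uinv = t(es$vectors) %*% D,
       lambda = es$values)
}

## transition probability matrix P(t) for one branch length (subs/site)
.gtrP <- function(eig, t) {
  P <- eig$U %*% (exp(eig$lambda * t) * eig$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

## ---- nucleotide coding -------------------------------------------------
## states coded as 4-bit masks: A=1, C=2, G=4, T=8; '?' and '-' = 15

.iupacMask <- local({
  m <- c(A=1L, C=2L, G=4L, T=8L, U=8L,
         R=5L, Y=10L, S=6L, W=9L, K=12L, M=3L,
         B=14L, D=13L, H=11L, V=7L, N=15L, "?"=15L, "-"=15L, "X"=15L)
  m
})

## character matrix -> integer mask matrix
.encodeMatrix <- function(m) {
  v <- .iupacMask[toupper(m)]
  if (anyNA(v)) {
    bad <- unique(toupper(m)[is.na(v)])
    stop("unknown nucleotide code(s): ", paste(bad, collapse = ", "))
  }
  matrix(as.integer(v), nrow = nrow(m), dimnames = dimnames(m))
}

## ---- pattern compression ----------------------------------------------
## Collapse identical columns; returns patterns (nTaxa x nPat mask matrix)
## and weights.  Exact: identical columns share computation.
.compressPatterns <- function(maskMatrix) {
  key <- apply(maskMatrix, 2L, paste, collapse = ",")
  tab <- table(factor(key, levels = unique(key)))
  firsts <- match(names(tab), key)
  list(patterns = maskMatrix[, firsts, drop = FALSE],
       weights = as.numeric(tab))
}

## Prepared likelihood data for one partition: mask patterns ordered by the
## tree's tip order, plus weights.
.preparePartitionData <- function(aln, sites, tipOrder) {
  concat <- do.call(cbind, aln@genes)
  sub <- concat[tipOrder, sites, drop = FALSE]
  cp <- .compressPatterns(.encodeMatrix(sub))
  cp
}
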