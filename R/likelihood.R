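## ---- likelihood contexts ----------------------------------------------
## A context freezes everything about tree shape and data that does not
## change between likelihood evaluations: compressed site patterns per
## partition (ordered by the tree's tips) and the postorder traversal.

.topoContext <- function(edge, nTip) {
  nNode <- 2L * nTip - 1L
  kids <- matrix(0L, nNode, 2L)
  for (i in seq_len(nrow(edge))) {
    v <- edge[i, 1L]
    kids[v, if (kids[v, 1L] == 0L) 1L else 2L] <- edge[i, 2L]
  }
  list(postorder = .postorderNodes(edge, nTip), kids = kids)
}

.likContext <- function(aln, scheme, tipOrder) {
  if (!all(tipOrder %in% aln@taxa))
    stop("tree tips not all present in alignment: ",
         paste(setdiff(tipOrder, aln@taxa), collapse = ", "))
  pats <- lapply(scheme@sites, function(s)
    .preparePartitionData(aln, s, tipOrder))
  list(patterns = lapply(pats, `[[`, "patterns"),
       weights = lapply(pats, `[[`, "weights"),
       nPart = length(pats),
       partLengths = vapply(scheme@sites, length, 0L))
}

## model tables (eigen + category rates) for a list of SubstitutionModel
.modelTables <- function(models) {
  eigs <- lapply(models, .gtrEigen)
  list(Us = lapply(eigs, `[[`, "U"),
       Uinvs = lapply(eigs, `[[`, "Uinv"),
       lambdas = lapply(eigs, `[[`, "lambda"),
       catRates = vapply(models, function(m) discretizeGamma(m@alpha, m@nCat),
                         numeric(models[[1]]@nCat)),
       pinv = vapply(models, function(m) m@pInv, 0),
       freqs = vapply(models, function(m) m@baseFreqs, numeric(4)))
}

## Core evaluation: lenByNode is (2n-1) x nPart of substitution branch
## lengths for the edge above each node; partIdx selects partitions.
.evalLoglik <- function(nTip, topo, lenByNode, ctx, tabs, partIdx = NULL) {
  if (is.null(partIdx)) partIdx <- seq_len(ctx$nPart)
  cpp_partition_loglik(nTip, topo$postorder, topo$kids, lenByNode,
                       ctx$patterns, ctx$weights,
                       tabs$Us, tabs$Uinvs, tabs$lambdas,
                       tabs$catRates, tabs$pinv, tabs$freqs,
                       as.integer(partIdx))
}

.checkRootedBinary <- function(phy) {
  n <- length(phy$tip.label)
  if (phy$Nnode != n - 1L)
    stop("tree must be rooted and binary")
  if (any(phy$edge.length < 0)) stop("negative branch lengths")
  invisible(n)
}

#' Phylogenetic log-likelihood under GTR+Gamma+I
#'
#' Felsenstein pruning over compressed site patterns, with per-node
#' rescaling so large trees do not underflow.  Branch lengths are expected
#' substitutions per site.  Gap and '?' characters are treated as missing;
#' IUPAC ambiguity codes contribute partial likelihood over their
#' compatible states.
#'
#' @param phy Rooted binary \code{phylo} with branch lengths in
#'   substitutions/site.
#' @param model A \linkS4class{SubstitutionModel}.
#' @param aln A \linkS4class{MultiGeneAlignment} (all genes concatenated).
#' @param sites Optional global site indices restricting the computation.
#' @return The log-likelihood (a single number).
#' @examples
#' aln <- multiGeneAlignment(list(g = matrix(c("A","A","T","T"), 2, 2,
#'   dimnames = list(c("a","b"), NULL))))
#' phy <- ape::read.tree(text = "(a:0.05,b:0.05);")
#' phy <- ape::collapse.singles(phy)
#' @export
logLikelihood <- function(phy, model, aln, sites = NULL) {
  concat <- do.call(cbind, aln@genes)
  if (!is.null(sites)) concat <- concat[, sites, drop = FALSE]
  aln_sub <- new("MultiGeneAlignment", taxa = aln@taxa,
                 genes = list(all = concat))
  scheme <- new("PartitionScheme",
                table = data.frame(partition = "all", gene = "all",
                                   multiplierIndex = 1L),
                sites = list(seq_len(ncol(concat))), nSites = ncol(concat))
  as.numeric(partitionedLogLikelihood(phy, list(model), 1, aln_sub, scheme))
}

#' Partitioned log-likelihood with rate multipliers
#'
#' Sums per-partition pruning log-likelihoods with each partition's branch
#' lengths scaled by its rate multiplier; substitution models are unlinked
#' across partitions (pass a list of one model per partition, or a single
#' model to share).
#'
#' @param phy Rooted binary \code{phylo}, branch lengths in subs/site.
#' @param models List of \linkS4class{SubstitutionModel}, length 1 or nPart.
#' @param multipliers Positive per-partition rate multipliers.
#' @param aln A \linkS4class{MultiGeneAlignment}.
#' @param scheme A \linkS4class{PartitionScheme} covering the alignment.
#' @return Total log-likelihood, with attribute \code{"byPartition"}.
#' @export
partitionedLogLikelihood <- function(phy, models, multipliers, aln, scheme) {
  n <- .checkRootedBinary(phy)
  nPart <- length(scheme@sites)
  if (length(multipliers) == 1L) multipliers <- rep(multipliers, nPart)
  if (length(multipliers) != nPart)
    stop("multipliers must have one entry per partition")
  if (any(multipliers <= 0)) stop("multipliers must be positive")
  if (length(models) == 1L) models <- rep(models, nPart)
  if (length(models) != nPart) stop("need one model per partition")
  ctx <- .likContext(aln, scheme, phy$tip.label)
  topo <- .topoContext(phy$edge, n)
  tabs <- .modelTables(models)
  lenNode <- numeric(2L * n - 1L)
  lenNode[phy$edge[, 2L]] <- phy$edge.length
  lenByNode <- outer(lenNode, multipliers)
  ll <- .evalLoglik(n, topo, lenByNode, ctx, tabs)
  structure(sum(ll), byPartition = ll)
}
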