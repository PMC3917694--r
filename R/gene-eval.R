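#' Kendall's tau-b between gene and combined node-age medians
#'
#' Rank correlation (tie-corrected tau-b) of divergence-time medians over
#' the nodes matched between a single-gene and the combined analysis.
#' The two-sided p-value is exact for small samples without ties and uses
#' the normal approximation otherwise (the behaviour of
#' \code{stats::cor.test}).
#'
#' @param geneMedians,combinedMedians Numeric vectors over matched nodes.
#' @return List with \code{tau} and \code{p}.
#' @export
kendallTau <- function(geneMedians, combinedMedians) {
  if (length(geneMedians) < 2L || length(geneMedians) != length(combinedMedians))
    stop("need at least 2 matched nodes in both vectors")
  ct <- suppressWarnings(stats::cor.test(geneMedians, combinedMedians,
                                         method = "kendall"))
  list(tau = unname(ct$estimate), p = ct$p.value)
}

#' Per-gene credibility-interval width table
#'
#' Widths (upper minus lower bound of the 95% CI) per node for each gene's
#' summary table, with per-gene means taken over the nodes that gene
#' actually recovered (missing nodes are excluded from that gene's mean).
#'
#' @param geneSummaries Named list of node-age tables (one per gene, as
#'   from \code{\link{nodeAgeTable}}, possibly with NA rows for missing
#'   nodes).
#' @return List with \code{widths} (data.frame node x gene) and
#'   \code{means} (named per-gene mean width).
#' @export
ciWidthTable <- function(geneSummaries) {
  splits <- unique(unlist(lapply(geneSummaries, function(s) s$split)))
  W <- sapply(geneSummaries, function(s)
    s$width[match(splits, s$split)])
  W <- matrix(W, nrow = length(splits),
              dimnames = list(splits, names(geneSummaries)))
  list(widths = as.data.frame(W),
       means = colMeans(W, na.rm = TRUE))
}

#' Kruskal-Wallis rank test on CI-width groups
#'
#' One group of interval widths per gene; returns the tie-corrected H
#' statistic and its chi-square p-value on k-1 degrees of freedom.
#' All-identical observations give H = 0.
#'
#' @param groups List of numeric vectors (one per gene).
#' @return List with \code{H}, \code{df}, \code{p}.
#' @examples
#' kruskalWallis(list(c(1, 2), c(3, 4)))  # H = 2.4
#' @export
kruskalWallis <- function(groups) {
  if (length(groups) < 2L || any(vapply(groups, length, 0L) < 1L))
    stop("need >= 2 groups with >= 1 observation each")
  x <- unlist(groups)
  if (length(unique(x)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(x, factor(rep(seq_along(groups),
                                          vapply(groups, length, 0L))))
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Overlap of per-gene credibility intervals at a node
#'
#' Pairwise overlap is the length of the intersection divided by the
#' length of the union (0 for disjoint, 1 for identical intervals); the
#' joint flag records whether all intervals share a common intersection.
#'
#' @param intervals List (or 2-column matrix) of (lower, upper) pairs.
#' @return List with \code{pairwise} (matrix) and \code{joint} (logical).
#' @export
ciOverlap <- function(intervals) {
  if (is.matrix(intervals))
    intervals <- split(intervals, row(intervals))
  k <- length(intervals)
  if (k < 2L) stop("need at least two intervals")
  lo <- vapply(intervals, `[`, 0, 1)
  up <- vapply(intervals, `[`, 0, 2)
  M <- matrix(1, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    inter <- max(0, min(up[i], up[j]) - max(lo[i], lo[j]))
    uni <- max(up[i], up[j]) - min(lo[i], lo[j])
    M[i, j] <- if (uni > 0) inter / uni else 1
  }
  dimnames(M) <- list(names(intervals), names(intervals))
  list(pairwise = M, joint = max(lo) < min(up) ||
         isTRUE(all.equal(max(lo), min(up))))
}

#' Match a gene's nodes against the combined consensus
#'
#' Nodes are matched by taxon bipartition; combined-consensus nodes absent
#' from the gene analysis form the missing set (a gene not recovering a
#' node is itself informative).
#'
#' @param geneSummary Node-age table from the single-gene analysis.
#' @param combinedSummary Node-age table from the combined analysis.
#' @param gene Gene name carried through to the output.
#' @return List with \code{gene}, \code{matched} (merged data.frame with
#'   gene and combined medians/CIs) and \code{missing} (split keys).
#' @export
geneComparison <- function(geneSummary, combinedSummary, gene = "gene") {
  m <- merge(combinedSummary, geneSummary, by = "split",
             suffixes = c(".combined", ".gene"))
  m <- m[is.finite(m$median.gene), , drop = FALSE]
  missing <- setdiff(combinedSummary$split, m$split)
  list(gene = gene, matched = m, missing = missing)
}

#' Saturation table: pairwise p-distance against MRCA age
#'
#' For every pair of taxa, pairs the median age of their most recent
#' common ancestor in the combined chronogram with their uncorrected
#' p-distance in one gene; a flattening of distance against age at large
#' ages indicates substitutional saturation.
#'
#' @param aln A \linkS4class{MultiGeneAlignment}.
#' @param gene Gene name within \code{aln}.
#' @param tree Combined-analysis \linkS4class{TimeTree} with median ages.
#' @return data.frame: taxonA, taxonB, age, pDistance.
#' @export
saturationTable <- function(aln, gene, tree) {
  m <- aln@genes[[gene]]
  if (is.null(m)) stop("unknown gene: ", gene)
  labs <- intersect(aln@taxa, tipLabels(tree))
  skipped <- setdiff(aln@taxa, labs)
  if (length(skipped))
    warning("taxa missing from chronogram skipped: ",
            paste(skipped, collapse = ", "))
  n <- nTip(tree)
  tipSets <- .cladeTips(tree@edge, n)
  idx <- match(labs, tipLabels(tree))
  out <- NULL
  for (i in seq_along(labs)) for (j in seq_len(i - 1L)) {
    ## MRCA: smallest clade containing both tips
    cand <- which(vapply(tipSets, function(s)
      all(c(idx[i], idx[j]) %in% s), TRUE))
    mrca <- cand[which.min(vapply(cand, function(v) length(tipSets[[v]]), 0L))]
    out <- rbind(out, data.frame(
      taxonA = labs[i], taxonB = labs[j],
      age = tree@ages[mrca],
      pDistance = suppressWarnings(pDistance(m, labs[i], labs[j]))))
  }
  out
}

#' Rate-based root-age back-calculation
#'
#' Converts a tree height in substitutions per site (from the combined
#' analysis) into a root age using an externally estimated gene-specific
#' substitution rate: \code{age = height * multiplier / rate}, with the
#' uncertainty interval propagated from the rate interval's endpoints.
#'
#' @param treeHeightSubs Tree height in substitutions/site.
#' @param geneMultiplier The gene's partition rate multiplier.
#' @param rate Substitution rate in subs/site/My (> 0).
#' @param rateInterval Optional (lower, upper) rate interval.
#' @return List with \code{age} (My) and, when an interval is given,
#'   \code{lower} and \code{upper}.
#' @examples
#' rateBasedRootAge(0.5, 1, 0.01)  # 50 My
#' @export
rateBasedRootAge <- function(treeHeightSubs, geneMultiplier, rate,
                             rateInterval = NULL) {
  stopifnot(treeHeightSubs > 0, geneMultiplier > 0)
  if (rate <= 0) stop("rate must be positive")
  out <- list(age = treeHeightSubs * geneMultiplier / rate)
  if (!is.null(rateInterval)) {
    if (any(rateInterval <= 0)) stop("rate interval must be positive")
    ages <- treeHeightSubs * geneMultiplier / rateInterval
    out$lower <- min(ages); out$upper <- max(ages)
  }
  out
}
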