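#' Pool samples from independent runs
#'
#' Removes the burn-in fraction from each run and concatenates the
#' remaining samples; provenance (run id per sample) is retained in the
#' \code{run} column.
#'
#' @param traces List of \linkS4class{Trace} objects from the same model.
#' @param burnIn Fraction of each run's samples to discard (default 0.25).
#' @return A pooled \linkS4class{Trace} (runId 0).
#' @export
concatRuns <- function(traces, burnIn = 0.25) {
  if (!length(traces)) stop("need at least one trace")
  labs <- traces[[1]]@tipLabels
  for (tr in traces) if (!setequal(tr@tipLabels, labs))
    stop("incompatible taxa across runs")
  pieces <- lapply(traces, function(tr) {
    n <- nrow(tr@params)
    keep <- seq_len(n) > floor(burnIn * n)
    p <- tr@params[keep, , drop = FALSE]
    p$run <- tr@runId
    list(params = p, trees = tr@trees[keep])
  })
  params <- do.call(rbind, lapply(pieces, `[[`, "params"))
  rownames(params) <- NULL
  trees <- do.call(c, lapply(pieces, `[[`, "trees"))
  new("Trace", params = params, trees = trees, tipLabels = labs,
      generations = seq_len(nrow(params)), runId = 0L,
      info = list(pooledFrom = length(traces), burnIn = burnIn))
}

## split frequency table of a trace: named numeric of frequencies
.splitFreqs <- function(trace) {
  n <- length(trace@trees)
  tab <- table(unlist(lapply(trace@trees, `[[`, "splits")))
  tab / n
}

#' Majority-rule consensus topology with split posterior probabilities
#'
#' Splits with frequency above 0.5 (mutually compatible by construction)
#' define the consensus; each retained split's posterior probability is
#' its sample frequency.  Splits at or below the threshold are not added,
#' so the consensus may be unresolved.
#'
#' @param trace A (pooled) \linkS4class{Trace}.
#' @return data.frame with columns \code{split} (taxon labels joined by
#'   "|") and \code{pp}, ordered by decreasing clade size; includes the
#'   root split with pp 1.
#' @export
majorityConsensus <- function(trace) {
  if (!length(trace@trees)) stop("empty trace")
  f <- .splitFreqs(trace)
  keep <- f[f > 0.5]
  size <- vapply(strsplit(names(keep), "\\|"), length, 0L)
  out <- data.frame(split = names(keep), pp = as.numeric(keep))
  out[order(-size), , drop = FALSE]
}

#' Node-age summary for one split
#'
#' Collects the age of the split's node from exactly those samples that
#' contain the split, and reports the mean, median and central 95%
#' credibility interval (2.5 and 97.5 percentiles with linear
#' interpolation between order statistics).
#'
#' @param trace A (pooled) \linkS4class{Trace}.
#' @param split Either a split key (labels joined by "|") or a character
#'   vector of taxon labels.
#' @return data.frame row: split, pp, mean, median, lower, upper, width;
#'   or NA fields (with pp 0) when the split is absent from every sample.
#' @export
nodeAgeSummary <- function(trace, split) {
  if (length(split) > 1L) split <- .splitKey(split)
  ages <- unlist(lapply(trace@trees, function(tr) {
    i <- match(split, tr$splits)
    if (is.na(i)) NULL else tr$ages[i]
  }))
  if (!length(ages))
    return(data.frame(split = split, pp = 0, mean = NA_real_,
                      median = NA_real_, lower = NA_real_, upper = NA_real_,
                      width = NA_real_))
  q <- stats::quantile(ages, c(0.025, 0.975), names = FALSE, type = 7)
  data.frame(split = split, pp = length(ages) / length(trace@trees),
             mean = mean(ages), median = stats::median(ages),
             lower = q[1], upper = q[2], width = q[2] - q[1])
}

#' Node-age table for every consensus split
#'
#' @param trace A (pooled) \linkS4class{Trace}.
#' @param consensus Optional consensus table (default
#'   \code{\link{majorityConsensus}} of the trace).
#' @return data.frame, one \code{\link{nodeAgeSummary}} row per split.
#' @export
nodeAgeTable <- function(trace, consensus = majorityConsensus(trace)) {
  out <- do.call(rbind, lapply(consensus$split, nodeAgeSummary,
                               trace = trace))
  rownames(out) <- NULL
  out
}

## build a (possibly multifurcating) rooted tree from compatible splits;
## returns list(edge, tipLabels, nodeSplit = split key per internal node)
.treeFromSplits <- function(splitKeys, tipLabelsAll) {
  sets <- lapply(strsplit(splitKeys, "\\|"), sort)
  full <- sort(tipLabelsAll)
  if (!any(vapply(sets, identical, TRUE, full)))  {
    sets <- c(list(full), sets)
    splitKeys <- c(.splitKey(full), splitKeys)
  }
  ord <- order(-vapply(sets, length, 0L))
  sets <- sets[ord]; splitKeys <- splitKeys[ord]
  nT <- length(tipLabelsAll)
  nInt <- length(sets)
  tipId <- stats::setNames(seq_len(nT), tipLabelsAll)
  intId <- nT + seq_len(nInt)
  ## parent of each internal node: smallest strictly-containing set
  parentInt <- rep(NA_integer_, nInt)
  for (i in seq_len(nInt)) {
    best <- NA_integer_
    for (j in seq_len(nInt)) {
      if (i == j) next
      if (length(sets[[j]]) > length(sets[[i]]) &&
          all(sets[[i]] %in% sets[[j]])) {
        if (is.na(best) || length(sets[[j]]) < length(sets[[best]])) best <- j
      }
    }
    parentInt[i] <- best
  }
  edges <- NULL
  for (i in seq_len(nInt)) if (!is.na(parentInt[i]))
    edges <- rbind(edges, c(intId[parentInt[i]], intId[i]))
  ## each tip attaches to the smallest set containing it
  for (t in seq_len(nT)) {
    lab <- tipLabelsAll[t]
    cand <- which(vapply(sets, function(s) lab %in% s, TRUE))
    best <- cand[which.min(vapply(cand, function(j) length(sets[[j]]), 0L))]
    edges <- rbind(edges, c(intId[best], tipId[[lab]]))
  }
  list(edge = edges, tipLabels = tipLabelsAll,
       nodeSplit = stats::setNames(splitKeys, intId))
}

#' Write an annotated consensus chronogram
#'
#' Produces a NEXUS file with a trees block whose single Newick tree has
#' branch lengths in My (from median node ages) and node comments carrying
#' the posterior probability, median age and 95% CI bounds
#' (\code{[&pp=..,median=..,lower=..,upper=..]}).  Round-trips through
#' \code{\link{readChronogram}}.
#'
#' @param consensus Consensus table from \code{\link{majorityConsensus}}.
#' @param summaries Node-age table from \code{\link{nodeAgeTable}} sharing
#'   the consensus splits.
#' @param path Output file.
#' @param tipLabelsAll All taxon labels.
#' @return Invisibly, \code{path}.
#' @export
writeChronogram <- function(consensus, summaries, path, tipLabelsAll) {
  tr <- .treeFromSplits(consensus$split, tipLabelsAll)
  n <- length(tipLabelsAll)
  nMax <- max(tr$edge)
  ch <- .childrenList(tr$edge, nMax)
  med <- stats::setNames(summaries$median, summaries$split)
  anno <- nrow(summaries) > 0 && !all(is.na(summaries$median))
  rows <- stats::setNames(seq_len(nrow(summaries)), summaries$split)
  ages <- numeric(nMax)
  assign_age <- function(v, parentAge) {
    if (v <= n) { ages[v] <<- 0; return(invisible()) }
    key <- tr$nodeSplit[[as.character(v)]]
    a <- if (!is.null(key) && key %in% names(med) && is.finite(med[[key]]))
      med[[key]] else if (is.na(parentAge)) 1 else parentAge * 0.9
    if (!is.na(parentAge)) a <- min(a, parentAge * 0.999)
    ages[v] <<- a
    for (cc in ch[[v]]) assign_age(cc, a)
  }
  rootId <- n + 1L
  assign_age(rootId, NA_real_)
  rec <- function(v, parentAge) {
    if (v <= n) {
      lbl <- tr$tipLabels[v]
      return(if (anno) sprintf("%s:%s", lbl, format(parentAge, digits = 10))
             else lbl)
    }
    kids <- vapply(ch[[v]], rec, "", parentAge = ages[v])
    key <- tr$nodeSplit[[as.character(v)]]
    cmt <- ""
    if (anno && !is.null(key) && key %in% names(rows)) {
      s <- summaries[rows[[key]], ]
      cmt <- sprintf("[&pp=%s,median=%s,lower=%s,upper=%s]",
                     format(s$pp, digits = 10), format(s$median, digits = 10),
                     format(s$lower, digits = 10), format(s$upper, digits = 10))
    }
    bl <- if (!is.na(parentAge) && anno)
      sprintf(":%s", format(parentAge - ages[v], digits = 10)) else ""
    sprintf("(%s)%s%s", paste(kids, collapse = ","), cmt, bl)
  }
  newick <- paste0(rec(rootId, NA_real_), ";")
  writeLines(c("#NEXUS", "begin trees;",
               paste0("  tree CONSENSUS = ", newick), "end;"), path)
  invisible(path)
}

#' Read an annotated chronogram written by \code{\link{writeChronogram}}
#'
#' @param path NEXUS file produced by \code{\link{writeChronogram}}.
#' @return List with \code{tree} (a \linkS4class{TimeTree} with median
#'   ages) and \code{summaries} (data.frame split/pp/median/lower/upper).
#' @export
readChronogram <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tl <- grep("tree\\s+\\S+\\s*=", lines, value = TRUE)[1]
  if (is.na(tl)) stop("no tree line found in ", path)
  newick <- sub("^.*?=\\s*", "", tl)
  ## pull comments out, keyed by a placeholder
  cmts <- list()
  repeat {
    m <- regexpr("\\[&[^]]*\\]", newick)
    if (m < 0) break
    cmts[[length(cmts) + 1L]] <- substr(newick, m + 2L,
                                        m + attr(m, "match.length") - 2L)
    tag <- sprintf("__C%d__", length(cmts))
    newick <- paste0(substr(newick, 1, m - 1L), tag,
                     substr(newick, m + attr(m, "match.length"), nchar(newick)))
  }
  phy <- ape::read.tree(text = newick)
  n <- length(phy$tip.label)
  tipSets <- .cladeTips(phy$edge, n)
  lab <- phy$node.label
  rows <- NULL
  for (i in seq_along(lab)) {
    if (is.null(lab[i]) || !nzchar(lab[i])) next
    mm <- regmatches(lab[i], regexpr("\\d+", lab[i]))
    if (!length(mm)) next
    kv <- strsplit(strsplit(cmts[[as.integer(mm)]], ",")[[1]], "=")
    vals <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                            vapply(kv, `[`, "", 1))
    rows <- rbind(rows,
      data.frame(split = .splitKey(phy$tip.label[tipSets[[n + i]]]),
                 pp = vals[["pp"]], median = vals[["median"]],
                 lower = vals[["lower"]], upper = vals[["upper"]]))
  }
  tt <- if (phy$Nnode == n - 1L && !is.null(phy$edge.length))
    tryCatch(asTimeTree(phy), error = function(e) NULL) else NULL
  list(tree = tt, phylo = phy, summaries = rows)
}
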