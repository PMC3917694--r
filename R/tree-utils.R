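#' @rdname TimeTree-accessors
#' @param object,x A \linkS4class{TimeTree}.
#' @export
setGeneric("nTip", function(x) standardGeneric("nTip"))

#' Accessors for TimeTree objects
#'
#' \code{nTip} returns the number of tips; \code{tipLabels} the taxon
#' labels; \code{nodeAges} the 2n-1 node ages (Mya); \code{branchDurations}
#' the per-edge durations (My); \code{branchRates} the per-edge relative
#' rates (or NULL when unset); \code{rootAge} the age of the root.
#'
#' @name TimeTree-accessors
#' @export
setMethod("nTip", "TimeTree", function(x) length(x@tipLabels))

#' @rdname TimeTree-accessors
#' @export
setGeneric("tipLabels", function(x) standardGeneric("tipLabels"))

#' @rdname TimeTree-accessors
#' @export
setMethod("tipLabels", "TimeTree", function(x) x@tipLabels)

#' @rdname TimeTree-accessors
#' @export
setGeneric("nodeAges", function(x) standardGeneric("nodeAges"))

#' @rdname TimeTree-accessors
#' @export
setMethod("nodeAges", "TimeTree", function(x) x@ages)

#' @rdname TimeTree-accessors
#' @export
setGeneric("rootAge", function(x) standardGeneric("rootAge"))

#' @rdname TimeTree-accessors
#' @export
setMethod("rootAge", "TimeTree", function(x) x@ages[nTip(x) + 1L])

#' @rdname TimeTree-accessors
#' @export
setGeneric("branchDurations", function(x) standardGeneric("branchDurations"))

#' @rdname TimeTree-accessors
#' @export
setMethod("branchDurations", "TimeTree", function(x)
  x@ages[x@edge[, 1L]] - x@ages[x@edge[, 2L]])

#' @rdname TimeTree-accessors
#' @export
setGeneric("branchRates", function(x) standardGeneric("branchRates"))

#' @rdname TimeTree-accessors
#' @export
setMethod("branchRates", "TimeTree", function(x)
  if (length(x@rates)) x@rates else NULL)

setMethod("show", "TimeTree", function(object) {
  cat(sprintf("TimeTree: %d tips, root age %.3f Mya%s\n",
              nTip(object), rootAge(object),
              if (length(object@rates)) ", with branch rates" else ""))
  cat("  tips:", paste(utils::head(object@tipLabels, 5), collapse = ", "),
      if (nTip(object) > 5) "..." else "", "\n")
})

setMethod("show", "MultiGeneAlignment", function(object) {
  lens <- vapply(object@genes, ncol, 0L)
  cat(sprintf("MultiGeneAlignment: %d taxa, %d genes, %d sites\n",
              length(object@taxa), length(lens), sum(lens)))
  cat("  genes:", paste(sprintf("%s (%d bp)", names(lens), lens), collapse = ", "), "\n")
})

setMethod("show", "CalibrationSet", function(object) {
  cat(sprintf("CalibrationSet: root Uniform(%g, %g) Mya, %d node calibration(s), %d constraint(s)\n",
              object@root@minAge, object@root@maxAge,
              length(object@nodes), length(object@constraints)))
})

setMethod("show", "Trace", function(object) {
  cat(sprintf("Trace (run %d): %d samples, generations %s..%s\n",
              object@runId, nrow(object@params),
              if (length(object@generations)) object@generations[1] else NA,
              if (length(object@generations)) utils::tail(object@generations, 1) else NA))
})

## ---- internal topology helpers (ape numbering) ------------------------

## parent vector: parentOf[node] = parent node id (0 for root)
.parentVec <- function(edge, nNode) {
  p <- integer(nNode)
  p[edge[, 2L]] <- edge[, 1L]
  p
}

## children list: childrenOf[[node]] = integer vector of children
.childrenList <- function(edge, nNode) {
  ch <- vector("list", nNode)
  for (i in seq_len(nrow(edge)))
    ch[[edge[i, 1L]]] <- c(ch[[edge[i, 1L]]], edge[i, 2L])
  ch
}

## postorder node sequence (children before parents), internal nodes only
.postorderNodes <- function(edge, nTip) {
  ch <- .childrenList(edge, max(edge))
  out <- integer(0)
  visit <- function(v) {
    for (c in ch[[v]]) if (c > nTip) visit(c)
    out <<- c(out, v)
  }
  visit(nTip + 1L)
  out
}

## tips descending from each node, as a list of integer vectors
.cladeTips <- function(edge, nTip) {
  nNode <- max(edge)
  ch <- .childrenList(edge, nNode)
  tips <- vector("list", nNode)
  for (i in seq_len(nTip)) tips[[i]] <- i
  for (v in .postorderNodes(edge, nTip))
    tips[[v]] <- sort(unlist(tips[ch[[v]]]))
  tips
}

## canonical split key for a clade (sorted labels joined by "|")
.splitKey <- function(labels) paste(sort(labels), collapse = "|")

## split keys for every internal node of a TimeTree, named by node id
treeSplits <- function(tree) {
  n <- nTip(tree)
  tips <- .cladeTips(tree@edge, n)
  ids <- (n + 1L):(2L * n - 1L)
  keys <- vapply(ids, function(v) .splitKey(tree@tipLabels[tips[[v]]]), "")
  names(keys) <- ids
  keys
}

#' Convert a TimeTree to an ape phylo
#'
#' Branch lengths are durations in My (or expected substitutions per site
#' when \code{useRates = TRUE} and the tree carries rates scaled by
#' \code{rate}).
#'
#' @param tree A \linkS4class{TimeTree}.
#' @param useRates Multiply durations by per-branch rates.
#' @param rate Base clock rate applied on top of relative rates.
#' @return An object of class \code{phylo}.
#' @export
asPhylo <- function(tree, useRates = FALSE, rate = 1) {
  len <- branchDurations(tree)
  if (useRates) {
    r <- branchRates(tree)
    if (is.null(r)) r <- rep(1, length(len))
    len <- len * r * rate
  }
  structure(list(edge = tree@edge, edge.length = len,
                 tip.label = tree@tipLabels, Nnode = nTip(tree) - 1L),
            class = "phylo", order = "cladewise")
}

#' Convert an ultrametric ape phylo to a TimeTree
#'
#' Node ages are taken as maximum root-to-tip depth minus node depth; tips
#' are forced to age zero (small rounding noise is tolerated).
#'
#' @param phy An ultrametric \code{phylo} with branch lengths in My.
#' @return A \linkS4class{TimeTree}.
#' @export
asTimeTree <- function(phy) {
  n <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  ages <- max(depth[seq_len(n)]) - depth
  ages[seq_len(n)] <- 0
  timeTree(phy$edge, phy$tip.label, ages)
}

## random resolved rooted topology on labels honoring monophyly constraints
## (constraints: list of character vectors, nested-compatible)
.sampleConstrainedTopology <- function(tipLabelsAll, constraints = list()) {
  cons <- lapply(constraints, function(x) sort(intersect(x, tipLabelsAll)))
  cons <- Filter(function(x) length(x) >= 2L, cons)
  ## verify nesting compatibility
  for (i in seq_along(cons)) for (j in seq_len(i - 1L)) {
    ov <- intersect(cons[[i]], cons[[j]])
    if (length(ov) && !setequal(ov, cons[[i]]) && !setequal(ov, cons[[j]]))
      stop("incompatible monophyly constraints")
  }
  ## order outer-first (larger sets first); build containment forest
  ord <- order(-vapply(cons, length, 0L))
  cons <- cons[ord]
  ## item = either a single label or a constraint index; recursively build
  nextNode <- 0L
  edges <- list()
  newick_join <- function(children) {
    ## children: list of node tokens (list(id=..)); random binary join
    items <- children
    while (length(items) > 1L) {
      pick <- sample.int(length(items), 2L)
      nextNode <<- nextNode + 1L
      id <- paste0("__n", nextNode)
      edges[[length(edges) + 1L]] <<- c(id, items[[pick[1]]])
      edges[[length(edges) + 1L]] <<- c(id, items[[pick[2]]])
      items <- c(items[-pick], list(id))
    }
    items[[1L]]
  }
  build <- function(memberLabels, candIdx) {
    ## candIdx: indices of constraints strictly inside memberLabels
    direct <- c()
    used <- rep(FALSE, length(candIdx))
    for (k in seq_along(candIdx)) {
      if (used[k]) next
      ci <- cons[[candIdx[k]]]
      inside_other <- FALSE
      for (k2 in seq_along(candIdx)) {
        if (k2 == k) next
        if (all(ci %in% cons[[candIdx[k2]]]) &&
            length(ci) < length(cons[[candIdx[k2]]])) { inside_other <- TRUE; break }
      }
      if (!inside_other) direct <- c(direct, candIdx[k])
    }
    tokens <- list()
    claimed <- character(0)
    for (d in direct) {
      sub <- cons[[d]]
      subCands <- candIdx[vapply(candIdx, function(j)
        j != d && all(cons[[j]] %in% sub), TRUE)]
      tokens <- c(tokens, list(build(sub, subCands)))
      claimed <- c(claimed, sub)
    }
    free <- setdiff(memberLabels, claimed)
    tokens <- c(tokens, as.list(free))
    newick_join(tokens)
  }
  rootTok <- build(tipLabelsAll, seq_along(cons))
  ## convert edge token list to ape numbering
  em <- do.call(rbind, edges)
  internalIds <- unique(em[, 1L])
  nT <- length(tipLabelsAll)
  idmap <- c(stats::setNames(seq_len(nT), tipLabelsAll),
             stats::setNames(rep(NA_integer_, length(internalIds)), internalIds))
  ## root gets nT+1; assign others in discovery order from root
  idmap[rootTok] <- nT + 1L
  nxt <- nT + 2L
  ## BFS from root over edges
  repeat {
    todo <- which(is.na(idmap[em[, 1L]]) == FALSE & is.na(idmap[em[, 2L]]) &
                  !(em[, 2L] %in% tipLabelsAll))
    if (!length(todo)) break
    for (i in todo) { idmap[em[i, 2L]] <- nxt; nxt <- nxt + 1L }
  }
  edge <- cbind(as.integer(idmap[em[, 1L]]), as.integer(idmap[em[, 2L]]))
  edge
}
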