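#' Write a trace to parameter and tree log files
#'
#' The parameter log is a tab-separated table (one row per sample, with
#' the generation index); the tree log holds one ultrametric Newick
#' string per sample, rebuilt from the sampled bipartitions and node
#' ages.  Both files append cleanly and are re-read by
#' \code{\link{readTrace}}.
#'
#' @param trace A \linkS4class{Trace}.
#' @param paramPath Output path for the parameter log (TSV).
#' @param treePath Output path for the tree log (one Newick per line).
#' @param append Append to existing logs instead of overwriting.
#' @return Invisibly, \code{c(paramPath, treePath)}.
#' @export
writeTrace <- function(trace, paramPath, treePath, append = FALSE) {
  p <- cbind(generation = trace@generations, run = trace@runId,
             trace@params)
  utils::write.table(p, paramPath, sep = "\t", row.names = FALSE,
                     quote = FALSE, append = append,
                     col.names = !append || !file.exists(paramPath))
  lines <- vapply(trace@trees, function(tr) {
    tt <- .treeFromSplits(tr$splits, trace@tipLabels)
    ages <- stats::setNames(tr$ages, tr$splits)
    n <- length(trace@tipLabels)
    ch <- .childrenList(tt$edge, max(tt$edge))
    rec <- function(v, parentAge) {
      if (v <= n) return(sprintf("%s:%s", tt$tipLabels[v],
                                 format(parentAge, digits = 12)))
      a <- ages[[tt$nodeSplit[[as.character(v)]]]]
      kids <- vapply(ch[[v]], rec, "", parentAge = a)
      bl <- if (is.na(parentAge)) ""
            else sprintf(":%s", format(parentAge - a, digits = 12))
      sprintf("(%s)%s", paste(kids, collapse = ","), bl)
    }
    paste0(rec(n + 1L, NA_real_), ";")
  }, "")
  if (append) cat(lines, file = treePath, sep = "\n", append = TRUE)
  else writeLines(lines, treePath)
  invisible(c(paramPath, treePath))
}

#' Read a trace written by \code{\link{writeTrace}}
#'
#' @param paramPath Parameter log path.
#' @param treePath Tree log path.
#' @return A \linkS4class{Trace} (runId taken from the log).
#' @export
readTrace <- function(paramPath, treePath) {
  p <- utils::read.table(paramPath, header = TRUE, sep = "\t")
  lines <- readLines(treePath, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (nrow(p) != length(lines))
    stop("parameter and tree logs have different sample counts")
  trees <- lapply(lines, function(x) {
    tt <- asTimeTree(ape::read.tree(text = x))
    keys <- treeSplits(tt)
    list(splits = unname(keys),
         ages = unname(tt@ages[as.integer(names(keys))]))
  })
  labs <- sort(strsplit(trees[[1]]$splits[which.max(nchar(
    trees[[1]]$splits))], "\\|")[[1]])
  new("Trace", params = p[, setdiff(names(p), c("generation", "run")),
                          drop = FALSE],
      trees = trees, tipLabels = labs,
      generations = as.integer(p$generation),
      runId = as.integer(p$run[1]), info = list(source = paramPath))
}
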