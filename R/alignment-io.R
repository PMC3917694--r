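#' Read a multi-gene alignment
#'
#' FASTA input takes one file per gene (gene names from \code{geneNames} or
#' the file basenames).  NEXUS input takes a single file whose \code{sets}
#' block \code{charset} lines delimit genes.  Characters are upper-cased;
#' '?' and '-' are both treated as missing by the likelihood but preserved
#' as written for round-tripping.
#'
#' @param path Character vector of FASTA paths, or one NEXUS path.
#' @param format "fasta" or "nexus".
#' @param geneNames Optional gene names for FASTA input.
#' @return A \linkS4class{MultiGeneAlignment}.
#' @export
readAlignment <- function(path, format = c("fasta", "nexus"), geneNames = NULL) {
  format <- match.arg(format)
  if (format == "fasta") {
    if (is.null(geneNames))
      geneNames <- sub("\\.[^.]*$", "", basename(path))
    genes <- stats::setNames(lapply(path, .readFastaMatrix), geneNames)
    multiGeneAlignment(genes)
  } else {
    .readNexusAlignment(path)
  }
}

.readFastaMatrix <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA headers in ", file)
  labels <- trimws(sub("^>", "", lines[hdr]))
  if (anyDuplicated(labels))
    stop("duplicate taxon label in ", file, ": ",
         labels[duplicated(labels)][1])
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i)
    gsub("\\s", "", paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")), "")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment in ", file, "; offending taxon: ",
         labels[which(lens != lens[1])[1]])
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- labels
  m
}

.readNexusAlignment <- function(file) {
  lines <- readLines(file, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  ## data matrix
  mstart <- grep("^\\s*matrix\\s*$", lines, ignore.case = TRUE)
  if (!length(mstart)) stop("no matrix block in ", file)
  mend <- grep("^\\s*;", lines)
  mend <- mend[mend > mstart[1]][1]
  rows <- lines[(mstart[1] + 1L):(mend - 1L)]
  rows <- rows[nzchar(trimws(rows))]
  parts <- regmatches(rows, regexpr("^\\s*\\S+", rows))
  labels <- trimws(parts)
  seqs <- toupper(gsub("\\s", "", sub("^\\s*\\S+\\s+", "", rows)))
  ## continuation lines (interleaved) are concatenated per label
  agg <- tapply(seqs, factor(labels, levels = unique(labels)), paste, collapse = "")
  labels <- names(agg)
  if (anyDuplicated(labels)) stop("duplicate taxon label in ", file)
  lens <- nchar(agg)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment in ", file, "; offending taxon: ",
         labels[which(lens != lens[1])[1]])
  m <- do.call(rbind, strsplit(unname(agg), ""))
  rownames(m) <- labels
  ## charsets
  cs <- regmatches(txt, gregexpr("charset\\s+[^;]+;", txt, ignore.case = TRUE))[[1]]
  if (!length(cs)) return(multiGeneAlignment(list(all = m)))
  genes <- list()
  for (line in cs) {
    body <- sub(";$", "", sub("(?i)charset\\s+", "", line, perl = TRUE))
    nm <- trimws(sub("=.*$", "", body))
    rng <- trimws(sub("^.*=", "", body))
    idx <- unlist(lapply(strsplit(rng, "\\s+")[[1]], function(tok) {
      ab <- as.integer(strsplit(tok, "-")[[1]])
      if (length(ab) == 1L) ab else ab[1]:ab[2]
    }))
    genes[[nm]] <- m[, idx, drop = FALSE]
  }
  multiGeneAlignment(genes)
}

#' Write a multi-gene alignment
#'
#' FASTA output writes one concatenated file (or one per gene when
#' \code{perGene = TRUE}); NEXUS output writes a data block plus a sets
#' block with one \code{charset} line per gene.
#'
#' @param aln A \linkS4class{MultiGeneAlignment}.
#' @param path Output file (FASTA concatenated or NEXUS), or a directory
#'   when \code{perGene = TRUE}.
#' @param format "fasta" or "nexus".
#' @param perGene Write one FASTA per gene into directory \code{path}.
#' @return Invisibly, the file path(s) written.
#' @export
writeAlignment <- function(aln, path, format = c("fasta", "nexus"),
                           perGene = FALSE) {
  format <- match.arg(format)
  if (format == "fasta" && perGene) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    files <- vapply(names(aln@genes), function(g) {
      f <- file.path(path, paste0(g, ".fasta"))
      .writeFastaMatrix(aln@genes[[g]], f)
      f
    }, "")
    return(invisible(files))
  }
  concat <- do.call(cbind, aln@genes)
  if (format == "fasta") {
    .writeFastaMatrix(concat, path)
  } else {
    lens <- vapply(aln@genes, ncol, 0L)
    ends <- cumsum(lens); starts <- ends - lens + 1L
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("#NEXUS", "", "begin data;",
                 sprintf("  dimensions ntax=%d nchar=%d;",
                         nrow(concat), ncol(concat)),
                 "  format datatype=dna missing=? gap=-;", "  matrix"), con)
    writeLines(sprintf("    %-30s %s", rownames(concat),
                       apply(concat, 1L, paste, collapse = "")), con)
    writeLines(c("  ;", "end;", "", "begin sets;"), con)
    writeLines(sprintf("  charset %s = %d-%d;", names(lens), starts, ends), con)
    writeLines("end;", con)
  }
  invisible(path)
}

.writeFastaMatrix <- function(m, file) {
  con <- file(file, "w"); on.exit(close(con))
  for (i in seq_len(nrow(m))) {
    writeLines(paste0(">", rownames(m)[i]), con)
    s <- paste(m[i, ], collapse = "")
    writeLines(substring(s, seq(1, nchar(s), 70),
                         pmin(seq(1, nchar(s), 70) + 69, nchar(s))), con)
  }
  invisible(file)
}

#' Build the partition scheme (by gene and by codon position)
#'
#' Coding genes are split into a combined first+second codon-position
#' partition and a third-position partition; non-coding genes form one
#' partition each.  With four coding and three intron genes this yields the
#' reference eleven-partition scheme.
#'
#' @param geneLengths Named integer vector of per-gene site counts, in
#'   concatenation order.
#' @param codingFlags Named (or positional) logical: is each gene coding?
#' @param readingFrames Integer 1-3 per coding gene: the codon position of
#'   the gene's first site (default 1 for all).  Must be supplied (or
#'   defaulted) for every coding gene.
#' @return A \linkS4class{PartitionScheme}.
#' @examples
#' buildPartitionScheme(c(MOS = 6L, MB = 4L), c(TRUE, FALSE))
#' @export
buildPartitionScheme <- function(geneLengths, codingFlags,
                                 readingFrames = NULL) {
  genes <- names(geneLengths)
  if (is.null(genes)) stop("geneLengths must be named")
  if (length(codingFlags) != length(geneLengths))
    stop("codingFlags must match genes")
  if (is.null(readingFrames)) readingFrames <- rep(1L, length(geneLengths))
  if (anyNA(readingFrames[codingFlags]))
    stop("coding gene with unspecified reading frame")
  ends <- cumsum(geneLengths); starts <- ends - geneLengths + 1L
  sites <- list(); tab <- NULL
  for (i in seq_along(genes)) {
    glob <- starts[i]:ends[i]
    if (codingFlags[i]) {
      pos <- ((seq_along(glob) - 1L + readingFrames[i] - 1L) %% 3L) + 1L
      sites[[length(sites) + 1L]] <- glob[pos != 3L]
      tab <- rbind(tab, data.frame(partition = paste0(genes[i], "_pos12"),
                                   gene = genes[i]))
      sites[[length(sites) + 1L]] <- glob[pos == 3L]
      tab <- rbind(tab, data.frame(partition = paste0(genes[i], "_pos3"),
                                   gene = genes[i]))
    } else {
      sites[[length(sites) + 1L]] <- glob
      tab <- rbind(tab, data.frame(partition = genes[i], gene = genes[i]))
    }
  }
  tab$multiplierIndex <- seq_len(nrow(tab))
  new("PartitionScheme", table = tab, sites = sites,
      nSites = as.integer(sum(geneLengths)))
}

#' Count parsimony-informative sites
#'
#' A column is parsimony-informative when at least two distinct unambiguous
#' nucleotide states are each present in at least two sequences; ambiguity
#' codes, gaps and missing data are excluded from the state counts.
#'
#' @param m Character matrix (taxa x sites).
#' @return Integer count of informative columns.
#' @export
countParsimonyInformative <- function(m) {
  good <- c("A", "C", "G", "T")
  sum(apply(toupper(m), 2L, function(col) {
    tb <- table(col[col %in% good])
    sum(tb >= 2L) >= 2L
  }))
}

#' Uncorrected p-distance between two taxa
#'
#' Proportion of differing sites among the columns where both sequences
#' carry an unambiguous nucleotide.
#'
#' @param m Character matrix (taxa x sites) with rownames.
#' @param taxonA,taxonB Row labels.
#' @return Fraction in [0, 1]; \code{NA} (with a warning) when no column is
#'   comparable.
#' @export
pDistance <- function(m, taxonA, taxonB) {
  good <- c("A", "C", "G", "T")
  a <- toupper(m[taxonA, ]); b <- toupper(m[taxonB, ])
  ok <- a %in% good & b %in% good
  if (!any(ok)) {
    warning("no comparable sites between ", taxonA, " and ", taxonB)
    return(NA_real_)
  }
  mean(a[ok] != b[ok])
}
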