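#' Read / write FASTA for GeneSets
#'
#' Thin wrappers around Biostrings, writing 80-column wrapped FASTA.
#'
#' @param file Path.
#' @return \code{readGeneFasta}: a \code{GeneSet}.
#' @export
readGeneFasta <- function(file) {
  geneSet(Biostrings::readDNAStringSet(file))
}

#' @rdname readGeneFasta
#' @param x GeneSet or DNAStringSet.
#' @export
writeGeneFasta <- function(x, file) {
  if (methods::is(x, "GeneSet")) x <- geneSeqs(x)
  Biostrings::writeXStringSet(x, file, width = 80L)
  invisible(file)
}

#' Read / write Newick trees carrying dual support labels
#'
#' Internal node labels use the dialect \code{"ufboot/shalrt"} (optionally
#' prefixed \code{"name|ufboot/shalrt"}; the name part is ignored here). The
#' root carries no support.
#'
#' @param file Path to a Newick file (or a Newick string via \code{text}).
#' @param text Optional Newick string instead of a file.
#' @return A \code{\link{supportTree}}.
#' @export
readSupportTree <- function(file = NULL, text = NULL) {
  phy <- if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text)
  ntip <- length(phy$tip.label)
  labs <- phy$node.label
  uf <- sh <- rep(NA_real_, phy$Nnode)
  if (!is.null(labs)) {
    core <- sub("^.*\\|", "", labs)
    parts <- strsplit(core, "/", fixed = TRUE)
    uf <- vapply(parts, function(p)
      if (length(p) == 2) suppressWarnings(as.numeric(p[1])) else NA_real_,
      numeric(1))
    sh <- vapply(parts, function(p)
      if (length(p) == 2) suppressWarnings(as.numeric(p[2])) else NA_real_,
      numeric(1))
  }
  names(uf) <- names(sh) <- as.character(ntip + seq_len(phy$Nnode))
  phy$node.label <- NULL
  supportTree(phy, uf, sh)
}

#' @rdname readSupportTree
#' @param st A \code{SupportTree}.
#' @export
writeSupportTree <- function(st, file = NULL) {
  phy <- treePhylo(st)
  sup <- treeSupport(st)
  ntip <- length(phy$tip.label)
  phy$node.label <- vapply(seq_len(phy$Nnode), function(i) {
    s <- sup[as.character(ntip + i), ]
    if (anyNA(s)) "" else sprintf("%g/%g", s[1], s[2])
  }, character(1))
  ape::write.tree(phy, file = if (is.null(file)) "" else file)
}
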