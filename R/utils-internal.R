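# Internal helpers shared across modules. Not exported.

STOP_CODONS <- c("TAA", "TAG", "TGA")
GREEK <- c("α", "β", "γ", "δ", "ε", "ζ",
           "η", "θ", "ι", "κ", "λ", "μ",
           "ν", "ξ", "ο", "π", "ρ", "σ",
           "τ", "υ", "φ", "χ", "ψ", "ω")

# synonymous families of the standard genetic code, stops excluded
.codonFamilies <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  split(names(gc), unname(gc))
}

.seqToCodons <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return(character(0))
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

.degap <- function(s) gsub("-", "", s, fixed = TRUE)

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# greek label sequence extended past omega ("alpha2", ...)
.greekLabel <- function(i) {
  k <- (i - 1L) %/% length(GREEK)
  g <- GREEK[(i - 1L) %% length(GREEK) + 1L]
  if (k == 0L) g else paste0(g, k + 1L)
}

# character matrix of an equal-width sequence set
.charMatrix <- function(seqs) {
  if (methods::is(seqs, "GeneSet")) seqs <- geneSeqs(seqs)
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  m <- as.matrix(seqs)
  rownames(m) <- names(seqs)
  m
}

# matches / compared-columns matrices for all pairs; columns gapped in either
# sequence of a pair are excluded from both counts when gap_exclude is TRUE
.matchCounts <- function(mat, gap_exclude = TRUE) {
  bases <- c("A", "C", "G", "T")
  if (!gap_exclude) bases <- c(bases, "-", "N")
  matches <- matrix(0, nrow(mat), nrow(mat))
  for (b in bases) {
    ind <- (mat == b) * 1
    matches <- matches + tcrossprod(ind)
  }
  if (gap_exclude) {
    nongap <- (mat != "-") * 1
    compared <- tcrossprod(nongap)
  } else {
    compared <- matrix(ncol(mat), nrow(mat), nrow(mat))
  }
  dimnames(matches) <- dimnames(compared) <- list(rownames(mat), rownames(mat))
  list(matches = matches, compared = compared)
}

# fractional identity between two equal-length character vectors (gap-excluded)
.pairIdentity <- function(a, b) {
  keep <- a != "-" & b != "-"
  if (!any(keep)) return(NA_real_)
  sum(a[keep] == b[keep]) / sum(keep)
}

# k-mer presence matrix (rows = sequences)
.kmerPresence <- function(seqs, k = 8L) {
  if (methods::is(seqs, "DNAStringSet"))
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  ss <- Biostrings::DNAStringSet(vapply(seqs, .degap, character(1)))
  out <- (Biostrings::oligonucleotideFrequency(ss, width = k) > 0) * 1
  rownames(out) <- names(seqs)
  out
}

# shared k-mer counts between one query and reference rows; pass a
# precomputed .kmerPresence matrix when screening many queries
.sharedKmers <- function(query, refs, k = 8L, ref_kmers = NULL) {
  if (is.null(ref_kmers)) ref_kmers <- .kmerPresence(refs, k)
  qk <- .kmerPresence(query, k = as.integer(log(ncol(ref_kmers), 4)))
  as.vector(ref_kmers %*% qk[1, ])
}

# descendant tip labels per node of a phylo (list indexed by node number)
.tipDescendants <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  out <- vector("list", nnode)
  for (i in seq_len(ntip)) out[[i]] <- phy$tip.label[i]
  # accumulate children bottom-up using the edge matrix in postorder
  for (e in ape::postorder(phy)) {
    par <- phy$edge[e, 1]; chi <- phy$edge[e, 2]
    out[[par]] <- c(out[[par]], out[[chi]])
  }
  out
}

# children of every node
.childrenList <- function(phy) {
  nnode <- length(phy$tip.label) + phy$Nnode
  ch <- vector("list", nnode)
  for (e in seq_len(nrow(phy$edge)))
    ch[[phy$edge[e, 1]]] <- c(ch[[phy$edge[e, 1]]], phy$edge[e, 2])
  ch
}

# branch length of the edge above each node (NA for root)
.stemLengths <- function(phy) {
  nnode <- length(phy$tip.label) + phy$Nnode
  out <- rep(NA_real_, nnode)
  out[phy$edge[, 2]] <- phy$edge.length
  out
}

.rootNode <- function(phy) length(phy$tip.label) + 1L
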