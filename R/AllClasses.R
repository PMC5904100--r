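#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

setOldClass("phylo")

#' GeneSet: curated marker-gene fragments on a common coding frame
#'
#' A set of nucleotide fragments sharing one coding frame (591 columns for
#' archaeal amoA), stored as a \linkS4class{DNAStringSet} plus per-gene
#' metadata (source study, OTU, clade, habitat and curation bookkeeping).
#' Gap characters (\code{-}) are allowed and mark codon deletions relative
#' to the common frame.
#'
#' @slot seqs A \code{DNAStringSet}; all elements have equal width (the
#'   common frame) and unique names.
#' @slot meta A \code{DataFrame} with one row per gene, rownames = gene ids.
#' @export
setClass("GeneSet", representation(seqs = "DNAStringSet", meta = "DataFrame"))

setValidity("GeneSet", function(object) {
  ids <- names(object@seqs)
  if (is.null(ids) || anyDuplicated(ids))
    return("sequences must carry unique names")
  if (length(object@seqs) > 0 && length(unique(Biostrings::width(object@seqs))) != 1)
    return("all sequences must share one frame width")
  if (nrow(object@meta) != length(object@seqs))
    return("meta must have one row per sequence")
  if (!identical(rownames(object@meta), ids))
    return("meta rownames must equal sequence names")
  TRUE
})

#' Construct a GeneSet
#'
#' @param seqs Named character vector or \code{DNAStringSet} of equal-width
#'   sequences in the common frame.
#' @param meta Optional data.frame/DataFrame of per-gene metadata (one row per
#'   sequence, matched by name).
#' @return A \linkS4class{GeneSet}.
#' @examples
#' gs <- geneSet(c(g1 = "ATGAAA", g2 = "ATGCCC"))
#' geneIds(gs)
#' @export
geneSet <- function(seqs, meta = NULL) {
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%04d", seq_along(seqs))
  if (is.null(meta)) {
    meta <- S4Vectors::DataFrame(row.names = names(seqs))
  } else {
    meta <- S4Vectors::DataFrame(meta, row.names = names(seqs))
  }
  methods::new("GeneSet", seqs = seqs, meta = meta)
}

#' @describeIn geneSet Gene identifiers.
#' @param x A \code{GeneSet}.
#' @export
geneIds <- function(x) names(x@seqs)

#' @describeIn geneSet Underlying \code{DNAStringSet}.
#' @export
geneSeqs <- function(x) x@seqs

#' @describeIn geneSet Per-gene metadata \code{DataFrame}.
#' @export
geneMeta <- function(x) x@meta

setMethod("length", "GeneSet", function(x) length(x@seqs))

setMethod("show", "GeneSet", function(object) {
  cat("GeneSet with", length(object), "genes",
      if (length(object)) paste0("(frame width ",
                                 Biostrings::width(object@seqs)[1], ")"), "\n")
  if (ncol(object@meta))
    cat("metadata:", paste(colnames(object@meta), collapse = ", "), "\n")
})

setMethod("[", "GeneSet", function(x, i, j, ..., drop = TRUE) {
  methods::new("GeneSet", seqs = x@seqs[i], meta = x@meta[i, , drop = FALSE])
})

#' Concatenate GeneSets
#' @param x,... GeneSet objects.
#' @export
combineGeneSets <- function(x, ...) {
  all <- c(list(x), list(...))
  seqs <- do.call(c, lapply(all, geneSeqs))
  metas <- lapply(all, geneMeta)
  cols <- unique(unlist(lapply(metas, colnames)))
  metas <- lapply(metas, function(m) {
    for (cl in setdiff(cols, colnames(m))) m[[cl]] <- NA
    m[, cols, drop = FALSE]
  })
  methods::new("GeneSet", seqs = seqs, meta = do.call(rbind, metas))
}

#' SupportTree: rooted tree with dual branch supports
#'
#' A rooted phylogeny whose internal branches carry both an ultrafast
#' bootstrap percentage (UFBoot) and an SH-aLRT percentage. Supports are
#' attached to the branch subtending each internal node. Leaves are OTU
#' representatives.
#'
#' @slot phy An \code{ape} \code{phylo} object (rooted).
#' @slot support Numeric matrix, one row per internal node (rownames are the
#'   phylo node numbers as character), columns \code{ufboot} and \code{shalrt}.
#'   The root row holds \code{NA} (no subtending branch).
#' @export
setClass("SupportTree", representation(phy = "phylo", support = "matrix"))

setValidity("SupportTree", function(object) {
  phy <- object@phy
  # rooted here means single-root (the root may be multifurcating, as after
  # collapsing unsupported branches)
  nnode <- length(phy$tip.label) + phy$Nnode
  hasParent <- tabulate(phy$edge[, 2], nnode) > 0
  if (sum(!hasParent) != 1) return("tree must have exactly one root")
  if (anyDuplicated(phy$tip.label)) return("leaf ids must be unique")
  ntip <- length(phy$tip.label)
  internal <- as.character(seq_len(phy$Nnode) + ntip)
  if (!setequal(rownames(object@support), internal))
    return("support must have one row per internal node")
  if (!identical(colnames(object@support), c("ufboot", "shalrt")))
    return("support columns must be ufboot, shalrt")
  vals <- object@support[!is.na(object@support)]
  if (length(vals) && (any(vals < 0) || any(vals > 100)))
    return("supports must lie in [0, 100]")
  TRUE
})

#' Construct a SupportTree
#'
#' @param phy Rooted \code{phylo}.
#' @param ufboot,shalrt Numeric vectors of branch supports for internal nodes,
#'   named by phylo node number (root entry may be absent or NA).
#' @return A \linkS4class{SupportTree}.
#' @export
supportTree <- function(phy, ufboot, shalrt) {
  ntip <- length(phy$tip.label)
  nodes <- as.character(seq_len(phy$Nnode) + ntip)
  sup <- matrix(NA_real_, nrow = length(nodes), ncol = 2,
                dimnames = list(nodes, c("ufboot", "shalrt")))
  if (!is.null(names(ufboot))) sup[names(ufboot), "ufboot"] <- ufboot
  else sup[, "ufboot"] <- ufboot
  if (!is.null(names(shalrt))) sup[names(shalrt), "shalrt"] <- shalrt
  else sup[, "shalrt"] <- shalrt
  methods::new("SupportTree", phy = phy, support = sup)
}

#' @describeIn supportTree The underlying \code{phylo}.
#' @param x A \code{SupportTree}.
#' @export
treePhylo <- function(x) x@phy

#' @describeIn supportTree Support matrix (ufboot, shalrt per internal node).
#' @export
treeSupport <- function(x) x@support

#' @describeIn supportTree Leaf labels.
#' @export
treeLeaves <- function(x) x@phy$tip.label

setMethod("show", "SupportTree", function(object) {
  cat("SupportTree:", length(object@phy$tip.label), "leaves,",
      object@phy$Nnode, "internal nodes\n")
  ok <- stats::complete.cases(object@support)
  cat("branches with both supports:", sum(ok), "\n")
})

#' Taxonomy: multilevel support-based clade taxonomy
#'
#' The named-clade taxonomy produced by collapsing unsupported branches and
#' applying the deterministic rank-assignment rules (order prefix, Greek
#' letters, dotted numeric subranks, incertae sedis).
#'
#' @slot taxa data.frame with columns \code{name}, \code{parent}, \code{level},
#'   \code{is_incertae_sedis}, \code{is_terminal}, \code{stem_length}, and a
#'   list column \code{members} of leaf (OTU) ids.
#' @export
setClass("Taxonomy", representation(taxa = "data.frame"))

setValidity("Taxonomy", function(object) {
  tx <- object@taxa
  need <- c("name", "parent", "level", "is_incertae_sedis",
            "is_terminal", "stem_length", "members")
  if (!all(need %in% colnames(tx))) return("missing taxa columns")
  if (anyDuplicated(tx$name)) return("taxon names must be unique")
  grammar <- "^[A-Za-z0-9]+(-[α-ω][0-9]*)?(-[0-9]+(\\.[0-9]+)*)?(-IS[0-9]*)?$|^[A-Za-z0-9/]+-IS[0-9]*$"
  if (nrow(tx) && !all(grepl(grammar, tx$name)))
    return("taxon name violates the rank-name grammar")
  for (i in seq_len(nrow(tx))) {
    p <- tx$parent[i]
    if (!is.na(p)) {
      j <- match(p, tx$name)
      if (is.na(j)) return(paste("unknown parent:", p))
      if (!all(tx$members[[i]] %in% tx$members[[j]]))
        return("child members must nest inside the parent's")
    }
  }
  TRUE
})

#' @describeIn assignRanks Taxa table of a Taxonomy.
#' @export
taxaTable <- function(x) x@taxa

setMethod("show", "Taxonomy", function(object) {
  tx <- object@taxa
  cat("Taxonomy with", nrow(tx), "named taxa on",
      length(unique(tx$level)), "levels\n")
  cat("incertae sedis:", sum(tx$is_incertae_sedis),
      " terminal:", sum(tx$is_terminal), "\n")
})

#' Most specific taxon of a leaf (OTU)
#'
#' @param x A \code{Taxonomy}.
#' @param id Leaf/OTU id.
#' @return Taxon name (deepest taxon whose member set contains \code{id}),
#'   or \code{NA} if the id is not covered.
#' @export
lineageOf <- function(x, id) {
  tx <- x@taxa
  hit <- vapply(tx$members, function(m) id %in% m, logical(1))
  if (!any(hit)) return(NA_character_)
  cand <- tx[hit, ]
  cand$name[which.max(cand$level)]
}
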