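#' @name taxonomy_engine
#' @title Support-threshold multilevel taxonomy
#'
#' @description
#' Collapse every internal branch whose support falls below the dual
#' thresholds (UFBoot >= 95 and SH-aLRT >= 85, boundary inclusive), then
#' assign multilevel rank labels deterministically: order prefixes seeded by
#' anchor leaves, Greek letters at level 1, dotted numerals deeper, with
#' two-leaf clades marked incertae sedis and ranks opened only where needed
#' to distinguish at least two eligible clades.
NULL

#' Collapse branches below the dual support thresholds
#'
#' Every internal branch with \code{ufboot < min_ufboot} OR
#' \code{shalrt < min_shalrt} is contracted: its children re-attach to its
#' parent; surviving branches keep their lengths and supports (the
#' contracted branch's own length is dropped). Leaves are never removed. Both thresholds are inclusive: a branch at
#' exactly (95, 85) is retained.
#'
#' @param st A \code{\link{supportTree}}.
#' @param min_ufboot,min_shalrt Thresholds in percent (defaults 95 and 85).
#' @return A (possibly multifurcating) \code{SupportTree}.
#' @export
collapseUnsupported <- function(st, min_ufboot = 95, min_shalrt = 85) {
  phy <- treePhylo(st)
  sup <- treeSupport(st)
  ntip <- length(phy$tip.label)
  root <- .rootNode(phy)
  nnode <- ntip + phy$Nnode
  par <- rep(NA_integer_, nnode)
  par[phy$edge[, 2]] <- phy$edge[, 1]
  len <- .stemLengths(phy)
  internal <- setdiff((ntip + 1L):nnode, root)
  bad <- logical(nnode)
  for (v in internal) {
    s <- sup[as.character(v), ]
    if (anyNA(s))
      stop("missing support value on the branch above node ", v)
    bad[v] <- s["ufboot"] < min_ufboot || s["shalrt"] < min_shalrt
  }
  kept <- c(seq_len(ntip), root, internal[!bad[internal]])
  newpar <- rep(NA_integer_, nnode)
  newlen <- rep(NA_real_, nnode)
  for (v in setdiff(kept, root)) {
    p <- par[v]
    while (bad[p]) p <- par[p]
    newpar[v] <- p; newlen[v] <- len[v]
  }
  keptInternal <- c(root, internal[!bad[internal]])
  newnum <- rep(NA_integer_, nnode)
  newnum[seq_len(ntip)] <- seq_len(ntip)
  newnum[keptInternal] <- ntip + seq_along(keptInternal)
  children <- setdiff(kept, root)
  edge <- cbind(newnum[newpar[children]], newnum[children])
  newphy <- structure(list(edge = edge,
                           edge.length = newlen[children],
                           tip.label = phy$tip.label,
                           Nnode = length(keptInternal)),
                      class = "phylo")
  newphy <- ape::reorder.phylo(newphy, "cladewise")
  uf <- sh <- rep(NA_real_, length(keptInternal))
  names(uf) <- names(sh) <- as.character(newnum[keptInternal])
  for (v in keptInternal[-1]) {
    uf[as.character(newnum[v])] <- sup[as.character(v), "ufboot"]
    sh[as.character(newnum[v])] <- sup[as.character(v), "shalrt"]
  }
  supportTree(newphy, uf, sh)
}

# deterministic ordering of sibling clades: descending stem length, then
# larger leaf count, then lexicographic smallest member id
.siblingOrder <- function(stems, counts, minids) {
  order(-stems, -counts, minids)
}

#' Assign multilevel rank labels to a collapsed tree
#'
#' Recursively over named clades: maximal supported subclades with at least
#' \code{min_clade} leaves are rank-eligible; exactly-two-leaf subclades are
#' named \code{<parent>-IS} (incertae sedis); a new rank level is opened only
#' when at least two eligible subclades must be distinguished (otherwise the
#' parent is terminal), except for manual overrides which force a rank onto
#' the listed clades. Eligible clades are labelled (Greek letters at level 1,
#' integers deeper) in descending order of stem branch length starting from
#' the longest; ties go to the larger leaf count, then the lexicographically
#' smallest member id. Singleton leaves carry the parent's name.
#'
#' @param st Collapsed \code{SupportTree}.
#' @param seeds Named character vector: anchor leaf id -> order prefix (e.g.
#'   \code{c(leafA = "NP", leafB = "NS")}). The order clade of a prefix is the
#'   largest clade containing all of its anchors and no anchor of another
#'   prefix.
#' @param min_clade Minimum leaves for rank eligibility (default 3).
#' @param manual_overrides List of character vectors of leaf ids; each must be
#'   monophyletic in the collapsed tree and is forced to receive a rank even
#'   when redundancy rules would suppress it.
#' @return A \code{\linkS4class{Taxonomy}}.
#' @export
assignRanks <- function(st, seeds, min_clade = 3L, manual_overrides = list()) {
  phy <- treePhylo(st)
  ntip <- length(phy$tip.label)
  root <- .rootNode(phy)
  miss <- setdiff(names(seeds), phy$tip.label)
  if (length(miss)) stop("seed anchor absent from tree: ",
                         paste(miss, collapse = ", "))
  tips <- .tipDescendants(phy)
  kids <- .childrenList(phy)
  stems <- .stemLengths(phy)
  anchors <- split(names(seeds), unname(seeds))
  prefixes <- names(anchors)
  orderNode <- vapply(prefixes, function(p) {
    own <- anchors[[p]]
    other <- setdiff(names(seeds), own)
    cand <- which(vapply(seq_len(ntip + phy$Nnode), function(v)
      all(own %in% tips[[v]]) && !any(other %in% tips[[v]]), logical(1)))
    if (length(cand) == 0)
      stop("no clade isolates the anchors of prefix ", p)
    cand[which.max(lengths(tips[cand]))]
  }, integer(1))
  ovKeys <- vapply(manual_overrides,
                   function(m) paste(sort(m), collapse = "\r"), character(1))
  nodeKey <- vapply(tips, function(m) paste(sort(m), collapse = "\r"),
                    character(1))
  if (length(ovKeys) && !all(ovKeys %in% nodeKey))
    stop("override clade not monophyletic in the collapsed tree")
  rows <- list()
  addRow <- function(name, parent, level, members, is_is, is_term, stem) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, parent = parent, level = level,
      is_incertae_sedis = is_is, is_terminal = is_term,
      stem_length = stem, members = I(list(sort(members))))
  }
  recurse <- function(node, name, level) {
    ch <- kids[[node]]
    chInternal <- ch[ch > ntip]
    counts <- lengths(tips[chInternal])
    isCands <- chInternal[counts == 2L]
    forced <- nodeKey[chInternal] %in% ovKeys
    eligible <- chInternal[counts >= min_clade | forced]
    elForced <- forced[counts >= min_clade | forced]
    open <- length(eligible) >= 2 || any(elForced)
    labelled <- if (length(eligible) >= 2) eligible else eligible[elForced]
    labelled <- setdiff(labelled, isCands[!(nodeKey[isCands] %in% ovKeys)])
    if (length(labelled)) {
      minids <- vapply(tips[labelled], function(m) sort(m)[1], character(1))
      ord <- .siblingOrder(stems[labelled], lengths(tips[labelled]), minids)
      labelled <- labelled[ord]
      for (i in seq_along(labelled)) {
        v <- labelled[i]
        lab <- if (level == 0) paste0(name, "-", .greekLabel(i))
               else if (level == 1) paste0(name, "-", i)
               else paste0(name, ".", i)
        sub <- recurse(v, lab, level + 1L)
        addRow(lab, name, level + 1L, tips[[v]], FALSE, !sub, stems[v])
      }
    }
    isCands <- isCands[!(nodeKey[isCands] %in% ovKeys)]
    if (length(isCands)) {
      minids <- vapply(tips[isCands], function(m) sort(m)[1], character(1))
      ord <- .siblingOrder(stems[isCands], lengths(tips[isCands]), minids)
      isCands <- isCands[ord]
      for (i in seq_along(isCands)) {
        lab <- if (i == 1) paste0(name, "-IS") else paste0(name, "-IS", i)
        addRow(lab, name, level + 1L, tips[[isCands[i]]], TRUE, TRUE,
               stems[isCands[i]])
      }
    }
    length(labelled) > 0
  }
  for (p in prefixes) {
    v <- orderNode[[p]]
    sub <- recurse(v, p, 0L)
    addRow(p, NA_character_, 0L, tips[[v]], FALSE, !sub, stems[v])
  }
  placed <- unique(unlist(tips[orderNode]))
  unplaced <- setdiff(phy$tip.label, placed)
  if (length(unplaced)) {
    addRow(paste0(paste(sort(prefixes), collapse = "/"), "-IS"),
           NA_character_, 0L, unplaced, TRUE, TRUE, NA_real_)
  }
  taxa <- do.call(rbind, rows)
  # present parents before children, deepest last within a lineage
  taxa <- taxa[order(taxa$level, taxa$name), ]
  rownames(taxa) <- NULL
  methods::new("Taxonomy", taxa = taxa)
}

#' Classify a sequence against the taxonomy
#'
#' Identity-based placement: the nearest OTU representative at
#' \code{min_identity} or better determines the most specific taxon;
#' otherwise the deepest taxon covering all representatives within
#' \code{lca_radius} (a lowest-common-ancestor fallback); otherwise
#' \code{"unclassified"}.
#'
#' @param gene Sequence in the common frame (character string).
#' @param taxonomy A \code{Taxonomy}.
#' @param representatives Named character vector of OTU representative
#'   sequences; names must match taxonomy member ids.
#' @param min_identity Direct-placement threshold (default 0.96).
#' @param lca_radius Relaxed radius for the fallback (default 0.90).
#' @return Taxon name or \code{"unclassified"}.
#' @export
classifyGene <- function(gene, taxonomy, representatives,
                         min_identity = 0.96, lca_radius = 0.90) {
  tx <- taxaTable(taxonomy)
  if (nrow(tx) == 0) stop("empty taxonomy")
  q <- strsplit(as.character(gene), "")[[1]]
  repMat <- .charMatrix(representatives)
  idents <- apply(repMat, 1, function(r) .pairIdentity(q, r))
  best <- which.max(idents)
  if (idents[best] >= min_identity)
    return(lineageOf(taxonomy, names(representatives)[best]))
  within <- names(representatives)[idents >= lca_radius]
  if (length(within)) {
    cover <- vapply(tx$members, function(m) all(within %in% m), logical(1))
    if (any(cover)) {
      cand <- tx[cover, ]
      return(cand$name[which.max(cand$level)])
    }
  }
  "unclassified"
}

#' Export taxonomy and annotated tree
#'
#' Writes (i) a Newick file whose internal node labels carry
#' \code{"name|ufboot/shalrt"} (name empty for unnamed clades) and (ii) a
#' flat TSV with one row per taxon (name, parent, level, flags, stem length,
#' comma-joined members) plus one OTU-to-lineage column block. The pair
#' round-trips losslessly through \code{\link{importTaxonomy}}.
#'
#' @param taxonomy A \code{Taxonomy}.
#' @param st The collapsed \code{SupportTree} the taxonomy was built from.
#' @param tree_file,taxa_file Output paths.
#' @return Invisibly, the two paths.
#' @export
exportTaxonomy <- function(taxonomy, st, tree_file, taxa_file) {
  phy <- treePhylo(st)
  sup <- treeSupport(st)
  ntip <- length(phy$tip.label)
  tips <- .tipDescendants(phy)
  tx <- taxaTable(taxonomy)
  txKey <- vapply(tx$members, function(m) paste(sort(m), collapse = "\r"),
                  character(1))
  labs <- vapply(seq_len(phy$Nnode), function(i) {
    v <- ntip + i
    key <- paste(sort(tips[[v]]), collapse = "\r")
    nm <- tx$name[match(key, txKey)]
    if (is.na(nm)) nm <- ""
    s <- sup[as.character(v), ]
    if (anyNA(s)) nm else sprintf("%s|%g/%g", nm, s[1], s[2])
  }, character(1))
  phy$node.label <- labs
  ape::write.tree(phy, file = tree_file)
  flat <- data.frame(name = tx$name, parent = tx$parent, level = tx$level,
                     is_incertae_sedis = tx$is_incertae_sedis,
                     is_terminal = tx$is_terminal,
                     stem_length = sprintf("%.17g", tx$stem_length),
                     members = vapply(tx$members, paste, character(1),
                                      collapse = ","))
  utils::write.table(flat, taxa_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(tree_file, taxa_file))
}

#' Re-import an exported taxonomy
#'
#' @param taxa_file Path written by \code{\link{exportTaxonomy}}.
#' @return A \code{Taxonomy} identical to the exported one.
#' @export
importTaxonomy <- function(taxa_file) {
  flat <- utils::read.table(taxa_file, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, quote = "")
  taxa <- data.frame(name = flat$name, parent = flat$parent,
                     level = as.integer(flat$level),
                     is_incertae_sedis = flat$is_incertae_sedis,
                     is_terminal = flat$is_terminal,
                     stem_length = as.numeric(flat$stem_length),
                     members = I(lapply(strsplit(flat$members, ","), sort)))
  methods::new("Taxonomy", taxa = taxa)
}

#' Flat OTU-to-lineage table
#'
#' @param taxonomy A \code{Taxonomy}.
#' @return data.frame with columns \code{otu} and \code{lineage} (the most
#'   specific taxon name).
#' @export
lineageTable <- function(taxonomy) {
  ids <- sort(unique(unlist(taxaTable(taxonomy)$members)))
  data.frame(otu = ids,
             lineage = vapply(ids, function(i) lineageOf(taxonomy, i),
                              character(1)))
}
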