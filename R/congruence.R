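#' @name tree_congruence
#' @title Internode certainty, tree certainty and clade congruence
#'
#' @description
#' Selects the most congruent tree among candidates by tree certainty (the
#' sum of internode certainty over internal branches) and classifies clades
#' shared with an external reference tree as congruent, compatible or
#' conflicting.
#'
#' @details
#' Internode certainty follows the two-most-prevalent-bipartition
#' normalisation: for a branch with relative frequency f1 across the tree
#' set and strongest observed conflicting bipartition frequency f2,
#' p1 = f1/(f1+f2), p2 = f2/(f1+f2) and IC = 1 + p1 log2 p1 + p2 log2 p2,
#' negated when f2 > f1. Frequencies count trees (not bootstrap replicates);
#' multifurcating candidates contribute only their resolved branches.
NULL

# canonical key of the bipartition induced by a tip set: the side not
# containing the alphabetically first leaf, sorted
.splitKey <- function(side, alltips) {
  ref <- sort(alltips)[1]
  if (ref %in% side) side <- setdiff(alltips, side)
  paste(sort(side), collapse = "\r")
}

# non-trivial bipartition keys of one tree (internal branches only)
.treeSplits <- function(phy, alltips) {
  ntip <- length(phy$tip.label)
  tips <- .tipDescendants(phy)
  root <- .rootNode(phy)
  nodes <- setdiff((ntip + 1L):(ntip + phy$Nnode), root)
  keys <- vapply(nodes, function(v) {
    side <- tips[[v]]
    if (length(side) <= 1L || length(side) >= ntip - 1L) return(NA_character_)
    .splitKey(side, alltips)
  }, character(1))
  stats::setNames(keys[!is.na(keys)], nodes[!is.na(keys)])
}

.splitsConflict <- function(keyA, keyB, alltips) {
  a <- strsplit(keyA, "\r", fixed = TRUE)[[1]]
  b <- strsplit(keyB, "\r", fixed = TRUE)[[1]]
  ac <- setdiff(alltips, a); bc <- setdiff(alltips, b)
  length(intersect(a, b)) > 0 && length(intersect(a, bc)) > 0 &&
    length(intersect(ac, b)) > 0 && length(intersect(ac, bc)) > 0
}

.checkLeafSets <- function(trees) {
  leaves <- lapply(trees, function(t) sort(t$tip.label))
  for (i in seq_along(trees)[-1]) {
    if (!identical(leaves[[i]], leaves[[1]])) {
      d <- c(setdiff(leaves[[1]], leaves[[i]]),
             setdiff(leaves[[i]], leaves[[1]]))
      stop("leaf-set mismatch; symmetric difference: ",
           paste(d, collapse = ", "))
    }
  }
  leaves[[1]]
}

#' Internode certainty profile of a focal tree
#'
#' @param focal \code{phylo} (or \code{SupportTree}) whose branches are
#'   scored.
#' @param tree_set List of \code{phylo} trees sharing the focal leaf set
#'   (the focal tree is counted as part of the set if present in it).
#' @return data.frame with one row per internal branch of the focal tree:
#'   node, f1, conflict frequency f2, and ic.
#' @export
internodeCertainty <- function(focal, tree_set) {
  if (methods::is(focal, "SupportTree")) focal <- treePhylo(focal)
  tree_set <- lapply(tree_set, function(t)
    if (methods::is(t, "SupportTree")) treePhylo(t) else t)
  alltips <- .checkLeafSets(c(list(focal), tree_set))
  n <- length(tree_set)
  counts <- table(unlist(lapply(tree_set, function(t)
    unique(unname(.treeSplits(t, alltips))))))
  fsplits <- .treeSplits(focal, alltips)
  out <- lapply(seq_along(fsplits), function(i) {
    key <- fsplits[[i]]
    f1 <- if (key %in% names(counts)) counts[[key]] / n else 0
    confl <- names(counts)[vapply(names(counts), .splitsConflict,
                                  logical(1), keyB = key, alltips = alltips)]
    f2 <- if (length(confl)) max(counts[confl]) / n else 0
    if (f2 == 0) {
      ic <- 1
    } else {
      p1 <- f1 / (f1 + f2); p2 <- f2 / (f1 + f2)
      ent <- function(p) if (p > 0) p * log2(p) else 0
      ic <- 1 + ent(p1) + ent(p2)
      if (f2 > f1) ic <- -ic
    }
    data.frame(node = as.integer(names(fsplits)[i]), f1 = f1, f2 = f2,
               ic = ic)
  })
  do.call(rbind, out)
}

#' Select the best tree by tree certainty
#'
#' TC(t) is the sum of internode certainty over the internal branches of t,
#' with branch frequencies taken across the whole candidate set. Ties are
#' reported and broken by the lexicographically smallest Newick
#' serialization.
#'
#' @param tree_set List of \code{phylo} / \code{SupportTree} objects (>= 2)
#'   over one leaf set.
#' @return List with \code{best} (index), \code{tree}, \code{tc}
#'   (numeric vector), and \code{tie} (logical).
#' @export
selectBestTree <- function(tree_set) {
  if (length(tree_set) < 2) stop("need at least two candidate trees")
  phys <- lapply(tree_set, function(t)
    if (methods::is(t, "SupportTree")) treePhylo(t) else t)
  tc <- vapply(phys, function(t)
    sum(internodeCertainty(t, phys)$ic), numeric(1))
  top <- which(tc == max(tc))
  tie <- length(top) > 1
  if (tie) {
    ser <- vapply(phys[top], function(t) ape::write.tree(t), character(1))
    top <- top[order(ser)[1]]
  }
  list(best = top[1], tree = tree_set[[top[1]]], tc = tc, tie = tie)
}

#' Congruence of reference clades within a focal tree
#'
#' For each internal clade of the reference tree whose linked members occur
#' in the focal tree: \code{congruent} when those members are monophyletic in
#' the focal tree; \code{compatible} when they are monophyletic once leaves
#' absent from the reference (unlinked) are ignored, so any non-monophyly is
#' attributable to taxa the reference does not contain; otherwise
#' \code{conflicting}. The compatibility rule is a formal proxy for expert
#' judgment and is labelled as such in the report.
#'
#' @param tree Focal \code{phylo} / \code{SupportTree}.
#' @param reference_tree Reference \code{phylo} (e.g. an rRNA phylogeny).
#' @param link_map Named character vector: focal leaf id -> reference leaf id
#'   (a subset of focal leaves).
#' @return data.frame: reference clade (comma-joined members), linked focal
#'   members, status; attribute \code{note} marks the proxy rule.
#' @export
sharedCladeCongruence <- function(tree, reference_tree, link_map) {
  if (length(link_map) == 0) stop("empty link map")
  if (methods::is(tree, "SupportTree")) tree <- treePhylo(tree)
  if (methods::is(reference_tree, "SupportTree"))
    reference_tree <- treePhylo(reference_tree)
  ntipR <- length(reference_tree$tip.label)
  tipsR <- .tipDescendants(reference_tree)
  nodesR <- (ntipR + 1L):(ntipR + reference_tree$Nnode)
  restricted <- ape::keep.tip(tree, names(link_map))
  out <- list()
  for (v in nodesR) {
    cladeR <- tipsR[[v]]
    if (length(cladeR) >= ntipR) next
    linked <- names(link_map)[link_map %in% cladeR]
    if (length(linked) < 2 || length(linked) >= length(link_map)) next
    status <- if (ape::is.monophyletic(tree, linked)) "congruent"
      else if (ape::is.monophyletic(restricted, linked)) "compatible"
      else "conflicting"
    out[[length(out) + 1L]] <- data.frame(
      reference_clade = paste(sort(cladeR), collapse = ","),
      linked_members = paste(sort(linked), collapse = ","),
      status = status)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(reference_clade = character(0), linked_members = character(0),
               status = character(0))
  attr(res, "note") <- "compatibility is a formal proxy for expert judgment"
  res
}
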