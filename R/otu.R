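#' @name otu_clustering
#' @title Average-neighbour OTU clustering
#'
#' @description
#' Pairwise identity distances over the common frame, average-neighbour
#' (average-linkage) agglomeration at a given identity threshold (96% for the
#' main OTU set, 97% for the chimera reference database, 99% for rRNA-style
#' use), and assignment of new sequences to existing OTUs.
NULL

#' Pairwise distance matrix over the common frame
#'
#' Distance is \code{1 - matches/compared}. Under the default gap policy
#' (\code{"exclude"}), columns gapped in either sequence of a pair are
#' excluded from both numerator and denominator; \code{"include"} scores gap
#' characters as ordinary (mis)matching states over all columns.
#'
#' @param genes \code{GeneSet}, \code{DNAStringSet} or named character vector
#'   of equal-width sequences.
#' @param gap_policy \code{"exclude"} (default) or \code{"include"}.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pairwiseDistances <- function(genes, gap_policy = c("exclude", "include")) {
  gap_policy <- match.arg(gap_policy)
  mat <- .charMatrix(genes)
  if (nrow(mat) < 2) warning("fewer than 2 sequences: degenerate matrix")
  mc <- .matchCounts(mat, gap_exclude = gap_policy == "exclude")
  d <- 1 - mc$matches / mc$compared
  diag(d) <- 0
  d
}

#' Average-neighbour clustering at an identity threshold
#'
#' Agglomerative average-linkage clustering: repeatedly merge the pair of
#' clusters with the smallest average inter-cluster distance while that
#' minimum is at most \code{1 - threshold_identity}. Ties take the
#' lowest-distance pair, then lexicographic cluster labels (a cluster is
#' labelled by its lexicographically smallest member id). The representative
#' of each OTU is the medoid (member minimising mean distance to co-members;
#' ties lexicographic).
#'
#' @param d Symmetric distance matrix with row/col names.
#' @param threshold_identity Identity threshold as a fraction (e.g. 0.96).
#' @return data.frame with columns \code{otu}, \code{member},
#'   \code{representative} (logical); OTUs are numbered \code{OTU001, ...} in
#'   order of their representative's id.
#' @export
averageNeighbour <- function(d, threshold_identity) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  ids <- rownames(d)
  cutoff <- 1 - threshold_identity
  members <- as.list(ids)
  sizes <- rep(1L, length(ids))
  D <- d
  labs <- ids
  while (length(members) > 1) {
    n <- length(members)
    Dm <- D; Dm[!upper.tri(Dm)] <- Inf
    mn <- min(Dm)
    if (mn > cutoff) break
    cand <- which(Dm == mn, arr.ind = TRUE)
    if (nrow(cand) > 1) { # tie: lexicographic on sorted label pairs
      keyOf <- function(i, j) paste(sort(c(labs[i], labs[j])), collapse = "\r")
      keys <- apply(cand, 1, function(rc) keyOf(rc[1], rc[2]))
      cand <- cand[order(keys)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    ni <- sizes[i]; nj <- sizes[j]
    newrow <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- ni + nj
    labs[i] <- min(c(labs[i], labs[j]))
    D[i, ] <- newrow; D[, i] <- newrow; D[i, i] <- 0
    members[[j]] <- NULL
    sizes <- sizes[-j]; labs <- labs[-j]
    D <- D[-j, -j, drop = FALSE]
  }
  reps <- vapply(members, function(m) {
    if (length(m) == 1) return(m)
    md <- rowMeans(d[m, m, drop = FALSE])
    sort(m[md == min(md)])[1]
  }, character(1))
  ord <- order(reps)
  out <- do.call(rbind, lapply(seq_along(ord), function(k) {
    m <- sort(members[[ord[k]]])
    data.frame(otu = sprintf("OTU%03d", k), member = m,
               representative = m == reps[ord[k]])
  }))
  rownames(out) <- NULL
  out
}

#' Assign new sequences to existing OTUs
#'
#' Each new gene is mapped to the OTU whose representative it matches at the
#' highest identity, provided that identity is at least \code{min_identity}
#' (strictly applied at the boundary); otherwise it is \code{"unassigned"}.
#'
#' @param new_genes \code{GeneSet} or named character vector in the common
#'   frame.
#' @param otus data.frame from \code{\link{averageNeighbour}}.
#' @param representatives Named character vector of representative sequences
#'   (same frame), named by member id.
#' @param min_identity Assignment threshold (default 0.96).
#' @return List with \code{assignments} (data.frame id/otu/identity) and
#'   \code{assignable_fraction}.
#' @export
assignToOtus <- function(new_genes, otus, representatives, min_identity = 0.96) {
  if (nrow(otus) == 0) stop("empty OTU set")
  if (methods::is(new_genes, "GeneSet"))
    new_genes <- stats::setNames(as.character(geneSeqs(new_genes)),
                                 geneIds(new_genes))
  repIds <- otus$member[otus$representative]
  otuOfRep <- stats::setNames(otus$otu[otus$representative], repIds)
  reps <- representatives[repIds]
  repMat <- .charMatrix(reps)
  out <- lapply(names(new_genes), function(id) {
    q <- strsplit(new_genes[[id]], "")[[1]]
    idents <- apply(repMat, 1, function(r) .pairIdentity(q, r))
    best <- which.max(idents)
    if (idents[best] >= min_identity) {
      data.frame(id = id, otu = unname(otuOfRep[repIds[best]]),
                 identity = unname(idents[best]))
    } else {
      data.frame(id = id, otu = "unassigned", identity = unname(idents[best]))
    }
  })
  out <- do.call(rbind, out)
  list(assignments = out,
       assignable_fraction = mean(out$otu != "unassigned"))
}
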