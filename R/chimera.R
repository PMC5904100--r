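#' @name chimera_screen
#' @title Reference-based two-parent chimera screening
#'
#' @description
#' Assembles a trusted reference database by abundance and identity
#' corroboration rules, then flags two-parent (bimeric) PCR artefacts with a
#' divergence (\code{d}) plus vote-score (\code{h}) decision rule at the
#' thresholds \code{mindiv = 1.7} and \code{minh = 0.10}.
#'
#' @details
#' The scorer contract: for a query Q and candidate parents A, B the chimeric
#' model at breakpoint b is \code{M(A,B,b) = A[1..b] + B[b+1..L]}. The best
#' model maximises the number of columns matching Q (ties: smallest b, then
#' lexicographic (A,B)). With \code{mQM} the matching columns of Q against the
#' best model and \code{mQT} against the better single parent of the reported
#' pair, \code{d = 100 (mQM - mQT)/L}. The vote score is computed on the
#' informative columns, i.e. those where the model and the better parent T
#' disagree: per side of b, Y counts columns where Q matches the model, N
#' where Q matches T, A where Q matches neither, and
#' \code{h_side = Y / (Y + beta N + gamma A)} with defaults beta = 8,
#' gamma = 0.5. \code{h} is the minimum over the sides that carry informative
#' columns (a side without any cannot veto); with no informative column at
#' all, \code{h = 0}. The decision is chimeric iff \code{d >= mindiv} and
#' \code{h >= minh}.
NULL

#' Chimera scorer parameters
#'
#' @param mindiv Minimum divergence percent (default 1.7).
#' @param minh Minimum vote score (default 0.10).
#' @param top_k_parents Candidate parents considered per query (default 6).
#' @param beta,gamma Vote weights for no-votes and abstentions.
#' @param candidate_gate Minimum query identity for a reference to be a
#'   candidate parent (default 0.80).
#' @return List of validated parameters.
#' @export
chimeraParams <- function(mindiv = 1.7, minh = 0.10, top_k_parents = 6L,
                          beta = 8, gamma = 0.5, candidate_gate = 0.80) {
  stopifnot(mindiv >= 0, minh >= 0, minh <= 1, top_k_parents >= 2)
  list(mindiv = mindiv, minh = minh, top_k_parents = as.integer(top_k_parents),
       beta = beta, gamma = gamma, candidate_gate = candidate_gate)
}

#' Build the trusted chimera reference database
#'
#' Members are admitted by (i) abundance: dereplicated multiplicity at least
#' \code{min_abundance}; (ii) identity corroboration: at least two matches at
#' \code{corroborate_identity} or better, at least one from an independent
#' study; or (iii) genome derivation (flagged input). The admitted set is then
#' clustered at \code{cluster_identity} by average-neighbour clustering and
#' represented by medoids, so no two database members exceed that identity.
#'
#' @param genes Named character vector / \code{GeneSet} of unique sequences in
#'   the common frame.
#' @param multiplicity Named integer vector (dereplication counts).
#' @param study_of Named character vector mapping gene id to study id.
#' @param genome_ids Character vector of ids flagged as genome-derived.
#' @param min_abundance Abundance rule threshold (default 5).
#' @param corroborate_identity Corroboration identity (default 0.99).
#' @param cluster_identity Final clustering identity (default 0.97).
#' @return List with \code{db} (named character vector of member sequences),
#'   \code{provenance} (data.frame id/rule) and \code{clusters}.
#' @export
buildReferenceDb <- function(genes, multiplicity, study_of,
                             genome_ids = character(0),
                             min_abundance = 5L, corroborate_identity = 0.99,
                             cluster_identity = 0.97) {
  if (methods::is(genes, "GeneSet"))
    genes <- stats::setNames(as.character(geneSeqs(genes)), geneIds(genes))
  ids <- names(genes)
  byAbundance <- ids[multiplicity[ids] >= min_abundance]
  byAbundance <- byAbundance[!is.na(byAbundance)]
  d <- pairwiseDistances(genes)
  ident <- 1 - d
  byCorrob <- character(0)
  for (id in ids) {
    hits <- ids[ident[id, ] >= corroborate_identity & ids != id]
    if (length(hits) >= 2 && any(study_of[hits] != study_of[id]))
      byCorrob <- c(byCorrob, id)
  }
  admitted <- unique(c(byAbundance, byCorrob, intersect(genome_ids, ids)))
  if (length(admitted) == 0) stop("no-reference: no sequence admitted")
  prov <- data.frame(
    id = admitted,
    rule = vapply(admitted, function(id) {
      if (id %in% byAbundance) "abundance>=5"
      else if (id %in% byCorrob) "identity-corroborated"
      else "genome"
    }, character(1)))
  if (length(admitted) > 1) {
    cl <- averageNeighbour(d[admitted, admitted, drop = FALSE],
                           threshold_identity = cluster_identity)
    keep <- cl$member[cl$representative]
  } else {
    cl <- data.frame(otu = "OTU001", member = admitted, representative = TRUE)
    keep <- admitted
  }
  list(db = genes[keep], provenance = prov, clusters = cl)
}

#' Score one query against the reference database
#'
#' Candidate parents are references at \code{candidate_gate} identity or
#' better, ranked by shared 8-mer count, top \code{top_k_parents} retained.
#' Every ordered candidate pair and every breakpoint column is searched for
#' the best two-parent model (see the module description for d and h).
#'
#' @param query Coding sequence in the common frame (character string).
#' @param db Named character vector of reference sequences (common frame).
#' @param params \code{\link{chimeraParams}} list.
#' @param query_id Optional id used in the verdict row.
#' @param .db_kmers,.db_mat Precomputed database k-mer presence and
#'   character matrices (internal batch optimisation).
#' @return One-row data.frame: query, parent_a, parent_b, breakpoint, d, h,
#'   decision (\code{chimeric}/\code{clean}/\code{no-parents}).
#' @export
scoreQuery <- function(query, db, params = chimeraParams(), query_id = "query",
                       .db_kmers = NULL, .db_mat = NULL) {
  if (length(db) == 0) stop("empty reference database")
  query <- as.character(query)
  L <- nchar(db[[1]])
  if (nchar(query) != L) stop("query does not share the reference frame")
  q <- strsplit(query, "")[[1]]
  dbMat <- if (is.null(.db_mat)) .charMatrix(db) else .db_mat
  idents <- apply(dbMat, 1, function(r) .pairIdentity(q, r))
  cand <- names(db)[idents >= params$candidate_gate]
  verdict <- function(pa, pb, b, d, h, dec)
    data.frame(query = query_id, parent_a = pa, parent_b = pb,
               breakpoint = b, d = d, h = h, decision = dec)
  if (length(cand) < 2)
    return(verdict(NA_character_, NA_character_, NA_integer_,
                   NA_real_, NA_real_, "no-parents"))
  shared <- .sharedKmers(query, db[cand],
                         ref_kmers = if (is.null(.db_kmers)) NULL
                                     else .db_kmers[cand, , drop = FALSE])
  cand <- cand[order(-shared, cand)][seq_len(min(params$top_k_parents,
                                                 length(cand)))]
  match <- lapply(cand, function(id) q == dbMat[id, ])
  names(match) <- cand
  best <- NULL
  for (a in cand) for (b2 in cand) {
    if (a == b2) next
    cumA <- cumsum(match[[a]])
    sufB <- sum(match[[b2]]) - cumsum(match[[b2]])
    sc <- cumA[seq_len(L - 1)] + sufB[seq_len(L - 1)]
    bk <- which.max(sc) # which.max takes the smallest index on ties
    cur <- list(a = a, b = b2, bk = bk, m = sc[bk])
    if (is.null(best) || cur$m > best$m ||
        (cur$m == best$m && (cur$bk < best$bk ||
          (cur$bk == best$bk &&
           paste(cur$a, cur$b) < paste(best$a, best$b)))))
      best <- cur
  }
  A <- dbMat[best$a, ]; B <- dbMat[best$b, ]; bk <- best$bk
  model <- c(A[seq_len(bk)], B[(bk + 1):L])
  mQM <- sum(q == model)
  mA <- sum(match[[best$a]]); mB <- sum(match[[best$b]])
  tid <- if (mB > mA) best$b else best$a
  tpar <- dbMat[tid, ]
  mQT <- max(mA, mB)
  d <- 100 * (mQM - mQT) / L
  info <- model != tpar
  side <- seq_len(L) <= bk
  hs <- vapply(c(TRUE, FALSE), function(left) {
    idx <- which(info & (side == left))
    if (length(idx) == 0) return(NA_real_)
    Y <- sum(q[idx] == model[idx])
    N <- sum(q[idx] == tpar[idx])
    Ab <- length(idx) - Y - N
    Y / (Y + params$beta * N + params$gamma * Ab)
  }, numeric(1))
  h <- if (all(is.na(hs))) 0 else min(hs, na.rm = TRUE)
  dec <- if (!is.na(d) && d >= params$mindiv && h >= params$minh)
    "chimeric" else "clean"
  verdict(best$a, best$b, bk, d, h, dec)
}

#' Screen a full gene set for chimeras
#'
#' Every gene receives a verdict; chimeric genes are removed from the
#' downstream set unless whitelisted (verified false positives re-admitted).
#'
#' @param genes Named character vector / \code{GeneSet} of queries.
#' @param db Reference database (named character vector, e.g.
#'   \code{buildReferenceDb(...)$db}).
#' @param params \code{\link{chimeraParams}}.
#' @param whitelist Ids retained regardless of verdict.
#' @return List with \code{verdicts} (data.frame, one row per gene, plus a
#'   \code{whitelisted} flag and an empty \code{external_label} slot for
#'   second-opinion methods) and \code{kept} (ids passing the screen).
#' @export
screenChimeras <- function(genes, db, params = chimeraParams(),
                           whitelist = character(0)) {
  if (methods::is(genes, "GeneSet"))
    genes <- stats::setNames(as.character(geneSeqs(genes)), geneIds(genes))
  dbK <- .kmerPresence(db)
  dbM <- .charMatrix(db)
  rows <- lapply(names(genes), function(id)
    scoreQuery(genes[[id]], db, params, query_id = id, .db_kmers = dbK,
               .db_mat = dbM))
  v <- do.call(rbind, rows)
  v$whitelisted <- v$query %in% whitelist
  v$external_label <- NA_character_
  kept <- v$query[v$decision != "chimeric" | v$whitelisted]
  list(verdicts = v, kept = kept)
}

#' Branch-length outlier report
#'
#' Flags leaves on unusually long terminal branches (a screening aid for the
#' manual, judgment-based tree inspection step; no automatic removal).
#'
#' @param st A \code{SupportTree}.
#' @param z Robust z-score threshold (default 3).
#' @return data.frame leaf/branch_length/z.
#' @export
branchLengthOutliers <- function(st, z = 3) {
  phy <- treePhylo(st)
  tipEdge <- match(seq_along(phy$tip.label), phy$edge[, 2])
  bl <- phy$edge.length[tipEdge]
  med <- stats::median(bl); madv <- stats::mad(bl)
  zz <- if (madv > 0) (bl - med) / madv else rep(0, length(bl))
  out <- data.frame(leaf = phy$tip.label, branch_length = bl, z = zz)
  out[out$z > z, , drop = FALSE]
}
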