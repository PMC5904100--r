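# exhaustive all-pairs x all-breakpoints oracle sharing only the published
# scorer contract (not the implementation): returns the best (A, B, b) and d
bruteForceScorer <- function(query, db, beta = 8, gamma = 0.5) {
  q <- strsplit(query, "")[[1]]
  L <- length(q)
  cands <- expand.grid(a = names(db), b = names(db),
                       stringsAsFactors = FALSE)
  cands <- cands[cands$a != cands$b, ]
  rows <- list()
  for (i in seq_len(nrow(cands))) {
    A <- strsplit(db[[cands$a[i]]], "")[[1]]
    B <- strsplit(db[[cands$b[i]]], "")[[1]]
    for (bk in 1:(L - 1)) {
      model <- c(A[1:bk], B[(bk + 1):L])
      rows[[length(rows) + 1]] <- data.frame(
        a = cands$a[i], b = cands$b[i], bk = bk, m = sum(q == model))
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$m, tab$bk, tab$a, tab$b), ]
  best <- tab[1, ]
  A <- strsplit(db[[best$a]], "")[[1]]
  B <- strsplit(db[[best$b]], "")[[1]]
  mQT <- max(sum(q == A), sum(q == B))
  list(a = best$a, b = best$b, bk = best$bk,
       d = 100 * (best$m - mQT) / L)
}

# independent bipartition bookkeeping using bitmasks over the leaf set,
# used to recompute IC/TC from scratch
bitSplits <- function(phy, leaves) {
  ntip <- length(phy$tip.label)
  desc <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- phy$tip.label[i]
  for (e in ape::postorder(phy))
    desc[[phy$edge[e, 1]]] <- c(desc[[phy$edge[e, 1]]], desc[[phy$edge[e, 2]]])
  masks <- vapply(desc, function(m)
    sum(2^(match(m, leaves) - 1)), numeric(1))
  full <- sum(2^(seq_along(leaves) - 1))
  internal <- setdiff((ntip + 1):(ntip + phy$Nnode), ntip + 1)
  ms <- masks[internal]
  ms <- vapply(ms, function(m)
    if (bitwAnd(m, 1) == 1) full - m else m, numeric(1))
  ms[ms != 0 & vapply(ms, function(m) sum(bitwAnd(m, 2^(0:30)) > 0),
                      numeric(1)) >= 2 &
       vapply(ms, function(m) sum(bitwAnd(full - m, 2^(0:30)) > 0),
              numeric(1)) >= 2]
}

bitConflict <- function(m1, m2, full) {
  bitwAnd(m1, m2) != 0 && bitwAnd(m1, full - m2) != 0 &&
    bitwAnd(full - m1, m2) != 0 && bitwAnd(full - m1, full - m2) != 0
}

oracleTc <- function(focal, trees, leaves) {
  full <- sum(2^(seq_along(leaves) - 1))
  counts <- table(unlist(lapply(trees, function(t)
    unique(bitSplits(t, leaves)))))
  tc <- 0
  for (m in bitSplits(focal, leaves)) {
    f1 <- if (as.character(m) %in% names(counts))
      counts[[as.character(m)]] / length(trees) else 0
    confl <- names(counts)[vapply(names(counts), function(x)
      bitConflict(as.numeric(x), m, full), logical(1))]
    f2 <- if (length(confl)) max(counts[confl]) / length(trees) else 0
    if (f2 == 0) { tc <- tc + 1; next }
    p1 <- f1 / (f1 + f2); p2 <- f2 / (f1 + f2)
    ent <- function(p) if (p > 0) p * log2(p) else 0
    ic <- 1 + ent(p1) + ent(p2)
    tc <- tc + if (f2 > f1) -ic else ic
  }
  tc
}
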