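# shared fixture builders; everything is generated in code

# random in-frame coding sequence (no internal stops) of n codons
randCodingSeq <- function(n_codons = 197L) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# a sequence with k mismatches relative to `base` at distinct positions
variantOf <- function(base, k, positions = NULL) {
  v <- strsplit(base, "")[[1]]
  if (is.null(positions)) positions <- sample(seq_along(v), k)
  for (i in positions) {
    alt <- setdiff(c("A", "C", "G", "T"), v[i])
    cand <- alt[!vapply(alt, function(b) {
      w <- v; w[i] <- b
      cd <- (i - 1) %/% 3
      paste(w[(3 * cd + 1):(3 * cd + 3)], collapse = "") %in%
        c("TAA", "TAG", "TGA")
    }, logical(1))]
    v[i] <- cand[1]
  }
  paste(v, collapse = "")
}

# tiny support tree from a newick string with "uf/sh" internal labels
supTree <- function(text) readSupportTree(text = text)

# naive O(n^3) average-linkage oracle: recompute every cluster-pair average
# from the original matrix at each step (independent of the implementation's
# running UPGMA update)
naiveAverageNeighbour <- function(d, threshold_identity) {
  cutoff <- 1 - threshold_identity
  clusters <- lapply(rownames(d), identity)
  repeat {
    n <- length(clusters)
    if (n == 1) break
    bestVal <- Inf; bestPair <- NULL
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      avg <- mean(d[clusters[[i]], clusters[[j]]])
      key <- paste(sort(c(min(clusters[[i]]), min(clusters[[j]]))),
                   collapse = "\r")
      if (avg < bestVal - 1e-12 ||
          (abs(avg - bestVal) <= 1e-12 && !is.null(bestPair) &&
           key < bestPair$key)) {
        bestVal <- avg; bestPair <- list(i = i, j = j, key = key)
      }
    }
    if (bestVal > cutoff) break
    clusters[[bestPair$i]] <- c(clusters[[bestPair$i]],
                                clusters[[bestPair$j]])
    clusters[[bestPair$j]] <- NULL
  }
  lapply(clusters, sort)
}

# partition of an averageNeighbour result as a canonical list
asPartition <- function(otus) {
  unname(lapply(split(otus$member, otus$otu), sort))
}

canonicalPartition <- function(parts) {
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, `[`, character(1), 1))]
}
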