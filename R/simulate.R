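#' @name synthetic_data
#' @title Synthetic marker-gene data with known ground truth
#'
#' @description
#' Generates every input the pipeline consumes — clade-structured trees with
#' dual branch supports, in-frame 591-nt coding sequences with clade-specific
#' GC and codon usage, two-parent chimeras with known breakpoints, corrupted
#' raw records (frameshifts, premature stops, truncations, reverse
#' complements) and multi-level habitat annotations — under one seed, with
#' registries recording the ground truth for every sequence.
NULL

#' Simulation configuration
#'
#' @param seed Integer seed fixing all outputs bit-identically.
#' @param n_clades Number of order-level clades (>= 2).
#' @param otus_per_clade Leaves (OTU representatives) per terminal clade.
#' @param subclades_per_clade 0 for flat orders, a single count, or a
#'   \code{c(min, max)} range sampled per order.
#' @param seqs_per_otu Sequences generated per OTU (the first is the
#'   representative itself).
#' @param frame_length_codons Coding-frame length in codons (default 197,
#'   i.e. the 591-nt core).
#' @param per_clade_gc_target GC fraction targets, recycled over orders.
#' @param mutation_rate Substitutions per site per branch-length unit.
#' @param within_otu_divergence Per-site mutation probability for OTU
#'   members relative to their representative.
#' @param chimera_fraction Fraction of the clean pool emitted as bimeras.
#' @param min_parent_divergence Minimum parent divergence for chimeras.
#' @param max_parent_divergence Maximum parent divergence (default 0.25):
#'   PCR chimeras arise between co-amplified, relatively similar templates,
#'   and 0.25 keeps both parents of any central-window bimera within the
#'   scorer's 80\% candidate gate (1 - 0.25 x 0.8 = 0.80).
#' @param breakpoint_window Central fraction of columns eligible as
#'   breakpoints (default 0.6).
#' @param corruption_spec Rates: \code{frameshift}, \code{stop},
#'   \code{truncation} (each in [0,1], summing below 1) and \code{revcomp}
#'   (probability a raw record is emitted reverse-complemented).
#' @param decoy_support_fraction Fraction of non-clade internal branches
#'   drawn with supra-threshold support (default 0: only true clades are
#'   supported).
#' @param n_studies Number of study labels sampled for metadata.
#' @return Validated configuration list.
#' @export
simConfig <- function(seed = 1L, n_clades = 4L, otus_per_clade = 5L,
                      subclades_per_clade = 0L, seqs_per_otu = 5L,
                      frame_length_codons = 197L,
                      per_clade_gc_target = c(0.40, 0.46, 0.52, 0.58),
                      mutation_rate = 1.0, within_otu_divergence = 0.01,
                      chimera_fraction = 0.1, min_parent_divergence = 0.05,
                      max_parent_divergence = 0.25, breakpoint_window = 0.6,
                      corruption_spec = list(frameshift = 0.05, stop = 0.05,
                                             truncation = 0.05,
                                             revcomp = 0.5),
                      decoy_support_fraction = 0, n_studies = 6L) {
  cfg <- as.list(environment())
  fr <- c(chimera_fraction, breakpoint_window, decoy_support_fraction,
          unlist(corruption_spec), per_clade_gc_target,
          within_otu_divergence)
  if (any(fr < 0 | fr > 1)) stop("configuration error: fractions must lie in [0,1]")
  if (n_clades < 2) stop("configuration error: n_clades must be >= 2")
  if (sum(unlist(corruption_spec[c("frameshift", "stop", "truncation")])) > 1)
    stop("configuration error: corruption rates exceed 1")
  if (frame_length_codons < 2) stop("configuration error: frame too short")
  cfg$per_clade_gc_target <- rep_len(per_clade_gc_target, n_clades)
  cfg
}

# per-family codon probabilities targeting a GC fraction (stops excluded)
.codonWeightsFromGc <- function(gc) {
  pb <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  fams <- .codonFamilies()
  lapply(fams, function(cods) {
    w <- vapply(cods, function(cd) {
      prod(pb[strsplit(cd, "")[[1]]])
    }, numeric(1))
    w / sum(w)
  })
}

# sample an in-frame coding sequence (uniform amino acids, codons from the
# per-family weight vectors), then pin its GC to the clade target by
# directed codon resampling: first two codon positions are largely fixed by
# the genetic code, so raw sampling alone cannot reach extreme targets
.sampleAncestor <- function(n_codons, weights, gc_target = NULL,
                            tol = 0.005) {
  fams <- .codonFamilies()
  aas <- sample(names(fams), n_codons, replace = TRUE)
  cods <- vapply(aas, function(aa)
    sample(fams[[aa]], 1, prob = weights[[aa]]), character(1))
  if (!is.null(gc_target)) {
    gcOf <- function(cd) vapply(strsplit(cd, ""), function(v)
      sum(v %in% c("G", "C")), numeric(1))
    cur <- sum(gcOf(cods)) / (3 * n_codons)
    for (it in seq_len(50L * n_codons)) {
      if (abs(cur - gc_target) <= tol) break
      i <- sample(n_codons, 1)
      aa <- sample(names(fams), 1)
      new <- sample(fams[[aa]], 1, prob = weights[[aa]])
      delta <- (gcOf(new) - gcOf(cods[i])) / (3 * n_codons)
      if ((cur < gc_target && delta > 0) || (cur > gc_target && delta < 0)) {
        cods[i] <- new
        cur <- cur + delta
      }
    }
  }
  paste(cods, collapse = "")
}

# mutate a character vector of bases at per-site probability p with a
# GC-biased replacement distribution; mutations creating stops are reverted
.mutateChars <- function(v, p, gc) {
  if (p <= 0) return(v)
  pb <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  hit <- which(stats::runif(length(v)) < p)
  for (i in hit) {
    alt <- setdiff(names(pb), v[i])
    new <- sample(alt, 1, prob = pb[alt])
    old <- v[i]
    v[i] <- new
    cd <- (i - 1L) %/% 3L
    codon <- paste(v[(3L * cd + 1L):(3L * cd + 3L)], collapse = "")
    if (codon %in% STOP_CODONS) v[i] <- old
  }
  v
}

.rsup <- function(high, n = 1L) {
  if (high) {
    uf <- stats::runif(n, 95, 100); sh <- stats::runif(n, 85, 100)
  } else {
    kind <- sample(1:3, n, replace = TRUE)
    uf <- ifelse(kind == 2, stats::runif(n, 95, 100), stats::runif(n, 40, 94.5))
    sh <- ifelse(kind == 1, stats::runif(n, 85, 100), stats::runif(n, 30, 84.5))
  }
  sprintf("%.2f/%.2f", pmin(uf, 100), pmin(sh, 100))
}

# join subtree strings pairwise at random into one node; internal joins get
# decoy-regime supports (high with probability decoy_fraction)
.binaryJoin <- function(items, isLeaf, leaf_bl = c(0.04, 0.08),
                        int_bl = c(0.02, 0.05), decoy_fraction = 0) {
  asChild <- function(k) {
    bl <- if (isLeaf[k]) stats::runif(1, leaf_bl[1], leaf_bl[2])
          else stats::runif(1, int_bl[1], int_bl[2])
    lab <- if (isLeaf[k]) "" else
      .rsup(stats::runif(1) < decoy_fraction)
    paste0(items[k], lab, ":", sprintf("%.6f", bl))
  }
  while (length(items) > 1) {
    pick <- sample(length(items), 2)
    joined <- paste0("(", asChild(pick[1]), ",", asChild(pick[2]), ")")
    items <- c(items[-pick], joined)
    isLeaf <- c(isLeaf[-pick], FALSE)
  }
  items
}

#' Simulate a support-labelled tree with known clade structure
#'
#' Builds a rooted bifurcating tree of order-level clades (optionally with
#' supported subclades), draws UFBoot/SH-aLRT pairs — true clade stems from
#' the high regime, all other internal branches sub-threshold except a
#' \code{decoy_support_fraction} — and records the rank labels implied by the
#' constructed clades as the true taxonomy (the generator's own labelling,
#' independent of the taxonomy engine).
#'
#' @param config \code{\link{simConfig}} output.
#' @param .reseed Set \code{FALSE} to use the current RNG state (internal
#'   orchestration).
#' @return List: \code{tree} (\code{SupportTree}), \code{truth} with
#'   \code{taxonomy} (leaf -> rank name), \code{seeds} (anchor leaf ->
#'   prefix), \code{orders} and \code{subclades} tables.
#' @export
simulateTree <- function(config, .reseed = TRUE) {
  if (config$n_clades < 2) stop("configuration error: n_clades must be >= 2")
  if (.reseed) set.seed(config$seed)
  prefixes <- c("NC", "NS", "NT", "NP",
                paste0("OR", seq_len(max(0, config$n_clades - 4)) + 4))
  prefixes <- prefixes[seq_len(config$n_clades)]
  scc <- config$subclades_per_clade
  orders <- list(); subRows <- list()
  orderStrs <- character(0)
  for (ci in seq_along(prefixes)) {
    p <- prefixes[ci]
    nsub <- if (length(scc) == 2) sample(scc[1]:scc[2], 1) else scc
    if (nsub >= 1) {
      subStrs <- character(0); leafCount <- 0L
      for (si in seq_len(nsub)) {
        leaves <- sprintf("%s_%02d", p, leafCount + seq_len(config$otus_per_clade))
        leafCount <- leafCount + config$otus_per_clade
        str <- .binaryJoin(leaves, rep(TRUE, length(leaves)),
                           decoy_fraction = config$decoy_support_fraction)
        stem <- stats::runif(1, 0.05, 0.20)
        subStrs[si] <- if (length(leaves) == 1) {
          paste0(leaves, ":", sprintf("%.6f", stem))
        } else {
          paste0(str, .rsup(TRUE), ":", sprintf("%.6f", stem))
        }
        subRows[[length(subRows) + 1L]] <-
          data.frame(order = p, subclade = si, stem = stem,
                     n_leaves = length(leaves),
                     members = I(list(sort(leaves))))
      }
      str <- .binaryJoin(subStrs, rep(FALSE, length(subStrs)),
                         decoy_fraction = config$decoy_support_fraction)
      # subclade stems are already attached; joins above them are decoys,
      # except the order stem appended below
      ostem <- stats::runif(1, 0.30, 0.50)
      allLeaves <- sprintf("%s_%02d", p, seq_len(leafCount))
    } else {
      allLeaves <- sprintf("%s_%02d", p, seq_len(config$otus_per_clade))
      str <- .binaryJoin(allLeaves, rep(TRUE, length(allLeaves)),
                         decoy_fraction = config$decoy_support_fraction)
      ostem <- stats::runif(1, 0.30, 0.50)
    }
    orderStrs[ci] <- paste0(str, .rsup(TRUE), ":", sprintf("%.6f", ostem))
    orders[[ci]] <- data.frame(order = p, stem = ostem,
                               members = I(list(sort(allLeaves))))
  }
  root <- .binaryJoin(orderStrs, rep(FALSE, length(orderStrs)),
                      decoy_fraction = config$decoy_support_fraction)
  nw <- paste0(root, ";")
  st <- readSupportTree(text = nw)
  ordersDf <- do.call(rbind, orders)
  subDf <- if (length(subRows)) do.call(rbind, subRows) else NULL
  truth <- .truthTaxonomy(ordersDf, subDf)
  seeds <- stats::setNames(
    vapply(ordersDf$members, `[`, character(1), 1), NULL)
  seeds <- stats::setNames(ordersDf$order, seeds)
  seeds <- stats::setNames(as.character(seeds), names(seeds))
  list(tree = st,
       truth = list(taxonomy = truth, seeds = seeds,
                    orders = ordersDf, subclades = subDf))
}

# the generator's own labelling of the clades it constructed (two levels):
# eligible subclades (>=3 leaves) get Greek labels by descending stem length
# when at least two need distinguishing; 2-leaf subclades become -IS
.truthTaxonomy <- function(ordersDf, subDf) {
  out <- character(0)
  for (i in seq_len(nrow(ordersDf))) {
    p <- ordersDf$order[i]
    leaves <- ordersDf$members[[i]]
    lab <- stats::setNames(rep(p, length(leaves)), leaves)
    if (!is.null(subDf)) {
      sc <- subDf[subDf$order == p, , drop = FALSE]
      elig <- sc[sc$n_leaves >= 3, , drop = FALSE]
      if (nrow(elig) >= 2) {
        elig <- elig[order(-elig$stem, -elig$n_leaves,
                           vapply(elig$members, `[`, character(1), 1)), ]
        for (k in seq_len(nrow(elig)))
          lab[elig$members[[k]]] <- paste0(p, "-", .greekLabel(k))
      }
      isc <- sc[sc$n_leaves == 2, , drop = FALSE]
      if (nrow(isc)) {
        isc <- isc[order(-isc$stem, -isc$n_leaves,
                         vapply(isc$members, `[`, character(1), 1)), ]
        for (k in seq_len(nrow(isc)))
          lab[isc$members[[k]]] <- paste0(p, "-IS", if (k > 1) k else "")
      }
    }
    out <- c(out, lab)
  }
  out
}

#' Evolve clade-structured coding sequences down a simulated tree
#'
#' One ancestral in-frame sequence per order clade is drawn from that
#' clade's GC-targeted codon weights; descendants accumulate GC-biased
#' substitutions proportional to branch length (stops always rejected), and
#' each leaf (OTU representative) spawns \code{seqs_per_otu} members, the
#' first an exact copy.
#'
#' @param sim Output of \code{\link{simulateTree}}.
#' @param config \code{\link{simConfig}} output.
#' @param .reseed See \code{\link{simulateTree}}.
#' @return List: \code{genes} (\code{GeneSet} of all member sequences, with
#'   otu/clade/study metadata), \code{representatives} (named character per
#'   leaf), \code{otu_of_seq} (named character).
#' @export
evolveSequences <- function(sim, config, .reseed = TRUE) {
  if (.reseed) set.seed(config$seed + 1L)
  st <- sim$tree
  phy <- treePhylo(st)
  if (length(phy$tip.label) < 2) stop("tree must have at least 2 leaves")
  ordersDf <- sim$truth$orders
  L <- 3L * config$frame_length_codons
  kids <- .childrenList(phy)
  lens <- .stemLengths(phy)
  tips <- .tipDescendants(phy)
  repSeq <- character(0)
  for (i in seq_len(nrow(ordersDf))) {
    gc <- config$per_clade_gc_target[i]
    w <- .codonWeightsFromGc(gc)
    members <- ordersDf$members[[i]]
    node <- if (length(members) == 1) match(members, phy$tip.label)
            else ape::getMRCA(phy, members)
    anc <- strsplit(.sampleAncestor(config$frame_length_codons, w,
                                    gc_target = gc), "")[[1]]
    walk <- function(v, seqv) {
      if (v <= length(phy$tip.label)) {
        repSeq[phy$tip.label[v]] <<- paste(seqv, collapse = "")
        return(invisible())
      }
      for (ch in kids[[v]]) {
        p <- min(0.75, config$mutation_rate * lens[ch])
        walk(ch, .mutateChars(seqv, p, gc))
      }
    }
    walk(node, anc)
  }
  ids <- character(0); seqs <- character(0)
  otu <- character(0); clade <- character(0)
  for (leaf in phy$tip.label) {
    pref <- sub("_.*$", "", leaf)
    base <- strsplit(repSeq[[leaf]], "")[[1]]
    gc <- config$per_clade_gc_target[match(pref, ordersDf$order)]
    for (k in seq_len(config$seqs_per_otu)) {
      id <- sprintf("%s_s%02d", leaf, k)
      sq <- if (k == 1) repSeq[[leaf]] else
        paste(.mutateChars(base, config$within_otu_divergence, gc),
              collapse = "")
      ids <- c(ids, id); seqs <- c(seqs, sq)
      otu <- c(otu, leaf); clade <- c(clade, pref)
    }
  }
  study <- sprintf("study%02d", sample(config$n_studies, length(ids),
                                       replace = TRUE))
  genes <- geneSet(stats::setNames(seqs, ids),
                   meta = data.frame(otu = otu, clade = clade, study = study))
  list(genes = genes, representatives = repSeq,
       otu_of_seq = stats::setNames(otu, ids))
}

#' Generate two-parent chimeras with a known registry
#'
#' Each chimera joins columns 1..b of parent A to b+1..L of parent B, with b
#' uniform in the central \code{breakpoint_window} fraction of columns and
#' parent divergence inside \code{[min_parent_divergence,
#' max_parent_divergence]} (chimeras form between co-amplified, related
#' templates).
#'
#' @param genes \code{GeneSet} or named character pool of clean sequences.
#' @param fraction Fraction of the pool emitted as chimeras.
#' @param min_parent_divergence Minimum pairwise parent distance.
#' @param max_parent_divergence Maximum pairwise parent distance (see
#'   \code{\link{simConfig}}).
#' @param seed Optional seed (NULL uses the current RNG state).
#' @param breakpoint_window Central window fraction (default 0.6).
#' @return List: \code{chimeras} (named character) and \code{registry}
#'   (data.frame id/parent_a/parent_b/breakpoint).
#' @export
makeChimeras <- function(genes, fraction, min_parent_divergence = 0.05,
                         max_parent_divergence = 0.25, seed = NULL,
                         breakpoint_window = 0.6) {
  if (!is.null(seed)) set.seed(seed)
  if (methods::is(genes, "GeneSet"))
    genes <- stats::setNames(as.character(geneSeqs(genes)), geneIds(genes))
  if (length(genes) < 2) stop("generation error: need at least 2 parents")
  n <- round(fraction * length(genes))
  reg <- data.frame(id = character(0), parent_a = character(0),
                    parent_b = character(0), breakpoint = integer(0))
  if (n == 0) return(list(chimeras = character(0), registry = reg))
  d <- pairwiseDistances(genes)
  elig <- which(d >= min_parent_divergence & d <= max_parent_divergence &
                  upper.tri(d), arr.ind = TRUE)
  if (nrow(elig) == 0)
    stop("generation error: no parent pair above min_parent_divergence")
  L <- nchar(genes[[1]])
  lo <- max(1L, floor(L * (1 - breakpoint_window) / 2))
  hi <- min(L - 1L, ceiling(L * (1 + breakpoint_window) / 2))
  pick <- elig[sample(nrow(elig), n, replace = n > nrow(elig)), , drop = FALSE]
  chim <- character(0)
  for (k in seq_len(n)) {
    a <- rownames(d)[pick[k, 1]]; b <- rownames(d)[pick[k, 2]]
    if (stats::runif(1) < 0.5) { tmp <- a; a <- b; b <- tmp }
    bk <- sample(lo:hi, 1)
    id <- sprintf("chim%03d", k)
    chim[id] <- paste0(substr(genes[[a]], 1, bk),
                       substr(genes[[b]], bk + 1, L))
    reg <- rbind(reg, data.frame(id = id, parent_a = a, parent_b = b,
                                 breakpoint = bk))
  }
  list(chimeras = chim, registry = reg)
}

#' Corrupt clean sequences into raw records
#'
#' Applies at most one corruption per record — a 1-2 nt indel frameshift, a
#' premature stop codon, or a truncation below 582 nt — and independently
#' emits a reverse-complemented copy with the configured probability. Every
#' record is logged with its corruption type (\code{clean}, \code{frameshift},
#' \code{stop}, \code{short}).
#'
#' @param genes \code{GeneSet} or named character vector of clean in-frame
#'   sequences.
#' @param corruption_spec See \code{\link{simConfig}}.
#' @param seed Optional seed.
#' @return List: \code{records} (named character raw sequences) and
#'   \code{registry} (data.frame id/type/revcomp).
#' @export
corruptSequences <- function(genes, corruption_spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (methods::is(genes, "GeneSet"))
    genes <- stats::setNames(as.character(geneSeqs(genes)), geneIds(genes))
  rates <- c(frameshift = corruption_spec$frameshift,
             stop = corruption_spec$stop,
             short = corruption_spec$truncation)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0,1]")
  types <- sample(c(names(rates), "clean"), length(genes), replace = TRUE,
                  prob = c(rates, 1 - sum(rates)))
  out <- character(length(genes)); names(out) <- names(genes)
  rc <- stats::runif(length(genes)) < corruption_spec$revcomp
  for (i in seq_along(genes)) {
    s <- .degap(genes[[i]]); L <- nchar(s)
    s <- switch(types[i],
      clean = s,
      frameshift = {
        k <- sample(1:2, 1)
        pos <- sample(seq(60L, L - 60L), 1)
        paste0(substr(s, 1, pos - 1), substr(s, pos + k, L))
      },
      stop = {
        cod <- sample(seq(4L, min(194L, L %/% 3L - 3L)), 1)
        paste0(substr(s, 1, 3 * (cod - 1)), sample(STOP_CODONS, 1),
               substr(s, 3 * cod + 1, L))
      },
      short = substr(s, 1, sample(400:581, 1)))
    if (rc[i]) s <- .revcomp(s)
    out[i] <- s
  }
  list(records = out,
       registry = data.frame(id = names(genes), type = types, revcomp = rc))
}

#' Assign multi-level habitat metadata per clade
#'
#' @param genes \code{GeneSet} with a \code{clade} metadata column, or a
#'   named character vector seq_id -> clade.
#' @param per_clade_distribution Named list: clade -> named probability
#'   vector over habitat paths (each summing to 1).
#' @param tree Optional \code{\link{habitatTree}} validating the paths.
#' @param broader_only Probability that an assignment is truncated to its
#'   parent category.
#' @param seed Optional seed.
#' @return data.frame seq_id / habitat.
#' @export
makeMetadata <- function(genes, per_clade_distribution,
                         tree = habitatTree(), broader_only = 0,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cladeOf <- if (methods::is(genes, "GeneSet"))
    stats::setNames(as.character(geneMeta(genes)$clade), geneIds(genes))
  else genes
  for (cl in names(per_clade_distribution)) {
    p <- per_clade_distribution[[cl]]
    if (abs(sum(p) - 1) > 1e-8)
      stop("configuration error: distribution for clade ", cl,
           " does not sum to 1")
    unknown <- setdiff(names(p), tree$path)
    if (length(unknown))
      stop("configuration error: unknown habitat ",
           paste(unknown, collapse = ", "))
  }
  miss <- setdiff(unique(cladeOf), names(per_clade_distribution))
  if (length(miss))
    stop("configuration error: no distribution for clade ",
         paste(miss, collapse = ", "))
  habitat <- vapply(cladeOf, function(cl) {
    p <- per_clade_distribution[[cl]]
    sample(names(p), 1, prob = p)
  }, character(1))
  if (broader_only > 0) {
    trunc <- stats::runif(length(habitat)) < broader_only
    habitat[trunc] <- vapply(habitat[trunc], function(h) {
      parts <- strsplit(h, "/", fixed = TRUE)[[1]]
      if (length(parts) > 1) paste(parts[-length(parts)], collapse = "/")
      else h
    }, character(1))
  }
  data.frame(seq_id = names(cladeOf), habitat = unname(habitat))
}

#' Generate a complete synthetic study under one seed
#'
#' Orchestrates tree simulation, sequence evolution, chimera generation,
#' corruption and metadata into the full raw input set plus ground-truth
#' registries. Every generated sequence appears in exactly one registry
#' (clean, chimera or corrupted).
#'
#' @param config \code{\link{simConfig}} output.
#' @param per_clade_distribution Optional habitat distributions (default: a
#'   simple clade-to-broad-habitat pattern).
#' @param broader_only Broader-only annotation fraction (default 0.1).
#' @return List: \code{raw} (named character raw records: corrupted clean
#'   pool plus chimeras), \code{genes} (clean \code{GeneSet}), \code{tree},
#'   \code{truth} (taxonomy, seeds, otu_of_seq, chimera and corruption
#'   registries), \code{metadata}.
#' @export
simulateAmoaData <- function(config = simConfig(),
                             per_clade_distribution = NULL,
                             broader_only = 0.1) {
  set.seed(config$seed)
  sim <- simulateTree(config, .reseed = FALSE)
  ev <- evolveSequences(sim, config, .reseed = FALSE)
  ch <- makeChimeras(ev$genes, config$chimera_fraction,
                     config$min_parent_divergence,
                     config$max_parent_divergence,
                     breakpoint_window = config$breakpoint_window)
  co <- corruptSequences(ev$genes, config$corruption_spec)
  if (is.null(per_clade_distribution)) {
    broads <- c("marine", "soils-sediments", "freshwater",
                "estuarine-coastal")
    ords <- sim$truth$orders$order
    per_clade_distribution <- stats::setNames(lapply(seq_along(ords),
      function(i) {
        main <- broads[(i - 1) %% length(broads) + 1]
        other <- broads[i %% length(broads) + 1]
        stats::setNames(c(0.8, 0.2), c(main, other))
      }), ords)
  }
  meta <- makeMetadata(ev$genes, per_clade_distribution,
                       broader_only = broader_only)
  raw <- c(co$records, ch$chimeras)
  # the first member of every OTU emulates a trusted genome-derived sequence
  genome_ids <- sprintf("%s_s01", names(ev$representatives))
  list(raw = raw, genes = ev$genes, tree = sim$tree,
       truth = c(sim$truth, list(otu_of_seq = ev$otu_of_seq,
                                 genome_ids = genome_ids,
                                 chimera_registry = ch$registry,
                                 corruption_registry = co$registry,
                                 representatives = ev$representatives)),
       metadata = meta)
}
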