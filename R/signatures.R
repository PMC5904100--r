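#' @name signatures
#' @title Base-composition and codon-usage signatures
#'
#' @description
#' Per-gene GC and purine content, Wright's effective number of codons (Nc),
#' and the global codon adaptation index (gCAI) scored against
#' relative-adaptiveness weights fitted on a reference set; per-OTU mean
#' deviations from the global (OTU-unweighted) average; and gene-versus-
#' genome linear regression.
NULL

#' GC and purine content of a coding sequence
#'
#' Percentages on the coding (sense) strand: \code{gc = 100 (G+C)/L},
#' \code{purine = 100 (A+G)/L}, computed on the degapped sequence.
#'
#' @param gene Nucleotide string.
#' @return Named numeric vector \code{c(gc =, purine =)}.
#' @export
baseComposition <- function(gene) {
  s <- .degap(as.character(gene))
  if (!nzchar(s)) stop("empty sequence")
  v <- strsplit(s, "")[[1]]
  L <- length(v)
  c(gc = 100 * sum(v %in% c("G", "C")) / L,
    purine = 100 * sum(v %in% c("A", "G")) / L)
}

#' Wright's effective number of codons (Nc)
#'
#' Per synonymous family with n codons observed and proportions p_i, the
#' codon homozygosity is \code{F = (n sum(p_i^2) - 1)/(n - 1)} (defined for
#' n >= 2). With Fk the mean F over observed families of redundancy k,
#' \code{Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6}, capped into [20, 61]. Met and
#' Trp (single-codon families) and stop codons are excluded; when a
#' redundancy class has no usable family (or a non-positive mean), the
#' uniform-usage expectation \code{Fk = 1/k} is substituted.
#'
#' @param gene In-frame nucleotide string (length divisible by 3 after
#'   degapping).
#' @return Nc value in [20, 61].
#' @export
effectiveNumberOfCodons <- function(gene) {
  s <- .degap(as.character(gene))
  cods <- .seqToCodons(s)
  cods <- cods[!cods %in% STOP_CODONS]
  if (length(cods) == 0) stop("no codons")
  fams <- .codonFamilies()
  sizes <- lengths(fams)
  counts <- table(factor(cods, levels = unlist(fams)))
  Fhat <- vapply(names(fams), function(aa) {
    n <- sum(counts[fams[[aa]]])
    if (n < 2) return(NA_real_)
    p <- counts[fams[[aa]]] / n
    (n * sum(p^2) - 1) / (n - 1)
  }, numeric(1))
  classes <- c(2, 3, 4, 6)
  mult <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)
  nc <- 2
  for (k in classes) {
    fk <- Fhat[sizes == k]
    fk <- fk[!is.na(fk)]
    Fbar <- if (length(fk) == 0) 1 / k else mean(fk)
    if (Fbar <= 0) Fbar <- 1 / k
    nc <- nc + mult[[as.character(k)]] / Fbar
  }
  min(max(nc, 20), 61)
}

#' Fit relative-adaptiveness (CAI) weights on a reference set
#'
#' Fixed mode: \code{w_c = f_c / max f} within each synonymous family over
#' the pooled reference codon counts. Iterative (dominant-bias, gCAI) mode:
#' starting from all references, weights are refitted and the top-scoring
#' half of the references kept until the set shrinks to
#' \code{max(1\% of references, 5)} or the weights change by less than
#' \code{tol}; the converged weights describe the dominant codon bias of the
#' reference set. Codons absent from the reference within an observed family
#' receive the pseudo-weight \code{0.5/max count}; families entirely
#' unobserved get \code{NA} weights and are skipped in scoring.
#'
#' @param reference_genes Named character vector / \code{GeneSet}.
#' @param mode \code{"iterative"} (default, gCAI semantics) or
#'   \code{"fixed"}.
#' @param tol Convergence tolerance on the maximum weight change.
#' @param max_iter Iteration cap.
#' @return List with \code{w} (named numeric per codon), \code{mode},
#'   \code{reference} (ids in the final reference set) and \code{trace}
#'   (data.frame iter/n_refs/max_delta).
#' @export
fitCaiWeights <- function(reference_genes, mode = c("iterative", "fixed"),
                          tol = 1e-6, max_iter = 50L) {
  mode <- match.arg(mode)
  if (methods::is(reference_genes, "GeneSet"))
    reference_genes <- stats::setNames(as.character(geneSeqs(reference_genes)),
                                       geneIds(reference_genes))
  if (length(reference_genes) == 0) stop("empty reference set")
  if (is.null(names(reference_genes)))
    names(reference_genes) <- sprintf("ref%04d", seq_along(reference_genes))
  fams <- .codonFamilies()
  fitOnce <- function(genes) {
    cods <- unlist(lapply(genes, function(g) .seqToCodons(.degap(g))))
    cods <- cods[!cods %in% STOP_CODONS]
    counts <- table(factor(cods, levels = unlist(fams)))
    w <- stats::setNames(rep(NA_real_, length(unlist(fams))), unlist(fams))
    for (aa in names(fams)) {
      fc <- counts[fams[[aa]]]
      mx <- max(fc)
      if (mx == 0) next
      wf <- as.numeric(fc) / mx
      wf[fc == 0] <- 0.5 / mx
      w[fams[[aa]]] <- wf
    }
    w
  }
  if (mode == "fixed") {
    w <- fitOnce(reference_genes)
    return(list(w = w, mode = mode, reference = names(reference_genes),
                trace = data.frame(iter = 1L,
                                   n_refs = length(reference_genes),
                                   max_delta = NA_real_)))
  }
  cur <- reference_genes
  floorN <- max(ceiling(0.01 * length(reference_genes)), 5L)
  w <- fitOnce(cur)
  trace <- data.frame(iter = 1L, n_refs = length(cur), max_delta = NA_real_)
  for (it in seq_len(max_iter)) {
    if (length(cur) <= floorN) break
    scores <- vapply(cur, function(g) gcai(g, list(w = w)), numeric(1))
    keep <- order(-scores, names(cur))[seq_len(max(ceiling(length(cur) / 2),
                                                   floorN))]
    cur <- cur[keep]
    wNew <- fitOnce(cur)
    delta <- max(abs(wNew - w), na.rm = TRUE)
    trace <- rbind(trace, data.frame(iter = it + 1L, n_refs = length(cur),
                                     max_delta = delta))
    w <- wNew
    if (delta < tol) break
  }
  list(w = w, mode = mode, reference = names(cur), trace = trace)
}

#' Codon adaptation index of one gene
#'
#' Geometric mean of the relative-adaptiveness weights over the scored
#' codons; single-codon families (Met, Trp), stop codons and codons of
#' families absent from the reference are excluded.
#'
#' @param gene In-frame nucleotide string.
#' @param weights Result of \code{\link{fitCaiWeights}} (or any list with a
#'   \code{w} element).
#' @return CAI value in (0, 1].
#' @export
gcai <- function(gene, weights) {
  w <- weights$w
  cods <- .seqToCodons(.degap(as.character(gene)))
  fams <- .codonFamilies()
  multi <- unlist(fams[lengths(fams) >= 2])
  cods <- cods[cods %in% multi]
  wv <- w[cods]
  wv <- wv[!is.na(wv)]
  if (length(wv) == 0) return(NA_real_)
  exp(mean(log(wv)))
}

#' Per-OTU signature deviations from the global average
#'
#' The global average G of each metric is the unweighted mean over OTU means
#' (not over genes), so large OTUs do not dominate. Each OTU reports its mean
#' deviation \code{m_otu - G} and the standard deviation of its genes'
#' deviations (0 for single-gene OTUs).
#'
#' @param records data.frame with column \code{gene} plus one column per
#'   metric (e.g. gc, purine, nc, gcai).
#' @param otu_map Named character vector gene id -> OTU id.
#' @return data.frame: otu, metric, mean_deviation, sd; attribute
#'   \code{global} holds the global averages.
#' @export
otuDeviations <- function(records, otu_map) {
  metrics <- setdiff(colnames(records), "gene")
  otu <- otu_map[records$gene]
  if (anyNA(otu)) {
    warning("records without OTU excluded: ", sum(is.na(otu)))
    records <- records[!is.na(otu), , drop = FALSE]
    otu <- otu[!is.na(otu)]
  }
  out <- list(); glob <- numeric(0)
  for (m in metrics) {
    means <- tapply(records[[m]], otu, mean)
    G <- mean(means)
    glob[m] <- G
    sds <- tapply(records[[m]], otu, function(v)
      if (length(v) > 1) stats::sd(v - G) else 0)
    out[[m]] <- data.frame(otu = names(means), metric = m,
                           mean_deviation = as.numeric(means - G),
                           sd = as.numeric(sds))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "global") <- glob
  res
}

#' Gene-versus-genome linear regression
#'
#' Ordinary least squares of gene-level signature values on genome-level
#' values, with R^2, the two-sided slope p-value and a residual table for
#' external diagnostics.
#'
#' @param gene_values,genome_values Paired numeric vectors (n >= 3).
#' @return List: slope, intercept, r_squared, p_value, n, residuals.
#' @export
geneVsGenomeRegression <- function(gene_values, genome_values) {
  stopifnot(length(gene_values) == length(genome_values))
  if (length(gene_values) < 3) stop("need at least 3 pairs")
  if (stats::var(genome_values) == 0) stop("zero variance in x")
  fit <- stats::lm(gene_values ~ genome_values)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       n = length(gene_values),
       residuals = data.frame(x = genome_values, y = gene_values,
                              residual = stats::residuals(fit)))
}

#' Signature table for a gene set
#'
#' @param genes \code{GeneSet} or named character vector.
#' @param weights Optional CAI weights (\code{\link{fitCaiWeights}}); when
#'   \code{NULL}, gcai is omitted.
#' @return data.frame: gene, gc, purine, nc (and gcai when weights given).
#' @export
signatureTable <- function(genes, weights = NULL) {
  if (methods::is(genes, "GeneSet"))
    genes <- stats::setNames(as.character(geneSeqs(genes)), geneIds(genes))
  out <- data.frame(gene = names(genes))
  bc <- t(vapply(genes, baseComposition, numeric(2)))
  out$gc <- bc[, "gc"]; out$purine <- bc[, "purine"]
  out$nc <- vapply(genes, effectiveNumberOfCodons, numeric(1))
  if (!is.null(weights))
    out$gcai <- vapply(genes, gcai, numeric(1), weights = weights)
  rownames(out) <- NULL
  out
}
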