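#' @name curation
#' @title Curation of raw marker-gene records
#'
#' @description
#' Reduces raw nucleotide records to in-frame, length-valid, stop-free,
#' frameshift-free fragments in the common 591-column coding frame:
#' ambiguity screening, six-frame open-reading-frame extraction, a
#' nearest-reference frameshift screen, global trimming and dereplication.
NULL

#' Remove records with ambiguous bases
#'
#' Records containing any character outside \code{ACGT} (e.g. \code{N} or
#' IUPAC ambiguity codes) are removed, as are empty records.
#'
#' @param records Named character vector or \code{DNAStringSet} of raw
#'   sequences.
#' @return List with \code{kept} (named character vector) and \code{log}
#'   (data.frame id/stage/reason for removals).
#' @export
screenAlphabet <- function(records) {
  if (methods::is(records, "DNAStringSet")) {
    records <- stats::setNames(as.character(records), names(records))
  }
  if (length(records) == 0) {
    warning("empty input")
    return(list(kept = character(0),
                log = data.frame(id = character(0), stage = character(0),
                                 reason = character(0))))
  }
  if (is.null(names(records))) names(records) <- sprintf("rec%05d", seq_along(records))
  records <- vapply(records, .degap, character(1)) # frame gaps are bookkeeping
  empty <- !nzchar(records)
  ambig <- grepl("[^ACGT]", records)
  bad <- empty | ambig
  log <- data.frame(id = names(records)[bad],
                    stage = rep("alphabet", sum(bad)),
                    reason = ifelse(empty[bad], "empty", "ambiguous"))
  list(kept = records[!bad], log = log)
}

# longest stop-free codon run in one reading; returns codon-run coordinates
.longestOrfRun <- function(s, offset) {
  n <- (nchar(s) - offset) %/% 3L
  if (n <= 0) return(list(len = 0L, start = NA_integer_))
  cods <- substring(s, offset + 3L * seq_len(n) - 2L, offset + 3L * seq_len(n))
  isStop <- cods %in% STOP_CODONS
  bounds <- c(0L, which(isStop), n + 1L)
  lens <- diff(bounds) - 1L
  k <- which.max(lens)
  list(len = lens[k], start = bounds[k] + 1L, ncod = n, any_stop = any(isStop))
}

#' Extract the longest in-frame stop-free fragment over six frames
#'
#' Scans both orientations and all three frame offsets per strand for the
#' longest open (stop-free) codon run, trimming partial codons at the termini.
#' Ties prefer the forward strand, then the lower frame offset.
#'
#' @param record Single nucleotide string (or named length-1 vector).
#' @param min_codons Minimum fragment length in codons (default 194,
#'   i.e. 582 nt).
#' @return On success, a list with \code{coding} (fragment), \code{strand}
#'   (\code{"+"}/\code{"-"}), \code{frame} (0/1/2) and \code{n_codons}.
#'   On failure, \code{list(rejected = TRUE, reason = ...)} where the reason
#'   is \code{"short"} when the record itself is shorter than
#'   \code{3 * min_codons} and \code{"no-orf"} otherwise.
#' @export
extractInFrame <- function(record, min_codons = 194L) {
  s <- unname(as.character(record))
  if (nchar(s) < 3L * min_codons)
    return(list(rejected = TRUE, reason = "short"))
  best <- NULL
  for (strand in c("+", "-")) {
    seqs <- if (strand == "+") s else .revcomp(s)
    for (off in 0:2) {
      run <- .longestOrfRun(seqs, off)
      if (is.null(best) || run$len > best$len) {
        best <- c(run, list(strand = strand, frame = off, seqs = seqs))
      }
    }
  }
  if (best$len < min_codons)
    return(list(rejected = TRUE, reason = "no-orf"))
  from <- best$frame + 3L * (best$start - 1L) + 1L
  frag <- substr(best$seqs, from, from + 3L * best$len - 1L)
  list(coding = frag, strand = best$strand, frame = best$frame,
       n_codons = best$len)
}

#' Screen a fragment for frameshifts against a reference set
#'
#' The fragment is globally aligned (affine gap penalties) to its nearest
#' reference, chosen by shared 8-mer count. It fails if the alignment
#' contains any gap run whose length is not a multiple of 3, or more than
#' \code{max_codon_deletions} whole-codon indels in total (the allowance for
#' biological codon deletions).
#'
#' @param gene Coding fragment (character string, degapped).
#' @param references Character vector / \code{DNAStringSet} / \code{GeneSet}
#'   of trusted in-frame sequences.
#' @param max_codon_deletions Maximum whole-codon indels tolerated (default 3).
#' @param gap_opening,gap_extension Affine gap parameters passed to the
#'   aligner.
#' @param .ref_kmers Precomputed reference k-mer presence matrix (internal
#'   batch optimisation).
#' @return List with \code{pass} (logical), \code{reason}, \code{reference}
#'   (id of the nearest reference).
#' @export
screenFrameshifts <- function(gene, references, max_codon_deletions = 3L,
                              gap_opening = 10, gap_extension = 2,
                              .ref_kmers = NULL) {
  if (methods::is(references, "GeneSet"))
    references <- stats::setNames(as.character(geneSeqs(references)),
                                  geneIds(references))
  if (methods::is(references, "DNAStringSet"))
    references <- stats::setNames(as.character(references), names(references))
  if (length(references) == 0) stop("empty reference set")
  references <- vapply(references, .degap, character(1))
  gene <- .degap(as.character(gene))
  shared <- .sharedKmers(gene, references, k = 6L, ref_kmers = .ref_kmers)
  ref <- references[[which.max(shared)]]
  refId <- names(references)[which.max(shared)]
  if (nchar(gene) == nchar(ref)) {
    # equal length and high column identity: the affine-gap optimum is
    # gapless, so no alignment is needed
    ham <- mean(strsplit(gene, "")[[1]] == strsplit(ref, "")[[1]])
    if (ham >= 0.8)
      return(list(pass = TRUE, reason = NA_character_, reference = refId))
  }
  aln <- Biostrings::pairwiseAlignment(
    gene, ref, type = "global",
    gapOpening = gap_opening, gapExtension = gap_extension)
  gaps <- c(IRanges::width(Biostrings::indel(Biostrings::pattern(aln))[[1]]),
            IRanges::width(Biostrings::indel(Biostrings::subject(aln))[[1]]))
  if (any(gaps %% 3L != 0L))
    return(list(pass = FALSE, reason = "frameshift", reference = refId))
  if (sum(gaps) / 3L > max_codon_deletions)
    return(list(pass = FALSE, reason = "excess-deletions", reference = refId))
  list(pass = TRUE, reason = NA_character_, reference = refId)
}

#' Globally trim genes to the common frame length
#'
#' All retained genes occupy exactly \code{target_length} columns of the
#' common frame; fragments shorter than \code{min_length} (582 nt by
#' default, allowing up to three codon deletions against the 591-nt frame)
#' are excluded, and shorter-than-target survivors are padded with trailing
#' frame gaps as columnar bookkeeping.
#'
#' @param genes Named character vector of coding fragments (may contain
#'   frame gaps).
#' @param target_length Common frame width in columns (default 591).
#' @param min_length Minimum degapped length retained (default 582).
#' @return List with \code{genes} (named character, all \code{target_length}
#'   columns) and \code{log} of exclusions.
#' @export
globalTrim <- function(genes, target_length = 591L, min_length = 582L) {
  genes <- vapply(genes, as.character, character(1))
  deg <- vapply(genes, .degap, character(1))
  lens <- nchar(deg)
  drop <- lens < min_length
  log <- data.frame(id = names(genes)[drop], stage = rep("trim", sum(drop)),
                    reason = rep("short", sum(drop)))
  kept <- genes[!drop]
  out <- vapply(kept, function(g) {
    if (nchar(g) > target_length) g <- substr(g, 1L, target_length)
    if (nchar(g) < target_length)
      g <- paste0(g, strrep("-", target_length - nchar(g)))
    g
  }, character(1))
  list(genes = out, log = log)
}

#' Collapse exact duplicates, keeping multiplicities
#'
#' @param genes Named character vector of coding sequences.
#' @return List with \code{genes} (unique sequences, named by their first
#'   occurrence), \code{multiplicity} (named integer), and \code{map}
#'   (named character: every input id to its representative id).
#' @export
dereplicate <- function(genes) {
  genes <- vapply(genes, as.character, character(1))
  key <- vapply(genes, .degap, character(1))
  first <- !duplicated(key)
  reps <- names(genes)[first]
  repOf <- stats::setNames(reps[match(key, key[first])], names(genes))
  mult <- table(factor(repOf, levels = reps))
  list(genes = genes[first],
       multiplicity = stats::setNames(as.integer(mult), reps),
       map = repOf)
}

#' Run the full curation pipeline on raw records
#'
#' Alphabet screen, six-frame in-frame extraction, optional frameshift screen
#' against references, and global trim. Returns the curated \code{GeneSet}
#' plus a rejection log (id, stage, reason).
#'
#' @param records Raw sequences (named character or \code{DNAStringSet}).
#' @param references Optional trusted in-frame sequences for the frameshift
#'   screen; when \code{NULL} that stage is skipped.
#' @param min_codons,target_length,max_codon_deletions See the stage
#'   functions.
#' @return List with \code{genes} (\code{GeneSet}), \code{log} (data.frame),
#'   and \code{frames} (per-gene strand/frame bookkeeping).
#' @export
curateSequences <- function(records, references = NULL, min_codons = 194L,
                            target_length = 591L, max_codon_deletions = 3L) {
  sc <- screenAlphabet(records)
  log <- sc$log
  frames <- data.frame(id = character(0), strand = character(0),
                       frame = integer(0))
  coding <- character(0)
  for (id in names(sc$kept)) {
    ex <- extractInFrame(sc$kept[[id]], min_codons = min_codons)
    if (isTRUE(ex$rejected)) {
      log <- rbind(log, data.frame(id = id, stage = "extract",
                                   reason = ex$reason))
      next
    }
    coding[id] <- ex$coding
    frames <- rbind(frames, data.frame(id = id, strand = ex$strand,
                                       frame = ex$frame))
  }
  if (!is.null(references) && length(coding)) {
    refK <- .kmerPresence(references, k = 6L)
    keep <- logical(length(coding))
    for (i in seq_along(coding)) {
      fs <- screenFrameshifts(coding[[i]], references,
                              max_codon_deletions = max_codon_deletions,
                              .ref_kmers = refK)
      keep[i] <- fs$pass
      if (!fs$pass)
        log <- rbind(log, data.frame(id = names(coding)[i],
                                     stage = "frameshift", reason = fs$reason))
    }
    coding <- coding[keep]
  }
  tr <- globalTrim(coding, target_length = target_length)
  log <- rbind(log, tr$log)
  gs <- geneSet(tr$genes,
                meta = data.frame(strand = frames$strand[match(names(tr$genes),
                                                               frames$id)],
                                  frame = frames$frame[match(names(tr$genes),
                                                             frames$id)]))
  list(genes = gs, log = log, frames = frames)
}
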