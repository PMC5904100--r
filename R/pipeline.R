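#' Run the full pipeline on a synthetic study
#'
#' Simulate raw records under one seed, curate them (alphabet, six-frame
#' extraction, frameshift screen, global trim), dereplicate, screen chimeras
#' against the trusted reference database, cluster OTUs, build the
#' support-threshold taxonomy, compute signature tables and habitat
#' profiles, and (optionally) write every export format.
#'
#' @param config \code{\link{simConfig}}.
#' @param params \code{\link{chimeraParams}}.
#' @param otu_identity OTU clustering identity (default 0.96).
#' @param min_ufboot,min_shalrt Branch support thresholds.
#' @param out_dir Optional directory for exports (FASTA, rejection log,
#'   verdict table, OTU membership, annotated Newick + lineage TSV,
#'   signature TSV, Krona text).
#' @return List with all intermediate results.
#' @export
runPipeline <- function(config = simConfig(), params = chimeraParams(),
                        otu_identity = 0.96, min_ufboot = 95,
                        min_shalrt = 85, out_dir = NULL) {
  data <- simulateAmoaData(config)

  # stage 1: curation; references for the frameshift screen are the
  # dereplicated full-frame (591 nt) extraction survivors
  pre <- curateSequences(data$raw, references = NULL)
  full <- as.character(geneSeqs(pre$genes))
  names(full) <- geneIds(pre$genes)
  refs <- dereplicate(full[!grepl("-", full, fixed = TRUE)])$genes
  cur <- curateSequences(data$raw, references = refs)
  genes <- cur$genes

  # stage 2: dereplicate and screen chimeras
  der <- dereplicate(stats::setNames(as.character(geneSeqs(genes)),
                                     geneIds(genes)))
  study <- stats::setNames(
    sub("^(.*)_s[0-9]+$", "\\1", names(der$genes)), names(der$genes))
  meta <- geneMeta(data$genes)
  studyOf <- stats::setNames(as.character(meta$study), geneIds(data$genes))
  study[names(study) %in% names(studyOf)] <-
    studyOf[names(study)[names(study) %in% names(studyOf)]]
  # genome-derived references come from assemblies, not from the PCR pool,
  # so they are added as trusted input rather than recovered from raw reads
  reps <- data$truth$representatives
  names(reps) <- paste0("genome_", names(reps))
  dbPool <- c(der$genes, reps[!reps %in% der$genes])
  dbMult <- c(der$multiplicity,
              stats::setNames(rep(1L, sum(!reps %in% der$genes)),
                              names(reps)[!reps %in% der$genes]))
  dbStudy <- c(study, stats::setNames(rep("genome", sum(!reps %in% der$genes)),
                                      names(reps)[!reps %in% der$genes]))
  db <- buildReferenceDb(dbPool, dbMult, dbStudy,
                         genome_ids = c(names(reps),
                                        intersect(data$truth$genome_ids,
                                                  names(der$genes))))
  scr <- screenChimeras(der$genes, db$db, params)
  kept <- der$genes[scr$kept]

  # stage 3: cluster OTUs and map every curated sequence to a tree leaf
  d <- pairwiseDistances(kept)
  otus <- averageNeighbour(d, otu_identity)
  leafAssign <- assignToOtus(
    kept, data.frame(otu = names(data$truth$representatives),
                     member = names(data$truth$representatives),
                     representative = TRUE),
    data$truth$representatives, min_identity = otu_identity)
  otuOfSeq <- stats::setNames(leafAssign$assignments$otu,
                              leafAssign$assignments$id)

  # stage 4: taxonomy from the support-labelled tree
  collapsed <- collapseUnsupported(data$tree, min_ufboot, min_shalrt)
  taxonomy <- assignRanks(collapsed, data$truth$seeds)

  # stage 5: signatures (CAI reference: OTU representatives)
  weights <- fitCaiWeights(data$truth$representatives)
  sig <- signatureTable(kept, weights)
  dev <- otuDeviations(
    data.frame(gene = sig$gene, gc = sig$gc, purine = sig$purine,
               nc = sig$nc, gcai = sig$gcai),
    otuOfSeq[otuOfSeq != "unassigned"])

  # stage 6: habitat profiles over the curated, mapped sequences
  cats <- loadCategories(data$metadata)
  mult <- der$multiplicity
  freq <- cladeFrequencyTable(taxonomy,
                              otuOfSeq[otuOfSeq != "unassigned"],
                              cats$assignments, mult)

  res <- list(data = data, curated = genes, rejection_log = cur$log,
              dereplicated = der, reference_db = db, verdicts = scr$verdicts,
              kept = kept, distances = d, otus = otus,
              otu_of_seq = otuOfSeq, collapsed = collapsed,
              taxonomy = taxonomy, cai_weights = weights, signatures = sig,
              otu_deviations = dev, habitat = cats,
              clade_frequencies = freq)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(x) file.path(out_dir, x)
    writeGeneFasta(geneSet(kept), fp("curated.fasta"))
    utils::write.table(cur$log, fp("rejections.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(scr$verdicts, fp("chimera_verdicts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(otus, fp("otus.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    exportTaxonomy(taxonomy, collapsed, fp("taxonomy.nwk"),
                   fp("taxonomy.tsv"))
    utils::write.table(sig, fp("signatures.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(dev, fp("otu_deviations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (nrow(freq)) {
      root <- taxaTable(taxonomy)$name[taxaTable(taxonomy)$level == 0][1]
      exportKrona(freq[freq$taxon == root, c("habitat", "count")],
                  fp("krona.txt"))
    }
    res$out_dir <- out_dir
  }
  res
}
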