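test_that("invalid configurations are rejected", {
  expect_error(simConfig(n_clades = 1), "n_clades")
  expect_error(simConfig(chimera_fraction = 1.2), "fractions")
  expect_error(simConfig(corruption_spec = list(frameshift = 0.5, stop = 0.4,
                                                truncation = 0.3,
                                                revcomp = 0)),
               "corruption")
})

test_that("simulated trees are deterministic and carry the forced clade structure", {
  cfg <- simConfig(seed = 5, n_clades = 4, otus_per_clade = 5,
                   subclades_per_clade = 0)
  s1 <- simulateTree(cfg)
  s2 <- simulateTree(cfg)
  expect_identical(writeSupportTree(s1$tree), writeSupportTree(s2$tree))
  phy <- treePhylo(s1$tree)
  expect_equal(length(phy$tip.label), 20)
  # order stems are fully supported: collapsing keeps exactly the 4 clades
  col <- collapseUnsupported(s1$tree)
  cp <- treePhylo(col)
  kids <- cp$edge[cp$edge[, 1] == 21, 2]
  expect_equal(length(kids), 4)
  sizes <- vapply(kids, function(v)
    length(ape::extract.clade(cp, v)$tip.label), numeric(1))
  expect_equal(sort(sizes), rep(5, 4), ignore_attr = TRUE)
})

test_that("clean sequences are full-frame, stop-free, and clade GC is monotone in target", {
  cfg <- simConfig(seed = 9, n_clades = 3, otus_per_clade = 4,
                   seqs_per_otu = 4,
                   per_clade_gc_target = c(0.40, 0.49, 0.58))
  sim <- simulateTree(cfg)
  ev <- evolveSequences(sim, cfg)
  seqs <- as.character(geneSeqs(ev$genes))
  expect_true(all(nchar(seqs) == 591))
  cods <- unlist(lapply(seqs, function(s)
    substring(s, seq(1, 589, 3), seq(3, 591, 3))))
  expect_false(any(cods %in% c("TAA", "TAG", "TGA")))
  gc <- vapply(seqs, function(s) baseComposition(s)[["gc"]], numeric(1))
  byClade <- tapply(gc, as.character(geneMeta(ev$genes)$clade), mean)
  ord <- byClade[sim$truth$orders$order]
  expect_true(all(diff(ord) > 0))
})

test_that("zero mutation rate propagates the clade ancestor unchanged", {
  cfg <- simConfig(seed = 2, n_clades = 2, otus_per_clade = 3,
                   mutation_rate = 0, within_otu_divergence = 0)
  ev <- evolveSequences(simulateTree(cfg), cfg)
  seqs <- split(as.character(geneSeqs(ev$genes)),
                as.character(geneMeta(ev$genes)$clade))
  for (cl in seqs) expect_equal(length(unique(cl)), 1)
})

test_that("chimeras reconstruct exactly from the registry", {
  cfg <- simConfig(seed = 3, n_clades = 3, otus_per_clade = 4,
                   seqs_per_otu = 3)
  ev <- evolveSequences(simulateTree(cfg), cfg)
  genes <- stats::setNames(as.character(geneSeqs(ev$genes)),
                           geneIds(ev$genes))
  ch <- makeChimeras(ev$genes, fraction = 0.1, seed = 11)
  expect_gt(nrow(ch$registry), 0)
  for (i in seq_len(nrow(ch$registry))) {
    r <- ch$registry[i, ]
    rebuilt <- paste0(substr(genes[[r$parent_a]], 1, r$breakpoint),
                      substr(genes[[r$parent_b]], r$breakpoint + 1, 591))
    expect_identical(unname(ch$chimeras[[r$id]]), rebuilt)
    expect_true(r$breakpoint >= 1 && r$breakpoint <= 590)
  }
  # zero fraction: empty registry; identical pool: generation error
  expect_equal(nrow(makeChimeras(ev$genes, 0)$registry), 0)
  same <- stats::setNames(rep(genes[[1]], 5), paste0("x", 1:5))
  expect_error(makeChimeras(same, 0.5, min_parent_divergence = 0.05,
                            seed = 1),
               "generation error")
})

test_that("corruption registry labels every record and zero rates pass through", {
  cfg <- simConfig(seed = 4, n_clades = 2, otus_per_clade = 3,
                   seqs_per_otu = 2)
  ev <- evolveSequences(simulateTree(cfg), cfg)
  genes <- stats::setNames(as.character(geneSeqs(ev$genes)),
                           geneIds(ev$genes))
  co0 <- corruptSequences(genes, list(frameshift = 0, stop = 0,
                                      truncation = 0, revcomp = 0.5),
                          seed = 7)
  expect_true(all(co0$registry$type == "clean"))
  for (i in seq_along(genes)) {
    expected <- if (co0$registry$revcomp[i])
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(genes[[i]]))) else genes[[i]]
    expect_identical(unname(co0$records[[i]]), expected)
  }
  co <- corruptSequences(genes, list(frameshift = 0.3, stop = 0.3,
                                     truncation = 0.3, revcomp = 0),
                         seed = 8)
  expect_setequal(co$registry$id, names(genes))
  short <- co$registry$id[co$registry$type == "short"]
  expect_true(all(nchar(co$records[short]) < 582))
})

test_that("habitat metadata recovers the configured distribution within a binomial 99% CI", {
  tree <- habitatTree(c("soil", "freshwater"))
  clades <- stats::setNames(rep("A", 1000), sprintf("s%04d", 1:1000))
  md <- makeMetadata(clades, list(A = c(soil = 0.8, freshwater = 0.2)),
                     tree = tree, seed = 21)
  nSoil <- sum(md$habitat == "soil")
  ci <- qbinom(c(0.005, 0.995), 1000, 0.8)
  expect_gte(nSoil, ci[1])
  expect_lte(nSoil, ci[2])
  # broader-only truncation
  tree2 <- habitatTree(c("marine/water"))
  md2 <- makeMetadata(clades, list(A = c(`marine/water` = 1)), tree = tree2,
                      broader_only = 0.2, seed = 22)
  nBroad <- sum(md2$habitat == "marine")
  ci2 <- qbinom(c(0.005, 0.995), 1000, 0.2)
  expect_gte(nBroad, ci2[1])
  expect_lte(nBroad, ci2[2])
  # malformed distribution
  expect_error(makeMetadata(clades, list(A = c(soil = 0.7)), tree = tree),
               "configuration error")
})

test_that("the full synthetic study is seed-deterministic and registries partition the output", {
  cfg <- simConfig(seed = 6, n_clades = 2, otus_per_clade = 3,
                   seqs_per_otu = 3)
  d1 <- simulateAmoaData(cfg)
  d2 <- simulateAmoaData(cfg)
  expect_identical(d1$raw, d2$raw)
  expect_identical(d1$metadata, d2$metadata)
  expect_identical(writeSupportTree(d1$tree), writeSupportTree(d2$tree))
  # every raw record is exactly one of: corrupted-pool record or chimera
  expect_setequal(names(d1$raw),
                  c(d1$truth$corruption_registry$id,
                    d1$truth$chimera_registry$id))
})
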