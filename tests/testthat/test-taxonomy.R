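test_that("collapse applies both thresholds inclusively", {
  # inner branch at (94, 90): fails UFBoot -> collapsed
  st1 <- supTree("(((a:1,b:1)94/90:1,c:1)96/90:1,(d:1,e:1)97/92:1)root;")
  c1 <- collapseUnsupported(st1)
  expect_equal(treePhylo(c1)$Nnode, treePhylo(st1)$Nnode - 1)
  # boundary (95, 85): retained
  st2 <- supTree("(((a:1,b:1)95/85:1,c:1)96/90:1,(d:1,e:1)97/92:1)root;")
  c2 <- collapseUnsupported(st2)
  expect_equal(treePhylo(c2)$Nnode, treePhylo(st2)$Nnode)
  expect_true(ape::is.monophyletic(treePhylo(c2), c("a", "b")))
  # SH-aLRT failing alone also collapses
  st3 <- supTree("(((a:1,b:1)99/84:1,c:1)96/90:1,(d:1,e:1)97/92:1)root;")
  expect_equal(treePhylo(collapseUnsupported(st3))$Nnode,
               treePhylo(st3)$Nnode - 1)
  # fully supported tree unchanged; collapse is idempotent
  cc <- collapseUnsupported(c2)
  expect_equal(ape::write.tree(treePhylo(cc)),
               ape::write.tree(treePhylo(c2)))
  # missing support is an error naming the branch
  stNA <- supTree("(((a:1,b:1):1,c:1)96/90:1,(d:1,e:1)97/92:1)root;")
  expect_error(collapseUnsupported(stNA), "missing support")
})

test_that("rank labels follow stem-length ordering, redundancy and IS rules", {
  # an order clade with child clades of sizes 5 (stem 0.02), 4 (stem 0.07)
  # and a singleton: two level-1 taxa, alpha = the longer-stemmed size-4
  nw <- paste0("((((a1:1,a2:1)99/99:1,(a3:1,a4:1)99/99:1,a5:1)99/99:0.02,",
               "((b1:1,b2:1)99/99:1,(b3:1,b4:1)99/99:1)99/99:0.07,",
               "x:1)99/99:0.5,",
               "((c1:1,c2:1,c3:1)99/99:0.2,y:1)99/99:0.5)root;")
  st <- collapseUnsupported(supTree(nw))
  tax <- assignRanks(st, seeds = c(a1 = "NP", c1 = "NS"))
  tt <- taxaTable(tax)
  expect_equal(unlist(tt$members[tt$name == "NP-α"]),
               c("b1", "b2", "b3", "b4"), ignore_attr = TRUE)
  expect_equal(unlist(tt$members[tt$name == "NP-β"]),
               c("a1", "a2", "a3", "a4", "a5"), ignore_attr = TRUE)
  # the singleton x stays directly in the order
  expect_equal(lineageOf(tax, "x"), "NP")
  # NS has a single eligible child: no new rank, NS is terminal
  expect_true(tt$is_terminal[tt$name == "NS"])
  expect_false(any(grepl("^NS-", tt$name)))
  expect_equal(lineageOf(tax, "c3"), "NS")
  expect_equal(lineageOf(tax, "y"), "NS")
})

test_that("two-leaf clades become incertae sedis and overrides force ranks", {
  nw <- paste0("(((a1:1,a2:1,a3:1)99/99:0.30,(b1:1,b2:1,b3:1)99/99:0.10,",
               "(i1:1,i2:1)99/99:0.20)99/99:0.5,",
               "((c1:1,c2:1,c3:1)99/99:0.2,(d1:1,d2:1)99/99:0.1)99/99:0.5)root;")
  st <- collapseUnsupported(supTree(nw))
  tax <- assignRanks(st, seeds = c(a1 = "NP", c1 = "NT"))
  tt <- taxaTable(tax)
  expect_equal(unlist(tt$members[tt$name == "NP-IS"]), c("i1", "i2"),
               ignore_attr = TRUE)
  expect_true(tt$is_incertae_sedis[tt$name == "NP-IS"])
  # NT has one eligible child (c's) and one 2-leaf child: no rank, only IS
  expect_equal(unlist(tt$members[tt$name == "NT-IS"]), c("d1", "d2"),
               ignore_attr = TRUE)
  expect_true(tt$is_terminal[tt$name == "NT"])
  # forcing the single eligible child of NT opens a rank (the long-branch
  # exception mechanism)
  tax2 <- assignRanks(st, seeds = c(a1 = "NP", c1 = "NT"),
                      manual_overrides = list(c("c1", "c2", "c3")))
  tt2 <- taxaTable(tax2)
  expect_true("NT-α" %in% tt2$name)
  # overrides must be monophyletic
  expect_error(assignRanks(st, seeds = c(a1 = "NP", c1 = "NT"),
                           manual_overrides = list(c("a1", "c1"))),
               "monophyletic")
  expect_error(assignRanks(st, seeds = c(zz = "NP")), "absent")
})

test_that("deeper levels use dotted numerals and labels are deterministic", {
  cfg <- simConfig(seed = 77, n_clades = 4, otus_per_clade = 4,
                   subclades_per_clade = c(3, 5))
  sim <- simulateTree(cfg)
  st <- collapseUnsupported(sim$tree)
  t1 <- assignRanks(st, sim$truth$seeds)
  t2 <- assignRanks(st, sim$truth$seeds)
  expect_identical(taxaTable(t1)$name, taxaTable(t2)$name)
  # grammar: prefix, optional greek, optional dotted numerals, optional -IS
  expect_true(all(grepl(
    "^[A-Z]+(-[α-ω][0-9]*)?(-[0-9]+(\\.[0-9]+)*)?(-IS[0-9]*)?$",
    taxaTable(t1)$name)))
})

test_that("taxa nest strictly and named children partition their parent", {
  cfg <- simConfig(seed = 78, n_clades = 3, otus_per_clade = 4,
                   subclades_per_clade = c(2, 4))
  sim <- simulateTree(cfg)
  tax <- assignRanks(collapseUnsupported(sim$tree), sim$truth$seeds)
  tt <- taxaTable(tax)
  for (i in seq_len(nrow(tt))) {
    p <- tt$parent[i]
    if (is.na(p)) next
    expect_true(all(tt$members[[i]] %in% tt$members[[match(p, tt$name)]]))
    expect_lt(length(tt$members[[i]]),
              length(tt$members[[match(p, tt$name)]]) + 1)
  }
  # children of one parent are disjoint
  for (p in unique(stats::na.omit(tt$parent))) {
    kids <- tt$members[tt$parent == p & !is.na(tt$parent)]
    allKids <- unlist(kids)
    expect_equal(anyDuplicated(allKids), 0)
  }
})

test_that("raising either support threshold never increases the taxon count", {
  cfg <- simConfig(seed = 79, n_clades = 3, otus_per_clade = 4,
                   subclades_per_clade = c(3, 5),
                   decoy_support_fraction = 0.3)
  sim <- simulateTree(cfg)
  nTaxa <- function(uf, sh)
    nrow(taxaTable(assignRanks(collapseUnsupported(sim$tree, uf, sh),
                               sim$truth$seeds)))
  base <- nTaxa(95, 85)
  expect_lte(nTaxa(98, 85), base)
  expect_lte(nTaxa(95, 95), base)
  expect_lte(nTaxa(99, 99), nTaxa(95, 85))
})

test_that("classification places by identity with an LCA fallback", {
  cfg <- simConfig(seed = 80, n_clades = 3, otus_per_clade = 4,
                   subclades_per_clade = 3, seqs_per_otu = 1)
  sim <- simulateTree(cfg)
  ev <- evolveSequences(sim, cfg)
  tax <- assignRanks(collapseUnsupported(sim$tree), sim$truth$seeds)
  reps <- ev$representatives
  # identical to a representative: its most specific taxon
  leaf <- names(reps)[1]
  expect_equal(classifyGene(reps[[leaf]], tax, reps),
               lineageOf(tax, leaf))
  # a sequence between two subclades of one order falls back to the order
  ords <- sim$truth$orders
  o1 <- ords$members[[1]]
  q <- reps[[o1[1]]]
  qv <- strsplit(q, "")[[1]]
  rv <- strsplit(reps[[o1[length(o1)]]], "")[[1]]
  pickHalf <- which(qv != rv)
  half <- pickHalf[seq_len(floor(length(pickHalf) / 2))]
  qv[half] <- rv[half]
  got <- classifyGene(paste(qv, collapse = ""), tax, reps,
                      min_identity = 0.999, lca_radius = 0.80)
  expect_true(got %in% c(ords$order[1],
                         grep(paste0("^", ords$order[1], "-"),
                              taxaTable(tax)$name, value = TRUE)))
  # nothing within the radius: unclassified
  rnd <- randCodingSeq(197)
  expect_equal(classifyGene(rnd, tax, reps, lca_radius = 0.95),
               "unclassified")
})

test_that("taxonomy export round-trips losslessly", {
  cfg <- simConfig(seed = 81, n_clades = 3, otus_per_clade = 3,
                   subclades_per_clade = c(2, 4))
  sim <- simulateTree(cfg)
  st <- collapseUnsupported(sim$tree)
  tax <- assignRanks(st, sim$truth$seeds)
  tf <- tempfile(fileext = ".nwk"); xf <- tempfile(fileext = ".tsv")
  exportTaxonomy(tax, st, tf, xf)
  tax2 <- importTaxonomy(xf)
  expect_equal(taxaTable(tax2)$name, taxaTable(tax)$name)
  expect_equal(taxaTable(tax2)$parent, taxaTable(tax)$parent)
  expect_equal(taxaTable(tax2)$stem_length, taxaTable(tax)$stem_length)
  expect_equal(lapply(taxaTable(tax2)$members, sort),
               lapply(taxaTable(tax)$members, sort), ignore_attr = TRUE)
  # the annotated newick carries name|ufboot/shalrt labels and IS suffixes
  nw <- readLines(tf)
  expect_true(grepl("\\|", nw))
  tt <- taxaTable(tax)
  if (any(tt$is_incertae_sedis)) expect_true(grepl("-IS", nw))
  # lineage strings at level k have k-1 numerals after the greek letter
  lt <- lineageTable(tax)
  expect_setequal(lt$otu, treeLeaves(st))
})

test_that("collapse plus rank assignment reproduces the generator's taxonomy", {
  for (sd in c(101, 102, 103, 104, 105)) {
    cfg <- simConfig(seed = sd, n_clades = 4, otus_per_clade = 4,
                     subclades_per_clade = c(3, 8))
    sim <- simulateTree(cfg)
    tax <- assignRanks(collapseUnsupported(sim$tree), sim$truth$seeds)
    lt <- lineageTable(tax)
    truth <- sim$truth$taxonomy
    expect_equal(mean(lt$lineage[match(names(truth), lt$otu)] == truth), 1)
  }
})
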