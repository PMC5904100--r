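# literal, independent transcription of Wright's estimator used as oracle
oracleNc <- function(seq) {
  gc <- Biostrings::GENETIC_CODE
  cods <- substring(seq, seq(1, nchar(seq) - 2, 3), seq(3, nchar(seq), 3))
  cods <- cods[!gc[cods] %in% "*"]
  aas <- gc[cods]
  famSize <- table(gc[gc != "*"])
  nc <- 2
  for (k in c(2, 3, 4, 6)) {
    fs <- numeric(0)
    for (aa in names(famSize)[famSize == k]) {
      sub <- cods[aas == aa]
      n <- length(sub)
      if (n < 2) next
      p <- as.numeric(table(factor(sub, levels = names(gc)[gc == aa]))) / n
      fs <- c(fs, (n * sum(p^2) - 1) / (n - 1))
    }
    fbar <- if (length(fs) == 0 || mean(fs) <= 0) 1 / k else mean(fs)
    nc <- nc + c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)[[as.character(k)]] / fbar
  }
  min(max(nc, 20), 61)
}

test_that("base composition and its reverse-complement symmetry hold", {
  expect_equal(baseComposition("ATGC"), c(gc = 50, purine = 50))
  expect_equal(baseComposition("GGCC"), c(gc = 100, purine = 50))
  expect_equal(baseComposition(strrep("A", 30)), c(gc = 0, purine = 100))
  expect_error(baseComposition(""), "empty")
  set.seed(71)
  for (i in 1:10) {
    s <- randCodingSeq(50)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(baseComposition(rc)[["gc"]], baseComposition(s)[["gc"]])
    expect_equal(baseComposition(rc)[["purine"]],
                 100 - baseComposition(s)[["purine"]])
  }
})

test_that("Nc attains its boundaries and matches the independent oracle", {
  gc <- Biostrings::GENETIC_CODE
  fams <- split(names(gc)[gc != "*"], gc[gc != "*"])
  # one codon per amino acid, each family observed >= 2 times: Nc = 20
  oneCodon <- paste(rep(vapply(fams, `[`, character(1), 1), 10),
                    collapse = "")
  expect_equal(effectiveNumberOfCodons(oneCodon), 20)
  # exactly uniform usage in every family: estimator exceeds 61, capped
  uniform <- paste(rep(unlist(fams), 12), collapse = "")
  expect_equal(effectiveNumberOfCodons(uniform), 61)
  # random in-frame genes agree with the literal transcription
  set.seed(72)
  for (i in 1:20) {
    g <- randCodingSeq(194)
    expect_equal(effectiveNumberOfCodons(g), oracleNc(g), tolerance = 1e-12)
  }
  expect_true(all(vapply(1:10, function(i)
    effectiveNumberOfCodons(randCodingSeq(30)), numeric(1)) >= 20))
})

test_that("fixed-mode CAI weights follow family-relative frequencies", {
  # family {AAA, AAG} with counts {30, 10}: w(AAA)=1, w(AAG)=1/3
  ref <- paste(c(rep("AAA", 30), rep("AAG", 10)), collapse = "")
  w <- fitCaiWeights(c(r = ref), mode = "fixed")
  expect_equal(unname(w$w["AAA"]), 1)
  expect_equal(unname(w$w["AAG"]), 1 / 3, tolerance = 1e-12)
  # single reference: its codons get 1, unused synonyms the pseudo-weight
  ref2 <- paste(rep("GGA", 20), collapse = "")
  w2 <- fitCaiWeights(c(r = ref2), mode = "fixed")
  expect_equal(unname(w2$w["GGA"]), 1)
  expect_equal(unname(w2$w["GGC"]), 0.5 / 20, tolerance = 1e-12)
  # unobserved families carry NA and are skipped in scoring
  expect_true(is.na(w2$w["AAA"]))
  expect_error(fitCaiWeights(character(0)), "empty reference")
})

test_that("gcai is the geometric mean of scored weights with exclusions", {
  ref <- paste(c(rep("AAA", 30), rep("AAG", 10)), collapse = "")
  w <- fitCaiWeights(c(r = ref), mode = "fixed")
  # one AAA (w=1) and one AAG (w=1/3): sqrt(1/3)
  expect_equal(gcai("AAAAAG", w), sqrt(1 / 3), tolerance = 1e-12)
  # only preferred codons: exactly 1; Met/Trp/stops never affect the score
  expect_equal(gcai("AAAATGTGGTAA", w), 1)
})

test_that("iterative weights converge to the dominant-bias subpopulation", {
  set.seed(73)
  gc <- Biostrings::GENETIC_CODE
  fams <- split(names(gc)[gc != "*"], gc[gc != "*"])
  fams <- fams[lengths(fams) >= 2]
  dominant <- vapply(fams, `[`, character(1), 1)
  biased <- replicate(45, paste(sample(dominant, 150, replace = TRUE),
                                collapse = ""))
  uniformG <- replicate(5, paste(sample(unlist(fams), 150, replace = TRUE),
                                 collapse = ""))
  refs <- stats::setNames(c(biased, uniformG), sprintf("g%02d", 1:50))
  it <- fitCaiWeights(refs, mode = "iterative")
  fx <- fitCaiWeights(refs[1:45], mode = "fixed")
  shared <- intersect(names(it$w)[!is.na(it$w)], names(fx$w)[!is.na(fx$w)])
  expect_lt(max(abs(it$w[shared] - fx$w[shared])), 0.05)
  # genes built from the dominant bias outscore uniform-usage genes
  sB <- vapply(biased[1:5], gcai, numeric(1), weights = it)
  sU <- vapply(uniformG, gcai, numeric(1), weights = it)
  expect_gt(min(sB), max(sU))
})

test_that("OTU deviations use the OTU-unweighted global average", {
  rec <- data.frame(gene = c("a1", "a2", "b1", "b2"),
                    gc = c(40, 40, 60, 60))
  map <- c(a1 = "O1", a2 = "O1", b1 = "O2", b2 = "O2")
  dev <- otuDeviations(rec, map)
  expect_equal(attr(dev, "global")[["gc"]], 50)
  expect_equal(dev$mean_deviation[dev$otu == "O1"], -10)
  expect_equal(dev$mean_deviation[dev$otu == "O2"], 10)
  # unequal OTU sizes do not move the global average
  rec2 <- data.frame(gene = c(sprintf("a%03d", 1:100), "b1", "b2"),
                     gc = c(rep(40, 100), 60, 60))
  map2 <- c(stats::setNames(rep("O1", 100), sprintf("a%03d", 1:100)),
            b1 = "O2", b2 = "O2")
  dev2 <- otuDeviations(rec2, map2)
  expect_equal(attr(dev2, "global")[["gc"]], 50)
  # duplicating every gene of one OTU changes nothing
  rec3 <- rbind(rec2, data.frame(gene = sprintf("c%03d", 1:100),
                                 gc = rep(40, 100)))
  map3 <- c(map2, stats::setNames(rep("O1", 100), sprintf("c%03d", 1:100)))
  dev3 <- otuDeviations(rec3, map3)
  expect_equal(dev3$mean_deviation, dev2$mean_deviation)
  # single-gene OTUs report sd 0
  dev4 <- otuDeviations(data.frame(gene = c("x", "y"), gc = c(1, 3)),
                        c(x = "O1", y = "O2"))
  expect_true(all(dev4$sd == 0))
})

test_that("gene-versus-genome regression matches the closed form", {
  x <- c(1, 2, 3, 4, 5)
  r <- geneVsGenomeRegression(x, x)
  expect_equal(r$slope, 1)
  expect_equal(r$r_squared, 1)
  set.seed(74)
  xg <- rnorm(12); yg <- 2.5 * xg + rnorm(12, sd = 0.3)
  fit <- geneVsGenomeRegression(yg, xg)
  slope <- sum((xg - mean(xg)) * (yg - mean(yg))) / sum((xg - mean(xg))^2)
  intercept <- mean(yg) - slope * mean(xg)
  r2 <- slope^2 * sum((xg - mean(xg))^2) /
    sum((yg - mean(yg))^2)
  expect_equal(fit$slope, slope, tolerance = 1e-12)
  expect_equal(fit$intercept, intercept, tolerance = 1e-12)
  expect_equal(fit$r_squared, r2, tolerance = 1e-12)
  expect_error(geneVsGenomeRegression(yg, rep(1, 12)), "zero variance")
  expect_error(geneVsGenomeRegression(1:2, 1:2), "at least 3")
})

test_that("clades with distinct GC targets produce matching deviation signs", {
  cfg <- simConfig(seed = 75, n_clades = 2, otus_per_clade = 8,
                   seqs_per_otu = 4, per_clade_gc_target = c(0.40, 0.58))
  ev <- evolveSequences(simulateTree(cfg), cfg)
  sig <- signatureTable(ev$genes)
  dev <- otuDeviations(data.frame(gene = sig$gene, gc = sig$gc),
                       ev$otu_of_seq)
  lowClade <- startsWith(dev$otu, "NC")
  signsOk <- c(dev$mean_deviation[lowClade] < 0,
               dev$mean_deviation[!lowClade] > 0)
  expect_gte(mean(signsOk), 0.95)
})
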