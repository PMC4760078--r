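test_that("sampled proteins honour composition targets, repeats and seeds", {
  spec <- compositionSpec("CP_rich", target_fractions = local({
    f <- setNames(rep(0.4 / 18, 20), EDCtools:::AA20)
    f["C"] <- 0.30; f["P"] <- 0.30; f
  }))
  p <- sampleProtein(spec, 200, seed = 1)
  cp <- mean(strsplit(p, "")[[1]] %in% c("C", "P"))
  expect_gte(cp, 0.55)
  expect_lte(cp, 0.65)

  rspec <- compositionSpec("unbiased", repeat_unit = "PQQC", repeat_copies = 5)
  expect_match(sampleProtein(rspec, 50, seed = 2), "PQQCPQQCPQQCPQQCPQQC")

  expect_identical(sampleProtein(spec, 120, seed = 9),
                   sampleProtein(spec, 120, seed = 9))
  expect_false(identical(sampleProtein(spec, 120, seed = 9),
                         sampleProtein(spec, 120, seed = 10)))

  big <- compositionSpec("unbiased", repeat_unit = "AAAAAAAAAA",
                         repeat_copies = 20)
  expect_error(sampleProtein(big, 50, seed = 1), "impossible spec")
})

test_that("composition fidelity holds across 100 seeds for every class", {
  classes <- c("GS_rich", "CP_rich", "aromatic_rich", "beta_keratin_like",
               "unbiased")
  grp <- list(c("G", "S"), c("C", "P"), c("F", "W", "Y", "H"))
  for (cl in classes) {
    spec <- compositionSpec(cl)
    errs <- vapply(1:100, function(s) {
      p <- strsplit(sampleProtein(spec, 150, seed = s), "")[[1]]
      emp <- table(factor(p, levels = EDCtools:::AA20)) / length(p)
      c(residue = max(abs(as.numeric(emp) - spec$target_fractions)),
        combined = max(vapply(grp, function(g)
          abs(sum(emp[g]) - sum(spec$target_fractions[g])), numeric(1))))
    }, numeric(2))
    ## expected (mean) composition error stays within 0.05 per class
    expect_lt(mean(errs["residue", ]), 0.05)
    expect_lt(mean(errs["combined", ]), 0.05)
  }
})

test_that("reverse translation round-trips through the genetic code", {
  expect_identical(substr(reverseTranslate("M", seed = 1), 1, 3), "ATG")
  for (s in 1:5) {
    p <- sampleProtein(compositionSpec("unbiased"), 60, seed = s)
    dna <- reverseTranslate(p, seed = s)
    expect_identical(nchar(dna), 3L * (nchar(p) + 1L))
    tr <- EDCtools:::translateDNA(dna)
    expect_identical(substr(tr, 1, nchar(p)), p)
    expect_identical(substr(tr, nchar(p) + 1, nchar(p) + 1), "*")
  }
  dna <- reverseTranslate("CP", seed = 7)
  expect_identical(nchar(dna), 9L)
  expect_identical(EDCtools:::translateDNA(dna), "CP*")
  expect_error(reverseTranslate("CZ"), "standard letters")
})

test_that("plantGene assembles the exact two-exon structure", {
  p <- sampleProtein(compositionSpec("unbiased"), 100, seed = 1)
  substr(p, 1, 1) <- "M"
  cds <- reverseTranslate(p, seed = 2)
  cds <- substr(cds, 1, nchar(cds) - 3)  # 300 nt
  pg <- plantGene(cds, utr5_len = 20, tata_to_donor = 75, intron_len = 100,
                  seed = 3)
  off <- pg$offsets
  ## exon1(75) + intron(100) + utr5(20) + cds(300) + stop(3)
  expect_identical(nchar(pg$fragment), 75L + 100L + 20L + 303L)
  expect_identical(substr(pg$fragment, 1, 6), "TATAAA")
  expect_identical(substr(pg$fragment, off$intron[1], off$intron[1] + 1), "GT")
  expect_identical(substr(pg$fragment, off$intron[2] - 1, off$intron[2]), "AG")
  expect_identical(substr(pg$fragment, off$cds[1], off$cds[1] + 2), "ATG")
  expect_identical(off$utr5[2] - off$utr5[1] + 1L, 20L)

  expect_error(plantGene(cds, 9, 75, 100), "utr5_len")
  expect_error(plantGene(cds, 31, 75, 100), "utr5_len")
  expect_error(plantGene(cds, 20, 59, 100), "tata_to_donor")
  expect_error(plantGene(cds, 20, 91, 100), "tata_to_donor")
})

test_that("a planted gene is recovered with identical coordinates", {
  ps <- plantedScaffold(seed = 11)
  ms <- scanScaffolds(setNames(ps$seq, "s"))
  gr <- geneModels(ms)
  off <- ps$planted$offsets
  i <- which(GenomicRanges::start(gr) == off$cds[1] + ps$offset)
  expect_identical(length(i), 1L)
  mc <- S4Vectors::mcols(gr)[i, ]
  expect_identical(GenomicRanges::end(gr)[i], off$cds[2] + ps$offset)
  expect_identical(mc$utr5_start, off$utr5[1] + ps$offset)
  expect_identical(mc$exon1_start, off$exon1[1] + ps$offset)
  expect_identical(mc$intron_start, off$intron[1] + ps$offset)
  expect_identical(mc$protein, ps$protein)
})

test_that("buildTruthSet matches its configuration", {
  cfg <- list(families = list(
    list(name = "F1", class = "GS_rich", n = 4L),
    list(name = "F2", class = "CP_rich", n = 2L),
    list(name = "F3", class = "beta_keratin_like", n = 6L)),
    n_decoys = 2L,
    pseudogenes = list(list(family = "F1", type = "premature_stop")))
  ts <- buildTruthSet(cfg, seed = 42L)
  expect_identical(length(truthGenes(ts)), 12L)
  st <- modelStatus(truthGenes(ts))
  expect_identical(sum(st == "pseudogene"), 1L)
  mut <- S4Vectors::mcols(geneModels(truthGenes(ts)))$mutations
  expect_match(mut[st == "pseudogene"], "^premature_stop@\\d+$")
  expect_identical(length(ts@decoys), 2L)

  ## translocated family members lie outside the S100A anchors
  cfg2 <- list(families = list(list(name = "F1", class = "GS_rich", n = 2L)),
               n_decoys = 0L,
               translocations = list(list(family = "BetaO",
                                          class = "beta_keratin_like",
                                          n = 2L, anchor = "ODF3B-like")))
  ts2 <- buildTruthSet(cfg2, seed = 7L)
  expect_identical(nrow(truthEvents(ts2)), 1L)
  map <- buildLocusMap(truthGenes(ts2), truthAnchors(ts2))
  g <- map@genes
  expect_true(all(g$inside[g$family == "BetaO"] == "outside"))
  expect_true(all(g$inside[g$family == "F1"] == "inside"))
})

test_that("a single-gene simulation contains exactly one qualifying structure", {
  cfg <- list(families = list(list(name = "F1", class = "GS_rich", n = 1L)),
              n_decoys = 0L)
  ts <- buildTruthSet(cfg, seed = 5L)
  ms <- scanScaffolds(truthScaffolds(ts))
  expect_identical(length(ms), 1L)
  m <- scoreAgainstTruth(ms, ts)
  expect_identical(m$structure$precision, 1)
  expect_identical(m$structure$recall, 1)
})

test_that("truth sets round-trip losslessly through disk", {
  ts <- buildTruthSet(seed = 7L)
  dir <- withr::local_tempdir()
  suppressWarnings(writeTruthSet(ts, dir))
  ts2 <- readTruthSet(dir)
  expect_identical(as.data.frame(geneModels(truthGenes(ts))),
                   as.data.frame(geneModels(truthGenes(ts2))))
  expect_identical(as.character(truthScaffolds(ts)),
                   as.character(truthScaffolds(ts2)))
  expect_identical(as.data.frame(truthAnchors(ts)),
                   as.data.frame(truthAnchors(ts2)))
  expect_identical(ts@seed, ts2@seed)
})
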