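params <- scanParams()

## scaffold with an ORF of exactly n codons (plus ATG is codon 1) in a
## pyrimidine-padded context that offers no acceptor
orfScaffold <- function(n_aa, seed = 1) {
  p <- sampleProtein(compositionSpec("unbiased"), n_aa, seed = seed)
  substr(p, 1, 1) <- "M"
  cds <- reverseTranslate(p, seed = seed + 1)
  set.seed(seed + 2)
  ## the TTAATTAATTAA block closes all reading frames upstream of the ATG
  paste0(EDCtools:::randomDNA(288, avoid = "TATA[AT]A"), "TTAATTAATTAA", cds,
         EDCtools:::randomDNA(300, avoid = "TATA[AT]A"))
}

test_that("ORF length bounds 50-500 are inclusive", {
  for (n in c(49L, 50L, 500L, 501L)) {
    sc <- orfScaffold(n, seed = n)
    orfs <- sixFrameOrfs(sc, params)
    found <- any(orfs$start == 301L & orfs$strand == "+" &
                 nchar(orfs$protein) == n)
    expect_identical(found, n %in% c(50L, 500L), label = paste("n =", n))
  }
})

test_that("six-frame scan equals brute-force enumeration on random scaffolds", {
  for (s in c(3, 17)) {
    set.seed(s)
    sc <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
                collapse = "")
    mine <- sixFrameOrfs(sc, params, min_protein_len = 20L)
    mine <- mine[mine$truncated == "", c("start", "end", "strand")]
    mine <- mine[order(mine$start, mine$end, mine$strand), ]
    rownames(mine) <- NULL
    oracle <- oracleOrfs(sc, 20L, 500L)
    rownames(oracle) <- NULL
    expect_identical(mine, oracle)
  }
})

test_that("scanning the reverse complement mirrors all models", {
  ps <- plantedScaffold(seed = 21)
  L <- nchar(ps$seq)
  m1 <- geneModels(scanScaffolds(setNames(ps$seq, "s")))
  m2 <- geneModels(scanScaffolds(setNames(EDCtools:::revComp(ps$seq), "s")))
  expect_identical(length(m1), length(m2))
  expect_identical(sort(L - GenomicRanges::end(m1) + 1L),
                   sort(GenomicRanges::start(m2)))
  expect_false(as.character(GenomicRanges::strand(m1)) ==
               as.character(GenomicRanges::strand(m2)))
})

test_that("acceptor rule takes the innermost AG within 10-30 nt", {
  ## build: pad | AG | utr(L) | ATG...; pad is pyrimidine-only
  mk <- function(L, extra_ag_at = NULL) {
    set.seed(99)
    utr <- paste(sample(c("A", "C", "T"), L, replace = TRUE), collapse = "")
    if (!is.null(extra_ag_at))  # extra AG ending extra_ag_at nt before ATG
      substr(utr, L - extra_ag_at - 1L, L - extra_ag_at) <- "AG"
    paste0(paste(rep("C", 40), collapse = ""), "AG", utr, "ATGGCTGCT")
  }
  s10 <- mk(10)
  r <- checkAcceptor(s10, 53L, "+", params)
  expect_true(r$ok)
  expect_identical(r$L, 10L)

  s31 <- mk(31)
  r31 <- checkAcceptor(s31, 74L, "+", params)
  expect_false(r31$ok)

  s9 <- mk(9)
  expect_false(checkAcceptor(s9, 52L, "+", params)$ok)

  ## two qualifying AGs at L = 25 (planted) and L = 12 (inner): inner wins
  s2 <- mk(25, extra_ag_at = 12)
  r2 <- checkAcceptor(s2, 68L, "+", params)
  expect_true(r2$ok)
  expect_identical(r2$L, 12L)

  ## scaffold edge: no upstream context
  r3 <- checkAcceptor("ATGGCTGCTAAA", 1L, "+", params)
  expect_false(r3$ok)
  expect_identical(r3$reason, "edge")
})

test_that("exon-1 search enforces the 60-90 nt TATA-donor distance", {
  mk <- function(d, tata2 = NULL) {
    ## [CT pad][TATAAA][pad to donor][GT][intron pad][acceptor context]
    set.seed(7)
    pre <- paste(sample(c("C", "T"), 50, replace = TRUE), collapse = "")
    gap <- EDCtools:::randomDNA(d - 6L, avoid = c("TATA[AT]A", "GT"))
    if (!is.null(tata2)) substr(gap, tata2, tata2 + 5L) <- "TATAAA"
    intr <- EDCtools:::randomDNA(60, avoid = c("TATA[AT]A", "GT"))
    paste0(pre, "TATAAA", gap, "GT", intr, "AG")
  }
  for (d in c(59L, 60L, 90L, 91L)) {
    s <- mk(d)
    acc_start <- nchar(s) - 1L
    r <- findExon1(s, acc_start, "+", params)
    expect_identical(r$found, d %in% c(60L, 90L), label = paste("d =", d))
    if (r$found) expect_identical(r$donor - r$tata[1], d)
  }
  ## two qualifying TATA boxes: the one nearest the acceptor is returned
  s <- mk(85L, tata2 = 10L)   # second TATA at offset 56+10-6.. ahead
  r <- findExon1(s, nchar(s) - 1L, "+", params)
  expect_true(r$found)
  expect_gt(r$tata[1], 56L)   # the downstream (nearer) TATA won
})

test_that("a gap-interrupted gene yields one partial model", {
  cfg <- list(families = list(list(name = "F1", class = "GS_rich", n = 2L)),
              n_decoys = 0L,
              gaps = list(list(family = "F1", len = 200L)))
  ts <- buildTruthSet(cfg, seed = 11L)
  st <- modelStatus(truthGenes(ts))
  expect_identical(sum(st == "partial"), 1L)
  pred <- scanScaffolds(truthScaffolds(ts))
  pst <- modelStatus(pred)
  expect_gte(sum(pst == "partial"), 1L)
  ## the partial prediction overlaps the truncated truth gene
  tg <- geneModels(truthGenes(ts))[st == "partial"]
  pp <- geneModels(pred)[pst == "partial"]
  expect_true(any(IRanges::overlapsAny(pp, tg, ignore.strand = TRUE)))
})

test_that("iterative annotation discovers homology-only genes in round two", {
  ## gene 1: full signals; gene 2: same family, no TATA box (ORF path
  ## rejects it) -- reachable only through homology to gene 1's protein
  p1 <- sampleProtein(compositionSpec("GS_rich"), 90, seed = 31)
  substr(p1, 1, 1) <- "M"
  p2 <- p1
  set.seed(32)
  idx <- sample(2:90, 18)  # ~80% identity to p1
  for (i in idx) substr(p2, i, i) <- sample(setdiff(EDCtools:::AA20,
                                                    substr(p2, i, i)), 1)
  cds1 <- reverseTranslate(p1, seed = 33)
  cds1 <- substr(cds1, 1, nchar(cds1) - 3)
  pg1 <- plantGene(cds1, 15, 70, 90, seed = 34)
  cds2 <- reverseTranslate(p2, seed = 35)
  set.seed(36)
  utr2 <- paste(sample(c("A", "C", "T"), 14, replace = TRUE), collapse = "")
  frag2 <- paste0(paste(rep("C", 40), collapse = ""), "AG", utr2, cds2)
  set.seed(37)
  ## gene 2 sits > exon1_search_window away from gene 1, in TATA-free
  ## background, so it cannot borrow gene 1's exon 1
  sc <- paste0(EDCtools:::randomDNA(400, avoid = "TATA[AT]A"), pg1$fragment,
               EDCtools:::randomDNA(1400, avoid = "TATA[AT]A"), frag2,
               EDCtools:::randomDNA(400, avoid = "TATA[AT]A"))
  scaffolds <- Biostrings::DNAStringSet(setNames(sc, "s"))
  g2_start <- 400L + nchar(pg1$fragment) + 1400L

  ## an unrelated initial query finds nothing by homology, but the ORF scan
  ## finds gene 1; its translation then reveals gene 2 in round 2
  weak <- sampleProtein(compositionSpec("unbiased"), 90, seed = 380)
  q0 <- Biostrings::AAStringSet(setNames(weak, "init"))

  inG2 <- function(ms) {
    gr <- geneModels(ms)
    which(GenomicRanges::start(gr) >= g2_start)
  }
  round1 <- scanScaffolds(scaffolds, params, queries = q0)
  expect_identical(length(inG2(round1)), 0L)  # gene 2 invisible in round 1

  final <- iterateAnnotation(scaffolds, q0, params)
  hit2 <- inG2(final)
  expect_gte(length(hit2), 1L)
  expect_gte(attr(final, "rounds"), 2L)
  ev <- S4Vectors::mcols(geneModels(final))$evidence[hit2]
  expect_true(any(grepl("homology", ev)))

  ## query order does not change the result
  qs <- Biostrings::AAStringSet(setNames(c(weak, p1), c("a", "b")))
  f1 <- iterateAnnotation(scaffolds, qs, params)
  f2 <- iterateAnnotation(scaffolds, rev(qs), params)
  expect_identical(as.data.frame(geneModels(f1)),
                   as.data.frame(geneModels(f2)))
})

test_that("expression support is attached by interval overlap", {
  ps <- plantedScaffold(seed = 41)
  ms <- scanScaffolds(setNames(ps$seq, "s"))
  cds <- ps$planted$offsets$cds + ps$offset
  sup <- data.frame(scaffold = "s", start = cds[1] + 10, end = cds[1] + 60)
  ms2 <- addExpressionEvidence(ms, sup)
  gr <- geneModels(ms2)
  i <- which(GenomicRanges::start(gr) == cds[1])
  expect_match(S4Vectors::mcols(gr)$evidence[i], "expression")
  others <- S4Vectors::mcols(gr)$evidence[-i]
  expect_false(any(grepl("expression", others)))
})
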