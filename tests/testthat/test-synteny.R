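## Build a small locus map directly from a data frame of genes.
mkMap <- function(genes, anchors = NULL) {
  gr <- GenomicRanges::GRanges("scaf",
    IRanges::IRanges(genes$start, genes$end), strand = genes$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = genes$id, status = "complete", evidence = "orf_scan",
    family = genes$family, protein = genes$protein, score = NA_real_,
    utr5_start = NA_integer_, utr5_end = NA_integer_,
    exon1_start = NA_integer_, exon1_end = NA_integer_,
    intron_start = NA_integer_, intron_end = NA_integer_, mutations = "")
  buildLocusMap(GeneModelSet(gr), anchors)
}

simpleGenes <- function(n, fam = "F", proteins = NULL, from = 1000) {
  data.frame(id = paste0(fam, seq_len(n)),
             start = from + (seq_len(n) - 1) * 500,
             end = from + (seq_len(n) - 1) * 500 + 200,
             strand = rep(c("+", "-"), length.out = n),
             family = fam,
             protein = proteins %||% replicate(n, sampleProtein(
               compositionSpec("unbiased"), 50, seed = sample.int(1e6, 1))),
             stringsAsFactors = FALSE)
}
`%||%` <- EDCtools:::`%||%`

test_that("locus maps rank genes and delimit the EDC", {
  set.seed(1)
  g <- simpleGenes(12)
  anchors <- data.frame(name = c("S100A12-like", "S100A11-like"),
                        start = c(100, 8000), end = c(300, 8200))
  map <- mkMap(g, anchors)
  expect_identical(map@genes$rank, 0:11)
  expect_identical(length(map@edc), 2L)
  expect_true(all(map@genes$inside == "inside"))

  ## missing anchor: everything unanchored
  map2 <- mkMap(g, anchors[1, ])
  expect_identical(length(map2@edc), 0L)
  expect_true(all(map2@genes$inside == "unanchored"))

  ## straddling gene is an error
  g3 <- g; g3$start[1] <- 250; g3$end[1] <- 450
  expect_error(mkMap(g3, anchors), "straddle")
})

test_that("ortholog linking is reciprocal-best and symmetric", {
  set.seed(2)
  prots <- vapply(1:6, function(i)
    sampleProtein(compositionSpec("GS_rich"), 60, seed = 50 + i), character(1))
  gA <- simpleGenes(6, fam = "F", proteins = prots)
  anchors <- data.frame(name = c("S100A12-like", "S100A11-like"),
                        start = c(100, 9000), end = c(300, 9200))
  mapA <- mkMap(gA, anchors)
  links <- linkOrthologs(mapA, mapA)
  expect_identical(nrow(links[links$type == "ortholog", ]), 6L)
  expect_true(all(links$identity[links$type == "ortholog"] == 1))

  ## remove one gene from B: one fewer ortholog link
  mapB <- mkMap(gA[-3, ], anchors)
  linksAB <- linkOrthologs(mapA, mapB)
  expect_identical(sum(linksAB$type == "ortholog"), 5L)

  ## symmetry: (A,B) equals the transpose of (B,A)
  linksBA <- linkOrthologs(mapB, mapA)
  ab <- linksAB[linksAB$type == "ortholog", c("idA", "idB")]
  ba <- linksBA[linksBA$type == "ortholog", c("idB", "idA")]
  names(ba) <- c("idA", "idB")
  expect_identical(ab[order(ab$idA), ], ba[order(ba$idA), ],
                   ignore_attr = TRUE)
})

test_that("collinear blocks equal exhaustive LIS chaining", {
  mkLinks <- function(rankB) data.frame(
    idA = paste0("a", seq_along(rankB)), idB = paste0("b", rankB),
    rankA = seq_along(rankB) - 1L, rankB = rankB, family = "F",
    identity = 1, type = "ortholog", stringsAsFactors = FALSE)

  cb <- collinearBlocks(mkLinks(0:9))
  expect_identical(length(cb$blocks), 1L)
  expect_identical(length(cb$blocks[[1]]), 10L)

  cb2 <- collinearBlocks(mkLinks(c(0L, 1L, 4L, 2L, 3L)))
  expect_identical(length(cb2$blocks[[1]]), 4L)
  expect_identical(length(cb2$rearranged), 1L)

  empty <- data.frame(type = character(0), rankA = integer(0),
                      rankB = integer(0))
  expect_identical(collinearBlocks(empty)$blocks, list())

  ## main chain length equals brute-force LIS on random permutations
  for (s in 1:10) {
    set.seed(s)
    v <- sample(0:9)
    cb3 <- collinearBlocks(mkLinks(v))
    expect_identical(length(cb3$blocks[[1]]), oracleLIS(v),
                     label = paste("perm seed", s))
  }
})

test_that("translocations are detected relative to the EDC interval", {
  set.seed(4)
  g <- rbind(simpleGenes(4, fam = "IN"),
             simpleGenes(2, fam = "OUT", from = 20000))
  g$id <- make.unique(g$id)
  anchors <- data.frame(
    name = c("S100A12-like", "S100A11-like", "SLAMF8-like"),
    start = c(100, 6000, 19000), end = c(300, 6200, 19200))
  map <- mkMap(g, anchors)
  tr <- detectTranslocations(map)
  expect_identical(nrow(tr), 2L)
  expect_true(all(tr$family == "OUT"))
  expect_true(all(tr$kind == "external_family"))
  expect_true(all(tr$nearest_anchor == "SLAMF8-like"))

  ## split family: members both inside and outside
  g2 <- g; g2$family <- "MIX"
  tr2 <- detectTranslocations(mkMap(g2, anchors))
  expect_identical(nrow(tr2), 2L)
  expect_true(all(tr2$kind == "translocated"))

  ## all inside: empty report
  tr3 <- detectTranslocations(mkMap(simpleGenes(4), anchors))
  expect_identical(nrow(tr3), 0L)

  ## no anchors: error
  expect_error(detectTranslocations(mkMap(simpleGenes(3))),
               "cannot classify")
})

test_that("compareLoci assembles links, blocks, translocations and counts", {
  set.seed(5)
  prots <- vapply(1:5, function(i)
    sampleProtein(compositionSpec("CP_rich"), 60, seed = 70 + i), character(1))
  anchors <- data.frame(name = c("S100A12-like", "S100A11-like"),
                        start = c(100, 9000), end = c(300, 9200))
  mapA <- mkMap(simpleGenes(5, fam = "F", proteins = prots), anchors)
  rep <- compareLoci(mapA, mapA)
  expect_s4_class(rep, "SyntenyReport")
  expect_identical(length(rep@blocks), 1L)
  expect_identical(rep@familyCounts$n, c(5L, 5L))
})
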