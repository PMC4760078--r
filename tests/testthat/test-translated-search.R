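B62 <- EDCtools:::.getMatrix("BLOSUM62")

test_that("a query identical to a planted CDS gives one full-length HSP", {
  p <- sampleProtein(compositionSpec("unbiased"), 80, seed = 3)
  substr(p, 1, 1) <- "M"
  cds <- reverseTranslate(p, seed = 4)
  set.seed(5)
  sc <- paste0(EDCtools:::randomDNA(500), cds, EDCtools:::randomDNA(500))
  h <- translatedSearch(setNames(p, "q"), sc)
  expect_identical(nrow(h), 1L)
  expect_identical(h$strand, "+")
  expect_identical(c(h$q_start, h$q_end), c(1L, 80L))
  expect_identical(h$identity, 1)
  ## strand symmetry: the reverse complement reports the mirrored hit
  hrc <- translatedSearch(setNames(p, "q"), EDCtools:::revComp(sc))
  expect_identical(hrc$strand, "-")
  expect_identical(hrc$score, h$score)
  expect_identical(nchar(sc) - hrc$s_nt_end + 1L, h$s_nt_start)
})

test_that("HSP scores match exhaustive Smith-Waterman on small instances", {
  ## planted 80%-identity target: the heuristic must find the SW optimum
  p <- sampleProtein(compositionSpec("unbiased"), 60, seed = 8)
  target <- p
  set.seed(9)
  for (i in sample(1:60, 12))
    substr(target, i, i) <- sample(setdiff(EDCtools:::AA20,
                                           substr(target, i, i)), 1)
  cds <- reverseTranslate(paste0("M", substr(target, 2, 60)), seed = 10)
  set.seed(11)
  sc <- paste0(EDCtools:::randomDNA(400), cds, EDCtools:::randomDNA(400))
  h <- translatedSearch(setNames(p, "q"), sc)
  expect_gte(nrow(h), 1L)
  sw <- oracleTranslatedBest(p, sc, B62)
  expect_identical(max(h$score), sw)

  ## random queries: both routes agree that nothing scores >= min_score
  set.seed(12)
  for (k in 1:2) {
    q <- sampleProtein(compositionSpec("unbiased"), 60, seed = 20 + k)
    h2 <- translatedSearch(setNames(q, "r"), substr(sc, 1, 1500))
    sw2 <- oracleTranslatedBest(q, substr(sc, 1, 1500), B62)
    if (sw2 < scanParams()$min_score) expect_identical(nrow(h2), 0L)
    else expect_identical(max(h2$score), sw2)
  }
})

test_that("invalid query letters are rejected", {
  expect_error(translatedSearch(setNames("MKLZ", "bad"), "ATGGCTAAA"),
               "outside the standard alphabet")
})
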