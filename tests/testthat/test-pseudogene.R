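test_that("single inactivating mutations are located within one codon", {
  set.seed(101)
  n_cases <- 30L
  correct_type <- 0L
  pos_ok <- 0L
  for (k in seq_len(n_cases)) {
    prot <- sampleProtein(compositionSpec("unbiased"), 80, seed = 200 + k)
    cds <- reverseTranslate(prot, seed = 300 + k)
    type <- if (k %% 2 == 0) "premature_stop" else "frameshift"
    codon <- sample(10:70, 1)
    if (type == "premature_stop") {
      mut <- cds
      substr(mut, codon * 3 - 2, codon * 3) <- "TAA"
    } else {
      pos <- codon * 3 - 1
      mut <- paste0(substr(cds, 1, pos - 1), substr(cds, pos + 1, nchar(cds)))
    }
    r <- detectPseudogene(mut, prot)
    expect_identical(attr(r, "status"), "mutated")
    if (nrow(r) >= 1 && r$type[1] == type) correct_type <- correct_type + 1L
    if (nrow(r) >= 1 && abs(r$codon[1] - codon) <= 1) pos_ok <- pos_ok + 1L
  }
  expect_identical(correct_type, n_cases)
  expect_identical(pos_ok, n_cases)
})

test_that("intact and unalignable loci are distinguished", {
  prot <- sampleProtein(compositionSpec("GS_rich"), 90, seed = 5)
  cds <- reverseTranslate(prot, seed = 6)
  r <- detectPseudogene(cds, prot)
  expect_identical(nrow(r), 0L)
  expect_identical(attr(r, "status"), "intact")

  set.seed(7)
  junk <- EDCtools:::randomDNA(300)
  r2 <- detectPseudogene(junk, prot)
  expect_identical(attr(r2, "status"), "unalignable")

  expect_error(detectPseudogene("ATGGCA", prot), "at least 30 nt")
  expect_error(detectPseudogene(cds, "MKL"), "at least 10 aa")
})

test_that("the aligner tolerates flanking non-coding context", {
  prot <- sampleProtein(compositionSpec("unbiased"), 60, seed = 15)
  cds <- reverseTranslate(prot, seed = 16)
  mut <- cds
  substr(mut, 30 * 3 - 2, 30 * 3) <- "TGA"
  set.seed(17)
  locus <- paste0(EDCtools:::randomDNA(50), mut, EDCtools:::randomDNA(50))
  r <- detectPseudogene(locus, prot)
  expect_identical(attr(r, "status"), "mutated")
  expect_identical(r$type[1], "premature_stop")
  expect_lte(abs(r$codon[1] - 30), 1)
})
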