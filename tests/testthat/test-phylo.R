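test_that("progressive alignment handles identical and near pairs", {
  m <- progressiveAlign(setNames(c("MKLVQW", "MKLVQW"), c("a", "b")))
  rows <- as.character(Biostrings::unmasked(m))
  expect_identical(unname(rows), c("MKLVQW", "MKLVQW"))

  m2 <- progressiveAlign(setNames(c("ACDEF", "ACEF"), c("a", "b")))
  rows2 <- as.character(Biostrings::unmasked(m2))
  expect_identical(unname(rows2), c("ACDEF", "AC-EF"))

  expect_error(progressiveAlign(setNames("ACDEF", "solo")), "at least 2")
})

test_that("alignments degap to their inputs regardless of input order", {
  fam <- simulateProteinFamilies(n_taxa = 3, seq_len = 50, seed = 2)
  seqs <- as.character(fam)
  msa <- progressiveAlign(fam)
  rows <- as.character(Biostrings::unmasked(msa))
  expect_identical(gsub("-", "", rows)[names(seqs)], seqs)
  ## shuffled input: same column count, same degap invariant
  perm <- c(4, 1, 6, 3, 2, 5)
  msa2 <- progressiveAlign(fam[perm])
  rows2 <- as.character(Biostrings::unmasked(msa2))
  expect_identical(unname(nchar(rows2[1])), unname(nchar(rows[1])))
  expect_identical(gsub("-", "", rows2)[names(seqs)], seqs)
})

test_that("core extraction is 1-based inclusive and drops all-gap rows", {
  rows <- c(a = paste(rep("A", 200), collapse = ""),
            b = paste(c(rep("A", 100), rep("-", 100)), collapse = ""),
            c = paste(c(rep("-", 150), rep("A", 50)), collapse = ""))
  msa <- Biostrings::AAMultipleAlignment(Biostrings::AAStringSet(rows))
  expect_warning(core <- extractCore(msa, 67, 126), "all-gap")
  expect_identical(unique(nchar(as.character(Biostrings::unmasked(core)))),
                   60L)
  expect_warning(dropped <- extractCore(msa, 141, 160), "all-gap")
  expect_identical(names(as.character(Biostrings::unmasked(dropped))),
                   c("a", "c"))
  full <- extractCore(msa, 1, 200)
  expect_identical(as.character(Biostrings::unmasked(full)), rows)
  expect_error(extractCore(msa, 10, 9), "invalid")
  expect_error(extractCore(msa, 0, 10), "invalid")
})

test_that("distances apply the stated corrections exactly", {
  rows <- c(x = strrep("A", 100), y = paste0(strrep("A", 99), "V"),
            z = strrep("A", 100))
  D <- alignmentDistances(rows, "p")
  expect_identical(D["x", "z"], 0)
  expect_identical(D["x", "y"], 0.01)
  rows2 <- c(x = strrep("A", 100),
             y = paste0(strrep("V", 10), strrep("A", 90)),
             z = strrep("A", 100))
  Dp <- alignmentDistances(rows2, "poisson")
  expect_equal(Dp["x", "y"], -log(0.9), tolerance = 1e-12)
  Dk <- alignmentDistances(rows2, "kimura_protein")
  expect_equal(Dk["x", "y"], -log(1 - 0.1 - 0.2 * 0.01), tolerance = 1e-12)
  ## too few shared columns -> missing
  rows3 <- c(x = paste0("AAAAA", strrep("-", 95)),
             y = paste0(strrep("-", 95), "AAAAA"),
             z = strrep("A", 100))
  D3 <- alignmentDistances(rows3, "p")
  expect_true(is.na(D3["x", "y"]))
})

test_that("neighbor joining recovers additive topologies with clean lengths", {
  ## 4-taxon additive matrix built from ((A:1,B:2):1,(C:3,D:1))
  D <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  D["A", "B"] <- D["B", "A"] <- 3
  D["A", "C"] <- D["C", "A"] <- 5
  D["A", "D"] <- D["D", "A"] <- 3
  D["B", "C"] <- D["C", "B"] <- 6
  D["B", "D"] <- D["D", "B"] <- 4
  D["C", "D"] <- D["D", "C"] <- 4
  tr <- supportTree(njTree(D))
  ## split AB|CD is recovered
  part <- ape::prop.part(tr)
  labs <- attr(part, "labels")
  sides <- lapply(part, function(p) sort(labs[p]))
  expect_true(list(c("A", "B")) %in% sides || list(c("C", "D")) %in% sides)
  expect_true(all(tr$edge.length >= 0))

  expect_error(njTree(matrix(c(0, NA, NA, 0), 2, 2)), "missing")

  ## random additive matrices, n in 4..8
  for (s in 1:20) {
    o <- oracleAdditiveMatrix(4 + (s %% 5), seed = s)
    nt <- supportTree(njTree(o$D))
    expect_true(sameTopology(o$tree, nt), label = paste("trial", s))
  }
})

test_that("bootstrap support is deterministic and finds certain cherries", {
  set.seed(30)
  a <- sampleProtein(compositionSpec("unbiased"), 60, seed = 601)
  b <- sampleProtein(compositionSpec("unbiased"), 60, seed = 602)
  ## t1 and t2 identical; t3-t5 close relatives of an unrelated sequence,
  ## so the (t1,t2) cherry is certain in every replicate
  rows <- c(t1 = a, t2 = a,
            t3 = EDCtools:::.mutateProtein(b, 0.05, 603),
            t4 = EDCtools:::.mutateProtein(b, 0.05, 604),
            t5 = EDCtools:::.mutateProtein(b, 0.05, 605))
  msa <- Biostrings::AAMultipleAlignment(Biostrings::AAStringSet(rows))
  bt <- bootstrapSupport(msa, n_replicates = 200, seed = 5)
  cs <- cladeSupport(bt, c("t1", "t2"))
  expect_true(cs$is_monophyletic)
  expect_gte(cs$support, 95)
  expect_identical(cs$classification, "strongly_supported")

  bt2 <- bootstrapSupport(msa, n_replicates = 200, seed = 5)
  expect_identical(supportValues(bt), supportValues(bt2))

  bt0 <- bootstrapSupport(msa, n_replicates = 0, seed = 5)
  expect_true(all(is.na(supportValues(bt0))))

  expect_identical(cladeSupport(bt, supportTree(bt)$tip.label)$support, NA_real_)
  expect_error(cladeSupport(bt, c("t1", "nope")), "unknown taxa")
})

test_that("planted families form recoverable monophyletic clades", {
  fam <- simulateProteinFamilies(n_taxa = 6, seq_len = 60, seed = 11)
  msa <- progressiveAlign(fam)
  bt <- bootstrapSupport(msa, n_replicates = 200, seed = 7)
  csA <- cladeSupport(bt, attr(fam, "clades")$A)
  csB <- cladeSupport(bt, attr(fam, "clades")$B)
  expect_true(csA$is_monophyletic)
  expect_true(csB$is_monophyletic)
  expect_gte(csA$support, 90)
  expect_gte(csB$support, 90)
})
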