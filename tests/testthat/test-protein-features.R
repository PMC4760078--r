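test_that("composition profiles count exactly", {
  p <- compositionProfile("GGSS")
  expect_identical(p$fractions[["G"]], 0.5)
  expect_identical(p$fractions[["S"]], 0.5)
  expect_identical(p$gs_combined, 1)
  expect_identical(compositionProfile("CPCP")$cp_combined, 1)
  pr <- compositionProfile(sampleProtein(compositionSpec("unbiased"), 137,
                                         seed = 1))
  expect_equal(sum(pr$fractions), 1, tolerance = 1e-12)
  ## exact counting: fractions times length are integers
  expect_true(all(abs(pr$fractions * 137 - round(pr$fractions * 137)) < 1e-9))
  expect_error(compositionProfile(""), "non-empty")
  expect_error(compositionProfile("MKLB"), "non-standard")
})

test_that("beta-core detection responds to propensity, not context", {
  lowctx <- paste(rep("P", 40), collapse = "")
  hit <- detectBetaCore(paste0(lowctx, paste(rep("V", 34), collapse = ""),
                               lowctx))
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$mean_propensity, 1.70, tolerance = 1e-9)
  expect_identical(hit$end - hit$start + 1L, 34L)

  none <- detectBetaCore(paste(rep("P", 100), collapse = ""))
  expect_identical(nrow(none), 0L)

  short <- detectBetaCore(paste(rep("V", 33), collapse = ""))
  expect_identical(nrow(short), 0L)
  expect_match(attr(short, "reason"), "shorter")
})

test_that("tandem repeats are found with the smallest-period tie-break", {
  ## flanks share no residue with the repeat unit, so the array cannot
  ## extend or rotate into them
  p <- paste0(strrep("W", 11), strrep("AQPGY", 6), strrep("K", 11))
  calls <- findTandemRepeats(p)
  expect_gte(nrow(calls), 1L)
  expect_identical(calls$unit[1], "AQPGY")
  expect_identical(calls$copies[1], 6L)

  mono <- findTandemRepeats("AAAAAA", min_unit = 1)
  expect_identical(mono$unit[1], "A")
  expect_identical(mono$copies[1], 6L)

  ## a random sequence carries no >= 3-copy array (checked against an
  ## independent brute-force period scan)
  r <- sampleProtein(compositionSpec("unbiased"), 200, seed = 6)
  calls_r <- findTandemRepeats(r)
  brute <- function(s, min_u = 2, max_u = 30, min_c = 3) {
    ch <- strsplit(s, "")[[1]]
    for (u in min_u:max_u) for (p0 in seq_len(length(ch) - min_c * u + 1)) {
      copies <- 1
      repeat {
        a <- p0 + copies * u
        if (a + u - 1 > length(ch)) break
        mism <- sum(ch[a:(a + u - 1)] != ch[(a - u):(a - 1)])
        if (mism > 1) break
        copies <- copies + 1
      }
      if (copies >= min_c) return(TRUE)
    }
    FALSE
  }
  expect_identical(nrow(calls_r) > 0, brute(r))
})

test_that("terminal motif profiles score shared termini maximally", {
  shared_n <- "MPCQQSNKYDDQ"
  set.seed(8)
  prots <- vapply(1:10, function(i) {
    body <- sampleProtein(compositionSpec("unbiased"), 60, seed = 40 + i)
    paste0(shared_n, body)
  }, character(1))
  names(prots) <- paste0("p", 1:10)
  tm <- terminalMotifProfiles(prots)
  expect_true(all(abs(colSums(tm$n_profile) - 1) < 1e-9))
  expect_lt(max(tm$scores$n_score) - min(tm$scores$n_score), 1e-9)
  ## a random protein scores below the members
  rnd <- paste0(sampleProtein(compositionSpec("unbiased"), 72, seed = 99))
  sc <- sum(log2(tm$n_profile[cbind(match(strsplit(substr(rnd, 1, 12), "")[[1]],
                                          EDCtools:::AA20), 1:12)] /
                 tm$background[strsplit(substr(rnd, 1, 12), "")[[1]]]))
  expect_lt(sc, min(tm$scores$n_score))
  expect_error(terminalMotifProfiles(prots[1:3]), "at least 5")
})

test_that("family classification follows the fixed precedence", {
  mk <- function(cp = 0, gs = 0, ar = 0) {
    f <- setNames(rep(0, 20), EDCtools:::AA20)
    f["C"] <- cp / 2; f["P"] <- cp / 2
    f["G"] <- gs / 2; f["S"] <- gs / 2
    f["Y"] <- ar
    f["A"] <- 1 - sum(f)
    list(length = 100, fractions = f, cp_combined = cp, gs_combined = gs,
         aromatic_combined = ar, kq_combined = 0)
  }
  nohit <- data.frame(start = integer(0), end = integer(0))
  hit <- data.frame(start = 1L, end = 34L, mean_propensity = 1.5)

  expect_identical(classifyFamily(mk(cp = 0.52), nohit)$class_label, "CP_rich")
  expect_identical(classifyFamily(mk(cp = 0.6), hit)$class_label,
                   "beta_keratin")
  r <- classifyFamily(mk(), nohit, homology_best_family = "EDQM",
                      homology_identity = 0.8)
  expect_identical(r$family, "EDQM")
  expect_identical(r$class_label, "other")
  expect_identical(classifyFamily(mk(gs = 0.55), nohit)$class_label, "GS_rich")
  expect_identical(classifyFamily(mk(ar = 0.3), nohit)$class_label,
                   "aromatic_rich")
  expect_identical(classifyFamily(mk(), nohit)$class_label, "other")
})

test_that("sampled proteins are classified into their generating class", {
  classes <- c(GS_rich = "GS_rich", CP_rich = "CP_rich",
               aromatic_rich = "aromatic_rich",
               beta_keratin_like = "beta_keratin", unbiased = "other")
  for (cl in names(classes)) {
    hits <- vapply(1:40, function(s) {
      p <- sampleProtein(compositionSpec(cl), 150, seed = 1000 + s)
      prof <- compositionProfile(p)
      bh <- detectBetaCore(p)
      classifyFamily(prof, bh)$class_label == classes[[cl]]
    }, logical(1))
    expect_gte(mean(hits), 0.9)
  }
})

test_that("profile mode scores beta cores against a seed profile", {
  prof <- matrix(-1, nrow = 20, ncol = 34,
                 dimnames = list(EDCtools:::AA20, NULL))
  prof["V", ] <- 2   # a degenerate profile rewarding valine everywhere
  bp <- betaCoreParams(seed_profile = prof, profile_threshold = 30)
  p <- paste0(strrep("P", 20), strrep("V", 34), strrep("P", 20))
  hit <- detectBetaCore(p, bp)
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$profile_score, 34 * 2, tolerance = 1e-9)
  expect_identical(nrow(detectBetaCore(strrep("P", 80), bp)), 0L)
})
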