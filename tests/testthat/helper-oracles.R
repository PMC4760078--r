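## Independent brute-force oracles used to validate the optimized
## implementations on small instances. These deliberately share no code
## with the package internals.

## Naive six-frame ORF enumeration: walk codons one by one.
oracleOrfs <- function(seq, min_len = 50L, max_len = 500L) {
  seq <- as.character(seq)
  L <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  gc <- Biostrings::GENETIC_CODE
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (f in 0:2) {
      npos <- (nchar(s) - f) %/% 3L
      if (npos < 1L) next
      aas <- character(npos)
      for (k in seq_len(npos)) {
        cod <- substr(s, f + 3L * k - 2L, f + 3L * k)
        aas[k] <- if (grepl("N", cod)) "X" else gc[[cod]]
      }
      k <- 1L
      seg_start <- 1L
      while (k <= npos + 1L) {
        if (k > npos || aas[k] %in% c("*", "X")) {
          seg <- if (seg_start <= k - 1L) seg_start:(k - 1L) else integer(0)
          m <- seg[which(aas[seg] == "M")[1]]
          if (length(m) && !is.na(m) && k <= npos && aas[k] == "*") {
            aalen <- (k - 1L) - m + 1L
            if (aalen >= min_len && aalen <= max_len) {
              o1 <- f + 3L * (m - 1L) + 1L
              o2 <- f + 3L * k
              iv <- if (strand == "+") c(o1, o2) else c(L - o2 + 1L, L - o1 + 1L)
              out[[length(out) + 1L]] <- data.frame(
                start = iv[1], end = iv[2], strand = strand)
            }
          }
          seg_start <- k + 1L
        }
        k <- k + 1L
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0)))
  df <- unique(do.call(rbind, out))
  df[order(df$start, df$end, df$strand), , drop = FALSE]
}

## Plain Smith-Waterman local alignment score with affine gaps
## (gap of length k costs open + ext * k), scalar DP.
oracleSW <- function(a, b, B, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - open - ext, E[i + 1, j] - ext)
      F[i + 1, j + 1] <- max(H[i, j + 1] - open - ext, F[i, j + 1] - ext)
      H[i + 1, j + 1] <- max(0, H[i, j] + B[av[i], bv[j]],
                             E[i + 1, j + 1], F[i + 1, j + 1])
      if (H[i + 1, j + 1] > best) best <- H[i + 1, j + 1]
    }
  }
  best
}

## Best SW score of a protein query against all six frame translations.
oracleTranslatedBest <- function(query, seq, B, open = 11, ext = 1) {
  seq <- as.character(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  best <- 0
  for (s in c(seq, rc)) {
    for (f in 0:2) {
      n <- (nchar(s) - f) %/% 3L
      if (n < 1L) next
      subj <- as.character(suppressWarnings(
        Biostrings::translate(Biostrings::DNAString(substr(s, f + 1L, f + 3L * n)),
                              if.fuzzy.codon = "X", no.init.codon = TRUE)))
      sc <- oracleSW(query, subj, B, open, ext)
      if (sc > best) best <- sc
    }
  }
  best
}

## Exhaustive longest strictly-increasing subsequence length (n <= 15).
oracleLIS <- function(v) {
  n <- length(v)
  best <- 0L
  for (k in n:1) {
    if (k <= best) break
    cmb <- utils::combn(n, k)
    for (c_ in seq_len(ncol(cmb))) {
      sub <- v[cmb[, c_]]
      if (all(diff(sub) > 0)) { best <- k; break }
    }
    if (best == k) break
  }
  best
}

## Random additive distance matrix from a random binary tree.
oracleAdditiveMatrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.1, 1)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

## Robinson-Foulds distance of 0 <=> same unrooted topology.
sameTopology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1] == 0
}

## Build a minimal scaffold with one planted gene and clean flanks.
plantedScaffold <- function(seed = 1L, plen = 80L, utr5 = 20L, d = 75L,
                            intron = 100L, class = "unbiased") {
  p <- sampleProtein(compositionSpec(class), plen, seed = seed)
  substr(p, 1, 1) <- "M"
  cds <- reverseTranslate(p, seed = seed + 1L)
  cds <- substr(cds, 1, nchar(cds) - 3L)
  pg <- plantGene(cds, utr5, d, intron, seed = seed + 2L)
  set.seed(seed + 3L)
  left <- EDCtools:::randomDNA(600L, avoid = "TATA[AT]A")
  right <- EDCtools:::randomDNA(600L, avoid = "TATA[AT]A")
  list(seq = paste0(left, pg$fragment, right),
       offset = 600L, planted = pg, protein = p)
}
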