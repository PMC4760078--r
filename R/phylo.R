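## ---------------------------------------------------------------------------
## Companion phylogeny for beta-keratin core segments: progressive multiple
## alignment, core-block extraction, corrected distances, neighbor joining
## and classical bootstrap support, with clade-monophyly queries.
## ---------------------------------------------------------------------------

## k-mer count distance between unaligned sequences (guide-tree metric).
.kmerDist <- function(seqs, k = 3L) {
  n <- length(seqs)
  counts <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(table(character(0)))
    table(substring(s, seq_len(nchar(s) - k + 1L),
                    seq_len(nchar(s) - k + 1L) + k - 1L))
  })
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ci <- counts[[i]]; cj <- counts[[j]]
    common <- intersect(names(ci), names(cj))
    shared <- if (length(common)) sum(pmin(ci[common], cj[common])) else 0
    denom <- max(1L, min(sum(ci), sum(cj)))
    D[i, j] <- D[j, i] <- 1 - shared / denom
  }
  D
}

## Global affine-gap alignment of two profiles given the column-column
## score matrix S (L1 x L2). Returns the traceback path as a two-row
## logical: which side advances at each alignment column.
.profileAlign <- function(S, gap_open, gap_ext) {
  L1 <- nrow(S); L2 <- ncol(S)
  NEG <- -1e9
  M <- matrix(NEG, L1 + 1L, L2 + 1L)
  X <- matrix(NEG, L1 + 1L, L2 + 1L)  # gap in profile 2 (advance 1)
  Y <- matrix(NEG, L1 + 1L, L2 + 1L)  # gap in profile 1 (advance 2)
  M[1, 1] <- 0
  for (i in seq_len(L1)) X[i + 1L, 1L] <- -gap_open - gap_ext * i
  for (j in seq_len(L2)) Y[1L, j + 1L] <- -gap_open - gap_ext * j
  for (i in seq_len(L1)) {
    for (j in seq_len(L2)) {
      M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + S[i, j]
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - gap_open - gap_ext,
                               X[i, j + 1L] - gap_ext)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - gap_open - gap_ext,
                               Y[i + 1L, j] - gap_ext)
    }
  }
  ## traceback from the best terminal state
  states <- c(M[L1 + 1L, L2 + 1L], X[L1 + 1L, L2 + 1L], Y[L1 + 1L, L2 + 1L])
  st <- which.max(states)
  i <- L1; j <- L2
  path <- list()
  while (i > 0L || j > 0L) {
    if (st == 1L && i > 0L && j > 0L) {
      path[[length(path) + 1L]] <- c(TRUE, TRUE)
      prevs <- c(M[i, j], X[i, j], Y[i, j])
      i <- i - 1L; j <- j - 1L
      st <- which.max(prevs)
    } else if (st == 2L || j == 0L) {
      path[[length(path) + 1L]] <- c(TRUE, FALSE)
      from_m <- M[i, j + 1L] - gap_open - gap_ext
      from_x <- X[i, j + 1L] - gap_ext
      st <- if (from_m >= from_x) 1L else 2L
      i <- i - 1L
    } else {
      path[[length(path) + 1L]] <- c(FALSE, TRUE)
      from_m <- M[i + 1L, j] - gap_open - gap_ext
      from_y <- Y[i + 1L, j] - gap_ext
      st <- if (from_m >= from_y) 1L else 3L
      j <- j - 1L
    }
  }
  do.call(rbind, rev(path))
}

## Column frequency matrix (20 x L) of an aligned block; gaps contribute 0.
.colFreq <- function(rows) {
  L <- nchar(rows[1])
  M <- matrix(0, 20L, L, dimnames = list(AA20, NULL))
  for (s in rows) {
    ch <- strsplit(s, "")[[1]]
    ok <- ch %in% AA20
    M[cbind(match(ch[ok], AA20), which(ok))] <-
      M[cbind(match(ch[ok], AA20), which(ok))] + 1
  }
  M / length(rows)
}

#' Progressive multiple alignment of protein sequences
#'
#' Builds a guide tree by UPGMA on 3-mer count distances and aligns
#' profiles along it with global affine-gap profile-profile alignment
#' (sum-of-pairs scoring under the chosen substitution matrix). Degapping
#' any output row recovers its input sequence.
#'
#' @param proteins \code{AAStringSet} or named character vector (>= 2).
#' @param matrix Substitution matrix name.
#' @param gap_open,gap_ext Affine gap costs.
#' @return An \code{AAMultipleAlignment} with rows in input order.
#' @export
progressiveAlign <- function(proteins, matrix = "BLOSUM62",
                             gap_open = 11, gap_ext = 1) {
  seqs <- as.character(proteins)
  nm <- names(proteins) %||% sprintf("seq%03d", seq_along(seqs))
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences")
  B <- .getMatrix(matrix)[AA20, AA20]
  if (n == 2L) {
    merge_order <- matrix(c(-1L, -2L), 1L, 2L)
  } else {
    D <- .kmerDist(seqs)
    hc <- hclust(as.dist(D), method = "average")
    merge_order <- hc$merge
  }
  ## each node holds the aligned rows (named) of its cluster
  nodes <- list()
  leaf <- function(i) setNames(seqs[i], nm[i])
  alignPair <- function(rows1, rows2) {
    P1 <- .colFreq(rows1); P2 <- .colFreq(rows2)
    S <- t(P1) %*% B %*% P2
    path <- .profileAlign(S, gap_open, gap_ext)
    expand <- function(rows, adv) {
      L <- nchar(rows[1])
      idx <- integer(nrow(path)); pos <- 0L
      out <- character(length(rows))
      take <- cumsum(adv)
      for (r in seq_along(rows)) {
        ch <- strsplit(rows[r], "")[[1]]
        out[r] <- paste(ifelse(adv, ch[take], "-"), collapse = "")
      }
      setNames(out, names(rows))
    }
    c(expand(rows1, path[, 1]), expand(rows2, path[, 2]))
  }
  for (r in seq_len(nrow(merge_order))) {
    a <- merge_order[r, 1]; b <- merge_order[r, 2]
    ra <- if (a < 0) leaf(-a) else nodes[[a]]
    rb <- if (b < 0) leaf(-b) else nodes[[b]]
    ## canonical orientation (smallest member name first) makes the result
    ## independent of the input order of the sequences
    if (min(names(rb)) < min(names(ra))) { tmp <- ra; ra <- rb; rb <- tmp }
    nodes[[r]] <- alignPair(ra, rb)
  }
  rows <- nodes[[nrow(merge_order)]]
  rows <- rows[nm]
  Biostrings::AAMultipleAlignment(Biostrings::AAStringSet(rows))
}

#' Extract a core column block from an alignment
#'
#' Columns are counted 1-based and inclusive. Rows that are entirely gaps
#' within the block are dropped with a warning.
#'
#' @param msa An \code{AAMultipleAlignment}.
#' @param start_col,end_col Column range (1-based inclusive).
#' @return An \code{AAMultipleAlignment} restricted to the block.
#' @export
extractCore <- function(msa, start_col, end_col) {
  rows <- as.character(Biostrings::unmasked(msa))
  L <- nchar(rows[1])
  if (start_col < 1L || end_col > L || start_col > end_col)
    stop("column range [", start_col, ", ", end_col,
         "] is invalid for an alignment of ", L, " columns")
  block <- substring(rows, start_col, end_col)
  names(block) <- names(rows)
  allgap <- !grepl("[^-]", block)
  if (any(allgap)) {
    warning("dropping all-gap row(s): ",
            paste(names(block)[allgap], collapse = ", "))
    block <- block[!allgap]
  }
  Biostrings::AAMultipleAlignment(Biostrings::AAStringSet(block))
}

#' Pairwise distances from a protein alignment
#'
#' Distances are computed over shared non-gap columns; pairs with fewer
#' than \code{min_shared} shared columns are flagged as missing (NA).
#'
#' @param msa An \code{AAMultipleAlignment} (or named character rows).
#' @param correction \code{"p"} (raw proportion), \code{"poisson"}
#'   (-ln(1-p)) or \code{"kimura_protein"} (-ln(1 - p - 0.2 p^2)).
#' @param min_shared Minimum shared columns per pair.
#' @return Symmetric matrix with zero diagonal; NA marks missing pairs.
#' @export
alignmentDistances <- function(msa, correction = c("p", "poisson",
                                                   "kimura_protein"),
                               min_shared = 10L) {
  correction <- match.arg(correction)
  rows <- if (is.character(msa)) msa else
    as.character(Biostrings::unmasked(msa))
  if (length(rows) < 3L) stop("need at least 3 sequences")
  chm <- do.call(rbind, strsplit(rows, ""))
  n <- nrow(chm)
  D <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- chm[i, ] != "-" & chm[j, ] != "-"
    ns <- sum(ok)
    if (ns < min_shared) { D[i, j] <- D[j, i] <- NA_real_; next }
    p <- sum(chm[i, ok] != chm[j, ok]) / ns
    d <- switch(correction,
      p = p,
      poisson = if (p >= 1) Inf else -log(1 - p),
      kimura_protein = {
        arg <- 1 - p - 0.2 * p^2
        if (arg <= 0) Inf else -log(arg)
      })
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining; negative branch lengths are clamped to zero
#' with the deficit moved to the adjacent (sister) branch, preserving
#' path lengths through the node.
#'
#' @param D Complete symmetric distance matrix with row/col names (n >= 3).
#' @return A \code{\linkS4class{SupportTree}} without support values.
#' @export
njTree <- function(D) {
  if (any(is.na(D)))
    stop("distance matrix has missing entries; impute them or drop taxa")
  tr <- ape::nj(as.dist(D))
  ## clamp negative branch lengths, moving the deficit to the sister edge
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    len <- tr$edge.length[e]
    parent <- tr$edge[e, 1]
    sib <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sib)) tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + abs(len)
    tr$edge.length[e] <- 0
  }
  new("SupportTree", tree = tr,
      support = rep(NA_real_, tr$Nnode), nboot = 0L)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal bipartition of the
#' point-estimate tree the percentage of replicates containing it
#' (classical bootstrap).
#'
#' @param msa An \code{AAMultipleAlignment}.
#' @param n_replicates Number of bootstrap replicates (0 = none).
#' @param seed Integer seed; identical seeds give identical supports.
#' @param correction Distance correction, see
#'   \code{\link{alignmentDistances}}.
#' @return A \code{\linkS4class{SupportTree}}; supports are percentages in
#'   [0, 100] per internal node of the point-estimate tree.
#' @export
bootstrapSupport <- function(msa, n_replicates = 1000L, seed = 1L,
                             correction = "poisson") {
  rows <- as.character(Biostrings::unmasked(msa))
  if (length(rows) < 4L) stop("need at least 4 sequences")
  D <- alignmentDistances(msa, correction)
  fin <- D[is.finite(D)]
  D[!is.finite(D)] <- if (length(fin)) max(fin) * 1.5 else 1
  point <- njTree(D)
  if (n_replicates <= 0L) return(point)
  chm <- do.call(rbind, strsplit(rows, ""))
  L <- ncol(chm)
  set.seed(seed)
  reps <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    sub <- chm[, cols, drop = FALSE]
    rws <- setNames(apply(sub, 1, paste, collapse = ""), names(rows))
    Db <- alignmentDistances(rws, correction, min_shared = 1L)
    finb <- Db[is.finite(Db)]
    Db[!is.finite(Db)] <- if (length(finb)) max(finb) * 1.5 else 1
    reps[[b]] <- njTree(Db)@tree
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(point@tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / n_replicates
  ## the "root" pseudo-node of the unrooted tree carries no bipartition
  support[1] <- NA_real_
  tr <- point@tree
  tr$node.label <- formatC(support, format = "f", digits = 1)
  tr$node.label[is.na(support)] <- ""
  new("SupportTree", tree = tr, support = support,
      nboot = as.integer(n_replicates))
}

#' Monophyly and support of a taxon subset
#'
#' Tests whether the taxa form one side of a bipartition of the unrooted
#' tree; when they do, returns the support of that branch and its
#' interpretation under the conventional thresholds (>= 90 supported,
#' >= 95 strongly supported).
#'
#' @param x A \code{\linkS4class{SupportTree}}.
#' @param taxa Character vector of tip labels (>= 2).
#' @return List with \code{is_monophyletic}, \code{support} (NA when the
#'   subset is the full taxon set or no bootstrap was run) and
#'   \code{classification} (\code{"strongly_supported"},
#'   \code{"supported"}, \code{"unsupported"} or NA).
#' @export
cladeSupport <- function(x, taxa) {
  tr <- x@tree
  tips <- tr$tip.label
  unknown <- setdiff(taxa, tips)
  if (length(unknown))
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (length(taxa) < 2L) stop("taxa subset must have at least 2 members")
  if (setequal(taxa, tips))
    return(list(is_monophyletic = TRUE, support = NA_real_,
                classification = NA_character_))
  parts <- ape::prop.part(tr)
  labs <- attr(parts, "labels")
  target <- sort(match(taxa, labs))
  comp <- sort(setdiff(seq_along(labs), target))
  hit <- NA_integer_
  for (k in seq_along(parts)) {
    pk <- sort(parts[[k]])
    if (identical(pk, target) || identical(pk, comp)) { hit <- k; break }
  }
  if (is.na(hit))
    return(list(is_monophyletic = FALSE, support = NA_real_,
                classification = NA_character_))
  sup <- x@support[hit]
  cls <- if (is.na(sup)) NA_character_
         else if (sup >= 95) "strongly_supported"
         else if (sup >= 90) "supported"
         else "unsupported"
  list(is_monophyletic = TRUE, support = sup, classification = cls)
}

#' Simulate two related protein families with distinct cores
#'
#' Generates two families descended from related ancestral sequences: a
#' shared random scaffold mutated to the requested between-family identity,
#' then per-taxon mutation to the requested within-family identity. Used to
#' benchmark clade recovery at desk scale.
#'
#' @param n_taxa Taxa per family.
#' @param seq_len Sequence length (>= 34; a distinct 34-residue core region
#'   differentiates the families).
#' @param within_identity Expected identity of taxa to their family
#'   ancestor.
#' @param between_identity Expected identity between the two ancestors.
#' @param seed Integer seed.
#' @return \code{AAStringSet} named \code{A1..An, B1..Bn} with attribute
#'   \code{"clades"} listing the two true clades.
#' @export
simulateProteinFamilies <- function(n_taxa = 8L, seq_len = 60L,
                                    within_identity = 0.8,
                                    between_identity = 0.4, seed = 1L) {
  set.seed(seed)
  mutate <- function(x, keep) {
    ch <- strsplit(x, "")[[1]]
    hit <- runif(length(ch)) > keep
    ch[hit] <- vapply(which(hit), function(i)
      sample(setdiff(AA20, ch[i]), 1L), character(1))
    paste(ch, collapse = "")
  }
  rootA <- paste(sample(AA20, seq_len, replace = TRUE), collapse = "")
  rootB <- mutate(rootA, between_identity)
  seqs <- c(
    setNames(vapply(seq_len(n_taxa), function(i) mutate(rootA, within_identity),
                    character(1)), paste0("A", seq_len(n_taxa))),
    setNames(vapply(seq_len(n_taxa), function(i) mutate(rootB, within_identity),
                    character(1)), paste0("B", seq_len(n_taxa))))
  out <- Biostrings::AAStringSet(seqs)
  attr(out, "clades") <- list(A = paste0("A", seq_len(n_taxa)),
                              B = paste0("B", seq_len(n_taxa)))
  out
}
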