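## ---------------------------------------------------------------------------
## Frameshift-aware protein-to-DNA alignment for pseudogene detection.
## The DNA is aligned to an intact reference protein with states for codon
## match (3 nt), frameshifting codons (2 or 4 nt), whole-codon insertion and
## deletion, and stop-codon emission; premature stops and frameshifts on the
## optimal path are the reported inactivating mutations.
## ---------------------------------------------------------------------------

#' Detect inactivating mutations in a candidate pseudogene locus
#'
#' Aligns a genomic locus to a reference protein with a frameshift-aware
#' dynamic program (global in the reference, free end gaps on the DNA).
#' Codon steps consume 3 nt; frameshift steps consume 2 or 4 nt at a
#' penalty; whole-codon insertions and deletions have linear per-codon
#' costs; a stop codon aligned to a reference residue is scored as a stop
#' emission. Premature stop codons and frameshifts on the optimal path are
#' reported in reference codon coordinates.
#'
#' @param locus_dna DNA sequence of the locus (at least 30 nt), in the
#'   reading orientation of the gene.
#' @param reference_protein Intact reference protein (at least 10 aa).
#' @param matrix_name Substitution matrix (default BLOSUM62).
#' @param fs_penalty Penalty for a 1-nt insertion or deletion (frameshift).
#' @param stop_penalty Penalty for emitting a stop codon against a residue.
#' @param gap_penalty Per-codon penalty for whole-codon indels.
#' @param score_floor Minimum alignment score to consider the locus
#'   alignable; defaults to 30\% of the reference self-score.
#' @return A data frame with columns \code{type} (\code{"premature_stop"} or
#'   \code{"frameshift"}) and \code{codon} (position in reference codon
#'   coordinates), with attributes \code{score} and \code{status}
#'   (\code{"intact"}, \code{"mutated"} or \code{"unalignable"}). An empty
#'   frame with status \code{"intact"} means the aligned span has an intact
#'   reading frame; status \code{"unalignable"} is distinct from intact.
#' @export
detectPseudogene <- function(locus_dna, reference_protein,
                             matrix_name = "BLOSUM62",
                             fs_penalty = 12, stop_penalty = 8,
                             gap_penalty = 10, score_floor = NULL) {
  locus_dna <- toupper(as.character(locus_dna))
  reference_protein <- toupper(as.character(reference_protein))
  m <- nchar(locus_dna)
  n <- nchar(reference_protein)
  if (m < 30L) stop("locus_dna must be at least 30 nt")
  if (n < 10L) stop("reference_protein must be at least 10 aa")
  B <- .getMatrix(matrix_name)
  ref <- strsplit(reference_protein, "")[[1]]
  if (!all(ref %in% rownames(B))) stop("reference contains unknown letters")
  if (is.null(score_floor)) {
    self <- sum(diag(B[ref, ref, drop = FALSE]))
    score_floor <- 0.3 * self
  }

  ## aa emitted by the codon ENDING at DNA position j (NA for j < 3)
  aa_end <- rep(NA_character_, m)
  if (m >= 3L) {
    starts <- 1:(m - 2L)
    codons <- substring(locus_dna, starts, starts + 2L)
    tr <- Biostrings::GENETIC_CODE[codons]
    tr[is.na(tr)] <- "X"           # codons containing N etc.
    aa_end[3:m] <- unname(tr)
  }
  ## substitution score vector template against each reference residue is
  ## built per row from the matrix; stop codons get the stop penalty
  is_stop <- !is.na(aa_end) & aa_end == "*"
  aa_idx <- match(aa_end, colnames(B))     # NA for stop already matched ('*')

  NEG <- -1e9
  Hprev <- numeric(m + 1L)                 # row i-1, index j+1
  ptr <- matrix(0L, nrow = n + 1L, ncol = m + 1L)  # 1 m3, 2 fs4, 3 fs2, 4 del, 5 ins
  Hmat <- matrix(NEG, nrow = n + 1L, ncol = m + 1L)
  Hmat[1, ] <- 0                           # free leading DNA
  Hprev <- Hmat[1, ]

  shift <- function(v, by) c(rep(NEG, by), v[seq_len(length(v) - by)])

  for (i in seq_len(n)) {
    srow <- B[ref[i], ][aa_idx]            # score vs codon ending at j
    srow[is.na(srow)] <- NEG
    srow[is_stop] <- -stop_penalty
    svec <- c(NEG, srow)                   # align to H indexing (j+1)

    cand_m3 <- shift(Hprev, 3L) + svec
    cand_f4 <- shift(Hprev, 4L) + svec - fs_penalty
    cand_f2 <- shift(Hprev, 2L) - fs_penalty
    cand_dl <- Hprev - gap_penalty
    base <- pmax(cand_m3, cand_f4, cand_f2, cand_dl)
    code <- ifelse(base == cand_m3, 1L,
            ifelse(base == cand_f4, 2L,
            ifelse(base == cand_f2, 3L, 4L)))
    ## whole-codon insertions along the row (linear per-codon cost):
    ## H[i,j] = max(base[j], H[i,j-3] - gap_penalty), solved per residue
    ## class mod 3 with a cummax scan
    final <- base
    for (r in 0:2) {
      idx <- which((seq_len(m + 1L) - 1L) %% 3L == r)
      v <- base[idx]
      kk <- seq_along(v)
      run <- cummax(v + gap_penalty * kk)
      f <- run - gap_penalty * kk
      final[idx] <- f
    }
    ins <- final > base + 1e-9
    code[ins] <- 5L
    ptr[i + 1L, ] <- code
    Hmat[i + 1L, ] <- final
    Hprev <- final
  }

  jbest <- which.max(Hmat[n + 1L, ]) - 1L
  best <- Hmat[n + 1L, jbest + 1L]
  empty <- data.frame(type = character(0), codon = integer(0))
  if (best < score_floor) {
    attr(empty, "score") <- best
    attr(empty, "status") <- "unalignable"
    return(empty)
  }

  ## traceback
  events <- list()
  i <- n; j <- jbest
  while (i > 0L) {
    code <- ptr[i + 1L, j + 1L]
    if (code == 1L) {
      if (j >= 3L && is_stop[j])
        events[[length(events) + 1L]] <- data.frame(type = "premature_stop", codon = i)
      i <- i - 1L; j <- j - 3L
    } else if (code == 2L) {
      events[[length(events) + 1L]] <- data.frame(type = "frameshift", codon = i)
      if (j >= 4L && is_stop[j])
        events[[length(events) + 1L]] <- data.frame(type = "premature_stop", codon = i)
      i <- i - 1L; j <- j - 4L
    } else if (code == 3L) {
      events[[length(events) + 1L]] <- data.frame(type = "frameshift", codon = i)
      i <- i - 1L; j <- j - 2L
    } else if (code == 4L) {
      i <- i - 1L
    } else if (code == 5L) {
      j <- j - 3L
    } else {
      break
    }
    if (j < 0L) break
  }
  out <- if (length(events)) do.call(rbind, rev(events)) else empty
  rownames(out) <- NULL
  attr(out, "score") <- best
  attr(out, "status") <- if (nrow(out)) "mutated" else "intact"
  out
}
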