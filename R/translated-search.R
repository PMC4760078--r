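## ---------------------------------------------------------------------------
## Translated seed-and-extend homology search (tBLASTn-style): protein
## queries against the six conceptual translations of a genomic scaffold.
## Word seeding with a scored single-substitution neighborhood, followed by
## local affine-gap extension of the seeded window.
## ---------------------------------------------------------------------------

.getMatrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

## Neighborhood of a k-mer word: the word itself plus all single-position
## substitutions whose score against the original word is >= threshold.
.wordNeighborhood <- function(word, B, threshold, cache) {
  hit <- cache[[word]]
  if (!is.null(hit)) return(hit)
  w <- strsplit(word, "")[[1]]
  self <- sum(diag(B[w, w, drop = FALSE]))
  out <- word
  for (p in seq_along(w)) {
    delta <- B[w[p], AA20] - B[w[p], w[p]]
    keep <- AA20[self + delta >= threshold & AA20 != w[p]]
    if (length(keep)) {
      v <- vapply(keep, function(a) { x <- w; x[p] <- a
                                      paste(x, collapse = "") }, character(1))
      out <- c(out, v)
    }
  }
  cache[[word]] <- out
  out
}

#' Translated seed-and-extend homology search
#'
#' Searches protein queries against all six reading frames of a genomic
#' scaffold. Exact word seeds (with a scored substitution neighborhood) are
#' located in each frame translation, seeded regions are extended by local
#' affine-gap alignment, and HSPs scoring at least \code{min_score} are
#' reported with coordinates on the protein and on the forward strand of
#' the scaffold.
#'
#' @param queries \code{AAStringSet} (or named character vector) of protein
#'   queries over the 20 standard letters plus X.
#' @param seq Scaffold sequence (character or \code{DNAString}).
#' @param params \code{\link{scanParams}} (substitution matrix, gap costs,
#'   word length, neighborhood threshold, score cutoff).
#' @return Data frame of HSPs sorted by scaffold position then descending
#'   score: \code{query_id}, \code{strand}, \code{frame}, \code{q_start},
#'   \code{q_end}, \code{s_aa_start}, \code{s_aa_end} (frame translation
#'   coordinates), \code{s_nt_start}, \code{s_nt_end} (forward scaffold
#'   coordinates), \code{score}, \code{identity}.
#' @export
translatedSearch <- function(queries, seq, params = scanParams()) {
  if (is.character(queries)) {
    nm <- names(queries) %||% sprintf("query%03d", seq_along(queries))
    queries <- Biostrings::AAStringSet(setNames(queries, nm))
  }
  if (!length(queries)) stop("queries must be non-empty")
  qchr <- as.character(queries)
  badq <- !vapply(qchr, function(q)
    all(strsplit(q, "")[[1]] %in% c(AA20, "X")), logical(1))
  if (any(badq))
    stop("queries contain letters outside the standard alphabet: ",
         paste(names(queries)[badq], collapse = ", "))
  seq <- as.character(seq)
  L <- nchar(seq)
  B <- .getMatrix(params$matrix)
  k <- params$seed_word_len
  cache <- new.env(parent = emptyenv())
  pad <- 15L
  hsps <- list()

  for (strand in c("+", "-")) {
    oseq <- if (strand == "+") seq else revComp(seq)
    for (f in 0:2) {
      tlen <- (nchar(oseq) - f) %/% 3L
      if (tlen < k) next
      subj <- translateDNA(substring(oseq, f + 1L, f + 3L * tlen))
      ## index subject words (skip words containing stop/ambiguity)
      npos <- tlen - k + 1L
      if (npos < 1L) next
      words <- substring(subj, seq_len(npos), seq_len(npos) + k - 1L)
      ok <- !grepl("[*X]", words)
      index <- split(which(ok), words[ok])
      subjAA <- Biostrings::AAString(subj)

      for (qi in seq_along(qchr)) {
        q <- qchr[qi]
        qlen <- nchar(q)
        if (qlen < k) next
        qwords <- substring(q, seq_len(qlen - k + 1L), seq_len(qlen - k + 1L) + k - 1L)
        seeds_q <- integer(0); seeds_s <- integer(0)
        for (qp in seq_along(qwords)) {
          if (grepl("[*X]", qwords[qp])) next
          for (w in .wordNeighborhood(qwords[qp], B,
                                      params$neighborhood_threshold, cache)) {
            sp <- index[[w]]
            if (!is.null(sp)) {
              seeds_q <- c(seeds_q, rep(qp, length(sp)))
              seeds_s <- c(seeds_s, sp)
            }
          }
        }
        if (!length(seeds_q)) next
        ## group seeds by diagonal, then by proximity along the subject
        diag <- seeds_s - seeds_q
        o <- order(diag, seeds_s)
        diag <- diag[o]; sq <- seeds_q[o]; ss <- seeds_s[o]
        grp <- cumsum(c(TRUE, diff(diag) != 0L | diff(ss) > 50L))
        windows <- unique(t(vapply(split(seq_along(grp), grp), function(ix) {
          ws <- max(1L, min(ss[ix]) - (min(sq[ix]) - 1L) - pad)
          we <- min(tlen, max(ss[ix]) + k - 1L + (qlen - max(sq[ix] + k - 1L)) + pad)
          c(ws, we)
        }, integer(2))))
        ## merge overlapping windows to avoid duplicate extensions
        if (nrow(windows) > 1L) {
          windows <- windows[order(windows[, 1]), , drop = FALSE]
          merged <- list(windows[1, ])
          for (r in 2:nrow(windows)) {
            lastw <- merged[[length(merged)]]
            if (windows[r, 1] <= lastw[2] + 1L)
              merged[[length(merged)]] <- c(lastw[1], max(lastw[2], windows[r, 2]))
            else merged[[length(merged) + 1L]] <- windows[r, ]
          }
          windows <- do.call(rbind, merged)
        }
        for (r in seq_len(nrow(windows))) {
          ws <- windows[r, 1]; we <- windows[r, 2]
          aln <- Biostrings::pairwiseAlignment(
            Biostrings::AAString(q), Biostrings::subseq(subjAA, ws, we),
            type = "local", substitutionMatrix = B,
            gapOpening = params$gap_open, gapExtension = params$gap_ext,
            scoreOnly = FALSE)
          sc <- Biostrings::score(aln)
          if (sc < params$min_score) next
          qr <- as.integer(c(
            IRanges::start(Biostrings::pattern(aln)@range),
            IRanges::end(Biostrings::pattern(aln)@range)))
          sr <- as.integer(c(
            IRanges::start(Biostrings::subject(aln)@range),
            IRanges::end(Biostrings::subject(aln)@range))) + ws - 1L
          o_nt <- c(f + 3L * (sr[1] - 1L) + 1L, f + 3L * sr[2])
          fwd <- if (strand == "+") o_nt else reflectInterval(o_nt[1], o_nt[2], L)
          hsps[[length(hsps) + 1L]] <- data.frame(
            query_id = names(queries)[qi], strand = strand,
            frame = if (strand == "+") f + 1L else -(f + 1L),
            q_start = qr[1], q_end = qr[2],
            s_aa_start = sr[1], s_aa_end = sr[2],
            s_nt_start = fwd[1], s_nt_end = fwd[2],
            score = sc, identity = Biostrings::pid(aln, type = "PID1") / 100,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hsps))
    return(data.frame(query_id = character(0), strand = character(0),
                      frame = integer(0), q_start = integer(0),
                      q_end = integer(0), s_aa_start = integer(0),
                      s_aa_end = integer(0), s_nt_start = integer(0),
                      s_nt_end = integer(0), score = numeric(0),
                      identity = numeric(0)))
  out <- do.call(rbind, hsps)
  key <- paste(out$query_id, out$strand, out$frame, out$s_nt_start,
               out$s_nt_end, out$q_start, out$q_end)
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$s_nt_start, -out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}
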