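## ---------------------------------------------------------------------------
## SEDC gene finder: six-frame ORF scan constrained by the SEDC splice-signal
## rules (acceptor 10-30 nt upstream of ATG; TATA box followed by a splice
## donor at 60-90 nt), assembly of two-exon gene models, homology-triggered
## rescue and iterative query expansion.
## ---------------------------------------------------------------------------

#' Parameters of the SEDC gene scan
#'
#' Defaults implement the canonical SEDC screening rules: conceptual
#' translations encoding proteins of 50-500 amino acids, a splice acceptor AG
#' 10-30 nt upstream of the start codon, and a noncoding exon 1 defined by a
#' TATA box followed by a splice donor GT at 60-90 nt.
#'
#' @param min_protein_len,max_protein_len ORF length bounds in amino acids
#'   (inclusive).
#' @param utr5_min,utr5_max Acceptor-to-ATG distance bounds (5' UTR length, nt).
#' @param tata_donor_min,tata_donor_max Distance from the first base of the
#'   TATA box to the first base of the GT donor (nt, inclusive bounds).
#' @param exon1_search_window How far upstream of the acceptor to look for
#'   exon 1 (nt).
#' @param tata_pattern Regular expression for the TATA box.
#' @param min_intron_len Minimum intron length (nt).
#' @param require_exon1 Drop ORF-scan models without a qualifying exon 1.
#' @param gap_min_run Minimum N-run length treated as an assembly gap.
#' @param relaxed_min_protein_len Lower ORF bound used when rescuing
#'   homology-supported loci.
#' @param matrix,gap_open,gap_ext Substitution matrix name and affine gap
#'   costs for the translated search.
#' @param seed_word_len,neighborhood_threshold,x_drop,min_score Seeding and
#'   extension parameters of the translated search.
#' @return A list of class \code{"ScanParams"}.
#' @export
scanParams <- function(min_protein_len = 50L, max_protein_len = 500L,
                       utr5_min = 10L, utr5_max = 30L,
                       tata_donor_min = 60L, tata_donor_max = 90L,
                       exon1_search_window = 1000L,
                       tata_pattern = "TATA[AT]A",
                       min_intron_len = 20L,
                       require_exon1 = TRUE,
                       gap_min_run = 10L,
                       relaxed_min_protein_len = 20L,
                       matrix = "BLOSUM62", gap_open = 11L, gap_ext = 1L,
                       seed_word_len = 4L, neighborhood_threshold = 13L,
                       x_drop = 20L, min_score = 55L) {
  p <- list(min_protein_len = as.integer(min_protein_len),
            max_protein_len = as.integer(max_protein_len),
            utr5_min = as.integer(utr5_min), utr5_max = as.integer(utr5_max),
            tata_donor_min = as.integer(tata_donor_min),
            tata_donor_max = as.integer(tata_donor_max),
            exon1_search_window = as.integer(exon1_search_window),
            tata_pattern = tata_pattern,
            min_intron_len = as.integer(min_intron_len),
            require_exon1 = isTRUE(require_exon1),
            gap_min_run = as.integer(gap_min_run),
            relaxed_min_protein_len = as.integer(relaxed_min_protein_len),
            matrix = matrix, gap_open = as.integer(gap_open),
            gap_ext = as.integer(gap_ext),
            seed_word_len = as.integer(seed_word_len),
            neighborhood_threshold = as.integer(neighborhood_threshold),
            x_drop = as.integer(x_drop), min_score = as.integer(min_score))
  stopifnot(p$min_protein_len > 0L, p$min_protein_len <= p$max_protein_len,
            p$utr5_min > 0L, p$utr5_min <= p$utr5_max,
            p$tata_donor_min > 0L, p$tata_donor_min <= p$tata_donor_max)
  structure(p, class = "ScanParams")
}

#' Assembly-gap runs of a scaffold
#'
#' @param seq DNA sequence (character or \code{DNAString}).
#' @param min_run Minimum N-run length to report.
#' @return Data frame with columns \code{start}, \code{end} (1-based
#'   inclusive) of the maximal N runs of at least \code{min_run} bases.
#' @export
gapRuns <- function(seq, min_run = 10L) {
  seq <- as.character(seq)
  m <- gregexpr(sprintf("N{%d,}", as.integer(min_run)), seq)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

## Parse one oriented frame translation into complete / truncated ORF
## candidates. Returns rows in oriented nt coordinates.
.parseFrame <- function(chars, f, min_len, max_len) {
  n <- length(chars)
  if (!n) return(NULL)
  bnd <- which(chars == "*" | chars == "X")
  seg_start <- c(1L, bnd + 1L)
  seg_end <- c(bnd - 1L, n)
  out <- vector("list", length(seg_start))
  for (i in seq_along(seg_start)) {
    a <- seg_start[i]; b <- seg_end[i]
    if (a > b) next
    mrel <- which(chars[a:b] == "M")
    if (!length(mrel)) next
    m <- a + mrel[1] - 1L
    aa_len <- b - m + 1L
    if (aa_len < min_len || aa_len > max_len) next
    term <- if (b < n) chars[b + 1L] else ""
    if (term == "*") {
      out[[i]] <- data.frame(
        o_start = f + 3L * (m - 1L) + 1L, o_end = f + 3L * (b + 1L),
        protein = paste(chars[m:b], collapse = ""),
        truncated = "", stringsAsFactors = FALSE)
    } else {
      out[[i]] <- data.frame(
        o_start = f + 3L * (m - 1L) + 1L, o_end = f + 3L * b,
        protein = paste(chars[m:b], collapse = ""),
        truncated = if (term == "X") "gap" else "edge",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Six-frame ORF scan of a genomic scaffold
#'
#' Conceptually translates the scaffold in all six frames and reports open
#' reading frames encoding proteins within the configured length bounds
#' (inclusive). Per stop codon and frame only the longest ORF (first ATG) is
#' reported; ORFs whose CDS would contain an ambiguous base are rejected,
#' but ORFs running into an assembly gap or the scaffold edge are reported
#' as truncated candidates.
#'
#' @param seq Scaffold sequence (character or \code{DNAString}).
#' @param params A \code{\link{scanParams}} object.
#' @param min_protein_len Optional override of the lower ORF bound.
#' @return Data frame sorted by forward start coordinate with columns
#'   \code{start}, \code{end} (forward, CDS including the stop codon when
#'   present), \code{o_start}, \code{o_end} (strand-oriented), \code{strand},
#'   \code{frame}, \code{protein}, \code{truncated}.
#' @export
sixFrameOrfs <- function(seq, params = scanParams(),
                         min_protein_len = params$min_protein_len) {
  seq <- as.character(seq)
  L <- nchar(seq)
  if (L < 3L) stop("scaffold is empty or too short")
  gaps <- gapRuns(seq, params$gap_min_run)
  res <- list()
  for (strand in c("+", "-")) {
    oseq <- if (strand == "+") seq else revComp(seq)
    for (f in 0:2) {
      sub <- substring(oseq, f + 1L)
      if (nchar(sub) < 3L) next
      chars <- strsplit(translateDNA(sub), "")[[1]]
      df <- .parseFrame(chars, f, min_protein_len, params$max_protein_len)
      if (is.null(df) || !nrow(df)) next
      df$strand <- strand
      df$frame <- if (strand == "+") f + 1L else -(f + 1L)
      if (strand == "+") {
        df$start <- df$o_start; df$end <- df$o_end
      } else {
        df$start <- L - df$o_end + 1L; df$end <- L - df$o_start + 1L
      }
      res[[length(res) + 1L]] <- df
    }
  }
  if (!length(res))
    return(data.frame(start = integer(0), end = integer(0),
                      o_start = integer(0), o_end = integer(0),
                      strand = character(0), frame = integer(0),
                      protein = character(0), truncated = character(0)))
  out <- do.call(rbind, res)
  ## gap-truncated candidates must actually abut a gap run of qualifying size
  if (nrow(gaps)) {
    keep <- out$truncated != "gap" | vapply(seq_len(nrow(out)), function(i) {
      if (out$truncated[i] != "gap") return(TRUE)
      edge <- if (out$strand[i] == "+") out$end[i] + 3L else out$start[i] - 3L
      any(gaps$start <= edge + 3L & gaps$end >= edge - 3L)
    }, logical(1))
    out <- out[keep, , drop = FALSE]
  } else {
    out <- out[out$truncated != "gap", , drop = FALSE]
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("start", "end", "o_start", "o_end", "strand", "frame",
          "protein", "truncated")]
}

## Acceptor check in oriented coordinates: is there an AG ending L nt
## upstream of the A of the ATG, with utr5_min <= L <= utr5_max?
## Returns the innermost (smallest L) qualifying UTR.
.acceptorOriented <- function(oseq, atg, params) {
  if (atg - params$utr5_min - 2L < 1L)
    return(list(ok = FALSE, reason = "edge"))
  for (L in params$utr5_min:params$utr5_max) {
    a1 <- atg - L - 2L
    if (a1 < 1L) break
    if (substr(oseq, a1, a1 + 1L) == "AG")
      return(list(ok = TRUE, L = L, utr = c(atg - L, atg - 1L),
                  acceptor = c(a1, a1 + 1L), reason = ""))
  }
  list(ok = FALSE, reason = "no_acceptor")
}

## Exon-1 search in oriented coordinates. acceptor_start = first base of the
## acceptor AG. Finds the TATA+donor pair nearest the acceptor.
.exon1Oriented <- function(oseq, acceptor_start, params) {
  win_lo <- acceptor_start + 1L - params$exon1_search_window
  clipped <- win_lo < 1L
  win_lo <- max(1L, win_lo)
  g_hi <- acceptor_start + 2L - params$min_intron_len
  if (g_hi < win_lo)
    return(list(found = FALSE, reason = if (clipped) "edge" else "no_donor"))
  region <- substr(oseq, win_lo, g_hi + 1L)
  m <- gregexpr("GT", region, fixed = TRUE)[[1]]
  if (m[1] == -1L)
    return(list(found = FALSE, reason = if (clipped) "edge" else "no_donor"))
  gs <- sort(as.integer(m) + win_lo - 1L, decreasing = TRUE)
  for (g in gs) {
    t_lo <- g - params$tata_donor_max
    t_hi <- g - params$tata_donor_min
    if (t_hi < 1L) next
    t_lo <- max(1L, t_lo)
    sub <- substr(oseq, t_lo, min(nchar(oseq), t_hi + 12L))
    tm <- gregexpr(params$tata_pattern, sub, perl = TRUE)[[1]]
    if (tm[1] == -1L) next
    ts <- as.integer(tm) + t_lo - 1L
    lens <- attr(tm, "match.length")
    ok <- which(ts >= g - params$tata_donor_max & ts <= g - params$tata_donor_min)
    if (!length(ok)) next
    k <- ok[which.max(ts[ok])]
    return(list(found = TRUE, tata = c(ts[k], ts[k] + lens[k] - 1L),
                donor = g, exon1 = c(ts[k], g - 1L), reason = ""))
  }
  list(found = FALSE, reason = if (clipped) "edge" else "no_tata")
}

#' Check for a splice acceptor upstream of a start codon
#'
#' Looks for an AG dinucleotide ending between \code{utr5_min} and
#' \code{utr5_max} nt upstream of the A of the ATG (strand-aware) and
#' returns the innermost qualifying 5' UTR.
#'
#' @param seq Scaffold sequence.
#' @param cds_start Forward-strand coordinate of the first base of the CDS
#'   (for minus-strand genes, of its last base, i.e. the oriented ATG).
#' @param strand \code{"+"} or \code{"-"}.
#' @param params \code{\link{scanParams}}.
#' @return List with \code{ok}, UTR length \code{L}, \code{utr5} interval in
#'   forward coordinates, and \code{reason} on rejection (\code{"edge"} when
#'   there is insufficient upstream context).
#' @export
checkAcceptor <- function(seq, cds_start, strand = "+", params = scanParams()) {
  seq <- as.character(seq)
  L <- nchar(seq)
  oseq <- if (strand == "+") seq else revComp(seq)
  atg <- if (strand == "+") cds_start else L - cds_start + 1L
  r <- .acceptorOriented(oseq, atg, params)
  if (r$ok && strand == "-") {
    r$utr <- reflectInterval(r$utr[1], r$utr[2], L)
    r$acceptor <- reflectInterval(r$acceptor[1], r$acceptor[2], L)
  }
  names(r)[names(r) == "utr"] <- "utr5"
  r
}

#' Locate the noncoding exon 1 upstream of a splice acceptor
#'
#' Searches up to \code{exon1_search_window} nt upstream of the intron
#' acceptor for a TATA box followed by a GT splice donor at a
#' first-base-to-first-base distance within the configured bounds and
#' returns the qualifying pair nearest the acceptor.
#'
#' @param seq Scaffold sequence.
#' @param acceptor_start Forward coordinate of the first base of the
#'   acceptor AG (strand-aware: for minus-strand genes the base that is the
#'   A of the AG in gene orientation).
#' @param strand \code{"+"} or \code{"-"}.
#' @param params \code{\link{scanParams}}.
#' @return List with \code{found}, \code{tata} and \code{exon1} intervals
#'   (forward coordinates), donor first-base position \code{donor}, and
#'   \code{reason} when absent.
#' @export
findExon1 <- function(seq, acceptor_start, strand = "+", params = scanParams()) {
  seq <- as.character(seq)
  L <- nchar(seq)
  oseq <- if (strand == "+") seq else revComp(seq)
  a <- if (strand == "+") acceptor_start else L - acceptor_start + 1L
  r <- .exon1Oriented(oseq, a, params)
  if (r$found && strand == "-") {
    r$tata <- reflectInterval(r$tata[1], r$tata[2], L)
    r$exon1 <- reflectInterval(r$exon1[1], r$exon1[2], L)
    r$donor <- L - r$donor + 1L
  }
  r
}

## Build one model row (all intervals in forward coordinates).
.modelRow <- function(scaffold_id, strand, cds, protein, status, evidence,
                      score = NA_real_, utr5 = c(NA, NA), exon1 = c(NA, NA),
                      intron = c(NA, NA)) {
  data.frame(scaffold = scaffold_id, strand = strand,
             cds_start = cds[1], cds_end = cds[2], protein = protein,
             status = status, evidence = evidence, score = score,
             utr5_start = utr5[1], utr5_end = utr5[2],
             exon1_start = exon1[1], exon1_end = exon1[2],
             intron_start = intron[1], intron_end = intron[2],
             stringsAsFactors = FALSE)
}

## Try to promote one ORF candidate into a full SEDC model.
## Returns a model row or NULL.
.orfToModel <- function(scaffold_id, seq, rcseq, L, orf, params,
                        evidence = "orf_scan", score = NA_real_,
                        require_exon1 = params$require_exon1,
                        keep_on_fail = FALSE) {
  oseq <- if (orf$strand == "+") seq else rcseq
  acc <- .acceptorOriented(oseq, orf$o_start, params)
  status <- if (orf$truncated != "") "partial" else "complete"
  refl <- function(iv) if (orf$strand == "+") iv else reflectInterval(iv[1], iv[2], L)
  if (!acc$ok) {
    if (keep_on_fail)
      return(.modelRow(scaffold_id, orf$strand, c(orf$start, orf$end),
                       orf$protein, "partial", evidence, score))
    return(NULL)
  }
  e1 <- .exon1Oriented(oseq, acc$acceptor[1], params)
  if (!e1$found) {
    if (require_exon1) {
      if (keep_on_fail)
        return(.modelRow(scaffold_id, orf$strand, c(orf$start, orf$end),
                         orf$protein, "partial", evidence, score,
                         utr5 = refl(acc$utr)))
      return(NULL)
    }
    return(.modelRow(scaffold_id, orf$strand, c(orf$start, orf$end),
                     orf$protein, status, evidence, score, utr5 = refl(acc$utr)))
  }
  intron <- c(e1$donor, acc$acceptor[2])
  .modelRow(scaffold_id, orf$strand, c(orf$start, orf$end), orf$protein,
            status, evidence, score, utr5 = refl(acc$utr),
            exon1 = refl(e1$exon1), intron = refl(intron))
}

#' Assemble SEDC gene models from ORF and homology evidence
#'
#' Promotes qualifying ORFs (acceptor and, by default, exon 1 present) to
#' gene models, rescues homology-supported regions not explained by any ORF
#' model using a relaxed minimum protein length, marks gap- or
#' edge-truncated models as partial, and resolves overlapping same-strand
#' models by highest score, then longest CDS, then leftmost position.
#'
#' @param scaffold_id Scaffold name.
#' @param seq Scaffold sequence.
#' @param orfs Output of \code{\link{sixFrameOrfs}} for this scaffold.
#' @param hsps Optional data frame of HSPs from \code{\link{translatedSearch}}.
#' @param params \code{\link{scanParams}}.
#' @return A \code{\linkS4class{GeneModelSet}}.
#' @export
assembleModels <- function(scaffold_id, seq, orfs, hsps = NULL,
                           params = scanParams()) {
  seq <- as.character(seq)
  L <- nchar(seq)
  rcseq <- revComp(seq)
  rows <- list()
  for (i in seq_len(nrow(orfs))) {
    r <- .orfToModel(scaffold_id, seq, rcseq, L, orfs[i, ], params)
    if (!is.null(r)) rows[[length(rows) + 1L]] <- r
  }
  models <- if (length(rows)) do.call(rbind, rows) else
    .modelRow(scaffold_id, "+", c(1L, 0L), "", "", "")[0, ]

  ## homology-triggered rescue of regions with HSP support but no ORF model
  if (!is.null(hsps) && nrow(hsps)) {
    hgr <- GenomicRanges::GRanges(scaffold_id,
      IRanges::IRanges(hsps$s_nt_start, hsps$s_nt_end), strand = hsps$strand)
    clusters <- GenomicRanges::reduce(hgr, min.gapwidth = 60L)
    mgr <- if (nrow(models)) GenomicRanges::GRanges(scaffold_id,
      IRanges::IRanges(models$cds_start, models$cds_end),
      strand = models$strand) else GenomicRanges::GRanges()
    unexplained <- clusters[!IRanges::overlapsAny(clusters, mgr)]
    if (length(unexplained)) {
      relaxed <- sixFrameOrfs(seq, params,
                              min_protein_len = params$relaxed_min_protein_len)
      rgr <- GenomicRanges::GRanges(scaffold_id,
        IRanges::IRanges(relaxed$start, relaxed$end), strand = relaxed$strand)
      for (k in seq_along(unexplained)) {
        cl <- unexplained[k]
        sc <- max(hsps$score[IRanges::overlapsAny(hgr, cl)])
        cand <- which(IRanges::overlapsAny(rgr, cl))
        if (!length(cand)) next
        ## rank candidate ORFs by HSP-score-weighted overlap so that a
        ## strongly supported locus beats an incidental longer ORF
        support <- vapply(cand, function(ci) {
          same <- hsps$strand == relaxed$strand[ci]
          ov <- pmin(hsps$s_nt_end, relaxed$end[ci]) -
                pmax(hsps$s_nt_start, relaxed$start[ci]) + 1L
          sum(hsps$score[same] * pmax(ov[same], 0L))
        }, numeric(1))
        cand <- cand[order(-support)]
        got <- NULL
        for (ci in cand) {
          got <- .orfToModel(scaffold_id, seq, rcseq, L, relaxed[ci, ], params,
                             evidence = "homology", score = sc)
          if (!is.null(got)) break
        }
        if (is.null(got)) {
          ## keep the best-supported ORF as a partial model on homology
          ## evidence alone
          got <- .orfToModel(scaffold_id, seq, rcseq, L, relaxed[cand[1], ],
                             params, evidence = "homology", score = sc,
                             keep_on_fail = TRUE)
        }
        models <- rbind(models, got)
      }
    }
    ## annotate ORF models that also have homology support
    if (nrow(models)) {
      mgr2 <- GenomicRanges::GRanges(scaffold_id,
        IRanges::IRanges(models$cds_start, models$cds_end),
        strand = models$strand)
      hit <- IRanges::overlapsAny(mgr2, hgr)
      models$evidence <- ifelse(hit & models$evidence == "orf_scan",
                                "orf_scan,homology", models$evidence)
    }
  }

  if (!nrow(models)) return(GeneModelSet())
  ## resolve overlapping same-strand models: highest score, then longest
  ## CDS, then leftmost
  gr <- GenomicRanges::GRanges(scaffold_id,
    IRanges::IRanges(models$cds_start, models$cds_end), strand = models$strand)
  ov <- GenomicRanges::findOverlaps(gr, ignore.strand = FALSE)
  comp <- seq_len(nrow(models))
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  for (j in seq_along(ov)) {
    a <- find(S4Vectors::queryHits(ov)[j]); b <- find(S4Vectors::subjectHits(ov)[j])
    if (a != b) comp[max(a, b)] <- min(a, b)
  }
  comp <- vapply(seq_len(nrow(models)), find, integer(1))
  keep <- integer(0)
  for (cmp in unique(comp)) {
    idx <- which(comp == cmp)
    sc <- models$score[idx]; sc[is.na(sc)] <- -Inf
    w <- models$cds_end[idx] - models$cds_start[idx]
    best <- idx[order(-sc, -w, models$cds_start[idx])][1]
    keep <- c(keep, best)
  }
  models <- models[sort(keep), , drop = FALSE]

  models <- models[order(models$cds_start, models$cds_end), , drop = FALSE]
  gr <- GenomicRanges::GRanges(models$scaffold,
    IRanges::IRanges(models$cds_start, models$cds_end), strand = models$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = sprintf("%s_g%03d", scaffold_id, seq_len(nrow(models))),
    status = models$status, evidence = models$evidence,
    family = NA_character_, protein = models$protein, score = models$score,
    utr5_start = as.integer(models$utr5_start),
    utr5_end = as.integer(models$utr5_end),
    exon1_start = as.integer(models$exon1_start),
    exon1_end = as.integer(models$exon1_end),
    intron_start = as.integer(models$intron_start),
    intron_end = as.integer(models$intron_end),
    mutations = "")
  GeneModelSet(gr)
}

#' Scan scaffolds for SEDC genes
#'
#' Runs the six-frame ORF scan (and, when queries are supplied, the
#' translated homology search) on every scaffold and assembles gene models.
#'
#' @param scaffolds A named \code{DNAStringSet} (or named character vector).
#' @param params \code{\link{scanParams}}.
#' @param queries Optional \code{AAStringSet} of protein queries.
#' @return A \code{\linkS4class{GeneModelSet}} over all scaffolds.
#' @export
scanScaffolds <- function(scaffolds, params = scanParams(), queries = NULL) {
  if (is.character(scaffolds)) scaffolds <- Biostrings::DNAStringSet(scaffolds)
  if (is.null(names(scaffolds)))
    names(scaffolds) <- sprintf("scaffold%02d", seq_along(scaffolds))
  sets <- lapply(names(scaffolds), function(id) {
    seq <- as.character(scaffolds[[id]])
    orfs <- sixFrameOrfs(seq, params)
    hsps <- if (!is.null(queries) && length(queries))
      translatedSearch(queries, seq, params) else NULL
    geneModels(assembleModels(id, seq, orfs, hsps, params))
  })
  gr <- suppressWarnings(do.call(c, sets))
  mc <- S4Vectors::mcols(gr)
  if (anyDuplicated(mc$gene_id))
    mc$gene_id <- sprintf("%s_r%04d", mc$gene_id, seq_along(gr))
  S4Vectors::mcols(gr) <- mc
  GeneModelSet(gr)
}

#' Iterative homology-seeded annotation
#'
#' Runs rounds of gene search in which the translations of newly predicted
#' models are added to the query set (deduplicated at 100\% identity) until
#' no new models are found or \code{max_rounds} is reached. The model set is
#' monotonically non-decreasing across rounds and independent of the input
#' order of the queries.
#'
#' @param scaffolds Named \code{DNAStringSet}.
#' @param initial_queries \code{AAStringSet} of starting queries.
#' @param params \code{\link{scanParams}}.
#' @param max_rounds Maximum number of search rounds.
#' @return A \code{\linkS4class{GeneModelSet}}; the number of rounds used is
#'   in \code{attr(x, "rounds")} and per-round model counts in
#'   \code{attr(x, "round_counts")}.
#' @export
iterateAnnotation <- function(scaffolds, initial_queries,
                              params = scanParams(), max_rounds = 10L) {
  if (is.character(scaffolds)) scaffolds <- Biostrings::DNAStringSet(scaffolds)
  if (!length(initial_queries)) stop("initial_queries must be non-empty")
  qs <- sort(unique(as.character(initial_queries)))
  key <- function(g) paste(GenomicRanges::seqnames(g), GenomicRanges::start(g),
                           GenomicRanges::end(g), GenomicRanges::strand(g))
  seen <- character(0)
  acc <- NULL
  counts <- integer(0)
  rounds <- 0L
  for (round in seq_len(max_rounds)) {
    rounds <- round
    queries <- Biostrings::AAStringSet(setNames(qs, sprintf("q%04d", seq_along(qs))))
    ms <- scanScaffolds(scaffolds, params, queries = queries)
    gr <- geneModels(ms)
    newk <- setdiff(key(gr), seen)
    acc <- if (is.null(acc)) gr else {
      add <- gr[key(gr) %in% newk]
      suppressWarnings(c(acc, add))
    }
    seen <- union(seen, key(gr))
    counts <- c(counts, length(acc))
    newq <- setdiff(S4Vectors::mcols(gr)$protein, qs)
    newq <- newq[!is.na(newq) & nzchar(newq)]
    if (!length(newk) || !length(newq)) break
    qs <- sort(unique(c(qs, newq)))
    if (round == max_rounds) break
  }
  acc <- acc[order(as.character(GenomicRanges::seqnames(acc)),
                   GenomicRanges::start(acc))]
  mc <- S4Vectors::mcols(acc)
  mc$gene_id <- sprintf("%s_g%03d", as.character(GenomicRanges::seqnames(acc)),
                        seq_along(acc))
  S4Vectors::mcols(acc) <- mc
  out <- GeneModelSet(acc)
  attr(out, "rounds") <- rounds
  attr(out, "round_counts") <- counts
  out
}

#' Attach expression-support evidence to gene models
#'
#' Transcription evidence (e.g. RNA-seq exon coverage summarized elsewhere)
#' enters the annotation only as a per-gene flag: models whose CDS overlaps
#' a supported interval gain \code{"expression"} evidence.
#'
#' @param models A \code{\linkS4class{GeneModelSet}}.
#' @param support Data frame with columns \code{scaffold}, \code{start},
#'   \code{end} (1-based inclusive) and optionally \code{supported}
#'   (logical; default TRUE).
#' @return The updated \code{GeneModelSet}.
#' @export
addExpressionEvidence <- function(models, support) {
  if (!nrow(support)) return(models)
  if (!"supported" %in% names(support)) support$supported <- TRUE
  support <- support[isTRUE(support$supported) | support$supported, , drop = FALSE]
  gr <- geneModels(models)
  sgr <- GenomicRanges::GRanges(support$scaffold,
                                IRanges::IRanges(support$start, support$end))
  hit <- IRanges::overlapsAny(gr, sgr, ignore.strand = TRUE)
  mc <- S4Vectors::mcols(gr)
  mc$evidence <- ifelse(hit & !grepl("expression", mc$evidence),
                        paste0(mc$evidence, ",expression"), mc$evidence)
  S4Vectors::mcols(gr) <- mc
  GeneModelSet(gr)
}
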