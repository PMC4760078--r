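## ---------------------------------------------------------------------------
## Per-protein feature profiles: amino-acid composition and combined bias
## metrics, tandem repeat structure, beta-sheet core detection (Chou-Fasman
## propensity or seeded profile), terminal motif profiles, and family
## classification.
## ---------------------------------------------------------------------------

#' Chou-Fasman beta-sheet conformational parameters
#'
#' Published beta-sheet propensities per residue; values above 1 favour
#' beta-strand conformation.
#' @return Named numeric vector over the 20 amino acids.
#' @export
chouFasmanBeta <- function() {
  c(A = 0.83, R = 0.93, N = 0.89, D = 0.54, C = 1.19, Q = 1.10, E = 0.37,
    G = 0.75, H = 0.87, I = 1.60, L = 1.30, K = 0.74, M = 1.05, F = 1.38,
    P = 0.55, S = 0.75, T = 1.19, W = 1.37, Y = 1.47, V = 1.70)
}

#' Parameters for beta-keratin core detection
#'
#' Beta-keratins (corneous beta-proteins) are defined by a 34-residue
#' segment with high propensity to form beta-sheets. Detection slides a
#' window of \code{window_len} residues and calls a hit when the mean
#' propensity reaches \code{propensity_threshold}, or, when a seed profile
#' built from curated core sequences is supplied, when the profile log-odds
#' score reaches \code{profile_threshold}.
#'
#' @param window_len Core segment length in residues.
#' @param propensity_table Residue-to-propensity map.
#' @param propensity_threshold Mean-propensity cutoff for a hit. The
#'   default (1.30) sits well above window means of unbiased sequence
#'   (about 1.03 +/- 0.06) and well below planted/typical beta cores.
#' @param seed_profile Optional position-specific scoring profile
#'   (20 x window_len matrix of log-odds), e.g. from
#'   \code{\link{terminalMotifProfiles}}-style construction on curated cores.
#' @param profile_threshold Score cutoff in profile mode.
#' @return A list of class \code{"BetaCoreParams"}.
#' @export
betaCoreParams <- function(window_len = 34L,
                           propensity_table = chouFasmanBeta(),
                           propensity_threshold = 1.30,
                           seed_profile = NULL, profile_threshold = 0) {
  stopifnot(window_len >= 1L, all(AA20 %in% names(propensity_table)))
  structure(list(window_len = as.integer(window_len),
                 propensity_table = propensity_table,
                 propensity_threshold = propensity_threshold,
                 seed_profile = seed_profile,
                 profile_threshold = profile_threshold),
            class = "BetaCoreParams")
}

#' Amino-acid composition profile of one protein
#'
#' Exact residue counts normalized by length, plus the combined bias
#' metrics used to characterize EDC protein families: glycine+serine,
#' cysteine+proline, aromatic (F+W+Y+H) and lysine+glutamine (the
#' transglutamination substrates).
#'
#' @param protein Amino-acid string over the standard alphabet.
#' @return List with \code{length}, \code{fractions} (named 20-vector),
#'   \code{gs_combined}, \code{cp_combined}, \code{aromatic_combined},
#'   \code{kq_combined}.
#' @export
compositionProfile <- function(protein) {
  protein <- as.character(protein)
  if (!nzchar(protein)) stop("protein must be non-empty")
  aa <- strsplit(protein, "")[[1]]
  if (!all(aa %in% AA20))
    stop("protein contains non-standard letters: ",
         paste(unique(setdiff(aa, AA20)), collapse = ""))
  counts <- table(factor(aa, levels = AA20))
  fr <- as.numeric(counts) / length(aa)
  names(fr) <- AA20
  list(length = length(aa), fractions = fr,
       gs_combined = sum(fr[c("G", "S")]),
       cp_combined = sum(fr[c("C", "P")]),
       aromatic_combined = sum(fr[c("F", "W", "Y", "H")]),
       kq_combined = sum(fr[c("K", "Q")]))
}

#' Detect beta-sheet core segments
#'
#' Slides a window of \code{window_len} residues over the protein and calls
#' windows whose mean beta propensity (or profile score, in profile mode)
#' reaches the threshold; runs of overlapping qualifying windows are merged
#' and the maximal-scoring window of each run is reported. Hit spans are
#' exactly \code{window_len} residues.
#'
#' @param protein Amino-acid string.
#' @param params \code{\link{betaCoreParams}}.
#' @return Data frame with columns \code{start}, \code{end},
#'   \code{mean_propensity} (or \code{profile_score}); zero rows (with
#'   attribute \code{reason}) when the protein is shorter than the window.
#' @export
detectBetaCore <- function(protein, params = betaCoreParams()) {
  protein <- as.character(protein)
  aa <- strsplit(protein, "")[[1]]
  w <- params$window_len
  empty <- data.frame(start = integer(0), end = integer(0),
                      mean_propensity = numeric(0))
  if (length(aa) < w) {
    attr(empty, "reason") <- "protein shorter than window"
    return(empty)
  }
  if (is.null(params$seed_profile)) {
    v <- params$propensity_table[aa]
    v[is.na(v)] <- 1.0
    cs <- c(0, cumsum(v))
    means <- (cs[(w + 1):length(cs)] - cs[seq_len(length(cs) - w)]) / w
    qual <- means >= params$propensity_threshold
    scores <- means
    colname <- "mean_propensity"
  } else {
    prof <- params$seed_profile
    n_win <- length(aa) - w + 1L
    scores <- vapply(seq_len(n_win), function(s) {
      sum(prof[cbind(match(aa[s:(s + w - 1L)], AA20), seq_len(w))])
    }, numeric(1))
    qual <- scores >= params$profile_threshold
    colname <- "profile_score"
  }
  if (!any(qual)) return(empty)
  r <- rle(qual)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  hits <- lapply(which(r$values), function(k) {
    idx <- starts[k]:ends[k]
    bi <- idx[which.max(scores[idx])]
    data.frame(start = bi, end = bi + w - 1L, score = scores[bi])
  })
  out <- do.call(rbind, hits)
  names(out)[3] <- colname
  rownames(out) <- NULL
  out
}

#' Find tandem repeats in a protein sequence
#'
#' Period-scanning detection of maximal perfect and near-perfect (at most
#' one mismatch per unit against the preceding unit) tandem arrays. Calls
#' are sorted by span length and selected greedily without overlap; equal
#' spans prefer the smallest period.
#'
#' @param protein Amino-acid string.
#' @param min_unit,max_unit Unit length bounds (residues).
#' @param min_copies Minimum number of tandem copies to call.
#' @return Data frame: \code{unit}, \code{copies}, \code{start}, \code{end},
#'   \code{span}.
#' @export
findTandemRepeats <- function(protein, min_unit = 2L, max_unit = 30L,
                              min_copies = 3L) {
  s <- strsplit(as.character(protein), "")[[1]]
  n <- length(s)
  calls <- list()
  addCall <- function(p, u, copies, mism) {
    calls[[length(calls) + 1L]] <<- data.frame(
      unit = paste(s[p:(p + u - 1L)], collapse = ""),
      copies = copies, start = p, end = p + copies * u - 1L,
      span = copies * u, mismatches = mism, stringsAsFactors = FALSE)
  }
  for (u in min_unit:min(max_unit, n %/% 2L)) {
    if (n < u * min_copies) next
    eq <- s[seq_len(n - u)] == s[(u + 1L):n]    # period-u equality
    bad <- cumsum(c(0L, !eq))                   # mismatch prefix counts
    ## perfect arrays: maximal all-TRUE runs of eq
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= (min_copies - 1L) * u))
      addCall(starts[k], u, r$lengths[k] %/% u + 1L, 0L)
    ## near-perfect arrays (at most one mismatch per unit boundary)
    p <- 1L
    while (p + u * min_copies - 1L <= n) {
      copies <- 1L; mism <- 0L
      q <- p
      while (q + 2L * u - 1L <= n) {
        m1 <- bad[q + u] - bad[q]               # mismatches unit q.. vs next
        if (m1 <= 1L) { copies <- copies + 1L; mism <- mism + m1; q <- q + u }
        else break
      }
      if (copies >= min_copies && mism > 0L) {
        addCall(p, u, copies, mism)
        p <- p + copies * u
      } else if (copies >= min_copies) {
        p <- p + copies * u                     # already covered exactly
      } else p <- p + 1L
    }
  }
  if (!length(calls))
    return(data.frame(unit = character(0), copies = integer(0),
                      start = integer(0), end = integer(0), span = integer(0)))
  calls <- do.call(rbind, calls)
  ## longest span first; equal spans prefer perfect arrays, then the
  ## smallest period, then the leftmost start
  calls <- calls[order(-calls$span, calls$mismatches, nchar(calls$unit),
                       calls$start), , drop = FALSE]
  chosen <- logical(nrow(calls))
  used <- rep(FALSE, length(s))
  for (i in seq_len(nrow(calls))) {
    idx <- calls$start[i]:calls$end[i]
    if (!any(used[idx])) { chosen[i] <- TRUE; used[idx] <- TRUE }
  }
  out <- calls[chosen, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Terminal motif profiles and conservation scores
#'
#' EDC proteins across the cluster share conserved sequence motifs at their
#' amino and carboxy termini. This builds position-specific frequency
#' profiles (pseudocount 0.5) from the terminal segments of a protein set
#' and scores each protein's termini as log-odds against the overall
#' residue background.
#'
#' @param proteins \code{AAStringSet} or named character vector (at least 5
#'   sequences of sufficient length).
#' @param n_len,c_len Lengths of the N- and C-terminal segments.
#' @param pseudocount Pseudocount added per residue per column.
#' @return List with \code{n_profile}, \code{c_profile} (20 x len column-
#'   normalized frequency matrices), \code{background}, and \code{scores}
#'   (data frame id, n_score, c_score).
#' @export
terminalMotifProfiles <- function(proteins, n_len = 12L, c_len = 12L,
                                  pseudocount = 0.5) {
  p <- as.character(proteins)
  nm <- names(proteins) %||% sprintf("p%03d", seq_along(p))
  keep <- nchar(p) >= max(n_len, c_len)
  if (sum(keep) < 5L)
    stop("need at least 5 proteins of length >= ", max(n_len, c_len))
  p <- p[keep]; nm <- nm[keep]
  allaa <- strsplit(paste(p, collapse = ""), "")[[1]]
  bg <- (table(factor(allaa, levels = AA20)) + pseudocount)
  bg <- as.numeric(bg / sum(bg)); names(bg) <- AA20

  mkProfile <- function(segs, len) {
    M <- matrix(pseudocount, nrow = 20L, ncol = len, dimnames = list(AA20, NULL))
    for (sg in segs) {
      ch <- strsplit(sg, "")[[1]]
      for (j in seq_len(len)) M[ch[j], j] <- M[ch[j], j] + 1
    }
    sweep(M, 2, colSums(M), "/")
  }
  nseg <- substring(p, 1L, n_len)
  cseg <- substring(p, nchar(p) - c_len + 1L, nchar(p))
  n_prof <- mkProfile(nseg, n_len)
  c_prof <- mkProfile(cseg, c_len)
  scoreSeg <- function(sg, prof) {
    ch <- strsplit(sg, "")[[1]]
    sum(log2(prof[cbind(match(ch, AA20), seq_along(ch))] / bg[ch]))
  }
  data_scores <- data.frame(
    id = nm,
    n_score = vapply(nseg, scoreSeg, numeric(1), prof = n_prof),
    c_score = vapply(cseg, scoreSeg, numeric(1), prof = c_prof),
    row.names = NULL)
  list(n_profile = n_prof, c_profile = c_prof, background = bg,
       scores = data_scores)
}

#' Classification thresholds for EDC protein families
#'
#' @param cp Combined cysteine+proline fraction above which a protein is
#'   CP-rich (anchored to the observation that C+P exceeds 50\% of residues
#'   in the most biased SEDC proteins).
#' @param gs Combined glycine+serine fraction for GS-rich.
#' @param aromatic Combined F+W+Y+H fraction for aromatic-rich (EDAA-like).
#' @param homology_identity Minimum identity for a homology-based family
#'   assignment to take precedence.
#' @return Named list of thresholds.
#' @export
classifyThresholds <- function(cp = 0.5, gs = 0.5, aromatic = 0.25,
                               homology_identity = 0.35) {
  list(cp = cp, gs = gs, aromatic = aromatic,
       homology_identity = homology_identity)
}

#' Classify one protein into an EDC family class
#'
#' Fixed precedence: (1) homology-assigned family at sufficient identity;
#' (2) beta-keratin if a beta-core hit is present; (3) CP-rich; (4) GS-rich;
#' (5) aromatic-rich; otherwise \code{"other"}.
#'
#' @param profile Output of \code{\link{compositionProfile}}.
#' @param beta_hits Output of \code{\link{detectBetaCore}} for the protein.
#' @param homology_best_family Optional family label from homology.
#' @param homology_identity Identity of the homology assignment.
#' @param thresholds \code{\link{classifyThresholds}}.
#' @return List with \code{class_label} and \code{family}.
#' @export
classifyFamily <- function(profile, beta_hits = NULL,
                           homology_best_family = NA_character_,
                           homology_identity = NA_real_,
                           thresholds = classifyThresholds()) {
  label <-
    if (!is.null(beta_hits) && nrow(beta_hits) > 0L) "beta_keratin"
    else if (profile$cp_combined > thresholds$cp) "CP_rich"
    else if (profile$gs_combined > thresholds$gs) "GS_rich"
    else if (profile$aromatic_combined >= thresholds$aromatic) "aromatic_rich"
    else "other"
  family <-
    if (!is.na(homology_best_family) && !is.na(homology_identity) &&
        homology_identity >= thresholds$homology_identity)
      homology_best_family
    else label
  list(class_label = label, family = family)
}

#' Feature profiles and classification for a protein set
#'
#' Computes composition profiles, repeat calls, beta-core hits and family
#' class labels for every protein.
#'
#' @param proteins \code{AAStringSet} or named character vector.
#' @param beta_params \code{\link{betaCoreParams}}.
#' @param thresholds \code{\link{classifyThresholds}}.
#' @param homology Optional data frame (id, family, identity) of
#'   homology-based assignments taking precedence at sufficient identity.
#' @param repeats Logical: also run tandem-repeat detection (slower).
#' @return A \code{\linkS4class{ProteinFeatureSet}}.
#' @export
proteinFeatures <- function(proteins, beta_params = betaCoreParams(),
                            thresholds = classifyThresholds(),
                            homology = NULL, repeats = FALSE) {
  p <- as.character(proteins)
  nm <- names(proteins) %||% sprintf("p%03d", seq_along(p))
  rows <- vector("list", length(p))
  reps <- list(); cores <- list()
  for (i in seq_along(p)) {
    prof <- compositionProfile(p[i])
    bh <- detectBetaCore(p[i], beta_params)
    hb <- NA_character_; hi <- NA_real_
    if (!is.null(homology)) {
      hrow <- homology[homology$id == nm[i], , drop = FALSE]
      if (nrow(hrow)) { hb <- hrow$family[1]; hi <- hrow$identity[1] }
    }
    cl <- classifyFamily(prof, bh, hb, hi, thresholds)
    rows[[i]] <- data.frame(
      id = nm[i], length = prof$length, t(prof$fractions),
      gs_combined = prof$gs_combined, cp_combined = prof$cp_combined,
      aromatic_combined = prof$aromatic_combined,
      kq_combined = prof$kq_combined,
      class_label = cl$class_label, family = cl$family,
      stringsAsFactors = FALSE)
    cores[[nm[i]]] <- bh
    if (repeats) reps[[nm[i]]] <- findTandemRepeats(p[i])
  }
  new("ProteinFeatureSet", table = do.call(rbind, rows),
      repeats = reps, betaCores = cores)
}
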