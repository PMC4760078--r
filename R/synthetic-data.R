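## ---------------------------------------------------------------------------
## Synthetic-genome generator: plants two-exon SEDC-type genes with the
## canonical promoter/splice signals, biased-composition protein families,
## decoy ORFs, pseudogenes, assembly gaps and translocated family copies,
## and records machine-readable ground truth.
## ---------------------------------------------------------------------------

## Residues used for planted beta-sheet cores (high Chou-Fasman beta
## propensity) and their sampling weights.
.betaCoreResidues <- c("V", "I", "T", "F", "Y", "W")

## Average residue frequencies of globular proteins (Swiss-Prot-like);
## the background composition of "unbiased" simulated proteins.
.naturalAAFreq <- local({
  f <- c(A = 8.25, C = 1.38, D = 5.45, E = 6.72, F = 3.86, G = 7.07,
         H = 2.27, I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06,
         P = 4.73, Q = 3.93, R = 5.53, S = 6.63, T = 5.35, V = 6.86,
         W = 1.10, Y = 2.92)
  f / sum(f)
})

#' Composition specification for a simulated protein class
#'
#' Describes the target amino-acid composition of one simulated EDC protein
#' family: glycine/serine-rich, cysteine/proline-rich, aromatic-rich,
#' beta-keratin-like (which additionally carries a planted 34-residue
#' beta-sheet core) or unbiased.
#'
#' @param class_label One of \code{"GS_rich"}, \code{"CP_rich"},
#'   \code{"aromatic_rich"}, \code{"beta_keratin_like"}, \code{"unbiased"}.
#' @param target_fractions Optional named numeric over the 20 amino acids
#'   summing to 1; when \code{NULL} a class-typical default is used.
#' @param repeat_unit Optional peptide to embed as an exact tandem array.
#' @param repeat_copies Number of tandem copies of \code{repeat_unit}.
#' @return A list of class \code{"CompositionSpec"}.
#' @export
compositionSpec <- function(class_label = c("GS_rich", "CP_rich",
                                            "aromatic_rich",
                                            "beta_keratin_like", "unbiased"),
                            target_fractions = NULL,
                            repeat_unit = NULL, repeat_copies = 0L) {
  class_label <- match.arg(class_label)
  if (is.null(target_fractions)) {
    f <- setNames(rep(0, 20), AA20)
    f[] <- switch(class_label,
      GS_rich = { f[AA20] <- 0.33 / 18; f["G"] <- 0.36; f["S"] <- 0.31; f },
      CP_rich = { f[AA20] <- 0.36 / 18; f["C"] <- 0.32; f["P"] <- 0.32; f },
      aromatic_rich = { f[AA20] <- 0.64 / 16; f["H"] <- 0.14; f["Y"] <- 0.14
                        f["F"] <- 0.06; f["W"] <- 0.02; f },
      beta_keratin_like = {
        core <- setNames(rep(0, 20), AA20)
        core[.betaCoreResidues] <- 1 / length(.betaCoreResidues)
        0.2 * core + 0.8 * .naturalAAFreq[AA20]
      },
      unbiased = .naturalAAFreq[AA20])
    target_fractions <- f
  }
  target_fractions <- target_fractions[AA20]
  if (any(is.na(target_fractions)) || any(target_fractions < 0) ||
      any(target_fractions > 1) || abs(sum(target_fractions) - 1) > 1e-9)
    stop("target_fractions must be a distribution over the 20 amino acids")
  ok <- switch(class_label,
    CP_rich = sum(target_fractions[c("C", "P")]) > 0.5,
    GS_rich = sum(target_fractions[c("G", "S")]) > 0.5,
    aromatic_rich = sum(target_fractions[c("F", "W", "Y", "H")]) >= 0.25,
    TRUE)
  if (!ok) stop("target_fractions violate the bias required for ", class_label)
  if (!is.null(repeat_unit)) {
    if (!nzchar(repeat_unit) || !all(strsplit(repeat_unit, "")[[1]] %in% AA20))
      stop("repeat_unit must be a non-empty standard-alphabet peptide")
    if (repeat_copies < 0) stop("repeat_copies must be >= 0")
  }
  structure(list(class_label = class_label,
                 target_fractions = target_fractions,
                 repeat_unit = repeat_unit,
                 repeat_copies = as.integer(repeat_copies)),
            class = "CompositionSpec")
}

#' Sample a protein sequence from a composition specification
#'
#' Draws an amino-acid sequence whose empirical composition approximates the
#' spec's target fractions. An exact tandem repeat array is embedded when the
#' spec requests one; beta-keratin-like specs additionally receive a planted
#' 34-residue segment of high beta-sheet propensity.
#'
#' @param spec A \code{\link{compositionSpec}}.
#' @param length Protein length (1 to 10000).
#' @param seed Integer seed; identical seeds give identical sequences.
#' @return A single amino-acid string.
#' @export
sampleProtein <- function(spec, length, seed = 1L) {
  stopifnot(inherits(spec, "CompositionSpec"))
  length <- as.integer(length)
  if (length < 1L || length > 10000L) stop("length must be in [1, 10000]")
  rep_len_total <- 0L
  if (!is.null(spec$repeat_unit) && spec$repeat_copies > 0L) {
    rep_len_total <- nchar(spec$repeat_unit) * spec$repeat_copies
    if (rep_len_total > length)
      stop("impossible spec: repeat_copies x nchar(repeat_unit) = ",
           rep_len_total, " exceeds length ", length)
  }
  set.seed(seed)
  core_len <- if (spec$class_label == "beta_keratin_like") 34L else 0L
  if (rep_len_total + core_len > length)
    stop("impossible spec: repeat array plus 34-residue beta core exceed length")

  ## background residues
  tf <- spec$target_fractions
  if (core_len > 0L) {
    ## compensate the planted core so the overall composition still tracks
    ## the target fractions
    core_f <- setNames(rep(0, 20), AA20)
    core_f[.betaCoreResidues] <- 1 / length(.betaCoreResidues)
    p <- core_len / length
    tf <- (tf - p * core_f) / (1 - p)
    tf[tf < 0] <- 0
    tf <- tf / sum(tf)
  }
  x <- sample(AA20, length, replace = TRUE, prob = tf)

  ## place repeat array, then the beta core in a non-overlapping free slot
  occupied <- integer(0)
  if (rep_len_total > 0L) {
    start <- sample.int(length - rep_len_total + 1L, 1L)
    unit <- strsplit(spec$repeat_unit, "")[[1]]
    idx <- start:(start + rep_len_total - 1L)
    x[idx] <- rep(unit, spec$repeat_copies)
    occupied <- idx
  }
  if (core_len > 0L) {
    free_starts <- setdiff(seq_len(length - core_len + 1L),
                           unique(unlist(lapply(occupied, function(i)
                             max(1L, i - core_len + 1L):i))))
    if (!length(free_starts))
      stop("impossible spec: no room for the beta core outside the repeat array")
    s <- if (length(free_starts) == 1L) free_starts else sample(free_starts, 1L)
    x[s:(s + core_len - 1L)] <- sample(.betaCoreResidues, core_len, replace = TRUE)
  }
  paste(x, collapse = "")
}

#' Reverse-translate a protein into a coding DNA sequence
#'
#' Chooses uniformly among synonymous codons for every residue and appends a
#' stop codon, so that translating the result in frame 0 recovers the input
#' protein followed by a stop.
#'
#' @param protein Amino-acid string over the 20 standard letters.
#' @param seed Integer seed for the codon choices.
#' @return A DNA string of length \code{3 * (nchar(protein) + 1)}.
#' @export
reverseTranslate <- function(protein, seed = 1L) {
  aa <- strsplit(protein, "")[[1]]
  if (!length(aa) || !all(aa %in% AA20))
    stop("protein must be non-empty and use only the 20 standard letters")
  set.seed(seed)
  codons <- vapply(aa, function(a) {
    opts <- .codonTable[[a]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1))
  paste0(paste(codons, collapse = ""), sample(.stopCodons, 1L))
}

## Diverge a protein from its ancestor by random point substitutions.
.mutateProtein <- function(protein, rate, seed) {
  set.seed(seed)
  ch <- strsplit(protein, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(AA20, ch[i]), 1L)
  paste(ch, collapse = "")
}

## Background filler that carries no TATA-box motif (so it cannot seed a
## spurious noncoding exon 1).
.bgFill <- function(n, tata_pattern = "TATA[AT]A") {
  randomDNA(n, avoid = tata_pattern)
}

#' Plant a complete two-exon SEDC gene around a coding sequence
#'
#' Assembles, in gene orientation, a fragment consisting of a noncoding
#' exon 1 that starts with a TATA box, a GT..AG intron, a 5' UTR of the
#' requested length and the ATG-initiated CDS terminated by a stop codon.
#' Filler bases are generated so that the fragment contains exactly one
#' qualifying SEDC gene structure: no stray TATA motif, no splice donor GT
#' between the planted donor and the acceptor, and a G-free 5' UTR (hence no
#' competing acceptor AG).
#'
#' @param cds DNA coding sequence: starts with ATG, length divisible by 3,
#'   no internal stop codon, stop codon \emph{not} included (one is added).
#' @param utr5_len 5' UTR length in nt, 10 to 30.
#' @param tata_to_donor Distance in nt from the first base of the TATA box to
#'   the first base of the GT donor, 60 to 90.
#' @param intron_len Intron length in nt (GT..AG inclusive), at least 20.
#' @param seed Integer seed for the filler bases and the stop codon.
#' @return A list: \code{fragment} (DNA string) and \code{offsets}, a list of
#'   1-based inclusive intervals (\code{exon1}, \code{intron}, \code{utr5},
#'   \code{cds}) plus \code{tata_start} and \code{protein}.
#' @export
plantGene <- function(cds, utr5_len, tata_to_donor, intron_len, seed = 1L) {
  utr5_len <- as.integer(utr5_len)
  tata_to_donor <- as.integer(tata_to_donor)
  intron_len <- as.integer(intron_len)
  if (utr5_len < 10L || utr5_len > 30L)
    stop("utr5_len must be in [10, 30] (got ", utr5_len, ")")
  if (tata_to_donor < 60L || tata_to_donor > 90L)
    stop("tata_to_donor must be in [60, 90] (got ", tata_to_donor, ")")
  if (intron_len < 20L) stop("intron_len must be >= 20")
  if (nchar(cds) %% 3L != 0L || substr(cds, 1, 3) != "ATG")
    stop("cds must start with ATG and have length divisible by 3")
  prot <- translateDNA(cds)
  if (grepl("\\*", prot)) stop("cds must not contain an internal stop codon")

  set.seed(seed)
  ## exon 1: TATAAA + filler up to the donor (exon1 spans TATA..donor-1)
  exon1_fill <- randomDNA(tata_to_donor - 6L, avoid = c("TATA[AT]A", "GT"))
  exon1 <- paste0("TATAAA", exon1_fill)
  ## intron: GT + filler + stop block + AG; no internal GT (would offer a
  ## nearer donor), no TATA motif. The TTAATTAATTAA block puts a stop codon
  ## in all three frames just upstream of the CDS, so the planted ATG is
  ## always the first start codon of its open segment.
  intron_fill <- randomDNA(intron_len - 16L, avoid = c("TATA[AT]A", "GT"))
  intron <- paste0("GT", intron_fill, "TTAATTAATTAA", "AG")
  ## 5' UTR: G-free so the planted acceptor AG is the innermost qualifying one
  utr5 <- randomDNA(utr5_len, avoid = "TATA[AT]A", alphabet = c("A", "C", "T"))
  stopc <- sample(.stopCodons, 1L)
  fragment <- paste0(exon1, intron, utr5, cds, stopc)

  e1 <- c(1L, tata_to_donor)
  it <- c(tata_to_donor + 1L, tata_to_donor + intron_len)
  u5 <- c(it[2] + 1L, it[2] + utr5_len)
  cd <- c(u5[2] + 1L, u5[2] + nchar(cds) + 3L)  # stop codon included
  list(fragment = fragment,
       offsets = list(tata_start = 1L, exon1 = e1, intron = it,
                      utr5 = u5, cds = cd, protein = prot))
}

#' Default simulation configuration
#'
#' Three tandem EDC gene families between the two S100A anchor intervals
#' (a glycine/serine-rich family of 4, an aromatic-rich family of 2 and a
#' beta-keratin-like family of 6 genes, 12 genes total), two decoy ORFs and
#' no pseudogenes, gaps or translocations. Fields can be overridden
#' individually by passing a partial config (unspecified fields keep their
#' defaults).
#'
#' @return A named list understood by \code{\link{buildTruthSet}}.
#' @export
defaultSimConfig <- function() {
  list(
    scaffold_id = "sim_EDC_scaffold",
    families = list(
      list(name = "EDGS", class = "GS_rich", n = 4L),
      list(name = "EDAA", class = "aromatic_rich", n = 2L),
      list(name = "BetaA", class = "beta_keratin_like", n = 6L)),
    protein_len = c(60L, 120L),
    utr5_len = c(10L, 30L),
    tata_to_donor = c(60L, 90L),
    intron_len = c(80L, 250L),
    intergenic = c(150L, 400L),
    within_family_divergence = 0.15,
    n_decoys = 2L,
    pseudogenes = list(),      # e.g. list(list(family="EDGS", type="premature_stop"))
    gaps = list(),             # e.g. list(list(family="EDGS", len=200L))
    translocations = list(),   # e.g. list(list(family="BetaO", class="beta_keratin_like",
                               #               n=2L, anchor="ODF3B-like"))
    anchor_len = 300L,
    pad = 250L
  )
}

## Plant one gene (possibly on the minus strand) into the piece list.
.geneRecord <- function(id, scaffold_id, strand, frag, off, family, status,
                        mutations, offset) {
  shift <- function(iv) iv + offset
  L <- nchar(frag)
  if (strand == "-") {
    frag <- revComp(frag)
    refl <- function(iv) reflectInterval(iv[1], iv[2], L) + offset
    list(seq = frag,
         row = data.frame(gene_id = id, scaffold = scaffold_id, strand = strand,
                          cds_start = refl(off$cds)[1], cds_end = refl(off$cds)[2],
                          utr5_start = refl(off$utr5)[1], utr5_end = refl(off$utr5)[2],
                          exon1_start = refl(off$exon1)[1], exon1_end = refl(off$exon1)[2],
                          intron_start = refl(off$intron)[1], intron_end = refl(off$intron)[2],
                          protein = off$protein, family = family, status = status,
                          mutations = mutations, stringsAsFactors = FALSE))
  } else {
    list(seq = frag,
         row = data.frame(gene_id = id, scaffold = scaffold_id, strand = strand,
                          cds_start = shift(off$cds)[1], cds_end = shift(off$cds)[2],
                          utr5_start = shift(off$utr5)[1], utr5_end = shift(off$utr5)[2],
                          exon1_start = shift(off$exon1)[1], exon1_end = shift(off$exon1)[2],
                          intron_start = shift(off$intron)[1], intron_end = shift(off$intron)[2],
                          protein = off$protein, family = family, status = status,
                          mutations = mutations, stringsAsFactors = FALSE))
  }
}

#' Build a synthetic genome with ground truth
#'
#' Generates one scaffold carrying tandem family blocks of planted SEDC genes
#' between two S100A-like anchor intervals, plus optional decoy ORFs,
#' pseudogenized copies (premature stop or frameshift), assembly gaps
#' truncating a gene, and translocated family copies placed outside the
#' anchors next to a named non-EDC anchor. After assembly the scaffold is
#' re-scanned with the default gene finder and any accidental qualifying
#' structure in background sequence is disrupted, so that the planted genes
#' are the only true signals.
#'
#' @param config Simulation configuration, see \code{\link{defaultSimConfig}}.
#' @param seed Integer master seed; all randomness derives from it.
#' @param verify Logical; re-scan and clean the scaffold (default TRUE).
#' @return A \code{\linkS4class{TruthSet}}.
#' @export
buildTruthSet <- function(config = defaultSimConfig(), seed = 42L,
                          verify = TRUE) {
  ## rare draws place signals so entangled that the post-assembly cleanup
  ## cannot resolve them; such draws are rejected and rebuilt from a
  ## re-derived seed (deterministic given `seed`)
  last <- NULL
  for (attempt in 0:4) {
    eff <- if (attempt == 0L) as.integer(seed) else
      deriveSeed(seed, paste0("rebuild", attempt))
    out <- tryCatch(.buildTruthSetOnce(config, eff, seed, verify),
                    error = function(e) e)
    if (!inherits(out, "error")) return(out)
    last <- out
  }
  stop(conditionMessage(last))
}

.buildTruthSetOnce <- function(config, eff_seed, record_seed, verify) {
  seed <- eff_seed
  cfg <- mergeConfig(defaultSimConfig(), config)
  if (!length(cfg$families) || !all(vapply(cfg$families, function(f) f$n, 1L) >= 1L))
    stop("config must name at least one family with at least one member")
  set.seed(deriveSeed(seed, "layout"))

  pieces <- character(0)    # scaffold chunks in order
  pos <- 0L                 # running length
  rows <- list()
  anchors <- list()
  decoys <- list()
  counter <- 0L

  addPiece <- function(s) {
    pieces[[length(pieces) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  addBg <- function(n) addPiece(.bgFill(n))
  addAnchor <- function(name) {
    anchors[[name]] <<- c(pos + 1L, pos + cfg$anchor_len)
    addPiece(.bgFill(cfg$anchor_len))
  }
  rint <- function(rg) if (rg[1] == rg[2]) rg[1] else sample(rg[1]:rg[2], 1L)

  ## family members descend from a common ancestor protein (tandem
  ## duplicates), diverged by point substitutions
  ancestors <- list()
  mkGene <- function(fam, status = "complete", mutations = "",
                     gap_len = 0L) {
    counter <<- counter + 1L
    gseed <- deriveSeed(seed, paste0("gene", counter))
    set.seed(gseed)
    if (is.null(ancestors[[fam$name]])) {
      plen <- rint(cfg$protein_len)
      ancestors[[fam$name]] <<- sampleProtein(
        compositionSpec(fam$class), plen,
        seed = deriveSeed(seed, paste0("anc", fam$name)))
    }
    prot <- .mutateProtein(ancestors[[fam$name]], cfg$within_family_divergence,
                           seed = deriveSeed(gseed, "prot"))
    substr(prot, 1L, 1L) <- "M"        # translation initiator
    cds <- reverseTranslate(prot, seed = deriveSeed(gseed, "rt"))
    cds <- substr(cds, 1L, nchar(cds) - 3L)  # plantGene adds the stop
    set.seed(deriveSeed(gseed, "params"))
    pg <- plantGene(cds, rint(cfg$utr5_len), rint(cfg$tata_to_donor),
                    rint(cfg$intron_len), seed = deriveSeed(gseed, "fill"))
    frag <- pg$fragment; off <- pg$offsets
    if (status == "pseudogene") {
      ## inactivate within the CDS (codon coordinates exclude ATG? no:
      ## codon 1 = ATG); pick an interior codon
      n_codon <- (off$cds[2] - off$cds[1] + 1L) %/% 3L - 1L  # sans stop
      ## strike early so no residual ORF reaches the minimum protein length
      codon <- sample(10:max(11L, min(45L, n_codon - 5L)), 1L)
      cpos <- off$cds[1] + (codon - 1L) * 3L
      if (mutations == "premature_stop") {
        substr(frag, cpos, cpos + 2L) <- "TAA"
        mutations <- paste0("premature_stop@", codon)
      } else {
        frag <- paste0(substr(frag, 1L, cpos - 1L), substr(frag, cpos + 1L, nchar(frag)))
        off$cds[2] <- off$cds[2] - 1L
        mutations <- paste0("frameshift@", codon)
      }
    }
    if (gap_len > 0L) {
      ## truncate the CDS while keeping the surviving 5' piece above the
      ## minimum ORF length, so the scanner can still report a partial model
      w <- off$cds[2] - off$cds[1] + 1L
      cut <- off$cds[1] + min(w - 20L, max(158L, w %/% 2L))
      substr(frag, cut, min(nchar(frag), cut + gap_len - 1L)) <-
        paste(rep("N", min(gap_len, nchar(frag) - cut + 1L)), collapse = "")
      status <- "partial"
    }
    strand <- sample(c("+", "-"), 1L)
    id <- sprintf("%s_%02d", fam$name, sum(vapply(rows, function(r)
      r$family == fam$name, logical(1))) + 1L)
    rec <- .geneRecord(id, cfg$scaffold_id, strand, frag, off, fam$name,
                       status, mutations, pos)
    addPiece(rec$seq)
    rows[[length(rows) + 1L]] <<- rec$row
  }

  ## --- layout ---------------------------------------------------------------
  addBg(cfg$pad)
  addAnchor("S100A12-like")

  pseudo_by_fam <- vapply(cfg$pseudogenes, function(p) p$family, character(1))
  pseudo_types <- vapply(cfg$pseudogenes, function(p) p$type, character(1))
  gap_by_fam <- vapply(cfg$gaps, function(g) g$family, character(1))

  for (fam in cfg$families) {
    for (k in seq_len(fam$n)) {
      addBg(rint(cfg$intergenic))
      status <- "complete"; mut <- ""; gap_len <- 0L
      if (k == 1L && fam$name %in% pseudo_by_fam) {
        status <- "pseudogene"
        mut <- pseudo_types[match(fam$name, pseudo_by_fam)]
      } else if (k == fam$n && fam$name %in% gap_by_fam) {
        gap_len <- cfg$gaps[[match(fam$name, gap_by_fam)]]$len
      }
      mkGene(fam, status = status, mutations = mut, gap_len = gap_len)
    }
  }
  addBg(rint(cfg$intergenic))

  ## decoy ORFs: a bare ORF with a pyrimidine-only pad upstream, so no
  ## acceptor AG can qualify and no TATA box precedes it
  for (d in seq_len(cfg$n_decoys)) {
    addBg(rint(cfg$intergenic))
    dseed <- deriveSeed(seed, paste0("decoy", d))
    set.seed(dseed)
    plen <- rint(c(55L, 90L))
    dprot <- sampleProtein(compositionSpec("unbiased"), plen,
                           seed = deriveSeed(dseed, "p"))
    substr(dprot, 1L, 1L) <- "M"
    dcds <- reverseTranslate(dprot, seed = deriveSeed(dseed, "rt"))
    pad <- paste(sample(c("C", "T"), 34L, replace = TRUE), collapse = "")
    decoys[[length(decoys) + 1L]] <-
      c(pos + 34L + 1L, pos + 34L + nchar(dcds))
    addPiece(paste0(pad, dcds))
  }
  addBg(rint(cfg$intergenic))
  addAnchor("S100A11-like")

  ## translocated copies beyond the EDC, next to a non-EDC anchor
  events <- data.frame(family = character(0), source_locus = character(0),
                       destination_locus = character(0))
  for (tr in cfg$translocations) {
    addBg(1500L)
    addAnchor(tr$anchor)
    famdef <- list(name = tr$family, class = tr$class, n = tr$n)
    for (k in seq_len(tr$n)) {
      addBg(rint(cfg$intergenic))
      mkGene(famdef)
    }
    events <- rbind(events, data.frame(
      family = tr$family, source_locus = "EDC",
      destination_locus = paste0(tr$anchor, "_locus")))
  }
  addBg(cfg$pad)

  scaffold <- paste(pieces, collapse = "")
  truth_df <- do.call(rbind, rows)

  ts <- .assembleTruthSet(scaffold, cfg$scaffold_id, truth_df, anchors,
                          decoys, events, record_seed)
  if (verify) ts <- .scrubSpuriousSignals(ts)
  ts
}

.assembleTruthSet <- function(scaffold, scaffold_id, truth_df, anchors,
                              decoys, events, seed) {
  sc <- Biostrings::DNAStringSet(setNames(scaffold, scaffold_id))
  gr <- GenomicRanges::GRanges(
    seqnames = truth_df$scaffold,
    ranges = IRanges::IRanges(truth_df$cds_start, truth_df$cds_end),
    strand = truth_df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = truth_df$gene_id, status = truth_df$status,
    evidence = "planted", family = truth_df$family,
    protein = truth_df$protein, score = NA_real_,
    utr5_start = as.integer(truth_df$utr5_start),
    utr5_end = as.integer(truth_df$utr5_end),
    exon1_start = as.integer(truth_df$exon1_start),
    exon1_end = as.integer(truth_df$exon1_end),
    intron_start = as.integer(truth_df$intron_start),
    intron_end = as.integer(truth_df$intron_end),
    mutations = truth_df$mutations)
  agr <- GenomicRanges::GRanges(
    seqnames = rep(scaffold_id, length(anchors)),
    ranges = IRanges::IRanges(
      vapply(anchors, `[`, 1L, 1),
      vapply(anchors, `[`, 1L, 2)))
  S4Vectors::mcols(agr)$name <- names(anchors)
  dgr <- if (length(decoys)) GenomicRanges::GRanges(
    seqnames = rep(scaffold_id, length(decoys)),
    ranges = IRanges::IRanges(vapply(decoys, `[`, 1L, 1),
                              vapply(decoys, `[`, 1L, 2)))
  else GenomicRanges::GRanges()
  new("TruthSet", scaffolds = sc, genes = GeneModelSet(gr), anchors = agr,
      decoys = dgr, events = events, seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Post-assembly cleanup: re-scan the simulated scaffold and disrupt every
## qualifying SEDC gene structure that is not a planted gene, and every
## usurping signal that would shift a planted gene's predicted exon 1 / UTR.
## Edits are single bases in background/filler sequence, or synonymous codon
## substitutions inside planted CDS (silent for the planted protein but
## destructive for the overlapping spurious signal or reading frame).
## ---------------------------------------------------------------------------

## codon interval of planted gene row ti covering codon index k (1-based,
## stop codon included)
.codonSpan <- function(cs, ce, minus, k) {
  if (minus) c(ce - 3L * k + 1L, ce - 3L * (k - 1L)) else
    c(cs + 3L * (k - 1L), cs + 3L * k - 1L)
}
## Local re-scan: the gene model (if any) that the scanner would produce at
## CDS (cs, ce, strand) given the current scaffold string. Only a window
## around the locus is scanned, which is sufficient because every gene
## signal lies within exon1_search_window of the CDS.
## Lightweight local re-scan (no S4 containers): complete SEDC models in
## the window [w1, w2], with intervals in scaffold coordinates.
.liteModels <- function(seqstr, w1, w2, params) {
  sub <- substr(seqstr, w1, w2)
  L <- nchar(sub)
  rcsub <- revComp(sub)
  out <- list()
  for (strand in c("+", "-")) {
    oseq <- if (strand == "+") sub else rcsub
    for (f in 0:2) {
      if (nchar(oseq) - f < 3L) next
      chars <- strsplit(translateDNA(substring(oseq, f + 1L)), "")[[1]]
      df <- .parseFrame(chars, f, params$min_protein_len,
                        params$max_protein_len)
      if (is.null(df) || !nrow(df)) next
      df <- df[df$truncated == "", , drop = FALSE]
      for (i in seq_len(nrow(df))) {
        acc <- .acceptorOriented(oseq, df$o_start[i], params)
        if (!acc$ok) next
        e1 <- .exon1Oriented(oseq, acc$acceptor[1], params)
        if (params$require_exon1 && !e1$found) next
        refl <- function(iv) if (strand == "+") iv else
          reflectInterval(iv[1], iv[2], L)
        cds <- refl(c(df$o_start[i], df$o_end[i]))
        utr <- refl(acc$utr)
        ex1 <- if (e1$found) refl(e1$exon1) else c(NA_integer_, NA_integer_)
        intr <- if (e1$found) refl(c(e1$donor, acc$acceptor[2])) else
          c(NA_integer_, NA_integer_)
        out[[length(out) + 1L]] <- data.frame(
          start = cds[1] + w1 - 1L, end = cds[2] + w1 - 1L, strand = strand,
          u1 = utr[1] + w1 - 1L, u2 = utr[2] + w1 - 1L,
          e1a = ex1[1] + w1 - 1L, e1b = ex1[2] + w1 - 1L,
          i1 = intr[1] + w1 - 1L, i2 = intr[2] + w1 - 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), u1 = integer(0), u2 = integer(0),
                      e1a = integer(0), e1b = integer(0), i1 = integer(0),
                      i2 = integer(0)))
  do.call(rbind, out)
}

.localWindow <- function(seqstr, cs, ce, params) {
  c(max(1L, cs - params$exon1_search_window - 200L),
    min(nchar(seqstr), ce + params$exon1_search_window + 200L))
}

## The structure the scanner assigns to the exact CDS (cs, ce, strand).
.localModel <- function(seqstr, cs, ce, strandchr, params) {
  w <- .localWindow(seqstr, cs, ce, params)
  ms <- .liteModels(seqstr, w[1], w[2], params)
  hit <- which(ms$start == cs & ms$end == ce & ms$strand == strandchr)
  if (!length(hit)) return(NULL)
  m <- ms[hit[1], ]
  list(utr5 = c(m$u1, m$u2), exon1 = c(m$e1a, m$e1b), intron = c(m$i1, m$i2))
}

## Keys of non-planted (and non-merge-dominated) models overlapping the
## locus window after an edit; used to demand strict progress.
.offendingModels <- function(seqstr, cs, ce, params, truth_df) {
  w <- .localWindow(seqstr, cs, ce, params)
  ms <- .liteModels(seqstr, w[1], w[2], params)
  if (!nrow(ms)) return(character(0))
  ovl <- ms$end >= cs - 200L & ms$start <= ce + 200L
  planted_ok <- paste(ms$start, ms$end, ms$strand) %in%
    paste(truth_df$cs, truth_df$ce, truth_df$strand)
  bad <- which(ovl & !planted_ok)
  keep <- logical(length(bad))
  for (j in seq_along(bad)) {
    i <- bad[j]
    mlen <- ms$end[i] - ms$start[i]
    ## dominated candidates lose the overlap merge to a longer planted model
    dominated <- any(truth_df$strand == ms$strand[i] &
                     truth_df$ce >= ms$start[i] & truth_df$cs <= ms$end[i] &
                     (truth_df$ce - truth_df$cs > mlen |
                      (truth_df$ce - truth_df$cs == mlen &
                       truth_df$cs <= ms$start[i])))
    keep[j] <- !dominated
  }
  bad <- bad[keep]
  paste(ms$start[bad], ms$end[bad], ms$strand[bad])
}

## Candidate single-base and synonymous-codon edits around the signal at
## sig_iv; the first edit for which accept(seqstr2) is TRUE is returned.
.editSignal <- function(seqstr, sig_iv, protected, cdsinfo, accept,
                        tried = new.env(parent = emptyenv())) {
  scid <- as.character(GenomicRanges::seqnames(protected))[1]
  scid_gr <- function(a, b) GenomicRanges::GRanges(scid, IRanges::IRanges(a, b))
  mark <- function(kk) { tried[[kk]] <- TRUE; TRUE }
  for (p in sig_iv[1]:sig_iv[2]) {
    if (!IRanges::overlapsAny(scid_gr(p, p), protected)) {
      base <- substr(seqstr, p, p)
      for (repl in setdiff(c("C", "G", "A", "T"), base)) {
        kk <- paste0(p, ":", repl)
        if (!is.null(tried[[kk]])) next
        s2 <- seqstr
        substr(s2, p, p) <- repl
        win <- substr(s2, max(1L, p - 6L), min(nchar(s2), p + 6L))
        if (!grepl("TATA[AT]A", win) && accept(s2) && mark(kk)) return(s2)
      }
    }
  }
  ## synonymous codon substitutions in a planted CDS covering the signal
  for (ti in seq_len(nrow(cdsinfo))) {
    ci <- cdsinfo[ti, ]
    if (sig_iv[2] < ci$cs || sig_iv[1] > ci$ce) next
    for (p in sig_iv[1]:sig_iv[2]) {
      if (p < ci$cs || p > ci$ce) next
      k <- if (ci$minus) (ci$ce - p) %/% 3L + 1L else (p - ci$cs) %/% 3L + 1L
      sp <- .codonSpan(ci$cs, ci$ce, ci$minus, k)
      cod_fwd <- substr(seqstr, sp[1], sp[2])
      cod <- if (ci$minus) revComp(cod_fwd) else cod_fwd
      aa <- Biostrings::GENETIC_CODE[[cod]]
      alts <- if (is.null(aa) || aa == "*") setdiff(.stopCodons, cod) else
        setdiff(.codonTable[[aa]], cod)
      for (alt in alts) {
        kk <- paste0(sp[1], ":", alt)
        if (!is.null(tried[[kk]])) next
        alt_fwd <- if (ci$minus) revComp(alt) else alt
        s2 <- seqstr
        substr(s2, sp[1], sp[2]) <- alt_fwd
        win <- substr(s2, max(1L, sp[1] - 6L), min(nchar(s2), sp[2] + 6L))
        if (!grepl("TATA[AT]A", win) && accept(s2) && mark(kk)) return(s2)
      }
    }
  }
  NULL
}

## Break the reading frame of a spurious ORF (forward cs..ce) by a direct
## stop-codon write in unprotected sequence or a synonymous planted-codon
## change; the first edit for which accept(seqstr2) is TRUE is returned.
.editOrf <- function(seqstr, cs, ce, minus_orf, protected, cdsinfo, accept,
                     tried = new.env(parent = emptyenv()), max_codon = 60L) {
  scid <- as.character(GenomicRanges::seqnames(protected))[1]
  gr1 <- function(a, b) GenomicRanges::GRanges(scid, IRanges::IRanges(a, b))
  mark <- function(kk) { tried[[kk]] <- TRUE; TRUE }
  n_codon <- (ce - cs + 1L) %/% 3L
  ks <- seq(2L, min(max_codon, n_codon - 1L))
  stopc_fwd <- if (minus_orf) "TTA" else "TAA"
  for (k in ks) {
    sp <- .codonSpan(cs, ce, minus_orf, k)
    if (substr(seqstr, sp[1], sp[2]) == stopc_fwd) next
    if (!IRanges::overlapsAny(gr1(sp[1], sp[2]), protected)) {
      kk <- paste0(sp[1], ":", stopc_fwd)
      if (!is.null(tried[[kk]])) next
      s2 <- seqstr
      substr(s2, sp[1], sp[2]) <- stopc_fwd
      if (accept(s2) && mark(kk)) return(s2)
    }
  }
  for (ti in seq_len(nrow(cdsinfo))) {
    ci <- cdsinfo[ti, ]
    if (ce < ci$cs || cs > ci$ce) next
    for (k in c(1L, ks)) {
      sp <- .codonSpan(cs, ce, minus_orf, k)
      if (sp[2] < ci$cs || sp[1] > ci$ce) next
      pks <- unique(c(
        if (ci$minus) (ci$ce - sp[2]) %/% 3L + 1L else (sp[1] - ci$cs) %/% 3L + 1L,
        if (ci$minus) (ci$ce - sp[1]) %/% 3L + 1L else (sp[2] - ci$cs) %/% 3L + 1L))
      pks <- pks[pks >= 1L & pks <= (ci$ce - ci$cs + 1L) %/% 3L]
      for (pk in pks) {
        psp <- .codonSpan(ci$cs, ci$ce, ci$minus, pk)
        cod_fwd <- substr(seqstr, psp[1], psp[2])
        cod <- if (ci$minus) revComp(cod_fwd) else cod_fwd
        aa <- Biostrings::GENETIC_CODE[[cod]]
        alts <- if (is.null(aa) || aa == "*") setdiff(.stopCodons, cod) else
          setdiff(.codonTable[[aa]], cod)
        for (alt in alts) {
          kk <- paste0(psp[1], ":", alt)
          if (!is.null(tried[[kk]])) next
          alt_fwd <- if (ci$minus) revComp(alt) else alt
          s2 <- seqstr
          substr(s2, psp[1], psp[2]) <- alt_fwd
          win <- substr(s2, max(1L, psp[1] - 6L), min(nchar(s2), psp[2] + 6L))
          if (!grepl("TATA[AT]A", win) && accept(s2) && mark(kk)) return(s2)
        }
      }
    }
  }
  NULL
}

.scrubSpuriousSignals <- function(ts, max_rounds = 40L) {
  params <- scanParams()
  truth <- geneModels(ts@genes)
  tm <- S4Vectors::mcols(truth)
  sq <- as.character(GenomicRanges::seqnames(truth))
  minus <- as.character(GenomicRanges::strand(truth)) == "-"
  mkiv <- function(s, e) GenomicRanges::GRanges(sq, IRanges::IRanges(
    pmax(1L, pmin(s, e)), pmax(s, e)))
  ## protect the planted signal-bearing bases: CDS, 5' UTR, TATA box,
  ## donor/acceptor and the intron stop block
  protected <- GenomicRanges::reduce(c(
    GenomicRanges::granges(truth),
    mkiv(tm$utr5_start, tm$utr5_end),
    mkiv(ifelse(minus, tm$exon1_end, tm$exon1_start),
         ifelse(minus, tm$exon1_end - 5L, tm$exon1_start + 5L)),
    mkiv(ifelse(minus, tm$intron_end, tm$intron_start),
         ifelse(minus, tm$intron_end - 1L, tm$intron_start + 1L)),
    mkiv(ifelse(minus, tm$intron_start, tm$intron_end),
         ifelse(minus, tm$intron_start + 13L, tm$intron_end - 13L))))
  cdsinfo <- data.frame(cs = GenomicRanges::start(truth),
                        ce = GenomicRanges::end(truth),
                        minus = minus,
                        complete = tm$status == "complete")
  truth_df <- data.frame(cs = cdsinfo$cs, ce = cdsinfo$ce,
                         strand = as.character(GenomicRanges::strand(truth)))
  truth_df <- truth_df[cdsinfo$complete, , drop = FALSE]
  cdsinfo <- cdsinfo[cdsinfo$complete, , drop = FALSE]

  key <- function(g) paste(GenomicRanges::seqnames(g), GenomicRanges::start(g),
                           GenomicRanges::end(g), GenomicRanges::strand(g))
  fullkey <- function(g) paste(key(g), S4Vectors::mcols(g)$utr5_start,
                               S4Vectors::mcols(g)$exon1_start,
                               S4Vectors::mcols(g)$intron_start)
  complete <- truth[tm$status == "complete"]
  broken <- truth[tm$status != "complete"]
  tried <- new.env(parent = emptyenv())   # never repeat an identical edit

  for (round in seq_len(max_rounds)) {
    pg <- geneModels(scanScaffolds(ts@scaffolds, params = params))
    mis <- pg[key(pg) %in% key(complete) & !fullkey(pg) %in% fullkey(complete)]
    spurious <- pg[!key(pg) %in% key(complete)]
    if (length(spurious) && length(broken))
      spurious <- spurious[!IRanges::overlapsAny(spurious, broken,
                                                 ignore.strand = TRUE)]
    if (!length(spurious) && !length(mis)) return(ts)
    if (isTRUE(getOption("EDCtools.scrub.verbose")))
      message("scrub round ", round, ": ", length(mis), " usurped, ",
              length(spurious), " spurious")
    progress <- FALSE

    handle <- function(g, want_structure) {
      mc <- S4Vectors::mcols(g)
      scid <- as.character(GenomicRanges::seqnames(g))
      seqstr <- as.character(ts@scaffolds[[scid]])
      gm <- as.character(GenomicRanges::strand(g)) == "-"
      cs <- GenomicRanges::start(g); ce <- GenomicRanges::end(g)
      strandchr <- as.character(GenomicRanges::strand(g))
      before <- .offendingModels(seqstr, cs, ce, params, truth_df)
      tkey <- paste(cs, ce, strandchr)
      mkAccept <- function(strict) function(s2) {
        after <- .offendingModels(s2, cs, ce, params, truth_df)
        if (strict && !all(after %in% before)) return(FALSE) # no new structures
        if (is.null(want_structure)) return(!(tkey %in% after))
        if (!all(after %in% before)) return(FALSE)
        m <- .localModel(s2, cs, ce, strandchr, params)
        !is.null(m) && identical(m$utr5, want_structure$utr5) &&
          identical(m$exon1, want_structure$exon1) &&
          identical(m$intron, want_structure$intron)
      }
      accept <- mkAccept(TRUE)
      sigs <- list()
      if (!is.na(mc$utr5_start))
        sigs$acceptor <- if (gm) c(mc$utr5_end + 1L, mc$utr5_end + 2L) else
          c(mc$utr5_start - 2L, mc$utr5_start - 1L)
      if (is.null(want_structure))
        sigs$atg <- if (gm) c(ce - 2L, ce) else c(cs, cs + 2L)
      if (!is.na(mc$exon1_start))
        sigs$tata <- if (gm) c(mc$exon1_end - 5L, mc$exon1_end) else
          c(mc$exon1_start, mc$exon1_start + 5L)
      if (!is.na(mc$intron_start))
        sigs$donor <- if (gm) c(mc$intron_end - 1L, mc$intron_end) else
          c(mc$intron_start, mc$intron_start + 1L)
      tiers <- if (is.null(want_structure)) list(mkAccept(TRUE), mkAccept(FALSE))
               else list(mkAccept(TRUE))
      for (acc in tiers) {
        for (sg in sigs) {
          if (any(is.na(sg))) next
          s2 <- .editSignal(seqstr, sg, protected, cdsinfo, acc, tried)
          if (!is.null(s2)) {
            ts@scaffolds[[scid]] <<- Biostrings::DNAString(s2)
            return(TRUE)
          }
        }
        if (is.null(want_structure)) {
          s2 <- .editOrf(seqstr, cs, ce, gm, protected, cdsinfo, acc, tried)
          if (!is.null(s2)) {
            ts@scaffolds[[scid]] <<- Biostrings::DNAString(s2)
            return(TRUE)
          }
        }
      }
      FALSE
    }

    vb <- isTRUE(getOption("EDCtools.scrub.verbose"))
    for (i in seq_len(length(mis))) {
      g <- mis[i]
      ti <- match(key(g), key(complete))
      tmc <- S4Vectors::mcols(complete)[ti, ]
      want <- list(utr5 = c(tmc$utr5_start, tmc$utr5_end),
                   exon1 = c(tmc$exon1_start, tmc$exon1_end),
                   intron = c(tmc$intron_start, tmc$intron_end))
      ok <- handle(g, want)
      if (vb) message("  usurped ", key(g), if (ok) " fixed" else " UNFIXED")
      if (ok) progress <- TRUE
    }
    for (i in seq_len(length(spurious))) {
      ok <- handle(spurious[i], NULL)
      if (vb) message("  spurious ", key(spurious[i]),
                      if (ok) " fixed" else " UNFIXED")
      if (ok) progress <- TRUE
    }

    if (!progress)
      stop("cannot disrupt a spurious gene structure nested in planted ",
           "features; try a different seed")
  }
  stop("spurious gene structures persisted after ", max_rounds,
       " scrub rounds")
}
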