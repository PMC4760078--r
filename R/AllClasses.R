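#' @import methods
NULL

setOldClass("phylo")

#' Set of SEDC gene models
#'
#' Container for two-exon SEDC-type gene models on one or more genomic
#' scaffolds. The coding interval (CDS, stop codon included) of each model is
#' held as a \link[GenomicRanges]{GRanges}; the noncoding exon 1, intron and
#' 5' UTR intervals, the translated protein, the model status
#' (\code{complete}, \code{partial} or \code{pseudogene}), the evidence trail
#' and the family label are metadata columns. All coordinates are 1-based
#' inclusive on the forward strand of the scaffold.
#'
#' @slot models A \code{GRanges} of CDS intervals with metadata columns
#'   \code{gene_id}, \code{status}, \code{evidence}, \code{family},
#'   \code{protein}, \code{score}, \code{utr5_start}, \code{utr5_end},
#'   \code{exon1_start}, \code{exon1_end}, \code{intron_start},
#'   \code{intron_end}, \code{mutations}.
#' @export
setClass("GeneModelSet", representation(models = "GRanges"))

.GMS_COLS <- c("gene_id", "status", "evidence", "family", "protein", "score",
               "utr5_start", "utr5_end", "exon1_start", "exon1_end",
               "intron_start", "intron_end", "mutations")

setValidity("GeneModelSet", function(object) {
  mc <- S4Vectors::mcols(object@models)
  miss <- setdiff(.GMS_COLS, colnames(mc))
  if (length(miss))
    return(paste("missing metadata columns:", paste(miss, collapse = ", ")))
  bad <- mc$status == "complete" &
    (GenomicRanges::width(object@models) %% 3L != 0L)
  if (any(bad))
    return("complete models must have CDS width divisible by 3")
  if (anyDuplicated(mc$gene_id))
    return("gene_id values must be unique")
  TRUE
})

#' Construct a GeneModelSet
#'
#' @param models GRanges of CDS intervals carrying the model metadata
#'   columns (missing columns are filled with defaults).
#' @return A \code{GeneModelSet}.
#' @export
GeneModelSet <- function(models = GenomicRanges::GRanges()) {
  mc <- S4Vectors::mcols(models)
  n <- length(models)
  defaults <- list(gene_id = if (n) sprintf("gene%03d", seq_len(n)) else character(0),
                   status = rep("complete", n), evidence = rep("", n),
                   family = rep(NA_character_, n), protein = rep(NA_character_, n),
                   score = rep(NA_real_, n),
                   utr5_start = rep(NA_integer_, n), utr5_end = rep(NA_integer_, n),
                   exon1_start = rep(NA_integer_, n), exon1_end = rep(NA_integer_, n),
                   intron_start = rep(NA_integer_, n), intron_end = rep(NA_integer_, n),
                   mutations = rep("", n))
  for (nm in names(defaults))
    if (!nm %in% colnames(mc)) mc[[nm]] <- defaults[[nm]]
  S4Vectors::mcols(models) <- mc
  new("GeneModelSet", models = models)
}

#' @describeIn GeneModelSet Number of gene models.
#' @param x A \code{GeneModelSet}.
#' @export
setMethod("length", "GeneModelSet", function(x) length(x@models))

#' Extract the CDS ranges of a model set
#' @param x A \code{GeneModelSet}.
#' @return A \code{GRanges}.
#' @export
geneModels <- function(x) x@models

#' Translated proteins of a model set
#' @param x A \code{GeneModelSet}.
#' @return An \code{AAStringSet} named by gene id.
#' @export
modelProteins <- function(x) {
  p <- S4Vectors::mcols(x@models)$protein
  p[is.na(p)] <- ""
  aa <- Biostrings::AAStringSet(p)
  names(aa) <- S4Vectors::mcols(x@models)$gene_id
  aa
}

#' Model status accessor
#' @param x A \code{GeneModelSet}.
#' @return Character vector of statuses named by gene id.
#' @export
modelStatus <- function(x)
  setNames(S4Vectors::mcols(x@models)$status, S4Vectors::mcols(x@models)$gene_id)

#' Family label accessor
#' @param x A \code{GeneModelSet}.
#' @return Character vector of family labels named by gene id.
#' @export
familyLabels <- function(x)
  setNames(S4Vectors::mcols(x@models)$family, S4Vectors::mcols(x@models)$gene_id)

setMethod("show", "GeneModelSet", function(object) {
  st <- table(S4Vectors::mcols(object@models)$status)
  cat("GeneModelSet with", length(object@models), "gene models on",
      length(unique(as.character(GenomicRanges::seqnames(object@models)))),
      "scaffold(s)\n")
  if (length(st))
    cat("  status:", paste(names(st), as.integer(st), sep = "=", collapse = ", "), "\n")
})

#' Synthetic-genome ground truth
#'
#' The output of \code{\link{buildTruthSet}}: simulated scaffolds together
#' with the planted gene models, anchor-gene intervals, decoy ORFs and
#' translocation events, all in scaffold coordinates.
#'
#' @slot scaffolds \code{DNAStringSet} of simulated scaffolds.
#' @slot genes \code{GeneModelSet} of planted genes (ground truth).
#' @slot anchors \code{GRanges} of named anchor-gene intervals.
#' @slot decoys \code{GRanges} of planted decoy ORFs.
#' @slot events \code{data.frame} of translocation events
#'   (family, source_locus, destination_locus).
#' @slot seed Integer master seed used for the simulation.
#' @export
setClass("TruthSet", representation(
  scaffolds = "DNAStringSet", genes = "GeneModelSet", anchors = "GRanges",
  decoys = "GRanges", events = "data.frame", seed = "integer"))

setValidity("TruthSet", function(object) {
  g <- geneModels(object@genes)
  if (length(g)) {
    sc <- as.character(GenomicRanges::seqnames(g))
    if (!all(sc %in% names(object@scaffolds)))
      return("gene models reference unknown scaffolds")
    lens <- Biostrings::width(object@scaffolds)[match(sc, names(object@scaffolds))]
    if (any(GenomicRanges::end(g) > lens) || any(GenomicRanges::start(g) < 1L))
      return("gene model outside its scaffold")
  }
  TRUE
})

#' @describeIn TruthSet Scaffold sequences.
#' @param x A \code{TruthSet}.
#' @export
truthScaffolds <- function(x) x@scaffolds

#' @describeIn TruthSet Planted gene models.
#' @export
truthGenes <- function(x) x@genes

#' @describeIn TruthSet Anchor-gene intervals.
#' @export
truthAnchors <- function(x) x@anchors

#' @describeIn TruthSet Translocation events.
#' @export
truthEvents <- function(x) x@events

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet:", length(object@scaffolds), "scaffold(s),",
      length(object@genes), "planted genes,",
      nrow(object@events), "translocation event(s), seed", object@seed, "\n")
})

#' Ordered gene map of an annotated locus
#'
#' Genes of one scaffold ordered by CDS start, with named anchor intervals
#' and, when both S100A anchors are present, the EDC interval they delimit.
#'
#' @slot scaffold_id Scaffold name.
#' @slot genes \code{data.frame}: gene_id, family, start, end, strand,
#'   rank (0-based), inside ("inside"/"outside"/"unanchored").
#' @slot anchors \code{data.frame}: name, start, end.
#' @slot edc Numeric of length 2 (EDC interval) or length 0 when the map is
#'   unanchored.
#' @export
setClass("LocusMap", representation(
  scaffold_id = "character", genes = "data.frame",
  anchors = "data.frame", edc = "numeric"))

setValidity("LocusMap", function(object) {
  g <- object@genes
  if (nrow(g) && !identical(sort(g$rank), 0:(nrow(g) - 1L)))
    return("ranks must be a permutation of 0..n-1")
  if (!length(object@edc) %in% c(0L, 2L))
    return("edc must have length 0 or 2")
  TRUE
})

setMethod("show", "LocusMap", function(object) {
  cat("LocusMap of", object@scaffold_id, "-", nrow(object@genes), "genes,",
      nrow(object@anchors), "anchors;",
      if (length(object@edc)) sprintf("EDC interval %d-%d",
                                      as.integer(object@edc[1]),
                                      as.integer(object@edc[2]))
      else "unanchored", "\n")
})

#' Synteny comparison of two locus maps
#'
#' @slot links \code{data.frame} of gene-to-gene links (idA, idB, rankA,
#'   rankB, family, identity, type).
#' @slot blocks List of integer vectors: indices into \code{links} forming
#'   collinear blocks.
#' @slot rearranged Integer vector of link indices outside every block.
#' @slot translocations \code{data.frame} (family, gene_id, map, nearest_anchor,
#'   kind).
#' @slot familyCounts \code{data.frame} of per-map family counts.
#' @export
setClass("SyntenyReport", representation(
  links = "data.frame", blocks = "list", rearranged = "integer",
  translocations = "data.frame", familyCounts = "data.frame"))

setMethod("show", "SyntenyReport", function(object) {
  cat("SyntenyReport:", nrow(object@links), "links,",
      length(object@blocks), "collinear block(s),",
      length(object@rearranged), "rearranged link(s),",
      nrow(object@translocations), "translocation record(s)\n")
})

#' Phylogenetic tree with bootstrap support
#'
#' An unrooted tree (\code{ape::phylo}) whose internal branches carry
#' bootstrap support percentages in [0, 100].
#'
#' @slot tree An \code{ape} \code{phylo} object.
#' @slot support Numeric vector of support values, one per internal node
#'   (NA on the root pseudo-node and when no bootstrap was run).
#' @slot nboot Number of bootstrap replicates used (0 = none).
#' @export
setClass("SupportTree", representation(
  tree = "phylo", support = "numeric", nboot = "integer"))

setValidity("SupportTree", function(object) {
  sup <- object@support[!is.na(object@support)]
  if (length(sup) && (any(sup < 0) || any(sup > 100)))
    return("support values must lie in [0, 100]")
  TRUE
})

#' @describeIn SupportTree Underlying \code{phylo} tree.
#' @param x A \code{SupportTree}.
#' @export
supportTree <- function(x) x@tree

#' @describeIn SupportTree Per-internal-node support values.
#' @export
supportValues <- function(x) x@support

setMethod("show", "SupportTree", function(object) {
  cat("SupportTree:", length(object@tree$tip.label), "taxa;",
      if (object@nboot > 0) paste0(object@nboot, " bootstrap replicates")
      else "no bootstrap", "\n")
})

#' Per-protein feature profiles
#'
#' Amino-acid composition, combined bias metrics, tandem-repeat calls,
#' beta-sheet core hits and the resulting family class label for a set of
#' proteins.
#'
#' @slot table \code{data.frame}: id, length, one column per amino acid
#'   (fractions), gs_combined, cp_combined, aromatic_combined, kq_combined,
#'   class_label.
#' @slot repeats Named list (by id) of repeat-call data.frames.
#' @slot betaCores Named list (by id) of beta-core hit data.frames.
#' @export
setClass("ProteinFeatureSet", representation(
  table = "data.frame", repeats = "list", betaCores = "list"))

setValidity("ProteinFeatureSet", function(object) {
  tb <- object@table
  if (nrow(tb)) {
    s <- rowSums(tb[, AA20, drop = FALSE])
    if (any(abs(s - 1) > 1e-9)) return("amino-acid fractions must sum to 1")
  }
  TRUE
})

#' @describeIn ProteinFeatureSet Feature table.
#' @param x A \code{ProteinFeatureSet}.
#' @export
featureTable <- function(x) x@table

setMethod("show", "ProteinFeatureSet", function(object) {
  cat("ProteinFeatureSet:", nrow(object@table), "proteins\n")
  if (nrow(object@table)) {
    cl <- table(object@table$class_label)
    cat("  classes:", paste(names(cl), as.integer(cl), sep = "=", collapse = ", "), "\n")
  }
})
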