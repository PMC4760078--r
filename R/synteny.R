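## ---------------------------------------------------------------------------
## Locus maps and synteny: gene order along a scaffold, EDC delimitation by
## the S100A anchor genes, ortholog linking between two maps, collinear
## block chaining and translocation detection.
## ---------------------------------------------------------------------------

#' Build an ordered locus map from gene models
#'
#' Orders the genes of one scaffold by CDS start, attaches named anchor
#' intervals, and, when both S100A anchors are present, computes the EDC
#' interval between them and labels every gene inside or outside it.
#'
#' @param models \code{\linkS4class{GeneModelSet}} restricted to one
#'   scaffold (or with a single scaffold).
#' @param anchors Named list/\code{data.frame} of anchor intervals
#'   (\code{name}, \code{start}, \code{end}) or a \code{GRanges} with a
#'   \code{name} column.
#' @param s100_names Names of the two S100A anchors delimiting the EDC.
#' @return A \code{\linkS4class{LocusMap}}.
#' @export
buildLocusMap <- function(models, anchors = NULL,
                          s100_names = c("S100A12-like", "S100A11-like")) {
  gr <- geneModels(models)
  scafs <- unique(as.character(GenomicRanges::seqnames(gr)))
  if (length(scafs) > 1L) stop("models must lie on a single scaffold")
  scaffold_id <- if (length(scafs)) scafs else "scaffold"
  mc <- S4Vectors::mcols(gr)
  g <- data.frame(gene_id = mc$gene_id, family = mc$family,
                  start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
                  strand = as.character(GenomicRanges::strand(gr)),
                  protein = mc$protein, status = mc$status,
                  stringsAsFactors = FALSE)
  g <- g[order(g$start, g$end), , drop = FALSE]
  g$rank <- seq_len(nrow(g)) - 1L

  adf <- data.frame(name = character(0), start = integer(0), end = integer(0))
  if (!is.null(anchors)) {
    if (is(anchors, "GRanges")) {
      adf <- data.frame(name = S4Vectors::mcols(anchors)$name,
                        start = GenomicRanges::start(anchors),
                        end = GenomicRanges::end(anchors),
                        stringsAsFactors = FALSE)
    } else adf <- as.data.frame(anchors, stringsAsFactors = FALSE)
  }
  edc <- numeric(0)
  if (all(s100_names %in% adf$name)) {
    a1 <- adf[adf$name == s100_names[1], ][1, ]
    a2 <- adf[adf$name == s100_names[2], ][1, ]
    edc <- c(min(a1$end, a2$end) + 1, max(a1$start, a2$start) - 1)
  }
  if (length(edc)) {
    inside <- g$start >= edc[1] & g$end <= edc[2]
    outside <- g$end < edc[1] | g$start > edc[2]
    strad <- !inside & !outside
    if (any(strad))
      stop("gene(s) straddle the EDC boundary: ",
           paste(g$gene_id[strad], collapse = ", "))
    g$inside <- ifelse(inside, "inside", "outside")
  } else {
    g$inside <- "unanchored"
  }
  new("LocusMap", scaffold_id = scaffold_id, genes = g, anchors = adf,
      edc = as.numeric(edc))
}

## Default protein similarity: global alignment identity (PID over aligned
## columns including internal gaps).
.protIdentity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = .getMatrix("BLOSUM62"),
    gapOpening = 11, gapExtension = 1)
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Link orthologous genes between two locus maps
#'
#' Computes pairwise protein identities within each shared family;
#' reciprocal-best-hit pairs at or above \code{min_identity} become
#' \code{ortholog} links, remaining same-family pairs are reported as
#' \code{family_only}. Ties are broken deterministically by identity, then
#' by the lower rank pair.
#'
#' @param mapA,mapB \code{\linkS4class{LocusMap}} objects whose gene tables
#'   carry proteins and family labels.
#' @param similarity Function (a, b) -> identity fraction; defaults to
#'   global alignment identity.
#' @param min_identity Minimum identity for an ortholog link.
#' @return Data frame of links: idA, idB, rankA, rankB, family, identity,
#'   type.
#' @export
linkOrthologs <- function(mapA, mapB, similarity = .protIdentity,
                          min_identity = 0.5) {
  gA <- mapA@genes; gB <- mapB@genes
  fams <- intersect(unique(gA$family), unique(gB$family))
  fams <- fams[!is.na(fams)]
  links <- list()
  for (fam in sort(fams)) {
    ia <- which(gA$family == fam); ib <- which(gB$family == fam)
    idm <- matrix(0, length(ia), length(ib))
    for (x in seq_along(ia)) for (y in seq_along(ib))
      idm[x, y] <- similarity(gA$protein[ia[x]], gB$protein[ib[y]])
    ## reciprocal best hits with deterministic tie-breaks (lower rank wins)
    bestA <- apply(idm, 1, function(r) which(r == max(r))[1])
    bestB <- apply(idm, 2, function(cl) which(cl == max(cl))[1])
    for (x in seq_along(ia)) {
      y <- bestA[x]
      type <- if (bestB[y] == x && idm[x, y] >= min_identity)
        "ortholog" else "family_only"
      links[[length(links) + 1L]] <- data.frame(
        idA = gA$gene_id[ia[x]], idB = gB$gene_id[ib[y]],
        rankA = gA$rank[ia[x]], rankB = gB$rank[ib[y]],
        family = fam, identity = idm[x, y], type = type,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(links))
    return(data.frame(idA = character(0), idB = character(0),
                      rankA = integer(0), rankB = integer(0),
                      family = character(0), identity = numeric(0),
                      type = character(0)))
  out <- do.call(rbind, links)
  out <- out[order(out$rankA, out$rankB), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Longest strictly increasing subsequence (O(n^2) DP, deterministic:
## earliest chain among equals).
.lis <- function(v) {
  n <- length(v)
  if (!n) return(integer(0))
  len <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (v[j] < v[i] && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L; prev[i] <- j
      }
    }
  }
  i <- which.max(len)
  chain <- integer(0)
  while (i != 0L) { chain <- c(i, chain); i <- prev[i] }
  chain
}

#' Chain links into collinear blocks
#'
#' Sorts ortholog links by rank on map A and extracts maximal chains that
#' strictly increase in both rank orders via longest-increasing-subsequence
#' chaining; chaining is repeated on the remaining links, so multiple
#' disjoint blocks can be reported. Links in no block (of size >= 2) are
#' reported as rearranged.
#'
#' @param links Link data frame from \code{\link{linkOrthologs}}
#'   (ortholog links are chained; family_only links are ignored).
#' @return List with \code{blocks} (list of integer vectors of row indices
#'   into \code{links}) and \code{rearranged} (integer vector).
#' @export
collinearBlocks <- function(links) {
  use <- which(links$type == "ortholog")
  if (!length(use)) return(list(blocks = list(), rearranged = integer(0)))
  remaining <- use[order(links$rankA[use], links$rankB[use])]
  blocks <- list()
  repeat {
    if (length(remaining) < 2L) break
    chain <- .lis(links$rankB[remaining])
    if (length(chain) < 2L) break
    blocks[[length(blocks) + 1L]] <- remaining[chain]
    remaining <- remaining[-chain]
  }
  list(blocks = blocks, rearranged = remaining)
}

#' Detect translocated family members relative to the EDC
#'
#' Families with members both inside and outside the EDC interval are
#' reported as translocations (listing the outside members and their
#' nearest non-EDC anchor); families entirely outside are reported as
#' external families.
#'
#' @param map A \code{\linkS4class{LocusMap}} with an EDC interval or named
#'   anchors.
#' @param s100_names The EDC-delimiting anchor names (excluded from
#'   "nearest non-EDC anchor" reporting).
#' @return Data frame: family, gene_id, nearest_anchor, kind
#'   (\code{"translocated"} or \code{"external_family"}).
#' @export
detectTranslocations <- function(map,
                                 s100_names = c("S100A12-like", "S100A11-like")) {
  g <- map@genes
  if (!length(map@edc) && !nrow(map@anchors))
    stop("cannot classify inside/outside: map has no anchors")
  if (!length(map@edc))
    stop("cannot classify inside/outside: EDC interval is absent")
  nonEDC <- map@anchors[!map@anchors$name %in% s100_names, , drop = FALSE]
  nearestAnchor <- function(gi) {
    if (!nrow(nonEDC)) return(NA_character_)
    gc <- (g$start[gi] + g$end[gi]) / 2
    ac <- (nonEDC$start + nonEDC$end) / 2
    nonEDC$name[which.min(abs(ac - gc))]
  }
  out <- list()
  for (fam in sort(unique(g$family[!is.na(g$family)]))) {
    idx <- which(g$family == fam)
    ins <- g$inside[idx] == "inside"
    if (all(ins)) next
    kind <- if (any(ins)) "translocated" else "external_family"
    for (gi in idx[!ins]) {
      out[[length(out) + 1L]] <- data.frame(
        family = fam, gene_id = g$gene_id[gi],
        nearest_anchor = nearestAnchor(gi), kind = kind,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(family = character(0), gene_id = character(0),
                      nearest_anchor = character(0), kind = character(0)))
  do.call(rbind, out)
}

#' Full synteny comparison of two locus maps
#'
#' Links orthologs, chains collinear blocks, detects translocations on each
#' map and tabulates per-map family counts (partial genes included and also
#' reported separately).
#'
#' @param mapA,mapB \code{\linkS4class{LocusMap}} objects.
#' @param similarity,min_identity Passed to \code{\link{linkOrthologs}}.
#' @return A \code{\linkS4class{SyntenyReport}}.
#' @export
compareLoci <- function(mapA, mapB, similarity = .protIdentity,
                        min_identity = 0.5) {
  links <- linkOrthologs(mapA, mapB, similarity, min_identity)
  cb <- collinearBlocks(links)
  trOf <- function(map, lab) {
    if (!length(map@edc)) return(NULL)
    d <- detectTranslocations(map)
    if (!nrow(d)) return(NULL)
    cbind(map = lab, d)
  }
  tr <- rbind(trOf(mapA, "A"), trOf(mapB, "B"))
  if (is.null(tr))
    tr <- data.frame(map = character(0), family = character(0),
                     gene_id = character(0), nearest_anchor = character(0),
                     kind = character(0))
  fc <- function(g, map) {
    if (!nrow(g)) return(NULL)
    agg <- stats::aggregate(list(n = g$gene_id), by = list(family = g$family),
                            FUN = length)
    np <- stats::aggregate(list(n_partial = g$status == "partial"),
                           by = list(family = g$family), FUN = sum)
    cbind(map = map, merge(agg, np, by = "family"))
  }
  counts <- rbind(fc(mapA@genes, "A"), fc(mapB@genes, "B"))
  if (is.null(counts))
    counts <- data.frame(map = character(0), family = character(0),
                         n = integer(0), n_partial = integer(0))
  new("SyntenyReport", links = links, blocks = cb$blocks,
      rearranged = as.integer(cb$rearranged), translocations = tr,
      familyCounts = counts)
}
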