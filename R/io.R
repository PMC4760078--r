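## ---------------------------------------------------------------------------
## Readers/writers: gene models and ground truth as GFF3 (1-based inclusive)
## + FASTA + TSV, so every stage can be run standalone on files.
## ---------------------------------------------------------------------------

.na2dot <- function(x) ifelse(is.na(x), ".", as.character(x))
.dot2na <- function(x) ifelse(is.na(x) | x == ".", NA_character_, x)

#' Write gene models as GFF3
#'
#' Emits gene, exon, five_prime_UTR and CDS features (1-based inclusive)
#' with the model id as \code{ID} and family/status/evidence/mutations as
#' gene attributes.
#'
#' @param x A \code{\linkS4class{GeneModelSet}}.
#' @param file Output path.
#' @export
writeGeneModelsGFF3 <- function(x, file) {
  gr <- geneModels(x)
  mc <- S4Vectors::mcols(gr)
  feats <- list()
  addf <- function(seqn, start, end, strand, type, id, parent = NA,
                   extra = NULL) {
    df <- data.frame(seqn = seqn, start = start, end = end, strand = strand,
                     type = type, ID = id, Parent = parent,
                     stringsAsFactors = FALSE)
    if (!is.null(extra)) df <- cbind(df, extra)
    feats[[length(feats) + 1L]] <<- df
  }
  for (i in seq_along(gr)) {
    sn <- as.character(GenomicRanges::seqnames(gr))[i]
    st <- as.character(GenomicRanges::strand(gr))[i]
    id <- mc$gene_id[i]
    iv <- c(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i],
            mc$utr5_start[i], mc$utr5_end[i],
            mc$exon1_start[i], mc$exon1_end[i])
    gspan <- range(iv, na.rm = TRUE)
    addf(sn, gspan[1], gspan[2], st, "gene", id,
         extra = data.frame(family = .na2dot(mc$family[i]),
                            status = mc$status[i],
                            evidence = mc$evidence[i],
                            mutations = ifelse(nzchar(mc$mutations[i]),
                                               mc$mutations[i], "."),
                            stringsAsFactors = FALSE))
    if (!is.na(mc$exon1_start[i]))
      addf(sn, mc$exon1_start[i], mc$exon1_end[i], st, "exon",
           paste0(id, ".exon1"), id)
    ## exon 2 = 5' UTR + CDS extent
    e2 <- range(c(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i],
                  mc$utr5_start[i], mc$utr5_end[i]), na.rm = TRUE)
    addf(sn, e2[1], e2[2], st, "exon", paste0(id, ".exon2"), id)
    if (!is.na(mc$utr5_start[i]))
      addf(sn, mc$utr5_start[i], mc$utr5_end[i], st, "five_prime_UTR",
           paste0(id, ".utr5"), id)
    addf(sn, GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i], st,
         "CDS", paste0(id, ".cds"), id)
  }
  if (!length(feats)) {
    writeLines("##gff-version 3", file)
    return(invisible(file))
  }
  df <- do.call(rbind, lapply(feats, function(d) {
    for (cc in c("family", "status", "evidence", "mutations"))
      if (!cc %in% names(d)) d[[cc]] <- NA_character_
    d
  }))
  out <- GenomicRanges::GRanges(df$seqn, IRanges::IRanges(df$start, df$end),
                                strand = df$strand)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    type = df$type, ID = df$ID,
    Parent = ifelse(is.na(df$Parent), NA_character_, df$Parent),
    phase = ifelse(df$type == "CDS", 0L, NA_integer_),
    family = df$family, status = df$status, evidence = df$evidence,
    mutations = df$mutations)
  rtracklayer::export(out, file, format = "gff3")
  invisible(file)
}

#' Read gene models from GFF3 (+ model table)
#'
#' Reconstructs a \code{\linkS4class{GeneModelSet}} written by
#' \code{\link{writeGeneModelsGFF3}}; proteins and scores are restored from
#' the companion model table when given.
#'
#' @param file GFF3 path.
#' @param table Optional data frame (or TSV path) with columns
#'   \code{gene_id}, \code{protein}, \code{score}.
#' @return A \code{\linkS4class{GeneModelSet}}.
#' @export
readGeneModelsGFF3 <- function(file, table = NULL) {
  gff <- rtracklayer::import(file, format = "gff3")
  if (is.character(table))
    table <- utils::read.table(table, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE, quote = "")
  mcg <- S4Vectors::mcols(gff)
  genes <- gff[mcg$type == "gene"]
  gm <- S4Vectors::mcols(genes)
  parentOf <- function(feat) {
    p <- S4Vectors::mcols(feat)$Parent
    vapply(as.list(p), function(v) if (length(v)) as.character(v)[1]
           else NA_character_, character(1))
  }
  rows <- list()
  for (i in seq_along(genes)) {
    id <- gm$ID[i]
    kids <- gff[!is.na(parentOf(gff)) & parentOf(gff) == id]
    kt <- S4Vectors::mcols(kids)$type
    kid_id <- S4Vectors::mcols(kids)$ID
    cds <- kids[kt == "CDS"][1]
    utr <- kids[kt == "five_prime_UTR"]
    ex1 <- kids[kt == "exon" & grepl("\\.exon1$", kid_id)]
    st <- as.character(GenomicRanges::strand(genes)[i])
    intron <- c(NA_integer_, NA_integer_)
    if (length(ex1) && length(utr)) {
      e2start <- min(GenomicRanges::start(cds), GenomicRanges::start(utr))
      e2end <- max(GenomicRanges::end(cds), GenomicRanges::end(utr))
      if (st == "-") intron <- c(e2end + 1L, GenomicRanges::start(ex1) - 1L)
      else intron <- c(GenomicRanges::end(ex1) + 1L, e2start - 1L)
    }
    prot <- NA_character_; scr <- NA_real_
    if (!is.null(table)) {
      tr <- table[table$gene_id == id, , drop = FALSE]
      if (nrow(tr)) {
        prot <- tr$protein[1]
        if ("score" %in% names(tr)) scr <- as.numeric(tr$score[1])
      }
    }
    rows[[i]] <- data.frame(
      seqn = as.character(GenomicRanges::seqnames(genes))[i], strand = st,
      cds_start = GenomicRanges::start(cds), cds_end = GenomicRanges::end(cds),
      gene_id = id, status = gm$status[i],
      evidence = gm$evidence[i], family = .dot2na(gm$family[i]),
      protein = prot, score = scr,
      utr5_start = if (length(utr)) GenomicRanges::start(utr) else NA_integer_,
      utr5_end = if (length(utr)) GenomicRanges::end(utr) else NA_integer_,
      exon1_start = if (length(ex1)) GenomicRanges::start(ex1) else NA_integer_,
      exon1_end = if (length(ex1)) GenomicRanges::end(ex1) else NA_integer_,
      intron_start = intron[1], intron_end = intron[2],
      mutations = ifelse(is.na(gm$mutations[i]) | gm$mutations[i] == ".",
                         "", gm$mutations[i]),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$seqn, IRanges::IRanges(df$cds_start, df$cds_end),
                               strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = df$gene_id, status = df$status, evidence = df$evidence,
    family = df$family, protein = df$protein, score = df$score,
    utr5_start = as.integer(df$utr5_start), utr5_end = as.integer(df$utr5_end),
    exon1_start = as.integer(df$exon1_start), exon1_end = as.integer(df$exon1_end),
    intron_start = as.integer(df$intron_start), intron_end = as.integer(df$intron_end),
    mutations = df$mutations)
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr))]
  GeneModelSet(gr)
}

#' Model table of a GeneModelSet
#'
#' Flat per-gene table (TSV-friendly): id, family, status, coordinates,
#' protein.
#' @param x A \code{\linkS4class{GeneModelSet}}.
#' @return data.frame.
#' @export
modelTable <- function(x) {
  gr <- geneModels(x)
  mc <- S4Vectors::mcols(gr)
  data.frame(gene_id = mc$gene_id,
             scaffold = as.character(GenomicRanges::seqnames(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             cds_start = GenomicRanges::start(gr),
             cds_end = GenomicRanges::end(gr),
             family = mc$family, status = mc$status, evidence = mc$evidence,
             score = mc$score, mutations = mc$mutations,
             protein = mc$protein, stringsAsFactors = FALSE)
}

#' Write a truth set to a directory
#'
#' Emits \code{scaffolds.fasta}, \code{truth.gff3} (gene structures and
#' anchor/decoy regions), \code{truth_table.tsv}, \code{events.tsv} and
#' \code{meta.yaml} (seed). The directory round-trips losslessly through
#' \code{\link{readTruthSet}}.
#'
#' @param ts A \code{\linkS4class{TruthSet}}.
#' @param dir Output directory (created if needed).
#' @export
writeTruthSet <- function(ts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(ts@scaffolds, file.path(dir, "scaffolds.fasta"))
  writeGeneModelsGFF3(ts@genes, file.path(dir, "truth.gff3"))
  utils::write.table(modelTable(ts@genes), file.path(dir, "truth_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  anch <- data.frame(
    name = S4Vectors::mcols(ts@anchors)$name,
    scaffold = as.character(GenomicRanges::seqnames(ts@anchors)),
    start = GenomicRanges::start(ts@anchors),
    end = GenomicRanges::end(ts@anchors))
  utils::write.table(anch, file.path(dir, "anchors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dec <- data.frame(
    scaffold = as.character(GenomicRanges::seqnames(ts@decoys)),
    start = GenomicRanges::start(ts@decoys),
    end = GenomicRanges::end(ts@decoys))
  utils::write.table(dec, file.path(dir, "decoys.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ts@events, file.path(dir, "events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(seed = ts@seed), file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a truth set from a directory
#'
#' @param dir Directory written by \code{\link{writeTruthSet}}.
#' @return A \code{\linkS4class{TruthSet}}.
#' @export
readTruthSet <- function(dir) {
  sc <- Biostrings::readDNAStringSet(file.path(dir, "scaffolds.fasta"))
  tb <- utils::read.table(file.path(dir, "truth_table.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE, quote = "")
  genes <- readGeneModelsGFF3(file.path(dir, "truth.gff3"), tb)
  anch <- utils::read.table(file.path(dir, "anchors.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  agr <- GenomicRanges::GRanges(anch$scaffold,
                                IRanges::IRanges(anch$start, anch$end))
  S4Vectors::mcols(agr)$name <- anch$name
  decf <- utils::read.table(file.path(dir, "decoys.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  dgr <- if (nrow(decf)) GenomicRanges::GRanges(
    decf$scaffold, IRanges::IRanges(decf$start, decf$end))
  else GenomicRanges::GRanges()
  ev <- utils::read.table(file.path(dir, "events.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!nrow(ev))
    ev <- data.frame(family = character(0), source_locus = character(0),
                     destination_locus = character(0))
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  new("TruthSet", scaffolds = sc, genes = genes, anchors = agr, decoys = dgr,
      events = ev, seed = as.integer(meta$seed))
}
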