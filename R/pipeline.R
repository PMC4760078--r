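## ---------------------------------------------------------------------------
## Pipeline orchestration: simulate -> scan -> classify -> (pseudogene
## screen) -> synteny -> phylo -> score, with a config that round-trips
## through YAML, per-stage outputs, and recovery metrics against the truth.
## ---------------------------------------------------------------------------

#' Default pipeline configuration
#'
#' @return Nested named list of stage toggles and stage parameters;
#'   round-trips losslessly through YAML.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 42L,
    stages = list(simulate = TRUE, scan = TRUE, classify = TRUE,
                  pseudo = FALSE, synteny = TRUE, phylo = FALSE,
                  score = TRUE),
    simulate = defaultSimConfig(),
    scan = list(require_exon1 = TRUE),
    classify = list(propensity_threshold = 1.30),
    phylo = list(n_replicates = 200L, correction = "poisson"),
    out_dir = NULL
  )
}

.checkConfigKeys <- function(config, reference = defaultRunConfig(),
                             path = "") {
  unknown <- setdiff(names(config), names(reference))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (nm in intersect(names(config), c("stages", "scan", "classify", "phylo")))
    if (is.list(config[[nm]])) {
      bad <- setdiff(names(config[[nm]]), names(reference[[nm]]))
      if (length(bad))
        stop("unknown config key(s): ", paste0(nm, "$", bad, collapse = ", "))
    }
  invisible(TRUE)
}

#' Load/validate a pipeline configuration
#'
#' @param x A named list or a YAML file path. Unknown keys are rejected.
#' @return Validated config list merged over the defaults.
#' @export
runConfig <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  .checkConfigKeys(x)
  cfg <- mergeConfig(defaultRunConfig(), x)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.configHash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(cfg, tf)
  unname(tools::md5sum(tf))
}

#' Score predictions against a truth set
#'
#' A predicted gene matches a truth gene when scaffold and strand agree and
#' both CDS endpoints lie within the coordinate tolerance. Family labels,
#' pseudogene calls and translocations are scored on top of the structure
#' matching; unmatched predictions are false positives.
#'
#' @param predictions \code{\linkS4class{GeneModelSet}}.
#' @param truth \code{\linkS4class{TruthSet}}.
#' @param coordinate_tolerance Max allowed shift (nt) per CDS endpoint.
#' @param family_map Optional named vector translating truth family names
#'   to the predicted family vocabulary before comparison.
#' @param pseudo_calls Optional data frame of pseudogene calls (scaffold,
#'   start, end, type).
#' @param translocation_families Optional character vector of families
#'   called translocated/external.
#' @return List of class \code{"RecoveryMetrics"}: \code{structure},
#'   \code{family}, \code{pseudogene}, \code{translocation} entries each
#'   with tp/fp/fn/precision/recall/f1, plus \code{matches}.
#' @export
scoreAgainstTruth <- function(predictions, truth, coordinate_tolerance = 0L,
                              family_map = NULL, pseudo_calls = NULL,
                              translocation_families = NULL) {
  tol <- as.integer(coordinate_tolerance)
  tg <- geneModels(truthGenes(truth))
  tmc <- S4Vectors::mcols(tg)
  pg <- geneModels(predictions)
  pmc <- S4Vectors::mcols(pg)
  tkey <- paste(GenomicRanges::seqnames(tg), GenomicRanges::strand(tg))
  pkey <- paste(GenomicRanges::seqnames(pg), GenomicRanges::strand(pg))

  match_of <- rep(NA_integer_, length(pg))   # index into truth
  used <- rep(FALSE, length(tg))
  for (i in seq_along(pg)) {
    cand <- which(tkey == pkey[i] & !used &
                  abs(GenomicRanges::start(tg) - GenomicRanges::start(pg)[i]) <= tol &
                  abs(GenomicRanges::end(tg) - GenomicRanges::end(pg)[i]) <= tol)
    if (length(cand)) {
      match_of[i] <- cand[1]
      used[cand[1]] <- TRUE
    }
  }
  prf <- function(tp, fp, fn) {
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else NA_real_
    list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
         f1 = f1)
  }
  complete_t <- which(tmc$status == "complete")
  tp_s <- sum(!is.na(match_of) & match_of %in% complete_t)
  fp_s <- sum(is.na(match_of))
  fn_s <- sum(!(complete_t %in% match_of[!is.na(match_of)]))
  structure_m <- prf(tp_s, fp_s, fn_s)

  ## family labels on matched genes
  fam_t <- tmc$family
  if (!is.null(family_map)) {
    mapped <- unname(family_map[fam_t])
    fam_t <- ifelse(is.na(mapped), fam_t, mapped)
  }
  mi <- which(!is.na(match_of) & !is.na(pmc$family))
  fam_tp <- sum(pmc$family[mi] == fam_t[match_of[mi]], na.rm = TRUE)
  fam_fp <- length(mi) - fam_tp
  fam_fn <- length(complete_t) - fam_tp
  family_m <- prf(fam_tp, fam_fp, max(0L, fam_fn))

  ## pseudogene calls by overlap with truth pseudogene CDS
  ps_t <- tg[tmc$status == "pseudogene"]
  if (is.null(pseudo_calls) ||
      !nrow(pseudo_calls <- as.data.frame(pseudo_calls))) {
    pseudogene_m <- prf(0L, 0L, length(ps_t))
  } else {
    cgr <- GenomicRanges::GRanges(pseudo_calls$scaffold,
      IRanges::IRanges(pseudo_calls$start, pseudo_calls$end))
    hit_t <- IRanges::overlapsAny(ps_t, cgr)
    hit_c <- IRanges::overlapsAny(cgr, ps_t)
    pseudogene_m <- prf(sum(hit_t), sum(!hit_c), sum(!hit_t))
  }

  ## translocations at family level
  ev_fams <- unique(truthEvents(truth)$family)
  called <- unique(translocation_families %||% character(0))
  translocation_m <- prf(length(intersect(called, ev_fams)),
                         length(setdiff(called, ev_fams)),
                         length(setdiff(ev_fams, called)))

  structure(list(structure = structure_m, family = family_m,
                 pseudogene = pseudogene_m, translocation = translocation_m,
                 matches = data.frame(
                   pred_id = pmc$gene_id,
                   truth_id = ifelse(is.na(match_of), NA_character_,
                                     tmc$gene_id[match_of]),
                   stringsAsFactors = FALSE)),
            class = "RecoveryMetrics")
}

#' @export
print.RecoveryMetrics <- function(x, ...) {
  cat("Recovery metrics\n")
  for (cat_ in c("structure", "family", "pseudogene", "translocation")) {
    m <- x[[cat_]]
    cat(sprintf("  %-14s tp=%d fp=%d fn=%d  P=%.3f R=%.3f F1=%.3f\n",
                cat_, m$tp, m$fp, m$fn,
                m$precision %||% NA, m$recall %||% NA, m$f1 %||% NA))
  }
  invisible(x)
}

## Map class labels of the classifier to the truth family names of a
## simulation config (class -> first family of that class).
.classToFamilyMap <- function(sim_cfg) {
  cls <- vapply(sim_cfg$families, function(f) f$class, character(1))
  nm <- vapply(sim_cfg$families, function(f) f$name, character(1))
  lab <- c(GS_rich = "GS_rich", CP_rich = "CP_rich",
           aromatic_rich = "aromatic_rich",
           beta_keratin_like = "beta_keratin", unbiased = "other")
  setNames(unname(lab[cls]), nm)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in fixed order
#' (simulate, scan, classify, pseudo, synteny, phylo, score); every output
#' is stamped with the config hash and seed, and a rerun with the same
#' config and seed is bit-identical for the deterministic stages.
#'
#' @param config See \code{\link{runConfig}} (list or YAML path).
#' @param out_dir Output directory (overrides \code{config$out_dir}); when
#'   NULL nothing is written to disk.
#' @return Invisible list: the run report (also written as
#'   \code{report.json} when an output directory is set) plus the stage
#'   objects (\code{truth}, \code{models}, \code{features}, \code{metrics},
#'   ...).
#' @export
runPipeline <- function(config = defaultRunConfig(), out_dir = NULL) {
  cfg <- runConfig(if (is.list(config)) config else config)
  out_dir <- out_dir %||% cfg$out_dir
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .configHash(cfg)
  report <- list(config_hash = hash, seed = cfg$seed, stages_run = character(0))
  res <- list(config = cfg)
  emit <- function(name, writer) {
    if (!is.null(out_dir)) writer(file.path(out_dir, name))
  }
  fail <- function(stage, e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)

  truth <- NULL
  if (isTRUE(cfg$stages$simulate)) {
    truth <- tryCatch(buildTruthSet(cfg$simulate, seed = cfg$seed),
                      error = function(e) fail("simulate", e))
    res$truth <- truth
    report$stages_run <- c(report$stages_run, "simulate")
    report$simulate <- list(n_genes = length(truthGenes(truth)),
                            n_scaffolds = length(truthScaffolds(truth)))
    if (!is.null(out_dir)) writeTruthSet(truth, file.path(out_dir, "truth"))
  }
  scaffolds <- if (!is.null(truth)) truthScaffolds(truth) else NULL
  if (is.null(scaffolds)) stop("no input scaffolds: enable the simulate stage")

  params <- scanParams(require_exon1 = isTRUE(cfg$scan$require_exon1))
  models <- NULL
  if (isTRUE(cfg$stages$scan)) {
    models <- tryCatch(scanScaffolds(scaffolds, params),
                       error = function(e) fail("scan", e))
    res$models <- models
    report$stages_run <- c(report$stages_run, "scan")
    report$scan <- list(n_models = length(models),
                        status = as.list(table(modelStatus(models))))
    emit("models.gff3", function(f) writeGeneModelsGFF3(models, f))
    emit("models.tsv", function(f)
      utils::write.table(modelTable(models), f, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    emit("proteins.fasta", function(f)
      Biostrings::writeXStringSet(modelProteins(models), f))
  }

  feats <- NULL
  if (isTRUE(cfg$stages$classify) && !is.null(models) && length(models)) {
    bp <- betaCoreParams(propensity_threshold = cfg$classify$propensity_threshold)
    feats <- tryCatch(proteinFeatures(modelProteins(models), bp),
                      error = function(e) fail("classify", e))
    ## push class labels back onto the models as family labels
    gr <- geneModels(models)
    mc <- S4Vectors::mcols(gr)
    mc$family <- featureTable(feats)$class_label[
      match(mc$gene_id, featureTable(feats)$id)]
    S4Vectors::mcols(gr) <- mc
    models <- GeneModelSet(gr)
    res$models <- models
    res$features <- feats
    report$stages_run <- c(report$stages_run, "classify")
    report$classify <- as.list(table(featureTable(feats)$class_label))
    emit("features.tsv", function(f)
      utils::write.table(featureTable(feats), f, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  }

  pseudo_calls <- NULL
  if (isTRUE(cfg$stages$pseudo) && !is.null(models) && length(models)) {
    pseudo_calls <- tryCatch(
      screenPseudogenes(scaffolds, models, params),
      error = function(e) fail("pseudo", e))
    res$pseudo_calls <- pseudo_calls
    report$stages_run <- c(report$stages_run, "pseudo")
    report$pseudo <- list(n_calls = nrow(pseudo_calls))
    emit("pseudogenes.tsv", function(f)
      utils::write.table(pseudo_calls, f, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  }

  synteny <- NULL
  if (isTRUE(cfg$stages$synteny) && !is.null(models) && !is.null(truth)) {
    synteny <- tryCatch({
      map_pred <- buildLocusMap(models, truthAnchors(truth))
      tr <- detectTranslocations(map_pred)
      list(map = map_pred, translocations = tr)
    }, error = function(e) fail("synteny", e))
    res$synteny <- synteny
    report$stages_run <- c(report$stages_run, "synteny")
    report$synteny <- list(n_translocation_records = nrow(synteny$translocations))
  }

  if (isTRUE(cfg$stages$phylo) && !is.null(models)) {
    fams <- familyLabels(models)
    beta <- modelProteins(models)[!is.na(fams) & fams == "beta_keratin"]
    if (length(beta) >= 4L) {
      ph <- tryCatch({
        msa <- progressiveAlign(beta)
        bootstrapSupport(msa, n_replicates = cfg$phylo$n_replicates,
                         seed = cfg$seed, correction = cfg$phylo$correction)
      }, error = function(e) fail("phylo", e))
      res$phylo <- ph
      report$stages_run <- c(report$stages_run, "phylo")
      emit("beta_keratins.nwk", function(f) ape::write.tree(ph@tree, f))
    }
  }

  if (isTRUE(cfg$stages$score) && !is.null(models) && !is.null(truth)) {
    fam_map <- .classToFamilyMap(cfg$simulate)
    metrics <- tryCatch(scoreAgainstTruth(
      models, truth, family_map = fam_map, pseudo_calls = pseudo_calls,
      translocation_families = if (!is.null(synteny))
        unique(synteny$translocations$family) else NULL),
      error = function(e) fail("score", e))
    res$metrics <- metrics
    report$stages_run <- c(report$stages_run, "score")
    report$score <- lapply(metrics[c("structure", "family", "pseudogene",
                                     "translocation")], function(m)
      m[c("tp", "fp", "fn", "precision", "recall", "f1")])
  }

  res$report <- report
  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Screen for pseudogenized SEDC loci
#'
#' Runs the translated search with the translations of the complete models
#' as queries, takes homology clusters not explained by a complete model,
#' and tests each with the frameshift-aware aligner against its
#' best-scoring query; loci with inactivating mutations are reported.
#'
#' @param scaffolds Named \code{DNAStringSet}.
#' @param models \code{\linkS4class{GeneModelSet}} of predicted models.
#' @param params \code{\link{scanParams}}.
#' @param flank Context added around each candidate locus (nt).
#' @return Data frame: scaffold, start, end, strand, reference query,
#'   mutation summary, type of the first mutation.
#' @export
screenPseudogenes <- function(scaffolds, models, params = scanParams(),
                              flank = 30L) {
  qs <- modelProteins(models)
  qs <- qs[S4Vectors::mcols(geneModels(models))$status == "complete"]
  if (!length(qs))
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      reference = character(0), mutations = character(0),
                      type = character(0)))
  out <- list()
  for (id in names(scaffolds)) {
    seq <- as.character(scaffolds[[id]])
    hsps <- translatedSearch(qs, seq, params)
    if (!nrow(hsps)) next
    hgr <- GenomicRanges::GRanges(id, IRanges::IRanges(hsps$s_nt_start,
                                                       hsps$s_nt_end),
                                  strand = hsps$strand)
    gm <- geneModels(models)
    gm <- gm[as.character(GenomicRanges::seqnames(gm)) == id]
    clusters <- GenomicRanges::reduce(hgr, min.gapwidth = 60L)
    unexplained <- clusters[!IRanges::overlapsAny(clusters, gm,
                                                  ignore.strand = TRUE)]
    for (k in seq_along(unexplained)) {
      cl <- unexplained[k]
      sel <- which(IRanges::overlapsAny(hgr, cl))
      best <- sel[which.max(hsps$score[sel])]
      qid <- hsps$query_id[best]
      st <- hsps$strand[best]
      s <- max(1L, GenomicRanges::start(cl) - flank)
      e <- min(nchar(seq), GenomicRanges::end(cl) + flank)
      locus <- substr(seq, s, e)
      if (st == "-") locus <- revComp(locus)
      mut <- detectPseudogene(locus, as.character(qs[[qid]]))
      if (attr(mut, "status") == "mutated")
        out[[length(out) + 1L]] <- data.frame(
          scaffold = id, start = s, end = e, strand = st, reference = qid,
          mutations = paste(sprintf("%s@%d", mut$type, mut$codon),
                            collapse = ";"),
          type = mut$type[1], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      reference = character(0), mutations = character(0),
                      type = character(0)))
  do.call(rbind, out)
}
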