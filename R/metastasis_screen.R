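# The four-stage screen reducing all lncRNAs to a metastasis-specific
# candidate list with a per-gene audit trail:
#   1. NB Wald DE, metastasis vs primary, padj < 0.15 (relaxed discovery).
#   2. Three tissue-specific control filters at padj < 0.01.
#   3. Per-patient pairwise direction consistency (> 2 opposite patients
#      removes a gene).
#   4. Same-strand overlap with protein-coding/pseudogene annotation flags
#      a candidate for curation (optionally resolved by a decision file).

#' Screen configuration
#'
#' @param stage1_padj discovery BH threshold (strict `<`), default 0.15.
#' @param stage2_padj control-filter BH threshold, default 0.01.
#' @param pairwise_max_opposite maximum number of patients allowed to show
#'   the opposite direction before a gene is removed (default 2: removal
#'   requires "more than two" opposite patients).
#' @param stage2_rule `"same-sign-drop"` (default) drops a survivor with
#'   metastasis direction d when a control comparison is significant with
#'   sign(LFC) = d, i.e. the control tissue deviates from the reference in
#'   the direction that could explain the metastasis signal;
#'   `"opposite-sign-drop"` inverts the reading.
#' @param masking_biotypes biotypes whose same-strand overlap flags a
#'   candidate for curation.
#' @return `screen_config` list.
#' @export
screen_config <- function(stage1_padj = 0.15, stage2_padj = 0.01,
                          pairwise_max_opposite = 2L,
                          stage2_rule = c("same-sign-drop",
                                          "opposite-sign-drop"),
                          masking_biotypes = c("protein_coding",
                                               "pseudogene")) {
  assert_scalar_number(stage1_padj, "stage1_padj", 0, 1)
  assert_scalar_number(stage2_padj, "stage2_padj", 0, 1)
  cfg <- list(stage1_padj = stage1_padj, stage2_padj = stage2_padj,
              pairwise_max_opposite = assert_count(pairwise_max_opposite,
                                                   "pairwise_max_opposite",
                                                   lower = 0L),
              stage2_rule = match.arg(stage2_rule),
              masking_biotypes = masking_biotypes)
  class(cfg) <- "screen_config"
  cfg
}

stage_report <- function(stage, input, surviving, dropped) {
  stopifnot(all(surviving %in% input))
  need <- setdiff(input, surviving)
  stopifnot(setequal(need, unique(dropped$gene_id)))
  rep <- list(stage = stage, input = input, surviving = surviving,
              dropped = dropped)
  class(rep) <- "stage_report"
  rep
}

empty_drops <- function() {
  data.frame(gene_id = character(0), stage = character(0),
             reason = character(0), comparison = character(0),
             lfc = numeric(0), padj = numeric(0), stringsAsFactors = FALSE)
}

drop_rows <- function(gene_id, stage, reason, comparison = NA_character_,
                      lfc = NA_real_, padj = NA_real_) {
  if (!length(gene_id)) return(empty_drops())
  data.frame(gene_id = gene_id, stage = stage, reason = reason,
             comparison = comparison, lfc = lfc, padj = padj,
             stringsAsFactors = FALSE)
}

#' Stage 1: discovery differential expression
#'
#' Tests lncRNA-biotype genes for metastasis vs primary differential
#' expression (positive fold change = up in metastases) and keeps genes
#' with padj strictly below `stage1_padj`.
#'
#' @param counts full count matrix (all biotypes; size factors are computed
#'   over all genes of the compared samples).
#' @param samples sample table.
#' @param models gene models (used to restrict testing to lncRNAs).
#' @param config [screen_config()].
#' @return list with `de` (DE table over lncRNAs), `report`
#'   (`stage_report`), and `directions` (named +1/-1 per survivor).
#' @export
stage1_de <- function(counts, samples, models, config = screen_config()) {
  validate_sample_table(samples)
  prim <- samples$sample_id[samples$cancer_status == "primary"]
  mets <- samples$sample_id[samples$cancer_status == "metastasis"]
  if (!length(prim) || !length(mets))
    stop_("stage 1 needs at least one primary and one metastasis sample")
  lnc <- intersect(rownames(counts),
                   models$gene_id[models$biotype == "lncRNA"])
  sf <- size_factors_median_of_ratios(counts[, c(prim, mets), drop = FALSE])
  de <- wald_test_two_group(counts[lnc, , drop = FALSE],
                            group_a = prim, group_b = mets, factors = sf,
                            shrink = TRUE)
  keep <- !is.na(de$padj) & de$padj < config$stage1_padj
  surv <- de$gene_id[keep]
  directions <- ifelse(de$log2FoldChange[keep] >= 0, 1L, -1L)
  names(directions) <- surv
  dropped <- rbind(
    drop_rows(de$gene_id[is.na(de$padj)], "stage1", "all_zero_counts",
              "metastasis_vs_primary"),
    drop_rows(de$gene_id[!is.na(de$padj) & !keep], "stage1",
              "padj_above_threshold", "metastasis_vs_primary",
              de$log2FoldChange[!is.na(de$padj) & !keep],
              de$padj[!is.na(de$padj) & !keep]))
  list(de = de,
       report = stage_report("stage1_de", de$gene_id, surv, dropped),
       directions = directions)
}

#' Stage 2: tissue-specific control filters
#'
#' Three control comparisons guard against tissue-of-origin confounding:
#' (a) each non-prostate normal tissue vs all primary tumors, (b) all
#' non-prostate normals together vs all primaries, (c) all non-prostate
#' normals vs BPH. Each comparison's fold change is oriented
#' control-minus-reference; a stage-1 survivor with metastasis direction d
#' is dropped when any comparison has padj below `stage2_padj` and a fold
#' change whose sign could explain the metastasis signal (see
#' `stage2_rule`). Filters are skipped with a warning when their control
#' samples are absent.
#'
#' @inheritParams stage1_de
#' @param directions named +1/-1 vector of stage-1 survivor directions.
#' @return `stage_report`.
#' @export
stage2_tissue_filters <- function(counts, samples, directions,
                                  models, config = screen_config()) {
  survivors <- names(directions)
  lnc <- intersect(rownames(counts),
                   models$gene_id[models$biotype == "lncRNA"])
  prim <- samples$sample_id[samples$cancer_status == "primary"]
  norm <- samples[samples$cancer_status == "normal" &
                    samples$tissue_site != "prostate", , drop = FALSE]
  bph <- samples$sample_id[samples$cancer_status == "bph"]

  comparisons <- list()
  if (nrow(norm)) {
    for (site in unique(norm$tissue_site)) {
      ids <- norm$sample_id[norm$tissue_site == site]
      if (length(ids) >= 2L)
        comparisons[[paste0("a:", site, "_vs_primary")]] <-
          list(ref = prim, ctl = ids)
    }
    if (nrow(norm) >= 2L)
      comparisons[["b:all_normals_vs_primary"]] <-
        list(ref = prim, ctl = norm$sample_id)
  } else {
    warning("stage 2: no non-prostate normal samples; filters (a) and (b) ",
            "skipped", call. = FALSE)
  }
  if (length(bph) >= 2L && nrow(norm) >= 2L) {
    comparisons[["c:all_normals_vs_bph"]] <-
      list(ref = bph, ctl = norm$sample_id)
  } else if (length(bph) < 2L) {
    warning("stage 2: no BPH samples; filter (c) skipped", call. = FALSE)
  }

  dropped <- empty_drops()
  still <- survivors
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    sf <- size_factors_median_of_ratios(
      counts[, c(cmp$ref, cmp$ctl), drop = FALSE])
    de <- wald_test_two_group(counts[lnc, , drop = FALSE],
                              group_a = cmp$ref, group_b = cmp$ctl,
                              factors = sf, shrink = TRUE)
    rownames(de) <- de$gene_id
    d <- directions[still]
    lfc <- de[still, "log2FoldChange"]
    padj <- de[still, "padj"]
    sig <- !is.na(padj) & padj < config$stage2_padj
    explains <- if (config$stage2_rule == "same-sign-drop")
      sign(lfc) == d else sign(lfc) == -d
    kill <- sig & explains & !is.na(lfc)
    if (any(kill)) {
      dropped <- rbind(dropped,
                       drop_rows(still[kill], "stage2",
                                 "tissue_specific_control", nm,
                                 lfc[kill], padj[kill]))
      still <- still[!kill]
    }
    if (!length(still)) break
  }
  stage_report("stage2_tissue_filters", survivors, still, dropped)
}

#' Stage 3: per-patient pairwise direction consistency
#'
#' For every patient with both primary and metastasis samples, the
#' per-gene direction is the sign of (mean normalized expression over the
#' patient's metastases) minus (normalized expression of the primary; mean
#' over primaries when a patient has several). A gene is removed when the
#' number of patients whose direction opposes its stage-1 direction
#' exceeds `pairwise_max_opposite`; exact zero differences count as
#' consistent.
#'
#' @inheritParams stage2_tissue_filters
#' @param factors optional size factors for the primary + metastasis
#'   samples (median-of-ratios over them when `NULL`).
#' @return `stage_report`.
#' @export
stage3_pairwise <- function(counts, samples, directions,
                            config = screen_config(), factors = NULL) {
  survivors <- names(directions)
  pm <- samples[samples$cancer_status %in% c("primary", "metastasis"), ,
                drop = FALSE]
  paired <- intersect(pm$patient_id[pm$cancer_status == "primary"],
                      pm$patient_id[pm$cancer_status == "metastasis"])
  if (!length(paired)) {
    warning("stage 3: no patient has both primary and metastasis samples; ",
            "all genes pass", call. = FALSE)
    return(stage_report("stage3_pairwise", survivors, survivors,
                        empty_drops()))
  }
  if (is.null(factors))
    factors <- size_factors_median_of_ratios(
      counts[, pm$sample_id, drop = FALSE])
  q <- sweep(counts[survivors, pm$sample_id, drop = FALSE], 2L,
             align_factors(factors, counts[, pm$sample_id, drop = FALSE]),
             "/")
  n_opp <- integer(length(survivors))
  for (p in paired) {
    pr <- pm$sample_id[pm$patient_id == p & pm$cancer_status == "primary"]
    mt <- pm$sample_id[pm$patient_id == p & pm$cancer_status == "metastasis"]
    diff <- rowMeans(q[, mt, drop = FALSE]) - rowMeans(q[, pr, drop = FALSE])
    # sign(0) = 0: never opposite
    n_opp <- n_opp + as.integer(sign(diff) == -directions)
  }
  kill <- n_opp > config$pairwise_max_opposite
  dropped <- drop_rows(survivors[kill], "stage3", "opposite_in_patients",
                       sprintf("%d_of_%d_patients_opposite",
                               n_opp[kill], length(paired)))
  stage_report("stage3_pairwise", survivors, survivors[!kill], dropped)
}

# Same-strand >= 1 bp overlap of query intervals with subject intervals
# (0-based half-open), via GenomicRanges.
same_strand_overlap <- function(query, subject) {
  if (!nrow(subject)) return(rep(FALSE, nrow(query)))
  gq <- GenomicRanges::GRanges(query$chrom,
                               IRanges::IRanges(query$start + 1L, query$end),
                               strand = query$strand)
  gs <- GenomicRanges::GRanges(subject$chrom,
                               IRanges::IRanges(subject$start + 1L,
                                                subject$end),
                               strand = subject$strand)
  IRanges::overlapsAny(gq, gs, minoverlap = 1L, ignore.strand = FALSE)
}

#' Stage 4: overlap flagging and optional curation decisions
#'
#' Candidates whose interval overlaps (same strand, >= 1 bp) any gene of a
#' masking biotype (protein-coding or pseudogene) are flagged
#' `needs_curation` but kept; the judgment itself is externalized to an
#' optional decision table (`gene_id`, `decision` = keep/drop). Without a
#' decision table all flagged candidates stay on the worklist.
#'
#' @param directions named +1/-1 vector of surviving candidates.
#' @param models gene models covering every candidate.
#' @param config [screen_config()].
#' @param curation optional data.frame with columns `gene_id`, `decision`.
#' @return list with `candidates` (data.frame gene_id, direction,
#'   curation_flag) and `report` (`stage_report`).
#' @export
stage4_overlap_filter <- function(directions, models,
                                  config = screen_config(),
                                  curation = NULL) {
  survivors <- names(directions)
  miss <- setdiff(survivors, models$gene_id)
  if (length(miss))
    stop_("candidate missing from gene models: '", miss[1L], "'")
  cand <- models[match(survivors, models$gene_id), , drop = FALSE]
  mask <- models[models$biotype %in% config$masking_biotypes, , drop = FALSE]
  flagged <- same_strand_overlap(cand, mask)
  flag <- ifelse(flagged, "needs_curation", "clean")
  keep <- rep(TRUE, length(survivors))
  dropped <- empty_drops()
  if (!is.null(curation)) {
    if (!all(c("gene_id", "decision") %in% names(curation)))
      stop_("curation table needs gene_id and decision columns")
    dec <- curation$decision[match(survivors, curation$gene_id)]
    kill <- flagged & !is.na(dec) & dec == "drop"
    keep <- !kill
    dropped <- drop_rows(survivors[kill], "stage4", "curation_drop",
                         "overlap_curation")
  }
  candidates <- data.frame(gene_id = survivors[keep],
                           direction = unname(directions[keep]),
                           curation_flag = flag[keep],
                           stringsAsFactors = FALSE)
  list(candidates = candidates,
       report = stage_report("stage4_overlap", survivors,
                             survivors[keep], dropped))
}

#' Run the full four-stage screen
#'
#' Executes discovery DE, tissue-specific control filters, per-patient
#' pairwise consistency and overlap flagging in order, returning the final
#' candidate set (with stage-1 directions and curation flags) and one
#' audit report per stage.
#'
#' @inheritParams stage1_de
#' @param curation optional curation decision data.frame (see
#'   [stage4_overlap_filter()]).
#' @return `screen_result` list: `candidates`, `reports` (4
#'   `stage_report`s), `stage1_de` (full DE table), `funnel` (named
#'   survivor counts).
#' @export
run_screen <- function(counts, samples, models, config = screen_config(),
                       curation = NULL) {
  validate_count_matrix(counts)
  validate_sample_table(samples)
  validate_gene_models(models)
  s1 <- stage1_de(counts, samples, models, config)
  r2 <- stage2_tissue_filters(counts, samples, s1$directions, models, config)
  d2 <- s1$directions[r2$surviving]
  r3 <- stage3_pairwise(counts, samples, d2, config)
  d3 <- d2[r3$surviving]
  s4 <- stage4_overlap_filter(d3, models, config, curation)
  reports <- list(s1$report, r2, r3, s4$report)
  funnel <- c(tested = length(s1$report$input),
              stage1 = length(s1$report$surviving),
              stage2 = length(r2$surviving),
              stage3 = length(r3$surviving),
              stage4 = length(s4$report$surviving))
  out <- list(candidates = s4$candidates, reports = reports,
              stage1_de = s1$de, funnel = funnel)
  class(out) <- "screen_result"
  out
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Metastasis lncRNA screen\n")
  cat(sprintf("  lncRNAs tested : %d\n", x$funnel[["tested"]]))
  cat(sprintf("  stage 1 (DE)   : %d\n", x$funnel[["stage1"]]))
  cat(sprintf("  stage 2 (tissue): %d\n", x$funnel[["stage2"]]))
  cat(sprintf("  stage 3 (pairwise): %d\n", x$funnel[["stage3"]]))
  cat(sprintf("  stage 4 (overlap): %d\n", x$funnel[["stage4"]]))
  up <- sum(x$candidates$direction > 0)
  cat(sprintf("  final candidates: %d (%d up, %d down; %d need curation)\n",
              nrow(x$candidates), up, nrow(x$candidates) - up,
              sum(x$candidates$curation_flag == "needs_curation")))
  invisible(x)
}

#' Write screen outputs to a directory
#'
#' Emits candidates.tsv (gene_id, direction, curation_flag),
#' stage_reports/stage<k>_dropped.tsv, and audit.json with the funnel and
#' every per-gene drop reason.
#'
#' @param result `screen_result` from [run_screen()].
#' @param dir output directory.
#' @export
write_screen_results <- function(result, dir) {
  dir.create(file.path(dir, "stage_reports"), showWarnings = FALSE,
             recursive = TRUE)
  utils::write.table(result$candidates, file.path(dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (rep in result$reports)
    utils::write.table(rep$dropped,
                       file.path(dir, "stage_reports",
                                 paste0(rep$stage, "_dropped.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
  audit <- list(
    funnel = as.list(result$funnel),
    stages = lapply(result$reports, function(rep)
      list(stage = rep$stage, n_input = length(rep$input),
           n_surviving = length(rep$surviving), dropped = rep$dropped)))
  jsonlite::write_json(audit, file.path(dir, "audit.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
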