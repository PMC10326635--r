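# Synthetic multi-site metastasis cohorts with planted ground truth.
#
# The generator emulates the statistical structure the screen assumes:
# NB-distributed counts dominated by patient-level effects, tissue-site
# expression programs shared by a site's normal tissue and the metastases
# seeded there, a small set of genuinely metastasis-specific lncRNAs,
# same-strand overlaps between lncRNAs and coding/pseudogenes, TF peaks
# enriched in the regulatory windows of the planted genes, and survival
# times whose hazard depends on an expression group.

#' Simulation configuration
#'
#' Defaults emulate an autopsy cohort of 25 patients in which six
#' contributed primary tumors (one of them two), each patient contributed a
#' handful of metastases spread over five sites at realistic site
#' frequencies, and normal tissue and BPH references are available.
#'
#' @param n_patients number of patients.
#' @param n_primaries_per_patient integer (same for all) or per-patient
#'   integer vector of primary tumor samples.
#' @param mets_per_patient integer or per-patient vector of metastasis
#'   samples.
#' @param tissue_sites metastatic site labels.
#' @param site_weights sampling weights for assigning each metastasis a
#'   site; defaults to liver 12, bone 18, lymph node 40, adrenal 7,
#'   subdural 6 (autopsy-cohort frequencies).
#' @param n_normals_per_site normal tissue samples per non-prostate site.
#' @param n_bph benign prostatic hyperplasia (normal prostate) samples.
#' @param n_genes total genes; `fraction_lncRNA` of them are lncRNAs, the
#'   remainder split 60/40 protein-coding/pseudogene.
#' @param fraction_lncRNA proportion of genes that are lncRNAs.
#' @param n_planted_met_genes lncRNAs given a metastasis-specific effect.
#' @param planted_lfc absolute log2 fold change of planted genes in
#'   metastases (a fixed 80% are planted up, the rest down).
#' @param n_tissue_specific_genes lncRNAs per site elevated in that site's
#'   normal tissue AND its metastases (the confound the tissue filters
#'   target).
#' @param tissue_lfc log2 elevation of tissue-specific (and site-marker)
#'   genes in their site; tissue-restricted lncRNAs are near-binary across
#'   tissues, so the default is large.
#' @param n_site_marker_genes lncRNAs per site elevated in that site's
#'   normal tissue only (not its metastases). They carry no
#'   metastasis-vs-primary signal but populate the control comparisons
#'   with genuine tissue differences, as real normal tissues do.
#' @param patient_effect_sd SD of the per-patient, per-gene-block shift on
#'   the log2 mean scale (all effect sizes in this configuration are
#'   log2). Block structure (one scalar per patient per
#'   block of genes) makes patient identity, not status, dominate the
#'   expression covariance, while remaining invisible to per-sample size
#'   factors.
#' @param n_patient_blocks number of gene blocks sharing a patient effect.
#' @param dispersion NB dispersion alpha (Var = mu + alpha mu^2).
#' @param baseline_log_mean_range range (natural log) of baseline mean
#'   counts.
#' @param fraction_overlapping_lnc fraction of lncRNAs placed to overlap a
#'   coding or pseudogene on the same strand.
#' @param peak_enriched_tfs TF labels planted as enriched near the planted
#'   metastasis genes.
#' @param n_background_tfs additional TFs with uniform peak placement.
#' @param peak_fg_prob,peak_bg_prob probability that a TF peak falls in the
#'   regulatory window of a planted (foreground) / other (background)
#'   lncRNA; enriched TFs use `peak_fg_prob` on foreground genes, every
#'   other TF/gene combination uses `peak_bg_prob`.
#' @param seed integer RNG seed; identical seed + config gives
#'   bit-identical output.
#' @return validated `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 25L,
                              n_primaries_per_patient = c(2L, rep(1L, 5L),
                                                          rep(0L, 19L)),
                              mets_per_patient = 3L,
                              tissue_sites = c("liver", "bone", "lymph_node",
                                               "adrenal", "subdural"),
                              site_weights = c(liver = 12, bone = 18,
                                               lymph_node = 40, adrenal = 7,
                                               subdural = 6),
                              n_normals_per_site = 12L,
                              n_bph = 12L,
                              n_genes = 2500L,
                              fraction_lncRNA = 0.8,
                              n_planted_met_genes = 20L,
                              planted_lfc = 3,
                              n_tissue_specific_genes = 6L,
                              tissue_lfc = 7,
                              n_site_marker_genes = 40L,
                              patient_effect_sd = 1,
                              n_patient_blocks = 50L,
                              dispersion = 0.15,
                              baseline_log_mean_range = c(2.3, 6.9),
                              fraction_overlapping_lnc = 0.1,
                              peak_enriched_tfs = c("FOXA1", "HOXB13"),
                              n_background_tfs = 18L,
                              peak_fg_prob = 0.8,
                              peak_bg_prob = 0.15,
                              seed = 1L) {
  cfg <- list(
    n_patients = assert_count(n_patients, "n_patients"),
    n_primaries_per_patient = n_primaries_per_patient,
    mets_per_patient = mets_per_patient,
    tissue_sites = tissue_sites,
    site_weights = site_weights,
    n_normals_per_site = assert_count(n_normals_per_site,
                                      "n_normals_per_site", lower = 0L),
    n_bph = assert_count(n_bph, "n_bph", lower = 0L),
    n_genes = assert_count(n_genes, "n_genes", lower = 10L),
    fraction_lncRNA = assert_scalar_number(fraction_lncRNA,
                                           "fraction_lncRNA", 0, 1),
    n_planted_met_genes = assert_count(n_planted_met_genes,
                                       "n_planted_met_genes", lower = 0L),
    planted_lfc = assert_scalar_number(planted_lfc, "planted_lfc"),
    n_tissue_specific_genes = assert_count(n_tissue_specific_genes,
                                           "n_tissue_specific_genes",
                                           lower = 0L),
    tissue_lfc = assert_scalar_number(tissue_lfc, "tissue_lfc"),
    n_site_marker_genes = assert_count(n_site_marker_genes,
                                       "n_site_marker_genes", lower = 0L),
    patient_effect_sd = assert_scalar_number(patient_effect_sd,
                                             "patient_effect_sd", 0),
    n_patient_blocks = assert_count(n_patient_blocks, "n_patient_blocks"),
    dispersion = assert_scalar_number(dispersion, "dispersion", 0,
                                      strict_lower = TRUE),
    baseline_log_mean_range = baseline_log_mean_range,
    fraction_overlapping_lnc = assert_scalar_number(
      fraction_overlapping_lnc, "fraction_overlapping_lnc", 0, 1),
    peak_enriched_tfs = peak_enriched_tfs,
    n_background_tfs = assert_count(n_background_tfs, "n_background_tfs",
                                    lower = 0L),
    peak_fg_prob = assert_scalar_number(peak_fg_prob, "peak_fg_prob", 0, 1),
    peak_bg_prob = assert_scalar_number(peak_bg_prob, "peak_bg_prob", 0, 1),
    seed = assert_count(seed, "seed", lower = 0L))

  np <- cfg$n_patients
  expand <- function(x, name) {
    if (length(x) == 1L) x <- rep(x, np)
    if (length(x) != np)
      stop_(name, " must be a single integer or one per patient")
    if (any(x < 0) || any(x != round(x)))
      stop_(name, " must be non-negative integers")
    as.integer(x)
  }
  cfg$n_primaries_per_patient <- expand(n_primaries_per_patient,
                                        "n_primaries_per_patient")
  cfg$mets_per_patient <- expand(mets_per_patient, "mets_per_patient")
  if (any(cfg$n_primaries_per_patient + cfg$mets_per_patient == 0L))
    stop_("every patient must contribute at least one sample")
  if (length(cfg$tissue_sites) < 1L) stop_("need at least one tissue site")
  if (is.null(names(cfg$site_weights)))
    names(cfg$site_weights) <- cfg$tissue_sites[seq_along(cfg$site_weights)]
  cfg$site_weights <- cfg$site_weights[cfg$tissue_sites]
  cfg$site_weights[is.na(cfg$site_weights)] <- 1
  names(cfg$site_weights) <- cfg$tissue_sites
  if (length(cfg$baseline_log_mean_range) != 2L ||
      diff(cfg$baseline_log_mean_range) < 0)
    stop_("baseline_log_mean_range must be an increasing pair")
  n_lnc <- round(cfg$n_genes * cfg$fraction_lncRNA)
  need <- cfg$n_planted_met_genes +
    (cfg$n_tissue_specific_genes + cfg$n_site_marker_genes) *
    length(cfg$tissue_sites)
  if (need > n_lnc)
    stop_("planted + tissue-specific + marker genes exceed the number of ",
          "lncRNAs")
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate gene models
#'
#' Lays lncRNAs, protein-coding genes and pseudogenes along a synthetic
#' chromosome with random strands (0-based half-open coordinates), and
#' relocates one masking gene inside each of a configurable subset of
#' lncRNAs so that they overlap on the same strand by >= 1 bp. TSS = start
#' on `+`, end - 1 on `-`.
#'
#' @param config a [simulation_config()].
#' @return validated gene model data.frame.
#' @export
simulate_gene_models <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed + 1L, {
    n <- config$n_genes
    n_lnc <- round(n * config$fraction_lncRNA)
    n_cod <- round((n - n_lnc) * 0.6)
    n_pse <- n - n_lnc - n_cod
    biotype <- sample(rep(c("lncRNA", "protein_coding", "pseudogene"),
                          c(n_lnc, n_cod, n_pse)))
    width <- ifelse(biotype == "lncRNA",
                    sample(500:8000, n, replace = TRUE),
                    sample(2000:20000, n, replace = TRUE))
    gap <- sample(10000:30000, n, replace = TRUE)
    start <- cumsum(gap) + c(0, cumsum(width))[seq_len(n)]
    end <- start + width
    strand <- sample(c("+", "-"), n, replace = TRUE)
    idx <- seq_len(n)
    gene_id <- character(n)
    gene_id[biotype == "lncRNA"] <- sprintf("lnc-%04d", seq_len(n_lnc))
    gene_id[biotype == "protein_coding"] <- sprintf("pcg-%04d", seq_len(n_cod))
    gene_id[biotype == "pseudogene"] <- sprintf("psg-%04d", seq_len(n_pse))

    # plant same-strand overlaps: move a masking gene inside the lncRNA
    lnc_idx <- idx[biotype == "lncRNA"]
    mask_idx <- idx[biotype != "lncRNA"]
    n_ov <- round(config$fraction_overlapping_lnc * length(lnc_idx))
    n_ov <- min(n_ov, length(mask_idx))
    if (n_ov > 0L) {
      ov_lnc <- sample(lnc_idx, n_ov)
      ov_mask <- sample(mask_idx, n_ov)
      for (k in seq_len(n_ov)) {
        i <- ov_lnc[k]; j <- ov_mask[k]
        w <- max(50L, min(width[j], width[i] - 2L))
        start[j] <- start[i] + 1L
        end[j] <- start[j] + w
        strand[j] <- strand[i]
      }
    }
    models <- data.frame(
      gene_id = gene_id, chrom = "chr1",
      start = as.integer(start), end = as.integer(end),
      strand = strand, biotype = biotype,
      tss = as.integer(ifelse(strand == "+", start, end - 1L)),
      transcript_length = pmax(200L, as.integer(round(0.7 * width))),
      stringsAsFactors = FALSE)
    validate_gene_models(models)
    models
  })
}

# Seeded selection of planted truth, shared by the count and peak
# generators so they agree on which genes carry signal.
plant_truth <- function(config, models) {
  lnc <- models$gene_id[models$biotype == "lncRNA"]
  n_sites <- length(config$tissue_sites)
  with_seed(config$seed + 2L, {
    picked <- sample(lnc, config$n_planted_met_genes +
                       (config$n_tissue_specific_genes +
                          config$n_site_marker_genes) * n_sites)
    take <- function(k) {
      out <- picked[seq_len(k)]
      picked <<- picked[-seq_len(k)]
      out
    }
    n_up <- ceiling(0.8 * config$n_planted_met_genes)
    planted <- data.frame(
      gene_id = take(config$n_planted_met_genes),
      direction = rep(c(1L, -1L),
                      c(n_up, config$n_planted_met_genes - n_up)),
      stringsAsFactors = FALSE)
    split_sites <- function(per_site) {
      if (per_site == 0L) {
        out <- rep(list(character(0)), n_sites)
      } else {
        out <- split(take(per_site * n_sites),
                     rep(config$tissue_sites, each = per_site))
        out <- out[config$tissue_sites]
      }
      names(out) <- config$tissue_sites
      out
    }
    tissue <- split_sites(config$n_tissue_specific_genes)
    markers <- split_sites(config$n_site_marker_genes)
    truth <- list(
      planted_met_genes = planted,
      tissue_specific_genes = tissue,
      site_marker_genes = markers,
      overlapping_lncRNAs = overlapping_lncrnas(models),
      peak_enriched_tfs = config$peak_enriched_tfs)
    class(truth) <- "synthetic_truth"
    truth
  })
}

# lncRNAs with a same-strand >= 1 bp overlap with a coding/pseudogene,
# computed from the final geometry (the ground truth for the stage-4
# filter).
overlapping_lncrnas <- function(models) {
  lnc <- models[models$biotype == "lncRNA", , drop = FALSE]
  mask <- models[models$biotype != "lncRNA", , drop = FALSE]
  if (!nrow(lnc) || !nrow(mask)) return(character(0))
  hit <- same_strand_overlap(lnc, mask)
  lnc$gene_id[hit]
}

#' Simulate cohort counts, sample table and planted truth
#'
#' Counts are NB draws with mean
#' exp(baseline + patient_effect + status_effect + site_effect):
#' planted metastasis genes carry +/- `planted_lfc` * log(2) in metastasis
#' samples only; tissue-specific genes carry `tissue_lfc` * log(2) in every
#' sample (normal or metastasis) located at their site; patient effects are
#' block-wise N(0, patient_effect_sd^2) shifts shared by all of a patient's
#' samples.
#'
#' @param config a [simulation_config()].
#' @param models gene models, defaulting to [simulate_gene_models()] on the
#'   same config.
#' @return list with `counts` (integer matrix), `samples` (sample table),
#'   `truth` (`synthetic_truth`), and `models`.
#' @export
simulate_cohort_counts <- function(config,
                                   models = simulate_gene_models(config)) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- plant_truth(config, models)
  with_seed(config$seed + 3L, {
    pats <- sprintf("P%02d", seq_len(config$n_patients))
    rows <- list()
    for (i in seq_len(config$n_patients)) {
      npr <- config$n_primaries_per_patient[i]
      if (npr > 0L)
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pats[i], cancer_status = "primary",
          tissue_site = "prostate", stringsAsFactors = FALSE)[rep(1L, npr), ]
      nme <- config$mets_per_patient[i]
      if (nme > 0L)
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pats[i], cancer_status = "metastasis",
          tissue_site = sample(config$tissue_sites, nme, replace = TRUE,
                               prob = config$site_weights),
          stringsAsFactors = FALSE)
    }
    for (site in config$tissue_sites) {
      if (config$n_normals_per_site > 0L)
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = sprintf("N-%s-%02d", site,
                               seq_len(config$n_normals_per_site)),
          cancer_status = "normal", tissue_site = site,
          stringsAsFactors = FALSE)
    }
    if (config$n_bph > 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = sprintf("B%02d", seq_len(config$n_bph)),
        cancer_status = "bph", tissue_site = "prostate",
        stringsAsFactors = FALSE)
    samples <- do.call(rbind, rows)
    samples <- data.frame(sample_id = sprintf("S%03d", seq_len(nrow(samples))),
                          samples, stringsAsFactors = FALSE)
    rownames(samples) <- NULL
    validate_sample_table(samples)

    g <- nrow(models)
    ns <- nrow(samples)
    baseline <- stats::runif(g, config$baseline_log_mean_range[1L],
                             config$baseline_log_mean_range[2L])
    block <- rep(seq_len(config$n_patient_blocks), length.out = g)
    all_pats <- unique(samples$patient_id)
    pat_eff <- matrix(stats::rnorm(length(all_pats) * config$n_patient_blocks,
                                   0, config$patient_effect_sd),
                      nrow = length(all_pats),
                      dimnames = list(all_pats, NULL))
    logmu <- matrix(baseline, g, ns)
    # all configured effect sizes are log2; the model works in natural log
    logmu <- logmu +
      t(pat_eff[samples$patient_id, block, drop = FALSE]) * log(2)

    is_met <- samples$cancer_status == "metastasis"
    pi <- match(truth$planted_met_genes$gene_id, models$gene_id)
    if (length(pi) && any(is_met))
      logmu[pi, is_met] <- logmu[pi, is_met] +
        truth$planted_met_genes$direction * config$planted_lfc * log(2)
    for (site in names(truth$tissue_specific_genes)) {
      ti <- match(truth$tissue_specific_genes[[site]], models$gene_id)
      at <- samples$tissue_site == site
      if (length(ti) && any(at))
        logmu[ti, at] <- logmu[ti, at] + config$tissue_lfc * log(2)
      # site markers: expressed by the normal tissue itself, diluted away
      # in the metastasis bulk, so they carry no stage-1 signal
      mi <- match(truth$site_marker_genes[[site]], models$gene_id)
      atn <- at & samples$cancer_status == "normal"
      if (length(mi) && any(atn))
        logmu[mi, atn] <- logmu[mi, atn] + config$tissue_lfc * log(2)
    }
    counts <- matrix(stats::rnbinom(g * ns, mu = exp(logmu),
                                    size = 1 / config$dispersion),
                     g, ns, dimnames = list(models$gene_id,
                                            samples$sample_id))
    storage.mode(counts) <- "integer"
    list(counts = counts, samples = samples, truth = truth, models = models)
  })
}

#' Simulate per-TF ChIP-seq peak sets
#'
#' For each TF, a peak (width 150-400 bp) is dropped uniformly into the
#' regulatory window of each lncRNA with probability `peak_bg_prob`;
#' enriched TFs use `peak_fg_prob` for the planted metastasis genes instead.
#'
#' @param config a [simulation_config()].
#' @param models gene models.
#' @param truth planted truth from the same config/models (recomputed when
#'   `NULL`).
#' @return named list of `peak_set` objects, one per TF.
#' @export
simulate_peaks <- function(config, models, truth = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(truth)) truth <- plant_truth(config, models)
  lnc <- models[models$biotype == "lncRNA", , drop = FALSE]
  win <- regulatory_regions(lnc)
  fg <- win$gene_id %in% truth$planted_met_genes$gene_id
  tfs <- c(config$peak_enriched_tfs,
           if (config$n_background_tfs > 0L)
             sprintf("TF%02d", seq_len(config$n_background_tfs)))
  with_seed(config$seed + 4L, {
    out <- lapply(tfs, function(tf) {
      p <- rep(config$peak_bg_prob, nrow(win))
      if (tf %in% config$peak_enriched_tfs)
        p[fg] <- config$peak_fg_prob
      hit <- stats::runif(nrow(win)) < p
      if (!any(hit))
        return(peak_set(data.frame(chrom = character(0), start = integer(0),
                                   end = integer(0)), tf))
      w <- sample(150:400, sum(hit), replace = TRUE)
      lo <- win$start[hit]
      hi <- pmax(lo + 1L, win$end[hit] - w)
      s <- as.integer(lo + floor(stats::runif(sum(hit)) * (hi - lo)))
      peak_set(data.frame(chrom = win$chrom[hit], start = s, end = s + w,
                          stringsAsFactors = FALSE), tf)
    })
    names(out) <- tfs
    out
  })
}

#' Simulate a survival cohort with a planted expression hazard ratio
#'
#' Event times are exponential; subjects in the high-expression group (top
#' quartile of a log-normal expression value) have their hazard multiplied
#' by `hr_expression`. Censoring is independent per-subject exponential,
#' calibrated so each subject is censored with probability `censor_rate`.
#' Clinical covariates (age, PSA, Gleason score, pT) are drawn from fixed
#' categorical/continuous distributions and carry no hazard effect.
#'
#' @param n cohort size (>= 10), default 81.
#' @param hr_expression true hazard ratio of high vs low expression (> 0).
#' @param censor_rate per-subject censoring probability in \[0, 1).
#' @param seed RNG seed.
#' @param base_hazard baseline event rate per time unit.
#' @return data.frame of survival records: sample_id, time, event, age,
#'   psa, gleason, pt, expression, expr_group.
#' @export
simulate_survival_cohort <- function(n = 81L, hr_expression = 2,
                                     censor_rate = 0.3, seed = 1L,
                                     base_hazard = 0.02) {
  n <- assert_count(n, "n", lower = 10L)
  assert_scalar_number(hr_expression, "hr_expression", 0, strict_lower = TRUE)
  if (!is.numeric(censor_rate) || censor_rate < 0 || censor_rate >= 1)
    stop_("censor_rate must lie in [0, 1)")
  with_seed(seed, {
    expression <- stats::rlnorm(n, meanlog = 3, sdlog = 1)
    expr_group <- dichotomize_q3(expression)
    h <- base_hazard * ifelse(expr_group == "high", hr_expression, 1)
    t_event <- stats::rexp(n, h)
    if (censor_rate > 0) {
      t_cens <- stats::rexp(n, h * censor_rate / (1 - censor_rate))
    } else {
      t_cens <- rep(Inf, n)
    }
    data.frame(
      sample_id = sprintf("PT%03d", seq_len(n)),
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      age = round(stats::rnorm(n, 62, 8)),
      psa = round(stats::rlnorm(n, log(9), 0.8), 1),
      gleason = sample(6:9, n, replace = TRUE,
                       prob = c(0.25, 0.45, 0.2, 0.1)),
      pt = sample(2:6, n, replace = TRUE,
                  prob = c(0.3, 0.3, 0.2, 0.15, 0.05)),
      expression = expression,
      expr_group = expr_group,
      stringsAsFactors = FALSE)
  })
}

#' Write a simulated cohort to an output directory
#'
#' Emits counts.tsv, samples.tsv, gene_models.bed, gene_models.gtf, one
#' BED3 per TF under peaks/, and truth tables (planted genes,
#' tissue-specific genes).
#'
#' @param cohort list from [simulate_cohort_counts()].
#' @param peaks optional named list of peak sets.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir, peaks = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_matrix(cohort$counts, file.path(dir, "counts.tsv"))
  write_sample_table(cohort$samples, file.path(dir, "samples.tsv"))
  write_gene_models(cohort$models, file.path(dir, "gene_models.bed"), "bed")
  write_gene_models(cohort$models, file.path(dir, "gene_models.gtf"), "gtf")
  utils::write.table(cohort$truth$planted_met_genes,
                     file.path(dir, "truth_planted.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ts <- cohort$truth$tissue_specific_genes
  utils::write.table(
    data.frame(site = rep(names(ts), lengths(ts)),
               gene_id = unlist(ts, use.names = FALSE)),
    file.path(dir, "truth_tissue_specific.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  if (!is.null(peaks)) {
    dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
    for (tf in names(peaks))
      write_peaks(peaks[[tf]], file.path(dir, "peaks", paste0(tf, ".bed")))
  }
  invisible(dir)
}
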