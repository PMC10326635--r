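test_that("identical seed and config give bit-identical cohorts", {
  cfg <- small_sim_config(seed = 5L)
  a <- simulate_cohort_counts(cfg)
  b <- simulate_cohort_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_peaks(cfg, a$models, a$truth),
                   simulate_peaks(cfg, b$models, b$truth))
  expect_identical(simulate_survival_cohort(seed = 9L),
                   simulate_survival_cohort(seed = 9L))
  # a different seed changes the data
  expect_false(identical(
    a$counts, simulate_cohort_counts(small_sim_config(seed = 6L))$counts))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(dispersion = 0), "> 0")
  expect_error(simulation_config(fraction_lncRNA = 1.2), "<= 1")
  expect_error(simulation_config(n_patients = 3L,
                                 n_primaries_per_patient = 0L,
                                 mets_per_patient = 0L),
               "at least one sample")
  expect_error(simulation_config(n_genes = 50L, n_planted_met_genes = 45L),
               "exceed")
  expect_error(simulation_config(mets_per_patient = c(1L, 2L)),
               "one per patient")
})

test_that("simulated counts match NB moments", {
  cfg <- simulation_config(
    n_patients = 100L, n_primaries_per_patient = 0L,
    mets_per_patient = 100L, tissue_sites = "liver",
    site_weights = c(liver = 1), n_normals_per_site = 0L, n_bph = 2L,
    n_genes = 10L, fraction_lncRNA = 0.8, n_planted_met_genes = 0L,
    n_tissue_specific_genes = 0L, n_site_marker_genes = 0L,
    patient_effect_sd = 0, dispersion = 0.2, seed = 31L)
  coh <- simulate_cohort_counts(cfg)
  mets <- coh$samples$sample_id[coh$samples$cancer_status == "metastasis"]
  cnt <- coh$counts[, mets]           # 10 genes x 10,000 draws
  mu <- rowMeans(cnt)
  v <- apply(cnt, 1, var)
  expect_true(all(abs(v / (mu + 0.2 * mu^2) - 1) < 0.1))
})

test_that("planted truth categories are disjoint and cover real genes", {
  cfg <- small_sim_config(seed = 2L)
  coh <- simulate_cohort_counts(cfg)
  tr <- coh$truth
  planted <- tr$planted_met_genes$gene_id
  tissue <- unlist(tr$tissue_specific_genes, use.names = FALSE)
  markers <- unlist(tr$site_marker_genes, use.names = FALSE)
  expect_length(intersect(planted, tissue), 0)
  expect_length(intersect(planted, markers), 0)
  expect_length(intersect(tissue, markers), 0)
  expect_true(all(c(planted, tissue, markers, tr$overlapping_lncRNAs) %in%
                    coh$models$gene_id))
  expect_true(all(tr$planted_met_genes$direction %in% c(-1L, 1L)))
  expect_equal(length(planted), cfg$n_planted_met_genes)
  expect_equal(lengths(tr$tissue_specific_genes),
               rep(cfg$n_tissue_specific_genes, 3), ignore_attr = TRUE)
})

test_that("a signal-free cohort yields no differential expression", {
  cfg <- simulation_config(
    n_patients = 10L, n_primaries_per_patient = 1L, mets_per_patient = 2L,
    tissue_sites = "liver", site_weights = c(liver = 1),
    n_normals_per_site = 2L, n_bph = 2L,
    n_genes = 1250L, fraction_lncRNA = 0.8,
    n_planted_met_genes = 0L, n_tissue_specific_genes = 0L,
    n_site_marker_genes = 0L, planted_lfc = 0, patient_effect_sd = 0,
    dispersion = 0.15, seed = 12L)
  coh <- simulate_cohort_counts(cfg)
  s <- coh$samples
  de <- wald_test_two_group(
    coh$counts[coh$models$gene_id[coh$models$biotype == "lncRNA"], ],
    s$sample_id[s$cancer_status == "primary"],
    s$sample_id[s$cancer_status == "metastasis"])
  expect_lte(sum(de$padj < 0.15, na.rm = TRUE), 0.01 * nrow(de))
})

test_that("patient identity dominates expression variance over status", {
  cfg <- simulation_config(
    n_patients = 8L, n_primaries_per_patient = c(2L, rep(1L, 5L), 0L, 0L),
    mets_per_patient = 3L, tissue_sites = c("liver", "bone"),
    site_weights = c(liver = 1, bone = 1), n_normals_per_site = 2L,
    n_bph = 2L, n_genes = 500L, n_planted_met_genes = 0L,
    n_tissue_specific_genes = 0L, n_site_marker_genes = 0L,
    planted_lfc = 0, patient_effect_sd = 2, seed = 3L)
  coh <- simulate_cohort_counts(cfg)
  s <- coh$samples
  paired <- intersect(s$patient_id[s$cancer_status == "primary"],
                      s$patient_id[s$cancer_status == "metastasis"])
  sub <- s[s$patient_id %in% paired &
             s$cancer_status %in% c("primary", "metastasis"), ]
  v <- vst_counts(coh$counts[, sub$sample_id])
  pc <- stats::prcomp(t(v), rank. = 2)$x
  r2 <- function(f) mean(vapply(1:2, function(k)
    summary(stats::lm(pc[, k] ~ factor(f)))$r.squared, numeric(1)))
  expect_gt(r2(sub$patient_id), r2(sub$cancer_status))
})

test_that("gene model geometry obeys the overlap and strand rules", {
  cfg <- small_sim_config(seed = 8L)
  models <- simulate_gene_models(cfg)
  validate_gene_models(models)
  # overlap fraction 0: no lncRNA overlaps a masking gene
  cfg0 <- small_sim_config(seed = 8L, fraction_overlapping_lnc = 0)
  coh0 <- simulate_cohort_counts(cfg0, simulate_gene_models(cfg0))
  expect_length(coh0$truth$overlapping_lncRNAs, 0)
  # with the default fraction some planted overlaps exist
  coh <- simulate_cohort_counts(cfg, models)
  expect_gt(length(coh$truth$overlapping_lncRNAs), 0)
  # TSS convention per strand
  expect_true(all(ifelse(models$strand == "+", models$tss == models$start,
                         models$tss == models$end - 1L)))
})

test_that("peak sets are sorted, placed in windows, and enrichable", {
  cfg <- simulation_config(
    n_genes = 1300L, fraction_lncRNA = 0.79, n_planted_met_genes = 27L,
    n_site_marker_genes = 0L, n_tissue_specific_genes = 0L,
    peak_enriched_tfs = "FOXA1", n_background_tfs = 5L,
    peak_fg_prob = 0.9, peak_bg_prob = 0.1, seed = 6L)
  models <- simulate_gene_models(cfg)
  coh <- simulate_cohort_counts(cfg, models)
  peaks <- simulate_peaks(cfg, models, coh$truth)
  expect_named(peaks, c("FOXA1", paste0("TF0", 1:5)))
  for (p in peaks) expect_true(all(diff(p$start) >= 0))
  lnc <- models[models$biotype == "lncRNA", ]
  bm <- binding_matrix(regulatory_regions(lnc), peaks)
  fe <- fisher_enrichment(bm, coh$truth$planted_met_genes$gene_id)
  expect_true(fe$p_adjusted[fe$tf_name == "FOXA1"] < 0.15)
  # a TF with zero peaks has zero overlaps and p = 1
  empty <- peak_set(data.frame(chrom = character(0), start = integer(0),
                               end = integer(0)), "NONE")
  bm2 <- cbind(bm, NONE = count_peak_overlaps(regulatory_regions(lnc),
                                              empty))
  fe2 <- fisher_enrichment(bm2, coh$truth$planted_met_genes$gene_id)
  expect_equal(fe2$p_one_tailed[fe2$tf_name == "NONE"], 1)
})

test_that("survival generator honors censoring and the planted hazard", {
  d0 <- simulate_survival_cohort(n = 200, hr_expression = 1.5,
                                 censor_rate = 0, seed = 2L)
  expect_true(all(d0$event == 1L))
  expect_true(all(d0$time > 0))
  expect_error(simulate_survival_cohort(censor_rate = 1), "censor_rate")
  expect_error(simulate_survival_cohort(hr_expression = 0), "> 0")
  expect_error(simulate_survival_cohort(n = 5), ">= 10")

  d <- simulate_survival_cohort(n = 500, hr_expression = 2,
                                censor_rate = 0.3, seed = 11L)
  cx <- cox_stratified(d, d$expr_group)
  hr <- cx$table$hr[cx$table$variable == "expression" & !cx$table$reference]
  expect_gte(hr, 1.7)
  expect_lte(hr, 2.3)
})

test_that("log-rank p-values are uniform when no hazard effect is planted", {
  ps <- vapply(1:200, function(i) {
    d <- simulate_survival_cohort(n = 60, hr_expression = 1,
                                  censor_rate = 0.2, seed = 1000L + i)
    km_logrank(d$time, d$event, d$expr_group)$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("cohort writers round-trip through the readers", {
  cfg <- small_sim_config(seed = 4L)
  coh <- simulate_cohort_counts(cfg)
  peaks <- simulate_peaks(cfg, coh$models, coh$truth)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir, peaks = peaks)
  expect_identical(read_count_matrix(file.path(dir, "counts.tsv")),
                   coh$counts)
  expect_equal(read_sample_table(file.path(dir, "samples.tsv")),
               coh$samples)
  mb <- read_gene_models(file.path(dir, "gene_models.bed"), "bed")
  expect_equal(mb, coh$models[, names(mb)])
  tf1 <- names(peaks)[1]
  back <- read_peaks(file.path(dir, "peaks", paste0(tf1, ".bed")), tf1)
  expect_equal(as.data.frame(back), as.data.frame(peaks[[tf1]]))
})
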