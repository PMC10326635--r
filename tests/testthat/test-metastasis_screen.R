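# Stage-level behavior on hand-built cohorts with known structure, plus
# end-to-end funnel properties on small simulated cohorts.

lnc_model_row <- function(id, chrom = "chr1", start = 0L, end = 1000L,
                          strand = "+", biotype = "lncRNA") {
  toy_models(list(id, chrom, start, end, strand, biotype))
}

test_that("stage 1 keeps planted genes with their true direction and drops
           strictly at the threshold", {
  cfg <- small_sim_config(seed = 9L)
  coh <- simulate_cohort_counts(cfg)
  s1 <- stage1_de(coh$counts, coh$samples, coh$models)
  planted <- coh$truth$planted_met_genes
  hit <- intersect(planted$gene_id, s1$report$surviving)
  expect_gte(length(hit), 0.7 * nrow(planted))
  expect_equal(unname(s1$directions[hit]),
               planted$direction[match(hit, planted$gene_id)])
  # dropped genes all carry a reason
  rep <- s1$report
  expect_setequal(c(rep$surviving, rep$dropped$gene_id), rep$input)

  # "less than" is strict: a gene whose padj equals the threshold drops
  thr <- max(s1$de$padj[s1$de$gene_id %in% rep$surviving], na.rm = TRUE)
  s1b <- stage1_de(coh$counts, coh$samples, coh$models,
                   screen_config(stage1_padj = thr))
  at_thr <- s1$de$gene_id[!is.na(s1$de$padj) & s1$de$padj == thr]
  expect_true(all(!at_thr %in% s1b$report$surviving))
  expect_true(all(s1b$report$surviving %in% rep$surviving))
})

test_that("stage 2 drops same-direction tissue signal and keeps the rest", {
  # 4 primaries, 4 liver + 4 bone normals, 2 BPH; constant counts in groups
  samples <- toy_samples(
    c(rep("primary", 4), rep("normal", 4), rep("normal", 4), rep("bph", 2)),
    c(rep("prostate", 4), rep("liver", 4), rep("bone", 4),
      rep("prostate", 2)))
  val <- function(prim, liver, bone, bph)
    c(rep(prim, 4), rep(liver, 4), rep(bone, 4), rep(bph, 2))
  counts <- toy_counts(rbind(
    lncLIV = val(100L, 800L, 100L, 100L),   # liver-elevated: confound
    lncMET = val(100L, 100L, 100L, 100L),   # flat in controls: genuine
    lncOPP = val(100L, 20L, 100L, 100L)),   # liver-DEPRESSED: opposite
    genes = c("lncLIV", "lncMET", "lncOPP"))
  models <- rbind(lnc_model_row("lncLIV"),
                  lnc_model_row("lncMET", start = 2000L, end = 3000L),
                  lnc_model_row("lncOPP", start = 4000L, end = 5000L))
  directions <- c(lncLIV = 1L, lncMET = 1L, lncOPP = 1L)
  rep2 <- stage2_tissue_filters(counts, samples, directions, models)
  expect_setequal(rep2$surviving, c("lncMET", "lncOPP"))
  drop <- rep2$dropped
  expect_equal(drop$gene_id, "lncLIV")
  expect_match(drop$comparison, "liver")
  expect_equal(drop$reason, "tissue_specific_control")

  # inverted reading keeps the same-direction gene and drops the opposite
  rep2b <- stage2_tissue_filters(counts, samples, directions, models,
                                 screen_config(stage2_rule =
                                                 "opposite-sign-drop"))
  expect_true("lncLIV" %in% rep2b$surviving)
  expect_false("lncOPP" %in% rep2b$surviving)
})

test_that("stage 2 skips filters with missing controls and warns", {
  samples <- toy_samples(c(rep("primary", 3), rep("metastasis", 3)),
                         c(rep("prostate", 3), rep("liver", 3)))
  counts <- toy_counts(matrix(100L, 2, 6), genes = c("lncA", "lncB"))
  models <- rbind(lnc_model_row("lncA"),
                  lnc_model_row("lncB", start = 2000L, end = 3000L))
  expect_warning(
    expect_warning(
      rep2 <- stage2_tissue_filters(counts, samples, c(lncA = 1L), models),
      "no non-prostate normal"),
    "no BPH")
  expect_equal(rep2$surviving, "lncA")
})

test_that("stage 3 applies the more-than-two-patients rule with the
           two-primary mean convention and ties as consistent", {
  ids <- c("a1", "a2", "b1", "b2",
           unlist(lapply(2:6, function(i) paste0(c("c", "d", "e"), i))))
  status <- c("primary", "primary", "metastasis", "metastasis",
              rep(c("primary", "metastasis", "metastasis"), 5))
  patient <- c(rep("p1", 4), rep(paste0("p", 2:6), each = 3))
  samples <- data.frame(sample_id = ids, patient_id = patient,
                        cancer_status = status,
                        tissue_site = ifelse(status == "primary",
                                             "prostate", "liver"),
                        stringsAsFactors = FALSE)
  row_for <- function(p1_prim, p1_mets, per_patient) {
    out <- c(p1_prim, p1_mets)
    for (i in 1:5) out <- c(out, per_patient[[i]])
    out
  }
  # X: patients (+,+,+,+,-,-) -> 2 opposite, retained
  x <- row_for(c(4L, 6L), c(10L, 10L),
               list(c(100L, 150L, 150L), c(100L, 150L, 150L),
                    c(100L, 150L, 150L), c(100L, 50L, 50L),
                    c(100L, 50L, 50L)))
  # Y: patients (+,+,+,-,-,-) -> 3 opposite, removed
  y <- row_for(c(4L, 6L), c(10L, 10L),
               list(c(100L, 150L, 150L), c(100L, 150L, 150L),
                    c(100L, 50L, 50L), c(100L, 50L, 50L),
                    c(100L, 50L, 50L)))
  # Z: every patient difference exactly zero -> ties, retained
  z <- rep(10L, length(ids))
  counts <- toy_counts(rbind(X = x, Y = y, Z = z),
                       genes = c("X", "Y", "Z"), samples = ids)
  directions <- c(X = 1L, Y = 1L, Z = 1L)
  rep3 <- stage3_pairwise(counts, samples, directions,
                          factors = rep(1, length(ids)))
  expect_setequal(rep3$surviving, c("X", "Z"))
  expect_equal(rep3$dropped$gene_id, "Y")
  expect_match(rep3$dropped$comparison, "3_of_6")
})

test_that("stage 3 passes everything with a warning when nothing is paired", {
  samples <- toy_samples(c("primary", "metastasis"), c("prostate", "liver"),
                         patient = c("p1", "p2"))
  counts <- toy_counts(matrix(10L, 1, 2), genes = "X")
  expect_warning(rep3 <- stage3_pairwise(counts, samples, c(X = 1L),
                                         factors = c(1, 1)),
                 "no patient")
  expect_equal(rep3$surviving, "X")
})

test_that("stage 4 flags same-strand >= 1 bp overlaps, half-open", {
  models <- rbind(
    toy_models(list("ln1", "chr1", 100, 200, "+", "lncRNA"),
               list("pc1", "chr1", 150, 300, "+", "protein_coding")),
    toy_models(list("ln2", "chr2", 100, 200, "+", "lncRNA"),
               list("pc2", "chr2", 200, 300, "+", "protein_coding")),
    toy_models(list("ln3", "chr3", 100, 200, "+", "lncRNA"),
               list("ps3", "chr3", 199, 300, "+", "pseudogene")),
    toy_models(list("ln4", "chr4", 100, 200, "+", "lncRNA"),
               list("pc4", "chr4", 150, 300, "-", "protein_coding")))
  dirs <- c(ln1 = 1L, ln2 = 1L, ln3 = -1L, ln4 = 1L)
  s4 <- stage4_overlap_filter(dirs, models)
  flags <- setNames(s4$candidates$curation_flag, s4$candidates$gene_id)
  expect_equal(flags[["ln1"]], "needs_curation")   # 50 bp overlap
  expect_equal(flags[["ln2"]], "clean")            # abutting, half-open
  expect_equal(flags[["ln3"]], "needs_curation")   # single base pair
  expect_equal(flags[["ln4"]], "clean")            # opposite strand
  expect_equal(nrow(s4$candidates), 4L)            # all kept without file
  expect_equal(s4$candidates$direction,
               unname(dirs[s4$candidates$gene_id]))

  # curation decisions drop only flagged entries marked "drop"
  cur <- data.frame(gene_id = c("ln1", "ln2"), decision = c("drop", "drop"))
  s4b <- stage4_overlap_filter(dirs, models, curation = cur)
  expect_false("ln1" %in% s4b$candidates$gene_id)
  expect_true("ln2" %in% s4b$candidates$gene_id)  # clean: file ignored
  expect_equal(s4b$report$dropped$reason, "curation_drop")

  expect_error(stage4_overlap_filter(c(zz = 1L), models),
               "missing from gene models.*zz")
})

test_that("a zero discovery threshold empties the funnel but keeps reports", {
  cfg <- small_sim_config(seed = 10L)
  coh <- simulate_cohort_counts(cfg)
  res <- run_screen(coh$counts, coh$samples, coh$models,
                    screen_config(stage1_padj = 0))
  expect_equal(nrow(res$candidates), 0L)
  expect_length(res$reports, 4L)
})

test_that("screen runs are deterministic and the funnel audit is complete", {
  for (seed in c(3L, 14L)) {
    cfg <- small_sim_config(seed = seed)
    coh <- simulate_cohort_counts(cfg)
    r1 <- run_screen(coh$counts, coh$samples, coh$models)
    r2 <- run_screen(coh$counts, coh$samples, coh$models)
    expect_identical(r1, r2)
    expect_true(all(diff(r1$funnel) <= 0))
    for (rep in r1$reports) {
      expect_setequal(c(rep$surviving, unique(rep$dropped$gene_id)),
                      rep$input)
      expect_length(intersect(rep$surviving, rep$dropped$gene_id), 0)
    }
    # direction conservation: final direction equals the stage-1 LFC sign
    de <- r1$stage1_de
    lfc <- de$log2FoldChange[match(r1$candidates$gene_id, de$gene_id)]
    expect_equal(r1$candidates$direction, ifelse(lfc >= 0, 1L, -1L))
  }
})

test_that("screen outputs are written with a machine-readable audit", {
  cfg <- small_sim_config(seed = 3L)
  coh <- simulate_cohort_counts(cfg)
  res <- run_screen(coh$counts, coh$samples, coh$models)
  dir <- withr::local_tempdir()
  write_screen_results(res, dir)
  cand <- utils::read.delim(file.path(dir, "candidates.tsv"))
  expect_equal(cand$gene_id, res$candidates$gene_id)
  audit <- jsonlite::read_json(file.path(dir, "audit.json"),
                               simplifyVector = TRUE)
  expect_equal(audit$funnel$stage4, unname(res$funnel[["stage4"]]))
  expect_equal(length(audit$stages), 4L)
})
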