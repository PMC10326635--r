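# Shared fixture builders. Everything is generated in code; no data files.

# small labelled count matrix
toy_counts <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# NB matrix with per-gene means mu, common dispersion alpha
nb_counts <- function(n_genes, n_samples, mu, alpha, seed = 1) {
  set.seed(seed)
  if (length(mu) == 1L) mu <- rep(mu, n_genes)
  m <- matrix(stats::rnbinom(n_genes * n_samples, mu = mu, size = 1 / alpha),
              n_genes, n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  storage.mode(m) <- "integer"
  m
}

# minimal gene model table from a compact spec list
toy_models <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(gene_id = r[[1]], chrom = r[[2]],
               start = as.integer(r[[3]]), end = as.integer(r[[4]]),
               strand = r[[5]], biotype = r[[6]],
               stringsAsFactors = FALSE)))
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df$transcript_length <- pmax(200L, df$end - df$start)
  df
}

# sample table for hand-built screen scenarios
toy_samples <- function(status, site, patient = NULL) {
  n <- length(status)
  data.frame(sample_id = paste0("s", seq_len(n)),
             patient_id = patient %||% paste0("p", seq_len(n)),
             cancer_status = status, tissue_site = site,
             stringsAsFactors = FALSE)
}

# small simulation config for fast end-to-end runs
small_sim_config <- function(seed = 1L, n_genes = 400L,
                             n_planted_met_genes = 8L, n_bph = 6L,
                             dispersion = 0.15, ...) {
  simulation_config(
    n_patients = 8L,
    n_primaries_per_patient = c(2L, rep(1L, 4L), rep(0L, 3L)),
    mets_per_patient = 3L,
    tissue_sites = c("liver", "bone", "lymph_node"),
    site_weights = c(liver = 1, bone = 1, lymph_node = 2),
    n_normals_per_site = 6L, n_bph = n_bph,
    n_genes = n_genes, fraction_lncRNA = 0.8,
    n_planted_met_genes = n_planted_met_genes, planted_lfc = 3,
    n_tissue_specific_genes = 3L, tissue_lfc = 7,
    n_site_marker_genes = 10L,
    patient_effect_sd = 1, dispersion = dispersion,
    seed = seed, ...)
}

# brute-force BH step-up: padj_(i) = min_{j >= i} min(1, m p_(j) / j)
bh_brute_force <- function(p) {
  ok <- !is.na(p)
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  o <- order(pv)
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(m * pv[o][i:m] / (i:m)))
  tmp <- numeric(m)
  tmp[o] <- adj
  out[ok] <- tmp
  out
}

# quadratic all-pairs interval overlap oracle (0-based half-open)
overlap_oracle <- function(regions, peaks) {
  vapply(seq_len(nrow(regions)), function(i) {
    sum(peaks$chrom == regions$chrom[i] &
          peaks$start < regions$end[i] &
          peaks$end > regions$start[i])
  }, integer(1))
}

# independent hypergeometric upper-tail sum via lchoose
hyper_tail_oracle <- function(a, K, N, n) {
  hi <- min(K, n)
  if (a > hi) return(0)
  ks <- a:hi
  terms <- exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n))
  sum(terms)
}

# piecewise-exponential survival times where the group effect reverses at
# a fixed changepoint (for PH-violation checks)
sim_reversing_effect <- function(n, hr1, hr2, t_change, base = 0.05,
                                 seed = 1) {
  set.seed(seed)
  grp <- factor(rep(c("low", "high"), length.out = n),
                levels = c("low", "high"))
  h1 <- base * ifelse(grp == "high", hr1, 1)
  h2 <- base * ifelse(grp == "high", hr2, 1)
  u <- runif(n)
  # invert piecewise-exponential CDF
  t1 <- -log(u) / h1
  t <- ifelse(t1 <= t_change, t1,
              t_change + (-log(u) - h1 * t_change) / h2)
  data.frame(time = t, event = 1L, group = grp)
}
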