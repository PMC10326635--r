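# Two-group negative-binomial differential expression: median-of-ratios
# normalization, method-of-moments dispersion, Wald test on a log-link NB
# GLM, BH correction, and the VST / TPM transforms used downstream.

#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over genes (restricted
#' to genes with a positive geometric mean across samples) of
#' count_ij / geometric_mean_i. Multiplying one sample's counts by c
#' multiplies its factor by c.
#'
#' @param counts count matrix (genes x samples).
#' @return named numeric vector of positive size factors, one per sample.
#' @export
size_factors_median_of_ratios <- function(counts) {
  validate_count_matrix(counts)
  .size_factors(counts)
}

# core computation; no uniqueness validation so comparisons may reuse a
# sample on both sides (e.g. self-vs-self null checks)
.size_factors <- function(counts) {
  logc <- log(counts)
  loggeo <- rowMeans(logc)            # -Inf whenever any count is zero
  use <- is.finite(loggeo)
  if (!any(use))
    stop_("cannot compute size factors: no gene has positive counts in ",
          "every sample")
  sf <- apply(logc[use, , drop = FALSE], 2L,
              function(lc) exp(stats::median(lc - loggeo[use])))
  if (any(!is.finite(sf) | sf <= 0))
    stop_("non-positive size factor computed; check input counts")
  sf
}

#' Method-of-moments NB dispersion per gene
#'
#' Estimates the dispersion alpha of the NB variance function
#' Var = mu + alpha * mu^2 from within-group variability of size-factor
#' normalized counts, pooled across groups, floored at `alpha_min`.
#'
#' @param counts count matrix.
#' @param factors size factors (named by sample or in column order).
#' @param groups factor/vector of group labels, one per sample; every group
#'   must have >= 2 samples.
#' @param alpha_min floor for the estimate (default 1e-8).
#' @param shrink moderate the per-gene estimates toward a mean-dispersion
#'   trend (lowess of log dispersion on log mean), weighting the gene's
#'   own estimate by its residual degrees of freedom against `prior_df`
#'   pseudo-observations. Default OFF: raw per-gene method-of-moments.
#' @param prior_df prior weight of the trend when `shrink = TRUE`.
#' @return numeric vector of per-gene dispersions.
#' @export
estimate_dispersion <- function(counts, factors, groups, alpha_min = 1e-8,
                                shrink = FALSE, prior_df = 10) {
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts))
    stop_("groups must have one label per sample")
  tab <- table(groups)
  if (any(tab < 2L))
    stop_("every group needs >= 2 samples for dispersion estimation; group '",
          names(tab)[which(tab < 2L)[1L]], "' has ", min(tab))
  factors <- align_factors(factors, counts)
  q <- sweep(counts, 2L, factors, "/")
  ss <- 0
  for (g in levels(groups)) {
    qg <- q[, groups == g, drop = FALSE]
    ss <- ss + rowSums((qg - rowMeans(qg))^2)
  }
  v <- ss / (ncol(counts) - nlevels(groups))
  mu <- rowMeans(q)
  # Var(count/s) = mu/s + alpha mu^2 at the per-sample scale; use mean(1/s)
  # for the shot-noise term.
  alpha <- (v - mu * mean(1 / factors)) / mu^2
  alpha[!is.finite(alpha)] <- alpha_min
  alpha <- pmax(alpha, alpha_min)
  if (shrink) {
    df <- ncol(counts) - nlevels(groups)
    usable <- mu > 0 & alpha > alpha_min
    la <- log(alpha)
    trend <- if (sum(usable) >= 10) {
      fit <- stats::lowess(log(mu[usable]), la[usable], f = 0.5)
      stats::approx(fit$x, fit$y, xout = log(pmax(mu, min(mu[usable]))),
                    rule = 2)$y
    } else rep(stats::median(la), length(alpha))
    w <- df / (df + prior_df)
    alpha <- pmax(exp(w * la + (1 - w) * trend), alpha_min)
  }
  alpha
}

align_factors <- function(factors, counts) {
  if (!is.null(names(factors))) {
    miss <- setdiff(colnames(counts), names(factors))
    if (length(miss)) stop_("no size factor for sample '", miss[1L], "'")
    factors <- factors[colnames(counts)]
  }
  if (length(factors) != ncol(counts))
    stop_("need one size factor per sample")
  if (any(factors <= 0)) stop_("size factors must be positive")
  factors
}

# Vectorized per-gene MLE of the NB group mean q on the normalized scale,
# with known per-gene dispersion and per-sample size factors (offsets).
# Solves sum_j (y_j - s_j q) / (1 + alpha s_j q) = 0 by Newton iteration.
nb_fit_group <- function(y, s, alpha, iter = 30L) {
  tot <- rowSums(y)
  q <- tot / sum(s)
  pos <- q > 0
  if (any(pos)) {
    qp <- q[pos]
    ap <- alpha[pos]
    yp <- y[pos, , drop = FALSE]
    for (i in seq_len(iter)) {
      mu <- qp %o% s
      den <- 1 + ap * mu
      f <- rowSums((yp - mu) / den)
      fp <- -rowSums(sweep((1 + ap * yp) / den^2, 2L, s, "*"))
      step <- f / fp
      qn <- qp - step
      qn[qn <= 0] <- qp[qn <= 0] / 10
      if (max(abs(qn - qp) / pmax(qp, 1e-12)) < 1e-10) { qp <- qn; break }
      qp <- qn
    }
    q[pos] <- qp
  }
  zero <- tot == 0
  # Continuity value for groups with no reads: half a read spread over the
  # group's total sequencing depth, so fold changes stay finite.
  q[zero] <- 0.5 / sum(s)
  mu <- q %o% s
  info <- rowSums(mu / (1 + alpha * mu))
  list(q = q, info = info, zero = zero)
}

#' Two-group negative-binomial Wald test
#'
#' Fits a per-gene NB model with log link, size-factor offsets and a group
#' indicator, and tests the group coefficient with a two-sided normal Wald
#' test. The fold change is oriented as group B over group A (positive =
#' higher in B). Genes with zero counts in every sample of both groups get
#' NA p-values and are excluded from the BH denominator.
#'
#' @param counts count matrix containing (at least) the samples of both
#'   groups.
#' @param group_a,group_b character vectors of sample IDs.
#' @param factors optional size factors for the union of the two groups;
#'   computed by median-of-ratios on that union when `NULL`.
#' @param dispersion optional per-gene dispersion; estimated by
#'   [estimate_dispersion()] on the two groups when `NULL`.
#' @param shrink passed to [estimate_dispersion()] when dispersions are
#'   estimated here (default OFF).
#' @return data.frame with columns `gene_id`, `baseMean`, `log2FoldChange`,
#'   `lfcSE`, `stat`, `pvalue`, `padj`.
#' @export
wald_test_two_group <- function(counts, group_a, group_b, factors = NULL,
                                dispersion = NULL, shrink = FALSE) {
  if (!length(group_a) || !length(group_b))
    stop_("both groups must be non-empty")
  miss <- setdiff(c(group_a, group_b), colnames(counts))
  if (length(miss)) stop_("sample not in count matrix: '", miss[1L], "'")
  sub <- counts[, c(group_a, group_b), drop = FALSE]
  if (is.null(factors)) factors <- .size_factors(sub)
  factors <- align_factors(factors, sub)
  if (is.null(dispersion)) {
    grp <- rep(c("A", "B"), c(length(group_a), length(group_b)))
    dispersion <- estimate_dispersion(sub, factors, grp, shrink = shrink)
  }
  if (length(dispersion) == 1L) dispersion <- rep(dispersion, nrow(sub))
  ia <- seq_along(group_a)
  ib <- length(group_a) + seq_along(group_b)
  fa <- nb_fit_group(sub[, ia, drop = FALSE], factors[ia], dispersion)
  fb <- nb_fit_group(sub[, ib, drop = FALSE], factors[ib], dispersion)

  lfc <- log2(fb$q / fa$q)
  se <- sqrt(1 / fa$info + 1 / fb$info) / log(2)
  stat <- lfc / se
  pvalue <- 2 * stats::pnorm(-abs(stat))
  all_zero <- fa$zero & fb$zero
  lfc[all_zero] <- NA_real_
  se[all_zero] <- NA_real_
  stat[all_zero] <- NA_real_
  pvalue[all_zero] <- NA_real_
  base_mean <- rowMeans(sweep(sub, 2L, factors, "/"))
  data.frame(
    gene_id = rownames(sub),
    baseMean = base_mean,
    log2FoldChange = lfc,
    lfcSE = se,
    stat = stat,
    pvalue = pvalue,
    padj = bh_adjust(pvalue),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment. NA p-values are propagated and excluded from the
#' number of tests m.
#'
#' @param p numeric vector of p-values in \[0, 1\], NA allowed.
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Variance-stabilizing transform of counts
#'
#' A monotone log-shift transform of size-factor normalized counts,
#' log2(count/s + pseudocount), which approximately decouples the per-gene
#' standard deviation from the mean for NB data at moderate-to-high counts.
#'
#' @param counts count matrix.
#' @param factors size factors (median-of-ratios when `NULL`).
#' @param pseudocount shift constant, default 4.
#' @return transformed matrix, same dimensions as `counts`.
#' @export
vst_counts <- function(counts, factors = NULL, pseudocount = 4) {
  if (is.null(factors)) factors <- size_factors_median_of_ratios(counts)
  factors <- align_factors(factors, counts)
  log2(sweep(counts, 2L, factors, "/") + pseudocount)
}

#' TPM normalization
#'
#' Transcripts per kilobase million: per sample, counts are divided by
#' transcript length in kb and rescaled so the column sums to 1e6. An
#' all-zero sample yields an all-zero column.
#'
#' @param counts count matrix.
#' @param lengths transcript lengths in bp, named by gene or in row order.
#' @return TPM matrix, same dimensions as `counts`.
#' @export
tpm_normalize <- function(counts, lengths) {
  if (!is.null(names(lengths))) {
    miss <- setdiff(rownames(counts), names(lengths))
    if (length(miss)) stop_("no length for gene '", miss[1L], "'")
    lengths <- lengths[rownames(counts)]
  }
  if (length(lengths) != nrow(counts))
    stop_("need one length per gene")
  if (any(lengths <= 0)) stop_("transcript lengths must be positive")
  rate <- counts / (lengths / 1000)
  tot <- colSums(rate)
  tot[tot == 0] <- 1          # all-zero sample stays all-zero, no NaN
  sweep(rate, 2L, tot, "/") * 1e6
}

#' Write a DE result table as TSV
#'
#' Column layout: gene_id, baseMean, log2FoldChange, lfcSE, stat, pvalue,
#' padj (tab-separated, NA for missing).
#'
#' @param de data.frame from [wald_test_two_group()].
#' @param path output path.
#' @export
write_de_table <- function(de, path) {
  cols <- c("gene_id", "baseMean", "log2FoldChange", "lfcSE", "stat",
            "pvalue", "padj")
  utils::write.table(de[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
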