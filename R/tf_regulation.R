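# Regulatory-window construction around TSSs, ChIP-seq peak overlap
# counting, one-tailed Fisher enrichment of TF binding sites in candidate
# windows against the all-lncRNA background, and AR-binding-site summaries.

#' Regulatory regions around the TSS
#'
#' The window spans 5 kb upstream and 2 kb downstream of the TSS in
#' transcription direction: `[tss - 5000, tss + 2000)` on the `+` strand
#' and the strand-mirrored `[tss - 2000 + 1, tss + 5000 + 1)` on `-`
#' (upstream = 5' of the gene). Windows are clipped at position 0.
#'
#' @param models gene model data.frame.
#' @param upstream,downstream window extents in bp (defaults 5000 / 2000).
#' @param stranded mirror the window on `-` strand genes (default TRUE); a
#'   naive unstranded reading applies the `+` convention everywhere.
#' @return data.frame gene_id, chrom, start, end, strand (0-based
#'   half-open).
#' @export
regulatory_regions <- function(models, upstream = 5000L, downstream = 2000L,
                               stranded = TRUE) {
  plus <- !stranded | models$strand == "+"
  start <- ifelse(plus, models$tss - upstream, models$tss - downstream + 1L)
  end <- ifelse(plus, models$tss + downstream, models$tss + upstream + 1L)
  start <- pmax(start, 0L)
  data.frame(gene_id = models$gene_id, chrom = models$chrom,
             start = as.integer(start), end = as.integer(end),
             strand = models$strand, stringsAsFactors = FALSE)
}

#' Count peaks overlapping each region
#'
#' Counts peaks with >= 1 bp intersection (half-open semantics) per
#' region. Chromosomes present in regions but absent from the peak set
#' contribute zero overlaps (reported once via a message).
#'
#' @param regions data.frame from [regulatory_regions()].
#' @param peaks a `peak_set` (or data.frame chrom/start/end).
#' @return integer vector of per-region peak counts, named by gene.
#' @export
count_peak_overlaps <- function(regions, peaks) {
  n <- nrow(regions)
  if (!nrow(peaks)) {
    out <- integer(n); names(out) <- regions$gene_id; return(out)
  }
  novel <- setdiff(unique(regions$chrom), unique(peaks$chrom))
  if (length(novel))
    message("count_peak_overlaps: no peaks on ",
            paste(novel, collapse = ", "), "; counting zero there")
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L,
                                                regions$end))
  gp <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L,
                                                peaks$end))
  # disjoint seqlevels are expected (they count zero); silence the
  # GRanges advisory about it
  out <- suppressWarnings(
    GenomicRanges::countOverlaps(gr, gp, minoverlap = 1L,
                                 ignore.strand = TRUE))
  names(out) <- regions$gene_id
  out
}

#' Peak-count matrix over genes x TFs
#'
#' @param regions regulatory regions (one per gene).
#' @param peak_list named list of `peak_set`s, one per TF.
#' @return integer matrix, rows = gene IDs, columns = TF names; the
#'   binary "has a binding site" view is `binding_matrix(...) >= 1`.
#' @export
binding_matrix <- function(regions, peak_list) {
  if (is.null(names(peak_list)))
    names(peak_list) <- vapply(peak_list, function(p)
      attr(p, "tf_name") %||% NA_character_, "")
  m <- vapply(peak_list, function(p)
    suppressMessages(count_peak_overlaps(regions, p)),
    integer(nrow(regions)))
  m <- matrix(m, nrow = nrow(regions),
              dimnames = list(regions$gene_id, names(peak_list)))
  m
}

#' One-tailed Fisher enrichment of TF binding in a foreground set
#'
#' Per TF, builds the 2x2 table of (has >= 1 site) x (foreground vs
#' background-minus-foreground) over the binary binding view and computes
#' the one-tailed (enrichment, "greater") hypergeometric p, BH-adjusted
#' across TFs. The background is every gene in the matrix (all lncRNAs).
#'
#' @param binding matrix from [binding_matrix()].
#' @param foreground character vector of gene IDs (subset of rows).
#' @param padj_cutoff enrichment call threshold on the adjusted p
#'   (default 0.15).
#' @return data.frame tf_name, a, b, c, d, odds_ratio, p_one_tailed,
#'   p_adjusted, enriched.
#' @export
fisher_enrichment <- function(binding, foreground, padj_cutoff = 0.15) {
  if (!length(foreground)) stop_("foreground set is empty")
  miss <- setdiff(foreground, rownames(binding))
  if (length(miss))
    stop_("foreground gene not in binding matrix: '", miss[1L], "'")
  fg <- rownames(binding) %in% foreground
  bound <- binding >= 1L
  a <- colSums(bound[fg, , drop = FALSE])
  b <- sum(fg) - a
  cc <- colSums(bound[!fg, , drop = FALSE])
  d <- sum(!fg) - cc
  n_total <- nrow(binding)
  # upper tail of Hypergeometric(N = a+b+c+d, K = a+c, n = a+b) at a
  p <- stats::phyper(a - 1, a + cc, b + d, a + b, lower.tail = FALSE)
  or <- (a * d) / (b * cc)
  padj <- bh_adjust(p)
  data.frame(tf_name = colnames(binding), a = as.integer(a),
             b = as.integer(b), c = as.integer(cc), d = as.integer(d),
             odds_ratio = or, p_one_tailed = p, p_adjusted = padj,
             enriched = padj < padj_cutoff,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tumor/normal AR binding-site summary for candidate genes
#'
#' Counts tumor-specific and normal-prostate-specific AR peaks in each
#' candidate's regulatory window and summarizes the fractions of
#' candidates with at least one site of each kind, the total counts, and
#' their ratio.
#'
#' @param candidates data.frame with a `gene_id` column (e.g. the screen's
#'   candidate set) or a character vector of gene IDs.
#' @param regions regulatory regions covering every candidate.
#' @param tumor_peaks,normal_peaks `peak_set`s of condition-specific AR
#'   binding sites.
#' @return list with `per_gene` (gene_id, n_tumor, n_normal) and `summary`
#'   (fraction/total per kind plus `tumor_normal_ratio`).
#' @export
arbs_summary <- function(candidates, regions, tumor_peaks, normal_peaks) {
  ids <- if (is.data.frame(candidates)) candidates$gene_id else candidates
  miss <- setdiff(ids, regions$gene_id)
  if (length(miss)) stop_("no regulatory region for gene '", miss[1L], "'")
  reg <- regions[match(ids, regions$gene_id), , drop = FALSE]
  nt <- suppressMessages(count_peak_overlaps(reg, tumor_peaks))
  nn <- suppressMessages(count_peak_overlaps(reg, normal_peaks))
  per_gene <- data.frame(gene_id = ids, n_tumor = as.integer(nt),
                         n_normal = as.integer(nn),
                         stringsAsFactors = FALSE)
  tot_t <- sum(nt); tot_n <- sum(nn)
  list(per_gene = per_gene,
       summary = data.frame(
         n_candidates = length(ids),
         frac_with_tumor_arbs = mean(nt >= 1),
         frac_with_normal_arbs = mean(nn >= 1),
         total_tumor_arbs = tot_t,
         total_normal_arbs = tot_n,
         tumor_normal_ratio = if (tot_n > 0) tot_t / tot_n else NA_real_))
}

#' TPM expression summary for a set of TFs
#'
#' Computes TPM for all genes, then reports each TF's mean TPM across
#' samples and its percentile among all genes' mean TPM (100 = most highly
#' expressed), flagging TFs in the top expression quartile.
#'
#' @param counts count matrix (all genes).
#' @param lengths transcript lengths (bp) named by gene or in row order.
#' @param tf_ids gene IDs of the TFs of interest.
#' @return list with `tpm` (TF x sample TPM matrix) and `summary`
#'   (gene_id, mean_tpm, percentile, top_quartile).
#' @export
tf_expression_summary <- function(counts, lengths, tf_ids) {
  miss <- setdiff(tf_ids, rownames(counts))
  if (length(miss)) stop_("unknown TF gene ID: '", miss[1L], "'")
  tpm <- tpm_normalize(counts, lengths)
  mean_tpm <- rowMeans(tpm)
  pct <- 100 * rank(mean_tpm, ties.method = "average") / length(mean_tpm)
  summary <- data.frame(gene_id = tf_ids,
                        mean_tpm = unname(mean_tpm[tf_ids]),
                        percentile = unname(pct[tf_ids]),
                        top_quartile = unname(pct[tf_ids] >= 75),
                        stringsAsFactors = FALSE)
  list(tpm = tpm[tf_ids, , drop = FALSE], summary = summary)
}
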