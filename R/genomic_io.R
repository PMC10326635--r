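# Readers and writers for the tabular/genomic formats the pipeline touches.
# All internal coordinates are 0-based half-open; conversion to/from 1-based
# conventions happens only here, at the I/O boundary.

CANCER_STATUSES <- c("normal", "bph", "primary", "metastasis")
GENE_BIOTYPES <- c("lncRNA", "protein_coding", "pseudogene")

## ---- validation -----------------------------------------------------------

#' Validate a count matrix
#'
#' A count matrix is an integer matrix of non-negative read counts with
#' unique gene row names and unique sample column names.
#'
#' @param counts matrix to validate.
#' @return the validated matrix, invisibly typed as integer-valued numeric.
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_("counts must have gene row names and sample column names")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup))
    stop_("duplicate gene ID in count matrix: ", dup[1L])
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup))
    stop_("duplicate sample ID in count matrix: ", dup[1L])
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad))
    stop_("count matrix cell is not a non-negative integer at gene '",
          rownames(counts)[bad[1L, 1L]], "', sample '",
          colnames(counts)[bad[1L, 2L]], "'")
  invisible(counts)
}

#' Validate a sample table
#'
#' @param samples data.frame with columns `sample_id`, `patient_id`,
#'   `cancer_status` (normal/bph/primary/metastasis) and `tissue_site`.
#'   Primary and BPH samples must be located in the prostate.
#' @return the validated data.frame, invisibly.
#' @export
validate_sample_table <- function(samples) {
  need <- c("sample_id", "patient_id", "cancer_status", "tissue_site")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop_("sample table is missing column(s): ", paste(miss, collapse = ", "))
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup))
    stop_("duplicate sample ID in sample table: ", dup[1L])
  bad <- setdiff(unique(samples$cancer_status), CANCER_STATUSES)
  if (length(bad))
    stop_("unknown cancer_status: ", bad[1L])
  off <- samples$cancer_status %in% c("bph", "primary") &
    samples$tissue_site != "prostate"
  if (any(off))
    stop_("sample '", samples$sample_id[which(off)[1L]],
          "' has status ", samples$cancer_status[which(off)[1L]],
          " but tissue_site != 'prostate'")
  invisible(samples)
}

#' Validate a gene model table
#'
#' Gene models carry one interval (0-based half-open), strand, biotype, TSS
#' and a transcript length per gene.
#'
#' @param models data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`, `tss`, `transcript_length`.
#' @return the validated data.frame, invisibly.
#' @export
validate_gene_models <- function(models) {
  need <- c("gene_id", "chrom", "start", "end", "strand", "biotype",
            "tss", "transcript_length")
  miss <- setdiff(need, names(models))
  if (length(miss))
    stop_("gene models missing column(s): ", paste(miss, collapse = ", "))
  dup <- models$gene_id[duplicated(models$gene_id)]
  if (length(dup))
    stop_("duplicate gene ID in gene models: ", dup[1L])
  if (any(!models$strand %in% c("+", "-")))
    stop_("unknown strand for gene '",
          models$gene_id[which(!models$strand %in% c("+", "-"))[1L]], "'")
  if (any(models$end <= models$start))
    stop_("end <= start for gene '",
          models$gene_id[which(models$end <= models$start)[1L]], "'")
  bad <- models$tss < models$start | models$tss >= models$end
  if (any(bad))
    stop_("TSS outside gene body for gene '", models$gene_id[which(bad)[1L]], "'")
  if (any(models$transcript_length <= 0))
    stop_("non-positive transcript_length for gene '",
          models$gene_id[which(models$transcript_length <= 0)[1L]], "'")
  bad <- setdiff(unique(models$biotype), GENE_BIOTYPES)
  if (length(bad))
    stop_("unknown biotype: ", bad[1L])
  invisible(models)
}

## ---- count matrix ---------------------------------------------------------

#' Read a count matrix from TSV
#'
#' Expects a header row of sample IDs and a first column of gene IDs.
#' Row and column order are preserved.
#'
#' @param path file path.
#' @return validated integer count matrix (genes x samples).
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_("count matrix file needs >= 2 columns: ", path)
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop_("non-numeric count cell in ", path)
  rownames(m) <- genes
  validate_count_matrix(m)
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix to TSV
#'
#' @param counts validated count matrix.
#' @param path output path; first column `gene_id`, then one column per sample.
#' @export
write_count_matrix <- function(counts, path) {
  validate_count_matrix(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- sample / clinical tables ---------------------------------------------

#' Read a sample metadata table from TSV
#' @param path file path.
#' @return validated sample data.frame.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "NA")
  validate_sample_table(df)
  df
}

#' Write a sample metadata table to TSV
#' @param samples validated sample data.frame.
#' @param path output path.
#' @export
write_sample_table <- function(samples, path) {
  validate_sample_table(samples)
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a clinical survival table from TSV
#'
#' Columns: `sample_id`, `time`, `event`, `age`, `psa`, `gleason`, `pt`,
#' plus one `expression` column (or per-gene expression columns).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_survival_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "NA")
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_("survival table missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$time <= 0)) stop_("survival times must be > 0")
  if (!all(df$event %in% c(0, 1))) stop_("event must be 0 or 1")
  df
}

#' Write a clinical survival table to TSV
#' @param records survival data.frame.
#' @param path output path.
#' @export
write_survival_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

## ---- gene models ----------------------------------------------------------

#' Read gene models from BED-like TSV or minimal gene-level GTF
#'
#' The BED-like format is 0-based half-open with columns chrom, start, end,
#' gene_id, score, strand, biotype, transcript_length (no header). GTF input
#' is 1-based inclusive and converted on read (start - 1); only `gene`
#' feature lines are used, with `gene_id` and `gene_biotype` attributes and
#' an optional `transcript_length` attribute (defaulting to the gene width).
#' The TSS is derived from strand: interval start on `+`, end - 1 on `-`.
#'
#' @param path file path.
#' @param format `"bed"` or `"gtf"`.
#' @return validated gene model data.frame.
#' @export
read_gene_models <- function(path, format = c("bed", "gtf")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- utils::read.delim(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 8L)
      stop_("gene model BED needs 8 columns ",
            "(chrom start end gene_id score strand biotype length): ", path)
    models <- data.frame(
      gene_id = as.character(df[[4L]]), chrom = as.character(df[[1L]]),
      start = as.integer(df[[2L]]), end = as.integer(df[[3L]]),
      strand = as.character(df[[6L]]), biotype = as.character(df[[7L]]),
      transcript_length = as.integer(df[[8L]]),
      stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    keep <- !grepl("^#", lines) & nzchar(lines)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    nbad <- which(lengths(fields) < 9L)
    if (length(nbad))
      stop_("malformed GTF line ", which(keep)[nbad[1L]], " in ", path)
    fm <- do.call(rbind, fields)
    fm <- fm[fm[, 3L] == "gene", , drop = FALSE]
    if (!nrow(fm)) stop_("no gene-level lines in GTF: ", path)
    attr_get <- function(attrs, key) {
      pat <- paste0(key, ' "([^"]*)"')
      m <- regexpr(pat, attrs)
      out <- rep(NA_character_, length(attrs))
      out[m > 0] <- sub(pat, "\\1", regmatches(attrs, m))
      out
    }
    attrs <- fm[, 9L]
    gid <- attr_get(attrs, "gene_id")
    bio <- attr_get(attrs, "gene_biotype")
    tlen <- suppressWarnings(as.integer(attr_get(attrs, "transcript_length")))
    start1 <- as.integer(fm[, 4L])
    end1 <- as.integer(fm[, 5L])
    if (any(is.na(gid))) stop_("GTF gene line without gene_id in ", path)
    models <- data.frame(
      gene_id = gid, chrom = fm[, 1L],
      start = start1 - 1L, end = end1,   # GTF 1-based inclusive -> half-open
      strand = fm[, 7L], biotype = bio,
      transcript_length = ifelse(is.na(tlen), end1 - start1 + 1L, tlen),
      stringsAsFactors = FALSE)
  }
  models$tss <- ifelse(models$strand == "+", models$start, models$end - 1L)
  models <- models[, c("gene_id", "chrom", "start", "end", "strand",
                       "biotype", "tss", "transcript_length")]
  validate_gene_models(models)
  models
}

#' Write gene models as BED-like TSV or minimal gene-level GTF
#' @param models validated gene model data.frame.
#' @param path output path.
#' @param format `"bed"` or `"gtf"`.
#' @export
write_gene_models <- function(models, path, format = c("bed", "gtf")) {
  format <- match.arg(format)
  validate_gene_models(models)
  if (format == "bed") {
    df <- data.frame(models$chrom, models$start, models$end, models$gene_id,
                     0L, models$strand, models$biotype,
                     models$transcript_length)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    attrs <- sprintf(
      'gene_id "%s"; gene_biotype "%s"; transcript_length "%d";',
      models$gene_id, models$biotype, models$transcript_length)
    df <- data.frame(models$chrom, "lncscreen", "gene",
                     models$start + 1L, models$end, ".", models$strand, ".",
                     attrs)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

## ---- peaks ----------------------------------------------------------------

#' Read a ChIP-seq peak set from BED
#'
#' @param path >= 3-column BED (0-based half-open), no header.
#' @param tf_name label of the assayed transcription factor.
#' @return a `peak_set`: data.frame (chrom, start, end) sorted by chrom then
#'   start, with attribute `tf_name`.
#' @export
read_peaks <- function(path, tf_name) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^(#|track|browser)", lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop_("malformed BED line ", which(keep)[bad[1L]], " in ", path)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start)
  if (length(bad))
    stop_("malformed BED line ", which(keep)[bad[1L]], " in ", path)
  peak_set(data.frame(chrom = chrom, start = start, end = end,
                      stringsAsFactors = FALSE), tf_name)
}

#' Construct/validate a peak set
#' @param intervals data.frame with chrom, start, end (0-based half-open).
#' @param tf_name TF label.
#' @return sorted `peak_set` data.frame.
#' @export
peak_set <- function(intervals, tf_name) {
  if (!all(c("chrom", "start", "end") %in% names(intervals)))
    stop_("peak set needs chrom, start, end columns")
  if (any(intervals$start < 0) || any(intervals$end <= intervals$start))
    stop_("peak intervals must satisfy 0 <= start < end")
  o <- order(intervals$chrom, intervals$start, intervals$end)
  out <- intervals[o, c("chrom", "start", "end"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tf_name") <- tf_name
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Write a peak set as BED3
#' @param peaks `peak_set`.
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  utils::write.table(peaks[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
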