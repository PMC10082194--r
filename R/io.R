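# Tab-separated readers and writers for the package's external formats.
# On-disk genomic coordinates are 1-based inclusive (SEG-like); everything
# in memory is 0-based half-open.  Readers convert on ingest, writers
# convert back.

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) hrd_stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    hrd_stop(path, ": missing required column(s): ",
             paste(miss, collapse = ", "))
  df
}

#' Read a binned copy-ratio profile TSV
#'
#' Columns: `chrom`, `start`, `end`, `ratio`, optional `usable` (0/1) and
#' `sample`.  `scale = "log2"` declares log2 ratios, converted to linear on
#' ingest; starts are 1-based on disk.
#'
#' @param path file path.
#' @param sample sample id (default: `sample` column or the file name).
#' @param scale `"linear"` or `"log2"`.
#' @param bin_width nominal bin width (default inferred from the first bin).
#' @return A `binned_profile`.
#' @export
read_binned_profile <- function(path, sample = NULL,
                                scale = c("linear", "log2"),
                                bin_width = NULL) {
  scale <- match.arg(scale)
  df <- read_tsv_checked(path, c("chrom", "start", "end", "ratio"))
  df$start <- df$start - 1
  if (scale == "log2") df$ratio <- 2^df$ratio
  sample <- sample %||% df$sample[1] %||% basename(path)
  bin_width <- bin_width %||% (df$end[1] - df$start[1])
  binned_profile(sample, df, bin_width)
}

#' Write / read a segment table (SEG-like TSV)
#'
#' Columns `sample`, `chrom`, `start`, `end`, `level`, `n_bins`; 1-based
#' starts on disk.
#'
#' @param seg a `segmented_profile`.
#' @param path file path.
#' @return `write_segments` returns `path` invisibly; `read_segments`
#'   returns a `segmented_profile` (without bin residuals, so cutoff
#'   estimation on it falls back to an explicit cutoff).
#' @export
write_segments <- function(seg, path) {
  s <- seg$segments
  out <- data.frame(sample = seg$sample, chrom = s$chrom, start = s$start + 1,
                    end = s$end, level = s$level, n_bins = s$n_bins)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  df <- read_tsv_checked(path, c("sample", "chrom", "start", "end", "level",
                                 "n_bins"))
  df$start <- df$start - 1
  structure(list(sample = df$sample[1],
                 segments = df[, c("chrom", "start", "end", "level",
                                   "n_bins")],
                 resid_mad = NA_real_),
            class = "segmented_profile")
}

#' Read an allele-specific segment TSV
#'
#' Columns `sample`, `chrom`, `start`, `end`, `total_cn`, `major_cn`,
#' `minor_cn`, `n_probes`; 1-based starts on disk.
#'
#' @param path file path.
#' @param sample sample id override.
#' @return An `allelic_profile`.
#' @export
read_allelic_segments <- function(path, sample = NULL) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "total_cn",
                                 "major_cn", "minor_cn", "n_probes"))
  df$start <- df$start - 1
  allelic_profile(sample %||% df$sample[1] %||% basename(path), df)
}

#' Read a caliper measurement TSV
#'
#' Columns `pdx`, `mouse`, `day` and either `volume_mm3` or the diameters
#' `a_mm`, `b_mm` (largest/smallest, in mm); volumes are computed from
#' diameters when absent.
#'
#' @param path file path.
#' @return Data frame with columns `pdx`, `mouse`, `day`, `volume` (and
#'   `arm` if present in the file).
#' @export
read_measurements <- function(path) {
  df <- read_tsv_checked(path, c("pdx", "mouse", "day"))
  if (is.null(df$volume_mm3)) {
    if (is.null(df$a_mm) || is.null(df$b_mm))
      hrd_stop(path, ": need volume_mm3 or a_mm and b_mm columns")
    df$volume <- tumour_volume(df$a_mm, df$b_mm)
  } else df$volume <- df$volume_mm3
  keep <- intersect(c("pdx", "mouse", "arm", "day", "volume"), names(df))
  df[, keep]
}

#' Read a RAD51 foci table TSV
#'
#' Columns `pdx`, `sample`, `arm` (`control`/`treated`), `cell_id`,
#' `marker_positive` (0/1), `foci_count`.
#'
#' @param path file path.
#' @return Data frame.
#' @export
read_foci <- function(path) {
  read_tsv_checked(path, c("pdx", "sample", "arm", "marker_positive",
                           "foci_count"))
}

#' Read an annotated variant TSV
#'
#' One row per variant per sample with the columns described in
#' [filter_wes_cohort()].
#'
#' @param path file path.
#' @return Data frame.
#' @export
read_variants <- function(path) {
  read_tsv_checked(path, c("sample", "chrom", "pos", "ref", "alt"))
}

#' Read a fusion call TSV
#'
#' Columns `sample`, `geneA`, `chromA`, `posA`, `geneB`, `chromB`, `posB`,
#' optionally `junction_reads`.
#'
#' @param path file path.
#' @return Data frame.
#' @export
read_fusions <- function(path) {
  read_tsv_checked(path, c("sample", "geneA", "chromA", "posA", "geneB",
                           "chromB", "posB"))
}

#' Read a genes-by-samples count matrix TSV
#'
#' First column `gene`, remaining columns one per sample.
#'
#' @param path file path.
#' @return Numeric matrix with gene rownames.
#' @export
read_counts_matrix <- function(path) {
  df <- read_tsv_checked(path, "gene")
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  rownames(m) <- df$gene
  storage.mode(m) <- "numeric"
  m
}

#' Read a gene coordinate BED-like TSV
#'
#' Columns `gene`, `chrom`, `start`, `end` (1-based starts on disk).
#'
#' @param path file path.
#' @return Data frame with 0-based half-open coordinates.
#' @export
read_gene_bed <- function(path) {
  df <- read_tsv_checked(path, c("gene", "chrom", "start", "end"))
  df$start <- df$start - 1
  df
}

#' Read a PDX annotation TSV
#'
#' Expected columns include `pdx`, `category` and any biomarker columns
#' used by [build_contingency()] (e.g. `hrd_class`, `brca_mutated_loh`,
#' `methylation_percent`, `rad51_status`, `survival_days`, `death_event`).
#'
#' @param path file path.
#' @return Data frame.
#' @export
read_annotations <- function(path) {
  read_tsv_checked(path, c("pdx", "category"))
}
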