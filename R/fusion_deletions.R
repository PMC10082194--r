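# Detection of genomic deletions from intra-chromosomal fusion transcripts.
#
# A same-chromosome fusion whose spanned region shows depleted expression of
# every gene it contains is evidence of a genomic deletion between the fusion
# breakpoints.

#' Median-of-ratios count normalization
#'
#' Computes per-sample size factors as the median, over genes with a positive
#' geometric mean across samples, of the ratio between the gene's count in
#' the sample and its geometric mean; each sample's counts are divided by its
#' size factor.  This removes sequencing-depth differences while being robust
#' to differentially expressed genes.
#'
#' @param counts numeric matrix, genes in rows, samples in columns, raw
#'   non-negative counts.
#' @return List with `normalized` (matrix, same dimensions) and
#'   `size_factors` (named numeric vector).
#' @examples
#' m <- matrix(c(2, 2, 8, 8), nrow = 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' median_of_ratios_normalize(m)$size_factors  # 0.5, 2
#' @export
median_of_ratios_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) hrd_stop("normalization needs >= 2 samples")
  if (any(counts < 0)) hrd_stop("counts must be non-negative")
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)  # genes with a positive count in every sample
  if (!any(use))
    hrd_stop("no gene has a positive count in every sample")
  # log-space median of ratios (the DESeq convention; for an even gene count
  # this is the geometric mean of the two middle ratios)
  sf <- apply(counts[use, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - log_gm[use]))
  })
  list(normalized = sweep(counts, 2, sf, "/"), size_factors = sf)
}

#' Build deletion candidates from fusion calls
#'
#' Keeps fusions whose partners lie on the same chromosome, spans the region
#' between the two breakpoints, collects the genes overlapping that region,
#' and retains candidates in which a fusion partner or any spanned gene
#' belongs to the DNA-damage-response gene list.  Inter-chromosomal fusions
#' are silently excluded.
#'
#' @param fusions data frame with columns `sample`, `geneA`, `chromA`,
#'   `posA`, `geneB`, `chromB`, `posB` (and optionally `junction_reads`).
#' @param genes data frame of gene coordinates: `gene`, `chrom`, `start`,
#'   `end`.
#' @param ddr_list character vector of DDR gene symbols (or a file path).
#' @return Data frame of unverdicted candidates: `sample`, `chrom`, `start`,
#'   `end`, `geneA`, `geneB`, `region_genes` (comma-separated).
#' @export
candidate_deletions <- function(fusions, genes, ddr_list) {
  if (is.character(ddr_list) && length(ddr_list) == 1L && file.exists(ddr_list))
    ddr_list <- read_gene_list(ddr_list)
  ddr <- toupper(ddr_list)
  out <- list()
  for (i in seq_len(nrow(fusions))) {
    f <- fusions[i, ]
    if (f$chromA != f$chromB) next
    lo <- min(f$posA, f$posB); hi <- max(f$posA, f$posB)
    inside <- genes$chrom == f$chromA & genes$end > lo & genes$start < hi
    region_genes <- genes$gene[inside]
    hit <- any(toupper(c(f$geneA, f$geneB, region_genes)) %in% ddr)
    if (!hit) next
    out[[length(out) + 1L]] <- data.frame(
      sample = f$sample, chrom = f$chromA, start = lo, end = hi,
      geneA = f$geneA, geneB = f$geneB,
      region_genes = paste(region_genes, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(), geneA = character(),
                      geneB = character(), region_genes = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# inclusive lower quantile with linear interpolation (quantile type 7)
lower_quantile <- function(x, q) stats::quantile(x, q, names = FALSE, type = 7)

#' Verdict a deletion candidate against normalized expression
#'
#' Criterion A: the candidate sample's summed normalized count over the
#' region's genes is at or below the `quantile`-th quantile of the same
#' region sum computed across all samples.  Criterion B: for every gene in
#' the region, the candidate sample's normalized count is at or below the
#' `quantile`-th quantile of that gene's counts across the other samples.
#' The verdict passes iff both criteria hold; a region containing no genes
#' fails with reason `no_genes`.
#'
#' @param candidate one row of a [candidate_deletions()] result (data frame
#'   or list with `sample` and `region_genes`).
#' @param normalized normalized expression matrix (genes x samples), e.g.
#'   `median_of_ratios_normalize(counts)$normalized`.
#' @param quantile depletion quantile (default 0.10).
#' @return List with `sample`, `genes`, `pass`, `criterion_a`, `criterion_b`,
#'   `region_sum_quantile` (the candidate's rank position of the region sum),
#'   `gene_quantiles` (per-gene reference quantile thresholds) and `reason`
#'   (`NA` or `"no_genes"`).
#' @export
test_deletion <- function(candidate, normalized, quantile = 0.10) {
  genes <- strsplit(candidate$region_genes, ",", fixed = TRUE)[[1]]
  genes <- genes[nzchar(genes)]
  sample <- candidate$sample
  if (!length(genes))
    return(list(sample = sample, genes = character(), pass = FALSE,
                criterion_a = FALSE, criterion_b = FALSE,
                region_sum_quantile = NA_real_, gene_quantiles = numeric(),
                reason = "no_genes"))
  missing <- setdiff(genes, rownames(normalized))
  if (length(missing))
    hrd_stop("candidate genes absent from expression matrix: ",
             paste(missing, collapse = ", "))
  if (!sample %in% colnames(normalized))
    hrd_stop("candidate sample absent from expression matrix: ", sample)
  sub <- normalized[genes, , drop = FALSE]
  region_sums <- colSums(sub)
  thr_a <- lower_quantile(region_sums, quantile)
  crit_a <- region_sums[[sample]] <= thr_a
  others <- setdiff(colnames(normalized), sample)
  gene_thr <- apply(sub[, others, drop = FALSE], 1, lower_quantile,
                    q = quantile)
  crit_b <- all(sub[, sample] <= gene_thr)
  list(sample = sample, genes = genes, pass = crit_a && crit_b,
       criterion_a = crit_a, criterion_b = crit_b,
       region_sum_quantile = stats::ecdf(region_sums)(region_sums[[sample]]),
       gene_quantiles = gene_thr, reason = NA_character_)
}

#' Run the full fusion-deletion screen
#'
#' @inheritParams candidate_deletions
#' @param counts raw counts matrix (genes x samples); normalized internally
#'   with [median_of_ratios_normalize()].
#' @param quantile depletion quantile (default 0.10).
#' @return Data frame of candidates with `pass`, `criterion_a`,
#'   `criterion_b`, `reason` columns appended.
#' @export
screen_fusion_deletions <- function(fusions, counts, genes, ddr_list,
                                    quantile = 0.10) {
  cands <- candidate_deletions(fusions, genes, ddr_list)
  if (!nrow(cands)) {
    cands$pass <- logical(); cands$criterion_a <- logical()
    cands$criterion_b <- logical(); cands$reason <- character()
    return(cands)
  }
  norm <- median_of_ratios_normalize(counts)$normalized
  verdicts <- lapply(seq_len(nrow(cands)), function(i)
    test_deletion(cands[i, ], norm, quantile))
  cands$pass <- vapply(verdicts, `[[`, logical(1), "pass")
  cands$criterion_a <- vapply(verdicts, `[[`, logical(1), "criterion_a")
  cands$criterion_b <- vapply(verdicts, `[[`, logical(1), "criterion_b")
  cands$reason <- vapply(verdicts, `[[`, character(1), "reason")
  cands
}
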