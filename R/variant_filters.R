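# Somatic variant filter cascades.
#
# Variants arrive fully annotated (depths, allele frequencies, functional
# class, clinical significance, population frequencies across databases,
# effect-predictor calls); the filters only consume annotations.  Every
# rejected variant carries the full ordered list of rules it failed, so the
# verdict is independent of rule evaluation order.

benign_vote_labels <- c("benign", "tolerated", "possibly damaging", "low",
                        "medium", "neutral")

predictor_names <- c("SIFT", "Polyphen2_HDIV", "MutationAssessor", "MetaSVM",
                     "FATHMM")

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

check_variant_fields <- function(variants, fields) {
  for (f in fields) {
    if (is.null(variants[[f]]))
      hrd_stop("variant table missing required column: ", f)
    if (any(is.na(variants[[f]])))
      hrd_stop("variant table has missing values in required column: ", f)
  }
}

finish_filter <- function(variants, reasons) {
  kept_idx <- which(!vapply(reasons, length, integer(1)))
  rej_idx <- setdiff(seq_len(nrow(variants)), kept_idx)
  structure(list(
    kept = variants[kept_idx, , drop = FALSE],
    rejected = variants[rej_idx, , drop = FALSE],
    reasons = reasons[rej_idx]), class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("<filter_result> kept ", nrow(x$kept), " / ",
      nrow(x$kept) + nrow(x$rejected), " variants\n", sep = "")
  if (length(x$reasons)) {
    tab <- sort(table(unlist(x$reasons)), decreasing = TRUE)
    cat("  rejection reasons: ",
        paste0(names(tab), "=", tab, collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Whole-exome somatic variant filter cascade
#'
#' Applies the cohort-wide exome filter rules, recording every failed rule per
#' variant: minimum alternative depth (2 reads), minimum alternative
#' frequency (0.25), clinical significance not benign, not a synonymous SNV,
#' exonic or splicing functional class, recurrence in fewer than
#' `max_recurrence` distinct tumours, every population-database frequency at
#' most `popfreq_max`, and fewer than 3 of the 5 effect predictors voting a
#' benign-leaning label (Benign / Tolerated / Possibly damaging / Low /
#' Medium / Neutral, matched case-insensitively; missing predictions never
#' count as benign votes).
#'
#' The two detection-quality minima are applied as independent filters by
#' default; `rule1_conjunctive = TRUE` instead removes a variant only when it
#' fails both (the literal conjunctive reading of the rule).
#'
#' @param variants cohort-wide data frame, one row per variant per sample,
#'   with columns `sample`, `chrom`, `pos`, `ref`, `alt`, `alt_depth`,
#'   `alt_freq`, `clinsig`, `exonic_class`, `func_class`, population
#'   frequency columns prefixed `popfreq_`, and predictor columns named
#'   `SIFT`, `Polyphen2_HDIV`, `MutationAssessor`, `MetaSVM`, `FATHMM`.
#' @param min_alt_depth,min_alt_freq detection-quality minima (defaults 2
#'   and 0.25).
#' @param max_recurrence variants present in at least this many distinct
#'   tumours are removed (default 5).
#' @param popfreq_max maximum population frequency in any database
#'   (default 0.001).
#' @param max_benign_votes variants with more than this many benign-leaning
#'   predictor votes are removed (default 2).
#' @param rule1_conjunctive apply the depth and frequency minima jointly
#'   instead of independently.
#' @return A `filter_result`: list with `kept` (data frame), `rejected`
#'   (data frame) and `reasons` (list of character vectors, parallel to
#'   `rejected`).
#' @export
filter_wes_cohort <- function(variants, min_alt_depth = 2,
                              min_alt_freq = 0.25, max_recurrence = 5,
                              popfreq_max = 0.001, max_benign_votes = 2,
                              rule1_conjunctive = FALSE) {
  check_variant_fields(variants, c("alt_depth", "alt_freq"))
  check_variant_fields(variants, c("sample", "chrom", "pos", "ref", "alt"))
  n <- nrow(variants)
  reasons <- vector("list", n)
  add <- function(fail, reason) {
    for (i in which(fail)) reasons[[i]] <<- c(reasons[[i]], reason)
    reasons
  }
  low_depth <- variants$alt_depth < min_alt_depth
  low_freq <- variants$alt_freq < min_alt_freq
  if (rule1_conjunctive) {
    reasons <- add(low_depth & low_freq, "min_alt_depth_and_freq")
  } else {
    reasons <- add(low_depth, "min_alt_depth")
    reasons <- add(low_freq, "min_alt_freq")
  }
  clinsig <- tolower(as.character(variants$clinsig %||% ""))
  reasons <- add(grepl("benign", clinsig), "benign_clinsig")
  reasons <- add(tolower(as.character(variants$exonic_class %||% "")) ==
                   "synonymous-snv", "synonymous")
  reasons <- add(!(tolower(as.character(variants$func_class %||% "")) %in%
                     c("exonic", "splicing")), "func_class")
  # recurrence: distinct tumours sharing the (chrom,pos,ref,alt) key
  key <- variant_key(variants)
  n_tumours <- vapply(split(variants$sample, key),
                      function(s) length(unique(s)), integer(1))
  reasons <- add(n_tumours[key] >= max_recurrence, "recurrence")
  pf_cols <- grep("^popfreq_", names(variants), value = TRUE)
  if (length(pf_cols)) {
    pf <- as.matrix(variants[, pf_cols, drop = FALSE])
    pf[is.na(pf)] <- 0
    reasons <- add(apply(pf, 1, max) > popfreq_max, "pop_freq")
  }
  pred_cols <- intersect(predictor_names, names(variants))
  if (length(pred_cols)) {
    votes <- Reduce(`+`, lapply(pred_cols, function(p) {
      lab <- tolower(trimws(as.character(variants[[p]])))
      as.integer(!is.na(lab) & lab %in% benign_vote_labels)
    }))
    reasons <- add(votes > max_benign_votes, "predictor_vote")
  }
  finish_filter(variants, reasons)
}

#' Targeted-panel variant filter
#'
#' Rejects variants with low allele frequency, low coverage, or a high
#' 1000 Genomes population frequency.  By default the three conditions act
#' independently (any one rejects); `conjunctive_popfreq = TRUE` implements
#' the literal reading in which a variant is excluded only when (low
#' frequency or low coverage) and high population frequency hold together.
#'
#' @param variants data frame with columns `alt_freq`, `total_depth` and
#'   `popfreq_1000g` (missing 1000 Genomes frequencies are treated as 0 with
#'   a warning).
#' @param vaf_min minimum allele frequency (default 0.05).
#' @param cov_min minimum total depth (default 100).
#' @param popfreq_max maximum 1000 Genomes frequency (default 0.001).
#' @param conjunctive_popfreq see above.
#' @return A `filter_result` (see [filter_wes_cohort()]).
#' @export
filter_targeted <- function(variants, vaf_min = 0.05, cov_min = 100,
                            popfreq_max = 0.001,
                            conjunctive_popfreq = FALSE) {
  check_variant_fields(variants, c("alt_freq", "total_depth"))
  pf <- variants$popfreq_1000g
  if (is.null(pf)) {
    warning("popfreq_1000g column missing; treating as 0", call. = FALSE)
    pf <- rep(0, nrow(variants))
  }
  if (anyNA(pf)) {
    warning("missing 1000 Genomes frequencies treated as 0", call. = FALSE)
    pf[is.na(pf)] <- 0
  }
  low_vaf <- variants$alt_freq < vaf_min
  low_cov <- variants$total_depth < cov_min
  high_pf <- pf > popfreq_max
  reasons <- vector("list", nrow(variants))
  if (conjunctive_popfreq) {
    fail <- (low_vaf | low_cov) & high_pf
    for (i in which(fail)) reasons[[i]] <- "quality_and_popfreq"
  } else {
    for (i in which(low_vaf)) reasons[[i]] <- c(reasons[[i]], "low_vaf")
    for (i in which(low_cov)) reasons[[i]] <- c(reasons[[i]], "low_coverage")
    for (i in which(high_pf)) reasons[[i]] <- c(reasons[[i]], "pop_freq_1000g")
  }
  finish_filter(variants, reasons)
}

#' Restrict variants to a gene list
#'
#' Keeps variants whose gene symbol is in the list; matching is exact after
#' upper-casing both sides.
#'
#' @param variants data frame with a `gene` column.
#' @param gene_list character vector of symbols, or a path readable by
#'   [read_gene_list()].
#' @return A `filter_result`; rejected variants carry reason `"gene_list"`.
#' @export
restrict_to_genes <- function(variants, gene_list) {
  if (is.character(gene_list) && length(gene_list) == 1L &&
      file.exists(gene_list))
    gene_list <- read_gene_list(gene_list)
  if (!length(gene_list)) hrd_stop("gene list is empty")
  inlist <- toupper(as.character(variants$gene)) %in% toupper(gene_list)
  reasons <- vector("list", nrow(variants))
  for (i in which(!inlist)) reasons[[i]] <- "gene_list"
  finish_filter(variants, reasons)
}

#' Infer LOH from the variant allele frequency
#'
#' Flags loss of heterozygosity when the variant allele frequency is at least
#' `vaf_loh_threshold` (inclusive): in a tumour that has lost the wild-type
#' allele, reads carry predominantly the variant.  The default threshold of
#' 0.7 is this package's choice; adjust for expected tumour purity.
#'
#' @param alt_freq variant allele frequency (fraction; vectorized).
#' @param vaf_loh_threshold inclusive threshold (default 0.7).
#' @return Logical vector.
#' @export
infer_loh_from_vaf <- function(alt_freq, vaf_loh_threshold = 0.7) {
  if (any(alt_freq < 0 | alt_freq > 1, na.rm = TRUE))
    hrd_stop("alt_freq must be in [0, 1]")
  alt_freq >= vaf_loh_threshold
}

#' Read a one-symbol-per-line gene list
#'
#' @param path text file, one gene symbol per line; blank lines and lines
#'   starting with `#` are ignored.
#' @return Character vector of unique symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Bundled gene lists
#'
#' Returns the path to one of the editable gene-list fixtures shipped with
#' the package: `"cgc"`, a cancer gene census symbol list (synthetic
#' placeholder subset of well-established census genes; replace with a full
#' licensed export for production use), or `"ddr"`, a DNA-damage-response
#' list assembled from genes annotated to DNA damage checkpoint, telomere
#' maintenance, DNA replication, DNA repair, translesion synthesis and
#' radiation-response processes.
#'
#' @param which `"cgc"` or `"ddr"`.
#' @return File path.
#' @export
bundled_gene_list <- function(which = c("cgc", "ddr")) {
  which <- match.arg(which)
  fname <- c(cgc = "cgc_genes_synthetic.txt", ddr = "ddr_genes.txt")[which]
  system.file("extdata", fname, package = "hrdkit", mustWork = TRUE)
}
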