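#' Score RAD51 foci positivity for one sample
#'
#' Given per-cell RAD51 foci counts for cells already gated on a cycling
#' marker (geminin/EdU/DAPI upstream), computes the percentage of
#' marker-positive cells with strictly more than `foci_threshold` foci.
#' With `inclusive = TRUE` the threshold becomes `>=` (at least that many
#' foci).
#'
#' @param cells data frame with columns `marker_positive` (logical or 0/1)
#'   and `foci_count` (non-negative integers); optionally `sample`, `arm`.
#' @param foci_threshold foci positivity cutoff (default 5, strict `>`).
#' @param min_cells minimum marker-positive cells per condition before a
#'   warning is issued (default 100).
#' @param inclusive count cells with `foci_count >= foci_threshold` instead
#'   of strictly more.
#' @return A `sample_foci_score`: list with `sample`, `arm`, `n_cells`,
#'   `percent_positive`.
#' @export
score_rad51_sample <- function(cells, foci_threshold = 5, min_cells = 100,
                               inclusive = FALSE) {
  if (is.null(cells$marker_positive) || is.null(cells$foci_count))
    hrd_stop("cells must have columns marker_positive and foci_count")
  if (any(cells$foci_count < 0)) hrd_stop("foci_count must be >= 0")
  mp <- cells[as.logical(cells$marker_positive), , drop = FALSE]
  if (!nrow(mp)) hrd_stop("no marker-positive cells in sample")
  if (nrow(mp) < min_cells)
    warning("only ", nrow(mp), " marker-positive cells (minimum ", min_cells,
            " recommended)", call. = FALSE)
  pos <- if (inclusive) mp$foci_count >= foci_threshold
         else mp$foci_count > foci_threshold
  structure(list(
    sample = if (!is.null(cells$sample)) cells$sample[1] else NA_character_,
    arm = if (!is.null(cells$arm)) cells$arm[1] else NA_character_,
    n_cells = nrow(mp),
    percent_positive = 100 * sum(pos) / nrow(mp)),
    class = "sample_foci_score")
}

#' Classify homologous-recombination functional status of a PDX
#'
#' A PDX is HR-deficient when the mean percentage of RAD51-foci-positive
#' cells across its cisplatin-treated xenografts is strictly below
#' `percent_threshold` (default 10%); otherwise HR-proficient.
#'
#' @param treated_percents numeric vector of treated-arm `percent_positive`
#'   values (one per xenograft), or a list of `sample_foci_score`s.
#' @param percent_threshold deficiency cutoff in percent (default 10).
#' @param weights optional cell counts for a cell-count-weighted mean
#'   (default unweighted).
#' @param pdx PDX identifier.
#' @return An `hr_status_call`: list with `pdx`, `mean_percent_positive`,
#'   `status` (`"HR-deficient"` or `"HR-proficient"`).
#' @export
classify_hr <- function(treated_percents, percent_threshold = 10,
                        weights = NULL, pdx = NA_character_) {
  if (is.list(treated_percents))
    treated_percents <- vapply(treated_percents,
                               function(s) s$percent_positive, numeric(1))
  if (!length(treated_percents)) hrd_stop("no treated sample scores for PDX ", pdx)
  m <- if (is.null(weights)) mean(treated_percents)
       else stats::weighted.mean(treated_percents, weights)
  structure(list(pdx = pdx, mean_percent_positive = m,
                 status = if (m < percent_threshold) "HR-deficient"
                          else "HR-proficient"),
            class = "hr_status_call")
}

#' @export
print.hr_status_call <- function(x, ...) {
  cat("<hr_status_call> ", x$pdx, ": ", x$status, " (mean ",
      round(x$mean_percent_positive, 1), "% RAD51-positive cells)\n", sep = "")
  invisible(x)
}

#' Score a whole foci table (per sample, then per PDX)
#'
#' @param foci data frame with columns `pdx`, `sample`, `arm`
#'   (`"control"`/`"treated"`), `marker_positive`, `foci_count`.
#' @inheritParams score_rad51_sample
#' @inheritParams classify_hr
#' @return List with `samples` (data frame of per-sample scores) and `pdx`
#'   (data frame with `pdx`, `mean_percent_positive`, `status` from treated
#'   arms).
#' @export
score_rad51_cohort <- function(foci, foci_threshold = 5,
                               percent_threshold = 10, min_cells = 100,
                               inclusive = FALSE) {
  per_sample <- do.call(rbind, lapply(
    split(foci, list(foci$pdx, foci$sample), drop = TRUE), function(d) {
      s <- score_rad51_sample(d, foci_threshold, min_cells, inclusive)
      data.frame(pdx = d$pdx[1], sample = s$sample, arm = s$arm,
                 n_cells = s$n_cells, percent_positive = s$percent_positive,
                 stringsAsFactors = FALSE)
    }))
  rownames(per_sample) <- NULL
  treated <- per_sample[per_sample$arm == "treated", , drop = FALSE]
  per_pdx <- do.call(rbind, lapply(split(treated, treated$pdx), function(d) {
    call <- classify_hr(d$percent_positive, percent_threshold, pdx = d$pdx[1])
    data.frame(pdx = call$pdx,
               mean_percent_positive = call$mean_percent_positive,
               status = call$status, stringsAsFactors = FALSE)
  }))
  rownames(per_pdx) <- NULL
  list(samples = per_sample, pdx = per_pdx)
}
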