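#' Construct a binned copy-ratio profile
#'
#' A binned profile holds ordered, non-overlapping fixed-width genomic bins
#' with a linear copy ratio per bin (1.0 = diploid baseline) and a usability
#' flag.  Shallow whole-genome sequencing pipelines typically produce such
#' profiles from read counts in 50 kb windows.
#'
#' @param sample sample identifier.
#' @param bins data frame with columns `chrom`, `start`, `end`, `ratio` and
#'   optionally `usable` (logical or 0/1, default all usable).  Coordinates
#'   0-based half-open.
#' @param bin_width nominal bin width in bp (informational; default 50000).
#' @return A `binned_profile` object.
#' @export
binned_profile <- function(sample, bins, bin_width = 50000) {
  need <- c("chrom", "start", "end", "ratio")
  if (!all(need %in% names(bins)))
    hrd_stop("bins must have columns ", paste(need, collapse = ", "))
  if (is.null(bins$usable)) bins$usable <- TRUE
  bins$usable <- as.logical(bins$usable)
  bins <- bins[order(match(bins$chrom, unique(bins$chrom)), bins$start), ,
               drop = FALSE]
  rownames(bins) <- NULL
  for (chrom in unique(bins$chrom)) {
    b <- bins[bins$chrom == chrom, ]
    if (any(b$start >= b$end)) hrd_stop("bin with start >= end on ", chrom)
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)]))
      hrd_stop("overlapping bins on ", chrom)
  }
  if (any(bins$ratio[bins$usable] <= 0, na.rm = TRUE))
    hrd_stop("usable bins must have ratio > 0")
  structure(list(sample = sample, bins = bins, bin_width = bin_width),
            class = "binned_profile")
}

#' @export
print.binned_profile <- function(x, ...) {
  cat("<binned_profile> sample ", x$sample, ": ", nrow(x$bins), " bins (",
      sum(x$bins$usable), " usable), width ", x$bin_width, " bp\n", sep = "")
  invisible(x)
}

#' Thin probe-level measurements to one probe per window
#'
#' Reduces dense probe-level profiles (e.g. from CGH arrays) so that at most
#' one randomly selected measured position is retained per non-overlapping
#' window per chromosome, making array profiles comparable with binned
#' sequencing profiles.
#'
#' @param probes data frame with columns `chrom`, `position`, `value`, sorted
#'   by position within chromosome.
#' @param window window width in bp (default 10000).
#' @param seed integer seed; the uniform within-window selection is
#'   reproducible under it.
#' @return Data frame of retained probes, same columns, original order.
#' @export
thin_probes <- function(probes, window = 10000, seed = 1L) {
  need <- c("chrom", "position", "value")
  if (!all(need %in% names(probes)))
    hrd_stop("probes must have columns ", paste(need, collapse = ", "))
  if (!nrow(probes)) return(probes)
  for (chrom in unique(probes$chrom)) {
    p <- probes$position[probes$chrom == chrom]
    if (is.unsorted(p)) hrd_stop("probes unsorted on ", chrom)
  }
  with_seed(seed, {
    keep <- logical(nrow(probes))
    for (chrom in unique(probes$chrom)) {
      idx <- which(probes$chrom == chrom)
      win <- probes$position[idx] %/% window
      for (w in unique(win)) {
        members <- idx[win == w]
        pick <- if (length(members) == 1L) members else
          members[sample.int(length(members), 1L)]
        keep[pick] <- TRUE
      }
    }
    probes[keep, , drop = FALSE]
  })
}

#' Estimate the per-profile minimal copy-number-alteration cutoff
#'
#' Determines the smallest difference between segment levels that should be
#' regarded as a real copy-number change for this profile.  All pairwise
#' absolute differences between the levels of large segments (>= `large_seg`)
#' are pooled; differences within noise cluster near zero while real
#' copy-number steps cluster at discrete offsets, so the cutoff is placed at
#' the first local minimum of a kernel density estimate of the differences.
#' When no local minimum exists (e.g. a flat genome), the fallback is
#' `3 * resid_mad`, three times the median absolute deviation of
#' within-segment bin residuals recorded at segmentation time.
#'
#' @param seg a `segmented_profile` with at least 2 segments.
#' @param large_seg minimum segment length (bp) entering the density estimate
#'   (default 10 Mb).
#' @return A `level_cutoff`: list with `value` (> 0, copy-ratio units) and
#'   `method` (`"density_valley"` or `"residual_mad"`).
#' @export
estimate_level_cutoff <- function(seg, large_seg = 10e6) {
  stopifnot(inherits(seg, "segmented_profile"))
  s <- seg$segments
  if (nrow(s) < 2)
    hrd_stop("cutoff estimation needs >= 2 segments; supply an explicit cutoff")
  big <- s[s$end - s$start >= large_seg, , drop = FALSE]
  fallback <- function() {
    v <- 3 * seg$resid_mad
    if (!is.finite(v) || v <= 0)
      hrd_stop("cannot estimate cutoff (no level structure, zero residual MAD);",
               " supply an explicit cutoff")
    list(value = v, method = "residual_mad")
  }
  res <- NULL
  if (nrow(big) >= 2) {
    d <- abs(as.numeric(stats::dist(big$level)))
    if (length(d) >= 2 && stats::sd(d) > 0) {
      dens <- stats::density(d, n = 512)
      y <- dens$y
      # first interior local minimum that follows a local maximum
      is_min <- which(diff(sign(diff(y))) > 0) + 1L
      is_max <- which(diff(sign(diff(y))) < 0) + 1L
      if (length(is_min) && length(is_max) && min(is_min) > min(is_max)) {
        v <- dens$x[min(is_min)]
        if (v > 0) res <- list(value = v, method = "density_valley")
      }
    }
  }
  if (is.null(res)) res <- fallback()
  structure(res, class = "level_cutoff")
}

#' @export
print.level_cutoff <- function(x, ...) {
  cat("<level_cutoff> ", signif(x$value, 4), " (", x$method, ")\n", sep = "")
  invisible(x)
}

as_cutoff <- function(cutoff) {
  if (inherits(cutoff, "level_cutoff")) return(cutoff)
  if (is_scalar_number(cutoff) && cutoff > 0)
    return(structure(list(value = cutoff, method = "user"),
                     class = "level_cutoff"))
  hrd_stop("cutoff must be a positive number or a level_cutoff object")
}

#' Merge adjacent segments separated by sub-cutoff level differences
#'
#' Iteratively merges, within each chromosome, the adjacent pair of segments
#' with the smallest level difference, as long as that difference is below the
#' cutoff.  The merged level is the bin-count-weighted mean.  Terminates when
#' no adjacent same-chromosome pair differs by less than the cutoff, so the
#' result is a fixed point.
#'
#' @param seg a `segmented_profile`.
#' @param cutoff a `level_cutoff` from [estimate_level_cutoff()] or a positive
#'   number.
#' @return The merged `segmented_profile`.
#' @export
merge_segments <- function(seg, cutoff) {
  stopifnot(inherits(seg, "segmented_profile"))
  cutoff <- as_cutoff(cutoff)
  s <- seg$segments
  repeat {
    if (nrow(s) < 2) break
    same <- s$chrom[-nrow(s)] == s$chrom[-1]
    d <- abs(diff(s$level))
    d[!same] <- Inf
    i <- which.min(d)
    if (d[i] >= cutoff$value) break
    w1 <- s$n_bins[i]; w2 <- s$n_bins[i + 1]
    s$level[i] <- (s$level[i] * w1 + s$level[i + 1] * w2) / (w1 + w2)
    s$end[i] <- s$end[i + 1]
    s$n_bins[i] <- w1 + w2
    s <- s[-(i + 1), , drop = FALSE]
  }
  rownames(s) <- NULL
  out <- seg
  out$segments <- s
  out
}

#' Count large-scale genomic alterations (LGAs) per chromosome arm
#'
#' An LGA is a chromosome-arm break between two adjacent large genomic
#' segments: after splitting segments by arm (excising the centromere), arm
#' segments longer than `min_segment` are retained, and one LGA is counted for
#' each consecutive retained pair whose genomic gap is smaller than `max_gap`
#' and whose level difference reaches the per-profile cutoff.
#'
#' @param seg a merged `segmented_profile`.
#' @param genome a [load_genome()] build covering every chromosome present.
#' @param cutoff a `level_cutoff` or positive number; minimum level difference
#'   for a break to count.
#' @param min_segment retained segments must be strictly longer than this
#'   (default 10 Mb).
#' @param max_gap the gap between retained neighbours must be strictly smaller
#'   than this (default 3 Mb).
#' @return An `lga_report`: list with `sample`, `per_arm` (named integer
#'   vector of break counts), `lga_total`, `classification` (`"HRD"`,
#'   `"HRP"` or `"borderline"`, see [classify_hrd()]), `review_flag`
#'   (free-text, e.g. for manual ploidy review; `NA` by default) and
#'   `parameters`.
#' @export
call_lgas <- function(seg, genome, cutoff, min_segment = 10e6, max_gap = 3e6) {
  stopifnot(inherits(seg, "segmented_profile"))
  cutoff <- as_cutoff(cutoff)
  s <- seg$segments
  missing_chr <- setdiff(unique(s$chrom), genome$chrom)
  if (length(missing_chr))
    hrd_stop("chromosome absent from genome build: ", missing_chr[1])
  # split every segment by arm, carrying its level
  pieces <- list()
  for (i in seq_len(nrow(s))) {
    sp <- split_by_arm(s$chrom[i], s$start[i], s$end[i], genome)
    if (nrow(sp)) {
      sp$level <- s$level[i]
      pieces[[length(pieces) + 1L]] <- sp
    }
  }
  arms <- arm_table(genome)
  per_arm <- stats::setNames(integer(nrow(arms)), arms$arm)
  if (length(pieces)) {
    pc <- do.call(rbind, pieces)
    for (arm in unique(pc$arm)) {
      a <- pc[pc$arm == arm, , drop = FALSE]
      a <- a[order(a$start), , drop = FALSE]
      a <- a[a$end - a$start > min_segment, , drop = FALSE]
      if (nrow(a) < 2) next
      gaps <- a$start[-1] - a$end[-nrow(a)]
      dlev <- abs(diff(a$level))
      per_arm[arm] <- sum(gaps < max_gap & dlev >= cutoff$value)
    }
  }
  total <- sum(per_arm)
  structure(
    list(sample = seg$sample, per_arm = per_arm, lga_total = total,
         classification = classify_hrd(total), review_flag = NA_character_,
         parameters = list(min_segment = min_segment, max_gap = max_gap,
                           cutoff = cutoff$value, cutoff_method = cutoff$method)),
    class = "lga_report")
}

#' @export
print.lga_report <- function(x, ...) {
  cat("<lga_report> sample ", x$sample, ": ", x$lga_total, " LGAs -> ",
      x$classification, "\n", sep = "")
  nz <- x$per_arm[x$per_arm > 0]
  if (length(nz))
    cat("  arms: ", paste0(names(nz), "=", nz, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Classify HRD status from an LGA total
#'
#' Samples with more than 20 LGAs are classified as homologous recombination
#' deficient (HRD), samples with fewer than 18 as proficient (HRP); totals of
#' 18--20 are flagged `"borderline"` for manual review and never auto-resolved.
#'
#' @param lga_total non-negative integer count of LGAs.
#' @return `"HRD"`, `"HRP"` or `"borderline"`.
#' @examples
#' classify_hrd(21)  # HRD
#' classify_hrd(17)  # HRP
#' classify_hrd(19)  # borderline
#' @export
classify_hrd <- function(lga_total) {
  if (!is_count(lga_total)) hrd_stop("lga_total must be a non-negative integer")
  if (lga_total > 20) "HRD" else if (lga_total < 18) "HRP" else "borderline"
}
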