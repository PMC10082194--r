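# Penalized least-squares change-point segmentation.
#
# The per-chromosome model is piecewise-constant Gaussian: the cost of a
# segment is its within-segment sum of squared deviations from the mean, and
# each additional breakpoint pays `penalty`.  The global optimum is found by
# optimal partitioning with PELT pruning, which is exact for this cost.

# Exact optimal partitioning with pruning over one numeric vector.
# Returns integer vector of segment end indices (last index always included).
pelt_1d <- function(x, penalty) {
  n <- length(x)
  if (n == 0L) return(integer())
  if (n == 1L) return(1L)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  seg_cost <- function(s, t) {
    # cost of segment x[s..t], s,t 1-based inclusive; vectorized over s
    len <- t - s + 1
    sm <- cs[t + 1] - cs[s]
    (cs2[t + 1] - cs2[s]) - sm^2 / len
  }
  F <- c(-penalty, rep(NA_real_, n))  # F[t+1] = optimal cost of x[1..t]
  prev <- integer(n)                  # last changepoint before t
  cand <- 1L                          # candidate segment starts (1-based)
  for (t in 1:n) {
    costs <- F[cand] + penalty + seg_cost(cand, t)
    best <- which.min(costs)
    F[t + 1] <- costs[best]
    prev[t] <- cand[best] - 1L
    # PELT prune: drop candidates that can never be optimal again
    keep <- F[cand] + seg_cost(cand, t) <= F[t + 1]
    cand <- c(cand[keep], t + 1L)
  }
  ends <- integer()
  t <- n
  while (t > 0L) {
    ends <- c(t, ends)
    t <- prev[t]
  }
  ends
}

#' Segment a binned copy-ratio profile
#'
#' Fits a per-chromosome piecewise-constant least-squares model to the usable
#' bins of a binned profile, with a fixed penalty per breakpoint, using exact
#' penalized optimal partitioning (PELT).  Chromosome boundaries are always
#' breakpoints.  Each output segment carries the mean ratio of its member bins
#' and their count.
#'
#' The default `penalty = "auto"` uses \eqn{2 \hat\sigma^2 \log n} per
#' chromosome, with \eqn{\hat\sigma} estimated robustly from lag-1 bin
#' differences (MAD / sqrt(2)) — a BIC-like choice calibrated on synthetic
#' step profiles.
#'
#' @param profile a `binned_profile` from [binned_profile()] or
#'   [read_binned_profile()].
#' @param penalty positive penalty per breakpoint in squared copy-ratio units,
#'   or `"auto"`.
#' @return A `segmented_profile`: list with `sample`, `segments` (data frame
#'   `chrom`, `start`, `end`, `level`, `n_bins`), and `resid_mad`, the median
#'   absolute deviation of within-segment bin residuals (used as the fallback
#'   for cutoff estimation).
#' @seealso [estimate_level_cutoff()], [merge_segments()], [call_lgas()]
#' @export
segment_profile <- function(profile, penalty = "auto") {
  stopifnot(inherits(profile, "binned_profile"))
  bins <- profile$bins[profile$bins$usable, , drop = FALSE]
  if (!nrow(bins)) hrd_stop("profile has no usable bins")
  auto <- identical(penalty, "auto")
  if (!auto && (!is_scalar_number(penalty) || penalty <= 0))
    hrd_stop("penalty must be a positive number or \"auto\"")
  segs <- list()
  resids <- list()
  for (chrom in unique(bins$chrom)) {
    b <- bins[bins$chrom == chrom, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    x <- b$ratio
    pen <- if (auto) {
      sd_hat <- if (length(x) > 1) stats::mad(diff(x)) / sqrt(2) else 0
      max(2 * sd_hat^2 * log(length(x)), 1e-8)
    } else penalty
    ends <- pelt_1d(x, pen)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    for (k in seq_along(ends)) {
      idx <- starts[k]:ends[k]
      level <- mean(x[idx])
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = chrom, start = b$start[starts[k]], end = b$end[ends[k]],
        level = level, n_bins = length(idx), stringsAsFactors = FALSE)
      resids[[length(resids) + 1L]] <- x[idx] - level
    }
  }
  segments <- do.call(rbind, segs)
  segments <- segments[order(match(segments$chrom, unique(bins$chrom)),
                             segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  structure(
    list(sample = profile$sample, segments = segments,
         resid_mad = stats::mad(unlist(resids), center = 0)),
    class = "segmented_profile")
}

#' @export
print.segmented_profile <- function(x, ...) {
  cat("<segmented_profile> sample ", x$sample, ": ", nrow(x$segments),
      " segments on ", length(unique(x$segments$chrom)), " chromosomes\n",
      sep = "")
  invisible(x)
}
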