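#' Construct an allele-specific copy-number profile
#'
#' Holds ordered, non-overlapping segments with integer total/major/minor copy
#' number and probe counts, as produced by allele-specific copy-number callers
#' from SNP/CGH arrays.  Substrate for the scar scores [score_loh()],
#' [score_tai()], [score_lst()] and their sum [hrd_scar_score()].
#'
#' @param sample sample identifier.
#' @param segments data frame with columns `chrom`, `start`, `end`,
#'   `total_cn`, `major_cn`, `minor_cn`, `n_probes` (0-based half-open
#'   coordinates).
#' @return An `allelic_profile` object.
#' @export
allelic_profile <- function(sample, segments) {
  need <- c("chrom", "start", "end", "total_cn", "major_cn", "minor_cn",
            "n_probes")
  if (!all(need %in% names(segments)))
    hrd_stop("segments must have columns ", paste(need, collapse = ", "))
  s <- segments[order(match(segments$chrom, unique(segments$chrom)),
                      segments$start), need, drop = FALSE]
  rownames(s) <- NULL
  if (nrow(s)) {
    bad <- s$major_cn < s$minor_cn | s$minor_cn < 0 |
      s$major_cn + s$minor_cn != s$total_cn
    if (any(bad))
      hrd_stop("segment ", which(bad)[1],
               ": need major_cn >= minor_cn >= 0 and major + minor = total")
    if (any(s$n_probes < 1)) hrd_stop("n_probes must be >= 1")
    if (any(s$start >= s$end)) hrd_stop("segment with start >= end")
    for (chrom in unique(s$chrom)) {
      ss <- s[s$chrom == chrom, ]
      if (nrow(ss) > 1 && any(ss$start[-1] < ss$end[-nrow(ss)]))
        hrd_stop("overlapping segments on ", chrom)
    }
  }
  structure(list(sample = sample, segments = s, smoothed = FALSE),
            class = "allelic_profile")
}

#' @export
print.allelic_profile <- function(x, ...) {
  cat("<allelic_profile> sample ", x$sample, ": ", nrow(x$segments),
      " segments", if (x$smoothed) " (smoothed)", "\n", sep = "")
  invisible(x)
}

#' Filter out small alterations and fuse like-state neighbours
#'
#' Removes segments shorter than `min_size` (their span is absorbed into the
#' flanking gap) and fuses neighbouring segments that share the same
#' (major, minor) state and are separated by less than `min_size` of removed
#' material or gap.  Fused probe counts are summed and the fused span runs
#' from the first to the last member.  The operation is idempotent.
#'
#' @param profile an `allelic_profile`.
#' @param min_size minimum alteration size in bp (default 3 Mb).
#' @return The smoothed `allelic_profile` (flagged `smoothed`).
#' @export
smooth_small_alterations <- function(profile, min_size = 3e6) {
  stopifnot(inherits(profile, "allelic_profile"))
  s <- profile$segments
  s <- s[s$end - s$start >= min_size, , drop = FALSE]
  if (nrow(s) > 1) {
    out <- s[1, , drop = FALSE]
    for (i in 2:nrow(s)) {
      j <- nrow(out)
      gap <- s$start[i] - out$end[j]
      if (s$chrom[i] == out$chrom[j] && gap < min_size &&
          s$major_cn[i] == out$major_cn[j] &&
          s$minor_cn[i] == out$minor_cn[j]) {
        out$end[j] <- s$end[i]
        out$n_probes[j] <- out$n_probes[j] + s$n_probes[i]
      } else {
        out <- rbind(out, s[i, , drop = FALSE])
      }
    }
    s <- out
  }
  rownames(s) <- NULL
  res <- profile
  res$segments <- s
  res$smoothed <- TRUE
  res
}

ensure_smoothed <- function(profile, min_size = 3e6) {
  if (isTRUE(profile$smoothed)) profile
  else smooth_small_alterations(profile, min_size)
}

# Split allelic segments by arm; n_probes prorated by retained length.
split_allelic_by_arm <- function(segments, genome) {
  pieces <- list()
  for (i in seq_len(nrow(segments))) {
    sp <- split_by_arm(segments$chrom[i], segments$start[i], segments$end[i],
                       genome)
    if (!nrow(sp)) next
    len0 <- segments$end[i] - segments$start[i]
    sp$major_cn <- segments$major_cn[i]
    sp$minor_cn <- segments$minor_cn[i]
    sp$n_probes <- segments$n_probes[i] * (sp$end - sp$start) / len0
    pieces[[length(pieces) + 1L]] <- sp
  }
  if (!length(pieces))
    return(data.frame(arm = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      major_cn = integer(), minor_cn = integer(),
                      n_probes = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, pieces)
}

#' Count LOH regions
#'
#' Counts maximal runs of contiguous segments with minor copy number zero
#' (contiguous = separated by less than `gap_max`) whose span is at least
#' `min_size` but which do not cover the chromosome's entire assayed extent.
#' The count is chromosome-level: runs may span the centromere.
#'
#' @param profile an `allelic_profile` (smoothed automatically if not yet).
#' @param genome a [load_genome()] build.
#' @param min_size minimum LOH span in bp (default 15 Mb).
#' @param gap_max maximum gap joining segments into one run (default 3 Mb).
#' @return Integer count.
#' @export
score_loh <- function(profile, genome, min_size = 15e6, gap_max = 3e6) {
  profile <- ensure_smoothed(profile)
  s <- profile$segments
  total <- 0L
  for (chrom in unique(s$chrom)) {
    sc <- s[s$chrom == chrom, , drop = FALSE]
    n <- nrow(sc)
    # run ids over contiguous (gap < gap_max) minor == 0 stretches
    run_id <- integer(n)
    cur <- 0L
    for (i in seq_len(n)) {
      if (sc$minor_cn[i] != 0) { run_id[i] <- 0L; next }
      if (i > 1 && run_id[i - 1] > 0 &&
          sc$start[i] - sc$end[i - 1] < gap_max) {
        run_id[i] <- run_id[i - 1]
      } else {
        cur <- cur + 1L
        run_id[i] <- cur
      }
    }
    for (r in setdiff(unique(run_id), 0L)) {
      members <- which(run_id == r)
      span <- sc$end[max(members)] - sc$start[min(members)]
      whole <- length(members) == n  # run covers every assayed segment
      if (span >= min_size && !whole) total <- total + 1L
    }
  }
  total
}

#' Count arms with telomeric allelic imbalance (TAI)
#'
#' An arm scores when the maximal run of allelically imbalanced segments
#' (major != minor) anchored at the arm's telomeric end sums to more than
#' `min_probes` probes, while the arm segment adjacent to the centromere is
#' allelically balanced (major == minor).  Arms with no assayed segments are
#' skipped.
#'
#' @inheritParams score_loh
#' @param min_probes the telomeric run must exceed this many probes
#'   (default 500).
#' @param gap_max maximum gap joining segments into one run (default 3 Mb).
#' @return Integer count of qualifying arms.
#' @export
score_tai <- function(profile, genome, min_probes = 500, gap_max = 3e6) {
  profile <- ensure_smoothed(profile)
  pc <- split_allelic_by_arm(profile$segments, genome)
  total <- 0L
  for (arm in unique(pc$arm)) {
    a <- pc[pc$arm == arm, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    is_p <- grepl("p$", arm)
    # orient from telomere toward centromere
    ord <- if (is_p) seq_len(nrow(a)) else rev(seq_len(nrow(a)))
    a <- a[ord, , drop = FALSE]
    # centromere-adjacent segment must be balanced
    cen_seg <- a[nrow(a), ]
    if (cen_seg$major_cn != cen_seg$minor_cn) next
    # telomere-anchored imbalanced run
    run_probes <- 0
    for (i in seq_len(nrow(a))) {
      if (a$major_cn[i] == a$minor_cn[i]) break
      if (i > 1) {
        gap <- if (is_p) a$start[i] - a$end[i - 1] else a$start[i - 1] - a$end[i]
        if (gap >= gap_max) break
      }
      run_probes <- run_probes + a$n_probes[i]
    }
    if (run_probes > min_probes) total <- total + 1L
  }
  total
}

#' Count large-scale state transitions (LST)
#'
#' After filtering alterations smaller than `smooth`, one LST is counted per
#' pair of consecutive arm segments of at least `min_segment` each, separated
#' by less than `smooth`, whose allele-specific (major, minor) states differ.
#'
#' @inheritParams score_loh
#' @param min_segment minimum flanking segment length in bp (default 10 Mb).
#' @param smooth smoothing size / maximum junction gap in bp (default 3 Mb).
#' @return Integer count.
#' @export
score_lst <- function(profile, genome, min_segment = 10e6, smooth = 3e6) {
  profile <- ensure_smoothed(profile, smooth)
  pc <- split_allelic_by_arm(profile$segments, genome)
  total <- 0L
  for (arm in unique(pc$arm)) {
    a <- pc[pc$arm == arm, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    a <- a[a$end - a$start >= min_segment, , drop = FALSE]
    if (nrow(a) < 2) next
    gaps <- a$start[-1] - a$end[-nrow(a)]
    changed <- diff(a$major_cn) != 0 | diff(a$minor_cn) != 0
    total <- total + sum(gaps < smooth & changed)
  }
  total
}

#' Compute the combined HRD scar score (LOH + TAI + LST)
#'
#' Applies small-alteration smoothing once and evaluates the three scar
#' components on the same smoothed profile.
#'
#' @inheritParams score_loh
#' @param loh_min,tai_min_probes,lst_min,smooth component thresholds (see the
#'   individual scorers).
#' @return A `scar_scores` object: list with `loh`, `tai`, `lst`, `total`.
#' @export
hrd_scar_score <- function(profile, genome, loh_min = 15e6,
                           tai_min_probes = 500, lst_min = 10e6,
                           smooth = 3e6) {
  sm <- ensure_smoothed(profile, smooth)
  loh <- score_loh(sm, genome, min_size = loh_min, gap_max = smooth)
  tai <- score_tai(sm, genome, min_probes = tai_min_probes, gap_max = smooth)
  lst <- score_lst(sm, genome, min_segment = lst_min, smooth = smooth)
  structure(list(sample = profile$sample, loh = loh, tai = tai, lst = lst,
                 total = loh + tai + lst),
            class = "scar_scores")
}

#' @export
print.scar_scores <- function(x, ...) {
  cat("<scar_scores> sample ", x$sample, ": LOH=", x$loh, " TAI=", x$tai,
      " LST=", x$lst, " total=", x$total, "\n", sep = "")
  invisible(x)
}
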