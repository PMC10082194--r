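# Shared fixture builders.  Everything is constructed in code; no files.

toy_genome <- function() load_genome("toy3")

# A segmented profile built directly from a segment table (levels known).
make_seg <- function(segments, sample = "s1", resid_mad = 0.01) {
  segments$n_bins <- segments$n_bins %||% pmax(1L, (segments$end - segments$start) %/% 50000)
  structure(list(sample = sample, segments = segments, resid_mad = resid_mad),
            class = "segmented_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# allelic profile from compact rows: list(chrom, start_mb, end_mb, major, minor, probes)
make_allelic <- function(rows, sample = "a1") {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = r[[1]], start = r[[2]] * 1e6, end = r[[3]] * 1e6,
               total_cn = r[[4]] + r[[5]], major_cn = r[[4]],
               minor_cn = r[[5]],
               n_probes = if (length(r) >= 6) r[[6]] else
                 max(1, round((r[[3]] - r[[2]]) * 20)),
               stringsAsFactors = FALSE)
  }))
  allelic_profile(sample, df)
}

# independent O(n^2) reference scan for LGA counting on one arm's retained
# segments (start, end, level)
brute_force_arm_lgas <- function(a, cutoff, min_segment = 10e6, max_gap = 3e6) {
  a <- a[order(a$start), , drop = FALSE]
  a <- a[a$end - a$start > min_segment, , drop = FALSE]
  count <- 0L
  if (nrow(a) < 2) return(count)
  for (i in seq_len(nrow(a) - 1)) {
    j <- i + 1
    if (a$start[j] - a$end[i] < max_gap &&
        abs(a$level[j] - a$level[i]) >= cutoff) count <- count + 1L
  }
  count
}

# independent enumeration oracle for the two-sided Fisher p-value, using
# explicit factorial arithmetic (lchoose), not dhyper
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- p[match(a, ks)]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}
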