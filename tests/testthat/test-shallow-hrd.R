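# exhaustive optimal-partitioning dynamic program (no pruning), used as the
# independent oracle for the penalized segmentation on small inputs
dp_segment_oracle <- function(x, penalty) {
  n <- length(x)
  cost <- function(s, t) {
    seg <- x[s:t]
    sum((seg - mean(seg))^2)
  }
  opt <- c(-penalty, rep(Inf, n))
  back <- integer(n)
  for (t in 1:n) {
    for (s in 1:t) {
      v <- opt[s] + penalty + cost(s, t)
      if (v < opt[t + 1]) { opt[t + 1] <- v; back[t] <- s - 1L }
    }
  }
  ends <- integer(); t <- n
  while (t > 0) { ends <- c(t, ends); t <- back[t] }
  ends
}

make_profile <- function(ratio, chrom = "chr1", bin_width = 50000,
                         sample = "p1") {
  n <- length(ratio)
  binned_profile(sample, data.frame(
    chrom = chrom, start = (0:(n - 1)) * bin_width,
    end = (1:n) * bin_width, ratio = ratio), bin_width)
}

test_that("probe thinning keeps one probe per window, reproducibly", {
  probes <- data.frame(chrom = "chr1", position = seq(0, 9000, by = 1000),
                       value = rnorm(10))
  thin <- thin_probes(probes, window = 10000, seed = 3)
  expect_equal(nrow(thin), 1)

  dense <- data.frame(chrom = "chr1", position = sort(sample.int(1e6, 500)),
                      value = rnorm(500))
  t1 <- thin_probes(dense, seed = 11)
  t2 <- thin_probes(dense, seed = 11)
  expect_identical(t1, t2)
  # at most one probe per 10 kb window
  expect_false(any(duplicated(t1$position %/% 10000)))

  expect_equal(nrow(thin_probes(probes[0, ], seed = 1)), 0)
  unsorted <- data.frame(chrom = "chr1", position = c(5, 1), value = 1:2)
  expect_error(thin_probes(unsorted, seed = 1), "unsorted")
})

test_that("segmentation recovers planted steps and matches the DP oracle", {
  # zero noise: exact recovery of 3 planted changes
  x <- rep(c(1.0, 1.6, 1.0, 1.4), each = 50)
  seg <- segment_profile(make_profile(x), penalty = 0.1)
  expect_equal(nrow(seg$segments), 4)
  expect_equal(seg$segments$n_bins, rep(50, 4))
  expect_equal(seg$segments$level, c(1.0, 1.6, 1.0, 1.4))

  # constant profile: one segment per chromosome
  flat <- binned_profile("f", data.frame(
    chrom = rep(c("chr1", "chr2"), each = 100),
    start = rep((0:99) * 5e4, 2), end = rep((1:100) * 5e4, 2),
    ratio = 1))
  sf <- segment_profile(flat, penalty = 0.1)
  expect_equal(nrow(sf$segments), 2)

  # noisy profiles match the exhaustive dynamic program exactly
  set.seed(7)
  for (rep_i in 1:10) {
    y <- rep(sample(c(1, 1.5, 2), 4, replace = TRUE), each = 40) +
      rnorm(160, 0, 0.05)
    y <- pmax(y, 0.05)
    pen <- 0.2
    seg <- segment_profile(make_profile(y), penalty = pen)
    got_ends <- cumsum(seg$segments$n_bins)
    expect_equal(got_ends, dp_segment_oracle(y, pen))
  }

  # planted steps + noise: breakpoints within 2 bins of truth
  set.seed(21)
  truth_ends <- c(60, 130, 200)
  z <- rep(c(1.0, 1.5, 1.0), times = c(60, 70, 70)) + rnorm(200, 0, 0.05)
  seg <- segment_profile(make_profile(pmax(z, 0.05)), penalty = "auto")
  ends <- cumsum(seg$segments$n_bins)
  expect_equal(length(ends), 3)
  expect_true(all(abs(ends - truth_ends) <= 2))

  expect_error(segment_profile(make_profile(x), penalty = -1), "positive")
})

test_that("level cutoff sits in the valley between noise and real steps", {
  set.seed(5)
  levels <- rep(c(1.0, 1.5, 2.0), times = 5) + rnorm(15, 0, 0.02)
  seg <- make_seg(data.frame(
    chrom = "chr1", start = (0:14) * 12e6, end = (1:15) * 12e6,
    level = levels, n_bins = 240))
  cut <- estimate_level_cutoff(seg)
  expect_gt(cut$value, 0.1)
  expect_lt(cut$value, 0.5)
  expect_equal(cut$method, "density_valley")
})

test_that("cutoff falls back to 3x residual MAD on level-free profiles", {
  seg <- make_seg(data.frame(
    chrom = "chr1", start = c(0, 50e6), end = c(50e6, 100e6),
    level = c(1.0, 1.0), n_bins = 1000), resid_mad = 0.01)
  cut <- estimate_level_cutoff(seg)
  expect_equal(cut$value, 0.03)
  expect_equal(cut$method, "residual_mad")

  single <- make_seg(data.frame(chrom = "chr1", start = 0, end = 50e6,
                                level = 1, n_bins = 1000))
  expect_error(estimate_level_cutoff(single), "explicit cutoff")
})

test_that("segment merging is iterative and stops at the cutoff", {
  near <- make_seg(data.frame(chrom = "chr1", start = c(0, 20e6),
                              end = c(20e6, 40e6), level = c(1.00, 1.02),
                              n_bins = c(400, 400)))
  merged <- merge_segments(near, 0.1)
  expect_equal(nrow(merged$segments), 1)
  expect_equal(merged$segments$level, 1.01)  # equal-weight mean
  expect_equal(merged$segments$n_bins, 800)

  far <- make_seg(data.frame(chrom = "chr1", start = c(0, 20e6),
                             end = c(20e6, 40e6), level = c(1.0, 1.6),
                             n_bins = c(400, 400)))
  expect_equal(nrow(merge_segments(far, 0.5)$segments), 2)

  # chain merging recomputes the weighted mean after every merge: with
  # cutoff 0.05 the first merge leaves levels 1.02 / 1.08 (gap 0.06), so the
  # chain collapses fully only once the cutoff clears that remerged gap
  chain <- make_seg(data.frame(chrom = "chr1", start = (0:2) * 20e6,
                               end = (1:3) * 20e6,
                               level = c(1.00, 1.04, 1.08),
                               n_bins = rep(400, 3)))
  expect_equal(nrow(merge_segments(chain, 0.05)$segments), 2)
  expect_equal(nrow(merge_segments(chain, 0.07)$segments), 1)

  # fixed point: no remaining adjacent pair differs by less than the cutoff
  set.seed(9)
  for (i in 1:20) {
    lv <- runif(8, 1, 2)
    s <- make_seg(data.frame(chrom = "chr1", start = (0:7) * 15e6,
                             end = (1:8) * 15e6, level = lv,
                             n_bins = rep(300, 8)))
    m <- merge_segments(s, 0.2)$segments
    if (nrow(m) > 1) expect_true(all(abs(diff(m$level)) >= 0.2))
    # merging never crosses chromosomes and preserves bin totals
    expect_equal(sum(m$n_bins), 8 * 300)
  }
})

test_that("LGA calling applies the size, gap and cutoff rules per arm", {
  g <- toy_genome()
  # two qualifying breaks on 1p (toy3 1p = [0, 95 Mb))
  s <- make_seg(data.frame(chrom = "chr1",
                           start = c(0, 20e6, 35e6),
                           end = c(20e6, 35e6, 50e6),
                           level = c(2, 3, 2), n_bins = rep(300, 3)))
  rep_ <- call_lgas(s, g, 0.5)
  expect_equal(rep_$lga_total, 2)
  expect_equal(unname(rep_$per_arm["1p"]), 2)

  # middle segment of 8 Mb is dropped; remaining gap 8 Mb kills the break
  s2 <- make_seg(data.frame(chrom = "chr1",
                            start = c(0, 20e6, 28e6),
                            end = c(20e6, 28e6, 45e6),
                            level = c(2, 3, 2), n_bins = rep(300, 3)))
  expect_equal(call_lgas(s2, g, 0.5)$lga_total, 0)

  # sub-cutoff level difference does not count
  s3 <- make_seg(data.frame(chrom = "chr1",
                            start = c(0, 20e6),
                            end = c(20e6, 40e6),
                            level = c(2, 2.1), n_bins = rep(300, 2)))
  expect_equal(call_lgas(s3, g, 0.5)$lga_total, 0)

  expect_error(call_lgas(make_seg(data.frame(
    chrom = "chrZ", start = 0, end = 20e6, level = 1, n_bins = 10)), g, 0.5),
    "chrZ")
})

test_that("LGA calling agrees with a brute-force reference on random profiles", {
  g <- toy_genome()
  set.seed(13)
  for (i in 1:300) {
    n <- sample(2:12, 1)
    # random arm-internal segments on 1q ([105, 200) Mb), random sizes/gaps
    bounds <- sort(runif(2 * n, 105e6, 200e6))
    a <- data.frame(chrom = "chr1",
                    start = bounds[seq(1, 2 * n, 2)],
                    end = bounds[seq(2, 2 * n, 2)],
                    level = sample(seq(1, 3, 0.25), n, replace = TRUE))
    a <- a[a$end > a$start, ]
    s <- make_seg(cbind(a, n_bins = pmax(1, (a$end - a$start) %/% 5e4)))
    got <- call_lgas(s, g, 0.4)$lga_total
    expect_equal(got, brute_force_arm_lgas(a, 0.4))
  }
})

test_that("LGA total is invariant under chromosome reordering", {
  g <- toy_genome()
  segs <- data.frame(
    chrom = rep(c("chr1", "chr2", "chr3"), each = 3),
    start = rep(c(0, 20e6, 35e6), 3), end = rep(c(20e6, 35e6, 50e6), 3),
    level = rep(c(2, 3, 2), 3), n_bins = 300)
  base <- call_lgas(make_seg(segs), g, 0.5)$lga_total
  set.seed(1)
  for (i in 1:5) {
    perm <- segs[sample.int(nrow(segs)), ]
    perm <- perm[order(match(perm$chrom, unique(perm$chrom)), perm$start), ]
    expect_equal(call_lgas(make_seg(perm), g, 0.5)$lga_total, base)
  }
})

test_that("tightening geometry parameters never raises the LGA count", {
  g <- toy_genome()
  set.seed(17)
  for (i in 1:50) {
    n <- sample(3:10, 1)
    bounds <- sort(runif(2 * n, 0, 95e6))
    a <- data.frame(chrom = "chr2", start = bounds[seq(1, 2 * n, 2)],
                    end = bounds[seq(2, 2 * n, 2)],
                    level = sample(seq(1, 3, 0.5), n, replace = TRUE))
    a <- a[a$end > a$start, ]
    s <- make_seg(cbind(a, n_bins = pmax(1, (a$end - a$start) %/% 5e4)))
    base <- call_lgas(s, g, 0.4)$lga_total
    expect_lte(call_lgas(s, g, 0.4, max_gap = 1e6)$lga_total, base)
    expect_lte(call_lgas(s, g, 0.4, min_segment = 15e6)$lga_total, base)
  }
})

test_that("HRD classification is a step function with 17/18 and 20/21 edges", {
  expect_equal(classify_hrd(21), "HRD")
  expect_equal(classify_hrd(20), "borderline")
  expect_equal(classify_hrd(18), "borderline")
  expect_equal(classify_hrd(17), "HRP")
  expect_equal(classify_hrd(0), "HRP")
  expect_equal(classify_hrd(100), "HRD")
  expect_error(classify_hrd(-1), "non-negative")
})
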