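test_that("small-alteration smoothing removes, fuses, and is idempotent", {
  # 12 Mb (2,1) / 2 Mb (3,1) / 12 Mb (2,1) -> one fused 26 Mb (2,1)
  p <- make_allelic(list(
    list("chr1", 0, 12, 2, 1), list("chr1", 12, 14, 3, 1),
    list("chr1", 14, 26, 2, 1)))
  sm <- smooth_small_alterations(p)
  expect_equal(nrow(sm$segments), 1)
  expect_equal(sm$segments$start, 0)
  expect_equal(sm$segments$end, 26e6)
  expect_equal(sm$segments$major_cn, 2)

  # different flanks stay separate after the small segment is removed
  p2 <- make_allelic(list(
    list("chr1", 0, 12, 2, 1), list("chr1", 12, 14, 3, 1),
    list("chr1", 14, 26, 3, 2)))
  sm2 <- smooth_small_alterations(p2)
  expect_equal(nrow(sm2$segments), 2)
  expect_equal(sm2$segments$minor_cn, c(1, 2))

  # idempotence
  expect_equal(smooth_small_alterations(sm)$segments, sm$segments)
  expect_equal(smooth_small_alterations(sm2)$segments, sm2$segments)
})

test_that("LOH counting enforces the size floor and whole-chromosome bar", {
  g <- toy_genome()
  # 30 Mb minor=0 run inside a covered chromosome -> 1
  p <- make_allelic(list(
    list("chr1", 0, 40, 1, 1), list("chr1", 40, 70, 2, 0),
    list("chr1", 70, 95, 1, 1)))
  expect_equal(score_loh(p, g), 1)

  # minor=0 across the whole assayed chromosome -> 0
  whole <- make_allelic(list(list("chr1", 0, 95, 1, 0)))
  expect_equal(score_loh(whole, g), 0)

  # 10 Mb run is below the 15 Mb floor -> 0
  short <- make_allelic(list(
    list("chr1", 0, 40, 1, 1), list("chr1", 40, 50, 2, 0),
    list("chr1", 50, 95, 1, 1)))
  expect_equal(score_loh(short, g), 0)

  # two minor=0 segments joined by a < 3 Mb gap form one run
  joined <- make_allelic(list(
    list("chr1", 0, 30, 1, 1), list("chr1", 30, 40, 1, 0),
    list("chr1", 42, 52, 1, 0), list("chr1", 52, 95, 1, 1)))
  expect_equal(score_loh(joined, g), 1)
})

test_that("TAI requires a telomeric imbalanced run and centromeric balance", {
  g <- toy_genome()
  # q arm of toy3 chr1 is [105, 200) Mb; telomere at 200
  yes <- make_allelic(list(
    list("chr1", 105, 150, 1, 1), list("chr1", 150, 200, 2, 1, 900)))
  expect_equal(score_tai(yes, g), 1)

  # same geometry, only 400 probes -> 0
  few <- make_allelic(list(
    list("chr1", 105, 150, 1, 1), list("chr1", 150, 200, 2, 1, 400)))
  expect_equal(score_tai(few, g), 0)

  # imbalance reaching the centromeric end -> 0
  full <- make_allelic(list(list("chr1", 105, 200, 2, 1, 1800)))
  expect_equal(score_tai(full, g), 0)

  # p arm orientation: telomere at 0
  p_arm <- make_allelic(list(
    list("chr2", 0, 50, 3, 1, 1000), list("chr2", 50, 95, 2, 2)))
  expect_equal(score_tai(p_arm, g), 1)

  # balanced telomeric segment -> 0
  bal <- make_allelic(list(
    list("chr1", 105, 150, 2, 2, 900), list("chr1", 150, 200, 1, 1, 900)))
  expect_equal(score_tai(bal, g), 0)
})

test_that("LST counts state changes between large adjacent segments", {
  g <- toy_genome()
  lst1 <- make_allelic(list(
    list("chr1", 105, 117, 2, 1), list("chr1", 117, 129, 3, 2)))
  expect_equal(score_lst(lst1, g), 1)

  # removed 2 Mb interruption leaves a 2 Mb gap < 3 Mb: still adjacent
  lst2 <- make_allelic(list(
    list("chr1", 105, 117, 2, 1), list("chr1", 117, 119, 1, 0),
    list("chr1", 119, 131, 3, 1)))
  expect_equal(score_lst(lst2, g), 1)

  # same state across the junction: no transition
  same <- make_allelic(list(
    list("chr1", 105, 117, 2, 1), list("chr1", 117, 129, 2, 1)))
  expect_equal(score_lst(same, g), 0)

  # one flank below 10 Mb: no transition
  small_flank <- make_allelic(list(
    list("chr1", 105, 117, 2, 1), list("chr1", 117, 125, 3, 2),
    list("chr1", 125, 200, 1, 1)))
  expect_equal(score_lst(small_flank, g), 0)
})

test_that("LST agrees with an independent pairwise scan on random profiles", {
  g <- toy_genome()
  # reference: smooth, split by arm, O(n^2) scan over all retained pairs
  brute_lst <- function(profile) {
    sm <- smooth_small_alterations(profile)
    total <- 0L
    for (chrom in unique(sm$segments$chrom)) {
      gb <- g[g$chrom == chrom, ]
      for (arm_bounds in list(c(0, gb$cen_start), c(gb$cen_end, gb$length))) {
        s <- sm$segments
        s <- s[s$chrom == chrom, ]
        s$start <- pmax(s$start, arm_bounds[1])
        s$end <- pmin(s$end, arm_bounds[2])
        s <- s[s$end - s$start >= 10e6, ]
        s <- s[order(s$start), ]
        if (nrow(s) < 2) next
        for (i in seq_len(nrow(s) - 1)) {
          if (s$start[i + 1] - s$end[i] < 3e6 &&
              (s$major_cn[i + 1] != s$major_cn[i] ||
               s$minor_cn[i + 1] != s$minor_cn[i]))
            total <- total + 1L
        }
      }
    }
    total
  }
  set.seed(31)
  for (i in 1:300) {
    n <- sample(2:10, 1)
    bounds <- sort(runif(2 * n, 0, 200e6))
    states <- cbind(major = sample(1:3, n, TRUE), minor = sample(0:2, n, TRUE))
    states[, 1] <- pmax(states[, 1], states[, 2])
    rows <- lapply(seq_len(n), function(k)
      list("chr3", bounds[2 * k - 1] / 1e6, bounds[2 * k] / 1e6,
           states[k, 1], states[k, 2]))
    prof <- make_allelic(rows)
    expect_equal(score_lst(prof, g), brute_lst(prof))
  }
})

test_that("scar scores are invariant under state-preserving subdivision", {
  g <- toy_genome()
  set.seed(8)
  for (i in 1:50) {
    sim <- simulate_allelic_profile(sample(0:3, 1), sample(0:2, 1),
                                    sample(0:4, 1), seed = i,
                                    sample = paste0("s", i))
    base <- hrd_scar_score(sim$profile, g)
    # split every segment in half (state preserved)
    s <- sim$profile$segments
    halves <- do.call(rbind, lapply(seq_len(nrow(s)), function(k) {
      mid <- (s$start[k] + s$end[k]) / 2
      rbind(transform(s[k, ], end = mid, n_probes = s$n_probes[k] / 2),
            transform(s[k, ], start = mid, n_probes = s$n_probes[k] / 2))
    }))
    split_prof <- allelic_profile(sim$profile$sample, halves)
    split_scores <- hrd_scar_score(split_prof, g)
    expect_equal(split_scores$loh, base$loh)
    expect_equal(split_scores$tai, base$tai)
    expect_equal(split_scores$lst, base$lst)
  }
})

test_that("limit behaviour: infinite thresholds drive scores to zero", {
  g <- toy_genome()
  sim <- simulate_allelic_profile(2, 1, 3, seed = 4)
  expect_equal(score_loh(sim$profile, g, min_size = 1e12), 0)
  expect_equal(score_lst(sim$profile, g, min_segment = 1e12), 0)
  expect_equal(score_tai(sim$profile, g, min_probes = Inf), 0)
})

test_that("combined scar score recovers planted events and sums components", {
  g <- toy_genome()
  sim <- simulate_allelic_profile(3, 2, 4, seed = 2, sample = "planted")
  sc <- hrd_scar_score(sim$profile, g)
  expect_equal(sc$loh, 3)
  expect_equal(sc$tai, 2)
  expect_equal(sc$lst, 4)
  expect_equal(sc$total, 9)

  empty <- allelic_profile("none", data.frame(
    chrom = character(), start = numeric(), end = numeric(),
    total_cn = integer(), major_cn = integer(), minor_cn = integer(),
    n_probes = numeric()))
  sc0 <- hrd_scar_score(empty, g)
  expect_equal(sc0$total, 0)

  # decoy events (10 Mb LOH, 300-probe TAI) never score
  dec <- simulate_allelic_profile(0, 0, 0, seed = 6, decoys = TRUE)
  expect_equal(hrd_scar_score(dec$profile, g)$total, 0)
})

test_that("random planted scar requests are recovered exactly", {
  g <- toy_genome()
  set.seed(19)
  reqs <- data.frame(loh = sample(0:6, 120, TRUE),
                     tai = sample(0:4, 120, TRUE),
                     lst = sample(0:8, 120, TRUE))
  reqs <- reqs[ceiling(reqs$loh / 2) + reqs$tai + ceiling(reqs$lst / 3) <= 6, ]
  for (i in seq_len(nrow(reqs))) {
    sim <- simulate_allelic_profile(reqs$loh[i], reqs$tai[i], reqs$lst[i],
                                    seed = 100 + i)
    sc <- hrd_scar_score(sim$profile, g)
    expect_equal(c(sc$loh, sc$tai, sc$lst),
                 c(reqs$loh[i], reqs$tai[i], reqs$lst[i]))
  }
})
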