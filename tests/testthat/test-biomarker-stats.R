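test_that("contingency assembly respects the explicit response grouping", {
  ann <- data.frame(
    category = c("CR", "PR", "SD", "PD", "PD", "SD"),
    hrd = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE))
  tab <- build_contingency(ann, "hrd", "cr_pr_sd_vs_pd")
  expect_equal(unclass(tab)[1, ], c(responder = 3, non_responder = 1),
               ignore_attr = TRUE)
  expect_equal(unclass(tab)[2, ], c(responder = 1, non_responder = 1),
               ignore_attr = TRUE)

  tab2 <- build_contingency(ann, "hrd", "cr_pr_vs_rest")
  expect_equal(sum(unclass(tab2)[, 1]), 2)  # CR + PR only

  # missing values are excluded and counted
  ann$hrd[1] <- NA
  tab3 <- build_contingency(ann, "hrd", "cr_pr_sd_vs_pd")
  expect_equal(attr(tab3, "n_excluded"), 1)
  expect_equal(sum(tab3), 5)

  expect_error(build_contingency(ann[0, ], "hrd", "cr_pr_sd_vs_pd"), "empty")
  bad <- data.frame(category = "XX", hrd = TRUE)
  expect_error(build_contingency(bad, "hrd", "cr_pr_sd_vs_pd"), "unknown")
})

test_that("Fisher p-values reproduce hand-checkable tables", {
  expect_equal(fisher_exact_two_sided(matrix(c(2, 1, 1, 2), 2)), 1)
  # symmetric diagonal table: the two extreme tables out of C(10,5)
  expect_equal(fisher_exact_two_sided(matrix(c(5, 0, 0, 5), 2)), 2 / 252)
  expect_warning(p0 <- fisher_exact_two_sided(matrix(c(0, 0, 3, 4), 2)),
                 "zero margin")
  expect_equal(p0, 1)
})

test_that("Fisher enumeration equals the factorial oracle exhaustively", {
  # every 2x2 table with total N <= 45, plus a stratified sweep to N = 60
  for (n in 2:45) {
    combos <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    combos <- combos[rowSums(combos) <= n, ]
    combos$d <- n - rowSums(combos)
    got <- suppressWarnings(mapply(function(a, b, c, d)
      fisher_exact_two_sided(matrix(c(a, c, b, d), 2)),
      combos$a, combos$b, combos$c, combos$d))  # zero margins warn by design
    want <- mapply(fisher_oracle, combos$a, combos$b, combos$c, combos$d)
    expect_equal(got, want, tolerance = 1e-12)
  }
  set.seed(67)
  for (i in 1:2000) {
    n <- sample(46:60, 1)
    cuts <- sort(sample(0:n, 3, replace = TRUE))
    a <- cuts[1]; b <- cuts[2] - cuts[1]; c <- cuts[3] - cuts[2]
    d <- n - cuts[3]
    expect_equal(suppressWarnings(
      fisher_exact_two_sided(matrix(c(a, c, b, d), 2))),
      fisher_oracle(a, b, c, d), tolerance = 1e-12)
  }
})

test_that("Fisher p agrees with stats::fisher.test and is transpose-invariant", {
  set.seed(71)
  for (i in 1:200) {
    m <- matrix(rpois(4, 8), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    p <- fisher_exact_two_sided(m)
    expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-9)
    expect_equal(p, fisher_exact_two_sided(t(m)))
    expect_equal(p, fisher_exact_two_sided(m[2:1, 2:1]))
  }
})

test_that("diagnostic metrics use standard column-wise definitions", {
  m <- matrix(c(14, 6, 1, 11), 2)  # rows: test +/-, cols: condition +/-
  dm <- diagnostic_metrics(m)
  expect_equal(dm$sensitivity, 14 / 20)
  expect_equal(dm$specificity, 11 / 12)

  perfect <- diagnostic_metrics(matrix(c(15, 0, 0, 40), 2))
  expect_equal(unlist(perfect), c(sensitivity = 1, specificity = 1,
                                  ppv = 1, npv = 1))

  # undefined denominators come back NA, never 0
  dm0 <- diagnostic_metrics(matrix(c(0, 0, 3, 4), 2))
  expect_true(is.na(dm0$sensitivity) || dm0$sensitivity >= 0)
  expect_true(is.na(diagnostic_metrics(matrix(c(0, 5, 0, 5), 2))$ppv))

  # sensitivity + false-negative rate = 1 when defined
  set.seed(73)
  for (i in 1:50) {
    m <- matrix(rpois(4, 6) + 1, 2)
    dm <- diagnostic_metrics(m)
    fnr <- m[2, 1] / (m[1, 1] + m[2, 1])
    expect_equal(dm$sensitivity + fnr, 1)
  }
})

test_that("methylation banding follows the observed complete/partial ranges", {
  expect_equal(classify_methylation(95), "complete")
  expect_equal(classify_methylation(90), "complete")
  expect_equal(classify_methylation(50), "partial")
  expect_equal(classify_methylation(0), "unmethylated")
  expect_equal(classify_methylation(9.9), "unmethylated")
  expect_warning(out <- classify_methylation(75), "outside the partial band")
  expect_equal(out, "partial")
  expect_error(classify_methylation(101), "\\[0, 100\\]")
})

test_that("combined biomarker is mutation-with-LOH OR complete methylation", {
  expect_true(brca_status(TRUE, 5)$combined_biomarker)
  expect_true(brca_status(FALSE, 95)$combined_biomarker)
  expect_false(brca_status(FALSE, 50)$combined_biomarker)
  expect_false(brca_status(FALSE, NA)$combined_biomarker)
})

test_that("Pearson correlation matches the closed form", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)), sqrt(27 / 28))
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "length")
})

test_that("Mann-Whitney exact p matches full label-permutation enumeration", {
  res <- mann_whitney_two_tailed(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)
  expect_equal(res$method, "exact")

  same <- mann_whitney_two_tailed(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)

  # brute force over all C(n+m, n) group assignments
  perm_oracle <- function(x, y) {
    pooled <- c(x, y); n <- length(x)
    idx <- utils::combn(length(pooled), n)
    us <- apply(idx, 2, function(ii) {
      r <- rank(pooled)
      sum(r[ii]) - n * (n + 1) / 2
    })
    u_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
    mu <- length(x) * length(y) / 2
    # two-sided by doubling the smaller tail (matching the exact convention)
    min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  }
  set.seed(79)
  for (i in 1:30) {
    x <- round(rnorm(sample(3:6, 1)), 6)
    y <- round(rnorm(sample(3:6, 1)) + 1, 6)
    got <- mann_whitney_two_tailed(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$p, perm_oracle(x, y), tolerance = 1e-10)
  }
})

test_that("Kaplan-Meier estimate reduces to the empirical survival function", {
  res <- km_and_gbw(c(1, 2, 3), c(1, 1, 1), rep("g", 3))
  expect_equal(res$km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(unname(res$medians["g"]), 2)

  skip_if_not_installed("survival")
  set.seed(83)
  t_ <- rexp(40, 0.1); e_ <- rbinom(40, 1, 0.7)
  ours <- km_and_gbw(t_, e_, rep("g", 40))
  ref <- survival::survfit(survival::Surv(t_, e_) ~ 1)
  ref_s <- summary(ref, times = ours$km$time)
  expect_equal(ours$km$survival, ref_s$surv, tolerance = 1e-10)
})

test_that("Gehan-Breslow-Wilcoxon detects separation and is null-calibrated", {
  # identical groups: statistic 0, p 1
  t_ <- c(1, 2, 3, 4); e_ <- c(1, 1, 1, 1)
  same <- km_and_gbw(c(t_, t_), c(e_, e_), rep(c("a", "b"), each = 4))
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)

  # well-separated exponentials: p matches a permutation oracle
  set.seed(89)
  t1 <- rexp(20, 1); t2 <- rexp(20, 0.25)
  time <- c(t1, t2); event <- rep(1, 40)
  grp <- rep(c("a", "b"), each = 20)
  got <- km_and_gbw(time, event, grp)
  stat_perm <- replicate(2000, {
    g <- sample(grp)
    km_and_gbw(time, event, g)$chisq
  })
  p_perm <- mean(stat_perm >= got$chisq)
  mc_err <- 3 * sqrt(max(p_perm, 1e-4) * (1 - p_perm) / 2000)
  expect_lt(abs(got$p - p_perm), max(0.01, mc_err + 0.005))

  expect_error(km_and_gbw(1:3, rep(1, 3), c("a", "b", "c")), "2 groups")
})
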