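# Contingency assembly, exact tests, diagnostic metrics, correlation, rank
# tests and survival comparison for biomarker-response association.

#' Assemble a 2x2 biomarker-by-response contingency table
#'
#' Cross-classifies cohort records by a biomarker predicate (rows) and a
#' response grouping (columns).  The grouping is an explicit argument because
#' different analyses use different responder definitions (e.g. CR+PR+SD
#' versus PD, or CR+PR versus the rest); no default is applied silently.
#' Records with a missing biomarker value or response category are excluded
#' and counted.
#'
#' @param annotations data frame with a response-category column (values in
#'   CR/PR/SD/PD) and the biomarker column.
#' @param biomarker name of a logical/0-1 column, or a logical vector.
#' @param grouping `"cr_pr_sd_vs_pd"` or `"cr_pr_vs_rest"`, or a character
#'   vector of categories counting as responders.
#' @param response_col name of the response-category column (default
#'   `"category"`).
#' @return A `contingency_table`: 2x2 integer matrix (rows biomarker +/-,
#'   columns responder/non-responder) with attribute `n_excluded`.
#' @export
build_contingency <- function(annotations, biomarker,
                              grouping = c("cr_pr_sd_vs_pd", "cr_pr_vs_rest"),
                              response_col = "category") {
  if (!nrow(annotations)) hrd_stop("empty annotation table")
  if (is.character(grouping) && length(grouping) == 1L &&
      grouping %in% c("cr_pr_sd_vs_pd", "cr_pr_vs_rest")) {
    responders <- switch(grouping, cr_pr_sd_vs_pd = c("CR", "PR", "SD"),
                         cr_pr_vs_rest = c("CR", "PR"))
  } else responders <- grouping
  bio <- if (is.character(biomarker) && length(biomarker) == 1L) {
    annotations[[biomarker]]
  } else biomarker
  if (is.null(bio)) hrd_stop("biomarker column not found")
  bio <- as.logical(bio)
  cat_ <- as.character(annotations[[response_col]])
  bad_cat <- !is.na(cat_) & !cat_ %in% response_levels
  if (any(bad_cat))
    hrd_stop("unknown response category: ", cat_[bad_cat][1])
  keep <- !is.na(bio) & !is.na(cat_)
  resp <- cat_[keep] %in% responders
  tab <- matrix(c(sum(bio[keep] & resp), sum(bio[keep] & !resp),
                  sum(!bio[keep] & resp), sum(!bio[keep] & !resp)),
                nrow = 2, byrow = TRUE,
                dimnames = list(biomarker = c("positive", "negative"),
                                response = c("responder", "non_responder")))
  structure(tab, n_excluded = sum(!keep),
            class = c("contingency_table", "matrix"))
}

#' Cross-classify two logical flags into a 2x2 table
#'
#' Convenience constructor for contingency analyses that do not involve the
#' CR/PR/SD/PD grouping, e.g. a functional test against a genomic
#' classification.  Rows follow `test_positive` (TRUE first), columns
#' `condition_positive`.
#'
#' @param test_positive,condition_positive logical vectors of equal length;
#'   pairs with missing values are dropped.
#' @return A `contingency_table` 2x2 matrix.
#' @export
contingency_from_flags <- function(test_positive, condition_positive) {
  keep <- !is.na(test_positive) & !is.na(condition_positive)
  t_ <- test_positive[keep]; c_ <- condition_positive[keep]
  tab <- matrix(c(sum(t_ & c_), sum(t_ & !c_),
                  sum(!t_ & c_), sum(!t_ & !c_)),
                nrow = 2, byrow = TRUE,
                dimnames = list(test = c("positive", "negative"),
                                condition = c("positive", "negative")))
  structure(tab, n_excluded = sum(!keep),
            class = c("contingency_table", "matrix"))
}

as_2x2 <- function(table) {
  m <- unclass(table)
  m <- matrix(as.numeric(m), nrow = 2)
  if (any(m < 0) || any(m != round(m)))
    hrd_stop("contingency table must hold non-negative integer counts")
  m
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Computes the exact two-sided p-value by direct enumeration: over all
#' tables with the observed margins, the hypergeometric probabilities no
#' greater than the observed table's probability (within relative tolerance
#' `1e-7` for ties) are summed — the probability-mass ordering convention
#' used by standard statistical software.
#'
#' @param table 2x2 matrix (a [build_contingency()] result or plain matrix).
#' @return The p-value.  A table with a zero margin returns 1 with a
#'   warning.
#' @examples
#' fisher_exact_two_sided(matrix(c(21, 9, 8, 17), nrow = 2))  # ~0.007
#' @export
fisher_exact_two_sided <- function(table) {
  m <- as_2x2(table)
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
    warning("zero margin: p = 1 by convention", call. = FALSE)
    return(1)
  }
  k <- max(0, c1 - (n - r1)):min(r1, c1)  # feasible values of cell (1,1)
  probs <- stats::dhyper(k, c1, n - c1, r1)
  p_obs <- probs[match(a, k)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Diagnostic metrics of a 2x2 biomarker-by-response table
#'
#' With rows biomarker +/- and columns responder/non-responder: sensitivity
#' is the biomarker-positive fraction of responders, specificity the
#' biomarker-negative fraction of non-responders, and PPV/NPV the
#' row-conditional responder and non-responder fractions.  A metric whose
#' denominator is zero is returned as `NA`, never as 0.
#'
#' @inheritParams fisher_exact_two_sided
#' @return List with `sensitivity`, `specificity`, `ppv`, `npv` (fractions).
#' @export
diagnostic_metrics <- function(table) {
  m <- as_2x2(table)
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  list(sensitivity = frac(a, a + c), specificity = frac(d, b + d),
       ppv = frac(a, a + b), npv = frac(d, c + d))
}

#' Classify a promoter methylation percentage
#'
#' Bands a methylation percentage into `"complete"` (>= `complete_min`),
#' `"partial"` (within `partial_range`), or `"unmethylated"` (below
#' `floor`).  Values falling between the bands are classed `"partial"` with
#' an out-of-band warning; the band boundaries reflect observed ranges, not
#' validated cutoffs, and are configurable.
#'
#' @param percent methylation percentage in [0, 100].
#' @param complete_min lower bound of the complete band (default 90).
#' @param partial_range two-element range of the partial band (default
#'   `c(40, 60)`).
#' @param floor detection floor below which the promoter is considered
#'   unmethylated (default 10).
#' @return `"unmethylated"`, `"partial"` or `"complete"`.
#' @export
classify_methylation <- function(percent, complete_min = 90,
                                 partial_range = c(40, 60), floor = 10) {
  if (!is_scalar_number(percent) || percent < 0 || percent > 100)
    hrd_stop("methylation percent must be in [0, 100]")
  if (percent >= complete_min) return("complete")
  if (percent < floor) return("unmethylated")
  if (percent < partial_range[1] || percent > partial_range[2])
    warning("methylation ", percent, "% is outside the partial band [",
            partial_range[1], ", ", partial_range[2],
            "]; classifying as partial", call. = FALSE)
  "partial"
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    hrd_stop("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    hrd_stop("zero variance in x or y")
  stats::cor(x, y, method = "pearson")
}

#' Two-tailed Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact p-value from the null rank-sum distribution when the smaller sample
#' has at most `exact_max` observations and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples.
#' @param exact_max largest min(n, m) for which the exact distribution is
#'   used (default 10).
#' @return List with `U` (statistic of the first sample), `p` and `method`.
#' @export
mann_whitney_two_tailed <- function(x, y, exact_max = 10) {
  if (!length(x) || !length(y)) hrd_stop("both samples must be non-empty")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && min(n, m) <= exact_max) {
    # exact: pwilcox gives P(U <= u) under the null
    p_lo <- stats::pwilcox(U, n, m)
    p_hi <- stats::pwilcox(U - 1, n, m, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- n * m / 2
  tie_tab <- table(r)
  sigma2 <- n * m / 12 * ((n + m + 1) -
    sum(tie_tab^3 - tie_tab) / ((n + m) * (n + m - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal_tie_corrected"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal_tie_corrected")
}

#' Kaplan-Meier estimate and Gehan-Breslow-Wilcoxon comparison
#'
#' Computes the product-limit survival estimate per group, the KM-based
#' median survival (first time the estimate drops to 0.5 or below; `NA` when
#' it never does), and for exactly two groups the Gehan-Breslow-Wilcoxon
#' test: the log-rank family statistic with the number at risk as the weight
#' at each event time, referred to chi-square on 1 df.
#'
#' @param time survival times (> 0).
#' @param event event indicator (1 = death, 0 = censored).
#' @param group group label per subject.
#' @return List with `km` (data frame `group`, `time`, `n_risk`, `n_event`,
#'   `survival`), `medians` (named vector), and for two groups `chisq` and
#'   `p`.
#' @export
km_and_gbw <- function(time, event, group) {
  if (any(time <= 0)) hrd_stop("survival times must be > 0")
  group <- as.character(group)
  groups <- unique(group)
  km_one <- function(t, e) {
    ord <- order(t)
    t <- t[ord]; e <- e[ord]
    times <- sort(unique(t[e == 1]))
    surv <- numeric(length(times)); n_risk <- integer(length(times))
    n_event <- integer(length(times))
    s <- 1
    for (i in seq_along(times)) {
      n_risk[i] <- sum(t >= times[i])
      n_event[i] <- sum(t == times[i] & e == 1)
      s <- s * (1 - n_event[i] / n_risk[i])
      surv[i] <- s
    }
    data.frame(time = times, n_risk = n_risk, n_event = n_event,
               survival = surv)
  }
  km <- do.call(rbind, lapply(groups, function(g) {
    d <- km_one(time[group == g], event[group == g])
    if (nrow(d)) cbind(group = g, d, stringsAsFactors = FALSE)
    else data.frame(group = character(), time = numeric(),
                    n_risk = integer(), n_event = integer(),
                    survival = numeric())
  }))
  medians <- vapply(groups, function(g) {
    d <- km[km$group == g, ]
    hit <- which(d$survival <= 0.5)
    if (length(hit)) d$time[min(hit)] else NA_real_
  }, numeric(1))
  out <- list(km = km, medians = medians)
  if (length(groups) == 2) {
    g1 <- group == groups[1]
    times <- sort(unique(time[event == 1]))
    num <- 0; var_sum <- 0
    for (tt in times) {
      at_risk <- time >= tt
      n_i <- sum(at_risk); n1_i <- sum(at_risk & g1)
      d_i <- sum(time == tt & event == 1)
      d1_i <- sum(time == tt & event == 1 & g1)
      if (n_i < 2 || d_i == 0) next
      e1_i <- d_i * n1_i / n_i
      v1_i <- d_i * (n1_i / n_i) * (1 - n1_i / n_i) * (n_i - d_i) / (n_i - 1)
      w <- n_i  # Gehan weight: number at risk
      num <- num + w * (d1_i - e1_i)
      var_sum <- var_sum + w^2 * v1_i
    }
    if (var_sum > 0) {
      out$chisq <- num^2 / var_sum
      out$p <- stats::pchisq(out$chisq, df = 1, lower.tail = FALSE)
    } else {
      out$chisq <- 0; out$p <- 1
    }
  } else if (length(groups) < 2) {
    out$chisq <- NULL
  } else {
    hrd_stop("the Gehan-Breslow-Wilcoxon comparison needs exactly 2 groups")
  }
  out
}

#' Combined BRCA biomarker status
#'
#' The combined biomarker is positive when the model carries a pathogenic
#' BRCA1/2 mutation with loss of the wild-type allele, or complete BRCA1
#' promoter methylation.
#'
#' @param brca_mutated_with_loh logical.
#' @param methylation_percent methylation percentage in [0, 100] (may be
#'   `NA`).
#' @param ... banding parameters passed to [classify_methylation()].
#' @return List with `methylation_class` and `combined_biomarker`.
#' @export
brca_status <- function(brca_mutated_with_loh, methylation_percent = NA,
                        ...) {
  mclass <- if (is.na(methylation_percent)) NA_character_
            else classify_methylation(methylation_percent, ...)
  list(methylation_class = mclass,
       combined_biomarker = isTRUE(as.logical(brca_mutated_with_loh)) ||
         identical(mclass, "complete"))
}
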