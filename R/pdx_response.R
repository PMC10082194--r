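#' Tumour volume from caliper diameters
#'
#' Computes the ellipsoid-approximation tumour volume `V = a * b^2 / 2` from
#' two perpendicular caliper diameters, `a` the largest and `b` the smallest.
#'
#' @param a largest diameter (mm).
#' @param b smallest diameter (mm); must satisfy `a >= b > 0`.
#' @return Volume in mm^3 (vectorized).
#' @examples
#' tumour_volume(10, 6)  # 180
#' @export
tumour_volume <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(b <= 0))
    hrd_stop("diameters must be finite and positive")
  if (any(b > a))
    hrd_stop("b > a: diameters appear swapped (a must be the largest)")
  a * b^2 / 2
}

#' Per-mouse volume, percent-change and relative-volume series
#'
#' Builds an ordered per-mouse series of tumour volume, percent volume change
#' `dvol = 100 * (V_t - V0) / V0` and relative tumour volume `rtv = V_t / V0`,
#' where `V0` is the volume at day 0 (treatment start).
#'
#' @param measurements data frame for one mouse with columns `day` and either
#'   `volume` (mm^3) or the diameters `a`, `b` (mm).
#' @param mouse mouse identifier (taken from a `mouse` column if present).
#' @return A `volume_series`: data frame `day`, `volume`, `dvol`, `rtv`
#'   ordered by day, with attribute `mouse`.
#' @export
delta_vol_series <- function(measurements, mouse = NULL) {
  m <- measurements
  if (is.null(mouse)) mouse <- if (!is.null(m$mouse)) m$mouse[1] else NA_character_
  if (is.null(m$volume)) {
    if (is.null(m$a) || is.null(m$b))
      hrd_stop("need a volume column or diameter columns a and b")
    m$volume <- tumour_volume(m$a, m$b)
  }
  if (anyDuplicated(m$day)) hrd_stop("duplicate measurement day for mouse ", mouse)
  m <- m[order(m$day), , drop = FALSE]
  if (!any(m$day == 0)) hrd_stop("missing day-0 measurement for mouse ", mouse)
  if (any(m$day < 0)) hrd_stop("negative day for mouse ", mouse)
  v0 <- m$volume[m$day == 0]
  if (v0 <= 0) hrd_stop("day-0 volume must be > 0")
  out <- data.frame(day = m$day, volume = m$volume,
                    dvol = 100 * (m$volume - v0) / v0,
                    rtv = m$volume / v0)
  attr(out, "mouse") <- mouse
  class(out) <- c("volume_series", "data.frame")
  out
}

min_eval_day <- 14

#' Best response of a volume series
#'
#' The minimum percent volume change over all measured timepoints at least 14
#' days after treatment start.
#'
#' @param series a [delta_vol_series()] result.
#' @return Best response in percent, or `NA` with a `not_evaluable` warning
#'   when no measurement at day >= 14 exists.
#' @export
best_response <- function(series) {
  late <- series$dvol[series$day >= min_eval_day]
  if (!length(late)) {
    warning("mouse not evaluable: no measurement at day >= 14",
            call. = FALSE)
    return(NA_real_)
  }
  min(late)
}

#' Best average response of a volume series
#'
#' For each measured timepoint `t >= 14`, the unweighted mean of the percent
#' volume changes over all measured days from 0 to `t` inclusive (the day-0
#' value, 0 by definition, is included unless `include_t0 = FALSE`); the best
#' average response is the minimum of these running means.
#'
#' @inheritParams best_response
#' @param include_t0 include the day-0 value in each running mean
#'   (default `TRUE`).
#' @return Best average response in percent, or `NA` when not evaluable.
#' @export
best_avg_response <- function(series, include_t0 = TRUE) {
  days <- series$day
  if (!any(days >= min_eval_day)) {
    warning("mouse not evaluable: no measurement at day >= 14",
            call. = FALSE)
    return(NA_real_)
  }
  use <- if (include_t0) rep(TRUE, length(days)) else days > 0
  cands <- vapply(days[days >= min_eval_day], function(t) {
    mean(series$dvol[use & days <= t])
  }, numeric(1))
  min(cands)
}

response_levels <- c("CR", "PR", "SD", "PD")

#' Classify a response category from the two best-response metrics
#'
#' Ordered rules, first match wins, all inequalities strict:
#' complete response (CR) when BestResponse < -95 and BestAvgResponse < -40;
#' partial response (PR) when BestResponse < -50 and BestAvgResponse < -20;
#' stable disease (SD) when BestResponse < 35 and BestAvgResponse < 30;
#' otherwise progressive disease (PD).
#'
#' @param best best response (percent).
#' @param best_avg best average response (percent).
#' @return One of `"CR"`, `"PR"`, `"SD"`, `"PD"`.
#' @export
classify_response <- function(best, best_avg) {
  if (!is_scalar_number(best) || !is_scalar_number(best_avg))
    hrd_stop("both response metrics must be defined")
  if (best < -95 && best_avg < -40) "CR"
  else if (best < -50 && best_avg < -20) "PR"
  else if (best < 35 && best_avg < 30) "SD"
  else "PD"
}

#' Per-mouse response metrics
#'
#' @param measurements data frame for one mouse (see [delta_vol_series()]).
#' @param include_t0 passed to [best_avg_response()].
#' @return One-row data frame: `mouse`, `best_response`, `best_avg_response`,
#'   `evaluable`.
#' @export
mouse_response <- function(measurements, include_t0 = TRUE) {
  series <- delta_vol_series(measurements)
  evaluable <- any(series$day >= min_eval_day)
  br <- if (evaluable) best_response(series) else NA_real_
  bar <- if (evaluable) best_avg_response(series, include_t0) else NA_real_
  data.frame(mouse = attr(series, "mouse"), best_response = br,
             best_avg_response = bar, evaluable = evaluable,
             stringsAsFactors = FALSE)
}

#' Aggregate mouse responses into a PDX model response
#'
#' Takes the medians of best response and best average response across
#' evaluable mice (mean-of-middle-two convention for even counts, i.e. the
#' default sample median) and classifies the model from the medians.
#'
#' @param responses data frame with columns `mouse`, `best_response`,
#'   `best_avg_response`, `evaluable` (one row per mouse of one PDX model).
#' @param pdx PDX model identifier.
#' @return A `model_response`: list with `pdx`, `median_best`,
#'   `median_best_avg`, `category`, `n_mice`, `n_evaluable`.
#' @export
aggregate_model <- function(responses, pdx = NA_character_) {
  ev <- responses[responses$evaluable, , drop = FALSE]
  if (!nrow(ev)) hrd_stop("no evaluable mice for PDX ", pdx)
  mb <- stats::median(ev$best_response)
  mba <- stats::median(ev$best_avg_response)
  structure(list(pdx = pdx, median_best = mb, median_best_avg = mba,
                 category = classify_response(mb, mba),
                 n_mice = nrow(responses), n_evaluable = nrow(ev)),
            class = "model_response")
}

#' @export
print.model_response <- function(x, ...) {
  cat("<model_response> ", x$pdx, ": ", x$category,
      " (median best ", round(x$median_best, 1), "%, median best-avg ",
      round(x$median_best_avg, 1), "%, ", x$n_evaluable, "/", x$n_mice,
      " evaluable mice)\n", sep = "")
  invisible(x)
}

#' Classify every PDX model in a measurement table
#'
#' @param measurements data frame with columns `pdx`, `mouse`, `day` and
#'   either `volume` or `a`, `b`.
#' @param include_t0 passed to [best_avg_response()].
#' @return Data frame, one row per PDX: `pdx`, `median_best`,
#'   `median_best_avg`, `category`, `n_mice`, `n_evaluable`.
#' @export
classify_cohort_response <- function(measurements, include_t0 = TRUE) {
  out <- lapply(split(measurements, measurements$pdx), function(md) {
    per_mouse <- do.call(rbind, lapply(split(md, md$mouse), mouse_response,
                                       include_t0 = include_t0))
    r <- aggregate_model(per_mouse, pdx = md$pdx[1])
    data.frame(pdx = r$pdx, median_best = r$median_best,
               median_best_avg = r$median_best_avg, category = r$category,
               n_mice = r$n_mice, n_evaluable = r$n_evaluable,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
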