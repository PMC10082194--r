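# Synthetic-cohort generator.
#
# Generates every input the pipeline consumes — binned copy-ratio profiles
# with planted arm breaks, allele-specific profiles with planted scar events,
# tumour-growth trajectories with treatment effects, RAD51 foci tables,
# variant tables with known pass/fail status, expression matrices with
# planted deletions — together with a recorded truth table, so every pipeline
# stage can be scored against known ground truth.  All randomness flows from
# one root seed through named substreams.

#' Cohort simulation specification
#'
#' Bundles the study-design parameters of a simulated PDX cohort.  The
#' defaults describe a 55-model triple-negative breast cancer cohort with an
#' HRD prevalence of 30/55 and response-probability tables calibrated so the
#' expected marginals are about 10 CR / 5 PR / 14 SD / 26 PD with 21/29
#' responders among HRD models; LGA totals are drawn above/below the 20/18
#' classification window (HRD: 21 plus Poisson(9); HRP: Poisson(8) capped at
#' 17).
#'
#' @param n_models number of PDX models (default 55).
#' @param hrd_prevalence fraction of HRD models (default 30/55).
#' @param response_probs 2x4 matrix of response-category probabilities, rows
#'   `HRD`/`HRP`, columns `CR`/`PR`/`SD`/`PD`; each row sums to 1.
#' @param lga_hrd_min,lga_hrd_mean,lga_hrp_mean,lga_hrp_max LGA count
#'   distribution parameters per state.
#' @param scar_means_hrd,scar_means_hrp expected planted (loh, tai, lst)
#'   counts per state.
#' @param bin_width bin width of simulated profiles in bp (default 50000).
#' @param bin_noise_sd Gaussian bin noise (copy-ratio units, default 0.05 —
#'   10% of the planted 0.5 level step).
#' @param level_step planted copy-ratio step across breaks (default 0.5).
#' @param genome genome build name for simulated profiles (default
#'   `"toy3"`).
#' @param schedule measurement days (default twice weekly for 42 days).
#' @param mice_per_arm treated/control mice per model (default 8).
#' @param growth_noise_sd multiplicative (log-scale) measurement noise
#'   (default 0.10).
#' @param ethical_volume sacrifice threshold in mm^3 (default 2000).
#' @param foci_mean_deficient,foci_mean_proficient Poisson means of per-cell
#'   RAD51 foci counts after treatment (defaults 1 and 9).
#' @param cells_per_sample scored marker-positive cells per sample
#'   (default 200).
#' @param seed root seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_models = 55, hrd_prevalence = 30 / 55,
                        response_probs = default_response_probs(),
                        lga_hrd_min = 21, lga_hrd_mean = 30,
                        lga_hrp_mean = 8, lga_hrp_max = 17,
                        scar_means_hrd = c(loh = 4, tai = 2, lst = 6),
                        scar_means_hrp = c(loh = 0.8, tai = 0.4, lst = 1.3),
                        bin_width = 50000, bin_noise_sd = 0.05,
                        level_step = 0.5, genome = "toy3",
                        schedule = c(0, 4, 7, 11, 14, 18, 21, 25, 28, 32, 35,
                                     39, 42),
                        mice_per_arm = 8, growth_noise_sd = 0.10,
                        ethical_volume = 2000,
                        foci_mean_deficient = 1, foci_mean_proficient = 9,
                        cells_per_sample = 200, seed = 1L) {
  if (hrd_prevalence < 0 || hrd_prevalence > 1)
    hrd_stop("hrd_prevalence must be in [0, 1]")
  rp <- as.matrix(response_probs)
  if (!all(dim(rp) == c(2, 4)) || any(abs(rowSums(rp) - 1) > 1e-8))
    hrd_stop("response_probs must be 2x4 with rows summing to 1")
  dimnames(rp) <- list(c("HRD", "HRP"), response_levels)
  structure(list(
    n_models = n_models, hrd_prevalence = hrd_prevalence,
    response_probs = rp, lga_hrd_min = lga_hrd_min,
    lga_hrd_mean = lga_hrd_mean, lga_hrp_mean = lga_hrp_mean,
    lga_hrp_max = lga_hrp_max, scar_means_hrd = scar_means_hrd,
    scar_means_hrp = scar_means_hrp, bin_width = bin_width,
    bin_noise_sd = bin_noise_sd, level_step = level_step, genome = genome,
    schedule = schedule, mice_per_arm = mice_per_arm,
    growth_noise_sd = growth_noise_sd, ethical_volume = ethical_volume,
    foci_mean_deficient = foci_mean_deficient,
    foci_mean_proficient = foci_mean_proficient,
    cells_per_sample = cells_per_sample, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_response_probs <- function() {
  matrix(c(0.30, 0.17, 0.23, 0.30,
           0.04, 0.00, 0.28, 0.68),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("HRD", "HRP"), c("CR", "PR", "SD", "PD")))
}

#' Draw HRD states and response categories only
#'
#' Fast label-level draw used for cohort-level statistical studies (power and
#' size of the biomarker-response association) where full profiles are not
#' needed.
#'
#' @param spec a [cohort_spec()].
#' @param seed overriding seed (default the spec's).
#' @return Data frame with `pdx`, `hrd_state`, `category`.
#' @export
simulate_cohort_labels <- function(spec, seed = spec$seed) {
  with_seed(derive_seed(seed, "labels"), {
    state <- ifelse(stats::runif(spec$n_models) < spec$hrd_prevalence,
                    "HRD", "HRP")
    category <- vapply(state, function(s) {
      sample(response_levels, 1, prob = spec$response_probs[s, ])
    }, character(1))
    data.frame(pdx = sprintf("PDX-%03d", seq_len(spec$n_models)),
               hrd_state = state, category = category,
               stringsAsFactors = FALSE)
  })
}

# Distribute k events over arms with given per-arm capacities (greedy,
# randomized order).  Returns integer vector parallel to capacities.
distribute_events <- function(k, capacities) {
  alloc <- integer(length(capacities))
  if (sum(capacities) < k)
    hrd_stop("requested ", k, " events but arm capacity is only ",
             sum(capacities))
  order_arms <- sample(seq_along(capacities))
  i <- 1L
  while (k > 0) {
    a <- order_arms[i]
    if (alloc[a] < capacities[a]) {
      alloc[a] <- alloc[a] + 1L
      k <- k - 1L
    }
    i <- if (i == length(order_arms)) 1L else i + 1L
  }
  alloc
}

#' Simulate a binned copy-ratio profile with planted arm breaks
#'
#' Plants the requested number of qualifying LGA breaks per arm: each arm is
#' tiled with alternating-level segments longer than 10 Mb, adjacent (gap
#' under 3 Mb, here contiguous) and separated by `level_step` in copy ratio,
#' so every junction is a qualifying break.  Gaussian bin noise is added on
#' top.  Bins overlapping the centromere are marked unusable.
#'
#' @param breaks_per_arm named integer vector (names = arm ids from the
#'   genome's arm table, e.g. `"1p"`); arms absent get a single flat
#'   segment.  Alternatively a single total, distributed over arms at
#'   random.
#' @param genome a genome build or name.
#' @param bin_width,noise_sd,level_step,seed see [cohort_spec()].
#' @param sample sample id.
#' @param min_segment minimum retained-segment size the planted geometry
#'   must respect (default 10 Mb).
#' @return List with `profile` (a `binned_profile`) and `truth_lga`
#'   (integer).
#' @export
simulate_binned_profile <- function(breaks_per_arm, genome = "toy3",
                                    bin_width = 50000, noise_sd = 0.05,
                                    level_step = 0.5, seed = 1L,
                                    sample = "sim", min_segment = 10e6) {
  if (is.character(genome)) genome <- load_genome(genome)
  arms <- arm_table(genome)
  seg_bins <- ceiling(min_segment / bin_width) + 1L  # length > min_segment
  capacity <- pmax(0L, (arms$end - arms$start) %/% bin_width %/% seg_bins - 1L)
  with_seed(derive_seed(seed, paste0("bins_", sample)), {
    if (length(breaks_per_arm) == 1L && is.null(names(breaks_per_arm))) {
      alloc <- distribute_events(breaks_per_arm, capacity)
      breaks_per_arm <- stats::setNames(alloc, arms$arm)
    }
    bad <- setdiff(names(breaks_per_arm), arms$arm)
    if (length(bad)) hrd_stop("unknown arm in planted breaks: ", bad[1])
    over <- breaks_per_arm > capacity[match(names(breaks_per_arm), arms$arm)]
    if (any(over))
      hrd_stop("planted geometry violates the genome: arm ",
               names(breaks_per_arm)[over][1], " cannot host ",
               breaks_per_arm[over][1], " qualifying breaks")
    bins_out <- list()
    for (gi in seq_len(nrow(genome))) {
      chrom <- genome$chrom[gi]
      starts <- seq(0, genome$length[gi] - bin_width, by = bin_width)
      ends <- starts + bin_width
      ratio <- rep(1.0, length(starts))
      usable <- !(starts < genome$cen_end[gi] & ends > genome$cen_start[gi])
      for (arm in arms$arm[arms$chrom == chrom]) {
        k <- if (arm %in% names(breaks_per_arm)) breaks_per_arm[[arm]] else 0L
        ai <- which(arms$arm == arm)
        in_arm <- which(starts >= arms$start[ai] & ends <= arms$end[ai])
        if (!length(in_arm)) next
        if (k > 0) {
          n_seg <- k + 1L
          n_avail <- length(in_arm)
          # random segment lengths, each >= seg_bins bins
          extra <- n_avail - n_seg * seg_bins
          cuts <- if (extra > 0) {
            add <- stats::rmultinom(1, extra, rep(1, n_seg))[, 1]
            seg_bins + add
          } else rep(seg_bins, n_seg)
          lev <- rep(c(1.0, 1.0 + level_step), length.out = n_seg)
          ratio[in_arm] <- rep(lev, times = cuts)[seq_len(n_avail)]
        }
      }
      if (noise_sd > 0)
        ratio <- pmax(ratio + stats::rnorm(length(ratio), 0, noise_sd), 0.01)
      bins_out[[gi]] <- data.frame(chrom = chrom, start = starts, end = ends,
                                   ratio = ratio, usable = usable,
                                   stringsAsFactors = FALSE)
    }
    prof <- binned_profile(sample, do.call(rbind, bins_out), bin_width)
    list(profile = prof, truth_lga = sum(breaks_per_arm))
  })
}

#' Simulate an allele-specific profile with planted scar events
#'
#' Plants the requested numbers of LOH, TAI and LST events on distinct
#' chromosome arms so each event scores exactly once and events do not
#' interfere: LOH events are interior 30 Mb minor-copy-zero segments isolated
#' by 3.5 Mb gaps; TAI events are imbalanced 40 Mb telomere-anchored runs
#' with a balanced centromeric segment; LST events are chains of adjacent
#' 12 Mb segments with alternating allele-specific states.  Optional decoy
#' events (10 Mb LOH, 300-probe TAI) exercise the size thresholds without
#' scoring.
#'
#' @param loh,tai,lst requested event counts.
#' @param genome genome build or name.
#' @param seed integer seed.
#' @param sample sample id.
#' @param decoys also plant sub-threshold decoy events.
#' @param probes_per_mb probe density (default 20, i.e. 800 probes per 40 Mb
#'   TAI run).
#' @return List with `profile` (an `allelic_profile`) and `truth`
#'   (list loh/tai/lst).
#' @export
simulate_allelic_profile <- function(loh = 0, tai = 0, lst = 0,
                                     genome = "toy3", seed = 1L,
                                     sample = "sim", decoys = FALSE,
                                     probes_per_mb = 20) {
  if (is.character(genome)) genome <- load_genome(genome)
  arms <- arm_table(genome)
  arm_len <- arms$end - arms$start
  mb <- 1e6
  np <- function(len) max(1, round(len / mb * probes_per_mb))
  seg <- function(chrom, start, end, major, minor)
    data.frame(chrom = chrom, start = start, end = end,
               total_cn = major + minor, major_cn = major, minor_cn = minor,
               n_probes = np(end - start), stringsAsFactors = FALSE)
  with_seed(derive_seed(seed, paste0("ascn_", sample)), {
    # assign arms: LOH arms host up to 2 events, LST arms up to 3 transitions
    usable <- which(arm_len >= 90 * mb)
    loh_cap_per_arm <- 2L
    lst_cap_per_arm <- 3L
    n_loh_arms <- ceiling(loh / loh_cap_per_arm)
    n_lst_arms <- ceiling(lst / lst_cap_per_arm)
    need <- n_loh_arms + tai + n_lst_arms
    if (need > length(usable))
      hrd_stop("requested events exceed arm capacity: need ", need,
               " arms of >= 90 Mb, have ", length(usable))
    chosen <- usable[sample.int(length(usable), need)]
    roles <- rep(c("loh", "tai", "lst"), c(n_loh_arms, tai, n_lst_arms))
    lst_left <- lst
    loh_left <- loh
    segs <- list()
    decoy_arms <- setdiff(usable, chosen)
    for (ai in seq_len(nrow(arms))) {
      chrom <- arms$chrom[ai]
      a0 <- arms$start[ai]; a1 <- arms$end[ai]
      is_p <- grepl("p$", arms$arm[ai])
      role <- if (ai %in% chosen) roles[match(ai, chosen)] else "none"
      # build arm content centromere-side -> telomere-side, then place
      tel_first <- is_p  # p arm: telomere at a0
      add <- function(pieces) segs[[length(segs) + 1L]] <<- pieces
      if (role == "loh") {
        # interior minor=0 segments of 20 Mb isolated by 3.5 Mb gaps;
        # short (4 Mb) balanced spacers keep events in separate runs without
        # creating >= 10 Mb neighbours that could score as LST
        k <- min(loh_cap_per_arm, loh_left)
        loh_left <- loh_left - k
        g <- 3.5 * mb
        ev <- 20 * mb; spacer <- 4 * mb
        pieces <- seg(chrom, a0, a0 + spacer, 1, 1)
        pos <- a0 + spacer + g
        for (j in seq_len(k)) {
          pieces <- rbind(pieces, seg(chrom, pos, pos + ev, 2, 0))
          pos <- pos + ev + g
          pieces <- rbind(pieces, seg(chrom, pos, pos + spacer, 1, 1))
          pos <- pos + spacer + g
        }
        pieces <- rbind(pieces, seg(chrom, pos, a1, 1, 1))
        add(pieces)
      } else if (role == "tai") {
        g <- 3.5 * mb
        run <- 40 * mb
        bal <- (a1 - a0) - run - g
        if (is_p) {
          add(rbind(seg(chrom, a0, a0 + run, 2, 1),
                    seg(chrom, a0 + run + g, a1, 1, 1)))
        } else {
          add(rbind(seg(chrom, a0, a0 + bal, 1, 1),
                    seg(chrom, a1 - run, a1, 2, 1)))
        }
      } else if (role == "lst") {
        k <- min(lst_cap_per_arm, lst_left)
        lst_left <- lst_left - k
        g <- 3.5 * mb
        sl <- 12 * mb
        states <- list(c(2, 1), c(3, 1))
        chain_len <- (k + 1) * sl
        if (is_p) {
          # balanced telomeric remainder first, chain at centromeric side
          rem0 <- a0; rem1 <- a1 - chain_len - g
          pieces <- seg(chrom, rem0, rem1, 1, 1)
          pos <- rem1 + g
          for (j in seq_len(k + 1)) {
            st <- states[[(j - 1) %% 2 + 1]]
            pieces <- rbind(pieces, seg(chrom, pos, pos + sl, st[1], st[2]))
            pos <- pos + sl
          }
          add(pieces)
        } else {
          pos <- a0
          pieces <- NULL
          for (j in seq_len(k + 1)) {
            st <- states[[(j - 1) %% 2 + 1]]
            pieces <- rbind(pieces, seg(chrom, pos, pos + sl, st[1], st[2]))
            pos <- pos + sl
          }
          pieces <- rbind(pieces, seg(chrom, pos + g, a1, 1, 1))
          add(pieces)
        }
      } else if (decoys && length(decoy_arms) && ai == decoy_arms[1]) {
        # sub-threshold decoys: 10 Mb LOH and a short telomeric imbalance
        g <- 3.5 * mb
        l1 <- 20 * mb; l2 <- 10 * mb  # LOH below the 15 Mb minimum
        p1 <- a0; p2 <- p1 + l1 + g; p3 <- p2 + l2 + g
        run <- (300 / probes_per_mb) * mb  # TAI run of only 300 probes
        rest1 <- a1 - run - g - p3
        add(rbind(seg(chrom, p1, p1 + l1, 1, 1),
                  seg(chrom, p2, p2 + l2, 2, 0),
                  seg(chrom, p3, p3 + rest1, 1, 1),
                  seg(chrom, a1 - run, a1, 2, 1)))
      } else {
        add(seg(chrom, a0, a1, 1, 1))
      }
    }
    prof <- allelic_profile(sample, do.call(rbind, segs))
    list(profile = prof, truth = list(loh = loh, tai = tai, lst = lst))
  })
}

# deterministic treated-arm volume-ratio trajectory per intended category
category_trajectory <- function(category, t) {
  switch(category,
         CR = exp(-0.3 * t),
         PR = 0.25 + 0.75 * exp(-0.25 * t),
         SD = 1 - 0.1 * (1 - exp(-0.1 * t)),
         PD = exp(0.06 * t),
         hrd_stop("unknown category: ", category))
}

#' Simulate a tumour-growth measurement table
#'
#' Control arms grow exponentially (lognormal growth-rate spread across
#' mice); treated arms follow category-specific trajectories (CR: decay
#' below 5% of the initial volume by day 14; PR: decay to about 25%; SD:
#' mild decline within the stable band; PD: continued growth), with
#' multiplicative lognormal measurement noise and removal of measurements
#' after the ethical volume limit is reached.
#'
#' @param truth data frame with columns `pdx` and `category` (e.g. from
#'   [simulate_cohort_labels()]).
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return List with `measurements` (data frame `pdx`, `mouse`, `arm`,
#'   `day`, `volume`) and `truth` (the input).
#' @export
simulate_growth_cohort <- function(truth, spec = cohort_spec(),
                                   seed = spec$seed) {
  if (!any(spec$schedule >= 14))
    hrd_stop("measurement schedule has no day >= 14")
  with_seed(derive_seed(seed, "growth"), {
    rows <- list()
    for (i in seq_len(nrow(truth))) {
      pdx <- truth$pdx[i]; category <- truth$category[i]
      for (arm in c("control", "treated")) {
        for (mi in seq_len(spec$mice_per_arm)) {
          v0 <- stats::runif(1, 60, 200)
          ratio <- if (arm == "treated") {
            category_trajectory(category, spec$schedule)
          } else {
            rate <- stats::rlnorm(1, log(0.07), 0.3)
            exp(rate * spec$schedule)
          }
          noise <- exp(stats::rnorm(length(spec$schedule), 0,
                                    spec$growth_noise_sd))
          noise[spec$schedule == 0] <- 1  # V0 is the reference measurement
          vol <- v0 * ratio * noise
          over <- which(vol >= spec$ethical_volume)
          keep <- if (length(over)) seq_len(min(over)) else
            seq_along(spec$schedule)
          rows[[length(rows) + 1L]] <- data.frame(
            pdx = pdx, mouse = paste0(pdx, "-", arm, "-m", mi), arm = arm,
            day = spec$schedule[keep], volume = vol[keep],
            stringsAsFactors = FALSE)
        }
      }
    }
    list(measurements = do.call(rbind, rows), truth = truth)
  })
}

#' Simulate a RAD51 foci table
#'
#' Per model, control and treated xenografts with per-cell foci counts drawn
#' from state-conditional Poisson mixtures: HR-deficient models keep low
#' treated foci counts (mean `foci_mean_deficient`) while proficient models
#' induce foci (mean `foci_mean_proficient`); control arms stay low in both.
#'
#' @param truth data frame with columns `pdx`, `hrd_state` (the HR
#'   functional state to emulate).
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @param samples_per_arm xenografts per arm (default 3).
#' @return Data frame `pdx`, `sample`, `arm`, `cell_id`, `marker_positive`,
#'   `foci_count`.
#' @export
simulate_foci_table <- function(truth, spec = cohort_spec(),
                                seed = spec$seed, samples_per_arm = 3) {
  with_seed(derive_seed(seed, "foci"), {
    rows <- list()
    for (i in seq_len(nrow(truth))) {
      deficient <- truth$hrd_state[i] == "HRD"
      for (arm in c("control", "treated")) {
        mu <- if (arm == "control") 0.5
              else if (deficient) spec$foci_mean_deficient
              else spec$foci_mean_proficient
        for (si in seq_len(samples_per_arm)) {
          n <- spec$cells_per_sample
          rows[[length(rows) + 1L]] <- data.frame(
            pdx = truth$pdx[i],
            sample = paste0(truth$pdx[i], "-", arm, "-s", si), arm = arm,
            cell_id = seq_len(n), marker_positive = 1L,
            foci_count = stats::rpois(n, mu), stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate a variant table with known filter verdicts
#'
#' Builds, per named exome filter rule, one variant violating exactly that
#' rule, plus `n_pass` variants passing every rule; the planted expectation
#' is recorded in the `expected_reason` column (`"pass"` for survivors).
#' The recurrence violator appears in five samples.
#'
#' @param seed integer seed.
#' @param n_pass number of all-pass variants (default 5).
#' @return Data frame ready for [filter_wes_cohort()], with truth columns
#'   `expected_reason`.
#' @export
simulate_variant_table <- function(seed = 1L, n_pass = 5) {
  with_seed(derive_seed(seed, "variants"), {
    base <- function(sample, pos) data.frame(
      sample = sample, gene = "BRCA2", chrom = "chr13", pos = pos,
      ref = "A", alt = "T", total_depth = 80L, alt_depth = 30L,
      alt_freq = 0.45, clinsig = "", exonic_class = "nonsynonymous-SNV",
      func_class = "exonic", popfreq_1000g = 0, popfreq_gnomad = 0,
      SIFT = "Damaging", Polyphen2_HDIV = "Probably damaging",
      MutationAssessor = "High", MetaSVM = "Damaging", FATHMM = "Damaging",
      expected_reason = "pass", stringsAsFactors = FALSE)
    rows <- list()
    pos <- 32900000
    for (k in seq_len(n_pass)) {
      pos <- pos + 10
      r <- base(sprintf("S%02d", k), pos)
      # two benign-leaning votes are allowed
      r$SIFT <- "Tolerated"; r$Polyphen2_HDIV <- "Benign"
      rows[[length(rows) + 1L]] <- r
    }
    plant <- function(mut, reason) {
      pos <<- pos + 10
      r <- base("S01", pos)
      r <- mut(r)
      r$expected_reason <- reason
      rows[[length(rows) + 1L]] <<- r
    }
    plant(function(r) { r$alt_depth <- 1L; r }, "min_alt_depth")
    plant(function(r) { r$alt_freq <- 0.10; r }, "min_alt_freq")
    plant(function(r) { r$clinsig <- "Likely_benign"; r }, "benign_clinsig")
    plant(function(r) { r$exonic_class <- "synonymous-SNV"; r }, "synonymous")
    plant(function(r) { r$func_class <- "intronic"; r }, "func_class")
    plant(function(r) { r$popfreq_gnomad <- 0.01; r }, "pop_freq")
    plant(function(r) {
      r$SIFT <- "Tolerated"; r$Polyphen2_HDIV <- "Benign"
      r$MutationAssessor <- "Neutral"; r
    }, "predictor_vote")
    # recurrence: same key in 5 distinct tumours
    pos <- pos + 10
    for (k in 1:5) {
      r <- base(sprintf("S%02d", k), pos)
      r$expected_reason <- "recurrence"
      rows[[length(rows) + 1L]] <- r
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate an expression matrix with one planted deletion and its fusion
#'
#' Generates a genes-by-samples negative-binomial count matrix with
#' per-sample depth factors, scales the counts of a block of consecutive
#' same-chromosome genes by `depletion` in one designated sample, and emits
#' the matching intra-chromosomal fusion call spanning that block.
#'
#' @param n_samples number of samples (default 30).
#' @param n_genes number of genes (default 60, laid across the toy genome).
#' @param deleted_sample index of the sample carrying the deletion
#'   (default 1).
#' @param region_genes indices of the deleted gene block (default 10:14).
#' @param depletion multiplicative depletion of the deleted block
#'   (default 0.01).
#' @param seed integer seed.
#' @return List with `counts` (matrix), `genes` (coordinate data frame),
#'   `fusions` (one-row data frame), `ddr_list` (symbols making the
#'   candidate DDR-relevant) and `truth` (deleted sample id and gene names).
#' @export
simulate_expression_with_deletion <- function(n_samples = 30, n_genes = 60,
                                              deleted_sample = 1,
                                              region_genes = 10:14,
                                              depletion = 0.01, seed = 1L) {
  with_seed(derive_seed(seed, "expression"), {
    genome <- load_genome("toy3")
    gene_names <- sprintf("GENE%03d", seq_len(n_genes))
    per_chrom <- ceiling(n_genes / nrow(genome))
    coords <- list()
    gi <- 1L
    for (ci in seq_len(nrow(genome))) {
      for (k in seq_len(per_chrom)) {
        if (gi > n_genes) break
        start <- (k - 1) * 3e6 + 1e6
        coords[[gi]] <- data.frame(
          gene = gene_names[gi], chrom = genome$chrom[ci],
          start = start, end = start + 1e5, stringsAsFactors = FALSE)
        gi <- gi + 1L
      }
    }
    genes <- do.call(rbind, coords)
    samples <- sprintf("S%02d", seq_len(n_samples))
    depth <- stats::rlnorm(n_samples, 0, 0.3)
    mu <- stats::rlnorm(n_genes, log(100), 0.5)
    counts <- matrix(stats::rnbinom(n_genes * n_samples,
                                    mu = outer(mu, depth), size = 10),
                     nrow = n_genes, dimnames = list(gene_names, samples))
    counts <- counts + 1  # keep every gene expressed in every sample
    stopifnot(all(genes$chrom[region_genes] == genes$chrom[region_genes[1]]))
    counts[region_genes, deleted_sample] <-
      pmax(0, round(counts[region_genes, deleted_sample] * depletion))
    lo <- min(region_genes); hi <- max(region_genes)
    fusions <- data.frame(
      sample = samples[deleted_sample],
      geneA = gene_names[lo - 1], chromA = genes$chrom[lo],
      posA = genes$start[lo] - 5e4,
      geneB = gene_names[hi + 1], chromB = genes$chrom[hi],
      posB = genes$end[hi] + 5e4, junction_reads = 12L,
      stringsAsFactors = FALSE)
    list(counts = counts, genes = genes, fusions = fusions,
         ddr_list = gene_names[region_genes],
         truth = list(sample = samples[deleted_sample],
                      genes = gene_names[region_genes]))
  })
}

#' Simulate a full linked cohort
#'
#' Draws model-level truth (HRD state, planted LGA total, planted scar
#' counts, response category), then generates every per-model input: binned
#' profiles, allele-specific profiles, growth measurements and foci tables,
#' plus a cohort annotation table.  BRCA biomarker flags are planted only in
#' HRD models (mutation-with-LOH or complete methylation), with
#' partial-methylation decoys among resistant models.
#'
#' @param spec a [cohort_spec()].
#' @param profiles also generate per-model binned and allelic profiles
#'   (slower; default `TRUE`).
#' @param seed overriding root seed (default the spec's).
#' @return List with `truth` (truth table), `annotations`, `measurements`,
#'   `foci`, and when `profiles = TRUE` lists `binned` and `allelic` keyed
#'   by PDX id.
#' @export
simulate_cohort <- function(spec = cohort_spec(), profiles = TRUE,
                            seed = spec$seed) {
  labels <- simulate_cohort_labels(spec, seed)
  truth <- with_seed(derive_seed(seed, "states"), {
    n <- nrow(labels)
    hrd <- labels$hrd_state == "HRD"
    lga <- ifelse(hrd,
                  spec$lga_hrd_min +
                    stats::rpois(n, spec$lga_hrd_mean - spec$lga_hrd_min),
                  pmin(spec$lga_hrp_max, stats::rpois(n, spec$lga_hrp_mean)))
    # scar rates share the latent HRD severity that drives the LGA count:
    # per-model means are the state means scaled by the model's LGA total
    # relative to the state's expected total
    scale_fac <- ifelse(hrd, lga / spec$lga_hrd_mean,
                        (lga + 1) / (spec$lga_hrp_mean + 1))
    sc <- sapply(c("loh", "tai", "lst"), function(comp) {
      mu <- ifelse(hrd, spec$scar_means_hrd[comp],
                   spec$scar_means_hrp[comp]) * scale_fac
      stats::rpois(n, mu)
    })
    if (is.null(dim(sc))) sc <- matrix(sc, nrow = n)
    colnames(sc) <- c("loh", "tai", "lst")
    # cap to the generator's per-genome arm capacity (LOH arms host 2
    # events, TAI arms 1, LST arms up to 3)
    n_arms <- 2L * nrow(load_genome(spec$genome))
    repeat {
      used <- ceiling(sc[, "loh"] / 2) + sc[, "tai"] +
        ceiling(sc[, "lst"] / 3)
      over <- used > n_arms
      if (!any(over)) break
      sc[over, ] <- pmax(sc[over, , drop = FALSE] - 1L, 0L)
    }
    brca_mut <- hrd & stats::runif(n) < 0.45
    meth <- ifelse(hrd & !brca_mut & stats::runif(n) < 0.7,
                   stats::runif(n, 90, 100), stats::runif(n, 0, 8))
    # partial-methylation decoys among resistant HRD models
    partial <- hrd & !brca_mut & meth < 10 & labels$category %in%
      c("SD", "PD") & stats::runif(n) < 0.3
    meth[partial] <- stats::runif(sum(partial), 40, 60)
    data.frame(labels, lga_true = lga, loh_true = sc[, "loh"],
               tai_true = sc[, "tai"], lst_true = sc[, "lst"],
               brca_mutated_loh = brca_mut,
               methylation_percent = round(meth, 1),
               stringsAsFactors = FALSE)
  })
  growth <- simulate_growth_cohort(truth, spec, seed)
  foci <- simulate_foci_table(truth, spec, seed)
  out <- list(truth = truth, measurements = growth$measurements, foci = foci)
  if (profiles) {
    genome <- load_genome(spec$genome)
    out$binned <- lapply(seq_len(nrow(truth)), function(i) {
      simulate_binned_profile(truth$lga_true[i], genome = genome,
                              bin_width = spec$bin_width,
                              noise_sd = spec$bin_noise_sd,
                              level_step = spec$level_step,
                              seed = derive_seed(seed, truth$pdx[i]),
                              sample = truth$pdx[i])
    })
    names(out$binned) <- truth$pdx
    out$allelic <- lapply(seq_len(nrow(truth)), function(i) {
      simulate_allelic_profile(truth$loh_true[i], truth$tai_true[i],
                               truth$lst_true[i], genome = genome,
                               seed = derive_seed(seed, truth$pdx[i]),
                               sample = truth$pdx[i])
    })
    names(out$allelic) <- truth$pdx
  }
  meth_class <- vapply(truth$methylation_percent, function(p)
    suppressWarnings(classify_methylation(p)), character(1))
  out$annotations <- data.frame(
    pdx = truth$pdx, category = truth$category,
    hrd_class = truth$hrd_state,
    brca_mutated_loh = truth$brca_mutated_loh,
    methylation_percent = truth$methylation_percent,
    methylation_class = meth_class,
    combined_biomarker = truth$brca_mutated_loh | meth_class == "complete",
    stringsAsFactors = FALSE)
  out
}
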