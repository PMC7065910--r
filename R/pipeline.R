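# End-to-end analysis: kymograph -> segmentation -> linked events -> spots
# -> classification, rates, per-event bp totals and QC -> condition summary.

#' Analyse one trace (simulated or loaded from a bundle)
#'
#' Runs dark-region segmentation, event linking, spot detection (when an
#' eGFP channel is present), classification and rate estimation, and
#' converts both signals to base pairs: `bp_dark` from the maximal
#' dark-region span and `bp_dL` from the tether-length change across the
#' event (only for events that do not overlap another event in time;
#' baseline and endpoint are medians of the five scan lines flanking the
#' event). Disagreement of the two estimators beyond `qc_tol` is flagged in
#' `qc_estimator_disagree`, not an error.
#'
#' @param trace an `sm_trace` or the list returned by
#'   [read_trace_bundle()]; must carry `kymo`, `series` and `schedule`.
#' @param threshold,threshold_frac see [segment_dark_regions()].
#' @param bead_margin_px bead margin for segmentation and spot detection.
#' @param motion_threshold_px classification motion threshold, in pixels.
#' @param r2_min,min_frac linear-region selection, see [estimate_rates()].
#' @param min_lines,min_width_px,max_gap_lines,max_jump_px see
#'   [link_events()].
#' @param min_snr spot detection threshold, see [detect_spots()].
#' @param merge_guard_px single-line dark-width jump (pixels) above which an
#'   event track is truncated: fork motion cannot widen a region that fast
#'   within one scan line, so such a jump marks two dark regions merging
#'   (e.g. after a collision), and only the pre-merge track is analysed.
#' @param use_spots use the eGFP channel for classification when present.
#' @param qc_tol relative dark-vs-length disagreement that raises the QC
#'   flag.
#' @param ss,ds elasticity parameter objects.
#' @return an object of class `trace_analysis`: `events` (one row per
#'   event), `edges`, `spots`, `segments`, `required_force`, `series`.
#'   `tidy()` returns the event table, `glance()` a one-row overview.
#' @export
analyze_trace <- function(trace, threshold = NULL, threshold_frac = 0.5,
                          bead_margin_px = 5L, motion_threshold_px = 3,
                          r2_min = 0.9, min_frac = 0.5, min_lines = 5L,
                          min_width_px = 3L, max_gap_lines = 2L,
                          max_jump_px = 5L, min_snr = 3, merge_guard_px = 3,
                          use_spots = TRUE, qc_tol = 0.1,
                          ss = ssdna_params(), ds = dsdna_params()) {
  kymo <- trace$kymo
  if (nrow(kymo$channels[[1]]) == 0) abort("kymograph has zero scan lines")
  px <- kymo$pixel_size_um
  segments <- segment_dark_regions(kymo, threshold = threshold,
                                   threshold_frac = threshold_frac,
                                   bead_margin_px = bead_margin_px)
  edges <- link_events(segments, max_gap_lines = max_gap_lines,
                       max_jump_px = max_jump_px, min_lines = min_lines,
                       min_width_px = min_width_px, pixel_size_um = px)
  if (nrow(edges)) {
    guard_um <- merge_guard_px * px
    # two dark regions approaching within the guard are about to merge into
    # one (a collision, or blur bridging the gap); each event is analysed
    # only up to that point, and a single-line width jump beyond the guard
    # (an already-merged region adopted by the linker) also ends the track
    # gaps are measured against *all* segmented intervals (not only linked
    # events): a neighbouring region too short to pass the event filters
    # still merges physically
    prox <- edges |>
      dplyr::left_join(
        segments |>
          dplyr::group_by(.data$line) |>
          dplyr::arrange(.data$start_um, .by_group = TRUE) |>
          dplyr::mutate(gap_prev = .data$start_um - dplyr::lag(.data$end_um),
                        gap_next = dplyr::lead(.data$start_um) - .data$end_um) |>
          dplyr::ungroup() |>
          dplyr::select("line", "start_um", "gap_prev", "gap_next"),
        by = c("line", "left_um" = "start_um")) |>
      dplyr::filter((!is.na(.data$gap_prev) & .data$gap_prev < guard_um) |
                      (!is.na(.data$gap_next) & .data$gap_next < guard_um))
    prox <- if (nrow(prox)) {
      prox |>
        dplyr::group_by(.data$event_id) |>
        dplyr::summarise(cut_line = min(.data$line), .groups = "drop")
    } else {
      tibble(event_id = integer(), cut_line = integer())
    }
    edges <- edges |>
      dplyr::left_join(prox, by = "event_id") |>
      dplyr::filter(is.na(.data$cut_line) | .data$line < .data$cut_line) |>
      dplyr::select(-"cut_line") |>
      dplyr::group_by(.data$event_id) |>
      dplyr::arrange(.data$line, .by_group = TRUE) |>
      dplyr::group_modify(function(d, key) {
        j <- which(diff(d$width_um) > guard_um)
        if (length(j)) d[seq_len(j[1]), ] else d
      }) |>
      dplyr::ungroup() |>
      dplyr::group_by(.data$event_id) |>
      dplyr::filter(dplyr::n() >= min_lines) |>
      # a genuine event nucleates from zero width; a track that first
      # appears mid-trace already wide is the continuation of a merged
      # region and would double-count an event
      dplyr::filter(dplyr::first(.data$line, order_by = .data$line) <= 5 |
                      .data$width_um[which.min(.data$line)] <= 6 * px) |>
      dplyr::ungroup()
  }
  spots <- if (use_spots) {
    detect_spots(kymo, events = edges, min_snr = min_snr,
                 bead_margin_px = bead_margin_px,
                 max_gap_lines = max_gap_lines, max_jump_px = max_jump_px,
                 min_lines = min_lines)
  } else {
    detect_spots(kymograph(kymo$channels["sytox"], px, kymo$line_time_s))
  }
  req <- required_force(edges, trace$schedule)
  if (nrow(edges) == 0) {
    events <- tibble(event_id = integer(), class = character(),
                     rate_total_bps = numeric(), rate_left_bps = numeric(),
                     rate_right_bps = numeric(), r2 = numeric(),
                     n_spots = integer(), force_pN = numeric(),
                     bp_dark = numeric(), bp_dL = numeric(),
                     ratable = logical(), qc_estimator_disagree = logical())
    return(structure(list(events = events, edges = edges, spots = spots,
                          segments = segments, required_force = req,
                          series = trace$series),
                     class = "trace_analysis"))
  }
  spans <- edges |>
    dplyr::group_by(.data$event_id) |>
    dplyr::summarise(t_first = min(.data$time_s), t_last = max(.data$time_s),
                     line_first = min(.data$line), line_last = max(.data$line),
                     .groups = "drop") |>
    dplyr::mutate(force_pN = schedule_force_at(
      trace$schedule, (.data$t_first + .data$t_last) / 2))

  per_force <- lapply(split(spans$event_id, spans$force_pN), function(ids) {
    f <- spans$force_pN[match(ids[1], spans$event_id)]
    ed <- edges[edges$event_id %in% ids, ]
    cl <- classify_events(ed, spots = spots, force = f,
                          motion_threshold_um = motion_threshold_px * px,
                          ss = ss, ds = ds)
    rt <- estimate_rates(ed, force = f, r2_min = r2_min, min_frac = min_frac,
                         ss = ss, ds = ds)
    dplyr::left_join(cl, rt, by = "event_id")
  })
  events <- dplyr::bind_rows(per_force) |>
    dplyr::left_join(spans, by = "event_id") |>
    dplyr::arrange(.data$event_id)

  # length-change estimator, only for events not overlapping others in time.
  # The baseline is taken just before the *extrapolated* event start (the
  # width-vs-time trend crossed back to zero width), not first detection:
  # a dark region only becomes resolvable about a pixel wide, and the
  # unwinding before that would otherwise be missed.
  len <- trace$series$length_um
  lt <- kymo$line_time_s
  n_series <- length(len)
  events$bp_dL <- NA_real_
  for (i in seq_len(nrow(events))) {
    others <- spans[spans$event_id != events$event_id[i], ]
    overlap <- any(others$t_first <= events$t_last[i] &
                     others$t_last >= events$t_first[i])
    if (overlap) next
    l0 <- events$line_first[i]; l1 <- min(events$line_last[i], n_series)
    t0 <- events$t_first[i]
    if (!is.na(events$onset_s[i])) {
      t0 <- min(max(events$onset_s[i], 0), events$t_first[i])
    }
    l0_base <- max(1L, min(l0 - 1L, floor(t0 / lt)))
    base_idx <- max(1, l0_base - 4):l0_base
    end_idx <- max(l0, l1 - 4):l1
    dL <- stats::median(len[end_idx]) - stats::median(len[base_idx])
    events$bp_dL[i] <- tryCatch(
      bp_from_length_change(dL, events$force_pN[i], ss, ds),
      error = function(e) {
        warn(paste0("event ", events$event_id[i], ": ", conditionMessage(e)))
        NA_real_
      })
  }
  events <- events |>
    dplyr::mutate(qc_estimator_disagree = !is.na(.data$bp_dL) &
                    abs(.data$bp_dL - .data$bp_dark) >
                      qc_tol * pmax(.data$bp_dark, 1)) |>
    dplyr::select("event_id", "class", "rate_total_bps", "rate_left_bps",
                  "rate_right_bps", "r2", "n_spots", "force_pN", "bp_dark",
                  "bp_dL", "ratable", "qc_estimator_disagree")
  structure(list(events = events, edges = edges, spots = spots,
                 segments = segments, required_force = req,
                 series = trace$series),
            class = "trace_analysis")
}

#' @export
print.trace_analysis <- function(x, ...) {
  cat("<trace_analysis>", nrow(x$events), "event(s);",
      "required force:", if (x$required_force$outcome == "N.U.") "N.U."
      else paste0(x$required_force$required_force_pN, " pN"), "\n")
  if (nrow(x$events)) print(x$events)
  invisible(x)
}

#' @method tidy trace_analysis
#' @export
tidy.trace_analysis <- function(x, ...) x$events

#' @method glance trace_analysis
#' @export
glance.trace_analysis <- function(x, ...) {
  tibble(n_events = nrow(x$events),
         n_bidirectional = sum(x$events$class == "bidirectional"),
         n_ratable = sum(x$events$ratable),
         required_force_pN = x$required_force$required_force_pN,
         outcome = x$required_force$outcome)
}

#' Simulate and analyse molecules until enough events are collected
#'
#' Repeatedly simulates molecules of `template` under `condition` (seeds
#' `seed`, `seed + 1`, ... one per molecule), analyses each trace, and stops
#' once at least `min_events` classified events have accumulated or
#' `max_molecules` is reached. The workhorse behind the benchmark suites.
#'
#' @param condition a [sim_condition()].
#' @param template a [template_spec()].
#' @param min_events events to collect (classified uni or bi).
#' @param imaging an [imaging_params()].
#' @param schedule a [force_schedule()].
#' @param seed base seed; molecule m uses `seed + m - 1`.
#' @param max_molecules hard cap on molecules simulated.
#' @param uni_direction passed to [simulate_trace()].
#' @param ... further arguments to [analyze_trace()].
#' @return a list: `events` (event table with a `molecule` column), `truth`
#'   (ground truth with `molecule`), `n_molecules`.
#' @export
run_condition <- function(condition, template = template_preset("lambda_48502"),
                          min_events = 40, imaging = imaging_params(),
                          schedule = force_schedule(30, imaging$duration_s),
                          seed = 1L, max_molecules = 200L,
                          uni_direction = "random", ...) {
  events <- list(); truths <- list(); m <- 0L; n_classified <- 0L
  while (n_classified < min_events && m < max_molecules) {
    m <- m + 1L
    tr <- simulate_trace(template, condition, imaging, schedule,
                         seed = seed + m - 1L, uni_direction = uni_direction)
    an <- analyze_trace(tr, ...)
    if (nrow(an$events)) {
      events[[m]] <- dplyr::mutate(an$events, molecule = m)
      n_classified <- n_classified +
        sum(an$events$class %in% c("unidirectional", "bidirectional") &
              an$events$ratable)
    }
    truths[[m]] <- dplyr::mutate(tr$truth, molecule = m)
  }
  list(events = dplyr::bind_rows(events), truth = dplyr::bind_rows(truths),
       n_molecules = m)
}

#' Benchmark suites reproducing the study's headline quantities
#'
#' Runs the full simulate -> track -> convert -> fit pipeline on a calibrated
#' fixture and reports recovered versus expected values with a pass/fail
#' verdict at the stated tolerance:
#'
#' * `fig1e` — helicase alone at 30 pN, >= 40 unidirectional events; mean
#'   rate vs 60 bp/s (10%).
#' * `fig4c` — helicase + RPA at 30 pN, mixed classes; unidirectional mean
#'   vs 72 bp/s, bidirectional total-expansion mean vs 117 bp/s (15% each),
#'   bidirectional/unidirectional ratio vs 1.6 (15%), bidirectional fraction
#'   vs 53%.
#' * `fig5d` — core-helicase + RPA at 35 pN; bidirectional/unidirectional
#'   ratio vs 1.7 (15%).
#' * `fig2_polarity` — single tensioned-strand fork on the nicked 6.4 kbp
#'   template run to completion at 30 pN, noiseless; unwound bp from both
#'   estimators vs 4,200 (5%).
#'
#' @param suite suite name.
#' @param seeds integer seeds; one pipeline run per seed, metrics pooled
#'   over runs.
#' @param min_events events per run for the event-set suites.
#' @return a tibble `suite, seed, metric, recovered, expected, tolerance,
#'   pass, n`.
#' @export
run_benchmark <- function(suite = c("fig1e", "fig4c", "fig5d",
                                    "fig2_polarity"),
                          seeds = 1L, min_events = 40) {
  suite <- match.arg(suite)
  if (!length(seeds)) abort("at least one seed is required")
  purrr::map_dfr(seeds, function(s) {
    switch(suite,
      fig1e = {
        rc <- run_condition(sim_condition_preset("blm_alone_30pN"),
                            min_events = min_events, seed = s * 1000L)
        ev <- rc$events[rc$events$class == "unidirectional" & rc$events$ratable, ]
        tibble(suite = suite, seed = s, metric = "mean_rate_bps",
               recovered = mean(ev$rate_total_bps), expected = 60,
               tolerance = 0.10, n = nrow(ev))
      },
      fig4c = {
        rc <- run_condition(sim_condition_preset("blm_rpa_30pN"),
                            min_events = min_events, seed = s * 1000L)
        sm <- summarize_condition(rc$events, "blm_rpa_30pN")
        tibble(suite = suite, seed = s,
               metric = c("mean_uni_bps", "mean_bi_bps", "bi_uni_ratio",
                          "fraction_bidirectional"),
               recovered = c(sm$mean_uni_bps, sm$mean_bi_bps,
                             sm$mean_bi_bps / sm$mean_uni_bps,
                             sm$fraction_bidirectional),
               expected = c(72, 117, 117 / 72, 0.53),
               tolerance = c(0.15, 0.15, 0.15, 0.16),
               n = sm$n_unidirectional + sm$n_bidirectional)
      },
      fig5d = {
        rc <- run_condition(sim_condition_preset("corebm_rpa_35pN"),
                            min_events = min_events,
                            schedule = force_schedule(35, 60), seed = s * 1000L)
        sm <- summarize_condition(rc$events, "corebm_rpa_35pN")
        tibble(suite = suite, seed = s, metric = "bi_uni_ratio",
               recovered = sm$mean_bi_bps / sm$mean_uni_bps, expected = 1.7,
               tolerance = 0.15,
               n = sm$n_unidirectional + sm$n_bidirectional)
      },
      fig2_polarity = {
        # long enough that the fork always completes its 4,200 bp segment
        # (70 s at 60 bp/s) regardless of where in the plateau it initiates
        imaging <- imaging_params(duration_s = 160, line_time_s = 0.2,
                                  noise = FALSE)
        tr <- simulate_trace(template_preset("nicked_6p4kbp"),
                             sim_condition(60, 0, initiation_force = c("30" = 1)),
                             imaging, force_schedule(30, 160), seed = s,
                             uni_direction = "right")
        an <- analyze_trace(tr)
        tibble(suite = suite, seed = s,
               metric = c("unwound_bp_dark", "unwound_bp_dL"),
               recovered = c(an$events$bp_dark[1], an$events$bp_dL[1]),
               expected = 4200, tolerance = 0.05, n = 1)
      })
  }) |>
    dplyr::mutate(pass = abs(.data$recovered - .data$expected) <=
                    .data$tolerance * .data$expected) |>
    dplyr::select("suite", "seed", "metric", "recovered", "expected",
                  "tolerance", "pass", "n")
}
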