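# Event-level inference: drift correction into the duplex frame, linear
# region selection, uni/bi classification, bp/s rates, required initiation
# force, rewinding detection and condition summaries.

# Longest contiguous window [i0, i1] with local linear fit R^2 >= r2_min and
# covering >= min_frac of the samples; O(1) per window via prefix sums.
# A window whose response sd is <= flat_tol counts as perfect (R^2 = 1): a
# static edge is a flat line up to localisation jitter, not a bad fit.
linear_region_fit <- function(t, y, r2_min = 0.9, min_frac = 0.5,
                              min_pts = 5L, flat_tol = 0) {
  n <- length(t)
  if (n < min_pts) {
    return(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                i0 = NA_integer_, i1 = NA_integer_, ok = FALSE))
  }
  ct <- cumsum(t); ct2 <- cumsum(t^2)
  cy <- cumsum(y); cy2 <- cumsum(y^2); cty <- cumsum(t * y)
  wstat <- function(i, j) {
    m <- j - i + 1
    st <- ct[j] - if (i > 1) ct[i - 1] else 0
    st2 <- ct2[j] - if (i > 1) ct2[i - 1] else 0
    sy <- cy[j] - if (i > 1) cy[i - 1] else 0
    sy2 <- cy2[j] - if (i > 1) cy2[i - 1] else 0
    sty <- cty[j] - if (i > 1) cty[i - 1] else 0
    sxx <- st2 - st^2 / m
    syy <- sy2 - sy^2 / m
    sxy <- sty - st * sy / m
    slope <- if (sxx > 0) sxy / sxx else 0
    scale_y <- max(syy, 1e-24)
    flat <- syy <= 1e-12 * max(sy2 / m, 1e-12) ||
      (m > 1 && sqrt(syy / (m - 1)) <= flat_tol)
    r2 <- if (flat) 1 else (sxy^2 / sxx) / scale_y
    list(slope = slope, intercept = (sy - slope * st) / m, r2 = r2)
  }
  len_min <- max(min_pts, ceiling(min_frac * n))
  # prefer windows anchored near the event start, where the forks are
  # known to be active: a fork that stops later (template end, collision)
  # then cannot pull the fit onto its plateau-adjacent slow phase
  anchor_n <- max(10L, ceiling(0.2 * n))
  for (anchored in c(TRUE, FALSE)) {
    for (len in n:len_min) {
      i_max <- n - len + 1
      starts <- if (anchored) seq_len(min(anchor_n, i_max)) else seq_len(i_max)
      for (i in starts) {
        s <- wstat(i, i + len - 1)
        if (s$r2 >= r2_min) {
          return(list(slope = s$slope, intercept = s$intercept, r2 = s$r2,
                      i0 = i, i1 = i + len - 1, ok = TRUE))
        }
      }
    }
  }
  # nothing met the floor: report the best minimal window, flagged not ok
  best <- NULL
  for (i in 1:(n - len_min + 1)) {
    s <- wstat(i, i + len_min - 1)
    if (is.null(best) || s$r2 > best$r2) {
      best <- c(s, list(i0 = i, i1 = i + len_min - 1))
    }
  }
  c(best, list(ok = FALSE))
}

# Restrict a series to its dominant early kinetic phase. A fork that stops
# mid-event (template end, collision) leaves a slope break that a single
# straight-line fit would blend across; when a two-segment piecewise fit is
# BIC-preferred and the segments genuinely differ in slope, either the short
# leading detection artefact (a dark region "catching up" to its true width
# while still about a pixel wide) is discarded, or the fit range is cut back
# to the long, steeper first segment. Noise alone does not split: BIC
# penalises the extra parameters and the slopes must differ by more than
# `slope_ratio`.
first_phase_idx <- function(t, y, min_pts = 10L, slope_ratio = 1.25,
                            max_iter = 4L, artifact_span = 0.4) {
  lo <- 1L; hi <- length(y)
  for (iter in seq_len(max_iter)) {
    n <- hi - lo + 1L
    if (n < 2L * min_pts + 5L) break
    tt <- t[lo:hi]; yy <- y[lo:hi]
    ct <- cumsum(tt); ct2 <- cumsum(tt^2)
    cy <- cumsum(yy); cy2 <- cumsum(yy^2); cty <- cumsum(tt * yy)
    seg <- function(i, j) {
      m <- j - i + 1
      st <- ct[j] - if (i > 1) ct[i - 1] else 0
      st2 <- ct2[j] - if (i > 1) ct2[i - 1] else 0
      sy <- cy[j] - if (i > 1) cy[i - 1] else 0
      sy2 <- cy2[j] - if (i > 1) cy2[i - 1] else 0
      sty <- cty[j] - if (i > 1) cty[i - 1] else 0
      sxx <- st2 - st^2 / m; syy <- sy2 - sy^2 / m; sxy <- sty - st * sy / m
      slope <- if (sxx > 0) sxy / sxx else 0
      rss <- max(syy - if (sxx > 0) sxy^2 / sxx else 0, 0)
      list(slope = slope, rss = rss)
    }
    full <- seg(1, n)
    best_c <- NA_integer_; best_rss <- Inf; s1 <- s2 <- 0
    for (cc in min_pts:(n - min_pts)) {
      a <- seg(1, cc); b <- seg(cc + 1, n)
      if (a$rss + b$rss < best_rss) {
        best_rss <- a$rss + b$rss; best_c <- cc
        s1 <- a$slope; s2 <- b$slope
      }
    }
    eps <- 1e-12
    bic1 <- n * log(full$rss / n + eps) + 3 * log(n)
    bic2 <- n * log(best_rss / n + eps) + 6 * log(n)
    differ <- abs(s1) > slope_ratio * abs(s2) + 1e-9 ||
      abs(s2) > slope_ratio * abs(s1) + 1e-9
    if (!(bic2 < bic1 && differ)) break
    # a leading segment confined to the blur-dominated span (the region is
    # still only a few pixels wide, whatever its length in lines) is a
    # detection artefact; a first phase extending beyond it is kinetics
    lead_span <- abs(yy[best_c] - yy[1])
    if (lead_span <= artifact_span && (n - best_c) >= 2L * min_pts) {
      lo <- lo + best_c            # blur-dominated lead-in: drop it
    } else if (abs(s1) > abs(s2)) {
      hi <- lo + best_c - 1L       # steeper long first phase: keep it
    } else {
      break                        # long slow lead-in: leave as is
    }
  }
  lo:hi
}

# correction factor moving lab-frame positions into the duplex frame:
# subtract kappa * (dark span left of the point), kappa = (x_ss - x_ds)/x_ss
duplex_frame_kappa <- function(force, ss, ds) {
  unwound_bp_extension(force, ss, ds) / polymer_extension(ss, force)
}

#' Classify events as unidirectional, bidirectional or ambiguous
#'
#' Edge criterion: edge positions are first corrected into the duplex frame
#' (subtracting `(x_ss - x_ds)/x_ss` times the dark span to the left of each
#' edge), which removes the apparent outward drift that growing ssDNA
#' imposes on downstream material. Each side's outward displacement is
#' converted to base pairs, and both sides are scaled up pro rata so that
#' they account for the full final dark span: a dark region is only
#' detectable once it is about a pixel wide, and the unwinding before
#' detection belongs to the sides in proportion to their observed motion.
#' An event is bidirectional when both sides exceed the motion threshold
#' (`motion_threshold_um` of dark-span growth, i.e.
#' `motion_threshold_um / x_ss(F)` bp), unidirectional when exactly one
#' does, ambiguous otherwise. Spot criterion: two spots assigned to the
#' event whose separation grows by more than `motion_threshold_um` also
#' mark it bidirectional.
#'
#' @param events event-line tibble from [link_events()].
#' @param spots spot tibble from [detect_spots()] (optional).
#' @param force force during the events, pN.
#' @param motion_threshold_um dark-span growth separating fork motion from
#'   edge jitter; conventionally 3 pixels' worth.
#' @param ss,ds elasticity parameter objects.
#' @return tibble `event_id, class, disp_left_bp, disp_right_bp, n_spots`.
#' @export
classify_events <- function(events, spots = NULL, force,
                            motion_threshold_um = 0.3,
                            ss = ssdna_params(), ds = dsdna_params()) {
  kappa <- duplex_frame_kappa(force, ss, ds)
  xss <- polymer_extension(ss, force)
  xds <- polymer_extension(ds, force)
  thr_bp <- motion_threshold_um * 1000 / xss
  per_event <- events |>
    dplyr::group_by(.data$event_id) |>
    dplyr::arrange(.data$line, .by_group = TRUE) |>
    dplyr::summarise(
      disp_left_bp = {
        cl <- .data$left_um - kappa * .data$dark_left_um
        (cl[1] - cl[length(cl)]) * 1000 / xds
      },
      disp_right_bp = {
        cr <- .data$right_um - kappa * (.data$dark_left_um + .data$width_um)
        (cr[length(cr)] - cr[1]) * 1000 / xds
      },
      w_end_bp = .data$width_um[length(.data$width_um)] * 1000 / xss,
      .groups = "drop") |>
    dplyr::mutate(
      obs_bp = pmax(.data$disp_left_bp, 0) + pmax(.data$disp_right_bp, 0),
      scale = dplyr::if_else(.data$obs_bp > 0,
                             pmax(.data$w_end_bp / .data$obs_bp, 1), 1),
      disp_left_bp = .data$disp_left_bp * .data$scale,
      disp_right_bp = .data$disp_right_bp * .data$scale)
  if (!is.null(spots) && nrow(spots)) {
    spot_stats <- spots |>
      dplyr::filter(!is.na(.data$event_id)) |>
      dplyr::group_by(.data$event_id) |>
      dplyr::summarise(
        n_spots = dplyr::n_distinct(.data$spot_id),
        spot_div = {
          # growth of the spot separation, over lines seeing >= 2 spots
          per_line <- split(.data$position_um, .data$line)
          per_line <- per_line[vapply(per_line, length, integer(1)) >= 2]
          if (length(per_line) >= 2) {
            seps <- vapply(per_line, function(p) diff(range(p)), numeric(1))
            seps[length(seps)] - seps[1]
          } else 0
        }, .groups = "drop")
    per_event <- dplyr::left_join(per_event, spot_stats, by = "event_id")
  }
  if (!"n_spots" %in% names(per_event)) {
    per_event$n_spots <- NA_integer_
    per_event$spot_div <- NA_real_
  }
  per_event |>
    dplyr::mutate(
      n_spots = dplyr::coalesce(.data$n_spots, 0L),
      left_moves = .data$disp_left_bp > thr_bp,
      right_moves = .data$disp_right_bp > thr_bp,
      spot_bi = !is.na(.data$spot_div) & .data$n_spots >= 2 &
        .data$spot_div > motion_threshold_um,
      class = dplyr::case_when(
        (left_moves & right_moves) | spot_bi ~ "bidirectional",
        xor(left_moves, right_moves) ~ "unidirectional",
        TRUE ~ "ambiguous")) |>
    dplyr::select("event_id", "class", "disp_left_bp", "disp_right_bp",
                  "n_spots")
}

#' Estimate unwinding rates in bp/s
#'
#' For each event, fits the linear region (longest contiguous window with
#' R^2 >= `r2_min` covering >= `min_frac` of the event) of: the dark-region
#' width versus time, giving the total expansion rate
#' (`slope / x_ss(F)`); and each duplex-frame-corrected edge versus time,
#' giving per-fork rates (`|slope| / x_ds(F)`, numerically equal to the
#' per-fork ssDNA growth divided by `x_ss`). Events with no qualifying
#' window are flagged unratable and excluded from downstream means.
#'
#' @param events event-line tibble from [link_events()].
#' @param force force during the fit window, pN.
#' @param r2_min local-fit R^2 floor for the linear region.
#' @param min_frac minimum fraction of the event the region must cover.
#' @param flat_tol_um edge-position sd below which an edge counts as static
#'   (rate 0) rather than unratable; absorbs subpixel localisation jitter.
#' @param min_fit_disp_um minimum dark-width growth across the selected fit
#'   window for the event to count as ratable: a slope measured over less
#'   growth than this is dominated by localisation noise and its
#'   selection-inflated estimate would bias condition means.
#' @param ss,ds elasticity parameter objects.
#' @return tibble `event_id, rate_total_bps, rate_left_bps, rate_right_bps,
#'   r2, fit_t0_s, fit_t1_s, n_lines, bp_dark, ratable`. `bp_dark` is the
#'   median of the five largest dark widths divided by `x_ss(F)`.
#' @export
estimate_rates <- function(events, force, r2_min = 0.9, min_frac = 0.5,
                           flat_tol_um = 0.05, min_fit_disp_um = 0.3,
                           ss = ssdna_params(), ds = dsdna_params()) {
  xss <- polymer_extension(ss, force)
  xds <- polymer_extension(ds, force)
  kappa <- duplex_frame_kappa(force, ss, ds)
  # restrict a monotone-growth series to its growth phase: everything up to
  # the first sample reaching 95% of the final level, so that the plateau
  # after a fork stops (template end, collision) cannot dilute the slope
  growth_idx <- function(y, flat_guard) {
    disp <- abs(y - y[1])
    top <- sort(disp, decreasing = TRUE)
    final <- stats::median(top[seq_len(min(5, length(top)))])
    if (final < flat_guard) return(seq_along(y))
    seq_len(max(which(disp >= 0.95 * final)[1], min(5L, length(y))))
  }
  events |>
    dplyr::group_by(.data$event_id) |>
    dplyr::arrange(.data$line, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      # 5-line running median knocks down edge-localisation noise without
      # biasing the slope of a linear stretch
      smooth5 <- function(y) {
        if (length(y) >= 7) stats::runmed(y, 5, endrule = "median") else y
      }
      w <- smooth5(d$width_um)
      gw <- growth_idx(w, 4 * flat_tol_um)
      gw <- gw[first_phase_idx(d$time_s[gw], w[gw])]
      ft <- linear_region_fit(d$time_s[gw], w[gw], r2_min, min_frac)
      cl <- smooth5(d$left_um - kappa * d$dark_left_um)
      cr <- smooth5(d$right_um - kappa * (d$dark_left_um + d$width_um))
      gl <- growth_idx(cl, 4 * flat_tol_um)
      gl <- gl[first_phase_idx(d$time_s[gl], cl[gl])]
      gr <- growth_idx(cr, 4 * flat_tol_um)
      gr <- gr[first_phase_idx(d$time_s[gr], cr[gr])]
      fl <- linear_region_fit(d$time_s[gl], cl[gl], r2_min, min_frac,
                              flat_tol = flat_tol_um)
      fr <- linear_region_fit(d$time_s[gr], cr[gr], r2_min, min_frac,
                              flat_tol = flat_tol_um)
      wtop <- sort(d$width_um, decreasing = TRUE)
      fit_disp <- if (isTRUE(ft$ok)) {
        abs(ft$slope) * (d$time_s[gw][ft$i1] - d$time_s[gw][ft$i0])
      } else 0
      ok_total <- isTRUE(ft$ok) && fit_disp >= min_fit_disp_um
      onset <- if (ok_total && ft$slope > 0) {
        -ft$intercept / ft$slope
      } else NA_real_
      tibble(
        rate_total_bps = if (ok_total) ft$slope * 1000 / xss else NA_real_,
        rate_left_bps = if (isTRUE(fl$ok)) abs(fl$slope) * 1000 / xds else NA_real_,
        rate_right_bps = if (isTRUE(fr$ok)) abs(fr$slope) * 1000 / xds else NA_real_,
        r2 = ft$r2,
        fit_t0_s = if (!is.na(ft$i0)) d$time_s[gw][ft$i0] else NA_real_,
        fit_t1_s = if (!is.na(ft$i1)) d$time_s[gw][ft$i1] else NA_real_,
        onset_s = onset,
        n_lines = nrow(d),
        bp_dark = stats::median(wtop[seq_len(min(5, length(wtop)))]) *
          1000 / xss,
        ratable = ok_total)
    }) |>
    dplyr::ungroup()
}

#' Required initiation force under a stepped protocol
#'
#' The plateau force of the first plateau containing a detected event
#' initiation; `"N.U."` (no unwinding) if nothing initiates up to the
#' schedule maximum. An initiation falling outside every plateau is assigned
#' to the following plateau with a warning.
#'
#' @param events event-line tibble from [link_events()] (possibly empty).
#' @param schedule a [force_schedule()].
#' @return one-row tibble `required_force_pN` (NA for no unwinding) and
#'   `outcome` (`"unwound"` or `"N.U."`).
#' @export
required_force <- function(events, schedule) {
  if (nrow(events) == 0) {
    return(tibble(required_force_pN = NA_real_, outcome = "N.U."))
  }
  t0 <- min(events$time_s)
  idx <- which(schedule$t_start_s <= t0 & t0 < schedule$t_end_s)
  if (!length(idx)) {
    idx <- which(schedule$t_start_s > t0)
    if (!length(idx)) {
      return(tibble(required_force_pN = NA_real_, outcome = "N.U."))
    }
    warn("event initiation outside any plateau; assigned to the next plateau")
  }
  tibble(required_force_pN = schedule$force_pN[idx[1]], outcome = "unwound")
}

#' Detect rewinding after a channel switch
#'
#' For each event present after `t_switch_s`, the dark width is tested for a
#' significantly negative trend (one-sided sign test on successive
#' differences) and the tether-length trend is required to oppose the
#' unwinding direction at that force; both together mark the event
#' `rewound`, a significantly positive width trend marks it `continued`,
#' anything else `indeterminate` (including post-switch windows shorter than
#' 5 lines). The rewind rate comes from the linear-region fit of the
#' shrinking width, as total bp/s.
#'
#' @param events event-line tibble from [link_events()].
#' @param series trace series (`time_s, force_pN, length_um`).
#' @param t_switch_s switch time, s.
#' @param force post-switch force, pN.
#' @param alpha sign-test significance level.
#' @param width_floor_um rate fitting ignores scan lines whose dark width is
#'   below this: a nearly closed region is narrower than the PSF and its
#'   measured width collapses faster than the true one.
#' @param ss,ds elasticity parameter objects.
#' @return tibble `event_id, status, rewind_rate_bps`.
#' @export
detect_rewinding <- function(events, series, t_switch_s, force, alpha = 0.05,
                             width_floor_um = 0.3,
                             ss = ssdna_params(), ds = dsdna_params()) {
  xss <- polymer_extension(ss, force)
  fac <- unwound_bp_extension(force, ss, ds)
  post_series <- series[series$time_s > t_switch_s, ]
  len_slope <- if (nrow(post_series) >= 5) {
    stats::coef(stats::lm(length_um ~ time_s, data = post_series))[2]
  } else NA_real_
  events |>
    dplyr::filter(.data$time_s > t_switch_s) |>
    dplyr::group_by(.data$event_id) |>
    dplyr::arrange(.data$line, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 5) {
        return(tibble(status = "indeterminate", rewind_rate_bps = NA_real_))
      }
      dw <- diff(d$width_um)
      dw <- dw[dw != 0]
      if (!length(dw)) {
        return(tibble(status = "indeterminate", rewind_rate_bps = NA_real_))
      }
      p_neg <- stats::binom.test(sum(dw < 0), length(dw),
                                 alternative = "greater")$p.value
      p_pos <- stats::binom.test(sum(dw > 0), length(dw),
                                 alternative = "greater")$p.value
      # length trend must oppose unwinding for a rewind call
      len_opposes <- !is.na(len_slope) && (len_slope * fac < 0)
      if (p_neg < alpha && len_opposes) {
        fd <- d[d$width_um >= width_floor_um, ]
        if (nrow(fd) < 5) fd <- d
        ft <- linear_region_fit(fd$time_s, fd$width_um, r2_min = 0.9,
                                min_frac = 0.5)
        rate <- if (isTRUE(ft$ok)) abs(ft$slope) * 1000 / xss else NA_real_
        tibble(status = "rewound", rewind_rate_bps = rate)
      } else if (p_pos < alpha) {
        tibble(status = "continued", rewind_rate_bps = NA_real_)
      } else {
        tibble(status = if (stats::sd(d$width_um) <= 1e-9) "continued"
               else "indeterminate", rewind_rate_bps = NA_real_)
      }
    }) |>
    dplyr::ungroup()
}

# Wilson 95% score interval for a binomial proportion
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(center - half, center + half)
}

#' Condition-level summary statistics
#'
#' Per-class mean, SD (n-1 denominator) and n of the event rates, the
#' bidirectional fraction with its Wilson 95% interval, and a two-sample
#' Student's t-test (pooled variance; Welch behind `welch = TRUE`) between
#' the two compared classes. Rates enter as the total expansion rate for
#' bidirectional events and the (single) fork rate for unidirectional ones.
#' Ambiguous or unratable events are excluded from means. Results are
#' invariant to event ordering.
#'
#' @param events tibble with at least `class` and `rate_total_bps` columns
#'   (e.g. the `events` table of [analyze_trace()] results, row-bound over
#'   molecules).
#' @param label condition label.
#' @param compare two class labels to test against each other.
#' @param welch use the Welch (unequal-variance) t-test instead of the
#'   pooled-variance Student's t-test.
#' @return one-row tibble with counts, per-class `mean_*`/`sd_*`,
#'   `fraction_bidirectional` (+ Wilson bounds) and `t_statistic`,
#'   `p_value`.
#' @export
summarize_condition <- function(events, label = "condition",
                                compare = c("bidirectional", "unidirectional"),
                                welch = FALSE) {
  ratable <- events[!is.na(events$rate_total_bps) &
                      events$class %in% c("unidirectional", "bidirectional"), ]
  cls <- function(cl) ratable$rate_total_bps[ratable$class == cl]
  uni <- cls("unidirectional"); bi <- cls("bidirectional")
  n_classified <- nrow(events[events$class %in%
                                c("unidirectional", "bidirectional"), ])
  n_bi_all <- sum(events$class == "bidirectional")
  ci <- wilson_ci(n_bi_all, n_classified)
  tt <- if (length(cls(compare[1])) >= 2 && length(cls(compare[2])) >= 2) {
    stats::t.test(cls(compare[1]), cls(compare[2]), var.equal = !welch)
  } else NULL
  if (is.null(tt)) {
    rlang::inform(paste0("condition '", label,
                         "': t-test omitted (a compared class has < 2 events)"))
  }
  tibble(
    condition = label,
    n_events = nrow(events),
    n_unidirectional = length(uni),
    n_bidirectional = length(bi),
    mean_uni_bps = if (length(uni)) mean(uni) else NA_real_,
    sd_uni_bps = if (length(uni) >= 2) stats::sd(uni) else NA_real_,
    mean_bi_bps = if (length(bi)) mean(bi) else NA_real_,
    sd_bi_bps = if (length(bi) >= 2) stats::sd(bi) else NA_real_,
    fraction_bidirectional = if (n_classified) n_bi_all / n_classified
      else NA_real_,
    fraction_bi_lo = ci[1], fraction_bi_hi = ci[2],
    t_statistic = if (!is.null(tt)) unname(tt$statistic) else NA_real_,
    p_value = if (!is.null(tt)) tt$p.value else NA_real_)
}
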