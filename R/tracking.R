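# Image-analysis stage: per-line dark-run segmentation of the Sytox channel,
# greedy nearest-neighbour linking into events with subpixel edges, and
# eGFP spot detection/linking.

#' Segment dark (ssDNA) regions in a Sytox kymograph
#'
#' Per scan line, finds maximal runs of pixels below threshold after
#' excluding a bead margin at both raster ends. The default threshold is
#' `threshold_frac` times the per-line duplex brightness, estimated as the
#' median of the brightest quartile of the analysis window (robust to lamp
#' drift and to dark regions covering most of the tether); pass `threshold`
#' for an absolute-counts mode. Edges are refined to subpixel by linear
#' interpolation of the threshold crossing between the bracketing pixels.
#'
#' @param kymo a [kymograph()].
#' @param channel channel holding the duplex stain.
#' @param threshold absolute threshold in counts, or `NULL` for
#'   median-relative thresholding.
#' @param threshold_frac fraction of the per-line duplex brightness used
#'   when `threshold` is `NULL`.
#' @param bead_margin_px pixels excluded at each raster end.
#' @return a tibble with one row per dark interval:
#'   `line, time_s, start_px, end_px, start_um, end_um, center_um, width_um`.
#' @export
segment_dark_regions <- function(kymo, channel = "sytox", threshold = NULL,
                                 threshold_frac = 0.5, bead_margin_px = 5L) {
  if (!channel %in% names(kymo$channels)) {
    abort(sprintf("channel '%s' not present", channel))
  }
  m <- kymo$channels[[channel]]
  n_px <- ncol(m)
  win <- (bead_margin_px + 1L):(n_px - bead_margin_px)
  if (length(win) < 3) abort("raster too narrow for the bead margin")
  if (all(m == m[1, 1])) abort("no signal: kymograph is constant")
  px <- kymo$pixel_size_um
  out <- vector("list", nrow(m))
  for (k in seq_len(nrow(m))) {
    # 3-px median prefilter: single-pixel shot noise cannot split a dark run
    v <- stats::runmed(m[k, ], 3, endrule = "median")
    bright <- v[win][v[win] >= stats::quantile(v[win], 0.75)]
    thr <- threshold %||% (threshold_frac * stats::median(bright))
    below <- v[win] < thr
    if (!any(below)) next
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    s_px <- win[starts[runs]]
    e_px <- win[ends[runs]]
    # subpixel crossings: positions are in um from the raster origin,
    # pixel j center at (j - 0.5) * px
    s_um <- vapply(s_px, function(s) {
      if (s > 1 && v[s - 1] >= thr && v[s - 1] > v[s]) {
        frac <- (v[s - 1] - thr) / (v[s - 1] - v[s])
        (s - 1.5 + frac) * px
      } else (s - 1) * px
    }, numeric(1))
    e_um <- vapply(e_px, function(e) {
      if (e < n_px && v[e + 1] >= thr && v[e + 1] > v[e]) {
        frac <- (v[e + 1] - thr) / (v[e + 1] - v[e])
        (e + 0.5 - frac) * px
      } else e * px
    }, numeric(1))
    out[[k]] <- tibble(line = k, time_s = (k - 1) * kymo$line_time_s,
                       start_px = s_px, end_px = e_px,
                       start_um = s_um, end_um = e_um,
                       center_um = (s_um + e_um) / 2,
                       width_um = e_um - s_um)
  }
  dplyr::bind_rows(out)
}

#' Link dark intervals through time into unwinding events
#'
#' Greedy nearest-neighbour linking of per-line dark intervals by centre
#' distance: an interval joins the open track whose last centre is nearest
#' and within `max_jump_px`, tolerating up to `max_gap_lines` missing lines.
#' Tracks shorter than `min_lines` or never reaching `min_width_px` are
#' discarded as shot-noise artefacts. For each event and line the dark span
#' strictly to the left of the event (`dark_left_um`) is recorded so that
#' downstream rate fitting can correct edge positions into the duplex frame.
#'
#' @param segments output of [segment_dark_regions()].
#' @param max_gap_lines,max_jump_px linking tolerances.
#' @param min_lines,min_width_px event-acceptance filters.
#' @param pixel_size_um pixel size (needed to express `max_jump_px` and
#'   `min_width_px` in micrometres).
#' @return a tibble with one row per event-line:
#'   `event_id, line, time_s, left_um, right_um, width_um, center_um,
#'    dark_left_um`.
#' @export
link_events <- function(segments, max_gap_lines = 2L, max_jump_px = 5L,
                        min_lines = 5L, min_width_px = 3L,
                        pixel_size_um = 0.1) {
  if (nrow(segments) == 0) {
    return(tibble(event_id = integer(), line = integer(), time_s = numeric(),
                  left_um = numeric(), right_um = numeric(),
                  width_um = numeric(), center_um = numeric(),
                  dark_left_um = numeric()))
  }
  max_jump_um <- max_jump_px * pixel_size_um
  tracks <- list()   # each: list(rows = list of row tibbles, last_center, last_line)
  open_idx <- integer(0)
  for (k in sort(unique(segments$line))) {
    seg_k <- segments[segments$line == k, ]
    # cumulative dark strictly left of each interval on this line
    ord <- order(seg_k$start_um)
    seg_k <- seg_k[ord, ]
    seg_k$dark_left_um <- cumsum(dplyr::lag(seg_k$width_um, default = 0))
    # close stale tracks
    if (length(open_idx)) {
      stale <- vapply(tracks[open_idx], function(tr) k - tr$last_line,
                      numeric(1)) > max_gap_lines + 1
      open_idx <- open_idx[!stale]
    }
    taken <- rep(FALSE, length(open_idx))
    for (j in seq_len(nrow(seg_k))) {
      d <- if (length(open_idx)) {
        vapply(tracks[open_idx],
               function(tr) abs(tr$last_center - seg_k$center_um[j]),
               numeric(1))
      } else numeric(0)
      d[taken] <- Inf
      best <- if (length(d)) which.min(d) else integer(0)
      if (length(best) && d[best] <= max_jump_um) {
        ti <- open_idx[best]
        tracks[[ti]]$rows[[length(tracks[[ti]]$rows) + 1L]] <- seg_k[j, ]
        tracks[[ti]]$last_center <- seg_k$center_um[j]
        tracks[[ti]]$last_line <- k
        taken[best] <- TRUE
      } else {
        tracks[[length(tracks) + 1L]] <- list(rows = list(seg_k[j, ]),
                                              last_center = seg_k$center_um[j],
                                              last_line = k)
        open_idx <- c(open_idx, length(tracks))
        taken <- c(taken, TRUE)
      }
    }
  }
  kept <- purrr::keep(tracks, function(tr) {
    length(tr$rows) >= min_lines &&
      max(vapply(tr$rows, function(r) r$width_um, numeric(1))) >=
        min_width_px * pixel_size_um
  })
  if (!length(kept)) {
    return(link_events(segments[0, ], pixel_size_um = pixel_size_um))
  }
  # order events by first appearance, then leftmost position
  starts <- vapply(kept, function(tr) tr$rows[[1]]$line, numeric(1))
  poss <- vapply(kept, function(tr) tr$rows[[1]]$center_um, numeric(1))
  kept <- kept[order(starts, poss)]
  purrr::imap_dfr(kept, function(tr, i) {
    rows <- dplyr::bind_rows(tr$rows)
    tibble(event_id = i, line = rows$line, time_s = rows$time_s,
           left_um = rows$start_um, right_um = rows$end_um,
           width_um = rows$width_um, center_um = rows$center_um,
           dark_left_um = rows$dark_left_um)
  })
}

#' Detect and link eGFP spots
#'
#' Per line, local maxima in the eGFP channel exceeding
#' `background + min_snr * noise` (median / MAD of the analysis window) are
#' taken as spot candidates, refined to subpixel by a three-point parabola,
#' and linked through time like dark intervals. Each spot track is assigned
#' to the event whose dark region (padded by `assign_tol_px`) contains its
#' mean position. An absent eGFP channel yields an empty result, not an
#' error.
#'
#' @param kymo a [kymograph()].
#' @param events event-line tibble from [link_events()] (optional; used only
#'   for event assignment).
#' @param channel spot channel name.
#' @param min_snr detection threshold in robust noise units.
#' @param bead_margin_px pixels excluded at each raster end.
#' @param max_gap_lines,max_jump_px linking tolerances.
#' @param min_lines minimum track length.
#' @param assign_tol_px padding around an event's dark span when assigning
#'   spots.
#' @return a tibble `spot_id, event_id, line, time_s, position_um, intensity`.
#' @export
detect_spots <- function(kymo, events = NULL, channel = "egfp", min_snr = 3,
                         bead_margin_px = 5L, max_gap_lines = 2L,
                         max_jump_px = 5L, min_lines = 5L, assign_tol_px = 3L) {
  empty <- tibble(spot_id = integer(), event_id = integer(), line = integer(),
                  time_s = numeric(), position_um = numeric(),
                  intensity = numeric())
  if (!channel %in% names(kymo$channels)) return(empty)
  m <- kymo$channels[[channel]]
  px <- kymo$pixel_size_um
  n_px <- ncol(m)
  win <- (bead_margin_px + 1L):(n_px - bead_margin_px)
  cand <- vector("list", nrow(m))
  for (k in seq_len(nrow(m))) {
    v <- m[k, ]
    bg <- stats::median(v[win])
    noise <- max(stats::mad(v[win]), 1e-9)
    thr <- bg + min_snr * noise
    inner <- win[-c(1, length(win))]
    is_max <- v[inner] >= thr & v[inner] >= v[inner - 1] & v[inner] > v[inner + 1]
    peaks <- inner[is_max]
    if (!length(peaks)) next
    pos <- vapply(peaks, function(p) {
      # parabolic subpixel refinement on log-free intensities
      a <- v[p - 1]; b <- v[p]; c <- v[p + 1]
      denom <- a - 2 * b + c
      delta <- if (abs(denom) > 1e-12) 0.5 * (a - c) / denom else 0
      (p - 0.5 + max(min(delta, 0.5), -0.5)) * px
    }, numeric(1))
    cand[[k]] <- tibble(line = k, time_s = (k - 1) * kymo$line_time_s,
                        position_um = pos, intensity = v[peaks] - bg)
  }
  cand <- dplyr::bind_rows(cand)
  if (nrow(cand) == 0) return(empty)
  # reuse the interval linker on zero-width "intervals"
  fake <- tibble(line = cand$line, time_s = cand$time_s,
                 start_px = NA_integer_, end_px = NA_integer_,
                 start_um = cand$position_um, end_um = cand$position_um,
                 center_um = cand$position_um, width_um = cand$intensity)
  linked <- link_events(fake, max_gap_lines = max_gap_lines,
                        max_jump_px = max_jump_px, min_lines = min_lines,
                        min_width_px = 0L, pixel_size_um = px)
  if (nrow(linked) == 0) return(empty)
  spots <- tibble(spot_id = linked$event_id, line = linked$line,
                  time_s = linked$time_s, position_um = linked$center_um,
                  intensity = linked$width_um)
  spots$event_id <- NA_integer_
  if (!is.null(events) && nrow(events)) {
    tol <- assign_tol_px * px
    span <- events |>
      dplyr::group_by(.data$event_id) |>
      dplyr::summarise(lo = min(.data$left_um) - tol,
                       hi = max(.data$right_um) + tol, .groups = "drop")
    mean_pos <- spots |>
      dplyr::group_by(.data$spot_id) |>
      dplyr::summarise(pos = mean(.data$position_um), .groups = "drop")
    for (i in seq_len(nrow(mean_pos))) {
      hit <- which(span$lo <= mean_pos$pos[i] & span$hi >= mean_pos$pos[i])
      if (length(hit)) {
        spots$event_id[spots$spot_id == mean_pos$spot_id[i]] <-
          span$event_id[hit[1]]
      }
    }
  }
  spots[, c("spot_id", "event_id", "line", "time_s", "position_um",
            "intensity")]
}

#' Edge-track plot for linked events
#'
#' @param events event-line tibble from [link_events()].
#' @return a ggplot of left/right edge positions over time, one colour per
#'   event.
#' @export
plot_edge_tracks <- function(events) {
  long <- tidyr::pivot_longer(events, c("left_um", "right_um"),
                              names_to = "side", values_to = "position_um")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$position_um,
                                     colour = factor(.data$event_id),
                                     linetype = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Edge position (µm)",
                  colour = "Event", linetype = "Edge")
}
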