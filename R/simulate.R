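# Synthetic trace generator: nick-initiated unwinding forks on a tethered
# template rendered into a Sytox (duplex) kymograph, an optional eGFP-RPA
# spot channel, and a constant-force length time series, with full ground
# truth. All randomness flows from `seed` through three fixed substreams
# (events: seed; channel-switch fates: seed+1; photon/readout noise: seed+2).

#' Kymograph container
#'
#' @param channels named list of numeric matrices (rows = scan lines in time
#'   order, columns = position along the scan); all the same shape, values
#'   >= 0.
#' @param pixel_size_um pixel size, micrometres.
#' @param line_time_s time per scan line, seconds.
#' @return an object of class `kymograph`.
#' @export
kymograph <- function(channels, pixel_size_um, line_time_s) {
  stopifnot(is.list(channels), length(channels) >= 1, !is.null(names(channels)))
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1) abort("all channels must share the same shape")
  if (any(vapply(channels, function(m) any(m < 0), logical(1)))) {
    abort("intensities must be >= 0")
  }
  if (pixel_size_um <= 0 || line_time_s <= 0) {
    abort("pixel_size_um and line_time_s must be positive")
  }
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 line_time_s = line_time_s),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<kymograph>", d[1], "lines x", d[2], "px;",
      paste(names(x$channels), collapse = ", "), "|",
      x$pixel_size_um, "um/px,", x$line_time_s, "s/line\n")
  invisible(x)
}

# Gaussian blur of each row, edge-replicated padding
blur_rows <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  n <- ncol(mat)
  idx <- c(rep(1L, r), seq_len(n), rep(n, r))
  padded <- mat[, idx, drop = FALSE]
  out <- mat
  for (i in seq_len(nrow(mat))) {
    v <- stats::filter(padded[i, ], k, sides = 2)
    out[i, ] <- v[(r + 1):(r + n)]
  }
  out
}

# fraction of each pixel [ (j-1)*px, j*px ) covered by the union of the
# disjoint sorted intervals (um)
pixel_coverage <- function(starts_um, ends_um, n_px, px) {
  cov <- numeric(n_px)
  for (i in seq_along(starts_um)) {
    a <- starts_um[i]; b <- ends_um[i]
    if (b <= a) next
    j0 <- max(1L, floor(a / px) + 1L)
    j1 <- min(n_px, ceiling(b / px))
    if (j1 < j0) next
    j <- j0:j1
    cov[j] <- cov[j] +
      (pmin(j * px, b) - pmax((j - 1) * px, a)) / px
  }
  pmin(cov, 1)
}

draw_trunc_norm <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v > 0) { out[i] <- v; break }
    }
  }
  out
}

#' Simulate a single-molecule unwinding trace
#'
#' Generates a ground-truthed trace of one tethered template under a
#' force-plateau schedule: nick-initiated forks whose Gaussian velocities,
#' uni/bi class and initiation-force thresholds come from `condition`; a
#' Sytox kymograph in which duplex fluorescence is lost where forks have
#' passed (dark regions), PSF-blurred and Poisson-noised; an optional
#' eGFP-RPA channel with a coil-bound spot at each moving fork whose
#' intensity grows with the coil; and a `time, force, length` series obeying
#' the tether elasticity at every scan line. Identical `(seed, arguments)`
#' give bit-identical output.
#'
#' Events initiate only once the scheduled force reaches their sampled
#' initiation threshold (uniform jitter within the first half of that
#' plateau); molecules whose thresholds exceed the schedule maximum never
#' unwind (the N.U. outcome). Forks stop at template ends, on collision with
#' a neighbouring event, at the trace end, or by rewinding after a channel
#' switch (see `switch_spec`).
#'
#' @param template a [template_spec()]; if it carries no nick positions the
#'   number of events is Poisson(`events_per_molecule_mean`) and nicks are
#'   placed uniformly over the interior 90% of the template.
#' @param condition a [sim_condition()].
#' @param imaging an [imaging_params()].
#' @param schedule a [force_schedule()]; the trace ends at
#'   `min(imaging$duration_s, max(schedule$t_end_s))`.
#' @param seed integer seed; all randomness derives from it.
#' @param uni_direction fork direction for unidirectional events: `"random"`,
#'   or `"left"`/`"right"` (e.g. `"right"` for a tensioned-strand fork on the
#'   6.4 kbp polarity template whose nick sits 2,200 bp from the left end).
#' @param switch_spec optional channel-switch: a list with `t_switch_s`,
#'   `p_continue` and `rewind_rate_bps`. After `t_switch_s` each active fork
#'   independently continues with probability `p_continue`, otherwise it
#'   rewinds toward its nick at `rewind_rate_bps` until the dark region
#'   closes.
#' @param ss,ds elasticity parameter objects.
#' @return an object of class `sm_trace`: `kymo` ([kymograph()]), `series`
#'   (tibble `time_s, force_pN, length_um`), `truth` (per-event tibble),
#'   generation parameters, and `offset_um` (position of the left template
#'   attachment in the raster).
#' @export
simulate_trace <- function(template, condition, imaging = imaging_params(),
                           schedule = force_schedule(30, imaging$duration_s),
                           seed = 1L,
                           uni_direction = c("random", "left", "right"),
                           switch_spec = NULL,
                           ss = ssdna_params(), ds = dsdna_params()) {
  uni_direction <- match.arg(uni_direction)
  px <- imaging$pixel_size_um
  lt <- imaging$line_time_s
  duration <- min(imaging$duration_s, max(schedule$t_end_s))
  n_lines <- max(1L, floor(duration / lt))
  t_lines <- (seq_len(n_lines) - 1) * lt
  f_lines <- schedule_force_at(schedule, t_lines)
  xss_nm <- polymer_extension(ss, f_lines)
  xds_nm <- polymer_extension(ds, f_lines)

  ## --- event layer ---------------------------------------------------
  set.seed(as.integer(seed))
  if (length(template$nick_positions)) {
    nicks <- template$nick_positions
  } else {
    n_ev <- stats::rpois(1, condition$events_per_molecule_mean)
    lo <- round(0.05 * template$total_bp); hi <- round(0.95 * template$total_bp)
    nicks <- if (n_ev > 0) sort(sample(lo:hi, n_ev)) else integer(0)
  }
  n_ev <- length(nicks)
  q <- condition$initiation_force
  q_forces <- as.numeric(names(q))
  ev <- vector("list", n_ev)
  for (i in seq_len(n_ev)) {
    u <- stats::runif(1)
    hit <- which(q >= u)
    thr <- if (length(hit)) q_forces[hit[1]] else Inf
    is_bi <- stats::runif(1) < condition$p_bidirectional
    if (is_bi) {
      v2 <- draw_trunc_norm(2, condition$velocity_bi_mean / 2,
                            condition$velocity_bi_sd / sqrt(2))
      v_l <- v2[1]; v_r <- v2[2]
    } else {
      v <- draw_trunc_norm(1, condition$velocity_uni_mean,
                           condition$velocity_uni_sd)
      dir <- switch(uni_direction,
                    random = if (stats::runif(1) < 0.5) "left" else "right",
                    uni_direction)
      v_l <- if (dir == "left") v else 0
      v_r <- if (dir == "right") v else 0
    }
    plateau <- which(schedule$force_pN >= thr)
    if (length(plateau)) {
      p <- plateau[1]
      t_init <- schedule$t_start_s[p] +
        stats::runif(1, 0, 0.5) * (schedule$t_end_s[p] - schedule$t_start_s[p])
      initiated <- t_init < duration
    } else {
      t_init <- NA_real_; initiated <- FALSE
    }
    ev[[i]] <- list(nick = nicks[i], thr = thr, initiated = initiated,
                    t_init = t_init, class = if (is_bi) "bi" else "uni",
                    v_l = v_l, v_r = v_r)
  }

  ## --- channel-switch fates ------------------------------------------
  set.seed(as.integer(seed) + 1L)
  cont_l <- cont_r <- rep(NA, n_ev)
  if (!is.null(switch_spec)) {
    for (i in seq_len(n_ev)) {
      cont_l[i] <- stats::runif(1) < switch_spec$p_continue
      cont_r[i] <- stats::runif(1) < switch_spec$p_continue
    }
  }

  ## --- fork trajectories (bp), stepped per scan line ------------------
  L <- matrix(rep(vapply(ev, `[[`, numeric(1), "nick"), each = n_lines),
              n_lines, n_ev)
  R <- L
  stop_l <- stop_r <- rep(NA_character_, n_ev)
  if (n_ev) {
    l_cur <- r_cur <- vapply(ev, `[[`, numeric(1), "nick")
    t_prev <- rep(NA_real_, n_ev)
    for (k in seq_len(n_lines)) {
      tk <- t_lines[k]
      for (i in seq_len(n_ev)) {
        e <- ev[[i]]
        if (!e$initiated || tk < e$t_init) next
        dt <- tk - max(t_prev[i], e$t_init, na.rm = TRUE)
        t_prev[i] <- tk
        if (dt <= 0) { L[k, i] <- l_cur[i]; R[k, i] <- r_cur[i]; next }
        rewinding <- !is.null(switch_spec) && tk > switch_spec$t_switch_s
        vl <- e$v_l; vr <- e$v_r
        if (rewinding) {
          if (!cont_l[i]) vl <- -switch_spec$rewind_rate_bps
          if (!cont_r[i]) vr <- -switch_spec$rewind_rate_bps
        }
        if (is.na(stop_l[i]) || (rewinding && !cont_l[i] && stop_l[i] != "rewound")) {
          l_new <- l_cur[i] - vl * dt
          if (vl < 0) l_new <- min(l_new, e$nick)   # rewind closes at the nick
          if (l_new <= 0) { l_new <- 0; stop_l[i] <- "template_end" }
          prev_r <- if (i > 1) r_cur[i - 1] else -Inf
          if (l_new < prev_r) {
            l_new <- prev_r
            stop_l[i] <- "collision"
            if (is.na(stop_r[i - 1])) stop_r[i - 1] <- "collision"
          }
          l_cur[i] <- l_new
        }
        if (is.na(stop_r[i]) || (rewinding && !cont_r[i] && stop_r[i] != "rewound")) {
          r_new <- r_cur[i] + vr * dt
          if (vr < 0) r_new <- max(r_new, e$nick)
          if (r_new >= template$total_bp) {
            r_new <- template$total_bp; stop_r[i] <- "template_end"
          }
          next_l <- if (i < n_ev) l_cur[i + 1] else Inf
          if (r_new > next_l) {
            r_new <- next_l
            stop_r[i] <- "collision"
            if (is.na(stop_l[i + 1])) stop_l[i + 1] <- "collision"
          }
          r_cur[i] <- r_new
        }
        if (rewinding && l_cur[i] >= e$nick && r_cur[i] <= e$nick &&
            (!cont_l[i] || !cont_r[i])) {
          stop_l[i] <- stop_r[i] <- "rewound"
        }
        L[k, i] <- l_cur[i]; R[k, i] <- r_cur[i]
      }
    }
    stop_l[is.na(stop_l)] <- "trace_end"
    stop_r[is.na(stop_r)] <- "trace_end"
  }

  ## --- length series and raster geometry ------------------------------
  W <- R - L
  n_ss_line <- if (n_ev) rowSums(W) else rep(0, n_lines)
  length_um <- (template$total_bp * xds_nm +
                  n_ss_line * (xss_nm - xds_nm)) / 1000
  margin <- imaging$bead_margin_px
  offset_um <- margin * px
  n_px <- ceiling(max(length_um) / px) + 2L * margin
  centers_um <- (seq_len(n_px) - 0.5) * px

  ## --- render channels -------------------------------------------------
  sytox <- matrix(0, n_lines, n_px)
  egfp <- if (condition$spot_channel) matrix(0, n_lines, n_px) else NULL
  sigma_px <- imaging$psf_sigma_um / px
  for (k in seq_len(n_lines)) {
    dark_cov <- numeric(n_px)
    if (n_ev) {
      live <- which(W[k, ] > 0)
      if (length(live)) {
        ints <- tibble(l = L[k, live], r = R[k, live])
        dl <- bp_to_um(ints$l, ints, xds_nm[k], xss_nm[k]) + offset_um
        dr <- bp_to_um(ints$r, ints, xds_nm[k], xss_nm[k]) + offset_um
        dark_cov <- pixel_coverage(dl, dr, n_px, px)
      }
    }
    sytox[k, ] <- imaging$dsdna_counts * (1 - dark_cov)
    if (!is.null(egfp) && n_ev) {
      prof <- numeric(n_px)
      for (i in seq_len(n_ev)) {
        ints_all <- tibble(l = L[k, W[k, ] > 0], r = R[k, W[k, ] > 0])
        coil_l <- ev[[i]]$nick - L[k, i]
        coil_r <- R[k, i] - ev[[i]]$nick
        if (coil_l > 0.5) {
          pos <- bp_to_um(L[k, i], ints_all, xds_nm[k], xss_nm[k]) + offset_um
          amp <- imaging$spot_counts_per_knt * coil_l / 1000
          prof <- prof + amp * px *
            stats::dnorm(centers_um, pos, imaging$psf_sigma_um)
        }
        if (coil_r > 0.5) {
          pos <- bp_to_um(R[k, i], ints_all, xds_nm[k], xss_nm[k]) + offset_um
          amp <- imaging$spot_counts_per_knt * coil_r / 1000
          prof <- prof + amp * px *
            stats::dnorm(centers_um, pos, imaging$psf_sigma_um)
        }
      }
      egfp[k, ] <- prof
    }
  }
  sytox <- blur_rows(sytox, sigma_px) + imaging$background_counts
  # bead glow: out-of-tether pixels rendered at duplex brightness so that
  # dark regions occur only where ssDNA is
  for (k in seq_len(n_lines)) {
    out_of <- centers_um < offset_um | centers_um > offset_um + length_um[k]
    sytox[k, out_of] <- imaging$dsdna_counts + imaging$background_counts
  }
  if (!is.null(egfp)) egfp <- egfp + imaging$background_counts

  ## --- noise ----------------------------------------------------------
  series_len <- length_um
  if (imaging$noise) {
    set.seed(as.integer(seed) + 2L)
    sytox <- matrix(stats::rpois(length(sytox), sytox), n_lines, n_px)
    if (!is.null(egfp)) {
      egfp <- matrix(stats::rpois(length(egfp), egfp), n_lines, n_px)
    }
    series_len <- length_um + stats::rnorm(n_lines, 0, imaging$length_noise_um)
  }

  channels <- list(sytox = sytox)
  if (!is.null(egfp)) channels$egfp <- egfp
  truth <- tibble(
    event_id = seq_len(n_ev),
    nick_bp = nicks,
    threshold_force_pN = vapply(ev, `[[`, numeric(1), "thr"),
    initiated = vapply(ev, `[[`, logical(1), "initiated"),
    t_init_s = vapply(ev, `[[`, numeric(1), "t_init"),
    class = vapply(ev, `[[`, character(1), "class"),
    v_left_bps = vapply(ev, `[[`, numeric(1), "v_l"),
    v_right_bps = vapply(ev, `[[`, numeric(1), "v_r"),
    bp_unwound_final = if (n_ev) W[n_lines, ] else numeric(0),
    stop_left = stop_l, stop_right = stop_r,
    cont_left = cont_l, cont_right = cont_r)

  structure(list(
    kymo = kymograph(channels, px, lt),
    series = tibble(time_s = t_lines, force_pN = f_lines,
                    length_um = series_len),
    truth = truth,
    template = template, condition = condition, imaging = imaging,
    schedule = schedule, seed = as.integer(seed),
    uni_direction = uni_direction, switch_spec = switch_spec,
    ss = ss, ds = ds, offset_um = offset_um,
    ideal_length_um = length_um),
    class = "sm_trace")
}

#' @export
print.sm_trace <- function(x, ...) {
  cat("<sm_trace>", x$template$label, "-", nrow(x$truth), "event(s),",
      nrow(x$series), "lines, seed", x$seed, "\n")
  invisible(x)
}

#' Re-simulate a trace with a buffer-channel switch
#'
#' Reproduces `trace` exactly up to `t_switch_s` (same seed and substreams),
#' after which each active fork independently continues at its velocity with
#' probability `new_condition$p_continue` or rewinds toward its nick at
#' `new_condition$rewind_rate_bps` until the dark region closes and the
#' tether length returns to its pre-event value — the signature of strand
#' reannealing after protein removal.
#'
#' @param trace an [simulate_trace()] result.
#' @param new_condition a [sim_condition()] supplying `p_continue` and
#'   `rewind_rate_bps` for the post-switch buffer.
#' @param t_switch_s switch time, within the trace duration.
#' @param extend_s extra imaging time appended after the original duration.
#' @return a new `sm_trace` covering the full (possibly extended) duration.
#' @export
simulate_channel_switch <- function(trace, new_condition, t_switch_s,
                                    extend_s = 0) {
  dur <- nrow(trace$series) * trace$imaging$line_time_s
  if (t_switch_s <= 0 || t_switch_s >= dur + extend_s) {
    abort("t_switch_s must fall inside the (extended) trace duration")
  }
  imaging <- trace$imaging
  imaging$duration_s <- imaging$duration_s + extend_s
  sched <- trace$schedule
  if (extend_s > 0) sched$t_end_s[nrow(sched)] <- sched$t_end_s[nrow(sched)] + extend_s
  simulate_trace(trace$template, trace$condition, imaging, sched,
                 seed = trace$seed, uni_direction = trace$uni_direction,
                 switch_spec = list(t_switch_s = t_switch_s,
                                    p_continue = new_condition$p_continue,
                                    rewind_rate_bps = new_condition$rewind_rate_bps),
                 ss = trace$ss, ds = trace$ds)
}

#' Heatmap of a kymograph channel
#'
#' @param object a [kymograph()].
#' @param channel channel name.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot kymograph
#' @export
autoplot.kymograph <- function(object, channel = names(object$channels)[1], ...) {
  m <- object$channels[[channel]]
  df <- expand.grid(line = seq_len(nrow(m)), px = seq_len(ncol(m)))
  df$intensity <- as.vector(m)
  df$time_s <- (df$line - 1) * object$line_time_s
  df$position_um <- (df$px - 0.5) * object$pixel_size_um
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position_um, y = .data$time_s,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Position (µm)", y = "Time (s)", fill = "Counts",
                  title = paste("Kymograph:", channel))
}
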