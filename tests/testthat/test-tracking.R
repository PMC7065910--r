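make_kymo <- function(mat, px = 0.1, lt = 0.1) {
  kymograph(list(sytox = mat), px, lt)
}

test_that("segmentation finds exactly the below-threshold runs", {
  m <- matrix(50, nrow = 3, ncol = 40)
  m[2, 16:20] <- 0            # one 5-px dark run
  m[3, c(12:14, 25:30)] <- 0  # two runs
  kym <- make_kymo(m)
  seg <- segment_dark_regions(kym, threshold = 25)
  expect_equal(sum(seg$line == 1), 0)   # uniformly bright line: no intervals
  s2 <- seg[seg$line == 2, ]
  expect_equal(nrow(s2), 1)
  expect_equal(s2$end_px - s2$start_px + 1L, 5L)
  expect_equal(nrow(seg[seg$line == 3, ]), 2)
})

test_that("segmentation errors on empty input and respects the bead margin", {
  m <- matrix(50, nrow = 2, ncol = 40)
  expect_error(segment_dark_regions(make_kymo(m)), "no signal")
  m2 <- m
  m2[, 1:4] <- 0    # dark inside the default 5-px margin only
  seg <- segment_dark_regions(make_kymo(m2), threshold = 25)
  expect_equal(nrow(seg), 0)
})

test_that("median-relative segmentation is invariant to a constant offset", {
  set.seed(1)
  m <- matrix(rpois(40 * 200, 50), nrow = 40)
  m[, 60:90] <- matrix(rpois(40 * 31, 5), nrow = 40)
  a <- segment_dark_regions(make_kymo(m))
  b <- segment_dark_regions(make_kymo(m + 20))
  expect_equal(a$line, b$line)
  expect_equal(a$start_px, b$start_px)
  expect_equal(a$end_px, b$end_px)
})

test_that("a single growing region links into one event with one static and
           one moving edge", {
  tr <- polarity_trace(seed = 5, duration_s = 100, line_time_s = 0.2)
  seg <- segment_dark_regions(tr$kymo)
  ed <- link_events(seg, pixel_size_um = tr$kymo$pixel_size_um)
  expect_equal(dplyr::n_distinct(ed$event_id), 1)
  expect_lt(diff(range(ed$left_um)), 0.1)        # static edge: <1 px drift
  expect_gt(diff(range(ed$right_um)), 1)         # moving edge
  expect_true(all(ed$left_um <= ed$right_um))
  expect_true(all(diff(ed$time_s) > 0))
})

test_that("three well-separated events on lambda are recovered with edges
           within one pixel of truth", {
  cnd <- sim_condition(60, 0, initiation_force = c("30" = 1))
  tr <- simulate_trace(three_nick_template(), cnd, quick_imaging(40),
                       force_schedule(30, 40), seed = 11,
                       uni_direction = "right")
  seg <- segment_dark_regions(tr$kymo)
  ed <- link_events(seg, pixel_size_um = 0.1)
  expect_equal(dplyr::n_distinct(ed$event_id), 3)
  # truth: right edge of event at nick k sits at nick*x_ds + unw*x_ss (+ all
  # upstream unwound ssDNA excess), left edge fixed at nick*x_ds (+ same)
  px <- tr$kymo$pixel_size_um
  tru <- tr$truth
  for (k in unique(ed$event_id)) {
    dk <- ed[ed$event_id == k, ]
    mid <- dk[nrow(dk) %/% 2, ]
    t_mid <- mid$time_s
    unw <- pmax(t_mid - tru$t_init_s, 0) * tru$v_right_bps
    excess_before <- function(nick) {
      sum(unw[tru$nick_bp < nick]) * (XSS_30 - XDS_30) / 1000
    }
    i <- which.min(abs(tru$nick_bp * XDS_30 / 1000 +
                         tr$offset_um - dk$left_um[1]))
    left_true <- tru$nick_bp[i] * XDS_30 / 1000 + excess_before(tru$nick_bp[i]) +
      tr$offset_um
    right_true <- left_true + unw[i] * XSS_30 / 1000
    expect_lt(abs(mid$left_um - left_true), px)
    expect_lt(abs(mid$right_um - right_true), px)
  }
})

test_that("edge localisation under default noise stays within one pixel RMS", {
  tr <- polarity_trace(seed = 6, noise = TRUE, duration_s = 100,
                       line_time_s = 0.2)
  seg <- segment_dark_regions(tr$kymo)
  ed <- link_events(seg, pixel_size_um = 0.1)
  ed <- ed[ed$time_s > tr$truth$t_init_s + 5, ]
  unw <- pmin((ed$time_s - tr$truth$t_init_s) * tr$truth$v_right_bps, 4200)
  right_true <- tr$truth$nick_bp * XDS_30 / 1000 + unw * XSS_30 / 1000 +
    tr$offset_um
  rms <- sqrt(mean((ed$right_um - right_true)^2))
  expect_lt(rms, 0.1)
})

test_that("spot detection sees the coil-bound fluorophores", {
  # bidirectional event: two spots moving apart
  cnd_bi <- sim_condition(60, 0, velocity_bi_mean = 120, velocity_bi_sd = 0,
                          p_bidirectional = 1, spot_channel = TRUE,
                          initiation_force = c("30" = 1))
  tr <- simulate_trace(template_preset("nicked_6p4kbp"), cnd_bi,
                       imaging_params(duration_s = 40, line_time_s = 0.2,
                                      noise = FALSE),
                       force_schedule(30, 40), seed = 12)
  seg <- segment_dark_regions(tr$kymo)
  ed <- link_events(seg, pixel_size_um = 0.1)
  sp <- detect_spots(tr$kymo, events = ed)
  expect_gte(dplyr::n_distinct(sp$spot_id), 2)
  by_line <- split(sp$position_um, sp$line)
  seps <- vapply(by_line[lengths(by_line) >= 2], function(p) diff(range(p)),
                 numeric(1))
  expect_gt(seps[length(seps)], seps[1])  # diverging
  # unidirectional event: at least one spot, at the moving dark edge
  tr_u <- polarity_trace(seed = 13, duration_s = 60, line_time_s = 0.2)
  tr_u$condition$spot_channel <- TRUE
  tr_u <- simulate_trace(tr_u$template, tr_u$condition, tr_u$imaging,
                         tr_u$schedule, seed = 13, uni_direction = "right")
  ed_u <- link_events(segment_dark_regions(tr_u$kymo), pixel_size_um = 0.1)
  sp_u <- detect_spots(tr_u$kymo, events = ed_u)
  expect_gte(dplyr::n_distinct(sp_u$spot_id), 1)
  joined <- dplyr::inner_join(sp_u, ed_u, by = "line")
  expect_lt(stats::median(abs(joined$position_um - joined$right_um)), 0.2)
  # absent channel: empty result, no error
  expect_equal(nrow(detect_spots(tr$kymo, channel = "missing")), 0)
})
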