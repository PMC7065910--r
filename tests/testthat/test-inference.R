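test_that("classification separates one-sided from two-sided motion", {
  t <- seq(0, 30, 0.1)
  uni <- synthetic_edges(v_left = 0, v_right = 60, t = t)
  bi <- synthetic_edges(v_left = 55, v_right = 62, t = t, event_id = 2L)
  still <- synthetic_edges(v_left = 0, v_right = 0.5, t = t, event_id = 3L)
  cl <- classify_events(dplyr::bind_rows(uni, bi, still), force = 30)
  expect_equal(cl$class, c("unidirectional", "bidirectional", "ambiguous"))
  # left-moving fork: the lab-frame nick edge drifts outward, but the
  # duplex-frame correction must keep the classification unidirectional
  lm_uni <- synthetic_edges(v_left = 60, v_right = 0, t = t)
  expect_equal(classify_events(lm_uni, force = 30)$class, "unidirectional")
})

test_that("two diverging spots mark an event bidirectional even when one
           edge motion is below threshold", {
  t <- seq(0, 30, 0.1)
  ed <- synthetic_edges(v_left = 5, v_right = 110, t = t)
  expect_equal(classify_events(ed, force = 30)$class, "unidirectional")
  xss <- polymer_extension(ssdna_params(), 30)
  spots <- dplyr::bind_rows(
    tibble::tibble(spot_id = 1L, event_id = 1L, line = seq_along(t),
                   time_s = t, position_um = ed$left_um, intensity = 5 * t),
    tibble::tibble(spot_id = 2L, event_id = 1L, line = seq_along(t),
                   time_s = t, position_um = ed$right_um, intensity = 110 * t))
  expect_equal(classify_events(ed, spots, force = 30)$class, "bidirectional")
})

test_that("noiseless constructed tracks give rates exact to float precision", {
  t <- seq(0, 30, 0.1)
  ed <- synthetic_edges(v_left = 45, v_right = 72, t = t)
  r <- estimate_rates(ed, force = 30)
  expect_equal(r$rate_total_bps, 117, tolerance = 1e-9)
  expect_equal(r$rate_left_bps, 45, tolerance = 1e-9)
  expect_equal(r$rate_right_bps, 72, tolerance = 1e-9)
  expect_equal(r$r2, 1)
  expect_true(r$ratable)
  expect_equal(r$rate_total_bps, r$rate_left_bps + r$rate_right_bps,
               tolerance = 1e-9)
  # static side reports rate 0, not unratable
  ed_u <- synthetic_edges(v_left = 0, v_right = 60, t = t)
  r_u <- estimate_rates(ed_u, force = 30)
  expect_equal(r_u$rate_left_bps, 0, tolerance = 1e-9)
  expect_equal(r_u$rate_total_bps, 60, tolerance = 1e-9)
})

test_that("the linear region excludes the plateau after a fork stops", {
  t <- seq(0, 40, 0.1)
  xss <- polymer_extension(ssdna_params(), 30)
  # width grows at 100 bp/s for 20 s, then the fork stops
  w <- pmin(t, 20) * 100 * xss / 1000
  ed <- tibble::tibble(event_id = 1L, line = seq_along(t), time_s = t,
                       left_um = 1, right_um = 1 + w, width_um = w,
                       center_um = 1 + w / 2, dark_left_um = 0)
  r <- estimate_rates(ed, force = 30)
  expect_equal(r$rate_total_bps, 100, tolerance = 0.02)
})

test_that("two-phase growth is fit on its first, active phase", {
  t <- seq(0, 40, 0.1)
  xss <- polymer_extension(ssdna_params(), 30)
  set.seed(42)
  w <- (pmin(t, 18) * 110 + pmax(t - 18, 0) * 55) * xss / 1000 +
    rnorm(length(t), 0, 0.02)
  fit <- unwindr:::linear_region_fit(
    t[unwindr:::first_phase_idx(t, w)], w[unwindr:::first_phase_idx(t, w)],
    0.9, 0.5)
  expect_equal(fit$slope * 1000 / xss, 110, tolerance = 0.05)
})

test_that("required force reads the first initiating plateau and N.U. when
           nothing initiates", {
  sched <- force_schedule(c(10, 20, 30, 40), 60)
  ed <- tibble::tibble(event_id = 1L, line = 1L, time_s = 130,
                       left_um = 1, right_um = 1.3, width_um = 0.3,
                       center_um = 1.15, dark_left_um = 0)
  rf <- required_force(ed, sched)
  expect_equal(rf$required_force_pN, 30)
  expect_equal(rf$outcome, "unwound")
  rf_nu <- required_force(ed[0, ], sched)
  expect_true(is.na(rf_nu$required_force_pN))
  expect_equal(rf_nu$outcome, "N.U.")
})

test_that("recovered required-force histogram matches the configured
           initiation quantiles", {
  cnd <- sim_condition(80, 0, initiation_force = c("10" = 0.3, "20" = 0.6,
                                                   "30" = 0.9, "40" = 0.95),
                       events_per_molecule_mean = 1)
  sched <- force_schedule(c(10, 20, 30, 40), 30)
  tpl <- template_spec(LAMBDA_BP, 24000L)
  got <- character(0)
  for (s in 1:60) {
    tr <- simulate_trace(tpl, cnd, imaging_params(duration_s = 120,
                                                  line_time_s = 0.2,
                                                  noise = FALSE),
                         sched, seed = 500 + s)
    an <- suppressWarnings(analyze_trace(tr))
    got <- c(got, if (an$required_force$outcome == "N.U.") "NU"
             else as.character(an$required_force$required_force_pN))
  }
  counts <- table(factor(got, levels = c("10", "20", "30", "40", "NU")))
  probs <- c(0.3, 0.3, 0.3, 0.05, 0.05)
  # each bin within its binomial 95% interval
  for (i in seq_along(probs)) {
    ci <- binom.test(counts[[i]], length(got), p = probs[i])$conf.int
    expect_true(probs[i] >= ci[1] && probs[i] <= ci[2])
  }
})

test_that("rewinding is detected with its rate, continuation and stasis are
           not called rewound", {
  t <- seq(0, 30, 0.2)
  xss <- polymer_extension(ssdna_params(), 30)
  mk <- function(w) tibble::tibble(event_id = 1L, line = seq_along(t),
                                   time_s = t, left_um = 1, right_um = 1 + w,
                                   width_um = w, center_um = 1 + w / 2,
                                   dark_left_um = 0)
  series <- function(slope) tibble::tibble(
    time_s = t, force_pN = 30, length_um = 3 + slope * t)
  shrink <- mk(pmax(1.5 - 50 * xss / 1000 * t, 0))
  out <- detect_rewinding(shrink, series(-50 * 0.188 / 1000), 0, force = 30)
  expect_equal(out$status, "rewound")
  expect_equal(out$rewind_rate_bps, 50, tolerance = 0.1)
  grow <- mk(0.5 + 30 * xss / 1000 * t)
  expect_equal(detect_rewinding(grow, series(30 * 0.188 / 1000), 0, 30)$status,
               "continued")
  flat <- mk(rep(1.2, length(t)))
  st <- detect_rewinding(flat, series(0), 0, 30)$status
  expect_false(st %in% "rewound")
})

test_that("summary statistics match hand-computed values and ignore event
           order", {
  ev <- tibble::tibble(
    class = rep(c("bidirectional", "unidirectional"), each = 3),
    rate_total_bps = c(1, 2, 3, 2, 3, 4), ratable = TRUE)
  sm <- summarize_condition(ev, "toy")
  expect_equal(sm$t_statistic, -1.224745, tolerance = 1e-5)
  expect_equal(sm$p_value, 0.2878641, tolerance = 1e-5)
  expect_equal(sm$mean_bi_bps, 2)
  expect_equal(sm$sd_bi_bps, 1)
  expect_equal(sm$fraction_bidirectional, 0.5)
  expect_true(sm$fraction_bi_lo > 0 && sm$fraction_bi_hi < 1)
  sm_shuffled <- summarize_condition(ev[sample(6), ], "toy")
  expect_equal(sm_shuffled, sm)
  same <- tibble::tibble(class = "unidirectional",
                         rate_total_bps = c(60, 60, 60), ratable = TRUE)
  sm2 <- suppressMessages(summarize_condition(same, "flat"))
  expect_equal(sm2$mean_uni_bps, 60)
  expect_equal(sm2$sd_uni_bps, 0)
  expect_true(is.na(sm2$t_statistic))
})

test_that("Welch option changes the test degrees of freedom, not the point
           estimates", {
  ev <- tibble::tibble(
    class = rep(c("bidirectional", "unidirectional"), c(4, 8)),
    rate_total_bps = c(110, 120, 100, 140, 60, 70, 65, 80, 75, 62, 71, 68),
    ratable = TRUE)
  a <- summarize_condition(ev, "x")
  b <- summarize_condition(ev, "x", welch = TRUE)
  expect_equal(a$mean_bi_bps, b$mean_bi_bps)
  expect_false(isTRUE(all.equal(a$p_value, b$p_value)))
})
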