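test_that("identical seed and configuration give bit-identical output", {
  cnd <- sim_condition_preset("blm_alone_30pN")
  args <- list(template_preset("lambda_48502"), cnd,
               imaging_params(duration_s = 10), force_schedule(30, 10))
  a <- do.call(simulate_trace, c(args, seed = 7))
  b <- do.call(simulate_trace, c(args, seed = 7))
  expect_identical(a$kymo$channels, b$kymo$channels)
  expect_identical(a$series, b$series)
  expect_identical(a$truth, b$truth)
  c2 <- do.call(simulate_trace, c(args, seed = 8))
  expect_false(identical(a$kymo$channels, c2$kymo$channels))
})

test_that("a molecule with no events is flat", {
  cnd <- sim_condition(60, 9, events_per_molecule_mean = 0)
  tr <- simulate_trace(template_preset("lambda_48502"), cnd,
                       quick_imaging(10), force_schedule(30, 10), seed = 1)
  expect_equal(nrow(tr$truth), 0)
  expect_equal(diff(range(tr$series$length_um)), 0)
  seg <- segment_dark_regions(tr$kymo)
  expect_equal(nrow(seg), 0)
})

test_that("a noiseless 100 bp/s fork grows the dark region at ~52.8 nm/s and
           the tether at ~18.8 nm/s", {
  tr <- polarity_trace(seed = 2, v = 100, duration_s = 60, line_time_s = 0.1)
  # length series slope over the active stretch
  act <- tr$series$time_s > tr$truth$t_init_s + 1 &
    tr$series$time_s < tr$truth$t_init_s + 20
  len_slope <- coef(lm(length_um ~ time_s, tr$series[act, ]))[[2]]
  expect_equal(len_slope * 1000, 100 * CONV_30, tolerance = 1e-6)
  # dark-region width slope from segmentation of the rendered image, over
  # the stretch where the region is wide enough to be blur-free
  seg <- segment_dark_regions(tr$kymo)
  seg <- seg[seg$time_s > tr$truth$t_init_s + 8 &
               seg$time_s < tr$truth$t_init_s + 20, ]
  w_slope <- coef(lm(width_um ~ time_s, seg))[[2]]
  expect_equal(w_slope * 1000, 100 * XSS_30, tolerance = 0.02)
})

test_that("initiation follows the force-step schedule and high thresholds
           give the no-unwinding outcome", {
  cnd <- sim_condition(60, 9, initiation_force = c("30" = 1),
                       events_per_molecule_mean = 1)
  sched <- force_schedule(c(10, 20, 30, 40), 20)
  tpl <- template_spec(LAMBDA_BP, 24000L)
  tr <- simulate_trace(tpl, cnd, quick_imaging(80), sched, seed = 5)
  expect_true(tr$truth$initiated)
  expect_gte(tr$truth$t_init_s, 40)  # the 30 pN plateau starts at 40 s
  expect_lt(tr$truth$t_init_s, 60)
  # threshold above the maximum scheduled force: never initiates
  cnd_nu <- sim_condition(60, 9, initiation_force = c("50" = 1))
  tr_nu <- simulate_trace(tpl, cnd_nu, quick_imaging(80), sched, seed = 5)
  expect_false(tr_nu$truth$initiated)
  expect_equal(tr_nu$truth$bp_unwound_final, 0)
})

test_that("a channel switch with full continuation changes nothing", {
  base <- polarity_trace(seed = 4, duration_s = 80, line_time_s = 0.1)
  sw <- simulate_channel_switch(base,
                                sim_condition(60, 0, p_continue = 1,
                                              rewind_rate_bps = 50),
                                t_switch_s = 30)
  expect_identical(base$kymo$channels, sw$kymo$channels)
  expect_identical(base$series, sw$series)
})

test_that("forced rewinding closes every dark region and restores the length", {
  base <- polarity_trace(seed = 4, duration_s = 120, line_time_s = 0.2)
  sw <- simulate_channel_switch(base,
                                sim_condition(60, 0, p_continue = 0,
                                              rewind_rate_bps = 80),
                                t_switch_s = 40)
  n <- nrow(sw$series)
  expect_equal(sw$series$length_um[n], sw$series$length_um[1], tolerance = 1e-9)
  expect_equal(sw$truth$stop_left, "rewound")
  expect_equal(sw$truth$stop_right, "rewound")
  seg_last <- segment_dark_regions(sw$kymo)
  expect_equal(sum(seg_last$line > 0.95 * n), 0)
})

test_that("per-fork continuation fates follow the configured probability", {
  # many single-event molecules; pool the moving-fork fates
  tpl <- template_spec(6400, 3200L)
  cont <- logical(0)
  for (s in 1:60) {
    tr <- simulate_trace(tpl, sim_condition(200, 0, initiation_force = c("30" = 1)),
                         imaging_params(duration_s = 4, line_time_s = 0.2,
                                        noise = FALSE),
                         force_schedule(30, 4), seed = 100 + s,
                         uni_direction = "right",
                         switch_spec = list(t_switch_s = 2, p_continue = 0.75,
                                            rewind_rate_bps = 50))
    cont <- c(cont, tr$truth$cont_right)
  }
  ci <- binom.test(sum(cont), length(cont), p = 0.75)$conf.int
  expect_true(0.75 >= ci[1] && 0.75 <= ci[2])
})

test_that("photon counts are integers under noise and parameters are
           validated", {
  tr <- polarity_trace(seed = 9, noise = TRUE, duration_s = 10,
                       line_time_s = 0.2)
  expect_true(all(tr$kymo$channels$sytox == round(tr$kymo$channels$sytox)))
  expect_true(all(tr$kymo$channels$sytox >= 0))
  expect_warning(imaging_params(psf_sigma_um = 0.01), "undersamples")
  expect_error(imaging_params(pixel_size_um = -0.1), "positive")
  expect_error(sim_condition(60, -1), "sd")
  expect_error(sim_condition(60, 9, p_bidirectional = 1.2), "\\[0, 1\\]")
  expect_error(sim_condition(60, 9, initiation_force = c("20" = 0.9, "10" = 0.1)),
               "nondecreasing|named")
})
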