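# shared fixtures, built in code

# values pinned from an independent high-precision evaluation of the
# closed forms (kB = 0.01380649 pN nm/K, T = 298 K, default parameters)
XSS_30 <- 0.527879376686944   # nm/nt
XDS_30 <- 0.339596657811885   # nm/bp
CONV_30 <- 0.188282718875059  # nm/bp
CROSSOVER <- 6.03673776831208 # pN
LAMBDA_BP <- 48502L

quick_imaging <- function(duration_s = 30, noise = FALSE, ...) {
  imaging_params(duration_s = duration_s, noise = noise, ...)
}

# one clean unidirectional event on the 6.4 kbp polarity template
polarity_trace <- function(seed = 1, noise = FALSE, duration_s = 160,
                           line_time_s = 0.2, v = 60) {
  simulate_trace(template_preset("nicked_6p4kbp"),
                 sim_condition(v, 0, initiation_force = c("30" = 1)),
                 imaging_params(duration_s = duration_s,
                                line_time_s = line_time_s, noise = noise),
                 force_schedule(30, duration_s), seed = seed,
                 uni_direction = "right")
}

# lambda template with three well-separated fixed nicks
three_nick_template <- function() {
  template_spec(LAMBDA_BP, c(10000L, 25000L, 40000L), "lambda_3nicks")
}

# synthetic edge-track tibble for a single event in closed form (no image):
# a uni or bi event with exact fork rates, expressed in lab-frame um
synthetic_edges <- function(v_left = 0, v_right = 60, nick_bp = 2200,
                            force = 30, t = seq(0, 30, 0.1), event_id = 1L) {
  xss <- polymer_extension(ssdna_params(), force)
  xds <- polymer_extension(dsdna_params(), force)
  dl <- v_left * t  # bp unwound by each fork
  dr <- v_right * t
  left_um <- (nick_bp - dl) * xds / 1000
  right_um <- ((nick_bp - dl) * xds + (dl + dr) * xss) / 1000
  tibble::tibble(event_id = event_id, line = seq_along(t),
                 time_s = t, left_um = left_um, right_um = right_um,
                 width_um = right_um - left_um,
                 center_um = (left_um + right_um) / 2,
                 dark_left_um = 0)
}
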