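test_that("difference array and onset peaks follow their definitions", {
  expect_error(difference_array(ca_trace(c(1, 2), fps = 10)), NA)
  da <- difference_array(c(0, 0, 10, 10, 0))
  expect_equal(da$d, c(0, 10, 0, -10))
  expect_equal(da$peak_indices, 3L)  # frame at the top of the rise
  flat <- difference_array(c(5, 5, 5, 5, 5))
  expect_length(flat$peak_indices, 0)
  expect_match(flat$diagnostic, "no prominent peaks")
})

test_that("a 5-beat trace yields exactly 5 onsets at the upstroke frames", {
  spec <- std_spec(fps = 50)
  gen <- make_transient_trace(spec)
  onsets <- detect_onsets(gen$trace, std_config())
  expect_length(onsets, 5)
  expected_frames <- round(gen$truth$onset_times_ms / 1000 * 50) + 1
  expect_true(all(abs(as.integer(onsets) - expected_frames) <= 2))
})

test_that("onset decimation is identity at or below the target rate", {
  tr <- make_transient_trace(std_spec(fps = 50))$trace
  ds <- downsample_for_onsets(tr, 100)
  expect_equal(ds$values, tr$values)
  expect_equal(attr(ds, "factor"), 1L)
})

test_that("high-rate onsets come from the decimated path, mapped to native frames", {
  spec <- std_spec(fps = 1000)
  gen <- make_transient_trace(spec)
  onsets <- detect_onsets(gen$trace, std_config())
  expect_length(onsets, 5)
  t_on <- (as.integer(onsets) - 1)  # ms at 1000 FPS
  expect_true(all(abs(t_on - gen$truth$onset_times_ms) <= 10 + 5))
})

test_that("decimation finds at least as many true onsets on noisy high-rate data", {
  spec <- std_spec(fps = 1000)
  gen <- make_transient_trace(spec)
  truth_ms <- gen$truth$onset_times_ms
  hits <- function(onset_frames) {
    sum(vapply(truth_ms, function(tm)
      any(abs((onset_frames - 1) - tm) < 100), logical(1)))
  }
  hit_ds <- 0; hit_native <- 0
  for (s in 1:5) {
    noisy <- add_noise(gen$trace, target_snr = 15, seed = s)
    hit_ds <- hit_ds + hits(as.integer(detect_onsets(noisy, std_config())))
    native <- difference_array(noisy)$peak_indices
    hit_native <- hit_native + hits(native)
  }
  expect_gte(hit_ds, hit_native)
  expect_equal(hit_ds, 25)  # every true onset found via decimation
})

test_that("segmentation offsets are 10% of the cycle and clamp at the start", {
  cfg <- std_config()
  # 1 Hz at 50 FPS: offset is 5 frames, i.e. 100 ms
  tr <- make_transient_trace(std_spec(fps = 50))$trace
  segs <- segment_transients(tr, c(10L, 60L), cfg)
  expect_equal(segs[[1]]$start_frame, 10L - 5L)
  expect_length(segs, 2)
  expect_equal(segs[[1]]$end_frame, 60L - 5L - 1L)
  # two onsets 1 s apart give one complete ~1 s first segment
  expect_equal(segs[[1]]$end_frame - segs[[1]]$start_frame + 1L, 50L)
  # onset too close to the start clamps to frame 1 with a flag
  segs2 <- segment_transients(tr, c(2L, 60L), cfg)
  expect_equal(segs2[[1]]$start_frame, 1L)
  expect_true(segs2[[1]]$clamped)
  expect_error(segment_transients(tr, integer(0), cfg), "no onsets")
})

test_that("averaging truncates to the shortest segment and tracks SD", {
  seg <- function(v, b) structure(list(values = v, start_frame = 1L,
                                       end_frame = length(v), beat_index = b,
                                       onset_frame = 1L, clamped = FALSE),
                                  class = "ca_segment")
  same <- average_transient(list(seg(c(1, 5, 2), 1), seg(c(1, 5, 2), 2)))
  expect_equal(same$values, c(1, 5, 2))
  expect_equal(same$per_beat_sd, c(0, 0, 0))
  two <- average_transient(list(seg(c(0, 2, 0), 1), seg(c(0, 4, 0), 2)))
  expect_equal(two$values, c(0, 3, 0))
  expect_equal(two$per_beat_sd, c(0, sqrt(2), 0))
  tr <- average_transient(list(seg(c(0, 2, 0, 1), 1), seg(c(0, 4, 0), 2)))
  expect_length(tr$values, 3)
})

test_that("averaging noisy beats beats any single beat against the template", {
  gen <- make_transient_trace(std_spec())
  clean_fit <- ca_analyze(gen$trace, std_config())
  template <- clean_fit$avg$values
  noisy <- add_noise(gen$trace, target_snr = 15, seed = 3)
  fit <- ca_analyze(noisy, std_config())
  n <- min(length(template), length(fit$avg$values)) - 2
  # best-shift RMSE so one-frame onset jitter does not mask the noise level
  rmse <- function(v) min(vapply(-2:2, function(sh) {
    idx <- seq_len(n) + max(sh, 0)
    tdx <- seq_len(n) + max(-sh, 0)
    if (max(idx) > length(v)) return(Inf)
    sqrt(mean((v[idx] - template[tdx])^2))
  }, numeric(1)))
  avg_rmse <- rmse(fit$avg$values)
  seg_rmses <- vapply(fit$segments, function(s) {
    if (length(s$values) < n + 2) return(Inf)
    rmse(s$values)
  }, numeric(1))
  expect_lt(avg_rmse, min(seg_rmses))
})

test_that("a symmetric triangular transient yields symmetric parameters", {
  # baseline 100, peak 200, 500 ms rise + 500 ms fall at 1 Hz, 100 FPS;
  # starts at its baseline so the terminal window is flat
  v <- c(rep(100, 50), seq(100, 200, length.out = 51)[-1],
         seq(200, 100, length.out = 51)[-1], rep(100, 49))
  avg <- structure(list(values = v, per_beat_sd = rep(0, length(v)),
                        n_beats = 1L), class = "ca_avg")
  p <- compute_parameters(avg, std_config(), 100)
  expect_equal(p$fmax_over_f0, 2.0, tolerance = 1e-6)
  expect_equal(p$t50_on, p$t50_off, tolerance = 1)
  expect_equal(p$t10_on + p$t90_off, p$t90_on + p$t10_off, tolerance = 2)
})

test_that("flat traces produce a flagged record, never an exception", {
  avg <- structure(list(values = rep(7, 100), per_beat_sd = rep(0, 100),
                        n_beats = 1L), class = "ca_avg")
  p <- compute_parameters(avg, std_config(), 100)
  expect_true("zero_magnitude" %in% p$flags)
  expect_true(is.na(p$t50_on))
  fit <- ca_analyze(ca_trace(rep(3, 500), fps = 100), std_config())
  expect_true(length(fit$flags) > 0)
  expect_true(is.na(fit$params$tau))
})

test_that("interpolated timing parameters match the dense-grid oracle", {
  spec <- std_spec()
  gen <- make_transient_trace(spec)
  fit <- ca_analyze(gen$trace, std_config())
  orc <- oracle_parameters(spec)
  tol <- 1000 / spec$fps + 1  # one frame plus one millisecond
  expect_lt(abs(fit$params$t50_on - orc$t50_on), tol)
  expect_lt(abs(fit$params$t50_off - orc$t50_off), tol)
  expect_lt(abs(fit$params$t90_on - orc$t90_on), tol)
  expect_lt(abs(fit$params$t10_off - orc$t10_off), tol)
  expect_lt(abs(fit$params$cd - orc$cd), 2 * tol)
  expect_lt(abs(fit$params$fmax_over_f0 - orc$fmax_over_f0), 0.02)
})

test_that("crossing interpolation equals brute-force dense-grid interpolation", {
  gen <- make_transient_trace(std_spec())
  fit <- ca_analyze(gen$trace, std_config())
  v <- fit$used_avg$values
  ip <- which.max(v)
  p <- fit$params
  m2 <- p$fmax - p$redefined_baseline
  for (frac in c(0, 0.1, 0.5, 0.9)) {
    thr <- p$redefined_baseline + frac * m2
    ours <- calcitrace:::first_rise_crossing(v, ip, thr)
    ours_ms <- (as.numeric(ours) - 1) * 10
    brute_ms <- brute_rise_crossing_ms(v, ip, thr, 100)
    expect_lt(abs(ours_ms - brute_ms), 1e-6)
  }
})

test_that("timing parameters are ordered on both limbs", {
  for (s in 1:5) {
    spec <- std_spec(tau_off = c(150, 200, 300, 400, 250)[s], seed = s)
    tr <- add_noise(make_transient_trace(spec)$trace, target_snr = 30, seed = s)
    p <- ca_analyze(tr, std_config())$params
    if ("zero_magnitude" %in% p$flags) next
    expect_true(p$t10_on <= p$t50_on)
    expect_true(p$t50_on <= p$t90_on)
    expect_true(p$t90_on <= p$t_on)
    expect_true(p$t10_off <= p$t50_off)
    expect_true(p$t50_off <= p$t90_off)
    if (!is.na(p$t_off)) expect_true(p$t90_off <= p$t_off)
  }
})

test_that("baseline redefinition changes noiseless parameters by under 5%", {
  gen <- make_transient_trace(std_spec())
  with3 <- ca_analyze(gen$trace, std_config())
  with0 <- ca_analyze(gen$trace,
                      std_config(baseline_redefine_fraction = 1e-9))
  for (f in c("t50_on", "t50_off", "t90_on", "tau")) {
    expect_lt(abs(with3$params[[f]] / with0$params[[f]] - 1), 0.05, label = f)
  }
})

test_that("tau fitting recovers a pure exponential decay exactly", {
  t_ms <- seq(0, 900, by = 10)
  y <- 80 * exp(-t_ms / 300) + 100
  avg <- structure(list(values = y, per_beat_sd = rep(0, length(y)),
                        n_beats = 1L), class = "ca_avg")
  params <- list(t50_off = 300 * log(2), redefined_baseline = 100, fmax = 180)
  tf <- fit_tau(avg, params, 100)
  expect_lt(abs(tf$tau / 300 - 1), 0.01)
  expect_gt(tf$gof, 0.999)
  expect_null(tf$flag)
})

test_that("model mismatch on the decay arm is flagged", {
  y <- seq(200, 100, length.out = 90)  # linear decay
  avg <- structure(list(values = c(100, 150, y),
                        per_beat_sd = rep(0, 92), n_beats = 1L),
                   class = "ca_avg")
  tf <- fit_tau(avg, list(t50_off = 400, redefined_baseline = 100,
                          fmax = 200), 100)
  expect_false(is.null(tf$flag))
  short <- structure(list(values = c(1, 5, 3), per_beat_sd = rep(0, 3),
                          n_beats = 1L), class = "ca_avg")
  expect_equal(fit_tau(short, list(), 100)$flag, "decay_arm_too_short")
})

test_that("tau stays within 10% of truth under noise across 100 seeds", {
  t_ms <- seq(0, 900, by = 10)
  clean <- 80 * exp(-t_ms / 300) + 100
  params <- list(t50_off = 300 * log(2), redefined_baseline = 100,
                 fmax = 180)
  taus <- vapply(1:100, function(s) {
    set.seed(s)
    y <- clean + rnorm(length(clean), sd = 80 / 20)  # signal-to-noise ~20
    avg <- structure(list(values = y, per_beat_sd = rep(0, length(y)),
                          n_beats = 1L), class = "ca_avg")
    fit_tau(avg, params, 100)$tau
  }, numeric(1))
  expect_lt(abs(mean(taus) / 300 - 1), 0.10)
  expect_gte(mean(abs(taus / 300 - 1) < 0.10), 0.9)
})

test_that("the full per-cell pipeline produces a complete record", {
  gen <- make_transient_trace(std_spec())
  fit <- ca_analyze(gen$trace, std_config())
  expect_s3_class(fit, "ca_fit")
  expect_equal(fit$params$n_beats, 5)
  expect_false(is_flagged(fit))
  co <- coef(fit)
  expect_true(all(c("tau", "t50_on", "fmax_over_f0", "snr") %in% names(co)))
  expect_gt(fit$params$beat_to_beat_ms, 0)
  expect_equal(fit$params$n_intervals, 4)
})

test_that("manual onset markers bypass difference-array detection", {
  gen <- make_transient_trace(std_spec())
  auto <- ca_analyze(gen$trace, std_config())
  manual <- ca_analyze(gen$trace, std_config(), onsets = auto$onsets)
  expect_equal(coef(manual), coef(auto), tolerance = 1e-12)
  shifted <- ca_analyze(gen$trace, std_config(), onsets = auto$onsets + 1L)
  expect_false(is_flagged(shifted))
})

test_that("per-beat mode reports every beat plus across-beat SD", {
  gen <- make_transient_trace(std_spec())
  fit <- ca_analyze(gen$trace, std_config(per_beat_output = TRUE))
  expect_length(fit$per_beat$params, 5)
  expect_true(all(is.finite(fit$per_beat$sd[c("tau", "t50_off")])))
  # identical steady-state beats: across-beat SD is tiny
  expect_lt(fit$per_beat$sd[["t50_off"]], 2)
})

test_that("fit methods expose residuals, fitted decay and simulation", {
  fit <- ca_analyze(make_transient_trace(std_spec())$trace, std_config())
  f <- fitted(fit)
  r <- residuals(fit)
  expect_equal(length(f), length(r))
  expect_lt(sqrt(mean(r^2)), 1)
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "ca_trace")
  expect_output(print(fit), "Calcium transient analysis")
  expect_output(print(summary(fit)), "beat")
})
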