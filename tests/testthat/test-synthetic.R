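test_that("generators are deterministic under a seed", {
  a <- make_transient_trace(std_spec())
  b <- make_transient_trace(std_spec())
  expect_identical(a$trace$values, b$trace$values)
  n1 <- add_noise(a$trace, target_snr = 20, seed = 5)
  n2 <- add_noise(b$trace, target_snr = 20, seed = 5)
  expect_identical(n1$values, n2$values)
  s1 <- make_random_field(n_rod = 3, n_dead = 1, seed = 9)
  s2 <- make_random_field(n_rod = 3, n_dead = 1, seed = 9)
  expect_identical(s1$stack$frames, s2$stack$frames)
  expect_identical(s1$truth$label_image, s2$truth$label_image)
})

test_that("trace shape matches its specification", {
  gen <- make_transient_trace(std_spec(fps = 1000))
  expect_length(gen$trace$values, 5000)
  expect_length(gen$truth$onset_times_ms, 5)
  expect_equal(diff(gen$truth$onset_times_ms), rep(1000, 4))
  # peak follows onset by the closed-form time to peak
  tp <- 30 * log(1 + 300 / 30)
  expect_equal(gen$truth$peak_times_ms - gen$truth$onset_times_ms,
               rep(tp, 5))
  expect_equal(gen$truth$tau, 300)
})

test_that("sampling commutes: decimating 1000 FPS equals direct 25 FPS", {
  hi <- make_transient_trace(std_spec(fps = 1000))$trace
  lo <- make_transient_trace(std_spec(fps = 25))$trace
  shared <- hi$values[seq(1, length(hi$values), by = 40)]
  expect_equal(shared, lo$values, tolerance = 1e-9)
})

test_that("noise amplitude follows the terminal-300-ms SD convention", {
  gen <- make_transient_trace(std_spec())
  expect_identical(add_noise(gen$trace, noise_sd_multiple = 0)$values,
                   gen$trace$values)
  tail_sd <- sd(tail(gen$trace$values, 30))
  resid_sd <- vapply(1:10, function(s) {
    noisy <- add_noise(gen$trace, noise_sd_multiple = 2.5, seed = s)
    sd(noisy$values - gen$trace$values)
  }, numeric(1))
  expect_lt(abs(mean(resid_sd) / (2.5 * tail_sd) - 1), 0.1)
  short <- ca_trace(c(1, 2), fps = 2)
  expect_error(add_noise(short, noise_sd_multiple = 1), "300 ms")
})

test_that("injected drift reaches its configured depth", {
  gen <- make_transient_trace(std_spec())
  same <- add_drift(gen$trace, "linear", 0)
  expect_equal(same$trace$values, gen$trace$values)
  lin <- add_drift(gen$trace, "linear", 0.1, baseline = 100)
  # offset ramps linearly from 0 to -10% of the baseline
  expect_equal(lin$truth$offset[1], 0)
  expect_equal(tail(lin$truth$offset, 1), -10)
  expect_equal(lin$trace$values, gen$trace$values + lin$truth$offset)
  # last-beat baseline sits ~10% of baseline below the first
  first_b <- min(lin$trace$values[1:100])
  last_b <- min(tail(lin$trace$values, 100))
  expect_equal((first_b - last_b) / 100, 0.1, tolerance = 0.3)
  ex <- add_drift(gen$trace, "exponential", 0.3, baseline = 100)
  expect_equal(tail(ex$trace$values, 1) - tail(gen$trace$values, 1),
               -30, tolerance = 0.01)
  expect_error(add_drift(gen$trace, "linear", 0.9), "fraction")
})

test_that("irregularity injection validates class and phase", {
  gen <- make_transient_trace(std_spec(tau_off = 150))
  out <- inject_irregularity(gen$trace, data.frame(), gen$truth)
  expect_identical(out$trace$values, gen$trace$values)
  expect_error(inject_irregularity(gen$trace,
                                   data.frame(beat = 1, class = "XXX",
                                              phase = 0.5, amplitude = 0.1),
                                   gen$truth), "EAD or DAD")
  expect_error(inject_irregularity(gen$trace,
                                   data.frame(beat = 1, class = "EAD",
                                              phase = 1.5, amplitude = 0.1),
                                   gen$truth), "phase")
  # DAD demands a completed decay: impossible at tau 300 / 1 Hz
  slow <- make_transient_trace(std_spec(tau_off = 300))
  expect_error(inject_irregularity(slow$trace,
                                   data.frame(beat = 1, class = "DAD",
                                              phase = 0.5, amplitude = 0.1),
                                   slow$truth), "mismatch")
  # injection records the event in the truth
  ok <- inject_irregularity(gen$trace,
                            data.frame(beat = 2, class = "EAD", phase = 0.4,
                                       amplitude = 0.2), gen$truth)
  expect_length(ok$truth$events, 1)
  expect_gt(max(abs(ok$trace$values - gen$trace$values)), 15)
})

test_that("image stacks render live rods, dead circles and an empty field", {
  st <- make_random_field(n_rod = 1, seed = 30)
  m <- segment_cells(average_frame(st$stack), "multi", std_config())
  expect_equal(sum(m$props$accepted), 1)
  empty <- make_image_stack(list(), field = list(shape = c(48, 48)), seed = 1)
  me <- segment_cells(average_frame(empty$stack), "multi", std_config())
  expect_equal(sum(me$props$accepted), 0)
})

test_that("overlapping cells beyond the limit are recorded as warnings", {
  cells <- list(
    list(center = c(40, 40), axes = c(20, 7), angle = 0,
         spec = std_spec(fps = 25, n_beats = 2)),
    list(center = c(44, 44), axes = c(20, 7), angle = 10,
         spec = std_spec(fps = 25, n_beats = 2)))
  st <- make_image_stack(cells, field = list(shape = c(96, 96)),
                         fps = 25, seed = 3)
  expect_gt(length(st$truth$warnings), 0)
})

test_that("the oracle is built from independent grid arithmetic", {
  # closed-form single-beat crossings agree with the oracle when the oracle
  # is evaluated against the true baseline (no terminal-window redefinition)
  spec <- std_spec(tau_off = 120)  # decays fully within the cycle
  tr <- make_transient_trace(spec)
  orc <- oracle_parameters(spec)
  # T50 rise relative to the transient foot: closed form vs dense grid
  expect_equal(orc$t50_on, tr$truth$t50_on, tolerance = 2)
  expect_equal(orc$t50_off, tr$truth$t50_off, tolerance = 6)
})
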