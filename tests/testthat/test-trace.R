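make_tiny_stack <- function(frames_list, fps = 10) {
  arr <- array(0, dim = c(length(frames_list), nrow(frames_list[[1]]),
                          ncol(frames_list[[1]])))
  for (i in seq_along(frames_list)) arr[i, , ] <- frames_list[[i]]
  ca_stack(arr, fps = fps)
}

tiny_mask <- function(label_image) {
  ca_mask(label_image,
          data.frame(label = 1L, area_px = sum(label_image == 1),
                     eccentricity = 0.9, bbox_r0 = 1, bbox_c0 = 1,
                     bbox_r1 = nrow(label_image), bbox_c1 = ncol(label_image),
                     accepted = TRUE, rejection_reason = "",
                     stringsAsFactors = FALSE))
}

test_that("extract_trace sums the pixels of the labeled region per frame", {
  f1 <- matrix(0, 3, 3); f1[1, 1] <- 1; f1[1, 2] <- 2; f1[2, 1] <- 3
  f2 <- matrix(0, 3, 3); f2[1, 1] <- 2; f2[1, 2] <- 2; f2[2, 1] <- 2
  lab <- matrix(0L, 3, 3); lab[1, 1] <- 1L; lab[1, 2] <- 1L; lab[2, 1] <- 1L
  st <- make_tiny_stack(list(f1, f2))
  tr <- extract_trace(st, tiny_mask(lab), 1)
  expect_equal(tr$values, c(6, 6))
  zero <- make_tiny_stack(list(matrix(0, 3, 3), matrix(0, 3, 3)))
  expect_equal(extract_trace(zero, tiny_mask(lab), 1)$values, c(0, 0))
  expect_error(extract_trace(st, tiny_mask(lab), 5), "unknown cell")
})

test_that("extraction is linear in pixel intensity", {
  gen <- make_image_stack(
    list(list(center = c(30, 30), axes = c(16, 5), angle = 0,
              spec = std_spec(fps = 25, n_beats = 2))),
    field = list(shape = c(64, 64), noise_gain = 0), fps = 25, seed = 6)
  lab <- gen$truth$label_image
  mask <- tiny_mask(lab)
  tr1 <- extract_trace(gen$stack, mask, 1)
  scaled <- ca_stack(gen$stack$frames * 3.5, fps = 25)
  tr2 <- extract_trace(scaled, mask, 1)
  expect_equal(tr2$values, 3.5 * tr1$values)
})

test_that("trace maxima line up with generator peak times", {
  gen <- make_image_stack(
    list(list(center = c(30, 30), axes = c(16, 5), angle = 0,
              spec = std_spec(fps = 50, n_beats = 3))),
    field = list(shape = c(64, 64), noise_gain = 0), fps = 50, seed = 6)
  tr <- extract_trace(gen$stack, tiny_mask(gen$truth$label_image), 1)
  truth_peaks <- make_transient_trace(gen$truth$specs[[1]])$truth$peak_times_ms
  t_ms <- trace_times_ms(tr)
  for (pt in truth_peaks) {
    w <- which(t_ms >= pt - 500 & t_ms <= pt + 500)
    local_peak <- t_ms[w[which.max(tr$values[w])]]
    expect_lte(abs(local_peak - pt), 1000 / tr$fps + 1e-9)
  }
})

test_that("uniform background subtracts to the clean trace", {
  cell <- list(center = c(30, 30), axes = c(16, 5), angle = 0,
               spec = std_spec(fps = 25, n_beats = 2))
  clean <- make_image_stack(list(cell),
                            field = list(shape = c(64, 64), background = 0,
                                         noise_gain = 0), fps = 25, seed = 7)
  dirty <- make_image_stack(list(cell),
                            field = list(shape = c(64, 64), background = 5,
                                         noise_gain = 0), fps = 25, seed = 7)
  lab <- clean$truth$label_image
  mask <- segment_cells(average_frame(dirty$stack), "single", std_config())
  lab_id <- mask$props$label[mask$props$accepted][1]
  tr_clean_raw <- extract_trace(clean$stack, mask, lab_id)
  tr_dirty <- extract_trace(dirty$stack, mask, lab_id)
  sub <- subtract_background(tr_dirty, dirty$stack, mask)
  expect_true(sub$background_subtracted)
  expect_equal(sub$values, tr_clean_raw$values,
               tolerance = 1e-6)
  # zero background: identity
  sub0 <- subtract_background(tr_clean_raw, clean$stack, mask)
  expect_equal(sub0$values, tr_clean_raw$values, tolerance = 1e-9)
  # full-frame mask: no background pixels left
  full <- tiny_mask(matrix(1L, 64, 64))
  expect_error(subtract_background(tr_dirty, dirty$stack, full),
               "entire frame")
})

test_that("background subtraction commutes with extraction", {
  cell <- list(center = c(30, 30), axes = c(16, 5), angle = 0,
               spec = std_spec(fps = 25, n_beats = 2))
  gen <- make_image_stack(list(cell),
                          field = list(shape = c(64, 64), background = 8,
                                       noise_gain = 0), fps = 25, seed = 8)
  mask <- segment_cells(average_frame(gen$stack), "single", std_config())
  lab_id <- mask$props$label[mask$props$accepted][1]
  # route 1: extract then subtract the estimated background
  r1 <- subtract_background(extract_trace(gen$stack, mask, lab_id),
                            gen$stack, mask)
  # route 2: subtract the constant background image from frames, then extract
  st2 <- ca_stack(gen$stack$frames - 8, fps = gen$stack$fps)
  r2 <- extract_trace(st2, mask, lab_id)
  expect_equal(r1$values, r2$values, tolerance = 1e-6)
})

test_that("SNR follows its defining formula and degenerates gracefully", {
  b <- 100
  v <- c(rep(b + 10, 20), rnorm(200, b - 6, 2))
  v <- v[v != b]
  snr <- signal_to_noise(v, b)
  expect_equal(as.numeric(snr), 10 / sd(v[v < b]), tolerance = 1e-9)
  # noiseless square pulse: zero SD below baseline -> +Inf sentinel with flag
  sq <- c(rep(99, 50), rep(110, 10), rep(99, 50))
  s2 <- signal_to_noise(sq, 100)
  expect_identical(as.numeric(s2), Inf)
  expect_equal(attr(s2, "flag"), "degenerate_noise_floor")
  # low SNR flags
  s3 <- signal_to_noise(c(rnorm(100, 99, 3), rep(101, 10)), 100)
  expect_equal(attr(s3, "flag"), "low_snr")
})

test_that("generator snr mode hits its target within 25%", {
  tr <- make_transient_trace(std_spec())$trace
  for (target in c(15, 20)) {
    meas <- vapply(1:5, function(s) {
      noisy <- add_noise(tr, target_snr = target, seed = s)
      fit <- ca_analyze(noisy, std_config())
      fit$params$snr
    }, numeric(1))
    expect_lt(abs(mean(meas) / target - 1), 0.25)
  }
})
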