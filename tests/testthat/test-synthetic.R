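test_that("a sourceless scene is exactly zero with an empty peak list", {
  sc <- generate_peaks_image(c(5, 6), n_peaks = 0, background_sigma = 0, seed = 1)
  expect_true(all(sc$frame$values == 0))
  expect_equal(nrow(sc$peaks), 0)
})

test_that("scene generation is deterministic under seed", {
  a <- generate_peaks_image(c(16, 16), n_peaks = 5, seed = 9)
  b <- generate_peaks_image(c(16, 16), n_peaks = 5, seed = 9)
  expect_identical(a, b)
  expect_error(generate_peaks_image(c(2, 2), n_peaks = 5), class = "ssx_validation_error")
})

test_that("bright-pixel count matches an independent double-loop scan", {
  sc <- generate_peaks_image(c(24, 32), n_peaks = 6, amplitude = 100,
                             peak_sigma = 1.2, background_sigma = 0.2, seed = 13)
  brute <- 0L
  for (r in 1:24) for (c in 1:32)
    if (sc$frame$values[r, c] > 50) brute <- brute + 1L
  expect_equal(sum(sc$frame$values > 50), brute)
  expect_gt(brute, 0L)
})

test_that("zero signal encodes the pedestal at the highest gain", {
  tab <- flat_tables(c(2, 2), gains = c(40, 2, 0.5), pedestals = c(1000, 800, 700))
  raw <- encode_raw(energy_frame(matrix(0, 2, 2)), tab)
  expect_true(all(raw$words == 1000L)) # gain bits 0b00, value14 = 1000
  raw2 <- encode_raw(energy_frame(matrix(2.5, 2, 2)),
                     flat_tables(c(2, 2), pedestals = c(900, 800, 700)))
  expect_true(all(raw2$words == 1000L)) # 900 + 2.5 * 40
})

test_that("auto-ranging picks the level found by exhaustive trial of all three", {
  tab <- jittered_tables(c(6, 50))
  set.seed(31)
  # energies spanning all three regimes, incl. values overflowing level 0/1
  e <- matrix(10^runif(300, -1, 4.4), 6, 50)
  raw <- encode_raw(energy_frame(e), tab)
  lv <- ssxpipe:::decode_gain_level(raw$words)
  v14 <- ssxpipe:::decode_value14(raw$words)
  for (i in sample(300, 60)) {
    r <- (i - 1) %% 6 + 1; c <- (i - 1) %/% 6 + 1
    pick <- NA
    for (k in 1:3) { # exhaustive trial, lowest index that fits wins
      v <- sign(e[r, c] * tab$gain[r, c, k] + tab$pedestal[r, c, k]) *
        floor(abs(e[r, c] * tab$gain[r, c, k] + tab$pedestal[r, c, k]) + 0.5)
      if (v < 16384) { pick <- k - 1; break }
    }
    expect_identical(lv[r, c], as.integer(pick))
    vk <- e[r, c] * tab$gain[r, c, pick + 1] + tab$pedestal[r, c, pick + 1]
    expect_equal(v14[r, c], sign(vk) * floor(abs(vk) + 0.5))
  }
})

test_that("saturation errors by default and clamps under the clamp policy", {
  tab <- flat_tables(c(2, 2), gains = c(40, 2, 0.5), pedestals = c(1000, 800, 700))
  too_hot <- energy_frame(matrix(1e6, 2, 2))
  expect_error(encode_raw(too_hot, tab), class = "ssx_saturation_error")
  clamped <- encode_raw(too_hot, tab, saturation = "clamp")
  expect_true(all(clamped$words == 3L * 16384L + 16383L)) # level 2, full scale
  too_cold <- energy_frame(matrix(-500, 2, 2))
  expect_error(encode_raw(too_cold, tab), class = "ssx_saturation_error")
  expect_true(all(encode_raw(too_cold, tab, saturation = "clamp")$words == 0L))
})

test_that("encoder never emits the reserved bit pattern 0b10", {
  tab <- jittered_tables(c(8, 64))
  set.seed(17)
  e <- matrix(10^runif(512, -1, 4.4), 8, 64)
  raw <- encode_raw(energy_frame(e), tab)
  expect_false(any(raw$words %/% 16384L == 2L))
})

test_that("auto-ranging is monotone: raising energy never raises the gain", {
  tab <- jittered_tables(c(1, 1))
  energies <- sort(10^seq(-1, 4.3, length.out = 120))
  levels <- vapply(energies, function(e) {
    ssxpipe:::decode_gain_level(encode_raw(energy_frame(matrix(e, 1, 1)), tab)$words)[1, 1]
  }, integer(1))
  expect_true(all(diff(levels) >= 0))
})

test_that("dark frames carry level-0 bits and the exact pedestal at zero noise", {
  tab <- jittered_tables(c(4, 16))
  d0 <- generate_dark(tab, noise_sigma = 0, seed = 1)
  expect_true(all(ssxpipe:::decode_gain_level(d0$words) == 0L))
  expect_equal(ssxpipe:::decode_value14(d0$words),
               matrix(round(tab$pedestal[, , 1]), 4, 16))
})

test_that("dark sample mean tracks the pedestal within 5 sigma / sqrt(n)", {
  tab <- flat_tables(c(4, 8), pedestals = c(1000, 800, 700))
  n <- 200; sigma <- 4
  acc <- matrix(0, 4, 8)
  for (i in seq_len(n)) {
    d <- generate_dark(tab, noise_sigma = sigma, seed = 300 + i)
    acc <- acc + ssxpipe:::decode_value14(d$words)
  }
  expect_true(all(abs(acc / n - 1000) <= 5 * sigma / sqrt(n)))
})

test_that("sequences alternate dark/lit with increasing ids and lit ground truth", {
  tab <- jittered_tables(c(4, 1024))
  seqq <- make_sequence(2, tab, scene_params = list(n_peaks = 5), seed = 3)
  expect_equal(vapply(seqq$frames, `[[`, character(1), "role"),
               c("dark", "lit", "dark", "lit"))
  expect_equal(vapply(seqq$frames, `[[`, numeric(1), "frame_id"), c(0, 1, 2, 3))
  expect_setequal(names(seqq$ground_truth), c("1", "3"))
  expect_s3_class(seqq$ground_truth[["1"]]$frame, "energy_frame")
  expect_identical(seqq, make_sequence(2, tab, scene_params = list(n_peaks = 5), seed = 3))
})

test_that("encode/correct round trip is bounded by the quantization step", {
  tab <- jittered_tables(c(8, 128))
  sc <- generate_peaks_image(c(8, 128), n_peaks = 8, amplitude = 5000,
                             peak_sigma = 1, background_sigma = 0.3, seed = 21)
  raw <- encode_raw(sc$frame, tab)
  back <- correct_frame(raw, tab)
  lv <- ssxpipe:::decode_gain_level(raw$words)
  gain_at <- tab$gain[cbind(rep(1:8, 128), rep(1:128, each = 8), as.vector(lv) + 1L)]
  err <- abs(as.vector(back$values) - as.vector(sc$frame$values))
  expect_true(all(err <= 0.5 / gain_at + 1e-12))
})
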