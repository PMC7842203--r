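test_that("correction applies (value - pedestal) / gain per decoded level", {
  tab <- flat_tables(c(2, 2), gains = c(40, 2, 0.5), pedestals = c(900, 800, 700))
  raw <- raw_frame(matrix(1000L, 2, 2)) # bits 0b00, value 1000
  e <- correct_frame(raw, tab)
  expect_equal(e$values, matrix(2.5, 2, 2))
  # level 1 and level 2 words
  raw2 <- raw_frame(matrix(c(1L * 16384L + 1000L, 3L * 16384L + 1000L,
                             1000L, 1000L), 2, 2))
  e2 <- correct_frame(raw2, tab)
  expect_equal(e2$values[1, 1], (1000 - 800) / 2)
  expect_equal(e2$values[2, 1], (1000 - 700) / 0.5)
})

test_that("invalid gain bits 0b10 become NaN by default, error on request", {
  tab <- flat_tables(c(2, 2))
  raw <- raw_frame(matrix(c(2L * 16384L + 1000L, 1000L, 1000L, 1000L), 2, 2))
  e <- correct_frame(raw, tab)
  expect_true(is.nan(e$values[1, 1]))
  expect_false(anyNA(e$values[-1]))
  expect_error(correct_frame(raw, tab, invalid = "error"), class = "ssx_integrity_error")
  # NaN pixels neither count as peaks nor get stored in CSR
  expect_equal(count_peak_pixels(e, -1e9), 3L)
  expect_equal(csr_nnz(csr_compress(e, -1e9, capacity = 10)), 3)
})

test_that("vectorized correction agrees bitwise with the scalar oracle", {
  tab <- jittered_tables(c(8, 64))
  set.seed(41)
  words <- matrix(sample(0L:65535L, 512, replace = TRUE), 8, 64)
  raw <- raw_frame(words)
  vec <- correct_frame(raw, tab)
  sca <- correct_frame_scalar(raw, tab)
  expect_identical(vec$values, sca$energy$values)
  n_valid <- sum(words %/% 16384L != 2L)
  expect_equal(sca$n_subtractions, n_valid)
  expect_equal(sca$n_divisions, n_valid)
})

test_that("peak-pixel count matches a brute-force nested loop", {
  sc <- generate_peaks_image(c(20, 30), n_peaks = 5, amplitude = 80,
                             background_sigma = 1, seed = 2)
  for (thr in c(-1e9, 0, 40, 100)) {
    brute <- 0L
    for (r in 1:20) for (c in 1:30)
      if (sc$frame$values[r, c] > thr) brute <- brute + 1L
    expect_equal(count_peak_pixels(sc$frame, thr), brute)
  }
  expect_equal(count_peak_pixels(energy_frame(matrix(0, 3, 3)), 1), 0L)
  expect_equal(count_peak_pixels(sc$frame, -1e9), 600L)
})

test_that("veto thresholds behave monotonically", {
  sc <- generate_peaks_image(c(16, 48), n_peaks = 10, amplitude = 100,
                             background_sigma = 0.5, seed = 6)
  counts <- vapply(c(-10, 0, 10, 50, 90, 200),
                   function(t) count_peak_pixels(sc$frame, t), integer(1))
  expect_true(all(diff(counts) <= 0)) # count non-increasing in signal threshold
  # accepted set shrinks as min_peak_pixels grows
  accept <- vapply(c(0, 1, 5, 50, 1e5), function(m)
    veto(sc$frame, veto_config(50, m))$accept, logical(1))
  expect_true(all(diff(accept) <= 0))
  expect_true(accept[1]) # min 0 accepts vacuously
  z <- energy_frame(matrix(0, 4, 4))
  expect_equal(veto(z, veto_config(1, 1)), list(accept = FALSE, count = 0L))
})

test_that("veto decision equals the brute-force pipeline recomputation", {
  tab <- jittered_tables(c(16, 64))
  sc <- generate_peaks_image(c(16, 64), n_peaks = 10, amplitude = 100,
                             peak_sigma = 1, background_sigma = 0.2, seed = 19)
  e <- correct_frame(encode_raw(sc$frame, tab), tab)
  v <- veto(e, veto_config(50, 5))
  brute <- 0L
  for (r in 1:16) for (c in 1:64) if (e$values[r, c] > 50) brute <- brute + 1L
  expect_equal(v$count, brute)
  expect_equal(v$accept, brute >= 5)
})

test_that("CSR compression matches the worked dense example", {
  e <- energy_frame(matrix(c(0, 5, 0, 0,
                             0, 0, 0, 7,
                             0, 0, 0, 0), 3, 4, byrow = TRUE))
  csr <- csr_compress(e, 0, capacity = 10)
  expect_equal(csr$indptr, c(0, 1, 2, 2))
  expect_equal(csr$indices, c(1L, 3L))
  expect_equal(csr$data, c(5, 7))
  empty <- csr_compress(energy_frame(matrix(0, 3, 4)), 0, capacity = 10)
  expect_equal(empty$indptr, rep(0, 4))
  expect_length(empty$data, 0)
  expect_equal(csr_decompress(empty)$values, matrix(0, 3, 4))
})

test_that("CSR round trip equals direct thresholding on random frames", {
  set.seed(27)
  for (i in 1:5) {
    v <- matrix(rnorm(30 * 40), 30, 40)
    v[v < 1.2] <- 0 # sparsify
    e <- energy_frame(v)
    csr <- csr_compress(e, 0.5, capacity = 1200)
    direct <- v * (v > 0.5)
    expect_equal(csr_decompress(csr)$values, direct)
    expect_equal(csr_nnz(csr), sum(v > 0.5))
    # indices strictly increasing within each row
    r <- rep(1:30, diff(csr$indptr))
    expect_true(all(tapply(csr$indices, r, function(ix)
      length(ix) < 2 || all(diff(ix) > 0)), na.rm = TRUE))
  }
})

test_that("capacity overflow raises a dedicated error naming the requirement", {
  e <- energy_frame(matrix(1, 4, 4))
  err <- expect_error(csr_compress(e, 0, capacity = 3), class = "ssx_overflow_error")
  expect_match(conditionMessage(err), "required capacity 16")
  expect_silent(csr_compress(e, 0, capacity = 16))
})

test_that("compress then decompress is idempotent on its own output", {
  sc <- generate_peaks_image(c(12, 20), n_peaks = 4, amplitude = 50,
                             background_sigma = 0, seed = 4)
  csr <- csr_compress(sc$frame, 0.01, capacity = 240)
  again <- csr_compress(csr_decompress(csr), 0.01, capacity = 240)
  expect_equal(again$indptr, csr$indptr)
  expect_equal(again$indices, csr$indices)
  expect_equal(again$data, csr$data)
})
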