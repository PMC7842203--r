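# Synthetic diffraction scenes, raw-word encoding, and chopper-interleaved
# dark/lit acquisition sequences: the package's stand-in for a detector.

#' Generate a synthetic diffraction scene
#'
#' Renders a zero-mean Gaussian background plus `n_peaks` isotropic
#' Gaussian spots (stand-ins for Bragg peaks) of the given amplitude at
#' uniformly drawn sub-pixel centers. Deliberately simple: no lattice
#' geometry, no Poisson counting statistics, so quantization bounds on the
#' encode/correct round trip stay exact.
#'
#' @param shape `c(rows, cols)`.
#' @param n_peaks number of spots, `>= 0` and at most the pixel count.
#' @param amplitude peak amplitude in energy units, `> 0`.
#' @param peak_sigma isotropic spot width in pixels (`0` collapses a spot
#'   onto its nearest pixel).
#' @param background_sigma standard deviation of the Gaussian background.
#' @param seed integer seed.
#' @return a list with `frame` (an [energy_frame()]) and `peaks`, a
#'   data.frame of `row`, `col`, `amplitude`, `sigma` per spot.
#' @export
generate_peaks_image <- function(shape, n_peaks = 20, amplitude = 100,
                                 peak_sigma = 1.5, background_sigma = 0.1,
                                 seed = 1L) {
  ssx_validate(length(shape) == 2 && all(shape >= 1), "shape must be two positive integers")
  ssx_validate(n_peaks >= 0, "n_peaks must be non-negative")
  ssx_validate(amplitude > 0, "amplitude must be positive")
  ssx_validate(peak_sigma >= 0 && background_sigma >= 0, "sigmas must be non-negative")
  rows <- as.integer(shape[1]); cols <- as.integer(shape[2])
  if (n_peaks > rows * cols)
    ssx_error("n_peaks exceeds the pixel count", "ssx_validation_error")
  with_seed(seed, {
    values <- matrix(if (background_sigma > 0) rnorm(rows * cols, 0, background_sigma) else 0,
                     rows, cols)
    peaks <- data.frame(row = runif(n_peaks, 1, rows), col = runif(n_peaks, 1, cols),
                        amplitude = rep(amplitude, n_peaks),
                        sigma = rep(peak_sigma, n_peaks))
  })
  for (i in seq_len(n_peaks)) {
    r0 <- peaks$row[i]; c0 <- peaks$col[i]
    if (peak_sigma == 0) {
      values[round(r0), round(c0)] <- values[round(r0), round(c0)] + amplitude
      next
    }
    # render within a +-5 sigma window; beyond it the spot is < 4e-6 amplitude
    rr <- max(1L, floor(r0 - 5 * peak_sigma)):min(rows, ceiling(r0 + 5 * peak_sigma))
    cc <- max(1L, floor(c0 - 5 * peak_sigma)):min(cols, ceiling(c0 + 5 * peak_sigma))
    g <- amplitude * exp(-(outer((rr - r0)^2, (cc - c0)^2, "+")) / (2 * peak_sigma^2))
    values[rr, cc] <- values[rr, cc] + g
  }
  list(frame = energy_frame(values), peaks = peaks)
}

#' Encode an energy frame into 16-bit gain-tagged raw words
#'
#' Emulates the detector's automatic per-pixel gain switching: for each
#' pixel the chosen level `k` is the smallest (highest-gain) index whose
#' digitized value `round(energy * gain[k] + pedestal[k])` still fits below
#' `2^14`. The word is then `(bits(k) << 14) | value14` with the bit map
#' level 0 -> `0b00`, 1 -> `0b01`, 2 -> `0b11`. Rounding is half away from
#' zero. A pixel representable at no level (overflow at level 2, or a value
#' below 0 at level 0 from a strongly negative energy) is a saturation
#' error, or is clamped into range when `saturation = "clamp"`.
#'
#' @param energy an [energy_frame()].
#' @param tables matching [make_calibration()] tables.
#' @param saturation `"error"` (default) or `"clamp"`.
#' @return a [raw_frame()].
#' @export
encode_raw <- function(energy, tables, saturation = c("error", "clamp")) {
  saturation <- match.arg(saturation)
  ssx_validate(inherits(energy, "energy_frame"), "energy must be an energy_frame")
  validate_gain_tables(tables)
  if (!identical(energy$shape, tables$shape))
    ssx_error("energy shape does not match calibration shape", "ssx_validation_error")
  e <- energy$values
  level <- matrix(NA_integer_, nrow(e), ncol(e))
  value <- matrix(NA_real_, nrow(e), ncol(e))
  for (k in 1:3) {
    v <- round_half_away(e * tables$gain[, , k] + tables$pedestal[, , k])
    pick <- is.na(level) & v < GAIN_BITS_MAX
    level[pick] <- k - 1L
    value[pick] <- v[pick]
  }
  under <- !is.na(value) & value < 0
  over <- is.na(level)
  if (any(under) || any(over)) {
    if (saturation == "error")
      ssx_error(sprintf("%d pixel(s) unrepresentable at any gain level",
                        sum(under) + sum(over)), "ssx_saturation_error")
    value[under] <- 0
    level[over] <- 2L
    value[over] <- GAIN_BITS_MAX - 1
  }
  raw_frame(matrix(encode_word(as.vector(level), as.vector(value)), nrow(e), ncol(e)))
}

#' Generate a synthetic dark frame
#'
#' Per pixel, `value14 = clamp(round(pedestal[0] + N(0, noise_sigma)), 0,
#' 2^14 - 1)` with gain bits at level 0 -- what the detector reads out when
#' the chopper blocks the beam.
#'
#' @param tables calibration tables supplying the true pedestal.
#' @param noise_sigma readout noise standard deviation in ADU, `>= 0`.
#' @param seed integer seed.
#' @return a [raw_frame()] whose gain bits all decode to level 0.
#' @export
generate_dark <- function(tables, noise_sigma = 5, seed = 1L) {
  validate_gain_tables(tables)
  ssx_validate(noise_sigma >= 0, "noise_sigma must be non-negative")
  p0 <- tables$pedestal[, , 1]
  v <- with_seed(seed, round_half_away(p0 + if (noise_sigma > 0)
    rnorm(length(p0), 0, noise_sigma) else 0))
  v <- pmin(pmax(v, 0), GAIN_BITS_MAX - 1)
  raw_frame(matrix(encode_word(0L, as.vector(v)), nrow(p0), ncol(p0)))
}

#' Build a chopper-interleaved acquisition sequence
#'
#' Emulates the chopper's strict dark/lit alternation: `2 * n_pairs` frames
#' with roles `dark, lit, dark, lit, ...` and frame ids increasing from 0.
#' Each lit frame encodes a freshly generated diffraction scene; its
#' pre-encoding energy frame and peak list are retained as ground truth.
#'
#' @param n_pairs number of dark/lit pairs, `>= 1`.
#' @param tables calibration tables.
#' @param scene_params list of arguments for [generate_peaks_image()]
#'   (`n_peaks`, `amplitude`, `peak_sigma`, `background_sigma`).
#' @param dark_noise_sigma dark readout noise in ADU.
#' @param seed top-level seed, fanned out into per-frame substreams.
#' @return an object of class `acquisition_sequence`: `frames` is a list of
#'   `list(frame_id, role, raw)`, `ground_truth` a list keyed by the lit
#'   frame id holding `frame` and `peaks`.
#' @export
make_sequence <- function(n_pairs, tables, scene_params = list(),
                          dark_noise_sigma = 5, seed = 1L) {
  ssx_validate(n_pairs >= 1, "n_pairs must be at least 1")
  validate_gain_tables(tables)
  frames <- vector("list", 2L * n_pairs)
  truth <- list()
  for (i in seq_len(n_pairs)) {
    dark_id <- 2L * (i - 1L)
    lit_id <- dark_id + 1L
    dark <- generate_dark(tables, dark_noise_sigma,
                          seed = substream_seed(seed, paste0("dark", dark_id)))
    scene <- do.call(generate_peaks_image, c(
      list(shape = tables$shape, seed = substream_seed(seed, paste0("scene", lit_id))),
      scene_params))
    lit <- encode_raw(scene$frame, tables)
    frames[[dark_id + 1L]] <- list(frame_id = dark_id, role = "dark", raw = dark)
    frames[[lit_id + 1L]] <- list(frame_id = lit_id, role = "lit", raw = lit)
    truth[[as.character(lit_id)]] <- scene
  }
  structure(list(frames = frames, ground_truth = truth, shape = tables$shape),
            class = "acquisition_sequence")
}

#' @export
print.acquisition_sequence <- function(x, ...) {
  cat(sprintf("<acquisition_sequence>  %d frames (%d dark/lit pairs), %d x %d\n",
              length(x$frames), length(x$frames) %/% 2L, x$shape[1], x$shape[2]))
  invisible(x)
}
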