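# Frame containers: 16-bit raw frames and floating-point energy frames.

GAIN_BITS_MAX <- 16384L # 2^14: value14 lives in [0, 2^14)

# Two-bit gain codes. Level 0 (highest gain) -> 0b00, level 1 -> 0b01,
# level 2 -> 0b11. 0b10 is reserved/invalid and never produced.
GAIN_BIT_CODES <- c(0L, 1L, 3L)
# bits value (0..3) -> gain level (0..2), NA for the invalid pattern 0b10
GAIN_BIT_DECODE <- c(0L, 1L, NA_integer_, 2L)

#' Raw detector frame
#'
#' A frame of 16-bit raw pixel words as produced by an adaptive-gain
#' detector: the two most significant bits carry the gain level
#' (`0b00`, `0b01`, `0b11`; `0b10` is invalid), the remaining 14 bits the
#' digitized value in ADU.
#'
#' @param words integer matrix of 16-bit words, values in `[0, 65535]`.
#' @return an object of class `raw_frame` with fields `words` and `shape`.
#' @export
raw_frame <- function(words) {
  ssx_validate(is.matrix(words) && length(words) > 0, "words must be a non-empty matrix")
  words <- matrix(as.integer(words), nrow(words), ncol(words))
  ssx_validate(!anyNA(words) && all(words >= 0L) && all(words <= 65535L),
               "raw words must be integers in [0, 65535]")
  structure(list(words = words, shape = dim(words)), class = "raw_frame")
}

#' Corrected energy frame
#'
#' Per-pixel floating-point energies in arbitrary detector units (ADU,
#' gain-normalized), the output of pedestal/gain correction. `NaN` marks
#' pixels whose raw word carried the invalid gain-bit pattern.
#'
#' @param values numeric matrix.
#' @return an object of class `energy_frame` with fields `values` and `shape`.
#' @export
energy_frame <- function(values) {
  ssx_validate(is.matrix(values) && length(values) > 0, "values must be a non-empty matrix")
  storage.mode(values) <- "double"
  ssx_validate(!any(is.infinite(values)), "energy values must be finite or NaN")
  structure(list(values = values, shape = dim(values)), class = "energy_frame")
}

#' @export
print.raw_frame <- function(x, ...) {
  lv <- decode_gain_level(x$words)
  cat(sprintf("<raw_frame %d x %d>  gain levels: %s\n",
              x$shape[1], x$shape[2],
              paste(sprintf("L%d:%d", 0:2, tabulate(lv + 1L, 3L)), collapse = " ")))
  invisible(x)
}

#' @export
print.energy_frame <- function(x, ...) {
  v <- x$values[!is.nan(x$values)]
  cat(sprintf("<energy_frame %d x %d>  range [%.3g, %.3g], %d NaN\n",
              x$shape[1], x$shape[2],
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              sum(is.nan(x$values))))
  invisible(x)
}

# Split raw words into gain level (0..2, NA for 0b10) and 14-bit value.
decode_gain_level <- function(words) {
  out <- GAIN_BIT_DECODE[words %/% GAIN_BITS_MAX + 1L]
  dim(out) <- dim(words)
  out
}
decode_value14 <- function(words) words %% GAIN_BITS_MAX

encode_word <- function(level, value14) {
  GAIN_BIT_CODES[level + 1L] * GAIN_BITS_MAX + as.integer(value14)
}

# Row-major uint16 little-endian byte image of a raw frame (the wire order
# in which the packetizer slices it into datagram payloads).
frame_to_bytes <- function(frame) pack_uint(as.vector(t(frame$words)), 2L)

bytes_to_frame <- function(bytes, rows, cols) {
  ssx_validate(length(bytes) == rows * cols * 2,
               "byte length does not match frame geometry")
  raw_frame(matrix(as.integer(unpack_uint(bytes, 2L)), rows, cols, byrow = TRUE))
}
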