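# Compute kernels: raw-to-energy conversion, Bragg-pixel veto, and CSR
# compression -- each paired with a scalar brute-force twin used as an
# independent oracle in the tests.

#' Convert a raw frame to energies
#'
#' Per pixel: decode the gain level `k` from the two MSBs, then
#' `energy = (value14 - pedestal[k]) / gain[k]` -- one integer subtraction
#' and one floating-point division per pixel. Negative energies (noise
#' below pedestal) are legal and not clipped. Words carrying the invalid
#' bit pattern `0b10` become `NaN` by default (`invalid = "error"` raises
#' instead).
#'
#' @param raw a [raw_frame()].
#' @param tables matching [make_calibration()] tables.
#' @param invalid `"nan"` or `"error"`: handling of the `0b10` bit pattern.
#' @return an [energy_frame()].
#' @export
correct_frame <- function(raw, tables, invalid = c("nan", "error")) {
  invalid <- match.arg(invalid)
  ssx_validate(inherits(raw, "raw_frame"), "raw must be a raw_frame")
  validate_gain_tables(tables)
  if (!identical(raw$shape, tables$shape))
    ssx_error("raw frame shape does not match calibration shape", "ssx_validation_error")
  lv <- decode_gain_level(raw$words)
  if (anyNA(lv) && invalid == "error")
    ssx_error(sprintf("%d pixel(s) carry the invalid gain-bit pattern 0b10", sum(is.na(lv))),
              "ssx_integrity_error")
  v <- decode_value14(raw$words)
  rows <- raw$shape[1]; cols <- raw$shape[2]
  idx <- cbind(rep(seq_len(rows), cols), rep(seq_len(cols), each = rows), as.vector(lv) + 1L)
  e <- (as.vector(v) - tables$pedestal[idx]) / tables$gain[idx]
  e[is.na(as.vector(lv))] <- NaN
  energy_frame(matrix(e, rows, cols))
}

#' Scalar reference conversion with operation counters
#'
#' A deliberately scalar (one pixel at a time) re-implementation of
#' [correct_frame()] that counts every integer subtraction and every
#' floating-point division it performs: the instrument behind the
#' per-frame operation budget of the correction (a 4-megapixel frame costs
#' exactly 4 million subtractions and 4 million divisions). Also serves as
#' the bitwise oracle for the vectorized kernel.
#'
#' @inheritParams correct_frame
#' @return a list with `energy` (an [energy_frame()]), `n_subtractions`
#'   and `n_divisions`.
#' @export
correct_frame_scalar <- function(raw, tables) {
  ssx_validate(inherits(raw, "raw_frame"), "raw must be a raw_frame")
  validate_gain_tables(tables)
  if (!identical(raw$shape, tables$shape))
    ssx_error("raw frame shape does not match calibration shape", "ssx_validation_error")
  rows <- raw$shape[1]; cols <- raw$shape[2]
  npix <- rows * cols
  words <- as.vector(raw$words)          # column-major scan, one word at a time
  ped <- as.vector(tables$pedestal)      # level k at offset (k-1)*npix
  gain <- as.vector(tables$gain)
  decode <- GAIN_BIT_DECODE
  e <- numeric(npix)
  n_sub <- 0; n_div <- 0
  for (i in seq_len(npix)) {
    w <- words[i]
    bits <- w %/% 16384L
    k <- decode[bits + 1L]
    if (is.na(k)) {
      e[i] <- NaN
      next
    }
    v <- w - bits * 16384L
    o <- i + k * npix
    d <- v - ped[o];  n_sub <- n_sub + 1
    e[i] <- d / gain[o];  n_div <- n_div + 1
  }
  list(energy = energy_frame(matrix(e, rows, cols)),
       n_subtractions = n_sub, n_divisions = n_div)
}

#' Count Bragg-peak pixels
#'
#' The simplistic hit-finding statistic: the number of pixels whose energy
#' strictly exceeds `signal_threshold`, with no noise correction or outlier
#' removal. `NaN` pixels never count.
#'
#' @param energy an [energy_frame()].
#' @param signal_threshold finite threshold in corrected ADU.
#' @return integer count.
#' @export
count_peak_pixels <- function(energy, signal_threshold) {
  ssx_validate(inherits(energy, "energy_frame"), "energy must be an energy_frame")
  ssx_validate(is.finite(signal_threshold), "signal_threshold must be finite")
  sum(!is.nan(energy$values) & energy$values > signal_threshold)
}

#' Veto configuration
#'
#' Two thresholds govern frame rejection: `signal_threshold` is the energy
#' a pixel must exceed to count as a Bragg-peak pixel, `min_peak_pixels`
#' the minimum number of such pixels for the frame to be accepted. No
#' physically meaningful defaults exist; both must be chosen per
#' experiment.
#'
#' @param signal_threshold per-pixel energy threshold (corrected ADU).
#' @param min_peak_pixels minimum accepted count, `>= 0`.
#' @return an object of class `veto_config`.
#' @export
veto_config <- function(signal_threshold, min_peak_pixels) {
  ssx_validate(is.finite(signal_threshold), "signal_threshold must be finite")
  ssx_validate(min_peak_pixels >= 0, "min_peak_pixels must be non-negative")
  structure(list(signal_threshold = signal_threshold,
                 min_peak_pixels = as.numeric(min_peak_pixels)),
            class = "veto_config")
}

#' Accept or reject a frame by its Bragg-pixel count
#'
#' @param energy an [energy_frame()].
#' @param cfg a [veto_config()].
#' @return a list with `accept` (logical; `TRUE` iff the count is at least
#'   `min_peak_pixels`) and `count`.
#' @export
veto <- function(energy, cfg) {
  ssx_validate(inherits(cfg, "veto_config"), "cfg must be a veto_config")
  n <- count_peak_pixels(energy, cfg$signal_threshold)
  list(accept = n >= cfg$min_peak_pixels, count = n)
}

#' Compress an energy frame to CSR
#'
#' Stores exactly the pixels strictly above `sparsify_threshold` in
#' compressed sparse row form: `indptr` is the exclusive cumulative sum of
#' per-row retained counts (the prefix-scan construction), `indices` the
#' 0-based column indices, `data` the values, all in row-major order. The
#' storage capacity is fixed a priori from the expected sparsity; if the
#' frame retains more pixels than `capacity`, a dedicated overflow error
#' names the required capacity before anything is written. `NaN` pixels
#' are never stored.
#'
#' @param energy an [energy_frame()].
#' @param sparsify_threshold retain values strictly above this.
#' @param capacity maximum storable values; defaults to 2\% of the pixel
#'   count.
#' @return an object of class `csr_image` with fields `shape`, `indptr`
#'   (length `rows + 1`), `indices`, `data`, `capacity` and `threshold`.
#' @export
csr_compress <- function(energy, sparsify_threshold = 0,
                         capacity = ceiling(0.02 * prod(energy$shape))) {
  ssx_validate(inherits(energy, "energy_frame"), "energy must be an energy_frame")
  ssx_validate(capacity >= 0, "capacity must be non-negative")
  v <- energy$values
  mask <- !is.nan(v) & v > sparsify_threshold
  nnz <- sum(mask)
  if (nnz > capacity)
    ssx_error(sprintf("CSR capacity overflow: %d values retained, capacity %d (required capacity %d)",
                      nnz, as.integer(capacity), nnz), "ssx_overflow_error")
  row_counts <- rowSums(mask)
  tv <- t(v); tm <- t(mask)
  keep <- which(tm)                       # row-major positions
  structure(list(
    shape = energy$shape,
    indptr = c(0, cumsum(row_counts)),
    indices = as.integer((keep - 1L) %% energy$shape[2]),
    data = as.numeric(tv[keep]),
    capacity = as.numeric(capacity),
    threshold = sparsify_threshold
  ), class = "csr_image")
}

validate_csr <- function(csr) {
  ssx_validate(inherits(csr, "csr_image"), "not a csr_image")
  rows <- csr$shape[1]; cols <- csr$shape[2]
  ok <- length(csr$indptr) == rows + 1 &&
    csr$indptr[1] == 0 &&
    !is.unsorted(csr$indptr) &&
    csr$indptr[rows + 1] == length(csr$indices) &&
    length(csr$indices) == length(csr$data) &&
    length(csr$data) <= csr$capacity &&
    (length(csr$indices) == 0 || (min(csr$indices) >= 0 && max(csr$indices) < cols))
  if (ok && length(csr$indices) > 0) {
    r <- rep(seq_len(rows), diff(csr$indptr))
    ok <- all(tapply(csr$indices, factor(r, levels = seq_len(rows)),
                     function(ix) length(ix) < 2 || all(diff(ix) > 0)), na.rm = TRUE)
  }
  if (!ok) ssx_error("malformed CSR image: invariants violated", "ssx_structural_error")
  invisible(csr)
}

#' Decompress a CSR image to a dense energy frame
#'
#' @param csr a [csr_compress()] result.
#' @return an [energy_frame()] with stored values at stored positions and
#'   zeros elsewhere.
#' @export
csr_decompress <- function(csr) {
  validate_csr(csr)
  rows <- csr$shape[1]; cols <- csr$shape[2]
  dense <- matrix(0, rows, cols)
  if (length(csr$data) > 0) {
    r <- rep(seq_len(rows), diff(csr$indptr))
    dense[cbind(r, csr$indices + 1L)] <- csr$data
  }
  energy_frame(dense)
}

#' Number of stored values in a CSR image
#' @param csr a `csr_image`.
#' @return `indptr[rows]`, the stored-value count.
#' @export
csr_nnz <- function(csr) as.integer(csr$indptr[length(csr$indptr)])

#' @export
print.csr_image <- function(x, ...) {
  cat(sprintf("<csr_image %d x %d>  %d/%s values stored (> %.3g)\n",
              x$shape[1], x$shape[2], csr_nnz(x), format(x$capacity), x$threshold))
  invisible(x)
}
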