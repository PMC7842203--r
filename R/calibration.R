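# Per-pixel three-gain correction coefficients and dark-frame pedestal tracking.

#' Create per-pixel gain/pedestal correction tables
#'
#' An adaptive-gain detector needs, for every pixel, a pedestal offset and a
#' gain factor for each of its three gain levels: six correction
#' coefficients per pixel (24 million for a 4-megapixel sensor). This
#' constructor builds such tables from three per-level scalars, optionally
#' dispersed per pixel by multiplicative uniform jitter to mimic real
#' sensor-to-sensor variation.
#'
#' @param shape integer vector `c(rows, cols)`, both positive.
#' @param gain_levels three strictly decreasing positive gains (ADU per
#'   energy unit); level 0 is the highest gain.
#' @param pedestal_levels three pedestal offsets in `[0, 2^14)` ADU.
#' @param jitter_fraction half-width `j` of the multiplicative jitter
#'   `U(1-j, 1+j)` applied independently to every coefficient; in `[0, 0.5)`.
#' @param seed integer seed making the jitter reproducible.
#' @return an object of class `gain_tables` with fields `shape`, `pedestal`
#'   and `gain`, the latter two arrays of dimension `c(rows, cols, 3)`.
#' @examples
#' tab <- make_calibration(c(16, 16), jitter_fraction = 0)
#' n_coefficients(tab) # 16 * 16 * 6
#' @export
make_calibration <- function(shape,
                             gain_levels = c(40, 2, 0.5),
                             pedestal_levels = c(1000, 800, 700),
                             jitter_fraction = 0.05,
                             seed = 1L) {
  ssx_validate(length(shape) == 2 && all(shape >= 1), "shape must be two positive integers")
  ssx_validate(length(gain_levels) == 3 && all(gain_levels > 0),
               "gain_levels must be three positive values")
  ssx_validate(all(diff(gain_levels) < 0),
               "gain_levels must be strictly decreasing (level 0 = highest gain)")
  ssx_validate(length(pedestal_levels) == 3 &&
                 all(pedestal_levels >= 0 & pedestal_levels < GAIN_BITS_MAX),
               "pedestal_levels must lie in [0, 2^14)")
  ssx_validate(jitter_fraction >= 0 && jitter_fraction < 0.5,
               "jitter_fraction must lie in [0, 0.5)")
  rows <- as.integer(shape[1]); cols <- as.integer(shape[2])
  npix <- rows * cols
  ped <- array(0, c(rows, cols, 3))
  gn <- array(0, c(rows, cols, 3))
  with_seed(seed, {
    for (k in 1:3) {
      gn[, , k] <- gain_levels[k] * runif(npix, 1 - jitter_fraction, 1 + jitter_fraction)
      ped[, , k] <- pedestal_levels[k] * runif(npix, 1 - jitter_fraction, 1 + jitter_fraction)
    }
  })
  # jitter on a pedestal near the top of range could leave [0, 2^14)
  ped <- pmin(ped, GAIN_BITS_MAX - 1)
  out <- structure(list(shape = c(rows, cols), pedestal = ped, gain = gn),
                   class = "gain_tables")
  validate_gain_tables(out)
  out
}

validate_gain_tables <- function(tables) {
  ssx_validate(inherits(tables, "gain_tables"), "not a gain_tables object")
  ssx_validate(all(tables$gain > 0), "all gains must be positive")
  g <- matrix(tables$gain, ncol = 3)
  ssx_validate(all(g[, 1] > g[, 2]) && all(g[, 2] > g[, 3]),
               "per-pixel gain must be strictly decreasing across levels")
  ssx_validate(all(tables$pedestal >= 0 & tables$pedestal < GAIN_BITS_MAX),
               "pedestals must lie in [0, 2^14)")
  invisible(tables)
}

#' Number of stored correction coefficients
#'
#' `rows * cols * 3 levels * 2` (one pedestal and one gain per level).
#'
#' @param tables a [make_calibration()] result.
#' @return coefficient count as a double (may exceed `.Machine$integer.max`).
#' @export
n_coefficients <- function(tables) {
  as.numeric(length(tables$pedestal)) + as.numeric(length(tables$gain))
}

#' @export
print.gain_tables <- function(x, ...) {
  cat(sprintf("<gain_tables %d x %d>  %s coefficients\n", x$shape[1], x$shape[2],
              format(n_coefficients(x), big.mark = ",")))
  for (k in 1:3)
    cat(sprintf("  level %d: gain ~%.3g, pedestal ~%.4g ADU\n", k - 1,
                mean(x$gain[, , k]), mean(x$pedestal[, , k])))
  invisible(x)
}

#' Running pedestal estimator for the highest gain level
#'
#' Dark frames (chopper closed) are interleaved with lit frames and used to
#' keep the level-0 pedestal current during continuous operation. The
#' tracker absorbs dark frames one at a time; only pixels whose gain bits
#' decode to level 0 contribute (other pixels are skipped, since isolated
#' pixels may sit at another level even in a dark). Two update modes:
#' `running_mean` (exact per-pixel arithmetic mean of absorbed values) and
#' `ema` (exponential moving average with weight `alpha`, for drift
#' tracking during long runs).
#'
#' @param shape `c(rows, cols)`.
#' @param mode `"running_mean"` or `"ema"`.
#' @param alpha EMA weight in `(0, 1]`; ignored for `running_mean`.
#' @return an object of class `pedestal_tracker`.
#' @seealso [update_pedestal()], [freeze_pedestal()]
#' @export
pedestal_tracker <- function(shape, mode = c("running_mean", "ema"), alpha = 0.05) {
  mode <- match.arg(mode)
  ssx_validate(length(shape) == 2 && all(shape >= 1), "shape must be two positive integers")
  if (mode == "ema")
    ssx_validate(alpha > 0 && alpha <= 1, "alpha must lie in (0, 1]")
  rows <- as.integer(shape[1]); cols <- as.integer(shape[2])
  structure(list(
    shape = c(rows, cols),
    estimate = matrix(NA_real_, rows, cols),
    n_pixel = matrix(0L, rows, cols),
    count = 0L,
    mode = mode,
    alpha = alpha
  ), class = "pedestal_tracker")
}

#' Absorb one dark frame into the pedestal estimate
#'
#' @param tracker a [pedestal_tracker()].
#' @param dark a [raw_frame()] of matching shape acquired with the beam off.
#' @return the updated tracker.
#' @export
update_pedestal <- function(tracker, dark) {
  ssx_validate(inherits(tracker, "pedestal_tracker"), "tracker must be a pedestal_tracker")
  ssx_validate(inherits(dark, "raw_frame"), "dark must be a raw_frame")
  if (!identical(tracker$shape, dark$shape))
    ssx_error("dark frame shape does not match tracker shape", "ssx_validation_error")
  lv <- decode_gain_level(dark$words)
  v <- decode_value14(dark$words)
  absorb <- !is.na(lv) & lv == 0L
  if (any(absorb)) {
    x <- as.numeric(v[absorb])
    if (tracker$mode == "running_mean") {
      n <- tracker$n_pixel[absorb] + 1L
      est <- tracker$estimate[absorb]
      est[n == 1L] <- 0
      tracker$estimate[absorb] <- est + (x - est) / n
      tracker$n_pixel[absorb] <- n
    } else {
      first <- tracker$n_pixel[absorb] == 0L
      est <- tracker$estimate[absorb]
      est[first] <- x[first]
      est[!first] <- (1 - tracker$alpha) * est[!first] + tracker$alpha * x[!first]
      tracker$estimate[absorb] <- est
      tracker$n_pixel[absorb] <- tracker$n_pixel[absorb] + 1L
    }
  }
  tracker$count <- tracker$count + 1L
  tracker
}

#' Write the tracked pedestal into the calibration tables
#'
#' Replaces the level-0 pedestal with the tracker's estimate; the pedestals
#' of the two lower-gain levels are taken as constant and left untouched.
#' Pixels never absorbed (always off level 0 in the darks) keep their prior
#' table value.
#'
#' @param tracker a [pedestal_tracker()] that has absorbed at least one dark.
#' @param tables a `gain_tables` object.
#' @return `tables` with `pedestal[,,1]` updated.
#' @export
freeze_pedestal <- function(tracker, tables) {
  ssx_validate(inherits(tracker, "pedestal_tracker"), "tracker must be a pedestal_tracker")
  validate_gain_tables(tables)
  if (tracker$count < 1L)
    ssx_error("no dark frames absorbed: pedestal estimate undefined", "ssx_validation_error")
  if (!identical(tracker$shape, tables$shape))
    ssx_error("tracker shape does not match tables shape", "ssx_validation_error")
  seen <- tracker$n_pixel > 0L
  p0 <- tables$pedestal[, , 1]
  p0[seen] <- tracker$estimate[seen]
  tables$pedestal[, , 1] <- pmin(p0, GAIN_BITS_MAX - 1)
  tables
}

#' @export
print.pedestal_tracker <- function(x, ...) {
  cat(sprintf("<pedestal_tracker %d x %d>  mode %s, %d dark(s) absorbed\n",
              x$shape[1], x$shape[2], x$mode, x$count))
  invisible(x)
}
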