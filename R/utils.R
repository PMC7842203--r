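# Internal helpers: classed errors, seeded evaluation, rounding, byte packing.

ssx_error <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "ssx_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

ssx_validate <- function(ok, msg) {
  if (!isTRUE(ok)) ssx_error(msg, "ssx_validation_error")
  invisible(TRUE)
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so seeded generators never perturb user code.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Fan a top-level seed out into a named, replayable substream seed (< 2^31).
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  (as.numeric(seed) * 48271 + h) %% 2147483647
}

# Round half away from zero, the fixed quantization rule of the raw encoder.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# --- little-endian byte packing (values carried as doubles; exact < 2^53) ---

pack_uint <- function(x, nbytes) {
  x <- as.numeric(x)
  if (length(x) == 0) return(raw(0))
  out <- raw(length(x) * nbytes)
  for (b in seq_len(nbytes)) {
    out[seq(b, length(out), by = nbytes)] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

unpack_uint <- function(bytes, nbytes) {
  v <- as.numeric(bytes)
  if (length(v) == 0) return(numeric(0))
  n <- length(v) %/% nbytes
  out <- numeric(n)
  for (b in nbytes:1) {
    out <- out * 256 + v[seq(b, length(v), by = nbytes)]
  }
  out
}

pack_int32 <- function(x) pack_uint(ifelse(x < 0, x + 4294967296, x), 4L)

unpack_int32 <- function(bytes) {
  v <- unpack_uint(bytes, 4L)
  ifelse(v >= 2147483648, v - 4294967296, v)
}

# float32 via writeBin/readBin on a connection-free raw round trip
pack_float32 <- function(x) writeBin(as.numeric(x), raw(), size = 4L, endian = "little")

unpack_float32 <- function(bytes) readBin(bytes, "numeric", n = length(bytes) %/% 4L,
                                          size = 4L, endian = "little")
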