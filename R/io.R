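# On-disk interchange: flat little-endian binaries with JSON sidecars for
# frame stacks, CSR triplets and datagram streams, plus the validated run
# configuration. Dependency-light and bit-exact by construction.

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    ssx_error(sprintf("missing JSON sidecar '%s'", sp), "ssx_validation_error")
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write a stack of frames to a flat binary file with a JSON sidecar
#'
#' Raw frames are stored as row-major little-endian uint16 (2 bytes per
#' pixel, bit-exact round trip); energy frames as row-major little-endian
#' float32. The sidecar records `rows`, `cols`, `dtype`, `n_frames` and the
#' per-frame `frame_id` and `role`.
#'
#' @param path output file (conventionally `.raw`); the sidecar is written
#'   at `paste0(path, ".json")`.
#' @param frames a list of [raw_frame()]s or of [energy_frame()]s (not
#'   mixed), or a single frame.
#' @param frame_ids,roles optional per-frame metadata vectors.
#' @return `path`, invisibly.
#' @export
write_frames <- function(path, frames, frame_ids = NULL, roles = NULL) {
  if (inherits(frames, c("raw_frame", "energy_frame"))) frames <- list(frames)
  ssx_validate(length(frames) >= 1, "no frames to write")
  is_raw <- vapply(frames, inherits, logical(1), "raw_frame")
  is_energy <- vapply(frames, inherits, logical(1), "energy_frame")
  ssx_validate(all(is_raw) || all(is_energy),
               "frames must be all raw_frame or all energy_frame")
  shape <- frames[[1]]$shape
  ssx_validate(all(vapply(frames, function(f) identical(f$shape, shape), logical(1))),
               "all frames must share one geometry")
  dtype <- if (all(is_raw)) "uint16" else "float32"
  con <- file(path, "wb")
  on.exit(close(con))
  for (f in frames) {
    bytes <- if (dtype == "uint16") frame_to_bytes(f)
             else pack_float32(as.vector(t(f$values)))
    writeBin(bytes, con)
  }
  write_sidecar(path, list(
    rows = shape[1], cols = shape[2], dtype = dtype, n_frames = length(frames),
    frame_id = if (is.null(frame_ids)) seq_along(frames) - 1L else frame_ids,
    role = if (is.null(roles)) rep("lit", length(frames)) else roles))
  invisible(path)
}

#' Read a frame stack written by [write_frames()]
#'
#' @param path the binary file; its sidecar must sit at
#'   `paste0(path, ".json")`.
#' @return a list with `frames` (list of [raw_frame()] or [energy_frame()]),
#'   `frame_ids` and `roles`.
#' @export
read_frames <- function(path) {
  meta <- read_sidecar(path)
  rows <- meta$rows; cols <- meta$cols
  bpp <- if (meta$dtype == "uint16") 2L else 4L
  frame_bytes <- rows * cols * bpp
  expected <- frame_bytes * meta$n_frames
  actual <- file.size(path)
  if (is.na(actual) || actual != expected)
    ssx_error(sprintf("frame file '%s' is %s bytes, sidecar implies %d (truncated or mismatched)",
                      path, format(actual), expected), "ssx_truncated_error")
  con <- file(path, "rb")
  on.exit(close(con))
  frames <- lapply(seq_len(meta$n_frames), function(i) {
    bytes <- readBin(con, "raw", frame_bytes)
    if (meta$dtype == "uint16") bytes_to_frame(bytes, rows, cols)
    else energy_frame(matrix(unpack_float32(bytes), rows, cols, byrow = TRUE))
  })
  list(frames = frames, frame_ids = meta$frame_id, roles = meta$role)
}

#' Write a CSR image as a flat binary triplet with a JSON sidecar
#'
#' `indptr` as int64, `indices` as int32, `data` as float32, concatenated
#' little-endian; shape, threshold, capacity and nnz in the sidecar.
#'
#' @param path output file (conventionally `.csr`).
#' @param csr a [csr_compress()] result.
#' @return `path`, invisibly.
#' @export
write_csr <- function(path, csr) {
  validate_csr(csr)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(pack_uint(csr$indptr, 8L), con)
  writeBin(pack_int32(csr$indices), con)
  writeBin(pack_float32(csr$data), con)
  write_sidecar(path, list(rows = csr$shape[1], cols = csr$shape[2],
                           threshold = csr$threshold, capacity = csr$capacity,
                           nnz = csr_nnz(csr)))
  invisible(path)
}

#' Read a CSR image written by [write_csr()]
#'
#' @param path the `.csr` file.
#' @return a `csr_image`; its structural invariants are re-validated on
#'   read.
#' @export
read_csr <- function(path) {
  meta <- read_sidecar(path)
  rows <- meta$rows; nnz <- meta$nnz
  expected <- (rows + 1) * 8 + nnz * 4 + nnz * 4
  actual <- file.size(path)
  if (is.na(actual) || actual != expected)
    ssx_error(sprintf("CSR file '%s' is %s bytes, sidecar implies %d",
                      path, format(actual), expected), "ssx_truncated_error")
  con <- file(path, "rb")
  on.exit(close(con))
  indptr <- unpack_uint(readBin(con, "raw", (rows + 1) * 8), 8L)
  indices <- as.integer(unpack_int32(readBin(con, "raw", nnz * 4)))
  data <- unpack_float32(readBin(con, "raw", nnz * 4))
  csr <- structure(list(shape = c(meta$rows, meta$cols), indptr = indptr,
                        indices = indices, data = data,
                        capacity = meta$capacity, threshold = meta$threshold),
                   class = "csr_image")
  validate_csr(csr)
}

#' Write a datagram stream file
#'
#' The raw concatenation of 8246-byte serialized datagrams (`.jfdg`), with
#' the frame geometry in a JSON sidecar.
#'
#' @param path output file.
#' @param datagrams list of [datagram()]s, written in the given order.
#' @param geometry `c(rows, cols)` recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_datagram_stream <- function(path, datagrams, geometry) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (d in datagrams) writeBin(serialize_datagram(d), con)
  write_sidecar(path, list(rows = geometry[1], cols = geometry[2],
                           n_datagrams = length(datagrams)))
  invisible(path)
}

#' Read a datagram stream file
#'
#' @param path a `.jfdg` file written by [write_datagram_stream()].
#' @return a list with `datagrams` and `geometry`.
#' @export
read_datagram_stream <- function(path) {
  meta <- read_sidecar(path)
  actual <- file.size(path)
  if (is.na(actual) || actual %% DG_TOTAL_BYTES != 0)
    ssx_error(sprintf("datagram stream '%s' is not a whole number of 8246-byte records", path),
              "ssx_truncated_error")
  con <- file(path, "rb")
  on.exit(close(con))
  n <- actual %/% DG_TOTAL_BYTES
  if (!is.null(meta$n_datagrams) && meta$n_datagrams != n)
    ssx_error("sidecar datagram count does not match file size", "ssx_truncated_error")
  datagrams <- lapply(seq_len(n), function(i)
    parse_datagram(readBin(con, "raw", DG_TOTAL_BYTES)))
  list(datagrams = datagrams, geometry = c(meta$rows, meta$cols))
}

# --- run configuration -------------------------------------------------------

run_config_defaults <- function() {
  list(
    seed = 1L,
    geometry = list(rows = 64L, cols = 1024L),
    calibration = list(gain_levels = c(40, 2, 0.5),
                       pedestal_levels = c(1000, 800, 700),
                       jitter_fraction = 0.05),
    scene = list(n_peaks = 20L, amplitude = 100, peak_sigma = 1.5,
                 background_sigma = 0.1),
    sequence = list(n_pairs = 4L, dark_noise_sigma = 5),
    channel = list(loss_probability = 0, reorder_window = 0L),
    pipeline = list(buffer_depth = 2L, credits = 2L, mode = "veto",
                    signal_threshold = 50, min_peak_pixels = 5L,
                    csr_threshold = 0, csr_capacity = NULL,
                    incomplete = "drop", output_ticks = 2L)
  )
}

merge_config <- function(defaults, user, prefix = "") {
  if (is.null(user)) return(defaults)
  ssx_validate(is.list(user), sprintf("config section '%s' must be an object", prefix))
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    ssx_error(sprintf("unknown config key '%s%s'", prefix, unknown[1]),
              "ssx_validation_error")
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], paste0(prefix, k, "."))
    else defaults[k] <- list(user[[k]]) # [<- keeps explicit NULLs as elements
  }
  defaults
}

#' Build a validated run configuration
#'
#' A single nested configuration drives every stage (geometry,
#' calibration, scene, sequence, channel, pipeline); unspecified fields
#' take defaults, unknown keys are rejected by name. All randomness flows
#' from the one top-level `seed`, fanned out into named substreams so each
#' stage is independently replayable.
#'
#' @param ... overrides as nested lists, e.g.
#'   `run_config(geometry = list(rows = 8), channel = list(loss_probability = 0.01))`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(...) {
  user <- list(...)
  cfg <- merge_config(run_config_defaults(), if (length(user)) user else NULL)
  ssx_validate(cfg$pipeline$mode %in% c("veto", "compress", "both"),
               "pipeline.mode must be veto, compress or both")
  ssx_validate(cfg$pipeline$incomplete %in% c("drop", "nan"),
               "pipeline.incomplete must be drop or nan")
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a JSON file
#'
#' Unknown keys raise a validation error naming the key; missing keys are
#' filled with defaults. `dump_config()` then `load_config()` is the
#' identity.
#'
#' @param path a JSON file.
#' @return a [run_config()].
#' @export
load_config <- function(path) {
  raw_cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- merge_config(run_config_defaults(), raw_cfg)
  # normalize integer-ish scalars parsed as double
  do.call(run_config, unclass(cfg))
}

#' Write a run configuration to a JSON file
#'
#' @param cfg a [run_config()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  ssx_validate(inherits(cfg, "run_config"), "cfg must be a run_config")
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

# Instantiate the domain objects a run_config describes.
config_tables <- function(cfg) {
  make_calibration(c(cfg$geometry$rows, cfg$geometry$cols),
                   gain_levels = cfg$calibration$gain_levels,
                   pedestal_levels = cfg$calibration$pedestal_levels,
                   jitter_fraction = cfg$calibration$jitter_fraction,
                   seed = substream_seed(cfg$seed, "calibration"))
}

config_pipeline <- function(cfg) {
  p <- cfg$pipeline
  pipeline_config(
    buffer_depth = p$buffer_depth, credits = p$credits, mode = p$mode,
    veto_cfg = if (p$mode %in% c("veto", "both"))
      veto_config(p$signal_threshold, p$min_peak_pixels),
    csr_threshold = p$csr_threshold, csr_capacity = p$csr_capacity,
    incomplete = p$incomplete, output_ticks = p$output_ticks)
}
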