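# Three-stage double-buffered pipeline orchestration: ingest/assemble,
# compute (correct + veto/compress), conditional credit-controlled output.
# Concurrency is emulated as a deterministic discrete-event schedule over
# logical ticks; the observable contract is the event ordering and the
# exact equivalence of outputs/metrics with a strictly sequential
# reference, not wall-clock overlap.

#' Pipeline configuration
#'
#' @param buffer_depth number of in-flight chunks (`>= 1`); 2 is classic
#'   double buffering (ingest of chunk n+2 overlaps compute of n+1 and
#'   writeback of n).
#' @param credits maximum queued output transfers (`>= 1`), the
#'   credit-based flow-control bound on the output queue.
#' @param mode `"veto"` (emit corrected frames that pass the Bragg-pixel
#'   veto), `"compress"` (CSR-compress every complete lit frame), or
#'   `"both"` (CSR only for veto-accepted frames).
#' @param veto_cfg a [veto_config()]; required for modes `"veto"`/`"both"`.
#' @param csr_threshold sparsification threshold for CSR modes.
#' @param csr_capacity a-priori CSR capacity; `NULL` for the 2\%-of-pixels
#'   default.
#' @param incomplete `"drop"` (default: frames with missing packets are
#'   counted and skipped -- a one-sided receiver cannot wait forever) or
#'   `"nan"` (process with missing payload zones set to `NaN`).
#' @param output_ticks logical duration of one output transfer; with slow
#'   writeback relative to compute, the credit bound becomes binding.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(buffer_depth = 2L, credits = 2L,
                            mode = c("veto", "compress", "both"),
                            veto_cfg = NULL, csr_threshold = 0,
                            csr_capacity = NULL,
                            incomplete = c("drop", "nan"),
                            output_ticks = 2L) {
  mode <- match.arg(mode)
  incomplete <- match.arg(incomplete)
  ssx_validate(buffer_depth >= 1, "buffer_depth must be at least 1")
  ssx_validate(credits >= 1, "credits must be at least 1")
  ssx_validate(output_ticks >= 1, "output_ticks must be at least 1")
  if (mode %in% c("veto", "both"))
    ssx_validate(inherits(veto_cfg, "veto_config"),
                 "veto_cfg must be a veto_config for veto/both modes")
  structure(list(buffer_depth = as.integer(buffer_depth),
                 credits = as.integer(credits), mode = mode,
                 veto_cfg = veto_cfg, csr_threshold = csr_threshold,
                 csr_capacity = csr_capacity, incomplete = incomplete,
                 output_ticks = as.integer(output_ticks)),
            class = "pipeline_config")
}

# Group a datagram stream by frame, recording per-frame arrival data and
# the ingest tick (arrival position) at which each frame completed.
ingest_stream <- function(datagrams, n_packets_expected) {
  frames <- new.env(parent = emptyenv())
  order_seen <- character(0)
  for (pos in seq_along(datagrams)) {
    d <- datagrams[[pos]]
    if (d$packets_in_frame != n_packets_expected)
      ssx_error(sprintf(
        "stream geometry mismatch: datagram declares %d packets/frame, tables imply %d",
        d$packets_in_frame, n_packets_expected), "ssx_validation_error")
    key <- as.character(d$frame_id)
    if (!exists(key, frames, inherits = FALSE)) {
      assign(key, list(dgs = list(), idx = numeric(0), complete_tick = NA_real_), frames)
      order_seen <- c(order_seen, key)
    }
    st <- get(key, frames, inherits = FALSE)
    st$dgs[[length(st$dgs) + 1L]] <- d
    if (!(d$packet_index %in% st$idx)) {
      st$idx <- c(st$idx, d$packet_index)
      if (length(st$idx) == n_packets_expected) st$complete_tick <- pos
    }
    assign(key, st, frames)
  }
  list(frames = frames, ids = sort(as.numeric(order_seen)),
       n_received = length(datagrams))
}

# Frame role under the chopper convention: ids start at 0 with a dark and
# alternate strictly, so even ids are dark.
frame_role <- function(frame_id) if (frame_id %% 2 == 0) "dark" else "lit"

# Assemble one frame's datagrams; in "nan" mode an incomplete frame is
# reconstructed with missing packet spans zero-filled, and the missing
# pixel positions are reported for NaN masking after correction.
assemble_for_compute <- function(st, geometry, incomplete_mode) {
  res <- assemble(st$dgs, geometry)
  res$masked_pixels <- NULL
  if (!res$complete && incomplete_mode == "nan") {
    n_bytes <- prod(geometry) * 2
    buf <- raw(n_bytes)
    for (d in st$dgs) buf[d$dest_offset + seq_len(d$payload_len)] <- d$payload
    res$frame <- bytes_to_frame(buf, geometry[1], geometry[2])
    masked <- unlist(lapply(res$missing, function(ix) {
      off <- ix * DG_PAYLOAD_BYTES
      len <- min(DG_PAYLOAD_BYTES, n_bytes - off)
      off / 2 + seq_len(len / 2) # 1-based row-major pixel positions
    }))
    res$masked_pixels <- masked
  }
  res
}

# Shared per-frame compute: dark -> pedestal update, lit -> correct then
# veto and/or compress. Returns the updated tracker plus output/accounting.
compute_frame <- function(res, role, tracker, tables, cfg) {
  out <- list(tracker = tracker, output = NULL, accepted = NA, bytes_out = 0)
  if (role == "dark") {
    out$tracker <- update_pedestal(tracker, res$frame)
    return(out)
  }
  tab <- if (tracker$count >= 1L) freeze_pedestal(tracker, tables) else tables
  energy <- correct_frame(res$frame, tab)
  if (!is.null(res$masked_pixels)) {
    ev <- t(energy$values)              # row-major positions from the assembler
    ev[res$masked_pixels] <- NaN
    energy <- energy_frame(t(ev))
  }
  accept <- TRUE
  if (cfg$mode %in% c("veto", "both"))
    accept <- veto(energy, cfg$veto_cfg)$accept
  out$accepted <- accept
  if (accept) {
    if (cfg$mode == "veto") {
      out$output <- energy
      out$bytes_out <- prod(energy$shape) * 4
    } else {
      cap <- if (is.null(cfg$csr_capacity)) ceiling(0.02 * prod(energy$shape))
             else cfg$csr_capacity
      csr <- csr_compress(energy, cfg$csr_threshold, cap)
      out$output <- csr
      out$bytes_out <- length(csr$indptr) * 8 + length(csr$indices) * 4 +
        length(csr$data) * 4
    }
  }
  out
}

new_report <- function(outputs, metrics, events, tracker) {
  structure(list(outputs = outputs, metrics = metrics,
                 events = events, tracker = tracker),
            class = "pipeline_report")
}

empty_events <- function() {
  data.frame(kind = character(0), frame_id = numeric(0), tick = numeric(0))
}

add_event <- function(events, kind, frame_id, tick) {
  rbind(events, data.frame(kind = kind, frame_id = frame_id, tick = tick))
}

#' Run the three-stage processing pipeline on a datagram stream
#'
#' Frames are assembled order-independently from the stream; a frame's
#' compute begins only after its completion event, computes are serialized
#' (one kernel at a time) but overlap the ingest of later frames, and
#' accepted outputs are queued under the credit bound -- all recorded as
#' `StageEvent`s on a logical tick axis. Dark frames (even ids) update the
#' pedestal tracker and produce no output; subsequent lit frames are
#' corrected against the tracked pedestal, then vetoed and/or
#' CSR-compressed per the configured mode. Frames are computed in frame-id
#' order among those fully assembled, so outputs and metrics are identical
#' to [run_sequential_reference()] for every buffer depth.
#'
#' @param datagrams the received datagram stream (any order, any
#'   interleaving of frames).
#' @param tables calibration tables defining the frame geometry.
#' @param cfg a [pipeline_config()].
#' @param n_packets_sent optional count of packets originally sent, for
#'   exact loss accounting; otherwise losses are inferred from the
#'   per-frame packet counts of frames actually observed.
#' @return an object of class `pipeline_report`: `outputs` (named by frame
#'   id), `metrics`, `events` (a data.frame of stage events) and the final
#'   pedestal `tracker`.
#' @export
run_pipeline <- function(datagrams, tables, cfg, n_packets_sent = NULL) {
  validate_gain_tables(tables)
  ssx_validate(inherits(cfg, "pipeline_config"), "cfg must be a pipeline_config")
  geometry <- tables$shape
  n_packets_expected <- ceiling(prod(geometry) * 2 / DG_PAYLOAD_BYTES)
  ing <- ingest_stream(datagrams, n_packets_expected)
  tracker <- pedestal_tracker(geometry)
  outputs <- list()
  events <- empty_events()
  m <- list(frames_seen = length(ing$ids), darks_absorbed = 0, lit_complete = 0,
            accepted = 0, rejected = 0, incomplete = 0,
            packets_received = ing$n_received, packets_lost = 0,
            bytes_in = ing$n_received * DG_TOTAL_BYTES, bytes_out = 0)
  expected_pkts <- length(ing$ids) * n_packets_expected
  m$packets_lost <- if (is.null(n_packets_sent)) expected_pkts - ing$n_received
                    else n_packets_sent - ing$n_received

  prev_compute_done <- -Inf
  output_done_hist <- numeric(0)  # done ticks of previously queued outputs
  frames_in_pipe_done <- numeric(0) # per processed frame, tick its buffer frees
  for (fid in ing$ids) {
    st <- get(as.character(fid), ing$frames, inherits = FALSE)
    res <- assemble_for_compute(st, geometry, cfg$incomplete)
    if (!res$complete) {
      m$incomplete <- m$incomplete + 1
      if (cfg$incomplete == "drop" || is.null(res$frame)) next
    } else {
      events <- add_event(events, "frame_complete", fid, st$complete_tick)
    }
    t_ready <- if (res$complete) st$complete_tick else ing$n_received
    # buffer reuse: with depth d, this frame's slot frees when the frame
    # d places back has fully left the pipe
    k <- length(frames_in_pipe_done)
    buffer_free <- if (k >= cfg$buffer_depth)
      frames_in_pipe_done[k - cfg$buffer_depth + 1L] else -Inf
    cs <- max(t_ready, prev_compute_done, buffer_free) + 1
    cd <- cs + 1
    events <- add_event(events, "compute_start", fid, cs)
    events <- add_event(events, "compute_done", fid, cd)
    prev_compute_done <- cd
    role <- frame_role(fid)
    cf <- compute_frame(res, role, tracker, tables, cfg)
    tracker <- cf$tracker
    left_pipe_at <- cd
    if (role == "dark") {
      m$darks_absorbed <- m$darks_absorbed + 1
    } else {
      if (res$complete) m$lit_complete <- m$lit_complete + 1
      if (isTRUE(cf$accepted)) {
        m$accepted <- m$accepted + 1
        q <- cd
        n_out <- length(output_done_hist)
        if (n_out >= cfg$credits) {
          # need a free credit: wait until enough earlier outputs complete
          gate <- sort(output_done_hist)[n_out - cfg$credits + 1L]
          if (gate > q) {
            events <- add_event(events, "credit_wait", fid, q)
            q <- gate
          }
        }
        od <- q + cfg$output_ticks
        events <- add_event(events, "output_queued", fid, q)
        events <- add_event(events, "output_done", fid, od)
        output_done_hist <- c(output_done_hist, od)
        outputs[[as.character(fid)]] <- cf$output
        m$bytes_out <- m$bytes_out + cf$bytes_out
        left_pipe_at <- od
      } else {
        m$rejected <- m$rejected + 1
      }
    }
    frames_in_pipe_done <- c(frames_in_pipe_done, left_pipe_at)
  }
  new_report(outputs, m, events, tracker)
}

#' Strictly sequential reference pipeline
#'
#' The equivalence oracle for [run_pipeline()]: the identical contract
#' executed one frame at a time (assemble, compute, output fully before
#' the next frame; buffer depth 1, single credit). Outputs and metrics
#' must match the pipelined run bit for bit; only the event-log timing
#' differs.
#'
#' @inheritParams run_pipeline
#' @return a `pipeline_report`.
#' @export
run_sequential_reference <- function(datagrams, tables, cfg, n_packets_sent = NULL) {
  validate_gain_tables(tables)
  ssx_validate(inherits(cfg, "pipeline_config"), "cfg must be a pipeline_config")
  geometry <- tables$shape
  n_packets_expected <- ceiling(prod(geometry) * 2 / DG_PAYLOAD_BYTES)
  ing <- ingest_stream(datagrams, n_packets_expected)
  tracker <- pedestal_tracker(geometry)
  outputs <- list()
  events <- empty_events()
  m <- list(frames_seen = length(ing$ids), darks_absorbed = 0, lit_complete = 0,
            accepted = 0, rejected = 0, incomplete = 0,
            packets_received = ing$n_received, packets_lost = 0,
            bytes_in = ing$n_received * DG_TOTAL_BYTES, bytes_out = 0)
  m$packets_lost <- if (is.null(n_packets_sent))
    length(ing$ids) * n_packets_expected - ing$n_received
  else n_packets_sent - ing$n_received

  tick <- ing$n_received # everything ingested before any compute: fully serial
  for (fid in ing$ids) {
    st <- get(as.character(fid), ing$frames, inherits = FALSE)
    res <- assemble_for_compute(st, geometry, cfg$incomplete)
    if (!res$complete) {
      m$incomplete <- m$incomplete + 1
      if (cfg$incomplete == "drop" || is.null(res$frame)) next
    } else {
      events <- add_event(events, "frame_complete", fid, tick)
    }
    cs <- tick + 1; cd <- cs + 1
    events <- add_event(events, "compute_start", fid, cs)
    events <- add_event(events, "compute_done", fid, cd)
    tick <- cd
    cf <- compute_frame(res, frame_role(fid), tracker, tables, cfg)
    tracker <- cf$tracker
    if (frame_role(fid) == "dark") {
      m$darks_absorbed <- m$darks_absorbed + 1
    } else {
      if (res$complete) m$lit_complete <- m$lit_complete + 1
      if (isTRUE(cf$accepted)) {
        m$accepted <- m$accepted + 1
        events <- add_event(events, "output_queued", fid, cd)
        events <- add_event(events, "output_done", fid, cd + cfg$output_ticks)
        tick <- cd + cfg$output_ticks
        outputs[[as.character(fid)]] <- cf$output
        m$bytes_out <- m$bytes_out + cf$bytes_out
      } else {
        m$rejected <- m$rejected + 1
      }
    }
  }
  new_report(outputs, m, events, tracker)
}

#' Detector data-stream rate
#'
#' `frames_per_second * pixels_per_frame * bits_per_pixel / 1e9` gigabits
#' per second: the arithmetic behind sizing an online-reduction system (a
#' 4-megapixel 16-bit detector at 2000 frames per second emits 128 Gb/s).
#'
#' @param frames_per_second,pixels_per_frame,bits_per_pixel non-negative.
#' @return rate in Gb/s.
#' @examples
#' stream_rate(2000, 4e6, 16) # 128
#' @export
stream_rate <- function(frames_per_second, pixels_per_frame, bits_per_pixel) {
  ssx_validate(frames_per_second >= 0 && pixels_per_frame >= 0 && bits_per_pixel >= 0,
               "all rate factors must be non-negative")
  frames_per_second * pixels_per_frame * bits_per_pixel / 1e9
}

#' @export
print.pipeline_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0(
    "<pipeline_report>  %d frame(s) seen\n",
    "  darks absorbed: %d   lit complete: %d   incomplete: %d\n",
    "  accepted: %d   rejected: %d   outputs: %d\n",
    "  packets: %d received, %d lost   bytes: %s in, %s out\n"),
    m$frames_seen, m$darks_absorbed, m$lit_complete, m$incomplete,
    m$accepted, m$rejected, length(x$outputs),
    m$packets_received, m$packets_lost,
    format(m$bytes_in, big.mark = ","), format(m$bytes_out, big.mark = ",")))
  invisible(x)
}
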