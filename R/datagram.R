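# Destination-addressed datagrams: bit-exact codec, packetizer, lossy
# reordering channel model, and an order-independent frame assembler with
# completion events -- a software emulation of one-sided RDMA-WRITE
# placement over an unreliable datagram transport.

DG_MAGIC <- charToRaw("JFDG")
DG_VERSION <- 1L
DG_HEADER_BYTES <- 54L
DG_PAYLOAD_BYTES <- 8192L   # four lines of 1024 16-bit pixels
DG_TOTAL_BYTES <- DG_HEADER_BYTES + DG_PAYLOAD_BYTES # 8246
DG_FLAG_LAST <- 1L          # header flag bit 0: last packet, immediate valid

#' Construct a datagram
#'
#' The on-the-wire unit of the emulation: a 54-byte little-endian header
#' followed by an 8192-byte payload slot (8246 bytes total). The header
#' carries, in order: magic `"JFDG"` (4), version (u16), `frame_id` (u64),
#' `packet_seq` (u32, globally incrementing), `packets_in_frame` (u32),
#' `packet_index` (u32), `dest_offset` (u64, byte offset of the payload in
#' the destination frame buffer -- the RDMA-WRITE address), `row_start`
#' (u32), `payload_len` (u16), `flags` (u16; bit 0 marks the last packet of
#' a frame, whose `immediate` is the 32-bit completion event), `immediate`
#' (u32) and `timestamp` (u64, arbitrary ticks).
#'
#' @param frame_id,packet_seq,packets_in_frame,packet_index,dest_offset,row_start,payload_len,flags,immediate,timestamp header fields.
#' @param payload raw vector of `payload_len` bytes.
#' @return an object of class `ssx_datagram`.
#' @export
datagram <- function(frame_id, packet_seq, packets_in_frame, packet_index,
                     dest_offset, row_start, payload_len, flags, immediate,
                     timestamp, payload) {
  ssx_validate(is.raw(payload) && length(payload) == payload_len,
               "payload must be a raw vector of payload_len bytes")
  ssx_validate(payload_len >= 1 && payload_len <= DG_PAYLOAD_BYTES,
               "payload_len must lie in [1, 8192]")
  structure(list(
    magic = DG_MAGIC, version = DG_VERSION,
    frame_id = as.numeric(frame_id), packet_seq = as.numeric(packet_seq),
    packets_in_frame = as.numeric(packets_in_frame),
    packet_index = as.numeric(packet_index),
    dest_offset = as.numeric(dest_offset), row_start = as.numeric(row_start),
    payload_len = as.integer(payload_len), flags = as.integer(flags),
    immediate = as.numeric(immediate), timestamp = as.numeric(timestamp),
    payload = payload
  ), class = "ssx_datagram")
}

#' @export
print.ssx_datagram <- function(x, ...) {
  cat(sprintf("<datagram frame %s pkt %s/%s seq %s offset %s len %d%s>\n",
              format(x$frame_id), format(x$packet_index),
              format(x$packets_in_frame), format(x$packet_seq),
              format(x$dest_offset), x$payload_len,
              if (bitwAnd(x$flags, DG_FLAG_LAST)) " LAST" else ""))
  invisible(x)
}

#' Packetize a raw frame into datagrams
#'
#' Slices the frame's row-major byte image into 8192-byte payloads (four
#' 1024-pixel detector lines in the native dialect) covering the frame
#' contiguously. `packet_seq` increments by one from `seq_start`;
#' `dest_offset = packet_index * 8192`; the final datagram (largest index)
#' carries flag bit 0 and `immediate = frame_id mod 2^32`, emulating
#' WRITE_WITH_IMM after the last WRITE. A frame whose byte count is not a
#' multiple of 8192 ends in a short `payload_len`.
#'
#' @param raw a [raw_frame()].
#' @param frame_id non-negative frame identifier.
#' @param seq_start first packet-sequence number to assign.
#' @param tick_start timestamp assigned to the first datagram (then +1 each).
#' @return a list of [datagram()]s in packet-index order.
#' @export
packetize <- function(raw, frame_id, seq_start = 0, tick_start = 0) {
  ssx_validate(inherits(raw, "raw_frame"), "raw must be a raw_frame")
  bytes <- frame_to_bytes(raw)
  n_bytes <- length(bytes)
  if (n_bytes == 0) ssx_error("cannot packetize an empty frame", "ssx_validation_error")
  n_packets <- ceiling(n_bytes / DG_PAYLOAD_BYTES)
  cols <- raw$shape[2]
  lapply(seq_len(n_packets), function(i) {
    off <- (i - 1) * DG_PAYLOAD_BYTES
    len <- min(DG_PAYLOAD_BYTES, n_bytes - off)
    last <- i == n_packets
    datagram(
      frame_id = frame_id,
      packet_seq = seq_start + i - 1,
      packets_in_frame = n_packets,
      packet_index = i - 1,
      dest_offset = off,
      row_start = off %/% (2 * cols),
      payload_len = len,
      flags = if (last) DG_FLAG_LAST else 0L,
      immediate = frame_id %% 4294967296,
      timestamp = tick_start + i - 1,
      payload = bytes[(off + 1):(off + len)]
    )
  })
}

#' Serialize a datagram to its 8246-byte wire form
#'
#' All multi-byte integers little-endian; the payload is zero-padded to the
#' full 8192-byte slot so every full datagram serializes to exactly 8246
#' bytes.
#'
#' @param d a [datagram()].
#' @return a raw vector of 8246 bytes.
#' @export
serialize_datagram <- function(d) {
  ssx_validate(inherits(d, "ssx_datagram"), "d must be a datagram")
  payload <- d$payload
  if (length(payload) < DG_PAYLOAD_BYTES)
    payload <- c(payload, raw(DG_PAYLOAD_BYTES - length(payload)))
  c(DG_MAGIC,
    pack_uint(d$version, 2L),
    pack_uint(d$frame_id, 8L),
    pack_uint(d$packet_seq, 4L),
    pack_uint(d$packets_in_frame, 4L),
    pack_uint(d$packet_index, 4L),
    pack_uint(d$dest_offset, 8L),
    pack_uint(d$row_start, 4L),
    pack_uint(d$payload_len, 2L),
    pack_uint(d$flags, 2L),
    pack_uint(d$immediate, 4L),
    pack_uint(d$timestamp, 8L),
    payload)
}

#' Parse a serialized datagram
#'
#' @param bytes raw vector holding one serialized datagram (at least the
#'   54-byte header plus its declared payload).
#' @return a [datagram()].
#' @export
parse_datagram <- function(bytes) {
  if (!is.raw(bytes) || length(bytes) < DG_HEADER_BYTES)
    ssx_error("buffer shorter than the 54-byte datagram header", "ssx_truncated_error")
  if (!identical(bytes[1:4], DG_MAGIC))
    ssx_error("bad datagram magic (expected 'JFDG')", "ssx_magic_error")
  version <- unpack_uint(bytes[5:6], 2L)
  if (version != DG_VERSION)
    ssx_error(sprintf("unsupported datagram version %d", version), "ssx_version_error")
  payload_len <- as.integer(unpack_uint(bytes[39:40], 2L))
  if (payload_len < 1 || payload_len > DG_PAYLOAD_BYTES)
    ssx_error(sprintf("corrupt header: payload_len %d outside [1, 8192]", payload_len),
              "ssx_truncated_error")
  if (length(bytes) < DG_HEADER_BYTES + payload_len)
    ssx_error("buffer truncated: payload shorter than payload_len", "ssx_truncated_error")
  datagram(
    frame_id = unpack_uint(bytes[7:14], 8L),
    packet_seq = unpack_uint(bytes[15:18], 4L),
    packets_in_frame = unpack_uint(bytes[19:22], 4L),
    packet_index = unpack_uint(bytes[23:26], 4L),
    dest_offset = unpack_uint(bytes[27:34], 8L),
    row_start = unpack_uint(bytes[35:38], 4L),
    payload_len = payload_len,
    flags = as.integer(unpack_uint(bytes[41:42], 2L)),
    immediate = unpack_uint(bytes[43:46], 4L),
    timestamp = unpack_uint(bytes[47:54], 8L),
    payload = bytes[DG_HEADER_BYTES + seq_len(payload_len)]
  )
}

#' Lossy, reordering channel model
#'
#' @param loss_probability independent per-datagram drop probability in
#'   `[0, 1]`.
#' @param reorder_window shuffle radius: a surviving datagram is displaced
#'   by at most this many positions. `0` preserves order.
#' @param seed integer seed; the channel is deterministic given it and
#'   never duplicates or corrupts packets.
#' @return an object of class `channel_model`.
#' @export
channel_model <- function(loss_probability = 0, reorder_window = 0L, seed = 1L) {
  ssx_validate(loss_probability >= 0 && loss_probability <= 1,
               "loss_probability must lie in [0, 1]")
  ssx_validate(reorder_window >= 0, "reorder_window must be non-negative")
  structure(list(loss_probability = loss_probability,
                 reorder_window = as.numeric(reorder_window),
                 seed = as.integer(seed)),
            class = "channel_model")
}

#' Pass datagrams through the channel
#'
#' Draws one uniform per input datagram (in input order) for the drop
#' decision, then displaces survivors by sorting on
#' `position + U(0, reorder_window)`, which bounds each displacement by the
#' window.
#'
#' @param datagrams list of [datagram()]s in send order.
#' @param model a [channel_model()].
#' @return the surviving datagrams in arrival order.
#' @export
channel_transmit <- function(datagrams, model) {
  ssx_validate(inherits(model, "channel_model"), "model must be a channel_model")
  n <- length(datagrams)
  if (n == 0) return(datagrams)
  with_seed(model$seed, {
    u <- runif(n)
    keep <- which(u >= model$loss_probability)
    out <- datagrams[keep]
    if (model$reorder_window > 0 && length(out) > 1) {
      key <- seq_along(out) + runif(length(out), 0, model$reorder_window)
      out <- out[order(key)]
    }
    out
  })
}

#' Assemble a frame from datagrams, order-independently
#'
#' Each payload is written at its `dest_offset` in a pre-sized destination
#' buffer, so the result is a pure function of the datagram set, not of
#' arrival order (the WRITE semantics that make a reshuffle step
#' unnecessary). Duplicate packets with identical bytes are idempotently
#' accepted; a duplicate offset with differing bytes is an integrity error.
#' The completion event fires only when every packet is present, and takes
#' its value from the `immediate` of the packet carrying the last-packet
#' flag.
#'
#' @param datagrams datagrams of a single frame, in any order (possibly
#'   incomplete or empty).
#' @param geometry `c(rows, cols)` of the expected frame.
#' @return an object of class `frame_result`: `frame` (a [raw_frame()] when
#'   complete, otherwise `NULL`), `received_map` (per-packet logical),
#'   `missing` (0-based packet indices), `complete`, and `event` (the
#'   32-bit immediate, `NULL` unless complete).
#' @export
assemble <- function(datagrams, geometry) {
  ssx_validate(length(geometry) == 2 && all(geometry >= 1),
               "geometry must be two positive integers")
  rows <- as.integer(geometry[1]); cols <- as.integer(geometry[2])
  n_bytes <- rows * cols * 2
  n_packets <- ceiling(n_bytes / DG_PAYLOAD_BYTES)
  buf <- raw(n_bytes)
  received <- logical(n_packets)
  event <- NULL
  fid <- NULL
  for (d in datagrams) {
    ssx_validate(inherits(d, "ssx_datagram"), "datagrams must be ssx_datagram objects")
    if (is.null(fid)) fid <- d$frame_id
    else if (d$frame_id != fid)
      ssx_error("datagrams from mixed frame_ids", "ssx_validation_error")
    if (d$packet_index >= n_packets || d$dest_offset + d$payload_len > n_bytes)
      ssx_error("datagram addresses bytes outside the frame buffer",
                "ssx_validation_error")
    span <- d$dest_offset + seq_len(d$payload_len)
    if (received[d$packet_index + 1]) {
      if (!identical(buf[span], d$payload))
        ssx_error(sprintf("conflicting duplicate for packet %d", d$packet_index),
                  "ssx_integrity_error")
    } else {
      buf[span] <- d$payload
      received[d$packet_index + 1] <- TRUE
    }
    if (bitwAnd(d$flags, DG_FLAG_LAST)) event <- d$immediate
  }
  missing <- which(!received) - 1L
  complete <- length(missing) == 0L
  structure(list(
    frame = if (complete) bytes_to_frame(buf, rows, cols) else NULL,
    received_map = received,
    missing = missing,
    complete = complete,
    event = if (complete) event else NULL,
    frame_id = fid
  ), class = "frame_result")
}

#' @export
print.frame_result <- function(x, ...) {
  cat(sprintf("<frame_result frame %s>  %d/%d packets, %s\n",
              format(x$frame_id), sum(x$received_map), length(x$received_map),
              if (x$complete) sprintf("complete (event %s)", format(x$event))
              else sprintf("missing %s", paste(x$missing, collapse = ","))))
  invisible(x)
}

#' Detect lost packets from sequence-number gaps
#'
#' A stream monitor over the globally incrementing `packet_seq`: given the
#' sequence numbers actually received and the sent range, returns the
#' missing ones -- the standard loss-detection instrument for one-sided
#' datagram transports.
#'
#' @param datagrams received datagrams (any frames, any order).
#' @param seq_start first sequence number sent.
#' @param n_sent number of packets sent.
#' @return numeric vector of lost sequence numbers (empty if none).
#' @export
sequence_gaps <- function(datagrams, seq_start, n_sent) {
  got <- vapply(datagrams, function(d) d$packet_seq, numeric(1))
  expected <- seq_start + seq_len(n_sent) - 1
  setdiff(expected, got)
}
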