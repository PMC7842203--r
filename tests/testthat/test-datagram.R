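test_that("a 512x1024 frame packetizes to 128 full datagrams", {
  raw <- raw_frame(matrix(1000L, 512, 1024))
  dgs <- packetize(raw, frame_id = 7)
  expect_length(dgs, 128)
  expect_true(all(vapply(dgs, function(d) d$payload_len, numeric(1)) == 8192))
  expect_equal(vapply(dgs, function(d) d$dest_offset, numeric(1)),
               (0:127) * 8192)
  expect_equal(vapply(dgs, function(d) d$packet_seq, numeric(1)), 0:127)
  # exactly one last-packet flag, on the largest index, carrying the event
  last <- vapply(dgs, function(d) bitwAnd(d$flags, 1L) == 1L, logical(1))
  expect_equal(which(last), 128L)
  expect_equal(dgs[[128]]$immediate, 7)
})

test_that("single-datagram frame and short-tail geometries are handled", {
  dgs <- packetize(raw_frame(matrix(1L, 4, 1024)), frame_id = 0)
  expect_length(dgs, 1)
  expect_equal(dgs[[1]]$dest_offset, 0)
  expect_equal(dgs[[1]]$payload_len, 8192L)
  expect_equal(bitwAnd(dgs[[1]]$flags, 1L), 1L)
  # 5 x 1024 pixels = 10240 bytes: one full packet + one 2048-byte tail
  tail2 <- packetize(raw_frame(matrix(1L, 5, 1024)), frame_id = 1)
  expect_length(tail2, 2)
  expect_equal(tail2[[2]]$payload_len, 2048L)
})

test_that("concatenated payloads reproduce the frame bytes exactly", {
  set.seed(5)
  raw <- raw_frame(matrix(sample(0L:16383L, 12 * 1024, replace = TRUE), 12, 1024))
  dgs <- packetize(raw, frame_id = 3)
  bytes <- do.call(c, lapply(dgs, function(d) d$payload))
  expect_identical(bytes, ssxpipe:::frame_to_bytes(raw))
})

test_that("serialize/parse round trips field-for-field at 8246 bytes", {
  raw <- raw_frame(matrix(42L, 8, 1024))
  for (d in packetize(raw, frame_id = 2^40 + 5, seq_start = 2^31)) {
    wire <- serialize_datagram(d)
    expect_length(wire, 8246)
    expect_equal(parse_datagram(wire), d)
  }
})

test_that("parse raises distinct classed errors for bad input", {
  d <- packetize(raw_frame(matrix(1L, 4, 1024)), 0)[[1]]
  wire <- serialize_datagram(d)
  bad_magic <- wire; bad_magic[1] <- as.raw(0)
  expect_error(parse_datagram(bad_magic), class = "ssx_magic_error")
  bad_ver <- wire; bad_ver[5] <- as.raw(9)
  expect_error(parse_datagram(bad_ver), class = "ssx_version_error")
  expect_error(parse_datagram(wire[1:40]), class = "ssx_truncated_error")
  expect_error(parse_datagram(wire[1:100]), class = "ssx_truncated_error")
})

test_that("identity channel passes everything through unchanged", {
  dgs <- packetize(raw_frame(matrix(1L, 16, 1024)), 0)
  expect_identical(channel_transmit(dgs, channel_model(0, 0, seed = 1)), dgs)
  expect_length(channel_transmit(dgs, channel_model(1, 0, seed = 1)), 0)
})

test_that("seeded losses equal an independent RNG-replay oracle", {
  dgs <- packetize(raw_frame(matrix(1L, 250, 1024)), 0) # ~63 packets
  dgs <- c(dgs, packetize(raw_frame(matrix(2L, 250, 1024)), 1, seq_start = 63))
  n <- length(dgs)
  model <- channel_model(0.5, 0, seed = 99)
  got <- channel_transmit(dgs, model)
  # oracle: replay the same seeded uniform stream
  set.seed(99)
  dropped_oracle <- which(runif(n) < 0.5)
  kept_seq <- vapply(got, function(d) d$packet_seq, numeric(1))
  expect_identical(sort(kept_seq), as.numeric(setdiff(seq_len(n) - 1, dropped_oracle - 1)))
  # the sequence-gap monitor reports exactly the dropped packets
  expect_identical(sort(sequence_gaps(got, 0, n)), as.numeric(dropped_oracle - 1))
})

test_that("reordering is bounded by the window and drops nothing", {
  dgs <- packetize(raw_frame(matrix(1L, 128, 1024)), 0) # 32 packets
  got <- channel_transmit(dgs, channel_model(0, 5, seed = 12))
  expect_length(got, length(dgs))
  pos <- vapply(got, function(d) d$packet_seq, numeric(1))
  expect_false(identical(pos, as.numeric(seq_along(dgs) - 1)))
  expect_true(all(abs(pos - (seq_along(pos) - 1)) <= 5))
  expect_identical(channel_transmit(dgs, channel_model(0, 5, seed = 12)), got)
})

test_that("assembly is order-independent and flags missing packets", {
  set.seed(8)
  raw <- raw_frame(matrix(sample(0L:16383L, 16 * 1024, replace = TRUE), 16, 1024))
  dgs <- packetize(raw, frame_id = 11)
  res <- assemble(rev(dgs), c(16, 1024))
  expect_true(res$complete)
  expect_identical(res$frame$words, raw$words)
  expect_equal(res$event, 11)
  # one packet removed
  res2 <- assemble(dgs[-2], c(16, 1024))
  expect_false(res2$complete)
  expect_equal(res2$missing, 1L)
  expect_null(res2$event)
  expect_null(res2$frame)
})

test_that("assembled bytes are identical across 200 random permutations", {
  set.seed(23)
  raw <- raw_frame(matrix(sample(0L:16383L, 64 * 1024, replace = TRUE), 64, 1024))
  dgs <- packetize(raw, frame_id = 4) # 16 packets
  ref <- assemble(dgs, c(64, 1024))
  for (i in 1:200) {
    res <- assemble(dgs[sample(length(dgs))], c(64, 1024))
    expect_identical(res$frame$words, ref$frame$words)
    expect_identical(res$event, ref$event)
  }
})

test_that("duplicates are idempotent; conflicting duplicates are an integrity error", {
  raw <- raw_frame(matrix(9L, 8, 1024))
  dgs <- packetize(raw, frame_id = 1)
  res <- assemble(c(dgs, dgs[1]), c(8, 1024))
  expect_true(res$complete)
  evil <- dgs[[1]]
  evil$payload[1] <- as.raw(255)
  expect_error(assemble(c(dgs, list(evil)), c(8, 1024)), class = "ssx_integrity_error")
  mixed <- packetize(raw, frame_id = 2)[[1]]
  expect_error(assemble(c(dgs, list(mixed)), c(8, 1024)), class = "ssx_validation_error")
})

test_that("packetize/assemble round trip is bit-exact across geometries", {
  for (shape in list(c(512, 1024), c(2048, 2048), c(128, 128), c(4, 1024))) {
    set.seed(sum(shape))
    raw <- raw_frame(matrix(sample(0L:16383L, prod(shape), replace = TRUE),
                            shape[1], shape[2]))
    res <- assemble(packetize(raw, 0), shape)
    expect_true(res$complete)
    expect_identical(res$frame$words, raw$words)
  }
})
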