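# Shared fixtures: small calibrations and scenes built in code at test time.

# jitter-free tables where every coefficient is exactly the level scalar
flat_tables <- function(shape = c(4, 8), gains = c(40, 2, 0.5),
                        pedestals = c(1000, 800, 700)) {
  make_calibration(shape, gains, pedestals, jitter_fraction = 0, seed = 1)
}

# realistic jittered tables on a one-datagram-wide geometry
jittered_tables <- function(shape = c(8, 1024), seed = 7) {
  make_calibration(shape, jitter_fraction = 0.05, seed = seed)
}

# a raw frame with specified words at a few pixels, level-0 pedestal elsewhere
raw_with_words <- function(tables, words_at = list()) {
  f <- generate_dark(tables, noise_sigma = 0, seed = 1)
  for (w in words_at) f$words[w$row, w$col] <- w$word
  raw_frame(f$words)
}

# packetized lossless stream for a whole acquisition sequence
sequence_stream <- function(seq) {
  dgs <- list()
  s <- 0
  for (f in seq$frames) {
    p <- packetize(f$raw, f$frame_id, seq_start = s, tick_start = s)
    s <- s + length(p)
    dgs <- c(dgs, p)
  }
  dgs
}
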