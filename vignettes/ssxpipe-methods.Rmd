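---
title: "Methods: emulating an online SSX data-reduction chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emulating an online SSX data-reduction chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssxpipe)
```

## The problem being emulated

Serial synchrotron crystallography (SSX) records thousands of still
diffraction snapshots per second from a stream of microcrystals. A chopper
alternates beam-off (dark) and beam-on (lit) exposures, so a 2000 Hz
acquisition delivers 1000 usable diffraction frames per second, and a
4-megapixel 16-bit detector emits

$$ 2000\ \mathrm{fps} \times 4\times10^6\ \mathrm{px} \times 16\ \mathrm{bit}
   = 128\ \mathrm{Gb\,s^{-1}}, $$

far too much to store raw. Production systems solve this with one-sided
(RDMA-WRITE-style) network placement into accelerator memory and a
three-stage streaming reduction: (i) ingest and frame assembly, (ii)
correction plus hit finding or compression, (iii) conditional output of
accepted frames. `ssxpipe` reproduces that chain *as software semantics*:
every stage is an ordinary deterministic function on synthetic data, so
the orderings, formats and equivalences that define the design become
directly testable. Real transport (UDP/RoCE), GPUs, and wall-clock
throughput are deliberately out of scope.

## Adaptive-gain correction model

Each pixel of the emulated detector digitizes through one of three gain
levels, automatically chosen per pixel by signal amplitude. A 16-bit raw
word holds the level in its two most significant bits (level 0 `0b00`,
level 1 `0b01`, level 2 `0b11`; `0b10` is reserved, and decodes to `NaN`
by default) and a 14-bit value in ADU. Conversion to energy is

$$ E = \frac{\mathrm{value}_{14} - \mathrm{pedestal}_k}{\mathrm{gain}_k}, $$

one integer subtraction and one floating-point division per pixel: 4
million of each per 4M frame, which `correct_frame_scalar()` verifies by
actually counting them in a per-pixel loop. Each pixel needs a pedestal
and a gain for each of the three levels — six coefficients per pixel, 24
million for a 4M sensor — held in `gain_tables`.

Defaults are `gain_levels = c(40, 2, 0.5)` ADU per energy unit and
`pedestal_levels = c(1000, 800, 700)` ADU with 5% multiplicative per-pixel
jitter, `U(1-j, 1+j)`. The absolute scale of gain factors is arbitrary in
ADU-based units; what matters structurally is that gains decrease strictly
with level (level 0 is the highest gain, the low-signal regime) and
pedestals stay inside the 14-bit range. The jitter model is a package
choice: real calibrations disperse per pixel, and a dispersed table makes
the tests sensitive to indexing errors that constant tables would hide.

### Encoding and its quantization bound

`encode_raw()` emulates the detector's auto-ranging: the chosen level is
the smallest `k` whose rounded value `round(E * gain_k + pedestal_k)`
still fits below $2^{14}$. Rounding is half-away-from-zero, fixed and
documented so the inverse bound is exact: a full encode-correct round
trip deviates from the original energy by at most $0.5/\mathrm{gain}_k$
per pixel, which the suite asserts pixel-for-pixel. Two degenerate cases
are treated as saturation (error by default, clamping into range under
`saturation = "clamp"`): overflow at level 2, and a value rounding below
0 at level 0 from a strongly negative energy. Handling underflow as
saturation rather than letting the level search continue keeps
auto-ranging monotone — raising a pixel's energy can only move it to an
equal or lower gain — and keeps the stored 14-bit value always valid.

### Pedestal tracking from darks

Darks are interleaved with lit frames by the chopper and refresh the
pedestal of the *highest* gain only; the other two levels' pedestals are
taken as constant. "Highest gain" maps to level index 0 because the
correction divides by the gain: level 0 has the largest divisor and is
where a dark sits. The tracker supports an exact per-pixel running mean
(default; verified against a brute-force averaging loop to 1e-9) and an
exponential moving average (`alpha` in (0,1]) for drift tracking in long
continuous runs. Dark pixels whose gain bits are not level 0 are skipped
rather than rejected — isolated pixels can sit at another level even in a
dark — which is why the tracker keeps a per-pixel absorption count
alongside the frame count: a correct mean needs per-pixel denominators.
On `freeze_pedestal()`, pixels never absorbed keep their prior table
value. With `N` darks of noise `sigma`, the estimate recovers the true
pedestal within $5\sigma/\sqrt{N}$ for at least 99% of pixels (checked at
N = 100, sigma = 5 ADU).

## Datagram dialect and order-independent assembly

Frames travel as destination-addressed datagrams mirroring one-sided
WRITE placement: 54-byte little-endian header plus an 8192-byte payload
slot (four 1024-pixel 16-bit lines), 8246 bytes total — the native packet
size of the emulated detector. The header field layout itself
(magic/version/frame and sequence numbers/destination offset/length/
flags/immediate/timestamp) is this package's own dialect: only the total
size, the incrementing packet-sequence number, the embedded destination
address and the 32-bit completion immediate are constrained by the system
being emulated. A 512×1024 frame packetizes to exactly 128 datagrams.

Because each packet carries its destination byte offset, the assembler
simply writes payloads where they say they belong: the result is a pure
function of the packet *set*, asserted over hundreds of random arrival
permutations. Identical duplicates are idempotently accepted (a rewrite
of the same bytes is harmless); a conflicting duplicate is a data
integrity error. The completion event — the immediate of the
flagged last-index packet — fires only when the frame is complete,
emulating WRITE_WITH_IMM after all WRITEs.

The channel model drops each packet independently with probability `p`
(one `runif` per packet, drawn in send order, so tests can replay the
exact dropped set from the seed) and displaces survivors by sorting on
`position + U(0, w)`, which provably bounds displacement by the window
`w`. It never duplicates or corrupts: those paths are exercised by
constructing bad packets directly.

## Hit finding and CSR compression

The veto is intentionally simplistic: count pixels with energy strictly
above `signal_threshold` (no noise correction, no outlier removal, NaN
never counts) and accept the frame when the count reaches
`min_peak_pixels`. Strict `>` is fixed so brute-force oracles are
unambiguous. Neither threshold has a meaningful default — they are
experiment-specific knobs — and the count is monotone in both, which the
suite checks.

The alternative to rejection is compression to CSR: retained pixels
(strictly above the sparsification threshold) are stored row-major with
`indptr` built as the exclusive prefix sum of per-row counts. The storage
capacity is fixed a priori from expected sparsity — default 2% of the
pixel count — and overflow is a dedicated error naming the capacity that
would have been required, raised before any partial write. Whether the
prefix sum is literally parallel is an implementation freedom; here it is
a sequential cumulative sum with the same observable behavior. Negative
corrected energies are legal (noise below pedestal) and never clipped;
they are simply below any sensible threshold.

## Pipeline orchestration and its equivalence contract

Concurrency is emulated as a deterministic event scheduler over logical
ticks rather than real threads: the production system's overlap is a
throughput device, but its *testable* surface is ordering and
equivalence. Ticks are dimensionless; ingest ticks are packet arrival
positions, each compute takes one tick, each output `output_ticks`
(default 2, chosen so that writeback is slower than compute and the
credit bound can actually bind in tests). The schedule enforces, per
frame: completion < compute start < compute done ≤ output queued ≤
output done; computes are serialized in frame-id order; a frame's buffer
slot frees only when it fully leaves the pipe, so at most `buffer_depth`
frames are in flight; and an output is queued only when fewer than
`credits` transfers are outstanding, logging a `credit_wait` event
otherwise. When no credit or buffer is free the source is blocked (the
schedule stalls); packets are never dropped by the receiver itself — a
back-pressure choice made here, documented as such.

Dark frames (even ids, from the strict chopper alternation — the header
carries no role field) update the pedestal tracker at their completion
and produce no output; lit frames are corrected against the tracker state
at their compute time, so a pedestal shift absorbed from a dark applies
to all later lit frames and never retroactively. Frames with missing
packets are dropped from compute by default and surfaced in the
`incomplete` count; `incomplete = "nan"` instead processes them with the
missing payload zones masked to NaN.

`run_sequential_reference()` executes the identical contract one frame
at a time. Because both implementations compute in frame-id order with
the same tracker evolution, outputs and metrics must agree *identically*
— not approximately — for every buffer depth and credit setting; the
suite asserts this over 50 seeded scenarios spanning loss rates {0,
0.01}, both veto and compress modes, and varying buffer/credit settings.
This equivalence is the package's core correctness argument: the
pipelined schedule may only change *when* things happen, never *what* is
computed.

## Randomness, file formats, problem sizes

All randomness flows from one top-level seed fanned into named
substreams (calibration, per-frame scenes and darks, channel), so any
stage replays independently. Interchange is deliberately dependency-light
and bit-exact: flat little-endian binaries (row-major uint16 frames,
float32 energies, int64/int32/float32 CSR triplets, concatenated
8246-byte datagram records) with JSON sidecars carrying geometry and
metadata; every reader re-validates sizes and structural invariants and
raises typed errors (validation vs. truncation vs. integrity), which the
CLI maps to exit codes 2 and 3.

Routine tests run on deliberately small geometries — frames of a few
thousand pixels (one to sixteen datagrams), 2-to-8-pair sequences,
32×32 calibration patches — because every property under test is
size-invariant; the two genuinely size-dependent facts (the 24-million
coefficient count and the 4-million-each operation count) are computed at
the full 4,000,000-pixel size, where "4M" is taken as exactly 4×10⁶
pixels for counting purposes. The scalar instrumented correction of a 4M
frame takes a few seconds in pure R.

## What the synthetic data does and does not show

The generator renders isotropic Gaussian spots at uniform sub-pixel
centers on zero-mean Gaussian background, encoded through the same gain
model the corrector inverts. That suffices to exercise every contract in
the chain — auto-ranging across all three gain regimes, quantization
bounds, sparsity, hit/no-hit discrimination — but it is not diffraction
physics: no crystal lattice or Ewald-sphere geometry, no Poisson counting
statistics (offered nowhere by default so the quantization bound stays
exact), no module gaps, no correlated detector artifacts. Passing tests
therefore demonstrate the correctness of the *reduction machinery*, not
the scientific adequacy of the simplistic veto on real lysozyme data; on
real data the veto thresholds would need tuning against a trusted peak
finder, which is explicitly outside this package's scope.

Other known limitations: the datagram dialect is not the vendor wire
format; pedestal tracking covers only the highest gain (the other levels
are assumed stable, as in the emulated system); energies are plain R
doubles validated against float32 representability at IO boundaries
rather than computed in true single precision; and the event-driven
scheduler models ordering, not latency, so no timing claim transfers to
hardware.
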