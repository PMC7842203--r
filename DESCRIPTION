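Package: ssxpipe
Title: Emulation of an Online Serial-Crystallography Data-Reduction Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Software emulation of the online data-reduction chain used for
    synchrotron serial crystallography (SSX) with adaptive-gain JUNGFRAU-style
    detectors. Synthetic diffraction frames are encoded into 16-bit raw words
    (two gain bits plus a 14-bit value), packetized into destination-addressed
    8246-byte datagrams, passed through a lossy reordering channel, reassembled
    order-independently with completion events, converted to energies via
    three-level pedestal/gain correction with dark-frame pedestal tracking,
    and then either vetoed by a Bragg-pixel count or compressed to the CSR
    sparse format - orchestrated as a credit-controlled double-buffered
    three-stage pipeline with a sequential reference implementation for
    equivalence checking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
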