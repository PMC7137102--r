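Package: emkit
Title: Core Building Blocks for Cryo-EM Image and Metadata Handling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for electron cryo-microscopy (cryo-EM)
    data handling: a typed four-dimensional image container with an explicit
    element-type system, byte-exact readers and writers for the MRC2014 and
    SPIDER image formats (single images, stacks and volumes), typed metadata
    tables with STAR (RELION dialect) and delimited-text backends, real-to-
    complex Fourier transforms with frequency-domain cropping and padding for
    ideal-interpolation rescaling, a library of composable image processors
    (arithmetic, windowing, scaling, low-pass filtering) with pipeline
    concatenation, and the 'em-image' / 'em-table' command-line tools built on
    top of them.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
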