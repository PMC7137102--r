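---
title: "emkit: design and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{emkit: design and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emkit)
```

`emkit` is a small foundation library for cryo-EM data handling: a typed 4-D
image container, byte-exact MRC2014 and SPIDER file handlers, typed metadata
tables with STAR and delimited-text backends, Fourier-domain rescaling, and a
composable processor pipeline exposed both as R functions and as the
`em-image` / `em-table` command-line tools. This vignette records how the
pieces work, the conventions and numerical choices they commit to, and why.

## The image model

An `em_image` is a dense 4-D array indexed `(n, z, y, x)`: `n` counts stack
items, `z` slices, `y` rows, `x` columns. Internally the buffer is stored
x-fastest, which is simultaneously R's native column-major order and the
MRC2014 column/row/section order, so file I/O never permutes data. Three
shapes matter in practice: a single 2-D image (`n = 1, z = 1`), a particle
stack (`n >= 1, z = 1`) and a 3-D volume (`n = 1, z > 1`). The container does
not forbid `n > 1, z > 1`, but the file handlers only write the three
standard shapes.

Every image carries an element type from {int8, int16, int32, uint8, uint16,
float32, float64}. R has no native narrow integer or single-precision
storage, so buffers are held as doubles and the dtype tag governs semantics:
all seven types embed exactly in a double, making in-memory storage lossless.
`dtype_cast()` is the single conversion authority:

* **Widening** (every source value exactly representable in the target) is
  value-exact; `dtype_widens()` exposes the partial order. Note int32 does
  *not* widen to float32 (24-bit mantissa), only to float64.
* **Narrowing to integers** rounds half-to-even — the IEEE default, which
  avoids the upward bias of round-half-up on noisy data — then either clamps
  to the target range (`"round-clamp"`, the default, matching how EM format
  converters traditionally saturate) or raises (`"error-on-overflow"`).
* **Narrowing to float32** performs exact binary rounding via a 4-byte
  serialization round trip.

Image statistics use the *population* standard deviation (divide by N), not
the sample formula, because that is what the MRC header RMS field records;
`table_stats()` follows the same convention so the two surfaces agree.

Angstrom per pixel is the only physical unit in the package. It is optional:
a file with a zero cell (MRC) or zero scale (SPIDER) yields `pixel_size =
NULL`, never 0, so downstream code cannot silently divide by a fake sampling
rate.

## File formats

**MRC2014.** The handler implements the 1024-byte header at the documented
byte offsets, modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16), the
`"MAP "` magic and the machine stamp. Conventions the format itself leaves
open were fixed as follows:

* *Stack versus volume.* Written stacks use `ispg = 0, mz = 1, nz = n`;
  volumes use `ispg = 1, mz = nz`. On read, `ispg = 1` means volume and
  `ispg = 0` with `nz > 1` means stack. This is the common interpretation of
  the MRC2014 space-group field.
* *Byte order.* Files are always written little-endian with machine stamp
  `0x44 0x44 0x00 0x00`; reads honour the stamp and byte-swap when it
  declares big-endian. Deterministic output beats native-order output.
* *Unrepresentable dtypes.* uint8 widens losslessly to mode 6; int32 and
  float64 narrow to mode 2 under the handle's cast policy. Complex and
  packed modes (3, 4, 101) are rejected.
* *Statistics.* `dmin`/`dmax`/`dmean`/`rms` are finalized from per-item
  moments so that after `close_image_file()` they describe the entire data
  section exactly (up to float32 header storage).
* *Extended headers* (`nsymbt > 0`) are preserved opaquely in
  `header_meta$extended_header` on read and never written: round-trip safety
  without pretending to understand vendor blocks.

**SPIDER.** The float-encoded header follows the published geometry rules:
`lenbyt = nsam * 4`, `labrec` the smallest integer with `labrec * lenbyt >=
1024`, `labbyt = labrec * lenbyt`. The package writes single-image (iform 1)
and single-volume (iform 3) files only — the stack-splitting workflow writes
one file per particle — while SPIDER stack files (`istack > 0`) are
read-supported. SPIDER has no endianness stamp, so the reader validates the
header geometry under little-endian first and retries big-endian; a file
failing both is rejected as malformed.

Both writers are cross-checked in the test suite against byte-level
reference writers and parsers (`write_reference_mrc()`, `ref_parse_mrc()`,
...) implemented directly from the format documentation with no shared code.

## Fourier transforms and rescaling

The transform convention is fixed package-wide: unnormalized forward (DC
coefficient = sum of pixel values), 1/N on the inverse. Spectra live in the
half-spectrum layout (non-negative x frequencies, `floor(x/2) + 1` columns);
the redundant half is reconstructed by Hermitian symmetry when needed. The
FFT backend is R's built-in `stats::fft`, wrapped to this contract; the test
suite checks it against `naive_dft()`, a direct O(N^2) evaluation of the
transform definition.

`spectral_resize()` implements Fourier cropping/padding: downscaling keeps
the centred low-frequency block, upscaling embeds the source spectrum in a
larger zero grid, and coefficients are rescaled by N_new/N_old so the
inverse preserves the real-space mean *exactly* (the DC term is never
altered). Two boundary choices needed fixing:

* *Even-grid Nyquist.* When cropping to even extent m, the kept block spans
  frequencies -m/2 .. m/2-1, so the new Nyquist row/column carries the
  source's -m/2 bin. Hermitian symmetry is then re-enforced as
  `X[k] <- (X[k] + conj(X[-k])) / 2`, which averages the two source Nyquist
  partners, guarantees a real inverse, and on upscaling performs the
  standard Nyquist-splitting. The same rule is implemented independently in
  the test oracle.
* *Odd targets are rejected.* Splitting a Nyquist bin across an odd grid has
  no canonical answer; restricting to even extents removes the ambiguity
  rather than hiding a convention inside the function.

## Processors and the pipeline

Processors are named parameter sets with a single `process()` contract:
**out-of-place** (the input image is never mutated) and **per item** (a
stack is processed image by image, so `process(p, stack)[i] ==
process(p, stack[i])` bit-for-bit). Out-of-place processing was chosen over
in-place mutation because it makes composition, caching and testing trivial;
in-place execution is an optimization that can be added behind the same
contract later.

* `math_proc()` computes in float64 regardless of the input dtype and casts
  back under round-clamp, so integer images cannot overflow mid-expression —
  they saturate only at the final store. A zero divisor is rejected at
  construction, not at application time.
* `scale_proc()` runs the spectral resize. Output precision follows the
  input: float64 stays float64, everything else becomes float32. (An early
  design always emitted float32; it was dropped because rounding N output
  pixels to float32 injects a relative mean error on the order of
  eps32/sqrt(N), silently discarding the exact mean preservation the
  spectral path provides. Precision present in the input is never thrown
  away.) The pixel size divides by the per-axis scale factor — half the
  pixels means twice the Angstrom per pixel; for anisotropic targets the x
  factor is used. Factor-form targets round to the nearest even extent.
* `window_proc()` crops or pads in real space around the centre: for an
  extent change Delta the left/top margin is `floor(Delta/2)`, which makes
  pad-then-crop an exact identity.
* `lowpass_proc()` multiplies the spectrum by a raised-cosine mask: 1 below
  `cutoff - edge_width`, 0 at and above `cutoff`, half-cosine in between.
  The default edge width of 0.02 cycles/pixel is the conventional
  anti-ringing compromise — a hard mask (`edge_width = 0`) rings visibly in
  real space. The radial frequency is saturated at the Nyquist radius 0.5:
  grid corners lie at |f| up to 0.707 and would otherwise be attenuated even
  by a "pass everything" cutoff of 0.5; with the saturation, cutoff 0.5 with
  a zero edge is the exact identity. The DC bin is never touched (mean
  preserved) and the mask never exceeds 1 (spectral energy cannot grow).

`pipe_proc()` concatenates processors; execution is strictly sequential in
insertion order, intermediates stay in memory and are never exposed, and a
failing step aborts the whole run (the error names the step index). Parallel
or DAG-shaped execution is deliberately out of scope.

## Tables, STAR and the filter grammar

An `em_table` is a tibble carrying explicit metadata column types
(int/float/string/bool); missing values are `NA` in memory, the tokens `.`
or `?` in STAR files (written back as `.`), and empty fields in TSV. Column
types on file read are inferred deterministically and
order-independently: int if every non-missing token is an integer literal,
else float if every token parses as a number, else string. A column whose
tokens are all missing carries no type evidence and reads back as string.

`write_star()` emits the RELION dialect — `data_` blocks, `loop_` tables,
`_label #N` ordinals — and serializes floats with the *shortest* decimal
representation that round-trips through parsing, so STAR and TSV round trips
are value-exact without fixed-width formatting loss. Strings are quoted when
they contain whitespace or look like markup; a string containing both quote
characters is rejected rather than half-escaped (STAR has no escape
sequence). Multi-line semicolon text fields are read, never written.
Key-value blocks parse as single-row tables; on write every table becomes a
loop, which preserves names, order, row count and values (the round-trip
contract) but not the key-value surface form.

`table_filter()` accepts a deliberately small grammar: the six comparison
operators over columns and literals, combined with `and`/`or`/`not` and
parentheses. Expressions are parsed with R's parser and then the AST is
whitelisted — arithmetic, function calls and anything else are rejected —
and comparisons are type-checked against the column types (ordering a string
column against a number is an error, not a coercion). Rows where the
predicate is missing are dropped. Sorting uses a stable radix sort (ties
keep input order, C-locale string comparison) so sorting is idempotent and
reproducible across platforms.

## Command-line tools

`em-image` applies its operation flags *in command-line order* as one
pipeline — the flag order is the pipeline, making the no-intermediate-files
semantics visible in the invocation. `em-table` instead fixes its operation
order (filter, then sort, then column selection) because relational
operations have an expected algebraic order regardless of flag position.
Stack positions on the command line are 1-based (`3@stack.mrcs`), following
the EM field convention, while the R API is 0-based. Every output is written
to a temporary file in the destination directory and atomically renamed, so
a failing invocation exits non-zero with a one-line diagnostic and leaves no
partial output. The tools are thin wrappers over `em_image_cli()` /
`em_table_cli()`, which the test suite drives both in-process and as
subprocesses.

## What the synthetic data does and does not emulate

All test inputs are generated by the fixtures module: seeded phantoms
(constant, impulse, checkerboard, centred Gaussian blob with sigma =
min(y, x)/6 and peak 1, uniform noise in [0, 1)), reference-format files
written byte-by-byte from the specifications, and a toy four-row metadata
table (defocus values 1.2, 2.5, 1.8, 3.0 micrometres-like numbers, one
quoted string with a space, one missing field) exercising the STAR corner
cases. Identical spec and seed reproduce bit-identical buffers, and the
generator restores the caller's RNG state.

These phantoms validate *containers, formats and transforms*: bit-exact
round trips, header conventions, spectral identities, grammar semantics.
They are not realistic cryo-EM data — there is no contrast transfer
function, no structured noise, no projection geometry, no dose weighting.
Passing tests therefore certify that the plumbing is exact, not that any
scientific processing decision (filter radii, scale factors) is appropriate
for real micrographs.

## Problem sizes and runtime

The test suite and the acceptance script size their inputs to what the
oracles can verify exhaustively: images of 4–64 pixels per axis (the naive
DFT oracle is capped at 4096 elements), stacks of up to 10 items, 200
randomized STAR documents of up to 50 rows by 8 columns, and 100-row tables
for the statistics oracles. The full suite runs in about a minute on one
CPU; every check is deterministic under fixed seeds.

## Known limitations

* MRC modes 3/4 (complex) and 101 (packed 4-bit), TIFF/EER/HDF5, and
  writing SPIDER stack files are unsupported.
* `spectral_resize()` requires even extents on resized axes.
* int64 is not an element type: R doubles cannot represent all 64-bit
  integers exactly, which would break the "storage is lossless" invariant.
* The filter grammar has no arithmetic or string functions; complex row
  selection belongs in R code, not in the mini-language.
* Boolean table columns serialize to STAR as 0/1 and read back as int: the
  STAR dialect has no boolean token, so the type does not survive a round
  trip.
* A volume stack (`n > 1, z > 1`) can exist in memory but not in a file
  written by this package.
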