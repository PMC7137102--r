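# Deterministic test-input generation and independent oracles. Everything
# here is deliberately written from first principles — the reference MRC and
# SPIDER writers/parsers implement the public format specifications byte by
# byte and share no code with the imageio module, and the naive DFT
# evaluates the transform definition directly — so agreement between these
# functions and the main modules is a genuine cross-implementation check.

#' Describe a deterministic phantom image
#'
#' @param dims Dimensions in `(n, z, y, x)` order (2- and 3-element vectors
#'   are promoted, as in [image_create()]).
#' @param pattern One of `"constant"`, `"impulse"`, `"checkerboard"`,
#'   `"gaussian-blob"`, `"uniform-noise"`.
#' @param seed Integer seed; the same spec and seed always produce a
#'   bit-identical buffer.
#' @param dtype Element type of the result.
#' @param value Constant value for the `"constant"` pattern.
#' @param pixel_size Optional pixel size carried by the phantom.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dims, pattern = "uniform-noise", seed = 1L,
                         dtype = "float32", value = 1,
                         pixel_size = NULL) {
  pattern <- match.arg(pattern, c("constant", "impulse", "checkerboard",
                                  "gaussian-blob", "uniform-noise"))
  structure(list(dims = .as_dims4(dims), pattern = pattern,
                 seed = as.integer(seed), dtype = dtype, value = value,
                 pixel_size = pixel_size),
            class = "phantom_spec")
}

#' Generate a phantom image
#'
#' Produces the deterministic test image described by a [phantom_spec()]:
#' a constant field, a unit impulse at `(y/2, x/2)` (zero-based), a 0/1
#' checkerboard, a centred 2-D Gaussian blob with `sigma = min(y, x) / 6`
#' and peak 1, or seeded uniform noise in `[0, 1)`.
#'
#' @param spec A `phantom_spec` (or arguments forwarded to [phantom_spec()]).
#' @param ... Forwarded to [phantom_spec()] when `spec` is a dims vector.
#' @return An `em_image`.
#' @export
make_phantom <- function(spec, ...) {
  if (!inherits(spec, "phantom_spec")) spec <- phantom_spec(spec, ...)
  d <- spec$dims
  nx <- d[["x"]]; ny <- d[["y"]]; nz <- d[["z"]]; n <- d[["n"]]
  total <- as.double(nx) * ny * nz * n
  buf <- switch(spec$pattern,
    constant = rep(as.double(spec$value), total),
    impulse = {
      sl <- numeric(nx * ny)
      sl[(ny %/% 2) * nx + nx %/% 2 + 1L] <- 1   # (y/2, x/2), zero-based
      rep(c(sl, numeric(nx * ny * (nz - 1L))), n)
    },
    checkerboard = {
      xi <- rep(seq_len(nx) - 1L, times = ny * nz * n)
      yi <- rep(rep(seq_len(ny) - 1L, each = nx), times = nz * n)
      as.double((xi + yi) %% 2L)
    },
    `gaussian-blob` = {
      sigma <- min(ny, nx) / 6
      cx <- nx %/% 2; cy <- ny %/% 2
      g <- outer(seq_len(nx) - 1L, seq_len(ny) - 1L, function(x, y) {
        exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2))
      })
      rep(as.vector(g), nz * n)
    },
    `uniform-noise` = {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
      set.seed(spec$seed, kind = "Mersenne-Twister")
      stats::runif(total)
    })
  buf <- dtype_cast(buf, "float64", spec$dtype)
  .new_em_image(array(buf, dim = c(nx, ny, nz, n)), spec$dtype,
                spec$pixel_size)
}

# --- independent byte-level reference writers ------------------------------

#' Write a reference MRC file directly from the format specification
#'
#' Emits the phantom described by `spec` as an MRC2014 file, constructing
#' the 1024-byte header field by field at the documented byte offsets —
#' independently of the package's own MRC writer — and returns the source
#' buffer so callers can check bit-exact agreement.
#'
#' @param path Output path.
#' @param spec A [phantom_spec()]. Float dtypes map to mode 2, int8 to mode
#'   0, int16 to mode 1, uint16 to mode 6.
#' @return Invisibly, a list with `path`, the retained `image` (an
#'   `em_image`), and the written `mode`.
#' @export
write_reference_mrc <- function(path, spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  img <- make_phantom(spec)
  d <- spec$dims
  mode <- switch(spec$dtype, int8 = 0L, int16 = 1L, uint16 = 6L,
                 float32 = 2L, float64 = 2L,
                 stop("reference writer supports int8/int16/uint16/float: ",
                      spec$dtype, call. = FALSE))
  volume <- d[["z"]] > 1L
  nx <- d[["x"]]; ny <- d[["y"]]
  nz <- if (volume) d[["z"]] else d[["n"]]
  mz <- if (volume) d[["z"]] else 1L
  ps <- if (is.null(spec$pixel_size)) 0 else spec$pixel_size
  m <- .buffer_moments(img$data)

  int_w <- function(v) writeBin(as.integer(v), raw(), size = 4L,
                                endian = "little")
  flt_w <- function(v) writeBin(as.double(v), raw(), size = 4L,
                                endian = "little")
  hdr <- raw(1024L)
  put <- function(word, bytes) {
    off <- (word - 1L) * 4L
    hdr[(off + 1L):(off + length(bytes))] <<- bytes
  }
  put(1L, int_w(nx)); put(2L, int_w(ny)); put(3L, int_w(nz))
  put(4L, int_w(mode))
  put(8L, int_w(nx)); put(9L, int_w(ny)); put(10L, int_w(mz))
  put(11L, flt_w(ps * nx)); put(12L, flt_w(ps * ny)); put(13L, flt_w(ps * mz))
  put(14L, flt_w(90)); put(15L, flt_w(90)); put(16L, flt_w(90))
  put(17L, int_w(1L)); put(18L, int_w(2L)); put(19L, int_w(3L))
  put(20L, flt_w(m[1])); put(21L, flt_w(m[2])); put(22L, flt_w(m[3]))
  put(23L, int_w(if (volume) 1L else 0L))
  put(24L, int_w(0L))
  put(53L, charToRaw("MAP "))
  put(54L, as.raw(c(0x44, 0x44, 0x00, 0x00)))
  put(55L, flt_w(m[4]))
  put(56L, int_w(0L))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  v <- as.vector(img$data)
  if (mode == 2L) {
    writeBin(as.double(v), con, size = 4L, endian = "little")
  } else {
    writeBin(as.integer(v), con, size = if (mode == 0L) 1L else 2L,
             endian = "little")
  }
  invisible(list(path = path, image = img, mode = mode))
}

#' Write a reference SPIDER file directly from the format specification
#'
#' Emits the phantom as a single-image (iform 1) or single-volume (iform 3)
#' SPIDER file, building the float-encoded header from the documented word
#' numbers and the labrec/labbyt/lenbyt geometry rules, independently of the
#' package's own writer. Pixel data are float32.
#'
#' @param path Output path.
#' @param spec A [phantom_spec()] with `n = 1`.
#' @return Invisibly, a list with `path` and the retained `image` (cast to
#'   float32, as the format stores).
#' @export
write_reference_spider <- function(path, spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims
  if (d[["n"]] != 1L) {
    stop("reference SPIDER writer emits single-image files", call. = FALSE)
  }
  img <- make_phantom(spec)
  v <- dtype_cast(img$data, img$dtype, "float32")
  nx <- d[["x"]]; ny <- d[["y"]]; nz <- d[["z"]]
  lenbyt <- nx * 4
  labrec <- ceiling(1024 / lenbyt)
  labbyt <- labrec * lenbyt
  m <- .buffer_moments(v)
  w <- numeric(labbyt / 4)
  w[1] <- nz                       # NSLICE
  w[2] <- ny                       # NROW
  w[3] <- ny * nz                  # IREC
  w[5] <- if (nz > 1L) 3 else 1    # IFORM
  w[6] <- 1                        # IMAMI
  w[7] <- m[2]; w[8] <- m[1]       # FMAX, FMIN
  w[9] <- m[3]; w[10] <- m[4]      # AV, SIG
  w[12] <- nx                      # NSAM
  w[13] <- labrec                  # LABREC
  w[21] <- if (is.null(spec$pixel_size)) 0 else spec$pixel_size  # SCALE
  w[22] <- labbyt; w[23] <- lenbyt
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(w, con, size = 4L, endian = "little")
  writeBin(as.double(as.vector(v)), con, size = 4L, endian = "little")
  img32 <- .new_em_image(array(v, dim = dim(img$data)), "float32",
                         spec$pixel_size)
  invisible(list(path = path, image = img32))
}

# --- independent reference header parsers ----------------------------------

#' Parse an MRC header with the independent reference parser
#'
#' Reads the documented header fields straight from their byte offsets
#' (little-endian), sharing no code with the package's MRC reader. Used to
#' check field-identity of files the package writes.
#'
#' @param path Path to an MRC file.
#' @return A list of header fields: `nx`, `ny`, `nz`, `mode`, `mx`, `my`,
#'   `mz`, `cella`, `dmin`, `dmax`, `dmean`, `ispg`, `nsymbt`, `map_id`,
#'   `machst`, `rms`.
#' @export
ref_parse_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 1024L)
  stopifnot(length(hdr) == 1024L)
  gi <- function(word) readBin(hdr[((word - 1L) * 4L + 1L):(word * 4L)],
                               "integer", size = 4L, endian = "little")
  gf <- function(word) readBin(hdr[((word - 1L) * 4L + 1L):(word * 4L)],
                               "double", size = 4L, endian = "little")
  list(nx = gi(1), ny = gi(2), nz = gi(3), mode = gi(4),
       mx = gi(8), my = gi(9), mz = gi(10),
       cella = c(gf(11), gf(12), gf(13)),
       dmin = gf(20), dmax = gf(21), dmean = gf(22),
       ispg = gi(23), nsymbt = gi(24),
       map_id = rawToChar(hdr[209:212]),
       machst = hdr[213:216],
       rms = gf(55))
}

#' Parse a SPIDER header with the independent reference parser
#'
#' @param path Path to a SPIDER file.
#' @return A list of header fields: `nslice`, `nrow`, `irec`, `iform`,
#'   `fmax`, `fmin`, `av`, `sig`, `nsam`, `labrec`, `scale`, `labbyt`,
#'   `lenbyt`, `istack`, `maxim`.
#' @export
ref_parse_spider <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  w <- readBin(con, "double", n = 256L, size = 4L, endian = "little")
  list(nslice = w[1], nrow = w[2], irec = w[3], iform = w[5],
       fmax = w[7], fmin = w[8], av = w[9], sig = w[10],
       nsam = w[12], labrec = w[13], scale = w[21], labbyt = w[22],
       lenbyt = w[23], istack = w[24], maxim = w[26])
}

# --- toy STAR fixture ------------------------------------------------------

#' Write the toy STAR fixture
#'
#' Emits a small one-block loop table with a minimal serializer independent
#' of [write_star()]: columns `id` (int), `defocus` (float), `name` (string,
#' one value with an embedded space, quoted) and `group` (string with one
#' missing value written as `.`).
#'
#' @param path Output path.
#' @return Invisibly, the expected parse result as an `em_table`.
#' @export
make_toy_star <- function(path) {
  lines <- c(
    "",
    "# toy micrograph table",
    "data_micrographs",
    "",
    "loop_",
    "_id #1",
    "_defocus #2",
    "_name #3",
    "_group #4",
    "1 1.2 mic_a g1",
    "2 2.5 mic_b g1",
    "3 1.8 \"mic c\" g2",
    "4 3.0 mic_d .",
    "")
  writeLines(lines, path)
  expected <- em_table(tibble::tibble(
    id = 1:4,
    defocus = c(1.2, 2.5, 1.8, 3.0),
    name = c("mic_a", "mic_b", "mic c", "mic_d"),
    group = c("g1", "g1", "g2", NA_character_)))
  invisible(expected)
}

#' Minimal independent STAR loop parser (oracle)
#'
#' A deliberately small re-implementation of STAR loop parsing — regex and
#' string splitting only, sharing no code with [read_star()] — used to check
#' that documents written by [write_star()] parse identically under a second
#' implementation. Handles `data_` blocks containing one `loop_` each, with
#' optional `#N` label ordinals, quoted tokens and full-line comments.
#'
#' @param path Path to a STAR file.
#' @return A named list (one entry per block) of lists with `labels` and
#'   `rows` (character matrix of raw tokens, one row per data line; quotes
#'   stripped, missing markers kept verbatim).
#' @export
ref_parse_star_loop <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  blocks <- list()
  cur <- NULL
  labels <- character(0)
  rows <- list()
  flush <- function() {
    if (!is.null(cur)) {
      mat <- if (length(rows)) do.call(rbind, rows) else
        matrix(character(0), ncol = length(labels))
      blocks[[cur]] <<- list(labels = labels, rows = mat)
    }
  }
  for (l in lines) {
    if (grepl("^data_", l)) {
      flush()
      cur <- sub("^data_", "", l)
      labels <- character(0)
      rows <- list()
    } else if (l == "loop_") {
      # nothing to do
    } else if (grepl("^_", l)) {
      labels <- c(labels, sub("^_([^ \t]+).*$", "\\1", l))
    } else {
      toks <- regmatches(l, gregexpr(
        "\"[^\"]*\"|'[^']*'|[^ \t]+", l))[[1]]
      toks <- sub("^[\"']", "", sub("[\"']$", "", toks))
      rows[[length(rows) + 1L]] <- toks
    }
  }
  flush()
  blocks
}

# --- naive DFT oracle ------------------------------------------------------

#' Naive discrete Fourier transform (oracle)
#'
#' Evaluates the full complex DFT directly from its defining sum in O(N^2)
#' operations, with no FFT and no code shared with [em_fft_forward()].
#' Unnormalized, like the package's forward transform. Capped at 4096
#' elements to keep oracle comparisons fast.
#'
#' @param buffer Numeric (or complex) vector or array of the real-space
#'   values, x fastest.
#' @param dims Spatial dims `(x, y)` or `(x, y, z)` of the buffer.
#' @return A complex array of the same dims holding the full spectrum.
#' @export
naive_dft <- function(buffer, dims) {
  dims_in <- as.integer(dims)
  dims <- if (length(dims_in) == 2L) c(dims_in, 1L) else dims_in
  stopifnot(length(dims) == 3L, prod(dims) == length(buffer))
  if (prod(dims) > 4096L) {
    stop("naive_dft capped at 4096 elements", call. = FALSE)
  }
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  x <- array(as.complex(buffer), dim = dims)
  out <- array(complex(1), dim = dims)
  wx <- exp(-2i * pi * outer(seq_len(nx) - 1L, seq_len(nx) - 1L) / nx)
  wy <- exp(-2i * pi * outer(seq_len(ny) - 1L, seq_len(ny) - 1L) / ny)
  wz <- exp(-2i * pi * outer(seq_len(nz) - 1L, seq_len(nz) - 1L) / nz)
  for (kz in seq_len(nz)) for (ky in seq_len(ny)) for (kx in seq_len(nx)) {
    phase <- outer(wx[kx, ], wy[ky, ]) %o% wz[kz, ]
    out[kx, ky, kz] <- sum(x * phase)
  }
  dim(out) <- dims_in
  out
}

#' Naive inverse DFT (oracle)
#'
#' Inverse transform computed through the conjugation identity
#' `idft(X) = conj(dft(conj(X))) / N`, reusing only [naive_dft()].
#'
#' @param spectrum Complex array (full layout).
#' @param dims Spatial dims as in [naive_dft()].
#' @return A complex array; take `Re()` for a Hermitian spectrum.
#' @export
naive_idft <- function(spectrum, dims) {
  Conj(naive_dft(Conj(spectrum), dims)) / length(spectrum)
}

# --- fixture set -----------------------------------------------------------

#' Materialize the standard fixture files
#'
#' Writes the reference MRC stack, MRC volume, SPIDER image, SPIDER volume
#' and toy STAR table into a directory, for manual inspection or ad-hoc
#' testing. (The test suite generates these on the fly instead.)
#'
#' @param dir Output directory, created if needed.
#' @return Character vector of the files written.
#' @export
make_fixture_set <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_reference_mrc(p("stack_16x16x10.mrcs"),
                      phantom_spec(c(10, 1, 16, 16), "uniform-noise",
                                   seed = 42L, dtype = "float32",
                                   pixel_size = 1.0))
  write_reference_mrc(p("volume_16x16x8.mrc"),
                      phantom_spec(c(1, 8, 16, 16), "gaussian-blob",
                                   dtype = "float32", pixel_size = 1.0))
  write_reference_mrc(p("image_int8.mrc"),
                      phantom_spec(c(1, 1, 16, 16), "checkerboard",
                                   dtype = "int8"))
  write_reference_spider(p("image_16x16.spi"),
                         phantom_spec(c(1, 1, 16, 16), "uniform-noise",
                                      seed = 7L, dtype = "float32"))
  write_reference_spider(p("volume_16x16x8.spi"),
                         phantom_spec(c(1, 8, 16, 16), "uniform-noise",
                                      seed = 8L, dtype = "float32"))
  make_toy_star(p("toy.star"))
  list.files(dir, full.names = TRUE)
}
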