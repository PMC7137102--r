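# Format-dispatched image I/O: byte-exact MRC2014 and SPIDER handlers behind
# one handle type. Conventions (fixed here, since the formats leave them
# open): files are always written little-endian with machine stamp
# 0x44 0x44 0x00 0x00; reads honour the stamp and byte-swap when needed.
# MRC stacks are written with ispg = 0, mz = 1, nz = n; volumes with
# ispg = 1, mz = nz. On read, ispg = 0 with nz > 1 means a stack and
# ispg = 1 a volume.

.EXT_FORMAT <- c(mrc = "mrc", mrcs = "mrc", map = "mrc",
                 spi = "spider", spider = "spider", stk = "spider")

.MRC_MODE_OF <- c(int8 = 0L, int16 = 1L, float32 = 2L, uint16 = 6L)
.MRC_DTYPE_OF <- c(`0` = "int8", `1` = "int16", `2` = "float32",
                   `6` = "uint16")

# nearest MRC-writable dtype for each supported dtype
.mrc_write_dtype <- function(dtype) {
  switch(dtype,
         int8 = "int8", int16 = "int16", float32 = "float32",
         uint16 = "uint16",
         uint8 = "uint16",      # lossless widening
         int32 = "float32",     # narrowed under the handle's cast policy
         float64 = "float32",
         stop("unsupported dtype for MRC: ", dtype, call. = FALSE))
}

.format_from_ext <- function(path) {
  ext <- tolower(tools::file_ext(path))
  fmt <- .EXT_FORMAT[ext]
  if (is.na(fmt)) {
    stop("cannot infer image format from extension '.", ext,
         "'; pass format explicitly", call. = FALSE)
  }
  unname(fmt)
}

.elem_bytes <- function(dtype) .dtype_info(dtype)$bits %/% 8L

# --- MRC header ------------------------------------------------------------

.mrc_parse_header <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024) {
    stop("malformed MRC header: file '", path, "' shorter than 1024 bytes",
         call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 1024L)
  if (!identical(rawToChar(hdr[209:212]), "MAP ")) {
    stop("malformed MRC header: missing 'MAP ' magic", call. = FALSE)
  }
  endian <- if (hdr[213] == as.raw(0x11)) "big" else "little"
  ri <- function(off) readBin(hdr[(off + 1):(off + 4)], "integer",
                              size = 4L, endian = endian)
  rf <- function(off) readBin(hdr[(off + 1):(off + 4)], "double",
                              size = 4L, endian = endian)
  h <- list(
    nx = ri(0), ny = ri(4), nz = ri(8), mode = ri(12),
    mx = ri(28), my = ri(32), mz = ri(36),
    cella = c(rf(40), rf(44), rf(48)),
    dmin = rf(76), dmax = rf(80), dmean = rf(84),
    ispg = ri(88), nsymbt = ri(92),
    rms = rf(216), nlabl = ri(220),
    endian = endian
  )
  if (h$nx < 1 || h$ny < 1 || h$nz < 1) {
    stop("malformed MRC header: non-positive dimensions", call. = FALSE)
  }
  if (!as.character(h$mode) %in% names(.MRC_DTYPE_OF)) {
    stop("unsupported MRC mode ", h$mode,
         " (supported: 0, 1, 2, 6)", call. = FALSE)
  }
  if (h$nsymbt < 0 || sz < 1024 + h$nsymbt) {
    stop("malformed MRC header: bad extended-header length", call. = FALSE)
  }
  if (h$nsymbt > 0) {
    h$extended_header <- readBin(con, "raw", n = h$nsymbt)
  }
  h
}

.mrc_build_header <- function(nx, ny, nz, mode, mz, cella, ispg,
                              stats = c(0, 0, 0, -1)) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4L,
                             endian = "little")
  wf <- function(v) writeBin(as.double(v), con, size = 4L,
                             endian = "little")
  wi(c(nx, ny, nz, mode, 0L, 0L, 0L, nx, ny, mz))       # words 1-10
  wf(c(cella, 90, 90, 90))                              # cella, cellb
  wi(c(1L, 2L, 3L))                                     # mapc/mapr/maps
  wf(stats[1:3])                                        # dmin/dmax/dmean
  wi(c(ispg, 0L))                                       # ispg, nsymbt
  writeBin(raw(100L), con)                              # extra, words 25-49
  wf(c(0, 0, 0))                                        # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)      # machine stamp
  wf(stats[4])                                          # rms
  wi(0L)                                                # nlabl
  writeBin(raw(800L), con)                              # labels
  hdr <- rawConnectionValue(con)
  stopifnot(length(hdr) == 1024L)
  hdr
}

# --- SPIDER header ---------------------------------------------------------

.spider_geometry <- function(nx) {
  lenbyt <- nx * 4L
  labrec <- as.integer(ceiling(1024 / lenbyt))
  list(lenbyt = lenbyt, labrec = labrec, labbyt = labrec * lenbyt)
}

.spider_try_header <- function(hdr_raw, endian) {
  w <- readBin(hdr_raw, "double", n = length(hdr_raw) %/% 4L, size = 4L,
               endian = endian)
  get <- function(i) if (i <= length(w)) w[i] else NA_real_
  h <- list(nslice = get(1), nrow = get(2), iform = get(5),
            imami = get(6), fmax = get(7), fmin = get(8), av = get(9),
            sig = get(10), nsam = get(12), labrec = get(13),
            scale = get(21), labbyt = get(22), lenbyt = get(23),
            istack = get(24), maxim = get(26), endian = endian)
  ok <- function(v) length(v) == 1L && is.finite(v) && v == round(v)
  if (!ok(h$nsam) || !ok(h$nrow) || !ok(h$nslice) || !ok(h$labrec) ||
      !ok(h$labbyt) || !ok(h$lenbyt) ||
      h$nsam < 1 || h$nrow < 1 || h$nslice < 1) {
    return(NULL)
  }
  geo <- .spider_geometry(as.integer(h$nsam))
  if (h$lenbyt != geo$lenbyt || h$labbyt != h$labrec * h$lenbyt ||
      h$labrec * h$lenbyt < 1024) {
    return(NULL)
  }
  if (!h$iform %in% c(1, 3)) return(NULL)
  if (h$iform == 1 && h$nslice > 1) return(NULL)
  h
}

.spider_parse_header <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024) {
    stop("malformed SPIDER header: file '", path,
         "' shorter than 1024 bytes", call. = FALSE)
  }
  con <- file(path, "rb")
  hdr_raw <- readBin(con, "raw", n = 1024L)
  close(con)
  h <- .spider_try_header(hdr_raw, "little")
  if (is.null(h)) h <- .spider_try_header(hdr_raw, "big")
  if (is.null(h)) {
    stop("malformed SPIDER header: geometry check failed", call. = FALSE)
  }
  h
}

.spider_build_header <- function(nx, ny, nz, iform, stats, scale) {
  geo <- .spider_geometry(nx)
  w <- numeric(geo$labbyt %/% 4L)
  w[1] <- nz; w[2] <- ny; w[3] <- ny * nz; w[5] <- iform
  w[6] <- 1                                    # imami: stats below are valid
  w[7] <- stats[2]; w[8] <- stats[1]           # fmax, fmin
  w[9] <- stats[3]; w[10] <- stats[4]          # av, sig
  w[12] <- nx; w[13] <- geo$labrec
  w[21] <- scale
  w[22] <- geo$labbyt; w[23] <- geo$lenbyt
  writeBin(w, raw(), size = 4L, endian = "little")
}

# --- handle ----------------------------------------------------------------

#' Open an image file
#'
#' Opens an MRC2014 or SPIDER file and returns a handle bound to that
#' format's implementation. For readable modes the header is parsed
#' immediately, so the handle reports dimensions, element type and pixel
#' size without touching the data section.
#'
#' @param path File path. The format is inferred from the extension
#'   (`.mrc`/`.mrcs`/`.map` are MRC; `.spi`/`.spider`/`.stk` are SPIDER)
#'   unless `format` is given.
#' @param mode `"read"`, `"write"` or `"read-write"`.
#' @param format `"mrc"`, `"spider"`, or `NULL` to infer from the extension.
#' @param cast_policy Narrowing policy used when written images must be
#'   converted to a file-representable element type (see [dtype_cast()]).
#' @return An `em_image_file` handle with fields `dims` (`n`,`z`,`y`,`x`),
#'   `dtype`, `pixel_size` and `header_meta`.
#' @export
open_image_file <- function(path, mode = c("read", "write", "read-write"),
                            format = NULL,
                            cast_policy = c("round-clamp",
                                            "error-on-overflow")) {
  mode <- match.arg(mode)
  cast_policy <- match.arg(cast_policy)
  if (is.null(format)) format <- .format_from_ext(path)
  if (!format %in% c("mrc", "spider")) {
    stop("unknown image format: ", format, call. = FALSE)
  }
  h <- new.env(parent = emptyenv())
  h$path <- path
  h$mode <- mode
  h$format <- format
  h$cast_policy <- cast_policy
  h$dims <- NULL
  h$dtype <- NULL
  h$pixel_size <- NULL
  h$header_meta <- list()
  h$item_moments <- list()   # per-item (min, max, sum, sumsq, count)
  class(h) <- "em_image_file"

  if (mode %in% c("read", "read-write")) {
    if (dir.exists(path)) {
      stop("'", path, "' is a directory, not an image file", call. = FALSE)
    }
    if (!file.exists(path)) {
      stop("file not found: ", path, call. = FALSE)
    }
    if (format == "mrc") .mrc_bind_header(h) else .spider_bind_header(h)
  }
  h
}

.mrc_bind_header <- function(h) {
  hd <- .mrc_parse_header(h$path)
  dims <- if (hd$ispg == 1) {
    c(n = 1L, z = as.integer(hd$nz), y = as.integer(hd$ny),
      x = as.integer(hd$nx))
  } else {
    c(n = as.integer(hd$nz), z = 1L, y = as.integer(hd$ny),
      x = as.integer(hd$nx))
  }
  h$dims <- dims
  h$dtype <- unname(.MRC_DTYPE_OF[as.character(hd$mode)])
  h$pixel_size <- if (hd$mx > 0 && hd$cella[1] > 0) hd$cella[1] / hd$mx
                  else NULL
  h$header_meta <- hd
  invisible(h)
}

.spider_bind_header <- function(h) {
  hd <- .spider_parse_header(h$path)
  if (hd$istack > 0) {
    n <- as.integer(hd$maxim)
    if (is.na(n) || n < 1) {
      stop("malformed SPIDER stack header: bad maxim", call. = FALSE)
    }
    dims <- c(n = n, z = 1L, y = as.integer(hd$nrow),
              x = as.integer(hd$nsam))
  } else {
    dims <- c(n = 1L, z = as.integer(hd$nslice),
              y = as.integer(hd$nrow), x = as.integer(hd$nsam))
  }
  h$dims <- dims
  h$dtype <- "float32"
  h$pixel_size <- if (is.finite(hd$scale) && hd$scale > 0) hd$scale else NULL
  h$header_meta <- hd
  invisible(h)
}

#' @export
print.em_image_file <- function(x, ...) {
  d <- x$dims
  cat(sprintf("<em_image_file> %s [%s, %s]%s\n", x$path, x$format, x$mode,
              if (is.null(d)) " (no data yet)" else
                sprintf("  n=%d z=%d y=%d x=%d %s",
                        d["n"], d["z"], d["y"], d["x"], x$dtype)))
  invisible(x)
}

# --- reading ---------------------------------------------------------------

#' Read one image from an open file
#'
#' Reads the item at a zero-based index. The returned image keeps the file's
#' element type (no silent cast on read); pixel size and the parsed source
#' header travel along in `pixel_size` / `header_meta`.
#'
#' @param h An `em_image_file` opened readable.
#' @param index Zero-based item index (`0` for single images and volumes).
#' @return An `em_image` with `n = 1`.
#' @export
read_image <- function(h, index = 0) {
  stopifnot(inherits(h, "em_image_file"))
  if (is.null(h$dims)) {
    stop("no image data in handle (empty write handle?)", call. = FALSE)
  }
  n <- h$dims[["n"]]
  if (length(index) != 1L || is.na(index) || index < 0 || index >= n) {
    stop("image index ", index, " out of range [0, ", n - 1L, "]",
         call. = FALSE)
  }
  if (h$format == "mrc") .mrc_read_item(h, index)
  else .spider_read_item(h, index)
}

.mrc_read_item <- function(h, index) {
  d <- h$dims
  hd <- h$header_meta
  bytes <- .elem_bytes(h$dtype)
  item_elems <- as.double(d[["z"]]) * d[["y"]] * d[["x"]]
  offset <- 1024 + hd$nsymbt + index * item_elems * bytes
  con <- file(h$path, "rb")
  on.exit(close(con))
  seek(con, where = offset, origin = "start")
  buf <- switch(h$dtype,
    int8    = readBin(con, "integer", n = item_elems, size = 1L,
                      signed = TRUE, endian = hd$endian),
    int16   = readBin(con, "integer", n = item_elems, size = 2L,
                      signed = TRUE, endian = hd$endian),
    uint16  = readBin(con, "integer", n = item_elems, size = 2L,
                      signed = FALSE, endian = hd$endian),
    float32 = readBin(con, "double", n = item_elems, size = 4L,
                      endian = hd$endian))
  if (length(buf) < item_elems) {
    stop("truncated MRC data section in '", h$path, "'", call. = FALSE)
  }
  data <- array(as.double(buf), dim = c(d[["x"]], d[["y"]], d[["z"]], 1L))
  .new_em_image(data, h$dtype, h$pixel_size, hd)
}

.spider_read_item <- function(h, index) {
  d <- h$dims
  hd <- h$header_meta
  geo <- .spider_geometry(d[["x"]])
  item_elems <- as.double(d[["z"]]) * d[["y"]] * d[["x"]]
  offset <- if (hd$istack > 0) {
    # overall header, then per-image header + data blocks
    geo$labbyt + index * (geo$labbyt + item_elems * 4) + geo$labbyt
  } else {
    geo$labbyt
  }
  con <- file(h$path, "rb")
  on.exit(close(con))
  seek(con, where = offset, origin = "start")
  buf <- readBin(con, "double", n = item_elems, size = 4L,
                 endian = hd$endian)
  if (length(buf) < item_elems) {
    stop("truncated SPIDER data section in '", h$path, "'", call. = FALSE)
  }
  data <- array(buf, dim = c(d[["x"]], d[["y"]], d[["z"]], 1L))
  .new_em_image(data, "float32", h$pixel_size, hd)
}

# --- writing ---------------------------------------------------------------

.moments_of <- function(x) {
  c(min(x), max(x), sum(x), sum(x * x), length(x))
}

.combine_moments <- function(items) {
  m <- do.call(rbind, items)
  total <- sum(m[, 5])
  mean <- sum(m[, 3]) / total
  var <- sum(m[, 4]) / total - mean^2
  c(min(m[, 1]), max(m[, 2]), mean, sqrt(max(var, 0)))
}

#' Write one image into an open file
#'
#' Writes (or appends) an item at a zero-based index; `index` may be at most
#' the current item count, so stacks grow densely. SPIDER files always store
#' float32 and hold a single image or volume; MRC files store the mode
#' nearest to the first written image's dtype (uint8 widens to mode 6,
#' int32/float64 narrow to float32 under the handle's cast policy). The MRC
#' min/max/mean/RMS header statistics always reflect the full file content.
#'
#' @param h An `em_image_file` opened writable.
#' @param img A single-item `em_image` (a 2-D image, or a volume for
#'   single-volume files).
#' @param index Zero-based target position; default appends.
#' @return The handle, invisibly.
#' @export
write_image <- function(h, img, index = NULL) {
  stopifnot(inherits(h, "em_image_file"), is_em_image(img))
  if (h$mode == "read") {
    stop("handle is read-only", call. = FALSE)
  }
  d <- im_dims(img)
  if (d[["n"]] != 1L) {
    stop("write_image takes a single-item image; loop over the stack or ",
         "use write_em_image()", call. = FALSE)
  }
  cur_n <- if (is.null(h$dims)) 0L else h$dims[["n"]]
  if (is.null(index)) index <- cur_n
  if (index > cur_n) {
    stop("sparse write: index ", index, " but file holds ", cur_n,
         " item(s); append at ", cur_n, call. = FALSE)
  }
  if (!is.null(h$dims) &&
      !identical(unname(h$dims[c("z", "y", "x")]),
                 unname(d[c("z", "y", "x")]))) {
    stop("image geometry does not match the open file", call. = FALSE)
  }
  if (h$format == "spider") {
    if (index > 0) {
      stop("writing SPIDER stacks is not supported; write individual files",
           call. = FALSE)
    }
    .spider_write_single(h, img)
  } else {
    if (d[["z"]] > 1L && index > 0) {
      stop("an MRC volume file holds a single volume", call. = FALSE)
    }
    .mrc_write_item(h, img, index)
  }
  invisible(h)
}

.mrc_write_item <- function(h, img, index) {
  d <- im_dims(img)
  if (is.null(h$dtype)) {
    h$dtype <- .mrc_write_dtype(img$dtype)
    h$pixel_size <- img$pixel_size
  }
  buf <- dtype_cast(img$data, img$dtype, h$dtype, policy = h$cast_policy)
  h$item_moments[[index + 1L]] <- .moments_of(buf)
  n_new <- max(index + 1L, if (is.null(h$dims)) 0L else h$dims[["n"]])
  h$dims <- c(n = if (d[["z"]] > 1L) 1L else n_new,
              z = d[["z"]], y = d[["y"]], x = d[["x"]])

  con <- if (file.exists(h$path)) file(h$path, "r+b") else file(h$path, "w+b")
  on.exit(close(con))
  .mrc_write_header(h, con)
  bytes <- .elem_bytes(h$dtype)
  item_elems <- as.double(d[["z"]]) * d[["y"]] * d[["x"]]
  seek(con, where = 1024 + index * item_elems * bytes, origin = "start",
       rw = "write")
  if (h$dtype == "float32") {
    writeBin(as.double(buf), con, size = 4L, endian = "little")
  } else {
    writeBin(as.integer(buf), con, size = bytes, endian = "little")
  }
  invisible(h)
}

.mrc_write_header <- function(h, con) {
  d <- h$dims
  volume <- d[["z"]] > 1L
  nz <- if (volume) d[["z"]] else d[["n"]]
  mz <- if (volume) d[["z"]] else 1L
  ispg <- if (volume) 1L else 0L
  ps <- if (is.null(h$pixel_size)) 0 else h$pixel_size
  cella <- ps * c(d[["x"]], d[["y"]], mz)
  stats <- if (length(h$item_moments)) .combine_moments(h$item_moments)
           else c(0, 0, 0, -1)
  hdr <- .mrc_build_header(d[["x"]], d[["y"]], nz,
                           .MRC_MODE_OF[[h$dtype]], mz, cella, ispg, stats)
  seek(con, where = 0, origin = "start", rw = "write")
  writeBin(hdr, con)
  invisible(h)
}

.spider_write_single <- function(h, img) {
  d <- im_dims(img)
  buf <- dtype_cast(img$data, img$dtype, "float32", policy = h$cast_policy)
  m <- .buffer_moments(buf)
  iform <- if (d[["z"]] > 1L) 3 else 1
  ps <- if (is.null(img$pixel_size)) 0 else img$pixel_size
  hdr <- .spider_build_header(d[["x"]], d[["y"]], d[["z"]], iform, m, ps)
  con <- file(h$path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(as.double(buf), con, size = 4L, endian = "little")
  h$dims <- d
  h$dtype <- "float32"
  h$pixel_size <- img$pixel_size
  invisible(h)
}

#' Close an image file handle
#'
#' Finalizes a written file (for MRC, the header statistics covering the
#' whole data section are flushed) and invalidates nothing: handles hold no
#' open connection between calls, so closing a read handle is a no-op.
#'
#' @param h An `em_image_file`.
#' @return `NULL`, invisibly.
#' @export
close_image_file <- function(h) {
  stopifnot(inherits(h, "em_image_file"))
  if (h$mode != "read" && h$format == "mrc" && !is.null(h$dims) &&
      length(h$item_moments)) {
    con <- file(h$path, "r+b")
    on.exit(close(con))
    .mrc_write_header(h, con)
  }
  invisible(NULL)
}

# --- probe and convenience wrappers ---------------------------------------

#' Inspect an image file without reading its data
#'
#' Parses only the header and reports the same metadata an open handle
#' would.
#'
#' @inheritParams open_image_file
#' @return A list with `format`, `dims` (`n`,`z`,`y`,`x`), `dtype` and
#'   `pixel_size` (`NULL` when the file does not declare one).
#' @export
em_probe <- function(path, format = NULL) {
  h <- open_image_file(path, mode = "read", format = format)
  list(format = h$format, dims = h$dims, dtype = h$dtype,
       pixel_size = h$pixel_size)
}

#' Read an image, stack or volume in one call
#'
#' @param path File path.
#' @param index Zero-based item to read, or `NULL` (default) to read every
#'   item into one stack.
#' @param format Optional explicit format.
#' @return An `em_image`.
#' @export
read_em_image <- function(path, index = NULL, format = NULL) {
  h <- open_image_file(path, mode = "read", format = format)
  if (!is.null(index)) return(read_image(h, index))
  n <- h$dims[["n"]]
  if (n == 1L) return(read_image(h, 0))
  image_stack(lapply(seq_len(n) - 1L, function(i) read_image(h, i)))
}

#' Write an image, stack or volume in one call
#'
#' Replaces `path` if it exists. Multi-item stacks can only go to MRC;
#' SPIDER output requires a single image or volume.
#'
#' @param img An `em_image`.
#' @param path Output path.
#' @param format Optional explicit format.
#' @param cast_policy Narrowing policy for file-type conversion.
#' @return `path`, invisibly.
#' @export
write_em_image <- function(img, path, format = NULL,
                           cast_policy = "round-clamp") {
  stopifnot(is_em_image(img))
  if (is.null(format)) format <- .format_from_ext(path)
  n <- im_dims(img)[["n"]]
  if (format == "spider" && n > 1L) {
    stop("SPIDER files hold a single image; split the stack first",
         call. = FALSE)
  }
  if (file.exists(path)) file.remove(path)
  h <- open_image_file(path, mode = "write", format = format,
                       cast_policy = cast_policy)
  for (i in seq_len(n) - 1L) {
    write_image(h, if (n == 1L) img else image_index(img, i), i)
  }
  close_image_file(h)
  invisible(path)
}
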