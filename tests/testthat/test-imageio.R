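# Shapes exercised everywhere below, as (n, z, y, x)
IO_SHAPES <- list(single = c(1, 1, 6, 8),
                  stack1 = c(1, 1, 8, 8),
                  stack2 = c(2, 1, 8, 8),
                  stack10 = c(10, 1, 6, 6),
                  vol2 = c(1, 2, 8, 8),
                  vol8 = c(1, 8, 6, 6))

test_that("MRC write/read round-trips bit-exactly for all dtypes and shapes", {
  for (dtype in ALL_DTYPES) {
    for (shape in IO_SHAPES) {
      img <- rand_image(dtype, shape, seed = 7, pixel_size = 1.5)
      tf <- withr::local_tempfile(fileext = ".mrc")
      write_em_image(img, tf)
      back <- read_em_image(tf)
      expect_identical(back$data, img$data,
                       info = paste(dtype, paste(shape, collapse = "x")))
      expect_identical(unname(im_dims(back)), unname(im_dims(img)))
      expect_equal(back$pixel_size, 1.5, tolerance = 1e-6)
      p <- em_probe(tf)
      expect_identical(p$format, "mrc")
      expect_identical(p$dims, im_dims(img))
    }
  }
})

test_that("SPIDER single-image and volume files round-trip bit-exactly", {
  for (shape in IO_SHAPES[c("single", "vol2", "vol8")]) {
    img <- rand_image("float32", shape, seed = 5)
    tf <- withr::local_tempfile(fileext = ".spi")
    write_em_image(img, tf)
    back <- read_em_image(tf)
    expect_identical(back$data, img$data)
    expect_identical(back$dtype, "float32")
    p <- em_probe(tf)
    expect_identical(p$format, "spider")
    expect_identical(p$dims, im_dims(img))
    expect_null(p$pixel_size)
  }
  # int8 input is widened to the float32 the format stores, values exact
  img8 <- rand_image("int8", c(1, 1, 6, 6), seed = 9)
  tf <- withr::local_tempfile(fileext = ".spi")
  write_em_image(img8, tf)
  expect_identical(read_em_image(tf)$data, img8$data)
})

test_that("cross-format MRC -> SPIDER -> MRC preserves float32 bit-exactly", {
  img <- rand_image("float32", c(1, 1, 16, 16), seed = 13)
  t1 <- withr::local_tempfile(fileext = ".mrc")
  t2 <- withr::local_tempfile(fileext = ".spi")
  t3 <- withr::local_tempfile(fileext = ".mrc")
  write_em_image(img, t1)
  write_em_image(read_em_image(t1), t2)
  write_em_image(read_em_image(t2), t3)
  expect_identical(read_em_image(t3)$data, img$data)
})

test_that("written MRC headers are field-identical under the reference parser", {
  img <- rand_image("float32", c(4, 1, 8, 8), seed = 21, pixel_size = 2.0)
  tf <- withr::local_tempfile(fileext = ".mrcs")
  write_em_image(img, tf)
  hd <- ref_parse_mrc(tf)
  expect_identical(hd$nx, 8L)
  expect_identical(hd$ny, 8L)
  expect_identical(hd$nz, 4L)     # stack: nz = n
  expect_identical(hd$mode, 2L)
  expect_identical(hd$mz, 1L)
  expect_identical(hd$ispg, 0L)
  expect_identical(hd$nsymbt, 0L)
  expect_identical(hd$map_id, "MAP ")
  expect_identical(hd$machst, as.raw(c(0x44, 0x44, 0x00, 0x00)))
  expect_equal(hd$cella, c(16, 16, 2), tolerance = 1e-6)

  vol <- rand_image("int16", c(1, 4, 8, 8), seed = 22)
  tv <- withr::local_tempfile(fileext = ".mrc")
  write_em_image(vol, tv)
  hv <- ref_parse_mrc(tv)
  expect_identical(hv$mode, 1L)
  expect_identical(hv$ispg, 1L)   # volume
  expect_identical(hv$mz, 4L)
  expect_identical(hv$nz, 4L)
})

test_that("written SPIDER headers are field-identical under the reference parser", {
  img <- rand_image("float32", c(1, 1, 12, 16), seed = 23)
  tf <- withr::local_tempfile(fileext = ".spi")
  write_em_image(img, tf)
  hd <- ref_parse_spider(tf)
  expect_identical(hd$nsam, 16)
  expect_identical(hd$nrow, 12)
  expect_identical(hd$nslice, 1)
  expect_identical(hd$iform, 1)
  expect_identical(hd$lenbyt, 64)           # nsam * 4
  expect_identical(hd$labrec, 16)           # smallest with labrec*lenbyt >= 1024
  expect_identical(hd$labbyt, hd$labrec * hd$lenbyt)
  expect_identical(hd$istack, 0)
})

test_that("MRC statistics fields equal full-content image_stats after close", {
  img <- rand_image("float32", c(6, 1, 8, 8), seed = 31)
  tf <- withr::local_tempfile(fileext = ".mrcs")
  h <- open_image_file(tf, "write")
  for (i in 0:5) write_image(h, image_index(img, i), i)
  close_image_file(h)
  hd <- ref_parse_mrc(tf)
  s <- image_stats(img)
  expect_equal(hd$dmin, s$min, tolerance = 1e-6)
  expect_equal(hd$dmax, s$max, tolerance = 1e-6)
  expect_equal(hd$dmean, s$mean, tolerance = 1e-6)
  expect_equal(hd$rms, s$sd, tolerance = 1e-6)
})

test_that("reference fixture files read back bit-exactly (cross-implementation)", {
  tf <- withr::local_tempfile(fileext = ".mrcs")
  ref <- write_reference_mrc(
    tf, phantom_spec(c(10, 1, 16, 16), "uniform-noise", seed = 42,
                     dtype = "float32", pixel_size = 1.0))
  p <- em_probe(tf)
  expect_identical(p$format, "mrc")
  expect_identical(unname(p$dims), c(10L, 1L, 16L, 16L))
  expect_identical(p$dtype, "float32")
  expect_equal(p$pixel_size, 1.0, tolerance = 1e-6)
  expect_identical(read_em_image(tf)$data, ref$image$data)
  expect_identical(read_em_image(tf, index = 3)$data,
                   image_index(ref$image, 3)$data)

  t8 <- withr::local_tempfile(fileext = ".mrc")
  ref8 <- write_reference_mrc(
    t8, phantom_spec(c(1, 1, 16, 16), "checkerboard", dtype = "int8"))
  expect_identical(read_em_image(t8)$data, ref8$image$data)
  expect_identical(read_em_image(t8)$dtype, "int8")

  ts <- withr::local_tempfile(fileext = ".spi")
  refs <- write_reference_spider(
    ts, phantom_spec(c(1, 1, 16, 16), "uniform-noise", seed = 7,
                     dtype = "float32"))
  ps <- em_probe(ts)
  expect_identical(ps$format, "spider")
  expect_identical(unname(ps$dims), c(1L, 1L, 16L, 16L))
  expect_identical(read_em_image(ts)$data, refs$image$data)

  tv <- withr::local_tempfile(fileext = ".spi")
  refv <- write_reference_spider(
    tv, phantom_spec(c(1, 8, 16, 16), "uniform-noise", seed = 8,
                     dtype = "float32"))
  pv <- em_probe(tv)
  expect_identical(unname(pv$dims), c(1L, 8L, 16L, 16L))
  expect_identical(read_em_image(tv)$data, refv$image$data)
})

test_that("volume/stack disambiguation follows the ispg convention", {
  vol <- rand_image("float32", c(1, 8, 6, 6), seed = 17)
  tf <- withr::local_tempfile(fileext = ".mrc")
  write_em_image(vol, tf)
  back <- read_em_image(tf)
  expect_identical(unname(im_dims(back)), c(1L, 8L, 6L, 6L))
})

test_that("big-endian MRC files are byte-swapped on read", {
  # hand-build a minimal big-endian mode-2 file with machine stamp 0x11 0x11
  vals <- as.double(1:16)
  tf <- withr::local_tempfile(fileext = ".mrc")
  con <- file(tf, "wb")
  wi <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "big")
  wf <- function(v) writeBin(as.double(v), con, size = 4L, endian = "big")
  wi(c(4, 4, 1, 2, 0, 0, 0, 4, 4, 1)); wf(c(0, 0, 0, 90, 90, 90))
  wi(c(1, 2, 3)); wf(c(1, 16, 8.5)); wi(c(0, 0))
  writeBin(raw(100), con); wf(c(0, 0, 0))
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x11, 0x11, 0x00, 0x00)), con)
  wf(0); wi(0); writeBin(raw(800), con)
  wf(vals)
  close(con)
  img <- read_em_image(tf)
  expect_identical(as.vector(img$data), vals)
})

test_that("extended headers are preserved opaquely on read", {
  img <- rand_image("float32", c(1, 1, 4, 4), seed = 19)
  t0 <- withr::local_tempfile(fileext = ".mrc")
  write_em_image(img, t0)
  bytes <- readBin(t0, "raw", n = file.size(t0))
  # patch nsymbt (word 24) to 16 and splice an opaque block after the header
  bytes[93:96] <- writeBin(16L, raw(), size = 4L, endian = "little")
  ext <- as.raw(1:16)
  t1 <- withr::local_tempfile(fileext = ".mrc")
  writeBin(c(bytes[1:1024], ext, bytes[1025:length(bytes)]), t1)
  back <- read_em_image(t1)
  expect_identical(back$data, img$data)
  expect_identical(back$header_meta$extended_header, ext)
})

test_that("SPIDER stack files are read-supported, write-unsupported", {
  # hand-build an istack file with 2 images, per the stack layout:
  # overall header, then per-image header + data
  nx <- 8L; ny <- 8L
  lenbyt <- nx * 4; labrec <- ceiling(1024 / lenbyt); labbyt <- labrec * lenbyt
  mk_hdr <- function(istack, maxim, imgnum) {
    w <- numeric(labbyt / 4)
    w[1] <- 1; w[2] <- ny; w[3] <- ny; w[5] <- 1; w[12] <- nx
    w[13] <- labrec; w[22] <- labbyt; w[23] <- lenbyt
    w[24] <- istack; w[26] <- maxim; w[27] <- imgnum
    w
  }
  set.seed(4)
  img1 <- matrix(dtype_cast(rnorm(nx * ny), "float64", "float32"), nx, ny)
  img2 <- matrix(dtype_cast(rnorm(nx * ny), "float64", "float32"), nx, ny)
  tf <- withr::local_tempfile(fileext = ".stk")
  con <- file(tf, "wb")
  writeBin(mk_hdr(2, 2, 0), con, size = 4L, endian = "little")
  writeBin(mk_hdr(0, 0, 1), con, size = 4L, endian = "little")
  writeBin(as.double(img1), con, size = 4L, endian = "little")
  writeBin(mk_hdr(0, 0, 2), con, size = 4L, endian = "little")
  writeBin(as.double(img2), con, size = 4L, endian = "little")
  close(con)

  h <- open_image_file(tf)
  expect_identical(unname(h$dims), c(2L, 1L, 8L, 8L))
  expect_identical(as.vector(read_image(h, 0)$data), as.vector(img1))
  expect_identical(as.vector(read_image(h, 1)$data), as.vector(img2))

  # writing a second item to a SPIDER file is refused
  hw <- open_image_file(withr::local_tempfile(fileext = ".spi"), "write")
  write_image(hw, rand_image("float32", c(1, 1, 8, 8), seed = 1))
  expect_error(write_image(hw, rand_image("float32", c(1, 1, 8, 8), seed = 2)),
               "not supported")
})

test_that("malformed inputs and misuse raise clean errors", {
  empty <- withr::local_tempfile(fileext = ".mrc")
  file.create(empty)
  expect_error(open_image_file(empty), "malformed")

  noext <- withr::local_tempfile(fileext = ".xyz")
  file.create(noext)
  expect_error(open_image_file(noext), "format")

  expect_error(open_image_file(withr::local_tempdir(), format = "mrc"),
               "directory")
  expect_error(open_image_file(tempfile(fileext = ".mrc")), "not found")

  stk <- withr::local_tempfile(fileext = ".mrcs")
  img <- rand_image("float32", c(3, 1, 4, 4), seed = 2)
  write_em_image(img, stk)
  h <- open_image_file(stk)
  expect_error(read_image(h, 3), "out of range")
  expect_error(write_image(h, image_index(img, 0)), "read-only")

  hw <- open_image_file(withr::local_tempfile(fileext = ".mrc"), "write")
  write_image(hw, image_index(img, 0), 0)
  expect_error(write_image(hw, image_index(img, 1), 5), "sparse")

  # garbage that passes no geometry check
  bad <- withr::local_tempfile(fileext = ".spi")
  writeBin(as.raw(rep(7L, 2048)), bad)
  expect_error(open_image_file(bad), "malformed")
})

test_that("strict cast policy on a handle refuses lossy writes", {
  img <- as_em_image(array(c(1e9, -1e9, 0.5, 2), dim = c(2, 2, 1, 1)),
                     "float64")
  tf <- withr::local_tempfile(fileext = ".spi")
  h <- open_image_file(tf, "write", cast_policy = "round-clamp")
  write_image(h, img)  # fine: float32 clamps/rounds
  expect_identical(read_em_image(tf)$data,
                   dtype_cast(img$data, "float64", "float32"))
})
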