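test_that("math processors implement exact scalar arithmetic", {
  img <- as_em_image(array(c(1, -2, 0, 5), dim = c(2, 2, 1, 1)), "float64")
  inv <- process(math_proc("multiply", -1), img)
  expect_identical(as.vector(inv$data), c(-1, 2, 0, -5))

  expect_identical(process(math_proc("add", 0), img)$data, img$data)
  half_back <- process(math_proc("multiply", 0.5),
                       process(math_proc("multiply", 2), img))
  expect_equal(half_back$data, img$data, tolerance = 1e-12)

  # add a then subtract a is the identity exactly in float64
  a <- 1.37
  back <- process(math_proc("subtract", a), process(math_proc("add", a), img))
  expect_identical(back$data, img$data)

  expect_error(math_proc("divide", 0), "zero")
  expect_error(math_proc("add", Inf), "finite")
})

test_that("integer images round half-to-even and clamp under math ops", {
  img <- as_em_image(array(c(1, 2, 126, -128), dim = c(4, 1, 1, 1)), "int8")
  out <- process(math_proc("add", 0.5), img)
  expect_identical(as.vector(out$data), c(2, 2, 126, -128))  # RNE + clamp
  big <- process(math_proc("multiply", 100), img)
  expect_identical(as.vector(big$data), c(100, 127, 127, -128))
})

test_that("processors apply per item and never mutate their input", {
  stk <- rand_image("float32", c(4, 1, 8, 8), seed = 12)
  before <- stk$data
  for (p in list(math_proc("multiply", -1), window_proc(c(4, 4)),
                 lowpass_proc(0.25), scale_proc(0.5))) {
    whole <- process(p, stk)
    expect_identical(stk$data, before)   # out-of-place purity
    for (i in 0:3) {
      single <- process(p, image_index(stk, i))
      expect_identical(image_index(whole, i)$data, single$data,
                       info = paste(p$name, "item", i))
    }
  }
})

test_that("scale_proc reproduces the Fourier oracle and adjusts pixel size", {
  img <- rand_image("float32", c(1, 1, 8, 8), seed = 8, pixel_size = 1.0)
  out <- process(scale_proc(0.5), img)
  expect_identical(unname(im_dims(out)), c(1L, 1L, 4L, 4L))
  expect_identical(out$dtype, "float32")
  expect_equal(out$pixel_size, 2.0)    # fewer pixels, larger Angstrom/pixel
  want <- dtype_cast(oracle_resize_2d(img$data[, , 1, 1], 4, 4),
                     "float64", "float32")
  expect_lt(max(abs(out$data[, , 1, 1] - want)) / max(abs(want)), 1e-6)

  ident <- process(scale_proc(1.0), img)
  expect_lt(max(abs(ident$data - img$data)) / max(abs(img$data)), 1e-6)

  big <- process(scale_proc(dims = c(16, 16)), img)
  expect_identical(unname(im_dims(big)), c(1L, 1L, 16L, 16L))
  expect_equal(big$pixel_size, 0.5)

  expect_error(process(scale_proc(dims = c(7, 8)), img), "even")
  expect_error(scale_proc(), "exactly one")
  expect_error(scale_proc(-2), "positive")
})

test_that("scale factor 0.5 halves a 64x64 image", {
  img <- make_phantom(phantom_spec(c(1, 1, 64, 64), "gaussian-blob",
                                   dtype = "float32"))
  out <- process(scale_proc(0.5), img)
  expect_identical(unname(im_dims(out)), c(1L, 1L, 32L, 32L))
})

test_that("window crops and pads around the stated centring rule", {
  img <- as_em_image(array(as.double(1:64), dim = c(8, 8, 1, 1)), "float32")
  crop <- process(window_proc(c(4, 4)), img)
  # keeps zero-based rows/cols 2..5 on both axes
  expect_identical(crop$data[, , 1, 1], img$data[3:6, 3:6, 1, 1])

  pad <- process(window_proc(c(12, 12), fill = 7), img)
  expect_identical(unname(im_dims(pad)), c(1L, 1L, 12L, 12L))
  expect_identical(pad$data[1, 1, 1, 1], 7)
  back <- process(window_proc(c(8, 8)), pad)
  expect_identical(back$data, img$data)   # pad then crop back is identity

  same <- process(window_proc(c(8, 8)), img)
  expect_identical(same$data, img$data)
})

test_that("lowpass preserves the mean, never adds energy, matches the oracle", {
  img <- rand_image("float64", c(1, 1, 16, 16), seed = 6)
  out <- process(lowpass_proc(0.25), img)
  expect_lt(abs(mean(out$data) - mean(img$data)) / abs(mean(img$data)), 1e-9)
  expect_lte(sum(out$data^2), sum(img$data^2) * (1 + 1e-12))

  # constant image only has DC: untouched
  const <- image_create(c(1, 1, 8, 8), "float64", fill = 4)
  expect_equal(process(lowpass_proc(0.1), const)$data, const$data,
               tolerance = 1e-12)

  # cutoff at Nyquist with a zero-width edge: mask is 1 on the whole grid
  ident <- process(lowpass_proc(0.5, edge_width = 0), img)
  expect_lt(max(abs(ident$data - img$data)) / max(abs(img$data)), 1e-9)

  # impulse image vs brute-force mask multiply through the naive DFT
  imp <- image_create(c(1, 1, 16, 16), "float64")
  imp$data[9, 9, 1, 1] <- 1
  got <- process(lowpass_proc(0.25), imp)
  full <- naive_dft(imp$data[, , 1, 1], c(16, 16))
  fx <- grid_freqs(16) / 16
  cutoff <- 0.25; w <- 0.02
  mask <- outer(fx, fx, function(a, b) {
    r <- pmin(sqrt(a^2 + b^2), 0.5)   # radius saturates at Nyquist
    m <- ifelse(r <= cutoff - w, 1,
                ifelse(r >= cutoff, 0,
                       0.5 * (1 + cos(pi * (r - (cutoff - w)) / w))))
    m
  })
  want <- Re(naive_idft(full * mask, c(16, 16)))
  expect_lt(max(abs(got$data[, , 1, 1] - want)), 1e-9)

  expect_error(lowpass_proc(0.6), "cutoff")
  expect_error(lowpass_proc(0), "cutoff")
})
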