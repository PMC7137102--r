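# Real-to-complex transforms and frequency-domain crop/pad. Convention fixed
# package-wide: the forward transform is unnormalized (DC coefficient = sum of
# real-space values); the inverse applies 1/N. Spectra are stored in the
# half-spectrum layout: only non-negative x frequencies, floor(x/2)+1 columns.

.is_float_dtype <- function(dtype) dtype %in% c("float32", "float64")

# index permutation mapping frequency k to -k (1-based array indices)
.conj_idx <- function(n) if (n == 1L) 1L else c(1L, n:2L)

# fftshift order for an even-length axis: frequencies -n/2 .. n/2-1
.fftshift_idx <- function(n) {
  if (n == 1L) return(1L)
  c((n %/% 2 + 1L):n, 1L:(n %/% 2))
}

.new_spectrum <- function(coeffs, source_dims) {
  structure(list(source_dims = source_dims, coeffs = coeffs),
            class = "em_spectrum")
}

#' @export
print.em_spectrum <- function(x, ...) {
  d <- x$source_dims
  cat(sprintf(
    "<em_spectrum> source n=%d z=%d y=%d x=%d  half-layout coeffs %s\n",
    d["n"], d["z"], d["y"], d["x"],
    paste(dim(x$coeffs), collapse = "x")))
  invisible(x)
}

#' Forward real-to-complex Fourier transform
#'
#' Computes the unnormalized discrete Fourier transform of each item of a
#' float image and keeps the non-redundant half spectrum (non-negative x
#' frequencies). The DC coefficient equals the sum of the real-space values.
#'
#' @param img An `em_image` with dtype float32 or float64. Integer images must
#'   be cast first (see [dtype_cast()]).
#' @return An `em_spectrum` holding `floor(x/2)+1` by `y` by `z` complex
#'   coefficients per item plus the real-space source dimensions.
#' @export
em_fft_forward <- function(img) {
  stopifnot(is_em_image(img))
  if (!.is_float_dtype(img$dtype)) {
    stop("forward transform requires a float image; cast ", img$dtype,
         " first", call. = FALSE)
  }
  d <- im_dims(img)
  nx <- d[["x"]]; ny <- d[["y"]]; nz <- d[["z"]]; n <- d[["n"]]
  nxh <- nx %/% 2 + 1L
  coeffs <- array(complex(1), dim = c(nxh, ny, nz, n))
  for (i in seq_len(n)) {
    full <- stats::fft(array(img$data[, , , i], dim = c(nx, ny, nz)))
    coeffs[, , , i] <- full[seq_len(nxh), , , drop = FALSE]
  }
  .new_spectrum(coeffs, d)
}

# Rebuild the full (nx, ny, nz) spectrum of one item from its half layout
# using Hermitian symmetry X[-k] = conj(X[k]).
.full_from_half <- function(half, nx, ny, nz) {
  nxh <- nx %/% 2 + 1L
  full <- array(complex(1), dim = c(nx, ny, nz))
  full[seq_len(nxh), , ] <- half
  if (nx > nxh) {
    iy <- .conj_idx(ny); iz <- .conj_idx(nz)
    for (kx in (nxh + 1L):nx) {
      full[kx, , ] <- Conj(half[nx - kx + 2L, iy, iz, drop = FALSE])
    }
  }
  full
}

#' Inverse Fourier transform
#'
#' Reconstructs the real-space image from a half-layout spectrum, applying
#' the 1/N normalization. `em_fft_inverse(em_fft_forward(img))` recovers
#' `img` to floating-point accuracy.
#'
#' @param spec An `em_spectrum`.
#' @return An `em_image` of dtype float64.
#' @export
em_fft_inverse <- function(spec) {
  stopifnot(inherits(spec, "em_spectrum"))
  d <- spec$source_dims
  nx <- d[["x"]]; ny <- d[["y"]]; nz <- d[["z"]]; n <- d[["n"]]
  nxh <- nx %/% 2 + 1L
  if (!all(dim(spec$coeffs) == c(nxh, ny, nz, n))) {
    stop("spectrum coefficient layout inconsistent with source_dims",
         call. = FALSE)
  }
  N <- as.double(nx) * ny * nz
  out <- array(0, dim = c(nx, ny, nz, n))
  for (i in seq_len(n)) {
    full <- .full_from_half(
      array(spec$coeffs[, , , i], dim = c(nxh, ny, nz)), nx, ny, nz)
    out[, , , i] <- Re(stats::fft(full, inverse = TRUE)) / N
  }
  .new_em_image(out, "float64")
}

# Crop or pad one axis of a full spectrum in fftshifted coordinates.
# arr has dims c(nx, ny, nz); axis is 1, 2 or 3; n_new is even (or equal).
.axis_resize_full <- function(arr, axis, n_new) {
  n_old <- dim(arr)[axis]
  if (n_new == n_old) return(arr)
  perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
  a <- aperm(arr, perm)
  sh <- a[.fftshift_idx(n_old), , , drop = FALSE]
  d_new <- dim(a); d_new[1] <- n_new
  if (n_new < n_old) {
    off <- (n_old - n_new) %/% 2L
    kept <- sh[(off + 1L):(off + n_new), , , drop = FALSE]
  } else {
    kept <- array(complex(1), dim = d_new)
    off <- (n_new - n_old) %/% 2L
    kept[(off + 1L):(off + n_old), , ] <- sh
  }
  out <- kept[.fftshift_idx(n_new), , , drop = FALSE]
  aperm(out, order(perm))
}

#' Resize a spectrum by Fourier cropping or padding
#'
#' Changes the spatial dimensions of a spectrum by keeping the centred
#' low-frequency block (downscale) or zero-padding the high frequencies
#' (upscale). Coefficients are rescaled by the ratio of element counts so
#' that the inverse transform preserves the real-space mean exactly.
#' Inverse-transforming a cropped spectrum is ideal sinc-interpolation
#' downsampling ("Fourier cropping").
#'
#' After the per-axis crop/pad the Hermitian symmetry of the spectrum is
#' re-enforced (`X[k] <- (X[k] + Conj(X[-k])) / 2`), which resolves the
#' even-grid Nyquist bins deterministically and guarantees a real inverse.
#'
#' @param spec An `em_spectrum`.
#' @param new_dims Target spatial dims, `(y, x)` or `(z, y, x)`; each resized
#'   axis must be even and >= 2. The stack size `n` is unchanged.
#' @return An `em_spectrum` with the new source dimensions.
#' @export
spectral_resize <- function(spec, new_dims) {
  stopifnot(inherits(spec, "em_spectrum"))
  d <- spec$source_dims
  nd <- as.numeric(new_dims)
  if (length(nd) == 2L) nd <- c(d[["z"]], nd)
  if (length(nd) != 3L) {
    stop("new_dims must be (y, x) or (z, y, x)", call. = FALSE)
  }
  nd <- stats::setNames(as.integer(nd), c("z", "y", "x"))
  old <- d[c("z", "y", "x")]
  for (ax in c("z", "y", "x")) {
    if (nd[[ax]] != old[[ax]]) {
      if (nd[[ax]] < 2L || nd[[ax]] %% 2L != 0L || old[[ax]] %% 2L != 0L) {
        stop("spectral_resize requires even source and target extents >= 2 ",
             "on every resized axis (", ax, ": ", old[[ax]], " -> ", nd[[ax]],
             ")", call. = FALSE)
      }
    }
  }
  if (all(nd == old)) return(spec)

  nx <- d[["x"]]; ny <- d[["y"]]; nz <- d[["z"]]; n <- d[["n"]]
  nxh <- nx %/% 2 + 1L
  nxh_new <- nd[["x"]] %/% 2 + 1L
  ratio <- (as.double(nd[["x"]]) * nd[["y"]] * nd[["z"]]) /
    (as.double(nx) * ny * nz)
  out <- array(complex(1), dim = c(nxh_new, nd[["y"]], nd[["z"]], n))
  rx <- .conj_idx(nd[["x"]]); ry <- .conj_idx(nd[["y"]]); rz <- .conj_idx(nd[["z"]])
  for (i in seq_len(n)) {
    full <- .full_from_half(
      array(spec$coeffs[, , , i], dim = c(nxh, ny, nz)), nx, ny, nz)
    full <- .axis_resize_full(full, 1L, nd[["x"]])
    full <- .axis_resize_full(full, 2L, nd[["y"]])
    full <- .axis_resize_full(full, 3L, nd[["z"]])
    full <- (full + Conj(full[rx, ry, rz, drop = FALSE])) / 2
    out[, , , i] <- full[seq_len(nxh_new), , , drop = FALSE] * ratio
  }
  .new_spectrum(out, stats::setNames(
    c(n, nd[["z"]], nd[["y"]], nd[["x"]]), c("n", "z", "y", "x")))
}
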