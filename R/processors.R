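# Composable image processors. Each processor is a small S3 object holding a
# name and a validated parameter list; `process()` applies it out-of-place,
# item by item over stacks, and never mutates its input or its parameters.

.new_processor <- function(name, params, class) {
  structure(list(name = name, params = params),
            class = c(class, "em_processor"))
}

#' @export
print.em_processor <- function(x, ...) {
  ps <- paste(names(x$params),
              vapply(x$params, function(v) paste(format(v), collapse = ","),
                     character(1)),
              sep = "=", collapse = ", ")
  cat(sprintf("<em_processor:%s> %s\n", x$name, ps))
  invisible(x)
}

#' Apply a processor to an image
#'
#' Runs a processor (or pipeline) on an image and returns the result as a new
#' image; the input is never modified. Multi-item stacks are processed item
#' by item, so `process(p, stack)` item `i` equals `process(p, stack_i)`.
#'
#' @param p An `em_processor` (from [math_proc()], [scale_proc()],
#'   [window_proc()], [lowpass_proc()] or [pipe_proc()]).
#' @param img An `em_image`.
#' @param ... Passed to methods.
#' @return An `em_image`.
#' @export
process <- function(p, img, ...) UseMethod("process")

#' @export
process.default <- function(p, img, ...) {
  stop("not an em_processor", call. = FALSE)
}

# Apply fun (one single-item em_image -> em_image) over every stack item.
.per_item <- function(img, fun) {
  n <- im_dims(img)[["n"]]
  if (n == 1L) return(fun(img))
  image_stack(lapply(seq_len(n) - 1L, function(i) fun(image_index(img, i))))
}

#' Arithmetic processor
#'
#' Element-wise arithmetic with a scalar operand: add, subtract, multiply or
#' divide. Computation is carried out in double precision regardless of the
#' input element type; the result is cast back to the input dtype under the
#' round-clamp policy, so integer images round half-to-even and saturate at
#' the type range.
#'
#' @param op One of `"add"`, `"subtract"`, `"multiply"`, `"divide"`.
#' @param operand Finite scalar; must be non-zero for `"divide"`.
#' @return An `em_processor`.
#' @examples
#' inv <- math_proc("multiply", -1)
#' process(inv, image_create(c(1, 1, 2, 2), fill = 3))
#' @export
math_proc <- function(op = c("add", "subtract", "multiply", "divide"),
                      operand) {
  op <- match.arg(op)
  if (!is.numeric(operand) || length(operand) != 1L || !is.finite(operand)) {
    stop("operand must be a finite scalar", call. = FALSE)
  }
  if (op == "divide" && operand == 0) {
    stop("division by zero", call. = FALSE)
  }
  .new_processor("math", list(op = op, operand = as.double(operand)),
                 "em_proc_math")
}

#' @export
process.em_proc_math <- function(p, img, ...) {
  stopifnot(is_em_image(img))
  v <- p$params$operand
  out <- switch(p$params$op,
                add      = img$data + v,
                subtract = img$data - v,
                multiply = img$data * v,
                divide   = img$data / v)
  out <- dtype_cast(out, "float64", img$dtype, policy = "round-clamp")
  dim(out) <- dim(img$data)
  .new_em_image(out, img$dtype, img$pixel_size, img$header_meta)
}

#' Fourier-cropping scale processor
#'
#' Rescales each image item through its Fourier transform: downscaling keeps
#' the centred low-frequency block, upscaling zero-pads it (ideal sinc
#' interpolation; see [spectral_resize()]). The output element type keeps the
#' precision the transform ran at: float64 input stays float64, anything else
#' becomes float32 (the Fourier path is inherently non-integral; double
#' precision is never silently discarded, so mean preservation survives to
#' the output exactly). The pixel size is divided by the scale factor (half
#' the pixels means twice the Angstrom/pixel).
#'
#' @param factor Positive scale factor; target extents are the source extents
#'   times `factor`, rounded to the nearest even integer. Give either this or
#'   `dims`.
#' @param dims Explicit target spatial dims `(y, x)` or `(z, y, x)`; each
#'   resized axis must be even and >= 2.
#' @return An `em_processor`.
#' @examples
#' half <- scale_proc(0.5)
#' @export
scale_proc <- function(factor = NULL, dims = NULL) {
  if (is.null(factor) == is.null(dims)) {
    stop("give exactly one of factor or dims", call. = FALSE)
  }
  if (!is.null(factor)) {
    if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
        factor <= 0) {
      stop("factor must be a positive scalar", call. = FALSE)
    }
    params <- list(factor = as.double(factor))
  } else {
    params <- list(dims = as.integer(dims))
  }
  .new_processor("scale", params, "em_proc_scale")
}

# nearest even integer, at least 2
.round_even <- function(x) pmax(2L, as.integer(2 * round(x / 2)))

#' @export
process.em_proc_scale <- function(p, img, ...) {
  stopifnot(is_em_image(img))
  d <- im_dims(img)
  if (!is.null(p$params$factor)) {
    f <- p$params$factor
    target <- c(
      z = if (d[["z"]] > 1L) .round_even(d[["z"]] * f) else 1L,
      y = .round_even(d[["y"]] * f),
      x = .round_even(d[["x"]] * f))
  } else {
    td <- p$params$dims
    target <- if (length(td) == 2L) c(z = d[["z"]], y = td[1], x = td[2])
              else c(z = td[1], y = td[2], x = td[3])
  }
  fx <- target[["x"]] / d[["x"]]
  ps <- if (is.null(img$pixel_size)) NULL else img$pixel_size / fx
  out_dtype <- if (img$dtype == "float64") "float64" else "float32"
  out <- .per_item(img, function(item) {
    if (!.is_float_dtype(item$dtype)) {
      item$dtype <- "float64"
    }
    em_fft_inverse(spectral_resize(em_fft_forward(item), target))
  })
  data <- dtype_cast(out$data, "float64", out_dtype)
  dim(data) <- dim(out$data)
  .new_em_image(data, out_dtype, ps, img$header_meta)
}

#' Windowing processor
#'
#' Real-space centred crop or pad. Smaller target extents crop; larger ones
#' pad with a constant fill. For an extent change of `delta`, the left/top
#' margin is `floor(delta / 2)`, so padding and then cropping back is the
#' identity.
#'
#' @param dims Target spatial dims `(y, x)` or `(z, y, x)`, each >= 1.
#' @param fill Fill value for padded regions (default 0); must be
#'   representable in the processed image's dtype.
#' @return An `em_processor`.
#' @export
window_proc <- function(dims, fill = 0) {
  dims <- as.integer(dims)
  if (!length(dims) %in% c(2L, 3L) || any(is.na(dims)) || any(dims < 1L)) {
    stop("dims must be 2 or 3 positive integers", call. = FALSE)
  }
  if (!is.numeric(fill) || length(fill) != 1L || !is.finite(fill)) {
    stop("fill must be a finite scalar", call. = FALSE)
  }
  .new_processor("window", list(dims = dims, fill = as.double(fill)),
                 "em_proc_window")
}

# centred source/destination ranges for one axis resize old -> new
.window_ranges <- function(old, new) {
  if (new <= old) {
    off <- (old - new) %/% 2L
    list(src = (off + 1L):(off + new), dst = seq_len(new))
  } else {
    off <- (new - old) %/% 2L
    list(src = seq_len(old), dst = (off + 1L):(off + old))
  }
}

#' @export
process.em_proc_window <- function(p, img, ...) {
  stopifnot(is_em_image(img))
  d <- im_dims(img)
  td <- p$params$dims
  target <- if (length(td) == 2L) c(z = d[["z"]], y = td[1], x = td[2])
            else c(z = td[1], y = td[2], x = td[3])
  fill <- dtype_cast(p$params$fill, "float64", img$dtype,
                     policy = "error-on-overflow")
  rx <- .window_ranges(d[["x"]], target[["x"]])
  ry <- .window_ranges(d[["y"]], target[["y"]])
  rz <- .window_ranges(d[["z"]], target[["z"]])
  n <- d[["n"]]
  out <- array(fill, dim = c(target[["x"]], target[["y"]], target[["z"]], n))
  out[rx$dst, ry$dst, rz$dst, ] <- img$data[rx$src, ry$src, rz$src, ,
                                            drop = FALSE]
  .new_em_image(out, img$dtype, img$pixel_size, img$header_meta)
}

#' Low-pass filter processor
#'
#' Attenuates spatial frequencies above a cutoff with a raised-cosine edge:
#' the spectral mask is 1 below `cutoff - edge_width`, 0 at and above
#' `cutoff`, with a half-cosine roll-off in between. The radial frequency is
#' saturated at the Nyquist radius 0.5, so grid corners (which lie beyond
#' 0.5) follow the Nyquist bin and a cutoff of 0.5 with a zero-width edge
#' passes the spectrum untouched. The DC term is never touched, so the image
#' mean is preserved, and the mask never exceeds 1, so spectral energy
#' cannot increase.
#'
#' @param cutoff Digital frequency in `(0, 0.5]` (cycles per pixel; 0.5 is
#'   Nyquist).
#' @param edge_width Width of the cosine edge in the same units (default
#'   0.02). Zero gives a hard cutoff.
#' @return An `em_processor`.
#' @export
lowpass_proc <- function(cutoff, edge_width = 0.02) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff) ||
      cutoff <= 0 || cutoff > 0.5) {
    stop("cutoff must be a digital frequency in (0, 0.5]", call. = FALSE)
  }
  if (!is.numeric(edge_width) || length(edge_width) != 1L ||
      !is.finite(edge_width) || edge_width < 0) {
    stop("edge_width must be >= 0", call. = FALSE)
  }
  .new_processor("lowpass",
                 list(cutoff = as.double(cutoff),
                      edge_width = as.double(edge_width)),
                 "em_proc_lowpass")
}

# raised-cosine mask value for radial digital frequency r
.lowpass_mask <- function(r, cutoff, w) {
  m <- numeric(length(r))
  m[r <= cutoff - w] <- 1
  edge <- r > cutoff - w & r < cutoff
  if (w > 0 && any(edge)) {
    m[edge] <- 0.5 * (1 + cos(pi * (r[edge] - (cutoff - w)) / w))
  }
  m[r == 0] <- 1
  m
}

#' @export
process.em_proc_lowpass <- function(p, img, ...) {
  stopifnot(is_em_image(img))
  d <- im_dims(img)
  out_dtype <- if (.is_float_dtype(img$dtype)) img$dtype else "float32"
  nx <- d[["x"]]; ny <- d[["y"]]; nz <- d[["z"]]
  nxh <- nx %/% 2 + 1L
  # signed frequency (cycles/pixel) per axis; half layout keeps fx >= 0
  fx <- (seq_len(nxh) - 1L) / nx
  fy <- ifelse(seq_len(ny) - 1L <= ny %/% 2, seq_len(ny) - 1L,
               seq_len(ny) - 1L - ny) / ny
  fz <- if (nz == 1L) 0 else
    ifelse(seq_len(nz) - 1L <= nz %/% 2, seq_len(nz) - 1L,
           seq_len(nz) - 1L - nz) / nz
  # radial digital frequency, saturated at the Nyquist radius so that a
  # cutoff of 0.5 passes the entire spectrum (grid corners lie beyond 0.5)
  r <- pmin(sqrt(outer(outer(fx^2, fy^2, `+`), fz^2, `+`)), 0.5)
  mask <- array(.lowpass_mask(as.vector(r), p$params$cutoff,
                              p$params$edge_width),
                dim = c(nxh, ny, nz))
  .per_item(img, function(item) {
    it <- item
    if (!.is_float_dtype(it$dtype)) it$dtype <- "float64"
    spec <- em_fft_forward(it)
    spec$coeffs[] <- as.vector(spec$coeffs) * as.vector(mask)
    res <- em_fft_inverse(spec)
    data <- dtype_cast(res$data, "float64", out_dtype)
    dim(data) <- dim(res$data)
    .new_em_image(data, out_dtype, item$pixel_size, item$header_meta)
  })
}
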