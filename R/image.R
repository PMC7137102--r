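# The 4-D image container. Pixel data live in an R double array with
# dimensions (x, y, z, n): x is the fastest axis, matching both R's
# column-major layout and the MRC2014 column/row/section order. User-facing
# dimension vectors are reported in (n, z, y, x) order.

.as_dims4 <- function(dims) {
  dims <- as.numeric(dims)
  if (length(dims) == 2L) dims <- c(1, 1, dims)
  if (length(dims) == 3L) dims <- c(1, dims)
  if (length(dims) != 4L) {
    stop("dims must have 2 (y,x), 3 (z,y,x) or 4 (n,z,y,x) elements",
         call. = FALSE)
  }
  if (any(!is.finite(dims)) || any(dims < 1) || any(dims != floor(dims))) {
    stop("dims must be integers >= 1", call. = FALSE)
  }
  stats::setNames(as.integer(dims), c("n", "z", "y", "x"))
}

.new_em_image <- function(data, dtype, pixel_size = NULL,
                          header_meta = list()) {
  d <- dim(data)
  if (is.null(d)) d <- length(data)
  if (length(d) < 4L) d <- c(d, rep(1L, 4L - length(d)))
  dim(data) <- d
  storage.mode(data) <- "double"
  structure(
    list(data = data, dtype = dtype, pixel_size = pixel_size,
         header_meta = header_meta),
    class = "em_image"
  )
}

#' Create a blank image
#'
#' Allocates a 4-D image container of the given dimensions, element type and
#' constant fill value. The container holds, in one object, a single 2-D
#' image (`n = 1, z = 1`), a stack of 2-D images (`n >= 1, z = 1`) or a 3-D
#' volume (`n = 1, z > 1`).
#'
#' @param dims Image dimensions in `(n, z, y, x)` order; 2- and 3-element
#'   vectors are promoted as `(y, x)` and `(z, y, x)`.
#' @param dtype Element type name (see [em_dtypes()]). Default `"float32"`.
#' @param fill Constant fill value; must be exactly representable in `dtype`.
#' @param pixel_size Optional physical sampling in Angstrom/pixel (> 0).
#' @return An `em_image` object.
#' @examples
#' img <- image_create(c(3, 1, 2, 2), "int8", fill = 7)
#' im_dims(img)
#' @export
image_create <- function(dims, dtype = "float32", fill = 0,
                         pixel_size = NULL) {
  d <- .as_dims4(dims)
  .dtype_info(dtype)
  if (length(fill) != 1L || !is.numeric(fill)) {
    stop("fill must be a single numeric value", call. = FALSE)
  }
  cast <- dtype_cast(fill, "float64", dtype, policy = "error-on-overflow")
  if (!identical(as.double(cast), as.double(fill))) {
    stop("fill value ", fill, " is not representable in dtype ", dtype,
         call. = FALSE)
  }
  if (!is.null(pixel_size)) {
    if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
      stop("pixel_size must be a positive scalar (Angstrom/pixel)",
           call. = FALSE)
    }
  }
  data <- array(as.double(fill), dim = unname(d[c("x", "y", "z", "n")]))
  .new_em_image(data, dtype, pixel_size)
}

#' @export
is_em_image <- function(x) inherits(x, "em_image")

#' Wrap an array as an image
#'
#' Builds an `em_image` from a numeric array laid out the way the package
#' stores pixels: dimensions `(x, y)`, `(x, y, z)` or `(x, y, z, n)` with x
#' fastest (the layout [as.array()] returns). Values must already be valid
#' for `dtype`; integer dtypes reject non-integral or out-of-range values.
#'
#' @param data Numeric vector, matrix or array.
#' @param dtype Element type of the result (default `"float32"`).
#' @param pixel_size Optional pixel size in Angstrom/pixel.
#' @return An `em_image`.
#' @export
as_em_image <- function(data, dtype = "float32", pixel_size = NULL) {
  stopifnot(is.numeric(data))
  cast <- dtype_cast(data, "float64", dtype, policy = "error-on-overflow")
  if (.dtype_is_int(dtype) && !isTRUE(all(cast == data))) {
    stop("data contains values not representable in dtype ", dtype,
         call. = FALSE)
  }
  d <- dim(data)
  if (is.null(d)) d <- length(data)
  out <- cast
  dim(out) <- d
  .new_em_image(out, dtype, pixel_size)
}

#' Image dimensions
#'
#' @param img An `em_image`.
#' @return Named integer vector `(n, z, y, x)`: image count, slices, rows,
#'   columns.
#' @export
im_dims <- function(img) {
  stopifnot(is_em_image(img))
  d <- dim(img$data)
  stats::setNames(as.integer(rev(d)), c("n", "z", "y", "x"))
}

#' @export
print.em_image <- function(x, ...) {
  d <- im_dims(x)
  kind <- if (d["n"] > 1L) "stack" else if (d["z"] > 1L) "volume" else "image"
  ps <- if (is.null(x$pixel_size)) "unset" else
    paste0(format(x$pixel_size), " A/px")
  cat(sprintf("<em_image> %s n=%d z=%d y=%d x=%d  dtype=%s  pixel_size=%s\n",
              kind, d["n"], d["z"], d["y"], d["x"], x$dtype, ps))
  invisible(x)
}

#' @export
as.array.em_image <- function(x, ...) x$data

#' Image statistics
#'
#' Minimum, maximum, mean and standard deviation over all `n * z * y * x`
#' elements. The standard deviation uses the population formula (divide by
#' N), matching the convention of the MRC header RMS field.
#'
#' @param img An `em_image`.
#' @return A one-row tibble with columns `min`, `max`, `mean`, `sd`.
#' @examples
#' image_stats(image_create(c(1, 1, 4, 4), fill = 5))
#' @export
image_stats <- function(img) {
  stopifnot(is_em_image(img))
  m <- .buffer_moments(img$data)
  tibble::tibble(min = m[1], max = m[2], mean = m[3], sd = m[4])
}

.buffer_moments <- function(x) {
  mu <- mean(x)
  c(min(x), max(x), mu, sqrt(mean((x - mu)^2)))
}

#' Extract one item from a stack
#'
#' Returns the `i`-th item of a stack as a new single-item image. The result
#' is always a copy; mutating it never affects the source stack.
#'
#' @param img An `em_image`.
#' @param i Zero-based item index, `0 <= i < n`.
#' @return An `em_image` with `n = 1` and the same `z`, `y`, `x`.
#' @export
image_index <- function(img, i) {
  stopifnot(is_em_image(img))
  n <- im_dims(img)[["n"]]
  if (length(i) != 1L || !is.numeric(i) || is.na(i) ||
      i != floor(i) || i < 0 || i >= n) {
    stop("image index ", i, " out of range [0, ", n - 1L, "]", call. = FALSE)
  }
  data <- img$data[, , , i + 1L, drop = FALSE]
  .new_em_image(data, img$dtype, img$pixel_size, img$header_meta)
}

#' Assemble images into a stack
#'
#' Concatenates single-item (or multi-item) images along the stack axis.
#' All inputs must share `z`, `y`, `x` and dtype. This is the inverse of
#' splitting a stack with [image_index()].
#'
#' @param imgs A list of `em_image` objects.
#' @return An `em_image` whose `n` is the total item count.
#' @export
image_stack <- function(imgs) {
  if (is_em_image(imgs)) imgs <- list(imgs)
  stopifnot(length(imgs) >= 1L, all(vapply(imgs, is_em_image, logical(1))))
  d1 <- dim(imgs[[1]]$data)[1:3]
  dt <- imgs[[1]]$dtype
  for (im in imgs) {
    if (!identical(dim(im$data)[1:3], d1) || !identical(im$dtype, dt)) {
      stop("all images in a stack must share (z, y, x) dims and dtype",
           call. = FALSE)
    }
  }
  ntot <- sum(vapply(imgs, function(im) dim(im$data)[4], numeric(1)))
  data <- array(unlist(lapply(imgs, function(im) as.vector(im$data)),
                       use.names = FALSE),
                dim = c(d1, ntot))
  .new_em_image(data, dt, imgs[[1]]$pixel_size, imgs[[1]]$header_meta)
}

#' Plot an image slice
#'
#' Renders one 2-D slice of an image as a ggplot2 raster, in the usual EM
#' display orientation (first row at the top).
#'
#' @param object An `em_image`.
#' @param item Zero-based stack item to show.
#' @param slice Zero-based z-slice to show.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.em_image <- function(object, item = 0, slice = 0, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for autoplot()", call. = FALSE)
  }
  d <- im_dims(object)
  sl <- object$data[, , slice + 1L, item + 1L]
  df <- expand.grid(x = seq_len(d[["x"]]), y = seq_len(d[["y"]]))
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL)
}
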