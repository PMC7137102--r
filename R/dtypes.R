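# Element-type system. Buffers are held as R doubles throughout; a dtype tag
# carries the on-disk element type and the cast semantics. All seven supported
# types are exactly representable in a double, so in-memory storage is lossless.

.DTYPE_TABLE <- data.frame(
  name = c("int8", "int16", "int32", "uint8", "uint16", "float32", "float64"),
  kind = c("signed-int", "signed-int", "signed-int",
           "unsigned-int", "unsigned-int", "float", "float"),
  bits = c(8L, 16L, 32L, 8L, 16L, 32L, 64L),
  min  = c(-128, -32768, -2147483648, 0, 0, -Inf, -Inf),
  max  = c(127, 32767, 2147483647, 255, 65535, Inf, Inf),
  stringsAsFactors = FALSE
)

# Largest finite float32
.F32_MAX <- 3.4028234663852886e38

# dst types every value of src widens to losslessly
.DTYPE_WIDENS <- list(
  int8    = c("int16", "int32", "float32", "float64"),
  int16   = c("int32", "float32", "float64"),
  int32   = c("float64"),
  uint8   = c("uint16", "int16", "int32", "float32", "float64"),
  uint16  = c("int32", "float32", "float64"),
  float32 = c("float64"),
  float64 = character()
)

#' Supported element types
#'
#' The image element types understood by emkit: three signed integer widths,
#' two unsigned widths and two IEEE floating-point widths. These cover the
#' MRC2014 modes 0/1/2/6 and the SPIDER float32 pixel type.
#'
#' @return A tibble with one row per type: `name`, `kind` (signed-int,
#'   unsigned-int or float), `bits`, and the representable `min`/`max`
#'   (infinite for the float types).
#' @examples
#' em_dtypes()
#' @export
em_dtypes <- function() {
  tibble::as_tibble(.DTYPE_TABLE)
}

.dtype_info <- function(name) {
  i <- match(name, .DTYPE_TABLE$name)
  if (is.na(i)) {
    stop("unsupported dtype: '", name, "' (supported: ",
         paste(.DTYPE_TABLE$name, collapse = ", "), ")", call. = FALSE)
  }
  .DTYPE_TABLE[i, ]
}

.dtype_is_int <- function(name) .dtype_info(name)$kind != "float"

#' Test whether one element type widens losslessly to another
#'
#' `TRUE` when every value representable in `src` is exactly representable in
#' `dst` (for example int8 to float32, or uint16 to int32). The relation is a
#' partial order: int32 does not widen to float32 because a 32-bit integer can
#' exceed the 24-bit float mantissa.
#'
#' @param src,dst Canonical dtype names (see [em_dtypes()]).
#' @return Logical scalar.
#' @export
dtype_widens <- function(src, dst) {
  .dtype_info(src); .dtype_info(dst)
  src == dst || dst %in% .DTYPE_WIDENS[[src]]
}

# Round a double buffer to the nearest float32 value (exact binary rounding
# via a 4-byte serialization round trip).
.quantize_f32 <- function(x) {
  d <- dim(x)
  out <- readBin(writeBin(as.double(x), raw(), size = 4L, endian = "little"),
                 what = "double", n = length(x), size = 4L, endian = "little")
  dim(out) <- d
  out
}

#' Cast a buffer between element types
#'
#' Converts values between the supported element types with explicit
#' narrowing semantics. Widening casts are always value-exact. Casting to an
#' integer type rounds half-to-even and then either clamps to the target range
#' (`"round-clamp"`, the default, matching common EM converter behaviour) or
#' raises an error (`"error-on-overflow"`). Casting to float32 rounds to the
#' nearest representable single-precision value.
#'
#' @param buffer Numeric vector or array of values (dims are preserved).
#' @param src Source dtype name; values in `buffer` are assumed valid for it.
#' @param dst Target dtype name.
#' @param policy Narrowing policy, `"round-clamp"` or `"error-on-overflow"`.
#' @return The converted buffer as a double vector/array (emkit stores every
#'   buffer as doubles; the dtype tag tracks the element type).
#' @examples
#' dtype_cast(c(-1, 0, 127), "int8", "float32")
#' dtype_cast(c(3.5, 2.5), "float32", "int16")      # round-half-to-even: 4, 2
#' dtype_cast(300, "float32", "int8")               # clamps to 127
#' @export
dtype_cast <- function(buffer, src, dst,
                       policy = c("round-clamp", "error-on-overflow")) {
  policy <- match.arg(policy)
  .dtype_info(src)
  info <- .dtype_info(dst)
  x <- buffer
  storage.mode(x) <- "double"

  if (dst == "float64") return(x)

  if (dst == "float32") {
    out <- .quantize_f32(x)
    blown <- is.finite(x) & !is.finite(out)
    if (any(blown)) {
      if (policy == "error-on-overflow") {
        stop("overflow casting ", src, " -> float32", call. = FALSE)
      }
      out[blown] <- sign(x[blown]) * .F32_MAX
    }
    return(out)
  }

  # integer target
  if (any(!is.finite(x))) {
    stop("non-finite value cannot be cast to ", dst, call. = FALSE)
  }
  r <- round(x)  # round-half-to-even
  over <- r < info$min | r > info$max
  if (any(over)) {
    if (policy == "error-on-overflow") {
      stop("overflow casting ", src, " -> ", dst, ": value out of [",
           info$min, ", ", info$max, "]", call. = FALSE)
    }
    r[r < info$min] <- info$min
    r[r > info$max] <- info$max
  }
  r
}
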