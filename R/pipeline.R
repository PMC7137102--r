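# Processor concatenation: an ordered pipeline that is itself a processor.
# Intermediates stay in memory and are never exposed; a failure at any step
# aborts the whole run with no partial output.

#' Processor pipeline
#'
#' Builds a pipeline processor from zero or more processors. Running the
#' pipeline applies each step in insertion order to the previous step's
#' output, without persisting any intermediate image. An empty pipeline is
#' the identity.
#'
#' @param ... `em_processor` objects, executed left to right.
#' @return An `em_processor` of class `em_proc_pipe`.
#' @examples
#' p <- pipe_proc(math_proc("multiply", -1), scale_proc(0.5))
#' @export
pipe_proc <- function(...) {
  steps <- list(...)
  for (s in steps) {
    if (!inherits(s, "em_processor")) {
      stop("pipeline steps must be em_processor objects", call. = FALSE)
    }
  }
  structure(list(name = "pipe", params = list(), steps = steps),
            class = c("em_proc_pipe", "em_processor"))
}

#' Append a processor to a pipeline
#'
#' @param pipe An `em_proc_pipe`.
#' @param p The `em_processor` to append; it runs after the existing steps.
#' @return The extended pipeline.
#' @export
add_processor <- function(pipe, p) {
  stopifnot(inherits(pipe, "em_proc_pipe"))
  if (!inherits(p, "em_processor")) {
    stop("p must be an em_processor", call. = FALSE)
  }
  pipe$steps <- c(pipe$steps, list(p))
  pipe
}

#' @export
print.em_proc_pipe <- function(x, ...) {
  cat(sprintf("<em_processor:pipe> %d step(s): %s\n", length(x$steps),
              paste(vapply(x$steps, function(s) s$name, character(1)),
                    collapse = " -> ")))
  invisible(x)
}

#' @export
process.em_proc_pipe <- function(p, img, ...) {
  stopifnot(is_em_image(img))
  out <- img
  for (k in seq_along(p$steps)) {
    out <- tryCatch(
      process(p$steps[[k]], out),
      error = function(e) {
        stop("pipeline step ", k, " (", p$steps[[k]]$name, ") failed: ",
             conditionMessage(e), call. = FALSE)
      })
  }
  out
}
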