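# Containers for pressure-mat data: a frame is a 32x16 non-negative matrix,
# an activity sample is 7 ordered frames plus a class label.

MAT_ROWS <- 32L
MAT_COLS <- 16L
N_FRAMES <- 7L

STATIC_CLASSES <- c("no_press", "stand", "object")
DYNAMIC_CLASSES <- c("jump", "walk", "lr_shift", "tiptoe")
ALL_CLASSES <- c(STATIC_CLASSES, DYNAMIC_CLASSES)

#' Construct a pressure frame
#'
#' One 32x16 grid of non-negative sensor readings (raw ADC counts or
#' normalized intensities), the atomic input of the system. Row index runs
#' along the 32-tape direction of the mat; indexing is (row, col).
#'
#' @param grid Numeric 32x16 matrix with non-negative entries (other shapes
#'   are allowed for toy examples but the canonical mat is 32x16).
#' @return The validated matrix, classed `"pressure_frame"`.
#' @export
#' @examples
#' f <- pressure_frame(matrix(0, 32, 16))
pressure_frame <- function(grid) {
  if (!is.matrix(grid) || !is.numeric(grid)) {
    stop("invalid argument: 'grid' must be a numeric matrix")
  }
  if (anyNA(grid) || any(grid < 0)) {
    stop("invalid argument: pressure values must be non-negative and non-missing")
  }
  structure(grid, class = c("pressure_frame", "matrix", "array"))
}

frame_values <- function(frame) {
  unclass(frame)
}

#' Construct an activity sample
#'
#' Seven ordered pressure frames plus a class label. Static postures carry
#' seven element-wise identical frames (the mat image does not change); that
#' invariant is enforced here.
#'
#' @param frames List of exactly 7 `pressure_frame`s (or plain matrices) of
#'   one common shape.
#' @param label Class label (single character string).
#' @param is_static Logical; `TRUE` for static postures. If `TRUE`, all frames
#'   must be identical.
#' @return List with elements `frames`, `label`, `is_static`, classed
#'   `"activity_sample"`.
#' @export
activity_sample <- function(frames, label, is_static) {
  if (!is.list(frames) || length(frames) != N_FRAMES) {
    stop(sprintf("invalid argument: a sample must have exactly %d frames", N_FRAMES))
  }
  frames <- lapply(frames, function(f) {
    if (inherits(f, "pressure_frame")) f else pressure_frame(f)
  })
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("invalid argument: all frames in a sample must share one shape")
  }
  if (!is.character(label) || length(label) != 1L || is.na(label)) {
    stop("invalid argument: 'label' must be a single character string")
  }
  if (!is.logical(is_static) || length(is_static) != 1L || is.na(is_static)) {
    stop("invalid argument: 'is_static' must be TRUE or FALSE")
  }
  if (is_static) {
    for (i in 2:N_FRAMES) {
      if (!identical(frame_values(frames[[i]]), frame_values(frames[[1L]]))) {
        stop("invariant violation: a static sample must have identical frames")
      }
    }
  }
  structure(list(frames = frames, label = label, is_static = is_static),
            class = "activity_sample")
}

#' Construct a dataset of activity samples
#'
#' @param samples List of `activity_sample` objects.
#' @param meta Optional list of metadata (e.g. the generator configuration).
#' @return List of samples classed `"pressure_dataset"` with a `meta`
#'   attribute.
#' @export
pressure_dataset <- function(samples, meta = list()) {
  if (!is.list(samples) || length(samples) == 0L) {
    stop("invalid argument: 'samples' must be a non-empty list")
  }
  ok <- vapply(samples, inherits, logical(1), what = "activity_sample")
  if (!all(ok)) {
    stop("invalid argument: every element must be an activity_sample")
  }
  structure(samples, class = "pressure_dataset", meta = meta)
}

#' Extract the labels of a dataset
#'
#' @param x A `pressure_dataset` or list of `activity_sample`s.
#' @return Character vector of labels.
#' @export
dataset_labels <- function(x) {
  vapply(x, function(s) s$label, character(1))
}

#' @export
print.pressure_dataset <- function(x, ...) {
  lab <- dataset_labels(x)
  cat(sprintf("<pressure_dataset> %d samples, %d classes\n", length(x),
              length(unique(lab))))
  print(table(label = lab))
  invisible(x)
}

#' @export
print.activity_sample <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<activity_sample> label='%s' (%s), %d frames of %dx%d\n",
              x$label, if (x$is_static) "static" else "dynamic",
              length(x$frames), d[1], d[2]))
  invisible(x)
}

# Total pressure mass of a sample (sum over all frames and cells).
sample_mass <- function(s) {
  sum(vapply(s$frames, sum, numeric(1)))
}
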