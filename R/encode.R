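# Encoding of pressure frames and 7-frame sequences into hypervectors.
#
# Two encoders are provided:
#  * "window": window-based local encoding. Overlapping w x w windows are each
#    random-projection encoded (sign(B x F)), bound to a per-position bipolar
#    ID vector, and superposed; frames of a dynamic sequence are additionally
#    bound to per-frame ID vectors and superposed. The superposed outputs are
#    deliberately NOT sign-quantized: integer-valued image vectors preserve
#    more information for the cosine classifier, and quantization belongs only
#    inside the per-window projection.
#  * "flat": the conventional random-projection baseline. The whole sample is
#    flattened (512 features static, 512*7 = 3584 dynamic) and passed through
#    sign(B x F) once.
#
# One projection basis B is shared by all window positions; positions are
# distinguished solely by ID binding (a per-position basis would make the IDs
# redundant).

# Row-major flattening of a matrix: reading order (row 1 left-to-right, ...).
flatten_rowmajor <- function(m) {
  as.vector(t(m))
}

# 0-based window origins for a rows x cols grid: r in {0, s, 2s, ...} with
# r + w <= rows, likewise for columns; partial windows at the right/bottom
# edge are dropped (no padding). Windows ordered row-major.
window_origins <- function(rows, cols, w, s) {
  if (w > rows || w > cols) {
    stop("invalid argument: window size 'w' exceeds a frame dimension")
  }
  if (w < 1 || s < 1) {
    stop("invalid argument: 'w' and 's' must be positive integers")
  }
  r0 <- seq.int(0L, rows - w, by = s)
  c0 <- seq.int(0L, cols - w, by = s)
  cbind(row = rep(r0, each = length(c0)), col = rep(c0, times = length(r0)))
}

# d x n matrix of linear indices into a rows x cols matrix: column i holds the
# row-major-flattened cell indices of window i.
window_index_matrix <- function(rows, cols, w, s) {
  org <- window_origins(rows, cols, w, s)
  i <- rep(seq_len(w), each = w)   # within-window row, row-major order
  j <- rep(seq_len(w), times = w)  # within-window col
  idx <- matrix(0L, nrow = w * w, ncol = nrow(org))
  for (k in seq_len(nrow(org))) {
    idx[, k] <- (org[k, 2L] + j - 1L) * rows + org[k, 1L] + i
  }
  idx
}

#' Extract sliding windows from a pressure frame
#'
#' Enumerates all fully contained w x w windows with step `s` between origins,
#' ordered row-major; partial windows at the right/bottom edge are dropped.
#' The window count is `(floor((rows-w)/s)+1) * (floor((cols-w)/s)+1)`.
#'
#' @param frame Numeric matrix (a `pressure_frame`).
#' @param w Window edge length (default 8).
#' @param s Step between window origins (default 3).
#' @return List with `origins` (n x 2 integer matrix of 0-based (row, col)
#'   origins) and `windows` (a `w*w` x n matrix whose column i is window i
#'   flattened row-major).
#' @export
#' @examples
#' ws <- extract_windows(matrix(runif(32 * 16), 32, 16))
#' ncol(ws$windows)  # 27 windows for the 32x16 mat at w = 8, s = 3
extract_windows <- function(frame, w = 8L, s = 3L) {
  if (!is.matrix(frame) || !is.numeric(frame)) {
    stop("invalid argument: 'frame' must be a numeric matrix")
  }
  org <- window_origins(nrow(frame), ncol(frame), w, s)
  idx <- window_index_matrix(nrow(frame), ncol(frame), w, s)
  vals <- matrix(frame[as.vector(idx)], nrow = w * w, ncol = nrow(org))
  list(origins = org, windows = vals)
}

#' Build a seeded encoder
#'
#' Holds everything the encoding needs: the Gaussian random-projection basis,
#' one bipolar ID hypervector per window position, and one per frame index.
#' Identical seeds reproduce the encoder bit-for-bit.
#'
#' @param method `"window"` for window-based local encoding (default) or
#'   `"flat"` for the conventional whole-sample baseline.
#' @param dim Hypervector dimensionality D. Defaults to 200 for the window
#'   encoder and 10000 for the flat baseline.
#' @param rows,cols Frame shape (default 32 x 16).
#' @param n_frames Frames per sample (default 7).
#' @param w,s Window edge length and step (defaults 8 and 3); window method
#'   only.
#' @param seed Master seed; spawns independent sub-seeds for the basis and the
#'   ID vectors.
#' @return An object of class `"hdc_encoder"`.
#' @export
#' @examples
#' enc <- hdc_encoder(dim = 50, seed = 1)
#' enc
hdc_encoder <- function(method = c("window", "flat"), dim = NULL,
                        rows = 32L, cols = 16L, n_frames = 7L,
                        w = 8L, s = 3L, seed = 1L) {
  method <- match.arg(method)
  if (is.null(dim)) dim <- if (method == "window") 200L else 10000L
  if (!is.numeric(dim) || length(dim) != 1L || dim < 1) {
    stop("invalid argument: 'dim' must be a positive integer")
  }
  dim <- as.integer(dim)
  rows <- as.integer(rows); cols <- as.integer(cols)
  seeds <- derive_seeds(seed, 3L)
  if (method == "window") {
    org <- window_origins(rows, cols, w, s)   # validates w, s
    n_win <- nrow(org)
    d <- as.integer(w)^2
    basis <- with_seed(seeds[1L], matrix(stats::rnorm(dim * d), dim, d))
    window_ids <- with_seed(seeds[2L],
                            matrix(sample(c(-1, 1), dim * n_win, replace = TRUE),
                                   dim, n_win))
  } else {
    d <- rows * cols * as.integer(n_frames)
    basis <- with_seed(seeds[1L], matrix(stats::rnorm(dim * d), dim, d))
    window_ids <- NULL
    n_win <- NA_integer_
  }
  frame_ids <- with_seed(seeds[3L],
                         matrix(sample(c(-1, 1), dim * n_frames, replace = TRUE),
                                dim, as.integer(n_frames)))
  structure(list(method = method, dim = dim, rows = rows, cols = cols,
                 n_frames = as.integer(n_frames),
                 w = as.integer(w), s = as.integer(s), n_windows = n_win,
                 basis = basis, window_ids = window_ids, frame_ids = frame_ids,
                 widx = if (method == "window") window_index_matrix(rows, cols, w, s) else NULL,
                 seed = as.integer(seed)),
            class = "hdc_encoder")
}

#' @export
print.hdc_encoder <- function(x, ...) {
  if (x$method == "window") {
    cat(sprintf(
      "<hdc_encoder> window-based local encoding: D=%d, %dx%d frames, w=%d, s=%d (%d windows), seed=%d\n",
      x$dim, x$rows, x$cols, x$w, x$s, x$n_windows, x$seed))
  } else {
    cat(sprintf("<hdc_encoder> flat random-projection baseline: D=%d, %dx%dx%d features, seed=%d\n",
                x$dim, x$rows, x$cols, x$n_frames, x$seed))
  }
  invisible(x)
}

#' Random-projection encode a single window
#'
#' Computes `sign(B %*% F)` for one flattened window: the elementary encoding
#' step. Zero projections quantize to +1 (fixed tie-break), so an all-zero
#' window maps to the all-ones hypervector.
#'
#' @param window A w x w numeric matrix (flattened row-major internally) or a
#'   length-d feature vector.
#' @param basis D x d projection matrix.
#' @return Bipolar hypervector of length D.
#' @export
encode_window <- function(window, basis) {
  f <- if (is.matrix(window)) flatten_rowmajor(window) else as.numeric(window)
  if (!is.matrix(basis) || ncol(basis) != length(f)) {
    stop("dimension mismatch: basis columns must equal the window feature length")
  }
  hv_sign(as.vector(basis %*% f))
}

#' Encode one pressure frame with the window-based encoder
#'
#' Every window i is projection-encoded to a bipolar W_i, bound to its
#' positional ID vector, and the n bound vectors are superposed:
#' `sum_i bind(W_i, ID_i)`. The result is integer-valued with elements in
#' `[-n, n]` and is not sign-quantized.
#'
#' @param frame Numeric matrix matching the encoder's frame shape.
#' @param encoder A window-method `hdc_encoder`.
#' @return Numeric hypervector of length `encoder$dim`.
#' @export
encode_frame <- function(frame, encoder) {
  if (!inherits(encoder, "hdc_encoder") || encoder$method != "window") {
    stop("invalid argument: 'encoder' must be a window-method hdc_encoder")
  }
  if (!is.matrix(frame) || nrow(frame) != encoder$rows || ncol(frame) != encoder$cols) {
    stop(sprintf("invalid argument: frame shape must be %dx%d to match the encoder",
                 encoder$rows, encoder$cols))
  }
  wins <- matrix(frame[as.vector(encoder$widx)], nrow = encoder$w^2)
  proj <- encoder$basis %*% wins          # D x n
  signs <- (proj >= 0) * 2 - 1            # per-window bipolar encodings
  rowSums(signs * encoder$window_ids)
}

#' Encode an activity sample
#'
#' Window method: a static sample is encoded from its (identical) first frame;
#' a dynamic sample encodes each frame, binds it to the frame's temporal ID
#' vector, and superposes the 7 bound vectors. Flat method: the sample is
#' flattened (first frame only when static) and projection-encoded in one
#' step, `sign(B %*% F)`.
#'
#' @param sample An `activity_sample`.
#' @param encoder An `hdc_encoder` built for the sample's frame shape.
#' @return Numeric hypervector of length `encoder$dim` (bipolar for the flat
#'   method; integer-valued for the window method).
#' @export
encode_sample <- function(sample, encoder) {
  if (!inherits(sample, "activity_sample")) {
    stop("invalid argument: 'sample' must be an activity_sample")
  }
  if (!inherits(encoder, "hdc_encoder")) {
    stop("invalid argument: 'encoder' must be an hdc_encoder")
  }
  if (encoder$method == "window") {
    if (sample$is_static) {
      return(encode_frame(frame_values(sample$frames[[1L]]), encoder))
    }
    acc <- numeric(encoder$dim)
    for (i in seq_along(sample$frames)) {
      acc <- acc + encode_frame(frame_values(sample$frames[[i]]), encoder) *
        encoder$frame_ids[, i]
    }
    return(acc)
  }
  # flat baseline
  f1 <- frame_values(sample$frames[[1L]])
  if (nrow(f1) != encoder$rows || ncol(f1) != encoder$cols) {
    stop(sprintf("invalid argument: frame shape must be %dx%d to match the encoder",
                 encoder$rows, encoder$cols))
  }
  d_frame <- encoder$rows * encoder$cols
  if (sample$is_static) {
    f <- flatten_rowmajor(f1)
    hv_sign(as.vector(encoder$basis[, seq_len(d_frame), drop = FALSE] %*% f))
  } else {
    f <- unlist(lapply(sample$frames, function(fr) flatten_rowmajor(frame_values(fr))),
                use.names = FALSE)
    hv_sign(as.vector(encoder$basis %*% f))
  }
}

#' Encode a sample with the conventional flat baseline
#'
#' Convenience wrapper: builds a seeded flat encoder for the sample's shape
#' and applies one whole-sample random projection, `sign(B %*% F)`. For
#' repeated encoding build the encoder once with [hdc_encoder()] and call
#' [encode_sample()].
#'
#' @param sample An `activity_sample`.
#' @param dim Hypervector dimensionality (default 10000, the baseline HDC
#'   setting).
#' @param seed Seed for the projection basis.
#' @return Bipolar hypervector of length `dim`.
#' @export
encode_flat_baseline <- function(sample, dim = 10000L, seed = 1L) {
  f1 <- frame_values(sample$frames[[1L]])
  enc <- hdc_encoder(method = "flat", dim = dim, rows = nrow(f1), cols = ncol(f1),
                     n_frames = length(sample$frames), seed = seed)
  encode_sample(sample, enc)
}
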