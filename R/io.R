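# Persistence: datasets and models round-trip losslessly through R's native
# serialized archive (compressed, typed), with an explicit format/version
# field that fails loudly on mismatch. A plain CSV export (one row per frame)
# is provided for interoperability with other tools.

DATASET_FORMAT <- "hdpress_dataset"
MODEL_FORMAT <- "hdpress_model"
FORMAT_VERSION <- 1L

#' Convert a dataset to a dense array
#'
#' @param data A `pressure_dataset`.
#' @return Numeric array of shape `(n_samples, 7, rows, cols)`.
#' @export
dataset_to_array <- function(data) {
  n <- length(data)
  f1 <- frame_values(data[[1L]]$frames[[1L]])
  arr <- array(0, dim = c(n, length(data[[1L]]$frames), nrow(f1), ncol(f1)))
  for (i in seq_len(n)) {
    for (j in seq_along(data[[i]]$frames)) {
      arr[i, j, , ] <- frame_values(data[[i]]$frames[[j]])
    }
  }
  arr
}

#' Save a dataset to a versioned archive
#'
#' @param data A `pressure_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_dataset <- function(data, path) {
  if (!inherits(data, "pressure_dataset")) data <- pressure_dataset(data)
  obj <- list(format = DATASET_FORMAT, version = FORMAT_VERSION,
              frames = dataset_to_array(data),
              labels = dataset_labels(data),
              is_static = vapply(data, function(s) s$is_static, logical(1)),
              meta = attr(data, "meta"))
  saveRDS(obj, path)
  invisible(path)
}

read_archive <- function(path, what) {
  obj <- tryCatch(suppressWarnings(readRDS(path)),
                  error = function(e) stop(sprintf(
                    "format error: cannot read '%s' (%s)", path, conditionMessage(e))))
  if (!is.list(obj) || is.null(obj$format) || obj$format != what) {
    stop(sprintf("format error: '%s' is not a %s archive", path, what))
  }
  if (is.null(obj$version) || obj$version != FORMAT_VERSION) {
    stop(sprintf("unsupported version: '%s' has format version %s, expected %d",
                 path, as.character(obj$version), FORMAT_VERSION))
  }
  obj
}

#' Load a dataset archive
#'
#' Validates the format and version fields and the shape consistency between
#' frames and labels; truncated or mismatched files raise a format error
#' rather than yielding silent partial data.
#'
#' @param path Path written by [save_dataset()].
#' @return A `pressure_dataset`.
#' @export
load_dataset <- function(path) {
  obj <- read_archive(path, DATASET_FORMAT)
  if (!is.array(obj$frames) || length(dim(obj$frames)) != 4L) {
    stop("format error: field 'frames' must be a 4-d array")
  }
  n <- dim(obj$frames)[1L]
  if (length(obj$labels) != n || length(obj$is_static) != n) {
    stop("format error: field 'labels' length does not match the frame array")
  }
  if (any(obj$frames < 0)) {
    stop("format error: field 'frames' contains negative pressure values")
  }
  samples <- lapply(seq_len(n), function(i) {
    frames <- lapply(seq_len(dim(obj$frames)[2L]), function(j) {
      pressure_frame(matrix(obj$frames[i, j, , ], dim(obj$frames)[3L],
                            dim(obj$frames)[4L]))
    })
    activity_sample(frames, obj$labels[i], obj$is_static[i])
  })
  pressure_dataset(samples, meta = obj$meta)
}

#' Export a dataset to CSV (one row per frame)
#'
#' Columns: `sample_id`, `frame_idx`, the 512 cell values `r0c0` ... `r31c15`
#' in row-major order (0-based (row, col) indexing), and `label`.
#'
#' @param data A `pressure_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(data, path) {
  if (!inherits(data, "pressure_dataset")) data <- pressure_dataset(data)
  f1 <- frame_values(data[[1L]]$frames[[1L]])
  rows <- nrow(f1); cols <- ncol(f1)
  cell_names <- paste0("r", rep(0:(rows - 1L), each = cols),
                       "c", rep(0:(cols - 1L), times = rows))
  n_frames <- length(data[[1L]]$frames)
  mat <- matrix(0, nrow = length(data) * n_frames, ncol = rows * cols,
                dimnames = list(NULL, cell_names))
  sample_id <- integer(nrow(mat)); frame_idx <- integer(nrow(mat))
  label <- character(nrow(mat))
  r <- 0L
  for (i in seq_along(data)) {
    for (j in seq_len(n_frames)) {
      r <- r + 1L
      mat[r, ] <- flatten_rowmajor(frame_values(data[[i]]$frames[[j]]))
      sample_id[r] <- i; frame_idx[r] <- j; label[r] <- data[[i]]$label
    }
  }
  df <- data.frame(sample_id = sample_id, frame_idx = frame_idx, mat,
                   label = label, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset from the CSV interchange format
#'
#' Inverse of [write_dataset_csv()]. A sample is flagged static when its
#' seven frames are element-wise identical.
#'
#' @param path CSV path.
#' @param rows,cols Frame shape (default 32 x 16).
#' @return A `pressure_dataset`.
#' @export
read_dataset_csv <- function(path, rows = 32L, cols = 16L) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("sample_id", "frame_idx", "label")
  if (!all(need %in% names(df))) {
    stop("format error: CSV must have sample_id, frame_idx, and label columns")
  }
  cell_cols <- setdiff(names(df), need)
  if (length(cell_cols) != rows * cols) {
    stop(sprintf("format error: expected %d cell columns, found %d",
                 rows * cols, length(cell_cols)))
  }
  samples <- lapply(unique(df$sample_id), function(sid) {
    sub <- df[df$sample_id == sid, , drop = FALSE]
    sub <- sub[order(sub$frame_idx), , drop = FALSE]
    frames <- lapply(seq_len(nrow(sub)), function(j) {
      pressure_frame(matrix(as.numeric(sub[j, cell_cols]), rows, cols,
                            byrow = TRUE))
    })
    static <- all(vapply(frames[-1L], function(f)
      identical(frame_values(f), frame_values(frames[[1L]])), logical(1)))
    activity_sample(frames, as.character(sub$label[1L]), static)
  })
  pressure_dataset(samples)
}

#' Save a fitted model to a versioned archive
#'
#' The archive holds the class prototypes, the full encoder (basis and ID
#' vectors), normalization range, class order, and seeds, so predictions are
#' bit-identical after a round trip.
#'
#' @param object A fitted `"hdc"` model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(object, path) {
  if (!inherits(object, "hdc")) {
    stop("invalid argument: 'object' must be a fitted 'hdc' model")
  }
  saveRDS(list(format = MODEL_FORMAT, version = FORMAT_VERSION, model = object),
          path)
  invisible(path)
}

#' Load a fitted model archive
#'
#' @param path Path written by [save_model()].
#' @return The `"hdc"` model.
#' @export
load_model <- function(path) {
  obj <- read_archive(path, MODEL_FORMAT)
  m <- obj$model
  if (!inherits(m, "hdc") || !is.matrix(m$prototypes) ||
      !is.numeric(m$prototypes) || anyNA(m$prototypes) ||
      ncol(m$prototypes) != length(m$classes) ||
      nrow(m$prototypes) != m$encoder$dim) {
    stop("format error: corrupted prototype block in model archive")
  }
  m
}
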