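# Prototype-based HDC classifier.
#
# Training accumulates the encoded hypervector of every training sample into
# its class prototype C_l (element-wise sum). Inference encodes the query and
# assigns the class whose prototype has the highest cosine similarity.
# Retraining runs mistake-driven online passes over the training set: each
# misclassified sample's encoding H is added to the true class prototype and
# subtracted from the wrongly predicted one (C_l += H, C_l' -= H), with a
# seeded shuffle per epoch.

# cosine scores of encodings E (D x N) against prototypes P (D x K).
# Zero-norm prototypes yield NA scores; zero-norm queries yield NA columns.
proto_scores <- function(P, E) {
  np <- sqrt(colSums(P * P))
  ne <- sqrt(colSums(E * E))
  S <- crossprod(P, E) / (np * rep(ne, each = ncol(P)))  # K x N
  S[!is.finite(S)] <- NA_real_
  S
}

# argmax with deterministic tie-break: highest score wins, ties and NA scores
# resolved by class order (first wins).
score_argmax <- function(S) {
  apply(S, 2L, function(sc) {
    sc[is.na(sc)] <- -Inf
    if (all(sc == -Inf)) 1L else which.max(sc)
  })
}

# One online retraining epoch over cached encodings. Returns updated
# prototypes and the accuracy observed during the pass.
retrain_pass <- function(P, E, label_idx, shuffle_seed) {
  ord <- with_seed(shuffle_seed, sample.int(ncol(E)))
  np <- sqrt(colSums(P * P))
  correct <- 0L
  for (j in ord) {
    e <- E[, j]
    ne <- sqrt(sum(e * e))
    sc <- as.vector(crossprod(P, e)) / (np * ne)
    sc[!is.finite(sc)] <- -Inf
    pred <- if (all(sc == -Inf)) 1L else which.max(sc)
    truth <- label_idx[j]
    if (pred == truth) {
      correct <- correct + 1L
    } else {
      P[, truth] <- P[, truth] + e
      P[, pred] <- P[, pred] - e
      np[truth] <- sqrt(sum(P[, truth]^2))
      np[pred] <- sqrt(sum(P[, pred]^2))
    }
  }
  list(prototypes = P, accuracy = correct / ncol(E))
}

# Encode a whole dataset in batched matrix products (one gemm against the
# projection basis instead of one gemv per sample); numerically identical to
# encode_sample() applied per sample.
encode_dataset <- function(samples, encoder, norm_range) {
  samples <- lapply(samples, normalize_sample, norm_range = norm_range)
  n <- length(samples)
  if (encoder$method == "flat") {
    d_frame <- encoder$rows * encoder$cols
    d <- d_frame * encoder$n_frames
    FM <- matrix(0, nrow = d, ncol = n)
    for (j in seq_len(n)) {
      s <- samples[[j]]
      if (s$is_static) {
        # identical frames: only the first frame's feature block is used,
        # zero padding leaves the projection unchanged
        FM[seq_len(d_frame), j] <- flatten_rowmajor(frame_values(s$frames[[1L]]))
      } else {
        FM[, j] <- unlist(lapply(s$frames, function(fr)
          flatten_rowmajor(frame_values(fr))), use.names = FALSE)
      }
    }
    return((encoder$basis %*% FM >= 0) * 2 - 1)
  }
  # window method: gather every distinct frame to encode, then recombine
  frames_per <- vapply(samples, function(s) if (s$is_static) 1L else
    length(s$frames), integer(1))
  offsets <- c(0L, cumsum(frames_per))
  d <- encoder$w^2
  n_win <- encoder$n_windows
  W <- matrix(0, nrow = d, ncol = n_win * sum(frames_per))
  col <- 0L
  for (s in samples) {
    k <- if (s$is_static) 1L else length(s$frames)
    for (i in seq_len(k)) {
      W[, col + seq_len(n_win)] <- frame_values(s$frames[[i]])[as.vector(encoder$widx)]
      col <- col + n_win
    }
  }
  S <- (encoder$basis %*% W >= 0) * 2 - 1
  E <- matrix(0, nrow = encoder$dim, ncol = n)
  for (j in seq_len(n)) {
    s <- samples[[j]]
    blk <- S[, offsets[j] * n_win + seq_len(n_win * frames_per[j]), drop = FALSE]
    if (s$is_static) {
      E[, j] <- rowSums(blk * encoder$window_ids)
    } else {
      acc <- numeric(encoder$dim)
      for (i in seq_len(frames_per[j])) {
        fe <- rowSums(blk[, (i - 1L) * n_win + seq_len(n_win), drop = FALSE] *
                        encoder$window_ids)
        acc <- acc + fe * encoder$frame_ids[, i]
      }
      E[, j] <- acc
    }
  }
  E
}

# Dataset-level min-max normalization to [0, 1]; the stored range comes from
# the training data so ADC scale is irrelevant at prediction time.
normalize_sample <- function(sample, norm_range) {
  lo <- norm_range[1L]; hi <- norm_range[2L]
  if (lo == 0 && hi == 1) return(sample)
  frames <- lapply(sample$frames, function(f) {
    g <- (frame_values(f) - lo) / (hi - lo)
    g[g < 0] <- 0
    pressure_frame(g)
  })
  structure(list(frames = frames, label = sample$label, is_static = sample$is_static),
            class = "activity_sample")
}

#' Fit a hyperdimensional-computing activity classifier
#'
#' Encodes every training sample into a D-dimensional hypervector, sums the
#' encodings per class into prototype hypervectors, and (optionally) runs
#' mistake-driven online retraining epochs. Classification is
#' nearest-prototype by cosine similarity.
#'
#' @param data A `pressure_dataset` (or list of `activity_sample`s) with at
#'   least one sample per class.
#' @param method `"window"` for the window-based local encoder (default) or
#'   `"flat"` for the conventional whole-sample random-projection baseline.
#' @param dim Hypervector dimensionality D; defaults to 200 for `"window"`
#'   and 10000 for `"flat"`.
#' @param w,s Window edge length and step for the window encoder (defaults 8
#'   and 3).
#' @param epochs Number of retraining epochs (default 20); 0 gives the pure
#'   accumulation model.
#' @param seed Master seed; deterministically spawns the encoder seed and the
#'   per-epoch shuffle seeds.
#' @param normalize If `TRUE` (default), frames are min-max normalized to
#'   `[0, 1]` using the range of the training data (stored in the model and
#'   re-applied at prediction time).
#' @return An object of class `"hdc"`: a list with `prototypes` (D x K
#'   matrix, one column per class in sorted label order), `classes`,
#'   `encoder`, `epochs_trained`, `accuracy_trace` (training accuracy
#'   observed during each retraining pass), `norm_range`, and `call`.
#' @seealso [predict.hdc()], [hdc_retrain()], [hdc_accuracy()]
#' @export
#' @examples
#' cfg <- synth_config(classes = c("no_press", "stand"), n_per_class = 10, seed = 1)
#' d <- generate_dataset(cfg)
#' fit <- hdc(d$train, dim = 100, epochs = 5, seed = 1)
#' fit
#' hdc_accuracy(fit, d$test)
hdc <- function(data, method = c("window", "flat"), dim = NULL,
                w = 8L, s = 3L, epochs = 20L, seed = 1L, normalize = TRUE) {
  method <- match.arg(method)
  if (!is.list(data) || length(data) == 0L) {
    stop("invalid argument: 'data' must be a non-empty list of activity samples")
  }
  if (epochs < 0) stop("invalid argument: 'epochs' must be >= 0")
  labels <- dataset_labels(data)
  classes <- sort(unique(labels))
  f1 <- frame_values(data[[1L]]$frames[[1L]])
  seeds <- derive_seeds(seed, 2L)
  encoder <- hdc_encoder(method = method, dim = dim,
                         rows = nrow(f1), cols = ncol(f1),
                         n_frames = length(data[[1L]]$frames),
                         w = w, s = s, seed = seeds[1L])
  norm_range <- if (normalize) {
    vals <- range(unlist(lapply(data, function(s)
      range(vapply(s$frames, function(f) range(frame_values(f)), numeric(2))))))
    if (vals[2L] > vals[1L]) vals else c(0, 1)
  } else {
    c(0, 1)
  }
  E <- encode_dataset(data, encoder, norm_range)
  label_idx <- match(labels, classes)
  P <- matrix(0, nrow = encoder$dim, ncol = length(classes),
              dimnames = list(NULL, classes))
  for (k in seq_along(classes)) {
    P[, k] <- rowSums(E[, label_idx == k, drop = FALSE])
  }
  trace <- numeric(0)
  if (epochs > 0) {
    epoch_seeds <- derive_seeds(seeds[2L], epochs)
    for (e in seq_len(epochs)) {
      res <- retrain_pass(P, E, label_idx, epoch_seeds[e])
      P <- res$prototypes
      trace <- c(trace, res$accuracy)
    }
  }
  structure(list(prototypes = P, classes = classes, encoder = encoder,
                 epochs_trained = as.integer(epochs), accuracy_trace = trace,
                 norm_range = norm_range, n_train = length(data),
                 seed = as.integer(seed), call = match.call()),
            class = "hdc")
}

#' Run additional mistake-driven retraining epochs
#'
#' Performs online passes over `data`: each misclassified sample's encoding H
#' is added to the correct class prototype and subtracted from the wrongly
#' assigned one, updates applied immediately, with a fresh seeded shuffle per
#' epoch.
#'
#' @param object A fitted `"hdc"` model.
#' @param data Training samples; every label must already be known to the
#'   model.
#' @param epochs Number of passes (default 1).
#' @param seed Seed for the per-epoch shuffles.
#' @return The updated `"hdc"` model.
#' @export
hdc_retrain <- function(object, data, epochs = 1L, seed = 1L) {
  stopifnot(inherits(object, "hdc"))
  if (!is.list(data) || length(data) == 0L) {
    stop("invalid argument: 'data' must be a non-empty list of activity samples")
  }
  labels <- dataset_labels(data)
  unknown <- setdiff(labels, object$classes)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown class: label(s) %s were not in the training label set",
                 paste(sQuote(unknown), collapse = ", ")))
  }
  E <- encode_dataset(data, object$encoder, object$norm_range)
  label_idx <- match(labels, object$classes)
  epoch_seeds <- derive_seeds(seed, epochs)
  P <- object$prototypes
  for (e in seq_len(epochs)) {
    res <- retrain_pass(P, E, label_idx, epoch_seeds[e])
    P <- res$prototypes
    object$accuracy_trace <- c(object$accuracy_trace, res$accuracy)
  }
  object$prototypes <- P
  object$epochs_trained <- object$epochs_trained + as.integer(epochs)
  object
}

#' Predict activity classes for new samples
#'
#' Encodes each query sample with the model's encoder and assigns the class
#' whose prototype has the highest cosine similarity. Ties and degenerate
#' (zero-norm) prototypes are resolved by class order, first wins; a query
#' that encodes to the zero vector is classified by class order with a
#' warning.
#'
#' @param object A fitted `"hdc"` model.
#' @param newdata A `pressure_dataset`, list of `activity_sample`s, or a
#'   single `activity_sample`.
#' @param type `"class"` (default) returns the predicted labels;
#'   `"scores"` returns a list with `class` and the N x K cosine score
#'   matrix (NA where a prototype is degenerate).
#' @param ... Unused.
#' @return Character vector of labels, or a list for `type = "scores"`.
#' @export
predict.hdc <- function(object, newdata, type = c("class", "scores"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "activity_sample")) newdata <- list(newdata)
  if (!is.list(newdata) || length(newdata) == 0L) {
    stop("invalid argument: 'newdata' must contain at least one sample")
  }
  E <- encode_dataset(newdata, object$encoder, object$norm_range)
  if (any(colSums(E * E) == 0)) {
    warning("query encoded to a zero hypervector; classified by class order")
  }
  S <- proto_scores(object$prototypes, E)   # K x N
  if (any(apply(S, 2L, function(s) all(is.na(s))))) {
    warning("all class similarities degenerate; classified by class order")
  }
  idx <- score_argmax(S)
  cls <- object$classes[idx]
  if (type == "class") return(cls)
  scores <- t(S)
  dimnames(scores) <- list(NULL, object$classes)
  list(class = cls, scores = scores)
}

#' Classification accuracy on labelled samples
#'
#' @param object A fitted `"hdc"` model.
#' @param data Non-empty labelled samples.
#' @return Fraction of samples whose predicted label equals the true label.
#' @export
hdc_accuracy <- function(object, data) {
  if (inherits(data, "activity_sample")) data <- list(data)
  if (!is.list(data) || length(data) == 0L) {
    stop("invalid argument: 'data' must contain at least one sample")
  }
  mean(predict(object, data) == dataset_labels(data))
}

#' @export
print.hdc <- function(x, ...) {
  cat("Hyperdimensional-computing activity classifier\n")
  cat(sprintf("  encoding : %s (D = %d%s)\n",
              if (x$encoder$method == "window") "window-based local" else "flat random projection",
              x$encoder$dim,
              if (x$encoder$method == "window")
                sprintf(", w = %d, s = %d, %d windows", x$encoder$w, x$encoder$s,
                        x$encoder$n_windows) else ""))
  cat(sprintf("  classes  : %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  trained  : %d samples, %d retraining epoch(s)\n",
              x$n_train, x$epochs_trained))
  if (length(x$accuracy_trace) > 0) {
    cat(sprintf("  training accuracy (last pass): %.3f\n",
                x$accuracy_trace[length(x$accuracy_trace)]))
  }
  invisible(x)
}

#' @export
summary.hdc <- function(object, ...) {
  out <- list(
    method = object$encoder$method,
    dim = object$encoder$dim,
    classes = object$classes,
    prototype_norms = sqrt(colSums(object$prototypes^2)),
    epochs_trained = object$epochs_trained,
    accuracy_trace = object$accuracy_trace,
    n_train = object$n_train
  )
  class(out) <- "summary.hdc"
  out
}

#' @export
print.summary.hdc <- function(x, ...) {
  cat(sprintf("HDC classifier (%s encoding, D = %d), %d training samples\n",
              x$method, x$dim, x$n_train))
  cat("Prototype L2 norms:\n")
  print(round(x$prototype_norms, 2))
  if (length(x$accuracy_trace) > 0) {
    cat(sprintf("Retraining: %d epochs; online accuracy %.3f -> %.3f\n",
                x$epochs_trained, x$accuracy_trace[1],
                x$accuracy_trace[length(x$accuracy_trace)]))
  } else {
    cat("No retraining epochs run.\n")
  }
  invisible(x)
}

#' Extract class prototype hypervectors
#'
#' @param object A fitted `"hdc"` model.
#' @param ... Unused.
#' @return D x K numeric matrix, one column per class.
#' @export
coef.hdc <- function(object, ...) {
  object$prototypes
}
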