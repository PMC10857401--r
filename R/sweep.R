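# Experiment harness: train-clean / test-noisy sweeps over a grid of noise
# intensities, comparing the window-based encoder against the flat
# random-projection baseline, averaged over seeded replicate runs.

#' Run a train-clean / test-noisy sweep over a noise-intensity grid
#'
#' For each of `n_seeds` replicate seeds: a fresh synthetic dataset is
#' generated, one model per method is trained on clean data, and test
#' accuracy is measured at every intensity on the grid. Frame-targeted noise
#' perturbs the test samples; prototype-targeted noise perturbs the stored
#' class hypervectors post-training; encoded-vector noise perturbs the
#' encoded queries (sign-quantized first for bitflip, since only quantized
#' vectors can be bit-flipped). Zero intensity reproduces the clean accuracy
#' exactly.
#'
#' @param kind Noise kind, as in [noise_spec()].
#' @param grid Numeric vector of intensities, sorted ascending, length >= 1.
#' @param cfg [synth_config()] describing the dataset; its seed is replaced
#'   by per-replicate sub-seeds.
#' @param target Noise target; default is the kind's natural target.
#' @param methods Encoders to compare: subset of `c("window", "flat")`.
#' @param dims Named dimensionalities per method. The default
#'   `c(window = 200, flat = 10000)` matches the usual operating points; use
#'   `c(window = 200, flat = 200)` for a D-matched comparison that isolates
#'   the encoder effect from capacity.
#' @param n_seeds Number of replicate runs (default 10).
#' @param epochs Retraining epochs per model (default 20).
#' @param seed Master seed for the whole sweep.
#' @return Object of class `"hdc_sweep"`: list with `results` (long
#'   data.frame: method, kind, target, intensity, seed, accuracy), the grid,
#'   and run metadata. `summary()` aggregates to mean/sd per method and
#'   intensity.
#' @export
noise_sweep <- function(kind, grid, cfg = synth_config(), target = NULL,
                        methods = c("window", "flat"),
                        dims = c(window = 200L, flat = 10000L),
                        n_seeds = 10L, epochs = 20L, seed = 1L) {
  if (!is.numeric(grid) || length(grid) == 0L) {
    stop("invalid argument: 'grid' must contain at least one intensity")
  }
  if (is.unsorted(grid)) {
    stop("invalid argument: 'grid' must be sorted ascending")
  }
  methods <- match.arg(methods, c("window", "flat"), several.ok = TRUE)
  # validates kind/target combination once, up front
  probe <- noise_spec(kind, grid[length(grid)], target = target)
  target <- probe$target
  run_seeds <- derive_seeds(seed, n_seeds)
  rows <- list()
  for (r in seq_len(n_seeds)) {
    sub <- derive_seeds(run_seeds[r], 3L + length(grid))
    cfg_r <- cfg; cfg_r$seed <- sub[1L]
    data <- generate_dataset(cfg_r)
    for (m in methods) {
      fit <- hdc(data$train, method = m, dim = dims[[m]], epochs = epochs,
                 seed = sub[2L])
      enc_test <- NULL
      if (target == "encoded_vector") {
        enc_test <- encode_dataset(data$test, fit$encoder, fit$norm_range)
        if (kind == "bitflip") enc_test <- (enc_test >= 0) * 2 - 1
      }
      truth <- dataset_labels(data$test)
      for (gi in seq_along(grid)) {
        spec <- noise_spec(kind, grid[gi], target = target, seed = sub[3L + gi])
        acc <- switch(target,
          frame = {
            noisy <- apply_noise(data$test, spec)
            hdc_accuracy(fit, noisy)
          },
          prototypes = {
            hdc_accuracy(apply_noise(fit, spec), data$test)
          },
          encoded_vector = {
            sseeds <- derive_seeds(spec$seed, ncol(enc_test))
            En <- enc_test
            for (j in seq_len(ncol(En))) {
              En[, j] <- apply_vector_noise(En[, j], spec, sseeds[j])
            }
            pred <- object_predict_encodings(fit, En)
            mean(pred == truth)
          })
        rows[[length(rows) + 1L]] <- data.frame(
          method = paste0(m, "_hdc"), kind = kind, target = target,
          intensity = grid[gi], seed = r, accuracy = acc,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(results = do.call(rbind, rows), kind = kind, target = target,
                 grid = grid, n_seeds = as.integer(n_seeds), methods = methods,
                 dims = dims, epochs = as.integer(epochs),
                 seed = as.integer(seed), config = cfg),
            class = "hdc_sweep")
}

# classify pre-encoded (possibly corrupted) queries against a model's clean
# prototypes.
object_predict_encodings <- function(object, E) {
  S <- proto_scores(object$prototypes, E)
  object$classes[score_argmax(S)]
}

#' @export
print.hdc_sweep <- function(x, ...) {
  cat(sprintf("<hdc_sweep> %s noise on %s, grid [%s], %d seed(s)\n",
              x$kind, x$target, paste(x$grid, collapse = ", "), x$n_seeds))
  print(summary(x))
  invisible(x)
}

#' Aggregate a noise sweep to per-condition means
#'
#' @param object An `"hdc_sweep"` result.
#' @param ... Unused.
#' @return data.frame with one row per (method, intensity): columns `method`,
#'   `intensity`, `mean`, `sd` (sd over replicate seeds; 0 when a single seed
#'   was run).
#' @export
summary.hdc_sweep <- function(object, ...) {
  res <- object$results
  agg <- stats::aggregate(accuracy ~ method + intensity, data = res,
                          FUN = function(a) c(mean = mean(a), sd = stats::sd(a)))
  out <- data.frame(method = agg$method, intensity = agg$intensity,
                    mean = agg$accuracy[, "mean"],
                    sd = ifelse(is.na(agg$accuracy[, "sd"]), 0,
                                agg$accuracy[, "sd"]),
                    stringsAsFactors = FALSE)
  out[order(out$method, out$intensity), , drop = FALSE]
}
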