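# Independent brute-force reference implementations used as oracles. These
# deliberately loop over windows, basis rows, and frames with scalar
# arithmetic, sharing no code path with the vectorized encoders.

# enumerate fully-contained window origins by direct looping
oracle_origins <- function(rows, cols, w, s) {
  out <- NULL
  r <- 0L
  while (r + w <= rows) {
    c <- 0L
    while (c + w <= cols) {
      out <- rbind(out, c(r, c))
      c <- c + s
    }
    r <- r + s
  }
  out
}

# naive window-based frame encoding: explicit loops, scalar dot products
oracle_encode_frame <- function(frame, enc) {
  org <- oracle_origins(nrow(frame), ncol(frame), enc$w, enc$s)
  acc <- numeric(enc$dim)
  for (i in seq_len(nrow(org))) {
    block <- frame[org[i, 1] + seq_len(enc$w), org[i, 2] + seq_len(enc$w)]
    f <- as.vector(t(block))  # row-major flattening
    for (k in seq_len(enc$dim)) {
      p <- sum(enc$basis[k, ] * f)
      sgn <- if (p >= 0) 1 else -1
      acc[k] <- acc[k] + sgn * enc$window_ids[k, i]
    }
  }
  acc
}

oracle_encode_sample <- function(sample, enc) {
  if (sample$is_static) {
    return(oracle_encode_frame(unclass(sample$frames[[1]]), enc))
  }
  acc <- numeric(enc$dim)
  for (i in seq_along(sample$frames)) {
    acc <- acc + oracle_encode_frame(unclass(sample$frames[[i]]), enc) *
      enc$frame_ids[, i]
  }
  acc
}

rand_frame <- function(seed, rows = 32, cols = 16) {
  set.seed(seed)
  matrix(runif(rows * cols), rows, cols)
}

static_sample_of <- function(frame, label = "a") {
  activity_sample(rep(list(pressure_frame(frame)), 7), label, TRUE)
}

dynamic_sample_of <- function(frames, label = "a") {
  activity_sample(lapply(frames, pressure_frame), label, FALSE)
}

rand_dynamic_sample <- function(seed, label = "a") {
  set.seed(seed)
  dynamic_sample_of(lapply(1:7, function(i) matrix(runif(32 * 16), 32, 16)),
                    label)
}
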