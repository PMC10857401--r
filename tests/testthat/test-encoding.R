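# Window extraction, per-window random projection, frame and sequence
# encoding, and the flat whole-sample baseline.

test_that("window enumeration matches direct origin enumeration and the 32x16 default gives 27", {
  f <- rand_frame(1)
  ws <- extract_windows(f, w = 8, s = 3)
  expect_equal(ncol(ws$windows), 27)
  expect_equal(nrow(ws$origins), 27)

  for (w in c(2, 4, 8, 16)) {
    for (s in 1:8) {
      org <- oracle_origins(32, 16, w, s)
      ws <- extract_windows(f, w = w, s = s)
      expect_equal(unname(ws$origins), unname(org),
                   info = sprintf("w=%d s=%d", w, s))
    }
  }

  ws <- extract_windows(f, w = 16, s = 16)
  expect_equal(unname(ws$origins), cbind(c(0L, 16L), c(0L, 0L)))

  sq <- matrix(runif(64), 8, 8)
  ws <- extract_windows(sq, w = 8, s = 1)
  expect_equal(nrow(ws$origins), 1)
  expect_equal(ws$windows[, 1], as.vector(t(sq)))

  expect_error(extract_windows(f, w = 20, s = 1), "exceeds")
})

test_that("per-window projection follows sign(B x F) with the +1 tie-break", {
  B <- rbind(c(1, 0, 0, 0), c(0, -1, 0, 0), c(0, 0, 2, 0))
  expect_identical(encode_window(c(5, 2, 1, 9), B), c(1, -1, 1))

  expect_identical(encode_window(matrix(0, 2, 2), matrix(rnorm(12), 3, 4)),
                   rep(1, 3))

  set.seed(9)
  Bp <- matrix(rnorm(5 * 16), 5, 16)
  f <- runif(16)
  expect_identical(encode_window(2 * f, Bp), encode_window(f, Bp))
  expect_error(encode_window(runif(9), Bp), "dimension mismatch")
})

test_that("vectorized frame encoding equals the naive double-loop reference", {
  enc <- hdc_encoder(dim = 40, seed = 7)
  for (sd in c(7, 8, 9)) {
    f <- rand_frame(sd)
    expect_identical(encode_frame(f, enc), oracle_encode_frame(f, enc))
  }
})

test_that("frame encodings are integer-valued superpositions bounded by the window count", {
  enc <- hdc_encoder(dim = 64, seed = 3)
  v <- encode_frame(rand_frame(4), enc)
  expect_true(all(v == round(v)))
  expect_true(all(abs(v) <= enc$n_windows))
})

test_that("a change confined to one window leaves untouched window encodings bit-identical", {
  enc <- hdc_encoder(dim = 80, seed = 11)
  f1 <- rand_frame(20)
  f2 <- f1
  f2[13:20, 5:12] <- runif(64)  # exactly the window at 0-based origin (12, 4)
  w1 <- extract_windows(f1, 8, 3)
  w2 <- extract_windows(f2, 8, 3)
  touched <- apply(w1$windows != w2$windows, 2, any)
  for (i in which(!touched)) {
    expect_identical(encode_window(w1$windows[, i], enc$basis),
                     encode_window(w2$windows[, i], enc$basis))
  }
  expect_gt(sum(!touched), 0)
})

test_that("sequence encoding binds frames to temporal IDs, with a single-frame static path", {
  enc <- hdc_encoder(dim = 60, seed = 5)
  f <- rand_frame(31)
  st <- static_sample_of(f)
  expect_identical(encode_sample(st, enc), encode_frame(f, enc))

  # identical frames with all-ones frame IDs: sequence = 7 x frame encoding
  enc1 <- enc
  enc1$frame_ids <- matrix(1, enc$dim, 7)
  dyn_same <- dynamic_sample_of(rep(list(f), 7))
  expect_equal(encode_sample(dyn_same, enc1), 7 * encode_frame(f, enc))

  dyn <- rand_dynamic_sample(77)
  expect_identical(encode_sample(dyn, enc), oracle_encode_sample(dyn, enc))
})

test_that("flat baseline flattens the whole sample through one projection", {
  zero_static <- static_sample_of(matrix(0, 32, 16))
  expect_identical(encode_flat_baseline(zero_static, dim = 30, seed = 1),
                   rep(1, 30))

  dyn <- rand_dynamic_sample(5)
  expect_identical(encode_flat_baseline(dyn, dim = 50, seed = 2),
                   encode_flat_baseline(dyn, dim = 50, seed = 2))

  # hand-checkable toy: 2x2 frame, static, basis picked so signs are known
  enc <- hdc_encoder(method = "flat", dim = 3, rows = 2, cols = 2,
                     n_frames = 7, seed = 1)
  enc$basis <- rbind(c(1, 0, 0, 0, rep(0, 24)),
                     c(0, -1, 0, 0, rep(0, 24)),
                     c(0, 0, 0, 3, rep(0, 24)))
  st <- static_sample_of(matrix(c(2, 5, 4, 1), 2, 2, byrow = TRUE))
  # row-major features: 2, 5, 4, 1 -> projections 2, -5, 3
  expect_identical(encode_sample(st, enc), c(1, -1, 1))
})

test_that("window encodings degrade more gracefully than flat under a 1-pixel shift", {
  # forefoot-contact footprints leave part of the mat untouched; the windows
  # covering untouched area encode identically before and after the shift,
  # which is the locality mechanism this property isolates (a full adult
  # stance covers nearly the whole 32x16 mat, leaving no untouched windows)
  hits <- 0L
  for (i in 1:50) {
    set.seed(1000 + i)
    ctr <- c(16 + rnorm(1), 8 + rnorm(1))
    f <- unclass(render_footprint(ctr, scale = 1, half = TRUE))
    f[f < 0.15] <- 0  # acquisition noise-floor suppression
    fs <- shift_frame(f, 1)
    enc <- hdc_encoder(dim = 200, seed = 2000 + i)
    cw <- hv_cosine(encode_frame(f, enc), encode_frame(fs, enc))
    encf <- hdc_encoder(method = "flat", dim = 200, seed = 3000 + i)
    cf <- hv_cosine(encode_sample(static_sample_of(f), encf),
                    encode_sample(static_sample_of(fs), encf))
    if (cw > cf) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.8)
})

test_that("encoder construction is seeded and validates its arguments", {
  e1 <- hdc_encoder(dim = 32, seed = 42)
  e2 <- hdc_encoder(dim = 32, seed = 42)
  expect_identical(e1$basis, e2$basis)
  expect_identical(e1$window_ids, e2$window_ids)
  expect_identical(e1$frame_ids, e2$frame_ids)
  expect_equal(e1$n_windows, 27)
  expect_error(hdc_encoder(dim = 0), "positive")
  expect_error(hdc_encoder(dim = 50, w = 40), "exceeds")
  expect_error(encode_frame(matrix(0, 8, 8), e1), "shape")
})
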