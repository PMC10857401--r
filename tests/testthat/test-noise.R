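# The three noise families: input noise on frames, sensor noise on values,
# memory/communication noise on hypervectors.

test_that("shift moves columns right with zero fill and edge loss", {
  f <- rand_frame(1)
  expect_identical(shift_frame(f, 0), f)
  expect_identical(shift_frame(f, 16), matrix(0, 32, 16))
  expect_identical(shift_frame(f, 20), matrix(0, 32, 16))

  g <- matrix(0, 4, 4); g[2, 1] <- 5
  s <- shift_frame(g, 1)
  expect_equal(s[2, 2], 5)
  expect_equal(sum(s), 5)
  expect_error(shift_frame(f, -1), "non-negative")
})

test_that("blur is a normalized Gaussian low-pass with mass conservation away from borders", {
  f <- rand_frame(2)
  expect_identical(blur_frame(f, 0), f)

  u <- matrix(0.7, 32, 16)
  b <- blur_frame(u, 1)
  expect_equal(b[10:22, 6:10], u[10:22, 6:10], tolerance = 1e-12)

  imp <- matrix(0, 32, 16); imp[16, 8] <- 1
  expect_equal(sum(blur_frame(imp, 1)), 1, tolerance = 0.01)
  expect_error(blur_frame(f, -0.1), "non-negative")
})

test_that("rotation is nearest-neighbour about the centre; 180 degrees twice is the identity", {
  f <- rand_frame(3)
  expect_identical(rotate_frame(f, 0), f)
  expect_identical(rotate_frame(f, 360), f)
  for (sd in 4:6) {
    g <- rand_frame(sd)
    expect_identical(rotate_frame(rotate_frame(g, 180), 180), g)
  }
  expect_true(all(rotate_frame(f, 37) >= 0))
})

test_that("Gaussian sensor noise has the requested moments and respects non-negativity", {
  f <- matrix(0.5, 32, 16)
  expect_identical(add_gaussian(f, 0), f)
  expect_identical(add_gaussian(f, 0.1, seed = 5), add_gaussian(f, 0.1, seed = 5))
  g <- add_gaussian(f, 0.1, seed = 6)
  expect_true(all(g >= 0))
  expect_gt(sd(g - f), 0.08)
  expect_lt(sd(g - f), 0.12)
  expect_error(add_gaussian(f, -1), "non-negative")
})

test_that("white sensor noise is bounded uniform and passes a KS check", {
  f <- matrix(1, 64, 32)
  expect_identical(add_white(f, 0), f)
  a <- 0.2
  g <- add_white(f, a, seed = 7)
  expect_true(all(abs(g - f) <= a + 1e-12))
  ks <- suppressWarnings(ks.test((g - f), "punif", -a, a))
  expect_gt(ks$p.value, 0.01)
  expect_error(add_white(f, -0.1), "non-negative")
})

test_that("packet loss zeroes exactly floor(ratio*D) seeded positions", {
  v <- hv_random_bipolar(200, seed = 8)
  expect_identical(packet_loss(v, 0, seed = 1), v)
  expect_identical(packet_loss(v, 1, seed = 1), rep(0, 200))
  z <- packet_loss(v, 0.5, seed = 2)
  expect_equal(sum(z == 0), 100)
  expect_identical(packet_loss(v, 0.5, seed = 2), z)
  expect_error(packet_loss(v, 1.2, seed = 1), "\\[0, 1\\]")
})

test_that("bitflip negates exactly floor(ratio*D) positions of a bipolar vector and is an involution", {
  v <- hv_random_bipolar(200, seed = 9)
  expect_identical(bitflip(v, 0, seed = 1), v)
  expect_identical(bitflip(v, 1, seed = 1), -v)
  b <- bitflip(v, 0.3, seed = 3)
  expect_equal(sum(b != v), 60)
  expect_identical(bitflip(b, 0.3, seed = 3), v)
  expect_error(bitflip(c(0.5, 1, -1), 0.1), "bipolar")
})

test_that("Gaussian vector noise scales with the target's element spread", {
  v <- rnorm(20000, sd = 3)
  expect_identical(gaussian_on_vector(v, 0, seed = 1), v)
  g <- gaussian_on_vector(v, 1, seed = 4)
  expect_identical(gaussian_on_vector(v, 1, seed = 4), g)
  expect_lt(abs(sd(g - v) / sd(v) - 1), 0.05)
  expect_error(gaussian_on_vector(v, -1), "non-negative")
})

test_that("noise specs validate the physically meaningful kind/target combinations", {
  expect_s3_class(noise_spec("shift", 2), "noise_spec")
  expect_equal(noise_spec("gaussian", 0.1)$family, "sensor")
  expect_equal(noise_spec("gaussian", 0.1, target = "prototypes")$family, "memory")
  expect_equal(noise_spec("packet_loss", 0.2)$target, "prototypes")
  expect_error(noise_spec("bitflip", 0.1, target = "prototypes"),
               "invalid combination")
  expect_error(noise_spec("shift", 1, target = "encoded_vector"),
               "invalid combination")
  expect_error(noise_spec("packet_loss", 2), "\\[0, 1\\]")
  expect_error(noise_spec("made_up", 1), "kind")
})

test_that("every noise kind at intensity zero is the exact identity through apply_noise", {
  f <- rand_frame(10)
  for (kind in c("shift", "blur", "rotation", "gaussian", "white")) {
    expect_identical(apply_noise(f, noise_spec(kind, 0, seed = 3)), f,
                     info = kind)
  }
  v <- hv_random_bipolar(100, seed = 11)
  expect_identical(apply_noise(v, noise_spec("packet_loss", 0,
                                             target = "encoded_vector")), v)
  expect_identical(apply_noise(v, noise_spec("bitflip", 0)), v)
  expect_identical(apply_noise(v, noise_spec("gaussian", 0,
                                             target = "encoded_vector")), v)
})

test_that("sample-level noise keeps static samples static and uses per-frame sub-seeds for dynamic", {
  st <- generate_sample("stand", synth_config(seed = 1), seed = 5)
  noisy <- apply_noise(st, noise_spec("gaussian", 0.05, seed = 9))
  expect_true(noisy$is_static)
  expect_identical(unclass(noisy$frames[[1]]), unclass(noisy$frames[[7]]))

  dyn <- generate_sample("walk", synth_config(seed = 1), seed = 6)
  noisy <- apply_noise(dyn, noise_spec("gaussian", 0.05, seed = 9))
  diff1 <- unclass(noisy$frames[[1]]) - unclass(dyn$frames[[1]])
  diff2 <- unclass(noisy$frames[[2]]) - unclass(dyn$frames[[2]])
  expect_false(identical(diff1, diff2))
})

test_that("full prototype packet loss degrades to class-order predictions with a warning", {
  d <- generate_dataset(synth_config(classes = c("no_press", "stand"),
                                     n_per_class = 10, seed = 2))
  fit <- hdc(d$train, dim = 50, epochs = 0, seed = 1)
  dead <- apply_noise(fit, noise_spec("packet_loss", 1, target = "prototypes"))
  expect_true(all(dead$prototypes == 0))
  expect_warning(p <- predict(dead, d$test), "class order")
  expect_true(all(p == sort(fit$classes)[1]))
})
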