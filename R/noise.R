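# Noise injection at the three points of the sensing pipeline where
# corruption arises: input noise on the acquired frames (shift, blur,
# rotation), sensor noise on the frame values (Gaussian, white), and
# memory/communication noise on stored hypervectors (packet loss / set-to-
# zero, bitflip, Gaussian). Frame-level intensities are understood on the
# normalized [0, 1] value scale. Every operation at intensity 0 is the exact
# identity, and all stochastic noise is seeded.

#' Shift a frame to the right
#'
#' Moves columns right by `k` pixels; vacated columns are zero-filled and
#' columns shifted past the edge are discarded (genuine information loss, as
#' when a subject stands off-centre on the mat).
#'
#' @param frame Numeric matrix.
#' @param k Non-negative integer number of pixels.
#' @return Matrix of the same shape.
#' @export
shift_frame <- function(frame, k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0) {
    stop("invalid argument: 'k' must be a non-negative integer")
  }
  k <- as.integer(k)
  if (k == 0L) return(frame)
  out <- matrix(0, nrow(frame), ncol(frame))
  if (k < ncol(frame)) {
    out[, (k + 1L):ncol(frame)] <- frame[, 1L:(ncol(frame) - k)]
  }
  out
}

# 1-D Gaussian kernel truncated at 3 sigma, normalized to sum 1.
gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# shift a matrix by (dr, dc) with zero fill.
shift2 <- function(m, dr, dc) {
  out <- matrix(0, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)); cs <- seq_len(ncol(m))
  rsrc <- rs - dr; csrc <- cs - dc
  rok <- rsrc >= 1 & rsrc <= nrow(m); cok <- csrc >= 1 & csrc <= ncol(m)
  out[rs[rok], cs[cok]] <- m[rsrc[rok], csrc[cok]]
  out
}

#' Gaussian-blur a frame
#'
#' Separable Gaussian low-pass filter with standard deviation `sigma`
#' (pixels), kernel truncated at 3 sigma, zero padding at the borders. Total
#' pressure mass is conserved up to border leakage; `sigma = 0` is the
#' identity.
#'
#' @param frame Numeric matrix.
#' @param sigma Kernel standard deviation in pixels, `>= 0`.
#' @return Matrix of the same shape.
#' @export
blur_frame <- function(frame, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    stop("invalid argument: 'sigma' must be non-negative")
  }
  if (sigma == 0) return(frame)
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  tmp <- matrix(0, nrow(frame), ncol(frame))
  for (o in -r:r) tmp <- tmp + k[o + r + 1L] * shift2(frame, o, 0L)
  out <- matrix(0, nrow(frame), ncol(frame))
  for (o in -r:r) out <- out + k[o + r + 1L] * shift2(tmp, 0L, o)
  out
}

#' Rotate a frame about its centre
#'
#' Nearest-neighbour resampling, zero fill outside the source grid; 0 degrees
#' is the identity. On the symmetric pixel grid a 180-degree rotation is an
#' exact involution.
#'
#' @param frame Numeric matrix.
#' @param degrees Rotation angle (counter-clockwise, any real).
#' @return Matrix of the same shape with non-negative entries preserved.
#' @export
rotate_frame <- function(frame, degrees) {
  if (degrees %% 360 == 0) return(frame)
  nr <- nrow(frame); nc <- ncol(frame)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  th <- degrees * pi / 180
  # inverse map each output cell to its source location
  rr <- matrix(seq_len(nr) - cr, nr, nc)
  cj <- matrix(rep(seq_len(nc) - cc, each = nr), nr, nc)
  src_r <- round(cos(th) * rr + sin(th) * cj + cr)
  src_c <- round(-sin(th) * rr + cos(th) * cj + cc)
  ok <- src_r >= 1 & src_r <= nr & src_c >= 1 & src_c <= nc
  out <- matrix(0, nr, nc)
  out[ok] <- frame[cbind(src_r[ok], src_c[ok])]
  out
}

#' Add Gaussian sensor noise to a frame
#'
#' I.i.d. zero-mean Gaussian noise per cell (standard deviation `sd` on the
#' normalized value scale), clipped to non-negative readings.
#'
#' @param frame Numeric matrix.
#' @param sd Noise standard deviation, `>= 0`.
#' @param seed RNG seed.
#' @return Matrix of the same shape.
#' @export
add_gaussian <- function(frame, sd, seed = 1L) {
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0) {
    stop("invalid argument: 'sd' must be non-negative")
  }
  if (sd == 0) return(frame)
  noise <- with_seed(seed, stats::rnorm(length(frame), 0, sd))
  pmax(frame + matrix(noise, nrow(frame), ncol(frame)), 0)
}

#' Add uniform white sensor noise to a frame
#'
#' I.i.d. uniform noise on `[-amplitude, +amplitude]` per cell, clipped to
#' non-negative readings.
#'
#' @param frame Numeric matrix.
#' @param amplitude Noise amplitude, `>= 0`.
#' @param seed RNG seed.
#' @return Matrix of the same shape.
#' @export
add_white <- function(frame, amplitude, seed = 1L) {
  if (!is.numeric(amplitude) || length(amplitude) != 1L || is.na(amplitude) ||
      amplitude < 0) {
    stop("invalid argument: 'amplitude' must be non-negative")
  }
  if (amplitude == 0) return(frame)
  noise <- with_seed(seed, stats::runif(length(frame), -amplitude, amplitude))
  pmax(frame + matrix(noise, nrow(frame), ncol(frame)), 0)
}

#' Packet-loss (set-to-zero) corruption of a hypervector
#'
#' Sets a seeded uniform sample of `floor(ratio * D)` distinct positions to
#' zero, modelling dropped transmissions or memory loss.
#'
#' @param v Numeric hypervector.
#' @param ratio Fraction of positions to zero, in `[0, 1]`.
#' @param seed RNG seed.
#' @return Corrupted hypervector.
#' @export
packet_loss <- function(v, ratio, seed = 1L) {
  check_hv(v)
  if (!is.numeric(ratio) || length(ratio) != 1L || is.na(ratio) ||
      ratio < 0 || ratio > 1) {
    stop("invalid argument: 'ratio' must be in [0, 1]")
  }
  m <- floor(ratio * length(v))
  if (m == 0) return(v)
  pos <- with_seed(seed, sample.int(length(v), m))
  v[pos] <- 0
  v
}

#' Bitflip corruption of a bipolar hypervector
#'
#' Negates a seeded uniform sample of `floor(ratio * D)` distinct positions:
#' the sign flip is the bipolar analogue of a memory/communication bit error.
#' Only quantized (bipolar) hypervectors can be bit-flipped; real-valued
#' vectors (e.g. class prototypes) are rejected.
#'
#' @param v Bipolar hypervector (all elements in \{-1, +1\}).
#' @param ratio Fraction of positions to flip, in `[0, 1]`.
#' @param seed RNG seed.
#' @return Corrupted bipolar hypervector.
#' @export
bitflip <- function(v, ratio, seed = 1L) {
  if (!is_bipolar(v)) {
    stop("invalid argument: bitflip requires a bipolar hypervector")
  }
  if (!is.numeric(ratio) || length(ratio) != 1L || is.na(ratio) ||
      ratio < 0 || ratio > 1) {
    stop("invalid argument: 'ratio' must be in [0, 1]")
  }
  m <- floor(ratio * length(v))
  if (m == 0) return(v)
  pos <- with_seed(seed, sample.int(length(v), m))
  v[pos] <- -v[pos]
  v
}

#' Additive Gaussian corruption of a stored hypervector
#'
#' Adds i.i.d. zero-mean Gaussian noise with standard deviation
#' `sd_rel * sd(v)`. The relative scaling makes one intensity axis comparable
#' across integer-valued prototypes and bipolar encodings of different
#' dimensionalities.
#'
#' @param v Numeric hypervector.
#' @param sd_rel Relative noise standard deviation, `>= 0`.
#' @param seed RNG seed.
#' @return Corrupted hypervector.
#' @export
gaussian_on_vector <- function(v, sd_rel, seed = 1L) {
  check_hv(v)
  if (!is.numeric(sd_rel) || length(sd_rel) != 1L || is.na(sd_rel) || sd_rel < 0) {
    stop("invalid argument: 'sd_rel' must be non-negative")
  }
  if (sd_rel == 0) return(v)
  sdv <- stats::sd(v)
  if (sdv == 0) return(v)
  v + with_seed(seed, stats::rnorm(length(v), 0, sd_rel * sdv))
}

NOISE_FAMILY <- c(shift = "input", blur = "input", rotation = "input",
                  white = "sensor", gaussian = "sensor",
                  packet_loss = "memory", bitflip = "memory")

#' Describe a noise condition
#'
#' Bundles the noise kind, intensity, target, and seed, and validates the
#' (family, kind, target) combination against where each noise physically
#' occurs: input noise (shift/blur/rotation) and sensor noise
#' (gaussian/white) act on frames; memory/communication noise acts on stored
#' hypervectors — packet loss and Gaussian on encoded vectors or class
#' prototypes, bitflips on (quantized) encoded vectors only, since prototype
#' values are floats.
#'
#' @param kind One of `"shift"`, `"blur"`, `"rotation"`, `"gaussian"`,
#'   `"white"`, `"packet_loss"`, `"bitflip"`.
#' @param intensity Real noise parameter: pixels for shift, kernel sd for
#'   blur, degrees for rotation, standard deviation for gaussian/white,
#'   fraction in `[0, 1]` for packet_loss/bitflip.
#' @param target `"frame"`, `"encoded_vector"`, or `"prototypes"`. Defaults
#'   to the kind's natural target (`"frame"` for input/sensor kinds,
#'   `"prototypes"` for packet loss, `"encoded_vector"` for bitflip and
#'   memory-Gaussian when given explicitly).
#' @param seed RNG seed for stochastic kinds.
#' @return Object of class `"noise_spec"`.
#' @export
#' @examples
#' noise_spec("shift", 2)
#' noise_spec("packet_loss", 0.25, target = "prototypes")
noise_spec <- function(kind, intensity, target = NULL, seed = 1L) {
  kinds <- names(NOISE_FAMILY)
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% kinds)) {
    stop(sprintf("invalid argument: 'kind' must be one of %s",
                 paste(kinds, collapse = ", ")))
  }
  if (!is.numeric(intensity) || length(intensity) != 1L || is.na(intensity)) {
    stop("invalid argument: 'intensity' must be a single number")
  }
  if (is.null(target)) {
    target <- switch(kind, packet_loss = "prototypes", bitflip = "encoded_vector",
                     "frame")
  }
  allowed <- switch(kind,
    shift = "frame", blur = "frame", rotation = "frame", white = "frame",
    gaussian = c("frame", "encoded_vector", "prototypes"),
    packet_loss = c("encoded_vector", "prototypes"),
    bitflip = "encoded_vector")
  if (!(target %in% allowed)) {
    stop(sprintf("invalid combination: noise kind '%s' cannot target '%s'",
                 kind, target))
  }
  family <- if (kind == "gaussian" && target != "frame") "memory" else
    unname(NOISE_FAMILY[kind])
  if (kind %in% c("packet_loss", "bitflip") && (intensity < 0 || intensity > 1)) {
    stop("invalid argument: 'intensity' must be a fraction in [0, 1]")
  }
  if (kind %in% c("shift", "blur", "gaussian", "white") && intensity < 0) {
    stop("invalid argument: 'intensity' must be non-negative")
  }
  structure(list(family = family, kind = kind, intensity = intensity,
                 target = target, seed = as.integer(seed)),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("<noise_spec> %s noise: kind=%s, intensity=%g, target=%s, seed=%d\n",
              x$family, x$kind, x$intensity, x$target, x$seed))
  invisible(x)
}

apply_frame_noise <- function(frame, spec, seed) {
  switch(spec$kind,
    shift = shift_frame(frame, spec$intensity),
    blur = blur_frame(frame, spec$intensity),
    rotation = rotate_frame(frame, spec$intensity),
    gaussian = add_gaussian(frame, spec$intensity, seed),
    white = add_white(frame, spec$intensity, seed))
}

apply_vector_noise <- function(v, spec, seed) {
  switch(spec$kind,
    packet_loss = packet_loss(v, spec$intensity, seed),
    bitflip = bitflip(v, spec$intensity, seed),
    gaussian = gaussian_on_vector(v, spec$intensity, seed))
}

#' Apply a noise condition to a frame, sample, hypervector, or model
#'
#' Dispatches on the target of `spec`. Frame-targeted noise accepts a matrix, an
#' `activity_sample`, or a whole dataset: dynamic samples get independent
#' sub-seeded noise per frame, while static samples are perturbed once and
#' replicated (the posture is a single image, and the static invariant is
#' preserved). Vector-targeted noise accepts a numeric hypervector.
#' Prototype-targeted noise accepts a fitted `"hdc"` model and perturbs every
#' class prototype with an independent sub-seed.
#'
#' @param x Object matching `spec$target`.
#' @param spec A [noise_spec()].
#' @return The perturbed object, same type as `x`.
#' @export
apply_noise <- function(x, spec) {
  if (!inherits(spec, "noise_spec")) {
    stop("invalid argument: 'spec' must be a noise_spec")
  }
  if (spec$target == "frame") {
    if (is.matrix(x)) {
      return(apply_frame_noise(x, spec, spec$seed))
    }
    if (inherits(x, "activity_sample")) {
      if (x$is_static) {
        g <- apply_frame_noise(frame_values(x$frames[[1L]]), spec, spec$seed)
        return(activity_sample(rep(list(pressure_frame(g)), length(x$frames)),
                               x$label, TRUE))
      }
      sub <- derive_seeds(spec$seed, length(x$frames))
      frames <- lapply(seq_along(x$frames), function(i) {
        pressure_frame(apply_frame_noise(frame_values(x$frames[[i]]), spec, sub[i]))
      })
      return(activity_sample(frames, x$label, FALSE))
    }
    if (is.list(x)) {
      sub <- derive_seeds(spec$seed, length(x))
      out <- lapply(seq_along(x), function(i) {
        si <- spec; si$seed <- sub[i]
        apply_noise(x[[i]], si)
      })
      if (inherits(x, "pressure_dataset")) out <- pressure_dataset(out, attr(x, "meta"))
      return(out)
    }
    stop("invalid argument: frame-targeted noise needs a frame, sample, or dataset")
  }
  if (spec$target == "encoded_vector") {
    if (!is.numeric(x)) {
      stop("invalid argument: encoded_vector-targeted noise needs a numeric hypervector")
    }
    return(apply_vector_noise(x, spec, spec$seed))
  }
  # prototypes
  if (!inherits(x, "hdc")) {
    stop("invalid argument: prototype-targeted noise needs a fitted 'hdc' model")
  }
  sub <- derive_seeds(spec$seed, ncol(x$prototypes))
  for (k in seq_len(ncol(x$prototypes))) {
    x$prototypes[, k] <- apply_vector_noise(x$prototypes[, k], spec, sub[k])
  }
  x
}
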