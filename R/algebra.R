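# Hypervector algebra: creation, bundling, binding, similarity, quantization.
# Hypervectors are plain numeric vectors; bipolarity ({-1,+1} elements) is a
# checked property, not a separate type, so superposed integer-valued vectors
# and quantized vectors live in one algebra.

check_hv <- function(v, arg = "hypervector") {
  if (!is.numeric(v) || length(v) < 1L || anyNA(v)) {
    stop(sprintf("invalid argument: '%s' must be a non-empty numeric vector", arg))
  }
  invisible(v)
}

#' Test whether a vector is bipolar
#'
#' A bipolar hypervector has every element in \{-1, +1\}.
#'
#' @param v Numeric vector.
#' @return `TRUE` if all elements are -1 or +1.
#' @export
#' @examples
#' is_bipolar(c(-1, 1, 1))   # TRUE
#' is_bipolar(c(0, 1))       # FALSE
is_bipolar <- function(v) {
  is.numeric(v) && length(v) >= 1L && !anyNA(v) && all(v == 1 | v == -1)
}

#' Generate a seeded random bipolar hypervector
#'
#' Elements are i.i.d. uniform on \{-1, +1\}. The same seed always yields the
#' same vector, which is what makes encoders and experiments replayable.
#'
#' @param dim Positive integer dimensionality D.
#' @param seed Non-negative integer seed.
#' @return Numeric vector of length `dim` with elements in \{-1, +1\}.
#' @export
#' @examples
#' hv_random_bipolar(8, seed = 1)
hv_random_bipolar <- function(dim, seed) {
  if (!is.numeric(dim) || length(dim) != 1L || is.na(dim) || dim < 1) {
    stop("invalid argument: 'dim' must be a positive integer")
  }
  with_seed(seed, sample(c(-1, 1), as.integer(dim), replace = TRUE))
}

#' Bundle (superpose) hypervectors
#'
#' Element-wise sum of a list of equal-dimension hypervectors. Bundling is the
#' aggregation used to build class prototypes: the sum stays closer (in cosine)
#' to each addend than to an unrelated random vector.
#'
#' @param vs Non-empty list of numeric vectors sharing one dimension.
#' @return Numeric vector: the element-wise sum.
#' @export
#' @examples
#' hv_bundle(list(c(1, -1), c(1, 1)))  # c(2, 0)
hv_bundle <- function(vs) {
  if (!is.list(vs) || length(vs) == 0L) {
    stop("invalid argument: 'vs' must be a non-empty list of hypervectors")
  }
  for (v in vs) check_hv(v)
  d <- length(vs[[1L]])
  for (v in vs) {
    if (length(v) != d) {
      stop("dimension mismatch: all bundled hypervectors must share one dimension")
    }
  }
  Reduce(`+`, vs)
}

#' Bind two hypervectors
#'
#' Element-wise multiplication. Binding with a bipolar ID vector tags a
#' hypervector (e.g. with a window position or frame index) and yields a
#' vector pseudo-orthogonal to its inputs; for a bipolar `b` it is exactly
#' self-inverse: `hv_bind(hv_bind(a, b), b) == a`.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Numeric vector: the element-wise product.
#' @export
#' @examples
#' hv_bind(c(1, 2, 3), c(-1, 1, -1))
hv_bind <- function(a, b) {
  check_hv(a, "a")
  check_hv(b, "b")
  if (length(a) != length(b)) {
    stop("dimension mismatch: 'a' and 'b' must have equal dimension")
  }
  a * b
}

#' Cosine similarity between hypervectors
#'
#' `dot(a, b) / (||a|| * ||b||)`, the inference metric of the classifier.
#'
#' @param a,b Numeric vectors of equal length, neither all-zero.
#' @return Scalar in `[-1, 1]`.
#' @export
#' @examples
#' hv_cosine(c(1, 0), c(1, 1))
hv_cosine <- function(a, b) {
  check_hv(a, "a")
  check_hv(b, "b")
  if (length(a) != length(b)) {
    stop("dimension mismatch: 'a' and 'b' must have equal dimension")
  }
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) {
    stop("degenerate similarity: cosine undefined for a zero-norm hypervector")
  }
  sum(a * b) / (na * nb)
}

#' Sign-quantize a hypervector to bipolar form
#'
#' Maps every positive element to +1 and every negative element to -1. Zero
#' maps to +1: the fixed tie-break keeps encoding deterministic, which matters
#' for all-zero (no-press) frames.
#'
#' @param v Numeric vector.
#' @return Bipolar vector of the same length.
#' @export
#' @examples
#' hv_sign(c(2.5, -0.1, 0))  # c(1, -1, 1)
hv_sign <- function(v) {
  check_hv(v)
  (v >= 0) * 2 - 1
}
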