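# Seeded generator of synthetic pressure-mat datasets with the structure of
# mat-collected activity data: 32x16 non-negative grids, 7-frame temporal
# trajectories, three static posture classes (no_press, stand, object) and
# four dynamic activity classes (jump, walk, lr_shift, tiptoe). Footprints
# are parametric ellipse pairs — enough spatial structure for window-local
# patterns to matter, with no biomechanical claims. Class identity is carried
# by coarse spatiotemporal signatures (mass trajectories, contact
# alternation), so the classifier must succeed from raw spatiotemporal
# pattern alone.

#' Configuration for the synthetic pressure-mat generator
#'
#' @param classes Character vector drawn from `no_press`, `stand`, `object`
#'   (static) and `jump`, `walk`, `lr_shift`, `tiptoe` (dynamic). Default:
#'   all seven.
#' @param n_per_class Samples generated per class (default 100).
#' @param jitter_sd Gaussian sensor jitter standard deviation on the `[0, 1]`
#'   value scale (default 0.05).
#' @param placement_sd Standard deviation (pixels) of the random translation
#'   of footprint centres between samples (default 1).
#' @param balance_sd Standard deviation of the random balance-tilt gradients:
#'   each sample's pressure image is modulated by a smooth multiplicative
#'   field `exp(b1*y + b2*x)` (centred coordinates, `b ~ N(0, balance_sd^2)`,
#'   field normalized to peak 1), emulating centre-of-pressure shifts between
#'   repetitions (default 1).
#' @param gain_range Per-frame contact-force gain for dynamic activities:
#'   every frame of a dynamic sample is scaled by an independent uniform draw
#'   from this range, emulating force variation over the movement
#'   (default `c(0.5, 1)`).
#' @param foot_sd Standard deviation (pixels) of the per-foot placement
#'   scatter: each rendered foot gets its own random offset (per sample for
#'   static postures, per frame for movements), emulating stance and step
#'   variation (default 1.2).
#' @param seed Master seed.
#' @return Object of class `"synth_config"`.
#' @export
synth_config <- function(classes = ALL_CLASSES, n_per_class = 100L,
                         jitter_sd = 0.05, placement_sd = 1,
                         balance_sd = 1, gain_range = c(0.5, 1),
                         foot_sd = 1.2, seed = 1L) {
  if (!is.character(classes) || length(classes) == 0L ||
      !all(classes %in% ALL_CLASSES)) {
    stop(sprintf("invalid argument: 'classes' must be a subset of {%s}",
                 paste(ALL_CLASSES, collapse = ", ")))
  }
  if (!is.numeric(n_per_class) || n_per_class < 1) {
    stop("invalid argument: 'n_per_class' must be >= 1")
  }
  if (jitter_sd < 0 || placement_sd < 0 || balance_sd < 0 || foot_sd < 0) {
    stop("invalid argument: standard deviations must be non-negative")
  }
  if (length(gain_range) != 2L || any(gain_range <= 0) ||
      gain_range[1L] > gain_range[2L]) {
    stop("invalid argument: 'gain_range' must be an increasing positive pair")
  }
  structure(list(classes = unique(classes), n_per_class = as.integer(n_per_class),
                 jitter_sd = jitter_sd, placement_sd = placement_sd,
                 balance_sd = balance_sd, gain_range = gain_range,
                 foot_sd = foot_sd, seed = as.integer(seed)),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "<synth_config> classes={%s}, n_per_class=%d, jitter_sd=%g, placement_sd=%g, balance_sd=%g, gain=[%g,%g], foot_sd=%g, seed=%d\n",
    paste(x$classes, collapse = ", "), x$n_per_class, x$jitter_sd,
    x$placement_sd, x$balance_sd, x$gain_range[1L], x$gain_range[2L],
    x$foot_sd, x$seed))
  invisible(x)
}

# One elliptical pressure blob with smooth exponential falloff; values <= 1.
ellipse_blob <- function(rows, cols, cr, cc, a, b, power = 1) {
  rr <- matrix(seq_len(rows), rows, cols)
  cj <- matrix(rep(seq_len(cols), each = rows), rows, cols)
  q <- ((rr - cr) / a)^2 + ((cj - cc) / b)^2
  v <- exp(-q^power)
  v[v < 0.02] <- 0
  v
}

#' Render a bipedal footprint frame
#'
#' Two elliptical high-pressure blobs (left and right foot) with smooth
#' intensity falloff, centred on `center`. With `half = TRUE` only forefoot
#' ellipses are rendered (tiptoe contact), which carries strictly less total
#' pressure mass. The renderer is deterministic; all values lie in `[0, 1]`.
#'
#' @param center Numeric `(row, col)` centre of the stance, inside the grid.
#' @param scale Positive size multiplier (default 1).
#' @param half If `TRUE`, render forefoot-only contact.
#' @param rows,cols Grid shape (default 32 x 16).
#' @param feet `"both"` (default), `"left"`, or `"right"`: which foot is in
#'   contact (single-foot frames are used by the walk and lr_shift classes).
#' @param foot_offsets Optional list with `left` and/or `right` numeric
#'   `(row, col)` offsets applied to the individual foot centres, modelling
#'   per-step/per-stance foot placement scatter.
#' @return A `pressure_frame`.
#' @export
render_footprint <- function(center, scale = 1, half = FALSE,
                             rows = 32L, cols = 16L, feet = "both",
                             foot_offsets = NULL) {
  if (length(center) != 2L || center[1L] < 1 || center[1L] > rows ||
      center[2L] < 1 || center[2L] > cols) {
    stop("invalid argument: 'center' must be a (row, col) location inside the grid")
  }
  if (!is.numeric(scale) || scale <= 0) {
    stop("invalid argument: 'scale' must be positive")
  }
  sep <- 4.2 * scale
  off <- list(left = c(0, 0), right = c(0, 0))
  if (!is.null(foot_offsets)) off[names(foot_offsets)] <- foot_offsets
  centres <- switch(feet,
    both = list(c(center[1L], center[2L] - sep / 2) + off$left,
                c(center[1L], center[2L] + sep / 2) + off$right),
    left = list(c(center[1L], center[2L] - sep / 2) + off$left),
    right = list(c(center[1L], center[2L] + sep / 2) + off$right),
    stop("invalid argument: 'feet' must be both, left, or right"))
  out <- matrix(0, rows, cols)
  for (ct in centres) {
    if (half) {
      # forefoot only: smaller ellipse shifted toward the toes (lower row idx)
      blob <- ellipse_blob(rows, cols, ct[1L] - 4.0 * scale, ct[2L],
                           a = 3.5 * scale, b = 2.2 * scale, power = 2)
    } else {
      blob <- ellipse_blob(rows, cols, ct[1L], ct[2L],
                           a = 7.0 * scale, b = 1.8 * scale, power = 2)
    }
    out <- pmax(out, blob)
  }
  pressure_frame(pmin(out, 1))
}

# Compact boxy single-blob signature of a resting object, distinct from the
# bipedal two-ellipse stance.
render_object <- function(center, scale, rows = 32L, cols = 16L) {
  # sharp-edged near-uniform plateau (power-4 superellipse at reduced
  # intensity): a rigid box loads its contact area evenly, unlike the peaked
  # pressure under a foot
  v <- 0.65 * ellipse_blob(rows, cols, center[1L], center[2L],
                           a = 4.5 * scale, b = 4.5 * scale, power = 4)
  pressure_frame(pmin(v, 1))
}

# Additive Gaussian sensor jitter followed by the acquisition firmware's
# noise-floor suppression: readings below 3 sigma are registered as exactly
# zero, as a thresholding ADC pipeline does for unloaded force-sensitive
# cells. Untouched sensels therefore read 0 almost always, with occasional
# above-threshold flickers.
add_jitter <- function(grid, jitter_sd) {
  if (jitter_sd == 0) return(grid)
  g <- grid + matrix(stats::rnorm(length(grid), 0, jitter_sd),
                     nrow(grid), ncol(grid))
  g <- pmin(pmax(g, 0), 1)
  g[g < 3 * jitter_sd] <- 0
  g
}

# Smooth multiplicative balance-tilt field, peak-normalized to 1: models the
# centre-of-pressure shifting between repetitions. Locally near-constant at
# window scale, so per-window sign quantization is almost invariant to it,
# while a holistic projection is not.
balance_field <- function(rows, cols, b1, b2) {
  y <- (seq_len(rows) - (rows + 1) / 2) / rows
  x <- (seq_len(cols) - (cols + 1) / 2) / cols
  m <- exp(outer(b1 * y, b2 * x, `+`))
  m / max(m)
}

#' Generate one synthetic activity sample
#'
#' Class signatures: `no_press` — 7 near-zero frames (jitter only); `stand` —
#' 7 identical full-footprint frames; `object` — 7 identical compact
#' single-blob frames; `jump` — footprint, then 3 airborne near-zero frames,
#' then landing footprint; `walk` — stance centre translating monotonically
#' along the mat with alternating single-foot contact; `lr_shift` — pressure
#' mass alternating between left-only and right-only foot frames; `tiptoe` —
#' full -> half -> full footprint progression across the 7 frames. Static
#' classes carry identical frames and `is_static = TRUE`.
#'
#' @param cls Class label, one of the config's classes.
#' @param cfg A [synth_config()].
#' @param seed Seed for this sample's randomness (placement, scale, jitter).
#' @return An `activity_sample`.
#' @export
generate_sample <- function(cls, cfg, seed = 1L) {
  if (!(cls %in% cfg$classes)) {
    stop(sprintf("unknown class: '%s' is not in the configured class set", cls))
  }
  rows <- MAT_ROWS; cols <- MAT_COLS
  with_seed(seed, {
    center <- c(rows / 2 + 0.5, cols / 2 + 0.5) +
      stats::rnorm(2, 0, cfg$placement_sd)
    center[1L] <- min(max(center[1L], 10), rows - 9)
    center[2L] <- min(max(center[2L], 6), cols - 5)
    scale <- stats::runif(1, 0.9, 1.1)
    js <- cfg$jitter_sd
    tilt <- stats::rnorm(2, 0, cfg$balance_sd)
    field <- balance_field(rows, cols, tilt[1L], tilt[2L])
    foot_off <- function() list(left = stats::rnorm(2, 0, cfg$foot_sd),
                                right = stats::rnorm(2, 0, cfg$foot_sd))

    make_static <- function(grid) {
      g <- add_jitter(frame_values(grid) * field, js)
      activity_sample(rep(list(pressure_frame(g)), N_FRAMES), cls, TRUE)
    }
    make_dynamic <- function(grids) {
      gains <- stats::runif(N_FRAMES, cfg$gain_range[1L], cfg$gain_range[2L])
      frames <- lapply(seq_len(N_FRAMES), function(i) {
        pressure_frame(add_jitter(frame_values(grids[[i]]) * field * gains[i], js))
      })
      activity_sample(frames, cls, FALSE)
    }
    zero <- pressure_frame(matrix(0, rows, cols))

    switch(cls,
      no_press = make_static(zero),
      stand = make_static(render_footprint(center, scale,
                                            foot_offsets = foot_off())),
      # a resting container sits near the mat's top edge, not where a person
      # stands
      object = make_static(render_object(c(center[1L] - 9, center[2L]), scale)),
      jump = {
        up <- render_footprint(center, scale, foot_offsets = foot_off())
        land <- render_footprint(center + stats::rnorm(2, 0, 0.5), scale,
                                 foot_offsets = foot_off())
        make_dynamic(list(up, zero, zero, zero, zero, zero, land))
      },
      walk = {
        path <- seq(center[1L] - 10, center[1L] + 10, length.out = N_FRAMES)
        path <- pmin(pmax(path, 6), rows - 5)
        # leading foot opposite to lr_shift's, so no frame index shares both
        # foot side and stance position with the in-place weight shift
        grids <- lapply(seq_len(N_FRAMES), function(i) {
          render_footprint(c(path[i], center[2L]), scale,
                           feet = if (i %% 2 == 1) "right" else "left",
                           foot_offsets = foot_off())
        })
        make_dynamic(grids)
      },
      lr_shift = {
        grids <- lapply(seq_len(N_FRAMES), function(i) {
          render_footprint(center, scale,
                           feet = if (i %% 2 == 1) "left" else "right",
                           foot_offsets = foot_off())
        })
        make_dynamic(grids)
      },
      tiptoe = {
        fr <- function(h) render_footprint(center, scale, half = h,
                                           foot_offsets = foot_off())
        make_dynamic(list(fr(FALSE), fr(TRUE), fr(TRUE), fr(TRUE), fr(TRUE),
                          fr(TRUE), fr(FALSE)))
      })
  })
}

#' Generate a seeded synthetic dataset with a stratified train/test split
#'
#' Draws `n_per_class` samples per configured class from independent per-class
#' sub-seed streams, then splits 80-20 per class (stratified, seeded,
#' rounding toward train).
#'
#' @param cfg A [synth_config()].
#' @param split If `TRUE` (default) return a stratified 80-20 split; if
#'   `FALSE` return the full dataset unsplit.
#' @return For `split = TRUE`, a list with `train` and `test`
#'   `pressure_dataset`s; otherwise one `pressure_dataset`.
#' @export
#' @examples
#' d <- generate_dataset(synth_config(classes = c("no_press", "stand"),
#'                                    n_per_class = 10, seed = 7))
#' length(d$train); length(d$test)
generate_dataset <- function(cfg, split = TRUE) {
  if (!inherits(cfg, "synth_config")) {
    stop("invalid argument: 'cfg' must be a synth_config")
  }
  if (split && cfg$n_per_class < 5L) {
    stop("invalid argument: n_per_class must be >= 5 for an 80-20 split (empty test stratum)")
  }
  class_seeds <- derive_seeds(cfg$seed, 2L * length(cfg$classes))
  train <- list(); test <- list(); all_samples <- list()
  for (ci in seq_along(cfg$classes)) {
    cls <- cfg$classes[ci]
    sample_seeds <- derive_seeds(class_seeds[ci], cfg$n_per_class)
    samples <- lapply(sample_seeds, function(sd) generate_sample(cls, cfg, sd))
    if (!split) {
      all_samples <- c(all_samples, samples)
    } else {
      n_test <- floor(cfg$n_per_class * 0.2)
      perm <- with_seed(class_seeds[length(cfg$classes) + ci],
                        sample.int(cfg$n_per_class))
      test <- c(test, samples[perm[seq_len(n_test)]])
      train <- c(train, samples[perm[(n_test + 1L):cfg$n_per_class]])
    }
  }
  meta <- list(config = unclass(cfg), format = "hdpress_synth", version = 1L)
  if (!split) return(pressure_dataset(all_samples, meta))
  list(train = pressure_dataset(train, meta), test = pressure_dataset(test, meta))
}
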