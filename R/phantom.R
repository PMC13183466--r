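#' Frame sequences
#'
#' A frame sequence is a list of numeric matrices (gray levels, row = y,
#' column = x) sharing one size, with a fixed frame rate. Frame `i` of the
#' list is frame index `i - 1` at time `(i - 1) / fps` seconds.
#'
#' @param frames List of numeric matrices.
#' @param fps Frames per second.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, fps) {
  stopifnot(is.list(frames), fps > 0)
  if (length(frames) > 0) {
    d <- dim(frames[[1]])
    ok <- vapply(frames, function(f) is.matrix(f) && identical(dim(f), d),
                 logical(1))
    if (!all(ok)) stopf("all frames must be matrices of identical size")
  }
  structure(frames, fps = fps, class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- if (length(x)) dim(x[[1]]) else c(0, 0)
  cat(sprintf("<frame_sequence> %d frames, %dx%d px, %g fps\n",
              length(x), d[1], d[2], attr(x, "fps")))
  invisible(x)
}

as_frame_list <- function(frames) {
  if (inherits(frames, "frame_sequence")) return(unclass(frames))
  stopifnot(is.list(frames))
  frames
}

frames_fps <- function(frames, fps = NULL) {
  if (!is.null(fps)) return(fps)
  fps <- attr(frames, "fps")
  if (is.null(fps)) stopf("fps not given and not carried by the frame sequence")
  fps
}

#' Specify a synthetic larva phantom
#'
#' The phantom emulates the assay recording: a dark elliptical body on a
#' brighter, linearly shaded background, whose major axis contracts while
#' the stimulus is on and relaxes while it is off, plus a blinking indicator
#' dot mirroring the stimulus state and optional additive Gaussian noise.
#' All randomness flows from `seed`; an identical spec and seed render a
#' bit-identical video.
#'
#' @param image_size `(height, width)` in pixels.
#' @param fps Frames per second (the assay camera records at 10).
#' @param protocol A [stimulus_protocol()]. The phantom renders
#'   `round(total_s * fps)` frames.
#' @param body_axes `(a0, b0)` resting semi-major/semi-minor axes, pixels.
#' @param body_center `(x, y)` initial body center; default frame center.
#' @param contraction_fraction Fractional reduction of the major axis at
#'   full contraction, in `[0, 1)`.
#' @param contraction_decline Fractional linear decline of the contraction
#'   over the protocol's cycles (0 = no fatigue; 0.3 = the last cycle
#'   contracts 30\% less than the first).
#' @param response_tau Exponential time constant of contraction onset and
#'   relaxation, seconds (0 = instantaneous).
#' @param drift_speed Slow centroid drift along +x, pixels/s.
#' @param body_intensity,background_intensity Gray levels; the body must be
#'   darker than the background.
#' @param background_gradient Gray-level span of a linear left-to-right
#'   shading added to the background.
#' @param indicator_center `(x, y)` of the indicator dot.
#' @param indicator_radius Indicator dot radius, pixels.
#' @param indicator_on_intensity,indicator_off_intensity Dot gray levels.
#' @param noise_sd Additive Gaussian noise standard deviation, gray levels.
#' @param bit_depth Output bit depth (8 by default; values are clipped to
#'   `[0, 2^bit_depth - 1]` and rounded).
#' @param seed Integer seed governing all randomness.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(120, 160),
                         fps = 10,
                         protocol = stimulus_protocol(),
                         body_axes = c(30, 10),
                         body_center = NULL,
                         contraction_fraction = 0.2,
                         contraction_decline = 0,
                         response_tau = 0.2,
                         drift_speed = 0,
                         body_intensity = 60,
                         background_intensity = 180,
                         background_gradient = 20,
                         indicator_center = c(14, 14),
                         indicator_radius = 5,
                         indicator_on_intensity = 255,
                         indicator_off_intensity = 40,
                         noise_sd = 0,
                         bit_depth = 8,
                         seed = 1L) {
  spec <- list(image_size = as.integer(image_size), fps = fps,
               protocol = protocol, body_axes = as.numeric(body_axes),
               body_center = if (is.null(body_center))
                 c((image_size[2] + 1) / 2, (image_size[1] + 1) / 2)
               else as.numeric(body_center),
               contraction_fraction = contraction_fraction,
               contraction_decline = contraction_decline,
               response_tau = response_tau, drift_speed = drift_speed,
               body_intensity = body_intensity,
               background_intensity = background_intensity,
               background_gradient = background_gradient,
               indicator_center = as.numeric(indicator_center),
               indicator_radius = indicator_radius,
               indicator_on_intensity = indicator_on_intensity,
               indicator_off_intensity = indicator_off_intensity,
               noise_sd = noise_sd, bit_depth = bit_depth,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(s) {
  maxv <- 2^s$bit_depth - 1
  if (s$fps <= 0) stopf("fps must be > 0")
  if (!inherits(s$protocol, "stimulus_protocol"))
    stopf("protocol must be a stimulus_protocol")
  if (s$contraction_fraction < 0 || s$contraction_fraction >= 1)
    stopf("contraction_fraction must be in [0, 1)")
  if (s$contraction_decline < 0 || s$contraction_decline > 1)
    stopf("contraction_decline must be in [0, 1]")
  if (s$body_intensity >= s$background_intensity)
    stopf("body_intensity (%g) must be below background_intensity (%g): the larva appears dark on a light background",
          s$body_intensity, s$background_intensity)
  ints <- c(s$body_intensity, s$background_intensity,
            s$indicator_on_intensity, s$indicator_off_intensity)
  if (any(ints < 0 | ints > maxv))
    stopf("intensities must lie within [0, %g] for bit depth %d", maxv, s$bit_depth)
  if (any(s$body_axes <= 0)) stopf("body_axes must be positive")
  if (s$response_tau < 0) stopf("response_tau must be >= 0")
  if (s$noise_sd < 0) stopf("noise_sd must be >= 0")
  invisible(s)
}

#' Ramanujan's second approximation to the ellipse perimeter
#'
#' @param a,b Semi-axes.
#' @return Perimeter (same units as the axes). Exact for circles; relative
#'   error far below any pixel-level tolerance for moderate eccentricities.
#' @export
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Analytic ground truth of a phantom, without rendering pixels
#'
#' Computes the per-frame stimulus state, instantaneous body axes, analytic
#' ellipse perimeter (Ramanujan's approximation) and centroid implied by a
#' [phantom_spec()]. [render_phantom()] renders exactly this truth.
#'
#' @param spec A [phantom_spec()].
#' @return Data frame with columns `frame` (0-based), `time_s`,
#'   `perimeter_true`, `led_state_true`, `centroid_x`, `centroid_y`,
#'   `axis_a`, `axis_b`.
#' @export
phantom_truth <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  p <- spec$protocol
  n <- round(p$total_s * spec$fps)
  t <- (seq_len(n) - 1) / spec$fps
  led <- protocol_led_state(p, n, spec$fps)

  # per-cycle contraction fraction with optional linear fatigue decline
  ncyc <- n_cycles(p)
  period <- p$on_s + p$off_s
  k <- pmin(pmax(floor((t - p$delay_s) / period) + 1, 1), ncyc)
  decline_scale <- if (ncyc > 1) (k - 1) / (ncyc - 1) else 0
  f <- spec$contraction_fraction * (1 - spec$contraction_decline * decline_scale)

  a0 <- spec$body_axes[1]
  dt <- 1 / spec$fps
  alpha <- if (spec$response_tau > 0) 1 - exp(-dt / spec$response_tau) else 1
  a <- numeric(n)
  a[1] <- a0
  target <- ifelse(led, a0 * (1 - f), a0)
  if (n > 1) for (i in 2:n) a[i] <- a[i - 1] + alpha * (target[i] - a[i - 1])

  data.frame(frame = seq_len(n) - 1L,
             time_s = t,
             perimeter_true = ellipse_perimeter(a, spec$body_axes[2]),
             led_state_true = led,
             centroid_x = spec$body_center[1] + spec$drift_speed * t,
             centroid_y = rep(spec$body_center[2], n),
             axis_a = a,
             axis_b = rep(spec$body_axes[2], n))
}

#' Render a synthetic larva video with ground truth
#'
#' @param spec A [phantom_spec()].
#' @return List with `frames` (a [frame_sequence()]) and `truth`
#'   (the [phantom_truth()] data frame).
#' @examples
#' spec <- phantom_spec(protocol = stimulus_protocol(2, 2, 1, 11),
#'                      image_size = c(64, 96), body_axes = c(14, 6))
#' ph <- render_phantom(spec)
#' length(ph$frames)   # 110 frames
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  truth <- phantom_truth(spec)
  n <- nrow(truth)
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  maxv <- 2^spec$bit_depth - 1

  # reject bodies that leave the frame, naming the first offending frame
  out_of_bounds <- truth$centroid_x - truth$axis_a < 1 |
    truth$centroid_x + truth$axis_a > nc |
    truth$centroid_y - truth$axis_b < 1 |
    truth$centroid_y + truth$axis_b > nr
  if (any(out_of_bounds))
    stopf("phantom body leaves the %dx%d frame at frame %d",
          nr, nc, truth$frame[which(out_of_bounds)[1]])

  x <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  y <- matrix(rep(seq_len(nr), nc), nr, nc)
  background <- spec$background_intensity +
    spec$background_gradient * (x - 1) / max(nc - 1, 1)
  ind <- (x - spec$indicator_center[1])^2 +
         (y - spec$indicator_center[2])^2 <= spec$indicator_radius^2
  if (!any(ind)) stopf("indicator dot covers no pixels")

  frames <- with_seed(spec$seed, {
    lapply(seq_len(n), function(i) {
      img <- background
      body <- ((x - truth$centroid_x[i]) / truth$axis_a[i])^2 +
              ((y - truth$centroid_y[i]) / truth$axis_b[i])^2 <= 1
      img[body] <- spec$body_intensity
      img[ind] <- if (truth$led_state_true[i]) spec$indicator_on_intensity
                  else spec$indicator_off_intensity
      if (spec$noise_sd > 0)
        img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
      round(clip(img, 0, maxv))
    })
  })
  list(frames = frame_sequence(frames, spec$fps), truth = truth)
}

#' Write a phantom to disk as numbered PNG frames plus a truth CSV
#'
#' Frames are written as `frame_000000.png`, `frame_000001.png`, ... in
#' `dir`, with the ground truth in `truth.csv` (columns `frame`, `time_s`,
#' `perimeter_true`, `led_state_true`, `centroid_x`, `centroid_y`).
#'
#' @param phantom Result of [render_phantom()].
#' @param dir Output directory (created if missing).
#' @param bit_depth Bit depth used when scaling gray levels to PNG.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir, bit_depth = 8) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_frames(phantom$frames, dir, bit_depth = bit_depth)
  truth <- phantom$truth[, c("frame", "time_s", "perimeter_true",
                             "led_state_true", "centroid_x", "centroid_y")]
  truth$led_state_true <- as.integer(truth$led_state_true)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Render a registered two-channel synthetic bouton field
#'
#' Emulates a motor-neuron terminal imaged in a cytosolic and a
#' mitochondrial fluorescence channel: `n_boutons` disk-shaped boutons on a
#' uniform background, with above-background intensity `cyto_level` in the
#' cytosolic channel and `mito_level` in the mitochondrial channel, so the
#' programmed content ratio is `mito_level / cyto_level`. Each channel is a
#' small z-stack (identical signal per slice; noise drawn independently per
#' slice) suitable for [project_average()].
#'
#' @param mito_level Above-background mitochondrial intensity (>= 0).
#' @param cyto_level Above-background cytosolic intensity (> 0).
#' @param background_level Uniform background gray level.
#' @param n_boutons Number of boutons.
#' @param noise_sd Additive Gaussian noise sd, gray levels.
#' @param seed Integer seed.
#' @param image_size `(height, width)` pixels.
#' @param bouton_radius Bouton radius, pixels.
#' @param n_slices Slices per stack.
#' @return List with `cyto` and `mito` (arrays `height x width x n_slices`),
#'   `truth_ratio`, `centers` (data frame of bouton centers `x`, `y`) and
#'   `bouton_radius`.
#' @export
render_bouton_pair <- function(mito_level, cyto_level, background_level = 20,
                               n_boutons = 6, noise_sd = 0, seed = 1L,
                               image_size = c(96, 96), bouton_radius = 4,
                               n_slices = 3) {
  if (cyto_level <= 0)
    stopf("cyto_level must be > 0 (the content ratio is undefined otherwise)")
  if (mito_level < 0 || background_level < 0)
    stopf("levels must be non-negative")
  nr <- image_size[1]; nc <- image_size[2]

  with_seed(seed, {
    # deterministic, non-overlapping bouton centers in the lower-right
    # three-quarters of the field (upper-left strip stays signal-free for
    # background ROIs)
    centers <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(centers) < n_boutons && tries < 10000) {
      tries <- tries + 1
      cand <- c(stats::runif(1, nc * 0.3, nc - bouton_radius - 2),
                stats::runif(1, nr * 0.3, nr - bouton_radius - 2))
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >
              2 * bouton_radius + 2))
        centers <- rbind(centers, cand)
    }
    if (nrow(centers) < n_boutons)
      stopf("could not place %d non-overlapping boutons in a %dx%d field",
            n_boutons, nr, nc)

    x <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    y <- matrix(rep(seq_len(nr), nc), nr, nc)
    inside <- matrix(FALSE, nr, nc)
    for (i in seq_len(nrow(centers)))
      inside <- inside | ((x - centers[i, 1])^2 + (y - centers[i, 2])^2 <=
                            bouton_radius^2)

    base_cyto <- background_level + cyto_level * inside
    base_mito <- background_level + mito_level * inside
    noisy_stack <- function(base) {
      arr <- array(0, c(nr, nc, n_slices))
      for (s in seq_len(n_slices)) {
        sl <- base
        if (noise_sd > 0)
          sl <- sl + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
        arr[, , s] <- pmax(sl, 0)
      }
      arr
    }
    list(cyto = noisy_stack(base_cyto),
         mito = noisy_stack(base_mito),
         truth_ratio = mito_level / cyto_level,
         centers = data.frame(x = centers[, 1], y = centers[, 2]),
         bouton_radius = bouton_radius)
  })
}

#' Convert analytic phantom truth into analysis-ready traces
#'
#' Builds the per-frame tracking trace and stimulus trace implied by a
#' phantom's analytic ground truth, optionally with Gaussian measurement
#' jitter on the perimeter, without rendering a single pixel. This gives a
#' fast path for validating the normalization / cycle-metrics stages at
#' full protocol length; the rendered path exercises the image stages.
#'
#' @param spec A [phantom_spec()].
#' @param jitter_sd Gaussian jitter added to the true perimeter, pixels.
#' @param seed Seed for the jitter; defaults to the spec's seed.
#' @return List with `track` (a `track_trace`), `led` (a `stimulus_trace`)
#'   and `truth`.
#' @export
truth_traces <- function(spec, jitter_sd = 0, seed = spec$seed) {
  truth <- phantom_truth(spec)
  n <- nrow(truth)
  perim <- truth$perimeter_true
  if (jitter_sd > 0)
    perim <- with_seed(seed, perim + stats::rnorm(n, 0, jitter_sd))
  track <- data.frame(frame = truth$frame, time_s = truth$time_s,
                      area = pi * truth$axis_a * truth$axis_b,
                      perimeter = perim,
                      x = truth$centroid_x, y = truth$centroid_y,
                      step_distance = c(0, sqrt(diff(truth$centroid_x)^2 +
                                                  diff(truth$centroid_y)^2)),
                      valid = TRUE)
  class(track) <- c("track_trace", class(track))
  led <- data.frame(frame = truth$frame,
                    roi_mean = ifelse(truth$led_state_true,
                                      spec$indicator_on_intensity,
                                      spec$indicator_off_intensity),
                    led_on = truth$led_state_true)
  attr(led, "threshold_used") <- NA_real_
  class(led) <- c("stimulus_trace", class(led))
  list(track = track, led = led, truth = truth)
}
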