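#' Segmentation parameters
#'
#' Defaults reproduce the published processing recipe: Gaussian blur of
#' radius 1, rolling-ball background subtraction with a 50-pixel radius,
#' Otsu thresholding of a dark larva on a light background.
#'
#' @param blur_radius Gaussian blur radius in pixels (>= 0; 0 disables).
#'   The kernel standard deviation is `sigma = radius` (fixed convention).
#' @param rolling_ball_radius Structuring-element radius for background
#'   subtraction, pixels (>= 1).
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Gray level used when `threshold_method = "fixed"`.
#' @param object_polarity `"dark_on_light"` (default; the larva is dark) or
#'   `"light_on_dark"`.
#' @param threshold_per_frame Compute the threshold on every frame (default)
#'   or once on a reference frame and freeze it (`FALSE`).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(blur_radius = 1,
                                rolling_ball_radius = 50,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                object_polarity = c("dark_on_light",
                                                    "light_on_dark"),
                                threshold_per_frame = TRUE) {
  threshold_method <- match.arg(threshold_method)
  object_polarity <- match.arg(object_polarity)
  if (blur_radius < 0) stopf("blur_radius must be >= 0")
  if (rolling_ball_radius < 1) stopf("rolling_ball_radius must be >= 1")
  if (threshold_method == "fixed" && !is_scalar_num(fixed_threshold))
    stopf("fixed_threshold must be a number when threshold_method = 'fixed'")
  structure(list(blur_radius = blur_radius,
                 rolling_ball_radius = rolling_ball_radius,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 object_polarity = object_polarity,
                 threshold_per_frame = threshold_per_frame),
            class = "segmentation_params")
}

#' Gaussian blur
#'
#' Isotropic Gaussian smoothing. The "radius" follows the fixed convention
#' `sigma = radius` (stated because image-processing tools disagree on the
#' radius-to-sigma mapping). A radius of 0 returns the input unchanged.
#'
#' @param frame Numeric matrix of gray levels.
#' @param radius Blur radius in pixels (>= 0).
#' @return Blurred matrix of the same size.
#' @export
gaussian_blur <- function(frame, radius = 1) {
  stopifnot(is.matrix(frame))
  if (radius < 0) stopf("radius must be >= 0")
  if (radius == 0) return(frame)
  as_plain_matrix(EBImage::gblur(frame, sigma = radius))
}

#' Rolling-ball background subtraction
#'
#' Estimates a smooth background by grayscale morphological opening with a
#' disk structuring element of the given radius and subtracts it, so that
#' objects smaller than the ball survive as the residual. For a dark object
#' on a light background (`polarity = "dark_on_light"`, the default) the
#' opening is applied to the photometric inverse — equivalently, a closing
#' of the original — so the returned residual is bright exactly where the
#' dark object was. The residual is clipped to be non-negative and never
#' exceeds the input's dynamic range.
#'
#' @param frame Numeric matrix.
#' @param ball_radius Structuring-element radius, pixels (>= 1; the ball
#'   must fit inside the frame).
#' @param polarity `"dark_on_light"` or `"light_on_dark"`.
#' @return Residual matrix (object-bright in both polarities).
#' @export
subtract_background <- function(frame, ball_radius = 50,
                                polarity = c("dark_on_light",
                                             "light_on_dark")) {
  polarity <- match.arg(polarity)
  stopifnot(is.matrix(frame))
  if (ball_radius < 1) stopf("ball_radius must be >= 1")
  side <- 2 * floor(ball_radius) + 1
  if (side > min(dim(frame)))
    stopf("ball of radius %g (diameter %d px) does not fit a %dx%d frame",
          ball_radius, side, nrow(frame), ncol(frame))
  brush <- EBImage::makeBrush(side, shape = "disc")
  work <- if (polarity == "dark_on_light") max(frame) - frame else frame
  # grayscale opening with windows clamped to the frame: pad with the
  # neutral element of each rank filter so the border is not dragged to 0
  k <- (side - 1L) %/% 2L
  pad <- function(m, value) {
    out <- matrix(value, nrow(m) + 2L * k, ncol(m) + 2L * k)
    out[(k + 1):(k + nrow(m)), (k + 1):(k + ncol(m))] <- m
    out
  }
  crop <- function(m) m[(k + 1):(nrow(m) - k), (k + 1):(ncol(m) - k)]
  # rank filters commute with positive rescaling; EBImage morphology expects
  # intensities in [0, 1], so filter on the rescaled image
  scale <- max(work, 1)
  ws <- work / scale
  er <- crop(as_plain_matrix(EBImage::erode(pad(ws, max(ws)), brush)))
  bg <- crop(as_plain_matrix(EBImage::dilate(pad(er, min(er)), brush))) * scale
  pmax(work - bg, 0)
}

#' Otsu threshold
#'
#' Threshold maximizing the between-class variance of the 256-bin intensity
#' histogram (inputs with values outside 0..255 are range-scaled onto the
#' 256 bins first, and the threshold mapped back). Ties are broken by the
#' lowest maximizing threshold. The returned gray level `T` splits pixels
#' into the classes `<= T` and `> T`.
#'
#' @param frame Numeric matrix with at least two distinct values.
#' @return Threshold gray level.
#' @export
otsu_threshold <- function(frame) {
  v <- as.vector(frame)
  rng <- range(v)
  if (diff(rng) == 0)
    stopf("constant image: no threshold separates two classes")
  scaled <- rng[1] < 0 || rng[2] > 255 || any(v != floor(v))
  if (scaled) {
    bins <- pmin(floor((v - rng[1]) / diff(rng) * 256), 255)
  } else {
    bins <- v
  }
  h <- tabulate(bins + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)                     # class-0 weight for cut after bin t
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  t_all <- 0:254
  w0 <- omega[t_all + 1L]
  m0 <- mu[t_all + 1L]
  sigma_b <- (mu_t * w0 - m0)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  t_best <- t_all[which.max(sigma_b)]    # which.max takes the first (lowest) tie
  if (scaled) rng[1] + (t_best + 1) / 256 * diff(rng) else t_best
}

#' Binarize a frame at a threshold
#'
#' The mask is `TRUE` exactly on object pixels: the class `<= threshold`
#' for `"dark_on_light"`, the class `> threshold` for `"light_on_dark"`.
#' (Internally the foreground is always `TRUE`, regardless of how a binary
#' video might be displayed.)
#'
#' @param frame Numeric matrix.
#' @param threshold Gray level.
#' @param polarity `"dark_on_light"` or `"light_on_dark"`.
#' @return Logical matrix.
#' @export
binarize <- function(frame, threshold,
                     polarity = c("dark_on_light", "light_on_dark")) {
  polarity <- match.arg(polarity)
  stopifnot(is.matrix(frame), is_scalar_num(threshold))
  if (polarity == "dark_on_light") frame <= threshold else frame > threshold
}

#' Segment one frame into a larva mask
#'
#' The full published chain, in order: Gaussian blur, rolling-ball
#' background subtraction, (Otsu or fixed) threshold, binarization. After
#' background subtraction the object is bright in both polarities, so the
#' final binarization always keeps the bright class. A frame with no object
#' left after background subtraction (constant residual) yields an empty
#' mask rather than an error.
#'
#' @param frame Numeric matrix.
#' @param params A [segmentation_params()].
#' @param frozen_threshold Optional precomputed threshold (used by the
#'   pipeline when `threshold_per_frame = FALSE`).
#' @return Logical mask, `TRUE` on larva pixels.
#' @export
segment_frame <- function(frame, params = segmentation_params(),
                          frozen_threshold = NULL) {
  stopifnot(inherits(params, "segmentation_params"))
  f <- gaussian_blur(frame, params$blur_radius)
  res <- subtract_background(f, params$rolling_ball_radius,
                             params$object_polarity)
  thr <- if (!is.null(frozen_threshold)) {
    frozen_threshold
  } else if (params$threshold_method == "fixed") {
    params$fixed_threshold
  } else {
    if (diff(range(res)) == 0) return(matrix(FALSE, nrow(res), ncol(res)))
    otsu_threshold(res)
  }
  binarize(res, thr, "light_on_dark")
}
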