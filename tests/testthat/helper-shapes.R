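# small geometric fixtures and phantom presets shared across tests

# canonical digital disk: radius r centered on a pixel
disk_mask <- function(r, pad = 3) {
  n <- 2 * (r + pad) + 1
  cx <- r + pad + 1
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - cx)^2 + (j - cx)^2 <= r^2)
}

# a compact phantom that fits a 64x96 frame; rolling ball scaled to match
small_phantom_spec <- function(...) {
  defaults <- list(image_size = c(64, 96), body_axes = c(14, 6),
                   protocol = stimulus_protocol(3, 2, 1, 21),
                   response_tau = 0.05, indicator_center = c(8, 8),
                   indicator_radius = 3)
  args <- list(...)
  do.call(phantom_spec, utils::modifyList(defaults, args))
}

small_seg_params <- function(...) segmentation_params(rolling_ball_radius = 20, ...)

# brute-force grayscale opening residual with the same disc brush:
# an independent oracle for subtract_background on tiny images
brute_subtract_background <- function(frame, ball_radius, polarity) {
  brush <- EBImage::makeBrush(2 * floor(ball_radius) + 1, shape = "disc")
  k <- (nrow(brush) - 1) / 2
  offs <- which(brush > 0, arr.ind = TRUE) - k - 1
  nr <- nrow(frame); nc <- ncol(frame)
  work <- if (polarity == "dark_on_light") max(frame) - frame else frame
  filt <- function(img, fun) {
    out <- matrix(NA_real_, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      rr <- i + offs[, 1]; cc <- j + offs[, 2]
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      out[i, j] <- fun(img[cbind(rr[ok], cc[ok])])
    }
    out
  }
  open <- filt(filt(work, min), max)
  pmax(work - open, 0)
}

# brute-force Otsu: maximize between-class variance over all 255 cut points
# of the 0..255 gray levels, computed directly from the pixel values
brute_otsu <- function(v) {
  best <- -Inf; best_t <- NA
  for (t in 0:254) {
    lo <- v <= t
    n0 <- sum(lo); n1 <- length(v) - n0
    if (n0 == 0 || n1 == 0) next
    sb <- (n0 / length(v)) * (n1 / length(v)) * (mean(v[lo]) - mean(v[!lo]))^2
    if (sb > best + 1e-12) { best <- sb; best_t <- t }
  }
  best_t
}
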