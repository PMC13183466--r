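#' Define a cyclic optogenetic stimulation protocol
#'
#' A protocol is a baseline delay followed by alternating on/off illumination
#' cycles. The defaults reproduce the assay's standard regime: 10 s of
#' unstimulated baseline, then 2 s on / 1 s off cycles for 20 minutes of
#' stimulation (so the default grid holds exactly 400 complete cycles).
#'
#' @param delay_s Baseline delay before the first illumination, seconds.
#' @param on_s Illumination duration per cycle, seconds (> 0).
#' @param off_s Rest duration per cycle, seconds (>= 0).
#' @param total_s Total recording duration, seconds. Defaults to
#'   `delay_s + 1200` (20 minutes of stimulation after the baseline).
#' @return An object of class `stimulus_protocol`.
#' @examples
#' stimulus_protocol()                 # the standard assay protocol
#' stimulus_protocol(0, 5, 5, 20)      # two 5 s-on / 5 s-off cycles
#' @export
stimulus_protocol <- function(delay_s = 10, on_s = 2, off_s = 1,
                              total_s = delay_s + 1200) {
  stopifnot(is_scalar_num(delay_s), is_scalar_num(on_s),
            is_scalar_num(off_s), is_scalar_num(total_s))
  if (on_s <= 0) stopf("on_s must be > 0 (got %g)", on_s)
  if (off_s < 0) stopf("off_s must be >= 0 (got %g)", off_s)
  if (delay_s < 0) stopf("delay_s must be >= 0 (got %g)", delay_s)
  if (total_s <= delay_s)
    stopf("total_s (%g) must exceed delay_s (%g)", total_s, delay_s)
  structure(list(delay_s = delay_s, on_s = on_s, off_s = off_s,
                 total_s = total_s),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(
    "<stimulus_protocol> delay %gs | %gs on / %gs off | total %gs (%d complete cycles)\n",
    x$delay_s, x$on_s, x$off_s, x$total_s, n_cycles(x)))
  invisible(x)
}

n_cycles <- function(protocol) {
  floor((protocol$total_s - protocol$delay_s) / (protocol$on_s + protocol$off_s))
}

#' Nominal per-frame stimulus state of a protocol
#'
#' @param protocol A [stimulus_protocol()].
#' @param n_frames Number of frames.
#' @param fps Frames per second.
#' @return Logical vector of length `n_frames`: `TRUE` where the stimulus is
#'   nominally on at frame time `frame / fps` (frame 0 at t = 0).
#' @export
protocol_led_state <- function(protocol, n_frames, fps) {
  stopifnot(inherits(protocol, "stimulus_protocol"), fps > 0, n_frames >= 0)
  t <- (seq_len(n_frames) - 1) / fps
  phase <- (t - protocol$delay_s) %% (protocol$on_s + protocol$off_s)
  t >= protocol$delay_s & phase < protocol$on_s
}

#' Enumerate the complete stimulation cycles of a protocol
#'
#' Cycle k (1-based) occupies the half-open interval
#' `[delay + (k-1)(on+off), delay + k(on+off))`, split into its on-window
#' followed by its off-window. Only complete cycles are returned, so the
#' windows tile `[delay, delay + n(on+off))` without overlap.
#'
#' @param protocol A [stimulus_protocol()].
#' @return Data frame with columns `cycle_index`, `on_start`, `on_end`,
#'   `off_start`, `off_end` (seconds).
#' @examples
#' grid <- build_cycle_grid(stimulus_protocol())   # 400 cycles
#' tail(grid$cycle_index, 10)                      # 391 ... 400
#' @export
build_cycle_grid <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  n <- n_cycles(protocol)
  if (n < 1)
    stopf("protocol admits no complete cycle (total %g s, delay %g s, period %g s)",
          protocol$total_s, protocol$delay_s, protocol$on_s + protocol$off_s)
  k <- seq_len(n)
  period <- protocol$on_s + protocol$off_s
  start <- protocol$delay_s + (k - 1) * period
  data.frame(cycle_index = k,
             on_start  = start,
             on_end    = start + protocol$on_s,
             off_start = start + protocol$on_s,
             off_end   = start + period)
}

#' Stimulus duty cycle
#'
#' Fraction of each stimulation cycle during which the stimulus is on,
#' as a percentage. The standard 2 s on / 1 s off regime gives 66.67,
#' reported as 67 when rounded.
#'
#' @param on_s,off_s On and off durations in seconds, or a
#'   [stimulus_protocol()] as the first argument.
#' @return Named list with `raw` (exact percent) and `rounded`
#'   (nearest integer).
#' @examples
#' duty_cycle(2, 1)$rounded   # 67
#' duty_cycle(5, 5)$raw       # 50
#' @export
duty_cycle <- function(on_s, off_s = NULL) {
  if (inherits(on_s, "stimulus_protocol")) {
    off_s <- on_s$off_s
    on_s <- on_s$on_s
  }
  stopifnot(is_scalar_num(on_s), is_scalar_num(off_s))
  if (on_s + off_s <= 0) stopf("on_s + off_s must be > 0")
  raw <- 100 * on_s / (on_s + off_s)
  list(raw = raw, rounded = round(raw))
}

#' Time-averaged metabolic load relative to endogenous activity
#'
#' Ratio of the assay's stimulation duty cycle to the motor neurons'
#' endogenous duty cycle during unrestrained locomotion (about 78% in
#' third-instar larvae), as a percentage. The standard 67% assay duty
#' cycle therefore corresponds to roughly 86% of the endogenous load.
#'
#' @param assay_duty Assay duty cycle, percent.
#' @param endogenous_duty Endogenous duty cycle, percent (> 0). Default 78.
#' @return Named list with `raw` and `rounded` percent.
#' @examples
#' metabolic_load(67, 78)$rounded   # 86
#' @export
metabolic_load <- function(assay_duty, endogenous_duty = 78) {
  stopifnot(is_scalar_num(assay_duty), is_scalar_num(endogenous_duty))
  if (endogenous_duty <= 0) stopf("endogenous_duty must be > 0")
  raw <- 100 * assay_duty / endogenous_duty
  list(raw = raw, rounded = round(raw))
}

#' Mean intensity of a region of interest, per frame
#'
#' Mirrors the acquisition-side "ROI activity, operation = average" node:
#' the arithmetic mean of the pixel intensities inside the region, one value
#' per frame. Typically placed over the indicator LED that mirrors the
#' stimulus state.
#'
#' @param frames A [frame_sequence()] or plain list of matrices.
#' @param roi A region created by [roi_disk()], [roi_rect()], [roi_ellipse()]
#'   or [roi_polygon()].
#' @return Numeric vector, one mean gray level per frame.
#' @export
roi_mean_trace <- function(frames, roi) {
  frames <- as_frame_list(frames)
  if (length(frames) == 0) stopf("no frames")
  mask <- roi_mask(roi, dim(frames[[1]]))
  if (!any(mask)) stopf("ROI covers no pixels")
  idx <- which(mask)
  vapply(frames, function(f) mean(f[idx]), numeric(1))
}

#' Decode the per-frame stimulus state from an indicator-ROI trace
#'
#' A frame is decoded as "on" when the ROI mean strictly exceeds the
#' threshold (a boundary value counts as off). In `"auto"` mode the
#' threshold is the midpoint between the two plateau levels found by
#' deterministic two-class (1-D k-means) clustering of the trace; auto mode
#' refuses traces without two separated plateaus (an indicator that never
#' blinked) and asks for a manual threshold instead.
#'
#' @param roi_trace Numeric vector of per-frame ROI means.
#' @param threshold Numeric gray level, or `"auto"` (default).
#' @return Data frame of class `stimulus_trace` with columns `frame`
#'   (0-based), `roi_mean`, `led_on`; the threshold is stored in
#'   `attr(, "threshold_used")`.
#' @export
decode_led_status <- function(roi_trace, threshold = "auto") {
  if (length(roi_trace) == 0) stopf("empty ROI trace")
  if (identical(threshold, "auto")) {
    threshold <- auto_led_threshold(roi_trace)
  }
  stopifnot(is_scalar_num(threshold))
  out <- data.frame(frame = seq_along(roi_trace) - 1L,
                    roi_mean = as.numeric(roi_trace),
                    led_on = roi_trace > threshold)
  attr(out, "threshold_used") <- threshold
  class(out) <- c("stimulus_trace", class(out))
  out
}

# Deterministic 1-D two-means: centers seeded at the trace extremes, Lloyd
# iterations until fixed. Errors when the trace has no two-plateau structure.
auto_led_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0)
    stopf("indicator trace is constant; LED never blinked - supply a manual threshold")
  c1 <- rng[1]; c2 <- rng[2]
  for (i in 1:100) {
    mid <- (c1 + c2) / 2
    lo <- x <= mid
    n1 <- mean(x[lo]); n2 <- mean(x[!lo])
    if (isTRUE(all.equal(c(n1, n2), c(c1, c2)))) break
    c1 <- n1; c2 <- n2
  }
  sep <- c2 - c1
  within_sd <- max(stats::sd(x[lo]), stats::sd(x[!lo]), na.rm = TRUE)
  if (!is.finite(within_sd)) within_sd <- 0
  # a unimodal trace splits into two halves whose spread rivals their
  # separation; two genuine plateaus are far apart relative to their noise
  if (sep < 4 * within_sd)
    stopf("indicator trace looks unimodal (plateau separation %.3g < 4 x within-plateau sd %.3g); supply a manual threshold", sep, within_sd)
  (c1 + c2) / 2
}

#' Align a protocol cycle grid to the decoded stimulus trace
#'
#' The protocol's delay is program-side while the video starts
#' asynchronously, so the grid is anchored on the data: the lag between the
#' nominal first on-time and the first decoded on-frame is measured and, by
#' default, the whole grid is shifted by it. Each cycle's on/off windows are
#' then mapped to half-open frame-index ranges via `frame t <-> time t/fps`.
#'
#' @param led A `stimulus_trace` from [decode_led_status()].
#' @param grid Cycle grid from [build_cycle_grid()].
#' @param fps Frames per second.
#' @param compensate_lag Shift the grid by the measured lag (default `TRUE`).
#' @return Data frame with, per cycle, `cycle_index` and the half-open frame
#'   ranges `on_first`, `on_last_excl`, `off_first`, `off_last_excl`
#'   (0-based). The measured lag in seconds is in `attr(, "lag_s")`.
#' @export
align_status <- function(led, grid, fps, compensate_lag = TRUE) {
  stopifnot(inherits(led, "stimulus_trace"), fps > 0)
  first_on <- which(led$led_on)[1]
  if (is.na(first_on))
    stopf("no decoded on-frames; cannot align the cycle grid")
  lag_s <- (first_on - 1) / fps - grid$on_start[1]
  period <- grid$off_end[1] - grid$on_start[1]
  if (abs(lag_s) >= period)
    stopf("measured onset lag (%.3f s) exceeds one full cycle (%.3f s); protocol and video do not match", lag_s, period)
  shift <- if (compensate_lag) lag_s else 0
  f <- function(t) as.integer(ceiling(round(t * fps, 9)))  # first frame with time >= t
  out <- data.frame(cycle_index   = grid$cycle_index,
                    on_first      = f(grid$on_start + shift),
                    on_last_excl  = f(grid$on_end + shift),
                    off_first     = f(grid$off_start + shift),
                    off_last_excl = f(grid$off_end + shift))
  attr(out, "lag_s") <- lag_s
  attr(out, "fps") <- fps
  out
}

#' Write / read the per-frame stimulus-status table
#'
#' One row per frame (`frame`, `roi_mean`, `led_on`), matching the CSV
#' contract of the acquisition pipeline's status logger.
#'
#' @param led A `stimulus_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); a `stimulus_trace` (reader).
#' @export
write_led_csv <- function(led, path) {
  stopifnot(inherits(led, "stimulus_trace"))
  df <- data.frame(frame = led$frame, roi_mean = led$roi_mean,
                   led_on = as.integer(led$led_on))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_led_csv
#' @export
read_led_csv <- function(path) {
  df <- utils::read.csv(path)
  out <- data.frame(frame = as.integer(df$frame), roi_mean = df$roi_mean,
                    led_on = as.logical(df$led_on))
  class(out) <- c("stimulus_trace", class(out))
  out
}
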