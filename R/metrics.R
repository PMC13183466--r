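#' Normalize a perimeter trace to its pre-stimulus baseline
#'
#' The baseline is the mean perimeter over the 2 s window immediately before
#' the first decoded illumination (`[t_on - baseline_s, t_on)`); every
#' perimeter value is divided by that window mean, which removes
#' between-animal differences in size and posture. Invalid frames stay
#' missing.
#'
#' @param trace A `track_trace` from [track_single()].
#' @param led A `stimulus_trace` from [decode_led_status()].
#' @param fps Frames per second.
#' @param baseline_s Baseline window length, seconds (default 2).
#' @return Data frame (`normalized_trace`): `frame`, `time_s`,
#'   `perimeter_norm`, `led_on`, `valid`; attributes `baseline_value`
#'   (pixels) and `baseline_window` (`c(start_s, end_s)`).
#' @export
normalize_trace <- function(trace, led, fps, baseline_s = 2) {
  stopifnot(inherits(trace, "track_trace"), inherits(led, "stimulus_trace"))
  if (nrow(trace) != nrow(led))
    stopf("trace (%d frames) and stimulus trace (%d frames) differ in length",
          nrow(trace), nrow(led))
  first_on <- which(led$led_on)[1]
  if (is.na(first_on)) stopf("stimulus trace contains no on-frames")
  t_on <- (first_on - 1) / fps
  win <- c(max(t_on - baseline_s, 0), t_on)
  in_win <- trace$time_s >= win[1] & trace$time_s < win[2]
  base_vals <- trace$perimeter[in_win & trace$valid]
  if (length(base_vals) == 0)
    stopf("no valid frames in the %g-%g s baseline window", win[1], win[2])
  baseline <- mean(base_vals)
  if (baseline <= 0) stopf("baseline perimeter is not positive")
  out <- data.frame(frame = trace$frame, time_s = trace$time_s,
                    perimeter_norm = trace$perimeter / baseline,
                    led_on = led$led_on, valid = trace$valid)
  attr(out, "baseline_value") <- baseline
  attr(out, "baseline_window") <- win
  class(out) <- c("normalized_trace", class(out))
  out
}

# linear interpolation of missing values inside a window, but only across
# gaps of at most `max_gap` frames; longer gaps stay missing
fill_small_gaps <- function(x, max_gap) {
  if (!anyNA(x) || all(is.na(x)) || max_gap < 1) return(x)
  zoo::na.approx(x, maxgap = max_gap, na.rm = FALSE)
}

#' Per-cycle contraction metrics
#'
#' For each stimulation cycle: `rest_value` is the mean normalized perimeter
#' over the trailing fraction of the *preceding* off-window (the animal
#' relaxes during the off phase; cycle 1 has no preceding off-window and
#' uses the pre-stimulus baseline, i.e. rest 1.0); `max_contraction_value`
#' is the minimum normalized perimeter within the cycle's on-window
#' (contraction shortens the outline); `amplitude = rest_value -
#' max_contraction_value`, positive for a contracting animal. Missing frames
#' are linearly interpolated inside cycle windows only when the gap is at
#' most `max_gap` frames; a cycle whose on-window has no valid frames gets
#' missing metrics and is flagged, as is any cycle with fewer valid
#' on-window frames than `min_valid_frames`.
#'
#' @param norm A `normalized_trace` from [normalize_trace()].
#' @param aligned Aligned cycle windows from [align_status()].
#' @param rest_fraction Trailing fraction of the preceding off-window used
#'   as the rest reference (default 0.5).
#' @param max_gap Longest missing-frame gap to interpolate, frames.
#' @param min_valid_frames Minimum valid on-window frames for an unflagged
#'   cycle; default half the on-window length.
#' @return Data frame (`cycle_metrics`): `cycle_index`, `rest_value`,
#'   `max_contraction_value`, `amplitude`, `n_valid_frames`, `flagged`.
#' @export
cycle_metrics <- function(norm, aligned, rest_fraction = 0.5, max_gap = 3,
                          min_valid_frames = NULL) {
  stopifnot(inherits(norm, "normalized_trace"))
  if (rest_fraction <= 0 || rest_fraction > 1)
    stopf("rest_fraction must be in (0, 1]")
  nfr <- nrow(norm)
  v <- norm$perimeter_norm
  v[!norm$valid] <- NA_real_
  ncyc <- nrow(aligned)
  res <- data.frame(cycle_index = aligned$cycle_index,
                    rest_value = NA_real_, max_contraction_value = NA_real_,
                    amplitude = NA_real_, n_valid_frames = 0L,
                    flagged = FALSE)
  # frame indices are 0-based; R vectors are 1-based
  idx_range <- function(first, last_excl) {
    lo <- max(first, 0L) + 1L
    hi <- min(last_excl, nfr)
    if (lo > hi) integer(0) else lo:hi
  }
  for (i in seq_len(ncyc)) {
    on_idx <- idx_range(aligned$on_first[i], aligned$on_last_excl[i])
    if (is.null(min_valid_frames)) {
      min_valid <- ceiling(length(on_idx) / 2)
    } else min_valid <- min_valid_frames
    n_valid <- sum(!is.na(v[on_idx]))
    res$n_valid_frames[i] <- n_valid
    if (n_valid == 0) {
      res$flagged[i] <- TRUE
      next
    }
    on_vals <- fill_small_gaps(v[on_idx], max_gap)
    res$max_contraction_value[i] <- min(on_vals, na.rm = TRUE)
    if (i == 1) {
      res$rest_value[i] <- 1
    } else {
      off_idx <- idx_range(aligned$off_first[i - 1],
                           aligned$off_last_excl[i - 1])
      k <- length(off_idx)
      tail_idx <- off_idx[seq(k - ceiling(k * rest_fraction) + 1, k)]
      rest_vals <- fill_small_gaps(v[tail_idx], max_gap)
      if (all(is.na(rest_vals))) {
        res$flagged[i] <- TRUE
        next
      }
      res$rest_value[i] <- mean(rest_vals, na.rm = TRUE)
    }
    res$amplitude[i] <- res$rest_value[i] - res$max_contraction_value[i]
    if (n_valid < min_valid) res$flagged[i] <- TRUE
  }
  class(res) <- c("cycle_metrics", class(res))
  res
}

#' Extract periodic epochs from a normalized trace
#'
#' Returns the sub-traces of length `epoch_len_s` starting at the first
#' stimulus onset and every `every_s` thereafter — the sampling used to
#' visualize slow changes over a long protocol (20 s epochs every 2 min by
#' default). The first and last epochs are flagged (`first`/`last`), and a
#' final epoch truncated by the end of the trace is flagged `truncated`.
#'
#' @param norm A `normalized_trace`.
#' @param epoch_len_s Epoch length, seconds (default 20).
#' @param every_s Sampling period, seconds (default 120).
#' @return List of epochs; each has `start_s`, `first`, `last`, `truncated`
#'   and `trace` (the sub-data-frame).
#' @export
epoch_extract <- function(norm, epoch_len_s = 20, every_s = 120) {
  stopifnot(inherits(norm, "normalized_trace"))
  t_end <- max(norm$time_s)
  if (epoch_len_s > t_end + 1e-9)
    stopf("epoch length (%g s) exceeds the trace (%g s)", epoch_len_s, t_end)
  first_on <- which(norm$led_on)[1]
  t0 <- if (is.na(first_on)) 0 else norm$time_s[first_on]
  starts <- seq(t0, t_end, by = every_s)
  starts <- starts[starts < t_end]
  epochs <- lapply(seq_along(starts), function(k) {
    s <- starts[k]
    sel <- norm$time_s >= s & norm$time_s < s + epoch_len_s
    list(start_s = s,
         first = k == 1L,
         last = k == length(starts),
         truncated = s + epoch_len_s > t_end + 1e-9,
         trace = norm[sel, , drop = FALSE])
  })
  epochs
}

#' First-k versus last-k cycle amplitude comparison
#'
#' The per-animal fatigue summary: mean contraction amplitude over the first
#' `k` cycles versus the final `k` complete cycles, their difference
#' (first - last; positive = fatigue) and ratio (last / first).
#'
#' @param cycles A `cycle_metrics` data frame.
#' @param k Number of cycles per end (default 3).
#' @return List with `first_k_amplitude`, `last_k_amplitude`, `difference`,
#'   `ratio`, `k`.
#' @export
fatigue_comparison <- function(cycles, k = 3) {
  stopifnot(inherits(cycles, "cycle_metrics"), k >= 1)
  n <- nrow(cycles)
  if (n < 2 * k)
    stopf("need at least %d complete cycles for a first-%d vs last-%d comparison (have %d)",
          2 * k, k, k, n)
  first_k <- mean(cycles$amplitude[seq_len(k)], na.rm = TRUE)
  last_k <- mean(cycles$amplitude[seq(n - k + 1, n)], na.rm = TRUE)
  list(first_k_amplitude = first_k, last_k_amplitude = last_k,
       difference = first_k - last_k, ratio = last_k / first_k, k = k)
}

#' Average normalized traces across animals
#'
#' Pointwise mean and sample standard deviation (n-1 convention) across
#' animals on the shared frame grid, ignoring missing frames; the per-point
#' number of contributing animals is reported. Traces of unequal length are
#' padded with missing values; `truncate_s` drops everything after that
#' time (used when one group's recording ends early).
#'
#' @param traces List of `normalized_trace` objects sharing one frame rate
#'   and protocol grid.
#' @param truncate_s Optional truncation time, seconds.
#' @return Data frame: `frame`, `time_s`, `mean`, `sd`, `n`.
#' @export
group_average_trace <- function(traces, truncate_s = NULL) {
  stopifnot(is.list(traces), length(traces) >= 1)
  if (length(traces) < 2)
    warnf("fewer than 2 traces: dispersion will be missing")
  lens <- vapply(traces, nrow, integer(1))
  nmax <- max(lens)
  m <- vapply(traces, function(tr) {
    x <- tr$perimeter_norm
    x[!tr$valid] <- NA_real_
    c(x, rep(NA_real_, nmax - length(x)))
  }, numeric(nmax))
  m <- matrix(m, nrow = nmax)
  ref <- traces[[which.max(lens)]]
  out <- data.frame(frame = ref$frame, time_s = ref$time_s,
                    mean = rowMeans(m, na.rm = TRUE),
                    sd = apply(m, 1, stats::sd, na.rm = TRUE),
                    n = rowSums(!is.na(m)))
  out$mean[out$n == 0] <- NA_real_
  if (!is.null(truncate_s)) out <- out[out$time_s <= truncate_s, , drop = FALSE]
  out
}

#' Two-group comparison of per-animal amplitudes
#'
#' Two-sided Student's t-test (equal-variance by default; Welch behind the
#' flag) on per-animal amplitude summaries, plus the box-plot quantities
#' used to display such comparisons: group mean, median, 25-75\% box and
#' 10-90\% whiskers.
#'
#' @param a,b Numeric vectors of per-animal amplitudes (each `n >= 2`).
#' @param var_equal Pooled-variance Student's t (default `TRUE`).
#' @return List (`group_result`): `t_statistic`, `df`, `p_value`, and
#'   `summary`, a data frame with one row per group.
#' @export
two_group_test <- function(a, b, var_equal = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stopf("each group needs at least 2 animals")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # t.test refuses constant data; handle the two degenerate limits
    if (mean(a) == mean(b)) {
      tt <- list(statistic = 0, parameter = length(a) + length(b) - 2,
                 p.value = 1)
    } else {
      tt <- list(statistic = sign(mean(a) - mean(b)) * Inf,
                 parameter = length(a) + length(b) - 2,
                 p.value = .Machine$double.xmin)
    }
  } else {
    ht <- stats::t.test(a, b, var.equal = var_equal)
    tt <- list(statistic = unname(ht$statistic),
               parameter = unname(ht$parameter),
               p.value = max(ht$p.value, .Machine$double.xmin))
  }
  box <- function(x, label) {
    q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
    data.frame(group = label, n = length(x), mean = mean(x),
               whisker_lo = q[1], q25 = q[2], median = q[3], q75 = q[4],
               whisker_hi = q[5])
  }
  structure(list(t_statistic = tt$statistic, df = tt$parameter,
                 p_value = tt$p.value,
                 summary = rbind(box(a, "a"), box(b, "b"))),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("<group_result> t = %.4g, df = %.4g, p = %.4g\n",
              x$t_statistic, x$df, x$p_value))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write per-cycle metrics to CSV
#'
#' @param cycles A `cycle_metrics` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cycles_csv <- function(cycles, path) {
  df <- as.data.frame(cycles)
  df$flagged <- as.integer(df$flagged)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
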