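# build classed track/stimulus traces from raw vectors, for analytic cases
make_track <- function(perimeter, fps = 10, valid = rep(TRUE, length(perimeter))) {
  n <- length(perimeter)
  tr <- data.frame(frame = seq_len(n) - 1L, time_s = (seq_len(n) - 1) / fps,
                   area = NA_real_, perimeter = perimeter,
                   x = 0, y = 0, step_distance = 0, valid = valid)
  tr$perimeter[!valid] <- NA_real_
  class(tr) <- c("track_trace", class(tr))
  tr
}
make_led <- function(on, fps = 10) {
  out <- data.frame(frame = seq_along(on) - 1L,
                    roi_mean = ifelse(on, 200, 10), led_on = on)
  attr(out, "threshold_used") <- 105
  class(out) <- c("stimulus_trace", class(out))
  out
}

test_that("normalization divides by the pre-stimulus window mean", {
  proto <- stimulus_protocol(2, 2, 1, 11)
  on <- protocol_led_state(proto, 110, 10)
  tr <- make_track(rep(80, 110))
  norm <- normalize_trace(tr, make_led(on), fps = 10)
  expect_equal(norm$perimeter_norm, rep(1, 110))
  expect_equal(attr(norm, "baseline_value"), 80)
  expect_equal(attr(norm, "baseline_window"), c(0, 2))

  # baseline window mean is exactly 1 even for a noisy trace
  set.seed(4)
  tr2 <- make_track(rnorm(110, 100, 4))
  norm2 <- normalize_trace(tr2, make_led(on), fps = 10)
  win <- attr(norm2, "baseline_window")
  sel <- norm2$time_s >= win[1] & norm2$time_s < win[2] & norm2$valid
  expect_equal(mean(norm2$perimeter_norm[sel]), 1, tolerance = 1e-12)
})

test_that("normalization removes animal size: scaled traces normalize identically", {
  spec1 <- small_phantom_spec(contraction_fraction = 0.2)
  spec2 <- small_phantom_spec(contraction_fraction = 0.2,
                              body_axes = spec1$body_axes * 1.5)
  t1 <- truth_traces(spec1); t2 <- truth_traces(spec2)
  n1 <- normalize_trace(t1$track, t1$led, spec1$fps)
  n2 <- normalize_trace(t2$track, t2$led, spec2$fps)
  expect_equal(n1$perimeter_norm, n2$perimeter_norm, tolerance = 1e-12)
})

test_that("steady-state normalized perimeter approaches the analytic contraction ratio", {
  spec <- small_phantom_spec(contraction_fraction = 0.2, response_tau = 0.05,
                             protocol = stimulus_protocol(3, 4, 2, 21))
  tt <- truth_traces(spec)
  norm <- normalize_trace(tt$track, tt$led, spec$fps)
  ratio_true <- ellipse_perimeter(spec$body_axes[1] * 0.8, spec$body_axes[2]) /
    ellipse_perimeter(spec$body_axes[1], spec$body_axes[2])
  late_on <- norm$led_on & (norm$time_s - spec$protocol$delay_s) %% 6 > 3
  expect_lt(abs(mean(norm$perimeter_norm[late_on]) / ratio_true - 1), 0.05)
})

test_that("normalization preconditions are enforced", {
  on <- c(rep(FALSE, 20), rep(TRUE, 10))
  tr <- make_track(rep(50, 30), valid = c(rep(FALSE, 20), rep(TRUE, 10)))
  expect_error(normalize_trace(tr, make_led(on), 10), "baseline")
  expect_error(normalize_trace(make_track(rep(1, 30)),
                               make_led(rep(FALSE, 30)), 10), "no on-frames")
})

test_that("cycle metrics recover a square wave exactly", {
  proto <- stimulus_protocol(2, 2, 2, 22)
  n <- 220
  on <- protocol_led_state(proto, n, 10)
  wave <- ifelse(on, 0.8, 1.0) * 100
  norm <- normalize_trace(make_track(wave), make_led(on), 10)
  al <- align_status(make_led(on), build_cycle_grid(proto), 10)
  cm <- cycle_metrics(norm, al)
  expect_equal(nrow(cm), 5)
  expect_equal(cm$rest_value, rep(1, 5))
  expect_equal(cm$max_contraction_value, rep(0.8, 5))
  expect_equal(cm$amplitude, rep(0.2, 5))
  expect_false(any(cm$flagged))

  # flat trace: zero amplitude everywhere
  flat <- normalize_trace(make_track(rep(70, n)), make_led(on), 10)
  expect_equal(cycle_metrics(flat, al)$amplitude, rep(0, 5))
})

test_that("slower response dynamics reduce the measured amplitude monotonically", {
  amp_for_tau <- function(tau) {
    spec <- small_phantom_spec(contraction_fraction = 0.3, response_tau = tau)
    tt <- truth_traces(spec)
    norm <- normalize_trace(tt$track, tt$led, spec$fps)
    al <- align_status(tt$led, build_cycle_grid(spec$protocol), spec$fps)
    mean(cycle_metrics(norm, al)$amplitude, na.rm = TRUE)
  }
  amps <- vapply(c(0.05, 0.5, 2), amp_for_tau, numeric(1))
  expect_true(all(diff(amps) < 0))
  full <- 1 - ellipse_perimeter(14 * 0.7, 6) / ellipse_perimeter(14, 6)
  expect_lt(abs(amps[1] / full - 1), 0.05)  # fast tau reaches the programmed drop
  expect_lt(amps[3], full * 0.8)            # slow tau cannot complete it
})

test_that("cycles with missing on-window data are flagged, short gaps interpolated", {
  proto <- stimulus_protocol(2, 2, 2, 18)
  n <- 180
  on <- protocol_led_state(proto, n, 10)
  wave <- ifelse(on, 80, 100)
  valid <- rep(TRUE, n)
  valid[21:40] <- FALSE   # kill cycle 1's entire on-window
  valid[62:63] <- FALSE   # 2-frame gap inside cycle 2's on-window
  tr <- make_track(wave, valid = valid)
  norm <- normalize_trace(tr, make_led(on), 10)
  al <- align_status(make_led(on), build_cycle_grid(proto), 10)
  cm <- cycle_metrics(norm, al, max_gap = 3)
  expect_true(cm$flagged[1])
  expect_true(is.na(cm$amplitude[1]))
  expect_false(cm$flagged[2])
  expect_equal(cm$amplitude[2], 0.2)
})

test_that("epoch extraction samples the protocol as documented", {
  spec <- phantom_spec()   # full default protocol, 1210 s
  tt <- truth_traces(spec)
  norm <- normalize_trace(tt$track, tt$led, spec$fps)
  ep <- epoch_extract(norm)            # 20 s epochs every 120 s
  expect_equal(length(ep), 10)
  expect_true(ep[[1]]$first && !ep[[1]]$last)
  expect_true(ep[[10]]$last && !ep[[10]]$first)
  expect_equal(ep[[1]]$start_s, 10)
  expect_equal(ep[[2]]$start_s, 130)
  expect_equal(nrow(ep[[1]]$trace), 200)
  expect_false(any(vapply(ep, `[[`, logical(1), "truncated")))

  expect_error(epoch_extract(norm, epoch_len_s = 1e5), "exceeds")
  single <- epoch_extract(norm, epoch_len_s = 20, every_s = 1210)
  expect_equal(length(single), 1)
})

test_that("fatigue comparison computes first-k and last-k means", {
  amp <- seq(0.2, 0.1, length.out = 400)
  cm <- data.frame(cycle_index = 1:400, rest_value = 1,
                   max_contraction_value = 1 - amp, amplitude = amp,
                   n_valid_frames = 20L, flagged = FALSE)
  class(cm) <- c("cycle_metrics", class(cm))
  fc <- fatigue_comparison(cm, 3)
  expect_equal(fc$first_k_amplitude, mean(amp[1:3]))
  expect_equal(fc$last_k_amplitude, mean(amp[398:400]))
  expect_equal(fc$difference, mean(amp[1:3]) - mean(amp[398:400]))

  const <- cm; const$amplitude <- rep(0.15, 400)
  fc2 <- fatigue_comparison(const, 3)
  expect_equal(fc2$difference, 0)
  expect_equal(fc2$ratio, 1)

  expect_error(fatigue_comparison(cm[1:5, ], 3), "at least 6")
})

test_that("group averaging uses the n-1 convention and respects missing data", {
  proto <- stimulus_protocol(1, 2, 1, 7)
  on <- protocol_led_state(proto, 70, 10)
  mk <- function(level, valid = rep(TRUE, 70)) {
    normalize_trace(make_track(rep(level, 70), valid = valid),
                    make_led(on), 10)
  }
  a <- mk(90); b <- mk(110)
  # equal traces: mean equals either, sd 0
  g0 <- group_average_trace(list(a, a))
  expect_equal(g0$mean, a$perimeter_norm)
  expect_equal(g0$sd, rep(0, 70))
  # traces 0.9 / 1.1 of their own baselines are both constant 1; scale one
  a2 <- a; a2$perimeter_norm <- rep(0.9, 70)
  b2 <- b; b2$perimeter_norm <- rep(1.1, 70)
  g <- group_average_trace(list(a2, b2))
  expect_equal(g$mean, rep(1, 70))
  expect_equal(g$sd, rep(sd(c(0.9, 1.1)), 70))
  expect_equal(g$sd[1], 0.1414214, tolerance = 1e-6)
  # a missing frame drops that timepoint's n
  v <- rep(TRUE, 70); v[30] <- FALSE
  g2 <- group_average_trace(list(mk(90, v), b2))
  expect_equal(g2$n[30], 1)
  expect_equal(g2$n[29], 2)
  # truncation
  g3 <- group_average_trace(list(a2, b2), truncate_s = 3)
  expect_equal(max(g3$time_s), 3)
  # permutation invariance
  g4 <- group_average_trace(list(b2, a2))
  expect_equal(g4$mean, g$mean)
  expect_equal(g4$sd, g$sd)
  expect_warning(group_average_trace(list(a2)), "fewer than 2")
})

test_that("two-group test matches the pooled-variance formula", {
  a <- c(1, 2, 3); b <- c(11, 12, 13)
  res <- two_group_test(a, b)
  sp2 <- ((2) * var(a) + (2) * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$t_statistic, t_hand)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * pt(abs(t_hand), 4, lower.tail = FALSE))

  same <- two_group_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  # degenerate zero-variance groups
  null_case <- two_group_test(c(2, 2), c(2, 2))
  expect_equal(null_case$p_value, 1)
  shift <- two_group_test(c(2, 2), c(5, 5))
  expect_gt(shift$p_value, 0)
  expect_lt(shift$p_value, 1e-100)

  expect_equal(res$summary$median, c(2, 12))
  expect_equal(res$summary$n, c(3, 3))
  expect_error(two_group_test(1, c(1, 2)), "at least 2")
})

test_that("all metrics are invariant to rescaling the raw perimeter", {
  spec <- small_phantom_spec(contraction_fraction = 0.25)
  tt <- truth_traces(spec, jitter_sd = 0.3)
  al <- align_status(tt$led, build_cycle_grid(spec$protocol), spec$fps)
  run <- function(track) {
    norm <- normalize_trace(track, tt$led, spec$fps)
    cycle_metrics(norm, al)
  }
  base <- run(tt$track)
  scaled <- tt$track
  scaled$perimeter <- scaled$perimeter * 3.7
  expect_equal(run(scaled), base, tolerance = 1e-12)
})
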