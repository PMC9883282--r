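test_that("flow signal is quiet for static cines and tracks motion", {
  frames <- replicate(10, matrix(100, 32, 32), simplify = FALSE)
  cine <- structure(list(frames = frames, times = (0:9) / 10,
                         pixel_pitch = 0.1, frame_rate = 10),
                    class = "cine_sequence")
  fs <- compute_flow_signal(cine)
  expect_true(all(fs$displacement == 0))
  expect_error(compute_flow_signal(
    structure(list(frames = frames[1], times = 0), class = "cine_sequence")),
    "at least 2")

  fx <- fx_noisy_ramp()
  fs <- compute_flow_signal(fx$acq$cine)
  expect_equal(nrow(fs), length(fx$acq$cine$frames))
  # peaks of the position signal land within one frame of the true events
  ev <- detect_events(fs$position, fs$frame_time)
  expect_lt(max(abs(ev[c(1, 2, 3, 5)] - fx$acq$events[c(1, 2, 3, 5)])),
            1 / fx$acq$params$frame_rate + 1e-9)
})

test_that("reversing the frame order mirrors the displacement signal", {
  fx <- fx_noisy_ramp()
  cine <- fx$acq$cine
  rev_cine <- structure(list(frames = rev(cine$frames), times = cine$times,
                             pixel_pitch = cine$pixel_pitch,
                             frame_rate = cine$frame_rate),
                        class = "cine_sequence")
  d_fwd <- compute_flow_signal(cine)$displacement
  d_rev <- compute_flow_signal(rev_cine)$displacement
  n <- length(d_fwd)
  # displacement between frames k-1,k maps to the mirrored pair
  expect_equal(d_rev[-1], rev(d_fwd[-1]))
})

test_that("detect_events finds the five acquisition events", {
  fx <- fx_noisy_ramp()
  ev <- detect_events(fx$acq$force$force_N, fx$acq$force$t_s)
  expect_length(ev, 5L)
  expect_true(all(diff(ev) > 0))
  true_ev <- fx$acq$events + fx$acq$params$sync_offset
  expect_lt(max(abs(ev[c(1, 2, 3, 5)] - true_ev[c(1, 2, 3, 5)])), 0.1)
  expect_lt(abs(ev[4] - true_ev[4]), 0.3)  # smoothing shifts the sweep top

  # too few peaks errors with the count
  t <- seq(0, 10, 0.02)
  flat <- pmax(0, 3 * (1 - abs(t - 5) / 0.2))
  expect_error(detect_events(flat, t), "0 pre-sweep")

  # two candidate peaks within the minimum separation merge into one
  two <- function(t) pmax(0, 4 * (1 - abs(t - 2) / 0.15)) +
    pmax(0, 5 * (1 - abs(t - 2.3) / 0.15))
  sig <- two(t) +
    pmax(0, 4 * (1 - abs(t - 3.5) / 0.15)) +
    pmax(0, 4 * (1 - abs(t - 4.7) / 0.15)) +
    ifelse(t >= 6 & t <= 8, 7 * (t - 6) / 2, 0) +
    pmax(0, 4 * (1 - abs(t - 9) / 0.15))
  ev <- detect_events(sig, t)
  expect_length(ev, 5L)
  # the merged double-spike kept the taller candidate
  expect_equal(ev[1], 2.3, tolerance = 0.05)
})

test_that("align_events follows the first/last least-squares rule", {
  ev <- c(2, 3.5, 5, 15, 17.5)
  id <- align_events(ev, ev)
  expect_equal(id$time_offset, 0)
  expect_equal(id$alignment_residual, 0)
  expect_true(id$valid)

  sh <- align_events(ev + 1.3, ev)
  expect_equal(sh$time_offset, 1.3)
  expect_equal(sh$alignment_residual, 0, tolerance = 1e-12)

  # middle events off by +0.3, -0.3, +0.2 -> residual 0.8 > 0.7
  pert <- ev; pert[2:4] <- pert[2:4] + c(0.3, -0.3, 0.2)
  bad <- align_events(pert, ev)
  expect_equal(bad$alignment_residual, 0.8)
  expect_false(bad$valid)

  # translation equivariance of the residual
  set.seed(1)
  for (i in 1:20) {
    a <- sort(runif(5, 0, 20)); b <- sort(runif(5, 0, 20))
    delta <- runif(1, -5, 5)
    expect_equal(align_events(a + delta, b + delta)$alignment_residual,
                 align_events(a, b)$alignment_residual, tolerance = 1e-9)
  }
})

test_that("assign_force interpolates and flags out-of-span frames", {
  cine <- structure(list(times = c(0, 1, 2, 3), frames = vector("list", 4)),
                    class = "cine_sequence")
  trace <- data.frame(t_s = c(0.5, 1.5, 2.5), force_N = 4)
  s <- assign_force(cine, trace, 0)
  expect_equal(s$force_N[s$in_span], c(4, 4))
  expect_true(all(is.na(s$force_N[!s$in_span])))
  expect_error(assign_force(cine, data.frame(t_s = 100:101, force_N = 0), 0),
               "overlap")
})

test_that("offset recovery holds across the spec's offset grid", {
  fx <- fx_noisy_ramp()  # offset +0.5 case
  expect_equal(attr(fx$sync, "time_offset"), 0.5,
               tolerance = 1 / fx$acq$params$frame_rate / 0.5)
  expect_true(attr(fx$sync, "valid"))
  # per-frame force against truth (away from the ramp-end force step)
  err <- abs(fx$sync$force_N - fx$acq$truth$applied_force_N)
  step <- fx$acq$truth$t_s < 14.9 | fx$acq$truth$t_s > 15.1
  expect_lt(max(err[step & is.finite(err)]), 0.3)

  for (off in c(-2, 2)) {
    pp <- phantom_params(speckle_level = 0.1, sync_offset = off,
                         rng_seed = 5L)
    acq <- generate_sequence(pp)
    s <- synchronize(acq$cine, acq$force)
    expect_lt(abs(attr(s, "time_offset") - off), 1 / pp$frame_rate)
  }
})
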