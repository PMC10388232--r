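test_that("trim keeps the half-open window and re-bases time", {
  s <- make_signal(seq_len(100), rate = 10)       # 10 s at 10 Hz
  out <- trim_signal(s, 2, 8)
  expect_equal(length(out), 60)
  expect_equal(out$time[1], 0)
  expect_equal(out$force, s$force[21:80])
  full <- trim_signal(s, 0, 10)
  expect_equal(full$force, s$force)
  expect_error(trim_signal(s, 5, 5), "keep_start")
  expect_error(trim_signal(s, 6, 2), "keep_start")
})

test_that("short gaps are linearly interpolated", {
  s <- make_signal(c(100, NA, 200))
  out <- remove_gaps(s, max_gap = 1)
  expect_equal(out$force, c(100, 150, 200))
  expect_false(any(out$gap))
})

test_that("remove_gaps is the identity on gap-free signals", {
  s <- make_signal(c(1, 2, 3, 4))
  expect_identical(remove_gaps(s), s)
})

test_that("long gaps split the signal and the longest stretch survives", {
  # 300 valid samples, a 50-sample gap, 200 valid samples
  f <- c(rnorm(300, 500, 10), rep(NA, 50), rnorm(200, 300, 10))
  s <- make_signal(f)
  out <- remove_gaps(s, max_gap = 5)
  expect_equal(length(out), 300)
  expect_equal(out$force, f[1:300])
  expect_true(all(is.finite(out$force)))
  expect_lte(length(out), length(s))
  expect_error(remove_gaps(make_signal(c(NA, NA, NA))), "entirely gaps")
})

test_that("a flat-zero signal contains no steps", {
  s <- make_signal(numeric(500))
  expect_length(detect_steps(s), 0)
})

test_that("contacts are recovered at their exact sample windows", {
  fx <- make_contact_signal(list(c(2, 0.8, 500)))
  steps <- detect_steps(fx$signal)
  expect_length(steps, 1)
  expect_lte(abs(steps[[1]]$start_index - fx$windows[1, 1]), 2)
  expect_lte(abs(steps[[1]]$end_index - fx$windows[1, 2]), 2)
  expect_equal(steps[[1]]$peak_force, 500)
  expect_equal(steps[[1]]$duration, 0.8, tolerance = 0.03)
})

test_that("multiple contacts come back disjoint and in time order", {
  fx <- make_contact_signal(list(c(1, 0.8, 500), c(2.8, 0.7, 450)))
  steps <- detect_steps(fx$signal)
  expect_length(steps, 2)
  expect_lt(steps[[1]]$end_index, steps[[2]]$start_index)
  for (i in 1:2) {
    expect_lte(abs(steps[[i]]$start_index - fx$windows[i, 1]), 2)
    expect_lte(abs(steps[[i]]$end_index - fx$windows[i, 2]), 2)
  }
})

test_that("contacts outside the duration band are excluded but reported", {
  # a 0.1 s double-contact blip plus a proper 0.8 s step
  fx <- make_contact_signal(list(c(1, 0.1, 600), c(3, 0.8, 500)))
  steps <- detect_steps(fx$signal)
  expect_length(steps, 1)
  expect_equal(steps[[1]]$start_index, fx$windows[2, 1])
  rejected <- attr(steps, "rejected")
  expect_length(rejected, 1)
  expect_equal(rejected[[1]]$duration, 0.1, tolerance = 0.03)
})

test_that("segmentation is invariant to uniform force rescaling", {
  fx <- make_contact_signal(list(c(1, 0.8, 500), c(3, 0.6, 420)))
  base <- detect_steps(fx$signal)
  scaled <- fx$signal
  scaled$force <- scaled$force * 12.5
  steps <- detect_steps(scaled)
  expect_equal(sapply(steps, `[[`, "start_index"),
               sapply(base, `[[`, "start_index"))
  expect_equal(sapply(steps, `[[`, "end_index"),
               sapply(base, `[[`, "end_index"))
})

test_that("step detection demands a gap-free signal and a sane threshold", {
  s <- make_signal(c(1, NA, 3))
  expect_error(detect_steps(s), "gap-free")
  expect_error(detect_steps(make_signal(1:10), threshold_fraction = 1.5),
               "threshold_fraction")
})

test_that("amplitude normalization uses body weight, else the peak", {
  fx <- make_contact_signal(list(c(1, 0.8, 800)))
  seg <- detect_steps(fx$signal)[[1]]
  bw <- normalize_amplitude(seg, body_weight = 700)
  expect_equal(max(bw), 800 / 700)
  pk <- normalize_amplitude(seg)
  expect_equal(max(pk), 1)
  expect_error(normalize_amplitude(seg, body_weight = -1), "body_weight")
  zero <- manual_segment(make_signal(numeric(50)), 10, 20)
  expect_error(normalize_amplitude(zero), "peak")
})

test_that("moving-average smoothing matches the shrinking-window contract", {
  s <- make_signal(c(0, 3, 0))
  expect_equal(smooth_signal(s, 3)$force, c(1.5, 1, 1.5))
  expect_identical(smooth_signal(s, 1), s)
  const <- make_signal(rep(42, 50))
  expect_equal(smooth_signal(const, 7)$force, rep(42, 50))
  expect_error(smooth_signal(s, 2), "odd")
})

test_that("smoothing never leaves the input range", {
  set.seed(11)
  f <- rnorm(300, 100, 50)
  s <- make_signal(f)
  for (w in c(3, 9, 21)) {
    sm <- smooth_signal(s, w)$force
    expect_gte(min(sm), min(f))
    expect_lte(max(sm), max(f))
  }
})
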