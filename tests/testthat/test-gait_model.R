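test_that("the healthy curve passes through its control points", {
  p <- gait_params(body_weight = 700)
  f <- healthy_step(p)
  expect_length(f, round(p$stance_duration * p$sample_rate))
  expect_equal(f[1], 0)
  expect_equal(f[length(f)], 0)
  expect_equal(max(f), 1.15 * 700, tolerance = 0.02)
  s <- seq(0, 1, length.out = length(f))
  expect_equal(f[which.min(abs(s - p$valley_time_frac))], 0.75 * 700,
               tolerance = 0.02)
  # the two local maxima sit on the configured peak fractions
  expect_equal(s[which.max(f)], p$peak1_time_frac, tolerance = 0.01)
})

test_that("the healthy curve is linear in body weight", {
  f1 <- healthy_step(gait_params(body_weight = 700))
  f2 <- healthy_step(gait_params(body_weight = 1400))
  expect_equal(f2, 2 * f1)
})

test_that("parameter validation rejects inconsistent profiles", {
  expect_error(gait_params(peak1_time_frac = 0.6, valley_time_frac = 0.5))
  expect_error(gait_params(body_weight = -10))
  expect_error(impairment_profile(severity = 1.5))
  expect_error(impairment_profile(mid_stance = -0.1))
})

test_that("zero impairment reproduces the healthy curve exactly", {
  p <- gait_params()
  expect_identical(impaired_step(p, impairment_profile(severity = 0)),
                   healthy_step(p))
})

test_that("impairment severity raises the DTW distance to the reference monotonically", {
  p <- gait_params(noise_sd = 0)
  ref <- healthy_step(p)
  d <- vapply(seq(0, 1, by = 0.1), function(sev) {
    dtw_distance(ref, impaired_step(p, impairment_profile(severity = sev)))
  }, numeric(1))
  expect_equal(d[1], 0)
  expect_true(all(diff(d) >= 0))
})

test_that("attenuating push-off alone suppresses the second peak", {
  p <- gait_params()
  f <- impaired_step(p, impairment_profile(push_off = 1))
  s <- seq(0, 1, length.out = length(f))
  second <- max(f[s > 0.6])
  first <- max(f[s < 0.4])
  expect_lt(second, first)
  healthy <- healthy_step(p)
  s_half <- s > 0.6
  expect_lt(second, max(healthy[s_half]))   # push-off visibly weakened
})

test_that("the severity scalar drives all three phase attenuations", {
  imp <- impairment_profile(severity = 0.4)
  expect_equal(unlist(imp[c("loading_response", "mid_stance", "push_off")]),
               c(loading_response = 0.4, mid_stance = 0.4, push_off = 0.4))
})

test_that("a noiseless trial round-trips through step detection", {
  p <- gait_params(noise_sd = 0)
  trial <- synth_trial(p, n_steps = 10)
  steps <- detect_steps(trial$signal)
  expect_length(steps, 10)
  det <- t(vapply(steps, function(s) c(s$start_index, s$end_index),
                  numeric(2)))
  expect_true(all(abs(det - trial$true_step_windows) <= 2))
})

test_that("simulated samples respect plate resolution and saturation", {
  trial <- synth_trial(gait_params(seed = 5), n_steps = 6)
  f <- trial$signal$force
  expect_true(all(abs(f / 0.3 - round(f / 0.3)) < 1e-9))
  expect_lte(max(f), 3500)
  expect_gte(min(f), -900)
  w <- trial$true_step_windows
  expect_true(all(w[, 1] < w[, 2]))
  expect_true(all(w[-1, 1] >= w[-nrow(w), 2]))      # disjoint, ordered
  expect_lte(max(w), length(trial$signal))
})

test_that("trials are bit-identical for a fixed seed", {
  p <- gait_params(seed = 99)
  t1 <- synth_trial(p, n_steps = 4)
  t2 <- synth_trial(p, n_steps = 4)
  expect_identical(t1$signal$force, t2$signal$force)
  pair1 <- synth_subject_pair(severity_before = 0.8, severity_after = 0.05,
                              n_steps = 3, seed = 7)
  pair2 <- synth_subject_pair(severity_before = 0.8, severity_after = 0.05,
                              n_steps = 3, seed = 7)
  expect_identical(pair1$before$signal$force, pair2$before$signal$force)
  expect_identical(pair1$after$signal$force, pair2$after$signal$force)
  # different sub-streams for the two conditions
  expect_false(pair1$before$seed == pair1$after$seed)
})

test_that("default condition stance lengths mirror the reference recordings", {
  pair <- synth_subject_pair(severity_before = 0.8, severity_after = 0.05,
                             n_steps = 1, seed = 1)
  expect_equal(length(healthy_step(gait_params())), 1025)
  expect_lte(unname(diff(pair$before$true_step_windows[1, ])), 1180)
  expect_equal(round(pair$before$params$stance_duration *
                       pair$before$params$sample_rate), 1180)
  expect_equal(round(pair$after$params$stance_duration *
                       pair$after$params$sample_rate), 1010)
})

test_that("identically generated noiseless steps are DTW-indistinguishable", {
  p <- gait_params(noise_sd = 0)
  trial <- synth_trial(p, n_steps = 3)
  steps <- lapply(detect_steps(trial$signal), normalize_amplitude,
                  body_weight = p$body_weight)
  expect_equal(dtw_distance(steps[[1]], steps[[2]]), 0)
  expect_equal(condition_distance(steps[[1]], steps[2:3]), 0)
})

test_that("quantization perturbs a noiseless step by at most one resolution step per sample", {
  p_exact <- gait_params(noise_sd = 0, quantization_step = 0)
  p_quant <- gait_params(noise_sd = 0)                 # 0.3 N resolution
  t_exact <- synth_trial(p_exact, n_steps = 1)
  t_quant <- synth_trial(p_quant, n_steps = 1)
  w <- t_exact$true_step_windows[1, ]
  expect_equal(t_quant$true_step_windows, t_exact$true_step_windows)
  s_exact <- t_exact$signal$force[(w[1] + 1):w[2]]
  s_quant <- t_quant$signal$force[(w[1] + 1):w[2]]
  n <- length(s_exact)
  expect_lte(dtw_distance(s_exact, s_quant),
             n * p_quant$quantization_step)
})
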