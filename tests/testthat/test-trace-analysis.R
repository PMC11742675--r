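test_that("SNR estimation separates clean steps from pure noise", {
  clean <- make_staircase(c(10, 0), len_per_level = 30)
  expect_equal(estimate_snr(clean), 1e6) # zero noise -> capped

  set.seed(4)
  flat <- tibble::tibble(time_s = seq(0, 29.9, by = 0.1),
                         intensity = rnorm(300))
  expect_lt(estimate_snr(flat), 1)
  expect_equal(estimate_snr(tibble::tibble(time_s = 0:49 / 10,
                                           intensity = rep(3, 50))), 0)

  # single fluorophore at unit intensity 5, noise 1: SNR concentrates
  # around the generator's step SNR of 5
  set.seed(8)
  tm <- trace_model(unit_intensity = 5, noise_sd = 1)
  snrs <- replicate(100, estimate_snr(simulate_trace(1, tm)))
  expect_gt(mean(snrs), 3.5)
  expect_lt(mean(snrs), 6.5)
})

test_that("step detection is exact on noiseless staircases", {
  for (k in 1:5) {
    levels <- seq(k, 0) * 10
    tr <- make_staircase(levels, len_per_level = 20)
    fit <- detect_steps(tr)
    expect_identical(fit$n_steps, as.integer(k))
    expect_equal(fit$level_values, levels)
    expect_length(fit$change_points, k)
  }
  flat <- make_staircase(5, len_per_level = 100)
  expect_identical(detect_steps(flat)$n_steps, 0L)
  expect_error(detect_steps(make_staircase(c(1, 0), len_per_level = 10)),
               "too short")
})

test_that("blink-like returns to a visited level are not double-counted", {
  # down (bleach-like), up (blink on), down again to the same level,
  # then a new minimum: two true bleaching steps
  tr <- make_staircase(c(20, 10, 20, 10, 0), len_per_level = 25)
  fit <- detect_steps(tr)
  expect_identical(fit$n_steps, 2L)
  expect_length(fit$level_values, 5L)
})

test_that("step counts are invariant to affine intensity rescaling", {
  set.seed(12)
  tm <- trace_model(unit_intensity = 5, noise_sd = 1)
  for (k in c(1, 3)) {
    tr <- simulate_trace(k, tm)
    base <- detect_steps(tr)$n_steps
    tr2 <- dplyr::mutate(tr, intensity = 3.7 * intensity + 120)
    expect_identical(detect_steps(tr2)$n_steps, base)
  }
})

test_that("noisy step recovery matches generator ground truth", {
  set.seed(55)
  tm <- trace_model(unit_intensity = 5, noise_sd = 1)
  ks <- rep(1:4, 15)
  rec <- vapply(ks, function(k) {
    detect_steps(simulate_trace(k, tm))$n_steps == k
  }, logical(1))
  expect_gt(mean(rec), 0.85)
})

test_that("polarization-state counting clusters fixed dipoles", {
  expect_identical(count_polarization_states(rep(42, 30)), 1L)
  two <- c(rnorm(40, 30, 0.001), rnorm(40, 120, 0.001))
  expect_identical(count_polarization_states(two), 2L)
  expect_error(count_polarization_states(numeric(0)), "No polarization")
  expect_error(count_polarization_states(rep(1, 5)), ">= 15")

  # wrap-around: angles near 0 and near 180 are the same state
  wrap <- c(rep(1, 20), rep(179, 20))
  expect_identical(count_polarization_states(wrap), 1L)
})

test_that("tetramer polarization counts undercount at coarse tolerance", {
  # at the 15 degree default, chance coincidences of projected dipole
  # angles merge states: the modal count for k = 4 is 3 (frozen from a
  # Monte-Carlo of uniform angle geometry), never above 4
  set.seed(61)
  cnt <- replicate(200, count_polarization_states(
    simulate_polarization_trace(4, 200, angle_noise_deg = 3)))
  expect_true(all(cnt <= 4))
  expect_identical(unname(which.max(tabulate(cnt, 4))), 3L)

  # a finer tolerance (and matching angular noise) recovers the truth
  set.seed(62)
  cnt5 <- replicate(200, count_polarization_states(
    simulate_polarization_trace(4, 200, angle_noise_deg = 1),
    tolerance_deg = 5))
  expect_identical(unname(which.max(tabulate(cnt5, 4))), 4L)
})

test_that("histograms collect accepted counts and exclude the rest", {
  h <- build_step_histogram(c(1, 1, 2, 3))
  expect_equal(h$k, 1:3)
  expect_equal(h$n, c(2, 1, 1))
  expect_equal(attr(h, "n_total"), 4)

  res <- tibble::tibble(particle_id = 1:4,
                        n_steps = c(2L, 0L, 3L, 5L),
                        accepted = c(TRUE, TRUE, FALSE, TRUE))
  h2 <- build_step_histogram(res)
  expect_equal(sum(h2$n), 2) # one zero-step excluded, one rejected
  expect_equal(attr(h2, "n_zero"), 1)

  all_rej <- tibble::tibble(particle_id = 1, n_steps = 2L,
                            accepted = FALSE)
  expect_error(build_step_histogram(all_rej), "No accepted")

  expect_lte(sum(build_step_histogram(c(1, 2, 0, 0))$n), 4)
})

test_that("analyze_traces aggregates per-particle results", {
  ds <- simulate_photobleaching_dataset(15, 4, 0.4, seed = 77)
  res <- analyze_traces(ds)
  expect_equal(nrow(res), 15)
  expect_true(all(is.na(res$snr[!ds$visible])))
  expect_true(all(!res$accepted[!ds$visible]))
  h <- build_step_histogram(res)
  expect_lte(attr(h, "n_total"), sum(ds$visible))
})
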