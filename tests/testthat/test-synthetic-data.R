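test_that("label counts follow the binomial mixing model", {
  expect_true(all(sample_label_counts(50, m = 4, p = 1) == 4))
  expect_true(all(sample_label_counts(50, m = 4, p = 0) == 0))

  n <- 1e5
  ks <- sample_label_counts(n, m = 4, p = 0.25, seed = 42)
  se <- sqrt(4 * 0.25 * 0.75 / n)
  expect_lt(abs(mean(ks) - 1.0), 3 * se)

  # goodness of fit of the empirical histogram against the exact pmf
  obs <- tabulate(ks + 1L, nbins = 5)
  gof <- suppressWarnings(
    stats::chisq.test(obs, p = dbinom(0:4, 4, 0.25)))
  expect_gt(gof$p.value, 0.01)

  expect_identical(sample_label_counts(100, 4, 0.25, seed = 7),
                   sample_label_counts(100, 4, 0.25, seed = 7))
  expect_error(sample_label_counts(10, 4, 1.5), "p")
  expect_error(sample_label_counts(10, 0, 0.5), "m")
})

test_that("zero-truncated draws are visible and reproducible", {
  ks <- sample_label_counts(500, m = 4, p = 0.25, seed = 3,
                            visible_only = TRUE)
  expect_length(ks, 500)
  expect_true(all(ks >= 1))
  expect_error(sample_label_counts(10, 4, 0, visible_only = TRUE),
               "visible")
})

test_that("noiseless traces are exact staircases ending at background", {
  for (k in 1:4) {
    tr <- simulate_trace(k, trace_model(noise_sd = 0), seed = 100 + k)
    drops <- which(diff(tr$intensity) < 0)
    expect_identical(length(drops), as.integer(k))
    expect_equal(tail(tr$intensity, 1), 0)
    # each drop is an integer multiple of one fluorophore's intensity
    expect_true(all(abs(diff(tr$intensity)[drops] %% 10) < 1e-12 |
                      abs(diff(tr$intensity)[drops] %% 10 - 10) < 1e-12))
  }
  tr0 <- simulate_trace(0, trace_model(noise_sd = 0, background = 2))
  expect_true(all(tr0$intensity == 2))
  expect_error(simulate_trace(1, trace_model(frame_rate_hz = -1)),
               "frame_rate")
})

test_that("trace generation is bit-reproducible under a fixed seed", {
  a <- simulate_trace(3, trace_model(), seed = 5)
  b <- simulate_trace(3, trace_model(), seed = 5)
  expect_identical(a$intensity, b$intensity)
  ds1 <- simulate_photobleaching_dataset(20, 4, 0.25, seed = 9)
  ds2 <- simulate_photobleaching_dataset(20, 4, 0.25, seed = 9)
  expect_identical(ds1$true_k, ds2$true_k)
  expect_identical(ds1$trace[[which(ds1$visible)[1]]]$intensity,
                   ds2$trace[[which(ds2$visible)[1]]]$intensity)
  expect_true(all(ds1$visible == (ds1$true_k > 0)))
})

test_that("blinking produces recoverable upward transitions", {
  tm <- trace_model(noise_sd = 0, bleach_rate_per_s = 0.005,
                    blink_on_off_rates_per_s = c(2, 0.05),
                    duration_s = 120)
  tr <- simulate_trace(2, tm, seed = 21)
  expect_true(any(diff(tr$intensity) > 0)) # at least one blink-on
})

test_that("polarization angles are uniform on [0, 180)", {
  expect_length(sample_polarization_states(0), 0)
  a1 <- sample_polarization_states(1, seed = 2)
  expect_true(a1 >= 0 && a1 < 180)
  expect_error(sample_polarization_states(-1), "k_labels")

  # pairwise minimum separation distribution matches a brute-force
  # Monte-Carlo of uniform angles under the circular metric
  min_sep <- function(a) {
    d <- abs(outer(a, a, "-")) %% 180
    d <- pmin(d, 180 - d)
    min(d[upper.tri(d)])
  }
  set.seed(31)
  pkg <- replicate(3000, min_sep(sample_polarization_states(4)))
  set.seed(32)
  oracle <- replicate(3000, min_sep(runif(4, 0, 180)))
  ks <- suppressWarnings(stats::ks.test(pkg, oracle))
  expect_gt(ks$p.value, 0.01)
})

test_that("noiseless CODEX curves match the closed form exactly", {
  tt <- seq(0, 5, length.out = 11)
  cv <- simulate_codex_curve(3, 1.3, tt)
  expect_equal(cv$signal, codex_signal(tt, 3, 1.3), tolerance = 1e-12)
  cv1 <- simulate_codex_curve(1, 2, tt)
  expect_true(all(cv1$signal == 1))
  expect_identical(simulate_codex_curve(4, 1, tt, 0.02, seed = 1)$signal,
                   simulate_codex_curve(4, 1, tt, 0.02, seed = 1)$signal)
  expect_error(simulate_codex_curve(4, 1, c(-1, 0)), "Mixing")
})

test_that("shift-table generator localizes perturbations to segments", {
  st0 <- simulate_shift_tables()
  expect_identical(st0$state_a, st0$state_b)

  seg <- data.frame(start = 52, end = 66, d_ca = 1)
  st <- simulate_shift_tables(segments = seg)
  pr <- csp_profile(st$state_a, st$state_b)
  inside <- pr$residue_number >= 52 & pr$residue_number <= 66
  expect_equal(pr$average_csp_ppm[inside], rep(0.5, sum(inside)))
  expect_true(all(pr$average_csp_ppm[!inside] == 0))

  # offsets built to hit CSP = 1.0 ppm are flagged dissimilar at 0.7
  seg2 <- data.frame(start = 52, end = 66, d_ca = 2)
  st2 <- simulate_shift_tables(segments = seg2)
  pr2 <- csp_profile(st2$state_a, st2$state_b)
  expect_equal(pr2$average_csp_ppm[inside], rep(1, sum(inside)))
  expect_true(all(!pr2$similar[inside]))
  expect_true(all(pr2$similar[!inside]))

  expect_error(
    simulate_shift_tables(segments = data.frame(start = c(1, 5),
                                                end = c(6, 9))),
    "overlap")
  expect_error(
    simulate_shift_tables(segments = data.frame(start = 0, end = 5)),
    "start")
})

test_that("cross-peak tables follow the dilution intensity model", {
  contacts <- tibble::tibble(pair_id = c("a", "b"),
                             class = c("intra", "inter"))
  tab1 <- simulate_crosspeak_table(contacts, labeled_fraction = 1)
  expect_equal(tab1$intensity_diluted / tab1$intensity_full, c(1, 1))
  tab <- simulate_crosspeak_table(contacts, labeled_fraction = 0.5)
  expect_equal(tab$intensity_diluted / tab$intensity_full, c(1, 0.5))
  expect_error(simulate_crosspeak_table(contacts, labeled_fraction = 0),
               "labeled_fraction")
})
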