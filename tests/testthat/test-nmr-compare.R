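test_that("average CSP follows the weighted four-nucleus formula", {
  expect_equal(average_csp(0, 0, 0, 0), 0)
  expect_equal(average_csp(d_ca = 1), 0.5)
  expect_equal(average_csp(d_cb = 1), 1.185)
  expect_equal(average_csp(d_c = 1), 0.47 / 2)
  expect_equal(average_csp(d_n = 1), 1.30 / 2)
  expect_true(is.na(average_csp(NA, NA, NA, NA)))
  # all four nuclei together
  expect_equal(average_csp(1, 1, 1, 1),
               sqrt((1 + 2.37^2 + 0.47^2 + 1.30^2) / 4))
})

test_that("CSP is sign-symmetric and monotone in each |delta|", {
  set.seed(19)
  for (i in 1:25) {
    d <- rnorm(4)
    base <- average_csp(d[1], d[2], d[3], d[4])
    flip <- d * sample(c(-1, 1), 4, replace = TRUE)
    expect_equal(average_csp(flip[1], flip[2], flip[3], flip[4]), base)
    j <- sample(4, 1)
    d2 <- d; d2[j] <- d2[j] * 1.5
    expect_gte(average_csp(d2[1], d2[2], d2[3], d2[4]), base)
  }
})

test_that("comparing a state against itself gives a zero profile", {
  st <- simulate_shift_tables()$state_a
  pr <- csp_profile(st, st)
  expect_true(all(pr$average_csp_ppm == 0))
  expect_true(all(pr$similar))
  expect_equal(nrow(csp_segments(pr)), 1)
})

test_that("a CSP exactly at the cutoff is classified dissimilar", {
  # similar is defined strictly as CSP < cutoff; probe the boundary with
  # an exactly representable CSP (d_ca = 1 -> CSP = 0.5)
  seg <- data.frame(start = 10, end = 12, d_ca = 1)
  st <- simulate_shift_tables(segments = seg)
  pr <- csp_profile(st$state_a, st$state_b, cutoff_ppm = 0.5)
  hit <- pr$residue_number %in% 10:12
  expect_equal(pr$average_csp_ppm[hit], rep(0.5, 3))
  expect_true(all(!pr$similar[hit]))
  # comfortably above the default 0.7 ppm cutoff -> dissimilar there too
  st2 <- simulate_shift_tables(segments = data.frame(start = 10, end = 12,
                                                     d_ca = 2))
  pr2 <- csp_profile(st2$state_a, st2$state_b)
  expect_true(all(!pr2$similar[pr2$residue_number %in% 10:12]))
})

test_that("disjoint residue sets cannot be compared", {
  st <- simulate_shift_tables()$state_a
  a <- st[st$residue_number <= 50, ]
  b <- st[st$residue_number > 50, ]
  expect_error(csp_profile(a, b), "share no residues")
})

test_that("residues missing from one state get a missing marker", {
  st <- simulate_shift_tables()$state_a
  b <- st[st$residue_number != 7, ]
  pr <- csp_profile(st, b)
  expect_true(is.na(pr$average_csp_ppm[pr$residue_number == 7]))
  expect_equal(pr$n_nuclei_used[pr$residue_number == 7], 0L)
})

test_that("secondary shifts subtract the random-coil scale", {
  st <- simulate_shift_tables()$state_a # built from the coil scale
  ss <- secondary_shifts(st)
  expect_true(all(ss$d_ca == 0, na.rm = TRUE))
  expect_true(all(ss$d_cb == 0, na.rm = TRUE))
  gly <- ss[ss$residue_type == "G", ]
  expect_true(all(is.na(gly$d_cb)))
  expect_true(all(is.na(gly$delta_delta)))

  ala <- tibble::tibble(residue_number = 1, residue_type = "A",
                        atom = "CA", shift_ppm = 56.5)
  expect_equal(secondary_shifts(ala)$d_ca, 4.0)
})

test_that("secondary-structure calls require sustained runs", {
  mk <- function(dd) tibble::tibble(residue_number = seq_along(dd),
                                    delta_delta = dd)
  expect_true(all(classify_secondary_structure(mk(rep(0, 10)))$structure ==
                    "coil"))
  lab <- classify_secondary_structure(mk(c(0, rep(3, 5), 0)))$structure
  expect_equal(lab, c("coil", rep("helix", 5), "coil"))
  alt <- classify_secondary_structure(mk(rep(c(3, -3), 5)))$structure
  expect_true(all(alt == "coil"))
  strand <- classify_secondary_structure(mk(rep(-3, 4)))$structure
  expect_true(all(strand == "strand"))
})

test_that("cross-peak classification uses the geometric-mean boundary", {
  pk <- function(r) tibble::tibble(pair_id = "x", intensity_full = 1,
                                   intensity_diluted = r)
  expect_equal(classify_crosspeaks(pk(1.0))$classification, "intra")
  expect_equal(classify_crosspeaks(pk(0.5))$classification, "inter")
  expect_equal(classify_crosspeaks(pk(0.707))$classification, "ambiguous")
  expect_error(classify_crosspeaks(pk(-1)), "> 0")
  expect_error(classify_crosspeaks(pk(0.5), labeled_fraction = 1),
               "labeled_fraction")
})

test_that("classifier reproduces noiseless labels and survives noise", {
  contacts <- tibble::tibble(pair_id = as.character(1:400),
                             class = rep(c("intra", "inter"), 200))
  clean <- simulate_crosspeak_table(contacts, 0.5)
  cls <- classify_crosspeaks(clean)
  expect_true(all(cls$classification == contacts$class))

  noisy <- simulate_crosspeak_table(contacts, 0.5, noise_sd = 0.10,
                                    seed = 1)
  cls_n <- classify_crosspeaks(noisy)
  expect_gte(mean(cls_n$classification == contacts$class), 0.95)
})
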