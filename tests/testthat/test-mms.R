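speeds_fixture <- function(seed = 31, group = "TD") {
  rec <- generate_recording(group_profile(group), seed = seed)
  compute_speed(zscore_frames(rec))
}

test_that("gluing concatenates region segments in fixed landmark order", {
  sp <- speeds_fixture()
  g1 <- glue_region(sp, "V1")
  g2 <- glue_region(sp, "V2")
  g3 <- glue_region(sp, "V3")
  expect_length(g1, 3900L)  # 26 x 150
  expect_length(g2, 2550L)  # 17 x 150
  expect_length(g3, 3750L)  # 25 x 150
  # first block is the lowest-index landmark of the region
  expect_equal(as.numeric(g1[1:150]), unname(unclass(sp)[, 17 + 1]))

  # a single-landmark region is that landmark's own series
  part <- structure(list(V1 = 0L, V2 = 1:33, V3 = 34:67),
                    class = "region_partition")
  expect_equal(as.numeric(glue_region(sp, "V1", part)),
               unname(unclass(sp)[, 1]))

  # permuting the glue order permutes samples but not their multiset
  idx <- trigeminal_partition()$V1
  set.seed(1)
  gp <- glue_region(sp, "V1", order = sample(idx))
  expect_equal(sort(as.numeric(gp)), sort(as.numeric(g1)))
  expect_error(glue_region(sp, "V1", order = idx[-1]), "permutation")
})

test_that("peak extraction finds strict interior maxima with plateau tie-break", {
  pk <- extract_peaks(c(0, 1, 0, 2, 0))
  expect_equal(pk$indices, c(2L, 4L))
  expect_equal(pk$amplitudes, c(1, 2))

  expect_length(extract_peaks(1:50)$indices, 0L)   # monotone
  expect_length(extract_peaks(50:1)$indices, 0L)

  # plateau flanked by lower values -> single peak at first plateau index
  pk2 <- extract_peaks(c(0, 3, 3, 3, 1, 4, 0))
  expect_equal(pk2$indices, c(2L, 6L))
  expect_equal(pk2$amplitudes, c(3, 4))

  # endpoints are never peaks
  expect_equal(extract_peaks(c(5, 1, 2, 1, 5))$indices, 3L)

  expect_error(extract_peaks(c(1, 2)), "insufficient")

  set.seed(5)
  expect_gt(length(extract_peaks(runif(3900))$indices), 100L)
})

test_that("a glued region of a synthetic recording yields over 100 peaks", {
  sp <- speeds_fixture(seed = 77)
  for (r in c("V1", "V2", "V3"))
    expect_gt(length(extract_peaks(glue_region(sp, r))$indices), 100L)
})

test_that("the empirical Gamma mean recovers known distribution means", {
  set.seed(101)
  mu1 <- empirical_gamma_mean(rgamma(1000, shape = 4, scale = 0.5))
  expect_gt(as.numeric(mu1), 1.8)   # true mean a*b = 2
  expect_lt(as.numeric(mu1), 2.2)

  mu2 <- empirical_gamma_mean(rexp(2000, rate = 1))
  expect_gt(as.numeric(mu2), 0.9)   # exponential mean 1
  expect_lt(as.numeric(mu2), 1.1)

  expect_error(empirical_gamma_mean(rep(2, 100)), "degenerate")
  expect_error(empirical_gamma_mean(rgamma(10, 2)), "insufficient")
  expect_error(empirical_gamma_mean(c(rep(-1, 10), rgamma(100, 2))),
               "data quality")
})

test_that("deviation series is the elementwise absolute gap from the mean", {
  expect_equal(as.numeric(deviation_series(c(1, 1, 1), 1)), c(0, 0, 0))
  expect_equal(as.numeric(deviation_series(c(0, 2), 1)), c(1, 1))
  s <- runif(57)
  expect_length(deviation_series(s, 0.5), 57L)
  expect_error(deviation_series(s, -1), "positive")
})

test_that("MMS standardization follows the local peak/minima scaling", {
  # peak 2 flanked by minima 0.5 and 0.5 -> 2 / (2 + 0.5) = 0.8
  dev <- c(0, 1, 0.5, 2, 0.5, 1, 0)
  m <- mms_standardize(dev)
  expect_equal(m$positions, c(2L, 4L, 6L))
  expect_equal(m$spike_values[2], 2 / 2.5)
  # peaks 1 at both ends: minima 0 and 0.5 -> 1 / 1.25
  expect_equal(m$spike_values[1], 1 / (1 + 0.25))
  expect_equal(m$spike_values[3], 1 / (1 + 0.25))

  # both flanking minima at zero -> spike attains the upper bound 1
  expect_equal(mms_standardize(c(0, 5, 0))$spike_values, 1)

  # full series: spikes at peak positions, zeros elsewhere
  expect_equal(m$full_series[m$positions], m$spike_values)
  expect_true(all(m$full_series[-m$positions] == 0))
})

test_that("every spike lies in (0, 1] for any positive deviation series", {
  set.seed(202)
  for (i in 1:25) {
    dev <- abs(rnorm(300, sd = runif(1, 0.1, 5)))
    m <- mms_standardize(dev)
    expect_true(all(m$spike_values > 0 & m$spike_values <= 1))
    expect_setequal(which(m$full_series > 0), m$positions)
  }
})

test_that("shuffling the glue order leaves the fitted signature stable", {
  sp <- speeds_fixture(seed = 55)
  idx <- trigeminal_partition()$V1
  g0 <- glue_region(sp, "V1")
  pk0 <- extract_peaks(g0)
  sig0 <- fit_gamma_mle(pk0$amplitudes)
  set.seed(9)
  for (i in 1:3) {
    gs <- glue_region(sp, "V1", order = sample(idx))
    pks <- extract_peaks(gs)
    # only segment junctions can differ: peak count moves by < 2 per seam
    expect_lt(abs(length(pks$indices) - length(pk0$indices)),
              2 * length(idx))
    sigs <- fit_gamma_mle(pks$amplitudes)
    expect_equal(sigs$shape, sig0$shape, tolerance = 0.05)
    expect_equal(sigs$scale, sig0$scale, tolerance = 0.05)
  }
})

test_that("MMS spikes are invariant to rescaling of the speed series", {
  sp <- speeds_fixture(seed = 66)
  g <- as.numeric(glue_region(sp, "V2"))
  mu <- empirical_gamma_mean(extract_peaks(g))
  base <- mms_standardize(deviation_series(g, as.numeric(mu)))
  for (c_scale in c(0.1, 10)) {
    mu_c <- empirical_gamma_mean(extract_peaks(c_scale * g))
    expect_equal(as.numeric(mu_c), c_scale * as.numeric(mu),
                 tolerance = 1e-6)
    m_c <- mms_standardize(deviation_series(c_scale * g, as.numeric(mu_c)))
    expect_equal(m_c$spike_values, base$spike_values, tolerance = 1e-6)
    expect_equal(m_c$positions, base$positions)
  }
})
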