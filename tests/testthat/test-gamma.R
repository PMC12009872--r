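test_that("the Gamma MLE recovers the exponential as shape 1", {
  set.seed(11)
  x <- rexp(2000, rate = 1)
  sig <- fit_gamma_mle(x)
  expect_gt(sig$shape, 0.9)
  expect_lt(sig$shape, 1.1)
  expect_equal(sig$mean, sig$shape * sig$scale)
})

test_that("the in-package MLE agrees with an independent fitter", {
  skip_if_not_installed("MASS")
  set.seed(12)
  x <- rgamma(800, shape = 3.2, scale = 0.4)
  sig <- fit_gamma_mle(x)
  ref <- MASS::fitdistr(x, "gamma")   # (shape, rate) parameterization
  expect_equal(sig$shape, unname(ref$estimate["shape"]), tolerance = 1e-4)
  expect_equal(sig$scale, 1 / unname(ref$estimate["rate"]), tolerance = 1e-4)
})

test_that("parameter recovery across the (shape, scale) grid stays under 10%", {
  set.seed(13)
  rel_err <- c()
  for (a in c(0.5, 1, 2, 4, 8)) for (b in c(0.1, 0.5, 1)) {
    x <- rgamma(500, shape = a, scale = b)
    sig <- fit_gamma_mle(x)
    rel_err <- c(rel_err, abs(sig$shape - a) / a, abs(sig$scale - b) / b)
  }
  expect_lt(median(rel_err), 0.10)
})

test_that("confidence intervals cover the truth and shrink with n", {
  set.seed(14)
  hits <- 0L
  for (i in 1:100) {
    x <- rgamma(1000, shape = 4, scale = 0.25)
    sig <- fit_gamma_mle(x)
    if (sig$ci_shape[1] < 4 && 4 < sig$ci_shape[2] &&
        sig$ci_scale[1] < 0.25 && 0.25 < sig$ci_scale[2])
      hits <- hits + 1L
  }
  expect_gte(hits, 90L)

  set.seed(15)
  for (a in c(0.5, 2, 8)) for (b in c(0.1, 1)) {
    w200 <- diff(fit_gamma_mle(rgamma(200, a, scale = b))$ci_shape)
    w2000 <- diff(fit_gamma_mle(rgamma(2000, a, scale = b))$ci_shape)
    expect_lt(w2000, w200)
  }
})

test_that("the MLE is scale-equivariant and rejects degenerate input", {
  set.seed(16)
  x <- rgamma(400, shape = 2.5, scale = 0.7)
  base <- fit_gamma_mle(x)
  for (c_scale in c(0.5, 3)) {
    sc <- fit_gamma_mle(c_scale * x)
    expect_equal(sc$shape, base$shape, tolerance = 1e-8)
    expect_equal(sc$scale, c_scale * base$scale, tolerance = 1e-8)
  }
  expect_error(fit_gamma_mle(rep(1, 100)), "degenerate")
  expect_error(fit_gamma_mle(c(-1, rgamma(99, 2))), "positive")
  expect_error(fit_gamma_mle(rgamma(10, 2)), "insufficient")
})

test_that("derived NSR and skewness follow the Gamma identities exactly", {
  set.seed(17)
  for (i in 1:5) {
    sig <- fit_gamma_mle(rgamma(300, shape = runif(1, 0.5, 9),
                                scale = runif(1, 0.1, 2)))
    expect_identical(derive_nsr(sig), sig$scale)          # NSR = b
    expect_identical(sig$mean, sig$shape * sig$scale)     # mean = a*b
    expect_equal(derive_skewness(sig), 2 / sqrt(sig$shape))
    expect_equal(sig$sd^2 / sig$mean, sig$nsr)  # NSR = variance/mean = b
  }
  # skewness falls toward the Gaussian limit as shape grows
  fake <- function(a) structure(list(shape = a, scale = 1),
                                class = "gamma_signature")
  expect_equal(derive_skewness(fake(4)), 1.0)
  expect_equal(derive_skewness(fake(1)), 2.0)
  expect_lt(derive_skewness(fake(1e6)), 1e-2)
})

test_that("signature-space norms are Euclidean and order-invariant", {
  fake <- function(a, b) structure(list(shape = a, scale = b),
                                   class = "gamma_signature")
  sigs <- list(V1 = fake(4, 3), V2 = fake(4, 4), V3 = fake(4, 0.0001))
  pt <- signature_space_point(sigs)
  expect_equal(pt$nsr_norm, sqrt(3^2 + 4^2 + 0.0001^2))
  sigs2 <- list(V1 = fake(4, 2), V2 = fake(4, 2), V3 = fake(4, 2))
  # skew_vector is (1,1,1) for shape 4, so skew_norm = sqrt(3)
  expect_equal(signature_space_point(sigs2)$skew_norm, sqrt(3))
  perm <- signature_space_point(sigs[c("V1", "V2", "V3")])
  expect_equal(perm$nsr_norm, pt$nsr_norm)
  expect_error(signature_space_point(sigs[1:2]), "incomplete")
})

test_that("pairwise rank-sum behaves under null, separation and symmetry", {
  set.seed(18)
  x <- rnorm(100)
  null_res <- pairwise_ranksum(list(a = x, b = x))
  expect_gt(null_res$p, 0.99)

  # gross regime separation (equal means, very different shapes): the
  # rank-sum test rejects at the 1% level in the large majority of runs
  reject <- 0L
  for (i in 1:100) {
    g1 <- rgamma(200, shape = 1, scale = 2)
    g2 <- rgamma(200, shape = 8, scale = 0.25)
    p <- pairwise_ranksum(list(a = g1, b = g2))$p
    if (p < 0.01) reject <- reject + 1L
  }
  expect_gte(reject, 80L)

  y <- rnorm(80, mean = 0.3)
  ab <- pairwise_ranksum(list(a = x, b = y))
  ba <- pairwise_ranksum(list(b = y, a = x))
  expect_equal(ab$p, ba$p)

  adj <- pairwise_ranksum(list(a = x, b = y, c = rnorm(80)), adjust = TRUE)
  expect_true("p_adj" %in% names(adj))
  expect_equal(nrow(adj), 3L)
  expect_warning(pairwise_ranksum(list(a = x, b = y, tiny = 1:3)),
                 "tiny")
})
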