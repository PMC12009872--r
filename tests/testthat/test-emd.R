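test_that("1-D EMD satisfies the elementary transport identities", {
  expect_equal(emd_1d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(emd_1d(0, 1), 1)                 # unit transport
  expect_equal(emd_1d(c(0, 0), c(1, 1)), 1)
  expect_equal(emd_1d(0, 10), 10)
  expect_equal(emd_1d(c(0, 1), c(1, 0)), 0)     # multisets equal
  expect_error(emd_1d(numeric(0), 1), "empty")
})

test_that("EMD equals the brute-force assignment cost on equal-size sets", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(2:5, 1)
    a <- round(runif(n, -3, 3), 2)
    b <- round(runif(n, -3, 3), 2)
    expect_equal(emd_1d(a, b), brute_force_emd_equal(a, b),
                 tolerance = 1e-12)
  }
})

test_that("EMD matches the quantile-function integral for unequal sizes", {
  # independent route: integral of |Qa(u) - Qb(u)| du over the union of
  # probability breakpoints i/n and j/m
  quantile_emd <- function(a, b) {
    a <- sort(a); b <- sort(b)
    u <- sort(unique(c(seq_along(a) / length(a), seq_along(b) / length(b))))
    lo <- c(0, u[-length(u)])
    qa <- a[ceiling(u * length(a) - 1e-12)]
    qb <- b[ceiling(u * length(b) - 1e-12)]
    sum(abs(qa - qb) * (u - lo))
  }
  set.seed(22)
  for (i in 1:200) {
    a <- runif(sample(1:6, 1), -2, 2)
    b <- runif(sample(1:6, 1), -2, 2)
    expect_equal(emd_1d(a, b), quantile_emd(a, b), tolerance = 1e-12)
  }
})

test_that("EMD agrees with the scipy reference implementation", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  set.seed(23)
  cases <- lapply(1:40, function(i)
    list(a = runif(sample(1:6, 1), -5, 5), b = runif(sample(1:6, 1), -5, 5)))
  inp <- tempfile(fileext = ".json")
  out <- tempfile(fileext = ".txt")
  jsonlite::write_json(cases, inp, auto_unbox = FALSE, digits = NA)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "from scipy.stats import wasserstein_distance",
    "cases = json.load(open(sys.argv[1]))",
    "with open(sys.argv[2], 'w') as fh:",
    "    for c in cases:",
    "        fh.write('%.17g\\n' % float(wasserstein_distance(c['a'], c['b'])))"),
    script)
  status <- system2("python", c(script, inp, out))
  skip_if(status != 0L, "python/scipy unavailable")
  ref <- as.numeric(readLines(out))
  ours <- vapply(cases, function(c) emd_1d(c$a, c$b), numeric(1))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("EMD obeys the metric axioms on random instances", {
  set.seed(24)
  for (i in 1:200) {
    a <- rnorm(10); b <- rnorm(10); c <- rnorm(10)
    dab <- emd_1d(a, b); dba <- emd_1d(b, a)
    expect_identical(dab, dba)
    expect_equal(emd_1d(a, sample(a)), 0)
    expect_lte(emd_1d(a, c), dab + emd_1d(b, c) + 1e-12)
    expect_gte(dab, 0)
  }
})

test_that("pairwise EMD matrices are symmetric with the declared structure", {
  set.seed(25)
  two <- pairwise_emd(list(x = rnorm(20), y = rnorm(20, 2)))
  expect_equal(dim(unclass(two)), c(2L, 2L))
  expect_equal(two[1, 2], two[2, 1])
  expect_equal(diag(unclass(two)), c(x = 0, y = 0))

  sets <- c(lapply(1:4, function(i) rgamma(50, 8, scale = 0.1)),
            lapply(1:4, function(i) rgamma(50, 1.5, scale = 0.8)))
  names(sets) <- c(paste0("TD.", 1:4), paste0("ASD.", 1:4))
  m <- pairwise_emd(sets, normalize = TRUE)
  expect_equal(max(m), 1)
  within <- c(m[1:4, 1:4][upper.tri(m[1:4, 1:4])],
              m[5:8, 5:8][upper.tri(m[5:8, 5:8])])
  between <- as.vector(m[1:4, 5:8])
  expect_lt(mean(within), mean(between))  # block structure

  expect_warning(pairwise_emd(list(a = 1:3, b = numeric(0), c = 4:6)),
                 "empty")
  expect_error(pairwise_emd(list(a = 1:3)), "at least two")
})

test_that("tree clustering cuts the EMD matrix into labeled subtypes", {
  # two perfectly separated blobs -> two pure leaves at 100%
  m <- matrix(1, 6, 6) - diag(6)
  m[1:3, 1:3] <- 0; m[4:6, 4:6] <- 0
  rownames(m) <- colnames(m) <- c(paste0("A.", 1:3), paste0("B.", 1:3))
  rep2 <- tree_cluster(structure(m, class = "emd_matrix"), k = 2,
                       labels = rep(c("A", "B"), each = 3))
  expect_equal(length(unique(rep2$assignments)), 2L)
  expect_true(all(rep2$composition$percent == 100))

  # per-leaf composition percentages always sum to 100
  set.seed(26)
  sets <- setNames(lapply(1:14, function(i) rnorm(30, mean = i %% 3)),
                   paste0("g", 1:14, ".", rep(c("X", "Y"), 7)))
  m14 <- pairwise_emd(sets)
  rep14 <- tree_cluster(m14, k = 14, labels = rep(c("X", "Y"), 7))
  expect_equal(length(unique(rep14$assignments)), 14L)
  sums <- tapply(rep14$composition$percent, rep14$composition$leaf, sum)
  expect_true(all(abs(sums - 100) < 0.01))

  rep6 <- tree_cluster(m14, k = 6, labels = rep(c("X", "Y"), 7))
  expect_equal(length(unique(rep6$assignments)), 6L)

  expect_error(tree_cluster(m14, k = 15), "domain error")
  expect_error(tree_cluster(m14, k = 1), "domain error")
})
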