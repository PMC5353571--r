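test_that("expected subsample frequency counts match exhaustive enumeration", {
  # X = (2, 1), m = 2: the three equally likely subsamples give
  # E[f_1(2)] = 4/3, E[f_2(2)] = 1/3
  ef <- expected_freq_counts(c(2, 1), m = 2)
  expect_equal(ef, c(4 / 3, 1 / 3))
  # identity subsample returns the observed tally; m = 1 has one singleton
  fc <- as_freq_counts(c(4, 2, 2, 1))
  ef <- expected_freq_counts(fc, m = fc$n)
  expect_equal(ef[c(1, 2, 4)], c(1, 2, 1))
  expect_equal(expected_freq_counts(fc, 1), c(1))
  expect_error(expected_freq_counts(fc, 10), "extrapolation")
})

test_that("rarefied Hill numbers match small-case enumeration and endpoints", {
  expect_equal(rarefied_hill(c(2, 1), m = 2, q = 0), 5 / 3)
  for (q in 0:2) expect_equal(rarefied_hill(c(5, 3, 1), 1, q), 1)
  x <- c(6, 4, 3, 2, 1, 1)
  for (q in 0:2)
    expect_equal(rarefied_hill(x, sum(x), q), observed_hill(x, q),
                 tolerance = 1e-10)
})

test_that("rarefied values agree with a 10000-subsample Monte-Carlo oracle", {
  x <- c(5, 3, 2, 1, 1)
  n <- sum(x)
  m <- 6
  pop <- rep(seq_along(x), x)
  set.seed(17)
  reps <- 10000
  idx <- replicate(reps, sample(pop, m))
  # index-scale statistics per subsample: richness, entropy, sum of squares
  rich <- numeric(reps); ent <- numeric(reps); ssq <- numeric(reps)
  for (i in seq_len(reps)) {
    tab <- tabulate(idx[, i], nbins = length(x))
    tab <- tab[tab > 0]
    rich[i] <- length(tab)
    ent[i] <- -sum((tab / m) * log(tab / m))
    ssq[i] <- sum(tab * (tab - 1)) / (m * (m - 1))
  }
  se3 <- function(v) 3 * sd(v) / sqrt(reps)
  expect_lt(abs(rarefied_hill(x, m, 0) - mean(rich)), se3(rich))
  expect_lt(abs(log(rarefied_hill(x, m, 1)) - mean(ent)), se3(ent))
  # the q=2 formula inverts 1/m + (m-1)/m * repeat-rate; compare on that scale
  expect_lt(abs((1 / rarefied_hill(x, m, 2) - 1 / m) * m / (m - 1) - mean(ssq)),
            se3(ssq))
})

test_that("size-based richness curve is increasing and concave over rarefied m", {
  x <- c(9, 5, 4, 3, 2, 2, 1, 1, 1)
  vals <- vapply(1:sum(x), function(m) rarefied_hill(x, m, 0), 1)
  expect_true(all(diff(vals) > 0))
  expect_true(all(diff(diff(vals)) < 1e-9))
})

test_that("extrapolated richness runs from S_obs to the Chao1 asymptote", {
  fc <- freq_counts(c(1, 2, 3), c(2, 1, 2))  # n=10, S=5, f1=2, f2=1
  expect_equal(extrapolated_richness(fc, 0), 5)
  expect_equal(extrapolated_richness(fc, 5), 5.737118, tolerance = 1e-6)
  expect_equal(extrapolated_richness(fc, 1e6), chao1(fc), tolerance = 1e-8)
  # no singletons: nothing to extrapolate
  expect_equal(extrapolated_richness(freq_counts(c(2, 3), c(2, 2)), 50), 4)
})

test_that("extrapolated Shannon and Simpson tend to their asymptotes", {
  expect_equal(extrapolated_hill(fc_east, 0, 1), observed_hill(fc_east, 1))
  expect_equal(extrapolated_hill(fc_east, 1e7, 2), simpson_asymptotic(fc_east),
               tolerance = 1e-4)
  expect_equal(extrapolated_hill(fc_east, 1e7, 1), shannon_asymptotic(fc_east),
               tolerance = 1e-4)
  # hand evaluation of the q=2 form at n + m* = 20
  expect_equal(extrapolated_hill(c(4, 3, 2, 1), 10, 2), 3.8297872340,
               tolerance = 1e-9)
  # monotone approach to the asymptote
  v1 <- vapply(c(0, 50, 200, 1000), function(ms)
    extrapolated_hill(fc_east, ms, 1), 1)
  expect_true(all(diff(v1) > 0))
})

test_that("coverage is seamless at the observed point and monotone in m", {
  expect_equal(coverage_at_size(fc_east, fc_east$n),
               sample_coverage(fc_east)$c_hat, tolerance = 1e-12)
  covs <- vapply(c(5, 25, 50, 100, 138, 200, 400), function(m)
    coverage_at_size(fc_east, m), 1)
  expect_true(all(diff(covs) > 0))
  expect_true(all(covs >= 0 & covs <= 1))
})

test_that("size_for_coverage inverts the coverage curve at integer sizes", {
  m <- size_for_coverage(fc_east, 0.76)
  expect_gte(coverage_at_size(fc_east, m), 0.76)
  expect_lt(coverage_at_size(fc_east, m - 1), 0.76)
})

test_that("curves pass through the observed point and carry the right segments", {
  cu <- build_curve(fc_east, q = 0, base_size = 300)
  expect_true(fc_east$n %in% cu$m)
  at_n <- cu[cu$m == fc_east$n, ]
  expect_equal(at_n$qD, 88)
  expect_identical(at_n$segment, "observed")
  expect_true(all(cu$qD[cu$segment == "rarefied"] < 88))
  expect_equal(max(cu$m), 300)
  # degenerate single-class assemblage: flat at 1
  cu1 <- build_curve(abundance_vector(5), q = 2, base_size = 20)
  expect_true(all(abs(cu1$qD - 1) < 1e-9))
  expect_error(build_curve(fc_east, 0, base_size = 300, grid_points = 0),
               "empty")
  # bootstrap bands are symmetric around the point estimate
  cub <- build_curve(fc_east, q = 2, base_size = 200, B = 30, seed = 4)
  expect_equal(cub$qD - cub$ci_low, cub$ci_high - cub$qD)
})
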