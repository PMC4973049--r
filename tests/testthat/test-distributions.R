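test_that("beta parameterisation from counts matches the observed proportion", {
  b <- beta_from_counts(1527, 2033)
  expect_equal(b$params$shape1, 1527)
  expect_equal(b$params$shape2, 506)
  expect_equal(dist_mean(b), 1527 / 2033)
  expect_equal(round(dist_mean(b), 3), 0.751)

  expect_equal(unlist(beta_from_counts(1, 2)$params),
               c(shape1 = 1, shape2 = 1))  # uniform
  expect_equal(round(dist_mean(beta_from_counts(87, 4546)), 5), 0.01914)

  u <- beta_from_counts(10, 40, prior = "uniform")
  expect_equal(unlist(u$params), c(shape1 = 11, shape2 = 31))

  expect_error(beta_from_counts(0, 10), "degenerate")
  expect_error(beta_from_counts(10, 10), "degenerate")
})

test_that("gamma method-of-moments reproduces requested moments", {
  g <- gamma_from_mean_se(263, 21.48)
  expect_equal(g$params$shape, (263 / 21.48)^2)
  expect_equal(g$params$scale, 21.48^2 / 263)
  expect_equal(round(g$params$shape, 1), 149.9)
  expect_equal(round(g$params$scale, 3), 1.754)
  expect_equal(dist_mean(g), 263)

  g2 <- gamma_from_mean_se(100, 10)
  expect_equal(unlist(g2$params), c(shape = 100, scale = 1))

  set.seed(11)
  x <- dist_sample(gamma_from_mean_se(586, 223.70), 1e5)
  expect_lt(abs(mean(x) - 586), 3 * 223.70 / sqrt(1e5))
  expect_lt(abs(sd(x) - 223.70), 3 * 223.70 / sqrt(1e5))

  expect_error(gamma_from_mean_se(-1, 10), "invalid moments")
  expect_error(gamma_from_mean_se(10, 0), "invalid moments")
})

test_that("beta method-of-moments fit for utility decrements", {
  b <- beta_from_mean_se(0.03, 0.003)
  expect_equal(dist_mean(b), 0.03)
  v <- with(b$params, shape1 * shape2 /
              ((shape1 + shape2)^2 * (shape1 + shape2 + 1)))
  expect_equal(sqrt(v), 0.003)
  expect_error(beta_from_mean_se(0.5, 0.6), "invalid moments")
})

test_that("sampling honours the family, support and determinism contract", {
  fx <- dist_spec("fixed", value = 0.9)
  expect_equal(dist_sample(fx, 5), rep(0.9, 5))

  set.seed(7); a <- dist_sample(beta_from_counts(1527, 2033), 100)
  set.seed(7); b <- dist_sample(beta_from_counts(1527, 2033), 100)
  expect_identical(a, b)

  set.seed(3)
  x <- dist_sample(beta_from_counts(1527, 2033), 1e5)
  q <- quantile(x, c(0.025, 0.975), names = FALSE)
  expect_lt(max(abs(q - qbeta(c(0.025, 0.975), 1527, 506))), 0.005)

  # parameter mapping: empirical moments match the specified moments
  # (4 MC SE: a mis-mapped parameter would be off by orders of magnitude)
  set.seed(5)
  specs <- list(beta_from_counts(30, 100),
                gamma_from_mean_se(386.42, 96.72),
                dist_spec("normal", mean = -0.604, se = 0.143),
                dist_spec("logitnormal", mu = 1.9, sigma = 0.93))
  for (sp in specs) {
    x <- dist_sample(sp, 1e5)
    expect_lt(abs(mean(x) - dist_mean(sp)), 4 * sd(x) / sqrt(1e5))
    if (sp$family %in% c("beta", "logitnormal"))
      expect_true(all(x >= 0 & x <= 1))
  }
})

test_that("constructor rejects invalid parameterisations", {
  expect_error(dist_spec("beta", shape1 = -1, shape2 = 2), "shape")
  expect_error(dist_spec("gamma", shape = 1, scale = 0), "shape and scale")
  expect_error(dist_spec("normal", mean = 0, se = -1), "se")
  expect_error(dist_spec("beta", shape1 = 1), "missing parameter")
})

test_that("point estimates: means, except posterior medians for logit-normal", {
  expect_equal(dist_point(gamma_from_mean_se(100, 10)), 100)
  ln <- dist_spec("logitnormal", mu = qlogis(0.87), sigma = 0.93)
  expect_equal(dist_point(ln), 0.87)
  expect_lt(dist_mean(ln), 0.87)  # left skew on the probability scale
})
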