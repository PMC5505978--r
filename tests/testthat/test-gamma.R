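test_that("fit_ellipsoid returns the sample mean and ridged covariance", {
  e <- fit_ellipsoid(matrix(c(0, 2), ncol = 1), "A")
  expect_equal(unname(e$center), 1)
  expect_equal(unname(e$covariance[1, 1]), 2, tolerance = 1e-9)

  # constant samples: ridge-only, strictly positive definite
  e0 <- fit_ellipsoid(matrix(1, nrow = 5, ncol = 2))
  expect_true(all(eigen(e0$covariance, symmetric = TRUE)$values > 0))

  expect_error(fit_ellipsoid(matrix(1, 1, 2)), class = "rrgamma_insufficient_data")
})

test_that("fit_ellipsoid recovers a known Gaussian within sampling error", {
  set.seed(314)
  n <- 10000
  L <- matrix(c(2, 0, 0.8, 0.5), 2)
  x <- t(c(1, -2) + L %*% matrix(rnorm(2 * n), 2))
  e <- fit_ellipsoid(x)
  truth <- L %*% t(L)
  se_mean <- sqrt(diag(truth) / n)
  expect_true(all(abs(e$center - c(1, -2)) < 3 * se_mean))
  expect_true(all(abs(e$covariance - truth) < 3 * (abs(truth) + 0.5) * sqrt(2 / n)))
})

test_that("pair_distance matches the 1-D closed form and simple geometry", {
  # printed-summary 1-D case: (0.75 - 0.41) / 0.41
  e1 <- structure(list(center = 0.00, covariance = matrix(0.01^2), n = 10,
                       group_id = "NSR"), class = "group_ellipsoid")
  e2 <- structure(list(center = 0.75, covariance = matrix(0.40^2), n = 10,
                       group_id = "AF"), class = "group_ellipsoid")
  expect_equal(pair_distance(e1, e2), (0.75 - 0.41) / 0.41, tolerance = 1e-12)
  expect_equal(round(pair_distance(e1, e2), 2), 0.83)

  # identical centers -> -1 regardless of covariances
  a <- fit_ellipsoid(matrix(rnorm(40), 20))
  b <- fit_ellipsoid(sweep(matrix(rnorm(40, sd = 3), 20), 2,
                           colMeans(matrix(rnorm(40, sd = 3), 20))))
  b$center <- a$center
  expect_equal(pair_distance(a, b), -1)

  # 2-D spherical: unit covariances, centers 4 apart -> (4 - 2) / 2 = 1
  s1 <- structure(list(center = c(0, 0), covariance = diag(2), n = 10,
                       group_id = "A"), class = "group_ellipsoid")
  s2 <- structure(list(center = c(4, 0), covariance = diag(2), n = 10,
                       group_id = "B"), class = "group_ellipsoid")
  expect_equal(pair_distance(s1, s2), 1)
})

test_that("pair_distance agrees with the ray-intersection root-finding oracle", {
  set.seed(99)
  for (rep in 1:50) {
    d <- sample(2:3, 1)
    mu1 <- rnorm(d); mu2 <- rnorm(d, 2)
    S1 <- random_spd(d); S2 <- random_spd(d)
    e1 <- structure(list(center = mu1, covariance = S1, n = 10, group_id = "A"),
                    class = "group_ellipsoid")
    e2 <- structure(list(center = mu2, covariance = S2, n = 10, group_id = "B"),
                    class = "group_ellipsoid")
    expect_equal(pair_distance(e1, e2), oracle_pair_distance(mu1, S1, mu2, S2),
                 tolerance = 1e-8)
  }
})

test_that("gamma_metric sums pair distances over unordered pairs", {
  set.seed(5)
  g <- lapply(c(0, 6, 12), function(m)
    fit_ellipsoid(matrix(rnorm(60, m), ncol = 2)))
  res <- gamma_metric(g)
  expect_equal(res$K, 3)
  expect_length(res$pair_distances, 3)
  hand <- pair_distance(g[[1]], g[[2]]) + pair_distance(g[[1]], g[[3]]) +
    pair_distance(g[[2]], g[[3]])
  expect_equal(res$gamma, hand)

  # three coincident groups: each pair contributes -1
  same <- lapply(1:3, function(i) {
    e <- fit_ellipsoid(matrix(rnorm(40), 20, 2)); e$center <- c(0, 0); e
  })
  expect_equal(gamma_metric(same)$gamma, -3)
  expect_error(gamma_metric(same[1]), class = "rrgamma_insufficient_groups")

  two <- gamma_metric(g[1:2])
  expect_equal(two$gamma, pair_distance(g[[1]], g[[2]]))
})

test_that("univariate gamma reproduces printed-summary arithmetic", {
  expect_equal(round(univariate_gamma(0.14, 0.10, 2.58, 0.75), 2), 1.87)
  expect_equal(univariate_gamma(1.01, 1.19, 31.77, 15.13), 0.8848,
               tolerance = 1e-4)
  expect_equal(univariate_gamma(5, 1, 5, 3), -1)
  expect_identical(univariate_gamma(0, 0, 1, 0), Inf)
  expect_error(univariate_gamma(1, 0, 1, 0), class = "rrgamma_degenerate_groups")
})

test_that("multivariate routine on 1-D inputs equals the univariate closed form", {
  set.seed(77)
  mk <- function(mu, sd) structure(
    list(center = mu, covariance = matrix(sd^2), n = 30, group_id = "g"),
    class = "group_ellipsoid")
  for (rep in 1:20) {
    x1 <- rnorm(30, 0, 0.5); x2 <- rnorm(30, 2, 1.5)
    expect_equal(pair_distance(mk(mean(x1), sd(x1)), mk(mean(x2), sd(x2))),
                 univariate_gamma(mean(x1), sd(x1), mean(x2), sd(x2)),
                 tolerance = 1e-12)
    # ellipsoids fitted from samples carry the documented 1e-10 ridge;
    # agreement then holds to ~1e-8 absolute
    ef1 <- fit_ellipsoid(matrix(x1, ncol = 1))
    ef2 <- fit_ellipsoid(matrix(x2, ncol = 1))
    expect_lt(abs(pair_distance(ef1, ef2) -
                    univariate_gamma(mean(x1), sd(x1), mean(x2), sd(x2))), 1e-8)
  }
})

test_that("gamma is symmetric, affine invariant, bounded below by -1", {
  set.seed(21)
  for (rep in 1:20) {
    d <- sample(2:4, 1)
    x1 <- matrix(rnorm(25 * d), 25)
    x2 <- matrix(rnorm(25 * d, 1.5), 25)
    e1 <- fit_ellipsoid(x1); e2 <- fit_ellipsoid(x2)
    g <- pair_distance(e1, e2)
    expect_identical(g, pair_distance(e2, e1))
    expect_gte(g, -1)

    # common invertible affine map
    A <- matrix(rnorm(d * d), d) + diag(d) * 2
    shift <- rnorm(d)
    t1 <- fit_ellipsoid(sweep(x1 %*% t(A), 2, shift, "+"))
    t2 <- fit_ellipsoid(sweep(x2 %*% t(A), 2, shift, "+"))
    expect_equal(pair_distance(t1, t2), g, tolerance = 1e-6)
  }
})

test_that("inflating both covariances strictly decreases gamma", {
  set.seed(3)
  e1 <- fit_ellipsoid(matrix(rnorm(60), 30))
  e2 <- fit_ellipsoid(matrix(rnorm(60, 3), 30))
  g0 <- pair_distance(e1, e2)
  for (c2 in c(1.5, 4, 16)) {
    e1c <- e1; e2c <- e2
    e1c$covariance <- e1$covariance * c2
    e2c$covariance <- e2$covariance * c2
    expect_lt(pair_distance(e1c, e2c), g0)
    g0 <- pair_distance(e1c, e2c)
  }
})
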