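symmetric_1d <- function(n = 50, sd = 0.1, seed = 1) {
  set.seed(seed)
  list(x = matrix(c(rnorm(n, -1, sd), rnorm(n, 1, sd)), ncol = 1,
                  dimnames = list(NULL, "f")),
       labels = rep(c("A", "B"), each = n))
}

test_that("logistic boundary sits near the symmetry point", {
  d <- symmetric_1d()
  m <- suppressWarnings(train_logistic(d$x, d$labels))
  boundary <- -m$intercept / m$weights[["f"]]
  expect_lt(abs(boundary), 0.1)
  expect_identical(predict(m, matrix(-1, 1, 1, dimnames = list(NULL, "f")),
                           type = "class"), "A")
})

test_that("weights are invariant under training-set duplication", {
  set.seed(2)
  x <- matrix(rnorm(200), ncol = 2, dimnames = list(NULL, c("u", "v")))
  labels <- rep(c("A", "B"), 50)
  x[labels == "B", 1] <- x[labels == "B", 1] + 1
  m1 <- train_logistic(x, labels)
  m2 <- train_logistic(rbind(x, x), c(labels, labels))
  expect_equal(coef(m1), coef(m2), tolerance = 1e-6)
})

test_that("estimates are consistent on a known logistic generative model", {
  set.seed(33)
  n <- 10000
  x <- matrix(rnorm(n), dimnames = list(NULL, "x"))
  beta <- 2
  y <- ifelse(runif(n) < plogis(beta * x), "pos", "neg")
  m <- train_logistic(x, factor(y, levels = c("neg", "pos")))
  se <- sqrt(1 / (n * mean(plogis(beta * x) * (1 - plogis(beta * x)) * x^2)))
  expect_lt(abs(m$weights[["x"]] - beta), 3 * se)
  expect_true(m$converged)
})

test_that("perfect separation is flagged but still yields a usable model", {
  d <- symmetric_1d(sd = 0.01)
  expect_warning(m <- train_logistic(d$x, d$labels),
                 class = "rrgamma_separation_warning")
  expect_false(m$converged)
  expect_identical(predict(m, d$x, type = "class"), d$labels)
})

test_that("stratified split evaluation is seeded and accurate when separable", {
  d <- symmetric_1d(sd = 0.05)
  r1 <- evaluate_split(d$x, d$labels, seed = 3)
  expect_equal(r1$accuracy, 1.0)
  expect_equal(r1$n_train + r1$n_val, 100)
  expect_equal(r1$n_val, 20)
  r2 <- evaluate_split(d$x, d$labels, seed = 3)
  expect_identical(r1$accuracy, r2$accuracy)
})

test_that("shuffled labels give chance-level accuracy", {
  set.seed(9)
  x <- matrix(rnorm(400), ncol = 2, dimnames = list(NULL, c("u", "v")))
  labels <- sample(rep(c("A", "B"), each = 100))
  accs <- vapply(1:10, function(s)
    evaluate_split(x, labels, seed = s)$accuracy, numeric(1))
  p0 <- 0.5
  expect_lt(abs(mean(accs) - p0), 3 * sqrt(p0 * (1 - p0) / (40 * 10)) + 0.05)
})

test_that("gamma-selected multivariate subsets beat mean RR alone (majority of seeds)", {
  wins <- 0L
  for (s in 1:10) {
    ds <- make_dataset(60, 40, 60, seed = 500 + s)
    fm <- feature_matrix(ds, 10)
    x <- fm[-(1:2)]
    ga <- gamma_analysis(x, fm$label, max_size = 2)
    acc_g <- evaluate_split(x, fm$label, subset = ga$subsets[[2]], seed = s)$accuracy
    acc_mean <- evaluate_split(x, fm$label, subset = "mean_d0", seed = s)$accuracy
    wins <- wins + (acc_g >= acc_mean)
  }
  expect_gte(wins, 6)
})

test_that("duration sweep: full window equals the untruncated evaluation", {
  ds <- make_dataset(30, 20, 60, seed = 71)
  fm <- feature_matrix(ds, 2)
  subset <- c("mean_d1", "sd_d1")
  sw <- duration_sweep(ds, c(60), list(subset), seed = 4)
  ref <- evaluate_split(fm[-(1:2)], fm$label, subset = subset, seed = 4)
  expect_equal(sw$accuracy["60s", 1], ref$accuracy, ignore_attr = TRUE)
})

test_that("short windows disqualify high-order subsets but not low orders", {
  ds <- make_dataset(12, 12, 60, seed = 99)
  sw <- duration_sweep(ds, c(3, 60),
                       list(c("mean_d10", "sd_d10"), c("mean_d0", "sd_d0")),
                       seed = 2)
  # order 10 needs 13 beats: impossible in 3 s at these heart rates
  expect_true(is.na(sw$accuracy["3s", 1]))
  expect_false(is.na(sw$accuracy["60s", 1]))
  # order 0 needs only 4 beats: evaluable in the same 3 s windows
  expect_false(is.na(sw$accuracy["3s", 2]))
  expect_gte(sw$n_used["3s", 2], 4)
})

test_that("fisher axis matches geometry and closed-form algebra", {
  set.seed(12)
  # spherical classes: axis parallel to the mean difference
  x <- rbind(matrix(rnorm(400), ncol = 2), sweep(matrix(rnorm(400), ncol = 2),
                                                 2, c(3, 1), "+"))
  colnames(x) <- c("u", "v")
  labels <- rep(c("A", "B"), each = 200)
  w <- fisher_axis(x, labels)
  delta <- c(3, 1) / sqrt(10)
  expect_gt(abs(sum(w * delta)), 0.98)
  # class swap flips the sign
  w2 <- fisher_axis(x, factor(labels, levels = c("B", "A")))
  expect_equal(w2, -w, tolerance = 1e-12)

  # 2x2 anisotropic closed form
  x1 <- matrix(rnorm(4000), ncol = 2) %*% diag(c(1, 0.2))
  x2 <- sweep(matrix(rnorm(4000), ncol = 2) %*% diag(c(1, 0.2)), 2, c(1, 1), "+")
  colnames(x1) <- colnames(x2) <- c("u", "v")
  xx <- rbind(x1, x2)
  ll <- rep(c("A", "B"), each = 2000)
  w3 <- fisher_axis(xx, ll)
  n <- nrow(x1)
  Sp <- ((n - 1) * cov(x1) + (n - 1) * cov(x2)) / (2 * n - 2)
  hand <- solve(Sp) %*% (colMeans(x2) - colMeans(x1))
  hand <- drop(hand / sqrt(sum(hand^2)))
  expect_equal(unname(w3), unname(hand), tolerance = 1e-10)
})

test_that("PCA components are ordered and capture rank structure", {
  set.seed(4)
  base <- rnorm(100)
  rank1 <- cbind(a = base, b = 2 * base, c = -base) + 1e-6 * matrix(rnorm(300), 100)
  p <- pca_components(rank1, 3)
  expect_gte(p$explained[1], 0.9999)
  expect_true(all(diff(p$explained_all) <= 1e-12))

  iso <- matrix(rnorm(3000), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  pi_ <- pca_components(iso, 3)
  expect_true(all(abs(pi_$explained - 1 / 3) < 0.1))
})
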