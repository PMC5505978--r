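# Independent oracles kept deliberately separate from the package's
# implementation paths.

# Ray-surface oracle: root-find the parameter t at which the ray
# mu + t * u pierces the 1-SD ellipsoid surface (x-mu)' S^-1 (x-mu) = 1.
oracle_ray_radius <- function(S, u) {
  Sinv <- solve(S)
  f <- function(t) {
    x <- t * u
    drop(t(x) %*% Sinv %*% x) - 1
  }
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-14)$root
}

oracle_pair_distance <- function(mu1, S1, mu2, S2) {
  delta <- mu2 - mu1
  D <- sqrt(sum(delta^2))
  u <- delta / D
  r1 <- oracle_ray_radius(S1, u)
  r2 <- oracle_ray_radius(S2, u)
  (D - r1 - r2) / (r1 + r2)
}

# random symmetric positive-definite matrix
random_spd <- function(d) {
  A <- matrix(rnorm(d * d), d)
  crossprod(A) + diag(d) * 0.1
}

# Brute-force subset search by direct enumeration with utils::combn and
# per-subset ellipsoid fits (independent of the package's incremental
# iterator and summary-statistic path).
oracle_best_subsets <- function(x, labels, max_size) {
  x <- as.matrix(x)
  labels <- factor(labels)
  g1 <- x[labels == levels(labels)[1], , drop = FALSE]
  g2 <- x[labels == levels(labels)[2], , drop = FALSE]
  out <- list()
  for (n in seq_len(max_size)) {
    combs <- utils::combn(ncol(x), n)
    gammas <- apply(combs, 2, function(idx) {
      e1 <- fit_ellipsoid(g1[, idx, drop = FALSE])
      e2 <- fit_ellipsoid(g2[, idx, drop = FALSE])
      pair_distance(e1, e2)
    })
    best <- which.max(gammas) # first maximum = lexicographically smallest
    out[[n]] <- list(subset = colnames(x)[combs[, best]], gamma = gammas[best])
  }
  out
}

# constant-rhythm fixture; rr defaults to a binary-exact value so that
# interval diffs are bitwise constant and derivatives exactly zero
constant_beats <- function(rr = 0.5, n = 76) {
  beat_sequence((0:(n - 1)) * rr, label = "NSR")
}

# interval implied for a printed univariate gamma when the four printed
# two-decimal inputs each carry +-0.005 rounding
gamma_rounding_interval <- function(mu1, sd1, mu2, sd2) {
  diff <- abs(mu2 - mu1)
  s <- sd1 + sd2
  lo <- (diff - 0.01 - (s + 0.01)) / (s + 0.01)
  hi <- (diff + 0.01 - (s - 0.01)) / (s - 0.01)
  c(lo, hi)
}
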