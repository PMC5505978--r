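#' Group ellipsoid model
#'
#' Models one rhythm group in a selected-variable space as the
#' 1-standard-deviation level surface of its sample mean and unbiased
#' sample covariance. A tiny ridge `1e-10 * mean(diag(Sigma))` (scale 1
#' when the covariance is identically zero) keeps the matrix positive
#' definite.
#'
#' @param x numeric matrix or data.frame, samples in rows (n >= 2).
#' @param group_id group tag ("NSR", "AF", ...).
#' @return object of class `group_ellipsoid` with fields `center`,
#'   `covariance`, `n`, `group_id`.
#' @export
fit_ellipsoid <- function(x, group_id = "group") {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L)
    rr_abort("rrgamma_insufficient_data", "need >= 2 samples per group")
  center <- colMeans(x)
  S <- stats::cov(x)
  S <- ridge_psd(S)
  structure(list(center = center, covariance = S, n = nrow(x),
                 group_id = as.character(group_id)[1]),
            class = "group_ellipsoid")
}

ridge_psd <- function(S, eps = 1e-10) {
  S <- as.matrix(S)
  scale <- mean(diag(S))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  S + eps * scale * diag(nrow(S))
}

#' @export
print.group_ellipsoid <- function(x, ...) {
  cat(sprintf("<group_ellipsoid> %s: n = %d, dim = %d\n",
              x$group_id, x$n, length(x$center)))
  invisible(x)
}

## Radius of the 1-SD ellipsoid surface along unit direction u:
## the ray mu + t*u meets (x-mu)' Sigma^-1 (x-mu) = 1 at
## t = 1 / sqrt(u' Sigma^-1 u).
ray_radius <- function(S, u) {
  S <- as.matrix(S)
  if (nrow(S) == 1L) return(sqrt(as.numeric(S)))
  q <- tryCatch(drop(crossprod(u, solve(S, u))), error = function(e) Inf)
  if (!is.finite(q) || q <= 0) return(0)
  1 / sqrt(q)
}

pair_distance_raw <- function(mu1, S1, mu2, S2) {
  delta <- mu2 - mu1
  D <- sqrt(sum(delta^2))
  if (D == 0) {
    if (sum(diag(as.matrix(S1))) + sum(diag(as.matrix(S2))) == 0)
      rr_abort("rrgamma_degenerate_groups",
               "coincident centers with zero-extent groups")
    return(-1)
  }
  u <- delta / D
  R <- ray_radius(S1, u) + ray_radius(S2, u)
  if (R == 0) return(Inf)
  (D - R) / R
}

#' Normalized surface-to-surface distance between two group ellipsoids
#'
#' With `u` the unit vector along the mean-mean axis and
#' `r_k = 1 / sqrt(u' Sigma_k^-1 u)` the radius at which that axis
#' pierces group k's 1-SD ellipsoid surface, the distance is
#' `d = (||mu2 - mu1|| - r1 - r2) / (r1 + r2)`: positive when the
#' surfaces do not overlap along the axis, negative when they do, and
#' exactly -1 when the centers coincide. In one dimension this reduces
#' to `(|mu1 - mu2| - (sd1 + sd2)) / (sd1 + sd2)`.
#'
#' @param e1,e2 [fit_ellipsoid()] objects of equal dimension.
#' @return scalar distance (`Inf` when both radii vanish along the axis
#'   but the centers differ).
#' @export
pair_distance <- function(e1, e2) {
  stopifnot(inherits(e1, "group_ellipsoid"), inherits(e2, "group_ellipsoid"))
  if (length(e1$center) != length(e2$center))
    stop("ellipsoids have different dimensions")
  pair_distance_raw(e1$center, e1$covariance, e2$center, e2$covariance)
}

#' The gamma metric over a set of groups
#'
#' Sum of [pair_distance()] over all unordered group pairs. For two
#' groups this is the pair distance itself; it is bounded below by -1
#' per pair, reaching -1 exactly when centers coincide.
#'
#' @param groups list of [fit_ellipsoid()] objects (K >= 2).
#' @return object of class `gamma_result` with fields `gamma`,
#'   `pair_distances` (named by "id1/id2"), `K`, `dim`.
#' @export
gamma_metric <- function(groups) {
  stopifnot(is.list(groups))
  K <- length(groups)
  if (K < 2L)
    rr_abort("rrgamma_insufficient_groups", "gamma needs at least 2 groups")
  ids <- vapply(seq_len(K), function(i) {
    id <- groups[[i]]$group_id
    if (is.null(id) || !nzchar(id)) as.character(i) else id
  }, character(1))
  pairs <- utils::combn(K, 2)
  d <- apply(pairs, 2, function(p) pair_distance(groups[[p[1]]], groups[[p[2]]]))
  names(d) <- apply(pairs, 2, function(p) paste(ids[p], collapse = "/"))
  structure(list(gamma = sum(d), pair_distances = d, K = K,
                 dim = length(groups[[1]]$center)),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> gamma = %.4f over K = %d groups (dim %d)\n",
              x$gamma, x$K, x$dim))
  invisible(x)
}

#' Univariate gamma from group summary statistics
#'
#' Closed form of the two-group gamma metric in one dimension, taking
#' each group's mean and standard deviation directly:
#' `(|mu2 - mu1| - (sd1 + sd2)) / (sd1 + sd2)`.
#'
#' @param mu1,sd1 first group mean and SD (sd >= 0).
#' @param mu2,sd2 second group mean and SD.
#' @return scalar gamma (`Inf` for separated zero-width groups).
#' @examples
#' univariate_gamma(0.14, 0.10, 2.58, 0.75) # 1.87 at two decimals
#' @export
univariate_gamma <- function(mu1, sd1, mu2, sd2) {
  stopifnot(sd1 >= 0, sd2 >= 0)
  s <- sd1 + sd2
  if (s == 0) {
    if (mu1 == mu2)
      rr_abort("rrgamma_degenerate_groups",
               "identical point groups have no defined separation")
    return(Inf)
  }
  (abs(mu2 - mu1) - s) / s
}
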