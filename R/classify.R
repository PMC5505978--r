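#' Unregularized logistic regression on a feature subset
#'
#' Maximum-likelihood logistic regression (no penalty) fitted by
#' iteratively reweighted least squares with gradient tolerance 1e-8 and
#' at most 100 iterations. Features are standardized internally on the
#' training set for optimizer stability (high-order derivative features
#' span several orders of magnitude) — mathematically neutral for
#' unpenalized ML — and the weights are reported back on the original
#' scale. Perfect separation (which makes the unpenalized ML diverge) is
#' reported via `converged = FALSE` and a warning; the capped-iteration
#' fit defines the model.
#'
#' @param x feature matrix or data.frame.
#' @param labels 2-level factor (or coercible); the second level is the
#'   positive class.
#' @param subset optional character vector of column names (default: all
#'   numeric columns).
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return object of class `rhythm_logit` with fields `weights`,
#'   `intercept`, `subset`, `converged`, `iterations`, `levels`.
#' @export
train_logistic <- function(x, labels, subset = NULL,
                           max_iter = 100L, tol = 1e-8) {
  xm <- select_features(x, subset)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two classes required")
  if (anyNA(xm)) stop("missing feature values are not allowed")
  y <- as.integer(labels == levels(labels)[2])
  mu <- colMeans(xm)
  sdev <- apply(xm, 2, stats::sd)
  sdev[sdev == 0] <- 1
  xs <- sweep(sweep(xm, 2, mu), 2, sdev, "/")
  X <- cbind(`(Intercept)` = 1, xs)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = tol,
                                                maxit = max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  ## complete separation can also stall the deviance at ~0 before glm's
  ## own extreme-probability warning fires: every fitted probability
  ## sitting hard against 0 or 1 is the same pathology
  if (all(pmin(fit$fitted.values, 1 - fit$fitted.values) < 1e-6))
    separated <- TRUE
  converged <- isTRUE(fit$converged) && !separated
  if (!converged)
    warning(structure(
      class = c("rrgamma_separation_warning", "warning", "condition"),
      list(message = "logistic fit did not converge (likely perfect separation); capped-iteration model returned",
           call = sys.call(-1))))
  b <- fit$coefficients
  w_std <- b[-1]
  weights <- w_std / sdev
  intercept <- b[1] - sum(w_std * mu / sdev)
  structure(list(weights = weights, intercept = unname(intercept),
                 subset = colnames(xm), converged = converged,
                 iterations = fit$iter, levels = levels(labels)),
            class = "rhythm_logit")
}

select_features <- function(x, subset) {
  if (is.data.frame(x)) x <- x[vapply(x, is.numeric, logical(1))]
  xm <- as.matrix(x)
  storage.mode(xm) <- "double"
  if (!is.null(subset)) {
    missing <- setdiff(subset, colnames(xm))
    if (length(missing))
      stop("unknown feature(s): ", paste(missing, collapse = ", "))
    xm <- xm[, subset, drop = FALSE]
  }
  xm
}

#' @export
print.rhythm_logit <- function(x, ...) {
  cat(sprintf("<rhythm_logit> %s vs %s; %d feature(s); %s in %d iterations\n",
              x$levels[1], x$levels[2], length(x$weights),
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(coef(x))
  invisible(x)
}

#' @export
coef.rhythm_logit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$weights)
}

#' @export
predict.rhythm_logit <- function(object, newdata,
                                 type = c("response", "class", "link"), ...) {
  type <- match.arg(type)
  xm <- select_features(newdata, object$subset)
  eta <- drop(xm %*% object$weights) + object$intercept
  switch(type,
         link = eta,
         response = stats::plogis(eta),
         class = object$levels[1L + (stats::plogis(eta) > 0.5)])
}

#' Hold-out accuracy under a stratified 80/20 split
#'
#' Splits the samples class-by-class (seeded) into a training subset
#' (80 % by default) and a validation subset, fits [train_logistic()] on
#' the training part and reports the fraction of correct validation
#' predictions.
#'
#' @inheritParams train_logistic
#' @param seed RNG seed controlling the split.
#' @param train_frac training fraction (default 0.8).
#' @return object of class `split_report`: `accuracy`, `n_train`,
#'   `n_val`, `split`, `seed`, `subset`, `converged`.
#' @export
evaluate_split <- function(x, labels, subset = NULL, seed = NULL,
                           train_frac = 0.8) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two classes required")
  xm <- select_features(x, subset)
  with_seed(seed, {
    idx_tr <- integer(0)
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      n_tr <- round(train_frac * length(idx))
      if (n_tr < 1L || length(idx) - n_tr < 1L)
        rr_abort("rrgamma_stratification_error",
                 sprintf("class %s cannot populate both splits", lv))
      idx_tr <- c(idx_tr, sample(idx, n_tr))
    }
    idx_val <- setdiff(seq_along(labels), idx_tr)
    model <- suppressWarnings(
      train_logistic(xm[idx_tr, , drop = FALSE], labels[idx_tr]))
    pred <- predict(model, xm[idx_val, , drop = FALSE], type = "class")
    structure(list(
      accuracy = mean(pred == as.character(labels[idx_val])),
      split = c(train = train_frac, val = 1 - train_frac),
      seed = seed, n_train = length(idx_tr), n_val = length(idx_val),
      subset = colnames(xm), converged = model$converged),
      class = "split_report")
  })
}

#' @export
print.split_report <- function(x, ...) {
  cat(sprintf("<split_report> accuracy = %.3f (train %d / val %d)%s\n",
              x$accuracy, x$n_train, x$n_val,
              if (x$converged) "" else " [non-converged fit]"))
  invisible(x)
}

#' Classification accuracy versus observation time
#'
#' For each window length, truncates every beat sequence to that
#' duration, re-extracts the state variables, and evaluates each feature
#' subset with [evaluate_split()]. Sequences too short for the required
#' derivative order at a given duration are dropped for that cell;
#' cells whose evaluable samples cannot populate a stratified split are
#' reported as `NA` rather than failing the sweep.
#'
#' @param dataset list of labelled [beat_sequence()] objects.
#' @param durations window lengths, seconds.
#' @param subsets list of character vectors of feature names.
#' @param seed RNG seed for the splits.
#' @param max_order derivative order to extract; default is the highest
#'   order any subset references.
#' @return object of class `duration_sweep`: `accuracy` matrix
#'   (durations x subsets), `n_used`, `durations`, `subsets`, `seed`.
#' @export
duration_sweep <- function(dataset, durations, subsets, seed = NULL,
                           max_order = NULL) {
  stopifnot(is.list(dataset), is.list(subsets), length(durations) >= 1L)
  subset_order <- function(feats) {
    ord <- suppressWarnings(as.integer(sub("^(mean|sd)_d", "", feats)))
    if (anyNA(ord)) stop("subset feature names must be mean_d<k>/sd_d<k>")
    max(ord)
  }
  orders <- vapply(subsets, subset_order, integer(1))
  if (!is.null(max_order)) orders[] <- as.integer(max_order)
  sub_names <- vapply(subsets, paste, character(1), collapse = "+")
  acc <- matrix(NA_real_, length(durations), length(subsets),
                dimnames = list(paste0(durations, "s"), sub_names))
  n_used <- matrix(0L, length(durations), length(subsets),
                   dimnames = dimnames(acc))
  labels_all <- dataset_labels(dataset)
  for (di in seq_along(durations)) {
    trunc <- lapply(dataset, function(b) {
      tryCatch(truncate_to_duration(b, durations[di]),
               rrgamma_insufficient_data = function(e) NULL)
    })
    ## features are re-extracted per subset at that subset's own top
    ## order, so short windows only disqualify the subsets that actually
    ## need long series
    for (si in seq_along(subsets)) {
      rows <- lapply(trunc, function(b) {
        if (is.null(b)) return(NULL)
        tryCatch(extract_features(b, orders[si]),
                 rrgamma_insufficient_data = function(e) NULL)
      })
      ok <- !vapply(rows, is.null, logical(1))
      if (sum(ok) < 4L) next
      fm <- do.call(rbind, rows[ok])
      labs <- factor(labels_all[ok])
      if (nlevels(labs) != 2L) next
      rep <- tryCatch(
        evaluate_split(fm, labs, subset = subsets[[si]], seed = seed),
        rrgamma_stratification_error = function(e) NULL)
      if (!is.null(rep)) {
        acc[di, si] <- rep$accuracy
        n_used[di, si] <- sum(ok)
      }
    }
  }
  structure(list(accuracy = acc, n_used = n_used, durations = durations,
                 subsets = subsets, seed = seed),
            class = "duration_sweep")
}

#' @export
print.duration_sweep <- function(x, ...) {
  cat("<duration_sweep> accuracy by observation window:\n")
  print(round(x$accuracy, 3))
  invisible(x)
}

#' @export
plot.duration_sweep <- function(x, ...) {
  graphics::matplot(x$durations, x$accuracy, type = "b", pch = 19,
                    xlab = "observation time (s)", ylab = "accuracy", ...)
  graphics::legend("bottomright", colnames(x$accuracy),
                   col = seq_len(ncol(x$accuracy)), lty = seq_len(ncol(x$accuracy)),
                   cex = 0.8, bty = "n")
  invisible(x)
}

#' Fisher discriminant axis
#'
#' The two-class linear discriminant direction
#' `w proportional to S_pooled^-1 (mu2 - mu1)` (pooled within-class
#' covariance), returned with unit norm; projecting samples on `w`
#' yields a one-dimensional classifier input.
#'
#' @inheritParams train_logistic
#' @return unit-norm named numeric vector.
#' @export
fisher_axis <- function(x, labels) {
  xm <- select_features(x, NULL)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two classes required")
  i1 <- labels == levels(labels)[1]
  x1 <- xm[i1, , drop = FALSE]; x2 <- xm[!i1, , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2)
  Sp <- ((n1 - 1) * stats::cov(x1) + (n2 - 1) * stats::cov(x2)) / (n1 + n2 - 2)
  delta <- colMeans(x2) - colMeans(x1)
  w <- tryCatch(solve(Sp, delta), error = function(e) {
    warning("singular pooled covariance; ridge applied")
    solve(ridge_psd(Sp, eps = 1e-8), delta)
  })
  w / sqrt(sum(w^2))
}

#' Principal components of the pooled feature matrix
#'
#' Label-blind PCA (centered, unscaled covariance eigenvectors in
#' descending eigenvalue order), whose leading components serve as
#' baseline classifier inputs.
#'
#' @param x feature matrix or data.frame.
#' @param n_components number of components to return.
#' @return list with `rotation` (loadings), `scores`,
#'   `explained` (variance fractions for the returned components),
#'   `explained_all`, `center`.
#' @export
pca_components <- function(x, n_components = 2L) {
  xm <- select_features(x, NULL)
  if (n_components > ncol(xm)) stop("more components than features")
  p <- stats::prcomp(xm, center = TRUE, scale. = FALSE)
  frac <- p$sdev^2 / sum(p$sdev^2)
  k <- seq_len(n_components)
  list(rotation = p$rotation[, k, drop = FALSE],
       scores = p$x[, k, drop = FALSE],
       explained = frac[k], explained_all = frac, center = p$center)
}
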