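#' Canonical state-variable names
#'
#' Two operators (arithmetic mean, unbiased-variance standard deviation)
#' applied to derivative orders `0..max_order`, named `mean_d<k>` and
#' `sd_d<k>`. The canonical ordering (all means, then all SDs, by order)
#' is used everywhere: feature tables, subset-search tie-breaking, CSVs.
#'
#' @param max_order highest derivative order (default 10, giving the
#'   22-variable grid).
#' @return character vector of feature names.
#' @export
feature_names <- function(max_order = 10L) {
  k <- 0:max_order
  c(paste0("mean_d", k), paste0("sd_d", k))
}

as_series_values <- function(s) {
  if (inherits(s, "rr_series")) s$values else as.numeric(s)
}

#' Arithmetic mean of a series
#' @param s an [rr_series()] or numeric vector.
#' @return scalar mean.
#' @export
series_mean <- function(s) {
  x <- as_series_values(s)
  if (length(x) < 1L) rr_abort("rrgamma_insufficient_data", "empty series")
  mean(x)
}

#' Standard deviation of a series (unbiased variance)
#'
#' Square root of the n-1-denominator sample variance.
#'
#' @param s an [rr_series()] or numeric vector with at least 2 values.
#' @return scalar standard deviation.
#' @export
series_sd <- function(s) {
  x <- as_series_values(s)
  if (length(x) < 2L)
    rr_abort("rrgamma_insufficient_data", "need >= 2 values for a SD")
  stats::sd(x)
}

#' State variables of one beat sequence
#'
#' Builds the derivative stack of the tachogram and applies the mean and
#' SD operators to every order, yielding `2 * (max_order + 1)` state
#' variables (22 with the default grid). Requires at least 2 samples at
#' the top order, i.e. `max_order + 3` beats.
#'
#' @param beats a [beat_sequence()].
#' @param max_order highest derivative order (default 10).
#' @return named numeric vector in canonical [feature_names()] order,
#'   with attributes `label` and `record_id`.
#' @export
extract_features <- function(beats, max_order = 10L) {
  rr <- beats_to_rr(beats)
  if (length(rr$values) < max_order + 2L)
    rr_abort("rrgamma_insufficient_data",
             sprintf("%d intervals cannot support SD at order %d",
                     length(rr$values), max_order))
  stack <- derivative_stack(rr, max_order)
  means <- vapply(stack$series, function(s) mean(s$values), numeric(1))
  sds   <- vapply(stack$series, function(s) stats::sd(s$values), numeric(1))
  out <- c(means, sds)
  names(out) <- feature_names(max_order)
  attr(out, "label") <- beats$label
  attr(out, "record_id") <- beats$record_id
  out
}

#' Feature table for a labelled dataset
#'
#' Applies [extract_features()] to every beat sequence and assembles the
#' canonical feature table (`record_id`, `label`, then the feature grid).
#' Sequences too short for the requested grid raise an error unless
#' `drop_incomplete = TRUE`, in which case they are dropped with a
#' message.
#'
#' @param dataset list of [beat_sequence()] objects.
#' @param max_order highest derivative order (default 10).
#' @param drop_incomplete drop sequences that cannot support the grid?
#' @return data.frame with columns `record_id`, `label`,
#'   `mean_d0..sd_d<max_order>`.
#' @export
feature_matrix <- function(dataset, max_order = 10L, drop_incomplete = FALSE) {
  stopifnot(is.list(dataset), length(dataset) >= 1L)
  rows <- lapply(dataset, function(b) {
    tryCatch(extract_features(b, max_order),
             rrgamma_insufficient_data = function(e) {
               if (drop_incomplete) NULL else stop(e)
             })
  })
  ok <- !vapply(rows, is.null, logical(1))
  if (!all(ok))
    message(sprintf("feature_matrix: dropped %d sequence(s) too short for order %d",
                    sum(!ok), max_order))
  rows <- rows[ok]
  if (length(rows) == 0L)
    rr_abort("rrgamma_insufficient_data", "no sequence supports the feature grid")
  mat <- do.call(rbind, rows)
  out <- data.frame(
    record_id = vapply(rows, function(r) attr(r, "record_id") %||% "", character(1)),
    label = vapply(rows, function(r) attr(r, "label") %||% "unlabeled", character(1)),
    mat, stringsAsFactors = FALSE, row.names = NULL
  )
  names(out) <- c("record_id", "label", feature_names(max_order))
  out
}

#' Correlation matrix of derivative orders
#'
#' Absolute Pearson correlations between the order-i and order-j series
#' of a stack. Because derived timestamps keep left endpoints, the
#' order-j series' time base is a prefix of the order-i one (j > i);
#' pairs are aligned on that shared prefix by trimming the longer
#' series' tail. Zero-variance pairings are reported as `NA` rather than
#' fabricated zeros; the diagonal is exactly 1.
#'
#' @param stack a [derivative_stack()].
#' @return `(max_order + 1)` square matrix of values in `[0, 1]` or `NA`.
#' @export
correlation_matrix <- function(stack) {
  stopifnot(inherits(stack, "derivative_stack"))
  m <- stack$max_order
  M <- matrix(NA_real_, m + 1L, m + 1L,
              dimnames = list(paste0("d", 0:m), paste0("d", 0:m)))
  for (i in 0:m) for (j in i:m) {
    L <- length(stack$series[[j + 1L]]$values)
    if (L < 2L) next
    xi <- stack$series[[i + 1L]]$values[seq_len(L)]
    xj <- stack$series[[j + 1L]]$values
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
    M[i + 1L, j + 1L] <- M[j + 1L, i + 1L] <- abs(stats::cor(xi, xj))
  }
  diag(M) <- 1
  M
}
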