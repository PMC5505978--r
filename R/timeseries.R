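#' Sampled (derived) RR series
#'
#' A series `x[n]` with time base `t_n`: the tachogram itself at order 0
#' (values are RR intervals in seconds) or its order-`k` time derivative
#' (units s^(1-k)). Timestamps are strictly increasing and carry, for
#' derived series, the left endpoint of each difference.
#'
#' @param values numeric vector `x[n]`.
#' @param timestamps numeric vector `t_n`, seconds, same length as values.
#' @param order derivative order, non-negative integer (0 = tachogram).
#' @param label,record_id provenance tags, see [beat_sequence()].
#' @return an object of class `rr_series`.
#' @export
rr_series <- function(values, timestamps, order = 0L,
                      label = "unlabeled", record_id = "") {
  values <- as.numeric(values)
  timestamps <- as.numeric(timestamps)
  order <- as.integer(order)
  if (length(values) != length(timestamps))
    stop("values and timestamps must have equal length")
  if (length(values) < 1L)
    rr_abort("rrgamma_insufficient_data", "empty series")
  if (any(!is.finite(values)) || any(!is.finite(timestamps)))
    stop("series values and timestamps must be finite")
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  if (order < 0L) stop("order must be >= 0")
  if (order == 0L && any(values <= 0))
    stop("order-0 RR intervals must be positive")
  structure(list(values = values, timestamps = timestamps, order = order,
                 label = as.character(label)[1],
                 record_id = as.character(record_id)[1]),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> order %d, %d samples, label = %s\n",
              x$order, length(x$values), x$label))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$values)

#' Forward finite-difference derivative of a series
#'
#' One application of the forward difference
#' `(x[n+1] - x[n]) / (t[n+1] - t[n])`, producing the next derivative
#' order. The result keeps the left endpoint `t_n` of each difference as
#' its timestamp so that differencing can be iterated.
#'
#' @param s an [rr_series()] with at least 2 samples.
#' @return an [rr_series()] of order `s$order + 1`, one sample shorter.
#' @export
finite_difference <- function(s) {
  stopifnot(inherits(s, "rr_series"))
  n <- length(s$values)
  if (n < 2L)
    rr_abort("rrgamma_insufficient_data",
             "need at least 2 samples to difference")
  dt <- diff(s$timestamps)
  if (any(dt == 0))
    rr_abort("rrgamma_zero_time_step", "duplicate timestamps in series")
  rr_series(values = diff(s$values) / dt,
            timestamps = s$timestamps[-n],
            order = s$order + 1L,
            label = s$label, record_id = s$record_id)
}

#' Stack of derivative orders 0..max_order
#'
#' Repeatedly applies [finite_difference()] to an order-0 tachogram.
#' Element `k + 1` of `$series` holds order `k`; each order is one sample
#' shorter than the previous.
#'
#' @param rr an order-0 [rr_series()].
#' @param max_order highest derivative order (default 10).
#' @return an object of class `derivative_stack`.
#' @export
derivative_stack <- function(rr, max_order = 10L) {
  stopifnot(inherits(rr, "rr_series"))
  max_order <- as.integer(max_order)
  if (rr$order != 0L) stop("derivative_stack starts from an order-0 series")
  if (max_order < 0L) stop("max_order must be >= 0")
  if (length(rr$values) <= max_order)
    rr_abort("rrgamma_insufficient_data",
             sprintf("series of length %d too short for order %d",
                     length(rr$values), max_order))
  series <- vector("list", max_order + 1L)
  series[[1L]] <- rr
  s <- rr
  for (k in seq_len(max_order)) {
    s <- finite_difference(s)
    series[[k + 1L]] <- s
  }
  structure(list(series = series, max_order = max_order),
            class = "derivative_stack")
}

#' @export
print.derivative_stack <- function(x, ...) {
  cat(sprintf("<derivative_stack> orders 0..%d, base length %d\n",
              x$max_order, length(x$series[[1]]$values)))
  invisible(x)
}
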