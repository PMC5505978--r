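## Truncated-normal scalar draw by rejection (bounds a few SD out, so
## the loop terminates immediately in practice).
rtrunc1 <- function(mean, sd, lower, upper) {
  if (sd == 0) return(min(max(mean, lower), upper))
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
}

## Expected ratio E[sample var] / marginal var for an AR(1) of length n
## with lag-1 coefficient phi; used to bias-correct the innovation scale
## so realized per-series sample SDs hit their target.
ar1_sd_bias <- function(n, phi) {
  if (n < 2 || phi == 0) return(1)
  k <- seq_len(n - 1)
  1 - (2 / (n * (n - 1))) * sum((n - k) * phi^k)
}

#' Simulate a normal-sinus-rhythm beat sequence
#'
#' One 1-min-style NSR tachogram: the per-series mean RR is drawn from a
#' Normal(0.80, 0.15^2) truncated to `[0.5, 1.2]` s (the between-series
#' spread of the NSR population), and beat-to-beat fluctuation is an
#' AR(1) process (lag-1 coefficient `autocorr`, default 0.95 — sinus
#' rhythm is smooth) superposed with a sinusoidal respiratory modulation
#' near 0.25 Hz. The total within-series SD is drawn per series from a
#' Normal(0.04, 0.02^2) truncated to `[0.005, 0.10]` s and split between
#' the respiratory and AR components by `resp_frac`; the AR innovation
#' scale is bias-corrected so the realized sample SD matches the drawn
#' target. RR values are floored at 0.3 s by redrawing (a safeguard
#' ~12 SD from the mean at the defaults).
#'
#' @param duration_s recording length, seconds (default 60).
#' @param mean_rr per-series mean RR, seconds; `NULL` draws it.
#' @param within_sd per-series beat-to-beat SD, seconds; `NULL` draws it.
#' @param autocorr lag-1 AR coefficient in `[0, 1)`.
#' @param resp_freq respiratory modulation frequency, Hz.
#' @param resp_frac fraction of the within-series SD assigned to the
#'   respiratory sinusoid (0-1).
#' @param rr_floor smallest admissible RR interval, seconds.
#' @param seed optional RNG seed.
#' @param record_id provenance tag.
#' @return a [beat_sequence()] labelled "NSR".
#' @export
simulate_nsr <- function(duration_s = 60, mean_rr = NULL, within_sd = NULL,
                         autocorr = 0.95, resp_freq = 0.25, resp_frac = 0.6,
                         rr_floor = 0.3, seed = NULL, record_id = "") {
  stopifnot(duration_s > 0, autocorr >= 0, autocorr < 1)
  with_seed(seed, {
    m <- mean_rr %||% rtrunc1(0.80, 0.15, 0.5, 1.2)
    s <- within_sd %||% rtrunc1(0.04, 0.02, 0.005, 0.10)
    if (m <= 3 * s) stop("mean_rr must exceed 3 * within_sd")
    n <- ceiling(duration_s / max(m - 3 * s, rr_floor)) + 5L
    amp <- resp_frac * s * sqrt(2)
    sd_ar <- s * sqrt(max(1 - resp_frac^2, 0))
    sd_ar <- sd_ar / sqrt(ar1_sd_bias(round(duration_s / m), autocorr))
    phase <- stats::runif(1, 0, 2 * pi) +
      2 * pi * resp_freq * m * seq_len(n)
    z <- if (sd_ar > 0) {
      innov <- stats::rnorm(n, 0, sd_ar * sqrt(1 - autocorr^2))
      as.numeric(stats::filter(innov, autocorr, method = "recursive",
                               init = stats::rnorm(1, 0, sd_ar)))
    } else rep(0, n)
    rr <- m + amp * sin(phase) + z
    bad <- which(rr < rr_floor)
    while (length(bad) > 0L) {
      rr[bad] <- m + amp * sin(phase[bad]) + stats::rnorm(length(bad), 0, sd_ar)
      bad <- which(rr < rr_floor)
    }
    beats_from_rr(rr, duration_s, label = "NSR", record_id = record_id)
  })
}

#' Simulate an atrial-fibrillation beat sequence
#'
#' One 1-min-style AF tachogram: the per-series mean RR is drawn from a
#' Normal(0.61, 0.08^2) truncated to `[0.35, 0.9]` s, and RR intervals
#' are near-independent Gamma draws (shape/rate set from the per-series
#' mean and a within-series SD drawn from Normal(0.12, 0.03^2) truncated
#' to `[0.04, 0.25]` s), coupled through a Gaussian AR(1) copula with
#' small lag-1 coefficient (default 0.1) — fibrillation conducts
#' irregularly, so successive intervals carry almost no memory. RR is
#' floored at 0.25 s by redrawing.
#'
#' @inheritParams simulate_nsr
#' @return a [beat_sequence()] labelled "AF".
#' @export
simulate_af <- function(duration_s = 60, mean_rr = NULL, within_sd = NULL,
                        autocorr = 0.1, rr_floor = 0.25, seed = NULL,
                        record_id = "") {
  stopifnot(duration_s > 0, autocorr >= 0, autocorr < 1)
  with_seed(seed, {
    m <- mean_rr %||% rtrunc1(0.61, 0.08, 0.35, 0.9)
    s <- within_sd %||% rtrunc1(0.12, 0.03, 0.04, 0.25)
    n <- ceiling(duration_s / max(m - 3 * s, rr_floor)) + 5L
    if (s == 0) {
      rr <- rep(m, n)
    } else {
      shape <- (m / s)^2
      rate <- shape / m
      z <- if (autocorr > 0) {
        innov <- stats::rnorm(n, 0, sqrt(1 - autocorr^2))
        as.numeric(stats::filter(innov, autocorr, method = "recursive",
                                 init = stats::rnorm(1)))
      } else stats::rnorm(n)
      rr <- stats::qgamma(stats::pnorm(z), shape = shape, rate = rate)
      bad <- which(rr < rr_floor)
      while (length(bad) > 0L) {
        rr[bad] <- stats::qgamma(stats::runif(length(bad)),
                                 shape = shape, rate = rate)
        bad <- which(rr < rr_floor)
      }
    }
    beats_from_rr(rr, duration_s, label = "AF", record_id = record_id)
  })
}

beats_from_rr <- function(rr, duration_s, label, record_id) {
  times <- c(0, cumsum(rr))
  keep <- times <= duration_s + 1e-12
  if (sum(keep) < 2L)
    rr_abort("rrgamma_insufficient_data",
             "duration too short for even two beats")
  beat_sequence(times[keep], label = label, record_id = record_id)
}

#' Simulate a labelled NSR/AF dataset
#'
#' Independent series from [simulate_nsr()] and [simulate_af()], with
#' record ids `NSR_001..` / `AF_001..`, reproducible under `seed`.
#'
#' @param n_nsr,n_af series counts per group (>= 1).
#' @param duration_s recording length per series, seconds.
#' @param seed optional RNG seed.
#' @return list of [beat_sequence()] objects (NSR first, then AF).
#' @export
make_dataset <- function(n_nsr, n_af, duration_s = 60, seed = NULL) {
  stopifnot(n_nsr >= 1L, n_af >= 1L)
  with_seed(seed, {
    c(lapply(seq_len(n_nsr), function(i)
        simulate_nsr(duration_s, record_id = sprintf("NSR_%04d", i))),
      lapply(seq_len(n_af), function(i)
        simulate_af(duration_s, record_id = sprintf("AF_%04d", i))))
  })
}

#' Labels of a beat-sequence dataset
#' @param dataset list of [beat_sequence()] objects.
#' @return character vector of rhythm labels.
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset, function(b) b$label, character(1))
}
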