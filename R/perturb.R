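#' Beat-timing jitter (timing uncertainty)
#'
#' Shifts every beat time by an independent draw from the uniform
#' distribution on `[-T, T]` with `T = T_ms / 1000` seconds, modelling R
#' peak detector inaccuracy. If any resulting inter-beat interval is
#' non-positive (possible at large `T` on short AF intervals) a
#' `rrgamma_perturbation_collision` error is raised rather than silently
#' re-sorting, which would change the noise model.
#'
#' @param beats a [beat_sequence()].
#' @param T_ms half-width of the jitter interval, milliseconds (> 0).
#' @param seed optional RNG seed (caller's RNG state is preserved).
#' @return a jittered [beat_sequence()] with the same label.
#' @export
jitter_beats <- function(beats, T_ms, seed = NULL) {
  stopifnot(inherits(beats, "beat_sequence"), T_ms > 0)
  T_s <- T_ms / 1000
  with_seed(seed, {
    times <- beats$times + stats::runif(length(beats$times), -T_s, T_s)
    if (any(diff(times) <= 0))
      rr_abort("rrgamma_perturbation_collision",
               sprintf("jitter T = %g ms collided with a short interval", T_ms))
    beat_sequence(times, label = beats$label, record_id = beats$record_id)
  })
}

#' Random beat deletion (missing beats)
#'
#' Removes `round(u * L)` distinct beats at indexes drawn uniformly from
#' `1..L`, `L` the original beat count, modelling missed detections.
#'
#' @param beats a [beat_sequence()].
#' @param u fraction of beats to drop, in `[0, 0.5]`.
#' @param seed optional RNG seed.
#' @return a [beat_sequence()] with `L - round(u * L)` beats.
#' @export
drop_beats <- function(beats, u, seed = NULL) {
  stopifnot(inherits(beats, "beat_sequence"), u >= 0, u <= 0.5)
  L <- length(beats$times)
  k <- round(u * L)
  if (k == 0L) return(beats)
  if (L - k < 2L)
    rr_abort("rrgamma_insufficient_data", "dropping would leave < 2 beats")
  with_seed(seed, {
    idx <- sample.int(L, k)
    beat_sequence(beats$times[-idx], label = beats$label,
                  record_id = beats$record_id)
  })
}

eligible_gaps <- function(times, min_gap = 0.4) which(diff(times) > min_gap)

#' Premature atrial contraction insertion
#'
#' Performs `round(u * L)` PAC events (L fixed at the original beat
#' count). Each event picks, uniformly among currently eligible gaps
#' (inter-beat interval > 400 ms), a gap `(b_i, b_{i+1})`, draws the
#' ectopic beat uniformly on `[b_i + 0.2, b_{i+1} - 0.2]`, inserts it,
#' and shifts `b_{i+1}` and all later beats forward by the ectopic
#' coupling interval — the sinus cycle resets, so total duration grows
#' by the sum of coupling intervals. Events are applied sequentially
#' with eligibility recomputed.
#'
#' @param beats a [beat_sequence()].
#' @param u fraction of events relative to beats, in `[0, 0.5]`.
#' @param seed optional RNG seed.
#' @return a [beat_sequence()] with `L + round(u * L)` beats.
#' @export
insert_pac <- function(beats, u, seed = NULL) {
  premature_insert(beats, u, seed, compensate = FALSE)
}

#' Premature ventricular contraction insertion
#'
#' Same ectopic placement rule as [insert_pac()], but the following
#' scheduled beat is deleted (compensatory pause) and later beats are
#' not shifted, so the beat count is unchanged.
#'
#' @inheritParams insert_pac
#' @return a [beat_sequence()] with the original beat count.
#' @export
insert_pvc <- function(beats, u, seed = NULL) {
  premature_insert(beats, u, seed, compensate = TRUE)
}

premature_insert <- function(beats, u, seed, compensate) {
  stopifnot(inherits(beats, "beat_sequence"), u >= 0, u <= 0.5)
  L <- length(beats$times)
  n_ev <- round(u * L)
  if (n_ev == 0L) return(beats)
  with_seed(seed, {
    times <- beats$times
    applied <- 0L
    for (e in seq_len(n_ev)) {
      elig <- eligible_gaps(times)
      if (length(elig) == 0L)
        rr_abort("rrgamma_eligibility_exhausted",
                 sprintf("no gap > 400 ms left after %d of %d insertions",
                         applied, n_ev),
                 applied = applied, requested = n_ev)
      g <- elig[sample.int(length(elig), 1L)]
      b <- stats::runif(1, times[g] + 0.2, times[g + 1L] - 0.2)
      if (compensate) {
        times <- c(times[seq_len(g)], b,
                   if (g + 2L <= length(times)) times[(g + 2L):length(times)])
      } else {
        shift <- b - times[g]
        times <- c(times[seq_len(g)], b,
                   times[(g + 1L):length(times)] + shift)
      }
      applied <- applied + 1L
    }
    beat_sequence(times, label = beats$label, record_id = beats$record_id)
  })
}

#' Pooled noisy NSR/AF dataset
#'
#' Builds the mixed training database used for noise-robust variable
#' selection: the NSR group is partitioned into quarters kept original /
#' corrupted by missing beats / by PAC / by PVC (any remainder goes to
#' the original quarter), each corrupted sample receiving a parameter
#' drawn uniformly from its pool; AF samples pass through unperturbed
#' here (timing-uncertainty and missing-beat sweeps on AF are run
#' separately with [jitter_beats()] / [drop_beats()]).
#'
#' @param nsr,af lists of [beat_sequence()] objects.
#' @param seed optional RNG seed.
#' @param mb_pool missing-beat fractions (default 1-5, 10, 15, 20 %).
#' @param pac_pool,pvc_pool ectopy fractions (default adds 30 %).
#' @return list with `sequences` (NSR then AF), `labels`, and a
#'   `manifest` data.frame (`record_id`, `group`, `kind`, `parameter`)
#'   enabling exact replay.
#' @export
build_pooled_noisy <- function(nsr, af, seed = NULL,
                               mb_pool = c(1:5, 10, 15, 20) / 100,
                               pac_pool = c(1:5, 10, 15, 20, 30) / 100,
                               pvc_pool = pac_pool) {
  stopifnot(length(nsr) >= 1L, length(af) >= 1L)
  with_seed(seed, {
    n <- length(nsr)
    q <- n %/% 4L
    perm <- sample.int(n)
    kinds <- rep("original", n)
    if (q > 0L) {
      kinds[perm[seq_len(q)]] <- "MB"
      kinds[perm[q + seq_len(q)]] <- "PAC"
      kinds[perm[2L * q + seq_len(q)]] <- "PVC"
    }
    params <- rep(NA_real_, n)
    out_nsr <- vector("list", n)
    for (i in seq_len(n)) {
      out_nsr[[i]] <- switch(
        kinds[i],
        original = nsr[[i]],
        MB = { params[i] <- sample(mb_pool, 1L)
               drop_beats(nsr[[i]], params[i]) },
        PAC = { params[i] <- sample(pac_pool, 1L)
                insert_pac(nsr[[i]], params[i]) },
        PVC = { params[i] <- sample(pvc_pool, 1L)
                insert_pvc(nsr[[i]], params[i]) }
      )
    }
    sequences <- c(out_nsr, af)
    manifest <- data.frame(
      record_id = vapply(sequences, function(b) b$record_id, character(1)),
      group = c(rep("NSR", n), rep("AF", length(af))),
      kind = c(kinds, rep("original", length(af))),
      parameter = c(params, rep(NA_real_, length(af))),
      stringsAsFactors = FALSE
    )
    list(sequences = sequences,
         labels = manifest$group,
         manifest = manifest)
  })
}
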