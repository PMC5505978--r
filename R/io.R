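fmt12 <- function(x) sprintf("%.12g", x)

#' Read a beat sequence from disk
#'
#' Two plain-text dialects are supported:
#' * `beat_text` — one beat occurrence time (seconds) per line, optional
#'   `#` comments and blank lines;
#' * `rr_csv` — header `t_seconds,rr_seconds`, '.' decimal separator;
#'   beat times are reconstructed by cumulative sum of the RR column,
#'   anchored so the first timestamp matches `t_seconds[1]`.
#'
#' @param path input file.
#' @param dialect one of "beat_text", "rr_csv".
#' @param label,record_id provenance tags; `record_id` defaults to the
#'   file name without extension.
#' @return a [beat_sequence()].
#' @export
read_beats <- function(path, dialect = c("beat_text", "rr_csv"),
                       label = "unlabeled", record_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    rr_abort("rrgamma_parse_error", paste("no such file:", path))
  record_id <- record_id %||% sub("\\.[^.]*$", "", basename(path))
  if (dialect == "beat_text") {
    raw <- readLines(path, warn = FALSE)
    stripped <- trimws(sub("#.*$", "", raw))
    keep <- which(nzchar(stripped))
    vals <- suppressWarnings(as.numeric(stripped[keep]))
    if (anyNA(vals))
      rr_abort("rrgamma_parse_error",
               sprintf("malformed beat time at line %d of %s",
                       keep[which(is.na(vals))[1]], path))
    times <- vals
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("t_seconds", "rr_seconds") %in% names(df)))
      rr_abort("rrgamma_parse_error",
               "rr_csv requires columns t_seconds,rr_seconds")
    rr <- as.numeric(df$rr_seconds)
    t0 <- as.numeric(df$t_seconds)
    bad <- which(!is.finite(rr) | rr <= 0)
    if (length(bad))
      rr_abort("rrgamma_parse_error",
               sprintf("non-positive RR interval at data row %d of %s",
                       bad[1], path))
    times <- t0[1] - rr[1] + c(0, cumsum(rr))
  }
  beat_sequence(times, label = label, record_id = record_id)
}

#' Write a beat sequence to disk
#'
#' Inverse of [read_beats()]; numbers are written at 12 significant
#' digits so write-read round trips are value-stable.
#'
#' @param beats a [beat_sequence()].
#' @param path output file.
#' @param dialect one of "beat_text", "rr_csv".
#' @return `path`, invisibly.
#' @export
write_beats <- function(beats, path, dialect = c("beat_text", "rr_csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(beats, "beat_sequence"))
  if (dialect == "beat_text") {
    writeLines(fmt12(beats$times), path)
  } else {
    rr <- beats_to_rr(beats)
    writeLines(c("t_seconds,rr_seconds",
                 paste(fmt12(rr$timestamps), fmt12(rr$values), sep = ",")),
               path)
  }
  invisible(path)
}

#' Write / read the canonical feature table CSV
#'
#' Fixed layout `record_id,label,mean_d0,...,mean_d<k>,sd_d0,...,sd_d<k>`
#' for cross-tool reproducibility.
#'
#' @param fm feature table from [feature_matrix()].
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_feature_table <- function(fm, path) {
  stopifnot(is.data.frame(fm), identical(names(fm)[1:2], c("record_id", "label")))
  num <- vapply(fm[-(1:2)], fmt12, character(nrow(fm)))
  if (nrow(fm) == 1L) num <- matrix(num, nrow = 1)
  out <- cbind(record_id = fm$record_id, label = fm$label, num)
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df)[1:2], c("record_id", "label")))
    rr_abort("rrgamma_parse_error",
             "feature table must start with record_id,label")
  expected <- grepl("^(mean|sd)_d[0-9]+$", names(df)[-(1:2)])
  if (!all(expected))
    rr_abort("rrgamma_parse_error", "unexpected feature column names")
  df
}
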