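#' Validate a retention data frame
#'
#' Checks and normalises a table of per-patient thyroid retention
#' measurements: one row per observation with columns `patient_id`
#' (character), `time_h` (hours post administration, strictly positive) and
#' `fraction` (fraction of administered activity in the gland, in
#' `(0, 1.5]`; measurement noise may push an observation slightly above 1
#' but not grossly). Duplicate `(patient_id, time_h)` pairs are rejected.
#'
#' @param data A data frame with columns `patient_id`, `time_h`, `fraction`.
#' @return A tibble sorted by patient then time, with attributes
#'   `n_patients` and `n_obs`.
#' @export
#' @examples
#' as_retention(data.frame(patient_id = "P1", time_h = c(2, 24),
#'                         fraction = c(0.1, 0.3)))
as_retention <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("patient_id", "time_h", "fraction")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("retention data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(data[need])
  out$patient_id <- as.character(out$patient_id)
  out$time_h <- as.numeric(out$time_h)
  out$fraction <- as.numeric(out$fraction)
  if (nrow(out) == 0) stop("retention data is empty", call. = FALSE)
  bad <- which(!is.finite(out$time_h) | out$time_h <= 0)
  if (length(bad) > 0) {
    stop("non-positive or missing time_h at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(out$fraction) | out$fraction <= 0 |
                 out$fraction > 1.5)
  if (length(bad) > 0) {
    stop("fraction outside (0, 1.5] at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(out[c("patient_id", "time_h")])
  if (any(dup)) {
    stop("duplicated (patient_id, time_h) at row(s) ",
         paste(utils::head(which(dup), 5), collapse = ", "), call. = FALSE)
  }
  out <- dplyr::arrange(out, .data$patient_id, .data$time_h)
  attr(out, "n_patients") <- dplyr::n_distinct(out$patient_id)
  attr(out, "n_obs") <- nrow(out)
  out
}

#' Read a retention table from delimited text
#'
#' Reads the standard retention format: a delimited text file with a header
#' row and columns `patient_id`, `time_h`, `fraction` (dot decimal). The
#' result is validated with [as_retention()]; schema mismatches, duplicate
#' observations and out-of-range values raise descriptive errors.
#'
#' @param path Path to a CSV (or other single-character-delimited) file.
#' @param delim Field delimiter, default `","`.
#' @return A validated retention tibble.
#' @export
read_retention <- function(path, delim = ",") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (nrow(raw) == 0) {
    stop("parse error: '", path, "' contains no data rows", call. = FALSE)
  }
  tryCatch(as_retention(raw), error = function(e) {
    stop("parse error in '", path, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Write a retention table to delimited text
#'
#' @param data A retention tibble (validated with [as_retention()]).
#' @param path Output path.
#' @param delim Field delimiter, default `","`.
#' @return `path`, invisibly.
#' @export
write_retention <- function(data, path, delim = ",") {
  data <- as_retention(data)
  readr::write_delim(data, path, delim = delim)
  invisible(path)
}

# Internal: pack a retention tibble into the 0-based index arrays the C++
# objective consumes. Ordering fixes patient identity across calls.
pack_data <- function(data) {
  data <- as_retention(data)
  ids <- unique(data$patient_id)
  idx <- match(data$patient_id, ids)
  ord <- order(idx, data$time_h)
  data <- data[ord, ]
  idx <- idx[ord]
  len <- as.integer(table(factor(idx, levels = seq_along(ids))))
  start <- cumsum(c(0L, len[-length(len)]))
  list(
    data = data, ids = ids,
    time = data$time_h, y = data$fraction,
    pat_start = start, pat_len = len,
    n_patients = length(ids), n_obs = nrow(data)
  )
}
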