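#' @useDynLib pbmsnlme, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @import dplyr
NULL

MODEL_IDS <- c("a3a", "a3b", "a4a", "a4b", "a4c", "a5a", "a5b", "a6a", "a6b")

MODEL_PARAMS <- list(
  a3a = c("a1", "l1", "l2"),
  a3b = c("l1", "l2", "l3"),
  a4a = c("a1", "a2", "l1", "l2"),
  a4b = c("a1", "a2", "l1", "l2"),
  a4c = c("a1", "l1", "l2", "l3"),
  a5a = c("a1", "a2", "l1", "l2", "l3"),
  a5b = c("a1", "a2", "l1", "l2", "l3"),
  a6a = c("a1", "a2", "a3", "l1", "l2", "l3"),
  a6b = c("a1", "a2", "a3", "l1", "l2", "l3")
)

model_code <- function(model_id) {
  match(match.arg(model_id, MODEL_IDS), MODEL_IDS) - 1L
}

#' Physical decay constant of 131-I
#'
#' \eqn{\lambda_{phys} = \ln(2) / T_{1/2}} with \eqn{T_{1/2} = 8.022} days,
#' expressed per hour. Every structural model adds this constant to the
#' biological rate in each exponential term, so retention curves describe
#' physically decaying activity. This is the package's single source for the
#' constant.
#'
#' @return The decay constant in 1/h.
#' @export
#' @examples
#' lambda_phys() # ln(2) / (8.022 * 24)
lambda_phys <- function() cpp_lambda_phys()

#' The bank of candidate retention models
#'
#' Returns the nine sum-of-exponential functions (SOEFs) considered for
#' thyroid 131-I retention, with three to six adjustable structural
#' parameters. In the mixed-effects framework each structural parameter
#' carries a fixed effect and a random-effect variance, and one residual
#' variance is added, so the fitted-parameter count is
#' `K = 2 * n_structural + 1`. Model `a3b` is the EANM SOP bi-exponential;
#' `a4c` extends it with a blood-pool amplitude `a1` and is the only model
#' that does not vanish at `t = 0`.
#'
#' @return A tibble with one row per model: `model_id`, `n_structural`,
#'   `param_names` (list-column), `nlme_K`.
#' @export
#' @examples
#' model_bank()
model_bank <- function() {
  tibble::tibble(
    model_id = MODEL_IDS,
    n_structural = unname(lengths(MODEL_PARAMS)),
    param_names = unname(MODEL_PARAMS),
    nlme_K = 2L * unname(lengths(MODEL_PARAMS)) + 1L
  )
}

check_params <- function(model_id, params) {
  wanted <- MODEL_PARAMS[[model_id]]
  if (is.null(names(params)) || !setequal(names(params), wanted) ||
      anyDuplicated(names(params))) {
    stop("model '", model_id, "' takes parameters {",
         paste(wanted, collapse = ", "), "}, got {",
         paste(names(params), collapse = ", "), "}", call. = FALSE)
  }
  p <- as.numeric(params[wanted])
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("structural parameters must be finite and >= 0", call. = FALSE)
  }
  names(p) <- wanted
  p
}

soef_denominator <- function(model_id, p) {
  switch(model_id,
    a3b = p[["l1"]] + p[["l2"]] - p[["l3"]],
    a4c = p[["l1"]] + p[["l2"]] - p[["l3"]],
    NA_real_
  )
}

#' Evaluate a structural retention model
#'
#' Computes the fraction of administered activity predicted by one of the
#' nine candidate models at the given times. All exponents include the
#' physical decay constant of 131-I (see [lambda_phys()]); amplitudes are
#' fractions of the administered activity, rates are in 1/h.
#'
#' @param model_id One of `model_bank()$model_id`.
#' @param params Named numeric vector holding exactly the model's
#'   structural parameters (see `model_bank()$param_names`); all values
#'   must be non-negative.
#' @param times Numeric vector of times post administration in hours
#'   (must be `>= 0`).
#' @return Numeric vector of predicted retention fractions.
#' @export
#' @examples
#' soef_eval("a3b", c(l1 = 0.08, l2 = 0.07, l3 = 0.001), times = c(2, 24, 96))
soef_eval <- function(model_id, params, times) {
  model_id <- match.arg(model_id, MODEL_IDS)
  p <- check_params(model_id, params)
  stopifnot(is.numeric(times), all(is.finite(times)), all(times >= 0))
  den <- soef_denominator(model_id, p)
  if (!is.na(den) && abs(den) < 1e-10) {
    stop("model '", model_id, "' is singular: |l1 + l2 - l3| = ",
         format(abs(den)), " < 1e-10", call. = FALSE)
  }
  out <- cpp_soef_eval(model_code(model_id), unname(p), as.numeric(times))
  attributes(out) <- NULL
  out
}

#' Closed-form time-integrated activity of a structural model
#'
#' Analytic value of \eqn{\int_0^\infty a(t)\,dt} in hours (per unit
#' administered activity): each exponential term `amplitude *
#' exp(-(rate + lambda_phys) * t)` integrates to
#' `amplitude / (rate + lambda_phys)`, with signs and composite rates
#' exactly as the model is written.
#'
#' @inheritParams soef_eval
#' @return Time-integrated activity in hours.
#' @export
#' @examples
#' soef_tia("a4c", c(a1 = 0.071, l1 = 0.079, l2 = 0.067, l3 = 0.0012))
soef_tia <- function(model_id, params) {
  model_id <- match.arg(model_id, MODEL_IDS)
  p <- check_params(model_id, params)
  lp <- lambda_phys()
  den <- soef_denominator(model_id, p)
  if (!is.na(den) && abs(den) < 1e-10) {
    stop("model '", model_id, "' is singular: |l1 + l2 - l3| < 1e-10",
         call. = FALSE)
  }
  rate <- function(lam) {
    eff <- lam + lp
    if (eff <= 0) stop("divergent integral: non-positive effective rate",
                       call. = FALSE)
    eff
  }
  switch(model_id,
    a3a = p[["a1"]] / rate(p[["l1"]]) - p[["a1"]] / rate(p[["l2"]]),
    a3b = {
      A <- p[["l1"]] / den
      A * (1 / rate(p[["l3"]]) - 1 / rate(p[["l1"]] + p[["l2"]]))
    },
    a4a = p[["a1"]] / rate(p[["l1"]]) + p[["a2"]] / rate(0) -
      (p[["a1"]] + p[["a2"]]) / rate(p[["l2"]]),
    a4b = (p[["a1"]] + p[["a2"]]) / rate(0) - p[["a1"]] / rate(p[["l1"]]) -
      p[["a2"]] / rate(p[["l2"]]),
    a4c = {
      A <- p[["l1"]] / den
      A * (1 / rate(p[["l3"]]) - 1 / rate(p[["l1"]] + p[["l2"]])) +
        p[["a1"]] / rate(p[["l1"]] + p[["l2"]])
    },
    a5a = p[["a1"]] / rate(p[["l1"]]) + p[["a2"]] / rate(p[["l2"]]) -
      (p[["a1"]] + p[["a2"]]) / rate(p[["l3"]]),
    a5b = (p[["a1"]] + p[["a2"]]) / rate(p[["l1"]]) -
      p[["a1"]] / rate(p[["l2"]]) - p[["a2"]] / rate(p[["l3"]]),
    a6a = p[["a1"]] / rate(p[["l1"]]) + p[["a2"]] / rate(p[["l2"]]) +
      p[["a3"]] / rate(0) -
      (p[["a1"]] + p[["a2"]] + p[["a3"]]) / rate(p[["l3"]]),
    a6b = p[["a1"]] / rate(p[["l1"]]) + p[["a2"]] / rate(0) -
      p[["a3"]] / rate(p[["l2"]]) -
      (p[["a1"]] + p[["a2"]] - p[["a3"]]) / rate(p[["l3"]])
  )
}
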