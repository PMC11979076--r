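#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a population fit
#'
#' One row per fitted parameter: fixed effects on the natural scale,
#' inter-individual variability on the `omega` (SD) scale with the
#' log-normal coefficient of variation `sqrt(exp(omega^2) - 1)`, and the
#' residual SD(s). RSEs come from the covariance of the estimates when
#' available.
#'
#' @param x A `pbms_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `type`, `estimate`, `cv`, `rse`.
#' @method tidy pbms_fit
#' @export
tidy.pbms_fit <- function(x, ...) {
  pn <- MODEL_PARAMS[[x$model_id]]
  nsig <- length(x$sigma)
  base <- tibble::tibble(
    term = names(x$theta),
    type = c(rep("fixed", length(pn)), rep("iiv", length(pn)),
             rep("residual", nsig)),
    estimate = natural_estimates(x),
    cv = c(rep(NA_real_, length(pn)), sqrt(exp(x$omega2) - 1),
           rep(NA_real_, nsig))
  )
  if (!is.null(x$rse)) base$rse <- x$rse$rse else base$rse <- NA_real_
  base
}

#' Glance at a population fit
#'
#' @param x A `pbms_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `model_id`, `error_model`, `K`, `n_obs`,
#'   `n_patients`, `of`, `aicc`, `converged`,
#'   `correlation_offdiag_max`.
#' @method glance pbms_fit
#' @export
glance.pbms_fit <- function(x, ...) {
  tibble::tibble(
    model_id = x$model_id, error_model = x$error_model, K = x$K,
    n_obs = x$n_obs, n_patients = x$n_patients, of = x$of,
    aicc = if (x$n_obs > x$K + 1) aicc(x$of, x$K, x$n_obs) else NA_real_,
    converged = x$converged,
    correlation_offdiag_max = x$correlation_offdiag_max
  )
}

#' Tidy a model-selection report
#'
#' @param x A `pbms_selection`.
#' @param ... Unused.
#' @return The per-model report tibble (gate outcome, objective, AICc,
#'   delta, Akaike weight), mirroring the published comparison table.
#' @method tidy pbms_selection
#' @export
tidy.pbms_selection <- function(x, ...) x$report

#' Glance at a model-selection report
#'
#' @param x A `pbms_selection`.
#' @param ... Unused.
#' @return One row: selected model, its weight, the candidate count and N.
#' @method glance pbms_selection
#' @export
glance.pbms_selection <- function(x, ...) {
  w <- x$report$weight[x$report$model_id == x$selected_model_id]
  tibble::tibble(
    selected_model_id = x$selected_model_id, selected_weight = w,
    n_models = nrow(x$report), n_gate_passed = sum(x$report$gate_passed),
    n_obs = x$n_obs
  )
}

#' @importFrom generics augment
#' @export
generics::augment

#' Augment retention data with individual predictions and residuals
#'
#' @param x A `pbms_fit`.
#' @param ... Unused.
#' @return The fitting data with `ipred` (empirical-Bayes individual
#'   prediction), `pred` (population prediction at `eta = 0`) and `iwres`
#'   (individual weighted residual).
#' @method augment pbms_fit
#' @export
augment.pbms_fit <- function(x, ...) {
  r <- iwres(x)
  r$pred <- vapply(r$time_h, function(t) {
    soef_eval(x$model_id, x$tvp, t)
  }, numeric(1))
  r[c("patient_id", "time_h", "fraction", "pred", "ipred", "iwres")]
}
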