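#' Corrected Akaike Information Criterion
#'
#' `aicc = of + 2K + 2K(K+1)/(N-K-1)`, where `of` is the minimised
#' objective (-2 log likelihood), `K` the number of fitted parameters and
#' `N` the number of observations.
#'
#' @param of Objective value(s), playing the role of `-2 ln L`.
#' @param K Number of fitted parameters.
#' @param N Number of observations.
#' @return The AICc value(s), unrounded.
#' @export
#' @examples
#' aicc(-1676, 9, 364)
aicc <- function(of, K, N) {
  if (any(N - K - 1 <= 0)) {
    stop("AICc undefined: need N > K + 1 (got N = ", N[1], ", K = ",
         K[which(N - K - 1 <= 0)[1]], ")", call. = FALSE)
  }
  of + 2 * K + 2 * K * (K + 1) / (N - K - 1)
}

#' Akaike weights
#'
#' Normalised model evidence `exp(-delta/2) / sum(exp(-delta/2))` with
#' `delta = aicc - min(aicc)`; subtracting the minimum before
#' exponentiating keeps the computation stable for large differences.
#' Invariant to adding any constant to all AICc values, so the engine's
#' likelihood-constant convention cancels.
#'
#' @param aicc_values Named numeric vector of AICc values.
#' @return Named weights summing to 1.
#' @export
#' @examples
#' akaike_weights(c(a = 0, b = 2))
akaike_weights <- function(aicc_values) {
  if (length(aicc_values) == 0) stop("no AICc values", call. = FALSE)
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Goodness-of-fit gate thresholds
#'
#' Defaults follow the published precision criteria: every fixed-effect
#' RSE `< 0.3`, every random-effect (inter- and intra-individual) RSE
#' `< 0.5`, and the maximum absolute off-diagonal correlation `< 0.8`
#' (strict inequalities; boundary values fail). The residual-trend check
#' is a reproducible stand-in for visual inspection of the fitted curves:
#' within each nominal sampling-time bin the individual weighted residuals
#' must not show a mean shifted from zero by more than a Bonferroni-
#' adjusted z threshold (familywise level `trend_alpha`). Set
#' `residual_trend = FALSE` to disable it.
#'
#' @param fixed_rse,random_rse,correlation Strict upper bounds.
#' @param residual_trend Whether the residual-trend check gates.
#' @param trend_alpha Familywise level of the residual-trend check.
#' @return A list of thresholds for [goodness_of_fit_gate()].
#' @export
gate_thresholds <- function(fixed_rse = 0.3, random_rse = 0.5,
                            correlation = 0.8, residual_trend = TRUE,
                            trend_alpha = 0.01) {
  list(fixed_rse = fixed_rse, random_rse = random_rse,
       correlation = correlation, residual_trend = residual_trend,
       trend_alpha = trend_alpha)
}

# Individual weighted residuals (EBE-based) per observation.
iwres <- function(fit) {
  pn <- MODEL_PARAMS[[fit$model_id]]
  ebe <- empirical_bayes(fit)
  dat <- dplyr::left_join(fit$data, ebe, by = "patient_id")
  eta <- as.matrix(dat[paste0("eta_", pn)])
  f <- vapply(seq_len(nrow(dat)), function(i) {
    p_i <- fit$tvp * exp(eta[i, ])
    soef_eval(fit$model_id, p_i, dat$time_h[i])
  }, numeric(1))
  res <- switch(fit$error_model,
    proportional = (dat$fraction - f) / (fit$sigma * abs(f)),
    additive = (dat$fraction - f) / fit$sigma,
    combined = (dat$fraction - f) /
      sqrt(fit$sigma[1]^2 + fit$sigma[2]^2 * f^2),
    exponential = (log(dat$fraction) - log(pmax(f, 1e-12))) / fit$sigma
  )
  tibble::tibble(patient_id = dat$patient_id, time_h = dat$time_h,
                 fraction = dat$fraction, ipred = f, iwres = res)
}

residual_trend_check <- function(fit, trend_alpha = 0.01) {
  r <- iwres(fit)
  bins <- r |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$iwres),
                     sd = stats::sd(.data$iwres), .groups = "drop") |>
    dplyr::mutate(z = .data$mean / (.data$sd / sqrt(.data$n)))
  zcrit <- stats::qnorm(1 - trend_alpha / (2 * nrow(bins)))
  list(bins = bins, z_max = max(abs(bins$z)), z_crit = zcrit,
       pass = all(abs(bins$z) < zcrit))
}

#' Apply the goodness-of-fit gate to a population fit
#'
#' @param fit A `pbms_fit` (or `NULL`/failed fit, which fails with reason
#'   `convergence`).
#' @param thresholds See [gate_thresholds()].
#' @return A list with `model_id`, `passed` and `reasons` (subset of
#'   `fixed_rse`, `random_rse`, `correlation`, `convergence`,
#'   `residual_trend`), plus the inspected summaries.
#' @export
goodness_of_fit_gate <- function(fit, thresholds = gate_thresholds()) {
  if (is.null(fit) || !isTRUE(fit$converged)) {
    return(list(model_id = if (is.null(fit)) NA_character_ else fit$model_id,
                passed = FALSE, reasons = "convergence",
                max_fixed_rse = NA_real_, max_random_rse = NA_real_,
                correlation_offdiag_max = NA_real_, trend = NULL))
  }
  reasons <- character(0)
  if (is.null(fit$rse) || anyNA(fit$rse$rse) ||
      !is.finite(fit$correlation_offdiag_max)) {
    reasons <- c(reasons, "convergence")
    max_fixed <- max_random <- NA_real_
  } else {
    max_fixed <- max(fit$rse$rse[fit$rse$type == "fixed"])
    max_random <- max(fit$rse$rse[fit$rse$type != "fixed"])
    if (max_fixed >= thresholds$fixed_rse) reasons <- c(reasons, "fixed_rse")
    if (max_random >= thresholds$random_rse) {
      reasons <- c(reasons, "random_rse")
    }
    if (fit$correlation_offdiag_max >= thresholds$correlation) {
      reasons <- c(reasons, "correlation")
    }
  }
  trend <- NULL
  if (isTRUE(thresholds$residual_trend)) {
    trend <- tryCatch(residual_trend_check(fit, thresholds$trend_alpha),
                      error = function(e) NULL)
    if (is.null(trend) || !isTRUE(trend$pass)) {
      reasons <- c(reasons, "residual_trend")
    }
  }
  list(model_id = fit$model_id, passed = length(reasons) == 0,
       reasons = reasons, max_fixed_rse = max_fixed,
       max_random_rse = max_random,
       correlation_offdiag_max = fit$correlation_offdiag_max,
       trend = trend)
}

#' Population-based model selection across the model bank
#'
#' Fits every candidate model with [fit_nlme()], applies the
#' goodness-of-fit gate, computes AICc for each fit, forms Akaike weights
#' over the gate-passing set only, and selects the highest-weight model
#' (ties broken by lower AICc, then fewer parameters). Gated-out models
#' appear in the report with their failure reasons and no weight.
#'
#' @inheritParams fit_nlme
#' @param model_ids Candidate models; default all nine.
#' @param thresholds See [gate_thresholds()].
#' @param keep_fits Keep the fitted objects in the result.
#' @return A `pbms_selection` object: tibble-like report (`$report`),
#'   `$selected_model_id`, `$fits` (if kept), `$n_obs`.
#' @export
run_pbms <- function(data, model_ids = model_bank()$model_id,
                     error_model = "proportional", n_starts = 1000L,
                     seed = 1L, thresholds = gate_thresholds(),
                     stage1_iter = 50L, polish_top = 5L,
                     keep_fits = TRUE) {
  stopifnot(length(model_ids) >= 1)
  model_ids <- unname(vapply(model_ids, match.arg, "",
                             choices = MODEL_IDS))
  data <- as_retention(data)
  n_obs <- nrow(data)

  fits <- vector("list", length(model_ids))
  names(fits) <- model_ids
  for (i in seq_along(model_ids)) {
    fits[[i]] <- tryCatch(
      fit_nlme(data, model_ids[i], error_model = error_model,
               n_starts = n_starts, seed = as.integer(seed) + i,
               stage1_iter = stage1_iter, polish_top = polish_top),
      error = function(e) structure(list(error = conditionMessage(e)),
                                    class = "pbms_failed_fit")
    )
  }

  gates <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    if (inherits(f, "pbms_failed_fit")) {
      g <- list(model_id = model_ids[i], passed = FALSE,
                reasons = "convergence", max_fixed_rse = NA_real_,
                max_random_rse = NA_real_,
                correlation_offdiag_max = NA_real_, trend = NULL)
    } else {
      g <- goodness_of_fit_gate(f, thresholds)
    }
    g
  })

  report <- tibble::tibble(
    model_id = model_ids,
    K = vapply(fits, function(f)
      if (inherits(f, "pbms_failed_fit")) NA_integer_ else f$K, integer(1)),
    of = vapply(fits, function(f)
      if (inherits(f, "pbms_failed_fit")) NA_real_ else f$of, numeric(1)),
    max_fixed_rse = vapply(gates, `[[`, numeric(1), "max_fixed_rse"),
    max_random_rse = vapply(gates, `[[`, numeric(1), "max_random_rse"),
    max_corr = vapply(gates, `[[`, numeric(1), "correlation_offdiag_max"),
    gate_passed = vapply(gates, `[[`, logical(1), "passed"),
    gate_reasons = vapply(gates, function(g)
      paste(g$reasons, collapse = ";"), character(1))
  )
  report$aicc <- unname(ifelse(is.na(report$of), NA_real_,
                               aicc(report$of, report$K, n_obs)))
  report$of <- unname(report$of)
  report$K <- unname(report$K)

  in_f <- report$gate_passed & !is.na(report$aicc)
  if (!any(in_f)) {
    stop("no model passed the goodness-of-fit gate; reasons: ",
         paste(sprintf("%s[%s]", report$model_id, report$gate_reasons),
               collapse = " "), call. = FALSE)
  }
  w <- akaike_weights(stats::setNames(report$aicc[in_f],
                                      report$model_id[in_f]))
  report$delta <- ifelse(in_f, report$aicc - min(report$aicc[in_f]),
                         NA_real_)
  report$weight <- NA_real_
  report$weight[in_f] <- unname(w[report$model_id[in_f]])

  elig <- report[in_f, ]
  elig <- elig[order(elig$aicc, elig$K), ]
  selected <- elig$model_id[1]

  structure(
    list(report = report, selected_model_id = selected,
         fits = if (keep_fits) fits else NULL, gates = gates,
         n_obs = n_obs, seed = as.integer(seed), n_starts = n_starts,
         error_model = error_model),
    class = "pbms_selection"
  )
}

#' @export
print.pbms_selection <- function(x, ...) {
  cat("Population-based model selection over", nrow(x$report),
      "candidate models (N =", x$n_obs, ")\n")
  cat("Selected model:", x$selected_model_id, "\n")
  print(tidy(x), n = Inf)
  invisible(x)
}
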