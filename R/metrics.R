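#' Per-patient time-integrated activities from a fit
#'
#' For a population fit the patient parameters are the empirical-Bayes-
#' adjusted values `P_i = TVP * exp(eta_i)`; for the individual-fit
#' comparator they are each patient's own estimates. The TIA is the
#' closed-form integral [soef_tia()] of the patient's curve, in hours per
#' unit administered activity.
#'
#' @param fit A `pbms_fit` or `pbms_individual` object.
#' @return A tibble with `patient_id` and `tia_h`.
#' @export
tia_per_patient <- function(fit) {
  if (inherits(fit, "pbms_fit")) {
    pn <- MODEL_PARAMS[[fit$model_id]]
    ebe <- empirical_bayes(fit)
    eta <- as.matrix(ebe[paste0("eta_", pn)])
    tibble::tibble(
      patient_id = ebe$patient_id,
      tia_h = vapply(seq_len(nrow(ebe)), function(i) {
        soef_tia(fit$model_id, fit$tvp * exp(eta[i, ]))
      }, numeric(1))
    )
  } else if (inherits(fit, "pbms_individual")) {
    tibble::tibble(
      patient_id = names(fit$params),
      tia_h = vapply(fit$params, function(p) soef_tia(fit$model_id, p),
                     numeric(1))
    )
  } else {
    stop("tia_per_patient() needs a pbms_fit or pbms_individual object",
         call. = FALSE)
  }
}

#' Compare per-patient TIAs of a method against a reference
#'
#' For each patient `j` the relative deviation is
#' `RD_j = (TIA_px,j - TIA_ref,j) / TIA_ref,j`. Summaries are the mean,
#' SD, median, min and max of the RDs, the root-mean-square error
#' `RMSE = sqrt(SD^2 + mean^2)` and the mean absolute percentage error
#' `MAPE = mean(|RD|)`. With the default population (n-denominator) SD the
#' RMSE is exactly the root of the mean squared RD.
#'
#' @param tias_px Tibble (`patient_id`, `tia_h`) or named vector for the
#'   method under evaluation.
#' @param tias_ref Same, for the reference method; patient sets must match.
#' @param sd_convention `"n"` (population SD, default) or `"n-1"`.
#' @return A `pbms_tia_comparison`: `$per_patient` tibble and `$summary`
#'   one-row tibble (fractions; multiply by 100 for percent).
#' @export
compare_tias <- function(tias_px, tias_ref, sd_convention = c("n", "n-1")) {
  sd_convention <- match.arg(sd_convention)
  as_named <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$tia_h, x$patient_id) else x
  }
  px <- as_named(tias_px)
  ref <- as_named(tias_ref)
  if (!setequal(names(px), names(ref))) {
    stop("patient sets differ between the two TIA vectors", call. = FALSE)
  }
  ref <- ref[names(px)]
  if (any(ref == 0)) stop("reference TIA of zero", call. = FALSE)
  rd <- (px - ref) / ref
  n <- length(rd)
  m <- mean(rd)
  s <- if (sd_convention == "n") {
    sqrt(mean((rd - m)^2))
  } else {
    stats::sd(rd)
  }
  structure(
    list(
      per_patient = tibble::tibble(patient_id = names(px),
                                   tia_px = unname(px),
                                   tia_ref = unname(ref), rd = unname(rd)),
      summary = tibble::tibble(
        n = n, mean_rd = m, sd_rd = s, median_rd = stats::median(rd),
        min_rd = min(rd), max_rd = max(rd),
        rmse = sqrt(s^2 + m^2), mape = mean(abs(rd))
      ),
      sd_convention = sd_convention
    ),
    class = "pbms_tia_comparison"
  )
}

#' @export
print.pbms_tia_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "TIA comparison over %d patients (percent):\n  RD %.1f (%.1f), median %.1f [%.1f, %.1f], RMSE %.1f, MAPE %.1f\n",
    s$n, 100 * s$mean_rd, 100 * s$sd_rd, 100 * s$median_rd,
    100 * s$min_rd, 100 * s$max_rd, 100 * s$rmse, 100 * s$mape))
  invisible(x)
}
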