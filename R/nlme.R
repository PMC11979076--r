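ERROR_MODELS <- c("additive", "proportional", "combined", "exponential")

error_code <- function(error_model) {
  match(match.arg(error_model, ERROR_MODELS), ERROR_MODELS) - 1L
}

n_sigma_pars <- function(error_model) if (error_model == "combined") 2L else 1L

# Build the log-scale search vector from natural-scale population values.
# sigma is given as SD(s); variances enter the objective.
build_theta <- function(model_id, tvp, omega2, sigma) {
  pn <- MODEL_PARAMS[[model_id]]
  tvp <- check_params(model_id, tvp)
  if (!setequal(names(omega2), pn)) {
    stop("omega2 must be named for ", paste(pn, collapse = ", "),
         call. = FALSE)
  }
  omega2 <- as.numeric(omega2[pn])
  stopifnot(all(omega2 >= 0), all(sigma > 0))
  lw <- ifelse(omega2 > 0, log(omega2), -800)
  c(log(tvp), lw, log(sigma^2))
}

theta_names <- function(model_id, error_model) {
  pn <- MODEL_PARAMS[[model_id]]
  sn <- if (error_model == "combined") c("sigma_add", "sigma_prop") else "sigma"
  c(paste0("tvp_", pn), paste0("omega2_", pn), sn)
}

make_objective <- function(pack, model_id, error_model, env,
                           inner_iter = 60, inner_gtol = 1e-6) {
  mcode <- model_code(model_id)
  ecode <- error_code(error_model)
  p <- length(MODEL_PARAMS[[model_id]])
  force(pack)
  function(theta) {
    if (any(!is.finite(theta) & theta > 0)) return(1e12)
    theta <- pmax(theta, -800)
    res <- cpp_laplace_nll(mcode, theta, p, pack$time, pack$y,
                           pack$pat_start, pack$pat_len, ecode, env$eta,
                           inner_iter, inner_gtol)
    if (!isTRUE(res$ok) || !is.finite(res$value)) {
      return(1e10 + sum(pmin(abs(theta), 50)))
    }
    env$eta <- res$eta
    # near-singular structural denominators are penalised, not fatal,
    # so the optimiser can retreat
    if (res$n_singular > 0) return(res$value + 1e6)
    res$value
  }
}

fd_grad <- function(fn, theta, f0 = NULL, h = 1e-6) {
  if (is.null(f0)) f0 <- fn(theta)
  vapply(seq_along(theta), function(k) {
    tk <- theta
    tk[k] <- tk[k] + h
    (fn(tk) - f0) / h
  }, numeric(1))
}

#' Laplace-approximate marginal -2 log-likelihood
#'
#' Evaluates the population objective for given population parameters: per
#' patient, the joint density of the observations (residual model applied
#' to the structural prediction at `P_i = TVP * exp(eta)`) and
#' `eta ~ N(0, diag(omega2))` is maximised over `eta` and
#' curvature-corrected (Laplace approximation); `-2 log` of the product
#' over patients is returned. All Gaussian normalisation constants
#' (`log 2*pi` terms) are included, identically for every model, so
#' information-criterion differences are invariant to the convention. For
#' the exponential error model the objective is that of the log-transformed
#' observations.
#'
#' @param data A retention tibble (see [as_retention()]).
#' @param model_id Structural model identifier.
#' @param tvp Named fixed effects (natural scale, positive).
#' @param omega2 Named random-effect variances (log scale), `>= 0`; a zero
#'   entry fixes that parameter's random effect at 0.
#' @param sigma Residual error SD (length 2 for `"combined"`:
#'   additive then proportional).
#' @param error_model Residual model.
#' @return The scalar objective value (-2 log approximate marginal
#'   likelihood).
#' @export
marginal_neg2ll <- function(data, model_id, tvp, omega2, sigma,
                            error_model = "proportional") {
  model_id <- match.arg(model_id, MODEL_IDS)
  error_model <- match.arg(error_model, ERROR_MODELS)
  pack <- pack_data(data)
  theta <- build_theta(model_id, tvp, omega2, sigma)
  env <- new.env()
  env$eta <- matrix(0, length(MODEL_PARAMS[[model_id]]), pack$n_patients)
  fn <- make_objective(pack, model_id, error_model, env,
                       inner_iter = 200, inner_gtol = 1e-8)
  fn(theta)
}

random_start <- function(model_id, error_model) {
  pn <- MODEL_PARAMS[[model_id]]
  is_rate <- grepl("^l", pn)
  tvp <- ifelse(is_rate,
                exp(stats::runif(length(pn), log(1e-4), log(1))),
                exp(stats::runif(length(pn), log(1e-3), log(1))))
  omega2 <- rep(0.5^2, length(pn))
  sigma <- if (error_model == "combined") c(0.1, 0.1) else 0.1
  c(log(tvp), log(omega2), log(sigma^2))
}

#' Fit a population model by multi-start Laplace NLME
#'
#' Maximises the Laplace-approximate marginal likelihood
#' ([marginal_neg2ll()]) over log-transformed fixed effects, random-effect
#' variances and residual variance(s), from `n_starts` randomised starting
#' points (rates drawn log-uniform on `[1e-4, 1]` 1/h, amplitudes on
#' `[1e-3, 1]`, `omega` start 0.5, `sigma` start 0.1). Each start is run
#' with a capped iteration budget and the most promising candidates are
#' polished to convergence; the converged fit with the lowest objective
#' wins, ties broken by the lowest start index. Uncertainty is derived
#' from the finite-difference Hessian of the objective at the optimum
#' (see [fit_uncertainty()]); per-patient empirical Bayes estimates are
#' recorded.
#'
#' @inheritParams marginal_neg2ll
#' @param n_starts Number of randomised starts.
#' @param seed Integer seed controlling all randomisation.
#' @param stage1_iter Outer iteration cap per exploratory start.
#' @param polish_top Number of best starts polished to full convergence.
#' @return A `pbms_fit` object; see [tidy.pbms_fit()] and
#'   [glance.pbms_fit()].
#' @export
fit_nlme <- function(data, model_id, error_model = "proportional",
                     n_starts = 1000L, seed = 1L,
                     stage1_iter = 50L, polish_top = 5L) {
  model_id <- match.arg(model_id, MODEL_IDS)
  error_model <- match.arg(error_model, ERROR_MODELS)
  stopifnot(n_starts >= 1)
  pack <- pack_data(data)
  p <- length(MODEL_PARAMS[[model_id]])

  set.seed(as.integer(seed))
  starts <- replicate(n_starts, random_start(model_id, error_model),
                      simplify = FALSE)

  run_start <- function(theta0, iter_max, polish = FALSE) {
    env <- new.env()
    env$eta <- matrix(0, p, pack$n_patients)
    fn <- make_objective(pack, model_id, error_model, env)
    nsig <- n_sigma_pars(error_model)
    gr <- function(theta) {
      # the likelihood valley narrows with the residual SD: keep the
      # finite-difference step well inside it
      sig <- exp(min(theta[(length(theta) - nsig + 1):length(theta)]) / 2)
      h <- min(1e-5, max(1e-9, 0.03 * sig / sqrt(pack$n_obs)))
      eta_save <- env$eta
      g <- fd_grad(fn, theta, h = h)
      env$eta <- eta_save
      g
    }
    one <- function(t0) {
      tryCatch(
        stats::nlminb(t0, fn, gradient = gr,
                      lower = -30, upper = 10,
                      control = list(iter.max = iter_max,
                                     eval.max = 10L * iter_max,
                                     rel.tol = 1e-8)),
        error = function(e) NULL
      )
    }
    res <- one(theta0)
    if (is.null(res)) return(NULL)
    converged <- res$convergence == 0L
    if (polish) {
      # restart until the objective is stable: with finite-difference
      # gradients the PORT return code alone is too pessimistic
      for (r in 1:8) {
        res2 <- one(res$par)
        if (is.null(res2)) break
        improved <- res$objective - res2$objective
        if (res2$objective <= res$objective) res <- res2
        if (improved < 1e-6 * (1 + abs(res$objective))) {
          converged <- TRUE
          break
        }
      }
    }
    list(theta = res$par, value = res$objective, converged = converged,
         env = env, message = res$message)
  }

  stage1 <- lapply(starts, run_start, iter_max = stage1_iter)
  vals <- vapply(stage1, function(s) if (is.null(s)) Inf else s$value,
                 numeric(1))
  ord <- order(vals)
  keep <- utils::head(ord[is.finite(vals[ord])], polish_top)
  if (length(keep) == 0) {
    stop("no start produced a finite objective for model '", model_id, "'",
         call. = FALSE)
  }
  polished <- lapply(keep, function(k) {
    r <- run_start(stage1[[k]]$theta, iter_max = 500L, polish = TRUE)
    if (is.null(r)) stage1[[k]] else c(r, list(start_index = k))
  })
  pvals <- vapply(polished, `[[`, numeric(1), "value")
  pconv <- vapply(polished, function(x) isTRUE(x$converged) && x$value < 1e6,
                  logical(1))
  if (!any(pconv)) {
    stop("no start converged for model '", model_id,
         "'; best objective was ", format(min(pvals)), call. = FALSE)
  }
  cand <- which(pconv)
  best <- cand[order(pvals[cand], keep[cand])][1]
  fit <- polished[[best]]

  # final refinement against a quiet objective (tight inner tolerance):
  # the exploratory phases tolerate inner-optimisation noise, the optimum
  # handed to the covariance step must not
  env <- new.env()
  env$eta <- fit$env$eta
  fn_final <- make_objective(pack, model_id, error_model, env,
                             inner_iter = 200, inner_gtol = 1e-8)
  nsig_f <- n_sigma_pars(error_model)
  gr_final <- function(theta) {
    sig <- exp(min(theta[(length(theta) - nsig_f + 1):length(theta)]) / 2)
    h <- min(1e-5, max(1e-9, 0.03 * sig / sqrt(pack$n_obs)))
    eta_save <- env$eta
    g <- fd_grad(fn_final, theta, h = h)
    env$eta <- eta_save
    g
  }
  refined <- tryCatch(
    stats::nlminb(fit$theta, fn_final, gradient = gr_final,
                  lower = -30, upper = 10,
                  control = list(iter.max = 200L, eval.max = 2000L,
                                 rel.tol = 1e-10)),
    error = function(e) NULL
  )
  theta_hat <- fit$theta
  if (!is.null(refined) && is.finite(refined$objective) &&
      refined$objective <= fit$value) {
    theta_hat <- refined$par
  }
  of <- fn_final(theta_hat)
  res_final <- cpp_laplace_nll(model_code(model_id), theta_hat, p,
                               pack$time, pack$y, pack$pat_start,
                               pack$pat_len, error_code(error_model),
                               env$eta, 200, 1e-8)

  nm <- theta_names(model_id, error_model)
  names(theta_hat) <- nm
  pn <- MODEL_PARAMS[[model_id]]
  tvp <- stats::setNames(exp(theta_hat[seq_len(p)]), pn)
  omega2 <- stats::setNames(exp(theta_hat[p + seq_len(p)]), pn)
  sig <- sqrt(exp(theta_hat[(2 * p + 1):length(theta_hat)]))

  out <- structure(
    list(
      model_id = model_id, error_model = error_model,
      theta = theta_hat, tvp = tvp, omega2 = omega2, omega = sqrt(omega2),
      sigma = unname(sig), of = of,
      per_patient = tibble::tibble(patient_id = pack$ids,
                                   neg2ll = as.numeric(res_final$per_patient)),
      converged = TRUE,
      n_starts_used = n_starts, best_start_index = fit$start_index %||% keep[best],
      start_objectives = vals,
      K = 2L * p + n_sigma_pars(error_model),
      n_obs = pack$n_obs, n_patients = pack$n_patients,
      seed = as.integer(seed),
      data = pack$data,
      eta_hat = env$eta
    ),
    class = "pbms_fit"
  )
  unc <- tryCatch(fit_uncertainty(out), error = function(e) NULL)
  if (is.null(unc)) {
    out$covariance <- NULL
    out$rse <- NULL
    out$correlation <- NULL
    out$correlation_offdiag_max <- NA_real_
    out$cov_ok <- FALSE
  } else {
    out$covariance <- unc$covariance
    out$rse <- unc$rse
    out$correlation <- unc$correlation
    out$correlation_offdiag_max <- unc$correlation_offdiag_max
    out$cov_ok <- all(is.finite(unc$rse$rse))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pbms_fit <- function(x, ...) {
  cat("Population NLME fit (Laplace), model", x$model_id,
      "| error model:", x$error_model, "\n")
  cat("  patients:", x$n_patients, " observations:", x$n_obs,
      " K:", x$K, "\n")
  cat("  -2LL:", format(x$of, digits = 8),
      " max off-diag corr:", format(x$correlation_offdiag_max, digits = 3),
      "\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Covariance-based uncertainty of a population fit
#'
#' Computes the covariance matrix of the estimates as twice the inverse
#' finite-difference Hessian of the objective (-2 log marginal likelihood)
#' at the optimum, on the log-parameter search scale. Relative standard
#' errors follow by the delta method: for a log-scale parameter the RSE of
#' the natural-scale estimate equals the log-scale SE (halved for `omega`
#' and `sigma`, which are reported on the SD scale while the search is over
#' their variances). The correlation matrix is scale-invariant.
#'
#' @param fit A `pbms_fit`.
#' @return A list with `covariance` (log scale), `rse` (tibble: term,
#'   type, estimate, rse), `correlation`, `correlation_offdiag_max`.
#' @export
fit_uncertainty <- function(fit) {
  stopifnot(inherits(fit, "pbms_fit"))
  pack <- pack_data(fit$data)
  p <- length(MODEL_PARAMS[[fit$model_id]])
  env <- new.env()
  env$eta <- fit$eta_hat
  fn <- make_objective(pack, fit$model_id, fit$error_model, env,
                       inner_iter = 200, inner_gtol = 1e-8)
  # central-difference Hessian on the log scale with a step wide enough to
  # average over the inner-optimisation roughness of the objective; the
  # warm-start state is reset before every evaluation for exchangeability
  eta0 <- fit$eta_hat
  fr <- function(t) {
    env$eta <- eta0
    fn(t)
  }
  th <- unname(fit$theta)
  d <- length(th)
  fd_hess <- function(h) {
    H <- matrix(0, d, d)
    for (i in seq_len(d)) {
      for (j in i:d) {
        ei <- ej <- rep(0, d)
        ei[i] <- h
        ej[j] <- h
        H[i, j] <- H[j, i] <-
          (fr(th + ei + ej) - fr(th + ei - ej) -
             fr(th - ei + ej) + fr(th - ei - ej)) / (4 * h * h)
      }
    }
    H
  }
  # widen the step until the curvature estimate is positive definite;
  # beyond ~0.1 on the log scale the quadratic approximation is gone and
  # the covariance step is declared failed
  H <- NULL
  for (h in c(0.02, 0.05, 0.1)) {
    Hc <- fd_hess(h)
    ev <- tryCatch(eigen(Hc, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) -1)
    if (all(is.finite(ev)) && min(ev) > 0) {
      H <- Hc
      break
    }
  }
  if (is.null(H)) H <- fd_hess(0.05) # reported, but will fail inversion
  cov_log <- tryCatch(2 * solve(H), error = function(e) NULL)
  nm <- names(fit$theta)
  if (is.null(cov_log) || any(!is.finite(cov_log)) ||
      any(diag(cov_log) <= 0)) {
    # singular or indefinite Hessian: flagged, gate treats the fit as failed
    rse <- tibble::tibble(term = nm,
                          type = c(rep("fixed", p), rep("iiv", p),
                                   rep("residual", length(nm) - 2 * p)),
                          estimate = natural_estimates(fit),
                          rse = NA_real_)
    return(list(covariance = NULL, rse = rse, correlation = NULL,
                correlation_offdiag_max = NA_real_))
  }
  dimnames(cov_log) <- list(nm, nm)
  se_log <- sqrt(diag(cov_log))
  # delta method to the reported scales
  scale_half <- grepl("^(omega2_|sigma)", nm) # reported as SDs
  rse_val <- ifelse(scale_half, se_log / 2, se_log)
  corr <- stats::cov2cor(cov_log)
  off <- abs(corr[upper.tri(corr)])
  list(
    covariance = cov_log,
    rse = tibble::tibble(
      term = nm,
      type = c(rep("fixed", p), rep("iiv", p),
               rep("residual", length(nm) - 2 * p)),
      estimate = natural_estimates(fit),
      rse = rse_val
    ),
    correlation = corr,
    correlation_offdiag_max = if (length(off)) max(off) else 0
  )
}

natural_estimates <- function(fit) {
  unname(c(fit$tvp, fit$omega, fit$sigma))
}

#' Empirical Bayes estimates of the random effects
#'
#' Per-patient posterior modes of `eta` given the population estimates.
#' Patients with sparse data shrink toward 0 (the prior mode); a parameter
#' with `omega2 = 0` has `eta = 0` for every patient.
#'
#' @param fit A `pbms_fit`.
#' @param data Optional retention tibble of (possibly new) patients;
#'   defaults to the fitting data.
#' @return A tibble with `patient_id` and one `eta_<param>` column per
#'   structural parameter.
#' @export
empirical_bayes <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "pbms_fit"))
  pn <- MODEL_PARAMS[[fit$model_id]]
  if (is.null(data)) {
    eta <- fit$eta_hat
    ids <- fit$per_patient$patient_id
  } else {
    pack <- pack_data(data)
    env <- new.env()
    env$eta <- matrix(0, length(pn), pack$n_patients)
    fn <- make_objective(pack, fit$model_id, fit$error_model, env,
                         inner_iter = 200, inner_gtol = 1e-8)
    fn(unname(fit$theta))
    eta <- env$eta
    ids <- pack$ids
  }
  out <- tibble::as_tibble(stats::setNames(
    as.data.frame(t(eta)), paste0("eta_", pn)))
  dplyr::bind_cols(tibble::tibble(patient_id = ids), out)
}

#' Parameter uncertainty by sampling importance resampling
#'
#' Draws parameter vectors from a multivariate-normal proposal centred at
#' the estimate (covariance from [fit_uncertainty()]), weights each draw by
#' the likelihood ratio `exp(-(of(theta) - of(theta_hat)) / 2)`, and
#' resamples without replacement proportionally to the weights. Confidence
#' intervals are the 2.5/97.5 percentiles of the resample on the natural
#' scale; the RSE is the resample SD divided by the estimate.
#'
#' @param fit A converged `pbms_fit` with a usable covariance.
#' @param n_samples Number of proposal draws.
#' @param n_resamples Resample size (without replacement).
#' @param seed Integer seed.
#' @return A tibble: term, type, estimate, ci_lo, ci_hi, rse; attribute
#'   `ess` carries the effective sample size and `degenerate_weights` is
#'   set when ESS < 10% of `n_samples`.
#' @export
sir_uncertainty <- function(fit, n_samples = 2000L, n_resamples = 200L,
                            seed = 1L) {
  stopifnot(inherits(fit, "pbms_fit"), !is.null(fit$covariance))
  set.seed(as.integer(seed))
  theta_hat <- unname(fit$theta)
  d <- length(theta_hat)
  ch <- chol(fit$covariance)
  Z <- matrix(stats::rnorm(n_samples * d), n_samples, d)
  draws <- sweep(Z %*% ch, 2, theta_hat, `+`)

  pack <- pack_data(fit$data)
  env <- new.env()
  env$eta <- fit$eta_hat
  fn <- make_objective(pack, fit$model_id, fit$error_model, env)
  of_hat <- fn(theta_hat)
  ofs <- apply(draws, 1, fn)
  logw <- -(ofs - of_hat) / 2
  logw <- logw - max(logw)
  w <- exp(logw)
  w <- w / sum(w)
  ess <- 1 / sum(w^2)
  idx <- sample.int(n_samples, n_resamples, replace = FALSE, prob = w)
  res <- draws[idx, , drop = FALSE]

  nm <- names(fit$theta)
  scale_half <- grepl("^(omega2_|sigma)", nm)
  natural <- sapply(seq_len(d), function(k) {
    if (scale_half[k]) exp(res[, k] / 2) else exp(res[, k])
  })
  est <- natural_estimates(fit)
  p <- length(MODEL_PARAMS[[fit$model_id]])
  out <- tibble::tibble(
    term = nm,
    type = c(rep("fixed", p), rep("iiv", p), rep("residual", d - 2 * p)),
    estimate = est,
    ci_lo = apply(natural, 2, stats::quantile, 0.025),
    ci_hi = apply(natural, 2, stats::quantile, 0.975),
    rse = apply(natural, 2, stats::sd) / est
  )
  attr(out, "ess") <- ess
  attr(out, "degenerate_weights") <- ess < 0.1 * n_samples
  out
}
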