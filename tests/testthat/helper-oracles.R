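# Independent oracles used across the suite. These are deliberate second
# transcriptions of the model formulas and of the marginal likelihood
# integral; they never call into the package's evaluation or fitting paths.

LPHYS_ORACLE <- log(2) / (8.022 * 24)

# literal transcription of the nine retention functions
oracle_soef <- function(model_id, p, t) {
  lp <- LPHYS_ORACLE
  with(as.list(p), switch(model_id,
    a3a = a1 * exp(-(l1 + lp) * t) - a1 * exp(-(l2 + lp) * t),
    a3b = l1 / (l2 + l1 - l3) *
      (exp(-(l3 + lp) * t) - exp(-(l1 + l2 + lp) * t)),
    a4a = a1 * exp(-(l1 + lp) * t) + a2 * exp(-lp * t) -
      (a1 + a2) * exp(-(l2 + lp) * t),
    a4b = (a1 + a2) * exp(-lp * t) - a1 * exp(-(l1 + lp) * t) -
      a2 * exp(-(l2 + lp) * t),
    a4c = l1 / (l2 + l1 - l3) *
      (exp(-(l3 + lp) * t) - exp(-(l1 + l2 + lp) * t)) +
      a1 * exp(-(l1 + l2 + lp) * t),
    a5a = a1 * exp(-(l1 + lp) * t) + a2 * exp(-(l2 + lp) * t) -
      (a1 + a2) * exp(-(l3 + lp) * t),
    a5b = (a1 + a2) * exp(-(l1 + lp) * t) - a1 * exp(-(l2 + lp) * t) -
      a2 * exp(-(l3 + lp) * t),
    a6a = a1 * exp(-(l1 + lp) * t) + a2 * exp(-(l2 + lp) * t) +
      a3 * exp(-lp * t) - (a1 + a2 + a3) * exp(-(l3 + lp) * t),
    a6b = a1 * exp(-(l1 + lp) * t) + a2 * exp(-lp * t) -
      a3 * exp(-(l2 + lp) * t) - (a1 + a2 - a3) * exp(-(l3 + lp) * t)
  ))
}

# random admissible parameter set for a model (away from singularities)
oracle_random_params <- function(model_id) {
  pn <- model_bank()$param_names[[match(model_id, model_bank()$model_id)]]
  repeat {
    p <- stats::setNames(ifelse(
      grepl("^a", pn),
      stats::runif(length(pn), 0.01, 1),
      exp(stats::runif(length(pn), log(1e-3), log(0.5)))
    ), pn)
    if (!model_id %in% c("a3b", "a4c")) return(p)
    if (abs(p[["l1"]] + p[["l2"]] - p[["l3"]]) > 1e-3) return(p)
  }
}

# per-observation density, matching the package's documented conventions
oracle_obs_logdens <- function(y, f, error_model, sigma) {
  switch(error_model,
    additive = stats::dnorm(y, f, sigma, log = TRUE),
    proportional = stats::dnorm(y, f, sigma * abs(f), log = TRUE),
    combined = stats::dnorm(y, f, sqrt(sigma[1]^2 + sigma[2]^2 * f^2),
                            log = TRUE),
    exponential = stats::dnorm(log(y), log(f), sigma, log = TRUE)
  )
}

# adaptive Gauss-Hermite -2 log marginal likelihood for datasets with a
# single free random effect per patient (all other omegas zero)
oracle_agh_neg2ll <- function(data, model_id, tvp, omega2, sigma,
                              error_model, n_nodes = 64) {
  free <- names(omega2)[omega2 > 0]
  stopifnot(length(free) == 1)
  omega <- sqrt(omega2[[free]])
  gh <- pracma::gaussHermite(n_nodes)
  total <- 0
  for (id in unique(data$patient_id)) {
    d <- data[data$patient_id == id, ]
    log_joint <- function(eta) {
      p <- tvp
      p[[free]] <- p[[free]] * exp(eta)
      f <- oracle_soef(model_id, p, d$time_h)
      sum(oracle_obs_logdens(d$fraction, f, error_model, sigma)) +
        stats::dnorm(eta, 0, omega, log = TRUE)
    }
    opt <- stats::optimize(function(e) -log_joint(e), c(-15, 15))
    mode <- opt$minimum
    h <- 1e-4
    curv <- -(log_joint(mode + h) - 2 * log_joint(mode) +
                log_joint(mode - h)) / h^2
    curv <- max(curv, 1e-8)
    s <- sqrt(2 / curv)
    lvals <- vapply(gh$x, function(x) log_joint(mode + s * x) + x^2,
                    numeric(1))
    m <- max(lvals)
    total <- total - 2 * (log(s) + m + log(sum(gh$w * exp(lvals - m))))
  }
  total
}

# small synthetic population for cheap fitting tests
tiny_population <- function(n_patients = 12, seed = 42,
                            gen = generating_params()) {
  design <- default_design(n_schedule_a = ceiling(n_patients * 0.7),
                           n_schedule_b = floor(n_patients * 0.3))
  simulate_population(design, gen, seed = seed)
}
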