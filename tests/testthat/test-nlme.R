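# one moderately sized fit shared by several blocks below
shared_pop <- tiny_population(n_patients = 14, seed = 31)
shared_fit <- fit_nlme(shared_pop, "a4c", n_starts = 8, seed = 17,
                       stage1_iter = 60, polish_top = 3)

test_that("with zero random effects the objective is the fixed-effects -2LL", {
  pop <- tiny_population(8, seed = 6)
  tvp <- c(a1 = 0.07, l1 = 0.08, l2 = 0.066, l3 = 0.0013)
  v <- marginal_neg2ll(pop, "a4c", tvp,
                       omega2 = c(a1 = 0, l1 = 0, l2 = 0, l3 = 0),
                       sigma = 0.05)
  f <- soef_eval("a4c", tvp, pop$time_h)
  hand <- -2 * sum(dnorm(pop$fraction, f, 0.05 * abs(f), log = TRUE))
  expect_equal(v, hand, tolerance = 1e-10)
})

test_that("the objective is invariant to patient order and additive over patients", {
  pop <- tiny_population(8, seed = 13)
  tvp <- c(a1 = 0.07, l1 = 0.08, l2 = 0.066, l3 = 0.0013)
  om <- c(a1 = 0.5, l1 = 0.8, l2 = 0.25, l3 = 0.7)
  v <- marginal_neg2ll(pop, "a4c", tvp, om, 0.048)
  shuf <- pop[sample(nrow(pop)), ]
  expect_equal(marginal_neg2ll(shuf, "a4c", tvp, om, 0.048), v,
               tolerance = 1e-8)
  ids <- unique(pop$patient_id)
  va <- marginal_neg2ll(pop[pop$patient_id %in% ids[1:4], ],
                        "a4c", tvp, om, 0.048)
  vb <- marginal_neg2ll(pop[!pop$patient_id %in% ids[1:4], ],
                        "a4c", tvp, om, 0.048)
  expect_equal(va + vb, v, tolerance = 1e-6)
})

test_that("Laplace objective matches adaptive Gauss-Hermite quadrature", {
  tvp <- c(a1 = 0.07, l1 = 0.08, l2 = 0.066, l3 = 0.0013)
  om <- c(a1 = 0, l1 = 0.5, l2 = 0, l3 = 0)
  dat <- data.frame(patient_id = rep(c("A", "B"), each = 3),
                    time_h = rep(c(2, 24, 96), 2),
                    fraction = c(0.1, 0.35, 0.3, 0.12, 0.4, 0.33))
  for (em in c("proportional", "additive", "exponential")) {
    sig <- if (em == "additive") 0.02 else 0.05
    expect_equal(
      marginal_neg2ll(dat, "a4c", tvp, om, sig, error_model = em),
      oracle_agh_neg2ll(dat, "a4c", tvp, om, sig, em),
      tolerance = 0.5 / 35, # absolute 0.5 on a ~35-unit value
      label = paste("laplace", em)
    )
  }
  sig <- c(0.02, 0.05)
  expect_equal(
    marginal_neg2ll(dat, "a4c", tvp, om, sig, error_model = "combined"),
    oracle_agh_neg2ll(dat, "a4c", tvp, om, sig, "combined"),
    tolerance = 0.05
  )
})

test_that("proportional-error objective shifts by 2N log c under rescaling", {
  pop <- tiny_population(6, seed = 19)
  tvp <- c(a1 = 0.4, l1 = 0.03, l2 = 0.3)
  om <- c(a1 = 0, l1 = 0, l2 = 0)
  v1 <- marginal_neg2ll(pop, "a3a", tvp, om, 0.05)
  cc <- 1.7
  pop2 <- pop
  pop2$fraction <- pop2$fraction * cc / 1.5 # keep inside (0, 1.5]
  tvp2 <- tvp
  tvp2[["a1"]] <- tvp[["a1"]] * cc / 1.5
  v2 <- marginal_neg2ll(pop2, "a3a", tvp2, om, 0.05)
  expect_equal(v2 - v1, 2 * nrow(pop) * log(cc / 1.5), tolerance = 1e-6)
})

test_that("noise-free homogeneous data give back the generating values", {
  gen <- generating_params(model_id = "a3a",
                           tvp = c(a1 = 0.5, l1 = 0.03, l2 = 0.3),
                           iiv_cv = c(a1 = 0, l1 = 0, l2 = 0),
                           sigma = 1e-12)
  design <- default_design(n_schedule_a = 10, n_schedule_b = 0,
                           missing_6h_patient = NULL)
  pop <- simulate_population(design, gen, seed = 2)
  fit <- fit_nlme(pop, "a3a", n_starts = 8, seed = 4,
                  stage1_iter = 200, polish_top = 3)
  expect_lt(max(abs(fit$tvp - gen$tvp) / gen$tvp), 1e-4)
})

test_that("the fitted optimum is at least as good as the generating values", {
  gen <- generating_params()
  at_truth <- marginal_neg2ll(shared_pop, "a4c", gen$tvp, gen$omega2,
                              gen$sigma)
  expect_lte(shared_fit$of, at_truth + 1e-6)
  # and the per-patient contributions add up to the reported objective
  expect_equal(sum(shared_fit$per_patient$neg2ll), shared_fit$of,
               tolerance = 1e-8)
})

test_that("empirical Bayes estimates shrink to zero as information vanishes", {
  ebe <- empirical_bayes(shared_fit)
  expect_equal(nrow(ebe), 14L)
  # thin every patient to the single 2-h sample: much less information,
  # so the posterior modes move toward the prior mode 0
  thin <- shared_pop[shared_pop$time_h == 2, ]
  ebe_thin <- empirical_bayes(shared_fit, thin)
  full_norm <- sqrt(rowSums(as.matrix(ebe[, -1])^2))
  thin_norm <- sqrt(rowSums(as.matrix(ebe_thin[, -1])^2))
  expect_lt(mean(thin_norm), mean(full_norm))
})

test_that("a zero-variance random effect pins its EBE at zero", {
  gen <- generating_params(iiv_cv = c(a1 = 0.5, l1 = 0.5, l2 = 0.5,
                                      l3 = 0))
  pop <- simulate_population(
    default_design(n_schedule_a = 8, n_schedule_b = 0,
                   missing_6h_patient = NULL), gen, seed = 12)
  tvp <- gen$tvp
  # evaluate EBEs at fixed population values with omega2_l3 = 0
  v <- marginal_neg2ll(pop, "a4c", tvp,
                       omega2 = c(a1 = 0.25, l1 = 0.25, l2 = 0.25,
                                  l3 = 0), sigma = 0.05)
  expect_true(is.finite(v))
  fake <- shared_fit
  fake$tvp <- tvp
  fake$omega2 <- c(a1 = 0.25, l1 = 0.25, l2 = 0.25, l3 = 0)
  fake$sigma <- 0.05
  fake$theta <- pbmsnlme:::build_theta("a4c", tvp, fake$omega2, 0.05)
  ebe <- empirical_bayes(fake, pop)
  expect_equal(ebe$eta_l3, rep(0, nrow(ebe)))
  expect_gt(max(abs(ebe$eta_a1)), 0)
})

test_that("EBE modes match a dense grid search on a tiny instance", {
  tvp <- c(a1 = 0.07, l1 = 0.08, l2 = 0.066, l3 = 0.0013)
  om <- c(a1 = 0, l1 = 0.5, l2 = 0, l3 = 0)
  dat <- data.frame(patient_id = "A", time_h = c(2, 24, 96),
                    fraction = c(0.1, 0.35, 0.3))
  fake <- shared_fit
  fake$tvp <- tvp
  fake$omega2 <- om
  fake$sigma <- 0.05
  fake$theta <- pbmsnlme:::build_theta("a4c", tvp, om, 0.05)
  ebe <- empirical_bayes(fake, dat)
  grid <- seq(-3, 3, by = 1e-4)
  joint <- vapply(grid, function(eta) {
    p <- tvp
    p[["l1"]] <- p[["l1"]] * exp(eta)
    f <- oracle_soef("a4c", p, dat$time_h)
    sum(oracle_obs_logdens(dat$fraction, f, "proportional", 0.05)) +
      dnorm(eta, 0, sqrt(0.5), log = TRUE)
  }, numeric(1))
  expect_equal(ebe$eta_l1, grid[which.max(joint)], tolerance = 1e-3)
})

test_that("covariance-based RSEs agree with SIR within 30 percent", {
  expect_true(shared_fit$cov_ok)
  sir <- sir_uncertainty(shared_fit, n_samples = 1500, n_resamples = 200,
                         seed = 5)
  wald <- shared_fit$rse$rse
  agree <- abs(sir$rse - wald) / wald
  expect_lt(stats::median(agree), 0.3)
  # determinism under the seed
  sir2 <- sir_uncertainty(shared_fit, n_samples = 1500, n_resamples = 200,
                          seed = 5)
  expect_identical(sir$ci_lo, sir2$ci_lo)
  expect_identical(sir$ci_hi, sir2$ci_hi)
})
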