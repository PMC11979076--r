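test_that("individual fitting enforces the K_max = N - 1 constraint", {
  d <- data.frame(patient_id = "P1", time_h = c(2, 24, 96),
                  fraction = c(0.1, 0.4, 0.3))
  expect_error(fit_individual(d), "at least 4")
  two <- data.frame(patient_id = c("P1", "P2"), time_h = c(2, 2),
                    fraction = c(0.1, 0.1))
  expect_error(fit_individual(two), "exactly one patient")
})

test_that("noise-free single-patient data are recovered exactly", {
  truth <- c(l1 = 0.08, l2 = 0.07, l3 = 0.0012)
  t <- c(2, 6, 24, 48, 96)
  d <- data.frame(patient_id = "P1", time_h = t,
                  fraction = soef_eval("a3b", truth, t))
  fit <- fit_individual(d, "a3b", n_starts = 60, seed = 3, sigma2 = 1e-8)
  expect_lt(max(abs(fit$params - truth) / truth), 1e-4)
  # TIA from the recovered parameters matches the generating TIA
  expect_equal(soef_tia("a3b", fit$params), soef_tia("a3b", truth),
               tolerance = 1e-4)
})

test_that("the individual optimum beats the generating parameters", {
  truth <- c(l1 = 0.08, l2 = 0.07, l3 = 0.0012)
  t <- c(2, 6, 24, 48, 120)
  set.seed(9)
  f <- soef_eval("a3b", truth, t)
  d <- data.frame(patient_id = "P1", time_h = t,
                  fraction = f * (1 + rnorm(5, 0, 0.05)))
  fit <- fit_individual(d, "a3b", n_starts = 60, seed = 3, sigma2 = 0.05^2)
  at_truth <- pbmsnlme:::ind_neg2ll("a3b", log(truth), d$time_h,
                                    d$fraction, 0.05^2)
  expect_lte(fit$of_contribution, at_truth + 1e-8)
})

test_that("pooled individual fitting keeps the published bookkeeping", {
  pop <- tiny_population(8, seed = 41)
  pooled <- fit_individual_pooled(pop, n_starts = 30, seed = 2)
  expect_equal(pooled$K, 3L * 8L)
  expect_equal(nrow(pooled$fits), 8L)
  expect_equal(sum(pooled$fits$of_contribution), pooled$of,
               tolerance = 1e-8)
  expect_equal(pooled$aicc, aicc(pooled$of, pooled$K, nrow(pop)))
  # the full design gives K = 3 x 73 = 219 without fitting: check the
  # arithmetic path on the published design size
  expect_equal(3L * default_design()$n_patients, 219L)
})

test_that("pooling one patient degenerates to that patient's fit", {
  pop <- tiny_population(6, seed = 43)
  one <- pop[pop$patient_id == pop$patient_id[1], ]
  pooled <- fit_individual_pooled(one, n_starts = 30, seed = 5)
  expect_equal(pooled$K, 3L)
  expect_equal(pooled$n_patients, 1L)
  single <- fit_individual(one, n_starts = 30, seed = 5 + 1L,
                           sigma2 = pooled$sigma2)
  expect_equal(unname(unlist(pooled$params)), unname(single$params),
               tolerance = 1e-6)
})

test_that("individual fits are per-patient optimal against the population fit", {
  pop <- tiny_population(8, seed = 47)
  pooled <- fit_individual_pooled(pop, n_starts = 30, seed = 2)
  popfit <- fit_nlme(pop, "a3b", n_starts = 6, seed = 3,
                     stage1_iter = 40, polish_top = 2)
  ebe <- empirical_bayes(popfit)
  for (id in unique(pop$patient_id)) {
    d <- pop[pop$patient_id == id, ]
    eta <- unlist(ebe[ebe$patient_id == id, -1])
    p_pop <- popfit$tvp * exp(eta)
    of_pop <- pbmsnlme:::ind_neg2ll("a3b", log(p_pop), d$time_h,
                                    d$fraction, pooled$sigma2)
    of_ind <- pbmsnlme:::ind_neg2ll("a3b", log(pooled$params[[id]]),
                                    d$time_h, d$fraction, pooled$sigma2)
    expect_lte(of_ind, of_pop + 1e-6)
  }
})
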