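test_that("default design reproduces the study accounting", {
  d <- default_design()
  expect_equal(d$n_patients, 73L)
  expect_equal(sum(lengths(d$schedule)), 364L)
  # 53 schedule-a patients (one lacking the 6-h sample), 20 schedule-b
  lasts <- vapply(d$schedule, max, numeric(1))
  expect_equal(sum(lasts == 96), 53L)
  expect_equal(sum(lasts == 120), 20L)
  expect_equal(sum(vapply(d$schedule, function(s) !6 %in% s, logical(1))),
               1L)
})

test_that("simulation is seed-deterministic and honours the design", {
  a <- simulate_population(seed = 9)
  b <- simulate_population(seed = 9)
  expect_identical(a$fraction, b$fraction)
  expect_equal(nrow(a), 364L)
  expect_equal(attr(a, "n_patients"), 73L)
  c_ <- simulate_population(seed = 10)
  expect_false(identical(a$fraction, c_$fraction))
})

test_that("zero variability collapses every patient onto the typical curve", {
  gen <- generating_params(iiv_cv = c(a1 = 0, l1 = 0, l2 = 0, l3 = 0),
                           sigma = 1e-12)
  pop <- simulate_population(default_design(), gen, seed = 3)
  pred <- soef_eval("a4c", gen$tvp, pop$time_h)
  expect_equal(pop$fraction, pred, tolerance = 1e-9)
})

test_that("simulated parameter spread matches the target CVs", {
  gen <- generating_params()
  design <- default_design(n_schedule_a = 5000, n_schedule_b = 0,
                           missing_6h_patient = NULL,
                           schedule_a = c(2, 24))
  pop <- simulate_population(design, gen, seed = 21)
  truth <- attr(pop, "true_params")
  for (pn in names(gen$tvp)) {
    v <- truth$value[truth$param == pn]
    cv_emp <- sd(v) / mean(v)
    expect_equal(cv_emp, unname(gen$iiv_cv[[pn]]), tolerance = 0.05)
  }
})

test_that("residual spread matches sigma and redraws are counted", {
  gen <- generating_params(iiv_cv = c(a1 = 0, l1 = 0, l2 = 0, l3 = 0))
  design <- default_design(n_schedule_a = 2000, n_schedule_b = 0,
                           missing_6h_patient = NULL,
                           schedule_a = c(2, 24, 96))
  pop <- simulate_population(design, gen, seed = 8)
  pred <- soef_eval("a4c", gen$tvp, pop$time_h)
  rel <- (pop$fraction - pred) / pred
  expect_equal(sd(rel), gen$sigma, tolerance = 0.05)
  expect_true(attr(pop, "redraws") >= 0)
})

test_that("the noiseless mean curve integrates to the closed-form TIA", {
  gen <- generating_params(iiv_cv = c(a1 = 0, l1 = 0, l2 = 0, l3 = 0),
                           sigma = 1e-12)
  grid <- seq(0, 2000, by = 0.5)
  f <- soef_eval("a4c", gen$tvp, grid)
  trap <- sum(diff(grid) * (head(f, -1) + tail(f, -1)) / 2)
  expect_equal(trap, soef_tia("a4c", gen$tvp), tolerance = 0.02)
})

test_that("the CV-to-omega mapping follows the log-normal relation", {
  gen <- generating_params()
  expect_equal(gen$omega2, log(1 + gen$iiv_cv^2), ignore_attr = TRUE)
  gen2 <- generating_params(cv_mode = "omega")
  expect_equal(sqrt(gen2$omega2), gen2$iiv_cv, ignore_attr = TRUE)
})
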