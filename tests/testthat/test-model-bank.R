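published_a4c_fixed <- c(a1 = 7.1e-2, l1 = 7.9e-2, l2 = 6.7e-2, l3 = 1.2e-3)

test_that("model bank lists the nine candidates with the published K", {
  mb <- model_bank()
  expect_equal(nrow(mb), 9L)
  expect_equal(mb$model_id,
               c("a3a", "a3b", "a4a", "a4b", "a4c", "a5a", "a5b",
                 "a6a", "a6b"))
  expect_equal(mb$nlme_K, c(7L, 7L, 9L, 9L, 9L, 11L, 11L, 13L, 13L))
  # parameter count matches the digit in the identifier
  expect_equal(mb$n_structural,
               as.integer(substr(mb$model_id, 2, 2)))
  expect_equal(mb$nlme_K, 2L * mb$n_structural + 1L)
  expect_equal(lengths(mb$param_names), mb$n_structural)
})

test_that("physical decay constant comes from the 8.022-day half-life", {
  expect_equal(lambda_phys(), log(2) / (8.022 * 24))
})

test_that("every model except a4c vanishes at t = 0; a4c returns a1", {
  set.seed(101)
  for (m in model_bank()$model_id) {
    for (r in 1:20) {
      p <- oracle_random_params(m)
      v0 <- soef_eval(m, p, 0)
      if (m == "a4c") {
        expect_equal(v0, unname(p[["a1"]]))
      } else {
        expect_equal(v0, 0, tolerance = 1e-14)
      }
    }
  }
  # the published typical values: the blood-pool amplitude survives at t=0
  expect_equal(soef_eval("a4c", published_a4c_fixed, 0), 7.1e-2)
})

test_that("evaluation agrees with an independent transcription of the formulas", {
  # frozen spot value computed beforehand with the literal transcription
  expect_equal(soef_eval("a4c", published_a4c_fixed, 24), 0.473119270554,
               tolerance = 1e-10)
  set.seed(202)
  for (m in model_bank()$model_id) {
    for (r in 1:10) {
      p <- oracle_random_params(m)
      t <- sort(runif(6, 0, 150))
      expect_equal(soef_eval(m, p, t), oracle_soef(m, p, t),
                   tolerance = 1e-12)
    }
  }
})

test_that("parameter names are checked strictly", {
  expect_error(soef_eval("a3a", c(a1 = 0.1, l1 = 0.1), 1),
               "takes parameters")
  expect_error(soef_eval("a3a", c(a1 = 0.1, l1 = 0.1, l2 = 0.2, l3 = 1), 1),
               "takes parameters")
  expect_error(soef_eval("a3b", c(l1 = 0.1, l2 = 0.1, l3 = -0.1), 1),
               ">= 0")
})

test_that("near-singular amplitude denominators are rejected", {
  expect_error(soef_eval("a4c", c(a1 = 0.1, l1 = 0.1, l2 = 0.1,
                                  l3 = 0.2 - 1e-12), 1),
               "singular")
  expect_error(soef_tia("a3b", c(l1 = 0.05, l2 = 0.05, l3 = 0.1)),
               "singular")
})

test_that("closed-form TIA matches quadrature and known limits", {
  # frozen value for the published typical parameters, checked beforehand
  # against adaptive quadrature to 1e-10
  expect_equal(soef_tia("a4c", published_a4c_fixed), 110.4844969658,
               tolerance = 1e-8)
  # symmetric cancellation
  expect_equal(soef_tia("a3a", c(a1 = 0.3, l1 = 0.05, l2 = 0.05)), 0)
  # single-exponential limit: second term dies, leaving a1/lambda_phys
  expect_equal(soef_tia("a3a", c(a1 = 0.1, l1 = 0, l2 = 1e8)),
               0.1 / lambda_phys(), tolerance = 1e-6)
  set.seed(303)
  for (m in model_bank()$model_id) {
    for (r in 1:10) {
      p <- oracle_random_params(m)
      q <- integrate(function(t) soef_eval(m, p, t), 0, Inf,
                     rel.tol = 1e-10, abs.tol = 0)$value
      expect_equal(soef_tia(m, p), q, tolerance = 1e-8)
    }
  }
})

test_that("TIA is linear in the amplitudes where amplitudes are free", {
  set.seed(404)
  for (m in c("a3a", "a4a", "a4b", "a5a", "a5b", "a6a", "a6b")) {
    p <- oracle_random_params(m)
    p2 <- p
    amp <- grepl("^a", names(p))
    p2[amp] <- 3.5 * p2[amp]
    expect_equal(soef_tia(m, p2), 3.5 * soef_tia(m, p),
                 tolerance = 1e-12)
  }
})
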