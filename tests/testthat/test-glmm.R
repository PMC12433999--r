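test_that("intercept-only fit is the closed-form Bernoulli MLE", {
  d <- bernoulli_dataset(5000, 47)
  f <- fit_intercept_only(d)
  expect_equal(plogis(f$beta0_hat), 0.0094, tolerance = 1e-12)
  expect_equal(f$se_beta0, 1 / sqrt(5000 * 0.0094 * (1 - 0.0094)),
               tolerance = 1e-12)
  expect_equal(f$loglik, 47 * log(0.0094) + 4953 * log(1 - 0.0094),
               tolerance = 1e-9)
  expect_equal(fit_intercept_only(bernoulli_dataset(2, 1))$beta0_hat, 0)
  expect_error(fit_intercept_only(bernoulli_dataset(10, 0)), "degenerate")
  expect_error(fit_intercept_only(bernoulli_dataset(10, 10)), "degenerate")
})

test_that("the dense-quadrature oracle behaves as an oracle should", {
  d <- tiny_dataset(seed = 4)
  ## all variances zero: integrals collapse to the Bernoulli log-likelihood
  vc0 <- variance_components(site = 0, interviewer = 0, household = 0)
  b0 <- -0.4
  bern <- sum(d$outcome * plogis(b0, log.p = TRUE) +
                (1 - d$outcome) * plogis(-b0, log.p = TRUE))
  expect_equal(loglik_oracle(d, b0, vc0, 101), bern, tolerance = 1e-12)

  ## single cluster, one observation, y = 1: independent trapezoid check
  d1 <- bernoulli_dataset(1, 1)
  z <- seq(-8, 8, length.out = 100001)
  direct <- log(sum(plogis(-1 + z) * dnorm(z)) * (z[2] - z[1]))
  expect_equal(loglik_oracle(d1, -1, variance_components(household = 1), 2001),
               direct, tolerance = 1e-8)

  ## quadrature convergence on a 3-level fixture
  vc <- variance_components(site = 0.3, interviewer = 0.5, household = 0.8)
  o1 <- loglik_oracle(d, -0.4, vc, 1001)
  o2 <- loglik_oracle(d, -0.4, vc, 2001)
  expect_lt(abs(o2 - o1), 1e-8)

  expect_error(loglik_oracle(bernoulli_dataset(100, 5), 0,
                             variance_components(household = 1)),
               "50 clusters")
})

test_that("nested-quadrature fits agree with the oracle at the optimum", {
  for (seed in c(4, 9)) {
    d <- tiny_dataset(seed = seed)
    f <- fit_glmm(d, model_spec(method = "agq", q_points = 21))
    o <- loglik_oracle(d, f$beta0_hat, f$varcomps, 2001)
    expect_lt(abs(f$loglik - o), 1e-4)
  }
})

test_that("an empty random-effects spec reduces to the intercept-only fit", {
  d <- tiny_dataset(seed = 2)
  f0 <- fit_glmm(d, model_spec(levels = character(0)))
  fi <- fit_intercept_only(d)
  expect_identical(f0$beta0_hat, fi$beta0_hat)
  expect_identical(f0$loglik, fi$loglik)
  expect_identical(f0$aic, fi$aic)
})

test_that("fitting data with no clustering recovers near-zero variances", {
  cfg <- population_config(seed = 31, villages_per_site = c(2, 2),
                           interviewers_per_site = c(3, 3),
                           households_per_village = 250,
                           household_size_dist = c(3, 3),
                           beta0 = qlogis(0.08))
  d <- generate_population(cfg)$data
  f <- fit_glmm(d, model_spec(tol = 1e-7))
  expect_true(all(unlist(f$varcomps$sigma2) < 0.05))
  fi <- fit_intercept_only(d)
  expect_lt(abs(f$beta0_hat - fi$beta0_hat), 3 * fi$se_beta0)
})

test_that("AIC/BIC arithmetic identities hold exactly", {
  d <- tiny_dataset(seed = 6)
  fits <- list(fit_intercept_only(d),
               fit_glmm(d, model_spec(levels = "household", tol = 1e-6)),
               fit_glmm(d, model_spec(method = "agq", q_points = 11)))
  for (f in fits) {
    expect_identical(f$aic, -2 * f$loglik + 2 * f$n_params)
    expect_identical(f$bic, -2 * f$loglik + log(f$n_obs) * f$n_params)
  }
})

test_that("optimization never degrades the likelihood from its start", {
  d <- tiny_dataset(seed = 8, n_hh = 10)
  f <- fit_glmm(d, model_spec(method = "agq", q_points = 21))
  start_ll <- loglik_oracle(d, qlogis(mean(d$outcome)),
                            variance_components(site = 0.09,
                                                interviewer = 0.09,
                                                household = 0.09), 1001)
  expect_gte(f$loglik + 1e-6, start_ll)
})

test_that("likelihood-ratio test arithmetic, clipping and boundary flag", {
  d <- tiny_dataset(seed = 12, n_hh = 16, sigma_w = 1.5)
  f0 <- fit_intercept_only(d)
  f1 <- fit_glmm(d, model_spec(levels = "household", tol = 1e-7))
  same <- lrt(f0, f0)
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)

  ## loglik difference of 3 with one extra parameter
  fa <- f1; fa$loglik <- f0$loglik + 3
  r <- lrt(f0, fa)
  expect_equal(r$statistic, 6, tolerance = 1e-12)
  expect_equal(r$df, 1)
  expect_equal(r$p_value, 0.0143, tolerance = 1e-3)
  expect_true(r$boundary)

  ## numerically lower alternative is clipped with a warning
  fb <- f1; fb$loglik <- f0$loglik - 0.5
  expect_warning(rc <- lrt(f0, fb), "clipped")
  expect_identical(rc$statistic, 0)

  f_other <- fit_intercept_only(bernoulli_dataset(100, 5))
  expect_error(lrt(f_other, f1), "different numbers")
})

test_that("household-level fit agrees with an independent mixed-model fitter", {
  ## lme4's adaptive quadrature is the external cross-check, never the engine
  cfg <- population_config(seed = 17, villages_per_site = c(2, 2),
                           interviewers_per_site = c(2, 2),
                           households_per_village = 300,
                           household_size_dist = c(4, 4),
                           beta0 = qlogis(0.07), sigma_w = 1.2)
  d <- generate_population(cfg)$data
  f <- fit_glmm(d, model_spec(levels = "household", tol = 1e-8))
  g <- lme4::glmer(outcome ~ 1 + (1 | household_id), data = d,
                   family = binomial, nAGQ = 25)
  expect_equal(f$beta0_hat, unname(lme4::fixef(g)), tolerance = 5e-3)
  expect_equal(f$varcomps$sigma2[["household"]],
               unname(as.numeric(lme4::VarCorr(g)$household_id)),
               tolerance = 0.02)
  expect_equal(f$loglik, as.numeric(stats::logLik(g)), tolerance = 1e-2)
})

test_that("sigma and Wald coverage recover in a replicated single-level study", {
  ## 200 simulated datasets, 400 households of 4: mean fitted sigma^2 within
  ## 10% of truth, beta0 interval coverage near nominal
  s2_true <- 1.0
  b0_true <- qlogis(0.15)
  est <- cov_hit <- numeric(200)
  for (r in 1:200) {
    cfg <- population_config(seed = 5000 + r, villages_per_site = c(1, 1),
                             interviewers_per_site = c(1, 1),
                             households_per_village = 200,
                             household_size_dist = c(4, 4),
                             beta0 = b0_true, sigma_w = sqrt(s2_true))
    d <- generate_population(cfg)$data
    f <- fit_glmm(d, model_spec(levels = "household", tol = 1e-7))
    est[r] <- f$varcomps$sigma2[["household"]]
    ci <- f$beta0_hat + c(-1.96, 1.96) * f$se_beta0
    cov_hit[r] <- ci[1] <= b0_true && b0_true <= ci[2]
  }
  expect_lt(abs(mean(est) - s2_true) / s2_true, 0.10)
  expect_gte(mean(cov_hit), 0.92)
  expect_lte(mean(cov_hit), 0.97)
})

test_that("model_spec validates nesting order and arguments", {
  expect_error(model_spec(levels = c("interviewer", "site")), "nesting order")
  expect_error(model_spec(levels = "county"), "unknown level")
  expect_error(model_spec(tol = 0), "tol")
  expect_error(fit_glmm(tiny_dataset(1),
                        model_spec(levels = "site")), NA)
})

test_that("non-nested cluster labels are rejected", {
  d <- tiny_dataset(seed = 1)
  d$interviewer_id[1] <- "I9"   # household split across interviewers
  expect_error(fit_glmm(d, model_spec()), "nesting")
})
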