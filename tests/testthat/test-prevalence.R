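test_that("crude prevalence arithmetic and interval symmetry", {
  d <- bernoulli_dataset(5000, 47)
  p <- crude_prevalence(d)
  expect_equal(p$theta_per_1000, 9.40, tolerance = 1e-12)
  expect_equal(p$sigma, 1000 * sqrt(0.0094 * (1 - 0.0094) / 5000),
               tolerance = 1e-12)
  expect_equal((p$lcb + p$ucb) / 2, p$theta_per_1000, tolerance = 1e-9)
  expect_equal(p$ucb - p$lcb, 2 * 1.96 * p$sigma, tolerance = 1e-9)
})

test_that("group tables keep first-appearance order and aggregate exactly", {
  d <- tiny_dataset(seed = 10, n_hh = 20)
  tab <- crude_prevalence(d, "interviewer_id")
  expect_identical(tab$label, unique(d$interviewer_id))
  ## event-weighted mean of group proportions equals the overall proportion
  expect_equal(sum(tab$n * tab$theta_per_1000) / sum(tab$n),
               crude_prevalence(d)$theta_per_1000, tolerance = 1e-12)
  expect_equal(sum(tab$events), sum(d$outcome))
})

test_that("published interval arithmetic is reproduced from the reference tables", {
  sv <- ref_table("reference_site_village.csv")
  ## every printed bound is theta -/+ 1.96 sigma up to print rounding:
  ## theta and sigma are printed to 2 dp, so a bound reconstructed from the
  ## printed values can differ by up to 0.005 + 1.96 * 0.005 ~ 0.015
  for (i in seq_len(nrow(sv))) {
    w <- wald_interval(sv$theta_per_1000[i], sv$sigma[i])
    expect_lt(abs(w[["lcb"]] - sv$lcb[i]), 0.016)
    expect_lt(abs(w[["ucb"]] - sv$ucb[i]), 0.016)
  }
  all_row <- sv[sv$label == "All", ]
  w <- wald_interval(all_row$theta_per_1000, all_row$sigma)
  expect_identical(round(unname(w), 2), c(8.60, 10.20))

  ## negative lower bound preserved, never truncated
  iv <- ref_table("reference_interviewer.csv")
  i8 <- iv[iv$label == "Interviewer 8", ]
  w8 <- wald_interval(i8$theta_per_1000, i8$sigma)
  expect_lt(w8[["lcb"]], 0)
  expect_lt(abs(w8[["lcb"]] - (-0.43)), 0.011)
})

test_that("summary arithmetic: ranges and gender means from the references", {
  sv <- ref_table("reference_site_village.csv")
  expect_equal(summary_arithmetic(sv[sv$group == "village_viwandani", ],
                                  "range"), 20.41, tolerance = 1e-9)
  expect_equal(summary_arithmetic(sv[sv$group == "village_korogocho", ],
                                  "range"), 12.76, tolerance = 1e-9)
  expect_identical(summary_arithmetic(sv[sv$label == "All", ], "range"), 0)

  iv <- ref_table("reference_interviewer.csv")
  mean_of <- function(site, sex)
    summary_arithmetic(iv[iv$site == site & iv$sex == sex, ], "mean_by")
  expect_equal(round(mean_of("Viwandani", "F"), 2), 7.44)
  expect_equal(round(mean_of("Viwandani", "M"), 2), 8.79)
  expect_equal(round(mean_of("Korogocho", "F"), 2), 9.31)
  expect_equal(round(mean_of("Korogocho", "M"), 2), 11.64)
})

test_that("adjusted prevalence: reductions and quadrature cross-check", {
  ## with all variances zero the population-average equals the crude rate
  d <- bernoulli_dataset(400, 30)
  f <- fit_glmm(d, model_spec(levels = character(0)))
  a <- adjusted_prevalence(f)
  expect_equal(a$theta_per_1000, crude_prevalence(d)$theta_per_1000,
               tolerance = 1e-9)

  f50 <- fit_intercept_only(bernoulli_dataset(1000, 500))
  a50 <- adjusted_prevalence(f50)
  expect_equal(a50$theta_per_1000, 500, tolerance = 1e-9)
  expect_equal(a50$theta_per_1000 - a50$lcb, a50$ucb - a50$theta_per_1000,
               tolerance = 1e-6)

  ## quadrature vs an independent dense trapezoid at beta0 = -4.69, s2 = 2.5
  fx <- f
  fx$beta0_hat <- -4.69
  fx$varcomps <- variance_components(site = 0.5, interviewer = 0.5,
                                     household = 1.5)
  ax <- adjusted_prevalence(fx)
  s <- sqrt(2.5)
  z <- seq(-8 * s, 8 * s, length.out = 20001)
  trap <- sum(plogis(-4.69 + z) * dnorm(z, 0, s)) * (z[2] - z[1])
  expect_equal(ax$theta_per_1000, 1000 * trap, tolerance = 1e-6)

  ## conditional variant is labelled and smaller for a rare outcome
  ac <- adjusted_prevalence(fx, estimand = "conditional")
  expect_identical(ac$estimand, "conditional")
  expect_lt(ac$theta_per_1000, ax$theta_per_1000)

  bad <- f
  bad$converged <- FALSE
  expect_error(adjusted_prevalence(bad), "non-converged")
})

test_that("chi-square homogeneity test matches the textbook statistic", {
  ## two groups with identical proportions and equal n
  d_eq <- as_survey_dataset(data.frame(
    individual_id = 1:200, site_id = rep(c("S1", "S2"), each = 100),
    village_id = rep(c("V1", "V2"), each = 100),
    household_id = sprintf("H%03d", 1:200),
    interviewer_id = rep(c("I1", "I2"), each = 100),
    interviewer_sex = "F",
    outcome = rep(c(rep(1L, 10), rep(0L, 90)), 2)))
  r_eq <- chi2_homogeneity(d_eq, "site_id")
  expect_equal(r_eq$statistic, 0, tolerance = 1e-12)
  expect_equal(r_eq$p_value, 1, tolerance = 1e-12)

  ## hand-computed Pearson statistic for [[90,10],[80,20]]
  d2 <- d_eq
  d2$outcome <- c(rep(1L, 10), rep(0L, 90), rep(1L, 20), rep(0L, 80))
  O <- matrix(c(90, 80, 10, 20), 2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  by_hand <- sum((O - E)^2 / E)
  r2 <- chi2_homogeneity(d2, "site_id")
  expect_equal(r2$statistic, by_hand, tolerance = 1e-9)
  expect_equal(r2$df, 1)

  d1 <- d_eq[d_eq$site_id == "S1", ]
  class(d1) <- class(d_eq)
  expect_error(chi2_homogeneity(d1, "site_id"), "at least 2 groups")
})

test_that("crude intervals undercover when clustering is ignored", {
  ## unclustered arm: binomial Wald coverage is near nominal; strongly
  ## household-clustered arm: the same interval falls apart
  icc_t <- c(household = 0.30, interviewer = 0.05, site = 0.05)
  tot <- (pi^2 / 3) / (1 - sum(icc_t))
  s2 <- icc_t * tot
  hits_flat <- hits_clus <- logical(300)
  for (r in 1:300) {
    cfg_f <- population_config(seed = 60000 + r, n_sites = 2,
                               villages_per_site = c(1, 1),
                               interviewers_per_site = c(1, 1),
                               households_per_village = 200,
                               household_size_dist = c(3, 3),
                               beta0 = qlogis(0.10))
    d_f <- generate_population(cfg_f)$data
    truth_f <- 1000 * marginal_prevalence(cfg_f)
    cp_f <- crude_prevalence(d_f)
    hits_flat[r] <- cp_f$lcb <= truth_f && truth_f <= cp_f$ucb

    cfg_c <- population_config(seed = 70000 + r, n_sites = 12,
                               villages_per_site = rep(1, 12),
                               interviewers_per_site = rep(2, 12),
                               households_per_village = 50,
                               household_size_dist = rep(2.5, 12),
                               beta0 = qlogis(0.10),
                               sigma_u = sqrt(s2[["site"]]),
                               sigma_v = sqrt(s2[["interviewer"]]),
                               sigma_w = sqrt(s2[["household"]]))
    cfg_c$beta0 <- qlogis(0.10)
    d_c <- generate_population(cfg_c)$data
    truth_c <- 1000 * marginal_prevalence(cfg_c)
    cp_c <- crude_prevalence(d_c)
    hits_clus[r] <- cp_c$lcb <= truth_c && truth_c <= cp_c$ucb
  }
  expect_gte(mean(hits_flat), 0.92)
  expect_lt(mean(hits_clus), 0.90)
})
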