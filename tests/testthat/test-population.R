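test_that("generation is deterministic and strictly nested", {
  cfg <- population_config(seed = 7, villages_per_site = c(2, 2),
                           interviewers_per_site = c(2, 2),
                           households_per_village = 40,
                           sigma_u = 0.3, sigma_v = 0.4, sigma_w = 0.8)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1$data, p2$data)
  expect_identical(p1$truth, p2$truth)
  cfg2 <- cfg; cfg2$seed <- 8L
  expect_false(identical(generate_population(cfg2)$data, p1$data))

  d <- p1$data
  ## single-valued nesting maps
  for (pair in list(c("household_id", "interviewer_id"),
                    c("household_id", "village_id"),
                    c("interviewer_id", "site_id"),
                    c("village_id", "site_id"))) {
    tab <- unique(d[, pair])
    expect_false(anyDuplicated(tab[[1]]) > 0)
  }
  sizes <- table(d$household_id)
  expect_true(all(sizes >= 1 & sizes <= 15))
  ## realized effects retained, mean-zero-distributed draws of right length
  expect_length(p1$truth$u, 2)
  expect_length(p1$truth$v, 4)
  expect_length(p1$truth$w, length(unique(d$household_id)))
})

test_that("truncated geometric size distribution hits its mean", {
  for (m in c(2.2, 3.5, 6)) {
    pr <- truncated_geometric_sizes(m)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_equal(sum((1:15) * pr), m, tolerance = 1e-8)
  }
  expect_error(truncated_geometric_sizes(0.5), "between 1 and 15")
})

test_that("marginal_prevalence quadrature: closed forms and oracle", {
  cfg0 <- population_config(beta0 = logit(0.0094))
  expect_identical(marginal_prevalence(cfg0), 0.0094)
  cfg_sym <- population_config(beta0 = 0, sigma_u = 0.7, sigma_v = 0.3,
                               sigma_w = 1.1)
  expect_equal(marginal_prevalence(cfg_sym), 0.5, tolerance = 1e-9)
  ## independent trapezoid oracle, total latent SD 1
  cfg1 <- population_config(beta0 = -4.66, sigma_w = 1)
  z <- seq(-8, 8, length.out = 4001)
  f <- plogis(-4.66 + z) * dnorm(z)
  oracle <- sum((f[-1] + f[-length(f)]) / 2 * diff(z))
  expect_equal(marginal_prevalence(cfg1), oracle, tolerance = 1e-7)
})

test_that("empirical rate of a large unclustered population matches the closed form", {
  ## no cluster variance, so the binomial 3-SE band applies directly
  cfg <- population_config(seed = 21, villages_per_site = c(6, 6),
                           interviewers_per_site = c(6, 6),
                           households_per_village = 1500,
                           household_size_dist = c(3, 3),
                           beta0 = logit(0.0094))
  d <- generate_population(cfg)$data
  p <- marginal_prevalence(cfg)
  tol <- 3 * sqrt(p * (1 - p) / nrow(d))
  expect_lt(abs(mean(d$outcome) - p), tol)
})

test_that("household clustering shows up as within-household concordance", {
  cfg <- population_config(seed = 3, villages_per_site = c(2, 2),
                           interviewers_per_site = c(2, 2),
                           households_per_village = 400,
                           household_size_dist = c(4, 4),
                           beta0 = qlogis(0.2), sigma_w = 3)
  d <- generate_population(cfg)$data
  expect_gt(pair_concordance(d, "household_id"),
            pair_concordance(d, "village_id"))
})

test_that("zero-variance outcomes are exchangeable across households", {
  cfg <- population_config(seed = 5, villages_per_site = c(2, 2),
                           interviewers_per_site = c(2, 2),
                           households_per_village = 150,
                           household_size_dist = c(4, 4),
                           beta0 = qlogis(0.3))
  d <- generate_population(cfg)$data
  obs <- pair_concordance(d, "household_id")
  set.seed(99)
  perm <- replicate(199, {
    dd <- d
    dd$outcome <- sample(dd$outcome)
    pair_concordance(dd, "household_id")
  })
  p_val <- (1 + sum(perm >= obs)) / 200
  expect_gt(p_val, 0.05)
})

test_that("dataset text round trip is exact, including missing outcomes", {
  cfg <- population_config(seed = 2, villages_per_site = c(2, 1),
                           interviewers_per_site = c(2, 1),
                           households_per_village = 30, sigma_w = 1)
  d <- generate_population(cfg)$data
  d$outcome[c(3, 17)] <- NA_integer_
  tf <- tempfile(fileext = ".csv")
  write_dataset(d, tf)
  d2 <- read_dataset(tf)
  expect_identical(as.data.frame(d), as.data.frame(d2))
})

test_that("malformed files are rejected with the offending line", {
  hdr <- "individual_id,site_id,village_id,household_id,interviewer_id,interviewer_sex,outcome"
  tf <- tempfile(fileext = ".csv")
  writeLines(c(hdr, "1,S1,V1,H1,I1,F,0", "2,S1,V1,H1,I1,F,2"), tf)
  expect_error(read_dataset(tf), "line 3")
  writeLines(c(hdr, "1,S1,V1,H1,I1,F,0", "2,S1,V1,H1,I2,F,1"), tf)
  expect_error(read_dataset(tf), "nesting")
})

test_that("population config round-trips through its YAML sidecar", {
  cfg <- preset_survey_config(seed = 9)
  tf <- tempfile(fileext = ".yaml")
  write_config(cfg, tf)
  cfg2 <- read_config(tf)
  for (f in c("beta0", "sigma_u", "sigma_v", "sigma_w", "seed",
              "villages_per_site", "interviewers_per_site"))
    expect_equal(cfg2[[f]], cfg[[f]], tolerance = 1e-12)
  expect_equal(cfg2$household_size_dist, cfg$household_size_dist,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the calibrated preset solves its own targets", {
  cfg <- preset_survey_config()
  expect_equal(marginal_prevalence(cfg), 0.0094, tolerance = 1e-8)
  vc <- variance_components(site = cfg$sigma_u^2,
                            interviewer = cfg$sigma_v^2,
                            household = cfg$sigma_w^2)
  expect_equal(icc(vc, "household"), 0.397, tolerance = 1e-8)
  expect_equal(icc(vc, "interviewer"), 0.101, tolerance = 1e-8)
  expect_equal(icc(vc, "site"), 0.070, tolerance = 1e-8)
})
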