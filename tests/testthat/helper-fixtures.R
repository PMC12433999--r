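## Small deterministic fixtures built in code.

## A tiny nested dataset: 2 sites, n_int interviewers, households of
## size hh_size, outcomes drawn from a household random-intercept model.
tiny_dataset <- function(seed = 1, n_hh = 12, hh_size = 3, n_int = 4,
                         beta0 = -0.5, sigma_w = 1) {
  set.seed(seed)
  iv_of_hh <- rep(sprintf("I%d", seq_len(n_int)),
                  each = ceiling(n_hh / n_int))[seq_len(n_hh)]
  hh <- rep(sprintf("H%02d", seq_len(n_hh)), each = hh_size)
  iv <- rep(iv_of_hh, each = hh_size)
  si <- ifelse(iv %in% sprintf("I%d", seq_len(ceiling(n_int / 2))),
               "S1", "S2")
  eta <- beta0 + rep(rnorm(n_hh, 0, sigma_w), each = hh_size)
  as_survey_dataset(data.frame(
    individual_id = seq_along(hh), site_id = si,
    village_id = paste0(si, "_V1"), household_id = hh,
    interviewer_id = iv, interviewer_sex = "F",
    outcome = rbinom(length(hh), 1, plogis(eta)),
    stringsAsFactors = FALSE))
}

## Dataset with a given event count among n records, one household each.
bernoulli_dataset <- function(n, events) {
  as_survey_dataset(data.frame(
    individual_id = seq_len(n), site_id = "S1", village_id = "S1_V1",
    household_id = sprintf("H%06d", seq_len(n)), interviewer_id = "I1",
    interviewer_sex = "F",
    outcome = c(rep(1L, events), rep(0L, n - events)),
    stringsAsFactors = FALSE))
}

ref_table <- function(name) {
  read.csv(system.file("extdata", name, package = "clustprev"),
           stringsAsFactors = FALSE)
}

## Empirical pairwise outcome concordance within a grouping.
pair_concordance <- function(data, group) {
  g <- split(data$outcome, data[[group]])
  num <- 0; den <- 0
  for (y in g) {
    m <- length(y)
    if (m < 2) next
    s <- sum(y)
    num <- num + s * (s - 1) + (m - s) * (m - s - 1)
    den <- den + m * (m - 1)
  }
  num / den
}
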