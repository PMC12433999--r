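#' Missing-at-random attrition model
#'
#' Describes an outcome-dropout mechanism on the logit scale,
#' \deqn{\mathrm{logit}\,P(\text{missing}) = \alpha +
#'   \gamma_s \mathbf{1}[\text{site} = \text{site\_level}] +
#'   \gamma_h (\text{household size} - \overline{\text{size}}) +
#'   \gamma_x \mathbf{1}[\text{interviewer female}]}
#' Dropout depends only on fully observed design variables, never on the
#' outcome, so the mechanism is missing at random by construction.  The
#' intercept \eqn{\alpha} is never user-set; it is solved by
#' \code{\link{calibrate_intercept}} so the mean dropout probability over
#' the records equals \code{target_rate}.
#'
#' @param target_rate Marginal missingness proportion in (0, 1); 0 disables
#'   attrition.
#' @param site_coef Log-odds increment for records in \code{site_level}.
#' @param hsize_coef Log-odds slope per household member (centred).
#' @param sex_coef Log-odds increment for female interviewers.
#' @param village_coef Log-odds slope on the standardized leave-one-out
#'   village event rate.  A positive value up-weights dropout in
#'   high-prevalence villages -- the prevalence-correlated (but still
#'   missing-at-random) mechanism used to study attrition bias: the rate
#'   excludes the record's own outcome, so dropout depends only on data
#'   observed for other individuals, never on the value that goes missing.
#' @param site_level Site id receiving \code{site_coef}; \code{NULL} picks
#'   the last site in first-appearance order at calibration time.
#' @param seed Integer seed for the dropout draws.
#' @return An object of class \code{mar_model} (uncalibrated:
#'   \code{intercept = NA}).
#' @export
mar_model <- function(target_rate, site_coef = 0.4, hsize_coef = 0.1,
                      sex_coef = 0, village_coef = 0,
                      site_level = NULL, seed = 1L) {
  if (target_rate < 0 || target_rate >= 1)
    stop("target_rate must be in [0, 1)", call. = FALSE)
  structure(list(target_rate = target_rate, site_coef = site_coef,
                 hsize_coef = hsize_coef, sex_coef = sex_coef,
                 village_coef = village_coef,
                 site_level = site_level, intercept = NA_real_,
                 seed = as.integer(seed)),
            class = "mar_model")
}

## linear predictor of the dropout model without intercept
mar_linpred <- function(data, model) {
  sizes <- stats::ave(rep(1L, nrow(data)), data$household_id, FUN = sum)
  site_level <- model$site_level %||% unique(data$site_id)[
    length(unique(data$site_id))]
  lp <- model$site_coef * (data$site_id == site_level) +
    model$hsize_coef * (sizes - mean(sizes)) +
    model$sex_coef * (data$interviewer_sex == "F")
  vc <- model$village_coef %||% 0
  if (vc != 0) {
    if (anyNA(data$outcome))
      stop("village-rate dropout channel needs fully observed outcomes",
           call. = FALSE)
    vsum <- stats::ave(data$outcome, data$village_id, FUN = sum)
    vn <- stats::ave(rep(1L, nrow(data)), data$village_id, FUN = sum)
    loo <- (vsum - data$outcome) / pmax(vn - 1L, 1L)
    vrate <- stats::ave(loo, data$village_id, FUN = mean)
    z <- (loo - mean(vrate)) / stats::sd(unique(vrate))
    lp <- lp + vc * z
  }
  lp
}

#' Calibrate the attrition intercept to the target rate
#'
#' Bisection on the intercept until the mean dropout probability over the
#' records is within 1e-6 of \code{target_rate}.  Deterministic; fails if
#' the target is unattainable given the coefficient magnitudes.
#'
#' @param data A \code{\link{survey_dataset}}.
#' @param model A \code{\link{mar_model}}.
#' @return The model with \code{intercept} filled in (and
#'   \code{site_level} resolved).
#' @export
calibrate_intercept <- function(data, model) {
  stopifnot(inherits(model, "mar_model"))
  if (model$target_rate == 0) { model$intercept <- -Inf; return(model) }
  if (model$target_rate <= 0.001 || model$target_rate >= 0.999)
    stop("target_rate must lie in (0.001, 0.999) for calibration",
         call. = FALSE)
  model$site_level <- model$site_level %||% unique(data$site_id)[
    length(unique(data$site_id))]
  lp <- mar_linpred(data, model)
  mean_rate <- function(a) mean(inv_logit(a + lp))
  lo <- -40; hi <- 40
  if (mean_rate(lo) > model$target_rate || mean_rate(hi) < model$target_rate)
    stop("target rate unattainable under the given coefficients",
         call. = FALSE)
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (mean_rate(mid) < model$target_rate) lo <- mid else hi <- mid
    if (abs(mean_rate(mid) - model$target_rate) < 1e-6 &&
        (hi - lo) < 1e-9) break
  }
  model$intercept <- (lo + hi) / 2
  model
}

#' Impose missing-at-random attrition on outcomes
#'
#' Each record's outcome is set to missing independently with its
#' model-implied dropout probability; cluster labels and covariates remain
#' fully observed.  Calibrates the intercept first if needed.  Deterministic
#' given \code{model$seed}.
#'
#' @param data A \code{\link{survey_dataset}}.
#' @param model A \code{\link{mar_model}}.
#' @return The dataset with missing outcomes.
#' @export
apply_attrition <- function(data, model) {
  stopifnot(inherits(model, "mar_model"))
  if (model$target_rate == 0) return(data)
  if (!is.finite(model$intercept)) model <- calibrate_intercept(data, model)
  pr <- inv_logit(model$intercept + mar_linpred(data, model))
  drop <- with_seed(split_seed(model$seed, "attrition"),
                    stats::runif(nrow(data)) < pr)
  out <- data
  out$outcome[drop] <- NA_integer_
  out
}
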