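#' Crude prevalence per 1,000 with Wald intervals
#'
#' For each group (or the whole dataset), the sample proportion scaled to
#' events per 1,000 with the binomial Wald standard error
#' \eqn{1000\sqrt{\hat p(1-\hat p)/n}} and 95\% bounds
#' \eqn{\hat\theta \mp 1.96\,\sigma}.  Lower bounds are deliberately not
#' truncated at zero: for rare outcomes in small groups a negative Wald
#' bound is part of the honest interval arithmetic.  Groups appear in order
#' of first appearance in the data.
#'
#' @param data A \code{\link{survey_dataset}}; records with missing outcomes
#'   are excluded.
#' @param group_by Optional column name to group by (e.g. \code{"site_id"},
#'   \code{"village_id"}, \code{"interviewer_id"}); \code{NULL} gives the
#'   single overall row labelled \code{"All"}.
#' @return A \code{prevalence_table}: data frame with columns \code{label},
#'   \code{n}, \code{events}, \code{theta_per_1000}, \code{sigma},
#'   \code{lcb}, \code{ucb}.
#' @export
crude_prevalence <- function(data, group_by = NULL) {
  d <- complete_cases(data)
  if (is.null(group_by)) {
    g <- rep("All", nrow(d))
  } else {
    if (!group_by %in% names(d))
      stop("unknown grouping column '", group_by, "'", call. = FALSE)
    g <- as.character(d[[group_by]])
  }
  labs <- unique(g)
  rows <- lapply(labs, function(lab) {
    y <- d$outcome[g == lab]
    n <- length(y)
    if (n == 0L) {
      warning("empty group '", lab, "' skipped")
      return(NULL)
    }
    prevalence_row(lab, n, sum(y))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("prevalence_table", "data.frame")
  out
}

prevalence_row <- function(label, n, events) {
  p <- events / n
  theta <- 1000 * p
  sigma <- 1000 * sqrt(p * (1 - p) / n)
  data.frame(label = label, n = n, events = events,
             theta_per_1000 = theta, sigma = sigma,
             lcb = theta - 1.96 * sigma, ucb = theta + 1.96 * sigma,
             stringsAsFactors = FALSE)
}

#' @export
print.prevalence_table <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  for (cl in c("theta_per_1000", "sigma", "lcb", "ucb"))
    y[[cl]] <- round(y[[cl]], digits)
  print(y)
  invisible(x)
}

#' Cluster-adjusted prevalence from a fitted model
#'
#' The default estimand is population-averaged: with fitted intercept
#' \eqn{\hat\beta_0} and total cluster variance
#' \eqn{\hat\sigma^2 = \sum_\ell \hat\sigma_\ell^2},
#' \deqn{\hat\theta = 1000 \int \mathrm{logit}^{-1}(\hat\beta_0 + z)\,
#'   \phi(z; 0, \hat\sigma^2)\, dz,}
#' the marginal event rate of the fitted hierarchical model.  The 95\%
#' interval applies the same transform to
#' \eqn{\hat\beta_0 \mp 1.96\,\mathrm{se}(\hat\beta_0)}.  The
#' \code{"conditional"} variant reports
#' \eqn{1000\,\mathrm{logit}^{-1}(\hat\beta_0)}, the rate of a cluster with
#' all random effects at zero; for a rare outcome it is smaller than the
#' population-averaged rate.  The returned row carries the estimand label.
#'
#' @param fit A converged \code{glmm_fit}.
#' @param estimand \code{"population"} (default) or \code{"conditional"}.
#' @return A one-row \code{prevalence_table} with an \code{estimand} column;
#'   \code{sigma} is the implied scale of the interval,
#'   \code{(ucb - lcb) / (2 * 1.96)}.
#' @export
adjusted_prevalence <- function(fit, estimand = c("population",
                                                  "conditional")) {
  stopifnot(inherits(fit, "glmm_fit"))
  estimand <- match.arg(estimand)
  if (!isTRUE(fit$converged))
    stop("refusing to compute adjusted prevalence from a non-converged fit",
         call. = FALSE)
  s2 <- sum(fit$varcomps$sigma2)
  transform <- function(b) {
    if (estimand == "population") gaussian_average_invlogit(b, s2)
    else inv_logit(b)
  }
  theta <- 1000 * transform(fit$beta0_hat)
  if (is.finite(fit$se_beta0)) {
    lcb <- 1000 * transform(fit$beta0_hat - 1.96 * fit$se_beta0)
    ucb <- 1000 * transform(fit$beta0_hat + 1.96 * fit$se_beta0)
  } else {
    lcb <- ucb <- NA_real_
  }
  out <- data.frame(label = "adjusted", n = fit$n_obs,
                    events = NA_integer_,
                    theta_per_1000 = theta,
                    sigma = (ucb - lcb) / (2 * 1.96),
                    lcb = lcb, ucb = ucb,
                    estimand = estimand, stringsAsFactors = FALSE)
  class(out) <- c("prevalence_table", "data.frame")
  out
}

#' Pearson chi-square test of homogeneity across groups
#'
#' Tests equality of outcome proportions across the grouping with the
#' uncorrected Pearson statistic on the groups-by-outcome contingency table
#' (degrees of freedom: groups minus 1).
#'
#' @param data A \code{\link{survey_dataset}}.
#' @param grouping Column name defining the groups.
#' @return A list: \code{statistic}, \code{df}, \code{p_value} and
#'   \code{low_expected} (\code{TRUE} when any expected cell is below 1, in
#'   which case the asymptotic reference is unreliable).
#' @export
chi2_homogeneity <- function(data, grouping) {
  d <- complete_cases(data)
  if (!grouping %in% names(d))
    stop("unknown grouping column '", grouping, "'", call. = FALSE)
  g <- factor(d[[grouping]], levels = unique(d[[grouping]]))
  if (nlevels(g) < 2L)
    stop("need at least 2 groups for a homogeneity test", call. = FALSE)
  tab <- table(g, factor(d$outcome, levels = c(0, 1)))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value),
       low_expected = any(ct$expected < 1))
}

#' Wald interval from a point estimate and standard error
#'
#' \eqn{\hat\theta \mp z\,\sigma}, the interval convention used throughout
#' the prevalence tables (no truncation at zero).  Useful for
#' reconstructing interval bounds from published point estimates and
#' standard errors.
#'
#' @param theta Point estimate (any scale).
#' @param sigma Standard error on the same scale.
#' @param z Normal quantile (default 1.96).
#' @return Named vector \code{c(lcb, ucb)}.
#' @export
wald_interval <- function(theta, sigma, z = 1.96) {
  c(lcb = theta - z * sigma, ucb = theta + z * sigma)
}

#' Summary arithmetic over a prevalence table
#'
#' \code{kind = "range"}: difference between the largest and smallest point
#' estimates.  \code{kind = "mean_by"}: unweighted mean of the point
#' estimates over the rows selected by \code{labels} (all rows when
#' \code{NULL}).
#'
#' @param table A \code{prevalence_table} (or data frame with a
#'   \code{theta_per_1000} column).
#' @param kind \code{"range"} or \code{"mean_by"}.
#' @param labels Optional character vector of row labels for
#'   \code{"mean_by"}.
#' @return A single number on the per-1,000 scale.
#' @export
summary_arithmetic <- function(table, kind = c("range", "mean_by"),
                               labels = NULL) {
  kind <- match.arg(kind)
  if (!nrow(table)) stop("empty table", call. = FALSE)
  th <- table$theta_per_1000
  if (kind == "range") return(max(th) - min(th))
  if (!is.null(labels)) th <- th[table$label %in% labels]
  if (!length(th)) stop("no rows match the requested labels", call. = FALSE)
  mean(th)
}
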