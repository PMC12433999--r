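#' Brute-force marginal log-likelihood by dense nested quadrature
#'
#' Independent test oracle for the random-intercept likelihood: integrates
#' the random effects level by level (household, then interviewer, then
#' site) with dense trapezoid rules spanning +/- 8 SD at every level,
#' working throughout in log space.  The site and interviewer grids share a
#' common lattice spacing so their sums land exactly on lattice points and
#' household contributions are evaluated without interpolation.  It shares
#' no code with the fitting kernels: no sufficient-statistic collapsing and
#' no adaptive recentring.  Deliberately restricted to small problems.
#'
#' @param data A \code{\link{survey_dataset}} (complete cases are used).
#' @param beta0 Intercept on the logit scale.
#' @param varcomps A \code{\link{variance_components}} object naming the
#'   levels to integrate (a level absent from it contributes no effect).
#' @param n_points Trapezoid points per level (default 1001).
#' @return The marginal log-likelihood.
#' @export
loglik_oracle <- function(data, beta0, varcomps, n_points = 1001L) {
  stopifnot(inherits(varcomps, "variance_components"))
  d <- complete_cases(data)
  n_clusters <- length(unique(d$household_id)) +
    length(unique(d$interviewer_id)) + length(unique(d$site_id))
  if (n_clusters > 50L)
    stop("loglik_oracle is a test oracle for small data (<= 50 clusters); ",
         "got ", n_clusters, call. = FALSE)
  n_points <- as.integer(n_points)
  s2 <- varcomps$sigma2
  sd_of <- function(lv) if (lv %in% names(s2)) sqrt(s2[[lv]]) else 0
  su <- sd_of("site"); sv <- sd_of("interviewer"); sw <- sd_of("household")

  ## grids for u and v share one spacing so u + v is again a lattice value
  smax <- max(su, sv)
  if (smax > 0) {
    step <- 16 * smax / (n_points - 1L)
    u_off <- if (su > 0) seq(-round(8 * su / step), round(8 * su / step)) else 0L
    v_off <- if (sv > 0) seq(-round(8 * sv / step), round(8 * sv / step)) else 0L
  } else {
    step <- 0
    u_off <- v_off <- 0L
  }
  u_grid <- u_off * step
  v_grid <- v_off * step
  ## lattice of possible u + v values
  s_off <- seq(min(u_off) + min(v_off), max(u_off) + max(v_off))
  s_grid <- beta0 + s_off * step

  ## log trapezoid weights for a grid of values of a N(0, s) density
  log_trap_w <- function(grid, s) {
    if (length(grid) == 1L) return(0)
    lw <- stats::dnorm(grid, 0, s, log = TRUE) + log(grid[2] - grid[1])
    lw[c(1, length(lw))] <- lw[c(1, length(lw))] - log(2)
    lw
  }
  logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

  ## household-integrated log-likelihood on the full s lattice
  hh_ids <- unique(d$household_id)
  A <- matrix(0, length(hh_ids), length(s_grid))
  w_grid <- if (sw > 0) seq(-8 * sw, 8 * sw, length.out = n_points) else 0
  lww <- log_trap_w(w_grid, sw)
  for (h in seq_along(hh_ids)) {
    y <- d$outcome[d$household_id == hh_ids[h]]
    acc <- matrix(0, length(s_grid), length(w_grid))
    for (k in seq_along(y)) {
      e <- outer(s_grid, w_grid, "+")
      acc <- acc + y[k] * stats::plogis(e, log.p = TRUE) +
        (1 - y[k]) * stats::plogis(-e, log.p = TRUE)
    }
    if (sw > 0) {
      acc <- sweep(acc, 2, lww, "+")
      mx <- apply(acc, 1, max)
      A[h, ] <- mx + log(rowSums(exp(acc - mx)))
    } else {
      A[h, ] <- acc[, 1]
    }
  }

  ## map household -> interviewer -> site
  first <- !duplicated(d$household_id)
  hh_iv <- d$interviewer_id[first][match(hh_ids, d$household_id[first])]
  iv_ids <- unique(d$interviewer_id)
  iv_si <- d$site_id[match(iv_ids, d$interviewer_id)]
  lwv <- log_trap_w(v_grid, sv)
  lwu <- log_trap_w(u_grid, su)
  off0 <- 1L - s_off[1]          # lattice index of offset 0

  total <- 0
  for (site in unique(d$site_id)) {
    B_site <- numeric(length(u_grid))   # log-integrand pieces summed over interviewers
    for (iv in iv_ids[iv_si == site]) {
      Ai <- colSums(A[hh_iv == iv, , drop = FALSE])  # over the s lattice
      ## for each u offset: integrate over v offsets
      Bj <- vapply(seq_along(u_off), function(a) {
        idx <- off0 + u_off[a] + v_off
        if (sv > 0) logsumexp(Ai[idx] + lwv) else Ai[idx]
      }, numeric(1))
      B_site <- B_site + Bj
    }
    total <- total + if (su > 0) logsumexp(B_site + lwu) else B_site[1]
  }
  total
}

#' Likelihood-ratio test between two nested fits
#'
#' Twice the log-likelihood difference, clipped at zero, referred to the
#' chi-square upper tail with degrees of freedom equal to the difference in
#' free parameters.  When the tested parameters are variances on the
#' boundary of their space the naive chi-square reference is conservative;
#' the result carries a \code{boundary} flag rather than a mixture
#' correction.
#'
#' @param fit_null,fit_alt \code{glmm_fit} objects on the same records,
#'   the null model nested in the alternative.
#' @return A list: \code{statistic}, \code{df}, \code{p_value},
#'   \code{boundary} and \code{clipped}.
#' @export
lrt <- function(fit_null, fit_alt) {
  stopifnot(inherits(fit_null, "glmm_fit"), inherits(fit_alt, "glmm_fit"))
  if (fit_null$n_obs != fit_alt$n_obs)
    stop("fits use different numbers of observations; not comparable",
         call. = FALSE)
  if (fit_null$n_params > fit_alt$n_params)
    stop("null model must have no more parameters than the alternative",
         call. = FALSE)
  stat <- 2 * (fit_alt$loglik - fit_null$loglik)
  clipped <- stat < 0
  if (clipped) {
    warning("alternative log-likelihood below null (numerical); ",
            "statistic clipped to 0")
    stat <- 0
  }
  df <- fit_alt$n_params - fit_null$n_params
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  ## variance parameters are tested on the boundary of their space
  boundary <- length(fit_alt$spec$levels) > length(fit_null$spec$levels)
  list(statistic = stat, df = df, p_value = p,
       boundary = boundary, clipped = clipped)
}
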