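## Intercept-only logistic model with nested random intercepts, fitted by
## maximum likelihood.  The model is fitted without delegating to an
## off-the-shelf mixed-model package: because the linear predictor carries no
## covariates, all individuals of a cluster at the innermost modelled level
## share one success probability, so the data collapse to (size, case-count)
## sufficient statistics and the innermost random effect can be integrated
## out by adaptive Gauss-Hermite quadrature at negligible cost.  Upper-level
## effects (site, interviewer), whose clusters are large and whose
## conditional posteriors are therefore close to normal, are handled by a
## Laplace approximation with the intercept profiled into the inner Newton
## step ("laplace" method), or by nested adaptive quadrature at every level
## ("agq" method, for accuracy checks and small data).

MODEL_LEVELS <- c("site", "interviewer", "household")
LEVEL_COLUMN <- c(site = "site_id", interviewer = "interviewer_id",
                  household = "household_id")

#' Model specification for the random-intercept fit
#'
#' @param levels Character vector, an ordered subset of
#'   \code{c("site", "interviewer", "household")} declared as nested random
#'   intercepts (outermost first).  \code{character(0)} requests the fixed
#'   intercept-only model.
#' @param method \code{"laplace"} (default): adaptive Gauss-Hermite
#'   quadrature over the innermost declared level, Laplace approximation
#'   over the remaining levels, intercept profiled.  \code{"agq"}: nested
#'   adaptive Gauss-Hermite quadrature at every declared level; accurate for
#'   any cluster size but intended for accuracy checks and small data.
#' @param q_points Quadrature points per level (default 15).
#' @param max_iter Maximum outer iterations.
#' @param tol Relative convergence tolerance of the outer optimizer.
#' @return An object of class \code{model_spec}.
#' @export
model_spec <- function(levels = c("site", "interviewer", "household"),
                       method = c("laplace", "agq"),
                       q_points = NULL, max_iter = 200, tol = 1e-8) {
  method <- match.arg(method)
  levels <- as.character(levels)
  if (!all(levels %in% MODEL_LEVELS))
    stop("unknown level(s): ", paste(setdiff(levels, MODEL_LEVELS),
                                     collapse = ", "), call. = FALSE)
  if (anyDuplicated(levels)) stop("duplicated levels", call. = FALSE)
  if (!identical(levels, MODEL_LEVELS[MODEL_LEVELS %in% levels]))
    stop("levels must respect the nesting order site > interviewer > household",
         call. = FALSE)
  if (is.null(q_points)) q_points <- 15L
  if (q_points < 1) stop("q_points must be >= 1", call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  structure(list(levels = levels, method = method,
                 q_points = as.integer(q_points),
                 max_iter = as.integer(max_iter), tol = tol),
            class = "model_spec")
}

#' Variance components of a fitted (or hypothesized) model
#'
#' Cluster-level variances on the latent logistic scale, together with the
#' fixed latent residual variance \eqn{\pi^2/3} of the logistic threshold
#' representation.
#'
#' @param site,interviewer,household Variances (\eqn{\sigma^2 \ge 0});
#'   \code{NULL} for a level absent from the model.
#' @return An object of class \code{variance_components}: a named list with
#'   \code{sigma2} (named numeric over included levels) and \code{residual}.
#' @export
variance_components <- function(site = NULL, interviewer = NULL,
                                household = NULL) {
  s2 <- c(site = site, interviewer = interviewer, household = household)
  if (length(s2) && any(s2 < 0))
    stop("variances must be >= 0", call. = FALSE)
  structure(list(sigma2 = s2, residual = LOGISTIC_RESIDUAL),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("variance components (latent logistic scale):\n")
  for (lv in names(x$sigma2))
    cat(sprintf("  %-12s sigma2 = %.4f\n", lv, x$sigma2[[lv]]))
  cat(sprintf("  %-12s sigma2 = %.4f (fixed)\n", "residual", x$residual))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Collapsing to sufficient statistics

## Collapse complete-case records for a set of declared levels.  The
## "binomial unit" is the cluster at the innermost declared level (each of
## its individuals shares one linear predictor); units with identical
## (size, cases) and identical upper-level membership are merged with a
## multiplicity count.
collapse_for_fit <- function(data, levels) {
  d <- complete_cases(data)
  inner <- levels[length(levels)]
  uppers <- levels[-length(levels)]
  unit <- d[[LEVEL_COLUMN[inner]]]
  uf <- factor(unit, levels = unique(unit))
  m <- as.integer(rowsum(rep(1L, nrow(d)), uf)[, 1])
  cc <- as.integer(rowsum(d$outcome, uf)[, 1])
  first <- !duplicated(uf)
  ord <- match(levels(uf), unit[first])
  up_ids <- lapply(uppers, function(lv) d[[LEVEL_COLUMN[lv]]][first][ord])
  names(up_ids) <- uppers
  key <- paste(m, cc, if (length(uppers))
    do.call(paste, c(up_ids, sep = "\r")) else "")
  ix <- !duplicated(key)
  cnt <- as.integer(rowsum(rep(1L, length(key)),
                           factor(key, levels = key[ix]))[, 1])
  upper_idx <- lapply(up_ids, function(v) {
    f <- factor(v[ix], levels = unique(v[ix]))
    list(idx = as.integer(f), ids = levels(f))
  })
  out <- list(m = m[ix], c = cc[ix], cnt = cnt,
              uppers = uppers, inner = inner, upper_idx = upper_idx,
              n_obs = nrow(d), n_events = sum(d$outcome),
              unit_tbl = list(m = m, c = cc, ids = levels(uf),
                              up = lapply(up_ids, identity)))
  ## parent map between two upper levels (interviewer within site)
  if (length(uppers) == 2L) {
    iv <- upper_idx[[2]]$idx; si <- upper_idx[[1]]$idx
    out$site_of_intv <- si[match(seq_along(upper_idx[[2]]$ids), iv)]
  }
  out
}

## ---------------------------------------------------------------------------
## Adaptive Gauss-Hermite kernel over the innermost level
##
## For collapsed binomial groups (m, c) at linear predictor t with
## random-effect sd s, returns the integrated log-likelihood
##   g(t) = log Integral Binom-kernel(c of m | plogis(t + w)) N(w; 0, s^2) dw
## and its first two derivatives in t (Fisher identities under the adaptive
## node posterior).  Nodes are recentred at the per-group conditional mode
## and rescaled by the conditional curvature; modes are warm-started across
## calls, which keeps repeated evaluation cheap inside optimization loops.
make_agh_kernel <- function(m, c, q_points) {
  gq <- pracma::gaussHermite(q_points)
  z <- gq$x
  lwz <- log(gq$w) + z^2
  zs <- z * sqrt(2)
  G <- length(m)
  mc <- m - c
  w_warm <- rep(0, G)

  function(t, s, deriv = TRUE, warm = TRUE) {
    if (s < 1e-8) {           # degenerate: no inner integration
      p <- sigmoid(t)
      g <- m * log_sigmoid(t) - mc * t
      if (!deriv) return(list(g = g))
      return(list(g = g, g1 = c - m * p, g2 = -m * p * (1 - p)))
    }
    isw2 <- 1 / (2 * s^2)
    hfun <- function(w) {
      x <- t + w
      m * log_sigmoid(x) - mc * x - w * w * isw2
    }
    w <- if (warm) w_warm else rep(0, G)
    h0 <- hfun(w)
    for (it in 1:40) {
      p <- sigmoid(t + w)
      h1 <- (c - m * p) - w / s^2
      if (max(abs(h1)) < 1e-9) break
      h2 <- -m * p * (1 - p) - 1 / s^2
      st <- -h1 / h2
      al <- rep(1, G)
      for (bt in 1:10) {
        hn <- hfun(w + al * st)
        bad <- hn < h0 - 1e-12
        if (!any(bad)) break
        al[bad] <- al[bad] / 2
      }
      w <- w + al * st
      h0 <- hfun(w)
    }
    if (warm) w_warm <<- w
    p <- sigmoid(t + w)
    tau <- 1 / sqrt(m * p * (1 - p) + 1 / s^2)
    W <- w + outer(tau, zs)
    S <- t + W
    LP <- log_sigmoid(S)
    A <- (m * LP - mc * S - W * W * isw2) + rep(lwz, each = G)
    lse <- row_logsumexp(A)
    g <- log(tau / s) - 0.5 * log(pi) + lse
    if (!deriv) return(list(g = g))
    Pi <- exp(A - lse)
    P <- exp(LP)
    D1 <- c - m * P
    D2 <- -m * P * (1 - P)
    g1 <- rowSums(Pi * D1)
    g2 <- rowSums(Pi * (D1 * D1 + D2)) - g1 * g1
    list(g = g, g1 = g1, g2 = g2)
  }
}

## ---------------------------------------------------------------------------
## "laplace" objective: AGH over the inner level, Laplace over upper levels,
## intercept profiled into the inner Newton step.

make_laplace_objective <- function(cd, q_points) {
  kern <- make_agh_kernel(cd$m, cd$c, q_points)
  cnt <- cd$cnt
  nup <- length(cd$uppers)
  if (nup >= 1) {
    i1 <- cd$upper_idx[[1]]$idx
    q1 <- length(cd$upper_idx[[1]]$ids)
    f1 <- factor(i1, levels = seq_len(q1))
  }
  if (nup == 2) {
    i2 <- cd$upper_idx[[2]]$idx
    q2 <- length(cd$upper_idx[[2]]$ids)
    parent <- cd$site_of_intv
    f2 <- factor(i2, levels = seq_len(q2))
  }
  q <- if (nup == 0) 0L else if (nup == 1) q1 else q1 + q2
  state <- new.env(parent = emptyenv())
  state$r <- rep(0, q)
  state$b0 <- NA_real_
  state$last_par <- NULL
  ## warm starts only help between nearby parameter values; after a large
  ## jump the stale modes slow the solves down more than a cold start
  maybe_reset <- function(par) {
    if (!is.null(state$last_par) &&
        max(abs(par - state$last_par)) > 0.75) {
      state$r <- rep(0, q)
      state$b0 <- NA_real_
    }
    state$last_par <- par
  }

  eta_of <- function(b0, r) {
    t <- rep(b0, length(cnt))
    if (nup >= 1) t <- t + r[i1]
    if (nup == 2) t <- t + r[q1 + i2]
    t
  }
  penalty <- function(r, s_up) {
    if (nup == 0) return(0)
    p <- sum(r[seq_len(q1)]^2) / (2 * s_up[1]^2)
    if (nup == 2) p <- p + sum(r[q1 + seq_len(q2)]^2) / (2 * s_up[2]^2)
    p
  }
  ## penalized joint objective F(b0, r) and a Newton step over (b0?, r).
  ## The objective is concave and the Hessian exact, so full Newton steps
  ## are taken without a function-value line search; progress is monitored
  ## through the gradient norm, with a single half-step retreat on the rare
  ## step that inflates it.
  inner_newton <- function(b0, r, s_in, s_up, profile_b0, max_it = 60) {
    grad_of <- function(gt, r) {
      w1 <- cnt * gt$g1
      gr_b <- if (profile_b0) sum(w1) else NULL
      gr_r <- NULL
      if (nup >= 1) {
        g1s <- as.numeric(rowsum(w1, f1)[, 1])
        gr_r <- g1s - r[seq_len(q1)] / s_up[1]^2
      }
      if (nup == 2) {
        g2s <- as.numeric(rowsum(w1, f2)[, 1])
        gr_r <- c(gr_r, g2s - r[q1 + seq_len(q2)] / s_up[2]^2)
      }
      c(gr_b, gr_r)
    }
    gt <- kern(eta_of(b0, r), s_in)
    if (q == 0L && !profile_b0) {   # nothing latent to solve for
      f0 <- sum(cnt * gt$g)
      return(list(b0 = b0, r = r, f = f0, gt = gt, converged = TRUE))
    }
    gr <- grad_of(gt, r)
    gnorm <- max(abs(gr))
    scale0 <- abs(sum(cnt * gt$g)) + 1
    converged <- FALSE
    for (it in seq_len(max_it)) {
      if (gnorm < max(1e-6 * scale0, 1e-5)) { converged <- TRUE; break }
      w2 <- -cnt * gt$g2
      dim_tot <- q + as.integer(profile_b0)
      H <- matrix(0, dim_tot, dim_tot)
      off <- as.integer(profile_b0)
      if (profile_b0) H[1, 1] <- sum(w2)
      if (nup >= 1) {
        d1 <- as.numeric(rowsum(w2, f1)[, 1])
        H[cbind(off + seq_len(q1), off + seq_len(q1))] <- d1 + 1 / s_up[1]^2
        if (profile_b0) {
          H[1, off + seq_len(q1)] <- d1
          H[off + seq_len(q1), 1] <- d1
        }
      }
      if (nup == 2) {
        d2 <- as.numeric(rowsum(w2, f2)[, 1])
        jj <- off + q1 + seq_len(q2)
        H[cbind(jj, jj)] <- d2 + 1 / s_up[2]^2
        if (profile_b0) { H[1, jj] <- d2; H[jj, 1] <- d2 }
        H[cbind(off + parent, jj)] <- d2
        H[cbind(jj, off + parent)] <- d2
      }
      step <- tryCatch(solve(H, gr), error = function(e) gr / max(diag(H)))
      al <- 1
      for (bt in 1:8) {
        b0n <- if (profile_b0) b0 + al * step[1] else b0
        rn <- if (q > 0) r + al * step[(off + 1):dim_tot] else r
        gtn <- kern(eta_of(b0n, rn), s_in)
        grn <- grad_of(gtn, rn)
        if (max(abs(grn)) < 2 * gnorm + 1e-3) break
        al <- al / 2
      }
      b0 <- b0n; r <- rn; gt <- gtn; gr <- grn; gnorm <- max(abs(gr))
    }
    f0 <- sum(cnt * gt$g) - penalty(r, s_up)
    list(b0 = b0, r = r, f = f0, gt = gt, converged = converged)
  }
  ## Laplace log-determinant correction over the upper-effect block
  laplace_correction <- function(gt, s_up) {
    if (nup == 0) return(0)
    w2 <- -cnt * gt$g2
    d1 <- as.numeric(rowsum(w2, f1)[, 1])
    if (nup == 1) {
      ld <- sum(log(d1 + 1 / s_up[1]^2))
      return(0.5 * (2 * q1 * log(s_up[1]) + ld))
    }
    d2 <- as.numeric(rowsum(w2, f2)[, 1])
    H <- matrix(0, q1 + q2, q1 + q2)
    H[cbind(seq_len(q1), seq_len(q1))] <- d1 + 1 / s_up[1]^2
    jj <- q1 + seq_len(q2)
    H[cbind(jj, jj)] <- d2 + 1 / s_up[2]^2
    H[cbind(parent, jj)] <- d2
    H[cbind(jj, parent)] <- d2
    ld <- as.numeric(determinant(H, logarithm = TRUE)$modulus)
    0.5 * (2 * q1 * log(s_up[1]) + 2 * q2 * log(s_up[2]) + ld)
  }
  ## negative profiled/unprofiled marginal log-likelihood
  list(
    nll_profiled = function(log_s, b0_start) {
      maybe_reset(c(0, log_s))
      s <- exp(log_s)
      s_in <- s[length(s)]; s_up <- s[-length(s)]
      b0 <- if (is.finite(state$b0)) state$b0 else b0_start
      res <- inner_newton(b0, state$r, s_in, s_up, profile_b0 = TRUE)
      state$r <- res$r; state$b0 <- res$b0
      -(res$f - laplace_correction(res$gt, s_up))
    },
    nll_full = function(par) {
      maybe_reset(par)
      b0 <- par[1]; s <- exp(par[-1])
      s_in <- s[length(s)]; s_up <- s[-length(s)]
      res <- inner_newton(b0, state$r, s_in, s_up, profile_b0 = FALSE)
      state$r <- res$r
      -(res$f - laplace_correction(res$gt, s_up))
    },
    profile_b0 = function() state$b0,
    upper_modes = function() state$r,
    state = state
  )
}

## ---------------------------------------------------------------------------
## "agq" objective: nested adaptive Gauss-Hermite at every level.

## One-dimensional adaptive GH integration of a child log-likelihood.
## `fun(x)` must return list(val, d1, d2) for a scalar offset x; returns the
## integrated value and its derivatives with respect to an offset added to x.
agh_integrate_1d <- function(fun, s, z, lw) {
  x <- 0
  e <- fun(x)
  f0 <- e$val - x^2 / (2 * s^2)
  for (it in 1:30) {
    h1 <- e$d1 - x / s^2
    ## derivatives propagated through nested quadrature carry ~1e-8 noise;
    ## a mode located to 1e-6 leaves an O(1e-12) error in the integral
    if (abs(h1) < 1e-6) break
    h2 <- min(e$d2 - 1 / s^2, -1e-12)
    st <- -h1 / h2
    al <- 1
    for (bt in 1:10) {
      xn <- x + al * st
      en <- fun(xn)
      fn <- en$val - xn^2 / (2 * s^2)
      if (fn >= f0 - 1e-9) break
      al <- al / 2
    }
    x <- xn; e <- en; f0 <- fn
  }
  tau <- 1 / sqrt(max(-(e$d2) , 0) + 1 / s^2)
  nodes <- x + tau * z * sqrt(2)
  evals <- lapply(nodes, fun)
  hv <- vapply(evals, `[[`, numeric(1), "val") - nodes^2 / (2 * s^2)
  a <- lw + z^2 + hv
  mx <- max(a)
  val <- log(tau / s) - 0.5 * log(pi) + mx + log(sum(exp(a - mx)))
  pi_q <- exp(a - mx); pi_q <- pi_q / sum(pi_q)
  d1s <- vapply(evals, `[[`, numeric(1), "d1")
  d2s <- vapply(evals, `[[`, numeric(1), "d2")
  d1 <- sum(pi_q * d1s)
  d2 <- sum(pi_q * (d2s + d1s^2)) - d1^2
  list(val = val, d1 = d1, d2 = d2)
}

## Exact-up-to-quadrature marginal log-likelihood with nested adaptive GH.
agq_loglik <- function(cd, b0, sigmas, q_points) {
  gq <- pracma::gaussHermite(q_points)
  z <- gq$x; lw <- log(gq$w)
  cnt <- cd$cnt
  nup <- length(cd$uppers)
  s_in <- sigmas[length(sigmas)]
  ## one cached kernel per cluster of the innermost upper level
  leaf <- function(sel) {
    k <- make_agh_kernel(cd$m[sel], cd$c[sel], q_points)
    csel <- cnt[sel]; nsel <- sum(sel)
    function(t) {
      gt <- k(rep(t, nsel), s_in)
      list(val = sum(csel * gt$g), d1 = sum(csel * gt$g1),
           d2 = sum(csel * gt$g2))
    }
  }
  if (nup == 0) {
    kern <- make_agh_kernel(cd$m, cd$c, q_points)
    gt <- kern(rep(b0, length(cnt)), s_in, warm = FALSE)
    return(sum(cnt * gt$g))
  }
  if (nup == 1) {
    i1 <- cd$upper_idx[[1]]$idx
    tot <- 0
    for (a in seq_along(cd$upper_idx[[1]]$ids)) {
      f <- leaf(i1 == a)
      tot <- tot + agh_integrate_1d(function(x) f(b0 + x),
                                    sigmas[1], z, lw)$val
    }
    return(tot)
  }
  ## site > interviewer > inner
  i1 <- cd$upper_idx[[1]]$idx; i2 <- cd$upper_idx[[2]]$idx
  tot <- 0
  for (a in seq_along(cd$upper_idx[[1]]$ids)) {
    jj <- unique(i2[i1 == a])
    leaves <- lapply(jj, function(j) leaf(i2 == j))
    site_fun <- function(u) {
      acc <- list(val = 0, d1 = 0, d2 = 0)
      for (f in leaves) {
        r <- agh_integrate_1d(function(v) f(b0 + u + v), sigmas[2], z, lw)
        acc$val <- acc$val + r$val
        acc$d1 <- acc$d1 + r$d1
        acc$d2 <- acc$d2 + r$d2
      }
      acc
    }
    tot <- tot + agh_integrate_1d(site_fun, sigmas[1], z, lw)$val
  }
  tot
}

## ---------------------------------------------------------------------------
## Public fitting interface

#' Fixed-intercept (no clustering) fit
#'
#' Closed-form maximum likelihood for the empty logistic model: the inverse
#' logit of the fitted intercept is the sample proportion, the standard
#' error is the observed-information one, and the log-likelihood is the
#' Bernoulli log-likelihood at the sample proportion.
#'
#' @param data A \code{\link{survey_dataset}} (records with missing outcomes
#'   are excluded).
#' @return A \code{glmm_fit} object with empty variance components.
#' @export
fit_intercept_only <- function(data) {
  d <- complete_cases(data)
  n <- nrow(d)
  if (n < 1) stop("no complete records", call. = FALSE)
  ev <- sum(d$outcome)
  if (ev == 0L || ev == n)
    stop("degenerate fit: outcome is all-", if (ev == 0L) "0" else "1",
         " (infinite logit)", call. = FALSE)
  p <- ev / n
  b0 <- logit(p)
  se <- 1 / sqrt(n * p * (1 - p))
  ll <- ev * log(p) + (n - ev) * log(1 - p)
  new_glmm_fit(beta0_hat = b0, se_beta0 = se,
               varcomps = variance_components(),
               loglik = ll, n_obs = n, n_params = 1L, converged = TRUE,
               ranef = list(),
               spec = model_spec(levels = character(0), method = "laplace"),
               boundary = FALSE)
}

new_glmm_fit <- function(beta0_hat, se_beta0, varcomps, loglik, n_obs,
                         n_params, converged, ranef, spec, boundary) {
  structure(list(
    beta0_hat = beta0_hat, se_beta0 = se_beta0, varcomps = varcomps,
    loglik = loglik,
    aic = -2 * loglik + 2 * n_params,
    bic = -2 * loglik + log(n_obs) * n_params,
    n_obs = n_obs, n_params = n_params, converged = converged,
    cluster_effect_predictions = ranef, spec = spec, boundary = boundary
  ), class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  lv <- x$spec$levels
  cat("intercept-only logistic model",
      if (length(lv)) paste0("with random intercepts: ",
                             paste(lv, collapse = " > ")) else
        "(no random effects)", "\n")
  cat(sprintf("  beta0 = %.4f (se %.4f)   plogis(beta0) = %.5f\n",
              x$beta0_hat, x$se_beta0, inv_logit(x$beta0_hat)))
  for (l in names(x$varcomps$sigma2))
    cat(sprintf("  sigma2[%s] = %.4f\n", l, x$varcomps$sigma2[[l]]))
  cat(sprintf("  logLik = %.3f  AIC = %.2f  BIC = %.2f  n = %d  converged: %s\n",
              x$loglik, x$aic, x$bic, x$n_obs, x$converged))
  if (x$boundary) cat("  note: variance estimate at the zero boundary\n")
  invisible(x)
}

#' Fit the nested random-intercept logistic model
#'
#' Maximizes the marginal likelihood of the intercept-only Bernoulli model
#' with nested normal random intercepts, integrating the random effects out
#' level by level, innermost first.  See \code{\link{model_spec}} for the
#' two estimation methods.  Starting values are the crude logit for the
#' intercept and 0.3 for every random-effect SD; variance components are
#' optimized on the log-SD scale, and a fitted log-SD below -6 is reported
#' as a variance of 0 with the boundary flag set.
#'
#' @param data A \code{\link{survey_dataset}}; records with missing outcomes
#'   are excluded before fitting.
#' @param spec A \code{\link{model_spec}}.
#' @return A \code{glmm_fit}: intercept and its standard error (observed
#'   information), \code{\link{variance_components}}, log-likelihood,
#'   AIC/BIC, convergence flag and per-cluster posterior-mode effect
#'   predictions.
#' @export
fit_glmm <- function(data, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  if (length(spec$levels) == 0L) return(fit_intercept_only(data))
  d <- complete_cases(data)
  if (nrow(d) < 1) stop("no complete records", call. = FALSE)
  ev <- sum(d$outcome)
  if (ev == 0L || ev == nrow(d))
    stop("degenerate fit: outcome is constant", call. = FALSE)
  for (lv in spec$levels) {
    if (length(unique(d[[LEVEL_COLUMN[lv]]])) < 2L)
      stop("need >= 2 clusters at level '", lv, "'", call. = FALSE)
  }
  validate_survey_dataset(d)
  cd <- collapse_for_fit(d, spec$levels)
  k <- length(spec$levels)
  b0_start <- logit(ev / nrow(d))

  if (spec$method == "laplace") {
    obj <- make_laplace_objective(cd, spec$q_points)
    fn <- function(ls) obj$nll_profiled(ls, b0_start)
    ## Derivative-free outer optimization: the warm-started objective is
    ## smooth only down to ~1e-5, which derails finite-difference
    ## quasi-Newton methods; the simplex search is insensitive to that
    ## noise floor (the same reason mixed-model fitters default to
    ## derivative-free outer optimizers).
    if (k == 1L) {
      o1 <- stats::optimize(function(x) fn(x), interval = c(-7, 3),
                            tol = 1e-7)
      log_s <- o1$minimum
      best <- o1$objective
      converged <- TRUE
    } else {
      reltol <- max(spec$tol, 1e-9)
      ctrl <- list(reltol = reltol, maxit = 40L * spec$max_iter)
      ## cheap 1-D profile fit of the innermost level alone moves its SD
      ## near the optimum before the joint simplex search; upper levels
      ## keep the fixed 0.3 start
      start <- rep(log(0.3), k)
      start[k] <- prestart_inner(d, spec)
      out <- stats::optim(start, fn, method = "Nelder-Mead",
                          control = ctrl)
      converged <- out$convergence == 0
      ## restart a stalled / degenerate simplex until it stops improving:
      ## weakly identified variance ridges routinely collapse the simplex
      ## before the optimum is reached
      restarts <- 0L
      while (!converged && restarts < 4L) {
        out2 <- stats::optim(out$par, fn, method = "Nelder-Mead",
                             control = ctrl)
        improved <- out$value - out2$value
        if (out2$value <= out$value) out <- out2
        converged <- out$convergence == 0 || improved < 1e-2
        restarts <- restarts + 1L
      }
      log_s <- out$par
      best <- out$value
    }
    fn(log_s)   # leave the inner state at the reported solution
    b0_hat <- obj$profile_b0()
    ## polish the intercept on the unprofiled objective (the profile step
    ## ignores the dependence of the Laplace determinant on beta0)
    pol <- stats::optimize(function(b) obj$nll_full(c(b, log_s)),
                           interval = b0_hat + c(-1, 1), tol = 1e-9)
    if (pol$objective <= best + 1e-9) b0_hat <- pol$minimum
    nll_final <- obj$nll_full(c(b0_hat, log_s))
    loglik <- -nll_final
    nll_fun <- obj$nll_full
    upper_r <- obj$upper_modes()
  } else {
    par0 <- c(b0_start, rep(log(0.3), k))
    nll_fun <- function(par) -agq_loglik(cd, par[1], exp(par[-1]),
                                         spec$q_points)
    out <- stats::nlminb(par0, nll_fun,
                         control = list(rel.tol = spec$tol,
                                        iter.max = spec$max_iter,
                                        eval.max = 20L * spec$max_iter))
    b0_hat <- out$par[1]
    log_s <- out$par[-1]
    loglik <- -out$objective
    converged <- out$convergence == 0
    upper_r <- NULL
  }

  sigma2 <- exp(2 * log_s)
  at_zero <- log_s < -6
  sigma2[at_zero] <- 0
  names(sigma2) <- spec$levels
  vc <- do.call(variance_components, as.list(sigma2))

  se_b0 <- se_from_information(nll_fun, b0_hat, log_s, at_zero,
                               method = spec$method)

  ranef <- predict_cluster_effects(cd, b0_hat, sigma2, spec, upper_r)

  new_glmm_fit(beta0_hat = b0_hat, se_beta0 = se_b0, varcomps = vc,
               loglik = loglik, n_obs = cd$n_obs, n_params = 1L + k,
               converged = converged, ranef = ranef, spec = spec,
               boundary = any(at_zero))
}

## Coarse 1-D profile fit of the innermost declared level alone, used as a
## starting value for its SD in the joint fit.
prestart_inner <- function(d, spec) {
  inner <- spec$levels[length(spec$levels)]
  cd1 <- collapse_for_fit(d, inner)
  obj1 <- make_laplace_objective(cd1, spec$q_points)
  b0s <- logit(cd1$n_events / cd1$n_obs)
  o <- stats::optimize(function(x) obj1$nll_profiled(x, b0s),
                       interval = c(-4, 2.5), tol = 1e-3)
  o$minimum
}

## Observed-information standard error of beta0 by central finite
## differences over (beta0, active log-SDs); boundary components are held
## fixed at their boundary value.
se_from_information <- function(nll_fun, b0, log_s, at_zero, method) {
  active <- c(TRUE, !at_zero)
  par <- c(b0, log_s)
  np <- sum(active)
  ## second differences need steps well above the objective's numerical
  ## noise floor (~1e-5 from warm-started inner solves); curvatures here are
  ## O(1)-O(10), so h = 0.05 keeps the truncation error in the percent range
  h <- rep(0.05, np)
  f0 <- nll_fun(par)
  idx <- which(active)
  Hm <- matrix(NA_real_, np, np)
  fp <- fm <- numeric(np)
  for (a in seq_len(np)) {
    pa <- par; pa[idx[a]] <- pa[idx[a]] + h[a]; fp[a] <- nll_fun(pa)
    pa <- par; pa[idx[a]] <- pa[idx[a]] - h[a]; fm[a] <- nll_fun(pa)
    Hm[a, a] <- (fp[a] - 2 * f0 + fm[a]) / h[a]^2
  }
  if (np > 1) {
    for (a in seq_len(np - 1)) for (b in (a + 1):np) {
      pa <- par
      pa[idx[a]] <- pa[idx[a]] + h[a]; pa[idx[b]] <- pa[idx[b]] + h[b]
      fpp <- nll_fun(pa)
      pa <- par
      pa[idx[a]] <- pa[idx[a]] + h[a]; pa[idx[b]] <- pa[idx[b]] - h[b]
      fpm <- nll_fun(pa)
      pa <- par
      pa[idx[a]] <- pa[idx[a]] - h[a]; pa[idx[b]] <- pa[idx[b]] + h[b]
      fmp <- nll_fun(pa)
      pa <- par
      pa[idx[a]] <- pa[idx[a]] - h[a]; pa[idx[b]] <- pa[idx[b]] - h[b]
      fmm <- nll_fun(pa)
      Hm[a, b] <- Hm[b, a] <- (fpp - fpm - fmp + fmm) / (4 * h[a] * h[b])
    }
  }
  V <- tryCatch(solve(Hm), error = function(e) NULL)
  if (!is.null(V) && is.finite(V[1, 1]) && V[1, 1] > 0) return(sqrt(V[1, 1]))
  if (is.finite(Hm[1, 1]) && Hm[1, 1] > 0) return(1 / sqrt(Hm[1, 1]))
  NA_real_
}

## Posterior-mode predictions of the cluster effects at the fitted
## parameters, per level, named by cluster id.
predict_cluster_effects <- function(cd, b0, sigma2, spec, upper_r) {
  out <- list()
  uppers <- cd$uppers
  if (length(uppers) && !is.null(upper_r)) {
    q1 <- length(cd$upper_idx[[1]]$ids)
    out[[uppers[1]]] <- stats::setNames(upper_r[seq_len(q1)],
                                        cd$upper_idx[[1]]$ids)
    if (length(uppers) == 2) {
      q2 <- length(cd$upper_idx[[2]]$ids)
      out[[uppers[2]]] <- stats::setNames(upper_r[q1 + seq_len(q2)],
                                          cd$upper_idx[[2]]$ids)
    }
  }
  ## inner-level modes per actual unit
  s_in <- sqrt(sigma2[[cd$inner]])
  ut <- cd$unit_tbl
  t_unit <- rep(b0, length(ut$m))
  if (length(uppers) && !is.null(upper_r)) {
    u1 <- out[[uppers[1]]]
    t_unit <- t_unit + u1[ut$up[[uppers[1]]]]
    if (length(uppers) == 2) {
      u2 <- out[[uppers[2]]]
      t_unit <- t_unit + u2[ut$up[[uppers[2]]]]
    }
  }
  if (s_in > 0) {
    w <- rep(0, length(ut$m))
    for (it in 1:80) {
      p <- stats::plogis(t_unit + w)
      h1 <- (ut$c - ut$m * p) - w / s_in^2
      if (max(abs(h1)) < 1e-9) break
      h2 <- -ut$m * p * (1 - p) - 1 / s_in^2
      ## damped Newton; the penalized log-likelihood is concave in w
      w <- w - pmax(pmin(h1 / h2, 3 * s_in), -3 * s_in)
    }
    out[[cd$inner]] <- stats::setNames(w, ut$ids)
  } else {
    out[[cd$inner]] <- stats::setNames(rep(0, length(ut$ids)), ut$ids)
  }
  out[MODEL_LEVELS[MODEL_LEVELS %in% names(out)]]
}
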