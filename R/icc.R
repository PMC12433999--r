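#' Intraclass correlation on the latent logistic scale
#'
#' For a binary outcome modelled with logistic random intercepts, the
#' latent-threshold convention fixes the individual-level residual variance
#' at \eqn{\pi^2/3}, so the ICC of level \eqn{\ell} is
#' \deqn{\mathrm{ICC}_\ell = \sigma_\ell^2 \Big/ \big(\textstyle\sum_k
#'   \sigma_k^2 + \pi^2/3\big)}
#' with the sum over all levels included in the model.  This is the
#' proportion of total latent outcome variance attributable to clustering at
#' that level.
#'
#' @param varcomps A \code{\link{variance_components}} object.
#' @param level One of the levels present in \code{varcomps}.
#' @return The ICC, in \eqn{[0, 1)}.
#' @export
icc <- function(varcomps, level) {
  stopifnot(inherits(varcomps, "variance_components"))
  if (!level %in% names(varcomps$sigma2))
    stop("level '", level, "' not present in the variance components",
         call. = FALSE)
  varcomps$sigma2[[level]] /
    (sum(varcomps$sigma2) + varcomps$residual)
}

#' Cumulative intraclass correlation of a hierarchical model
#'
#' The summed cluster variances over the total latent variance:
#' \eqn{\sum_k \sigma_k^2 / (\sum_k \sigma_k^2 + \pi^2/3)}.  It equals the
#' correlation between two individuals sharing all modelled clusters, and is
#' monotone non-decreasing as levels are added to the model.
#'
#' @param varcomps A \code{\link{variance_components}} object.
#' @return The cumulative ICC (0 when no levels are included).
#' @export
icc_cumulative <- function(varcomps) {
  stopifnot(inherits(varcomps, "variance_components"))
  s <- sum(varcomps$sigma2)
  s / (s + varcomps$residual)
}

#' Variance decomposition table
#'
#' One row per modelled level plus the latent residual, with each level's
#' variance and its share of the total; shares sum to one.
#'
#' @param varcomps A \code{\link{variance_components}} object.
#' @return A data frame with columns \code{level}, \code{sigma2},
#'   \code{share}.
#' @export
variance_decomposition <- function(varcomps) {
  stopifnot(inherits(varcomps, "variance_components"))
  s2 <- c(varcomps$sigma2, residual = varcomps$residual)
  data.frame(level = names(s2), sigma2 = as.numeric(s2),
             share = as.numeric(s2) / sum(s2), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Flag levels with substantial clustering
#'
#' Applies the working rule that an ICC above the threshold indicates
#' clustering that must not be ignored in the analysis.
#'
#' @param varcomps A \code{\link{variance_components}} object.
#' @param threshold ICC threshold (default 0.1).
#' @return Named logical vector over the included levels.
#' @export
substantial_clustering <- function(varcomps, threshold = 0.1) {
  stopifnot(inherits(varcomps, "variance_components"))
  vapply(names(varcomps$sigma2),
         function(l) icc(varcomps, l) > threshold, logical(1))
}
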