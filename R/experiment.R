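#' Experiment grid: attrition level x clustering structure x handling
#'
#' Defines the simulation experiment that crosses simulated attrition
#' rates, random-intercept structures and missing-data handling
#' (complete-case versus sequential-KNN completion).
#'
#' @param attrition_rates Numeric vector of marginal missingness rates
#'   (default 0, 0.10, 0.20).
#' @param structures Named list of \code{\link{model_spec}} objects;
#'   defaults to the seven nested structures from the fixed-intercept model
#'   up to site > interviewer > household.
#' @param handling Character subset of
#'   \code{c("complete_case", "sknn_imputed")}.
#' @param replicates Number of replicates (>= 1).
#' @param base_seed Integer; all per-replicate attrition/imputation seeds
#'   are split from it.
#' @param resample_population Logical: draw a fresh population per
#'   replicate (only when a \code{population_config} is supplied to
#'   \code{\link{run_grid}}).  Default \code{FALSE}: one census, re-used,
#'   with attrition re-drawn per replicate.
#' @param mar A \code{\link{mar_model}} template (its target rate is
#'   overwritten cell by cell); default \code{mar_model(0.1)}.
#' @param sknn An \code{\link{sknn_config}}.
#' @return An object of class \code{experiment_grid}.
#' @export
experiment_grid <- function(attrition_rates = c(0, 0.10, 0.20),
                            structures = default_structures(),
                            handling = c("complete_case", "sknn_imputed"),
                            replicates = 1L,
                            base_seed = 1L,
                            resample_population = FALSE,
                            mar = mar_model(0.1),
                            sknn = sknn_config()) {
  handling <- match.arg(handling, c("complete_case", "sknn_imputed"),
                        several.ok = TRUE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  stopifnot(all(vapply(structures, inherits, logical(1), "model_spec")))
  if (is.null(names(structures)))
    names(structures) <- vapply(structures, function(s)
      if (length(s$levels)) paste(s$levels, collapse = "+") else "none",
      character(1))
  structure(list(attrition_rates = attrition_rates,
                 structures = structures, handling = handling,
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed),
                 resample_population = isTRUE(resample_population),
                 mar = mar, sknn = sknn),
            class = "experiment_grid")
}

#' The seven default clustering structures
#'
#' Fixed intercept only; each single level; site + interviewer;
#' household + site; and the full three-level hierarchy.
#'
#' @param method,q_points Passed to \code{\link{model_spec}}.
#' @return A named list of \code{model_spec} objects.
#' @export
default_structures <- function(method = "laplace", q_points = NULL) {
  specs <- list(
    none = character(0),
    site = "site",
    interviewer = "interviewer",
    household = "household",
    `site+interviewer` = c("site", "interviewer"),
    `site+household` = c("site", "household"),
    `site+interviewer+household` = c("site", "interviewer", "household")
  )
  lapply(specs, function(lv) model_spec(levels = lv, method = method,
                                        q_points = q_points))
}

#' Run the full experiment grid
#'
#' For every (replicate, attrition rate, handling, structure) cell:
#' generate or reuse the population, impose calibrated MAR attrition
#' (rate 0 means none), either drop incomplete records or complete them by
#' sequential KNN, fit the structure, and record prevalence, interval
#' width, variance components, ICCs and information criteria.  Failures
#' are recorded as non-converged rows with \code{NA} estimates, never
#' dropped.  The whole table is deterministic given the grid's
#' \code{base_seed}.
#'
#' @param population A \code{\link{survey_dataset}} or a
#'   \code{\link{population_config}}.
#' @param grid An \code{\link{experiment_grid}}.
#' @return A \code{results_table} data frame, one row per cell.
#' @export
run_grid <- function(population, grid) {
  stopifnot(inherits(grid, "experiment_grid"))
  rows <- list()
  base_data <- NULL
  if (inherits(population, "survey_dataset")) base_data <- population
  for (rep_i in seq_len(grid$replicates)) {
    if (is.null(base_data) || (grid$resample_population && rep_i > 1L)) {
      cfg <- population
      if (!inherits(cfg, "population_config"))
        stop("population must be a survey_dataset or population_config",
             call. = FALSE)
      cfg$seed <- split_seed(grid$base_seed, paste0("pop", rep_i))
      pop <- generate_population(cfg)
      data_rep <- pop$data
      if (!grid$resample_population) base_data <- data_rep
    } else {
      data_rep <- base_data
    }
    for (rate in grid$attrition_rates) {
      mar <- grid$mar
      mar$target_rate <- rate
      mar$seed <- split_seed(grid$base_seed,
                             paste0("attr", rep_i, "_", rate))
      attrited <- apply_attrition(data_rep, mar)
      for (hd in grid$handling) {
        d_used <- if (hd == "sknn_imputed" && rate > 0) {
          sk <- grid$sknn
          sk$seed <- split_seed(grid$base_seed,
                                paste0("sknn", rep_i, "_", rate))
          impute_sknn(attrited, sk)
        } else attrited
        for (sn in names(grid$structures)) {
          rows[[length(rows) + 1L]] <-
            grid_cell(d_used, grid$structures[[sn]], rate, hd, sn, rep_i)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("results_table", "data.frame")
  out
}

grid_cell <- function(data, spec, rate, handling, structure_name, rep_i) {
  na_row <- function(msg) data.frame(
    replicate = rep_i, attrition_rate = rate, handling = handling,
    structure = structure_name, n_complete = sum(!is.na(data$outcome)),
    prev_per_1000 = NA_real_, se = NA_real_, lcb = NA_real_, ucb = NA_real_,
    ci_width = NA_real_, sigma2_site = NA_real_,
    sigma2_interviewer = NA_real_, sigma2_household = NA_real_,
    icc_site = NA_real_, icc_interviewer = NA_real_,
    icc_household = NA_real_, icc_cumulative = NA_real_,
    loglik = NA_real_, aic = NA_real_, bic = NA_real_,
    converged = FALSE, note = msg, stringsAsFactors = FALSE)
  res <- tryCatch({
    fit <- fit_glmm(data, spec)
    pt <- if (length(spec$levels)) adjusted_prevalence(fit) else {
      cp <- crude_prevalence(data)
      cp
    }
    vc <- fit$varcomps
    s2 <- function(l) if (l %in% names(vc$sigma2)) vc$sigma2[[l]] else NA_real_
    ic <- function(l) if (l %in% names(vc$sigma2)) icc(vc, l) else NA_real_
    data.frame(
      replicate = rep_i, attrition_rate = rate, handling = handling,
      structure = structure_name, n_complete = fit$n_obs,
      prev_per_1000 = pt$theta_per_1000, se = pt$sigma,
      lcb = pt$lcb, ucb = pt$ucb, ci_width = pt$ucb - pt$lcb,
      sigma2_site = s2("site"), sigma2_interviewer = s2("interviewer"),
      sigma2_household = s2("household"),
      icc_site = ic("site"), icc_interviewer = ic("interviewer"),
      icc_household = ic("household"),
      icc_cumulative = icc_cumulative(vc),
      loglik = fit$loglik, aic = fit$aic, bic = fit$bic,
      converged = fit$converged, note = "", stringsAsFactors = FALSE)
  }, error = function(e) na_row(conditionMessage(e)))
  res
}

#' Rank clustering structures by information criteria
#'
#' Within each (replicate, attrition rate, handling) block, structures are
#' ranked by AIC with BIC breaking ties.
#'
#' @param table A \code{results_table} from \code{\link{run_grid}}.
#' @return The table with a \code{rank} column added, ordered best-first
#'   within block.
#' @export
compare_models <- function(table) {
  if (!all(c("aic", "bic", "structure") %in% names(table)))
    stop("not a results table", call. = FALSE)
  key <- interaction(table$replicate, table$attrition_rate, table$handling,
                     drop = TRUE)
  pieces <- lapply(split(seq_len(nrow(table)), key), function(ix) {
    blk <- table[ix, , drop = FALSE]
    ord <- order(blk$aic, blk$bic)
    blk <- blk[ord, , drop = FALSE]
    blk$rank <- seq_len(nrow(blk))
    blk
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- class(table)
  out
}
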