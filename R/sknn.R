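#' Configuration of sequential k-nearest-neighbour imputation
#'
#' Missing binary outcomes are filled by majority vote of the \code{k}
#' nearest complete records under a Gower-type distance built from the only
#' information the empty model carries: cluster co-membership (same
#' household, same interviewer, same village, same site) plus household
#' size and interviewer sex.  Household co-membership gets the dominant
#' weight so that imputation preserves household-level clustering.  In
#' sequential mode, records imputed earlier join the donor pool for later
#' records.
#'
#' @param k Number of donors (default 15).  For hot-deck voting the pool
#'   must be large enough that same-household donors are a minority:
#'   copying household co-members into their own household inflates the
#'   household variance component, while a pool of distant donors dilutes
#'   it; around 15 the two effects balance at the default missingness
#'   levels (see the methods vignette for the calibration).
#' @param weights Named numeric mismatch weights; defaults
#'   \code{c(household = 3, interviewer = 1, village = 1, site = 0.5,
#'   hsize = 1, sex = 1)}.  \code{hsize} applies to the absolute
#'   household-size difference scaled by its range (14); the others to
#'   binary mismatch indicators.
#' @param sequential Logical: let earlier imputations donate to later ones.
#' @param vote How the k donors determine the imputed value.
#'   \code{"hotdeck"} (default): draw one donor at random from the k
#'   nearest and copy its outcome -- for a rare binary outcome this
#'   preserves the event rate among imputed cells, whereas a majority vote
#'   suppresses the minority class almost entirely.  \code{"majority"}:
#'   classical majority vote, ties resolved by the single nearest donor and
#'   then by a seeded coin flip.
#' @param seed Integer seed for the hot-deck draws / randomized tie-break.
#' @return An object of class \code{sknn_config}.
#' @export
sknn_config <- function(k = 15L,
                        weights = c(household = 3, interviewer = 1,
                                    village = 1, site = 0.5,
                                    hsize = 1, sex = 1),
                        sequential = TRUE,
                        vote = c("hotdeck", "majority"),
                        seed = 1L) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  vote <- match.arg(vote)
  needed <- c("household", "interviewer", "village", "site", "hsize", "sex")
  if (!all(needed %in% names(weights)))
    stop("weights must name: ", paste(needed, collapse = ", "), call. = FALSE)
  structure(list(k = as.integer(k), weights = weights[needed],
                 sequential = isTRUE(sequential), vote = vote,
                 seed = as.integer(seed)),
            class = "sknn_config")
}

#' Sequential k-nearest-neighbour imputation of missing outcomes
#'
#' Records with missing outcomes are processed in a deterministic order:
#' descending number of complete records in the record's household (the
#' best-informed records are imputed first and become reliable donors),
#' ties broken by individual id.  Each is imputed from its \code{k}
#' nearest donors according to the configured vote rule; equidistant donors
#' are ordered by a seeded permutation so heavily tied village blocks do
#' not recycle the same few donors.  Observed outcomes are never altered
#' and the output contains no missing outcomes.
#'
#' @param data A \code{\link{survey_dataset}}.
#' @param config An \code{\link{sknn_config}}.
#' @return The completed dataset, with attributes \code{imputed_ids}
#'   (individual ids imputed, in processing order) and \code{sknn_log}
#'   (a data frame of record id, donor ids and the vote).
#' @export
impute_sknn <- function(data, config = sknn_config()) {
  stopifnot(inherits(config, "sknn_config"))
  miss <- which(is.na(data$outcome))
  if (!length(miss)) {
    attr(data, "imputed_ids") <- integer(0)
    attr(data, "sknn_log") <- data.frame(individual_id = integer(0),
                                         donors = character(0),
                                         votes_for_1 = integer(0),
                                         k = integer(0),
                                         tie_break = character(0))
    return(data)
  }
  donor <- !is.na(data$outcome)
  if (sum(donor) < config$k)
    stop("fewer complete records (", sum(donor), ") than k = ", config$k,
         call. = FALSE)
  hsize <- stats::ave(rep(1L, nrow(data)), data$household_id, FUN = sum)
  n_complete_hh <- stats::ave(donor, data$household_id, FUN = sum)
  ord <- miss[order(-n_complete_hh[miss], data$individual_id[miss])]
  w <- config$weights
  wsum <- sum(w)
  outcome <- data$outcome
  rng_seed <- split_seed(config$seed, "sknn-tiebreak")
  log_rows <- vector("list", length(ord))

  ## candidate index lists by cluster
  by_village <- split(seq_len(nrow(data)), data$village_id)
  by_site <- split(seq_len(nrow(data)), data$site_id)

  for (step in seq_along(ord)) {
    i <- ord[step]
    cand <- by_village[[data$village_id[i]]]
    cand <- cand[donor[cand]]
    cand <- cand[cand != i]
    if (length(cand) < config$k) {
      cand <- by_site[[data$site_id[i]]]
      cand <- cand[donor[cand] & cand != i]
    }
    if (length(cand) < config$k) {
      cand <- which(donor); cand <- cand[cand != i]
    }
    if (length(cand) < config$k)
      stop("fewer than k donors available for record ",
           data$individual_id[i], call. = FALSE)
    dist <- (w[["household"]] * (data$household_id[cand] != data$household_id[i]) +
             w[["interviewer"]] * (data$interviewer_id[cand] != data$interviewer_id[i]) +
             w[["village"]] * (data$village_id[cand] != data$village_id[i]) +
             w[["site"]] * (data$site_id[cand] != data$site_id[i]) +
             w[["hsize"]] * abs(hsize[cand] - hsize[i]) / 14 +
             w[["sex"]] * (data$interviewer_sex[cand] != data$interviewer_sex[i])) /
      wsum
    ## Ties in the Gower distance are common (whole village blocks share
    ## a profile); breaking them by any fixed record order would recycle
    ## the same few donors for every recipient in a stratum and turn the
    ## donor pool's sampling noise into systematic bias.  Each recipient
    ## therefore gets its own seeded random tie-break.
    tie_key <- with_seed(rng_seed + step, stats::runif(length(cand)))
    ord_sel <- order(dist, tie_key)[seq_len(config$k)]
    sel <- cand[ord_sel]
    votes <- outcome[sel]
    tie_break <- "none"
    if (config$vote == "hotdeck") {
      pick <- with_seed(rng_seed + step,
                        sample.int(config$k, 1L))
      val <- votes[pick]
      tie_break <- "hotdeck"
    } else if (mean(votes) > 0.5) {
      val <- 1L
    } else if (mean(votes) < 0.5) {
      val <- 0L
    } else {
      d_sel <- dist[ord_sel]
      nearest <- sel[d_sel == min(d_sel)]
      if (length(unique(outcome[nearest])) == 1L) {
        val <- outcome[nearest[1]]
        tie_break <- "nearest"
      } else {
        val <- with_seed(rng_seed + step,
                         as.integer(stats::runif(1) < 0.5))
        tie_break <- "coin"
      }
    }
    outcome[i] <- val
    if (config$sequential) donor[i] <- TRUE
    log_rows[[step]] <- data.frame(
      individual_id = data$individual_id[i],
      donors = paste(data$individual_id[sel], collapse = ";"),
      votes_for_1 = sum(votes), k = config$k, tie_break = tie_break,
      stringsAsFactors = FALSE)
  }
  out <- data
  out$outcome <- outcome
  attr(out, "imputed_ids") <- data$individual_id[ord]
  attr(out, "sknn_log") <- do.call(rbind, log_rows)
  out
}

#' Evaluate an imputation against the pre-attrition truth
#'
#' @param truth The complete pre-attrition \code{\link{survey_dataset}}.
#' @param imputed The completed dataset returned by
#'   \code{\link{impute_sknn}}.
#' @param imputed_ids Individual ids of the imputed cells; defaults to the
#'   \code{imputed_ids} attribute of \code{imputed}.
#' @param spec Optional \code{\link{model_spec}} used to fit both datasets
#'   for the ICC comparison; \code{NULL} skips the (relatively expensive)
#'   ICC shift.
#' @return A list: \code{accuracy} (fraction of imputed cells matching
#'   truth), \code{prevalence_error} (imputed minus true crude rate, per
#'   1,000) and \code{icc_shift} (named per-level ICC difference, imputed
#'   minus truth; \code{NULL} if no spec given).
#' @export
imputation_quality <- function(truth, imputed,
                               imputed_ids = attr(imputed, "imputed_ids"),
                               spec = NULL) {
  if (!identical(truth$individual_id, imputed$individual_id))
    stop("record ids of truth and imputed datasets are not aligned",
         call. = FALSE)
  if (anyNA(imputed$outcome))
    stop("imputed dataset still contains missing outcomes", call. = FALSE)
  idx <- match(imputed_ids, truth$individual_id)
  accuracy <- if (length(idx)) {
    mean(imputed$outcome[idx] == truth$outcome[idx])
  } else NA_real_
  prev_err <- 1000 * (mean(imputed$outcome) - mean(truth$outcome))
  icc_shift <- NULL
  if (!is.null(spec)) {
    f_t <- fit_glmm(truth, spec)
    f_i <- fit_glmm(imputed, spec)
    icc_shift <- vapply(spec$levels, function(l)
      icc(f_i$varcomps, l) - icc(f_t$varcomps, l), numeric(1))
  }
  list(accuracy = accuracy, prevalence_error = prev_err,
       icc_shift = icc_shift)
}
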