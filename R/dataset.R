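#' Survey dataset container
#'
#' A \code{survey_dataset} is a data frame of individual screening records
#' with columns \code{individual_id}, \code{site_id}, \code{village_id},
#' \code{household_id}, \code{interviewer_id}, \code{interviewer_sex}
#' (\code{"F"}/\code{"M"}) and \code{outcome} (0, 1 or \code{NA} for a
#' missing screening result).  Construction validates the strict nesting of
#' the design: every household belongs to exactly one village and one
#' interviewer, every interviewer to exactly one site, every village to one
#' site.
#'
#' @param data A data frame with the columns above.
#' @return The validated data frame with class \code{survey_dataset}.
#' @export
as_survey_dataset <- function(data) {
  needed <- c("individual_id", "site_id", "village_id", "household_id",
              "interviewer_id", "interviewer_sex", "outcome")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  data <- as.data.frame(data)[needed]
  data$outcome <- as.integer(data$outcome)
  validate_survey_dataset(data)
  class(data) <- c("survey_dataset", "data.frame")
  data
}

validate_survey_dataset <- function(data) {
  bad <- which(!(data$outcome %in% c(0L, 1L) | is.na(data$outcome)))
  if (length(bad))
    stop("outcome must be 0, 1 or missing; offending record(s): ",
         paste(utils::head(data$individual_id[bad], 5), collapse = ", "),
         call. = FALSE)
  if (!all(data$interviewer_sex %in% c("F", "M")))
    stop("interviewer_sex must be 'F' or 'M'", call. = FALSE)
  if (anyDuplicated(data$individual_id))
    stop("individual_id values must be unique", call. = FALSE)
  check_single_valued <- function(child, parent, what) {
    tab <- unique(data.frame(child = data[[child]], parent = data[[parent]]))
    dup <- tab$child[duplicated(tab$child)]
    if (length(dup))
      stop(what, " violated: ", child, " ", dup[1],
           " maps to multiple ", parent, " values", call. = FALSE)
  }
  check_single_valued("household_id", "village_id", "nesting")
  check_single_valued("household_id", "interviewer_id", "nesting")
  check_single_valued("interviewer_id", "site_id", "nesting")
  check_single_valued("village_id", "site_id", "nesting")
  check_single_valued("interviewer_id", "interviewer_sex", "consistency")
  invisible(data)
}

#' @export
print.survey_dataset <- function(x, ...) {
  n <- nrow(x)
  nc <- sum(!is.na(x$outcome))
  cat(sprintf(
    "survey_dataset: %d individuals, %d households, %d interviewers, %d villages, %d sites\n",
    n, length(unique(x$household_id)), length(unique(x$interviewer_id)),
    length(unique(x$village_id)), length(unique(x$site_id))))
  cat(sprintf("  outcomes: %d observed (%d events), %d missing\n",
              nc, sum(x$outcome, na.rm = TRUE), n - nc))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Write / read a survey dataset as delimited text
#'
#' Comma-separated layout with a header row and columns
#' \code{individual_id, site_id, village_id, household_id, interviewer_id,
#' interviewer_sex, outcome}; a missing outcome is an empty field.  Reading
#' validates the domain and the cluster nesting and reports the first
#' offending line on failure, so a written dataset always round-trips to an
#' identical object.
#'
#' @param data A \code{\link{survey_dataset}}.
#' @param path File path.
#' @return \code{read_dataset} returns a \code{survey_dataset};
#'   \code{write_dataset} returns \code{path} invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "survey_dataset"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = NULL)
  needed <- c("individual_id", "site_id", "village_id", "household_id",
              "interviewer_id", "interviewer_sex", "outcome")
  if (!identical(names(raw), needed))
    stop("unexpected header in ", path, "; expected: ",
         paste(needed, collapse = ","), call. = FALSE)
  bad <- which(!(raw$outcome %in% c("0", "1", "")))
  if (length(bad))
    stop("parse error in ", path, " line ", bad[1] + 1L,
         ": outcome must be 0, 1 or empty, got '", raw$outcome[bad[1]], "'",
         call. = FALSE)
  raw$individual_id <- as.integer(raw$individual_id)
  raw$outcome <- ifelse(raw$outcome == "", NA_integer_,
                        as.integer(raw$outcome))
  as_survey_dataset(raw)
}

## Complete-case view used by all fitting code.
complete_cases <- function(data) {
  out <- data[!is.na(data$outcome), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(data)
  out
}

#' Write / read a population configuration
#'
#' The sidecar config file is YAML: scalar fields as keys, the household
#' size distribution as a nested list of per-site probability vectors.
#'
#' @param config A \code{\link{population_config}}.
#' @param path File path.
#' @return \code{read_config} returns a \code{population_config}.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "population_config"))
  lst <- unclass(config)
  lst$household_size_dist <- lapply(seq_len(nrow(config$household_size_dist)),
                                    function(i) config$household_size_dist[i, ])
  yaml::write_yaml(lst, path, precision = 17)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$household_size_dist <- do.call(rbind, lst$household_size_dist)
  do.call(population_config, lst)
}
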