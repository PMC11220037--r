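# Plain-text readers/writers for the pipeline's tabular interchange formats.
# All files are tab-separated with a header row.

#' Read and write per-trial behavioral tables
#'
#' Tab-separated, one row per trial: `subject_id`, `condition` (0|2),
#' `stimulus_class` (target|novel|lure), `response` (match|nonmatch|none),
#' `rt_s` (empty for omissions), `block_index`.
#'
#' @param path file path.
#' @return `read_trial_table()` returns a data frame with an `rt` column in
#'   seconds (`NA` for omissions).
#' @export
read_trial_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "condition", "stimulus_class", "response", "rt_s",
            "block_index")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("trial table lacks columns: ", paste(miss, collapse = ", "))
  d$rt <- suppressWarnings(as.numeric(d$rt_s))
  d$rt_s <- NULL
  d
}

#' @rdname read_trial_table
#' @param trials data frame with columns `subject_id`, `condition`,
#'   `stimulus_class`, `response`, `rt`, `block_index`.
#' @export
write_trial_table <- function(trials, path) {
  out <- data.frame(subject_id = trials$subject_id,
                    condition = trials$condition,
                    stimulus_class = trials$stimulus_class,
                    response = trials$response,
                    rt_s = ifelse(is.na(trials$rt), "",
                                  format(trials$rt, digits = 15,
                                         scientific = FALSE, trim = TRUE)),
                    block_index = trials$block_index,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write activation matrices
#'
#' Tab-separated, first column `subject_id`, remaining columns one per
#' feature (parcel).
#'
#' @param path file path.
#' @return `read_activation_matrix()` returns a numeric matrix with subject
#'   row names.
#' @export
read_activation_matrix <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_activation_matrix
#' @param activation subjects x features numeric matrix with dimnames.
#' @export
write_activation_matrix <- function(activation, path) {
  d <- data.frame(subject_id = rownames(activation),
                  activation, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write parcel-to-network label tables
#'
#' Tab-separated: `parcel_id`, `network` (Yeo-7 labels).
#'
#' @param path file path.
#' @export
read_parcel_labels <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("parcel_id", "network") %in% names(d)))
  d
}

#' @rdname read_parcel_labels
#' @param labels data frame `parcel_id`, `network`.
#' @export
write_parcel_labels <- function(labels, path) {
  write.table(labels[, c("parcel_id", "network")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write covariate/cluster tables
#'
#' Tab-separated: `subject_id`, `site`, `family`, `age`, `age2`, `sex`,
#' `raceeth`, `fd`, `fd2`.
#'
#' @param path file path.
#' @export
read_covariates <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_covariates
#' @param covariates covariate data frame.
#' @export
write_covariates <- function(covariates, path) {
  write.table(covariates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cohort EEA table
#'
#' Tab-separated: `subject_id`, `eea_0back`, `eea_2back`, `eea_mean`,
#' `converged`.
#'
#' @param eea data frame from [fit_cohort()].
#' @param path file path.
#' @export
write_eea_table <- function(eea, path) {
  write.table(eea, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eea_table
#' @export
read_eea_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write an exclusion report
#'
#' Tab-separated: `subject_id`, `condition`, `accuracy`, `omission_rate`,
#' `excluded` (0|1), `reason`.
#'
#' @param report report data frame from [apply_quality_exclusions()].
#' @param path file path.
#' @export
write_exclusion_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write posterior summaries of a fit as JSON
#'
#' Per-subject JSON with posterior medians, SDs, rhat per parameter, and the
#' convergence flag.
#'
#' @param fit a [fit_subject()] result.
#' @param path file path.
#' @export
write_posterior_summary <- function(fit, path) {
  sds <- apply(fit$draws, 3, sd)
  obj <- list(subject_id = fit$subject_id,
              medians = as.list(fit$medians),
              sds = as.list(sds),
              rhat = as.list(fit$rhat),
              converged = fit$converged,
              rounds = fit$rounds)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
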