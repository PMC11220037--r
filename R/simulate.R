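#' Simulate first-passage times of the Wiener diffusion
#'
#' Brownian-bridge-corrected Euler-Maruyama simulation on a fixed time grid
#' (`dt`, default 1e-4 s).  Within each step the exact bridge crossing
#' probability `exp(-2 d0 d1 / dt)` is used to detect boundary hits between
#' grid points, which removes the O(sqrt(dt)) first-passage bias of plain
#' Euler stepping.
#'
#' @inheritParams wiener_fpt_density
#' @param n number of passages to simulate (scalar `v`), or `v` may be a
#'   vector of per-trial drifts (then `n` is ignored).
#' @param dt Euler step in seconds.
#' @param tmax give up (censor) after this time.
#' @return data frame with `t` (passage time) and `boundary`
#'   (`"upper"`, `"lower"`, or `NA` if censored at `tmax`).
#' @export
simulate_fpt <- function(n, v, a, z, dt = 1e-4, tmax = 20) {
  check_wiener_args(v[1], a, z)
  vv <- if (length(v) > 1) as.numeric(v) else rep(as.numeric(v), n)
  sim <- euler_fpt_cpp(vv, a, z, dt, tmax)
  boundary <- rep(NA_character_, length(sim$boundary))
  boundary[sim$boundary == 1L] <- "upper"
  boundary[sim$boundary == 0L] <- "lower"
  data.frame(t = sim$t, boundary = boundary, stringsAsFactors = FALSE)
}

#' Simulate a subject's n-back trial set from DDM parameters
#'
#' Draws decision times by diffusion simulation ([simulate_fpt()]), adds
#' uniform non-decision time on `[t0, t0 + st0]`, censors at the response
#' window, and injects contaminant omissions with probability `p_contam`.
#' Responses are decoded from the absorbing boundary by accuracy coding
#' (upper = correct: "match" for targets, "nonmatch" otherwise).
#'
#' @param params a [ddm_parameters()] vector.
#' @param schedule data frame with one row per trial: columns `condition`
#'   (0 or 2), `stimulus_class`, and optionally `block_index` (see
#'   [build_task_schedule()]).
#' @param seed optional integer seed (set for reproducibility).
#' @param response_window response deadline in seconds.
#' @param dt Euler step for the diffusion simulation.
#' @return data frame of trials: `condition`, `stimulus_class`, `response`,
#'   `rt` (`NA` for omissions), `block_index`.
#' @export
simulate_trials <- function(params, schedule, seed = NULL,
                            response_window = RESPONSE_WINDOW_DEFAULT,
                            dt = 1e-4) {
  validate_ddm_parameters(unclass(params))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(schedule)
  response <- character(n)
  rt <- rep(NA_real_, n)
  for (cond in c(0, 2)) {
    idx <- which(as.integer(as.character(schedule$condition)) == cond)
    if (!length(idx)) next
    p <- cond_slice(params, cond)
    cls <- match(schedule$stimulus_class[idx], c("target", "novel", "lure"))
    v <- c(p[["v_target"]], p[["v_novel"]], p[["v_lure"]])[cls]
    contam <- runif(length(idx)) < p[["p_contam"]]
    sim <- simulate_fpt(length(idx), v, p[["a"]], p[["z"]], dt = dt,
                        tmax = response_window)
    t0p <- p[["t0"]] + p[["st0"]] * runif(length(idx))
    rt_i <- sim$t + t0p
    responded <- !contam & !is.na(sim$boundary) & rt_i <= response_window
    correct_resp <- ifelse(schedule$stimulus_class[idx] == "target",
                           "match", "nonmatch")
    wrong_resp <- ifelse(correct_resp == "match", "nonmatch", "match")
    resp <- ifelse(sim$boundary == "upper", correct_resp, wrong_resp)
    response[idx] <- ifelse(responded, resp, "none")
    rt[idx] <- ifelse(responded, rt_i, NA_real_)
  }
  out <- data.frame(
    condition = as.integer(as.character(schedule$condition)),
    stimulus_class = schedule$stimulus_class,
    response = response,
    rt = rt,
    block_index = if ("block_index" %in% names(schedule))
      schedule$block_index else 0L,
    stringsAsFactors = FALSE)
  out
}

#' Behavioral quality exclusions
#'
#' Applies the behavioral data-quality filter: response times below 200 ms are
#' removed trial-wise first (fast guesses), then any subject with accuracy
#' below 55% (over non-omitted trials) or an omission rate above 25% (over all
#' trials) in either load condition is excluded.  A subject with no scorable
#' trials in a condition is excluded with reason `"no data"`.
#'
#' @param trials data frame of trials across subjects, with columns
#'   `subject_id`, `condition`, `stimulus_class`, `response`, `rt`.
#' @param accuracy_min minimum accuracy (default 0.55).
#' @param omission_max maximum omission rate (default 0.25).
#' @param rt_min fast-guess threshold in seconds (default 0.200).
#' @return list with `retained` (subject ids), `report` (one row per
#'   subject x condition: accuracy, omission rate, excluded flag, reason), and
#'   `trials` (the RT-filtered trials of retained subjects).
#' @export
apply_quality_exclusions <- function(trials, accuracy_min = 0.55,
                                     omission_max = 0.25, rt_min = 0.200) {
  stopifnot(all(c("subject_id", "condition", "stimulus_class", "response")
                %in% names(trials)))
  fast <- !is.na(trials$rt) & trials$rt < rt_min
  trials <- trials[!fast, , drop = FALSE]
  subjects <- unique(trials$subject_id)
  rows <- list()
  retained <- character(0)
  for (s in subjects) {
    keep <- TRUE
    for (cond in c(0, 2)) {
      tt <- trials[trials$subject_id == s &
                     as.integer(as.character(trials$condition)) == cond, ,
                   drop = FALSE]
      if (nrow(tt) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = s, condition = cond, accuracy = NA_real_,
          omission_rate = NA_real_, excluded = 1L, reason = "no data",
          stringsAsFactors = FALSE)
        keep <- FALSE
        next
      }
      omit <- tt$response == "none"
      om_rate <- mean(omit)
      scorable <- tt[!omit, , drop = FALSE]
      acc <- if (nrow(scorable) == 0) NA_real_ else
        mean(trial_outcome_code(scorable$stimulus_class,
                                scorable$response) == 0L)
      reason <- ""
      if (nrow(scorable) == 0) {
        reason <- "no data"
      } else {
        if (acc < accuracy_min) reason <- "low accuracy"
        if (om_rate > omission_max)
          reason <- if (nzchar(reason))
            paste(reason, "high omissions", sep = "; ") else "high omissions"
      }
      excl <- nzchar(reason)
      if (excl) keep <- FALSE
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s, condition = cond, accuracy = acc,
        omission_rate = om_rate, excluded = as.integer(excl),
        reason = reason, stringsAsFactors = FALSE)
    }
    if (keep) retained <- c(retained, s)
  }
  report <- do.call(rbind, rows)
  list(retained = retained, report = report,
       trials = trials[trials$subject_id %in% retained, , drop = FALSE])
}
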