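#' DDM parameter vector for the two n-back load conditions
#'
#' Builds the 16-parameter vector the likelihood consumes: per condition
#' (0-back, 2-back) three drift rates (target, novel, lure), boundary
#' separation `a`, non-decision time `t0`, uniform non-decision variability
#' width `st0`, relative start point `z`, and contaminant-omission probability
#' `p_contam`.  The within-trial diffusion coefficient is fixed at 1, a scale
#' convention; drift and boundary estimates are comparable only under the same
#' convention.  Between-trial drift and start-point variability (sv, sz) are
#' deliberately not part of the model.
#'
#' @param v_0back,v_2back numeric length-3 drift rates, ordered
#'   (target, novel, lure), evidence units per second.
#' @param a_0back,a_2back boundary separation (> 0).
#' @param t0_0back,t0_2back non-decision time in seconds (>= 0).
#' @param st0_0back,st0_2back width of uniform non-decision-time variability
#'   (>= 0).
#' @param z_0back,z_2back relative start point in (0, 1); 0.5 is unbiased.
#' @param p_contam_0back,p_contam_2back contaminant-omission probability in
#'   `[0, 1]`.
#' @return named numeric vector of length 16, class `"ddm_parameters"`.
#' @export
ddm_parameters <- function(v_0back, a_0back, t0_0back, st0_0back, z_0back,
                           p_contam_0back,
                           v_2back = v_0back, a_2back = a_0back,
                           t0_2back = t0_0back, st0_2back = st0_0back,
                           z_2back = z_0back,
                           p_contam_2back = p_contam_0back) {
  mk <- function(v, a, t0, st0, z, pc) {
    stopifnot(length(v) == 3)
    c(v, a, t0, st0, z, pc)
  }
  x <- c(mk(v_0back, a_0back, t0_0back, st0_0back, z_0back, p_contam_0back),
         mk(v_2back, a_2back, t0_2back, st0_2back, z_2back, p_contam_2back))
  names(x) <- PAR_NAMES_16
  validate_ddm_parameters(x)
  class(x) <- c("ddm_parameters", "numeric")
  x
}

validate_ddm_parameters <- function(x) {
  if (length(x) != 16 || !is.numeric(x) || anyNA(x))
    stop("DDM parameters must be a complete numeric vector of length 16")
  for (o in c(0L, 8L)) {
    a <- x[o + 4L]; t0 <- x[o + 5L]; st0 <- x[o + 6L]
    z <- x[o + 7L]; pc <- x[o + 8L]
    if (a <= 0) stop("boundary separation 'a' must be > 0")
    if (z <= 0 || z >= 1) stop("start point 'z' must lie in (0, 1)")
    if (t0 < 0) stop("non-decision time 't0' must be >= 0")
    if (st0 < 0) stop("'st0' must be >= 0")
    if (pc < 0 || pc > 1) stop("'p_contam' must lie in [0, 1]")
  }
  invisible(x)
}

as_theta_row <- function(params) {
  validate_ddm_parameters(unclass(params))
  matrix(unclass(params), nrow = 1)
}

cond_slice <- function(params, condition) {
  o <- if (condition == 0) 0L else 8L
  p <- unclass(params)[(o + 1L):(o + 8L)]
  names(p) <- PAR_NAMES_COND
  p
}

#' Wiener first-passage-time density
#'
#' Density of the first passage of a Wiener process with drift `v`, diffusion
#' coefficient 1, absorbing boundaries at 0 and `a`, and start `z * a`, at the
#' named boundary.  Evaluated with the small-time / large-time series
#' representations and an automatic switching rule (series truncated at
#' relative tolerance 1e-8 of the unit-boundary density).  Integrates to 1
#' over both boundaries and all t > 0.
#'
#' @param t decision times in seconds (density is 0 for t <= 0).
#' @param v drift rate.
#' @param a boundary separation (> 0).
#' @param z relative start point in (0, 1).
#' @param boundary `"upper"` or `"lower"`.
#' @return numeric vector of densities (>= 0).
#' @export
wiener_fpt_density <- function(t, v, a, z, boundary = c("upper", "lower")) {
  boundary <- match.arg(boundary)
  check_wiener_args(v, a, z)
  wiener_pdf_cpp(as.numeric(t), v, a, z, boundary == "upper")
}

#' Wiener first-passage-time CDF at one boundary
#'
#' P(T <= t and absorption at the named boundary), computed by composite
#' Gauss-Legendre integration of [wiener_fpt_density()].
#'
#' @inheritParams wiener_fpt_density
#' @return numeric vector of probabilities.
#' @export
wiener_fpt_cdf <- function(t, v, a, z, boundary = c("upper", "lower")) {
  boundary <- match.arg(boundary)
  check_wiener_args(v, a, z)
  wiener_cdf_cpp(as.numeric(t), v, a, z, boundary == "upper")
}

#' Total absorption probability at the upper boundary
#'
#' Closed-form probability that the process is eventually absorbed at the
#' upper (correct) boundary.
#'
#' @inheritParams wiener_fpt_density
#' @return scalar probability.
#' @export
wiener_prob_upper <- function(v, a, z) {
  check_wiener_args(v, a, z)
  prob_upper_cpp(v, a, z)
}

check_wiener_args <- function(v, a, z) {
  if (!is.numeric(a) || length(a) != 1 || is.na(a) || a <= 0)
    stop("boundary separation 'a' must be a positive scalar")
  if (!is.numeric(z) || length(z) != 1 || is.na(z) || z <= 0 || z >= 1)
    stop("start point 'z' must lie in (0, 1)")
  if (!is.numeric(v) || length(v) != 1 || is.na(v))
    stop("drift 'v' must be a finite scalar")
  invisible(NULL)
}

#' Outcome probabilities for one condition and stimulus class
#'
#' Probability of a correct response, an error response, and an omission
#' within the response window, under accuracy coding (the upper boundary is
#' the correct response for every stimulus class: "match" for targets,
#' "nonmatch" for novels and lures).  Omissions mix a contaminant component
#' with design censoring:
#' `P(omit) = p_contam + (1 - p_contam) * P(T_decision + T_nondecision > window)`.
#'
#' @param params a [ddm_parameters()] vector.
#' @param condition 0 or 2 (load level).
#' @param stimulus_class `"target"`, `"novel"`, or `"lure"`.
#' @param response_window response deadline in seconds (default 2.0).
#' @return named numeric vector `c(correct, error, omission)`, summing to 1.
#' @export
response_probability <- function(params, condition, stimulus_class,
                                 response_window = RESPONSE_WINDOW_DEFAULT) {
  p <- cond_slice(params, condition)
  k <- match(stimulus_class, c("target", "novel", "lure"))
  if (is.na(k)) stop("unknown stimulus class: ", stimulus_class)
  if (response_window <= p[["t0"]] && p[["st0"]] == 0)
    warning("response window does not exceed t0: no response is possible")
  out <- outcome_probs_cpp(p[[k]], p[["a"]], p[["t0"]], p[["st0"]],
                           p[["z"]], p[["p_contam"]], response_window)
  names(out) <- c("correct", "error", "omission")
  out
}

trial_outcome_code <- function(stimulus_class, response) {
  # 0 = correct response, 1 = error response, 2 = omission
  out <- integer(length(response))
  correct <- ifelse(stimulus_class == "target", "match", "nonmatch")
  out[response == "none"] <- 2L
  hit <- response != "none" & response == correct
  out[hit] <- 0L
  out[response != "none" & !hit] <- 1L
  out
}

prepare_trial_data <- function(trials, response_window) {
  required <- c("condition", "stimulus_class", "response")
  if (!all(required %in% names(trials)))
    stop("trial table needs columns: ", paste(required, collapse = ", "))
  cond <- as.integer(as.character(trials$condition))
  if (!all(cond %in% c(0L, 2L))) stop("condition must be 0 or 2")
  cls <- match(trials$stimulus_class, c("target", "novel", "lure")) - 1L
  if (anyNA(cls)) stop("stimulus_class must be target, novel or lure")
  if (!all(trials$response %in% c("match", "nonmatch", "none")))
    stop("response must be match, nonmatch or none")
  rt <- trials$rt
  none <- trials$response == "none"
  if (any(none & !is.na(rt)))
    stop("rt must be absent when response is 'none'")
  if (any(!none & (is.na(rt) | rt <= 0 | rt > response_window)))
    stop("observed rt must lie in (0, response_window]")
  list(cond = as.integer(cond == 2L), cls = cls,
       outc = trial_outcome_code(trials$stimulus_class, trials$response),
       rt = ifelse(is.na(rt), -1, rt))
}

#' Log-likelihood of a single trial
#'
#' For an observed response at `rt`, the likelihood is
#' `(1 - p_contam) * E[f_boundary(rt - t0')]` where `t0'` is uniform on
#' `[t0, t0 + st0]` (10-node Gauss-Legendre quadrature) and the boundary is
#' determined by accuracy coding.  For an omission it is
#' `p_contam + (1 - p_contam) * P(no response within the window)`.
#' Returns `-Inf` for observations impossible under the parameters; invalid
#' parameters raise an error instead.
#'
#' @param trial one-row data frame with columns `condition`, `stimulus_class`,
#'   `response`, `rt` (`NA` for omissions).
#' @param params a [ddm_parameters()] vector.
#' @param response_window response deadline in seconds.
#' @return scalar log-density (or `-Inf`).
#' @export
trial_log_likelihood <- function(trial, params,
                                 response_window = RESPONSE_WINDOW_DEFAULT) {
  subject_log_likelihood(trial, params, response_window)
}

#' Joint log-likelihood of one subject's trial set
#'
#' Sum of [trial_log_likelihood()] over independent trials; `-Inf` propagates.
#'
#' @param trials data frame of trials for one subject (columns `condition`,
#'   `stimulus_class`, `response`, `rt`).
#' @inheritParams trial_log_likelihood
#' @return scalar total log-likelihood.
#' @export
subject_log_likelihood <- function(trials, params,
                                   response_window = RESPONSE_WINDOW_DEFAULT) {
  if (is.null(nrow(trials)) || nrow(trials) == 0)
    stop("trial set is empty")
  validate_ddm_parameters(unclass(params))
  d <- prepare_trial_data(trials, response_window)
  ll <- ddm_loglik_cpp(as_theta_row(params), d$cond, d$cls, d$outc, d$rt,
                       response_window)
  if (is.na(ll)) stop("invalid DDM parameters")
  ll
}
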