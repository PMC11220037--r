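#' Split-chain Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half (so within-chain non-stationarity also inflates the statistic).
#' Values below 1.1 are conventionally taken as converged.
#'
#' @param draws a draws x chains matrix, or a draws x chains x parameters
#'   array (then one rhat per parameter is returned).
#' @return numeric rhat (vector if `draws` has a parameter dimension).
#' @export
gelman_rubin_rhat <- function(draws) {
  if (length(dim(draws)) == 3) {
    return(apply(draws, 3, gelman_rubin_rhat))
  }
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) stop("rhat requires at least 2 chains")
  n <- nrow(draws)
  half <- floor(n / 2)
  if (half < 2) stop("chains too short to split")
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split)
  means <- colMeans(split)
  vars <- apply(split, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W < 1e-300) return(1)
  var_hat <- (half - 1) / half * W + B / half
  sqrt(var_hat / W)
}

logit_pc <- function(p) qlogis(pmin(pmax(p / 0.5, 1e-12), 1 - 1e-12))
inv_logit_pc <- function(eta) 0.5 * plogis(eta)

PC_COLS <- c(8L, 16L)

to_sampling_scale <- function(theta, free_pc) {
  for (j in PC_COLS[free_pc]) theta[, j] <- logit_pc(theta[, j])
  theta
}

to_natural_scale <- function(theta, free_pc) {
  for (j in PC_COLS[free_pc]) theta[, j] <- inv_logit_pc(theta[, j])
  theta
}

# log |d p / d eta| for the contaminant-probability logit transform
log_jacobian_pc <- function(theta_s, free_pc) {
  lj <- numeric(nrow(theta_s))
  for (j in PC_COLS[free_pc]) {
    p <- plogis(theta_s[, j])
    lj <- lj + log(0.5) + log(p) + log1p(-p)
  }
  lj
}

#' Bayesian individual-level DDM fit by DE-MCMC
#'
#' Samples the joint posterior of the 16 DDM parameters (8 per load
#' condition) for one subject under truncated-normal priors, using
#' differential-evolution MCMC with `3 x n_free` interacting chains.  After a
#' warm-up phase, sampling rounds of `n_keep` iterations are repeated until
#' the split-chain rhat of every free parameter drops below `rhat_max`, up to
#' `max_rounds` rounds; a fit that never converges is retained but flagged.
#' The contaminant probability is sampled on the logit scale (with the
#' appropriate Jacobian) to respect its bounds.
#'
#' @param trials data frame of one subject's trials (columns `condition`,
#'   `stimulus_class`, `response`, `rt`).
#' @param priors a [prior_spec()] with 16 rows (see [default_priors()]).
#' @param response_window response deadline in seconds.
#' @param n_burn warm-up iterations (discarded).
#' @param n_keep iterations kept per round.
#' @param max_rounds maximum number of sampling rounds.
#' @param rhat_max convergence threshold (default 1.1).
#' @param seed optional integer seed.
#' @param subject_id optional identifier stored in the result.
#' @return object of class `"ddm_fit"`: `draws` (n_keep x chains x 16 array,
#'   natural scale), `medians`, `rhat`, `converged`, `rounds`,
#'   `accept_rate`.
#' @export
fit_subject <- function(trials, priors, response_window = RESPONSE_WINDOW_DEFAULT,
                        n_burn = 300, n_keep = 500, max_rounds = 5,
                        rhat_max = 1.1, seed = NULL, subject_id = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_prior_spec(priors)
  if (nrow(priors) != 16) stop("priors must cover all 16 DDM parameters")
  d <- prepare_trial_data(trials, response_window)
  if (all(d$outc == 2L))
    stop("all trials are omissions: individual estimation is not identifiable")
  free <- priors$lower < priors$upper
  free_pc <- priors$lower[PC_COLS] < priors$upper[PC_COLS]
  n_free <- sum(free)
  n_chains <- 3L * max(n_free, 2L)

  log_post_s <- function(theta_s) {
    nat <- to_natural_scale(theta_s, free_pc)
    lp <- prior_logpdf(priors, nat) + log_jacobian_pc(theta_s, free_pc)
    ok <- is.finite(lp)
    if (any(ok)) {
      ll <- ddm_loglik_cpp(nat[ok, , drop = FALSE], d$cond, d$cls, d$outc,
                           d$rt, response_window)
      ll[is.na(ll)] <- -Inf
      lp[ok] <- lp[ok] + ll
    }
    lp
  }

  # initialize from the prior, insisting on finite posteriors
  theta <- to_sampling_scale(sample_from_prior(priors, n_chains), free_pc)
  lp_cur <- log_post_s(theta)
  for (tries in 1:50) {
    bad <- !is.finite(lp_cur)
    if (!any(bad)) break
    theta[bad, ] <- to_sampling_scale(sample_from_prior(priors, sum(bad)),
                                      free_pc)[, , drop = FALSE]
    lp_cur[bad] <- log_post_s(theta[bad, , drop = FALSE])
  }
  if (any(!is.finite(lp_cur)))
    stop("could not find prior draws with finite posterior density")

  n_acc <- 0L; n_prop <- 0L
  # burn-in-only migration: a random ring of chains proposes neighbours'
  # states (with jitter), MH-accepted -- quickly pulls stragglers into the
  # posterior region without breaking stationarity of the sampling phase
  migrate_step <- function() {
    k <- max(2L, stats::rbinom(1, n_chains, 0.1))
    sel <- sample.int(n_chains, k)
    src <- c(sel[-1], sel[1])
    prop <- theta[src, , drop = FALSE] +
      matrix(runif(k * 16, -1e-3, 1e-3), k, 16)
    prop[, !free] <- theta[sel, !free, drop = FALSE]
    lp_prop <- log_post_s(prop)
    acc <- log(runif(k)) < lp_prop - lp_cur[sel]
    acc[!is.finite(lp_prop)] <- FALSE
    theta[sel[acc], ] <<- prop[acc, , drop = FALSE]
    lp_cur[sel[acc]] <<- lp_prop[acc]
  }
  # differential-evolution proposal with randomized-subspace crossover: each
  # chain updates a random subset of free coordinates, with the jump scale
  # 2.38/sqrt(2 d_sel) matched to the subset size (full-dimension jumps with
  # gamma = 1 are mixed in for mode hopping)
  free_idx <- which(free)
  de_step <- function(n_iter, migrate = FALSE) {
    for (it in seq_len(n_iter)) {
      if (migrate && runif(1) < 0.2) migrate_step()
      r1 <- sample.int(n_chains, n_chains, replace = TRUE)
      r2 <- sample.int(n_chains, n_chains, replace = TRUE)
      # avoid degenerate difference vectors
      clash <- r1 == r2 | r1 == seq_len(n_chains) | r2 == seq_len(n_chains)
      while (any(clash)) {
        r1[clash] <- sample.int(n_chains, sum(clash), replace = TRUE)
        r2[clash] <- sample.int(n_chains, sum(clash), replace = TRUE)
        clash <- r1 == r2 | r1 == seq_len(n_chains) | r2 == seq_len(n_chains)
      }
      cr <- sample(c(0.25, 0.5, 1), 1)
      mask <- matrix(FALSE, n_chains, 16)
      mask[, free_idx] <- runif(n_chains * n_free) < cr
      none <- rowSums(mask) == 0L
      if (any(none))
        mask[cbind(which(none),
                   free_idx[sample.int(n_free, sum(none), replace = TRUE)])] <-
          TRUE
      d_sel <- rowSums(mask)
      g <- if (runif(1) < 0.1) rep(1, n_chains) else
        2.38 / sqrt(2 * d_sel) * runif(n_chains, 0.5, 1.5)
      diff <- theta[r1, , drop = FALSE] - theta[r2, , drop = FALSE]
      step <- (g * diff + matrix(runif(n_chains * 16, -1e-4, 1e-4),
                                 n_chains, 16)) * mask
      prop <- theta + step
      lp_prop <- log_post_s(prop)
      acc <- log(runif(n_chains)) < lp_prop - lp_cur
      acc[!is.finite(lp_prop)] <- FALSE
      theta[acc, ] <<- prop[acc, , drop = FALSE]
      lp_cur[acc] <<- lp_prop[acc]
      n_acc <<- n_acc + sum(acc); n_prop <<- n_prop + n_chains
    }
  }

  # warm-up: DE with migration, while recording late-burn states to build a
  # frozen moment-matched Gaussian used for independence-MH mixture proposals
  # during the sampling phase (frozen before sampling, so the kernel is a
  # fixed valid MCMC kernel; independence jumps break the random-walk
  # autocorrelation of pure DE moves)
  pool <- matrix(NA_real_, 0, 16)
  n_pool_iters <- min(200L, n_burn %/% 2L)
  de_step(n_burn - n_pool_iters, migrate = TRUE)
  for (it in seq_len(n_pool_iters)) {
    de_step(1L, migrate = TRUE)
    if (it %% 5L == 0L) pool <- rbind(pool, theta)
  }
  freeze_gaussian <- function(states) {
    if (nrow(states) <= 5L * n_free) return(NULL)
    mu_p <- colMeans(states[, free_idx, drop = FALSE])
    sig_p <- 1.44 * stats::cov(states[, free_idx, drop = FALSE])
    diag(sig_p) <- diag(sig_p) + 1e-10
    ch <- tryCatch(chol(sig_p), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    list(mu = mu_p, chol = ch, ldet = sum(log(diag(ch))))
  }
  ind_prop <- freeze_gaussian(pool)
  ind_logq <- function(theta_s) {
    dev <- sweep(theta_s[, free_idx, drop = FALSE], 2, ind_prop$mu)
    w <- backsolve(ind_prop$chol, t(dev), transpose = TRUE)
    -0.5 * colSums(w^2) - ind_prop$ldet
  }
  ind_step <- function() {
    zmat <- matrix(rnorm(n_chains * n_free), n_chains, n_free)
    prop <- theta
    prop[, free_idx] <- rep(ind_prop$mu, each = n_chains) +
      zmat %*% ind_prop$chol
    lp_prop <- log_post_s(prop)
    ratio <- lp_prop - lp_cur + ind_logq(theta) - ind_logq(prop)
    acc <- log(runif(n_chains)) < ratio
    acc[!is.finite(lp_prop)] <- FALSE
    theta[acc, ] <<- prop[acc, , drop = FALSE]
    lp_cur[acc] <<- lp_prop[acc]
    n_acc <<- n_acc + sum(acc); n_prop <<- n_prop + n_chains
  }
  rounds <- 0L
  converged <- FALSE
  draws_s <- NULL
  while (rounds < max_rounds && !converged) {
    rounds <- rounds + 1L
    store <- array(NA_real_, c(n_keep, n_chains, 16))
    for (it in seq_len(n_keep)) {
      if (!is.null(ind_prop) && runif(1) < 0.5) ind_step() else de_step(1L)
      store[it, , ] <- theta
    }
    draws_s <- store
    rh <- rep(1, 16)
    rh[free] <- vapply(which(free), function(j)
      gelman_rubin_rhat(draws_s[, , j]), 0)
    converged <- all(rh < rhat_max)
    if (!converged) {
      # re-freeze the independence proposal from this round's draws (the
      # reported draws always come from a round run under a fixed kernel)
      thin <- store[seq(5, n_keep, by = 5), , , drop = FALSE]
      flat <- matrix(aperm(thin, c(2, 1, 3)), ncol = 16)
      refreshed <- freeze_gaussian(flat)
      if (!is.null(refreshed)) ind_prop <- refreshed
    }
  }

  draws_nat <- draws_s
  for (j in PC_COLS[free_pc]) draws_nat[, , j] <- inv_logit_pc(draws_s[, , j])
  dimnames(draws_nat) <- list(NULL, NULL, priors$parameter)
  med <- apply(draws_nat, 3, median)
  names(rh) <- priors$parameter
  structure(list(draws = draws_nat, medians = med, rhat = rh,
                 converged = converged, rounds = rounds,
                 accept_rate = n_acc / n_prop, n_chains = n_chains,
                 n_trials = length(d$cond), subject_id = subject_id,
                 response_window = response_window),
            class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("Individual DDM fit (DE-MCMC)\n")
  cat(sprintf("  chains: %d, rounds: %d, accept rate: %.2f\n",
              x$n_chains, x$rounds, x$accept_rate))
  cat(sprintf("  max rhat: %.3f (%s)\n", max(x$rhat),
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$medians, 3))
  invisible(x)
}

#' Extract EEA from a fitted DDM
#'
#' EEA per load condition is the mean of the posterior medians of the three
#' stimulus-class drift rates; `eea_mean` averages the two conditions.
#' Non-converged fits still yield values, with the convergence flag carried
#' along for the caller to filter on.
#'
#' @param fit a [fit_subject()] result.
#' @return one-row data frame: `subject_id`, `eea_0back`, `eea_2back`,
#'   `eea_mean`, `converged`.
#' @export
compute_eea <- function(fit) {
  stopifnot(inherits(fit, "ddm_fit"))
  m <- fit$medians
  e0 <- mean(m[c("v_target_0back", "v_novel_0back", "v_lure_0back")])
  e2 <- mean(m[c("v_target_2back", "v_novel_2back", "v_lure_2back")])
  data.frame(subject_id = if (is.null(fit$subject_id)) NA_character_
             else fit$subject_id,
             eea_0back = e0, eea_2back = e2, eea_mean = (e0 + e2) / 2,
             converged = fit$converged, stringsAsFactors = FALSE)
}

#' Posterior predictive check of a fitted DDM
#'
#' Simulates `n_rep` replicate trial sets from parameter vectors drawn from
#' the posterior and compares observed accuracy, omission rate, and RT
#' deciles (per condition) against the replicate predictive distribution.
#'
#' @param fit a [fit_subject()] result.
#' @param trials the observed trials the fit was based on.
#' @param n_rep number of posterior replicates.
#' @param seed optional integer seed.
#' @param level predictive interval coverage (default 0.95).
#' @return data frame with one row per statistic: `condition`, `stat`,
#'   `observed`, `pred_lo`, `pred_hi`, `inside`.
#' @export
posterior_predictive_check <- function(fit, trials, n_rep = 100, seed = NULL,
                                       level = 0.95) {
  stopifnot(inherits(fit, "ddm_fit"))
  if (!is.null(seed)) set.seed(seed)
  schedule <- trials[, c("condition", "stimulus_class")]
  nd <- dim(fit$draws)
  idx_draw <- sample.int(nd[1], n_rep, replace = TRUE)
  idx_chain <- sample.int(nd[2], n_rep, replace = TRUE)
  stats_of <- function(tt) {
    out <- list()
    for (cond in c(0, 2)) {
      tc <- tt[as.integer(as.character(tt$condition)) == cond, , drop = FALSE]
      omit <- tc$response == "none"
      sc <- tc[!omit, , drop = FALSE]
      acc <- if (nrow(sc)) mean(trial_outcome_code(sc$stimulus_class,
                                                   sc$response) == 0L)
             else NA_real_
      dec <- if (nrow(sc) >= 10)
        quantile(sc$rt, probs = seq(0.1, 0.9, by = 0.1), names = FALSE)
      else rep(NA_real_, 9)
      out[[as.character(cond)]] <- c(accuracy = acc, omission = mean(omit),
                                     setNames(dec, paste0("rt_q", 1:9 * 10)))
    }
    out
  }
  obs <- stats_of(trials)
  reps <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    th <- fit$draws[idx_draw[r], idx_chain[r], ]
    params <- structure(th, names = PAR_NAMES_16,
                        class = c("ddm_parameters", "numeric"))
    reps[[r]] <- stats_of(simulate_trials(params, schedule,
                                          response_window =
                                            fit$response_window,
                                          dt = 1e-3))
  }
  alpha <- (1 - level) / 2
  rows <- list()
  for (cond in c("0", "2")) {
    stat_names <- names(obs[[cond]])
    mat <- do.call(rbind, lapply(reps, function(r) r[[cond]]))
    for (s in stat_names) {
      qs <- quantile(mat[, s], probs = c(alpha, 1 - alpha), na.rm = TRUE,
                     names = FALSE)
      o <- obs[[cond]][[s]]
      rows[[length(rows) + 1L]] <- data.frame(
        condition = as.integer(cond), stat = s, observed = o,
        pred_lo = qs[1], pred_hi = qs[2],
        inside = !is.na(o) && o >= qs[1] && o <= qs[2],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Fit every subject in a trial table
#'
#' Convenience loop over [fit_subject()] followed by [compute_eea()].
#'
#' @param trials data frame of trials across subjects (column `subject_id`).
#' @param priors a [prior_spec()].
#' @param seed integer seed controlling the whole loop.
#' @param ... passed to [fit_subject()].
#' @return list with `eea` (one row per subject) and `fits` (list of
#'   `ddm_fit`).
#' @export
fit_cohort <- function(trials, priors, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  subjects <- unique(trials$subject_id)
  fits <- vector("list", length(subjects))
  names(fits) <- subjects
  for (s in subjects) {
    fits[[s]] <- fit_subject(trials[trials$subject_id == s, , drop = FALSE],
                             priors, subject_id = s, ...)
  }
  eea <- do.call(rbind, lapply(fits, compute_eea))
  rownames(eea) <- NULL
  list(eea = eea, fits = fits)
}

#' Build informative priors from a synthetic reference cohort
#'
#' Emulates the informative-prior construction step: simulates a reference
#' cohort of engaged subjects, fits each individually under [vague_priors()],
#' pools all posterior draws per parameter, and fits a truncated normal to
#' each pool.  (A hierarchical group-level fit of the reference sample is out
#' of scope; pooling individual posteriors is the documented substitution.)
#'
#' @param n_subjects reference cohort size (default 300).
#' @param seed integer seed.
#' @param spec a [population_spec()]; defaults to the package default.
#' @param max_pool cap on pooled draws per parameter before the truncated
#'   normal fit.
#' @param ... passed to [fit_subject()].
#' @return a [prior_spec()].
#' @export
emulate_priors <- function(n_subjects = 300, seed = 1, spec = NULL,
                           max_pool = 2e5, ...) {
  set.seed(seed)
  if (is.null(spec)) spec <- population_spec(n_subjects = n_subjects)
  spec$n_subjects <- n_subjects
  cohort <- simulate_cohort(spec, seed = seed, behavior = TRUE)
  excl <- apply_quality_exclusions(cohort$trials)
  pri <- vague_priors()
  fits <- fit_cohort(excl$trials, pri, seed = seed + 1, ...)$fits
  bounds <- ddm_parameter_bounds()
  loc <- numeric(16); sc <- numeric(16)
  for (j in seq_len(16)) {
    pool <- unlist(lapply(fits, function(f) as.numeric(f$draws[, , j])))
    if (length(pool) > max_pool) pool <- sample(pool, max_pool)
    est <- fit_truncated_normal_prior(pool, bounds$lower[j], bounds$upper[j])
    loc[j] <- est[["location"]]; sc[j] <- est[["scale"]]
  }
  prior_spec(location = loc, scale = sc, lower = bounds$lower,
             upper = bounds$upper, parameters = bounds$parameter)
}
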