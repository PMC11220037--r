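YEO7 <- c("VIS", "SMN", "DAN", "VAN", "LIM", "FPN", "DMN")

#' Planted network-activation effect sizes (Table-1-style preset)
#'
#' Per-network planted correlations of 0-back and 2-back activation with
#' overall (covariate-adjusted, standardized) EEA, plus the planted
#' cross-condition activation correlation.  FPN/DAN/SMN values follow the
#' divergent pattern reported for the child cohort (2-back positive, 0-back
#' negative for task-positive networks; reversed for the somatomotor
#' network); the four remaining networks are given symmetric small splits
#' consistent with their load-contrast associations.  These are targets of
#' the generator, not results.
#'
#' @return data frame with one row per Yeo-7 network: `network`, `r_0back`,
#'   `r_2back`, `rho_cross`, `mu_0back`, `mu_2back`.
#' @export
activation_preset_table1 <- function() {
  data.frame(
    network = YEO7,
    r_0back = c(0.053, 0.020, -0.070, 0.041, 0.101, -0.270, -0.006),
    r_2back = c(-0.053, -0.290, 0.170, -0.041, -0.101, 0.170, 0.006),
    rho_cross = c(0.30, 0.38, 0.36, 0.30, 0.30, 0.24, 0.30),
    mu_0back = c(0.30, -0.10, 0.00, 0.05, -0.05, 0.10, -0.20),
    mu_2back = c(0.40, -0.50, 0.45, 0.20, -0.10, 0.50, -0.50),
    stringsAsFactors = FALSE)
}

#' Population specification for the synthetic cohort generator
#'
#' Defines every distribution the generator draws from: the between-subject
#' DDM parameter population (per condition), the latent EEA structure
#' (cross-condition correlation, family/site components, covariate channel),
#' the cluster design (sites, families), covariate distributions, and the
#' activation model (planted network correlations with EEA, cross-condition
#' correlation, baselines, noise).  The implied latent covariance structure
#' is checked for feasibility at construction.
#'
#' @param n_subjects cohort size.
#' @param activation an [activation_preset_table1()]-shaped data frame.
#' @param n_sites number of acquisition sites.
#' @param sigma_v between-subject SD of EEA (drift units).
#' @param rho_eea latent correlation between 0-back and 2-back EEA.
#' @return list of class `"population_spec"`.
#' @export
population_spec <- function(n_subjects = 500,
                            activation = activation_preset_table1(),
                            n_sites = 20, sigma_v = 0.7, rho_eea = 0.45) {
  spec <- list(
    n_subjects = n_subjects,
    # mean drift per condition x class (target, novel, lure)
    class_means = rbind(`0` = c(2.6, 3.0, 2.4), `2` = c(1.6, 2.2, 1.2)),
    sigma_v = sigma_v,
    rho_eea = rho_eea,
    eea_family_frac = 0.30,   # family share of latent EEA SD
    eea_site_frac = 0.10,
    eea_cov_weight = 0.30,    # covariate share of the EEA deviation
    eea_cov_mix = c(age = 0.35, sex = 0.15, fd = -0.92),
    # remaining DDM parameters: population mean / sd / bounds per condition
    param_pop = list(
      a = list(mean = c(1.1, 1.3), sd = c(0.15, 0.20), lower = 0.5,
               upper = 3),
      t0 = list(mean = c(0.35, 0.38), sd = c(0.05, 0.05), lower = 0.15,
                upper = 0.8),
      st0 = list(mean = c(0.15, 0.15), sd = c(0.05, 0.05), lower = 0.02,
                 upper = 0.5),
      z = list(mean = c(0.5, 0.5), sd = c(0.04, 0.04), lower = 0.25,
               upper = 0.75),
      p_contam = list(mean = c(0.04, 0.04), sd = c(0.03, 0.03), lower = 0,
                      upper = 0.3)),
    # clusters and covariates
    n_sites = n_sites,
    family_size_probs = c(`1` = 0.8, `2` = 0.2),
    age_range = c(9, 11),
    raceeth_probs = c(0.5, 0.2, 0.2, 0.1),
    fd_meanlog = log(0.20), fd_sdlog = 0.5,
    # activation model
    activation = activation,
    parcels_per_network = c(VIS = 60, SMN = 60, DAN = 55, VAN = 55,
                            LIM = 30, FPN = 70, DMN = 70),
    sigma_net = 0.5,
    sigma_parcel = 0.5,
    act_site_frac = 0.10,
    act_family_frac = 0.15,
    act_cov_effect = 0.30,    # nuisance effect size, units of sigma_net
    act_cov_mix = c(age = 0.25, sex = 0.10, fd = 0.96))
  class(spec) <- "population_spec"
  validate_population_spec(spec)
  spec
}

validate_population_spec <- function(spec) {
  act <- spec$activation
  stopifnot(identical(act$network, YEO7))
  if (any(abs(act$r_0back) >= 1) || any(abs(act$r_2back) >= 1))
    stop("planted correlations must lie in (-1, 1)")
  s2 <- spec$act_site_frac^2
  f2 <- spec$act_family_frac^2
  g2 <- act$rho_cross - act$r_0back * act$r_2back - s2 - f2
  if (any(g2 < 0))
    stop("infeasible activation covariance: rho_cross too small for the ",
         "planted correlations and cluster components")
  for (cc in c("r_0back", "r_2back")) {
    h2 <- 1 - act[[cc]]^2 - g2 - s2 - f2
    if (any(h2 < 0))
      stop("infeasible activation covariance: planted ", cc,
           " incompatible with rho_cross (unit variance exceeded)")
  }
  fe2 <- spec$eea_family_frac^2 + spec$eea_site_frac^2
  rho_ind <- (spec$rho_eea - fe2) / (1 - fe2)
  if (rho_ind <= -1 || rho_ind >= 1)
    stop("infeasible EEA correlation given family/site components")
  invisible(spec)
}

#' Build the canonical n-back task schedule
#'
#' Per load condition: 8 blocks of 10 trials, each block containing exactly 2
#' target trials and 2 or 3 lure trials (chosen uniformly at random), the
#' remainder novel, with trial order randomized within block.  80 trials per
#' condition in total.
#'
#' @param seed optional integer seed.
#' @return data frame: `condition` (0/2), `block_index` (0-7),
#'   `stimulus_class`.
#' @export
build_task_schedule <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (cond in c(0L, 2L)) {
    for (b in 0:7) {
      n_lure <- sample(2:3, 1)
      cls <- sample(c(rep("target", 2), rep("lure", n_lure),
                      rep("novel", 10 - 2 - n_lure)))
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, block_index = b, stimulus_class = cls,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate covariates and the site/family cluster design
#'
#' Assigns each subject to a site and a family nested within site (family
#' sizes drawn from `spec$family_size_probs`), and draws age, sex, a 4-level
#' race/ethnicity code, and framewise displacement (lognormal), with squared
#' terms derived.
#'
#' @param spec a [population_spec()].
#' @param seed optional integer seed.
#' @return data frame: `subject_id`, `site`, `family`, `age`, `age2`, `sex`,
#'   `raceeth`, `fd`, `fd2`.
#' @export
generate_covariates_and_clusters <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_subjects
  size_opts <- as.integer(names(spec$family_size_probs))
  sizes <- integer(0)
  while (sum(sizes) < n) {
    draw <- size_opts[sample.int(length(size_opts), 64, replace = TRUE,
                                 prob = spec$family_size_probs)]
    sizes <- c(sizes, draw)
  }
  cum <- cumsum(sizes)
  k <- which(cum >= n)[1]
  sizes <- sizes[seq_len(k)]
  sizes[k] <- sizes[k] - (cum[k] - n)
  family <- rep(seq_along(sizes), sizes)
  site <- 1L + (family - 1L) %% spec$n_sites
  data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    site = sprintf("site%02d", site),
    family = sprintf("fam%05d", family),
    age = runif(n, spec$age_range[1], spec$age_range[2]),
    sex = sample(c("F", "M"), n, replace = TRUE),
    raceeth = sample(paste0("grp", 1:4), n, replace = TRUE,
                     prob = spec$raceeth_probs),
    fd = exp(rnorm(n, spec$fd_meanlog, spec$fd_sdlog)),
    stringsAsFactors = FALSE) -> cov
  cov$age2 <- cov$age^2
  cov$fd2 <- cov$fd^2
  cov[, c("subject_id", "site", "family", "age", "age2", "sex", "raceeth",
          "fd", "fd2")]
}

std <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# standardized covariate index from mixing weights on (age, sex, log fd)
covariate_index <- function(covariates, mix) {
  raw <- mix[["age"]] * std(covariates$age) +
    mix[["sex"]] * std(as.numeric(covariates$sex == "M")) +
    mix[["fd"]] * std(log(covariates$fd))
  std(raw)
}

truncnorm_draw <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd); pup <- pnorm(upper, mean, sd)
  qnorm(plo + (pup - plo) * runif(n), mean, sd)
}

#' Sample per-subject DDM parameters (behavioral ground truth)
#'
#' Draws each subject's 16 DDM parameters from the population model: class
#' drifts share a per-condition latent EEA deviation (with cross-condition
#' correlation, family/site components, and a covariate channel); remaining
#' parameters are independent truncated normals.  True EEA per condition is
#' the mean of the three class drifts.
#'
#' @param spec a [population_spec()].
#' @param covariates output of [generate_covariates_and_clusters()]; generated
#'   internally when `NULL`.
#' @param seed optional integer seed.
#' @return data frame (ground truth): cluster IDs, the 16 parameters, true
#'   EEA per condition and mean, and `eea_latent_z`, the standardized
#'   covariate-free latent EEA used to plant activation correlations.
#' @export
sample_population_parameters <- function(spec, covariates = NULL,
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(covariates))
    covariates <- generate_covariates_and_clusters(spec)
  n <- nrow(covariates)
  fe <- spec$eea_family_frac; se <- spec$eea_site_frac
  shared2 <- fe^2 + se^2
  rho_ind <- (spec$rho_eea - shared2) / (1 - shared2)
  z1 <- rnorm(n); z2 <- rnorm(n)
  ind0 <- z1
  ind2 <- rho_ind * z1 + sqrt(1 - rho_ind^2) * z2
  fam_eff <- rnorm(length(unique(covariates$family)))
  names(fam_eff) <- unique(covariates$family)
  site_eff <- rnorm(length(unique(covariates$site)))
  names(site_eff) <- unique(covariates$site)
  base <- fe * fam_eff[covariates$family] + se * site_eff[covariates$site]
  delta0 <- sqrt(1 - shared2) * ind0 + base
  delta2 <- sqrt(1 - shared2) * ind2 + base
  wc <- spec$eea_cov_weight
  C <- covariate_index(covariates, spec$eea_cov_mix)
  d0 <- sqrt(1 - wc^2) * delta0 + wc * C
  d2 <- sqrt(1 - wc^2) * delta2 + wc * C
  truth <- covariates[, c("subject_id", "site", "family")]
  for (ci in 1:2) {
    cond <- c("0back", "2back")[ci]
    d <- if (ci == 1) d0 else d2
    cm <- spec$class_means[ci, ]
    truth[[paste0("v_target_", cond)]] <- cm[1] + spec$sigma_v * d
    truth[[paste0("v_novel_", cond)]] <- cm[2] + spec$sigma_v * d
    truth[[paste0("v_lure_", cond)]] <- cm[3] + spec$sigma_v * d
    for (p in names(spec$param_pop)) {
      pp <- spec$param_pop[[p]]
      truth[[paste0(p, "_", cond)]] <-
        truncnorm_draw(n, pp$mean[ci], pp$sd[ci], pp$lower, pp$upper)
    }
    truth[[paste0("eea_", cond)]] <- mean(cm) + spec$sigma_v * d
  }
  truth$eea_mean <- (truth$eea_0back + truth$eea_2back) / 2
  truth$eea_latent_z <- (delta0 + delta2) / sqrt(2 + 2 * spec$rho_eea)
  truth
}

#' Generate parcel-level activation matrices
#'
#' Per subject and parcel, activation is a network baseline plus a planted
#' EEA component (via the standardized latent EEA), a shared "general
#' activation" factor inducing the cross-condition correlation, site and
#' family random effects, a nuisance-covariate effect, and parcel-level
#' noise.  The load-contrast matrix is the elementwise 2-back minus 0-back
#' difference; the general-activation, site, and family components cancel in
#' it by construction (they are shared across conditions).
#'
#' @param truth output of [sample_population_parameters()].
#' @param spec a [population_spec()].
#' @param covariates matching covariate table.
#' @param seed optional integer seed.
#' @return list of class `"activation_set"`: matrices `act_0back`,
#'   `act_2back`, `act_load` (subjects x parcels, dimnames set) and `labels`
#'   (`parcel_id`, `network`).
#' @export
generate_activation_maps <- function(truth, spec, covariates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_population_spec(spec)
  n <- nrow(truth)
  act <- spec$activation
  s <- spec$act_site_frac; f <- spec$act_family_frac
  g <- sqrt(act$rho_cross - act$r_0back * act$r_2back - s^2 - f^2)
  zE <- truth$eea_latent_z
  G <- rnorm(n)
  site_eff <- rnorm(length(unique(truth$site)))
  names(site_eff) <- unique(truth$site)
  fam_eff <- rnorm(length(unique(truth$family)))
  names(fam_eff) <- unique(truth$family)
  Sv <- site_eff[truth$site]; Fv <- fam_eff[truth$family]
  Cact <- covariate_index(covariates, spec$act_cov_mix)
  ppn <- spec$parcels_per_network[YEO7]
  P <- sum(ppn)
  labels <- data.frame(parcel_id = sprintf("p%03d", seq_len(P)),
                       network = rep(YEO7, ppn), stringsAsFactors = FALSE)
  mats <- list()
  for (ci in 1:2) {
    cond <- c("0back", "2back")[ci]
    r <- if (ci == 1) act$r_0back else act$r_2back
    mu <- if (ci == 1) act$mu_0back else act$mu_2back
    h <- sqrt(1 - r^2 - g^2 - s^2 - f^2)
    M <- matrix(0, n, P, dimnames = list(truth$subject_id, labels$parcel_id))
    col <- 0L
    for (k in seq_along(YEO7)) {
      u <- r[k] * zE + g[k] * G + s * Sv + f * Fv + h[k] * rnorm(n)
      signal <- mu[k] + spec$act_cov_effect * spec$sigma_net * Cact +
        spec$sigma_net * u
      cols <- (col + 1L):(col + ppn[k])
      M[, cols] <- signal +
        matrix(rnorm(n * ppn[k], sd = spec$sigma_parcel), n, ppn[k])
      col <- col + ppn[k]
    }
    mats[[paste0("act_", cond)]] <- M
  }
  mats$act_load <- mats$act_2back - mats$act_0back
  mats$labels <- labels
  class(mats) <- "activation_set"
  mats
}

#' Simulate behavioral trial tables for a ground-truth cohort
#'
#' Builds a task schedule per subject ([build_task_schedule()]) and simulates
#' each subject's trials from their true DDM parameters
#' ([simulate_trials()]).
#'
#' @param truth output of [sample_population_parameters()].
#' @param seed optional integer seed.
#' @param dt Euler step for the diffusion simulation (1e-3 is ample for bulk
#'   cohort synthesis; oracles use 1e-4).
#' @return data frame of trials across subjects (column `subject_id` first).
#' @export
generate_cohort_behavior <- function(truth, seed = NULL, dt = 1e-3) {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    params <- structure(as.numeric(truth[i, PAR_NAMES_16]),
                        names = PAR_NAMES_16,
                        class = c("ddm_parameters", "numeric"))
    sched <- build_task_schedule()
    tt <- simulate_trials(params, sched, dt = dt)
    tt <- cbind(subject_id = truth$subject_id[i], tt,
                stringsAsFactors = FALSE)
    out[[i]] <- tt
  }
  do.call(rbind, out)
}

#' Simulate a complete synthetic cohort
#'
#' Orchestrates the generator: covariates and clusters, behavioral ground
#' truth, activation maps, and (optionally) simulated trial tables.
#'
#' @param spec a [population_spec()].
#' @param seed integer seed for the whole cohort.
#' @param behavior also simulate the per-trial behavioral data (slow for
#'   large cohorts; the activation analyses only need the ground truth).
#' @param dt Euler step for behavioral simulation.
#' @return list of class `"eea_cohort"`: `covariates`, `truth`, `activation`,
#'   and `trials` (when `behavior = TRUE`).
#' @export
simulate_cohort <- function(spec, seed = 1, behavior = FALSE, dt = 1e-3) {
  set.seed(as.integer(seed))
  covariates <- generate_covariates_and_clusters(spec)
  truth <- sample_population_parameters(spec, covariates)
  activation <- generate_activation_maps(truth, spec, covariates)
  out <- list(covariates = covariates, truth = truth,
              activation = activation, spec = spec, seed = seed)
  if (behavior) out$trials <- generate_cohort_behavior(truth, dt = dt)
  class(out) <- "eea_cohort"
  out
}

#' Implied population R-squared of the load-contrast activation for EEA
#'
#' Closed-form multiple R-squared of the standardized latent EEA on the seven
#' network load-contrast (2-0) signals implied by a population specification,
#' including the attenuation from finite parcels per network.  Useful for
#' calibrating planted effect sizes to a target predictive ceiling.
#'
#' @param spec a [population_spec()].
#' @return scalar R-squared in `[0, 1)`.
#' @export
implied_load_r2 <- function(spec) {
  act <- spec$activation
  b <- act$r_2back - act$r_0back
  m <- spec$parcels_per_network[YEO7]
  noise_add <- 2 * spec$sigma_parcel^2 / (m * spec$sigma_net^2)
  delta <- (2 - 2 * act$rho_cross) - b^2 + noise_add
  t <- sum(b^2 / delta)
  t / (1 + t)
}

#' Rescale planted correlations to a target population R-squared
#'
#' Multiplies every planted network-EEA correlation by a common factor chosen
#' so that [implied_load_r2()] equals `target`, keeping the planted
#' cross-condition correlations fixed.  Errors if no feasible factor exists.
#'
#' @param spec a [population_spec()].
#' @param target desired population R-squared of the load contrast for EEA.
#' @return the rescaled `population_spec`.
#' @export
calibrate_activation_r2 <- function(spec, target = 0.36) {
  f <- function(phi) {
    s2 <- spec
    s2$activation$r_0back <- phi * spec$activation$r_0back
    s2$activation$r_2back <- phi * spec$activation$r_2back
    implied_load_r2(s2) - target
  }
  # upper feasibility limit for the common factor
  phi_hi <- 3
  while (phi_hi > 1e-3) {
    ok <- tryCatch({
      s2 <- spec
      s2$activation$r_0back <- phi_hi * spec$activation$r_0back
      s2$activation$r_2back <- phi_hi * spec$activation$r_2back
      validate_population_spec(s2)
      TRUE
    }, error = function(e) FALSE)
    if (ok) break
    phi_hi <- phi_hi * 0.95
  }
  if (f(phi_hi) < 0)
    stop("target R-squared is not attainable under this specification")
  phi <- stats::uniroot(f, c(1e-6, phi_hi), tol = 1e-8)$root
  spec$activation$r_0back <- phi * spec$activation$r_0back
  spec$activation$r_2back <- phi * spec$activation$r_2back
  validate_population_spec(spec)
  spec
}

#' Simulate clustered bivariate data with known population correlation
#'
#' Draws (x, y) pairs sharing site and family random components (inducing
#' intra-cluster correlation in each variable and a known between-variable
#' correlation), for calibrating clustered inference procedures.  The
#' population correlation equals `rho` exactly.
#'
#' @param n_sites,families_per_site,family_size balanced cluster design.
#' @param site_sd,family_sd SD of the shared site and family components (the
#'   residual SD is chosen so both variables have unit variance).
#' @param rho target population correlation between x and y.
#' @param seed optional integer seed.
#' @return data frame `x`, `y`, `site`, `family` with attribute `"rho"`.
#' @export
simulate_clustered_bivariate <- function(n_sites = 30, families_per_site = 5,
                                         family_size = 2, site_sd = 0.3,
                                         family_sd = 0.3, rho = 0.3,
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_sites * families_per_site * family_size
  site <- rep(seq_len(n_sites), each = families_per_site * family_size)
  family <- rep(seq_len(n_sites * families_per_site), each = family_size)
  e2 <- 1 - site_sd^2 - family_sd^2
  if (e2 <= 0) stop("site and family SDs exceed unit variance")
  rho0 <- (rho - site_sd^2 - family_sd^2) / e2
  if (abs(rho0) >= 1)
    stop("target rho infeasible given the shared cluster components")
  sx <- rnorm(n_sites)[site]
  fx <- rnorm(n_sites * families_per_site)[family]
  ex <- rnorm(n)
  ey <- rho0 * ex + sqrt(1 - rho0^2) * rnorm(n)
  out <- data.frame(x = site_sd * sx + family_sd * fx + sqrt(e2) * ex,
                    y = site_sd * sx + family_sd * fx + sqrt(e2) * ey,
                    site = sprintf("site%02d", site),
                    family = sprintf("fam%04d", family),
                    stringsAsFactors = FALSE)
  attr(out, "rho") <- rho
  out
}

#' Simulate a covariate-confounded null cohort
#'
#' Outcome and features both depend on the same nuisance covariates but are
#' conditionally independent given them: the calibration target for the
#' cross-validated partial correlation (its mean out-of-fold value should be
#' zero).
#'
#' @param n subjects.
#' @param n_features feature (parcel) count.
#' @param seed optional integer seed.
#' @param strength covariate effect size on the outcome and features.
#' @return list: `X` (n x n_features), `y`, `covariates`.
#' @export
simulate_confounded_null <- function(n = 500, n_features = 100, seed = NULL,
                                     strength = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  spec <- population_spec(n_subjects = n)
  covariates <- generate_covariates_and_clusters(spec)
  C <- covariate_index(covariates, c(age = 0.4, sex = 0.2, fd = 0.89))
  y <- strength * C + sqrt(1 - strength^2) * rnorm(n)
  gam <- rnorm(n_features, 0.4, 0.15)
  X <- outer(C, gam) + matrix(rnorm(n * n_features), n, n_features)
  dimnames(X) <- list(covariates$subject_id,
                      sprintf("p%03d", seq_len(n_features)))
  list(X = X, y = y, covariates = covariates)
}
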