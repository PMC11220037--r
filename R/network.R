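#' Network-mean activation extraction
#'
#' Per subject and network, the unweighted mean of activation over the
#' network's member features (parcels or vertices), for one contrast.
#'
#' @param activation subjects x features matrix with feature column names.
#' @param labels data frame `parcel_id`, `network` covering every feature.
#' @return subjects x networks matrix (columns in Yeo-7 order where present).
#' @export
extract_network_means <- function(activation, labels) {
  activation <- as.matrix(activation)
  ids <- colnames(activation)
  if (is.null(ids)) stop("activation matrix must have feature column names")
  net <- labels$network[match(ids, labels$parcel_id)]
  if (anyNA(net))
    stop("unlabeled features: ",
         paste(head(ids[is.na(net)], 5), collapse = ", "))
  nets <- intersect(YEO7, unique(net))
  if (!length(nets)) nets <- sort(unique(net))
  out <- vapply(nets, function(nw)
    rowMeans(activation[, net == nw, drop = FALSE]), numeric(nrow(activation)))
  if (is.null(dim(out)))
    out <- matrix(out, nrow = 1, dimnames = list(NULL, nets))
  rownames(out) <- rownames(activation)
  out
}

#' Residualize variables on the nuisance covariates
#'
#' OLS residuals of each column on intercept + age, age squared, sex,
#' race/ethnicity dummies, FD, and FD squared.  Rows with missing values are
#' dropped (complete-case) with a message.
#'
#' @param variables numeric vector, matrix, or data frame of variables.
#' @param covariates covariate table ([covariate_design()] columns).
#' @return residual matrix with the same column names (complete cases only;
#'   kept row indices in attribute `"rows"`).
#' @export
residualize_on_covariates <- function(variables, covariates) {
  V <- as.matrix(variables)
  D <- covariate_design(covariates)
  ok <- complete.cases(V) & complete.cases(D)
  if (!all(ok)) message("dropping ", sum(!ok), " incomplete rows")
  V <- V[ok, , drop = FALSE]
  dq <- design_qr(D[ok, , drop = FALSE])
  res <- qr.resid(dq$qr, V)
  attr(res, "rows") <- which(ok)
  res
}

#' Z-score a vector (mean 0, SD 1)
#'
#' @param x numeric vector.
#' @return standardized vector.
#' @export
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant")
  (x - mean(x)) / s
}

# cluster resample: sites with replacement; with two-stage resampling,
# families are additionally resampled within each drawn site; returns row
# indices
resample_clusters <- function(cl, two_stage = FALSE) {
  sites <- sample.int(cl$n_sites, cl$n_sites, replace = TRUE)
  idx_list <- lapply(sites, function(s) {
    fams <- cl$site_fams[[s]]
    if (two_stage)
      fams <- fams[sample.int(length(fams), length(fams), replace = TRUE)]
    unlist(cl$fam_rows[fams], use.names = FALSE)
  })
  unlist(idx_list, use.names = FALSE)
}

cluster_index <- function(site, family) {
  key <- paste(site, family, sep = "\r")
  fam_rows <- split(seq_along(key), key)
  fam_site <- vapply(strsplit(names(fam_rows), "\r", fixed = TRUE),
                     `[`, "", 1L)
  usite <- unique(fam_site)
  site_fams <- lapply(usite, function(s) which(fam_site == s))
  list(n_sites = length(usite), site_fams = site_fams, fam_rows = fam_rows)
}

cluster_boot <- function(stat_fn, site, family, n_boot, seed = NULL,
                         two_stage = FALSE, max_redraw_frac = 0.01) {
  if (!is.null(seed)) set.seed(seed)
  cl <- cluster_index(site, family)
  if (cl$n_sites < 2 && length(unique(family)) < 2)
    stop("clustered bootstrap needs at least 2 clusters")
  reps <- numeric(n_boot)
  redraws <- 0L
  max_redraws <- max(1, ceiling(max_redraw_frac * n_boot))
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- resample_clusters(cl, two_stage)
      val <- stat_fn(idx)
      if (is.finite(val)) break
      redraws <- redraws + 1L
      if (redraws > max_redraws)
        stop("more than ", 100 * max_redraw_frac,
             "% of bootstrap replicates were degenerate")
    }
    reps[b] <- val
  }
  attr(reps, "redraws") <- redraws
  reps
}

boot_ci <- function(estimate, reps, level, n_boot, scheme) {
  alpha <- (1 - level) / 2
  qs <- quantile(reps, probs = c(alpha, 1 - alpha), names = FALSE)
  structure(list(estimate = estimate, lower = qs[1], upper = qs[2],
                 level = level, n_boot = n_boot, scheme = scheme,
                 replicates = reps),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("%.3f [%.3f, %.3f] (%d%% CI, %d %s bootstrap replicates)\n",
              x$estimate, x$lower, x$upper, round(100 * x$level), x$n_boot,
              x$scheme))
  invisible(x)
}

#' Clustered bootstrap confidence interval for a Pearson correlation
#'
#' Cluster bootstrap honoring nesting of families within sites.  The default
#' scheme (`stages = "site"`) resamples sites with replacement and keeps each
#' drawn site's families (hence members) intact — the standard consistent
#' scheme for nested data, which respects both cluster levels because whole
#' families always travel with their site.  `stages = "site-family"`
#' additionally resamples families within each drawn site (a two-stage
#' variant, available for sensitivity analyses; it systematically widens the
#' intervals).  The CI is the percentile interval of the correlation across
#' replicates.  Replicates with zero variance in either variable are redrawn
#' (an error is raised if more than 1% of replicates degenerate).
#'
#' @param x,y numeric vectors (n >= 10).
#' @param site,family cluster identifiers per subject.
#' @param n_boot bootstrap replicates (default 2000).
#' @param level confidence level (default 0.95).
#' @param seed optional integer seed.
#' @param stages `"site"` (default) or `"site-family"`.
#' @return object of class `"bootstrap_ci"`.
#' @export
clustered_bootstrap_ci <- function(x, y, site, family, n_boot = 2000,
                                   level = 0.95, seed = NULL,
                                   stages = c("site", "site-family")) {
  stages <- match.arg(stages)
  n <- length(x)
  stopifnot(length(y) == n, length(site) == n, length(family) == n)
  if (n < 10) stop("need at least 10 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("correlation undefined for constant input")
  est <- cor(x, y)
  stat <- function(idx) {
    if (sd(x[idx]) == 0 || sd(y[idx]) == 0) return(NA_real_)
    cor(x[idx], y[idx])
  }
  reps <- cluster_boot(stat, site, family, n_boot, seed,
                       two_stage = stages == "site-family")
  boot_ci(est, reps, level, n_boot, paste0("clustered (", stages, ")"))
}

#' Clustered bootstrap CI for a difference of absolute correlations
#'
#' Within each clustered bootstrap replicate (shared resample), computes
#' `|cor(x1, y)| - |cor(x2, y)|`; the CI is the percentile interval of that
#' difference.  Used to compare the strength of two predictors of the same
#' outcome (e.g., the load contrast versus a single-condition activation).
#'
#' @param x1,x2 the two predictors.
#' @param y shared outcome.
#' @inheritParams clustered_bootstrap_ci
#' @return object of class `"bootstrap_ci"`.
#' @export
bootstrap_diff_ci <- function(x1, y, x2, site, family, n_boot = 2000,
                              level = 0.95, seed = NULL,
                              stages = c("site", "site-family")) {
  stages <- match.arg(stages)
  n <- length(y)
  stopifnot(length(x1) == n, length(x2) == n)
  est <- abs(cor(x1, y)) - abs(cor(x2, y))
  stat <- function(idx) {
    if (sd(x1[idx]) == 0 || sd(x2[idx]) == 0 || sd(y[idx]) == 0)
      return(NA_real_)
    abs(cor(x1[idx], y[idx])) - abs(cor(x2[idx], y[idx]))
  }
  reps <- cluster_boot(stat, site, family, n_boot, seed,
                       two_stage = stages == "site-family")
  boot_ci(est, reps, level, n_boot, paste0("clustered (", stages, ")"))
}

#' Compare subset and full network regression models
#'
#' Fits OLS of (residualized) EEA on a subset of network load-contrast means
#' and on all networks, reporting for each the correlation between observed
#' and model-fitted EEA with a clustered bootstrap CI (the model is refitted
#' within every replicate).
#'
#' @param network_means subjects x networks matrix (residualized load
#'   contrast).
#' @param eea residualized EEA vector.
#' @param subset network names for the reduced model (default FPN, DAN, SMN).
#' @param site,family cluster identifiers.
#' @param n_boot,level,seed bootstrap settings.
#' @return list with `bootstrap_ci` elements `subset` and `full`, plus the
#'   network names used.
#' @export
network_regression_compare <- function(network_means, eea,
                                       subset = c("FPN", "DAN", "SMN"),
                                       site, family, n_boot = 2000,
                                       level = 0.95, seed = NULL,
                                       stages = c("site", "site-family")) {
  stages <- match.arg(stages)
  two_stage <- stages == "site-family"
  network_means <- as.matrix(network_means)
  if (!all(subset %in% colnames(network_means)))
    stop("subset networks absent from the network-mean matrix: ",
         paste(setdiff(subset, colnames(network_means)), collapse = ", "))
  fit_r <- function(cols, idx) {
    Xs <- cbind(1, network_means[idx, cols, drop = FALSE])
    ys <- eea[idx]
    ft <- lm.fit(Xs, ys)
    fv <- ys - ft$residuals
    if (sd(fv) == 0 || sd(ys) == 0) return(NA_real_)
    cor(fv, ys)
  }
  all_idx <- seq_along(eea)
  est_sub <- fit_r(subset, all_idx)
  est_full <- fit_r(colnames(network_means), all_idx)
  if (!is.null(seed)) set.seed(seed)
  reps_sub <- cluster_boot(function(idx) fit_r(subset, idx),
                           site, family, n_boot, two_stage = two_stage)
  reps_full <- cluster_boot(function(idx) fit_r(colnames(network_means), idx),
                            site, family, n_boot, two_stage = two_stage)
  scheme <- paste0("clustered (", stages, ")")
  list(subset = boot_ci(est_sub, reps_sub, level, n_boot, scheme),
       full = boot_ci(est_full, reps_full, level, n_boot, scheme),
       subset_networks = subset,
       full_networks = colnames(network_means))
}

#' Decile-bin summary of network activation by EEA rank
#'
#' Ranks subjects by (covariate-adjusted) EEA, splits them into `n_bins`
#' near-equal ordered bins (any remainder spread over the lowest bins), and
#' reports each bin's mean activation with a normal-theory 95% CI per
#' activation column, plus the OLS slope of bin means on bin rank.
#'
#' @param eea ranking variable.
#' @param activation matrix or data frame of activation columns (e.g., FPN
#'   0-back, FPN 2-back).
#' @param n_bins number of bins (default 10).
#' @param level CI level for the bin means.
#' @return list: `bins` (bin x column means and CIs), `slopes` (per column).
#' @export
decile_bin_summary <- function(eea, activation, n_bins = 10, level = 0.95) {
  A <- as.matrix(activation)
  n <- length(eea)
  if (n < 10) stop("need at least 10 subjects")
  stopifnot(nrow(A) == n)
  ord <- order(eea)
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1, extra), rep(0, n_bins - extra))
  bin <- integer(n)
  bin[ord] <- rep(seq_len(n_bins), sizes)
  zc <- qnorm(1 - (1 - level) / 2)
  rows <- list()
  for (b in seq_len(n_bins)) {
    sel <- bin == b
    for (j in seq_len(ncol(A))) {
      v <- A[sel, j]
      se <- sd(v) / sqrt(length(v))
      rows[[length(rows) + 1L]] <- data.frame(
        bin = b, variable = colnames(A)[j], mean = mean(v),
        ci_lo = mean(v) - zc * se, ci_hi = mean(v) + zc * se,
        n = length(v), stringsAsFactors = FALSE)
    }
  }
  bins <- do.call(rbind, rows)
  slopes <- vapply(colnames(A), function(cn) {
    bm <- bins$mean[bins$variable == cn]
    coef(lm(bm ~ seq_len(n_bins)))[2]
  }, 0)
  names(slopes) <- colnames(A)
  list(bins = bins, slopes = slopes, bin_assignment = bin)
}

#' Quadrant summary of 0-back vs 2-back activation and EEA
#'
#' Z-scores the three inputs, fits the OLS regression of 2-back on 0-back
#' activation, and splits subjects into four quadrants: above/below the
#' regression line crossed with 0-back activation above/below its mean (zero
#' after z-scoring).  Subjects above the line have higher 2-back activation
#' than expected from their 0-back activation.  Reports mean z-scored EEA and
#' count per quadrant.
#'
#' @param act_0back,act_2back network activation per subject (residualized).
#' @param eea EEA per subject (residualized).
#' @return list: `quadrants` (quadrant, mean_eea_z, n), `slope`, `intercept`,
#'   `assignment` (per-subject quadrant label).
#' @export
quadrant_summary <- function(act_0back, act_2back, eea) {
  n <- length(eea)
  if (n < 4) stop("need at least 4 subjects")
  x0 <- zscore(act_0back); x2 <- zscore(act_2back); ez <- zscore(eea)
  fit <- lm(x2 ~ x0)
  above <- unname(x2 > fitted(fit))
  right <- x0 > 0
  quad <- ifelse(above & !right, "upper_left",
                 ifelse(above & right, "upper_right",
                        ifelse(!above & !right, "lower_left", "lower_right")))
  qs <- c("upper_left", "upper_right", "lower_left", "lower_right")
  rows <- lapply(qs, function(q) {
    sel <- quad == q
    data.frame(quadrant = q,
               mean_eea_z = if (any(sel)) mean(ez[sel]) else NA_real_,
               n = sum(sel), stringsAsFactors = FALSE)
  })
  list(quadrants = do.call(rbind, rows),
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       assignment = quad)
}
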