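#' Build the nuisance-covariate design matrix
#'
#' Intercept + age, age squared, sex, dummy-coded race/ethnicity, framewise
#' displacement, and framewise displacement squared.  Collinear columns are
#' dropped with a warning downstream (rank-revealing QR).
#'
#' @param covariates data frame with columns `age`, `age2`, `sex`, `raceeth`,
#'   `fd`, `fd2`.
#' @return numeric design matrix (n x p) including the intercept column.
#' @export
covariate_design <- function(covariates) {
  need <- c("age", "age2", "sex", "raceeth", "fd", "fd2")
  miss <- setdiff(need, names(covariates))
  if (length(miss))
    stop("covariate table lacks columns: ", paste(miss, collapse = ", "))
  df <- covariates[, need]
  df$sex <- factor(df$sex)
  df$raceeth <- factor(df$raceeth)
  model.matrix(~ age + age2 + sex + raceeth + fd + fd2, data = df)
}

# rank-revealing QR of the design; returns object for coef/resid computation
design_qr <- function(D) {
  qrd <- qr(D)
  if (qrd$rank < ncol(D)) {
    drop <- colnames(D)[qrd$pivot[(qrd$rank + 1):ncol(D)]]
    warning("dropping collinear covariate columns: ",
            paste(drop, collapse = ", "))
    D <- D[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
    qrd <- qr(D)
  }
  list(qr = qrd, columns = colnames(D))
}

design_coef <- function(dq, Y) {
  B <- qr.coef(dq$qr, as.matrix(Y))
  B[is.na(B)] <- 0
  B
}

#' Cross-validation fold assignment
#'
#' Leave-one-site-out (`"loso"`: one fold per site) or k-fold with family
#' members kept in the same fold (families are assigned whole, greedily
#' balancing subject counts; deterministic under `seed`).
#'
#' @param cohort data frame with `subject_id` and cluster columns `site`,
#'   `family` (family required for k-fold, site for LOSO).
#' @param scheme `"loso"` or `"kfold"`.
#' @param k number of folds for `"kfold"`.
#' @param seed optional integer seed (k-fold tie-breaking).
#' @param min_site_warn warn when a LOSO fold has fewer subjects than this.
#' @return data frame `subject_id`, `fold` (character), with attribute
#'   `scheme`.
#' @export
make_folds <- function(cohort, scheme = c("loso", "kfold"), k = 10,
                       seed = NULL, min_site_warn = 10) {
  scheme <- match.arg(scheme)
  if (scheme == "loso") {
    if (!"site" %in% names(cohort)) stop("LOSO needs a 'site' column")
    fold <- as.character(cohort$site)
    small <- names(which(table(fold) < min_site_warn))
    if (length(small))
      warning("LOSO folds with fewer than ", min_site_warn, " subjects: ",
              paste(small, collapse = ", "))
  } else {
    if (!"family" %in% names(cohort)) stop("k-fold needs a 'family' column")
    if (!is.null(seed)) set.seed(seed)
    fams <- table(cohort$family)
    ord <- order(-as.numeric(fams), sample.int(length(fams)))
    sizes <- numeric(k)
    assign <- integer(length(fams))
    names(assign) <- names(fams)[ord]
    for (i in seq_along(ord)) {
      j <- which.min(sizes)
      assign[i] <- j
      sizes[j] <- sizes[j] + as.numeric(fams[ord[i]])
    }
    fold <- sprintf("fold%02d", assign[cohort$family])
  }
  out <- data.frame(subject_id = cohort$subject_id, fold = fold,
                    stringsAsFactors = FALSE)
  attr(out, "scheme") <- scheme
  out
}

#' Fit one training-fold principal-components-regression model
#'
#' Centers features on training means, extracts `K` principal components,
#' regresses each component expression and the outcome on the nuisance
#' design, and fits OLS of the residualized outcome on the residualized
#' component expressions.  Component loadings are orthonormal.
#'
#' @param X training feature matrix (subjects x features).
#' @param y training outcome.
#' @param design training nuisance design matrix ([covariate_design()]), or
#'   `NULL` for no covariates (intercept only).
#' @param K number of components (<= rank of `X` after centering).
#' @return list of class `"pcr_fold_model"`: centering vector, loadings,
#'   nuisance betas for components and outcome, prediction weights.
#' @export
fit_pcr_fold <- function(X, y, design, K) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(design)) design <- matrix(1, n, 1,
                                        dimnames = list(NULL, "(Intercept)"))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (K > rank) stop("K exceeds the rank of the centered training matrix")
  V <- sv$v[, seq_len(K), drop = FALSE]
  scores <- sv$u[, seq_len(K), drop = FALSE] %*% diag(sv$d[seq_len(K)], K)
  dq <- design_qr(design)
  B_scores <- design_coef(dq, scores)
  b_y <- design_coef(dq, y)
  D <- design[, dq$columns, drop = FALSE]
  rs <- scores - D %*% B_scores
  ry <- as.numeric(y - D %*% b_y)
  fit <- lm.fit(cbind(1, rs), ry)
  w <- coef(fit)
  w[is.na(w)] <- 0
  structure(list(mu = mu, loadings = V, K = K, B_scores = B_scores,
                 b_y = b_y, weights = w, design_columns = dq$columns,
                 feature_ids = colnames(X)),
            class = "pcr_fold_model")
}

#' Apply a PCR fold model to held-out data
#'
#' Projects test rows (centered on training means) onto the training
#' loadings, residualizes test component expressions and outcome with the
#' training betas, applies the prediction weights, and returns the
#' out-of-sample partial correlation between predictions and the
#' residualized outcome.
#'
#' @param model a [fit_pcr_fold()] result.
#' @param X,y,design test-fold data (feature columns must match training).
#' @return list: `r` (fold partial correlation, `NA` with a warning for
#'   folds of fewer than 3 subjects), `predicted`, `y_residualized`.
#' @export
predict_and_correlate <- function(model, X, y, design) {
  X <- as.matrix(X)
  if (!is.null(model$feature_ids) && !is.null(colnames(X)) &&
      !identical(colnames(X), model$feature_ids))
    stop("test feature columns do not match the training features")
  n <- nrow(X)
  if (is.null(design)) design <- matrix(1, n, 1,
                                        dimnames = list(NULL, "(Intercept)"))
  D <- design[, model$design_columns, drop = FALSE]
  scores <- sweep(X, 2, model$mu) %*% model$loadings
  rs <- scores - D %*% model$B_scores
  ry <- as.numeric(y - D %*% model$b_y)
  pred <- as.numeric(cbind(1, rs) %*% model$weights)
  if (n < 3) {
    warning("fold has fewer than 3 subjects; correlation undefined")
    return(list(r = NA_real_, predicted = pred, y_residualized = ry))
  }
  list(r = cor(pred, ry), predicted = pred, y_residualized = ry)
}

#' Select the number of PCR components by nested cross-validation
#'
#' For each candidate K, runs the full residualize-fit-predict procedure
#' across `n_inner` inner folds of the training data (never touching test
#' rows) and scores by the mean inner partial correlation.  Returns the
#' argmax K, ties broken toward smaller K.  Candidates exceeding the
#' training rank are dropped with a warning.
#'
#' @param X,y,design training data only.
#' @param candidates candidate K values.
#' @param n_inner number of inner folds (default 5).
#' @param families optional family IDs; inner folds then keep families whole.
#' @param seed optional integer seed for the inner split.
#' @return selected K (integer), with attribute `"scores"` (mean inner r per
#'   candidate).
#' @export
select_num_components <- function(X, y, design, candidates = NULL,
                                  n_inner = 5, families = NULL, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(candidates)) candidates <- default_k_grid(n, ncol(X), design)
  if (is.null(families)) families <- as.character(seq_len(n))
  inner <- make_folds(data.frame(subject_id = as.character(seq_len(n)),
                                 family = families,
                                 stringsAsFactors = FALSE),
                      scheme = "kfold", k = n_inner)
  folds <- sort(unique(inner$fold))
  min_rank <- min(vapply(folds, function(f)
    min(sum(inner$fold != f), ncol(X)) - 1L, 0L))
  feasible_all <- candidates[candidates <= min_rank]
  if (length(feasible_all) < length(candidates))
    warning("dropping candidate K above the inner training rank")
  if (!length(feasible_all)) stop("no feasible candidate K")
  scores <- matrix(NA_real_, n_inner, length(candidates))
  for (fi in seq_along(folds)) {
    te <- inner$fold == folds[fi]
    Xtr <- X[!te, , drop = FALSE]
    feasible <- feasible_all
    Kmax <- max(feasible)
    base <- fit_pcr_fold(Xtr, y[!te], subdesign(design, !te), Kmax)
    for (ki in seq_along(candidates)) {
      K <- candidates[ki]
      if (!K %in% feasible) next
      mk <- truncate_pcr_model(base, y[!te], subdesign(design, !te), Xtr, K)
      scores[fi, ki] <- predict_and_correlate(
        mk, X[te, , drop = FALSE], y[te], subdesign(design, te))$r
    }
  }
  mean_r <- colMeans(scores, na.rm = TRUE)
  mean_r[is.nan(mean_r)] <- -Inf
  K <- candidates[which.max(mean_r)]  # which.max takes the first (smallest K)
  attr(K, "scores") <- setNames(mean_r, candidates)
  K
}

subdesign <- function(design, idx) {
  if (is.null(design)) NULL else design[idx, , drop = FALSE]
}

# refit the final OLS step of a fold model with fewer components, reusing the
# already-computed loadings and nuisance betas
truncate_pcr_model <- function(model, y, design, X, K) {
  if (K == model$K) return(model)
  n <- nrow(as.matrix(X))
  if (is.null(design)) design <- matrix(1, n, 1,
                                        dimnames = list(NULL, "(Intercept)"))
  m <- model
  m$loadings <- model$loadings[, seq_len(K), drop = FALSE]
  m$B_scores <- model$B_scores[, seq_len(K), drop = FALSE]
  m$K <- K
  D <- design[, model$design_columns, drop = FALSE]
  scores <- sweep(as.matrix(X), 2, model$mu) %*% m$loadings
  rs <- scores - D %*% m$B_scores
  ry <- as.numeric(y - D %*% model$b_y)
  w <- coef(lm.fit(cbind(1, rs), ry))
  w[is.na(w)] <- 0
  m$weights <- w
  m
}

default_k_grid <- function(n_train, n_features, design) {
  p <- if (is.null(design)) 1L else ncol(design)
  # cap so the largest candidate stays feasible inside 5-fold inner splits
  cap <- min(as.integer(floor(0.8 * n_train)) - p - 2L, n_features - 1L)
  ks <- c(5L, 10L, 25L, 50L, 100L, 250L, cap)
  sort(unique(ks[ks >= 1L & ks <= cap]))
}

#' Run the full cross-validated PCR prediction pipeline
#'
#' Per outer fold: selects K by nested inner cross-validation on the training
#' rows, fits the PCR fold model, and scores the held-out fold by the
#' out-of-sample partial correlation.  Fold correlations are averaged
#' unweighted; every subject receives exactly one out-of-fold prediction.
#'
#' @param X activation matrix (subjects x features).
#' @param y outcome (e.g., EEA).
#' @param covariates covariate table ([covariate_design()] columns), or
#'   `NULL`.
#' @param folds a [make_folds()] assignment aligned with rows of `X`.
#' @param candidates candidate K grid (default [default_k_grid()]).
#' @param families optional family IDs for family-respecting inner folds.
#' @param seed optional integer seed.
#' @param consensus `"fold_average"` (z-scored average of per-fold feature
#'   maps) or `"none"`.
#' @return list of class `"pcr_cv"`: `fold_results` (fold, K, r, n),
#'   `mean_r`, `predictions` (per subject), `consensus`.
#' @export
run_cv_pipeline <- function(X, y, covariates, folds, candidates = NULL,
                            families = NULL, seed = NULL,
                            consensus = c("fold_average", "none")) {
  consensus <- match.arg(consensus)
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, nrow(folds) == n)
  design <- if (is.null(covariates)) NULL else covariate_design(covariates)
  fold_ids <- sort(unique(folds$fold))
  rows <- list(); preds <- vector("list", length(fold_ids))
  maps <- list(); skipped <- 0L
  for (fi in seq_along(fold_ids)) {
    te <- folds$fold == fold_ids[fi]
    if (sum(te) < 3) {
      warning("skipping fold ", fold_ids[fi], ": fewer than 3 subjects")
      skipped <- skipped + 1L
      next
    }
    Xtr <- X[!te, , drop = FALSE]
    inner_fams <- if (is.null(families)) folds$subject_id[!te]
                  else families[!te]
    K <- select_num_components(Xtr, y[!te], subdesign(design, !te),
                               candidates = candidates,
                               families = inner_fams)
    model <- fit_pcr_fold(Xtr, y[!te], subdesign(design, !te), K)
    res <- predict_and_correlate(model, X[te, , drop = FALSE], y[te],
                                 subdesign(design, te))
    rows[[length(rows) + 1L]] <- data.frame(
      fold = fold_ids[fi], K = as.integer(K), r = res$r, n = sum(te),
      stringsAsFactors = FALSE)
    preds[[fi]] <- data.frame(
      subject_id = folds$subject_id[te], fold = fold_ids[fi],
      y_residualized = res$y_residualized, y_predicted = res$predicted,
      stringsAsFactors = FALSE)
    if (consensus == "fold_average")
      maps[[length(maps) + 1L]] <- consensus_feature_map(model,
                                                         standardize = FALSE)
  }
  if (skipped > 0.2 * length(fold_ids))
    stop("more than 20% of folds were skipped")
  fold_results <- do.call(rbind, rows)
  cons <- NULL
  if (consensus == "fold_average" && length(maps)) {
    raw <- rowMeans(do.call(cbind, maps))
    cons <- zscore_map(raw, colnames(X))
  }
  structure(list(fold_results = fold_results,
                 mean_r = mean(fold_results$r, na.rm = TRUE),
                 predictions = do.call(rbind, preds),
                 consensus = cons),
            class = "pcr_cv")
}

#' @export
print.pcr_cv <- function(x, ...) {
  cat("Cross-validated PCR prediction\n")
  cat(sprintf("  folds: %d, mean out-of-fold partial r = %.3f\n",
              nrow(x$fold_results), x$mean_r))
  print(x$fold_results, row.names = FALSE)
  invisible(x)
}

#' Consensus feature map of a PCR model
#'
#' Per feature: the sum over components of loading times prediction beta —
#' the feature-space weight vector of the fitted model.  When aggregating
#' across folds, per-fold maps are computed first and averaged
#' ([run_cv_pipeline()]); the final map is z-scored (mean 0, SD 1) for
#' reporting.  A map with zero variance (all betas zero) is returned raw
#' with attribute `zscored = FALSE`.
#'
#' @param model a [fit_pcr_fold()] model, or a list of them (averaged).
#' @param standardize z-score the map (default `TRUE`).
#' @return named numeric vector, one weight per feature.
#' @export
consensus_feature_map <- function(model, standardize = TRUE) {
  if (inherits(model, "pcr_fold_model")) model <- list(model)
  maps <- lapply(model, function(m)
    as.numeric(m$loadings %*% m$weights[-1]))
  raw <- rowMeans(do.call(cbind, maps))
  ids <- model[[1]]$feature_ids
  if (!standardize) return(setNames(raw, ids))
  zscore_map(raw, ids)
}

zscore_map <- function(raw, ids) {
  if (sd(raw) < 1e-300) {
    out <- setNames(raw, ids)
    attr(out, "zscored") <- FALSE
    return(out)
  }
  out <- setNames(as.numeric(scale(raw)), ids)
  attr(out, "zscored") <- TRUE
  out
}
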