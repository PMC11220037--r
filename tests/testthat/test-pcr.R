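# Cross-validated PCR: fold construction, residualized fits, component
# selection, consensus maps, leakage guards

make_xy <- function(n = 200, p = 50, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%02d", 1:p)))
  list(X = X, n = n, p = p)
}

test_that("LOSO folds equal sites; k-fold balances whole families", {
  spec <- population_spec(n_subjects = 200, n_sites = 21)
  cov <- generate_covariates_and_clusters(spec, seed = 2)
  expect_warning(loso <- make_folds(cov, "loso"), "fewer than 10")
  expect_equal(sort(unique(loso$fold)), sort(unique(cov$site)))
  # 100 singleton families into 10 folds of 10
  cov10 <- data.frame(subject_id = as.character(1:100),
                      family = as.character(1:100))
  kf <- make_folds(cov10, "kfold", k = 10, seed = 3)
  expect_true(all(table(kf$fold) == 10))
})

test_that("siblings always share a fold", {
  fams <- rep(sprintf("f%02d", 1:30), times = rep(c(2, 1), 15))
  cohort <- data.frame(subject_id = as.character(seq_along(fams)),
                       family = fams)
  for (s in 1:25) {
    kf <- make_folds(cohort, "kfold", k = 5, seed = s)
    split_fams <- tapply(kf$fold, cohort$family,
                         function(f) length(unique(f)))
    expect_true(all(split_fams == 1))
  }
})

test_that("PCR fold model matches a normal-equations oracle", {
  d <- make_xy(120, 12, seed = 4)
  set.seed(5)
  D <- cbind(1, rnorm(120), rnorm(120))
  colnames(D) <- c("(Intercept)", "c1", "c2")
  y <- rnorm(120)
  K <- 5
  m <- fit_pcr_fold(d$X, y, D, K)
  # oracle: explicit centering, eigendecomposition, solve() regressions
  Xc <- sweep(d$X, 2, colMeans(d$X))
  V <- eigen(crossprod(Xc))$vectors[, 1:K]
  S <- Xc %*% V
  B <- solve(crossprod(D), crossprod(D, S))
  by <- solve(crossprod(D), crossprod(D, y))
  rs <- S - D %*% B; ry <- y - D %*% by
  Z <- cbind(1, rs)
  w <- solve(crossprod(Z), crossprod(Z, ry))
  # loadings are sign/rotation free; compare the feature-space composition
  expect_equal(abs(crossprod(m$loadings) - diag(K)) |> max(), 0,
               tolerance = 1e-8)
  map_pkg <- as.numeric(m$loadings %*% m$weights[-1])
  map_orc <- as.numeric(V %*% w[-1])
  expect_equal(map_pkg, map_orc, tolerance = 1e-8)
  # nuisance betas reproduce the oracle solver in feature space
  expect_equal(as.numeric(m$loadings %*% t(m$B_scores[-1, , drop = FALSE])),
               as.numeric(V %*% t(B[-1, , drop = FALSE])), tolerance = 1e-8)
})

test_that("zero covariates reduce the model to plain PCR", {
  d <- make_xy(100, 10, seed = 6)
  y <- rnorm(100)
  m <- fit_pcr_fold(d$X, y, NULL, 4)
  res <- predict_and_correlate(m, d$X, y, NULL)
  Xc <- sweep(d$X, 2, colMeans(d$X))
  S <- Xc %*% eigen(crossprod(Xc))$vectors[, 1:4]
  plain <- fitted(lm(y ~ S))
  expect_equal(cor(res$predicted, plain), 1, tolerance = 1e-8)
})

test_that("full-rank K reproduces ordinary least squares", {
  d <- make_xy(80, 8, seed = 7)
  y <- rnorm(80)
  m <- fit_pcr_fold(d$X, y, NULL, 8)
  res <- predict_and_correlate(m, d$X, y, NULL)
  full <- fitted(lm(y ~ d$X))
  expect_equal(cor(res$predicted, full - mean(full)), 1, tolerance = 1e-8)
  expect_error(fit_pcr_fold(d$X, y, NULL, 60), "rank")
})

test_that("test fold identical to training reproduces the in-sample fit", {
  d <- make_xy(90, 9, seed = 8)
  y <- rnorm(90)
  m <- fit_pcr_fold(d$X, y, NULL, 3)
  res <- predict_and_correlate(m, d$X, y, NULL)
  in_sample <- cor(res$predicted, res$y_residualized)
  expect_equal(res$r, in_sample)
})

test_that("noiseless planted components are recovered out of sample", {
  set.seed(9)
  n <- 300; p <- 40
  L <- matrix(rnorm(2 * p), 2, p)
  F2 <- matrix(rnorm(n * 2), n, 2)
  X <- F2 %*% L
  colnames(X) <- sprintf("f%02d", 1:p)
  y <- as.numeric(F2 %*% c(1, -2))
  m <- fit_pcr_fold(X[1:200, ], y[1:200], NULL, 2)
  res <- predict_and_correlate(m, X[201:300, ], y[201:300], NULL)
  expect_gt(res$r, 0.99)
})

test_that("component selection matches a brute-force inner-CV loop", {
  set.seed(10)
  n <- 200; p <- 50
  d <- make_xy(n, p, seed = 10)
  y <- d$X[, 1] - d$X[, 2] + rnorm(n, sd = 2)
  Ks <- c(2L, 5L, 10L, 20L)
  set.seed(77)
  K_pkg <- select_num_components(d$X, y, NULL, candidates = Ks, seed = 33)
  # brute force: identical inner folds (replayed), fresh PCR code path
  set.seed(33)
  inner <- make_folds(data.frame(subject_id = as.character(1:n),
                                 family = as.character(1:n)),
                      scheme = "kfold", k = 5)
  scores <- matrix(NA_real_, 5, length(Ks))
  fold_ids <- sort(unique(inner$fold))
  for (fi in seq_along(fold_ids)) {
    te <- inner$fold == fold_ids[fi]
    Xtr <- d$X[!te, ]; ytr <- y[!te]
    mu <- colMeans(Xtr); Xc <- sweep(Xtr, 2, mu)
    V <- svd(Xc)$v
    for (ki in seq_along(Ks)) {
      S <- Xc %*% V[, 1:Ks[ki], drop = FALSE]
      w <- coef(lm(ytr ~ S))
      Ste <- sweep(d$X[te, ], 2, mu) %*% V[, 1:Ks[ki], drop = FALSE]
      pred <- cbind(1, Ste) %*% w
      scores[fi, ki] <- cor(as.numeric(pred), y[te] - mean(ytr))
    }
  }
  K_brute <- Ks[which.max(colMeans(scores))]
  expect_identical(as.integer(K_pkg), K_brute)
})

test_that("pure-noise outcomes still return some candidate without error", {
  d <- make_xy(120, 30, seed = 11)
  y <- rnorm(120)
  K <- select_num_components(d$X, y, NULL, candidates = c(2L, 5L, 10L),
                             seed = 12)
  expect_true(as.integer(K) %in% c(2L, 5L, 10L))
})

test_that("pipeline averages folds unweighted and is order invariant", {
  nc <- simulate_confounded_null(240, 40, seed = 13)
  folds <- make_folds(nc$covariates, "kfold", k = 4, seed = 14)
  res <- run_cv_pipeline(nc$X, nc$y, nc$covariates, folds,
                         candidates = c(5L, 10L), seed = 15)
  expect_equal(res$mean_r, mean(res$fold_results$r))
  expect_equal(nrow(res$predictions), 240)
  expect_equal(anyDuplicated(res$predictions$subject_id), 0)
  # permuting subject order (folds fixed per subject) leaves results unchanged
  perm <- sample(240)
  res2 <- run_cv_pipeline(nc$X[perm, ], nc$y[perm], nc$covariates[perm, ],
                          folds[perm, ], candidates = c(5L, 10L), seed = 15)
  expect_equal(res2$mean_r, res$mean_r, tolerance = 1e-10)
  m1 <- res$predictions[order(res$predictions$subject_id), ]
  m2 <- res2$predictions[order(res2$predictions$subject_id), ]
  expect_equal(m1$y_predicted, m2$y_predicted, tolerance = 1e-10)
})

test_that("training artifacts never depend on test-fold outcomes", {
  d <- make_xy(150, 20, seed = 16)
  y <- rnorm(150)
  te <- seq_len(50)
  m1 <- fit_pcr_fold(d$X[-te, ], y[-te], NULL, 5)
  y_scrambled <- y
  y_scrambled[te] <- sample(y[te])
  m2 <- fit_pcr_fold(d$X[-te, ], y_scrambled[-te], NULL, 5)
  expect_identical(m1, m2)
})

test_that("consensus maps compose loadings with betas", {
  d <- make_xy(100, 15, seed = 17)
  y <- rnorm(100)
  m <- fit_pcr_fold(d$X, y, NULL, 4)
  raw <- consensus_feature_map(m, standardize = FALSE)
  brute <- as.numeric(m$loadings %*% m$weights[-1])
  expect_equal(unname(raw), brute, tolerance = 1e-10)
  zs <- consensus_feature_map(m)
  expect_equal(mean(zs), 0, tolerance = 1e-10)
  expect_equal(sd(zs), 1, tolerance = 1e-10)
  # K = 1: map proportional to the first loading vector
  m1 <- fit_pcr_fold(d$X, y, NULL, 1)
  raw1 <- consensus_feature_map(m1, standardize = FALSE)
  expect_equal(unname(raw1), as.numeric(m1$loadings) * m1$weights[2],
               tolerance = 1e-12)
  # all-zero betas: raw map returned with a flag instead of z-scores
  m0 <- m; m0$weights[] <- 0
  z0 <- consensus_feature_map(m0)
  expect_false(attr(z0, "zscored"))
  expect_true(all(z0 == 0))
})

test_that("tiny test folds are skipped; excessive skipping errors", {
  d <- make_xy(152, 10, seed = 18)
  y <- rnorm(152)
  folds <- data.frame(subject_id = as.character(1:152),
                      fold = c(rep(sprintf("f%d", 1:5), each = 30), "g", "g"))
  expect_warning(
    res <- run_cv_pipeline(d$X, y, NULL, folds, candidates = c(2L, 5L)),
    "fewer than 3")
  expect_equal(nrow(res$fold_results), 5)
  # more than 20% of folds unusable -> hard error
  folds_bad <- data.frame(subject_id = as.character(1:152),
                          fold = c(rep("a", 74), rep("b", 74),
                                   "c", "c", "d", "d"))
  expect_error(suppressWarnings(
    run_cv_pipeline(d$X, y, NULL, folds_bad, candidates = c(2L, 5L))),
    "20%")
})
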