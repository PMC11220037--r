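# Network means, residualization, clustered bootstrap, regression comparison,
# decile bins, quadrants

fixture_cohort <- function(n = 300, seed = 31) {
  spec <- population_spec(n_subjects = n)
  simulate_cohort(spec, seed = seed)
}

test_that("network means are exact group-by means", {
  set.seed(1)
  A <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(NULL, sprintf("p%03d", 1:20)))
  labels <- data.frame(parcel_id = sprintf("p%03d", 1:20),
                       network = rep(c("FPN", "DAN", "SMN", "VIS"), each = 5))
  nm <- extract_network_means(A, labels)
  oracle <- t(apply(A, 1, function(row) tapply(row, labels$network, mean)))
  for (nw in colnames(nm))
    expect_equal(nm[, nw], oracle[, nw], tolerance = 1e-12,
                 ignore_attr = TRUE)
  # constant network
  A2 <- A; A2[, 1:5] <- 0.7
  expect_true(all(extract_network_means(A2, labels)[, "FPN"] == 0.7))
  # two-feature network with values 1 and 3
  A3 <- matrix(c(1, 3), 1, 2, dimnames = list(NULL, c("q1", "q2")))
  l3 <- data.frame(parcel_id = c("q1", "q2"), network = c("X", "X"))
  expect_equal(unname(extract_network_means(A3, l3)[1, 1]), 2)
  expect_error(extract_network_means(A, labels[-1, ]), "unlabeled")
})

test_that("residualization is OLS-exact and orthogonal to the design", {
  coh <- fixture_cohort(250, seed = 7)
  y <- coh$truth$eea_mean
  res <- residualize_on_covariates(cbind(y = y), coh$covariates)
  D <- covariate_design(coh$covariates)
  expect_lt(max(abs(crossprod(D, res))), 1e-8)
  oracle <- resid(lm(y ~ D - 1))
  expect_equal(as.numeric(res), as.numeric(oracle), tolerance = 1e-10)
  # orthogonal variable: residual equals the centred variable
  set.seed(2)
  v <- rnorm(250)
  v_orth <- resid(lm(v ~ D - 1)) # construct exactly orthogonal input
  res2 <- residualize_on_covariates(cbind(v = v_orth), coh$covariates)
  expect_equal(as.numeric(res2), as.numeric(v_orth - mean(v_orth)),
               tolerance = 1e-9)
})

test_that("z-scoring is idempotent and refuses constants", {
  set.seed(3)
  x <- rnorm(100, 5, 3)
  expect_equal(zscore(zscore(x)), zscore(x), tolerance = 1e-12)
  expect_error(zscore(rep(1, 10)), "constant")
})

test_that("degenerate clustering reduces to the ordinary bootstrap", {
  set.seed(4)
  n <- 150
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  ids <- as.character(seq_len(n))
  ci <- clustered_bootstrap_ci(x, y, site = ids, family = ids,
                               n_boot = 1500, seed = 5)
  # ordinary case-resampling bootstrap replicates
  set.seed(6)
  ord <- replicate(1500, {
    idx <- sample.int(n, n, replace = TRUE)
    cor(x[idx], y[idx])
  })
  expect_gt(ks.test(ci$replicates, ord)$p.value, 0.01)
  expect_error(clustered_bootstrap_ci(rep(1, n), y, ids, ids),
               "constant")
})

test_that("bootstrap CI is ordered and narrows with more data", {
  d1 <- simulate_clustered_bivariate(n_sites = 20, families_per_site = 4,
                                     rho = 0.3, seed = 8)
  ci1 <- clustered_bootstrap_ci(d1$x, d1$y, d1$site, d1$family,
                                n_boot = 800, seed = 9)
  expect_lte(ci1$lower, ci1$estimate)
  expect_gte(ci1$upper, ci1$estimate)
  d2 <- simulate_clustered_bivariate(n_sites = 80, families_per_site = 4,
                                     rho = 0.3, seed = 10)
  ci2 <- clustered_bootstrap_ci(d2$x, d2$y, d2$site, d2$family,
                                n_boot = 800, seed = 11)
  expect_lt(ci2$upper - ci2$lower, ci1$upper - ci1$lower)
})

test_that("difference CI collapses for identical predictors and ignores sign", {
  d <- simulate_clustered_bivariate(rho = 0.3, seed = 12)
  ci_same <- bootstrap_diff_ci(d$x, d$y, d$x, d$site, d$family,
                               n_boot = 300, seed = 13)
  expect_identical(c(ci_same$lower, ci_same$upper), c(0, 0))
  set.seed(14)
  x2 <- rnorm(nrow(d))
  ci_a <- bootstrap_diff_ci(d$x, d$y, x2, d$site, d$family,
                            n_boot = 400, seed = 15)
  ci_b <- bootstrap_diff_ci(-d$x, d$y, x2, d$site, d$family,
                            n_boot = 400, seed = 15)
  expect_equal(c(ci_a$lower, ci_a$upper), c(ci_b$lower, ci_b$upper),
               tolerance = 1e-12)
})

test_that("nested network regressions never lose in-sample fit", {
  coh <- fixture_cohort(400, seed = 16)
  nm <- extract_network_means(coh$activation$act_load,
                              coh$activation$labels)
  rr <- residualize_on_covariates(cbind(eea = coh$truth$eea_mean, nm),
                                  coh$covariates)
  cmp <- network_regression_compare(rr[, -1], rr[, 1],
                                    site = coh$covariates$site,
                                    family = coh$covariates$family,
                                    n_boot = 200, seed = 17)
  expect_gte(cmp$full$estimate, cmp$subset$estimate)
  # single-network subset equals the absolute bivariate correlation
  cmp1 <- network_regression_compare(rr[, -1], rr[, 1], subset = "FPN",
                                     site = coh$covariates$site,
                                     family = coh$covariates$family,
                                     n_boot = 50, seed = 18)
  expect_equal(cmp1$subset$estimate, abs(cor(rr[, "FPN"], rr[, 1])),
               tolerance = 1e-10)
  expect_error(network_regression_compare(rr[, -1], rr[, 1],
                                          subset = "NOPE",
                                          site = coh$covariates$site,
                                          family = coh$covariates$family),
               "absent")
})

test_that("decile bins partition by rank and track monotone signals", {
  set.seed(19)
  eea <- rnorm(20)
  act <- cbind(a = rnorm(20))
  db <- decile_bin_summary(eea, act)
  expect_true(all(table(db$bin_assignment) == 2))
  # deterministic increasing function of EEA: strictly increasing bin means
  act2 <- cbind(mono = 2 * eea + 1)
  db2 <- decile_bin_summary(eea, act2)
  expect_true(all(diff(db2$bins$mean) > 0))
  expect_gt(db2$slopes[["mono"]], 0)
  # remainder spread over the lowest bins
  db3 <- decile_bin_summary(rnorm(23), cbind(x = rnorm(23)))
  expect_equal(as.integer(table(db3$bin_assignment)[1:3]), c(3L, 3L, 3L))
  expect_error(decile_bin_summary(rnorm(5), cbind(x = rnorm(5))), "at least")
})

test_that("quadrant assignment matches brute-force classification", {
  set.seed(20)
  n <- 200
  a0 <- rnorm(n); a2 <- 0.6 * a0 + rnorm(n); eea <- rnorm(n)
  q <- quadrant_summary(a0, a2, eea)
  z0 <- (a0 - mean(a0)) / sd(a0)
  z2 <- (a2 - mean(a2)) / sd(a2)
  ft <- lm(z2 ~ z0)
  ref <- character(n)
  for (i in seq_len(n)) {
    above <- z2[i] > coef(ft)[1] + coef(ft)[2] * z0[i]
    right <- z0[i] > 0
    ref[i] <- if (above && !right) "upper_left" else
      if (above && right) "upper_right" else
        if (!above && !right) "lower_left" else "lower_right"
  }
  expect_identical(q$assignment, ref)
  expect_equal(sum(q$quadrants$n), n)
})

test_that("quadrant ordering follows the planted construction", {
  set.seed(21)
  n <- 400
  a0 <- rnorm(n); a2 <- 0.5 * a0 + rnorm(n)
  eea <- resid(lm(a2 ~ a0))  # EEA == deviation from the regression line
  q <- quadrant_summary(a0, a2, eea)
  qt <- q$quadrants
  expect_gt(qt$mean_eea_z[qt$quadrant == "upper_left"],
            qt$mean_eea_z[qt$quadrant == "lower_right"])
  # independent activations: quadrant means near zero
  a2i <- rnorm(n); eei <- rnorm(n)
  qi <- quadrant_summary(a0, a2i, eei)
  expect_true(all(abs(qi$quadrants$mean_eea_z) < 3 / sqrt(50)))
})
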