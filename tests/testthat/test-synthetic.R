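# Synthetic cohort generator: population parameters, covariates/clusters,
# activation maps with planted moments

test_that("degenerate population SDs collapse to the mean subject", {
  spec <- population_spec(n_subjects = 40, sigma_v = 0)
  for (p in names(spec$param_pop)) spec$param_pop[[p]]$sd <- c(0, 0)
  spec$eea_cov_weight <- 0
  truth <- sample_population_parameters(spec, seed = 3)
  expect_lt(diff(range(truth$v_target_0back)), 1e-9)
  expect_lt(diff(range(truth$a_2back)), 1e-9)
  expect_equal(truth$eea_0back, rowMeans(truth[, c("v_target_0back",
                                                   "v_novel_0back",
                                                   "v_lure_0back")]))
})

test_that("population draws respect bounds and the planted EEA correlation", {
  spec <- population_spec(n_subjects = 2000, rho_eea = 0.5)
  truth <- sample_population_parameters(spec, seed = 12)
  expect_true(all(truth$a_0back > 0))
  expect_true(all(truth$z_2back > 0 & truth$z_2back < 1))
  expect_true(all(truth$p_contam_0back >= 0 & truth$p_contam_0back <= 1))
  r <- cor(truth$eea_0back, truth$eea_2back)
  expect_gt(r, 0.45); expect_lt(r, 0.55)
  expect_equal(truth$eea_mean, (truth$eea_0back + truth$eea_2back) / 2)
})

test_that("higher true drift yields higher simulated accuracy", {
  spec <- population_spec(n_subjects = 60)
  truth <- sample_population_parameters(spec, seed = 5)
  set.seed(6)
  trials <- generate_cohort_behavior(truth, dt = 2e-3)
  acc <- sapply(truth$subject_id, function(s) {
    tt <- trials[trials$subject_id == s & trials$response != "none", ]
    mean(eeanet:::trial_outcome_code(tt$stimulus_class, tt$response) == 0L)
  })
  expect_gt(cor(truth$eea_mean, acc, method = "spearman"), 0.5)
})

test_that("cohort behavior is byte-identical under one seed", {
  spec <- population_spec(n_subjects = 4)
  truth <- sample_population_parameters(spec, seed = 2)
  t1 <- generate_cohort_behavior(truth, seed = 9, dt = 2e-3)
  t2 <- generate_cohort_behavior(truth, seed = 9, dt = 2e-3)
  expect_identical(t1, t2)
})

test_that("cluster design arithmetic and degenerate clustering hold", {
  spec <- population_spec(n_subjects = 1000, n_sites = 20)
  spec$family_size_probs <- c(`2` = 1)
  cov <- generate_covariates_and_clusters(spec, seed = 4)
  expect_equal(nrow(cov), 1000)
  expect_equal(length(unique(cov$family)), 500)
  expect_equal(length(unique(cov$site)), 20)
  # families nested within sites
  expect_true(all(rowSums(table(cov$family, cov$site) > 0) == 1))
  # all-singleton families: one subject each
  spec$family_size_probs <- c(`1` = 1)
  cov1 <- generate_covariates_and_clusters(spec, seed = 4)
  expect_equal(length(unique(cov1$family)), 1000)
  expect_true(all(c("age2", "fd2") %in% names(cov1)))
  expect_equal(cov1$age2, cov1$age^2)
})

test_that("null activation model carries no EEA signal", {
  spec <- population_spec(n_subjects = 1500)
  spec$activation$r_0back[] <- 0
  spec$activation$r_2back[] <- 0
  spec$act_cov_effect <- 0
  coh <- simulate_cohort(spec, seed = 8)
  nm <- extract_network_means(coh$activation$act_load, coh$activation$labels)
  rs <- cor(nm, coh$truth$eea_latent_z)
  expect_true(all(abs(rs) < 3 / sqrt(1500)))
})

test_that("planted activation correlations are recovered at n = 4000", {
  spec <- population_spec(n_subjects = 4000)
  coh <- simulate_cohort(spec, seed = 21)
  nm0 <- extract_network_means(coh$activation$act_0back, coh$activation$labels)
  nm2 <- extract_network_means(coh$activation$act_2back, coh$activation$labels)
  resid <- residualize_on_covariates(
    cbind(eea = coh$truth$eea_mean, nm0, nm2), coh$covariates)
  eea_r <- resid[, 1]
  zse <- 2 / sqrt(4000)  # ~2 Fisher-z standard errors
  for (k in seq_along(eeanet:::YEO7)) {
    expect_lt(abs(cor(resid[, 1 + k], eea_r) - spec$activation$r_0back[k]),
              zse + 0.015)
    expect_lt(abs(cor(resid[, 8 + k], eea_r) - spec$activation$r_2back[k]),
              zse + 0.015)
    # cross-condition correlation matches the planted rho_cross
    expect_lt(abs(cor(resid[, 1 + k], resid[, 8 + k]) -
                    spec$activation$rho_cross[k]), 0.05)
  }
})

test_that("infeasible covariance specifications fail at construction", {
  spec <- population_spec(n_subjects = 10)
  spec$activation$rho_cross[6] <- -0.05  # below r0*r2 + cluster shares
  expect_error(validate_population_spec(spec), "infeasible")
  spec2 <- population_spec(n_subjects = 10)
  spec2$activation$r_2back[6] <- 0.99
  expect_error(validate_population_spec(spec2), "infeasible")
})

test_that("R-squared calibration hits its target", {
  spec <- population_spec(n_subjects = 10)
  spec36 <- calibrate_activation_r2(spec, 0.36)
  expect_equal(implied_load_r2(spec36), 0.36, tolerance = 1e-6)
  # planted ratios preserved
  expect_equal(spec36$activation$r_2back / spec$activation$r_2back,
               spec36$activation$r_0back / spec$activation$r_0back)
  expect_error(calibrate_activation_r2(spec, 0.99), "not attainable")
})

test_that("clustered bivariate simulator attains its population correlation", {
  rs <- sapply(1:40, function(i)
    cor(simulate_clustered_bivariate(rho = 0.3, seed = i)$x,
        simulate_clustered_bivariate(rho = 0.3, seed = i)$y))
  expect_lt(abs(mean(rs) - 0.3), 0.03)
})
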