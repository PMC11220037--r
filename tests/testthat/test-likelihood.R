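# Trial and subject log-likelihood under the censored contaminant mixture

test_that("outcome probabilities behave at the mixture extremes", {
  p <- fixture_params()
  p1 <- unclass(p); p1[c(8, 16)] <- 1
  p1 <- structure(p1, class = c("ddm_parameters", "numeric"))
  pr <- response_probability(p1, 2, "target")
  expect_identical(unname(pr[["omission"]]), 1)
  p0 <- unclass(p); p0[c(8, 16)] <- 0
  p0 <- structure(p0, class = c("ddm_parameters", "numeric"))
  pr_inf <- response_probability(p0, 0, "novel", response_window = 1e4)
  expect_lt(pr_inf[["omission"]], 1e-8)
})

test_that("outcome probabilities sum to one and respond to drift and window", {
  p <- fixture_params()
  for (cond in c(0, 2)) for (cl in c("target", "novel", "lure")) {
    pr <- response_probability(p, cond, cl)
    expect_equal(unname(sum(pr)), 1, tolerance = 1e-6)
  }
  # P(correct | target) nondecreasing in v_target
  pc <- sapply(c(0.5, 1, 2, 4), function(v) {
    pp <- unclass(fixture_params()); pp[1] <- v
    response_probability(structure(pp, class = c("ddm_parameters", "numeric")),
                         0, "target")[["correct"]]
  })
  expect_true(all(diff(pc) > 0))
  # shrinking the window weakly increases P(omission)
  po <- sapply(c(2, 1.5, 1, 0.8), function(w)
    response_probability(p, 2, "lure", response_window = w)[["omission"]])
  expect_true(all(diff(po) >= 0))
})

test_that("outcome probabilities match large-sample simulator frequencies", {
  p <- fixture_params()
  n <- 4e4
  sched <- data.frame(condition = 2, stimulus_class = rep("lure", n))
  set.seed(71)
  tt <- simulate_trials(p, sched, dt = 1e-3)
  pr <- response_probability(p, 2, "lure")
  obs <- c(mean(tt$response == "nonmatch"), mean(tt$response == "match"),
           mean(tt$response == "none"))
  for (k in 1:3) {
    se <- sqrt(pr[[k]] * (1 - pr[[k]]) / n)
    expect_lt(abs(obs[k] - pr[[k]]), 4 * se + 2e-3)
  }
})

test_that("degenerate st0 reduces to the plain shifted density", {
  pp <- unname(unclass(fixture_params()))
  pp[6] <- 0  # st0_0back
  p <- structure(pp, class = c("ddm_parameters", "numeric"))
  tr <- one_trial(0, "novel", "nonmatch", 0.75)
  ll <- trial_log_likelihood(tr, p)
  ref <- log((1 - pp[8]) *
               wiener_fpt_density(0.75 - pp[5], pp[2], pp[4], pp[7], "upper"))
  expect_equal(ll, ref, tolerance = 1e-12)
})

test_that("responses are impossible under pure contamination", {
  pp <- unclass(fixture_params()); pp[c(8, 16)] <- 1
  p <- structure(pp, class = c("ddm_parameters", "numeric"))
  expect_identical(trial_log_likelihood(one_trial(0, "target", "match", 0.6), p),
                   -Inf)
})

test_that("st0 quadrature matches adaptive numerical integration", {
  p <- unname(unclass(fixture_params()))
  tr <- one_trial(2, "lure", "nonmatch", 0.9)  # correct -> upper boundary
  ll <- trial_log_likelihood(tr, fixture_params())
  t0 <- p[13]; st0 <- p[14]
  f <- Vectorize(function(tp)
    wiener_fpt_density(0.9 - tp, p[11], p[12], p[15], "upper"))
  ref <- log((1 - p[16]) *
               integrate(f, t0, t0 + st0, rel.tol = 1e-10)$value / st0)
  expect_equal(ll, ref, tolerance = 1e-6)
})

test_that("omission likelihood equals the censored mixture", {
  p <- unname(unclass(fixture_params()))
  ll <- trial_log_likelihood(one_trial(2, "target", "none"), fixture_params())
  surv <- Vectorize(function(tp)
    eeanet:::wiener_survival_cpp(2 - tp, p[9], p[12], p[15]))
  sbar <- integrate(surv, p[13], p[13] + p[14], rel.tol = 1e-10)$value / p[14]
  expect_equal(ll, log(p[16] + (1 - p[16]) * sbar), tolerance = 1e-6)
})

test_that("impossible observed RTs yield -Inf, invalid parameters error", {
  pp <- unname(unclass(fixture_params()))
  pp[5] <- 0.5; pp[6] <- 0  # t0 = 0.5, st0 = 0
  p <- structure(pp, class = c("ddm_parameters", "numeric"))
  expect_identical(trial_log_likelihood(one_trial(0, "target", "match", 0.4), p),
                   -Inf)
  bad <- unclass(fixture_params()); bad[4] <- -1
  expect_error(trial_log_likelihood(one_trial(0, "target", "match", 0.5),
                                    structure(bad, class = "ddm_parameters")),
               "'a' must be")
})

test_that("subject log-likelihood is an additive loop over trials", {
  p <- fixture_params()
  tt <- fixture_trials()[1:20, ]
  total <- subject_log_likelihood(tt, p)
  brute <- sum(vapply(seq_len(nrow(tt)), function(i)
    trial_log_likelihood(tt[i, ], p), 0))
  expect_equal(total, brute, tolerance = 1e-10)
  one <- tt[3, ]
  expect_equal(subject_log_likelihood(one, p), trial_log_likelihood(one, p))
  expect_equal(subject_log_likelihood(rbind(one, one), p),
               2 * trial_log_likelihood(one, p))
  expect_error(subject_log_likelihood(tt[0, ], p), "empty")
})

test_that("the log-likelihood profile peaks near the generating drift", {
  p <- fixture_params()
  sched <- data.frame(condition = 0,
                      stimulus_class = rep(c("target", "novel", "lure"), 400))
  set.seed(55)
  tt <- simulate_trials(p, sched, dt = 1e-3)
  grid <- seq(1.0, 3.4, by = 0.2)  # truth: v_target_0back = 2.2
  prof <- vapply(grid, function(v) {
    pp <- unclass(p); pp[1] <- v
    subject_log_likelihood(tt, structure(pp, class = "ddm_parameters"))
  }, 0)
  expect_lt(abs(grid[which.max(prof)] - 2.2), 0.3)
})
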