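test_that("model enumeration covers all masks plus the Gaussian model", {
  for (fam in c("start", "stop")) {
    ms <- enumerate_models(fam)
    expect_length(ms, 16L)
    expect_equal(sum(vapply(ms, `[[`, logical(1), "gaussian")), 1L)
    expect_false(anyDuplicated(names(ms)) > 0)
  }
  # purely social stop models are impossible on unrestricted data
  un <- enumerate_models("stop", restricted = FALSE)
  flagged <- names(un)[vapply(un, `[[`, logical(1), "structural_zero")]
  expect_setequal(flagged, c("G2", "G4", "G2+G4"))
  re <- enumerate_models("stop", restricted = TRUE)
  expect_false(any(vapply(re, `[[`, logical(1), "structural_zero")))
})

test_that("a model with all parameters fixed has exact evidence", {
  b <- toy_bout3()
  obs <- make_stop_observations(b)
  m <- hazard_model("stop", "G1")
  pr <- applause_priors(gamma1 = prior_fixed(0.2))
  ev <- estimate_evidence(m, obs, pr, n_samples = 10, replicates = 2)
  expect_equal(ev$se, 0)
  expect_equal(ev$log_evidence,
               as.numeric(stop_loglik(obs, m, c(gamma1 = 0.2))))
})

test_that("importance sampling agrees with grid quadrature on a toy bout", {
  b <- toy_bout3()
  sobs <- make_stop_observations(b)
  obs <- make_start_observations(b, 0.1)
  models <- list(hazard_model("start", "L1"), hazard_model("start", "L2"),
                 hazard_model("start", c("L1", "L2")),
                 hazard_model("stop", "G1"), hazard_model("stop", "G3"),
                 hazard_model("stop", c("G1", "G3")))
  for (m in models) {
    o <- if (m$family == "start") obs else sobs
    ev <- estimate_evidence(m, o, n_samples = 4000, replicates = 8,
                            seed = 100, n_max = 5)
    qz <- quad_evidence(m, o, n_grid = 401, n_max = 5)
    expect_lt(abs(ev$log_evidence - qz), 3 * ev$se + 0.02)
  }
})

test_that("log-sum-exp aggregation is invariant to constant shifts", {
  set.seed(2)
  x <- rnorm(500, -800, 30)
  expect_equal(applause:::logsumexp(x + 123.4) - 123.4,
               applause:::logsumexp(x), tolerance = 1e-12)
  expect_identical(applause:::logsumexp(rep(-Inf, 5)), -Inf)
})

test_that("evidence estimation is deterministic given a seed", {
  b <- toy_bout3()
  obs <- make_stop_observations(b)
  m <- hazard_model("stop", "G1")
  e1 <- estimate_evidence(m, obs, n_samples = 500, replicates = 3, seed = 9)
  e2 <- estimate_evidence(m, obs, n_samples = 500, replicates = 3, seed = 9)
  expect_identical(e1$replicate_values, e2$replicate_values)
})

test_that("Monte-Carlo error shrinks like one over root samples", {
  b <- toy_bout3()
  obs <- make_stop_observations(b)
  m <- hazard_model("stop", "G1")
  set.seed(5)
  se_at <- function(n) mean(replicate(25, {
    estimate_evidence(m, obs, n_samples = n, replicates = 4)$se
  }))
  ratio <- se_at(200) / se_at(800)
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.9)
})

test_that("all prior draws impossible yields -Inf evidence with diagnostic", {
  b <- toy_bout3()
  obs <- make_stop_observations(b)
  ev <- estimate_evidence(hazard_model("stop", "G2"), obs, n_samples = 100,
                          replicates = 2, seed = 3)
  expect_identical(ev$log_evidence, -Inf)
  expect_match(ev$diagnostic, "zero")
})

test_that("posterior means reduce to the prior under a flat likelihood", {
  # an empty observation set gives every draw likelihood 1
  m <- hazard_model("start", "L2")
  obs0 <- make_start_observations(toy_bout3(), 0.1)[0, ]
  pm <- posterior_mean(m, obs0, n_samples = 4000, replicates = 4, seed = 2)
  expect_equal(pm["lambda2", "mean"], 5, tolerance = 0.05)  # Exp(1/5) prior mean
})

test_that("conjugate geometric-Beta posterior mean is recovered", {
  # constant stopping + Uniform(0,1) prior is Beta-Bernoulli over claps:
  # posterior Beta(1 + stops, 1 + continues)
  set.seed(6)
  b <- simulate_bout(sim_config(gamma1 = 0.15, gamma2 = 0, gamma3 = 1e-9),
                     N = 12)
  obs <- make_stop_observations(b)
  stops <- sum(obs$stopped); conts <- sum(!obs$stopped)
  closed <- (1 + stops) / (2 + stops + conts)
  pm <- posterior_mean(hazard_model("stop", "G1"), obs, n_samples = 20000,
                       replicates = 8, seed = 11)
  expect_equal(pm["gamma1", "mean"], closed,
               tolerance = 6 * pm["gamma1", "se_mean"] / closed)
})

test_that("model ranking normalizes probabilities and flags ties", {
  mk <- function(model, lz, se) structure(
    list(model = model, log_evidence = lz, se = se,
         replicate_values = lz, n_samples = 10, replicates = 2),
    class = "evidence_estimate")
  tab <- rank_models(list(mk("A", log(0.5), 0), mk("B", log(0.25), 0)))
  expect_equal(tab$rel_prob, c(2 / 3, 1 / 3))
  expect_false(any(tab$unresolved))
  tied <- rank_models(list(mk("A", -10, 0.5), mk("B", -10, 0.5)))
  expect_true(all(tied$unresolved))
})

test_that("small effective sample size triggers a warning", {
  set.seed(44)
  bl <- sim_study_bouts(seed = 44)
  obs <- make_stop_observations(bl)
  expect_warning(
    posterior_mean(hazard_model("stop", c("G2", "G3")), obs,
                   n_samples = 300, replicates = 2, n_max = 30),
    "effective sample size")
})
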