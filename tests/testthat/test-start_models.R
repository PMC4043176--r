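test_that("starting rate combines the active cue terms", {
  expect_equal(start_rate(0.7, 0.5, c(lambda1 = 0)), 0)
  expect_equal(start_rate(0.5, 0, c(lambda2 = 2.15)), 1.075)
  expect_equal(start_rate(0.9, 0.9, c(lambda1 = 0.3)), 0.3)
  expect_equal(start_rate(0.5, 0.25,
                          c(lambda1 = 0.1, lambda2 = 1, lambda3 = 2,
                            lambda4 = 4)),
               0.1 + 0.5 + 2 * 0.25 + 1)
  expect_error(start_rate(0.5, 0, c(lambda2 = -1)), "negative")
})

test_that("frame probability is the exponential-hazard conversion", {
  expect_equal(start_frame_probability(0, 0.1), 0)
  expect_equal(start_frame_probability(2.15, 0.1), 1 - exp(-0.215))
  # small rate*dt limit: p ~ rate*dt within 1%
  expect_equal(start_frame_probability(0.1, 0.1), 0.01, tolerance = 0.01)
  expect_error(start_frame_probability(-1, 0.1))
})

test_that("Gaussian frame probability matches numerical integration", {
  # quadrature oracle: truncated-Normal interval mass over survival
  num <- stats::integrate(dnorm, 1.0, 1.1, mean = 1.5, sd = 0.5)$value
  den <- stats::integrate(dnorm, 1.0, Inf, mean = 1.5, sd = 0.5)$value
  expect_equal(gaussian_start_probability(1.0, 0.1, 1.5, 0.5), num / den,
               tolerance = 1e-6)
  expect_lt(gaussian_start_probability(0, 0.1, 10, 0.5), 1e-12)
  expect_equal(gaussian_start_probability(1.5, 1e6, 1.5, 0.5), 1)
  # survivor underflow forces a start
  expect_equal(gaussian_start_probability(40, 0.1, 1.5, 0.5), 1)
})

test_that("starting log-likelihood sums frame log-probabilities", {
  m2 <- hazard_model("start", "L2")
  expect_equal(start_loglik(NULL, m2, c(lambda2 = 1), dt = 0.1), 0)
  # a single survived frame at p = 0.2
  obs1 <- data.frame(group_id = "g", talk_id = "1", individual_id = "x",
                     t0 = 0, rho = 0.5, nb = 0, started = FALSE)
  lam <- -log(0.8) / (0.5 * 0.1)          # rate giving p = 0.2 at rho = 0.5
  expect_equal(start_loglik(obs1, m2, c(lambda2 = lam), dt = 0.1), log(0.8))

  # toy bout: brute-force product over frames, computed independently
  b <- toy_bout3()
  dt <- 0.1
  obs <- make_start_observations(b, dt)
  lam2 <- 1.7
  brute <- 0
  for (i in seq_len(nrow(obs))) {
    p <- 1 - exp(-lam2 * obs$rho[i] * dt)
    brute <- brute + if (obs$started[i]) log(p) else log(1 - p)
  }
  expect_equal(as.numeric(start_loglik(obs, m2, c(lambda2 = lam2))), brute)
})

test_that("the combined equation nests the pure linear model exactly", {
  set.seed(21)
  b <- simulate_bout(sim_config(), N = 15)
  obs <- make_start_observations(b, 0.1)
  full <- hazard_model("start", c("L1", "L2", "L3", "L4"))
  m2 <- hazard_model("start", "L2")
  expect_identical(
    as.numeric(start_loglik(obs, full, c(lambda1 = 0, lambda2 = 1.9,
                                         lambda3 = 0, lambda4 = 0))),
    as.numeric(start_loglik(obs, m2, c(lambda2 = 1.9))))
})

test_that("a model that cannot explain an observed start returns -Inf", {
  # neighbour-only model, but the second starter has no started neighbour
  b <- make_toy_bout(c(0, 1), c(3, 4), claps = list(c(0, 3), c(1, 4)))
  b$seat_col <- c(1L, 5L)                  # seats far apart: no adjacency
  obs <- make_start_observations(b, 0.5)
  ll <- start_loglik(obs, hazard_model("start", "L4"), c(lambda4 = 2))
  expect_identical(as.numeric(ll), -Inf)
  expect_match(attr(ll, "diagnostic"), "probability 0")
})

test_that("continuous-time log density converges under frame refinement", {
  # each observed start contributes log(1 - exp(-r*dt)) ~ log(r*dt), so the
  # raw log-likelihood shifts by log(2) per start when dt halves; the
  # frame-free quantity is loglik - n_starts*log(dt), whose residual dt
  # dependence is first order and must halve with dt
  set.seed(8)
  b <- simulate_bout(sim_config(), N = 18)
  m2 <- hazard_model("start", "L2")
  ll_dens <- function(dt) {
    obs <- make_start_observations(b, dt)
    as.numeric(start_loglik(obs, m2, c(lambda2 = 2.15))) -
      sum(obs$started) * log(dt)
  }
  # independent continuous-time oracle from the exact event times:
  # sum over starts of log(lambda*rho just before the start) minus the
  # integral of the hazard over every individual's susceptible exposure
  lam <- 2.15
  st <- sort(b$start_time)
  N <- length(st)
  exact <- 0
  for (j in 2:N) {
    ev <- st[st < st[j]]
    ends <- c(ev[-1], st[j])
    exact <- exact + log(lam * length(ev) / N) -
      lam * sum((ends - ev) * seq_along(ev) / N)
  }
  err <- vapply(c(0.1, 0.025, 0.00625), function(dt)
    abs(ll_dens(dt) - exact), numeric(1))
  expect_lt(err[3], err[1])
  expect_lt(err[3] / abs(exact), 0.01)
})

test_that("vectorized multi-draw likelihoods equal the scalar path", {
  set.seed(13)
  bl <- bout_list(lapply(1:2, function(i)
    simulate_bout(sim_config(), N = 10, talk_id = as.character(i))))
  obs <- make_start_observations(bl, 0.1)
  for (terms in list("L2", c("L1", "L3"), c("L2", "L4"), "gaussian")) {
    m <- hazard_model("start", terms)
    th <- applause:::sample_prior(applause_priors(), m$params, 6)
    fast <- applause:::start_loglik_draws(obs, m, th)
    slow <- vapply(seq_len(6), function(j)
      as.numeric(start_loglik(obs, m, th[j, ])), numeric(1))
    expect_equal(fast, slow, tolerance = 1e-10)
  }
})
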