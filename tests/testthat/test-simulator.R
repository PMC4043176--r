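test_that("start waiting times follow the competing-exponentials law", {
  cfg <- sim_config(lambda = 2.15)
  # N = 2: a single waiting time ~ Exp(lambda/2), mean 2/lambda
  set.seed(1)
  w <- replicate(1e5, simulate_starts(cfg, N = 2)[2])
  expect_equal(mean(w), 2 / 2.15, tolerance = 0.01)
  # literal-proportion reading divides the total rate by N
  set.seed(1)
  wl <- replicate(2e4, simulate_starts(sim_config(lambda = 2.15,
                                                  literal_rate = TRUE),
                                       N = 2)[2])
  expect_equal(mean(wl) / (2 / 2.15), 2, tolerance = 0.05)
})

test_that("mean first-to-last start interval matches the harmonic formula", {
  set.seed(2)
  e <- run_ensemble(sim_config(), n_runs = 1e4)
  expected <- (2 / 2.15) * sum(1 / seq_len(19))
  expect_equal(mean(e$summaries$start_spread), expected, tolerance = 0.02)
})

test_that("simulation is reproducible given a seed", {
  b1 <- simulate_bout(sim_config(), seed = 77)
  b2 <- simulate_bout(sim_config(), seed = 77)
  expect_identical(b1$start_time, b2$start_time)
  expect_identical(b1$clap_times, b2$clap_times)
  e1 <- run_ensemble(sim_config(), n_runs = 50, seed = 5)$summaries
  e2 <- run_ensemble(sim_config(), n_runs = 50, seed = 5)$summaries
  expect_identical(e1, e2)
})

test_that("a certain stop probability stops everyone after one clap", {
  set.seed(3)
  b <- simulate_bout(sim_config(gamma2 = 0, gamma3 = 30, n_max = 30))
  expect_true(all(vapply(b$clap_times, length, integer(1)) == 1L))
  expect_equal(b$start_time, b$stop_time)
})

test_that("independent stopping follows the inhomogeneous geometric law", {
  # with gamma2 = 0 each individual's clap count is independent with
  # p(n) = h(n) * prod_{k<n} (1 - h(k)), h(n) = gamma3 * n / n_max
  g3 <- 0.2; n_max <- 30
  set.seed(4)
  e <- run_ensemble(sim_config(gamma2 = 0, gamma3 = g3, n_max = n_max),
                    n_runs = 250, keep_bouts = TRUE)
  counts <- unlist(lapply(e$bouts, function(b)
    vapply(b$clap_times, length, integer(1))))
  h <- pmin(g3 * (1:200) / n_max, 1)
  pmf <- h * cumprod(c(1, 1 - h[-200]))
  # chi-squared goodness of fit on bins with expected count >= 5
  brk <- c(0, 5, 8, 10, 12, 14, 16, 18, 20, 23, Inf)
  obs_bin <- table(cut(counts, brk))
  exp_bin <- vapply(seq_len(length(brk) - 1), function(i)
    sum(pmf[(1:200) > brk[i] & (1:200) <= brk[i + 1]]), numeric(1))
  chi <- sum((as.numeric(obs_bin) - length(counts) * exp_bin)^2 /
               (length(counts) * exp_bin))
  expect_lt(chi, qchisq(0.999, df = length(exp_bin) - 1))
})

test_that("every run terminates with a schema-valid bout", {
  set.seed(5)
  for (r in 1:10) {
    b <- simulate_bout(sim_config(), N = sample(5:25, 1))
    expect_s3_class(b, "bout")          # construction runs full validation
    expect_true(all(!is.na(b$stop_time)))
    expect_true(all(vapply(seq_len(nrow(b)), function(i)
      length(b$clap_times[[i]]) >= 1, logical(1))))
  }
})

test_that("degenerate configurations are rejected", {
  expect_error(simulate_starts(sim_config(lambda = 0)), "never spreads")
  expect_error(simulate_bout(sim_config(gamma1 = 0, gamma2 = 0.5,
                                        gamma3 = 0)),
               "not terminate")
})

test_that("ensemble summaries match the bout-level computation", {
  # the C++ summary path and the R bout path consume the same RNG stream
  # for the first run's start and clap draws
  cfg <- sim_config()
  set.seed(123)
  m <- applause:::sim_ensemble_cpp(1L, cfg$N, cfg$lambda, FALSE, FALSE, 1L,
                                   cfg$gamma1, cfg$gamma2, cfg$gamma3,
                                   cfg$n_max, cfg$interval_mean,
                                   cfg$interval_sd, cfg$interval_min)
  set.seed(123)
  b <- simulate_bout(cfg)
  s <- summarize_bouts(b)$per_bout
  expect_equal(unname(m[1, "start_spread"]), s$start_spread)
  expect_equal(unname(m[1, "stop_spread"]), s$stop_spread)
  expect_equal(unname(m[1, "length"]), s$length)
  expect_equal(unname(m[1, "mean_claps"]), s$mean_claps)
})

test_that("claps per person are over-dispersed relative to Poisson", {
  set.seed(6)
  e <- run_ensemble(sim_config(), n_runs = 1500)
  x <- e$summaries$mean_claps
  expect_gt(var(x) / mean(x), 1)
})

test_that("large-N ensemble means track the mean-field equations", {
  # mean-field regime: a 10% initial clapping fraction avoids the O(1 s)
  # take-off jitter of a single initiator, and moderate per-clap stopping
  # probabilities keep the per-second conversion p / 0.28 accurate
  set.seed(42)
  N <- 2000; n0 <- 200
  cfg <- sim_config(N = N, n0 = n0, gamma1 = 0.01, gamma2 = 0.08,
                    gamma3 = 0)
  grid <- seq(0, 25, by = 0.25)
  runs <- 30
  acc <- matrix(0, length(grid), 3)
  for (r in seq_len(runs)) {
    tr <- audience_trajectory(simulate_bout(cfg), grid)
    acc <- acc + cbind(1 - tr$rho_clapping, tr$clapping_now, tr$rho_stopped)
  }
  acc <- acc / runs
  ode <- mean_field_trajectory(
    ode_params(lambda2 = 2.15, gamma1 = 0.01 / 0.28, gamma2 = 0.08 / 0.28,
               S0 = 1 - n0 / N, I0 = n0 / N), horizon = 25, step = 0.25)
  expect_lt(max(abs(acc[, 1] - ode$S)), 0.03)
  expect_lt(max(abs(acc[, 2] - ode$I)), 0.03)
  expect_lt(max(abs(acc[, 3] - ode$R)), 0.03)
})
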