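test_that("bout summaries compute the interval statistics by hand", {
  s <- summarize_bouts(toy_bout3())
  p <- s$per_bout
  expect_equal(p$start_spread, 2)
  expect_equal(p$stop_spread, 2)
  expect_equal(p$length, 6)
  expect_equal(p$first_stop, 4)
  expect_equal(p$mean_claps, 5)
  # identical bouts have zero standard error
  s12 <- summarize_bouts(bout_list(replicate(12, toy_bout3(),
                                             simplify = FALSE)))
  # latency is unrecorded (NA) for hand-built bouts; all real stats have SE 0
  expect_true(all(s12$means$se[s12$means$statistic != "first_start_latency"]
                  == 0))
  # single starter: zero spread, flagged
  b1 <- make_toy_bout(c(0, NA), c(3, NA), claps = list(c(0, 1, 2, 3), NULL))
  p1 <- summarize_bouts(b1)$per_bout
  expect_equal(p1$start_spread, 0)
  expect_true(p1$single_starter)
})

test_that("S/I/R curves aggregate bouts with interquartile bands", {
  bl <- bout_list(replicate(6, toy_bout3(), simplify = FALSE))
  cur <- sir_curves(bl)
  # identical bouts: zero-width bands
  expect_equal(cur$started_lo, cur$started_hi)
  expect_equal(cur$started_lo, cur$started_med)
  # bands contain the median by construction, medians monotone
  set.seed(61)
  e <- run_ensemble(sim_config(), n_runs = 40, keep_bouts = TRUE)
  cr <- sir_curves(e$bouts)
  expect_true(all(cr$started_lo <= cr$started_med + 1e-12 &
                    cr$started_med <= cr$started_hi + 1e-12))
  expect_true(all(diff(cr$started_med) >= -1e-12))
  expect_true(all(diff(cr$stopped_med) >= -1e-12))
})

test_that("the median currently-clapping curve is unimodal over many bouts", {
  set.seed(65)
  e <- run_ensemble(sim_config(), n_runs = 1000, keep_bouts = TRUE)
  cr <- sir_curves(e$bouts, time_grid = seq(0, 10, by = 0.1))
  m <- cr$clapping_med
  # at most one switch from rising to falling (tolerance for plateaus)
  d <- diff(m)
  d <- d[abs(d) > 1e-9]
  switches <- sum(diff(sign(d)) != 0)
  expect_lte(switches, 1L)
})

test_that("claps distribution reports overdispersion and coverage", {
  set.seed(62)
  e <- run_ensemble(sim_config(), n_runs = 1200)
  obs12 <- run_ensemble(sim_config(), n_runs = 12)$summaries$mean_claps
  cd <- claps_distribution(e, observed = obs12)
  expect_gt(cd$variance_ratio, 1)
  expect_equal(sum(cd$proportion), 1, tolerance = 1e-12)
  expect_gte(sum(cd$observed$inside), 10)   # central 95% holds most draws
  # degenerate ensemble: single bin, matching observation trivially inside
  cd0 <- claps_distribution(rep(10, 150), observed = 10)
  expect_equal(sum(cd0$proportion > 0), 1L)
  expect_true(all(cd0$observed$inside))
  expect_error(claps_distribution(rep(10, 50)), "at least 100")
})

test_that("consistency test recovers extreme orders exactly", {
  set.seed(63)
  base <- generate_study(study_design(group_sizes = c(10, 10),
                                      non_starters = 0))
  # talk 2 rebuilt with identical start/stop order as talk 1
  same <- bout_list(list(base[[1]], clone_with_order(base[[1]], "2", FALSE)))
  ct <- consistency_test(same, n_randomizations = 200, seed = 1)
  expect_equal(ct$median_rho_start, 1)
  expect_lt(ct$p_start, 0.05)
  rev2 <- bout_list(list(base[[1]], clone_with_order(base[[1]], "2", TRUE)))
  ctr <- consistency_test(rev2, n_randomizations = 200, seed = 1)
  expect_equal(ctr$median_rho_start, -1)
})

test_that("null p-values are uniform under no consistency effect", {
  set.seed(64)
  des <- study_design(group_sizes = c(12, 12, 12, 12), non_starters = 0)
  pv <- replicate(120, {
    bl <- generate_study(des, consistency = 0)
    consistency_test(bl, n_randomizations = 199)$p_start
  })
  d <- suppressWarnings(stats::ks.test(pv, "punif")$statistic)
  expect_lt(unname(d), 0.15)
})

test_that("groups with too few shared starters are excluded", {
  b1 <- make_toy_bout(c(0, 1, 2), c(4, 5, 6))
  b2 <- make_toy_bout(c(0, NA, NA), c(4, NA, NA),
                      claps = list(c(0, 2, 4), NULL, NULL), talk_id = "2")
  expect_error(suppressMessages(consistency_test(bout_list(list(b1, b2)))),
               "3 shared starters")
})
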