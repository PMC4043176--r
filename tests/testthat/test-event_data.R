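test_that("CSV reading builds a validated bout from minimal input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "group_id,talk_id,individual_id,seat_row,seat_col,start_time,stop_time,clap_times",
    "a,1,p1,1,1,0.0,3.0,0;1;2;3",
    "a,1,p2,1,2,0.5,3.5,0.5;1.5;2.5;3.5"), f)
  bl <- read_bouts(f)
  expect_length(bl, 1L)
  expect_equal(attr(bl[[1]], "N"), 2L)
  expect_equal(min(bl[[1]]$start_time), 0)
})

test_that("invariant violations are rejected with the record named", {
  expect_error(make_toy_bout(c(0, 1), c(4, 0.5),
                             claps = list(NULL, NULL)),
               "stop_time < start_time.*i02")
  expect_error(make_toy_bout(c(0, 1), c(4, 5),
                             claps = list(c(0, 2, 1, 4), c(1, 3, 5))),
               "not strictly increasing.*i01")
  expect_error(make_toy_bout(c(0, 1), c(4, 5),
                             claps = list(c(0, 2, 4), c(1.5, 3, 5))),
               "span")
  # non-starter with a stop time
  rec <- data.frame(individual_id = c("a", "b"), seat_row = 1,
                    seat_col = 1:2, start_time = c(0, NA),
                    stop_time = c(2, 3))
  expect_error(bout("g", "1", rec, shift_origin = FALSE), "non-starter")
})

test_that("synthetic study output round-trips through CSV and JSON", {
  set.seed(31)
  bl <- generate_study(study_design(group_sizes = c(6, 5), non_starters = 1))
  for (fmt in c("csv", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_bouts(bl, f, fmt)
    bl2 <- read_bouts(f, fmt)
    expect_length(bl2, length(bl))
    for (i in seq_along(bl)) {
      a <- bl[[i]]; b <- bl2[[i]]
      expect_equal(attr(b, "group_id"), attr(a, "group_id"))
      expect_equal(b$individual_id, a$individual_id)
      expect_equal(b$start_time, a$start_time, tolerance = 1e-10)
      expect_equal(b$stop_time, a$stop_time, tolerance = 1e-10)
      expect_equal(unlist(b$clap_times), unlist(a$clap_times),
                   tolerance = 1e-10)
    }
  }
})

test_that("audience trajectory walks the toy event sequence exactly", {
  b <- toy_bout3()
  tr <- audience_trajectory(b, c(0, 0.5, 1, 1.5, 2, 3, 4, 4.5, 5, 6, 7))
  expect_equal(tr$rho_clapping,
               c(1, 1, 2, 2, 3, 3, 3, 3, 3, 3, 3) / 3)
  expect_equal(tr$rho_stopped, c(0, 0, 0, 0, 0, 0, 1, 1, 2, 3, 3) / 3)
  expect_equal(tr$clapping_now, tr$rho_clapping - tr$rho_stopped)
  # origin and absorbing end state
  expect_equal(tr$rho_clapping[1], 1 / 3)
  expect_equal(tr$rho_stopped[nrow(tr)], 1)
  expect_error(audience_trajectory(make_toy_bout(NA_real_, NA_real_)),
               "no starters")
})

test_that("trajectory fractions are monotone on simulated bouts", {
  set.seed(4)
  for (r in 1:5) {
    b <- simulate_bout(sim_config(), N = 12)
    tr <- audience_trajectory(b, seq(0, max(b$stop_time), by = 0.1))
    expect_true(all(diff(tr$rho_clapping) >= 0))
    expect_true(all(diff(tr$rho_stopped) >= 0))
  }
})

test_that("start observations cover susceptible exposure frame by frame", {
  b <- toy_bout3()
  dt <- 0.1
  obs <- make_start_observations(b, dt)
  # the initiator is conditioned on and contributes nothing
  expect_false("i01" %in% obs$individual_id)
  # frame counts: floor(start/dt) + 1 frames per later starter
  expect_equal(sum(obs$individual_id == "i02"), floor(1 / dt) + 1)
  expect_equal(sum(obs$individual_id == "i03"), floor(2 / dt) + 1)
  # exactly one started frame per starter, in the frame containing the start
  expect_equal(sum(obs$started), 2L)
  expect_equal(obs$t0[obs$started], c(1, 2))
  # individual starting within the first frame: one observation
  b2 <- make_toy_bout(c(0, 0.05), c(1, 1), claps = list(c(0, 1), c(0.05, 1)))
  o2 <- make_start_observations(b2, dt)
  expect_equal(nrow(o2), 1L)
  expect_true(o2$started)
})

test_that("non-starters contribute susceptible frames for the whole bout", {
  b <- make_toy_bout(c(0, 1, NA), c(3, 4, NA),
                     claps = list(c(0, 1.5, 3), c(1, 2.5, 4), NULL))
  obs <- make_start_observations(b, 0.5)
  ns <- obs[obs$individual_id == "i03", ]
  expect_equal(nrow(ns), ceiling(4 / 0.5))
  expect_false(any(ns$started))
  # conservation: total frames match the hand formula
  expect_equal(nrow(obs), (floor(1 / 0.5) + 1) + ceiling(4 / 0.5))
})

test_that("state snapshots use the full audience as denominator", {
  b <- toy_bout3()
  obs <- make_start_observations(b, 0.5)
  i3 <- obs[obs$individual_id == "i03", ]
  expect_equal(i3$rho, c(1, 1, 2, 2, 3) / 3)
  # i03's neighbours on the row are only i02 (started at 1)
  expect_equal(i3$nb, c(0, 0, 1, 1, 1))
})

test_that("stop observations emit one row per clap with the stop last", {
  b <- toy_bout3()
  obs <- make_stop_observations(b)
  expect_equal(nrow(obs), 5 + 5 + 5)
  expect_equal(attr(obs, "n_max_observed"), 5L)
  i1 <- obs[obs$individual_id == "i01", ]
  expect_equal(i1$n, 1:5)
  expect_equal(i1$stopped, c(rep(FALSE, 4), TRUE))
  # rho_stopped at the instant of each clap, own stop excluded
  expect_equal(obs$rho_stopped[obs$individual_id == "i02"],
               c(0, 0, 0, 0, 1) / 3)
})

test_that("restriction keeps only claps strictly after the first stop", {
  b <- toy_bout3()
  all_obs <- make_stop_observations(b)
  res <- make_stop_observations(b, restrict_after_first_stop = TRUE)
  # first stop is at t = 4; hand count of claps at or before 4: all of i01's
  # five, i02's claps at 1..4 (4), i03's at 2..4 (3)
  expect_equal(nrow(res), nrow(all_obs) - (5 + 4 + 3))
  expect_true(all(res$t > 4))
  expect_true(all(res$rho_stopped > 0))
})

test_that("missing clap times error and can be reconstructed", {
  b <- make_toy_bout(c(0, 0.5), c(2.8, 3.3), claps = list(NULL, NULL))
  expect_error(make_stop_observations(b), "reconstruct")
  b2 <- reconstruct_clap_times(b, interval_mean = 0.28)
  expect_equal(length(b2$clap_times[[1]]), round(2.8 / 0.28) + 1)
  expect_equal(b2$clap_times[[1]][1], b2$start_time[1])
  expect_equal(max(b2$clap_times[[2]]), b2$stop_time[2])
  expect_silent(make_stop_observations(b2))
})

test_that("seat neighbours follow grid adjacency", {
  rec <- data.frame(individual_id = as.character(1:6),
                    seat_row = rep(1:2, each = 3), seat_col = rep(1:3, 2),
                    start_time = c(0, 1, 2, 3, 4, 5),
                    stop_time = c(9, 9, 9, 9, 9, 9))
  rec$clap_times <- rep(list(NULL), 6)
  b <- bout("g", "1", rec, shift_origin = FALSE)
  nb <- seat_neighbours(b)
  expect_setequal(b$individual_id[nb[[which(b$individual_id == "1")]]],
                  c("2", "4"))
  nb_diag <- seat_neighbours(b, diagonal = TRUE)
  expect_setequal(b$individual_id[nb_diag[[which(b$individual_id == "1")]]],
                  c("2", "4", "5"))
})
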