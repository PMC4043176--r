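#' Configuration of the stochastic bout simulator
#'
#' Defaults are the best-fit combined model: linear social starting at
#' `lambda = 2.15` per second, stopping after each clap with probability
#' `gamma2 * R + gamma3 * n / n_max` (`gamma2 = 0.63`, `gamma3 = 0.05`,
#' `n_max = 30`), clap intervals `Normal(0.28 s, 0.09 s)` truncated below at
#' 0.01 s, and an audience of `N = 20`.
#'
#' Two start-stage readings are available. The default (`literal_rate =
#' FALSE`) treats `lambda * (I + R)` as the hazard of each susceptible
#' individual, so the total rate of the next start is
#' `lambda * (N - k) * k / N` when `k` have started — consistent with the
#' per-individual starting hazard the model selection fits. The
#' literal-proportion variant (`literal_rate = TRUE`) uses
#' `lambda * S * (I + R)` as the total rate.
#'
#' @param N audience size, or a vector of sizes recycled across ensemble
#'   runs.
#' @param lambda social starting rate (per second, `> 0`).
#' @param start_response `"linear"` (rate proportional to the started
#'   fraction) or `"quadratic"` (proportional to its square; the best-fit
#'   alternative uses `lambda = 4.0`).
#' @param literal_rate use the literal total-rate reading (see Details).
#' @param n0 number of individuals clapping at time 0 (default 1, the
#'   initiator).
#' @param gamma1,gamma2,gamma3 per-clap stopping terms: constant,
#'   proportional to the stopped fraction R, and proportional to the
#'   individual's clap count over `n_max`. `gamma1` defaults to 0 (the
#'   two-term best-fit rule); a positive value gives the constant-initiation
#'   variant matching the mean-field equations.
#' @param n_max normalizing clap count.
#' @param interval_mean,interval_sd,interval_min clap-interval distribution
#'   (seconds); draws below `interval_min` are redrawn.
#' @param n_runs default ensemble size for [run_ensemble()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(N = 20, lambda = 2.15,
                       start_response = c("linear", "quadratic"),
                       literal_rate = FALSE, n0 = 1,
                       gamma1 = 0, gamma2 = 0.63, gamma3 = 0.05, n_max = 30,
                       interval_mean = 0.28, interval_sd = 0.09,
                       interval_min = 0.01, n_runs = 1) {
  start_response <- match.arg(start_response)
  stopifnot(all(N >= 2), lambda >= 0, gamma1 >= 0, gamma2 >= 0, gamma3 >= 0,
            n_max > 0, interval_mean > 0, interval_sd >= 0, n0 >= 1,
            n_runs >= 1)
  structure(list(N = as.integer(N), lambda = lambda,
                 start_response = start_response,
                 literal_rate = literal_rate, n0 = as.integer(n0),
                 gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3,
                 n_max = as.integer(n_max), interval_mean = interval_mean,
                 interval_sd = interval_sd, interval_min = interval_min,
                 n_runs = n_runs),
            class = "sim_config")
}

check_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$lambda <= 0)
    stop("lambda = 0: the bout never spreads beyond the initiator")
  if (config$gamma1 <= 0 && config$gamma3 <= 0)
    stop("gamma1 = gamma3 = 0: no individual can ever initiate stopping, ",
         "the simulation would not terminate")
  invisible(config)
}

#' Simulate the starting stage of a bout
#'
#' The initiator claps at time 0; thereafter the waiting time to each
#' subsequent start is exponentially distributed with the configured rate
#' (see [sim_config()]), until everyone has started.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @param N audience size override.
#' @return Strictly increasing start times, `t[1] = 0`, length `N`.
#' @export
simulate_starts <- function(config = sim_config(), seed = NULL,
                            N = config$N[1L]) {
  check_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  sim_starts_cpp(N, config$lambda, config$start_response == "quadratic",
                 config$literal_rate, config$n0)
}

#' Simulate the stopping stage of a bout
#'
#' Event-driven loop over next-clap times: the individual with the earliest
#' pending clap performs it, stops with the per-clap probability
#' `gamma1 + gamma2 * R + gamma3 * n / n_max` (clamped to `[0, 1]`, with `R`
#' the currently stopped fraction of the audience), or claps again after a
#' truncated-Normal interval. Runs until all individuals have stopped.
#'
#' @param start_times start times from [simulate_starts()].
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @param group_id,talk_id identifiers for the returned bout.
#' @return A [bout()] with full per-clap times; seats are assigned at
#'   random on a 3-row grid.
#' @export
simulate_stops <- function(start_times, config = sim_config(), seed = NULL,
                           group_id = "sim", talk_id = "1") {
  check_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  claps <- sim_stops_cpp(start_times, config$gamma1, config$gamma2,
                         config$gamma3, config$n_max, config$interval_mean,
                         config$interval_sd, config$interval_min)
  n <- length(start_times)
  seats <- assign_seats(n)[sample.int(n), , drop = FALSE]
  records <- data.frame(individual_id = sprintf("i%03d", seq_len(n)),
                        seat_row = seats$seat_row, seat_col = seats$seat_col,
                        start_time = as.numeric(start_times),
                        stop_time = vapply(claps, function(ct) ct[length(ct)],
                                           numeric(1)),
                        stringsAsFactors = FALSE)
  records$clap_times <- lapply(claps, as.numeric)
  bout(group_id, talk_id, records, shift_origin = FALSE)
}

#' Simulate one complete bout
#'
#' @inheritParams simulate_stops
#' @param config a [sim_config()].
#' @param N audience size override.
#' @return A [bout()].
#' @export
simulate_bout <- function(config = sim_config(), seed = NULL,
                          N = config$N[1L], group_id = "sim", talk_id = "1") {
  if (!is.null(seed)) set.seed(seed)
  simulate_stops(simulate_starts(config, N = N), config,
                 group_id = group_id, talk_id = talk_id)
}

#' Simulate an ensemble of bouts
#'
#' Repeats the full bout simulation `n_runs` times (audience sizes recycled
#' from `config$N`) and returns per-run summary statistics: the interval
#' from first to last start (`start_spread`), from first to last stop
#' (`stop_spread`), the bout length from first start to last stop
#' (`length`), the mean number of claps per individual (`mean_claps`) and
#' the time of the first stop. With `keep_bouts = TRUE` the simulated bouts
#' themselves are returned as well (memory permitting).
#'
#' @param config a [sim_config()].
#' @param n_runs number of runs (default `config$n_runs`).
#' @param seed optional integer seed.
#' @param keep_bouts also return the bouts as a [bout_list()].
#' @return A list of class `applause_ensemble` with elements `summaries`
#'   (data.frame, one row per run) and `bouts` (or `NULL`).
#' @export
run_ensemble <- function(config = sim_config(), n_runs = config$n_runs,
                         seed = NULL, keep_bouts = FALSE) {
  check_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  if (keep_bouts) {
    sizes <- rep_len(config$N, n_runs)
    bouts <- lapply(seq_len(n_runs), function(r)
      simulate_bout(config, N = sizes[r], group_id = "sim",
                    talk_id = as.character(r)))
    summaries <- do.call(rbind, lapply(bouts, function(b) {
      s <- summarize_bouts(b)$per_bout
      s[, c("N", "start_spread", "stop_spread", "length", "mean_claps",
            "first_stop")]
    }))
    bouts <- bout_list(bouts)
  } else {
    summaries <- as.data.frame(sim_ensemble_cpp(
      n_runs, config$N, config$lambda,
      config$start_response == "quadratic", config$literal_rate, config$n0,
      config$gamma1, config$gamma2, config$gamma3, config$n_max,
      config$interval_mean, config$interval_sd, config$interval_min))
    bouts <- NULL
  }
  structure(list(summaries = summaries, bouts = bouts, config = config),
            class = "applause_ensemble")
}

#' @export
print.applause_ensemble <- function(x, ...) {
  s <- x$summaries
  cat(sprintf("Applause ensemble: %d runs\n", nrow(s)))
  cat(sprintf("  mean bout length %.2f s, start spread %.2f s, stop spread %.2f s, %.1f claps/person\n",
              mean(s$length), mean(s$start_spread), mean(s$stop_spread),
              mean(s$mean_claps)))
  invisible(x)
}

# seats distributed as evenly as possible across three rows
assign_seats <- function(N, rows = 3) {
  per <- rep(N %/% rows, rows) + (seq_len(rows) <= N %% rows)
  data.frame(seat_row = rep(seq_len(rows), per),
             seat_col = unlist(lapply(per, seq_len)))
}
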