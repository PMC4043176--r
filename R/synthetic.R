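#' Description of the experimental design to emulate
#'
#' The reference design: six audience groups of sizes 20, 20, 20, 18, 16
#' and 13 (107 students in total), each attending two talks, seated in
#' three rows; 3 of the 107 never clap. The latency from the end of the
#' talk to the first clap is Normal(2.1 s, 0.6 s) truncated at 0 (recorded
#' as bout metadata; bout times are relative to the first clap).
#'
#' @param group_sizes audience size per group.
#' @param talks_per_group bouts per group.
#' @param rows seating rows.
#' @param non_starters number of individuals (study-wide) who never clap.
#' @param latency_mean,latency_sd first-clap latency distribution (s).
#' @return A list of class `study_design`.
#' @export
study_design <- function(group_sizes = c(20, 20, 20, 18, 16, 13),
                         talks_per_group = 2, rows = 3, non_starters = 3,
                         latency_mean = 2.1, latency_sd = 0.6) {
  stopifnot(all(group_sizes >= 2), talks_per_group >= 1, rows >= 1,
            non_starters >= 0, non_starters < sum(group_sizes))
  structure(list(group_sizes = as.integer(group_sizes),
                 talks_per_group = as.integer(talks_per_group),
                 rows = as.integer(rows),
                 non_starters = as.integer(non_starters),
                 latency_mean = latency_mean, latency_sd = latency_sd),
            class = "study_design")
}

rtnorm_min <- function(n, mean, sd, min = 0) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < min
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < min
  }
  x
}

#' Generate a study-shaped synthetic dataset under known models
#'
#' Simulates complete clap-event data with the experimental design of
#' [study_design()] under any candidate starting and stopping model —
#' including neighbour-driven terms, evaluated on the seating grid, and the
#' Gaussian variants — so that parameter recovery and model selection can
#' be validated against ground truth. Starting is a competing-exponentials
#' event loop over per-individual hazards from [start_rate()] (hazards are
#' piecewise constant between starts); stopping is the event-driven
#' per-clap loop of the simulator with probabilities from
#' [stop_probability()] or [gaussian_stop_probability()].
#'
#' Individual consistency: with `consistency > 0`, each individual carries
#' a latent multiplicative frailty on their starting hazard, shared across
#' their group's two talks, so that eager individuals tend to start early
#' in both — reproducing the observed cross-talk correlation of starting
#' orders. `consistency = 0` gives independent orders (and a well-specified
#' likelihood); `consistency = 1` gives deterministic, identical orders.
#' Use [calibrate_consistency()] to find the effect size matching a target
#' Spearman correlation. Frailty requires a rate-based starting model.
#'
#' @param design a [study_design()].
#' @param start_model,start_params a `"start"`-family [hazard_model()] and
#'   its named parameters.
#' @param stop_model,stop_params a `"stop"`-family [hazard_model()] and its
#'   named parameters; the model must be able to initiate stopping (a
#'   constant or clap-count term, or the Gaussian model) or generation
#'   errors before starting.
#' @param seed optional integer seed.
#' @param consistency individual-consistency effect size in `[0, 1]`.
#' @param n_max normalizing clap count for the clap-count stopping term.
#' @param interval_mean,interval_sd,interval_min clap-interval distribution.
#' @param diagonal count diagonal seats as neighbours.
#' @return A [bout_list()] of `length(group_sizes) * talks_per_group`
#'   bouts, with the generating models, parameters and seed in attribute
#'   `truth`.
#' @export
generate_study <- function(design = study_design(),
                           start_model = hazard_model("start", "lambda2"),
                           start_params = c(lambda2 = 2.15),
                           stop_model = hazard_model("stop", c("gamma2", "gamma3")),
                           stop_params = c(gamma2 = 0.63, gamma3 = 0.05),
                           seed = NULL, consistency = 0, n_max = 30,
                           interval_mean = 0.28, interval_sd = 0.09,
                           interval_min = 0.01, diagonal = FALSE) {
  stopifnot(inherits(design, "study_design"),
            start_model$family == "start", stop_model$family == "stop",
            consistency >= 0, consistency <= 1)
  if (!stop_model$gaussian) {
    check_active(stop_params, stop_model)
    ini <- full_params(stop_params, paste0("gamma", 1:4))
    if (ini[["gamma1"]] <= 0 && ini[["gamma3"]] <= 0)
      stop("stopping model ", stop_model$label, " with these parameters can ",
           "never initiate stopping (no constant or clap-count term)")
  }
  if (!start_model$gaussian) check_active(start_params, start_model)
  if (consistency > 0 && start_model$gaussian)
    stop("consistency frailty requires a rate-based starting model")
  if (!is.null(seed)) set.seed(seed)

  n_groups <- length(design$group_sizes)
  total <- sum(design$group_sizes)
  group_of <- rep(seq_len(n_groups), design$group_sizes)
  ns_global <- sample.int(total, design$non_starters)
  bouts <- list()
  for (g in seq_len(n_groups)) {
    N <- design$group_sizes[g]
    ids <- sprintf("g%d_i%02d", g, seq_len(N))
    seats <- assign_seats(N, design$rows)[sample.int(N), , drop = FALSE]
    non_starter <- which(group_of == g) %in% ns_global
    if (consistency >= 1) {
      z <- stats::rnorm(N)
      frail <- rep(1, N)
      forced <- order(z, decreasing = TRUE)
      forced <- forced[!non_starter[forced]]
    } else {
      frail <- frailty_weights(N, consistency)
      forced <- NULL
    }
    for (talk in seq_len(design$talks_per_group)) {
      bouts[[length(bouts) + 1L]] <- generate_bout(
        N, ids, seats, non_starter, frail, start_model, start_params,
        stop_model, stop_params, n_max, interval_mean, interval_sd,
        interval_min, diagonal, design,
        group_id = paste0("g", g), talk_id = as.character(talk),
        forced_order = forced)
    }
  }
  out <- bout_list(bouts)
  attr(out, "truth") <- list(start_model = start_model$label,
                             start_params = start_params,
                             stop_model = stop_model$label,
                             stop_params = stop_params,
                             consistency = consistency, n_max = n_max,
                             seed = seed)
  out
}

# multiplicative starting-hazard frailties with a shared latent eagerness.
# The log-frailty scale tau = 6 e / (1 - e) is capped at 6 to keep waiting
# times within floating-point range (the cap saturates the achievable
# cross-talk correlation near 0.95); effect 1 is generated separately by
# forcing the start order to the latent ranks.
frailty_weights <- function(N, effect) {
  if (effect <= 0) return(rep(1, N))
  z <- stats::rnorm(N)
  tau <- min(6, 6 * effect / (1 - effect))
  exp(tau * z)
}

generate_bout <- function(N, ids, seats, non_starter, frail, start_model,
                          start_params, stop_model, stop_params, n_max,
                          interval_mean, interval_sd, interval_min, diagonal,
                          design, group_id, talk_id, forced_order = NULL) {
  nb_idx <- neighbours_from_seats(seats, diagonal)
  start_t <- rep(NA_real_, N)
  eligible <- which(!non_starter)
  if (!length(eligible)) stop("all individuals are non-starters")

  if (start_model$gaussian) {
    init <- sample(eligible, 1L)
    start_t[init] <- 0
    others <- setdiff(eligible, init)
    start_t[others] <- rtnorm_min(length(others), start_params[["mu"]],
                                  start_params[["sigma"]], 1e-6)
  } else if (!is.null(forced_order)) {
    # deterministic start order (consistency effect 1): the waiting time of
    # each stage is the competing-exponentials total, the starter identity
    # is fixed by the latent ranks
    start_t[forced_order[1L]] <- 0
    t <- 0
    for (k in seq_along(forced_order)[-1L]) {
      started <- !is.na(start_t)
      rho <- sum(started) / N
      sus <- which(is.na(start_t) & !non_starter)
      total <- sum(vapply(sus, function(i) {
        nb <- nb_idx[[i]]
        nbf <- if (length(nb)) mean(started[nb]) else 0
        start_rate(rho, nbf, start_params)
      }, numeric(1)))
      if (total <= 0) break
      t <- t + stats::rexp(1L) / total
      start_t[forced_order[k]] <- t
    }
  } else {
    init <- eligible[sample.int(length(eligible), 1L,
                                prob = frail[eligible] / sum(frail[eligible]))]
    start_t[init] <- 0
    t <- 0
    repeat {
      sus <- which(is.na(start_t) & !non_starter)
      if (!length(sus)) break
      started <- !is.na(start_t)
      rho <- sum(started) / N
      base <- vapply(sus, function(i) {
        nb <- nb_idx[[i]]
        nbf <- if (length(nb)) mean(started[nb]) else 0
        start_rate(rho, nbf, start_params)
      }, numeric(1))
      h <- frail[sus] * base
      if (all(h <= 0)) break  # nobody can be recruited any more
      w <- ifelse(h > 0, stats::rexp(length(h)) / h, Inf)
      k <- which.min(w)
      t <- t + w[k]
      start_t[sus[k]] <- t
    }
  }

  claps <- generate_stops(start_t, stop_model, stop_params, n_max, nb_idx, N,
                          interval_mean, interval_sd, interval_min)
  records <- data.frame(individual_id = ids, seat_row = seats$seat_row,
                        seat_col = seats$seat_col, start_time = start_t,
                        stop_time = vapply(claps, function(ct)
                          if (length(ct)) ct[length(ct)] else NA_real_,
                          numeric(1)),
                        stringsAsFactors = FALSE)
  records$clap_times <- claps
  b <- bout(group_id, talk_id, records, shift_origin = FALSE)
  attr(b, "first_start_latency") <- rtnorm_min(1L, design$latency_mean,
                                               design$latency_sd)
  b
}

# event-driven stopping stage under an arbitrary stopping model
generate_stops <- function(start_t, stop_model, stop_params, n_max, nb_idx,
                           N, interval_mean, interval_sd, interval_min) {
  claps <- rep(list(NULL), N)
  active <- which(!is.na(start_t))
  if (!length(active)) return(claps)
  nxt <- rep(Inf, N); nxt[active] <- start_t[active]
  nclap <- integer(N)
  stopped <- rep(FALSE, N)
  stop_t <- rep(NA_real_, N)
  remaining <- length(active)
  guard <- 0L
  while (remaining > 0L) {
    guard <- guard + 1L
    if (guard > 1e6) stop("stopping stage failed to terminate")
    i <- which.min(nxt)
    tm <- nxt[i]
    nclap[i] <- nclap[i] + 1L
    claps[[i]] <- c(claps[[i]], tm)
    if (stop_model$gaussian) {
      p <- gaussian_stop_probability(nclap[i], stop_params[["m"]],
                                     stop_params[["s"]])
    } else {
      nb <- nb_idx[[i]]
      nbf <- if (length(nb)) mean(stopped[nb]) else 0
      p <- stop_probability(sum(stopped) / N, nclap[i], nbf, stop_params,
                            n_max)
    }
    if (stats::runif(1L) < p) {
      stopped[i] <- TRUE
      stop_t[i] <- tm
      nxt[i] <- Inf
      remaining <- remaining - 1L
    } else {
      nxt[i] <- tm + rtnorm_min(1L, interval_mean, interval_sd, interval_min)
    }
  }
  claps
}

neighbours_from_seats <- function(seats, diagonal = FALSE) {
  fake <- data.frame(seat_row = seats$seat_row, seat_col = seats$seat_col)
  class(fake) <- c("bout", "data.frame")
  seat_neighbours(fake, diagonal)
}

#' Calibrate the consistency effect size to a target correlation
#'
#' Finds, by bisection on repeated synthetic studies, the
#' `consistency` effect for [generate_study()] under which the expected
#' cross-talk Spearman correlation of starting orders (median across
#' groups, mean across studies) equals `target_rho`.
#'
#' @param target_rho target median Spearman correlation (e.g. 0.53).
#' @param design a [study_design()].
#' @param n_studies synthetic studies per candidate effect.
#' @param iterations bisection steps.
#' @param seed optional integer seed.
#' @param ... passed to [generate_study()] (models and parameters).
#' @return The calibrated effect size in `(0, 1)`.
#' @export
calibrate_consistency <- function(target_rho, design = study_design(),
                                  n_studies = 30, iterations = 7,
                                  seed = NULL, ...) {
  stopifnot(target_rho > 0, target_rho < 1)
  if (!is.null(seed)) set.seed(seed)
  med_rho <- function(effect) {
    mean(vapply(seq_len(n_studies), function(s) {
      bl <- generate_study(design, consistency = effect, ...)
      stats::median(cross_talk_rho(bl)$rho_start, na.rm = TRUE)
    }, numeric(1)))
  }
  lo <- 0; hi <- 1
  for (k in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    if (med_rho(mid) < target_rho) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# recover a study_design from observed bouts (used by simulate methods)
design_from_bouts <- function(bouts) {
  bouts <- as_bout_list(bouts)
  gids <- vapply(bouts, attr, "", "group_id")
  first <- !duplicated(gids)
  study_design(group_sizes = vapply(bouts[first], attr, 1L, "N"),
               talks_per_group = max(table(gids)),
               rows = max(vapply(bouts, function(b) max(b$seat_row), 1)),
               non_starters = sum(vapply(bouts[first], function(b)
                 sum(!starters(b)), numeric(1))))
}
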