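# small bouts and independent oracles used across the suite

# bout from explicit start/stop times; clap times at unit intervals between
# them unless given; seats in one row so everyone is everyone's neighbour
# only via left/right adjacency
make_toy_bout <- function(starts, stops, claps = NULL, group_id = "t",
                          talk_id = "1") {
  n <- length(starts)
  if (is.null(claps))
    claps <- lapply(seq_len(n), function(i)
      if (is.na(starts[i])) NULL else seq(starts[i], stops[i], by = 1))
  rec <- data.frame(individual_id = sprintf("i%02d", seq_len(n)),
                    seat_row = 1L, seat_col = seq_len(n),
                    start_time = starts, stop_time = stops,
                    stringsAsFactors = FALSE)
  rec$clap_times <- claps
  bout(group_id, talk_id, rec, shift_origin = FALSE)
}

# starts 0,1,2 / stops 4,5,6: the printed toy example used repeatedly
toy_bout3 <- function() make_toy_bout(c(0, 1, 2), c(4, 5, 6))

# --- grid-quadrature evidence oracle ------------------------------------
# Dense trapezoid quadrature of the evidence integral over the prior, fully
# independent of the package's importance-sampling path: the likelihood is
# evaluated through the scalar loglik functions, one grid point at a time.
quad_evidence <- function(model, obs, prior = applause_priors(),
                          n_grid = 161, n_max = NULL) {
  params <- model$params
  grids <- lapply(params, function(nm) {
    sup <- prior[[nm]]$support
    seq(sup[1], sup[2], length.out = n_grid)
  })
  names(grids) <- params
  wts <- lapply(grids, function(g) {
    w <- rep(diff(g)[1], length(g)); w[c(1, length(g))] <- w[1] / 2; w
  })
  if (is.null(n_max)) n_max <- attr(obs, "n_max_observed")
  ll_at <- function(th) {
    names(th) <- params
    if (model$family == "start") as.numeric(start_loglik(obs, model, th))
    else as.numeric(stop_loglik(obs, model, th, n_max = n_max))
  }
  if (length(params) == 1L) {
    lv <- vapply(grids[[1]], function(x)
      ll_at(x) + prior[[params]]$logd(x), numeric(1))
    lw <- log(wts[[1]])
  } else if (length(params) == 2L) {
    gr <- expand.grid(a = grids[[1]], b = grids[[2]])
    lv <- mapply(function(a, b)
      ll_at(c(a, b)) + prior[[params[1]]]$logd(a) + prior[[params[2]]]$logd(b),
      gr$a, gr$b)
    lw <- log(as.numeric(outer(wts[[1]], wts[[2]])))
  } else stop("oracle supports 1-2 parameters")
  keep <- is.finite(lv)
  if (!any(keep)) return(-Inf)
  m <- max(lv[keep])
  m + log(sum(exp(lv[keep] - m + lw[keep])))
}

# second-talk bout for the same individuals whose start/stop order copies
# (or reverses) the first talk's
clone_with_order <- function(b, talk_id = "2", reverse = FALSE) {
  n <- nrow(b)
  r <- rank(b$start_time)
  rs <- rank(b$stop_time)
  if (reverse) { r <- n + 1 - r; rs <- n + 1 - rs }
  starts <- (r - 1) * 0.2
  stops <- 3 + (rs - 1) * 0.2
  rec <- data.frame(individual_id = b$individual_id, seat_row = b$seat_row,
                    seat_col = b$seat_col, start_time = starts,
                    stop_time = stops, stringsAsFactors = FALSE)
  rec$clap_times <- lapply(seq_len(n), function(i)
    seq(starts[i], stops[i], length.out = 4))
  bout(attr(b, "group_id"), talk_id, rec, shift_origin = FALSE)
}

# study sizes used throughout: six groups, two talks each
study_sizes <- c(20, 20, 20, 18, 16, 13)

# 12 bouts from the event-driven simulator at the best-fit parameters
sim_study_bouts <- function(cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- rep(study_sizes, each = 2)
  bout_list(lapply(seq_along(sizes), function(i)
    simulate_bout(cfg, N = sizes[i], group_id = paste0("g", (i + 1) %/% 2),
                  talk_id = as.character(2 - i %% 2))))
}
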