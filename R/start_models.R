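#' Starting hazard of a susceptible individual
#'
#' The per-second rate at which a susceptible individual starts clapping,
#' as a linear combination of cues: a constant term, the fraction of the
#' audience already clapping (linear and quadratic), and the fraction of the
#' individual's seat neighbours already clapping.
#'
#' @param rho fraction of the audience already clapping (I + R), in `[0, 1]`.
#' @param nb fraction of the focal individual's seat neighbours already
#'   clapping, in `[0, 1]`.
#' @param params named numeric vector; any of `lambda1`, `lambda2`,
#'   `lambda3`, `lambda4` (per second, `>= 0`); missing terms are inactive
#'   (exactly 0).
#' @return Rate in claps-starting per second, vectorized over `rho`/`nb`.
#' @export
start_rate <- function(rho, nb = 0, params) {
  p <- full_params(params, paste0("lambda", 1:4))
  if (any(p < 0)) stop("negative starting rate parameter")
  p[["lambda1"]] + p[["lambda2"]] * rho + p[["lambda3"]] * rho^2 +
    p[["lambda4"]] * nb
}

full_params <- function(params, names_all) {
  stopifnot(!is.null(names(params)), all(names(params) %in% names_all))
  p <- stats::setNames(numeric(length(names_all)), names_all)
  p[names(params)] <- params
  p
}

#' Convert a per-second rate to a per-frame probability
#'
#' `1 - exp(-rate * dt)`: the probability that an event with constant hazard
#' `rate` occurs within a frame of length `dt`. For `rate * dt` small this is
#' approximately `rate * dt`, so likelihoods are stable under frame
#' refinement.
#'
#' @param rate hazard in events per second (`>= 0`).
#' @param dt frame length in seconds (`> 0`).
#' @return Probability in `[0, 1)`.
#' @export
start_frame_probability <- function(rate, dt) {
  stopifnot(all(rate >= 0), dt > 0)
  -expm1(-rate * dt)
}

#' Per-frame starting probability under the Gaussian reaction-time model
#'
#' Individuals wait for the bout's first clap and then start after a
#' normally distributed response time. The probability of starting in the
#' frame `[t0, t0 + dt)`, given not yet started by `t0`, is
#' `(Phi(t0 + dt) - Phi(t0)) / (1 - Phi(t0))` with `Phi` the Normal CDF with
#' mean `mu` and sd `sigma`. When the survivor `1 - Phi(t0)` underflows the
#' start is forced (probability 1).
#'
#' @param t0 frame start time (seconds after the first clap).
#' @param dt frame length (seconds).
#' @param mu,sigma mean and sd of the response time (seconds, `sigma > 0`).
#' @return Probability in `[0, 1]`, vectorized over `t0`.
#' @export
gaussian_start_probability <- function(t0, dt, mu, sigma) {
  stopifnot(sigma > 0, dt > 0)
  surv <- stats::pnorm(t0, mu, sigma, lower.tail = FALSE)
  num <- stats::pnorm(t0 + dt, mu, sigma) - stats::pnorm(t0, mu, sigma)
  p <- ifelse(surv <= .Machine$double.xmin, 1, pmin(pmax(num / surv, 0), 1))
  p
}

#' Log-likelihood of starting observations under a model
#'
#' Sums `log p` over frames in which the individual started and `log(1 - p)`
#' over frames in which they did not, with `p` the model's per-frame starting
#' probability. Returns `-Inf` (with a `diagnostic` attribute) when the model
#' assigns probability 0 to an observed start — the model cannot explain the
#' datum.
#'
#' @param obs observations from [make_start_observations()].
#' @param model a `"start"`-family [hazard_model()].
#' @param params named numeric vector of the model's parameters.
#' @param dt frame length; defaults to the `dt` attribute of `obs`.
#' @return Log-probability of the observation set (0 for an empty set).
#' @export
start_loglik <- function(obs, model, params, dt = attr(obs, "dt")) {
  stopifnot(inherits(model, "hazard_model"), model$family == "start")
  if (is.null(obs) || nrow(obs) == 0L) return(0)
  if (model$gaussian) {
    p <- gaussian_start_probability(obs$t0, dt, params[["mu"]], params[["sigma"]])
    lp <- ifelse(obs$started, log(p), log1p(-p))
  } else {
    check_active(params, model)
    r <- start_rate(obs$rho, obs$nb, params)
    p <- start_frame_probability(r, dt)
    lp <- ifelse(obs$started, log(p), -r * dt)
  }
  ll <- sum(lp)
  if (!is.finite(ll) && any(obs$started & !is.finite(lp)))
    attr(ll, "diagnostic") <- "model assigns probability 0 to an observed start"
  ll
}

check_active <- function(params, model) {
  extra <- setdiff(names(params), model$params)
  if (length(extra) && any(params[extra] != 0))
    stop("parameters inactive under model ", model$label, " must be 0: ",
         paste(extra, collapse = ", "))
  invisible(TRUE)
}

# --- vectorized multi-draw log-likelihoods (importance-sampling engine) --

# design matrix of active start terms, columns in model$params order
start_design <- function(obs, model) {
  cols <- list(lambda1 = rep(1, nrow(obs)), lambda2 = obs$rho,
               lambda3 = obs$rho^2, lambda4 = obs$nb)
  do.call(cbind, cols[model$params])
}

# theta: draws matrix (M x k), columns named by model$params.
# Returns length-M vector of log-likelihoods. Exactly equal to looping
# start_loglik over rows of theta (tested), but evaluated via sufficient
# statistics for the survived frames.
start_loglik_draws <- function(obs, model, theta, dt = attr(obs, "dt")) {
  if (is.null(obs) || nrow(obs) == 0L) return(rep(0, nrow(theta)))
  if (model$gaussian) {
    ind <- start_individuals(obs, dt)
    mu <- theta[, "mu"]; sigma <- theta[, "sigma"]
    bnd <- sort(unique(c(0, ind$t0[ind$started], ind$t1[ind$started],
                         ind$t_end[!ind$started])))
    Z <- outer(bnd, mu, "-") / rep(sigma, each = length(bnd))
    lPhiC <- stats::pnorm(Z, lower.tail = FALSE, log.p = TRUE)
    Phi <- stats::pnorm(Z)
    ix <- function(x) match(x, bnd)
    st <- ind$started
    mass <- log(pmax(Phi[ix(ind$t1[st]), , drop = FALSE] -
                       Phi[ix(ind$t0[st]), , drop = FALSE], 0))
    return(colSums(mass) +
             colSums(lPhiC[ix(ind$t_end[!st]), , drop = FALSE]) -
             nrow(ind) * lPhiC[ix(0), ])
  }
  X <- start_design(obs, model)
  ns <- obs$started
  # survived frames contribute -rate*dt, linear in theta
  a <- -dt * colSums(X[!ns, , drop = FALSE])
  lin <- as.numeric(theta %*% a)
  if (any(ns)) {
    Xs <- X[ns, , drop = FALSE]
    key <- do.call(paste, as.data.frame(Xs))
    u <- !duplicated(key)
    w <- as.numeric(table(factor(key, levels = key[u])))
    R <- Xs[u, , drop = FALSE] %*% t(theta)       # unique-rate x M matrix
    lin <- lin + as.numeric(crossprod(w, log(-expm1(-dt * R))))
  }
  lin
}

# per-individual summary for the Gaussian model: the conditional per-frame
# products telescope exactly to interval probabilities of the response time
start_individuals <- function(obs, dt) {
  key <- paste(obs$group_id, obs$talk_id, obs$individual_id, sep = "\r")
  sp <- split(seq_len(nrow(obs)), key)
  t0 <- t1 <- t_end <- numeric(length(sp)); started <- logical(length(sp))
  for (i in seq_along(sp)) {
    idx <- sp[[i]]
    s <- obs$started[idx]
    started[i] <- any(s)
    if (started[i]) {
      t0[i] <- obs$t0[idx][s]; t1[i] <- t0[i] + dt
    } else t_end[i] <- max(obs$t0[idx]) + dt
  }
  data.frame(t0 = t0, t1 = t1, t_end = t_end, started = started)
}
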