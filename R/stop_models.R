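#' Per-clap stopping probability
#'
#' After each clap an individual stops with a probability combining a
#' constant term, the fraction of the audience that has already stopped
#' (full audience size as denominator), the individual's own clap count
#' relative to the normalizing maximum `n_max`, and the fraction of seat
#' neighbours already stopped. The combination is clamped to `[0, 1]`.
#'
#' @param rho_stopped fraction of the audience already stopped, in `[0, 1]`.
#' @param n clap index of the focal individual (`>= 1`).
#' @param nb_stopped fraction of seat neighbours already stopped.
#' @param params named numeric vector; any of `gamma1`, `gamma2`, `gamma3`,
#'   `gamma4` (per clap, `>= 0`); missing terms are inactive.
#' @param n_max normalizing clap count for the clap-number cue (`> 0`).
#' @return Probability per clap, vectorized.
#' @export
stop_probability <- function(rho_stopped, n, nb_stopped = 0, params,
                             n_max = 30) {
  p <- full_params(params, paste0("gamma", 1:4))
  if (any(p < 0)) stop("negative stopping parameter")
  stopifnot(n_max > 0)
  pmin(pmax(p[["gamma1"]] + p[["gamma2"]] * rho_stopped +
              p[["gamma3"]] * n / n_max + p[["gamma4"]] * nb_stopped, 0), 1)
}

#' Per-clap stopping hazard under the Gaussian preferred-duration model
#'
#' Individuals clap a normally distributed number of times (mean `m`, sd
#' `s`), independent of others. With a half-integer continuity correction
#' the probability of stopping at clap `n`, given having reached it, is
#' `(Phi(n + 1/2) - Phi(n - 1/2)) / (1 - Phi(n - 1/2))`, clamped to
#' `[0, 1]`; survivor underflow forces a stop (probability 1).
#'
#' @param n clap index (`>= 1`).
#' @param m,s mean and sd of the preferred clap count (`s > 0`).
#' @return Probability per clap, vectorized over `n`.
#' @export
gaussian_stop_probability <- function(n, m, s) {
  stopifnot(s > 0, all(n >= 1))
  surv <- stats::pnorm(n - 0.5, m, s, lower.tail = FALSE)
  num <- stats::pnorm(n + 0.5, m, s) - stats::pnorm(n - 0.5, m, s)
  ifelse(surv <= .Machine$double.xmin, 1, pmin(pmax(num / surv, 0), 1))
}

#' Log-likelihood of stopping observations under a model
#'
#' Sums `log p` over claps at which the individual stopped and `log(1 - p)`
#' over claps after which they continued. A model that assigns probability 0
#' to an observed stop — e.g. a purely social model at the bout's first stop,
#' when nobody has stopped yet — yields `-Inf` with a `diagnostic`
#' attribute.
#'
#' @param obs observations from [make_stop_observations()].
#' @param model a `"stop"`-family [hazard_model()].
#' @param params named numeric vector of the model's parameters.
#' @param n_max normalizing clap count; defaults to the maximum observed
#'   count in `obs`.
#' @return Log-probability of the observation set (0 for an empty set).
#' @export
stop_loglik <- function(obs, model, params,
                        n_max = attr(obs, "n_max_observed")) {
  stopifnot(inherits(model, "hazard_model"), model$family == "stop")
  if (is.null(obs) || nrow(obs) == 0L) return(0)
  if (model$gaussian) {
    p <- gaussian_stop_probability(obs$n, params[["m"]], params[["s"]])
  } else {
    check_active(params, model)
    p <- stop_probability(obs$rho_stopped, obs$n, obs$nb_stopped, params, n_max)
  }
  lp <- ifelse(obs$stopped, log(p), log1p(-p))
  ll <- sum(lp)
  if (!is.finite(ll) && any(obs$stopped & !is.finite(lp)))
    attr(ll, "diagnostic") <- paste0(
      "model ", model$label, " assigns probability 0 to an observed stop ",
      "(it cannot explain the first stop of a bout)")
  ll
}

# --- vectorized multi-draw log-likelihood -------------------------------

stop_design <- function(obs, model, n_max) {
  cols <- list(gamma1 = rep(1, nrow(obs)), gamma2 = obs$rho_stopped,
               gamma3 = obs$n / n_max, gamma4 = obs$nb_stopped)
  do.call(cbind, cols[model$params])
}

# theta: M x k draws matrix, columns named by model$params; identical
# observation rows (audience-state fractions are discrete) are collapsed to
# weighted unique rows before the matrix products
stop_loglik_draws <- function(obs, model, theta,
                              n_max = attr(obs, "n_max_observed"),
                              chunk = 5000L) {
  if (is.null(obs) || nrow(obs) == 0L) return(rep(0, nrow(theta)))
  if (model$gaussian) {
    ind <- stop_individuals(obs)
    m <- theta[, "m"]; s <- theta[, "s"]
    # all Normal-CDF evaluations share a small set of half-integer
    # boundaries; evaluate them once per draw as a boundary x draw matrix
    bnd <- sort(unique(c(ind$first_n - 0.5, ind$last_n - 0.5,
                         ind$last_n + 0.5)))
    Z <- outer(bnd, m, "-") / rep(s, each = length(bnd))
    lPhiC <- stats::pnorm(Z, lower.tail = FALSE, log.p = TRUE)  # log survivor
    Phi <- stats::pnorm(Z)
    ix <- function(x) match(x, bnd)
    st <- ind$stopped
    mass <- log(pmax(Phi[ix(ind$last_n[st] + 0.5), , drop = FALSE] -
                       Phi[ix(ind$last_n[st] - 0.5), , drop = FALSE], 0))
    ll <- colSums(mass) +
      colSums(lPhiC[ix(ind$last_n[!st] + 0.5), , drop = FALSE]) -
      colSums(lPhiC[ix(ind$first_n - 0.5), , drop = FALSE])
    return(ll)
  }
  X <- stop_design(obs, model, n_max)
  key <- do.call(paste, c(as.data.frame(X), list(obs$stopped)))
  u <- !duplicated(key)
  w <- as.numeric(table(factor(key, levels = key[u])))
  Xu <- X[u, , drop = FALSE]
  stopped_u <- obs$stopped[u]
  M <- nrow(theta)
  ll <- numeric(M)
  ws <- w[stopped_u]; wc <- w[!stopped_u]
  Xs <- Xu[stopped_u, , drop = FALSE]; Xc <- Xu[!stopped_u, , drop = FALSE]
  for (from in seq(1L, M, by = chunk)) {
    to <- min(from + chunk - 1L, M)
    tt <- t(theta[from:to, , drop = FALSE])
    Ps <- pmin(Xs %*% tt, 1)
    Pc <- pmin(Xc %*% tt, 1)
    ll[from:to] <- as.numeric(crossprod(ws, log(Ps))) +
      as.numeric(crossprod(wc, log1p(-Pc)))
  }
  ll
}

# per-individual clap-range summary: conditional Gaussian hazards telescope
# over consecutive claps, so only the first included clap and the last clap
# (with its outcome) matter
stop_individuals <- function(obs) {
  key <- paste(obs$group_id, obs$talk_id, obs$individual_id, sep = "\r")
  sp <- split(seq_len(nrow(obs)), key)
  first_n <- last_n <- numeric(length(sp)); stopped <- logical(length(sp))
  for (i in seq_along(sp)) {
    idx <- sp[[i]]
    first_n[i] <- min(obs$n[idx])
    j <- idx[which.max(obs$n[idx])]
    last_n[i] <- obs$n[j]
    stopped[i] <- obs$stopped[j]
  }
  data.frame(first_n = first_n, last_n = last_n, stopped = stopped)
}
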