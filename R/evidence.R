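logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

loglik_draws <- function(model, obs, theta, n_max = NULL) {
  if (model$family == "start") start_loglik_draws(obs, model, theta)
  else stop_loglik_draws(obs, model, theta,
                         n_max = n_max %||% attr(obs, "n_max_observed"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one importance-sampling pass: draws, log-likelihoods, per-replicate
# evidence and pooled posterior summaries
is_engine <- function(model, obs, prior, n_samples, replicates, seed, n_max) {
  stopifnot(inherits(model, "hazard_model"))
  if (!is.null(seed)) set.seed(seed)
  free <- vapply(model$params, function(nm) !(prior[[nm]]$fixed %||% FALSE),
                 logical(1))
  if (!any(free)) {
    th <- sample_prior(prior, model$params, 1L)
    ll <- loglik_draws(model, obs, th, n_max)
    return(list(logz_rep = ll, theta = th, ll = ll, n_samples = 1L,
                replicates = 1L, exact = TRUE))
  }
  stopifnot(n_samples >= 2, replicates >= 2)
  logz_rep <- numeric(replicates)
  ths <- vector("list", replicates); lls <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    th <- sample_prior(prior, model$params, n_samples)
    ll <- loglik_draws(model, obs, th, n_max)
    logz_rep[r] <- logsumexp(ll) - log(n_samples)
    ths[[r]] <- th; lls[[r]] <- ll
  }
  list(logz_rep = logz_rep, theta = do.call(rbind, ths),
       ll = unlist(lls), rep_id = rep(seq_len(replicates), each = n_samples),
       n_samples = n_samples, replicates = replicates, exact = FALSE)
}

#' Marginal likelihood of a model by importance sampling from the prior
#'
#' Estimates the model evidence `P(D | M) = integral P(D | phi, M)
#' P(phi | M) dphi` as the mean of the likelihood over `n_samples` draws
#' from the prior, aggregated in log space with log-sum-exp stabilization.
#' The whole calculation is repeated `replicates` times (default 8) and the
#' mean and standard error of the replicate log-evidences are reported; the
#' Monte-Carlo uncertainty shrinks as `1/sqrt(n_samples)`, so `n_samples` is
#' doubled (e.g. by [applause_select()]) when two candidate models cannot be
#' distinguished.
#'
#' A model whose parameters are all held fixed by [prior_fixed()] priors has
#' a degenerate integral: the evidence equals the exact likelihood with
#' standard error 0.
#'
#' @param model a [hazard_model()].
#' @param obs observations from [make_start_observations()] or
#'   [make_stop_observations()], matching the model's family.
#' @param prior an [applause_priors()] list.
#' @param n_samples prior draws per replicate.
#' @param replicates independent repetitions (`>= 2`).
#' @param seed optional integer seed for reproducibility.
#' @param n_max normalizing clap count for stop models; defaults to the
#'   maximum observed count in `obs`.
#' @return An object of class `evidence_estimate`: list with `model`,
#'   `log_evidence`, `se`, `replicate_values`, `n_samples`, `replicates`.
#'   If every prior draw has zero likelihood the evidence is `-Inf` with a
#'   `diagnostic` element.
#' @export
estimate_evidence <- function(model, obs, prior = applause_priors(),
                              n_samples = 1e4, replicates = 8, seed = NULL,
                              n_max = NULL) {
  eng <- is_engine(model, obs, prior, n_samples, replicates, seed, n_max)
  est <- structure(list(model = model$label,
                        log_evidence = mean(eng$logz_rep),
                        se = if (eng$exact) 0 else
                          stats::sd(eng$logz_rep) / sqrt(eng$replicates),
                        replicate_values = eng$logz_rep,
                        n_samples = eng$n_samples,
                        replicates = eng$replicates),
                   class = "evidence_estimate")
  if (!is.finite(est$log_evidence) && all(!is.finite(eng$ll)))
    est$diagnostic <- "likelihood is zero at every prior draw"
  est
}

#' @export
print.evidence_estimate <- function(x, ...) {
  cat(sprintf("Model %s: log evidence %.3f (SE %.3f; %d x %g samples)\n",
              x$model, x$log_evidence, x$se, x$replicates, x$n_samples))
  if (!is.null(x$diagnostic)) cat("  note:", x$diagnostic, "\n")
  invisible(x)
}

#' Posterior parameter summaries by self-normalized importance sampling
#'
#' Weights prior draws by their likelihood to obtain posterior means and
#' standard deviations of the model's parameters, the between-replicate
#' standard error of each posterior mean, and the effective sample size
#' `(sum w)^2 / sum w^2` (a warning is issued below 50).
#'
#' @inheritParams estimate_evidence
#' @return A `data.frame` with one row per parameter: `mean`, `sd`,
#'   `se_mean`, and attribute `ess`.
#' @export
posterior_mean <- function(model, obs, prior = applause_priors(),
                           n_samples = 1e4, replicates = 8, seed = NULL,
                           n_max = NULL) {
  eng <- is_engine(model, obs, prior, n_samples, replicates, seed, n_max)
  posterior_from_engine(eng, model)
}

posterior_from_engine <- function(eng, model) {
  th <- eng$theta
  if (eng$exact) {
    out <- data.frame(mean = as.numeric(th[1, ]), sd = 0, se_mean = 0,
                      row.names = colnames(th))
    attr(out, "ess") <- Inf
    return(out)
  }
  w <- exp(eng$ll - max(eng$ll))
  if (all(w == 0) || !is.finite(max(eng$ll)))
    stop("likelihood is zero at every prior draw; posterior undefined")
  wm <- function(v, wt) sum(wt * v) / sum(wt)
  means <- apply(th, 2, wm, wt = w)
  sds <- sqrt(pmax(apply(th, 2, function(v) wm(v^2, w)) - means^2, 0))
  rep_means <- sapply(seq_len(eng$replicates), function(r) {
    idx <- eng$rep_id == r
    apply(th[idx, , drop = FALSE], 2, wm, wt = w[idx])
  })
  rep_means <- matrix(rep_means, ncol = eng$replicates)
  se <- apply(rep_means, 1, stats::sd) / sqrt(eng$replicates)
  ess <- sum(w)^2 / sum(w^2)
  if (ess < 50)
    warning(sprintf("effective sample size %.1f < 50 for model %s; increase n_samples",
                    ess, model$label))
  out <- data.frame(mean = means, sd = sds, se_mean = se,
                    row.names = colnames(th))
  attr(out, "ess") <- ess
  out
}

#' Rank candidate models by marginal likelihood
#'
#' Orders evidence estimates and, assuming all models equally probable a
#' priori, normalizes them into relative posterior model probabilities.
#' Pairs of adjacent models whose log-evidence difference is below 2
#' combined standard errors are flagged `unresolved` — the trigger for
#' increasing the number of importance samples.
#'
#' @param estimates a list of [estimate_evidence()] results (`>= 2`).
#' @return A `data.frame` ordered by decreasing log evidence with columns
#'   `model`, `log_evidence`, `se`, `rel_prob`, `unresolved`.
#' @export
rank_models <- function(estimates) {
  stopifnot(length(estimates) >= 2)
  tab <- data.frame(
    model = vapply(estimates, `[[`, character(1), "model"),
    log_evidence = vapply(estimates, `[[`, numeric(1), "log_evidence"),
    se = vapply(estimates, `[[`, numeric(1), "se"),
    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$log_evidence), , drop = FALSE]
  lz <- tab$log_evidence
  tab$rel_prob <- if (all(!is.finite(lz))) rep(NA_real_, length(lz)) else
    exp(lz - logsumexp(lz))
  tab$unresolved <- FALSE
  for (i in seq_len(nrow(tab) - 1L)) {
    d <- tab$log_evidence[i] - tab$log_evidence[i + 1L]
    s <- sqrt(tab$se[i]^2 + tab$se[i + 1L]^2)
    if (is.finite(d) && d <= 2 * s) tab$unresolved[c(i, i + 1L)] <- TRUE
    if (!is.finite(d) && !is.finite(tab$log_evidence[i])) tab$unresolved[c(i, i + 1L)] <- TRUE
  }
  rownames(tab) <- NULL
  tab
}
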