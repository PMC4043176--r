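#' Fit and compare applause hazard models by Bayesian model selection
#'
#' The central modelling function: turns a collection of bouts into the
#' event-history observation set of the requested family (per-frame starting
#' observations or per-clap stopping observations), estimates the marginal
#' likelihood of every candidate model by importance sampling from the
#' prior, ranks the models, and computes posterior parameter summaries.
#' Parameters are population-level: likelihoods are pooled across all bouts
#' and groups.
#'
#' When the top two models cannot be distinguished (log-evidence difference
#' below 2 combined standard errors) the number of importance samples is
#' doubled, up to `max_doublings` times.
#'
#' @param bouts a [bout_list()] (or single [bout()]).
#' @param family `"start"` or `"stop"`.
#' @param models candidate list from [enumerate_models()] (the default), or
#'   any list of [hazard_model()] objects of the family.
#' @param prior an [applause_priors()] list.
#' @param dt frame length (seconds) for starting observations.
#' @param restricted for the stop family: analyse only claps after each
#'   bout's first stop, the restricted data set on which purely social
#'   models are admissible.
#' @param n_samples importance samples per replicate.
#' @param replicates independent replicates per model (default 8).
#' @param seed optional integer seed.
#' @param n_max normalizing clap count for stop models; default: maximum
#'   observed clap count in the data.
#' @param max_doublings times `n_samples` may be doubled when the top two
#'   models are unresolved.
#' @param diagonal include diagonal seats as neighbours.
#' @return An object of class `applause_fit`: list with `ranking` (the
#'   [rank_models()] table), `evidence` (per-model estimates), `posterior`
#'   (per-model posterior summaries), `best` (label of the top model),
#'   `models`, `settings` and `observations`.
#' @seealso [estimate_evidence()], [posterior_mean()], [rank_models()]
#' @export
applause_select <- function(bouts, family = c("start", "stop"),
                            models = NULL, prior = applause_priors(),
                            dt = 0.1, restricted = FALSE,
                            n_samples = 1e4, replicates = 8, seed = NULL,
                            n_max = NULL, max_doublings = 0,
                            diagonal = FALSE) {
  family <- match.arg(family)
  bouts <- as_bout_list(bouts)
  if (is.null(models)) models <- enumerate_models(family, restricted)
  stopifnot(all(vapply(models, function(m) m$family == family, logical(1))))
  obs <- if (family == "start") make_start_observations(bouts, dt, diagonal)
  else make_stop_observations(bouts, restricted, diagonal)
  if (family == "stop" && is.null(n_max)) n_max <- attr(obs, "n_max_observed")
  if (!is.null(seed)) set.seed(seed)

  run_all <- function(ns) {
    ev <- vector("list", length(models)); po <- vector("list", length(models))
    for (i in seq_along(models)) {
      m <- models[[i]]
      if (isTRUE(m$structural_zero)) {
        ev[[i]] <- structure(list(model = m$label, log_evidence = -Inf, se = 0,
                                  replicate_values = rep(-Inf, replicates),
                                  n_samples = ns, replicates = replicates,
                                  diagnostic = "structurally impossible: cannot explain the first stop"),
                             class = "evidence_estimate")
        po[[i]] <- NULL
        next
      }
      eng <- is_engine(m, obs, prior, ns, replicates, seed = NULL, n_max = n_max)
      ev[[i]] <- structure(list(model = m$label,
                                log_evidence = mean(eng$logz_rep),
                                se = if (eng$exact) 0 else
                                  stats::sd(eng$logz_rep) / sqrt(eng$replicates),
                                replicate_values = eng$logz_rep,
                                n_samples = eng$n_samples,
                                replicates = eng$replicates),
                           class = "evidence_estimate")
      po[[i]] <- if (all(!is.finite(eng$ll))) NULL else
        suppressWarnings(posterior_from_engine(eng, m))
    }
    names(ev) <- names(po) <- vapply(models, `[[`, character(1), "label")
    list(ev = ev, po = po)
  }

  ns <- n_samples
  for (pass in seq_len(max_doublings + 1L)) {
    res <- run_all(ns)
    ranking <- rank_models(res$ev)
    if (nrow(ranking) < 2L || !ranking$unresolved[1L] || pass > max_doublings)
      break
    ns <- 2L * ns
  }

  structure(list(ranking = ranking, evidence = res$ev, posterior = res$po,
                 best = ranking$model[1L], models = models,
                 observations = obs, design = design_from_bouts(bouts),
                 settings = list(family = family, dt = dt,
                                 restricted = restricted, n_samples = ns,
                                 replicates = replicates, seed = seed,
                                 n_max = n_max, prior = prior),
                 n_bouts = length(bouts)),
            class = "applause_fit")
}

#' @export
print.applause_fit <- function(x, ...) {
  cat(sprintf("Applause %s-model selection over %d bouts (%d candidate models)\n",
              x$settings$family, x$n_bouts, length(x$models)))
  if (x$settings$family == "stop")
    cat(sprintf("  %s data, n_max = %d\n",
                if (x$settings$restricted) "restricted (after first stop)" else "unrestricted",
                x$settings$n_max))
  top <- utils::head(x$ranking, 5L)
  top$log_evidence <- round(top$log_evidence, 2)
  top$se <- round(top$se, 3)
  top$rel_prob <- signif(top$rel_prob, 3)
  print(top, row.names = FALSE)
  cat(sprintf("Best model: %s\n", x$best))
  invisible(x)
}

#' @export
summary.applause_fit <- function(object, ...) {
  cat(sprintf("Bayesian model selection, %s family (%d x %g importance samples per model)\n\n",
              object$settings$family, object$settings$replicates,
              object$settings$n_samples))
  print(object$ranking, row.names = FALSE)
  cat("\nPosterior summaries, best model (", object$best, "):\n", sep = "")
  print(object$posterior[[object$best]])
  invisible(object)
}

#' @export
coef.applause_fit <- function(object, model = object$best, ...) {
  po <- object$posterior[[model]]
  if (is.null(po)) stop("no posterior summary available for model ", model)
  stats::setNames(po$mean, rownames(po))
}

#' @export
logLik.applause_fit <- function(object, ...) {
  m <- object$models[[object$best]]
  params <- coef(object)
  ll <- if (object$settings$family == "start")
    start_loglik(object$observations, m, params, dt = object$settings$dt)
  else stop_loglik(object$observations, m, params, n_max = object$settings$n_max)
  structure(as.numeric(ll), df = length(params), class = "logLik")
}

#' @export
plot.applause_fit <- function(x, n_top = 10, ...) {
  tab <- utils::head(x$ranking, n_top)
  tab <- tab[is.finite(tab$log_evidence), , drop = FALSE]
  tab <- tab[rev(seq_len(nrow(tab))), ]
  mid <- graphics::barplot(tab$log_evidence - max(tab$log_evidence),
                           names.arg = tab$model, horiz = TRUE, las = 1,
                           xlab = "log evidence (relative to best model)",
                           ...)
  graphics::segments(tab$log_evidence - max(tab$log_evidence) - 2 * tab$se, mid,
                     tab$log_evidence - max(tab$log_evidence) + 2 * tab$se, mid)
  invisible(x)
}

#' Write a model-selection result to JSON
#'
#' Serializes the ranking, per-model evidence estimates (log evidence,
#' standard error, sample counts, replicate values), posterior summaries,
#' and a reproducibility block (seed, frame length, `n_max`, restriction
#' flag, prior supports and means).
#'
#' @param fit an `applause_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "applause_fit"))
  pr <- lapply(fit$settings$prior, function(p)
    list(mean = p$mean, support = p$support, fixed = p$fixed))
  out <- list(
    family = fit$settings$family,
    best = fit$best,
    ranking = fit$ranking,
    models = lapply(fit$evidence, function(e)
      list(log_evidence = e$log_evidence, se = e$se,
           n_samples = e$n_samples, replicates = e$replicates,
           replicate_values = e$replicate_values,
           diagnostic = e$diagnostic,
           posterior = if (!is.null(fit$posterior[[e$model]]))
             cbind(parameter = rownames(fit$posterior[[e$model]]),
                   fit$posterior[[e$model]]))),
    reproducibility = list(seed = fit$settings$seed, dt = fit$settings$dt,
                           n_max = fit$settings$n_max,
                           restricted = fit$settings$restricted,
                           n_samples = fit$settings$n_samples,
                           replicates = fit$settings$replicates,
                           priors = pr))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

#' Simulate new bouts from a fitted model selection
#'
#' Regenerates study-shaped data under the top-ranked model at its posterior
#' means, on the same audiences (group sizes, seats and talks) as the fitted
#' data. The complementary process (stopping when a start family was fitted,
#' and vice versa) uses the package's reference best-fit parameters from
#' [sim_config()] unless a model/parameter pair is supplied.
#'
#' @param object an `applause_fit`.
#' @param nsim number of replicate studies.
#' @param seed optional integer seed.
#' @param other_model,other_params [hazard_model()] and named parameters for
#'   the complementary family.
#' @param ... unused.
#' @return A [bout_list()] (`nsim = 1`) or a list of them.
#' @export
simulate.applause_fit <- function(object, nsim = 1, seed = NULL,
                                  other_model = NULL, other_params = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- sim_config()
  if (object$settings$family == "start") {
    start_model <- object$models[[object$best]]
    start_params <- coef(object)
    stop_model <- other_model %||% hazard_model("stop", c("gamma2", "gamma3"))
    stop_params <- other_params %||% c(gamma2 = cfg$gamma2, gamma3 = cfg$gamma3)
  } else {
    stop_model <- object$models[[object$best]]
    stop_params <- coef(object)
    start_model <- other_model %||% hazard_model("start", "lambda2")
    start_params <- other_params %||% c(lambda2 = cfg$lambda)
  }
  design <- object$design %||% study_design()
  out <- lapply(seq_len(nsim), function(i)
    generate_study(design, start_model, start_params, stop_model, stop_params,
                   n_max = object$settings$n_max %||% cfg$n_max))
  if (nsim == 1L) out[[1L]] else out
}
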