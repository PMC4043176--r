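#' Specify a starting or stopping hazard model
#'
#' Candidate models are identified by which cue terms are active. For
#' starting, the per-second rate of a susceptible individual is
#' \deqn{\lambda_1 + \lambda_2 \rho + \lambda_3 \rho^2 + \lambda_4 \nu,}
#' where \eqn{\rho} is the fraction of the audience already clapping and
#' \eqn{\nu} the fraction of the focal individual's seat neighbours already
#' clapping; the Gaussian alternative says individuals start a normally
#' distributed time (mean `mu`, sd `sigma`) after the first clap. For
#' stopping, the per-clap probability is
#' \deqn{\gamma_1 + \gamma_2 \rho_{stopped} + \gamma_3 n/n_{max} + \gamma_4
#' \nu_{stopped},} with \eqn{n} the focal individual's clap count, or the
#' Gaussian alternative of a normally distributed preferred clap count
#' (mean `m`, sd `s`).
#'
#' @param family `"start"` or `"stop"`.
#' @param terms for rate/probability models, which terms are active: a subset
#'   of `"lambda1"..."lambda4"` (start) or `"gamma1"..."gamma4"` (stop), also
#'   accepted in the short serialized form `"L2"`, `"G3"`, etc.; or
#'   `"gaussian"`.
#' @return An object of class `hazard_model` with elements `family`, `terms`
#'   (full parameter names), `gaussian`, `label` (serialized name such as
#'   `"L2+L4"`, `"G2+G3"`, `"G_start"`, `"G_stop"`) and `structural_zero`
#'   (see [enumerate_models()]).
#' @export
hazard_model <- function(family = c("start", "stop"), terms) {
  family <- match.arg(family)
  base <- if (family == "start") "lambda" else "gamma"
  short <- if (family == "start") "L" else "G"
  if (length(terms) == 1L && terms %in% c("gaussian", paste0("G_", family))) {
    return(structure(list(family = family, terms = "gaussian", gaussian = TRUE,
                          label = paste0("G_", family),
                          params = if (family == "start") c("mu", "sigma") else c("m", "s"),
                          structural_zero = FALSE),
                     class = "hazard_model"))
  }
  idx <- sort(unique(vapply(terms, function(tm) {
    if (grepl(paste0("^", base, "[1-4]$"), tm)) as.integer(substring(tm, nchar(base) + 1L))
    else if (grepl(paste0("^", short, "[1-4]$"), tm)) as.integer(substring(tm, 2L))
    else stop("unknown term for ", family, " family: ", tm)
  }, integer(1))))
  if (!length(idx)) stop("at least one term must be active")
  structure(list(family = family, terms = paste0(base, idx), gaussian = FALSE,
                 label = paste(paste0(short, idx), collapse = "+"),
                 params = paste0(base, idx),
                 structural_zero = FALSE),
            class = "hazard_model")
}

#' @export
print.hazard_model <- function(x, ...) {
  cat(sprintf("Hazard model %s (%s family)%s\n", x$label, x$family,
              if (x$structural_zero) " [structurally impossible on unrestricted data]" else ""))
  invisible(x)
}

#' Enumerate all candidate models of a family
#'
#' All 15 non-empty combinations of the four cue terms plus the Gaussian
#' model: 16 candidates per family. For the unrestricted stopping data the
#' purely social combinations (subsets of the stopped-fraction and
#' neighbour-stopped terms, i.e. of \{G2, G4\}) are flagged
#' `structural_zero`: at least one individual must stop when nobody has
#' stopped yet, an event those models give probability 0. On the restricted
#' data (claps after the first stop) they are admissible.
#'
#' @param family `"start"` or `"stop"`.
#' @param restricted for the stop family, whether the models will be fitted
#'   to observations restricted to after the first stop.
#' @return A list of [hazard_model()] objects, named by label.
#' @export
enumerate_models <- function(family = c("start", "stop"), restricted = FALSE) {
  family <- match.arg(family)
  masks <- lapply(1:15, function(m) which(bitwAnd(m, 2^(0:3)) > 0))
  models <- lapply(masks, function(idx)
    hazard_model(family, paste0(if (family == "start") "lambda" else "gamma", idx)))
  models <- c(models, list(hazard_model(family, "gaussian")))
  if (family == "stop" && !restricted) {
    for (i in seq_along(models)) {
      tm <- models[[i]]$terms
      if (!models[[i]]$gaussian && all(tm %in% c("gamma2", "gamma4")))
        models[[i]]$structural_zero <- TRUE
    }
  }
  names(models) <- vapply(models, `[[`, character(1), "label")
  models
}
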