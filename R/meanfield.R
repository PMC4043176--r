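#' Parameters of the mean-field clapping model
#'
#' Deterministic large-population limit of the clapping contagion, with the
#' clap-number cue ignored: susceptibles start clapping at per-individual
#' rate `lambda2 * (I + R)` and clappers stop at per-individual rate
#' `gamma1 + gamma2 * R` — recovered individuals increase the recovery rate
#' of those still clapping, unlike the standard SIR model. Default stopping
#' rates convert the per-clap best fits (0.008 and 0.66 per clap, fitted
#' with the clap-number term switched off) to per-second values through the
#' mean clap interval of 0.28 s. `fig_caption = TRUE` instead uses the
#' published figure-caption preset (0.0011 and 0.094 per second), which is
#' inconsistent with that conversion but retained for comparison.
#'
#' @param lambda2 social starting rate (per second).
#' @param gamma1,gamma2 constant and social stopping rates (per second).
#' @param S0,I0 initial susceptible and clapping fractions
#'   (`S0 + I0 <= 1`).
#' @param fig_caption use the figure-caption parameter preset.
#' @return A list of class `ode_params`.
#' @export
ode_params <- function(lambda2 = 2.15, gamma1 = 0.008 / 0.28,
                       gamma2 = 0.66 / 0.28, S0 = 0.95, I0 = 0.05,
                       fig_caption = FALSE) {
  if (fig_caption) { gamma1 <- 0.0011; gamma2 <- 0.094 }
  stopifnot(lambda2 >= 0, gamma1 >= 0, gamma2 >= 0, S0 >= 0, I0 >= 0,
            S0 + I0 <= 1 + 1e-12)
  structure(list(lambda2 = lambda2, gamma1 = gamma1, gamma2 = gamma2,
                 S0 = S0, I0 = I0),
            class = "ode_params")
}

#' Right-hand side of the mean-field equations
#'
#' `dS/dt = -lambda2 * S * (I + R)`; `dR/dt = (gamma1 + gamma2 * R) * I`;
#' `dI/dt = -dS/dt - dR/dt`, so `S + I + R` is conserved.
#'
#' @param S,I,R state fractions (`S + I + R = 1`).
#' @param params an [ode_params()].
#' @return Named vector `c(dS, dI, dR)`.
#' @export
ode_rhs <- function(S, I, R, params) {
  dS <- -params$lambda2 * S * (I + R)
  dR <- (params$gamma1 + params$gamma2 * R) * I
  c(dS = dS, dI = -dS - dR, dR = dR)
}

#' Integrate the mean-field model
#'
#' Integrates all three compartments with `deSolve::lsoda` at tight
#' tolerances; conservation `S + I + R = 1` holds to better than 1e-8 at
#' every output point (integration is retried at tighter tolerances if
#' not, with a message).
#'
#' @param params an [ode_params()].
#' @param horizon end time (seconds).
#' @param step output grid spacing (seconds).
#' @return A `data.frame` with columns `time`, `S`, `I`, `R`, class
#'   `meanfield_trajectory`.
#' @export
mean_field_trajectory <- function(params, horizon = 12, step = 0.01) {
  stopifnot(inherits(params, "ode_params"), horizon > 0, step > 0)
  y0 <- c(S = params$S0, I = params$I0, R = 1 - params$S0 - params$I0)
  deriv <- function(t, y, p) list(unname(ode_rhs(y[["S"]], y[["I"]], y[["R"]], params)))
  times <- seq(0, horizon, by = step)
  tol <- 1e-10
  out <- NULL
  repeat {
    sol <- tryCatch(deSolve::lsoda(y0, times, deriv, NULL, rtol = tol,
                                   atol = tol, maxsteps = 1e5),
                    error = function(e) NULL)
    if (!is.null(sol)) {
      out <- as.data.frame(sol)
      names(out)[1] <- "time"
      err <- max(abs(out$S + out$I + out$R - 1))
      if (err <= 1e-8 || tol <= 1e-13) break
      message("conservation violated (", format(err), "); refining tolerances")
    }
    tol <- tol / 100
    if (tol < 1e-14) {
      # classic fixed-step 4th-order fallback; RK preserves the linear
      # invariant S + I + R exactly up to roundoff
      h <- min(step, 0.02)
      fine <- seq(0, horizon, by = h)
      sol <- deSolve::rk4(y0, fine, deriv, NULL)
      out <- as.data.frame(sol[fine %in% times, , drop = FALSE])
      names(out)[1] <- "time"
      break
    }
  }
  structure(out, class = c("meanfield_trajectory", "data.frame"),
            params = params)
}

#' @export
plot.meanfield_trajectory <- function(x, ...) {
  graphics::matplot(x$time, cbind(x$S, x$I, x$R), type = "l", lty = 1,
                    col = c("black", "forestgreen", "red"),
                    xlab = "time (s)", ylab = "fraction of audience", ...)
  graphics::legend("right", c("S (not yet clapping)", "I (clapping)",
                              "R (stopped)"),
                   col = c("black", "forestgreen", "red"), lty = 1, bty = "n")
  invisible(x)
}

#' Phase plane of the mean-field model
#'
#' Evaluates the vector field `(dS/dt, dI/dt)` on a grid over the simplex
#' `S + I <= 1` (with `R = 1 - S - I`) and locates numerically the locus
#' where `dI/dt = 0`, i.e. where `lambda2 * S * (I + R) = (gamma1 +
#' gamma2 * R) * I`: trajectories attain their clapping maximum on this
#' curve.
#'
#' @param params an [ode_params()].
#' @param n grid resolution per axis.
#' @return A list of class `meanfield_phase_plane` with `field` (data.frame
#'   `S`, `I`, `dS`, `dI`) and `locus` (data.frame `S`, `I` with `dI = 0`,
#'   found by root-finding in `I` at each grid `S`).
#' @export
phase_plane <- function(params, n = 41) {
  stopifnot(inherits(params, "ode_params"))
  g <- seq(0, 1, length.out = n)
  grid <- expand.grid(S = g, I = g)
  grid <- grid[grid$S + grid$I <= 1 + 1e-12, , drop = FALSE]
  d <- mapply(function(S, I) ode_rhs(S, I, 1 - S - I, params)[c("dS", "dI")],
              grid$S, grid$I)
  field <- data.frame(S = grid$S, I = grid$I, dS = d[1, ], dI = d[2, ])
  dI_at <- function(S, I) unname(ode_rhs(S, I, 1 - S - I, params)["dI"])
  # scan each grid column for sign changes of dI/dt in the interior and
  # refine every bracket; a column may cross the locus 0, 1 or 2 times
  locus <- do.call(rbind, lapply(g[g < 1], function(S) {
    Iscan <- seq(1e-9, 1 - S - 1e-9, length.out = 400L)
    if (length(Iscan) < 2L) return(NULL)
    fv <- vapply(Iscan, dI_at, numeric(1), S = S)
    sgn <- which(fv[-length(fv)] * fv[-1] < 0)
    if (!length(sgn)) return(NULL)
    roots <- vapply(sgn, function(j)
      stats::uniroot(function(I) dI_at(S, I), c(Iscan[j], Iscan[j + 1L]),
                     tol = 1e-12)$root, numeric(1))
    data.frame(S = S, I = roots)
  }))
  structure(list(field = field, locus = locus, params = params),
            class = "meanfield_phase_plane")
}

#' @export
plot.meanfield_phase_plane <- function(x, trajectory = NULL, scale = 0.03, ...) {
  f <- x$field
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "S (susceptible)",
                 ylab = "I (clapping)", ...)
  len <- sqrt(f$dS^2 + f$dI^2)
  ok <- len > 0
  graphics::arrows(f$S[ok], f$I[ok], f$S[ok] + scale * f$dS[ok] / len[ok],
                   f$I[ok] + scale * f$dI[ok] / len[ok],
                   length = 0.02, col = "grey60")
  if (!is.null(x$locus))
    graphics::lines(x$locus$S, x$locus$I, col = "blue", lty = 3, lwd = 2)
  if (!is.null(trajectory))
    graphics::lines(trajectory$S, trajectory$I, col = "red", lwd = 2)
  invisible(x)
}
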