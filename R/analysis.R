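#' Study-level summary statistics of applause bouts
#'
#' Per bout: the interval from the first to the last start
#' (`start_spread`), from the first to the last stop (`stop_spread`), the
#' bout length from first start to last stop (`length`), the time of the
#' first stop, the mean number of claps per starter (when clap times are
#' available), and the first-clap latency when recorded as bout metadata.
#' Across bouts: means with standard errors (sample sd over the square root
#' of the number of bouts).
#'
#' @param bouts a [bout()] or [bout_list()].
#' @return A list of class `bout_summary` with `per_bout` (one row per
#'   bout; bouts with a single starter have zero spreads and are flagged)
#'   and `means` (mean and `se` per statistic).
#' @export
summarize_bouts <- function(bouts) {
  bouts <- as_bout_list(bouts)
  per <- do.call(rbind, lapply(bouts, function(b) {
    st <- b$start_time[starters(b)]
    sp <- b$stop_time[starters(b)]
    if (!length(st)) stop("bout with no starters")
    claps <- vapply(b$clap_times[starters(b)], length, integer(1))
    lat <- attr(b, "first_start_latency")
    data.frame(group_id = attr(b, "group_id"), talk_id = attr(b, "talk_id"),
               N = attr(b, "N"), n_starters = length(st),
               first_start_latency = if (is.null(lat)) NA_real_ else lat,
               start_spread = max(st) - min(st),
               stop_spread = max(sp) - min(sp),
               length = max(sp) - min(st),
               first_stop = min(sp),
               mean_claps = if (all(claps > 0)) mean(claps) else NA_real_,
               single_starter = length(st) == 1L,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  stats <- c("first_start_latency", "start_spread", "stop_spread", "length",
             "first_stop", "mean_claps")
  means <- data.frame(
    statistic = stats,
    mean = vapply(stats, function(s) mean(per[[s]]), numeric(1)),
    se = vapply(stats, function(s)
      stats::sd(per[[s]]) / sqrt(nrow(per)), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_bout = per, means = means), class = "bout_summary")
}

#' @export
print.bout_summary <- function(x, ...) {
  cat(sprintf("Summary of %d applause bouts\n", nrow(x$per_bout)))
  m <- x$means
  m$mean <- round(m$mean, 3); m$se <- round(m$se, 3)
  print(m, row.names = FALSE)
  invisible(x)
}

#' Median S/I/R curves with interquartile bands across bouts
#'
#' On a common absolute time grid (seconds from each bout's first clap),
#' computes the across-bout median and 25/75% quantiles of the fraction
#' started, stopped, and currently clapping.
#'
#' @param bouts a [bout_list()] with at least 2 bouts.
#' @param time_grid grid in seconds; default 0 to the latest stop in steps
#'   of 0.05 s.
#' @return A `data.frame` (class `sir_curves`) with columns `time` and, for
#'   each of `started`, `stopped`, `clapping`: `_med`, `_lo`, `_hi`.
#' @export
sir_curves <- function(bouts, time_grid = NULL) {
  bouts <- as_bout_list(bouts)
  stopifnot(length(bouts) >= 2L)
  if (is.null(time_grid)) {
    end <- max(vapply(bouts, bout_last_stop, numeric(1)))
    time_grid <- seq(0, end, by = 0.05)
  }
  traj <- lapply(bouts, audience_trajectory, time_grid = time_grid)
  q <- function(field, p) apply(vapply(traj, `[[`, numeric(length(time_grid)),
                                       field), 1, stats::quantile, probs = p)
  out <- data.frame(time = time_grid,
                    started_med = q("rho_clapping", 0.5),
                    started_lo = q("rho_clapping", 0.25),
                    started_hi = q("rho_clapping", 0.75),
                    stopped_med = q("rho_stopped", 0.5),
                    stopped_lo = q("rho_stopped", 0.25),
                    stopped_hi = q("rho_stopped", 0.75),
                    clapping_med = q("clapping_now", 0.5),
                    clapping_lo = q("clapping_now", 0.25),
                    clapping_hi = q("clapping_now", 0.75))
  structure(out, class = c("sir_curves", "data.frame"))
}

#' @export
plot.sir_curves <- function(x, ...) {
  graphics::plot(NA, xlim = range(x$time), ylim = c(0, 1),
                 xlab = "time from first clap (s)",
                 ylab = "proportion of audience", ...)
  band <- function(lo, hi, col)
    graphics::polygon(c(x$time, rev(x$time)), c(lo, rev(hi)), border = NA,
                      col = grDevices::adjustcolor(col, 0.25))
  band(x$started_lo, x$started_hi, "black")
  band(x$stopped_lo, x$stopped_hi, "red")
  graphics::lines(x$time, x$started_med, col = "black", lwd = 2)
  graphics::lines(x$time, x$stopped_med, col = "red", lwd = 2)
  graphics::lines(x$time, x$clapping_med, col = "forestgreen", lwd = 2)
  graphics::legend("right", c("started", "stopped", "currently clapping"),
                   col = c("black", "red", "forestgreen"), lwd = 2, bty = "n")
  invisible(x)
}

#' Distribution of mean claps per person across simulation runs
#'
#' Histogram (unit bins) of the per-run average number of claps per
#' individual, a matched Poisson probability mass with the same mean, the
#' variance ratio (simulated variance over Poisson variance, i.e. over the
#' mean), and, for supplied observed per-bout means, whether each lies
#' within the central 95% of the simulated distribution.
#'
#' @param ensemble an `applause_ensemble` from [run_ensemble()] (at least
#'   100 runs) or a numeric vector of per-run mean claps.
#' @param observed optional numeric vector of observed per-bout mean claps.
#' @return A list of class `claps_distribution`: `mean_claps` (per run),
#'   `breaks`/`proportion` (unit-bin histogram), `poisson` (matched pmf on
#'   the same bins), `variance_ratio`, `central95`, and `observed` with
#'   logical `inside`.
#' @export
claps_distribution <- function(ensemble, observed = NULL) {
  x <- if (inherits(ensemble, "applause_ensemble"))
    ensemble$summaries$mean_claps else as.numeric(ensemble)
  if (length(x) < 100L) stop("ensemble must have at least 100 runs")
  bins <- seq(floor(min(x)), ceiling(max(x)))
  mid <- bins[-length(bins)]
  h <- graphics::hist(x, breaks = bins, plot = FALSE, right = FALSE)
  m <- mean(x)
  pois <- stats::dpois(mid, m)
  ci <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
  obs <- if (!is.null(observed))
    data.frame(value = observed, inside = observed >= ci[1] & observed <= ci[2])
  structure(list(mean_claps = x, breaks = bins, mids = mid,
                 proportion = h$counts / length(x), poisson = pois,
                 mean = m, variance_ratio = stats::var(x) / m,
                 central95 = ci, observed = obs),
            class = "claps_distribution")
}

#' @export
print.claps_distribution <- function(x, ...) {
  cat(sprintf("Mean claps per person over %d runs: mean %.2f, variance ratio vs Poisson %.2f\n",
              length(x$mean_claps), x$mean, x$variance_ratio))
  cat(sprintf("  central 95%%: [%.1f, %.1f]\n", x$central95[1], x$central95[2]))
  if (!is.null(x$observed))
    cat(sprintf("  observed bout means inside central 95%%: %d of %d\n",
                sum(x$observed$inside), nrow(x$observed)))
  invisible(x)
}

#' @export
plot.claps_distribution <- function(x, ...) {
  graphics::plot(x$mids, x$proportion, type = "h", lwd = 8, lend = 1,
                 col = "grey70", xlab = "average claps per individual",
                 ylab = "proportion of runs", ...)
  graphics::lines(x$mids, x$poisson, lty = 2)
  if (!is.null(x$observed))
    graphics::points(x$observed$value, rep(0, nrow(x$observed)), pch = 8)
  invisible(x)
}

# per-group cross-talk Spearman correlations of start and stop orders,
# over individuals who started in both talks (groups with < 3 shared
# starters yield NA)
cross_talk_rho <- function(bouts) {
  bouts <- as_bout_list(bouts)
  gids <- vapply(bouts, attr, "", "group_id")
  out <- lapply(unique(gids), function(g) {
    bs <- bouts[gids == g]
    if (length(bs) < 2L) return(NULL)
    b1 <- bs[[1L]]; b2 <- bs[[2L]]
    shared <- intersect(b1$individual_id[starters(b1)],
                        b2$individual_id[starters(b2)])
    if (length(shared) < 3L)
      return(data.frame(group_id = g, n_shared = length(shared),
                        rho_start = NA_real_, rho_stop = NA_real_))
    s1 <- b1$start_time[match(shared, b1$individual_id)]
    s2 <- b2$start_time[match(shared, b2$individual_id)]
    e1 <- b1$stop_time[match(shared, b1$individual_id)]
    e2 <- b2$stop_time[match(shared, b2$individual_id)]
    data.frame(group_id = g, n_shared = length(shared),
               rho_start = stats::cor(s1, s2, method = "spearman"),
               rho_stop = stats::cor(e1, e2, method = "spearman"))
  })
  do.call(rbind, out)
}

#' Individual-consistency test of start and stop orders
#'
#' For each group with two talks, the Spearman rank correlation between the
#' orders in which the shared starters started (and stopped) clapping in
#' talk 1 versus talk 2; the test statistic is the median correlation
#' across groups. The null distribution is built by independently permuting
#' one talk's order within each group and recomputing the pooled median;
#' the p-value is the fraction of null medians at least as large as the
#' observed one. Groups with fewer than 3 shared starters are excluded
#' (with a message).
#'
#' @param bouts a [bout_list()] containing two talks per group.
#' @param n_randomizations permutations for the null distribution.
#' @param seed optional integer seed.
#' @return A list of class `consistency_test`: `per_group`,
#'   `median_rho_start`, `p_start`, `median_rho_stop`, `p_stop`,
#'   `n_randomizations`.
#' @export
consistency_test <- function(bouts, n_randomizations = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  per <- cross_talk_rho(bouts)
  if (is.null(per) || !nrow(per)) stop("no group has two talks")
  drop <- is.na(per$rho_start)
  if (any(drop))
    message(sum(drop), " group(s) excluded (< 3 shared starters)")
  keep <- per[!drop, , drop = FALSE]
  if (!nrow(keep)) stop("no group with >= 3 shared starters")
  obs_start <- stats::median(keep$rho_start)
  obs_stop <- stats::median(keep$rho_stop)

  null_medians <- function() {
    # permuting one talk's order makes the two orders independent while
    # preserving each group's size; a permuted rank vector's Spearman
    # correlation with the other talk is that of a random permutation
    vapply(seq_len(n_randomizations), function(r) {
      rs <- vapply(keep$n_shared, function(n)
        stats::cor(seq_len(n), sample.int(n), method = "spearman"),
        numeric(1))
      stats::median(rs)
    }, numeric(1))
  }
  null_s <- null_medians()
  null_e <- null_medians()
  structure(list(per_group = per,
                 median_rho_start = obs_start,
                 p_start = mean(null_s >= obs_start),
                 median_rho_stop = obs_stop,
                 p_stop = mean(null_e >= obs_stop),
                 n_randomizations = n_randomizations),
            class = "consistency_test")
}

#' @export
print.consistency_test <- function(x, ...) {
  cat(sprintf("Cross-talk consistency over %d group(s), %d randomizations\n",
              nrow(x$per_group), x$n_randomizations))
  cat(sprintf("  start order: median rho = %.2f, p = %.4g\n",
              x$median_rho_start, x$p_start))
  cat(sprintf("  stop order:  median rho = %.2f, p = %.4g\n",
              x$median_rho_stop, x$p_stop))
  invisible(x)
}
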