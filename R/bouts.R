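#' Construct an applause bout
#'
#' A bout is one complete episode of audience applause: one record per
#' audience member giving when (if ever) they started and stopped clapping,
#' their seat on the room's row/column grid, and optionally the times of
#' every individual clap. Times are in seconds relative to the first clap of
#' the bout, so at least one starter has `start_time == 0`.
#'
#' @param group_id,talk_id identifiers of the audience group and of the talk
#'   (presentation) the bout followed.
#' @param records a `data.frame` with columns `individual_id`, `seat_row`,
#'   `seat_col`, `start_time`, `stop_time` and optionally a list column
#'   `clap_times`. Non-starters have `NA` start and stop times and no clap
#'   times.
#' @param shift_origin if `TRUE` (default), subtract the earliest start time
#'   from all times so the bout's first clap is at 0.
#'
#' @return An object of class `bout`: the validated record table plus
#'   `group_id`, `talk_id` and the audience size `N` as attributes.
#' @export
bout <- function(group_id, talk_id, records, shift_origin = TRUE) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  req <- c("individual_id", "seat_row", "seat_col", "start_time", "stop_time")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("bout records missing column(s): ", paste(miss, collapse = ", "))
  if (!"clap_times" %in% names(records))
    records$clap_times <- rep(list(NULL), nrow(records))
  if (anyDuplicated(records$individual_id))
    stop("duplicated individual_id in bout (", group_id, ", ", talk_id, ")")

  if (shift_origin && any(!is.na(records$start_time))) {
    origin <- min(records$start_time, na.rm = TRUE)
    records$start_time <- records$start_time - origin
    records$stop_time <- records$stop_time - origin
    records$clap_times <- lapply(records$clap_times, function(ct)
      if (is.null(ct) || !length(ct)) NULL else ct - origin)
  }
  # deterministic tie-breaking: order by (start time, individual id)
  ord <- order(records$start_time, as.character(records$individual_id),
               na.last = TRUE)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL

  b <- structure(records, class = c("bout", "data.frame"),
                 group_id = group_id, talk_id = talk_id, N = nrow(records))
  validate_bout(b)
  b
}

#' @export
print.bout <- function(x, ...) {
  st <- starters(x)
  cat(sprintf("Applause bout: group %s, talk %s, N = %d (%d starters)\n",
              attr(x, "group_id"), attr(x, "talk_id"), attr(x, "N"),
              sum(st)))
  if (any(st))
    cat(sprintf("  start spread %.2f s, bout length %.2f s\n",
                max(x$start_time[st]) - min(x$start_time[st]),
                max(x$stop_time[st]) - min(x$start_time[st])))
  invisible(x)
}

starters <- function(b) !is.na(b$start_time)

has_clap_times <- function(b) {
  all(vapply(which(starters(b)), function(i) length(b$clap_times[[i]]) >= 1L,
             logical(1)))
}

validate_bout <- function(b) {
  id <- function(i) sprintf("record individual_id=%s (group %s, talk %s)",
                            b$individual_id[i], attr(b, "group_id"),
                            attr(b, "talk_id"))
  for (i in seq_len(nrow(b))) {
    s <- b$start_time[i]; e <- b$stop_time[i]; ct <- b$clap_times[[i]]
    if (is.na(s)) {
      if (!is.na(e)) stop("non-starter has a stop_time: ", id(i))
      if (length(ct)) stop("non-starter has clap_times: ", id(i))
      next
    }
    if (is.na(e)) stop("starter without stop_time: ", id(i))
    if (e < s) stop("stop_time < start_time: ", id(i))
    if (length(ct)) {
      if (any(diff(ct) <= 0))
        stop("clap_times not strictly increasing: ", id(i))
      if (abs(ct[1] - s) > 1e-8 || abs(ct[length(ct)] - e) > 1e-8)
        stop("clap_times must span [start_time, stop_time]: ", id(i))
    }
  }
  st <- b$start_time[starters(b)]
  if (length(st) && min(st) > 1e-8)
    stop("bout time origin is not the first clap (earliest start ",
         format(min(st)), " s); construct with shift_origin = TRUE")
  invisible(b)
}

#' Bundle bouts into a collection
#'
#' @param ... `bout` objects, or a single list of them.
#' @return A list of bouts with class `bout_list`.
#' @export
bout_list <- function(...) {
  bl <- list(...)
  if (length(bl) == 1L && !inherits(bl[[1]], "bout")) bl <- bl[[1]]
  stopifnot(all(vapply(bl, inherits, logical(1), "bout")))
  structure(bl, class = "bout_list")
}

#' @export
print.bout_list <- function(x, ...) {
  cat(sprintf("Collection of %d applause bouts (audience sizes %s)\n",
              length(x),
              paste(vapply(x, attr, 1L, "N"), collapse = ", ")))
  invisible(x)
}

#' @export
`[.bout_list` <- function(x, i) bout_list(unclass(x)[i])

as_bout_list <- function(x) {
  if (inherits(x, "bout")) bout_list(list(x))
  else if (inherits(x, "bout_list")) x
  else bout_list(x)
}

bout_last_stop <- function(b) {
  if (!any(starters(b))) stop("bout has no starters")
  max(b$stop_time, na.rm = TRUE)
}

bout_first_stop <- function(b) min(b$stop_time, na.rm = TRUE)

# --- file I/O -----------------------------------------------------------

#' Read or write applause bouts
#'
#' The CSV dialect has one row per audience member with header
#' `group_id,talk_id,individual_id,seat_row,seat_col,start_time,stop_time,clap_times`;
#' `clap_times` is a semicolon-separated list of seconds and an empty
#' `start_time` marks a non-starter. The JSON format mirrors the same schema
#' (an array of bout objects, each with a `records` array). All times are in
#' seconds relative to the bout's first clap; on reading, each bout's time
#' origin is shifted so its earliest start is 0.
#'
#' @param path file to read or write.
#' @param format `"csv"` or `"json"`; guessed from the file extension when
#'   missing.
#' @param bouts a `bout_list` (or single `bout`) to write.
#' @return `read_bouts` returns a [bout_list()]; `write_bouts` returns
#'   `path` invisibly.
#' @export
read_bouts <- function(path, format = c("csv", "json")) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  format <- if (missing(format)) guess_format(path) else match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = list(group_id = "character",
                                            talk_id = "character",
                                            individual_id = "character",
                                            clap_times = "character"))
    df$clap_times <- lapply(df$clap_times, parse_clap_times)
  } else {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    rows <- list()
    for (bt in raw) for (r in bt$records) {
      rows[[length(rows) + 1L]] <- data.frame(
        group_id = as.character(bt$group_id),
        talk_id = as.character(bt$talk_id),
        individual_id = as.character(r$individual_id),
        seat_row = as.integer(r$seat_row),
        seat_col = as.integer(r$seat_col),
        start_time = if (is.null(r$start_time)) NA_real_ else as.numeric(r$start_time),
        stop_time = if (is.null(r$stop_time)) NA_real_ else as.numeric(r$stop_time),
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$clap_times <- list(
        if (is.null(r$clap_times) || !length(r$clap_times)) NULL
        else as.numeric(unlist(r$clap_times)))
    }
    df <- do.call(rbind, rows)
  }
  df_to_bouts(df)
}

guess_format <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
}

parse_clap_times <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
}

df_to_bouts <- function(df) {
  need <- c("group_id", "talk_id", "individual_id", "seat_row", "seat_col",
            "start_time", "stop_time")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("malformed input, missing column(s): ",
                         paste(miss, collapse = ", "))
  key <- interaction(df$group_id, df$talk_id, drop = TRUE, lex.order = TRUE)
  bl <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    sub <- df[idx, , drop = FALSE]
    bout(sub$group_id[1], sub$talk_id[1],
         sub[, c("individual_id", "seat_row", "seat_col", "start_time",
                 "stop_time", "clap_times")])
  })
  bout_list(unname(bl))
}

#' @rdname read_bouts
#' @export
write_bouts <- function(bouts, path, format = c("csv", "json")) {
  bouts <- as_bout_list(bouts)
  format <- if (missing(format)) guess_format(path) else match.arg(format)
  if (format == "csv") {
    df <- do.call(rbind, lapply(bouts, function(b) {
      data.frame(group_id = attr(b, "group_id"), talk_id = attr(b, "talk_id"),
                 individual_id = b$individual_id, seat_row = b$seat_row,
                 seat_col = b$seat_col, start_time = b$start_time,
                 stop_time = b$stop_time,
                 clap_times = vapply(b$clap_times, function(ct)
                   if (is.null(ct)) "" else paste(format(ct, digits = 12, trim = TRUE,
                                                         scientific = FALSE),
                                                  collapse = ";"),
                   character(1)),
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else {
    out <- lapply(bouts, function(b) {
      list(group_id = attr(b, "group_id"), talk_id = attr(b, "talk_id"),
           records = lapply(seq_len(nrow(b)), function(i) {
             r <- list(individual_id = b$individual_id[i],
                       seat_row = b$seat_row[i], seat_col = b$seat_col[i])
             if (!is.na(b$start_time[i])) {
               r$start_time <- b$start_time[i]
               r$stop_time <- b$stop_time[i]
               if (length(b$clap_times[[i]]))
                 r$clap_times <- b$clap_times[[i]]
             }
             r
           }))
    })
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

# --- neighbours ---------------------------------------------------------

#' Seat neighbours on the seating grid
#'
#' Immediate neighbours are the occupied seats directly left, right, in
#' front of and behind the focal seat (the audience sits in rows facing the
#' presenter); `diagonal = TRUE` also counts the four diagonal seats.
#'
#' @param b a [bout()].
#' @param diagonal include diagonal seats.
#' @return A list, indexed like the bout's records, of integer vectors of
#'   neighbouring record indices.
#' @export
seat_neighbours <- function(b, diagonal = FALSE) {
  dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  if (diagonal) {
    dr <- c(dr, -1L, -1L, 1L, 1L); dc <- c(dc, -1L, 1L, -1L, 1L)
  }
  key <- paste(b$seat_row, b$seat_col)
  lookup <- match(key, key)  # guard duplicated seats
  if (anyDuplicated(key)) stop("duplicated seat in bout")
  lapply(seq_len(nrow(b)), function(i) {
    nb <- paste(b$seat_row[i] + dr, b$seat_col[i] + dc)
    which(key %in% nb)
  })
}

# --- audience state trajectory ------------------------------------------

#' Audience S/I/R composition through time
#'
#' Returns, on a time grid, the fraction of the audience that has started
#' clapping (`rho_clapping`, the "already infected" I + R), the fraction
#' that has started and then stopped (`rho_stopped`, R), and the fraction
#' currently clapping (I). All fractions use the full audience size N as
#' denominator; non-starters stay susceptible throughout. The fractions are
#' stepwise constant with jumps exactly at start/stop events.
#'
#' @param b a [bout()].
#' @param time_grid numeric vector of times (seconds); default: the bout's
#'   event times.
#' @return A `data.frame` with columns `time`, `rho_clapping`,
#'   `rho_stopped`, `clapping_now`.
#' @export
audience_trajectory <- function(b, time_grid = NULL) {
  if (!inherits(b, "bout")) stop("`b` must be a bout")
  if (!any(starters(b))) stop("empty bout: no starters")
  N <- attr(b, "N")
  st <- sort(b$start_time[starters(b)])
  sp <- sort(b$stop_time[starters(b)])
  if (is.null(time_grid)) time_grid <- sort(unique(c(st, sp)))
  started <- vapply(time_grid, function(t) sum(st <= t), numeric(1))
  stopped <- vapply(time_grid, function(t) sum(sp <= t), numeric(1))
  data.frame(time = time_grid,
             rho_clapping = started / N,
             rho_stopped = stopped / N,
             clapping_now = (started - stopped) / N)
}

# fractions already started / already stopped at time t, plus neighbour
# versions, used by the observation builders. "Already" means event time
# <= t for starts and < t for stops (a stopping decision cannot see the
# stop it creates).
state_at <- function(b, t, nb_idx) {
  N <- attr(b, "N")
  started <- !is.na(b$start_time) & b$start_time <= t
  stopped <- !is.na(b$stop_time) & b$stop_time < t
  list(rho_clapping = sum(started) / N,
       rho_stopped = sum(stopped) / N,
       started = started, stopped = stopped)
}

# --- observation sets ----------------------------------------------------

#' Per-frame starting observations
#'
#' Discretizes each bout into frames of length `dt` and emits, for every
#' individual while susceptible, one observation per frame carrying the
#' audience state at the frame start (fraction already clapping, fraction of
#' seat neighbours already clapping) and the binary outcome started / not
#' started. The initiator (start time 0) is conditioned on — the analysis of
#' starting begins after the first clap — and contributes no observations.
#' Starters contribute frames up to and including the frame containing their
#' start; non-starters contribute frames until the bout's last stop.
#'
#' @param bouts a [bout()] or [bout_list()].
#' @param dt frame length in seconds (default 0.1).
#' @param diagonal passed to [seat_neighbours()].
#' @return A `data.frame` with columns `group_id`, `talk_id`,
#'   `individual_id`, `t0` (frame start), `rho` (fraction already clapping),
#'   `nb` (neighbour fraction already clapping) and logical `started`, with
#'   the frame length in attribute `dt`.
#' @export
make_start_observations <- function(bouts, dt = 0.1, diagonal = FALSE) {
  stopifnot(dt > 0)
  bouts <- as_bout_list(bouts)
  out <- lapply(bouts, function(b) {
    N <- attr(b, "N")
    nb_idx <- seat_neighbours(b, diagonal)
    end <- bout_last_stop(b)
    is_start <- starters(b)
    started_t <- b$start_time
    rows <- vector("list", nrow(b))
    for (i in seq_len(nrow(b))) {
      s <- b$start_time[i]
      if (!is.na(s) && s <= 0) next  # initiator: conditioned on, not modelled
      nfr <- if (!is.na(s)) floor(s / dt) + 1L else ceiling(end / dt)
      if (nfr < 1L) next
      t0 <- (seq_len(nfr) - 1L) * dt
      rho <- vapply(t0, function(t) sum(started_t <= t, na.rm = TRUE), numeric(1)) / N
      nbv <- if (length(nb_idx[[i]])) {
        nbs <- started_t[nb_idx[[i]]]
        vapply(t0, function(t) mean(!is.na(nbs) & nbs <= t), numeric(1))
      } else rep(0, nfr)
      outc <- rep(FALSE, nfr)
      if (!is.na(s)) outc[nfr] <- TRUE
      rows[[i]] <- data.frame(group_id = attr(b, "group_id"),
                              talk_id = attr(b, "talk_id"),
                              individual_id = b$individual_id[i],
                              t0 = t0, rho = rho, nb = nbv, started = outc,
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  })
  obs <- do.call(rbind, out)
  rownames(obs) <- NULL
  structure(obs, dt = dt)
}

#' Per-clap stopping observations
#'
#' Emits one observation per clap per individual: the clap index, the
#' audience state at the instant of that clap (fraction already stopped, with
#' the full audience size as denominator; fraction of seat neighbours already
#' stopped) and the binary outcome stopped / continued. The last clap of each
#' starter has outcome stopped. With `restrict_after_first_stop = TRUE` only
#' claps strictly after the bout's first stop are emitted — the restricted
#' data set on which a purely social stopping model is admissible.
#'
#' @param bouts a [bout()] or [bout_list()].
#' @param restrict_after_first_stop drop all claps up to and including the
#'   bout's first stop event.
#' @param diagonal passed to [seat_neighbours()].
#' @return A `data.frame` with columns `group_id`, `talk_id`,
#'   `individual_id`, `n` (clap index, from 1), `t` (clap time),
#'   `rho_stopped`, `nb_stopped` and logical `stopped`, with the maximum
#'   observed clap count in attribute `n_max_observed`.
#' @export
make_stop_observations <- function(bouts, restrict_after_first_stop = FALSE,
                                   diagonal = FALSE) {
  bouts <- as_bout_list(bouts)
  out <- lapply(bouts, function(b) {
    if (!has_clap_times(b))
      stop("bout (group ", attr(b, "group_id"), ", talk ", attr(b, "talk_id"),
           ") has starters without clap_times; reconstruct them first, ",
           "e.g. with reconstruct_clap_times()")
    N <- attr(b, "N")
    nb_idx <- seat_neighbours(b, diagonal)
    first_stop <- bout_first_stop(b)
    stops_t <- b$stop_time
    rows <- vector("list", nrow(b))
    for (i in seq_len(nrow(b))) {
      ct <- b$clap_times[[i]]
      if (!length(ct)) next
      n <- seq_along(ct)
      keep <- if (restrict_after_first_stop) ct > first_stop + 1e-12 else rep(TRUE, length(ct))
      if (!any(keep)) next
      rho <- vapply(ct, function(t) sum(!is.na(stops_t) & stops_t < t), numeric(1)) / N
      nbv <- if (length(nb_idx[[i]])) {
        nbs <- stops_t[nb_idx[[i]]]
        vapply(ct, function(t) mean(!is.na(nbs) & nbs < t), numeric(1))
      } else rep(0, length(ct))
      outc <- c(rep(FALSE, length(ct) - 1L), TRUE)
      rows[[i]] <- data.frame(group_id = attr(b, "group_id"),
                              talk_id = attr(b, "talk_id"),
                              individual_id = b$individual_id[i],
                              n = n[keep], t = ct[keep], rho_stopped = rho[keep],
                              nb_stopped = nbv[keep], stopped = outc[keep],
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  })
  obs <- do.call(rbind, out)
  rownames(obs) <- NULL
  structure(obs, n_max_observed = if (is.null(obs)) 0L else max(obs$n))
}

#' Reconstruct clap times from start/stop times
#'
#' When per-clap times were not coded, claps are placed at equal intervals
#' between each starter's start and stop time, using the clap count implied
#' by the mean clap interval (default 0.28 s).
#'
#' @param bouts a [bout()] or [bout_list()].
#' @param interval_mean mean clap interval in seconds.
#' @return The input with `clap_times` filled for every starter.
#' @export
reconstruct_clap_times <- function(bouts, interval_mean = 0.28) {
  one <- function(b) {
    for (i in which(starters(b))) {
      if (length(b$clap_times[[i]])) next
      s <- b$start_time[i]; e <- b$stop_time[i]
      if (e - s < 1e-9) {
        b$clap_times[[i]] <- s
      } else {
        k <- max(2L, round((e - s) / interval_mean) + 1L)
        b$clap_times[[i]] <- seq(s, e, length.out = k)
      }
    }
    b
  }
  if (inherits(bouts, "bout")) one(bouts) else bout_list(lapply(bouts, one))
}
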