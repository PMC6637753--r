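#' Piecewise-constant perturbation schedule
#'
#' A schedule is a baseline parameter set plus an ordered list of events,
#' each applying named parameter overrides on a half-open time window
#' `[t_start, t_end)`. `t_end = Inf` means open-ended. Events affecting the
#' same parameter must not overlap.
#'
#' @param baseline Named parameter vector (see [default_parameters()]).
#' @param events List of events; each event is a list with elements
#'   `t_start` (h), `t_end` (h, may be `Inf`) and `overrides` (named numeric).
#' @return Object of class `grn_schedule`.
#' @export
#' @examples
#' sch <- perturbation_schedule(default_parameters(),
#'   list(list(t_start = 100, t_end = 105, overrides = c(Src = 0.2))))
perturbation_schedule <- function(baseline, events = list()) {
  baseline <- validate_parameters(baseline)
  if (length(events) > 0) {
    for (e in events) {
      if (!all(c("t_start", "t_end", "overrides") %in% names(e)))
        stop("each event needs t_start, t_end and overrides", call. = FALSE)
      if (!is.finite(e$t_start) || e$t_start < 0 || e$t_end <= e$t_start)
        stop("event times must satisfy 0 <= t_start < t_end", call. = FALSE)
      apply_overrides(baseline, e$overrides)  # validates names
    }
    ## overlap check per parameter
    for (nm in unique(unlist(lapply(events, function(e) names(unlist(e$overrides)))))) {
      ivl <- do.call(rbind, lapply(events, function(e) {
        if (nm %in% names(unlist(e$overrides))) c(e$t_start, e$t_end) else NULL
      }))
      if (!is.null(ivl) && nrow(ivl) > 1) {
        ivl <- ivl[order(ivl[, 1]), , drop = FALSE]
        if (any(ivl[-nrow(ivl), 2] > ivl[-1, 1] + 1e-12))
          stop("overlapping events for parameter ", nm, call. = FALSE)
      }
    }
    events <- events[order(vapply(events, `[[`, 1, "t_start"))]
  }
  structure(list(baseline = baseline, events = events),
            class = "grn_schedule")
}

#' Effective parameters of a schedule at a given time
#' @param schedule A `grn_schedule`.
#' @param t Time (h).
#' @return Named parameter vector with all active overrides applied.
#' @export
schedule_parameters_at <- function(schedule, t) {
  p <- schedule$baseline
  for (e in schedule$events)
    if (t >= e$t_start && t < e$t_end) p <- apply_overrides(p, e$overrides)
  p
}

## internal: event boundaries within [0, t_end]
.schedule_breaks <- function(schedule, t_end) {
  b <- c(0, t_end)
  for (e in schedule$events)
    b <- c(b, e$t_start, if (is.finite(e$t_end)) e$t_end)
  sort(unique(b[b >= 0 & b <= t_end]))
}

#' Integrate the model over a perturbation schedule
#'
#' Integrates the 29-variable system with a stiff-capable adaptive solver
#' (`deSolve::lsoda`), restarting the integration exactly at every event
#' boundary so that parameter steps are sharp. Output is sampled on a
#' regular grid.
#'
#' @param schedule A `grn_schedule` (or a bare parameter vector, treated as
#'   an event-free schedule).
#' @param initial Initial state vector (29 components; see [initial_state()]).
#' @param t_end End time (h), > 0.
#' @param output_step Output sampling step (h).
#' @param rtol,atol Solver tolerances.
#' @param compiled Use the compiled right-hand side (default); set to
#'   `FALSE` to integrate through the reference R implementation
#'   ([grn_rhs()]), which is much slower but must agree.
#' @return Object of class `grn_trajectory`: list with elements `time`
#'   (vector, h), `state` (matrix time x 29, canonical column names),
#'   `schedule`.
#' @export
#' @examples
#' tr <- integrate_model(default_parameters(), t_end = 50, output_step = 1)
#' dim(tr$state)
integrate_model <- function(schedule, initial = NULL, t_end = 600,
                            output_step = 0.5, rtol = 1e-8, atol = 1e-10,
                            compiled = TRUE) {
  if (!inherits(schedule, "grn_schedule"))
    schedule <- perturbation_schedule(schedule)
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  if (output_step <= 0 || output_step > t_end)
    stop("output_step must be in (0, t_end]", call. = FALSE)
  if (is.null(initial)) initial <- initial_state(schedule$baseline)
  if (length(initial) != 29L || !all(is.finite(initial)))
    stop("initial state must be 29 finite values", call. = FALSE)
  y <- stats::setNames(as.numeric(initial)[match(species_names(),
        if (is.null(names(initial))) species_names() else names(initial))],
        species_names())
  if (anyNA(y)) stop("initial state names do not match canonical species",
                     call. = FALSE)

  grid <- seq(0, t_end, by = output_step)
  breaks <- .schedule_breaks(schedule, t_end)
  out <- matrix(NA_real_, nrow = length(grid), ncol = 29,
                dimnames = list(NULL, species_names()))
  out_t <- grid
  filled <- 1L
  out[1L, ] <- y

  for (i in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1L]
    p <- schedule_parameters_at(schedule, t0)
    seg_grid <- grid[grid > t0 & grid <= t1]
    times <- unique(c(t0, seg_grid, t1))
    sol <- if (compiled) {
      deSolve::lsoda(unname(y), times, func = "grn_derivs", parms = unname(p),
                     dllname = "let7cycle", initfunc = "grn_initmod",
                     rtol = rtol, atol = atol, maxsteps = 100000)
    } else {
      deSolve::lsoda(unname(y), times,
                     func = function(t, yy, pp) list(unname(grn_rhs(yy, t, pp))),
                     parms = p, rtol = rtol, atol = atol, maxsteps = 100000)
    }
    if (nrow(sol) < length(times) || !all(is.finite(sol[, -1])))
      stop("integration failed near t = ",
           signif(sol[nrow(sol), 1], 6), " h", call. = FALSE)
    y <- stats::setNames(sol[nrow(sol), -1], species_names())
    if (length(seg_grid) > 0) {
      idx <- match(seg_grid, times)
      out[filled + seq_along(seg_grid), ] <- sol[idx, -1, drop = FALSE]
      filled <- filled + length(seg_grid)
    }
  }
  structure(list(time = out_t, state = out, schedule = schedule),
            class = "grn_trajectory")
}

#' @export
print.grn_trajectory <- function(x, ...) {
  cat("grn_trajectory:", length(x$time), "time points, 0 to",
      max(x$time), "h;", ncol(x$state), "species\n")
  invisible(x)
}

#' Write / read a trajectory as CSV
#'
#' First column `time_h`, then the 29 canonical species columns.
#'
#' @param traj A `grn_trajectory`.
#' @param path File path.
#' @param comment Optional comment lines (each written prefixed with `#`).
#' @return `write_trajectory`: invisibly `path`; `read_trajectory`: a
#'   `grn_trajectory` (without schedule).
#' @export
write_trajectory <- function(traj, path, comment = NULL) {
  stopifnot(inherits(traj, "grn_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  df <- data.frame(time_h = traj$time, traj$state, check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  if (names(df)[1] != "time_h" || !setequal(names(df)[-1], species_names()))
    stop("not a canonical trajectory CSV: ", path, call. = FALSE)
  structure(list(time = df$time_h,
                 state = as.matrix(df[, species_names(), drop = FALSE]),
                 schedule = NULL),
            class = "grn_trajectory")
}
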