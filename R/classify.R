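#' Find local maxima with a minimum prominence
#'
#' Simple deterministic peak detector on a sampled signal: a peak is a
#' strict local maximum whose prominence (height above the higher of the
#' two flanking valleys, valleys taken between consecutive peaks or signal
#' ends) is at least `min_prominence`.
#'
#' @param x Numeric vector.
#' @param min_prominence Minimum prominence (same units as `x`).
#' @return Integer vector of peak indices.
#' @export
find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(cand) == 0) return(integer(0))
  keep <- logical(length(cand))
  bounds <- c(1L, cand, n)
  for (i in seq_along(cand)) {
    left_valley <- min(x[bounds[i]:cand[i]])
    right_valley <- min(x[cand[i]:bounds[i + 2L]])
    prom <- x[cand[i]] - max(left_valley, right_valley)
    keep[i] <- prom >= min_prominence
  }
  cand[keep]
}

#' Classify the dynamical regime of a trajectory
#'
#' Analyzes the final `window_fraction` of a trajectory (the transient is
#' discarded) and labels the dynamics as `steady`,
#' `proliferative_oscillations` (both cyclin E/Cdk2 and cyclin B/Cdk1
#' oscillate with amplitude above threshold) or `endocycle_like` (cyclin
#' E/Cdk2 oscillates but cyclin B/Cdk1 does not; repeated rounds of DNA
#' replication without mitosis).
#'
#' A species counts as oscillating when its peak-to-trough amplitude over
#' the window is at least `delta_abs` (a.u.) and at least `delta_rel`
#' relative to its peak. The period is the mean inter-peak interval when
#' at least 3 peaks (minimum prominence `delta_abs`) are detected.
#'
#' @param traj A `grn_trajectory`.
#' @param window_fraction Fraction of the horizon analyzed (default 0.4,
#'   i.e. the last 40 percent).
#' @param delta_rel Relative amplitude threshold (default 0.05).
#' @param delta_abs Absolute amplitude threshold (a.u., default 0.01).
#' @return Object of class `grn_regime`: list with `label`, `amplitude`
#'   (named per-species peak-to-trough), `period` (named, h; `NA` when
#'   fewer than 3 peaks), `oscillating` (named logical), and
#'   `steady_state` (named vector, final state, when label is `steady`).
#' @export
#' @examples
#' tr <- integrate_model(apply_overrides(default_parameters(),
#'   c(V_SLET7 = 0)), t_end = 300)
#' classify_regime(tr)$label
classify_regime <- function(traj, window_fraction = 0.4,
                            delta_rel = 0.05, delta_abs = 0.01) {
  stopifnot(inherits(traj, "grn_trajectory"))
  if (window_fraction <= 0 || window_fraction > 1)
    stop("window_fraction must be in (0, 1]", call. = FALSE)
  t_max <- max(traj$time)
  sel <- traj$time >= (1 - window_fraction) * t_max
  if (sum(sel) < 3L)
    stop("analysis window shorter than 3 output steps", call. = FALSE)
  w <- traj$state[sel, , drop = FALSE]
  tw <- traj$time[sel]

  pk <- apply(w, 2, max)
  amp <- pk - apply(w, 2, min)
  rel <- ifelse(pk > 0, amp / pk, 0)
  oscillating <- amp >= delta_abs & rel >= delta_rel

  period <- vapply(colnames(w), function(sp) {
    if (!oscillating[[sp]]) return(NA_real_)
    peaks <- find_peaks(w[, sp], min_prominence = delta_abs)
    if (length(peaks) < 3) return(NA_real_)
    mean(diff(tw[peaks]))
  }, 1)

  label <- if (oscillating[["Ce"]] && oscillating[["Cb"]]) {
    "proliferative_oscillations"
  } else if (oscillating[["Ce"]]) {
    "endocycle_like"
  } else {
    "steady"
  }
  structure(list(label = label, amplitude = amp, period = period,
                 oscillating = oscillating,
                 steady_state = if (label == "steady") w[nrow(w), ] else NULL,
                 window_fraction = window_fraction,
                 delta_rel = delta_rel, delta_abs = delta_abs),
            class = "grn_regime")
}

#' @export
print.grn_regime <- function(x, ...) {
  cat("regime:", x$label, "| Ce amp:", signif(x$amplitude[["Ce"]], 4),
      "Cb amp:", signif(x$amplitude[["Cb"]], 4))
  if (is.finite(x$period[["Cb"]]))
    cat(" | Cb period:", signif(x$period[["Cb"]], 4), "h")
  cat("\n")
  invisible(x)
}

#' Two-parameter regime map
#'
#' Classifies the asymptotic regime on a rectangular grid in two parameters.
#' Each cell is an independent `integrate_model()` + [classify_regime()]
#' run from the same initial state.
#'
#' @param param_x,param_y Parameter names (must exist in the parameter set).
#' @param values_x,values_y Ascending numeric grids.
#' @param base Baseline parameters.
#' @param initial Initial state (default [initial_state()] of `base`).
#' @param t_end,output_step,window_fraction,delta_rel,delta_abs Passed to
#'   the integration / classification.
#' @return Object of class `grn_scan`: list with `labels` (character matrix
#'   values_x rows x values_y columns), the axes, and classification settings.
#' @export
scan_2d <- function(param_x, values_x, param_y, values_y,
                    base = default_parameters(), initial = NULL,
                    t_end = 600, output_step = 0.5, window_fraction = 0.4,
                    delta_rel = 0.05, delta_abs = 0.01) {
  if (length(values_x) == 0 || length(values_y) == 0)
    stop("value grids must be non-empty", call. = FALSE)
  if (is.unsorted(values_x) || is.unsorted(values_y))
    stop("value grids must be ascending", call. = FALSE)
  apply_overrides(base, stats::setNames(c(values_x[1], values_y[1]),
                                        c(param_x, param_y)))  # validate names
  if (is.null(initial)) initial <- initial_state(base)
  labels <- matrix(NA_character_, length(values_x), length(values_y),
                   dimnames = list(signif(values_x, 8), signif(values_y, 8)))
  for (i in seq_along(values_x)) {
    for (j in seq_along(values_y)) {
      p <- apply_overrides(base, stats::setNames(
        c(values_x[i], values_y[j]), c(param_x, param_y)))
      res <- tryCatch({
        tr <- integrate_model(p, initial = initial, t_end = t_end,
                              output_step = output_step)
        classify_regime(tr, window_fraction, delta_rel, delta_abs)$label
      }, error = function(e) {
        stop("scan cell (", param_x, "=", values_x[i], ", ", param_y, "=",
             values_y[j], "): ", conditionMessage(e), call. = FALSE)
      })
      labels[i, j] <- res
    }
  }
  structure(list(labels = labels, param_x = param_x, values_x = values_x,
                 param_y = param_y, values_y = values_y,
                 delta_rel = delta_rel, delta_abs = delta_abs),
            class = "grn_scan")
}

#' Fraction of a regime map that is oscillatory
#'
#' @param scan A `grn_scan` (or a character matrix of labels).
#' @param weights Optional matrix of cell areas / weights (defaults to equal).
#' @return Named numeric vector: `proliferative` (fraction of the plane in
#'   proliferative limit-cycle oscillations) and `endocycle` (fraction
#'   endocycle-like, reported separately).
#' @export
oscillatory_area <- function(scan, weights = NULL) {
  labels <- if (inherits(scan, "grn_scan")) scan$labels else scan
  if (!is.matrix(labels) && !is.character(labels))
    stop("malformed label grid", call. = FALSE)
  if (is.null(weights)) weights <- array(1, dim = dim(as.matrix(labels)))
  w <- weights / sum(weights)
  c(proliferative = sum(w[labels == "proliferative_oscillations"]),
    endocycle = sum(w[labels == "endocycle_like"]))
}

#' Write a regime map as a labeled CSV grid
#'
#' Rows are `param_x` values, columns `param_y` values; the first column
#' holds the x-axis values, the header row the y-axis values.
#'
#' @param scan A `grn_scan`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scan_csv <- function(scan, path) {
  stopifnot(inherits(scan, "grn_scan"))
  df <- data.frame(scan$values_x, scan$labels, check.names = FALSE)
  names(df) <- c(paste0(scan$param_x, "\\", scan$param_y), scan$values_y)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
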