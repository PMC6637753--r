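#' Specification of a heterogeneous cell population
#'
#' Cell-to-cell heterogeneity is parametric: each kinetic parameter of each
#' cell is drawn independently and uniformly from
#' `[p0 (1 - f), p0 (1 + f)]` around its basal value `p0`, where `f` is the
#' jitter fraction. External inputs (by default `GF` and `Src`, which are
#' protocol-controlled) are exempt.
#'
#' @param n_cells Number of cells (>= 1).
#' @param jitter_fraction Uniform jitter fraction `f` in `[0, 1)`.
#' @param start Initial state name: `"NT"` (non-transformed quiescent
#'   fixture) or `"T"` (transformed proliferative fixture).
#' @param base Basal parameter set.
#' @param seed Integer random seed (all draws are reproducible given it).
#' @param exempt Parameter names exempt from jitter.
#' @return Object of class `grn_population_spec`.
#' @export
population_spec <- function(n_cells = 500, jitter_fraction = 0.25,
                            start = c("NT", "T"),
                            base = default_parameters(), seed = 1,
                            exempt = c("GF", "Src")) {
  start <- match.arg(start)
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  if (jitter_fraction < 0 || jitter_fraction >= 1)
    stop("jitter_fraction must be in [0, 1)", call. = FALSE)
  base <- validate_parameters(base)
  bad <- setdiff(exempt, names(base))
  if (length(bad)) stop("unknown exempt parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(n_cells = as.integer(n_cells),
                 jitter_fraction = jitter_fraction, start = start,
                 base = base, seed = as.integer(seed), exempt = exempt),
            class = "grn_population_spec")
}

#' Draw the per-cell parameter sets of a population
#'
#' All draws come from a single seeded stream laid out as an
#' `n_cells x n_parameters` matrix, so cell `i`'s parameters do not depend
#' on how many cells are eventually simulated or in which order.
#'
#' @param spec A `grn_population_spec`.
#' @return Numeric matrix, `n_cells` rows x parameters (canonical columns).
#' @export
draw_population <- function(spec) {
  stopifnot(inherits(spec, "grn_population_spec"))
  p0 <- spec$base
  f <- spec$jitter_fraction
  set.seed(spec$seed)
  u <- matrix(stats::runif(spec$n_cells * length(p0), -1, 1),
              nrow = spec$n_cells, byrow = TRUE)
  draws <- sweep(1 + f * u, 2, p0, `*`)
  colnames(draws) <- names(p0)
  draws[, spec$exempt] <- rep(p0[spec$exempt], each = spec$n_cells)
  draws
}

#' Compute the quiescent and transformed attractor fixtures
#'
#' The non-transformed quiescent fixture (`NT`) is the converged state
#' under basal parameters (negligible Src) from the low-activation
#' bootstrap state. The transformed proliferative fixture (`T`) is the
#' state reached after a transient Src pulse (default 0.2 a.u. for
#' 100-105 h) flips the epigenetic switch. Both are verified by their
#' index pair: NT must classify `NT_quiescent`, T must classify
#' `T_proliferative`; failure is a calibration error.
#'
#' @param base Basal parameter set.
#' @param horizon Convergence horizon per fixture (h).
#' @param src_pulse Src level of the transforming pulse (a.u.).
#' @param window_fraction Index evaluation window.
#' @return List with elements `NT` and `T` (named state vectors) and
#'   `indexes` (the verified CPI/NTSI pairs).
#' @export
make_fixtures <- function(base = default_parameters(), horizon = 1000,
                          src_pulse = 0.2, window_fraction = 0.4) {
  trNT <- integrate_model(base, initial = initial_state(base),
                          t_end = horizon, output_step = 1)
  yNT <- trNT$state[nrow(trNT$state), ]
  sch <- perturbation_schedule(base, list(
    list(t_start = 100, t_end = 105, overrides = c(Src = src_pulse))))
  trT <- integrate_model(sch, initial = yNT, t_end = horizon, output_step = 1)
  yT <- trT$state[nrow(trT$state), ]

  iNT <- c(CPI = cpi_from_trajectory(trNT, window_fraction),
           NTSI = ntsi_from_trajectory(trNT, window_fraction))
  iT <- c(CPI = cpi_from_trajectory(trT, window_fraction),
          NTSI = ntsi_from_trajectory(trT, window_fraction))
  if (classify_cell(iNT[["CPI"]], iNT[["NTSI"]]) != "NT_quiescent")
    stop("calibration error: NT fixture does not classify NT_quiescent ",
         "(CPI = ", signif(iNT[["CPI"]], 4), ", NTSI = ",
         signif(iNT[["NTSI"]], 4), ")", call. = FALSE)
  if (classify_cell(iT[["CPI"]], iT[["NTSI"]]) != "T_proliferative")
    stop("calibration error: T fixture does not classify T_proliferative ",
         "(CPI = ", signif(iT[["CPI"]], 4), ", NTSI = ",
         signif(iT[["NTSI"]], 4), ")", call. = FALSE)
  list(NT = yNT, T = yT, indexes = list(NT = iNT, T = iT))
}

#' Simulate a heterogeneous cell population
#'
#' Integrates every cell independently from the named fixture state under
#' its own jittered parameter set, computes the per-cell index pair
#' (CPI from window maxima, NTSI from window means) and quadrant label,
#' and summarizes switching: a cell has switched when its
#' transformed / non-transformed status (NTSI threshold) differs from the
#' zero-jitter reference cell run under basal parameters.
#'
#' Cells whose integration fails are recorded and excluded; more than 5
#' percent failures is an error.
#'
#' @param spec A `grn_population_spec`.
#' @param horizon Simulation horizon per cell (h).
#' @param window_fraction Final fraction used for indexes and summaries.
#' @param fixtures Optional precomputed [make_fixtures()] result (saves the
#'   two fixture runs).
#' @param output_step Trajectory sampling step (h).
#' @return Object of class `grn_population`: list with `cells` (data.frame:
#'   cell, CPI, NTSI, label, switched, max_Mb, max_Me, max_Md, max_Ma,
#'   mean_Let7, mean_MRas, failed), `summary` (quadrant counts, switch
#'   fraction, n_failed), `reference` (reference-cell indexes and label),
#'   and `spec`.
#' @export
run_population <- function(spec, horizon = 1000, window_fraction = 0.4,
                           fixtures = NULL, output_step = 1) {
  stopifnot(inherits(spec, "grn_population_spec"))
  if (is.null(fixtures)) fixtures <- make_fixtures(spec$base)
  y0 <- fixtures[[spec$start]]
  draws <- draw_population(spec)

  one_cell <- function(p) {
    tr <- integrate_model(stats::setNames(as.numeric(p), names(spec$base)),
                          initial = y0, t_end = horizon,
                          output_step = output_step)
    sel <- tr$time >= (1 - window_fraction) * horizon
    w <- tr$state[sel, , drop = FALSE]
    cpi <- sum(apply(w[, cpi_species(), drop = FALSE], 2, max))
    ntsi <- ntsi_from_levels(colMeans(
      w[, unlist(ntsi_species(), use.names = FALSE), drop = FALSE]))
    c(CPI = cpi, NTSI = ntsi,
      max_Md = max(w[, "Md"]), max_Me = max(w[, "Me"]),
      max_Ma = max(w[, "Ma"]), max_Mb = max(w[, "Mb"]),
      mean_Let7 = mean(w[, "Let7"]), mean_MRas = mean(w[, "MRas"]),
      mean_Ras = mean(w[, "Ras"]), max_Cb = max(w[, "Cb"]),
      max_Ce = max(w[, "Ce"]))
  }

  ref <- one_cell(spec$base)
  ref_label <- classify_cell(ref[["CPI"]], ref[["NTSI"]])
  ref_transformed <- !(ref[["NTSI"]] > 10)

  rows <- vector("list", spec$n_cells)
  failed <- logical(spec$n_cells)
  for (i in seq_len(spec$n_cells)) {
    res <- tryCatch(one_cell(draws[i, ]), error = function(e) NULL)
    if (is.null(res)) {
      failed[i] <- TRUE
      rows[[i]] <- rep(NA_real_, 11)
    } else rows[[i]] <- res
  }
  if (mean(failed) > 0.05)
    stop("more than 5% of cell integrations failed (",
         sum(failed), "/", spec$n_cells, ")", call. = FALSE)
  m <- do.call(rbind, rows)
  colnames(m) <- c("CPI", "NTSI", "max_Md", "max_Me", "max_Ma", "max_Mb",
                   "mean_Let7", "mean_MRas", "mean_Ras", "max_Cb", "max_Ce")
  cells <- data.frame(cell = seq_len(spec$n_cells), m, failed = failed)
  ok <- !failed
  cells$label <- NA_character_
  cells$label[ok] <- classify_cell(cells$CPI[ok], cells$NTSI[ok])
  cells$switched <- NA
  cells$switched[ok] <- (!(cells$NTSI[ok] > 10)) != ref_transformed

  counts <- table(factor(cells$label[ok],
                         levels = c("NT_quiescent", "NT_proliferative",
                                    "T_quiescent", "T_proliferative")))
  summary <- list(quadrant_counts = counts,
                  switch_fraction = mean(cells$switched[ok]),
                  n_failed = sum(failed), n_cells = spec$n_cells)
  structure(list(cells = cells, summary = summary,
                 reference = list(indexes = ref[c("CPI", "NTSI")],
                                  label = ref_label),
                 spec = spec),
            class = "grn_population")
}

#' @export
print.grn_population <- function(x, ...) {
  cat("grn_population:", x$spec$n_cells, "cells, f =",
      x$spec$jitter_fraction, ", start =", x$spec$start, "\n")
  print(x$summary$quadrant_counts)
  cat("switch fraction:", signif(x$summary$switch_fraction, 4),
      "| failed:", x$summary$n_failed, "\n")
  invisible(x)
}

#' Export per-cell (x, y) summaries for scatter plots
#'
#' For cyclin mRNAs (`Md`, `Me`, `Ma`, `Mb`) the window maximum is used;
#' for all other species the window mean (`mean_Let7`, `mean_MRas`,
#' `mean_Ras`), matching the statistics entering CPI and NTSI.
#'
#' @param result A `grn_population`.
#' @param x_species,y_species Species names among the exported summaries
#'   (`Md`, `Me`, `Ma`, `Mb`, `Let7`, `MRas`, `Ras`, `Cb`, `Ce`).
#' @param path Optional CSV output path.
#' @return data.frame with one row per surviving cell: cell, x, y, label.
#' @export
scatter_export <- function(result, x_species, y_species, path = NULL) {
  stopifnot(inherits(result, "grn_population"))
  pick <- function(sp) {
    col <- switch(sp,
                  Md = "max_Md", Me = "max_Me", Ma = "max_Ma", Mb = "max_Mb",
                  Cb = "max_Cb", Ce = "max_Ce",
                  Let7 = "mean_Let7", MRas = "mean_MRas", Ras = "mean_Ras",
                  stop("no exported summary for species ", sp, call. = FALSE))
    result$cells[[col]]
  }
  ok <- !result$cells$failed
  df <- data.frame(cell = result$cells$cell[ok],
                   x = pick(x_species)[ok], y = pick(y_species)[ok],
                   label = result$cells$label[ok])
  names(df)[2:3] <- c(x_species, y_species)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  df
}
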