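#' Specification of a synthetic tumor / non-tumor expression cohort
#'
#' The generator emulates the statistical structure of bulk tumor cohorts:
#' non-tumor samples are heterogeneous cells around the non-transformed
#' quiescent attractor, tumor samples are a mixture of transformed
#' proliferative cells and (a configurable fraction of) "non-activated"
#' tumors that resemble normals; per-gene measurement noise is
#' multiplicative lognormal (expression values are positive and
#' right-skewed).
#'
#' @param n_non_tumor,n_tumor Sample counts (>= 1 each).
#' @param mixing Fraction of tumor samples drawn from the non-transformed
#'   attractor ("non-activated tumors"), in `[0, 1]`.
#' @param noise_cv Coefficient of variation of the lognormal measurement
#'   noise (>= 0).
#' @param jitter_fraction Uniform parameter jitter of the underlying cells.
#' @param seed Integer seed.
#' @return Object of class `grn_cohort_spec`.
#' @export
cohort_spec <- function(n_non_tumor = 9, n_tumor = 36, mixing = 0.2,
                        noise_cv = 0.2, jitter_fraction = 0.5, seed = 1) {
  if (n_non_tumor < 1 || n_tumor < 1) stop("counts must be >= 1", call. = FALSE)
  if (mixing < 0 || mixing > 1) stop("mixing must be in [0, 1]", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (jitter_fraction < 0 || jitter_fraction >= 1)
    stop("jitter_fraction must be in [0, 1)", call. = FALSE)
  structure(list(n_non_tumor = as.integer(n_non_tumor),
                 n_tumor = as.integer(n_tumor), mixing = mixing,
                 noise_cv = noise_cv, jitter_fraction = jitter_fraction,
                 seed = as.integer(seed)),
            class = "grn_cohort_spec")
}

#' Generate a synthetic expression cohort from the population model
#'
#' Each sample is one simulated cell: its per-species summaries (window
#' maxima for the cyclin mRNAs, window means otherwise - the statistics
#' entering CPI and NTSI) are mapped to gene symbols through `gene_map`
#' and multiplied by lognormal noise with coefficient of variation
#' `spec$noise_cv`. Non-tumor samples start from the NT fixture; tumor
#' samples start from the T fixture except for a `spec$mixing` fraction
#' started from the NT fixture (non-activated tumors). Deterministic given
#' `spec$seed`.
#'
#' @param spec A `grn_cohort_spec`.
#' @param base Basal parameters.
#' @param gene_map Gene-to-species table (default [default_gene_map()]).
#' @param horizon,window_fraction Per-cell simulation settings.
#' @param fixtures Optional precomputed [make_fixtures()] result.
#' @return A `grn_cohort` (see [cohort_matrix()]); attribute
#'   `true_attractor` records each sample's generating attractor.
#' @export
generate_cohort <- function(spec, base = default_parameters(),
                            gene_map = default_gene_map(), horizon = 1000,
                            window_fraction = 0.4, fixtures = NULL) {
  stopifnot(inherits(spec, "grn_cohort_spec"))
  if (is.null(fixtures)) fixtures <- make_fixtures(base)
  n <- spec$n_non_tumor + spec$n_tumor
  set.seed(spec$seed)
  n_mixed <- round(spec$mixing * spec$n_tumor)
  ## tumor samples starting from the NT attractor ("non-activated")
  mixed_idx <- if (n_mixed > 0) sample(seq_len(spec$n_tumor), n_mixed) else integer(0)
  start <- c(rep("NT", spec$n_non_tumor),
             ifelse(seq_len(spec$n_tumor) %in% mixed_idx, "NT", "T"))
  u <- matrix(stats::runif(n * length(base), -1, 1), nrow = n, byrow = TRUE)
  draws <- sweep(1 + spec$jitter_fraction * u, 2, base, `*`)
  colnames(draws) <- names(base)
  draws[, c("GF", "Src")] <- rep(base[c("GF", "Src")], each = n)
  noise <- matrix(stats::rlnorm(nrow(gene_map) * n,
                                meanlog = -0.5 * log(1 + spec$noise_cv^2),
                                sdlog = sqrt(log(1 + spec$noise_cv^2))),
                  nrow = nrow(gene_map))

  maxed <- cpi_species()
  expr <- matrix(NA_real_, nrow(gene_map), n,
                 dimnames = list(gene_map$gene,
                                 sprintf("S%03d", seq_len(n))))
  for (i in seq_len(n)) {
    tr <- integrate_model(stats::setNames(draws[i, ], names(base)),
                          initial = fixtures[[start[i]]], t_end = horizon,
                          output_step = 1)
    sel <- tr$time >= (1 - window_fraction) * horizon
    w <- tr$state[sel, , drop = FALSE]
    vals <- vapply(gene_map$species, function(sp) {
      if (sp %in% maxed) max(w[, sp]) else mean(w[, sp])
    }, 1)
    expr[, i] <- vals * noise[, i]
  }
  groups <- c(rep("non_tumor", spec$n_non_tumor), rep("tumor", spec$n_tumor))
  ch <- cohort_matrix(expr, stats::setNames(groups, colnames(expr)), gene_map)
  attr(ch, "true_attractor") <- stats::setNames(start, colnames(expr))
  attr(ch, "spec") <- spec
  ch
}

#' Principal-component projection of cohort samples
#'
#' Standard PCA (via [stats::prcomp()]) on the standardized expression of
#' the network-component genes; plumbing used to check that synthetic
#' tumor / normal groups separate when `mixing = 0` and overlap partially
#' when `mixing > 0`. Constant genes are dropped with a warning.
#'
#' @param cohort A `grn_cohort`.
#' @param n_components Number of components returned.
#' @param log_transform Use `log1p` expression (default TRUE).
#' @return data.frame: sample, group, PC1..PCk.
#' @export
pca_projection <- function(cohort, n_components = 2, log_transform = TRUE) {
  stopifnot(inherits(cohort, "grn_cohort"))
  if (ncol(cohort$expr) < 3) stop("need at least 3 samples", call. = FALSE)
  m <- t(cohort$expr[cohort$gene_map$gene, , drop = FALSE])
  if (log_transform) m <- log1p(m)
  keep <- apply(m, 2, stats::sd) > 0
  if (!all(keep)) {
    warning("dropping constant gene(s): ",
            paste(colnames(m)[!keep], collapse = ", "))
    m <- m[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(pc$x))
  out <- data.frame(sample = rownames(m), group = unname(cohort$groups),
                    pc$x[, seq_len(k), drop = FALSE])
  rownames(out) <- NULL
  out
}
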