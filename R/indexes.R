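#' Species entering the proliferation / transformation indexes
#'
#' `cpi_species()` are the four free cyclin mRNAs summed (as window maxima)
#' into the cell proliferation index (CPI). `ntsi_species()` are the eight
#' transformation-network species of the non-transformed state index
#' (NTSI): the two inhibitors (numerator) and six activators (denominator).
#'
#' @return Character vectors of canonical species names.
#' @export
cpi_species <- function() c("Md", "Me", "Ma", "Mb")

#' @rdname cpi_species
#' @export
ntsi_species <- function() {
  list(inhibitors = c("PTEN", "Let7"),
       activators = c("IL6", "NFKB", "STAT3", "miR21", "Lin28", "Ras"))
}

#' Cell proliferation index (CPI) from a trajectory
#'
#' CPI = max(Md) + max(Me) + max(Ma) + max(Mb), maxima of the free cyclin
#' mRNAs over the final analysis window. Cells with CPI above 1 are
#' considered proliferating.
#'
#' @param traj A `grn_trajectory`.
#' @param window_fraction Final fraction of the horizon used (default 0.4).
#' @return CPI (a.u., scalar).
#' @export
cpi_from_trajectory <- function(traj, window_fraction = 0.4) {
  stopifnot(inherits(traj, "grn_trajectory"))
  sel <- traj$time >= (1 - window_fraction) * max(traj$time)
  if (sum(sel) < 3L) stop("analysis window too short", call. = FALSE)
  sum(apply(traj$state[sel, cpi_species(), drop = FALSE], 2, max))
}

#' Non-transformed state index (NTSI) from species levels
#'
#' NTSI = (PTEN + Let7) / (IL6 + NFKB + STAT3 + miR21 + Lin28 + Ras).
#' High values indicate a non-transformed state (threshold 10 in the
#' population analysis).
#'
#' @param levels Named numeric vector containing the 8 NTSI species.
#' @param eps Pseudocount guarding a zero denominator (with a warning).
#' @return NTSI (unitless, >= 0).
#' @export
#' @examples
#' ntsi_from_levels(c(PTEN = 1, Let7 = 9, IL6 = 1/6, NFKB = 1/6,
#'   STAT3 = 1/6, miR21 = 1/6, Lin28 = 1/6, Ras = 1/6))
ntsi_from_levels <- function(levels, eps = 1e-9) {
  sp <- ntsi_species()
  need <- c(sp$inhibitors, sp$activators)
  if (!all(need %in% names(levels)))
    stop("missing NTSI species: ",
         paste(setdiff(need, names(levels)), collapse = ", "), call. = FALSE)
  if (any(levels[need] < 0) || !all(is.finite(levels[need])))
    stop("NTSI species levels must be finite and >= 0", call. = FALSE)
  num <- sum(levels[sp$inhibitors])
  den <- sum(levels[sp$activators])
  if (den <= 0) {
    warning("zero NTSI denominator; using pseudocount eps = ", eps)
    den <- eps
  }
  num / den
}

#' NTSI from a trajectory
#'
#' Species levels are taken as means over the final analysis window
#' (maxima are reserved for CPI).
#'
#' @inheritParams cpi_from_trajectory
#' @param eps Passed to [ntsi_from_levels()].
#' @return NTSI (unitless).
#' @export
ntsi_from_trajectory <- function(traj, window_fraction = 0.4, eps = 1e-9) {
  stopifnot(inherits(traj, "grn_trajectory"))
  sel <- traj$time >= (1 - window_fraction) * max(traj$time)
  if (sum(sel) < 3L) stop("analysis window too short", call. = FALSE)
  sp <- unlist(ntsi_species(), use.names = FALSE)
  ntsi_from_levels(colMeans(traj$state[sel, sp, drop = FALSE]), eps = eps)
}

#' Classify a cell from its (CPI, NTSI) pair
#'
#' The four quadrants: proliferative iff CPI strictly exceeds
#' `cpi_threshold`; non-transformed iff NTSI strictly exceeds
#' `ntsi_threshold`. Strict inequalities implement the "above which"
#' reading of both thresholds, so the boundary pair (CPI = 1, NTSI = 10)
#' is neither proliferative nor non-transformed (label `T_quiescent`).
#'
#' @param cpi,ntsi Index values (scalars or equal-length vectors).
#' @param cpi_threshold,ntsi_threshold Positive thresholds (defaults 1, 10).
#' @return Character label(s) in `NT_quiescent`, `NT_proliferative`,
#'   `T_quiescent`, `T_proliferative`.
#' @export
#' @examples
#' classify_cell(0.5, 20)  # NT_quiescent
#' classify_cell(3, 0.1)   # T_proliferative
classify_cell <- function(cpi, ntsi, cpi_threshold = 1, ntsi_threshold = 10) {
  if (cpi_threshold <= 0 || ntsi_threshold <= 0)
    stop("thresholds must be > 0", call. = FALSE)
  proliferative <- cpi > cpi_threshold
  transformed <- !(ntsi > ntsi_threshold)
  paste0(ifelse(transformed, "T_", "NT_"),
         ifelse(proliferative, "proliferative", "quiescent"))
}

#' Default gene-name mapping table
#'
#' Maps expression-matrix gene symbols to model species for the index
#' computation; editable and replaceable, since public expression matrices
#' use gene symbols that differ from the model names. The packaged copy lives at
#' `system.file("extdata", "gene_map.tsv", package = "let7cycle")`.
#'
#' @return data.frame with columns `gene` and `species`.
#' @export
default_gene_map <- function() {
  data.frame(
    gene = c("CCND1", "CCNE1", "CCNA2", "CCNB1", "MIRLET7C", "PTEN",
             "IL6", "NFKB1", "STAT3", "MIR21", "LIN28A", "KRAS"),
    species = c("Md", "Me", "Ma", "Mb", "Let7", "PTEN",
                "IL6", "NFKB", "STAT3", "miR21", "Lin28", "Ras"),
    stringsAsFactors = FALSE)
}

#' Read a gene-name mapping table
#' @param path TSV with columns `gene`, `species`.
#' @return data.frame as in [default_gene_map()].
#' @export
read_gene_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("gene", "species") %in% names(df)))
    stop("gene map needs columns gene, species", call. = FALSE)
  bad <- setdiff(df$species, species_names())
  if (length(bad)) stop("unknown species in gene map: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  df[, c("gene", "species")]
}

#' Construct a tumor / non-tumor expression cohort
#'
#' @param expr Non-negative numeric matrix, genes (rows, named) x samples
#'   (columns, named).
#' @param groups Character vector (`non_tumor` / `tumor`), one per sample
#'   (named or in column order).
#' @param gene_map Gene-to-species mapping (default [default_gene_map()]).
#' @return Object of class `grn_cohort`.
#' @export
cohort_matrix <- function(expr, groups, gene_map = default_gene_map()) {
  if (!is.matrix(expr) || is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expr must be a matrix with gene row names and sample column names",
         call. = FALSE)
  if (length(groups) != ncol(expr))
    stop("one group label per sample required", call. = FALSE)
  if (!is.null(names(groups))) groups <- groups[colnames(expr)]
  groups <- as.character(groups)
  if (!all(groups %in% c("non_tumor", "tumor")))
    stop("groups must be 'non_tumor' or 'tumor'", call. = FALSE)
  need <- gene_map$gene
  missing <- setdiff(need, rownames(expr))
  if (length(missing))
    stop("required gene(s) missing from cohort: ",
         paste(missing, collapse = ", "), call. = FALSE)
  sub <- expr[need, , drop = FALSE]
  if (anyNA(sub) || any(!is.finite(sub)) || any(sub < 0))
    stop("required genes contain missing / negative values", call. = FALSE)
  structure(list(expr = expr, groups = stats::setNames(groups, colnames(expr)),
                 gene_map = gene_map),
            class = "grn_cohort")
}

#' @export
print.grn_cohort <- function(x, ...) {
  cat("grn_cohort:", nrow(x$expr), "genes x", ncol(x$expr), "samples (",
      sum(x$groups == "non_tumor"), "non-tumor /", sum(x$groups == "tumor"),
      "tumor )\n")
  invisible(x)
}

#' CPI and NTSI for every sample of an expression cohort
#'
#' Maps genes to model species through the cohort's gene map, optionally
#' normalizes each gene to its non-tumor group mean, computes per-sample
#' CPI (sum of the four cyclin mRNA levels) and NTSI, then summarizes per
#' group. Group location differences are tested with a rank-based
#' two-sample (Wilcoxon) test.
#'
#' @param cohort A `grn_cohort`.
#' @param normalize Divide each gene by its non-tumor group mean first
#'   (mimics expression "relative to the non-tumor condition").
#' @param eps Pseudocount for zero NTSI denominators.
#' @return List with `per_sample` (data.frame: sample, group, CPI, NTSI,
#'   label) and `summary` (data.frame per group with mean CPI / NTSI,
#'   ratios to non-tumor, and Wilcoxon p-values as attributes `p_cpi`,
#'   `p_ntsi` when both groups are present).
#' @export
indexes_from_cohort <- function(cohort, normalize = FALSE, eps = 1e-9) {
  stopifnot(inherits(cohort, "grn_cohort"))
  gm <- cohort$gene_map
  expr <- cohort$expr[gm$gene, , drop = FALSE]
  rownames(expr) <- gm$species
  if (normalize) {
    nt <- cohort$groups == "non_tumor"
    if (!any(nt)) stop("normalize requires a non_tumor group", call. = FALSE)
    ref <- rowMeans(expr[, nt, drop = FALSE])
    ref[ref == 0] <- 1   # constant-zero gene: leave as is
    expr <- expr / ref
  }
  cpi <- colSums(expr[cpi_species(), , drop = FALSE])
  ntsi <- apply(expr, 2, function(v) ntsi_from_levels(v, eps = eps))
  per_sample <- data.frame(sample = colnames(expr),
                           group = unname(cohort$groups),
                           CPI = unname(cpi), NTSI = unname(ntsi),
                           label = classify_cell(unname(cpi), unname(ntsi)),
                           stringsAsFactors = FALSE)
  agg <- stats::aggregate(cbind(CPI, NTSI) ~ group, per_sample, mean)
  if ("non_tumor" %in% agg$group) {
    ref <- agg[agg$group == "non_tumor", ]
    agg$CPI_rel_non_tumor <- agg$CPI / ref$CPI
    agg$NTSI_rel_non_tumor <- agg$NTSI / ref$NTSI
  }
  if (length(unique(per_sample$group)) == 2) {
    attr(agg, "p_cpi") <- stats::wilcox.test(CPI ~ group, per_sample,
                                             exact = FALSE)$p.value
    attr(agg, "p_ntsi") <- stats::wilcox.test(NTSI ~ group, per_sample,
                                              exact = FALSE)$p.value
  }
  list(per_sample = per_sample, summary = agg)
}

#' Read / write a cohort (expression TSV + sample annotation TSV)
#'
#' The expression file is a TSV with genes as rows (first column `gene`)
#' and samples as columns; the annotation file has columns `sample_id` and
#' `group` (`non_tumor` / `tumor`). Lines starting with `#` are ignored.
#'
#' @param expr_path,groups_path File paths.
#' @param gene_map Mapping table (default [default_gene_map()]).
#' @return A `grn_cohort`.
#' @export
read_cohort <- function(expr_path, groups_path,
                        gene_map = default_gene_map()) {
  ex <- utils::read.delim(expr_path, check.names = FALSE, comment.char = "#")
  if (names(ex)[1] != "gene") stop("expression TSV must start with a 'gene' column",
                                   call. = FALSE)
  m <- as.matrix(ex[, -1, drop = FALSE])
  rownames(m) <- ex$gene
  an <- utils::read.delim(groups_path, check.names = FALSE, comment.char = "#")
  if (!all(c("sample_id", "group") %in% names(an)))
    stop("annotation TSV needs sample_id, group columns", call. = FALSE)
  g <- stats::setNames(an$group, an$sample_id)
  if (!setequal(names(g), colnames(m)))
    stop("annotation samples do not match expression columns", call. = FALSE)
  cohort_matrix(m, g[colnames(m)], gene_map)
}

#' @rdname read_cohort
#' @param cohort A `grn_cohort` to write.
#' @param comment Optional comment line(s) prefixed with `#`.
#' @export
write_cohort <- function(cohort, expr_path, groups_path, comment = NULL) {
  stopifnot(inherits(cohort, "grn_cohort"))
  con <- file(expr_path, "w"); on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  df <- data.frame(gene = rownames(cohort$expr), cohort$expr,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  con2 <- file(groups_path, "w"); on.exit(close(con2), add = TRUE)
  if (!is.null(comment)) writeLines(paste0("# ", comment), con2)
  utils::write.table(data.frame(sample_id = names(cohort$groups),
                                group = unname(cohort$groups)),
                     con2, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(expr_path)
}
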