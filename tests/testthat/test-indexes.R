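make_traj <- function(values, n = 11) {
  ## constant trajectory with chosen species levels
  y <- stats::setNames(numeric(29), species_names())
  y[names(values)] <- values
  st <- matrix(rep(y, each = n), nrow = n,
               dimnames = list(NULL, species_names()))
  structure(list(time = seq(0, 100, length.out = n), state = st,
                 schedule = NULL), class = "grn_trajectory")
}

test_that("CPI is the exact sum of window maxima of the cyclin mRNAs", {
  tr <- make_traj(c(Md = 0.5, Me = 1.0, Ma = 0.8, Mb = 0.7))
  expect_identical(cpi_from_trajectory(tr), 3.0)
  expect_identical(cpi_from_trajectory(make_traj(c())), 0)
  ## maxima, not endpoints: put a transient peak inside the window
  tr2 <- make_traj(c(Md = 0.5, Me = 1.0, Ma = 0.8, Mb = 0.7))
  tr2$state[10, "Me"] <- 2.0
  expect_identical(cpi_from_trajectory(tr2, window_fraction = 1), 4.0)
})

test_that("NTSI is the exact inhibitor/activator ratio", {
  lv <- c(PTEN = 1, Let7 = 9, IL6 = 1/6, NFKB = 1/6, STAT3 = 1/6,
          miR21 = 1/6, Lin28 = 1/6, Ras = 1/6)
  expect_equal(ntsi_from_levels(lv), 10.0)
  lv0 <- lv; lv0[c("PTEN", "Let7")] <- 0
  expect_equal(ntsi_from_levels(lv0), 0)
  lvz <- lv; lvz[3:8] <- 0
  expect_warning(v <- ntsi_from_levels(lvz), "pseudocount")
  expect_gt(v, 1e9)
})

test_that("classify_cell reproduces the four quadrants with strict thresholds", {
  expect_identical(classify_cell(0.5, 20), "NT_quiescent")
  expect_identical(classify_cell(3, 20), "NT_proliferative")
  expect_identical(classify_cell(0.5, 0.1), "T_quiescent")
  expect_identical(classify_cell(3, 0.1), "T_proliferative")
  ## boundary: strict inequalities, so (1, 10) is transformed-quiescent?
  ## no: NTSI must strictly exceed 10 to be non-transformed, CPI strictly
  ## exceed 1 to proliferate => (1, 10) is quiescent and transformed is
  ## decided by NTSI > 10 being FALSE -> transformed... the tie-break rule
  ## adopted is "above which": strictly greater means non-transformed.
  expect_identical(classify_cell(1, 10), "T_quiescent")
  expect_identical(classify_cell(1 + 1e-9, 10 + 1e-9), "NT_proliferative")
  expect_error(classify_cell(1, 1, cpi_threshold = 0), "thresholds")
  ## vectorized
  expect_identical(classify_cell(c(0.5, 3), c(20, 0.1)),
                   c("NT_quiescent", "T_proliferative"))
})

test_that("CPI scales linearly and NTSI is scale-invariant", {
  set.seed(1)
  lv <- stats::setNames(stats::runif(8, 0.1, 2),
                        unlist(ntsi_species(), use.names = FALSE))
  expect_equal(ntsi_from_levels(3 * lv), ntsi_from_levels(lv))
  tr <- make_traj(c(Md = 0.4, Me = 0.3, Ma = 0.2, Mb = 0.1))
  tr3 <- tr; tr3$state <- tr$state * 3
  expect_equal(cpi_from_trajectory(tr3), 3 * cpi_from_trajectory(tr))
})

test_that("NTSI is monotone in its components", {
  base <- stats::setNames(rep(0.5, 8), unlist(ntsi_species(), use.names = FALSE))
  v0 <- ntsi_from_levels(base)
  for (sp in ntsi_species()$inhibitors) {
    up <- base; up[sp] <- 1
    expect_gt(ntsi_from_levels(up), v0)
  }
  for (sp in ntsi_species()$activators) {
    up <- base; up[sp] <- 1
    expect_lt(ntsi_from_levels(up), v0)
  }
})

cohort_from_levels <- function(nt, t, n_nt = 3, n_t = 3) {
  gm <- default_gene_map()
  m <- cbind(matrix(rep(nt, n_nt), ncol = n_nt),
             matrix(rep(t, n_t), ncol = n_t))
  rownames(m) <- gm$gene
  colnames(m) <- paste0("s", seq_len(n_nt + n_t))
  cohort_matrix(m, c(rep("non_tumor", n_nt), rep("tumor", n_t)), gm)
}

test_that("cohort CPI is linear: doubling cyclins doubles tumor CPI", {
  gm <- default_gene_map()
  nt <- stats::setNames(rep(1, nrow(gm)), gm$gene)
  t <- nt
  t[c("CCND1", "CCNE1", "CCNA2", "CCNB1")] <- 2
  ch <- cohort_from_levels(nt, t)
  res <- indexes_from_cohort(ch)
  cpi <- res$summary$CPI
  names(cpi) <- res$summary$group
  expect_equal(unname(cpi["tumor"] / cpi["non_tumor"]), 2)
})

test_that("single-group cohort with normalization gives per-sample CPI 4", {
  gm <- default_gene_map()
  set.seed(2)
  m <- matrix(stats::runif(nrow(gm) * 4, 0.5, 3), nrow = nrow(gm),
              dimnames = list(gm$gene, paste0("s", 1:4)))
  m[, ] <- m[, 1]   # identical samples -> each equals the group mean
  ch <- cohort_matrix(m, rep("non_tumor", 4), gm)
  res <- indexes_from_cohort(ch, normalize = TRUE)
  expect_equal(res$per_sample$CPI, rep(4, 4))
})

test_that("cohort schema errors name the missing gene", {
  gm <- default_gene_map()
  m <- matrix(1, nrow = nrow(gm) - 1, ncol = 2,
              dimnames = list(gm$gene[-3], c("a", "b")))
  expect_error(cohort_matrix(m, c("non_tumor", "tumor")), gm$gene[3])
})

test_that("cohorts round-trip through TSV files", {
  gm <- default_gene_map()
  set.seed(4)
  m <- matrix(stats::runif(nrow(gm) * 5, 0, 2), nrow = nrow(gm),
              dimnames = list(gm$gene, paste0("s", 1:5)))
  ch <- cohort_matrix(m, c(rep("non_tumor", 2), rep("tumor", 3)), gm)
  fe <- tempfile(fileext = ".tsv"); fg <- tempfile(fileext = ".tsv")
  write_cohort(ch, fe, fg, comment = "synthetic")
  ch2 <- read_cohort(fe, fg)
  expect_equal(ch2$expr, ch$expr, tolerance = 1e-8)
  expect_identical(unname(ch2$groups), unname(ch$groups))
})

test_that("the packaged gene map file matches the built-in default", {
  f <- system.file("extdata", "gene_map.tsv", package = "let7cycle")
  expect_true(nzchar(f))
  expect_identical(read_gene_map(f), default_gene_map())
})
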