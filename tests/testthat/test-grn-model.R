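test_that("absorbing origin: zero state with zero synthesis gives zero derivative", {
  p <- default_parameters()
  p[grep("^V_S", names(p))] <- 0      # all synthesis rates
  p[c("GF", "Src")] <- 0
  d <- grn_rhs(stats::setNames(numeric(29), species_names()), 0, p)
  expect_true(all(d == 0))
})

test_that("empty state with cyclin D drive: only synthesis terms act", {
  p <- apply_overrides(default_parameters(), c(GF = 1))
  d <- grn_rhs(stats::setNames(numeric(29), species_names()), 0, p)
  expect_gt(d[["Md"]], 0)
  expect_true(all(d[c("CLd", "CLe", "CLa", "CLb", "CL_IL6", "CL_Ras")] == 0))
})

test_that("rhs agrees with the independent flux-bookkeeping oracle", {
  p <- default_parameters()
  states <- c(list(fixtures_cache()$NT, fixtures_cache()$T),
              { set.seed(7); lapply(1:10, function(i) random_state()) })
  for (y in states) {
    d1 <- grn_rhs(y, 0, p)
    d2 <- flux_oracle_rhs(y, p)
    expect_lt(max(abs(d1 - d2) / pmax(abs(d2), 1e-8)), 1e-6)
  }
})

test_that("compiled and reference right-hand sides agree", {
  p <- default_parameters()
  set.seed(3)
  for (i in 1:10) {
    y <- random_state()
    dR <- unname(grn_rhs(y, 0, p))
    dC <- deSolve::DLLfunc(y = unname(y), dllname = "let7cycle",
                           func = "grn_derivs", initfunc = "grn_initmod",
                           parms = unname(p), times = 0)$dy
    expect_equal(dR, dC, tolerance = 1e-12)
  }
})

test_that("non-finite state is rejected naming the component", {
  y <- fixtures_cache()$NT
  y["IL6"] <- NaN
  expect_error(grn_rhs(y), "IL6")
})

test_that("forward invariance: boundary components never get negative derivatives", {
  set.seed(42)
  p <- default_parameters()
  for (i in 1:50) {
    y <- random_state()
    zero_idx <- sample(29, sample(1:5, 1))
    y[zero_idx] <- 0
    d <- grn_rhs(y, 0, p)
    expect_true(all(d[zero_idx] >= 0),
                info = paste("boundary:", paste(species_names()[zero_idx],
                                                collapse = ",")))
  }
})

test_that("sponge stoichiometry: binding fluxes cancel between Let7 and complexes", {
  ## with complex decay and all plain decays switched off, d(Let7) + sum
  ## d(CL_i) must vanish identically (binding/unbinding fluxes only)
  p <- default_parameters()
  p[grep("^kdCL_", names(p))] <- 0
  p[c("V_SLET7", "kd_LET7", "kdL7_LIN28")] <- 0
  set.seed(5)
  for (i in 1:20) {
    y <- random_state()
    d <- grn_rhs(y, 0, p)
    expect_lt(abs(d[["Let7"]] +
                    sum(d[c("CLd", "CLe", "CLa", "CLb", "CL_IL6", "CL_Ras")])),
              1e-10)
  }
})

test_that("monotone repression: raising Let7 never increases any cyclin/Cdk derivative", {
  set.seed(8)
  for (i in 1:20) {
    y <- random_state()
    y2 <- y
    y2["Let7"] <- y[["Let7"]] * 2 + 1
    d1 <- grn_rhs(y)
    d2 <- grn_rhs(y2)
    expect_true(all(d2[c("Cd", "Ce", "Ca", "Cb")] <=
                      d1[c("Cd", "Ce", "Ca", "Cb")] + 1e-12))
  }
})

test_that("decoupling limit: without sponging of cyclin mRNAs the blocks separate", {
  p <- apply_overrides(default_parameters(),
                       c(kA_MD = 0, kA_ME = 0, kA_MA = 0, kA_MB = 0,
                         kD_MD = 0, kD_ME = 0, kD_MA = 0, kD_MB = 0,
                         k_GFRAS = 0))
  trans <- c("Let7", "NFKB", "MLin28", "Lin28", "MIL6", "CL_IL6", "IL6",
             "STAT3", "miR21", "MPTEN", "PTEN", "MRas", "CL_Ras", "Ras")
  cyc <- setdiff(species_names(), trans)
  set.seed(9)
  for (i in 1:10) {
    y <- random_state()
    y2 <- y
    y2[cyc] <- stats::runif(length(cyc), 0, 3)   # perturb cell-cycle block only
    d1 <- grn_rhs(y, 0, p)
    d2 <- grn_rhs(y2, 0, p)
    expect_equal(d1[trans], d2[trans], tolerance = 1e-12)
    ## and the converse: cell-cycle derivatives depend on the transformation
    ## block only through Let7
    y3 <- y
    y3[setdiff(trans, "Let7")] <- stats::runif(length(trans) - 1, 0, 3)
    d3 <- grn_rhs(y3, 0, p)
    expect_equal(d1[cyc], d3[cyc], tolerance = 1e-12)
  }
})

test_that("apply_overrides handles protocol overrides, identity and bad names", {
  p <- default_parameters()
  p2 <- apply_overrides(p, c(V_SLET7 = 0.5))
  expect_equal(p2[["V_SLET7"]], 0.5)
  expect_equal(p2[names(p2) != "V_SLET7"], p[names(p) != "V_SLET7"])
  expect_identical(apply_overrides(p, c()), p)
  p3 <- apply_overrides(p, c(k_AA1NFKB = 0, k_AA2NFKB = 0, k_AA3NFKB = 0))
  expect_true(all(p3[c("k_AA1NFKB", "k_AA2NFKB", "k_AA3NFKB")] == 0))
  expect_error(apply_overrides(p, c(NOT_A_PARAM = 1)), "NOT_A_PARAM")
})

test_that("parameter config files round-trip losslessly and reject bad input", {
  p <- apply_overrides(default_parameters(), c(V_SLET7 = pi, GF = exp(1)))
  f <- tempfile(fileext = ".cfg")
  write_parameters(p, f)
  expect_identical(read_parameters(f), p)
  writeLines(c("V_SLET7 = 2", "BOGUS = 1"), f)
  expect_error(read_parameters(f), "BOGUS")
  writeLines("V_SLET7 = notanumber", f)
  expect_error(read_parameters(f), "non-numeric")
  writeLines(character(0), f)
  expect_identical(read_parameters(f), default_parameters())
})

test_that("network topology matches the implemented interactions", {
  topo <- network_topology()
  expect_false(anyDuplicated(topo[, c("source", "target")]) > 0)
  ## Let-7 sponges exactly the six target mRNAs
  sponge <- topo[topo$source == "Let7", "target"]
  expect_setequal(sponge, c("Md", "Me", "Ma", "Mb", "MIL6", "MRas"))
  ## the three NF-kB activating branches
  act_n <- topo[topo$target == "NFKB" & topo$sign == "+", "source"]
  expect_setequal(act_n, c("Src", "STAT3", "Ras"))
  expect_true(all(topo$mechanism %in%
    c("transcription", "translation-block-by-complexation", "translation",
      "activation", "inactivation", "degradation-promotion")))
})

test_that("state vectors round-trip through CSV", {
  y <- fixtures_cache()$T
  f <- tempfile(fileext = ".csv")
  write_state(y, f)
  expect_equal(read_state(f), y, tolerance = 1e-12)
})
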