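test_that("pure decay: zero-synthesis parameters drive all species to zero", {
  p <- default_parameters()
  p[grep("^V_S", names(p))] <- 0
  p[c("GF", "Src")] <- 0
  y0 <- fixtures_cache()$T
  tr <- integrate_model(p, initial = y0, t_end = 300, output_step = 1)
  final <- tr$state[nrow(tr$state), ]
  expect_true(all(final < 1e-3))
  ## monotone decay of the total material
  tot <- rowSums(tr$state)
  expect_true(all(diff(tot) <= 1e-8))
})

test_that("integration is deterministic (bitwise identical repeats)", {
  sch <- perturbation_schedule(default_parameters(), list(
    list(t_start = 50, t_end = 55, overrides = c(Src = 0.5))))
  tr1 <- integrate_model(sch, initial = fixtures_cache()$NT, t_end = 150,
                         output_step = 1)
  tr2 <- integrate_model(sch, initial = fixtures_cache()$NT, t_end = 150,
                         output_step = 1)
  expect_identical(tr1$state, tr2$state)
})

test_that("events give sharp parameter steps at the boundary", {
  ## a step in V_SLET7 to zero: Let7 synthesis stops exactly at t = 10
  sch <- perturbation_schedule(default_parameters(), list(
    list(t_start = 10, t_end = Inf, overrides = c(V_SLET7 = 0))))
  tr <- integrate_model(sch, initial = fixtures_cache()$NT, t_end = 30,
                        output_step = 0.5)
  l7 <- tr$state[, "Let7"]
  before <- l7[tr$time <= 10]
  expect_lt(max(abs(diff(before))), 0.5)        # quasi-steady before
  expect_lt(l7[tr$time == 15], l7[tr$time == 10] * 0.8)  # decaying after
})

test_that("adaptive integration matches an independent fixed-step RK4 oracle", {
  p <- default_parameters()
  y0 <- fixtures_cache()$T   # oscillating state: a non-trivial comparison
  tr <- integrate_model(p, initial = y0, t_end = 10, output_step = 10,
                        rtol = 1e-10, atol = 1e-12)
  y_adaptive <- tr$state[nrow(tr$state), ]
  y_rk4 <- rk4_integrate(y0, p, t_end = 10, dt = 1e-3)
  rel <- abs(y_adaptive - y_rk4) / pmax(abs(y_rk4), 1e-8)
  expect_lt(max(rel), 1e-4)
})

test_that("halving solver tolerances leaves reported values essentially unchanged", {
  y0 <- fixtures_cache()$T
  tr1 <- integrate_model(default_parameters(), initial = y0, t_end = 200,
                         output_step = 1, rtol = 1e-8, atol = 1e-10)
  tr2 <- integrate_model(default_parameters(), initial = y0, t_end = 200,
                         output_step = 1, rtol = 5e-9, atol = 5e-11)
  c1 <- cpi_from_trajectory(tr1); c2 <- cpi_from_trajectory(tr2)
  expect_lt(abs(c1 - c2) / c1, 1e-3)
})

test_that("schedules validate events and overlaps", {
  p <- default_parameters()
  expect_error(perturbation_schedule(p, list(list(t_start = -1, t_end = 2,
                                                  overrides = c(GF = 1)))),
               "t_start")
  expect_error(perturbation_schedule(p, list(
    list(t_start = 0, t_end = 10, overrides = c(GF = 1)),
    list(t_start = 5, t_end = 15, overrides = c(GF = 2)))), "overlapping")
  ## non-overlapping and different-parameter events are fine
  sch <- perturbation_schedule(p, list(
    list(t_start = 0, t_end = 10, overrides = c(GF = 1)),
    list(t_start = 5, t_end = 15, overrides = c(Src = 1))))
  expect_s3_class(sch, "grn_schedule")
  expect_equal(schedule_parameters_at(sch, 7)[["Src"]], 1)
  expect_equal(schedule_parameters_at(sch, 12)[["GF"]],
               p[["GF"]])
})

test_that("constant trajectory classifies steady with zero amplitudes", {
  st <- matrix(rep(fixtures_cache()$NT, each = 101), nrow = 101,
               dimnames = list(NULL, species_names()))
  tr <- structure(list(time = 0:100, state = st, schedule = NULL),
                  class = "grn_trajectory")
  r <- classify_regime(tr)
  expect_equal(r$label, "steady")
  expect_true(all(r$amplitude == 0))
  expect_false(is.null(r$steady_state))
})

test_that("synthetic sine in Ce and Cb recovers the injected period", {
  tm <- seq(0, 600, by = 0.5)
  st <- matrix(0.001, nrow = length(tm), ncol = 29,
               dimnames = list(NULL, species_names()))
  wave <- 0.1 + 0.05 * sin(2 * pi * tm / 25)     # amplitude 10 x delta_abs
  st[, "Ce"] <- wave
  st[, "Cb"] <- wave
  tr <- structure(list(time = tm, state = st, schedule = NULL),
                  class = "grn_trajectory")
  r <- classify_regime(tr)
  expect_equal(r$label, "proliferative_oscillations")
  expect_lt(abs(r$period[["Cb"]] - 25), 1)
  expect_lt(abs(r$period[["Ce"]] - 25), 1)
})

test_that("classification is invariant to halving the output step", {
  p <- apply_overrides(default_parameters(), c(V_SLET7 = 0))
  y0 <- fixtures_cache()$NT
  l1 <- classify_regime(integrate_model(p, y0, t_end = 400, output_step = 1))$label
  l2 <- classify_regime(integrate_model(p, y0, t_end = 400, output_step = 0.5))$label
  expect_identical(l1, l2)
})

test_that("1x1 scan equals a direct classify run and area trivials hold", {
  p <- default_parameters()
  y0 <- fixtures_cache()$NT
  sc <- scan_2d("V_SLET7", 0, "GF", 1, base = p, initial = y0, t_end = 400,
                output_step = 1)
  direct <- classify_regime(integrate_model(
    apply_overrides(p, c(V_SLET7 = 0, GF = 1)), y0, t_end = 400,
    output_step = 1))$label
  expect_identical(unname(sc$labels[1, 1]), direct)
  ## trivial areas
  all_s <- matrix("steady", 3, 3)
  expect_equal(unname(oscillatory_area(all_s)["proliferative"]), 0)
  all_p <- matrix("proliferative_oscillations", 3, 3)
  expect_equal(unname(oscillatory_area(all_p)["proliferative"]), 1)
  mixed <- matrix(c("proliferative_oscillations", "endocycle_like",
                    "steady", "steady"), 2, 2)
  a <- oscillatory_area(mixed)
  expect_equal(unname(a["proliferative"]), 0.25)
  expect_equal(unname(a["endocycle"]), 0.25)
})

test_that("trajectories round-trip through CSV", {
  tr <- integrate_model(default_parameters(), initial = fixtures_cache()$NT,
                        t_end = 20, output_step = 1)
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f, comment = "test")
  tr2 <- read_trajectory(f)
  expect_equal(tr2$time, tr$time)
  expect_equal(tr2$state, tr$state, tolerance = 1e-6)
})

test_that("peak finder respects prominence", {
  x <- c(0, 1, 0.995, 1.2, 0, 3, 0, 0.5, 0)
  expect_identical(find_peaks(x, min_prominence = 2), 6L)
  expect_true(all(c(4L, 6L) %in% find_peaks(x, min_prominence = 0.2)))
})
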