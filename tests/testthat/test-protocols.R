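test_that("a purely hydraulic root gives a straight Jv(P) line through 0", {
  g <- discretize(branched_rs(), 2e-3)
  p <- hydro_params()
  b <- bath_solution(Ce = 0)
  ser <- simulate_jvp(g, p, b, pressure_steps = seq(0, 0.5, by = 0.1))
  co <- coef(lm(Jv ~ x, data = ser))
  expect_lt(abs(co[1]), 1e-10)
  expect_equal(linearity_gap(ser), 0, tolerance = 1e-9)
  expect_error(simulate_jvp(g, p, b, pressure_steps = c(0, 0.1, 0.2)),
               "4 pressure steps")
})

test_that("the sweep at atmospheric pressure reproduces the exudation flow", {
  g <- discretize(branched_rs(), 2e-3)
  p <- transport_params()
  b <- bath_solution()
  ser <- simulate_jvp(g, p, b, pressure_steps = c(0, 0.1, 0.2, 0.3))
  st <- solve_steady_state(g, p, bath_solution(Pe = 0),
                           control = solve_control())
  expect_equal(ser$Jv[1], st$Jv_base_ul, tolerance = 1e-6)
})

test_that("linearity gap is the normalized bisector residual", {
  ser <- experiment_series("jvp", x = c(0, 0.5, 1), Jv = c(0, 0.1, 1))
  expect_equal(linearity_gap(ser), 0.4)
  # invariance under affine rescaling of both axes
  ser2 <- experiment_series("jvp", x = 2 * c(0, 0.5, 1) + 1,
                            Jv = 50 * c(0, 0.1, 1) - 3)
  expect_equal(linearity_gap(ser2), 0.4)
  expect_error(linearity_gap(experiment_series("jvp", c(0, 1), c(0, 1))),
               "3 distinct")
  expect_error(
    linearity_gap(experiment_series("jvp", c(0, 0.5, 1), c(1, 1, 1))),
    "constant")
})

test_that("measurement noise is reproducible and correctly scaled", {
  ser <- experiment_series("jvp", x = seq(0, 1, length.out = 1000),
                           Jv = rep(2, 1000))
  expect_identical(add_measurement_noise(ser, 0)$Jv, ser$Jv)
  n1 <- add_measurement_noise(ser, 0.05, relative = TRUE, seed = 3)
  n2 <- add_measurement_noise(ser, 0.05, relative = TRUE, seed = 3)
  expect_identical(n1$Jv, n2$Jv)
  rel_sd <- sd((n1$Jv - ser$Jv) / ser$Jv)
  expect_lt(abs(rel_sd - 0.05), 0.005)
})

test_that("cut-and-flow uses protocol defaults and is coherent with Jv(P)", {
  rs <- line_rs(0.2)
  g <- discretize(rs, 1e-3)
  p <- hydro_params()
  b <- bath_solution(Ce = 0)
  cf <- simulate_cut_and_flow(g, p, b, cut_positions = c(0.05, 0.1))
  expect_equal(attr(cf, "operating_pressure"), 0.2)
  expect_equal(cf$x, c(0.2, 0.15, 0.1))
  bpeg <- bath_solution(Ce = 0, w_peg = 0.15)
  cfp <- simulate_cut_and_flow(g, p, bpeg, cut_positions = c(0.05, 0.1))
  expect_equal(attr(cfp, "operating_pressure"), 0.3)

  # cross-protocol consistency: a root cut beyond all laterals equals the
  # equivalent shortened root with an open distal face (constant K profile)
  g_short <- discretize(line_rs(0.15), 1e-3)
  g_short$nodes$is_cut_face[which.min(g_short$nodes$dist_tip)] <- TRUE
  st <- solve_steady_state(g_short, p, bath_solution(Pe = 0.2, Ce = 0))
  expect_equal(cf$Jv[2], st$Jv_base_ul, tolerance = 1e-8)
})

test_that("experiment series validate their inputs", {
  expect_error(experiment_series("jvp", x = c(-0.1, 0, 0.1, 0.2),
                                 Jv = rep(0, 4)), ">= 0")
  expect_error(experiment_series("jvp", x = c(0, 0.1), Jv = 0), "length")
  ser <- experiment_series("cutflow", x = c(0.3, 0.2), Jv = c(1, 2),
                           operating_pressure = 0.2)
  expect_s3_class(ser, "experiment_series")
  expect_error(
    simulate_cut_and_flow(discretize(line_rs(0.2), 1e-3), hydro_params(),
                          bath_solution(Ce = 0),
                          cut_positions = c(0.1, 0.05)),
    "increasing")
})
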