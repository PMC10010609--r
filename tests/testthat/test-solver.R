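test_that("local radial fluxes follow the composite driving force", {
  rev <- list(surface = pi * 1.05e-3 * 1e-3)
  params <- transport_params(k = 1e-7, sigma = 0.85)
  bath <- bath_solution(Pe = 0.1, Ce = 0)
  # Pe - P = 0.1 MPa, C - Ce = 40 -> osmotic term adds 0.08424 MPa
  j <- radial_water_flux(rev, P = 0, C = 40, params = params, bath = bath)
  expect_equal(j, 1e-7 * (0.1 + 0.08424) * pi * 1.05e-3 * 1e-3,
               tolerance = 1e-4)
  expect_equal(j, 6.08e-14, tolerance = 1e-2)
  # all gradients zero
  b0 <- bath_solution(Pe = 0, Ce = 13.72)
  expect_equal(radial_water_flux(rev, P = 0, C = 13.72, params = params,
                                 bath = b0), 0)
  # an external PEG pressure larger than the inward terms reverses the flux
  bpeg <- bath_solution(Pe = 0.1, Ce = 0, w_peg = 0.15)
  expect_lt(radial_water_flux(rev, P = 0, C = 40, params = params,
                              bath = bpeg), 0)
})

test_that("radial solute flux is uptake minus leak", {
  rev <- list(surface = 3.30e-6)
  bath <- bath_solution(Ce = 10)
  p <- transport_params(Js_star = 1e-7, Ps = 1e-9)
  expect_equal(radial_solute_flux(rev, C = 10, p, bath), 1e-7 * 3.30e-6)
  # zero at the flux-free concentration difference Js*/Ps
  expect_equal(radial_solute_flux(rev, C = 10 + 100, p, bath), 0)
  expect_equal(radial_solute_flux(rev, C = 10 + 50, p, bath),
               (1e-7 - 5e-8) * 3.30e-6, tolerance = 1e-12)
})

test_that("axial conductance interpolates, clamps, and scales with viscosity", {
  p <- transport_params(K_knots = data.frame(dist = c(0, 0.1),
                                             K = c(1e-12, 1e-10)))
  expect_equal(axial_conductance_at(0.05, p), 5.05e-11, tolerance = 1e-12)
  expect_equal(axial_conductance_at(0.2, p), 1e-10)    # clamp beyond knots
  expect_equal(axial_conductance_at(0.05, p, mu = 14),
               5.05e-11 / 14, tolerance = 1e-12)
  p1 <- transport_params(K_knots = data.frame(dist = 0.1, K = 3e-11))
  expect_equal(axial_conductance_at(c(0, 0.2), p1), c(3e-11, 3e-11))
})

test_that("equilibrium bath gives zero pressures and flows", {
  g <- discretize(branched_rs(), 1e-3)
  p <- transport_params()
  b <- bath_solution(Pe = 0)
  pw <- solve_pressure(g, p, b, C = b$Ce, C_peg = 0)
  expect_true(all(abs(pw$P) < 1e-15))
  expect_true(all(abs(pw$J) < 1e-25))
  expect_equal(pw$Jv_base, 0)
})

test_that("flows are linear in conductances at fixed concentrations", {
  g <- discretize(branched_rs(), 2e-3)
  b <- bath_solution(Pe = 0.2)
  p1 <- hydro_params(k = 1e-7, K = 1e-10)
  p2 <- hydro_params(k = 2e-7, K = 2e-10)
  s1 <- solve_steady_state(g, p1, b)
  s2 <- solve_steady_state(g, p2, b)
  expect_equal(s2$Jv_base, 2 * s1$Jv_base, tolerance = 1e-10)
})

test_that("hydrostatic solve matches the electrical-analogue oracle", {
  for (seed in c(2, 9, 17)) {
    rs <- generate_synthetic_rsa(primary_length = 0.06, lateral_density = 60,
                                 lateral_length_mean = 0.015,
                                 lateral_length_sd = 0.004, seed = seed)
    g <- discretize(rs, 1e-3)
    expect_lte(nrow(g$nodes), 150)
    p <- hydro_params()
    b <- bath_solution(Pe = 0.25, Ce = 0)
    st <- solve_steady_state(g, p, b)
    orc <- oracle_hydrostatic(g, p, b)
    expect_equal(st$Jv_base, orc$Jv, tolerance = 1e-10)
    expect_equal(st$P, orc$P, tolerance = 1e-10)
  }
  # also with an open cut face
  g <- cut_at_distance(discretize(line_rs(0.1), 1e-3), 0.04)
  p <- hydro_params()
  b <- bath_solution(Pe = 0.3, Ce = 0)
  st <- solve_steady_state(g, p, b)
  expect_equal(st$Jv_base, oracle_hydrostatic(g, p, b)$Jv, tolerance = 1e-10)
})

test_that("one-REV solve agrees with the osmometer closed form", {
  g1 <- discretize(line_rs(1e-3), 1e-3)
  p <- transport_params(K_knots = data.frame(dist = 5e-4, K = 1e-6))
  ctrl <- solve_control(tol = 1e-12, max_iter = 5000)
  m <- osmometer_model(sum(g1$nodes$surface), p, bath_solution())
  for (Pe in c(0, 0.05, 0.2, 0.5)) {
    st <- solve_steady_state(g1, p, bath_solution(Pe = Pe), control = ctrl)
    os <- osmometer_steady_state(m, Pe)
    expect_equal(st$Jv_base_ul, os$Jv_ul, tolerance = 1e-8)
    expect_equal(st$C[1], os$C, tolerance = 1e-6)
  }
})

test_that("zero-flow steady state pins C - Ce at Js*/Ps", {
  p <- transport_params()        # Js*/Ps = 100
  balance_Pe <- -vant_hoff_term(100, sigma = p$sigma)
  # closed form: exact
  m <- osmometer_model(1e-3, p, bath_solution())
  os <- osmometer_steady_state(m, balance_Pe)
  expect_equal(os$C - 13.72, 100, tolerance = 1e-12)
  expect_equal(os$Jv, 0, tolerance = 1e-25)
  # architecture solve at the balance pressure
  g <- discretize(branched_rs(), 2e-3)
  st <- solve_steady_state(g, p, bath_solution(Pe = balance_Pe),
                           control = solve_control(tol = 1e-10))
  expect_true(all(abs(st$C - 13.72 - 100) < 1e-4))
  expect_lt(abs(st$Jv_base_ul), 1e-8)
})

test_that("active uptake without permeability has no steady state at rest", {
  g <- discretize(line_rs(0.05), 1e-3)
  p <- transport_params(Js_star = 1e-7, Ps = 0)
  expect_error(solve_steady_state(g, p, bath_solution(Pe = 0)),
               "unbounded accumulation")
})

test_that("water and solute balances close on random architectures", {
  for (seed in 1:4) {
    rs <- generate_synthetic_rsa(primary_length = 0.2, lateral_density = 50,
                                 seed = seed)
    g <- discretize(rs, 1.5e-3)
    st <- solve_steady_state(g, transport_params(),
                             bath_solution(Pe = 0.15))
    rep <- conservation_report(st, g)
    expect_lt(rep$water_node, 1e-10)
    expect_lt(rep$water_global, 1e-10)
    expect_lt(rep$solute_global, 1e-10)
    expect_true(all(st$C >= 0))
  }
})

test_that("basal outflow is non-decreasing in applied pressure", {
  g <- discretize(branched_rs(), 2e-3)
  p <- transport_params()
  Jv <- vapply(seq(0, 0.5, by = 0.1), function(Pe) {
    solve_steady_state(g, p, bath_solution(Pe = Pe))$Jv_base
  }, numeric(1))
  expect_true(all(diff(Jv) > 0))
})

test_that("halving the REV length changes Jv by less than 1 percent", {
  rs <- generate_synthetic_rsa(primary_length = 0.15, lateral_density = 40,
                               seed = 12)
  p <- transport_params()
  b <- bath_solution(Pe = 0.2)
  j1 <- solve_steady_state(discretize(rs, 1e-3), p, b)$Jv_base
  j2 <- solve_steady_state(discretize(rs, 0.5e-3), p, b)$Jv_base
  expect_lt(abs(j2 / j1 - 1), 0.01)
})

test_that("the per-REV state exports to a tidy table", {
  g <- discretize(branched_rs(), 2e-3)
  st <- solve_steady_state(g, transport_params(), bath_solution(Pe = 0.1))
  tab <- solve_state_table(st, g)
  expect_equal(nrow(tab), nrow(g$nodes))
  expect_true(all(c("P_MPa", "C_mol_m3", "C_peg_kg_l", "j_m3_s",
                    "J_m3_s") %in% names(tab)))
  f <- withr::local_tempfile(fileext = ".csv")
  solve_state_table(st, g, f)
  back <- utils::read.csv(f)
  expect_equal(back$P_MPa, tab$P_MPa, tolerance = 1e-12)
})
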