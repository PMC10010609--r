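# shared small inversion problem: short root, 3 cuts, 6 pressure steps,
# coarse REVs -- big enough to be identifiable, small enough for fast tests
small_problem <- function(seed = 31, with_solutes = TRUE) {
  rs <- generate_synthetic_rsa(primary_length = 0.18, lateral_density = 40,
                               lateral_length_mean = 0.03,
                               lateral_length_sd = 0.01, seed = seed)
  g <- discretize(rs, 2.5e-3)
  blades <- c(0.05, 0.09, 0.13)
  Kkn <- synthetic_k_profile(blades, K_tip = 3e-12, K_base = 6e-11,
                             seed = seed + 1)
  ptrue <- transport_params(
    k = 1.2e-7, K_knots = Kkn,
    Js_star = if (with_solutes) 1.3e-7 else 0,
    Ps = if (with_solutes) 1.5e-9 else 0,
    sigma = if (with_solutes) 0.85 else 0)
  b <- bath_solution(Ce = if (with_solutes) 13.72 else 0)
  steps <- c(0, 0.05, 0.15, 0.1, 0.25, 0.2)
  jvp <- simulate_jvp(g, ptrue, b, steps)
  cf <- simulate_cut_and_flow(g, ptrue, b, cut_positions = blades)
  list(g = g, ptrue = ptrue, jvp = jvp, cf = cf, blades = blades)
}

test_that("K profiles are built from cut positions with one knot per cut", {
  kn <- make_k_profile(seq(0.05, 0.37, by = 0.04), 1e-11)
  expect_equal(nrow(kn), 9)          # 9 cuts + k, Js*, Ps = 12 parameters
  expect_error(make_k_profile(c(0.1, 0.1), 1e-11), "duplicate")
  expect_error(make_k_profile(c(0.2, 0.1), 1e-11), "increasing")
  p <- transport_params(K_knots = make_k_profile(0.1, 5e-11))
  expect_equal(axial_conductance_at(c(0, 0.1, 0.3), p), rep(5e-11, 3))
  fg <- first_guess_k_profile(c(0.05, 0.09, 0.15))
  expect_equal(fg$K, c(1e-12, 1e-12, 1e-10))
})

test_that("synthetic conductance profiles are monotone and reproducible", {
  kn1 <- synthetic_k_profile(c(0.05, 0.1, 0.2, 0.3), seed = 4)
  kn2 <- synthetic_k_profile(c(0.05, 0.1, 0.2, 0.3), seed = 4)
  expect_identical(kn1, kn2)
  expect_true(all(diff(kn1$K) >= 0))
})

test_that("the objective is zero at the truth, additive, and order-invariant", {
  pr <- small_problem()
  F0 <- objective(pr$ptrue, pr$g, pr$jvp, pr$cf)
  expect_lt(F0, 1e-12)
  # perturbing one observation by e raises F by e^2
  jvp_e <- pr$jvp
  jvp_e$Jv[3] <- jvp_e$Jv[3] + 0.01
  expect_equal(objective(pr$ptrue, pr$g, jvp_e, pr$cf), F0 + 0.01^2,
               tolerance = 1e-4)
  # point order does not matter
  perm <- c(4, 1, 6, 2, 5, 3)
  jvp_p <- experiment_series("jvp", pr$jvp$x[perm], pr$jvp$Jv[perm],
                             bath = attr(pr$jvp, "bath"))
  expect_equal(objective(pr$ptrue, pr$g, jvp_p, pr$cf), F0,
               tolerance = 1e-6)
})

test_that("monotone K parameter transform round-trips", {
  K <- c(2e-12, 5e-12, 4e-11, 8e-11)
  expect_equal(rootflow:::.theta_to_K(rootflow:::.K_to_theta(K, TRUE), TRUE),
               K, tolerance = 1e-12)
  expect_equal(rootflow:::.theta_to_K(rootflow:::.K_to_theta(K, FALSE),
                                      FALSE), K, tolerance = 1e-12)
})

test_that("the staged fit recovers known parameters from clean data", {
  pr <- small_problem()
  fr <- fit(pr$g, pr$jvp, pr$cf)
  expect_s3_class(fr, "fit_result")
  expect_lt(abs(fr$params$k / pr$ptrue$k - 1), 0.05)
  expect_true(all(abs(fr$params$K_knots$K / pr$ptrue$K_knots$K - 1) < 0.15))
  expect_gt(fr$R2, 0.999)
  # joint objective does not increase across stages
  Fj <- fr$stage_trace$F_joint
  expect_lte(Fj[3], Fj[1] * (1 + 1e-9))
  expect_lte(Fj[3], Fj[2] * (1 + 1e-9))
})

test_that("full fit on solute-free data agrees with the pure-hydraulic fit", {
  pr <- small_problem(seed = 57, with_solutes = FALSE)
  fr_full <- fit(pr$g, pr$jvp, pr$cf)
  fr_ph <- fit_pure_hydraulic(pr$g, pr$jvp, pr$cf, linear_threshold = 0)
  # nested models: on data without solute transport both recover the truth
  expect_lt(abs(fr_full$params$k / pr$ptrue$k - 1), 0.05)
  expect_lt(abs(fr_ph$params$k / pr$ptrue$k - 1), 0.05)
  expect_lt(abs(fr_ph$params$k / fr_full$params$k - 1), 0.06)
  expect_lt(abs(fr_ph$P0), 0.02)     # no osmotic offset to absorb
})

test_that("fitted k is insensitive to the solute parameters and to sigma", {
  pr <- small_problem()
  scan <- sensitivity_scan(pr$g, pr$jvp, pr$ptrue,
                           js_factors = 10^seq(-1, 1, by = 1),
                           ps_factors = 10^seq(-1, 1, by = 1),
                           sigmas = c(0.5, 0.85, 1))
  at_best <- scan$scan[scan$scan$factor == 1, ]
  expect_true(all(abs(at_best$k / scan$k0 - 1) < 1e-3))
  expect_true(all(at_best$F <= scan$scan$F + 1e-12))
  sig_k <- scan$sigma_refits$k
  expect_lt(max(abs(sig_k / scan$k0 - 1)), 0.15)
})

test_that("degraded single-series fits warn", {
  pr <- small_problem()
  expect_warning(fit(pr$g, jvp_series = pr$jvp,
                     config = fit_config(stage2_maxit = 2, stage3_maxit = 2)),
                 "weakly identifiable")
  expect_error(fit(pr$g), "at least one")
})
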