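test_that("conditional rate bundles enforce the partner-effect ordering", {
  g <- conditional_rates(1, 15, 60, 70, units = "percent")
  expect_equal(unlist(g[c("nu_S", "nu_I", "delta_I", "delta_S")]),
               c(nu_S = 0.01, nu_I = 0.15, delta_I = 0.60, delta_S = 0.70))
  expect_error(conditional_rates(0.2, 0.1, 0.3, 0.5), "nu_S < nu_I")
  expect_error(conditional_rates(0.1, 0.2, 0.5, 0.3), "delta_I < delta_S")
  expect_error(conditional_rates(0, 0.2, 0.3, 0.5), "\\(0, 1\\)")
  expect_error(conditional_rates(0.1, 1, 0.3, 0.5), "\\(0, 1\\)")
})

test_that("exposure is the convex combination of group prevalences", {
  expect_equal(exposure(0.3, 0.9, 0), 0.3)
  expect_equal(exposure(0.3, 0.9, 1), 0.9)
  expect_equal(exposure(0.2, 0.4, 0.5), 0.3)
})

test_that("the generalized dynamics have the stated boundary signs", {
  set.seed(41)
  for (k in 1:25) {
    g1 <- draw_conditional_rates(); g2 <- draw_conditional_rates()
    m <- runif(1); rho_j <- runif(1)
    model <- general_model(g1, g2, m)
    at0 <- general_rhs(c(0, rho_j), model)[1]
    expect_equal(at0, g1$nu_S + m * rho_j * (g1$nu_I - g1$nu_S))
    expect_gt(at0, 0)
    at1 <- general_rhs(c(1, rho_j), model)[1]
    expect_equal(at1, -(g1$delta_I + m * (1 - rho_j) * (g1$delta_S - g1$delta_I)))
    expect_lt(at1, 0)
  }
})

test_that("nearly state-independent rates balance at nu/(nu + delta)", {
  eps <- 1e-9
  g <- conditional_rates(0.3, 0.3 + eps, 0.2, 0.2 + eps)
  model <- general_model(g, g, m = 0.4)
  rho <- 0.3 / (0.3 + 0.2)
  expect_lt(max(abs(general_rhs(c(rho, rho), model))), 1e-8)
  expect_equal(general_reaction(0.7, g, 0.4), rho, tolerance = 1e-7)
  expect_equal(general_reaction(0.1, g, 0.4), rho, tolerance = 1e-7)
})

test_that("reaction values are interior, increasing, and match the root oracle", {
  g1 <- demo_concave_group1(); g2 <- demo_concave_group2()
  # segregated case: root of (1-r)(0.15 r + 0.01(1-r)) = r(0.6 r + 0.7(1-r))
  expect_equal(general_reaction(0.5, g1, 0),
               oracle_general_reaction(0.5, g1, 0), tolerance = 1e-10)
  set.seed(42)
  for (k in 1:30) {
    g <- if (k %% 2) g1 else draw_conditional_rates()
    m <- runif(1); rj <- runif(1)
    r <- general_reaction(rj, g, m)
    expect_gt(r, 0); expect_lt(r, 1)
    expect_equal(r, oracle_general_reaction(rj, g, m), tolerance = 1e-9)
  }
  # strictly increasing in the other group's prevalence
  expect_gt(general_reaction(0.6, g2, 0.5), general_reaction(0.2, g2, 0.5))
  rs <- general_reaction(seq(0, 1, by = 0.1), g1, 0.7)
  expect_true(all(diff(rs) > 0))
})

test_that("curvature classification follows the rate gaps", {
  expect_equal(curvature_class(demo_concave_group1()), "concave")   # 0.14 > 0.10
  expect_equal(curvature_class(demo_concave_group2()), "concave")   # 0.79 > 0.19
  expect_equal(curvature_class(conditional_rates(0.1, 0.2, 0.3, 0.6)),
               "convex")
  expect_equal(curvature_class(conditional_rates(0.1, 0.3, 0.2, 0.4)),
               "linear")
})

test_that("the stationary state is interior, stable, and matches integration", {
  g1 <- demo_concave_group1(); g2 <- demo_concave_group2()
  # symmetric groups give equal components at any m
  for (m in c(0, 0.5, 1)) {
    eq <- general_equilibrium(general_model(g1, g1, m))
    expect_equal(eq$state[1], eq$state[2], tolerance = 1e-12)
    expect_true(eq$positive); expect_true(eq$stable)
  }
  for (m in c(0, 0.3, 0.7, 1)) {
    model <- general_model(g1, g2, m)
    eq <- general_equilibrium(model)
    expect_false(eq$multiple)           # corner starts agree
    tr <- general_integrate(c(0.5, 0.5), model, tol = 1e-12)
    expect_equal(eq$state, attr(tr, "final_state"), tolerance = 1e-6)
  }
})

test_that("general curves feed the mixing analyses unchanged", {
  model <- general_model(demo_concave_group1(), demo_concave_group2(), 0)
  cv <- general_curve(model, seq(0, 1, by = 0.01))
  expect_true(all(cv$rho1 > 0 & cv$rho1 < 1 & cv$rho2 > 0 & cv$rho2 < 1))
  verdict <- detect_monotonicity(cv$rho1, cv$m)
  expect_equal(verdict$pattern, "interior_max")
  rep <- pareto_inefficient_set(cv)
  expect_gt(sum(rep$dominated), 0L)
  expect_equal(detect_monotonicity(cv$rho2, cv$m)$pattern, "decreasing")
})
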