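test_that("reaction function solves the per-group stationarity quadratic", {
  expect_equal(sis_reaction(0, lambda_i = 3, m = 1), 0)
  expect_equal(sis_reaction(0.7, lambda_i = 2, m = 0), 0.5)
  expect_equal(sis_reaction(0.4, 0.55, 0.5),
               oracle_sis_reaction(0.4, 0.55, 0.5), tolerance = 1e-9)
  expect_equal(round(sis_reaction(0.4, 0.55, 0.5), 4), 0.1265)

  set.seed(21)
  for (k in 1:40) {
    lam <- runif(1, 0.1, 5); m <- runif(1); rj <- runif(1)
    expect_equal(sis_reaction(rj, lam, m), oracle_sis_reaction(rj, lam, m),
                 tolerance = 1e-8)
  }
})

test_that("equilibrium solver finds the endemic state and its stability", {
  eq <- solve_equilibrium(adoption_rates(2, 5), 1)
  expect_equal(eq$state, c(0.6, 0.75), tolerance = 1e-10)
  expect_true(eq$positive)
  expect_true(eq$stable)
  expect_lt(eq$residual, 1e-12)

  # above the mixing threshold the no-diffusion state prevails
  eq0 <- solve_equilibrium(adoption_rates(0.25, 2), 0.8)
  expect_equal(eq0$state, c(0, 0))
  expect_false(eq0$positive)
  expect_equal(eq0$mbar, 0.6)

  # symmetric rates reduce to the single-group SIS equilibrium at any m
  for (m in c(0, 0.31, 1))
    expect_equal(solve_equilibrium(adoption_rates(2, 2), m)$state,
                 c(0.5, 0.5), tolerance = 1e-10)

  # user group order is preserved when canonical orientation swapped
  expect_equal(solve_equilibrium(adoption_rates(5, 2), 1)$state,
               c(0.75, 0.6), tolerance = 1e-10)
})

test_that("closed-form endpoint equilibria evaluate the printed formulas", {
  ep <- endpoint_equilibria(adoption_rates(0.55, 2))
  expect_equal(ep$m0, c(0, 0.5))
  prod <- 0.55 * 2
  expect_equal(ep$m1, c((prod - 1) / (prod + 2), (prod - 1) / (prod + 0.55)))

  expect_equal(endpoint_equilibria(adoption_rates(2, 5))$m1, c(0.6, 0.75))
  expect_equal(endpoint_equilibria(adoption_rates(0.5, 2))$m1, c(0, 0))
  expect_equal(endpoint_equilibria(adoption_rates(5, 2))$m0, c(0.8, 0.5))
})

test_that("fixed-point equilibria agree with long-horizon integration", {
  set.seed(22)
  for (k in 1:40) {
    l <- draw_rates_away_from_thresholds()
    m <- runif(1)
    mb <- mixsis:::mbar_canonical(l[1], l[2])
    if (!is.na(mb) && abs(m - mb) < 0.05) next   # slow manifold at the fold
    eq <- solve_equilibrium(adoption_rates(l[1], l[2]), m)
    tr <- sis_integrate(c(0.5, 0.5), adoption_rates(l[1], l[2]), m,
                        tol = 1e-12)
    expect_equal(eq$state, attr(tr, "final_state"), tolerance = 1e-6)
  }
})

test_that("equilibrium curves obey the comparative-statics propositions", {
  cv <- equilibrium_curve(adoption_rates(0.55, 2))
  expect_equal(nrow(cv), 201L)
  # avg and diff are exact functions of the group columns
  expect_equal(cv$avg, (cv$rho1 + cv$rho2) / 2)
  expect_equal(cv$diff, cv$rho2 - cv$rho1)
  # sensitive group strictly decreasing; gap positive and strictly decreasing
  expect_true(all(diff(cv$rho2) < 0))
  expect_true(all(cv$diff[-1] > 0))
  expect_true(all(diff(cv$diff) < 0))
  # resistant group rises from 0 to an interior maximum, then falls
  expect_equal(detect_monotonicity(cv$rho1, cv$m)$pattern, "interior_max")

  # equal rates: every column constant in m
  cve <- equilibrium_curve(adoption_rates(1.5, 1.5), seq(0, 1, by = 0.02))
  expect_lt(max(abs(cve$rho1 - cve$rho1[1])), 1e-12)
  expect_lt(max(abs(cve$rho2 - cve$rho2[1])), 1e-12)
})

test_that("curve endpoints coincide with the closed forms and the threshold", {
  for (l in list(c(0.55, 2), c(2, 5), c(1.3, 3.7))) {
    cv <- equilibrium_curve(adoption_rates(l[1], l[2]), seq(0, 1, by = 0.25))
    ep <- endpoint_equilibria(adoption_rates(l[1], l[2]))
    expect_equal(c(cv$rho1[1], cv$rho2[1]), ep$m0, tolerance = 1e-10)
    expect_equal(c(cv$rho1[nrow(cv)], cv$rho2[nrow(cv)]), ep$m1,
                 tolerance = 1e-10)
  }

  # endemic level vanishes as m approaches the threshold from below
  r <- adoption_rates(0.3, 2)
  mb <- mixing_threshold(r)$mbar
  grid <- c(seq(0.01, mb - 1e-4, length.out = 30), mb, 0.9)
  cv <- equilibrium_curve(r, grid)
  expect_lt(cv$rho2[30], 5e-3)
  expect_true(all(diff(cv$rho2[1:30]) < 0))
  expect_equal(cv$rho2[31], 0)          # at and above mbar: extinction
  expect_equal(cv$rho2[32], 0)
  expect_equal(attr(cv, "mbar"), mb)
})

test_that("curves reject malformed grids and keep user group order", {
  expect_error(equilibrium_curve(adoption_rates(1, 2), c(0.5, 0.2)),
               "increasing")
  expect_error(equilibrium_curve(adoption_rates(1, 2), c(-0.1, 0.5)))
  cv <- equilibrium_curve(adoption_rates(2, 0.55), seq(0, 1, by = 0.5))
  cv2 <- equilibrium_curve(adoption_rates(0.55, 2), seq(0, 1, by = 0.5))
  expect_equal(cv$rho1, cv2$rho2)
  expect_equal(cv$rho2, cv2$rho1)
  expect_equal(cv$diff, cv2$diff)       # always sensitive minus resistant
})
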