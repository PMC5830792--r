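test_that("the exemplar rate pairs classify to their regions", {
  expect_equal(classify_region(adoption_rates(0.25, 2))$label, "B")
  expect_equal(classify_region(adoption_rates(0.3, 4))$label, "C")
  expect_equal(classify_region(adoption_rates(1, 4))$label, "D")
  expect_equal(classify_region(adoption_rates(2, 5))$label, "E")
  expect_equal(classify_region(adoption_rates(0.5, 0.9))$label, "A")
  expect_equal(classify_region(adoption_rates(0.55, 2))$label, "C")

  # boundary ties are flagged but labelled deterministically by precedence
  reg <- classify_region(adoption_rates(0.5, 2))        # product exactly 1
  expect_equal(reg$label, "B")
  expect_true(reg$boundary_flags[["product_eq_1"]])
  reg2 <- classify_region(adoption_rates(0.7, 1))
  expect_equal(reg2$label, "A")
  expect_true(reg2$boundary_flags[["lambda2_eq_1"]])
})

test_that("closed-form C/D boundary candidate agrees with the numeric scan", {
  set.seed(31)
  grid1 <- seq(0.15, 2.8, length.out = 7)
  grid2 <- seq(1.3, 5.8, length.out = 7)
  for (l1 in grid1) for (l2 in grid2) {
    if (l1 >= l2) next
    if (l1 * l2 <= 1.05) next                            # region B
    e_gap <- l1^0.75 * (l2 + 1) - l2^0.75 * (l1 + 1)
    cd_gap <- l1 - sqrt(l2) / (l2 - sqrt(l2) + 1)
    if (e_gap >= -0.02 || abs(cd_gap) < 0.03) next       # near other borders
    reg <- classify_region(adoption_rates(l1, l2))
    expect_equal(reg$label, reg$closed_form_label,
                 info = sprintf("lambda = (%g, %g)", l1, l2))
  }
})

test_that("monotonicity detection classifies difference patterns", {
  m <- seq(0, 1, by = 0.01)
  expect_equal(detect_monotonicity(rep(0.3, 101), m)$pattern, "constant")
  expect_equal(detect_monotonicity(m^2, m)$pattern, "increasing")
  expect_equal(detect_monotonicity(1 - m, m)$pattern, "decreasing")
  # sub-tolerance wiggles are noise
  expect_equal(detect_monotonicity(0.5 + 1e-9 * sin(20 * m), m)$pattern,
               "constant")
  v <- -(m - 0.3)^2
  verdict <- detect_monotonicity(v, m)
  expect_equal(verdict$pattern, "interior_max")
  expect_equal(verdict$argmax, 0.3, tolerance = 1e-6)   # parabolic refinement
  verdict2 <- detect_monotonicity((m - 0.66)^2, m)
  expect_equal(verdict2$pattern, "interior_min")
  expect_equal(verdict2$argmin, 0.66, tolerance = 1e-6)
  expect_error(detect_monotonicity(c(1, 2)), "3")
})

test_that("Pareto-dominated mixing levels match the regional structure", {
  # pure trade-off when both curves are monotone in opposite directions
  cve <- equilibrium_curve(adoption_rates(2, 5), seq(0, 1, by = 0.01))
  expect_equal(sum(pareto_inefficient_set(cve)$dominated), 0L)
  expect_equal(sum(pareto_inefficient_set(cve, "desirable")$dominated), 0L)

  # region-C behaviour: every m whose resistant level exceeds the bipartite
  # value is dominated, with m = 1 a valid witness
  cv <- equilibrium_curve(adoption_rates(0.3, 4), seq(0, 1, by = 0.01))
  rep <- pareto_inefficient_set(cv)
  expect_gt(sum(rep$dominated), 0L)
  worse_than_bipartite <- cv$rho1 > cv$rho1[nrow(cv)] + 1e-9
  expect_true(all(rep$dominated[worse_than_bipartite]))
  last <- cv[nrow(cv), ]
  for (i in which(worse_than_bipartite)) {
    expect_lte(last$rho1, cv$rho1[i])
    expect_lte(last$rho2, cv$rho2[i])
  }
  # witnesses dominate every point of their interval
  for (j in seq_len(nrow(rep$intervals))) {
    iv <- rep$intervals[j, ]
    wi <- which.min(abs(cv$m - iv$witness_m))
    inside <- cv$m >= iv$m_lo & cv$m <= iv$m_hi
    expect_true(all(cv$rho1[wi] <= cv$rho1[inside] + 1e-9))
    expect_true(all(cv$rho2[wi] <= cv$rho2[inside] + 1e-9))
  }

  # with a desirable trait the bipartite extreme itself is inefficient
  repd <- pareto_inefficient_set(cv, "desirable")
  expect_true(repd$dominated[nrow(cv)])

  # degenerate grid
  one <- equilibrium_curve(adoption_rates(0.3, 4), 0.5)
  expect_equal(nrow(pareto_inefficient_set(one)$intervals), 0L)
})

test_that("a dominated mixing level implies a non-monotonic resistant curve", {
  set.seed(32)
  for (k in 1:12) {
    l2 <- runif(1, 1.2, 5)
    l1 <- runif(1, 0.15, min(l2, 1.6))
    cv <- try(equilibrium_curve(adoption_rates(l1, l2),
                                seq(0, 1, by = 0.01)), silent = TRUE)
    if (inherits(cv, "try-error")) next
    rep <- pareto_inefficient_set(cv)
    if (sum(rep$dominated) == 0L) next
    pos <- mixsis:::curve_resistant(cv) > 1e-9 | cv$m < 1e-9
    verdict <- detect_monotonicity(mixsis:::curve_resistant(cv)[pos],
                                   cv$m[pos])
    expect_false(verdict$pattern %in% c("increasing", "decreasing"),
                 info = sprintf("lambda = (%g, %g)", l1, l2))
  }
})

test_that("optimal mixing selects the stated extremes per objective", {
  cvB <- equilibrium_curve(adoption_rates(0.25, 2), seq(0, 1, by = 0.01))
  expect_equal(optimal_mixing(cvB, "max_avg")$m, 0)     # segregation maximizes
  # above the threshold diffusion dies out, so the minimum is reached at mbar
  expect_equal(optimal_mixing(cvB, "min_avg")$m, attr(cvB, "mbar"))

  cvE <- equilibrium_curve(adoption_rates(2, 5), seq(0, 1, by = 0.01))
  expect_equal(optimal_mixing(cvE, "max_avg")$m, 1)     # bipartite maximizes
  expect_equal(optimal_mixing(cvE, "min_avg")$m, 0)

  cvC <- equilibrium_curve(adoption_rates(0.3, 4), seq(0, 1, by = 0.01))
  expect_equal(optimal_mixing(cvC, "min_avg")$m, 1)     # region C minimum
  expect_gt(optimal_mixing(cvC, "max_avg")$m, 0)        # interior maximum
  expect_lt(optimal_mixing(cvC, "max_avg")$m, 1)

  cvD <- equilibrium_curve(adoption_rates(1.2, 4), seq(0, 1, by = 0.01))
  expect_equal(optimal_mixing(cvD, "min_avg")$m, 0)     # region D minimum

  # wherever the endemic state persists up to m = 1, the between-group gap
  # is smallest in the bipartite case
  for (cv in list(cvC, cvD, cvE))
    expect_equal(optimal_mixing(cv, "min_diff")$m, 1)
  # in region B the gap hits zero once diffusion is extinguished
  expect_equal(optimal_mixing(cvB, "min_diff")$m, attr(cvB, "mbar"))
})
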