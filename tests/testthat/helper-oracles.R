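# Independent oracles used across the suite.  These deliberately avoid the
# closed-form/quadratic code paths they are used to check: roots come from
# bracketing searches on the raw stationarity polynomials, and origin
# stability from base eigen() on a Jacobian assembled here.

# largest root in [0,1] of lambda (1-r)(m rho_j + (1-m) r) - r = 0,
# by sign scan plus uniroot
oracle_sis_reaction <- function(rho_j, lambda, m) {
  f <- function(r) lambda * (1 - r) * (m * rho_j + (1 - m) * r) - r
  grid <- seq(0, 1, by = 1e-3)
  fg <- vapply(grid, f, numeric(1))
  ix <- which(fg[-length(fg)] * fg[-1] <= 0)
  if (!length(ix)) return(if (abs(f(0)) < 1e-12) 0 else NA_real_)
  i <- ix[length(ix)]
  if (fg[i] == 0 && fg[i + 1] == 0) return(grid[i + 1])
  stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-14)$root
}

# unique root in (0,1) of the state-conditional stationarity polynomial
oracle_general_reaction <- function(rho_j, g, m) {
  f <- function(r) {
    I <- (1 - m) * r + m * rho_j
    (1 - r) * (g$nu_I * I + g$nu_S * (1 - I)) -
      r * (g$delta_I * I + g$delta_S * (1 - I))
  }
  stats::uniroot(f, c(0, 1), tol = 1e-14)$root
}

# origin Jacobian assembled from first principles; leading eigenvalue via
# base eigen()
oracle_origin_eigenvalue <- function(l1, l2, m) {
  J <- matrix(c(l1 * (1 - m) - 1, l2 * m,
                l1 * m, l2 * (1 - m) - 1), nrow = 2)
  max(Re(eigen(J, only.values = TRUE)$values))
}

# threshold mixing level by bisection on the sign of the leading origin
# eigenvalue (positive below the threshold, negative above)
oracle_mbar_bisect <- function(l1, l2, tol = 1e-10) {
  lo <- 0; hi <- 1
  if (oracle_origin_eigenvalue(l1, l2, 1) > 0) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (oracle_origin_eigenvalue(l1, l2, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# random admissible rate draws kept away from the bifurcation manifolds
# (|lambda_i - 1| and |lambda1*lambda2 - 1| above `margin`), where
# integration horizons needed for tight agreement blow up
draw_rates_away_from_thresholds <- function(margin = 0.05) {
  repeat {
    l2 <- stats::runif(1, 0.3, 5)
    l1 <- stats::runif(1, 0.2, l2)
    if (abs(l1 - 1) > margin && abs(l2 - 1) > margin &&
        abs(l1 * l2 - 1) > margin)
      return(c(l1, l2))
  }
}

# draws in the region with a proper interior mixing threshold:
# lambda2 > 1 > lambda1 * lambda2
draw_rates_with_threshold <- function() {
  l2 <- stats::runif(1, 1.05, 5)
  u <- stats::runif(1, 0.05, 0.95)
  c(u / l2, l2)
}

# valid state-conditional rate bundle
draw_conditional_rates <- function() {
  nu <- sort(stats::runif(2, 0.01, 0.95))
  de <- sort(stats::runif(2, 0.01, 0.95))
  conditional_rates(nu[1], nu[2] + 1e-3, de[1], de[2] + 1e-3)
}

demo_concave_group1 <- function() conditional_rates(1, 15, 60, 70, units = "percent")
demo_concave_group2 <- function() conditional_rates(1, 80, 1, 20, units = "percent")
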