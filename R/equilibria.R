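# Endemic equilibria of the two-type SIS model and their dependence on
# the mixing level m.
#
# Holding the other group's infected fraction rho_j fixed, a group's
# stationarity condition
#
#   lambda (1 - rho)(m rho_j + (1 - m) rho) - rho = 0
#
# is quadratic in rho; its largest root in [0,1] is the group's reaction
# to rho_j.  The composition of the two reaction functions is monotone
# increasing, so iterating it downward from 1 converges to the largest
# fixed point, which is the almost-globally-stable endemic state whenever
# one exists (lambda2 > 1 and either lambda1*lambda2 > 1 or m below the
# mixing threshold mbar).

#' Per-group SIS reaction function
#'
#' Largest \eqn{\rho_i \in [0,1]} with \eqn{\dot\rho_i = 0} holding the
#' other group's infected fraction fixed, computed from the closed
#' quadratic with stable branch selection.
#'
#' @param rho_j other group's infected fraction, in \[0, 1\].
#' @param lambda_i effective adoption rate of this group.
#' @param m mixing level in \[0, 1\].
#' @return The stationary infected fraction, a number in \[0, 1\].
#' @examples
#' sis_reaction(0, lambda_i = 2, m = 0)    # isolated SIS equilibrium 0.5
#' sis_reaction(0.4, 0.55, 0.5)            # about 0.1265
#' @export
sis_reaction <- function(rho_j, lambda_i, m) {
  stopifnot(is.numeric(rho_j), all(rho_j >= 0 & rho_j <= 1),
            is.numeric(lambda_i), lambda_i > 0)
  m <- check_m(m)
  vapply(rho_j, reaction_canonical, numeric(1), lam = lambda_i, m = m)
}

# scalar core; stationarity polynomial A r^2 + B r + C with
# A = -lam(1-m), B = lam(1-m) - lam m rho_j - 1, C = lam m rho_j >= 0.
reaction_canonical <- function(rho_j, lam, m) {
  A <- -lam * (1 - m)
  B <- lam * (1 - m) - lam * m * rho_j - 1
  C <- lam * m * rho_j
  if (abs(A) < 1e-300) {               # m = 1: linear in rho
    r <- C / (1 + lam * rho_j)
  } else if (C == 0) {                 # no between-group source
    r <- max(0, 1 - 1 / (lam * (1 - m)))
  } else {
    # A < 0: larger root takes the minus branch
    r <- (-B - sqrt(B^2 - 4 * A * C)) / (2 * A)
  }
  min(max(r, 0), 1)
}

mbar_canonical <- function(l1, l2) {
  prod <- l1 * l2
  if (l2 <= 1 || prod > 1) return(NA_real_)
  min(max(1 - (1 - prod) / (l1 + l2 - 2 * prod), 0), 1)
}

positive_exists <- function(l1, l2, m) {
  prod <- l1 * l2
  l2 > 1 && (prod > 1 || m < mbar_canonical(l1, l2))
}

# Largest fixed point of the composed reaction map, canonical orientation.
# Aitken-accelerated monotone iteration started from x0 (default 1),
# followed by a Newton polish on the 2-D stationarity system.
solve_canonical <- function(l1, l2, m, x0 = NULL, tol = 1e-12) {
  if (!positive_exists(l1, l2, m)) return(c(0, 0))
  h <- function(x) reaction_canonical(reaction_canonical(x, l1, m), l2, m)
  x <- if (is.null(x0) || !is.finite(x0) || x0 <= 0) 1 else min(x0, 1)
  for (k in seq_len(300L)) {
    x1 <- h(x); x2 <- h(x1)
    if (abs(x2 - x1) < 1e-14) { x <- x2; break }
    d <- x2 - 2 * x1 + x
    xa <- if (abs(d) > 1e-300) x - (x1 - x)^2 / d else x2
    x <- if (is.finite(xa) && xa > 0 && xa <= 1) xa else x2
  }
  rho <- c(reaction_canonical(x, l1, m), x)
  # Newton polish on F_i = lam_i (1-rho_i)(m rho_j + (1-m) rho_i) - rho_i
  lam <- c(l1, l2)
  for (k in seq_len(40L)) {
    mix <- m * rev(rho) + (1 - m) * rho
    FF <- lam * (1 - rho) * mix - rho
    if (max(abs(FF)) < 1e-15) break
    J <- equilibrium_jacobian(rho, l1, l2, m)
    step <- tryCatch(solve(J, FF), error = function(e) NULL)
    if (is.null(step)) break
    rho_new <- pmin(pmax(rho - step, 0), 1)
    if (max(abs(rho_new - rho)) < 1e-16) { rho <- rho_new; break }
    rho <- rho_new
  }
  rho
}

# Jacobian of the delta = 1 dynamics at an arbitrary state, canonical order.
equilibrium_jacobian <- function(rho, l1, l2, m) {
  lam <- c(l1, l2)
  mix <- m * rev(rho) + (1 - m) * rho
  dii <- lam * (-mix + (1 - rho) * (1 - m)) - 1
  dij <- lam * (1 - rho) * m
  matrix(c(dii[1], dij[2], dij[1], dii[2]), nrow = 2L)
}

#' Endemic equilibrium of the two-type SIS model
#'
#' Computes the almost-globally-stable stationary state for given
#' effective adoption rates and mixing level.  Returns the no-diffusion
#' state \eqn{(0,0)} when no positive state exists (\eqn{\lambda_2 \le 1},
#' or \eqn{\lambda_1\lambda_2 \le 1} with \eqn{m \ge \bar m}); otherwise
#' the largest fixed point of the composed reaction functions, found by
#' monotone iteration from \eqn{(1,1)} with Aitken acceleration and a
#' Newton polish, with stability certified by the Jacobian eigenvalues.
#'
#' @inheritParams sis_rhs
#' @param tol acceptable stationarity residual \eqn{\max_i|\dot\rho_i|}.
#' @return An object of class `equilibrium_result`: list with `state`
#'   (user group order), `positive`, `residual`, `stable`, `eigenvalues`,
#'   and `mbar` (`NA` when not defined).
#' @examples
#' solve_equilibrium(adoption_rates(2, 5), m = 1)$state      # (0.6, 0.75)
#' solve_equilibrium(adoption_rates(0.25, 2), m = 0.8)$state # (0, 0)
#' @export
solve_equilibrium <- function(rates, m, tol = 1e-10) {
  rates <- as_rates(rates)
  m <- check_m(m)
  rho <- solve_canonical(rates$lambda1, rates$lambda2, m)
  equilibrium_result(rho, rates, m, tol)
}

equilibrium_result <- function(rho_canonical, rates, m, tol = 1e-10,
                               positivity = 1e-9) {
  l1 <- rates$lambda1; l2 <- rates$lambda2
  lam <- c(l1, l2)
  mix <- m * rev(rho_canonical) + (1 - m) * rho_canonical
  res <- max(abs(lam * (1 - rho_canonical) * mix - rho_canonical))
  if (res > tol)
    stop(sprintf(paste0("equilibrium solver residual %.3e exceeds tol %.3e ",
                        "at lambda=(%g,%g), m=%g"), res, tol, l1, l2, m),
         call. = FALSE)
  ev <- eigen(equilibrium_jacobian(rho_canonical, l1, l2, m),
              only.values = TRUE)$values
  structure(list(state = unswap(rates, rho_canonical),
                 positive = all(rho_canonical > positivity),
                 residual = res,
                 stable = all(Re(ev) <= 1e-8),
                 eigenvalues = ev,
                 mbar = mbar_canonical(l1, l2)),
            class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("Equilibrium state: rho = (%.6f, %.6f)%s\n",
              x$state[1], x$state[2],
              if (x$positive) "  [endemic]" else "  [no diffusion]"))
  cat(sprintf("  residual = %.2e; %s\n", x$residual,
              if (x$stable) "stable" else "NOT certified stable"))
  if (!is.na(x$mbar)) cat(sprintf("  mixing threshold mbar = %.6f\n", x$mbar))
  invisible(x)
}

#' Closed-form equilibria at the segregation and bipartite extremes
#'
#' At `m = 0` each group is an isolated SIS system with equilibrium
#' \eqn{\max(0, 1 - 1/\lambda_i)}.  At `m = 1` (bipartite case) the
#' endemic state is
#' \eqn{\left(\frac{\lambda_1\lambda_2-1}{\lambda_1\lambda_2+\lambda_2},
#'            \frac{\lambda_1\lambda_2-1}{\lambda_1\lambda_2+\lambda_1}\right)}
#' when \eqn{\lambda_1\lambda_2 > 1}, and \eqn{(0,0)} otherwise.
#'
#' @inheritParams sis_rhs
#' @return A list with numeric length-2 elements `m0` and `m1` in user
#'   group order.
#' @examples
#' endpoint_equilibria(adoption_rates(2, 5))
#' @export
endpoint_equilibria <- function(rates) {
  rates <- as_rates(rates)
  l1 <- rates$lambda1; l2 <- rates$lambda2
  m0 <- pmax(0, 1 - 1 / c(l1, l2))
  prod <- l1 * l2
  m1 <- if (prod > 1) c((prod - 1) / (prod + l2), (prod - 1) / (prod + l1))
        else c(0, 0)
  list(m0 = unswap(rates, m0), m1 = unswap(rates, m1))
}

#' Equilibrium infection levels as a function of the mixing level
#'
#' Tabulates the endemic equilibrium over a grid of mixing levels,
#' warm-starting each solve from its neighbour.  The `avg` column is the
#' population average \eqn{(\rho_1^E+\rho_2^E)/2} and `diff` is the
#' sensitive-minus-resistant gap \eqn{\rho_2^E-\rho_1^E} (in canonical
#' orientation, so `diff >= 0`); `rho1`/`rho2` are reported in user group
#' order.
#'
#' @inheritParams sis_rhs
#' @param m_grid strictly increasing mixing levels within \[0, 1\].
#' @param tol stationarity residual tolerance per grid point.
#' @return A data frame of class `equilibrium_curve` with columns `m`,
#'   `rho1`, `rho2`, `avg`, `diff`, `positive`, and attributes `mbar`,
#'   `lambda` (user order) and `swapped`.
#' @examples
#' cv <- equilibrium_curve(adoption_rates(0.55, 2), seq(0, 1, by = 0.05))
#' head(cv)
#' @export
equilibrium_curve <- function(rates, m_grid = seq(0, 1, length.out = 201L),
                              tol = 1e-10) {
  rates <- as_rates(rates)
  stopifnot(is.numeric(m_grid), length(m_grid) >= 1L,
            all(m_grid >= 0 & m_grid <= 1))
  if (is.unsorted(m_grid, strictly = TRUE))
    stop("`m_grid` must be strictly increasing", call. = FALSE)
  l1 <- rates$lambda1; l2 <- rates$lambda2
  n <- length(m_grid)
  rho1 <- rho2 <- numeric(n)
  warm <- NULL
  for (i in seq_len(n)) {
    rho <- solve_canonical(l1, l2, m_grid[i], x0 = warm)
    # residual check (cheap) -- fail loudly with the offending m
    mix <- m_grid[i] * rev(rho) + (1 - m_grid[i]) * rho
    res <- max(abs(c(l1, l2) * (1 - rho) * mix - rho))
    if (res > tol)
      stop(sprintf("curve solve failed at m = %g (residual %.3e)",
                   m_grid[i], res), call. = FALSE)
    rho1[i] <- rho[1]; rho2[i] <- rho[2]
    warm <- if (rho[2] > 0) rho[2] else NULL
  }
  pos <- rho1 > 1e-9 & rho2 > 1e-9
  out1 <- if (isTRUE(rates$swapped)) rho2 else rho1
  out2 <- if (isTRUE(rates$swapped)) rho1 else rho2
  curve <- data.frame(m = m_grid, rho1 = out1, rho2 = out2,
                      avg = (rho1 + rho2) / 2, diff = rho2 - rho1,
                      positive = pos)
  attr(curve, "mbar") <- mbar_canonical(l1, l2)
  attr(curve, "lambda") <- user_lambda(rates)
  attr(curve, "swapped") <- isTRUE(rates$swapped)
  class(curve) <- c("equilibrium_curve", "data.frame")
  curve
}

# canonical-orientation accessors for curve columns
curve_resistant <- function(curve) {
  if (isTRUE(attr(curve, "swapped"))) curve$rho2 else curve$rho1
}
curve_sensitive <- function(curve) {
  if (isTRUE(attr(curve, "swapped"))) curve$rho1 else curve$rho2
}
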