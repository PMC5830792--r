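# Mean-field dynamics of the two-type SIS model.
#
# With rho_i the infected fraction of group i and m the mixing level (the
# expected fraction of between-group interactions),
#
#   drho_i/dt = delta_i * [ lambda_i (1 - rho_i) (m rho_j + (1 - m) rho_i) - rho_i ]
#
# where lambda_i = p upsilon_i / delta_i is group i's effective adoption
# rate.  The delta_i prefactor only rescales time per group, so equilibria
# depend on (lambda_1, lambda_2, m) alone.

#' Right-hand side of the two-type SIS mean dynamic
#'
#' Evaluates the time derivative \eqn{(\dot\rho_1, \dot\rho_2)} of the
#' infected fractions.  With `deltas` omitted the per-group recovery rates
#' are set to 1, a time rescaling that leaves equilibria unchanged.
#'
#' @param state numeric length-2, infected fractions `(rho1, rho2)` in
#'   user group order.
#' @param rates an [adoption_rates()] object (or coercible input).
#' @param m mixing level in \[0, 1\].
#' @param deltas optional positive recovery-rate pair.
#' @return Numeric length-2 derivative, user group order.
#' @examples
#' sis_rhs(c(0.2, 0.4), adoption_rates(0.55, 2), m = 0.5)
#' @export
sis_rhs <- function(state, rates, m, deltas = c(1, 1)) {
  rates <- as_rates(rates)
  m <- check_m(m)
  state <- check_state(state)
  stopifnot(is.numeric(deltas), length(deltas) == 2L, all(deltas > 0))
  lam <- user_lambda(rates)
  mix <- m * rev(state) + (1 - m) * state
  deltas * (lam * (1 - state) * mix - state)
}

#' Integrate the two-type SIS mean dynamic
#'
#' Solves the ODE system with a stiff-capable adaptive integrator
#' ([deSolve::lsoda]).  When `horizon` is `NULL` the integration proceeds
#' in chunks until the stationarity residual \eqn{\max_i |\dot\rho_i|}
#' falls below `tol` (or `max_time` is reached), so the final row is an
#' equilibrium up to `tol`.
#'
#' @inheritParams sis_rhs
#' @param state0 initial infected fractions.
#' @param horizon integration time; `NULL` for adaptive stopping.
#' @param tol stationarity residual for adaptive stopping.
#' @param max_time cap on the adaptive horizon.
#' @param n_out number of output rows per chunk (or over `horizon`).
#' @return A data frame with columns `t`, `rho1`, `rho2` (user group
#'   order) and attributes `final_state` and `residual`.
#' @examples
#' tr <- sis_integrate(c(0.01, 0.01), adoption_rates(2, 5), m = 1)
#' attr(tr, "final_state")  # close to (0.6, 0.75)
#' @export
sis_integrate <- function(state0, rates, m, deltas = c(1, 1),
                          horizon = NULL, tol = 1e-10, max_time = 2e5,
                          n_out = 101L) {
  rates <- as_rates(rates)
  m <- check_m(m)
  state0 <- check_state(state0)
  lam <- user_lambda(rates)
  derivs <- function(t, y, parms) {
    y <- pmin(pmax(y, 0), 1)
    mix <- m * rev(y) + (1 - m) * y
    list(deltas * (lam * (1 - y) * mix - y))
  }
  run_chunk <- function(y0, t_end) {
    out <- deSolve::lsoda(y = c(rho1 = y0[1], rho2 = y0[2]),
                          times = seq(0, t_end, length.out = n_out),
                          func = derivs, parms = NULL,
                          rtol = 1e-12, atol = 1e-14)
    if (any(!is.finite(out)))
      stop("non-finite state during integration", call. = FALSE)
    as.data.frame(out)
  }
  residual_at <- function(y) max(abs(derivs(0, y, NULL)[[1]]))

  if (!is.null(horizon)) {
    traj <- run_chunk(state0, horizon)
  } else {
    traj <- run_chunk(state0, 100)
    t_off <- 100
    y <- unlist(traj[nrow(traj), c("rho1", "rho2")], use.names = FALSE)
    while (residual_at(y) > tol && t_off < max_time) {
      chunk <- run_chunk(y, min(2 * t_off, max_time - t_off))
      chunk$time <- chunk$time + t_off
      t_off <- chunk$time[nrow(chunk)]
      traj <- rbind(traj, chunk[-1L, ])
      y <- unlist(chunk[nrow(chunk), c("rho1", "rho2")], use.names = FALSE)
    }
  }
  names(traj) <- c("t", "rho1", "rho2")
  over <- max(c(traj$rho1, traj$rho2) - 1, -c(traj$rho1, traj$rho2), 0)
  if (over > 1e-9)
    warning(sprintf("trajectory left [0,1]^2 by %.2e; clipped", over))
  traj$rho1 <- pmin(pmax(traj$rho1, 0), 1)
  traj$rho2 <- pmin(pmax(traj$rho2, 0), 1)
  final <- unlist(traj[nrow(traj), c("rho1", "rho2")], use.names = FALSE)
  attr(traj, "final_state") <- final
  attr(traj, "residual") <- residual_at(final)
  traj
}

# Jacobian of the (delta-scaled) dynamics at the origin; canonical order.
origin_jacobian <- function(lambda1, lambda2, m, deltas = c(1, 1)) {
  matrix(c(deltas[1] * (lambda1 * (1 - m) - 1), deltas[2] * lambda2 * m,
           deltas[1] * lambda1 * m,             deltas[2] * (lambda2 * (1 - m) - 1)),
         nrow = 2L)
}

#' Leading eigenvalue of the linearization at the no-diffusion state
#'
#' The off-diagonal entries of the origin Jacobian are nonnegative, so its
#' eigenvalues are real; the larger one decides local stability of
#' \eqn{(0,0)}.
#'
#' @inheritParams sis_rhs
#' @return The largest eigenvalue (a real number).
#' @export
origin_leading_eigenvalue <- function(rates, m, deltas = c(1, 1)) {
  rates <- as_rates(rates)
  m <- check_m(m)
  J <- origin_jacobian(rates$lambda1, rates$lambda2, m, deltas)
  a <- J[1, 1]; d <- J[2, 2]; bc <- J[1, 2] * J[2, 1]
  ((a + d) + sqrt((a - d)^2 + 4 * bc)) / 2
}

#' Mixing threshold for stability of the no-diffusion state
#'
#' When \eqn{\lambda_2 > 1 \ge \lambda_1\lambda_2} there is a threshold
#' mixing level
#' \deqn{\bar m = 1 - \frac{1 - \lambda_1\lambda_2}
#'                         {\lambda_1 + \lambda_2 - 2\lambda_1\lambda_2}}
#' below which a positive endemic state exists and above which the
#' no-diffusion state is globally stable.  \eqn{\bar m = 1} exactly when
#' \eqn{\lambda_1\lambda_2 = 1}.  Outside that parameter region the
#' threshold is not defined: for \eqn{\lambda_2 \le 1} the origin is
#' stable for every m, and for \eqn{\lambda_1\lambda_2 > 1} it is unstable
#' for every m.
#'
#' @inheritParams sis_rhs
#' @param m optional mixing level at which to also report the origin's
#'   leading eigenvalue and local stability.
#' @return A list of class `origin_stability` with elements `mbar` (or
#'   `NA` when undefined), `origin_stable`, and `leading_eigenvalue`
#'   (both `NA` unless `m` is supplied).
#' @examples
#' mixing_threshold(adoption_rates(0.25, 2))$mbar  # 0.6
#' @export
mixing_threshold <- function(rates, m = NULL) {
  rates <- as_rates(rates)
  l1 <- rates$lambda1; l2 <- rates$lambda2
  prod <- l1 * l2
  mbar <- NA_real_
  if (l2 > 1 && prod <= 1) {
    den <- l1 + l2 - 2 * prod
    # den = l1(1 - prod/l1... ) > 0 throughout the admissible region:
    # l1 + l2 - 2 l1 l2 >= 2 sqrt(prod) - 2 prod > 0 for prod <= 1
    stopifnot(den > 0)
    mbar <- 1 - (1 - prod) / den
    mbar <- min(max(mbar, 0), 1)
  }
  lead <- NA_real_; stable <- NA
  if (!is.null(m)) {
    lead <- origin_leading_eigenvalue(rates, m)
    stable <- lead < 1e-12
  }
  structure(list(mbar = mbar, origin_stable = stable,
                 leading_eigenvalue = lead,
                 lambda = user_lambda(rates)),
            class = "origin_stability")
}

#' @export
print.origin_stability <- function(x, ...) {
  cat("Origin (no-diffusion) stability report\n")
  cat(sprintf("  lambda = (%g, %g)\n", x$lambda[1], x$lambda[2]))
  if (is.na(x$mbar)) cat("  mixing threshold: not defined for these rates\n")
  else cat(sprintf("  mixing threshold mbar = %.6f\n", x$mbar))
  if (!is.na(x$leading_eigenvalue))
    cat(sprintf("  leading eigenvalue = %.6g (origin %s)\n",
                x$leading_eigenvalue,
                if (isTRUE(x$origin_stable)) "stable" else "unstable"))
  invisible(x)
}
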