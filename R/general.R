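# Generalized contagion with state-conditional adoption and recovery.
#
# Beyond the SIS assumption that only the infected state is contagious,
# each group carries four rates conditional on the partner's state:
# nu_S (adopt when meeting a susceptible), nu_I (adopt when meeting an
# infected), delta_I (recover when meeting an infected), delta_S (recover
# when meeting a susceptible), with 0 < nu_S < nu_I < 1 and
# 0 < delta_I < delta_S < 1.  With I_i = (1-m) rho_i + m rho_j the
# probability of meeting an infected partner,
#
#   drho_i/dt = (1-rho_i)[nu_I I_i + nu_S (1-I_i)]
#             - rho_i   [delta_I I_i + delta_S (1-I_i)].
#
# Since nu_S > 0 there is no extinction: every reaction value is interior,
# and for concave-concave (or convex-convex) group pairs the stationary
# state is unique and globally stable.

#' State-conditional contagion and recovery rates for one group
#'
#' @param nu_S adoption rate when the partner is susceptible, in (0, 1).
#' @param nu_I adoption rate when the partner is infected; `nu_S < nu_I`.
#' @param delta_I recovery rate when the partner is infected, in (0, 1).
#' @param delta_S recovery rate when the partner is susceptible;
#'   `delta_I < delta_S`.
#' @param units `"fraction"` (default) or `"percent"`; percent inputs are
#'   divided by 100.
#' @return An object of class `conditional_rates`.
#' @examples
#' conditional_rates(1, 15, 60, 70, units = "percent")
#' @export
conditional_rates <- function(nu_S, nu_I, delta_I, delta_S,
                              units = c("fraction", "percent")) {
  units <- match.arg(units)
  r <- c(nu_S = nu_S, nu_I = nu_I, delta_I = delta_I, delta_S = delta_S)
  if (units == "percent") r <- r / 100
  if (any(!is.finite(r)) || any(r <= 0) || any(r >= 1))
    stop("conditional rates must lie strictly in (0, 1)", call. = FALSE)
  if (!(r["nu_S"] < r["nu_I"]))
    stop("need nu_S < nu_I (infected partners are more contagious)",
         call. = FALSE)
  if (!(r["delta_I"] < r["delta_S"]))
    stop("need delta_I < delta_S (infected partners slow recovery)",
         call. = FALSE)
  structure(as.list(r), class = "conditional_rates")
}

#' Two-group generalized contagion model
#'
#' @param group1,group2 [conditional_rates()] bundles.
#' @param m mixing level in \[0, 1\].
#' @return An object of class `general_model`.
#' @examples
#' general_model(conditional_rates(1, 15, 60, 70, "percent"),
#'               conditional_rates(1, 80, 1, 20, "percent"), m = 0.5)
#' @export
general_model <- function(group1, group2, m) {
  stopifnot(inherits(group1, "conditional_rates"),
            inherits(group2, "conditional_rates"))
  structure(list(group1 = group1, group2 = group2, m = check_m(m)),
            class = "general_model")
}

#' Probability of meeting an infected partner
#'
#' The exposure of group i, \eqn{I_i = (1-m)\rho_i + m\rho_j}.
#'
#' @param rho_i,rho_j infected fractions of own and other group.
#' @param m mixing level.
#' @return A fraction in \[0, 1\].
#' @export
exposure <- function(rho_i, rho_j, m) {
  stopifnot(all(rho_i >= 0 & rho_i <= 1), all(rho_j >= 0 & rho_j <= 1))
  m <- check_m(m)
  (1 - m) * rho_i + m * rho_j
}

#' Right-hand side of the generalized contagion dynamics
#'
#' @param state infected fractions `(rho1, rho2)`.
#' @param model a [general_model()].
#' @return Numeric length-2 derivative.
#' @export
general_rhs <- function(state, model) {
  stopifnot(inherits(model, "general_model"))
  state <- check_state(state)
  vapply(1:2, function(i) {
    g <- model[[i]]
    I <- exposure(state[i], state[3L - i], model$m)
    (1 - state[i]) * (g$nu_I * I + g$nu_S * (1 - I)) -
      state[i] * (g$delta_I * I + g$delta_S * (1 - I))
  }, numeric(1))
}

#' Reaction function of the generalized model
#'
#' The unique root in (0, 1) of the second-degree stationarity polynomial
#' for one group, holding the other group's infected fraction fixed.  The
#' endpoint signs \eqn{\dot\rho_i|_{\rho_i=0} > 0} and
#' \eqn{\dot\rho_i|_{\rho_i=1} < 0} bracket the root; it is strictly
#' increasing in `rho_j`.
#'
#' @param rho_j other group's infected fraction (vectorized).
#' @param group_rates a [conditional_rates()] bundle.
#' @param m mixing level.
#' @return The stationary infected fraction(s), strictly inside (0, 1).
#' @export
general_reaction <- function(rho_j, group_rates, m) {
  stopifnot(inherits(group_rates, "conditional_rates"),
            all(rho_j >= 0 & rho_j <= 1))
  m <- check_m(m)
  vapply(rho_j, general_reaction_scalar, numeric(1),
         g = group_rates, m = m)
}

# stationarity polynomial a r^2 + b r + c with
#   a = (1-m)(ddelta - dnu),  c = nu_S + dnu m rho_j > 0,
#   b = (1-m) dnu - c - (delta_S - ddelta m rho_j)
# where dnu = nu_I - nu_S > 0 and ddelta = delta_S - delta_I > 0;
# f(0) = c > 0 and f(1) < 0 give the interior bracket.
general_reaction_scalar <- function(rho_j, g, m) {
  dnu <- g$nu_I - g$nu_S
  dde <- g$delta_S - g$delta_I
  cc <- g$nu_S + dnu * m * rho_j
  A2 <- g$delta_S - dde * m * rho_j
  a <- (1 - m) * (dde - dnu)
  b <- (1 - m) * dnu - cc - A2
  if (abs(a) < 1e-12) return(min(max(-cc / b, 0), 1))
  D <- b^2 - 4 * a * cc
  s <- if (b >= 0) 1 else -1
  q <- -(b + s * sqrt(D)) / 2
  roots <- c(q / a, if (q != 0) cc / q else NA_real_)
  r <- roots[!is.na(roots) & roots > 0 & roots < 1][1]
  if (is.na(r)) stop("no interior stationary root; invalid rates?",
                     call. = FALSE)
  r
}

#' Curvature of a group's reaction function
#'
#' The reaction function is strictly concave in `rho_j` when
#' \eqn{(\nu_I-\nu_S) > (\delta_S-\delta_I)}, strictly convex when the
#' inequality is reversed, and linear at equality (within `tol`).
#'
#' @param group_rates a [conditional_rates()] bundle.
#' @param tol tolerance band for the linear verdict.
#' @return `"concave"`, `"convex"`, or `"linear"`.
#' @examples
#' curvature_class(conditional_rates(1, 15, 60, 70, "percent"))  # concave
#' @export
curvature_class <- function(group_rates, tol = 1e-12) {
  stopifnot(inherits(group_rates, "conditional_rates"))
  gap <- (group_rates$nu_I - group_rates$nu_S) -
    (group_rates$delta_S - group_rates$delta_I)
  if (abs(gap) <= tol) "linear" else if (gap > 0) "concave" else "convex"
}

#' Integrate the generalized contagion dynamics
#'
#' Same adaptive scheme as [sis_integrate()], for the state-conditional
#' model.
#'
#' @inheritParams sis_integrate
#' @param model a [general_model()].
#' @return Data frame `t`, `rho1`, `rho2` with attributes `final_state`
#'   and `residual`.
#' @export
general_integrate <- function(state0, model, horizon = NULL, tol = 1e-10,
                              max_time = 2e5, n_out = 101L) {
  stopifnot(inherits(model, "general_model"))
  state0 <- check_state(state0)
  derivs <- function(t, y, parms) list(general_rhs(pmin(pmax(y, 0), 1), model))
  traj <- as.data.frame(deSolve::lsoda(
    y = c(rho1 = state0[1], rho2 = state0[2]),
    times = seq(0, if (is.null(horizon)) 100 else horizon, length.out = n_out),
    func = derivs, parms = NULL, rtol = 1e-12, atol = 1e-14))
  if (is.null(horizon)) {
    t_off <- traj$time[nrow(traj)]
    y <- unlist(traj[nrow(traj), c("rho1", "rho2")], use.names = FALSE)
    while (max(abs(general_rhs(y, model))) > tol && t_off < max_time) {
      chunk <- as.data.frame(deSolve::lsoda(
        y = c(rho1 = y[1], rho2 = y[2]),
        times = seq(0, min(2 * t_off, max_time - t_off), length.out = n_out),
        func = derivs, parms = NULL, rtol = 1e-12, atol = 1e-14))
      chunk$time <- chunk$time + t_off
      t_off <- chunk$time[nrow(chunk)]
      traj <- rbind(traj, chunk[-1L, ])
      y <- unlist(chunk[nrow(chunk), c("rho1", "rho2")], use.names = FALSE)
    }
  }
  names(traj) <- c("t", "rho1", "rho2")
  traj$rho1 <- pmin(pmax(traj$rho1, 0), 1)
  traj$rho2 <- pmin(pmax(traj$rho2, 0), 1)
  final <- unlist(traj[nrow(traj), c("rho1", "rho2")], use.names = FALSE)
  attr(traj, "final_state") <- final
  attr(traj, "residual") <- max(abs(general_rhs(final, model)))
  traj
}

#' Stationary state of the generalized contagion model
#'
#' Fixed point of the composed reaction functions by monotone iteration
#' from the (1, 1) corner (Aitken-accelerated) with a Newton polish.  In
#' the concave-concave and convex-convex cases the state is unique and
#' globally stable; for mixed curvature the solver also iterates upward
#' from (0, 0) and flags multiplicity when the two limits disagree.
#'
#' @param model a [general_model()].
#' @param tol acceptable stationarity residual.
#' @return A list of class `equilibrium_result` (see
#'   [solve_equilibrium()]) with extra fields `curvature` (per-group) and
#'   `multiple` (logical: distinct fixed points found from the two corner
#'   starts).
#' @export
general_equilibrium <- function(model, tol = 1e-10) {
  stopifnot(inherits(model, "general_model"))
  cls <- c(curvature_class(model$group1), curvature_class(model$group2))
  if (length(unique(cls[cls != "linear"])) > 1L)
    warning("mixed curvature: uniqueness of the stationary state is not guaranteed")
  down <- general_fixed_point(model, from = 1)
  up <- general_fixed_point(model, from = 0)
  multiple <- max(abs(down - up)) > 1e-8
  if (multiple)
    warning(sprintf("distinct fixed points from corner starts (gap %.2e)",
                    max(abs(down - up))))
  rho <- down
  res <- max(abs(general_rhs(rho, model)))
  if (res > tol)
    stop(sprintf("general equilibrium residual %.3e exceeds tol", res),
         call. = FALSE)
  ev <- eigen(general_jacobian(rho, model), only.values = TRUE)$values
  structure(list(state = rho, positive = all(rho > 1e-9 & rho < 1 - 1e-9),
                 residual = res, stable = all(Re(ev) <= 1e-8),
                 eigenvalues = ev, mbar = NA_real_,
                 curvature = cls, multiple = multiple),
            class = "equilibrium_result")
}

general_fixed_point <- function(model, from = 1) {
  h <- function(x) general_reaction_scalar(
    general_reaction_scalar(x, model$group1, model$m), model$group2, model$m)
  x <- from
  for (k in seq_len(500L)) {
    x1 <- h(x); x2 <- h(x1)
    if (abs(x2 - x1) < 1e-15) { x <- x2; break }
    d <- x2 - 2 * x1 + x
    xa <- if (abs(d) > 1e-300) x - (x1 - x)^2 / d else x2
    x <- if (is.finite(xa) && xa >= 0 && xa <= 1) xa else x2
  }
  rho <- c(general_reaction_scalar(x, model$group1, model$m), x)
  for (k in seq_len(40L)) {
    FF <- general_rhs(rho, model)
    if (max(abs(FF)) < 1e-15) break
    J <- general_jacobian(rho, model)
    step <- tryCatch(solve(J, FF), error = function(e) NULL)
    if (is.null(step)) break
    rho_new <- pmin(pmax(rho - step, 0), 1)
    if (max(abs(rho_new - rho)) < 1e-16) { rho <- rho_new; break }
    rho <- rho_new
  }
  rho
}

general_jacobian <- function(rho, model) {
  J <- matrix(0, 2L, 2L)
  m <- model$m
  for (i in 1:2) {
    g <- model[[i]]
    dnu <- g$nu_I - g$nu_S
    dde <- g$delta_S - g$delta_I
    I <- exposure(rho[i], rho[3L - i], m)
    inf_rate <- g$nu_S + dnu * I
    rec_rate <- g$delta_S - dde * I
    J[i, i] <- -inf_rate + (1 - rho[i]) * dnu * (1 - m) -
      rec_rate + rho[i] * dde * (1 - m)
    J[i, 3L - i] <- (1 - rho[i]) * dnu * m + rho[i] * dde * m
  }
  J
}

#' Equilibrium curve of the generalized model over the mixing grid
#'
#' @inheritParams general_equilibrium
#' @param model a [general_model()] (its `m` is ignored in favour of the
#'   grid).
#' @param m_grid strictly increasing mixing levels within \[0, 1\].
#' @return A data frame of class `equilibrium_curve` with the same
#'   columns as [equilibrium_curve()] (`diff = rho2 - rho1`; `positive`
#'   is always `TRUE` since the general model admits no extinction).
#' @export
general_curve <- function(model, m_grid = seq(0, 1, length.out = 201L),
                          tol = 1e-10) {
  stopifnot(inherits(model, "general_model"))
  if (is.unsorted(m_grid, strictly = TRUE) && length(m_grid) > 1L)
    stop("`m_grid` must be strictly increasing", call. = FALSE)
  n <- length(m_grid)
  rho1 <- rho2 <- numeric(n)
  for (i in seq_len(n)) {
    mi <- general_model(model$group1, model$group2, m_grid[i])
    rho <- general_fixed_point(mi, from = 1)
    res <- max(abs(general_rhs(rho, mi)))
    if (res > tol)
      stop(sprintf("general curve solve failed at m = %g (residual %.3e)",
                   m_grid[i], res), call. = FALSE)
    rho1[i] <- rho[1]; rho2[i] <- rho[2]
  }
  curve <- data.frame(m = m_grid, rho1 = rho1, rho2 = rho2,
                      avg = (rho1 + rho2) / 2, diff = rho2 - rho1,
                      positive = TRUE)
  attr(curve, "mbar") <- NA_real_
  attr(curve, "swapped") <- FALSE
  class(curve) <- c("equilibrium_curve", "data.frame")
  curve
}
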