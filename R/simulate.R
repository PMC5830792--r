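# Finite-population stochastic process underlying the mean dynamics.
#
# Two groups of binary-state agents update synchronously each period
# against start-of-period states: each agent interacts with probability p
# (always, in the general model), drawing a partner uniformly from the
# other group with probability m and from its own group (excluding
# itself) otherwise.  A susceptible agent with an infected partner
# becomes infected with probability upsilon_i (times its susceptibility
# multiplier, capped at 1); each infected agent recovers with probability
# delta_i, independently.  Interaction sampling is one-sided: the
# partner's state is read, not updated through that contact, matching the
# term structure of the mean-field equations.

#' Configuration for the stochastic two-group simulator
#'
#' @param params a [sis_params()] object (SIS variant) or a
#'   [general_model()] (state-conditional variant; its `m` slot is
#'   ignored in favour of `m` here).
#' @param m mixing level in \[0, 1\].
#' @param N integer length-2 group sizes (equal sizes are the baseline
#'   design; unequal sizes are allowed).
#' @param periods number of update periods.
#' @param replicates number of independent replicate runs.
#' @param seed RNG seed; a fixed seed makes trajectories bitwise
#'   reproducible.
#' @param init initial infected fractions per group.
#' @param heterogeneity within-group susceptibility spread: `list(type =
#'   "none")` or `list(type = "lognormal", sigma = s)` for per-agent
#'   multipliers with mean 1 applied to the infection probability.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(params, m, N = c(10000L, 10000L),
                       periods = 2000L, replicates = 20L, seed = 1L,
                       init = c(0.1, 0.1),
                       heterogeneity = list(type = "none")) {
  stopifnot(inherits(params, "sis_params") || inherits(params, "general_model"))
  m <- check_m(m)
  N <- as.integer(N)
  stopifnot(length(N) == 2L, all(N >= 0L), periods >= 1L, replicates >= 1L,
            length(init) == 2L, all(init >= 0 & init <= 1))
  if (m > 0 && any(N < 1L))
    stop("between-group interactions need agents in both groups",
         call. = FALSE)
  if (m < 1 && any(N < 2L))
    stop("own-group interactions need at least 2 agents per group when m < 1",
         call. = FALSE)
  stopifnot(is.list(heterogeneity),
            heterogeneity$type %in% c("none", "lognormal"))
  if (heterogeneity$type == "lognormal")
    stopifnot(is.numeric(heterogeneity$sigma), heterogeneity$sigma >= 0)
  structure(list(params = params, m = m, N = N,
                 periods = as.integer(periods),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed), init = init,
                 heterogeneity = heterogeneity),
            class = "sim_config")
}

# partner states for every agent of one group (FALSE where no interaction)
draw_partner_states <- function(s_own, s_oth, interact, m) {
  n <- length(s_own)
  ps <- logical(n)
  cross <- interact & (stats::runif(n) < m)
  own <- interact & !cross
  nc <- sum(cross)
  if (nc > 0L)
    ps[cross] <- s_oth[sample.int(length(s_oth), nc, replace = TRUE)]
  no <- sum(own)
  if (no > 0L) {
    i_own <- which(own)
    j <- sample.int(n - 1L, no, replace = TRUE)
    j <- j + (j >= i_own)            # uniform over own group excluding self
    ps[own] <- s_own[j]
  }
  ps
}

step_group_sis <- function(s_own, s_oth, p, m, nu, delta, mult) {
  n <- length(s_own)
  interact <- stats::runif(n) < p
  ps <- draw_partner_states(s_own, s_oth, interact, m)
  newinf <- !s_own & ps & (stats::runif(n) < pmin(1, nu * mult))
  recov <- s_own & (stats::runif(n) < delta)
  (s_own & !recov) | newinf
}

step_group_general <- function(s_own, s_oth, m, g, mult) {
  n <- length(s_own)
  ps <- draw_partner_states(s_own, s_oth, rep(TRUE, n), m)
  prob <- ifelse(s_own,
                 ifelse(ps, g$delta_I, g$delta_S),
                 pmin(1, ifelse(ps, g$nu_I, g$nu_S) * mult))
  switch_state <- stats::runif(n) < prob
  xor(s_own, switch_state)
}

#' One synchronous update of the agent population
#'
#' Both groups are updated against the start-of-period states.  Uses the
#' current RNG stream; call [set.seed()] (or use [run_ensemble()]) for
#' reproducibility.
#'
#' @param states list with logical vectors `s1`, `s2` (infected
#'   indicators) and multiplier vectors `mult1`, `mult2`.
#' @param config a [sim_config()].
#' @return The updated `states` list.
#' @export
sim_step <- function(states, config) {
  p <- config$params
  if (inherits(p, "sis_params")) {
    n1 <- step_group_sis(states$s1, states$s2, p$p, config$m,
                         p$upsilon[1], p$delta[1], states$mult1)
    n2 <- step_group_sis(states$s2, states$s1, p$p, config$m,
                         p$upsilon[2], p$delta[2], states$mult2)
  } else {
    n1 <- step_group_general(states$s1, states$s2, config$m, p$group1,
                             states$mult1)
    n2 <- step_group_general(states$s2, states$s1, config$m, p$group2,
                             states$mult2)
  }
  states$s1 <- n1
  states$s2 <- n2
  states
}

init_states <- function(config) {
  k <- round(config$init * config$N)
  mult <- lapply(1:2, function(i) {
    h <- config$heterogeneity
    if (h$type == "lognormal" && h$sigma > 0)
      stats::rlnorm(config$N[i], meanlog = -h$sigma^2 / 2, sdlog = h$sigma)
    else rep(1, config$N[i])
  })
  list(s1 = seq_len(config$N[1]) <= k[1],
       s2 = seq_len(config$N[2]) <= k[2],
       mult1 = mult[[1]], mult2 = mult[[2]])
}

#' Run an ensemble of stochastic replicates
#'
#' Simulates `replicates` independent trajectories and summarizes the
#' infected fractions per period (mean and standard error across
#' replicates), plus quasi-stationary final-window averages computed over
#' the last 20% of periods, conditioning on non-extinct replicates
#' (extinct ones are flagged and reported separately, never reseeded).
#'
#' @param config a [sim_config()].
#' @param keep_trajectories keep the full per-replicate fraction
#'   trajectories in the result.
#' @return An object of class `sim_ensemble`: list with `summary` (data
#'   frame `t, rho1_mean, rho1_se, rho2_mean, rho2_se`), `final` (list
#'   with per-group window means `rho`, standard errors `se`, per-replicate
#'   window means, and `extinct` flags), `config`, and optionally
#'   `trajectories`.
#' @export
run_ensemble <- function(config, keep_trajectories = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  Tn <- config$periods
  R <- config$replicates
  R1 <- matrix(NA_real_, Tn + 1L, R)
  R2 <- matrix(NA_real_, Tn + 1L, R)
  for (r in seq_len(R)) {
    st <- init_states(config)
    R1[1L, r] <- mean(st$s1); R2[1L, r] <- mean(st$s2)
    for (t in seq_len(Tn)) {
      st <- sim_step(st, config)
      R1[t + 1L, r] <- mean(st$s1)
      R2[t + 1L, r] <- mean(st$s2)
    }
  }
  se <- function(M) apply(M, 1L, stats::sd) / sqrt(R)
  summary <- data.frame(t = 0:Tn,
                        rho1_mean = rowMeans(R1), rho1_se = se(R1),
                        rho2_mean = rowMeans(R2), rho2_se = se(R2))
  win <- (Tn + 1L - max(1L, floor(0.2 * Tn))):(Tn + 1L)
  w1 <- colMeans(R1[win, , drop = FALSE])
  w2 <- colMeans(R2[win, , drop = FALSE])
  extinct <- R1[Tn + 1L, ] + R2[Tn + 1L, ] == 0
  keep <- if (any(!extinct)) !extinct else rep(TRUE, R)
  final <- list(
    rho = c(mean(w1[keep]), mean(w2[keep])),
    se = c(stats::sd(w1[keep]), stats::sd(w2[keep])) / sqrt(sum(keep)),
    window_means = cbind(rho1 = w1, rho2 = w2),
    extinct = extinct)
  out <- list(summary = summary, final = final, config = config)
  if (keep_trajectories) out$trajectories <- list(rho1 = R1, rho2 = R2)
  structure(out, class = "sim_ensemble")
}

#' @export
print.sim_ensemble <- function(x, ...) {
  cat(sprintf("Stochastic ensemble: N = (%d, %d), %d periods, %d replicates\n",
              x$config$N[1], x$config$N[2], x$config$periods,
              x$config$replicates))
  cat(sprintf("  final-window means: rho = (%.4f, %.4f) +/- (%.4f, %.4f)\n",
              x$final$rho[1], x$final$rho[2], x$final$se[1], x$final$se[2]))
  if (any(x$final$extinct))
    cat(sprintf("  %d replicate(s) went extinct\n", sum(x$final$extinct)))
  invisible(x)
}

#' Expected-value (deterministic) update of the SIS process
#'
#' The zero-noise limit of one synchronous period: an explicit Euler step
#' of the mean-field equations with time step 1,
#' \eqn{\rho_i' = \rho_i + p\upsilon_i(1-\rho_i)(m\rho_j+(1-m)\rho_i) -
#' \delta_i\rho_i}.
#'
#' @param state infected fractions `(rho1, rho2)`.
#' @param params a [sis_params()].
#' @param m mixing level.
#' @return The updated fraction pair.
#' @export
meanfield_step <- function(state, params, m) {
  stopifnot(inherits(params, "sis_params"))
  state <- check_state(state)
  m <- check_m(m)
  mix <- m * rev(state) + (1 - m) * state
  state + params$p * params$upsilon * (1 - state) * mix -
    params$delta * state
}

#' Compare ensemble means with the mean dynamic
#'
#' Reports two deviations of the ensemble from its deterministic mean
#' dynamic: `max_deviation`, the distance of the final-window means from
#' the equilibrium, and `traj_deviation`, the largest distance between
#' the per-period ensemble mean trajectory and the deterministic
#' trajectory started from the same initial fractions (the synchronous
#' process's exact mean dynamic is the unit-step Euler map, see
#' [meanfield_step()]).  The trajectory deviation shrinks like
#' \eqn{1/\sqrt{N}} as populations grow.
#'
#' @param ensemble a [run_ensemble()] result.
#' @param rates [adoption_rates()] (or coercible) matching the simulated
#'   parameters; for the state-conditional variant pass the
#'   [general_model()].
#' @param m mixing level of the run.
#' @return A list of class `meanfield_comparison` with `equilibrium`,
#'   `final` (ensemble final-window means), per-group `deviation`,
#'   `max_deviation`, and `traj_deviation`.
#' @export
compare_to_meanfield <- function(ensemble, rates, m) {
  stopifnot(inherits(ensemble, "sim_ensemble"))
  eq <- if (inherits(rates, "general_model"))
    general_equilibrium(general_model(rates$group1, rates$group2, m))$state
  else solve_equilibrium(as_rates(rates), m)$state
  dev <- abs(ensemble$final$rho - eq)

  cfg <- ensemble$config
  state <- round(cfg$init * cfg$N) / cfg$N      # realized initial fractions
  n_t <- nrow(ensemble$summary)
  det <- matrix(NA_real_, n_t, 2L)
  det[1L, ] <- state
  for (t in seq_len(n_t - 1L)) {
    state <- if (inherits(cfg$params, "sis_params"))
      meanfield_step(state, cfg$params, cfg$m)
    else state + general_rhs(state, general_model(cfg$params$group1,
                                                  cfg$params$group2, cfg$m))
    det[t + 1L, ] <- state
  }
  traj_dev <- max(abs(cbind(ensemble$summary$rho1_mean,
                            ensemble$summary$rho2_mean) - det))
  structure(list(equilibrium = eq, final = ensemble$final$rho,
                 deviation = dev, max_deviation = max(dev),
                 traj_deviation = traj_dev,
                 N = ensemble$config$N),
            class = "meanfield_comparison")
}

#' @export
print.meanfield_comparison <- function(x, ...) {
  cat(sprintf("Mean-field comparison (N = %d, %d)\n", x$N[1], x$N[2]))
  cat(sprintf("  equilibrium (%.4f, %.4f) vs ensemble (%.4f, %.4f); max dev %.4g\n",
              x$equilibrium[1], x$equilibrium[2], x$final[1], x$final[2],
              x$max_deviation))
  cat(sprintf("  max trajectory deviation from the mean dynamic: %.4g\n",
              x$traj_deviation))
  invisible(x)
}
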