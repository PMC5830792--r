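# Parameterization of the two-type SIS model.
#
# The raw parameters are an interaction probability (or rate) p and
# per-group infection and recovery probabilities (or rates) upsilon_i,
# delta_i.  Equilibria and long-run dynamics depend on them only through
# the effective adoption rates lambda_i = p * upsilon_i / delta_i, so most
# functions in the package take an `adoption_rates` object.

#' Raw parameters of the two-type SIS model
#'
#' Bundles the per-period interaction probability `p` and the per-group
#' infection (`upsilon`) and recovery (`delta`) probabilities.  All three
#' may equivalently be read as continuous-time rates; only the composite
#' effective adoption rates \eqn{\lambda_i = p\,\upsilon_i/\delta_i} matter
#' for equilibria, so probabilities are accepted and used unchanged.
#'
#' @param p interaction probability per period, in (0, 1].
#' @param upsilon numeric length-2, per-contact infection probabilities for
#'   groups 1 and 2, each in (0, 1).
#' @param delta numeric length-2, recovery probabilities, each in (0, 1).
#' @return An object of class `sis_params`.
#' @seealso [effective_rates()] to reduce to the two effective adoption
#'   rates; [sim_config()] for the stochastic simulator, which uses the raw
#'   parameters directly.
#' @examples
#' sis_params(p = 1, upsilon = c(0.4, 0.5), delta = c(0.2, 0.1))
#' @export
sis_params <- function(p, upsilon, delta) {
  stopifnot(is.numeric(p), length(p) == 1L,
            is.numeric(upsilon), length(upsilon) == 2L,
            is.numeric(delta), length(delta) == 2L)
  if (!is.finite(p) || p <= 0 || p > 1)
    stop("`p` must lie in (0, 1]", call. = FALSE)
  if (any(!is.finite(upsilon)) || any(upsilon <= 0) || any(upsilon > 1))
    stop("`upsilon` components must lie in (0, 1]", call. = FALSE)
  if (any(!is.finite(delta)) || any(delta <= 0) || any(delta > 1))
    stop("`delta` components must lie in (0, 1]", call. = FALSE)
  structure(list(p = p, upsilon = upsilon, delta = delta),
            class = "sis_params")
}

#' Effective adoption rates of the two groups
#'
#' Constructs the pair \eqn{(\lambda_1, \lambda_2)} of dimensionless
#' effective adoption rates that, together with the mixing level m, fully
#' determine the mean-field dynamics.  Internally the pair is canonicalized
#' so that \eqn{\lambda_1 \le \lambda_2} (group 2 is the *sensitive* group,
#' group 1 the *resistant* one); the `swapped` flag records whether the
#' user-supplied order was reversed, and user-facing outputs undo the swap.
#'
#' @param lambda1,lambda2 positive effective adoption rates in user group
#'   order.
#' @return An object of class `adoption_rates` with elements `lambda1 <=
#'   lambda2` (canonical order) and logical `swapped`.
#' @examples
#' adoption_rates(0.55, 2)       # a resistant/sensitive pair
#' adoption_rates(2, 0.55)$swapped
#' @export
adoption_rates <- function(lambda1, lambda2) {
  stopifnot(is.numeric(lambda1), length(lambda1) == 1L,
            is.numeric(lambda2), length(lambda2) == 1L)
  if (!is.finite(lambda1) || !is.finite(lambda2) || lambda1 <= 0 || lambda2 <= 0)
    stop("effective adoption rates must be strictly positive", call. = FALSE)
  swapped <- lambda1 > lambda2
  if (swapped) { tmp <- lambda1; lambda1 <- lambda2; lambda2 <- tmp }
  structure(list(lambda1 = lambda1, lambda2 = lambda2, swapped = swapped),
            class = "adoption_rates")
}

#' Reduce raw SIS parameters to effective adoption rates
#'
#' Computes \eqn{\lambda_i = p\,\upsilon_i/\delta_i} componentwise and
#' canonicalizes the pair (see [adoption_rates()]).
#'
#' @param params a [sis_params()] object.
#' @return An `adoption_rates` object.
#' @examples
#' effective_rates(sis_params(1, c(0.5, 0.5), c(0.25, 0.5)))  # (2, 1)
#' @export
effective_rates <- function(params) {
  stopifnot(inherits(params, "sis_params"))
  adoption_rates(params$p * params$upsilon[1] / params$delta[1],
                 params$p * params$upsilon[2] / params$delta[2])
}

# lambda pair in the order the user supplied the groups
user_lambda <- function(rates) {
  l <- c(rates$lambda1, rates$lambda2)
  if (isTRUE(rates$swapped)) rev(l) else l
}

# undo canonical orientation on a length-2 per-group vector
unswap <- function(rates, x) if (isTRUE(rates$swapped)) x[c(2L, 1L)] else x

as_rates <- function(x) {
  if (inherits(x, "adoption_rates")) return(x)
  if (inherits(x, "sis_params")) return(effective_rates(x))
  if (is.numeric(x) && length(x) == 2L) return(adoption_rates(x[1], x[2]))
  stop("cannot interpret `rates`; supply adoption_rates(), sis_params() or a length-2 numeric",
       call. = FALSE)
}

check_m <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 0 || m > 1)
    stop("mixing level `m` must be a single number in [0, 1]", call. = FALSE)
  m
}

check_state <- function(state, tol = 1e-8) {
  if (!is.numeric(state) || length(state) != 2L || any(!is.finite(state)))
    stop("`state` must be a finite numeric vector (rho1, rho2)", call. = FALSE)
  if (any(state < -tol) || any(state > 1 + tol))
    stop("`state` components must lie in [0, 1]", call. = FALSE)
  pmin(pmax(state, 0), 1)
}

#' @export
print.sis_params <- function(x, ...) {
  cat("Two-type SIS parameters\n")
  cat(sprintf("  p = %g; upsilon = (%g, %g); delta = (%g, %g)\n",
              x$p, x$upsilon[1], x$upsilon[2], x$delta[1], x$delta[2]))
  l <- user_lambda(effective_rates(x))
  cat(sprintf("  effective adoption rates: lambda = (%g, %g)\n", l[1], l[2]))
  invisible(x)
}

#' @export
print.adoption_rates <- function(x, ...) {
  l <- user_lambda(x)
  cat(sprintf("Effective adoption rates: lambda1 = %g, lambda2 = %g%s\n",
              l[1], l[2],
              if (isTRUE(x$swapped)) "  (canonical order swaps groups)" else ""))
  invisible(x)
}
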