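# Qualitative regimes of the effective-adoption-rate plane.
#
# The (lambda1, lambda2) plane (canonical lambda1 <= lambda2) splits into
# five regions by how the equilibrium infection levels respond to mixing:
#   A: lambda2 <= 1 -- no diffusion for any m.
#   B: lambda1*lambda2 <= 1 -- endemic only below mbar; average decreasing.
#   E: lambda1^(3/4)(lambda2+1) >= lambda2^(3/4)(lambda1+1) -- all three
#      curves monotone (average increasing).
#   C: resistant-group level non-monotonic in m (interior maximum).
#   D: otherwise (resistant level increasing, average interior maximum).
# The closed-form C/D boundary candidate lambda1 = sqrt(lambda2) /
# (lambda2 - sqrt(lambda2) + 1) is used as a cross-check; the numeric
# monotonicity scan is authoritative.

#' Classify effective adoption rates into qualitative regions
#'
#' Assigns one of the labels A-E by the precedence A, B, E, then C/D via
#' a numeric monotonicity scan of the resistant group's equilibrium curve.
#' Inequalities within `tol` of equality are recorded in `boundary_flags`
#' (the label is still assigned deterministically by precedence).
#'
#' @inheritParams sis_rhs
#' @param m_grid mixing grid used for the C/D monotonicity scan.
#' @param tol boundary-tie tolerance on the defining inequalities.
#' @return An object of class `region_label`: list with `label`,
#'   `boundary_flags` (named logical), `mbar` (`NA` unless defined),
#'   `closed_form_label` (C/D candidate from the closed-form boundary,
#'   `NA` for A/B/E) and `scan_pattern`.
#' @examples
#' classify_region(adoption_rates(0.25, 2))$label  # "B"
#' classify_region(adoption_rates(2, 5))$label     # "E"
#' @export
classify_region <- function(rates, m_grid = seq(0, 1, length.out = 201L),
                            tol = 1e-9) {
  rates <- as_rates(rates)
  l1 <- rates$lambda1; l2 <- rates$lambda2
  prod <- l1 * l2
  e_gap <- l1^0.75 * (l2 + 1) - l2^0.75 * (l1 + 1)
  cd_gap <- l1 - sqrt(l2) / (l2 - sqrt(l2) + 1)
  flags <- c(lambda2_eq_1 = abs(l2 - 1) <= tol,
             product_eq_1 = abs(prod - 1) <= tol,
             e_boundary = abs(e_gap) <= tol,
             cd_boundary = abs(cd_gap) <= tol)
  closed_form <- NA_character_
  pattern <- NA_character_
  if (l2 <= 1 + tol) {
    label <- "A"
  } else if (prod <= 1 + tol) {
    label <- "B"
  } else if (e_gap >= -tol) {
    label <- "E"
  } else {
    closed_form <- if (cd_gap < 0) "C" else "D"
    curve <- equilibrium_curve(rates, m_grid)
    verdict <- detect_monotonicity(curve_resistant(curve), curve$m)
    pattern <- verdict$pattern
    label <- if (pattern %in% c("interior_max", "interior_min")) "C" else "D"
  }
  structure(list(label = label, boundary_flags = flags,
                 mbar = mbar_canonical(l1, l2),
                 closed_form_label = closed_form,
                 scan_pattern = pattern,
                 lambda = user_lambda(rates)),
            class = "region_label")
}

#' @export
print.region_label <- function(x, ...) {
  cat(sprintf("Region %s for lambda = (%g, %g)\n",
              x$label, x$lambda[1], x$lambda[2]))
  if (any(x$boundary_flags))
    cat("  near boundary:", names(which(x$boundary_flags)), "\n")
  if (!is.na(x$mbar)) cat(sprintf("  mbar = %.6f\n", x$mbar))
  invisible(x)
}

#' Monotonicity pattern of a curve over the mixing grid
#'
#' Classifies a tabulated curve as increasing, decreasing, constant, or
#' possessing an interior maximum/minimum, from the sign sequence of
#' finite differences with magnitude filter `tol`.  An interior extremum
#' location is refined by a parabolic pass through the three surrounding
#' grid points.
#'
#' @param values curve values on the grid.
#' @param m_grid grid locations (defaults to an index grid).
#' @param tol differences with absolute value below `tol` count as flat.
#' @return A list of class `monotonicity_verdict`: `pattern` in
#'   `{increasing, decreasing, interior_max, interior_min, constant}`,
#'   and `argmax`/`argmin` (grid location, refined) when interior.
#' @examples
#' detect_monotonicity(c(0, 1, 0.5), c(0, 0.5, 1))$pattern  # interior_max
#' @export
detect_monotonicity <- function(values, m_grid = NULL, tol = 1e-7) {
  stopifnot(is.numeric(values), length(values) >= 3L)
  if (is.null(m_grid)) m_grid <- seq_along(values)
  stopifnot(length(m_grid) == length(values))
  d <- diff(values)
  s <- sign(d) * (abs(d) > tol)
  cs <- rle(s[s != 0])$values
  pattern <- if (length(cs) == 0L) "constant"
  else if (all(cs == 1)) "increasing"
  else if (all(cs == -1)) "decreasing"
  else if (cs[1] == 1 && cs[length(cs)] == -1) "interior_max"
  else if (cs[1] == -1 && cs[length(cs)] == 1) "interior_min"
  else {
    # mixed pattern beyond tolerance: fall back on the global extremum
    i_max <- which.max(values); i_min <- which.min(values)
    if (i_max > 1L && i_max < length(values)) "interior_max"
    else if (i_min > 1L && i_min < length(values)) "interior_min"
    else if (values[length(values)] >= values[1L]) "increasing" else "decreasing"
  }
  argmax <- argmin <- NA_real_
  if (pattern == "interior_max")
    argmax <- refine_extremum(m_grid, values, which.max(values))
  if (pattern == "interior_min")
    argmin <- refine_extremum(m_grid, values, which.min(values))
  structure(list(pattern = pattern, argmax = argmax, argmin = argmin),
            class = "monotonicity_verdict")
}

# parabolic vertex through the three points around index i
refine_extremum <- function(m, v, i) {
  if (i <= 1L || i >= length(v)) return(m[i])
  x1 <- m[i - 1L]; x2 <- m[i]; x3 <- m[i + 1L]
  y1 <- v[i - 1L]; y2 <- v[i]; y3 <- v[i + 1L]
  den <- (x2 - x1) * (y2 - y3) - (x2 - x3) * (y2 - y1)
  if (abs(den) < 1e-300) return(x2)
  vert <- x2 - 0.5 * ((x2 - x1)^2 * (y2 - y3) - (x2 - x3)^2 * (y2 - y1)) / den
  if (vert > x1 && vert < x3) vert else x2
}

#' Pareto-inefficient mixing levels
#'
#' A grid point m is Pareto-dominated if some other grid point m' gives a
#' weakly better equilibrium level for both groups and a strictly better
#' one (beyond `tol`) for at least one, where "better" is lower when the
#' trait is undesirable (infection) and higher when desirable.
#' Contiguous dominated points are merged into intervals, each carrying a
#' witness m' that dominates every point of the interval.
#'
#' @param curve an [equilibrium_curve()] (or [general_curve()]) result.
#' @param orientation `"undesirable"` (default; lower infection is
#'   better) or `"desirable"`.
#' @param tol strict-improvement tolerance.
#' @return A list of class `pareto_report`: `orientation`, `dominated`
#'   (logical per grid point), and `intervals` (data frame `m_lo`,
#'   `m_hi`, `witness_m`).
#' @examples
#' cv <- equilibrium_curve(adoption_rates(0.3, 4), seq(0, 1, by = 0.01))
#' pareto_inefficient_set(cv)$intervals
#' @export
pareto_inefficient_set <- function(curve,
                                   orientation = c("undesirable", "desirable"),
                                   tol = 1e-9) {
  orientation <- match.arg(orientation)
  sgn <- if (orientation == "undesirable") -1 else 1
  b1 <- sgn * curve$rho1
  b2 <- sgn * curve$rho2
  n <- length(b1)
  dominated <- logical(n)
  dominators <- vector("list", n)
  if (n >= 2L) {
    for (i in seq_len(n)) {
      dom <- b1 >= b1[i] - tol & b2 >= b2[i] - tol &
        (b1 > b1[i] + tol | b2 > b2[i] + tol)
      dominated[i] <- any(dom)
      dominators[[i]] <- dom
    }
  }
  # merge contiguous dominated points while a common dominator remains
  intervals <- NULL
  idx <- which(dominated)
  if (length(idx)) {
    start <- idx[1]; common <- dominators[[idx[1]]]; prev <- idx[1]
    flush <- function(lo, hi, common) {
      j <- which(common)
      # witness: the dominator with the largest worst-case improvement
      gain <- pmin(b1[j] - max(b1[lo:hi]), b2[j] - max(b2[lo:hi]))
      best <- j[which.max(gain)]
      data.frame(m_lo = curve$m[lo], m_hi = curve$m[hi],
                 witness_m = curve$m[best[1]])
    }
    for (k in idx[-1]) {
      joint <- common & dominators[[k]]
      if (k == prev + 1L && any(joint)) {
        common <- joint; prev <- k
      } else {
        intervals <- rbind(intervals, flush(start, prev, common))
        start <- k; common <- dominators[[k]]; prev <- k
      }
    }
    intervals <- rbind(intervals, flush(start, prev, common))
  } else {
    intervals <- data.frame(m_lo = numeric(0), m_hi = numeric(0),
                            witness_m = numeric(0))
  }
  structure(list(orientation = orientation, dominated = dominated,
                 m_grid = curve$m, intervals = intervals),
            class = "pareto_report")
}

#' @export
print.pareto_report <- function(x, ...) {
  cat(sprintf("Pareto analysis (trait %s): %d of %d grid points dominated\n",
              x$orientation, sum(x$dominated), length(x$dominated)))
  if (nrow(x$intervals)) print(x$intervals) else cat("  no inefficient mixing levels\n")
  invisible(x)
}

#' Optimal mixing level for a stated objective
#'
#' Grid argmin/argmax over an equilibrium curve with local parabolic
#' refinement for interior optima; ties resolved to the smallest m.
#' Objectives: minimize or maximize the average level, or minimize the
#' between-group gap `|diff|` (always attained at the bipartite extreme
#' m = 1 when the groups differ).
#'
#' @param curve an [equilibrium_curve()] (or [general_curve()]) result.
#' @param objective one of `"min_avg"`, `"max_avg"`, `"min_diff"`.
#' @return List with `m` (the optimizer), `value`, and `objective`.
#' @examples
#' cv <- equilibrium_curve(adoption_rates(2, 5), seq(0, 1, by = 0.01))
#' optimal_mixing(cv, "max_avg")$m  # 1
#' @export
optimal_mixing <- function(curve, objective = c("min_avg", "max_avg", "min_diff")) {
  objective <- match.arg(objective)
  v <- switch(objective,
              min_avg = curve$avg, max_avg = -curve$avg,
              min_diff = abs(curve$diff))
  i <- which(v <= min(v) + 1e-15)[1]        # smallest m on ties
  strict <- i > 1L && i < length(v) &&
    v[i - 1L] > v[i] + 1e-12 && v[i + 1L] > v[i] + 1e-12
  m_star <- if (strict) refine_extremum(curve$m, -v, i) else curve$m[i]
  value <- switch(objective, max_avg = curve$avg[i], min_avg = curve$avg[i],
                  min_diff = abs(curve$diff[i]))
  list(m = m_star, value = value, objective = objective)
}
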