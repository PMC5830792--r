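# Configuration files and tabular serialization.
#
# Run configurations are YAML or JSON.  Recognized keys:
#   model: "sis" | "general"
#   lambda1, lambda2            -- effective adoption rates, or
#   p, upsilon, delta           -- raw SIS parameters (upsilon/delta length 2)
#   general: list(group1 = list(nu_S, nu_I, delta_I, delta_S), group2 = ...)
#   units: "fraction" | "percent"   (general model rates)
#   m                           -- single mixing level, or
#   m_grid: list(from, to, points) or a numeric vector
#   N, periods, replicates, init, heterogeneity   -- simulator settings
#   seed, tol, out
# Unknown keys are rejected before any computation.

CONFIG_KEYS <- c("model", "lambda1", "lambda2", "p", "upsilon", "delta",
                 "general", "units", "m", "m_grid", "N", "periods",
                 "replicates", "init", "heterogeneity", "seed", "tol", "out")

#' Read and validate a run configuration
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A validated list of class `run_config` whose `rates`, `model`
#'   (general variant), `m`/`m_grid` and simulator fields are parsed into
#'   package objects.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("config must be .yaml, .yml or .json", call. = FALSE))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  unknown <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  model <- cfg$model %||% "sis"
  if (!model %in% c("sis", "general"))
    stop("`model` must be \"sis\" or \"general\"", call. = FALSE)
  out <- list(model = model, seed = cfg$seed %||% 1L,
              tol = cfg$tol %||% 1e-10, out = cfg$out)
  if (model == "sis") {
    if (!is.null(cfg$lambda1) || !is.null(cfg$lambda2)) {
      if (is.null(cfg$lambda1) || is.null(cfg$lambda2))
        stop("both `lambda1` and `lambda2` are required", call. = FALSE)
      out$rates <- adoption_rates(cfg$lambda1, cfg$lambda2)
    }
    if (!is.null(cfg$p)) {
      out$params <- sis_params(cfg$p, unlist(cfg$upsilon), unlist(cfg$delta))
      out$rates <- out$rates %||% effective_rates(out$params)
    }
    if (is.null(out$rates))
      stop("SIS config needs `lambda1`/`lambda2` or `p`/`upsilon`/`delta`",
           call. = FALSE)
  } else {
    if (is.null(cfg$general) || is.null(cfg$general$group1) ||
        is.null(cfg$general$group2))
      stop("general config needs `general: {group1: ..., group2: ...}`",
           call. = FALSE)
    units <- cfg$units %||% "fraction"
    mk <- function(g) do.call(conditional_rates,
                              c(g[c("nu_S", "nu_I", "delta_I", "delta_S")],
                                list(units = units)))
    out$group1 <- mk(cfg$general$group1)
    out$group2 <- mk(cfg$general$group2)
  }
  if (!is.null(cfg[["m"]])) out$m <- check_m(cfg[["m"]])
  if (!is.null(cfg[["m_grid"]])) {
    g <- cfg[["m_grid"]]
    out$m_grid <- if (is.list(g))
      seq(g[["from"]] %||% 0, g[["to"]] %||% 1,
          length.out = g[["points"]] %||% 201L)
    else as.numeric(g)
  }
  for (k in c("N", "periods", "replicates", "init", "heterogeneity"))
    if (!is.null(cfg[[k]])) out[[k]] <- cfg[[k]]
  structure(out, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt12 <- function(x) {
  if (is.numeric(x)) sprintf("%.12g", x) else as.character(x)
}

#' Write an equilibrium curve as CSV
#'
#' Comma-separated, header row, `.` decimal, LF line endings, floats with
#' 12 significant digits; columns `m, rho1, rho2, avg, diff, positive`.
#'
#' @param curve an [equilibrium_curve()] or [general_curve()] result.
#' @param path output file (or `""` for stdout).
#' @export
write_curve_csv <- function(curve, path) {
  df <- as.data.frame(lapply(curve, fmt12), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Read back an equilibrium-curve CSV
#'
#' @param path file written by [write_curve_csv()].
#' @return A data frame of class `equilibrium_curve`.
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(identical(names(df),
                      c("m", "rho1", "rho2", "avg", "diff", "positive")))
  df$positive <- as.logical(df$positive)
  class(df) <- c("equilibrium_curve", "data.frame")
  df
}

#' Write a trajectory (deterministic or per-replicate) as CSV
#'
#' @param traj data frame with a `t` column plus `rho1`, `rho2` (and
#'   optionally `replicate`).
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(lapply(as.data.frame(traj), fmt12),
                      stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' JSON report for an equilibrium result
#'
#' @param eq an `equilibrium_result` (see [solve_equilibrium()]).
#' @param path optional output file; with `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to file.
#' @export
equilibrium_report_json <- function(eq, path = NULL) {
  stopifnot(inherits(eq, "equilibrium_result"))
  rep <- list(state = eq$state, positive = eq$positive,
              residual = eq$residual, stable = eq$stable)
  if (!is.na(eq$mbar)) rep$mbar <- eq$mbar
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
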