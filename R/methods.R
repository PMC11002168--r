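#' @export
print.ifn_fit <- function(x, ...) {
  cat("Responder-model fit over", length(x$conditions), "condition(s):",
      paste(x$conditions, collapse = ", "), "\n")
  cat("Weighted least-squares objective:", format(x$objective, digits = 6), "\n")
  if (length(x$estimates)) {
    cat("Estimated entries:\n")
    print(signif(x$estimates, 5))
  } else cat("No free parameters (evaluation-only fit).\n")
  invisible(x)
}

#' @export
summary.ifn_fit <- function(object, ...) {
  d <- object$diagnostics
  structure(list(
    conditions = object$conditions,
    estimates = object$estimates,
    parameters = object$parameters,
    objective = object$objective,
    n_starts = nrow(d$starts),
    best_start = d$best_start,
    converged = d$converged,
    weighting = object$args$weighting,
    scales = object$scales
  ), class = "summary.ifn_fit")
}

#' @export
print.summary.ifn_fit <- function(x, ...) {
  cat("Responder-model fit\n")
  cat("  conditions :", paste(x$conditions, collapse = ", "), "\n")
  cat("  objective  :", format(x$objective, digits = 6),
      sprintf("(weighting: %s)\n", x$weighting))
  cat("  multistart :", x$n_starts, "starts, best =", x$best_start,
      if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  if (length(x$estimates)) {
    cat("  estimates  :\n")
    print(signif(x$estimates, 5))
  }
  cat("  resolved parameters per condition:\n")
  print(coef_matrix(x$parameters))
  invisible(x)
}

coef_matrix <- function(parameters) {
  m <- vapply(parameters, function(p) unlist(p[.par_names]),
              numeric(length(.par_names)))
  rownames(m) <- .par_names
  m
}

#' @export
coef.ifn_fit <- function(object, ...) coef_matrix(object$parameters)

#' Model predictions from a fit
#'
#' Deterministic model trajectories at the fitted parameters.
#'
#' @param object an `"ifn_fit"`.
#' @param times reporting grid (hours, starting at 0); default: the
#'   observed time points of each condition.
#' @param conditions subset of condition labels; default all.
#' @param ... unused.
#' @return `data.frame` with columns `condition`, `time_h`, `pct_model`,
#'   `ifn_model`.
#' @export
predict.ifn_fit <- function(object, times = NULL, conditions = NULL, ...) {
  conds <- conditions %||% object$conditions
  if (is.null(times)) {
    out <- object$fitted
    return(out[out$condition %in% conds, , drop = FALSE])
  }
  out <- NULL
  for (cond in conds) {
    traj <- simulate_ifn(object$parameters[[cond]], times,
                         rtol = object$args$rtol, atol = object$args$atol)
    out <- rbind(out, data.frame(condition = cond, time_h = traj$time_h,
                                 pct_model = traj$percent_positive,
                                 ifn_model = traj$ifn_pg_ml))
  }
  out
}

#' @export
residuals.ifn_fit <- function(object, ...) object$residuals

#' Overlay fitted curves on the observations
#'
#' Two base-graphics panels: percent IFN-alpha-positive cells and
#' supernatant concentration versus time, observed points with fitted
#' model curves per condition.
#'
#' @param x an `"ifn_fit"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ifn_fit <- function(x, ...) {
  conds <- x$conditions
  cols <- seq_along(conds)
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  dense <- seq(0, max(x$observations$time_h), length.out = 131L)
  pred <- predict(x, times = dense)
  for (what in c("pct", "ifn")) {
    obs_col <- if (what == "pct") "pct_pos" else "ifn_pg_ml"
    mod_col <- if (what == "pct") "pct_model" else "ifn_model"
    ylab <- if (what == "pct") "% IFNα-positive cells" else
      "IFNα (pg/mL)"
    ylim <- range(0, x$observations[[obs_col]], pred[[mod_col]])
    plot(NA, xlim = range(dense), ylim = ylim, xlab = "time (h)", ylab = ylab)
    for (i in seq_along(conds)) {
      o <- x$observations[x$observations$condition == conds[i], ]
      p <- pred[pred$condition == conds[i], ]
      points(o$time_h, o[[obs_col]], col = cols[i], pch = 16, cex = 0.7)
      lines(p$time_h, p[[mod_col]], col = cols[i])
    }
    if (what == "pct")
      legend("topleft", legend = conds, col = cols, lty = 1, bty = "n",
             cex = 0.8)
  }
  invisible(x)
}

#' Simulate synthetic datasets at the fitted parameters
#'
#' Draws `nsim` synthetic datasets (see [generate_dataset()]) from the
#' fitted parameter sets, e.g. for posterior-predictive-style checks of
#' the noise model.
#'
#' @param object an `"ifn_fit"`.
#' @param nsim number of datasets.
#' @param seed base RNG seed (dataset `i` uses `seed + i - 1`).
#' @param noise a [noise_model()].
#' @param t_grid reporting grid in hours.
#' @param ... unused.
#' @return A list of `nsim` `"ifn_dataset"` objects.
#' @export
simulate.ifn_fit <- function(object, nsim = 1, seed = 1L,
                             noise = noise_model(), t_grid = 0:26, ...) {
  lapply(seq_len(nsim), function(i)
    generate_dataset(object$parameters, t_grid = t_grid, noise = noise,
                     seed = seed + i - 1L))
}
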