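#' Compare a nested family of fit constraint structures by parsimony
#'
#' Ranks fits of increasingly permissive constraint structures (each
#' member frees a superset of the previous member's condition-specific
#' parameters) by objective versus the number of condition-specific
#' parameters, and flags the smallest structure whose objective is within
#' `factor` of the fully-free member's.
#'
#' @param fits a (preferably named) list of `"ifn_fit"` objects on the
#'   same observations, forming a nested family.
#' @param factor slack multiplier on the fully-free objective
#'   (default 1.05).
#' @return A `data.frame` of class `"ifn_parsimony"` with one row per
#'   member: `label`, `n_condition_specific`, `n_estimated`, `objective`,
#'   `ratio_to_full`, `selected`.
#' @export
parsimony_compare <- function(fits, factor = 1.05) {
  if (!is.list(fits) || !length(fits) ||
      !all(vapply(fits, inherits, logical(1L), "ifn_fit")))
    stop("fits must be a non-empty list of ifn_fit objects", call. = FALSE)
  labels <- names(fits) %||% paste0("spec", seq_along(fits))
  labels[labels == ""] <- paste0("spec", which(labels == ""))
  free_sets <- lapply(fits, function(f) f$layout$free_pars)
  est_sets <- lapply(fits, function(f) f$layout$est_pars)
  n_cs <- lengths(free_sets)
  n_est <- vapply(fits, function(f) nrow(f$layout$entries), integer(1L))
  ord <- order(n_cs, n_est)
  if (length(fits) > 1L) {
    for (i in seq_len(length(fits) - 1L)) {
      a <- ord[i]; b <- ord[i + 1L]
      if (!all(free_sets[[a]] %in% free_sets[[b]]) ||
          !all(est_sets[[a]] %in% est_sets[[b]]))
        stop("fit family is not nested: '", labels[a],
             "' is not contained in '", labels[b], "'", call. = FALSE)
    }
  }
  obj <- vapply(fits, `[[`, numeric(1L), "objective")
  full <- ord[length(ord)]
  within <- obj <= factor * obj[full]
  sel_pos <- which(within[ord])[1L]
  selected <- seq_along(fits) == ord[sel_pos]
  out <- data.frame(label = labels, n_condition_specific = as.integer(n_cs),
                    n_estimated = n_est, objective = obj,
                    ratio_to_full = obj / obj[full], selected = selected)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ifn_parsimony", "data.frame"), factor = factor)
}

#' @export
print.ifn_parsimony <- function(x, ...) {
  cat("Parsimony comparison (slack factor ", attr(x, "factor"), "):\n",
      sep = "")
  print.data.frame(x, digits = 6)
  cat("Selected:", x$label[x$selected], "\n")
  invisible(x)
}

#' Profile the objective along one parameter
#'
#' Identifiability diagnostic: for each grid value the parameter is held
#' fixed there (in all conditions, or in one condition for a
#' condition-specific parameter) and all remaining free parameters are
#' re-optimized. A well-identified parameter yields a profile minimized
#' at (within tolerance of) its fitted value and rising monotonically
#' away from it.
#'
#' @param fit an `"ifn_fit"` whose configuration is reused for the
#'   re-fits.
#' @param param parameter name; must be estimated (not fixed) in `fit`.
#' @param grid non-empty numeric vector of values to profile over.
#' @param condition for a condition-specific parameter, the condition
#'   whose value is profiled (others stay free). Default: the parameter
#'   is pinned in every condition.
#' @param n_starts multistart count for the re-fits (default: as in
#'   `fit`).
#' @return `data.frame` of class `"ifn_profile"` with columns `value`,
#'   `objective`; attributes `param`, `fit_objective` and (when
#'   available) `fit_value`.
#' @export
profile_parameter <- function(fit, param, grid, condition = NULL,
                              n_starts = NULL) {
  stopifnot(inherits(fit, "ifn_fit"))
  if (!param %in% .par_names)
    stop("unknown parameter: ", param, call. = FALSE)
  if (!is.numeric(grid) || !length(grid) || any(!is.finite(grid)))
    stop("grid must be a non-empty finite numeric vector", call. = FALSE)
  m <- fit$layout$map
  est_rows <- m$par == param & !is.na(m$key)
  if (!any(est_rows))
    stop("parameter '", param, "' is fixed in this fit and cannot be profiled",
         call. = FALSE)
  conds <- fit$conditions
  target <- if (is.null(condition)) m$cond[est_rows] else condition
  if (!all(target %in% conds)) stop("unknown condition", call. = FALSE)

  roles2 <- fit$args$roles
  role_vec <- vapply(conds, function(cd) .role_for(roles2, param, cd),
                     character(1L))
  names(role_vec) <- conds
  role_vec[target] <- "fixed"
  roles2[[param]] <- role_vec

  fixed_pc <- .normalize_fixed(fit$args$fixed, conds)
  obj <- numeric(length(grid))
  for (i in seq_along(grid)) {
    f2 <- fixed_pc
    for (cd in target) f2[[cd]][[param]] <- grid[i]
    refit <- ifn_fit(fit$observations, roles = roles2, fixed = f2,
                     bounds = fit$args$bounds,
                     n_starts = n_starts %||% fit$args$n_starts,
                     seed = fit$args$seed, weighting = fit$args$weighting,
                     loq = fit$args$loq, rtol = fit$args$rtol,
                     atol = fit$args$atol)
    obj[i] <- refit$objective
  }
  fit_value <- if (length(target) == 1L)
    fit$parameters[[target]][[param]]
  else if (length(unique(vapply(fit$parameters[target], `[[`, numeric(1L), param))) == 1L)
    fit$parameters[[target[1L]]][[param]]
  else NA_real_
  structure(data.frame(value = grid, objective = obj),
            class = c("ifn_profile", "data.frame"),
            param = param, fit_objective = fit$objective,
            fit_value = fit_value)
}

#' @export
print.ifn_profile <- function(x, ...) {
  cat("Objective profile for '", attr(x, "param"), "' (fit objective ",
      format(attr(x, "fit_objective"), digits = 6), "):\n", sep = "")
  print.data.frame(x, digits = 6)
  invisible(x)
}
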