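#' Default parameter bounds for fitting
#'
#' Generous log-scale envelopes around the biologically plausible range of
#' each parameter; optimization is performed in log-space within these.
#' Individual bounds can be overridden by name, e.g.
#' `ifn_bounds(T = c(1, 1e4))`.
#'
#' @param ... named length-2 numeric vectors `c(lower, upper)` replacing
#'   the default bound for that parameter.
#' @return Named list of `c(lower, upper)` per parameter.
#' @export
ifn_bounds <- function(...) {
  b <- list(fr = c(1e-4, 0.5), sr = c(1e-3, 0.99),
            kon = c(1e-3, 1e2), koff = c(1e-3, 1e2),
            kf = c(1, 1e6), df = c(1e-4, 10),
            T = c(1e-1, 1e5), H = c(1, 8))
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), .par_names)
    if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    b[names(dots)] <- dots
  }
  for (nm in names(b)) {
    v <- b[[nm]]
    if (length(v) != 2L || !all(is.finite(v)) || v[1L] <= 0 || v[1L] >= v[2L])
      stop("bound for '", nm, "' must be 0 < lower < upper", call. = FALSE)
  }
  b
}

# ---- role map / layout ------------------------------------------------------
#
# Roles declare, per parameter, how it enters a (multi-condition) fit:
#   "fixed"  -- held at the value supplied in `fixed` (default role)
#   "free"   -- one estimated value per condition
#   "shared" -- one estimated value common to all conditions
#   any other string -- a share-group id; conditions mapped to the same id
#                       share one estimated value
# A role may be a single string (applied to all conditions) or a character
# vector named by condition mixing the above.

.role_for <- function(roles, par, cond) {
  r <- roles[[par]]
  if (is.null(r)) return("fixed")
  if (length(r) == 1L && is.null(names(r))) return(unname(r))
  if (!cond %in% names(r))
    stop("role for parameter '", par, "' does not cover condition '", cond, "'",
         call. = FALSE)
  unname(r[[cond]])
}

# normalize `fixed` to one named value-list per condition, with the
# default fractions merged in
.normalize_fixed <- function(fixed, conds) {
  defaults <- list(fr = 0.01, sr = 0.5)
  fixed <- fixed %||% list()
  per_cond <- length(fixed) > 0L && all(names(fixed) %in% conds) &&
    all(vapply(fixed, is.list, logical(1L)))
  out <- list()
  for (cond in conds) {
    out[[cond]] <- if (per_cond)
      modifyList(defaults, fixed[[cond]] %||% list())
    else modifyList(defaults, fixed)
  }
  out
}

.build_layout <- function(roles, conds, fixed, bounds) {
  bad <- setdiff(names(roles), .par_names)
  if (length(bad))
    stop("unknown parameters in roles: ", paste(bad, collapse = ", "),
         call. = FALSE)
  fixed <- .normalize_fixed(fixed, conds)
  map <- NULL
  for (par in .par_names) {
    for (cond in conds) {
      role <- .role_for(roles, par, cond)
      if (identical(role, "fixed")) {
        val <- fixed[[cond]][[par]]
        if (is.null(val))
          stop("no fixed value supplied for parameter '", par,
               "' in condition '", cond, "'", call. = FALSE)
        map <- rbind(map, data.frame(par = par, cond = cond, key = NA_character_,
                                     fixed = as.numeric(val)))
      } else {
        group <- switch(role, free = paste0("c:", cond), shared = "all", role)
        map <- rbind(map, data.frame(par = par, cond = cond,
                                     key = paste0(par, "|", group),
                                     fixed = NA_real_))
      }
    }
  }
  keys <- unique(map$key[!is.na(map$key)])
  entries <- data.frame(
    key = keys,
    par = vapply(strsplit(keys, "|", fixed = TRUE), `[[`, character(1L), 1L)
  )
  entries$lower <- vapply(entries$par, function(p) bounds[[p]][1L], numeric(1L))
  entries$upper <- vapply(entries$par, function(p) bounds[[p]][2L], numeric(1L))
  cs <- unique(map$par[!is.na(map$key) & grepl("\\|c:", map$key)])
  est <- unique(entries$par)
  list(map = map, entries = entries, conds = conds,
       free_pars = cs, est_pars = est)
}

# resolve a named natural-scale estimate vector (by key) into one
# parameter set per condition
.resolve_params <- function(layout, theta, check = FALSE) {
  out <- list()
  for (cond in layout$conds) {
    m <- layout$map[layout$map$cond == cond, ]
    vals <- ifelse(is.na(m$key), m$fixed, theta[m$key])
    names(vals) <- m$par
    out[[cond]] <- .params_unchecked(vals)
    if (check) .validate_params(out[[cond]])
  }
  out
}

# ---- objective --------------------------------------------------------------

.obs_scales <- function(obs, weighting) {
  if (identical(weighting, "none")) return(list(pct = 1, ifn = 1))
  if (!identical(weighting, "max_observed"))
    stop("unknown weighting scheme: ", weighting, call. = FALSE)
  s_pct <- max(obs$pct_pos, 0)
  s_ifn <- max(obs$ifn_pg_ml, 0)
  list(pct = if (s_pct > 0) s_pct else 1,
       ifn = if (s_ifn > 0) s_ifn else 1)
}

# weighted residual vector across conditions and both observables;
# censored concentration points get the one-sided penalty max(0, model - LOQ)
.fit_residuals <- function(params_by_condition, obs, scales, loq,
                           rtol = 1e-8, atol = 1e-10) {
  res <- NULL
  for (cond in names(params_by_condition)) {
    o <- obs[obs$condition == cond, , drop = FALSE]
    tg <- o$time_h
    sim_t <- if (tg[1L] > 0) c(0, tg) else tg
    traj <- simulate_ifn(params_by_condition[[cond]], sim_t,
                         rtol = rtol, atol = atol)
    idx <- match(tg, traj$time_h)
    m_pct <- traj$percent_positive[idx]
    m_ifn <- traj$ifn_pg_ml[idx]
    r_pct <- (m_pct - o$pct_pos) / scales$pct
    r_ifn <- (m_ifn - o$ifn_pg_ml) / scales$ifn
    cens <- o$below_loq == 1L
    r_ifn[cens] <- pmax(0, m_ifn[cens] - loq) / scales$ifn
    res <- rbind(res, data.frame(condition = cond, time_h = tg,
                                 pct_resid = r_pct, ifn_resid = r_ifn,
                                 pct_model = m_pct, ifn_model = m_ifn))
  }
  res
}

#' Least-squares objective over multiple conditions
#'
#' Sum over conditions and time points of weighted squared residuals on
#' both observables, percent positive and supernatant IFN-alpha. With the
#' default `"max_observed"` weighting each observable's residuals are
#' divided by the maximum observed value of that observable across all
#' conditions, so percentages and concentrations contribute comparably;
#' `"none"` uses unit weights. Concentration points flagged below the
#' limit of quantification contribute zero when the model is also below
#' `loq`, and `(model - loq)^2` (scaled) otherwise.
#'
#' @param params an [ifn_params()] object (single condition) or a named
#'   list of them, with names matching the observation conditions.
#' @param observations an [ifn_observations()] table.
#' @param weighting `"max_observed"` (default) or `"none"`.
#' @param loq ELISA limit of quantification for IFN-alpha (pg/mL).
#' @return Nonnegative scalar; 0 iff the model passes through every
#'   uncensored point exactly (and stays below `loq` at censored points).
#' @export
ifn_objective <- function(params, observations, weighting = "max_observed",
                          loq = 12.5) {
  obs <- ifn_observations(observations)
  conds <- unique(obs$condition)
  if (inherits(params, "ifn_params")) {
    if (length(conds) != 1L)
      stop("a single parameter set was given for ", length(conds),
           " conditions", call. = FALSE)
    params <- setNames(list(params), conds)
  }
  if (!setequal(names(params), conds))
    stop("condition labels of parameters and observations do not match",
         call. = FALSE)
  scales <- .obs_scales(obs, weighting)
  r <- .fit_residuals(params[conds], obs, scales, loq)
  sum(r$pct_resid^2) + sum(r$ifn_resid^2)
}

# ---- fit --------------------------------------------------------------------

#' Fit the responder model to one or more observed time courses
#'
#' Joint weighted least squares over all conditions and both observables
#' (see [ifn_objective()]), with each parameter declared fixed, shared
#' across conditions (optionally in share groups), or condition-specific.
#' Positive parameters spanning decades are optimized in log-space with
#' bounded Levenberg-Marquardt refinement from `n_starts` seeded starts
#' drawn log-uniformly within the bounds; the best local minimum is
#' returned and ties go to the lowest start index, so results are
#' deterministic given `seed`.
#'
#' @param observations an [ifn_observations()] table (or a data.frame in
#'   its dialect).
#' @param roles named list declaring each parameter's role: `"fixed"`
#'   (default), `"free"` (condition-specific), `"shared"`, or a character
#'   vector named by condition mixing those with share-group ids.
#' @param fixed values for fixed parameters: a flat named list applied to
#'   every condition, or a list of such lists named by condition. `fr` and
#'   `sr` default to 0.01 and 0.5.
#' @param bounds per-parameter bounds from [ifn_bounds()].
#' @param n_starts number of multistart draws (default 16).
#' @param seed RNG seed for the start draws.
#' @param weighting,loq see [ifn_objective()].
#' @param rtol,atol integrator tolerances used during fitting.
#' @param extra_starts optional list of additional start points (named
#'   natural-scale vectors keyed like the estimated entries), refined
#'   after the random starts; used e.g. to warm-start a nested family
#'   member from a simpler member's solution.
#' @return An object of class `"ifn_fit"` with components `parameters`
#'   (resolved [ifn_params()] per condition), `estimates` (named
#'   natural-scale vector of estimated entries), `objective`, `residuals`,
#'   `fitted`, `diagnostics` (per-start objectives, best start index,
#'   convergence flags) and the fit configuration. Methods: `print`,
#'   `summary`, `coef`, `predict`, `residuals`, `plot`, `simulate`.
#' @examples
#' truth <- ifn_regimes()["cpg_0.5"]
#' ds <- generate_dataset(truth, noise = noise_model(elisa_cv = 0,
#'                        n_cells_per_well = Inf))
#' fit <- ifn_fit(ds$observations, roles = list(T = "free", koff = "free"),
#'                fixed = lapply(truth, unclass), n_starts = 4)
#' coef(fit)
#' @export
ifn_fit <- function(observations, roles = list(), fixed = list(),
                    bounds = ifn_bounds(), n_starts = 16, seed = 1L,
                    weighting = "max_observed", loq = 12.5,
                    rtol = 1e-8, atol = 1e-10, extra_starts = list()) {
  obs <- ifn_observations(observations)
  conds <- unique(obs$condition)
  layout <- .build_layout(roles, conds, fixed, bounds)
  entries <- layout$entries
  n_ent <- nrow(entries)
  scales <- .obs_scales(obs, weighting)

  n_points <- nrow(obs) + sum(obs$below_loq == 0L)
  if (n_points < n_ent)
    stop("under-determined fit: ", n_ent, " free parameter entries but only ",
         n_points, " uncensored data points", call. = FALSE)

  n_res <- 2L * nrow(obs)
  resid_fun <- function(lt) {
    th <- setNames(exp(lt), entries$key)
    pbc <- .resolve_params(layout, th)
    r <- tryCatch(.fit_residuals(pbc, obs, scales, loq, rtol, atol),
                  error = function(e) NULL)
    if (is.null(r)) return(rep_len(1e6, n_res))
    c(r$pct_resid, r$ifn_resid)
  }

  if (n_ent == 0L) {
    pbc <- .resolve_params(layout, numeric(0L), check = TRUE)
    est <- setNames(numeric(0L), character(0L))
    diag <- list(starts = data.frame(start = integer(0L),
                                     objective = numeric(0L),
                                     converged = logical(0L)),
                 best_start = NA_integer_, converged = TRUE)
  } else {
    llo <- log(entries$lower); lup <- log(entries$upper)
    starts <- .with_seed(seed, {
      m <- matrix(runif(n_starts * n_ent, rep(llo, each = n_starts),
                        rep(lup, each = n_starts)),
                  nrow = n_starts)
      # redraw any start that violates its bounds (cannot occur for
      # uniform draws; kept as a guard for degenerate bounds)
      for (j in seq_len(n_starts)) {
        while (any(m[j, ] < llo | m[j, ] > lup))
          m[j, ] <- runif(n_ent, llo, lup)
      }
      m
    })
    for (es in extra_starts) {
      if (!all(entries$key %in% names(es)))
        stop("extra start does not cover all estimated entries", call. = FALSE)
      starts <- rbind(starts, pmin(pmax(log(es[entries$key]), llo), lup))
    }
    n_all <- nrow(starts)
    sols <- vector("list", n_all)
    objs <- rep(Inf, n_all)
    conv <- logical(n_all)
    for (j in seq_len(n_all)) {
      r <- tryCatch(
        suppressWarnings(
        minpack.lm::nls.lm(par = starts[j, ], lower = llo, upper = lup,
                           fn = resid_fun,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 100, ftol = 1e-12, ptol = 1e-12))),
        error = function(e) NULL)
      if (is.null(r)) next
      objs[j] <- r$deviance
      sols[[j]] <- setNames(exp(r$par), entries$key)
      conv[j] <- r$info %in% 1:4
    }
    best <- which.min(objs)   # ties: lowest index
    if (!is.finite(objs[best]))
      stop("all multistarts failed", call. = FALSE)
    est <- sols[[best]]
    pbc <- .resolve_params(layout, est, check = TRUE)
    diag <- list(starts = data.frame(start = seq_len(n_all),
                                     objective = objs, converged = conv),
                 best_start = best, converged = any(conv))
  }

  resid <- .fit_residuals(pbc, obs, scales, loq, rtol, atol)
  objective <- sum(resid$pct_resid^2) + sum(resid$ifn_resid^2)

  structure(list(
    conditions = conds,
    parameters = pbc,
    estimates = est,
    objective = objective,
    residuals = resid[, c("condition", "time_h", "pct_resid", "ifn_resid")],
    fitted = resid[, c("condition", "time_h", "pct_model", "ifn_model")],
    diagnostics = diag,
    layout = layout,
    scales = scales,
    observations = obs,
    args = list(roles = roles, fixed = fixed, bounds = bounds,
                n_starts = n_starts, seed = seed, weighting = weighting,
                loq = loq, rtol = rtol, atol = atol)
  ), class = "ifn_fit")
}
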