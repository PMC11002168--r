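#' Fold change over the unprimed condition
#'
#' Elementwise ratio `primed / unprimed` for matched-time series; 1.0
#' means no priming effect, values above 1 indicate sensitization and
#' below 1 desensitization. Points with an unprimed value of 0 yield
#' `NA` (flagged with a warning), never infinity.
#'
#' @param primed,unprimed equal-length numeric series on matched times.
#' @return Numeric vector of fold changes.
#' @export
fold_change <- function(primed, unprimed) {
  if (!is.numeric(primed) || !is.numeric(unprimed) ||
      length(primed) != length(unprimed) || !length(primed))
    stop("primed and unprimed must be equal-length non-empty numeric series",
         call. = FALSE)
  bad <- unprimed == 0
  out <- primed / unprimed
  if (any(bad)) {
    warning(sum(bad), " point(s) with unprimed value 0 set to NA")
    out[bad] <- NA_real_
  }
  out
}

#' Fold change by randomized pairing of replicates
#'
#' Pairs each primed replicate with a uniformly random unprimed partner
#' -- a random permutation (without replacement) when replicate counts
#' match, sampling with replacement otherwise -- and returns the ratios.
#' Uses the current RNG state; seed with [set.seed()] for
#' reproducibility.
#'
#' @param primed,unprimed non-empty numeric replicate vectors.
#' @return Numeric vector of fold-change samples, one per primed
#'   replicate.
#' @export
randomized_pairing_fold_change <- function(primed, unprimed) {
  if (!length(primed) || !length(unprimed))
    stop("primed and unprimed must be non-empty", call. = FALSE)
  partners <- if (length(unprimed) == 1L) rep(unprimed, length(primed))
  else if (length(primed) == length(unprimed))
    unprimed[sample.int(length(unprimed))]
  else unprimed[sample.int(length(unprimed), length(primed), replace = TRUE)]
  fold_change(primed, partners)
}

#' Replicate spread
#'
#' Sample standard deviation (n - 1 denominator) of replicate values.
#'
#' @param values numeric vector of at least 2 replicate values.
#' @return The sample SD.
#' @export
replicate_spread <- function(values) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("replicate_spread needs at least 2 values", call. = FALSE)
  sd(values)
}

#' Seeded parameter-recovery study
#'
#' Repeats generate-then-fit over `n_seeds` independent synthetic
#' datasets drawn at the ground-truth parameters and records every
#' estimated entry against its generating value. This is the package's
#' calibration instrument: with the defaults (hourly sampling over 26 h,
#' 3 replicates, binomial counting over 25,000 cells, 5% ELISA CV) it
#' measures how well each free parameter is identified under realistic
#' measurement noise.
#'
#' @param truth named list of generating [ifn_params()] per condition
#'   (single `ifn_params` accepted).
#' @param roles parameter roles as in [ifn_fit()].
#' @param fixed fixed values; default: every fixed-role parameter is held
#'   at its generating value.
#' @param n_seeds number of repetitions (default 20).
#' @param seed base seed; repetition `i` derives its dataset and
#'   multistart seeds from it.
#' @param noise a [noise_model()].
#' @param t_grid sampling grid in hours.
#' @param n_starts,weighting,bounds passed to [ifn_fit()].
#' @return A `data.frame` of class `"ifn_recovery"` with one row per
#'   repetition and estimated entry: `rep`, `seed`, `key`, `par`,
#'   `estimate`, `truth`, `rel_error`. `summary()` reports the median
#'   estimate and median relative error per entry.
#' @export
recovery_study <- function(truth, roles, fixed = NULL, n_seeds = 20,
                           seed = 1L, noise = noise_model(), t_grid = 0:26,
                           n_starts = 16, weighting = "max_observed",
                           bounds = ifn_bounds()) {
  if (inherits(truth, "ifn_params")) truth <- list(condition_1 = truth)
  if (is.null(fixed)) fixed <- lapply(truth, function(p) unclass(p))
  conds <- names(truth)
  layout <- .build_layout(roles, conds, fixed, bounds)
  truth_of_key <- vapply(layout$entries$key, function(k) {
    rows <- layout$map[!is.na(layout$map$key) & layout$map$key == k, ]
    vals <- vapply(rows$cond, function(cd) truth[[cd]][[rows$par[1L]]],
                   numeric(1L))
    vals[[1L]]
  }, numeric(1L))

  out <- NULL
  for (i in seq_len(n_seeds)) {
    ds_seed <- seed + 131L * i
    ds <- generate_dataset(truth, t_grid = t_grid, noise = noise,
                           seed = ds_seed)
    fit <- ifn_fit(ds$observations, roles = roles, fixed = fixed,
                   bounds = bounds, n_starts = n_starts,
                   seed = ds_seed + 7919L, weighting = weighting,
                   loq = noise$loq_ifn)
    est <- fit$estimates
    out <- rbind(out, data.frame(
      rep = i, seed = ds_seed, key = names(est),
      par = layout$entries$par[match(names(est), layout$entries$key)],
      estimate = unname(est), truth = unname(truth_of_key[names(est)]),
      rel_error = abs(unname(est) - unname(truth_of_key[names(est)])) /
        abs(unname(truth_of_key[names(est)]))))
  }
  rownames(out) <- NULL
  structure(out, class = c("ifn_recovery", "data.frame"))
}

#' @export
summary.ifn_recovery <- function(object, ...) {
  keys <- unique(object$key)
  out <- data.frame(
    key = keys,
    par = object$par[match(keys, object$key)],
    truth = object$truth[match(keys, object$key)],
    median_estimate = vapply(keys, function(k)
      median(object$estimate[object$key == k]), numeric(1L)),
    median_rel_error = vapply(keys, function(k)
      median(object$rel_error[object$key == k]), numeric(1L)))
  rownames(out) <- NULL
  out
}

# ---- dose-response scenario -------------------------------------------------

# map resolved per-condition parameters onto a layout's estimated entries
# (shared/grouped entries take the value of the group's first condition)
.warm_start <- function(layout, parameters) {
  n <- nrow(layout$entries)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- layout$entries$key[i]
    cds <- layout$map$cond[!is.na(layout$map$key) & layout$map$key == k]
    out[i] <- parameters[[cds[1L]]][[layout$entries$par[i]]]
  }
  setNames(out, layout$entries$key)
}

#' Parameter roles for the multi-dose fit structure
#'
#' Builds the constraint structure used for the joint dose-response fit:
#' `kon`, `H` and `df` common to all CpG-C doses (`kon` separate for
#' R848), `kf` shared by the lower doses and R848 but separate at
#' 50 ug/mL CpG-C, and `T`/`koff` condition-specific unless pooled into
#' a common CpG-C group (`t_role`/`koff_role` = `"cpg"`). Conditions are
#' recognized as R848 by a label starting with "r848"; everything else
#' is treated as a CpG-C dose, with the label `"cpg_50"` getting its own
#' secretion rate.
#'
#' @param conds character vector of condition labels.
#' @param t_role,koff_role `"free"` (condition-specific, the default) or
#'   `"cpg"` (one common value for all CpG-C doses).
#' @return A roles list for [ifn_fit()].
#' @export
ifn_dose_roles <- function(conds, t_role = "free", koff_role = "free") {
  is_r8 <- grepl("^r848", conds)
  pick <- function(role) {
    v <- ifelse(is_r8, "free", if (role == "cpg") "cpg" else "free")
    setNames(v, conds)
  }
  list(
    kon = setNames(ifelse(is_r8, "free", "cpg"), conds),
    H = "shared", df = "shared",
    kf = setNames(ifelse(conds == "cpg_50", "free", "hi"), conds),
    T = pick(t_role), koff = pick(koff_role)
  )
}

#' Configure a dose-response scenario
#'
#' Declares a full end-to-end scenario: ground-truth parameters (or a
#' pre-made observation table), sampling design, noise, the nested
#' family of constraint structures to compare, and the seed that fixes
#' generation and multistarts.
#'
#' @param conditions named list of ground-truth [ifn_params()] per
#'   condition (default: the four fitted regimes, [ifn_regimes()]).
#' @param data optional [ifn_observations()] table; when supplied,
#'   generation is skipped and `conditions` is only used for
#'   simulate-only overlays.
#' @param t_grid sampling grid in hours.
#' @param noise a [noise_model()].
#' @param family optional named list of roles lists forming the nested
#'   family; default: threshold and turn-off rate pooled across CpG-C
#'   doses, then `T` freed, then both freed.
#' @param n_starts,factor multistart count and parsimony slack.
#' @param seed scenario seed (fixes generation and fitting).
#' @param fit set `FALSE` for simulate-only overlays.
#' @param out_dir optional output directory for the JSON report and CSV
#'   curve/observation tables.
#' @return A list of class `"ifn_scenario"`.
#' @export
dose_response_config <- function(conditions = ifn_regimes(), data = NULL,
                                 t_grid = 0:26, noise = noise_model(),
                                 family = NULL, n_starts = 16, factor = 1.05,
                                 seed = 1L, fit = TRUE, out_dir = NULL) {
  labels <- if (!is.null(data)) unique(ifn_observations(data)$condition)
  else names(conditions)
  if (is.null(family))
    family <- list(
      pooled_T_koff = ifn_dose_roles(labels, "cpg", "cpg"),
      free_T = ifn_dose_roles(labels, "free", "cpg"),
      free_T_koff = ifn_dose_roles(labels, "free", "free"))
  if (is.null(names(family)))
    names(family) <- paste0("spec", seq_along(family))
  structure(list(conditions = conditions, data = data, t_grid = t_grid,
                 noise = noise, family = family, n_starts = n_starts,
                 factor = factor, seed = as.integer(seed), fit = fit,
                 out_dir = out_dir),
            class = "ifn_scenario")
}

#' Run a dose-response scenario end to end
#'
#' Generates (or loads) the observations, fits every member of the
#' nested constraint family jointly across conditions, ranks them with
#' [parsimony_compare()], and assembles a machine-readable report. With
#' `out_dir` set, writes `report.json`, `curves.csv` (fitted vs observed
#' time courses of the selected fit) and `observations.csv`; if a stage
#' fails after partial output, a `FAILED` marker file with the error
#' message is flushed alongside before the error propagates.
#'
#' @param config an [dose_response_config()] scenario.
#' @return A list of class `"ifn_dose_response"` with `dataset`, `fits`,
#'   `parsimony`, `report` and `curves` (the latter two `NULL` for
#'   simulate-only runs, which instead return model `curves` only).
#' @export
run_dose_response <- function(config) {
  stopifnot(inherits(config, "ifn_scenario"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  run <- function() {
    if (!is.null(config$data)) {
      obs <- ifn_observations(config$data)
      dataset <- list(observations = obs)
    } else {
      dataset <- generate_dataset(config$conditions, t_grid = config$t_grid,
                                  noise = config$noise, seed = config$seed)
      obs <- dataset$observations
    }
    if (!is.null(out_dir))
      write_observations(obs, file.path(out_dir, "observations.csv"))

    if (!isTRUE(config$fit)) {
      curves <- NULL
      for (cond in names(config$conditions)) {
        traj <- simulate_ifn(config$conditions[[cond]], config$t_grid)
        curves <- rbind(curves, data.frame(
          condition = cond, time_h = traj$time_h,
          pct_model = traj$percent_positive, ifn_model = traj$ifn_pg_ml))
      }
      if (!is.null(out_dir))
        write.csv(curves, file.path(out_dir, "curves.csv"), row.names = FALSE)
      return(structure(list(dataset = dataset, fits = NULL, parsimony = NULL,
                            report = NULL, curves = curves),
                       class = "ifn_dose_response"))
    }

    # fit the family in order, warm-starting each member from the
    # previous member's solution so that a more permissive (nested)
    # structure can never rank worse for lack of a good start
    fits <- list()
    prev <- NULL
    conds_all <- unique(obs$condition)
    for (nm in names(config$family)) {
      r <- config$family[[nm]]
      warm <- if (is.null(prev)) list() else {
        lay <- .build_layout(r, conds_all, list(), ifn_bounds())
        list(.warm_start(lay, prev$parameters))
      }
      fits[[nm]] <- ifn_fit(obs, roles = r, n_starts = config$n_starts,
                            seed = config$seed + 17L,
                            loq = config$noise$loq_ifn,
                            extra_starts = warm)
      prev <- fits[[nm]]
    }
    pars <- parsimony_compare(fits, factor = config$factor)
    sel_label <- pars$label[pars$selected]
    sel_fit <- fits[[sel_label]]

    curves <- merge(as.data.frame(obs), sel_fit$fitted,
                    by = c("condition", "time_h"), sort = FALSE)
    report <- list(
      seed = config$seed,
      conditions = sel_fit$conditions,
      family = names(config$family),
      objectives = setNames(vapply(fits, `[[`, numeric(1L), "objective"),
                            names(fits)),
      selected = sel_label,
      parameters = lapply(sel_fit$parameters, function(p)
        unclass(p)[.par_names]),
      converged = vapply(fits, function(f) f$diagnostics$converged,
                         logical(1L)))
    if (!is.null(out_dir)) {
      jsonlite::write_json(report, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA)
      write.csv(curves, file.path(out_dir, "curves.csv"), row.names = FALSE)
    }
    structure(list(dataset = dataset, fits = fits, parsimony = pars,
                   report = report, curves = curves),
              class = "ifn_dose_response")
  }
  tryCatch(run(), error = function(e) {
    if (!is.null(out_dir))
      writeLines(paste("scenario failed:", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
    stop(e)
  })
}

#' @export
print.ifn_dose_response <- function(x, ...) {
  cat("Dose-response scenario run\n")
  if (!is.null(x$parsimony)) print(x$parsimony)
  else cat("(simulate-only: model curves for",
           length(unique(x$curves$condition)), "conditions)\n")
  invisible(x)
}
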