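#' Measurement-noise model for synthetic readouts
#'
#' Describes the two measurement channels emulated by the generator:
#' flow-cytometric percent-positive readouts (binomial counting of
#' positive events among the cells acquired per well) and ELISA
#' concentrations (multiplicative lognormal noise with unit median and
#' left-censoring at the limit of quantification). Defaults follow the
#' experimental setup: 25,000 cells per well, 5% assay CV, IFN-alpha LOQ
#' 12.5 pg/mL (the TNF-alpha LOQ of 7.8 pg/mL is carried for interface
#' completeness; no TNF-alpha time courses are generated), and 3
#' replicates.
#'
#' @param n_cells_per_well cells acquired per well (>= 1; `Inf` disables
#'   counting noise).
#' @param elisa_cv coefficient of variation of the concentration noise
#'   (>= 0; 0 disables it).
#' @param loq_ifn,loq_tnf limits of quantification (pg/mL).
#' @param replicate_count replicates averaged per reported point.
#' @param seed default RNG seed for [generate_dataset()].
#' @return An object of class `"ifn_noise"`.
#' @export
noise_model <- function(n_cells_per_well = 25000, elisa_cv = 0.05,
                        loq_ifn = 12.5, loq_tnf = 7.8,
                        replicate_count = 3L, seed = 1L) {
  stopifnot(n_cells_per_well >= 1, elisa_cv >= 0, loq_ifn > 0, loq_tnf > 0,
            replicate_count >= 1)
  structure(list(n_cells_per_well = n_cells_per_well, elisa_cv = elisa_cv,
                 loq_ifn = loq_ifn, loq_tnf = loq_tnf,
                 replicate_count = as.integer(replicate_count),
                 seed = as.integer(seed)),
            class = "ifn_noise")
}

#' Flow-cytometry counting noise on a positive-cell fraction
#'
#' Draws `k ~ Binomial(n_cells, true_fraction)` and returns
#' `100 * k / n_cells`, emulating the counting of positive events among
#' the acquired cells. Uses the current RNG state. With `n_cells = Inf`
#' the exact percentage is returned.
#'
#' @param true_fraction fraction(s) of positive cells in \[0, 1\].
#' @param n_cells number of acquired cells.
#' @return Observed percentage(s).
#' @export
sample_percent_positive <- function(true_fraction, n_cells) {
  if (any(!is.finite(true_fraction)) || any(true_fraction < 0) ||
      any(true_fraction > 1))
    stop("true_fraction must lie in [0, 1]", call. = FALSE)
  if (length(n_cells) != 1L || n_cells < 1)
    stop("n_cells must be a scalar >= 1", call. = FALSE)
  if (is.infinite(n_cells)) return(100 * true_fraction)
  100 * rbinom(length(true_fraction), size = n_cells,
               prob = true_fraction) / n_cells
}

#' ELISA noise and limit-of-quantification censoring
#'
#' Multiplies each true concentration by a lognormal factor with unit
#' median and coefficient of variation `cv`; values below `loq` are
#' reported at `loq` with a censoring flag (standard ELISA reporting of
#' left-censored concentrations). Uses the current RNG state.
#'
#' @param true_conc true concentration(s) in pg/mL (>= 0).
#' @param cv coefficient of variation (>= 0; 0 disables noise).
#' @param loq limit of quantification (pg/mL).
#' @return A list with `value` (reported concentrations) and `below_loq`
#'   (logical flags).
#' @export
apply_elisa_noise_and_loq <- function(true_conc, cv, loq) {
  stopifnot(all(is.finite(true_conc)), all(true_conc >= 0), cv >= 0, loq > 0)
  n <- length(true_conc)
  fac <- if (cv > 0) rlnorm(n, meanlog = 0, sdlog = sqrt(log1p(cv^2))) else
    rep(1, n)
  v <- true_conc * fac
  below <- v < loq
  list(value = ifelse(below, loq, v), below_loq = below)
}

#' Generate a synthetic multi-condition dataset
#'
#' For each condition and replicate, simulates the responder ODE at the
#' ground-truth parameters, draws percent-positive readouts by binomial
#' cell counting and concentrations with multiplicative lognormal ELISA
#' noise, averages replicates (attaching the SEM across them), and
#' censors reported mean concentrations below the IFN-alpha LOQ.
#' Regenerating with the same seed reproduces the dataset bit-exactly;
#' the caller's RNG state is left untouched.
#'
#' @param truth a named list of ground-truth [ifn_params()] per condition
#'   (a single `ifn_params` is accepted and labelled `"condition_1"`).
#' @param t_grid reporting grid in hours (default hourly, 0-26 h).
#' @param noise a [noise_model()].
#' @param seed RNG seed (default: the seed stored in `noise`).
#' @return An object of class `"ifn_dataset"`: list with `observations`
#'   (an [ifn_observations()] table), `truth`, `noise` and `seed`.
#' @examples
#' ds <- generate_dataset(ifn_regimes()["cpg_0.5"], seed = 7)
#' head(ds$observations)
#' @export
generate_dataset <- function(truth, t_grid = 0:26, noise = noise_model(),
                             seed = noise$seed) {
  if (inherits(truth, "ifn_params")) truth <- list(condition_1 = truth)
  if (!is.list(truth) || is.null(names(truth)) || any(names(truth) == "") ||
      !all(vapply(truth, inherits, logical(1L), "ifn_params")))
    stop("truth must be a named list of ifn_params objects", call. = FALSE)
  stopifnot(inherits(noise, "ifn_noise"))
  R <- noise$replicate_count
  rows <- .with_seed(seed, {
    out <- NULL
    for (cond in names(truth)) {
      traj <- simulate_ifn(truth[[cond]], t_grid)
      frac <- traj$f1 + traj$f2
      nt <- length(t_grid)
      pct_draws <- vapply(seq_len(R), function(r)
        sample_percent_positive(frac, noise$n_cells_per_well), numeric(nt))
      conc_draws <- vapply(seq_len(R), function(r)
        traj$ifn_pg_ml * (if (noise$elisa_cv > 0)
          rlnorm(nt, 0, sqrt(log1p(noise$elisa_cv^2))) else rep(1, nt)),
        numeric(nt))
      pct_draws <- matrix(pct_draws, nrow = nt)
      conc_draws <- matrix(conc_draws, nrow = nt)
      pct <- rowMeans(pct_draws)
      pct_sem <- if (R > 1L) apply(pct_draws, 1L, sd) / sqrt(R) else NA_real_
      conc <- rowMeans(conc_draws)
      ifn_sem <- if (R > 1L) apply(conc_draws, 1L, sd) / sqrt(R) else NA_real_
      below <- conc < noise$loq_ifn
      out <- rbind(out, data.frame(
        condition = cond, time_h = t_grid,
        pct_pos = pct, pct_pos_sem = pct_sem,
        ifn_pg_ml = ifelse(below, noise$loq_ifn, conc),
        ifn_sem = ifn_sem, below_loq = as.integer(below)))
    }
    out
  })
  structure(list(observations = ifn_observations(rows), truth = truth,
                 noise = noise, seed = as.integer(seed)),
            class = "ifn_dataset")
}

#' @export
print.ifn_dataset <- function(x, ...) {
  cat("Synthetic dataset:", length(x$truth), "condition(s) x",
      length(unique(x$observations$time_h)), "time points x",
      x$noise$replicate_count, "replicates (seed", x$seed, ")\n")
  cat("Conditions:", paste(names(x$truth), collapse = ", "), "\n")
  invisible(x)
}
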