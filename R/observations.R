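#' Observed time courses
#'
#' Validates and normalizes a table of measured time courses: one row per
#' condition and time point with the percent of IFN-alpha-positive cells
#' and the supernatant IFN-alpha concentration, optional per-point SEMs,
#' and a flag marking concentrations left-censored at the ELISA limit of
#' quantification. Rows are ordered by condition (order of first
#' appearance) and then by time.
#'
#' @param x a `data.frame` with columns `condition`, `time_h`, `pct_pos`,
#'   `ifn_pg_ml` and optionally `pct_pos_sem`, `ifn_sem`,
#'   `below_loq` (0/1).
#' @return A `data.frame` of class `"ifn_obs"` with all seven columns.
#' @export
ifn_observations <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("condition", "time_h", "pct_pos", "ifn_pg_ml")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing observation columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- as.data.frame(x)
  if (is.null(x$pct_pos_sem)) x$pct_pos_sem <- NA_real_
  if (is.null(x$ifn_sem)) x$ifn_sem <- NA_real_
  if (is.null(x$below_loq)) x$below_loq <- 0L
  x$condition <- as.character(x$condition)
  for (nm in c("time_h", "pct_pos", "ifn_pg_ml", "pct_pos_sem", "ifn_sem"))
    x[[nm]] <- as.numeric(x[[nm]])
  x$below_loq <- as.integer(x$below_loq)
  if (any(!x$below_loq %in% c(0L, 1L)))
    stop("below_loq must be 0 or 1", call. = FALSE)
  if (any(!is.finite(x$time_h)))
    stop("time_h must be finite", call. = FALSE)
  if (any(!is.finite(x$pct_pos)) || any(x$pct_pos < 0) || any(x$pct_pos > 100))
    stop("pct_pos must lie in [0, 100]", call. = FALSE)
  ok <- x$below_loq == 1L | (is.finite(x$ifn_pg_ml) & x$ifn_pg_ml >= 0)
  if (any(!ok))
    stop("ifn_pg_ml must be >= 0 where not censored", call. = FALSE)

  cond_order <- unique(x$condition)
  x <- x[order(match(x$condition, cond_order), x$time_h), , drop = FALSE]
  rownames(x) <- NULL
  for (cond in cond_order) {
    tt <- x$time_h[x$condition == cond]
    if (anyDuplicated(tt))
      stop("duplicated time points in condition '", cond, "'", call. = FALSE)
  }
  cols <- c("condition", "time_h", "pct_pos", "pct_pos_sem",
            "ifn_pg_ml", "ifn_sem", "below_loq")
  structure(x[, cols], class = c("ifn_obs", "data.frame"))
}

#' Read or write observed time courses as CSV
#'
#' CSV dialect: columns `condition, time_h, pct_pos, pct_pos_sem,
#' ifn_pg_ml, ifn_sem, below_loq` (0/1).
#'
#' @param path file path.
#' @param obs an [ifn_observations()] table.
#' @return `read_observations` returns an `"ifn_obs"` table;
#'   `write_observations` returns `path` invisibly.
#' @export
read_observations <- function(path) {
  ifn_observations(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_observations
#' @export
write_observations <- function(obs, path) {
  obs <- ifn_observations(obs)
  write.csv(as.data.frame(obs), path, row.names = FALSE)
  invisible(path)
}
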