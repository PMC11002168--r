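#' Model parameters
#'
#' Constructs and validates the full parameter set of the responder model.
#' `fr` and `sr` are population fractions (first responders and the maximum
#' second-responder pool) and default to the fixed values used throughout:
#' 1% first responders and a 50% second-responder pool.
#'
#' @param kon activation rate (per hour, > 0); encodes stimulus strength.
#' @param koff turn-off rate of activated cells (per hour, > 0).
#' @param kf IFN-alpha secretion rate per unit activated-cell fraction
#'   (pg/mL per hour, >= 0).
#' @param df first-order IFN-alpha consumption/degradation rate (per hour, >= 0).
#' @param T IFN-alpha threshold for second-responder activation (pg/mL, > 0).
#' @param H Hill coefficient of the paracrine activation gate
#'   (dimensionless, >= 1; any positive real >= 1, not restricted to integers).
#' @param fr fraction of first responders (dimensionless, in (0,1)).
#' @param sr maximum fraction of potential second responders (in (0,1));
#'   `fr + sr` must not exceed 1.
#' @return An object of class `"ifn_params"`: a named list with fields
#'   `fr, sr, kon, koff, kf, df, T, H`.
#' @examples
#' p <- ifn_params(kon = 0.4, koff = 0.2, kf = 6600, df = 0.04, T = 440, H = 4)
#' @export
ifn_params <- function(kon, koff, kf, df, T, H, fr = 0.01, sr = 0.5) {
  p <- list(fr = fr, sr = sr, kon = kon, koff = koff, kf = kf, df = df,
            T = T, H = H)
  .validate_params(p)
  structure(p, class = "ifn_params")
}

.validate_params <- function(p) {
  for (nm in .par_names) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a finite numeric scalar", call. = FALSE)
  }
  if (p$fr <= 0 || p$fr >= 1) stop("fr must lie in (0, 1)", call. = FALSE)
  if (p$sr <= 0 || p$sr >= 1) stop("sr must lie in (0, 1)", call. = FALSE)
  if (p$fr + p$sr > 1) stop("fr + sr must not exceed 1", call. = FALSE)
  if (p$kon <= 0) stop("kon must be > 0", call. = FALSE)
  if (p$koff <= 0) stop("koff must be > 0", call. = FALSE)
  if (p[["T"]] <= 0) stop("T must be > 0", call. = FALSE)
  if (p$kf < 0) stop("kf must be >= 0", call. = FALSE)
  if (p$df < 0) stop("df must be >= 0", call. = FALSE)
  if (p$H < 1) stop("H must be >= 1", call. = FALSE)
  invisible(p)
}

# fast internal constructor: values already guaranteed admissible (bounds)
.params_unchecked <- function(values) {
  structure(as.list(values[.par_names]), class = "ifn_params")
}

#' @export
print.ifn_params <- function(x, ...) {
  cat("IFN responder model parameters:\n")
  v <- unlist(x[.par_names])
  print(signif(v, 6))
  invisible(x)
}

#' @export
as.numeric.ifn_params <- function(x, ...) unlist(x[.par_names])

#' Fitted parameter regimes for the four stimulation conditions
#'
#' The four parameter sets describing pDC IFN-alpha responses to CpG-C at
#' 0.5, 5 and 50 ug/mL and to R848: rising CpG-C dose lowers the
#' second-responder threshold `T`, speeds turn-off `koff`, and at the
#' highest dose reduces the secretion rate `kf`; R848 acts through a much
#' faster `kon` with a low threshold. `kon`, `H` and `df` (and `kf` except
#' at 50 ug/mL CpG-C) are common across conditions.
#'
#' @return Named list of [ifn_params()] objects with elements
#'   `cpg_0.5`, `cpg_5`, `cpg_50`, `r848`.
#' @examples
#' ifn_regimes()$cpg_0.5
#' @export
ifn_regimes <- function() {
  list(
    cpg_0.5 = ifn_params(kon = 0.4, koff = 0.2, kf = 6600, df = 0.04,
                         T = 440, H = 4),
    cpg_5   = ifn_params(kon = 0.4, koff = 0.33, kf = 6600, df = 0.04,
                         T = 230, H = 4),
    cpg_50  = ifn_params(kon = 0.4, koff = 2, kf = 2000, df = 0.04,
                         T = 20, H = 4),
    r848    = ifn_params(kon = 1.5, koff = 1, kf = 6600, df = 0.04,
                         T = 20, H = 4)
  )
}

#' Read and write model parameters as JSON or YAML
#'
#' Serializes exactly the eight fields `fr, sr, kon, koff, kf, df, T, H`.
#'
#' @param params an [ifn_params()] object.
#' @param path file path.
#' @return `read_params_*` return an [ifn_params()] object; the writers
#'   return `path` invisibly.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "ifn_params"))
  jsonlite::write_json(unclass(params)[.par_names], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(ifn_params, as.list(x)[.par_names])
}

#' @rdname write_params_json
#' @export
write_params_yaml <- function(params, path) {
  stopifnot(inherits(params, "ifn_params"))
  yaml::write_yaml(unclass(params)[.par_names], path)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(ifn_params, as.list(x)[.par_names])
}
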