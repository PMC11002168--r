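#' Hill activation gate
#'
#' Fraction of maximal paracrine activation at IFN-alpha concentration
#' `ifn`: `ifn^H / (T^H + ifn^H)`. Strictly increasing in `ifn`, equal to
#' 1/2 at `ifn == T`; exactly 0 at `ifn == 0` for any `H`.
#'
#' @param ifn IFN-alpha concentration (pg/mL, >= 0); vectorized.
#' @param T half-activation threshold (pg/mL, > 0).
#' @param H Hill coefficient (>= 1).
#' @return Numeric vector of activation fractions in \[0, 1).
#' @examples
#' hill_activation(440, 440, 4)   # 0.5
#' hill_activation(880, 440, 4)   # 16/17
#' @export
hill_activation <- function(ifn, T, H) {
  if (!is.numeric(ifn) || any(!is.finite(ifn)) || any(ifn < 0))
    stop("ifn must be finite and >= 0", call. = FALSE)
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0)
    stop("T must be a finite scalar > 0", call. = FALSE)
  if (!is.numeric(H) || length(H) != 1L || !is.finite(H) || H < 1)
    stop("H must be a finite scalar >= 1", call. = FALSE)
  r <- (ifn / T)^H
  out <- r / (1 + r)
  out[is.infinite(r)] <- 1
  out[ifn == 0] <- 0
  out
}

#' Right-hand side of the responder ODE system
#'
#' Rates of change of the three states: activated first-responder fraction
#' `f1`, activated second-responder fraction `f2`, and supernatant
#' IFN-alpha concentration `ifn`:
#' \deqn{df1/dt = kon (fr - f1) - koff\, f1}
#' \deqn{df2/dt = kon \frac{[IFN]^H}{T^H + [IFN]^H} (sr - f2) - koff\, f2}
#' \deqn{d[IFN]/dt = kf (f1 + f2) - df\,[IFN]}
#' At `f1 = fr` the first rate is `-koff * fr < 0`, so `f1 <= fr` is
#' forward-invariant; analogously for `f2 = sr`, and `ifn >= 0`.
#'
#' @param state numeric length-3 state `(f1, f2, ifn)` (names optional).
#' @param params an [ifn_params()] object.
#' @return Named numeric length-3 vector of derivatives (per hour; pg/mL
#'   per hour for `ifn`).
#' @export
ifn_derivatives <- function(state, params) {
  stopifnot(inherits(params, "ifn_params"))
  if (!is.numeric(state) || length(state) != 3L || any(!is.finite(state)))
    stop("state must be a finite numeric vector of length 3", call. = FALSE)
  f1 <- state[[1L]]; f2 <- state[[2L]]; ifn <- state[[3L]]
  h <- if (ifn > 0) hill_activation(ifn, params[["T"]], params$H) else 0
  c(f1  = params$kon * (params$fr - f1) - params$koff * f1,
    f2  = params$kon * h * (params$sr - f2) - params$koff * f2,
    ifn = params$kf * (f1 + f2) - params$df * ifn)
}

#' Simulate the responder model
#'
#' Integrates the ODE system with an adaptive explicit Runge-Kutta scheme
#' (Dormand-Prince 4(5), compiled right-hand side) on a reporting grid that
#' must start at 0 hours. The returned states are guaranteed to satisfy the
#' invariants `0 <= f1 <= fr`, `0 <= f2 <= sr`, `ifn >= 0` (solver rounding
#' within a 1e-7 relative band is clipped onto the bounds; anything larger
#' raises an error, as does integrator failure).
#'
#' @param params an [ifn_params()] object.
#' @param times strictly increasing reporting grid in hours, starting at 0.
#'   Default: hourly over the 26 h observation window.
#' @param init initial state `(f1, f2, ifn)`; default all-zero rest state
#'   at stimulus addition.
#' @param rtol,atol integrator relative/absolute tolerances.
#' @return A trajectory: `data.frame` of class `"ifn_traj"` with columns
#'   `time_h`, `f1`, `f2`, `ifn_pg_ml` and
#'   `percent_positive = 100 * (f1 + f2)`.
#' @examples
#' traj <- simulate_ifn(ifn_regimes()$cpg_0.5)
#' head(traj)
#' @export
simulate_ifn <- function(params, times = 0:26, init = c(f1 = 0, f2 = 0, ifn = 0),
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "ifn_params"))
  if (!is.numeric(times) || length(times) < 1L || times[1L] != 0 ||
      (length(times) > 1L && any(diff(times) <= 0)))
    stop("times must be strictly increasing and start at 0", call. = FALSE)
  init <- unname(init)
  if (length(init) != 3L || any(!is.finite(init)))
    stop("init must be a finite numeric state of length 3", call. = FALSE)
  if (init[1L] < 0 || init[1L] > params$fr || init[2L] < 0 ||
      init[2L] > params$sr || init[3L] < 0)
    stop("init violates state bounds (0 <= f1 <= fr, 0 <= f2 <= sr, ifn >= 0)",
         call. = FALSE)

  if (length(times) == 1L) {
    st <- init
  } else {
    y <- c(f1 = init[1L], f2 = init[2L], ifn = init[3L])
    out <- try(deSolve::ode(
      y = y, times = times, func = "ifnwave_derivs",
      parms = unlist(params[.par_names]), dllname = "ifnwave",
      initfunc = "ifnwave_initmod", method = "ode45",
      rtol = rtol, atol = atol
    ), silent = TRUE)
    if (inherits(out, "try-error") || nrow(out) < length(times) ||
        anyNA(out[, c("f1", "f2", "ifn")]))
      stop("integration failure: the ODE solver did not reach the end of the grid",
           call. = FALSE)
    st <- out
  }
  if (length(times) == 1L) {
    f1 <- st[1L]; f2 <- st[2L]; ifn <- st[3L]
  } else {
    f1 <- st[, "f1"]; f2 <- st[, "f2"]; ifn <- st[, "ifn"]
  }
  f1 <- .clip_state(f1, params$fr, "f1")
  f2 <- .clip_state(f2, params$sr, "f2")
  ifn <- .clip_state(ifn, Inf, "ifn")
  structure(
    data.frame(time_h = times, f1 = f1, f2 = f2, ifn_pg_ml = ifn,
               percent_positive = 100 * (f1 + f2)),
    class = c("ifn_traj", "data.frame"),
    params = params
  )
}

# clip solver rounding onto [0, hi]; error beyond a small relative band
.clip_state <- function(x, hi, what) {
  tol <- 1e-7 * max(1, if (is.finite(hi)) hi else max(abs(x), 1))
  if (any(x < -tol) || (is.finite(hi) && any(x > hi * (1 + 1e-7) + tol)))
    stop("integrated state '", what, "' violates its invariant beyond solver tolerance",
         call. = FALSE)
  pmin(pmax(x, 0), hi)
}

#' Steady state of the responder model
#'
#' The first-responder fraction settles at the closed form
#' `f1* = kon * fr / (kon + koff)`. The coupled pair (`f2*`, `ifn*`) solves
#' `f2* = sr * a / (a + koff)` with `a = kon * hill(ifn*)` and
#' `ifn* = kf (f1* + f2*) / df`, found by scalar root finding on `ifn*`
#' within `[kf f1*/df, kf (f1* + sr)/df]`.
#'
#' @param params an [ifn_params()] object with `koff > 0` and, unless
#'   `kf == 0`, `df > 0`.
#' @return Named numeric vector `c(f1, f2, ifn)`.
#' @examples
#' steady_state(ifn_regimes()$cpg_0.5)
#' @export
steady_state <- function(params) {
  stopifnot(inherits(params, "ifn_params"))
  f1s <- params$kon * params$fr / (params$kon + params$koff)
  if (params$kf == 0) return(c(f1 = f1s, f2 = 0, ifn = 0))
  if (params$df <= 0)
    stop("steady state requires df > 0 when kf > 0", call. = FALSE)
  f2_of <- function(ifn) {
    a <- params$kon * hill_activation(ifn, params[["T"]], params$H)
    params$sr * a / (a + params$koff)
  }
  g <- function(ifn) params$kf * (f1s + f2_of(ifn)) / params$df - ifn
  lo <- params$kf * f1s / params$df
  hi <- params$kf * (f1s + params$sr) / params$df
  if (g(lo) < 0 || g(hi) > 0)
    stop("steady-state bracket failed; parameters outside admissible region",
         call. = FALSE)
  root <- uniroot(g, c(lo, hi), tol = 1e-13 * max(1, hi))$root
  f2s <- f2_of(root)
  # self-consistency of both fixed-point equations
  r1 <- abs(params$kf * (f1s + f2s) / params$df - root) / max(root, 1e-12)
  a <- params$kon * hill_activation(root, params[["T"]], params$H)
  r2 <- abs(params$sr * a / (a + params$koff) - f2s) / max(f2s, 1e-12)
  stopifnot(r1 < 1e-10, r2 < 1e-10)
  c(f1 = f1s, f2 = f2s, ifn = root)
}

#' Percent IFN-alpha-positive cells along a trajectory
#'
#' `100 * (f1 + f2)` at each time point, bounded above by
#' `100 * (fr + sr)`.
#'
#' @param traj a trajectory from [simulate_ifn()].
#' @return Numeric vector of percentages.
#' @export
percent_positive <- function(traj) {
  stopifnot(inherits(traj, "ifn_traj"))
  traj$percent_positive
}

#' Export a trajectory as CSV
#'
#' Writes columns `time_h, f1, f2, ifn_pg_ml, percent_positive`.
#'
#' @param traj a trajectory from [simulate_ifn()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ifn_traj"))
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
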