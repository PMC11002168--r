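# Fixed-step classical RK4 integrator over the exported derivative
# function: an independent reference for the adaptive compiled solver.
rk4_simulate <- function(params, times, h = 1e-3) {
  f <- function(y) unname(ifn_derivatives(y, params))
  out <- matrix(NA_real_, nrow = length(times), ncol = 3L,
                dimnames = list(NULL, c("f1", "f2", "ifn")))
  y <- c(0, 0, 0)
  t <- 0
  stopifnot(times[1L] == 0)
  out[1L, ] <- y
  for (i in seq_along(times)[-1L]) {
    while (t < times[i] - 1e-12) {
      hh <- min(h, times[i] - t)
      k1 <- f(y)
      k2 <- f(y + hh / 2 * k1)
      k3 <- f(y + hh / 2 * k2)
      k4 <- f(y + hh * k3)
      y <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + hh
    }
    out[i, ] <- y
  }
  out
}

# sup-norm error relative to the sup-norm of the reference series
rel_sup <- function(x, ref) max(abs(x - ref)) / max(abs(ref))

# noiseless measurement model: exact percentages and concentrations
noiseless <- function(replicate_count = 1L, seed = 1L)
  noise_model(n_cells_per_well = Inf, elisa_cv = 0,
              replicate_count = replicate_count, seed = seed)
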