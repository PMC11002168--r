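test_that("hill activation gate has the exact half-saturation and limit values", {
  expect_identical(hill_activation(0, 440, 4), 0)
  for (T in c(0.5, 20, 440, 1e4)) {
    for (H in c(1, 2.5, 4, 8)) {
      expect_equal(hill_activation(T, T, H), 0.5, tolerance = 1e-12)
    }
  }
  expect_equal(hill_activation(880, 440, 4), 16 / 17, tolerance = 1e-12)
  # strictly increasing in concentration
  v <- hill_activation(c(1, 10, 100, 440, 1000, 1e4), 440, 4)
  expect_true(all(diff(v) > 0))
  expect_true(all(v >= 0 & v <= 1))
  # overflow of (ifn/T)^H rounds to the limit 1
  expect_equal(hill_activation(1e5, 0.1, 8), 1)
  expect_error(hill_activation(-1, 440, 4), "ifn")
  expect_error(hill_activation(10, 0, 4), "T")
  expect_error(hill_activation(10, 440, 0.5), "H")
})

test_that("parameter construction enforces the model's invariants", {
  p <- ifn_params(kon = 0.4, koff = 0.2, kf = 6600, df = 0.04, T = 440, H = 4)
  expect_s3_class(p, "ifn_params")
  expect_identical(unname(as.numeric(p)[1:2]), c(0.01, 0.5))
  expect_error(ifn_params(kon = 0.4, koff = 0.2, kf = 1, df = 1, T = 1, H = 4,
                          fr = 0.6, sr = 0.5), "fr \\+ sr")
  expect_error(ifn_params(kon = 0, koff = 0.2, kf = 1, df = 1, T = 1, H = 4),
               "kon")
  expect_error(ifn_params(kon = 1, koff = 0.2, kf = 1, df = 1, T = -5, H = 4),
               "T")
  expect_error(ifn_params(kon = 1, koff = 0.2, kf = 1, df = 1, T = 1, H = 0.2),
               "H")
  expect_error(ifn_params(kon = 1, koff = 0.2, kf = -1, df = 1, T = 1, H = 4),
               "kf")
})

test_that("derivatives implement the three right-hand sides", {
  p <- ifn_params(kon = 0.4, koff = 0.2, kf = 6600, df = 0.04, T = 440, H = 4)
  # from rest only first responders activate (hill(0) = 0)
  expect_equal(unname(ifn_derivatives(c(0, 0, 0), p)),
               c(p$kon * p$fr, 0, 0), tolerance = 1e-15)
  # saturation boundary: decay only on the cell fractions
  d <- ifn_derivatives(c(p$fr, p$sr, 440), p)
  expect_equal(unname(d[1]), -p$koff * p$fr, tolerance = 1e-15)
  expect_equal(unname(d[2]),
               p$kon * 0.5 * 0 - p$koff * p$sr, tolerance = 1e-15)
  expect_equal(unname(d[3]), p$kf * (p$fr + p$sr) - p$df * 440,
               tolerance = 1e-12)
  # hand-computed interior point with hill = 1/2
  expect_equal(unname(ifn_derivatives(c(0.005, 0.1, 440), p)),
               c(0.001, 0.06, 675.4), tolerance = 1e-12)
})

test_that("simulation respects the time grid contract and degenerate cases", {
  p <- ifn_regimes()$cpg_0.5
  tr <- simulate_ifn(p, times = 0)
  expect_equal(nrow(tr), 1L)
  expect_equal(unname(unlist(tr[1, c("f1", "f2", "ifn_pg_ml")])), c(0, 0, 0))
  expect_error(simulate_ifn(p, times = 1:5), "start at 0")
  expect_error(simulate_ifn(p, times = c(0, 2, 2, 3)), "strictly increasing")
  expect_error(simulate_ifn(p, init = c(0.5, 0, 0)), "bounds")
  # no secretion: no paracrine signal, no second responders
  p0 <- ifn_params(kon = 0.4, koff = 0.2, kf = 0, df = 0.04, T = 440, H = 4)
  tr0 <- simulate_ifn(p0)
  expect_true(all(tr0$ifn_pg_ml == 0))
  expect_true(all(tr0$f2 == 0))
})

test_that("with kf = 0 the first-responder equation matches its closed form", {
  p <- ifn_params(kon = 0.4, koff = 0.2, kf = 0, df = 0.04, T = 440, H = 4)
  tr <- simulate_ifn(p, times = seq(0, 26, by = 0.5))
  k <- p$kon + p$koff
  f1_exact <- p$kon * p$fr / k * (1 - exp(-k * tr$time_h))
  expect_lt(max(abs(tr$f1 - f1_exact)), 1e-8)
})

test_that("steady state solves the fixed-point equations and matches integration", {
  p0 <- ifn_params(kon = 0.4, koff = 0.2, kf = 0, df = 0.04, T = 440, H = 4)
  expect_equal(unname(steady_state(p0)),
               c(0.4 * 0.01 / 0.6, 0, 0), tolerance = 1e-12)
  expect_equal(unname(steady_state(p0))[1], 1 / 150, tolerance = 1e-12)
  p <- ifn_regimes()$cpg_0.5
  ss <- steady_state(p)
  # hill(ifn*) ~ 1 at this regime: f2* ~ sr*kon/(kon+koff) = 1/3
  expect_equal(unname(ss["f2"]), 1 / 3, tolerance = 1e-3)
  expect_equal(unname(ss["ifn"]), 5.61e4, tolerance = 1e-3)
  # long-horizon integration converges to it
  tr <- simulate_ifn(p, times = seq(0, 600, by = 10))
  final <- unlist(tr[nrow(tr), c("f1", "f2", "ifn_pg_ml")])
  expect_lt(max(abs(final - ss) / ss), 1e-4)
})

test_that("percent positive is 100 (f1 + f2), bounded by the responder pools", {
  p <- ifn_regimes()$cpg_0.5
  tr <- simulate_ifn(p)
  expect_identical(percent_positive(tr), 100 * (tr$f1 + tr$f2))
  expect_true(all(percent_positive(tr) <= 100 * (p$fr + p$sr)))
  ss <- steady_state(p)
  expect_equal(100 * (ss[["f1"]] + ss[["f2"]]), 34.0, tolerance = 1e-3)
})

test_that("integrated states stay inside their invariant box", {
  b <- ifn_bounds()
  set.seed(101)
  for (i in 1:25) {
    p <- ifn_params(
      kon = exp(runif(1, log(b$kon[1]), log(b$kon[2]))),
      koff = exp(runif(1, log(b$koff[1]), log(b$koff[2]))),
      kf = exp(runif(1, log(b$kf[1]), log(b$kf[2]))),
      df = exp(runif(1, log(b$df[1]), log(b$df[2]))),
      T = exp(runif(1, log(b$T[1]), log(b$T[2]))),
      H = runif(1, 1, 8))
    tr <- simulate_ifn(p)
    expect_true(all(tr$f1 >= 0 & tr$f1 <= p$fr))
    expect_true(all(tr$f2 >= 0 & tr$f2 <= p$sr))
    expect_true(all(tr$ifn_pg_ml >= 0))
  }
})

test_that("tightening the integrator tolerance tenfold leaves states unchanged to 1e-6", {
  for (p in ifn_regimes()) {
    a <- simulate_ifn(p)
    b <- simulate_ifn(p, rtol = 1e-9, atol = 1e-11)
    expect_lt(rel_sup(a$f1, b$f1), 1e-6)
    expect_lt(rel_sup(a$f2, b$f2), 1e-6)
    expect_lt(rel_sup(a$ifn_pg_ml, b$ifn_pg_ml), 1e-6)
  }
})

test_that("comparative statics: higher threshold delays second responders, higher kon speeds first", {
  base <- ifn_regimes()$cpg_0.5
  tt <- 0:26
  prev <- NULL
  for (T in c(110, 440, 1760)) {
    p <- ifn_params(kon = base$kon, koff = base$koff, kf = base$kf,
                    df = base$df, T = T, H = base$H)
    f2 <- simulate_ifn(p, tt)$f2
    if (!is.null(prev)) expect_true(all(f2[-1] < prev[-1]))
    prev <- f2
  }
  prev <- NULL
  for (kon in c(0.1, 0.4, 1.6)) {
    p <- ifn_params(kon = kon, koff = base$koff, kf = 0, df = base$df,
                    T = base$T, H = base$H)
    f1 <- simulate_ifn(p, tt)$f1
    if (!is.null(prev)) expect_true(all(f1[-1] > prev[-1]))
    prev <- f1
  }
})

test_that("a steep Hill gate acts as a threshold switch", {
  base <- ifn_regimes()$cpg_0.5
  p <- ifn_params(kon = base$kon, koff = base$koff, kf = base$kf,
                  df = base$df, T = base$T, H = 8)
  tr <- simulate_ifn(p, seq(0, 26, by = 0.25))
  h <- hill_activation(tr$ifn_pg_ml, p$T, 64)
  # negligible activation below the threshold, near-maximal above
  expect_true(all(h[tr$ifn_pg_ml < 0.9 * p$T] < 1e-2))
  expect_true(all(h[tr$ifn_pg_ml > 1.1 * p$T] > 0.99))
  expect_true(any(tr$ifn_pg_ml > 1.1 * p$T))
})

test_that("parameters round-trip through JSON and YAML with the eight field names", {
  p <- ifn_regimes()$cpg_5
  fj <- tempfile(fileext = ".json")
  fy <- tempfile(fileext = ".yaml")
  write_params_json(p, fj)
  write_params_yaml(p, fy)
  expect_identical(names(jsonlite::read_json(fj)),
                   c("fr", "sr", "kon", "koff", "kf", "df", "T", "H"))
  expect_equal(read_params_json(fj), p, tolerance = 1e-12)
  expect_equal(read_params_yaml(fy), p, tolerance = 1e-12)
})

test_that("trajectories export the documented CSV columns", {
  tr <- simulate_ifn(ifn_regimes()$cpg_50, 0:5)
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  x <- read.csv(f)
  expect_identical(names(x),
                   c("time_h", "f1", "f2", "ifn_pg_ml", "percent_positive"))
  expect_equal(x$percent_positive, 100 * (x$f1 + x$f2), tolerance = 1e-12)
})
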