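truth1 <- ifn_regimes()["cpg_0.5"]
truth2 <- ifn_regimes()[c("cpg_0.5", "cpg_5")]

test_that("objective vanishes on noiseless data and scores a known residual exactly", {
  ds <- generate_dataset(truth1, noise = noiseless())
  expect_lt(ifn_objective(truth1$cpg_0.5, ds$observations), 1e-10)
  # one perturbed percentage point, unit weights: a single squared residual
  obs <- ds$observations
  i <- which(obs$time_h == 10)
  obs$pct_pos[i] <- obs$pct_pos[i] + 2
  expect_equal(ifn_objective(truth1$cpg_0.5, obs, weighting = "none"), 4.0,
               tolerance = 1e-9)
})

test_that("the generating parameters minimize the objective on noiseless data", {
  ds <- generate_dataset(truth1, noise = noiseless())
  p <- truth1$cpg_0.5
  at_truth <- ifn_objective(p, ds$observations)
  for (nm in c("kon", "koff", "kf", "df", "T", "H")) {
    for (fac in c(0.5, 1.5)) {
      q <- unclass(p)
      q[[nm]] <- q[[nm]] * fac
      pq <- do.call(ifn_params, q)
      expect_gt(ifn_objective(pq, ds$observations), at_truth + 1e-8)
    }
  }
})

test_that("objective is invariant under permutation of rows and labels must match", {
  ds <- generate_dataset(truth2, seed = 5)
  obs <- ds$observations
  set.seed(1)
  shuffled <- obs[sample(nrow(obs)), ]
  expect_equal(ifn_objective(truth2, shuffled), ifn_objective(truth2, obs),
               tolerance = 1e-14)
  wrong <- truth2
  names(wrong) <- c("a", "b")
  expect_error(ifn_objective(wrong, obs), "condition labels")
})

test_that("censored points are judged against the LOQ, not the reported value", {
  ds <- generate_dataset(truth1, seed = 3)
  obs <- ds$observations
  cens <- obs$below_loq == 1L
  expect_true(any(cens))
  o0 <- ifn_objective(truth1$cpg_0.5, obs)
  obs$ifn_pg_ml[cens] <- 5   # arbitrary below-LOQ report
  expect_equal(ifn_objective(truth1$cpg_0.5, obs), o0, tolerance = 1e-14)
})

test_that("a fit with nothing free echoes its inputs with near-zero objective", {
  ds <- generate_dataset(truth1, noise = noiseless())
  fit <- ifn_fit(ds$observations, roles = list(),
                 fixed = lapply(truth1, unclass))
  expect_length(fit$estimates, 0L)
  expect_lt(fit$objective, 1e-10)
  expect_equal(coef(fit)["T", "cpg_0.5"], 440)
  expect_true(fit$diagnostics$converged)
})

test_that("under-determined specifications are rejected", {
  ds <- generate_dataset(truth1, noise = noiseless(), t_grid = 0)
  expect_error(
    ifn_fit(ds$observations, roles = list(T = "free", koff = "free",
                                          kon = "free"),
            fixed = lapply(truth1, unclass)),
    "under-determined")
})

test_that("noiseless single-condition fit recovers T and koff to within 1%", {
  ds <- generate_dataset(truth1, noise = noiseless())
  fit <- ifn_fit(ds$observations, roles = list(T = "free", koff = "free"),
                 fixed = lapply(truth1, unclass))
  expect_lt(abs(fit$estimates[["T|c:cpg_0.5"]] - 440) / 440, 0.01)
  expect_lt(abs(fit$estimates[["koff|c:cpg_0.5"]] - 0.2) / 0.2, 0.01)
  expect_equal(fit$objective,
               ifn_objective(fit$parameters, ds$observations), tolerance = 1e-12)
})

test_that("a joint shared/free fit recovers all six distinct values within 2%", {
  ds <- generate_dataset(truth2, noise = noiseless())
  fit <- ifn_fit(ds$observations,
                 roles = list(kon = "shared", H = "shared", kf = "shared",
                              df = "shared", T = "free", koff = "free"),
                 n_starts = 8)
  est <- fit$estimates
  want <- c("kon|all" = 0.4, "H|all" = 4, "kf|all" = 6600, "df|all" = 0.04,
            "T|c:cpg_0.5" = 440, "T|c:cpg_5" = 230,
            "koff|c:cpg_0.5" = 0.2, "koff|c:cpg_5" = 0.33)
  for (k in names(want))
    expect_lt(abs(est[[k]] - want[[k]]) / want[[k]], 0.02)
})

test_that("multistart fitting is deterministic given the seed", {
  ds <- generate_dataset(truth1, seed = 9)
  f1 <- ifn_fit(ds$observations, roles = list(T = "free", koff = "free"),
                fixed = lapply(truth1, unclass), n_starts = 4, seed = 11)
  f2 <- ifn_fit(ds$observations, roles = list(T = "free", koff = "free"),
                fixed = lapply(truth1, unclass), n_starts = 4, seed = 11)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$objective, f2$objective)
  expect_identical(f1$diagnostics$starts, f2$diagnostics$starts)
})

test_that("fit methods expose parameters, predictions and residuals coherently", {
  ds <- generate_dataset(truth1, seed = 2)
  fit <- ifn_fit(ds$observations, roles = list(T = "free", koff = "free"),
                 fixed = lapply(truth1, unclass), n_starts = 4)
  cm <- coef(fit)
  expect_identical(dim(cm), c(8L, 1L))
  expect_identical(rownames(cm),
                   c("fr", "sr", "kon", "koff", "kf", "df", "T", "H"))
  pr <- predict(fit)
  expect_identical(names(pr), c("condition", "time_h", "pct_model", "ifn_model"))
  expect_equal(nrow(pr), 27L)
  pr2 <- predict(fit, times = c(0, 13, 26))
  expect_equal(pr2$time_h, c(0, 13, 26))
  r <- residuals(fit)
  expect_equal(fit$objective, sum(r$pct_resid^2) + sum(r$ifn_resid^2),
               tolerance = 1e-12)
  sm <- summary(fit)
  expect_s3_class(sm, "summary.ifn_fit")
  expect_output(print(sm), "multistart")
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]]$observations, "ifn_obs")
})

test_that("observation tables validate, sort and round-trip through CSV", {
  ds <- generate_dataset(truth2, seed = 8)
  f <- tempfile(fileext = ".csv")
  write_observations(ds$observations, f)
  back <- read_observations(f)
  expect_equal(as.data.frame(back), as.data.frame(ds$observations),
               tolerance = 1e-12)
  # out-of-order time points are sorted within a condition
  one <- as.data.frame(ds$observations)
  one <- one[one$condition == "cpg_0.5", ]
  rownames(one) <- NULL
  shuffled <- one[rev(seq_len(nrow(one))), ]
  expect_equal(as.data.frame(ifn_observations(shuffled)), one,
               tolerance = 1e-12)
  bad <- as.data.frame(ds$observations)
  bad$pct_pos[1] <- 150
  expect_error(ifn_observations(bad), "pct_pos")
  bad2 <- as.data.frame(ds$observations)[c(1, 1, 2), ]
  expect_error(ifn_observations(bad2), "duplicated")
})
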