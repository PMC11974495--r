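test_that("jaccard dissimilarity agrees with set counting and vegan", {
  pa <- rbind(a = c(1, 1, 0), b = c(0, 1, 1))
  d <- jaccard_matrix(pa)
  expect_equal(d[1, 2], 1 - 1 / 3, tolerance = 1e-12)
  pa2 <- rbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0), c = c(0, 0, 1, 1))
  d2 <- jaccard_matrix(pa2)
  expect_equal(d2[1, 2], 0)      # identical sites
  expect_equal(d2[1, 3], 1)      # disjoint sites
  set.seed(8)
  m <- matrix(rbinom(200, 1, 0.4), 10, 20)
  m[1, ] <- c(1, rep(0, 19))     # keep rows non-empty
  dm <- jaccard_matrix(m)
  expect_equal(dm[lower.tri(dm)],
               as.vector(vegan::vegdist(m, method = "jaccard", binary = TRUE)),
               tolerance = 1e-12)
  bad <- rbind(a = c(1, 0), b = c(0, 0))
  expect_error(jaccard_matrix(bad), "b")
})

test_that("I-spline basis hits its boundary values and integrates M-splines", {
  set.seed(9)
  v <- runif(60, 2, 9)
  b <- ispline_basis(v, K = 3)
  expect_equal(drop(eval_ispline(b, min(v))), rep(0, 3))
  expect_equal(drop(eval_ispline(b, max(v))), rep(1, 3))
  # interior values match numeric integration of the M-spline density
  t2 <- c(rep(b$boundary[1], 2), b$knots, rep(b$boundary[2], 2))
  xs <- seq(min(v), max(v), length.out = 9)
  I <- eval_ispline(b, xs)
  for (k in 1:3) {
    oracle <- vapply(xs, function(x)
      integrate(function(u) mspline_oracle(u, k, 2, t2), min(v), x,
                subdivisions = 500)$value, numeric(1))
    expect_equal(I[, k], oracle, tolerance = 1e-4)
  }
  # monotone non-decreasing
  expect_true(all(diff(I[, 1]) >= -1e-12))
  expect_error(ispline_basis(rep(1, 10)), "distinct")
})

sim_gdm_data <- function(n = 40, alpha = 0.1, beta = c(0.5, 0.8, 0.3),
                         seed = 3) {
  set.seed(seed)
  x <- sort(runif(n, 0, 10))
  b <- ispline_basis(x, K = length(beta))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  I <- eval_ispline(b, x)
  Z <- abs(I[pairs[, 1], ] - I[pairs[, 2], ])
  eta <- alpha + drop(Z %*% beta)
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- 1 - exp(-eta)
  list(d = d + t(d), env = cbind(pred = x))
}

test_that("GDM refits dissimilarities generated exactly from the model", {
  dat <- sim_gdm_data()
  fit <- fit_gdm(dat$d, env = dat$env, K = 3)
  expect_gt(fit$pct_deviance_explained, 99)
  expect_equal(sum(fit$coefficients), 1.6, tolerance = 0.05 * 1.6)
  expect_equal(fit$intercept, 0.1, tolerance = 0.02)
  expect_lte(fit$model_deviance, fit$null_deviance)
})

test_that("constant dissimilarities yield an intercept-only fit", {
  n <- 12
  d <- matrix(0.4, n, n); diag(d) <- 0
  set.seed(10)
  env <- cbind(p1 = rnorm(n), p2 = rnorm(n))
  fit <- fit_gdm(d, env = env, K = 3)
  expect_lt(abs(fit$pct_deviance_explained), 1)
  expect_lt(sum(fit$coefficients), 0.05)
})

test_that("shuffling a predictor collapses its coefficient sum", {
  dat <- sim_gdm_data(n = 35, seed = 12)
  set.seed(13)
  env2 <- cbind(dat$env, noise = rnorm(35))
  fit <- fit_gdm(dat$d, env = env2, K = 3)
  imp <- rowSums(fit$coefficients)
  expect_gt(imp["pred"], 10 * max(imp["noise"], 1e-6))
  env_shuf <- env2
  env_shuf[, "pred"] <- sample(env_shuf[, "pred"])
  fit_s <- fit_gdm(dat$d, env = env_shuf, K = 3)
  expect_lt(rowSums(fit_s$coefficients)["pred"], 0.25 * imp["pred"])
})

test_that("constrained fit matches a dense grid search on a tiny problem", {
  set.seed(14)
  n <- 6
  x <- c(0, 1.5, 3.2, 5.0, 7.7, 10)
  b <- ispline_basis(x, K = 1)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  z <- abs(eval_ispline(b, x)[pairs[, 1], 1] -
             eval_ispline(b, x)[pairs[, 2], 1])
  d_up <- pmin(pmax(1 - exp(-(0.15 + 0.9 * z)) + rnorm(15, 0, 0.03),
                    0.01), 0.99)
  d <- matrix(0, n, n); d[upper.tri(d)] <- d_up; d <- d + t(d)
  fit <- fit_gdm(d, env = cbind(pred = x), K = 1)
  coarse <- gdm_grid_oracle(d_up, z, seq(0, 1, by = 0.01),
                            seq(0, 3, by = 0.01))
  oracle <- gdm_grid_oracle(d_up, z,
                            seq(max(0, coarse$par[1] - 0.02),
                                coarse$par[1] + 0.02, by = 1e-4),
                            seq(max(0, coarse$par[2] - 0.02),
                                coarse$par[2] + 0.02, by = 1e-4))
  expect_equal(fit$intercept, oracle$par[1], tolerance = 1e-3)
  expect_equal(fit$coefficients[1, 1], oracle$par[2], tolerance = 1e-3)
})

test_that("partial responses are monotone and importance ranks are stable", {
  dat <- sim_gdm_data(n = 30, seed = 15)
  set.seed(16)
  env2 <- cbind(dat$env, other = rnorm(30))
  fit <- fit_gdm(dat$d, env = env2, K = 3)
  ti <- gdm_transform_and_importance(fit)
  for (cu in ti$curves) expect_true(all(diff(cu$partial_distance) >= -1e-9))
  expect_equal(unname(ti$importance),
               unname(sort(rowSums(fit$coefficients), decreasing = TRUE)))
  # curve endpoints: 0 at min, coefficient sum at max
  cu <- ti$curves[["pred"]]
  expect_equal(cu$partial_distance[1], 0, tolerance = 1e-9)
  expect_equal(cu$partial_distance[nrow(cu)],
               sum(fit$coefficients["pred", ]), tolerance = 1e-9)
  # site reordering leaves importance unchanged
  perm <- sample(30)
  fit_p <- fit_gdm(dat$d[perm, perm], env = env2[perm, , drop = FALSE], K = 3)
  expect_equal(rowSums(fit_p$coefficients), rowSums(fit$coefficients),
               tolerance = 1e-4)
})

test_that("the negative-exponential link behaves at reference points", {
  dat <- sim_gdm_data(n = 20, seed = 17)
  fit <- fit_gdm(dat$d, env = dat$env, K = 3)
  # eta = 0 -> 0; eta = ln 2 -> 0.5 (direct link check on the fit object)
  fit0 <- fit
  fit0$intercept <- 0; fit0$coefficients[] <- 0
  expect_equal(gdm_predict(fit0, dat$env[1, , drop = FALSE],
                           dat$env[1, , drop = FALSE]), 0)
  fit0$intercept <- log(2)
  expect_equal(gdm_predict(fit0, dat$env[1, , drop = FALSE],
                           dat$env[2, , drop = FALSE]), 0.5)
  # predictions live in [0, 1) and clamp out-of-range covariates
  p <- gdm_predict(fit, dat$env[1:5, , drop = FALSE],
                   dat$env[6:10, , drop = FALSE])
  expect_true(all(p >= 0 & p < 1))
  expect_warning(gdm_predict(fit, dat$env[1, , drop = FALSE] * 0 + 99,
                             dat$env[2, , drop = FALSE]), "clamped")
})

test_that("geographic distance enters through its own spline", {
  cfg <- sim_config(n_beaches = 12, n_transects = 1, n_levels = 4,
                    n_species = 25, seed = 18)
  sim <- simulate_metacommunity(cfg)
  cd <- composite_design(sim$design)
  pa <- sim$pa
  d <- jaccard_matrix(pa)
  geo <- geo_distance_matrix(cd$lon, cd$lat)
  env <- as.matrix(cd[, c("grain_size", "dist_low_tide")])
  fit <- fit_gdm(d, env = env, geo = geo, K = 3)
  expect_true("geographic" %in% fit$predictors)
  expect_true(all(fit$coefficients >= 0))
  expect_gte(fit$pct_deviance_explained, 0)
})
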