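test_that("trend surface has the right columns and parity", {
  set.seed(20)
  lon <- runif(30, 3, 9); lat <- runif(30, 51, 55)
  S <- trend_surface(lon, lat)
  expect_equal(colnames(S), c("x", "y", "x2", "y2", "xy"))
  expect_equal(unname(colMeans(S[, c("x", "y")])), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(S[, c("x", "y")], 2, sd)), c(1, 1),
               tolerance = 1e-9)
  # reflection x -> -x flips x and xy, preserves x2
  S2 <- trend_surface(-lon, lat)
  expect_equal(S2[, "x"], -S[, "x"])
  expect_equal(S2[, "xy"], -S[, "xy"])
  expect_equal(S2[, "x2"], S[, "x2"])
  expect_warning(S3 <- trend_surface(rep(1, 30), lat), "constant longitude")
  expect_equal(colnames(S3), c("y", "y2"))
})

test_that("single-species MC likelihood equals the closed form for any M", {
  set.seed(21)
  n <- 25
  X <- matrix(rnorm(n * 2), n, 2)
  a <- 0.3; b <- c(0.8, -0.5)
  eta <- a + drop(X %*% b)
  y <- matrix(rbinom(n, 1, pnorm(eta)), n, 1)
  params <- list(a = a, B = matrix(b, 1, 2), G = NULL, L = NULL)
  exact <- -sum(y * pnorm(eta, log.p = TRUE) +
                  (1 - y) * pnorm(-eta, log.p = TRUE))
  for (M in c(1, 7, 100))
    expect_equal(as.numeric(
      mc_probit_negloglik(params, y, X, M = M, seed = 2)),
      exact, tolerance = 1e-10)
})

test_that("saturated intercepts drive the negative log-likelihood to zero", {
  y <- matrix(1L, 10, 3)
  params <- list(a = rep(20, 3), B = NULL, G = NULL, L = NULL)
  expect_lt(as.numeric(mc_probit_negloglik(params, y, M = 10, seed = 1)),
            1e-10)
})

test_that("rank-1 MC likelihood matches Gauss-Hermite quadrature", {
  set.seed(22)
  n <- 10
  y <- matrix(rbinom(2 * n, 1, 0.5), n, 2)
  a <- c(0.2, -0.3); l <- c(0.8, 0.6)
  params <- list(a = a, B = NULL, G = NULL, L = matrix(l, 2, 1))
  # oracle: integrate the two-species product over the shared factor
  ll_gh <- sum(vapply(seq_len(n), function(i) {
    s <- 2 * y[i, ] - 1
    log(gh_expect(function(h)
      pnorm(s[1] * (a[1] + l[1] * h)) * pnorm(s[2] * (a[2] + l[2] * h)),
      n = 96))
  }, numeric(1)))
  nll_mc <- mc_probit_negloglik(params, y, M = 1e5, seed = 3)
  # per-site mean log-likelihood agrees to three decimals
  expect_lt(abs(as.numeric(nll_mc) - (-ll_gh)) / n, 1e-3)
})

test_that("chunked evaluation agrees with the direct core", {
  set.seed(23)
  n <- 15; S <- 4
  y <- matrix(rbinom(n * S, 1, 0.5), n, S)
  X <- matrix(rnorm(n * 2), n, 2)
  params <- list(a = rnorm(S), B = matrix(rnorm(S * 2), S, 2), G = NULL,
                 L = matrix(rnorm(S), S, 1))
  h <- metasandy:::antithetic_normal(64, 1, 9)
  direct <- metasandy:::mc_probit_core(params, y, X, NULL, h,
                                       grad = TRUE, species_ll = TRUE)
  chunked <- metasandy:::mc_probit_eval(params, y, X, NULL, h,
                                        species_ll = TRUE, score = TRUE,
                                        max_cells = 100)
  expect_equal(chunked$ll_site, direct$ll_site, tolerance = 1e-10)
  expect_equal(chunked$ll_species, direct$ll_species, tolerance = 1e-10)
  expect_equal(chunked$Gmat, direct$Gmat, tolerance = 1e-10)
})

test_that("MC likelihood converges in the number of draws", {
  cfg <- sim_config(n_beaches = 5, n_transects = 1, n_levels = 2,
                    n_species = 5, rank = 2, seed = 24)
  sim <- simulate_metacommunity(cfg)
  y <- unclass(sim$pa)[, ]
  params <- list(a = qnorm(pmin(pmax(colMeans(y), 0.1), 0.9)), B = NULL,
                 G = NULL, L = matrix(0.5, 5, 2))
  n1 <- mc_probit_negloglik(params, y, M = 1e4, seed = 5)
  n2 <- mc_probit_negloglik(params, y, M = 2e4, seed = 6)
  expect_lt(abs(n1 - n2) / abs(n1), 0.001)
})

test_that("loadings are identified only up to rotation", {
  set.seed(25)
  n <- 12; S <- 4; r <- 2
  y <- matrix(rbinom(n * S, 1, 0.5), n, S)
  L <- matrix(rnorm(S * r), S, r)
  theta <- 0.7
  Q <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  p1 <- list(a = rep(0, S), B = NULL, G = NULL, L = L)
  p2 <- list(a = rep(0, S), B = NULL, G = NULL, L = L %*% Q)
  expect_equal(tcrossprod(L), tcrossprod(L %*% Q), tolerance = 1e-12)
  # identical Sigma implies identical likelihood under the same draws only
  # in distribution; compare the large-M limits
  n1 <- mc_probit_negloglik(p1, y, M = 4e4, seed = 7)
  n2 <- mc_probit_negloglik(p2, y, M = 4e4, seed = 7)
  expect_equal(as.numeric(n1), as.numeric(n2), tolerance = 5e-3)
})

fit_small_jsdm <- function() {
  cfg <- sim_config(n_beaches = 12, n_transects = 1, n_levels = 8,
                    n_species = 12, rank = 2, seed = 26)
  sim <- simulate_metacommunity(cfg)
  dm <- design_matrices(sim$design)
  attr(sim$pa, "groups") <- setNames(
    sim$taxonomy$group[match(colnames(sim$pa), sim$taxonomy$otu_id)],
    colnames(sim$pa))
  fit <- fit_jsdm(sim$pa, dm$X, dm$S,
                  jsdm_spec(mc_samples = 50, rank = 2, iterations = 150,
                            mc_report = 2000, seed = 27))
  list(sim = sim, fit = fit, dm = dm)
}

test_that("fitting improves the likelihood and yields a valid correlation matrix", {
  sf <- fit_small_jsdm()
  fit <- sf$fit
  y <- unclass(sf$sim$pa)[, ]
  init <- metasandy:::init_params(y, sf$dm$X, sf$dm$S, 2, 27)
  nll_init <- mc_probit_negloglik(init, y, sf$dm$X, sf$dm$S, M = 2000,
                                  seed = 28)
  nll_final <- mc_probit_negloglik(fit$params, y, sf$dm$X, sf$dm$S,
                                   M = 2000, seed = 28)
  expect_lte(as.numeric(nll_final), as.numeric(nll_init))
  # R: PSD, unit diagonal, bounded entries
  expect_equal(unname(diag(fit$R)), rep(1, ncol(y)))
  expect_true(all(abs(fit$R) <= 1 + 1e-12))
  expect_gte(min(eigen(fit$Sigma, symmetric = TRUE,
                       only.values = TRUE)$values), 1 - 1e-8)
  expect_true(fit$pseudo_r2["mcfadden"] >= 0 &&
                fit$pseudo_r2["mcfadden"] <= 1)
  # same spec, same data: identical fit (determinism)
  fit2 <- fit_jsdm(sf$sim$pa, sf$dm$X, sf$dm$S,
                   jsdm_spec(mc_samples = 50, rank = 2, iterations = 150,
                             mc_report = 2000, seed = 27))
  expect_identical(fit$params, fit2$params)
})

test_that("Wald machinery scales correctly and flags aliased columns", {
  sf <- fit_small_jsdm()
  w <- wald_significance(sf$fit)
  expect_true(all(c("species", "term", "estimate", "se", "z", "p",
                    "stars") %in% names(w)))
  ok <- !is.na(w$se)
  expect_gt(sum(ok), 0)
  expect_equal(w$z[ok], w$estimate[ok] / w$se[ok])
  expect_equal(w$p[ok], 2 * pnorm(-abs(w$z[ok])))
  # halving the SE doubles |z| by construction of the ratio
  expect_equal(w$estimate[ok][1] / (w$se[ok][1] / 2), 2 * w$z[ok][1])
  expect_identical(metasandy:::star_codes(c(0.2, 0.04, 0.009, 5e-4, NA)),
                   c("", "*", "**", "***", ""))
})

test_that("association filtering keeps the extreme tails, symmetrically", {
  sf <- fit_small_jsdm()
  A <- association_matrix(sf$fit, tail = 0.025)
  expect_equal(unname(diag(A)), rep(1, ncol(A)))
  expect_true(isTRUE(all.equal(A, t(A))))
  off <- A[upper.tri(A)]
  kept <- sum(!is.na(off))
  expect_lte(kept, ceiling(0.05 * length(off)) + 2)  # percentile ties
  expect_gte(kept, 1)
  # rows come out ordered by higher-taxon group
  expect_false(is.unsorted(attr(A, "groups")))
})

test_that("two species with a strong shared loading are retained positive", {
  cfg <- sim_config(n_beaches = 25, n_transects = 1, n_levels = 8,
                    n_species = 10, rank = 1, biotic_scale = 0.3, seed = 29)
  d <- generate_design(cfg)
  p <- draw_latent_params(cfg)
  p$L[, 1] <- 0.2
  p$L[1:2, 1] <- 3          # a strongly coupled pair
  p$G[] <- 0
  pa <- simulate_presence_absence(d, p, seed = 30)
  dm <- design_matrices(d)
  fit <- fit_jsdm(pa, dm$X, NULL,
                  jsdm_spec(mc_samples = 50, rank = 1, iterations = 200,
                            mc_report = 2000, seed = 31))
  A <- association_matrix(fit, tail = 0.025)
  expect_false(is.na(A["OTU001", "OTU002"]))
  expect_gt(A["OTU001", "OTU002"], 0)
})
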