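#' Jaccard dissimilarity matrix from a presence/absence table
#'
#' `d(i, j) = 1 - |A & B| / |A | B|` on the OTU presence sets of the two
#' sites.
#'
#' @param pa binary site x OTU matrix.
#' @return Symmetric site x site matrix in \[0, 1\] with zero diagonal.
#' @export
jaccard_matrix <- function(pa) {
  pa <- (as.matrix(pa) > 0) + 0
  rich <- rowSums(pa)
  if (any(rich == 0))
    stop("site(s) with zero OTUs: ",
         paste(rownames(pa)[rich == 0], collapse = ", "))
  inter <- tcrossprod(pa)
  union <- outer(rich, rich, "+") - inter
  d <- 1 - inter / union
  diag(d) <- 0
  d
}

#' Monotone I-spline basis
#'
#' Order-2 (piecewise-quadratic) I-splines: integrals of order-2 M-splines
#' on quantile knots.  Each of the `K` basis functions is 0 at the predictor
#' minimum, 1 at the maximum and non-decreasing in between, so non-negative
#' coefficients yield a monotone transform.  Knots are placed at the
#' `seq(0, 1, length.out = K)` quantiles of the observed values (for K = 3:
#' minimum, median, maximum).  Evaluation clamps to the observed range.
#'
#' Internally each I-spline is a tail sum of B-splines one order higher on
#' the same interior knots (the classic I-/B-spline identity), evaluated via
#' [splines::splineDesign()].
#'
#' @param values observed predictor values used to place knots.
#' @param K number of basis functions (default 3).
#' @return Object of class `ispline_basis` with elements `knots` (interior),
#'   `boundary`, `K`, `order`.
#' @export
ispline_basis <- function(values, K = 3) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < K)
    stop("need at least K distinct predictor values")
  rng <- range(values)
  if (rng[1] == rng[2]) stop("constant predictor")
  # K = 1: the order-1 I-spline, a linear ramp over the range
  ord <- if (K == 1) 1L else 2L
  interior <- if (K >= 3) {
    qs <- quantile(values, probs = seq(0, 1, length.out = K),
                   names = FALSE)[-c(1, K)]
    pmin(pmax(qs, rng[1] + 1e-12), rng[2] - 1e-12)
  } else numeric(0)
  structure(list(boundary = rng, knots = interior, K = K, order = ord),
            class = "ispline_basis")
}

#' Evaluate an I-spline basis
#'
#' @param basis an [ispline_basis()].
#' @param x numeric values (clamped to the basis range).
#' @return Matrix `length(x)` x `K`; column k is the k-th I-spline.
#' @export
eval_ispline <- function(basis, x) {
  b <- basis$boundary
  x <- pmin(pmax(x, b[1]), b[2])
  if (basis$K == 1)
    return(matrix((x - b[1]) / (b[2] - b[1]), ncol = 1))
  ord <- basis$order + 1L  # B-splines one order above the M-splines
  kn <- c(rep(b[1], ord), basis$knots, rep(b[2], ord))
  B <- splines::splineDesign(kn, x, ord = ord, outer.ok = TRUE)
  # I_k = sum of B-splines k+1 .. K+1 (tail sums, skipping the first)
  nb <- ncol(B)
  out <- matrix(0, length(x), basis$K)
  for (k in seq_len(basis$K))
    out[, k] <- rowSums(B[, (k + 1):nb, drop = FALSE])
  out
}

# pairwise |I_k(x_i) - I_k(x_j)| design for one predictor
pair_design_env <- function(basis, values, pairs) {
  I <- eval_ispline(basis, values)
  abs(I[pairs[, 1], , drop = FALSE] - I[pairs[, 2], , drop = FALSE])
}

gdm_deviance <- function(d, dhat) {
  dhat <- pmin(pmax(dhat, 1e-9), 1 - 1e-9)
  t1 <- ifelse(d > 0, d * log(d / dhat), 0)
  t2 <- ifelse(d < 1, (1 - d) * log((1 - d) / (1 - dhat)), 0)
  sum(2 * (t1 + t2))
}

#' Fit a generalised dissimilarity model
#'
#' Models pairwise compositional dissimilarity as
#' `dhat = 1 - exp(-eta)` with
#' `eta = alpha + sum_p sum_k beta_pk |I_k(x_pi) - I_k(x_pj)|`, all
#' coefficients constrained non-negative, by minimising the binomial-type
#' deviance `sum 2[d log(d/dhat) + (1-d) log((1-d)/(1-dhat))]`
#' (with `0 log 0 = 0`).  Geographic distance enters through its own
#' I-spline basis evaluated on the pairwise km distance itself.  Site pairs
#' are weighted uniformly.
#'
#' @param d site x site dissimilarity matrix (e.g. [jaccard_matrix()]).
#' @param env site x covariate matrix (may be `NULL` if `geo` given).
#' @param geo optional site x site geographic distance matrix (km).
#' @param K I-splines per predictor (default 3).
#' @param max_iter optimiser iteration cap.
#' @return Object of class `gdm_fit`: `intercept`, `coefficients`
#'   (predictor x K), `bases`, `null_deviance`, `model_deviance`,
#'   `pct_deviance_explained`, `predictors`.
#' @export
fit_gdm <- function(d, env = NULL, geo = NULL, K = 3, max_iter = 1000) {
  d <- as.matrix(d)
  n <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  dv <- d[upper.tri(d)]
  if (is.null(env) && is.null(geo)) stop("need env and/or geo predictors")

  bases <- list(); Z <- list()
  if (!is.null(env)) {
    env <- as.matrix(env)
    stopifnot(nrow(env) == n)
    for (p in colnames(env)) {
      bases[[p]] <- ispline_basis(env[, p], K = K)
      Z[[p]] <- pair_design_env(bases[[p]], env[, p], pairs)
    }
  }
  if (!is.null(geo)) {
    gkm <- geo[upper.tri(geo)]
    bases[["geographic"]] <- ispline_basis(gkm, K = K)
    Z[["geographic"]] <- eval_ispline(bases[["geographic"]], gkm)
  }
  preds <- names(Z)
  Zm <- do.call(cbind, Z)                       # pairs x (P*K)
  np <- ncol(Zm)

  obj <- function(par) {
    eta <- par[1] + drop(Zm %*% par[-1])
    gdm_deviance(dv, 1 - exp(-eta))
  }
  grad <- function(par) {
    eta <- par[1] + drop(Zm %*% par[-1])
    dhat <- pmin(pmax(1 - exp(-eta), 1e-9), 1 - 1e-9)
    # dD/deta = 2[ (1-d) - d (1-dhat)/dhat ]
    g <- 2 * ((1 - dv) - dv * (1 - dhat) / dhat)
    c(sum(g), drop(crossprod(Zm, g)))
  }
  start <- c(max(0.01, -log(1 - pmin(mean(dv), 0.99))), rep(0.01, np))
  fit <- optim(start, obj, grad, method = "L-BFGS-B",
               lower = rep(0, np + 1),
               control = list(maxit = max_iter, factr = 1e4))
  if (fit$convergence != 0 && fit$convergence != 52) {
    gn <- sqrt(sum(grad(fit$par)^2))
    stop("GDM optimiser did not converge (code ", fit$convergence,
         ", gradient norm ", signif(gn, 3), ")")
  }
  # null model: intercept only
  null_fit <- optimize(function(a) gdm_deviance(dv, 1 - exp(-a)),
                       c(0, 20), tol = 1e-10)
  D0 <- null_fit$objective
  Dm <- fit$value
  # no explainable deviance (all observed dissimilarities equal)
  pct <- if (D0 <= 1e-8) 0 else 100 * (1 - Dm / D0)
  coefs <- matrix(fit$par[-1], nrow = length(preds), byrow = TRUE,
                  dimnames = list(preds, paste0("I", seq_len(K))))
  structure(list(intercept = fit$par[1], coefficients = coefs,
                 bases = bases, null_deviance = D0, model_deviance = Dm,
                 pct_deviance_explained = pct,
                 null_intercept = null_fit$minimum,
                 predictors = preds, K = K, n_pairs = length(dv)),
            class = "gdm_fit")
}

#' Predictor importance and partial-response curves from a GDM fit
#'
#' Importance of predictor `p` is the sum of its I-spline coefficients (the
#' total partial ecological distance across the predictor's range); the
#' partial-response curve is `f_p(x) = sum_k beta_pk I_k(x)` on a grid.
#'
#' @param fit a `gdm_fit`.
#' @param n_grid grid points per curve.
#' @return List with `importance` (named, sorted decreasing) and `curves`
#'   (per predictor, data frame of `x` and `partial_distance`).
#' @export
gdm_transform_and_importance <- function(fit, n_grid = 200) {
  imp <- rowSums(fit$coefficients)
  curves <- lapply(fit$predictors, function(p) {
    b <- fit$bases[[p]]
    x <- seq(b$boundary[1], b$boundary[2], length.out = n_grid)
    data.frame(x = x,
               partial_distance = drop(eval_ispline(b, x) %*%
                                         fit$coefficients[p, ]))
  })
  names(curves) <- fit$predictors
  list(importance = sort(imp, decreasing = TRUE), curves = curves)
}

#' Predict dissimilarity for new site pairs from a GDM fit
#'
#' @param fit a `gdm_fit`.
#' @param env_i,env_j covariate row vectors (or matrices) of the two sites
#'   of each pair, columns as in fitting; `NULL` if no env predictors.
#' @param geo_km optional pairwise geographic distances.
#' @return Predicted dissimilarities in \[0, 1).  Covariates outside the
#'   training range are clamped with a warning.
#' @export
gdm_predict <- function(fit, env_i = NULL, env_j = NULL, geo_km = NULL) {
  n <- if (!is.null(env_i)) nrow(as.matrix(env_i)) else length(geo_km)
  eta <- rep(fit$intercept, n)
  warn_clamp <- FALSE
  for (p in fit$predictors) {
    b <- fit$bases[[p]]
    if (p == "geographic") {
      if (is.null(geo_km)) stop("fit includes geographic distance: supply geo_km")
      x <- geo_km
      if (any(x < b$boundary[1] | x > b$boundary[2])) warn_clamp <- TRUE
      Zp <- eval_ispline(b, x)
    } else {
      xi <- as.matrix(env_i)[, p]; xj <- as.matrix(env_j)[, p]
      if (any(c(xi, xj) < b$boundary[1] | c(xi, xj) > b$boundary[2]))
        warn_clamp <- TRUE
      Zp <- abs(eval_ispline(b, xi) - eval_ispline(b, xj))
    }
    eta <- eta + drop(Zp %*% fit$coefficients[p, ])
  }
  if (warn_clamp) warning("covariates outside training range were clamped")
  1 - exp(-eta)
}
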