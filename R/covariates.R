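#' Standardise an environmental covariate matrix
#'
#' Centres and scales every column to mean 0, sd 1, recording the
#' standardisation so new values can be placed on the same scale.
#'
#' @param env numeric site x covariate matrix (or data frame).
#' @return Standardised matrix with attribute `"standardisation"` (list of
#'   `mean` and `sd` per column).
#' @export
standardise_env <- function(env) {
  env <- as.matrix(env)
  if (any(!is.finite(env))) stop("missing or non-finite covariate values")
  s <- apply(env, 2, sd)
  if (any(s == 0))
    stop("constant covariate column(s): ",
         paste(colnames(env)[s == 0], collapse = ", "))
  m <- colMeans(env)
  out <- sweep(sweep(env, 2, m), 2, s, "/")
  attr(out, "standardisation") <- list(mean = m, sd = s)
  out
}

#' Prune highly correlated covariates
#'
#' Greedy pairwise pruning: while any pair has `|r| > r_max`, take the most
#' correlated pair and drop the member with the larger mean absolute
#' correlation to all remaining covariates (ties broken by column order).
#'
#' @param env site x covariate matrix.
#' @param r_max absolute Pearson correlation threshold (strict; default 0.7).
#' @return List with `env` (pruned matrix) and `report` (data frame of drops
#'   with the offending `|r|`).
#' @export
correlation_prune <- function(env, r_max = 0.7) {
  env <- as.matrix(env)
  if (ncol(env) < 2) stop("need at least two covariates")
  s <- apply(env, 2, sd)
  if (any(s == 0))
    stop("constant covariate column(s): ",
         paste(colnames(env)[s == 0], collapse = ", "))
  dropped <- data.frame(covariate = character(0), abs_r = numeric(0))
  repeat {
    if (ncol(env) < 2) break
    r <- abs(cor(env)); diag(r) <- 0
    if (max(r) <= r_max) break
    idx <- which(r == max(r), arr.ind = TRUE)[1, ]
    mean_abs <- colMeans(abs(cor(env)))  # includes the self 1 equally for all
    victim <- if (mean_abs[idx[1]] >= mean_abs[idx[2]]) idx[1] else idx[2]
    dropped <- rbind(dropped, data.frame(covariate = colnames(env)[victim],
                                         abs_r = max(r)))
    env <- env[, -victim, drop = FALSE]
  }
  list(env = env, report = dropped)
}

vif_values <- function(env) {
  vapply(seq_len(ncol(env)), function(k) {
    # perfect fits are expected under exact collinearity: VIF becomes Inf
    r2 <- suppressWarnings(
      summary(lm(env[, k] ~ env[, -k, drop = FALSE]))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Stepwise covariate exclusion by variance inflation factor
#'
#' Iteratively drops the covariate with the largest VIF
#' (`1 / (1 - R2)` from regressing it on the others) until every VIF is
#' below `vif_max`.  Perfect collinearity yields an infinite VIF and the
#' column is dropped, not an error.
#'
#' @param env site x covariate matrix.
#' @param vif_max threshold (default 2; note VIF >= 1 always).
#' @return List with `env` (retained matrix), `report` (VIF trajectory per
#'   step) and `final_vif` (named VIFs of the retained set).
#' @export
vif_stepwise <- function(env, vif_max = 2) {
  env <- as.matrix(env)
  if (ncol(env) < 2) stop("need at least two covariates")
  if (nrow(env) <= ncol(env)) stop("need more sites than covariates")
  if (vif_max <= 1) stop("vif_max must exceed 1 (VIF >= 1 by construction)")
  traj <- list()
  repeat {
    v <- setNames(vif_values(env), colnames(env))
    traj[[length(traj) + 1]] <- v
    if (max(v) < vif_max || ncol(env) <= 2) break
    env <- env[, -which.max(v), drop = FALSE]
  }
  list(env = env, report = traj,
       final_vif = setNames(vif_values(env), colnames(env)))
}

#' Great-circle distance matrix between sites (km)
#'
#' Haversine distances on a sphere of radius 6371 km.
#'
#' @param lon,lat coordinates in decimal degrees.
#' @return Symmetric site x site matrix in kilometres, zero diagonal.
#' @export
geo_distance_matrix <- function(lon, lat) {
  if (any(abs(lat) > 90)) stop("latitude outside [-90, 90]")
  if (any(abs(lon) > 180)) stop("longitude outside [-180, 180]")
  m <- geosphere::distm(cbind(lon, lat),
                        fun = function(a, b)
                          geosphere::distHaversine(a, b, r = 6371000)) / 1000
  dimnames(m) <- NULL
  m
}

#' Per-site environmental or spatial distinctiveness
#'
#' A site's distinctiveness is its mean distance to all other sites —
#' Euclidean distance on standardised covariates for environmental
#' distinctiveness, or a geographic km matrix for spatial distinctiveness —
#' z-scored across sites.  `method = "centroid"` uses distance to the
#' feature centroid instead of the mean pairwise distance.
#'
#' @param x site x feature matrix, or a precomputed distance matrix with
#'   `is_distance = TRUE`.
#' @param is_distance interpret `x` as a site x site distance matrix.
#' @param method `"mean"` (mean pairwise distance, default) or `"centroid"`.
#' @return Named numeric vector of z-scored distinctiveness values.
#' @export
distinctiveness <- function(x, is_distance = FALSE,
                            method = c("mean", "centroid")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 sites")
  raw <- if (is_distance) {
    stopifnot(nrow(x) == ncol(x))
    rowSums(x) / (n - 1)
  } else if (method == "centroid") {
    sqrt(rowSums(sweep(x, 2, colMeans(x))^2))
  } else {
    rowSums(as.matrix(dist(x))) / (n - 1)
  }
  ctr <- raw - mean(raw)
  s <- sqrt(mean(ctr^2))  # population sd: z-scores satisfy sum(z^2) = n
  if (s == 0) stop("degenerate distinctiveness: all sites identical")
  setNames(ctr / s, rownames(x))
}
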