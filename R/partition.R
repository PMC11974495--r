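#' Fit the 8-model grid over assembly components
#'
#' Fits the joint model for every subset of the three assembly components —
#' E (environment, the `X B'` term), S (space, the trend surface `S G'`)
#' and C (biotic association, the latent factor `L`) — under the same
#' specification and seed.  A component excluded from a subset has its
#' parameters removed entirely (C excluded means rank 0, an independent
#' probit).  Per-site and per-species McFadden R-squared values are computed
#' against the exact intercept-only probit.
#'
#' @param y binary site x species matrix.
#' @param X standardised environmental design.
#' @param S_design spatial trend surface.
#' @param spec a [jsdm_spec()].
#' @return Object of class `component_grid`: per-subset fits' log-likelihood
#'   vectors and R-squared matrices, plus the full fit.
#' @export
component_loglik_grid <- function(y, X, S_design, spec = jsdm_spec()) {
  subsets <- list(none = character(0), E = "E", S = "S", C = "C",
                  ES = c("E", "S"), EC = c("E", "C"), SC = c("S", "C"),
                  ESC = c("E", "S", "C"))
  null <- null_probit(as.matrix(y))
  fits <- list(); site_r2 <- list(); species_r2 <- list()
  full_fit <- NULL
  for (nm in names(subsets)) {
    comps <- subsets[[nm]]
    if (!length(comps)) {
      site_r2[[nm]] <- rep(0, nrow(y))
      species_r2[[nm]] <- rep(0, ncol(y))
      next
    }
    sp <- spec
    sp$rank <- if ("C" %in% comps) spec$rank else 0L
    f <- tryCatch(
      fit_jsdm(y, X = if ("E" %in% comps) X else NULL,
               S_design = if ("S" %in% comps) S_design else NULL,
               spec = sp),
      error = function(e) stop("component grid member '", nm,
                               "' failed: ", conditionMessage(e)))
    site_r2[[nm]] <- 1 - f$ll_site / null$ll_site
    species_r2[[nm]] <- 1 - f$ll_species / null$ll_species
    fits[[nm]] <- list(log_likelihood = f$log_likelihood)
    if (nm == "ESC") full_fit <- f
  }
  structure(list(site_r2 = site_r2, species_r2 = species_r2,
                 fits = fits, full_fit = full_fit, null = null,
                 richness = rowSums(y),
                 site_ids = rownames(y), species_ids = colnames(y)),
            class = "component_grid")
}

# Shapley values for 3 players from a value function given as a named list
# v over subsets "none","E","S","C","ES","EC","SC","ESC" of vectors.
shapley3 <- function(v) {
  val <- function(set) {
    key <- paste0(c("E", "S", "C")[c("E", "S", "C") %in% set],
                  collapse = "")
    if (key == "") key <- "none"
    v[[key]]
  }
  players <- c("E", "S", "C")
  out <- list()
  for (p in players) {
    others <- setdiff(players, p)
    contrib <- 0
    subs <- list(character(0), others[1], others[2], others)
    wts <- c(2, 1, 1, 2) / 6   # |T|! (3-|T|-1)! / 3!
    for (k in seq_along(subs))
      contrib <- contrib + wts[k] * (val(c(subs[[k]], p)) - val(subs[[k]]))
    out[[p]] <- contrib
  }
  out
}

#' Shapley variation partitioning of a component grid
#'
#' Allocates each site's (and species') full-model R-squared among
#' environment, space and biotic association by Shapley averaging of the
#' marginal R-squared gains over all orderings of the three components.
#' The allocation is exact: contributions sum to the full-model R-squared
#' (efficiency), are symmetric in the component labels, and reduce to the
#' solo gains when the components are additive.  Shares are the absolute
#' contributions normalised to sum 1.
#'
#' @param grid a [component_loglik_grid()] result.
#' @return Object of class `partition_result`: data frames `sites` (site,
#'   richness, partial_E/S/C, share_E/S/C) and `species` (species,
#'   partial_E/S/C, share_E/S/C); sites with all-zero contributions carry
#'   `NA` shares and are flagged in attribute `"degenerate_sites"`.
#' @export
partition_r2 <- function(grid) {
  stopifnot(inherits(grid, "component_grid"))
  ph_site <- shapley3(grid$site_r2)
  ph_sp <- shapley3(grid$species_r2)
  share <- function(ph) {
    tot <- abs(ph$E) + abs(ph$S) + abs(ph$C)
    tot0 <- tot == 0
    tot[tot0] <- NA
    list(E = abs(ph$E) / tot, S = abs(ph$S) / tot, C = abs(ph$C) / tot,
         degenerate = tot0)
  }
  ss <- share(ph_site); sp <- share(ph_sp)
  sites <- data.frame(site = grid$site_ids, richness = grid$richness,
                      partial_E = ph_site$E, partial_S = ph_site$S,
                      partial_C = ph_site$C, share_E = ss$E,
                      share_S = ss$S, share_C = ss$C, row.names = NULL)
  species <- data.frame(species = grid$species_ids,
                        partial_E = ph_sp$E, partial_S = ph_sp$S,
                        partial_C = ph_sp$C, share_E = sp$E,
                        share_S = sp$S, share_C = sp$C, row.names = NULL)
  structure(list(sites = sites, species = species,
                 full_site_r2 = grid$site_r2$ESC,
                 full_species_r2 = grid$species_r2$ESC),
            class = "partition_result",
            degenerate_sites = grid$site_ids[ss$degenerate])
}

#' Variation partitioning of assembly processes
#'
#' Convenience wrapper: fits the component grid and Shapley-partitions it.
#'
#' @inheritParams component_loglik_grid
#' @return A `partition_result` (the grid is attached as attribute
#'   `"grid"`).
#' @export
partition_assembly <- function(y, X, S_design, spec = jsdm_spec()) {
  grid <- component_loglik_grid(y, X, S_design, spec)
  out <- partition_r2(grid)
  attr(out, "grid") <- grid
  out
}

pinball_loss <- function(res, tau = 0.5) sum(res * (tau - (res < 0)))

# IRLS for quantile regression (epsilon-annealed reweighting), followed by
# an interpolation polish: an optimal median fit passes through p data
# points, so refit exactly through the p best-fitting candidates.
fit_pinball <- function(Xd, yv, tau = 0.5) {
  p <- ncol(Xd)
  beta <- qr.coef(qr(Xd), yv)
  for (eps in c(1e-2, 1e-4, 1e-6, 1e-9)) {
    for (it in 1:30) {
      r <- yv - drop(Xd %*% beta)
      w <- ifelse(r >= 0, tau, 1 - tau) / pmax(abs(r), eps)
      b2 <- tryCatch(qr.coef(qr(Xd * sqrt(w)), yv * sqrt(w)),
                     error = function(e) beta)
      if (any(is.na(b2))) b2 <- beta
      if (max(abs(b2 - beta)) < 1e-12) { beta <- b2; break }
      beta <- b2
    }
  }
  best <- pinball_loss(yv - drop(Xd %*% beta), tau)
  # polish: exact fits through p of the 2p+2 smallest-residual points
  r <- abs(yv - drop(Xd %*% beta))
  cand <- order(r)[seq_len(min(length(yv), 2 * p + 2))]
  if (length(cand) >= p) {
    combs <- utils::combn(cand, p)
    for (k in seq_len(ncol(combs))) {
      idx <- combs[, k]
      b <- tryCatch(solve(Xd[idx, , drop = FALSE], yv[idx]),
                    error = function(e) NULL)
      if (is.null(b) || any(!is.finite(b))) next
      loss <- pinball_loss(yv - drop(Xd %*% b), tau)
      if (loss < best - 1e-12) { best <- loss; beta <- b }
    }
  }
  list(coefficients = beta, loss = best)
}

#' Median (50% quantile) polynomial regression with bootstrap inference
#'
#' Minimises the pinball (check) loss at tau = 0.5 for a polynomial design
#' of the given degree.  P-values for the non-intercept coefficients come
#' from a case-resampling bootstrap: twice the smaller tail proportion of
#' the bootstrap coefficient distribution on either side of zero.
#'
#' @param y response (e.g. a component share per site).
#' @param x predictor.
#' @param degree polynomial degree (1 or 2; default 2).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed bootstrap seed.
#' @return Object of class `quantreg_fit`: `coefficients`, `p_values`
#'   (`NA` for the intercept), `significant` (any non-intercept p < 0.05),
#'   `tau`, `degree`, `loss`.
#' @export
median_quantile_regression <- function(y, x, degree = 2, n_boot = 1000,
                                       seed = 1L) {
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]; x <- x[keep]
  if (length(y) < degree + 2)
    stop("need at least ", degree + 2, " observations")
  if (sd(x) == 0) stop("degenerate predictor (sd 0)")
  Xd <- outer(x, 0:degree, `^`)
  colnames(Xd) <- c("(Intercept)", paste0("x", seq_len(degree)))
  fit <- fit_pinball(Xd, y)
  cf <- setNames(fit$coefficients, colnames(Xd))
  p <- rep(NA_real_, length(cf)); names(p) <- names(cf)
  if (n_boot > 0) {
    set.seed(seed)
    bb <- matrix(NA_real_, n_boot, length(cf))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(length(y), replace = TRUE)
      if (sd(x[idx]) == 0) next
      bb[b, ] <- fit_pinball(Xd[idx, , drop = FALSE], y[idx])$coefficients
    }
    for (k in 2:length(cf)) {
      v <- bb[is.finite(bb[, k]), k]
      p[k] <- min(1, 2 * min(mean(v <= 0), mean(v >= 0)))
    }
  }
  structure(list(coefficients = cf, p_values = p,
                 significant = any(p[-1] < 0.05, na.rm = TRUE),
                 tau = 0.5, degree = degree, loss = fit$loss,
                 n = length(y)),
            class = "quantreg_fit")
}

#' Quantile-regression table of assembly-process shares against predictors
#'
#' For every (component share, predictor) pair fits a median quantile
#' regression of the per-site share on the predictor, flagging significant
#' trends — the tabular backbone of panel plots of assembly-process
#' importance against environmental distinctiveness, spatial
#' distinctiveness, OTU richness and individual covariates.
#'
#' @param partition a `partition_result`.
#' @param predictors data frame of per-site predictors, rows aligned with
#'   `partition$sites` (e.g. env/spatial distinctiveness, richness,
#'   standardised covariates).
#' @param degree polynomial degree of each regression (default 2).
#' @param n_boot,seed bootstrap settings passed through.
#' @return Data frame: predictor, component, coefficients (one column per
#'   polynomial term), p-values and `significant`.
#' @export
internal_structure_analysis <- function(partition, predictors, degree = 2,
                                        n_boot = 1000, seed = 1L) {
  stopifnot(inherits(partition, "partition_result"))
  predictors <- as.data.frame(predictors)
  if (nrow(predictors) != nrow(partition$sites))
    stop("predictors must have one row per site")
  comps <- c(E = "share_E", S = "share_S", C = "share_C")
  rows <- list()
  for (pn in names(predictors)) {
    for (cn in names(comps)) {
      f <- median_quantile_regression(partition$sites[[comps[cn]]],
                                      predictors[[pn]], degree = degree,
                                      n_boot = n_boot,
                                      seed = seed + length(rows))
      rows[[length(rows) + 1]] <- data.frame(
        predictor = pn, component = cn,
        t(f$coefficients), t(setNames(f$p_values,
                                      paste0("p_", names(f$p_values)))),
        significant = f$significant, check.names = FALSE)
    }
  }
  do.call(rbind, rows)
}
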