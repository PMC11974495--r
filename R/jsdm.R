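#' Second-order spatial trend surface
#'
#' Z-scores each coordinate, then returns the columns
#' `(x, y, x^2, y^2, xy)` — a second-order polynomial surface capturing
#' smooth spatial trends in occurrence.  A constant coordinate's columns are
#' dropped with a warning.
#'
#' @param lon,lat site coordinates (decimal degrees).
#' @return Site x (up to 5) matrix with named columns.
#' @export
trend_surface <- function(lon, lat) {
  cols <- list()
  if (sd(lon) > 0) cols$x <- drop(scale(lon)) else
    warning("constant longitude: x columns dropped")
  if (sd(lat) > 0) cols$y <- drop(scale(lat)) else
    warning("constant latitude: y columns dropped")
  out <- list()
  if (!is.null(cols$x)) out$x <- cols$x
  if (!is.null(cols$y)) out$y <- cols$y
  if (!is.null(cols$x)) out$x2 <- cols$x^2
  if (!is.null(cols$y)) out$y2 <- cols$y^2
  if (!is.null(cols$x) && !is.null(cols$y)) out$xy <- cols$x * cols$y
  if (!length(out)) stop("both coordinates constant")
  do.call(cbind, out)
}

#' Specification of a joint species distribution model fit
#'
#' @param mc_samples Monte-Carlo draws used during optimisation (common
#'   random numbers across iterations; antithetic pairs).
#' @param rank latent dimension of the species covariance factor; `NULL`
#'   defaults to `ceiling(S / 2)` at fit time.
#' @param iterations optimiser iterations (default 500).
#' @param learning_rate Adam step size.
#' @param patience plateau-scheduler patience: after this many
#'   non-improving iterations the learning rate is multiplied by
#'   `reduce_factor` (defaults 10 and 0.9).
#' @param reduce_factor multiplicative learning-rate decay in (0, 1).
#' @param mc_report Monte-Carlo draws for the final reported log-likelihood.
#' @param seed integer seed for the Monte-Carlo draws and initialisation.
#' @return Object of class `jsdm_spec`.
#' @export
jsdm_spec <- function(mc_samples = 100, rank = NULL, iterations = 500,
                      learning_rate = 0.05, patience = 10,
                      reduce_factor = 0.9, mc_report = 10000, seed = 1L) {
  stopifnot(mc_samples >= 1, iterations >= 1,
            reduce_factor > 0, reduce_factor < 1, patience >= 1)
  structure(list(mc_samples = as.integer(mc_samples), rank = rank,
                 iterations = as.integer(iterations),
                 learning_rate = learning_rate, patience = as.integer(patience),
                 reduce_factor = reduce_factor,
                 mc_report = as.integer(mc_report), seed = as.integer(seed)),
            class = "jsdm_spec")
}

# antithetic, moment-matched standard-normal draws, M x r (M rounded up to
# even): pairing h with -h zeroes the sample mean, rescaling fixes each
# column's sample variance at exactly 1 — both standard variance-reduction
# devices for smooth integrands
antithetic_normal <- function(M, r, seed) {
  set.seed(seed)
  half <- ceiling(M / 2)
  h <- matrix(rnorm(half * r), half, r)
  h <- rbind(h, -h)
  if (half > 1)
    h <- sweep(h, 2, sqrt(colMeans(h^2)), "/")
  h
}

# Core Monte-Carlo probit machinery.
# params: list(a = S-vector, B = S x Kx or NULL, G = S x Ks or NULL,
#              L = S x r or NULL)
# Returns per-site log-likelihood, per-species marginal log-likelihood and,
# if grad = TRUE, analytic gradients.
mc_probit_core <- function(params, y, X, S_design, h, grad = FALSE,
                           species_ll = FALSE) {
  n <- nrow(y); S <- ncol(y)
  if (is.null(h) || !nrow(h)) h <- matrix(0, 1, 0)
  M <- nrow(h)
  s <- 2 * y - 1
  mu <- matrix(params$a, n, S, byrow = TRUE)
  if (!is.null(params$B)) mu <- mu + X %*% t(params$B)
  if (!is.null(params$G)) mu <- mu + S_design %*% t(params$G)
  idx_site <- rep(seq_len(n), M)
  A <- mu[idx_site, , drop = FALSE]
  if (!is.null(params$L) && ncol(params$L) > 0 && ncol(h) > 0) {
    lh <- h %*% t(params$L)                       # M x S
    A <- A + lh[rep(seq_len(M), each = n), , drop = FALSE]
  }
  sA <- s[idx_site, , drop = FALSE] * A
  lPhi <- pnorm(sA, log.p = TRUE)
  lp <- matrix(rowSums(lPhi), n, M)               # log p_im
  mx <- apply(lp, 1, max)
  wraw <- exp(lp - mx)
  sw <- rowSums(wraw)
  ll_site <- mx + log(sw) - log(M)
  out <- list(ll_site = ll_site, ll = sum(ll_site))
  if (species_ll) {
    # per-species marginal MC likelihood with the same draws
    out$ll_species <- vapply(seq_len(S), function(j) {
      lj <- matrix(lPhi[, j], n, M)
      mj <- apply(lj, 1, max)
      sum(mj + log(rowMeans(exp(lj - mj))))
    }, numeric(1))
  }
  if (grad) {
    w <- wraw / sw                                 # n x M mixture weights
    ratio <- s[idx_site, , drop = FALSE] *
      exp(-0.918938533204673 - 0.5 * sA * sA - lPhi)  # phi(a)/Phi(a), stable
    Gfull <- ratio * as.vector(w)                  # weight rows by w_im
    Gmat <- rowsum(Gfull, group = idx_site, reorder = TRUE)   # n x S
    g <- list(a = -colSums(Gmat))
    if (!is.null(params$B)) g$B <- -t(crossprod(X, Gmat))
    if (!is.null(params$G)) g$G <- -t(crossprod(S_design, Gmat))
    if (!is.null(params$L) && ncol(params$L) > 0) {
      Hrep <- h[rep(seq_len(M), each = n), , drop = FALSE]
      g$L <- -crossprod(Gfull, Hrep)
    }
    out$grad <- g
    out$Gmat <- Gmat
  }
  out
}

# Chunked two-pass evaluation for large Monte-Carlo samples: per-site and
# per-species log-likelihoods plus the per-site score factor Gmat
# (sum_m w_im ratio_ijm) without materialising the (n*M) x S array at once.
mc_probit_eval <- function(params, y, X, S_design, h, species_ll = TRUE,
                           score = TRUE, max_cells = 4e6) {
  n <- nrow(y); S <- ncol(y); M <- nrow(h)
  s <- 2 * y - 1
  mu <- matrix(params$a, n, S, byrow = TRUE)
  if (!is.null(params$B)) mu <- mu + X %*% t(params$B)
  if (!is.null(params$G)) mu <- mu + S_design %*% t(params$G)
  has_L <- !is.null(params$L) && ncol(params$L) > 0 && ncol(h) > 0
  chunk <- max(1L, floor(max_cells / (n * S)))
  blocks <- split(seq_len(M), ceiling(seq_len(M) / chunk))

  lp <- matrix(0, n, M)
  spMx <- matrix(-Inf, n, S); spSm <- matrix(0, n, S)
  for (bl in blocks) {
    A <- mu[rep(seq_len(n), length(bl)), , drop = FALSE]
    if (has_L) {
      lh <- h[bl, , drop = FALSE] %*% t(params$L)
      A <- A + lh[rep(seq_along(bl), each = n), , drop = FALSE]
    }
    lPhi <- pnorm(s[rep(seq_len(n), length(bl)), , drop = FALSE] * A,
                  log.p = TRUE)
    lp[, bl] <- matrix(rowSums(lPhi), n, length(bl))
    if (species_ll) {
      for (j in seq_len(S)) {
        Vj <- matrix(lPhi[, j], n, length(bl))
        bm <- do.call(pmax, c(as.data.frame(Vj), list(spMx[, j])))
        spSm[, j] <- spSm[, j] * exp(spMx[, j] - bm) +
          rowSums(exp(Vj - bm))
        spMx[, j] <- bm
      }
    }
  }
  mx <- apply(lp, 1, max)
  lse <- mx + log(rowSums(exp(lp - mx)))
  out <- list(ll_site = lse - log(M), ll = sum(lse - log(M)))
  if (species_ll)
    out$ll_species <- colSums(spMx + log(spSm) - log(M))
  if (score) {
    Gmat <- matrix(0, n, S)
    for (bl in blocks) {
      idx <- rep(seq_len(n), length(bl))
      A <- mu[idx, , drop = FALSE]
      if (has_L) {
        lh <- h[bl, , drop = FALSE] %*% t(params$L)
        A <- A + lh[rep(seq_along(bl), each = n), , drop = FALSE]
      }
      sA <- s[idx, , drop = FALSE] * A
      lPhi <- pnorm(sA, log.p = TRUE)
      w <- exp(matrix(rowSums(lPhi), n, length(bl)) - lse)
      ratio <- s[idx, , drop = FALSE] *
        exp(-0.918938533204673 - 0.5 * sA * sA - lPhi)
      Gmat <- Gmat + rowsum(ratio * as.vector(w), group = idx,
                            reorder = TRUE)
    }
    out$Gmat <- Gmat
  }
  out
}

#' Monte-Carlo multivariate probit negative log-likelihood
#'
#' Evaluates
#' `-sum_i log[(1/M) sum_m prod_j Phi((2 y_ij - 1)(mu_ij + (L h_m)_j))]`
#' with `mu = intercept + X B' + S G'` and `h_m` i.i.d. standard-normal
#' rank-vectors (antithetic, fixed by `seed`: common random numbers).
#'
#' @param params list with `a` (intercepts), and optionally `B`, `G`, `L`.
#' @param y binary site x species matrix.
#' @param X standardised environmental design.
#' @param S_design spatial trend-surface design.
#' @param M number of Monte-Carlo draws.
#' @param seed seed for the draws.
#' @return Scalar negative log-likelihood; attribute `"ll_site"` holds the
#'   per-site log-likelihood vector.
#' @export
mc_probit_negloglik <- function(params, y, X = NULL, S_design = NULL,
                                M = 1000, seed = 1L) {
  if (any(!vapply(params, function(p) all(is.finite(p)), logical(1))))
    stop("non-finite parameters")
  r <- if (is.null(params$L)) 0 else ncol(params$L)
  h <- if (r > 0) antithetic_normal(M, r, seed) else NULL
  res <- mc_probit_core(params, y, X, S_design, h, grad = FALSE)
  structure(-res$ll, ll_site = res$ll_site)
}

init_params <- function(y, X, S_design, r, seed) {
  S <- ncol(y)
  prev <- pmin(pmax(colMeans(y), 0.02), 0.98)
  set.seed(seed + 7L)
  par <- list(a = qnorm(prev),
              B = if (!is.null(X)) matrix(0, S, ncol(X)) else NULL,
              G = if (!is.null(S_design)) matrix(0, S, ncol(S_design)) else NULL,
              L = if (r > 0) matrix(rnorm(S * r, 0, 0.05), S, r) else NULL)
  # warm start from independent per-species probit GLMs on a maximal
  # linearly independent feature set (straight-coastline designs make the
  # trend surface rank-deficient); coefficients are clipped against
  # separation.  The optimiser then mainly learns the latent factor.
  feats <- cbind(if (!is.null(X)) X, if (!is.null(S_design)) S_design)
  if (!is.null(feats)) {
    Fm <- cbind(1, feats)
    qrF <- qr(Fm)
    keep <- sort(qrF$pivot[seq_len(qrF$rank)])
    for (j in seq_len(S)) {
      cf <- rep(0, ncol(Fm))
      fit <- tryCatch(
        suppressWarnings(glm.fit(Fm[, keep, drop = FALSE], y[, j],
                                 family = binomial("probit"),
                                 control = list(maxit = 25))),
        error = function(e) NULL)
      if (is.null(fit)) next
      cf[keep] <- fit$coefficients
      cf[!is.finite(cf)] <- 0
      cf <- pmin(pmax(cf, -4), 4)
      par$a[j] <- cf[1]
      pos <- 2L
      if (!is.null(X)) { par$B[j, ] <- cf[pos:(pos + ncol(X) - 1)]
        pos <- pos + ncol(X) }
      if (!is.null(S_design)) par$G[j, ] <- cf[pos:(pos + ncol(S_design) - 1)]
    }
  }
  par
}

flatten_params <- function(p) unlist(p, use.names = FALSE)

#' Fit the joint species distribution model
#'
#' Adaptive-gradient (Adam) minimisation of the Monte-Carlo multivariate
#' probit negative log-likelihood over species intercepts, environmental
#' coefficients `B`, spatial trend coefficients `G` and the low-rank
#' covariance factor `L` (species covariance `Sigma = L L' + I`).  A plateau
#' scheduler multiplies the learning rate by `reduce_factor` after
#' `patience` non-improving iterations.  The final log-likelihood is
#' re-evaluated with `mc_report` fresh antithetic draws, and the species
#' association matrix is `R = D^{-1/2} Sigma D^{-1/2}`.
#'
#' @param y binary site x species matrix (a `pa_table` keeps its groups).
#' @param X standardised environmental design (or `NULL` to omit the
#'   environmental component).
#' @param S_design spatial trend surface (or `NULL` to omit space).
#' @param spec a [jsdm_spec()].
#' @return Object of class `jsdm_fit` with elements `params`, `Sigma`, `R`,
#'   `log_likelihood`, `ll_site`, `ll_species`, `null_ll`, `null_ll_site`,
#'   `null_ll_species`, `pseudo_r2` (McFadden and Nagelkerke), `trace`.
#' @export
fit_jsdm <- function(y, X = NULL, S_design = NULL, spec = jsdm_spec()) {
  y <- as.matrix(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary")
  S <- ncol(y); n <- nrow(y)
  r <- spec$rank
  if (is.null(r)) r <- ceiling(S / 2)
  if (r > S) stop("configuration error: rank exceeds number of species")
  if (!is.null(X)) X <- as.matrix(X)
  if (!is.null(S_design)) S_design <- as.matrix(S_design)

  par <- init_params(y, X, S_design, r, spec$seed)

  # fresh antithetic draws every iteration (doubly stochastic optimisation):
  # a fixed Monte-Carlo sample lets the latent factors overfit its atoms,
  # inflating L and with it the fixed-effect coefficients
  set.seed(spec$seed)
  half <- ceiling(spec$mc_samples / 2)
  draw_h <- function() {
    hh <- matrix(rnorm(half * r), half, r)
    rbind(hh, -hh)
  }
  h <- if (r > 0) draw_h() else NULL

  lr <- spec$learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  m <- lapply(par, function(p) if (is.null(p)) NULL else p * 0)
  v <- m
  best <- Inf; stall <- 0L
  trace <- numeric(spec$iterations)
  for (it in seq_len(spec$iterations)) {
    if (r > 0 && it > 1) h <- draw_h()
    res <- mc_probit_core(par, y, X, S_design, h, grad = TRUE)
    nll <- -res$ll
    if (!is.finite(nll))
      stop("divergence (loss not finite): try a smaller learning rate")
    trace[it] <- nll
    if (nll < best - 1e-7) { best <- nll; stall <- 0L } else {
      stall <- stall + 1L
      if (stall >= spec$patience) { lr <- lr * spec$reduce_factor; stall <- 0L }
    }
    for (nm in names(par)) {
      if (is.null(par[[nm]])) next
      g <- res$grad[[nm]]
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g^2
      mhat <- m[[nm]] / (1 - b1^it)
      vhat <- v[[nm]] / (1 - b2^it)
      par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }

  # final likelihood with a large fresh antithetic sample
  h_rep <- if (r > 0) antithetic_normal(spec$mc_report, r, spec$seed + 1L)
    else matrix(0, 1, 0)
  fin <- mc_probit_eval(par, y, X, S_design, h_rep,
                        species_ll = TRUE, score = TRUE)

  null <- null_probit(y)
  L <- if (r > 0) par$L else matrix(0, S, 0)
  Sigma <- tcrossprod(L) + diag(S)
  R <- cov2cor(Sigma)
  dimnames(R) <- dimnames(Sigma) <- list(colnames(y), colnames(y))
  mcf <- 1 - fin$ll / null$ll
  nobs <- n * S  # per binary observation
  nag <- (1 - exp((2 / nobs) * (null$ll - fin$ll))) /
    (1 - exp((2 / nobs) * null$ll))
  structure(list(params = par, rank = r, Sigma = Sigma, R = R,
                 groups = attr(y, "groups"),
                 log_likelihood = fin$ll, ll_site = fin$ll_site,
                 ll_species = fin$ll_species,
                 null_ll = null$ll, null_ll_site = null$ll_site,
                 null_ll_species = null$ll_species,
                 pseudo_r2 = c(mcfadden = mcf, nagelkerke = nag),
                 Gmat = fin$Gmat, X = X, S_design = S_design, y = y,
                 spec = spec, trace = trace, final_nll = -fin$ll),
            class = "jsdm_fit")
}

# exact intercept-only probit: MLE intercept is qnorm(prevalence)
null_probit <- function(y) {
  prev <- pmin(pmax(colMeans(y), 1 / (2 * nrow(y))), 1 - 1 / (2 * nrow(y)))
  P <- matrix(prev, nrow(y), ncol(y), byrow = TRUE)
  ll_mat <- y * log(P) + (1 - y) * log(1 - P)
  list(ll = sum(ll_mat), ll_site = rowSums(ll_mat),
       ll_species = colSums(ll_mat))
}

#' McFadden pseudo-R-squared of a JSDM fit
#'
#' `1 - logL_model / logL_null` with the exact intercept-only probit as the
#' null; the Nagelkerke variant is also carried on the fit object.
#'
#' @param fit a `jsdm_fit`.
#' @return Scalar in \[0, 1\] (up to Monte-Carlo error).
#' @export
pseudo_r2 <- function(fit) unname(fit$pseudo_r2["mcfadden"])

#' Wald significance of JSDM coefficients
#'
#' Standard errors from the empirical (outer-product / BHHH) information of
#' the per-site scores, block-diagonal per species over that species'
#' intercept, environmental and spatial coefficients; the latent factor `L`
#' is held at its estimate (profile approximation).  Two-sided normal
#' p-values; star codes `*` p<0.05, `**` p<0.01, `***` p<0.001.
#'
#' @param fit a `jsdm_fit`.
#' @return Data frame: species, term, estimate, se, z, p, stars.
#' @export
wald_significance <- function(fit) {
  y <- fit$y; X <- fit$X; Sd <- fit$S_design
  Gmat <- fit$Gmat   # n x S per-site score factor at the optimum
  feats <- cbind(`(Intercept)` = 1,
                 if (!is.null(X)) X,
                 if (!is.null(Sd)) Sd)
  terms <- colnames(feats)
  # aliased columns (e.g. trend-surface degeneracy on straight coastlines)
  # get missing SEs rather than a singular solve
  qrF <- qr(feats)
  keep <- sort(qrF$pivot[seq_len(qrF$rank)])
  if (length(keep) < ncol(feats))
    message("aliased coefficient column(s): ",
            paste(terms[-keep], collapse = ", "), "; SEs reported missing")
  res <- vector("list", ncol(y))
  for (j in seq_len(ncol(y))) {
    sc <- feats[, keep, drop = FALSE] * Gmat[, j]   # n x q per-site score
    Fj <- crossprod(sc)
    est <- c(fit$params$a[j],
             if (!is.null(X)) fit$params$B[j, ],
             if (!is.null(Sd)) fit$params$G[j, ])
    se <- rep(NA_real_, length(est))
    Fi <- tryCatch(solve(Fj), error = function(e) NULL)
    if (is.null(Fi) || any(diag(Fi) <= 0)) {
      message("singular information for species ", j, "; SEs missing")
    } else se[keep] <- sqrt(diag(Fi))
    z <- est / se
    p <- 2 * pnorm(-abs(z))
    res[[j]] <- data.frame(species = colnames(y)[j], term = terms,
                           estimate = est, se = se, z = z, p = p,
                           stars = star_codes(p), row.names = NULL)
  }
  do.call(rbind, res)
}

star_codes <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                              ifelse(p < 0.01, "**",
                                     ifelse(p < 0.05, "*", ""))))
}

#' Filtered biotic-association matrix
#'
#' Off-diagonal entries of the species correlation matrix `R` outside the
#' `[tail, 1 - tail]` percentile band of all off-diagonal values are
#' retained (the strongest positive and negative associations); the rest are
#' masked as `NA`.  Rows/columns are ordered by higher-taxon group when the
#' fit carries group labels.
#'
#' @param fit a `jsdm_fit`.
#' @param tail fraction retained in each tail (default 0.025, i.e. the 5%
#'   most extreme associations overall).
#' @return Correlation matrix with unit diagonal and `NA` for masked
#'   entries; attribute `"groups"` carries the ordering labels.
#' @export
association_matrix <- function(fit, tail = 0.025) {
  R <- fit$R
  ord <- seq_len(nrow(R))
  if (!is.null(fit$groups)) ord <- order(fit$groups, colnames(R))
  R <- R[ord, ord]
  off <- R[upper.tri(R)]
  lo <- quantile(off, tail); hi <- quantile(off, 1 - tail)
  mask <- R > lo & R < hi
  diag(mask) <- FALSE
  R[mask] <- NA
  attr(R, "groups") <- if (!is.null(fit$groups)) fit$groups[ord] else NULL
  R
}
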