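# Independent oracles used across the suite.  Everything here is written
# from first principles (recursions, quadrature, enumeration) and never
# calls the package's own implementation of the quantity it checks.

# recursive M-spline of order `ord` on knot vector t (density-normalised)
mspline_oracle <- function(x, k, ord, t) {
  if (ord == 1)
    return(ifelse(x >= t[k] & x < t[k + 1], 1 / (t[k + 1] - t[k]), 0))
  d <- t[k + ord] - t[k]
  if (d == 0) return(0 * x)
  (ord * ((x - t[k]) * mspline_oracle(x, k, ord - 1, t) +
            (t[k + ord] - x) * mspline_oracle(x, k + 1, ord - 1, t))) /
    ((ord - 1) * d)
}

# Gauss-Hermite nodes/weights by Golub-Welsch (physicists' weight e^{-x^2})
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# E[f(Z)] for Z ~ N(0,1) by Gauss-Hermite (change of variable x = z/sqrt(2))
gh_expect <- function(f, n = 64) {
  gh <- gauss_hermite(n)
  sum(gh$weights * f(sqrt(2) * gh$nodes)) / sqrt(pi)
}

# P(Z1 < a, Z2 < b) for standard bivariate normal with correlation rho,
# by 1-D quadrature over the first coordinate
pbivnorm_oracle <- function(a, b, rho) {
  if (abs(rho) < 1e-12) return(pnorm(a) * pnorm(b))
  integrate(function(z) dnorm(z) * pnorm((b - rho * z) / sqrt(1 - rho^2)),
            -Inf, a, rel.tol = 1e-10)$value
}

# tetrachoric correlation from a binary 2x2 table: numeric inversion of the
# bivariate-normal cell probability at the observed margins
tetrachoric_oracle <- function(x, y) {
  p1 <- mean(x); p2 <- mean(y); p11 <- mean(x & y)
  a <- qnorm(p1); b <- qnorm(p2)
  f <- function(r) pbivnorm_oracle(-a, -b, r) - mean(!x & !y)
  uniroot(f, c(-0.999, 0.999), tol = 1e-8)$root
}

# dense grid search for the single-predictor K=1 GDM (deviance objective)
gdm_grid_oracle <- function(d, z, alpha_grid, beta_grid) {
  best <- c(NA, NA); best_dev <- Inf
  for (a in alpha_grid) for (b in beta_grid) {
    dhat <- pmin(pmax(1 - exp(-(a + b * z)), 1e-9), 1 - 1e-9)
    dev <- sum(2 * (ifelse(d > 0, d * log(d / dhat), 0) +
                      ifelse(d < 1, (1 - d) * log((1 - d) / (1 - dhat)), 0)))
    if (dev < best_dev) { best_dev <- dev; best <- c(a, b) }
  }
  list(par = best, deviance = best_dev)
}

# exhaustive pinball-loss grid search for median regression coefficients
pinball_grid_oracle <- function(y, x, intercepts, slopes, tau = 0.5) {
  best <- c(NA, NA); best_loss <- Inf
  for (a in intercepts) for (b in slopes) {
    r <- y - a - b * x
    loss <- sum(r * (tau - (r < 0)))
    if (loss < best_loss) { best_loss <- loss; best <- c(a, b) }
  }
  list(coef = best, loss = best_loss)
}

# small standardised environment + trend surface from a design
design_matrices <- function(design) {
  cd <- composite_design(design)
  list(cd = cd,
       X = standardise_env(as.matrix(cd[, env_covariate_names()])),
       S = trend_surface(cd$lon, cd$lat))
}
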