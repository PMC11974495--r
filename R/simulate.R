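#' Configuration for the synthetic metacommunity generator
#'
#' Bundles every knob of the generator.  Defaults emulate the sampling design
#' the package targets: 24 beaches along a ~650 km coastline, three parallel
#' transects per beach with eight tidal levels each (576 physical samples,
#' 192 beach-by-level composites), on the order of a hundred retained
#' meiofaunal OTUs in about a dozen higher taxa, probit occurrence with
#' linear environmental responses, a smooth second-order spatial trend and a
#' low-rank residual species covariance, plus read-depth and low-level
#' contamination noise of the kind the downstream abundance filter removes.
#'
#' @param n_beaches,n_transects,n_levels study geometry (positive integers).
#' @param n_species number of meiofaunal OTUs in the latent community.
#' @param n_offtarget extra OTUs that appear in the read table but are
#'   excluded downstream by taxonomy (non-meiofauna or <85% identity).
#' @param rank latent dimension of the species covariance factor.
#' @param env_scale,spatial_scale,biotic_scale standard deviation of the
#'   total environmental, spatial and latent-factor contribution to the
#'   probit linear predictor (per-coefficient SDs are scaled by the number of
#'   columns so each knob controls one component's overall strength).
#' @param intercept_mean,intercept_sd distribution of species probit
#'   intercepts; the defaults give realistic sparse-but-recurrent prevalences.
#' @param gp_range_km range (km) of the exponential covariance of the
#'   along-coast Gaussian process generating beach-level covariates.
#' @param coast_length_km coastline length spanned by the beaches.
#' @param depth_meanlog,depth_sdlog log-normal sequencing-depth parameters.
#' @param low_depth_fraction fraction of physical samples forced below the
#'   3000-read retention threshold.
#' @param contamination_rate probability that an absent OTU receives a
#'   sub-threshold contamination read count in a given sample.
#' @param missing_fraction fraction of physical samples dropped entirely
#'   (field losses; the design the package emulates retained 550 of 576).
#' @param seed integer seed fixing every random draw of the generator.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_beaches = 24, n_transects = 3, n_levels = 8,
                       n_species = 120, n_offtarget = 6, rank = 5,
                       env_scale = 1.2, spatial_scale = 0.5, biotic_scale = 1,
                       intercept_mean = -0.8, intercept_sd = 0.8,
                       gp_range_km = 100, coast_length_km = 650,
                       depth_meanlog = log(20000), depth_sdlog = 0.6,
                       low_depth_fraction = 0.02, contamination_rate = 0.01,
                       missing_fraction = 0, seed = 1L) {
  cfg <- list(n_beaches = n_beaches, n_transects = n_transects,
              n_levels = n_levels, n_species = n_species,
              n_offtarget = n_offtarget, rank = rank,
              env_scale = env_scale, spatial_scale = spatial_scale,
              biotic_scale = biotic_scale, intercept_mean = intercept_mean,
              intercept_sd = intercept_sd, gp_range_km = gp_range_km,
              coast_length_km = coast_length_km,
              depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
              low_depth_fraction = low_depth_fraction,
              contamination_rate = contamination_rate,
              missing_fraction = missing_fraction, seed = as.integer(seed))
  for (f in c("n_beaches", "n_transects", "n_levels", "n_species", "rank"))
    if (cfg[[f]] < 1) stop("configuration error: '", f, "' must be positive")
  if (cfg$rank > cfg$n_species)
    stop("configuration error: rank must not exceed n_species")
  for (f in c("contamination_rate", "low_depth_fraction", "missing_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("configuration error: '", f, "' must lie in [0,1]")
  if (cfg$gp_range_km <= 0 || cfg$coast_length_km <= 0)
    stop("configuration error: spatial ranges must be positive")
  structure(cfg, class = "sim_config")
}

# coastline endpoints for coordinate interpolation (WGS84 decimal degrees);
# a straight segment -- monotone coordinates are what matters downstream
.coast_start <- c(lon = 3.5, lat = 51.5)
.coast_end   <- c(lon = 8.5, lat = 55.0)

#' Names of the environmental covariates carried by a study design
#' @return Character vector of the six covariate column names.
#' @export
env_covariate_names <- function() {
  c("grain_size", "dist_low_tide", "spring_tide_range",
    "beach_slope", "salinity", "annual_temp")
}

#' Generate a synthetic beach-transect study design
#'
#' Lays out `n_beaches` beaches along a straight stretch of coastline,
#' each with `n_transects` transects of `n_levels` tidal levels.  Beach-level
#' covariates (grain size, spring tide range, beach slope, salinity, annual
#' temperature) are drawn from a Gaussian process along the coast with an
#' exponential covariance (range `gp_range_km`), mimicking the spatial
#' autocorrelation of real shorelines; distance from the low-tide line is an
#' equidistant 100..0 grid across tidal levels within every transect.
#'
#' @param config a [sim_config()].
#' @return A `study_design` data frame with one row per physical sample:
#'   `sample_id`, `composite_id`, `beach_id`, `transect_id`, `tidal_level`,
#'   `coast_position_km`, `lon`, `lat` and the six covariates.
#' @export
generate_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nb <- config$n_beaches
  # beach positions: even spacing with jitter, kept strictly increasing
  pos <- seq(0, config$coast_length_km, length.out = nb)
  if (nb > 1) {
    gap <- diff(pos)[1]
    pos <- pos + runif(nb, -0.3, 0.3) * gap
    pos <- sort(pos)
  }
  frac <- if (nb > 1) (pos - min(pos)) / (max(pos) - min(pos)) else 0.5
  lon <- .coast_start["lon"] + frac * (.coast_end["lon"] - .coast_start["lon"])
  lat <- .coast_start["lat"] + frac * (.coast_end["lat"] - .coast_start["lat"])

  # beach-level covariates: GP with exponential kernel along the coast
  K <- exp(-as.matrix(dist(pos)) / config$gp_range_km)
  cK <- chol(K + diag(1e-8, nb))
  z <- crossprod(cK, matrix(rnorm(nb * 5), nb, 5))  # nb x 5 unit-variance GP
  beach_env <- data.frame(
    grain_size        = pmax(80, 280 + 90 * z[, 1]),
    spring_tide_range = pmax(0.5, 2.6 + 0.8 * z[, 2]),
    beach_slope       = pmax(0.3, 3.2 + 1.2 * z[, 3]),
    salinity          = 30.5 + 0.7 * z[, 4],
    annual_temp       = 10.5 + 0.9 * z[, 5])

  lvl <- seq_len(config$n_levels)
  dist_lt <- if (config$n_levels > 1)
    100 * (config$n_levels - lvl) / (config$n_levels - 1) else 50
  grid <- expand.grid(tidal_level = lvl,
                      transect_id = seq_len(config$n_transects),
                      beach_id = seq_len(nb))
  design <- data.frame(
    sample_id = sprintf("B%02dT%dL%d", grid$beach_id, grid$transect_id,
                        grid$tidal_level),
    composite_id = sprintf("B%02d_L%d", grid$beach_id, grid$tidal_level),
    beach_id = grid$beach_id, transect_id = grid$transect_id,
    tidal_level = grid$tidal_level,
    coast_position_km = pos[grid$beach_id],
    lon = unname(lon[grid$beach_id]), lat = unname(lat[grid$beach_id]),
    grain_size = beach_env$grain_size[grid$beach_id],
    dist_low_tide = dist_lt[grid$tidal_level],
    spring_tide_range = beach_env$spring_tide_range[grid$beach_id],
    beach_slope = beach_env$beach_slope[grid$beach_id],
    salinity = beach_env$salinity[grid$beach_id],
    annual_temp = beach_env$annual_temp[grid$beach_id],
    stringsAsFactors = FALSE)
  class(design) <- c("study_design", "data.frame")
  design
}

#' Composite-level (beach x tidal level) view of a study design
#'
#' @param design a `study_design`.
#' @return One row per composite sample with coordinates and covariates
#'   (identical across the transect replicates being merged).
#' @export
composite_design <- function(design) {
  d <- design[!duplicated(design$composite_id), , drop = FALSE]
  d <- d[order(d$beach_id, d$tidal_level), , drop = FALSE]
  rownames(d) <- d$composite_id
  d
}

#' Draw latent community parameters for the generative probit model
#'
#' The generative twin of the fitted joint model: per-species probit
#' intercepts, linear environmental coefficients `B`, spatial trend-surface
#' coefficients `G` and a low-rank loading matrix `L` whose implied species
#' covariance is `L L' + I`.  Per-entry SDs are `*_scale / sqrt(n_columns)`
#' so each scale knob sets the SD of that component's total contribution to
#' the linear predictor.
#'
#' @param config a [sim_config()].
#' @param n_env number of environmental covariates (6 in the emulated design).
#' @param n_spatial number of trend-surface columns (5: x, y, x2, y2, xy).
#' @return An object of class `latent_params`: list with `intercepts`, `B`
#'   (species x n_env), `G` (species x n_spatial), `L` (species x rank).
#' @export
draw_latent_params <- function(config, n_env = 6, n_spatial = 5) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  S <- config$n_species
  p <- list(
    intercepts = rnorm(S, config$intercept_mean, config$intercept_sd),
    B = matrix(rnorm(S * n_env, 0, config$env_scale / sqrt(n_env)), S, n_env),
    G = matrix(rnorm(S * n_spatial, 0, config$spatial_scale / sqrt(n_spatial)),
               S, n_spatial),
    L = matrix(rnorm(S * config$rank, 0, config$biotic_scale / sqrt(config$rank)),
               S, config$rank),
    rank = config$rank)
  dimnames(p$B) <- list(otu_ids(S), env_covariate_names()[seq_len(n_env)])
  rownames(p$G) <- rownames(p$L) <- otu_ids(S)
  names(p$intercepts) <- otu_ids(S)
  structure(p, class = "latent_params")
}

otu_ids <- function(n, prefix = "OTU") sprintf("%s%03d", prefix, seq_len(n))

#' Simulate a presence/absence community from latent parameters
#'
#' Occurrence follows the multivariate probit model: species `j` is present
#' at composite site `i` iff
#' `intercept_j + (X B')_ij + (S G')_ij + (H L')_ij + eps_ij > 0`,
#' with `H` the site-level standard-normal latent factors and `eps` standard
#' normal.  Covariates are standardised and the spatial design is the
#' second-order trend surface of the scaled coordinates, exactly as the
#' fitting side builds them.
#'
#' @param design a `study_design` (occurrence is defined at composite level).
#' @param params a `latent_params`.
#' @param seed integer seed.
#' @return Binary matrix (composites x species) of class `pa_table`, with a
#'   `"design"` attribute holding the composite design.
#' @export
simulate_presence_absence <- function(design, params, seed = 1L) {
  stopifnot(inherits(params, "latent_params"))
  cd <- composite_design(design)
  X <- standardise_env(as.matrix(cd[, colnames(params$B), drop = FALSE]))
  Sd <- trend_surface(cd$lon, cd$lat)
  if (ncol(Sd) != ncol(params$G))
    stop("dimension mismatch: spatial design has ", ncol(Sd),
         " columns but params$G has ", ncol(params$G))
  n <- nrow(cd); S <- length(params$intercepts); r <- ncol(params$L)
  set.seed(seed)
  H <- matrix(rnorm(n * r), n, r)
  eta <- rep(params$intercepts, each = n) + X %*% t(params$B) +
    Sd %*% t(params$G) + H %*% t(params$L)
  y <- (eta + matrix(rnorm(n * S), n, S) > 0) + 0L
  dimnames(y) <- list(cd$composite_id, names(params$intercepts))
  structure(y, class = c("pa_table", class(y)), design = cd)
}

#' Simulate a taxonomy table for the generated OTUs
#'
#' Meiofaunal OTUs get best-hit identities above 85% (so they survive the
#' taxonomy filter) and higher-taxon labels drawn with proportions typical of
#' beach meiofauna metabarcoding (Nematoda- and Copepoda-dominated).
#' Off-target OTUs alternate between non-meiofauna hits and sub-85% identity
#' hits; both classes are removed by the downstream taxonomy filter.
#'
#' @param config a [sim_config()].
#' @return Data frame: `otu_id`, `best_identity_pct`, `assigned_rank`,
#'   `group`, `is_meiofauna`.
#' @export
simulate_taxonomy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  groups <- c(Nematoda = 42, Copepoda = 21, Clitellata = 16, Polychaeta = 12,
              Gastrotricha = 9, Platyhelminthes = 8, Acoela = 7,
              Collembola = 4, Rotifera = 3, Branchiopoda = 2, Nemertea = 1,
              Tardigrada = 1, Arachnida = 1)
  S <- config$n_species
  grp <- sample(names(groups), S, replace = TRUE, prob = groups)
  pct <- runif(S, 85.5, 100)
  tax <- data.frame(otu_id = otu_ids(S), best_identity_pct = pct,
                    assigned_rank = assign_rank(pct), group = grp,
                    is_meiofauna = TRUE, stringsAsFactors = FALSE)
  no <- config$n_offtarget
  if (no > 0) {
    off_meio <- seq_len(no) %% 2 == 0  # half low-identity meiofauna
    off_pct <- ifelse(off_meio, runif(no, 60, 85), runif(no, 90, 100))
    off <- data.frame(
      otu_id = sprintf("OTU%03d", S + seq_len(no)),
      best_identity_pct = off_pct,
      assigned_rank = assign_rank(off_pct),
      group = ifelse(off_meio, "Nematoda", "Bacillariophyta"),
      is_meiofauna = off_meio, stringsAsFactors = FALSE)
    tax <- rbind(tax, off)
  }
  tax
}

#' Simulate a noisy read-count table from a presence/absence community
#'
#' Each physical sample inherits the occurrence vector of its composite.
#' Present OTUs receive log-normal relative abundances, floored at 0.0012 and
#' renormalised (every genuine occurrence stays detectable above the 0.03%
#' abundance filter), then scaled by a log-normal sequencing depth.  Absent
#' OTUs receive, with probability `contamination_rate`, a contamination count
#' strictly below 0.03% of the sample total — the tag-jump-like noise the
#' abundance filter is designed to remove.  A `low_depth_fraction` of samples
#' is forced below 3000 reads (to be dropped by the depth filter) and
#' `missing_fraction` of samples is removed outright.
#'
#' @param pa a `pa_table` at composite level.
#' @param design the `study_design` (physical samples).
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param taxonomy optional taxonomy with off-target OTUs to spike in.
#' @return Integer matrix (physical samples x OTUs) of class `read_counts`.
#' @export
simulate_read_counts <- function(pa, design, config, seed = 1L,
                                 taxonomy = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$contamination_rate < 0)
    stop("configuration error: negative contamination_rate")
  set.seed(seed)
  keep <- rep(TRUE, nrow(design))
  if (config$missing_fraction > 0)
    keep[sample(nrow(design), round(config$missing_fraction * nrow(design)))] <- FALSE
  des <- design[keep, , drop = FALSE]
  n <- nrow(des)
  otus <- colnames(pa)
  off <- character(0)
  if (!is.null(taxonomy)) off <- setdiff(taxonomy$otu_id, otus)
  all_otus <- c(otus, off)
  S <- length(all_otus)

  low <- runif(n) < config$low_depth_fraction
  depth <- pmax(3334, round(rlnorm(n, config$depth_meanlog, config$depth_sdlog)))
  depth[low] <- sample(100:2999, sum(low), replace = TRUE)

  counts <- matrix(0L, n, S, dimnames = list(des$sample_id, all_otus))
  pres_off <- if (length(off))
    matrix(runif(n * length(off)) < 0.3, n, length(off)) else NULL
  for (i in seq_len(n)) {
    pres <- c(pa[des$composite_id[i], ] == 1L,
              if (length(off)) pres_off[i, ] else NULL)
    np <- sum(pres)
    if (np > 0) {
      rel <- rlnorm(np, 0, 1.2)
      rel <- rel / sum(rel)
      rel <- pmax(rel, 0.0012)
      rel <- rel / sum(rel)
      counts[i, pres] <- pmax(1L, as.integer(round(rel * depth[i])))
    }
    abs_idx <- which(!pres)
    if (config$contamination_rate > 0 && length(abs_idx)) {
      hit <- abs_idx[runif(length(abs_idx)) < config$contamination_rate]
      if (length(hit)) {
        cc <- floor(runif(length(hit)) * 3e-4 * depth[i])
        counts[i, hit] <- as.integer(cc)
      }
    }
  }
  structure(counts, class = c("read_counts", class(counts)), design = des)
}

#' Simulate a complete synthetic metacommunity data set
#'
#' One call producing everything the pipeline consumes: design, taxonomy,
#' the true latent parameters and presence/absence matrix, and the noisy
#' read-count table.  All randomness derives from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return List with `design`, `taxonomy`, `params`, `pa`, `counts` and
#'   `truth` (the generative parameters, for recovery checks).
#' @export
simulate_metacommunity <- function(config = sim_config()) {
  design <- generate_design(config)
  params <- draw_latent_params(config)
  taxonomy <- simulate_taxonomy(config)
  pa <- simulate_presence_absence(design, params, seed = config$seed + 3L)
  counts <- simulate_read_counts(pa, design, config, seed = config$seed + 4L,
                                 taxonomy = taxonomy)
  list(design = design, taxonomy = taxonomy, params = params, pa = pa,
       counts = counts,
       truth = list(params = params, pa = pa, config = config))
}
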