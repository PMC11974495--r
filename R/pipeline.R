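#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis.  Unknown keys
#' are rejected so typos fail loudly; every random stage takes an explicit
#' seed derived from `seed`.
#'
#' @param sim a [sim_config()] for the synthetic-data stage (ignored when
#'   external tables are supplied to [run_pipeline()]).
#' @param min_rel,min_reads,min_occupancy preprocessing thresholds.
#' @param r_max,vif_max covariate-selection thresholds.
#' @param gdm_K I-splines per GDM predictor.
#' @param jsdm a [jsdm_spec()].
#' @param partition_degree,partition_boot quantile-regression settings for
#'   the internal-structure analysis.
#' @param out_dir output directory (`NULL`: nothing written to disk).
#' @param seed master seed.
#' @param ... unknown keys: an error.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), min_rel = 0.0003,
                            min_reads = 3000, min_occupancy = 10,
                            r_max = 0.7, vif_max = 2, gdm_K = 3,
                            jsdm = jsdm_spec(), partition_degree = 2,
                            partition_boot = 1000, out_dir = NULL,
                            seed = 1L, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "))
  structure(list(sim = sim, min_rel = min_rel, min_reads = min_reads,
                 min_occupancy = min_occupancy, r_max = r_max,
                 vif_max = vif_max, gdm_K = gdm_K, jsdm = jsdm,
                 partition_degree = partition_degree,
                 partition_boot = partition_boot, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_msg <- function(...) message("[metasandy] ", ...)

#' Run the end-to-end metacommunity assembly pipeline
#'
#' Executes simulate (or ingest) -> preprocess -> select covariates ->
#' fit GDM -> fit JSDM -> partition -> internal-structure regressions, and
#' returns a machine-readable report of every headline statistic
#' (preprocessing tallies, GDM deviances / % explained / intercept /
#' coefficient sums, JSDM log-likelihood and pseudo-R-squared, median
#' component shares, regression table).  With `out_dir` set, the report is
#' written as JSON alongside CSV exports of the community matrix, partition
#' and regression tables.
#'
#' @param config a [pipeline_config()].
#' @param data optional list with `counts`, `taxonomy`, `design` to analyse
#'   external tables instead of simulating (column layout as produced by
#'   [simulate_metacommunity()]).
#' @return The report (list), invisibly the full `pipeline_result` with all
#'   fitted objects.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  timings <- list()
  tic <- function() Sys.time()
  toc <- function(start, stage) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), start,
                                             units = "secs"))
  }

  st <- tic()
  if (is.null(data)) {
    stage_msg("simulate: generating synthetic metacommunity")
    sim <- simulate_metacommunity(config$sim)
  } else {
    stage_msg("ingest: using supplied tables")
    sim <- data
  }
  toc(st, "simulate")

  st <- tic()
  stage_msg("preprocess: abundance/depth filters, merge, community matrix")
  grouping <- setNames(sim$design$composite_id, sim$design$sample_id)
  pa <- preprocess_community(sim$counts, sim$taxonomy, grouping,
                             min_rel = config$min_rel,
                             min_reads = config$min_reads,
                             min_occupancy = config$min_occupancy)
  toc(st, "preprocess")

  cd <- composite_design(sim$design)
  cd <- cd[match(rownames(pa), cd$composite_id), , drop = FALSE]

  st <- tic()
  stage_msg("select-covariates: correlation prune + stepwise VIF")
  env_raw <- as.matrix(cd[, env_covariate_names()])
  pruned <- correlation_prune(env_raw, r_max = config$r_max)
  vif <- vif_stepwise(pruned$env, vif_max = config$vif_max)
  env_sel <- standardise_env(vif$env)
  toc(st, "select_covariates")

  st <- tic()
  stage_msg("fit-gdm: ", ncol(env_sel), " covariates + geographic distance")
  geo <- geo_distance_matrix(cd$lon, cd$lat)
  d <- jaccard_matrix(pa)
  gdm <- fit_gdm(d, env = env_sel, geo = geo, K = config$gdm_K)
  gdm_imp <- gdm_transform_and_importance(gdm)
  toc(st, "gdm")

  st <- tic()
  stage_msg("fit-jsdm: ", nrow(pa), " sites x ", ncol(pa), " OTUs")
  Sd <- trend_surface(cd$lon, cd$lat)
  jsdm <- fit_jsdm(pa, X = env_sel, S_design = Sd, spec = config$jsdm)
  wald <- wald_significance(jsdm)
  assoc <- association_matrix(jsdm)
  toc(st, "jsdm")

  st <- tic()
  stage_msg("partition: 8-model grid + Shapley allocation")
  part <- partition_assembly(pa, env_sel, Sd, spec = config$jsdm)
  env_dist <- distinctiveness(env_sel)
  spa_dist <- distinctiveness(geo, is_distance = TRUE)
  predictors <- data.frame(env_distinctiveness = env_dist,
                           spatial_distinctiveness = spa_dist,
                           richness = as.numeric(scale(rowSums(pa))))
  predictors <- cbind(predictors, as.data.frame(env_sel))
  regressions <- internal_structure_analysis(
    part, predictors, degree = config$partition_degree,
    n_boot = config$partition_boot, seed = config$seed)
  toc(st, "partition")

  report <- list(
    preprocessing = list(
      n_physical_samples = nrow(sim$counts),
      n_composite_samples = nrow(pa),
      n_retained_otus = ncol(pa),
      n_groups = length(unique(attr(pa, "groups")))),
    covariates = list(
      dropped_by_correlation = pruned$report$covariate,
      retained = colnames(vif$env),
      max_vif = max(vif$final_vif)),
    gdm = list(
      null_deviance = gdm$null_deviance,
      model_deviance = gdm$model_deviance,
      pct_deviance_explained = gdm$pct_deviance_explained,
      intercept = gdm$intercept,
      coefficient_sums = as.list(gdm_imp$importance)),
    jsdm = list(
      log_likelihood = jsdm$log_likelihood,
      pseudo_r2_mcfadden = unname(jsdm$pseudo_r2["mcfadden"]),
      pseudo_r2_nagelkerke = unname(jsdm$pseudo_r2["nagelkerke"]),
      rank = jsdm$rank,
      n_significant_env = sum(wald$p < 0.05 &
                                wald$term %in% colnames(env_sel),
                              na.rm = TRUE)),
    partition = list(
      median_share_E = stats::median(part$sites$share_E, na.rm = TRUE),
      median_share_S = stats::median(part$sites$share_S, na.rm = TRUE),
      median_share_C = stats::median(part$sites$share_C, na.rm = TRUE)),
    timings = timings,
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(as.data.frame(unclass(pa)[seq_len(nrow(pa)), , drop = FALSE]),
              file.path(config$out_dir, "community_matrix.csv"))
    write.csv(part$sites, file.path(config$out_dir, "partition.csv"),
              row.names = FALSE)
    write.csv(regressions, file.path(config$out_dir, "regressions.csv"),
              row.names = FALSE)
    write.csv(wald, file.path(config$out_dir, "jsdm_coefficients.csv"),
              row.names = FALSE)
  }

  invisible(structure(list(report = report, pa = pa, env = env_sel,
                           geo = geo, gdm = gdm, gdm_importance = gdm_imp,
                           jsdm = jsdm, wald = wald, association = assoc,
                           partition = part, regressions = regressions,
                           predictors = predictors, design = cd),
                      class = "pipeline_result"))
}
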