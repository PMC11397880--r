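#' Run the full survey analysis pipeline
#'
#' Executes, in order: the geometry report for the configured camera over
#' the design's heights and tilts; expansion of the factorial flight design;
#' simulation of counts and coder ratings (or ingestion of user-supplied
#' CSVs); the reduced-dataset filter; the Poisson random-intercept model
#' with its null-model likelihood-ratio test, plus the per-angle submodels;
#' and the inter-coder agreement summary. All artifacts are written under
#' `out_dir` together with a run manifest (seed, per-stage row counts, file
#' fingerprints). Any stage failure is re-thrown with a stage label;
#' artifacts written before the failure are retained.
#'
#' @param config a `pipeline_config` from [read_pipeline_config()] or
#'   [as_pipeline_config()].
#' @param out_dir output directory, created if needed.
#' @param counts_csv,coders_csv optional paths to user-supplied tables; when
#'   given they replace the simulation stage (ingest mode).
#' @return the manifest, invisibly a list also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, counts_csv = NULL, coders_csv = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("tirsurvey")),
                   r_version = as.character(getRversion()),
                   seed = config$seed, stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  note <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
  }
  emit <- function(data, file) {
    path <- file.path(out_dir, file)
    write_table_csv(data, path)
    unname(tools::md5sum(path))
  }

  cam <- stage("geometry", do.call(camera_model, config$camera))
  geo <- stage("geometry", geometry_report(
    cam, heights_agl_m = config$design$heights,
    tilts_deg = tilt_from_gimbal(config$design$angles),
    canopy_height_m = config$design$canopy_height_m))
  note("geometry", rows = nrow(geo), md5 = emit(geo, "geometry.csv"))

  design <- stage("design", expand_design(
    config$design$n_sites, config$design$flights_per_site,
    config$design$heights, config$design$angles, config$design$speeds,
    base_speed = min(config$design$speeds),
    transect_length_m = config$design$transect_length_m, seed = config$seed))
  note("design", rows = nrow(design),
       videos_per_flight = nrow(design) / length(unique(design$flight_id)),
       md5 = emit(design, "design.csv"))

  if (is.null(counts_csv)) {
    sim_args <- utils::modifyList(
      list(n_sites = config$design$n_sites,
           flights_per_site = config$design$flights_per_site,
           heights = config$design$heights, angles = config$design$angles,
           speeds = config$design$speeds, seed = config$seed),
      config$simulation)
    sc <- stage("simulate", do.call(sim_config, sim_args))
    sim <- stage("simulate", generate_counts(sc))
    counts <- sim$counts
    truth <- sim$truth
    coders <- stage("simulate", generate_coder_ratings(counts, sc))
    jsonlite::write_json(truth[!vapply(truth, is.null, TRUE)],
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    note("simulate", rows = nrow(counts), coder_rows = nrow(coders),
         md5 = emit(counts, "counts.csv"))
  } else {
    counts <- stage("ingest", read_count_table(counts_csv))
    coders <- if (!is.null(coders_csv)) stage("ingest", read_coder_table(coders_csv))
             else NULL
    note("ingest", rows = nrow(counts),
         counts_md5 = unname(tools::md5sum(counts_csv)))
  }
  if (!is.null(coders)) emit(coders, "coders.csv")

  fit_data <- if (isTRUE(config$inference$reduced_filter))
    stage("filter", reduced_dataset_filter(counts)) else counts
  note("filter", rows = nrow(fit_data),
       flights = length(unique(fit_data$flight_id)))

  preds <- config$inference$predictors
  nq <- config$inference$n_quad
  fits <- stage("fit", {
    full <- fit_poisson_glmm(fit_data, predictors = preds, n_quad = nq)
    null <- fit_poisson_glmm(fit_data, predictors = character(0), n_quad = nq)
    res <- list(full = list(fit = full, lrt = likelihood_ratio_test(full, null),
                            dispersion = dispersion_statistic(full, fit_data)))
    for (ang in sort(unique(as.character(counts$angle_deg)))) {
      sub <- counts[as.character(counts$angle_deg) == ang, ]
      sub_preds <- setdiff(preds, "angle_deg")
      f <- fit_poisson_glmm(sub, predictors = sub_preds, n_quad = nq)
      n0 <- fit_poisson_glmm(sub, predictors = character(0), n_quad = nq)
      res[[paste0("angle_", ang)]] <-
        list(fit = f, lrt = likelihood_ratio_test(f, n0))
    }
    res
  })
  fit_json <- lapply(fits, function(blk) {
    out <- list(beta = as.list(blk$fit$beta), sigma = blk$fit$sigma,
                loglik = blk$fit$loglik, converged = blk$fit$converged,
                n_obs = blk$fit$n_obs, n_groups = blk$fit$n_groups,
                lrt = list(statistic = blk$lrt$statistic, df = blk$lrt$df,
                           p_value = blk$lrt$p_value))
    if (!is.null(blk$fit$se)) out$se <- as.list(blk$fit$se)
    if (!is.null(blk$dispersion)) out$dispersion <- blk$dispersion
    out
  })
  jsonlite::write_json(fit_json, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  flat <- do.call(rbind, lapply(names(fits), function(nm) data.frame(
    model = nm, n_obs = fits[[nm]]$fit$n_obs, sigma = fits[[nm]]$fit$sigma,
    loglik = fits[[nm]]$fit$loglik, lrt_statistic = fits[[nm]]$lrt$statistic,
    lrt_df = fits[[nm]]$lrt$df, lrt_p = fits[[nm]]$lrt$p_value)))
  note("fit", models = length(fits), md5 = emit(flat, "fit_summary.csv"))

  agr <- NULL
  if (!is.null(coders)) {
    agr <- stage("agreement", agreement_summary(coders, design))
    jsonlite::write_json(
      list(zone_shares = agr$zone_shares, marginal_shares = agr$marginal_shares,
           band_convention = agr$band_convention),
      file.path(out_dir, "agreement.json"), auto_unbox = TRUE, digits = NA)
    note("agreement", cells = nrow(agr$cells),
         md5 = emit(agr$cells, "agreement_cells.csv"))
  }

  manifest$stages <- manifest$stages
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(manifest, list(fits = fits, agreement = agr,
                             counts = counts, design = design)))
}
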