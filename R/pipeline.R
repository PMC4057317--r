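# End-to-end pipeline driver: simulate -> fit -> cluster (per feature
# vector) -> classify -> evaluate, with seeded stages, on-disk artifacts and
# a run configuration object.

#' Pipeline run configuration
#'
#' Bundles all settings of one end-to-end run. The defaults describe the demo
#' cohort (6 treated animals of which 3 with a 72 h scan, 3 controls, 64 x 64
#' x 8 tumors over a 2 x 2 cm field of view) which runs on one CPU in a few
#' minutes; pass `matrix_size = 128`, `n_slices = 14`, `fov_mm = 40`,
#' `n_treated = 14`, ... for the full-size study design.
#'
#' @param n_treated,n_treated_72h,n_control cohort design, see
#'   [cohort_design()].
#' @param matrix_size,n_slices,fov_mm grid settings, see
#'   [acquisition_protocol()].
#' @param noise_sd Rician noise SD (signal units; the equilibrium signal is
#'   1000).
#' @param lesion_fractions per-treated-animal target non-viable fraction at
#'   sacrifice (`NULL`: evenly spread 0 to 0.5).
#' @param feature_vectors named list of feature vectors to cluster with
#'   (default: the eleven study subsets from [study_feature_vectors()]).
#' @param isodata optional list of overrides for [isodata_params()].
#' @param alpha significance level for cluster classification.
#' @param r2_threshold criterion-1 retention cut.
#' @param histology_section_mm,histology_cv synthetic histology settings.
#' @param seed integer master seed (required; all stages derive their seeds
#'   from it).
#' @param out_dir output directory for artifacts (`NULL`: keep everything in
#'   memory only).
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_treated = 6L, n_treated_72h = 3L, n_control = 3L,
                       matrix_size = 64L, n_slices = 8L, fov_mm = 20,
                       noise_sd = 25, lesion_fractions = NULL,
                       feature_vectors = study_feature_vectors(),
                       isodata = list(), alpha = 0.05, r2_threshold = 0.7,
                       histology_section_mm = 0.3, histology_cv = 0.05,
                       seed, out_dir = NULL) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("run_config requires an explicit integer seed")
  if (is.null(names(feature_vectors)))
    names(feature_vectors) <- vapply(feature_vectors, paste, "",
                                     collapse = "+")
  cfg <- structure(list(
    n_treated = n_treated, n_treated_72h = n_treated_72h,
    n_control = n_control, matrix_size = matrix_size, n_slices = n_slices,
    fov_mm = fov_mm, noise_sd = noise_sd,
    lesion_fractions = lesion_fractions, feature_vectors = feature_vectors,
    isodata = isodata, alpha = alpha, r2_threshold = r2_threshold,
    histology_section_mm = histology_section_mm, histology_cv = histology_cv,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' @param config a `run_config` (or plain list with the same fields).
#' @return The config, invisibly; errors describe the offending field.
#' @export
validate_run_config <- function(config) {
  if (is.null(config$seed) || !is.finite(config$seed))
    stop("config is missing an explicit seed")
  if (config$alpha <= 0 || config$alpha >= 1)
    stop("alpha must lie in (0, 1)")
  for (fv in config$feature_vectors)
    if (!all(fv %in% c("T1", "T2", "ADC", "MTR")))
      stop("invalid feature vector: ", paste(fv, collapse = "+"))
  invisible(config)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

config_checksum <- function(config) {
  text_checksum(yaml::as.yaml(config[setdiff(names(config), "out_dir")]))
}

stage_msg <- function(stage, t0, ...) {
  message(sprintf("[%s] %s (%.1f s)", stage, paste0(...),
                  as.numeric(proc.time()[3] - t0)))
}

#' Run the full analysis pipeline
#'
#' Executes, from one seeded configuration: synthetic cohort generation, raw
#' signal simulation with Rician noise, voxelwise parameter-map fitting with
#' noise-level exclusion, pooled ISODATA clustering per feature vector,
#' temporal cluster classification into viable/non-viable tissue, synthetic
#' histology, and the three-criterion feature-vector evaluation. Re-running
#' with the same configuration reproduces all outputs.
#'
#' @param config a [run_config()].
#' @return An object of class `mpmri_pipeline`: list with the `config`,
#'   `design`, `fitted_scans`, per-feature-vector results (`per_fv`: model,
#'   fraction table, class map, viability fractions, rim fraction), the
#'   histology `sections` and per-animal `histology_fractions`, the combined
#'   fraction `pairs` (histology vs MRI) and `true_pairs` (ground truth vs
#'   MRI), the `evaluation` report and the parameter `summary` for the
#'   selected feature vector.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  t0 <- proc.time()[3]
  seed <- config$seed

  design <- cohort_design(config$n_treated, config$n_treated_72h,
                          config$n_control)
  protocol <- acquisition_protocol(matrix_size = config$matrix_size,
                                   n_slices = config$n_slices,
                                   fov_mm = config$fov_mm,
                                   noise_sd = config$noise_sd)
  lesion <- lesion_spec(fractions = config$lesion_fractions)
  cohort <- generate_cohort(design, lesion = lesion, protocol = protocol,
                            seed = derive_seed(seed, 1L))
  stage_msg("simulate", t0, sprintf("cohort of %d scans generated (seed %d)",
                                    length(cohort$scans), seed))

  bg_mask <- cohort$geometry$background
  fitted_scans <- vector("list", length(cohort$scans))
  names(fitted_scans) <- names(cohort$scans)
  for (i in seq_along(cohort$scans)) {
    sc <- cohort$scans[[i]]
    series <- simulate_signal_series(sc, protocol)
    if (config$noise_sd > 0)
      series <- add_rician_noise(series, config$noise_sd,
                                 seed = derive_seed(seed, 100L + i))
    maps <- fit_parameter_maps(series, protocol, sc$tumor_mask,
                               background_mask = bg_mask)
    fitted_scans[[i]] <- list(animal = sc$animal, group = sc$group,
                              timepoint = sc$timepoint,
                              sacrifice = sc$sacrifice,
                              true_nonviable_fraction =
                                sc$true_nonviable_fraction,
                              maps = maps)
  }
  stage_msg("fit", t0, "parameter maps fitted for all scans")

  sections <- simulate_histology(cohort,
                                 section_spacing_mm =
                                   config$histology_section_mm,
                                 area_noise_cv = config$histology_cv,
                                 seed = derive_seed(seed, 2L))
  hist_frac <- do.call(rbind, lapply(split(sections, sections$animal),
    function(s) data.frame(animal = s$animal[1], group = s$group[1],
                           histology = histology_volume_fraction(s),
                           stringsAsFactors = FALSE)))
  stage_msg("histology", t0, "synthetic histology sections sampled")

  animals <- design$animals
  sac_key <- paste(animals$animal, animals$sacrifice, sep = "_")
  group_of <- ifelse(animals$group == "control", "control",
                     animals$sacrifice)

  per_fv <- list()
  pair_rows <- list()
  true_rows <- list()
  rim_rows <- list()
  for (fv_name in names(config$feature_vectors)) {
    fv <- config$feature_vectors[[fv_name]]
    fm <- assemble_feature_matrix(fitted_scans, fv)
    nf <- normalize_features(fm)
    ip <- do.call(isodata_params,
                  c(config$isodata, list(seed = derive_seed(seed, 3L))))
    model <- isodata_cluster(nf, ip)
    ftab <- cluster_fraction_table(model, nf)
    cmap <- classify_clusters(ftab, design, alpha = config$alpha)
    viab <- make_viability_map(model, nf, cmap, fitted_scans)

    frac_at <- function(key) {
      i <- match(sub("_[^_]+$", "", key), viab$fractions$animal)
      tp <- sub("^.*_", "", key)
      v <- viab$fractions$fraction[viab$fractions$animal ==
                                     sub("_[^_]+$", "", key) &
                                     viab$fractions$timepoint == tp]
      if (length(v)) v[1] else NA_real_
    }
    isodata_frac <- vapply(sac_key, frac_at, numeric(1))
    pair_rows[[fv_name]] <- data.frame(
      feature_vector = fv_name, animal = animals$animal, group = group_of,
      histology = hist_frac$histology[match(animals$animal,
                                            hist_frac$animal)],
      isodata = isodata_frac, stringsAsFactors = FALSE)
    true_frac <- vapply(sac_key, function(k)
      cohort$scans[[k]]$true_nonviable_fraction, numeric(1))
    true_rows[[fv_name]] <- data.frame(
      feature_vector = fv_name, animal = animals$animal, group = group_of,
      true_fraction = true_frac, isodata = isodata_frac,
      stringsAsFactors = FALSE)

    treated_ids <- animals$animal[animals$group == "treated"]
    rim_vals <- vapply(treated_ids, function(a) {
      key <- paste(a, "pre", sep = "_")
      rim_misassignment_fraction(viab$volumes[[key]],
                                 fitted_scans[[key]]$maps$tumor_mask)
    }, numeric(1))
    rim_rows[[fv_name]] <- data.frame(feature_vector = fv_name,
                                      rim_fraction = mean(rim_vals,
                                                          na.rm = TRUE),
                                      stringsAsFactors = FALSE)
    per_fv[[fv_name]] <- list(model = model, fractions = ftab,
                              class_map = cmap,
                              viability_fractions = viab$fractions,
                              viability_volumes = viab$volumes,
                              rim_fractions = rim_vals)
    stage_msg("cluster", t0,
              sprintf("%s: %d clusters, %d non-viable", fv_name, model$k,
                      sum(cmap$class == "nonviable")))
  }
  pairs <- do.call(rbind, c(pair_rows, list(make.row.names = FALSE)))
  true_pairs <- do.call(rbind, c(true_rows, list(make.row.names = FALSE)))
  rim <- do.call(rbind, c(rim_rows, list(make.row.names = FALSE)))

  evaluation <- evaluate_feature_vectors(pairs, rim = rim,
                                         r2_threshold = config$r2_threshold,
                                         alpha = config$alpha)
  stage_msg("evaluate", t0,
            sprintf("selected feature vector: %s",
                    if (is.na(evaluation$selected)) "none"
                    else evaluation$selected))

  summary_sel <- NULL
  if (!is.na(evaluation$selected)) {
    sel <- per_fv[[evaluation$selected]]
    summary_sel <- summarize_parameters(
      fitted_scans,
      list(volumes = sel$viability_volumes),
      design)
  }

  result <- structure(list(
    config = config, design = design, protocol = protocol,
    fitted_scans = fitted_scans, per_fv = per_fv,
    sections = sections, histology_fractions = hist_frac,
    pairs = pairs, true_pairs = true_pairs, rim = rim,
    evaluation = evaluation, summary = summary_sel,
    checksum = config_checksum(config)
  ), class = "mpmri_pipeline")

  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(result, config$out_dir)
    stage_msg("write", t0, sprintf("artifacts written to %s",
                                   config$out_dir))
  }
  result
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ck <- result$checksum
  write_table_csv(result$pairs, file.path(dir, "fraction_pairs.csv"), ck)
  write_table_csv(result$true_pairs, file.path(dir, "true_fraction_pairs.csv"),
                  ck)
  write_table_csv(result$sections, file.path(dir, "histology_sections.csv"),
                  ck)
  write_table_csv(result$rim, file.path(dir, "rim_fractions.csv"), ck)
  write_table_csv(result$evaluation$r2, file.path(dir, "r2_identity.csv"), ck)
  write_table_csv(result$evaluation$correlations,
                  file.path(dir, "correlations.csv"), ck)
  if (!is.null(result$evaluation$wolfe))
    write_table_csv(result$evaluation$wolfe,
                    file.path(dir, "wolfe_tests.csv"), ck)
  if (!is.null(result$summary)) {
    write_table_csv(result$summary$summary,
                    file.path(dir, "parameter_summary.csv"), ck)
    if (!is.null(result$summary$tests))
      write_table_csv(result$summary$tests,
                      file.path(dir, "parameter_tests.csv"), ck)
  }
  sel <- result$evaluation$selected
  if (!is.na(sel)) {
    write_table_csv(result$per_fv[[sel]]$class_map,
                    file.path(dir, "cluster_classes.csv"), ck)
    write_table_csv(result$per_fv[[sel]]$viability_fractions,
                    file.path(dir, "viability_fractions.csv"), ck)
    vol_dir <- file.path(dir, "viability_volumes")
    dir.create(vol_dir, showWarnings = FALSE)
    pix <- result$protocol$pixdim
    for (key in names(result$per_fv[[sel]]$viability_volumes))
      write_volume(result$per_fv[[sel]]$viability_volumes[[key]],
                   file.path(vol_dir, sprintf("%s_viability.nii.gz", key)),
                   pix)
  }
  cfg <- result$config
  cfg$feature_vectors <- lapply(cfg$feature_vectors, as.character)
  yaml::write_yaml(c(unclass(cfg), list(checksum = ck)),
                   file.path(dir, "run_config.yaml"))
  invisible(dir)
}

#' @export
print.mpmri_pipeline <- function(x, ...) {
  cat("Multiparametric MRI segmentation pipeline run\n")
  cat(sprintf("  cohort: %d treated / %d controls; %d feature vectors\n",
              x$design$n_treated, x$design$n_control, length(x$per_fv)))
  print(x$evaluation)
  invisible(x)
}
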