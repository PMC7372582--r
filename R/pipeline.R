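# End-to-end orchestration: simulate -> preprocess -> train -> screen ->
# hits -> cluster -> report, with per-stage derived seeds, a JSON manifest
# and a summary report. The single run seed fans out deterministically to
# each stage so any stage can be rerun in isolation.

#' Build a pipeline run configuration
#'
#' Collects every stage's parameters in one (YAML-serializable) list. The
#' `screen` element is a [screen_config()]; the remaining elements carry
#' the preprocessing, classification, hit-calling and clustering
#' parameters with the package defaults.
#'
#' @param screen A [screen_config()] (its seed is overridden by `seed`).
#' @param seed Single integer run seed, fanned out to all stages.
#' @param min_cells QC threshold for [qc_filter_images()].
#' @param corr_cutoff,nzv_freq_cut,nzv_unique_cut Feature selection
#'   parameters.
#' @param moa_doses Doses pooled for classifier training.
#' @param ntree Random-forest size.
#' @param n_components PCA components for Mahalanobis hit calling.
#' @param threshold_method,threshold_alpha Distance threshold calibration
#'   (see [calibrate_distance_threshold()]); `threshold_method = "fixed"`
#'   with `threshold_value` uses an absolute squared-distance cutoff.
#' @param threshold_value Absolute threshold when `threshold_method =
#'   "fixed"` (e.g. the 1500 of a screen whose data scale is known).
#' @param eac_threshold,margin,min_eac_lines Selectivity rules.
#' @param run_loco Run leave-one-cell-line-out cross-validation.
#' @param shrinkage Covariance shrinkage for the DMSO reference.
#' @return A `run_config` list.
#' @export
run_config <- function(screen = screen_config(), seed = 1L,
                       min_cells = 20, corr_cutoff = 0.95,
                       nzv_freq_cut = 95 / 5, nzv_unique_cut = 0.1,
                       moa_doses = NULL, ntree = 500,
                       n_components = 15,
                       threshold_method = c("f", "chisq", "empirical",
                                            "fixed"),
                       threshold_alpha = 0.001, threshold_value = 1500,
                       eac_threshold = -3, margin = 2, min_eac_lines = 2,
                       run_loco = FALSE, shrinkage = "none") {
  threshold_method <- match.arg(threshold_method)
  cfg <- as.list(environment())
  cfg$screen$seed <- .derive_seed(seed, "synth")
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_run_config()]: a `run_config`; [write_run_config()]:
#'   `path`, invisibly.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sc_args <- y$screen %||% list()
  sc_args <- sc_args[intersect(names(sc_args), names(formals(screen_config)))]
  screen <- do.call(screen_config, sc_args)
  rc_args <- y[intersect(names(y), setdiff(names(formals(run_config)),
                                           "screen"))]
  do.call(run_config, c(list(screen = screen), rc_args))
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  y <- unclass(config)
  y$screen <- unclass(y$screen)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the full screen analysis pipeline
#'
#' Generates (or accepts) a screen, preprocesses every cell line, trains
#' the mechanism classifier on the reference library (when present),
#' computes Mahalanobis and nuclei-count z-score activities for the
#' screening library, applies the selectivity rules, clusters the panel's
#' response profiles, and — for synthetic screens — compares the called
#' selective set against the planted ground truth. All outputs, plus a
#' JSON manifest carrying the config hash and seed, are written under
#' `output_dir` when given.
#'
#' @param config A [run_config()].
#' @param output_dir Optional directory for CSV/JSON outputs.
#' @param screen Optional pre-generated `pheno_screen` (skips simulation;
#'   its ground truth, if any, is still used for the recovery report).
#' @return A `pheno_run` list: `screen`, `prep`, `moa`, `loco`, `hits`
#'   (per-line distances, z-scores, hit calls, `combined`), `clustering`,
#'   `report`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), output_dir = NULL,
                         screen = NULL) {
  t0 <- Sys.time()
  if (is.null(screen)) screen <- generate_screen(config$screen)
  cfg <- config
  panel_eac <- screen$config$eac_lines
  panel_ctrl <- screen$config$control_lines

  # --- preprocessing (per line) ----------------------------------------
  prep <- preprocess_screen(screen, min_cells = cfg$min_cells,
                            nzv_freq_cut = cfg$nzv_freq_cut,
                            nzv_unique_cut = cfg$nzv_unique_cut,
                            corr_cutoff = cfg$corr_cutoff)
  wells_by_line <- lapply(prep, `[[`, "wells")

  # --- mechanism classifier on the reference library -------------------
  moa <- NULL
  loco <- NULL
  has_ref <- nrow(screen$annotations) > 0
  if (has_ref) {
    moa <- lapply(names(wells_by_line), function(ln) {
      w <- wells_by_line[[ln]]
      ref_wells <- w[w$compound %in% c("DMSO", screen$annotations$compound), ]
      labeled <- build_training_set(ref_wells, screen$annotations,
                                    doses = cfg$moa_doses)
      train_moa_classifier(labeled, ntree = cfg$ntree,
                           seed = .derive_seed(cfg$seed, paste0("rf_", ln)))
    })
    names(moa) <- names(wells_by_line)
    if (isTRUE(cfg$run_loco) && length(panel_eac) >= 3) {
      harmonized <- harmonize_features(wells_by_line[panel_eac])
      labeled <- bind_rows(lapply(harmonized, function(w) {
        build_training_set(
          w[w$compound %in% c("DMSO", screen$annotations$compound), ],
          screen$annotations, doses = cfg$moa_doses)
      }))
      loco <- loco_cv(labeled, lines = panel_eac, ntree = cfg$ntree,
                      seed = .derive_seed(cfg$seed, "loco"))
    }
  }

  # --- phenotypic activity (PCA + Mahalanobis) per line ----------------
  screen_cmps <- unique(screen$platemap$compound[
    screen$platemap$role == "treatment" &
      !screen$platemap$compound %in% screen$annotations$compound])
  dist_rows <- list()
  pca_by_line <- list()
  for (ln in names(wells_by_line)) {
    w <- wells_by_line[[ln]]
    pca <- fit_pca(w, n_components = cfg$n_components)
    pca_by_line[[ln]] <- pca
    ref <- dmso_reference(pca, shrinkage = cfg$shrinkage)
    d2 <- mahalanobis_to_dmso(pca$scores, ref)
    thr <- switch(cfg$threshold_method,
                  fixed = cfg$threshold_value,
                  f = calibrate_distance_threshold(
                    ref, "f", cfg$threshold_alpha),
                  chisq = calibrate_distance_threshold(
                    ref, "chisq", cfg$threshold_alpha),
                  empirical = calibrate_distance_threshold(
                    ref, "empirical", cfg$threshold_alpha,
                    d2[pca$scores$role == "vehicle_control"]))
    sc <- pca$scores
    sc$distance <- d2
    per_cmp <- sc |>
      filter(.data$role == "treatment",
             .data$compound %in% screen_cmps) |>
      group_by(.data$compound) |>
      summarise(distance = median(.data$distance), .groups = "drop")
    per_cmp$cell_line <- ln
    per_cmp$threshold <- thr
    dist_rows[[ln]] <- per_cmp
  }
  distances <- bind_rows(dist_rows)

  hits <- NULL
  if (length(screen_cmps) > 0) {
    thr_by_line <- distances |>
      distinct(.data$cell_line, .data$threshold)
    pheno <- call_phenotypic_hits(
      distances, panel_eac, panel_ctrl,
      threshold = setNames(thr_by_line$threshold, thr_by_line$cell_line),
      min_eac_lines = cfg$min_eac_lines)

    # wells with QC-removed images have unreliable total counts (artifact
    # fields of view); exclude them from the viability arm and let the
    # incomplete-compound rule handle the gaps
    counts <- well_nuclei_counts(screen$cells)
    removed <- bind_rows(lapply(prep, function(p)
      distinct(p$qc_log[, c("cell_line", "plate", "well")])))
    if (nrow(removed) > 0) {
      counts <- anti_join(counts, removed,
                          by = c("cell_line", "plate", "well"))
    }
    zs <- compute_zscores(counts, screen$platemap)
    z_screen <- zs$per_compound[zs$per_compound$compound %in% screen_cmps, ]
    viab <- call_viability_hits(z_screen, panel_eac, panel_ctrl,
                                eac_threshold = cfg$eac_threshold,
                                margin = cfg$margin,
                                min_eac_lines = cfg$min_eac_lines)
    combined <- combine_hits(pheno, viab)
    hits <- list(distances = distances, zscores = z_screen,
                 phenotypic = pheno, viability = viab, combined = combined)
  }

  # --- response clustering ---------------------------------------------
  clustering <- NULL
  if (!is.null(hits)) {
    active <- union(hits$phenotypic$by_compound$compound[
      hits$phenotypic$by_compound$n_eac_hits > 0],
      hits$viability$by_compound$compound[
        hits$viability$by_compound$n_eac_hits > 0])
    rm_in <- hits$distances[hits$distances$compound %in% active,
                            c("compound", "cell_line", "distance")]
    names(rm_in)[3] <- "value"
    if (length(unique(rm_in$compound)) >= 3) {
      mat <- response_matrix(rm_in)
      if (nrow(mat) >= 3) {
        clustering <- cluster_cell_line_responses(mat)
      }
    }
  }

  # --- ground-truth recovery report ------------------------------------
  recovery <- NULL
  if (!is.null(screen$truth) && !is.null(hits)) {
    planted <- ground_truth_hit_set(screen$truth, cfg$min_eac_lines)
    called <- hits$combined$compound
    tp <- length(intersect(called, planted))
    recovery <- list(
      n_planted = length(planted), n_called = length(called),
      true_positives = tp,
      sensitivity = if (length(planted) > 0) tp / length(planted) else NA,
      fdr = if (length(called) > 0) 1 - tp / length(called) else 0)
  }

  report <- list(
    seed = cfg$seed,
    cell_lines = names(wells_by_line),
    wells_per_line = vapply(wells_by_line, nrow, integer(1)),
    images_removed = vapply(prep, function(p) nrow(p$qc_log), integer(1)),
    features_retained = vapply(wells_by_line,
                               function(w) length(feature_columns(w)),
                               integer(1)),
    features_dropped = lapply(prep, function(p) table(p$report$reason)),
    oob_error = if (has_ref) vapply(moa, `[[`, numeric(1), "oob_error"),
    n_selective_phenotypic = if (!is.null(hits))
      sum(hits$phenotypic$by_compound$selective),
    n_selective_viability = if (!is.null(hits))
      sum(hits$viability$by_compound$selective),
    n_selective_any = if (!is.null(hits)) nrow(hits$combined),
    recovery = recovery,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  run <- structure(list(screen = screen, prep = prep, moa = moa,
                        loco = loco, hits = hits, clustering = clustering,
                        report = report, config = cfg),
                   class = "pheno_run")
  if (!is.null(output_dir)) {
    run$manifest <- .write_run_outputs(run, output_dir)
  }
  run
}

# Serialize the run's tabular outputs plus a manifest with the config hash.
.write_run_outputs <- function(run, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(name) { p <- file.path(output_dir, name); paths[name] <<- p; p }

  cfg_path <- put("config.yaml")
  write_run_config(run$config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  write_platemap(run$screen$platemap, put("platemap.csv"))
  for (ln in names(run$prep)) {
    write_profiles(run$prep[[ln]]$wells,
                   put(paste0("profiles_", gsub("[^A-Za-z0-9]", "_", ln),
                              ".csv")))
  }
  if (!is.null(run$hits)) {
    ht <- left_join(run$hits$distances,
                    run$hits$zscores[, c("compound", "cell_line", "z")],
                    by = c("compound", "cell_line"))
    ht$phenotypic_hit <- ht$distance > ht$threshold
    write_hit_table(ht, put("hit_table.csv"))
    write_hit_table(run$hits$combined, put("selective_hits.json"),
                    format = "json")
  }
  if (!is.null(run$clustering)) {
    export_dendrogram(run$clustering, put("cell_line_dendrogram.nwk"))
  }
  rep_path <- put("report.json")
  jsonlite::write_json(run$report, rep_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  manifest <- list(config_hash = cfg_hash, seed = run$config$seed,
                   created = format(Sys.time(), tz = "UTC"),
                   outputs = as.list(paths))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE)
  manifest
}

#' @export
print.pheno_run <- function(x, ...) {
  r <- x$report
  cat("phenoscreen pipeline run (seed ", r$seed, ")\n", sep = "")
  cat("  lines: ", paste(r$cell_lines, collapse = ", "), "\n")
  cat("  wells/line: ", paste(r$wells_per_line, collapse = ", "), "\n")
  if (!is.null(r$oob_error)) {
    cat(sprintf("  OOB error per line: %s\n",
                paste(sprintf("%.1f%%", 100 * r$oob_error), collapse = ", ")))
  }
  if (!is.null(r$n_selective_any)) {
    cat("  selective hits: ", r$n_selective_phenotypic, " phenotypic, ",
        r$n_selective_viability, " viability, ", r$n_selective_any,
        " combined\n", sep = "")
  }
  if (!is.null(r$recovery)) {
    cat(sprintf("  planted-hit recovery: sensitivity %.2f, FDR %.2f\n",
                r$recovery$sensitivity, r$recovery$fdr))
  }
  invisible(x)
}
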