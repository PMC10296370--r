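#' Pipeline configuration
#'
#' Collects every stage parameter with the analysis defaults: 8
#' unwanted-variation factors, 80 clinical pseudo-replicate clusters, top
#' 200 lipid features, 50-repeat five-fold cross-validation for
#' classifiability, BMI cutoff 25 kg/m2, and 5% FDR. Either `simulate`
#' (a [sim_config()]) or both file paths must be provided.
#'
#' @param simulate Optional [sim_config()]; when given, the run starts by
#'   generating a synthetic cohort.
#' @param clinical_path,lipid_path Input CSVs when not simulating.
#' @param discovery_fraction Recruitment fraction forming the discovery
#'   cohort.
#' @param k,n_clusters,batch_fdr,bio_p,n_pcs Normalization parameters.
#' @param fdr Association FDR threshold.
#' @param n_features,penalty Fixed LRS hyperparameters; when `NULL` both are
#'   chosen by [select_lrs_features()].
#' @param penalty_grid,n_features_grid,n_boot Bootstrap-selection settings.
#' @param ics_repeats,ics_folds Classifiability cross-validation settings.
#' @param ics_threshold Binary-call rule inside the classifiability
#'   cross-validation: "half" (posterior 0.5, the native class prediction of
#'   a logistic model) or "youden".
#' @param bmi_cutoff Stratification boundary.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL,
                            clinical_path = NULL, lipid_path = NULL,
                            discovery_fraction = 394 / 580,
                            k = 8, n_clusters = 80,
                            batch_fdr = 0.05, bio_p = 0.05, n_pcs = 30,
                            fdr = 0.05,
                            n_features = NULL, penalty = NULL,
                            penalty_grid = 10^seq(-3, 3),
                            n_features_grid = c(50, 100, 200),
                            n_boot = 100,
                            ics_repeats = 50, ics_folds = 5,
                            ics_threshold = "half",
                            bmi_cutoff = 25,
                            seed = 1L) {
  if (is.null(simulate) && (is.null(clinical_path) || is.null(lipid_path))) {
    abort("pipeline_config: provide either a simulate config or both input paths")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
          parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data simulation or loading; sCAD labelling and
#' recruitment split; pseudo-replicate RUV-III normalization fitted on the
#' discovery cohort (plus QC samples) and transferred frozen to the
#' validation cohort; per-species association with FDR control on the
#' combined cohort; Framingham, lipid-ridge and combined model fits on the
#' discovery cohort; individual classifiability, modifying-variable scan and
#' BMI stratification; and validation ROC/AUC evaluation with DeLong's test
#' and the per-individual model-overlap table. Artifacts are written to
#' `out_dir` with a manifest recording the config hash, seed and package
#' version.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; `NULL` skips writing files.
#' @return List with every stage's result.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  dat <- stage("load", {
    if (!is.null(config$simulate)) {
      sim <- simulate_cohort(config$simulate)
      list(clinical = sim$clinical, lipids = sim$lipids, truth = sim$truth)
    } else {
      load_cohort(config$clinical_path, config$lipid_path)
    }
  })
  clinical <- dat$clinical
  lipids <- dat$lipids

  labels <- stage("label", assign_scad_labels(clinical))
  split <- stage("split",
                 split_by_recruitment(labels, clinical, config$discovery_fraction))
  disc_ids <- split$sample_id[split$cohort == "discovery"]
  valid_ids <- split$sample_id[split$cohort == "validation"]
  qc_ids <- clinical$sample_id[clinical$role != "study"]

  norm <- stage("normalize", {
    fit_rows <- lipids$sample_id %in% c(disc_ids, qc_ids)
    lip_fit <- lipids[fit_rows, ]
    clin_fit <- clinical[match(lip_fit$sample_id, clinical$sample_id), ]
    reps <- make_pseudo_replicates(clin_fit,
                                   n_clusters = min(config$n_clusters,
                                                    length(disc_ids)))
    controls <- select_control_features(lip_fit, clin_fit,
                                        batch_fdr = config$batch_fdr,
                                        bio_p = config$bio_p)
    fit <- ruv3_fit(lip_fit, reps, controls, k = config$k)
    lip_valid <- lipids[lipids$sample_id %in% valid_ids, ]
    adj_valid <- ruv3_transfer(lip_valid, fit$model)
    diag_pre <- pca_diagnostics(lip_fit, clin_fit,
                                n_pcs = min(config$n_pcs, nrow(lip_fit) - 1))
    diag_post <- pca_diagnostics(fit$adjusted, clin_fit,
                                 n_pcs = min(config$n_pcs, nrow(lip_fit) - 1))
    adj_disc <- fit$adjusted[fit$adjusted$sample_id %in% disc_ids, ]
    list(model = fit$model, controls = controls,
         adjusted_discovery = adj_disc, adjusted_validation = adj_valid,
         diagnostics_pre = diag_pre, diagnostics_post = diag_post)
  })
  adj_disc <- norm$adjusted_discovery
  adj_valid <- norm$adjusted_validation
  adj_all <- bind_rows(adj_disc, adj_valid)

  assoc <- stage("associate", {
    fit_lipid_associations(adj_all, labels, clinical = clinical)
  })
  forest <- stage("associate", export_forest_data(assoc, fdr = config$fdr))

  models <- stage("train", {
    clin_disc <- clinical[match(disc_ids, clinical$sample_id), ]
    clin_valid <- clinical[match(valid_ids, clinical$sample_id), ]
    frs_disc <- setNames(framingham_risk(clin_disc), disc_ids)
    frs_valid <- setNames(framingham_risk(clin_valid), valid_ids)

    # fixed hyperparameters collapse the grid to a single point; the
    # bootstrap informativity ranking is used either way
    sel <- select_lrs_features(
      adj_disc, labels,
      penalty_grid = config$penalty %||% config$penalty_grid,
      n_features_grid = config$n_features %||% config$n_features_grid,
      n_boot = config$n_boot,
      seed = seed + 10L, split = split
    )
    penalty <- sel$chosen_penalty
    n_feat <- sel$chosen_n
    features <- sel$ranking[seq_len(n_feat)]

    lrs <- fit_ridge_logistic(adj_disc, labels, penalty, features = features)
    frs_model <- fit_frs_model(frs_disc, labels)
    combined <- fit_combined(adj_disc, frs_disc, labels, penalty,
                             features = features)
    list(lrs = lrs, frs = frs_model, combined = combined,
         selection = sel, features = features, penalty = penalty,
         frs_discovery = frs_disc, frs_validation = frs_valid)
  })

  ics <- stage("ics", {
    compute_ics(adj_disc, labels, features = models$features,
                penalty = models$penalty,
                r = config$ics_repeats, f = config$ics_folds,
                seed = seed + 20L, threshold = config$ics_threshold)
  })
  scan <- stage("ics", find_modifying_variable(ics, clinical))
  strata <- stage("ics", {
    win <- attr(scan, "winner")
    wv <- clinical[[win]][clinical$role == "study"]
    cutoff <- if (win == "bmi") config$bmi_cutoff else
      if (is.logical(wv)) 0.5 else median(wv, na.rm = TRUE)
    stratify_cohort(clinical, variable = win, cutoff = cutoff)
  })

  evalr <- stage("evaluate", {
    clin_valid <- clinical[match(valid_ids, clinical$sample_id), ]
    vdata <- adj_valid |> mutate(frs = unname(models$frs_validation[.data$sample_id]))
    mods <- list(lrs = models$lrs, frs = models$frs, combined = models$combined)
    aucs <- evaluate_subcohorts(mods, vdata, labels, strata)
    pred_lrs <- predict_risk(models$lrs, vdata)
    pred_frs <- predict_risk(models$frs, vdata)
    y_valid <- labels_to_binary(labels, pred_lrs$sample_id)
    dl <- delong_test(pred_lrs$risk, pred_frs$risk, y_valid)
    overlap <- compare_model_targets(pred_lrs$call, pred_frs$call, y_valid)
    list(auc_table = aucs, delong_lrs_vs_frs = dl, overlap = overlap,
         pred_lrs = pred_lrs, pred_frs = pred_frs)
  })

  result <- list(
    clinical = clinical, lipids = lipids, labels = labels, split = split,
    normalization = norm, associations = assoc, forest = forest,
    models = models, ics = ics, modifier_scan = scan, strata = strata,
    evaluation = evalr, truth = dat$truth, config = config
  )

  if (!is.null(out_dir)) stage("write", write_pipeline_artifacts(result, out_dir))
  result
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) readr::write_csv(x, file.path(out_dir, f))
  w(result$labels, "labels.csv")
  w(result$split, "split.csv")
  w(result$normalization$diagnostics_pre, "pc_diagnostics_pre.csv")
  w(result$normalization$diagnostics_post, "pc_diagnostics_post.csv")
  w(result$associations, "associations.csv")
  w(result$forest, "forest.csv")
  w(result$ics, "ics.csv")
  w(as_tibble(result$modifier_scan), "modifier_scan.csv")
  w(result$strata, "strata.csv")
  w(result$evaluation$auc_table, "auc_table.csv")
  w(result$evaluation$overlap, "overlap.csv")
  jsonlite::write_json(
    list(
      delong = glance(result$evaluation$delong_lrs_vs_frs),
      models = purrr::map(result$models[c("lrs", "frs", "combined")], glance)
    ),
    file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  cfg <- result$config
  cfg$simulate <- unclass(cfg$simulate)
  jsonlite::write_json(
    list(config_hash = rlang::hash(cfg), seed = result$config$seed,
         package_version = as.character(packageVersion("lipidcad")),
         created = format(Sys.time(), tz = "UTC")),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
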