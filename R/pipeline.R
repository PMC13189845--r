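#' Pipeline configuration
#'
#' Nested configuration for the full simulate -> preprocess -> habitats ->
#' features -> select -> train -> evaluate pipeline. Every block falls back
#' to its module defaults; the single global seed is expanded
#' deterministically into per-stage seeds. Round-trips through YAML.
#'
#' @param n_per_site Patients per site.
#' @param positive_fraction Fraction of malignant cases per site.
#' @param cohort A [cohort_config()].
#' @param preprocess A [preprocess_config()].
#' @param k_range Candidate cluster numbers for habitat selection.
#' @param min_habitat_voxels Minimum habitat size.
#' @param features A [feature_config()].
#' @param selection A [selection_config()].
#' @param cv_folds Logistic-model CV folds.
#' @param train_fraction Training share of the pooled non-external sites.
#' @param external_site Site held out for external validation.
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_per_site = c(site_A = 12, site_B = 12, site_C = 16),
                            positive_fraction = 0.45,
                            cohort = cohort_config(),
                            preprocess = preprocess_config(),
                            k_range = 2:10,
                            min_habitat_voxels = 64L,
                            features = feature_config(),
                            selection = selection_config(),
                            cv_folds = 5L,
                            train_fraction = 0.7,
                            external_site = "site_C",
                            seed = 1L) {
  structure(list(n_per_site = n_per_site, positive_fraction = positive_fraction,
                 cohort = cohort, preprocess = preprocess, k_range = k_range,
                 min_habitat_voxels = as.integer(min_habitat_voxels),
                 features = features, selection = selection,
                 cv_folds = as.integer(cv_folds),
                 train_fraction = train_fraction,
                 external_site = external_site, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read/write a pipeline configuration as YAML
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns the path;
#'   `read_pipeline_config()` the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) return(lapply(unclass(x), strip))
    x <- unclass(x)
    if (!is.null(names(x))) as.list(x) else x # keep names through YAML maps
  }
  yaml::write_yaml(strip(config), path)
  path
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cohort <- do.call(cohort_config, raw$cohort[setdiff(names(raw$cohort), c("signature_pool"))])
  pipeline_config(
    n_per_site = unlist(raw$n_per_site),
    positive_fraction = raw$positive_fraction,
    cohort = cohort,
    preprocess = do.call(preprocess_config, raw$preprocess),
    k_range = raw$k_range,
    min_habitat_voxels = raw$min_habitat_voxels,
    features = do.call(feature_config, raw$features),
    selection = do.call(selection_config, raw$selection),
    cv_folds = raw$cv_folds,
    train_fraction = raw$train_fraction,
    external_site = raw$external_site,
    seed = raw$seed
  )
}

# Stratified 7:3-style split of the pooled non-external sites.
split_cohort <- function(manifest, external_site, train_fraction, seed) {
  pooled <- manifest$patient_id[manifest$site != external_site]
  y <- manifest$label[manifest$site != external_site]
  train_ids <- character()
  with_seed(seed, {
    for (cls in unique(y)) {
      ids <- pooled[y == cls]
      n_tr <- round(train_fraction * length(ids))
      train_ids <- c(train_ids, sample(ids, n_tr))
    }
  })
  list(
    train = train_ids,
    test = setdiff(pooled, train_ids),
    external = manifest$patient_id[manifest$site == external_site]
  )
}

#' Run the full habitat-radiomics study on a synthetic cohort
#'
#' Simulates a three-site cohort, preprocesses every patient (bias
#' correction, resampling, per-patient z-scoring for clustering), selects
#' the global cluster number on the training patients, clusters all
#' patients at that k with canonical descending-ADC habitat labels,
#' extracts 321 features for the whole lesion and each habitat, runs the
#' staged feature selection and fits one logistic model per region, and
#' evaluates every model on the training, test and external cohorts
#' together with the mean-ADC baseline.
#'
#' @param config A [pipeline_config()].
#' @param phantoms Optional pre-built cohort (as from [make_cohort()]);
#'   simulated from the config when omitted.
#' @return A `habitat_study`: `results` (tibble model x cohort with AUC and
#'   CI), `models`, `selections`, `evaluations`, `k_global`, `features`
#'   (the full feature table), `split`, `manifest`.
#' @export
run_study <- function(config = pipeline_config(), phantoms = NULL) {
  seed <- config$seed
  if (is.null(phantoms)) {
    cohort <- make_cohort(config$n_per_site, config$positive_fraction,
                          config$cohort, seed = derive_seed(seed, "simulate"))
  } else {
    cohort <- phantoms
  }
  manifest <- cohort$manifest

  prep <- purrr::map(cohort$phantoms, preprocess_patient,
                     config = config$preprocess)

  split <- split_cohort(manifest, config$external_site,
                        config$train_fraction, derive_seed(seed, "split"))

  vox <- purrr::map(prep, function(p) {
    build_voxel_matrix(p$standardized %||% p$volume, p$mask)
  })
  ksel <- cohort_k_selection(vox[split$train], config$k_range,
                             seed = derive_seed(seed, "kselect"))
  k <- ksel$k_global

  habitats <- purrr::imap(prep, function(p, id) {
    km <- kmeans_fit(vox[[id]], k, seed = derive_seed(seed, paste0("km_", id)))
    assign_habitats(km, p$mask, p$volume, min_size = config$min_habitat_voxels)
  })

  features <- extract_cohort_features(prep, habitats, manifest, config$features)

  region_names <- c("whole", paste0("habitat_", seq_len(k)))
  feat_cols <- feature_names(config$features)
  models <- list(); selections <- list(); evaluations <- list(); rows <- list()

  label_of <- setNames(manifest$label, manifest$patient_id)
  for (rg in region_names) {
    sub <- dplyr::filter(features, .data$region == rg)
    sub <- sub[match(manifest$patient_id, sub$patient_id), ]
    complete <- stats::complete.cases(sub[feat_cols])
    tab <- sub[feat_cols]
    ids <- sub$patient_id
    tr <- ids %in% split$train & complete
    if (sum(tr) < 4 || length(unique(label_of[ids[tr]])) < 2) next
    sel <- select_features(tab[tr, ], label_of[ids[tr]], config$selection)
    model <- fit_logistic(tab[tr, ], label_of[ids[tr]],
                          features = sel$survivors,
                          cv_folds = config$cv_folds,
                          seed = derive_seed(seed, paste0("cv_", rg)))
    selections[[rg]] <- sel
    models[[rg]] <- model
    for (coh in c("train", "test", "external")) {
      use <- ids %in% split[[coh]] & complete
      if (sum(use) < 4 || min(table(label_of[ids[use]])) < 2) next
      ev <- evaluate_model(model, tab[use, ], label_of[ids[use]])
      evaluations[[paste(rg, coh, sep = ".")]] <- ev
      n_feat <- length(model$feature_names)
      rows[[paste(rg, coh, sep = ".")]] <- tibble::tibble(
        model = rg, cohort = coh, n = sum(use), auc = ev$auc,
        auc_lo = ev$auc_ci[1], auc_hi = ev$auc_ci[2],
        n_features = n_feat
      )
    }
  }

  # mean-ADC baseline on the preprocessed (unstandardized) ADC maps
  adc_scores <- mean_adc_baseline(
    purrr::map(prep, function(p) p$volume$adc),
    purrr::map(prep, function(p) p$mask)
  )
  adc_scores$patient_id <- names(prep)
  for (coh in c("train", "test", "external")) {
    use <- adc_scores$patient_id %in% split[[coh]]
    y <- label_of[adc_scores$patient_id[use]]
    if (length(unique(y)) < 2 || min(table(y)) < 2) next
    ci <- delong_ci(adc_scores$score[use], y)
    rows[[paste("mean_adc", coh, sep = ".")]] <- tibble::tibble(
      model = "mean_adc", cohort = coh, n = sum(use), auc = ci[["auc"]],
      auc_lo = ci[["lo"]], auc_hi = ci[["hi"]], n_features = 1L
    )
  }

  structure(
    list(results = dplyr::bind_rows(rows), models = models,
         selections = selections, evaluations = evaluations,
         k_global = k, k_selection = ksel, features = features,
         habitats = habitats, split = split, manifest = manifest,
         adc_baseline = adc_scores, config = config),
    class = "habitat_study"
  )
}

#' @export
print.habitat_study <- function(x, ...) {
  cat(sprintf("Habitat radiomics study: %d patients, global k = %d\n",
              nrow(x$manifest), x$k_global))
  print(tidyr::pivot_wider(x$results[c("model", "cohort", "auc")],
                           names_from = "cohort", values_from = "auc"))
  invisible(x)
}

#' Run the pipeline and write versioned artifacts
#'
#' Executes simulate -> write/read NIfTI -> preprocess -> habitats ->
#' features -> select -> train -> evaluate, writing per-stage outputs
#' (NIfTI dataset + manifest, habitat label maps, Calinski-Harabasz
#' curves, feature table, selection JSON, evaluation JSON) under
#' `output_dir`. Reruns with the same config and seed reproduce all
#' numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Artifact directory.
#' @return The `habitat_study`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- make_cohort(config$n_per_site, config$positive_fraction,
                        config$cohort, seed = derive_seed(config$seed, "simulate"))
  man <- write_nifti_dataset(cohort, file.path(output_dir, "nifti"))
  reread <- read_cohort(file.path(output_dir, "nifti", "manifest.csv"))
  study <- run_study(config, phantoms = reread)

  for (id in names(study$habitats)) {
    write_nifti_volume(study$habitats[[id]]$labels,
                       config$preprocess$target_spacing_mm,
                       file.path(output_dir, sprintf("%s_habitats.nii.gz", id)),
                       integer = TRUE)
  }
  readr::write_csv(study$k_selection$curves, file.path(output_dir, "ch_curves.csv"))
  readr::write_csv(study$features, file.path(output_dir, "features.csv"))
  sel_json <- purrr::map(study$selections, function(s) {
    list(stages = s$stages, survivors = s$survivors, lambda = s$lasso$lambda)
  })
  jsonlite::write_json(sel_json, file.path(output_dir, "selection.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(k_global = study$k_global,
         results = study$results),
    file.path(output_dir, "evaluation.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  write_pipeline_config(config, file.path(output_dir, "config.yaml"))
  invisible(study)
}
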