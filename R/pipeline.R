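#' Configuration for the end-to-end modelling pipeline
#'
#' Collects paths and parameters for a full run: curation thresholds,
#' cross-validation settings, the train/test split, the baseline model
#' list, an optional feature-subset selector (mirroring total-protein-only
#' and phosphoprotein-only model variants), and an optional perturbation
#' stage.  Defaults follow the study conventions: 25% detection, 0.2
#' resistance cutoff, 7 folds, 0.05 Q2Y increment, 6 test samples.
#'
#' @param matrix_path,response_path Required input files (see
#'   [read_feature_matrix()], [read_response()]).
#' @param sample_meta_path,annotations_path Optional metadata sidecars.
#' @param detection_threshold,resistance_threshold,folds,delta_q2,max_orthogonal,test_n,seed
#'   Pipeline parameters.
#' @param models Baseline models for the comparison stage (`NULL` skips it).
#' @param feature_subset `"all"`, `"total_only"`, `"phospho_only"`,
#'   `"receptor_only"`, or a character vector of feature ids.
#' @param perturb Optional list with `samples` and `features` for the
#'   in-silico inhibition stage (runs on a receptor-only model).
#' @param out_dir Output directory for run artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix_path, response_path,
                            sample_meta_path = NULL, annotations_path = NULL,
                            detection_threshold = 0.25,
                            resistance_threshold = 0.2,
                            folds = 7, delta_q2 = 0.05, max_orthogonal = 3,
                            test_n = 6, seed = 1,
                            models = NULL, feature_subset = "all",
                            perturb = NULL, out_dir = tempfile("opls_run_")) {
  stopifnot(detection_threshold > 0, detection_threshold <= 1,
            resistance_threshold > 0, resistance_threshold < 1,
            folds >= 2, delta_q2 >= 0, test_n >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' @param path Config file; keys match [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

run_stage <- function(name, manifest_env, expr) {
  message(sprintf("[%s] start", name))
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  manifest_env$stages <- c(manifest_env$stages, name)
  res
}

subset_features <- function(x, selector) {
  if (identical(selector, "all")) return(x)
  keep <- switch(
    paste(selector[1], collapse = ""),
    total_only = which(x$feature_meta$kind == "total"),
    phospho_only = which(x$feature_meta$kind == "phospho"),
    receptor_only = which(x$feature_meta$is_receptor),
    which(x$feature_meta$feature_id %in% selector)
  )
  if (!length(keep)) stop("feature subset selector matched no features")
  x[, keep]
}

#' Run the full curation / modelling / comparison pipeline
#'
#' Executes read -> curate (intersect, detection-filter, impute,
#' autoscale) -> stratified split -> O-PLS fit -> VIP/signature ->
#' optional baseline comparison -> optional receptor perturbation, writing
#' every artifact plus a machine-readable manifest into the configured
#' output directory.  Any stage error is re-signalled with the stage name;
#' artifacts produced before the failure are retained alongside a
#' `FAILED` marker file.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the fitted `model`, `vip`, `signature`,
#'   `split`, optional `comparison` and `perturbation`, and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$matrix_path, config$response_path,
              config$sample_meta_path, config$annotations_path))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  env <- new.env(); env$stages <- character()

  result <- tryCatch({
    x <- run_stage("read", env, read_feature_matrix(
      config$matrix_path, annotations = config$annotations_path,
      sample_meta = config$sample_meta_path))
    y <- run_stage("read_response", env, read_response(config$response_path))

    curated <- run_stage("curate", env, {
      x <- subset_features(x, config$feature_subset)
      al <- intersect_datasets(x, y)
      filt <- filter_by_detection(al$x, config$detection_threshold)
      message(sprintf("  curated: %d samples x %d features (of %d)",
                      nrow(filt$values), ncol(filt$values),
                      ncol(x$values)))
      sc <- autoscale(impute_missing(filt))
      list(x = sc$x, scaling = sc$scaling, y = al$y, raw = filt)
    })
    write_feature_matrix(curated$x, file.path(config$out_dir, "curated_matrix.tsv"))

    split <- run_stage("split", env, stratified_split(
      curated$x, curated$y, test_n = config$test_n, seed = config$seed,
      threshold = config$resistance_threshold))

    model <- run_stage("fit", env, {
      xtr <- curated$x[split$train_ids, ]
      m <- fit_opls(xtr, curated$y$auc[split$train_ids],
                    max_orthogonal = config$max_orthogonal,
                    folds = config$folds, delta_q2 = config$delta_q2,
                    seed = config$seed, scaling = curated$scaling)
      message(sprintf("  R2Y=%.3f Q2Y=%.3f, %d orthogonal component(s)",
                      m$stats$R2Y, m$stats$Q2Y, m$n_orthogonal))
      m
    })
    save_opls(model, file.path(config$out_dir, "model.json"))

    vip <- run_stage("vip", env, compute_vip(model))
    utils::write.table(vip, file.path(config$out_dir, "vip.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    signature <- run_stage("signature", env, select_signature(vip))
    utils::write.table(signature, file.path(config$out_dir, "signature.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    scores <- scores_projection(model, curated$raw)
    utils::write.table(scores, file.path(config$out_dir, "scores.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

    comparison <- NULL
    if (!is.null(config$models)) {
      comparison <- run_stage("compare", env, run_baselines(
        train = list(x = curated$x[split$train_ids, ],
                     y = curated$y$auc[split$train_ids]),
        test = list(x = curated$x[split$test_ids, ],
                    y = curated$y$auc[split$test_ids]),
        model_specs = config$models, seed = config$seed))
      write_comparison_report(comparison,
                              file.path(config$out_dir, "comparison.tsv"),
                              file.path(config$out_dir, "comparison.json"))
    }

    perturbation <- NULL
    if (!is.null(config$perturb)) {
      perturbation <- run_stage("perturb", env, {
        rm_model <- build_receptor_model(curated$raw, curated$y,
                                         folds = config$folds,
                                         seed = config$seed)
        simulate_inhibition(rm_model, curated$raw,
                            target_samples = config$perturb$samples,
                            target_features = config$perturb$features)
      })
      utils::write.table(perturbation,
                         file.path(config$out_dir, "perturbation.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }

    list(model = model, vip = vip, signature = signature, split = split,
         comparison = comparison, perturbation = perturbation,
         out_dir = config$out_dir)
  }, error = function(e) {
    writeLines(conditionMessage(e), file.path(config$out_dir, "FAILED"))
    stop(e)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("oplsense")),
    config = lapply(unclass(config), function(v) if (is.null(v)) NULL else v),
    stages = env$stages,
    n_samples = length(result$split$train_ids) + length(result$split$test_ids),
    n_features = length(result$model$feature_ids),
    n_orthogonal = result$model$n_orthogonal,
    stats = result$model$stats[c("R2Y", "Q2Y", "R2X_pred", "R2X_orthog")],
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(result)
}
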