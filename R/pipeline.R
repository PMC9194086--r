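#' End-to-end obstruction-prediction pipeline
#'
#' Chains every stage on one cohort: imaging/age train-validation split,
#' log2 transform, per-gene standardization fitted on the training samples
#' (optionally on all samples), covariate-adjusted differential expression
#' on the full cohort, stability-voting feature selection on the training
#' slice, then the requested classifier heads trained on the selected
#' features and evaluated on both slices.
#'
#' @param cohort a [simulate_cohort()] result, or a list with elements
#'   `matrix` (raw [expr_matrix()]) and `metadata`.
#' @param n_non_validation non-obstructive validation count for
#'   [split_cohort()].
#' @param selection a [selection_config()].
#' @param features optional explicit feature set (skips selection).
#' @param require_deg if `TRUE`, intersect selected features with DEG calls.
#' @param fc_threshold,alpha DEG rule parameters.
#' @param algorithms classifier heads to train.
#' @param folds CV folds for hyperparameter choice.
#' @param seed integer seed for the training stage.
#' @param scale_on fit the standardizer on `"train"` (leakage-safe default)
#'   or `"all"` samples.
#' @return a list with `split`, `scaler`, `degs`, `votes`, `features`,
#'   `models` (per algorithm: `model`, `train_report`, `validation_report`)
#'   and the standardized matrices.
#' @export
run_pipeline <- function(cohort, n_non_validation = 6,
                         selection = selection_config(),
                         features = NULL, require_deg = FALSE,
                         fc_threshold = 1, alpha = 0.05,
                         algorithms = c("glm_elastic_net", "random_forest",
                                        "svm_linear"),
                         folds = 7, seed = 1,
                         scale_on = c("train", "all")) {
  scale_on <- match.arg(scale_on)
  md <- validate_metadata(cohort$metadata)
  x_raw <- cohort$matrix
  split <- split_cohort(md, n_non_validation)
  train_ids <- split$sample_id[split$set == "train"]
  valid_ids <- split$sample_id[split$set == "validation"]
  x_log <- log_transform(x_raw)
  scaler <- fit_scaler(x_log, if (scale_on == "train") train_ids else NULL)
  x_std <- apply_scaler(x_log, scaler)
  labels <- stats::setNames(md$group, md$sample_id)
  degs <- call_degs(x_log, md, fc_threshold = fc_threshold, alpha = alpha)

  x_train <- subset_matrix(x_std, samples = train_ids)
  votes <- NULL
  if (is.null(features)) {
    votes <- run_selection(x_train, labels[train_ids], selection)
    features <- votes$final_features
    if (require_deg)
      features <- intersect(features, degs$gene_id[degs$status != "ns"])
  }
  models <- list()
  if (length(features) == 0) {
    message("no features selected; classifier heads skipped")
  } else {
    x_valid <- subset_matrix(x_std, samples = valid_ids)
    for (alg in algorithms) {
      m <- train_model(x_train, labels[train_ids], features, algorithm = alg,
                       folds = folds, seed = seed,
                       num_trees = selection$num_trees)
      tr_rep <- compute_report(predict_scores(m, x_train), labels[train_ids])
      va_rep <- if (length(valid_ids))
        compute_report(predict_scores(m, x_valid), labels[valid_ids])
      models[[alg]] <- list(model = m, train_report = tr_rep,
                            validation_report = va_rep)
    }
  }
  list(split = split, scaler = scaler, degs = degs, votes = votes,
       features = features, models = models, matrix_log = x_log,
       matrix_std = x_std, metadata = md)
}
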