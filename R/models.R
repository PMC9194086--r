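# Positive class everywhere in the package: "obstructive".
POSITIVE <- "obstructive"

as_label_factor <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (!all(labels %in% c("obstructive", "non_obstructive")))
    stop("labels must be 'obstructive' or 'non_obstructive'")
  factor(labels, levels = c("non_obstructive", "obstructive"))
}

#' Default hyperparameter grids for the three classifier heads
#'
#' The grids mirror the study protocol: elastic net with 14 evenly spaced
#' mixing values alpha in \[0, 0.8\] crossed with penalty strengths lambda in
#' \[0, 1\] (21 evenly spaced values by default); random forest with
#' `mtry` in 1..4; linear SVM with 11 log-spaced costs C from 1e-4 to 1.
#'
#' @param algorithm `"glm_elastic_net"`, `"random_forest"` or `"svm_linear"`.
#' @param n_lambda number of lambda values for the elastic-net grid.
#' @return a named list of candidate parameter vectors.
#' @export
default_grid <- function(algorithm = c("glm_elastic_net", "random_forest",
                                       "svm_linear"),
                         n_lambda = 21) {
  switch(match.arg(algorithm),
         glm_elastic_net = list(alpha = seq(0, 0.8, length.out = 14),
                                lambda = seq(0, 1, length.out = n_lambda)),
         random_forest = list(mtry = 1:4),
         svm_linear = list(C = 10^seq(-4, 0, length.out = 11)))
}

# Stratified k-fold assignment: within each class, a random permutation is
# dealt round-robin into folds, so fold sizes differ by at most one per
# class and every fold keeps both classes when k <= min class size.
stratified_folds <- function(labels, k, seed) {
  y <- as_label_factor(labels)
  if (k < 2) stop("cv_folds must be >= 2")
  if (k > min(table(y)))
    stop("cv_folds exceeds the smallest class size (", min(table(y)), ")")
  fold <- integer(length(y))
  withr::local_seed(seed)
  for (cl in levels(y)) {
    i <- which(y == cl)
    fold[i] <- (sample(seq_along(i)) - 1L) %% k + 1L
  }
  fold
}

#' Area under the ROC curve by the Mann-Whitney definition
#'
#' The probability that a random positive (obstructive) sample outscores a
#' random negative one, counting ties as 1/2 — computed from midranks, so
#' it equals exhaustive pair counting exactly.
#'
#' @param scores numeric scores, higher meaning more obstructive-like.
#' @param labels class labels (both classes must be present).
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(scores, labels) {
  y <- as_label_factor(labels)
  n_pos <- sum(y == POSITIVE); n_neg <- sum(y != POSITIVE)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == POSITIVE]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# ROC staircase over all score thresholds, from (0,0) to (1,1).
roc_points <- function(scores, labels) {
  y <- as_label_factor(labels)
  o <- order(scores, decreasing = TRUE)
  pos <- y[o] == POSITIVE
  tpr <- cumsum(pos) / sum(pos)
  fpr <- cumsum(!pos) / sum(!pos)
  keep <- c(diff(scores[o]) != 0, TRUE)  # collapse tied scores to one point
  data.frame(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]))
}

#' Classification report: confusion matrix, AUC, kappa, F1
#'
#' Thresholds the positive-class score (predicted obstructive when
#' `score > threshold`), then reports the confusion matrix, sensitivity and
#' specificity for the obstructive class, Cohen's kappa
#' `(p_o - p_e) / (1 - p_e)` with chance agreement from the marginal
#' products, F1 `2TP / (2TP + FP + FN)`, the Mann-Whitney AUC, and the ROC
#' staircase. Degenerate marginals (`p_e = 1`) yield kappa 0 with
#' `kappa_degenerate = TRUE`.
#'
#' @param scores per-sample positive-class scores.
#' @param labels true class labels.
#' @param threshold decision threshold on the score (default 0.5).
#' @return an object of class `eval_report` (a list of the above fields).
#' @export
compute_report <- function(scores, labels, threshold = 0.5) {
  y <- as_label_factor(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  pred <- scores > threshold
  truth <- y == POSITIVE
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  n <- length(y)
  p_o <- (tp + tn) / n
  p_e <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  degen <- abs(1 - p_e) < .Machine$double.eps^0.5
  kappa <- if (degen) 0 else (p_o - p_e) / (1 - p_e)
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  structure(list(
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
    auc = compute_auc(scores, y),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    kappa = kappa, kappa_degenerate = degen, f1 = f1,
    threshold = threshold, n = n,
    roc = roc_points(scores, y)), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report (positive class: obstructive)\n")
  cat(sprintf("  n=%d  TP=%d FP=%d TN=%d FN=%d (threshold %.2f)\n", x$n,
              x$confusion["TP"], x$confusion["FP"], x$confusion["TN"],
              x$confusion["FN"], x$threshold))
  cat(sprintf("  AUC %.3f | sens %.3f | spec %.3f | kappa %.3f | F1 %.3f\n",
              x$auc, x$sensitivity, x$specificity, x$kappa, x$f1))
  invisible(x)
}

# samples x features numeric matrix for the modelling back-ends
feature_frame <- function(x, features) {
  stopifnot(inherits(x, "expr_matrix"))
  miss <- setdiff(features, gene_ids(x))
  if (length(miss)) stop("feature absent from matrix: ", miss[1])
  t(x$values[features, , drop = FALSE])
}

fit_head <- function(algorithm, X, y, par, seed, num_trees) {
  switch(algorithm,
    glm_elastic_net = {
      # fit along a decreasing lambda path including the candidate, then
      # extract at the candidate value: glmnet's recommended usage
      lam <- sort(unique(c(par$lambda, seq(1, 0, length.out = 21))),
                  decreasing = TRUE)
      if (ncol(X) == 1) X <- cbind(X, .zero = 0)  # glmnet needs >= 2 columns
      # suppress glmnet's small-class-size advisory, unavoidable at n ~ 35
      suppressWarnings(
        glmnet::glmnet(X, y, family = "binomial", alpha = par$alpha,
                       lambda = lam, standardize = FALSE))
    },
    random_forest = ranger::ranger(
      x = X, y = y, mtry = min(par$mtry, ncol(X)), num.trees = num_trees,
      probability = TRUE, num.threads = 1, seed = seed),
    svm_linear = {
      withr::local_seed(seed)
      kernlab::ksvm(X, y, type = "C-svc", kernel = kernlab::vanilladot(),
                    C = par$C, scaled = FALSE, prob.model = FALSE)
    })
}

score_head <- function(algorithm, fit, X, par) {
  switch(algorithm,
    glm_elastic_net = {
      if (ncol(X) == 1) X <- cbind(X, .zero = 0)
      as.numeric(stats::plogis(
        glmnet::predict.glmnet(fit, X, s = par$lambda, exact = FALSE)))
    },
    random_forest = as.numeric(
      stats::predict(fit, X, num.threads = 1)$predictions[, POSITIVE]),
    svm_linear = {
      # with levels (non_obstructive, obstructive) kernlab's decision value
      # is positive on the obstructive side
      d <- as.numeric(kernlab::predict(fit, X, type = "decision"))
      stats::plogis(d)
    })
}

expand_candidates <- function(algorithm, grid) {
  if (length(grid) == 0 || any(lengths(grid) == 0)) stop("empty hyperparameter grid")
  switch(algorithm,
    glm_elastic_net = expand.grid(alpha = grid$alpha, lambda = grid$lambda,
                                  KEEP.OUT.ATTRS = FALSE),
    random_forest = data.frame(mtry = grid$mtry),
    svm_linear = data.frame(C = grid$C))
}

# Tie order: stronger regularization first (larger lambda, then larger
# alpha; smaller mtry; smaller C), so which.max resolves AUC ties that way.
candidate_order <- function(algorithm, cand) {
  switch(algorithm,
    glm_elastic_net = order(-cand$lambda, -cand$alpha),
    random_forest = order(cand$mtry),
    svm_linear = order(cand$C))
}

#' Train one classifier head with cross-validated hyperparameter choice
#'
#' Runs stratified k-fold cross-validation over the hyperparameter grid,
#' scores every candidate by mean held-out AUC, picks the best (ties broken
#' toward stronger regularization), then refits that candidate on the full
#' training slice. All randomness (fold assignment, forest bootstraps)
#' derives from `seed`.
#'
#' @param x an [expr_matrix()] (standardized) holding the training samples.
#' @param labels training class labels.
#' @param features gene ids to use as predictors (non-empty).
#' @param algorithm one of `"glm_elastic_net"`, `"random_forest"`,
#'   `"svm_linear"`.
#' @param grid hyperparameter grid (default [default_grid()] for the
#'   algorithm).
#' @param folds number of CV folds (default 7).
#' @param seed integer seed.
#' @param num_trees forest size for the random-forest head.
#' @return an object of class `trained_model`: algorithm, selected
#'   hyperparameters, features, the fitted back-end object, per-candidate
#'   mean CV AUC (`cv_results`), and resubstitution AUC after refit.
#' @export
train_model <- function(x, labels, features,
                        algorithm = c("glm_elastic_net", "random_forest",
                                      "svm_linear"),
                        grid = NULL, folds = 7, seed = 1,
                        num_trees = 200) {
  algorithm <- match.arg(algorithm)
  if (length(features) == 0) stop("feature list must be non-empty")
  y <- as_label_factor(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  X <- feature_frame(x, features)
  if (is.null(grid)) grid <- default_grid(algorithm)
  cand <- expand_candidates(algorithm, grid)
  cand <- cand[candidate_order(algorithm, cand), , drop = FALSE]
  fold <- stratified_folds(y, folds, seed)
  withr::local_seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, folds * nrow(cand) + 1)
  auc_fold <- matrix(NA_real_, nrow(cand), folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (algorithm == "glm_elastic_net") {
      # one lambda-path fit per alpha serves every lambda candidate
      Xtr <- X[tr, , drop = FALSE]; Xte <- X[!tr, , drop = FALSE]
      if (ncol(Xtr) == 1) { Xtr <- cbind(Xtr, .zero = 0); Xte <- cbind(Xte, .zero = 0) }
      lam <- sort(unique(grid$lambda), decreasing = TRUE)
      for (a in unique(cand$alpha)) {
        fit <- suppressWarnings(
          glmnet::glmnet(Xtr, y[tr], family = "binomial", alpha = a,
                         lambda = lam, standardize = FALSE))
        pr <- glmnet::predict.glmnet(fit, Xte, s = lam, exact = FALSE)
        auc_l <- apply(pr, 2, compute_auc, labels = y[!tr])
        rows <- which(cand$alpha == a)
        auc_fold[rows, f] <- auc_l[match(cand$lambda[rows], lam)]
      }
    } else {
      for (ci in seq_len(nrow(cand))) {
        par <- as.list(cand[ci, , drop = FALSE])
        fit <- fit_head(algorithm, X[tr, , drop = FALSE], y[tr], par,
                        seed = sub_seeds[(f - 1) * nrow(cand) + ci], num_trees)
        sc <- score_head(algorithm, fit, X[!tr, , drop = FALSE], par)
        auc_fold[ci, f] <- compute_auc(sc, y[!tr])
      }
    }
  }
  mean_auc <- rowMeans(auc_fold)
  best <- which.max(mean_auc)
  par <- as.list(cand[best, , drop = FALSE])
  final <- fit_head(algorithm, X, y, par, seed = sub_seeds[length(sub_seeds)],
                    num_trees)
  cv <- cbind(cand, mean_cv_auc = mean_auc)
  model <- structure(list(algorithm = algorithm, hyperparameters = par,
                          features = features, fit = final,
                          cv_results = cv, folds = folds, seed = seed,
                          num_trees = num_trees), class = "trained_model")
  model$auc_resub <- compute_auc(predict_scores(model, x), y)
  model$auc_cv <- mean_auc[best]
  model
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("trained_model: %s on %d feature(s) [%s]\n", x$algorithm,
              length(x$features), paste(x$features, collapse = ", ")))
  cat("  hyperparameters:",
      paste(names(x$hyperparameters), signif(unlist(x$hyperparameters), 4),
            sep = "=", collapse = ", "), "\n")
  cat(sprintf("  CV AUC %.3f | resubstitution AUC %.3f\n", x$auc_cv, x$auc_resub))
  invisible(x)
}

#' Positive-class scores of a trained model on new samples
#'
#' Elastic net: logistic-transformed linear predictor; random forest:
#' positive-class vote fraction; linear SVM: logistic transform of the
#' decision value (a monotone map to \[0, 1\]; AUC is unaffected, and the
#' 0.5 threshold corresponds to the SVM decision boundary).
#'
#' @param model a [train_model()] result.
#' @param x an [expr_matrix()] standardized with the training scaler.
#' @return named numeric vector of scores in \[0, 1\], one per sample.
#' @export
predict_scores <- function(model, x) {
  stopifnot(inherits(model, "trained_model"))
  X <- feature_frame(x, model$features)
  stats::setNames(score_head(model$algorithm, model$fit, X,
                             model$hyperparameters), rownames(X))
}
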