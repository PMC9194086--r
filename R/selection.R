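#' Configuration of the iterated stability-voting feature selection
#'
#' Defaults encode the study protocol: 20 iterations; in each, an
#' elastic-net GLM with 7-fold CV keeps the top 100 genes by coefficient
#' importance, a random forest with 7-fold CV keeps the top 50, and a second
#' random forest keeps the top 5; genes kept strictly more than 10 times
#' across iterations are the final features.
#'
#' @param n_iterations number of selection iterations (default 20).
#' @param top_glm,top_rf_first,top_rf_final sizes of the selection ladder
#'   (defaults 100, 50, 5).
#' @param vote_threshold strict lower bound on vote counts for a gene to be
#'   final (default 10, i.e. at least 11 of 20).
#' @param cv_folds CV folds inside each ranking step (default 7).
#' @param base_seed iteration i runs under seed `base_seed + i`.
#' @param resample how the training samples are perturbed between
#'   iterations: `"bootstrap"` (default) redraws them with replacement
#'   within each class, so votes measure stability of a gene's importance
#'   under cohort perturbation; `"none"` reuses the identical samples and
#'   only CV-fold assignment and forest randomness vary.
#' @param glm_grid,rf_grid hyperparameter grids (defaults [default_grid()]).
#' @param num_trees forest size for the random-forest rankings.
#' @return an object of class `selection_config`.
#' @export
selection_config <- function(n_iterations = 20, top_glm = 100,
                             top_rf_first = 50, top_rf_final = 5,
                             vote_threshold = 10, cv_folds = 7,
                             base_seed = 0,
                             resample = c("bootstrap", "none"),
                             glm_grid = default_grid("glm_elastic_net"),
                             rf_grid = default_grid("random_forest"),
                             num_trees = 200) {
  cfg <- list(n_iterations = n_iterations, top_glm = top_glm,
              top_rf_first = top_rf_first, top_rf_final = top_rf_final,
              vote_threshold = vote_threshold, cv_folds = cv_folds,
              base_seed = as.integer(base_seed),
              resample = match.arg(resample), glm_grid = glm_grid,
              rf_grid = rf_grid, num_trees = num_trees)
  if (!(cfg$top_rf_final <= cfg$top_rf_first && cfg$top_rf_first <= cfg$top_glm))
    stop("ladder sizes must satisfy top_rf_final <= top_rf_first <= top_glm")
  if (cfg$vote_threshold >= cfg$n_iterations)
    stop("vote_threshold must be smaller than n_iterations")
  if (cfg$cv_folds < 2) stop("cv_folds must be >= 2")
  structure(cfg, class = "selection_config")
}

# |point-biserial correlation| of each gene with the class, used as the
# deterministic tie-break behind the elastic-net coefficient ranking.
point_biserial <- function(values, y01) {
  v <- values - rowMeans(values)
  s <- sqrt(rowSums(v^2))
  yc <- y01 - mean(y01)
  r <- as.numeric(v %*% yc) / (s * sqrt(sum(yc^2)))
  r[!is.finite(r)] <- 0
  abs(r)
}

#' Rank genes by elastic-net coefficient importance
#'
#' Selects (alpha, lambda) over the grid by mean stratified k-fold CV AUC,
#' refits at the selected pair on the full slice, and orders all genes by
#' decreasing absolute coefficient. Zero-coefficient genes (and exact ties)
#' are ordered by decreasing absolute point-biserial correlation with the
#' class, then by gene id — the ranking is fully deterministic given `seed`.
#'
#' @param x an [expr_matrix()] (standardized training slice).
#' @param labels training class labels.
#' @param grid elastic-net grid (`alpha`, `lambda`).
#' @param folds CV folds.
#' @param seed integer seed (governs fold assignment).
#' @return character vector: all genes in decreasing importance order.
#' @export
glm_rank <- function(x, labels, grid = default_grid("glm_elastic_net"),
                     folds = 7, seed = 1) {
  stopifnot(inherits(x, "expr_matrix"))
  y <- as_label_factor(labels)
  X <- t(x$values)
  if (all(apply(X, 2, stats::sd) == 0)) stop("all genes are constant")
  if (length(grid$alpha) == 0 || length(grid$lambda) == 0)
    stop("empty hyperparameter grid")
  lam <- sort(unique(grid$lambda), decreasing = TRUE)
  fold <- stratified_folds(y, folds, seed)
  auc <- array(0, c(length(grid$alpha), length(lam)))
  for (f in seq_len(folds)) {
    tr <- fold != f
    for (ai in seq_along(grid$alpha)) {
      fit <- suppressWarnings(
        glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "binomial",
                       alpha = grid$alpha[ai], lambda = lam,
                       standardize = FALSE))
      pr <- glmnet::predict.glmnet(fit, X[!tr, , drop = FALSE], s = lam,
                                   exact = FALSE)
      auc[ai, ] <- auc[ai, ] +
        apply(pr, 2, compute_auc, labels = y[!tr]) / folds
    }
  }
  # ties toward stronger regularization: scan lambdas large-to-small,
  # alphas large-to-small
  best <- c(NA, NA); best_auc <- -Inf
  for (li in seq_along(lam)) for (ai in rev(seq_along(grid$alpha))) {
    if (auc[ai, li] > best_auc + 1e-12) { best <- c(ai, li); best_auc <- auc[ai, li] }
  }
  fit <- suppressWarnings(
    glmnet::glmnet(X, y, family = "binomial", alpha = grid$alpha[best[1]],
                   lambda = lam, standardize = FALSE))
  co <- abs(as.numeric(stats::coef(fit, s = lam[best[2]]))[-1])
  pb <- point_biserial(x$values, as.numeric(y == POSITIVE))
  gene_ids(x)[order(-co, -pb, gene_ids(x))]
}

#' Rank candidate genes by random-forest impurity importance
#'
#' Selects `mtry` over the grid by mean stratified k-fold CV AUC of
#' probability forests, refits on the full slice, and orders the candidates
#' by decreasing Gini impurity-decrease importance (ties by gene id).
#' Deterministic given `seed`.
#'
#' @param x an [expr_matrix()] (standardized training slice).
#' @param labels training class labels.
#' @param candidates gene ids to rank (subset of the matrix genes).
#' @param grid forest grid (`mtry`).
#' @param folds CV folds.
#' @param seed integer seed (fold assignment and forest bootstraps).
#' @param num_trees forest size.
#' @return character vector: `candidates` in decreasing importance order.
#' @export
rf_rank <- function(x, labels, candidates = gene_ids(x),
                    grid = default_grid("random_forest"), folds = 7,
                    seed = 1, num_trees = 200) {
  stopifnot(inherits(x, "expr_matrix"))
  miss <- setdiff(candidates, gene_ids(x))
  if (length(miss)) stop("candidate gene absent from matrix: ", miss[1])
  if (length(grid$mtry) == 0) stop("empty hyperparameter grid")
  y <- as_label_factor(labels)
  X <- t(x$values[candidates, , drop = FALSE])
  mtry <- sort(unique(pmin(grid$mtry, ncol(X))))
  fold <- stratified_folds(y, folds, seed)
  withr::local_seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, folds * length(mtry) + 1)
  auc <- numeric(length(mtry))
  for (f in seq_len(folds)) {
    tr <- fold != f
    for (mi in seq_along(mtry)) {
      fit <- ranger::ranger(x = X[tr, , drop = FALSE], y = y[tr],
                            mtry = mtry[mi], num.trees = num_trees,
                            probability = TRUE, num.threads = 1,
                            seed = sub_seeds[(f - 1) * length(mtry) + mi])
      sc <- stats::predict(fit, X[!tr, , drop = FALSE],
                           num.threads = 1)$predictions[, POSITIVE]
      auc[mi] <- auc[mi] + compute_auc(sc, y[!tr]) / folds
    }
  }
  best <- mtry[which.max(auc)]  # ties: smaller mtry (list is ascending)
  fit <- ranger::ranger(x = X, y = y, mtry = best, num.trees = num_trees,
                        probability = TRUE, importance = "impurity",
                        num.threads = 1, seed = sub_seeds[length(sub_seeds)])
  imp <- fit$variable.importance[candidates]
  candidates[order(-imp, candidates)]
}

#' Iterated GLM -> RF -> RF stability-voting feature selection
#'
#' Runs `n_iterations` selection ladders. Iteration i (seeded
#' `base_seed + i`) ranks all genes with [glm_rank()] and keeps the top
#' `top_glm`, re-ranks the survivors with [rf_rank()] keeping `top_rf_first`,
#' then ranks once more with [rf_rank()] keeping `top_rf_final`. Votes count
#' how many iterations retained each gene; genes with strictly more than
#' `vote_threshold` votes are the final features. By default each iteration
#' runs on a stratified bootstrap of the training samples, so votes measure
#' how stably a gene's importance survives cohort perturbation; with
#' `resample = "none"` only CV-fold assignment and forest randomness vary,
#' and vote counts degenerate toward 0 or `n_iterations`.
#'
#' @param x an [expr_matrix()] (standardized training slice).
#' @param labels training class labels.
#' @param config a [selection_config()].
#' @return an object of class `feature_votes`: `votes` (named count per
#'   gene), `iterations` (list of per-iteration top-`top_rf_final` lists),
#'   `final_features` (ordered by votes, then gene id) and the `config`.
#' @export
run_selection <- function(x, labels, config = selection_config()) {
  stopifnot(inherits(x, "expr_matrix"), inherits(config, "selection_config"))
  y <- as_label_factor(labels)
  if (config$cv_folds > min(table(y)))
    stop("cv_folds exceeds the smallest class size")
  n_genes <- nrow(x$values)
  if (n_genes < config$top_glm)
    warning("fewer genes (", n_genes, ") than top_glm (", config$top_glm,
            "); ladder truncates")
  iterations <- vector("list", config$n_iterations)
  for (i in seq_len(config$n_iterations)) {
    it_seed <- config$base_seed + i
    withr::local_seed(it_seed)
    seeds <- sample.int(.Machine$integer.max, 3)
    if (config$resample == "bootstrap") {
      idx <- unlist(lapply(levels(y), function(cl) {
        j <- which(y == cl); sample(j, length(j), replace = TRUE)
      }))
      x_it <- expr_matrix_resample(x, idx)
      y_it <- y[idx]
    } else {
      x_it <- x; y_it <- y
    }
    g1 <- utils::head(glm_rank(x_it, y_it, grid = config$glm_grid,
                               folds = config$cv_folds, seed = seeds[1]),
                      config$top_glm)
    g2 <- utils::head(rf_rank(x_it, y_it, candidates = g1,
                              grid = config$rf_grid,
                              folds = config$cv_folds, seed = seeds[2],
                              num_trees = config$num_trees),
                      config$top_rf_first)
    g3 <- utils::head(rf_rank(x_it, y_it, candidates = g2,
                              grid = config$rf_grid,
                              folds = config$cv_folds, seed = seeds[3],
                              num_trees = config$num_trees),
                      config$top_rf_final)
    iterations[[i]] <- g3
  }
  votes <- stats::setNames(integer(n_genes), gene_ids(x))
  tal <- table(unlist(iterations))
  votes[names(tal)] <- as.integer(tal)
  final <- names(votes)[votes > config$vote_threshold]
  final <- final[order(-votes[final], final)]
  structure(list(votes = votes, iterations = iterations,
                 final_features = final, config = config),
            class = "feature_votes")
}

#' @export
print.feature_votes <- function(x, ...) {
  cat(sprintf("feature_votes: %d iterations, %d gene(s) above %d votes\n",
              x$config$n_iterations, length(x$final_features),
              x$config$vote_threshold))
  if (length(x$final_features))
    print(x$votes[x$final_features])
  invisible(x)
}

#' Write a vote table to TSV
#'
#' Columns `gene_id`, `votes`, `selected` (0/1).
#'
#' @param votes a [run_selection()] result.
#' @param path output path.
#' @export
write_votes <- function(votes, path) {
  stopifnot(inherits(votes, "feature_votes"))
  df <- data.frame(gene_id = names(votes$votes), votes = unname(votes$votes),
                   selected = as.integer(names(votes$votes) %in%
                                           votes$final_features))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
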