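test_that("default grids match the protocol ranges", {
  g <- default_grid("glm_elastic_net")
  expect_length(g$alpha, 14)
  expect_equal(range(g$alpha), c(0, 0.8))
  expect_true(all(g$lambda >= 0 & g$lambda <= 1))
  expect_identical(default_grid("random_forest")$mtry, 1:4)
  C <- default_grid("svm_linear")$C
  expect_length(C, 11)
  expect_equal(range(C), c(1e-4, 1))
})

test_that("auc matches exhaustive pair counting", {
  lab <- c("obstructive", "non_obstructive", "obstructive", "non_obstructive")
  expect_equal(compute_auc(c(0.9, 0.8, 0.3, 0.2), lab), 0.75)  # 3 of 4 pairs
  expect_equal(compute_auc(c(1, 0, 1, 0), lab), 1)
  expect_equal(compute_auc(rep(0.4, 4), lab), 0.5)
  expect_error(compute_auc(1:3, rep("obstructive", 3)), "both classes")
  withr::with_seed(41, {
    for (i in 1:50) {
      n <- sample(4:12, 1)
      lab <- sample(c("obstructive", "non_obstructive"), n, replace = TRUE)
      if (length(unique(lab)) < 2) next
      sc <- round(runif(n), 1)  # coarse scores force ties
      expect_equal(compute_auc(sc, lab), auc_pairs(sc, lab), tolerance = 1e-12)
    }
  })
})

test_that("auc is complementary under score negation and monotone-invariant", {
  withr::with_seed(42, {
    lab <- sample(c("obstructive", "non_obstructive"), 20, replace = TRUE)
    sc <- rnorm(20)  # tie-free a.s.
    expect_equal(compute_auc(sc, lab) + compute_auc(-sc, lab), 1)
    expect_equal(compute_auc(sc, lab), compute_auc(plogis(3 * sc + 2), lab))
    expect_equal(compute_auc(sc, lab), compute_auc(rank(sc), lab))
  })
})

test_that("auc agrees with pROC on random score sets", {
  skip_if_not_installed("pROC")
  withr::with_seed(43, {
    for (i in 1:20) {
      lab <- sample(c("obstructive", "non_obstructive"), 30, replace = TRUE)
      if (length(unique(lab)) < 2) next
      sc <- round(rnorm(30), 1)
      ref <- as.numeric(pROC::auc(pROC::roc(
        response = factor(lab, c("non_obstructive", "obstructive")),
        predictor = sc, quiet = TRUE, direction = "<")))
      expect_equal(compute_auc(sc, lab), ref, tolerance = 1e-12)
    }
  })
})

test_that("report metrics match the closed-form definitions", {
  lab13 <- rep(c("obstructive", "non_obstructive"), c(7, 6))
  r <- compute_report(c(rep(0.9, 7), rep(0.1, 6)), lab13)
  expect_equal(unname(r$confusion), c(7, 0, 6, 0))
  expect_equal(r$sensitivity, 1)
  expect_equal(r$f1, 1)
  expect_equal(r$kappa, 1)

  lab20 <- rep(c("obstructive", "non_obstructive"), each = 10)
  r2 <- compute_report(c(rep(c(0.9, 0.1), 5), rep(c(0.9, 0.1), 5)), lab20)
  expect_equal(unname(r2$confusion), c(5, 5, 5, 5))
  expect_equal(r2$kappa, 0)

  # TP=6 FN=1 TN=5 FP=1: p_o = 11/13, p_e = (7*7 + 6*6)/169
  lab <- rep(c("obstructive", "non_obstructive"), c(7, 6))
  sc <- c(rep(0.8, 6), 0.2, 0.7, rep(0.3, 5))
  r3 <- compute_report(sc, lab)
  expect_equal(unname(r3$confusion), c(6, 1, 5, 1))
  expect_equal(r3$kappa, (11 / 13 - 85 / 169) / (1 - 85 / 169))
  expect_equal(r3$f1, 12 / 14)
  expect_equal(r3$sensitivity, 6 / 7)
})

test_that("report agrees with independent confusion enumeration on random sets", {
  withr::with_seed(44, {
    for (i in 1:200) {
      n <- sample(6:20, 1)
      lab <- sample(c("obstructive", "non_obstructive"), n, replace = TRUE)
      if (length(unique(lab)) < 2) next
      sc <- runif(n)
      r <- compute_report(sc, lab)
      tp <- sum(sc > 0.5 & lab == "obstructive")
      fp <- sum(sc > 0.5 & lab == "non_obstructive")
      fn <- sum(sc <= 0.5 & lab == "obstructive")
      tn <- sum(sc <= 0.5 & lab == "non_obstructive")
      expect_identical(unname(r$confusion), c(tp, fp, tn, fn))
      expect_equal(r$n, tp + fp + tn + fn)
      po <- (tp + tn) / n
      pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
      expect_equal(r$kappa, (po - pe) / (1 - pe))
      # ROC staircase: monotone from (0,0) to (1,1)
      expect_equal(r$roc$fpr[1], 0); expect_equal(r$roc$tpr[1], 0)
      expect_equal(r$roc$fpr[nrow(r$roc)], 1)
      expect_equal(r$roc$tpr[nrow(r$roc)], 1)
      expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))
    }
  })
})

test_that("degenerate marginals give kappa 0 with a flag", {
  lab <- rep(c("obstructive", "non_obstructive"), c(3, 3))
  r <- compute_report(rep(0.9, 6), lab)   # everything predicted positive
  expect_false(r$kappa_degenerate)        # marginals not fully degenerate
  r2 <- compute_report(c(0.9, 0.9, 0.9, 0.1, 0.1, 0.1),
                       c("obstructive", "obstructive", "obstructive",
                         "non_obstructive", "non_obstructive", "non_obstructive"))
  expect_equal(r2$kappa, 1)
})

make_sep_matrix <- function(n_pos = 8, n_neg = 8, seed = 1) {
  withr::with_seed(seed, {
    v <- rbind(sep = c(rnorm(n_pos, 3), rnorm(n_neg, -3)),
               noise1 = rnorm(n_pos + n_neg),
               noise2 = rnorm(n_pos + n_neg))
    colnames(v) <- sprintf("s%02d", seq_len(n_pos + n_neg))
    list(x = expr_matrix(v, rep("mRNA", 3), "standardized"),
         labels = rep(c("obstructive", "non_obstructive"), c(n_pos, n_neg)))
  })
}

test_that("every head separates a perfectly separable problem", {
  d <- make_sep_matrix()
  for (alg in c("glm_elastic_net", "random_forest", "svm_linear")) {
    m <- train_model(d$x, d$labels, c("sep", "noise1"), algorithm = alg,
                     folds = 4, seed = 2)
    expect_true(all(unlist(m$hyperparameters) %in%
                      unlist(default_grid(alg))))
    expect_equal(compute_auc(predict_scores(m, d$x), d$labels), 1)
  }
  expect_error(train_model(d$x, d$labels, character(0)), "non-empty")
  expect_error(train_model(d$x, d$labels, "ghost"), "absent")
  expect_error(train_model(d$x, rep("obstructive", 16), "sep"), "both classes")
})

test_that("single-feature heads train and score", {
  d <- make_sep_matrix()
  for (alg in c("glm_elastic_net", "random_forest", "svm_linear")) {
    m <- train_model(d$x, d$labels, "sep", algorithm = alg, folds = 4, seed = 3)
    sc <- predict_scores(m, d$x)
    expect_true(all(sc >= 0 & sc <= 1))
    expect_equal(compute_auc(sc, d$labels), 1)
  }
})

test_that("scores are finite, in [0,1], and invariant to sample order", {
  d <- make_sep_matrix(seed = 5)
  m <- train_model(d$x, d$labels, c("sep", "noise1", "noise2"),
                   algorithm = "random_forest", folds = 4, seed = 4)
  sc <- predict_scores(m, d$x)
  perm <- withr::with_seed(1, sample(sample_ids(d$x)))
  sc2 <- predict_scores(m, subset_matrix(d$x, samples = perm))
  expect_equal(sc2, sc[perm])
  expect_true(all(is.finite(sc)))
})

test_that("training is deterministic given the seed", {
  d <- make_sep_matrix(seed = 6)
  for (alg in c("glm_elastic_net", "random_forest", "svm_linear")) {
    m1 <- train_model(d$x, d$labels, c("sep", "noise1"), algorithm = alg,
                      folds = 4, seed = 11)
    m2 <- train_model(d$x, d$labels, c("sep", "noise1"), algorithm = alg,
                      folds = 4, seed = 11)
    expect_identical(m1$hyperparameters, m2$hyperparameters)
    expect_equal(predict_scores(m1, d$x), predict_scores(m2, d$x))
  }
})

test_that("a null elastic net scores everyone at chance", {
  # balanced classes + pure noise + maximal penalty: zero coefficients and
  # zero intercept, so every score is exactly 0.5
  withr::with_seed(7, {
    v <- matrix(rnorm(40), 2, 20,
                dimnames = list(c("g1", "g2"), sprintf("s%02d", 1:20)))
  })
  x <- expr_matrix(v, rep("mRNA", 2), "standardized")
  lab <- rep(c("obstructive", "non_obstructive"), 10)
  m <- train_model(x, lab, c("g1", "g2"), algorithm = "glm_elastic_net",
                   grid = list(alpha = 1, lambda = 1), folds = 4, seed = 1)
  expect_equal(unname(predict_scores(m, x)), rep(0.5, 20))
})
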