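# standardized matrix with one strong discriminative gene among noise
sep_cohort <- function(n_noise, seed, n_pos = 15, n_neg = 15, delta = 3) {
  withr::with_seed(seed, {
    p <- n_noise + 1
    v <- matrix(rnorm(p * (n_pos + n_neg)), p,
                dimnames = list(sprintf("g%03d", seq_len(p)),
                                sprintf("s%03d", seq_len(n_pos + n_neg))))
    v[1, seq_len(n_pos)] <- v[1, seq_len(n_pos)] + delta
    v <- t(scale(t(v)))
    list(x = expr_matrix(v, rep("mRNA", p), "standardized"),
         labels = rep(c("obstructive", "non_obstructive"), c(n_pos, n_neg)))
  })
}

test_that("glm ranking puts a perfectly separating gene first", {
  top1 <- 0
  for (s in 1:20) {
    d <- sep_cohort(n_noise = 99, seed = s)
    top1 <- top1 + (glm_rank(d$x, d$labels, folds = 5, seed = s)[1] == "g001")
  }
  expect_gte(top1, 19)
})

test_that("duplicated informative genes tie deterministically by gene id", {
  d <- sep_cohort(n_noise = 30, seed = 2)
  v <- rbind(d$x$values, g999 = d$x$values["g001", ])  # exact duplicate column
  x <- expr_matrix(v, rep("mRNA", nrow(v)), "standardized")
  r <- glm_rank(x, d$labels, folds = 5, seed = 2)
  # both copies carry identical information: they occupy the top ranks and
  # the |correlation| tie resolves by ascending gene id
  expect_setequal(r[1:2], c("g001", "g999"))
  expect_identical(which(r == "g001") < which(r == "g999"), TRUE)
})

test_that("degenerate inputs error cleanly", {
  v <- matrix(1, 3, 10, dimnames = list(paste0("g", 1:3), paste0("s", 1:10)))
  x <- expr_matrix(v, rep("mRNA", 3), "standardized")
  lab <- rep(c("obstructive", "non_obstructive"), 5)
  expect_error(glm_rank(x, lab, folds = 2, seed = 1), "constant")
  expect_error(glm_rank(sep_cohort(5, 1)$x, sep_cohort(5, 1)$labels,
                        grid = list(alpha = numeric(0), lambda = 0.1),
                        folds = 2, seed = 1), "empty")
  d <- sep_cohort(5, 1)
  expect_error(rf_rank(d$x, d$labels, candidates = "ghost", seed = 1), "ghost")
  # a fold without both classes is impossible by construction: folds are
  # stratified, and over-large k errors up front
  expect_error(rf_rank(d$x, d$labels, folds = 20, seed = 1), "class size")
})

test_that("rf ranking is deterministic and handles a single candidate", {
  d <- sep_cohort(n_noise = 20, seed = 3)
  r1 <- rf_rank(d$x, d$labels, folds = 5, seed = 7)
  r2 <- rf_rank(d$x, d$labels, folds = 5, seed = 7)
  expect_identical(r1, r2)
  expect_identical(rf_rank(d$x, d$labels, candidates = "g005",
                           folds = 5, seed = 1), "g005")
})

test_that("rf ranking detects an interacting pair beyond marginal effects", {
  ok <- 0; n_seeds <- 25
  for (s in 1:n_seeds) {
    withr::with_seed(s, {
      v <- matrix(rnorm(10 * 100), 10, 100,
                  dimnames = list(sprintf("g%02d", 1:10),
                                  sprintf("s%03d", 1:100)))
      lab <- ifelse(xor(v[1, ] > 0, v[2, ] > 0),
                    "obstructive", "non_obstructive")
    })
    if (min(table(lab)) < 7) next
    x <- expr_matrix(v, rep("mRNA", 10), "standardized")
    r <- rf_rank(x, lab, seed = s)
    ok <- ok + all(match(c("g01", "g02"), r) <= 5)
  }
  expect_gte(ok / n_seeds, 0.8)
})

small_config <- function(...) {
  selection_config(top_glm = 30, top_rf_first = 15, top_rf_final = 5,
                   cv_folds = 4, ...)
}

test_that("a single-iteration run returns exactly its top-final list", {
  d <- sep_cohort(n_noise = 59, seed = 4)
  v <- run_selection(d$x, d$labels,
                     small_config(n_iterations = 1, vote_threshold = 0,
                                  base_seed = 3, resample = "none"))
  expect_identical(length(v$iterations), 1L)
  expect_setequal(v$final_features, v$iterations[[1]])
  expect_identical(unname(v$votes[v$iterations[[1]]]), rep(1L, 5))
})

test_that("votes conserve the audit trail and respect the ladder bounds", {
  d <- sep_cohort(n_noise = 59, seed = 5)
  v <- run_selection(d$x, d$labels,
                     small_config(n_iterations = 3, vote_threshold = 1,
                                  base_seed = 9))
  expect_true(all(lengths(v$iterations) <= 5))
  expect_true(all(v$votes <= 3))
  tal <- table(unlist(v$iterations))
  for (g in names(tal))
    expect_identical(v$votes[[g]], as.integer(tal[[g]]))
  expect_true(all(v$final_features %in% unlist(v$iterations)))
  expect_identical(sum(v$votes), sum(lengths(v$iterations)))
})

test_that("selection is deterministic and threshold-monotone", {
  d <- sep_cohort(n_noise = 39, seed = 6)
  v1 <- run_selection(d$x, d$labels,
                      small_config(n_iterations = 2, vote_threshold = 0,
                                   base_seed = 21))
  v2 <- run_selection(d$x, d$labels,
                      small_config(n_iterations = 2, vote_threshold = 0,
                                   base_seed = 21))
  expect_identical(v1$votes, v2$votes)
  expect_identical(v1$iterations, v2$iterations)
  v3 <- run_selection(d$x, d$labels,
                      small_config(n_iterations = 2, vote_threshold = 1,
                                   base_seed = 21))
  expect_identical(v3$votes, v1$votes)  # threshold does not touch votes
  expect_true(all(v3$final_features %in% v1$final_features))
})

test_that("the ladder truncates with a warning when genes run short", {
  d <- sep_cohort(n_noise = 10, seed = 7)
  expect_warning(
    v <- run_selection(d$x, d$labels,
                       selection_config(n_iterations = 1, vote_threshold = 0,
                                        top_glm = 100, top_rf_first = 50,
                                        top_rf_final = 5, cv_folds = 4,
                                        base_seed = 1)),
    "truncates")
  expect_lte(length(v$iterations[[1]]), 5)
})

test_that("the strongly planted gene survives the whole ladder", {
  d <- sep_cohort(n_noise = 59, seed = 8)
  v <- run_selection(d$x, d$labels,
                     small_config(n_iterations = 3, vote_threshold = 2,
                                  base_seed = 2))
  expect_true("g001" %in% v$final_features)
})

test_that("vote tables serialize with selection flags", {
  d <- sep_cohort(n_noise = 29, seed = 9)
  v <- run_selection(d$x, d$labels,
                     small_config(n_iterations = 1, vote_threshold = 0,
                                  base_seed = 1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_votes(v, f)
  tab <- read.delim(f)
  expect_identical(nrow(tab), 30L)
  expect_setequal(tab$gene_id[tab$selected == 1], v$final_features)
})
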