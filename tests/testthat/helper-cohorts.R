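# Shared fixture builders. Everything is generated in code at test time.

# small hand-built raw expression matrix
toy_matrix <- function(values = matrix(c(0, 3, 1023,
                                         1, 7, 511), nrow = 3,
                                       dimnames = list(c("g1", "g2", "g3"),
                                                       c("s1", "s2"))),
                       biotype = c("mRNA", "lncRNA", "mRNA")) {
  expr_matrix(values, biotype, "raw")
}

# metadata table matching the study composition: 26 obstructive samples of
# which n_ident imaging-identifiable, 22 non-obstructive
study_metadata <- function(n_ident = 7, seed = 42) {
  withr::with_seed(seed, {
    data.frame(
      sample_id = sprintf("S%03d", 1:48),
      group = rep(c("obstructive", "non_obstructive"), c(26, 22)),
      age_days = c(rlnorm(26, log(7.5), 1.3), rlnorm(22, log(120), 2.2)),
      weight_kg = c(rlnorm(26, log(3.15), 0.12), rlnorm(22, log(5.25), 0.77)),
      imaging_identifiable = c(rep(c(TRUE, FALSE), c(n_ident, 26 - n_ident)),
                               rep(FALSE, 22)),
      stringsAsFactors = FALSE)
  })
}

# standardized training slice + labels from a simulated cohort
training_slice <- function(cohort) {
  sp <- split_cohort(cohort$metadata)
  tr <- sp$sample_id[sp$set == "train"]
  xl <- log_transform(cohort$matrix)
  xs <- apply_scaler(xl, fit_scaler(xl, tr))
  list(x = subset_matrix(xs, samples = tr),
       labels = stats::setNames(cohort$metadata$group,
                                cohort$metadata$sample_id)[tr],
       train_ids = tr,
       valid_ids = sp$sample_id[sp$set == "validation"],
       x_all = xs)
}

# literal step-down Holm oracle: for each hypothesis, the smallest nominal
# alpha at which the sequential procedure rejects it
holm_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  alphas <- sort(unique(c(pmin(1, (m - seq_len(m) + 1) * p[o]), 1)))
  adj <- rep(NA_real_, m)
  for (a in alphas) {
    rejected <- logical(m)
    for (step in seq_len(m)) {            # literal sequential walk
      i <- o[step]
      # relative tolerance so a candidate alpha equal to (m-step+1)*p
      # counts as a rejection despite floating-point division
      if ((m - step + 1) * p[i] <= a * (1 + 1e-12)) rejected[i] <- TRUE
      else break
    }
    adj[is.na(adj) & rejected] <- a
  }
  adj[is.na(adj)] <- 1
  adj
}

# exhaustive pair-counting AUC oracle
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == "obstructive"]
  neg <- scores[labels != "obstructive"]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}
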