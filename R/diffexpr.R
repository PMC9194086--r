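#' Holm step-down multiple-testing adjustment
#'
#' Step-down familywise-error control: with raw p-values sorted ascending,
#' the i-th adjusted value is `min(1, max_{j<=i} (m-j+1) p_(j))`, mapped
#' back to input order. Always at least the raw p and never above the
#' Bonferroni adjustment.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order as `p`.
#' @export
holm_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- cummax(pmin(1, (m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Fits, for every gene at once, the per-gene linear model
#   log2 expression ~ intercept + group + standardized log(age + 1)
# by one QR decomposition of the shared design matrix. Returns the group
# coefficient (log2FC, obstructive minus non-obstructive) and its two-sided
# Wald p per gene. A constant age covariate is dropped with a warning.
fit_gene_models <- function(values, group, age_days) {
  y <- t(values)                        # samples x genes
  g01 <- as.numeric(group == "obstructive")
  if (length(unique(group)) < 2) stop("both groups must be present")
  if (min(table(group)) < 2) stop("need at least 2 samples per group")
  la <- log(age_days + 1)
  if (stats::sd(la) == 0) {
    warning("age covariate is constant; dropped from the per-gene model")
    X <- cbind(intercept = 1, group = g01)
  } else {
    X <- cbind(intercept = 1, group = g01,
               z_log_age = (la - mean(la)) / stats::sd(la))
  }
  df <- nrow(X) - ncol(X)
  if (df <= 0) stop("zero residual degrees of freedom")
  qrX <- qr(X)
  coefs <- qr.coef(qrX, y)              # p x genes
  res <- qr.resid(qrX, y)
  sigma2 <- colSums(res^2) / df
  xtx_inv_22 <- chol2inv(qr.R(qrX))[2, 2]
  se <- sqrt(sigma2 * xtx_inv_22)
  tstat <- coefs[2, ] / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se == 0] <- 1                       # exactly-fit genes carry no evidence
  list(log2fc = coefs[2, ], p_raw = pmin(1, pmax(p, .Machine$double.xmin)),
       df = df)
}

#' Covariate-adjusted test for one gene
#'
#' Per-gene Gaussian linear model of log2 expression on group with a
#' standardized `log(age + 1)` covariate, absorbing the strong age-class
#' confounding of the cohort. The group coefficient is the adjusted log2
#' fold change (obstructive minus non-obstructive); its two-sided Wald p is
#' returned unadjusted.
#'
#' @param values numeric vector of per-sample log2 expression.
#' @param group character/factor of `obstructive` / `non_obstructive`.
#' @param age_days per-sample age covariate.
#' @return list with `log2fc` and `p_raw`.
#' @export
test_gene <- function(values, group, age_days) {
  fit <- fit_gene_models(matrix(values, nrow = 1,
                                dimnames = list("g", names(values))),
                         group, age_days)
  list(log2fc = unname(fit$log2fc), p_raw = unname(fit$p_raw))
}

#' Call differentially expressed genes
#'
#' Applies the study's decision rule to every gene: a gene is `up` when its
#' age-adjusted log2 fold change is `>= fc_threshold` and Holm-adjusted p
#' `< alpha`, `down` when the fold change is `<= -fc_threshold` with the
#' same significance, otherwise `ns`.
#'
#' @param x an [expr_matrix()] in `log` state.
#' @param metadata sample metadata covering exactly the matrix samples.
#' @param fc_threshold absolute log2 fold-change threshold (default 1).
#' @param alpha familywise significance level on Holm-adjusted p (default 0.05).
#' @return data.frame with columns `gene_id`, `biotype`, `log2fc`, `p_raw`,
#'   `p_holm`, `status`; a `summary` attribute tabulates up/down calls per
#'   biotype.
#' @export
call_degs <- function(x, metadata, fc_threshold = 1, alpha = 0.05) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$transform != "log")
    stop("call_degs expects a log-transformed matrix, got '", x$transform, "'")
  md <- validate_metadata(metadata)
  if (!setequal(md$sample_id, sample_ids(x)))
    stop("metadata samples do not match matrix samples")
  md <- md[match(sample_ids(x), md$sample_id), ]
  fit <- fit_gene_models(x$values, md$group, md$age_days)
  p_holm <- holm_adjust(fit$p_raw)
  status <- rep("ns", length(fit$log2fc))
  status[fit$log2fc >= fc_threshold & p_holm < alpha] <- "up"
  status[fit$log2fc <= -fc_threshold & p_holm < alpha] <- "down"
  out <- data.frame(gene_id = gene_ids(x), biotype = unname(x$biotype),
                    log2fc = unname(fit$log2fc), p_raw = unname(fit$p_raw),
                    p_holm = p_holm, status = status,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "summary") <- table(biotype = out$biotype,
                                status = factor(out$status,
                                                c("up", "down", "ns")))
  out
}
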