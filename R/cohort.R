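#' Imaging- and age-driven train/validation split
#'
#' Reproduces the cohort-splitting rule of the target study: obstructive
#' patients whose obstruction is NOT identifiable by preoperative imaging
#' (echocardiography / CTA) form the obstructive training set and the
#' identifiable ones the validation set; non-obstructive patients are ranked
#' by surgical age and the oldest go to training, the youngest
#' `n_non_validation` to validation. Age ties are broken by ascending
#' sample id so the split is fully deterministic.
#'
#' @param metadata sample metadata (see [read_metadata()] for columns).
#' @param n_non_validation number of non-obstructive samples assigned to
#'   the validation set (default 6).
#' @return a data.frame with columns `sample_id` and `set`
#'   (`"train"` / `"validation"`), one row per sample in `metadata` order.
#' @export
split_cohort <- function(metadata, n_non_validation = 6) {
  md <- validate_metadata(metadata)
  n_non <- sum(md$group == "non_obstructive")
  if (length(n_non_validation) != 1 || n_non_validation < 0 ||
      n_non_validation > n_non || n_non_validation != round(n_non_validation))
    stop("n_non_validation must be a count between 0 and the number of non-obstructive samples (", n_non, ")")
  set <- stats::setNames(rep("train", nrow(md)), md$sample_id)
  set[md$group == "obstructive" & md$imaging_identifiable] <- "validation"
  non <- md[md$group == "non_obstructive", ]
  ord <- non$sample_id[order(-non$age_days, non$sample_id)]
  if (n_non_validation > 0)
    set[utils::tail(ord, n_non_validation)] <- "validation"
  data.frame(sample_id = md$sample_id, set = unname(set[md$sample_id]),
             stringsAsFactors = FALSE)
}

#' Two-sample Wilcoxon (Mann-Whitney) rank-sum test
#'
#' Normal approximation with tie correction and continuity correction, the
#' form used for the clinical group comparisons at these sample sizes.
#' When every pooled value is identical the test statistic is degenerate
#' and `p = 1` is returned.
#'
#' @param x,y numeric vectors (non-empty).
#' @return list with `statistic` (the Mann-Whitney U of `x` vs `y`) and
#'   `p_value` (two-sided).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1)
    return(list(statistic = length(x) * length(y) / 2, p_value = 1))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = min(1, wt$p.value))
}

#' Pearson chi-square and Fisher exact tests for contingency tables
#'
#' `pearson_chi2_2x2` is the uncorrected (no Yates continuity) Pearson
#' chi-square; `fisher_exact_2x2` the two-sided exact test summing
#' hypergeometric probabilities no larger than the observed table's. Both
#' accept general r x c tables; the names record the dominant 2 x 2 use.
#'
#' @param table matrix of non-negative counts with positive margins.
#' @return `pearson_chi2_2x2`: list with `statistic`, `df`, `p_value`;
#'   `fisher_exact_2x2`: list with `p_value`.
#' @export
pearson_chi2_2x2 <- function(table) {
  tab <- check_table(table)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' @rdname pearson_chi2_2x2
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- check_table(table)
  list(p_value = stats::fisher.test(tab)$p.value)
}

check_table <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("test undefined: table has a zero margin")
  tab
}

#' Clinical characteristics table with per-variable group comparisons
#'
#' Builds a Table-1-style report contrasting obstructive and non-obstructive
#' samples. Continuous variables are summarized as median (Q1, Q3) per group
#' with a Wilcoxon rank-sum p; categorical variables as n (%) per group with
#' Pearson chi-square when all expected cells are at least 5 and Fisher's
#' exact test otherwise. A categorical variable with a single observed level
#' is reported descriptively with the test skipped (`note` column).
#'
#' @param metadata sample metadata.
#' @param continuous,categorical character vectors of column names.
#' @return a data.frame with one row per variable (one per level for
#'   multi-level categoricals): summaries per group, `test` used, `p_value`,
#'   and `note`.
#' @export
cohort_table <- function(metadata,
                         continuous = c("age_days", "weight_kg"),
                         categorical = "imaging_identifiable") {
  md <- validate_metadata(metadata)
  miss <- setdiff(c(continuous, categorical), names(md))
  if (length(miss)) stop("unknown variable: ", miss[1])
  is_o <- md$group == "obstructive"
  rows <- list()
  fmt_cont <- function(v) sprintf("%.2f (%.2f, %.2f)",
                                  stats::median(v),
                                  stats::quantile(v, 0.25),
                                  stats::quantile(v, 0.75))
  for (v in continuous) {
    xo <- md[[v]][is_o]; xn <- md[[v]][!is_o]
    w <- wilcoxon_rank_sum(xo, xn)
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, level = NA_character_,
      obstructive = fmt_cont(xo), non_obstructive = fmt_cont(xn),
      test = "wilcoxon", p_value = w$p_value, note = NA_character_,
      stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    f <- if (is.logical(md[[v]])) factor(md[[v]], c(FALSE, TRUE))
         else as.factor(md[[v]])
    tab <- table(f, factor(md$group, c("obstructive", "non_obstructive")))
    pct <- sweep(tab, 2, colSums(tab), "/") * 100
    if (nlevels(droplevels(f)) < 2) {
      test <- "none"; p <- NA_real_
      note <- "single observed level; test skipped"
    } else {
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        test <- "fisher"; p <- fisher_exact_2x2(tab)$p_value
      } else {
        test <- "pearson_chi2"; p <- pearson_chi2_2x2(tab)$p_value
      }
      note <- NA_character_
    }
    lev <- levels(f)
    show <- if (length(lev) == 2 && all(lev %in% c("FALSE", "TRUE")))
      "TRUE" else lev  # boolean flags: report the TRUE row only
    for (l in show) {
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = l,
        obstructive = sprintf("%d (%.1f)", tab[l, 1], pct[l, 1]),
        non_obstructive = sprintf("%d (%.1f)", tab[l, 2], pct[l, 2]),
        test = test, p_value = p, note = note, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
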