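#' Configuration for the synthetic TAPVC cohort generator
#'
#' Defaults emulate the study cohort this package targets: 26 preoperative
#' obstructive and 22 non-obstructive patients, roughly 10^4 transcripts,
#' surgical age strongly confounded with class (log-normal per class with
#' medians near 7.5 vs 120 days), and 7 of 26 obstructive samples
#' identifiable by preoperative imaging. Planted marker genes receive an
#' additive shift of `planted_log2fc` on the log2 negative-binomial mean in
#' the obstructive class only: down-regulated markers are labeled mRNA and
#' up-regulated ones lncRNA, mirroring the biotypes of the cohort's two
#' reference markers.
#'
#' @param n_obstructive,n_non_obstructive per-class sample counts.
#' @param n_genes number of transcripts to simulate.
#' @param n_planted_up,n_planted_down numbers of planted up-/down-regulated
#'   marker genes (obstructive relative to non-obstructive).
#' @param planted_log2fc absolute planted effect, log2 units.
#' @param nb_dispersion negative-binomial size parameter (> 0); smaller
#'   means more overdispersion.
#' @param baseline_log_mean_range range (log2 units) of per-gene baseline
#'   mean expression, drawn uniformly.
#' @param age_params per-class `meanlog`/`sdlog` of log-normal surgical age
#'   in days.
#' @param weight_params per-class `meanlog`/`sdlog` of log-normal surgical
#'   weight in kg.
#' @param frac_identifiable_obstructive fraction of obstructive samples
#'   flagged imaging-identifiable (rounded to a count).
#' @param lnc_fraction fraction of non-planted genes labeled lncRNA.
#' @param size_factor_sd standard deviation of per-sample log-normal library
#'   size factors; 0 (default) disables library-size variation.
#' @param seed integer seed; identical configs give bit-identical cohorts.
#'
#' @return an object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_obstructive = 26,
                         n_non_obstructive = 22,
                         n_genes = 10000,
                         n_planted_up = 1,
                         n_planted_down = 1,
                         planted_log2fc = 3,
                         nb_dispersion = 10,
                         baseline_log_mean_range = c(3, 8),
                         age_params = list(
                           obstructive = c(meanlog = log(7.5), sdlog = 1.3),
                           non_obstructive = c(meanlog = log(120), sdlog = 2.2)),
                         weight_params = list(
                           obstructive = c(meanlog = log(3.15), sdlog = 0.12),
                           non_obstructive = c(meanlog = log(5.25), sdlog = 0.77)),
                         frac_identifiable_obstructive = 7 / 26,
                         lnc_fraction = 0.3,
                         size_factor_sd = 0,
                         seed = 1L) {
  cfg <- list(n_obstructive = n_obstructive,
              n_non_obstructive = n_non_obstructive,
              n_genes = n_genes, n_planted_up = n_planted_up,
              n_planted_down = n_planted_down, planted_log2fc = planted_log2fc,
              nb_dispersion = nb_dispersion,
              baseline_log_mean_range = baseline_log_mean_range,
              age_params = age_params, weight_params = weight_params,
              frac_identifiable_obstructive = frac_identifiable_obstructive,
              lnc_fraction = lnc_fraction, size_factor_sd = size_factor_sd,
              seed = as.integer(seed))
  for (f in c("n_obstructive", "n_non_obstructive", "n_genes",
              "n_planted_up", "n_planted_down")) {
    v <- cfg[[f]]
    if (length(v) != 1 || !is.finite(v) || v < 0 || v != round(v))
      stop("invalid config field '", f, "': must be a non-negative count")
  }
  if (cfg$n_planted_up + cfg$n_planted_down > cfg$n_genes)
    stop("invalid config field 'n_planted_up': planted genes exceed n_genes")
  if (cfg$nb_dispersion <= 0)
    stop("invalid config field 'nb_dispersion': must be > 0")
  if (cfg$frac_identifiable_obstructive < 0 || cfg$frac_identifiable_obstructive > 1)
    stop("invalid config field 'frac_identifiable_obstructive': must be in [0,1]")
  if (cfg$lnc_fraction < 0 || cfg$lnc_fraction > 1)
    stop("invalid config field 'lnc_fraction': must be in [0,1]")
  if (length(cfg$baseline_log_mean_range) != 2 ||
      diff(cfg$baseline_log_mean_range) < 0)
    stop("invalid config field 'baseline_log_mean_range': must be an increasing pair")
  if (cfg$size_factor_sd < 0)
    stop("invalid config field 'size_factor_sd': must be >= 0")
  structure(cfg, class = "synth_config")
}

#' Simulate a synthetic two-class leukocyte transcript cohort
#'
#' Draws raw counts per gene and sample from a negative binomial whose log2
#' mean is a uniform per-gene baseline, plus the signed planted effect for
#' marker genes in obstructive samples, plus an optional per-sample library
#' size factor. Surgical age and weight are log-normal per class, and
#' exactly `round(frac_identifiable_obstructive * n_obstructive)` obstructive
#' samples carry the imaging-identifiable flag.
#'
#' @param config a [synth_config()].
#' @return an object of class `synth_cohort`: list with `matrix` (a raw
#'   [expr_matrix()]), `metadata` (sample table) and `truth` (data.frame of
#'   planted gene ids with signed true log2 effects).
#' @export
simulate_cohort <- function(config = synth_config()) {
  if (!inherits(config, "synth_config"))
    config <- do.call(synth_config, config)
  withr::local_seed(config$seed)
  n_o <- config$n_obstructive; n_n <- config$n_non_obstructive
  n <- n_o + n_n; g <- config$n_genes
  gene_id <- sprintf("G%06d", seq_len(g))
  sample_id <- sprintf("S%03d", seq_len(n))
  group <- rep(c("obstructive", "non_obstructive"), c(n_o, n_n))

  n_dn <- config$n_planted_down; n_up <- config$n_planted_up
  planted <- if (n_dn + n_up > 0) sample.int(g, n_dn + n_up) else integer(0)
  idx_dn <- planted[seq_len(n_dn)]
  idx_up <- planted[n_dn + seq_len(n_up)]
  effect <- numeric(g)
  effect[idx_dn] <- -config$planted_log2fc
  effect[idx_up] <- config$planted_log2fc

  biotype <- ifelse(stats::runif(g) < config$lnc_fraction, "lncRNA", "mRNA")
  biotype[idx_dn] <- "mRNA"    # down marker emulates an mRNA
  biotype[idx_up] <- "lncRNA"  # up marker emulates a lncRNA

  base <- stats::runif(g, config$baseline_log_mean_range[1],
                       config$baseline_log_mean_range[2])
  log2mu <- matrix(base, g, n) +
    outer(effect, as.numeric(group == "obstructive"))
  if (config$size_factor_sd > 0) {
    sf <- stats::rlnorm(n, 0, config$size_factor_sd)
    log2mu <- sweep(log2mu, 2, log2(sf), "+")
  }
  counts <- matrix(stats::rnbinom(g * n, mu = 2^log2mu,
                                  size = config$nb_dispersion), g, n)
  dimnames(counts) <- list(gene_id, sample_id)

  age <- numeric(n); wt <- numeric(n)
  for (cl in c("obstructive", "non_obstructive")) {
    i <- group == cl
    ap <- config$age_params[[cl]]; wp <- config$weight_params[[cl]]
    age[i] <- stats::rlnorm(sum(i), ap[["meanlog"]], ap[["sdlog"]])
    wt[i] <- stats::rlnorm(sum(i), wp[["meanlog"]], wp[["sdlog"]])
  }
  n_ident <- round(config$frac_identifiable_obstructive * n_o)
  ident <- rep(FALSE, n)
  ident[sample(which(group == "obstructive"), n_ident)] <- TRUE

  metadata <- data.frame(sample_id = sample_id, group = group,
                         age_days = age, weight_kg = wt,
                         imaging_identifiable = ident,
                         stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = gene_id[planted],
                      log2fc = effect[planted],
                      biotype = biotype[planted],
                      stringsAsFactors = FALSE)
  structure(list(matrix = expr_matrix(counts, biotype, "raw"),
                 metadata = validate_metadata(metadata),
                 truth = truth, config = config),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("synth_cohort: %d obstructive + %d non-obstructive samples, %d genes, %d planted\n",
              sum(x$metadata$group == "obstructive"),
              sum(x$metadata$group == "non_obstructive"),
              nrow(x$matrix$values), nrow(x$truth)))
  invisible(x)
}

#' Recovery of planted marker genes by a feature-selection run
#'
#' @param selected character vector of selected gene ids.
#' @param truth the `truth` data.frame of a [simulate_cohort()] result (or a
#'   character vector of planted ids).
#' @return a list with per-gene hit flags (`hits`), `n_selected`,
#'   `n_truth`, and `recall` (defined as 1 when both sets are empty).
#' @export
truth_recovery_report <- function(selected, truth) {
  ids <- if (is.data.frame(truth)) truth$gene_id else as.character(truth)
  hits <- stats::setNames(ids %in% selected, ids)
  recall <- if (length(ids) == 0) {
    if (length(selected) == 0) 1 else NA_real_
  } else mean(hits)
  list(hits = hits, n_selected = length(selected), n_truth = length(ids),
       recall = recall)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `matrix.tsv` (expression TSV), `metadata.csv` and `truth.tsv`
#' under `dir`.
#'
#' @param cohort a `synth_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expr_matrix(cohort$matrix, file.path(dir, "matrix.tsv"))
  write_metadata(cohort$metadata, file.path(dir, "metadata.csv"))
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
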