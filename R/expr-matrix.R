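#' Expression matrix container
#'
#' A light container for a gene-by-sample transcript abundance matrix with
#' per-gene biotype labels (`mRNA` / `lncRNA`) and an explicit transform
#' state, so that downstream stages can refuse input on the wrong scale.
#'
#' @param values numeric matrix, genes in rows, samples in columns; both
#'   dimensions must carry unique names. Raw matrices must be non-negative.
#' @param biotype character vector of per-gene labels, `"mRNA"` or
#'   `"lncRNA"`, recycled names optional (matched to `rownames(values)`).
#' @param transform one of `"raw"`, `"log"`, `"standardized"`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `biotype` (named by gene) and `transform`.
#' @export
expr_matrix <- function(values, biotype, transform = c("raw", "log", "standardized")) {
  transform <- match.arg(transform)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene id: ", rownames(values)[duplicated(rownames(values))][1])
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id: ", colnames(values)[duplicated(colnames(values))][1])
  if (any(!is.finite(values)))
    stop("`values` must be finite")
  if (transform == "raw" && any(values < 0))
    stop("raw expression values must be non-negative")
  if (length(biotype) != nrow(values))
    stop("`biotype` must have one entry per gene")
  if (!all(biotype %in% c("mRNA", "lncRNA")))
    stop("biotype labels must be 'mRNA' or 'lncRNA'")
  biotype <- stats::setNames(as.character(biotype), rownames(values))
  structure(list(values = values, biotype = biotype, transform = transform),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$transform))
  cat(sprintf("  biotypes: %d mRNA, %d lncRNA\n",
              sum(x$biotype == "mRNA"), sum(x$biotype == "lncRNA")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param x an `expr_matrix`.
#' @return character vector of ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an expression matrix by sample and/or gene ids
#'
#' @param x an `expr_matrix`.
#' @param samples,genes character vectors of ids to keep (default: all).
#' @return an `expr_matrix` restricted to the requested ids, in the
#'   requested order.
#' @export
subset_matrix <- function(x, samples = NULL, genes = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  g <- if (is.null(genes)) gene_ids(x) else genes
  s <- if (is.null(samples)) sample_ids(x) else samples
  miss <- setdiff(g, gene_ids(x))
  if (length(miss)) stop("unknown gene id: ", miss[1])
  miss <- setdiff(s, sample_ids(x))
  if (length(miss)) stop("unknown sample id: ", miss[1])
  expr_matrix(x$values[g, s, drop = FALSE], x$biotype[g], x$transform)
}

# internal: column-resampled copy (bootstrap replicates get suffixed ids)
expr_matrix_resample <- function(x, idx) {
  v <- x$values[, idx, drop = FALSE]
  colnames(v) <- sprintf("%s.%d", colnames(v), seq_along(idx))
  expr_matrix(v, x$biotype, x$transform)
}

# ---- file formats ---------------------------------------------------------

#' Read / write the expression-matrix TSV format
#'
#' The on-disk format is a tab-separated table whose first column is
#' `gene_id`, second `biotype`, and remaining columns one per sample.
#' `read_expr_matrix` validates structure eagerly: ragged rows are reported
#' with their line number, duplicate ids by name, and negative values (for
#' `transform = "raw"`) rejected.
#'
#' @param path file path.
#' @param transform transform state to stamp on the matrix read
#'   (the format itself is state-agnostic); default `"raw"`.
#' @return `read_expr_matrix`: an [expr_matrix()].
#' @export
read_expr_matrix <- function(path, transform = "raw") {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nf) == 0) stop("parse error: empty file: ", path)
  bad <- which(nf != nf[1])
  if (length(bad))
    stop(sprintf("parse error: ragged row at line %d of %s", bad[1], path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3 || names(df)[1] != "gene_id" || names(df)[2] != "biotype")
    stop("format error: expected columns gene_id, biotype, <samples...>")
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(vals)) stop("format error: non-numeric expression values")
  rownames(vals) <- df$gene_id
  expr_matrix(vals, df$biotype, transform)
}

#' @rdname read_expr_matrix
#' @param x an `expr_matrix` to write.
#' @param digits significant digits used when serializing values.
#' @return `write_expr_matrix`: `path`, invisibly.
#' @export
write_expr_matrix <- function(x, path, digits = 10) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = gene_ids(x), biotype = unname(x$biotype),
                   signif(x$values, digits), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the sample-metadata CSV
#'
#' Columns: `sample_id`, `group` (`obstructive` / `non_obstructive`),
#' `age_days`, `weight_kg`, `imaging_identifiable` (logical). The
#' imaging-identifiable flag may be set only for obstructive samples.
#'
#' @param path file path.
#' @return `read_metadata`: a validated `data.frame`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_metadata(md)
}

#' @rdname read_metadata
#' @param md metadata `data.frame` to write.
#' @export
write_metadata <- function(md, path) {
  utils::write.csv(validate_metadata(md), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_metadata <- function(md) {
  need <- c("sample_id", "group", "age_days", "imaging_identifiable")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing column: ", miss[1])
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample id: ", md$sample_id[duplicated(md$sample_id)][1])
  if (!all(md$group %in% c("obstructive", "non_obstructive")))
    stop("group must be 'obstructive' or 'non_obstructive'")
  md$imaging_identifiable <- as.logical(md$imaging_identifiable)
  if (any(md$imaging_identifiable & md$group != "obstructive"))
    stop("imaging_identifiable may be TRUE only for obstructive samples")
  if (any(!is.finite(md$age_days)) || any(md$age_days < 0))
    stop("age_days must be finite and non-negative")
  md
}

# ---- transforms -----------------------------------------------------------

#' Log-transform raw expression values
#'
#' Applies `log2(x + 1)` entry-wise, the usual variance-stabilizing first
#' step before standardization, keeping fold changes on the log2 scale used
#' by the differential-expression rule.
#'
#' @param x an `expr_matrix` in `raw` state.
#' @return an `expr_matrix` in `log` state, same shape.
#' @export
log_transform <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$transform != "raw")
    stop("log_transform expects a raw matrix, got state '", x$transform, "'")
  expr_matrix(log2(x$values + 1), x$biotype, "log")
}

#' Per-gene standardization fitted on a sample subset
#'
#' `fit_scaler` computes per-gene center (mean) and scale (sample standard
#' deviation, n-1 denominator) over the given samples — typically the
#' training set, so validation samples are standardized with training
#' parameters and no information leaks across the split. Genes with zero
#' variance on the fitting subset are flagged degenerate and map to zero.
#'
#' @param x an `expr_matrix` in `log` state.
#' @param samples sample ids to fit on (default: all).
#' @return `fit_scaler`: an `expr_scaler` data.frame with columns
#'   `gene_id`, `center`, `scale`, `degenerate`.
#' @export
fit_scaler <- function(x, samples = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$transform != "log")
    stop("fit_scaler expects a log-transformed matrix, got '", x$transform, "'")
  if (is.null(samples)) samples <- sample_ids(x)
  if (length(samples) < 2) stop("need at least 2 samples to fit a scaler")
  v <- subset_matrix(x, samples = samples)$values
  ctr <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  degen <- sdv == 0
  out <- data.frame(gene_id = gene_ids(x), center = ctr,
                    scale = ifelse(degen, 1, sdv), degenerate = degen,
                    row.names = NULL)
  class(out) <- c("expr_scaler", "data.frame")
  out
}

#' @rdname fit_scaler
#' @param scaler an `expr_scaler` (fit on the training samples).
#' @return `apply_scaler`: an `expr_matrix` in `standardized` state.
#' @export
apply_scaler <- function(x, scaler) {
  stopifnot(inherits(x, "expr_matrix"), inherits(scaler, "expr_scaler"))
  if (x$transform != "log")
    stop("apply_scaler expects a log-transformed matrix, got '", x$transform, "'")
  if (!identical(scaler$gene_id, gene_ids(x)))
    stop("scaler genes do not match matrix genes")
  z <- (x$values - scaler$center) / scaler$scale
  z[scaler$degenerate, ] <- 0
  expr_matrix(z, x$biotype, "standardized")
}

#' @rdname fit_scaler
#' @param path file path for the serialized scaler (TSV).
#' @export
write_scaler <- function(scaler, path) {
  utils::write.table(as.data.frame(scaler), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname fit_scaler
#' @export
read_scaler <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  out$degenerate <- as.logical(out$degenerate)
  class(out) <- c("expr_scaler", "data.frame")
  out
}
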