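# Expression-level comparisons and coefficient-of-variation statistics.

#' Expression matrix with sample metadata
#'
#' Wraps a genes x samples matrix of fpkm values together with per-sample
#' metadata (`sample`, `tissue`, `condition` in normal/tumor, `patient`).
#' Paired samples share a `patient` key across conditions.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids), values >= 0.
#' @param meta Data frame with columns `sample`, `tissue`, `condition`,
#'   `patient`; one row per column of `values`.
#' @return Object of class `expr_matrix`: list with `values` and `meta`.
#' @export
expression_matrix <- function(values, meta) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (any(values < 0, na.rm = TRUE)) stop("fpkm values must be >= 0")
  need <- c("sample", "tissue", "condition", "patient")
  if (!all(need %in% names(meta))) {
    stop("meta needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(meta) != ncol(values)) {
    stop("meta must have one row per sample column")
  }
  if (!all(meta$sample == colnames(values))) {
    meta <- meta[match(colnames(values), meta$sample), , drop = FALSE]
    if (anyNA(meta$sample)) stop("meta samples do not match matrix columns")
  }
  if (!all(meta$condition %in% c("normal", "tumor"))) {
    stop("condition must be 'normal' or 'tumor'")
  }
  structure(list(values = values, meta = meta), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples (%d normal, %d tumor)\n",
              nrow(x$values), ncol(x$values),
              sum(x$meta$condition == "normal"),
              sum(x$meta$condition == "tumor")))
  invisible(x)
}

condition_samples <- function(m, condition) {
  if (is.null(condition)) return(m$meta$sample)
  m$meta$sample[m$meta$condition == condition]
}

#' Per-gene mean of log2(fpkm + 1)
#'
#' Expression levels are converted to log2(fpkm + 1) and averaged across
#' the selected samples, the standard transform for level comparisons.
#'
#' @param m [expression_matrix()].
#' @param samples Sample ids to average over (default: all).
#' @param condition Optionally restrict to one condition instead.
#' @return Named numeric vector of per-gene means.
#' @export
log_mean_expression <- function(m, samples = NULL, condition = NULL) {
  if (is.null(samples)) samples <- condition_samples(m, condition)
  if (!length(samples)) stop("empty sample selection")
  rowMeans(log2(m$values[, samples, drop = FALSE] + 1))
}

#' Compare expression between gene groups (Wilcoxon rank-sum)
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test; exact for small groups
#' without ties, tie-corrected normal approximation otherwise (the
#' behaviour of [stats::wilcox.test()]).
#'
#' @param values_with,values_without Numeric vectors (each length >= 2),
#'   e.g. per-gene mean expression for the pG4 and non-pG4 sets.
#' @return List `median_with`, `median_without`, `p`.
#' @export
group_compare <- function(values_with, values_without) {
  if (length(values_with) < 2L || length(values_without) < 2L) {
    stop("both groups must have at least 2 values")
  }
  if (length(unique(c(values_with, values_without))) == 1L) {
    warning("all values tied; p set to 1")
    p <- 1
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(values_with, values_without)$p.value)
  }
  list(median_with = stats::median(values_with),
       median_without = stats::median(values_without), p = p)
}

#' Tumor/normal log2 fold change per gene
#'
#' Per gene, `log2((mean tumor fpkm + 1) / (mean normal fpkm + 1))`, with
#' condition means over all samples of each condition. If pG4/non-pG4 gene
#' sets are supplied, the sets are contrasted by Welch's two-sample t test
#' on the per-gene log2 fold changes.
#'
#' @param m [expression_matrix()] containing both conditions.
#' @param genes_with,genes_without Optional character vectors of gene ids.
#' @return List `log2fc` (named per-gene vector) and, when sets are given,
#'   `contrast` with `mean_with`, `mean_without`, `t`, `p`.
#' @export
tumor_normal_log2fc <- function(m, genes_with = NULL, genes_without = NULL) {
  sn <- condition_samples(m, "normal")
  st <- condition_samples(m, "tumor")
  if (!length(sn) || !length(st)) {
    stop("both 'normal' and 'tumor' conditions must be present")
  }
  mt <- rowMeans(m$values[, st, drop = FALSE])
  mn <- rowMeans(m$values[, sn, drop = FALSE])
  lfc <- log2((mt + 1) / (mn + 1))
  out <- list(log2fc = lfc)
  if (!is.null(genes_with) && !is.null(genes_without)) {
    tt <- stats::t.test(lfc[genes_with], lfc[genes_without],
                        var.equal = FALSE)
    out$contrast <- list(mean_with = unname(tt$estimate[1L]),
                         mean_without = unname(tt$estimate[2L]),
                         t = unname(tt$statistic), p = tt$p.value)
  }
  out
}

cv_result <- function(cv, n_excluded, unit) {
  structure(list(cv = cv, n_excluded = n_excluded, unit = unit),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV over %d %ss (median %.1f%%), %d zero-mean %ss excluded\n",
              length(x$cv), x$unit, stats::median(x$cv), x$n_excluded,
              x$unit))
  invisible(x)
}

#' Per-gene coefficient of variation across patients (indiv-CV)
#'
#' For each gene, `100 * SD / mean` of expression across the individual
#' samples of one condition (sample SD, n-1 denominator). Computed on
#' linear fpkm by default — the definition applies to expression itself,
#' with log transforms reserved for plotting — with `log_scale` to switch.
#' Genes with zero mean have an undefined CV and are excluded and counted.
#'
#' @param m [expression_matrix()].
#' @param condition Condition to compute across (`"normal"` or
#'   `"tumor"`); `NULL` uses all samples.
#' @param log_scale If `TRUE`, compute on log2(fpkm + 1) values.
#' @return A `cv_result`: named `cv` vector (percent), `n_excluded`.
#' @export
indiv_cv <- function(m, condition = NULL, log_scale = FALSE) {
  samples <- condition_samples(m, condition)
  if (length(samples) < 2L) {
    stop("need at least 2 samples in the selected condition")
  }
  v <- m$values[, samples, drop = FALSE]
  if (log_scale) v <- log2(v + 1)
  mu <- rowMeans(v)
  sdv <- apply(v, 1L, stats::sd)
  keep <- mu != 0
  cv_result(100 * sdv[keep] / mu[keep], sum(!keep), unit = "gene")
}

#' Per-sample coefficient of variation across a gene set (g-CV)
#'
#' For each sample, `100 * SD / mean` of expression over the genes of
#' `gene_set` — a per-patient measure of how dispersed the transcriptome is
#' within a set (e.g. pG4 versus non-pG4 genes).
#'
#' @param m [expression_matrix()].
#' @param gene_set Non-empty character vector of gene ids.
#' @param condition Optionally restrict to one condition.
#' @param log_scale If `TRUE`, compute on log2(fpkm + 1) values.
#' @return A `cv_result`: named per-sample `cv` vector (percent).
#' @export
g_cv <- function(m, gene_set, condition = NULL, log_scale = FALSE) {
  if (!length(gene_set)) stop("gene_set must be non-empty")
  missing <- setdiff(gene_set, rownames(m$values))
  if (length(missing)) {
    stop("unknown genes in gene_set: ", paste(utils::head(missing, 3L),
                                              collapse = ", "))
  }
  samples <- condition_samples(m, condition)
  v <- m$values[gene_set, samples, drop = FALSE]
  if (log_scale) v <- log2(v + 1)
  mu <- colMeans(v)
  sdv <- apply(v, 2L, stats::sd)
  keep <- mu != 0
  cv_result(100 * sdv[keep] / mu[keep], sum(!keep), unit = "sample")
}

#' Paired tumor/normal test on per-patient statistics
#'
#' Two-sided paired t test on tumor minus normal differences (e.g. of
#' per-patient g-CV values), with the inclusion rule that at least
#' `min_pairs` complete tumor/normal pairs must be available (default 15).
#' Vectors are matched by name when both are named, otherwise by position.
#'
#' @param cv_normal,cv_tumor Numeric vectors of per-patient statistics.
#' @param min_pairs Minimum complete pairs required (default 15).
#' @return List `p`, `mean_diff` (tumor - normal), `direction` (one of
#'   "down", "none", "up"), `n_pairs`. Zero-variance non-zero differences
#'   are degenerate: `p` is NA with a warning.
#' @export
paired_condition_test <- function(cv_normal, cv_tumor, min_pairs = 15L) {
  if (!is.null(names(cv_normal)) && !is.null(names(cv_tumor))) {
    common <- intersect(names(cv_normal), names(cv_tumor))
    cv_normal <- cv_normal[common]; cv_tumor <- cv_tumor[common]
  } else if (length(cv_normal) != length(cv_tumor)) {
    stop("unnamed vectors must have equal length")
  }
  keep <- is.finite(cv_normal) & is.finite(cv_tumor)
  d <- cv_tumor[keep] - cv_normal[keep]
  n <- length(d)
  if (n < min_pairs) {
    stop("paired comparison requires at least ", min_pairs,
         " matched tumor/normal pairs; got ", n)
  }
  if (all(d == 0)) {
    return(list(p = 1, mean_diff = 0, direction = "none", n_pairs = n))
  }
  if (stats::sd(d) == 0) {
    warning("zero-variance non-zero differences; paired t undefined")
    return(list(p = NA_real_, mean_diff = mean(d),
                direction = if (mean(d) < 0) "down" else "up", n_pairs = n))
  }
  tt <- stats::t.test(d)
  list(p = tt$p.value, mean_diff = mean(d),
       direction = if (mean(d) < 0) "down" else if (mean(d) > 0) "up"
                   else "none",
       n_pairs = n)
}
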