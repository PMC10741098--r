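#' Compute raw light/heavy polysome abundance log-ratios
#'
#' Joins a count matrix to a gene table and computes per-gene log2 abundance
#' ratios from pseudocounted counts-per-million: for each library,
#' abundance = (count + pseudocount) / lib_size x 1e6, and each ratio is the
#' log2 quotient of two abundances. Four ratios are reported: the raw
#' wild-type and mutant light/heavy ratios (`raw_wt = log2(WT_L/WT_H)`,
#' `raw_mt = log2(MT_L/MT_H)`) and the cross-line per-fraction ratios
#' (`mt_over_wt_h = log2(MT_H/WT_H)`, `mt_over_wt_l = log2(MT_L/WT_L)`).
#' Genes with a raw count below `min_count` in any library are excluded
#' (expression filter); the exclusion count is logged.
#'
#' @param counts a CountMatrix ([read_counts()] / [simulate_counts()]); its
#'   `lib_size` attribute is used when present, otherwise column sums.
#' @param genes a gene table with `gene_id`, `orf_length`, `site_count`.
#' @param min_count expression filter: minimum raw count required in every
#'   library (default 10).
#' @param pseudocount added to every count before CPM (default 0.5).
#' @param outlier_k optional: when non-`NULL`, genes whose `raw_wt` or
#'   `raw_mt` lies more than `outlier_k` interquartile ranges beyond the
#'   quartiles are excluded (logged). Default `NULL` (no outlier removal).
#' @return A RatioTable: data frame with `gene_id`, `log2_orf`,
#'   `site_count`, `raw_wt`, `raw_mt`, `mt_over_wt_h`, `mt_over_wt_l`;
#'   adjusted columns are added by [adjust_by_orf()] and [double_adjust()].
#' @export
compute_ratios <- function(counts, genes, min_count = 10, pseudocount = 0.5,
                           outlier_k = NULL) {
  labs <- lib_labels()
  if (!is.data.frame(counts) || !all(c("gene_id", labs) %in% names(counts)))
    stop_input("counts must contain gene_id and %s", paste(labs, collapse = ", "))
  if (!is.data.frame(genes) ||
      !all(c("gene_id", "orf_length", "site_count") %in% names(genes)))
    stop_input("genes must contain gene_id, orf_length, site_count")
  if (min_count < 0 || pseudocount < 0)
    stop_config("min_count and pseudocount must be non-negative")

  lib <- attr(counts, "lib_size")
  if (is.null(lib)) lib <- colSums(as.matrix(counts[labs]))
  lib <- lib[labs]
  if (any(!is.finite(lib)) || any(lib <= 0))
    stop_input("library sizes must be positive")

  tab <- merge(genes[c("gene_id", "orf_length", "site_count")],
               counts[c("gene_id", labs)], by = "gene_id")
  if (nrow(tab) == 0L) stop_input("counts and genes share no gene_id")
  n_unjoined <- nrow(counts) - nrow(tab)
  if (n_unjoined > 0L)
    pr_log("compute_ratios: %d count row(s) had no gene attributes and were dropped",
           n_unjoined)

  cm <- as.matrix(tab[labs])
  pass <- rowSums(cm >= min_count) == 4L
  if (!any(pass))
    stop_input("no genes pass the expression filter (min_count = %g)", min_count)
  if (any(!pass))
    pr_log("compute_ratios: excluded %d gene(s) below min_count = %g in at least one library",
           sum(!pass), min_count)
  tab <- tab[pass, , drop = FALSE]
  cm <- cm[pass, , drop = FALSE]

  cpm <- sweep(cm + pseudocount, 2L, lib, "/") * 1e6
  out <- data.frame(
    gene_id = tab$gene_id,
    log2_orf = log2(tab$orf_length),
    site_count = as.integer(tab$site_count),
    raw_wt = log2(cpm[, "WT_L"] / cpm[, "WT_H"]),
    raw_mt = log2(cpm[, "MT_L"] / cpm[, "MT_H"]),
    mt_over_wt_h = log2(cpm[, "MT_H"] / cpm[, "WT_H"]),
    mt_over_wt_l = log2(cpm[, "MT_L"] / cpm[, "WT_L"]),
    stringsAsFactors = FALSE
  )

  if (!is.null(outlier_k)) {
    keep <- !ratio_outlier(out$raw_wt, outlier_k) &
      !ratio_outlier(out$raw_mt, outlier_k)
    if (any(!keep))
      pr_log("compute_ratios: excluded %d outlier gene(s) beyond %g x IQR",
             sum(!keep), outlier_k)
    out <- out[keep, , drop = FALSE]
    if (nrow(out) == 0L) stop_input("all genes removed as outliers")
  }
  rownames(out) <- NULL
  out
}

ratio_outlier <- function(v, k) {
  qs <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
  iqr <- qs[2] - qs[1]
  v < qs[1] - k * iqr | v > qs[2] + k * iqr
}

#' ORF-length adjustment of the light/heavy log-ratios
#'
#' Fits, independently for wild type and mutant, a local regression
#' ([local_fit()]) of the raw light/heavy log-ratio on log2 ORF length and
#' stores the residuals as the adjusted log-ratios (`adj_wt`, `adj_mt`):
#' the part of the ratio not explained by ORF length. The R-squared of each
#' fit (variance explained by ORF length) is logged and attached as
#' attributes `r2_wt` / `r2_mt`.
#'
#' @param table a RatioTable from [compute_ratios()].
#' @param span,degree local regression parameters (defaults 0.75 and 2,
#'   the conventional LOESS defaults).
#' @return the table with `adj_wt` and `adj_mt` columns added.
#' @export
adjust_by_orf <- function(table, span = 0.75, degree = 2) {
  req <- c("log2_orf", "raw_wt", "raw_mt")
  if (!is.data.frame(table) || !all(req %in% names(table)))
    stop_input("table must contain %s", paste(req, collapse = ", "))
  if (nrow(table) < 30L)
    stop_input("need at least 30 genes for a meaningful adjustment, got %d",
               nrow(table))
  fit_wt <- local_fit(table$log2_orf, table$raw_wt, span = span, degree = degree)
  fit_mt <- local_fit(table$log2_orf, table$raw_mt, span = span, degree = degree)
  table$adj_wt <- fit_wt$residuals
  table$adj_mt <- fit_mt$residuals
  attr(table, "r2_wt") <- fit_wt$r.squared
  attr(table, "r2_mt") <- fit_mt$r.squared
  pr_log("adjust_by_orf: LOESS R-squared WT = %.3f, MT = %.3f",
         fit_wt$r.squared, fit_mt$r.squared)
  table
}

#' Double adjustment: subtract the mutant adjusted ratio
#'
#' `double_adj = adj_wt - adj_mt` per gene: the change of the
#' ORF-length-adjusted log-ratio attributable to miRNA activity, cancelling
#' regulation shared by the two isogenic cell lines.
#'
#' @param table a RatioTable with `adj_wt`, `adj_mt` (see [adjust_by_orf()]).
#' @return the table with a `double_adj` column added.
#' @export
double_adjust <- function(table) {
  if (!is.data.frame(table) || !all(c("adj_wt", "adj_mt") %in% names(table)))
    stop_input("table must contain adj_wt and adj_mt; run adjust_by_orf first")
  table$double_adj <- table$adj_wt - table$adj_mt
  table
}

#' Two-predictor local regression of the raw ratio
#'
#' Fits the wild-type raw log-ratio on (log2 ORF length, log2(site count +
#' 1)) jointly — the exploratory surface showing both determinants at once.
#' A zero-spread site-count column is dropped by [local_fit()], so the call
#' degrades to the 1D ORF-length fit on degenerate inputs.
#'
#' @inheritParams adjust_by_orf
#' @param response which raw column to model (default `"raw_wt"`).
#' @return the [local_fit()] object (fitted values, residuals, R-squared).
#' @export
joint_loess_surface <- function(table, span = 0.75, degree = 2,
                                response = "raw_wt") {
  req <- c("log2_orf", "site_count", response)
  if (!is.data.frame(table) || !all(req %in% names(table)))
    stop_input("table must contain %s", paste(req, collapse = ", "))
  if (nrow(table) < 30L)
    stop_input("need at least 30 genes, got %d", nrow(table))
  x <- cbind(log2_orf = table$log2_orf,
             log2_sites = log2(table$site_count + 1))
  local_fit(x, table[[response]], span = span, degree = degree)
}
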