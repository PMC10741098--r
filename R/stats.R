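#' Compare miRNA-targeted vs untargeted genes
#'
#' Splits genes into a targeted group (site count above `high_threshold`,
#' default > 50 distinct miRNA families) and an untargeted group (no site at
#' all) and compares the supplied values — typically raw or adjusted
#' light/heavy log-ratios — with a two-sided two-sample t-test and a
#' two-sided variance-ratio F-test. The t-test is Welch (unequal variances)
#' by default because the two groups routinely show unequal dispersion;
#' `var_equal = TRUE` restores the pooled-variance Student test.
#'
#' @param values numeric vector (one value per gene).
#' @param site_counts integer vector of binding-site counts, same length.
#' @param high_threshold targeted genes have `site_count > high_threshold`.
#' @param var_equal use the pooled-variance Student t-test.
#' @return An object of class `"group_comparison"`: labels, group sizes and
#'   means, `t_stat`/`t_pvalue`, and `f_stat` (variance ratio
#'   targeted/untargeted) with `f_pvalue`.
#' @export
compare_groups <- function(values, site_counts, high_threshold = 50,
                           var_equal = FALSE) {
  if (length(values) != length(site_counts))
    stop_input("values and site_counts differ in length")
  ok <- is.finite(values) & !is.na(site_counts)
  values <- values[ok]; site_counts <- site_counts[ok]
  a <- values[site_counts > high_threshold]
  b <- values[site_counts == 0]
  if (length(a) < 2L || length(b) < 2L)
    stop_input("insufficient data: %d targeted and %d untargeted gene(s); need >= 2 each",
               length(a), length(b))
  tt <- stats::t.test(a, b, var.equal = var_equal)
  ft <- stats::var.test(a, b)
  structure(list(
    group_a_label = sprintf("> %g sites", high_threshold),
    group_b_label = "no site",
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), mean_b = mean(b),
    t_stat = unname(tt$statistic), t_pvalue = tt$p.value,
    f_stat = unname(ft$statistic), f_pvalue = ft$p.value,
    var_equal = var_equal
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Targeted vs untargeted group comparison\n")
  cat(sprintf("  %s: n = %d, mean = %.4f\n", x$group_a_label, x$n_a, x$mean_a))
  cat(sprintf("  %s: n = %d, mean = %.4f\n", x$group_b_label, x$n_b, x$mean_b))
  cat(sprintf("  %s t-test: t = %.3f, p = %.3g\n",
              if (x$var_equal) "Student" else "Welch", x$t_stat, x$t_pvalue))
  cat(sprintf("  F-test (variance ratio %.3f): p = %.3g\n",
              x$f_stat, x$f_pvalue))
  invisible(x)
}

#' Resampling null distribution of a group mean
#'
#' Draws `n_samples` simple random samples (without replacement) from the
#' full value vector, each of the same size as the target group, and
#' records their means. The empirical p-value of the observed target-group
#' mean uses the add-one correction
#' `(1 + #\{sample means >= observed\}) / (n_samples + 1)`. Values are
#' sorted internally before sampling so the result depends only on the
#' multiset of values, the target indices' values, and the seed.
#'
#' @param values numeric vector over the gene universe.
#' @param target_indices indices of the target group within `values`.
#' @param n_samples number of random samples (default 1000).
#' @param seed RNG seed for the draws.
#' @return An object of class `"sampling_null"`: `sample_means`,
#'   `observed_mean`, `max_sample_mean`, `empirical_p`, `sample_size`,
#'   `n_samples`.
#' @export
sampling_null <- function(values, target_indices, n_samples = 1000,
                          seed = 1L) {
  if (length(target_indices) == 0L) stop_input("empty target index set")
  if (any(target_indices < 1L) || any(target_indices > length(values)))
    stop_input("target indices out of range")
  if (anyDuplicated(target_indices)) stop_input("duplicated target indices")
  size <- length(target_indices)
  if (size > length(values)) stop_input("target group larger than universe")
  observed <- mean(values[target_indices])
  pool <- sort(values)  # order invariance
  set.seed(as.integer(seed))
  means <- vapply(seq_len(n_samples),
                  function(i) mean(pool[sample.int(length(pool), size)]),
                  numeric(1))
  structure(list(
    n_samples = as.integer(n_samples), sample_size = size,
    sample_means = means, observed_mean = observed,
    max_sample_mean = max(means),
    empirical_p = (1 + sum(means >= observed)) / (n_samples + 1)
  ), class = "sampling_null")
}

#' @export
print.sampling_null <- function(x, ...) {
  cat("Resampling null of the target-group mean\n")
  cat(sprintf("  %d samples of size %d\n", x$n_samples, x$sample_size))
  cat(sprintf("  observed mean = %.4f, max sample mean = %.4f\n",
              x$observed_mean, x$max_sample_mean))
  cat(sprintf("  empirical p = %.4g\n", x$empirical_p))
  invisible(x)
}

#' Mean ratio per binding-site count
#'
#' Groups genes by exact binding-site count and reports, per count, the
#' number of genes and the mean of the chosen ratio column, together with
#' the plotting abscissa `x = log2(site_count + 1)`. With
#' `normalize_per_kb = TRUE` genes are instead binned into deciles of sites
#' per kilobase of ORF, and `x = log2(mean sites-per-kb + 1)` per bin.
#'
#' @param table a RatioTable (needs `site_count`, the value column and, for
#'   per-kb normalization, `log2_orf`).
#' @param value_column name of the ratio column to average (e.g. `"raw_wt"`,
#'   `"adj_wt"`, `"double_adj"`).
#' @param normalize_per_kb normalize site counts by ORF length in kb and
#'   bin by deciles.
#' @param min_n minimum group size for a row to be kept (default 1 = all).
#' @return A TrendTable: data frame `site_count` (`NA` for per-kb bins),
#'   `x`, `n_genes`, `mean_value`.
#' @export
trend_by_site_count <- function(table, value_column,
                                normalize_per_kb = FALSE, min_n = 1L) {
  if (!is.data.frame(table) || !value_column %in% names(table))
    stop_input("column '%s' not found", value_column)
  v <- table[[value_column]]
  if (!normalize_per_kb) {
    key <- table$site_count
    agg <- aggregate_mean(v, key)
    out <- data.frame(site_count = as.integer(agg$key),
                      x = log2(as.numeric(agg$key) + 1),
                      n_genes = agg$n, mean_value = agg$mean,
                      stringsAsFactors = FALSE)
    out <- out[order(out$site_count), , drop = FALSE]
  } else {
    if (!"log2_orf" %in% names(table))
      stop_input("per-kb normalization needs a log2_orf column")
    per_kb <- table$site_count / (2^table$log2_orf / 1000)
    br <- unique(stats::quantile(per_kb, probs = seq(0, 1, 0.1), names = FALSE))
    bin <- cut(per_kb, breaks = br, include.lowest = TRUE, labels = FALSE)
    agg <- aggregate_mean(v, bin)
    kb_mean <- aggregate_mean(per_kb, bin)$mean
    out <- data.frame(site_count = NA_integer_,
                      x = log2(kb_mean + 1),
                      n_genes = agg$n, mean_value = agg$mean,
                      stringsAsFactors = FALSE)
    out <- out[order(out$x), , drop = FALSE]
  }
  out <- out[out$n_genes >= min_n, , drop = FALSE]
  rownames(out) <- NULL
  out
}

aggregate_mean <- function(v, key) {
  ord_keys <- sort(unique(key))
  f <- factor(key, levels = ord_keys)
  data.frame(key = ord_keys,
             n = as.integer(tabulate(f, nbins = length(ord_keys))),
             mean = as.numeric(tapply(v, f, mean)),
             stringsAsFactors = FALSE)
}

#' Linearity of a site-count trend
#'
#' Least-squares line of the per-count mean values on `x = log2(count + 1)`
#' (optionally weighted by group size) plus the Pearson correlation of the
#' same pairs.
#'
#' @param trend a TrendTable from [trend_by_site_count()].
#' @param weighting `"none"` or `"by_n"` (weight each row by its gene
#'   count).
#' @return `list(slope, intercept, pearson_r)`.
#' @export
trend_linearity <- function(trend, weighting = c("none", "by_n")) {
  weighting <- match.arg(weighting)
  if (!is.data.frame(trend) ||
      !all(c("x", "n_genes", "mean_value") %in% names(trend)))
    stop_input("trend must have x, n_genes, mean_value columns")
  if (nrow(trend) < 3L) stop_input("need at least 3 trend rows")
  if (stats::sd(trend$x) == 0) stop_input("degenerate trend: x has no variance")
  w <- if (weighting == "by_n") trend$n_genes else NULL
  fit <- stats::lm(mean_value ~ x, data = trend, weights = w)
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       pearson_r = stats::cor(trend$x, trend$mean_value))
}

#' Mean ORF length per binding-site count
#'
#' Per exact site count, the number of genes and the mean log2 ORF length;
#' the genome-wide mean log2 ORF length is attached as attribute
#' `genome_mean` (the reference line: in real transcriptomes the per-count
#' mean crosses it around a count of 5).
#'
#' @param genes a gene table with `orf_length` and `site_count`.
#' @return A TrendTable: `site_count`, `x = log2(count + 1)`, `n_genes`,
#'   `mean_value` (mean log2 ORF length), with attribute `genome_mean`.
#' @export
orf_length_by_site_count <- function(genes) {
  if (!is.data.frame(genes) || nrow(genes) == 0L ||
      !all(c("orf_length", "site_count") %in% names(genes)))
    stop_input("genes must be nonempty with orf_length and site_count")
  l2 <- log2(genes$orf_length)
  agg <- aggregate_mean(l2, genes$site_count)
  out <- data.frame(site_count = as.integer(agg$key),
                    x = log2(as.numeric(agg$key) + 1),
                    n_genes = agg$n, mean_value = agg$mean,
                    stringsAsFactors = FALSE)
  out <- out[order(out$site_count), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "genome_mean") <- mean(l2)
  out
}

#' JSON summaries of test objects
#'
#' Serializes a [compare_groups()] or [sampling_null()] result to a JSON
#' file (sample means included for the latter).
#'
#' @param x a `group_comparison` or `sampling_null` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(x, path) {
  if (!inherits(x, c("group_comparison", "sampling_null")))
    stop_input("x must be a group_comparison or sampling_null object")
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
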