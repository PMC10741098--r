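# Independent oracles used across the suite. These deliberately re-derive
# results through different code paths (lm.wfit QR, numerical CDF
# integration, brute-force loops) than the implementation under test.

# Brute-force per-point tricube weighted-least-squares local regression.
# Mirrors the documented procedure: q nearest neighbours, boundary ties
# included with weight zero, local polynomial solved by R's QR (lm.wfit),
# rank-deficient windows falling back to the local weighted mean.
loess_oracle <- function(x, y, span = 0.75, degree = 2) {
  x <- as.matrix(x)
  n <- length(y)
  q <- ceiling(span * n)
  scl <- rep(1, ncol(x))
  if (ncol(x) == 2) {
    scl <- apply(x, 2, function(v) {
      k <- floor(0.05 * length(v))
      sv <- sort(v)
      if (length(v) - 2 * k < 2) sd(v) else sd(sv[(k + 1):(length(v) - k)])
    })
  }
  xs <- sweep(x, 2, scl, "/")
  vapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(xs) - xs[i, ])^2))
    dmax <- sort(d)[q]
    idx <- which(d <= dmax)
    if (dmax == 0) return(mean(y[idx]))
    w <- (1 - (d[idx] / dmax)^3)^3
    u <- sweep(x[idx, , drop = FALSE], 2, x[i, ])
    Z <- cbind(1, u)
    if (degree == 2) {
      Z <- cbind(Z, u^2)
      if (ncol(u) == 2) Z <- cbind(Z, u[, 1] * u[, 2])
    }
    f <- lm.wfit(Z, y[idx], w)
    if (f$rank < ncol(Z)) sum(w * y[idx]) / sum(w) else f$coefficients[1]
  }, numeric(1))
}

# Student-t CDF by numerical integration of the density (no pt()).
t_cdf_num <- function(t, df) {
  dens <- function(u)
    exp(lgamma((df + 1) / 2) - lgamma(df / 2) - 0.5 * log(df * pi) -
          (df + 1) / 2 * log1p(u^2 / df))
  0.5 + sign(t) * integrate(dens, 0, abs(t), rel.tol = 1e-12)$value
}

# F CDF by numerical integration of the density (no pf()).
f_cdf_num <- function(f, d1, d2) {
  dens <- function(u)
    exp((d1 / 2) * log(d1 / d2) + (d1 / 2 - 1) * log(u) -
          ((d1 + d2) / 2) * log1p(d1 * u / d2) - lbeta(d1 / 2, d2 / 2))
  integrate(dens, 0, f, rel.tol = 1e-12)$value
}

# Welch two-sided t-test p-value from first principles.
welch_p_num <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * (1 - t_cdf_num(abs(t), df))
}

# Two-sided variance-ratio p-value from first principles.
ftest_p_num <- function(a, b) {
  f <- var(a) / var(b)
  p <- f_cdf_num(f, length(a) - 1, length(b) - 1)
  2 * min(p, 1 - p)
}

# Adjusted + double-adjusted ratio table for a simulated experiment.
sim_ratio_table <- function(config, wt_shift = 0, mt_shift = 0, ...) {
  e <- simulate_experiment(config, wt_shift = wt_shift, mt_shift = mt_shift)
  rt <- suppressMessages(compute_ratios(e$counts, e$genes, ...))
  rt <- suppressMessages(suppressWarnings(adjust_by_orf(rt)))
  double_adjust(rt)
}

# Hand-rolled count matrix with a lib_size attribute.
make_counts <- function(gene_id, wl, wh, ml, mh, lib = NULL) {
  cm <- data.frame(gene_id = gene_id, WT_L = as.integer(wl),
                   WT_H = as.integer(wh), MT_L = as.integer(ml),
                   MT_H = as.integer(mh), stringsAsFactors = FALSE)
  if (!is.null(lib)) {
    names(lib) <- c("WT_L", "WT_H", "MT_L", "MT_H")
    attr(cm, "lib_size") <- lib
  }
  cm
}

make_genes <- function(gene_id, orf, sites) {
  data.frame(gene_id = gene_id, orf_length = as.integer(orf),
             site_count = as.integer(sites), stringsAsFactors = FALSE)
}
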