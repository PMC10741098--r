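test_that("symmetric counts give zero log-ratios and known counts known ratios", {
  genes <- make_genes(c("g1", "g2"), c(900, 1200), c(0, 3))
  cm <- make_counts(c("g1", "g2"), c(10, 40), c(10, 10), c(10, 20),
                    c(10, 20), lib = rep(1000, 4))
  rt <- compute_ratios(cm, genes, min_count = 0, pseudocount = 0.5)
  g1 <- rt[rt$gene_id == "g1", ]
  expect_equal(as.numeric(g1[c("raw_wt", "raw_mt", "mt_over_wt_h",
                               "mt_over_wt_l")]),
               c(0, 0, 0, 0))
  # 40 vs 10 with zero pseudocount is exactly log2(4) = 2
  rt0 <- compute_ratios(cm, genes, min_count = 0, pseudocount = 0)
  expect_equal(rt0$raw_wt[rt0$gene_id == "g2"], 2)
  expect_equal(rt0$log2_orf, log2(c(900, 1200)))
})

test_that("ratios equal an independent recomputation on a random fixture", {
  set.seed(51)
  n <- 100
  ids <- sprintf("g%03d", 1:n)
  genes <- make_genes(ids, sample(200:5000, n), rpois(n, 3))
  lib <- c(2e5, 3e5, 2.5e5, 1.5e5)
  cm <- make_counts(ids, rpois(n, 200), rpois(n, 150), rpois(n, 180),
                    rpois(n, 120), lib = lib)
  pc <- 0.5
  rt <- suppressMessages(compute_ratios(cm, genes, min_count = 10,
                                        pseudocount = pc))
  # first-principles recomputation, gene by gene
  for (k in sample(nrow(rt), 20)) {
    g <- rt$gene_id[k]
    row <- cm[cm$gene_id == g, ]
    cpm <- c((row$WT_L + pc) / lib[1], (row$WT_H + pc) / lib[2],
             (row$MT_L + pc) / lib[3], (row$MT_H + pc) / lib[4]) * 1e6
    expect_equal(rt$raw_wt[k], log2(cpm[1] / cpm[2]))
    expect_equal(rt$raw_mt[k], log2(cpm[3] / cpm[4]))
    expect_equal(rt$mt_over_wt_h[k], log2(cpm[4] / cpm[2]))
    expect_equal(rt$mt_over_wt_l[k], log2(cpm[3] / cpm[1]))
  }
  # the expression filter removes exactly the genes below threshold
  low <- apply(as.matrix(cm[, -1]), 1, min) < 10
  expect_equal(nrow(rt), sum(!low))
})

test_that("the expression filter and failure modes are reported", {
  genes <- make_genes(c("g1", "g2"), c(500, 600), c(0, 0))
  cm <- make_counts(c("g1", "g2"), c(100, 2), c(50, 50), c(60, 60),
                    c(70, 70))
  expect_message(rt <- compute_ratios(cm, genes), "excluded 1 gene")
  expect_equal(nrow(rt), 1)
  expect_error(suppressMessages(compute_ratios(cm, genes, min_count = 1000)),
               class = "polyratio_input_error")
  expect_error(compute_ratios(cm, make_genes("zz", 100, 0)),
               class = "polyratio_input_error")
})

test_that("optional IQR outlier exclusion removes extreme ratios and is logged", {
  set.seed(52)
  n <- 200
  ids <- sprintf("g%03d", 1:n)
  genes <- make_genes(ids, rep(1000, n), rep(0, n))
  wl <- rpois(n, 500)
  wl[1] <- 500000  # one wildly light-shifted gene
  cm <- make_counts(ids, wl, rpois(n, 500), rpois(n, 500), rpois(n, 500))
  expect_message(rt <- compute_ratios(cm, genes, outlier_k = 3),
                 "outlier")
  expect_false("g001" %in% rt$gene_id)
})

test_that("adjustment residuals remove the ORF-length trend", {
  set.seed(53)
  n <- 300
  l2 <- runif(n, 8, 13)
  genes <- make_genes(sprintf("g%03d", 1:n), round(2^l2), rpois(n, 2))
  rt <- data.frame(gene_id = genes$gene_id, log2_orf = log2(genes$orf_length),
                   site_count = genes$site_count,
                   raw_wt = rep(0.7, n),
                   raw_mt = -0.1 * log2(genes$orf_length)^2 +
                     1.5 * log2(genes$orf_length) - 3,
                   stringsAsFactors = FALSE)
  adj <- suppressMessages(adjust_by_orf(rt))
  # constant response: residuals identically (numerically) zero
  expect_lt(max(abs(adj$adj_wt)), 1e-10)
  # smooth monotone (quadratic on this range) trend: removed to precision
  expect_lt(max(abs(adj$adj_mt)), 1e-6)
  expect_equal(attr(adj, "r2_wt"), 1)  # zero-variance convention
  expect_error(adjust_by_orf(rt[1:10, ]), class = "polyratio_input_error")
})

test_that("adjustment sharpens the site-count signal relative to raw ratios", {
  rt <- sim_ratio_table(sim_config(n_genes = 5000, seed = 54))
  l2s <- log2(rt$site_count + 1)
  expect_gt(cor(rt$adj_wt, l2s), cor(rt$raw_wt, l2s))
})

test_that("double adjustment is the exact difference of adjusted ratios", {
  rt <- data.frame(adj_wt = c(1, 0.3, 0), adj_mt = c(-1, 0.3, 0.2))
  out <- double_adjust(rt)
  expect_identical(out$double_adj, c(2, 0, -0.2))
  expect_error(double_adjust(data.frame(adj_wt = 1)),
               class = "polyratio_input_error")
})

test_that("the planted effect size is recovered by the double-adjusted trend", {
  rt <- sim_ratio_table(sim_config(n_genes = 20000, seed = 55))
  tr <- trend_by_site_count(rt, "double_adj")
  lin <- trend_linearity(tr[tr$site_count <= 20, ], weighting = "by_n")
  expect_equal(lin$slope, 0.5, tolerance = 0.2)  # 0.5 +/- 0.1
  expect_gt(lin$pearson_r, 0.9)
})

test_that("residual means are near zero on noisy inputs", {
  rt <- sim_ratio_table(sim_config(n_genes = 5000, seed = 56))
  expect_lt(abs(mean(rt$adj_wt)), 0.01 * sd(rt$raw_wt))
  expect_lt(abs(mean(rt$adj_mt)), 0.01 * sd(rt$raw_mt))
})

test_that("planted dispersion contrast is recovered by the variance-ratio test", {
  hits <- vapply(1:25, function(i) {
    rt <- sim_ratio_table(sim_config(n_genes = 5000, seed = 5600 + i))
    ft <- var.test(rt$adj_wt, rt$adj_mt)
    ft$estimate > 1 && ft$p.value < 0.05
  }, logical(1))
  expect_gte(sum(hits), 24)
})

test_that("a shared miRNA-independent perturbation cancels in the double-adjusted trend", {
  cfg <- sim_config(n_genes = 10000, seed = 57)
  slope_of <- function(wt_shift, mt_shift) {
    rt <- sim_ratio_table(cfg, wt_shift = wt_shift, mt_shift = mt_shift)
    tr <- trend_by_site_count(rt, "double_adj")
    trend_linearity(tr[tr$site_count <= 20, ], weighting = "by_n")$slope
  }
  set.seed(570)
  shared <- rnorm(cfg$n_genes, 0, 0.5)   # site-count-independent, shared
  expect_lt(abs(slope_of(shared, shared) - slope_of(0, 0)), 0.02)
})

test_that("the joint ORF-by-site surface degrades to the 1D fit when sites are constant", {
  set.seed(58)
  n <- 400
  rt <- data.frame(log2_orf = runif(n, 8, 13), site_count = rep(2L, n))
  rt$raw_wt <- sin(rt$log2_orf) + rnorm(n, sd = 0.2)
  expect_warning(f2 <- joint_loess_surface(rt), "zero-spread")
  f1 <- local_fit(rt$log2_orf, rt$raw_wt)
  expect_lt(max(abs(f2$fitted - f1$fitted)), 1e-8)
})

test_that("a noise-free additive surface is captured by the joint fit", {
  set.seed(59)
  n <- 2000
  rt <- data.frame(log2_orf = runif(n, 8, 13),
                   site_count = rpois(n, 4))
  l2s <- log2(rt$site_count + 1)
  rt$raw_wt <- (-0.2 * rt$log2_orf^2 + 3 * rt$log2_orf) + (0.5 * l2s - 0.1 * l2s^2)
  fit <- joint_loess_surface(rt)
  expect_lt(max(abs(fit$residuals)), 1e-3)
  # row permutation permutes predictions identically
  perm <- sample(n)
  fitp <- joint_loess_surface(rt[perm, ])
  expect_lt(max(abs(fitp$fitted - fit$fitted[perm])), 1e-10)
})
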