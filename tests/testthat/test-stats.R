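test_that("identical groups give a null comparison", {
  v <- c(1, 2, 3, 1, 2, 3)
  s <- c(60, 60, 60, 0, 0, 0)
  cmp <- compare_groups(v, s)
  expect_equal(cmp$t_stat, 0)
  expect_equal(cmp$f_stat, 1)
  expect_equal(cmp$mean_a, cmp$mean_b)
})

test_that("t and F p-values match numerically integrated CDF oracles", {
  a <- c(1, 2, 3)
  b <- c(1, 2, 3, 4, 5, 6)
  cmp <- compare_groups(c(a, b), c(rep(60, 3), rep(0, 6)))
  expect_equal(cmp$n_a, 3)
  expect_equal(cmp$f_stat, (1 / 3.5), tolerance = 1e-12)
  expect_equal(cmp$f_pvalue, ftest_p_num(a, b), tolerance = 1e-6)
  expect_equal(cmp$t_pvalue, welch_p_num(a, b), tolerance = 1e-6)

  set.seed(61)
  a2 <- rnorm(40, 0.4, 1.3)
  b2 <- rnorm(90, 0, 0.8)
  cmp2 <- compare_groups(c(a2, b2), c(rep(99, 40), rep(0, 90)))
  expect_equal(cmp2$t_pvalue, welch_p_num(a2, b2), tolerance = 1e-6)
  expect_equal(cmp2$f_pvalue, ftest_p_num(a2, b2), tolerance = 1e-6)
  # pooled-variance variant reproduces the classical Student test
  cmp3 <- compare_groups(c(a2, b2), c(rep(99, 40), rep(0, 90)),
                         var_equal = TRUE)
  expect_equal(cmp3$t_pvalue,
               t.test(a2, b2, var.equal = TRUE)$p.value)
})

test_that("too-small groups are an error and output prints", {
  expect_error(compare_groups(1:5, c(60, 0, 0, 0, 0)),
               class = "polyratio_input_error")
  v <- rnorm(100)
  s <- c(rep(60, 8), rep(0, 92))
  expect_output(print(compare_groups(v, s)), "Welch")
})

test_that("a planted positive effect shifts the targeted-group mean upward", {
  rt <- sim_ratio_table(sim_config(n_genes = 8000, seed = 62))
  cmp <- compare_groups(rt$adj_wt, rt$site_count)
  expect_gt(cmp$mean_a, cmp$mean_b)
  expect_lt(cmp$t_pvalue, 0.01)
})

test_that("resampling null handles boundary cases exactly", {
  # observed mean at the bottom: every sample mean beats it, p = 1
  v <- as.numeric(1:100)
  nul <- sampling_null(v, 1:5, n_samples = 200, seed = 1)
  expect_equal(nul$empirical_p, (1 + 200) / 201)
  expect_equal(nul$sample_size, 5)
  expect_length(nul$sample_means, 200)
  # all values identical: each sample mean ties the observed mean
  nul2 <- sampling_null(rep(2.5, 50), 1:7, n_samples = 100, seed = 1)
  expect_equal(nul2$empirical_p, 1)
  expect_equal(nul2$max_sample_mean, 2.5)
  expect_error(sampling_null(v, integer(0)), class = "polyratio_input_error")
  expect_output(print(nul), "empirical p")
})

test_that("resampling null is reproducible and invariant to value order", {
  set.seed(63)
  v <- rnorm(500)
  idx <- sample(500, 49)
  n1 <- sampling_null(v, idx, n_samples = 300, seed = 9)
  n2 <- sampling_null(v, idx, n_samples = 300, seed = 9)
  expect_identical(n1, n2)
  # permute the universe, remap the target indices
  perm <- sample(500)
  vp <- v[perm]
  idxp <- match(idx, perm)
  n3 <- sampling_null(vp, idxp, n_samples = 300, seed = 9)
  expect_identical(n1$sample_means, n3$sample_means)
  expect_equal(n1$observed_mean, n3$observed_mean)
  expect_equal(n1$empirical_p, n3$empirical_p)
})

test_that("site-count trends aggregate exact groups", {
  rt <- data.frame(site_count = c(0L, 3L), value = c(0.1, 0.7),
                   log2_orf = c(10, 11))
  tr <- trend_by_site_count(rt, "value")
  expect_identical(tr$site_count, c(0L, 3L))
  expect_identical(tr$n_genes, c(1L, 1L))
  expect_equal(tr$mean_value, c(0.1, 0.7))
  expect_equal(tr$x, log2(c(1, 4)))
  # all-zero counts collapse to one row holding the global mean
  rt0 <- data.frame(site_count = rep(0L, 5), value = 1:5)
  tr0 <- trend_by_site_count(rt0, "value")
  expect_equal(nrow(tr0), 1)
  expect_equal(tr0$mean_value, 3)
  expect_error(trend_by_site_count(rt, "nope"),
               class = "polyratio_input_error")
})

test_that("trend rows equal brute-force group means on a large simulation", {
  rt <- sim_ratio_table(sim_config(n_genes = 10000, seed = 64))
  tr <- trend_by_site_count(rt, "double_adj")
  expect_equal(sum(tr$n_genes), nrow(rt))
  for (k in sample(nrow(tr), 10)) {
    sel <- rt$site_count == tr$site_count[k]
    expect_equal(tr$n_genes[k], sum(sel))
    expect_equal(tr$mean_value[k], mean(rt$double_adj[sel]))
  }
  # per-kb variant partitions all genes and keys by sites per kilobase
  trk <- trend_by_site_count(rt, "double_adj", normalize_per_kb = TRUE)
  expect_equal(sum(trk$n_genes), nrow(rt))
  expect_true(all(is.na(trk$site_count)))
  expect_true(all(diff(trk$x) > 0))
})

test_that("trend linearity summarises collinear and planted trends correctly", {
  tr <- data.frame(x = 0:4, n_genes = c(50L, 30L, 10L, 5L, 2L),
                   mean_value = 0.3 * (0:4) - 1)
  lin <- trend_linearity(tr)
  expect_equal(lin$pearson_r, 1)
  expect_equal(lin$slope, 0.3)
  expect_equal(lin$intercept, -1)
  linw <- trend_linearity(tr, weighting = "by_n")
  expect_equal(linw$slope, 0.3)
  expect_error(trend_linearity(tr[1:2, ]), class = "polyratio_input_error")
  flat <- data.frame(x = rep(1, 4), n_genes = 1L, mean_value = rnorm(4))
  expect_error(trend_linearity(flat), class = "polyratio_input_error")
})

test_that("a null trend is flat: no spurious site-count slope", {
  rt <- sim_ratio_table(sim_config(n_genes = 20000, seed = 65,
                                   beta_mirna = 0))
  tr <- trend_by_site_count(rt, "double_adj")
  lin <- trend_linearity(tr[tr$site_count <= 20, ], weighting = "by_n")
  expect_lt(abs(lin$slope), 0.05)
  expect_lt(abs(lin$pearson_r), 0.3)
})

test_that("mean ORF length per site count reports exact means and the genome reference", {
  g <- make_genes(c("a", "b", "c"), c(512, 1024, 2048), c(0, 0, 4))
  tr <- orf_length_by_site_count(g)
  expect_identical(tr$site_count, c(0L, 4L))
  expect_equal(tr$mean_value, c(mean(c(9, 10)), 11))
  expect_equal(attr(tr, "genome_mean"), 10)
  expect_error(orf_length_by_site_count(g[0, ]),
               class = "polyratio_input_error")
})

test_that("ORF-length trend across site counts reflects the coupling", {
  # no coupling: per-count means scatter around the genome mean
  g0 <- simulate_gene_attributes(sim_config(n_genes = 10000, seed = 66,
                                            site_orf_coupling = 0))
  tr0 <- orf_length_by_site_count(g0)
  big <- tr0[tr0$n_genes >= 100, ]
  se <- sd(log2(g0$orf_length)) / sqrt(big$n_genes)
  dev <- abs(big$mean_value - attr(tr0, "genome_mean"))
  expect_true(all(dev < 3 * se))
  expect_gt(mean(dev < 2 * se), 0.8)
  # positive coupling: mean ORF length climbs with the site count
  g1 <- simulate_gene_attributes(sim_config(n_genes = 10000, seed = 66,
                                            site_orf_coupling = 0.6))
  tr1 <- orf_length_by_site_count(g1)
  big1 <- tr1[tr1$n_genes >= 50, ]
  expect_gt(cor(big1$site_count, big1$mean_value, method = "spearman"), 0)
})

test_that("comparison and null objects serialize to JSON", {
  v <- rnorm(60)
  s <- c(rep(60, 5), rep(0, 55))
  f <- tempfile(fileext = ".json")
  write_stats_json(compare_groups(v, s), f)
  j <- jsonlite::read_json(f)
  expect_equal(j$n_a, 5)
  expect_error(write_stats_json(list(), f), class = "polyratio_input_error")
})
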