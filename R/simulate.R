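#' Configuration for a synthetic polysome-profiling experiment
#'
#' Bundles and validates every parameter of the generative model used by
#' [simulate_gene_attributes()] and [simulate_counts()]. The defaults are the
#' "full-effect" study conditions used throughout the package's validation:
#' a transcriptome-scale experiment (12,000 genes) with a planted miRNA
#' effect on the wild-type light/heavy log-ratio (`beta_mirna = 0.5` per unit
#' log2(sites + 1)), larger gene-level ratio dispersion in wild type than in
#' the miRNA-deficient mutant (`sigma_wt = 0.35` vs `sigma_mt = 0.2`), an
#' exponentially decaying (geometric) binding-site-count distribution
#' coupled to ORF length so that roughly 50 genes carry more than 50 sites,
#' and overdispersed negative-binomial count noise.
#'
#' @param n_genes number of genes (>= 2).
#' @param seed master seed; the complete experiment is a deterministic
#'   function of the configuration, including this seed.
#' @param orf_log2_mean,orf_log2_sd mean and sd of log2 ORF length
#'   (nucleotides). Defaults give a median ORF of ~1.35 kb.
#' @param site_decay geometric decay of the binding-site-count distribution:
#'   the baseline probability ratio P(count = k+1) / P(count = k), in (0, 1).
#' @param site_orf_coupling strength (>= 0) of the dependence of site count
#'   on ORF length: the decay parameter of each gene is
#'   `plogis(qlogis(site_decay) + site_orf_coupling * z)` with `z` the
#'   standardized log2 ORF length, so longer ORFs accumulate more sites
#'   when coupling > 0.
#' @param beta_mirna planted shift of the true wild-type light/heavy
#'   log2-ratio per unit log2(site_count + 1). 0 plants no miRNA effect.
#' @param orf_curve named numeric vector `(level, slope, pivot, scale)` of
#'   the monotone-decreasing baseline curve mapping log2 ORF length `u` to
#'   the baseline log-ratio:
#'   `level - slope * scale * log1p(exp((u - pivot) / scale))` — flat for
#'   short ORFs, declining at rate `slope` beyond `pivot`, i.e. a
#'   softplus-saturating decline giving the LOESS stage genuine
#'   nonlinearity.
#' @param sigma_wt,sigma_mt gene-level sds (log2 units) of the wild-type and
#'   mutant true log-ratios around their expected values.
#' @param nb_dispersion negative-binomial dispersion of the count noise
#'   (variance = mu + dispersion * mu^2); values below 1e-12 give Poisson
#'   counts.
#' @param lib_sizes 4 positive library sizes, order WT_L, WT_H, MT_L, MT_H.
#' @param base_expr_log2_mean,base_expr_log2_sd mean and sd of the log2 total
#'   expression level per gene (arbitrary units; only relative levels
#'   matter).
#'
#' @return An object of class `"sim_config"` (a validated named list).
#' @seealso [simulate_experiment()] for the one-call generator.
#' @examples
#' cfg <- sim_config(n_genes = 500, seed = 42)
#' cfg
#' @export
sim_config <- function(n_genes = 12000L,
                       seed = 1L,
                       orf_log2_mean = 10.4,
                       orf_log2_sd = 0.85,
                       site_decay = 0.87,
                       site_orf_coupling = 0.4,
                       beta_mirna = 0.5,
                       orf_curve = c(level = 0.5, slope = 0.6,
                                     pivot = 10, scale = 1),
                       sigma_wt = 0.35,
                       sigma_mt = 0.2,
                       nb_dispersion = 0.05,
                       lib_sizes = c(WT_L = 5e6, WT_H = 5e6,
                                     MT_L = 5e6, MT_H = 5e6),
                       base_expr_log2_mean = 4,
                       base_expr_log2_sd = 1.5) {
  chk_num <- function(v, field, lo = -Inf, hi = Inf, len = 1L) {
    if (!is.numeric(v) || length(v) != len || anyNA(v) || any(!is.finite(v)))
      stop_config("'%s' must be finite numeric of length %d", field, len)
    if (any(v < lo) || any(v > hi))
      stop_config("'%s' out of range [%g, %g]", field, lo, hi)
    v
  }
  n_genes <- as.integer(chk_num(n_genes, "n_genes", lo = 2))
  seed <- as.integer(chk_num(seed, "seed",
                             lo = -.Machine$integer.max,
                             hi = .Machine$integer.max))
  chk_num(orf_log2_mean, "orf_log2_mean")
  chk_num(orf_log2_sd, "orf_log2_sd", lo = 1e-12)
  chk_num(site_decay, "site_decay", lo = 1e-12, hi = 1 - 1e-12)
  chk_num(site_orf_coupling, "site_orf_coupling", lo = 0)
  chk_num(beta_mirna, "beta_mirna")
  orf_curve <- chk_num(orf_curve, "orf_curve", len = 4L)
  if (is.null(names(orf_curve)) ||
      !setequal(names(orf_curve), c("level", "slope", "pivot", "scale")))
    stop_config("'orf_curve' must be named (level, slope, pivot, scale)")
  if (orf_curve[["slope"]] < 0 || orf_curve[["scale"]] <= 0)
    stop_config("'orf_curve' requires slope >= 0 and scale > 0")
  chk_num(sigma_wt, "sigma_wt", lo = 1e-12)
  chk_num(sigma_mt, "sigma_mt", lo = 1e-12)
  chk_num(nb_dispersion, "nb_dispersion", lo = 0)
  lib_sizes <- chk_num(lib_sizes, "lib_sizes", lo = 1, len = 4L)
  chk_num(base_expr_log2_mean, "base_expr_log2_mean")
  chk_num(base_expr_log2_sd, "base_expr_log2_sd", lo = 1e-12)
  names(lib_sizes) <- lib_labels()

  structure(list(
    n_genes = n_genes, seed = seed,
    orf_log2_mean = orf_log2_mean, orf_log2_sd = orf_log2_sd,
    site_decay = site_decay, site_orf_coupling = site_orf_coupling,
    beta_mirna = beta_mirna,
    orf_curve = orf_curve[c("level", "slope", "pivot", "scale")],
    sigma_wt = sigma_wt, sigma_mt = sigma_mt,
    nb_dispersion = nb_dispersion, lib_sizes = lib_sizes,
    base_expr_log2_mean = base_expr_log2_mean,
    base_expr_log2_sd = base_expr_log2_sd
  ), class = "sim_config")
}

lib_labels <- function() c("WT_L", "WT_H", "MT_L", "MT_H")

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic polysome experiment configuration\n")
  cat(sprintf("  %d genes, seed %d\n", x$n_genes, x$seed))
  cat(sprintf("  ORF log2 length ~ N(%.2f, %.2f), floored at 150 nt\n",
              x$orf_log2_mean, x$orf_log2_sd))
  cat(sprintf("  site count: geometric decay %.3f, ORF coupling %.2f\n",
              x$site_decay, x$site_orf_coupling))
  cat(sprintf("  planted miRNA effect beta = %.3f per log2(sites+1)\n",
              x$beta_mirna))
  cat(sprintf("  ratio noise: sigma_wt = %.2f, sigma_mt = %.2f; NB dispersion %.3f\n",
              x$sigma_wt, x$sigma_mt, x$nb_dispersion))
  cat(sprintf("  library sizes: %s\n",
              paste(format(x$lib_sizes, big.mark = ","), collapse = ", ")))
  invisible(x)
}

# baseline log-ratio as a function of log2 ORF length: softplus-saturating,
# monotone decreasing
orf_baseline <- function(u, p) {
  p[["level"]] - p[["slope"]] * p[["scale"]] *
    log1p(exp((u - p[["pivot"]]) / p[["scale"]]))
}

#' Simulate per-gene attributes (ORF length and miRNA binding-site count)
#'
#' ORF lengths are drawn log-normally (parameters from `config`), rounded to
#' integers and floored at 150 nt. Binding-site counts — the number of
#' distinct miRNA families with conserved 3'-UTR sites — are geometric with
#' per-gene decay modulated by standardized log2 ORF length, reproducing two
#' empirical features of real transcriptomes: the number of genes with a
#' given count decays exponentially with the count, and genes with many
#' sites tend to have longer ORFs (when `site_orf_coupling > 0`).
#'
#' @param config a [sim_config()] object.
#' @return A data frame (GeneTable) with columns `gene_id`, `orf_length`
#'   (nucleotides), `site_count`.
#' @examples
#' g <- simulate_gene_attributes(sim_config(n_genes = 100, seed = 7))
#' head(g)
#' @export
simulate_gene_attributes <- function(config) {
  if (!inherits(config, "sim_config"))
    stop_config("'config' must be a sim_config object")
  set.seed(config$seed)
  n <- config$n_genes
  l2 <- rnorm(n, config$orf_log2_mean, config$orf_log2_sd)
  orf <- pmax(150L, as.integer(round(2^l2)))
  z <- as.numeric(scale(log2(orf)))
  if (anyNA(z)) z <- rep(0, n)  # degenerate: all ORFs identical
  decay <- plogis(qlogis(config$site_decay) + config$site_orf_coupling * z)
  sites <- rgeom(n, prob = 1 - decay)
  data.frame(
    gene_id = sprintf("G%0*d", nchar(as.character(n)), seq_len(n)),
    orf_length = orf,
    site_count = as.integer(sites),
    stringsAsFactors = FALSE
  )
}

#' Simulate polysome RNA-seq counts for four libraries
#'
#' Generates raw counts for the four libraries WT_L, WT_H, MT_L, MT_H
#' (wild-type/mutant x light/heavy polysome). Per gene, a total expression
#' level is drawn log-normally; the true wild-type light/heavy log2-ratio is
#' `orf_curve(log2 orf) + beta_mirna * log2(site_count + 1) + N(0, sigma_wt)`
#' and the mutant ratio is `orf_curve(log2 orf) + N(0, sigma_mt)` — the
#' mutant lacks miRNA activity, so the planted site-count effect is absent
#' and the gene-level dispersion is lower. The light-fraction allocation
#' probability is the inverse logit of the true ratio scaled by ln 2 (so the
#' allocation odds are exactly `2^ratio`), and counts are negative-binomial
#' around `allocation x expression x library size`.
#'
#' `wt_shift` / `mt_shift` add extra per-gene shifts to the true log-ratios
#' before counts are drawn — used to plant gene-set signals (spike-ins) or
#' shared, miRNA-independent perturbations in both cell lines.
#'
#' @param genes a GeneTable from [simulate_gene_attributes()].
#' @param config a [sim_config()] object.
#' @param wt_shift,mt_shift numeric, length 1 or `nrow(genes)`: additive
#'   shifts of the true WT / MT log-ratios (default 0).
#' @return A CountMatrix: data frame with columns `gene_id`, `WT_L`, `WT_H`,
#'   `MT_L`, `MT_H` and attribute `lib_size` (the realized column sums).
#' @examples
#' cfg <- sim_config(n_genes = 200, seed = 3)
#' cm <- simulate_counts(simulate_gene_attributes(cfg), cfg)
#' head(cm)
#' attr(cm, "lib_size")
#' @export
simulate_counts <- function(genes, config, wt_shift = 0, mt_shift = 0) {
  if (!inherits(config, "sim_config"))
    stop_config("'config' must be a sim_config object")
  if (!is.data.frame(genes) || nrow(genes) == 0L ||
      !all(c("gene_id", "orf_length", "site_count") %in% names(genes)))
    stop_input("'genes' must be a nonempty gene table with gene_id, orf_length, site_count")
  if (anyDuplicated(genes$gene_id))
    stop_input("duplicated gene_id in gene table")
  n <- nrow(genes)
  if (!length(wt_shift) %in% c(1L, n) || !length(mt_shift) %in% c(1L, n))
    stop_input("wt_shift/mt_shift must have length 1 or nrow(genes)")

  # independent stream from the attribute draws (documented draw order:
  # expression, WT noise, MT noise, then counts per library)
  set.seed((config$seed + 1000003L) %% .Machine$integer.max)
  expr <- 2^rnorm(n, config$base_expr_log2_mean, config$base_expr_log2_sd)
  eps_wt <- rnorm(n, 0, config$sigma_wt)
  eps_mt <- rnorm(n, 0, config$sigma_mt)

  u <- log2(genes$orf_length)
  base <- orf_baseline(u, config$orf_curve)
  rho_wt <- base + config$beta_mirna * log2(genes$site_count + 1) +
    eps_wt + wt_shift
  rho_mt <- base + eps_mt + mt_shift

  p_wt <- plogis(rho_wt * log(2))
  p_mt <- plogis(rho_mt * log(2))
  share <- expr / sum(expr)
  libs <- config$lib_sizes
  mu <- cbind(WT_L = 2 * p_wt * share * libs[["WT_L"]],
              WT_H = 2 * (1 - p_wt) * share * libs[["WT_H"]],
              MT_L = 2 * p_mt * share * libs[["MT_L"]],
              MT_H = 2 * (1 - p_mt) * share * libs[["MT_H"]])

  draw <- function(m) {
    v <- if (config$nb_dispersion < 1e-12) rpois(n, m)
    else rnbinom(n, mu = m, size = 1 / config$nb_dispersion)
    as.integer(v)
  }
  counts <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  for (lab in lib_labels()) counts[[lab]] <- draw(mu[, lab])
  attr(counts, "lib_size") <- colSums(as.matrix(counts[lib_labels()]))
  counts
}

#' Simulate a complete polysome-profiling experiment
#'
#' Convenience wrapper calling [simulate_gene_attributes()] then
#' [simulate_counts()].
#'
#' @inheritParams simulate_counts
#' @param config a [sim_config()] object.
#' @return `list(genes = GeneTable, counts = CountMatrix)`.
#' @export
simulate_experiment <- function(config, wt_shift = 0, mt_shift = 0) {
  genes <- simulate_gene_attributes(config)
  counts <- simulate_counts(genes, config,
                            wt_shift = wt_shift, mt_shift = mt_shift)
  list(genes = genes, counts = counts)
}
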