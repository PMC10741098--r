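#' Run the full analysis chain on a synthetic experiment
#'
#' End-to-end driver: simulate a polysome-profiling experiment, compute and
#' ORF-length-adjust the light/heavy log-ratios, double-adjust against the
#' mutant, summarize site-count trends, compare targeted vs untargeted
#' genes, build the resampling null of the targeted-group mean, and run
#' gene-set enrichment on the double-adjusted ratio. Every stage output is
#' written under `out_dir` as TSV/JSON, together with a provenance record
#' (`provenance.json`: configuration, seed, package and R versions, and
#' MD5 checksums of the written input tables). All randomness derives from
#' `config$seed`; two runs with the same configuration produce
#' byte-identical outputs.
#'
#' Gene sets for the enrichment stage are built from the synthetic universe:
#' `n_decoy_sets` random sets plus one real-signal set
#' (`HIGH_SITE_COUNT`, the genes with `site_count >= 20`), which should
#' surface at the top whenever a positive miRNA effect is planted.
#'
#' @param out_dir output directory (created).
#' @param config a [sim_config()]; its seed drives every stage.
#' @param span,degree adjustment LOESS parameters.
#' @param min_count,pseudocount expression filter / CPM parameters.
#' @param high_threshold targeted-group site-count threshold.
#' @param n_samples resampling-null sample count.
#' @param n_perm enrichment permutation count.
#' @param n_decoy_sets number of random decoy gene sets.
#' @return Invisibly, a list with every stage result (`genes`, `counts`,
#'   `ratios`, `trend_adj`, `trend_double`, `orf_trend`, `comparison_raw`,
#'   `comparison_adj`, `null`, `enrichment`, `paths`).
#' @examples
#' \donttest{
#' res <- run_pipeline(tempfile("run"), sim_config(n_genes = 800, seed = 1),
#'                     n_samples = 100, n_perm = 50)
#' res$comparison_adj
#' }
#' @export
run_pipeline <- function(out_dir,
                         config = sim_config(),
                         span = 0.75, degree = 2,
                         min_count = 10, pseudocount = 0.5,
                         high_threshold = 50,
                         n_samples = 1000, n_perm = 1000,
                         n_decoy_sets = 50) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(out_dir, ...)

  # simulate
  genes <- simulate_gene_attributes(config)
  counts <- simulate_counts(genes, config)
  write_tsv_table(genes, path("genes.tsv"))
  write_tsv_table(counts, path("counts.tsv"))
  htseq_paths <- write_counts_htseq(counts, path("htseq"))

  # ratios + adjustment
  ratios <- compute_ratios(counts, genes, min_count = min_count,
                           pseudocount = pseudocount)
  ratios <- adjust_by_orf(ratios, span = span, degree = degree)
  ratios <- double_adjust(ratios)
  write_tsv_table(ratios, path("ratios.tsv"))

  # trends
  trend_adj <- trend_by_site_count(ratios, "adj_wt")
  trend_double <- trend_by_site_count(ratios, "double_adj")
  orf_trend <- orf_length_by_site_count(genes)
  write_tsv_table(trend_adj, path("trend_adj_wt.tsv"))
  write_tsv_table(trend_double, path("trend_double_adj.tsv"))
  write_tsv_table(orf_trend, path("trend_orf_length.tsv"))

  # group comparisons (raw and adjusted) + resampling null; skipped with a
  # log line when the targeted group is too small for a test
  try_compare <- function(col, file) {
    tryCatch({
      cmp <- compare_groups(ratios[[col]], ratios$site_count,
                            high_threshold = high_threshold)
      write_stats_json(cmp, path(file))
      cmp
    }, polyratio_input_error = function(e) {
      pr_log("run_pipeline: %s comparison skipped (%s)", col,
             conditionMessage(e))
      NULL
    })
  }
  cmp_raw <- try_compare("raw_wt", "compare_raw_wt.json")
  cmp_adj <- try_compare("adj_wt", "compare_adj_wt.json")

  targets <- which(ratios$site_count > high_threshold)
  nul <- NULL
  if (length(targets) > 0L) {
    nul <- sampling_null(ratios$adj_wt, targets, n_samples = n_samples,
                         seed = config$seed)
    write_stats_json(nul, path("sampling_null.json"))
  } else {
    pr_log("run_pipeline: no gene above the %g-site threshold; skipping the resampling null",
           high_threshold)
  }

  # enrichment on the double-adjusted ratio
  sets <- make_decoy_sets(ratios$gene_id, genes,
                          n_decoy_sets = n_decoy_sets,
                          seed = config$seed)
  values <- stats::setNames(ratios$double_adj, ratios$gene_id)
  enr <- enrich_sets(values, sets, n_perm = n_perm, seed = config$seed)
  write_enrichment(enr, path("enrichment.tsv"))

  # provenance
  prov <- list(
    package = "polyratio",
    version = as.character(utils::packageVersion("polyratio")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass(config),
    parameters = list(span = span, degree = degree, min_count = min_count,
                      pseudocount = pseudocount,
                      high_threshold = high_threshold,
                      n_samples = n_samples, n_perm = n_perm,
                      n_decoy_sets = n_decoy_sets),
    input_checksums = stats::setNames(
      as.list(unname(tools::md5sum(c(path("genes.tsv"),
                                     path("counts.tsv"))))),
      c("genes.tsv", "counts.tsv")),
    r2_wt = attr(ratios, "r2_wt"),
    r2_mt = attr(ratios, "r2_mt")
  )
  jsonlite::write_json(prov, path("provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(genes = genes, counts = counts, ratios = ratios,
                 trend_adj = trend_adj, trend_double = trend_double,
                 orf_trend = orf_trend,
                 comparison_raw = cmp_raw, comparison_adj = cmp_adj,
                 null = nul, enrichment = enr,
                 paths = c(out_dir = out_dir, htseq_paths)))
}

# Random decoy gene sets over the analyzed universe plus one real-signal
# set containing the high-site-count genes.
make_decoy_sets <- function(universe, genes, n_decoy_sets = 50, seed = 1L) {
  set.seed(as.integer(seed))
  sets <- lapply(seq_len(n_decoy_sets), function(i) {
    m <- sample(20:200, 1L)
    sample(universe, min(m, length(universe)))
  })
  names(sets) <- sprintf("DECOY_%03d", seq_len(n_decoy_sets))
  high <- genes$gene_id[genes$site_count >= 20]
  high <- intersect(high, universe)
  if (length(high) >= 5L) sets$HIGH_SITE_COUNT <- high
  attr(sets, "descriptions") <-
    stats::setNames(c(rep("random decoy set", n_decoy_sets),
                      if (length(high) >= 5L) "genes with >= 20 binding sites"),
                    names(sets))
  sets
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat YAML whose keys are [sim_config()] fields and/or [run_pipeline()]
#' parameters. Returns the two argument lists; unknown keys are an error.
#'
#' @param path YAML file path.
#' @param overrides named list overriding file values (e.g. parsed CLI
#'   flags).
#' @return `list(config = <sim_config>, pipeline = <named list>)`.
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop_format("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop_format("%s: config must be a YAML mapping", path)
  for (nm in names(overrides)) vals[[nm]] <- overrides[[nm]]
  sim_fields <- names(formals(sim_config))
  pipe_fields <- setdiff(names(formals(run_pipeline)), c("out_dir", "config"))
  unknown <- setdiff(names(vals), c(sim_fields, pipe_fields))
  if (length(unknown) > 0L)
    stop_config("unknown configuration key(s): %s",
                paste(unknown, collapse = ", "))
  sim_args <- vals[intersect(names(vals), sim_fields)]
  if (!is.null(sim_args$orf_curve)) sim_args$orf_curve <- unlist(sim_args$orf_curve)
  if (!is.null(sim_args$lib_sizes)) sim_args$lib_sizes <- unlist(sim_args$lib_sizes)
  list(config = do.call(sim_config, sim_args),
       pipeline = vals[intersect(names(vals), pipe_fields)])
}
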