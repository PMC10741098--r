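#' Read four HTSeq-count tables into a count matrix
#'
#' Each input is a two-column, headerless TSV (`gene_id TAB count`) as
#' written by HTSeq-count. The special counter rows HTSeq appends
#' (`__no_feature`, `__ambiguous`, ...) are ignored. Gene identifiers are
#' uppercased (gene symbols are the join key throughout the package) and
#' the four files are inner-joined; genes missing from any file are dropped
#' and the drop is logged. Library sizes are the column sums of the joined
#' matrix.
#'
#' @param paths character vector of 4 file paths, order light/heavy
#'   wild-type then light/heavy mutant by default.
#' @param labels column labels for the 4 libraries.
#' @return A CountMatrix: data frame `gene_id` + 4 count columns, with
#'   attribute `lib_size`.
#' @export
read_counts <- function(paths, labels = lib_labels()) {
  if (length(paths) != 4L || length(labels) != 4L)
    stop_input("need exactly 4 paths and 4 labels")
  if (anyDuplicated(labels)) stop_input("library labels must be unique")

  tabs <- lapply(paths, read_htseq_file)
  for (i in seq_len(4L)) names(tabs[[i]])[2L] <- labels[i]

  merged <- Reduce(function(a, b) merge(a, b, by = "gene_id"), tabs)
  if (nrow(merged) == 0L)
    stop_format("no genes shared by all four count files")
  n_union <- length(unique(unlist(lapply(tabs, `[[`, "gene_id"))))
  dropped <- n_union - nrow(merged)
  if (dropped > 0L)
    pr_log("read_counts: dropped %d gene(s) absent from at least one file", dropped)
  merged <- merged[order(merged$gene_id), , drop = FALSE]
  rownames(merged) <- NULL
  attr(merged, "lib_size") <- colSums(as.matrix(merged[labels]))
  merged
}

read_htseq_file <- function(path) {
  if (!file.exists(path)) stop_format("count file not found: %s", path)
  lines <- readLines(path)
  idx <- which(!startsWith(lines, "__") & nzchar(lines))
  if (length(idx) == 0L) stop_format("%s: no gene rows", path)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    j <- which(nf != 2L)[1L]
    stop_format("%s line %d: expected 2 tab-separated fields, got %d",
                path, idx[j], nf[j])
  }
  ids <- toupper(vapply(parts, `[[`, character(1), 1L))
  raw <- vapply(parts, `[[`, character(1), 2L)
  v <- suppressWarnings(as.numeric(raw))
  bad <- is.na(v) | v != floor(v) | v < 0
  if (any(bad)) {
    j <- which(bad)[1L]
    stop_format("%s line %d: count '%s' is not a non-negative integer",
                path, idx[j], raw[j])
  }
  counts <- as.integer(v)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop_format("%s: duplicated gene id '%s'", path, dup[1L])
  data.frame(gene_id = ids, count = counts, stringsAsFactors = FALSE)
}

#' Write a count matrix as four HTSeq-count-style files
#'
#' One two-column headerless TSV per library (`gene_id TAB count`), no
#' special counter rows.
#'
#' @param counts a CountMatrix (see [read_counts()]).
#' @param dir output directory (created if missing).
#' @param labels the 4 count columns to write.
#' @return the 4 file paths, invisibly.
#' @export
write_counts_htseq <- function(counts, dir, labels = lib_labels()) {
  if (!all(c("gene_id", labels) %in% names(counts)))
    stop_input("counts lacks required columns")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(labels, ".tsv"))
  for (i in seq_along(labels)) {
    utils::write.table(counts[, c("gene_id", labels[i])], paths[i],
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

#' Read a TargetScan-style conserved-site table
#'
#' Consumes a headered TSV with (at least) a gene-symbol column and a
#' miRNA-family column, optionally a site-region column; the column names
#' are configurable because TargetScan release layouts vary. Gene symbols
#' are uppercased.
#'
#' @param path file path.
#' @param gene_col,mirna_col,region_col column names in the file; set
#'   `region_col = NULL` if the file has no region column.
#' @return data frame with columns `gene_symbol`, `mirna_family` and, when
#'   present, `site_region`.
#' @export
read_target_sites <- function(path, gene_col = "gene_symbol",
                              mirna_col = "mirna_family",
                              region_col = "site_region") {
  if (!file.exists(path)) stop_format("site table not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(gene_col, mirna_col))
    if (!col %in% names(df))
      stop_format("%s: missing required column '%s'", path, col)
  out <- data.frame(gene_symbol = toupper(as.character(df[[gene_col]])),
                    mirna_family = as.character(df[[mirna_col]]),
                    stringsAsFactors = FALSE)
  if (!is.null(region_col) && region_col %in% names(df))
    out$site_region <- as.character(df[[region_col]])
  bad <- which(!nzchar(out$gene_symbol) | !nzchar(out$mirna_family) |
                 is.na(out$gene_symbol) | is.na(out$mirna_family))
  if (length(bad) > 0L)
    stop_format("%s row %d: empty gene symbol or miRNA family", path, bad[1L] + 1L)
  out
}

#' Count distinct miRNA families with conserved sites per gene
#'
#' The binding-site count of a gene is the number of *unique* miRNA
#' families with at least one record passing the region filter — repeated
#' sites of the same family count once. Genes in `master_genes` absent from
#' the records receive count 0.
#'
#' @param records data frame as returned by [read_target_sites()].
#' @param region_filter `"UTR3"` (keep only 3'-UTR records, the default;
#'   a no-op when the records carry no `site_region` column) or `"any"`.
#' @param master_genes optional character vector of gene symbols defining
#'   the universe; genes with no sites get `site_count = 0`.
#' @return data frame `gene_id`, `site_count`, one row per gene.
#' @examples
#' rec <- data.frame(gene_symbol = c("GA", "GA", "GA", "GB"),
#'                   mirna_family = c("miR-1", "miR-1", "miR-2", "miR-1"))
#' count_sites(rec)
#' @export
count_sites <- function(records, region_filter = c("UTR3", "any"),
                        master_genes = NULL) {
  region_filter <- match.arg(region_filter)
  if (!is.data.frame(records) ||
      !all(c("gene_symbol", "mirna_family") %in% names(records)))
    stop_input("records must have gene_symbol and mirna_family columns")
  rec <- records
  if (region_filter == "UTR3" && "site_region" %in% names(rec)) {
    n0 <- nrow(rec)
    rec <- rec[rec$site_region == "UTR3", , drop = FALSE]
    if (nrow(rec) < n0)
      pr_log("count_sites: excluded %d non-3'-UTR record(s)", n0 - nrow(rec))
  }
  rec$gene_symbol <- toupper(rec$gene_symbol)
  counts <- if (nrow(rec) == 0L) {
    data.frame(gene_id = character(0), site_count = integer(0),
               stringsAsFactors = FALSE)
  } else {
    u <- unique(rec[c("gene_symbol", "mirna_family")])
    agg <- as.data.frame(table(u$gene_symbol), stringsAsFactors = FALSE)
    names(agg) <- c("gene_id", "site_count")
    agg$site_count <- as.integer(agg$site_count)
    agg
  }
  if (!is.null(master_genes)) {
    master <- unique(toupper(master_genes))
    counts <- merge(data.frame(gene_id = master, stringsAsFactors = FALSE),
                    counts, by = "gene_id", all.x = TRUE)
    counts$site_count[is.na(counts$site_count)] <- 0L
  }
  counts <- counts[order(counts$gene_id), , drop = FALSE]
  rownames(counts) <- NULL
  counts
}

#' Read a GMT gene-set file
#'
#' One set per line: `name TAB description TAB member TAB member ...`.
#' Members are uppercased and de-duplicated per set. Lines with fewer than
#' three fields and duplicated set names are rejected with the offending
#' line number.
#'
#' @param path GMT file path.
#' @return A GeneSetCollection: named list of character vectors of member
#'   symbols, with a `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_format("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_format("%s: empty GMT file", path)
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop_format("%s line %d: expected >= 3 tab-separated fields, got %d",
                  path, i, length(f))
    nm[i] <- f[1L]
    desc[i] <- f[2L]
    members <- unique(toupper(f[-(1:2)]))
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop_format("%s line %d: gene set '%s' has no members", path, i, f[1L])
    sets[[i]] <- members
  }
  if (anyDuplicated(nm)) {
    i <- which(duplicated(nm))[1L]
    stop_format("%s line %d: duplicated set name '%s'", path, i, nm[i])
  }
  names(sets) <- nm
  names(desc) <- nm
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of member-symbol vectors; an optional
#'   `descriptions` attribute supplies the second column (default `"NA"`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop_input("sets must be a named list")
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "NA"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a simple TSV table
#'
#' Plain headered tab-separated serialization used for gene tables, count
#' matrices and ratio tables. `read_tsv_table` refuses files with
#' duplicated header names.
#'
#' @param df data frame to write.
#' @param path file path.
#' @return `write_tsv_table`: `path` invisibly; `read_tsv_table`: the data
#'   frame.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop_format("table not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (anyDuplicated(names(df)))
    stop_format("%s: duplicated column names", path)
  df
}
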