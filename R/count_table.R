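#' Read an OTU-by-sample read-count table
#'
#' Reads a delimited text file of non-negative integer read counts into a
#' validated count matrix with taxa as rows and samples as columns. The first
#' column holds taxon identifiers; the header row holds sample identifiers.
#' The field separator is sniffed (tab first, then comma) unless given.
#'
#' @param path Path to a TSV/CSV file.
#' @param orientation `"taxa_by_samples"` (default) if rows are taxa, or
#'   `"samples_by_taxa"` if the file is transposed; the returned matrix is
#'   always taxa x samples.
#' @param sep Field separator; `NULL` (default) sniffs tab then comma.
#' @return Integer matrix (taxa x samples) with unique dimnames.
#' @export
read_count_table <- function(path, orientation = c("taxa_by_samples", "samples_by_taxa"),
                             sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("count table file not found: %s", path)
  sep <- sep %||% sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  ids <- as.character(df[[1]])
  # data-frame subsetting deduplicates repeated column names, so check the
  # header before extracting the matrix
  if (anyDuplicated(names(df)[-1]))
    stopf("duplicate sample ids in %s: %s", path,
          paste(unique(names(df)[-1][duplicated(names(df)[-1])]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  bad <- which(!is.finite(m) | m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("count table cell is not a non-negative integer: row '%s', column '%s'",
          rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]])
  }
  if (orientation == "samples_by_taxa") m <- t(m)
  storage.mode(m) <- "integer"
  validate_count_table(m)
  m
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Validate a count table
#'
#' Checks the invariants of the count-table container: numeric non-negative
#' integer entries, unique taxon and sample identifiers.
#'
#' @param x Matrix, taxa x samples.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_count_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stopf("count table must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stopf("count table must have taxon row names and sample column names")
  if (anyDuplicated(rownames(x))) stopf("duplicate taxon ids: %s",
    paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x))) stopf("duplicate sample ids: %s",
    paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (any(x < 0)) stopf("count table has negative entries")
  invisible(x)
}

#' Write a count table as TSV
#'
#' @param x Count matrix (taxa x samples).
#' @param path Output path.
#' @param id_column Name of the first (taxon id) column.
#' @export
write_count_table <- function(x, path, id_column = "taxon_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert read counts to per-sample relative abundances
#'
#' Each column (sample) is divided by its total so that columns sum to one.
#'
#' @param x Count matrix (taxa x samples).
#' @return Numeric matrix of proportions, same shape and dimnames.
#' @export
to_relative_abundance <- function(x) {
  x <- as_matrix_checked(x, "count table")
  tot <- colSums(x)
  zero <- which(tot <= 0)
  if (length(zero) > 0)
    stopf("sample(s) with zero total reads: %s",
          paste(colnames(x)[zero], collapse = ", "))
  sweep(x, 2, tot, "/")
}

#' Subsample each sample to an even sequencing depth
#'
#' Rarefies every sample (column) to the same number of reads by subsampling
#' without replacement (multivariate hypergeometric), the usual depth
#' homogenization applied before diversity and distance calculations.
#' Samples whose total is below `depth` are dropped with a warning.
#'
#' @param x Count matrix (taxa x samples).
#' @param depth Target depth; default is the minimum column sum.
#' @param seed Optional integer seed for reproducible subsampling.
#' @return Count matrix whose retained columns each sum to `depth`.
#' @export
rarefy_even_depth <- function(x, depth = NULL, seed = NULL) {
  x <- as_matrix_checked(x, "count table")
  tot <- colSums(x)
  depth <- depth %||% min(tot)
  if (length(depth) != 1 || !is.finite(depth) || depth <= 0 || depth != floor(depth))
    stopf("depth must be a single positive integer")
  keep <- tot >= depth
  if (!all(keep)) {
    warnf("dropping %d sample(s) below depth %d: %s", sum(!keep), depth,
          paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) == 0) stopf("no samples at or above depth %d", depth)
  # vegan warns heuristically when a community has no zero counts; our
  # inputs are validated integer read counts, so silence it
  out <- with_seed_or_not(seed, t(suppressWarnings(vegan::rrarefy(t(x), depth))))
  storage.mode(out) <- "integer"
  out
}

#' Collapse a count table to a higher taxonomic rank
#'
#' Sums counts over taxa sharing the same label at `rank`. Taxa with an empty
#' or missing label at that rank are pooled into an `"Unidentified"` row, so
#' per-sample read totals are conserved. `rank = "category"` maps phyla to
#' food categories through `food_map`.
#'
#' @param x Count matrix (taxa x samples), rows named by taxon id.
#' @param taxonomy Data frame from [read_taxonomy()]: column `taxon_id` plus
#'   rank columns `kingdom` ... `species`.
#' @param rank One of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`, or `"category"`.
#' @param food_map Named character vector `phylum -> category`
#'   (see [default_food_category_map()]); required when `rank = "category"`.
#' @return Count matrix (labels x samples).
#' @export
collapse_to_rank <- function(x, taxonomy, rank, food_map = NULL) {
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
  if (!(rank %in% c(ranks, "category")))
    stopf("unknown rank '%s'; must be one of %s or 'category'", rank,
          paste(ranks, collapse = ", "))
  x <- as_matrix_checked(x, "count table")
  idx <- match(rownames(x), taxonomy$taxon_id)
  if (anyNA(idx))
    stopf("taxa missing from taxonomy: %s",
          paste(utils::head(rownames(x)[is.na(idx)], 5), collapse = ", "))
  lookup_rank <- if (rank == "category") "phylum" else rank
  lab <- as.character(taxonomy[[lookup_rank]][idx])
  lab[is.na(lab) | lab == "" | lab == "Unidentified"] <- "Unidentified"
  if (rank == "category") {
    food_map <- food_map %||% default_food_category_map()
    known <- lab != "Unidentified"
    lab[known] <- unname(food_map[lab[known]])
    lab[is.na(lab)] <- "other"
  }
  out <- rowsum(x, group = lab)
  out[order(rownames(out) == "Unidentified", rownames(out)), , drop = FALSE]
}

#' Drop host-assigned taxa from a count table
#'
#' Removes rows whose taxonomy `identity_flag` is `"host"` (predator reads
#' amplified alongside the prey), the first filtering step of the pipeline.
#'
#' @inheritParams collapse_to_rank
#' @return Filtered count matrix.
#' @export
remove_host_taxa <- function(x, taxonomy) {
  idx <- match(rownames(x), taxonomy$taxon_id)
  host <- !is.na(idx) & taxonomy$identity_flag[idx] == "host"
  x[!host, , drop = FALSE]
}
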