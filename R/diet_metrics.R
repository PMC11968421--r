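#' Per-group frequency of occurrence (FO)
#'
#' FO of taxon i in a group is `100 * N_i / T`: the number of stomachs in
#' which the taxon is detected (at least `min_reads` reads) as a percentage
#' of the group's stomachs with food.
#'
#' @param x Count matrix (taxa x samples).
#' @param groups Named character/factor vector mapping sample id to group,
#'   or a vector aligned with `colnames(x)`.
#' @param min_reads Detection threshold in reads (default 1).
#' @return Matrix of FO percentages, taxa x groups.
#' @export
frequency_of_occurrence <- function(x, groups, min_reads = 1) {
  if (min_reads < 1) stopf("min_reads must be >= 1")
  groups <- align_groups(groups, colnames(x))
  pres <- x >= min_reads
  sapply(split(seq_along(groups), groups), function(j)
    100 * rowMeans(pres[, j, drop = FALSE]))
}

#' Per-group relative read abundance (RRA)
#'
#' The per-sample read proportion of each taxon, averaged over the group's
#' samples and expressed as a percentage; RRA columns (with any
#' "Unidentified" row included) sum to 100 per group.
#'
#' @inheritParams frequency_of_occurrence
#' @return Matrix of RRA percentages, taxa x groups.
#' @export
relative_read_abundance <- function(x, groups) {
  groups <- align_groups(groups, colnames(x))
  p <- to_relative_abundance(x)
  sapply(split(seq_along(groups), groups), function(j)
    100 * rowMeans(p[, j, drop = FALSE]))
}

align_groups <- function(groups, sample_ids) {
  if (!is.null(names(groups))) {
    miss <- setdiff(sample_ids, names(groups))
    if (length(miss) > 0)
      stopf("samples without a group assignment: %s", paste(miss, collapse = ", "))
    groups <- groups[sample_ids]
  } else if (length(groups) != length(sample_ids)) {
    stopf("groups must be named by sample id or aligned with the samples")
  }
  lev <- if (is.factor(groups)) levels(groups) else unique(as.character(groups))
  g <- factor(as.character(groups), levels = lev)
  empty <- setdiff(levels(g), unique(as.character(g)))
  if (length(empty) > 0) stopf("empty group(s): %s", paste(empty, collapse = ", "))
  g
}

#' Build a per-group diet profile (FO + RRA)
#'
#' Bundles per-group FO and RRA at a chosen taxonomic rank, the unit passed
#' to category aggregation, feeding-strategy classification and overlap.
#'
#' @inheritParams frequency_of_occurrence
#' @param taxonomy,rank,food_map Optional: collapse `x` with
#'   [collapse_to_rank()] first (default: use rows of `x` as-is, rank "otu").
#' @param categories Optional named vector `taxon -> food category` attached
#'   to the profile (used by [category_rra()]).
#' @return A `diet_profile`: list with `rank`, `groups`, `n` (samples per
#'   group), matrices `fo` and `rra` (taxa x groups) and `categories`.
#' @export
diet_profile <- function(x, groups, taxonomy = NULL, rank = "otu",
                         food_map = NULL, min_reads = 1, categories = NULL) {
  if (!is.null(taxonomy) && rank != "otu")
    x <- collapse_to_rank(x, taxonomy, rank, food_map)
  g <- align_groups(groups, colnames(x))
  if (is.null(categories) && rank == "phylum") {
    fm <- food_map %||% default_food_category_map()
    categories <- stats::setNames(
      ifelse(rownames(x) == "Unidentified", "other",
             ifelse(is.na(fm[rownames(x)]), "other", fm[rownames(x)])),
      rownames(x))
  }
  structure(list(
    rank = rank,
    groups = levels(g),
    n = as.integer(table(g)[levels(g)]),
    fo = frequency_of_occurrence(x, g, min_reads),
    rra = relative_read_abundance(x, g),
    categories = categories
  ), class = "diet_profile")
}

#' @export
print.diet_profile <- function(x, ...) {
  cat(sprintf("Diet profile at rank '%s': %d taxa, %d group(s) [%s]\n",
              x$rank, nrow(x$rra), length(x$groups),
              paste(sprintf("%s (n=%d)", x$groups, x$n), collapse = ", ")))
  invisible(x)
}

#' Aggregate a phylum-level profile to food categories
#'
#' Category RRA is the sum of the member phyla's RRA (RRA is linear in
#' reads); category FO is reported as the maximum member-phylum FO, a lower
#' bound on the FO of the union of phyla, since the per-sample incidences
#' are no longer available at profile level.
#'
#' @param profile A `diet_profile` at phylum rank (or any rank with a
#'   `categories` map attached).
#' @param food_map Optional named vector `taxon -> category` overriding the
#'   profile's own map.
#' @return List with matrices `rra` and `fo_lower_bound`
#'   (category x group).
#' @export
category_rra <- function(profile, food_map = NULL) {
  cats <- resolve_categories(profile, food_map)
  rra <- rowsum(profile$rra, group = cats)
  fo <- do.call(rbind, lapply(split(seq_along(cats), cats), function(i)
    apply(profile$fo[i, , drop = FALSE], 2, max)))
  ord <- category_order(rownames(rra))
  list(rra = rra[ord, , drop = FALSE], fo_lower_bound = fo[ord, , drop = FALSE])
}

resolve_categories <- function(profile, food_map = NULL) {
  taxa <- rownames(profile$rra)
  if (!is.null(food_map)) {
    cats <- unname(food_map[taxa])
  } else if (!is.null(profile$categories)) {
    cats <- unname(profile$categories[taxa])
  } else {
    stopf("profile has no food-category map; supply food_map")
  }
  cats[is.na(cats) | taxa == "Unidentified"] <- "other"
  cats
}

category_order <- function(nm) {
  ref <- c("phytoplankton", "protozoa", "zooplankton", "zoobenthos", "detritus", "other")
  order(match(nm, ref, nomatch = length(ref) + 1L))
}

#' Mean food-category RRA across groups
#'
#' The unweighted arithmetic mean over groups of each category's RRA,
#' summarizing the overall diet make-up across populations or seasons.
#'
#' @param profile A phylum-rank `diet_profile` (or list of profiles sharing
#'   a category map, whose group columns are pooled).
#' @param food_map Optional category map override.
#' @return Named numeric vector of category means (percent).
#' @export
mean_category_rra <- function(profile, food_map = NULL) {
  if (inherits(profile, "diet_profile")) profiles <- list(profile) else profiles <- profile
  mats <- lapply(profiles, function(p) category_rra(p, food_map)$rra)
  m <- do.call(cbind, mats)
  rowMeans(m)
}

#' Classify per-taxon feeding strategy from FO and RRA
#'
#' Quadrant rule on the Costello-style FO-vs-RRA plane: low FO with high RRA
#' marks specialized feeding on that prey, high FO with low RRA a
#' generalized strategy; the remaining quadrants are `rare` and `dominant`.
#' Values exactly at a cut classify to the "high" side.
#'
#' @param fo,rra Numeric vectors of FO and RRA percentages (same length).
#' @param fo_cut,rra_cut Quadrant cut-offs in percent, in (0, 100).
#' @return Character vector of labels
#'   (`specialist`/`generalist`/`rare`/`dominant`).
#' @export
feeding_strategy <- function(fo, rra, fo_cut = 50, rra_cut = 25) {
  if (fo_cut <= 0 || fo_cut >= 100 || rra_cut <= 0 || rra_cut >= 100)
    stopf("cuts must lie strictly between 0 and 100")
  hi_fo <- fo >= fo_cut
  hi_rra <- rra >= rra_cut
  out <- ifelse(hi_fo & hi_rra, "dominant",
         ifelse(hi_fo & !hi_rra, "generalist",
         ifelse(!hi_fo & hi_rra, "specialist", "rare")))
  names(out) <- names(fo) %||% names(rra)
  out
}

#' Per-sample trophic diversity indices
#'
#' Shannon-Wiener `H' = -sum p_i log p_i`, Pielou evenness
#' `J = H' / log S` and Levins niche breadth `B = 1 / sum p_i^2`, computed
#' from each sample's read proportions; `S` is the number of taxa detected
#' in that sample. `J` is undefined (NA) when `S = 1`.
#'
#' @param x Count matrix (taxa x samples), typically at OTU rank.
#' @param log_base Base of the logarithm: `exp(1)` (default, nats) or `2`
#'   (bits, the QIIME convention).
#' @param exclude_unidentified Drop the "Unidentified" row first?
#' @return Data frame with one row per sample: `sample_id`, `S`, `H`, `J`, `B`.
#' @export
diversity_indices <- function(x, log_base = exp(1), exclude_unidentified = FALSE) {
  x <- as_matrix_checked(x, "count table")
  if (exclude_unidentified) x <- x[rownames(x) != "Unidentified", , drop = FALSE]
  if (any(colSums(x) <= 0)) stopf("sample(s) with no reads: %s",
    paste(colnames(x)[colSums(x) <= 0], collapse = ", "))
  p <- to_relative_abundance(x)
  S <- colSums(p > 0)
  H <- vegan::diversity(t(p), index = "shannon", base = log_base)
  B <- vegan::diversity(t(p), index = "invsimpson")
  J <- ifelse(S > 1, H / log(S, base = log_base), NA_real_)
  data.frame(sample_id = colnames(x), S = as.integer(S),
             H = unname(H), J = unname(J), B = unname(B),
             stringsAsFactors = FALSE)
}

#' Group mean and standard error of diversity indices
#'
#' @param indices Output of [diversity_indices()].
#' @param groups Sample-to-group map (named vector, or aligned).
#' @return Data frame: group, n, then mean and SE of H, J, B.
#' @export
diversity_group_summary <- function(indices, groups) {
  g <- align_groups(groups, indices$sample_id)
  agg <- function(v, f) tapply(v, g, f)
  data.frame(group = levels(g),
             n = as.integer(table(g)[levels(g)]),
             H_mean = as.numeric(agg(indices$H, mean)), H_se = as.numeric(agg(indices$H, se)),
             J_mean = as.numeric(agg(indices$J, function(v) mean(v, na.rm = TRUE))),
             J_se = as.numeric(agg(indices$J, se)),
             B_mean = as.numeric(agg(indices$B, mean)), B_se = as.numeric(agg(indices$B, se)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Schoener diet overlap between two proportion vectors
#'
#' `alpha = 1 - 0.5 * sum |P_x - P_y|`, ranging from 0 (no overlap) to 1
#' (identical resource use); values above 0.6 are conventionally considered
#' biologically significant. Inputs on a shared taxon index are renormalized
#' to sum to one, tolerating the rounding of printed report tables.
#'
#' @param p_x,p_y Non-negative vectors on the same taxon index (percent or
#'   proportion scale).
#' @param tol Allowed relative deviation of each input sum from 1 (after
#'   percent rescaling) before renormalization is refused; default 0.02.
#' @return Scalar overlap in \[0, 1\].
#' @export
schoener_overlap <- function(p_x, p_y, tol = 0.02) {
  p_x <- normalize_diet_vector(p_x, tol, "p_x")
  p_y <- normalize_diet_vector(p_y, tol, "p_y")
  1 - 0.5 * sum(abs(p_x - p_y))
}

normalize_diet_vector <- function(p, tol, what) {
  if (any(p < 0)) stopf("%s has negative entries", what)
  s <- sum(p)
  if (s <= 0) stopf("%s is all zero", what)
  if (s > 50) p <- p / 100  # percent scale
  if (abs(sum(p) - 1) > tol) stopf("%s does not sum to 1 within tolerance (sum = %.4f)",
                                   what, sum(p))
  p / sum(p)
}

#' Pairwise Schoener overlap matrix across groups
#'
#' @param rra Matrix of diet proportions or RRA percentages (taxa x groups),
#'   or a `diet_profile` whose `rra` slot is used.
#' @param threshold Biological-significance threshold (default 0.6).
#' @param tol Passed to [schoener_overlap()].
#' @return An `overlap_matrix`: list with the symmetric `alpha` matrix
#'   (unit diagonal), `threshold`, `min`, `max` and `n_exceed` (pairs above
#'   the threshold).
#' @export
overlap_matrix <- function(rra, threshold = 0.6, tol = 0.02) {
  if (inherits(rra, "diet_profile")) rra <- rra$rra
  rra <- as_matrix_checked(rra, "RRA matrix")
  k <- ncol(rra)
  if (k < 2) stopf("need at least two groups")
  a <- diag(1, k)
  dimnames(a) <- list(colnames(rra), colnames(rra))
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    a[i, j] <- a[j, i] <- schoener_overlap(rra[, i], rra[, j], tol = tol)
  off <- a[upper.tri(a)]
  structure(list(alpha = a, threshold = threshold,
                 min = min(off), max = max(off),
                 n_exceed = sum(off > threshold)),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("Schoener overlap: %d units, range [%.2f, %.2f], %d pair(s) > %.1f\n",
              ncol(x$alpha), x$min, x$max, x$n_exceed, x$threshold))
  print(round(x$alpha, 2))
  invisible(x)
}

#' Stomach-fullness summary per group
#'
#' Counts stomachs per fullness grade 0-5 and reports the fullness index
#' (percentage at grades 4-5, the well-filled stomachs whose contents are
#' sampled) and the empty index (percentage at grade 0).
#'
#' @param metadata Data frame with `sample_id`, `group`, `fullness_grade`.
#' @return Data frame: one row per group with grade counts `g0`..`g5`, `n`,
#'   `fullness_index` and `empty_index` (percent).
#' @export
fullness_summary <- function(metadata) {
  if (!"fullness_grade" %in% names(metadata))
    stopf("metadata has no fullness_grade column")
  g <- align_groups(stats::setNames(metadata$group, metadata$sample_id),
                    metadata$sample_id)
  tab <- table(g, factor(metadata$fullness_grade, levels = 0:5))
  n <- rowSums(tab)
  out <- data.frame(group = rownames(tab), as.data.frame.matrix(tab),
                    n = as.integer(n),
                    fullness_index = 100 * (tab[, "4"] + tab[, "5"]) / n,
                    empty_index = 100 * tab[, "0"] / n,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[2:7] <- paste0("g", 0:5)
  out
}
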