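#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` on counts or proportions;
#' bounded in \[0, 1\] for non-negative data.
#'
#' @param x Count or proportion matrix (taxa x samples).
#' @return A [stats::dist] over samples with attribute `metric = "bray_curtis"`.
#' @export
bray_curtis <- function(x) {
  x <- as_matrix_checked(x, "abundance matrix")
  if (ncol(x) < 2) stopf("need at least two samples")
  if (any(colSums(x) <= 0))
    stopf("sample(s) with zero total: %s", paste(colnames(x)[colSums(x) <= 0], collapse = ", "))
  d <- vegan::vegdist(t(x), method = "bray")
  attr(d, "metric") <- "bray_curtis"
  d
}

#' Weighted UniFrac distance between samples
#'
#' Phylogenetically weighted dissimilarity: each branch contributes its
#' length times the absolute difference in the relative read mass of its
#' descendant taxa, `sum_b len(b) * |A_b - B_b|`. The normalized variant
#' (default) divides by `sum_b len(b) * (A_b + B_b)`, bounding the distance
#' in \[0, 1\].
#'
#' @param x Count matrix (taxa x samples); converted to proportions per sample.
#' @param tree Rooted `phylo` tree whose tip labels cover all row names of `x`.
#'   Extra tips are pruned.
#' @param normalized Use the normalized variant? Default `TRUE`.
#' @return A [stats::dist] over samples with attribute
#'   `metric = "weighted_unifrac"`.
#' @export
weighted_unifrac <- function(x, tree, normalized = TRUE) {
  x <- as_matrix_checked(x, "count table")
  missing <- setdiff(rownames(x), tree$tip.label)
  if (length(missing) > 0)
    stopf("taxa absent from the tree: %s", paste(missing, collapse = ", "))
  extra <- setdiff(tree$tip.label, rownames(x))
  if (length(extra) > 0) tree <- ape::keep.tip(tree, rownames(x))
  p <- to_relative_abundance(x)

  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  n <- ncol(p)
  mass <- matrix(0, ntip + nnode, n)
  mass[seq_len(ntip), ] <- p[tree$tip.label, , drop = FALSE]
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
    mass[par, ] <- mass[par, ] + mass[chd, ]
  }
  branch_mass <- mass[tree$edge[, 2], , drop = FALSE]  # per-edge descendant mass
  len <- tree$edge.length

  d <- matrix(0, n, n, dimnames = list(colnames(p), colnames(p)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- sum(len * abs(branch_mass[, i] - branch_mass[, j]))
    if (normalized) {
      den <- sum(len * (branch_mass[, i] + branch_mass[, j]))
      num <- if (den > 0) num / den else 0
    }
    d[i, j] <- d[j, i] <- num
  }
  d <- stats::as.dist(d)
  attr(d, "metric") <- "weighted_unifrac"
  d
}

#' Non-metric multidimensional scaling (NMDS)
#'
#' Kruskal's NMDS minimizing stress-1 through monotone regression of the
#' configuration distances on the observed dissimilarity ranks
#' (\pkg{vegan}'s `monoMDS` engine), restarted from random configurations;
#' the lowest-stress solution is returned.
#'
#' @param d A [stats::dist] of sample dissimilarities.
#' @param k Embedding dimension (default 2).
#' @param n_restarts Number of random restarts beyond the metric-scaling
#'   start (default 20).
#' @param seed Optional seed for the random restarts.
#' @return An `nmds_result`: list with `points` (samples x k), `stress`
#'   (Kruskal stress-1, in \[0, 1\]), `converged` and `n_restarts`.
#' @export
nmds <- function(d, k = 2, n_restarts = 20, seed = NULL) {
  n <- attr(d, "Size")
  if (k >= n) stopf("k must be smaller than the number of samples (%d)", n)
  if (k < 2) stopf("k must be at least 2")
  with_seed_or_not(seed, {
    best <- vegan::monoMDS(d, k = k, model = "global")
    for (r in seq_len(n_restarts)) {
      y0 <- matrix(stats::rnorm(n * k), n, k)
      fit <- vegan::monoMDS(d, y = y0, k = k, model = "global")
      if (fit$stress < best$stress) best <- fit
    }
    structure(list(points = best$points,
                   stress = best$stress,
                   converged = best$icause != 1L,  # 1 = iteration cap hit
                   n_restarts = n_restarts, k = k),
              class = "nmds_result")
  })
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS (k = %d): stress = %.4f (%s; %d restarts)\n", x$k, x$stress,
              if (x$stress < 0.2) "interpretable, < 0.2" else ">= 0.2", x$n_restarts))
  invisible(x)
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance (Anderson's pseudo-F
#' partition of the squared inter-point distances), with the permutation
#' p-value `(1 + #(F_perm >= F_obs)) / (1 + n_perm)` from free permutation
#' of the group labels. Backed by [vegan::adonis2()].
#'
#' @param d A [stats::dist] over samples.
#' @param groups Sample-to-group map (named vector or aligned with the
#'   `dist` labels); at least two groups.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed.
#' @return A `permanova_result` data frame with rows for the group term,
#'   residual and total: `df`, `SumsOfSqs`, `MeanSqs`, `F_model`, `R2`,
#'   `p_value`, plus attribute `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  labs <- attr(d, "Labels") %||% as.character(seq_len(attr(d, "Size")))
  g <- align_groups(groups, labs)
  if (nlevels(g) < 2) stopf("PERMANOVA needs at least two groups")
  df <- data.frame(group = g)
  fit <- with_seed_or_not(seed,
    vegan::adonis2(d ~ group, data = df, permutations = n_perm, by = "terms"))
  ms <- fit$SumOfSqs / fit$Df
  out <- data.frame(term = c("group", "residual", "total"),
                    df = fit$Df,
                    SumsOfSqs = fit$SumOfSqs,
                    MeanSqs = c(ms[1], ms[2], NA),
                    F_model = c(fit$F[1], NA, NA),
                    R2 = fit$R2,
                    p_value = c(fit$`Pr(>F)`[1], NA, NA),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_perm") <- n_perm
  class(out) <- c("permanova_result", "data.frame")
  out
}

#' Pairwise PERMANOVA between all group pairs
#'
#' @inheritParams permanova
#' @return Data frame, one row per group pair, with the group-term and
#'   residual df, sums of squares, mean squares, pseudo-F, R2 and p.
#' @export
pairwise_permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  labs <- attr(d, "Labels")
  g <- align_groups(groups, labs)
  m <- as.matrix(d)
  pairs <- utils::combn(levels(g), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    keep <- g %in% pairs[, i]
    sub <- stats::as.dist(m[keep, keep])
    fit <- permanova(sub, droplevels(g[keep]),
                     n_perm = n_perm,
                     seed = if (is.null(seed)) NULL else seed + i)
    data.frame(comparison = paste(pairs[, i], collapse = "-"),
               df = fit$df[1], df_residual = fit$df[2],
               SumsOfSqs = fit$SumsOfSqs[1], SumsOfSqs_residual = fit$SumsOfSqs[2],
               MeanSqs = fit$MeanSqs[1], MeanSqs_residual = fit$MeanSqs[2],
               F_model = fit$F_model[1], R2 = fit$R2[1],
               R2_residual = fit$R2[2], p_value = fit$p_value[1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Kruskal-Wallis test with compact letter display
#'
#' Overall Kruskal-Wallis rank-sum test (midranks, tie-corrected variance)
#' followed by pairwise Kruskal-Wallis tests; groups that do not differ at
#' `alpha` share a letter (Piepho insert-and-absorb display).
#'
#' @param values Numeric vector of a per-sample index.
#' @param groups Group labels aligned with `values` (or named by sample).
#' @param alpha Significance level for the letter display (default 0.05).
#' @param p_adjust Multiplicity adjustment for the pairwise p-values
#'   (a [stats::p.adjust] method; default `"none"`).
#' @return List with `H` (tie-corrected statistic), `df`, `p_value`,
#'   `pairwise_p` (symmetric matrix) and `letters` (named by group,
#'   ordered by decreasing mean rank).
#' @export
kruskal_wallis_letters <- function(values, groups, alpha = 0.05, p_adjust = "none") {
  g <- factor(as.character(groups), levels = unique(as.character(groups)))
  if (nlevels(g) < 2) stopf("need at least two groups")
  ok <- is.finite(values)
  values <- values[ok]; g <- droplevels(g[ok])
  if (length(unique(values)) == 1) {
    letters_out <- stats::setNames(rep("a", nlevels(g)), levels(g))
    pw <- matrix(1, nlevels(g), nlevels(g), dimnames = list(levels(g), levels(g)))
    return(list(H = 0, df = nlevels(g) - 1, p_value = 1,
                pairwise_p = pw, letters = letters_out))
  }
  kw <- stats::kruskal.test(values, g)
  lv <- levels(g)
  pw <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  diag(pw) <- 1
  for (i in seq_along(lv)[-length(lv)]) for (j in (i + 1):length(lv)) {
    keep <- g %in% lv[c(i, j)]
    p <- if (length(unique(values[keep])) == 1) 1 else
      stats::kruskal.test(values[keep], droplevels(g[keep]))$p.value
    pw[i, j] <- pw[j, i] <- p
  }
  adj <- pw
  adj[upper.tri(adj)] <- stats::p.adjust(pw[upper.tri(pw)], method = p_adjust)
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  mean_rank <- tapply(rank(values), g, mean)
  ord <- order(-mean_rank)
  letters_out <- cld_insert_absorb(adj[ord, ord, drop = FALSE], alpha)[lv]
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value, pairwise_p = adj, letters = letters_out)
}

# Piepho (2004) insert-and-absorb compact letter display from a symmetric
# p-value matrix; rows assumed ordered (e.g. by mean rank).
cld_insert_absorb <- function(p, alpha) {
  k <- nrow(p)
  cols <- list(rep(TRUE, k))  # letter columns: logical membership vectors
  sig <- which(p < alpha & upper.tri(p), arr.ind = TRUE)
  if (nrow(sig) > 0) for (s in seq_len(nrow(sig))) {
    i <- sig[s, 1]; j <- sig[s, 2]
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        a <- col; a[i] <- FALSE
        b <- col; b[j] <- FALSE
        cols[[ci]] <- a
        cols[[length(cols) + 1]] <- b
      }
    }
    # absorb columns that are subsets of another
    drop <- rep(FALSE, length(cols))
    for (ci in seq_along(cols)) for (cj in seq_along(cols)) {
      if (ci != cj && !drop[cj] && !drop[ci] &&
          all(cols[[ci]] | !cols[[cj]]) && !identical(cols[[ci]], cols[[cj]]))
        drop[cj] <- TRUE
      if (ci < cj && identical(cols[[ci]], cols[[cj]])) drop[cj] <- TRUE
    }
    cols <- cols[!drop]
  }
  lab <- vapply(seq_len(k), function(i)
    paste(letters[which(vapply(cols, function(c) c[i], logical(1)))], collapse = ""),
    character(1))
  stats::setNames(lab, rownames(p))
}

#' LDA effect-size biomarker screen (LEfSe-style)
#'
#' Two-stage screen for taxa that discriminate groups: (1) per-taxon
#' Kruskal-Wallis test at `alpha` on relative abundances scaled to 1e6 per
#' sample; (2) bootstrap rounds of a linear discriminant analysis on the
#' surviving taxa, combining the raw between-class mean difference with the
#' LDA-projected difference into an effect size reported on a log10 scale.
#' Taxa with a score at or above `lda_threshold` are flagged with the group
#' in which they are enriched. Scores follow the LEfSe convention but exact
#' equality with the Galaxy implementation is not promised.
#'
#' @param x Count matrix (taxa x samples).
#' @param groups Sample-to-group map; every group needs >= 2 samples.
#' @param lda_threshold Minimum log10 score to flag (default 4).
#' @param alpha Kruskal-Wallis screen level (default 0.05).
#' @param n_boot Bootstrap LDA rounds averaged (default 30).
#' @param seed Optional seed.
#' @return Data frame per screened taxon: `taxon`, `kw_p_value`,
#'   `enriched_group`, `lda_score`, `passes_threshold`.
#' @export
lda_effect_size <- function(x, groups, lda_threshold = 4, alpha = 0.05,
                            n_boot = 30, seed = NULL) {
  g <- align_groups(groups, colnames(x))
  if (any(table(g) < 2)) stopf("every group needs at least two samples")
  # canonicalize sample and group order so the bootstrap draws (and hence
  # the flagged set) do not depend on input column order
  ord <- order(colnames(x))
  x <- x[, ord, drop = FALSE]
  g <- factor(as.character(g)[ord], levels = sort(unique(as.character(g))))
  ab <- to_relative_abundance(x) * 1e6
  kw_p <- apply(ab, 1, function(v)
    if (length(unique(v)) == 1) 1 else stats::kruskal.test(v, g)$p.value)
  res <- data.frame(taxon = rownames(ab), kw_p_value = kw_p,
                    enriched_group = NA_character_, lda_score = NA_real_,
                    passes_threshold = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  keep <- which(kw_p < alpha)
  if (length(keep) == 0) return(res)

  feats <- t(ab[keep, , drop = FALSE])  # samples x surviving taxa
  class_means <- apply(feats, 2, function(v) tapply(v, g, mean))
  if (is.null(dim(class_means))) class_means <- matrix(class_means, nrow = nlevels(g),
    dimnames = list(levels(g), colnames(feats)))
  gm <- apply(class_means, 2, function(m) max(m) - min(m))  # max pairwise raw diff
  enriched <- levels(g)[apply(class_means, 2, which.max)]

  eff <- with_seed_or_not(seed, {
    acc <- numeric(ncol(feats)); nok <- 0
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(split(seq_along(g), g), function(i)
        sample(i, max(2, ceiling(length(i) * 2 / 3)))))
      xb <- feats[idx, , drop = FALSE]
      xb <- xb + matrix(stats::rnorm(length(xb), sd = 1e-3 * max(1, stats::sd(xb))),
                        nrow(xb), ncol(xb))
      fit <- tryCatch(suppressWarnings(MASS::lda(xb, grouping = droplevels(g[idx]))),
                      error = function(e) NULL)
      if (is.null(fit)) next
      w <- fit$scaling[, 1]
      w_unit <- w / sqrt(sum(w^2))
      ld <- drop(xb %*% w_unit)
      ld_means <- tapply(ld, droplevels(g[idx]), mean)
      effect_size <- max(ld_means) - min(ld_means)
      acc <- acc + (gm + abs(w_unit) * effect_size) / 2
      nok <- nok + 1
    }
    if (nok == 0) gm else acc / nok
  })
  score <- log10(1 + pmax(eff, 0))
  res$enriched_group[keep] <- enriched
  res$lda_score[keep] <- score
  res$passes_threshold[keep] <- score >= lda_threshold & kw_p[keep] < alpha
  res
}

#' Per-sample rarefaction curves
#'
#' Mean observed taxon richness (or Shannon index) over repeated random
#' subsamples at each depth, used to judge whether per-sample sequencing
#' depth saturates the diet inventory.
#'
#' @param x Count matrix (taxa x samples).
#' @param depths Increasing vector of subsampling depths; default 10 steps
#'   up to the smallest sample total.
#' @param metric `"observed_taxa"` or `"shannon"`.
#' @param reps Subsamples averaged per depth (default 10).
#' @param seed Optional seed.
#' @return Data frame: `sample_id`, `depth`, `value`.
#' @export
rarefaction_curve <- function(x, depths = NULL, metric = c("observed_taxa", "shannon"),
                              reps = 10, seed = NULL) {
  metric <- match.arg(metric)
  x <- as_matrix_checked(x, "count table")
  depths <- depths %||% unique(pmax(1, round(seq(1, min(colSums(x)), length.out = 10))))
  if (any(depths > min(colSums(x))))
    stopf("depths exceed the smallest sample total (%d)", min(colSums(x)))
  f <- if (metric == "observed_taxa") function(v) sum(v > 0) else
    function(v) vegan::diversity(v, index = "shannon")
  with_seed_or_not(seed, {
    grid <- expand.grid(sample_id = colnames(x), depth = depths,
                        stringsAsFactors = FALSE)
    grid$value <- mapply(function(s, dp) {
      mean(replicate(reps, f(drop(suppressWarnings(vegan::rrarefy(x[, s], dp))))))
    }, grid$sample_id, grid$depth)
    grid[order(grid$sample_id, grid$depth), ]
  })
}

#' Species accumulation over samples (random orderings)
#'
#' Distribution of the cumulative taxon richness of the first `m` samples
#' over random sample orderings (the boxplot behind sample-size adequacy
#' judgments). Backed by [vegan::specaccum()] with `method = "random"`.
#'
#' @param x Count matrix (taxa x samples).
#' @param n_orders Number of random orderings (default 100).
#' @param seed Optional seed.
#' @return List with `sites` (1..n), `richness_mean`, `richness_sd` and the
#'   raw `perm` matrix (sites x orderings).
#' @export
accumulation_curve <- function(x, n_orders = 100, seed = NULL) {
  x <- as_matrix_checked(x, "count table")
  if (ncol(x) < 2) stopf("need at least two samples")
  acc <- with_seed_or_not(seed,
    vegan::specaccum(t(x), method = "random", permutations = n_orders))
  list(sites = acc$sites, richness_mean = acc$richness,
       richness_sd = acc$sd, perm = acc$perm)
}
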