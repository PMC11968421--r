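test_that("Bray-Curtis matches its closed form and bounds", {
  m <- tiny_counts(matrix(c(1L, 0L, 3L, 2L, 2L, 2L), 3, 2))
  expect_equal(as.vector(bray_curtis(m)), 4 / 10)
  same <- tiny_counts(cbind(c(1L, 2L), c(1L, 2L)))
  expect_equal(as.vector(bray_curtis(same)), 0)
  disj <- tiny_counts(cbind(c(5L, 0L), c(0L, 7L)))
  expect_equal(as.vector(bray_curtis(disj)), 1)
  set.seed(1)
  r <- tiny_counts(matrix(rpois(30, 4) + 1L, 5, 6))
  d <- bray_curtis(r)
  expect_true(all(d >= 0 & d <= 1))
})

test_that("weighted UniFrac equals naive branch enumeration and its limits", {
  # identical compositions: zero
  m <- tiny_counts(cbind(c(3L, 1L), c(6L, 2L)), taxa = c("A", "B"))
  tr <- star_tree(c("A", "B"))
  expect_equal(as.vector(weighted_unifrac(m, tr)), 0, tolerance = 1e-12)

  # two-leaf star, unit branches, disjoint mass: normalized distance 1
  m2 <- tiny_counts(cbind(c(5L, 0L), c(0L, 5L)), taxa = c("A", "B"))
  expect_equal(as.vector(weighted_unifrac(m2, tr)), 1)

  # star tree with unit branches: normalized variant == half L1 on
  # proportions (the denominator is the constant 2), raw variant == full L1
  set.seed(7)
  taxa <- sprintf("L%d", 1:6)
  m3 <- tiny_counts(matrix(rpois(18, 8) + 1L, 6, 3), taxa = taxa)
  p <- sweep(m3, 2, colSums(m3), "/")
  L1 <- as.vector(dist(t(p), method = "manhattan"))
  expect_equal(as.vector(weighted_unifrac(m3, star_tree(taxa), normalized = TRUE)),
               L1 / 2, tolerance = 1e-10)
  expect_equal(as.vector(weighted_unifrac(m3, star_tree(taxa), normalized = FALSE)),
               L1, tolerance = 1e-10)

  # random 5-leaf trees against the enumeration oracle
  for (i in 1:5) {
    set.seed(100 + i)
    tr5 <- ape::rtree(5, br = stats::rexp)
    m5 <- tiny_counts(matrix(rpois(15, 10) + 1L, 5, 3), taxa = tr5$tip.label)
    for (norm in c(TRUE, FALSE)) {
      expect_equal(as.vector(weighted_unifrac(m5, tr5, normalized = norm)),
                   as.vector(oracle_weighted_unifrac(m5, tr5, normalized = norm)),
                   tolerance = 1e-10)
    }
  }

  expect_error(weighted_unifrac(tiny_counts(cbind(c(1L, 1L)), taxa = c("A", "Z")), tr),
               "Z")
})

test_that("weighted UniFrac agrees with the phyloseq reference implementation", {
  set.seed(21)
  tr <- ape::rtree(8, br = stats::rexp)
  m <- tiny_counts(matrix(rpois(40, 12) + 1L, 8, 5), taxa = tr$tip.label)
  mine <- weighted_unifrac(m, tr, normalized = TRUE)
  ps <- phyloseq::phyloseq(phyloseq::otu_table(m, taxa_are_rows = TRUE),
                           phyloseq::phy_tree(tr))
  ref <- phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE)
  expect_equal(as.vector(mine), as.vector(ref), tolerance = 1e-10)
})

test_that("NMDS recovers embeddable configurations and stress shrinks with k", {
  set.seed(5)
  pts <- matrix(rnorm(20), 10, 2)
  fit <- nmds(dist(pts), k = 2, n_restarts = 10, seed = 1)
  expect_lt(fit$stress, 1e-3)

  tri <- dist(rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)))
  expect_lt(nmds(tri, k = 2, n_restarts = 5, seed = 2)$stress, 1e-4)

  set.seed(6)
  d <- dist(matrix(rnorm(8 * 6), 8, 6))
  s2 <- nmds(d, k = 2, n_restarts = 10, seed = 3)$stress
  s3 <- nmds(d, k = 3, n_restarts = 10, seed = 3)$stress
  expect_lte(s3, s2 + 1e-8)

  # re-embedding the fitted configuration cannot increase stress
  fit2 <- nmds(d, k = 2, n_restarts = 10, seed = 4)
  refit <- nmds(dist(fit2$points), k = 2, n_restarts = 10, seed = 4)
  expect_lte(refit$stress, fit2$stress + 1e-6)

  expect_error(nmds(tri, k = 3), "smaller")
})

test_that("PERMANOVA partitions variance and matches exact enumeration at small n", {
  # zero within-group, positive between-group distance: R2 = 1
  pts <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  d <- dist(pts)
  attr(d, "Labels") <- sprintf("u%d", 1:4)
  g <- setNames(c("a", "a", "b", "b"), attr(d, "Labels"))
  fit <- permanova(d, g, n_perm = 99, seed = 1)
  expect_equal(fit$R2[1], 1, tolerance = 1e-9)
  expect_equal(fit$R2[1] + fit$R2[2], 1, tolerance = 1e-9)

  # exact enumeration oracle, n = 6
  set.seed(3)
  pts6 <- rbind(matrix(rnorm(6), 3), matrix(rnorm(6, 2), 3))
  d6 <- dist(pts6)
  attr(d6, "Labels") <- sprintf("u%d", 1:6)
  g6 <- setNames(rep(c("a", "b"), each = 3), attr(d6, "Labels"))
  fit6 <- permanova(d6, g6, n_perm = 9999, seed = 2)
  expect_equal(fit6$p_value[1],
               oracle_permanova_p(d6, factor(unname(g6))), tolerance = 1e-12)
  expect_equal(fit6$F_model[1], oracle_pseudo_F(d6, factor(unname(g6))),
               tolerance = 1e-9)
  expect_error(permanova(d6, setNames(rep("a", 6), attr(d6, "Labels"))),
               "two groups")
})

test_that("PERMANOVA type-I error is nominal under an exchangeable null", {
  n_sim <- 500
  rej <- vapply(seq_len(n_sim), function(i) {
    sc <- two_group_effect_scenario(0, n_per_group = 6, n_taxa = 12,
                                    depth = 500, seed = 5000 + i)
    d <- bray_curtis(sc$counts)
    permanova(d, sc$groups, n_perm = 99, seed = 100000 + i)$p_value[1] <= 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("Kruskal-Wallis letters separate disjoint groups and share on ties", {
  v <- c(1, 2, 3, 4, 5, 11, 12, 13, 14, 15)
  g <- rep(c("lo", "hi"), each = 5)
  kw <- kruskal_wallis_letters(v, g)
  expect_true(kw$letters["lo"] != kw$letters["hi"])

  # identical values: single shared letter, p = 1
  kw0 <- kruskal_wallis_letters(rep(2, 8), rep(c("a", "b"), 4))
  expect_equal(kw0$p_value, 1)
  expect_equal(unname(kw0$letters), c("a", "a"))

  # hand-computed H for (1,2,3) vs (4,5,6), no ties
  kw1 <- kruskal_wallis_letters(1:6, rep(c("a", "b"), each = 3))
  expect_equal(kw1$H, 3.857143, tolerance = 1e-6)

  # three groups, middle one overlapping both: letters must cover all
  # non-significant pairs
  set.seed(8)
  v3 <- c(rnorm(6, 0), rnorm(6, 1.5), rnorm(6, 10))
  g3 <- rep(c("a", "b", "c"), each = 6)
  kw3 <- kruskal_wallis_letters(v3, g3)
  for (i in c("a", "b", "c")) for (j in c("a", "b", "c")) {
    if (i < j) {
      share <- any(strsplit(kw3$letters[i], "")[[1]] %in%
                   strsplit(kw3$letters[j], "")[[1]])
      expect_equal(share, kw3$pairwise_p[i, j] >= 0.05)
    }
  }
})

test_that("LDA effect size flags separated taxa, spares identical ones, ignores order", {
  sc <- two_group_effect_scenario(3, n_per_group = 10, n_taxa = 20,
                                  n_affected = 3, seed = 42)
  res <- lda_effect_size(sc$counts, sc$groups, seed = 1)
  flagged <- res$taxon[res$passes_threshold]
  expect_true(all(sc$truth %in% flagged))
  expect_true(all(res$lda_score[res$passes_threshold] >= 4))

  # a taxon with an identical distribution across groups is never flagged
  m <- sc$counts
  m["OTU020", ] <- 50L
  res2 <- lda_effect_size(m, sc$groups, seed = 1)
  expect_false(res2$passes_threshold[res2$taxon == "OTU020"])

  # sample order invariance of the flagged set
  perm <- sample(ncol(sc$counts))
  res3 <- lda_effect_size(sc$counts[, perm], sc$groups[perm], seed = 1)
  expect_setequal(res3$taxon[res3$passes_threshold], flagged)
})

test_that("rarefaction curves saturate at richness and grow with depth", {
  m <- tiny_counts(matrix(c(10L, 5L, 0L, 3L, 2L, 1L), 3, 2))
  rc <- rarefaction_curve(m, depths = c(1, 6), reps = 5, seed = 1)
  expect_equal(rc$value[rc$depth == 1], c(1, 1))
  full <- rarefaction_curve(m, depths = min(colSums(m)), reps = 3, seed = 2)
  expect_equal(full$value[full$sample_id == "s2"], 3)  # its full richness

  set.seed(4)
  r <- tiny_counts(matrix(rpois(40, 3), 10, 4) + 0L)
  r[1, ] <- r[1, ] + 50L  # ensure positive totals
  rc2 <- rarefaction_curve(r, depths = c(5, 25), reps = 20, seed = 3)
  by_s <- split(rc2$value, rc2$sample_id)
  for (v in by_s) expect_lte(v[1], v[2] + 0.25)  # monotone within MC error
})

test_that("accumulation curves match exact enumeration for n = 4 and cap at total richness", {
  set.seed(9)
  m <- tiny_counts(matrix(rbinom(24, 1, 0.5) * rpois(24, 5), 6, 4))
  m[1, ] <- m[1, ] + 1L
  ac <- accumulation_curve(m, n_orders = 600, seed = 2)
  total_rich <- sum(rowSums(m) > 0)
  expect_true(all(ac$perm[4, ] == total_rich))

  # exact expected curve over all 24 orderings
  rich_union <- function(cols) sum(rowSums(m[, cols, drop = FALSE]) > 0)
  exact <- rowMeans(vapply(all_perms(1:4), function(p)
    vapply(1:4, function(k) rich_union(p[1:k]), numeric(1)), numeric(4)))
  expect_equal(ac$richness_mean, exact, tolerance = 0.2)

  dup <- tiny_counts(cbind(c(2L, 1L), c(2L, 1L), c(2L, 1L)))
  ad <- accumulation_curve(dup, n_orders = 10, seed = 1)
  expect_equal(ad$richness_mean, rep(2, 3))
})
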