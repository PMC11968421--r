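# Independent oracles and tiny fixture builders used across the suite.
# Everything here is deliberately naive (enumeration / direct formulas),
# kept separate from the package's own code paths.

# a small count matrix with dimnames
tiny_counts <- function(m, taxa = NULL, samples = NULL) {
  m <- as.matrix(m)
  rownames(m) <- taxa %||% sprintf("t%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all permutations of a vector (n! lists) -- enumeration oracle backbone
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_perms(v[-i]), function(p) c(v[i], p))))
}

# Anderson pseudo-F computed directly from squared distances
oracle_pseudo_F <- function(d, g) {
  m <- as.matrix(d)^2
  n <- length(g)
  SST <- sum(m[upper.tri(m)]) / n
  SSW <- sum(vapply(split(seq_len(n), g), function(i) {
    s <- m[i, i, drop = FALSE]
    sum(s[upper.tri(s)]) / length(i)
  }, numeric(1)))
  a <- nlevels(g)
  ((SST - SSW) / (a - 1)) / (SSW / (n - a))
}

# exact PERMANOVA p by full enumeration of unit relabelings (identity included)
oracle_permanova_p <- function(d, g) {
  F0 <- oracle_pseudo_F(d, g)
  Fs <- vapply(all_perms(seq_along(g)), function(p)
    oracle_pseudo_F(stats::as.dist(as.matrix(d)[p, p]), g), numeric(1))
  mean(Fs >= F0 - 1e-12)
}

# exact Mantel p by full enumeration (identity included)
oracle_mantel_p <- function(d1, d2, method = "pearson") {
  r0 <- stats::cor(as.vector(d1), as.vector(d2), method = method)
  rs <- vapply(all_perms(seq_len(attr(d1, "Size"))), function(p)
    stats::cor(as.vector(stats::as.dist(as.matrix(d1)[p, p])), as.vector(d2),
               method = method), numeric(1))
  mean(rs >= r0 - 1e-12)
}

# weighted UniFrac by naive per-branch enumeration of descendant tips
oracle_weighted_unifrac <- function(x, tree, normalized = TRUE) {
  p <- sweep(x, 2, colSums(x), "/")
  ntip <- length(tree$tip.label)
  tip_descendants <- function(node) {
    if (node <= ntip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tip_descendants))
  }
  edge_mass <- t(vapply(seq_len(nrow(tree$edge)), function(e) {
    tips <- tree$tip.label[tip_descendants(tree$edge[e, 2])]
    colSums(p[tips, , drop = FALSE])
  }, numeric(ncol(p))))
  len <- tree$edge.length
  n <- ncol(p)
  out <- matrix(0, n, n, dimnames = list(colnames(p), colnames(p)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- sum(len * abs(edge_mass[, i] - edge_mass[, j]))
    if (normalized) num <- num / sum(len * (edge_mass[, i] + edge_mass[, j]))
    out[i, j] <- out[j, i] <- num
  }
  stats::as.dist(out)
}

# star tree with unit branch lengths over the given tip labels
star_tree <- function(tips) {
  ape::read.tree(text = paste0("(", paste0(tips, ":1", collapse = ","), ");"))
}

# minimal taxonomy frame for a count matrix
tiny_taxonomy <- function(taxa, phylum = NULL, flag = NULL) {
  data.frame(taxon_id = taxa, kingdom = "Eukaryota",
             phylum = phylum %||% rep("Chlorophyta", length(taxa)),
             class = "", order = "", family = "", genus = "", species = "",
             identity_flag = flag %||% rep("annotated", length(taxa)),
             stringsAsFactors = FALSE)
}

# report-table rounding (half-up at 2 decimals)
round_2 <- function(x) dietbarcode:::round_half_up(x, 2)
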