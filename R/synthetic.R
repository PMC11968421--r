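#' Configuration for the synthetic stomach-content generator
#'
#' Builds the design object consumed by [simulate_counts()]. The two
#' ready-made scenarios mirror a typical multi-site stomach-content survey:
#' `"populations"` has five sites — three reservoirs and two rivers — with
#' 3-5 stomachs each (23 in total); `"seasons"` has four seasons of 15
#' stomachs from one reservoir. Read depths are log-normal around 1e5
#' reads per stomach and compositions are Dirichlet-multinomial around
#' group base compositions, optionally shifted on the logit scale by
#' environmental covariates.
#'
#' @param scenario `"populations"` or `"seasons"`.
#' @param n_taxa Number of OTUs (excluding the pooled "Unidentified" taxon).
#' @param theta Dirichlet concentration of per-stomach compositions around
#'   the group mean (default 20; larger = less overdispersion).
#' @param depth_meanlog,depth_sdlog Log-normal read-depth parameters
#'   (defaults `log(1e5)` and 0.15).
#' @param unidentified_fraction Expected read share of the "Unidentified"
#'   taxon (default 0.05); 0 omits the taxon entirely.
#' @param env_effect Scale of the log-linear environmental effect on the
#'   group compositions (default 1; 0 for a pure exchangeable null). Group
#'   compositions share one base composition and differ through this effect
#'   plus `group_divergence`, so the driver behind the differences is known.
#' @param n_env_responsive Number of taxa whose logits respond to the first
#'   environmental variable (default 4).
#' @param group_divergence SD of the per-group, per-taxon log-scale
#'   deviation not explained by the environment (default 0.3), emulating
#'   unmeasured local prey-availability differences.
#' @param seed Optional seed stored in the config and used by
#'   [simulate_counts()].
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(scenario = c("populations", "seasons"),
                             n_taxa = 24, theta = 20,
                             depth_meanlog = log(1e5), depth_sdlog = 0.15,
                             unidentified_fraction = 0.05,
                             env_effect = 1, n_env_responsive = 4,
                             group_divergence = 0.3, seed = NULL) {
  scenario <- match.arg(scenario)
  if (theta <= 0) stopf("theta must be positive")
  if (unidentified_fraction < 0 || unidentified_fraction >= 1)
    stopf("unidentified_fraction must be in [0, 1)")
  groups <- if (scenario == "populations") {
    data.frame(name = c("QDH", "SKSK", "XJ", "DJ", "NDJ"),
               n_samples = c(3L, 5L, 5L, 5L, 5L),
               latitude = c(29.6, 26.4, 24.1, 23.1, 19.7),
               longitude = c(119.0, 118.3, 108.7, 114.4, 110.3),
               stringsAsFactors = FALSE)
  } else {
    data.frame(name = c("Spring", "Summer", "Autumn", "Winter"),
               n_samples = rep(15L, 4),
               latitude = rep(26.4, 4), longitude = rep(118.3, 4),
               stringsAsFactors = FALSE)
  }
  structure(list(scenario = scenario, groups = groups, n_taxa = n_taxa,
                 theta = theta, depth_meanlog = depth_meanlog,
                 depth_sdlog = depth_sdlog,
                 unidentified_fraction = unidentified_fraction,
                 env_effect = env_effect, n_env_responsive = n_env_responsive,
                 group_divergence = group_divergence,
                 env_vars = c("TEMP", "DO", "pH", "COND", "TD", "PI", "AN", "TP", "TN"),
                 seed = seed),
            class = "synthetic_config")
}

#' Simulate a grouped stomach-content metabarcoding dataset
#'
#' Draws, per stomach, a composition from a Dirichlet around its group's
#' base composition (concentration `theta`), shifts group compositions on
#' the logit scale by a log-linear effect of the first (standardized)
#' environmental variable, then draws reads from a multinomial at a
#' log-normal depth. An "Unidentified" taxon receives the configured read
#' fraction. Taxonomy assigns OTUs to real phyla spanning the five food
#' categories; the phylogeny is a random bifurcating tree with exponential
#' branch lengths; metadata carries lengths, weights, sex, fullness grades
#' and jittered per-group GPS coordinates. Byte-identical under a fixed
#' seed.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `counts` (taxa x samples), `taxonomy`, `metadata`,
#'   `env` (per-group rows), `tree` and `truth` (the group base
#'   compositions actually used).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed_or_not(cfg$seed %||% NULL, simulate_counts_impl(cfg))
}

simulate_counts_impl <- function(cfg) {
  K <- cfg$n_taxa
  g <- cfg$groups
  taxa <- sprintf("OTU%03d", seq_len(K))
  phyla_pool <- names(default_food_category_map())
  phyla <- rep(phyla_pool, length.out = K)

  # per-group environment: TEMP tracks latitude, others around typical
  # freshwater monitoring values with group-level variation
  nG <- nrow(g)
  env <- data.frame(
    TEMP = 28 - 0.6 * (g$latitude - min(g$latitude)) + stats::rnorm(nG, 0, 1),
    DO   = stats::rnorm(nG, 8, 1),
    pH   = stats::rnorm(nG, 7.5, 0.3),
    COND = stats::rlnorm(nG, log(250), 0.3),
    TD   = stats::rlnorm(nG, log(20), 0.4),
    PI   = stats::rlnorm(nG, log(3), 0.3),
    AN   = stats::rlnorm(nG, log(0.3), 0.4),
    TP   = stats::rlnorm(nG, log(0.05), 0.4),
    TN   = stats::rlnorm(nG, log(1.5), 0.3),
    row.names = g$name)

  # one shared base composition; groups differ through the environmental
  # effect plus a mild unexplained log-scale divergence, so the driver
  # behind between-group differences is known by construction
  base <- rdirichlet1(rep(2, K))
  z1 <- as.numeric(scale(env$TEMP))
  if (nG < 2 || stats::sd(env$TEMP) == 0) z1 <- rep(0, nG)
  effect <- numeric(K)
  idx_resp <- seq_len(min(cfg$n_env_responsive, K))
  effect[idx_resp] <- cfg$env_effect * rep(c(1, -1), length.out = length(idx_resp))
  pi_g <- t(vapply(seq_len(nG), function(i) {
    eta <- log(base) + effect * z1[i] +
      stats::rnorm(K, 0, cfg$group_divergence %||% 0)
    exp(eta - max(eta)) / sum(exp(eta - max(eta)))
  }, numeric(K)))

  u <- cfg$unidentified_fraction
  all_taxa <- if (u > 0) c(taxa, "Unidentified") else taxa
  sample_ids <- unlist(lapply(seq_len(nG), function(i)
    sprintf("%s_%02d", g$name[i], seq_len(g$n_samples[i]))))
  group_of <- rep(g$name, g$n_samples)

  counts <- matrix(0L, length(all_taxa), length(sample_ids),
                   dimnames = list(all_taxa, sample_ids))
  for (s in seq_along(sample_ids)) {
    i <- match(group_of[s], g$name)
    p <- rdirichlet1(cfg$theta * pi_g[i, ])
    if (u > 0) p <- c((1 - u) * p, u)
    depth <- max(1L, round(stats::rlnorm(1, cfg$depth_meanlog, cfg$depth_sdlog)))
    counts[, s] <- stats::rmultinom(1, depth, p)[, 1]
  }

  taxonomy <- data.frame(
    taxon_id = all_taxa,
    kingdom = "Eukaryota",
    phylum = c(phyla, if (u > 0) "")[seq_along(all_taxa)],
    class = "", order = "", family = "", genus = "", species = "",
    identity_flag = c(rep("annotated", K), if (u > 0) "unidentified"),
    stringsAsFactors = FALSE)

  tree <- ape::rtree(length(all_taxa), tip.label = sample(all_taxa),
                     br = stats::rexp)

  sl <- stats::rlnorm(length(sample_ids), log(12), 0.2)
  metadata <- data.frame(
    sample_id = sample_ids,
    group = group_of,
    standard_length = round(sl, 1),
    body_weight = round(0.03 * sl^3 * stats::rlnorm(length(sl), 0, 0.1), 1),
    sex = sample(c("M", "F", "unknown"), length(sample_ids), TRUE, c(0.45, 0.45, 0.1)),
    fullness_grade = sample(4:5, length(sample_ids), TRUE),
    latitude = g$latitude[match(group_of, g$name)] + stats::rnorm(length(sample_ids), 0, 0.01),
    longitude = g$longitude[match(group_of, g$name)] + stats::rnorm(length(sample_ids), 0, 0.01),
    date = NA_character_,
    stringsAsFactors = FALSE)

  list(counts = counts, taxonomy = taxonomy, metadata = metadata,
       env = env, tree = tree,
       truth = list(base_composition = pi_g, taxa = taxa,
                    env_responsive = taxa[idx_resp]))
}

#' Two-group dataset with a known compositional effect
#'
#' Generates two groups whose compositions differ by a stated logit shift
#' on a known subset of taxa, with the truth labels attached — the standard
#' input for power and recovery benchmarks of PERMANOVA and the LDA
#' effect-size screen. `effect_size = 0` gives an exchangeable null with an
#' empty truth set.
#'
#' @param effect_size Logit shift applied to the affected taxa in group B
#'   (>= 0).
#' @param n_per_group Stomachs per group (default 15).
#' @param n_taxa Number of taxa (default 30).
#' @param n_affected Number of shifted taxa (default 5; 0 when
#'   `effect_size = 0`).
#' @param theta Dirichlet concentration (default 20).
#' @param depth Reads per stomach (default 20000).
#' @param seed Optional seed.
#' @return List with `counts`, `groups` (named vector) and `truth`
#'   (affected taxon ids; empty when `effect_size = 0`).
#' @export
two_group_effect_scenario <- function(effect_size, n_per_group = 15, n_taxa = 30,
                                      n_affected = 5, theta = 20, depth = 20000,
                                      seed = NULL) {
  if (effect_size < 0) stopf("effect_size must be >= 0")
  with_seed_or_not(seed, {
    taxa <- sprintf("OTU%03d", seq_len(n_taxa))
    base <- rdirichlet1(rep(2, n_taxa))
    affected <- if (effect_size > 0) seq_len(min(n_affected, n_taxa)) else integer(0)
    eta <- log(base)
    eta_b <- eta
    eta_b[affected] <- eta_b[affected] + effect_size
    pA <- exp(eta - max(eta)); pA <- pA / sum(pA)
    pB <- exp(eta_b - max(eta_b)); pB <- pB / sum(pB)
    ids <- c(sprintf("A_%02d", seq_len(n_per_group)),
             sprintf("B_%02d", seq_len(n_per_group)))
    counts <- sapply(seq_along(ids), function(s) {
      p <- rdirichlet1(theta * (if (s <= n_per_group) pA else pB))
      stats::rmultinom(1, depth, p)[, 1]
    })
    dimnames(counts) <- list(taxa, ids)
    list(counts = counts,
         groups = stats::setNames(rep(c("A", "B"), each = n_per_group), ids),
         truth = taxa[affected])
  })
}
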