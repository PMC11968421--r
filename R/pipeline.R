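#' Run the full stomach-content diet-analysis pipeline
#'
#' Orchestrates every stage from a single configuration: depth
#' homogenization, per-group FO/RRA diet profiles with category
#' aggregation and feeding-strategy labels, per-sample diversity indices
#' with Kruskal-Wallis letters, Schoener overlap, Bray-Curtis (and, given
#' a tree, weighted UniFrac) distances, NMDS, pairwise PERMANOVA, the LDA
#' effect-size screen, and — given an environmental table — VIF screening,
#' Spearman correlations, standardized regression, Hellinger/DCA/RDA and
#' Mantel tests against geographic distance. Stages whose inputs are
#' absent are skipped with a notice collected into the run manifest. All
#' numeric outputs are written as TSV plus a JSON manifest (inputs, seed,
#' parameters, package version); any stage failure aborts with the stage
#' name, retaining outputs already written.
#'
#' @param config Either a list or a path to a JSON file. Recognized
#'   entries: `counts`, `taxonomy`, `metadata`, `env`, `tree` (paths or
#'   in-memory objects), or `synthetic = list(...)` (arguments to
#'   [synthetic_config()]); `out_dir` (required); `seed`; optional
#'   thresholds `min_reads`, `fo_cut`, `rra_cut`, `lda_threshold`,
#'   `vif_threshold`, `overlap_threshold`, `rarefy_depth`, and permutation
#'   counts `n_perm_permanova` (999), `n_perm_rda` (5000),
#'   `n_perm_mantel` (10000).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- pipeline_defaults(config)
  if (is.null(cfg$out_dir)) stopf("config must name an out_dir")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  notices <- character(0)
  t0 <- Sys.time()
  say <- function(stage) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), stage))
  stage <- function(name, expr) {
    say(name)
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  out <- function(name) file.path(cfg$out_dir, name)
  wtsv <- function(df, name) {
    utils::write.table(df, out(name), sep = "\t", quote = FALSE, row.names = FALSE)
    name
  }
  files <- character(0)

  dat <- stage("load inputs", load_pipeline_inputs(cfg))
  counts <- dat$counts
  input_paths <- Filter(is.character, cfg[c("counts", "taxonomy", "metadata",
                                            "env", "tree")])
  if (!is.null(cfg$synthetic))
    input_paths <- list(synthetic = cfg$synthetic$scenario %||% "populations")
  input_md5 <- lapply(Filter(file.exists, unlist(input_paths)),
                      function(p) unname(tools::md5sum(p)))

  counts <- stage("host removal + rarefaction", {
    counts <- remove_host_taxa(counts, dat$taxonomy)
    rarefy_even_depth(counts, depth = cfg$rarefy_depth, seed = cfg$seed)
  })
  meta <- dat$metadata[dat$metadata$sample_id %in% colnames(counts), , drop = FALSE]
  groups <- stats::setNames(meta$group, meta$sample_id)

  prof <- stage("diet profiles (FO/RRA)", {
    p <- diet_profile(counts, groups, taxonomy = dat$taxonomy, rank = "phylum",
                      min_reads = cfg$min_reads)
    files <- c(files, wtsv(profile_as_table(p), "diet_profile_phylum.tsv"))
    p
  })
  catg <- stage("food-category aggregation", {
    ca <- category_rra(prof)
    files <- c(files, wtsv(data.frame(category = rownames(ca$rra), ca$rra,
                                      check.names = FALSE), "category_rra.tsv"))
    ca
  })
  strat <- stage("feeding strategy", {
    s <- data.frame(phylum = rep(rownames(prof$fo), ncol(prof$fo)),
                    group = rep(colnames(prof$fo), each = nrow(prof$fo)),
                    FO = as.vector(prof$fo), RRA = as.vector(prof$rra),
                    strategy = feeding_strategy(as.vector(prof$fo), as.vector(prof$rra),
                                                cfg$fo_cut, cfg$rra_cut),
                    stringsAsFactors = FALSE)
    files <- c(files, wtsv(s, "feeding_strategy.tsv"))
    s
  })
  divs <- stage("diversity indices + letters", {
    di <- diversity_indices(counts)
    summ <- diversity_group_summary(di, groups)
    kwl <- kruskal_wallis_letters(di$H, groups[di$sample_id])
    summ$H_letters <- kwl$letters[summ$group]
    files <- c(files, wtsv(di, "diversity_per_sample.tsv"),
               wtsv(summ, "diversity_group_summary.tsv"))
    list(per_sample = di, summary = summ, kw = kwl)
  })
  ovl <- stage("Schoener overlap", {
    o <- overlap_matrix(prof, threshold = cfg$overlap_threshold)
    files <- c(files, wtsv(data.frame(unit = rownames(o$alpha), o$alpha,
                                      check.names = FALSE), "overlap_matrix.tsv"))
    o
  })
  fullness <- if ("fullness_grade" %in% names(meta)) {
    stage("fullness summary", {
      fs <- fullness_summary(meta)
      files <- c(files, wtsv(fs, "fullness_summary.tsv"))
      fs
    })
  } else { notices <- c(notices, "no fullness_grade: fullness summary skipped"); NULL }

  bc <- stage("Bray-Curtis distance", bray_curtis(counts))
  files <- c(files, wtsv(dist_as_table(bc), "bray_curtis.tsv"))
  wuf <- if (!is.null(dat$tree)) {
    stage("weighted UniFrac", {
      d <- weighted_unifrac(counts, dat$tree)
      files <- c(files, wtsv(dist_as_table(d), "weighted_unifrac.tsv"))
      d
    })
  } else { notices <- c(notices, "no tree: weighted UniFrac skipped"); NULL }

  nm <- stage("NMDS", {
    fit <- nmds(wuf %||% bc, k = 2, seed = cfg$seed)
    files <- c(files, wtsv(data.frame(sample_id = rownames(fit$points), fit$points,
                                      stress = fit$stress), "nmds_coordinates.tsv"))
    fit
  })
  perma <- stage("pairwise PERMANOVA", {
    pp <- pairwise_permanova(bc, groups, n_perm = cfg$n_perm_permanova, seed = cfg$seed)
    files <- c(files, wtsv(pp, "permanova_pairwise.tsv"))
    pp
  })
  lefse <- stage("LDA effect size", {
    le <- lda_effect_size(counts, groups, lda_threshold = cfg$lda_threshold,
                          seed = cfg$seed)
    files <- c(files, wtsv(le, "lda_effect_size.tsv"))
    le
  })

  env_res <- NULL
  if (!is.null(dat$env)) {
    env_res <- stage("environmental drivers", {
      env <- dat$env[match(meta$group, rownames(dat$env)), , drop = FALSE]
      rownames(env) <- meta$sample_id
      vr <- vif_screen(env, threshold = cfg$vif_threshold)
      env_sel <- env[, vr$variable[vr$retained], drop = FALSE]
      rra_units <- t(relative_read_abundance(counts, groups))  # groups x taxa
      env_units <- dat$env[rownames(rra_units), , drop = FALSE]
      sp <- if (nrow(rra_units) >= 4) spearman_correlations(rra_units, env_units)
            else { notices <- c(notices, "fewer than 4 units: Spearman skipped"); NULL }
      hel <- hellinger_transform(counts)
      dca <- dca_gradient_length(hel)
      rda_res <- if (dca$recommendation == "CCA") {
        notices <- c(notices,
          sprintf("DCA gradient length %.2f: recommended CCA - not implemented", dca$lga))
        NULL
      } else {
        r <- rda_ordination(hel, env_sel, n_perm = cfg$n_perm_rda, seed = cfg$seed)
        files <- c(files, wtsv(r$envfit, "rda_envfit.tsv"))
        r
      }
      mant <- if (all(c("latitude", "longitude") %in% names(meta))) {
        gd <- geographic_distance(meta)
        m <- mantel_test(bc, gd, n_perm = cfg$n_perm_mantel, seed = cfg$seed)
        jsonlite::write_json(m[c("statistic", "r_squared", "p_value", "n_perm", "method")],
                             out("mantel.json"), auto_unbox = TRUE, digits = NA)
        m
      } else { notices <- c(notices, "no coordinates: Mantel skipped"); NULL }
      # group-level standardized regression of trophic diversity on the
      # retained drivers, when there are enough analysis units
      di_H <- diversity_indices(counts)$H
      h_by_group <- tapply(di_H, groups[colnames(counts)], mean)
      env_g <- dat$env[names(h_by_group), vr$variable[vr$retained], drop = FALSE]
      mlr <- if (length(h_by_group) > ncol(env_g) + 1) {
        m <- standardized_regression(as.numeric(h_by_group), env_g)
        files <- c(files, wtsv(m$coefficients, "diversity_regression.tsv"))
        m
      } else { notices <- c(notices,
          "too few units for the diversity regression: skipped"); NULL }
      # size/group GLM on per-sample diversity (gamma, log link)
      glm_h <- if ("standard_length" %in% names(meta) &&
                   all(di_H > 0) && nlevels(factor(meta$group)) >= 2) {
        gd <- data.frame(H = di_H, SL = meta$standard_length[
          match(colnames(counts), meta$sample_id)], group = meta$group[
          match(colnames(counts), meta$sample_id)])
        gf <- glm_fit(H ~ SL + group, gd, family = "gamma-log")
        files <- c(files, wtsv(gf$coefficients, "glm_diversity.tsv"))
        gf
      } else { notices <- c(notices, "GLM stage skipped (needs standard_length, positive H and >=2 groups)"); NULL }
      files <- c(files, wtsv(vr, "vif_report.tsv"))
      if (!is.null(sp))
        files <- c(files, wtsv(data.frame(taxon = rownames(sp$rho), sp$rho,
                                          check.names = FALSE), "spearman_rho.tsv"))
      list(vif = vr, spearman = sp, mlr = mlr, glm = glm_h,
           dca = dca, rda = rda_res, mantel = mant)
    })
  } else notices <- c(notices, "no environmental table: driver stage skipped")

  manifest <- list(
    package = "dietbarcode",
    version = as.character(utils::packageVersion("dietbarcode")),
    seed = cfg$seed,
    parameters = cfg[c("min_reads", "fo_cut", "rra_cut", "lda_threshold",
                       "vif_threshold", "overlap_threshold",
                       "n_perm_permanova", "n_perm_rda", "n_perm_mantel")],
    inputs = input_paths,
    input_md5 = input_md5,
    outputs = files,
    notices = notices,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(counts = counts, profile = prof, categories = catg,
                 strategy = strat, diversity = divs, overlap = ovl,
                 fullness = fullness, bray_curtis = bc, unifrac = wuf,
                 nmds = nm, permanova = perma, lefse = lefse,
                 env = env_res, manifest = manifest))
}

pipeline_defaults <- function(cfg) {
  defaults <- list(seed = 20220101L, min_reads = 1L, fo_cut = 50, rra_cut = 25,
                   lda_threshold = 4, vif_threshold = 10, overlap_threshold = 0.6,
                   rarefy_depth = NULL, n_perm_permanova = 999L,
                   n_perm_rda = 5000L, n_perm_mantel = 10000L)
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  cfg
}

load_pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$synthetic)) {
    sc <- do.call(synthetic_config, c(cfg$synthetic, list(seed = cfg$seed)))
    dat <- simulate_counts(sc)
    cfg$input_paths <- list(synthetic = sc$scenario)
    return(dat)
  }
  if (is.null(cfg$counts)) stopf("config needs either 'counts' inputs or a 'synthetic' block")
  get <- function(x, reader) if (is.character(x)) reader(x) else x
  paths <- Filter(is.character, cfg[c("counts", "taxonomy", "metadata", "env", "tree")])
  list(counts = get(cfg$counts, read_count_table),
       taxonomy = get(cfg$taxonomy, read_taxonomy),
       metadata = get(cfg$metadata, read_sample_metadata),
       env = if (is.null(cfg$env)) NULL else get(cfg$env, read_env_table),
       tree = if (is.null(cfg$tree)) NULL else get(cfg$tree, read_taxon_tree))
}

profile_as_table <- function(p) {
  out <- data.frame(phylum = rownames(p$rra), stringsAsFactors = FALSE)
  if (!is.null(p$categories)) out$category <- unname(p$categories[out$phylum])
  for (grp in p$groups) {
    out[[paste0(grp, "_FO")]] <- round_half_up(p$fo[, grp], 2)
    out[[paste0(grp, "_RRA")]] <- round_half_up(p$rra[, grp], 2)
  }
  out
}

dist_as_table <- function(d) {
  m <- as.matrix(d)
  data.frame(unit = rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Profile-mode diet analysis from a group-level FO/RRA table
#'
#' Runs the diet-metric stages that need only a published-style group-level
#' profile (no raw counts): food-category aggregation, across-group
#' category means, pairwise Schoener overlap and feeding-strategy labels.
#'
#' @param profile A `diet_profile` (e.g. [paper_fixture()] or
#'   [read_diet_profile_tsv()]) or a path to a profile TSV.
#' @param fo_cut,rra_cut Feeding-strategy quadrant cuts (percent).
#' @param overlap_threshold Schoener significance threshold (default 0.6).
#' @return List with `category_rra` (category x group), `category_means`,
#'   `overlap` (an `overlap_matrix`) and `strategy` (long data frame).
#' @export
profile_mode <- function(profile, fo_cut = 50, rra_cut = 25, overlap_threshold = 0.6) {
  if (is.character(profile)) profile <- read_diet_profile_tsv(profile)
  stopifnot(inherits(profile, "diet_profile"))
  ca <- category_rra(profile)
  strategy <- data.frame(
    taxon = rep(rownames(profile$fo), ncol(profile$fo)),
    group = rep(colnames(profile$fo), each = nrow(profile$fo)),
    FO = as.vector(profile$fo), RRA = as.vector(profile$rra),
    strategy = feeding_strategy(as.vector(profile$fo), as.vector(profile$rra),
                                fo_cut, rra_cut),
    stringsAsFactors = FALSE)
  list(category_rra = ca$rra,
       category_means = rowMeans(ca$rra),
       overlap = overlap_matrix(profile, threshold = overlap_threshold),
       strategy = strategy)
}
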