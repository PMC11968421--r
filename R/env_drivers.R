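#' Iterative variance-inflation-factor screen
#'
#' `VIF_k = 1 / (1 - R2_k)` from regressing variable k on all others;
#' the highest-VIF variable is removed (perfectly collinear ones first,
#' reported as `Inf`) and VIFs recomputed until all retained variables are
#' at or below `threshold`.
#'
#' @param env Data frame or matrix of numeric environmental variables
#'   (rows = units, columns = variables).
#' @param threshold Maximum tolerated VIF (default 10).
#' @return A `vif_report` data frame: `variable`, `vif` (final VIF for
#'   retained variables, VIF at removal otherwise), `retained`,
#'   `removal_order` (NA if retained).
#' @export
vif_screen <- function(env, threshold = 10) {
  X <- as_matrix_checked(as.matrix(env), "environmental table")
  if (ncol(X) < 2) stopf("need at least two variables")
  const <- apply(X, 2, function(v) stats::var(v) == 0)
  if (any(const)) stopf("constant variable(s): %s",
                        paste(colnames(X)[const], collapse = ", "))
  vars <- colnames(X)
  removed <- character(0)
  vif_at_removal <- numeric(0)
  active <- vars
  repeat {
    v <- vif_values(X[, active, drop = FALSE])
    worst <- which.max(v)
    if (length(active) <= 1 || v[worst] <= threshold) break
    removed <- c(removed, active[worst])
    vif_at_removal <- c(vif_at_removal, v[worst])
    active <- active[-worst]
  }
  final <- if (length(active) > 1) vif_values(X[, active, drop = FALSE])
           else stats::setNames(1, active)
  out <- data.frame(variable = vars,
                    vif = ifelse(vars %in% active, final[vars],
                                 vif_at_removal[match(vars, removed)]),
                    retained = vars %in% active,
                    removal_order = match(vars, removed),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("vif_report", "data.frame")
  out
}

vif_values <- function(X) {
  vapply(seq_len(ncol(X)), function(k) {
    # perfect fits are expected (that is what the screen detects); the
    # "essentially perfect fit" warning is noise here
    r2 <- suppressWarnings(summary(stats::lm(X[, k] ~ X[, -k, drop = FALSE]))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(colnames(X))
}

#' Spearman correlations between prey taxa and environmental variables
#'
#' Midrank Spearman's rho for every (taxon, variable) pair with two-sided
#' p-values (exact permutation null when there are no ties and n is small,
#' the t approximation otherwise), plus significance stars at 0.05/0.01.
#' Constant columns yield NA.
#'
#' @param prey Matrix of per-unit prey abundances (units x taxa), e.g. RRA.
#' @param env Data frame/matrix of environmental variables on the same units.
#' @return List of matrices `rho`, `p_value`, `stars` (taxa x variables).
#' @export
spearman_correlations <- function(prey, env) {
  prey <- as.matrix(prey); env <- as.matrix(env)
  if (nrow(prey) != nrow(env)) stopf("prey and env must share their units")
  if (nrow(prey) < 4) stopf("need at least 4 units")
  rho <- p <- matrix(NA_real_, ncol(prey), ncol(env),
                     dimnames = list(colnames(prey), colnames(env)))
  for (i in seq_len(ncol(prey))) for (j in seq_len(ncol(env))) {
    x <- prey[, i]; y <- env[, j]
    if (stats::var(x) == 0 || stats::var(y) == 0) next
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    rho[i, j] <- unname(ct$estimate); p[i, j] <- ct$p.value
  }
  stars <- ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
  list(rho = rho, p_value = p, stars = stars)
}

#' Multiple linear regression with standardized predictors
#'
#' Ordinary least squares of a (possibly transformed) response on z-scored
#' environmental predictors. When `transform = "auto"`, the response is
#' checked for normality (Shapiro-Wilk at 0.05) and, if it fails, the log
#' or inverse transform giving the higher Shapiro-Wilk p is applied; the
#' chosen transform is recorded.
#'
#' @param y Numeric response vector (e.g. a per-unit diversity index).
#' @param env Data frame/matrix of predictors on the same units.
#' @param transform `"auto"`, `"none"`, `"log"` or `"inverse"`.
#' @return List with `coefficients` (estimate, SE, t, p per term),
#'   `r_squared`, `transform`, `shapiro_p` (of the response as used).
#' @export
standardized_regression <- function(y, env,
                                    transform = c("auto", "none", "log", "inverse")) {
  transform <- match.arg(transform)
  X <- as_matrix_checked(as.matrix(env), "predictors")
  if (length(y) != nrow(X)) stopf("response and predictors must share their units")
  if (length(y) <= ncol(X) + 1) stopf("need more units than predictors + 1")
  sw <- function(v) if (length(unique(v)) < 3) 0 else stats::shapiro.test(v)$p.value
  if (transform == "auto") {
    if (sw(y) >= 0.05) transform <- "none"
    else {
      cand <- c(none = sw(y),
                log = if (all(y > 0)) sw(log(y)) else -Inf,
                inverse = if (all(y != 0)) sw(1 / y) else -Inf)
      transform <- names(which.max(cand))
    }
  }
  yt <- switch(transform, none = y,
               log = { if (any(y <= 0)) stopf("log transform needs positive response"); log(y) },
               inverse = { if (any(y == 0)) stopf("inverse transform needs nonzero response"); 1 / y })
  Z <- scale(X)
  if (any(!is.finite(Z))) stopf("constant predictor cannot be standardized")
  qrX <- qr(cbind(1, Z))
  if (qrX$rank < ncol(Z) + 1) {
    aliased <- colnames(Z)[qrX$pivot[-seq_len(qrX$rank)] - 1]
    stopf("singular design; aliased column(s): %s", paste(aliased, collapse = ", "))
  }
  df <- data.frame(y = yt, Z)
  fit <- stats::lm(y ~ ., data = df)
  cf <- summary(fit)$coefficients
  list(coefficients = data.frame(term = rownames(cf), estimate = cf[, 1],
                                 se = cf[, 2], t = cf[, 3], p_value = cf[, 4],
                                 stringsAsFactors = FALSE, row.names = NULL),
       r_squared = summary(fit)$r.squared,
       transform = transform, shapiro_p = sw(yt))
}

#' Food-category GLMs for size and group effects
#'
#' Generalized linear model with either a binomial error and logit link
#' (prey presence/absence) or a gamma error and log link (strictly positive
#' diversity indices), fit by IRLS via [stats::glm()]. Wald tests per
#' coefficient; gamma dispersion from the Pearson chi-square. Possible
#' complete separation under the binomial family is flagged from fitted
#' probabilities collapsing to 0/1.
#'
#' @param formula Model formula, e.g. `present ~ standard_length * group`.
#' @param data Data frame holding the variables.
#' @param family `"binomial-logit"` or `"gamma-log"`.
#' @param max_iter IRLS iteration cap (default 100).
#' @return A `glm_fit` list: `coefficients` table, `family`, `deviance`,
#'   `dispersion`, `converged`, `separation`, and the underlying `model`.
#' @export
glm_fit <- function(formula, data, family = c("binomial-logit", "gamma-log"),
                    max_iter = 100) {
  family <- match.arg(family)
  fam <- switch(family,
                "binomial-logit" = stats::binomial(link = "logit"),
                "gamma-log" = stats::Gamma(link = "log"))
  resp <- stats::model.response(stats::model.frame(formula, data))
  if (family == "binomial-logit" && !all(resp %in% c(0, 1)))
    stopf("binomial-logit response must be 0/1 presence")
  if (family == "gamma-log" && any(resp <= 0))
    stopf("gamma-log response must be strictly positive")
  fit <- suppressWarnings(stats::glm(formula, data = data, family = fam,
                                     control = stats::glm.control(maxit = max_iter)))
  cf <- summary(fit)$coefficients
  dispersion <- if (family == "gamma-log")
    sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual else 1
  separation <- family == "binomial-logit" &&
    (any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8))
  structure(list(
    coefficients = data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                              statistic = cf[, 3], p_value = cf[, 4],
                              stringsAsFactors = FALSE, row.names = NULL),
    family = family, deviance = fit$deviance, dispersion = dispersion,
    converged = fit$converged, separation = separation, model = fit),
    class = "glm_fit")
}

#' Hellinger transformation
#'
#' Square root of the per-sample read proportions; after the transform each
#' sample's squared values sum to one, making compositional data suitable
#' for linear (Euclidean) ordination such as RDA.
#'
#' @param x Count or abundance matrix (taxa x samples).
#' @return Transformed matrix, same shape.
#' @export
hellinger_transform <- function(x) {
  x <- as_matrix_checked(x, "abundance matrix")
  if (any(x < 0)) stopf("abundances must be non-negative")
  if (any(colSums(x) <= 0))
    stopf("sample(s) with zero total: %s", paste(colnames(x)[colSums(x) <= 0], collapse = ", "))
  t(vegan::decostand(t(x), method = "hellinger"))
}

#' DCA gradient length and ordination recommendation
#'
#' Detrended correspondence analysis (detrending by 26 segments, Hill's
#' nonlinear rescaling, via [vegan::decorana()]); the first-axis gradient
#' length (LGA, in SD units of species turnover) selects the ordination
#' family: linear RDA below 3 SD, unimodal CCA above 4 SD, both (defaulting
#' to RDA) in between.
#'
#' @param x Transformed abundance matrix (taxa x samples).
#' @return List with `lga`, `axis_lengths` (4 axes) and `recommendation`
#'   (`"RDA"`, `"CCA"` or `"both"`).
#' @export
dca_gradient_length <- function(x) {
  x <- as_matrix_checked(x, "abundance matrix")
  if (ncol(x) < 3 || nrow(x) < 2) stopf("need at least 3 samples and 2 taxa")
  dec <- tryCatch(vegan::decorana(t(x)),
                  error = function(e) NULL)
  if (is.null(dec)) {
    axis_lengths <- rep(0, 4)
  } else {
    sc <- vegan::scores(dec, display = "sites", choices = 1:4)
    axis_lengths <- apply(sc, 2, function(v) diff(range(v)))
  }
  lga <- axis_lengths[1]
  list(lga = unname(lga), axis_lengths = unname(axis_lengths),
       recommendation = recommend_ordination(lga))
}

# the gradient-length decision rule: linear below 3 SD, unimodal above 4 SD,
# either in between (RDA is taken as the working default for "both")
recommend_ordination <- function(lga) {
  if (lga < 3) "RDA" else if (lga > 4) "CCA" else "both"
}

#' Redundancy analysis with permutation tests and envfit vectors
#'
#' Constrained ordination of (Hellinger-transformed) diet data on
#' environmental predictors via [vegan::rda()]: the response is centered,
#' constrained axes are the principal components of the fitted values.
#' Monte-Carlo permutation tests (pseudo-F, rows of the predictors
#' permuted) assess the full model and the first axis; per-variable envfit
#' gives the r2 of each predictor against the first two axis site scores
#' with a permutation p.
#'
#' @param x Transformed abundance matrix (taxa x samples), e.g. from
#'   [hellinger_transform()].
#' @param env Data frame of predictors (rows = samples, post-VIF).
#' @param n_perm Permutations for both tests (default 5000).
#' @param seed Optional seed.
#' @return An `rda_result`: `eigenvalues`, `prop_constrained` and
#'   `prop_total` per constrained axis, `site_scores`, `species_scores`,
#'   `biplot`, `global_test`/`axis1_test` (F, p), and `envfit` table
#'   (`RDA1`, `RDA2` direction cosines, `r2`, `p_value`).
#' @export
rda_ordination <- function(x, env, n_perm = 5000, seed = NULL) {
  x <- as_matrix_checked(x, "abundance matrix")
  env <- as.data.frame(env)
  if (ncol(x) != nrow(env)) stopf("samples and predictor rows must match")
  if (ncol(env) > ncol(x) - 1) stopf("more predictors than samples - 1")
  resp <- t(x)
  mod <- vegan::rda(resp ~ ., data = env)
  eig <- mod$CCA$eig
  # a saturated or single-predictor model can expose fewer than two axes
  n_axes <- length(mod$CCA$eig) + length(mod$CA$eig)
  choices <- seq_len(min(2L, n_axes))
  pad2 <- function(m) if (ncol(m) >= 2) m[, 1:2, drop = FALSE] else
    cbind(m, matrix(NA_real_, nrow(m), 2 - ncol(m)))
  with_seed_or_not(seed, {
    glob <- vegan::anova.cca(mod, permutations = n_perm)
    ax1 <- vegan::anova.cca(mod, by = "axis", permutations = n_perm,
                            cutoff = 0.99)
    ef <- vegan::envfit(mod, env, permutations = n_perm, choices = choices)
    arrows <- pad2(as.matrix(ef$vectors$arrows))
    structure(list(
      eigenvalues = eig,
      prop_constrained = eig / sum(eig),
      prop_total = eig / mod$tot.chi,
      site_scores = pad2(vegan::scores(mod, display = "sites", choices = choices)),
      species_scores = pad2(vegan::scores(mod, display = "species", choices = choices)),
      biplot = pad2(as.matrix(vegan::scores(mod, display = "bp", choices = choices))),
      global_test = list(F = glob$F[1], p_value = glob$`Pr(>F)`[1], n_perm = n_perm),
      axis1_test = list(F = ax1$F[1], p_value = ax1$`Pr(>F)`[1], n_perm = n_perm),
      envfit = data.frame(variable = rownames(arrows),
                          RDA1 = arrows[, 1], RDA2 = arrows[, 2],
                          r2 = ef$vectors$r, p_value = ef$vectors$pvals,
                          stringsAsFactors = FALSE, row.names = NULL),
      model = mod), class = "rda_result")
  })
}

#' Great-circle geographic distances between samples
#'
#' Haversine distance on an Earth radius of 6371.0 km from decimal-degree
#' GPS coordinates.
#'
#' @param metadata Data frame with `sample_id` (or unit id), `latitude`,
#'   `longitude`.
#' @return A [stats::dist] in kilometres with attribute `metric = "geographic"`.
#' @export
geographic_distance <- function(metadata) {
  for (req in c("latitude", "longitude"))
    if (!req %in% names(metadata)) stopf("metadata is missing '%s'", req)
  bad <- is.na(metadata$latitude) | is.na(metadata$longitude)
  if (any(bad)) stopf("missing coordinates for: %s",
                      paste(metadata$sample_id[bad], collapse = ", "))
  pts <- cbind(metadata$longitude, metadata$latitude)
  m <- geosphere::distm(pts, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
  dimnames(m) <- list(metadata$sample_id, metadata$sample_id)
  d <- stats::as.dist(m)
  attr(d, "metric") <- "geographic"
  d
}

#' Mantel test between two distance matrices
#'
#' Correlation of the lower-triangle entries of two distance matrices over
#' the same units, with significance from simultaneous row/column
#' permutation of one matrix; `p = (1 + #(r_perm >= r_obs)) / (1 + n_perm)`.
#' Backed by [vegan::mantel()]. Both the statistic and its square are
#' reported.
#'
#' @param d1,d2 [stats::dist] objects over the same units in the same order.
#' @param n_perm Permutations (default 10000).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param seed Optional seed.
#' @return A `mantel_result` list: `statistic`, `r_squared`, `p_value`,
#'   `n_perm`, `method`.
#' @export
mantel_test <- function(d1, d2, n_perm = 10000,
                        method = c("pearson", "spearman"), seed = NULL) {
  method <- match.arg(method)
  if (attr(d1, "Size") != attr(d2, "Size")) stopf("distance matrices differ in size")
  l1 <- attr(d1, "Labels"); l2 <- attr(d2, "Labels")
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2))
    stopf("distance matrices must be over the same units in the same order")
  fit <- with_seed_or_not(seed,
    vegan::mantel(d1, d2, method = method, permutations = n_perm))
  structure(list(statistic = unname(fit$statistic),
                 r_squared = unname(fit$statistic)^2,
                 p_value = fit$signif, n_perm = n_perm, method = method),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel (%s): r = %.4f, r2 = %.4f, p = %.4g (%d permutations)\n",
              x$method, x$statistic, x$r_squared, x$p_value, x$n_perm))
  invisible(x)
}
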