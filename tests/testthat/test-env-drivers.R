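test_that("VIF screen keeps orthogonal variables and removes exact duplicates first", {
  # columns orthogonal to each other *and* to the intercept, so the
  # with-intercept regressions behind the VIFs have R2 exactly 0
  set.seed(1)
  Z <- qr.Q(qr(cbind(1, matrix(rnorm(30), 10, 3))))[, -1]
  colnames(Z) <- c("a", "b", "c")
  vr <- vif_screen(Z)
  expect_true(all(vr$retained))
  expect_equal(vr$vif, rep(1, 3), tolerance = 1e-9)

  X <- cbind(Z, dup = Z[, 1])
  vr2 <- vif_screen(X)
  expect_true(any(is.infinite(vr2$vif)))
  expect_equal(sum(!vr2$retained), 1)
  expect_equal(vr2$removal_order[!vr2$retained], 1)

  # re-running the screen on its own retained set is a no-op
  keep <- vr2$variable[vr2$retained]
  vr3 <- vif_screen(X[, keep])
  expect_true(all(vr3$retained))
})

test_that("VIF equals 1/(1-R2) on a construction with known R2 = 0.5", {
  set.seed(2)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(40), 10, 4))))[, -1]
  # var3 = unit mass split equally between span(var1) and a direction
  # orthogonal to the others (all centered): R2 of var3 on (var1, var2) is 0.5
  X <- cbind(v1 = Q[, 1], v2 = Q[, 2], v3 = sqrt(0.5) * Q[, 1] + sqrt(0.5) * Q[, 3])
  vr <- vif_screen(X, threshold = 10)
  expect_equal(vr$vif[vr$variable == "v3"], 2, tolerance = 1e-9)
})

test_that("Spearman correlations hit the monotone extremes and the t-approximate p is close to exact", {
  prey <- cbind(up = c(1, 3, 5, 8, 9), down = c(9, 7, 4, 3, 1))
  env <- cbind(grad = c(0.2, 0.9, 1.4, 2.2, 3.0))
  sp <- spearman_correlations(prey, env)
  expect_equal(sp$rho["up", "grad"], 1)
  expect_equal(sp$rho["down", "grad"], -1)

  # exact permutation p over all 120 orderings vs the reported p
  x <- c(2, 6, 4, 9, 7)
  y <- c(1.1, 2.3, 3.0, 4.4, 3.9)
  got <- spearman_correlations(cbind(t = x), cbind(v = y))
  r0 <- cor(x, y, method = "spearman")
  rs <- vapply(all_perms(seq_along(y)), function(p)
    cor(x, y[p], method = "spearman"), numeric(1))
  p_exact <- mean(abs(rs) >= abs(r0) - 1e-12)
  expect_lt(abs(got$p_value["t", "v"] - p_exact), 0.01)
  # ties fall back to the t approximation and still report a finite p
  tie <- spearman_correlations(cbind(t = c(1, 1, 2, 3, 4)), cbind(v = y))
  expect_true(is.finite(tie$p_value["t", "v"]))

  const <- spearman_correlations(cbind(c = rep(1, 5)), env)
  expect_true(is.na(const$rho["c", "grad"]))
})

test_that("standardized regression recovers exact fits and calibrates its p-values", {
  set.seed(5)
  Z <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 * scale(Z[, 1])[, 1] + 5
  fit <- suppressWarnings(standardized_regression(y, Z, transform = "none"))
  cf <- fit$coefficients
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(cf$estimate[cf$term == "a"], 2, tolerance = 1e-6)
  expect_equal(cf$estimate[cf$term %in% c("b", "c")], c(0, 0), tolerance = 1e-6)

  # intercept-only fit returns the mean
  y2 <- rnorm(20)
  one <- stats::lm(y2 ~ 1)
  expect_equal(unname(coef(one)[1]), mean(y2))

  # type-I calibration: pure-noise responses reject at ~5%
  set.seed(6)
  rej <- vapply(1:500, function(i) {
    yy <- rnorm(20)
    f <- standardized_regression(yy, Z, transform = "none")
    f$coefficients$p_value[f$coefficients$term == "a"] < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)

  expect_error(standardized_regression(rnorm(20), cbind(Z, d = Z[, 1])), "aliased")
})

test_that("GLMs respect their links and recover known parameters", {
  # logit at coefficients (0,0): fitted probability one half everywhere
  d0 <- data.frame(y = rep(c(0, 1), 50), x = rnorm(100))
  f0 <- glm_fit(y ~ 1, d0, family = "binomial-logit")
  expect_equal(unique(round(f0$model$fitted.values, 10)), 0.5)

  # binomial with no effect: slope within 3 SE of zero
  set.seed(7)
  d1 <- data.frame(y = rbinom(200, 1, 0.5), SL = rnorm(200))
  f1 <- glm_fit(y ~ SL, d1, family = "binomial-logit")
  sl <- f1$coefficients[f1$coefficients$term == "SL", ]
  expect_lt(abs(sl$estimate), 3 * sl$se)

  # gamma-log with log-mean 1 + 0.5 SL: both coefficients within 3 SE of truth
  set.seed(8)
  SL <- rnorm(300)
  shape <- 20
  ymu <- exp(1 + 0.5 * SL)
  d2 <- data.frame(y = rgamma(300, shape = shape, rate = shape / ymu), SL = SL)
  f2 <- glm_fit(y ~ SL, d2, family = "gamma-log")
  cf <- f2$coefficients
  expect_lt(abs(cf$estimate[1] - 1), 3 * cf$se[1])
  expect_lt(abs(cf$estimate[2] - 0.5), 3 * cf$se[2])
  expect_true(f2$converged)
  expect_gt(f2$dispersion, 0)

  expect_error(glm_fit(y ~ SL, data.frame(y = c(-1, 2), SL = 1:2), "gamma-log"),
               "positive")
})

test_that("Hellinger rows have unit sum of squares and reproduce the closed form", {
  m <- tiny_counts(cbind(c(1L, 0L), c(25L, 75L)))
  h <- hellinger_transform(m)
  expect_equal(unname(h[, 1]), c(1, 0))
  expect_equal(unname(h[, 2]), c(0.5, sqrt(0.75)), tolerance = 1e-9)
  set.seed(9)
  r <- tiny_counts(matrix(rpois(24, 6) + 1L, 4, 6))
  hr <- hellinger_transform(r)
  expect_equal(unname(colSums(hr^2)), rep(1, 6), tolerance = 1e-9)
  # Euclidean distance on Hellinger values is the Hellinger distance
  p <- sweep(r, 2, colSums(r), "/")
  direct <- sqrt(sum((sqrt(p[, 1]) - sqrt(p[, 2]))^2))
  expect_equal(as.matrix(dist(t(hr)))[1, 2], direct, tolerance = 1e-9)
})

test_that("DCA gradient length drives the RDA/CCA recommendation", {
  expect_equal(dietbarcode:::recommend_ordination(2.5), "RDA")
  expect_equal(dietbarcode:::recommend_ordination(3.57), "both")
  expect_equal(dietbarcode:::recommend_ordination(4.5), "CCA")
  expect_equal(dietbarcode:::recommend_ordination(3), "both")
  expect_equal(dietbarcode:::recommend_ordination(4), "both")

  # near-identical samples: negligible gradient, linear ordination
  base <- c(40L, 30L, 20L, 10L)
  m <- tiny_counts(sapply(1:6, function(i) base + sample(0:1, 4, TRUE)))
  short <- dca_gradient_length(m)
  expect_lt(short$lga, 3)
  expect_equal(short$recommendation, "RDA")

  # long gradient with unimodal turnover: > 4 SD, unimodal ordination
  grad <- seq(0, 10, length.out = 24)
  optima <- seq(0, 10, length.out = 15)
  resp <- sapply(grad, function(g) {
    mu <- 200 * exp(-(g - optima)^2 / (2 * 0.6^2))
    rpois(length(optima), mu)
  })
  set.seed(10)
  m2 <- tiny_counts(resp)
  keep <- colSums(m2) > 0
  long <- dca_gradient_length(m2[, keep])
  expect_gt(long$lga, 4)
  expect_equal(long$recommendation, "CCA")
})

test_that("RDA captures a single linear driver and obeys the eigenvalue identity", {
  set.seed(11)
  n <- 12
  z <- scale(rnorm(n))[, 1]
  Y <- outer(c(1, -0.5, 0.25, 0.1), z)  # taxa x samples, exactly linear in z
  Y <- Y + 2  # keep positive-ish, centering happens inside
  dimnames(Y) <- list(sprintf("t%d", 1:4), sprintf("s%d", 1:n))
  env <- data.frame(z = z, noise = rnorm(n))
  fit <- rda_ordination(Y, env["z"], n_perm = 99, seed = 1)
  expect_equal(unname(fit$prop_constrained[1]), 1, tolerance = 1e-9)
  ef <- fit$envfit
  expect_equal(ef$r2[ef$variable == "z"], 1, tolerance = 1e-6)

  # eigenvalue sum equals the variance captured by the fitted values
  fit2 <- rda_ordination(Y + matrix(rnorm(4 * n, 0, 0.1), 4, n), env,
                         n_perm = 99, seed = 2)
  mod <- fit2$model
  expect_equal(sum(fit2$eigenvalues), mod$CCA$tot.chi, tolerance = 1e-9)
  expect_error(rda_ordination(Y[, 1:3], data.frame(a = 1:3, b = 3:1, c = c(1, 3, 2))),
               "predictors")
})

test_that("RDA coefficients recover a known multivariate linear effect within 3 SE", {
  set.seed(12)
  n <- 30
  z <- scale(rnorm(n))[, 1]
  beta <- c(0.8, -0.4, 0.2, 0)
  Y <- t(sapply(beta, function(b) 5 + b * z + rnorm(n, 0, 0.3)))
  dimnames(Y) <- list(sprintf("t%d", 1:4), sprintf("s%d", 1:n))
  env <- data.frame(z = z)
  fit <- rda_ordination(Y, env, n_perm = 99, seed = 3)
  # the constrained model is the multivariate least-squares fit: its fitted
  # values equal the per-taxon OLS fitted values ...
  ols_fitted <- sapply(1:4, function(k) fitted(stats::lm(Y[k, ] ~ z)))
  expect_equal(unname(fitted(fit$model)), unname(ols_fitted), tolerance = 1e-8,
               ignore_attr = TRUE)
  # ... and the per-taxon OLS slopes recover the generating coefficients
  for (k in 1:4) {
    ols <- summary(stats::lm(Y[k, ] ~ z))$coefficients
    expect_lt(abs(ols["z", "Estimate"] - beta[k]), 3 * ols["z", "Std. Error"])
  }
})

test_that("geographic distances follow the haversine closed forms", {
  md <- data.frame(sample_id = c("o", "e", "n", "anti"),
                   latitude = c(0, 0, 1, 0), longitude = c(0, 1, 0, 180))
  d <- as.matrix(geographic_distance(md))
  expect_equal(d["o", "e"], 6371 * pi / 180, tolerance = 1e-4)
  expect_equal(d["o", "n"], 6371 * pi / 180, tolerance = 1e-4)
  expect_equal(d["o", "anti"], 6371 * pi, tolerance = 1e-3)
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_error(geographic_distance(data.frame(sample_id = "x", latitude = NA,
                                              longitude = 3)), "x")
})

test_that("Mantel matches exact enumeration at n = 5 and is calibrated under the null", {
  set.seed(13)
  d1 <- dist(rnorm(5)); d2 <- dist(rnorm(5))
  mt <- mantel_test(d1, d2, n_perm = 9999, seed = 1)
  expect_equal(mt$p_value, oracle_mantel_p(d1, d2), tolerance = 1e-12)
  expect_equal(mt$r_squared, mt$statistic^2)

  # perfectly proportional matrices: statistic 1, minimum attainable p
  d3 <- dist(matrix(rnorm(16), 8, 2))
  mt2 <- mantel_test(d3, 2 * d3, n_perm = 999, seed = 2)
  expect_equal(mt2$statistic, 1, tolerance = 1e-12)
  expect_equal(mt2$p_value, 1 / 1000, tolerance = 1e-12)

  # common relabeling of both matrices leaves the statistic unchanged
  perm <- sample(8)
  m3 <- as.matrix(d3); m4 <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
  s1 <- mantel_test(as.dist(m3), as.dist(m4), n_perm = 99, seed = 3)$statistic
  s2 <- mantel_test(as.dist(m3[perm, perm]), as.dist(m4[perm, perm]),
                    n_perm = 99, seed = 3)$statistic
  expect_equal(s1, s2, tolerance = 1e-12)

  # type-I calibration on independent random matrices
  set.seed(14)
  rej <- vapply(1:500, function(i) {
    a <- dist(rnorm(10)); b <- dist(rnorm(10))
    mantel_test(a, b, n_perm = 99)$p_value <= 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})
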