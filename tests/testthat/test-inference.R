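test_that("perfect linear fit yields exact coefficients and zero robust SEs", {
  d <- data.frame(x = 1:12, town = rep(c("a", "b", "c"), 4))
  d$y <- 2 + 3 * d$x
  fit <- fit_ols_cluster(y ~ x, d, cluster = "town")
  expect_equal(unname(fit$coefficients), c(2, 3), tolerance = 1e-10)
  expect_equal(unname(fit$robust_se), c(0, 0), tolerance = 1e-8)
  expect_equal(fit$r_squared, 1)
})

test_that("CR1 sandwich matches a by-hand matrix evaluation on a toy dataset", {
  d <- data.frame(
    y = c(1.2, 0.8, 2.5, 2.9, 4.1, 3.5),
    x = c(0.1, 0.4, 1.0, 1.3, 2.0, 2.2),
    town = c("a", "a", "b", "b", "c", "c")
  )
  fit <- fit_ols_cluster(y ~ x, d, cluster = "town")

  X <- cbind(1, d$x)
  beta <- solve(crossprod(X), crossprod(X, d$y))
  e <- d$y - X %*% beta
  meat <- matrix(0, 2, 2)
  for (g in unique(d$town)) {
    idx <- d$town == g
    s <- t(X[idx, , drop = FALSE]) %*% e[idx]
    meat <- meat + s %*% t(s)
  }
  G <- 3; N <- 6; K <- 2
  V <- G / (G - 1) * (N - 1) / (N - K) *
    solve(crossprod(X)) %*% meat %*% solve(crossprod(X))
  expect_equal(unname(fit$robust_se), sqrt(diag(V)), tolerance = 1e-10)
  expect_equal(unname(fit$coefficients), as.vector(beta), tolerance = 1e-10)

  skip_if_not_installed("sandwich")
  lf <- lm(y ~ x, d)
  expect_equal(unname(fit$vcov),
               unname(sandwich::vcovCL(lf, cluster = d$town, type = "HC1")),
               tolerance = 1e-10)
})

test_that("with singleton clusters CR1 collapses to HC1", {
  skip_if_not_installed("sandwich")
  set.seed(4)
  d <- data.frame(x = rnorm(25), z = rnorm(25))
  d$y <- 1 + 0.5 * d$x - d$z + rnorm(25)
  d$id <- sprintf("c%02d", 1:25)
  fit <- fit_ols_cluster(y ~ x + z, d, cluster = "id")
  lf <- lm(y ~ x + z, d)
  expect_equal(unname(fit$vcov),
               unname(sandwich::vcovHC(lf, type = "HC1")),
               tolerance = 1e-10)
})

test_that("clustered fit is invariant to labeling and within-cluster order", {
  set.seed(12)
  d <- data.frame(x = rnorm(60), town = rep(sprintf("t%d", 1:10), each = 6))
  d$y <- 0.3 * d$x + rnorm(60) + rep(rnorm(10), each = 6)
  f1 <- fit_ols_cluster(y ~ x, d, cluster = "town")

  relab <- d
  relab$town <- sprintf("renamed_%s", rev(relab$town))
  f2 <- fit_ols_cluster(y ~ x, relab, cluster = "town")
  expect_equal(f1$coefficients, f2$coefficients)
  expect_equal(f1$robust_se, f2$robust_se, tolerance = 1e-12)

  perm <- unlist(lapply(split(seq_len(60), d$town), sample))
  f3 <- fit_ols_cluster(y ~ x, d[perm, ], cluster = "town")
  expect_equal(f1$robust_se, f3$robust_se, tolerance = 1e-12)
})

test_that("degenerate designs are rejected with informative errors", {
  d <- data.frame(x = 1:10, town = rep(c("a", "b"), 5))
  d$y <- rnorm(10)
  d$x2 <- 2 * d$x
  expect_error(fit_ols_cluster(y ~ x + x2, d, cluster = "town"), "collinear.*x2")
  expect_error(
    fit_ols_cluster(y ~ x, transform(d, town = "a"), cluster = "town"),
    "at least 2 clusters"
  )
  expect_error(fit_ols_cluster(y ~ x, d, cluster = "nope"), "not in data")
})

test_that("paired one-tailed t test matches the closed-form computation", {
  a <- c(1, 2, 3); b <- c(2, 2, 4)          # diffs -1, 0, -1
  res <- paired_t_one_tailed(a, b, alternative = "less")
  expect_equal(res$t, -2, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$mean_diff, -2 / 3, tolerance = 1e-12)
  expect_equal(res$p, pt(-2, df = 2), tolerance = 1e-12)
  res_g <- paired_t_one_tailed(a, b, alternative = "greater")
  expect_equal(res_g$p, 1 - pt(-2, df = 2), tolerance = 1e-12)

  expect_error(paired_t_one_tailed(1:10, 1:10 + 1), "zero variance")
})

test_that("paired t one-tailed p-values are uniform under the null", {
  set.seed(6)
  ps <- replicate(500, {
    a <- rnorm(20); b <- rnorm(20)
    paired_t_one_tailed(a, b)$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("predicted contrasts are linear, antisymmetric and validated", {
  coefs <- c(`(Intercept)` = 0.1, frag = 0.5, vk = -0.2, age = 0.01)
  expect_equal(
    predicted_contrast(coefs, c(frag = 1, vk = 1), c(frag = 1, vk = 1))$predicted_difference,
    0
  )
  ab <- predicted_contrast(coefs, c(frag = 0.8, vk = 1), c(frag = 0.3))
  ba <- predicted_contrast(coefs, c(frag = 0.3), c(frag = 0.8, vk = 1))
  expect_equal(ab$predicted_difference, -ba$predicted_difference)
  expect_equal(ab$predicted_difference, 0.5 * 0.5 + (-0.2) * 1)

  set.seed(3)
  for (r in 1:10) {
    cf <- setNames(rnorm(4), c("a", "b", "c", "d"))
    pa <- setNames(rnorm(3), c("a", "b", "c"))
    pb <- setNames(rnorm(2), c("b", "d"))
    fwd <- predicted_contrast(cf, pa, pb)$predicted_difference
    rev_ <- predicted_contrast(cf, pb, pa)$predicted_difference
    expect_equal(fwd, -rev_, tolerance = 1e-12)
  }
  expect_error(predicted_contrast(coefs, c(unknown = 1), c(frag = 0)), "not in the model")
})

test_that("robustness subset keeps strictly-above-threshold towns", {
  cov_ <- c(A = 0.10, B = 0.16, C = 0.20)
  keep <- robustness_subset(cov_, 0.15)
  expect_setequal(as.character(keep), c("B", "C"))
  expect_equal(attr(keep, "n_retained"), 2L)
  expect_equal(attr(keep, "mean_coverage"), 0.18)
  expect_length(robustness_subset(cov_, 0), 3L)

  set.seed(14)
  for (r in 1:10) {
    cv <- setNames(runif(166, 0, 0.4), paste0("t", 1:166))
    th <- runif(1, 0, 0.3)
    kept <- robustness_subset(cv, th)
    if (length(kept) > 0) expect_gte(attr(kept, "mean_coverage"), th)
  }
})
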