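# Differential engine: normalization, dispersion, NB GLM, Wald test,
# calling, VST, clustering and power.

test_that("size factors follow median-of-ratios", {
  # sample B doubles sample A: ratios are (1/sqrt(2), sqrt(2))
  A <- c(10, 5, 50, 7)
  K <- cbind(A, 2 * A)
  s <- size_factors(K)
  expect_equal(s, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # identical samples: all equal
  K2 <- cbind(A, A, A)
  expect_equal(size_factors(K2), rep(1, 3))

  # invariant to window order
  set.seed(101)
  K3 <- matrix(rnbinom(500, mu = 30, size = 5) + 1L, 100, 5)
  expect_equal(size_factors(K3), size_factors(K3[sample(100), ]))

  expect_error(size_factors(matrix(0L, 4, 3)), "positive counts")
})

test_that("dispersion estimation clamps, matches hand MoM and recovers truth", {
  # constant row: variance 0 -> clamped at the floor
  K <- rbind(
    rep(10, 4),
    c(4, 8, 12, 16)
  )
  expect_warning(a <- estimate_dispersion(K, rep(1, 4)), "20 windows")
  expect_equal(a[1], 1e-8)

  # hand method-of-moments: mean 10, var 34.667 -> (34.667-10)/100
  row <- c(2, 7, 10, 21) # mean 10, var 66 -- use an exact constructed row
  y <- c(4, 9, 11, 16) # mean 10, var 24.667
  expect_warning(a2 <- estimate_dispersion(rbind(y, y + 1), rep(1, 4)))
  expect_equal(a2[1], (var(y) - 10) / 100, tolerance = 1e-12)

  # recovery on synthetic NB data with trend blending
  co <- full_cohort()
  sim <- simulate_counts(111, co,
    n_windows = 2000, dispersion = 0.1,
    covariate_effects = list(age = 0, gender = 0, batch = 0)
  )
  s <- size_factors(sim$counts)
  alpha <- estimate_dispersion(sim$counts, s)
  expect_gt(median(alpha), 0.08)
  expect_lt(median(alpha), 0.12)
})

# log-likelihood of a two-group NB model, used by the brute-force oracle
nb_loglik <- function(y, g, s, alpha, b0, b1) {
  mu <- s * exp(b0 + b1 * g)
  sum(dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
}

test_that("two-group NB fit matches the closed form and a likelihood grid", {
  set.seed(121)
  # closed form with unit size factors: log2 ratio of group means
  g <- rep(c(0, 1), each = 12)
  X <- cbind(intercept = 1, group = g)
  y <- rnbinom(24, mu = 40 * 2^(0.7 * g), size = 10)
  fit <- fit_nb_glm(y, X, rep(1, 24), 0.1)
  expect_equal(
    fit$log2fc,
    log2(mean(y[g == 1]) / mean(y[g == 0])),
    tolerance = 1e-6
  )

  # constant counts: group coefficient 0
  fit0 <- fit_nb_glm(rep(20L, 24), X, rep(1, 24), 0.1)
  expect_equal(fit0$log2fc, 0, tolerance = 1e-10)

  # brute-force grid maximizer agrees on random small instances
  for (i in 1:20) {
    n <- 16L
    g <- rep(c(0, 1), each = n / 2)
    s <- runif(n, 0.5, 2)
    alpha <- runif(1, 0.05, 0.3)
    y <- rnbinom(n, mu = s * exp(runif(1, 2, 4) + runif(1, -1, 1) * g),
      size = 1 / alpha
    )
    if (any(tapply(y, g, sum) == 0)) next
    fit <- fit_nb_glm(y, cbind(intercept = 1, group = g), s, alpha)
    b_hat <- fit$beta
    # two-stage grid around the IRLS-free moment start
    b0g <- seq(b_hat[1] - 0.5, b_hat[1] + 0.5, length.out = 101)
    b1g <- seq(b_hat[2] - 0.5, b_hat[2] + 0.5, length.out = 101)
    ll <- outer(b0g, b1g, Vectorize(function(b0, b1) nb_loglik(y, g, s, alpha, b0, b1)))
    ix <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    b0f <- seq(b0g[ix[1]] - 0.01, b0g[ix[1]] + 0.01, length.out = 201)
    b1f <- seq(b1g[ix[2]] - 0.01, b1g[ix[2]] + 0.01, length.out = 201)
    llf <- outer(b0f, b1f, Vectorize(function(b0, b1) nb_loglik(y, g, s, alpha, b0, b1)))
    ixf <- which(llf == max(llf), arr.ind = TRUE)[1, ]
    expect_equal(b_hat[2], b1f[ixf[2]], tolerance = 1e-3)
  }

  expect_error(
    fit_nb_glm(y, cbind(1, g, g), s, 0.1),
    "rank deficient"
  )
})

test_that("NB estimate concentrates around an injected log2FC of 1", {
  co <- full_cohort()
  X <- design_matrix(co, "5hmC")
  set.seed(123)
  hits <- vapply(1:200, function(i) {
    y <- rnbinom(nrow(co), mu = 50 * 2^(co$group == "SCZ"), size = 10)
    fit <- fit_nb_glm(y, X, rep(1, nrow(co)), 0.1)
    fit$log2fc >= 0.8 && fit$log2fc <= 1.2
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("Wald p-values follow the normal tail and are sign-symmetric", {
  expect_equal(wald_test(0.6, 0.2), 2 * pnorm(-3), tolerance = 1e-12)
  expect_equal(wald_test(0, 0.3), 1)
  expect_equal(wald_test(0.4, 0.1), wald_test(-0.4, 0.1))
  expect_error(wald_test(1, 0), "positive")
})

test_that("region calling applies both thresholds with direction", {
  res <- data.frame(
    pvalue = c(1e-4, 1e-4, 1e-3, 1e-4),
    log2fc = c(0.8, -0.8, 0.8, 0.3)
  )
  expect_identical(call_regions(res), c("hyper", "hypo", "none", "none"))
})

test_that("VST is log2 of normalized counts plus one and monotone", {
  expect_equal(vst_counts(matrix(3), s = 1)[1], 2)
  expect_equal(vst_counts(matrix(0), s = 1)[1], 0)
  K <- matrix(0:10, ncol = 1)
  v <- vst_counts(K, s = 1)
  expect_true(all(diff(v[, 1]) > 0))
})

test_that("clustering separates shifted blocks and tolerates duplicates", {
  set.seed(131)
  # hyper regions elevated in one sample block, hypo regions in the other
  # (5 SD), so within-group correlations dominate between-group ones
  x <- matrix(rnorm(50 * 20), 50, 20)
  x[1:25, 11:20] <- x[1:25, 11:20] + 5
  x[26:50, 1:10] <- x[26:50, 1:10] + 5
  colnames(x) <- paste0("s", 1:20)
  cl <- cluster_samples(x)
  truth <- rep(1:2, each = 10)
  tab <- table(cl$labels, truth)
  expect_true(all(rowSums(tab > 0) == 1)) # pure clusters: ARI = 1

  # duplicated sample merges first at height 0
  x2 <- cbind(x[, 1:5], dup = x[, 1])
  cl2 <- cluster_samples(x2)
  expect_equal(min(cl2$hclust$height), 0, tolerance = 1e-12)

  # order invariance up to label renaming
  perm <- sample(20)
  cl3 <- cluster_samples(x[, perm])
  expect_identical(
    unname(cl3$labels == cl3$labels[1]),
    unname((cl$labels[perm]) == cl$labels[perm][1])
  )

  expect_error(cluster_samples(cbind(x[, 1:3], const = rep(1, 50))), "constant")
})

test_that("power function behaves at the null, the limit and a mid effect", {
  expect_identical(region_power(0, 66, 77, 0.05), 0.05)
  expect_gt(region_power(5, 66, 77, 0.05), 0.999)
  p <- region_power(0.43, 66, 77, 0.05)
  expect_gt(p, 0.65)
  expect_lt(p, 0.75)
  # monotone non-decreasing in d
  d <- seq(0, 2, by = 0.1)
  expect_true(all(diff(region_power(d, 30, 30, 0.05)) >= 0))
  expect_error(region_power(0.5, 30, 30, alpha = 1.5), "alpha")
})
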