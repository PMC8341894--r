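test_that("PGLS at lambda = 0 equals OLS (star-phylogeny limit)", {
  n <- 12
  star <- simulate_tree(n, seed = 40, scale = 1)  # ultrametric: C(0) = I
  set.seed(41)
  x <- stats::rnorm(n); y <- 1 + 0.5 * x + stats::rnorm(n, 0, 0.2)
  names(x) <- names(y) <- star$tip.label
  X <- cbind(`(Intercept)` = 1, x = x); rownames(X) <- star$tip.label
  f <- pgls_fit(star, y, X, corr = 0)
  ols <- stats::lm(y ~ x)
  expect_equal(unname(f$coefficients), unname(stats::coef(ols)),
               tolerance = 1e-10)
  expect_equal(unname(f$se), unname(sqrt(diag(stats::vcov(ols)))),
               tolerance = 1e-10)
})

test_that("PGLS matches dense-matrix GLS algebra on a small tree", {
  tr <- simulate_tree(5, seed = 42, scale = 3)
  set.seed(43)
  x <- stats::setNames(stats::rnorm(5), tr$tip.label)
  y <- stats::setNames(2 + x + stats::rnorm(5, 0, 0.3), tr$tip.label)
  X <- cbind(`(Intercept)` = 1, x = x); rownames(X) <- tr$tip.label
  f <- pgls_fit(tr, y, X, "BM")
  C <- ape::vcv(tr)[tr$tip.label, tr$tip.label]
  expect_equal(unname(f$coefficients),
               dense_gls(C, X[tr$tip.label, ], y[tr$tip.label]),
               tolerance = 1e-12)
})

test_that("PGLS recovers a known slope under BM simulation", {
  tr <- simulate_tree(200, seed = 44, scale = 5)
  slopes <- vapply(1:20, function(s) {
    set.seed(500 + s)
    x <- stats::setNames(phytools::fastBM(tr, sig2 = 0.1), tr$tip.label)
    y <- x + stats::setNames(phytools::fastBM(tr, sig2 = 0.05), tr$tip.label)
    X <- cbind(`(Intercept)` = 1, x = x); rownames(X) <- tr$tip.label
    f <- pgls_fit(tr, y, X, "BM")
    unname(f$coefficients["x"])
  }, 0)
  expect_lt(abs(mean(slopes) - 1), 2 * stats::sd(slopes) / sqrt(20))
})

test_that("phylogenetic residuals satisfy the GLS normal equations", {
  tr <- fx_tree6()
  set.seed(45)
  size <- stats::setNames(stats::rnorm(6, 2, 0.3), tr$tip.label)
  # exact proportionality: all residuals zero
  y <- 0.8 * size
  expect_equal(max(abs(phylo_residuals(tr, y, size))), 0, tolerance = 1e-12)

  y2 <- y + stats::setNames(stats::rnorm(6, 0, 0.2), tr$tip.label)
  r <- phylo_residuals(tr, y2, size)
  C <- ape::vcv(tr)[tr$tip.label, tr$tip.label]
  Ci <- solve(C)
  X <- cbind(1, size[tr$tip.label])
  expect_lt(max(abs(t(X) %*% Ci %*% r[tr$tip.label])), 1e-10)
})

test_that("slope heterogeneity interaction is zero for duplicated regimes", {
  # duplicated-data construction: both regimes carry the same exact linear
  # (size, y) relationship, so the interaction estimate is exactly zero
  tr2 <- simulate_tree(10, seed = 48, scale = 5)
  sz <- stats::setNames(stats::rnorm(10, 2, 0.4), tr2$tip.label)
  yy <- 0.5 + 1.1 * sz
  reg <- stats::setNames(rep(c("p", "q"), each = 5), tr2$tip.label)
  out <- slope_heterogeneity_test(tr2, yy, sz, reg)
  expect_equal(out$contrasts$estimate, 0, tolerance = 1e-8)

  # type-I calibration: identical slopes -> rejection near nominal alpha
  tr <- simulate_tree(20, seed = 46, scale = 5)
  set.seed(49)
  pvals <- vapply(1:120, function(i) {
    x <- stats::setNames(phytools::fastBM(tr, sig2 = 0.1), tr$tip.label)
    e <- stats::setNames(phytools::fastBM(tr, sig2 = 0.05), tr$tip.label)
    yv <- 1 + x + e
    rg <- stats::setNames(rep(c("p", "q"), each = 10), tr$tip.label)
    suppressWarnings(slope_heterogeneity_test(tr, yv, x, rg)$F_p)
  }, 0)
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.15)
})

test_that("a planted slope offset is detected with the right sign", {
  tr <- simulate_tree(100, seed = 50, scale = 5)
  reg <- stats::setNames(rep(c("p", "q"), 50), tr$tip.label)
  hits <- vapply(1:30, function(i) {
    set.seed(600 + i)
    x <- stats::setNames(phytools::fastBM(tr, sig2 = 0.2), tr$tip.label)
    e <- stats::setNames(phytools::fastBM(tr, sig2 = 0.01), tr$tip.label)
    y <- 1 + x + ifelse(reg == "q", -0.3 * x, 0) + e
    out <- slope_heterogeneity_test(tr, y, x, reg, reference = "p")
    out$contrasts$estimate[out$contrasts$regime == "q"] < 0
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("small regimes are dropped with a warning", {
  tr <- simulate_tree(12, seed = 51, scale = 5)
  set.seed(52)
  x <- stats::setNames(stats::rnorm(12, 2, 0.4), tr$tip.label)
  y <- 1 + x + stats::rnorm(12, 0, 0.1)
  names(y) <- tr$tip.label
  reg <- stats::setNames(c(rep("p", 6), rep("q", 5), "r"), tr$tip.label)
  expect_warning(out <- slope_heterogeneity_test(tr, y, x, reg),
                 "fewer than")
  expect_setequal(out$contrasts$regime, "q")
})

test_that("fineness ratio follows its formula and is scale invariant", {
  expect_equal(fineness_ratio(4.5, 1, 1), 4.5)
  expect_equal(fineness_ratio(29, 10, 10), 2.9)
  expect_equal(fineness_ratio(3 * 29, 3 * 10, 3 * 10),
               fineness_ratio(29, 10, 10))
  expect_error(fineness_ratio(1, 0, 1), "positive")
})

test_that("size correction passes excluded columns through untouched", {
  f <- make_fixture("paper-like")
  res <- size_correct(f$tree, f$traits)
  expect_equal(res[, "max_body_size"],
               stats::setNames(f$traits$max_body_size, f$traits$species)[
                 rownames(res)])
  expect_false(identical(res[, "eye_diameter"],
                         stats::setNames(f$traits$eye_diameter,
                                         f$traits$species)[rownames(res)]))
  # residual sign convention: recovered mean residual of zp tips for eye
  # diameter should exceed that of other regimes (theta_zp > 0 in truth)
  zp <- names(f$tip_states)[f$tip_states == "zp"]
  expect_gt(mean(res[zp, "eye_diameter"]),
            mean(res[setdiff(rownames(res), zp), "eye_diameter"]))
})
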