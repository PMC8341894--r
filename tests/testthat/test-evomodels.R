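test_that("likelihood matches the closed-form bivariate normal on a cherry", {
  pt <- parse_simmap("(A:{bi,1.0},B:{bi,1.0}):0;")
  y <- c(A = 0.3, B = -0.2)
  a <- 0.7; s2 <- 0.4; th <- 0.1
  ll <- model_loglik(pt, y, "OU1", list(alpha = a, sigma2 = s2, theta = th))
  v <- s2 * (1 - exp(-2 * a)) / (2 * a)   # stationary-root OU tip variance
  V <- diag(v, 2)                          # shared path length 0 at the root
  r <- y - th
  ll_direct <- -0.5 * (2 * log(2 * pi) + log(det(V)) +
                         as.numeric(t(r) %*% solve(V) %*% r))
  expect_equal(ll, ll_direct, tolerance = 1e-10)
})

test_that("model moments match Monte-Carlo moments on a painted tree", {
  pt <- fx_painted6()
  pars <- list(alpha = 0.5, sigma2 = c(bi = 0.3, zp = 0.8),
               theta = c(bi = 0, zp = 2))
  mo <- ou_moments(pt, "OUMV", pars)
  nrep <- 100000
  Y <- simulate_traits(pt, "OUMV", pars, n_traits = nrep, seed = 7)
  Y <- Y[names(mo$mean), ]
  se_m <- sqrt(diag(mo$cov) / nrep)
  expect_true(all(abs(rowMeans(Y) - mo$mean) < 4 * se_m))
  empV <- stats::cov(t(Y))
  se_V <- sqrt((outer(diag(mo$cov), diag(mo$cov)) + mo$cov^2) / nrep)
  expect_true(all(abs(empV - mo$cov) < 4 * se_V))
})

test_that("OU collapses to BM and multi-regime models nest their single versions", {
  pt <- fx_painted6()
  set.seed(61)
  y <- simulate_traits(pt, "BM1", list(sigma2 = 0.3, root = 0.2))[, 1]
  ll_ou <- model_loglik(pt, y, "OU1",
                        list(alpha = 1e-12, sigma2 = 0.3, theta = 0.5))
  ll_bm <- model_loglik(pt, y, "BM1", list(sigma2 = 0.3, mu = 0.5))
  expect_equal(ll_ou, ll_bm, tolerance = 1e-6)

  # OUM with equal optima = OU1; BMS with equal rates = BM1
  ll_oum <- model_loglik(pt, y, "OUM",
                         list(alpha = 0.4, sigma2 = 0.3,
                              theta = c(bi = 0.5, zp = 0.5)))
  ll_ou1 <- model_loglik(pt, y, "OU1",
                         list(alpha = 0.4, sigma2 = 0.3, theta = 0.5))
  expect_equal(ll_oum, ll_ou1, tolerance = 1e-8)
  ll_bms <- model_loglik(pt, y, "BMS",
                         list(sigma2 = c(bi = 0.3, zp = 0.3), mu = 0.5))
  expect_equal(ll_bms, ll_bm, tolerance = 1e-8)
})

test_that("BM1 ML rate equals the closed-form GLS estimator", {
  pt <- fx_painted6()
  set.seed(62)
  y <- simulate_traits(pt, "BM1", list(sigma2 = 0.4, root = 1))[, 1]
  f <- fit_model(pt, y, "BM1")
  C <- ape::vcv(pt)[names(y), names(y)]
  Ci <- solve(C)
  one <- rep(1, length(y))
  mu <- as.numeric(t(one) %*% Ci %*% y / (t(one) %*% Ci %*% one))
  s2 <- as.numeric(t(y - mu) %*% Ci %*% (y - mu)) / length(y)
  expect_equal(unname(f$sigma2[1]), s2, tolerance = 1e-8)
  expect_equal(f$mu, mu, tolerance = 1e-8)
  # refitting gives an identical result (no randomness in the optimizer)
  f2 <- fit_model(pt, y, "BM1")
  expect_identical(f$par, f2$par)
})

test_that("AICc uses tip count and the small-sample correction", {
  pt <- fx_painted6()
  set.seed(63)
  y <- simulate_traits(pt, "BM1", list(sigma2 = 0.4, root = 1))[, 1]
  f <- fit_model(pt, y, "BM1")
  k <- 2; n <- 6
  expect_equal(f$aicc,
               -2 * f$loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1))
})

test_that("stationary variance follows sigma2 / (2 alpha)", {
  expect_equal(stationary_variance(1, 2), 1)
  expect_equal(stationary_variance(1, 4), 2 * stationary_variance(1, 2))
  expect_equal(stationary_variance(2, 2), stationary_variance(1, 2) / 2)
  expect_warning(sv <- stationary_variance(0, 2), "undefined")
  expect_true(is.infinite(sv))
})

test_that("increasing attraction shrinks realized dispersion around the optimum", {
  pt <- fx_painted150()
  vars <- vapply(c(0.5, 2, 8), function(a) {
    y <- simulate_traits(pt, "OU1",
                         list(alpha = a, sigma2 = 0.5, theta = 0),
                         n_traits = 200, seed = 64)
    mean(apply(y, 2, stats::var))
  }, 0)
  expect_true(all(diff(vars) < 0))
})

test_that("model averaging reproduces hand arithmetic and its invariants", {
  mk_fit <- function(model, aicc, theta = NULL, alpha = NULL, sigma2 = 0.3,
                     se = NULL, regimes = c("bi", "zp")) {
    structure(list(model = model, aicc = aicc, retained = TRUE,
                   theta = theta, alpha = alpha,
                   sigma2 = if (length(sigma2) > 1) sigma2
                            else c(sigma2 = sigma2),
                   se = se, regimes = regimes), class = "model_fit")
  }
  f1 <- mk_fit("OUM", 100, theta = c(bi = 0, zp = 1), alpha = 2,
               se = c(theta_bi = 0.1, theta_zp = 0.1, alpha = 0.5,
                      sigma2 = 0.05))
  f2 <- mk_fit("OU1", 102, theta = c(bi = 0.5, zp = 0.5), alpha = 1,
               se = c(theta = 0.2, alpha = 0.4, sigma2 = 0.05))
  avg <- average_models(list(OUM = list(f1), OU1 = list(f2)), level = 0.999)
  # delta = (0, 2): weights exp(0)/Z and exp(-1)/Z
  expect_equal(sort(avg$table$weight, decreasing = TRUE),
               c(0.7311, 0.2689), tolerance = 1e-4)
  expect_equal(sum(avg$table$weight), 1)
  expect_equal(sum(avg$table$adjusted_weight, na.rm = TRUE), 1)
  # averaged optimum: w1 * 1 + w2 * 0.5 for zp
  w <- avg$table$weight[avg$table$model == "OUM"]
  expect_equal(unname(avg$theta["zp"]), w * 1 + (1 - w) * 0.5,
               tolerance = 1e-4)

  # single-model set: weight 1, averaged = that model's parameters
  avg1 <- average_models(list(OUM = list(f1)))
  expect_equal(avg1$table$weight, 1)
  expect_equal(unname(avg1$theta["zp"]), 1)
  expect_equal(unname(avg1$theta_se["zp"]), 0.1, tolerance = 1e-10)

  # weights invariant to a constant shift of all AICc values
  f1b <- mk_fit("OUM", 300, theta = c(bi = 0, zp = 1), alpha = 2)
  f2b <- mk_fit("OU1", 302, theta = c(bi = 0.5, zp = 0.5), alpha = 1)
  avg_b <- average_models(list(OUM = list(f1b), OU1 = list(f2b)),
                          level = 0.999)
  expect_equal(avg_b$table$weight, avg$table$weight, tolerance = 1e-12)

  # non-retained iterations are excluded before averaging
  f_bad <- mk_fit("OU1", 1, theta = c(bi = 9, zp = 9), alpha = 9)
  f_bad$retained <- FALSE
  avg_c <- average_models(list(OUM = list(f1), OU1 = list(f2, f_bad)),
                          level = 0.999)
  expect_equal(sort(avg_c$table$weight, decreasing = TRUE),
               c(0.7311, 0.2689), tolerance = 1e-4)

  # the confidence set is the smallest prefix reaching the level
  f3 <- mk_fit("BMS", 120, sigma2 = c(bi = 0.3, zp = 0.3))
  avg_d <- average_models(list(OUM = list(f1), OU1 = list(f2),
                               BMS = list(f3)), level = 0.95)
  expect_setequal(avg_d$confidence_set, c("OUM", "OU1"))
  expect_equal(sum(avg_d$table$adjusted_weight, na.rm = TRUE), 1)
})

test_that("Hessian screening flags saddle points", {
  pt <- fx_painted6()
  set.seed(65)
  y <- simulate_traits(pt, "BM1", list(sigma2 = 0.4, root = 1))[, 1]
  f <- fit_model(pt, y, "BM1")
  expect_true(f$retained)
  expect_true(all(f$hessian_eigen > -1e-8))
  expect_true(!is.null(f$se))
})
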