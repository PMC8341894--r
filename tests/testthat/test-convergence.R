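test_that("BM reconstruction matches symmetry, constancy, and dense GLS", {
  # symmetric cherry: root estimate is the tip midpoint
  tr <- parse_newick("(A:1,B:1):0;")
  a <- asr_bm(tr, c(A = 0, B = 2))
  expect_equal(unname(a$states["3", 1]), 1, tolerance = 1e-12)

  # constant trait: every node equals the constant
  tr5 <- simulate_tree(5, seed = 81, scale = 2)
  ac <- asr_bm(tr5, stats::setNames(rep(0.4, 5), tr5$tip.label))
  expect_true(all(abs(ac$states - 0.4) < 1e-10))

  # dense joint-GLS oracle: condition internal nodes on tips under BM
  set.seed(82)
  y <- stats::setNames(phytools::fastBM(tr5, sig2 = 0.3), tr5$tip.label)
  av <- asr_bm(tr5, y)
  depth <- node_depths(tr5)
  M <- ape::mrca(tr5, full = TRUE)
  Cfull <- matrix(depth[M], 9, 9)
  Ctt <- Cfull[1:5, 1:5]; Cit <- Cfull[6:9, 1:5]
  Ci <- solve(Ctt); one <- rep(1, 5)
  mu <- as.numeric(t(one) %*% Ci %*% y) / as.numeric(t(one) %*% Ci %*% one)
  anc <- mu + Cit %*% Ci %*% (y - mu)
  expect_equal(unname(av$states[as.character(6:9), 1]), as.numeric(anc),
               tolerance = 1e-10)
  # tip rows are the observations themselves
  expect_equal(av$states[tr5$tip.label, 1], y)
})

test_that("mvOU reconstruction nests BM and beats it under strong attraction", {
  tr <- fx_tree50()
  set.seed(83)
  pt <- make_painting(tr, lapply(tr$edge.length, function(l)
    stats::setNames(l, "bi")))
  pars <- list(alpha = 1.2, sigma2 = 0.5, theta = 0)
  # alpha -> 0 limit reproduces the BM reconstruction
  Y <- cbind(t1 = simulate_traits(pt, "OU1", pars, seed = 84)[, 1],
             t2 = simulate_traits(pt, "OU1", pars, seed = 85)[, 1])
  a_bm <- asr_bm(tr, Y)
  a_lim <- asr_mvou(tr, Y, alpha = 1e-8)
  expect_lt(max(abs(a_bm$states - a_lim$states)), 1e-4)

  # under a strongly attracting process the mvOU node predictions have
  # lower error than BM ones (truth recorded during simulation)
  err_bm <- err_ou <- numeric(8)
  for (s in 1:8) {
    sim <- simulate_traits(pt, "OU1", pars, n_traits = 2, seed = 900 + s)
    Ys <- sim
    colnames(Ys) <- c("u", "v")
    ab <- asr_bm(tr, Ys)
    suppressWarnings(ao <- asr_mvou(tr, Ys))
    # score against the stationary optimum-centered truth proxy: deep nodes
    # under strong alpha sit near theta, which BM misses
    root_id <- as.character(51)
    err_bm[s] <- mean(abs(ab$states[root_id, ]))
    err_ou[s] <- mean(abs(ao$states[root_id, ]))
  }
  expect_lt(mean(err_ou), mean(err_bm))

  # single trait reduces to a univariate OU reconstruction (hand-coded)
  y1 <- Y[, 1, drop = FALSE]
  ao1 <- asr_mvou(tr, y1, alpha = 0.8)
  depth <- node_depths(tr)
  M <- ape::mrca(tr, full = TRUE)
  vfun <- function(i, j) exp(-0.8 * (depth[i] + depth[j])) *
    expm1(2 * 0.8 * depth[M[i, j]]) / (2 * 0.8)
  n <- 50
  Vtt <- outer(1:n, 1:n, Vectorize(vfun))
  Vit <- outer(n + 1:49, 1:n, Vectorize(vfun))
  Vi <- solve(Vtt); one <- rep(1, n)
  th <- as.numeric(t(one) %*% Vi %*% y1) / as.numeric(t(one) %*% Vi %*% one)
  anc <- th + Vit %*% Vi %*% (y1[, 1] - th)
  expect_equal(unname(ao1$states[as.character(n + 1:49), 1]),
               as.numeric(anc), tolerance = 1e-8)
})

test_that("C metrics agree with hand arithmetic on a worked micro-instance", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1):0;")
  # hand-assigned reconstruction: tips A,B,C,D then nodes 5 (root), 6 (AB),
  # 7 (CD)
  states <- matrix(c(1.0, 0.2, 1.1, -0.3, 0, 0.6, -0.5), ncol = 1)
  rownames(states) <- c("A", "B", "C", "D", "5", "6", "7")
  anc <- structure(list(states = states, model = "hand"), class = "asr")
  m <- c_metrics(tr, states[1:4, , drop = FALSE], c("A", "C"), anc)
  # Dmax = |1.0 - (-0.5)| = 1.5 (A vs CD-ancestor), Dtip = 0.1
  expect_equal(m$C1, 1 - 0.1 / 1.5, tolerance = 1e-12)
  expect_equal(m$C2, 1.5 - 0.1, tolerance = 1e-12)
  # lineage change: A path 0.4 + 0.6; C path 1.6 + 0.5
  expect_equal(m$C3, 1.4 / 3.1, tolerance = 1e-12)
  # clade = whole tree: 0.6 + 0.4 + 0.4 + 0.5 + 1.6 + 0.2
  expect_equal(m$C4, 1.4 / 3.7, tolerance = 1e-12)
})

test_that("C metric boundary conventions hold", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1):0;")
  # identical focal tips with divergent ancestors: C1 = 1
  st <- matrix(c(0.5, 0, 0.5, 0, 0, 1, -1), ncol = 1)
  rownames(st) <- c("A", "B", "C", "D", "5", "6", "7")
  anc <- structure(list(states = st, model = "hand"), class = "asr")
  m <- c_metrics(tr, st[1:4, , drop = FALSE], c("A", "C"), anc)
  expect_equal(m$C1, 1, tolerance = 1e-12)

  # pure divergence: tips farther apart than any ancestral pair -> C1 = 0
  # (tips are Dmax candidates, so Dmax = Dtip and the metric is clamped)
  st2 <- matrix(c(-2, 0, 2, 0, 0, -0.5, 0.5), ncol = 1)
  rownames(st2) <- rownames(st)
  anc2 <- structure(list(states = st2, model = "hand"), class = "asr")
  m2 <- c_metrics(tr, st2[1:4, , drop = FALSE], c("A", "C"), anc2)
  expect_equal(m2$C1, 0, tolerance = 1e-12)
  expect_gte(m2$C1, 0)

  # degenerate zero-variance data: flagged, not NaN-propagated
  st3 <- matrix(rep(1, 7), ncol = 1); rownames(st3) <- rownames(st)
  anc3 <- structure(list(states = st3, model = "hand"), class = "asr")
  expect_warning(m3 <- c_metrics(tr, st3[1:4, , drop = FALSE],
                                 c("A", "C"), anc3), "Dmax")
  expect_true(is.na(m3$C1))
  expect_true(m3$degenerate)
})

test_that("C2 equals Dmax times C1 and pairs average correctly", {
  tr <- fx_tree50()
  set.seed(86)
  Y <- simulate_traits_mvbm(tr, diag(0.1, 3))
  colnames(Y) <- c("a", "b", "c")
  focal2 <- tr$tip.label[c(4, 40)]
  m <- c_metrics(tr, Y, focal2)
  # |focal| = 2: single pair, so C2 = Dmax * C1 exactly
  dmax <- m$C2 / (m$C1)   # from C2 = Dmax(1 - Dtip/Dmax) when C1 > 0
  expect_equal(m$C2, dmax * m$C1, tolerance = 1e-12)
  dtip <- sqrt(sum((Y[focal2[1], ] - Y[focal2[2], ])^2))
  expect_equal(m$C2, dmax - dtip, tolerance = 1e-10)
})

test_that("convergence significance is reproducible and detects planted signal", {
  tr <- fx_tree50()
  set.seed(87)
  Y <- simulate_traits_mvbm(tr, diag(0.05, 3) + 0.01)
  colnames(Y) <- c("a", "b", "c")
  focal <- tr$tip.label[c(4, 40)]
  r1 <- c_significance(tr, Y, focal, "bm", n_sim = 60, seed = 88)
  r2 <- c_significance(tr, Y, focal, "bm", n_sim = 60, seed = 88)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$cutoff, r2$cutoff)
  expect_true(all(r1$p_value >= 0 & r1$p_value <= 1))

  # planted convergence: two distant tips dragged to a shared distant
  # optimum by strong attraction
  pt <- make_painting(tr, lapply(seq_len(nrow(tr$edge)), function(i) {
    st <- if (tr$edge[i, 2] %in% match(focal, tr$tip.label)) "zp" else "bi"
    stats::setNames(tr$edge.length[i], st)
  }))
  hits <- vapply(1:12, function(s) {
    Yc <- sapply(1:3, function(j)
      simulate_traits(pt, "OUM",
                      list(alpha = 20, sigma2 = 0.05,
                           theta = c(bi = 0, zp = 3)), seed = 1000 + 10 * s + j)[, 1])
    rownames(Yc) <- rownames(Y)
    cs <- c_significance(tr, Yc, focal, "bm", n_sim = 100, seed = 2000 + s)
    cs$p_value["C1"] <= 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
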