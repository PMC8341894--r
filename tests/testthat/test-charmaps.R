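test_that("pruning likelihood matches trivial and closed-form cases", {
  Q <- two_state_q(0.4, 0.4, c("a", "b"))
  # a single observed tip (the other marginalized out as missing data)
  tr <- parse_newick("(A:1.3,B:1.3):0;")
  ll <- mk_loglik(tr, c(A = "a", B = NA), Q, root_prior = "uniform")
  # marginalizing B leaves P(A = a) = sum_r pi_r P_ra(t)
  P <- ape::matexpo(Q * 1.3)
  expect_equal(ll, log(0.5 * P[1, 1] + 0.5 * P[2, 1]), tolerance = 1e-12)

  # cherry, both tips observed: closed form sum_r pi_r P_r,sA P_r,sB
  ll2 <- mk_loglik(tr, c(A = "a", B = "b"), Q, root_prior = "uniform")
  expect_equal(ll2, log(0.5 * P[1, 1] * P[1, 2] + 0.5 * P[2, 1] * P[2, 2]),
               tolerance = 1e-10)
})

test_that("pruning equals brute-force enumeration on random small trees", {
  set.seed(21)
  for (rep in 1:6) {
    n <- sample(4:7, 1)
    k <- sample(2:3, 1)
    states <- letters[1:k]
    tr <- random_labelled_tree(n)
    Q <- matrix(stats::runif(k * k, 0.05, 0.5), k,
                dimnames = list(states, states))
    diag(Q) <- 0; diag(Q) <- -rowSums(Q)
    tips <- stats::setNames(sample(states, n, TRUE), tr$tip.label)
    prior <- stats::setNames(rep(1 / k, k), states)
    expect_equal(mk_loglik(tr, tips, Q, prior),
                 enum_mk_loglik(tr, tips, Q, prior), tolerance = 1e-10)
  }
})

test_that("ML fitting recovers rates and respects model nesting", {
  # degenerate: one observed state drives the rate to the lower bound
  tr <- simulate_tree(30, seed = 23, scale = 5)
  same <- stats::setNames(rep("a", 30), tr$tip.label)
  f0 <- fit_mk(tr, same, "ER", states = c("a", "b"))
  expect_lt(f0$rates[1], 1e-6)

  # parameter recovery: ER q = 0.5 on a 200-tip tree, median over replicates
  tr2 <- simulate_tree(200, seed = 24, scale = 2)
  Q <- two_state_q(0.5, 0.5, c("a", "b"))
  qh <- vapply(1:10, function(s) {
    tips <- simulate_discrete(tr2, Q, seed = 100 + s)$tip_states
    fit_mk(tr2, tips, "ER")$rates[1]
  }, 0)
  expect_lt(abs(stats::median(qh) - 0.5) / 0.5, 0.2)

  # nesting: ARD likelihood >= ER likelihood at the optimum
  tips <- simulate_discrete(tr2, Q, seed = 125)$tip_states
  fer <- fit_mk(tr2, tips, "ER")
  far <- fit_mk(tr2, tips, "ARD")
  expect_gte(far$loglik, fer$loglik - 1e-6)
})

test_that("maps with a zero generator are single-state with no transitions", {
  tr <- fx_tree6()
  Q <- matrix(c(-1e-9, 1e-9, 1e-9, -1e-9), 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  tips <- stats::setNames(rep("a", 6), tr$tip.label)
  maps <- sample_maps(tr, tips, Q, n_draws = 5, seed = 26)
  for (m in maps) {
    expect_equal(sum(count_transitions(m)), 0)
    expect_equal(unname(time_in_state(m)["a"]), sum(tr$edge.length))
  }
})

test_that("endpoint-conditioned path sampling matches rejection sampling", {
  # one branch, unequal endpoints: mean number of true state changes
  Q <- two_state_q(0.45, 0.25, c("a", "b"))
  tlen <- 2.0
  P <- ape::matexpo(Q * tlen)
  set.seed(27)
  env <- new.env(); env$pow <- list()
  nsamp <- 20000
  jumps_unif <- vapply(seq_len(nsamp), function(i)
    length(morphconv:::.sample_path(Q, tlen, 1L, 2L, P, env)) - 1L,
    0L)
  # oracle: forward-simulate unconditioned paths, keep those ending in b
  sim_fwd <- function() {
    s <- 1L; tcur <- 0; changes <- 0L
    repeat {
      w <- stats::rexp(1, -Q[s, s])
      if (tcur + w > tlen) break
      tcur <- tcur + w; s <- 3L - s; changes <- changes + 1L
    }
    c(s, changes)
  }
  rej <- replicate(60000, sim_fwd())
  keep <- rej[1, ] == 2L
  expect_gt(sum(keep), 5000)
  m1 <- mean(jumps_unif); m2 <- mean(rej[2, keep])
  se <- sqrt(stats::var(jumps_unif) / nsamp + stats::var(rej[2, keep]) / sum(keep))
  expect_lt(abs(m1 - m2), 4 * se)
  # parity: paths from a to b need an odd number of changes
  expect_true(all(jumps_unif %% 2 == 1))
})

test_that("sampled paintings reproduce tip states and marginal node posteriors", {
  tr <- fx_tree6()
  Q <- two_state_q(0.3, 0.2, c("a", "b"))
  set.seed(28)
  tips <- simulate_discrete(tr, Q)$tip_states
  maps <- sample_maps(tr, tips, Q, n_draws = 4000, seed = 29)
  for (m in maps[1:50])
    expect_identical(painting_tip_states(m)[names(tips)], tips)
  s <- summarize_maps(maps)
  marg <- ancestral_marginals(tr, tips, Q)
  mc_se <- sqrt(0.25 / length(maps))
  expect_lt(max(abs(s$node_posterior[7:11, ] - marg[7:11, ])), 5 * mc_se)
})

test_that("map summaries average hand-built paintings exactly", {
  p1 <- parse_simmap("(A:{bi,1.0},B:{bi,0.5:zp,0.5}):0;")
  p2 <- parse_simmap("(A:{zp,0.25:bi,0.75},B:{bi,1.0}):0;")
  s <- summarize_maps(list(p1, p2))
  expect_equal(s$mean_transitions, 1)        # (1 + 1) / 2
  expect_equal(unname(s$mean_transition_matrix["bi", "zp"]), 0.5)
  expect_equal(unname(s$mean_transition_matrix["zp", "bi"]), 0.5)
  expect_equal(unname(s$time_fraction["zp"]), (0.25 + 0.125) / 2)
  expect_equal(sum(s$time_fraction), 1)
  expect_equal(sum(s$transition_pct), 100)

  # single single-state map
  s1 <- summarize_maps(list(parse_simmap("(A:{bi,1.0},B:{bi,1.0}):0;")))
  expect_equal(s1$mean_transitions, 0)
  expect_equal(unname(s1$time_fraction["bi"]), 1)

  expect_error(summarize_maps(list()), "empty")
})

test_that("mean transition counts agree with the generator expectation", {
  f <- make_fixture("paper-like")
  Q <- f$truth$Q
  maps <- sample_maps(f$tree, f$tip_states, Q, n_draws = 60, seed = 30)
  s <- summarize_maps(maps)
  expected <- mean(vapply(maps, expected_transitions, 0, Q = Q))
  counts <- vapply(maps, function(m) sum(count_transitions(m)), 0)
  se <- stats::sd(counts) / sqrt(length(maps))
  expect_lt(abs(s$mean_transitions - expected), 4 * se + 1)
})
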