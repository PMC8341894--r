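# Shared small fixtures, built in code. Generation is seeded so every test
# sees the same objects; anything expensive is memoized per test run.

two_state_q <- function(q12 = 0.2, q21 = 0.3, states = c("bi", "zp")) {
  Q <- matrix(c(-q12, q12, q21, -q21), 2, byrow = TRUE,
              dimnames = list(states, states))
  Q
}

fx <- local({
  cache <- new.env(parent = emptyenv())
  function(name, builder) {
    if (!exists(name, cache)) assign(name, builder(), cache)
    get(name, cache)
  }
})

fx_tree6 <- function() fx("tree6", function() simulate_tree(6, seed = 11, scale = 5))
fx_tree50 <- function() fx("tree50", function() simulate_tree(50, seed = 31, scale = 10))

fx_painted6 <- function() fx("painted6", function() {
  simulate_discrete(fx_tree6(), two_state_q(), seed = 3)$painting
})

# 150-tip two-regime painted tree used by the recovery checks
fx_painted150 <- function() fx("painted150", function() {
  tr <- simulate_tree(150, seed = 21, scale = 3)
  simulate_discrete(tr, two_state_q(0.1, 0.15), seed = 22)$painting
})

# brute-force Mk likelihood by enumeration over internal node states
enum_mk_loglik <- function(tree, tip_states, Q, prior) {
  states <- rownames(Q)
  k <- length(states)
  n <- length(tree$tip.label)
  P <- lapply(seq_len(nrow(tree$edge)),
              function(i) ape::matexpo(Q * tree$edge.length[i]))
  nint <- tree$Nnode
  tot <- 0
  for (comb in 0:(k^nint - 1)) {
    assign_int <- (comb %/% k^(0:(nint - 1))) %% k + 1
    ns <- c(match(tip_states[tree$tip.label], states), assign_int)
    pr <- prior[ns[n + 1]]
    for (i in seq_len(nrow(tree$edge)))
      pr <- pr * P[[i]][ns[tree$edge[i, 1]], ns[tree$edge[i, 2]]]
    tot <- tot + pr
  }
  unname(log(tot))
}

# direct dense-matrix GLS, the linear-algebra oracle for PGLS/ASR checks
dense_gls <- function(C, X, y) {
  Ci <- solve(C)
  beta <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y)
  as.numeric(beta)
}

random_labelled_tree <- function(n, labels = NULL) {
  tr <- simulate_tree(n, seed = NULL, scale = 1)
  if (!is.null(labels)) tr$tip.label <- labels
  tr
}
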