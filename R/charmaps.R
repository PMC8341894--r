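#' @title Mk models and stochastic character maps
#' @name charmaps
#' @description
#' Discrete foraging-regime histories are modelled as a continuous-time
#' Markov chain (Mk model) on the tree. The likelihood is computed by
#' Felsenstein pruning with per-branch matrix exponentials; maps are drawn
#' empirical-Bayes style: node states are sampled from their joint
#' conditional distribution given the tip data, then each branch's path is
#' sampled from the endpoint-conditioned CTMC by uniformization.
NULL

## per-tree pruning workspace --------------------------------------------------

.mk_prep <- function(tree, tip_states, Q) {
  states <- rownames(Q)
  n <- length(tree$tip.label)
  k <- length(states)
  if (is.null(names(tip_states))) names(tip_states) <- tree$tip.label
  obs <- tip_states[tree$tip.label]
  bad <- setdiff(stats::na.omit(unique(obs)), states)
  if (length(bad)) stop("state(s) not in alphabet: ", paste(bad, collapse = ", "))
  L <- matrix(1, n + tree$Nnode, k)        # partial likelihoods
  for (i in seq_len(n)) if (!is.na(obs[i])) L[i, ] <- as.numeric(states == obs[i])
  po <- reorder(tree, "postorder")
  eord <- match(paste(po$edge[, 1], po$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  list(states = states, n = n, k = k, L = L, edge_post = eord)
}

#' Mk log-likelihood by pruning
#'
#' @param tree a validated `phylo`.
#' @param tip_states named character vector of tip states; `NA` means
#'   missing (uniform partial likelihood).
#' @param Q generator matrix with state dimnames.
#' @param root_prior `"stationary"` (default), `"uniform"`, or a named
#'   probability vector over states.
#' @return the log-likelihood (sum over root states of the prior times the
#'   conditional likelihood of the tip data).
#' @export
mk_loglik <- function(tree, tip_states, Q, root_prior = "stationary") {
  validate_tree(tree); validate_q(Q)
  w <- .mk_prep(tree, tip_states, Q)
  prior <- .mk_root_prior(root_prior, Q)
  res <- .mk_pruning(tree, w, Q)
  lik <- sum(prior * res$L[w$n + 1L, ])
  if (lik <= 0) return(-Inf)
  log(lik) + res$logZ
}

.mk_root_prior <- function(root_prior, Q) {
  states <- rownames(Q)
  if (is.character(root_prior) && length(root_prior) == 1) {
    if (root_prior == "stationary") return(stationary_distribution(Q))
    if (root_prior == "uniform")
      return(stats::setNames(rep(1 / length(states), length(states)), states))
    stop("unknown root prior: ", root_prior)
  }
  if (abs(sum(root_prior) - 1) > 1e-8) stop("root prior must sum to 1")
  root_prior[states]
}

.mk_pruning <- function(tree, w, Q, keep_P = FALSE) {
  L <- w$L; logZ <- 0
  Ps <- if (keep_P) vector("list", nrow(tree$edge)) else NULL
  for (i in w$edge_post) {
    P <- ape::matexpo(Q * tree$edge.length[i])
    if (keep_P) Ps[[i]] <- P
    contrib <- as.numeric(P %*% L[tree$edge[i, 2], ])
    s <- sum(contrib)
    if (s <= 0) return(list(L = L, logZ = -Inf, P = Ps))
    logZ <- logZ + log(s)
    L[tree$edge[i, 1], ] <- L[tree$edge[i, 1], ] * (contrib / s)
  }
  list(L = L, logZ = logZ, P = Ps)
}

#' Marginal ancestral state probabilities under an Mk model
#'
#' Standard down-pass/up-pass marginals; binary trees only.
#'
#' @inheritParams mk_loglik
#' @return matrix (nodes x states) of marginal posterior probabilities;
#'   rows for tips are their observed indicators.
#' @export
ancestral_marginals <- function(tree, tip_states, Q,
                                root_prior = "stationary") {
  validate_tree(tree); validate_q(Q)
  w <- .mk_prep(tree, tip_states, Q)
  prior <- .mk_root_prior(root_prior, Q)
  res <- .mk_pruning(tree, w, Q, keep_P = TRUE)
  n <- w$n; k <- w$k
  nn <- n + tree$Nnode
  # per-edge contribution vectors (at the parent), recomputed unnormalized
  contrib <- vector("list", nrow(tree$edge))
  for (i in seq_len(nrow(tree$edge)))
    contrib[[i]] <- as.numeric(res$P[[i]] %*% res$L[tree$edge[i, 2], ])
  up <- matrix(NA_real_, nn, k)
  up[n + 1L, ] <- prior
  pre <- rev(w$edge_post)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  for (i in pre) {
    u <- tree$edge[i, 1]; v <- tree$edge[i, 2]
    sibs <- setdiff(kids[[as.character(u)]], i)
    excl <- up[u, ]
    for (j in sibs) excl <- excl * contrib[[j]]
    up[v, ] <- as.numeric(t(res$P[[i]]) %*% excl)
  }
  marg <- up * res$L[seq_len(nn), ]
  marg <- marg / rowSums(marg)
  dimnames(marg) <- list(NULL, w$states)
  marg
}

## ---- ML fitting -------------------------------------------------------------

.mk_build_q <- function(rates, k, states, model) {
  Q <- matrix(0, k, k, dimnames = list(states, states))
  idx <- which(row(Q) != col(Q))
  if (model == "ER") {
    Q[idx] <- rates[1]
  } else if (model == "ARD") {
    Q[idx] <- rates
  } else { # SYM
    m <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      m <- m + 1
      Q[i, j] <- rates[m]; Q[j, i] <- rates[m]
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

.mk_npar <- function(model, k)
  switch(model, ER = 1L, SYM = as.integer(k * (k - 1) / 2),
         ARD = as.integer(k * (k - 1)))

#' Fit an Mk model by maximum likelihood
#'
#' Rates are optimized on the log scale (bounded quasi-Newton, three
#' deterministic starting magnitudes around a parsimony-flavoured initial
#' rate).
#'
#' @inheritParams mk_loglik
#' @param model rate-matrix symmetry class: `"ER"`, `"SYM"`, or `"ARD"`.
#' @param states optional state alphabet; defaults to the observed states.
#' @return list with `Q` (ML generator), `loglik`, `model`, `rates`,
#'   `convergence` (0 means converged), and `root_prior`.
#' @export
fit_mk <- function(tree, tip_states, model = c("ER", "SYM", "ARD"),
                   root_prior = "stationary", states = NULL) {
  model <- match.arg(model)
  validate_tree(tree)
  if (is.null(names(tip_states))) names(tip_states) <- tree$tip.label
  if (is.null(states)) states <- sort(unique(stats::na.omit(tip_states)))
  k <- length(states)
  if (k < 2) {
    # degenerate: a single observed state pins every rate at the lower bound
    Q <- matrix(0, 1, 1, dimnames = list(states, states))
    return(list(Q = Q, loglik = 0, model = model, rates = numeric(0),
                convergence = 0L, root_prior = root_prior))
  }
  npar <- .mk_npar(model, k)
  tlen <- sum(tree$edge.length)
  r0 <- max(length(unique(stats::na.omit(tip_states))) - 1, 1) / tlen
  nll <- function(lr) {
    Q <- .mk_build_q(exp(lr), k, states, model)
    ll <- mk_loglik(tree, tip_states, Q, root_prior)
    if (!is.finite(ll)) 1e10 else -ll
  }
  lower <- rep(log(1e-9), npar); upper <- rep(log(1e3 / mean(tree$edge.length)), npar)
  ## the Mk likelihood flattens at high rates (saturation plateau); scan a
  ## deterministic log-spaced grid first so quasi-Newton starts near the
  ## interior optimum rather than overshooting onto the plateau
  grid <- exp(seq(log(max(r0 * 1e-2, 1e-8)),
                  log(10 / mean(tree$edge.length)), length.out = 12))
  gval <- vapply(grid, function(r) nll(rep(log(r), npar)), 0)
  starts <- grid[order(gval)][1:3]
  best <- NULL
  for (r_st in starts) {
    st <- rep(log(r_st), npar)
    fit <- tryCatch(
      stats::optim(st, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("Mk optimization failed from every start")
  Q <- .mk_build_q(exp(best$par), k, states, model)
  list(Q = Q, loglik = -best$value, model = model, rates = exp(best$par),
       convergence = best$convergence, root_prior = root_prior)
}

## ---- stochastic mapping -----------------------------------------------------

## endpoint-conditioned CTMC path on one branch, by uniformization.
## Returns a named duration vector (rootward to tipward).
.sample_path <- function(Q, t, a, b, P, Rpow_env, max_jumps = 10000L) {
  states <- rownames(Q)
  k <- length(states)
  Omega <- max(-diag(Q))
  if (Omega <= 0 || t <= 0) return(stats::setNames(t, states[a]))
  R <- diag(k) + Q / Omega
  # grow cached powers of R in Rpow_env$pow as needed
  pw <- function(m) {
    if (m == 0) return(diag(k))
    while (length(Rpow_env$pow) < m)
      Rpow_env$pow[[length(Rpow_env$pow) + 1L]] <-
        if (length(Rpow_env$pow) == 0) R else Rpow_env$pow[[length(Rpow_env$pow)]] %*% R
    Rpow_env$pow[[m]]
  }
  lt <- Omega * t
  logdenom <- log(P[a, b])
  u <- stats::runif(1)
  acc <- 0; nj <- -1L
  for (m in 0:max_jumps) {
    pm <- exp(-lt + m * log(lt) - lgamma(m + 1) + log(pw(m)[a, b]) - logdenom)
    acc <- acc + pm
    if (u <= acc) { nj <- m; break }
  }
  if (nj < 0L) stop("endpoint-conditioned sampling exceeded jump cap")
  if (nj == 0L) return(stats::setNames(t, states[a]))
  seq_states <- integer(nj + 1); seq_states[1] <- a; seq_states[nj + 1] <- b
  if (nj > 1) for (i in 2:nj) {
    prev <- seq_states[i - 1]
    wts <- R[prev, ] * pw(nj + 1 - i)[, b]
    seq_states[i] <- sample.int(k, 1, prob = wts)
  }
  times <- sort(stats::runif(nj)) * t
  # collapse virtual (self) jumps into segments
  seg_s <- integer(0); seg_d <- numeric(0)
  cur <- a; t0 <- 0
  for (i in seq_len(nj)) {
    if (seq_states[i + 1] != cur) {
      seg_s <- c(seg_s, cur); seg_d <- c(seg_d, times[i] - t0)
      t0 <- times[i]; cur <- seq_states[i + 1]
    }
  }
  seg_s <- c(seg_s, cur); seg_d <- c(seg_d, t - t0)
  stats::setNames(seg_d, states[seg_s])
}

#' Draw stochastic character maps
#'
#' For each draw, samples all node states from their joint conditional
#' distribution given the tips (pre-order sweep over pruning partials),
#' then samples an endpoint-conditioned path on every branch by
#' uniformization. Every returned painting reproduces the observed tip
#' states exactly.
#'
#' @inheritParams mk_loglik
#' @param n_draws number of maps.
#' @param seed optional integer seed.
#' @param rate_gamma optional length-2 vector `c(shape, rate)`; when given,
#'   each draw multiplies `Q` by an overall rate factor drawn from this
#'   Gamma distribution (mean `shape/rate`), an approximation to rate-prior
#'   mapping. Default `NULL` uses `Q` as is (empirical Bayes).
#' @return list of `simmap` paintings.
#' @export
sample_maps <- function(tree, tip_states, Q, n_draws = 1,
                        root_prior = "stationary", seed = NULL,
                        rate_gamma = NULL) {
  validate_tree(tree); validate_q(Q)
  stopifnot(n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  states <- rownames(Q)
  n <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  out <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    Qd <- if (is.null(rate_gamma)) Q
          else Q * stats::rgamma(1, rate_gamma[1], rate_gamma[2])
    w <- .mk_prep(tree, tip_states, Qd)
    prior <- .mk_root_prior(root_prior, Qd)
    res <- .mk_pruning(tree, w, Qd, keep_P = TRUE)
    if (!is.finite(res$logZ)) stop("tip data impossible under Q")
    node_state <- integer(n + tree$Nnode)
    pr <- prior * res$L[n + 1L, ]
    node_state[n + 1L] <- sample.int(w$k, 1, prob = pr)
    for (i in rev(w$edge_post)) {            # preorder
      u <- tree$edge[i, 1]; v <- tree$edge[i, 2]
      pv <- res$P[[i]][node_state[u], ] * res$L[v, ]
      node_state[v] <- sample.int(w$k, 1, prob = pv)
    }
    Rpow_env <- new.env(parent = emptyenv()); Rpow_env$pow <- list()
    maps <- vector("list", nrow(tree$edge))
    for (i in seq_len(nrow(tree$edge)))
      maps[[i]] <- .sample_path(Qd, tree$edge.length[i],
                                node_state[tree$edge[i, 1]],
                                node_state[tree$edge[i, 2]],
                                res$P[[i]], Rpow_env)
    out[[d]] <- make_painting(tree, maps, alphabet = states)
  }
  out
}

#' Summarize a set of stochastic character maps
#'
#' @param maps list of `simmap` paintings sharing one topology.
#' @return list with `mean_transitions` (total), `mean_transition_matrix`
#'   (per ordered pair), `transition_pct` (each ordered pair's mean count as
#'   a percentage of the mean total), `time_fraction` (mean fraction of
#'   total tree time per state), `node_posterior` (nodes x states frequency
#'   of node states across maps), and `n_maps`.
#' @export
summarize_maps <- function(maps) {
  if (!length(maps)) stop("empty map set")
  e1 <- maps[[1]]$edge
  for (m in maps)
    if (!identical(m$edge, e1) ||
        !identical(m$tip.label, maps[[1]]$tip.label))
      stop("maps do not share a topology")
  states <- sort(unique(unlist(lapply(maps, function(m) colnames(m$mapped.edge)))))
  k <- length(states)
  cnt <- matrix(0, k, k, dimnames = list(states, states))
  tis <- stats::setNames(rep(0, k), states)
  n_nodes <- length(maps[[1]]$tip.label) + maps[[1]]$Nnode
  post <- matrix(0, n_nodes, k, dimnames = list(NULL, states))
  for (m in maps) {
    cm <- count_transitions(m)
    cnt[rownames(cm), colnames(cm)] <- cnt[rownames(cm), colnames(cm)] + cm
    ti <- time_in_state(m)
    tis[names(ti)] <- tis[names(ti)] + ti / sum(ti)
    ns <- painting_node_states(m)
    post[cbind(seq_len(n_nodes), match(ns, states))] <-
      post[cbind(seq_len(n_nodes), match(ns, states))] + 1
  }
  nm <- length(maps)
  mean_mat <- cnt / nm
  total <- sum(mean_mat)
  pct <- if (total > 0) 100 * mean_mat / total else mean_mat
  list(mean_transitions = total,
       mean_transition_matrix = mean_mat,
       transition_pct = pct,
       time_fraction = tis / nm,
       node_posterior = post / nm,
       n_maps = nm)
}
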