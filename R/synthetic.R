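#' @title Synthetic trees, regime histories, and traits
#' @name synthetic
#' @description
#' Generators with known truth for every downstream stage: taxa-conditioned
#' birth-death trees, continuous-time Markov (CTMC) regime histories painted
#' onto branches, and continuous traits evolving by exact Gaussian
#' transition sampling under single- or multi-regime Brownian motion (BM)
#' and Ornstein-Uhlenbeck (OU) models. No Euler discretization anywhere:
#' both processes have closed-form transition kernels and are sampled
#' segment by segment.
NULL

#' Validate a CTMC generator matrix
#'
#' @param Q square matrix with non-negative off-diagonals and zero row sums;
#'   dimnames give the state alphabet.
#' @return `Q`, invisibly.
#' @export
validate_q <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) stop("Q must be square")
  if (is.null(rownames(Q))) stop("Q must carry state names as dimnames")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("Q off-diagonals must be non-negative")
  if (any(abs(rowSums(Q)) > 1e-8 * max(abs(Q), 1)))
    stop("Q rows must sum to zero")
  invisible(Q)
}

#' Stationary distribution of a CTMC generator
#'
#' @param Q a validated generator matrix.
#' @return named probability vector solving pi Q = 0.
#' @export
stationary_distribution <- function(Q) {
  validate_q(Q)
  ev <- eigen(t(Q))
  v <- abs(Re(ev$vectors[, which.min(abs(ev$values))]))
  stats::setNames(v / sum(v), rownames(Q))
}

#' Simulate an ultrametric birth-death tree with a fixed number of tips
#'
#' Thin, validated wrapper over [phytools::pbtree()] (taxa-stop simulation,
#' extant tips only), with an internal retry cap when extinction prevents
#' reaching `n_tips`.
#'
#' @param n_tips number of extant tips (>= 2).
#' @param birth,death per-lineage speciation and extinction rates
#'   (death < birth).
#' @param scale if non-NULL, rescale the tree to this root-to-tip height
#'   (millions of years).
#' @param seed optional integer seed; the draw is reproducible given it.
#' @param max_tries retry cap before erroring.
#' @return a validated ultrametric `phylo` with exactly `n_tips` tips.
#' @export
simulate_tree <- function(n_tips, birth = 1, death = 0, scale = NULL,
                          seed = NULL, max_tries = 1000) {
  stopifnot(n_tips >= 2, birth > 0, death >= 0, death < birth)
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(max_tries)) {
    tr <- tryCatch(
      phytools::pbtree(b = birth, d = death, n = n_tips, scale = scale,
                       extant.only = TRUE, quiet = TRUE),
      error = function(e) NULL)
    if (!is.null(tr) && length(tr$tip.label) == n_tips) {
      validate_tree(tr)
      return(tr)
    }
  }
  stop("failed to obtain ", n_tips, " extant tips in ", max_tries, " tries")
}

#' Simulate a discrete regime history on a tree
#'
#' Draws the root state from `root_prior`, then evolves the CTMC forward
#' along every branch (preorder), recording the full segment history as a
#' regime painting. Tip states are the tipward segment state of each
#' terminal branch.
#'
#' @param tree a validated `phylo`.
#' @param Q generator matrix (states as dimnames).
#' @param root_prior named probability vector over states; default is the
#'   stationary distribution of `Q`.
#' @param seed optional integer seed.
#' @return list with `tip_states` (named character) and `painting`
#'   (a `simmap` object holding the true history).
#' @export
simulate_discrete <- function(tree, Q, root_prior = NULL, seed = NULL) {
  validate_tree(tree)
  validate_q(Q)
  if (!is.null(seed)) set.seed(seed)
  states <- rownames(Q)
  if (is.null(root_prior)) root_prior <- stationary_distribution(Q)
  if (abs(sum(root_prior) - 1) > 1e-8) stop("root_prior must sum to 1")
  root_prior <- root_prior[states]
  n <- length(tree$tip.label)
  node_state <- character(n + tree$Nnode)
  root <- n + 1L
  node_state[root] <- sample(states, 1, prob = root_prior)
  ord <- reorder(tree, "cladewise")
  maps <- vector("list", nrow(tree$edge))
  edge_ord <- match(paste(ord$edge[, 1], ord$edge[, 2]),
                    paste(tree$edge[, 1], tree$edge[, 2]))
  for (j in seq_len(nrow(ord$edge))) {
    i <- edge_ord[j]
    s <- node_state[tree$edge[i, 1]]
    left <- tree$edge.length[i]
    seg_s <- character(0); seg_d <- numeric(0)
    repeat {
      rate <- -Q[s, s]
      wait <- if (rate > 0) stats::rexp(1, rate) else Inf
      if (wait >= left) {
        seg_s <- c(seg_s, s); seg_d <- c(seg_d, left)
        break
      }
      seg_s <- c(seg_s, s); seg_d <- c(seg_d, wait)
      left <- left - wait
      p <- Q[s, ]; p[s] <- 0
      s <- sample(states, 1, prob = p)
    }
    maps[[i]] <- stats::setNames(seg_d, seg_s)
    node_state[tree$edge[i, 2]] <- s
  }
  painting <- make_painting(tree, maps, alphabet = states)
  list(tip_states = stats::setNames(node_state[seq_len(n)], tree$tip.label),
       painting = painting)
}

## regime-resolved parameter lookup: scalar applies to every state
.par_for <- function(p, state) {
  if (length(p) == 1 && is.null(names(p))) return(unname(p))
  if (!state %in% names(p)) stop("missing parameter for regime '", state, "'")
  unname(p[[state]])
}

#' Simulate continuous traits on a regime-painted tree
#'
#' Exact transition sampling, segment by segment along every branch:
#' a BM segment of duration `dt` in regime `s` draws from
#' `N(x, sigma2_s * dt)`; an OU segment draws from
#' `N(theta_s + (x - theta_s) exp(-alpha dt),
#'    sigma2_s (1 - exp(-2 alpha dt)) / (2 alpha))`.
#' Traits are independent given the painting (one column per trait).
#'
#' @param pt a validated `simmap` painting.
#' @param model one of `"BM1"`, `"BMS"`, `"OU1"`, `"OUM"`, `"OUMV"`.
#' @param params list with elements as the model requires: `sigma2` (scalar,
#'   or named per regime for BMS/OUMV), `alpha` (OU models), `theta` (scalar
#'   for OU1, named per regime for OUM/OUMV), and optional `root` (ancestral
#'   trait value; default 0 for BM models, the root-regime `theta` for OU).
#' @param n_traits number of independent replicate traits to simulate.
#' @param seed optional integer seed.
#' @return matrix of tip values (`n_tips` x `n_traits`) with tip labels as
#'   row names.
#' @export
simulate_traits <- function(pt, model = c("BM1", "BMS", "OU1", "OUM", "OUMV"),
                            params, n_traits = 1, seed = NULL) {
  model <- match.arg(model)
  validate_painting(pt)
  if (!is.null(seed)) set.seed(seed)
  is_ou <- model %in% c("OU1", "OUM", "OUMV")
  alpha <- if (is_ou) params$alpha else 0
  if (is_ou && (is.null(alpha) || alpha < 0)) stop("OU models need alpha >= 0")
  sigma2 <- params$sigma2
  if (is.null(sigma2)) stop("params$sigma2 is required")
  n <- length(pt$tip.label)
  root <- n + 1L
  root_state <- painting_node_states(pt)[root]
  x0 <- params$root
  if (is.null(x0))
    x0 <- if (is_ou) .par_for(params$theta, root_state) else 0
  X <- matrix(NA_real_, n + pt$Nnode, n_traits)
  X[root, ] <- x0
  ord <- reorder(pt, "cladewise")
  edge_ord <- match(paste(ord$edge[, 1], ord$edge[, 2]),
                    paste(pt$edge[, 1], pt$edge[, 2]))
  for (j in seq_along(edge_ord)) {
    i <- edge_ord[j]
    x <- X[pt$edge[i, 1], ]
    m <- pt$maps[[i]]
    for (k in seq_along(m)) {
      s <- names(m)[k]; dt <- m[[k]]
      s2 <- .par_for(sigma2, s)
      if (s2 <= 0) {
        if (s2 < 0) stop("sigma2 must be positive")
        v <- 0
      }
      if (is_ou && alpha > 0) {
        th <- .par_for(params$theta, s)
        decay <- exp(-alpha * dt)
        v <- s2 * -expm1(-2 * alpha * dt) / (2 * alpha)
        x <- th + (x - th) * decay +
          stats::rnorm(n_traits, 0, sqrt(v))
      } else {
        x <- x + stats::rnorm(n_traits, 0, sqrt(s2 * dt))
      }
    }
    X[pt$edge[i, 2], ] <- x
  }
  out <- X[seq_len(n), , drop = FALSE]
  rownames(out) <- pt$tip.label
  out
}

#' Simulate correlated traits under multivariate Brownian motion
#'
#' Tip values have covariance `kronecker(R, C)` with `C` the unit-rate BM
#' tip covariance of the tree (shared path lengths) and `R` the evolutionary
#' trait covariance. Used as the simulation null for the convergence tests.
#'
#' @param tree a validated `phylo`.
#' @param R trait covariance matrix (p x p, possibly with trait dimnames).
#' @param root ancestral mean, recycled over traits.
#' @param seed optional integer seed.
#' @return `n_tips` x `p` matrix of tip values.
#' @export
simulate_traits_mvbm <- function(tree, R, root = 0, seed = NULL) {
  validate_tree(tree)
  if (!is.null(seed)) set.seed(seed)
  C <- ape::vcv(tree)
  LC <- t(chol(C))
  LR <- chol(R)
  n <- nrow(C); p <- nrow(R)
  Y <- LC %*% matrix(stats::rnorm(n * p), n, p) %*% LR
  Y <- sweep(Y, 2, rep_len(root, p), "+")
  rownames(Y) <- rownames(C)
  colnames(Y) <- colnames(R)
  Y
}

#' The regime generator used by the paper-like preset
#'
#' Relative rates are concentrated among the three benthic modes, with
#' rarer gains of zooplanktivory (mostly from benthic invertivory) and fast
#' reversal, so that at stationarity roughly 10 percent of transitions are
#' zooplanktivory gains and the dwell fraction in that regime is a few
#' percent. `rate_scale` multiplies the whole matrix.
#'
#' @param rate_scale overall rate multiplier (transitions per million
#'   years scale).
#' @return a 4-state generator matrix over `bi`, `fc`, `oc`, `zp`.
#' @export
preset_regime_q <- function(rate_scale = 1) {
  states <- c("bi", "fc", "oc", "zp")
  Q <- matrix(0, 4, 4, dimnames = list(states, states))
  Q["bi", "fc"] <- 0.30; Q["fc", "bi"] <- 0.30
  Q["fc", "oc"] <- 0.20; Q["oc", "fc"] <- 0.20
  Q["bi", "oc"] <- 0.05; Q["oc", "bi"] <- 0.05
  Q["bi", "zp"] <- 0.10; Q["fc", "zp"] <- 0.02; Q["oc", "zp"] <- 0.01
  Q["zp", "bi"] <- 0.65; Q["zp", "oc"] <- 0.20
  diag(Q) <- -rowSums(Q)
  Q * rate_scale
}

#' Expected number of regime transitions of a painting's generating process
#'
#' Sums, over branches and states, the expected time in each state times
#' that state's leaving rate, using the realized painting as the time-in-
#' state expectation.
#'
#' @param pt a `simmap` painting.
#' @param Q the generator that produced it.
#' @return expected transition count (numeric).
#' @export
expected_transitions <- function(pt, Q) {
  validate_q(Q)
  tis <- time_in_state(pt)
  sum(tis[rownames(Q)] * -diag(Q))
}

#' Count independent origins of a state on a painting
#'
#' An origin is a maximal connected set of tree points in the focal state
#' that contains at least one tip; equivalently, the number of distinct
#' into-state transition events (or a root start) ancestral to tips in the
#' state.
#'
#' @param pt a `simmap` painting.
#' @param state focal state.
#' @return integer count of independent origins leading to extant tips.
#' @export
count_origins <- function(pt, state) {
  n <- length(pt$tip.label)
  node_state <- painting_node_states(pt)
  tip_in <- which(node_state[seq_len(n)] == state)
  if (!length(tip_in)) return(0L)
  parent <- integer(n + pt$Nnode)
  parent[pt$edge[, 2]] <- pt$edge[, 1]
  # entry point of the state run containing each focal tip: walk rootward
  # while the lineage stays in the state through the whole parent edge
  edge_of <- integer(n + pt$Nnode)
  edge_of[pt$edge[, 2]] <- seq_len(nrow(pt$edge))
  entry <- integer(0)
  for (tip in tip_in) {
    v <- tip
    repeat {
      e <- edge_of[v]
      m <- pt$maps[[e]]
      run <- rev(names(m))
      if (run[1] != state) break          # degenerate zero-length run
      if (any(run != state)) {            # state entered on this edge
        # index of the last into-state boundary on this edge
        k <- max(which(names(m) != state))
        entry_id <- paste0("e", e, ".", k)
        break
      }
      v <- parent[v]
      if (v == n + 1L) { entry_id <- "root"; break }
      if (node_state[v] != state) { entry_id <- paste0("n", v); break }
    }
    entry <- c(entry, entry_id)
  }
  length(unique(entry))
}

#' Built-in synthetic study presets
#'
#' `"cherry-min"` is a two-tip, one-trait smoke fixture. `"paper-like"`
#' emulates the study conditions: a 79-tip ultrametric tree of height 42
#' (millions of years), a 4-state foraging regime history whose generator
#' is scaled so the expected number of transitions over the realized tree
#' is 28, and 8 continuous traits (7 log-scale linear measurements plus
#' log maximum body size) built from an allometric slope on a Brownian
#' log standard length plus regime-dependent residual processes with known
#' optima. The preset seed is part of the preset definition, chosen so the
#' truth painting shows several independent zooplanktivory origins among a
#' handful of zp tips, as in the study system.
#'
#' @param name preset id: `"cherry-min"` or `"paper-like"`.
#' @param seed integer seed; defaults to the preset's canonical seed.
#' @param out_dir if non-NULL, write `tree.nwk`, `painting.simmap`,
#'   `states.csv`, `traits.csv`, and `truth.json` there.
#' @return list with `tree`, `painting`, `tip_states`, `traits` (data frame,
#'   species in rows), and `truth` (generating parameters).
#' @export
make_fixture <- function(name = c("paper-like", "cherry-min"), seed = NULL,
                         out_dir = NULL) {
  name <- match.arg(name)
  if (name == "cherry-min") {
    if (is.null(seed)) seed <- 1L
    set.seed(seed)
    tree <- parse_newick("(A:1,B:1):0;")
    maps <- list(stats::setNames(1, "bi"), stats::setNames(1, "bi"))
    painting <- make_painting(tree, maps, alphabet = "bi")
    sigma2 <- 1
    y <- simulate_traits(painting, "BM1", list(sigma2 = sigma2, root = 0))
    traits <- data.frame(species = tree$tip.label, trait1 = as.numeric(y))
    truth <- list(preset = name, seed = seed, model = "BM1",
                  sigma2 = sigma2, root = 0)
    tip_states <- painting_tip_states(painting)
  } else {
    if (is.null(seed)) seed <- 2026L
    set.seed(seed)
    tree <- simulate_tree(79, birth = 1, death = 0, scale = 42)
    Qrel <- preset_regime_q(1)
    pi0 <- stationary_distribution(Qrel)
    flux <- sum(pi0 * -diag(Qrel))
    rate_scale <- 28 / (sum(tree$edge.length) * flux)
    Q <- preset_regime_q(rate_scale)
    # condition the regime draw on the documented preset features:
    # >= 3 independent zp origins among >= 4 zp tips
    for (try in 1:200) {
      hist <- simulate_discrete(tree, Q)
      nzp <- sum(hist$tip_states == "zp")
      if (nzp >= 4 && count_origins(hist$painting, "zp") >= 3) break
    }
    painting <- hist$painting
    tip_states <- hist$tip_states
    trait_names <- c("eye_diameter", "ascending_process", "mouth_width",
                     "head_width", "body_depth", "body_width",
                     "caudal_fin_ratio", "max_body_size")
    # log10 standard length evolves by BM around 2 (= 100 mm)
    sl <- simulate_traits(painting, "BM1",
                          list(sigma2 = 0.002, root = 2))[, 1]
    theta0 <- stats::setNames(rep(0, 4), c("bi", "fc", "oc", "zp"))
    resid_models <- list(
      eye_diameter     = list(model = "OUM",
        params = list(alpha = 0.15, sigma2 = 0.004,
                      theta = replace(theta0, "zp", 0.08))),
      ascending_process = list(model = "BM1",
        params = list(sigma2 = 0.004, root = 0)),
      mouth_width      = list(model = "OU1",
        params = list(alpha = 0.1, sigma2 = 0.003, theta = 0)),
      head_width       = list(model = "OU1",
        params = list(alpha = 0.1, sigma2 = 0.003, theta = 0)),
      body_depth       = list(model = "OU1",
        params = list(alpha = 0.2, sigma2 = 0.002, theta = 0)),
      body_width       = list(model = "OUMV",
        params = list(alpha = 0.15,
                      sigma2 = c(bi = 0.004, fc = 0.003, oc = 0.003,
                                 zp = 0.006),
                      theta = replace(theta0, "zp", -0.12))),
      caudal_fin_ratio = list(model = "OUM",
        params = list(alpha = 0.15, sigma2 = 0.004,
                      theta = replace(1 + theta0, "zp", 0.85))),
      max_body_size    = list(model = "OU1",
        params = list(alpha = 0.1, sigma2 = 0.004, theta = 0)))
    slopes <- c(eye_diameter = 0.9, ascending_process = 1.1,
                mouth_width = 1.0, head_width = 1.0, body_depth = 1.0,
                body_width = 1.0, caudal_fin_ratio = 0,
                max_body_size = 1.0)
    intercepts <- c(eye_diameter = -1.0, ascending_process = -0.9,
                    mouth_width = -1.1, head_width = -0.8,
                    body_depth = -0.25, body_width = -0.8,
                    caudal_fin_ratio = 0, max_body_size = 0.12)
    traits <- data.frame(species = tree$tip.label,
                         standard_length = unname(sl))
    for (tn in trait_names) {
      rm_ <- resid_models[[tn]]
      r <- simulate_traits(painting, rm_$model, rm_$params)[, 1]
      traits[[tn]] <- intercepts[[tn]] + slopes[[tn]] * sl + r
    }
    truth <- list(preset = name, seed = seed, n_tips = 79, height = 42,
                  Q = Q, rate_scale = rate_scale,
                  expected_transitions = expected_transitions(painting, Q),
                  n_zp_tips = sum(tip_states == "zp"),
                  zp_origins = count_origins(painting, "zp"),
                  slopes = slopes, intercepts = intercepts,
                  resid_models = resid_models, sl_sigma2 = 0.002)
  }
  out <- list(tree = tree, painting = painting, tip_states = tip_states,
              traits = traits, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(write_newick(tree), file.path(out_dir, "tree.nwk"))
    writeLines(write_simmap_text(painting),
               file.path(out_dir, "painting.simmap"))
    utils::write.csv(data.frame(species = names(tip_states),
                                regime = unname(tip_states)),
                     file.path(out_dir, "states.csv"), row.names = FALSE)
    utils::write.csv(traits, file.path(out_dir, "traits.csv"),
                     row.names = FALSE)
    jsonlite::write_json(truth[names(truth) != "resid_models"],
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }
  out
}
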