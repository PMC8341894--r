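#' @title Distance-based convergence metrics C1-C4
#' @name convergence
#' @description
#' Convergence of a focal tip set is measured against the maximum
#' morphospace distance their lineages ever spanned: for each focal pair,
#' `Dtip` is the Euclidean distance between tip trait vectors and `Dmax`
#' the maximum distance between reconstructed states on the two lineages'
#' node paths from their MRCA to the tips (tips included among the
#' candidates, which forces `C1` into `[0, 1]`). `C1 = 1 - Dtip/Dmax`,
#' `C2 = Dmax - Dtip`, `C3` divides `C2` by the summed branch-wise change
#' along both lineages, and `C4` by the total branch-wise change in the
#' smallest clade containing all focal tips. Significance comes from a
#' correlated-Brownian simulation null parameterized by the evolutionary
#' covariance of the observed data.
NULL

## ---- ancestral reconstruction ----------------------------------------------

## Linear operator mapping tip values to BM (GLS/ML) ancestral estimates:
## anc = A %*% Y, rows = internal nodes (root first).
.asr_bm_operator <- function(tree) {
  n <- length(tree$tip.label)
  depth <- node_depths(tree)
  M <- ape::mrca(tree, full = TRUE)
  Cfull <- matrix(depth[M], nrow(M), nrow(M))
  tipi <- seq_len(n); inti <- n + seq_len(tree$Nnode)
  Ctt <- Cfull[tipi, tipi]
  Cit <- Cfull[inti, tipi, drop = FALSE]
  Cinv1 <- solve(Ctt, rep(1, n))
  w <- Cinv1 / sum(Cinv1)                       # GLS root-mean weights
  G <- Cit %*% solve(Ctt)
  A <- matrix(rep(w, each = tree$Nnode), tree$Nnode, n) +
    G - (G %*% rep(1, n)) %*% t(w)
  rownames(A) <- as.character(inti)
  A
}

#' Ancestral state reconstruction under Brownian motion
#'
#' Per-trait GLS (maximum likelihood) estimates at every internal node;
#' equivalent to the re-rooted phylogenetic-mean construction. Tip rows of
#' the result are the observed values.
#'
#' @param tree a validated `phylo`.
#' @param Y species x traits matrix with species rownames (a named vector
#'   is accepted for a single trait).
#' @return an `asr` list: `states` ((tips + internals) x traits matrix,
#'   tips first in tip-label order), `model = "BM"`.
#' @export
asr_bm <- function(tree, Y) {
  validate_tree(tree)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1,
                                   dimnames = list(names(Y), "trait"))
  Y <- as.matrix(Y)[tree$tip.label, , drop = FALSE]
  if (anyNA(Y)) stop("Y has missing values or species")
  A <- .asr_bm_operator(tree)
  states <- rbind(Y, A %*% Y)
  rownames(states) <- c(tree$tip.label,
                        as.character(length(tree$tip.label) +
                                       seq_len(tree$Nnode)))
  structure(list(states = states, model = "BM", params = NULL),
            class = "asr")
}

## OU tip/node covariance pieces for a single-regime OU with unit diffusion
.ou_v <- function(depthA, depthB, depthM, alpha) {
  if (alpha == 0) return(depthM)
  exp(-alpha * (depthA + depthB)) * expm1(2 * alpha * depthM) / (2 * alpha)
}

#' Ancestral state reconstruction under a single-regime multivariate OU
#'
#' Fits one shared attraction `alpha` and a full trait covariance by
#' maximum likelihood (optimum and trait covariance profiled analytically;
#' `alpha` by one-dimensional bounded search), then returns best linear
#' unbiased node predictions under the fitted process. Because the joint
#' covariance is a Kronecker product of the trait covariance and a common
#' tree kernel, the node predictions are separable across traits. As
#' `alpha -> 0` the predictions converge to [asr_bm()].
#'
#' @inheritParams asr_bm
#' @param alpha if `NULL` (default) the attraction is estimated by maximum
#'   likelihood; a fixed positive value skips the search (useful for limit
#'   checks).
#' @return an `asr` list: `states`, `model = "mvOU"`, `params`
#'   (`alpha`, `theta`, `R` trait covariance).
#' @export
asr_mvou <- function(tree, Y, alpha = NULL) {
  validate_tree(tree)
  if (!check_ultrametric(tree, 1e-6)$ultrametric)
    stop("mvOU reconstruction requires an ultrametric tree")
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1,
                                   dimnames = list(names(Y), "trait"))
  Y <- as.matrix(Y)[tree$tip.label, , drop = FALSE]
  if (anyNA(Y)) stop("Y has missing values or species")
  n <- nrow(Y); p <- ncol(Y)
  depth <- node_depths(tree)
  Tht <- max(depth[seq_len(n)])
  M <- ape::mrca(tree, full = TRUE)
  Dm <- matrix(depth[M], nrow(M), nrow(M))
  tipi <- seq_len(n); inti <- n + seq_len(tree$Nnode)
  nll <- function(la) {
    a <- exp(la)
    V <- .ou_v(outer(depth[tipi], rep(1, n)), outer(rep(1, n), depth[tipi]),
               Dm[tipi, tipi], a)
    U <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(U)) return(1e10)
    onew <- backsolve(U, rep(1, n), transpose = TRUE)
    Yw <- backsolve(U, Y, transpose = TRUE)
    th <- as.numeric(crossprod(onew, Yw) / sum(onew^2))
    Rw <- Yw - outer(onew, th)
    R_ml <- crossprod(Rw) / n
    detR <- determinant(R_ml, logarithm = TRUE)
    if (detR$sign <= 0) return(1e10)
    0.5 * (n * p * log(2 * pi) + p * 2 * sum(log(diag(U))) +
             n * as.numeric(detR$modulus) + n * p)
  }
  if (is.null(alpha)) {
    lo <- log(1e-8); hi <- log(50 / Tht)
    opt <- stats::optimize(nll, c(lo, hi), tol = 1e-8)
    cand <- c(lo, opt$minimum)
    alpha <- exp(cand[which.min(vapply(cand, nll, 0))])
    if (alpha <= 1.0000001e-8)
      warning("alpha at lower bound; mvOU reconstruction ~ BM reconstruction")
  } else stopifnot(alpha > 0)
  Vtt <- .ou_v(outer(depth[tipi], rep(1, n)), outer(rep(1, n), depth[tipi]),
               Dm[tipi, tipi], alpha)
  Vit <- .ou_v(outer(depth[inti], rep(1, n)),
               outer(rep(1, length(inti)), depth[tipi]),
               Dm[inti, tipi, drop = FALSE], alpha)
  U <- chol(Vtt)
  onew <- backsolve(U, rep(1, n), transpose = TRUE)
  Yw <- backsolve(U, Y, transpose = TRUE)
  theta <- as.numeric(crossprod(onew, Yw) / sum(onew^2))
  Rw <- Yw - outer(onew, theta)
  R_hat <- crossprod(Rw) / n
  G <- Vit %*% chol2inv(U)
  anc <- matrix(theta, tree$Nnode, p, byrow = TRUE) +
    G %*% sweep(Y, 2, theta)
  states <- rbind(Y, anc)
  rownames(states) <- c(tree$tip.label, as.character(inti))
  structure(list(states = states, model = "mvOU",
                 params = list(alpha = alpha,
                               theta = stats::setNames(theta, colnames(Y)),
                               R = R_hat)),
            class = "asr")
}

## ---- C metrics --------------------------------------------------------------

## Precomputed geometry for a focal set on a fixed tree: node paths from
## each focal tip to each pairwise MRCA, and the edge set of the smallest
## clade containing all focal tips.
.conv_prep <- function(tree, focal) {
  n <- length(tree$tip.label)
  fi <- match(focal, tree$tip.label)
  if (anyNA(fi)) stop("focal tip(s) not in tree: ",
                      paste(focal[is.na(fi)], collapse = ", "))
  if (length(fi) < 2) stop("need at least two focal tips")
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  M <- ape::mrca(tree)
  path_to <- function(tip, anc_node) {
    v <- tip; out <- v
    while (v != anc_node) { v <- parent[v]; out <- c(out, v) }
    out
  }
  pairs <- utils::combn(seq_along(fi), 2)
  pair_info <- lapply(seq_len(ncol(pairs)), function(q) {
    i <- fi[pairs[1, q]]; j <- fi[pairs[2, q]]
    m <- M[i, j]
    list(i = i, j = j, mrca = m,
         path_i = path_to(i, m), path_j = path_to(j, m))
  })
  clade_root <- if (length(fi) == 2) pair_info[[1]]$mrca
                else ape::getMRCA(tree, focal)
  ## edges of the subtree rooted at clade_root
  in_clade <- logical(n + tree$Nnode)
  in_clade[clade_root] <- TRUE
  ord <- reorder(tree, "cladewise")
  eord <- match(paste(ord$edge[, 1], ord$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  clade_edges <- integer(0)
  for (i in eord) {
    if (in_clade[tree$edge[i, 1]]) {
      in_clade[tree$edge[i, 2]] <- TRUE
      clade_edges <- c(clade_edges, i)
    }
  }
  list(tree = tree, focal = focal, pairs = pair_info,
       clade_root = clade_root, clade_edges = clade_edges)
}

.c_metrics_core <- function(prep, states) {
  tree <- prep$tree
  edge <- tree$edge
  de <- sqrt(rowSums((states[edge[prep$clade_edges, 2], , drop = FALSE] -
                        states[edge[prep$clade_edges, 1], , drop = FALSE])^2))
  clade_total <- sum(de)
  edge_len_of <- stats::setNames(seq_len(nrow(edge)), edge[, 2])
  lineage_change <- function(path) {
    if (length(path) < 2) return(0)
    a <- states[path[-length(path)], , drop = FALSE]
    b <- states[path[-1], , drop = FALSE]
    sum(sqrt(rowSums((a - b)^2)))
  }
  c1 <- c2 <- c3 <- c4 <- numeric(length(prep$pairs))
  flagged <- FALSE
  for (q in seq_along(prep$pairs)) {
    pr <- prep$pairs[[q]]
    Pi <- states[pr$path_i, , drop = FALSE]
    Pj <- states[pr$path_j, , drop = FALSE]
    cross <- outer(rowSums(Pi^2), rep(1, nrow(Pj))) +
      outer(rep(1, nrow(Pi)), rowSums(Pj^2)) - 2 * Pi %*% t(Pj)
    dmax <- sqrt(max(pmax(cross, 0)))
    dtip <- sqrt(sum((states[pr$i, ] - states[pr$j, ])^2))
    if (dmax <= 0) {
      c1[q] <- NA_real_; flagged <- TRUE
      c2[q] <- 0
    } else {
      c1[q] <- 1 - dtip / dmax
      c2[q] <- dmax - dtip
    }
    tot_lin <- lineage_change(pr$path_i) + lineage_change(pr$path_j)
    c3[q] <- if (tot_lin > 0) c2[q] / tot_lin else NA_real_
    c4[q] <- if (clade_total > 0) c2[q] / clade_total else NA_real_
  }
  list(C1 = mean(c1), C2 = mean(c2), C3 = mean(c3), C4 = mean(c4),
       degenerate = flagged)
}

#' Convergence metrics C1-C4 for a focal tip set
#'
#' @param tree a validated `phylo`.
#' @param Y species x traits matrix (the morphospace; typically
#'   size-corrected residuals plus log maximum body size).
#' @param focal character vector of focal tip labels (>= 2).
#' @param anc an `asr` object from [asr_bm()] or [asr_mvou()]; computed
#'   under BM if omitted.
#' @return list with `C1`-`C4` (averaged over focal pairs), `degenerate`
#'   (TRUE when some pair had `Dmax = 0`, leaving `C1` undefined), and
#'   `asr_model`.
#' @export
c_metrics <- function(tree, Y, focal, anc = NULL) {
  validate_tree(tree)
  if (is.null(anc)) anc <- asr_bm(tree, Y)
  if (!inherits(anc, "asr")) stop("anc must be an 'asr' object")
  prep <- .conv_prep(tree, focal)
  out <- .c_metrics_core(prep, anc$states)
  if (out$degenerate)
    warning("Dmax = 0 for some focal pair; C1 undefined there")
  out$asr_model <- anc$model
  out
}

#' Significance of convergence against a Brownian null
#'
#' Estimates the evolutionary trait covariance of the observed data under
#' BM, simulates `n_sim` correlated-BM tip datasets on the same tree, and
#' recomputes the C metrics for each with the same focal set and
#' reconstruction model. The p-value is the proportion of null values
#' greater than or equal to the observed one (observed excluded from the
#' null); the cutoff is the empirical 95th percentile (type-7 quantile) of
#' the null.
#'
#' @inheritParams c_metrics
#' @param asr_model `"bm"` or `"mvou"` (the mvOU `alpha` is refit on every
#'   simulated dataset).
#' @param n_sim number of null simulations.
#' @param seed optional integer seed.
#' @param ridge relative ridge added to a non-positive-definite estimated
#'   covariance (logged via a message when used).
#' @return a `convergence_result` list: `observed` (C1-C4), `cutoff`,
#'   `p_value`, `n_sim`, `seed`, `asr_model`, `focal`.
#' @export
c_significance <- function(tree, Y, focal, asr_model = c("bm", "mvou"),
                           n_sim = 500, seed = NULL, ridge = 1e-8) {
  asr_model <- match.arg(asr_model)
  validate_tree(tree)
  stopifnot(n_sim >= 1)
  if (!is.null(seed)) set.seed(seed)
  Y <- as.matrix(Y)[tree$tip.label, , drop = FALSE]
  prep <- .conv_prep(tree, focal)
  reconstruct <- if (asr_model == "bm") {
    A <- .asr_bm_operator(tree)
    function(Yx) rbind(Yx, A %*% Yx)
  } else {
    function(Yx) asr_mvou(tree, Yx)$states
  }
  obs <- .c_metrics_core(prep, reconstruct(Y))
  if (obs$degenerate) stop("Dmax = 0 in observed data; C1 undefined")
  ## evolutionary covariance of the observed data under BM (lambda = 1)
  R <- evolutionary_covariance(tree, Y, lambda = 1)$cov
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= ridge * max(ev)) {
    message("ridging a near-singular trait covariance")
    R <- R + diag(ridge * max(ev), ncol(R))
  }
  LC <- t(chol(ape::vcv(tree)[tree$tip.label, tree$tip.label]))
  LR <- chol(R)
  n <- nrow(Y); p <- ncol(Y)
  null <- matrix(NA_real_, n_sim, 4,
                 dimnames = list(NULL, c("C1", "C2", "C3", "C4")))
  for (s in seq_len(n_sim)) {
    Ys <- LC %*% matrix(stats::rnorm(n * p), n, p) %*% LR
    rownames(Ys) <- tree$tip.label
    m <- .c_metrics_core(prep, reconstruct(Ys))
    null[s, ] <- c(m$C1, m$C2, m$C3, m$C4)
  }
  obs_v <- c(C1 = obs$C1, C2 = obs$C2, C3 = obs$C3, C4 = obs$C4)
  pv <- vapply(1:4, function(j) mean(null[, j] >= obs_v[j], na.rm = TRUE), 0)
  cut <- vapply(1:4, function(j)
    stats::quantile(null[, j], 0.95, na.rm = TRUE, names = FALSE, type = 7), 0)
  structure(list(observed = obs_v,
                 cutoff = stats::setNames(cut, names(obs_v)),
                 p_value = stats::setNames(pv, names(obs_v)),
                 null = null, n_sim = n_sim, seed = seed,
                 asr_model = asr_model, focal = focal),
            class = "convergence_result")
}
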