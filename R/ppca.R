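#' @title Phylogenetic principal component analysis
#' @name ppca
#' @description
#' PCA of the evolutionary correlation matrix: trait covariances are
#' estimated by generalized least squares under the tree's BM covariance
#' with Pagel's lambda scaling the shared-history entries, lambda being
#' optimized by maximum likelihood. The correlation (not covariance)
#' matrix is decomposed; scores project the evolutionarily standardized,
#' phylogenetically mean-centered traits on its eigenvectors.
NULL

#' Evolutionary covariance matrix and phylogenetic means
#'
#' @param tree a validated `phylo`.
#' @param Y species x traits matrix (rownames are species).
#' @param lambda `"ML"` (optimize in `[0, 1]`) or a fixed value.
#' @return list with `cov` (traits x traits evolutionary covariance,
#'   divisor `n - 1`), `means` (GLS phylogenetic means), `lambda`, and
#'   `loglik` (joint multivariate-normal log-likelihood at the estimate).
#' @export
evolutionary_covariance <- function(tree, Y, lambda = "ML") {
  validate_tree(tree)
  Y <- as.matrix(Y)
  if (is.null(rownames(Y))) stop("Y must have species rownames")
  Y <- Y[tree$tip.label, , drop = FALSE]
  if (anyNA(Y)) stop("Y has missing values or species")
  C <- ape::vcv(tree)[tree$tip.label, tree$tip.label]
  n <- nrow(Y); p <- ncol(Y)
  eval_at <- function(l) {
    Cl <- .lambda_cov(C, l)
    U <- tryCatch(chol(Cl), error = function(e) NULL)
    if (is.null(U)) return(NULL)
    one_w <- backsolve(U, rep(1, n), transpose = TRUE)
    Yw <- backsolve(U, Y, transpose = TRUE)
    a <- as.numeric(crossprod(one_w, Yw) / sum(one_w^2))
    Rw <- Yw - outer(one_w, a)
    S <- crossprod(Rw)
    dimnames(S) <- list(colnames(Y), colnames(Y))
    R_ml <- S / n
    detR <- determinant(R_ml, logarithm = TRUE)
    # a rank-deficient trait set still has a covariance; only the
    # lambda likelihood is undefined there
    ll <- if (detR$sign <= 0) -Inf else
      -0.5 * (n * p * log(2 * pi) + p * 2 * sum(log(diag(U))) +
                n * as.numeric(detR$modulus) + n * p)
    list(a = a, cov = S / (n - 1), loglik = ll)
  }
  if (identical(lambda, "ML")) {
    obj <- function(l) {
      e <- eval_at(l)
      if (is.null(e) || !is.finite(e$loglik)) -1e10 else e$loglik
    }
    opt <- stats::optimize(obj, c(0, 1), maximum = TRUE, tol = 1e-8)
    cand <- c(0, opt$maximum, 1)
    lambda <- cand[which.max(vapply(cand, obj, 0))]
  }
  e <- eval_at(lambda)
  if (is.null(e)) stop("non-positive-definite covariance at lambda = ", lambda)
  list(cov = e$cov, means = stats::setNames(e$a, colnames(Y)),
       lambda = lambda, loglik = e$loglik)
}

#' Phylogenetic PCA of the evolutionary correlation matrix
#'
#' Axes are eigenvectors of the evolutionary correlation matrix, ordered
#' by decreasing eigenvalue, each signed so its largest-magnitude loading
#' is positive. Scores standardize the phylogenetically centered traits by
#' their evolutionary standard deviations before projection. Eigenvalues
#' sum to the trait count; axes with eigenvalues below `rank_tol` are
#' flagged as beyond the matrix rank.
#'
#' @inheritParams evolutionary_covariance
#' @param rank_tol eigenvalue threshold for the rank flag.
#' @return a `phylo_pca` list: `lambda`, `correlation`, `loadings`,
#'   `scores`, `eigenvalues`, `var_explained`, `rank_ok` (logical per
#'   axis), `means`, `sds`.
#' @export
phylo_pca <- function(tree, Y, lambda = "ML", rank_tol = 1e-10) {
  Y <- as.matrix(Y)
  if (ncol(Y) < 2) stop("need at least two traits")
  ec <- evolutionary_covariance(tree, Y, lambda)
  sds <- sqrt(diag(ec$cov))
  if (any(sds <= 0)) stop("constant trait column")
  corr <- ec$cov / outer(sds, sds)
  eig <- eigen(corr, symmetric = TRUE)
  V <- eig$vectors
  for (j in seq_len(ncol(V)))
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  dimnames(V) <- list(colnames(Y), paste0("PC", seq_len(ncol(V))))
  Yc <- sweep(Y[tree$tip.label, , drop = FALSE], 2, ec$means)
  Ystd <- sweep(Yc, 2, sds, "/")
  scores <- Ystd %*% V
  ev <- eig$values
  structure(list(lambda = ec$lambda, correlation = corr, loadings = V,
                 scores = scores, eigenvalues = ev,
                 var_explained = ev / sum(ev),
                 rank_ok = ev > rank_tol,
                 means = ec$means, sds = sds),
            class = "phylo_pca")
}

#' PGLS of PC scores on a covariate
#'
#' One maximum-likelihood-lambda PGLS per axis (e.g. size on the first
#' three axes, to ask whether the PCA is secretly an allometric axis).
#'
#' @param tree a validated `phylo`.
#' @param scores species x axes matrix.
#' @param covariate named numeric vector over species.
#' @param axes which axes to test.
#' @return data frame: axis, slope, se, t, df, p, lambda.
#' @export
score_regression <- function(tree, scores, covariate,
                             axes = seq_len(min(3, ncol(scores)))) {
  out <- lapply(axes, function(j) {
    y <- stats::setNames(scores[tree$tip.label, j], tree$tip.label)
    X <- cbind(`(Intercept)` = 1, covariate = covariate[tree$tip.label])
    rownames(X) <- tree$tip.label
    f <- pgls_fit(tree, y, X, corr = "lambda")
    data.frame(axis = colnames(scores)[j],
               slope = unname(f$coefficients["covariate"]),
               se = unname(f$se["covariate"]),
               t = unname(f$t["covariate"]),
               df = f$df, p = unname(f$p["covariate"]),
               lambda = f$lambda)
  })
  do.call(rbind, out)
}
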