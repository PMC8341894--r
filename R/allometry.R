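#' @title Phylogenetic size correction and allometric slope tests
#' @name allometry
#' @description
#' Generalized least squares under the Brownian-motion covariance of the
#' tree (optionally with maximum-likelihood Pagel's lambda scaling of the
#' shared-history covariances), phylogenetic residuals that carry the
#' convention "positive = larger than the allometric expectation", a
#' regime-by-size interaction test for heterogeneous allometric slopes,
#' and the drag-related fineness ratio.
NULL

.lambda_cov <- function(C, lambda) {
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  Cl
}

.pgls_core <- function(C, X, y) {
  U <- chol(C)
  Xw <- backsolve(U, X, transpose = TRUE)
  yw <- backsolve(U, y, transpose = TRUE)
  qrX <- qr(Xw)
  if (qrX$rank < ncol(X)) stop("singular design matrix")
  beta <- qr.coef(qrX, yw)
  res_w <- yw - Xw %*% beta
  rss <- sum(res_w^2)
  n <- length(y); p <- ncol(X)
  s2_ml <- rss / n
  logdet <- 2 * sum(log(diag(U)))
  loglik <- -0.5 * (n * log(2 * pi * s2_ml) + logdet + n)
  XtX_inv <- chol2inv(qr.R(qrX))
  list(beta = beta, rss = rss, sigma2 = rss / (n - p),
       vcov = rss / (n - p) * XtX_inv, loglik = loglik,
       df = n - p, U = U)
}

#' Phylogenetic generalized least squares
#'
#' Fits `y = X beta + e` with `e ~ N(0, sigma2 * C_lambda)`, `C` the BM
#' covariance of the tree (shared root-path lengths) and `lambda` either
#' fixed at 1 (`corr = "BM"`) or optimized by maximum likelihood over
#' `[0, 1]` (`corr = "lambda"`).
#'
#' @param tree a validated `phylo`.
#' @param y named response vector (names are species).
#' @param X design matrix with rows in any species order matching its
#'   rownames (a plain intercept column is added if `X` is `NULL`).
#' @param corr `"BM"` (lambda fixed at 1), `"lambda"` (ML), or a fixed
#'   numeric lambda in `[0, 1]` (0 reduces to ordinary least squares on an
#'   ultrametric tree).
#' @return a `pgls_fit` list: `coefficients`, `se`, `t`, `p`, `df`,
#'   `lambda`, `sigma2`, `loglik`, `residuals` (response-scale,
#'   `y - X beta`), `fitted`, `vcov`.
#' @export
pgls_fit <- function(tree, y, X = NULL, corr = c("BM", "lambda")) {
  fixed_lambda <- NULL
  if (is.numeric(corr)) {
    stopifnot(length(corr) == 1, corr >= 0, corr <= 1)
    fixed_lambda <- corr
    corr <- "fixed"
  } else corr <- match.arg(corr)
  validate_tree(tree)
  if (is.null(names(y))) stop("y must be named by species")
  y <- y[tree$tip.label]
  if (anyNA(y)) stop("y is missing species present in the tree")
  if (is.null(X)) X <- matrix(1, length(y), 1,
                              dimnames = list(tree$tip.label, "(Intercept)"))
  X <- X[tree$tip.label, , drop = FALSE]
  C <- ape::vcv(tree)[tree$tip.label, tree$tip.label]
  if (corr == "lambda") {
    prof <- function(l) .pgls_core(.lambda_cov(C, l), X, y)$loglik
    opt <- stats::optimize(prof, c(0, 1), maximum = TRUE, tol = 1e-8)
    # compare against the boundaries explicitly
    cand <- c(0, opt$maximum, 1)
    ll <- vapply(cand, prof, 0)
    lambda <- cand[which.max(ll)]
  } else lambda <- if (corr == "fixed") fixed_lambda else 1
  core <- .pgls_core(.lambda_cov(C, lambda), X, y)
  beta <- stats::setNames(as.numeric(core$beta), colnames(X))
  se <- stats::setNames(sqrt(diag(core$vcov)), colnames(X))
  tval <- beta / se
  structure(list(coefficients = beta, se = se, t = tval,
                 p = 2 * stats::pt(-abs(tval), core$df),
                 df = core$df, lambda = lambda, sigma2 = core$sigma2,
                 loglik = core$loglik,
                 residuals = stats::setNames(
                   as.numeric(y - X %*% core$beta), tree$tip.label),
                 fitted = stats::setNames(as.numeric(X %*% core$beta),
                                          tree$tip.label),
                 vcov = core$vcov, corr = corr),
            class = "pgls_fit")
}

#' Phylogenetic residuals of a trait on body size
#'
#' PGLS of `trait ~ size` under strict BM correlation; the returned
#' residuals are on the response scale, so positive values mean the trait
#' is larger than expected given body size.
#'
#' @param tree a validated `phylo`.
#' @param trait,size named numeric vectors over the tree's species.
#' @return named residual vector.
#' @export
phylo_residuals <- function(tree, trait, size) {
  X <- cbind(`(Intercept)` = 1, size = size[tree$tip.label])
  rownames(X) <- tree$tip.label
  fit <- pgls_fit(tree, trait, X, corr = "BM")
  fit$residuals
}

#' Size-correct a trait table
#'
#' Applies [phylo_residuals()] to every trait column except those named in
#' `exclude` (maximum body size is never size-corrected; untransformed
#' ratio traits are still residualized, as in the source analysis, unless
#' excluded).
#'
#' @param tree a validated `phylo`.
#' @param traits data frame with a `species` column, a size column, and
#'   trait columns.
#' @param size_col name of the size covariate column.
#' @param exclude trait columns to pass through untouched.
#' @return matrix (species x traits) of residuals, with excluded columns
#'   appended unchanged.
#' @export
size_correct <- function(tree, traits, size_col = "standard_length",
                         exclude = "max_body_size") {
  stopifnot("species" %in% names(traits), size_col %in% names(traits))
  rownames(traits) <- traits$species
  traits <- traits[tree$tip.label, ]
  size <- stats::setNames(traits[[size_col]], tree$tip.label)
  tn <- setdiff(names(traits), c("species", size_col))
  out <- matrix(NA_real_, length(tree$tip.label), length(tn),
                dimnames = list(tree$tip.label, tn))
  for (v in tn) {
    yv <- stats::setNames(traits[[v]], tree$tip.label)
    out[, v] <- if (v %in% exclude) yv
    else phylo_residuals(tree, yv, size)
  }
  out
}

#' Test for regime-dependent allometric slopes
#'
#' PGLS of `trait ~ size * regime`: each non-reference regime contributes
#' an interaction coefficient measuring how its slope differs from the
#' reference regime's. Regimes with fewer than `min_n` species are dropped
#' with a warning. Reports each interaction contrast (estimate, t, df, p)
#' and the overall interaction F test against the common-slope model.
#'
#' @param tree a validated `phylo`.
#' @param trait,size named numeric vectors.
#' @param regimes named character vector of regime assignments.
#' @param reference reference regime; default is the most frequent one
#'   (alphabetical tie-break).
#' @param corr `"BM"` (default) or `"lambda"`.
#' @param min_n minimum species per regime.
#' @return list with `contrasts` (data frame: regime, estimate, se, t, df,
#'   p), `F`, `df1`, `df2`, `F_p`, `reference`, `fit` (the full
#'   `pgls_fit`).
#' @export
slope_heterogeneity_test <- function(tree, trait, size, regimes,
                                     reference = NULL,
                                     corr = c("BM", "lambda"), min_n = 2) {
  corr <- match.arg(corr)
  validate_tree(tree)
  regimes <- regimes[tree$tip.label]
  tab <- table(regimes)
  small <- names(tab)[tab < min_n]
  if (length(small)) {
    warning("dropping regime(s) with fewer than ", min_n, " species: ",
            paste(small, collapse = ", "))
    keep <- tree$tip.label[!regimes %in% small]
    tree <- prune_to_species(tree, keep)
    regimes <- regimes[tree$tip.label]
    tab <- table(regimes)
  }
  if (length(tab) < 2) stop("need at least two regimes")
  if (is.null(reference))
    reference <- names(sort(tab, decreasing = TRUE))[1]
  lev <- c(reference, sort(setdiff(names(tab), reference)))
  sp <- tree$tip.label
  dd <- data.frame(size = size[sp], regime = factor(regimes, levels = lev))
  y <- trait[sp]
  D <- stats::model.matrix(~ size * regime, dd)
  rownames(D) <- sp
  colnames(D) <- sub("regime", "regime_", colnames(D), fixed = TRUE)
  fit <- pgls_fit(tree, y, D, corr = corr)
  ix <- grep("^size:regime_", names(fit$coefficients))
  contrasts <- data.frame(
    regime = sub("^size:regime_", "", names(fit$coefficients)[ix]),
    estimate = unname(fit$coefficients[ix]),
    se = unname(fit$se[ix]),
    t = unname(fit$t[ix]),
    df = fit$df,
    p = unname(fit$p[ix]))
  ## overall interaction F: compare with the common-slope model at the
  ## same lambda
  D0 <- D[, !grepl("^size:regime_", colnames(D)), drop = FALSE]
  C <- ape::vcv(tree)[sp, sp]
  Cl <- .lambda_cov(C, fit$lambda)
  full <- .pgls_core(Cl, D, y)
  red <- .pgls_core(Cl, D0, y)
  q <- length(ix)
  Fstat <- ((red$rss - full$rss) / q) / (full$rss / full$df)
  list(contrasts = contrasts, F = Fstat, df1 = q, df2 = full$df,
       F_p = stats::pf(Fstat, q, full$df, lower.tail = FALSE),
       reference = reference, fit = fit)
}

#' Body fineness ratio
#'
#' Standard length divided by the square root of maximum body depth times
#' maximum body width; a drag-related shape index (higher is more
#' streamlined, with a volume-for-surface optimum near 4.5).
#'
#' @param SL,depth,width positive lengths in the same units (vectorized).
#' @return the ratio `SL / sqrt(depth * width)`.
#' @export
fineness_ratio <- function(SL, depth, width) {
  if (any(SL <= 0) || any(depth <= 0) || any(width <= 0))
    stop("all inputs must be positive")
  SL / sqrt(depth * width)
}

#' Percentage of a count relative to a total
#'
#' Data-summary convenience for reporting sampling fractions
#' (e.g. 79 of 134 species = 59 percent).
#'
#' @param k count sampled.
#' @param n total count.
#' @param digits rounding digits for the percentage.
#' @return `round(100 * k / n, digits)`.
#' @export
sampling_fraction <- function(k, n, digits = 1) {
  stopifnot(n > 0, k >= 0)
  round(100 * k / n, digits)
}
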