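#' @title Multi-regime BM and OU trait models on painted trees
#' @name evomodels
#' @description
#' Five models of continuous trait evolution along a regime-painted tree:
#' `BM1` (one rate), `BMS` (per-regime rates), `OU1` (one optimum), `OUM`
#' (per-regime optima, shared rate), and `OUMV` (per-regime optima and
#' rates, shared attraction `alpha`). The OU mean for tip `i` is
#' `sum_k theta_k W_ik`, where `W_ik` integrates `alpha exp(-alpha (T - s))`
#' over lineage `i`'s time in regime `k`, and the root mass `exp(-alpha T)`
#' is assigned to the root regime's optimum (the stationary-root convention
#' that lets the weights sum to one with no separate root parameter). The
#' covariance comes from segment-wise integration of the regime-dependent
#' diffusion along shared root paths; BM models are the `alpha -> 0` limit.
NULL

## ---- painted-tree workspace -------------------------------------------------

## Per-node path quantities in root-depth coordinates; reused by every
## likelihood evaluation on the same painting.
.paint_index <- function(pt, require_ultrametric = FALSE) {
  validate_painting(pt)
  n <- length(pt$tip.label)
  nn <- n + pt$Nnode
  depth <- node_depths(pt)
  Ttot <- max(depth[seq_len(n)])
  if (require_ultrametric && !check_ultrametric(pt, 1e-6)$ultrametric)
    stop("OU models require an ultrametric tree")
  ord <- reorder(pt, "cladewise")
  eord <- match(paste(ord$edge[, 1], ord$edge[, 2]),
                paste(pt$edge[, 1], pt$edge[, 2]))
  segs <- vector("list", nrow(pt$edge))
  for (i in seq_len(nrow(pt$edge))) {
    m <- pt$maps[[i]]
    s1 <- depth[pt$edge[i, 1]] + cumsum(unname(m))
    s0 <- c(depth[pt$edge[i, 1]], s1[-length(s1)])
    segs[[i]] <- list(state = names(m), s0 = s0, s1 = s1)
  }
  states <- colnames(pt$mapped.edge)
  states <- states[colSums(pt$mapped.edge) > 0]
  list(pt = pt, n = n, nn = nn, depth = depth, T = Ttot,
       edge_pre = eord, segs = segs, states = states,
       root_state = painting_node_states(pt)[n + 1L],
       mrca = ape::mrca(pt))
}

## Accumulated integrals along root paths for given alpha and per-state
## sigma2 (named, or scalar recycled). Returns per-node:
##   I[v]  = int_0^{d_v} sigma2(s) e^{2 alpha s} ds   (alpha > 0)
##           int_0^{d_v} sigma2(s) ds                 (alpha == 0)
##   w[v,] = per-state int over path of alpha e^{alpha s} ds (alpha > 0)
.path_integrals <- function(idx, alpha, sigma2, want_w = FALSE) {
  I <- numeric(idx$nn)
  W <- if (want_w) matrix(0, idx$nn, length(idx$states),
                          dimnames = list(NULL, idx$states)) else NULL
  pt <- idx$pt
  for (i in idx$edge_pre) {
    u <- pt$edge[i, 1]; v <- pt$edge[i, 2]
    sg <- idx$segs[[i]]
    s2 <- vapply(sg$state, function(s) .par_for(sigma2, s), 0)
    if (alpha > 0) {
      # exp(2 a s0) * expm1(2 a (s1 - s0)) avoids cancellation at small alpha
      dI <- sum(s2 * exp(2 * alpha * sg$s0) *
                  expm1(2 * alpha * (sg$s1 - sg$s0)) / (2 * alpha))
    } else {
      dI <- sum(s2 * (sg$s1 - sg$s0))
    }
    I[v] <- I[u] + dI
    if (want_w) {
      W[v, ] <- W[u, ]
      dws <- exp(alpha * sg$s0) * expm1(alpha * (sg$s1 - sg$s0))
      for (k in seq_along(sg$state))
        W[v, sg$state[k]] <- W[v, sg$state[k]] + dws[k]
    }
  }
  list(I = I, W = W)
}

## Mean design and covariance for a model/parameter combination.
## sigma2 enters V linearly; theta enters the mean linearly through W.
.ou_structure <- function(idx, alpha, sigma2) {
  tipi <- seq_len(idx$n)
  pint <- .path_integrals(idx, alpha, sigma2, want_w = alpha > 0)
  M <- idx$mrca[tipi, tipi]
  V <- matrix(pint$I[M], idx$n, idx$n)
  if (alpha > 0) {
    dfac <- exp(-alpha * idx$depth[tipi])
    V <- V * outer(dfac, dfac)
    W <- pint$W[tipi, , drop = FALSE] * dfac
    W[, idx$root_state] <- W[, idx$root_state] + dfac * 1
  } else {
    W <- matrix(1, idx$n, 1)
  }
  dimnames(V) <- list(idx$pt$tip.label, idx$pt$tip.label)
  list(V = V, W = W)
}

#' Mean vector and tip covariance matrix of a trait model on a painting
#'
#' @param pt a regime-painted tree (`simmap`).
#' @param model one of `"BM1"`, `"BMS"`, `"OU1"`, `"OUM"`, `"OUMV"`.
#' @param params list: `sigma2` (scalar or named per regime), `alpha` and
#'   `theta` for OU models (`theta` scalar for OU1, named for OUM/OUMV),
#'   `mu` (ancestral mean) for BM models.
#' @return list with `mean` (named vector over tips) and `cov` (matrix).
#' @export
ou_moments <- function(pt, model = c("BM1", "BMS", "OU1", "OUM", "OUMV"),
                       params) {
  model <- match.arg(model)
  is_ou <- model %in% c("OU1", "OUM", "OUMV")
  idx <- .paint_index(pt, require_ultrametric = is_ou)
  alpha <- if (is_ou) params$alpha else 0
  if (is_ou && (is.null(alpha) || alpha <= 0))
    stop("OU models need alpha > 0; use a BM model for alpha = 0")
  st <- .ou_structure(idx, alpha, params$sigma2)
  if (is_ou) {
    th <- vapply(idx$states, function(s) .par_for(params$theta, s), 0)
    mu <- as.numeric(st$W %*% th)
  } else {
    mu0 <- if (is.null(params$mu)) 0 else params$mu
    mu <- rep(mu0, idx$n)
  }
  list(mean = stats::setNames(mu, pt$tip.label), cov = st$V)
}

#' Log-likelihood of a trait vector under a model on a painted tree
#'
#' @inheritParams ou_moments
#' @param y named numeric vector of tip trait values.
#' @return multivariate-normal log density.
#' @export
model_loglik <- function(pt, y, model, params) {
  mo <- ou_moments(pt, model, params)
  y <- y[names(mo$mean)]
  .mvn_loglik(y - mo$mean, mo$cov)
}

.mvn_loglik <- function(r, V) {
  U <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(U)) return(-Inf)
  rw <- backsolve(U, r, transpose = TRUE)
  -0.5 * (length(r) * log(2 * pi) + 2 * sum(log(diag(U))) + sum(rw^2))
}

## GLS solve of y on design W under covariance V; returns beta, residual
## quadratic form, and the profile ML log-likelihood pieces.
.gls_profile <- function(V, Wd, y) {
  U <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(U)) return(NULL)
  Ww <- backsolve(U, Wd, transpose = TRUE)
  yw <- backsolve(U, y, transpose = TRUE)
  qrW <- qr(Ww)
  if (qrW$rank < ncol(Wd)) return(NULL)
  beta <- qr.coef(qrW, yw)
  rss <- sum((yw - Ww %*% beta)^2)
  list(beta = beta, rss = rss, logdet = 2 * sum(log(diag(U))))
}

## ---- ML fitting -------------------------------------------------------------

.model_regimes <- function(model, idx)
  switch(model,
         BM1 = , OU1 = character(0),
         BMS = , OUM = , OUMV = idx$states)

.model_npar <- function(model, R)
  switch(model, BM1 = 2L, BMS = R + 1L, OU1 = 3L,
         OUM = R + 2L, OUMV = 2L * R + 1L)

## negative log-likelihood as a function of the full parameter vector,
## used for the numerical Hessian at the optimum
.full_nll <- function(pt, y, model, idx) {
  states <- idx$states
  function(p) {
    params <- .unpack_pars(p, model, states)
    if (any(unlist(params[c("sigma2")]) <= 0)) return(Inf)
    if (model %in% c("OU1", "OUM", "OUMV") && params$alpha <= 0) return(Inf)
    ll <- tryCatch(model_loglik(pt, y, model, params),
                   error = function(e) -Inf)
    if (!is.finite(ll)) Inf else -ll
  }
}

.pack_pars <- function(fit, model, states) {
  switch(model,
    BM1  = c(mu = fit$mu, sigma2 = unname(fit$sigma2)),
    BMS  = c(mu = fit$mu, stats::setNames(fit$sigma2[states],
                                          paste0("sigma2_", states))),
    OU1  = c(theta = unname(fit$theta[1]), alpha = fit$alpha,
             sigma2 = unname(fit$sigma2)),
    OUM  = c(stats::setNames(fit$theta[states], paste0("theta_", states)),
             alpha = fit$alpha, sigma2 = unname(fit$sigma2)),
    OUMV = c(stats::setNames(fit$theta[states], paste0("theta_", states)),
             alpha = fit$alpha,
             stats::setNames(fit$sigma2[states],
                             paste0("sigma2_", states))))
}

.unpack_pars <- function(p, model, states) {
  g <- function(nm) unname(p[nm])
  switch(model,
    BM1  = list(mu = g("mu"), sigma2 = g("sigma2")),
    BMS  = list(mu = g("mu"),
                sigma2 = stats::setNames(p[paste0("sigma2_", states)] |>
                                           unname(), states)),
    OU1  = list(theta = g("theta"), alpha = g("alpha"), sigma2 = g("sigma2")),
    OUM  = list(theta = stats::setNames(unname(p[paste0("theta_", states)]),
                                        states),
                alpha = g("alpha"), sigma2 = g("sigma2")),
    OUMV = list(theta = stats::setNames(unname(p[paste0("theta_", states)]),
                                        states),
                alpha = g("alpha"),
                sigma2 = stats::setNames(unname(p[paste0("sigma2_", states)]),
                                         states)))
}

#' Fit a trait-evolution model on a painted tree by maximum likelihood
#'
#' Location parameters (`theta` or the BM mean) are profiled out by
#' generalized least squares; a single diffusion scale is profiled
#' analytically where the model allows it. The attraction parameter is
#' optimized by bounded quasi-Newton from 8 deterministic starting values
#' of `alpha` log-spaced over `[1e-6, 10 / tree height]`; ties are broken
#' by the higher log-likelihood, then the lower `alpha`. The Hessian of
#' the negative log-likelihood over the full parameter vector is evaluated
#' by central differences (step `1e-4` times the parameter scale); a fit
#' is `retained` only if no eigenvalue is below `-1e-8` and the Hessian is
#' invertible with positive diagonal variances (the screening used before
#' model averaging).
#'
#' @inheritParams ou_moments
#' @param y named numeric vector of tip trait values.
#' @return a `model_fit` list: `model`, `theta`, `alpha`, `sigma2`, `mu`,
#'   `loglik`, `npar`, `n`, `aicc`, `par` (full ML vector), `se`,
#'   `hessian_eigen`, `retained`, `convergence`.
#' @export
fit_model <- function(pt, y, model = c("BM1", "BMS", "OU1", "OUM", "OUMV")) {
  model <- match.arg(model)
  is_ou <- model %in% c("OU1", "OUM", "OUMV")
  idx <- .paint_index(pt, require_ultrametric = is_ou)
  if (is.null(names(y))) stop("y must be named by species")
  y <- y[pt$tip.label]
  if (anyNA(y)) stop("y is missing species present in the tree")
  n <- idx$n
  R <- length(idx$states)
  npar <- .model_npar(model, R)
  if (n <= npar + 1) stop("AICc undefined: n <= npar + 1")
  sv <- rep(1, length(idx$states)); names(sv) <- idx$states

  bm1 <- local({   # closed form; also seeds the other models
    st <- .ou_structure(idx, 0, sv)
    g <- .gls_profile(st$V, st$W, y)
    s2 <- g$rss / n
    ll <- -0.5 * (n * log(2 * pi * s2) + g$logdet + n)
    list(mu = as.numeric(g$beta), sigma2 = s2, loglik = ll)
  })

  if (model == "BM1") {
    fit <- list(mu = bm1$mu, sigma2 = c(sigma2 = bm1$sigma2),
                theta = NULL, alpha = NULL, loglik = bm1$loglik,
                convergence = 0L)
  } else if (model == "BMS") {
    nllf <- function(ls2) {
      s2 <- stats::setNames(exp(ls2), idx$states)
      st <- .ou_structure(idx, 0, s2)
      g <- .gls_profile(st$V, st$W, y)
      if (is.null(g)) return(1e10)
      0.5 * (n * log(2 * pi) + g$logdet + g$rss + 0)  # full, not profiled
    }
    best <- NULL
    for (mult in c(0.3, 1, 3)) {
      o <- tryCatch(stats::optim(rep(log(bm1$sigma2 * mult), R), nllf,
                                 method = "L-BFGS-B",
                                 lower = rep(log(bm1$sigma2) - 12, R),
                                 upper = rep(log(bm1$sigma2) + 12, R),
                                 control = list(maxit = 500)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stop("BMS optimization failed")
    s2 <- stats::setNames(exp(best$par), idx$states)
    st <- .ou_structure(idx, 0, s2)
    g <- .gls_profile(st$V, st$W, y)
    fit <- list(mu = as.numeric(g$beta), sigma2 = s2, theta = NULL,
                alpha = NULL, loglik = -best$value,
                convergence = best$convergence)
  } else {
    ## OU models: profile theta by GLS; OU1/OUM also profile a single sigma2
    a_starts <- exp(seq(log(1e-6), log(10 / idx$T), length.out = 8))
    a_lo <- log(1e-8); a_hi <- log(50 / idx$T)
    if (model %in% c("OU1", "OUM")) {
      nllf <- function(la) {
        st <- .ou_structure(idx, exp(la), sv)
        Wd <- if (model == "OU1") rowSums(st$W) |> matrix(ncol = 1) else st$W
        g <- .gls_profile(st$V, Wd, y)
        if (is.null(g)) return(1e10)
        s2 <- g$rss / n
        0.5 * (n * log(2 * pi * s2) + g$logdet + n)
      }
      best <- NULL
      for (a0 in a_starts) {
        o <- tryCatch(stats::optim(log(a0), nllf, method = "L-BFGS-B",
                                   lower = a_lo, upper = a_hi,
                                   control = list(maxit = 200)),
                      error = function(e) NULL)
        if (is.null(o)) next
        if (is.null(best) || o$value < best$value - 1e-12 ||
            (abs(o$value - best$value) <= 1e-12 && o$par < best$par))
          best <- o
      }
      if (is.null(best)) stop(model, " optimization failed")
      alpha <- exp(best$par)
      st <- .ou_structure(idx, alpha, sv)
      Wd <- if (model == "OU1") matrix(rowSums(st$W), ncol = 1) else st$W
      g <- .gls_profile(st$V, Wd, y)
      s2 <- g$rss / n
      theta <- if (model == "OU1")
        stats::setNames(rep(as.numeric(g$beta), R), idx$states)
      else stats::setNames(as.numeric(g$beta), idx$states)
      fit <- list(mu = NULL, sigma2 = c(sigma2 = s2), theta = theta,
                  alpha = alpha, loglik = -best$value,
                  convergence = best$convergence)
      if (model == "OU1") fit$theta1 <- as.numeric(g$beta)
    } else { # OUMV
      nllf <- function(p) {
        alpha <- exp(p[1])
        s2 <- stats::setNames(exp(p[-1]), idx$states)
        st <- .ou_structure(idx, alpha, s2)
        g <- .gls_profile(st$V, st$W, y)
        if (is.null(g)) return(1e10)
        0.5 * (n * log(2 * pi) + g$logdet + g$rss)
      }
      best <- NULL
      for (a0 in a_starts) {
        o <- tryCatch(stats::optim(c(log(a0), rep(log(bm1$sigma2), R)), nllf,
                                   method = "L-BFGS-B",
                                   lower = c(a_lo, rep(log(bm1$sigma2) - 12, R)),
                                   upper = c(a_hi, rep(log(bm1$sigma2) + 12, R)),
                                   control = list(maxit = 500)),
                      error = function(e) NULL)
        if (is.null(o)) next
        if (is.null(best) || o$value < best$value - 1e-12 ||
            (abs(o$value - best$value) <= 1e-12 && o$par[1] < best$par[1]))
          best <- o
      }
      if (is.null(best)) stop("OUMV optimization failed")
      alpha <- exp(best$par[1])
      s2 <- stats::setNames(exp(best$par[-1]), idx$states)
      st <- .ou_structure(idx, alpha, s2)
      g <- .gls_profile(st$V, st$W, y)
      fit <- list(mu = NULL, sigma2 = s2,
                  theta = stats::setNames(as.numeric(g$beta), idx$states),
                  alpha = alpha, loglik = -best$value,
                  convergence = best$convergence)
    }
  }

  par <- .pack_pars(
    list(mu = fit$mu, sigma2 = fit$sigma2, alpha = fit$alpha,
         theta = if (model == "OU1") stats::setNames(rep(fit$theta1, R),
                                                     idx$states)
                 else fit$theta),
    model, idx$states)
  nll_full <- .full_nll(pt, y, model, idx)
  H <- .num_hessian(nll_full, par)
  He <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  vars <- tryCatch(diag(solve(H)), error = function(e) NULL)
  retained <- min(He) > -1e-8 && !is.null(vars) && all(vars > 0)
  se <- if (!is.null(vars) && all(vars > 0))
    stats::setNames(sqrt(vars), names(par)) else NULL
  aicc <- -2 * fit$loglik + 2 * npar + 2 * npar * (npar + 1) / (n - npar - 1)
  theta_out <- if (model %in% c("OUM", "OUMV")) fit$theta
    else if (model == "OU1") stats::setNames(rep(fit$theta1, R), idx$states)
    else NULL
  structure(list(model = model, theta = theta_out, alpha = fit$alpha,
                 sigma2 = fit$sigma2, mu = fit$mu,
                 loglik = fit$loglik, npar = npar, n = n, aicc = aicc,
                 par = par, se = se, hessian_eigen = He,
                 retained = retained, convergence = fit$convergence,
                 regimes = idx$states),
            class = "model_fit")
}

## central-difference Hessian, step 1e-4 x parameter scale
.num_hessian <- function(f, p, rel_step = 1e-4) {
  m <- length(p)
  h <- rel_step * pmax(abs(p), 1e-3)
  H <- matrix(NA_real_, m, m)
  f0 <- f(p)
  for (i in seq_len(m)) {
    for (j in i:m) {
      if (i == j) {
        pp <- p; pp[i] <- p[i] + h[i]; fp <- f(pp)
        pm <- p; pm[i] <- p[i] - h[i]; fm <- f(pm)
        H[i, i] <- (fp - 2 * f0 + fm) / h[i]^2
      } else {
        ppp <- p; ppp[c(i, j)] <- p[c(i, j)] + h[c(i, j)]
        ppm <- p; ppm[i] <- p[i] + h[i]; ppm[j] <- p[j] - h[j]
        pmp <- p; pmp[i] <- p[i] - h[i]; pmp[j] <- p[j] + h[j]
        pmm <- p; pmm[c(i, j)] <- p[c(i, j)] - h[c(i, j)]
        H[i, j] <- H[j, i] <-
          (f(ppp) - f(ppm) - f(pmp) + f(pmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' Stationary variance of an OU process
#'
#' @param alpha attraction strength (> 0).
#' @param sigma2 diffusion rate (scalar or vector).
#' @return `sigma2 / (2 alpha)`; `Inf` (flagged by a warning) when
#'   `alpha == 0`.
#' @export
stationary_variance <- function(alpha, sigma2) {
  if (length(alpha) != 1 || alpha < 0) stop("alpha must be a scalar >= 0")
  if (alpha == 0) {
    warning("alpha = 0: stationary variance undefined (Inf)")
    return(rep(Inf, length(sigma2)))
  }
  sigma2 / (2 * alpha)
}

## ---- AICc model averaging ---------------------------------------------------

#' AICc weights, 95 percent confidence set, and model-averaged parameters
#'
#' Input is one list per model of `model_fit`s over map iterations
#' (`fits[[model]][[iteration]]`). Iterations failing the Hessian screen
#' (`retained = FALSE`) are dropped per model; a model with no retained
#' iteration is dropped with a warning. Delta-AICc is computed within each
#' iteration across the models retained there, then averaged per model;
#' weights are `exp(-delta/2)` normalized. The confidence set is the
#' smallest prefix of weight-ordered models whose cumulative weight is
#' `>= level`; adjusted weights renormalize over that set and drive the
#' parameter averages `p_bar = sum w_m p_m` and unconditional standard
#' errors `sum w_m sqrt(var_m + (p_m - p_bar)^2)`.
#'
#' @param fits named list (by model id) of lists of `model_fit`s.
#' @param level confidence-set cumulative weight threshold.
#' @return a `model_average` list: `table` (model, n_retained, mean
#'   delta-AICc, weight, adjusted weight), `confidence_set`, `theta`,
#'   `alpha`, `sigma2`, their unconditional SEs, and per-regime
#'   `stationary_variance`.
#' @export
average_models <- function(fits, level = 0.95) {
  stopifnot(is.list(fits), !is.null(names(fits)))
  models <- names(fits)
  n_iter <- max(lengths(fits))
  aicc <- matrix(NA_real_, n_iter, length(models),
                 dimnames = list(NULL, models))
  for (m in models) for (i in seq_along(fits[[m]])) {
    f <- fits[[m]][[i]]
    if (isTRUE(f$retained)) aicc[i, m] <- f$aicc
  }
  keep <- colSums(!is.na(aicc)) > 0
  if (!any(keep)) stop("no retained fits in any model")
  if (any(!keep))
    warning("dropping model(s) with no retained iteration: ",
            paste(models[!keep], collapse = ", "))
  models <- models[keep]; aicc <- aicc[, models, drop = FALSE]
  aicc <- aicc[rowSums(!is.na(aicc)) > 0, , drop = FALSE]
  delta <- aicc - apply(aicc, 1, min, na.rm = TRUE)
  dbar <- colMeans(delta, na.rm = TRUE)
  w <- exp(-dbar / 2); w <- w / sum(w)
  ord <- order(w, decreasing = TRUE)
  cum <- cumsum(w[ord])
  inset <- ord[seq_len(which(cum >= level)[1])]
  wadj <- stats::setNames(rep(NA_real_, length(models)), models)
  wadj[inset] <- w[inset] / sum(w[inset])

  ## per-model mean parameter estimates and variances over retained iters
  regs <- unique(unlist(lapply(fits, function(fl)
    unlist(lapply(fl, function(f) f$regimes)))))
  collect <- function(model, getter) {
    vals <- lapply(fits[[model]], function(f)
      if (isTRUE(f$retained)) getter(f) else NULL)
    vals <- vals[!vapply(vals, is.null, TRUE)]
    if (!length(vals)) return(NULL)
    Reduce(`+`, vals) / length(vals)
  }
  se_of <- function(f, nm) if (!is.null(f$se) && nm %in% names(f$se))
    f$se[[nm]]^2 else NA_real_
  avg_par <- function(nm_for_model, value_for_model) {
    ms <- names(which(!is.na(wadj)))
    ms <- ms[vapply(ms, function(m) !is.null(value_for_model(m)), TRUE)]
    if (!length(ms)) return(list(est = NA_real_, se = NA_real_, models = ms))
    ww <- wadj[ms] / sum(wadj[ms])
    est <- sum(ww * vapply(ms, function(m) value_for_model(m), 0))
    sev <- vapply(ms, function(m) {
      vs <- vapply(fits[[m]], function(f)
        if (isTRUE(f$retained)) se_of(f, nm_for_model(m)) else NA_real_, 0)
      mean(vs, na.rm = TRUE)
    }, 0)
    pe <- vapply(ms, function(m) value_for_model(m), 0)
    use <- sum(ww * sqrt(pmax(sev, 0) + (pe - est)^2), na.rm = TRUE)
    list(est = est, se = use, models = ms)
  }
  is_ou_m <- function(m) m %in% c("OU1", "OUM", "OUMV")
  theta_avg <- lapply(stats::setNames(regs, regs), function(r)
    avg_par(function(m) if (m == "OU1") "theta" else paste0("theta_", r),
            function(m) {
              if (!is_ou_m(m)) return(NULL)
              v <- collect(m, function(f) f$theta[[r]])
              v
            }))
  alpha_avg <- avg_par(function(m) "alpha",
                       function(m) if (is_ou_m(m))
                         collect(m, function(f) f$alpha) else NULL)
  sigma_avg <- lapply(stats::setNames(regs, regs), function(r)
    avg_par(function(m) if (m %in% c("BMS", "OUMV"))
              paste0("sigma2_", r) else "sigma2",
            function(m) collect(m, function(f)
              if (length(f$sigma2) == 1) unname(f$sigma2)
              else f$sigma2[[r]])))
  tab <- data.frame(model = models,
                    n_retained = colSums(!is.na(aicc)),
                    mean_delta_aicc = dbar,
                    weight = w,
                    adjusted_weight = wadj,
                    row.names = NULL)
  tab <- tab[order(-tab$weight), ]
  th <- vapply(theta_avg, function(a) a$est, 0)
  s2 <- vapply(sigma_avg, function(a) a$est, 0)
  structure(list(
    table = tab,
    confidence_set = models[inset],
    theta = th,
    theta_se = vapply(theta_avg, function(a) a$se, 0),
    alpha = alpha_avg$est, alpha_se = alpha_avg$se,
    sigma2 = s2,
    sigma2_se = vapply(sigma_avg, function(a) a$se, 0),
    stationary_variance = if (is.finite(alpha_avg$est) &&
                              !is.na(alpha_avg$est) && alpha_avg$est > 0)
      s2 / (2 * alpha_avg$est) else rep(NA_real_, length(s2)),
    level = level), class = "model_average")
}
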