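# Dense multi-kernel REML machinery shared by the variance-component,
# prediction and adjusted-means code.
#
# Model: y = X beta + sum_k u_k + e,  u_k ~ N(0, theta_k V_k),
#        e ~ N(0, theta_e I)  (optional), plus an optional *known* offset
#        covariance added to V with coefficient 1 (used when a residual
#        variance has been profiled out beforehand).
#
# Estimation: average-information updates with step halving, falling back
# to a monotone EM-type multiplicative update when an AI step fails to
# improve the restricted likelihood. Components are kept non-negative by
# projection. Convergence: relative REML log-likelihood change < 1e-8.

mm_reml <- function(y, X, Vlist, include_resid = TRUE, offset = NULL,
                    init = NULL, max_iter = 200, tol = 1e-8,
                    ridge = 1e-6) {
  n <- length(y)
  X <- as.matrix(X)
  if (nrow(X) != n) stop_data("X rows do not match y")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  p <- ncol(X)
  K <- length(Vlist)
  if (K == 0 && !include_resid) stop_config("no variance components")
  nms <- names(Vlist) %||% paste0("K", seq_len(K))
  if (include_resid) {
    Vlist <- c(Vlist, list(residual = diag(n)))
    nms <- c(nms, "residual")
  }
  Vlist <- lapply(Vlist, unclass)
  r <- length(Vlist)
  vy <- var(y)
  if (vy <= 0) { # constant response: all variances zero
    beta <- qr.coef(qr(X), y)
    return(list(theta = setNames(rep(0, r), nms), beta = beta,
                loglik = NA_real_, Py = rep(0, n), converged = TRUE,
                blups = lapply(setNames(seq_len(r), nms), function(i) rep(0, n)),
                iterations = 0L))
  }
  lb <- 1e-10 * vy
  theta <- init %||% rep(vy / r / vapply(Vlist, function(V) mean(diag(V)), 0), length.out = r)
  theta <- pmax(theta, lb)

  eval_fit <- function(theta) {
    V <- matrix(0, n, n)
    for (k in seq_len(r)) V <- V + theta[k] * Vlist[[k]]
    if (!is.null(offset)) V <- V + offset
    dbar <- mean(diag(V))
    ch <- tryCatch(chol(V + diag(ridge * dbar, n)), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    XtVi <- crossprod(X, Vinv)               # p x n
    XtViX <- XtVi %*% X
    chx <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chx)) return(NULL)
    XtViy <- drop(XtVi %*% y)
    beta <- backsolve(chx, forwardsolve(t(chx), XtViy))
    P <- Vinv - crossprod(XtVi, chol2inv(chx) %*% XtVi)
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                    sum(y * Py))
    list(ll = ll, P = P, Py = Py, beta = beta)
  }

  fit <- eval_fit(theta)
  if (is.null(fit)) stop_data("initial covariance not positive definite")
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    W <- vapply(Vlist, function(V) drop(V %*% fit$Py), numeric(n))  # n x r
    PW <- fit$P %*% W
    quad <- colSums(fit$Py * W)              # y' P Vk P y
    trPV <- vapply(Vlist, function(V) sum(fit$P * V), 0)
    score <- 0.5 * (quad - trPV)
    AI <- 0.5 * crossprod(W, PW)
    free <- !(theta <= lb & score < 0)       # boundary components stay put
    step <- rep(0, r)
    ok <- FALSE
    if (any(free)) {
      Ai <- AI[free, free, drop = FALSE]
      Ai <- Ai + diag(1e-8 * mean(diag(Ai)) + 1e-300, sum(free))
      d_free <- tryCatch(solve(Ai, score[free]), error = function(e) NULL)
      if (!is.null(d_free)) {
        step[free] <- d_free
        h <- 1
        for (half in 1:6) {
          cand <- pmax(theta + h * step, ifelse(free, lb, theta))
          cand[!free] <- theta[!free]
          f2 <- eval_fit(cand)
          if (!is.null(f2) && is.finite(f2$ll) && f2$ll >= fit$ll - 1e-12) {
            ok <- TRUE; break
          }
          h <- h / 2
        }
      }
    }
    if (!ok) {                                # EM-type multiplicative fallback
      cand <- theta
      upd <- free & trPV > 0 & quad > 0
      cand[upd] <- theta[upd] * quad[upd] / trPV[upd]
      cand <- pmax(cand, lb)
      f2 <- eval_fit(cand)
      if (is.null(f2) || !is.finite(f2$ll)) break
    }
    rel <- abs(f2$ll - fit$ll) / (1 + abs(fit$ll))
    theta <- if (ok) pmax(theta + h * step, lb) else cand
    theta[!free] <- pmax(theta[!free], lb)
    fit <- f2
    if (rel < tol) { converged <- TRUE; break }
  }
  theta[theta <= 2 * lb] <- 0
  blups <- lapply(setNames(seq_len(r), nms), function(k)
    theta[k] * drop(Vlist[[k]] %*% fit$Py))
  list(theta = setNames(theta, nms), beta = fit$beta, loglik = fit$ll,
       Py = fit$Py, P = fit$P, converged = converged, iterations = it,
       blups = blups, X = X)
}

# ---- spectral (EMMA-style) single-kernel REML ------------------------------

# Eigen-decompose an observation-level covariance structure once; any fixed
# effect design can then be handled exactly in the rotated basis.
emma_eigen <- function(K_obs) {
  K_obs <- unclass(K_obs)
  e <- eigen((K_obs + t(K_obs)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(abs(e$values)))
    stop_data("kinship is not positive semidefinite")
  e$values <- pmax(e$values, 0)
  e
}

# Profile REML criterion over lambda = sigma2_u / sigma2_e with rotated
# data; returns -2 * restricted log-likelihood up to a constant.
emma_crit <- function(log_lambda, ys, Xs, d) {
  lambda <- exp(log_lambda)
  w <- 1 / (lambda * d + 1)
  n <- length(ys); p <- ncol(Xs)
  XtWX <- crossprod(Xs, Xs * w)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(1e300)
  b <- backsolve(ch, forwardsolve(t(ch), crossprod(Xs, ys * w)))
  rss <- sum(w * (ys - drop(Xs %*% b))^2)
  (n - p) * log(rss / (n - p)) + sum(log(lambda * d + 1)) +
    2 * sum(log(diag(ch)))
}

# Exact single-kernel REML via the spectral decomposition. `eig` comes from
# emma_eigen(K_obs); X is the fixed-effect design on the original scale.
emma_reml <- function(y, X, eig, interval = c(-12, 12)) {
  U <- eig$vectors; d <- eig$values
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, as.matrix(X))
  opt <- optimize(emma_crit, interval, ys = ys, Xs = Xs, d = d)
  lambda <- exp(opt$minimum)
  # boundary checks: compare against (near-)zero and huge lambda
  for (b in interval)
    if (emma_crit(b, ys, Xs, d) < opt$objective) {
      lambda <- exp(b); opt$objective <- emma_crit(b, ys, Xs, d)
    }
  w <- 1 / (lambda * d + 1)
  n <- length(y); p <- ncol(Xs)
  XtWX <- crossprod(Xs, Xs * w)
  b <- solve(XtWX, crossprod(Xs, ys * w))
  rss <- sum(w * (ys - drop(Xs %*% b))^2)
  s2e <- rss / (n - p)
  list(lambda = lambda, sigma2_e = s2e, sigma2_u = lambda * s2e,
       ys = ys, Xs = Xs, d = d, U = U, crit = opt$objective)
}

# Wald tests of fixed-effect columns in the rotated model with weights
# fixed at the null-model variance components (P3D) or re-estimated
# (exact). Returns estimates, standard errors and two-sided P-values for
# the requested columns.
rotated_wald <- function(ys, Xs, d, lambda, test_cols) {
  w <- 1 / (lambda * d + 1)
  n <- length(ys); p <- ncol(Xs)
  sw <- sqrt(w)
  fit <- lm.fit(Xs * sw, ys * sw)
  if (fit$rank < p) return(NULL)
  s2 <- sum(fit$residuals^2) / (n - p)
  R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  R[lower.tri(R)] <- 0
  dv <- numeric(p)
  dv[fit$qr$pivot] <- diag(chol2inv(R))   # un-pivot the (X'WX)^{-1} diagonal
  est <- fit$coefficients[test_cols]
  se <- sqrt(s2 * dv[test_cols])
  tval <- est / se
  pval <- 2 * pt(abs(tval), df = n - p, lower.tail = FALSE)
  list(estimate = est, se = se, p = pval, df = n - p)
}
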