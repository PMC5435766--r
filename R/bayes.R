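#' Bayesian partition of genetic variance over effect classes
#'
#' Gibbs-sampled ridge regression of the adjusted means on three design
#' blocks -- additive codes, dominance indicators, and all four types of
#' digenic epistatic products (AxA, AxD, DxA, DxD) over a (sub)sample of
#' marker pairs -- with one normal prior variance per class. The reported
#' quantity is the posterior mean of each class's share of the realized
#' genetic variance, i.e. var over individuals of that class's genetic
#' values divided by the summed class variances; shares lie in [0, 1] and
#' sum to 1 by construction.
#'
#' @param means across-environment adjusted means (one row per genotype).
#' @param design \code{design_matrices} over the same genotypes.
#' @param n_pairs number of digenic pairs to sample (pair subsampling keeps
#'   the epistasis block tractable; the sampled pairs are recorded).
#' @param chains,n_iter,burnin,thin Gibbs configuration (defaults: 2 chains
#'   x 3000 iterations, 1000 burn-in, thin 2; seeds split per chain).
#' @param seed master seed.
#' @param df0 prior degrees of freedom for all variance components.
#' @param X_fixed unpenalized fixed-effect design projected out of the
#'   response and all design columns before sampling (Frisch-Waugh);
#'   defaults to intercept + inbred/hybrid group, so the heterosis gap is
#'   not misattributed to the dominance class.
#' @return list with \code{shares} (posterior mean additive/dominance/
#'   epistatic shares), \code{rhat} (split R-hat per share; a warning is
#'   attached when any exceeds 1.1), \code{samples}, \code{pairs}.
#' @export
bayesian_variance_partition <- function(means, design, n_pairs = 3000,
                                        chains = 2, n_iter = 3000,
                                        burnin = 1000, thin = 2, seed = 1,
                                        df0 = 5, X_fixed = NULL) {
  stopifnot(inherits(means, "phenotype_table"), inherits(design, "design_matrices"))
  idx <- match(means$genotype_id, design$ids)
  if (anyNA(idx)) stop_data("genotypes in means missing from design")
  A <- design$A[idx, , drop = FALSE]
  D <- design$D[idx, , drop = FALSE]
  m <- ncol(A)
  if (is.null(X_fixed))
    X_fixed <- cbind(1, as.numeric(design$group[idx] == "hybrid"))
  pairs <- with_seed(split_seed(seed, "bvp_pairs"), {
    all_p <- if (choose(m, 2) <= n_pairs) t(combn(m, 2)) else
      t(replicate(n_pairs, sample.int(m, 2)))
    unique(all_p)
  })
  epi <- cbind(A[, pairs[, 1]] * A[, pairs[, 2]],
               A[, pairs[, 1]] * D[, pairs[, 2]],
               D[, pairs[, 1]] * A[, pairs[, 2]],
               D[, pairs[, 1]] * D[, pairs[, 2]])
  # Frisch-Waugh: project the fixed effects out of response and columns
  Xf <- qr(as.matrix(X_fixed))
  proj <- function(M) M - qr.fitted(Xf, M)
  X <- proj(cbind(A, D, epi))
  cls <- c(rep(0L, m), rep(1L, m), rep(2L, ncol(epi)))
  keep <- apply(X, 2, function(v) any(abs(v) > 1e-12))
  X <- X[, keep, drop = FALSE]; cls <- cls[keep]
  y <- drop(proj(means$value))
  vy <- var(y)
  # prior scales: half the phenotypic variance split equally over classes,
  # converted to a per-effect variance through the class's summed column
  # variance (BGLR-style R2 heuristic)
  sumv <- vapply(0:2, function(c) sum(apply(X[, cls == c, drop = FALSE], 2, var)), 0)
  S0 <- 0.5 * vy / 3 / pmax(sumv, 1e-8)
  Se <- 0.5 * vy
  samples <- lapply(seq_len(chains), function(ch) {
    with_seed(split_seed(seed, paste0("bvp_chain", ch)), {
      out <- gibbs_brr_cpp(y, X, cls, 3L, as.integer(n_iter),
                           as.integer(burnin), as.integer(thin),
                           df0, S0, df0, Se)
      sh <- out$var_g / rowSums(out$var_g)
      colnames(sh) <- c("additive", "dominance", "epistatic")
      list(shares = sh, s2e = out$s2e)
    })
  })
  all_sh <- do.call(rbind, lapply(samples, `[[`, "shares"))
  shares <- colMeans(all_sh)
  rhat <- vapply(1:3, function(j)
    split_rhat(lapply(samples, function(s) s$shares[, j])), 0)
  names(rhat) <- names(shares)
  warn <- NULL
  if (any(rhat > 1.1, na.rm = TRUE)) {
    warn <- paste("chains may not have mixed: split R-hat >",
                  "1.1 for", paste(names(rhat)[rhat > 1.1], collapse = ", "))
    warning(warn)
  }
  list(shares = shares, rhat = rhat, warning = warn,
       samples = all_sh, pairs = pairs)
}

# split R-hat (Gelman-Rubin) over a list of chains of a scalar quantity
split_rhat <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(x) {
    h <- floor(length(x) / 2)
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  B <- n * var(means)
  W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}
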