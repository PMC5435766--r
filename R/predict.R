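#' Multi-kernel GBLUP fit
#'
#' Fits y = 1 mu + sum_k g_k + e on adjusted entry means, with
#' g_k ~ N(0, sigma2_k K_k) for each supplied relationship matrix, by
#' average-information REML (EM fallback). BLUPs are recovered from the
#' mixed-model equations; predictions for new individuals use the stored
#' alpha_k = sigma2_k P y weights (conditional-expectation contract).
#'
#' @param means \code{phenotype_table} of across-environment adjusted means
#'   (one record per genotype).
#' @param kernels named list of \code{relationship_matrix} objects indexed
#'   identically to the genotypes of \code{means}.
#' @param X optional fixed-effect design (default intercept only).
#' @return object of class \code{gblup_fit}: mu, variance components,
#'   per-kernel BLUPs, alpha weights, fitted values, REML log-likelihood.
#' @export
fit_gblup <- function(means, kernels, X = NULL) {
  stopifnot(inherits(means, "phenotype_table"), length(kernels) >= 1)
  ids <- means$genotype_id
  if (anyDuplicated(ids)) stop_data("means must hold one record per genotype")
  Ks <- lapply(kernels, function(K) {
    if (!identical(attr(K, "ids"), ids)) K <- rm_subset(K, ids)
    K
  })
  y <- means$value
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  fit <- mm_reml(y, X, lapply(Ks, unclass))
  if (!fit$converged && !is.na(fit$loglik))
    stop_data("GBLUP REML did not converge after ", fit$iterations,
              " iterations")
  nk <- names(kernels) %||% paste0("K", seq_along(kernels))
  theta <- fit$theta
  blups <- fit$blups[seq_along(kernels)]
  names(blups) <- nk
  alpha <- lapply(seq_along(kernels), function(k) theta[k] * fit$Py)
  names(alpha) <- nk
  mu <- drop(fit$beta)[1]
  fitted <- drop(as.matrix(X) %*% fit$beta) + Reduce(`+`, blups)
  structure(list(mu = mu, beta = fit$beta,
                 variances = setNames(theta, c(nk, "residual")),
                 blups = blups, alpha = alpha, fitted = fitted,
                 log_likelihood = fit$loglik, ids = ids,
                 kernels = Ks, X = X, y = y),
            class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat("gblup_fit: n =", length(x$ids), "| variances:\n")
  print(round(x$variances, 5))
  invisible(x)
}

#' Predict genetic values of new individuals from a GBLUP fit
#'
#' prediction = X_new beta + sum_k K_new,train alpha_k, the BLUP
#' conditional expectation given the training data. A new individual
#' identical to a training one receives that individual's fitted genetic
#' value; one with a zero cross-kernel row receives its fixed-effect mean.
#'
#' @param fit \code{gblup_fit}.
#' @param cross_kernels named list (same names/order as the fit's kernels)
#'   of new x train cross-blocks, e.g. from \code{\link{kernel_cross}}.
#' @param X_new fixed-effect design of the new individuals; defaults to an
#'   intercept column (only valid when the fit used an intercept only).
#' @return numeric vector of predicted values for the new individuals.
#' @export
predict_new <- function(fit, cross_kernels, X_new = NULL) {
  stopifnot(inherits(fit, "gblup_fit"))
  if (length(cross_kernels) != length(fit$alpha))
    stop_data("cross-kernel count does not match the fit")
  n_new <- nrow(cross_kernels[[1]])
  if (is.null(X_new)) {
    if (length(fit$beta) > 1)
      stop_data("fit has covariates; supply X_new")
    X_new <- matrix(1, n_new, 1)
  }
  pred <- drop(as.matrix(X_new) %*% fit$beta)
  for (k in seq_along(cross_kernels)) {
    Kc <- cross_kernels[[k]]
    if (ncol(Kc) != length(fit$ids) || nrow(Kc) != n_new)
      stop_data("cross-kernel dimensions do not match the fit")
    pred <- pred + drop(Kc %*% fit$alpha[[k]])
  }
  pred
}

# assemble the kernel sets of the three standard models from a design
standard_kernels <- function(design, shrink = TRUE, bandwidth = "median") {
  Ga <- additive_relationship(design, shrink = shrink)
  Gd <- tryCatch(dominance_relationship(design, shrink = shrink),
                 error = function(e) NULL)
  Ge <- gaussian_kernel(design, bandwidth = bandwidth)
  list(A = list(additive = Ga),
       AD = if (is.null(Gd)) NULL else list(additive = Ga, dominance = Gd),
       ADE = if (is.null(Gd)) NULL else
         list(additive = Ga, dominance = Gd, gaussian = Ge))
}

#' Cross-validated genomic prediction of hybrid performance
#'
#' Five-fold protocol: every estimation set contains 100\% of the inbred
#' lines and 80\% of the hybrids; the held-out 20\% of hybrids form the
#' test set. Kernels are computed once on all individuals (marker data of
#' unphenotyped hybrids is legitimately available); test phenotypes are
#' masked during fitting. Accuracy = Pearson cor(predicted, observed) /
#' sqrt(H2).
#'
#' @param means across-environment adjusted means, one row per genotype.
#' @param kernels named list of \code{relationship_matrix} objects over all
#'   individuals (names "additive", "dominance", "gaussian" select models).
#' @param group named character vector genotype_id -> "inbred"/"hybrid".
#' @param h2 heritability for standardization.
#' @param folds number of folds (default 5); test folds of < 3 are an error.
#' @param n_repeats independent fold partitions (default 5).
#' @param seed integer; fold assignment depends only on (seed, hybrid ids).
#' @param models subset of c("A", "AD", "ADE").
#' @param use_group include the inbred/hybrid group label as a fixed
#'   covariate (default TRUE): the heterosis gap between population means
#'   otherwise loads onto the kernels and destabilizes the additive-only
#'   variance fit.
#' @return \code{cv_report}: data frame of per-repeat, per-fold, per-model
#'   accuracies with a summary attribute.
#' @export
crossvalidate <- function(means, kernels, group, h2, folds = 5,
                          n_repeats = 5, seed = 1,
                          models = c("A", "AD", "ADE"), use_group = TRUE) {
  stopifnot(inherits(means, "phenotype_table"))
  ids <- means$genotype_id
  hybs <- sort(ids[group[ids] == "hybrid"])
  if (length(hybs) < folds * 3) stop_config("folds smaller than 3 hybrids")
  model_sets <- list(A = "additive", AD = c("additive", "dominance"),
                     ADE = c("additive", "dominance", "gaussian"))
  miss <- setdiff(unique(unlist(model_sets[models])), names(kernels))
  if (length(miss)) stop_config("kernels missing for models: ",
                                paste(miss, collapse = ", "))
  out <- list()
  for (rep_i in seq_len(n_repeats)) {
    fold_of <- with_seed(split_seed(seed, paste0("cvfold", rep_i)),
                         sample(rep(seq_len(folds), length.out = length(hybs))))
    for (f in seq_len(folds)) {
      test_ids <- hybs[fold_of == f]
      train_rows <- !(ids %in% test_ids)
      train_means <- phenotype_table(means[train_rows, , drop = FALSE],
                                     stage = pheno_stage(means))
      obs <- means$value[match(test_ids, ids)]
      Xtr <- if (use_group)
        cbind(1, as.numeric(group[train_means$genotype_id] == "hybrid"))
      else NULL
      Xte <- if (use_group) cbind(1, rep(1, length(test_ids))) else NULL
      for (mod in models) {
        kn <- model_sets[[mod]]
        Ktr <- lapply(kernels[kn], rm_subset, ids = train_means$genotype_id)
        fit <- fit_gblup(train_means, Ktr, X = Xtr)
        Kcross <- lapply(kernels[kn], function(K) {
          unclass(K)[match(test_ids, attr(K, "ids")),
                     match(train_means$genotype_id, attr(K, "ids")),
                     drop = FALSE]
        })
        pred <- predict_new(fit, Kcross, X_new = Xte)
        acc <- if (sd(pred) == 0 || sd(obs) == 0) 0
               else cor(pred, obs) / sqrt(h2)
        out[[length(out) + 1]] <- data.frame(repeat_i = rep_i, fold = f,
                                             model = mod, accuracy = acc,
                                             n_test = length(test_ids))
      }
    }
  }
  res <- do.call(rbind, out)
  summ <- aggregate(accuracy ~ model, data = res,
                    FUN = function(a) c(mean = mean(a), sd = sd(a)))
  structure(res, class = c("cv_report", "data.frame"), summary = summ,
            seed = seed, h2 = h2)
}

#' Independent validation of fitted prediction models
#'
#' Evaluates per-model accuracy on a genotyped and phenotyped validation
#' set (e.g. new crosses grown in a new environment), standardizing the
#' Pearson correlation by the square root of the \emph{training} H2, as
#' when the validation trial cannot estimate its own heritability.
#'
#' @param fits named list of \code{gblup_fit} objects (e.g. A, AD, ADE).
#' @param kernel_sets named list (same names) of lists of training
#'   \code{relationship_matrix} objects used by each fit, for cross-blocks.
#' @param val_design \code{design_matrices} of the validation individuals
#'   on the training marker panel.
#' @param val_means \code{phenotype_table} of validation adjusted means.
#' @param h2 training heritability.
#' @param X_new optional fixed-effect design for the validation individuals
#'   (defaults to intercept + hybrid-group column when the fits carry two
#'   fixed effects, since validation sets are hybrids).
#' @return data frame with model, accuracy, n.
#' @export
independent_validate <- function(fits, kernel_sets, val_design, val_means,
                                 h2, X_new = NULL) {
  if (nrow(val_means) == 0) stop_data("empty validation set")
  obs <- val_means$value[match(val_design$ids, val_means$genotype_id)]
  if (anyNA(obs)) stop_data("validation phenotypes missing for some individuals")
  out <- lapply(names(fits), function(mod) {
    Kcross <- lapply(kernel_sets[[mod]], kernel_cross, new_design = val_design)
    Xn <- X_new
    if (is.null(Xn) && length(fits[[mod]]$beta) == 2)
      Xn <- cbind(1, rep(1, length(val_design$ids)))
    pred <- predict_new(fits[[mod]], Kcross, X_new = Xn)
    data.frame(model = mod,
               accuracy = if (sd(pred) == 0) 0 else cor(pred, obs) / sqrt(h2),
               n = length(obs))
  })
  do.call(rbind, out)
}
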