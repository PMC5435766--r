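# Shared scan plumbing: stack adjusted means over environments, expand the
# genotype-level kinship and design matrices to observation level, and
# rotate everything into the spectral basis of the kinship.

scan_context <- function(means, design, kinship) {
  stopifnot(inherits(means, "phenotype_table"), inherits(design, "design_matrices"))
  idx <- match(means$genotype_id, design$ids)
  if (anyNA(idx)) stop_data("genotypes in means missing from design matrices")
  kid <- match(means$genotype_id, attr(kinship, "ids"))
  if (anyNA(kid)) stop_data("genotypes in means missing from kinship")
  env <- factor(means$environment)
  X0 <- if (nlevels(env) > 1) stats::model.matrix(~ env)
        else matrix(1, nrow(means), 1)       # intercept + environment effects
  K_obs <- unclass(kinship)[kid, kid, drop = FALSE]
  eig <- emma_eigen(K_obs)
  null <- emma_reml(means$value, X0, eig)
  list(y = means$value, X0 = X0, idx = idx, eig = eig, null = null,
       A = design$A, D = design$D, map = design$map, group = design$group,
       ids = design$ids)
}

#' Kinship-corrected single-marker scan for additive and dominance effects
#'
#' Model per marker: Y = X beta + S s + Z u + e over environment-stacked
#' adjusted entry means, with the marker's additive and dominance columns
#' entering jointly as fixed effects, environment as a fixed covariate,
#' and a polygenic term with the kinship as covariance. By default the
#' null-model variance components are estimated once and reused for every
#' marker (P3D); \code{mode = "exact"} re-estimates them per marker.
#'
#' @param means \code{phenotype_table} of adjusted means (one or more
#'   environments; stacked with an environment covariate).
#' @param design \code{design_matrices} over the scanned individuals.
#' @param kinship \code{relationship_matrix} covering all individuals.
#' @param mode "p3d" or "exact".
#' @return \code{scan_result} data frame: marker, chromosome, cM, additive
#'   and dominance estimates and P-values, plus the null variance
#'   components as attributes.
#' @export
main_effect_scan <- function(means, design, kinship, mode = c("p3d", "exact")) {
  mode <- match.arg(mode)
  ctx <- scan_context(means, design, kinship)
  m <- ncol(ctx$A)
  U <- ctx$null$U; d <- ctx$null$d
  ys <- ctx$null$ys; Xs0 <- ctx$null$Xs
  As <- crossprod(U, ctx$A[ctx$idx, , drop = FALSE])
  Ds <- crossprod(U, ctx$D[ctx$idx, , drop = FALSE])
  p0 <- ncol(Xs0)
  out <- data.frame(marker_id = ctx$map$marker_id,
                    chromosome = ctx$map$chromosome, cM = ctx$map$cM,
                    effect_a = NA_real_, effect_d = NA_real_,
                    p_a = NA_real_, p_d = NA_real_, note = "")
  has_d <- apply(ctx$D[ctx$idx, , drop = FALSE], 2, function(z) var(z) > 0)
  for (j in seq_len(m)) {
    acol <- ctx$A[ctx$idx, j]
    if (var(acol) == 0 && !has_d[j]) { out$p_a[j] <- 1; out$p_d[j] <- 1
      out$note[j] <- "constant"; next }
    Xs <- cbind(Xs0, As[, j], if (has_d[j]) Ds[, j])
    lambda <- ctx$null$lambda
    if (mode == "exact") {
      ex <- emma_reml(ctx$y, cbind(ctx$X0, acol,
                                   if (has_d[j]) ctx$D[ctx$idx, j]), ctx$eig)
      lambda <- ex$lambda
    }
    w <- rotated_wald(ys, Xs, d, lambda, test_cols = p0 + seq_len(1 + has_d[j]))
    if (is.null(w)) { out$p_a[j] <- 1; out$p_d[j] <- 1
      out$note[j] <- "rank-deficient"; next }
    out$effect_a[j] <- w$estimate[1]; out$p_a[j] <- w$p[1]
    if (has_d[j]) { out$effect_d[j] <- w$estimate[2]; out$p_d[j] <- w$p[2] }
    else out$p_d[j] <- NA_real_
  }
  structure(out, class = c("scan_result", "data.frame"),
            sigma2_u = ctx$null$sigma2_u, sigma2_e = ctx$null$sigma2_e,
            mode = mode)
}

#' Bonferroni-Holm step-down correction
#'
#' @param p_values finite P-values (one family).
#' @param alpha family-wise level.
#' @return logical rejection flags aligned with \code{p_values}.
#' @export
holm_correct <- function(p_values, alpha = 0.1) {
  ok <- is.finite(p_values)
  flags <- rep(FALSE, length(p_values))
  p <- p_values[ok]
  m <- length(p)
  if (m == 0) return(flags)
  o <- order(p)
  thr <- alpha / (m - seq_len(m) + 1)
  rej <- p[o] <= thr
  if (any(!rej)) rej[which(!rej)[1]:m] <- FALSE  # step-down stop
  f <- logical(m); f[o] <- rej
  flags[ok] <- f
  flags
}

# build the eight fixed columns of the two-locus model for a marker pair
pair_columns <- function(A, D, idx, j, k) {
  a1 <- A[idx, j]; a2 <- A[idx, k]; d1 <- D[idx, j]; d2 <- D[idx, k]
  cbind(a1 = a1, a2 = a2, d1 = d1, d2 = d2,
        i11 = a1 * a2, i12 = a1 * d2, i21 = d1 * a2, i22 = d1 * d2)
}

#' Full two-dimensional epistasis scan
#'
#' For every retained marker pair, fits the eight-term fixed model
#' (a1, a2, d1, d2, i11 = AxA, i12 = AxD, i21 = DxA, i22 = DxD) on the
#' kinship-whitened data, reusing the null-model spectral decomposition
#' (P3D). Pairs that are nearly collinear (within-pair r2 above
#' \code{max_r2}) or closer than \code{min_cM} on the same chromosome are
#' skipped and recorded.
#'
#' @inheritParams main_effect_scan
#' @param max_r2 collinearity filter on the additive codes of the pair.
#' @param min_cM minimum within-chromosome map distance.
#' @param pairs optional 2-column matrix of marker indices to restrict the
#'   scan (used by the permutation routine and tests).
#' @return \code{scan_result} data frame, one row per tested pair, with
#'   estimates and P-values of the four interaction terms.
#' @export
epistasis_scan_2d <- function(means, design, kinship, max_r2 = 0.9,
                              min_cM = 5, pairs = NULL) {
  ctx <- scan_context(means, design, kinship)
  res <- epistasis_scan_core(ctx, max_r2, min_cM, pairs)
  structure(res, class = c("scan_result", "data.frame"),
            sigma2_u = ctx$null$sigma2_u, sigma2_e = ctx$null$sigma2_e)
}

epistasis_scan_core <- function(ctx, max_r2 = 0.9, min_cM = 5, pairs = NULL,
                                ys = ctx$null$ys) {
  m <- ncol(ctx$A)
  if (is.null(pairs)) {
    pairs <- t(combn(m, 2))
  }
  A_idx <- ctx$A[ctx$idx, , drop = FALSE]
  same_chr <- ctx$map$chromosome[pairs[, 1]] == ctx$map$chromosome[pairs[, 2]]
  dist_cM <- abs(ctx$map$cM[pairs[, 1]] - ctx$map$cM[pairs[, 2]])
  r2 <- vapply(seq_len(nrow(pairs)), function(i) {
    a1 <- A_idx[, pairs[i, 1]]; a2 <- A_idx[, pairs[i, 2]]
    if (var(a1) == 0 || var(a2) == 0) return(1)
    cor(a1, a2)^2
  }, 0)
  skip <- r2 > max_r2 | (same_chr & dist_cM < min_cM)
  U <- ctx$null$U; d <- ctx$null$d; Xs0 <- ctx$null$Xs
  p0 <- ncol(Xs0)
  terms <- c("i11", "i12", "i21", "i22")
  n_pair <- nrow(pairs)
  est <- matrix(NA_real_, n_pair, 4, dimnames = list(NULL, terms))
  pv <- matrix(NA_real_, n_pair, 4, dimnames = list(NULL, paste0("p_", terms)))
  note <- ifelse(skip, ifelse(r2 > max_r2, "collinear", "proximal"), "")
  for (i in which(!skip)) {
    M <- pair_columns(ctx$A, ctx$D, ctx$idx, pairs[i, 1], pairs[i, 2])
    keep <- apply(M, 2, function(v) var(v) > 0)
    if (!any(keep[5:8])) { note[i] <- "no-interaction-contrast"; next }
    Ms <- crossprod(U, M[, keep, drop = FALSE])
    Xs <- cbind(Xs0, Ms)
    w <- rotated_wald(ys, Xs, d, ctx$null$lambda,
                      test_cols = p0 + seq_len(sum(keep)))
    if (is.null(w)) { note[i] <- "rank-deficient"; next }
    nm <- colnames(M)[keep]
    for (t in seq_along(terms)) {
      hit <- match(terms[t], nm)
      if (!is.na(hit)) { est[i, t] <- w$estimate[hit]; pv[i, t] <- w$p[hit] }
    }
  }
  data.frame(marker1 = ctx$map$marker_id[pairs[, 1]],
             marker2 = ctx$map$marker_id[pairs[, 2]],
             chrom1 = ctx$map$chromosome[pairs[, 1]],
             chrom2 = ctx$map$chromosome[pairs[, 2]],
             est, pv, note = note, row.names = NULL)
}

#' Permutation thresholds for the epistasis scan
#'
#' Permutes the genotype-to-phenotype assignment within the inbred and
#' hybrid groups separately (keeping a genotype's environment profile
#' together, preserving G-by-E structure), reruns the 2D scan, records the
#' genome-wide minimum P per interaction term, and returns the
#' ceiling(alpha * n_perm)-th smallest minimum as the per-term threshold.
#'
#' @inheritParams epistasis_scan_2d
#' @param n_perm number of permutations (>= 50).
#' @param alpha genome-wide level.
#' @param seed integer seed; thresholds are fully reproducible.
#' @return list with \code{thresholds} (named per term), \code{minima}
#'   (n_perm x 4 matrix) and the call parameters.
#' @export
permutation_threshold <- function(means, design, kinship, n_perm = 100,
                                  alpha = 0.05, seed = 1, max_r2 = 0.9,
                                  min_cM = 5, pairs = NULL) {
  if (n_perm < 50) stop_config("n_perm must be >= 50")
  if (ceiling(alpha * n_perm) < 1)
    stop_config("n_perm too small for requested alpha")
  ctx <- scan_context(means, design, kinship)
  gids <- unique(means$genotype_id)
  grp <- ctx$group[match(gids, ctx$ids)]
  minima <- matrix(NA_real_, n_perm, 4,
                   dimnames = list(NULL, c("i11", "i12", "i21", "i22")))
  U <- ctx$null$U
  key <- paste(means$genotype_id, means$environment)
  for (b in seq_len(n_perm)) {
    # permute whole genotype phenotype profiles within each group
    donor <- with_seed(split_seed(seed, paste0("perm", b)), {
      new <- gids
      for (g in unique(grp)) {
        i <- which(grp == g)
        new[i] <- gids[i][sample.int(length(i))]
      }
      setNames(new, gids)
    })
    yp <- means$value[match(paste(donor[means$genotype_id],
                                  means$environment), key)]
    ysp <- drop(crossprod(U, yp))
    res <- epistasis_scan_core(ctx, max_r2, min_cM, pairs, ys = ysp)
    for (t in c("i11", "i12", "i21", "i22"))
      minima[b, t] <- suppressWarnings(min(res[[paste0("p_", t)]], na.rm = TRUE))
  }
  minima[!is.finite(minima)] <- 1
  k <- ceiling(alpha * n_perm)
  thr <- apply(minima, 2, function(v) sort(v)[k])
  list(thresholds = thr, minima = minima, alpha = alpha, n_perm = n_perm,
       seed = seed)
}

#' Explained phenotypic and genotypic variance of detected QTL
#'
#' Multiple regression of the adjusted means on the detected-QTL design
#' columns, added in increasing P-value order; reports the sequential
#' adjusted-R2 increment per QTL, the total, and the genotypic proportion
#' pG = total R2 / H2 (capped at 1 with a warning).
#'
#' @param means \code{phenotype_table} of adjusted means.
#' @param detected data frame with columns \code{marker_id} and \code{p}
#'   (one row per detected QTL term) and \code{term} ("a" or "d").
#' @param design \code{design_matrices}.
#' @param h2 broad-sense heritability used for standardization.
#' @return list with \code{per_qtl} (sequential increments), \code{total_r2},
#'   \code{pG}, \code{capped}.
#' @export
explained_variance <- function(means, detected, design, h2) {
  if (nrow(detected) == 0) stop_data("no detected QTL")
  idx <- match(means$genotype_id, design$ids)
  env <- factor(means$environment)
  X0 <- if (nlevels(env) > 1) stats::model.matrix(~ env)
        else matrix(1, nrow(means), 1)
  detected <- detected[order(detected$p), , drop = FALSE]
  cols <- lapply(seq_len(nrow(detected)), function(i) {
    j <- match(detected$marker_id[i], design$map$marker_id)
    if (detected$term[i] == "a") design$A[idx, j] else design$D[idx, j]
  })
  y <- means$value
  n <- length(y)
  # adjusted R2 = 1 - (RSS / (n - p)) / (TSS / (n - 1))
  adj_r2 <- function(Xf) {
    f <- lm.fit(Xf, y)
    rss <- sum(f$residuals^2)
    tss <- sum((y - mean(y))^2)
    1 - (rss / (n - f$rank)) / (tss / (n - 1))
  }
  Xcur <- X0
  r2_prev <- adj_r2(Xcur)
  inc <- numeric(nrow(detected))
  dropped <- logical(nrow(detected))
  for (i in seq_along(cols)) {
    Xnew <- cbind(Xcur, cols[[i]])
    if (qr(Xnew)$rank <= qr(Xcur)$rank) {
      dropped[i] <- TRUE
      warning("collinear QTL column dropped: ", detected$marker_id[i])
      next
    }
    r2_new <- adj_r2(Xnew)
    inc[i] <- r2_new - r2_prev
    r2_prev <- r2_new
    Xcur <- Xnew
  }
  total <- r2_prev - adj_r2(X0)
  pG <- total / h2
  capped <- FALSE
  if (is.finite(pG) && pG > 1) { warning("pG > 1; capped"); pG <- 1; capped <- TRUE }
  list(per_qtl = data.frame(marker_id = detected$marker_id,
                            term = detected$term, p = detected$p,
                            r2_increment = inc, dropped = dropped),
       total_r2 = total, pG = pG, capped = capped)
}

#' Cross-validated mapping-based prediction accuracy
#'
#' Five-fold protocol: folds partition the hybrids only; each estimation
#' set contains all inbred lines plus 80\% of hybrids. Per fold, QTL are
#' detected in the estimation set (main-effect scan + Holm at
#' \code{alpha}), marker effects are estimated by multiple regression on
#' the detected columns, test hybrids are predicted from those effects,
#' and accuracy is cor(predicted, observed) / sqrt(H2). The kinship is
#' recomputed from the estimation set only (no leakage).
#'
#' @param means \code{phenotype_table} of adjusted means.
#' @param design \code{design_matrices} for all individuals.
#' @param h2 heritability for standardization.
#' @param folds number of folds (default 5).
#' @param alpha Holm family-wise level for detection (default 0.1).
#' @param seed fold-assignment seed.
#' @param models character subset of c("A", "AD"): additive-only predicts
#'   from additive columns; "AD" adds dominance columns of detected QTL.
#' @return data frame of per-fold, per-model accuracies (zero with a flag
#'   when a fold detects no QTL).
#' @export
cv_mapping_accuracy <- function(means, design, h2, folds = 5, alpha = 0.1,
                                seed = 1, models = c("A", "AD")) {
  gids <- unique(means$genotype_id)
  grp <- design$group[match(gids, design$ids)]
  hybs <- gids[grp == "hybrid"]
  fold_of <- with_seed(split_seed(seed, "cv_mapping"),
                       sample(rep(seq_len(folds), length.out = length(hybs))))
  out <- list()
  for (f in seq_len(folds)) {
    test_ids <- hybs[fold_of == f]
    est_rows <- !(means$genotype_id %in% test_ids)
    est_means <- phenotype_table(means[est_rows, , drop = FALSE],
                                 stage = pheno_stage(means))
    est_ids <- unique(est_means$genotype_id)
    keep <- design$ids %in% est_ids
    est_design <- structure(list(A = design$A[keep, , drop = FALSE],
                                 D = design$D[keep, , drop = FALSE],
                                 map = design$map, ids = design$ids[keep],
                                 group = design$group[keep]),
                            class = "design_matrices")
    Kest <- grm_from_design(est_design)
    scan <- main_effect_scan(est_means, est_design, Kest)
    # one genome-wide family over both terms, per the main-scan convention
    fam_p <- c(scan$p_a, scan$p_d)
    fam_term <- rep(c("a", "d"), each = nrow(scan))
    fam_marker <- rep(scan$marker_id, 2)
    flags <- holm_correct(fam_p, alpha)
    det <- data.frame(marker_id = fam_marker[flags], term = fam_term[flags],
                      p = fam_p[flags])
    test_rows <- means$genotype_id %in% test_ids
    obs <- tapply(means$value[test_rows], means$genotype_id[test_rows], mean)
    for (mod in models) {
      det_m <- if (mod == "A") det[det$term == "a", , drop = FALSE] else det
      if (nrow(det_m) == 0) {
        out[[length(out) + 1]] <- data.frame(fold = f, model = mod,
                                             accuracy = 0, n_qtl = 0,
                                             flagged = TRUE)
        next
      }
      # effect estimation by multiple regression in the estimation set
      eidx <- match(est_means$genotype_id, est_design$ids)
      Xq <- vapply(seq_len(nrow(det_m)), function(i) {
        j <- match(det_m$marker_id[i], design$map$marker_id)
        if (det_m$term[i] == "a") est_design$A[eidx, j] else est_design$D[eidx, j]
      }, numeric(nrow(est_means)))
      ef <- factor(est_means$environment)
      envX <- if (nlevels(ef) > 1) stats::model.matrix(~ ef)
              else matrix(1, nrow(est_means), 1)
      fitq <- lm.fit(cbind(envX, Xq), est_means$value)
      bq <- fitq$coefficients[ncol(envX) + seq_len(nrow(det_m))]
      bq[is.na(bq)] <- 0
      tidx <- match(names(obs), design$ids)
      Xt <- vapply(seq_len(nrow(det_m)), function(i) {
        j <- match(det_m$marker_id[i], design$map$marker_id)
        if (det_m$term[i] == "a") design$A[tidx, j] else design$D[tidx, j]
      }, numeric(length(obs)))
      pred <- drop(Xt %*% bq)
      acc <- if (sd(pred) == 0) 0 else cor(pred, obs) / sqrt(h2)
      out[[length(out) + 1]] <- data.frame(fold = f, model = mod,
                                           accuracy = acc,
                                           n_qtl = nrow(det_m), flagged = FALSE)
    }
  }
  do.call(rbind, out)
}

# internal kinship used inside mapping CV: one minus Rogers distance from
# the additive codes of the estimation set
grm_from_design <- function(design) {
  d <- as.matrix(stats::dist(design$A, method = "manhattan")) / (2 * ncol(design$A))
  relationship_matrix(1 - d, kind = "kinship", ids = design$ids)
}
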