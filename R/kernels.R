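#' Relationship matrix constructor
#'
#' @param values symmetric individuals x individuals matrix.
#' @param kind one of "kinship", "additive", "dominance", "gaussian".
#' @param ids individual identifiers.
#' @param params list of construction parameters needed to compute
#'   cross-blocks for new individuals (centers, scale, shrinkage intensity,
#'   bandwidth, training codes).
#' @return matrix of class \code{relationship_matrix}.
#' @export
relationship_matrix <- function(values, kind, ids = rownames(values),
                                params = list()) {
  values <- as.matrix(values)
  if (max(abs(values - t(values))) > 1e-10) stop_data("matrix not symmetric")
  if (any(!is.finite(diag(values))) || any(diag(values) <= 0))
    stop_data("diagonal must be finite and positive")
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(values)))
  dimnames(values) <- list(ids, ids)
  structure(values, kind = kind, ids = ids, params = params,
            class = c("relationship_matrix", "matrix"))
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat("relationship_matrix (", attr(x, "kind"), "): ", nrow(x), " x ",
      ncol(x), "\n", sep = "")
  invisible(x)
}

rm_subset <- function(K, ids) {
  i <- match(ids, attr(K, "ids"))
  if (anyNA(i)) stop_data("ids missing from relationship matrix")
  relationship_matrix(unclass(K)[i, i, drop = FALSE], attr(K, "kind"),
                      ids = ids, params = attr(K, "params"))
}

#' Rogers-distance kinship
#'
#' K(i, j) = 1 - mean per-locus Rogers distance. For biallelic loci with
#' per-individual allele frequencies (homozygote -> (1, 0), heterozygote
#' -> (1/2, 1/2)) the per-locus distance reduces to |p_i - p_j| =
#' |code_i - code_j| / 2, so identical lines score 1, opposite inbreds 0,
#' and a hybrid scores 0.5 against either parent at a divergent locus.
#'
#' @param markers \code{marker_matrix} with complete (or imputed) codes;
#'   missing values are mean-imputed per marker.
#' @return \code{relationship_matrix} of kind "kinship", entries in [0, 1].
#' @export
rogers_kinship <- function(markers) {
  stopifnot(inherits(markers, "marker_matrix"))
  if (ncol(markers$codes) == 0) stop_data("zero markers")
  x <- f_infinity_design(markers)$A
  d <- as.matrix(stats::dist(x, method = "manhattan")) / (2 * ncol(x))
  relationship_matrix(1 - d, kind = "kinship", ids = markers$ids)
}

# Ledoit-Wolf-type single-parameter linear shrinkage of a crossproduct
# similarity S = (1/m) sum_k w_k w_k' toward its own diagonal. The
# analytic intensity is the ratio of the summed sampling variances of the
# off-diagonal entries (estimated over markers) to their summed squared
# magnitude, clipped to [0, 1]. delta -> 0 as the number of markers grows.
shrink_intensity <- function(Xc) {
  m <- ncol(Xc)
  if (m < 2) return(0)
  S <- tcrossprod(Xc) / m
  S2 <- tcrossprod(Xc^2) / m          # mean of squared products
  varS <- (S2 - S^2) / (m - 1)        # var of the mean product
  num <- sum(varS) - sum(diag(varS))
  den <- sum(S^2) - sum(diag(S)^2)
  if (den <= 0) return(0)
  min(max(num / den, 0), 1)
}

crossprod_kernel <- function(Xc, kind, shrink, delta = NULL) {
  n <- nrow(Xc)
  if (n < 2) stop_data("fewer than 2 individuals")
  S <- tcrossprod(Xc)
  if (sum(abs(S)) < 1e-12)
    stop_data("no ", kind, " variation (all-zero design)")
  d <- 0
  if (shrink) d <- if (is.null(delta)) shrink_intensity(Xc) else delta
  Ssh <- (1 - d) * S + d * diag(diag(S), n)
  cc <- mean(diag(Ssh))
  relationship_matrix(Ssh / cc, kind = kind,
                      params = list(centers = attr(Xc, "centers"),
                                    scale_c = cc, delta = d))
}

#' Additive genomic relationship matrix
#'
#' G_a = A_c A_c' / c with A_c the column-centered additive codes and
#' c = trace(A_c A_c') / n, so the mean diagonal is 1. With
#' \code{shrink = TRUE} the crossproduct is first shrunk linearly toward
#' its own diagonal with an analytically estimated intensity (see
#' \code{\link{rogers_kinship}} for the kinship alternative).
#'
#' @param design \code{design_matrices} from \code{f_infinity_design}.
#' @param shrink apply linear shrinkage toward the diagonal target.
#' @param delta optional fixed shrinkage intensity in [0, 1] overriding the
#'   analytic estimate.
#' @return \code{relationship_matrix} of kind "additive".
#' @export
additive_relationship <- function(design, shrink = TRUE, delta = NULL) {
  stopifnot(inherits(design, "design_matrices"))
  ctr <- colMeans(design$A)
  Xc <- sweep(design$A, 2, ctr)
  attr(Xc, "centers") <- ctr
  K <- crossprod_kernel(Xc, "additive", shrink, delta)
  attr(K, "ids") <- design$ids; dimnames(K) <- list(design$ids, design$ids)
  attr(K, "train_centered") <- Xc
  K
}

#' Dominance genomic relationship matrix
#'
#' As \code{\link{additive_relationship}} but on the centered heterozygote
#' indicator D (F-infinity parameterization). An all-inbred panel has no
#' dominance variation and raises a data error.
#'
#' @inheritParams additive_relationship
#' @return \code{relationship_matrix} of kind "dominance".
#' @export
dominance_relationship <- function(design, shrink = TRUE, delta = NULL) {
  stopifnot(inherits(design, "design_matrices"))
  ctr <- colMeans(design$D)
  Xc <- sweep(design$D, 2, ctr)
  attr(Xc, "centers") <- ctr
  K <- crossprod_kernel(Xc, "dominance", shrink, delta)
  attr(K, "ids") <- design$ids; dimnames(K) <- list(design$ids, design$ids)
  attr(K, "train_centered") <- Xc
  K
}

#' Gaussian kernel over stacked additive and dominance codes
#'
#' K(i, j) = exp(-d2_ij / q) with d2 the squared Euclidean distance on the
#' column-stacked (A, D) codes, so heterozygosity differences contribute.
#' \code{bandwidth = "median"} sets q to the median off-diagonal d2, a
#' scale-free default; all higher-order epistatic interactions are
#' implicitly represented through the exponential.
#'
#' @param design \code{design_matrices}.
#' @param bandwidth positive scalar q, or "median".
#' @return \code{relationship_matrix} of kind "gaussian", entries in (0, 1].
#' @export
gaussian_kernel <- function(design, bandwidth = "median") {
  stopifnot(inherits(design, "design_matrices"))
  X <- cbind(design$A, design$D)
  d2 <- as.matrix(stats::dist(X))^2
  if (identical(bandwidth, "median")) {
    off <- d2[upper.tri(d2)]
    q <- median(off)
    if (!is.finite(q) || q <= 0)
      stop_data("degenerate bandwidth: all individuals identical")
  } else {
    q <- as.numeric(bandwidth)
    if (!is.finite(q) || q <= 0) stop_config("bandwidth must be positive")
  }
  relationship_matrix(exp(-d2 / q), kind = "gaussian", ids = design$ids,
                      params = list(bandwidth = q, train_codes = X))
}

#' Cross-block of a relationship matrix for new individuals
#'
#' Computes K(new, train) consistently with how the training matrix was
#' built: centered crossproducts reuse the training column centers, scale
#' and shrinkage intensity (off-diagonal blocks scale by 1 - delta, since
#' the diagonal target contributes nothing off-diagonal); the Gaussian
#' kernel reuses the training bandwidth.
#'
#' @param K training \code{relationship_matrix}.
#' @param new_design \code{design_matrices} for the new individuals (same
#'   marker panel and order as the training design).
#' @return matrix new x train.
#' @export
kernel_cross <- function(K, new_design) {
  kind <- attr(K, "kind"); p <- attr(K, "params")
  if (kind == "kinship") {
    stop_data("cross-blocks for raw kinship are not defined; use additive")
  } else if (kind %in% c("additive", "dominance")) {
    Xn <- if (kind == "additive") new_design$A else new_design$D
    Xn <- sweep(Xn, 2, p$centers)
    tr <- attr(K, "train_centered")
    if (is.null(tr)) stop_data("training codes not attached to this kernel")
    out <- (1 - p$delta) * tcrossprod(Xn, tr) / p$scale_c
  } else if (kind == "gaussian") {
    Xn <- cbind(new_design$A, new_design$D)
    tr <- p$train_codes
    d2 <- outer(rowSums(Xn^2), rowSums(tr^2), "+") - 2 * tcrossprod(Xn, tr)
    out <- exp(-pmax(d2, 0) / p$bandwidth)
  } else stop_data("unknown kernel kind: ", kind)
  rownames(out) <- new_design$ids; colnames(out) <- attr(K, "ids")
  out
}
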