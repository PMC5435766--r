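#' Marker matrix container
#'
#' Holds coded biallelic genotypes (rows = individuals, columns = markers),
#' with codes -1 (homozygote bb), 0 (heterozygote), +1 (homozygote AA) and
#' NA for missing, the marker map, and a per-individual group label
#' ("inbred" or "hybrid"). Inbred rows may not contain heterozygote codes.
#'
#' @param codes numeric matrix, individuals x markers, entries in {-1,0,1,NA}.
#' @param map \code{genetic_map} with one row per marker column.
#' @param ids individual identifiers (default: rownames of codes).
#' @param group character vector, one of "inbred"/"hybrid" per individual.
#' @return A \code{marker_matrix} object.
#' @export
marker_matrix <- function(codes, map, ids = rownames(codes),
                          group = rep("inbred", nrow(codes))) {
  codes <- as.matrix(codes)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(codes)))
  if (ncol(codes) != nrow(map))
    stop_data("codes has ", ncol(codes), " markers but map has ", nrow(map))
  if (length(ids) != nrow(codes) || length(group) != nrow(codes))
    stop_data("ids/group length does not match number of individuals")
  ok <- codes %in% c(-1, 0, 1) | is.na(codes)
  if (!all(ok)) stop_data("genotype codes must be -1, 0, +1 or NA")
  bad <- group == "inbred" & apply(codes == 0, 1, any, na.rm = TRUE)
  if (any(bad)) stop_data("inbred individual(s) carry heterozygote codes: ",
                          paste(head(ids[bad], 3), collapse = ", "))
  dimnames(codes) <- list(ids, map$marker_id)
  structure(list(codes = codes, map = map, ids = as.character(ids),
                 group = as.character(group)),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("marker_matrix:", nrow(x$codes), "individuals x", ncol(x$codes),
      "markers |", sum(x$group == "inbred"), "inbred,",
      sum(x$group == "hybrid"), "hybrid |",
      length(unique(x$map$chromosome)), "chromosomes\n")
  invisible(x)
}

subset_markers <- function(mm, keep) {
  marker_matrix(mm$codes[, keep, drop = FALSE],
                {m <- mm$map[keep, , drop = FALSE]; rownames(m) <- NULL;
                 class(m) <- c("genetic_map", "data.frame"); m},
                ids = mm$ids, group = mm$group)
}

subset_individuals <- function(mm, keep) {
  marker_matrix(mm$codes[keep, , drop = FALSE], mm$map,
                ids = mm$ids[keep], group = mm$group[keep])
}

#' Combine two marker matrices on the same marker panel
#'
#' @param a,b \code{marker_matrix} objects sharing an identical map.
#' @return A \code{marker_matrix} stacking the individuals of both.
#' @export
bind_individuals <- function(a, b) {
  if (!identical(a$map$marker_id, b$map$marker_id))
    stop_data("marker panels differ; cannot combine")
  marker_matrix(rbind(a$codes, b$codes), a$map,
                ids = c(a$ids, b$ids), group = c(a$group, b$group))
}

#' Infer immortalized-F2 hybrid genotypes from their DH parents
#'
#' Hybrid genotypes are fully determined by the parents: identical parental
#' homozygotes transmit the homozygote, opposite homozygotes give a
#' heterozygote (code 0), and a missing value in either parent propagates.
#' Numerically the hybrid code is the mean of the two parental codes.
#'
#' @param parents \code{marker_matrix} of fully homozygous lines.
#' @param design \code{crossing_design} whose parents all occur in
#'   \code{parents}.
#' @return \code{marker_matrix} of the hybrids (group "hybrid").
#' @export
infer_hybrid_genotypes <- function(parents, design) {
  stopifnot(inherits(parents, "marker_matrix"), inherits(design, "crossing_design"))
  miss <- !(c(design$parent1, design$parent2) %in% parents$ids)
  if (any(miss)) stop_data("design parents missing from marker matrix: ",
                           paste(unique(c(design$parent1, design$parent2)[miss]), collapse = ", "))
  het <- which(parents$codes == 0, arr.ind = TRUE)
  if (nrow(het) > 0)
    stop_data("heterozygous parent locus: line ", parents$ids[het[1, 1]],
              " at marker ", parents$map$marker_id[het[1, 2]])
  i1 <- match(design$parent1, parents$ids)
  i2 <- match(design$parent2, parents$ids)
  codes <- (parents$codes[i1, , drop = FALSE] + parents$codes[i2, , drop = FALSE]) / 2
  marker_matrix(codes, parents$map, ids = design$hybrid_id,
                group = rep("hybrid", nrow(design)))
}

#' Marker quality control
#'
#' Retains markers whose missing fraction is strictly below \code{miss_max}
#' and whose minor allele frequency is strictly above \code{maf_min}, both
#' computed over the supplied individuals. Boundary values are removed
#' (strict inequalities), mirroring "MAF > 5%" / "missing < 5%" wording;
#' ties are listed in the report.
#'
#' @param markers \code{marker_matrix}.
#' @param maf_min minimum (exclusive) minor allele frequency, in [0, 0.5].
#' @param miss_max maximum (exclusive) missing fraction, in [0, 1].
#' @return list with elements \code{markers} (filtered matrix) and
#'   \code{report} (data frame of removed markers with reasons and values).
#' @export
qc_filter <- function(markers, maf_min = 0.05, miss_max = 0.05) {
  stopifnot(inherits(markers, "marker_matrix"))
  if (ncol(markers$codes) == 0 || nrow(markers$codes) == 0)
    stop_data("empty marker matrix")
  if (maf_min < 0 || maf_min > 0.5) stop_config("maf_min must lie in [0, 0.5]")
  if (miss_max < 0 || miss_max > 1) stop_config("miss_max must lie in [0, 1]")
  x <- markers$codes
  missf <- colMeans(is.na(x))
  p <- colMeans((x + 1) / 2, na.rm = TRUE)  # frequency of the +1 allele
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  drop_miss <- missf >= miss_max
  drop_maf <- maf <= maf_min
  keep <- !(drop_miss | drop_maf)
  report <- data.frame(
    marker_id = markers$map$marker_id[!keep],
    reason = ifelse(drop_miss[!keep] & drop_maf[!keep], "missing+maf",
                    ifelse(drop_miss[!keep], "missing", "maf")),
    maf = maf[!keep], missing_fraction = missf[!keep],
    at_boundary = (maf[!keep] == maf_min) | (missf[!keep] == miss_max),
    row.names = NULL)
  list(markers = subset_markers(markers, keep), report = report)
}

#' Collapse markers in perfect linkage disequilibrium
#'
#' Within each chromosome, markers whose pairwise squared correlation equals
#' one (|r| >= 1 - 1e-12 on complete cases) are collapsed to a single
#' representative: the marker with the lowest map position in its cluster.
#' Sign flips (r = -1) count as perfect LD. Monomorphic columns, for which r
#' is undefined, are never clustered.
#'
#' @param markers \code{marker_matrix} without missing values.
#' @param tol numerical tolerance on 1 - |r|.
#' @return list with \code{markers} (deduplicated) and \code{clusters}
#'   (data frame mapping each removed marker to its kept representative).
#' @export
dedup_perfect_ld <- function(markers, tol = 1e-12) {
  stopifnot(inherits(markers, "marker_matrix"))
  if (anyNA(markers$codes))
    stop_data("dedup_perfect_ld requires complete genotypes (impute first)")
  keep <- rep(TRUE, ncol(markers$codes))
  rep_of <- character(0); member <- character(0)
  for (chr in unique(markers$map$chromosome)) {
    idx <- which(markers$map$chromosome == chr)
    if (length(idx) < 2) next
    x <- markers$codes[, idx, drop = FALSE]
    sds <- apply(x, 2, sd)
    poly <- which(sds > 0)
    if (length(poly) < 2) next
    r <- suppressWarnings(cor(x[, poly, drop = FALSE]))
    perfect <- abs(r) >= 1 - tol
    assigned <- rep(NA_integer_, length(poly))
    cl <- 0L
    for (j in seq_along(poly)) {        # markers are in map order already
      if (!is.na(assigned[j])) next
      cl <- cl + 1L
      members <- which(perfect[j, ] & is.na(assigned))
      assigned[members] <- cl
      if (length(members) > 1) {
        keep_j <- members[1]            # lowest map position
        drop_j <- members[-1]
        keep[idx[poly[drop_j]]] <- FALSE
        rep_of <- c(rep_of, rep(markers$map$marker_id[idx[poly[keep_j]]], length(drop_j)))
        member <- c(member, markers$map$marker_id[idx[poly[drop_j]]])
      }
    }
  }
  list(markers = subset_markers(markers, keep),
       clusters = data.frame(representative = rep_of, member = member,
                             row.names = NULL))
}

#' F-infinity metric design matrices
#'
#' Builds the additive design A (equal to the genotype code, -1/0/+1) and
#' the dominance design D (indicator of the heterozygote, 0/1). Fully
#' inbred rows therefore have an all-zero D row. Missing genotypes are
#' either mean-imputed per marker (A gets the marker mean, D the marker
#' heterozygosity rate) or raise an error, depending on \code{impute}.
#'
#' @param markers \code{marker_matrix}.
#' @param impute one of "mean" or "none".
#' @return list of class \code{design_matrices} with elements \code{A},
#'   \code{D}, \code{map}, \code{ids}, \code{group}.
#' @export
f_infinity_design <- function(markers, impute = c("mean", "none")) {
  stopifnot(inherits(markers, "marker_matrix"))
  impute <- match.arg(impute)
  A <- markers$codes
  D <- (markers$codes == 0) * 1
  if (anyNA(A)) {
    if (impute == "none")
      stop_data("missing genotypes present and impute = \"none\"")
    for (j in which(colSums(is.na(A)) > 0)) {
      na <- is.na(A[, j])
      A[na, j] <- mean(A[, j], na.rm = TRUE)
      D[na, j] <- mean(D[, j], na.rm = TRUE)
    }
  }
  structure(list(A = A, D = D, map = markers$map, ids = markers$ids,
                 group = markers$group),
            class = "design_matrices")
}
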