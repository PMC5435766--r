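#' Variance component container
#'
#' @param components named numeric vector of variance components; expected
#'   names include \code{sigma2_genotype}, \code{sigma2_gca},
#'   \code{sigma2_sca}, \code{sigma2_gxe}, \code{sigma2_env_x_gca},
#'   \code{sigma2_env_x_sca}, \code{sigma2_residual} (all >= 0).
#' @param n_env,n_rep trial dimensions used for heritability.
#' @param significance optional named numeric of likelihood-ratio P-values.
#' @return object of class \code{variance_components}.
#' @export
variance_components <- function(components, n_env, n_rep,
                                significance = NULL) {
  if (any(components < -1e-12, na.rm = TRUE))
    stop_data("variance components must be non-negative")
  components <- pmax(components, 0)
  out <- structure(list(components = components, n_env = n_env,
                        n_rep = n_rep, significance = significance),
                   class = "variance_components")
  out$heritability <- tryCatch(heritability(out), error = function(e) NA_real_)
  out
}

#' @export
print.variance_components <- function(x, ...) {
  cat("variance_components (n_env =", x$n_env, ", n_rep =", x$n_rep, ")\n")
  print(round(x$components, 5))
  cat("H2 =", round(x$heritability, 4), "\n")
  invisible(x)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' H2 = s2_G / (s2_G + s2_GxE / N_E + s2_E / (N_E N_R)): the genotypic
#' share of the variance of genotype means given the trial's environment
#' and replicate structure.
#'
#' @param vc \code{variance_components}, or a named numeric vector with
#'   \code{sigma2_genotype}, \code{sigma2_gxe}, \code{sigma2_residual}.
#' @param n_env,n_rep override the trial dimensions stored in \code{vc}.
#' @return H2 in [0, 1].
#' @export
heritability <- function(vc, n_env = NULL, n_rep = NULL) {
  if (inherits(vc, "variance_components")) {
    comp <- vc$components
    n_env <- n_env %||% vc$n_env
    n_rep <- n_rep %||% vc$n_rep
  } else comp <- vc
  need <- c("sigma2_genotype", "sigma2_gxe", "sigma2_residual")
  if (!all(need %in% names(comp)))
    stop_data("need components ", paste(need, collapse = ", "))
  if (is.null(n_env) || is.null(n_rep)) stop_config("n_env and n_rep required")
  g <- comp[["sigma2_genotype"]]
  denom <- g + comp[["sigma2_gxe"]] / n_env +
    comp[["sigma2_residual"]] / (n_env * n_rep)
  if (denom <= 0) stop_data("zero phenotypic variance in H2 denominator")
  g / denom
}

#' Outlier detection on plot data (Anscombe-Tukey style rejection)
#'
#' Within each environment, observations are screened against the
#' genotype-means model y = mu + g + e: an observation whose internally
#' studentized residual exceeds the rejection bound is flagged. The bound
#' is the normal quantile at which about one observation in
#' \code{1/rate} is rejected under normality (the classic premium
#' calibration; default rate 1/250).
#'
#' @param plots plot-stage \code{phenotype_table}.
#' @param rate expected null rejection rate per observation.
#' @return list with \code{pheno} (cleaned table) and \code{removed}
#'   (data frame: genotype, environment, replicate, value, statistic).
#' @export
detect_outliers <- function(plots, rate = 1 / 250) {
  stopifnot(inherits(plots, "phenotype_table"))
  if (pheno_stage(plots) != "plot") stop_data("expected a plot-stage table")
  cutoff <- qnorm(1 - rate / 2)
  removed <- list()
  keep <- rep(TRUE, nrow(plots))
  for (env in unique(plots$environment)) {
    i <- which(plots$environment == env)
    if (length(i) < 3) { warning("fewer than 3 observations in ", env,
                                 "; skipping outlier test"); next }
    y <- plots$value[i]
    g <- factor(plots$genotype_id[i])
    res <- y - ave(y, g)
    n_cell <- ave(rep(1, length(i)), g, FUN = sum)
    dfr <- length(i) - nlevels(g)
    if (dfr <= 0) next
    s2 <- sum(res^2) / dfr
    if (s2 <= 0) next                       # all values identical
    lev <- 1 / n_cell                       # leverage of a cell-means model
    std <- res / sqrt(s2 * (1 - lev))
    std[n_cell == 1] <- 0                   # single plots are their own mean
    bad <- which(abs(std) > cutoff)
    if (length(bad) > 0) {
      keep[i[bad]] <- FALSE
      removed[[env]] <- data.frame(
        genotype_id = plots$genotype_id[i[bad]], environment = env,
        replicate = plots$replicate[i[bad]], value = y[bad],
        statistic = std[bad], row.names = NULL)
    }
  }
  removed <- if (length(removed)) do.call(rbind, c(removed, make.row.names = FALSE))
             else data.frame(genotype_id = character(0), environment = character(0),
                             replicate = integer(0), value = numeric(0),
                             statistic = numeric(0))
  list(pheno = phenotype_table(plots[keep, , drop = FALSE], stage = "plot"),
       removed = removed)
}

#' Adjusted means within each environment
#'
#' Fits y = mu + g_i + e per environment with genotype fixed, so with
#' balanced data the adjusted mean is the arithmetic mean of a genotype's
#' plots in that environment.
#'
#' @param plots plot-stage \code{phenotype_table}.
#' @return \code{phenotype_table} at stage "within_env_means" (replicate 1).
#' @export
adjust_means_within_env <- function(plots) {
  stopifnot(inherits(plots, "phenotype_table"))
  agg <- aggregate(value ~ genotype_id + environment, data = plots, FUN = mean)
  phenotype_table(data.frame(genotype_id = agg$genotype_id,
                             environment = agg$environment,
                             replicate = 1L, value = agg$value),
                  stage = "within_env_means")
}

#' Adjusted means across environments
#'
#' Fits y_ik = g_i + l_k + e with genotype fixed and environment (and
#' residual) random, via REML; the adjusted mean of genotype i is its fixed
#' estimate. With complete data and zero environment variance this equals
#' the mean of the within-environment means. Genotypes observed in no
#' environment are dropped with a warning.
#'
#' @param within \code{phenotype_table} of within-environment means.
#' @return \code{phenotype_table} at stage "across_env_means"
#'   (environment "ALL").
#' @export
adjust_means_across_env <- function(within) {
  stopifnot(inherits(within, "phenotype_table"))
  gid <- factor(within$genotype_id)
  env <- factor(within$environment)
  if (nlevels(env) == 1) {
    out <- data.frame(genotype_id = levels(gid), environment = "ALL",
                      replicate = 1L,
                      value = tapply(within$value, gid, mean)[levels(gid)])
    return(phenotype_table(out, stage = "across_env_means"))
  }
  X <- stats::model.matrix(~ 0 + gid)
  Zl <- stats::model.matrix(~ 0 + env)
  fit <- mm_reml(within$value, X, list(env = tcrossprod(Zl)))
  out <- data.frame(genotype_id = levels(gid), environment = "ALL",
                    replicate = 1L, value = as.numeric(fit$beta))
  phenotype_table(out, stage = "across_env_means")
}

#' One-step GCA/SCA variance decomposition
#'
#' Fits the joint lines-plus-hybrids model
#' y = mu + group + p + (pl) + m + f + s + (ml) + (fl) + (sl) + l + e
#' with all effects random except the mean and group. Both parental GCA
#' factors are draws from one DH panel, so their variances are constrained
#' equal; the reported \code{sigma2_gca} is the total GCA variance of a
#' hybrid (both parents), matching the convention
#' sigma2_genotype = sigma2_gca + sigma2_sca.
#'
#' Estimation is exact two-stage REML under cell-balanced data: the plot
#' residual comes from the pooled within-(genotype x environment)-cell
#' variance (the saturated cell-level interaction effects make within-cell
#' contrasts pure error), and the remaining components are estimated by
#' dense average-information REML on the cell means with the known
#' residual offset.
#'
#' @param plots plot-stage \code{phenotype_table} covering lines and hybrids.
#' @param pedigree \code{crossing_design} mapping each hybrid to its parents.
#' @param groups named character vector genotype_id -> "inbred"/"hybrid";
#'   if NULL, genotypes present in \code{pedigree$hybrid_id} are hybrids.
#' @param significance FALSE, TRUE (all components), or a character vector
#'   of components to test by likelihood-ratio against the dropped model
#'   (0.5 chi2_0 + 0.5 chi2_1 mixture reference).
#' @return \code{variance_components} with hybrid-side components, plus
#'   parent-side entries \code{sigma2_genotype_parents},
#'   \code{sigma2_gxe_parents} and the environment main variance.
#' @export
fit_gca_sca <- function(plots, pedigree, groups = NULL, significance = FALSE) {
  stopifnot(inherits(plots, "phenotype_table"), inherits(pedigree, "crossing_design"))
  gids <- unique(plots$genotype_id)
  if (is.null(groups)) {
    groups <- setNames(ifelse(gids %in% pedigree$hybrid_id, "hybrid", "inbred"), gids)
  }
  hyb <- gids[groups[gids] == "hybrid"]
  if (!all(hyb %in% pedigree$hybrid_id))
    stop_data("hybrids without pedigree: ",
              paste(head(setdiff(hyb, pedigree$hybrid_id), 3), collapse = ", "))

  # stage 1: pooled within-cell residual
  cell <- paste(plots$genotype_id, plots$environment)
  cm <- ave(plots$value, cell)
  n_cell_obs <- ave(rep(1, nrow(plots)), cell, FUN = sum)
  dfe <- sum(tapply(n_cell_obs, cell, `[`, 1) - 1)
  s2e <- if (dfe > 0) sum((plots$value - cm)^2) / dfe else 0
  if (dfe == 0)
    warning("single plot per cell: residual aliased with G-by-E terms; sigma2_residual set to 0")

  # stage 2: cell means with known residual offset s2e / n_cell
  agg <- aggregate(value ~ genotype_id + environment, data = plots, FUN = mean)
  cnt <- aggregate(value ~ genotype_id + environment, data = plots, FUN = length)
  n <- nrow(agg)
  is_hyb <- groups[agg$genotype_id] == "hybrid"
  env <- factor(agg$environment)
  gid <- factor(agg$genotype_id)
  parents <- sort(unique(c(pedigree$parent1, pedigree$parent2)))
  pk <- match(agg$genotype_id, pedigree$hybrid_id)

  Zl <- stats::model.matrix(~ 0 + env)
  # line genetic effect (line cells only)
  lin_lev <- sort(unique(agg$genotype_id[!is_hyb]))
  Zp <- matrix(0, n, length(lin_lev))
  Zp[cbind(which(!is_hyb), match(agg$genotype_id[!is_hyb], lin_lev))] <- 1
  # combined GCA design: two 1s per hybrid cell on the parent panel
  Zg <- matrix(0, n, length(parents))
  hr <- which(is_hyb)
  Zg[cbind(hr, match(pedigree$parent1[pk[hr]], parents))] <- 1
  Zg[cbind(hr, match(pedigree$parent2[pk[hr]], parents))] <-
    Zg[cbind(hr, match(pedigree$parent2[pk[hr]], parents))] + 1
  # SCA
  hyb_lev <- sort(unique(agg$genotype_id[is_hyb]))
  Zs <- matrix(0, n, length(hyb_lev))
  Zs[cbind(hr, match(agg$genotype_id[is_hyb], hyb_lev))] <- 1
  # GCA x environment: parent-by-env columns
  ne <- nlevels(env)
  Zgl <- matrix(0, n, length(parents) * ne)
  ek <- as.integer(env)
  Zgl[cbind(hr, (ek[hr] - 1) * length(parents) + match(pedigree$parent1[pk[hr]], parents))] <- 1
  idx2 <- cbind(hr, (ek[hr] - 1) * length(parents) + match(pedigree$parent2[pk[hr]], parents))
  Zgl[idx2] <- Zgl[idx2] + 1
  # saturated cell-level terms: diagonal indicator structures
  Dpl <- diag(as.numeric(!is_hyb))
  Dsl <- diag(as.numeric(is_hyb))
  offset <- diag(s2e / cnt$value, n)

  Vlist <- list(env = tcrossprod(Zl),
                line = tcrossprod(Zp),
                gca = tcrossprod(Zg),
                sca = tcrossprod(Zs),
                env_x_gca = tcrossprod(Zgl),
                line_x_env = Dpl,
                env_x_sca = Dsl)
  Vlist <- Vlist[vapply(Vlist, function(V) sum(abs(V)) > 0, TRUE)]
  X <- cbind(1, as.numeric(is_hyb))
  fit <- mm_reml(agg$value, X, Vlist, include_resid = FALSE, offset = offset)
  if (!fit$converged) {
    fit2 <- mm_reml(agg$value, X, Vlist, include_resid = FALSE,
                    offset = offset + diag(1e-4 * var(agg$value), n))
    if (fit2$converged) fit <- fit2
  }
  th <- fit$theta
  gv <- function(nm) if (nm %in% names(th)) th[[nm]] else 0
  nr <- mean(cnt$value)
  comp <- c(
    sigma2_genotype      = 2 * gv("gca") + gv("sca"),
    sigma2_gca           = 2 * gv("gca"),
    sigma2_sca           = gv("sca"),
    sigma2_gxe           = 2 * gv("env_x_gca") + gv("env_x_sca"),
    sigma2_env_x_gca     = 2 * gv("env_x_gca"),
    sigma2_env_x_sca     = gv("env_x_sca"),
    sigma2_residual      = s2e,
    sigma2_env           = gv("env"),
    sigma2_genotype_parents = gv("line"),
    sigma2_gxe_parents   = gv("line_x_env"))

  sig <- NULL
  if (!isFALSE(significance)) {
    comps <- if (isTRUE(significance)) names(Vlist) else {
      map <- c(gca = "gca", sca = "sca", env_x_gca = "env_x_gca",
               env_x_sca = "env_x_sca", line = "line",
               line_x_env = "line_x_env", env = "env",
               sigma2_gca = "gca", sigma2_sca = "sca")
      unname(map[significance])
    }
    sig <- vapply(comps, function(k) {
      f0 <- mm_reml(agg$value, X, Vlist[names(Vlist) != k],
                    include_resid = FALSE, offset = offset)
      lr <- max(0, 2 * (fit$loglik - f0$loglik))
      0.5 * pchisq(lr, df = 1, lower.tail = FALSE) + 0.5 * (lr <= 0)
    }, 0)
    names(sig) <- comps
  }
  variance_components(comp, n_env = ne, n_rep = nr, significance = sig)
}
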