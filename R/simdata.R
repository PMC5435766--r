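#' Simulate a biparental doubled-haploid population
#'
#' Each DH line is a single doubled gamete of the F1 between two fully
#' homozygous founders that differ at every mapped marker, so every marker
#' is informative with expected allele frequency one half. Meiosis is
#' simulated per chromosome as a Markov chain along the map with Haldane
#' recombination fractions r = (1 - exp(-2 d / 100)) / 2 between adjacent
#' markers (no crossover interference). Lines are coded +1 for the
#' parent-1 allele and -1 for the parent-2 allele; heterozygotes cannot
#' occur.
#'
#' @param map \code{genetic_map}.
#' @param n_lines number of DH lines (>= 2).
#' @param seed integer seed; fully determines the output.
#' @return \code{marker_matrix} of homozygous lines (group "inbred").
#' @export
simulate_dh_population <- function(map, n_lines, seed = 1) {
  if (!inherits(map, "genetic_map") || nrow(map) == 0)
    stop_config("map must be a non-empty genetic_map")
  if (n_lines < 2) stop_config("n_lines must be >= 2")
  chrs <- unique(map$chromosome)
  with_seed(split_seed(seed, "dh_meiosis"), {
    cols <- lapply(chrs, function(chr) {
      pos <- map$cM[map$chromosome == chr]
      m <- length(pos)
      r <- if (m > 1) (1 - exp(-2 * diff(pos) / 100)) / 2 else numeric(0)
      first <- ifelse(runif(n_lines) < 0.5, 1, -1)
      if (m == 1) return(matrix(first, ncol = 1))
      # switch[, k] == TRUE means a recombination between markers k and k+1
      sw <- matrix(runif(n_lines * (m - 1)) < rep(r, each = n_lines), n_lines)
      cum <- matrix(0L, n_lines, m)
      cum[, -1] <- t(apply(sw, 1, cumsum))
      first * (-1)^cum
    })
    geno <- do.call(cbind, cols)
  })
  marker_matrix(geno, map, ids = sprintf("DH%03d", seq_len(n_lines)),
                group = rep("inbred", n_lines))
}

#' Random immortalized-F2 crossing design
#'
#' Draws unordered parent pairs without replacement (no self-crosses, no
#' duplicate pairs), capping per-parent usage at
#' \code{ceiling(2 n_crosses / n_parents) + 1}. When enough crosses are
#' requested (>= n_parents / 2), a first pass pairs a random shuffle of all
#' parents so every line serves as a parent at least once.
#'
#' @param n_parents number of available lines.
#' @param n_crosses number of single crosses; at most choose(n_parents, 2).
#' @param seed integer seed.
#' @param parent_ids optional parent labels (default DH001, ...).
#' @return \code{crossing_design} data frame with columns \code{parent1},
#'   \code{parent2}, \code{hybrid_id}.
#' @export
make_crossing_design <- function(n_parents, n_crosses, seed = 1,
                                 parent_ids = sprintf("DH%03d", seq_len(n_parents))) {
  if (n_parents < 2) stop_config("need at least 2 parents")
  if (n_crosses < 1 || n_crosses > n_parents * (n_parents - 1) / 2)
    stop_config("n_crosses must lie in [1, choose(n_parents, 2)]")
  cap <- ceiling(2 * n_crosses / n_parents) + 1
  with_seed(split_seed(seed, "crossing_design"), {
    pairs <- matrix(integer(0), 0, 2)
    if (n_crosses >= n_parents / 2) {        # coverage pass
      ord <- sample.int(n_parents)
      k <- floor(n_parents / 2)
      pairs <- cbind(ord[seq_len(k)], ord[k + seq_len(k)])
      if (n_parents %% 2 == 1)               # odd one out gets a partner
        pairs <- rbind(pairs, c(ord[n_parents],
                                sample(ord[-n_parents], 1)))
      pairs <- pairs[seq_len(min(nrow(pairs), n_crosses)), , drop = FALSE]
    }
    key <- function(p) paste(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]))
    used <- tabulate(pairs, n_parents)
    seen <- key(pairs)
    tries <- 0
    while (nrow(pairs) < n_crosses) {
      avail <- which(used < cap)
      if (length(avail) < 2 || tries > 200 * n_crosses) { # cap too tight: relax
        cap <- cap + 1; tries <- 0; next
      }
      cand <- sample(avail, 2)
      k <- key(matrix(cand, 1))
      tries <- tries + 1
      if (k %in% seen) next
      pairs <- rbind(pairs, cand)
      seen <- c(seen, k)
      used[cand] <- used[cand] + 1
    }
  })
  p1 <- parent_ids[pmin(pairs[, 1], pairs[, 2])]
  p2 <- parent_ids[pmax(pairs[, 1], pairs[, 2])]
  crossing_design(p1, p2)
}

#' Crossing design constructor
#'
#' @param parent1,parent2 parent identifiers per cross (no self-crosses,
#'   no duplicate unordered pairs).
#' @param hybrid_id optional hybrid labels.
#' @return \code{crossing_design} data frame.
#' @export
crossing_design <- function(parent1, parent2,
                            hybrid_id = sprintf("HYB%03d", seq_along(parent1))) {
  if (any(parent1 == parent2)) stop_config("self-crosses are not allowed")
  k <- paste(pmin(parent1, parent2), pmax(parent1, parent2))
  if (anyDuplicated(k)) stop_config("duplicate unordered parent pairs")
  structure(data.frame(parent1 = as.character(parent1),
                       parent2 = as.character(parent2),
                       hybrid_id = as.character(hybrid_id),
                       stringsAsFactors = FALSE),
            class = c("crossing_design", "data.frame"))
}

#' Ground-truth genetic architecture for simulation
#'
#' Houses the generative counterparts of per-QTL additive (a) and dominance
#' (d) effects, digenic epistatic effects of the four types (AA, AD, DA,
#' DD), per-environment main shifts, per-effect-class G-by-E scales,
#' and the plot residual scale.
#'
#' @param qtl_positions integer marker indices of the QTL.
#' @param additive_effects,dominance_effects numeric vectors aligned with
#'   \code{qtl_positions}.
#' @param epistatic_pairs data frame with columns \code{locus1},
#'   \code{locus2} (marker indices), \code{type} in {"AA","AD","DA","DD"},
#'   \code{effect}; or NULL.
#' @param env_effects per-environment main shifts (length >= n_env used).
#' @param gxe_sd named numeric, environment-interaction scale per effect
#'   class, as a multiple of that class's root-mean-square effect:
#'   \code{c(additive=, dominance=, epistasis=)}.
#' @param residual_sd plot-level residual standard deviation.
#' @param mu overall mean; \code{group_shift} is added to hybrids (the
#'   heterosis gap between population means).
#' @param seed integer; fully determines all downstream randomness.
#' @return object of class \code{sim_truth}.
#' @export
sim_truth <- function(qtl_positions, additive_effects, dominance_effects,
                      epistatic_pairs = NULL, env_effects = 0,
                      gxe_sd = c(additive = 0, dominance = 0, epistasis = 0),
                      residual_sd = 0, mu = 1.65, group_shift = 0.44,
                      seed = 1) {
  q <- length(qtl_positions)
  if (length(additive_effects) != q || length(dominance_effects) != q)
    stop_config("effect vectors must align with qtl_positions")
  if (!is.null(epistatic_pairs)) {
    stopifnot(all(c("locus1", "locus2", "type", "effect") %in% names(epistatic_pairs)))
    if (!all(epistatic_pairs$type %in% c("AA", "AD", "DA", "DD")))
      stop_config("epistatic type must be AA, AD, DA or DD")
  }
  gxe <- c(additive = 0, dominance = 0, epistasis = 0)
  gxe[names(gxe_sd)] <- gxe_sd
  structure(list(gxe_targets = NULL,
                 qtl_positions = as.integer(qtl_positions),
                 additive_effects = as.numeric(additive_effects),
                 dominance_effects = as.numeric(dominance_effects),
                 epistatic_pairs = epistatic_pairs,
                 env_effects = as.numeric(env_effects),
                 gxe_sd = gxe, residual_sd = residual_sd,
                 mu = mu, group_shift = group_shift,
                 seed = as.integer(seed)),
            class = "sim_truth")
}

# Genetic values from code matrix (individuals x markers) under a given set
# of effect vectors. Used for both the truth's main effects and their
# per-environment redraws.
genetic_values <- function(codes, truth, a = truth$additive_effects,
                           d = truth$dominance_effects,
                           epi = if (is.null(truth$epistatic_pairs)) NULL
                                 else truth$epistatic_pairs$effect) {
  qp <- truth$qtl_positions
  if (length(qp) > 0 && max(qp) > ncol(codes))
    stop_config("QTL index out of range for the marker matrix")
  g <- rep(0, nrow(codes))
  if (length(qp) > 0) {
    x <- codes[, qp, drop = FALSE]
    z <- (x == 0) * 1
    g <- g + drop(x %*% a) + drop(z %*% d)
  }
  ep <- truth$epistatic_pairs
  if (!is.null(ep) && nrow(ep) > 0) {
    if (max(ep$locus1, ep$locus2) > ncol(codes))
      stop_config("epistatic locus index out of range")
    for (i in seq_len(nrow(ep))) {
      x1 <- codes[, ep$locus1[i]]; x2 <- codes[, ep$locus2[i]]
      w <- switch(ep$type[i],
                  AA = x1 * x2,
                  AD = x1 * (x2 == 0),
                  DA = (x1 == 0) * x2,
                  DD = (x1 == 0) * (x2 == 0))
      g <- g + epi[i] * w
    }
  }
  g
}

# Per-environment redraws of every effect class: class effects become
# effect + Normal(0, gxe_sd[class] * rms(class effects)). Used for
# uncalibrated truths; calibrated truths use gxe_interaction_draw instead.
env_effect_draw <- function(truth, n_env, seed_stage) {
  with_seed(split_seed(truth$seed, seed_stage), {
    lapply(seq_len(n_env), function(k) {
      a <- truth$additive_effects +
        rnorm(length(truth$additive_effects), 0,
              truth$gxe_sd["additive"] * rms(truth$additive_effects))
      d <- truth$dominance_effects +
        rnorm(length(truth$dominance_effects), 0,
              truth$gxe_sd["dominance"] * rms(truth$dominance_effects))
      epi <- NULL
      if (!is.null(truth$epistatic_pairs) && nrow(truth$epistatic_pairs) > 0)
        epi <- truth$epistatic_pairs$effect +
          rnorm(nrow(truth$epistatic_pairs), 0,
                truth$gxe_sd["epistasis"] * rms(truth$epistatic_pairs$effect))
      list(a = a, d = d, epi = epi)
    })
  })
}

# Calibrated-truth G-by-E: one iid deviation per (parent, environment)
# feeding both of a parent's hybrids (GCA-by-environment), one iid
# deviation per (hybrid, environment) (SCA-by-environment), and one per
# (line, environment). Each environment's vectors are (i) orthogonalized in
# value space against the realized main component of the same structure
# (parental for GCA-by-E, cross-specific for SCA-by-E) and against the
# deviations of earlier environments -- otherwise the random cross terms
# between deviations and main effects leak into the REML main-effect
# estimates -- and (ii) centered and scaled so the realized deviation
# variances over the simulated population equal the calibrated targets
# exactly. Returns one deviation vector (aligned with geno$ids) per
# environment.
gxe_interaction_draw <- function(truth, design, geno, n_env, seed_stage) {
  parents <- sort(unique(c(design$parent1, design$parent2)))
  i1 <- match(design$parent1, parents); i2 <- match(design$parent2, parents)
  hyb_pos <- match(design$hybrid_id, geno$ids)
  line_ids <- geno$ids[geno$group == "inbred"]
  line_pos <- match(line_ids, geno$ids)
  exg <- truth$gxe_targets$additive %||% 0
  exs <- truth$gxe_targets$dominance %||% 0
  pl_t <- truth$gxe_targets$parents %||% 0
  ctr <- function(v) v - mean(v)
  exact_scale <- function(v, target) {
    if (target <= 0 || length(v) < 2) return(rep(0, length(v)))
    v <- ctr(v)
    s <- sqrt(mean(v^2))
    if (s == 0) return(v)
    v * sqrt(target) / s
  }
  orth <- function(v, basis) {
    for (b in basis) {
      ss <- sum(ctr(b)^2)
      if (ss > 0) v <- v - sum(ctr(v) * ctr(b)) / ss * b
    }
    v
  }
  # realized main components on this population
  g_main <- genetic_values(geno$codes, truth)
  hv_main <- g_main[hyb_pos]
  gca_basis <- list(); sca_basis <- list(); line_basis <- list()
  par_basis <- list()
  if (length(hyb_pos) > 0 && sd(hv_main) > 0) {
    Z <- matrix(0, nrow(design), length(parents))
    Z[cbind(seq_len(nrow(design)), i1)] <- 1
    Z[cbind(seq_len(nrow(design)), i2)] <- Z[cbind(seq_len(nrow(design)), i2)] + 1
    fit <- lm.fit(cbind(1, Z), hv_main)
    par_main <- fit$coefficients[-1]
    par_main[is.na(par_main)] <- 0
    gca_basis <- list(unname(par_main))
    sca_basis <- list(unname(fit$residuals))
  }
  if (length(line_pos) > 1) line_basis <- list(g_main[line_pos])
  with_seed(split_seed(truth$seed, seed_stage), {
    lapply(seq_len(n_env), function(k) {
      out <- numeric(length(geno$ids))
      if (length(hyb_pos) > 0) {
        # parent-level draw, orthogonalized in the hybrid-value metric
        w <- rnorm(length(parents))
        for (b in gca_basis) {
          bv <- ctr(b[i1] + b[i2])
          wv <- ctr(w[i1] + w[i2])
          ss <- sum(bv^2)
          if (ss > 0) w <- w - sum(wv * bv) / ss * b
        }
        gca_basis[[length(gca_basis) + 1]] <<- w
        sl <- orth(rnorm(nrow(design)), sca_basis)
        sca_basis[[length(sca_basis) + 1]] <<- sl
        out[hyb_pos] <- exact_scale(w[i1] + w[i2], exg) + exact_scale(sl, exs)
      }
      if (length(line_pos) > 1) {
        pl <- orth(rnorm(length(line_pos)), line_basis)
        line_basis[[length(line_basis) + 1]] <<- pl
        out[line_pos] <- exact_scale(pl, pl_t)
      }
      out
    })
  })
}


#' Simulate plot-level multi-environment phenotypes
#'
#' Generates a plot-level phenotype table for all DH lines and all hybrids
#' of the crossing design. The genetic value of an individual in
#' environment k uses environment-specific effect vectors obtained by
#' redrawing each effect class around the truth (scaled by
#' \code{truth$gxe_sd}); environment main shifts come from
#' \code{truth$env_effects}, plot residuals are iid normal with sd
#' \code{truth$residual_sd}. Bit-exactly reproducible from
#' \code{truth$seed}.
#'
#' @param dh parental \code{marker_matrix}.
#' @param design \code{crossing_design} (or NULL for lines only).
#' @param truth \code{sim_truth}.
#' @param n_env number of environments (>= 1).
#' @param n_rep plots per genotype and environment (>= 1).
#' @return \code{phenotype_table} at plot stage.
#' @export
simulate_trait <- function(dh, design, truth, n_env = 3, n_rep = 2) {
  stopifnot(inherits(truth, "sim_truth"))
  if (n_env < 1 || n_rep < 1) stop_config("n_env and n_rep must be >= 1")
  if (length(truth$env_effects) < n_env)
    stop_config("truth$env_effects shorter than n_env")
  geno <- dh
  if (!is.null(design)) geno <- bind_individuals(dh, infer_hybrid_genotypes(dh, design))
  n <- nrow(geno$codes)
  g_main <- genetic_values(geno$codes, truth)
  if (!is.null(truth$gxe_targets) && !is.null(design)) {
    # calibrated truth: model-consistent iid interaction deviations,
    # variance-exact per environment (see the methods vignette)
    dev <- gxe_interaction_draw(truth, design, geno, n_env, "gxe_train")
  } else {
    envs <- env_effect_draw(truth, n_env, "gxe_train")
    dev <- lapply(seq_len(n_env), function(k)
      genetic_values(geno$codes, truth, a = envs[[k]]$a, d = envs[[k]]$d,
                     epi = envs[[k]]$epi) - g_main)
  }
  out <- vector("list", n_env)
  with_seed(split_seed(truth$seed, "plot_residuals"), {
    for (k in seq_len(n_env)) {
      base <- truth$mu + truth$group_shift * (geno$group == "hybrid") +
        truth$env_effects[k] + g_main + dev[[k]]
      out[[k]] <- data.frame(
        genotype_id = rep(geno$ids, n_rep),
        environment = sprintf("E%02d", k),
        replicate = rep(seq_len(n_rep), each = n),
        value = rep(base, n_rep) + rnorm(n * n_rep, 0, truth$residual_sd),
        stringsAsFactors = FALSE)
    }
  })
  phenotype_table(do.call(rbind, out), stage = "plot")
}

#' Independent-validation scenario
#'
#' Generates \code{n_new_parents} additional DH lines from the same F1
#' (new meioses with a seed-derived stream) and crosses within a small
#' validation parent pool -- the new lines plus \code{n_old_parents}
#' lines drawn from the training panel, so most validation crosses are
#' between previously unphenotyped parents. The new hybrids are phenotyped
#' in one \emph{new} environment: all per-class G-by-E deviations and the
#' environment shift are fresh draws under the same truth.
#'
#' @param dh training parental \code{marker_matrix}.
#' @param truth the \emph{same} \code{sim_truth} used for training.
#' @param n_new_parents number of new DH lines.
#' @param n_new_crosses number of validation hybrids.
#' @param seed integer seed for the new meioses, pairing and environment.
#' @param n_rep plots per hybrid in the validation trial (default 3).
#' @param n_old_parents training lines admitted to the validation pool
#'   (default 2).
#' @return list with \code{parents} (combined panel), \code{hybrids}
#'   (validation \code{marker_matrix}), \code{design}, and \code{pheno}
#'   (plot-stage \code{phenotype_table} of the validation environment).
#' @export
simulate_validation_scenario <- function(dh, truth, n_new_parents,
                                         n_new_crosses, seed = 1, n_rep = 3,
                                         n_old_parents = 2) {
  new_dh <- simulate_dh_population(dh$map, max(n_new_parents, 2),
                                   seed = split_seed(seed, "val_meiosis"))
  new_dh <- subset_individuals(new_dh, seq_len(n_new_parents))
  new_dh$ids <- sprintf("NDH%03d", seq_len(n_new_parents))
  rownames(new_dh$codes) <- new_dh$ids
  all_par <- bind_individuals(dh, new_dh)
  with_seed(split_seed(seed, "val_pairing"), {
    pool <- c(sample(dh$ids, min(n_old_parents, length(dh$ids))), new_dh$ids)
    if (n_new_crosses > choose(length(pool), 2))
      stop_config("validation pool too small for n_new_crosses")
    seen <- character(0); p1 <- character(0); p2 <- character(0)
    while (length(p1) < n_new_crosses) {
      pr <- sample(pool, 2)
      if (!any(pr %in% new_dh$ids)) next   # every cross has a new parent
      k <- paste(min(pr), max(pr))
      if (k %in% seen) next
      seen <- c(seen, k); p1 <- c(p1, pr[1]); p2 <- c(p2, pr[2])
    }
  })
  design <- crossing_design(p1, p2,
                            hybrid_id = sprintf("VAL%03d", seq_len(n_new_crosses)))
  hybrids <- infer_hybrid_genotypes(all_par, design)
  # one new environment: fresh deviation draws of every effect class
  vt <- truth
  vt$seed <- split_seed(seed, "val_env_truth")
  g_main <- genetic_values(hybrids$codes, truth)
  if (!is.null(truth$gxe_targets)) {
    dev <- gxe_interaction_draw(vt, design, hybrids, 1, "gxe_validation")[[1]]
  } else {
    env <- env_effect_draw(vt, 1, "gxe_validation")[[1]]
    dev <- genetic_values(hybrids$codes, truth, a = env$a, d = env$d,
                          epi = env$epi) - g_main
  }
  with_seed(split_seed(seed, "val_residuals"), {
    shift <- with_seed(split_seed(seed, "val_env_shift"),
                       rnorm(1, 0, max(sd(truth$env_effects), 0)))
    base <- truth$mu + truth$group_shift + shift + g_main + dev
    pheno <- data.frame(
      genotype_id = rep(hybrids$ids, n_rep),
      environment = "EVAL",
      replicate = rep(seq_len(n_rep), each = nrow(design)),
      value = rep(base, n_rep) + rnorm(nrow(design) * n_rep, 0, truth$residual_sd),
      stringsAsFactors = FALSE)
  })
  list(parents = all_par, hybrids = hybrids, design = design,
       pheno = phenotype_table(pheno, stage = "plot"))
}

#' Calibrate a genetic architecture to target variance components
#'
#' Draws a polygenic truth (QTL spread over the map, normal effects per
#' class) and rescales the additive, dominance and epistatic effect vectors
#' so the \emph{realized} variance decomposition among the design's hybrids
#' matches the targets: sigma2_GCA and sigma2_SCA among hybrids, plus
#' residual and G-by-E scales hitting the target ratios. Realized
#' components are measured by least-squares decomposition of the exact
#' hybrid genetic values into parental GCA and SCA parts, so the
#' calibration is exact for the realized population rather than an
#' expectation.
#'
#' @param dh parental \code{marker_matrix}.
#' @param design \code{crossing_design}.
#' @param n_qtl number of QTL.
#' @param sigma2_gca,sigma2_sca target GCA / SCA variances among hybrids.
#' @param sigma2_env_x_gca,sigma2_env_x_sca target G-by-E components
#'   (environment-specific GCA/SCA deviation variances).
#' @param sigma2_gxe_parents target genotype-by-environment variance of the
#'   parental lines.
#' @param sigma2_resid plot residual variance.
#' @param epi_share share of hybrid genetic variance from digenic epistasis
#'   (split equally over AA/AD/DA/DD pairs); the additive and dominance
#'   targets are matched net of the epistatic contributions.
#' @param n_env number of environments to draw main shifts for.
#' @param env_sd sd of environment main shifts (Mg/ha).
#' @param seed master seed stored in the truth.
#' @return \code{sim_truth} calibrated to the targets.
#' @export
calibrate_truth <- function(dh, design, n_qtl = 60,
                            sigma2_gca = 0.0110, sigma2_sca = 0.0156,
                            sigma2_env_x_gca = 0.0243,
                            sigma2_env_x_sca = 0.0561,
                            sigma2_gxe_parents = 0.0770,
                            sigma2_resid = 0.0211,
                            epi_share = 0, n_env = 3, env_sd = 0.15,
                            seed = 1) {
  m <- ncol(dh$codes)
  if (n_qtl > m) stop_config("n_qtl exceeds marker count")
  with_seed(split_seed(seed, "truth_draw"), {
    qp <- sort(sample.int(m, n_qtl))
    a0 <- rnorm(n_qtl); d0 <- rnorm(n_qtl)
    ep <- NULL
    if (epi_share > 0) {
      n_pair <- min(40, choose(n_qtl, 2))
      prs <- t(replicate(n_pair, sample(qp, 2)))
      ep <- data.frame(locus1 = prs[, 1], locus2 = prs[, 2],
                       type = rep(c("AA", "AD", "DA", "DD"), length.out = n_pair),
                       effect = rnorm(n_pair))
    }
    env_eff <- rnorm(n_env, 0, env_sd)
  })
  hyb <- infer_hybrid_genotypes(dh, design)
  decomp <- function(truth) diallel_decomp(dh, design, truth)
  # scale the epistatic block first so it carries epi_share of the total
  # genetic variance among the design's hybrids
  if (epi_share > 0) {
    e_tot <- epi_share * (sigma2_gca + sigma2_sca)
    epi_tr <- function() sim_truth(qp, 0 * a0, 0 * d0, ep,
                                   env_effects = env_eff, seed = seed)
    dd <- decomp(epi_tr())
    ep$effect <- ep$effect * sqrt(e_tot / max(dd$gca + dd$sca, 1e-12))
  }
  # fixed-point rescaling: additive effects govern GCA, dominance governs
  # SCA; the (fixed) epistatic contributions to either are absorbed by the
  # iteration
  a <- a0; d <- d0
  for (it in 1:4) {
    dd <- decomp(sim_truth(qp, a, d, ep, env_effects = env_eff, seed = seed))
    da <- decomp(sim_truth(qp, a, 0 * d, NULL, env_effects = env_eff, seed = seed))$gca
    ds <- decomp(sim_truth(qp, 0 * a, d, NULL, env_effects = env_eff, seed = seed))$sca
    a <- a * sqrt(max(sigma2_gca - (dd$gca - da), 0.05 * sigma2_gca) / max(da, 1e-12))
    d <- d * sqrt(max(sigma2_sca - (dd$sca - ds), 0.05 * sigma2_sca) / max(ds, 1e-12))
  }
  out <- sim_truth(qp, a, d, ep, env_effects = env_eff,
                   gxe_sd = c(additive = 0, dominance = 0, epistasis = 0),
                   residual_sd = sqrt(sigma2_resid), seed = seed)
  # calibrated truths carry G-by-E targets; simulate_trait then draws
  # model-consistent interaction deviations that realize these variances
  # exactly (see gxe_interaction_draw and the methods vignette)
  out$gxe_targets <- list(additive = sigma2_env_x_gca,
                          dominance = sigma2_env_x_sca,
                          parents = sigma2_gxe_parents)
  out
}

# Exact finite-panel combining-ability decomposition: the GCA of parent i
# is the mean genetic value of its crosses over the *full* half-diallel of
# the panel, SCA the remainder; realized variances are evaluated on the
# observed crosses. Avoids the overfit of a least-squares decomposition
# when crosses scarcely outnumber parents. Only the loci referenced by the
# truth are materialized.
diallel_decomp <- function(dh, design, truth) {
  loci <- sort(unique(c(truth$qtl_positions,
                        truth$epistatic_pairs$locus1,
                        truth$epistatic_pairs$locus2)))
  tr2 <- truth
  tr2$qtl_positions <- match(truth$qtl_positions, loci)
  if (!is.null(tr2$epistatic_pairs)) {
    tr2$epistatic_pairs$locus1 <- match(truth$epistatic_pairs$locus1, loci)
    tr2$epistatic_pairs$locus2 <- match(truth$epistatic_pairs$locus2, loci)
  }
  X <- dh$codes[, loci, drop = FALSE]
  np <- nrow(X)
  pr <- t(combn(np, 2))
  H <- genetic_values((X[pr[, 1], , drop = FALSE] + X[pr[, 2], , drop = FALSE]) / 2,
                      tr2)
  mu <- mean(H)
  sums <- numeric(np); cnts <- numeric(np)
  for (k in 1:2) {
    sums <- sums + unname(tapply(H, factor(pr[, k], levels = seq_len(np)), sum,
                                 default = 0))
    cnts <- cnts + tabulate(pr[, k], np)
  }
  sums[is.na(sums)] <- 0
  gca <- sums / pmax(cnts, 1) - mu
  i1 <- match(design$parent1, dh$ids); i2 <- match(design$parent2, dh$ids)
  h_obs <- genetic_values((X[i1, , drop = FALSE] + X[i2, , drop = FALSE]) / 2, tr2)
  gca_obs <- gca[i1] + gca[i2]
  sca_obs <- h_obs - mu - gca_obs
  pv <- function(v) mean((v - mean(v))^2)
  list(gca = pv(gca_obs), sca = pv(sca_obs), total = pv(h_obs))
}
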