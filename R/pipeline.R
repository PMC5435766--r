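#' Default pipeline configuration
#'
#' Returns the full desk-scale run configuration as a nested list; every
#' field is documented by its name and default. Unknown keys in a user
#' config are rejected by \code{\link{run_pipeline}}.
#'
#' @return named list (a RunConfig).
#' @export
default_config <- function() {
  list(
    seed = 1,
    out_dir = "hybridqg_run",
    stages = list(simulate = TRUE, qc = TRUE, kernels = TRUE, means = TRUE,
                  varcomp = TRUE, scan = TRUE, scan2d = FALSE,
                  predict = TRUE),
    sim = list(n_lines = 180, n_crosses = 318, n_env = 3, n_rep = 2,
               n_chr = 19, n_markers = 20, chr_len = 80, n_qtl = 60,
               sigma2_gca = 0.0110, sigma2_sca = 0.0156,
               sigma2_env_x_gca = 0.0243, sigma2_env_x_sca = 0.0561,
               sigma2_resid = 0.0211, epi_share = 0),
    qc = list(maf = 0.05, miss = 0.05, dedup = TRUE),
    kernels = list(shrink = TRUE, bandwidth = "median"),
    scan = list(alpha = 0.1),
    scan2d = list(n_perm = 100, alpha = 0.05),
    predict = list(models = c("A", "AD", "ADE"), folds = 5, repeats = 2)
  )
}

check_config <- function(config) {
  ref <- default_config()
  extra <- setdiff(names(config), names(ref))
  if (length(extra)) stop_config("unknown config keys: ",
                                 paste(extra, collapse = ", "))
  for (k in names(config)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
      bad <- setdiff(names(config[[k]]), names(ref[[k]]))
      if (length(bad)) stop_config("unknown config keys in ", k, ": ",
                                   paste(bad, collapse = ", "))
      ref[[k]][names(config[[k]])] <- config[[k]]
    } else ref[[k]] <- config[[k]]
  }
  ref
}

#' Run the full pipeline from one configuration
#'
#' Executes the enabled stages in dependency order -- simulate, qc,
#' kernels, means, varcomp, scan, scan2d, predict -- writing each stage's
#' outputs under \code{out_dir} and returning a manifest with input
#' hashes, seeds and per-stage outputs. Rerunning with the same config is
#' bit-identical for deterministic stages. A single master seed is split
#' hierarchically per stage, so toggling one stage never shifts another's
#' randomness.
#'
#' @param config RunConfig list (see \code{\link{default_config}}) or a
#'   path to a JSON file holding one.
#' @return manifest list (also written to \code{out_dir/manifest.json}).
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- check_config(config)
  st <- cfg$stages
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("hybridqg")),
                   seed = cfg$seed, stages = list())
  paths <- list()
  log_stage <- function(stage, t0, outputs) {
    manifest$stages[[stage]] <<- list(
      seed = split_seed(cfg$seed, stage),
      outputs = outputs,
      md5 = as.list(tools::md5sum(unlist(outputs))),
      wall_seconds = round(as.numeric(Sys.time()) - t0, 3))
    message(sprintf("[%s] done in %.2fs (seed %d)", stage,
                    as.numeric(Sys.time()) - t0, split_seed(cfg$seed, stage)))
  }
  need <- function(what, stage) {
    if (is.null(paths[[what]]))
      stop_config("stage '", stage, "' requires upstream output '", what,
                  "' (enable its stage or provide it)")
  }

  dh <- design <- truth <- geno_all <- NULL
  if (isTRUE(st$simulate)) {
    t0 <- as.numeric(Sys.time())
    s <- cfg$sim
    map <- default_map(s$n_chr, s$n_markers, s$chr_len)
    dh <- simulate_dh_population(map, s$n_lines, seed = split_seed(cfg$seed, "simulate"))
    design <- make_crossing_design(s$n_lines, s$n_crosses,
                                   seed = split_seed(cfg$seed, "design"),
                                   parent_ids = dh$ids)
    truth <- calibrate_truth(dh, design, n_qtl = s$n_qtl,
                             sigma2_gca = s$sigma2_gca, sigma2_sca = s$sigma2_sca,
                             sigma2_env_x_gca = s$sigma2_env_x_gca,
                             sigma2_env_x_sca = s$sigma2_env_x_sca,
                             sigma2_resid = s$sigma2_resid,
                             epi_share = s$epi_share, n_env = s$n_env,
                             seed = split_seed(cfg$seed, "truth"))
    pheno <- simulate_trait(dh, design, truth, n_env = s$n_env, n_rep = s$n_rep)
    geno_all <- bind_individuals(dh, infer_hybrid_genotypes(dh, design))
    p <- file.path(cfg$out_dir, c("geno.tsv", "pheno.tsv", "truth.json",
                                  "crosses.tsv"))
    write_geno_tsv(geno_all, p[1]); write_pheno_tsv(pheno, p[2])
    write_truth_json(truth, p[3])
    write.table(as.data.frame(design), p[4], sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths$geno <- p[1]; paths$pheno <- p[2]; paths$design <- p[4]
    log_stage("simulate", t0, as.list(p))
  }

  if (isTRUE(st$qc)) {
    t0 <- as.numeric(Sys.time())
    need("geno", "qc")
    geno <- geno_all %||% read_geno_tsv(paths$geno)
    flt <- qc_filter(geno, cfg$qc$maf, cfg$qc$miss)
    if (isTRUE(cfg$qc$dedup)) {
      dd <- dedup_perfect_ld(flt$markers)
      flt$markers <- dd$markers
      flt$ld_clusters <- dd$clusters
    }
    p <- file.path(cfg$out_dir, c("filtered.tsv", "qc_report.json"))
    write_geno_tsv(flt$markers, p[1])
    jsonlite::write_json(list(removed = flt$report,
                              ld_clusters = flt$ld_clusters %||% list()),
                         p[2], auto_unbox = TRUE, digits = NA)
    paths$filtered <- p[1]
    geno_all <- flt$markers
    log_stage("qc", t0, as.list(p))
  }

  dsg <- NULL
  if (isTRUE(st$kernels)) {
    t0 <- as.numeric(Sys.time())
    need("filtered", "kernels")
    geno <- geno_all %||% read_geno_tsv(paths$filtered)
    dsg <- f_infinity_design(geno)
    Kk <- rogers_kinship(geno)
    Ka <- additive_relationship(dsg, shrink = isTRUE(cfg$kernels$shrink))
    Kd <- tryCatch(dominance_relationship(dsg, shrink = isTRUE(cfg$kernels$shrink)),
                   error = function(e) NULL)
    Kg <- gaussian_kernel(dsg, cfg$kernels$bandwidth)
    p <- file.path(cfg$out_dir, paste0("K_", c("kinship", "additive",
                                               "dominance", "gaussian"), ".tsv"))
    write_kernel_tsv(Kk, p[1]); write_kernel_tsv(Ka, p[2])
    if (!is.null(Kd)) write_kernel_tsv(Kd, p[3]) else p <- p[-3]
    write_kernel_tsv(Kg, p[length(p)])
    paths$kinship <- p[1]
    paths$kernels <- list(additive = Ka, dominance = Kd, gaussian = Kg,
                          kinship = Kk)
    log_stage("kernels", t0, as.list(p))
  }

  means_env <- means_all <- NULL
  if (isTRUE(st$means)) {
    t0 <- as.numeric(Sys.time())
    need("pheno", "means")
    plots <- read_pheno_tsv(paths$pheno)
    cln <- detect_outliers(plots)
    means_env <- adjust_means_within_env(cln$pheno)
    means_all <- adjust_means_across_env(means_env)
    p <- file.path(cfg$out_dir, c("means_within_env.tsv", "means_across_env.tsv"))
    write_pheno_tsv(means_env, p[1]); write_pheno_tsv(means_all, p[2])
    paths$means_env <- p[1]; paths$means_all <- p[2]
    log_stage("means", t0, as.list(p))
  }

  if (isTRUE(st$varcomp)) {
    t0 <- as.numeric(Sys.time())
    need("pheno", "varcomp"); need("design", "varcomp")
    plots <- read_pheno_tsv(paths$pheno)
    des <- read.delim(paths$design)
    ped <- crossing_design(des$parent1, des$parent2, des$hybrid_id)
    vc <- fit_gca_sca(detect_outliers(plots)$pheno, ped)
    p <- file.path(cfg$out_dir, "varcomp.json")
    jsonlite::write_json(list(components = as.list(vc$components),
                              n_env = vc$n_env, n_rep = vc$n_rep,
                              heritability = vc$heritability),
                         p, auto_unbox = TRUE, digits = NA)
    paths$varcomp <- p
    manifest$heritability <- vc$heritability
    log_stage("varcomp", t0, list(p))
  }

  if (isTRUE(st$scan)) {
    t0 <- as.numeric(Sys.time())
    need("means_env", "scan")
    if (is.null(paths$kernels)) stop_config("stage 'scan' requires the kernels stage")
    scan <- main_effect_scan(means_env, dsg, paths$kernels$kinship)
    fam <- c(scan$p_a, scan$p_d)
    flags <- holm_correct(fam, cfg$scan$alpha)
    scan$sig_a <- flags[seq_len(nrow(scan))]
    scan$sig_d <- flags[nrow(scan) + seq_len(nrow(scan))]
    p <- file.path(cfg$out_dir, "scan.tsv")
    write.table(scan, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$scan <- p
    log_stage("scan", t0, list(p))
  }

  if (isTRUE(st$scan2d)) {
    t0 <- as.numeric(Sys.time())
    need("means_env", "scan2d")
    if (is.null(paths$kernels)) stop_config("stage 'scan2d' requires the kernels stage")
    res <- epistasis_scan_2d(means_env, dsg, paths$kernels$kinship)
    thr <- permutation_threshold(means_env, dsg, paths$kernels$kinship,
                                 n_perm = cfg$scan2d$n_perm,
                                 alpha = cfg$scan2d$alpha,
                                 seed = split_seed(cfg$seed, "scan2d"))
    for (t in c("i11", "i12", "i21", "i22"))
      res[[paste0("sig_", t)]] <- !is.na(res[[paste0("p_", t)]]) &
        res[[paste0("p_", t)]] <= thr$thresholds[t]
    p <- file.path(cfg$out_dir, c("scan2d.tsv", "scan2d_thresholds.json"))
    write.table(res, p[1], sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(as.list(thr$thresholds), p[2], auto_unbox = TRUE,
                         digits = NA)
    paths$scan2d <- p[1]
    log_stage("scan2d", t0, as.list(p))
  }

  if (isTRUE(st$predict)) {
    t0 <- as.numeric(Sys.time())
    need("means_all", "predict")
    if (is.null(paths$kernels)) stop_config("stage 'predict' requires the kernels stage")
    geno <- geno_all %||% read_geno_tsv(paths$filtered)
    grp <- setNames(geno$group, geno$ids)
    h2 <- manifest$heritability %||% 0.5
    kns <- Filter(Negate(is.null),
                  paths$kernels[c("additive", "dominance", "gaussian")])
    mods <- cfg$predict$models
    if (is.null(kns$dominance)) mods <- intersect(mods, "A")
    cv <- crossvalidate(means_all, kns,
                        group = grp, h2 = h2, folds = cfg$predict$folds,
                        n_repeats = cfg$predict$repeats,
                        seed = split_seed(cfg$seed, "predict"),
                        models = mods)
    p <- file.path(cfg$out_dir, "cv_report.json")
    jsonlite::write_json(list(results = as.data.frame(cv),
                              summary = attr(cv, "summary")),
                         p, auto_unbox = TRUE, digits = NA)
    paths$cv <- p
    log_stage("predict", t0, list(p))
  }

  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
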