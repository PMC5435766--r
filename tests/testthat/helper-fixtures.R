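# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# three fully homozygous toy parents on three markers, for hand enumeration
toy_parents <- function() {
  map <- genetic_map(chromosome = c("A01", "A01", "A02"),
                     marker_id = c("m1", "m2", "m3"), cM = c(0, 10, 0))
  codes <- rbind(P1 = c(1, 1, -1),
                 P2 = c(-1, 1, 1),
                 P3 = c(1, -1, -1))
  marker_matrix(codes, map, ids = rownames(codes))
}

# mid-scale calibrated world shared across phenostat / gwas / predict tests:
# 100 DH lines, 160 hybrids, 19 x 15 markers, reference-calibrated truth (published variance components),
# 3 environments x 2 replicates
panel_world <- function() fixture("panel_world", function() {
  map <- default_map(n_markers = 15)
  dh <- simulate_dh_population(map, 100, seed = 404)
  des <- make_crossing_design(100, 160, seed = 404, parent_ids = dh$ids)
  truth <- calibrate_truth(dh, des, n_qtl = 50, seed = 404)
  pheno <- simulate_trait(dh, des, truth, n_env = 3, n_rep = 2)
  all <- bind_individuals(dh, infer_hybrid_genotypes(dh, des))
  within <- adjust_means_within_env(pheno)
  across <- adjust_means_across_env(within)
  list(map = map, dh = dh, design = des, truth = truth, pheno = pheno,
       all = all, dsg = f_infinity_design(all),
       within = within, across = across)
})

# population variance (divides by n, not n - 1)
pop_var <- function(x) mean((x - mean(x))^2)

# an exact F2-frequency hybrid population and a DH population on one marker
# panel, with exact genotype counts (no sampling noise)
exact_f2_panel <- function(n_markers = 4) {
  map <- default_map(n_chr = 1, n_markers = n_markers, chr_len = 30)
  f2 <- marker_matrix(matrix(rep(c(1, 0, 0, -1), n_markers), 4, n_markers),
                      map, ids = paste0("F", 1:4),
                      group = rep("hybrid", 4))
  dhp <- marker_matrix(matrix(rep(c(1, -1), n_markers), 2, n_markers),
                       map, ids = paste0("L", 1:2))
  list(f2 = f2, dh = dhp)
}

# connected components of an adjacency matrix by neighborhood expansion
# (brute-force oracle for perfect-LD clustering)
igraph_free_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    frontier <- i
    while (length(frontier)) {
      comp[frontier] <- cur
      nb <- which(colSums(adj[frontier, , drop = FALSE] != 0) > 0)
      frontier <- nb[is.na(comp[nb])]
    }
  }
  comp
}

# independent dense-REML log-likelihood used by oracle tests (kept free of
# package internals: plain chol algebra)
oracle_reml_nll <- function(theta, y, X, Vlist, offset = NULL) {
  n <- length(y)
  V <- if (is.null(offset)) matrix(0, n, n) else offset
  for (k in seq_along(Vlist)) V <- V + theta[k] * Vlist[[k]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(1e12)
  Vi <- chol2inv(ch)
  XtVi <- crossprod(X, Vi)
  XtViX <- XtVi %*% X
  chx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chx)) return(1e12)
  b <- backsolve(chx, forwardsolve(t(chx), XtVi %*% y))
  Py <- drop(Vi %*% y - crossprod(XtVi, b))
  0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) + sum(y * Py))
}
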