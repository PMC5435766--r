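#' Phenotype table constructor
#'
#' Plot-level or adjusted-mean records: one row per (genotype, environment,
#' replicate). Duplicate keys and non-finite values are rejected.
#'
#' @param records data frame with columns \code{genotype_id},
#'   \code{environment}, \code{replicate}, \code{value}.
#' @param stage one of "plot", "within_env_means", "across_env_means".
#' @return \code{phenotype_table} data frame.
#' @export
phenotype_table <- function(records,
                            stage = c("plot", "within_env_means",
                                      "across_env_means")) {
  stage <- match.arg(stage)
  need <- c("genotype_id", "environment", "replicate", "value")
  if (!all(need %in% names(records)))
    stop_data("phenotype table needs columns ", paste(need, collapse = ", "))
  if (!all(is.finite(records$value))) stop_data("non-finite phenotype values")
  key <- paste(records$genotype_id, records$environment, records$replicate)
  if (anyDuplicated(key)) stop_data("duplicate (genotype, environment, replicate) keys")
  records <- as.data.frame(records)[, need]
  attr(records, "stage") <- stage
  class(records) <- c("phenotype_table", "data.frame")
  records
}

pheno_stage <- function(x) attr(x, "stage") %||% "plot"

#' Write / read the genotype TSV dialect
#'
#' Rows are markers; the first three columns are \code{marker_id},
#' \code{chromosome}, \code{cM}; remaining columns are individuals with
#' cells in {-1, 0, 1, NA}.
#'
#' @param mm \code{marker_matrix}.
#' @param path output file.
#' @export
write_geno_tsv <- function(mm, path) {
  df <- cbind(mm$map, as.data.frame(t(mm$codes)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_geno_tsv
#' @param group per-individual group labels, or "infer" to label any
#'   individual carrying a heterozygote code as "hybrid".
#' @export
read_geno_tsv <- function(path, group = "infer") {
  df <- read.delim(path, check.names = FALSE)
  map <- genetic_map(df$chromosome, df$marker_id, df$cM)
  ord <- match(map$marker_id, df$marker_id)
  codes <- t(as.matrix(df[ord, -(1:3), drop = FALSE]))
  if (identical(group, "infer"))
    group <- ifelse(apply(codes == 0, 1, any, na.rm = TRUE), "hybrid", "inbred")
  marker_matrix(codes, map, ids = colnames(df)[-(1:3)], group = group)
}

#' Write / read the phenotype TSV dialect
#'
#' Columns \code{genotype_id}, \code{environment}, \code{replicate},
#' \code{value} (plain decimal, '.' separator).
#'
#' @param pheno \code{phenotype_table}.
#' @param path output file.
#' @export
write_pheno_tsv <- function(pheno, path) {
  write.table(as.data.frame(pheno), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_pheno_tsv
#' @param stage stage label for the resulting table.
#' @export
read_pheno_tsv <- function(path, stage = "plot") {
  phenotype_table(read.delim(path), stage = stage)
}

#' Round-trip a simulation truth through JSON
#'
#' @param truth \code{sim_truth}.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ep <- x$epistatic_pairs
  if (!is.null(ep) && length(ep) == 0) ep <- NULL
  out <- sim_truth(x$qtl_positions, x$additive_effects, x$dominance_effects,
                   epistatic_pairs = ep, env_effects = x$env_effects,
                   gxe_sd = unlist(x$gxe_sd), residual_sd = x$residual_sd,
                   mu = x$mu, group_shift = x$group_shift, seed = x$seed)
  out$gxe_targets <- x$gxe_targets
  out
}

#' Write / read a relationship matrix as TSV with a JSON sidecar
#'
#' @param K \code{relationship_matrix}.
#' @param path TSV path; the sidecar is \code{paste0(path, ".json")}.
#' @export
write_kernel_tsv <- function(K, path) {
  df <- data.frame(id = attr(K, "ids"), as.data.frame(unclass(K)[,]),
                   check.names = FALSE)
  names(df) <- c("id", attr(K, "ids"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(kind = attr(K, "kind")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_kernel_tsv
#' @export
read_kernel_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  ids <- as.character(df$id)
  m <- as.matrix(df[, -1, drop = FALSE])
  kind <- "kinship"
  if (file.exists(paste0(path, ".json")))
    kind <- jsonlite::read_json(paste0(path, ".json"))$kind
  relationship_matrix(m, kind = kind, ids = ids)
}

#' Minimal VCF reader (GT field only)
#'
#' Converts the GT field of a plain-text VCF to marker codes: 0/0 -> +1
#' (reference homozygote), 1/1 -> -1, 0/1 or 1/0 -> 0, missing -> NA.
#' Phased separators are accepted. Positions are taken from the POS column
#' (interpreted directly as map coordinates unless a map is supplied).
#'
#' @param path VCF file (uncompressed).
#' @param group per-individual group labels or "infer".
#' @return \code{marker_matrix}.
#' @export
read_vcf_gt <- function(path, group = "infer") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  header <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  body <- strsplit(lines[-1], "\t")
  ids <- header[-(1:9)]
  gt_codes <- function(fields) {
    gt <- sub(":.*", "", fields)
    gt <- gsub("\\|", "/", gt)
    unname(c("0/0" = 1, "1/1" = -1, "0/1" = 0, "1/0" = 0)[gt])
  }
  codes <- t(vapply(body, function(f) gt_codes(f[-(1:9)]),
                    numeric(length(ids))))
  map <- genetic_map(chromosome = vapply(body, `[`, "", 1),
                     marker_id = vapply(body, `[`, "", 3),
                     cM = as.numeric(vapply(body, `[`, "", 2)))
  ord <- match(map$marker_id, vapply(body, `[`, "", 3))
  codes <- t(codes[ord, , drop = FALSE])
  if (identical(group, "infer"))
    group <- ifelse(apply(codes == 0, 1, any, na.rm = TRUE), "hybrid", "inbred")
  marker_matrix(codes, map, ids = ids, group = group)
}
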