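#' Construct a genetic map
#'
#' A genetic map is a data frame with columns \code{marker_id},
#' \code{chromosome} and \code{cM}. Positions must be non-negative and are
#' made strictly increasing within a chromosome by jittering exact ties by a
#' negligible amount (1e-6 cM), so that marker order is always well defined.
#'
#' @param chromosome character vector of chromosome labels (e.g. "A01").
#' @param marker_id unique marker identifiers.
#' @param cM map positions in centimorgans, non-decreasing within chromosome.
#' @return A \code{genetic_map} data frame.
#' @export
genetic_map <- function(chromosome, marker_id, cM) {
  if (length(chromosome) == 0) stop_config("genetic map is empty")
  if (anyDuplicated(marker_id)) stop_config("duplicate marker_id in map")
  if (any(cM < 0)) stop_config("negative cM position")
  map <- data.frame(marker_id = as.character(marker_id),
                    chromosome = as.character(chromosome),
                    cM = as.numeric(cM), stringsAsFactors = FALSE)
  map <- map[order(map$chromosome, map$cM), , drop = FALSE]
  for (chr in unique(map$chromosome)) {
    i <- which(map$chromosome == chr)
    if (any(diff(map$cM[i]) < 0)) stop_config("cM not sorted on ", chr)
    while (any(diff(map$cM[i]) <= 0)) {          # tie-jitter
      j <- i[which(diff(map$cM[i]) <= 0) + 1L]
      map$cM[j] <- map$cM[j - 1L] + 1e-6
    }
  }
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Default desk-scale genome
#'
#' 19 chromosomes named A01--A10 and C01--C09 (the rapeseed complement),
#' each of length \code{chr_len} cM carrying \code{n_markers} equally spaced
#' markers. The default 19 x 80 = 1,520 markers matches the scale of a
#' pruned 60K-array panel (~1.5K unique SNPs).
#'
#' @param n_chr number of chromosomes (<= 19 with the default labels).
#' @param n_markers markers per chromosome.
#' @param chr_len chromosome length in cM.
#' @return A \code{genetic_map}.
#' @export
default_map <- function(n_chr = 19, n_markers = 80, chr_len = 80) {
  labels <- c(sprintf("A%02d", 1:10), sprintf("C%02d", 1:9))
  if (n_chr > length(labels)) labels <- c(labels, sprintf("X%02d", seq_len(n_chr - 19)))
  chrs <- labels[seq_len(n_chr)]
  pos <- seq(0, chr_len, length.out = n_markers)
  genetic_map(chromosome = rep(chrs, each = n_markers),
              marker_id = paste0(rep(chrs, each = n_markers), "_m",
                                 sprintf("%03d", rep(seq_len(n_markers), n_chr))),
              cM = rep(pos, n_chr))
}
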