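#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif var sd cor median optimize pchisq pt
#'   pnorm qnorm quantile setNames aggregate ave lm.fit dist model.matrix
#' @importFrom utils read.delim write.table head combn packageVersion
#' @importFrom tools md5sum
#' @useDynLib hybridqg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Deterministic hierarchical seed splitting: one master seed, independent
# named streams per stage, so toggling one stage never shifts another's
# randomness. Kept strictly below 2^31 - 1 (R integers are 32-bit).
split_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  x <- (abs(master) %% 2147483647)
  # two rounds of a Lehmer-style mix keep streams well separated
  x <- (x * 48271 + h) %% 2147483647
  x <- (x * 69621 + 7919 * h + 1) %% 2147483647
  as.integer(x %% 2147483646 + 1)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rms <- function(x) if (length(x) == 0) 0 else sqrt(mean(x^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(structure(
  class = c("hybridqg_config_error", "error", "condition"),
  list(message = paste0(...), call = sys.call(-1))))

stop_data <- function(...) stop(structure(
  class = c("hybridqg_data_error", "error", "condition"),
  list(message = paste0(...), call = sys.call(-1))))
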