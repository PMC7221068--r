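# data.table non-standard evaluation is used throughout the quant module
.datatable.aware <- TRUE

#' Derive a stage seed from a master seed
#'
#' All stochastic stages of the pipeline take explicit seeds. A pipeline-level
#' master seed maps to per-stage seeds by fixed offsets so that stages are
#' reproducible independently of each other and of execution order.
#'
#' @param seed Integer master seed.
#' @param stage Stage name, one of `"genome"`, `"design"`, `"counts"`,
#'   `"reads"`, `"atac"`, `"quant"`, `"misc"`.
#' @return An integer seed, guaranteed `< 2^31`.
#' @export
derive_seed <- function(seed, stage = "misc") {
  offsets <- c(genome = 1L, design = 2L, counts = 3L, reads = 4L,
               atac = 5L, quant = 6L, misc = 7L)
  if (!stage %in% names(offsets)) {
    stop("unknown stage: ", stage)
  }
  s <- (as.integer(seed) %% 2000000L) * 1000L + offsets[[stage]]
  as.integer(s)
}

# geometric mean of strictly positive values
geomean <- function(x) exp(mean(log(x)))

# row-wise geometric means of a positive matrix
row_geomean <- function(m) exp(rowMeans(log(m)))

# log-uniform sampling in [lo, hi]
runif_log <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

#' Render a fraction as the truncated integer percentage used in reporting
#'
#' Truncation (floor), not rounding to nearest, is used so that rendered
#' percentages agree with the conventional presentation of set-overlap
#' fractions (e.g. 3091/3492 renders as 88, not 89). Zero denominators render
#' as 0.
#'
#' @param num,den Numerator and denominator counts.
#' @return Integer percentage in `[0, 100]`.
#' @export
format_percentage <- function(num, den) {
  if (length(den) != length(num)) stop("num and den lengths differ")
  out <- ifelse(den > 0, floor(100 * num / den), 0)
  as.integer(out)
}

# stable hash of an arbitrary config-like list: keys are sorted recursively
# before hashing so semantically identical configs hash identically
canonicalize_config <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) {
      x <- x[order(nm)]
    }
    lapply(x, canonicalize_config)
  } else {
    x
  }
}

#' Hash a configuration list
#'
#' Key order does not affect the hash; values do.
#'
#' @param config A (possibly nested) named list.
#' @return A character hash.
#' @export
config_hash <- function(config) {
  rlang::hash(canonicalize_config(config))
}

# validate a probability-like scalar
check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
    stop(name, " must be a single number in [", lo, ", ", hi, "]")
  }
  invisible(x)
}
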