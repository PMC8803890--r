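#' Regularly sampled scalar time series
#'
#' Light container for a regularly sampled series with a per-sample
#' validity mask. Missing (invalid) samples are encoded as `NA` in
#' `values`; all downstream operations drop embedding vectors that would
#' span an invalid sample rather than imputing.
#'
#' @param values numeric vector; `NA` marks invalid samples.
#' @param step sampling interval (time units per sample), a single
#'   positive number. Purely metadata: all internal computation is in
#'   sample units.
#' @return An object of class `ccm_series` with fields `values`, `step`
#'   and `mask` (logical, `TRUE` = valid).
#' @examples
#' s <- ccm_series(c(1, 2, NA, 4), step = 8)
#' s$mask
#' @export
ccm_series <- function(values, step = 1) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("series must contain at least one sample")
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0)
    stop("step must be a single positive number")
  structure(list(values = values, step = step, mask = !is.na(values)),
            class = "ccm_series")
}

#' Coerce to a ccm_series
#'
#' @param x a `ccm_series` or numeric vector (`NA` = invalid sample).
#' @param step sampling interval used when `x` is a bare vector.
#' @return a `ccm_series`.
#' @export
as_ccm_series <- function(x, step = 1) {
  if (inherits(x, "ccm_series")) return(x)
  ccm_series(x, step = step)
}

#' @export
print.ccm_series <- function(x, ...) {
  cat(sprintf("<ccm_series> %d samples (%d valid), step = %g\n",
              length(x$values), sum(x$mask), x$step))
  invisible(x)
}

#' @export
length.ccm_series <- function(x) length(x$values)

#' Read a two-column (time, value) CSV as a series
#'
#' Missing values may be encoded as empty fields or a NaN/NA token. The
#' time column is used only to infer the sampling step; samples must be
#' regularly spaced.
#'
#' @param path file path.
#' @return a `ccm_series`.
#' @export
read_series_csv <- function(path) {
  d <- utils::read.csv(path, header = TRUE,
                       na.strings = c("", "NA", "NaN", "nan"))
  if (ncol(d) < 2L) stop("expected a two-column (time, value) CSV")
  tm <- as.numeric(d[[1L]])
  step <- if (length(tm) > 1L) stats::median(diff(tm)) else 1
  ccm_series(as.numeric(d[[2L]]), step = step)
}

#' Write a series to a two-column (time, value) CSV
#'
#' @param series a `ccm_series` (or numeric vector).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  series <- as_ccm_series(series)
  n <- length(series$values)
  d <- data.frame(time = (seq_len(n) - 1) * series$step,
                  value = series$values)
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

# z-score a values vector, ignoring NA; constant series are centred only.
# Affine rescaling is neutral for Pearson cross-map skill but makes
# Euclidean embedding distances unit-free.
zscore <- function(v) {
  mu <- mean(v, na.rm = TRUE)
  sdv <- stats::sd(v, na.rm = TRUE)
  if (!is.finite(sdv) || sdv == 0) return(v - mu)
  (v - mu) / sdv
}

# Deterministic derived seed for sub-computation k of master seed `seed`;
# kept strictly below 2^31 - 1.
derive_seed <- function(seed, k) {
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
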