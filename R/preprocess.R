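#' Filter genes with low expression at every stage
#'
#' A gene is removed only when its replicate-averaged count is below
#' `min_mean` in every stage; one sufficiently expressed stage rescues it
#' (the comparison is strict: a stage average exactly at `min_mean` keeps
#' the gene). Gene order is otherwise preserved, and the operation is
#' idempotent.
#'
#' @param series a count-scale [stage_series()].
#' @param min_mean minimal stage-average count (default 10).
#' @return Filtered `stage_series`.
#' @export
filter_low_expression <- function(series, min_mean = 10) {
  stopifnot(is_stage_series(series))
  if (series$scale != "count")
    stop("filter_low_expression expects count-scale input")
  m <- stage_means(series)
  keep <- apply(m >= min_mean, 1L, any)
  subset_genes(series, keep)
}

#' Log2-transform a count series, keeping zeros at zero
#'
#' Positive counts map to `log2(count)`; zero counts are kept as 0 (no
#' pseudocount), so values in (0,1) map to negative logs.
#'
#' @param series a count-scale [stage_series()].
#' @return A log2-scale `stage_series`.
#' @export
log2_transform <- function(series) {
  stopifnot(is_stage_series(series))
  if (series$scale != "count") stop("log2_transform expects count-scale input")
  v <- series$values
  if (any(v < 0, na.rm = TRUE)) stop("negative counts are not allowed")
  pos <- !is.na(v) & v > 0
  v[pos] <- log2(v[pos])
  stage_series(v, series$genes, series$stages, scale = "log2")
}

#' Baseline-subtracted mean differential profiles
#'
#' Averages log2 values over replicates per stage, then subtracts each
#' gene's baseline-stage mean from every stage, so `d[, 1] == 0` exactly.
#' Adding a gene-wise constant to all log values leaves the result
#' unchanged.
#'
#' @param series a log2-scale [stage_series()] whose first stage is the
#'   baseline.
#' @return numeric matrix gene x stage of differential values.
#' @export
differential_profiles <- function(series) {
  stopifnot(is_stage_series(series))
  if (series$scale != "log2")
    stop("differential_profiles expects log2-scale input")
  m <- stage_means(series)
  d <- m - m[, 1L]
  if (any(!is.finite(d))) stop("non-finite differential values")
  d
}
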