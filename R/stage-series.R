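#' Staged expression series container
#'
#' A `stage_series` holds a gene x stage x replicate tensor of expression
#' values on an ordered stage axis whose first stage is the designated
#' baseline (in the motivating application, sorted pancreatic endocrine
#' progenitors that do not yet express beta-cell genes). Values are tagged
#' with their scale: `"count"` (non-negative normalized counts) or `"log2"`.
#'
#' @param values numeric 3-d array `[gene, stage, replicate]`. `NA` entries
#'   mark missing replicates; every gene must keep at least one observed
#'   replicate per stage.
#' @param genes character vector of unique gene identifiers (rows).
#' @param stages character vector of unique, ordered stage labels; the first
#'   label is the baseline stage.
#' @param scale `"count"` or `"log2"`.
#' @return An object of class `stage_series`.
#' @export
stage_series <- function(values, genes, stages, scale = c("count", "log2")) {
  scale <- match.arg(scale)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-d array [gene, stage, replicate]")
  if (dim(values)[1L] != length(genes))
    stop("dim(values)[1] must equal length(genes)")
  if (dim(values)[2L] != length(stages))
    stop("dim(values)[2] must equal length(stages)")
  if (anyDuplicated(genes))
    stop("duplicate gene identifier: ",
         genes[duplicated(genes)][1L])
  if (anyDuplicated(stages)) stop("stage labels must be unique")
  if (length(stages) < 2L) stop("need at least two stages")
  if (scale == "count" && any(values < 0, na.rm = TRUE))
    stop("count-scale values must be non-negative")
  n_obs <- apply(!is.na(values), c(1L, 2L), sum)
  if (any(n_obs == 0L))
    stop("every gene needs at least one observed replicate per stage")
  dimnames(values) <- list(genes, stages, NULL)
  structure(
    list(values = values, genes = as.character(genes),
         stages = as.character(stages), scale = scale),
    class = "stage_series")
}

#' @export
print.stage_series <- function(x, ...) {
  cat(sprintf("stage_series: %d genes x %d stages x %d replicates [%s scale]\n",
              length(x$genes), length(x$stages), dim(x$values)[3L], x$scale))
  cat("stages:", paste(x$stages, collapse = " -> "),
      sprintf("(baseline: %s)\n", x$stages[1L]))
  invisible(x)
}

#' @rdname stage_series
#' @param x object to test.
#' @export
is_stage_series <- function(x) inherits(x, "stage_series")

n_genes <- function(series) length(series$genes)
n_stages <- function(series) length(series$stages)
n_replicates <- function(series) dim(series$values)[3L]

subset_genes <- function(series, keep) {
  stopifnot(is_stage_series(series))
  idx <- if (is.character(keep)) match(keep, series$genes) else which(keep)
  if (anyNA(idx)) stop("unknown gene identifier in subset")
  stage_series(series$values[idx, , , drop = FALSE],
               series$genes[idx], series$stages, series$scale)
}

#' Per-stage replicate means
#'
#' @param series a `stage_series`.
#' @return numeric matrix gene x stage of replicate-averaged values
#'   (`NA` replicates excluded).
#' @export
stage_means <- function(series) {
  stopifnot(is_stage_series(series))
  v <- series$values
  R <- dim(v)[3L]
  tot <- matrix(0, dim(v)[1L], dim(v)[2L])
  cnt <- matrix(0, dim(v)[1L], dim(v)[2L])
  for (r in seq_len(R)) {
    x <- v[, , r]
    ok <- !is.na(x)
    x[!ok] <- 0
    tot <- tot + x
    cnt <- cnt + ok
  }
  m <- tot / cnt
  dimnames(m) <- list(series$genes, series$stages)
  m
}
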