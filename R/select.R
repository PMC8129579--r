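#' Bounded area between a differential profile and its baseline
#'
#' The area of the region bounded by the piecewise-linear time-series
#' profile of absolute differentials and the zero baseline, on a unit-spaced
#' stage axis: the trapezoidal integral of `|d|`. Zero iff the profile is
#' identically zero; scales linearly, `bounded_area(c * d) = c *
#' bounded_area(d)` for `c > 0`.
#'
#' @param d numeric vector of length >= 2 (one profile), or a gene x stage
#'   matrix (row-wise areas).
#' @return Non-negative numeric scalar or per-gene vector.
#' @export
bounded_area <- function(d) {
  if (is.matrix(d)) {
    if (ncol(d) < 2L) stop("profiles need at least two stages")
    if (any(!is.finite(d))) stop("non-finite profile values")
    return(as.vector(abs(d) %*% .trapz_weights(ncol(d))))
  }
  if (length(d) < 2L) stop("profiles need at least two stages")
  if (any(!is.finite(d))) stop("non-finite profile values")
  sum(.trapz_weights(length(d)) * abs(d))
}

#' Null model for bounded areas
#'
#' Log-normal law of bounded deviation areas under no differential
#' expression; `log_mu` and `log_sigma` are the mean and standard deviation
#' of the natural log of the area.
#'
#' @param log_mu,log_sigma log-scale mean and sd (`log_sigma > 0`).
#' @param n_null size of the null sample the fit is based on.
#' @return A `null_model` object.
#' @export
null_model <- function(log_mu, log_sigma, n_null = NA_integer_) {
  if (!is.finite(log_mu) || !is.finite(log_sigma) || log_sigma <= 0)
    stop("log_sigma must be positive and parameters finite")
  structure(list(log_mu = log_mu, log_sigma = log_sigma, n_null = n_null),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("null_model: ln(area) ~ Normal(%.4f, %.4f), n = %s\n",
              x$log_mu, x$log_sigma, format(x$n_null)))
  invisible(x)
}

#' Fit the log-normal null from biological-replicate variability
#'
#' For every gene and replicate, computes the bounded area of the replicate
#' profile minus the gene's cross-replicate mean profile, pools all strictly
#' positive areas over genes, and fits a normal to their natural logs by
#' maximum likelihood. Duplicating genes leaves the fit unchanged (pure
#' pooling).
#'
#' @param series a log2-scale [stage_series()] with >= 2 replicates
#'   observed at every stage of every gene.
#' @return A [null_model()].
#' @export
estimate_null <- function(series) {
  stopifnot(is_stage_series(series))
  if (series$scale != "log2") stop("estimate_null expects log2-scale input")
  v <- series$values
  n_obs <- apply(!is.na(v), c(1L, 2L), sum)
  if (any(n_obs < 2L))
    stop("insufficient replication: need >= 2 replicates per stage per gene")
  m <- stage_means(series)
  S <- n_stages(series); R <- n_replicates(series)
  w <- .trapz_weights(S)
  areas <- matrix(NA_real_, n_genes(series), R)
  for (r in seq_len(R)) {
    dev <- v[, , r] - m
    areas[, r] <- abs(dev) %*% w
  }
  a <- areas[!is.na(areas) & areas > 0]
  if (length(a) < 2L)
    stop("no positive replicate deviation areas: replicates are identical")
  la <- log(a)
  mu <- mean(la)
  sigma <- sqrt(mean((la - mu) ^ 2))          # ML estimate
  if (sigma <= 0) stop("degenerate null fit: zero variance")
  null_model(mu, sigma, length(a))
}

#' Upper-tail p-value of a bounded area under the log-normal null
#'
#' `p = 1 - Phi((ln area - log_mu) / log_sigma)` for positive areas; an
#' exactly zero area (profile identical to baseline) gets `p = 1`.
#'
#' @param area non-negative area(s).
#' @param null a [null_model()].
#' @return p-value(s) in (0, 1].
#' @export
area_pvalue <- function(area, null) {
  stopifnot(inherits(null, "null_model"))
  if (any(!is.finite(area)) || any(area < 0)) stop("areas must be finite and >= 0")
  p <- rep(1, length(area))
  pos <- area > 0
  p[pos] <- stats::pnorm((log(area[pos]) - null$log_mu) / null$log_sigma,
                         lower.tail = FALSE)
  p
}

#' Selection configuration
#'
#' @param alpha significance level for both the adjusted (seed) and
#'   unadjusted (candidate) calls; default 0.01.
#' @param correction multiple-testing correction; only `"bonferroni"`.
#' @return A `selection_config` list.
#' @export
selection_config <- function(alpha = 0.01, correction = "bonferroni") {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  correction <- match.arg(correction, "bonferroni")
  structure(list(alpha = alpha, correction = correction),
            class = "selection_config")
}

#' Classify genes into seeds, candidates, and the rest
#'
#' Bonferroni-adjusts p-values (`p_adj = min(1, p * n_tests)`) and labels
#' each gene `seed` if `p_adj < alpha`, `candidate` if only the unadjusted
#' `p < alpha`, else `none`.
#'
#' @param p named numeric vector of per-gene p-values.
#' @param config a [selection_config()].
#' @param n_tests number of tests for the correction; must be at least
#'   `length(p)`.
#' @return data.frame `gene_id`, `p`, `p_adj`, `label`.
#' @export
classify_genes <- function(p, config = selection_config(),
                           n_tests = length(p)) {
  if (n_tests < length(p))
    stop("n_tests must be at least the number of p-values")
  p_adj <- pmin(1, p * n_tests)
  label <- ifelse(p_adj < config$alpha, "seed",
                  ifelse(p < config$alpha, "candidate", "none"))
  data.frame(gene_id = if (is.null(names(p))) as.character(seq_along(p))
             else names(p),
             p = as.vector(p), p_adj = as.vector(p_adj), label = label,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Score and classify all genes of a differential-profile matrix
#'
#' Convenience wrapper: bounded areas, p-values against `null`, and
#' seed/candidate labels in one table.
#'
#' @param profiles gene x stage differential matrix (rownames = gene ids).
#' @param null a [null_model()].
#' @param config a [selection_config()].
#' @return data.frame `gene_id`, `area`, `p`, `p_adj`, `label`.
#' @export
select_genes <- function(profiles, null, config = selection_config()) {
  a <- bounded_area(profiles)
  p <- stats::setNames(area_pvalue(a, null), rownames(profiles))
  out <- classify_genes(p, config, n_tests = length(p))
  cbind(out[, "gene_id", drop = FALSE], area = a,
        out[, c("p", "p_adj", "label")])
}
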