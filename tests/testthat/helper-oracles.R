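# Independent oracles and small fixture builders shared across tests.

# Brute-force piecewise-linear area: sample the linear interpolant of |d|
# on a fine sub-grid (knots included, so the quadrature is exact for a
# piecewise-linear curve up to float rounding) and integrate trapezoid-wise.
area_oracle <- function(d, k = 200L) {
  T <- length(d)
  x <- seq(1, T, length.out = (T - 1L) * k + 1L)
  y <- stats::approx(seq_len(T), abs(d), xout = x)$y
  sum((y[-1L] + y[-length(y)]) / 2 * diff(x))
}

# Exhaustive hypergeometric enumeration of P(X >= a) for a 2x2 table with
# fixed margins, using nothing but choose().
fisher_oracle <- function(a, b, c, d) {
  K <- a + b; n <- a + c; N <- a + b + c + d
  xs <- max(0, n - (N - K)):min(K, n)
  pr <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  sum(pr[xs >= a])
}

# Count-scale series with prescribed per-stage replicate values.
# `reps` is a list of gene x stage matrices, one per replicate.
series_from_reps <- function(reps, genes = NULL, stages = NULL,
                             scale = "count") {
  G <- nrow(reps[[1L]]); S <- ncol(reps[[1L]])
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(G))
  if (is.null(stages)) stages <- paste0("S", seq_len(S))
  arr <- array(NA_real_, dim = c(G, S, length(reps)))
  for (r in seq_along(reps)) arr[, , r] <- reps[[r]]
  stage_series(arr, genes, stages, scale = scale)
}

# Series whose replicates all equal `m` (gene x stage matrix).
series_from_means <- function(m, n_reps = 3L, scale = "count", ...) {
  series_from_reps(rep(list(m), n_reps), scale = scale, ...)
}

# Strong-signal step-only world used by the pattern/break recovery tests:
# effects far above the detection threshold implied by the log-normal null,
# so recovery exercises the clustering machinery rather than raw power
# (the contract-pinned effect size 2 lives in test-acceptance.R and is red).
strong_step_config <- function(seed = 5L, ...) {
  sim_config(n_genes = 800L, frac_de = 0.25, effect_log2 = 8,
             shape_mix = c(step = 1, ramp = 0, pulse = 0, decay = 0),
             n_terms = 24L, term_size = 12L, term_purity = 1, seed = seed,
             ...)
}

# Planted clean bounded area of each gene in a truth table.
planted_areas <- function(truth, effect, S = 6L) {
  vapply(seq_len(nrow(truth)), function(i) {
    if (!truth$is_de[i]) return(0)
    bounded_area(shape_profile(truth$shape[i], truth$break_stage[i], S) *
                 effect)
  }, numeric(1))
}

# Majority planted break/sign of a pattern's DE members.
majority_truth <- function(members, truth) {
  m <- truth[match(members, truth$gene_id), ]
  m <- m[m$is_de & !is.na(m$is_de), ]
  if (!nrow(m)) return(NULL)
  list(break_stage = as.integer(names(sort(table(m$break_stage),
                                           decreasing = TRUE))[1L]),
       sign = as.integer(names(sort(table(m$sign), decreasing = TRUE))[1L]))
}
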