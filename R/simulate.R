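#' Simulation configuration
#'
#' Describes the synthetic multi-stage RNA-seq world: an ordered stage axis
#' whose first stage is the progenitor baseline, a set of planted
#' differentially expressed (DE) genes with step/ramp/pulse/decay temporal
#' shapes anchored at known break stages with known signs, and log-normal
#' replicate noise calibrated on profile-deviation areas.
#'
#' The default noise parameters (1.09, 0.44) are the mean and standard
#' deviation of the natural log of replicate-vs-mean bounded deviation areas
#' — the null-model parameters the selection stage is designed to recover.
#'
#' @param n_genes number of genes.
#' @param n_stages number of ordered stages (default 6).
#' @param n_replicates biological replicates per stage (default 3, min 2).
#' @param baseline_stage_index index of the baseline stage. The stage axis
#'   invariant places the baseline first, so only 1 is accepted; the argument
#'   exists to make the contract explicit.
#' @param frac_de fraction of genes with planted differential expression.
#' @param shape_mix named proportions over `c("step","ramp","pulse","decay")`;
#'   must sum to 1.
#' @param effect_log2 planted differential magnitude in log2 units (the
#'   maximum absolute deviation of the clean profile from baseline).
#' @param noise_log_mu,noise_log_sigma parameters of the log-normal law of
#'   bounded deviation areas (natural-log scale). Defaults 1.09 and 0.44.
#' @param base_expression_log2 center of per-gene baseline log2 expression;
#'   genes get a uniform +/-2 spread around it.
#' @param n_terms number of leaf annotation terms to simulate.
#' @param term_size genes per term.
#' @param term_purity fraction of each term's members sharing the term's
#'   dominant planted shape/sign/break.
#' @param seed integer RNG seed; fixing it fixes every output byte.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_genes = 2000L, n_stages = 6L, n_replicates = 3L,
                       baseline_stage_index = 1L, frac_de = 0.1,
                       shape_mix = c(step = 0.4, ramp = 0.3, pulse = 0.2,
                                     decay = 0.1),
                       effect_log2 = 2, noise_log_mu = 1.09,
                       noise_log_sigma = 0.44, base_expression_log2 = 10,
                       n_terms = 20L, term_size = 15L, term_purity = 0.9,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_stages = as.integer(n_stages),
              n_replicates = as.integer(n_replicates),
              baseline_stage_index = as.integer(baseline_stage_index),
              frac_de = frac_de, shape_mix = shape_mix,
              effect_log2 = effect_log2, noise_log_mu = noise_log_mu,
              noise_log_sigma = noise_log_sigma,
              base_expression_log2 = base_expression_log2,
              n_terms = as.integer(n_terms), term_size = as.integer(term_size),
              term_purity = term_purity, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 1L || n_stages < 3L) stop("non-positive or too-small sizes")
    if (n_replicates < 2L) stop("n_replicates must be >= 2")
    if (baseline_stage_index != 1L)
      stop("baseline must be the first stage (baseline_stage_index = 1)")
    if (frac_de < 0 || frac_de > 1) stop("frac_de must be in [0, 1]")
    if (frac_de > 0 && frac_de * n_genes < 1)
      stop("frac_de * n_genes must be >= 1 when DE genes are requested")
    shapes <- c("step", "ramp", "pulse", "decay")
    if (!all(names(shape_mix) %in% shapes) || any(shape_mix < 0))
      stop("shape_mix must be non-negative proportions over step/ramp/pulse/decay")
    if (abs(sum(shape_mix) - 1) > 1e-8) stop("shape_mix proportions must sum to 1")
    if (effect_log2 <= 0 || noise_log_sigma <= 0)
      stop("effect_log2 and noise_log_sigma must be positive")
    if (term_purity < 0 || term_purity > 1) stop("term_purity must be in [0, 1]")
    if (term_size > n_genes) stop("term_size cannot exceed n_genes")
  })
  invisible(cfg)
}

default_stage_labels <- function(S) {
  if (S == 6L) c("E15.5KO", "E15.5HET", "P1", "P4", "P12", "P60")
  else paste0("S", seq_len(S))
}

#' Clean planted temporal shapes
#'
#' Unit-amplitude shape profiles on stage indices `1..S`, zero at the
#' baseline (index 1). `brk` is the planted break stage: the stage the
#' time-break machinery should single out as the main break. `step` is flat
#' then plateaus from the break on; `ramp` rises monotonically from the
#' baseline and saturates at the break; `pulse` goes up at the break and
#' back down after it; `decay` peaks right after the baseline and declines.
#'
#' @param shape one of `"step"`, `"ramp"`, `"pulse"`, `"decay"`.
#' @param brk planted break stage index (>= 2).
#' @param S number of stages.
#' @return numeric profile of length `S`.
#' @export
shape_profile <- function(shape, brk, S) {
  p <- numeric(S)
  switch(shape,
    step = {                      # flat, then plateau from the break on
      p[brk:S] <- 1
    },
    ramp = {                      # monotone rise from baseline, saturating at brk
      p[1:brk] <- seq(0, 1, length.out = brk)
      if (brk < S) p[(brk + 1L):S] <- 1
    },
    pulse = {                     # up at brk, back down after
      p[brk] <- 1
      if (brk + 1L <= S) p[brk + 1L] <- 0.3
    },
    decay = {                     # early peak at stage 2, monotone decline
      p[2:S] <- 1 - 0.8 * (seq(2L, S) - 2L) / (S - 2L)
    },
    stop("unknown shape: ", shape))
  p
}

# Admissible planted break stages per shape (pulse needs room to come down;
# decay peaks right after baseline by construction).
.break_support <- function(shape, S) {
  switch(shape,
    step = 2:S, ramp = 2:S, pulse = 2:(S - 1L), decay = 2L)
}

# Random smooth shape over S stages with unit bounded area.
.unit_shapes <- function(n, S, w) {
  raw <- matrix(stats::rnorm(n * S), n, S)
  sm <- t(apply(raw, 1L, .smooth121))
  a <- abs(sm) %*% w
  bad <- which(a < 1e-8)
  while (length(bad)) {                        # vanishing area: redraw
    sm[bad, ] <- t(apply(matrix(stats::rnorm(length(bad) * S), ncol = S),
                         1L, .smooth121))
    a[bad] <- abs(sm[bad, , drop = FALSE]) %*% w
    bad <- which(a < 1e-8)
  }
  sm / as.vector(a)
}

# Build zero-sum per-replicate deviation profiles whose bounded areas
# (replicate vs cross-replicate mean) equal the prescribed per-gene targets
# exactly. Deviations from a mean obey a triangle inequality in the
# bounded-area norm (max area <= sum of the others), so the R targets of a
# gene must be compatible; the generator uses one shared target per gene,
# which is always feasible. Alternating projection: center to zero sum,
# rescale each replicate to its target area, repeat.
.calibrate_deviations <- function(A, u, w, tol = 1e-11, max_iter = 400L) {
  G <- dim(u)[1L]; R <- dim(u)[2L]; S <- dim(u)[3L]
  if (R == 2L) {
    # antisymmetric pair: both deviations share one shape and one area draw
    e <- array(0, dim = c(G, 2L, S))
    e[, 1L, ] <- A[, 1L] * u[, 1L, ]
    e[, 2L, ] <- -e[, 1L, ]
    return(e)
  }
  e <- array(0, dim = c(G, R, S))
  for (r in seq_len(R)) e[, r, ] <- A[, r] * u[, r, ]
  rel <- Inf
  for (iter in seq_len(max_iter)) {
    m <- e[, 1L, ]
    for (r in 2:R) m <- m + e[, r, ]
    m <- m / R
    for (r in seq_len(R)) e[, r, ] <- e[, r, ] - m
    ae <- matrix(0, G, R)
    for (s in seq_len(S)) ae <- ae + w[s] * abs(e[, , s])
    rel <- max(abs(ae - A) / A)
    if (rel < tol) break
    sc <- A / pmax(ae, 1e-300)
    for (r in seq_len(R)) e[, r, ] <- e[, r, ] * sc[, r]
  }
  if (rel >= tol)
    warning("deviation calibration did not fully converge; max relative ",
            "area error ", signif(rel, 3))
  # final centering so the zero-sum property is exact
  m <- e[, 1L, ]
  for (r in 2:R) m <- m + e[, r, ]
  m <- m / R
  for (r in seq_len(R)) e[, r, ] <- e[, r, ] - m
  e
}

#' Simulate a staged count series with planted temporal structure
#'
#' Generates a gene x stage x replicate count tensor. DE genes get a clean
#' log2 profile `baseline + shape(stage) * sign * effect_log2`; all genes get
#' (i) a smooth gene-level profile perturbation whose baseline-subtracted
#' bounded area is an iid LogNormal(noise_log_mu, noise_log_sigma) draw, and
#' (ii) zero-sum per-replicate perturbations whose replicate-vs-mean bounded
#' deviation areas are iid draws from the same law. Counts are
#' `round(2^log2value)`, hence non-negative integers.
#'
#' @param config a [sim_config()].
#' @return list with `series` (a [stage_series()] on count scale) and `truth`
#'   (data.frame: `gene_id`, `is_de`, `shape`, `break_stage`, `sign`;
#'   non-DE genes carry `NA` shape/break/sign).
#' @export
simulate_counts <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  G <- config$n_genes; S <- config$n_stages; R <- config$n_replicates
  w <- .trapz_weights(S)
  stages <- default_stage_labels(S)
  genes <- sprintf("G%05d", seq_len(G))

  n_de <- round(config$frac_de * G)
  de_idx <- if (n_de > 0) sort(sample.int(G, n_de)) else integer(0)
  shapes <- names(config$shape_mix)
  truth <- data.frame(gene_id = genes, is_de = FALSE,
                      shape = NA_character_, break_stage = NA_integer_,
                      sign = NA_integer_, stringsAsFactors = FALSE)
  clean <- matrix(0, G, S)
  if (n_de > 0) {
    g_shape <- sample(shapes, n_de, replace = TRUE, prob = config$shape_mix)
    g_sign <- sample(c(1L, -1L), n_de, replace = TRUE)
    g_brk <- vapply(g_shape, function(sh) {
      sup <- .break_support(sh, S)
      if (length(sup) == 1L) sup else sample(sup, 1L)
    }, integer(1))
    truth$is_de[de_idx] <- TRUE
    truth$shape[de_idx] <- g_shape
    truth$break_stage[de_idx] <- g_brk
    truth$sign[de_idx] <- g_sign
    for (k in seq_len(n_de)) {
      clean[de_idx[k], ] <- shape_profile(g_shape[k], g_brk[k], S) *
        g_sign[k] * config$effect_log2
    }
  }

  base <- config$base_expression_log2 + stats::runif(G, -2, 2)

  # gene-level noise: baseline-anchored smooth shape with prescribed area
  g_shapes <- .unit_shapes(G, S, w)
  g0 <- g_shapes - g_shapes[, 1L]
  a0 <- abs(g0) %*% w
  bad <- which(a0 < 1e-8)
  while (length(bad)) {
    g_shapes[bad, ] <- .unit_shapes(length(bad), S, w)
    g0[bad, ] <- g_shapes[bad, , drop = FALSE] - g_shapes[bad, 1L]
    a0[bad] <- abs(g0[bad, , drop = FALSE]) %*% w
    bad <- which(a0 < 1e-8)
  }
  A0 <- stats::rlnorm(G, config$noise_log_mu, config$noise_log_sigma)
  gdev <- g0 * as.vector(A0 / a0)

  # replicate-level noise: zero-sum deviations with prescribed areas.
  # One area draw per gene, shared by its replicates: deviations from a mean
  # always satisfy max(area) <= sum(other areas), so independent per-replicate
  # targets would be infeasible with positive probability; sharing the draw
  # keeps the marginal law exactly log-normal.
  A <- matrix(rep(stats::rlnorm(G, config$noise_log_mu,
                                config$noise_log_sigma), R), G, R)
  u <- array(0, dim = c(G, R, S))
  for (r in seq_len(R)) u[, r, ] <- .unit_shapes(G, S, w)
  e <- .calibrate_deviations(A, u, w)

  log2_vals <- array(0, dim = c(G, S, R))
  for (r in seq_len(R)) log2_vals[, , r] <- base + clean + gdev + e[, r, ]
  counts <- round(2 ^ log2_vals)
  counts[counts < 0] <- 0

  list(series = stage_series(counts, genes, stages, scale = "count"),
       truth = truth)
}

#' Simulate annotation sets, a term hierarchy, and a category map
#'
#' Builds `n_terms` leaf gene sets whose members predominantly share a
#' planted (shape, sign, break) combination — so function-based clustering
#' has signal — plus parent terms that union pairs of leaves and a single
#' root, giving an acyclic child-to-parent hierarchy. Each leaf is mapped to
#' a functional category determined by its dominant shape and sign.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` data.frame from [simulate_counts()].
#' @return list with `annotations` (named list term -> gene ids), `hierarchy`
#'   (data.frame `child`, `parent`), `categories` (data.frame `term_id`,
#'   `category`, `kind`), and `term_info` (per-term dominant shape/sign/break).
#' @export
simulate_annotations <- function(config, truth) {
  validate_sim_config(config)
  if (config$term_size > config$n_genes)
    stop("term_size cannot exceed n_genes")
  set.seed(config$seed + 1L)
  de <- truth[truth$is_de, , drop = FALSE]
  non_de <- truth$gene_id[!truth$is_de]
  cells <- if (nrow(de))
    split(de$gene_id, interaction(de$shape, de$sign, de$break_stage, drop = TRUE))
  else list()
  if (length(cells)) cells <- cells[order(names(cells))]
  cell_meta <- if (length(cells)) do.call(rbind, lapply(names(cells), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    data.frame(cell = nm, shape = parts[1L], sign = as.integer(parts[2L]),
               break_stage = as.integer(parts[3L]), stringsAsFactors = FALSE)
  })) else NULL

  ann <- list(); info <- NULL
  for (t in seq_len(config$n_terms)) {
    tid <- sprintf("T%04d", t)
    if (length(cells)) {
      ci <- ((t - 1L) %% length(cells)) + 1L
      pool <- cells[[ci]]
      n_pure <- stats::rbinom(1L, config$term_size, config$term_purity)
      # pure pool first; top up from other DE genes of the same shape/sign
      pure <- pool[sample.int(length(pool), min(n_pure, length(pool)))]
      if (length(pure) < n_pure) {
        ext <- setdiff(de$gene_id[de$shape == cell_meta$shape[ci] &
                                  de$sign == cell_meta$sign[ci]], pure)
        pure <- c(pure, ext[sample.int(length(ext),
                                       min(n_pure - length(pure), length(ext)))])
      }
      n_imp <- config$term_size - length(pure)
      imp_pool <- setdiff(c(non_de, setdiff(de$gene_id, cells[[ci]])), pure)
      impure <- imp_pool[sample.int(length(imp_pool), min(n_imp, length(imp_pool)))]
      members <- sort(unique(c(pure, impure)))
      meta <- cell_meta[ci, ]
    } else {
      members <- sort(truth$gene_id[sample.int(nrow(truth), config$term_size)])
      meta <- data.frame(shape = NA_character_, sign = NA_integer_,
                         break_stage = NA_integer_)
    }
    ann[[tid]] <- members
    info <- rbind(info, data.frame(
      term_id = tid, shape = meta$shape, sign = meta$sign,
      break_stage = meta$break_stage, is_leaf = TRUE, stringsAsFactors = FALSE))
  }

  # parents union consecutive leaf pairs; parents hang off a single root
  leaves <- names(ann)
  hier <- NULL
  n_pairs <- length(leaves) %/% 2L
  parents <- character(0)
  for (p in seq_len(n_pairs)) {
    pid <- sprintf("P%03d", p)
    kids <- leaves[c(2L * p - 1L, 2L * p)]
    ann[[pid]] <- sort(unique(unlist(ann[kids], use.names = FALSE)))
    hier <- rbind(hier, data.frame(child = kids, parent = pid,
                                   stringsAsFactors = FALSE))
    parents <- c(parents, pid)
    info <- rbind(info, data.frame(term_id = pid, shape = NA_character_,
                                   sign = NA_integer_, break_stage = NA_integer_,
                                   is_leaf = FALSE, stringsAsFactors = FALSE))
  }
  if (length(parents)) {
    ann[["ROOT"]] <- sort(unique(unlist(ann[parents], use.names = FALSE)))
    hier <- rbind(hier, data.frame(child = parents, parent = "ROOT",
                                   stringsAsFactors = FALSE))
    info <- rbind(info, data.frame(term_id = "ROOT", shape = NA_character_,
                                   sign = NA_integer_, break_stage = NA_integer_,
                                   is_leaf = FALSE, stringsAsFactors = FALSE))
  }

  cat_of <- function(i) {
    if (is.na(info$shape[i])) "CAT_general"
    else paste0("CAT_", info$shape[i], "_", ifelse(info$sign[i] > 0, "pos", "neg"))
  }
  categories <- data.frame(
    term_id = info$term_id,
    category = vapply(seq_len(nrow(info)), cat_of, character(1)),
    kind = "functional_category", stringsAsFactors = FALSE)

  list(annotations = ann, hierarchy = hier, categories = categories,
       term_info = info)
}
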