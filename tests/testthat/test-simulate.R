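test_that("configuration is validated", {
  expect_error(sim_config(shape_mix = c(step = 0.7, ramp = 0.7)), "sum to 1")
  expect_error(sim_config(n_replicates = 1), ">= 2")
  expect_error(sim_config(n_genes = 50, frac_de = 0.001), ">= 1")
  expect_error(sim_config(term_size = 100, n_genes = 50), "term_size")
  expect_error(sim_config(baseline_stage_index = 2), "first stage")
  expect_error(sim_config(effect_log2 = -1), "positive")
})

test_that("fixed seed fixes every output byte", {
  cfg <- sim_config(n_genes = 120L, frac_de = 0.2, n_terms = 6L,
                    term_size = 8L, seed = 7L)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$series$values, s2$series$values)
  expect_identical(s1$truth, s2$truth)
  a1 <- simulate_annotations(cfg, s1$truth)
  a2 <- simulate_annotations(cfg, s2$truth)
  expect_identical(a1, a2)
  # and through the writers
  d1 <- tempfile(); d2 <- tempfile()
  simulate_to_dir(cfg, d1); simulate_to_dir(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("frac_de = 0 plants no signal and truth invariants hold", {
  cfg <- sim_config(n_genes = 80L, frac_de = 0, seed = 3L)
  sim <- simulate_counts(cfg)
  expect_false(any(sim$truth$is_de))
  expect_true(all(is.na(sim$truth$shape)))
  expect_true(all(is.na(sim$truth$break_stage)))
  expect_true(all(is.na(sim$truth$sign)))
  expect_true(all(sim$series$values >= 0))
  expect_true(all(sim$series$values == round(sim$series$values)))

  cfg2 <- sim_config(n_genes = 200L, frac_de = 0.3, seed = 3L)
  tr <- simulate_counts(cfg2)$truth
  expect_true(all(tr$break_stage[tr$is_de] >= 2L))
  expect_true(all(tr$sign[tr$is_de] %in% c(-1L, 1L)))
  # planted baseline-stage mean differential is zero by construction
  d <- differential_profiles(log2_transform(simulate_counts(cfg2)$series))
  expect_true(all(d[, 1L] == 0))
})

test_that("replicate deviation areas follow the target log-normal", {
  cfg <- sim_config(n_genes = 10000L, frac_de = 0, seed = 42L)
  lg <- log2_transform(simulate_counts(cfg)$series)
  m <- stage_means(lg)
  # one area per gene (replicate areas share a gene-level draw)
  areas <- as.vector(abs(lg$values[, , 1L] - m) %*% c(.5, 1, 1, 1, 1, .5))
  expect_lt(abs(mean(log(areas)) - 1.09), 3 * 0.44 / sqrt(10000))
  ks <- stats::ks.test(areas, stats::plnorm, meanlog = 1.09, sdlog = 0.44)
  expect_gt(ks$p.value, 0.01)
})

test_that("DE genes carry the planted mean log2 profile", {
  cfg <- sim_config(n_genes = 400L, frac_de = 0.25, effect_log2 = 8,
                    seed = 9L)
  sim <- simulate_counts(cfg)
  d <- differential_profiles(log2_transform(sim$series))
  tr <- sim$truth
  de <- which(tr$is_de)
  # averaged over the most populated (shape, break, sign) cell, noise
  # cancels and the differential approaches shape * sign * effect
  key <- paste(tr$shape[de], tr$break_stage[de], tr$sign[de])
  top <- names(sort(table(key), decreasing = TRUE))[1L]
  cell <- de[key == top]
  expect_gte(length(cell), 3L)
  parts <- strsplit(top, " ")[[1L]]
  avg <- colMeans(d[tr$gene_id[cell], , drop = FALSE])
  expect_equal(unname(avg),
               shape_profile(parts[1L], as.integer(parts[2L]), 6L) *
                 as.integer(parts[3L]) * 8,
               tolerance = 0.5)
})

test_that("annotations: purity, DAG hierarchy, binomial impurity", {
  # shapes restricted so every (shape, sign) pool is large enough that
  # purity-1 terms can always be filled with pure members
  cfg <- sim_config(n_genes = 600L, frac_de = 0.4, n_terms = 30L,
                    shape_mix = c(step = 0.5, ramp = 0.5, pulse = 0,
                                  decay = 0),
                    term_size = 10L, term_purity = 1, seed = 11L)
  sim <- simulate_counts(cfg)
  ann <- simulate_annotations(cfg, sim$truth)
  tr <- sim$truth
  leaf <- ann$term_info[ann$term_info$is_leaf, ]
  for (i in seq_len(nrow(leaf))) {
    g <- ann$annotations[[leaf$term_id[i]]]
    m <- tr[match(g, tr$gene_id), ]
    expect_true(all(m$is_de & m$shape == leaf$shape[i] &
                    m$sign == leaf$sign[i]), info = leaf$term_id[i])
  }
  # hierarchy is a DAG: leaves-first order exists and covers all nodes
  expect_no_error(patternseq:::.topo_leaves_first(ann$hierarchy))
  # parents union their children's genes
  p1 <- ann$hierarchy$parent[1L]
  kids <- ann$hierarchy$child[ann$hierarchy$parent == p1]
  expect_setequal(ann$annotations[[p1]],
                  unique(unlist(ann$annotations[kids])))

  # impure member fraction ~ Binomial(term_size, 1 - purity)
  cfg2 <- sim_config(n_genes = 2000L, frac_de = 0.5, n_terms = 60L,
                     term_size = 20L, term_purity = 0.8, seed = 12L)
  sim2 <- simulate_counts(cfg2)
  ann2 <- simulate_annotations(cfg2, sim2$truth)
  tr2 <- sim2$truth
  leaf2 <- ann2$term_info[ann2$term_info$is_leaf, ]
  impure <- vapply(seq_len(nrow(leaf2)), function(i) {
    g <- ann2$annotations[[leaf2$term_id[i]]]
    m <- tr2[match(g, tr2$gene_id), ]
    mean(!(m$is_de & !is.na(m$shape) & m$shape == leaf2$shape[i] &
           m$sign == leaf2$sign[i]))
  }, numeric(1))
  n_draws <- nrow(leaf2) * 20L
  se <- sqrt(0.2 * 0.8 / n_draws)
  expect_lt(abs(mean(impure) - 0.2), 4 * se)
})
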