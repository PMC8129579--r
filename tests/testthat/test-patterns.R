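# Hand-built profile fixtures: 6 stages, baseline-subtracted (first = 0).
step_up <- c(0, 1, 1, 1, 1, 1)
step_dn <- -step_up

test_that("cluster_term: identity, separation, and regression identities", {
  # all genes share one identical profile -> one TP containing all
  X <- rbind(a = step_up, b = step_up, c = step_up)
  tps <- cluster_term(X, seeds = c("a", "b"))
  expect_length(tps, 1L)
  expect_setequal(tps[[1]]$members, c("a", "b", "c"))
  expect_equal(unname(tps[[1]]$template), step_up)

  # anti-correlated seed groups separate under the positive-slope rule
  X2 <- rbind(u1 = step_up, u2 = step_up + c(0, .01, 0, 0, 0, 0),
              d1 = step_dn, d2 = step_dn + c(0, 0, .01, 0, 0, 0))
  tps2 <- cluster_term(X2, seeds = rownames(X2),
                       p_values = c(u1 = 1e-5, u2 = 1e-4, d1 = 1e-5,
                                    d2 = 1e-4))
  expect_length(tps2, 2L)
  mem <- lapply(tps2, `[[`, "members")
  expect_true(setequal(mem[[1]], c("u1", "u2")) ||
              setequal(mem[[1]], c("d1", "d2")))
  expect_length(intersect(mem[[1]], mem[[2]]), 0L)

  # candidate = 2x template joins (R^2 = 1, slope 2); -template is excluded
  X3 <- rbind(s = step_up, twice = 2 * step_up, neg = -step_up)
  tps3 <- cluster_term(X3, seeds = "s")
  expect_length(tps3, 1L)
  expect_setequal(tps3[[1]]$members, c("s", "twice"))
  expect_identical(tps3[[1]]$seed_members, "s")
  expect_error(cluster_term(X3, seeds = character(0)), "seed")
})

test_that("every TP keeps a seed; members are seeds or candidates", {
  set.seed(33)
  G <- 40L
  X <- matrix(rnorm(G * 6), G, 6)
  X[, 1] <- 0
  rownames(X) <- sprintf("g%02d", seq_len(G))
  sel <- data.frame(gene_id = rownames(X),
                    p = runif(G),
                    label = sample(c("seed", "candidate", "none"), G,
                                   replace = TRUE),
                    stringsAsFactors = FALSE)
  ann <- list(TA = rownames(X)[1:20], TB = rownames(X)[15:40])
  fp <- find_patterns(sel, X, ann, hierarchy = NULL)
  seeds <- sel$gene_id[sel$label == "seed"]
  cands <- sel$gene_id[sel$label == "candidate"]
  for (p in fp$patterns) {
    expect_gte(length(intersect(p$seed_members, seeds)), 1L)
    expect_true(all(p$members %in% c(seeds, cands)))
  }
  # de_genes = seeds plus TP candidates only
  in_tp <- unique(unlist(lapply(fp$patterns, `[[`, "members")))
  expect_setequal(fp$de_genes, union(seeds, intersect(cands, in_tp)))
})

test_that("seeds are unconditionally DE; TP-less candidates are not", {
  X <- rbind(s1 = step_up, c1 = step_up, lonely_seed = c(0, 2, 0, 2, 0, 2),
             lonely_cand = c(0, -2, 0, -2, 0, 2))
  sel <- data.frame(gene_id = rownames(X), p = c(1e-6, 5e-3, 1e-6, 5e-3),
                    label = c("seed", "candidate", "seed", "candidate"),
                    stringsAsFactors = FALSE)
  ann <- list(TA = c("s1", "c1"))   # the lonely pair is annotated nowhere
  fp <- find_patterns(sel, X, ann)
  expect_true("lonely_seed" %in% fp$de_genes)     # seed without any term
  expect_false("lonely_cand" %in% fp$de_genes)    # candidate in no TP
  expect_true("c1" %in% fp$de_genes)              # rescued by co-clustering
})

test_that("leaf-first processing removes clustered genes from ancestors", {
  # child term clusters g1..g4; parent must only see g5, g6
  X <- rbind(g1 = step_up, g2 = step_up, g3 = step_up, g4 = step_up,
             g5 = c(0, 0, 0, 1, 1, 1), g6 = c(0, 0, 0, 1, 1, 1))
  sel <- data.frame(gene_id = rownames(X), p = rep(1e-6, 6),
                    label = rep("seed", 6), stringsAsFactors = FALSE)
  ann <- list(child = c("g1", "g2", "g3", "g4"),
              parent = c("g1", "g2", "g3", "g4", "g5", "g6"))
  hier <- data.frame(child = "child", parent = "parent",
                     stringsAsFactors = FALSE)
  fp <- find_patterns(sel, X, ann, hier)
  parent_tps <- Filter(function(p) p$term_id == "parent", fp$patterns)
  parent_members <- unlist(lapply(parent_tps, `[[`, "members"))
  expect_length(intersect(parent_members, c("g1", "g2", "g3", "g4")), 0L)
  expect_setequal(parent_members, c("g5", "g6"))
  expect_error(
    find_patterns(sel, X, ann,
                  data.frame(child = c("a", "b"), parent = c("b", "a"))),
    "cyclic")
})

test_that("de_genes is monotone in seeds and the search is deterministic", {
  set.seed(44)
  X <- matrix(rnorm(20 * 6), 20, 6); X[, 1] <- 0
  rownames(X) <- sprintf("g%02d", 1:20)
  sel <- data.frame(gene_id = rownames(X), p = runif(20, 0, 0.009),
                    label = c(rep("seed", 5), rep("candidate", 15)),
                    stringsAsFactors = FALSE)
  ann <- list(TA = rownames(X)[1:12], TB = rownames(X)[8:20])
  fp1 <- find_patterns(sel, X, ann)
  sel2 <- sel
  sel2$label[6] <- "seed"                       # promote one candidate
  fp2 <- find_patterns(sel2, X, ann)
  expect_true(all(fp1$de_genes %in% fp2$de_genes))
  # identical inputs -> identical memberships
  fp1b <- find_patterns(sel, X, ann)
  expect_identical(fp1, fp1b)
})

test_that("planted patterns are recovered in a strong-signal world", {
  cfg <- strong_step_config()
  sim <- simulate_counts(cfg)
  ann <- simulate_annotations(cfg, sim$truth)
  lg <- log2_transform(filter_low_expression(sim$series))
  prof <- differential_profiles(lg)
  nm <- estimate_null(lg)
  sel <- select_genes(prof, nm)
  fp <- find_patterns(sel, prof, ann$annotations, ann$hierarchy)
  expect_gt(length(fp$patterns), 5L)

  # genes whose planted area clears the seed threshold comfortably are
  # recovered as DE
  seed_thr <- exp(nm$log_mu + qnorm(1 - 0.01 / nrow(prof)) * nm$log_sigma)
  det <- sim$truth$is_de &
    planted_areas(sim$truth, cfg$effect_log2) > 1.2 * seed_thr
  expect_gte(mean(sim$truth$gene_id[det] %in% fp$de_genes), 0.9)

  # with purity 1, leaf terms overwhelmingly yield a single TP
  leaf_tp <- table(vapply(Filter(function(p) grepl("^T", p$term_id),
                                 fp$patterns), `[[`, character(1), "term_id"))
  expect_gte(mean(leaf_tp == 1L), 0.9)
})
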