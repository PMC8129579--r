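#' Clustering configuration for temporal patterns
#'
#' Membership criterion for template clustering: a profile joins a cluster
#' when simple linear regression of the profile on the cluster template
#' (intercept estimated but unconstrained) reaches `R^2 >= min_r2` with a
#' positive slope. This is the package's concrete instantiation of
#' linear-model-based profile clustering; both knobs are configurable.
#'
#' @param min_r2 minimal coefficient of determination (default 0.8).
#' @param require_positive_slope require slope > 0 (default TRUE); with it
#'   a profile equal to minus the template is excluded.
#' @param max_iter maximal template-refinement iterations (default 20).
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(min_r2 = 0.8, require_positive_slope = TRUE,
                           max_iter = 20L) {
  if (!(min_r2 > 0 && min_r2 <= 1)) stop("min_r2 must be in (0, 1]")
  structure(list(min_r2 = min_r2,
                 require_positive_slope = isTRUE(require_positive_slope),
                 max_iter = as.integer(max_iter)),
            class = "cluster_config")
}

# R^2 and slope sign of each row of X regressed on each template (rows of Tm).
# Returns ok (logical m x k: meets criterion) and r2 (m x k, NA when either
# profile has zero variance).
.fit_matrix <- function(X, Tm, config) {
  C <- suppressWarnings(stats::cor(t(X), t(Tm)))
  C <- matrix(C, nrow(X), nrow(Tm))
  r2 <- C ^ 2
  ok <- !is.na(C) & r2 >= config$min_r2
  if (config$require_positive_slope) ok <- ok & C > 0
  list(ok = ok, r2 = r2)
}

# Greedy template clustering. X: item x stage matrix (named rows);
# founders: ordered row names allowed to found clusters (seeds for TPs, all
# items for MP summarization). Non-founders fitting no cluster stay
# unassigned; founders fitting no cluster found their own. Ties go to the
# lowest cluster index; all steps are deterministic.
.template_cluster <- function(X, founders, config) {
  stopifnot(all(founders %in% rownames(X)))
  items <- rownames(X)
  templates <- NULL
  assign <- stats::setNames(rep(NA_integer_, length(items)), items)

  # founding pass: templates stay at founder profiles
  for (f in founders) {
    if (is.null(templates)) {
      templates <- X[f, , drop = FALSE]
      assign[f] <- 1L
      next
    }
    fit <- .fit_matrix(X[f, , drop = FALSE], templates, config)
    if (any(fit$ok)) {
      assign[f] <- which.max(ifelse(fit$ok[1L, ], fit$r2[1L, ], -Inf))
    } else {
      templates <- rbind(templates, X[f, , drop = FALSE])
      assign[f] <- nrow(templates)
    }
  }

  # refinement: recompute templates as member means, reassign everything
  for (iter in seq_len(config$max_iter)) {
    for (k in seq_len(nrow(templates))) {
      members <- items[!is.na(assign) & assign == k]
      if (length(members))
        templates[k, ] <- colMeans(X[members, , drop = FALSE])
    }
    fit <- .fit_matrix(X, templates, config)
    new_assign <- assign
    for (i in seq_along(items)) {
      oks <- fit$ok[i, ]
      new_assign[i] <- if (any(oks))
        which.max(ifelse(oks, fit$r2[i, ], -Inf)) else NA_integer_
    }
    # founders that fit nothing re-found singleton clusters
    lost <- founders[is.na(new_assign[founders])]
    for (f in lost) {
      templates <- rbind(templates, X[f, , drop = FALSE])
      new_assign[f] <- nrow(templates)
    }
    if (identical(new_assign, assign)) break
    assign <- new_assign
  }

  # drop empty clusters, renumber in founding order
  used <- sort(unique(assign[!is.na(assign)]))
  remap <- stats::setNames(seq_along(used), used)
  assign[!is.na(assign)] <- remap[as.character(assign[!is.na(assign)])]
  templates <- templates[used, , drop = FALSE]
  for (k in seq_len(nrow(templates))) {
    members <- items[!is.na(assign) & assign == k]
    templates[k, ] <- colMeans(X[members, , drop = FALSE])
  }
  list(assignment = assign, templates = templates)
}

#' Cluster the profiles of one functional term into Temporal Patterns
#'
#' Seeds are processed in increasing p-value order (ties by gene id); a seed
#' whose profile fits no existing pattern founds a new one with its profile
#' as template. All genes of the term (seeds and candidates) then join the
#' best-fitting pattern under the [cluster_config()] criterion; templates
#' are recomputed as member means and membership re-evaluated until stable.
#' Patterns that end up without a seed are discarded (their candidate
#' members become unassigned); every returned pattern contains at least one
#' seed.
#'
#' @param profiles gene x stage differential matrix restricted to the genes
#'   annotated to one term (rownames = gene ids).
#' @param seeds character vector of seed gene ids (subset of rownames).
#' @param config a [cluster_config()].
#' @param p_values optional named p-values used to order seeds.
#' @return list of patterns, each `list(members, seed_members, template)`.
#' @export
cluster_term <- function(profiles, seeds, config = cluster_config(),
                         p_values = NULL) {
  if (!length(seeds)) stop("cluster_term needs at least one seed")
  stopifnot(all(seeds %in% rownames(profiles)))
  ord <- if (is.null(p_values)) order(seeds)
         else order(p_values[seeds], seeds)
  res <- .template_cluster(profiles, seeds[ord], config)
  out <- list()
  for (k in seq_len(nrow(res$templates))) {
    members <- sort(names(res$assignment)[!is.na(res$assignment) &
                                          res$assignment == k])
    sm <- intersect(members, seeds)
    if (!length(sm)) next                        # seedless cluster: discard
    out[[length(out) + 1L]] <-
      list(members = members, seed_members = sort(sm),
           template = colMeans(profiles[members, , drop = FALSE]))
  }
  out
}

# Reverse-topological (leaves first) order of terms over child->parent
# edges; sibling ties broken lexicographically. Errors on cycles.
.topo_leaves_first <- function(edges) {
  nodes <- sort(unique(c(edges$child, edges$parent)))
  # out-degree = number of children still unprocessed; process a node once
  # all its children are done
  kids <- split(edges$child, edges$parent)
  n_kids <- stats::setNames(rep(0L, length(nodes)), nodes)
  n_kids[names(kids)] <- lengths(kids)
  parents_of <- split(edges$parent, edges$child)
  ready <- sort(nodes[n_kids == 0L])
  out <- character(0)
  while (length(ready)) {
    n <- ready[1L]; ready <- ready[-1L]
    out <- c(out, n)
    for (p in parents_of[[n]] %||% character(0)) {
      n_kids[p] <- n_kids[p] - 1L
      if (n_kids[p] == 0L) ready <- sort(c(ready, p))
    }
  }
  if (length(out) != length(nodes)) stop("cyclic hierarchy")
  out
}

# All ancestors of each term (transitive closure of child->parent edges).
.ancestors <- function(edges) {
  parents_of <- split(edges$parent, edges$child)
  memo <- new.env(parent = emptyenv())
  anc <- function(n) {
    if (!is.null(memo[[n]])) return(memo[[n]])
    ps <- unique(parents_of[[n]] %||% character(0))
    res <- ps
    for (p in ps) res <- union(res, anc(p))
    memo[[n]] <- res
    res
  }
  nodes <- unique(c(edges$child, edges$parent))
  stats::setNames(lapply(nodes, anc), nodes)
}

#' Find Temporal Patterns across all annotated terms
#'
#' Processes hierarchical terms leaves-first; once a term's patterns are
#' formed, their member genes are removed from the annotation sets of all
#' its ancestor terms before those are processed (redundancy reduction
#' along the term hierarchy). Terms absent from the hierarchy (for example
#' pathways) are processed afterwards, in lexicographic order, without gene
#' removal. Terms whose (remaining) annotated genes contain no seed are
#' skipped and reported. A gene counts as differentially expressed when it
#' is a seed, or a candidate belonging to at least one pattern.
#'
#' @param selection a selection table as returned by [select_genes()] /
#'   [classify_genes()] (columns `gene_id`, `p`, `label`).
#' @param profiles gene x stage differential matrix.
#' @param annotations named list: term id -> character vector of gene ids.
#' @param hierarchy data.frame with columns `child`, `parent`, or NULL for
#'   flat annotations.
#' @param config a [cluster_config()].
#' @return list with `patterns` (each `list(term_id, tp_index, members,
#'   seed_members, template)`), `de_genes`, `skipped_terms`.
#' @export
find_patterns <- function(selection, profiles, annotations, hierarchy = NULL,
                          config = cluster_config()) {
  seeds <- selection$gene_id[selection$label == "seed"]
  cands <- selection$gene_id[selection$label == "candidate"]
  universe <- intersect(c(seeds, cands), rownames(profiles))
  pv <- stats::setNames(selection$p, selection$gene_id)

  ann <- lapply(annotations, function(g) intersect(g, universe))
  ann <- ann[lengths(ann) > 0L]

  has_hier <- !is.null(hierarchy) && nrow(hierarchy) > 0L
  if (has_hier) {
    order_h <- .topo_leaves_first(hierarchy)
    anc <- .ancestors(hierarchy)
    hier_terms <- intersect(order_h, names(ann))
    flat_terms <- sort(setdiff(names(ann), order_h))
  } else {
    hier_terms <- character(0)
    flat_terms <- sort(names(ann))
  }

  patterns <- list()
  skipped <- character(0)
  for (term in c(hier_terms, flat_terms)) {
    genes <- ann[[term]]
    if (!length(genes)) next
    term_seeds <- intersect(genes, seeds)
    if (!length(term_seeds)) {
      skipped <- c(skipped, term)
      next
    }
    tps <- cluster_term(profiles[genes, , drop = FALSE], term_seeds, config,
                        p_values = pv)
    if (length(tps)) {
      for (i in seq_along(tps)) {
        tps[[i]]$term_id <- term
        tps[[i]]$tp_index <- i
        patterns[[length(patterns) + 1L]] <- tps[[i]]
      }
      if (has_hier && term %in% names(anc)) {
        clustered <- unique(unlist(lapply(tps, `[[`, "members"),
                                   use.names = FALSE))
        for (a in anc[[term]]) {
          if (!is.null(ann[[a]]))
            ann[[a]] <- setdiff(ann[[a]], clustered)
        }
      }
    }
  }

  in_tp <- unique(unlist(lapply(patterns, `[[`, "members"), use.names = FALSE))
  de <- sort(union(intersect(seeds, selection$gene_id),
                   intersect(cands, in_tp)))
  list(patterns = patterns, de_genes = de, skipped_terms = skipped)
}
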