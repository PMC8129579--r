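#' One-sided Fisher's exact test for a 2x2 table
#'
#' Upper-tail (enrichment) test: the p-value is the hypergeometric
#' probability `P(X >= a)` of observing at least `a` case genes in the
#' category, given the table margins. The odds ratio is the sample
#' cross-product `(a d) / (b c)`, with `Inf` when the denominator is zero.
#'
#' @param a,b,c,d non-negative integer cell counts: `a` = in case and in
#'   category, `b` = in category only, `c` = in case only, `d` = neither.
#'   Alternatively pass a 2x2 matrix as `a`.
#' @return list `odds_ratio`, `p`.
#' @export
fisher_exact_one_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L))
    b <- a[1L, 2L]; c <- a[2L, 1L]; d <- a[2L, 2L]; a <- a[1L, 1L]
  }
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  p <- stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  list(odds_ratio = or, p = p)
}

#' Stage-grouped enrichment of Main-Pattern gene sets
#'
#' For each functional category (within each category kind) and each case —
#' all positive MPs, all negative MPs, and sign crossed with the break
#' groups of `bconfig$grouping` — builds the 2x2 table of case membership
#' versus category membership over the background gene universe and applies
#' [fisher_exact_one_sided()]. FDR q-values are Benjamini-Hochberg,
#' computed within each (kind, case) family; `significant` flags `q <
#' fdr_alpha`. Duplicate gene ids are counted once throughout (set
#' semantics); a category with no gene in a case gets `p = 1`.
#'
#' @param mps `main_patterns` list from [summarize_main_patterns()].
#' @param category_map data.frame `term_id`, `category`, `kind`.
#' @param annotations named list term id -> gene ids (category membership is
#'   the union over the category's terms, intersected with the background).
#' @param background character vector: the gene universe (by default the
#'   selected DE genes; configurable to the full expressed universe).
#' @param bconfig a [break_config()] supplying the break grouping.
#' @param fdr_alpha significance level on q-values (default 0.05).
#' @return data.frame `kind`, `case`, `category`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p`, `q`, `significant`.
#' @export
build_cases <- function(mps, category_map, annotations, background,
                        bconfig = break_config(), fdr_alpha = 0.05) {
  background <- unique(background)
  if (!length(background)) stop("empty background universe")
  signs <- vapply(mps, `[[`, character(1), "sign")
  brks <- vapply(mps, `[[`, integer(1), "time_break")
  gene_union <- function(idx)
    intersect(unique(unlist(lapply(mps[idx], `[[`, "genes"),
                            use.names = FALSE)), background)
  cases <- list(positive_all = gene_union(which(signs == "positive")),
                negative_all = gene_union(which(signs == "negative")))
  for (grp in names(bconfig$grouping)) {
    st <- bconfig$grouping[[grp]]
    for (sg in c("positive", "negative")) {
      cases[[paste0(sg, "_", grp)]] <-
        gene_union(which(signs == sg & brks %in% st))
    }
  }

  out <- NULL
  for (kind in sort(unique(category_map$kind))) {
    km <- category_map[category_map$kind == kind, , drop = FALSE]
    cats <- sort(unique(km$category))
    cat_genes <- lapply(cats, function(cc) {
      terms <- km$term_id[km$category == cc]
      intersect(unique(unlist(annotations[terms], use.names = FALSE)),
                background)
    })
    names(cat_genes) <- cats
    for (case_name in names(cases)) {
      cg <- cases[[case_name]]
      rows <- lapply(cats, function(cc) {
        inc <- cat_genes[[cc]]
        a <- length(intersect(cg, inc))
        b <- length(inc) - a
        c_ <- length(cg) - a
        d <- length(background) - a - b - c_
        ft <- fisher_exact_one_sided(a, b, c_, d)
        data.frame(kind = kind, case = case_name, category = cc,
                   a = a, b = b, c = c_, d = d,
                   odds_ratio = ft$odds_ratio, p = ft$p,
                   stringsAsFactors = FALSE)
      })
      fam <- do.call(rbind, rows)
      fam$q <- stats::p.adjust(fam$p, method = "BH")
      fam$significant <- fam$q < fdr_alpha
      out <- rbind(out, fam)
    }
  }
  rownames(out) <- NULL
  out
}
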