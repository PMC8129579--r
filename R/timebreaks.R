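#' Time-break configuration
#'
#' Houses the 20% change threshold, where the break search starts (the
#' second stage: the baseline itself can never be a break), and the mapping
#' from break stages to developmental break groups used by stage-grouped
#' enrichment. The default grouping for a six-stage axis follows the
#' embryonic / nascent / older beta-cell reading: stage 2 is embryonic,
#' stages 3-4 nascent, stages 5-6 older.
#'
#' @param threshold fraction of the pattern mean a stage-to-stage change
#'   must exceed (default 0.2).
#' @param search_start first stage index examined (default 2).
#' @param grouping named list: group label -> integer stage indices.
#' @param tpbar_mode how the pattern mean TP-bar is computed: `"abs"`
#'   (mean of |TP(x)|, default — stable for balanced up/down patterns) or
#'   `"signed"` (plain mean).
#' @return A `break_config` list.
#' @export
break_config <- function(threshold = 0.2, search_start = 2L,
                         grouping = list(embryonic = 2L, nascent = c(3L, 4L),
                                         older = c(5L, 6L)),
                         tpbar_mode = c("abs", "signed")) {
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  if (search_start < 2L) stop("search_start must be at least stage 2")
  structure(list(threshold = threshold, search_start = as.integer(search_start),
                 grouping = grouping, tpbar_mode = match.arg(tpbar_mode)),
            class = "break_config")
}

#' Assign candidate time breaks to a pattern template
#'
#' A stage `x_i` (from `search_start` on) is a candidate break when the
#' change to either adjacent stage exceeds `threshold` times the pattern
#' mean: `|TP(x_i) - TP(x_{i-1})| / TPbar > threshold` or, for `i < T`,
#' `|TP(x_{i+1}) - TP(x_i)| / TPbar > threshold`. For the last stage only
#' the backward difference applies, but the change relative to the most
#' recent previously identified break is also evaluated. The ratio to
#' TP-bar cancels any positive scaling of the template, so break assignment
#' is scale-invariant. An all-zero template is unclassifiable (no breaks).
#'
#' @param template numeric pattern profile TP(x_1..x_T), baseline-subtracted.
#' @param config a [break_config()].
#' @return list `candidates` (integer stage indices), `main` (stage index or
#'   `NA`), `tpbar`, `unclassifiable` flag.
#' @export
assign_time_breaks <- function(template, config = break_config()) {
  T <- length(template)
  if (T < 3L) stop("template needs at least three stages")
  if (any(!is.finite(template))) stop("non-finite template")
  tpbar <- if (config$tpbar_mode == "abs") mean(abs(template))
           else mean(template)
  if (abs(tpbar) == 0)
    return(list(candidates = integer(0), main = NA_integer_, tpbar = 0,
                unclassifiable = TRUE))
  thr <- config$threshold
  cand <- integer(0)
  for (i in seq(config$search_start, T)) {
    back <- abs(template[i] - template[i - 1L]) / abs(tpbar)
    hit <- back > thr
    if (i < T) {
      fwd <- abs(template[i + 1L] - template[i]) / abs(tpbar)
      hit <- hit || fwd > thr
    } else if (!hit && length(cand)) {
      prev <- max(cand)        # most recent previously identified break
      hit <- abs(template[i] - template[prev]) / abs(tpbar) > thr
    }
    if (hit) cand <- c(cand, i)
  }
  main <- if (length(cand)) select_main_break(template, cand) else NA_integer_
  list(candidates = cand, main = main, tpbar = tpbar,
       unclassifiable = length(cand) == 0L)
}

#' Select the main time break
#'
#' Among candidate breaks, the one whose template value deviates most from
#' the (zero) baseline; ties go to the earlier stage.
#'
#' @param template numeric pattern profile.
#' @param candidates integer candidate stage indices (ascending).
#' @return The main break stage index.
#' @export
select_main_break <- function(template, candidates) {
  if (!length(candidates)) stop("no candidate breaks: unclassifiable pattern")
  candidates <- sort(candidates)
  candidates[which.max(abs(template[candidates]))]
}

#' Summarize Temporal Patterns into Main Patterns
#'
#' Groups patterns by their main break stage (up to T-1 groups; five on a
#' six-stage axis) and, within each group, clusters the pattern templates
#' with the same template-clustering operator used for genes — every
#' template may found a cluster, so every classified pattern lands in
#' exactly one Main Pattern and singletons stay singleton. The MP profile
#' is the mean of its member templates; the MP inherits the group's break
#' and is classified positive/negative by its sign at that break.
#' Patterns without a break are returned separately as unclassified.
#'
#' @param patterns list of temporal patterns (`term_id`, `tp_index`,
#'   `members`, `template`), e.g. from [find_patterns()].
#' @param config a [cluster_config()].
#' @param bconfig a [break_config()].
#' @return list with `main_patterns` (each `list(mp_id, time_break, sign,
#'   profile, tp_ids, genes)`) and `unclassified_tps` (character tp ids).
#' @export
summarize_main_patterns <- function(patterns, config = cluster_config(),
                                    bconfig = break_config()) {
  if (!length(patterns))
    return(list(main_patterns = list(), unclassified_tps = character(0)))
  tp_ids <- vapply(patterns, function(p)
    paste0(p$term_id, ".", p$tp_index), character(1))
  ord <- order(tp_ids)
  patterns <- patterns[ord]; tp_ids <- tp_ids[ord]
  breaks <- vapply(patterns, function(p)
    assign_time_breaks(p$template, bconfig)$main %||% NA_integer_, integer(1))

  unclassified <- tp_ids[is.na(breaks)]
  mps <- list()
  for (b in sort(unique(breaks[!is.na(breaks)]))) {
    idx <- which(!is.na(breaks) & breaks == b)
    X <- do.call(rbind, lapply(patterns[idx], `[[`, "template"))
    rownames(X) <- tp_ids[idx]
    res <- .template_cluster(X, rownames(X), config)
    for (k in sort(unique(res$assignment))) {
      members <- names(res$assignment)[res$assignment == k]
      profile <- colMeans(X[members, , drop = FALSE])
      genes <- sort(unique(unlist(lapply(patterns[idx][match(members, tp_ids[idx])],
                                         `[[`, "members"), use.names = FALSE)))
      mps[[length(mps) + 1L]] <- list(
        time_break = b, sign = classify_mp_sign(profile, b),
        profile = profile, tp_ids = members, genes = genes)
    }
  }
  for (i in seq_along(mps)) mps[[i]]$mp_id <- sprintf("MP%03d", i)
  list(main_patterns = mps, unclassified_tps = unclassified)
}

#' Sign of a Main Pattern at its time break
#'
#' @param profile MP profile MP(x_1..x_T).
#' @param time_break break stage index.
#' @return `"positive"` if `MP(break) > 0`, `"negative"` if `< 0`,
#'   `"unclassifiable"` when exactly 0.
#' @export
classify_mp_sign <- function(profile, time_break) {
  v <- profile[time_break]
  if (v > 0) "positive" else if (v < 0) "negative" else "unclassifiable"
}
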