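#' Pipeline configuration
#'
#' Collects file paths and all stage-level settings for [run_pipeline()].
#' Every threshold actually used is echoed into the run manifest.
#'
#' @param counts path to a counts TSV (see [read_counts()]).
#' @param gmt path to a GMT annotation file.
#' @param hierarchy optional path to a `child<TAB>parent` TSV; when absent
#'   the pipeline runs in flat-annotation mode.
#' @param category_map optional path to a `term_id/category/kind` TSV;
#'   enrichment is skipped without it.
#' @param exclusion optional path to a gene exclusion list (one id/line).
#' @param out_dir output directory (created if needed).
#' @param stage_order optional stage axis order (first = baseline).
#' @param min_mean_count low-expression filter threshold (default 10).
#' @param alpha selection significance level (default 0.01).
#' @param null_mu,null_sigma optional fixed null parameters overriding
#'   [estimate_null()] (for example the published 1.09 / 0.44).
#' @param min_r2 template-clustering R^2 threshold (default 0.8).
#' @param break_threshold time-break threshold (default 0.2).
#' @param exclusion_stage when to apply the exclusion list:
#'   `"post_selection"` (drop from the seed/candidate lists, default) or
#'   `"pre_filter"` (drop from the input series).
#' @param background enrichment background: `"de"` (selected DE genes,
#'   default) or `"expressed"` (all filtered genes).
#' @param seed integer seed recorded in the manifest (the pipeline itself
#'   is deterministic given its inputs).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts, gmt = NULL, hierarchy = NULL,
                            category_map = NULL, exclusion = NULL,
                            out_dir = ".", stage_order = NULL,
                            min_mean_count = 10, alpha = 0.01,
                            null_mu = NULL, null_sigma = NULL, min_r2 = 0.8,
                            break_threshold = 0.2,
                            exclusion_stage = c("post_selection", "pre_filter"),
                            background = c("de", "expressed"), seed = 1L) {
  structure(list(counts = counts, gmt = gmt, hierarchy = hierarchy,
                 category_map = category_map, exclusion = exclusion,
                 out_dir = out_dir, stage_order = stage_order,
                 min_mean_count = min_mean_count, alpha = alpha,
                 null_mu = null_mu, null_sigma = null_sigma, min_r2 = min_r2,
                 break_threshold = break_threshold,
                 exclusion_stage = match.arg(exclusion_stage),
                 background = match.arg(background), seed = as.integer(seed)),
            class = "pipeline_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full temporal-pattern pipeline
#'
#' Orchestrates read -> (exclude) -> filter -> log2 -> differential
#' profiles -> null fit -> seed/candidate selection -> (exclude) ->
#' function-based pattern search -> time breaks and Main Patterns ->
#' stage-grouped enrichment, writing every stage table plus a JSON run
#' manifest to `config$out_dir`. Deterministic: identical inputs give
#' byte-identical output tables.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with all in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  log_msg <- function(...) message("[patternseq] ", ...)

  series <- read_counts(config$counts, stage_order = config$stage_order)
  n_input <- n_genes(series)
  excl <- if (!is.null(config$exclusion)) read_exclusion(config$exclusion)
          else character(0)
  n_excluded_pre <- 0L
  if (length(excl) && config$exclusion_stage == "pre_filter") {
    before <- n_genes(series)
    series <- apply_exclusion(series, excl)
    n_excluded_pre <- before - n_genes(series)
    log_msg("excluded ", n_excluded_pre, " gene(s) before filtering")
  }

  series <- filter_low_expression(series, config$min_mean_count)
  n_filtered <- n_genes(series)
  log_msg(n_filtered, " of ", n_input, " genes pass the expression filter")

  lg <- log2_transform(series)
  profiles <- differential_profiles(lg)

  null <- if (!is.null(config$null_mu) && !is.null(config$null_sigma)) {
    log_msg("using fixed null parameters (", config$null_mu, ", ",
            config$null_sigma, ")")
    null_model(config$null_mu, config$null_sigma)
  } else estimate_null(lg)

  sel_cfg <- selection_config(alpha = config$alpha)
  selection <- select_genes(profiles, null, sel_cfg)

  n_excluded_post <- 0L
  if (length(excl) && config$exclusion_stage == "post_selection") {
    hit <- selection$gene_id %in% excl & selection$label != "none"
    n_excluded_post <- sum(hit)
    selection$label[selection$gene_id %in% excl] <- "none"
    log_msg("excluded ", n_excluded_post, " selected gene(s) post selection")
  }
  .write_tsv(selection, file.path(config$out_dir, "selection.tsv"))
  n_seeds <- sum(selection$label == "seed")
  n_cands <- sum(selection$label == "candidate")
  log_msg(n_seeds, " seeds, ", n_cands, " candidates")

  annotations <- if (!is.null(config$gmt)) read_gmt(config$gmt) else list()
  hierarchy <- if (!is.null(config$hierarchy)) read_hierarchy(config$hierarchy)
               else NULL
  if (is.null(hierarchy)) log_msg("flat-annotation mode (no hierarchy)")

  clu_cfg <- cluster_config(min_r2 = config$min_r2)
  fp <- find_patterns(selection, profiles, annotations, hierarchy, clu_cfg)
  tp_rows <- tpl_rows <- NULL
  for (p in fp$patterns) {
    tp_rows <- rbind(tp_rows, data.frame(
      term_id = p$term_id, tp_index = p$tp_index, gene_id = p$members,
      is_seed = p$members %in% p$seed_members, stringsAsFactors = FALSE))
    tpl_rows <- rbind(tpl_rows, data.frame(
      term_id = p$term_id, tp_index = p$tp_index,
      stage = colnames(profiles), value = unname(p$template),
      stringsAsFactors = FALSE))
  }
  .write_tsv(tp_rows %||% data.frame(term_id = character(0),
                                     tp_index = integer(0),
                                     gene_id = character(0),
                                     is_seed = logical(0)),
             file.path(config$out_dir, "tps.tsv"))
  .write_tsv(tpl_rows %||% data.frame(term_id = character(0),
                                      tp_index = integer(0),
                                      stage = character(0),
                                      value = numeric(0)),
             file.path(config$out_dir, "tp_templates.tsv"))
  log_msg(length(fp$patterns), " temporal pattern(s), ",
          length(fp$de_genes), " DE gene(s)")

  bcfg <- break_config(threshold = config$break_threshold)
  if (n_stages(series) != 6L) {
    # default grouping is six-stage specific; fall back to thirds
    S <- n_stages(series)
    idx <- 2:S
    thirds <- split(idx, cut(idx, 3, labels = c("embryonic", "nascent",
                                                "older")))
    bcfg <- break_config(threshold = config$break_threshold,
                         grouping = thirds[lengths(thirds) > 0])
  }
  mp <- summarize_main_patterns(fp$patterns, clu_cfg, bcfg)
  mp_rows <- mpp_rows <- mpg_rows <- NULL
  for (m in mp$main_patterns) {
    mp_rows <- rbind(mp_rows, data.frame(
      mp_id = m$mp_id, time_break = m$time_break, sign = m$sign,
      tp_count = length(m$tp_ids), gene_count = length(m$genes),
      stringsAsFactors = FALSE))
    mpp_rows <- rbind(mpp_rows, data.frame(
      mp_id = m$mp_id, stage = colnames(profiles), value = unname(m$profile),
      stringsAsFactors = FALSE))
    mpg_rows <- rbind(mpg_rows, data.frame(
      mp_id = m$mp_id, gene_id = m$genes, stringsAsFactors = FALSE))
  }
  .write_tsv(mp_rows %||% data.frame(mp_id = character(0),
                                     time_break = integer(0),
                                     sign = character(0),
                                     tp_count = integer(0),
                                     gene_count = integer(0)),
             file.path(config$out_dir, "mps.tsv"))
  .write_tsv(mpp_rows %||% data.frame(mp_id = character(0),
                                      stage = character(0),
                                      value = numeric(0)),
             file.path(config$out_dir, "mp_profiles.tsv"))
  .write_tsv(mpg_rows %||% data.frame(mp_id = character(0),
                                      gene_id = character(0)),
             file.path(config$out_dir, "mp_genes.tsv"))
  log_msg(length(mp$main_patterns), " main pattern(s), ",
          length(mp$unclassified_tps), " unclassified TP(s)")

  enrichment <- NULL
  if (!is.null(config$category_map) && length(mp$main_patterns)) {
    cmap <- read_category_map(config$category_map)
    background <- if (config$background == "de") fp$de_genes
                  else series$genes
    if (length(background)) {
      enrichment <- build_cases(mp$main_patterns, cmap, annotations,
                                background, bcfg)
      .write_tsv(enrichment, file.path(config$out_dir, "enrichment.tsv"))
    }
  }

  manifest <- list(
    config = config[setdiff(names(unclass(config)), NULL)],
    versions = list(patternseq = as.character(utils::packageVersion("patternseq")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    funnel = list(genes_input = n_input,
                  genes_excluded_pre = n_excluded_pre,
                  genes_filtered = n_filtered,
                  seeds = n_seeds, candidates = n_cands,
                  genes_excluded_post = n_excluded_post,
                  de_genes = length(fp$de_genes),
                  tps = length(fp$patterns),
                  mps = length(mp$main_patterns),
                  mp_genes = length(unique(unlist(lapply(mp$main_patterns,
                                                         `[[`, "genes"))))),
    thresholds = list(min_mean_count = config$min_mean_count,
                      alpha = config$alpha,
                      null_mu = null$log_mu, null_sigma = null$log_sigma,
                      min_r2 = config$min_r2,
                      break_threshold = config$break_threshold),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(list(selection = selection, patterns = fp, main = mp,
                 enrichment = enrichment, null = null, manifest = manifest))
}

#' Write a complete synthetic fixture to disk
#'
#' Runs [simulate_counts()] and [simulate_annotations()] and writes counts,
#' truth, GMT, hierarchy, and category-map files into `out_dir`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @return Invisibly, the named file paths.
#' @export
simulate_to_dir <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_counts(config)
  ann <- simulate_annotations(config, sim$truth)
  paths <- list(counts = file.path(out_dir, "counts.tsv"),
                truth = file.path(out_dir, "truth.tsv"),
                gmt = file.path(out_dir, "annotations.gmt"),
                hierarchy = file.path(out_dir, "hierarchy.tsv"),
                category_map = file.path(out_dir, "categories.tsv"))
  write_counts(sim$series, paths$counts)
  write_truth(sim$truth, paths$truth)
  write_gmt(ann$annotations, paths$gmt)
  write_hierarchy(ann$hierarchy, paths$hierarchy)
  write_category_map(ann$categories, paths$category_map)
  invisible(paths)
}
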