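#' Write and read staged count tables
#'
#' Counts TSV layout: a `gene_id` column followed by one column per
#' stage/replicate named `<stage>_<rep>` (the stage label is everything
#' before the last underscore). Reading is independent of column order;
#' duplicate gene ids and ragged rows are rejected with informative errors.
#'
#' @param series a [stage_series()].
#' @param path file path.
#' @export
write_counts <- function(series, path) {
  stopifnot(is_stage_series(series))
  v <- series$values
  R <- dim(v)[3L]
  cols <- list(gene_id = series$genes)
  for (s in seq_along(series$stages)) {
    for (r in seq_len(R)) {
      cols[[paste0(series$stages[s], "_", r)]] <- v[, s, r]
    }
  }
  df <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @param stage_order optional character vector fixing the stage axis order
#'   (first = baseline); defaults to order of first appearance in the header.
#' @param scale scale tag of the values (default `"count"`).
#' @return `read_counts` returns a [stage_series()].
#' @export
read_counts <- function(path, stage_order = NULL, scale = "count") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, fill = FALSE)
  if (!"gene_id" %in% names(df)) stop("counts file must have a gene_id column")
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene id in counts file: ",
         df$gene_id[duplicated(df$gene_id)][1L])
  value_cols <- setdiff(names(df), "gene_id")
  if (!length(value_cols)) stop("counts file has no value columns")
  if (!all(grepl("_", value_cols)))
    stop("value columns must be named <stage>_<rep>: ",
         value_cols[!grepl("_", value_cols)][1L])
  stg <- sub("_[^_]*$", "", value_cols)
  if (is.null(stage_order)) stage_order <- unique(stg)
  if (!all(stg %in% stage_order))
    stop("unknown stage label in counts header: ",
         setdiff(stg, stage_order)[1L])
  G <- nrow(df)
  R <- max(table(stg))
  arr <- array(NA_real_, dim = c(G, length(stage_order), R))
  fill_idx <- stats::setNames(rep(0L, length(stage_order)), stage_order)
  for (j in seq_along(value_cols)) {
    s <- match(stg[j], stage_order)
    fill_idx[s] <- fill_idx[s] + 1L
    x <- df[[value_cols[j]]]
    if (!is.numeric(x)) stop("non-numeric values in column ", value_cols[j])
    arr[, s, fill_idx[s]] <- x
  }
  stage_series(arr, df$gene_id, stage_order, scale = scale)
}

#' Gene-set (GMT) files
#'
#' Standard GMT: one term per line, `term<TAB>description<TAB>gene...`.
#'
#' @param annotations named list term id -> character gene ids.
#' @param path file path.
#' @export
write_gmt <- function(annotations, path) {
  lines <- vapply(names(annotations), function(t)
    paste(c(t, t, annotations[[t]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @return `read_gmt` returns a named list term id -> gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": need term, description, >=1 gene")
    out[[f[1L]]] <- unique(f[-(1:2)])
  }
  out
}

#' Term hierarchy, category map, exclusion list, and truth tables
#'
#' Plain TSV helpers: the hierarchy is a `child<TAB>parent` edge table, the
#' category map has columns `term_id`, `category`, `kind`, the exclusion
#' list is one gene id per line, and the truth table is the planted ground
#' truth of [simulate_counts()].
#'
#' @param hierarchy data.frame `child`, `parent`.
#' @param path file path.
#' @export
write_hierarchy <- function(hierarchy, path) {
  utils::write.table(hierarchy[, c("child", "parent")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hierarchy
#' @export
read_hierarchy <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, fill = FALSE)
  if (!all(c("child", "parent") %in% names(df)))
    stop("hierarchy file needs child and parent columns")
  df[, c("child", "parent")]
}

#' @rdname write_hierarchy
#' @param categories data.frame `term_id`, `category`, `kind`.
#' @export
write_category_map <- function(categories, path) {
  utils::write.table(categories[, c("term_id", "category", "kind")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hierarchy
#' @export
read_category_map <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, fill = FALSE)
  need <- c("term_id", "category", "kind")
  if (!all(need %in% names(df)))
    stop("category map needs term_id, category, kind columns")
  dup <- duplicated(df[, c("term_id", "kind")])
  if (any(dup))
    stop("term mapped to more than one category of the same kind: ",
         df$term_id[dup][1L])
  df[, need]
}

#' @rdname write_hierarchy
#' @export
read_exclusion <- function(path) {
  x <- readLines(path)
  unique(x[nzchar(trimws(x))])
}

#' @rdname write_hierarchy
#' @param truth truth data.frame from [simulate_counts()].
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hierarchy
#' @export
read_truth <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    fill = FALSE)
}

#' Remove a user-supplied exclusion list from a series
#'
#' Listed genes (for example known contaminants from a neighboring cell
#' population) are dropped; ids not present in the series produce a warning
#' but no error. An empty list is the identity.
#'
#' @param series a [stage_series()].
#' @param exclusion character vector of gene ids to remove.
#' @return The filtered series.
#' @export
apply_exclusion <- function(series, exclusion) {
  stopifnot(is_stage_series(series))
  exclusion <- unique(exclusion)
  if (!length(exclusion)) return(series)
  missing <- setdiff(exclusion, series$genes)
  if (length(missing))
    warning(length(missing), " exclusion id(s) not present, e.g. ",
            missing[1L])
  keep <- !(series$genes %in% exclusion)
  subset_genes(series, keep)
}
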