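# Result-page artifacts: summary table, gene-annotation table, basic query
# summary, annotation-coverage statistics and bar-chart data. All outputs
# are TSV/plain text with deterministic ordering.

#' Build the enrichment summary table
#'
#' The six-column display of enriched sets: set name, brief description,
#' category, overlap count, raw and adjusted p-value — filtered at the
#' cut-off and sorted by adjusted p (ties: larger overlap, then name).
#'
#' @param res An adjusted `ora_result`.
#' @param cutoff Adjusted-p cut-off (see [select_significant()]).
#' @return data.frame with columns `set_name`, `description`, `category`,
#'   `overlap`, `p_raw`, `p_adjusted`.
#' @export
build_summary <- function(res, cutoff = 0.05) {
  sel <- select_significant(res, cutoff)
  data.frame(set_name = sel$set_name, description = sel$description,
             category = sel$category, overlap = sel$k, p_raw = sel$p_raw,
             p_adjusted = sel$p_adjusted, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write the summary table as TSV
#'
#' @param summary A [build_summary()] data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_summary <- function(summary, path) {
  out <- summary
  out$p_raw <- format_pval(out$p_raw)
  out$p_adjusted <- format_pval(out$p_adjusted)
  write_tsv_det(out, path)
}

#' Build the gene-set annotation table for the query
#'
#' One row per non-redundant query gene listing every gene set of the full
#' collection that contains it (not only significant sets), with the sets'
#' categories — the gene-centric view of the result page.
#'
#' @param query Character vector of query gene IDs.
#' @param collection A `GeneSetCollection`.
#' @return data.frame with columns `gene`, `n_sets`, `sets` and
#'   `categories` (both `;`-joined, aligned), genes in first-seen query
#'   order; genes in no set keep an empty `sets` field.
#' @export
build_annotation <- function(query, collection) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  query <- unique(trim_ids(as.character(query)))
  set_names <- vapply(collection$sets, function(s) s$name, character(1L))
  set_cats <- vapply(collection$sets, function(s) s$category, character(1L))
  rows <- lapply(query, function(g) {
    hit <- vapply(collection$sets, function(s) g %in% s$members, logical(1L))
    data.frame(gene = g, n_sets = sum(hit),
               sets = paste(set_names[hit], collapse = ";"),
               categories = paste(set_cats[hit], collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(gene = character(), n_sets = integer(),
                      sets = character(), categories = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Basic query summary text
#'
#' The pre-analysis report: how many IDs were submitted, how many were
#' non-redundant, which were dropped for falling outside the background,
#' and which categories were analyzed.
#'
#' @param audit A [query_audit()].
#' @param categories Categories selected for the run.
#' @return Character vector of report lines.
#' @export
basic_summary <- function(audit, categories = GSORA_CATEGORIES) {
  stopifnot(inherits(audit, "QueryAudit"))
  dropped <- audit$dropped_not_in_background
  c(sprintf("Submitted IDs:            %d", audit$raw_count),
    sprintf("Non-redundant IDs:        %d", length(audit$nonredundant)),
    sprintf("Redundant IDs removed:    %d",
            audit$raw_count - length(audit$nonredundant)),
    sprintf("Dropped (not in background): %d", length(dropped)),
    if (length(dropped)) paste0("  ", sort(dropped)) else NULL,
    sprintf("Categories analyzed:      %s", paste(categories, collapse = ", ")))
}

#' Annotation coverage of a background
#'
#' For each category, the fraction of background genes belonging to at
#' least one set of that category; overall coverage uses the union across
#' categories. Aggregating sets from diverse sources raises this coverage
#' well beyond what a single annotation system provides, which is the
#' rationale for a multi-category collection.
#'
#' @param collection A `GeneSetCollection`.
#' @param bg A [background()].
#' @param categories Categories to report (default: all four).
#' @return A data.frame with columns `category` (including an `"overall"`
#'   row), `annotated`, `background`, `percent` (full precision; round for
#'   display).
#' @export
coverage <- function(collection, bg, categories = GSORA_CATEGORIES) {
  stopifnot(inherits(collection, "GeneSetCollection"),
            inherits(bg, "Background"))
  bad <- setdiff(categories, GSORA_CATEGORIES)
  if (length(bad)) stop("unknown categor(ies): ", paste(bad, collapse = ", "))
  nbg <- length(bg$genes)
  cover_of <- function(cats) {
    keep <- vapply(collection$sets, function(s) s$category %in% cats,
                   logical(1L))
    genes <- unique(unlist(lapply(collection$sets[keep],
                                  function(s) s$members), use.names = FALSE))
    length(intersect(genes, bg$genes))
  }
  ann <- vapply(categories, cover_of, integer(1L))
  overall <- cover_of(categories)
  data.frame(category = c(categories, "overall"),
             annotated = c(ann, overall),
             background = nbg,
             percent = 100 * c(ann, overall) / nbg,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bar-chart data for significant sets
#'
#' Top-k sets per category among the significant results, with the
#' log10-converted adjusted p-value used as bar height. Adjusted p-values
#' of exactly 0 (possible only through floating-point underflow) are
#' floored at 1e-300 to keep the chart finite.
#'
#' @param res An adjusted `ora_result`.
#' @param top_k Sets kept per category.
#' @param cutoff Significance cut-off.
#' @return data.frame with columns `set_name`, `category`,
#'   `neg_log10_p_adjusted`, in [select_significant()] order.
#' @export
bar_chart_data <- function(res, top_k = 10L, cutoff = 0.05) {
  sel <- select_significant(res, cutoff)
  keep <- unlist(lapply(split(seq_len(nrow(sel)), sel$category),
                        function(idx) head(idx, top_k)), use.names = FALSE)
  sel <- sel[sort(keep), , drop = FALSE]
  data.frame(set_name = sel$set_name, category = sel$category,
             neg_log10_p_adjusted = -log10(pmax(sel$p_adjusted, 1e-300)),
             stringsAsFactors = FALSE, row.names = NULL)
}
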