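# Format conversion among gene locus, gene symbol and microarray probe-set
# identifiers. Relations are many-to-many in both directions (one probe set
# can measure several loci and vice versa); conversions keep every target,
# since arbitrating would silently bias enrichment counts.

ID_KINDS <- c("locus", "symbol", "probe")

#' Read an identifier mapping table
#'
#' TSV with a header from `{locus, symbol, probe}` (at least `locus`);
#' blank cells mark missing relations; fully duplicated rows are collapsed.
#'
#' @param path Path to the TSV.
#' @return An `IdMappingTable`: data.frame with columns `locus`, `symbol`,
#'   `probe` (`NA` where absent).
#' @export
read_mapping <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   check.names = FALSE, na.strings = NULL)
  id_mapping_table(df)
}

#' Construct an identifier mapping table
#'
#' @param df data.frame with columns from `{locus, symbol, probe}`; `locus`
#'   is required and must be non-empty in every row.
#' @return An `IdMappingTable`.
#' @export
id_mapping_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"locus" %in% names(df)) stop("mapping table must have a 'locus' column")
  extra <- setdiff(names(df), ID_KINDS)
  if (length(extra)) stop("unknown mapping column(s): ", paste(extra, collapse = ", "))
  for (col in setdiff(ID_KINDS, names(df))) df[[col]] <- NA_character_
  df <- df[, ID_KINDS, drop = FALSE]
  for (col in ID_KINDS) {
    df[[col]] <- trimws(as.character(df[[col]]))
    df[[col]][!nzchar(df[[col]]) | is.na(df[[col]])] <- NA_character_
  }
  if (anyNA(df$locus)) stop("every mapping row needs a non-empty locus")
  df <- unique(df)
  rownames(df) <- NULL
  class(df) <- c("IdMappingTable", "data.frame")
  df
}

#' Write an identifier mapping table
#'
#' @param table An `IdMappingTable`.
#' @param path Output path (TSV, deterministic row order).
#' @return Invisibly, `path`.
#' @export
write_mapping <- function(table, path) {
  stopifnot(inherits(table, "IdMappingTable"))
  df <- as.data.frame(table)
  df <- df[order(df$locus, df$symbol, df$probe, method = "radix",
                 na.last = TRUE), , drop = FALSE]
  write_tsv_det(df, path)
}

#' Convert identifiers between ID kinds
#'
#' Each input ID is joined against the mapping table; all targets are kept
#' (one-to-many relations are flagged, never collapsed). Unmapped IDs are
#' data, not an error.
#'
#' @param ids Character vector of input IDs.
#' @param from,to ID kinds, each one of `"locus"`, `"symbol"`, `"probe"`;
#'   must differ.
#' @param table An `IdMappingTable`.
#' @return A `ConversionReport`: list with `per_id` (data.frame: `id`,
#'   `n_targets`, `targets` list-column, `unmapped`, `one_to_many`) and
#'   `mapped` (flat deduplicated target list, first-seen order).
#' @export
convert_ids <- function(ids, from, to, table) {
  from <- match.arg(from, ID_KINDS)
  to <- match.arg(to, ID_KINDS)
  if (from == to) stop("'from' and 'to' must differ")
  stopifnot(inherits(table, "IdMappingTable"))
  ids <- unique(trim_ids(as.character(ids)))
  targets <- lapply(ids, function(id) {
    hit <- table[[to]][!is.na(table[[from]]) & table[[from]] == id]
    sort(unique(hit[!is.na(hit)]))
  })
  per_id <- data.frame(id = ids,
                       n_targets = lengths(targets),
                       unmapped = lengths(targets) == 0L,
                       one_to_many = lengths(targets) > 1L,
                       stringsAsFactors = FALSE)
  per_id$targets <- targets
  structure(list(per_id = per_id,
                 mapped = unique(unlist(targets, use.names = FALSE)) %||% character(),
                 from = from, to = to),
            class = "ConversionReport")
}

#' @export
print.ConversionReport <- function(x, ...) {
  cat(sprintf("ConversionReport %s -> %s: %d input IDs, %d mapped targets, %d unmapped, %d one-to-many\n",
              x$from, x$to, nrow(x$per_id), length(x$mapped),
              sum(x$per_id$unmapped), sum(x$per_id$one_to_many)))
  invisible(x)
}

# Advisory heuristic: Affymetrix probe-set IDs end in "_at" (with optional
# s/x/a qualifiers). A declared ID type always wins.
detect_id_type <- function(ids) {
  probe_like <- grepl("_[asx]?_?at$|_at$", ids)
  if (all(probe_like)) "probe" else if (!any(probe_like)) "locus" else "mixed"
}

#' Resolve a query list to gene loci
#'
#' Enrichment always runs in locus space: probe-set queries are expanded to
#' all their loci first (keeping every target of a multi-locus probe). The
#' ID kind is auto-detected from the `_at` probe suffix unless declared;
#' mixed-looking input without a declaration is an error.
#'
#' @param query Character vector of query IDs.
#' @param table An `IdMappingTable` (may be `NULL` for declared/detected
#'   locus input).
#' @param id_type `"auto"` (default), `"locus"`, `"probe"` or `"symbol"`.
#' @return List with `loci` (deduplicated, first-seen order) and `audit`
#'   (list: `id_type`, `n_input`, `n_loci`, `n_unmapped`, `n_one_to_many`).
#' @export
query_to_locus <- function(query, table = NULL,
                           id_type = c("auto", "locus", "probe", "symbol")) {
  id_type <- match.arg(id_type)
  query <- unique(trim_ids(as.character(query)))
  if (id_type == "auto") {
    id_type <- detect_id_type(query)
    if (id_type == "mixed") {
      stop("query mixes probe-like and locus-like IDs; declare the type ",
           "explicitly with id_type = 'locus' or 'probe' (--id-type on the CLI)")
    }
  }
  if (id_type == "locus") {
    return(list(loci = query,
                audit = list(id_type = "locus", n_input = length(query),
                             n_loci = length(query), n_unmapped = 0L,
                             n_one_to_many = 0L)))
  }
  if (is.null(table)) stop("a mapping table is required to convert ", id_type,
                           " IDs to loci")
  rep <- convert_ids(query, from = id_type, to = "locus", table = table)
  if (length(rep$mapped) == 0L) {
    stop("none of the ", length(query), " ", id_type, " IDs mapped to a ",
         "locus; check that the mapping table matches the array/organism")
  }
  list(loci = rep$mapped,
       audit = list(id_type = id_type, n_input = length(query),
                    n_loci = length(rep$mapped),
                    n_unmapped = sum(rep$per_id$unmapped),
                    n_one_to_many = sum(rep$per_id$one_to_many)))
}
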