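# Gene-set containers and GMT interchange.

#' Construct a gene set
#'
#' A named collection of gene identifiers sharing an annotation: a GO term's
#' propagated genes, a gene family, a literature-derived signature or a motif
#' target group.
#'
#' @param name Non-empty set identifier, unique within a collection.
#' @param description Free-text description.
#' @param members Character vector of gene IDs; deduplicated, must be
#'   non-empty. IDs are case-sensitive and whitespace-stripped.
#' @param category One of `geneset_categories()`.
#' @param provenance Optional named list (e.g. `author`, `pubmed_id`,
#'   `source_db`, `url`).
#' @return A `GeneSet` object.
#' @export
#' @examples
#' gene_set("LEE_COLD_UP", "cold-induced genes", c("AT1G01000", "AT1G02000"))
gene_set <- function(name, description = "", members, category = "Curated",
                     provenance = NULL) {
  name <- trimws(name)
  if (!nzchar(name)) stop("gene set name must be non-empty")
  category <- match.arg(category, GSORA_CATEGORIES)
  members <- unique(trim_ids(as.character(members)))
  if (length(members) == 0L) stop("gene set '", name, "' has no members")
  structure(
    list(name = name, description = as.character(description)[1L],
         category = category, members = members, provenance = provenance),
    class = "GeneSet"
  )
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s' [%s], %d members: %s%s\n",
              x$name, x$category, length(x$members),
              paste(head(x$members, 5L), collapse = ", "),
              if (length(x$members) > 5L) ", ..." else ""))
  invisible(x)
}

#' Construct a gene-set collection
#'
#' @param sets List of [gene_set()] objects; names must be unique.
#' @param organism Free-text organism label.
#' @return A `GeneSetCollection`. The gene universe (union of all members)
#'   is available via [collection_universe()], so it can never drift from
#'   the member sets.
#' @export
gene_set_collection <- function(sets = list(), organism = "unspecified") {
  stopifnot(is.list(sets))
  for (s in sets) {
    if (!inherits(s, "GeneSet")) stop("all elements must be GeneSet objects")
  }
  nm <- vapply(sets, function(s) s$name, character(1L))
  dup <- nm[duplicated(nm)]
  if (length(dup)) {
    stop("duplicate gene set name(s): ", paste(unique(dup), collapse = ", "))
  }
  names(sets) <- nm
  structure(list(organism = organism, sets = sets),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cats <- table(factor(vapply(x$sets, function(s) s$category, character(1L)),
                       levels = GSORA_CATEGORIES))
  cat(sprintf("GeneSetCollection (%s): %d sets, %d genes in universe\n",
              x$organism, length(x$sets), length(collection_universe(x))))
  cat("  ", paste(sprintf("%s=%d", names(cats), as.integer(cats)),
                  collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' Universe of a collection
#'
#' @param collection A `GeneSetCollection`.
#' @return Character vector: the union of all member sets (sorted).
#' @export
collection_universe <- function(collection) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  sort(unique(unlist(lapply(collection$sets, function(s) s$members),
                     use.names = FALSE)))
}

#' Subset a collection by category
#'
#' @param collection A `GeneSetCollection`.
#' @param categories Character vector, subset of `geneset_categories()`.
#' @return A `GeneSetCollection` with only the matching sets.
#' @export
filter_categories <- function(collection, categories) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  bad <- setdiff(categories, GSORA_CATEGORIES)
  if (length(bad)) stop("unknown categor(ies): ", paste(bad, collapse = ", "))
  keep <- vapply(collection$sets, function(s) s$category %in% categories,
                 logical(1L))
  gene_set_collection(collection$sets[keep], organism = collection$organism)
}

#' Construct an analysis background
#'
#' The reference gene population against which enrichment is judged: either
#' a precomputed whole-genome list or a user-supplied custom background.
#'
#' @param genes Character vector of gene IDs (deduplicated; must be
#'   non-empty).
#' @param source `"precomputed_genome"` or `"user_supplied"`.
#' @return A `Background` object.
#' @export
background <- function(genes, source = c("precomputed_genome",
                                         "user_supplied")) {
  source <- match.arg(source)
  genes <- unique(trim_ids(as.character(genes)))
  if (length(genes) == 0L) stop("background must contain at least one gene")
  structure(list(genes = genes, source = source), class = "Background")
}

#' @export
print.Background <- function(x, ...) {
  cat(sprintf("Background (%s): %d genes\n", x$source, length(x$genes)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Broad-style GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate member IDs
#' within a line are collapsed; duplicate set names are an error.
#'
#' @param path Path to a GMT file.
#' @param organism Organism label for the collection.
#' @param category Default category assigned to every set (override per set
#'   with [attach_metadata()]).
#' @return A `GeneSetCollection`.
#' @export
read_gmt <- function(path, organism = "unspecified", category = "Curated") {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    fields <- trimws(fields)
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (length(fields) < 3L || length(members) == 0L) {
      stop(sprintf("malformed GMT line %d in %s: need name, description and >=1 member",
                   i, path))
    }
    sets[[i]] <- gene_set(fields[[1L]], fields[[2L]], members,
                          category = category)
  }
  gene_set_collection(sets, organism = organism)
}

#' Write a GMT gene-set file
#'
#' One tab-separated line per set with members in sorted order, so output is
#' deterministic and `read_gmt(write_gmt(x))` reproduces member sets exactly.
#'
#' @param collection A `GeneSetCollection`.
#' @param path Output path. UTF-8, Unix newlines.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  lines <- vapply(collection$sets, function(s) {
    paste(c(s$name, s$description, sort(s$members)), collapse = "\t")
  }, character(1L))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Attach provenance metadata from a sidecar TSV
#'
#' The sidecar carries per-set provenance (category, PubMed ID, author,
#' source database, URL) keyed by set name, keeping the GMT file itself
#' interchange-clean. Sidecar rows naming sets absent from the collection
#' are reported as a warning.
#'
#' @param collection A `GeneSetCollection`.
#' @param sidecar Path to a TSV with header columns `name` plus any of
#'   `category`, `pubmed_id`, `author`, `source_db`, `url` (blank cells
#'   allowed).
#' @return The updated `GeneSetCollection`.
#' @export
attach_metadata <- function(collection, sidecar) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  meta <- read.delim(sidecar, sep = "\t", header = TRUE,
                     colClasses = "character", check.names = FALSE,
                     na.strings = NULL)
  if (nrow(meta) == 0L) return(collection)
  if (!"name" %in% names(meta)) stop("sidecar must have a 'name' column")
  if ("category" %in% names(meta)) {
    bad <- setdiff(setdiff(unique(trimws(meta$category)), ""),
                   GSORA_CATEGORIES)
    if (length(bad)) {
      stop("sidecar category outside {", paste(GSORA_CATEGORIES, collapse = ", "),
           "}: ", paste(bad, collapse = ", "))
    }
  }
  unmatched <- 0L
  prov_cols <- intersect(c("pubmed_id", "author", "source_db", "url"),
                         names(meta))
  for (i in seq_len(nrow(meta))) {
    nm <- trimws(meta$name[[i]])
    s <- collection$sets[[nm]]
    if (is.null(s)) {
      unmatched <- unmatched + 1L
      next
    }
    if ("category" %in% names(meta) && nzchar(trimws(meta$category[[i]]))) {
      s$category <- trimws(meta$category[[i]])
    }
    prov <- as.list(meta[i, prov_cols, drop = FALSE])
    prov <- prov[vapply(prov, function(v) nzchar(trimws(v)), logical(1L))]
    if (length(prov)) s$provenance <- utils::modifyList(s$provenance %||% list(),
                                                        lapply(prov, trimws))
    collection$sets[[nm]] <- s
  }
  if (unmatched > 0L) {
    warning(sprintf("%d sidecar row(s) name sets absent from the collection",
                    unmatched))
  }
  collection
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical curated-set name
#'
#' Literature-derived sets are named `AUTHOR_DESCRIPTION[_UP|_DN]`, starting
#' with the first author's name: uppercase tokens joined by underscores,
#' with runs of non-alphanumeric characters collapsed to a single
#' underscore.
#'
#' @param author First author's surname (non-empty).
#' @param description Short description of the set (non-empty).
#' @param direction Optional `"UP"` or `"DN"` suffix for directional sets.
#' @return The canonical set name.
#' @export
#' @examples
#' make_curated_name("Coudert", "CRL1 crown root development", "UP")
make_curated_name <- function(author, description, direction = NULL) {
  if (!nzchar(trimws(author))) stop("author must be non-empty")
  if (!nzchar(trimws(description))) stop("description must be non-empty")
  if (!is.null(direction)) direction <- match.arg(direction, c("UP", "DN"))
  canon <- function(x) {
    x <- toupper(x)
    x <- gsub("[^A-Z0-9]+", "_", x)
    gsub("^_+|_+$", "", x)
  }
  paste(c(canon(author), canon(description), direction), collapse = "_")
}
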