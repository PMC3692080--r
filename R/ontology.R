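# Ontology DAG handling: OBO subset I/O, true-path annotation propagation,
# and enriched-term hierarchy export as Graphviz DOT.

#' Construct an ontology graph
#'
#' A directed acyclic graph of terms with child-to-parent `is_a` / `part_of`
#' edges, as distributed for the Gene Ontology and Plant Ontology.
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`.
#' @param edges data.frame with columns `child`, `parent`, `relation`
#'   (values `is_a` or `part_of`). Endpoints must exist in `terms`.
#' @return An `OntologyGraph`.
#' @export
ontology_graph <- function(terms, edges) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)))
  if (nrow(edges) == 0L) {
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("child", "parent", "relation") %in% names(edges)))
  if (anyDuplicated(terms$id)) stop("duplicate term id(s)")
  dangling <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(dangling)) {
    stop("edge endpoint(s) not in term set: ",
         paste(head(dangling, 5L), collapse = ", "))
  }
  g <- structure(list(terms = terms[order(terms$id), , drop = FALSE],
                      edges = edges), class = "OntologyGraph")
  cyc <- find_cycle_member(g)
  if (!is.null(cyc)) stop("ontology graph contains a cycle through term ", cyc)
  g
}

# igraph object with edges child -> parent; vertex order = sorted term ids.
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("child", "parent"), drop = FALSE],
    directed = TRUE, vertices = graph$terms$id)
}

find_cycle_member <- function(graph) {
  if (nrow(graph$edges) == 0L) return(NULL)
  ig <- igraph::graph_from_data_frame(
    graph$edges[, c("child", "parent"), drop = FALSE],
    directed = TRUE, vertices = graph$terms$id)
  if (igraph::is_dag(ig)) return(NULL)
  # a vertex on some cycle: any vertex reachable from itself via >=1 edge
  for (v in graph$terms$id) {
    reach <- names(igraph::subcomponent(ig, v, mode = "out"))
    preds <- graph$edges$child[graph$edges$parent == v]
    if (v %in% graph$edges$parent && any(preds %in% reach)) return(v)
    if (any(graph$edges$child == v & graph$edges$parent == v)) return(v)
  }
  graph$terms$id[[1L]]
}

#' @export
print.OntologyGraph <- function(x, ...) {
  cat(sprintf("OntologyGraph: %d terms, %d edges, roots: %s\n",
              nrow(x$terms), nrow(x$edges),
              paste(ontology_roots(x), collapse = ", ")))
  invisible(x)
}

#' Root terms of an ontology graph
#'
#' @param graph An `OntologyGraph`.
#' @return Character vector of term IDs with no parent.
#' @export
ontology_roots <- function(graph) {
  stopifnot(inherits(graph, "OntologyGraph"))
  sort(setdiff(graph$terms$id, graph$edges$child))
}

#' Read an OBO 1.2 subset
#'
#' Parses `[Term]` stanzas with `id`, `name`, optional `namespace`, `is_a`
#' and `relationship: part_of` tags. Obsolete terms are excluded.
#' Relationship types other than `part_of` are ignored with a warning (only
#' `is_a` and `part_of` participate in true-path propagation).
#'
#' @param path Path to an OBO file.
#' @return An `OntologyGraph`.
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  in_term <- FALSE
  terms <- list()
  cur <- NULL
  ignored_rel <- character()
  flush_term <- function(cur, terms) {
    if (is.null(cur) || isTRUE(cur$obsolete)) return(terms)
    if (is.null(cur$id)) stop("OBO [Term] stanza without an id")
    terms[[cur$id]] <- cur
    terms
  }
  for (line in lines) {
    if (startsWith(line, "[")) {
      terms <- flush_term(cur, terms)
      cur <- NULL
      in_term <- identical(line, "[Term]")
      if (in_term) cur <- list(name = "", namespace = "", parents = character(),
                               relations = character(), obsolete = FALSE)
      next
    }
    if (!in_term || !nzchar(line)) next
    kv <- regmatches(line, regexpr("^[a-z_]+:", line))
    if (!length(kv)) next
    key <- sub(":$", "", kv)
    val <- trimws(sub("^[a-z_]+:", "", line))
    val <- trimws(sub("!.*$", "", val))  # strip trailing "! label" comments
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_obsolete") cur$obsolete <- identical(val, "true")
    else if (key == "is_a") {
      cur$parents <- c(cur$parents, val)
      cur$relations <- c(cur$relations, "is_a")
    } else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1L]]
      if (length(parts) >= 2L && parts[[1L]] == "part_of") {
        cur$parents <- c(cur$parents, parts[[2L]])
        cur$relations <- c(cur$relations, "part_of")
      } else if (length(parts) >= 1L) {
        ignored_rel <- c(ignored_rel, parts[[1L]])
      }
    }
  }
  terms <- flush_term(cur, terms)
  if (length(ignored_rel)) {
    warning("ignored relationship type(s): ",
            paste(unique(ignored_rel), collapse = ", "))
  }
  ids <- names(terms)
  term_df <- data.frame(
    id = ids,
    name = vapply(terms, function(t) t$name, character(1L)),
    namespace = vapply(terms, function(t) t$namespace, character(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
  edge_list <- lapply(terms, function(t) {
    if (!length(t$parents)) return(NULL)
    data.frame(child = t$id, parent = t$parents, relation = t$relations,
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, c(edge_list, list(NULL)))
  if (is.null(edges)) {
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
  }
  # edges to obsolete/unknown targets are dangling: report as an error
  dangling <- setdiff(unique(edges$parent), ids)
  if (length(dangling)) {
    stop("is_a/part_of target(s) not defined as non-obsolete terms: ",
         paste(head(dangling, 5L), collapse = ", "))
  }
  ontology_graph(term_df, edges)
}

#' Write an ontology graph as an OBO 1.2 subset
#'
#' Terms are emitted in sorted ID order with their `is_a` and
#' `relationship: part_of` tags, so output is deterministic and
#' `read_obo(write_obo(g))` reproduces the graph.
#'
#' @param graph An `OntologyGraph`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_obo <- function(graph, path) {
  stopifnot(inherits(graph, "OntologyGraph"))
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(graph$terms))) {
    id <- graph$terms$id[[i]]
    stanza <- c("[Term]",
                paste0("id: ", id),
                paste0("name: ", graph$terms$name[[i]]))
    if (nzchar(graph$terms$namespace[[i]])) {
      stanza <- c(stanza, paste0("namespace: ", graph$terms$namespace[[i]]))
    }
    e <- graph$edges[graph$edges$child == id, , drop = FALSE]
    e <- e[order(e$parent), , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      stanza <- c(stanza, if (e$relation[[j]] == "is_a") {
        paste0("is_a: ", e$parent[[j]])
      } else {
        paste0("relationship: part_of ", e$parent[[j]])
      })
    }
    out <- c(out, stanza, "")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a two-column gene-to-term annotation TSV
#'
#' Columns `gene`, `term`; a header row is auto-detected by a first cell
#' equal to `gene`. Pairs are deduplicated.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `gene` and `term`.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && startsWith(tolower(lines[[1L]]), "gene")) {
    lines <- lines[-1L]
  }
  if (!length(lines)) {
    return(data.frame(gene = character(), term = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) stop("annotation line ", bad[[1L]], " has fewer than 2 fields")
  ann <- data.frame(gene = trimws(vapply(parts, `[[`, character(1L), 1L)),
                    term = trimws(vapply(parts, `[[`, character(1L), 2L)),
                    stringsAsFactors = FALSE)
  unique(ann)
}

#' Propagate direct annotations up the ontology (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to all of that term's
#' ancestors, so every term's gene set is the union of direct annotations
#' over the term and its descendants. One gene set is produced per term
#' with at least one gene after propagation; propagation follows `is_a` and
#' `part_of` edges and never crosses namespaces (ontology roots are
#' disjoint).
#'
#' @param graph An `OntologyGraph`.
#' @param annotations data.frame with columns `gene`, `term` (direct
#'   annotations), e.g. from [read_annotations()].
#' @param unknown_terms Annotations to terms absent from the graph are
#'   skipped with a warning (`"warn"`, default) or raise an error
#'   (`"error"`).
#' @param organism Organism label for the resulting collection.
#' @return A `GeneSetCollection` of category-`GO` sets, named by term ID
#'   with the term name as description.
#' @export
propagate_annotations <- function(graph, annotations,
                                  unknown_terms = c("warn", "error"),
                                  organism = "unspecified") {
  stopifnot(inherits(graph, "OntologyGraph"))
  unknown_terms <- match.arg(unknown_terms)
  annotations <- unique(as.data.frame(annotations,
                                      stringsAsFactors = FALSE)[, c("gene", "term")])
  unknown <- setdiff(unique(annotations$term), graph$terms$id)
  if (length(unknown)) {
    msg <- paste0(length(unknown), " annotation term(s) absent from the graph: ",
                  paste(head(unknown, 5L), collapse = ", "))
    if (unknown_terms == "error") stop(msg)
    warning(msg, "; their annotations were skipped")
    annotations <- annotations[!annotations$term %in% unknown, , drop = FALSE]
  }
  ids <- graph$terms$id
  members <- setNames(vector("list", length(ids)), ids)
  direct <- split(annotations$gene, annotations$term)
  for (t in names(direct)) members[[t]] <- unique(direct[[t]])
  if (nrow(graph$edges)) {
    ig <- as_igraph(graph)
    # children precede parents in topological order of child->parent edges,
    # so one sweep accumulates each term's genes into all its ancestors
    topo <- names(igraph::topo_sort(ig, mode = "out"))
    parents <- split(graph$edges$parent, graph$edges$child)
    for (t in topo) {
      if (is.null(members[[t]])) next
      for (p in parents[[t]]) {
        members[[p]] <- unique(c(members[[p]], members[[t]]))
      }
    }
  }
  keep <- ids[!vapply(members, is.null, logical(1L))]
  name_of <- setNames(graph$terms$name, graph$terms$id)
  sets <- lapply(keep, function(t) {
    gene_set(t, name_of[[t]], members[[t]], category = "GO")
  })
  gene_set_collection(sets, organism = organism)
}

#' Induced subgraph of significant terms and their ancestors
#'
#' For hierarchy charts: takes the significantly enriched terms and returns
#' the induced graph over those terms plus every ancestor, so the chart
#' shows each enriched term in its ontological context. Ancestors that are
#' not themselves significant carry `NA` significance ("ancestor-only").
#'
#' @param graph An `OntologyGraph`.
#' @param significant data.frame with columns `term`, `p_adjusted` (or a
#'   named numeric vector of adjusted p-values). All terms must be in the
#'   graph. Empty input yields an empty subgraph.
#' @return An `OntologySubgraph`: list with `terms` (id, name, namespace,
#'   p_adjusted) and `edges` restricted to the node set.
#' @export
enriched_subgraph <- function(graph, significant) {
  stopifnot(inherits(graph, "OntologyGraph"))
  if (is.numeric(significant)) {
    significant <- data.frame(term = names(significant),
                              p_adjusted = unname(significant),
                              stringsAsFactors = FALSE)
  }
  significant <- as.data.frame(significant, stringsAsFactors = FALSE)
  if (nrow(significant) == 0L) {
    return(structure(list(
      terms = cbind(graph$terms[0L, , drop = FALSE], p_adjusted = numeric()),
      edges = graph$edges[0L, , drop = FALSE]), class = "OntologySubgraph"))
  }
  missing <- setdiff(significant$term, graph$terms$id)
  if (length(missing)) {
    stop("significant term(s) not in graph: ",
         paste(head(missing, 5L), collapse = ", "))
  }
  ig <- as_igraph(graph)
  nodes <- unique(unlist(lapply(significant$term, function(t) {
    names(igraph::subcomponent(ig, t, mode = "out"))
  })))
  nodes <- sort(nodes)
  terms <- graph$terms[graph$terms$id %in% nodes, , drop = FALSE]
  pmap <- setNames(significant$p_adjusted, significant$term)
  terms$p_adjusted <- unname(pmap[terms$id])
  edges <- graph$edges[graph$edges$child %in% nodes &
                         graph$edges$parent %in% nodes, , drop = FALSE]
  structure(list(terms = terms, edges = edges), class = "OntologySubgraph")
}

#' Render an enriched-term hierarchy as Graphviz DOT
#'
#' Emits DOT text (the `dot` layout program's input language); rendering to
#' an image is left to the caller. Nodes are filled by significance bin;
#' ancestor-only nodes are left unfilled. Output is deterministic: nodes
#' and edges are emitted in sorted order, so identical inputs give
#' byte-identical DOT.
#'
#' @param subgraph An `OntologySubgraph` from [enriched_subgraph()].
#' @param bins Increasing adjusted-p bin edges for the color ramp; a node
#'   with `p_adjusted < bins[i]` (smallest such i) gets `colors[i]`.
#' @param colors Fill colors, one per bin, dark to light.
#' @return A single string of DOT source.
#' @export
render_dot <- function(subgraph,
                       bins = c(1e-10, 1e-5, 0.01, 0.05),
                       colors = c("#b2182b", "#ef8a62", "#fddbc7", "#fff7ec")) {
  stopifnot(inherits(subgraph, "OntologySubgraph"))
  if (length(bins) != length(colors)) stop("need one color per bin")
  if (is.unsorted(bins, strictly = TRUE)) stop("bins must be strictly increasing")
  esc <- function(x) gsub('"', '\\\\"', x)
  lines <- c("digraph enrichment_hierarchy {",
             "  rankdir=BT;",
             "  node [shape=box, style=rounded];")
  terms <- subgraph$terms[order(subgraph$terms$id), , drop = FALSE]
  for (i in seq_len(nrow(terms))) {
    p <- terms$p_adjusted[[i]]
    label <- if (is.na(p)) {
      sprintf("%s\\n%s", esc(terms$name[[i]]), esc(terms$id[[i]]))
    } else {
      sprintf("%s\\n%s\\np.adj=%s", esc(terms$name[[i]]), esc(terms$id[[i]]),
              format_pval(p))
    }
    attrs <- sprintf('label="%s"', label)
    if (!is.na(p)) {
      bin <- which(p < bins)
      if (length(bin)) {
        attrs <- paste0(attrs,
                        sprintf(', style="rounded,filled", fillcolor="%s"',
                                colors[[min(bin)]]))
      }
    }
    lines <- c(lines, sprintf('  "%s" [%s];', esc(terms$id[[i]]), attrs))
  }
  edges <- subgraph$edges
  if (nrow(edges)) {
    edges <- edges[order(edges$child, edges$parent), , drop = FALSE]
    style <- ifelse(edges$relation == "part_of", ' [style=dashed]', "")
    lines <- c(lines, sprintf('  "%s" -> "%s"%s;', esc(edges$child),
                              esc(edges$parent), style))
  }
  paste(c(lines, "}", ""), collapse = "\n")
}
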