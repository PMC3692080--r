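test_that("OBO parsing builds edges, drops obsolete terms and flags problems", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: T:A", "name: alpha",
               "namespace: biological_process", "",
               "[Term]", "id: T:B", "name: beta", "is_a: T:A ! alpha", "",
               "[Term]", "id: T:C", "name: gone", "is_obsolete: true", "",
               "[Term]", "id: T:D", "name: delta",
               "relationship: part_of T:A", ""), f)
  g <- expect_silent(read_obo(f))
  expect_setequal(g$terms$id, c("T:A", "T:B", "T:D"))
  expect_identical(ontology_roots(g), "T:A")
  expect_identical(g$edges$relation[g$edges$child == "T:D"], "part_of")
  expect_identical(g$edges$parent[g$edges$child == "T:B"], "T:A")

  # unknown relationship types are ignored with a warning
  writeLines(c("[Term]", "id: T:A", "name: a", "",
               "[Term]", "id: T:B", "name: b",
               "relationship: regulates T:A", ""), f)
  expect_warning(g2 <- read_obo(f), "regulates")
  expect_identical(nrow(g2$edges), 0L)

  # dangling is_a target is an error
  writeLines(c("[Term]", "id: T:B", "name: b", "is_a: T:MISSING", ""), f)
  expect_error(read_obo(f), "T:MISSING")
})

test_that("cycles are rejected, naming a cycle member", {
  terms <- data.frame(id = c("A", "B"), name = c("a", "b"), namespace = "bp")
  edges <- data.frame(child = c("A", "B"), parent = c("B", "A"),
                      relation = "is_a")
  expect_error(ontology_graph(terms, edges), "cycle through term [AB]")
})

test_that("OBO write/read round-trips random synthetic DAGs", {
  for (seed in 1:5) {
    cfg <- sim_config(seed = seed, dag_terms = 50L)
    g <- make_dag(cfg)$graph
    f <- withr::local_tempfile(fileext = ".obo")
    write_obo(g, f)
    back <- read_obo(f)
    expect_identical(back$terms, g$terms)
    key <- function(e) sort(paste(e$child, e$parent, e$relation))
    expect_identical(key(back$edges), key(g$edges))
  }
})

test_that("true-path propagation matches the edge-expansion closure oracle", {
  # hand example: gene on a leaf reaches every ancestor up to the root
  terms <- data.frame(id = c("root", "P", "L"), name = c("r", "p", "l"),
                      namespace = "bp")
  edges <- data.frame(child = c("L", "P"), parent = c("P", "root"),
                      relation = "is_a")
  g <- ontology_graph(terms, edges)
  ann <- data.frame(gene = "g1", term = "L")
  coll <- propagate_annotations(g, ann)
  expect_setequal(names(coll$sets), c("root", "P", "L"))
  for (s in coll$sets) expect_identical(s$members, "g1")
  expect_true(all(vapply(coll$sets, `[[`, character(1L), "category") == "GO"))

  # no annotations -> empty collection
  empty <- propagate_annotations(g, data.frame(gene = character(),
                                               term = character()))
  expect_length(empty, 0L)

  # random DAGs: per-term sets equal the brute-force closure; size
  # monotonicity along every edge; the root covers all annotated genes
  for (seed in 1:8) {
    cfg <- sim_config(seed = seed, dag_terms = 40L, ann_genes = 60L,
                      universe_size = 500L)
    d <- make_dag(cfg)
    coll <- propagate_annotations(d$graph, d$annotations)
    expected <- oracle_propagate(d$graph, d$annotations)
    expect_setequal(names(coll$sets), names(expected))
    for (t in names(expected)) {
      expect_identical(sort(coll$sets[[t]]$members), expected[[t]])
    }
    size_of <- function(t) if (is.null(coll$sets[[t]])) 0L else
      length(coll$sets[[t]]$members)
    for (i in seq_len(nrow(d$graph$edges))) {
      expect_gte(size_of(d$graph$edges$parent[[i]]),
                 size_of(d$graph$edges$child[[i]]))
    }
    root <- ontology_roots(d$graph)[[1L]]
    expect_setequal(coll$sets[[root]]$members, unique(d$annotations$gene))
  }
})

test_that("annotations to unknown terms are skipped with a warning, or error on request", {
  terms <- data.frame(id = "A", name = "a", namespace = "bp")
  g <- ontology_graph(terms, data.frame(child = character(),
                                        parent = character(),
                                        relation = character()))
  ann <- data.frame(gene = c("g1", "g2"), term = c("A", "ZZ"))
  expect_warning(coll <- propagate_annotations(g, ann), "ZZ")
  expect_identical(coll$sets$A$members, "g1")
  expect_error(propagate_annotations(g, ann, unknown_terms = "error"), "ZZ")
})

test_that("enriched subgraph is the ancestor closure of the significant terms", {
  terms <- data.frame(id = c("root", "P", "L", "other"),
                      name = c("r", "p", "l", "o"), namespace = "bp")
  edges <- data.frame(child = c("L", "P", "other"),
                      parent = c("P", "root", "root"), relation = "is_a")
  g <- ontology_graph(terms, edges)

  sub <- enriched_subgraph(g, setNames(1e-6, "L"))
  expect_identical(sub$terms$id, c("L", "P", "root"))
  expect_identical(sub$terms$p_adjusted[sub$terms$id == "L"], 1e-6)
  expect_true(all(is.na(sub$terms$p_adjusted[sub$terms$id != "L"])))
  expect_identical(nrow(sub$edges), 2L)

  expect_identical(enriched_subgraph(g, setNames(0.01, "root"))$terms$id, "root")
  expect_identical(nrow(enriched_subgraph(g, numeric())$terms), 0L)
  expect_error(enriched_subgraph(g, setNames(0.01, "nope")), "nope")

  # random DAG: node set equals the brute-force ancestor closure and always
  # contains every significant term
  for (seed in 1:5) {
    d <- make_dag(sim_config(seed = seed, dag_terms = 60L))
    sub <- withr::with_seed(seed, {
      sig <- sample(d$graph$terms$id, 5L)
      enriched_subgraph(d$graph, setNames(runif(5L, 0, 0.05), sig))
    })
    expect_identical(sort(sub$terms$id), oracle_ancestors(d$graph, sig))
    expect_true(all(sig %in% sub$terms$id))
    expect_true(all(sub$edges$child %in% sub$terms$id &
                      sub$edges$parent %in% sub$terms$id))
  }
})

test_that("DOT output is valid, counts nodes/edges and is deterministic", {
  terms <- data.frame(id = c("root", "P", "L"), name = c("r", "p", "l"),
                      namespace = "bp")
  edges <- data.frame(child = c("L", "P"), parent = c("P", "root"),
                      relation = "is_a")
  g <- ontology_graph(terms, edges)
  sub <- enriched_subgraph(g, setNames(1e-6, "L"))
  dot <- render_dot(sub)
  expect_identical(dot, render_dot(sub))  # byte-identical on repeat
  expect_match(dot, "^digraph")
  lines <- strsplit(dot, "\n")[[1L]]
  expect_length(grep("\\[label=", lines), 3L)
  expect_length(grep("->", lines), 2L)
  # only the significant leaf is filled; ancestor-only nodes stay uncolored
  expect_length(grep("fillcolor", lines), 1L)
  expect_match(grep('"L"', lines, value = TRUE)[[1L]], "fillcolor")

  empty <- render_dot(enriched_subgraph(g, numeric()))
  expect_match(empty, "digraph")
  expect_no_match(empty, "->")
})
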