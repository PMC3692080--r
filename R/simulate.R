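# Seeded synthetic-data generators: gene universes, set collections,
# planted-enrichment queries, random ontology DAGs and ID-mapping tables.
# Every generator is a pure function of a simulation config: one integer
# seed drives a separate named RNG stream per generator, so adding a
# generator never perturbs existing fixtures, and the caller's RNG state is
# always restored.

#' Simulation configuration
#'
#' Parameters of the synthetic study conditions. Defaults emulate a
#' plant-genome-scale enrichment run at desk scale: a 5,000-gene universe,
#' 200 gene sets of 20-100 genes, and a 150-gene query in which half the
#' genes come from one planted set — the shape of a differential-expression
#' list (such as a cold-stress up-regulated list) carrying one strong
#' biological signal.
#'
#' @param seed Integer seed driving all generator streams.
#' @param universe_size Number of genes in the synthetic universe.
#' @param n_sets Number of gene sets.
#' @param set_size_range Length-2 integer vector, min/max set size.
#' @param planted_sets Number of sets the query signal is drawn from.
#' @param query_size Number of query genes.
#' @param signal_fraction Fraction of the query drawn from the planted
#'   sets' union, in `[0, 1]`.
#' @param dag_terms Number of ontology terms in the random DAG.
#' @param dag_max_parents Maximum parents per non-root term.
#' @param ann_genes Number of genes receiving direct DAG annotations.
#' @param n_loci Loci in the synthetic ID-mapping table.
#' @param multi_locus_frac Fraction of probes mapping to two loci.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, universe_size = 5000L, n_sets = 200L,
                       set_size_range = c(20L, 100L), planted_sets = 1L,
                       query_size = 150L, signal_fraction = 0.5,
                       dag_terms = 50L, dag_max_parents = 3L,
                       ann_genes = 100L, n_loci = 200L,
                       multi_locus_frac = 0.1) {
  cfg <- list(seed = as.integer(seed), universe_size = as.integer(universe_size),
              n_sets = as.integer(n_sets),
              set_size_range = as.integer(set_size_range),
              planted_sets = as.integer(planted_sets),
              query_size = as.integer(query_size),
              signal_fraction = as.numeric(signal_fraction),
              dag_terms = as.integer(dag_terms),
              dag_max_parents = as.integer(dag_max_parents),
              ann_genes = as.integer(ann_genes), n_loci = as.integer(n_loci),
              multi_locus_frac = as.numeric(multi_locus_frac))
  if (cfg$signal_fraction < 0 || cfg$signal_fraction > 1) {
    stop("signal_fraction must lie in [0, 1]")
  }
  if (length(cfg$set_size_range) != 2L ||
      cfg$set_size_range[[1L]] > cfg$set_size_range[[2L]]) {
    stop("set_size_range must be c(min, max) with min <= max")
  }
  if (cfg$set_size_range[[2L]] > cfg$universe_size) {
    stop("set sizes cannot exceed the universe size")
  }
  positive <- c("universe_size", "query_size", "dag_terms", "dag_max_parents")
  for (f in positive) {
    if (cfg[[f]] < 1L) stop(f, " must be positive")
  }
  if (cfg$n_sets < 0L || cfg$planted_sets < 0L) stop("counts must be non-negative")
  if (cfg$planted_sets > cfg$n_sets) stop("planted_sets cannot exceed n_sets")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic gene-set collection and background
#'
#' Universe genes are `g000001..gNNNNNN`; each set samples its members
#' uniformly without replacement with a size drawn uniformly from the
#' configured range; categories are assigned round-robin over the four
#' categories. The background is the whole universe. Deterministic for a
#' fixed seed.
#'
#' @param config A [sim_config()].
#' @return List with `collection` (a `GeneSetCollection`) and `bg` (a
#'   [background()]).
#' @export
make_collection <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  universe <- sprintf("g%06d", seq_len(config$universe_size))
  with_stream(config$seed, "collection", {
    sets <- vector("list", config$n_sets)
    for (i in seq_len(config$n_sets)) {
      size <- sample(config$set_size_range[[1L]]:config$set_size_range[[2L]], 1L)
      sets[[i]] <- gene_set(
        sprintf("SET%04d", i),
        sprintf("synthetic gene set %d", i),
        sample(universe, size),
        category = GSORA_CATEGORIES[[(i - 1L) %% 4L + 1L]])
    }
    list(collection = gene_set_collection(sets, organism = "synthetic"),
         bg = background(universe, source = "precomputed_genome"))
  })
}

#' Generate a query with planted enrichment signal
#'
#' Plants `planted_sets` gene sets and draws
#' `ceiling(signal_fraction * query_size)` query genes from their union;
#' the remainder is drawn uniformly from the rest of the background.
#' Planted sets are chosen uniformly among choices whose union is large
#' enough to supply the signal portion; if no choice is feasible the
#' config is rejected.
#'
#' @param config A [sim_config()].
#' @param collection A `GeneSetCollection` from [make_collection()].
#' @param bg The matching [background()].
#' @return List with `query` (character vector, `query_size` distinct
#'   genes), `planted` (names of the planted sets) and `signal_genes`.
#' @export
make_query <- function(config, collection, bg) {
  stopifnot(inherits(config, "sim_config"),
            inherits(collection, "GeneSetCollection"),
            inherits(bg, "Background"))
  if (config$planted_sets > length(collection$sets)) {
    stop("planted_sets exceeds the number of sets in the collection")
  }
  n_signal <- as.integer(ceiling(config$signal_fraction * config$query_size))
  all_union <- collection_universe(collection)
  if (config$planted_sets > 0L && length(all_union) < n_signal) {
    stop("no choice of planted sets can supply ", n_signal, " signal genes")
  }
  with_stream(config$seed, "query", {
    planted <- character()
    union_genes <- character()
    if (config$planted_sets > 0L && n_signal > 0L) {
      nm <- names(collection$sets)
      sizes <- lengths(lapply(collection$sets, function(s) s$members))
      best <- sum(sort(sizes, decreasing = TRUE)[seq_len(config$planted_sets)])
      if (best < n_signal) {
        stop("no choice of ", config$planted_sets, " planted set(s) can ",
             "supply ", n_signal, " signal genes")
      }
      for (attempt in 1:1000) {
        planted <- sort(sample(nm, config$planted_sets))
        union_genes <- unique(unlist(lapply(collection$sets[planted],
                                            function(s) s$members),
                                     use.names = FALSE))
        if (length(union_genes) >= n_signal) break
        if (attempt == 1000L) {
          stop("could not find a planted-set choice whose union supplies ",
               n_signal, " signal genes")
        }
      }
    } else if (config$planted_sets > 0L) {
      planted <- sort(sample(names(collection$sets), config$planted_sets))
    }
    signal <- if (n_signal > 0L && length(planted)) {
      sample(union_genes, n_signal)
    } else character()
    pool <- setdiff(bg$genes, signal)
    n_noise <- config$query_size - length(signal)
    if (n_noise > length(pool)) stop("query_size exceeds the background")
    noise <- if (n_noise > 0L) sample(pool, n_noise) else character()
    list(query = c(signal, noise), planted = planted, signal_genes = signal)
  })
}

#' Generate a random layered ontology DAG with annotations
#'
#' Term 1 is the root; each later term draws 1..`dag_max_parents` parents
#' uniformly from earlier terms, so the graph is acyclic by construction.
#' Roughly one edge in five is `part_of`, the rest `is_a`. Each of
#' `ann_genes` genes is directly annotated to 1-3 random terms.
#'
#' @param config A [sim_config()].
#' @return List with `graph` (an `OntologyGraph`) and `annotations`
#'   (data.frame `gene`, `term`).
#' @export
make_dag <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config$seed, "dag", {
    nt <- config$dag_terms
    ids <- sprintf("T:%07d", seq_len(nt))
    terms <- data.frame(id = ids,
                        name = sprintf("synthetic term %d", seq_len(nt)),
                        namespace = "biological_process",
                        stringsAsFactors = FALSE)
    edges <- NULL
    if (nt > 1L) {
      edge_rows <- lapply(2:nt, function(i) {
        np <- sample(seq_len(min(config$dag_max_parents, i - 1L)), 1L)
        parents <- sample(seq_len(i - 1L), np)
        data.frame(child = ids[[i]], parent = ids[parents],
                   relation = sample(c("is_a", "part_of"), np,
                                     replace = TRUE, prob = c(0.8, 0.2)),
                   stringsAsFactors = FALSE)
      })
      edges <- do.call(rbind, edge_rows)
    }
    if (is.null(edges)) {
      edges <- data.frame(child = character(), parent = character(),
                          relation = character(), stringsAsFactors = FALSE)
    }
    graph <- ontology_graph(terms, edges)
    genes <- sprintf("g%06d", sample(config$universe_size,
                                     min(config$ann_genes,
                                         config$universe_size)))
    ann_rows <- lapply(genes, function(g) {
      data.frame(gene = g, term = sample(ids, min(nt, sample(1:3, 1L))),
                 stringsAsFactors = FALSE)
    })
    annotations <- unique(do.call(rbind, c(ann_rows, list(NULL))))
    if (is.null(annotations)) {
      annotations <- data.frame(gene = character(), term = character(),
                                stringsAsFactors = FALSE)
    }
    rownames(annotations) <- NULL
    list(graph = graph, annotations = annotations)
  })
}

#' Generate a synthetic ID-mapping table
#'
#' Each locus `L00001..` gets 0-2 symbols and 0-3 probes; a configurable
#' fraction of probes additionally map to a second locus, stressing
#' many-to-many conversion.
#'
#' @param config A [sim_config()].
#' @return An `IdMappingTable`.
#' @export
make_mapping <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config$seed, "mapping", {
    loci <- sprintf("L%05d", seq_len(config$n_loci))
    rows <- list()
    probe_counter <- 0L
    for (i in seq_along(loci)) {
      symbols <- if ((ns <- sample(0:2, 1L)) > 0L) {
        sprintf("SYM%05d%s", i, LETTERS[seq_len(ns)])
      } else NA_character_
      np <- sample(0:3, 1L)
      probes <- if (np > 0L) {
        sprintf("p%05d_at", probe_counter + seq_len(np))
      } else NA_character_
      probe_counter <- probe_counter + np
      rows[[i]] <- expand.grid(locus = loci[[i]], symbol = symbols,
                               probe = probes, stringsAsFactors = FALSE,
                               KEEP.OUT.ATTRS = FALSE)
    }
    df <- do.call(rbind, rows)
    # cross-link a fraction of probes to a second locus
    probes_all <- unique(df$probe[!is.na(df$probe)])
    n_multi <- floor(config$multi_locus_frac * length(probes_all))
    if (n_multi > 0L && length(loci) > 1L) {
      multi <- sample(probes_all, n_multi)
      extra <- lapply(multi, function(p) {
        home <- unique(df$locus[!is.na(df$probe) & df$probe == p])
        other <- sample(setdiff(loci, home), 1L)
        data.frame(locus = other, symbol = NA_character_, probe = p,
                   stringsAsFactors = FALSE)
      })
      df <- rbind(df, do.call(rbind, extra))
    }
    id_mapping_table(df)
  })
}

#' Write a full synthetic fixture directory
#'
#' Emits `collection.gmt`, `background.txt`, `query.txt`, `dag.obo`,
#' `annotations.tsv`, `mapping.tsv` and `truth.json` (planted sets and
#' signal genes) so a complete analysis can be run from files alone.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
simulate_fixtures <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  coll <- make_collection(config)
  qry <- make_query(config, coll$collection, coll$bg)
  dag <- make_dag(config)
  mapping <- make_mapping(config)
  write_gmt(coll$collection, file.path(outdir, "collection.gmt"))
  write_id_list(coll$bg$genes, file.path(outdir, "background.txt"))
  write_id_list(qry$query, file.path(outdir, "query.txt"))
  write_obo(dag$graph, file.path(outdir, "dag.obo"))
  write_tsv_det(dag$annotations[order(dag$annotations$gene,
                                      dag$annotations$term), , drop = FALSE],
                file.path(outdir, "annotations.tsv"))
  write_mapping(mapping, file.path(outdir, "mapping.tsv"))
  jsonlite::write_json(list(seed = config$seed, planted = qry$planted,
                            signal_genes = sort(qry$signal_genes)),
                       file.path(outdir, "truth.json"), auto_unbox = FALSE)
  invisible(list(collection = coll$collection, bg = coll$bg, query = qry,
                 dag = dag, mapping = mapping))
}
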