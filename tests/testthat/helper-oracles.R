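# Independent oracles used across the suite. These deliberately take a
# different computational route from the package (stats::dhyper summation,
# hand-written step-up/step-down adjustments, closed-testing Simes, repeated
# edge expansion) so agreement is evidence, not tautology.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Upper-tail hypergeometric probability by brute-force pmf summation.
oracle_hyper_tail <- function(N, n, K, k) {
  hi <- min(n, K)
  if (k > hi) return(0)
  sum(stats::dhyper(k:hi, K, N - K, n))
}

# Two-sided Fisher by enumeration of the conditional distribution: sum the
# point probabilities of all tables no more probable than the observed one.
oracle_fisher_two_sided <- function(N, n, K, k) {
  lo <- max(0L, n + K - N)
  hi <- min(n, K)
  pmf <- stats::dhyper(lo:hi, K, N - K, n)
  obs <- stats::dhyper(k, K, N - K, n)
  sum(pmf[pmf <= obs * (1 + 1e-7)])
}

# Hand-written adjustment procedures (independent of stats::p.adjust).
oracle_bonferroni <- function(p) pmin(1, length(p) * p)

oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  adj[order(o)]
}

oracle_hochberg <- function(p) {
  m <- length(p)
  o <- order(p)
  s <- (m - seq_len(m) + 1) * p[o]
  adj <- pmin(1, rev(cummin(rev(s))))
  adj[order(o)]
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  s <- m / seq_len(m) * p[o]
  adj <- pmin(1, rev(cummin(rev(s))))
  adj[order(o)]
}

oracle_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  s <- cm * m / seq_len(m) * p[o]
  adj <- pmin(1, rev(cummin(rev(s))))
  adj[order(o)]
}

# Hommel adjusted p by explicit closed testing with Simes local tests:
# adjusted p of hypothesis i = max over all subsets S containing i of the
# Simes p-value of S. Exponential in m; use only for small m.
oracle_hommel_closed <- function(p) {
  m <- length(p)
  stopifnot(m <= 14L)
  adj <- numeric(m)
  idx <- seq_len(m)
  for (mask in seq_len(2^m) - 1L) {
    S <- idx[bitwAnd(mask, bitwShiftL(1L, idx - 1L)) != 0L]
    if (!length(S)) next
    ps <- sort(p[S])
    simes <- min(length(S) * ps / seq_along(ps))
    adj[S] <- pmax(adj[S], pmin(1, simes))
  }
  adj
}

# Transitive-closure propagation oracle: repeated edge expansion until the
# per-term gene sets stop changing.
oracle_propagate <- function(graph, annotations) {
  members <- lapply(setNames(graph$terms$id, graph$terms$id), function(t) {
    sort(unique(annotations$gene[annotations$term == t]))
  })
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(graph$edges))) {
      ch <- graph$edges$child[[i]]
      pa <- graph$edges$parent[[i]]
      merged <- sort(unique(c(members[[pa]], members[[ch]])))
      if (!identical(merged, members[[pa]])) {
        members[[pa]] <- merged
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  members[lengths(members) > 0L]
}

# Ancestor closure by repeated edge expansion.
oracle_ancestors <- function(graph, terms) {
  nodes <- unique(terms)
  repeat {
    parents <- unique(graph$edges$parent[graph$edges$child %in% nodes])
    new <- union(nodes, parents)
    if (length(new) == length(nodes)) break
    nodes <- new
  }
  sort(nodes)
}

# A tiny hand-built collection shared by several reporting tests.
toy_collection <- function() {
  gene_set_collection(list(
    gene_set("GO_A", "process A", c("g1", "g2", "g3"), category = "GO"),
    gene_set("FAM_B", "family B", c("g2", "g4"), category = "GeneFamily"),
    gene_set("CUR_C", "curated C", c("g1", "g4", "g5"), category = "Curated"),
    gene_set("MOT_D", "motif D", c("g6"), category = "Motif")
  ), organism = "toy")
}
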