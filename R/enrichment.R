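# Over-representation testing on the 2x2 overlap table.
#
# The table for one gene set against one query, all counts taken within the
# analysis background:
#   N = background size, n = query genes in background,
#   K = gene-set genes in background, k = query/set overlap.
# Under the null that the query is a uniform draw from the background, k is
# Hypergeometric(N, K, n); over-representation significance is the upper
# tail P(X >= k).

#' Construct a 2x2 overlap contingency table
#'
#' @param N Background size.
#' @param n Query genes within the background.
#' @param K Gene-set genes within the background.
#' @param k Overlap of query and set within the background.
#' @return A `ContingencyTable` (validated: `0 <= k`, `k <= min(n, K)`,
#'   `n <= N`, `K <= N`, and `k >= n + K - N`).
#' @export
contingency_table <- function(N, n, K, k) {
  v <- c(N = N, n = n, K = K, k = k)
  if (any(v != floor(v)) || any(v < 0)) {
    stop("N, n, K, k must be non-negative integers")
  }
  if (n > N || K > N) stop("n and K cannot exceed N")
  if (k > min(n, K)) stop("k cannot exceed min(n, K)")
  if (k < n + K - N) stop("k cannot be below n + K - N (cell counts would go negative)")
  structure(as.list(setNames(as.integer(v), names(v))),
            class = "ContingencyTable")
}

#' @export
print.ContingencyTable <- function(x, ...) {
  cat(sprintf("ContingencyTable: N=%d, n=%d, K=%d, k=%d\n", x$N, x$n, x$K, x$k))
  invisible(x)
}

# log hypergeometric pmf over a vector of overlap counts i
log_hyper_pmf <- function(N, n, K, i) {
  lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
}

# numerically stable sum of exp(logx)
log_space_sum <- function(logx) {
  logx <- logx[is.finite(logx)]
  if (!length(logx)) return(0)
  m <- max(logx)
  exp(m) * sum(exp(logx - m))
}

#' Hypergeometric over-representation test
#'
#' Exact one-sided upper-tail probability
#' \eqn{p = \sum_{i=k}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i}/\binom{N}{n}},
#' computed by log-space summation of the exact point probabilities (no
#' normal approximation).
#'
#' @param table A [contingency_table()].
#' @return The raw p-value.
#' @export
#' @examples
#' hypergeom_test(contingency_table(N = 10, n = 5, K = 5, k = 5))  # 1/choose(10,5)
hypergeom_test <- function(table) {
  stopifnot(inherits(table, "ContingencyTable"))
  hyper_upper_tail(table$N, table$n, table$K, table$k)
}

hyper_upper_tail <- function(N, n, K, k) {
  hi <- min(n, K)
  if (k <= max(0L, n + K - N)) return(1)
  min(1, log_space_sum(log_hyper_pmf(N, n, K, k:hi)))
}

#' Fisher's exact test on the overlap table
#'
#' With margins fixed, the conditional distribution of the overlap is
#' hypergeometric, so the one-sided (`"greater"`) Fisher test is identical
#' to [hypergeom_test()] — the package's default enrichment statistic. The
#' two-sided p-value sums the point probabilities of every table (same
#' margins) no more probable than the observed one.
#'
#' @param table A [contingency_table()].
#' @param sided `"greater"` (over-representation, default) or
#'   `"two_sided"`.
#' @return The raw p-value.
#' @export
fisher_exact_test <- function(table, sided = c("greater", "two_sided")) {
  stopifnot(inherits(table, "ContingencyTable"))
  sided <- match.arg(sided)
  if (sided == "greater") return(hypergeom_test(table))
  lo <- max(0L, table$n + table$K - table$N)
  hi <- min(table$n, table$K)
  logp <- log_hyper_pmf(table$N, table$n, table$K, lo:hi)
  obs <- log_hyper_pmf(table$N, table$n, table$K, table$k)
  # include tables whose point probability is <= observed, with a relative
  # tolerance guarding against ties lost to rounding
  min(1, log_space_sum(logp[logp <= obs + log(1 + 1e-7)]))
}

#' Chi-squared test on the overlap table
#'
#' Pearson chi-squared with 1 degree of freedom on the 2x2 table of counts
#' `(k, n-k, K-k, N-n-K+k)`, optionally with the Yates continuity
#' correction (on by default). This is an approximation to the exact tests;
#' the result carries a `small_expected` attribute flagging any expected
#' cell below 5, where the approximation is unreliable.
#'
#' @param table A [contingency_table()].
#' @param yates Apply the Yates continuity correction.
#' @return The p-value, with attributes `statistic` (the chi-squared value)
#'   and `small_expected` (logical).
#' @export
chisq_test <- function(table, yates = TRUE) {
  stopifnot(inherits(table, "ContingencyTable"))
  N <- table$N; n <- table$n; K <- table$K; k <- table$k
  if (n == 0L || K == 0L || n == N || K == N) {
    stop("chi-squared statistic undefined: a table margin is zero")
  }
  O <- c(k, n - k, K - k, N - n - K + k)
  E <- c(n * K, n * (N - K), (N - n) * K, (N - n) * (N - K)) / N
  d <- abs(O - E)
  if (yates) d <- pmax(0, d - 0.5)
  stat <- sum(d^2 / E)
  p <- pchisq(stat, df = 1L, lower.tail = FALSE)
  structure(p, statistic = stat, small_expected = any(E < 5))
}

#' Build the overlap table for a query against one gene set
#'
#' Query and set are first intersected with the background; genes outside
#' the background never enter the counts (they are reported through the
#' query audit instead).
#'
#' @param query Character vector of query gene IDs.
#' @param geneset A [gene_set()] (or character vector of member IDs).
#' @param bg A [background()].
#' @return List with `table` (a `ContingencyTable`) and `overlap_members`
#'   (sorted character vector, length `k`).
#' @export
build_table <- function(query, geneset, bg) {
  stopifnot(inherits(bg, "Background"))
  members <- if (inherits(geneset, "GeneSet")) geneset$members else
    unique(as.character(geneset))
  query <- unique(as.character(query))
  q_bg <- intersect(query, bg$genes)
  if (length(q_bg) == 0L) {
    stop("no query gene is present in the background; check the ID type ",
         "(locus vs probe) and the background list")
  }
  s_bg <- intersect(members, bg$genes)
  overlap <- sort(intersect(q_bg, s_bg))
  list(table = contingency_table(N = length(bg$genes), n = length(q_bg),
                                 K = length(s_bg), k = length(overlap)),
       overlap_members = overlap)
}

#' Audit a raw query list
#'
#' Deduplicates the submitted IDs and records which non-redundant IDs fall
#' outside the analysis background — the ID redundancy report shown before
#' any enrichment statistics.
#'
#' @param query_raw Character vector of submitted IDs (duplicates allowed).
#' @param bg A [background()].
#' @return A `QueryAudit`: list with `raw_count`, `nonredundant`,
#'   `dropped_not_in_background`.
#' @export
query_audit <- function(query_raw, bg) {
  stopifnot(inherits(bg, "Background"))
  query_raw <- trim_ids(as.character(query_raw))
  nonred <- unique(query_raw)
  structure(list(raw_count = length(query_raw),
                 nonredundant = nonred,
                 dropped_not_in_background = setdiff(nonred, bg$genes)),
            class = "QueryAudit")
}

#' @export
print.QueryAudit <- function(x, ...) {
  cat(basic_summary(x), sep = "\n")
  invisible(x)
}

#' Run over-representation analysis of a query against a collection
#'
#' For every gene set passing the size filters, builds the 2x2 overlap
#' table against the background and computes the raw enrichment p-value
#' with the chosen test. Adjustment for multiple testing is a separate
#' stage ([adjust_results()]), since the family is defined over the whole
#' run. Sets with no overlap are retained with p = 1 so the annotation
#' table stays complete.
#'
#' @param query Character vector of query gene IDs (duplicates allowed;
#'   audited and deduplicated).
#' @param collection A `GeneSetCollection`.
#' @param bg A [background()]; defaults to the collection universe as a
#'   precomputed background.
#' @param test `"fisher"` (default), `"hypergeometric"` or `"chisq"`.
#'   One-sided Fisher and the hypergeometric test are the same statistic;
#'   both are provided by name.
#' @param categories Optional subset of `geneset_categories()` to test.
#' @param min_size,max_size Gene-set size filters (within the background);
#'   defaults are permissive (min 2, no upper bound).
#' @param sided Sidedness for `test = "fisher"`.
#' @param yates Yates continuity correction for `test = "chisq"`.
#' @return An `ora_result`: list with `results` (data.frame, one row per
#'   tested set in deterministic category-then-name order: `set_name`,
#'   `description`, `category`, `N`, `n`, `K`, `k`, `fold_enrichment`,
#'   `p_raw`, `p_adjusted` (NA until adjusted), `overlap_members`
#'   (list-column)), `audit` (the [query_audit()]), `test`, and `bg_source`.
#' @export
run_enrichment <- function(query, collection, bg = NULL,
                           test = c("fisher", "hypergeometric", "chisq"),
                           categories = NULL, min_size = 2L, max_size = Inf,
                           sided = c("greater", "two_sided"), yates = TRUE) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  test <- match.arg(test)
  sided <- match.arg(sided)
  if (is.null(bg)) bg <- background(collection_universe(collection))
  if (!is.null(categories)) collection <- filter_categories(collection, categories)
  audit <- query_audit(query, bg)
  q_bg <- intersect(audit$nonredundant, bg$genes)
  if (length(q_bg) == 0L) {
    stop("no query gene is present in the background; check the ID type ",
         "(locus vs probe) and the background list")
  }
  sets <- collection$sets
  # deterministic order: canonical category order, then set name
  ord <- order(match(vapply(sets, function(s) s$category, character(1L)),
                     GSORA_CATEGORIES),
               vapply(sets, function(s) s$name, character(1L)),
               method = "radix")
  sets <- sets[ord]
  N <- length(bg$genes)
  n <- length(q_bg)
  rows <- lapply(sets, function(s) {
    s_bg <- intersect(s$members, bg$genes)
    K <- length(s_bg)
    if (K < min_size || K > max_size) return(NULL)
    overlap <- sort(intersect(q_bg, s_bg))
    k <- length(overlap)
    tab <- contingency_table(N, n, K, k)
    p <- switch(test,
                fisher = fisher_exact_test(tab, sided = sided),
                hypergeometric = hypergeom_test(tab),
                chisq = as.numeric(chisq_test(tab, yates = yates)))
    list(set_name = s$name, description = s$description,
         category = s$category, N = N, n = n, K = K, k = k,
         fold_enrichment = if (K > 0L) (k / n) / (K / N) else NA_real_,
         p_raw = p, overlap_members = overlap)
  })
  rows <- unname(rows[!vapply(rows, is.null, logical(1L))])
  res <- data.frame(
    set_name = vapply(rows, `[[`, character(1L), "set_name"),
    description = vapply(rows, `[[`, character(1L), "description"),
    category = vapply(rows, `[[`, character(1L), "category"),
    N = vapply(rows, `[[`, integer(1L), "N"),
    n = vapply(rows, `[[`, integer(1L), "n"),
    K = vapply(rows, `[[`, integer(1L), "K"),
    k = vapply(rows, `[[`, integer(1L), "k"),
    fold_enrichment = vapply(rows, `[[`, numeric(1L), "fold_enrichment"),
    p_raw = vapply(rows, `[[`, numeric(1L), "p_raw"),
    p_adjusted = NA_real_,
    stringsAsFactors = FALSE, row.names = NULL)
  res$overlap_members <- lapply(rows, `[[`, "overlap_members")
  structure(list(results = res, audit = audit, test = test,
                 bg_source = bg$source),
            class = "ora_result")
}

#' @export
print.ora_result <- function(x, ...) {
  cat(sprintf("ora_result: %d gene sets tested (%s test), query n=%d of N=%d\n",
              nrow(x$results), x$test,
              if (nrow(x$results)) x$results$n[[1L]] else 0L,
              if (nrow(x$results)) x$results$N[[1L]] else 0L))
  if (!all(is.na(x$results$p_adjusted))) {
    cat(sprintf("  %d sets with adjusted p < 0.05\n",
                sum(x$results$p_adjusted < 0.05, na.rm = TRUE)))
  }
  invisible(x)
}
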