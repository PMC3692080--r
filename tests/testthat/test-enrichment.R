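test_that("overlap tables count within the background and validate invariants", {
  bg <- background(sprintf("g%d", 1:10))
  out <- build_table(c("g1", "g2", "gX"), c("g2", "g3"), bg)
  expect_identical(out$table$N, 10L)
  expect_identical(out$table$n, 2L)  # gX dropped
  expect_identical(out$table$K, 2L)
  expect_identical(out$table$k, 1L)
  expect_identical(out$overlap_members, "g2")

  # query = set = background: all four counts collapse
  all_bg <- background(sprintf("g%d", 1:6))
  t2 <- build_table(all_bg$genes, all_bg$genes, all_bg)$table
  expect_identical(c(t2$N, t2$n, t2$K, t2$k), rep(6L, 4L))

  expect_error(build_table(c("zz"), c("g1"), bg), "background")
  expect_error(contingency_table(10, 11, 2, 1), "exceed N")
  expect_error(contingency_table(10, 3, 2, 3), "min\\(n, K\\)")
  expect_error(contingency_table(10, -1, 2, 1), "non-negative")
  expect_error(contingency_table(4, 3, 3, 1), "n \\+ K - N")

  # random fixtures: k equals the brute-force three-way intersection
  for (seed in 1:5) {
    withr::with_seed(seed, {
      u <- sprintf("g%03d", 1:80)
      bgv <- sample(u, 60)
      q <- sample(u, 25)
      s <- sample(u, 30)
      tab <- build_table(q, s, background(bgv))$table
      expect_identical(tab$k, length(Reduce(intersect, list(q, s, bgv))))
    })
  }
})

test_that("hypergeometric tail matches brute-force pmf summation", {
  expect_identical(hypergeom_test(contingency_table(10, 5, 5, 0)), 1)
  expect_equal(hypergeom_test(contingency_table(10, 5, 5, 5)),
               1 / choose(10, 5), tolerance = 1e-14)
  # spot-check across margins against dhyper summation
  for (seed in 1:20) {
    withr::with_seed(seed, {
      N <- sample(5:400, 1)
      n <- sample(0:N, 1)
      K <- sample(0:N, 1)
      lo <- max(0, n + K - N)
      k <- lo + sample.int(min(n, K) - lo + 1L, 1L) - 1L
      expect_equal(hypergeom_test(contingency_table(N, n, K, k)),
                   oracle_hyper_tail(N, n, K, k), tolerance = 1e-12)
    })
  }
})

test_that("tail probability is strictly decreasing in the overlap", {
  N <- 200L; n <- 40L; K <- 30L
  p <- vapply(1:30, function(k) hypergeom_test(contingency_table(N, n, K, k)),
              numeric(1L))
  expect_true(all(diff(p) < 0))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("one-sided Fisher equals the hypergeometric tail; two-sided matches enumeration", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      N <- sample(5:60, 1)
      n <- sample(1:N, 1)
      K <- sample(1:N, 1)
      lo <- max(0, n + K - N)
      k <- lo + sample.int(min(n, K) - lo + 1L, 1L) - 1L
      tab <- contingency_table(N, n, K, k)
      expect_identical(fisher_exact_test(tab, "greater"), hypergeom_test(tab))
      expect_equal(fisher_exact_test(tab, "two_sided"),
                   oracle_fisher_two_sided(N, n, K, k), tolerance = 1e-12)
      # cross-check both sides against the reference implementation
      m <- matrix(c(tab$k, tab$n - tab$k, tab$K - tab$k,
                    tab$N - tab$n - tab$K + tab$k), nrow = 2)
      expect_equal(fisher_exact_test(tab, "greater"),
                   stats::fisher.test(m, alternative = "greater")$p.value,
                   tolerance = 1e-9)
      expect_equal(fisher_exact_test(tab, "two_sided"),
                   stats::fisher.test(m, alternative = "two.sided")$p.value,
                   tolerance = 1e-9)
    })
  }
  # perfectly balanced table: two-sided includes the whole support
  expect_equal(fisher_exact_test(contingency_table(20, 10, 10, 5), "two_sided"), 1)
})

test_that("chi-squared statistic matches the hand formula and the exact test asymptotically", {
  # observed exactly at expectation: statistic 0, p = 1 (without Yates)
  tab <- contingency_table(100, 20, 10, 2)
  res <- chisq_test(tab, yates = FALSE)
  expect_equal(attr(res, "statistic"), 0)
  expect_equal(as.numeric(res), 1)

  # hand-computed Pearson statistic on a fixed table
  tab <- contingency_table(1000, 100, 100, 30)
  O <- c(30, 70, 70, 830)
  E <- c(100 * 100, 100 * 900, 900 * 100, 900 * 900) / 1000
  expect_equal(attr(chisq_test(tab, yates = FALSE), "statistic"),
               sum((O - E)^2 / E), tolerance = 1e-12)
  # agrees with the reference implementation, with and without Yates
  m <- matrix(c(30, 70, 70, 830), nrow = 2)
  expect_equal(as.numeric(chisq_test(tab, yates = FALSE)),
               suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value),
               tolerance = 1e-12)
  expect_equal(as.numeric(chisq_test(tab, yates = TRUE)),
               suppressWarnings(stats::chisq.test(m, correct = TRUE)$p.value),
               tolerance = 1e-12)
  # cross-test consistency: in the moderate tail the one-sided (halved)
  # Yates chi-squared p tracks the exact tail within 10% relative; deep in
  # the tail the asymptotic approximation falls apart, which is why the
  # exact tests are the default
  for (k in 12:15) {
    tabk <- contingency_table(1000, 100, 100, k)
    p_exact <- hypergeom_test(tabk)
    p_chi <- as.numeric(chisq_test(tabk, yates = TRUE)) / 2
    expect_lt(abs(p_chi - p_exact) / p_exact, 0.1)
  }

  expect_false(attr(chisq_test(tab), "small_expected"))
  expect_true(attr(chisq_test(contingency_table(100, 3, 3, 1)), "small_expected"))
  expect_error(chisq_test(contingency_table(10, 0, 5, 0)), "margin")
})

test_that("run_enrichment orders deterministically, filters and audits", {
  coll <- toy_collection()
  bg <- background(sprintf("g%d", 1:10))
  res <- run_enrichment(c("g1", "g2", "g1", "gZZ"), coll, bg, min_size = 1L)
  # deterministic order: canonical category order, then set name
  expect_identical(res$results$set_name, c("GO_A", "FAM_B", "CUR_C", "MOT_D"))
  expect_identical(res$results$k[res$results$set_name == "GO_A"], 2L)
  expect_identical(res$results$overlap_members[[which(res$results$set_name == "GO_A")]],
                   c("g1", "g2"))
  # k = 0 sets retained with p = 1
  expect_identical(res$results$p_raw[res$results$set_name == "MOT_D"], 1)
  # audit captures redundancy and out-of-background IDs
  expect_identical(res$audit$raw_count, 4L)
  expect_length(res$audit$nonredundant, 3L)
  expect_identical(res$audit$dropped_not_in_background, "gZZ")
  # |overlap| always equals k; fold enrichment matches (k/n)/(K/N)
  expect_identical(lengths(res$results$overlap_members), res$results$k)
  expect_equal(res$results$fold_enrichment,
               with(res$results, (k / n) / (K / N)))

  # category filter restricts the rows
  go_only <- run_enrichment(c("g1", "g2"), coll, bg, categories = "GO",
                            min_size = 1L)
  expect_identical(go_only$results$category, "GO")

  # size filter: default min_size = 2 drops the singleton motif set
  res2 <- run_enrichment(c("g1", "g2"), coll, bg)
  expect_false("MOT_D" %in% res2$results$set_name)

  # a query equal to one set gives that set the smallest raw p
  res3 <- run_enrichment(coll$sets$CUR_C$members, coll, bg, min_size = 1L)
  expect_identical(res3$results$set_name[which.min(res3$results$p_raw)], "CUR_C")
})

test_that("planted-enrichment fixture attains the smallest raw p-value", {
  cfg <- sim_config(seed = 31L, universe_size = 2000L, n_sets = 80L,
                    set_size_range = c(20L, 60L), query_size = 100L,
                    signal_fraction = 0.5)
  cc <- make_collection(cfg)
  q <- make_query(cfg, cc$collection, cc$bg)
  res <- run_enrichment(q$query, cc$collection, cc$bg)
  expect_identical(res$results$set_name[which.min(res$results$p_raw)],
                   q$planted)
})
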