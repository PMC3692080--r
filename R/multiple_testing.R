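# Multiple-testing adjustment across the tested gene sets.
#
# With tens of thousands of gene sets in a collection, raw p-values must be
# corrected. Six procedures are offered; Benjamini-Yekutieli (valid under
# arbitrary dependence, appropriate because gene sets overlap heavily) is
# the default, paired with the one-sided Fisher test.

GSORA_ADJUST_METHODS <- c(by = "BY", bonferroni = "bonferroni", bh = "BH",
                          hochberg = "hochberg", hommel = "hommel",
                          holm = "holm")

#' Adjust raw p-values for multiple testing
#'
#' Six procedures over one family of m tests:
#' * `bonferroni`: `min(1, m * p)`;
#' * `holm`: step-down Bonferroni;
#' * `hochberg`: step-up Simes-based;
#' * `hommel`: Simes-based closed testing;
#' * `bh`: Benjamini-Hochberg step-up FDR;
#' * `by` (default): Benjamini-Yekutieli — BH inflated by
#'   \eqn{c(m) = \sum_{i=1}^m 1/i}, valid under arbitrary dependence.
#'
#' Computation is delegated to [stats::p.adjust()]; adjusted values are
#' returned in the input order.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @param method One of `"by"`, `"bonferroni"`, `"bh"`, `"hochberg"`,
#'   `"hommel"`, `"holm"`.
#' @return Numeric vector of adjusted p-values, same length and order as
#'   `p`.
#' @export
#' @examples
#' adjust_p(c(0.01, 0.02, 0.03), "bonferroni")
adjust_p <- function(p, method = c("by", "bonferroni", "bh", "hochberg",
                                   "hommel", "holm")) {
  method <- match.arg(method)
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("all p-values must lie in [0, 1]")
  }
  p.adjust(p, method = GSORA_ADJUST_METHODS[[method]])
}

#' Adjust an enrichment run
#'
#' Fills the `p_adjusted` column of an [run_enrichment()] result. By
#' default all tested sets form one family; `per_category = TRUE` adjusts
#' within each category separately (for per-category displays).
#'
#' @param res An `ora_result`.
#' @param method Adjustment method, see [adjust_p()].
#' @param per_category Adjust within each category as its own family.
#' @return The `ora_result` with `p_adjusted` filled and the adjustment
#'   recorded in `$adjust_method`.
#' @export
adjust_results <- function(res, method = c("by", "bonferroni", "bh",
                                           "hochberg", "hommel", "holm"),
                           per_category = FALSE) {
  stopifnot(inherits(res, "ora_result"))
  method <- match.arg(method)
  df <- res$results
  if (nrow(df)) {
    if (per_category) {
      for (cat in unique(df$category)) {
        idx <- which(df$category == cat)
        df$p_adjusted[idx] <- adjust_p(df$p_raw[idx], method)
      }
    } else {
      df$p_adjusted <- adjust_p(df$p_raw, method)
    }
  }
  res$results <- df
  res$adjust_method <- method
  res$adjust_family <- if (per_category) "per_category" else "pooled"
  res
}

#' Select significantly enriched sets
#'
#' Filters adjusted results at a cut-off and orders them for display:
#' ascending adjusted p, ties broken by larger overlap then set name.
#'
#' @param res An adjusted `ora_result` (or its `results` data.frame).
#' @param cutoff Significance threshold on the adjusted p-value, in
#'   `(0, 1]`.
#' @return The filtered, sorted results data.frame.
#' @export
select_significant <- function(res, cutoff = 0.05) {
  if (inherits(res, "ora_result")) res <- res$results
  stopifnot(is.data.frame(res))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff > 1) {
    stop("cutoff must lie in (0, 1]")
  }
  if (anyNA(res$p_adjusted) && nrow(res)) {
    stop("results have not been adjusted; call adjust_results() first")
  }
  sel <- res[res$p_adjusted < cutoff, , drop = FALSE]
  sel[order(sel$p_adjusted, -sel$k, sel$set_name, method = "radix"), ,
      drop = FALSE]
}
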