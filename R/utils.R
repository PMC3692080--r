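# Internal helpers shared across modules.

# Strip surrounding whitespace; keep IDs case-sensitive (plant locus IDs carry
# case-significant suffixes).
trim_ids <- function(x) {
  x <- trimws(x)
  x[nzchar(x)]
}

#' Read a plain-text ID list
#'
#' One identifier per line; blank lines and lines starting with `#` are
#' ignored; surrounding whitespace is stripped. IDs are case-sensitive.
#'
#' @param path Path to a text file.
#' @return Character vector of IDs in file order (duplicates retained; callers
#'   that need a non-redundant list deduplicate explicitly and report it).
#' @export
read_id_list <- function(path) {
  if (!file.exists(path)) stop("ID list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Write a plain-text ID list
#'
#' @param ids Character vector of IDs.
#' @param path Output path. UTF-8, Unix newlines.
#' @return Invisibly, `path`.
#' @export
write_id_list <- function(ids, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(as.character(ids), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# Deterministic TSV writer: tab-separated, Unix newlines, no quoting, NA -> "".
write_tsv_det <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "", eol = "\n")
  invisible(path)
}

# Format p-values for report files: full double precision, stable across runs.
format_pval <- function(p) formatC(p, format = "g", digits = 15)

# Scoped RNG: run `expr` under a seed derived from (seed, stream name) and
# restore the caller's RNG state afterwards. Each generator owns a named
# stream so adding one generator never perturbs another's output.
with_stream <- function(seed, stream, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  sub_seed <- (abs(as.integer(seed)) %% 1000003L) * 2011L + (h %% 65521L)
  sub_seed <- sub_seed %% 2147483647L
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(sub_seed)
  expr
}
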