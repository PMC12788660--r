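#' @useDynLib peakTE, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state so package internals never
#' perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Metadata header written at the top of every table ("#key=value" lines).
meta_header <- function(meta) {
  if (is.null(meta) || length(meta) == 0L) return(character(0))
  paste0("#", names(meta), "=", vapply(meta, as.character, character(1)))
}

#' Write a table as TSV with an optional metadata header
#'
#' Header lines start with `#`; the column-name row follows. Numeric
#' formatting is fixed (15 significant digits) so identical content yields
#' byte-identical files.
#'
#' @param x A data.frame. List columns are collapsed with `,`.
#' @param path Output path.
#' @param meta Named character vector/list written as `#key=value` lines.
#' @return `path`, invisibly.
#' @export
write_tsv_meta <- function(x, path, meta = NULL) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.list(x[[j]]))
      x[[j]] <- vapply(x[[j]], function(v) paste(v, collapse = ","), character(1))
    if (is.double(x[[j]])) x[[j]] <- formatC(x[[j]], digits = 15, format = "g")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  hdr <- meta_header(meta)
  if (length(hdr)) writeLines(hdr, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_meta()]
#'
#' @param path File path.
#' @return A data.frame; the metadata header is attached as attribute `meta`.
#' @export
read_tsv_meta <- function(path) {
  lines <- readLines(path)
  n_meta <- sum(cumprod(grepl("^#", lines)))
  meta_lines <- if (n_meta) lines[seq_len(n_meta)] else character(0)
  body <- lines[(length(meta_lines) + 1L):length(lines)]
  x <- utils::read.table(text = body, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, comment.char = "",
                         check.names = FALSE)
  if (length(meta_lines)) {
    kv <- sub("^#", "", meta_lines)
    meta <- sub("^[^=]*=", "", kv)
    names(meta) <- sub("=.*$", "", kv)
    attr(x, "meta") <- meta
  }
  x
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Stable short hash of an R object (used for config provenance).
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(x), tf)
  unname(tools::md5sum(tf))
}
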