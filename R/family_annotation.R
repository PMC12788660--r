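## TE family annotation of cluster representatives: offline against a
## user-supplied consensus library (the default, fully reproducible path),
## or online against a Dfam-style sequence-search API (optional, mockable,
## never contacted unless explicitly enabled).

#' Read a consensus library FASTA
#'
#' Header convention: `>name [classification]` -- the first word is the
#' family name, the remainder (if any) a free-text classification label.
#'
#' @param path FASTA file.
#' @return data.frame with `name`, `classification`, `sequence`.
#' @export
read_consensus_library <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  name <- sub("\\s.*$", "", hdr)
  cls <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), NA_character_)
  data.frame(name = name, classification = cls,
             sequence = as.character(x), stringsAsFactors = FALSE)
}

empty_annotation <- function(representative_id) {
  data.frame(representative_id = representative_id,
             hit_name = NA_character_, hit_accession = NA_character_,
             classification = NA_character_, identity = NA_real_,
             e_value = NA_real_, bit_score = NA_real_,
             source = "none", stringsAsFactors = FALSE)
}

#' Annotate a representative against an offline consensus library
#'
#' The hit is the library entry with maximal [pairwise_identity()] to the
#' representative (ties to the lexicographically smallest name), reported
#' only when identity reaches `min_identity`. Statistical support fields
#' (`e_value`, `bit_score`) are not defined for this scoring and are `NA`;
#' the achieved identity is recorded instead.
#'
#' @param representative Non-empty nucleotide string.
#' @param library data.frame from [read_consensus_library()].
#' @param min_identity Minimum identity to report a hit (default 0.85).
#' @param representative_id Identifier copied into the result.
#' @return One-row annotation data.frame (`source` one of
#'   `"offline_library"`, `"none"`).
#' @export
annotate_offline <- function(representative, library, min_identity = 0.85,
                             representative_id = NA_character_) {
  if (!nzchar(representative)) stop("annotate_offline: empty representative")
  stopifnot(nrow(library) >= 1L)
  ids <- vapply(library$sequence, pairwise_identity, numeric(1),
                a = representative, USE.NAMES = FALSE)
  best <- which(ids == max(ids))
  best <- best[order(library$name[best])][1L]
  if (ids[best] < min_identity) return(empty_annotation(representative_id))
  data.frame(representative_id = representative_id,
             hit_name = library$name[best], hit_accession = NA_character_,
             classification = library$classification[best],
             identity = ids[best], e_value = NA_real_, bit_score = NA_real_,
             source = "offline_library", stringsAsFactors = FALSE)
}

#' Annotate a representative via a Dfam-style sequence-search API
#'
#' Disabled unless an endpoint is given. All failures (unreachable
#' endpoint, timeout, malformed response) degrade to a `source = "none"`
#' annotation with a warning -- never fatal. Sequences over 10 kb are
#' rejected before any request, as the service imposes length limits.
#'
#' @param representative Nucleotide string.
#' @param endpoint Base URL of the search service, or `NULL` (no request).
#' @param fetch Function `(url) -> parsed list`; injectable for testing.
#'   The default reads the URL and parses JSON via the `jsonlite` package.
#' @param timeout Seconds before giving up.
#' @param representative_id Identifier copied into the result.
#' @return One-row annotation data.frame (`source` one of `"dfam_api"`,
#'   `"none"`).
#' @export
annotate_dfam <- function(representative, endpoint = NULL,
                          fetch = default_fetch,
                          timeout = 30, representative_id = NA_character_) {
  if (is.null(endpoint)) return(empty_annotation(representative_id))
  if (nchar(representative) > 10000L) {
    warning("sequence exceeds 10 kb service limit; not submitted")
    return(empty_annotation(representative_id))
  }
  url <- paste0(endpoint, "?sequence=", representative)
  res <- tryCatch(fetch(url), error = function(e) {
    warning("family-annotation service query failed: ",
            conditionMessage(e))
    NULL
  })
  hits <- res$results %||% res$hits
  if (is.null(hits) || length(hits) == 0L)
    return(empty_annotation(representative_id))
  top <- hits[[1L]]
  data.frame(representative_id = representative_id,
             hit_name = top$name %||% NA_character_,
             hit_accession = top$accession %||% NA_character_,
             classification = top$classification %||% NA_character_,
             identity = NA_real_,
             e_value = as.numeric(top$e_value %||% NA),
             bit_score = as.numeric(top$bit_score %||% NA),
             source = "dfam_api", stringsAsFactors = FALSE)
}

default_fetch <- function(url) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for online annotation")
  jsonlite::fromJSON(url, simplifyVector = FALSE)
}

#' Annotate a table of representatives
#'
#' Offline library annotation by default; the online route is used only
#' when `endpoint` is non-`NULL` and only for representatives the library
#' failed to annotate.
#'
#' @param families data.frame with a `representative` column (e.g. from
#'   [cluster_peak_sequences()]).
#' @param library Optional consensus library data.frame.
#' @param min_identity Offline identity threshold.
#' @param endpoint Optional online endpoint.
#' @param fetch Injectable fetch function (see [annotate_dfam()]).
#' @return Annotation data.frame, one row per representative.
#' @export
annotate_families <- function(families, library = NULL, min_identity = 0.85,
                              endpoint = NULL, fetch = default_fetch) {
  rows <- lapply(seq_len(nrow(families)), function(i) {
    id <- as.character(families$cluster_id[i] %||% i)
    ann <- if (!is.null(library))
      annotate_offline(families$representative[i], library, min_identity,
                       representative_id = id)
    else empty_annotation(id)
    if (ann$source == "none" && !is.null(endpoint))
      ann <- annotate_dfam(families$representative[i], endpoint, fetch,
                           representative_id = id)
    ann
  })
  do.call(rbind, rows)
}
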