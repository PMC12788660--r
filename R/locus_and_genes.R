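## Population locus table: cross-sample merging of insertion breakpoints,
## per-group allele frequencies (fraction of carrier samples -- presence /
## absence, not genotype dosage), AF filtering, gene-feature intersection,
## and population-structure summaries.

#' Merge per-sample insertions into population loci
#'
#' Calls within the size range are grouped per chromosome by
#' single-linkage on breakpoint distance: two calls link when their
#' breakpoints are at most `breakpoint_tolerance` bp apart, and linkage is
#' transitive. Each group becomes one locus; a sample contributing several
#' calls to a group is represented by its longest one. The locus position
#' is the (rounded) median of member breakpoints.
#'
#' @param calls Calls table, all samples pooled.
#' @param size_range `c(lo, hi)` insertion-length window, bp.
#' @param breakpoint_tolerance Single-linkage distance, bp (default 50).
#' @return A `population_loci` data.frame: `locus_id`, `chrom`, `position`,
#'   `interval_start`, `interval_end`, `n_carriers`, `rep_length`, and list
#'   columns `carriers` (named character vector sample -> sequence, `""`
#'   when the caller gave none) and `carrier_lengths`.
#' @export
extract_loci <- function(calls, size_range, breakpoint_tolerance = 50L) {
  stopifnot(length(size_range) == 2L, size_range[1] <= size_range[2],
            breakpoint_tolerance >= 0L)
  x <- calls[calls$length >= size_range[1] & calls$length <= size_range[2], ,
             drop = FALSE]
  if (!nrow(x)) return(empty_loci())
  rows <- list()
  for (ch in sort(unique(x$chrom))) {
    xc <- x[x$chrom == ch, , drop = FALSE]
    xc <- xc[order(xc$pos, xc$sample_id, -xc$length), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(diff(xc$pos) > breakpoint_tolerance)))
    for (g in unique(grp)) {
      m <- xc[grp == g, , drop = FALSE]
      ## one carrier per sample: longest call wins, then smallest position
      m <- m[order(m$sample_id, -m$length, m$pos), , drop = FALSE]
      m <- m[!duplicated(m$sample_id), , drop = FALSE]
      m <- m[order(m$sample_id), , drop = FALSE]
      rows[[length(rows) + 1L]] <- list(
        chrom = ch,
        position = as.integer(round(stats::median(m$pos))),
        interval_start = min(m$pos), interval_end = max(m$pos),
        carriers = stats::setNames(m$sequence, m$sample_id),
        carrier_lengths = stats::setNames(m$length, m$sample_id))
    }
  }
  df <- data.frame(
    locus_id = sprintf("locus_%05d", seq_along(rows)),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    position = vapply(rows, `[[`, integer(1), "position"),
    interval_start = vapply(rows, function(r) as.integer(r$interval_start),
                            integer(1)),
    interval_end = vapply(rows, function(r) as.integer(r$interval_end),
                          integer(1)),
    n_carriers = vapply(rows, function(r) length(r$carriers), integer(1)),
    rep_length = vapply(rows, function(r) as.integer(max(r$carrier_lengths)),
                        integer(1)),
    stringsAsFactors = FALSE)
  df$carriers <- lapply(rows, `[[`, "carriers")
  df$carrier_lengths <- lapply(rows, `[[`, "carrier_lengths")
  class(df) <- c("population_loci", "data.frame")
  df
}

empty_loci <- function() {
  df <- data.frame(locus_id = character(0), chrom = character(0),
                   position = integer(0), interval_start = integer(0),
                   interval_end = integer(0), n_carriers = integer(0),
                   rep_length = integer(0), stringsAsFactors = FALSE)
  df$carriers <- list()
  df$carrier_lengths <- list()
  class(df) <- c("population_loci", "data.frame")
  df
}

#' Filter loci by identity to a family consensus
#'
#' A locus is kept iff at least one carrier sequence reaches
#' `min_identity` to the consensus; carriers below threshold are dropped
#' from kept loci. Carriers without sequence never match.
#'
#' @param loci A `population_loci` table.
#' @param consensus Non-empty nucleotide string.
#' @param min_identity Identity threshold (default 0.85).
#' @return Filtered `population_loci` table.
#' @export
filter_loci_by_consensus <- function(loci, consensus, min_identity = 0.85) {
  stopifnot(nzchar(consensus))
  if (!nrow(loci)) return(loci)
  keep <- logical(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    cs <- loci$carriers[[i]]
    ok <- vapply(cs, function(s)
      nzchar(s) && pairwise_identity(s, consensus) >= min_identity,
      logical(1))
    keep[i] <- any(ok)
    if (keep[i]) {
      loci$carriers[[i]] <- cs[ok]
      loci$carrier_lengths[[i]] <- loci$carrier_lengths[[i]][ok]
      loci$n_carriers[i] <- sum(ok)
      loci$rep_length[i] <- max(loci$carrier_lengths[[i]])
    }
  }
  out <- loci[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-group allele frequencies for loci
#'
#' AF of a locus in a group is the fraction of that group's (QC-passing)
#' samples carrying the insertion -- presence/absence, not dosage. Groups
#' with zero passing samples are omitted.
#'
#' @param loci `population_loci` table.
#' @param groups Named character vector sample_id -> group.
#' @param passing_samples Samples forming the denominators (default: all
#'   samples in `groups`).
#' @return Numeric matrix loci x groups; also attached to `loci` by
#'   [with_group_af()].
#' @export
compute_group_af <- function(loci, groups, passing_samples = names(groups)) {
  stopifnot(all(passing_samples %in% names(groups)))
  g <- groups[passing_samples]
  denom <- table(g)
  gnames <- sort(names(denom)[denom > 0])
  af <- matrix(0, nrow = nrow(loci), ncol = length(gnames),
               dimnames = list(loci$locus_id, gnames))
  for (i in seq_len(nrow(loci))) {
    carriers <- intersect(names(loci$carriers[[i]]), passing_samples)
    if (length(carriers)) {
      tab <- table(factor(groups[carriers], levels = gnames))
      af[i, ] <- as.numeric(tab) / as.numeric(denom[gnames])
    }
  }
  af
}

#' Filter loci on group allele frequency
#'
#' @param loci `population_loci` table.
#' @param af Matrix from [compute_group_af()] (rows parallel to `loci`).
#' @param min_af Threshold in \[0, 1\].
#' @param scope `"any_group"` keeps a locus whose maximum group AF reaches
#'   the threshold; `"all_groups"` requires the minimum to.
#' @return List with filtered `loci` and matching `af` matrix.
#' @export
filter_af <- function(loci, af, min_af = 0.75,
                      scope = c("any_group", "all_groups")) {
  scope <- match.arg(scope)
  stopifnot(min_af >= 0, min_af <= 1, nrow(af) == nrow(loci))
  stat <- if (scope == "any_group") apply(af, 1L, max)
          else apply(af, 1L, min)
  keep <- stat >= min_af
  out <- loci[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(loci = out, af = af[keep, , drop = FALSE])
}

#' Pairwise shared high-frequency locus counts between groups
#'
#' `M[g, h]` counts loci whose AF reaches `af_threshold` in both groups;
#' the diagonal is the per-group count. Symmetric by construction.
#'
#' @param af Loci x groups AF matrix.
#' @param af_threshold Threshold (default 0.75).
#' @return Symmetric integer matrix groups x groups.
#' @export
shared_loci_matrix <- function(af, af_threshold = 0.75) {
  stopifnot(ncol(af) >= 2L)
  hi <- af >= af_threshold
  m <- crossprod(hi)
  storage.mode(m) <- "integer"
  m
}

#' Binary presence/absence matrix of samples by loci
#'
#' @param loci `population_loci` table.
#' @param samples Character vector fixing row order.
#' @return Integer 0/1 matrix, samples x loci.
#' @export
presence_matrix <- function(loci, samples) {
  m <- matrix(0L, nrow = length(samples), ncol = nrow(loci),
              dimnames = list(samples, loci$locus_id))
  for (j in seq_len(nrow(loci))) {
    cs <- intersect(names(loci$carriers[[j]]), samples)
    m[cs, j] <- 1L
  }
  m
}

#' Two-dimensional embedding of the presence/absence matrix
#'
#' Classical metric multidimensional scaling (principal-coordinates
#' analysis) on Jaccard distances between samples' presence profiles.
#' Fully deterministic: reruns on the same matrix are bit-identical; the
#' `seed` argument is accepted for interface uniformity and recorded, but
#' the decomposition itself uses no randomness. Axis signs are fixed so
#' the largest-magnitude loading on each axis is positive.
#'
#' @param m Binary samples x loci matrix (at least 3 samples).
#' @param seed Recorded in the result's metadata.
#' @return Numeric samples x 2 coordinate matrix with attribute `method`.
#' @export
embed_presence <- function(m, seed = 42L) {
  if (nrow(m) < 3L)
    stop("embedding needs at least 3 samples; reduce analysis scope")
  d <- stats::dist(m, method = "binary")
  d[!is.finite(d)] <- 0
  xy <- stats::cmdscale(d, k = 2L)
  if (ncol(xy) < 2L)  # degenerate geometry: pad with zeros
    xy <- cbind(xy, matrix(0, nrow(xy), 2L - ncol(xy)))
  for (j in 1:2) {
    i <- which.max(abs(xy[, j]))
    if (xy[i, j] < 0) xy[, j] <- -xy[, j]
  }
  dimnames(xy) <- list(rownames(m), c("dim1", "dim2"))
  attr(xy, "method") <- "classical MDS (PCoA), Jaccard distance"
  attr(xy, "seed") <- as.integer(seed)
  xy
}

#' Hierarchical clustering of groups by AF profile
#'
#' Agglomerative clustering (average linkage, Euclidean distance) of the
#' group-by-locus allele-frequency matrix; deterministic.
#'
#' @param af_matrix Groups x loci numeric matrix.
#' @return An [stats::hclust] tree whose leaves are the groups.
#' @export
cluster_groups <- function(af_matrix) {
  stopifnot(nrow(af_matrix) >= 2L)
  stats::hclust(stats::dist(af_matrix, method = "euclidean"),
                method = "average")
}

## ---- gene-feature intersection -----------------------------------------

#' Load a gene annotation GTF
#'
#' Light line validation (9 tab-separated fields) with the offending line
#' number on failure, then standard import as GRanges.
#'
#' @param path GTF file.
#' @return A `GRanges` with `type` and `gene_id` metadata columns.
#' @export
read_gene_annotation <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L))
    stop("malformed GTF line ", body[which(nf != 9L)[1L]], " in ", path)
  rtracklayer::import(path, format = "gtf")
}

#' Classify loci by overlapping gene feature
#'
#' Feature at the locus breakpoint, by precedence CDS > UTR > exon >
#' intron (inside a gene body with no exon overlap) > intergenic, so the
#' reported categories are disjoint. `gene_id` is attached whenever the
#' locus falls in a gene (ties to the lexicographically smallest id).
#'
#' @param loci `population_loci` table.
#' @param annotation `GRanges` from [read_gene_annotation()].
#' @return data.frame `locus_id`, `feature_type`, `gene_id`.
#' @export
classify_features <- function(loci, annotation) {
  if (!nrow(loci))
    return(data.frame(locus_id = character(0), feature_type = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE))
  pts <- GenomicRanges::GRanges(
    loci$chrom, IRanges::IRanges(loci$position, width = 1L))
  type <- tolower(as.character(annotation$type))
  is_utr <- type %in% c("utr", "five_prime_utr", "three_prime_utr",
                        "5utr", "3utr")
  pick <- function(sel) {
    hits <- GenomicRanges::findOverlaps(pts, annotation[sel],
                                        ignore.strand = TRUE)
    hits
  }
  feature <- rep("intergenic", nrow(loci))
  gene <- rep(NA_character_, nrow(loci))
  assign_hits <- function(sel, label) {
    hits <- pick(sel)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    gid <- as.character(annotation$gene_id[sel][s])
    for (i in unique(q)) {
      if (feature[i] == "intergenic") {
        feature[i] <<- label
        g <- sort(gid[q == i])
        gene[i] <<- g[1L]
      }
    }
  }
  assign_hits(type == "cds", "CDS")
  assign_hits(is_utr, "UTR")
  assign_hits(type == "exon", "exon")
  assign_hits(type == "gene", "intron")
  data.frame(locus_id = loci$locus_id, feature_type = feature,
             gene_id = gene, stringsAsFactors = FALSE)
}

#' Flatten a locus table for TSV output
#'
#' Carrier maps become `sample:sequence-length` strings; optional AF
#' columns are appended.
#'
#' @param loci `population_loci` table.
#' @param af Optional AF matrix from [compute_group_af()].
#' @return Plain data.frame suitable for [write_tsv_meta()].
#' @export
flatten_loci <- function(loci, af = NULL) {
  df <- as.data.frame(loci)[, c("locus_id", "chrom", "position",
                                "interval_start", "interval_end",
                                "n_carriers", "rep_length")]
  df$carriers <- vapply(loci$carriers, function(cs)
    paste(names(cs), collapse = ","), character(1))
  if (!is.null(af)) {
    colnames_af <- paste0("af_", colnames(af))
    for (j in seq_len(ncol(af))) df[[colnames_af[j]]] <- af[, j]
  }
  df
}
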