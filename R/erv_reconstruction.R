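## Solo-LTR and full-length ERV reconstruction.
##
## An endogenous retrovirus integrates as LTR-internal-LTR; recombination
## between the two identical LTRs usually leaves a solo LTR, so an LTR
## family shows up as a sharp insertion-size peak (the LTR length) plus a
## rarer population of much larger full-length insertions. The
## reconstruction route is: build an LTR consensus from the peak's size
## range, keep loci whose carriers match it, merge loci within a generous
## distance (overestimating the internal length to absorb resolution
## noise in repetitive regions), intersect the merged loci with all large
## insertions, and validate each large insertion by scanning both of its
## halves for the LTR.

#' Majority-vote consensus from a size range
#'
#' Restricts to in-range calls with usable (non-empty, untruncated)
#' sequences, takes the modal length (ties to the smaller), and returns
#' the per-column majority base over the same-length sequences (column
#' ties broken alphabetically).
#'
#' @param calls Calls table.
#' @param lo,hi Inclusive length range, bp.
#' @return Consensus nucleotide string of the modal length.
#' @export
build_range_consensus <- function(calls, lo, hi) {
  sel <- calls$length >= lo & calls$length <= hi &
    nzchar(calls$sequence) & !calls$truncated
  if (!any(sel)) stop("no usable sequences in [", lo, ", ", hi, "]")
  seqs <- calls$sequence[sel]
  lens <- nchar(seqs)
  tab <- table(lens)
  modal <- as.integer(names(tab)[tab == max(tab)])
  modal <- min(modal)
  seqs <- seqs[lens == modal]
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  cons <- apply(mat, 2L, function(col) {
    t <- table(col)
    cand <- names(t)[t == max(t)]
    sort(cand)[1L]
  })
  paste(cons, collapse = "")
}

#' Keep loci whose carriers match the LTR consensus
#'
#' Identical contract to [filter_loci_by_consensus()] (delegated).
#'
#' @inheritParams filter_loci_by_consensus
#' @param ltr_consensus LTR consensus string.
#' @return Filtered `population_loci` table.
#' @export
filter_ltr_loci <- function(loci, ltr_consensus, min_identity = 0.85) {
  filter_loci_by_consensus(loci, ltr_consensus, min_identity)
}

#' Merge loci lying within a distance of one another
#'
#' Per-chromosome single-linkage on representative positions with gap
#' <= `distance` (transitive); each merged locus spans its members and
#' records them.
#'
#' @param loci `population_loci` table.
#' @param distance Linkage distance, bp (default 10000 -- a deliberate
#'   overestimate of the internal length, so paired LTRs whose partner
#'   call was missed still merge).
#' @return data.frame `merged_id`, `chrom`, `start`, `end`, `n_members`,
#'   list column `member_locus_ids`, and list column `carriers` (union of
#'   member carrier maps, longest sequence per sample).
#' @export
merge_proximal_loci <- function(loci, distance = 10000L) {
  stopifnot(distance >= 0L)
  if (!nrow(loci)) {
    df <- data.frame(merged_id = character(0), chrom = character(0),
                     start = integer(0), end = integer(0),
                     n_members = integer(0), stringsAsFactors = FALSE)
    df$member_locus_ids <- list()
    df$carriers <- list()
    return(df)
  }
  rows <- list()
  for (ch in sort(unique(loci$chrom))) {
    lc <- loci[loci$chrom == ch, , drop = FALSE]
    lc <- lc[order(lc$position), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(diff(lc$position) > distance)))
    for (g in unique(grp)) {
      m <- lc[grp == g, , drop = FALSE]
      carr <- unlist(m$carriers)
      ## longest sequence per sample across members
      if (length(carr)) {
        ord <- order(names(carr), -nchar(carr))
        carr <- carr[ord][!duplicated(names(carr)[ord])]
      }
      rows[[length(rows) + 1L]] <- list(
        chrom = ch, start = min(m$interval_start),
        end = max(m$interval_end),
        member_locus_ids = m$locus_id, carriers = carr)
    }
  }
  df <- data.frame(
    merged_id = sprintf("merged_%04d", seq_along(rows)),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    start = vapply(rows, function(r) as.integer(r$start), integer(1)),
    end = vapply(rows, function(r) as.integer(r$end), integer(1)),
    n_members = vapply(rows, function(r) length(r$member_locus_ids),
                       integer(1)),
    stringsAsFactors = FALSE)
  df$member_locus_ids <- lapply(rows, `[[`, "member_locus_ids")
  df$carriers <- lapply(rows, `[[`, "carriers")
  df
}

#' Intersect merged LTR loci with large insertions
#'
#' One candidate per (merged locus, call) pair where the call is strictly
#' longer than `internal_min` and its breakpoint falls within the merged
#' interval padded by `pad` bp on each side.
#'
#' @param merged Output of [merge_proximal_loci()].
#' @param all_calls Calls table, all samples.
#' @param internal_min Strict length floor, bp (default 4000 -- a
#'   conservative underestimate of the internal region).
#' @param pad Interval padding, bp (default 50).
#' @return data.frame of candidates: `merged_id`, `sample_id`, `chrom`,
#'   `pos`, `length`, `sequence`, `truncated`, with unset validation
#'   columns (`half_identity_1`, `half_identity_2`, `status`).
#' @export
find_internal_candidates <- function(merged, all_calls,
                                     internal_min = 4000L, pad = 50L) {
  stopifnot(internal_min >= 1L)
  big <- all_calls[all_calls$length > internal_min, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(merged))) {
    sel <- big$chrom == merged$chrom[i] &
      big$pos >= merged$start[i] - pad & big$pos <= merged$end[i] + pad
    if (any(sel)) {
      cand <- big[sel, , drop = FALSE]
      cand$merged_id <- merged$merged_id[i]
      out[[length(out) + 1L]] <- cand
    }
  }
  if (!length(out)) {
    df <- insertion_calls()
    df$merged_id <- character(0)
  } else df <- do.call(rbind, out)
  df$half_identity_1 <- rep(NA_real_, nrow(df))
  df$half_identity_2 <- rep(NA_real_, nrow(df))
  df$status <- rep(NA_character_, nrow(df))
  rownames(df) <- NULL
  df
}

## Best identity of the LTR consensus within one scan region: windows of
## length nchar(consensus) at the given stride, plus the terminal window.
## Short-circuits when a perfect window is found.
scan_best_identity <- function(seq, consensus, stride = 10L) {
  n <- nchar(seq)
  L <- nchar(consensus)
  if (n <= L) return(pairwise_identity(seq, consensus))
  starts <- unique(c(1L, seq.int(1L, n - L + 1L, by = stride), n - L + 1L))
  ## evaluate the two terminal windows first: an LTR sits at an element's
  ## ends, so this short-circuits the common case
  starts <- unique(c(1L, n - L + 1L, starts))
  best <- 0
  for (s in starts) {
    id <- pairwise_identity(substr(seq, s, s + L - 1L), consensus)
    if (id > best) best <- id
    if (best >= 1) break
  }
  best
}

#' Validate candidates as full-length ERVs by split-half LTR scanning
#'
#' Each candidate sequence is split at `floor(len / 2)`; every window of
#' the LTR consensus length (stride `stride`, plus the terminal window) in
#' each half is scored by [pairwise_identity()] against the consensus, and
#' the per-half maxima decide the status: `full_length` when both reach
#' `min_identity`, otherwise `rejected_one_half` / `rejected_both_halves`.
#' With `overlap_margin = TRUE` (default) each half's scan region is
#' extended across the midpoint by one consensus length, so an LTR
#' straddling the split cannot be missed by both halves. Candidates whose
#' stored sequence was truncated are marked `rejected_truncated`.
#' Identical sequences are validated once (memoised).
#'
#' @param candidates data.frame from [find_internal_candidates()].
#' @param ltr_consensus LTR consensus string.
#' @param min_identity Per-half identity threshold (default 0.85).
#' @param stride Scan stride, bp (default 10; 1 gives an exhaustive scan).
#' @param overlap_margin Extend each half's scan region across the
#'   midpoint by one consensus length.
#' @return `candidates` with `half_identity_1`, `half_identity_2`,
#'   `status` filled in.
#' @export
validate_full_length <- function(candidates, ltr_consensus,
                                 min_identity = 0.85, stride = 10L,
                                 overlap_margin = TRUE) {
  if (!nrow(candidates)) return(candidates)
  L <- nchar(ltr_consensus)
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(candidates))) {
    if (candidates$truncated[i] || !nzchar(candidates$sequence[i])) {
      candidates$status[i] <- "rejected_truncated"
      next
    }
    s <- candidates$sequence[i]
    key <- s
    if (!is.null(cache[[key]])) {
      hit <- cache[[key]]
    } else {
      n <- nchar(s)
      mid <- n %/% 2L
      m <- if (overlap_margin) L else 0L
      h1 <- substr(s, 1L, min(n, mid + m))
      h2 <- substr(s, max(1L, mid + 1L - m), n)
      hit <- c(scan_best_identity(h1, ltr_consensus, stride),
               scan_best_identity(h2, ltr_consensus, stride))
      cache[[key]] <- hit
    }
    candidates$half_identity_1[i] <- hit[1L]
    candidates$half_identity_2[i] <- hit[2L]
    ok <- hit >= min_identity
    candidates$status[i] <- if (all(ok)) "full_length"
      else if (any(ok)) "rejected_one_half" else "rejected_both_halves"
  }
  candidates
}

#' Brute-force scan of all large insertions against an internal consensus
#'
#' The validation oracle for the peak-based route: every call strictly
#' longer than `internal_min` is scored against the internal-region
#' consensus. Because a full-length element carries two LTRs in addition
#' to the internal region, identity is normalised by the consensus length
#' (coverage of the consensus), not by the longer sequence, so an exact
#' internal region embedded in a longer call scores 1.
#'
#' @param all_calls Calls table.
#' @param internal_consensus Internal-region consensus string.
#' @param internal_min Strict length floor, bp (default 4000).
#' @param min_identity Reporting threshold (default 0.85).
#' @return data.frame of reported calls with an `internal_identity`
#'   column, ordered by chrom/pos.
#' @export
brute_force_internal_scan <- function(all_calls, internal_consensus,
                                      internal_min = 4000L,
                                      min_identity = 0.85) {
  stopifnot(nzchar(internal_consensus))
  big <- all_calls[all_calls$length > internal_min & !all_calls$truncated &
                   nzchar(all_calls$sequence), , drop = FALSE]
  if (!nrow(big)) {
    big$internal_identity <- numeric(0)
    return(big)
  }
  L <- nchar(internal_consensus)
  big$internal_identity <- vapply(big$sequence, function(s)
    .lcs_length_cpp(s, internal_consensus) / L, numeric(1),
    USE.NAMES = FALSE)
  out <- big[big$internal_identity >= min_identity, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' End-to-end ERV reconstruction from calls
#'
#' Convenience driver: consensus from the LTR size range, locus
#' extraction and consensus filtering, proximity merging, large-insertion
#' intersection, and split-half validation. Several LTR size windows may
#' be supplied (shorter LTR variants are a known failure mode of a single
#' narrow window); their loci are pooled before merging.
#'
#' @param calls Calls table, all samples.
#' @param ltr_ranges List of `c(lo, hi)` LTR size windows (bp).
#' @param ltr_identity Identity threshold for LTR loci (default 0.85).
#' @param merge_distance Locus merging distance, bp (default 10000).
#' @param internal_min Strict internal-length floor, bp (default 4000).
#' @param pad Intersection padding, bp (default 50).
#' @param breakpoint_tolerance Locus-merging tolerance, bp (default 50).
#' @param stride Validation scan stride (default 10).
#' @return List: `ltr_consensus`, `solo_loci` (filtered LTR loci),
#'   `merged`, `candidates` (validated), `full_length` (subset with
#'   status `full_length`).
#' @export
reconstruct_erv <- function(calls, ltr_ranges = list(c(1370L, 1380L)),
                            ltr_identity = 0.85, merge_distance = 10000L,
                            internal_min = 4000L, pad = 50L,
                            breakpoint_tolerance = 50L, stride = 10L) {
  if (!is.list(ltr_ranges)) ltr_ranges <- list(ltr_ranges)
  cons <- build_range_consensus(calls, ltr_ranges[[1L]][1],
                                ltr_ranges[[1L]][2])
  pieces <- lapply(ltr_ranges, function(r) {
    loci <- extract_loci(calls, r, breakpoint_tolerance)
    filter_ltr_loci(loci, cons, ltr_identity)
  })
  solo <- do.call(rbind, pieces)
  if (nrow(solo)) {
    solo <- solo[order(solo$chrom, solo$position), , drop = FALSE]
    solo$locus_id <- sprintf("locus_%05d", seq_len(nrow(solo)))
    rownames(solo) <- NULL
  }
  merged <- merge_proximal_loci(solo, merge_distance)
  cand <- find_internal_candidates(merged, calls, internal_min, pad)
  cand <- validate_full_length(cand, cons, ltr_identity, stride)
  list(ltr_consensus = cons, solo_loci = solo, merged = merged,
       candidates = cand,
       full_length = cand[!is.na(cand$status) &
                          cand$status == "full_length", , drop = FALSE])
}
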