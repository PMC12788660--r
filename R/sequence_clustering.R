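## Within-peak sequence clustering: percent identity, length-variant
## pre-grouping, greedy first-fit clustering against frozen
## representatives, peak-weighted sampling, and count extrapolation.

#' Percent identity between two sequences
#'
#' Optimal global alignment score under match = 1, mismatch = 0, gap = 0 --
#' i.e. the longest-common-subsequence length -- normalised by the longer
#' sequence length. Symmetric, in \[0, 1\]; the max-length denominator is
#' conservative in that truncation is penalised.
#'
#' @param a,b Non-empty nucleotide strings.
#' @return Identity fraction.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("pairwise_identity: empty sequence")
  .lcs_length_cpp(a, b) / max(nchar(a), nchar(b))
}

#' Pre-group sequences into length-variant groups
#'
#' Greedy single pass in input order: a sequence joins the first group
#' whose anchor length L (the founding member's) satisfies
#' `|len - L| <= tolerance * L`, else it founds a new group.
#'
#' @param lengths Integer vector of sequence lengths, in processing order.
#' @param tolerance Relative tolerance (default 0.10).
#' @return Integer vector of group indices (1-based), same order as input.
#' @export
length_groups <- function(lengths, tolerance = 0.10) {
  stopifnot(tolerance >= 0)
  n <- length(lengths)
  grp <- integer(n)
  anchors <- numeric(0)
  for (i in seq_len(n)) {
    hit <- which(abs(lengths[i] - anchors) <= tolerance * anchors)
    if (length(hit)) grp[i] <- hit[1L]
    else {
      anchors <- c(anchors, lengths[i])
      grp[i] <- length(anchors)
    }
  }
  grp
}

#' Greedy first-fit identity clustering
#'
#' Sequences are processed in the given order; each is compared against
#' existing cluster representatives (frozen at seeding) and joins the
#' first whose identity is at least `threshold`, otherwise it seeds a new
#' cluster with itself as representative.
#'
#' @param ids Identifiers, parallel to `seqs`.
#' @param seqs Nucleotide strings, in processing order.
#' @param threshold Identity threshold in (0, 1\].
#' @return List of clusters; each a list with `representative` (the
#'   seeding sequence), `member_ids`, `member_seqs`.
#' @export
greedy_cluster <- function(ids, seqs, threshold = 0.85) {
  stopifnot(length(ids) == length(seqs), threshold > 0, threshold <= 1)
  reps <- character(0)
  members <- list()
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (pairwise_identity(seqs[i], reps[k]) >= threshold) {
        members[[k]]$ids <- c(members[[k]]$ids, ids[i])
        members[[k]]$seqs <- c(members[[k]]$seqs, seqs[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, seqs[i])
      members[[length(reps)]] <- list(ids = ids[i], seqs = seqs[i])
    }
  }
  lapply(seq_along(reps), function(k)
    list(representative = reps[k],
         member_ids = members[[k]]$ids,
         member_seqs = members[[k]]$seqs))
}

## Canonical processing order for greedy clustering: descending
## exact-duplicate multiplicity, then descending length, then lexicographic.
## Seeding with the most frequent variants stabilises representatives.
canonical_order <- function(seqs) {
  mult <- table(seqs)
  m <- as.integer(mult[seqs])
  order(-m, -nchar(seqs), seqs)
}

#' Peak-weighted sequence sampling
#'
#' When a size cluster holds more members than `sampling_threshold`, a
#' subset is drawn without replacement with probability proportional to
#' `1 / (1 + |length - peak_position|)`, overweighting sequences near the
#' peak (more likely bona fide family members than boundary artifacts).
#'
#' @param ids,lengths Parallel vectors describing the members.
#' @param peak_position Peak size, bp.
#' @param sampling_threshold Maximum retained (default 200).
#' @param seed RNG seed (sampling is deterministic given the seed).
#' @return List with `idx` (indices of retained members, input order
#'   preserved) and `sampled` (logical, whether sampling occurred).
#' @export
sample_cluster_sequences <- function(ids, lengths, peak_position,
                                     sampling_threshold = 200L, seed = 42L) {
  stopifnot(sampling_threshold >= 1L, length(ids) == length(lengths))
  n <- length(ids)
  if (n <= sampling_threshold)
    return(list(idx = seq_len(n), sampled = FALSE))
  w <- 1 / (1 + abs(lengths - peak_position))
  idx <- with_seed(seed, sample.int(n, sampling_threshold, prob = w))
  list(idx = sort(idx), sampled = TRUE)
}

#' Select a cluster's reported representative
#'
#' `most_frequent`: modal exact sequence (ties lexicographic smallest);
#' `longest`: maximal length (ties lexicographic); `median_length`: member
#' nearest the median member length (ties shorter, then lexicographic).
#'
#' @param member_seqs Character vector of member sequences (non-empty).
#' @param strategy One of `"most_frequent"`, `"longest"`, `"median_length"`.
#' @return A single sequence.
#' @export
select_representative <- function(member_seqs,
                                  strategy = c("most_frequent", "longest",
                                               "median_length")) {
  strategy <- match.arg(strategy)
  stopifnot(length(member_seqs) >= 1L)
  switch(strategy,
    most_frequent = {
      tab <- table(member_seqs)
      cand <- names(tab)[tab == max(tab)]
      sort(cand)[1L]
    },
    longest = {
      cand <- member_seqs[nchar(member_seqs) == max(nchar(member_seqs))]
      sort(cand)[1L]
    },
    median_length = {
      med <- stats::median(nchar(member_seqs))
      d <- abs(nchar(member_seqs) - med)
      cand <- member_seqs[d == min(d)]
      cand <- cand[nchar(cand) == min(nchar(cand))]
      sort(cand)[1L]
    })
}

#' Extrapolate sampled cluster sizes to the full peak
#'
#' `estimated_total = round(members * n_total / n_sampled)` (round half to
#' even, R's default); with no sampling the estimate equals the member
#' count.
#'
#' @param member_counts Integer vector of per-cluster member counts
#'   (must sum to `n_sampled`).
#' @param n_total Total members in the size cluster.
#' @param n_sampled Members actually clustered.
#' @return Integer vector of estimated totals.
#' @export
extrapolate_counts <- function(member_counts, n_total, n_sampled) {
  if (n_sampled == 0L) stop("extrapolate_counts: n_sampled must be positive")
  stopifnot(n_sampled <= n_total, sum(member_counts) == n_sampled)
  if (n_sampled == n_total) return(as.integer(member_counts))
  as.integer(round(member_counts * n_total / n_sampled))
}

#' Cluster the sequences of one size peak into subfamilies
#'
#' Restricts the calls to the peak's size range, applies peak-weighted
#' sampling when needed, pre-groups by length, greedily clusters each
#' length group (canonical order: descending duplicate multiplicity, then
#' descending length, then lexicographic), selects representatives, and
#' extrapolates member counts back to the full peak.
#'
#' @param calls Calls table (sequences required; truncated or empty
#'   sequences are excluded).
#' @param cluster One row of a `size_clusters` object.
#' @param config A [peak_config()].
#' @return A data.frame with one row per sequence cluster: `cluster_id`,
#'   `member_count`, `estimated_total`, `sampled`, `representative`, and a
#'   list column `member_ids` (row indices into `calls`).
#' @export
cluster_peak_sequences <- function(calls, cluster, config = peak_config()) {
  in_peak <- which(calls$length >= cluster$start &
                   calls$length <= cluster$end &
                   nzchar(calls$sequence) & !calls$truncated)
  if (!length(in_peak)) return(empty_sequence_clusters())
  n_total <- length(in_peak)
  samp <- sample_cluster_sequences(in_peak, calls$length[in_peak],
                                   cluster$peak_position,
                                   config$sampling_threshold,
                                   seed = config$rng_seed)
  use <- in_peak[samp$idx]
  seqs <- calls$sequence[use]
  ord <- canonical_order(seqs)
  seqs <- seqs[ord]
  ids <- use[ord]
  grp <- length_groups(nchar(seqs), config$length_tolerance)
  out <- list()
  for (g in sort(unique(grp))) {
    sel <- grp == g
    out <- c(out, greedy_cluster(ids[sel], seqs[sel],
                                 config$identity_threshold))
  }
  member_counts <- vapply(out, function(cl) length(cl$member_ids), integer(1))
  est <- extrapolate_counts(member_counts, n_total, length(use))
  df <- data.frame(
    cluster_id = seq_along(out),
    member_count = member_counts,
    estimated_total = est,
    sampled = samp$sampled,
    representative = vapply(out, function(cl)
      select_representative(cl$member_seqs, config$consensus_strategy),
      character(1)),
    stringsAsFactors = FALSE)
  df$member_ids <- lapply(out, function(cl) cl$member_ids)
  df <- df[order(-df$member_count, df$representative), , drop = FALSE]
  df$cluster_id <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

empty_sequence_clusters <- function() {
  df <- data.frame(cluster_id = integer(0), member_count = integer(0),
                   estimated_total = integer(0), sampled = logical(0),
                   representative = character(0), stringsAsFactors = FALSE)
  df$member_ids <- list()
  df
}
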