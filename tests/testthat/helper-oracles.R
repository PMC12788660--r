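# Independent oracles used to validate the package's primitives.

# Plain-R dynamic program for the LCS length. Written independently of the
# package's compiled routine; kept for small inputs only.
r_lcs <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) return(0L)
  prev <- integer(m + 1)
  for (i in seq_len(n)) {
    cur <- integer(m + 1)
    for (j in seq_len(m)) {
      cur[j + 1] <- if (x[i] == y[j]) prev[j] + 1L
                    else max(prev[j + 1], cur[j])
    }
    prev <- cur
  }
  prev[m + 1]
}

# Library-based oracle: optimal global alignment score under match = 1,
# mismatch = 0, gap = 0 equals the LCS length.
biostrings_lcs <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                  baseOnly = TRUE)
  as.integer(Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = mat, gapOpening = 0, gapExtension = 0,
    type = "global")))
}

# Independent re-implementation of the greedy first-fit rule: each
# sequence joins the first cluster whose frozen representative reaches the
# identity threshold, else seeds a new cluster.
first_fit_oracle <- function(ids, seqs, threshold) {
  reps <- character(0)
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    k <- 0L
    for (r in seq_along(reps)) {
      if (pairwise_identity(seqs[i], reps[r]) >= threshold) { k <- r; break }
    }
    if (k == 0L) {
      reps <- c(reps, seqs[i])
      k <- length(reps)
    }
    assign[i] <- k
  }
  list(assign = assign, reps = reps)
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Two consensus sequences with deliberately low mutual identity: biased,
# disjointly weighted alphabets keep the LCS short.
low_identity_pair <- function(n) {
  a <- rand_seq(n, c("A", "A", "A", "C", "C", "G"))
  b <- rand_seq(n, c("T", "T", "T", "G", "G", "C"))
  list(a = a, b = b)
}

make_calls <- function(lens, chrom = "chr1", sample_id = "s1",
                       pos = NULL, seqs = "") {
  insertion_calls(sample_id = sample_id, chrom = chrom,
                  pos = pos %||% seq_along(lens) * 1000L,
                  length = lens, sequence = seqs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
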