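# Unit tests use a scaled-down element (200 bp LTR, 800 bp internal) so
# each case runs in milliseconds; the full-size geometry is exercised by
# the acceptance suite.

ltr_len <- 200L
int_len <- 800L

make_erv_parts <- function(seed = 31) {
  set.seed(seed)
  list(ltr = rand_seq(ltr_len), int = rand_seq(int_len))
}

test_that("range consensus is the per-column majority at the modal length", {
  s <- rand_seq(50)
  calls <- insertion_calls(c("a", "b", "c"), "chr1", c(1L, 2L, 3L), 50L,
                           c(s, s, s))
  expect_equal(build_range_consensus(calls, 40L, 60L), s)

  # majority at one column
  s2 <- s; substr(s2, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                         substr(s, 10, 10))[1]
  calls2 <- insertion_calls(c("a", "b", "c"), "chr1", 1:3, 50L,
                            c(s, s, s2))
  expect_equal(build_range_consensus(calls2, 40L, 60L), s)
  expect_error(build_range_consensus(insertion_calls(), 40L, 60L),
               "no usable")
})

test_that("majority vote recovers a planted consensus from mutated copies", {
  for (sd in 1:10) {
    set.seed(sd)
    cons <- rand_seq(300)
    copies <- vapply(1:50, function(i) {
      b <- strsplit(cons, "")[[1]]
      hit <- which(runif(300) < 0.02)
      for (j in hit) b[j] <- sample(setdiff(c("A", "C", "G", "T"), b[j]), 1)
      paste(b, collapse = "")
    }, character(1))
    calls <- insertion_calls(paste0("s", 1:50), "chr1",
                             seq_len(50) * 1000L, 300L, copies)
    expect_equal(build_range_consensus(calls, 290L, 310L), cons)
  }
})

test_that("LTR locus filtering keeps only carriers at threshold identity", {
  set.seed(32)
  parts <- make_erv_parts()
  mut <- function(s, k) {
    b <- strsplit(s, "")[[1]]
    i <- sample(length(b), k)
    b[i] <- vapply(b[i], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    paste(b, collapse = "")
  }
  near <- mut(parts$ltr, 10L)       # ~95% identity
  p <- low_identity_pair(ltr_len)   # decoy far from the consensus
  calls <- insertion_calls(c("a", "b", "c"), "chr1",
                           c(1000L, 1004L, 50000L), ltr_len,
                           c(parts$ltr, near, p$b))
  loci <- extract_loci(calls, c(150L, 250L), 50L)
  kept <- filter_ltr_loci(loci, parts$ltr, 0.85)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$n_carriers, 2L)
})

test_that("proximal locus merging is transitive and monotone", {
  calls <- insertion_calls(letters[1:3], "chr1", c(0L, 9000L, 18000L) + 1L,
                           246L, "")
  loci <- extract_loci(calls, c(200L, 300L), 50L)
  expect_equal(nrow(loci), 3L)
  m <- merge_proximal_loci(loci, 10000L)
  expect_equal(nrow(m), 1L)   # chain links transitively
  expect_equal(m$n_members, 3L)
  expect_equal(nrow(merge_proximal_loci(loci, 4000L)), 3L)

  # every input locus lands in exactly one merged locus
  expect_setequal(unlist(m$member_locus_ids), loci$locus_id)

  n_prev <- Inf
  for (d in c(0L, 1000L, 5000L, 10000L, 50000L)) {
    n <- nrow(merge_proximal_loci(loci, d))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("internal candidates require strict length excess inside the padded interval", {
  merged <- data.frame(merged_id = "m1", chrom = "chr1", start = 1000L,
                       end = 2000L, n_members = 1L)
  merged$member_locus_ids <- list("l1")
  merged$carriers <- list(c(a = ""))
  mk <- function(len, pos) insertion_calls("a", "chr1", pos, len,
                                           rand_seq(len))
  set.seed(33)
  expect_equal(nrow(find_internal_candidates(merged, mk(4500L, 1500L),
                                             4000L, 50L)), 1L)
  expect_equal(nrow(find_internal_candidates(merged, mk(3999L, 1500L),
                                             4000L, 50L)), 0L)
  expect_equal(nrow(find_internal_candidates(merged, mk(4000L, 1500L),
                                             4000L, 50L)), 0L)  # strict >
  expect_equal(nrow(find_internal_candidates(merged, mk(5000L, 4000L),
                                             4000L, 50L)), 0L)  # outside pad
  expect_equal(nrow(find_internal_candidates(merged, mk(5000L, 2049L),
                                             4000L, 50L)), 1L)  # inside pad
})

test_that("split-half validation classifies planted, half, and random cases", {
  set.seed(34)
  parts <- make_erv_parts()
  full <- paste0(parts$ltr, parts$int, parts$ltr)
  one_half <- paste0(parts$ltr, parts$int, rand_seq(ltr_len))
  none <- rand_seq(nchar(full))
  cand <- insertion_calls(c("a", "b", "c"), "chr1", c(1L, 2L, 3L),
                          nchar(full), c(full, one_half, none))
  cand$merged_id <- "m1"
  cand$half_identity_1 <- cand$half_identity_2 <- NA_real_
  cand$status <- NA_character_
  out <- validate_full_length(cand, parts$ltr, 0.85, stride = 10L)
  expect_equal(out$status, c("full_length", "rejected_one_half",
                             "rejected_both_halves"))
  expect_equal(out$half_identity_1[1], 1.0)
  expect_equal(out$half_identity_2[1], 1.0)
  expect_lt(out$half_identity_2[2], 0.85)
})

test_that("truncated candidate sequences are rejected with a distinct flag", {
  set.seed(35)
  long <- rand_seq(10500)
  cand <- insertion_calls("a", "chr1", 1L, 10500L, long)
  cand$merged_id <- "m1"
  cand$half_identity_1 <- cand$half_identity_2 <- NA_real_
  cand$status <- NA_character_
  out <- validate_full_length(cand, rand_seq(200L), 0.85)
  expect_equal(out$status, "rejected_truncated")
})

test_that("brute-force internal scan reports embedded internals, not decoys", {
  set.seed(36)
  parts <- make_erv_parts()
  full <- paste0(parts$ltr, parts$int, parts$ltr)
  decoy <- rand_seq(nchar(full), c("A", "A", "A", "C"))  # low coverage
  calls <- insertion_calls(c("a", "b"), "chr1", c(1L, 2L), nchar(full),
                           c(full, decoy))
  hits <- brute_force_internal_scan(calls, parts$int, internal_min = 1000L,
                                    min_identity = 0.85)
  expect_equal(hits$sample_id, "a")
  expect_equal(hits$internal_identity, 1.0)
})

test_that("the peak route's full-length set is a subset of the brute-force scan", {
  erv_spec <- list(ltr_length = ltr_len, internal_length = 1200L,
                   n_full = 5L, n_solo = 20L, af = 0.5, p_full = 0.5)
  pop <- simulate_population(
    families = list(), groups = c(A = 6L, B = 6L), erv_spec = erv_spec,
    background_rate = 10L, background_range = c(1300L, 3000L),
    contigs = c(chr1 = 3e7, chr2 = 3e7), min_spacing = 25000L, seed = 5L)
  res <- reconstruct_erv(pop$calls, ltr_ranges = list(c(ltr_len - 5L,
                                                        ltr_len + 5L)),
                         merge_distance = 10000L, internal_min = 1200L)
  expect_gt(nrow(res$full_length), 0L)
  bf <- brute_force_internal_scan(pop$calls,
                                  attr(pop$erv_truth, "internal_consensus"),
                                  internal_min = 1200L)
  key <- function(df) paste(df$sample_id, df$chrom, df$pos)
  expect_true(all(key(res$full_length) %in% key(bf)))
})
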