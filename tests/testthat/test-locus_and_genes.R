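two_group_calls <- function() {
  insertion_calls(
    sample_id = c("a", "b", "c"), chrom = "chr1",
    pos = c(1000L, 1004L, 1015L), length = 246L, sequence = "")
}

test_that("breakpoints within tolerance merge into one locus", {
  loci <- extract_loci(two_group_calls(), c(200L, 300L), 50L)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$n_carriers, 3L)
  expect_equal(loci$position, 1004L)  # median breakpoint
  expect_equal(c(loci$interval_start, loci$interval_end), c(1000L, 1015L))

  far <- insertion_calls(c("a", "b"), "chr1", c(1000L, 2000L), 246L, "")
  expect_equal(nrow(extract_loci(far, c(200L, 300L), 50L)), 2L)
})

test_that("single linkage is transitive and one carrier per sample wins", {
  chain <- insertion_calls(c("a", "b", "c"), "chr1",
                           c(1000L, 1040L, 1080L), 246L, "")
  expect_equal(nrow(extract_loci(chain, c(200L, 300L), 50L)), 1L)

  dup <- insertion_calls(c("a", "a", "b"), "chr1", c(1000L, 1005L, 1010L),
                         c(240L, 250L, 246L), "")
  loci <- extract_loci(dup, c(200L, 300L), 50L)
  expect_equal(loci$n_carriers, 2L)
  expect_equal(unname(loci$carrier_lengths[[1]]["a"]), 250L)  # longest
})

test_that("locus extraction is invariant to sample order", {
  set.seed(21)
  calls <- insertion_calls(
    sample_id = sample(letters[1:6], 60, replace = TRUE),
    chrom = sample(c("chr1", "chr2"), 60, replace = TRUE),
    pos = sample(1:20, 60, replace = TRUE) * 5000L +
      sample(-20:20, 60, replace = TRUE),
    length = 246L, sequence = "")
  a <- extract_loci(calls, c(200L, 300L), 50L)
  b <- extract_loci(calls[sample(nrow(calls)), ], c(200L, 300L), 50L)
  expect_equal(a$position, b$position)
  expect_equal(a$chrom, b$chrom)
  expect_equal(lapply(a$carriers, names), lapply(b$carriers, names))
})

test_that("raising the breakpoint tolerance never increases locus count", {
  set.seed(22)
  calls <- insertion_calls(
    sample_id = sample(letters[1:5], 80, replace = TRUE), chrom = "chr1",
    pos = sort(sample(1:100000, 80)), length = 246L, sequence = "")
  n_prev <- Inf
  for (tol in c(0L, 10L, 100L, 1000L, 10000L)) {
    n <- nrow(extract_loci(calls, c(200L, 300L), tol))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("consensus filtering keeps planted loci and drops decoys", {
  set.seed(23)
  p <- low_identity_pair(246)
  mut <- function(s, k) {
    b <- strsplit(s, "")[[1]]
    i <- sample(length(b), k)
    b[i] <- vapply(b[i], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    paste(b, collapse = "")
  }
  calls <- insertion_calls(
    sample_id = rep(c("a", "b"), 4),
    chrom = "chr1", pos = rep(c(1e3, 5e3, 9e3, 13e3), each = 2) + c(0, 4),
    length = 246L,
    sequence = c(mut(p$a, 12), mut(p$a, 12),   # planted ~95% identity
                 mut(p$a, 12), mut(p$a, 12),
                 mut(p$b, 12), mut(p$b, 12),   # decoy family
                 mut(p$b, 12), mut(p$b, 12)))
  loci <- extract_loci(calls, c(200L, 300L), 50L)
  expect_equal(nrow(loci), 4L)
  kept <- filter_loci_by_consensus(loci, p$a, 0.85)
  expect_equal(nrow(kept), 2L)
  expect_true(all(kept$position < 9000))
  # carriers below threshold are dropped from kept loci
  expect_true(all(vapply(kept$carriers, function(cs)
    all(vapply(cs, function(s) pairwise_identity(s, p$a) >= 0.85,
               logical(1))), logical(1))))
})

test_that("group AF is the carrier fraction among passing samples", {
  groups <- setNames(rep(c("G1", "G2"), each = 4),
                     paste0("s", 1:8))
  calls <- insertion_calls(paste0("s", c(1, 2, 3, 5)), "chr1",
                           c(1000L, 1001L, 1002L, 1003L), 246L, "")
  loci <- extract_loci(calls, c(200L, 300L), 50L)
  af <- compute_group_af(loci, groups)
  expect_equal(af[1, "G1"], 0.75)
  expect_equal(af[1, "G2"], 0.25)

  # carriers outside passing_samples are excluded from the numerator
  af2 <- compute_group_af(loci, groups,
                          passing_samples = paste0("s", c(2:4, 5:8)))
  expect_equal(af2[1, "G1"], 2 / 3)

  # a fully carried group reaches 1
  all_calls <- insertion_calls(paste0("s", 1:4), "chr1",
                               1000L + 0:3, 246L, "")
  af3 <- compute_group_af(extract_loci(all_calls, c(200L, 300L), 50L),
                          groups)
  expect_equal(af3[1, "G1"], 1.0)
})

test_that("simulated Bernoulli carriers recover the planted AF", {
  af_true <- c(G1 = 0.3, G2 = 0.8)
  n_per <- 25L
  groups <- setNames(rep(names(af_true), each = n_per),
                     paste0("s", seq_len(2 * n_per)))
  for (sd in 1:20) {
    set.seed(sd)
    carriers <- names(groups)[runif(length(groups)) <
                                af_true[groups[names(groups)]]]
    if (length(carriers) == 0) next
    calls <- insertion_calls(carriers, "chr1",
                             1000L + seq_along(carriers) %% 41L, 246L, "")
    af <- compute_group_af(extract_loci(calls, c(200L, 300L), 50L), groups)
    for (g in names(af_true)) {
      se <- sqrt(af_true[[g]] * (1 - af_true[[g]]) / n_per)
      expect_lte(abs(af[1, g] - af_true[[g]]), 3 * se)
    }
  }
})

test_that("AF filtering honours any-group vs all-groups scope", {
  af <- matrix(c(0.8, 0.1), 1, dimnames = list("locus_00001", c("A", "B")))
  loci <- extract_loci(insertion_calls("a", "chr1", 1L, 246L, ""),
                       c(200L, 300L), 50L)
  expect_equal(nrow(filter_af(loci, af, 0.75, "any_group")$loci), 1L)
  expect_equal(nrow(filter_af(loci, af, 0.75, "all_groups")$loci), 0L)
  expect_equal(nrow(filter_af(loci, af, 0, "all_groups")$loci), 1L)
})

test_that("shared-loci matrix equals the brute-force double loop", {
  set.seed(24)
  af <- matrix(runif(60), 15, 4, dimnames = list(NULL, LETTERS[1:4]))
  m <- shared_loci_matrix(af, 0.75)
  expect_true(isSymmetric(m))
  for (g in 1:4) for (h in 1:4) {
    expect_equal(m[g, h], sum(af[, g] >= 0.75 & af[, h] >= 0.75))
    expect_gte(m[g, g], m[g, h])
  }
  one <- matrix(c(1, 1), 1, dimnames = list(NULL, c("A", "B")))
  expect_equal(shared_loci_matrix(one, 0.75)["A", "B"], 1L)
  not <- matrix(c(0.8, 0.6), 1, dimnames = list(NULL, c("A", "B")))
  expect_equal(shared_loci_matrix(not, 0.75)["A", "B"], 0L)
})

test_that("presence matrix marks carriers with consistent marginals", {
  calls <- insertion_calls(c("a", "a", "b"), "chr1",
                           c(1000L, 5000L, 1002L), 246L, "")
  loci <- extract_loci(calls, c(200L, 300L), 50L)
  m <- presence_matrix(loci, c("a", "b"))
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(unname(rowSums(m)), c(2, 1))
  expect_equal(unname(m["b", ]), c(1, 0))
})

test_that("feature classification follows CDS > UTR > exon > intron precedence", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(paste(c(
    'chr1\tx\tgene\t1000\t5000\t.\t+\t.\tgene_id "G1";',
    'chr1\tx\texon\t1200\t1400\t.\t+\t.\tgene_id "G1";',
    'chr1\tx\tCDS\t1250\t1350\t.\t+\t.\tgene_id "G1";',
    'chr1\tx\tfive_prime_utr\t1200\t1249\t.\t+\t.\tgene_id "G1";'),
    collapse = "\n"), gtf)
  ann <- read_gene_annotation(gtf)
  mk <- function(pos) {
    calls <- insertion_calls("a", "chr1", pos, 246L, "")
    extract_loci(calls, c(200L, 300L), 0L)
  }
  expect_equal(classify_features(mk(1300L), ann)$feature_type, "CDS")
  expect_equal(classify_features(mk(1220L), ann)$feature_type, "UTR")
  expect_equal(classify_features(mk(1380L), ann)$feature_type, "exon")
  intron <- classify_features(mk(3000L), ann)
  expect_equal(intron$feature_type, "intron")
  expect_equal(intron$gene_id, "G1")
  inter <- classify_features(mk(9000L), ann)
  expect_equal(inter$feature_type, "intergenic")
  expect_true(is.na(inter$gene_id))
})

test_that("malformed GTF lines fail fatally with the line number", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c('chr1\tx\tgene\t1\t10\t.\t+\t.\tgene_id "G";',
               "chr1\tbroken line"), gtf)
  expect_error(read_gene_annotation(gtf), "line 2")
})

test_that("presence embedding is deterministic and separates planted groups", {
  set.seed(25)
  m <- matrix(0L, 40, 30)
  m[1:20, 1:15] <- rbinom(300, 1, 0.9)    # group 1 loci
  m[21:40, 16:30] <- rbinom(300, 1, 0.9)  # group 2 loci
  rownames(m) <- paste0("s", 1:40)
  e1 <- embed_presence(m, seed = 42L)
  e2 <- embed_presence(m, seed = 42L)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(40L, 2L))
  expect_true(all(is.finite(e1)))
  intra <- c(dist(e1[1:20, ]), dist(e1[21:40, ]))
  inter <- as.matrix(dist(e1))[1:20, 21:40]
  expect_gt(mean(inter), mean(intra))
  expect_error(embed_presence(m[1:2, ]), "at least 3")
})

test_that("group clustering merges identical AF profiles first", {
  af <- rbind(A = c(1, 0, 0), B = c(1, 0, 0), C = c(0, 1, 1))
  tree <- cluster_groups(af)
  expect_setequal(tree$labels, c("A", "B", "C"))
  expect_equal(tree$height[1], 0)
  first <- sort(tree$labels[-tree$merge[1, ]])
  expect_equal(first, c("A", "B"))

  # orthogonal one-hot rows merge at their Euclidean distances
  oh <- rbind(X = c(1, 0), Y = c(0, 1))
  t2 <- cluster_groups(oh)
  expect_equal(t2$height, sqrt(2))
})
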