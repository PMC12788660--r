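test_that("mutation at divergence zero is the identity", {
  s <- rand_seq(100)
  expect_identical(mutate_sequence(s, 0, 1L), s)
})

test_that("mutated fraction matches the binomial expectation", {
  set.seed(41)
  cons <- rand_seq(1000)
  fracs <- vapply(1:100, function(sd) {
    m <- mutate_sequence(cons, 0.05, sd)
    mean(strsplit(m, "")[[1]] != strsplit(cons, "")[[1]])
  }, numeric(1))
  se <- sqrt(0.05 * 0.95 / 1000 / 100)
  expect_lte(abs(mean(fracs) - 0.05), 3 * se)
  # and identity to the consensus stays high
  expect_gte(pairwise_identity(cons, mutate_sequence(cons, 0.05, 7L)), 0.90)
})

test_that("mutation is deterministic under the seed", {
  cons <- rand_seq(500)
  expect_identical(mutate_sequence(cons, 0.1, 9L),
                   mutate_sequence(cons, 0.1, 9L))
})

test_that("allele frequency extremes produce all or no carriers", {
  fam1 <- synthetic_family("F", modal_length = 246, length_jitter_sd = 0,
                           per_copy_divergence = 0, n_loci = 1L,
                           group_af = c(A = 1.0))
  pop1 <- simulate_population(list(fam1), groups = c(A = 4L),
                              background_rate = 0L, seed = 3L)
  expect_equal(sort(unique(pop1$calls$sample_id)), sort(pop1$samples))

  fam0 <- synthetic_family("F", modal_length = 246, group_af = c(A = 0.0))
  pop0 <- simulate_population(list(fam0), groups = c(A = 4L),
                              background_rate = 0L, seed = 3L)
  expect_equal(nrow(pop0$calls), 0L)
})

test_that("simulation is deterministic and complete against its truth table", {
  fams <- list(synthetic_family("F1", modal_length = 246,
                                n_loci = 5L, group_af = c(A = 0.6, B = 0.4)))
  p1 <- simulate_population(fams, groups = c(A = 4L, B = 4L),
                            background_rate = 10L, seed = 13L)
  p2 <- simulate_population(fams, groups = c(A = 4L, B = 4L),
                            background_rate = 10L, seed = 13L)
  expect_identical(p1$calls, p2$calls)

  # truth completeness: every record is planted or background
  n_planted <- sum(p1$truth$n_carriers)
  n_background <- 10L * length(p1$samples)
  expect_equal(nrow(p1$calls), n_planted + n_background)

  # changing the seed changes the draw
  p3 <- simulate_population(fams, groups = c(A = 4L, B = 4L),
                            background_rate = 10L, seed = 14L)
  expect_false(identical(p1$calls, p3$calls))
})

test_that("a family AF for an unknown group is a config error", {
  fam <- synthetic_family("F", modal_length = 246,
                          group_af = c(A = 0.5, Z = 0.5))
  expect_error(simulate_population(list(fam), groups = c(A = 2L),
                                   background_rate = 0L, seed = 1L),
               "unknown group")
})

test_that("emitted VCFs are accepted unchanged by the reader", {
  fams <- list(synthetic_family("F1", modal_length = 300, n_loci = 4L,
                                group_af = c(A = 0.8)))
  pop <- simulate_population(fams, groups = c(A = 3L),
                             background_rate = 5L, seed = 17L)
  d <- tempfile()
  write_population(pop, d)
  for (s in pop$samples) {
    back <- read_insertion_vcf(file.path(d, paste0(s, ".vcf")), s)
    orig <- pop$calls[pop$calls$sample_id == s, , drop = FALSE]
    orig <- orig[order(orig$chrom, orig$pos), , drop = FALSE]
    expect_equal(back$pos, orig$pos)
    expect_equal(back$length, orig$length)
    expect_equal(back$sequence, orig$sequence)
  }
  g <- read_group_table(file.path(d, "groups.tsv"))
  expect_equal(sort(names(g)), sort(pop$samples))
})

test_that("a YAML simulation spec reproduces the in-code configuration", {
  spec <- system.file("extdata", "example_sim.yaml", package = "peakTE")
  args <- read_sim_spec(spec)
  expect_length(args$families, 2L)
  expect_equal(args$families[[1]]$modal_length, 246L)
  expect_equal(args$families[[1]]$group_af, c(A = 0.7, B = 0.3))
  expect_equal(args$groups, c(A = 10L, B = 10L))
  expect_equal(args$erv_spec$n_full, 4L)
  expect_equal(args$seed, 42L)
  # the YAML arguments are accepted by the generator (scaled down for speed)
  args$families <- args$families[1]
  args$erv_spec <- NULL
  args$groups <- c(A = 2L, B = 2L)
  args$background_rate <- 2L
  pop <- do.call(simulate_population, args)
  expect_s3_class(pop, "synthetic_population")
  expect_gt(nrow(pop$calls), 0L)
})

test_that("end-to-end discovery recovers planted families, AFs and ERVs", {
  fams <- list(
    synthetic_family("SINE1", modal_length = 246, length_jitter_sd = 3,
                     per_copy_divergence = 0.02, n_loci = 25L,
                     group_af = c(A = 0.7, B = 0.3)),
    synthetic_family("LINE1", modal_length = 3000, length_jitter_sd = 8,
                     per_copy_divergence = 0.02, n_loci = 15L,
                     group_af = c(A = 0.5, B = 0.5)))
  pop <- simulate_population(
    fams, groups = c(A = 10L, B = 10L),
    erv_spec = list(ltr_length = 500L, internal_length = 4450L,
                    n_full = 4L, n_solo = 15L, af = 0.6, p_full = 0.5),
    background_rate = 60L, contigs = c(chr1 = 2e8, chr2 = 2e8),
    min_spacing = 25000L, seed = 29L)

  peaks <- detect_peaks(pop$calls)
  for (m in c(246, 500, 3000))
    expect_true(any(peaks$start <= m & peaks$end >= m),
                info = paste("modal", m))

  # >= 95% of planted SINE loci recovered at the 246 peak
  i <- which(peaks$start <= 246 & peaks$end >= 246)[1]
  loci <- extract_loci(pop$calls, c(peaks$start[i], peaks$end[i]), 50L)
  truth <- pop$truth[pop$truth$family == "SINE1", ]
  hit <- vapply(seq_len(nrow(truth)), function(k)
    any(loci$chrom == truth$chrom[k] &
          abs(loci$position - truth$position[k]) <= 50), logical(1))
  expect_gte(mean(hit), 0.95)

  # group AFs near the planted values
  af <- compute_group_af(loci, pop$groups)
  matched <- vapply(seq_len(nrow(loci)), function(j) {
    k <- which(truth$chrom == loci$chrom[j] &
                 abs(truth$position - loci$position[j]) <= 50)
    if (length(k)) k[1] else NA_integer_
  }, integer(1))
  for (g in c("A", "B")) {
    tr <- fams[[1]]$group_af[[g]]
    se <- sqrt(tr * (1 - tr) / 10)
    errs <- abs(af[!is.na(matched), g] - tr)
    expect_lte(mean(errs), 3 * se)
  }

  # every planted full-length ERV locus recovered
  res <- reconstruct_erv(pop$calls, ltr_ranges = list(c(495L, 505L)),
                         internal_min = 4000L)
  full_truth <- Filter(function(r) r$type == "full", pop$erv_truth)
  rec <- vapply(full_truth, function(r)
    any(res$full_length$chrom == r$chrom &
          abs(res$full_length$pos - r$position) <= 100), logical(1))
  expect_true(all(rec))
})
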