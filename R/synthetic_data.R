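## Synthetic multi-sample insertion-call generator.
##
## Emulates the statistical structure the pipeline assumes in real
## cohorts: TE families with characteristic modal lengths and small
## length jitter, per-copy sequence divergence from a family consensus,
## group-stratified allele frequencies, solo-LTR and full LTR-INT-LTR
## elements at shared loci, and a uniform background of unrelated
## structural-variant insertions. Everything is deterministic under the
## supplied seed and ships with a truth table for end-to-end checks.

#' Define a synthetic TE family
#'
#' @param name Family name.
#' @param consensus Family consensus sequence (generated at `modal_length`
#'   from the family seed if omitted).
#' @param modal_length Characteristic insertion length, bp.
#' @param length_jitter_sd SD of per-copy length jitter, bp.
#' @param per_copy_divergence Per-base substitution probability applied to
#'   each emitted copy (0 = exact copies).
#' @param n_loci Number of distinct genomic loci carrying the family.
#' @param group_af Named vector of per-group allele frequencies (the
#'   probability each sample of that group carries each locus).
#' @return List of class `synthetic_family`.
#' @export
synthetic_family <- function(name, consensus = NULL, modal_length,
                             length_jitter_sd = 3, per_copy_divergence = 0.02,
                             n_loci = 10L, group_af) {
  stopifnot(per_copy_divergence >= 0, per_copy_divergence < 1, n_loci >= 1L,
            all(group_af >= 0), all(group_af <= 1))
  structure(list(name = name, consensus = consensus,
                 modal_length = as.integer(modal_length),
                 length_jitter_sd = length_jitter_sd,
                 per_copy_divergence = per_copy_divergence,
                 n_loci = as.integer(n_loci), group_af = group_af),
            class = "synthetic_family")
}

#' Point-mutate a sequence
#'
#' Each base is independently substituted with probability `divergence`,
#' uniformly over the three alternative bases; deterministic under `seed`.
#'
#' @param consensus Nucleotide string.
#' @param divergence Substitution probability per base, in \[0, 1).
#' @param seed RNG seed.
#' @return Mutated string of the same length.
#' @export
mutate_sequence <- function(consensus, divergence, seed) {
  stopifnot(divergence >= 0, divergence < 1)
  if (divergence == 0) return(consensus)
  with_seed(seed, {
    b <- strsplit(consensus, "", fixed = TRUE)[[1L]]
    hit <- which(stats::runif(length(b)) < divergence)
    for (i in hit)
      b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
    paste(b, collapse = "")
  })
}

## Fit a drawn length: 3' truncation when shorter, random 3' padding when
## longer (mimics the 5'/3' truncation seen in real elements while keeping
## identity to the consensus high).
fit_length <- function(seq, len) {
  n <- nchar(seq)
  if (len <= n) return(substr(seq, 1L, len))
  paste0(seq, random_dna(len - n))
}

#' Simulate a multi-group insertion-call population
#'
#' For every family locus, each sample carries the insertion with its
#' group's allele frequency; carried copies draw a length from
#' `round(Normal(modal_length, jitter))` (clipped at 1), mutate the family
#' consensus at the per-copy divergence, and are fitted to the drawn
#' length by terminal truncation/padding. ERV loci emit full-length
#' LTR+internal+LTR copies in designated carriers and solo LTRs
#' elsewhere. Background insertions are uniform in length over
#' `background_range` with random sequence. Loci are placed uniformly per
#' contig with a minimum spacing so distinct loci stay unambiguous under
#' breakpoint merging; per-sample breakpoints jitter around the locus
#' position by up to `breakpoint_jitter` bp.
#'
#' @param families List of [synthetic_family()] objects.
#' @param groups Named integer vector: samples per group.
#' @param erv_spec Optional list with `ltr_consensus`, `internal_consensus`
#'   (or `internal_length`), `n_full` and `n_solo` loci, `af` (carrier
#'   probability per locus), and `p_full` (probability a carrier at a full
#'   locus holds the full-length element rather than a solo LTR).
#' @param background_rate Background insertions per sample (default 100).
#' @param background_range Length range of background insertions.
#' @param contigs Named integer vector of contig lengths.
#' @param min_spacing Minimum distance between distinct planted loci, bp.
#' @param breakpoint_jitter Max per-sample breakpoint offset, bp.
#' @param with_gtf Also build a toy gene annotation overlapping a known
#'   subset of loci.
#' @param seed Master seed; all randomness derives from it.
#' @return List of class `synthetic_population`: `calls` (pooled calls
#'   table), `samples`, `groups` (sample -> group map), `truth` (per-locus
#'   records with per-sample carrier status), `erv_truth` (per-ERV-locus
#'   records), `families`, `gtf` (data.frame or `NULL`), `seed`.
#' @export
simulate_population <- function(families = list(),
                                groups = c(A = 10L, B = 10L),
                                erv_spec = NULL,
                                background_rate = 100L,
                                background_range = c(100L, 9000L),
                                contigs = c(chr1 = 50000000L,
                                            chr2 = 50000000L),
                                min_spacing = 200L,
                                breakpoint_jitter = 20L,
                                with_gtf = FALSE,
                                seed = 42L) {
  stopifnot(length(groups) >= 1L, !is.null(names(groups)))
  samples <- unlist(lapply(names(groups), function(g)
    sprintf("%s_s%02d", g, seq_len(groups[[g]]))))
  sample_group <- stats::setNames(
    rep(names(groups), times = as.integer(groups)), samples)

  ## family consensus sequences
  families <- lapply(seq_along(families), function(i) {
    f <- families[[i]]
    if (is.null(f$consensus))
      f$consensus <- with_seed(seed + 1000L + i,
                               random_dna(f$modal_length))
    f
  })

  ## locus placement: one global draw with min spacing, assigned in order
  n_fam_loci <- sum(vapply(families, `[[`, integer(1), "n_loci"))
  n_erv_loci <- if (is.null(erv_spec)) 0L
    else (erv_spec$n_full %||% 0L) + (erv_spec$n_solo %||% 0L)
  pos_tab <- with_seed(seed + 1L,
    place_loci(n_fam_loci + n_erv_loci, contigs, min_spacing))

  calls <- list()
  truth <- list()
  li <- 0L
  rec <- function(...) list(...)

  for (fi in seq_along(families)) {
    f <- families[[fi]]
    af <- f$group_af
    if (!all(names(groups) %in% names(af)))
      stop("family '", f$name, "': allele frequency missing for group(s) ",
           paste(setdiff(names(groups), names(af)), collapse = ","))
    if (!all(names(af) %in% names(groups)))
      stop("family '", f$name, "': allele frequency for unknown group(s) ",
           paste(setdiff(names(af), names(groups)), collapse = ","))
    for (k in seq_len(f$n_loci)) {
      li <- li + 1L
      ch <- pos_tab$chrom[li]; p0 <- pos_tab$pos[li]
      carrier <- with_seed(seed + 10000L + li * 7L,
        stats::runif(length(samples)) < af[sample_group[samples]])
      names(carrier) <- samples
      for (s in samples[carrier]) {
        sd_i <- seed + 20000L + li * 131L +
          match(s, samples) * 17L
        emitted <- with_seed(sd_i, {
          len <- max(1L, as.integer(round(stats::rnorm(
            1, f$modal_length, f$length_jitter_sd))))
          sq <- mutate_sequence(f$consensus, f$per_copy_divergence,
                                sd_i + 1L)
          sq <- fit_length(sq, len)
          bp <- p0 + sample.int(2L * breakpoint_jitter + 1L, 1L) -
            breakpoint_jitter - 1L
          list(len = len, sq = sq, bp = bp)
        })
        calls[[length(calls) + 1L]] <- data.frame(
          sample_id = s, chrom = ch, pos = emitted$bp,
          length = emitted$len, sequence = emitted$sq,
          stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1L]] <- rec(
        family = f$name, chrom = ch, position = p0,
        carriers = names(which(carrier)), n_carriers = sum(carrier))
    }
  }

  ## ERV loci: full LTR-INT-LTR in designated carriers, solo LTRs in others
  erv_truth <- list()
  if (!is.null(erv_spec)) {
    ltr <- erv_spec$ltr_consensus %||%
      with_seed(seed + 2L, random_dna(erv_spec$ltr_length %||% 1374L))
    int <- erv_spec$internal_consensus %||%
      with_seed(seed + 3L, random_dna(erv_spec$internal_length %||% 4450L))
    full_seq <- paste0(ltr, int, ltr)
    n_full <- erv_spec$n_full %||% 0L
    n_solo <- erv_spec$n_solo %||% 0L
    af <- erv_spec$af %||% 0.5
    p_full <- erv_spec$p_full %||% 0.5
    for (k in seq_len(n_full + n_solo)) {
      li <- li + 1L
      is_full_locus <- k <= n_full
      ch <- pos_tab$chrom[li]; p0 <- pos_tab$pos[li]
      st <- with_seed(seed + 30000L + li * 13L, {
        carrier <- stats::runif(length(samples)) < af
        full <- carrier & is_full_locus &
          (stats::runif(length(samples)) < p_full)
        ## a full-ERV locus carries both element forms: at least one full
        ## copy and at least one solo LTR (the locus is discoverable from
        ## its LTR-sized insertions)
        if (is_full_locus && !any(full)) {
          i <- if (any(carrier)) which(carrier)[1L] else 1L
          carrier[i] <- TRUE; full[i] <- TRUE
        }
        if (is_full_locus && !any(carrier & !full)) {
          i <- which(!carrier)
          i <- if (length(i)) i[1L] else which(full)[1L]
          carrier[i] <- TRUE; full[i] <- FALSE
        }
        list(carrier = carrier, full = full)
      })
      names(st$carrier) <- names(st$full) <- samples
      for (s in samples[st$carrier]) {
        sq <- if (st$full[[s]]) full_seq else ltr
        bp <- with_seed(seed + 40000L + li * 19L + match(s, samples),
          p0 + sample.int(2L * breakpoint_jitter + 1L, 1L) -
            breakpoint_jitter - 1L)
        calls[[length(calls) + 1L]] <- data.frame(
          sample_id = s, chrom = ch, pos = bp, length = nchar(sq),
          sequence = sq, stringsAsFactors = FALSE)
      }
      erv_truth[[length(erv_truth) + 1L]] <- rec(
        chrom = ch, position = p0,
        type = if (is_full_locus) "full" else "solo",
        carriers = names(which(st$carrier)),
        full_carriers = names(which(st$full)))
    }
    attr(erv_truth, "ltr_consensus") <- ltr
    attr(erv_truth, "internal_consensus") <- int
  }

  ## uniform background, random sequence
  n_truth_records <- length(calls)
  if (background_rate > 0L) {
    for (s in samples) {
      bg <- with_seed(seed + 50000L + match(s, samples) * 23L, {
        n <- background_rate
        len <- sample.int(background_range[2] - background_range[1] + 1L,
                          n, replace = TRUE) + background_range[1] - 1L
        chrom <- sample(names(contigs), n, replace = TRUE)
        pos <- vapply(chrom, function(cn)
          sample.int(contigs[[cn]] - 1000L, 1L) + 500L, integer(1))
        sq <- vapply(len, random_dna, character(1))
        data.frame(sample_id = s, chrom = chrom, pos = pos, length = len,
                   sequence = sq, stringsAsFactors = FALSE)
      })
      calls[[length(calls) + 1L]] <- bg
    }
  }

  calls <- do.call(rbind, calls)
  calls <- insertion_calls(calls$sample_id, calls$chrom, calls$pos,
                           calls$length, calls$sequence)
  calls <- calls[order(calls$sample_id, calls$chrom, calls$pos), ,
                 drop = FALSE]
  rownames(calls) <- NULL

  truth_df <- if (length(truth)) data.frame(
    family = vapply(truth, `[[`, character(1), "family"),
    chrom = vapply(truth, `[[`, character(1), "chrom"),
    position = vapply(truth, function(r) as.integer(r$position), integer(1)),
    n_carriers = vapply(truth, function(r) as.integer(r$n_carriers),
                        integer(1)),
    stringsAsFactors = FALSE) else NULL
  if (!is.null(truth_df))
    truth_df$carriers <- lapply(truth, `[[`, "carriers")

  gtf <- if (with_gtf && !is.null(truth_df))
    toy_gtf(truth_df, contigs) else NULL

  structure(list(calls = calls, samples = samples, groups = sample_group,
                 truth = truth_df, erv_truth = erv_truth,
                 families = families, gtf = gtf, seed = as.integer(seed),
                 n_planted_calls = n_truth_records),
            class = "synthetic_population")
}

## Uniform locus placement with minimum spacing, spread across contigs.
place_loci <- function(n, contigs, min_spacing) {
  if (n == 0L)
    return(data.frame(chrom = character(0), pos = integer(0)))
  per <- ceiling(n / length(contigs))
  remaining <- n
  out <- list()
  for (cn in names(contigs)) {
    slots <- (contigs[[cn]] - 2000L) %/% max(1L, min_spacing)
    k <- min(per, remaining, slots)
    if (k <= 0L) next
    pos <- sort(sample.int(slots, k)) * min_spacing + 1000L
    out[[cn]] <- data.frame(chrom = cn, pos = as.integer(pos),
                            stringsAsFactors = FALSE)
    remaining <- remaining - k
  }
  if (remaining > 0L)
    stop("contigs too small to place ", n, " loci at spacing ", min_spacing)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Toy gene annotation overlapping a deterministic subset of planted loci:
## every third locus gets a gene whose CDS covers the breakpoint, every
## third+1 a gene whose body (but no exon) covers it.
toy_gtf <- function(truth_df, contigs) {
  rows <- list()
  gi <- 0L
  for (i in seq_len(nrow(truth_df))) {
    kind <- i %% 3L
    if (kind == 2L) next  # intergenic by construction
    gi <- gi + 1L
    ch <- truth_df$chrom[i]; p <- truth_df$position[i]
    gid <- sprintf("GENE%04d", gi)
    gene <- c(p - 500L, p + 500L)
    add <- function(feature, start, end)
      rows[[length(rows) + 1L]] <<- data.frame(
        seqname = ch, source = "synthetic", feature = feature,
        start = start, end = end, score = ".", strand = "+", frame = ".",
        attribute = sprintf('gene_id "%s"; transcript_id "%s.t1";',
                            gid, gid),
        stringsAsFactors = FALSE)
    add("gene", gene[1], gene[2])
    if (kind == 0L) {               # CDS over the breakpoint
      add("exon", p - 50L, p + 50L)
      add("CDS", p - 50L, p + 50L)
      add("five_prime_utr", gene[1], gene[1] + 20L)
    } else {                        # intron: exon away from the breakpoint
      add("exon", gene[1], gene[1] + 40L)
    }
  }
  do.call(rbind, rows)
}

#' Read a simulation specification from YAML
#'
#' Keys mirror [simulate_population()] arguments: `families` (list of
#' [synthetic_family()] field sets), `groups` (group -> sample count),
#' `erv` (optional ERV block), plus `background_rate`, `background_range`,
#' `contigs`, `min_spacing`, `seed`.
#'
#' @param path YAML file.
#' @return Named list of arguments for [simulate_population()].
#' @export
read_sim_spec <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  args$families <- lapply(y$families, function(f) {
    f$group_af <- unlist(f$group_af)
    do.call(synthetic_family, f)
  })
  args$groups <- vapply(y$groups, as.integer, integer(1))
  if (!is.null(y$erv)) args$erv_spec <- y$erv
  for (k in c("background_rate", "min_spacing", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- as.integer(y[[k]])
  if (!is.null(y$background_range))
    args$background_range <- as.integer(unlist(y$background_range))
  if (!is.null(y$contigs))
    args$contigs <- vapply(y$contigs, as.numeric, numeric(1))
  if (!is.null(y$with_gtf)) args$with_gtf <- isTRUE(y$with_gtf)
  args
}

#' Write a synthetic population to disk
#'
#' Per-sample VCFs (`<sample>.vcf`), a `groups.tsv` sample-to-group table,
#' `truth.tsv` / `erv_truth.tsv`, and `annotation.gtf` when present.
#'
#' @param pop A `synthetic_population`.
#' @param dir Output directory (created if needed).
#' @param contig_lengths Optional named vector for VCF `##contig` headers.
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir, contig_lengths = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in pop$samples)
    write_insertion_vcf(pop$calls[pop$calls$sample_id == s, , drop = FALSE],
                        file.path(dir, paste0(s, ".vcf")), contig_lengths)
  utils::write.table(
    data.frame(sample_id = names(pop$groups), group = unname(pop$groups)),
    file.path(dir, "groups.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(pop$truth))
    write_tsv_meta(pop$truth, file.path(dir, "truth.tsv"),
                   meta = c(seed = pop$seed))
  if (length(pop$erv_truth)) {
    ervdf <- data.frame(
      chrom = vapply(pop$erv_truth, `[[`, character(1), "chrom"),
      position = vapply(pop$erv_truth, function(r) as.integer(r$position),
                        integer(1)),
      type = vapply(pop$erv_truth, `[[`, character(1), "type"),
      stringsAsFactors = FALSE)
    ervdf$carriers <- lapply(pop$erv_truth, `[[`, "carriers")
    write_tsv_meta(ervdf, file.path(dir, "erv_truth.tsv"),
                   meta = c(seed = pop$seed))
  }
  if (!is.null(pop$gtf))
    utils::write.table(pop$gtf, file.path(dir, "annotation.gtf"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  invisible(dir)
}
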