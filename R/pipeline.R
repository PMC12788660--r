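## End-to-end orchestration: filter -> peaks -> cluster -> annotate ->
## loci -> (erv) -> (popstruct), from a single config, writing a flat
## output hierarchy of TSV/FASTA/BED artifacts. Every table carries a
## metadata header with the package version, a config hash, and the seed,
## and contains no timestamps, so identical runs are byte-identical.

#' Build a pipeline run configuration
#'
#' @param vcf_dir Directory of per-sample VCFs (`<sample>.vcf`), or `NULL`
#'   when `calls` are passed to [run_pipeline()] directly.
#' @param group_table Path to the sample-to-group TSV, or a named vector.
#' @param gtf Optional gene-annotation GTF path.
#' @param consensus_library Optional consensus FASTA for offline family
#'   annotation.
#' @param out_dir Output directory.
#' @param min_size,min_insertions,excluded_contigs Per-sample filtering
#'   (see [filter_sample()]).
#' @param peak A [peak_config()].
#' @param breakpoint_tolerance Cross-sample locus-merging tolerance, bp.
#' @param min_af,af_scope Locus AF filter for the population-structure
#'   stage.
#' @param erv `NULL` to skip ERV reconstruction, else a list of arguments
#'   for [reconstruct_erv()] (e.g. `list(ltr_ranges = list(c(1370, 1380)))`).
#' @param run_popstruct Compute AF-filtered presence matrix, embedding,
#'   shared-loci matrix and group dendrogram.
#' @param annotation_min_identity Offline annotation threshold.
#' @param seed Master seed recorded in all outputs.
#' @return List of class `run_config`.
#' @export
run_config <- function(vcf_dir = NULL, group_table = NULL, gtf = NULL,
                       consensus_library = NULL, out_dir = "peakTE_out",
                       min_size = 100L, min_insertions = 1000L,
                       excluded_contigs = character(0),
                       peak = peak_config(),
                       breakpoint_tolerance = 50L,
                       min_af = 0.75, af_scope = "any_group",
                       erv = NULL, run_popstruct = TRUE,
                       annotation_min_identity = 0.85, seed = 42L) {
  structure(list(vcf_dir = vcf_dir, group_table = group_table, gtf = gtf,
                 consensus_library = consensus_library, out_dir = out_dir,
                 min_size = as.integer(min_size),
                 min_insertions = as.integer(min_insertions),
                 excluded_contigs = excluded_contigs, peak = peak,
                 breakpoint_tolerance = as.integer(breakpoint_tolerance),
                 min_af = min_af, af_scope = af_scope, erv = erv,
                 run_popstruct = run_popstruct,
                 annotation_min_identity = annotation_min_identity,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; `peak:` holds
#' [peak_config()] fields and `erv:` the [reconstruct_erv()] arguments.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pk <- do.call(peak_config, y$peak %||% list())
  y$peak <- NULL
  if (!is.null(y$erv) && !is.null(y$erv$ltr_ranges))
    y$erv$ltr_ranges <- lapply(y$erv$ltr_ranges, as.integer)
  do.call(run_config, c(y, list(peak = pk)))
}

#' Run the full discovery pipeline
#'
#' Stages: per-sample filtering and QC; pooled size-peak detection;
#' per-peak sequence clustering; representative annotation (offline
#' library when configured); per-peak population locus extraction with
#' group allele frequencies and gene-feature annotation; optional ERV
#' reconstruction; optional population-structure summaries. Artifacts are
#' written under `config$out_dir`; a stage failure aborts with the stage
#' named, retaining completed outputs.
#'
#' @param config A `run_config`.
#' @param calls Optional pre-loaded pooled calls table (bypasses
#'   `vcf_dir`).
#' @param groups Optional named sample -> group vector (bypasses
#'   `group_table`).
#' @return Invisibly, a list of class `peakTE_run` with the in-memory
#'   stage products (`qc`, `calls`, `peaks`, `families`, `annotations`,
#'   `loci`, `af`, `features`, `erv`, `popstruct`, `out_dir`).
#' @export
run_pipeline <- function(config, calls = NULL, groups = NULL) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  meta <- c(peakTE_version = as.character(utils::packageVersion("peakTE")),
            config_hash = config_hash(unclass(config)),
            seed = config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## --- input + per-sample QC -------------------------------------------
  qc_list <- list()
  filtered <- stage("filter", {
    if (is.null(calls)) {
      stopifnot(!is.null(config$vcf_dir))
      paths <- list.files(config$vcf_dir, pattern = "\\.vcf(\\.gz)?$",
                          full.names = TRUE)
      calls <- do.call(rbind, lapply(paths, function(p)
        read_insertion_vcf(p, sub("\\.vcf(\\.gz)?$", "", basename(p)))))
    }
    if (is.null(groups)) {
      groups <- if (is.character(config$group_table) &&
                    length(config$group_table) == 1L)
        read_group_table(config$group_table)
      else config$group_table
    }
    per_sample <- split(calls, calls$sample_id)
    res <- lapply(per_sample, filter_sample, min_size = config$min_size,
                  min_insertions = config$min_insertions,
                  excluded_contigs = config$excluded_contigs)
    qc <- do.call(rbind, lapply(res, `[[`, "report"))
    rownames(qc) <- NULL
    passing <- qc$sample_id[qc$passed]
    kept <- do.call(rbind, lapply(res[qc$passed], `[[`, "calls"))
    if (is.null(kept)) kept <- insertion_calls()
    rownames(kept) <- NULL
    write_tsv_meta(qc, file.path(out, "qc_summary.tsv"), meta)
    list(calls = kept, qc = qc, passing = passing, groups = groups)
  })
  calls <- filtered$calls
  groups <- filtered$groups
  if (is.null(groups))
    groups <- stats::setNames(rep("all", length(unique(calls$sample_id))),
                              unique(calls$sample_id))

  ## --- peaks ------------------------------------------------------------
  peaks <- stage("peaks", {
    pk <- detect_peaks(calls, config$peak)
    tab <- as.data.frame(pk)
    tab$sub_peaks <- NULL
    write_tsv_meta(tab, file.path(out, "peaks.tsv"), meta)
    pk
  })

  ## --- per-peak sequence clustering + annotation ------------------------
  families <- stage("cluster", {
    fam <- lapply(seq_len(nrow(peaks)), function(i) {
      f <- cluster_peak_sequences(calls, peaks[i, ], config$peak)
      if (nrow(f)) f$peak_id <- i
      f
    })
    fam <- do.call(rbind, fam[vapply(fam, nrow, integer(1)) > 0])
    if (is.null(fam)) {
      fam <- empty_sequence_clusters()
      fam$peak_id <- integer(0)
    }
    tab <- fam
    tab$member_ids <- NULL
    write_tsv_meta(tab, file.path(out, "families.tsv"), meta)
    fa <- file.path(out, "representatives.fa")
    hdr <- sprintf(">peak%d-%d_cluster%d",
                   peaks$start[fam$peak_id], peaks$end[fam$peak_id],
                   fam$cluster_id)
    writeLines(as.vector(rbind(hdr, fam$representative)), fa)
    fam
  })

  annotations <- stage("annotate", {
    if (!is.null(config$consensus_library) && nrow(families)) {
      lib <- read_consensus_library(config$consensus_library)
      ann <- annotate_families(families, lib,
                               config$annotation_min_identity)
      ann$peak_id <- families$peak_id
      write_tsv_meta(ann, file.path(out, "annotations.tsv"), meta)
      ann
    } else NULL
  })

  ## --- population loci per peak ----------------------------------------
  loci_res <- stage("loci", {
    all_loci <- list()
    for (i in seq_len(nrow(peaks))) {
      lo <- extract_loci(calls, c(peaks$start[i], peaks$end[i]),
                         config$breakpoint_tolerance)
      if (nrow(lo)) {
        lo$peak_id <- i
        all_loci[[length(all_loci) + 1L]] <- lo
      }
    }
    loci <- if (length(all_loci)) do.call(rbind, all_loci) else empty_loci()
    if (nrow(loci)) {
      loci$locus_id <- sprintf("locus_%05d", seq_len(nrow(loci)))
      rownames(loci) <- NULL
    }
    af <- compute_group_af(loci, groups,
                           intersect(names(groups), filtered$passing))
    flat <- flatten_loci(loci, af)
    if (nrow(loci)) flat$peak_id <- loci$peak_id
    write_tsv_meta(flat, file.path(out, "loci.tsv"), meta)
    write_locus_bed(loci, file.path(out, "loci.bed"))
    features <- if (!is.null(config$gtf)) {
      ann <- read_gene_annotation(config$gtf)
      ft <- classify_features(loci, ann)
      write_tsv_meta(ft, file.path(out, "feature_annotation.tsv"), meta)
      ft
    } else NULL
    list(loci = loci, af = af, features = features)
  })

  ## --- ERV reconstruction (optional) -----------------------------------
  erv <- if (!is.null(config$erv)) stage("erv", {
    res <- do.call(reconstruct_erv, c(list(calls = calls), config$erv))
    cand <- res$candidates
    cand$sequence <- NULL
    write_tsv_meta(cand, file.path(out, "erv_candidates.tsv"), meta)
    write_tsv_meta(flatten_loci(res$solo_loci),
                   file.path(out, "erv_solo_loci.tsv"), meta)
    if (nrow(res$full_length)) {
      fl <- res$full_length
      writeLines(as.vector(rbind(
        sprintf(">fullERV_%s_%d_%s", fl$chrom, fl$pos, fl$sample_id),
        fl$sequence)), file.path(out, "erv_full_length.fa"))
    }
    res
  }) else NULL

  ## --- population structure (optional) ---------------------------------
  popstruct <- if (config$run_popstruct && nrow(loci_res$loci) &&
                   ncol(loci_res$af) >= 1L) stage("popstruct", {
    kept <- filter_af(loci_res$loci, loci_res$af, config$min_af,
                      config$af_scope)
    pm <- presence_matrix(kept$loci,
                          intersect(names(groups), filtered$passing))
    emb <- if (nrow(pm) >= 3L && ncol(pm) >= 1L)
      embed_presence(pm, config$seed) else NULL
    if (!is.null(emb))
      write_tsv_meta(data.frame(sample_id = rownames(emb),
                                dim1 = emb[, 1], dim2 = emb[, 2],
                                group = unname(groups[rownames(emb)])),
                     file.path(out, "embedding.tsv"), meta)
    shared <- if (ncol(kept$af) >= 2L)
      shared_loci_matrix(kept$af, config$min_af) else NULL
    if (!is.null(shared))
      write_tsv_meta(data.frame(group = rownames(shared),
                                as.data.frame(shared),
                                check.names = FALSE),
                     file.path(out, "shared_loci.tsv"), meta)
    tree <- if (ncol(loci_res$af) >= 2L)
      cluster_groups(t(loci_res$af)) else NULL
    list(presence = pm, embedding = emb, shared = shared, tree = tree)
  }) else NULL

  invisible(structure(
    list(qc = filtered$qc, calls = calls, peaks = peaks,
         families = families, annotations = annotations,
         loci = loci_res$loci, af = loci_res$af,
         features = loci_res$features, erv = erv, popstruct = popstruct,
         out_dir = out, config = config),
    class = "peakTE_run"))
}

#' @export
print.peakTE_run <- function(x, ...) {
  cat("peakTE run:", nrow(x$qc), "sample(s),",
      sum(x$qc$passed), "passing QC\n")
  cat("  peaks:", nrow(x$peaks), " sequence clusters:", nrow(x$families),
      " loci:", nrow(x$loci), "\n")
  if (!is.null(x$erv))
    cat("  full-length ERV calls:", nrow(x$erv$full_length), "\n")
  cat("  outputs:", x$out_dir, "\n")
  invisible(x)
}
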