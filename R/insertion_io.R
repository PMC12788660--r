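## Insertion-call I/O and per-sample QC.
##
## Insertion calls are held in a plain data.frame ("calls table") with
## columns sample_id, chrom, pos (1-based VCF breakpoint), length (bp),
## sequence (IUPAC string, possibly ""), truncated (logical). All interval
## arithmetic elsewhere in the package is 0-based half-open; VCF positions
## are 1-based and BED exports are 0-based half-open.

MAX_STORED_SEQ <- 10000L

#' Construct an insertion-calls table
#'
#' @param sample_id,chrom,pos,length,sequence Vectors, recycled to common
#'   length. `sequence` may be `""` when the caller omitted it.
#' @return A `data.frame` of calls. Sequences longer than 10 kb are stored
#'   truncated to 10 kb with `truncated = TRUE`; truncated sequences are
#'   excluded from identity computations downstream.
#' @export
insertion_calls <- function(sample_id = character(0), chrom = character(0),
                            pos = integer(0), length = integer(0),
                            sequence = character(0)) {
  n <- max(length(pos), length(length))
  if (n == 0L) {
    sample_id <- chrom <- sequence <- character(0)
    pos <- length <- integer(0)
  }
  df <- data.frame(sample_id = rep_len(as.character(sample_id), n),
                   chrom = rep_len(as.character(chrom), n),
                   pos = rep_len(as.integer(pos), n),
                   length = rep_len(as.integer(length), n),
                   sequence = rep_len(as.character(sequence), n),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    stopifnot(all(df$length >= 1L), all(df$pos >= 1L))
    too_long <- !is.na(df$sequence) & nchar(df$sequence) > MAX_STORED_SEQ
    df$truncated <- too_long
    df$sequence[too_long] <- substr(df$sequence[too_long], 1L, MAX_STORED_SEQ)
  } else df$truncated <- logical(0)
  df
}

#' Read insertion calls from a per-sample VCF
#'
#' Accepts the dialect written by short-read insertion callers: one record
#' per insertion with the inserted sequence in ALT (leading reference base)
#' and/or an `SVLEN` INFO field. Length precedence is SVLEN, then inserted
#' sequence length; records with neither are skipped with a warning.
#' Non-insertion records (symbolic non-INS ALTs, deletions) are skipped and
#' counted.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param sample_id Sample identifier attached to every call.
#' @return Calls table (see [insertion_calls()]), with attribute
#'   `n_skipped` giving the number of skipped records.
#' @export
read_insertion_vcf <- function(path, sample_id) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(fix) == 0L)
    return(insertion_calls())
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  info <- vcfR::getINFO(v)

  alt <- fix$ALT
  ref <- fix$REF
  svtype <- sub(".*SVTYPE=([^;]+).*", "\\1", info)
  svtype[!grepl("SVTYPE=", info)] <- NA_character_
  svlen <- suppressWarnings(as.integer(sub(".*SVLEN=(-?[0-9]+).*", "\\1", info)))
  svlen[!grepl("SVLEN=", info)] <- NA_integer_

  ## inserted sequence: ALT minus the leading REF base, when ALT is literal
  symbolic <- grepl("^<", alt)
  seq_ins <- rep("", length(alt))
  literal <- !symbolic & !is.na(alt) & nchar(alt) > nchar(ref) &
    substr(alt, 1L, nchar(ref)) == ref
  seq_ins[literal] <- substr(alt[literal], nchar(ref[literal]) + 1L,
                             nchar(alt[literal]))

  is_ins <- (is.na(svtype) | svtype == "INS") &
    (literal | (symbolic & alt == "<INS>"))
  len <- ifelse(!is.na(svlen) & svlen > 0L, svlen, nchar(seq_ins))
  usable <- is_ins & len >= 1L
  n_missing <- sum(is_ins & len < 1L)
  if (n_missing > 0L)
    warning(n_missing, " insertion record(s) in '", path,
            "' had neither SVLEN nor an inserted sequence; skipped")
  n_skipped <- sum(!usable)

  out <- insertion_calls(sample_id = sample_id,
                         chrom = fix$CHROM[usable],
                         pos = as.integer(fix$POS[usable]),
                         length = len[usable],
                         sequence = seq_ins[usable])
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Filter one sample's calls and report QC
#'
#' Applies the size floor and contig exclusion, then judges the sample
#' against a minimum surviving-call count (the QC threshold is applied
#' after size filtering by default; set `qc_before_size_filter = TRUE` to
#' count raw calls instead).
#'
#' @param calls Calls table for one sample.
#' @param min_size Minimum insertion length in bp retained (default 100).
#' @param min_insertions Minimum surviving calls for the sample to pass QC
#'   (default 1000).
#' @param excluded_contigs Character vector of contig names to drop
#'   (e.g. sex chromosomes); default none.
#' @param qc_before_size_filter Apply the QC count to raw calls.
#' @return `list(calls = <filtered table>, report = <one-row QC data.frame
#'   with sample_id, n_raw, n_pass, passed>)`.
#' @export
filter_sample <- function(calls, min_size = 100L, min_insertions = 1000L,
                          excluded_contigs = character(0),
                          qc_before_size_filter = FALSE) {
  stopifnot(min_size >= 1L, min_insertions >= 0L)
  n_raw <- nrow(calls)
  keep <- calls$length >= min_size & !(calls$chrom %in% excluded_contigs)
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  n_pass <- nrow(out)
  qc_n <- if (qc_before_size_filter) n_raw else n_pass
  report <- data.frame(
    sample_id = if (n_raw) calls$sample_id[1L] else NA_character_,
    n_raw = n_raw, n_pass = n_pass,
    passed = qc_n >= min_insertions,
    stringsAsFactors = FALSE)
  list(calls = out, report = report)
}

#' Write insertion calls as a per-sample VCF
#'
#' Emits one `SVTYPE=INS` record per call with the inserted sequence in ALT
#' (prefixed by an `N` reference base) and `SVLEN` in INFO; truncated
#' sequences are written as symbolic `<INS>` with a `TRUNCATED` flag.
#'
#' @param calls Calls table (one sample).
#' @param path Output path.
#' @param contig_lengths Optional named integer vector for `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_insertion_vcf <- function(calls, path, contig_lengths = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=peakTE",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Insertion length\">",
    "##INFO=<ID=TRUNCATED,Number=0,Type=Flag,Description=\"Stored sequence truncated\">",
    "##ALT=<ID=INS,Description=\"Insertion\">"), con)
  if (!is.null(contig_lengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       names(contig_lengths), as.integer(contig_lengths)), con)
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(calls)) {
    ord <- order(calls$chrom, calls$pos)
    calls <- calls[ord, , drop = FALSE]
    alt <- ifelse(calls$truncated | calls$sequence == "",
                  "<INS>", paste0("N", calls$sequence))
    info <- paste0("SVTYPE=INS;SVLEN=", calls$length,
                   ifelse(calls$truncated, ";TRUNCATED", ""))
    writeLines(paste(calls$chrom, calls$pos, ".", "N", alt, ".", "PASS",
                     info, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a sample-to-group membership table
#'
#' @param path TSV with columns `sample_id` and `group`.
#' @return Named character vector mapping sample_id to group.
#' @export
read_group_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("sample_id", "group") %in% names(x)))
  stats::setNames(as.character(x$group), as.character(x$sample_id))
}

#' Export loci as BED intervals
#'
#' One 0-based half-open single-base interval per locus breakpoint
#' (1-based position p becomes `[p-1, p)`), with the locus id as the name
#' column and the representative insertion length as the score/value
#' column.
#'
#' @param loci Locus table from [extract_loci()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_locus_bed <- function(loci, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(loci))
    writeLines(paste(loci$chrom, loci$position - 1L, loci$position,
                     loci$locus_id, loci$rep_length, sep = "\t"), con)
  invisible(path)
}
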