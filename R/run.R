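# Pipeline orchestration: FASTQ run files in, taxonomically filtered ZOTUs
# out, with a per-stage count report and a Process record capturing every
# parameter value used.

PIPELINE_VERSION <- "zotudb-pipeline/0.1.0"

#' Run the full amplicon-to-ZOTU pipeline
#'
#' Paired (Illumina) platforms: primer trimming of both mates, pair
#' merging, expected-error + length filtering, dereplication, denoising,
#' taxonomy filtering. Single-read (454 / Ion Torrent) platforms: the same
#' flow without the merge stage.
#'
#' @param fwd_path FASTQ path (forward reads, or the single-read file).
#' @param rev_path reverse-read FASTQ for paired platforms; must be NULL
#'   for single-read platforms and present for paired ones (checked before
#'   any processing).
#' @param params a [pipeline_params()] object.
#' @param reference reference FASTA path or parsed reference data.frame
#'   (see [read_reference_fasta()]).
#' @param out_dir optional output directory; when given, writes
#'   \code{zotus.fasta} (\code{>Zotu<N>;size=<abundance>} headers),
#'   \code{stage_report.json} and \code{process_record.csv}.
#' @param srr optional run accession recorded in the Process record.
#' @return list with \code{zotus} (kept ZOTUs with taxon assignments),
#'   \code{discarded} (ZOTUs failing the taxonomy filter), \code{report}
#'   (named integer stage counts), \code{process} (one-row data.frame of
#'   every parameter used) and \code{mapping} (unique -> centroid).
#' @export
run_pipeline <- function(fwd_path, rev_path = NULL, params, reference,
                         out_dir = NULL, srr = NA_character_) {
  stopifnot(inherits(params, "pipeline_params"))
  paired <- params$platform %in% PAIRED_PLATFORMS
  if (paired && is.null(rev_path))
    stop("platform ", params$platform,
         " is paired-end: a reverse-read file is required")
  if (!paired && !is.null(rev_path))
    stop("platform ", params$platform,
         " is single-read: no reverse-read file expected")

  fwd <- read_fastq(fwd_path)
  n_in <- n_reads(fwd)
  trim_discarded <- 0L
  merge_failed <- 0L

  if (paired) {
    rev <- read_fastq(rev_path)
    if (n_reads(rev) != n_in)
      stop("forward and reverse files have different read counts")
    merged_list <- vector("list", n_in)
    for (i in seq_len(n_in)) {
      fr <- list(read_id = fwd$read_id[i], sequence = fwd$sequence[i],
                 qualities = fwd$qualities[[i]])
      rr <- list(read_id = rev$read_id[i], sequence = rev$sequence[i],
                 qualities = rev$qualities[[i]])
      ft <- trim_primers(fr, params$fwd_primer, params$rev_primer)
      rt <- trim_primers(rr, params$rev_primer, params$fwd_primer)
      if (is.null(ft) || is.null(rt)) {
        trim_discarded <- trim_discarded + 1L
        next
      }
      m <- merge_pair(ft, rt, min_overlap = params$min_overlap)
      if (is.null(m)) merge_failed <- merge_failed + 1L else merged_list[[i]] <- m
    }
    merged_list <- Filter(Negate(is.null), merged_list)
    reads <- list(
      read_id = vapply(merged_list, `[[`, character(1), "read_id"),
      sequence = vapply(merged_list, `[[`, character(1), "sequence"),
      qualities = lapply(merged_list, `[[`, "qualities")
    )
  } else {
    trimmed <- vector("list", n_in)
    for (i in seq_len(n_in)) {
      rd <- list(read_id = fwd$read_id[i], sequence = fwd$sequence[i],
                 qualities = fwd$qualities[[i]])
      t <- trim_primers(rd, params$fwd_primer, params$rev_primer)
      if (is.null(t)) trim_discarded <- trim_discarded + 1L else trimmed[[i]] <- t
    }
    trimmed <- Filter(Negate(is.null), trimmed)
    reads <- list(
      read_id = vapply(trimmed, `[[`, character(1), "read_id"),
      sequence = vapply(trimmed, `[[`, character(1), "sequence"),
      qualities = lapply(trimmed, `[[`, "qualities")
    )
  }

  filt <- quality_filter(reads, max_ee = params$max_ee,
                         min_length = params$min_length)
  uniques <- dereplicate(filt$reads$sequence)
  den <- denoise(uniques, alpha = params$alpha, min_size = params$min_size,
                 marker = params$marker)
  tax <- taxonomy_filter(den$zotus, reference)

  report <- c(
    reads_in = n_in,
    trim_discarded = trim_discarded,
    merge_failed = merge_failed,
    filter_removed = as.integer(filt$report["n_in"] - filt$report["n_out"]),
    reads_filtered = as.integer(filt$report["n_out"]),
    denoise_unabsorbed = as.integer(den$unabsorbed_reads),
    reads_in_zotus = as.integer(sum(den$zotus$abundance)),
    zotus_denoised = nrow(den$zotus),
    zotus_kept = nrow(tax$kept),
    zotus_tax_discarded = nrow(tax$discarded),
    reads_in_kept_zotus = as.integer(sum(tax$kept$abundance))
  )
  names(report) <- sub("\\.n_in$|\\.n_out$", "", names(report))

  process <- data.frame(
    srr = srr,
    platform = params$platform, marker = params$marker,
    fwd_primer = params$fwd_primer, rev_primer = params$rev_primer,
    max_ee = params$max_ee, min_overlap = params$min_overlap,
    min_length = params$min_length,
    alpha = params$alpha, min_size = params$min_size,
    pipeline_version = PIPELINE_VERSION,
    stringsAsFactors = FALSE
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_zotu_fasta(tax$kept, file.path(out_dir, "zotus.fasta"))
    jsonlite::write_json(as.list(report),
                         file.path(out_dir, "stage_report.json"),
                         auto_unbox = TRUE)
    utils::write.csv(process, file.path(out_dir, "process_record.csv"),
                     row.names = FALSE)
  }

  list(zotus = tax$kept, discarded = tax$discarded, report = report,
       process = process, mapping = den$mapping)
}
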