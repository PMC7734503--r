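# FASTQ I/O. Reading uses Biostrings (Sanger Phred+33, plain or gzip);
# internally a read set is a plain list: ids, sequences, and a list of
# integer Phred vectors, which keeps per-read quality arithmetic cheap.

#' Read a FASTQ file into a read set
#'
#' @param path FASTQ file (Sanger Phred+33 encoding; .gz accepted).
#' @return list with \code{read_id} (character), \code{sequence}
#'   (character), \code{qualities} (list of integer vectors).
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
  quals <- S4Vectors::mcols(seqs)$qualities
  list(
    read_id = names(seqs),
    sequence = as.character(seqs),
    qualities = lapply(as.character(quals), function(q) {
      as.integer(charToRaw(q)) - 33L
    })
  )
}

#' Write a read set to FASTQ
#'
#' @param reads a read set as from [read_fastq()].
#' @param path output path (plain text).
#' @export
write_fastq <- function(reads, path) {
  n <- length(reads$read_id)
  if (n == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  qual_str <- vapply(reads$qualities, function(q) {
    rawToChar(as.raw(pmin(q, 93L) + 33L))
  }, character(1))
  out <- character(4L * n)
  out[seq(1, by = 4, length.out = n)] <- paste0("@", reads$read_id)
  out[seq(2, by = 4, length.out = n)] <- reads$sequence
  out[seq(3, by = 4, length.out = n)] <- "+"
  out[seq(4, by = 4, length.out = n)] <- qual_str
  writeLines(out, path)
  invisible(path)
}

# Subset a read set by logical or integer index.
.subset_reads <- function(reads, idx) {
  list(read_id = reads$read_id[idx],
       sequence = reads$sequence[idx],
       qualities = reads$qualities[idx])
}

#' Number of reads in a read set
#' @param reads a read set.
#' @return integer count.
#' @export
n_reads <- function(reads) length(reads$read_id)

#' Write ZOTUs to FASTA with size annotations
#'
#' Headers follow the \code{>Zotu<N>;size=<abundance>} convention.
#'
#' @param zotus data.frame with \code{zotu_id}, \code{sequence},
#'   \code{abundance}.
#' @param path output FASTA path.
#' @export
write_zotu_fasta <- function(zotus, path) {
  lines <- character(0)
  if (nrow(zotus) > 0L) {
    lines <- as.vector(rbind(
      sprintf(">%s;size=%d", zotus$zotu_id, zotus$abundance),
      zotus$sequence
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a ZOTU FASTA with size annotations
#'
#' @param path FASTA whose headers carry \code{;size=N}.
#' @return data.frame with \code{zotu_id}, \code{sequence}, \code{abundance}.
#' @export
read_zotu_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  hdr <- names(seqs)
  size <- suppressWarnings(as.integer(sub("^.*;size=(\\d+).*$", "\\1", hdr)))
  if (length(hdr) && anyNA(size))
    stop("FASTA headers lack ;size= annotations: ",
         paste(utils::head(hdr[is.na(size)], 3), collapse = ", "))
  data.frame(
    zotu_id = sub(";.*$", "", hdr),
    sequence = as.character(seqs),
    abundance = size,
    stringsAsFactors = FALSE
  )
}
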