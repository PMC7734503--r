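# Taxonomic filtering of ZOTUs against a lineage-bearing reference FASTA
# (UNITE-style headers). A ZOTU survives iff its best alignment identity is
# at least 70% and the best hit's kingdom is Fungi.

.RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus",
            "species")
.RANK_PREFIX <- c(kingdom = "k__", phylum = "p__", class = "c__",
                  order = "o__", family = "f__", genus = "g__",
                  species = "s__")

#' Parse a UNITE-style FASTA header into a 7-rank lineage
#'
#' Dialect: \code{accession|k__...;p__...;c__...;o__...;f__...;g__...;s__...|SH-id}.
#' Unresolved ranks may be empty or "unidentified".
#'
#' @param header one FASTA header line (without the leading ">").
#' @return list with \code{accession}, \code{sh_id} and the seven rank
#'   fields (\code{kingdom} ... \code{species}).
#' @export
parse_unite_header <- function(header) {
  parts <- strsplit(header, "|", fixed = TRUE)[[1]]
  if (length(parts) != 3L)
    stop("unparseable reference header (expected acc|lineage|SH): ", header)
  ranks <- strsplit(parts[2], ";", fixed = TRUE)[[1]]
  if (length(ranks) != 7L)
    stop("unparseable lineage (expected 7 ranks) in reference header: ",
         header)
  vals <- mapply(function(r, want) {
    if (!startsWith(r, want))
      stop("lineage rank '", r, "' lacks prefix ", want,
           " in reference header: ", header)
    sub(paste0("^", want), "", r)
  }, ranks, .RANK_PREFIX)
  out <- c(list(accession = parts[1], sh_id = parts[3]),
           as.list(vals))
  names(out) <- c("accession", "sh_id", .RANKS)
  out
}

#' Read a lineage-bearing reference FASTA
#'
#' @param path FASTA with UNITE-style headers.
#' @return data.frame with \code{accession}, \code{sh_id}, the seven rank
#'   columns, \code{lineage} (the raw lineage string) and \code{sequence}.
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("reference FASTA is empty: ", path)
  rows <- lapply(seq_along(seqs), function(i) {
    h <- parse_unite_header(names(seqs)[i])
    data.frame(accession = h$accession, sh_id = h$sh_id,
               kingdom = h$kingdom, phylum = h$phylum, class = h$class,
               order = h$order, family = h$family, genus = h$genus,
               species = h$species,
               lineage = strsplit(names(seqs)[i], "|", fixed = TRUE)[[1]][2],
               sequence = as.character(seqs[[i]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percent identity of the best global-with-free-end-gaps alignment
#'
#' Aligns the query against the subject end-to-end with unpenalized
#' terminal gaps (match +1, mismatch -1, gap open/extend -1) and returns
#' 100 x matches / alignment columns of the best-scoring alignment.
#'
#' @param query,subject DNA strings.
#' @return numeric percent identity in [0, 100].
#' @export
alignment_identity <- function(query, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query),
    subject = Biostrings::DNAString(subject),
    type = "overlap", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 1
  )
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  if (cols == 0L) return(0)
  100 * Biostrings::nmatch(aln) / cols
}

#' Filter ZOTUs by reference similarity and fungal lineage
#'
#' Every ZOTU is aligned against every reference sequence; the best hit is
#' the maximum percent identity (ties resolved to the first reference in
#' file order). A ZOTU is kept iff its best identity is at least
#' \code{min_identity} percent and the best hit's kingdom is Fungi; kept
#' ZOTUs carry the hit's lineage and identity.
#'
#' @param zotus data.frame with \code{zotu_id}, \code{sequence} (and any
#'   additional columns, preserved).
#' @param reference data.frame from [read_reference_fasta()], or a FASTA
#'   path.
#' @param min_identity percent identity threshold (default 70).
#' @return list with \code{kept} (zotus plus \code{best_hit},
#'   \code{lineage}, \code{identity}) and \code{discarded} (zotus plus
#'   \code{best_identity}, \code{reason}: "low_identity" or "non_fungal").
#' @export
taxonomy_filter <- function(zotus, reference, min_identity = 70) {
  if (is.character(reference)) reference <- read_reference_fasta(reference)
  if (nrow(reference) == 0L) stop("reference is empty")
  n <- nrow(zotus)
  if (n == 0L) {
    return(list(kept = cbind(zotus, best_hit = character(),
                             lineage = character(), identity = numeric()),
                discarded = cbind(zotus, best_identity = numeric(),
                                  reason = character())))
  }
  best_idx <- integer(n)
  best_pid <- numeric(n)
  for (i in seq_len(n)) {
    pids <- vapply(reference$sequence, function(ref) {
      alignment_identity(zotus$sequence[i], ref)
    }, numeric(1), USE.NAMES = FALSE)
    best_idx[i] <- which.max(pids)   # first max = first in reference order
    best_pid[i] <- pids[best_idx[i]]
  }
  fungal <- reference$kingdom[best_idx] == "Fungi"
  keep <- best_pid >= min_identity & fungal
  kept <- zotus[keep, , drop = FALSE]
  if (nrow(kept)) {
    kept$best_hit <- reference$accession[best_idx[keep]]
    kept$lineage <- reference$lineage[best_idx[keep]]
    kept$identity <- best_pid[keep]
  } else {
    kept$best_hit <- character(0)
    kept$lineage <- character(0)
    kept$identity <- numeric(0)
  }
  discarded <- zotus[!keep, , drop = FALSE]
  if (nrow(discarded)) {
    discarded$best_identity <- best_pid[!keep]
    discarded$reason <- ifelse(best_pid[!keep] < min_identity,
                               "low_identity", "non_fungal")
  } else {
    discarded$best_identity <- numeric(0)
    discarded$reason <- character(0)
  }
  rownames(kept) <- NULL
  rownames(discarded) <- NULL
  list(kept = kept, discarded = discarded)
}
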