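# Accession mining from publication text, and the publication -> study
# mapping used to link literature to sequence-archive records.

#' Recognized sequence-archive accession prefixes
#'
#' The prefix classes recognized in publication text, with the INSDC archive
#' each belongs to: the SRA namespaces (submission SRA, study SRP, sample SRS,
#' experiment SRX, run SRR), the BioProject namespaces (PRJNA, PRJEB) and the
#' ENA namespaces (study ERP, sample ERS).
#'
#' @return data.frame with columns \code{prefix_class} and \code{archive}.
#' @export
accession_prefixes <- function() {
  data.frame(
    prefix_class = c("SRA", "SRP", "SRS", "SRX", "SRR",
                     "PRJNA", "PRJEB", "ERP", "ERS"),
    archive = c("SRA", "SRA", "SRA", "SRA", "SRA",
                "BioProject", "BioProject", "ENA", "ENA"),
    stringsAsFactors = FALSE
  )
}

# One alternation, longest prefixes first, with non-alphanumeric boundaries on
# both sides. An accession is the prefix followed by 4-9 digits; this matches
# real INSDC identifiers and rejects prefixes embedded inside words
# ("surplus") and digit-less prefixes ("the SRA Study").
.ACCESSION_RE <- paste0(
  "(?<![A-Za-z0-9])",
  "(PRJNA|PRJEB|SRA|SRP|SRS|SRX|SRR|ERP|ERS)",
  "([0-9]{4,9})",
  "(?![A-Za-z0-9])"
)

#' Extract sequence-archive accessions from plain text
#'
#' Scans plain text (PDF-to-text conversion happens upstream) for accession
#' identifiers of the nine recognized prefix classes. Matches are
#' non-overlapping, reported in order of occurrence; the same accession
#' appearing at several offsets is reported at each.
#'
#' @param text a single character string; may be empty.
#' @return data.frame with columns \code{accession}, \code{prefix_class},
#'   \code{archive}, \code{char_offset} (0-based offset into \code{text}).
#' @export
#' @examples
#' extract_accessions("deposited in the SRA Study SRP043706.")
extract_accessions <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(accession = character(), prefix_class = character(),
                      archive = character(), char_offset = integer(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr(.ACCESSION_RE, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  acc <- regmatches(text, list(m))[[1]]
  prefix <- sub("[0-9]+$", "", acc)
  pref_tab <- accession_prefixes()
  data.frame(
    accession = acc,
    prefix_class = prefix,
    archive = pref_tab$archive[match(prefix, pref_tab$prefix_class)],
    char_offset = as.integer(m) - 1L,
    stringsAsFactors = FALSE
  )
}

#' Validate accession strings against the known prefix classes
#'
#' @param accessions character vector.
#' @return logical vector, TRUE where the string is a well-formed accession of
#'   a recognized prefix class.
#' @export
is_valid_accession <- function(accessions) {
  grepl(paste0("^(PRJNA|PRJEB|SRA|SRP|SRS|SRX|SRR|ERP|ERS)[0-9]{4,9}$"),
        accessions)
}

#' Map a publication to its sequence-archive studies
#'
#' If structured cross-references (the DataBankList element of a PubMed
#' record, supplied by an adapter) are present, those accessions are used —
#' validated against the known prefix classes. Otherwise the publication body
#' text is mined with [extract_accessions()]. The result is deduplicated by
#' accession string.
#'
#' Cross-reference entries whose accession fits no known prefix class are
#' rejected with a warning and returned in the \code{"rejected"} attribute —
#' reported, never silently dropped.
#'
#' @param pub a list with at least \code{doi} (non-empty) and
#'   \code{body_text}; see [publication_record()].
#' @param databank_refs optional data.frame with columns \code{archive_name}
#'   and \code{accession} (may have zero rows).
#' @return data.frame as from [extract_accessions()] (\code{char_offset} is
#'   NA for structured references, which carry no text position), with a
#'   \code{"rejected"} attribute listing invalid structured accessions.
#' @export
map_publication_to_studies <- function(pub, databank_refs = NULL) {
  stopifnot(is.list(pub), nzchar(pub$doi))
  if (!is.null(databank_refs) && nrow(databank_refs) > 0L) {
    ok <- is_valid_accession(databank_refs$accession)
    rejected <- databank_refs$accession[!ok]
    if (length(rejected)) {
      warning("rejected databank references with unrecognized accessions: ",
              paste(rejected, collapse = ", "), call. = FALSE)
    }
    acc <- databank_refs$accession[ok]
    prefix <- sub("[0-9]+$", "", acc)
    pref_tab <- accession_prefixes()
    out <- data.frame(
      accession = acc,
      prefix_class = prefix,
      archive = pref_tab$archive[match(prefix, pref_tab$prefix_class)],
      char_offset = rep(NA_integer_, length(acc)),
      stringsAsFactors = FALSE
    )
  } else {
    rejected <- character()
    out <- extract_accessions(pub$body_text %||% "")
  }
  out <- out[!duplicated(out$accession), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a publication record
#'
#' @param doi non-empty DOI string.
#' @param title article title.
#' @param body_text plain text extracted from the article (may be empty; then
#'   no accession matches are possible).
#' @param pmid,abstract optional.
#' @return a list of class \code{publication_record}.
#' @export
publication_record <- function(doi, title = "", body_text = "",
                               pmid = NULL, abstract = NULL) {
  stopifnot(is.character(doi), length(doi) == 1L, nzchar(doi))
  structure(list(doi = doi, pmid = pmid, title = title,
                 abstract = abstract, body_text = body_text),
            class = "publication_record")
}

#' Expand an accession range into individual accessions
#'
#' Publications often cite run ranges such as "SRR1502225-SRR1502736". The
#' text miner deliberately reports the two endpoints as separate matches
#' (typographic dashes make in-line expansion lossy); this explicit utility
#' expands a validated endpoint pair.
#'
#' @param from,to accession strings sharing a prefix class, \code{from <= to}.
#' @return character vector of accessions from \code{from} to \code{to}
#'   inclusive, zero-padded to the endpoint width.
#' @export
expand_accession_range <- function(from, to) {
  stopifnot(is_valid_accession(from), is_valid_accession(to))
  pf <- sub("[0-9]+$", "", from)
  pt <- sub("[0-9]+$", "", to)
  if (pf != pt) stop("range endpoints have different prefix classes: ",
                     pf, " vs ", pt)
  nf <- sub("^[A-Z]+", "", from)
  nt <- sub("^[A-Z]+", "", to)
  if (as.numeric(nt) < as.numeric(nf)) stop("range endpoints out of order")
  width <- nchar(nf)
  sprintf("%s%0*d", pf, width, seq(as.integer(nf), as.integer(nt)))
}
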