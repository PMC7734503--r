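# Primer reference table and primer resolution from SRA experiment design
# descriptions. The marker amplified (ITS1 or ITS2) is a mandatory pipeline
# parameter and is rarely stated as structured metadata, so it is recovered
# from primer mentions in free text.

#' Platforms accepted by the amplicon pipeline
#' @export
PLATFORMS <- c("ILLUMINA_MISEQ", "ILLUMINA_HISEQ", "LS454_JUNIOR",
               "LS454_FLX_TITANIUM", "LS454_FLX_PLUS", "ION_PGM")

#' Platforms whose runs are paired-end and require merging
#' @export
PAIRED_PLATFORMS <- c("ILLUMINA_MISEQ", "ILLUMINA_HISEQ")

#' Load a primer reference table
#'
#' The bundled table lists universal fungal ITS primers with name, direction
#' (fwd/rev), sequence (IUPAC), the ITS subunit they amplify, and
#' semicolon-separated aliases.
#'
#' @param path TSV path; default is the bundled table.
#' @return data.frame with columns \code{name}, \code{direction},
#'   \code{sequence}, \code{marker}, \code{aliases}.
#' @export
read_primer_table <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("primers.tsv")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#", fill = TRUE)
  need <- c("name", "direction", "sequence", "marker", "aliases")
  if (!all(need %in% names(tab)))
    stop("primer table must have columns: ", paste(need, collapse = ", "))
  tab$aliases[is.na(tab$aliases)] <- ""
  tab
}

#' Resolve the primer pair and marker from an experiment design description
#'
#' Scans the free-text design description for primer names or aliases
#' (case-insensitive, word-bounded). A resolution requires exactly one
#' forward and one reverse primer mention agreeing on the marker subunit;
#' ambiguity (two or more candidate primers in the same direction, or a
#' marker conflict) yields NULL with a logged report rather than a guess.
#'
#' @param srx_design free-text design description (e.g. from an SRX record).
#' @param primer_table as from [read_primer_table()].
#' @return NULL, or a list with \code{fwd}, \code{rev} (primer sequences),
#'   \code{fwd_name}, \code{rev_name} and \code{marker} ("ITS1" or "ITS2").
#' @export
#' @examples
#' resolve_primers("amplified with fITS7 and ITS4", read_primer_table())
resolve_primers <- function(srx_design, primer_table = read_primer_table()) {
  stopifnot(is.character(srx_design), length(srx_design) == 1L)
  if (is.na(srx_design) || !nzchar(srx_design)) return(NULL)
  hit <- vapply(seq_len(nrow(primer_table)), function(i) {
    names_i <- c(primer_table$name[i],
                 strsplit(primer_table$aliases[i], ";", fixed = TRUE)[[1]])
    names_i <- names_i[nzchar(names_i)]
    any(vapply(names_i, function(nm) {
      grepl(paste0("(?<![A-Za-z0-9])", .regex_escape(nm), "(?![A-Za-z0-9])"),
            srx_design, perl = TRUE, ignore.case = TRUE)
    }, logical(1)))
  }, logical(1))
  fwd <- which(hit & primer_table$direction == "fwd")
  rev <- which(hit & primer_table$direction == "rev")
  if (length(fwd) == 0L || length(rev) == 0L) {
    .log_msg("resolve_primers: fewer than two primer mentions found")
    return(NULL)
  }
  if (length(fwd) > 1L || length(rev) > 1L) {
    .log_msg("resolve_primers: ambiguous primer mentions (",
             paste(primer_table$name[c(fwd, rev)], collapse = ", "), ")")
    return(NULL)
  }
  if (primer_table$marker[fwd] != primer_table$marker[rev]) {
    .log_msg("resolve_primers: forward/reverse primers amplify different ",
             "subunits")
    return(NULL)
  }
  list(fwd = primer_table$sequence[fwd], rev = primer_table$sequence[rev],
       fwd_name = primer_table$name[fwd], rev_name = primer_table$name[rev],
       marker = primer_table$marker[fwd])
}

.regex_escape <- function(s) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)

#' Construct and validate an SRA object hierarchy
#'
#' Models the SRA namespace mapping: a study (SRP) owns experiments (SRX),
#' each experiment references exactly one sample (SRS), and runs (SRR) point
#' at experiments. A sample accession must be present for every experiment
#' ("Sample is always defined"): experiments without a sample are invalid.
#'
#' @param study study accession (SRP).
#' @param experiments data.frame with columns \code{srx}, \code{platform},
#'   \code{design_description}, \code{sample} (SRS accession; required
#'   non-empty), optional \code{fwd_primer}, \code{rev_primer}.
#' @param runs data.frame with columns \code{srr}, \code{srx}.
#' @return a list of class \code{sra_hierarchy}.
#' @export
sra_hierarchy <- function(study, experiments, runs) {
  stopifnot(is.character(study), length(study) == 1L)
  stopifnot(all(c("srx", "platform", "sample") %in% names(experiments)))
  stopifnot(all(c("srr", "srx") %in% names(runs)))
  if (any(is.na(experiments$sample) | !nzchar(experiments$sample)))
    stop("every experiment must reference a sample (Sample is always defined)")
  bad_platform <- setdiff(unique(experiments$platform), PLATFORMS)
  if (length(bad_platform))
    stop("unknown platform(s): ", paste(bad_platform, collapse = ", "))
  orphan <- setdiff(runs$srx, experiments$srx)
  if (length(orphan))
    stop("runs reference unknown experiments: ",
         paste(orphan, collapse = ", "))
  structure(list(study = study, experiments = experiments, runs = runs),
            class = "sra_hierarchy")
}
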