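# Internal helpers shared across modules.

#' IUPAC nucleotide code expansions
#'
#' Named list mapping each IUPAC degeneracy code to the set of plain bases it
#' stands for. Used by primer matching.
#' @keywords internal
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse-complement a DNA string
#'
#' IUPAC-aware reverse complement (e.g. R -> Y). Works on plain character
#' vectors; heavier lifting elsewhere uses Biostrings.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")   # "ACGT"
#' revcomp("AAGR")   # "YCTT"
revcomp <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr("ACGTURYSWKMBDHVNacgturyswkmbdhvn",
                 "TGCAAYRSWMKVHDBNtgcaayrswmkvhdbn", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# TRUE where primer base (IUPAC) is compatible with read base; N in the read
# matches nothing except primer N (conservative).
.iupac_base_match <- function(primer_chars, read_chars) {
  mapply(function(p, r) {
    allowed <- .IUPAC[[toupper(p)]]
    if (is.null(allowed)) return(FALSE)
    toupper(r) %in% allowed
  }, primer_chars, read_chars, USE.NAMES = FALSE)
}

# Split a string into single characters.
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# message() wrapper used for soft warnings the contracts require to be
# "logged, not raised"; kept quiet during tests unless options(zotudb.verbose).
.log_msg <- function(...) {
  if (isTRUE(getOption("zotudb.verbose", FALSE))) message(...)
  invisible(NULL)
}

# Path to a bundled extdata file.
.extdata <- function(name) {
  p <- system.file("extdata", name, package = "zotudb")
  if (!nzchar(p)) stop("bundled file not found: ", name)
  p
}
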