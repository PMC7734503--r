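# Read-level processing stages: expected-error filtering, primer trimming,
# paired-end merging, dereplication and UNOISE3-style denoising.

#' Pipeline parameter set
#'
#' The mandatory arguments are the primer pair, the ITS subunit marker and
#' the sequencing platform; the optional filtering parameters default to the
#' recommended values maxEE = 1.0, minOverlap = 60 bp and minimum length
#' 250 bp, and the denoiser to alpha = 2, min_size = 8 (the published
#' defaults of the cited denoising algorithm).
#'
#' @param fwd_primer,rev_primer primer sequences (IUPAC codes allowed).
#' @param marker "ITS1" or "ITS2".
#' @param platform one of [PLATFORMS].
#' @param max_ee maximum expected errors per read (inclusive bound).
#' @param min_overlap minimum merge overlap in bases.
#' @param min_length minimum read length after trimming/merging.
#' @param alpha denoiser skew steepness.
#' @param min_size minimum abundance for a de-novo centroid.
#' @return a list of class \code{pipeline_params}.
#' @export
pipeline_params <- function(fwd_primer, rev_primer, marker, platform,
                            max_ee = 1.0, min_overlap = 60L,
                            min_length = 250L, alpha = 2.0, min_size = 8L) {
  stopifnot(nzchar(fwd_primer), nzchar(rev_primer))
  marker <- match.arg(marker, c("ITS1", "ITS2"))
  platform <- match.arg(platform, PLATFORMS)
  stopifnot(max_ee > 0, min_overlap >= 1, min_length >= 1,
            alpha > 0, min_size >= 1)
  structure(list(fwd_primer = toupper(fwd_primer),
                 rev_primer = toupper(rev_primer),
                 marker = marker, platform = platform,
                 max_ee = max_ee, min_overlap = as.integer(min_overlap),
                 min_length = as.integer(min_length),
                 alpha = alpha, min_size = as.integer(min_size)),
            class = "pipeline_params")
}

#' Expected number of errors of a read
#'
#' EE = sum over bases of 10^(-Q/10), the expectation of the error count
#' implied by the Phred scores.
#'
#' @param qualities integer vector of Phred scores (>= 0).
#' @return a single numeric; 0 for an empty vector.
#' @export
#' @examples
#' expected_errors(rep(20L, 10))  # 0.1
expected_errors <- function(qualities) {
  if (length(qualities) == 0L) return(0)
  stopifnot(all(qualities >= 0))
  sum(10^(-qualities / 10))
}

#' Filter reads on expected errors and length
#'
#' A read survives iff its expected errors are at most \code{max_ee} (the
#' boundary EE == maxEE passes) and its length is at least
#' \code{min_length} (inclusive).
#'
#' @param reads a read set.
#' @param max_ee maximum expected errors.
#' @param min_length minimum length in bases.
#' @return list with \code{reads} (survivors) and \code{report}
#'   (named counts: n_in, n_out, removed_ee, removed_length).
#' @export
quality_filter <- function(reads, max_ee = 1.0, min_length = 250L) {
  n <- n_reads(reads)
  if (n == 0L) {
    return(list(reads = reads,
                report = c(n_in = 0L, n_out = 0L,
                           removed_ee = 0L, removed_length = 0L)))
  }
  ee <- vapply(reads$qualities, expected_errors, numeric(1))
  len <- nchar(reads$sequence)
  ok_len <- len >= min_length
  ok_ee <- ee <= max_ee
  keep <- ok_len & ok_ee
  list(
    reads = .subset_reads(reads, keep),
    report = c(n_in = n, n_out = sum(keep),
               # a read failing both is attributed to the length gate
               removed_ee = sum(ok_len & !ok_ee),
               removed_length = sum(!ok_len))
  )
}

# All start positions (1-based) where primer matches read with at most
# max_mismatch IUPAC-aware mismatches.
.find_primer_hits <- function(read_chars, primer_chars, max_mismatch = 1L) {
  np <- length(primer_chars)
  nr <- length(read_chars)
  if (nr < np) return(integer())
  # match matrix: rows = primer positions, cols = read positions
  M <- vapply(primer_chars, function(p) {
    allowed <- .IUPAC[[toupper(p)]]
    if (is.null(allowed)) rep(FALSE, nr) else toupper(read_chars) %in% allowed
  }, logical(nr))
  if (nr == 1L) M <- matrix(M, nrow = 1L)
  starts <- seq_len(nr - np + 1L)
  mism <- vapply(starts, function(s) {
    np - sum(M[cbind(s:(s + np - 1L), seq_len(np))])
  }, numeric(1))
  starts[mism <= max_mismatch]
}

#' Trim the primer pair from a read
#'
#' The forward primer must match at the 5' end (at most one IUPAC-aware
#' mismatch); the matched prefix is removed. If the reverse complement of
#' the reverse primer is found downstream (same mismatch allowance), it and
#' everything 3' of it are removed too. Reads without a 5' forward-primer
#' hit are discarded (NULL).
#'
#' @param read list with \code{sequence} and \code{qualities}.
#' @param fwd_primer,rev_primer primer sequences (IUPAC allowed).
#' @param max_mismatch mismatches tolerated per primer site.
#' @return the trimmed read (same shape) or NULL.
#' @export
trim_primers <- function(read, fwd_primer, rev_primer, max_mismatch = 1L) {
  rc <- .chars(read$sequence)
  fp <- .chars(toupper(fwd_primer))
  np <- length(fp)
  if (length(rc) < np) return(NULL)
  mism5 <- np - sum(.iupac_base_match(fp, rc[seq_len(np)]))
  if (mism5 > max_mismatch) return(NULL)
  seq_chars <- rc[-seq_len(np)]
  qual <- read$qualities[-seq_len(np)]
  # reverse-primer site: reverse complement of the reverse primer, searched
  # anywhere downstream; leftmost hit wins, everything from it on is cut
  rp_rc <- .chars(revcomp(toupper(rev_primer)))
  hits <- .find_primer_hits(seq_chars, rp_rc, max_mismatch)
  if (length(hits)) {
    cut <- hits[1] - 1L
    seq_chars <- seq_chars[seq_len(cut)]
    qual <- qual[seq_len(cut)]
  }
  list(read_id = read$read_id, sequence = paste(seq_chars, collapse = ""),
       qualities = qual)
}

# Number of matching bases for every relative shift of r against f,
# computed with FFT cross-correlation per base letter. Shift s means r[j]
# sits at f position j + s; returned vector covers s = (1-nr)..(nf-1).
.overlap_match_counts <- function(f_int, r_int) {
  nf <- length(f_int)
  nr <- length(r_int)
  acc <- numeric(nf + nr - 1L)
  for (b in c(65L, 67L, 71L, 84L)) {  # A C G T
    fb <- as.numeric(f_int == b)
    rb <- as.numeric(r_int == b)
    if (!any(fb > 0) || !any(rb > 0)) next
    acc <- acc + stats::convolve(fb, rb, type = "open")
  }
  round(acc)
}

#' Merge a read pair into a consensus sequence
#'
#' The reverse read is reverse-complemented, then the relative offset
#' maximizing an alignment score (matches minus 4x mismatches over the
#' overlap, no indels) is selected. The merge is accepted iff the overlap
#' spans at least \code{min_overlap} bases and its identity is at least
#' \code{min_identity}. Consensus: at agreeing overlap positions the merged
#' quality is min(Qf + Qr, 41); at disagreements the higher-quality base
#' wins (ties to the forward read) with merged quality |Qf - Qr|.
#'
#' @param fwd,rev reads (lists with \code{sequence}, \code{qualities});
#'   \code{rev} as sequenced.
#' @param min_overlap minimum acceptable overlap length (bases).
#' @param min_identity minimum fraction of matching overlap positions.
#' @return merged read, or NULL when no acceptable overlap exists.
#' @export
merge_pair <- function(fwd, rev, min_overlap = 60L, min_identity = 0.9) {
  f <- utf8ToInt(toupper(fwd$sequence))
  r_seq <- revcomp(rev$sequence)
  r <- utf8ToInt(toupper(r_seq))
  r_qual <- base::rev(rev$qualities)
  nf <- length(f)
  nr <- length(r)
  if (nf == 0L || nr == 0L) return(NULL)
  shifts <- seq.int(1L - nr, nf - 1L)
  matches <- .overlap_match_counts(f, r)
  ov_len <- pmin(nf, shifts + nr) - pmax(1L, shifts + 1L) + 1L
  score <- matches - 4 * (ov_len - matches)
  best <- which.max(score)
  s <- shifts[best]
  L <- ov_len[best]
  if (L < min_overlap) return(NULL)
  if (matches[best] / L < min_identity) return(NULL)
  # consensus over the union span
  g <- seq.int(min(1L, s + 1L), max(nf, s + nr))
  has_f <- g >= 1L & g <= nf
  has_r <- g >= s + 1L & g <= s + nr
  fq <- unlist(fwd$qualities)
  seq_out <- integer(length(g))
  qual_out <- integer(length(g))
  fi <- g
  ri <- g - s
  # forward-only positions
  fo <- has_f & !has_r
  seq_out[fo] <- f[fi[fo]]
  qual_out[fo] <- fq[fi[fo]]
  # reverse-only positions
  ro <- has_r & !has_f
  seq_out[ro] <- r[ri[ro]]
  qual_out[ro] <- r_qual[ri[ro]]
  # overlap
  bo <- has_f & has_r
  fb <- f[fi[bo]]; rb <- r[ri[bo]]
  fqb <- fq[fi[bo]]; rqb <- r_qual[ri[bo]]
  agree <- fb == rb
  ob <- ifelse(agree, fb, ifelse(fqb >= rqb, fb, rb))
  oq <- ifelse(agree, pmin(fqb + rqb, 41L), abs(fqb - rqb))
  seq_out[bo] <- ob
  qual_out[bo] <- oq
  list(read_id = fwd$read_id,
       sequence = intToUtf8(seq_out),
       qualities = as.integer(qual_out),
       overlap = L)
}

#' Dereplicate sequences into unique sequences with abundances
#'
#' Exact string grouping; output sorted by abundance descending, ties
#' broken lexicographically.
#'
#' @param sequences character vector.
#' @return data.frame with \code{sequence} and \code{abundance};
#'   abundances sum to \code{length(sequences)}.
#' @export
dereplicate <- function(sequences) {
  if (length(sequences) == 0L)
    return(data.frame(sequence = character(), abundance = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(sequences)
  out <- data.frame(sequence = names(tab),
                    abundance = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abundance, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' The denoiser skew threshold
#'
#' beta(d) = 1 / 2^(alpha d + 1): the maximum allowed abundance ratio for a
#' candidate at edit distance d from an established centroid. Strictly
#' decreasing in d; beta(0) = 1/2.
#'
#' @param d edit distance (non-negative).
#' @param alpha steepness (default 2).
#' @return numeric threshold.
#' @export
beta_threshold <- function(d, alpha = 2) 1 / 2^(alpha * d + 1)

#' Denoise dereplicated uniques into zero-radius OTUs
#'
#' Greedy pass in descending abundance: a unique with abundance a joins the
#' nearest eligible centroid — a centroid at edit distance d whose own
#' (dereplicated) abundance a_c satisfies a / a_c <= beta(d) — with ties on
#' distance resolved towards the more abundant (earlier) centroid.
#' Otherwise it founds a new centroid iff a >= min_size; below that it is
#' left unabsorbed and counted. Absorbed abundances accumulate into their
#' centroid's output abundance.
#'
#' @param uniques data.frame with \code{sequence}, \code{abundance}
#'   (resorted internally to abundance-descending, ties lexicographic).
#' @param alpha skew steepness.
#' @param min_size minimum abundance to found a centroid.
#' @param marker marker annotation copied onto each ZOTU.
#' @return list with \code{zotus} (data.frame: zotu_id, sequence, abundance,
#'   marker, length; sorted by abundance descending), \code{mapping}
#'   (data.frame: sequence, abundance, centroid — NA when unabsorbed) and
#'   \code{unabsorbed_reads} (total reads in min_size-rejected uniques).
#' @export
denoise <- function(uniques, alpha = 2, min_size = 8L, marker = "ITS2") {
  uniques <- uniques[order(-uniques$abundance, uniques$sequence), ,
                     drop = FALSE]
  n <- nrow(uniques)
  cen_seq <- character()
  cen_own <- integer()     # centroid's own dereplicated abundance
  cen_tot <- integer()     # accumulated output abundance
  assign_to <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    a <- uniques$abundance[i]
    s <- uniques$sequence[i]
    joined <- FALSE
    if (length(cen_seq)) {
      d <- as.integer(utils::adist(s, cen_seq))
      eligible <- which(a / cen_own <= beta_threshold(d, alpha))
      if (length(eligible)) {
        pick <- eligible[order(d[eligible], seq_along(eligible))][1]
        cen_tot[pick] <- cen_tot[pick] + a
        assign_to[i] <- pick
        joined <- TRUE
      }
    }
    if (!joined && a >= min_size) {
      cen_seq <- c(cen_seq, s)
      cen_own <- c(cen_own, a)
      cen_tot <- c(cen_tot, a)
      assign_to[i] <- length(cen_seq)
    }
  }
  ord <- order(-cen_tot, seq_along(cen_tot))
  zotus <- data.frame(
    zotu_id = if (length(ord)) paste0("Zotu", seq_along(ord)) else character(),
    sequence = cen_seq[ord],
    abundance = cen_tot[ord],
    marker = rep(marker, length.out = length(ord)),
    stringsAsFactors = FALSE
  )
  zotus$length <- nchar(zotus$sequence)
  # remap centroid indices to output ids
  id_of <- character(length(cen_seq))
  id_of[ord] <- zotus$zotu_id
  mapping <- data.frame(
    sequence = uniques$sequence,
    abundance = uniques$abundance,
    centroid = ifelse(is.na(assign_to), NA_character_, id_of[assign_to]),
    stringsAsFactors = FALSE
  )
  list(zotus = zotus, mapping = mapping,
       unabsorbed_reads = sum(uniques$abundance[is.na(assign_to)]))
}
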