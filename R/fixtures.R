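# Synthetic data generators: every input the framework consumes can be
# produced offline with known ground truth. All generators are pure
# functions of their arguments plus a seed (the caller's RNG state is
# saved and restored).

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate random DNA sequences
#'
#' @param n number of sequences.
#' @param length sequence length (recycled).
#' @param seed RNG seed.
#' @return character vector.
#' @export
random_dna <- function(n, length = 260L, seed = 1L) {
  .with_seed(seed, {
    length <- rep_len(length, n)
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), length[i], replace = TRUE),
            collapse = "")
    }, character(1))
  })
}

#' Generate well-separated "true" ZOTU sequences
#'
#' Random sequences with every pairwise edit distance at least
#' \code{min_dist} (re-drawn until satisfied; for realistic lengths random
#' sequences are essentially always far apart).
#'
#' @param n number of ZOTUs.
#' @param length sequence length.
#' @param min_dist minimum pairwise edit distance.
#' @param seed RNG seed.
#' @return character vector of pairwise-distinct sequences.
#' @export
random_zotus <- function(n, length = 260L, min_dist = 5L, seed = 1L) {
  .with_seed(seed, {
    out <- character(0)
    tries <- 0L
    while (length(out) < n) {
      cand <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                    collapse = "")
      if (!length(out) ||
          min(utils::adist(cand, out)) >= min_dist) out <- c(out, cand)
      tries <- tries + 1L
      if (tries > 50L * n) stop("cannot place ", n, " ZOTUs at distance ",
                                min_dist)
    }
    out
  })
}

#' Specification for a synthetic amplicon library
#'
#' Defaults mirror a small contemporary ITS2 soil survey: 10 true ZOTUs at
#' least 5 edits apart, 200 reads each, 0.5% per-base substitution error,
#' constant Q30 Phred scores, 250 bp paired reads.
#'
#' @param true_zotus character vector of distinct template sequences.
#' @param reads_per_zotu reads simulated per template.
#' @param per_base_error_rate substitution probability per base in [0, 1).
#' @param quality constant Phred score assigned to every base.
#' @param read_length read length in bases.
#' @param paired TRUE for overlapping Illumina-style mates, FALSE for a
#'   single 454/Ion Torrent-style read spanning the amplicon.
#' @param fwd_primer,rev_primer primers attached to the amplicon ends.
#' @param seed RNG seed; a fixed seed yields byte-identical output.
#' @return list of class \code{library_spec}.
#' @export
library_spec <- function(true_zotus, reads_per_zotu = 200L,
                         per_base_error_rate = 0.005, quality = 30L,
                         read_length = 250L, paired = TRUE,
                         fwd_primer = "GCATCGATGAAGAACGCAGC",
                         rev_primer = "TCCTCCGCTTATTGATATGC",
                         seed = 1L) {
  stopifnot(!anyDuplicated(true_zotus),
            per_base_error_rate >= 0, per_base_error_rate < 1)
  structure(list(true_zotus = true_zotus, reads_per_zotu = reads_per_zotu,
                 per_base_error_rate = per_base_error_rate,
                 quality = as.integer(quality),
                 read_length = as.integer(read_length), paired = paired,
                 fwd_primer = toupper(fwd_primer),
                 rev_primer = toupper(rev_primer), seed = seed),
            class = "library_spec")
}

# substitute bases at given positions with uniformly drawn different bases
.mutate <- function(seq_chars, positions) {
  for (p in positions) {
    seq_chars[p] <- sample(setdiff(c("A", "C", "G", "T"), seq_chars[p]), 1L)
  }
  seq_chars
}

#' Simulate FASTQ run files from a library specification
#'
#' Reads carry the configured primers at the correct ends; substitution
#' errors are injected per base at the configured rate. Paired mode emits
#' overlapping mates (forward read from the amplicon 5' end, reverse read
#' the reverse complement of its 3' end). Deterministic under the spec
#' seed.
#'
#' @param spec a [library_spec()].
#' @param out_dir directory for the FASTQ file(s).
#' @param basename file stem; writes \code{<stem>_R1.fastq} (and
#'   \code{_R2} when paired) or \code{<stem>.fastq}.
#' @return list with \code{fwd}, \code{rev} (paths; rev NULL if single)
#'   and \code{truth} — data.frame read_id, zotu_index, errors_fwd,
#'   errors_rev.
#' @export
make_fastq <- function(spec, out_dir, basename = "synthetic") {
  stopifnot(inherits(spec, "library_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .with_seed(spec$seed, {
    amplicons <- paste0(spec$fwd_primer, spec$true_zotus,
                        revcomp(spec$rev_primer))
    fwd_reads <- list(read_id = character(), sequence = character(),
                      qualities = list())
    rev_reads <- fwd_reads
    truth <- list()
    k <- 0L
    for (zi in seq_along(amplicons)) {
      amp <- .chars(amplicons[zi])
      for (r in seq_len(spec$reads_per_zotu)) {
        k <- k + 1L
        id <- sprintf("read_%d_%d", zi, r)
        if (spec$paired) {
          f_len <- min(spec$read_length, length(amp))
          f <- amp[seq_len(f_len)]
          r_len <- min(spec$read_length, length(amp))
          rseq <- .chars(revcomp(paste(
            amp[seq.int(length(amp) - r_len + 1L, length(amp))],
            collapse = "")))
          ef <- which(stats::runif(f_len) < spec$per_base_error_rate)
          er <- which(stats::runif(r_len) < spec$per_base_error_rate)
          f <- .mutate(f, ef)
          rseq <- .mutate(rseq, er)
          fwd_reads$read_id[k] <- id
          fwd_reads$sequence[k] <- paste(f, collapse = "")
          fwd_reads$qualities[[k]] <- rep(spec$quality, f_len)
          rev_reads$read_id[k] <- id
          rev_reads$sequence[k] <- paste(rseq, collapse = "")
          rev_reads$qualities[[k]] <- rep(spec$quality, r_len)
          truth[[k]] <- data.frame(read_id = id, zotu_index = zi,
                                   errors_fwd = length(ef),
                                   errors_rev = length(er),
                                   stringsAsFactors = FALSE)
        } else {
          s_len <- length(amp)
          s <- amp
          es <- which(stats::runif(s_len) < spec$per_base_error_rate)
          s <- .mutate(s, es)
          fwd_reads$read_id[k] <- id
          fwd_reads$sequence[k] <- paste(s, collapse = "")
          fwd_reads$qualities[[k]] <- rep(spec$quality, s_len)
          truth[[k]] <- data.frame(read_id = id, zotu_index = zi,
                                   errors_fwd = length(es),
                                   errors_rev = NA_integer_,
                                   stringsAsFactors = FALSE)
        }
      }
    }
    if (spec$paired) {
      fwd_path <- file.path(out_dir, paste0(basename, "_R1.fastq"))
      rev_path <- file.path(out_dir, paste0(basename, "_R2.fastq"))
      write_fastq(fwd_reads, fwd_path)
      write_fastq(rev_reads, rev_path)
    } else {
      fwd_path <- file.path(out_dir, paste0(basename, ".fastq"))
      rev_path <- NULL
      write_fastq(fwd_reads, fwd_path)
    }
    list(fwd = fwd_path, rev = rev_path,
         truth = do.call(rbind, truth))
  })
}

.FUNGAL_PHYLA <- c("Ascomycota", "Basidiomycota", "Mortierellomycota",
                   "Mucoromycota", "Chytridiomycota", "Rozellomycota",
                   "Glomeromycota")
.OUTGROUPS <- data.frame(
  kingdom = c("Viridiplantae", "Metazoa", "Rhizaria"),
  phylum = c("Streptophyta", "Arthropoda", "Cercozoa"),
  stringsAsFactors = FALSE
)

.make_lineage <- function(kingdom, phylum, i) {
  sprintf("k__%s;p__%s;c__Class%d;o__Order%d;f__Family%d;g__Genus%d;s__Genus%d_sp%d",
          kingdom, phylum, i, i, i, i, i, i)
}

#' Generate a lineage-bearing reference FASTA with known truth
#'
#' Fungal records contain every supplied true ZOTU (so planted sequences
#' hit at 100% identity), optional extra fungal references, and non-fungal
#' decoy records verified at generation to align below the contamination
#' threshold against every true ZOTU.
#'
#' @param true_zotus template sequences to embed as fungal references.
#' @param path output FASTA path.
#' @param n_extra_fungal additional random fungal references.
#' @param n_outgroup non-fungal decoy records.
#' @param phyla fungal phyla cycled over the fungal records.
#' @param max_decoy_identity decoys are re-drawn until below this percent
#'   identity to every true ZOTU (default 70).
#' @param seed RNG seed.
#' @return list with \code{path} and \code{truth} — data.frame accession,
#'   kingdom, phylum, is_true_zotu, zotu_index.
#' @export
make_reference_fasta <- function(true_zotus, path, n_extra_fungal = 5L,
                                 n_outgroup = 5L, phyla = .FUNGAL_PHYLA,
                                 max_decoy_identity = 70, seed = 1L) {
  .with_seed(seed, {
    recs <- list()
    add <- function(acc, lineage, sh, seq_, meta) {
      recs[[length(recs) + 1L]] <<- c(
        list(header = sprintf("%s|%s|%s", acc, lineage, sh), seq = seq_),
        meta)
    }
    zlen <- if (length(true_zotus)) nchar(true_zotus[1]) else 260L
    i <- 0L
    for (zi in seq_along(true_zotus)) {
      i <- i + 1L
      ph <- phyla[(i - 1L) %% length(phyla) + 1L]
      add(sprintf("SYN%05d", i), .make_lineage("Fungi", ph, i),
          sprintf("SH%07d.08FU", i), true_zotus[zi],
          list(kingdom = "Fungi", phylum = ph, is_true_zotu = TRUE,
               zotu_index = zi))
    }
    for (j in seq_len(n_extra_fungal)) {
      i <- i + 1L
      ph <- phyla[(i - 1L) %% length(phyla) + 1L]
      s <- paste(sample(c("A", "C", "G", "T"), zlen, replace = TRUE),
                 collapse = "")
      add(sprintf("SYN%05d", i), .make_lineage("Fungi", ph, i),
          sprintf("SH%07d.08FU", i), s,
          list(kingdom = "Fungi", phylum = ph, is_true_zotu = FALSE,
               zotu_index = NA_integer_))
    }
    for (j in seq_len(n_outgroup)) {
      i <- i + 1L
      og <- .OUTGROUPS[(j - 1L) %% nrow(.OUTGROUPS) + 1L, ]
      repeat {
        s <- paste(sample(c("A", "C", "G", "T"), zlen, replace = TRUE),
                   collapse = "")
        if (!length(true_zotus)) break
        pid <- max(vapply(true_zotus, function(z) alignment_identity(s, z),
                          numeric(1)))
        if (pid < max_decoy_identity) break
      }
      add(sprintf("SYN%05d", i), .make_lineage(og$kingdom, og$phylum, i),
          sprintf("SH%07d.08FU", i), s,
          list(kingdom = og$kingdom, phylum = og$phylum,
               is_true_zotu = FALSE, zotu_index = NA_integer_))
    }
    lines <- unlist(lapply(recs, function(r) c(paste0(">", r$header),
                                               r$seq)))
    writeLines(lines, path)
    truth <- do.call(rbind, lapply(recs, function(r) {
      data.frame(accession = sub("\\|.*$", "", r$header),
                 kingdom = r$kingdom, phylum = r$phylum,
                 is_true_zotu = r$is_true_zotu, zotu_index = r$zotu_index,
                 stringsAsFactors = FALSE)
    }))
    list(path = path, truth = truth)
  })
}

#' Generate a publication corpus and raw sample metadata with truth keys
#'
#' The corpus plants one accession per recognized prefix class amid decoy
#' substrings (prefixes inside words, digit-less prefixes, too-short digit
#' runs). The metadata table mixes every recognized date and coordinate
#' dialect, gazetteer country names and aliases, plus malformed rows whose
#' truth entries mark the expected-absent outcome.
#'
#' @param seed RNG seed.
#' @param gazetteer gazetteer used to draw countries and compute expected
#'   geography.
#' @return list with \code{text}, \code{accession_truth} (accession,
#'   prefix_class, archive), \code{samples} (raw metadata data.frame) and
#'   \code{sample_truth} (expected curated values per row).
#' @export
make_corpus_and_metadata <- function(seed = 1L,
                                     gazetteer = read_gazetteer()) {
  .with_seed(seed, {
    pref <- accession_prefixes()
    accs <- sprintf("%s%06d", pref$prefix_class,
                    sample(100000:999999, nrow(pref)))
    planted <- data.frame(accession = accs,
                          prefix_class = pref$prefix_class,
                          archive = pref$archive, stringsAsFactors = FALSE)
    decoys <- c("surplus material", "the SRA Study was large",
                "preSRP999999 embedded", "SRR12 too short",
                "PRJNA (no digits)", "ERS999999999999 overlong")
    sentences <- c(
      sprintf("Reads were deposited under %s.", accs),
      decoys,
      sprintf("Runs %s and %s were re-used.", accs[5], accs[1])
    )
    text <- paste(sample(sentences), collapse = " ")

    # raw metadata rows covering every dialect; truth from bookkeeping
    g <- gazetteer[sample(nrow(gazetteer), 6L), ]
    mk_dms <- function(lat, lon) {
      f <- function(v, hemis) {
        h <- if (v >= 0) hemis[1] else hemis[2]
        v <- abs(v)
        d <- floor(v)
        m <- round((v - d) * 60)
        sprintf("%d°%02d′%s", d, m, h)
      }
      paste(f(lat, c("N", "S")), f(lon, c("E", "W")))
    }
    mk_hemi <- function(lat, lon) {
      sprintf("%.2f %s %.2f %s", abs(lat), if (lat >= 0) "N" else "S",
              abs(lon), if (lon >= 0) "E" else "W")
    }
    dms_lat <- 52 + 9 / 60
    dms_lon <- 4 + 29 / 60
    rows <- list(
      list(date = "2014-08-12", exp_date = "2014-08-12",
           latlon = mk_hemi(round(g$centroid_lat[1], 2),
                            round(g$centroid_lon[1], 2)),
           exp_lat = round(g$centroid_lat[1], 2),
           exp_lon = round(g$centroid_lon[1], 2),
           country = g$country_name[1]),
      list(date = "12-Aug-2014", exp_date = "2014-08-12",
           latlon = format_coordinates(g$centroid_lat[2], g$centroid_lon[2]),
           exp_lat = round(g$centroid_lat[2], 6),
           exp_lon = round(g$centroid_lon[2], 6),
           country = g$country_name[2]),
      list(date = "Aug-2014", exp_date = "2014-08",
           latlon = mk_dms(dms_lat, dms_lon),
           exp_lat = round(dms_lat, 6), exp_lon = round(dms_lon, 6),
           country = g$country_name[3]),
      list(date = "2014", exp_date = "2014",
           latlon = NA_character_, exp_lat = NA_real_, exp_lon = NA_real_,
           country = g$country_name[4]),
      list(date = "08/12/2014", exp_date = "2014-08-12",
           latlon = "95 N 10 E", exp_lat = NA_real_, exp_lon = NA_real_,
           country = g$country_name[5]),
      list(date = "sometime in summer", exp_date = NA_character_,
           latlon = "not recorded", exp_lat = NA_real_, exp_lon = NA_real_,
           country = "Atlantis")
    )
    samples <- do.call(rbind, lapply(seq_along(rows), function(i) {
      data.frame(srs = sprintf("SRS%06d", 100000L + i),
                 collection_date = rows[[i]]$date,
                 geo_loc_name = rows[[i]]$country,
                 lat_lon = rows[[i]]$latlon,
                 env_biome = "temperate broadleaf forest soil",
                 env_material = "soil",
                 stringsAsFactors = FALSE)
    }))
    sample_truth <- do.call(rbind, lapply(seq_along(rows), function(i) {
      r <- rows[[i]]
      is_known <- i <= 5L
      gi <- if (is_known) which(gazetteer$country_name == r$country) else NA
      has_coords <- !is.na(r$exp_lat)
      exp_lat <- r$exp_lat
      exp_lon <- r$exp_lon
      src <- NA_character_
      if (is_known) {
        if (!has_coords) {
          exp_lat <- gazetteer$centroid_lat[gi]
          exp_lon <- gazetteer$centroid_lon[gi]
          src <- "CENTROID_FALLBACK"
        } else {
          inside <- exp_lat >= gazetteer$bbox_min_lat[gi] &&
            exp_lat <= gazetteer$bbox_max_lat[gi] &&
            exp_lon >= gazetteer$bbox_min_lon[gi] &&
            exp_lon <= gazetteer$bbox_max_lon[gi]
          if (inside) {
            src <- "REPORTED"
          } else {
            exp_lat <- gazetteer$centroid_lat[gi]
            exp_lon <- gazetteer$centroid_lon[gi]
            src <- "CORRECTED"
          }
        }
      }
      data.frame(
        srs = sprintf("SRS%06d", 100000L + i),
        expected_date = r$exp_date,
        expected_country = if (is_known) r$country else NA_character_,
        expected_continent = if (is_known) gazetteer$continent[gi]
                             else NA_character_,
        expected_lat = exp_lat,
        expected_lon = exp_lon,
        expected_coord_source = src,
        stringsAsFactors = FALSE)
    }))
    list(text = text, accession_truth = planted, samples = samples,
         sample_truth = sample_truth)
  })
}
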