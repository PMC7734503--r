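# The persistent integrated data model: Literature / Study / Sequence /
# Taxonomy / Location components, the deduplicated ZOTU reference set, and
# the incremental update that maintains it with 'contains' provenance.
#
# The backing engine is an in-memory set of data frames inside an
# environment, with CSV import/export; the interface (new_store /
# update_store / import / export / queries) is engine-agnostic.

.STORE_TABLES <- c("articles", "source", "studies", "experiments", "samples",
                   "runs", "reference_sequence", "contains", "process",
                   "assign_taxa")

.empty_store_tables <- function() {
  list(
    articles = data.frame(doi = character(), pmid = character(),
                          title = character(), stringsAsFactors = FALSE),
    source = data.frame(doi = character(), srp = character(),
                        stringsAsFactors = FALSE),
    studies = data.frame(srp = character(), stringsAsFactors = FALSE),
    experiments = data.frame(srx = character(), srp = character(),
                             platform = character(), sample = character(),
                             design_description = character(),
                             stringsAsFactors = FALSE),
    samples = data.frame(srs = character(),
                         collection_date_iso = character(),
                         country = character(), geoname_id = integer(),
                         continent = character(), latitude = numeric(),
                         longitude = numeric(), coord_source = character(),
                         biome_label = character(),
                         biome_envo_id = character(),
                         raw_collection_date = character(),
                         raw_geo_loc_name = character(),
                         raw_lat_lon = character(),
                         raw_env_biome = character(),
                         raw_env_material = character(),
                         stringsAsFactors = FALSE),
    runs = data.frame(srr = character(), srx = character(),
                      stringsAsFactors = FALSE),
    reference_sequence = data.frame(ref_id = integer(),
                                    sequence = character(),
                                    marker = character(), length = integer(),
                                    stringsAsFactors = FALSE),
    contains = data.frame(ref_id = integer(), srs = character(),
                          srr = character(), abundance = integer(),
                          stringsAsFactors = FALSE),
    process = data.frame(srr = character(), platform = character(),
                         marker = character(), fwd_primer = character(),
                         rev_primer = character(), max_ee = numeric(),
                         min_overlap = integer(), min_length = integer(),
                         alpha = numeric(), min_size = integer(),
                         pipeline_version = character(),
                         stringsAsFactors = FALSE),
    assign_taxa = data.frame(ref_id = integer(), lineage = character(),
                             best_hit_name = character(),
                             identity = numeric(), stringsAsFactors = FALSE)
  )
}

#' Create an empty ZOTU store
#'
#' @return an environment of class \code{zotu_store} holding the component
#'   tables (articles, source, studies, experiments, samples, runs,
#'   reference_sequence, contains, process, assign_taxa).
#' @export
new_store <- function() {
  st <- new.env(parent = emptyenv())
  tabs <- .empty_store_tables()
  for (nm in names(tabs)) assign(nm, tabs[[nm]], envir = st)
  class(st) <- "zotu_store"
  st
}

#' @export
print.zotu_store <- function(x, ...) {
  cat("<zotu_store>\n")
  for (nm in .STORE_TABLES)
    cat(sprintf("  %-20s %d rows\n", nm, nrow(get(nm, envir = x))))
  invisible(x)
}

#' Incrementally update the ZOTU reference set
#'
#' For every input ZOTU observation the sequence (uppercased; zero-radius
#' semantics, exact string equality, no near-duplicate merging) is looked
#' up in the reference set. A miss inserts a new reference sequence plus a
#' 'contains' row; a hit adds the 'contains' row only. Replaying a (ref,
#' run) pair already present adds nothing — the update is idempotent per
#' run. Conservation: inserted_refs + reused_refs = contains_added for
#' every update.
#'
#' @param store a [new_store()] environment.
#' @param sample_zotus list of per-run entries, each a list with
#'   \code{srs}, \code{srr} and \code{zotus} — a data.frame with
#'   \code{sequence}, \code{abundance}, \code{marker} and optionally
#'   \code{lineage}, \code{best_hit}, \code{identity} (stored as taxon
#'   assignments for newly inserted references). Sequences must be unique
#'   within one run's entry.
#' @return list \code{inserted_refs}, \code{reused_refs},
#'   \code{contains_added}, \code{replays_skipped}.
#' @export
update_store <- function(store, sample_zotus) {
  stopifnot(inherits(store, "zotu_store"))
  refs <- get("reference_sequence", envir = store)
  contains <- get("contains", envir = store)
  taxa <- get("assign_taxa", envir = store)
  inserted <- 0L
  reused <- 0L
  replays <- 0L
  next_id <- if (nrow(refs)) max(refs$ref_id) + 1L else 1L
  # sequence -> ref_id / marker lookups
  lookup <- structure(refs$ref_id, names = refs$sequence)
  marker_of <- structure(refs$marker, names = refs$sequence)
  contains_key <- paste(contains$ref_id, contains$srr)
  added_keys <- character()
  new_contains <- list()
  new_refs <- list()
  new_taxa <- list()
  for (entry in sample_zotus) {
    z <- entry$zotus
    if (nrow(z) == 0L) next
    seqs <- toupper(z$sequence)
    if (anyDuplicated(seqs))
      stop("duplicate sequences within one run's ZOTU set (", entry$srr, ")")
    for (j in seq_len(nrow(z))) {
      s <- seqs[j]
      hit <- lookup[s]
      if (is.na(hit)) {
        rid <- next_id
        next_id <- next_id + 1L
        lookup[s] <- rid
        marker_of[s] <- z$marker[j]
        new_refs[[length(new_refs) + 1L]] <- data.frame(
          ref_id = rid, sequence = s, marker = z$marker[j],
          length = nchar(s), stringsAsFactors = FALSE)
        if (!is.null(z$lineage) && !is.na(z$lineage[j])) {
          idty <- if (is.null(z$identity)) NA_real_ else z$identity[j]
          if (!is.na(idty) && (idty < 70 || idty > 100))
            stop("taxon assignment identity outside [70, 100] for ", s)
          new_taxa[[length(new_taxa) + 1L]] <- data.frame(
            ref_id = rid, lineage = z$lineage[j],
            best_hit_name = if (is.null(z$best_hit)) NA_character_
                            else z$best_hit[j],
            identity = idty, stringsAsFactors = FALSE)
        }
        inserted <- inserted + 1L
      } else {
        rid <- unname(hit)
        # same sequence, conflicting marker annotation is a hard error
        stored_marker <- unname(marker_of[s])
        if (!is.na(stored_marker) && stored_marker != z$marker[j])
          stop("marker conflict for sequence already stored as ",
               stored_marker, ": ", s)
        key <- paste(rid, entry$srr)
        if (key %in% contains_key || key %in% added_keys) {
          replays <- replays + 1L
          next
        }
        reused <- reused + 1L
      }
      added_keys[length(added_keys) + 1L] <- paste(rid, entry$srr)
      new_contains[[length(new_contains) + 1L]] <- data.frame(
        ref_id = rid, srs = entry$srs, srr = entry$srr,
        abundance = as.integer(z$abundance[j]), stringsAsFactors = FALSE)
    }
  }
  if (length(new_refs))
    refs <- rbind(refs, do.call(rbind, new_refs))
  if (length(new_contains))
    contains <- rbind(contains, do.call(rbind, new_contains))
  if (length(new_taxa))
    taxa <- rbind(taxa, do.call(rbind, new_taxa))
  rownames(refs) <- rownames(contains) <- rownames(taxa) <- NULL
  assign("reference_sequence", refs, envir = store)
  assign("contains", contains, envir = store)
  assign("assign_taxa", taxa, envir = store)
  list(inserted_refs = inserted, reused_refs = reused,
       contains_added = inserted + reused, replays_skipped = replays)
}

#' Ingest curated samples and the SRA object hierarchy
#'
#' Populates the Literature, Study and Location components with referential
#' closure checks: a run whose experiment is missing, or an experiment
#' without a sample ("Sample is always defined"), is rejected per record
#' with a report — never a partial silent load.
#'
#' @param store a [new_store()] environment.
#' @param curated data.frame from [curate_samples()].
#' @param hierarchy an [sra_hierarchy()] or a plain list with \code{study},
#'   \code{experiments}, \code{runs} (unvalidated input is checked here,
#'   record by record).
#' @param publication_links optional data.frame with \code{doi},
#'   \code{pmid}, \code{title}, \code{srp} mapping literature to studies.
#' @return list with per-table ingested counts and \code{rejected}
#'   (data.frame: record, reason).
#' @export
import_curated <- function(store, curated, hierarchy,
                           publication_links = NULL) {
  stopifnot(inherits(store, "zotu_store"))
  exps <- hierarchy$experiments
  runs <- hierarchy$runs
  rejected <- list()
  # experiments must reference a sample
  no_sample <- is.na(exps$sample) | !nzchar(exps$sample)
  for (srx in exps$srx[no_sample])
    rejected[[length(rejected) + 1L]] <- data.frame(
      record = srx, reason = "experiment lacks a sample",
      stringsAsFactors = FALSE)
  exps_ok <- exps[!no_sample, , drop = FALSE]
  # runs must reference an ingested experiment
  dangling <- !(runs$srx %in% exps_ok$srx)
  for (srr in runs$srr[dangling])
    rejected[[length(rejected) + 1L]] <- data.frame(
      record = srr, reason = "run references missing experiment",
      stringsAsFactors = FALSE)
  runs_ok <- runs[!dangling, , drop = FALSE]

  studies <- rbind(get("studies", envir = store),
                   data.frame(srp = hierarchy$study,
                              stringsAsFactors = FALSE))
  assign("studies", unique(studies), envir = store)
  exp_rows <- data.frame(srx = exps_ok$srx, srp = hierarchy$study,
                         platform = exps_ok$platform,
                         sample = exps_ok$sample,
                         design_description =
                           if ("design_description" %in% names(exps_ok))
                             exps_ok$design_description
                           else NA_character_,
                         stringsAsFactors = FALSE)
  assign("experiments",
         unique(rbind(get("experiments", envir = store), exp_rows)),
         envir = store)
  assign("runs",
         unique(rbind(get("runs", envir = store),
                      runs_ok[, c("srr", "srx"), drop = FALSE])),
         envir = store)
  old_samples <- get("samples", envir = store)
  new_samples <- curated[!(curated$srs %in% old_samples$srs), , drop = FALSE]
  samples <- if (nrow(old_samples) == 0L) curated else
    rbind(old_samples, new_samples)
  assign("samples", samples, envir = store)
  if (!is.null(publication_links) && nrow(publication_links)) {
    art <- data.frame(doi = publication_links$doi,
                      pmid = publication_links$pmid %||% NA_character_,
                      title = publication_links$title %||% NA_character_,
                      stringsAsFactors = FALSE)
    assign("articles",
           unique(rbind(get("articles", envir = store), art)), envir = store)
    src <- data.frame(doi = publication_links$doi,
                      srp = publication_links$srp, stringsAsFactors = FALSE)
    assign("source",
           unique(rbind(get("source", envir = store), src)), envir = store)
  }
  rej <- if (length(rejected)) do.call(rbind, rejected) else
    data.frame(record = character(), reason = character(),
               stringsAsFactors = FALSE)
  list(studies = 1L, experiments = nrow(exp_rows),
       runs = nrow(runs_ok), samples = nrow(curated), rejected = rej)
}

#' Record pipeline Process parameters for a run
#'
#' One record per processed run; re-recording the same run replaces its row.
#' @param store a store.
#' @param process one-row data.frame as produced by [run_pipeline()].
#' @export
record_process <- function(store, process) {
  stopifnot(inherits(store, "zotu_store"))
  p <- get("process", envir = store)
  p <- p[p$srr != process$srr, , drop = FALSE]
  assign("process", rbind(p, process[names(p)]), envir = store)
  invisible(store)
}

#' Export a store to a directory of CSV files
#'
#' @param store a store.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
export_store <- function(store, dir) {
  stopifnot(inherits(store, "zotu_store"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in .STORE_TABLES)
    utils::write.csv(get(nm, envir = store),
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  invisible(dir)
}

#' Import a store from a directory of CSV files
#'
#' The inverse of [export_store()]: re-importing an exported store yields a
#' field-by-field equal store.
#'
#' @param dir directory written by [export_store()].
#' @return a \code{zotu_store}.
#' @export
import_store <- function(dir) {
  st <- new_store()
  proto <- .empty_store_tables()
  for (nm in .STORE_TABLES) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) stop("missing store table file: ", path)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = NA)
    if (nrow(tab) == 0L) tab <- proto[[nm]][, names(tab), drop = FALSE]
    # restore column types that read.csv guesses differently
    for (cn in names(proto[[nm]])) {
      if (!(cn %in% names(tab))) next
      if (is.integer(proto[[nm]][[cn]])) tab[[cn]] <- as.integer(tab[[cn]])
      else if (is.double(proto[[nm]][[cn]])) tab[[cn]] <- as.double(tab[[cn]])
      else if (is.character(proto[[nm]][[cn]]))
        tab[[cn]] <- as.character(tab[[cn]])
    }
    # columns beyond the schema prototype (e.g. curated sample fields):
    # an all-NA column round-trips as logical; the schema has no logical
    # columns, so restore it to character
    for (cn in setdiff(names(tab), names(proto[[nm]])))
      if (is.logical(tab[[cn]]) && all(is.na(tab[[cn]])))
        tab[[cn]] <- as.character(tab[[cn]])
    assign(nm, tab, envir = st)
  }
  st
}

#' Access one component table of a store
#'
#' @param store a store.
#' @param name one of the component table names (see [new_store()]).
#' @return the table as a data.frame.
#' @export
store_table <- function(store, name) {
  stopifnot(inherits(store, "zotu_store"), name %in% .STORE_TABLES)
  get(name, envir = store)
}
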