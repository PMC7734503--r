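# Biogeographic diversity queries over the store: phylum-by-continent
# counts, shared ZOTUs among geographic units, and taxon distributions
# within a latitude band. All queries are presence-based (a ZOTU either
# occurs in a unit or it does not); abundance is never read.

#' Fungal phyla printed individually in phylum-by-continent tables
#'
#' Phyla outside this display list collapse into "Other"; lineages with an
#' unresolved phylum count as "Unidentified". Configurable per call.
#' @export
DEFAULT_PHYLA <- c("Ascomycota", "Basidiomycota", "Chytridiomycota",
                   "Glomeromycota", "Mortierellomycota", "Mucoromycota",
                   "Rozellomycota")

# ref_id x unit presence pairs, derived contains -> samples -> curated unit.
.presence <- function(store, unit = c("continent", "country")) {
  unit <- match.arg(unit)
  contains <- store_table(store, "contains")
  samples <- store_table(store, "samples")
  m <- merge(contains, samples[, c("srs", unit)], by = "srs")
  m <- m[!is.na(m[[unit]]) & nzchar(m[[unit]]), , drop = FALSE]
  unique(data.frame(ref_id = m$ref_id, unit = m[[unit]],
                    stringsAsFactors = FALSE))
}

# extract a rank value from a stored lineage string (k__...;p__...;...).
.lineage_rank <- function(lineage, rank) {
  pref <- .RANK_PREFIX[[rank]]
  vapply(strsplit(lineage, ";", fixed = TRUE), function(parts) {
    hit <- parts[startsWith(parts, pref)]
    if (length(hit) == 0L) return(NA_character_)
    val <- sub(paste0("^", pref), "", hit[1])
    if (!nzchar(val) || tolower(val) == "unidentified") NA_character_ else val
  }, character(1))
}

#' Count distinct ZOTUs per phylum and continent
#'
#' Counts distinct reference sequences per (phylum, continent) cell; a ZOTU
#' present on two continents is counted once per continent. Phyla outside
#' \code{display_phyla} are pooled as "Other"; lineages with no resolved
#' phylum as "Unidentified".
#'
#' @param store a store with taxon assignments and curated locations.
#' @param display_phyla phyla printed individually.
#' @return data.frame phylum x continent of counts (phyla as rows, one
#'   column per continent present in the store).
#' @export
phylum_by_continent <- function(store, display_phyla = DEFAULT_PHYLA) {
  pres <- .presence(store, "continent")
  taxa <- store_table(store, "assign_taxa")
  empty <- data.frame(phylum = character(), stringsAsFactors = FALSE)
  if (nrow(pres) == 0L) return(empty)
  m <- merge(pres, taxa[, c("ref_id", "lineage")], by = "ref_id",
             all.x = TRUE)
  phylum <- rep(NA_character_, nrow(m))
  has_lin <- !is.na(m$lineage)
  phylum[has_lin] <- .lineage_rank(m$lineage[has_lin], "phylum")
  phylum[is.na(phylum)] <- "Unidentified"
  phylum[!(phylum %in% c(display_phyla, "Unidentified"))] <- "Other"
  tab <- table(phylum, m$unit)
  out <- as.data.frame.matrix(tab)
  out <- data.frame(phylum = rownames(out), out, check.names = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$phylum), , drop = FALSE]
}

# per-unit ZOTU id sets
.unit_sets <- function(store, unit = "continent") {
  pres <- .presence(store, unit)
  split(pres$ref_id, pres$unit)
}

#' ZOTUs of one unit also present elsewhere
#'
#' shared(unit) = |Z(unit) intersected with the union of all other units'
#' ZOTU sets|, on presence.
#'
#' @param store a store.
#' @param unit the geographic unit name (e.g. a continent).
#' @param by "continent" or "country".
#' @return integer count (0 when the unit is absent or alone).
#' @export
shared_zotus <- function(store, unit, by = "continent") {
  sets <- .unit_sets(store, by)
  if (!(unit %in% names(sets))) return(0L)
  others <- unlist(sets[setdiff(names(sets), unit)], use.names = FALSE)
  length(intersect(sets[[unit]], others))
}

#' Pairwise shared-ZOTU counts between units
#'
#' pairwise(u, v) = |Z(u) intersect Z(v)|; symmetric, and the diagonal is
#' each unit's distinct ZOTU count.
#'
#' @param store a store.
#' @param by "continent" or "country".
#' @return a symmetric integer matrix with unit names on both dimensions.
#' @export
pairwise_overlap <- function(store, by = "continent") {
  sets <- .unit_sets(store, by)
  units <- names(sets)
  n <- length(units)
  m <- matrix(0L, n, n, dimnames = list(units, units))
  for (i in seq_len(n)) for (j in seq_len(n))
    m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  m
}

#' Distribution of a taxon within a latitude band
#'
#' Filters samples to the latitude band (inclusive) and ZOTUs to those
#' whose assigned lineage carries the taxon at the stated rank; reports the
#' distinct-ZOTU count per sample. The default band is the tropics
#' (+/- 23.43651 degrees, the astronomical tropic latitude).
#'
#' @param store a store.
#' @param rank one of kingdom, phylum, class, order, family, genus,
#'   species.
#' @param name taxon name at that rank (e.g. "Russulaceae").
#' @param lat_min,lat_max latitude band in decimal degrees, inclusive.
#' @return data.frame with \code{srs}, \code{latitude}, \code{longitude},
#'   \code{n_zotus}; zero rows when the taxon or band is empty.
#' @export
taxon_in_latitude_band <- function(store, rank, name,
                                   lat_min = -23.43651,
                                   lat_max = 23.43651) {
  if (!(rank %in% .RANKS))
    stop("unknown rank '", rank, "'; valid ranks: ",
         paste(.RANKS, collapse = ", "))
  samples <- store_table(store, "samples")
  contains <- store_table(store, "contains")
  taxa <- store_table(store, "assign_taxa")
  in_band <- !is.na(samples$latitude) &
    samples$latitude >= lat_min & samples$latitude <= lat_max
  samp <- samples[in_band, , drop = FALSE]
  empty <- data.frame(srs = character(), latitude = numeric(),
                      longitude = numeric(), n_zotus = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(samp) == 0L || nrow(taxa) == 0L) return(empty)
  hit_refs <- taxa$ref_id[!is.na(.lineage_rank(taxa$lineage, rank)) &
                            .lineage_rank(taxa$lineage, rank) == name]
  if (length(hit_refs) == 0L) return(empty)
  cc <- contains[contains$srs %in% samp$srs &
                   contains$ref_id %in% hit_refs, , drop = FALSE]
  if (nrow(cc) == 0L) return(empty)
  counts <- tapply(cc$ref_id, cc$srs, function(x) length(unique(x)))
  out <- data.frame(srs = names(counts),
                    n_zotus = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- merge(out, samp[, c("srs", "latitude", "longitude")], by = "srs")
  out <- out[order(out$srs), c("srs", "latitude", "longitude", "n_zotus")]
  rownames(out) <- NULL
  out
}

#' Export band-query results as GeoJSON points
#'
#' Map-ready output: one Point feature per sample with its distinct-ZOTU
#' count as a property.
#'
#' @param band_result as from [taxon_in_latitude_band()].
#' @param path output file.
#' @export
write_geojson_points <- function(band_result, path) {
  features <- lapply(seq_len(nrow(band_result)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(band_result$longitude[i],
                                         band_result$latitude[i])),
         properties = list(srs = band_result$srs[i],
                           n_zotus = band_result$n_zotus[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
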