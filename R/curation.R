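# Metadata curation: heterogeneous free-text sample annotations are
# standardized into comparable fields (ISO dates, decimal coordinates,
# gazetteer countries and continents, ENVO biome terms) while every original
# value is kept as provenance.

#' Standardize a collection-date string to ISO 8601
#'
#' Recognized dialects: \code{YYYY-MM-DD}, \code{DD-Mon-YYYY},
#' \code{Mon-YYYY}, \code{YYYY} and \code{MM/DD/YYYY}. Partial dates keep
#' only the precision actually present ("2014" stays a year, "Aug-2014"
#' becomes "2014-08"). Anything else fails soft: NA with a logged warning —
#' silent guessing would corrupt provenance.
#'
#' @param raw a character scalar (may be NA/empty).
#' @return ISO-8601 date string at the input's precision, or NA_character_.
#' @export
#' @examples
#' standardize_date("12-Aug-2014")  # "2014-08-12"
#' standardize_date("Aug-2014")     # "2014-08"
#' standardize_date("2014")         # "2014"
standardize_date <- function(raw) {
  if (length(raw) != 1L) return(vapply(raw, standardize_date, character(1),
                                       USE.NAMES = FALSE))
  if (is.na(raw)) return(NA_character_)
  s <- trimws(raw)
  if (!nzchar(s)) return(NA_character_)
  months <- c(jan = 1, feb = 2, mar = 3, apr = 4, may = 5, jun = 6,
              jul = 7, aug = 8, sep = 9, oct = 10, nov = 11, dec = 12)
  ok_day <- function(y, m, d) {
    !is.na(as.Date(sprintf("%04d-%02d-%02d", y, m, d), format = "%Y-%m-%d"))
  }
  # YYYY-MM-DD
  if (grepl("^\\d{4}-\\d{1,2}-\\d{1,2}$", s)) {
    p <- as.integer(strsplit(s, "-", fixed = TRUE)[[1]])
    if (ok_day(p[1], p[2], p[3]))
      return(sprintf("%04d-%02d-%02d", p[1], p[2], p[3]))
  }
  # DD-Mon-YYYY
  if (grepl("^\\d{1,2}-[A-Za-z]{3}-\\d{4}$", s)) {
    p <- strsplit(s, "-", fixed = TRUE)[[1]]
    m <- months[tolower(p[2])]
    if (!is.na(m) && ok_day(as.integer(p[3]), m, as.integer(p[1])))
      return(sprintf("%04d-%02d-%02d", as.integer(p[3]), m, as.integer(p[1])))
  }
  # Mon-YYYY
  if (grepl("^[A-Za-z]{3}-\\d{4}$", s)) {
    p <- strsplit(s, "-", fixed = TRUE)[[1]]
    m <- months[tolower(p[1])]
    if (!is.na(m)) return(sprintf("%04d-%02d", as.integer(p[2]), m))
  }
  # YYYY
  if (grepl("^\\d{4}$", s)) return(s)
  # MM/DD/YYYY
  if (grepl("^\\d{1,2}/\\d{1,2}/\\d{4}$", s)) {
    p <- as.integer(strsplit(s, "/", fixed = TRUE)[[1]])
    if (ok_day(p[3], p[1], p[2]))
      return(sprintf("%04d-%02d-%02d", p[3], p[1], p[2]))
  }
  .log_msg("standardize_date: unparseable date '", raw, "'")
  NA_character_
}

# Parse one coordinate component: decimal degrees or DMS with a hemisphere
# letter. Returns signed decimal degrees or NA.
.parse_coord_component <- function(s, hemis) {
  s <- trimws(s)
  hemi <- NA_character_
  m <- regmatches(s, regexpr(sprintf("[%s]$", hemis), toupper(s)))
  if (length(m) && nzchar(m)) {
    hemi <- m
    s <- trimws(sub(sprintf("[%s%s]$", hemis, tolower(hemis)), "", s))
  }
  # DMS: degrees, optional minutes, optional seconds with unicode or ASCII marks
  dms <- regmatches(
    s,
    regexec(paste0("^(-?\\d+(?:\\.\\d+)?)\\s*[°d]",
                   "(?:\\s*(\\d+(?:\\.\\d+)?)\\s*[′'m])?",
                   "(?:\\s*(\\d+(?:\\.\\d+)?)\\s*[″\"s])?$"), s)
  )[[1]]
  if (length(dms)) {
    deg <- as.numeric(dms[2])
    mins <- if (nzchar(dms[3])) as.numeric(dms[3]) else 0
    secs <- if (nzchar(dms[4])) as.numeric(dms[4]) else 0
    if (mins >= 60 || secs >= 60) return(NA_real_)
    val <- abs(deg) + mins / 60 + secs / 3600
    if (deg < 0) val <- -val
  } else if (grepl("^-?\\d+(\\.\\d+)?$", s)) {
    val <- as.numeric(s)
  } else {
    return(NA_real_)
  }
  if (!is.na(hemi) && hemi %in% c("S", "W")) val <- -val
  val
}

#' Parse a free-text coordinate field into decimal latitude/longitude
#'
#' Accepts decimal-with-hemisphere ("52.15 N 4.48 E"), signed decimal
#' ("52.15, 4.48") and degree-minute-second notation ("52°09′36″N
#' 4°29′E"); DMS is converted as deg + min/60 + sec/3600, negated
#' for the S and W hemispheres. Results are rounded to 6 decimal places.
#' Malformed or out-of-range input yields NULL with a logged warning.
#'
#' @param raw a character scalar.
#' @return named numeric vector \code{c(latitude=, longitude=)} or NULL.
#' @export
#' @examples
#' parse_coordinates("52°09′N 4°29′E")
#' parse_coordinates("-33.87, 151.21")
parse_coordinates <- function(raw) {
  if (is.null(raw) || length(raw) != 1L || is.na(raw)) return(NULL)
  s <- trimws(raw)
  if (!nzchar(s)) return(NULL)
  # split into a latitude part and a longitude part
  if (grepl(",", s, fixed = TRUE)) {
    parts <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  } else if (grepl("[NnSs]", s)) {
    # hemisphere-annotated: split after the N/S letter
    parts <- regmatches(
      s, regexec("^(.*?[NnSs])\\s+(.*[EeWw])$", s))[[1]][-1]
  } else {
    parts <- strsplit(s, "\\s+")[[1]]
  }
  if (length(parts) != 2L) {
    .log_msg("parse_coordinates: cannot split '", raw, "'")
    return(NULL)
  }
  lat <- .parse_coord_component(parts[1], "NS")
  lon <- .parse_coord_component(parts[2], "EW")
  if (is.na(lat) || is.na(lon)) {
    .log_msg("parse_coordinates: malformed '", raw, "'")
    return(NULL)
  }
  if (abs(lat) > 90 || abs(lon) > 180) {
    .log_msg("parse_coordinates: out of range '", raw, "'")
    return(NULL)
  }
  c(latitude = round(lat, 6), longitude = round(lon, 6))
}

#' Format decimal coordinates as a signed-decimal field
#'
#' The inverse of [parse_coordinates()] on the signed-decimal dialect;
#' used by the round-trip property tests.
#' @param lat,lon decimal degrees.
#' @return character scalar like \code{"52.15, 4.48"}.
#' @export
format_coordinates <- function(lat, lon) {
  sprintf("%.6f, %.6f", lat, lon)
}

#' Load the bundled country gazetteer
#'
#' Countries with aliases, GeoNames identifiers, continent membership,
#' centroid coordinates and a bounding box — the offline stand-in for the
#' GeoNames country hierarchy.
#'
#' @param path TSV path; default is the bundled gazetteer.
#' @return data.frame, one row per country.
#' @export
read_gazetteer <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("gazetteer.tsv")
  g <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("country_name", "aliases", "geoname_id", "continent",
            "centroid_lat", "centroid_lon",
            "bbox_min_lat", "bbox_min_lon", "bbox_max_lat", "bbox_max_lon")
  if (!all(need %in% names(g)))
    stop("gazetteer must have columns: ", paste(need, collapse = ", "))
  g$aliases[is.na(g$aliases)] <- ""
  bad <- g$centroid_lat < g$bbox_min_lat | g$centroid_lat > g$bbox_max_lat |
    g$centroid_lon < g$bbox_min_lon | g$centroid_lon > g$bbox_max_lon
  if (any(bad))
    stop("gazetteer centroid outside bbox for: ",
         paste(g$country_name[bad], collapse = ", "))
  g
}

#' Assign curated geography to a sample
#'
#' The raw country term is matched case-insensitively against gazetteer
#' names and aliases; the continent and GeoNames id come from the matched
#' entry. Coordinates are taken as reported when inside the country's
#' bounding box; replaced by the country centroid when absent
#' (\code{CENTROID_FALLBACK}) or outside the box (\code{CORRECTED} — the
#' offline equivalent of the map-based coordinate repair).
#'
#' @param country_raw raw country term (may be NA).
#' @param coords NULL or numeric \code{c(latitude, longitude)}.
#' @param gazetteer as from [read_gazetteer()].
#' @return list with \code{country}, \code{geoname_id}, \code{continent},
#'   \code{latitude}, \code{longitude}, \code{coord_source}; all-NA fields
#'   (with \code{coord_source="REPORTED"} retained only when coords given)
#'   when the country is unknown.
#' @export
assign_geography <- function(country_raw, coords = NULL,
                             gazetteer = read_gazetteer()) {
  empty <- list(country = NA_character_, geoname_id = NA_integer_,
                continent = NA_character_, latitude = NA_real_,
                longitude = NA_real_, coord_source = NA_character_)
  if (is.null(country_raw) || is.na(country_raw) || !nzchar(trimws(country_raw))) {
    if (!is.null(coords)) {
      empty$latitude <- unname(coords[1]); empty$longitude <- unname(coords[2])
      empty$coord_source <- "REPORTED"
    }
    return(empty)
  }
  key <- tolower(trimws(country_raw))
  # SRA geo_loc_name convention is "Country: region"; match on the country part
  key <- trimws(strsplit(key, ":", fixed = TRUE)[[1]][1])
  idx <- which(vapply(seq_len(nrow(gazetteer)), function(i) {
    nms <- tolower(c(gazetteer$country_name[i],
                     strsplit(gazetteer$aliases[i], ";", fixed = TRUE)[[1]]))
    key %in% trimws(nms)
  }, logical(1)))
  if (length(idx) == 0L) {
    .log_msg("assign_geography: unknown country '", country_raw, "'")
    if (!is.null(coords)) {
      empty$latitude <- unname(coords[1]); empty$longitude <- unname(coords[2])
      empty$coord_source <- "REPORTED"
    }
    return(empty)
  }
  g <- gazetteer[idx[1], ]
  if (is.null(coords)) {
    lat <- g$centroid_lat; lon <- g$centroid_lon; src <- "CENTROID_FALLBACK"
  } else {
    lat <- unname(coords[1]); lon <- unname(coords[2])
    inside <- lat >= g$bbox_min_lat && lat <= g$bbox_max_lat &&
      lon >= g$bbox_min_lon && lon <= g$bbox_max_lon
    if (inside) {
      src <- "REPORTED"
    } else {
      lat <- g$centroid_lat; lon <- g$centroid_lon; src <- "CORRECTED"
    }
  }
  list(country = g$country_name, geoname_id = as.integer(g$geoname_id),
       continent = g$continent, latitude = lat, longitude = lon,
       coord_source = src)
}

#' Load the bundled ENVO term dictionary
#'
#' @param path TSV path with columns \code{label} and \code{envo_id};
#'   default bundled dictionary.
#' @return data.frame.
#' @export
read_envo_dictionary <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("envo_terms.tsv")
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("label", "envo_id") %in% names(d)))
    stop("ENVO dictionary must have columns label, envo_id")
  d
}

#' Tag a habitat description with an ENVO term
#'
#' Exact dictionary lookup: the longest dictionary label contained
#' (case-insensitively) in the habitat text wins. This replaces named-entity
#' recognition with a deterministic contract: term in, ENVO id out.
#'
#' @param habitat_raw free-text habitat/biome description.
#' @param envo_dictionary as from [read_envo_dictionary()].
#' @return NULL, or list with \code{label} and \code{envo_id}.
#' @export
tag_environment <- function(habitat_raw,
                            envo_dictionary = read_envo_dictionary()) {
  if (is.null(habitat_raw) || is.na(habitat_raw) || !nzchar(habitat_raw))
    return(NULL)
  hay <- tolower(habitat_raw)
  hit <- vapply(tolower(envo_dictionary$label), function(lab) {
    grepl(lab, hay, fixed = TRUE)
  }, logical(1))
  if (!any(hit)) return(NULL)
  cand <- envo_dictionary[hit, , drop = FALSE]
  best <- cand[order(-nchar(cand$label), cand$label)[1], ]
  list(label = best$label, envo_id = best$envo_id)
}

#' Curate a table of raw sample metadata
#'
#' Applies date standardization, coordinate parsing, geography assignment
#' and environment tagging to every row of a raw sample table, producing a
#' curated table that also carries every raw value as provenance columns
#' (\code{raw_*}) — curation is non-destructive.
#'
#' @param samples data.frame with columns \code{srs}, and optionally
#'   \code{collection_date}, \code{geo_loc_name}, \code{lat_lon},
#'   \code{env_biome}, \code{env_material}.
#' @param gazetteer,envo_dictionary reference tables; bundled defaults.
#' @return data.frame of curated samples, one row per input row.
#' @export
curate_samples <- function(samples, gazetteer = read_gazetteer(),
                           envo_dictionary = read_envo_dictionary()) {
  stopifnot("srs" %in% names(samples))
  get_col <- function(nm) {
    if (nm %in% names(samples)) as.character(samples[[nm]])
    else rep(NA_character_, nrow(samples))
  }
  date_raw <- get_col("collection_date")
  country_raw <- get_col("geo_loc_name")
  latlon_raw <- get_col("lat_lon")
  biome_raw <- get_col("env_biome")
  material_raw <- get_col("env_material")
  out <- lapply(seq_len(nrow(samples)), function(i) {
    coords <- parse_coordinates(latlon_raw[i])
    geo <- assign_geography(country_raw[i], coords, gazetteer)
    env <- tag_environment(biome_raw[i], envo_dictionary)
    data.frame(
      srs = samples$srs[i],
      collection_date_iso = standardize_date(date_raw[i]),
      country = geo$country,
      geoname_id = geo$geoname_id,
      continent = geo$continent,
      latitude = geo$latitude,
      longitude = geo$longitude,
      coord_source = geo$coord_source,
      biome_label = if (is.null(env)) NA_character_ else env$label,
      biome_envo_id = if (is.null(env)) NA_character_ else env$envo_id,
      raw_collection_date = date_raw[i],
      raw_geo_loc_name = country_raw[i],
      raw_lat_lon = latlon_raw[i],
      raw_env_biome = biome_raw[i],
      raw_env_material = material_raw[i],
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
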