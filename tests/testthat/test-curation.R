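test_that("dates standardize to ISO 8601 at their native precision", {
  cases <- list(
    c("12-Aug-2014", "2014-08-12"),
    c("2014-08-12", "2014-08-12"),
    c("Aug-2014", "2014-08"),
    c("2014", "2014"),
    c("08/12/2014", "2014-08-12")
  )
  for (cs in cases) expect_equal(standardize_date(cs[1]), cs[2])
  expect_true(is.na(standardize_date("sometime in summer")))
  expect_true(is.na(standardize_date("2014-13-40")))
  expect_true(is.na(standardize_date(NA_character_)))
})

test_that("coordinates parse from all three dialects", {
  expect_equal(parse_coordinates("52°09′N 4°29′E"),
               c(latitude = 52.15, longitude = round(4 + 29 / 60, 6)))
  expect_equal(parse_coordinates("52°09′36″N 4°29′E"),
               c(latitude = round(52 + 9 / 60 + 36 / 3600, 6),
                 longitude = round(4 + 29 / 60, 6)))
  expect_equal(parse_coordinates("52.15 N 4.48 E"),
               c(latitude = 52.15, longitude = 4.48))
  expect_equal(parse_coordinates("33.87 S 151.21 E"),
               c(latitude = -33.87, longitude = 151.21))
  expect_equal(parse_coordinates("52.15, 4.48"),
               c(latitude = 52.15, longitude = 4.48))
  expect_equal(parse_coordinates("0 N 0 E"),
               c(latitude = 0, longitude = 0))
  expect_null(parse_coordinates("95 N 10 E"))
  expect_null(parse_coordinates("10 N 190 E"))
  expect_null(parse_coordinates("not recorded"))
})

test_that("coordinate format/parse round-trips within 1e-6 degrees", {
  set.seed(7)
  lat <- c(stats::runif(200, -90, 90), -90, 90, 0)
  lon <- c(stats::runif(200, -180, 180), -180, 180, 0)
  for (i in seq_along(lat)) {
    back <- parse_coordinates(format_coordinates(lat[i], lon[i]))
    expect_lt(abs(back["latitude"] - lat[i]), 1e-6)
    expect_lt(abs(back["longitude"] - lon[i]), 1e-6)
  }
})

test_that("geography assignment: fallback, passthrough, correction", {
  gaz <- read_gazetteer()
  nl <- gaz[gaz$country_name == "Netherlands", ]

  g <- assign_geography("Netherlands", NULL, gaz)
  expect_equal(g$continent, "Europe")
  expect_equal(g$geoname_id, nl$geoname_id)
  expect_identical(g$latitude, nl$centroid_lat)   # centroid exactly
  expect_identical(g$longitude, nl$centroid_lon)
  expect_equal(g$coord_source, "CENTROID_FALLBACK")

  g <- assign_geography("Netherlands", c(52.1, 4.5), gaz)
  expect_equal(g$coord_source, "REPORTED")
  expect_equal(c(g$latitude, g$longitude), c(52.1, 4.5))

  g <- assign_geography("Netherlands", c(-33.9, 151.2), gaz)
  expect_equal(g$coord_source, "CORRECTED")
  expect_identical(c(g$latitude, g$longitude),
                   c(nl$centroid_lat, nl$centroid_lon))

  # case-insensitive alias matching
  expect_equal(assign_geography("the netherlands", NULL, gaz)$country,
               "Netherlands")
  # unknown country: geography absent
  g <- assign_geography("Atlantis", NULL, gaz)
  expect_true(is.na(g$country) && is.na(g$continent))
})

test_that("assigned coordinates always stay in range", {
  gaz <- read_gazetteer()
  set.seed(13)
  for (i in 1:100) {
    cn <- sample(gaz$country_name, 1)
    coords <- if (stats::runif(1) < 0.3) NULL else
      c(stats::runif(1, -90, 90), stats::runif(1, -180, 180))
    g <- assign_geography(cn, coords, gaz)
    expect_true(g$latitude >= -90 && g$latitude <= 90)
    expect_true(g$longitude >= -180 && g$longitude <= 180)
    if (g$coord_source == "CENTROID_FALLBACK") {
      gi <- gaz[gaz$country_name == g$country, ]
      expect_identical(g$latitude, gi$centroid_lat)
      expect_identical(g$longitude, gi$centroid_lon)
    }
  }
})

test_that("environment tagging picks the longest dictionary label", {
  dict <- data.frame(label = c("soil", "forest soil"),
                     envo_id = c("ENVO:00001998", "ENVO:00002261"),
                     stringsAsFactors = FALSE)
  hit <- tag_environment("temperate broadleaf forest soil", dict)
  expect_equal(hit$label, "forest soil")
  expect_equal(hit$envo_id, "ENVO:00002261")
  expect_identical(tag_environment("FOREST SOIL", dict), hit)
  expect_null(tag_environment("", dict))
  expect_null(tag_environment("open ocean", dict))
})

test_that("curation is non-destructive: provenance reconstructs raw input", {
  corp <- make_corpus_and_metadata(seed = 3)
  cur <- curate_samples(corp$samples)
  expect_identical(cur$raw_collection_date,
                   as.character(corp$samples$collection_date))
  expect_identical(cur$raw_geo_loc_name,
                   as.character(corp$samples$geo_loc_name))
  expect_identical(cur$raw_lat_lon, as.character(corp$samples$lat_lon))
  expect_identical(cur$raw_env_biome, as.character(corp$samples$env_biome))
  expect_identical(cur$raw_env_material,
                   as.character(corp$samples$env_material))
})

test_that("curated values match the generator's truth table", {
  for (seed in c(2, 5, 9)) {
    corp <- make_corpus_and_metadata(seed = seed)
    cur <- curate_samples(corp$samples)
    tr <- corp$sample_truth
    expect_equal(cur$collection_date_iso, tr$expected_date)
    expect_equal(cur$country, tr$expected_country)
    expect_equal(cur$continent, tr$expected_continent)
    expect_equal(cur$coord_source, tr$expected_coord_source)
    both <- !is.na(tr$expected_lat)
    expect_equal(cur$latitude[both], tr$expected_lat[both], tolerance = 1e-6)
    expect_equal(cur$longitude[both], tr$expected_lon[both],
                 tolerance = 1e-6)
  }
})
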