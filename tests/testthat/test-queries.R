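simple_store <- function() {
  st <- new_store()
  lin <- function(ph, fam = "Russulaceae")
    sprintf("k__Fungi;p__%s;c__C;o__O;f__%s;g__G;s__S", ph, fam)
  z <- function(s, l) data.frame(sequence = s, abundance = 5L,
                                 marker = "ITS2", lineage = l,
                                 best_hit = "H", identity = 95,
                                 stringsAsFactors = FALSE)
  update_store(st, list(
    list(srs = "SRS_EU", srr = "R1",
         zotus = rbind(z("AAAA", lin("Basidiomycota")),
                       z("CCCC", lin("Ascomycota", "Amanitaceae")))),
    list(srs = "SRS_AS", srr = "R2",
         zotus = rbind(z("AAAA", lin("Basidiomycota")),
                       z("GGGG", lin("Weirdomycota", "Mockaceae"))))))
  assign("samples", data.frame(
    srs = c("SRS_EU", "SRS_AS"),
    continent = c("Europe", "Asia"),
    country = c("Netherlands", "Indonesia"),
    latitude = c(52.1, -5.0), longitude = c(4.5, 120.0),
    stringsAsFactors = FALSE), envir = st)
  st
}

test_that("phylum-by-continent counts presence once per continent", {
  st <- simple_store()
  tab <- phylum_by_continent(st)
  get <- function(ph, cont) {
    v <- tab[[cont]][tab$phylum == ph]
    if (length(v)) v else 0L
  }
  expect_equal(get("Basidiomycota", "Europe"), 1L)
  expect_equal(get("Basidiomycota", "Asia"), 1L)  # spans two continents
  expect_equal(get("Ascomycota", "Europe"), 1L)
  expect_equal(get("Other", "Asia"), 1L)          # Weirdomycota pooled
  expect_equal(nrow(phylum_by_continent(new_store())), 0L)
})

test_that("shared and pairwise overlaps follow set semantics", {
  st <- simple_store()
  # Z(Europe) = {AAAA, CCCC}, Z(Asia) = {AAAA, GGGG}
  expect_equal(shared_zotus(st, "Europe"), 1L)
  expect_equal(shared_zotus(st, "Asia"), 1L)
  expect_equal(shared_zotus(st, "Oceania"), 0L)
  m <- pairwise_overlap(st)
  expect_equal(m["Europe", "Asia"], 1L)
  expect_true(isSymmetric(m))
  expect_equal(m["Europe", "Europe"], 2L)
  expect_equal(m["Asia", "Asia"], 2L)
})

test_that("a single-continent store shares nothing", {
  st <- simple_store()
  samp <- store_table(st, "samples")
  samp$continent <- "Europe"
  assign("samples", samp, envir = st)
  expect_equal(shared_zotus(st, "Europe"), 0L)
})

test_that("latitude-band taxon queries filter by band and lineage", {
  st <- simple_store()
  res <- taxon_in_latitude_band(st, "family", "Russulaceae")
  # only SRS_AS (lat -5) is inside the tropics; its Russulaceae ZOTU: AAAA
  expect_equal(res$srs, "SRS_AS")
  expect_equal(res$n_zotus, 1L)
  # the European sample at lat 52.1 is excluded
  expect_false("SRS_EU" %in% res$srs)
  wide <- taxon_in_latitude_band(st, "family", "Russulaceae", -90, 90)
  expect_setequal(wide$srs, c("SRS_EU", "SRS_AS"))
  expect_equal(nrow(taxon_in_latitude_band(st, "family", "Nosuchaceae")),
               0L)
  expect_error(taxon_in_latitude_band(st, "subtribe", "X"),
               "kingdom.*phylum")
})

test_that("band results export as GeoJSON points", {
  st <- simple_store()
  res <- taxon_in_latitude_band(st, "family", "Russulaceae", -90, 90)
  path <- tempfile(fileext = ".geojson")
  write_geojson_points(res, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), nrow(res))
  expect_equal(gj$features[[1]]$geometry$type, "Point")
})

test_that("double counting across continents is bounded by distinct totals", {
  set.seed(61)
  for (i in 1:5) {
    rs <- random_query_store(n_refs = 30, n_samples = 15, n_contains = 120)
    m <- pairwise_overlap(rs$store)
    per_cont <- diag(m)
    global <- length(unique(rs$contains$ref_id[
      rs$contains$srs %in% rs$samples$srs]))
    expect_gte(sum(per_cont), global)
  }
})
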