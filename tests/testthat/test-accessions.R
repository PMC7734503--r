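test_that("extract_accessions finds accessions with offsets and archives", {
  hits <- extract_accessions("deposited in the SRA Study SRP043706.")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$accession, "SRP043706")
  expect_equal(hits$prefix_class, "SRP")
  expect_equal(hits$archive, "SRA")
  expect_equal(hits$char_offset, 27L)

  expect_equal(nrow(extract_accessions("")), 0L)

  hits <- extract_accessions(
    "see PRJNA12345 and runs SRR1502225–SRR1502736; contact surplus@x")
  expect_setequal(hits$accession,
                  c("PRJNA12345", "SRR1502225", "SRR1502736"))
  expect_false(any(hits$prefix_class == "SRP"))
})

test_that("extract_accessions rejects in-word and digit-less prefixes", {
  expect_equal(nrow(extract_accessions("the SRA Study was large")), 0L)
  expect_equal(nrow(extract_accessions("preSRP999999 or SRP999999x")), 0L)
  expect_equal(nrow(extract_accessions("SRR12 too few digits")), 0L)
  expect_equal(nrow(extract_accessions("ERS9999999999 too many")), 0L)
})

test_that("extraction is idempotent, offset-sorted, concatenation-stable", {
  txt1 <- "Data at SRP043706 and PRJEB123456."
  txt2 <- " Later ERS765432 appeared."
  h1 <- extract_accessions(txt1)
  expect_identical(h1, extract_accessions(txt1))
  expect_true(!is.unsorted(h1$char_offset))
  h12 <- extract_accessions(paste0(txt1, txt2))
  h2 <- extract_accessions(txt2)
  expect_equal(h12$accession, c(h1$accession, h2$accession))
  expect_equal(h12$char_offset,
               c(h1$char_offset, h2$char_offset + nchar(txt1)))
})

test_that("every match carries the archive its prefix maps to", {
  pref <- accession_prefixes()
  txt <- paste(sprintf("%s123456", pref$prefix_class), collapse = " and ")
  hits <- extract_accessions(txt)
  expect_equal(nrow(hits), nrow(pref))
  expect_equal(hits$archive,
               pref$archive[match(hits$prefix_class, pref$prefix_class)])
})

test_that("extraction agrees with the brute-force scan oracle", {
  set.seed(11)
  for (rep in 1:20) {
    corp <- make_corpus_and_metadata(seed = rep)
    got <- extract_accessions(corp$text)
    want <- oracle_scan_accessions(corp$text)
    expect_equal(got$accession, want$accession)
    expect_equal(got$char_offset, want$char_offset)
  }
})

test_that("structured databank references take precedence and are validated", {
  pub <- publication_record("10.1000/x", body_text = "body cites SRP99999")
  refs <- data.frame(archive_name = "BioProject", accession = "PRJNA12345",
                     stringsAsFactors = FALSE)
  out <- map_publication_to_studies(pub, refs)
  expect_equal(out$accession, "PRJNA12345")

  out <- map_publication_to_studies(
    publication_record("10.1000/x", body_text = "SRP043706"))
  expect_equal(out$accession, "SRP043706")

  bad <- data.frame(archive_name = "SRA", accession = "XYZ123",
                    stringsAsFactors = FALSE)
  expect_warning(out <- map_publication_to_studies(pub, bad), "XYZ123")
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "rejected"), "XYZ123")
})

test_that("accession ranges expand explicitly, never implicitly", {
  hits <- extract_accessions("runs SRR1502225-SRR1502736 were used")
  expect_equal(nrow(hits), 2L)  # endpoints only
  expanded <- expand_accession_range("SRR1502225", "SRR1502230")
  expect_equal(expanded,
               sprintf("SRR%d", 1502225:1502230))
  expect_error(expand_accession_range("SRR1502225", "SRX1502230"),
               "prefix")
})

test_that("resolve_primers finds oriented pairs case-insensitively", {
  tab <- read_primer_table()
  hit <- resolve_primers("amplified with fITS7 and ITS4", tab)
  expect_equal(hit$fwd_name, "fITS7")
  expect_equal(hit$rev_name, "ITS4")
  expect_equal(hit$marker, "ITS2")

  expect_identical(resolve_primers("primers its4 and FITS7", tab), hit)
  expect_null(resolve_primers("", tab))
  expect_null(resolve_primers("only ITS4 was given", tab))
  # two candidate forward primers -> ambiguity, absent
  expect_null(resolve_primers("with fITS7 or gITS7 and ITS4", tab))
})

test_that("sra_hierarchy enforces the sample constraint", {
  exps <- data.frame(srx = "SRX1", platform = "ILLUMINA_MISEQ",
                     sample = "SRS1", stringsAsFactors = FALSE)
  runs <- data.frame(srr = "SRR1", srx = "SRX1", stringsAsFactors = FALSE)
  h <- sra_hierarchy("SRP1000", exps, runs)
  expect_s3_class(h, "sra_hierarchy")
  exps_bad <- exps
  exps_bad$sample <- ""
  expect_error(sra_hierarchy("SRP1000", exps_bad, runs), "Sample is always")
  runs_bad <- data.frame(srr = "SRR2", srx = "SRX9")
  expect_error(sra_hierarchy("SRP1000", exps, runs_bad), "unknown experiment")
})
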