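mk_zotus <- function(seqs, marker = "ITS2", lineage = NULL) {
  df <- data.frame(sequence = seqs,
                   abundance = seq_along(seqs) + 1L,
                   marker = marker, stringsAsFactors = FALSE)
  if (!is.null(lineage)) {
    df$lineage <- lineage
    df$best_hit <- "HIT"
    df$identity <- 90
  }
  df
}

test_that("update_store deduplicates sequences and tracks provenance", {
  st <- new_store()
  r1 <- update_store(st, list(
    list(srs = "SRS1", srr = "SRR1", zotus = mk_zotus(c("AAAA", "CCCC")))))
  r2 <- update_store(st, list(
    list(srs = "SRS2", srr = "SRR2", zotus = mk_zotus(c("CCCC", "GGGG")))))
  expect_equal(r1$inserted_refs, 2L)
  expect_equal(r2$inserted_refs, 1L)
  expect_equal(r2$reused_refs, 1L)
  expect_equal(nrow(store_table(st, "reference_sequence")), 3L)
  expect_equal(nrow(store_table(st, "contains")), 4L)
  # conservation within each update
  expect_equal(r1$contains_added, r1$inserted_refs + r1$reused_refs)
  expect_equal(r2$contains_added, r2$inserted_refs + r2$reused_refs)
})

test_that("replaying a run is idempotent", {
  st <- new_store()
  entry <- list(srs = "SRS1", srr = "SRR1",
                zotus = mk_zotus(c("AAAA", "CCCC")))
  update_store(st, list(entry))
  r <- update_store(st, list(entry))
  expect_equal(r$inserted_refs, 0L)
  expect_equal(r$contains_added, 0L)
  expect_equal(r$replays_skipped, 2L)
  expect_equal(nrow(store_table(st, "contains")), 2L)
})

test_that("sequence case is normalized; marker conflicts are hard errors", {
  st <- new_store()
  update_store(st, list(list(srs = "S1", srr = "R1",
                             zotus = mk_zotus("acgt"))))
  r <- update_store(st, list(list(srs = "S2", srr = "R2",
                                  zotus = mk_zotus("ACGT"))))
  expect_equal(r$reused_refs, 1L)
  expect_error(
    update_store(st, list(list(srs = "S3", srr = "R3",
                               zotus = mk_zotus("ACGT", marker = "ITS1")))),
    "marker conflict")
  expect_error(
    update_store(st, list(list(srs = "S4", srr = "R4",
                               zotus = mk_zotus(c("TTTT", "TTTT"))))),
    "duplicate")
})

test_that("contains additivity holds over multi-update schedules", {
  set.seed(51)
  pool <- random_dna(60, 20, seed = 51)
  st <- new_store()
  seen <- character()
  total_contains <- 0L
  run_i <- 0L
  for (upd in 1:4) {
    entries <- lapply(1:3, function(k) {
      run_i <<- run_i + k
      list(srs = sprintf("SRS%03d", upd * 10 + k),
           srr = sprintf("SRR%03d", upd * 10 + k),
           zotus = mk_zotus(sample(pool, sample(5:15, 1))))
    })
    r <- update_store(st, entries)
    n_obs <- sum(vapply(entries, function(e) nrow(e$zotus), integer(1)))
    expect_equal(r$contains_added, n_obs)
    expect_equal(r$inserted_refs + r$reused_refs, r$contains_added)
    new_seqs <- unique(unlist(lapply(entries,
                                     function(e) e$zotus$sequence)))
    expect_equal(r$inserted_refs, length(setdiff(new_seqs, seen)))
    seen <- union(seen, new_seqs)
    total_contains <- total_contains + n_obs
    expect_equal(nrow(store_table(st, "contains")), total_contains)
    expect_equal(nrow(store_table(st, "reference_sequence")),
                 length(seen))
  }
})

test_that("the final reference set is order-insensitive", {
  set.seed(52)
  pool <- random_dna(20, 15, seed = 52)
  entries <- lapply(1:5, function(k) {
    list(srs = paste0("S", k), srr = paste0("R", k),
         zotus = mk_zotus(sample(pool, 8)))
  })
  seqs_of <- function(perm) {
    st <- new_store()
    for (e in entries[perm]) update_store(st, list(e))
    sort(store_table(st, "reference_sequence")$sequence)
  }
  base <- seqs_of(1:5)
  for (p in list(5:1, c(3, 1, 5, 2, 4))) {
    expect_equal(seqs_of(p), base)
  }
})

test_that("taxon assignments are stored for new references and gated", {
  st <- new_store()
  lin <- "k__Fungi;p__Ascomycota;c__C;o__O;f__F;g__G;s__S"
  update_store(st, list(list(srs = "S1", srr = "R1",
                             zotus = mk_zotus("AAAA", lineage = lin))))
  taxa <- store_table(st, "assign_taxa")
  expect_equal(taxa$lineage, lin)
  expect_equal(taxa$identity, 90)
  bad <- mk_zotus("CCCC", lineage = lin)
  bad$identity <- 60
  expect_error(update_store(st, list(list(srs = "S2", srr = "R2",
                                          zotus = bad))),
               "identity")
})

test_that("import_curated enforces referential closure record by record", {
  st <- new_store()
  curated <- curate_samples(data.frame(
    srs = c("SRS1", "SRS2"), geo_loc_name = "Netherlands",
    stringsAsFactors = FALSE))
  h <- list(study = "SRP1000",
            experiments = data.frame(
              srx = c("SRX1", "SRX2", "SRX3"),
              platform = "ILLUMINA_MISEQ",
              sample = c("SRS1", "SRS2", ""),
              stringsAsFactors = FALSE),
            runs = data.frame(
              srr = c("SRR1", "SRR2", "SRR9"),
              srx = c("SRX1", "SRX2", "SRX404"),
              stringsAsFactors = FALSE))
  rep <- import_curated(st, curated, h)
  expect_equal(rep$experiments, 2L)
  expect_equal(rep$runs, 2L)
  expect_setequal(rep$rejected$record, c("SRX3", "SRR9"))
  expect_equal(nrow(store_table(st, "runs")), 2L)
  expect_equal(nrow(store_table(st, "samples")), 2L)
})

test_that("a store survives a CSV export/import round trip", {
  set.seed(53)
  st <- new_store()
  lin <- "k__Fungi;p__Basidiomycota;c__C;o__O;f__F;g__G;s__S"
  update_store(st, list(
    list(srs = "SRS1", srr = "SRR1",
         zotus = mk_zotus(random_dna(5, 30, seed = 53), lineage = lin)),
    list(srs = "SRS2", srr = "SRR2",
         zotus = mk_zotus(random_dna(3, 30, seed = 54), lineage = lin))))
  curated <- curate_samples(data.frame(
    srs = c("SRS1", "SRS2"), geo_loc_name = c("Chile", "Japan"),
    lat_lon = c("-35.7, -71.5", NA), collection_date = c("2014", NA),
    stringsAsFactors = FALSE))
  import_curated(st, curated, list(
    study = "SRP1",
    experiments = data.frame(srx = c("SRX1", "SRX2"),
                             platform = "ILLUMINA_MISEQ",
                             sample = c("SRS1", "SRS2"),
                             stringsAsFactors = FALSE),
    runs = data.frame(srr = c("SRR1", "SRR2"), srx = c("SRX1", "SRX2"),
                      stringsAsFactors = FALSE)))
  record_process(st, data.frame(
    srr = "SRR1", platform = "ILLUMINA_MISEQ", marker = "ITS2",
    fwd_primer = "A", rev_primer = "C", max_ee = 1, min_overlap = 60L,
    min_length = 250L, alpha = 2, min_size = 8L,
    pipeline_version = "test", stringsAsFactors = FALSE))
  dir <- tempfile()
  export_store(st, dir)
  st2 <- import_store(dir)
  for (nm in c("reference_sequence", "contains", "assign_taxa", "samples",
               "experiments", "runs", "studies", "process")) {
    expect_equal(store_table(st2, nm), store_table(st, nm),
                 info = nm)
  }
})
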