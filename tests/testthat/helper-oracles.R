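# Independent oracles used by the property and acceptance tests. These are
# deliberately separate implementations (plain loops, own dynamic
# programming) so that package code is never checked against itself.

# Brute-force accession scan: walk every position, check prefix, digits and
# word boundaries by hand.
oracle_scan_accessions <- function(text) {
  prefixes <- c("PRJNA", "PRJEB", "SRA", "SRP", "SRS", "SRX", "SRR",
                "ERP", "ERS")
  chars <- strsplit(text, "")[[1]]
  is_alnum <- function(ch) grepl("[A-Za-z0-9]", ch)
  out <- list()
  n <- length(chars)
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (p in prefixes) {
      np <- nchar(p)
      if (i + np - 1L > n) next
      if (paste(chars[i:(i + np - 1L)], collapse = "") != p) next
      if (i > 1L && is_alnum(chars[i - 1L])) next
      j <- i + np
      digits <- 0L
      while (j <= n && grepl("[0-9]", chars[j])) {
        digits <- digits + 1L
        j <- j + 1L
      }
      if (digits < 4L || digits > 9L) next
      if (j <= n && is_alnum(chars[j])) next
      out[[length(out) + 1L]] <- data.frame(
        accession = paste(chars[i:(j - 1L)], collapse = ""),
        prefix_class = p, char_offset = i - 1L, stringsAsFactors = FALSE)
      i <- j
      matched <- TRUE
      break
    }
    if (!matched) i <- i + 1L
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(accession = character(), prefix_class = character(),
               char_offset = integer(), stringsAsFactors = FALSE)
}

# Plain dynamic-programming Levenshtein distance.
oracle_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  na <- length(x)
  nb <- length(y)
  prev <- 0:nb
  for (i in seq_len(na)) {
    cur <- numeric(nb + 1L)
    cur[1] <- i
    for (j in seq_len(nb)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L,
                         prev[j] + (x[i] != y[j]))
    }
    prev <- cur
  }
  prev[nb + 1L]
}

# Independent transcription of the denoising rule: sort by abundance
# (ties lexicographic), then for each unique exhaustively examine every
# established centroid with the skew threshold beta(d) = 1 / 2^(alpha d + 1)
# computed from scratch, joining the nearest eligible one.
oracle_denoise <- function(uniques, alpha = 2, min_size = 8) {
  ord <- order(-uniques$abundance, uniques$sequence)
  uniques <- uniques[ord, , drop = FALSE]
  centroids <- list()  # each: seq, own, total
  assigned <- rep(NA_integer_, nrow(uniques))
  for (i in seq_len(nrow(uniques))) {
    a <- uniques$abundance[i]
    s <- uniques$sequence[i]
    best <- NA_integer_
    best_d <- Inf
    for (k in seq_along(centroids)) {
      d <- oracle_levenshtein(s, centroids[[k]]$seq)
      thr <- 1 / 2^(alpha * d + 1)
      if (a / centroids[[k]]$own <= thr && d < best_d) {
        best <- k
        best_d <- d
      }
    }
    if (!is.na(best)) {
      centroids[[best]]$total <- centroids[[best]]$total + a
      assigned[i] <- best
    } else if (a >= min_size) {
      centroids[[length(centroids) + 1L]] <-
        list(seq = s, own = a, total = a)
      assigned[i] <- length(centroids)
    }
  }
  if (!length(centroids))
    return(data.frame(sequence = character(), abundance = integer(),
                      stringsAsFactors = FALSE))
  out <- data.frame(
    sequence = vapply(centroids, `[[`, character(1), "seq"),
    abundance = vapply(centroids, function(c) as.integer(c$total),
                       integer(1)),
    stringsAsFactors = FALSE)
  out[order(-out$abundance, seq_len(nrow(out))), , drop = FALSE]
}

# Needleman-Wunsch with free end gaps, match +1 / mismatch -1 / gap -1 per
# position; identity = matches / alignment columns on a deterministic
# traceback (diagonal preferred, then up, then left).
oracle_alignment_identity <- function(q, s) {
  x <- strsplit(q, "")[[1]]
  y <- strsplit(s, "")[[1]]
  n <- length(x)
  m <- length(y)
  S <- matrix(0, n + 1L, m + 1L)   # free leading gaps
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- S[i, j] + if (x[i] == y[j]) 1 else -1
      S[i + 1L, j + 1L] <- max(sub, S[i, j + 1L] - 1, S[i + 1L, j] - 1)
    }
  }
  # free trailing gaps: best cell on the last row or column
  lastcol <- S[, m + 1L]
  lastrow <- S[n + 1L, ]
  if (max(lastcol) >= max(lastrow)) {
    i <- which.max(lastcol) - 1L
    j <- m
  } else {
    i <- n
    j <- which.max(lastrow) - 1L
  }
  matches <- 0L
  cols <- 0L
  while (i > 0L && j > 0L) {
    sub <- S[i, j] + if (x[i] == y[j]) 1 else -1
    if (S[i + 1L, j + 1L] == sub) {
      matches <- matches + (x[i] == y[j])
      cols <- cols + 1L
      i <- i - 1L
      j <- j - 1L
    } else if (S[i + 1L, j + 1L] == S[i, j + 1L] - 1) {
      cols <- cols + 1L
      i <- i - 1L
    } else {
      cols <- cols + 1L
      j <- j - 1L
    }
  }
  if (cols == 0L) return(0)
  100 * matches / cols
}

# Mutate a sequence to an approximate target identity (substitutions only).
mutate_to_identity <- function(seq, identity) {
  chars <- strsplit(seq, "")[[1]]
  n_mut <- round(length(chars) * (1 - identity / 100))
  pos <- sample(length(chars), n_mut)
  for (p in pos)
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  paste(chars, collapse = "")
}

# Small random store builder used by query-equivalence tests: returns the
# store plus the raw tables the brute-force recomputation uses.
random_query_store <- function(n_refs = 50, n_samples = 20, n_contains = 300,
                               continents = c("Africa", "Asia", "Europe",
                                              "Oceania")) {
  phyla <- c("Ascomycota", "Basidiomycota", "Mucoromycota", "Weirdomycota",
             "unidentified")
  families <- c("Russulaceae", "Amanitaceae", "Boletaceae")
  st <- new_store()
  refs <- data.frame(
    ref_id = seq_len(n_refs),
    sequence = paste0("SEQ", seq_len(n_refs)),
    marker = "ITS2", length = 10L, stringsAsFactors = FALSE)
  ph <- sample(phyla, n_refs, replace = TRUE)
  fam <- sample(families, n_refs, replace = TRUE)
  taxa <- data.frame(
    ref_id = refs$ref_id,
    lineage = sprintf("k__Fungi;p__%s;c__C;o__O;f__%s;g__G;s__S", ph, fam),
    best_hit_name = "HIT", identity = 90, stringsAsFactors = FALSE)
  samples <- data.frame(
    srs = sprintf("SRS%04d", seq_len(n_samples)),
    continent = sample(continents, n_samples, replace = TRUE),
    country = "X",
    latitude = round(stats::runif(n_samples, -60, 60), 4),
    longitude = round(stats::runif(n_samples, -180, 180), 4),
    stringsAsFactors = FALSE)
  contains <- unique(data.frame(
    ref_id = sample(n_refs, n_contains, replace = TRUE),
    srs = sample(samples$srs, n_contains, replace = TRUE),
    stringsAsFactors = FALSE))
  contains$srr <- paste0("RUN_", contains$srs)
  contains$abundance <- sample(1:100, nrow(contains), replace = TRUE)
  assign("reference_sequence", refs, envir = st)
  assign("assign_taxa", taxa, envir = st)
  assign("samples", samples, envir = st)
  assign("contains", contains, envir = st)
  list(store = st, refs = refs, taxa = taxa, samples = samples,
       contains = contains, phyla = ph, families = fam)
}
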