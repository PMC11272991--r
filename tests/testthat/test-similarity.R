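test_that("local alignment follows the documented contract", {
  p <- alignment_params()
  expect_identical(local_align("ACGT", "ACGT")[1:3],
                   list(raw_score = 8L, identities = 4L, aln_length = 4L))
  # local alignment trims a trailing mismatch
  expect_identical(local_align("ACGT", "ACGA")[1:3],
                   list(raw_score = 6L, identities = 3L, aln_length = 3L))
  # no positive-scoring alignment at all
  expect_identical(local_align("AAAA", "TTTT")[1:3],
                   list(raw_score = 0L, identities = 0L, aln_length = 0L))
  # ambiguity codes are mismatches even against themselves
  expect_identical(local_align("ACGN", "ACGN")[1:3],
                   list(raw_score = 6L, identities = 3L, aln_length = 3L))
  expect_error(local_align("", "ACGT"), "non-empty")
  expect_error(local_align("ACGT", ""), "non-empty")
})

test_that("fast kernels agree with the matrix-DP oracle and Biostrings", {
  mat <- matrix(-3L, 16, 16,
                dimnames = list(Biostrings::DNA_ALPHABET[1:16],
                                Biostrings::DNA_ALPHABET[1:16]))
  diag(mat)[1:4] <- 2L
  set.seed(11)
  for (rep in 1:60) {
    q <- random_dna(sample(8:45, 1))
    s <- if (runif(1) < 0.5) mutate_dna(q, runif(1, 0, 0.4))
         else random_dna(sample(8:45, 1))
    got <- local_align(q, s)
    ora <- oracle_align(q, s)
    expect_identical(got$raw_score, ora[["raw_score"]])
    expect_identical(got$identities, ora[["identities"]])
    expect_identical(got$aln_length, ora[["aln_length"]])
    # batch (SIMD when available) path must equal the single-pair path
    batch <- acrobar:::.sw_align_batch_cpp(q, c(s, q), 2L, -3L, 5L, 2L)
    expect_identical(unname(batch[1, ]),
                     c(got$raw_score, got$identities, got$aln_length))
    # independent score cross-check: Biostrings local alignment
    bs <- Biostrings::pairwiseAlignment(q, s, substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 2,
                                        type = "local")
    expect_identical(got$raw_score,
                     max(0L, as.integer(Biostrings::score(bs))))
  }
})

test_that("bit scores follow the Karlin-Altschul form", {
  p <- alignment_params()
  expect_equal(bit_score(100, p), (0.625 * 100 - log(0.41)) / log(2),
               tolerance = 1e-12)
  expect_equal(bit_score(100, p), 91.456, tolerance = 1e-3)
  expect_equal(bit_score(0, p), 1.286, tolerance = 1e-3)
  raw <- 0:50
  expect_true(all(diff(bit_score(raw, p)) > 0))
  # e-value definition
  expect_equal(e_value(10, 100, 1000), 100 * 1000 * 2^-10)
})

test_that("search ranks, deduplicates, excludes and truncates hits", {
  db <- toy_db()
  h <- search_db("ACGTACGTACGTACGTACGT", db)
  expect_identical(h$subject_id[1], "d1")
  expect_identical(h$pct_identity[1], 100)
  expect_true(all(diff(h$bit_score) <= 0))

  # two identical records tie and are ordered by subject id
  db2 <- build_reference_db(reference_records(
    c("b", "a"), c("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGT"),
    c("Acropora tenuis", "Acropora millepora"), locus = "mtCR"))
  h2 <- search_db("ACGTACGTACGTACGTACGT", db2)
  expect_identical(h2$subject_id, c("a", "b"))
  expect_identical(h2$pct_identity, c(100, 100))

  # excluding the query's own record removes it from the hits
  h3 <- search_db(db$records[1, ], db, exclude = "d1")
  expect_false("d1" %in% h3$subject_id)

  expect_identical(nrow(search_db("ACGTACGTACGTACGTACGT", db,
                                  max_hits = 1L)), 1L)
  empty <- build_reference_db(reference_records(
    character(0), character(0), character(0), locus = "mtCR"))
  expect_error(search_db("ACGT", empty), "empty")
  # disjoint-alphabet query yields no positive hits at all
  ac_only <- build_reference_db(reference_records(
    c("x", "y"), c("ACACACACAC", "CACACACACA"), "Acropora millepora",
    locus = "mtCR"))
  expect_identical(nrow(search_db("GTGTGTGTGT", ac_only)), 0L)
})

test_that("search matches a brute-force align-and-sort oracle", {
  set.seed(23)
  for (rep in 1:12) {
    n_rec <- sample(4:9, 1)
    base <- random_dna(50)
    seqs <- vapply(seq_len(n_rec), function(i) {
      if (runif(1) < 0.7) mutate_dna(base, runif(1, 0, 0.2))
      else random_dna(50)
    }, "")
    db <- build_reference_db(reference_records(
      sprintf("r%02d", seq_len(n_rec)), seqs,
      paste("Acropora", acrobar:::sim_epithet(rep(1:3, length.out = n_rec))),
      locus = "mtCR"))
    q <- mutate_dna(base, 0.1)
    got <- search_db(q, db, query_id = "q")

    p <- alignment_params()
    rows <- lapply(seq_len(n_rec), function(i) {
      a <- oracle_align(q, seqs[i])
      if (a[["raw_score"]] <= 0) return(NULL)
      data.frame(subject_id = sprintf("r%02d", i),
                 species = db$records$species[i],
                 pct = round(100 * a[["identities"]] / a[["aln_length"]], 3),
                 bit = round(bit_score(a[["raw_score"]], p), 1),
                 raw = a[["raw_score"]], stringsAsFactors = FALSE)
    })
    want <- do.call(rbind, rows)
    want <- want[order(-want$bit, -want$pct, want$subject_id), ]
    expect_identical(got$subject_id, want$subject_id)
    expect_identical(got$bit_score, want$bit)
    expect_identical(got$pct_identity, want$pct)
    expect_identical(got$raw_score, want$raw)
  }
})

test_that("hit ordering is a stable total order under permutation", {
  set.seed(5)
  db <- build_reference_db(reference_records(
    sprintf("r%02d", 1:8),
    vapply(1:8, function(i) mutate_dna(strrep("ACGT", 15), 0.05), ""),
    paste("Acropora", acrobar:::sim_epithet(rep(1:4, 2))), locus = "mtCR"))
  q <- mutate_dna(strrep("ACGT", 15), 0.05)
  ref <- search_db(q, db, query_id = "q")
  for (rep in 1:6) {
    perm <- db$records[sample(nrow(db$records)), ]
    db2 <- build_reference_db(perm)
    expect_identical(search_db(q, db2, query_id = "q"), ref)
  }
})

test_that("tabular hit files round-trip and apply the best-HSP rule", {
  tmp <- tempfile(fileext = ".tsv")
  lines <- c(
    "q1\tref|Acropora millepora\t100.000\t500\t0\t0\t1\t500\t1\t500\t1e-100\t500.0",
    "q1\tref|Acropora millepora\t99.000\t500\t5\t0\t1\t500\t1\t500\t1e-90\t480.0",
    "q1\ts2|Acropora tenuis\t99.500\t480\t2\t0\t1\t480\t1\t480\t1e-95\t490.0",
    "q2\ts2|Acropora tenuis\t98.000\t450\t9\t0\t1\t450\t1\t450\t1e-80\t430.0")
  writeLines(lines, tmp)
  tabs <- read_tabular_hits(tmp)
  expect_identical(names(tabs), c("q1", "q2"))
  # best HSP per subject kept: the 500.0-bit row wins over 480.0
  q1 <- tabs$q1
  expect_identical(nrow(q1), 2L)
  expect_identical(q1$bit_score[q1$subject_id == "ref|Acropora millepora"],
                   500)
  expect_identical(q1$subject_id[1], "ref|Acropora millepora")
  expect_identical(q1$subject_species,
                   c("Acropora millepora", "Acropora tenuis"))

  # write -> read preserves the decision-relevant columns
  out <- tempfile(fileext = ".tsv")
  write_tabular_hits(tabs, out)
  lookup <- setNames(c("Acropora millepora", "Acropora tenuis"),
                     c("ref|Acropora millepora", "s2|Acropora tenuis"))
  back <- read_tabular_hits(out, species_lookup = lookup)
  for (qid in names(tabs)) {
    cols <- c("query_id", "subject_id", "subject_species", "pct_identity",
              "aln_length", "bit_score")
    expect_identical(back[[qid]][cols], tabs[[qid]][cols])
  }

  # empty file -> empty list
  writeLines(character(0), tmp)
  expect_identical(read_tabular_hits(tmp), list())

  # malformed numbers are flagged with their line
  writeLines(c(lines[1], sub("480.0", "abc", lines[2])), tmp)
  expect_error(read_tabular_hits(tmp), "line 2")

  # unresolved subject species are collected into the error
  writeLines("q1\tnospecies\t99.0\t100\t1\t0\t1\t100\t1\t100\t1e-10\t180.0",
             tmp)
  expect_error(read_tabular_hits(tmp), "nospecies")
})

test_that("locus verification picks the best locus or stays unknown", {
  set.seed(31)
  mt <- vapply(1:3, function(i) random_dna(120), "")
  nuc <- vapply(1:3, function(i) random_dna(120), "")
  refs <- list(
    mtCR = build_reference_db(reference_records(
      sprintf("m%d", 1:3), mt, "Acropora sp.", locus = "mtCR")),
    PaxC = build_reference_db(reference_records(
      sprintf("p%d", 1:3), nuc, "Acropora sp.", locus = "PaxC")))
  expect_identical(verify_locus(mt[1], refs), "mtCR")
  expect_identical(verify_locus(mutate_dna(nuc[2], 0.05), refs), "PaxC")
  expect_identical(verify_locus(random_dna(30), refs, min_bits = 50),
                   "UNKNOWN")
  # equal best bit scores across loci stay unresolved
  both <- list(
    A = build_reference_db(reference_records("a", mt[1], "Acropora sp.",
                                             locus = "A")),
    B = build_reference_db(reference_records("b", mt[1], "Acropora sp.",
                                             locus = "B")))
  expect_identical(verify_locus(mt[1], both), "UNKNOWN")
})

test_that("rotation to an anchor recovers the original frame", {
  r <- rotate_to_anchor("TTGGAACC", "AACC", min_anchor_bits = 5)
  expect_identical(r$sequence, "AACCTTGG")
  expect_identical(r$offset, 4L)

  r0 <- rotate_to_anchor("AACCTTGG", "AACC", min_anchor_bits = 5)
  expect_identical(r0$offset, 0L)
  expect_identical(r0$sequence, "AACCTTGG")

  expect_error(rotate_to_anchor("AACCTTGG", "GGGG", min_anchor_bits = 5),
               "anchor not found")
  expect_error(rotate_to_anchor("ACGT", "ACGTACGT"), "shorter")

  # random rotations of anchored sequences are undone exactly
  set.seed(47)
  anchor <- random_dna(40)
  for (rep in 1:10) {
    body <- random_dna(200)
    seq <- paste0(anchor, body)
    off <- sample(nchar(seq) - 1, 1)
    rotated <- paste0(substr(seq, off + 1, nchar(seq)), substr(seq, 1, off))
    rec <- rotate_to_anchor(rotated, anchor)
    expect_identical(rec$sequence, seq)
  }
})
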