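hit_row <- function(species, pct, bit, id = "s1") {
  data.frame(query_id = "q1", subject_id = id, subject_species = species,
             pct_identity = pct, aln_length = 500L, raw_score = 100L,
             bit_score = bit, e_value = 1e-10, stringsAsFactors = FALSE)
}

test_that("the four-step decision tree fires the documented rules", {
  X <- "Acropora alpha"; Y <- "Acropora beta"

  # single perfect hit
  r <- assign_species(hit_row(X, 100, 500), mode = "barcode")
  expect_identical(r$status, "ASSIGNED")
  expect_identical(r$species, X)
  expect_identical(r$rule_path, "UNIQUE_100")
  expect_identical(r$n_species_at_100, 1L)

  # two species at 100%: perfect-identity tie, bit tie, identity tie
  two <- rbind(hit_row(X, 100, 500, "s1"), hit_row(Y, 100, 500, "s2"))
  r2 <- assign_species(two, mode = "barcode")
  expect_identical(r2$status, "UNASSIGNED_TIE")
  expect_identical(r2$n_species_at_100, 2L)

  # barcode prioritises the unique 100% match; genome mode follows the
  # higher bit score instead
  mixed <- rbind(hit_row(X, 100, 480, "s1"), hit_row(Y, 99.5, 500, "s2"))
  rb <- assign_species(mixed, mode = "barcode")
  expect_identical(c(rb$species, rb$rule_path), c(X, "UNIQUE_100"))
  rg <- assign_species(mixed, mode = "genome")
  expect_identical(c(rg$species, rg$rule_path), c(Y, "BITSCORE_TOP"))

  # identity tie-break runs over the bit-tied hits and can still tie
  tie3 <- rbind(hit_row(X, 99, 500, "s1"), hit_row(Y, 99, 500, "s2"),
                hit_row(X, 98, 500, "s3"))
  r3 <- assign_species(tie3, mode = "barcode")
  expect_identical(r3$status, "UNASSIGNED_TIE")

  # ...or resolve when one species edges ahead
  tie4 <- rbind(hit_row(X, 99.5, 500, "s1"), hit_row(Y, 99, 500, "s2"))
  r4 <- assign_species(tie4, mode = "genome")
  expect_identical(c(r4$species, r4$rule_path), c(X, "IDENTITY_TIEBREAK"))

  # empty table
  r0 <- assign_species(empty_hit_table(), query_id = "qx")
  expect_identical(r0$status, "NO_HITS")
  expect_identical(r0$query_id, "qx")
  expect_identical(r0$n_species_at_100, 0L)
})

test_that("ambiguous-label winners are flagged, not silently dropped", {
  amb <- rbind(hit_row("Acropora sp.", 100, 500, "s1"),
               hit_row("Acropora alpha", 99, 480, "s2"))
  r <- assign_species(amb, mode = "barcode")
  expect_identical(r$status, "ASSIGNED_AMBIGUOUS")
  expect_identical(r$species, "Acropora sp.")
})

test_that("assignment is permutation-invariant and ignores dominated hits", {
  set.seed(13)
  tab <- rbind(hit_row("Acropora alpha", 99.5, 500, "s1"),
               hit_row("Acropora beta", 99.5, 490, "s2"),
               hit_row("Acropora gamma", 100, 480, "s3"),
               hit_row("Acropora alpha", 98, 470, "s4"))
  base <- assign_species(tab, mode = "barcode")
  for (rep in 1:10) {
    shuffled <- tab[sample(nrow(tab)), ]
    expect_identical(assign_species(shuffled, mode = "barcode"), base)
  }
  # a same-species hit dominated in both bit score and identity is inert
  dominated <- rbind(tab, hit_row("Acropora alpha", 97, 400, "s9"))
  same <- assign_species(dominated, mode = "barcode")
  expect_identical(same[c("status", "species", "rule_path")],
                   base[c("status", "species", "rule_path")])
})

test_that("random decision tables agree with the set-comprehension oracle", {
  set.seed(99)
  species_pool <- c("Acropora alpha", "Acropora beta", "Acropora sp.")
  for (rep in 1:300) {
    k <- sample(1:6, 1)
    tab <- data.frame(
      species = sample(species_pool, k, replace = TRUE),
      pct = sample(c(98, 99, 100), k, replace = TRUE),
      bit = sample(c(480, 500), k, replace = TRUE))
    for (mode in c("barcode", "genome")) {
      got <- assign_species(as_hit_table(tab), mode = mode)
      want <- oracle_rule(tab, mode)
      expect_identical(got$status, want$status)
      expect_identical(got$rule_path, want$rule)
      if (!is.na(want$species)) expect_identical(got$species, want$species)
      if (mode == "genome") expect_false(got$rule_path == "UNIQUE_100")
    }
  }
})

test_that("two-locus concordance follows the concurrence rule", {
  a <- function(species, status = "ASSIGNED", locus = "mtCR",
                qid = "AQ001") {
    hits <- if (is.null(species)) empty_hit_table() else {
      h <- hit_row(species, 100, 500)
      h$query_id <- qid
      h
    }
    assign_species(hits, mode = "barcode", locus = locus, query_id = qid)
  }
  mt <- a("Acropora abrotanoides")
  nuc <- a("Acropora abrotanoides", locus = "PaxC")
  cc <- concord(mt, nuc)
  expect_identical(cc$final, "CONCORDANT_SPECIES")
  expect_identical(cc$final_species, "Acropora abrotanoides")

  cc2 <- concord(a("Acropora alpha"), a(NULL, locus = "PaxC"))
  expect_identical(cc2$final, "PRELIMINARY_MT_ONLY")
  expect_true(is.na(cc2$final_species))

  cc3 <- concord(a(NULL), a("Acropora beta", locus = "PaxC"))
  expect_identical(cc3$final, "PRELIMINARY_NUC_ONLY")

  cc4 <- concord(a("Acropora alpha"), a("Acropora beta", locus = "PaxC"))
  expect_identical(cc4$final, "DISCORDANT")
  expect_true(is.na(cc4$final_species))

  # an ambiguous label never concurs
  cc5 <- concord(a("Acropora sp."), a("Acropora sp.", locus = "PaxC"))
  expect_identical(cc5$final, "NONE")

  # a cf.-qualified winner is ASSIGNED_AMBIGUOUS: it cannot concur, so the
  # cleanly assigned locus is left as a single-marker preliminary identity
  cc6 <- concord(a("Acropora cf. alpha"), a("Acropora alpha",
                                            locus = "PaxC"))
  expect_identical(cc6$final, "PRELIMINARY_NUC_ONLY")

  expect_error(concord(a("Acropora alpha"),
                       a("Acropora alpha", qid = "AQ999", locus = "PaxC")),
               "different samples")
  expect_error(concord(a("Acropora alpha"), a("Acropora alpha")),
               "locus")
})

test_that("concord_all pairs loci and backfills missing ones", {
  rows <- rbind(
    assign_species(hit_row("Acropora alpha", 100, 500), locus = "mtCR",
                   mode = "barcode"),
    assign_species(hit_row("Acropora alpha", 100, 500), locus = "PaxC",
                   mode = "barcode"))
  rows$query_id <- c("S1", "S2")
  cc <- concord_all(rows, mt_locus = "mtCR")
  expect_identical(nrow(cc), 2L)
  expect_identical(cc$final[cc$sample_id == "S1"], "PRELIMINARY_MT_ONLY")
  expect_identical(cc$final[cc$sample_id == "S2"], "PRELIMINARY_NUC_ONLY")
})
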