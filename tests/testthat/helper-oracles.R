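# Independent oracles, written from the contracts rather than the
# implementation. The alignment oracle is a plain-matrix Gotoh DP with the
# documented tie-break order (diagonal > gap-in-subject > gap-in-query >
# restart; optimum = first strictly-best cell in row-major order); the
# assignment oracle re-evaluates the four-step rule with set operations.

oracle_align <- function(query, subject, match = 2, mismatch = -3,
                         gap_open = 5, gap_extend = 2) {
  enc <- function(s) {
    v <- match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T"))
    ifelse(is.na(v), 5L, v)
  }
  q <- enc(query); s <- enc(subject)
  m <- length(q); n <- length(s)
  gi <- gap_open + gap_extend; ge <- gap_extend
  NEG <- -1e9
  zero <- c(0, 0, 0)  # score, identities, length
  H <- array(0, c(m + 1, n + 1, 3))
  Fm <- array(rep(c(NEG, 0, 0), each = (m + 1) * (n + 1)), c(m + 1, n + 1, 3))
  Em <- Fm
  best <- zero
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      eo <- H[i + 1, j, 1] - gi
      ee <- Em[i + 1, j, 1] - ge
      Em[i + 1, j + 1, ] <- if (eo >= ee) {
        c(eo, H[i + 1, j, 2], H[i + 1, j, 3] + 1)
      } else {
        c(ee, Em[i + 1, j, 2], Em[i + 1, j, 3] + 1)
      }
      fo <- H[i, j + 1, 1] - gi
      fe <- Fm[i, j + 1, 1] - ge
      Fm[i + 1, j + 1, ] <- if (fo >= fe) {
        c(fo, H[i, j + 1, 2], H[i, j + 1, 3] + 1)
      } else {
        c(fe, Fm[i, j + 1, 2], Fm[i, j + 1, 3] + 1)
      }
      ident <- q[i] == s[j] && q[i] <= 4
      h <- H[i, j, ] + c(if (ident) match else mismatch, as.integer(ident), 1)
      if (Em[i + 1, j + 1, 1] > h[1]) h <- Em[i + 1, j + 1, ]
      if (Fm[i + 1, j + 1, 1] > h[1]) h <- Fm[i + 1, j + 1, ]
      if (h[1] <= 0) h <- zero
      H[i + 1, j + 1, ] <- h
      if (h[1] > best[1]) best <- h
    }
  }
  setNames(as.integer(best), c("raw_score", "identities", "aln_length"))
}

# independent four-step rule evaluation over a bare hits table with columns
# species, pct, bit (already rounded to decision precision)
oracle_rule <- function(tab, mode) {
  if (nrow(tab) == 0L) {
    return(list(species = NA_character_, rule = "NONE", status = "NO_HITS"))
  }
  finish <- function(winner, rule) {
    amb <- grepl("\\b(sp\\.|cf\\.|aff\\.)( |$)", winner) |
      !grepl("^\\S+ \\S+$", winner)
    list(species = winner, rule = rule,
         status = if (amb) "ASSIGNED_AMBIGUOUS" else "ASSIGNED")
  }
  perfect <- unique(tab$species[tab$pct == 100])
  if (mode == "barcode" && length(perfect) == 1L) {
    return(finish(perfect, "UNIQUE_100"))
  }
  at_top_bit <- tab[tab$bit == max(tab$bit), , drop = FALSE]
  leaders <- unique(at_top_bit$species)
  if (length(leaders) == 1L) {
    return(finish(leaders, "BITSCORE_TOP"))
  }
  best_pct <- at_top_bit[at_top_bit$pct == max(at_top_bit$pct), , drop = FALSE]
  finalists <- unique(best_pct$species)
  if (length(finalists) == 1L) {
    return(finish(finalists, "IDENTITY_TIEBREAK"))
  }
  list(species = NA_character_, rule = "NONE", status = "UNASSIGNED_TIE")
}

# wrap a bare (species, pct, bit) table as a package hit table
as_hit_table <- function(tab, query_id = "q1") {
  data.frame(query_id = query_id,
             subject_id = sprintf("s%02d", seq_len(nrow(tab))),
             subject_species = tab$species,
             pct_identity = tab$pct,
             aln_length = 500L,
             raw_score = 100L,
             bit_score = tab$bit,
             e_value = 1e-10,
             stringsAsFactors = FALSE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(s, p) {
  v <- strsplit(s, "")[[1]]
  hit <- which(runif(length(v)) < p)
  if (length(hit) > 0) {
    v[hit] <- vapply(v[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, "")
  }
  paste(v, collapse = "")
}

# small two-species toy database used across tests
toy_db <- function() {
  build_reference_db(reference_records(
    c("d1", "d2", "m1"),
    c("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGA", "TTGCATTGCATTGCATTGCA"),
    c("Acropora digitifera", "Acropora digitifera", "Acropora millepora"),
    locus = "mtCR"))
}
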