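ASSIGN_STATUS <- c("ASSIGNED", "ASSIGNED_AMBIGUOUS", "UNASSIGNED_TIE",
                   "NO_HITS")

#' Assign a species to a query from its hit table
#'
#' The hierarchical decision tree applied per query and locus, evaluated
#' over distinct species (multiple hits to the same species never form a
#' tie):
#'
#' 1. *Barcode mode only*: if exactly one species is matched at 100.000%
#'    identity, assign it (`UNIQUE_100`).
#' 2. Otherwise, if exactly one species carries the maximum bit score,
#'    assign it (`BITSCORE_TOP`).
#' 3. Otherwise, among the bit-score-tied hits, if exactly one species
#'    carries the maximum percent identity, assign it (`IDENTITY_TIEBREAK`).
#' 4. Otherwise no species is assigned (`UNASSIGNED_TIE`).
#'
#' Genome mode (used for whole-mitogenome identification) skips step 1
#' because full-length genomes rarely reach a meaningful 100% match. Ties
#' use bit scores rounded to 1 decimal and identities to 3 decimals, the
#' granularity of tabular BLAST reports. A winning label that carries an
#' open-nomenclature qualifier gives status `ASSIGNED_AMBIGUOUS`; such
#' results are excluded from "assigned" tallies downstream.
#'
#' @param hits Hit table from [search_db()] or [read_tabular_hits()].
#' @param mode `"barcode"` or `"genome"`.
#' @param locus Optional locus tag recorded in the result.
#' @param min_aln_length Hits with a shorter alignment are ignored
#'   (default 0: no coverage requirement).
#' @param query_id Query id used when `hits` has no rows.
#' @return One-row `data.frame` with `query_id`, `locus`, `status`,
#'   `species` (grouping key or `NA`), `rule_path`, `top_identity`,
#'   `n_species_at_100`.
#' @examples
#' db <- build_reference_db(reference_records(
#'   c("r1", "r2"), c("ACGTACGTAC", "ACGTACGTAT"),
#'   c("Acropora millepora", "Acropora tenuis"), locus = "mtCR"))
#' assign_species(search_db("ACGTACGTAC", db), mode = "barcode")
#' @export
assign_species <- function(hits, mode = c("barcode", "genome"), locus = NA,
                           min_aln_length = 0L, query_id = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(hits))
  if (nrow(hits) > 0L) {
    query_id <- hits$query_id[1L]
    hits <- hits[hits$aln_length >= min_aln_length, , drop = FALSE]
  }
  result <- function(status, species, rule, top_id, n100) {
    out <- data.frame(query_id = query_id, locus = locus, status = status,
                      species = species, rule_path = rule,
                      top_identity = top_id, n_species_at_100 = n100,
                      stringsAsFactors = FALSE)
    class(out) <- c("assignment", "data.frame")
    out
  }
  if (nrow(hits) == 0L) {
    return(result("NO_HITS", NA_character_, "NONE", NA_real_, 0L))
  }
  hits <- sort_hits(hits)
  s100 <- unique(hits$subject_species[hits$pct_identity == 100])
  n100 <- length(s100)
  top_id <- max(hits$pct_identity)

  winner <- NULL
  rule <- "NONE"
  if (mode == "barcode" && n100 == 1L) {
    winner <- s100
    rule <- "UNIQUE_100"
  } else {
    top_bit <- max(hits$bit_score)
    tied <- hits[hits$bit_score == top_bit, , drop = FALSE]
    sb <- unique(tied$subject_species)
    if (length(sb) == 1L) {
      winner <- sb
      rule <- "BITSCORE_TOP"
    } else {
      top_pct <- max(tied$pct_identity)
      sp <- unique(tied$subject_species[tied$pct_identity == top_pct])
      if (length(sp) == 1L) {
        winner <- sp
        rule <- "IDENTITY_TIEBREAK"
      }
    }
  }
  if (is.null(winner)) {
    return(result("UNASSIGNED_TIE", NA_character_, "NONE", top_id, n100))
  }
  status <- if (is_unambiguous(parse_species_label(winner))) "ASSIGNED"
            else "ASSIGNED_AMBIGUOUS"
  result(status, winner, rule, top_id, n100)
}

#' Assign species for every query against a database
#'
#' Convenience wrapper: searches each query with [search_db()] and applies
#' [assign_species()], returning one row per query.
#'
#' @param queries Record table of query sequences (`record_id`, `sequence`).
#' @param db Reference database.
#' @param mode,params,max_hits,min_aln_length Passed through.
#' @param locus Locus tag recorded on every row (defaults to the database's).
#' @return `data.frame` of assignment rows.
#' @export
assign_queries <- function(queries, db, mode = c("barcode", "genome"),
                           params = alignment_params(), max_hits = 100L,
                           min_aln_length = 0L, locus = db$locus) {
  mode <- match.arg(mode)
  rows <- lapply(seq_len(nrow(queries)), function(i) {
    hits <- search_db(queries[i, ], db, params = params, max_hits = max_hits)
    assign_species(hits, mode = mode, locus = locus,
                   min_aln_length = min_aln_length,
                   query_id = queries$record_id[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-locus concordance of per-locus assignments
#'
#' A specimen receives a species identity only when both markers were
#' unambiguously assigned and agree at binomial level
#' (`CONCORDANT_SPECIES`). Two unambiguous assignments to different species
#' are `DISCORDANT`; exactly one assigned locus gives a preliminary,
#' single-marker identity; anything else (including ambiguous-label
#' assignments, which never concur) is `NONE`.
#'
#' @param mt,nuc One-row assignment `data.frame`s for the same query at two
#'   different loci (mitochondrial and nuclear).
#' @return One-row `data.frame`: `sample_id`, per-locus status and species,
#'   `final` (one of `CONCORDANT_SPECIES`, `DISCORDANT`,
#'   `PRELIMINARY_MT_ONLY`, `PRELIMINARY_NUC_ONLY`, `NONE`) and
#'   `final_species` (only for concordant samples).
#' @export
concord <- function(mt, nuc) {
  stopifnot(is.data.frame(mt), nrow(mt) == 1L,
            is.data.frame(nuc), nrow(nuc) == 1L)
  if (!identical(mt$query_id, nuc$query_id)) {
    stop("assignments refer to different samples: ", mt$query_id, " vs ",
         nuc$query_id, call. = FALSE)
  }
  if (!is.na(mt$locus) && !is.na(nuc$locus) &&
      identical(mt$locus, nuc$locus)) {
    stop("both assignments are for locus ", mt$locus, call. = FALSE)
  }
  mt_ok <- mt$status == "ASSIGNED"
  nuc_ok <- nuc$status == "ASSIGNED"
  final <- if (mt_ok && nuc_ok) {
    if (same_species(mt$species, nuc$species)) "CONCORDANT_SPECIES"
    else "DISCORDANT"
  } else if (mt_ok) {
    "PRELIMINARY_MT_ONLY"
  } else if (nuc_ok) {
    "PRELIMINARY_NUC_ONLY"
  } else {
    "NONE"
  }
  data.frame(
    sample_id = mt$query_id,
    mt_locus = mt$locus, mt_status = mt$status, mt_species = mt$species,
    nuc_locus = nuc$locus, nuc_status = nuc$status, nuc_species = nuc$species,
    final = final,
    final_species = if (final == "CONCORDANT_SPECIES") mt$species
                    else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Concordance across a table of per-locus assignments
#'
#' Pairs the two loci per query id and applies [concord()]. Queries seen at
#' only one locus get a missing (`NO_HITS`) placeholder for the other.
#'
#' @param assignments `data.frame` of assignment rows for exactly two loci.
#' @param mt_locus Which locus plays the mitochondrial role (default: first
#'   locus in the table).
#' @return `data.frame`, one row per query id.
#' @export
concord_all <- function(assignments, mt_locus = NULL) {
  loci <- unique(assignments$locus)
  if (length(loci) != 2L) {
    stop("need assignments for exactly two loci, found: ",
         paste(loci, collapse = ", "), call. = FALSE)
  }
  if (is.null(mt_locus)) mt_locus <- loci[1L]
  nuc_locus <- setdiff(loci, mt_locus)
  placeholder <- function(qid, locus) {
    assign_species(empty_hit_table(), locus = locus, query_id = qid)
  }
  ids <- unique(assignments$query_id)
  rows <- lapply(ids, function(qid) {
    mt <- assignments[assignments$query_id == qid &
                        assignments$locus == mt_locus, , drop = FALSE]
    nuc <- assignments[assignments$query_id == qid &
                         assignments$locus == nuc_locus, , drop = FALSE]
    if (nrow(mt) == 0L) mt <- placeholder(qid, mt_locus)
    if (nrow(nuc) == 0L) nuc <- placeholder(qid, nuc_locus)
    concord(mt[1L, ], nuc[1L, ])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write assignment rows as TSV
#'
#' Columns: `sample_id`, `locus`, `status`, `species`, `rule_path`,
#' `top_identity`, `n_species_at_100`.
#'
#' @param assignments Assignment rows.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_assignments <- function(assignments, path) {
  out <- data.frame(sample_id = assignments$query_id,
                    locus = assignments$locus,
                    status = assignments$status,
                    species = assignments$species,
                    rule_path = assignments$rule_path,
                    top_identity = formatC(assignments$top_identity,
                                           format = "f", digits = 3),
                    n_species_at_100 = assignments$n_species_at_100)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
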