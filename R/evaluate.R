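#' Leave-one-out self-identification of a reference database
#'
#' Every record is queried against the database minus itself and assigned in
#' genome mode (bit score first, identity tie-break, no 100%-identity
#' shortcut). Records whose species has only one record are excluded as
#' queries -- they cannot possibly self-identify -- but remain in the
#' database as possible hits. Correctness is judged at binomial level
#' (genus + epithet; qualifiers on the truth label are ignored).
#'
#' @param db Reference database (>= 2 records).
#' @param params [alignment_params()].
#' @param max_hits Hits kept per query.
#' @param min_aln_length Passed to [assign_species()].
#' @return Object of class `loo_result`: list with `outcomes` (a
#'   `data.frame`: `record_id`, `true_species`, `assigned_species`,
#'   `status`, `rule_path`, `verdict`), `n_evaluated`, `n_correct` and
#'   `success_rate_pct` (`NA` when nothing was evaluable).
#' @examples
#' db <- build_reference_db(reference_records(
#'   c("a1", "a2", "b1"), c("ACGTACGTACGT", "ACGTACGTACGT", "TTGCATTGCATT"),
#'   c("Acropora digitifera", "Acropora digitifera", "Acropora millepora"),
#'   locus = "mitogenome"))
#' loo_evaluate(db)
#' @export
loo_evaluate <- function(db, params = alignment_params(), max_hits = 100L,
                         min_aln_length = 0L) {
  stopifnot(inherits(db, "reference_db"))
  if (nrow(db$records) < 2L) {
    stop("leave-one-out needs at least 2 records", call. = FALSE)
  }
  singles <- singleton_species(db)
  rec <- db$records
  rows <- lapply(seq_len(nrow(rec)), function(i) {
    base <- data.frame(record_id = rec$record_id[i],
                       true_species = rec$species[i],
                       stringsAsFactors = FALSE)
    if (rec$species[i] %in% singles) {
      base$assigned_species <- NA_character_
      base$status <- NA_character_
      base$rule_path <- NA_character_
      base$verdict <- "EXCLUDED_SINGLETON"
      return(base)
    }
    hits <- search_db(rec[i, ], db, params = params, max_hits = max_hits,
                      exclude = rec$record_id[i])
    res <- assign_species(hits, mode = "genome", locus = db$locus,
                          min_aln_length = min_aln_length,
                          query_id = rec$record_id[i])
    base$assigned_species <- res$species
    base$status <- res$status
    base$rule_path <- res$rule_path
    base$verdict <- if (res$status == "ASSIGNED" &&
                          same_species(res$species, rec$species[i])) {
      "CORRECT"
    } else if (res$status %in% c("ASSIGNED", "ASSIGNED_AMBIGUOUS")) {
      "INCORRECT"
    } else {
      "UNASSIGNED"
    }
    base
  })
  outcomes <- do.call(rbind, rows)
  rownames(outcomes) <- NULL
  evaluated <- outcomes$verdict != "EXCLUDED_SINGLETON"
  n_eval <- sum(evaluated)
  n_correct <- sum(outcomes$verdict == "CORRECT")
  structure(
    list(outcomes = outcomes,
         n_evaluated = n_eval,
         n_correct = n_correct,
         success_rate_pct = if (n_eval == 0L) NA_real_ else
           round(100 * n_correct / n_eval, 2)),
    class = "loo_result"
  )
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf(
    "leave-one-out: %d evaluated, %d correct (%s%%), %d excluded singleton(s)\n",
    x$n_evaluated, x$n_correct,
    if (is.na(x$success_rate_pct)) "NA" else
      formatC(x$success_rate_pct, format = "f", digits = 2),
    sum(x$outcomes$verdict == "EXCLUDED_SINGLETON")))
  invisible(x)
}

#' Identification success rate from a verdict table
#'
#' Percentage of `CORRECT` verdicts among non-excluded records, to 2
#' decimals. Unassigned records count in the denominator: a tie is a failed
#' identification.
#'
#' @param verdicts Character vector of verdicts (`CORRECT`, `INCORRECT`,
#'   `UNASSIGNED`, `EXCLUDED_SINGLETON`).
#' @return Numeric percentage.
#' @examples
#' success_rate(c(rep("CORRECT", 35), rep("INCORRECT", 75)))  # 31.82
#' @export
success_rate <- function(verdicts) {
  kept <- verdicts[verdicts != "EXCLUDED_SINGLETON"]
  if (length(kept) == 0L) {
    stop("nothing evaluable: all records excluded", call. = FALSE)
  }
  round(100 * sum(kept == "CORRECT") / length(kept), 2)
}

#' Write a leave-one-out report
#'
#' Writes the per-record outcome table as TSV and, optionally, the summary
#' (`n_evaluated`, `n_correct`, `success_rate_pct`) as JSON.
#'
#' @param loo A `loo_result`.
#' @param tsv_path Output TSV.
#' @param json_path Optional output JSON.
#' @return Invisibly, `tsv_path`.
#' @export
write_loo_report <- function(loo, tsv_path, json_path = NULL) {
  stopifnot(inherits(loo, "loo_result"))
  write.table(loo$outcomes, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(n_evaluated = loo$n_evaluated, n_correct = loo$n_correct,
           success_rate_pct = loo$success_rate_pct),
      json_path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  }
  invisible(tsv_path)
}
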