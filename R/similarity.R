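#' Alignment scoring parameters
#'
#' Scoring scheme for local DNA alignment plus the Karlin-Altschul
#' parameters that rescale raw scores into bit scores. The defaults are the
#' classic blastn-style values: match +2, mismatch -3, gap open 5, gap
#' extend 2 (a gap of length k costs `gap_open + k * gap_extend`), lambda
#' 0.625 nats per score unit and K 0.41.
#'
#' @param match Match reward (integer >= 1).
#' @param mismatch Mismatch penalty (integer <= -1).
#' @param gap_open Gap opening cost (integer >= 0).
#' @param gap_extend Per-column gap extension cost (integer >= 1).
#' @param lambda Karlin-Altschul lambda (> 0), nats per raw-score unit.
#' @param K Karlin-Altschul K, in (0, 1).
#' @return Object of class `alignment_params`.
#' @examples
#' alignment_params()
#' @export
alignment_params <- function(match = 2L, mismatch = -3L, gap_open = 5L,
                             gap_extend = 2L, lambda = 0.625, K = 0.41) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  stopifnot(match >= 1L, mismatch <= -1L, gap_open >= 0L, gap_extend >= 1L,
            lambda > 0, K > 0, K < 1)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "alignment_params")
}

#' @export
print.alignment_params <- function(x, ...) {
  cat(sprintf(
    "alignment_params: match %+d, mismatch %+d, gap %d+%dk, lambda %g, K %g\n",
    x$match, x$mismatch, x$gap_open, x$gap_extend, x$lambda, x$K))
  invisible(x)
}

#' Local alignment of two DNA sequences
#'
#' Smith-Waterman local alignment with affine gaps. The alignment length
#' counts all aligned columns including gap columns; IUPAC ambiguity codes
#' (including N) score as mismatches and never count as identities, even
#' against themselves. When no positive-scoring local alignment exists, all
#' fields are zero.
#'
#' @param query,subject DNA strings (non-empty).
#' @param params [alignment_params()].
#' @return Named list: `raw_score`, `identities`, `aln_length`, `qstart`,
#'   `qend`, `sstart`, `send` (1-based coordinates; zeros when there is no
#'   alignment).
#' @examples
#' local_align("ACGT", "ACGA")  # trailing mismatch trimmed: score 6, 3/3
#' @export
local_align <- function(query, subject, params = alignment_params()) {
  stopifnot(inherits(params, "alignment_params"))
  if (!nzchar(query) || !nzchar(subject)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  res <- .sw_align_cpp(query, subject, params$match, params$mismatch,
                       params$gap_open, params$gap_extend)
  as.list(res)
}

#' Karlin-Altschul bit score
#'
#' `(lambda * raw_score - ln K) / ln 2`, unrounded. Strictly increasing in
#' the raw score. Hit tables store the value rounded to 1 decimal, the
#' granularity at which bit-score ties are decided.
#'
#' @param raw_score Integer raw alignment score(s).
#' @param params [alignment_params()].
#' @return Numeric vector of bit scores.
#' @export
bit_score <- function(raw_score, params = alignment_params()) {
  (params$lambda * raw_score - log(params$K)) / log(2)
}

#' Expected number of chance hits (E-value)
#'
#' `m * n * 2^-bits` with `m` the query length and `n` the total database
#' length. Reported for completeness; no assignment decision uses it.
#'
#' @param bits Bit score(s).
#' @param query_length,db_length Search-space dimensions.
#' @return Numeric vector.
#' @export
e_value <- function(bits, query_length, db_length) {
  as.numeric(query_length) * as.numeric(db_length) * 2^(-bits)
}

# canonical hit-table ordering: bit score desc, percent identity desc,
# subject id asc -- a total order because subject ids are unique
sort_hits <- function(hits) {
  hits[order(-hits$bit_score, -hits$pct_identity, hits$subject_id), ,
       drop = FALSE]
}

new_hit_table <- function(query_id, subject_id, subject_species,
                          identities, aln_length, raw_score, bit, evalue) {
  out <- data.frame(
    query_id = query_id,
    subject_id = subject_id,
    subject_species = subject_species,
    pct_identity = round(100 * identities / pmax(aln_length, 1L), 3),
    aln_length = as.integer(aln_length),
    raw_score = as.integer(raw_score),
    bit_score = round(bit, 1),
    e_value = evalue,
    stringsAsFactors = FALSE
  )
  out <- sort_hits(out)
  rownames(out) <- NULL
  out
}

#' An empty hit table
#'
#' Zero-row table with the hit-table columns; the result of a search with no
#' positive-scoring alignments, and a convenient placeholder for queries
#' whose locus failed recovery.
#'
#' @param query_id Unused; kept for symmetry with table constructors.
#' @return Zero-row hit table `data.frame`.
#' @export
empty_hit_table <- function(query_id = character(0)) {
  data.frame(query_id = character(0), subject_id = character(0),
             subject_species = character(0), pct_identity = numeric(0),
             aln_length = integer(0), raw_score = integer(0),
             bit_score = numeric(0), e_value = numeric(0),
             stringsAsFactors = FALSE)
}

#' Search a query sequence against a reference database
#'
#' Aligns the query to every record of the database (optionally excluding a
#' set of record ids, as in leave-one-out evaluation), keeps hits with a
#' positive raw score, and returns them sorted by bit score (descending),
#' then percent identity (descending), then subject id. Bit scores are
#' rounded to 1 decimal and identities to 3 decimals before storage, the
#' precision at which ties are decided downstream.
#'
#' @param query Query sequence: a DNA string, or a one-row record table (as
#'   from [reference_records()]) whose `record_id` becomes the hit table's
#'   `query_id`.
#' @param db A [build_reference_db()] database.
#' @param params [alignment_params()].
#' @param max_hits Keep at most this many hits.
#' @param exclude Record ids never reported as subjects.
#' @param query_id Query id used when `query` is a plain string.
#' @return Hit table `data.frame` with columns `query_id`, `subject_id`,
#'   `subject_species`, `pct_identity`, `aln_length`, `raw_score`,
#'   `bit_score`, `e_value`.
#' @export
search_db <- function(query, db, params = alignment_params(),
                      max_hits = 100L, exclude = character(0),
                      query_id = "query") {
  stopifnot(inherits(db, "reference_db"), inherits(params, "alignment_params"))
  if (nrow(db$records) == 0L) stop("empty reference database", call. = FALSE)
  if (is.data.frame(query)) {
    stopifnot(nrow(query) == 1L)
    query_id <- query$record_id
    query <- query$sequence
  }
  if (!nzchar(query)) stop("empty query sequence", call. = FALSE)
  subjects <- db$records[!(db$records$record_id %in% exclude), , drop = FALSE]
  if (nrow(subjects) == 0L) return(empty_hit_table())
  m <- .sw_align_batch_cpp(query, subjects$sequence, params$match,
                           params$mismatch, params$gap_open,
                           params$gap_extend)
  keep <- m[, "raw_score"] > 0L
  if (!any(keep)) return(empty_hit_table())
  m <- m[keep, , drop = FALSE]
  subjects <- subjects[keep, , drop = FALSE]
  bits <- bit_score(m[, "raw_score"], params)
  hits <- new_hit_table(
    query_id = query_id,
    subject_id = subjects$record_id,
    subject_species = subjects$species,
    identities = m[, "identities"],
    aln_length = m[, "aln_length"],
    raw_score = m[, "raw_score"],
    bit = bits,
    evalue = e_value(bits, nchar(query), sum(nchar(db$records$sequence)))
  )
  head(hits, max_hits)
}

#' Read BLAST tabular (outfmt 6) hit files
#'
#' Reads the standard 12-column tab-separated hit format (`qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore`),
#' keeps the best-bit-score row per query/subject pair, resolves subject
#' species through `species_lookup` (falling back to text after a `"|"` in
#' the subject id), and returns one sorted hit table per query. Raw scores
#' are not part of the format and are stored as `NA`; all downstream
#' decisions use the bit score and percent identity columns.
#'
#' @param path Tabular hits file.
#' @param species_lookup Named character vector mapping subject ids to raw
#'   species labels.
#' @param genus_expand See [parse_species_label()].
#' @return Named list of hit tables, one per distinct query id.
#' @export
read_tabular_hits <- function(path, species_lookup = NULL,
                              genus_expand = "Acropora") {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) return(list())
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (nrow(raw) == 0L) return(list())
  if (ncol(raw) != 12L) {
    stop("expected 12 tab-separated columns, found ", ncol(raw),
         call. = FALSE)
  }
  names(raw) <- cols
  for (col in c("pident", "bitscore", "length", "evalue")) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(val)) {
      stop(sprintf("non-numeric %s at line %d", col, which(is.na(val))[1L]),
           call. = FALSE)
    }
    raw[[col]] <- val
  }
  species_raw <- if (!is.null(species_lookup)) {
    unname(species_lookup[raw$sseqid])
  } else {
    rep(NA_character_, nrow(raw))
  }
  fallback <- grepl("|", raw$sseqid, fixed = TRUE)
  species_raw[is.na(species_raw) & fallback] <-
    sub("^[^|]*\\|", "", raw$sseqid[is.na(species_raw) & fallback])
  if (anyNA(species_raw)) {
    stop("no species resolution for subject id(s): ",
         paste(unique(raw$sseqid[is.na(species_raw)]), collapse = ", "),
         call. = FALSE)
  }
  lab <- parse_species_table(species_raw, genus_expand = genus_expand)
  raw$subject_species <- lab$species

  per_query <- split(raw, raw$qseqid)
  out <- lapply(per_query, function(d) {
    # best HSP per subject: highest bit score, then highest identity
    d <- d[order(-d$bitscore, -d$pident), , drop = FALSE]
    d <- d[!duplicated(d$sseqid), , drop = FALSE]
    h <- data.frame(
      query_id = d$qseqid,
      subject_id = d$sseqid,
      subject_species = d$subject_species,
      pct_identity = round(d$pident, 3),
      aln_length = as.integer(d$length),
      raw_score = NA_integer_,
      bit_score = round(d$bitscore, 1),
      e_value = d$evalue,
      stringsAsFactors = FALSE
    )
    h <- sort_hits(h)
    rownames(h) <- NULL
    h
  })
  out[unique(raw$qseqid)]
}

#' Write hit tables in BLAST tabular (outfmt 6) format
#'
#' Percent identity is printed with 3 decimals and bit score with 1, so
#' files round-trip bit-exactly through [read_tabular_hits()]. Mismatch
#' counts are derived as `aln_length - identities`; alignment coordinates
#' are not tracked by [search_db()] and are written as 0.
#'
#' @param hits A hit table or list of hit tables.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_tabular_hits <- function(hits, path) {
  if (is.data.frame(hits)) hits <- list(hits)
  rows <- do.call(rbind, hits)
  nident <- ifelse(is.na(rows$raw_score), NA_integer_,
                   as.integer(round(rows$pct_identity * rows$aln_length / 100)))
  out <- data.frame(
    qseqid = rows$query_id,
    sseqid = rows$subject_id,
    pident = formatC(rows$pct_identity, format = "f", digits = 3),
    length = rows$aln_length,
    mismatch = ifelse(is.na(nident), 0L, rows$aln_length - nident),
    gapopen = 0L, qstart = 0L, qend = 0L, sstart = 0L, send = 0L,
    evalue = formatC(rows$e_value, format = "g", digits = 3),
    bitscore = formatC(rows$bit_score, format = "f", digits = 1)
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Identify which locus a sequence comes from
#'
#' Aligns the query against one reference database per locus and returns the
#' locus with the highest best bit score, provided it reaches `min_bits`;
#' ties between loci (at 1-decimal bit precision) and sub-threshold best
#' hits return `"UNKNOWN"`. This is the sanity check that an amplicon really
#' is the region it is supposed to be.
#'
#' @param query DNA string.
#' @param locus_refs Named list of [build_reference_db()] databases, one per
#'   locus.
#' @param params [alignment_params()].
#' @param min_bits Bit-score floor below which no locus is called.
#' @return Locus tag, or `"UNKNOWN"`.
#' @export
verify_locus <- function(query, locus_refs, params = alignment_params(),
                         min_bits = 50) {
  stopifnot(is.list(locus_refs), length(locus_refs) >= 1L,
            !is.null(names(locus_refs)))
  best <- vapply(locus_refs, function(db) {
    if (nrow(db$records) == 0L) return(-Inf)
    m <- .sw_align_batch_cpp(query, db$records$sequence, params$match,
                             params$mismatch, params$gap_open,
                             params$gap_extend)
    round(max(bit_score(m[, "raw_score"], params)), 1)
  }, 0)
  top <- max(best)
  if (top < min_bits || sum(best == top) > 1L) return("UNKNOWN")
  names(best)[which.max(best)]
}

#' Rotate a circular sequence so an anchor starts at position 1
#'
#' Circular sequences (e.g. mitochondrial genomes) deposited with arbitrary
#' origins are brought to a common frame by locating the best local
#' alignment of a short anchor within the doubled sequence and rotating so
#' the anchor's start becomes position 1. This is an anchor-seeded
#' standardisation, not a full cyclic-alignment algorithm.
#'
#' @param circular_seq DNA string to rotate.
#' @param anchor Anchor sequence (shorter than `circular_seq`).
#' @param params [alignment_params()].
#' @param min_anchor_bits Minimum bit score for the anchor match; below it
#'   the anchor is declared not found.
#' @return List with `sequence` (rotated) and `offset` (0-based rotation
#'   applied, in `[0, nchar(circular_seq))`).
#' @examples
#' rotate_to_anchor("TTGGAACC", "AACC", min_anchor_bits = 5)
#' @export
rotate_to_anchor <- function(circular_seq, anchor,
                             params = alignment_params(),
                             min_anchor_bits = 50) {
  len <- nchar(circular_seq)
  if (nchar(anchor) >= len) {
    stop("anchor must be shorter than the sequence", call. = FALSE)
  }
  doubled <- paste0(circular_seq, circular_seq)
  aln <- .sw_align_cpp(anchor, doubled, params$match, params$mismatch,
                       params$gap_open, params$gap_extend)
  if (aln[["raw_score"]] <= 0L ||
      bit_score(aln[["raw_score"]], params) < min_anchor_bits) {
    stop("anchor not found", call. = FALSE)
  }
  offset <- (aln[["sstart"]] - 1L) %% len
  rotated <- if (offset == 0L) circular_seq else
    paste0(substr(circular_seq, offset + 1L, len),
           substr(circular_seq, 1L, offset))
  list(sequence = rotated, offset = offset)
}
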