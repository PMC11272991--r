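IUPAC_DNA <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
               "V", "H", "D", "B", "N")

#' Build a table of species-labelled reference records
#'
#' Validates and assembles the per-record table used throughout the package:
#' one row per sequence, with the species label parsed into genus, epithet,
#' qualifier and a canonical grouping key. Sequences are stored uppercase and
#' must use the IUPAC DNA alphabet.
#'
#' @param record_id Character vector of record identifiers.
#' @param sequence Character vector of DNA sequences.
#' @param species Character vector of raw species labels (recycled if
#'   length 1).
#' @param locus Locus tag shared by all records (e.g. `"mtCR"`, `"PaxC"`,
#'   `"mitogenome"`).
#' @param source Free-text provenance (recycled).
#' @param genus_expand Genus substituted for abbreviated genus letters in
#'   species labels.
#' @return A `data.frame` with columns `record_id`, `locus`, `sequence`,
#'   `species_raw`, `genus`, `epithet`, `qualifier`, `species`,
#'   `unambiguous`, `source`.
#' @examples
#' reference_records("r1", "ACGT", "Acropora millepora", locus = "mtCR")
#' @export
reference_records <- function(record_id, sequence, species, locus,
                              source = "", genus_expand = "Acropora") {
  n <- length(record_id)
  stopifnot(length(sequence) == n)
  if (length(species) == 1L) species <- rep(species, n)
  stopifnot(length(species) == n)
  if (length(source) == 1L) source <- rep(source, n)
  if (n == 0L) source <- character(0)
  if (length(locus) != 1L) {
    stop("'locus' must be a single tag", call. = FALSE)
  }
  sequence <- toupper(sequence)
  bad <- !nzchar(sequence) |
    grepl(sprintf("[^%s]", paste(IUPAC_DNA, collapse = "")), sequence)
  if (any(bad)) {
    stop("non-IUPAC or empty sequence(s) for record(s): ",
         paste(record_id[bad], collapse = ", "), call. = FALSE)
  }
  lab <- parse_species_table(species, genus_expand = genus_expand)
  out <- data.frame(record_id = as.character(record_id),
                    locus = rep(locus, n), sequence = sequence,
                    stringsAsFactors = FALSE)
  out <- cbind(out, lab)
  out$source <- source
  rownames(out) <- NULL
  out
}

#' Build a curated per-locus reference database
#'
#' Indexes reference records by species, rejecting duplicate record ids and
#' mixed loci. Unambiguous labels are counted per binomial; ambiguous labels
#' (sp./cf./aff. and other decorations) are counted under their own raw
#' label. Species represented by a single record are flagged as singletons;
#' the leave-one-out evaluation excludes them as queries while keeping them
#' as possible hits.
#'
#' @param records Record table from [reference_records()] or
#'   [read_records()].
#' @param genus_filter Optional genus name; records of other genera are
#'   dropped (the number dropped is kept in the `n_dropped` field).
#' @return An object of class `reference_db`: list with `locus`, `records`,
#'   `species_counts` (named integer vector) and `n_dropped`.
#' @examples
#' rec <- reference_records(c("r1", "r2", "r3"), c("ACGT", "ACGA", "TTTT"),
#'                          c("Acropora digitifera", "Acropora digitifera",
#'                            "Acropora millepora"), locus = "mtCR")
#' db <- build_reference_db(rec)
#' db$species_counts
#' @export
build_reference_db <- function(records, genus_filter = NULL) {
  stopifnot(is.data.frame(records))
  if (nrow(records) > 0L) {
    loci <- unique(records$locus)
    if (length(loci) > 1L) {
      stop("records mix locus tags: ", paste(loci, collapse = ", "),
           call. = FALSE)
    }
    dup <- unique(records$record_id[duplicated(records$record_id)])
    if (length(dup) > 0L) {
      stop("duplicate record id(s): ", paste(dup, collapse = ", "),
           call. = FALSE)
    }
  }
  n_dropped <- 0L
  if (!is.null(genus_filter) && nrow(records) > 0L) {
    keep <- records$genus == capitalise(genus_filter)
    n_dropped <- sum(!keep)
    records <- records[keep, , drop = FALSE]
    rownames(records) <- NULL
  }
  counts <- if (nrow(records) == 0L) {
    integer(0)
  } else {
    tab <- table(records$species)
    setNames(as.integer(tab), names(tab))
  }
  structure(
    list(locus = if (nrow(records) > 0L) records$locus[1L] else NA_character_,
         records = records,
         species_counts = counts,
         n_dropped = n_dropped),
    class = "reference_db"
  )
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("reference_db: locus %s, %d record(s), %d species key(s)",
              x$locus, nrow(x$records), length(x$species_counts)),
      if (x$n_dropped > 0L) sprintf(" (%d dropped by genus filter)",
                                    x$n_dropped) else "",
      "\n", sep = "")
  invisible(x)
}

#' Species represented by a single record
#'
#' @param db A `reference_db`.
#' @return Character vector of singleton species keys.
#' @export
singleton_species <- function(db) {
  stopifnot(inherits(db, "reference_db"))
  names(db$species_counts)[db$species_counts == 1L]
}

#' Read reference records from FASTA (and optional metadata)
#'
#' Sequences come from a FASTA file; species labels come from a tab-separated
#' metadata table (columns `record_id`, `species`, `locus`) when given, and
#' otherwise from the FASTA header text after the first whitespace. Metadata
#' takes precedence over header text. Ids present in only one of the two
#' inputs are an error.
#'
#' @param fasta_path FASTA file.
#' @param metadata_path Optional metadata TSV.
#' @param locus Locus tag used when no metadata is given.
#' @param genus_expand See [parse_species_label()].
#' @return Record table as from [reference_records()].
#' @export
read_records <- function(fasta_path, metadata_path = NULL, locus = "unknown",
                         genus_expand = "Acropora") {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  header_species <- trimws(sub("^\\S+", "", headers))
  sequence <- as.character(seqs)
  if (is.null(metadata_path)) {
    species <- ifelse(nzchar(header_species), header_species, "unknown sp.")
    return(reference_records(ids, sequence, species, locus = locus,
                             source = fasta_path,
                             genus_expand = genus_expand))
  }
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE,
                     colClasses = "character")
  need <- c("record_id", "species", "locus")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0L) {
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  only_fa <- setdiff(ids, meta$record_id)
  only_md <- setdiff(meta$record_id, ids)
  if (length(only_fa) > 0L || length(only_md) > 0L) {
    stop("record ids do not match between FASTA and metadata; ",
         "FASTA only: [", paste(only_fa, collapse = ", "),
         "]; metadata only: [", paste(only_md, collapse = ", "), "]",
         call. = FALSE)
  }
  loci <- unique(meta$locus)
  if (length(loci) > 1L) {
    stop("metadata mixes locus tags (", paste(loci, collapse = ", "),
         "); split inputs per locus", call. = FALSE)
  }
  m <- match(ids, meta$record_id)
  reference_records(ids, sequence, meta$species[m], locus = loci,
                    source = fasta_path, genus_expand = genus_expand)
}

#' Write reference records to FASTA (and optional metadata)
#'
#' The FASTA header carries `record_id` and the raw species label; sequences
#' are wrapped at 60 columns. Round-tripping through [read_records()]
#' preserves ids, sequences and species label text.
#'
#' @param records Record table.
#' @param fasta_path Output FASTA file.
#' @param metadata_path Optional output metadata TSV (`record_id`, `species`,
#'   `locus`).
#' @return Invisibly, `fasta_path`.
#' @export
write_records <- function(records, fasta_path, metadata_path = NULL) {
  seqs <- Biostrings::DNAStringSet(records$sequence)
  names(seqs) <- paste(records$record_id, records$species_raw)
  Biostrings::writeXStringSet(seqs, fasta_path, width = 60L)
  if (!is.null(metadata_path)) {
    write.table(
      data.frame(record_id = records$record_id,
                 species = records$species_raw,
                 locus = records$locus),
      metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta_path)
}
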