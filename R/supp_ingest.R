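#' Read a key=value column-mapping file
#'
#' Survey spreadsheets do not have standardised headers, so the readers take
#' an external mapping from logical field names to the actual column
#' headers. Lines look like `sample_id=Sample ID`; `#` starts a comment.
#'
#' @param path Mapping file.
#' @return Named character vector (logical name -> column header).
#' @export
read_column_mapping <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  bad <- vapply(kv, length, 0L) != 2L
  if (any(bad)) {
    stop("malformed mapping line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  setNames(trimws(vapply(kv, `[`, "", 2L)),
           trimws(vapply(kv, `[`, "", 1L)))
}

# read a spreadsheet-ish table: csv, tsv or xlsx (xlsx needs readxl)
read_table_any <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading xlsx requires the 'readxl' package; ",
           "export the sheet to csv/tsv instead", call. = FALSE)
    }
    as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
  } else if (ext == "tsv" || ext == "txt") {
    read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
}

map_column <- function(tab, mapping, key, required = TRUE) {
  if (!key %in% names(mapping)) {
    if (required) {
      stop("column mapping lacks required key: ", key, call. = FALSE)
    }
    return(NULL)
  }
  col <- mapping[[key]]
  if (!col %in% names(tab)) {
    if (required) {
      stop(sprintf("mapped column '%s' (for %s) not found in table", col,
                   key), call. = FALSE)
    }
    return(NULL)
  }
  tab[[col]]
}

parse_flag <- function(x) {
  tolower(trimws(as.character(x))) %in% c("yes", "y", "true", "1", "x")
}

# tolerant numeric parse: "n/a", "-", "" become NA rather than errors
parse_identity <- function(x) {
  suppressWarnings(as.numeric(gsub("%", "", trimws(as.character(x)))))
}

#' Read a per-sample two-locus identification table
#'
#' Reads the spreadsheet layout of a two-locus barcoding survey: one row per
#' sample with, per locus, a recovery flag, the matched species and the top
#' percent identity. Accepts csv/tsv (and xlsx via the optional readxl
#' package); column headers are resolved through a mapping file (see
#' [read_column_mapping()]; required keys `sample_id`, `mtcr_species`,
#' `mtcr_identity`, `paxc_species`, `paxc_identity`; optional
#' `mtcr_recovered`, `paxc_recovered` -- when absent, recovery is inferred
#' from non-empty cells). Species text is parsed with
#' [parse_species_label()], so open-nomenclature labels are flagged
#' ambiguous. Identity cells that are not numbers ("n/a") become missing
#' values, not errors.
#'
#' @param path Table file.
#' @param mapping Named mapping (or path to a mapping file). Default: the
#'   mapping shipped with the package matching the synthetic example layout.
#' @param genus_expand See [parse_species_label()].
#' @return `data.frame` of class `sample_rows`: `sample_id`, `has_mtcr`,
#'   `has_paxc` and per-locus `*_species_raw`, `*_species`, `*_status`,
#'   `*_identity`.
#' @export
read_s1 <- function(path, mapping = NULL, genus_expand = "Acropora") {
  if (is.null(mapping)) {
    mapping <- system.file("extdata", "s1_mapping.txt", package = "acrobar",
                           mustWork = TRUE)
  }
  if (is.character(mapping) && length(mapping) == 1L && file.exists(mapping)) {
    mapping <- read_column_mapping(mapping)
  }
  tab <- read_table_any(path)
  sample_id <- as.character(map_column(tab, mapping, "sample_id"))

  one_locus <- function(prefix) {
    species_raw <- as.character(map_column(tab, mapping,
                                           paste0(prefix, "_species")))
    species_raw[is.na(species_raw)] <- ""
    identity <- parse_identity(map_column(tab, mapping,
                                          paste0(prefix, "_identity")))
    rec <- map_column(tab, mapping, paste0(prefix, "_recovered"),
                      required = FALSE)
    recovered <- if (is.null(rec)) {
      nzchar(trimws(species_raw)) | !is.na(identity)
    } else {
      parse_flag(rec)
    }
    status <- rep(NA_character_, nrow(tab))
    key <- rep(NA_character_, nrow(tab))
    has_sp <- recovered & nzchar(trimws(species_raw))
    if (any(has_sp)) {
      lab <- parse_species_table(species_raw[has_sp],
                                 genus_expand = genus_expand)
      key[has_sp] <- lab$species
      status[has_sp] <- ifelse(lab$unambiguous, "ASSIGNED",
                               "ASSIGNED_AMBIGUOUS")
    }
    status[recovered & !has_sp] <- "UNASSIGNED"
    identity[!recovered] <- NA_real_
    list(recovered = recovered, species_raw = species_raw, species = key,
         status = status, identity = identity)
  }
  mt <- one_locus("mtcr")
  nu <- one_locus("paxc")
  out <- data.frame(
    sample_id = sample_id,
    has_mtcr = mt$recovered, has_paxc = nu$recovered,
    mtcr_species_raw = mt$species_raw, mtcr_species = mt$species,
    mtcr_status = mt$status, mtcr_identity = mt$identity,
    paxc_species_raw = nu$species_raw, paxc_species = nu$species,
    paxc_status = nu$status, paxc_identity = nu$identity,
    stringsAsFactors = FALSE
  )
  class(out) <- c("sample_rows", "data.frame")
  out
}

#' Read a per-record mitogenome identification table
#'
#' One row per reference mitogenome: the species it is supposed to be, the
#' species its best database match identified, and whether the record was
#' excluded from evaluation as the single representative of its species.
#' Required mapping keys: `record_id`, `supposed_species`, `matched_species`;
#' optional `excluded`.
#'
#' @inheritParams read_s1
#' @return `data.frame` of class `mito_rows`: `record_id`,
#'   `supposed_species_raw`, `supposed_species`, `matched_species_raw`,
#'   `matched_species`, `excluded_singleton`, `verdict`.
#' @export
read_s2 <- function(path, mapping = NULL, genus_expand = "Acropora") {
  if (is.null(mapping)) {
    mapping <- system.file("extdata", "s2_mapping.txt", package = "acrobar",
                           mustWork = TRUE)
  }
  if (is.character(mapping) && length(mapping) == 1L && file.exists(mapping)) {
    mapping <- read_column_mapping(mapping)
  }
  tab <- read_table_any(path)
  record_id <- as.character(map_column(tab, mapping, "record_id"))
  supposed_raw <- as.character(map_column(tab, mapping, "supposed_species"))
  matched_raw <- as.character(map_column(tab, mapping, "matched_species"))
  matched_raw[is.na(matched_raw)] <- ""
  excl <- map_column(tab, mapping, "excluded", required = FALSE)
  excluded <- if (is.null(excl)) rep(FALSE, nrow(tab)) else parse_flag(excl)

  sup <- parse_species_table(supposed_raw, genus_expand = genus_expand)
  mat_key <- rep(NA_character_, nrow(tab))
  has_match <- nzchar(trimws(matched_raw))
  if (any(has_match)) {
    mat <- parse_species_table(matched_raw[has_match],
                               genus_expand = genus_expand)
    mat_key[has_match] <- mat$species
  }
  verdict <- ifelse(
    excluded, "EXCLUDED_SINGLETON",
    ifelse(!has_match, "UNASSIGNED",
           ifelse(mapply(same_species, mat_key, sup$species),
                  "CORRECT", "INCORRECT")))
  out <- data.frame(
    record_id = record_id,
    supposed_species_raw = supposed_raw, supposed_species = sup$species,
    matched_species_raw = matched_raw, matched_species = mat_key,
    excluded_singleton = excluded, verdict = verdict,
    stringsAsFactors = FALSE
  )
  class(out) <- c("mito_rows", "data.frame")
  out
}

#' Recompute headline statistics from ingested survey tables
#'
#' Applies the package's counting and aggregation rules to a parsed table:
#' for per-sample two-locus rows ([read_s1()]), the recovery counts,
#' per-locus assigned counts (unambiguous labels only), identity means,
#' standard deviations (n - 1) and minima among assigned samples, strict
#' `> 99%` counts, single-locus assignment counts and the two-locus
#' concordant count; for mitogenome rows ([read_s2()]), the leave-one-out
#' exclusions and identification success rate.
#'
#' @param rows A `sample_rows` or `mito_rows` table.
#' @return Named list of statistics.
#' @export
recompute_results <- function(rows) {
  UseMethod("recompute_results")
}

#' @export
recompute_results.sample_rows <- function(rows) {
  both <- rows$has_mtcr & rows$has_paxc
  mtcr_only <- rows$has_mtcr & !rows$has_paxc
  mt_as <- !is.na(rows$mtcr_status) & rows$mtcr_status == "ASSIGNED"
  nu_as <- !is.na(rows$paxc_status) & rows$paxc_status == "ASSIGNED"
  concordant <- both & mt_as & nu_as &
    mapply(same_species, rows$mtcr_species, rows$paxc_species)
  mt_id <- rows$mtcr_identity[mt_as]
  nu_id <- rows$paxc_identity[nu_as]
  list(
    n_samples = nrow(rows),
    n_mtcr_recovered = sum(rows$has_mtcr),
    n_paxc_recovered = sum(rows$has_paxc),
    n_both_loci = sum(both),
    n_mtcr_only = sum(mtcr_only),
    n_mtcr_assigned = sum(mt_as),
    n_mtcr_assigned_gt99 = sum(mt_id > 99, na.rm = TRUE),
    mean_mtcr_identity_assigned = round(mean(mt_id, na.rm = TRUE), 2),
    sd_mtcr_identity_assigned = round(sd(mt_id, na.rm = TRUE), 2),
    n_paxc_assigned = sum(nu_as),
    mean_paxc_identity_assigned = round(mean(nu_id, na.rm = TRUE), 2),
    sd_paxc_identity_assigned = round(sd(nu_id, na.rm = TRUE), 2),
    min_paxc_identity_assigned = if (any(!is.na(nu_id)))
      min(nu_id, na.rm = TRUE) else NA_real_,
    n_mtcr_only_assigned = sum(mtcr_only & mt_as),
    n_concordant = sum(concordant)
  )
}

#' @export
recompute_results.mito_rows <- function(rows) {
  list(
    n_records = nrow(rows),
    n_excluded_singleton = sum(rows$verdict == "EXCLUDED_SINGLETON"),
    n_evaluated = sum(rows$verdict != "EXCLUDED_SINGLETON"),
    n_correct = sum(rows$verdict == "CORRECT"),
    loo_success_rate_pct = success_rate(rows$verdict)
  )
}
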