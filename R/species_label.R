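#' Parse a species name with open-nomenclature qualifiers
#'
#' Splits a raw species string into genus, epithet and qualifier. Open
#' nomenclature qualifiers ("sp.", "cf.", "aff.") mark labels that do not
#' identify a species unambiguously and are excluded from "assigned" tallies
#' downstream; any other non-binomial decoration (strain tags, "isolate ...",
#' a bare genus) is classed as `other` and is equally ambiguous. A single
#' abbreviated genus letter ("A.") expands to `genus_expand`.
#'
#' Normalisation: internal whitespace is collapsed, the genus is capitalised
#' and everything after it lowercased, because public-database headers are
#' inconsistently cased and spaced.
#'
#' @param raw Species string, e.g. `"Acropora millepora"`, `"Acropora sp."`,
#'   `"A. cf. tenuis"`.
#' @param genus_expand Genus substituted for a single-letter abbreviation.
#' @return An object of class `species_label`: a list with `genus`,
#'   `epithet` (may be `""`), `qualifier` (one of `"none"`, `"sp"`, `"cf"`,
#'   `"aff"`, `"other"`) and `raw` (the normalised input).
#' @examples
#' parse_species_label("Acropora millepora")
#' parse_species_label("Acropora sp.")
#' parse_species_label("A. cf. tenuis")
#' @export
parse_species_label <- function(raw, genus_expand = "Acropora") {
  if (length(raw) != 1L || is.na(raw) || !is.character(raw)) {
    stop("'raw' must be a single character string", call. = FALSE)
  }
  txt <- collapse_ws(raw)
  if (!nzchar(txt)) {
    stop("cannot parse an empty species label", call. = FALSE)
  }
  toks <- strsplit(txt, " ", fixed = TRUE)[[1L]]
  genus <- toks[1L]
  if (grepl("^[A-Za-z]\\.$", genus)) genus <- genus_expand
  genus <- capitalise(genus)
  rest <- tolower(toks[-1L])
  norm_raw <- collapse_ws(paste(c(genus, rest), collapse = " "))

  lbl <- function(epithet, qualifier) {
    structure(list(genus = genus, epithet = epithet, qualifier = qualifier,
                   raw = norm_raw),
              class = "species_label")
  }

  if (length(rest) == 0L) return(lbl("", "other"))
  t2 <- rest[1L]
  if (t2 %in% c("sp", "sp.")) return(lbl("", "sp"))
  if (t2 %in% c("cf", "cf.", "aff", "aff.")) {
    qual <- sub("\\.$", "", t2)
    if (length(rest) >= 2L && is_epithet(rest[2L])) {
      return(lbl(rest[2L], qual))
    }
    return(lbl("", "other"))
  }
  if (length(rest) == 1L && is_epithet(t2)) return(lbl(t2, "none"))
  # trailing decoration (isolate tags etc.): keep the epithet but flag it
  lbl(if (is_epithet(t2)) t2 else "", "other")
}

collapse_ws <- function(x) gsub("[[:space:]]+", " ", trimws(x))

capitalise <- function(x) {
  paste0(toupper(substr(x, 1L, 1L)), tolower(substring(x, 2L)))
}

is_epithet <- function(x) grepl("^[a-z][a-z-]*$", x) && x != "sp"

#' @export
format.species_label <- function(x, ...) {
  switch(x$qualifier,
    none = paste(x$genus, x$epithet),
    sp = paste(x$genus, "sp."),
    cf = paste(x$genus, "cf.", x$epithet),
    aff = paste(x$genus, "aff.", x$epithet),
    other = x$raw
  )
}

#' @export
print.species_label <- function(x, ...) {
  cat(format(x),
      if (is_unambiguous(x)) "" else sprintf(" [ambiguous: %s]", x$qualifier),
      "\n", sep = "")
  invisible(x)
}

#' Is a species label an unambiguous binomial?
#'
#' True only for plain binomials without open-nomenclature qualifiers.
#' Ambiguous labels never count as identified species in summary tallies.
#'
#' @param label A `species_label`.
#' @return Logical scalar.
#' @export
is_unambiguous <- function(label) {
  stopifnot(inherits(label, "species_label"))
  identical(label$qualifier, "none")
}

#' Canonical grouping key for a species label
#'
#' Unambiguous binomials key on `"Genus epithet"`, so records of one species
#' group together regardless of header decoration. Ambiguous labels key on
#' their full normalised text, so distinct raw labels stay distinct (and an
#' "Acropora sp." never merges with a named species).
#'
#' @param label A `species_label`.
#' @return Character scalar.
#' @export
species_key <- function(label) {
  stopifnot(inherits(label, "species_label"))
  if (is_unambiguous(label)) paste(label$genus, label$epithet)
  else format(label)
}

#' Do two species keys denote the same species?
#'
#' Compares at binomial level (genus + epithet); qualifiers are ignored, so
#' `"Acropora cf. tenuis"` and `"Acropora tenuis"` agree. Keys without an
#' epithet (e.g. `"Acropora sp."`) never match anything.
#'
#' @param a,b Species keys as returned by [species_key()], or
#'   `species_label` objects.
#' @return Logical scalar (`FALSE` when either side is `NA`).
#' @export
same_species <- function(a, b) {
  la <- if (inherits(a, "species_label")) a else
    if (is.na(a)) return(FALSE) else parse_species_label(a)
  lb <- if (inherits(b, "species_label")) b else
    if (is.na(b)) return(FALSE) else parse_species_label(b)
  nzchar(la$epithet) && nzchar(lb$epithet) &&
    identical(la$genus, lb$genus) && identical(la$epithet, lb$epithet)
}

# vectorised parse: one row per input label (memoised over unique values)
parse_species_table <- function(x, genus_expand = "Acropora") {
  ux <- unique(x)
  parsed <- lapply(ux, parse_species_label, genus_expand = genus_expand)
  idx <- match(x, ux)
  data.frame(
    species_raw = x,
    genus = vapply(parsed, `[[`, "", "genus")[idx],
    epithet = vapply(parsed, `[[`, "", "epithet")[idx],
    qualifier = vapply(parsed, `[[`, "", "qualifier")[idx],
    species = vapply(parsed, species_key, "")[idx],
    unambiguous = vapply(parsed, is_unambiguous, TRUE)[idx],
    stringsAsFactors = FALSE
  )
}
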