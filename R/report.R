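#' Summarise per-locus assignment results
#'
#' Tallies assignment outcomes for one locus and computes the identity
#' statistics reported for barcode surveys: mean and sample standard
#' deviation (n - 1 denominator) of the top percent identity among
#' unambiguously assigned queries, and counts of assigned queries whose top
#' identity strictly exceeds each threshold. Ambiguous-label assignments
#' are tallied separately and excluded from all "assigned" statistics.
#'
#' @param results Assignment rows (all for the same locus).
#' @param thresholds Identity thresholds for the strict `> threshold`
#'   counts.
#' @return Object of class `summary_report`: list with `locus`, `n_queries`,
#'   `n_assigned`, `n_assigned_ambiguous`, `n_unassigned`, `n_no_hits`,
#'   `mean_top_identity_assigned`, `sd_top_identity_assigned`,
#'   `n_assigned_identity_gt` (named by threshold).
#' @export
summarize_assignments <- function(results, thresholds = 99) {
  stopifnot(is.data.frame(results))
  loci <- unique(results$locus[!is.na(results$locus)])
  if (length(loci) > 1L) {
    stop("results mix loci: ", paste(loci, collapse = ", "), call. = FALSE)
  }
  assigned <- results[results$status == "ASSIGNED", , drop = FALSE]
  top <- assigned$top_identity
  gt <- vapply(thresholds, function(th) sum(top > th), 0L)
  structure(
    list(locus = if (length(loci) == 1L) loci else NA_character_,
         n_queries = nrow(results),
         n_assigned = nrow(assigned),
         n_assigned_ambiguous = sum(results$status == "ASSIGNED_AMBIGUOUS"),
         n_unassigned = sum(results$status == "UNASSIGNED_TIE"),
         n_no_hits = sum(results$status == "NO_HITS"),
         mean_top_identity_assigned = if (nrow(assigned) > 0L)
           mean(top) else NA_real_,
         sd_top_identity_assigned = if (nrow(assigned) > 1L)
           sd(top) else NA_real_,
         n_assigned_identity_gt = setNames(gt, as.character(thresholds))),
    class = "summary_report"
  )
}

#' @export
print.summary_report <- function(x, ...) {
  cat(sprintf("summary_report (%s): %d queries\n", x$locus, x$n_queries))
  cat(sprintf(
    "  assigned %d, ambiguous %d, unassigned (tie) %d, no hits %d\n",
    x$n_assigned, x$n_assigned_ambiguous, x$n_unassigned, x$n_no_hits))
  if (!is.na(x$mean_top_identity_assigned)) {
    cat(sprintf("  top identity among assigned: mean %.2f%% (SD %s)\n",
                x$mean_top_identity_assigned,
                if (is.na(x$sd_top_identity_assigned)) "NA" else
                  sprintf("%.2f", x$sd_top_identity_assigned)))
  }
  for (th in names(x$n_assigned_identity_gt)) {
    cat(sprintf("  assigned with identity > %s%%: %d\n", th,
                x$n_assigned_identity_gt[[th]]))
  }
  invisible(x)
}

#' Distributions of top identity and 100%-tie multiplicity
#'
#' Per query: the highest percent identity across its hits (binned, default
#' 0.5-point bins over 90-100, with an extra `<90` bin so mass is conserved)
#' and the number of distinct species matched at exactly 100.000% identity.
#' A query with no hits contributes multiplicity 0 and no identity bin.
#' These are the two distributions that show why barcodes fail: top
#' identities pile up near 100 while the 100% matches spread over several
#' species.
#'
#' @param tables List of hit tables (possibly empty ones).
#' @param bin_width Identity bin width.
#' @param range Identity range covered by the bins.
#' @return List with `top_identity_histogram` and
#'   `tie_multiplicity_histogram` (named integer vectors).
#' @export
hit_distributions <- function(tables, bin_width = 0.5, range = c(90, 100)) {
  if (is.data.frame(tables)) tables <- list(tables)
  breaks <- seq(range[1L], range[2L], by = bin_width)
  nb <- length(breaks) - 1L
  bin_labels <- c(sprintf("<%g", breaks[1L]),
                  sprintf("[%g,%g%s", breaks[-length(breaks)], breaks[-1L],
                          c(rep(")", nb - 1L), "]")))
  id_hist <- setNames(integer(length(bin_labels)), bin_labels)
  ties <- integer(length(tables))
  for (i in seq_along(tables)) {
    h <- tables[[i]]
    if (nrow(h) == 0L) next
    top <- max(h$pct_identity)
    ties[i] <- length(unique(h$subject_species[h$pct_identity == 100]))
    k <- if (top < breaks[1L]) 0L else min(findInterval(top, breaks), nb)
    id_hist[k + 1L] <- id_hist[k + 1L] + 1L
  }
  tie_tab <- table(factor(ties, levels = 0:max(c(ties, 0L))))
  list(
    top_identity_histogram = id_hist,
    tie_multiplicity_histogram = setNames(as.integer(tie_tab),
                                          names(tie_tab))
  )
}

#' Write a summary report as TSV and JSON
#'
#' @param report A `summary_report`.
#' @param tsv_path Output TSV (one field per row).
#' @param json_path Optional output JSON.
#' @return Invisibly, `tsv_path`.
#' @export
write_summary_report <- function(report, tsv_path, json_path = NULL) {
  stopifnot(inherits(report, "summary_report"))
  flat <- c(locus = report$locus,
            n_queries = report$n_queries,
            n_assigned = report$n_assigned,
            n_assigned_ambiguous = report$n_assigned_ambiguous,
            n_unassigned = report$n_unassigned,
            n_no_hits = report$n_no_hits,
            mean_top_identity_assigned = report$mean_top_identity_assigned,
            sd_top_identity_assigned = report$sd_top_identity_assigned,
            setNames(report$n_assigned_identity_gt,
                     paste0("n_assigned_identity_gt_",
                            names(report$n_assigned_identity_gt))))
  write.table(data.frame(field = names(flat), value = unname(flat)),
              tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(report[names(report)], json_path,
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(tsv_path)
}

#' Plot the two hit distributions to SVG (cosmetic)
#'
#' @param dists Output of [hit_distributions()].
#' @param path Output SVG file.
#' @return Invisibly, `path`.
#' @export
plot_hit_distributions <- function(dists, path) {
  grDevices::svg(path, width = 10, height = 5)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
  graphics::barplot(dists$top_identity_histogram, las = 2,
                    main = "Top percent identity", ylab = "queries")
  graphics::barplot(dists$tie_multiplicity_histogram, las = 1,
                    main = "Species matched at 100% identity",
                    ylab = "queries", xlab = "species count")
  invisible(path)
}
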