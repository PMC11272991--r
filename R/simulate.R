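#' Configuration for the two-locus barcode simulator
#'
#' Defines the statistical structure of a synthetic barcode study: a set of
#' species, each with one haplotype per locus derived from a common ancestor
#' at the interspecific divergence rate; specimens sampled around their
#' species haplotype at the intraspecific rate; cross-species haplotype
#' sharing, which creates the irresolvable 100%-identity ties that defeat
#' barcode identification; and per-locus recovery dropout emulating
#' amplification/sequencing failure.
#'
#' Defaults emulate a two-locus *Acropora* barcoding study: 25 species x 5
#' specimens, an ~900 bp mitochondrial control-region-like locus that almost
#' always amplifies (dropout 0.016) and a ~550 bp nuclear-intron-like locus
#' that fails often (dropout 0.449), with low divergence at both loci and
#' substantial mitochondrial haplotype sharing. Divergence values are
#' per-site substitution probabilities, not corrected distances.
#'
#' @param n_species Number of species (>= 1).
#' @param samples_per_species Specimens sampled per species (>= 1).
#' @param seq_length Named integer vector, sequence length per locus.
#' @param intra_div Named vector, per-site substitution probability of a
#'   specimen relative to its species haplotype.
#' @param inter_div Named vector, per-site substitution probability of a
#'   species haplotype relative to the ancestor.
#' @param share_prob Probability that a species adopts another species'
#'   haplotype at a locus (applied independently per locus and species).
#' @param dropout Named vector, probability that a specimen's locus fails
#'   recovery.
#' @param seed Integer seed; identical configurations and seeds give
#'   byte-identical datasets.
#' @param ref_depth Extra reference records per species and locus beyond the
#'   one designated haplotype record (drawn at `intra_div`).
#' @param indel_rate Optional per-site indel probability (default 0; the
#'   identity-tie failure mode is substitution-driven).
#' @param genus Genus used for simulated species names.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 25L,
                              samples_per_species = 5L,
                              seq_length = c(mtCR = 900L, PaxC = 550L),
                              intra_div = c(mtCR = 0.002, PaxC = 0.005),
                              inter_div = c(mtCR = 0.010, PaxC = 0.020),
                              share_prob = 0.3,
                              dropout = c(mtCR = 0.016, PaxC = 0.449),
                              seed = 1L,
                              ref_depth = 0L,
                              indel_rate = 0,
                              genus = "Acropora") {
  loci <- names(seq_length)
  if (is.null(loci) || any(!nzchar(loci))) {
    stop("'seq_length' must be a named vector (one entry per locus)",
         call. = FALSE)
  }
  for (nm in c("intra_div", "inter_div", "dropout")) {
    v <- get(nm)
    if (!identical(sort(names(v)), sort(loci))) {
      stop(sprintf("'%s' must be named for the same loci as 'seq_length'",
                   nm), call. = FALSE)
    }
    if (any(v < 0 | v > 1)) {
      stop(sprintf("'%s' must lie in [0, 1]", nm), call. = FALSE)
    }
  }
  if (share_prob < 0 || share_prob > 1) {
    stop("'share_prob' must lie in [0, 1]", call. = FALSE)
  }
  if (indel_rate < 0 || indel_rate > 1) {
    stop("'indel_rate' must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n_species >= 1L, samples_per_species >= 1L,
            all(seq_length >= 1L), ref_depth >= 0L)
  structure(
    list(n_species = as.integer(n_species),
         samples_per_species = as.integer(samples_per_species),
         loci = loci,
         seq_length = seq_length[loci],
         intra_div = intra_div[loci],
         inter_div = inter_div[loci],
         share_prob = share_prob,
         dropout = dropout[loci],
         seed = as.integer(seed),
         ref_depth = as.integer(ref_depth),
         indel_rate = indel_rate,
         genus = genus),
    class = "simulation_config"
  )
}

SIM_BASES <- c("A", "C", "G", "T")

# substitute each site with probability `rate`, uniformly over the other
# three bases; optional indels (deletion or single-base insertion)
mutate_seq <- function(chars, rate, indel_rate = 0) {
  n <- length(chars)
  hit <- which(runif(n) < rate)
  if (length(hit) > 0L) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    chars[hit] <- SIM_BASES[(match(chars[hit], SIM_BASES) - 1L + shift) %% 4L + 1L]
  }
  if (indel_rate > 0) {
    ind <- which(runif(n) < indel_rate)
    for (i in rev(ind)) {
      if (runif(1) < 0.5) {
        chars <- chars[-i]
      } else {
        chars <- append(chars, sample(SIM_BASES, 1L), after = i)
      }
    }
  }
  chars
}

# deterministic letter-only epithets: 1 -> "sima", 27 -> "simaa", ...
sim_epithet <- function(i) {
  out <- character(length(i))
  for (k in seq_along(i)) {
    n <- i[k]
    s <- ""
    while (n > 0L) {
      r <- (n - 1L) %% 26L
      s <- paste0(letters[r + 1L], s)
      n <- (n - 1L) %/% 26L
    }
    out[k] <- paste0("sim", s)
  }
  out
}

#' Simulate a two-locus barcode dataset
#'
#' Per locus: one random ancestor sequence; per species, a haplotype mutated
#' from the ancestor at `inter_div`, then -- with probability `share_prob` --
#' replaced by a copy of another species' haplotype; per
#' specimen, a sequence mutated from its species haplotype at `intra_div`,
#' dropped entirely with probability `dropout`. The reference database gets
#' one designated record per species haplotype (plus `ref_depth` extra
#' records per species); the specimens are the queries. Loci use independent
#' RNG substreams derived from the seed by fixed offsets, so adding a locus
#' leaves earlier loci unchanged.
#'
#' @param config A [simulation_config()].
#' @return Object of class `synthetic_dataset`: list with `config`,
#'   `reference` (named list of [build_reference_db()] objects per locus),
#'   `haplotypes` (per locus, named character vector of species haplotypes),
#'   `queries` (`data.frame`: `query_id`, `locus`, `sequence`; one row per
#'   recovered locus) and `truth` (`data.frame`: `query_id`, `species_raw`,
#'   `species`).
#' @examples
#' ds <- simulate_dataset(simulation_config(n_species = 3,
#'   samples_per_species = 2, seq_length = c(mtCR = 120),
#'   intra_div = c(mtCR = 0), inter_div = c(mtCR = 0.05),
#'   share_prob = 0, dropout = c(mtCR = 0), seed = 7))
#' ds$truth
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  n_sp <- config$n_species
  n_per <- config$samples_per_species
  n_samples <- n_sp * n_per
  species_of_sample <- rep(seq_len(n_sp), each = n_per)
  species_raw <- paste(config$genus, sim_epithet(seq_len(n_sp)))
  sample_ids <- sprintf("S%03d", seq_len(n_samples))

  reference <- list()
  haplotypes <- list()
  queries <- NULL
  for (li in seq_along(config$loci)) {
    locus <- config$loci[li]
    L <- config$seq_length[[locus]]
    set.seed((config$seed + 7919L * li) %% 2147483647L)

    ancestor <- sample(SIM_BASES, L, replace = TRUE)
    haps <- lapply(seq_len(n_sp), function(s) {
      mutate_seq(ancestor, config$inter_div[[locus]], config$indel_rate)
    })
    # haplotype sharing: species adopt another species' haplotype in
    # sequence, so chained sharing collapses haplotype pools (share_prob 1
    # with two species leaves both carrying one identical haplotype)
    if (n_sp > 1L) {
      shared <- runif(n_sp) < config$share_prob
      for (s in which(shared)) {
        others <- setdiff(seq_len(n_sp), s)
        donor <- others[sample.int(length(others), 1L)]
        haps[[s]] <- haps[[donor]]
      }
    }
    hap_str <- vapply(haps, paste, "", collapse = "")
    haplotypes[[locus]] <- setNames(hap_str, species_raw)

    ref_id <- sprintf("REF_%s_%03d", locus, seq_len(n_sp))
    ref_seq <- hap_str
    ref_species <- species_raw
    if (config$ref_depth > 0L) {
      for (d in seq_len(config$ref_depth)) {
        extra <- vapply(seq_len(n_sp), function(s) {
          paste(mutate_seq(haps[[s]], config$intra_div[[locus]],
                           config$indel_rate), collapse = "")
        }, "")
        ref_id <- c(ref_id, sprintf("REF_%s_%03d_x%d", locus, seq_len(n_sp), d))
        ref_seq <- c(ref_seq, extra)
        ref_species <- c(ref_species, species_raw)
      }
    }
    reference[[locus]] <- build_reference_db(reference_records(
      ref_id, ref_seq, ref_species, locus = locus, source = "simulated"))

    sample_seq <- vapply(seq_len(n_samples), function(j) {
      paste(mutate_seq(haps[[species_of_sample[j]]],
                       config$intra_div[[locus]], config$indel_rate),
            collapse = "")
    }, "")
    recovered <- runif(n_samples) >= config$dropout[[locus]]
    if (any(recovered)) {
      queries <- rbind(queries, data.frame(
        query_id = sample_ids[recovered], locus = locus,
        sequence = sample_seq[recovered], stringsAsFactors = FALSE))
    }
  }
  truth_lab <- parse_species_table(species_raw[species_of_sample],
                                   genus_expand = config$genus)
  structure(
    list(config = config,
         reference = reference,
         haplotypes = haplotypes,
         queries = if (is.null(queries)) data.frame(
           query_id = character(0), locus = character(0),
           sequence = character(0), stringsAsFactors = FALSE) else queries,
         truth = data.frame(query_id = sample_ids,
                            species_raw = truth_lab$species_raw,
                            species = truth_lab$species,
                            stringsAsFactors = FALSE)),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d species x %d samples, loci: %s (seed %d)\n",
    x$config$n_species, x$config$samples_per_species,
    paste(x$config$loci, collapse = ", "), x$config$seed))
  for (locus in x$config$loci) {
    cat(sprintf("  %s: %d reference record(s), %d recovered quer%s\n",
                locus, nrow(x$reference[[locus]]$records),
                sum(x$queries$locus == locus),
                if (sum(x$queries$locus == locus) == 1L) "y" else "ies"))
  }
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Per locus: reference FASTA + metadata TSV and query FASTA. Plus a truth
#' TSV and the configuration as a flat `key=value` file.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (locus in dataset$config$loci) {
    db <- dataset$reference[[locus]]
    write_records(db$records,
                  file.path(dir, sprintf("reference_%s.fasta", locus)),
                  file.path(dir, sprintf("reference_%s.tsv", locus)))
    q <- dataset$queries[dataset$queries$locus == locus, , drop = FALSE]
    seqs <- Biostrings::DNAStringSet(q$sequence)
    names(seqs) <- q$query_id
    Biostrings::writeXStringSet(
      seqs, file.path(dir, sprintf("queries_%s.fasta", locus)), width = 60L)
  }
  write.table(dataset$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- dataset$config
  keys <- c(n_species = cfg$n_species,
            samples_per_species = cfg$samples_per_species,
            setNames(cfg$seq_length, paste0("seq_length.", cfg$loci)),
            setNames(cfg$intra_div, paste0("intra_div.", cfg$loci)),
            setNames(cfg$inter_div, paste0("inter_div.", cfg$loci)),
            share_prob = cfg$share_prob,
            setNames(cfg$dropout, paste0("dropout.", cfg$loci)),
            seed = cfg$seed, ref_depth = cfg$ref_depth,
            indel_rate = cfg$indel_rate)
  writeLines(paste0(names(keys), "=", keys), file.path(dir, "config.txt"))
  invisible(dir)
}

#' Pool a simulated locus into one reference database
#'
#' Combines the designated reference records with the recovered query
#' records (labelled with their true species) into a single database --
#' the layout used for leave-one-out evaluation of simulated data.
#'
#' @param dataset A `synthetic_dataset`.
#' @param locus Locus tag.
#' @return A `reference_db`.
#' @export
pooled_reference <- function(dataset, locus) {
  stopifnot(inherits(dataset, "synthetic_dataset"),
            locus %in% dataset$config$loci)
  q <- dataset$queries[dataset$queries$locus == locus, , drop = FALSE]
  truth_raw <- dataset$truth$species_raw[match(q$query_id,
                                               dataset$truth$query_id)]
  ref <- dataset$reference[[locus]]$records
  qrec <- reference_records(q$query_id, q$sequence, truth_raw, locus = locus,
                            source = "simulated",
                            genus_expand = dataset$config$genus)
  build_reference_db(rbind(ref, qrec))
}

#' Identification success as a function of interspecific divergence
#'
#' Sweeps the interspecific divergence over a grid: for each value,
#' simulates datasets (at the base configuration with `inter_div` replaced
#' for every locus), pools each locus' reference and query records, runs
#' [loo_evaluate()], and averages the per-locus success rates. Replicates
#' use consecutive seeds derived from the base seed, shared across grid
#' values (common random numbers).
#'
#' @param base A [simulation_config()].
#' @param inter_div_grid Numeric vector of interspecific divergence values.
#' @param replicates Simulated datasets per grid value (>= 1).
#' @param params [alignment_params()].
#' @param max_hits Hits kept per query in the evaluation.
#' @return `data.frame` ordered by `inter_div`: `inter_div`,
#'   `mean_success_pct`, `sd_success_pct`, `n_replicates`.
#' @export
power_curve <- function(base, inter_div_grid, replicates = 20L,
                        params = alignment_params(), max_hits = 100L) {
  stopifnot(inherits(base, "simulation_config"))
  if (length(inter_div_grid) == 0L) {
    stop("'inter_div_grid' must be non-empty", call. = FALSE)
  }
  stopifnot(replicates >= 1L)
  rows <- lapply(sort(inter_div_grid), function(g) {
    rates <- vapply(seq_len(replicates), function(r) {
      cfg <- base
      cfg$inter_div[] <- g
      cfg$seed <- (base$seed + r) %% 2147483647L
      ds <- simulate_dataset(cfg)
      per_locus <- vapply(cfg$loci, function(locus) {
        db <- pooled_reference(ds, locus)
        loo_evaluate(db, params = params, max_hits = max_hits)$success_rate_pct
      }, 0)
      mean(per_locus, na.rm = TRUE)
    }, 0)
    data.frame(inter_div = g,
               mean_success_pct = mean(rates),
               sd_success_pct = if (replicates > 1L) sd(rates) else NA_real_,
               n_replicates = replicates)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
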