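# Single-molecule molecular inversion probes: UMI-deduplicated capture-event
# counting normalized by a co-captured plasmid that carries one variant-marked
# copy of every target.

#' Simulate an smMIP capture read table
#'
#' Per probe, unique capture events are Poisson(efficiency x template copies)
#' where template copies are `true_copy_number` (genomic rDNA), 1 (genomic
#' single-copy locus) or `plasmid_to_genome_molar_ratio` (plasmid, for both
#' probe classes). Each event receives a random 12-base UMI and emits at
#' least one read; a configurable fraction of reads carries an unreadable
#' diagnostic allele. Distinct templates that draw the same UMI at the same
#' probe merge downstream (an undercount), as in real smMIP data.
#'
#' @param config A [sim_config()]; uses `probes`, `true_copy_number`,
#'   `plasmid_to_genome_molar_ratio`, `reads_per_event`,
#'   `smmip_ambiguous_rate`, `seed`.
#' @return A tibble of reads with columns `probe_id`, `umi`, `allele`
#'   (`"ref"` genomic, `"alt"` plasmid, `"amb"` unreadable) and a `truth`
#'   attribute with the per-(probe, source) true event counts.
#' @export
simulate_smmip_reads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  probes <- config$probes
  if (is.null(probes) || nrow(probes) == 0) abort("empty probe set")
  stopifnot(all(c("probe_id", "target", "efficiency") %in% names(probes)))

  withr::with_seed(config$seed, {
    per_probe <- purrr::pmap(probes, function(probe_id, target, efficiency) {
      copies_genomic <- if (target == "rdna") config$true_copy_number else 1
      n_gen <- rpois(1, efficiency * copies_genomic)
      n_pla <- rpois(1, efficiency * config$plasmid_to_genome_molar_ratio)
      tibble(
        probe_id = probe_id,
        source = rep(c("genomic", "plasmid"), c(n_gen, n_pla)),
        event = seq_len(n_gen + n_pla)
      )
    })
    events <- dplyr::bind_rows(per_probe)
    events$umi <- random_umis(nrow(events))

    n_reads <- 1L + rpois(nrow(events), max(0, config$reads_per_event - 1))
    reads <- events[rep(seq_len(nrow(events)), n_reads), ]
    allele <- ifelse(reads$source == "genomic", "ref", "alt")
    amb <- runif(nrow(reads)) < config$smmip_ambiguous_rate
    allele[amb] <- "amb"
    reads$allele <- allele
  })

  out <- reads[, c("probe_id", "umi", "allele")]
  truth <- events %>%
    count(.data$probe_id, .data$source, name = "n_events")
  attr(out, "truth") <- truth
  attr(out, "seed") <- config$seed
  out
}

random_umis <- function(n, length = 12L) {
  m <- matrix(sample(BASES, n * length, replace = TRUE), nrow = length)
  apply(m, 2, paste, collapse = "")
}

#' Deduplicate smMIP reads into unique capture events
#'
#' One capture event per distinct (probe, UMI) pair. The event source is
#' assigned from the diagnostic allele — plasmid if any of its reads carries
#' a designated plasmid variant, genomic for the reference allele — using
#' majority vote across the event's reads; events whose reads are all
#' ambiguous are dropped and their count logged as an attribute.
#'
#' @param reads A tibble with columns `probe_id`, `umi`, `allele`.
#' @param plasmid_alleles,genomic_alleles Allele values diagnostic for each
#'   source (defaults `"alt"` / `"ref"`).
#' @param probes Optional probe panel (adds the `target` class column).
#' @return A `capture_table` tibble: `probe_id`, (`target`,) `n_genomic`,
#'   `n_plasmid`; attribute `n_ambiguous_dropped`.
#' @export
smmip_dedup <- function(reads, plasmid_alleles = "alt",
                        genomic_alleles = "ref", probes = NULL) {
  stopifnot(all(c("probe_id", "umi", "allele") %in% names(reads)))
  calls <- reads %>%
    mutate(src = dplyr::case_when(
      .data$allele %in% plasmid_alleles ~ "plasmid",
      .data$allele %in% genomic_alleles ~ "genomic",
      TRUE ~ NA_character_
    )) %>%
    filter(!is.na(.data$src)) %>%
    group_by(.data$probe_id, .data$umi) %>%
    summarise(
      source = names(which.max(table(.data$src))),
      .groups = "drop"
    )
  n_events_total <- dplyr::n_distinct(reads[, c("probe_id", "umi")])
  n_dropped <- n_events_total - nrow(calls)

  out <- calls %>%
    count(.data$probe_id, .data$source) %>%
    tidyr::pivot_wider(
      names_from = "source", values_from = "n",
      values_fill = 0L, names_prefix = "n_"
    )
  for (col in c("n_genomic", "n_plasmid")) {
    if (!col %in% names(out)) out[[col]] <- 0L
  }
  if (!is.null(probes)) {
    out <- left_join(out, probes[, c("probe_id", "target")], by = "probe_id")
    out <- out[, c("probe_id", "target", "n_genomic", "n_plasmid")]
  }
  attr(out, "n_ambiguous_dropped") <- n_dropped
  class(out) <- c("capture_table", class(out))
  out
}

#' smMIP copy-number estimate
#'
#' Per single-copy probe `j`, `P_j = plasmid_j / genomic_j` estimates the
#' plasmids per genome; `P` aggregates over probes. Per rDNA probe `m`,
#' `c_m = (genomic_m / plasmid_m) * P`; the estimate aggregates over rDNA
#' probes. Because both counts within a probe share that probe's capture
#' efficiency, the efficiency cancels.
#'
#' @param table A `capture_table` with a `target` column (`"rdna"` /
#'   `"single_copy"`), e.g. from [smmip_dedup()] with `probes` supplied.
#' @param combine `"median"` (default; robust to a failing probe) or
#'   `"mean"` aggregation across probes.
#' @return A one-row `cn_estimate` tibble (`method = "smMIP"`) with the
#'   plasmids-per-genome estimate carried alongside.
#' @export
smmip_estimate <- function(table, combine = c("median", "mean")) {
  combine <- match.arg(combine)
  agg <- if (combine == "median") median else mean
  stopifnot(all(c("probe_id", "target", "n_genomic", "n_plasmid") %in%
    names(table)))
  sc <- table[table$target == "single_copy", ]
  rd <- table[table$target == "rdna", ]
  if (nrow(sc) == 0 || nrow(rd) == 0) {
    abort("need at least one single-copy probe and one rDNA probe")
  }
  if (all(sc$n_plasmid == 0) || all(rd$n_plasmid == 0)) {
    abort("zero plasmid capture events on an entire probe class")
  }
  sc <- sc[sc$n_genomic > 0 & sc$n_plasmid > 0, ]
  rd <- rd[rd$n_plasmid > 0, ]
  plasmids_per_genome <- agg(sc$n_plasmid / sc$n_genomic)
  value <- agg(rd$n_genomic / rd$n_plasmid * plasmids_per_genome)
  cn_estimate(
    method = "smMIP", value = value,
    plasmids_per_genome = plasmids_per_genome,
    n_sc_probes = nrow(sc), n_rdna_probes = nrow(rd)
  )
}
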