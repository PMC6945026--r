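# Relative-read (RR) copy-number estimation from alignment record counts.
# Counting follows the published workflow: every mapped record (each mate
# separately) counts, duplicates are retained, and no mapping-quality filter
# is applied; a record counts toward a region if its reference span overlaps
# the region by at least one base. Region coordinates are handled internally
# as 0-based half-open.

#' Read an alignment table from a SAM file
#'
#' Converts the SAM through samtools (via Rsamtools) and returns one row per
#' mapped record; unmapped records are excluded and each mate of a pair is a
#' separate record. Duplicates are retained.
#'
#' @param sam_path Path to a SAM (or BAM) file.
#' @return A tibble with columns `qname`, `seqname`, `pos`, `width`,
#'   `strand`, `mapq` — `pos` is the 1-based leftmost reference position and
#'   `width` the reference span of the alignment.
#' @export
read_alignments <- function(sam_path) {
  if (!file.exists(sam_path)) abort(sprintf("no such file: %s", sam_path))
  path <- sam_path
  if (!grepl("\\.bam$", sam_path, ignore.case = TRUE)) {
    dest <- tempfile()
    path <- Rsamtools::asBam(sam_path, dest, indexDestination = FALSE)
  }
  g <- as.data.frame(GenomicAlignments::readGAlignments(
    Rsamtools::BamFile(path),
    param = Rsamtools::ScanBamParam(what = c("qname", "mapq"))
  ))
  out <- tibble(
    qname = g$qname,
    seqname = as.character(g$seqnames),
    pos = g$start,
    width = g$width,
    strand = as.character(g$strand),
    mapq = g$mapq
  )
  class(out) <- c("read_alignments", class(out))
  out
}

normalize_regions <- function(regions, convention = c("bed", "onebased")) {
  convention <- match.arg(convention)
  stopifnot(all(c("name", "seqname", "start", "end") %in% names(regions)))
  out <- as_tibble(regions)
  if (convention == "onebased") {
    out$start <- out$start - 1L
  }
  if (any(out$start >= out$end)) {
    abort("regions must have start < end after normalization")
  }
  out
}

#' Count alignment records per region
#'
#' A record counts toward a region if its alignment span overlaps the region
#' by at least one base (`overlap` counting) — the regional-view semantics of
#' samtools — and additionally by whether its start position lies inside the
#' region (`start` counting, used inside the GC-corrected likelihood).
#'
#' @param alignments A tibble of alignment records ([read_alignments()] or
#'   [simulate_reads()] output).
#' @param regions A tibble with columns `name`, `seqname`, `start`, `end`, or
#'   a `reference_model` (its repeat region plus control regions are used).
#' @param convention Coordinate convention of `regions`: `"bed"` (0-based
#'   half-open, the default and the internal representation) or `"onebased"`
#'   (1-based inclusive, as printed coordinates usually are).
#' @return A `count_summary` tibble: one row per region with `n_overlap`,
#'   `n_start` and `region_length`, plus the genome-wide `total_mapped`
#'   record count as an attribute (also repeated in column `total_mapped`).
#' @export
count_regions <- function(alignments, regions, convention = "bed") {
  if (inherits(regions, "reference_model")) {
    regions <- dplyr::bind_rows(regions$repeat_region, regions$control_regions)
  }
  regions <- normalize_regions(regions, convention)
  known <- unique(alignments$seqname)
  if (nrow(regions) > 0 && !all(regions$seqname %in% known)) {
    bad <- setdiff(unique(regions$seqname), known)
    abort(sprintf(
      "region(s) on sequence(s) absent from the alignments: %s",
      paste(bad, collapse = ", ")
    ))
  }
  total <- nrow(alignments)
  aln_end <- alignments$pos + alignments$width - 1L # 1-based inclusive
  counts <- purrr::pmap(regions, function(name, seqname, start, end, ...) {
    on_seq <- alignments$seqname == seqname
    # region 1-based inclusive span is [start + 1, end]
    n_overlap <- sum(on_seq & alignments$pos <= end & aln_end >= start + 1L)
    n_start <- sum(on_seq & alignments$pos >= start + 1L &
      alignments$pos <= end)
    tibble(
      region = name, seqname = seqname, start = start, end = end,
      region_length = end - start,
      n_overlap = n_overlap, n_start = n_start
    )
  })
  out <- dplyr::bind_rows(counts)
  out$total_mapped <- total
  attr(out, "total_mapped") <- total
  class(out) <- c("count_summary", class(out))
  out
}

#' Relative-read (RR) copy-number estimate
#'
#' The published coverage-ratio formula: with `N_region` records on the
#' repeat region, `N_tot` mapped records genome-wide, collapsed genome length
#' `G` and repeat-unit length `L`, the copy number is
#' `(N_region * G) / (N_tot * L)`. The counting span and the unit length are
#' independent parameters: the worm workflow counts over a 10,735-bp printed
#' span but divides by the 7,197-bp unit.
#'
#' @param counts A [count_regions()] result.
#' @param genome_length Collapsed genome length `G` in bases.
#' @param unit_length Repeat unit length `L` in bases; defaults to the
#'   region's own length, which is the right choice for single-copy audits.
#' @param region Name of the region to estimate (default `"rdna"`).
#' @param counting `"overlap"` (default) or `"start"` record counting.
#' @return A one-row `cn_estimate` tibble with columns `method`, `value`,
#'   `region`, `n_region`, `n_total`.
#' @export
estimate_rr <- function(counts, genome_length, unit_length = NULL,
                        region = "rdna", counting = c("overlap", "start")) {
  counting <- match.arg(counting)
  row <- counts[counts$region == region, ]
  if (nrow(row) != 1) abort(sprintf("region '%s' not in count summary", region))
  n_tot <- attr(counts, "total_mapped") %||% row$total_mapped
  if (n_tot == 0) abort("no mapped records: N_tot = 0")
  if (is.null(unit_length)) unit_length <- row$region_length
  n_reg <- if (counting == "overlap") row$n_overlap else row$n_start
  if (n_reg == 0) warn(sprintf("no records on region '%s'; estimate is 0", region))
  cn_estimate(
    method = "RR",
    value = (as.numeric(n_reg) * genome_length) / (as.numeric(n_tot) * unit_length),
    region = region, n_region = n_reg, n_total = n_tot
  )
}

cn_estimate <- function(method, value, conf.low = NA_real_,
                        conf.high = NA_real_, ...) {
  out <- tibble(
    method = method, value = value,
    conf.low = conf.low, conf.high = conf.high, ...
  )
  class(out) <- c("cn_estimate", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Single-copy control-region audit
#'
#' Applies the RR estimator to each single-copy control region, with the unit
#' length equal to the region's own length, so each estimate should be ~1 in
#' an undistorted library. The mean across regions is the per-library
#' inflation statistic used to diagnose coverage distortion.
#'
#' @param alignments Alignment records.
#' @param ref A `reference_model`, or a tibble of control regions.
#' @param genome_length Collapsed genome length; taken from `ref` when a
#'   `reference_model` is supplied.
#' @return A `control_audit` tibble, one RR estimate per control region;
#'   `glance()` returns the mean and range.
#' @export
estimate_control_regions <- function(alignments, ref, genome_length = NULL) {
  if (inherits(ref, "reference_model")) {
    regions <- ref$control_regions
    genome_length <- genome_length %||% ref$genome_length
  } else {
    regions <- ref
    if (is.null(genome_length)) abort("`genome_length` is required")
  }
  if (nrow(regions) == 0) {
    out <- tibble(
      region = character(), value = numeric(),
      n_region = integer(), n_total = integer()
    )
    class(out) <- c("control_audit", class(out))
    return(out)
  }
  counts <- count_regions(alignments, regions)
  out <- purrr::map_dfr(regions$name, function(nm) {
    est <- estimate_rr(counts, genome_length, region = nm)
    tibble(
      region = nm, value = est$value,
      n_region = est$n_region, n_total = est$n_total
    )
  })
  class(out) <- c("control_audit", class(out))
  out
}

#' @method glance control_audit
#' @export
glance.control_audit <- function(x, ...) {
  tibble(
    n_regions = nrow(x), mean = mean(x$value),
    min = min(x$value), max = max(x$value)
  )
}

#' Downsampling stability analysis
#'
#' Each replicate keeps every alignment record independently with probability
#' `fraction` (record-level Bernoulli thinning) and re-estimates copy number,
#' quantifying how much of the between-library error could be explained by
#' read sampling alone.
#'
#' @param alignments Alignment records.
#' @param ref A `reference_model` (supplies regions, genome and unit length,
#'   and the GC profile machinery for `method = "gcc"`).
#' @param fraction Retention probability in (0, 1].
#' @param n_reps Number of replicates (must be >= 1).
#' @param seed Integer seed.
#' @param method `"rr"` or `"gcc"`.
#' @param ... Passed to [fit_gc_profile()] when `method = "gcc"`.
#' @return A tibble with one row per replicate (`rep`, `value`, `n_kept`);
#'   `glance()` gives the mean, the percent spread
#'   (100 * (max - min) / mean) and the full-data estimate.
#' @export
downsample_estimates <- function(alignments, ref, fraction = 0.05,
                                 n_reps = 10, seed = 1L,
                                 method = c("rr", "gcc"), ...) {
  method <- match.arg(method)
  if (n_reps < 1) abort("`n_reps` must be at least 1")
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1]")
  est_fun <- function(aln) {
    if (method == "rr") {
      counts <- count_regions(aln, ref$repeat_region)
      estimate_rr(counts, ref$genome_length, ref$unit_length)$value
    } else {
      prof <- fit_gc_profile(aln, ref, ...)
      estimate_gcc(aln, ref, prof)$value
    }
  }
  full <- est_fun(alignments)
  reps <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_reps), function(r) {
      keep <- runif(nrow(alignments)) < fraction
      aln <- alignments[keep, ]
      tibble(rep = r, value = est_fun(aln), n_kept = sum(keep))
    })
  })
  attr(reps, "full_value") <- full
  attr(reps, "fraction") <- fraction
  class(reps) <- c("downsample_estimates", class(reps))
  reps
}

#' @method glance downsample_estimates
#' @export
glance.downsample_estimates <- function(x, ...) {
  tibble(
    n_reps = nrow(x),
    mean = mean(x$value),
    sd = sd(x$value),
    percent_spread = 100 * (max(x$value) - min(x$value)) / mean(x$value),
    full_value = attr(x, "full_value"),
    fraction = attr(x, "fraction")
  )
}
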