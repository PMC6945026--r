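# Reference model: the collapsed genome plus repeat locus and control regions.
# Sequences are held as an integer base vector (1=A, 2=C, 3=G, 4=T) with a
# cached cumulative-GC vector, which keeps fragment-GC lookups O(1); FASTA
# output materialises a Biostrings DNAStringSet on demand.

BASES <- c("A", "C", "G", "T")

#' Genome length and repeat constants of the worm and yeast workflows
#'
#' The constants used by the published estimation workflows: the collapsed
#' genome length, the repeat-unit length, and the rDNA counting span
#' (1-based inclusive coordinates as printed for the worm assembly WS235).
#'
#' @param organism `"celegans"` or `"scerevisiae"`.
#' @return A list with `genome_length`, `unit_length` and (for the worm) the
#'   rDNA `region` as a 1-based inclusive coordinate pair on ChrI.
#' @export
reference_constants <- function(organism = c("celegans", "scerevisiae")) {
  organism <- match.arg(organism)
  switch(organism,
    celegans = list(
      genome_length = 100286070,
      unit_length = 7197,
      region = list(seqname = "ChrI", start = 15060299, end = 15071033)
    ),
    scerevisiae = list(
      genome_length = 12157105,
      unit_length = 9100,
      flank_left = 8800,
      flank_right = 30900
    )
  )
}

#' Build a synthetic collapsed reference genome
#'
#' Constructs a single-chromosome genome containing exactly one copy of a
#' tandem-repeat unit (the "collapsed" representation real assemblies use for
#' rDNA) plus a set of disjoint single-copy control regions of the same
#' length. Background GC is either homogeneous or tiled into isochore blocks;
#' the repeat unit's GC composition is settable independently.
#'
#' @param config A [sim_config()].
#' @return An object of class `reference_model` with fields
#'   `bases` (integer base vector), `genome_length`, `unit_length`,
#'   `repeat_region` / `control_regions` (0-based half-open tibbles), and a
#'   cache environment used by the read simulator and GC-profile fitter.
#' @export
build_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  G <- config$genome_length
  L <- config$repeat_unit_length

  withr::with_seed(config$seed, {
    bg_gc <- per_base_gc(G, config$gc_background, config$isochore_length)
    bases <- random_bases(G, bg_gc)
    # the unit is short enough that iid sampling would miss the configured
    # GC target by several points; draw an exact composition instead
    unit <- exact_gc_bases(L, config$gc_repeat)
  })

  # place the repeat at 60% of the genome, control regions in the first half
  repeat_start <- as.integer(floor(G * 0.6)) # 0-based
  bases[(repeat_start + 1):(repeat_start + L)] <- unit

  ctrl <- place_control_regions(G, L, repeat_start, config$n_control_regions)

  ref <- structure(
    list(
      seqname = "chr1",
      bases = bases,
      genome_length = G,
      unit_length = L,
      repeat_region = tibble(
        name = "rdna", seqname = "chr1",
        start = repeat_start, end = repeat_start + L
      ),
      control_regions = ctrl,
      gc_repeat = config$gc_repeat,
      seed = config$seed,
      cache = new.env(parent = emptyenv())
    ),
    class = "reference_model"
  )
  ref$cache$gc_cumsum <- c(0, cumsum(as.integer(bases == 2L | bases == 3L)))
  ref
}

per_base_gc <- function(n, gc, block) {
  if (length(gc) == 1) {
    return(rep(gc, n))
  }
  n_blocks <- ceiling(n / block)
  block_gc <- runif(n_blocks, min(gc), max(gc))
  rep(block_gc, each = block)[seq_len(n)]
}

random_bases <- function(n, gc) {
  is_gc <- runif(n) < gc
  strong <- sample(c(2L, 3L), n, replace = TRUE) # C or G
  weak <- sample(c(1L, 4L), n, replace = TRUE) # A or T
  ifelse(is_gc, strong, weak)
}

exact_gc_bases <- function(n, gc) {
  n_gc <- round(n * gc)
  is_gc <- logical(n)
  is_gc[sample.int(n, n_gc)] <- TRUE
  strong <- sample(c(2L, 3L), n, replace = TRUE)
  weak <- sample(c(1L, 4L), n, replace = TRUE)
  ifelse(is_gc, strong, weak)
}

place_control_regions <- function(G, L, repeat_start, n_wanted) {
  # evenly spaced, strictly before the repeat locus, pairwise disjoint
  span_end <- repeat_start - L
  n_fit <- max(0L, min(n_wanted, floor(span_end / (1.5 * L))))
  if (n_fit < n_wanted) {
    warn(sprintf(
      "only %d of %d requested control regions fit in the background",
      n_fit, n_wanted
    ))
  }
  starts <- as.integer(floor(seq(0, span_end - L, length.out = n_fit)))
  tibble(
    name = sprintf("control_%02d", seq_len(n_fit)),
    seqname = "chr1",
    start = starts,
    end = starts + L
  )
}

#' GC fraction of an interval of the reference
#'
#' @param ref A `reference_model`.
#' @param start,end 0-based half-open interval.
#' @return GC fraction.
#' @export
reference_gc <- function(ref, start, end) {
  cs <- ref$cache$gc_cumsum
  (cs[end + 1] - cs[start + 1]) / (end - start)
}

#' Write the reference genome as FASTA and its regions as BED
#'
#' BED output is 0-based half-open; the FASTA holds the collapsed genome.
#'
#' @param ref A `reference_model`.
#' @param fasta,bed Output paths (`NULL` to skip either).
#' @return `ref`, invisibly.
#' @export
write_reference <- function(ref, fasta = NULL, bed = NULL) {
  if (!is.null(fasta)) {
    dna <- Biostrings::DNAStringSet(paste(BASES[ref$bases], collapse = ""))
    names(dna) <- ref$seqname
    Biostrings::writeXStringSet(dna, fasta)
  }
  if (!is.null(bed)) {
    regions <- dplyr::bind_rows(ref$repeat_region, ref$control_regions)
    readr::write_tsv(
      regions[, c("seqname", "start", "end", "name")],
      bed,
      col_names = FALSE
    )
  }
  invisible(ref)
}

#' @export
print.reference_model <- function(x, ...) {
  cat("<reference_model>\n")
  cat(sprintf(
    "  %s: %s bp, repeat unit %s bp at [%d, %d), %d control regions\n",
    x$seqname, format(x$genome_length, big.mark = ","),
    format(x$unit_length, big.mark = ","),
    x$repeat_region$start, x$repeat_region$end, nrow(x$control_regions)
  ))
  invisible(x)
}
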