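#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator in one validated list.
#' The defaults describe a small but realistic study system: a collapsed
#' reference genome carrying a single tandem-repeat locus, an isochore-like
#' heterogeneous background GC landscape, tagmentation-style paired 75-bp
#' short reads whose fragments are accepted with a unimodal Gaussian weight in
#' fragment GC, Poisson droplet partitioning for ddPCR, per-probe capture
#' efficiencies with a co-captured normalization plasmid for smMIP, and
#' Gaussian nuclear FISH foci whose integrated intensity is proportional to
#' copy number.
#'
#' @param seed Integer seed. Identical configurations produce byte-identical
#'   outputs from every generator.
#' @param true_copy_number Repeat copies per haploid genome (positive real).
#' @param genome_length Length in bases of the *collapsed* reference genome
#'   (one copy of the repeat unit included), as reference genomes ship it.
#' @param repeat_unit_length Length of one repeat unit in bases. Must be at
#'   least `read_length`.
#' @param gc_repeat Target GC fraction of the repeat unit sequence.
#' @param gc_background Either a single GC fraction for a homogeneous
#'   background, or a length-2 range; with a range, the background is tiled
#'   with isochore blocks of `isochore_length` whose GC is drawn uniformly
#'   from the range. A heterogeneous background is what makes per-GC-bin rate
#'   estimation possible when the repeat's GC differs from the genome average.
#' @param isochore_length Block length in bases for the heterogeneous
#'   background.
#' @param gc_bias_mode `"none"` (uniform fragment sampling) or `"unimodal"`
#'   (Gaussian acceptance weight in fragment GC).
#' @param gc_bias_center,gc_bias_width Center and standard-deviation width of
#'   the unimodal acceptance weight `w(g) = exp(-(g - center)^2 / (2 width^2))`.
#' @param fragment_mean,fragment_sd Fragment length distribution (bases);
#'   lengths are truncated normal on `[2 * read_length, 2000]`.
#' @param read_length Read length in bases (default 75, paired).
#' @param n_read_pairs Number of read pairs to emit.
#' @param plasmid_to_genome_molar_ratio Plasmid molecules per genomic copy in
#'   the smMIP reaction (default 19, i.e. a 1:19 genome:plasmid molar ratio).
#' @param probes smMIP probe panel: a tibble with columns `probe_id`,
#'   `target` (`"rdna"` or `"single_copy"`) and `efficiency` (expected unique
#'   capture events per template copy). Defaults to three rDNA and four
#'   single-copy probes with deliberately unequal efficiencies.
#' @param reads_per_event Mean sequenced reads per unique capture event.
#' @param smmip_ambiguous_rate Fraction of reads whose diagnostic allele is
#'   unreadable (dropped during deduplication).
#' @param droplet_count Number of ddPCR droplets.
#' @param droplet_volume Droplet volume in nanolitres (default 0.85 nL).
#' @param n_control_regions Number of single-copy control regions recorded in
#'   the reference (default 29); fewer are placed, with a warning, if the
#'   genome cannot hold them disjointly.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       true_copy_number = 100,
                       genome_length = 2e6,
                       repeat_unit_length = 500,
                       gc_repeat = 0.55,
                       gc_background = c(0.30, 0.60),
                       isochore_length = 10000,
                       gc_bias_mode = c("none", "unimodal"),
                       gc_bias_center = 0.40,
                       gc_bias_width = 0.12,
                       fragment_mean = 350,
                       fragment_sd = 50,
                       read_length = 75,
                       n_read_pairs = 1e5,
                       plasmid_to_genome_molar_ratio = 19,
                       probes = default_smmip_probes(),
                       reads_per_event = 3,
                       smmip_ambiguous_rate = 0,
                       droplet_count = 20000,
                       droplet_volume = 0.85,
                       n_control_regions = 29L) {
  gc_bias_mode <- match.arg(gc_bias_mode)
  cfg <- list(
    seed = as.integer(seed),
    true_copy_number = true_copy_number,
    genome_length = as.integer(genome_length),
    repeat_unit_length = as.integer(repeat_unit_length),
    gc_repeat = gc_repeat,
    gc_background = gc_background,
    isochore_length = as.integer(isochore_length),
    gc_bias_mode = gc_bias_mode,
    gc_bias_center = gc_bias_center,
    gc_bias_width = gc_bias_width,
    fragment_mean = fragment_mean,
    fragment_sd = fragment_sd,
    read_length = as.integer(read_length),
    n_read_pairs = as.integer(n_read_pairs),
    plasmid_to_genome_molar_ratio = plasmid_to_genome_molar_ratio,
    probes = probes,
    reads_per_event = reads_per_event,
    smmip_ambiguous_rate = smmip_ambiguous_rate,
    droplet_count = as.integer(droplet_count),
    droplet_volume = droplet_volume,
    n_control_regions = as.integer(n_control_regions)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1)
  if (cfg$true_copy_number <= 0) {
    abort("`true_copy_number` must be positive.")
  }
  if (cfg$repeat_unit_length < cfg$read_length) {
    abort(sprintf(
      "`repeat_unit_length` (%d) must be at least `read_length` (%d).",
      cfg$repeat_unit_length, cfg$read_length
    ))
  }
  if (cfg$fragment_mean <= cfg$read_length) {
    abort("`fragment_mean` must exceed `read_length`.")
  }
  if (cfg$genome_length < 10 * cfg$repeat_unit_length) {
    abort("`genome_length` must be at least 10 * `repeat_unit_length`.")
  }
  if (!cfg$gc_bias_mode %in% c("none", "unimodal")) {
    abort("unknown `gc_bias_mode`")
  }
  if (any(cfg$gc_background < 0 | cfg$gc_background > 1) ||
    !length(cfg$gc_background) %in% 1:2) {
    abort("`gc_background` must be a GC fraction or range within [0, 1].")
  }
  if (cfg$gc_bias_width <= 0) abort("`gc_bias_width` must be positive.")
  if (cfg$plasmid_to_genome_molar_ratio <= 0) {
    abort("`plasmid_to_genome_molar_ratio` must be positive.")
  }
  if (cfg$droplet_volume <= 0) abort("`droplet_volume` must be positive.")
  invisible(cfg)
}

#' Default smMIP probe panel
#'
#' Three rDNA-targeting and four single-copy-targeting probes with unequal
#' capture efficiencies (expected unique events per template copy); the
#' plasmid normalization makes the estimator invariant to these values.
#'
#' @return A tibble with columns `probe_id`, `target`, `efficiency`.
#' @export
default_smmip_probes <- function() {
  tibble(
    probe_id = c("rdna_1", "rdna_2", "rdna_3", "sc_1", "sc_2", "sc_3", "sc_4"),
    target = c(rep("rdna", 3), rep("single_copy", 4)),
    efficiency = c(15, 40, 90, 220, 310, 450, 600)
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  genome %s bp, repeat unit %s bp, true copy number %s\n",
    format(x$genome_length, big.mark = ","),
    format(x$repeat_unit_length, big.mark = ","), x$true_copy_number
  ))
  cat(sprintf(
    "  gc bias: %s (center %.2f, width %.2f); %s read pairs of %d bp\n",
    x$gc_bias_mode, x$gc_bias_center, x$gc_bias_width,
    format(x$n_read_pairs, big.mark = ","), x$read_length
  ))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
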