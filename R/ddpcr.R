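# Droplet digital PCR: Poisson zero-class quantification with a single-copy
# reference channel.

#' Construct a droplet assay record
#'
#' @param n_droplets Total droplets read.
#' @param positives_target,positives_reference Positive droplet counts for
#'   the target (repeat) and reference (single-copy gene) channels.
#' @param droplet_volume Droplet volume in nanolitres (default 0.85 nL).
#' @param reference_copies_per_genome Copies of the reference locus per
#'   haploid genome (default 1, e.g. TUB1).
#' @return A one-row `droplet_assay` tibble.
#' @export
droplet_assay <- function(n_droplets, positives_target, positives_reference,
                          droplet_volume = 0.85,
                          reference_copies_per_genome = 1) {
  stopifnot(
    n_droplets >= 0, positives_target >= 0, positives_reference >= 0,
    positives_target <= n_droplets, positives_reference <= n_droplets,
    droplet_volume > 0
  )
  out <- tibble(
    n_droplets = as.integer(n_droplets),
    positives_target = as.integer(positives_target),
    positives_reference = as.integer(positives_reference),
    droplet_volume = droplet_volume,
    reference_copies_per_genome = reference_copies_per_genome
  )
  class(out) <- c("droplet_assay", class(out))
  out
}

#' Poisson concentration from a positive-droplet count
#'
#' With positive fraction `p = k / n`, the template concentration is
#' `lambda = -log(1 - p) / v` copies per unit volume (Poisson zero class).
#' The 95% confidence interval propagates the normal approximation on `p`
#' through the log: `lambda +/- 1.96 * sqrt(p / (n (1 - p))) / v`.
#'
#' @param k Positive droplets.
#' @param n Total droplets (must exceed `k`; a saturated assay carries no
#'   information about the concentration).
#' @param v Droplet volume (nL).
#' @return A one-row tibble: `lambda` (copies/nL), `conf.low`, `conf.high`,
#'   `k`, `n`, `volume`.
#' @export
ddpcr_lambda <- function(k, n, v = 0.85) {
  if (n <= 0) abort("`n` must be positive")
  if (k < 0 || k > n) abort("`k` must lie in [0, n]")
  if (k == n) abort("all droplets positive: assay saturated, dilute and rerun")
  p <- k / n
  lambda <- -log(1 - p) / v
  se <- sqrt(p / (n * (1 - p))) / v
  tibble(
    lambda = lambda,
    conf.low = max(0, lambda - 1.96 * se),
    conf.high = lambda + 1.96 * se,
    se = se, k = as.integer(k), n = as.integer(n), volume = v
  )
}

#' ddPCR copy-number estimate
#'
#' Target and reference concentrations are computed with [ddpcr_lambda()]
#' from the same reaction; the copy number is their ratio scaled by the
#' reference locus copy number. The interval propagates the two channel
#' standard errors assuming independence.
#'
#' @param assay A [droplet_assay()].
#' @return A one-row `cn_estimate` tibble (`method = "ddPCR"`).
#' @export
ddpcr_copy_number <- function(assay) {
  stopifnot(inherits(assay, "droplet_assay"))
  if (assay$positives_reference == 0) {
    abort("no positive reference droplets: reference concentration is 0")
  }
  lt <- ddpcr_lambda(assay$positives_target, assay$n_droplets, assay$droplet_volume)
  lr <- ddpcr_lambda(assay$positives_reference, assay$n_droplets, assay$droplet_volume)
  ratio <- lt$lambda / lr$lambda
  value <- ratio * assay$reference_copies_per_genome
  rel_se <- sqrt((lt$se / lt$lambda)^2 + (lr$se / lr$lambda)^2)
  se <- value * rel_se
  cn_estimate(
    method = "ddPCR", value = value,
    conf.low = max(0, value - 1.96 * se), conf.high = value + 1.96 * se,
    lambda_target = lt$lambda, lambda_reference = lr$lambda
  )
}

#' Simulate a droplet assay
#'
#' Per-droplet target and reference molecule counts are independent
#' Poisson(`lambda * v`); a droplet is positive on a channel when it holds at
#' least one molecule of that template.
#'
#' @param lambda_target,lambda_reference Template concentrations (copies/nL).
#' @param config A [sim_config()] (`droplet_count`, `droplet_volume`, `seed`).
#' @return A `droplet_assay` with a `truth` attribute holding the per-droplet
#'   occupancy tibble.
#' @export
simulate_droplets <- function(lambda_target, lambda_reference, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$droplet_count
  if (n <= 0) abort("`droplet_count` must be positive")
  v <- config$droplet_volume
  truth <- withr::with_seed(config$seed, tibble(
    droplet = seq_len(n),
    n_target = rpois(n, lambda_target * v),
    n_reference = rpois(n, lambda_reference * v)
  ))
  assay <- droplet_assay(
    n_droplets = n,
    positives_target = sum(truth$n_target > 0),
    positives_reference = sum(truth$n_reference > 0),
    droplet_volume = v
  )
  attr(assay, "truth") <- truth
  assay
}
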