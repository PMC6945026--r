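# CHEF pulsed-field gel: ladder calibration (piecewise-linear in migration vs
# log size), band-size -> copy-number arithmetic, and replicate statistics.

#' Default chromosome ladder for CHEF calibration
#'
#' Rung sizes follow the S. cerevisiae chromosome set plus the large
#' H. wingei chromosomes (up to 3.13 Mb); migration distances are generated
#' from a log-linear mobility model, so this ladder is synthetic but spans
#' the range the assay uses.
#'
#' @return A `ladder_calibration` tibble with columns `migration` (arbitrary
#'   units, increasing) and `size` (bases, decreasing).
#' @export
chef_ladder <- function() {
  sizes <- c(
    3130000, 2700000, 2500000, 2350000, 1810000, 1660000, 1370000,
    1125000, 1020000, 945000, 785000, 680000, 610000, 565000,
    450000, 365000, 290000, 225000
  )
  ladder_calibration(
    migration = 120 * (log10(3.5e6) - log10(sizes)),
    size = sizes
  )
}

#' Construct a ladder calibration
#'
#' @param migration Migration distances (arbitrary units).
#' @param size Rung sizes in bases; must be strictly decreasing in
#'   migration distance.
#' @return A `ladder_calibration` tibble sorted by migration.
#' @export
ladder_calibration <- function(migration, size) {
  stopifnot(length(migration) == length(size), length(size) >= 2)
  o <- order(migration)
  migration <- migration[o]
  size <- size[o]
  if (any(diff(size) >= 0)) {
    abort("ladder size must strictly decrease with migration distance")
  }
  out <- tibble(migration = migration, size = size)
  class(out) <- c("ladder_calibration", class(out))
  out
}

#' Band size from migration distance
#'
#' Piecewise-linear interpolation in (migration, log size); exact at ladder
#' rungs, geometric-mean interpolation between them.
#'
#' @param migration Measured migration distance(s).
#' @param ladder A [ladder_calibration()].
#' @return Size(s) in bases.
#' @export
calibrate_size <- function(migration, ladder) {
  stopifnot(inherits(ladder, "ladder_calibration"))
  if (any(migration < min(ladder$migration) |
    migration > max(ladder$migration))) {
    abort("migration outside the ladder range: band beyond ladder resolution")
  }
  exp(approx(ladder$migration, log(ladder$size), xout = migration)$y)
}

size_to_migration <- function(size, ladder) {
  if (any(size > max(ladder$size) | size < min(ladder$size))) {
    abort("band size outside the ladder range")
  }
  approx(log(ladder$size), ladder$migration, xout = log(size))$y
}

#' Copy number from an excised-array band size
#'
#' The array size minus the restriction flanks, divided by the repeat-unit
#' length: `copies = (size - flank_left - flank_right) / unit_length`. The
#' worm workflow divides the total band size directly (flanks 0); the yeast
#' BamHI workflow subtracts the 8.8 kb centromere-proximal and 30.9 kb
#' telomere-proximal flanks. Reported to the nearest integer with the
#' unrounded value retained.
#'
#' @param size Band size in bases (from [calibrate_size()]).
#' @param unit_length Repeat unit length in bases.
#' @param flank_left,flank_right Non-repeat flank lengths included in the
#'   band (bases).
#' @param role Band role, `"primary"` or `"minor"` (population sub-band).
#' @return A `cn_estimate` tibble (`method = "CHEF"`) with rounded `value`
#'   and unrounded `value_raw`.
#' @export
chef_copy_number <- function(size, unit_length, flank_left = 0,
                             flank_right = 0, role = "primary") {
  flanks <- flank_left + flank_right
  if (any(size <= flanks)) {
    abort("band size does not exceed the flank total: no array to measure")
  }
  raw <- (size - flanks) / unit_length
  cn_estimate(
    method = "CHEF", value = round(raw), value_raw = raw,
    size = size, role = role
  )
}

#' Replicate summary for CHEF measurements
#'
#' Mean, sample (n-1) standard deviation and coefficient of variation
#' `CV% = 100 * sd / mean`. A single value has no dispersion estimate and is
#' reported with `cv_percent = NA`.
#'
#' @param values Replicate copy-number values.
#' @return A one-row tibble: `n`, `mean`, `mean_rounded`, `sd`, `cv_percent`.
#' @export
chef_replicates <- function(values) {
  values <- values[!is.na(values)]
  m <- mean(values)
  s <- if (length(values) >= 2) sd(values) else NA_real_
  tibble(
    n = length(values), mean = m, mean_rounded = round(m),
    sd = s, cv_percent = 100 * s / m
  )
}

#' Simulate a CHEF band measurement
#'
#' The true band size is `copies * unit_length + flanks`; its migration is
#' found by inverting the ladder's monotone size-to-distance map after
#' applying Gaussian measurement noise on log-size (gel physics are not
#' modelled).
#'
#' @param true_copies True array copy number.
#' @param unit_length Repeat unit length (bases).
#' @param flank_left,flank_right Flank sizes included in the band (bases).
#' @param ladder A [ladder_calibration()].
#' @param noise_sd Measurement noise SD in log-size units.
#' @param n_replicates Number of replicate measurements.
#' @param seed Integer seed.
#' @return A `chef_measurement` tibble with one row per replicate:
#'   `replicate`, `migration`, `true_size`.
#' @export
simulate_chef_measurement <- function(true_copies, unit_length,
                                      flank_left = 0, flank_right = 0,
                                      ladder = chef_ladder(),
                                      noise_sd = 0.05, n_replicates = 1,
                                      seed = 1L) {
  true_size <- true_copies * unit_length + flank_left + flank_right
  if (true_size <= flank_left + flank_right) {
    abort("band size does not exceed the flank total")
  }
  withr::with_seed(seed, {
    measured <- exp(log(true_size) + rnorm(n_replicates, 0, noise_sd))
  })
  out <- tibble(
    replicate = seq_len(n_replicates),
    migration = size_to_migration(measured, ladder),
    true_size = true_size
  )
  class(out) <- c("chef_measurement", class(out))
  out
}
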