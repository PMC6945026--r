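test_that("sim_config rejects inconsistent geometry", {
  expect_error(sim_config(repeat_unit_length = 50), "read_length")
  expect_error(sim_config(fragment_mean = 60), "fragment_mean")
  expect_error(
    sim_config(genome_length = 3000, repeat_unit_length = 500),
    "10"
  )
  expect_error(sim_config(true_copy_number = 0), "positive")
})

test_that("reference construction is deterministic and places regions", {
  cfg <- sim_config(
    seed = 5, genome_length = 5e5, repeat_unit_length = 5000,
    n_control_regions = 29
  )
  ref1 <- build_reference(cfg)
  ref2 <- build_reference(cfg)
  expect_identical(ref1$bases, ref2$bases)

  f1 <- tempfile(fileext = ".fa")
  f2 <- tempfile(fileext = ".fa")
  write_reference(ref1, fasta = f1)
  write_reference(ref2, fasta = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))

  expect_equal(ref1$repeat_region$end - ref1$repeat_region$start, 5000)
  expect_equal(nrow(ref1$control_regions), 29)
  # control regions pairwise disjoint and clear of the repeat
  cr <- ref1$control_regions[order(ref1$control_regions$start), ]
  expect_true(all(cr$start[-1] >= cr$end[-nrow(cr)]))
  expect_true(all(cr$end <= ref1$repeat_region$start))
})

test_that("repeat and background GC compositions hit their targets", {
  cfg <- sim_config(
    seed = 9, genome_length = 5e5, repeat_unit_length = 5000,
    gc_repeat = 0.55, gc_background = 0.35
  )
  ref <- build_reference(cfg)
  rr <- ref$repeat_region
  gc_rep <- reference_gc(ref, rr$start, rr$end)
  gc_bg <- reference_gc(ref, 0, rr$start)
  expect_lt(abs(gc_rep - 0.55), 0.02)
  expect_lt(abs(gc_bg - 0.35), 0.02)
})

test_that("unbiased read share matches the closed-form expectation", {
  for (cc in c(1, 10)) {
    cfg <- sim_config(
      seed = 11 + cc, true_copy_number = cc, genome_length = 1e6,
      repeat_unit_length = 500, n_read_pairs = 3e4, gc_bias_mode = "none"
    )
    ref <- build_reference(cfg)
    reads <- simulate_reads(ref, cfg)
    G <- cfg$genome_length
    L <- cfg$repeat_unit_length
    p_expect <- cc * L / (G + (cc - 1) * L)
    counts <- count_regions(reads, ref$repeat_region)
    n <- nrow(reads)
    p_hat <- counts$n_start[counts$region == "rdna"] / n
    tol <- 3 * sqrt(p_expect * (1 - p_expect) / n) + 1e-4
    expect_lt(abs(p_hat - p_expect), tol)
  }
})

test_that("every simulated read carries exactly one truth record", {
  sim <- tiny_sim()
  reads <- sim$reads
  expect_equal(nrow(reads), 2 * attr(reads, "n_pairs"))
  expect_true(all(reads$origin %in% c("repeat", "background")))
  expect_true(all(!is.na(reads$copy_index[reads$origin == "repeat"])))
  expect_true(all(is.na(reads$copy_index[reads$origin == "background"])))
  # determinism
  reads2 <- simulate_reads(sim$ref, sim$cfg)
  expect_identical(reads$pos, reads2$pos)
})

test_that("a degenerate acceptance weight is rejected with a diagnostic", {
  cfg <- sim_config(
    seed = 2, genome_length = 1e6, repeat_unit_length = 500,
    n_read_pairs = 1000, gc_bias_mode = "unimodal",
    gc_bias_center = 0.999, gc_bias_width = 0.004
  )
  ref <- build_reference(cfg)
  expect_error(simulate_reads(ref, cfg), "degenerate")
})

test_that("droplet simulation follows the Poisson zero class", {
  cfg <- sim_config(seed = 21, droplet_count = 20000)
  v <- cfg$droplet_volume

  a0 <- simulate_droplets(0, 1 / v, cfg)
  expect_equal(a0$positives_target, 0L)

  a1 <- simulate_droplets(1 / v, 0.05 / v, cfg)
  p <- a1$positives_target / a1$n_droplets
  p_exp <- 1 - exp(-1)
  expect_lt(abs(p - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / a1$n_droplets))

  truth <- attr(a1, "truth")
  expect_equal(nrow(truth), a1$n_droplets)
  expect_equal(sum(truth$n_target > 0), a1$positives_target)
})

test_that("smMIP read table conserves truth events and encodes sources", {
  cfg <- sim_config(seed = 31, true_copy_number = 50)
  reads <- simulate_smmip_reads(cfg)
  truth <- attr(reads, "truth")
  # every truth event appears among the reads (each event emits >= 1 read)
  ct <- smmip_dedup(reads, probes = cfg$probes)
  got <- dplyr::arrange(
    tidyr::pivot_longer(ct, c("n_genomic", "n_plasmid"),
      names_to = "source", values_to = "n"
    ),
    probe_id, source
  )
  got$source <- sub("n_", "", got$source)
  want <- dplyr::arrange(truth, probe_id, source)
  merged <- dplyr::left_join(want, got[, c("probe_id", "source", "n")],
    by = c("probe_id", "source")
  )
  # UMI collisions can only merge events (undercount), never create them
  expect_true(all(merged$n <= merged$n_events))
  expect_true(all(merged$n >= merged$n_events - 3))
})

test_that("CHEF simulation round-trips exactly at zero noise", {
  ladder <- chef_ladder()
  m <- simulate_chef_measurement(412, 7197, noise_sd = 0, seed = 3)
  size <- calibrate_size(m$migration, ladder)
  expect_equal(chef_copy_number(size, 7197)$value_raw, 412, tolerance = 1e-9)
  expect_error(
    simulate_chef_measurement(0, 9100, flank_left = 8800, flank_right = 30900),
    "flank"
  )
})

test_that("CHEF replicate noise at 0.05 log-units lands in the observed CV range", {
  m <- simulate_chef_measurement(412, 7197,
    noise_sd = 0.05,
    n_replicates = 3, seed = 17
  )
  copies <- chef_copy_number(
    calibrate_size(m$migration, chef_ladder()), 7197
  )$value_raw
  cv <- cv_percent(copies)
  expect_gt(cv, 0.3) # order of magnitude of the observed 3-15%
  expect_lt(cv, 50)
})

test_that("a rendered zero-noise focus integrates to its configured total", {
  st <- simulate_fish_stack(
    n_cells = 1, copy_number = 100, p_two_foci = 0,
    noise_sd = 0, seed = 4, cell_box = c(40, 40, 24)
  )
  expect_equal(sum(st$fish), 100, tolerance = 0.01)
})

test_that("the foci-per-cell mixture and intensity scaling follow the configuration", {
  st <- simulate_fish_stack(
    n_cells = 600, copy_number = 10, p_two_foci = 0.76,
    noise_sd = 0, seed = 6, cell_box = c(14, 14, 10)
  )
  expect_lt(abs(mean(st$truth$n_foci) - 1.76), 3 * sqrt(0.76 * 0.24 / 600))

  lo <- simulate_fish_stack(20, 70, noise_sd = 0, seed = 8)
  hi <- simulate_fish_stack(20, 412, noise_sd = 0, seed = 8)
  expect_equal(sum(hi$fish) / sum(lo$fish), 412 / 70, tolerance = 0.01)
})
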