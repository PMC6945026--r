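test_that("uniform coverage on a homogeneous genome yields a flat profile", {
  cfg <- sim_config(
    seed = 23, true_copy_number = 1, genome_length = 1e6,
    repeat_unit_length = 500, gc_repeat = 0.40, gc_background = 0.40,
    n_read_pairs = 5e4, gc_bias_mode = "none"
  )
  ref <- build_reference(cfg)
  reads <- simulate_reads(ref, cfg)
  prof <- fit_gc_profile(reads, ref)
  busy <- prof[prof$n_positions > 5000, ]
  rate0 <- glance(prof)$mean_rate
  # populated bins agree with the global rate within 3 Poisson SDs
  for (i in seq_len(nrow(busy))) {
    se <- sqrt(rate0 / busy$n_positions[i])
    expect_lt(abs(busy$rate[i] - rate0), 3 * se + 0.1 * rate0)
  }
})

test_that("a fitted profile reproduces the acceptance weight up to a constant", {
  # fragment length pinned near the window size so window GC is the
  # fragment GC and the comparison against w(g) is direct
  cfg <- sim_config(
    seed = 29, true_copy_number = 1, genome_length = 1e6,
    repeat_unit_length = 500, n_read_pairs = 2e5, gc_bias_mode = "unimodal",
    fragment_mean = 300, fragment_sd = 10
  )
  ref <- build_reference(cfg)
  reads <- simulate_reads(ref, cfg)
  prof <- fit_gc_profile(reads, ref)
  w <- function(g) exp(-(g - cfg$gc_bias_center)^2 / (2 * cfg$gc_bias_width^2))
  busy <- prof[prof$n_positions > 20000 & prof$n_starts > 500, ]
  scale <- stats::median(busy$rate / w(busy$gc_mid))
  rel_dev <- abs(busy$rate / (scale * w(busy$gc_mid)) - 1)
  expect_lt(max(rel_dev), 0.10)
})

test_that("zero reads produce an all-zero profile with a warning", {
  sim <- tiny_sim()
  none <- sim$reads[0, ]
  expect_warning(prof <- fit_gc_profile(none, sim$ref), "no read starts")
  expect_true(all(prof$rate == 0))
  expect_error(estimate_gcc(none, sim$ref, prof), "0")
})

test_that("GCC under a flat profile equals the start-density RR identity exactly", {
  sim <- tiny_sim()
  prof <- fit_gc_profile(sim$reads, sim$ref)
  flat <- flatten_gc_profile(prof)
  gcc <- estimate_gcc(sim$reads, sim$ref, flat)
  # with a constant rate the MLE is the repeat start density over the
  # background start density (start-counting, background-normalized RR)
  rate0 <- attr(prof, "n_background_starts") /
    attr(prof, "n_background_positions")
  expect_equal(gcc$value, gcc$n_region / (sim$ref$unit_length * rate0))
})

test_that("GCC matches start-based RR when repeat and background share GC", {
  cfg <- sim_config(
    seed = 37, true_copy_number = 20, genome_length = 1e6,
    repeat_unit_length = 500, gc_repeat = 0.45, gc_background = 0.45,
    n_read_pairs = 2e5, gc_bias_mode = "unimodal"
  )
  ref <- build_reference(cfg)
  reads <- simulate_reads(ref, cfg)
  prof <- fit_gc_profile(reads, ref)
  gcc <- estimate_gcc(reads, ref, prof)$value
  counts <- count_regions(reads, ref$repeat_region)
  rr <- estimate_rr(counts, ref$genome_length, ref$unit_length,
    counting = "start"
  )$value
  expect_equal(gcc, rr, tolerance = 0.03)
})

test_that("expected repeat counts and both estimators increase with copy number", {
  vals <- purrr::map_dfr(c(5, 20, 80), function(cc) {
    cfg <- sim_config(
      seed = 41, true_copy_number = cc, genome_length = 1e6,
      repeat_unit_length = 500, n_read_pairs = 5e4, gc_bias_mode = "none"
    )
    ref <- build_reference(cfg)
    reads <- simulate_reads(ref, cfg)
    counts <- count_regions(reads, ref$repeat_region)
    prof <- fit_gc_profile(reads, ref)
    tibble::tibble(
      cc = cc,
      n_rep = counts$n_overlap[1],
      rr = estimate_rr(counts, ref$genome_length, ref$unit_length)$value,
      gcc = estimate_gcc(reads, ref, prof)$value
    )
  })
  expect_true(all(diff(vals$n_rep) > 0))
  expect_true(all(diff(vals$rr) > 0))
  expect_true(all(diff(vals$gcc) > 0))
})

test_that("with no GC bias the RR estimator is unbiased across simulations", {
  cfg0 <- sim_config(
    seed = 1, true_copy_number = 10, genome_length = 1e6,
    repeat_unit_length = 500, n_read_pairs = 2e4, gc_bias_mode = "none"
  )
  ref <- build_reference(cfg0)
  ests <- vapply(1:50, function(s) {
    cfg <- sim_config(
      seed = s, true_copy_number = 10, genome_length = 1e6,
      repeat_unit_length = 500, n_read_pairs = 2e4, gc_bias_mode = "none"
    )
    reads <- simulate_reads(ref, cfg)
    counts <- count_regions(reads, ref$repeat_region)
    estimate_rr(counts, ref$genome_length, ref$unit_length)$value
  }, numeric(1))
  se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 10), 2 * se + 0.1)
})
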