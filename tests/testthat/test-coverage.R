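test_that("SAM round-trip: record counting matches the simulator's truth", {
  cfg <- sim_config(
    seed = 13, true_copy_number = 5, genome_length = 1e5,
    repeat_unit_length = 500, n_read_pairs = 500, gc_bias_mode = "none"
  )
  ref <- build_reference(cfg)
  reads <- simulate_reads(ref, cfg)
  sam <- tempfile(fileext = ".sam")
  write_read_files(reads, ref, cfg, sam = sam)
  aln <- read_alignments(sam)
  expect_equal(nrow(aln), 2 * cfg$n_read_pairs)
  expect_setequal(aln$pos, reads$pos)
})

test_that("unmapped records are excluded, empty files yield zero records", {
  header <- c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chr1\tLN:1000")
  f_empty <- tempfile(fileext = ".sam")
  writeLines(header, f_empty)
  expect_equal(nrow(read_alignments(f_empty)), 0)

  f_mix <- tempfile(fileext = ".sam")
  writeLines(c(
    header,
    "r1\t0\tchr1\t100\t60\t75M\t*\t0\t0\t*\t*",
    "r2\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"
  ), f_mix)
  aln <- read_alignments(f_mix)
  expect_equal(nrow(aln), 1)
  expect_equal(aln$pos, 100)
})

test_that("region counting uses >= 1-base overlap and flags unknown sequences", {
  aln <- tibble::tibble(
    qname = c("a", "b", "c"), seqname = "chr1",
    pos = c(101L, 27L, 201L), width = 75L, strand = "+"
  )
  # region [100, 200) is 1-based inclusive [101, 200]
  regions <- tibble::tibble(
    name = "reg", seqname = "chr1", start = 100L, end = 200L
  )
  counts <- count_regions(aln, regions)
  # read b spans [27, 101]: overlaps by exactly one base; read c starts at
  # 201, one base past the region, and does not count
  expect_equal(counts$n_overlap, 2)
  expect_equal(counts$n_start, 1)
  expect_equal(attr(counts, "total_mapped"), 3)

  bad <- tibble::tibble(name = "x", seqname = "chrZ", start = 1L, end = 10L)
  expect_error(count_regions(aln, bad), "chrZ")
})

test_that("the RR formula reproduces hand-computed values and its invariances", {
  mk_counts <- function(n_rep, n_tot) {
    out <- tibble::tibble(
      region = "rdna", seqname = "chr1", start = 0L, end = 10735L,
      region_length = 10735L, n_overlap = n_rep, n_start = n_rep,
      total_mapped = n_tot
    )
    attr(out, "total_mapped") <- n_tot
    out
  }
  # identity: region share equal to L/G gives exactly 1
  c1 <- estimate_rr(mk_counts(7197L, 100286070L), 100286070, 7197)
  expect_equal(c1$value, 1.0)
  # hand evaluation of the printed formula
  c2 <- estimate_rr(mk_counts(10000L, 1000000L), 100286070, 7197)
  expect_equal(c2$value, 139.35, tolerance = 0.005)
  # scale invariance
  c3 <- estimate_rr(mk_counts(20000L, 2000000L), 100286070, 7197)
  expect_equal(c3$value, c2$value)
  # degenerate inputs
  expect_error(estimate_rr(mk_counts(0L, 0L), 100286070, 7197), "N_tot")
  expect_warning(
    z <- estimate_rr(mk_counts(0L, 10L), 100286070, 7197),
    "estimate is 0"
  )
  expect_equal(z$value, 0)
})

test_that("RR equals a brute-force recount of the raw records", {
  sim <- tiny_sim()
  counts <- count_regions(sim$reads, sim$ref$repeat_region)
  est <- estimate_rr(counts, sim$ref$genome_length, sim$ref$unit_length)
  rs <- sim$ref$repeat_region$start
  re <- sim$ref$repeat_region$end
  n_rep <- 0
  for (i in seq_len(nrow(sim$reads))) {
    p <- sim$reads$pos[i]
    if (p <= re && p + sim$reads$width[i] - 1 >= rs + 1) n_rep <- n_rep + 1
  }
  expect_equal(est$n_region, n_rep)
  expect_equal(
    est$value,
    n_rep * sim$ref$genome_length / (nrow(sim$reads) * sim$ref$unit_length)
  )
})

test_that("control-region audit reads ~1 under uniform coverage and isolates repeat inflation", {
  sim <- tiny_sim()
  audit <- estimate_control_regions(sim$reads, sim$ref)
  expect_equal(nrow(audit), 29)
  # overlap counting admits reads hanging over either region edge, so a
  # 500-bp region with 75-bp reads reads (L + rl - 1) / L above 1
  L <- sim$ref$unit_length
  expected <- (L + 74) / L
  p <- L / sim$ref$genome_length
  n <- nrow(sim$reads)
  tol <- 3 * sqrt(p * (1 - p) / n) / p + 0.05
  expect_true(all(abs(audit$value - expected) < tol))
  expect_lt(abs(mean(audit$value) - expected), 0.05)

  # doubling repeat-region records inflates the rDNA call but leaves the
  # control audit in place: the audit diagnoses locus-specific distortion
  rep_rows <- sim$reads[sim$reads$origin == "repeat", ]
  distorted <- dplyr::bind_rows(sim$reads, rep_rows)
  audit2 <- estimate_control_regions(distorted, sim$ref)
  expect_lt(abs(mean(audit2$value) - mean(audit$value)), 0.02)

  empty <- estimate_control_regions(
    sim$reads, sim$ref$control_regions[0, ],
    genome_length = sim$ref$genome_length
  )
  expect_equal(nrow(empty), 0)
})

test_that("downsampling at fraction 1 is exact and bad arguments error", {
  sim <- tiny_sim()
  ds <- downsample_estimates(sim$reads, sim$ref,
    fraction = 1, n_reps = 3, seed = 1
  )
  expect_true(all(ds$value == attr(ds, "full_value")))
  expect_error(
    downsample_estimates(sim$reads, sim$ref, n_reps = 0),
    "n_reps"
  )
  expect_error(
    downsample_estimates(sim$reads, sim$ref, fraction = 0),
    "fraction"
  )
})

test_that("downsampling spread is small relative to cross-library error", {
  cfg <- sim_config(
    seed = 19, true_copy_number = 50, genome_length = 1e6,
    repeat_unit_length = 500, n_read_pairs = 2e5, gc_bias_mode = "none"
  )
  ref <- build_reference(cfg)
  reads <- simulate_reads(ref, cfg)
  ds <- downsample_estimates(reads, ref, fraction = 0.05, n_reps = 10, seed = 7)
  g <- glance(ds)
  # read resampling alone explains only a few percent of variation, far
  # below the tens-of-percent differences seen between library preps
  expect_lt(g$percent_spread, 20)
  expect_lt(abs(g$mean - g$full_value) / g$full_value, 0.05)
})
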