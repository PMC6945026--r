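test_that("Poisson zero-class inversion matches hand-computed values", {
  expect_equal(ddpcr_lambda(0, 100)$lambda, 0)
  # p = 1 - exp(-1)  =>  lambda * v = 1 exactly
  n <- 1e6
  k <- round(n * (1 - exp(-1)))
  v <- 0.85
  expect_equal(ddpcr_lambda(k, n, v)$lambda * v, 1, tolerance = 1e-5)
  # hand evaluation
  expect_equal(ddpcr_lambda(2000, 20000, 0.85)$lambda, -log(0.9) / 0.85,
    tolerance = 1e-12
  )
  expect_equal(ddpcr_lambda(2000, 20000, 0.85)$lambda, 0.1240, tolerance = 5e-4)
  expect_error(ddpcr_lambda(100, 100), "saturated")
  expect_error(ddpcr_lambda(1, 0), "positive")
})

test_that("ddPCR copy number is the concentration ratio times reference copies", {
  a <- droplet_assay(20000, 5000, 5000)
  expect_equal(ddpcr_copy_number(a)$value, 1)
  a2 <- droplet_assay(20000, 5000, 5000, reference_copies_per_genome = 2)
  expect_equal(ddpcr_copy_number(a2)$value, 2)
  expect_error(
    ddpcr_copy_number(droplet_assay(20000, 100, 0)),
    "reference"
  )
})

test_that("ddPCR concentration estimate is consistent as droplet count grows", {
  lambda_true <- 1.2 / 0.85
  bias <- vapply(c(1e3, 1e4, 1e5), function(n) {
    cfg <- sim_config(seed = 5, droplet_count = n)
    a <- simulate_droplets(lambda_true, 0.1, cfg)
    ddpcr_lambda(a$positives_target, a$n_droplets, a$droplet_volume)$lambda -
      lambda_true
  }, numeric(1))
  expect_lt(abs(bias[3]), abs(bias[1]) + 0.02)
  expect_lt(abs(bias[3]) / lambda_true, 0.02)
})

test_that("UMI deduplication keys on the (probe, UMI) pair", {
  reads <- tibble::tibble(
    probe_id = c(rep("p1", 5), "p2"),
    umi = c(rep("AAAATTTTCCCC", 5), "AAAATTTTCCCC"),
    allele = c(rep("ref", 5), "alt")
  )
  ct <- smmip_dedup(reads)
  expect_equal(sum(ct$n_genomic) + sum(ct$n_plasmid), 2)
  expect_equal(ct$n_genomic[ct$probe_id == "p1"], 1)
  expect_equal(ct$n_plasmid[ct$probe_id == "p2"], 1)
})

test_that("ambiguous alleles are dropped and logged", {
  reads <- tibble::tibble(
    probe_id = c("p1", "p1", "p1"),
    umi = c("A", "B", "C"),
    allele = c("ref", "amb", "amb")
  )
  ct <- smmip_dedup(reads)
  expect_equal(attr(ct, "n_ambiguous_dropped"), 2)
  expect_equal(sum(ct$n_genomic), 1)
})

test_that("the worked capture-table example yields exactly 100 copies", {
  tab <- tibble::tibble(
    probe_id = c("sc", "rdna"),
    target = c("single_copy", "rdna"),
    n_genomic = c(1000, 10000),
    n_plasmid = c(19000, 1900)
  )
  est <- smmip_estimate(tab)
  expect_equal(est$plasmids_per_genome, 19)
  expect_equal(est$value, 100)

  # rDNA probe counts equal to SC probe counts -> one copy per genome
  tab2 <- tibble::tibble(
    probe_id = c("sc", "rdna"), target = c("single_copy", "rdna"),
    n_genomic = c(1000, 1000), n_plasmid = c(19000, 19000)
  )
  expect_equal(smmip_estimate(tab2)$value, 1)
})

test_that("per-probe efficiency rescaling leaves the estimate unchanged", {
  tab <- tibble::tibble(
    probe_id = c("sc1", "sc2", "rd1", "rd2"),
    target = c("single_copy", "single_copy", "rdna", "rdna"),
    n_genomic = c(1000, 2000, 10000, 5000),
    n_plasmid = c(19000, 38000, 1900, 950)
  )
  base <- smmip_estimate(tab)$value
  tab10 <- tab
  tab10$n_genomic[c(1, 3)] <- tab10$n_genomic[c(1, 3)] * 10
  tab10$n_plasmid[c(1, 3)] <- tab10$n_plasmid[c(1, 3)] * 10
  expect_equal(smmip_estimate(tab10)$value, base)
})

test_that("degenerate capture tables are rejected", {
  no_plasmid <- tibble::tibble(
    probe_id = c("sc", "rdna"), target = c("single_copy", "rdna"),
    n_genomic = c(10, 10), n_plasmid = c(0, 0)
  )
  expect_error(smmip_estimate(no_plasmid), "plasmid")
  expect_error(
    smmip_estimate(no_plasmid[1, ]),
    "at least one"
  )
  expect_error(
    simulate_smmip_reads(sim_config(probes = default_smmip_probes()[0, ])),
    "empty probe set"
  )
})

test_that("simulated smMIP estimates recover truth across plasmid ratios", {
  for (ratio in c(1, 19, 50)) {
    cfg <- sim_config(
      seed = 7 + ratio, true_copy_number = 100,
      plasmid_to_genome_molar_ratio = ratio
    )
    reads <- simulate_smmip_reads(cfg)
    ct <- smmip_dedup(reads, probes = cfg$probes)
    est <- smmip_estimate(ct)
    expect_lt(abs(est$value / 100 - 1), 0.15)
  }
})

test_that("a 10x more efficient probe does not shift the simulated estimate", {
  probes <- default_smmip_probes()
  probes$efficiency <- 300
  cfg_eq <- sim_config(seed = 51, true_copy_number = 80, probes = probes)
  probes10 <- probes
  probes10$efficiency[1] <- 3000
  cfg_10 <- sim_config(seed = 51, true_copy_number = 80, probes = probes10)
  e_eq <- smmip_estimate(smmip_dedup(simulate_smmip_reads(cfg_eq),
    probes = probes
  ))$value
  e_10 <- smmip_estimate(smmip_dedup(simulate_smmip_reads(cfg_10),
    probes = probes10
  ))$value
  expect_lt(abs(e_eq / 80 - 1), 0.1)
  expect_lt(abs(e_10 / 80 - 1), 0.1)
})
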