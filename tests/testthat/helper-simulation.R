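# Shared small fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# a small unbiased simulation used across coverage tests
tiny_sim <- function() {
  memo("tiny_sim", function() {
    cfg <- sim_config(
      seed = 42, true_copy_number = 10, genome_length = 1e6,
      repeat_unit_length = 500, n_read_pairs = 2e4, gc_bias_mode = "none"
    )
    ref <- build_reference(cfg)
    list(cfg = cfg, ref = ref, reads = simulate_reads(ref, cfg))
  })
}

# straight-line reimplementation of the percent-error summary, used as an
# independent oracle against error_summary()
oracle_error_summary <- function(table, method, input_ng = NULL,
                                 strains = NULL, overrides = c(B30 = 35)) {
  refs <- list()
  for (s in unique(table$strain)) {
    vals <- table$value[table$method == "chef" & table$strain == s &
      !is.na(table$value)]
    refs[[s]] <- if (length(vals)) mean(vals) else unname(overrides[s])
  }
  errs <- c()
  for (i in seq_len(nrow(table))) {
    row <- table[i, ]
    if (row$method != method || is.na(row$value)) next
    if (!is.null(input_ng) &&
      (is.na(row$input_ng) || row$input_ng != input_ng)) {
      next
    }
    if (!is.null(strains) && !row$strain %in% strains) next
    errs <- c(errs, 100 * abs(row$value - refs[[row$strain]]) /
      refs[[row$strain]])
  }
  errs
}
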