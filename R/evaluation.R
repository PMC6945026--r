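# Method-comparison layer: percent error against the CHEF reference,
# replicate CV, correlation and Welch tests, grouped error summaries, and a
# regression harness over the bundled benchmark tables.

#' Bundled benchmark tables
#'
#' Copy-number estimates for a panel of C. elegans wild isolates (CHEF
#' replicates plus Nextera WGS relative-read and GC-corrected estimates at
#' two input amounts) and a panel of S. cerevisiae strains (CHEF replicates,
#' previously reported and re-sequenced GC-corrected WGS estimates, and
#' ddPCR triplicates), transcribed into tidy long form.
#'
#' @param organism `"celegans"` or `"scerevisiae"`.
#' @return A `benchmark_table` tibble with columns `strain`, `method`,
#'   `replicate`, `value` and organism-specific annotation columns
#'   (`input_ng`, `sra`, `control`, `genotype_mismatch`).
#' @export
benchmark_table <- function(organism = c("celegans", "scerevisiae")) {
  organism <- match.arg(organism)
  file <- switch(organism,
    celegans = "table1_celegans.csv",
    scerevisiae = "table2_scerevisiae.csv"
  )
  path <- system.file("extdata", file, package = "repeatdepth")
  out <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
  attr(out, "organism") <- organism
  class(out) <- c("benchmark_table", class(out))
  out
}

#' Percent error of an estimate against a reference
#'
#' `100 * |estimate - reference| / reference`.
#'
#' @param estimate,reference Numeric vectors (reference must be positive).
#' @return Percent error(s).
#' @export
percent_error <- function(estimate, reference) {
  if (anyNA(reference) || any(reference <= 0)) {
    abort("`reference` must be positive")
  }
  100 * abs(estimate - reference) / reference
}

#' Coefficient of variation in percent
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation; `NA` for
#' fewer than two values.
#'
#' @param values Numeric vector (`NA` dropped).
#' @return CV in percent, or `NA`.
#' @export
cv_percent <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    return(NA_real_)
  }
  100 * sd(values) / mean(values)
}

#' Pearson correlation
#'
#' Product-moment correlation with pairwise-complete observations; `NA`
#' (with a warning suppressed) for constant input.
#'
#' @param x,y Numeric vectors.
#' @return Correlation coefficient.
#' @export
pearson <- function(x, y) {
  suppressWarnings(cor(x, y, use = "pairwise.complete.obs"))
}

#' Welch two-sample t-test (tidy)
#'
#' Two-sided Welch test, as used to compare CHEF and ddPCR replicate sets.
#'
#' @param values_a,values_b Numeric vectors.
#' @return A one-row tibble: `statistic`, `p.value`, `df`, `estimate_a`,
#'   `estimate_b`.
#' @export
welch_t <- function(values_a, values_b) {
  fit <- t.test(values_a, values_b, var.equal = FALSE)
  tibble(
    statistic = unname(fit$statistic),
    p.value = fit$p.value,
    df = unname(fit$parameter),
    estimate_a = unname(fit$estimate[1]),
    estimate_b = unname(fit$estimate[2])
  )
}

#' CHEF reference value per strain
#'
#' The unrounded mean of available CHEF replicates; strains without CHEF
#' replicates fall back to `overrides` (by default B30 = 35, its separately
#' established CHEF-based copy number).
#'
#' @param table A [benchmark_table()].
#' @param overrides Named numeric vector of per-strain reference values used
#'   when no CHEF replicate exists.
#' @return A tibble `strain`, `reference`.
#' @export
chef_reference <- function(table, overrides = c(B30 = 35)) {
  refs <- table %>%
    filter(.data$method == "chef", !is.na(.data$value)) %>%
    group_by(.data$strain) %>%
    summarise(reference = mean(.data$value), .groups = "drop")
  missing <- setdiff(unique(table$strain), refs$strain)
  if (length(missing)) {
    fallback <- if (length(overrides)) {
      unname(overrides[missing])
    } else {
      rep(NA_real_, length(missing))
    }
    extra <- tibble(strain = missing, reference = fallback)
    if (any(is.na(extra$reference))) {
      abort(sprintf(
        "no CHEF reference and no override for strain(s): %s",
        paste(extra$strain[is.na(extra$reference)], collapse = ", ")
      ))
    }
    refs <- dplyr::bind_rows(refs, extra)
  }
  refs
}

#' Per-measurement percent errors for one method
#'
#' Each measurement of the chosen method is compared with its strain's CHEF
#' reference (full-precision replicate mean, see [chef_reference()]).
#'
#' @param table A [benchmark_table()] (or any tibble with `strain`,
#'   `method`, `replicate`, `value`).
#' @param method Method to evaluate (e.g. `"rr"`, `"gcc"`, `"ddpcr"`,
#'   `"wgs_reseq"`).
#' @param input_ng Optional input-amount filter (tables that carry it).
#' @param strains Optional strain subset.
#' @param overrides Passed to [chef_reference()].
#' @return An `error_summary` tibble, one row per measurement, with columns
#'   `strain`, `replicate`, `value`, `reference`, `percent_error`;
#'   `glance()` aggregates mean/min/max/median (raw and rounded to whole
#'   percent, the reporting convention).
#' @export
error_summary <- function(table, method, input_ng = NULL, strains = NULL,
                          overrides = c(B30 = 35)) {
  refs <- chef_reference(table, overrides)
  rows <- table[table$method == method & !is.na(table$value), ]
  if (!is.null(input_ng) && "input_ng" %in% names(rows)) {
    rows <- rows[!is.na(rows$input_ng) & rows$input_ng == input_ng, ]
  }
  if (!is.null(strains)) rows <- rows[rows$strain %in% strains, ]
  if (nrow(rows) == 0) abort("no measurements match the selection")
  out <- rows %>%
    left_join(refs, by = "strain") %>%
    mutate(percent_error = percent_error(.data$value, .data$reference)) %>%
    select(dplyr::any_of(c(
      "strain", "method", "input_ng", "replicate",
      "value", "reference", "percent_error"
    )))
  class(out) <- c("error_summary", class(out))
  out
}

#' @method glance error_summary
#' @export
glance.error_summary <- function(x, ...) {
  e <- x$percent_error
  tibble(
    n = length(e),
    mean = mean(e), min = min(e), max = max(e), median = median(e),
    mean_rounded = round(mean(e)), min_rounded = round(min(e)),
    max_rounded = round(max(e)), median_rounded = round(median(e))
  )
}

#' @rdname autoplot-repeatdepth
#' @method autoplot error_summary
#' @export
autoplot.error_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = stats::reorder(.data$strain, .data$reference),
    y = .data$percent_error
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 3, size = 3) +
    ggplot2::labs(
      x = NULL, y = "percent error vs CHEF reference",
      title = "Per-measurement copy-number error"
    ) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-strain CHEF replicate statistics
#'
#' @param table A [benchmark_table()].
#' @return A tibble `strain`, `n`, `mean`, `mean_rounded`, `sd`,
#'   `cv_percent`.
#' @export
chef_replicate_stats <- function(table) {
  table %>%
    filter(.data$method == "chef", !is.na(.data$value)) %>%
    group_by(.data$strain) %>%
    summarise(
      n = dplyr::n(), mean = mean(.data$value),
      mean_rounded = round(mean(.data$value)),
      sd = sd(.data$value),
      cv_percent = cv_percent(.data$value),
      .groups = "drop"
    )
}

#' Regression harness over the bundled benchmark tables
#'
#' Recomputes every headline summary statistic from the bundled fixtures —
#' the WGS mean percent errors by input amount and correction, the CHEF
#' replicate CV range and median, the reference strain means, the ddPCR
#' error mean and maximum, and the re-sequenced WGS mean deviation — and
#' compares each against its published value.
#'
#' @return A tibble `quantity`, `value`, `expected`, `pass`; `value` is the
#'   recomputed statistic rounded to the reporting precision (whole percent
#'   or whole copies), `expected` the published figure.
#' @export
benchmark_report <- function() {
  t1 <- benchmark_table("celegans")
  t2 <- benchmark_table("scerevisiae")

  wgs <- purrr::map_dfr(
    list(
      list(q = "t1_mean_error_rr_10ng", m = "rr", i = 10, exp = 18),
      list(q = "t1_mean_error_rr_50ng", m = "rr", i = 50, exp = 58),
      list(q = "t1_mean_error_gcc_10ng", m = "gcc", i = 10, exp = 15),
      list(q = "t1_mean_error_gcc_50ng", m = "gcc", i = 50, exp = 29)
    ),
    function(case) {
      g <- glance(error_summary(t1, case$m, input_ng = case$i))
      tibble(quantity = case$q, value = g$mean_rounded, expected = case$exp)
    }
  )

  cvs <- chef_replicate_stats(t1)
  chef <- tibble(
    quantity = c(
      "t1_chef_cv_min", "t1_chef_cv_max", "t1_chef_cv_median",
      "t1_chef_mean_MY1", "t1_chef_mean_JU775"
    ),
    value = c(
      round(min(cvs$cv_percent)), round(max(cvs$cv_percent)),
      round(median(cvs$cv_percent)),
      cvs$mean_rounded[cvs$strain == "MY1"],
      cvs$mean_rounded[cvs$strain == "JU775"]
    ),
    expected = c(3, 15, 6, 412, 70)
  )

  dd <- glance(error_summary(t2, "ddpcr"))
  wild <- unique(t2$strain[!t2$control])
  rs <- glance(error_summary(t2, "wgs_reseq", strains = wild))
  t2rows <- tibble(
    quantity = c(
      "t2_ddpcr_mean_error", "t2_ddpcr_max_error", "t2_reseq_mean_error"
    ),
    value = c(dd$mean_rounded, dd$max_rounded, rs$mean_rounded),
    expected = c(22, 41, 18)
  )

  out <- dplyr::bind_rows(wgs, chef, t2rows)
  out$pass <- out$value == out$expected
  out
}
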