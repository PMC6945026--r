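# Maximum-likelihood GC-content correction.
#
# Model: the number of read starts at reference position i is Poisson with
# rate c(i) * lambda(g_i), where g_i is the GC fraction of the W-base window
# starting at i, lambda is a piecewise-constant rate per GC bin estimated
# from background (non-repeat) positions where the local copy number is 1,
# and c(i) is the copy number. For the repeat region the MLE of c is
#
#   c_hat = (read starts inside the repeat region) / sum_i lambda(g_i)
#
# with the sum over repeat-region positions. Start-position counting is used
# inside the likelihood for model coherence even though region counting for
# the plain RR estimator uses >= 1-base overlap; the divergence is
# deliberate and tested.

window_gc_bins <- function(ref, window, bin_width) {
  key <- sprintf("gcbins_%d_%g", window, bin_width)
  hit <- ref$cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  cs <- ref$cache$gc_cumsum
  G <- ref$genome_length
  n_elig <- G - window + 1L
  gwin <- (cs[(window + 1):(G + 1)] - cs[1:n_elig]) / window
  edges <- seq(0, 1, by = bin_width)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  bin <- findInterval(gwin, edges, rightmost.closed = TRUE)
  res <- list(
    n_eligible = n_elig, edges = edges, bin = bin,
    gc_mid = (edges[-length(edges)] + edges[-1]) / 2
  )
  ref$cache[[key]] <- res
  res
}

# GC anchor of a record: the start of the W-base window used as its GC
# covariate. Plus-strand records anchor at their start; minus-strand records
# anchor so the window ends at their alignment end. Either way the window
# lies inside the originating fragment (for W at or below the fragment
# length), so window GC tracks the fragment GC that drove any bias.
gc_anchor_positions <- function(alignments, ref, window) {
  sel <- alignments$seqname == ref$seqname
  pos <- alignments$pos[sel]
  if ("strand" %in% names(alignments)) {
    minus <- alignments$strand[sel] == "-"
    w <- alignments$width[sel]
    pos[minus] <- pos[minus] + w[minus] - window
  }
  pos
}

position_mask <- function(ref, window) {
  # background eligible positions: window fits in the genome and does not
  # overlap the repeat region (nor contain N, which the generator never emits)
  rs <- ref$repeat_region$start
  re <- ref$repeat_region$end
  n_elig <- ref$genome_length - window + 1L
  i <- seq_len(n_elig)
  !(i + window - 1L > rs & i <= re) # overlap with repeat span (1-based)
}

#' Fit a per-GC-bin read-start rate profile
#'
#' For every eligible background position `i` (window fits the genome, no
#' overlap with the repeat region), the GC fraction of the `window`-base
#' window starting at `i` is binned, and the per-bin rate is read starts at
#' positions in the bin divided by the number of such positions. Bins holding
#' fewer than `min_positions` eligible positions are merged into their
#' nearest populated neighbour.
#'
#' @param alignments Alignment records (tibble with `pos`).
#' @param ref A `reference_model`.
#' @param window Window size in bases (default 300, approximately the
#'   fragment scale, so window GC tracks fragment GC).
#' @param bin_width GC-bin width (default 0.05).
#' @param min_positions Minimum eligible positions per bin before merging.
#' @return A `gc_bias_profile` tibble with one row per (merged) bin:
#'   `gc_lo`, `gc_hi`, `gc_mid`, `n_positions`, `n_starts`, `rate`.
#' @export
fit_gc_profile <- function(alignments, ref, window = 300, bin_width = 0.05,
                           min_positions = 100) {
  bins <- window_gc_bins(ref, window, bin_width)
  bg <- position_mask(ref, window)
  n_bins <- length(bins$gc_mid)

  pos_tab <- tabulate(bins$bin[bg], nbins = n_bins)

  starts <- gc_anchor_positions(alignments, ref, window)
  starts <- starts[starts >= 1L & starts <= bins$n_eligible]
  starts <- starts[bg[starts]]
  start_tab <- tabulate(bins$bin[starts], nbins = n_bins)

  if (sum(start_tab) == 0) {
    warn("no read starts on eligible background positions; all rates are 0")
  }

  # merge under-populated bins into the nearest populated neighbour
  group <- seq_len(n_bins)
  populated <- which(pos_tab >= min_positions)
  if (length(populated) == 0) abort("no GC bin holds enough positions")
  for (b in seq_len(n_bins)) {
    if (pos_tab[b] < min_positions) {
      group[b] <- populated[which.min(abs(populated - b))]
    }
  }
  if (length(unique(group[pos_tab > 0])) == 1 && n_bins > 1) {
    warn("all positions fall in one GC bin; correction degenerates to RR")
  }

  merged <- tibble(
    bin = seq_len(n_bins),
    group = group,
    n_positions = pos_tab,
    n_starts = start_tab
  ) %>%
    group_by(.data$group) %>%
    summarise(
      n_positions = sum(.data$n_positions),
      n_starts = sum(.data$n_starts),
      .groups = "drop"
    )
  rate_by_group <- setNames(
    ifelse(merged$n_positions > 0, merged$n_starts / merged$n_positions, 0),
    merged$group
  )

  out <- tibble(
    gc_lo = bins$edges[-length(bins$edges)],
    gc_hi = bins$edges[-1],
    gc_mid = bins$gc_mid,
    n_positions = pos_tab,
    n_starts = start_tab,
    group = group,
    rate = unname(rate_by_group[as.character(group)])
  )
  attr(out, "window") <- window
  attr(out, "bin_width") <- bin_width
  attr(out, "n_background_positions") <- sum(pos_tab)
  attr(out, "n_background_starts") <- sum(start_tab)
  class(out) <- c("gc_bias_profile", class(out))
  out
}

#' Constant (flat) bias profile
#'
#' A profile whose every bin carries the same rate; under it the GC-corrected
#' estimator reduces exactly to the start-counting, background-normalized
#' relative-read estimate. Useful as a null in tests and sanity checks.
#'
#' @param profile A fitted [fit_gc_profile()] to flatten (its overall
#'   background start rate becomes the constant).
#' @return A `gc_bias_profile`.
#' @export
flatten_gc_profile <- function(profile) {
  rate0 <- attr(profile, "n_background_starts") /
    attr(profile, "n_background_positions")
  out <- profile
  out$rate <- rate0
  out
}

profile_rate_lookup <- function(profile, gc_bin) {
  profile$rate[gc_bin]
}

#' GC-corrected copy-number estimate (maximum likelihood)
#'
#' Under the Poisson rate model (see [fit_gc_profile()]) the MLE of the
#' repeat copy number is the count of read starts inside the repeat region
#' divided by the sum of background-fitted rates over the repeat-region
#' positions.
#'
#' @param alignments Alignment records.
#' @param ref A `reference_model`.
#' @param profile A [fit_gc_profile()] fitted on the same sample.
#' @return A one-row `cn_estimate` tibble (`method = "GCC"`).
#' @export
estimate_gcc <- function(alignments, ref, profile) {
  window <- attr(profile, "window")
  bins <- window_gc_bins(ref, window, attr(profile, "bin_width"))
  rs <- ref$repeat_region$start
  re <- ref$repeat_region$end
  # Window GC over the repeat is computed treating the unit as circular: in
  # the tandem array the sequence following any unit position is the next
  # copy, which the collapsed reference truncates; extending windows into
  # the downstream flank would assign the wrong GC context to the last
  # `window` bases of the unit.
  unit_gc <- as.integer(ref$bases[(rs + 1L):re] %in% c(2L, 3L))
  L <- length(unit_gc)
  cs2 <- c(0, cumsum(c(unit_gc, unit_gc)))
  i <- seq_len(L)
  g_rep <- (cs2[i + window] - cs2[i]) / window
  bin_rep <- findInterval(g_rep, bins$edges, rightmost.closed = TRUE)
  lam <- sum(profile_rate_lookup(profile, bin_rep))
  if (lam == 0) {
    abort("sum of per-position rates over the repeat region is 0")
  }
  # numerator: records whose GC anchor lies in the repeat; anchors of
  # repeat-start records wrap circularly, mirroring the window treatment
  sel <- alignments$seqname == ref$seqname
  anchors <- gc_anchor_positions(alignments, ref, window)
  starts <- alignments$pos[sel]
  in_rep <- starts >= rs + 1L & starts <= re
  anchors[in_rep] <- rs + ((anchors[in_rep] - rs - 1L) %% L) + 1L
  n_start <- sum(anchors >= rs + 1L & anchors <= re)
  cn_estimate(
    method = "GCC", value = n_start / lam,
    region = ref$repeat_region$name, n_region = n_start,
    n_total = nrow(alignments)
  )
}

#' @method glance gc_bias_profile
#' @export
glance.gc_bias_profile <- function(x, ...) {
  tibble(
    window = attr(x, "window"),
    bin_width = attr(x, "bin_width"),
    n_bins = length(unique(x$group)),
    n_background_positions = attr(x, "n_background_positions"),
    n_background_starts = attr(x, "n_background_starts"),
    mean_rate = attr(x, "n_background_starts") /
      attr(x, "n_background_positions")
  )
}

#' @method tidy gc_bias_profile
#' @export
tidy.gc_bias_profile <- function(x, ...) {
  as_tibble(x)[, c("gc_mid", "gc_lo", "gc_hi", "n_positions", "n_starts", "rate")]
}

#' @rdname autoplot-repeatdepth
#' @method autoplot gc_bias_profile
#' @export
autoplot.gc_bias_profile <- function(object, ...) {
  d <- dplyr::filter(as_tibble(object), .data$n_positions > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gc_mid, y = .data$rate)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_positions), alpha = 0.6) +
    ggplot2::scale_size_continuous(guide = "none") +
    ggplot2::labs(
      x = "window GC fraction", y = "read starts per eligible position",
      title = "Fitted GC-bias profile"
    )
}
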