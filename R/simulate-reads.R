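# Paired-read simulator over the *expanded* genome (repeat unit replicated
# true_copy_number times), with optional unimodal GC acceptance on fragment
# GC, emitting truth alignments in collapsed-reference coordinates.

expanded_layout <- function(ref, copy_number) {
  key <- sprintf("expanded_%g", copy_number)
  hit <- ref$cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  L <- ref$unit_length
  rs <- ref$repeat_region$start # 0-based collapsed repeat start
  n_full <- floor(copy_number)
  partial <- round((copy_number - n_full) * L)
  rep_len <- as.integer(n_full * L + partial)

  unit <- ref$bases[(rs + 1):(rs + L)]
  expanded <- c(
    ref$bases[seq_len(rs)],
    rep(unit, times = n_full),
    if (partial > 0) unit[seq_len(partial)],
    ref$bases[(rs + L + 1):ref$genome_length]
  )
  lay <- list(
    repeat_start = rs,
    repeat_len = rep_len,
    length = length(expanded),
    bases = expanded,
    gc_cumsum = c(0, cumsum(as.integer(expanded == 2L | expanded == 3L)))
  )
  ref$cache[[key]] <- lay
  lay
}

# map 1-based expanded positions to 1-based collapsed positions
collapse_positions <- function(pos, lay, unit_length) {
  rs <- lay$repeat_start
  in_rep <- pos > rs & pos <= rs + lay$repeat_len
  after <- pos > rs + lay$repeat_len
  out <- pos
  out[in_rep] <- rs + ((pos[in_rep] - rs - 1L) %% unit_length) + 1L
  out[after] <- pos[after] - (lay$repeat_len - unit_length)
  out
}

#' Simulate GC-biased paired-end reads with truth alignments
#'
#' Fragments are drawn uniformly from the expanded genome (the repeat unit
#' replicated `true_copy_number` times), lengths truncated-normal on
#' `[2 * read_length, 2000]`. Under `gc_bias_mode = "unimodal"` a fragment of
#' GC fraction `g` is accepted with probability
#' `exp(-(g - center)^2 / (2 width^2))`, emulating tagmentation bias; under
#' `"none"` all fragments are accepted. Each fragment yields one read per
#' mate; truth alignments are reported in collapsed-reference coordinates,
#' with reads lying wholly inside the repeat flagged multi-mapping and
#' assigned to the single collapsed unit.
#'
#' @param ref A [build_reference()] result.
#' @param config A [sim_config()]; `true_copy_number`, `n_read_pairs`, the
#'   fragment model and the bias parameters are taken from it.
#' @return A tibble of `2 * n_read_pairs` alignment records with columns
#'   `qname`, `mate`, `seqname`, `pos` (1-based collapsed start), `width`,
#'   `strand`, `multi` (wholly repeat-internal), `fragment_gc`, and truth
#'   columns `origin` (`"repeat"`/`"background"`) and `copy_index` (which
#'   array copy the read came from, `NA` for background). Attributes carry
#'   `n_pairs`, `acceptance_rate` and the seed.
#' @export
simulate_reads <- function(ref, config) {
  stopifnot(inherits(ref, "reference_model"), inherits(config, "sim_config"))
  lay <- expanded_layout(ref, config$true_copy_number)
  rl <- config$read_length
  n <- config$n_read_pairs
  lo <- 2 * rl
  hi <- 2000

  frag_start <- integer(0)
  frag_len <- integer(0)
  frag_gc <- numeric(0)
  tried <- 0
  accepted <- 0

  withr::with_seed(config$seed, {
    while (length(frag_start) < n) {
      m <- max(1e4, ceiling((n - length(frag_start)) * 1.2))
      len <- pmin(
        hi,
        pmax(lo, round(truncnorm::rtruncnorm(
          m,
          a = lo, b = hi,
          mean = config$fragment_mean, sd = config$fragment_sd
        )))
      )
      start <- 1L + floor(runif(m) * (lay$length - len + 1))
      gc <- (lay$gc_cumsum[start + len] - lay$gc_cumsum[start]) / len
      keep <- if (config$gc_bias_mode == "none") {
        rep(TRUE, m)
      } else {
        runif(m) < exp(-(gc - config$gc_bias_center)^2 /
          (2 * config$gc_bias_width^2))
      }
      tried <- tried + m
      accepted <- accepted + sum(keep)
      if (tried >= 2e5 && accepted / tried < 1e-4) {
        abort(paste(
          "GC bias is degenerate: fewer than 0.01% of fragments are",
          "acceptable under the configured acceptance weight."
        ))
      }
      frag_start <- c(frag_start, start[keep])
      frag_len <- c(frag_len, len[keep])
      frag_gc <- c(frag_gc, gc[keep])
    }
  })
  frag_start <- frag_start[seq_len(n)]
  frag_len <- frag_len[seq_len(n)]
  frag_gc <- frag_gc[seq_len(n)]

  p1 <- frag_start
  p2 <- frag_start + frag_len - rl
  pos_exp <- c(p1, p2)

  rs <- lay$repeat_start
  in_rep_whole <- pos_exp > rs & (pos_exp + rl - 1) <= rs + lay$repeat_len
  pos <- collapse_positions(pos_exp, lay, ref$unit_length)
  copy_index <- ifelse(
    in_rep_whole,
    (pos_exp - rs - 1L) %/% ref$unit_length + 1L,
    NA_integer_
  )

  reads <- tibble(
    qname = rep(sprintf("frag%07d", seq_len(n)), 2),
    mate = rep(c(1L, 2L), each = n),
    seqname = ref$seqname,
    pos = as.integer(pos),
    width = rl,
    strand = rep(c("+", "-"), each = n),
    multi = in_rep_whole,
    fragment_gc = rep(frag_gc, 2),
    fragment_length = rep(frag_len, 2),
    origin = ifelse(in_rep_whole, "repeat", "background"),
    copy_index = as.integer(copy_index),
    pos_expanded = as.integer(pos_exp)
  )
  attr(reads, "n_pairs") <- n
  attr(reads, "seed") <- config$seed
  attr(reads, "acceptance_rate") <- accepted / tried
  class(reads) <- c("read_alignments", class(reads))
  reads
}

#' Write simulated reads as a FASTQ pair and a truth SAM
#'
#' Sequences are reconstructed from the expanded genome (mate 2 written
#' reverse-complemented in the FASTQ, as a sequencer would emit it); base
#' qualities are uniform. The SAM carries the minimal mandatory columns with
#' truth coordinates on the collapsed reference; wholly repeat-internal reads
#' are written with MAPQ 0 to mark multi-mapping, all others MAPQ 60.
#'
#' @param reads A [simulate_reads()] tibble.
#' @param ref The `reference_model` the reads were simulated from.
#' @param config The matching [sim_config()].
#' @param fastq1,fastq2,sam Output paths (`NULL` to skip any of them).
#' @return `reads`, invisibly.
#' @export
write_read_files <- function(reads, ref, config, fastq1 = NULL, fastq2 = NULL,
                             sam = NULL) {
  lay <- expanded_layout(ref, config$true_copy_number)
  rl <- config$read_length
  seq_of <- function(p) {
    idx <- rep(p, each = rl) + rep(0:(rl - 1), times = length(p))
    matrix(BASES[lay$bases[idx]], nrow = rl)
  }
  revcomp <- c("T", "G", "C", "A")
  names(revcomp) <- BASES

  m1 <- reads[reads$mate == 1L, ]
  m2 <- reads[reads$mate == 2L, ]
  s1 <- apply(seq_of(m1$pos_expanded), 2, paste, collapse = "")
  s2m <- seq_of(m2$pos_expanded)
  s2 <- apply(s2m[rev(seq_len(rl)), , drop = FALSE], 2, function(x) {
    paste(revcomp[x], collapse = "")
  })
  qual <- strrep("I", rl)

  write_fq <- function(path, ids, seqs) {
    writeLines(
      as.vector(rbind(paste0("@", ids), seqs, "+", qual)),
      path
    )
  }
  if (!is.null(fastq1)) write_fq(fastq1, m1$qname, s1)
  if (!is.null(fastq2)) write_fq(fastq2, m2$qname, s2)

  if (!is.null(sam)) {
    header <- c(
      "@HD\tVN:1.6\tSO:unsorted",
      sprintf("@SQ\tSN:%s\tLN:%d", ref$seqname, ref$genome_length)
    )
    # rows are ordered: all mate-1 records, then all mate-2 records
    flag <- ifelse(reads$mate == 1L, 0x1 + 0x40 + 0x20, 0x1 + 0x80 + 0x10)
    pnext <- c(m2$pos, m1$pos)
    tlen <- ifelse(reads$mate == 1L, reads$fragment_length,
      -reads$fragment_length
    )
    body <- sprintf(
      "%s\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t%s",
      reads$qname, flag, reads$seqname, reads$pos,
      ifelse(reads$multi, 0L, 60L), rl, pnext, tlen,
      c(s1, s2), qual
    )
    writeLines(c(header, body), sam)
  }
  invisible(reads)
}
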