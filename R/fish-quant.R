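# FISH quantification: nucleus segmentation (global Otsu + 3-D connected
# components, with optional marker-based separation of touching nuclei),
# focus detection (3-D local maxima above a robust intra-nuclear threshold)
# and integrated spot intensity as a relative copy-number readout.

#' Segment nuclei in a DAPI stack
#'
#' Global Otsu threshold followed by 3-D connected components (6-neighbour
#' connectivity, built from per-slice labelling merged across slices).
#' Components smaller than `min_voxels` are discarded. When
#' `split_touching = TRUE`, components containing two or more well-separated
#' local maxima of the smoothed DAPI signal are split by assigning voxels to
#' the nearest marker.
#'
#' @param dapi 3-D numeric array.
#' @param threshold Numeric threshold; `NULL` (default) uses Otsu on the
#'   whole volume.
#' @param min_voxels Minimum component size in voxels.
#' @param split_touching Split merged components at intensity markers.
#' @param min_marker_sep Minimum marker separation in voxels for a split.
#' @return An integer array of nucleus labels (0 = background).
#' @export
segment_nuclei <- function(dapi, threshold = NULL, min_voxels = 200,
                           split_touching = FALSE, min_marker_sep = 8) {
  if (is.null(threshold)) threshold <- otsu_threshold(dapi)
  mask <- dapi > threshold
  if (!any(mask)) {
    return(array(0L, dim(dapi)))
  }
  labels <- label_components_3d(mask)
  if (split_touching) {
    labels <- split_by_markers(labels, dapi, min_marker_sep)
  }
  sizes <- tabulate(labels)
  drop <- which(sizes < min_voxels)
  if (length(drop)) labels[labels %in% drop] <- 0L
  relabel_consecutive(labels)
}

otsu_threshold <- function(a) {
  v <- as.vector(a)
  rng <- range(v)
  if (diff(rng) == 0) {
    return(rng[1])
  }
  img <- EBImage::Image(matrix((v - rng[1]) / diff(rng), ncol = 1))
  th <- EBImage::otsu(img, range = c(0, 1), levels = 256)
  rng[1] + th * diff(rng)
}

# 3-D connected components: per-slice EBImage::bwlabel, then a union-find
# merge of labels that overlap between adjacent z slices.
label_components_3d <- function(mask) {
  dims <- dim(mask)
  nz <- dims[3]
  slabs <- vector("list", nz)
  offset <- 0L
  for (z in seq_len(nz)) {
    lab <- EBImage::bwlabel(EBImage::Image(mask[, , z] * 1))
    lab <- as.integer(lab)
    lab[lab > 0L] <- lab[lab > 0L] + offset
    offset <- offset + max(lab, 0L)
    slabs[[z]] <- lab
  }
  parent <- seq_len(offset)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i)
    rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (z in seq_len(nz - 1)) {
    a <- slabs[[z]]
    b <- slabs[[z + 1]]
    both <- a > 0L & b > 0L
    if (any(both)) {
      pairs <- unique(cbind(a[both], b[both]))
      for (r in seq_len(nrow(pairs))) union(pairs[r, 1], pairs[r, 2])
    }
  }
  roots <- vapply(seq_len(offset), find, integer(1))
  out <- array(0L, dims)
  for (z in seq_len(nz)) {
    lab <- slabs[[z]]
    nonzero <- lab > 0L
    lab[nonzero] <- roots[lab[nonzero]]
    out[, , z] <- lab
  }
  out
}

relabel_consecutive <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0) {
    return(labels)
  }
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  nonzero <- labels > 0L
  labels[nonzero] <- map[labels[nonzero]]
  labels
}

smooth_stack <- function(a, sigma = 2) {
  dims <- dim(a)
  out <- a
  for (z in seq_len(dims[3])) {
    out[, , z] <- as.numeric(EBImage::gblur(EBImage::Image(a[, , z]), sigma))
  }
  # light z smoothing
  if (dims[3] >= 3) {
    zsm <- out
    zsm[, , 2:(dims[3] - 1)] <- (out[, , 1:(dims[3] - 2)] +
      out[, , 2:(dims[3] - 1)] + out[, , 3:dims[3]]) / 3
    out <- zsm
  }
  out
}

split_by_markers <- function(labels, dapi, min_sep) {
  sm <- smooth_stack(dapi)
  next_label <- max(labels) + 1L
  for (id in sort(unique(labels[labels > 0L]))) {
    vox <- which(labels == id, arr.ind = TRUE)
    vals <- sm[labels == id]
    ord <- order(vals, decreasing = TRUE)
    markers <- matrix(numeric(0), ncol = 3)
    for (k in ord[seq_len(min(length(ord), 2000))]) {
      p <- vox[k, ]
      if (nrow(markers) == 0 ||
        min(sqrt(colSums((t(markers) - p)^2))) >= min_sep) {
        if (vals[k] > 0.5 * vals[ord[1]]) markers <- rbind(markers, p)
      }
      if (nrow(markers) >= 4) break
    }
    if (nrow(markers) >= 2) {
      d2 <- sapply(seq_len(nrow(markers)), function(m) {
        (vox[, 1] - markers[m, 1])^2 + (vox[, 2] - markers[m, 2])^2 +
          (vox[, 3] - markers[m, 3])^2
      })
      assign_to <- max.col(-d2)
      for (m in 2:nrow(markers)) {
        sel <- vox[assign_to == m, , drop = FALSE]
        labels[sel] <- next_label
        next_label <- next_label + 1L
      }
    }
  }
  labels
}

#' Detect FISH foci and quantify integrated intensity
#'
#' Candidate foci are 3-D local maxima (26-neighbourhood) whose value
#' exceeds `median + k_mad * MAD` of the intra-nuclear voxel distribution of
#' their nucleus. Maxima closer than `radius` merge into the brighter one.
#' Integrated intensity is the sum of voxel values within a sphere of
#' `radius` voxels around the peak minus the nucleus median background times
#' the sphere voxel count; size is the count of sphere voxels above half-max.
#'
#' @param fish 3-D numeric array (FISH channel).
#' @param labels Nucleus label array from [segment_nuclei()].
#' @param k_mad Threshold in MAD units above the intra-nuclear median.
#' @param radius Integration radius in voxels (default `3 * psf_sigma`).
#' @param psf_sigma Point-spread width used for the default radius.
#' @return A `foci_table` tibble: `cell`, `x`, `y`, `z`, `intensity`,
#'   `size`, `peak`; zero rows (with a warning) when no nuclei are present.
#' @export
detect_foci <- function(fish, labels, k_mad = 5, radius = NULL,
                        psf_sigma = 1.5) {
  if (is.null(radius)) radius <- 3 * psf_sigma
  empty <- tibble(
    cell = integer(), x = integer(), y = integer(), z = integer(),
    intensity = numeric(), size = integer(), peak = numeric()
  )
  class(empty) <- c("foci_table", class(empty))
  if (max(labels) == 0L) {
    warn("no nuclei in the label array; returning an empty foci table")
    return(empty)
  }
  is_max <- local_maxima_3d(fish)
  cand <- which(is_max & labels > 0L)
  if (length(cand) == 0) {
    return(empty)
  }
  cand_lab <- labels[cand]
  cand_val <- fish[cand]

  stats_by_lab <- tibble(lab = as.vector(labels[labels > 0L]),
                         val = fish[labels > 0L]) %>%
    group_by(.data$lab) %>%
    summarise(
      med = median(.data$val), madv = mad(.data$val), .groups = "drop"
    )
  med <- setNames(stats_by_lab$med, stats_by_lab$lab)
  madv <- setNames(stats_by_lab$madv, stats_by_lab$lab)
  thr <- med[as.character(cand_lab)] + k_mad * madv[as.character(cand_lab)]
  keep <- cand_val > thr
  cand <- cand[keep]
  cand_lab <- cand_lab[keep]
  cand_val <- cand_val[keep]
  if (length(cand) == 0) {
    return(empty)
  }

  dims <- dim(fish)
  ci <- arrayInd(cand, dims)
  # merge maxima closer than radius, keeping the brighter
  ord <- order(cand_val, decreasing = TRUE)
  kept <- logical(length(cand))
  for (k in ord) {
    p <- ci[k, ]
    sel <- which(kept)
    if (length(sel) == 0 ||
      min((ci[sel, 1] - p[1])^2 + (ci[sel, 2] - p[2])^2 +
        (ci[sel, 3] - p[3])^2) > radius^2) {
      kept[k] <- TRUE
    }
  }
  ci <- ci[kept, , drop = FALSE]
  cand_lab <- cand_lab[kept]
  cand_val <- cand_val[kept]

  # background for subtraction: per-nucleus median over voxels *outside*
  # every integration sphere, so the foci do not contaminate their own
  # background estimate
  sphere <- sphere_offsets(radius)
  in_sphere <- array(FALSE, dims)
  sphere_vox <- function(k) {
    p <- ci[k, ]
    ox <- p[1] + sphere[, 1]
    oy <- p[2] + sphere[, 2]
    oz <- p[3] + sphere[, 3]
    ok <- ox >= 1 & ox <= dims[1] & oy >= 1 & oy <= dims[2] &
      oz >= 1 & oz <= dims[3]
    cbind(ox[ok], oy[ok], oz[ok])
  }
  for (k in seq_len(nrow(ci))) in_sphere[sphere_vox(k)] <- TRUE
  outside <- labels > 0L & !in_sphere
  bg_tab <- tibble(lab = as.vector(labels[outside]),
                   val = fish[outside]) %>%
    group_by(.data$lab) %>%
    summarise(bg = median(.data$val), .groups = "drop")
  bg_by_lab <- setNames(bg_tab$bg, bg_tab$lab)

  rows <- purrr::map_dfr(seq_len(nrow(ci)), function(k) {
    p <- ci[k, ]
    vox <- sphere_vox(k)
    vals <- fish[vox]
    bg <- unname(bg_by_lab[as.character(cand_lab[k])])
    if (is.na(bg)) bg <- unname(med[as.character(cand_lab[k])])
    half <- bg + (cand_val[k] - bg) / 2
    tibble(
      cell = as.integer(cand_lab[k]),
      x = p[1], y = p[2], z = p[3],
      intensity = sum(vals) - bg * length(vals),
      size = sum(vals >= half),
      peak = cand_val[k]
    )
  })
  class(rows) <- c("foci_table", class(rows))
  rows
}

local_maxima_3d <- function(a) {
  dims <- dim(a)
  out <- array(TRUE, dims)
  shifts <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  shifts <- shifts[!(shifts$dx == 0 & shifts$dy == 0 & shifts$dz == 0), ]
  pad <- -Inf
  for (s in seq_len(nrow(shifts))) {
    sh <- shifted_array(a, shifts$dx[s], shifts$dy[s], shifts$dz[s], pad)
    out <- out & (a >= sh)
  }
  out
}

shifted_array <- function(a, dx, dy, dz, pad) {
  dims <- dim(a)
  out <- array(pad, dims)
  src <- list(
    x = max(1, 1 - dx):min(dims[1], dims[1] - dx),
    y = max(1, 1 - dy):min(dims[2], dims[2] - dy),
    z = max(1, 1 - dz):min(dims[3], dims[3] - dz)
  )
  out[src$x, src$y, src$z] <-
    a[src$x + dx, src$y + dy, src$z + dz]
  out
}

sphere_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  as.matrix(g[g$x^2 + g$y^2 + g$z^2 <= radius^2, ])
}

#' Per-cell focus counts including zero-focus cells
#'
#' @param foci A [detect_foci()] table.
#' @param labels The nucleus label array the foci were called on.
#' @return A tibble `cell`, `n_foci`.
#' @export
foci_per_cell <- function(foci, labels) {
  cells <- tibble(cell = seq_len(max(labels, 0L)))
  counts <- count(as_tibble(foci), .data$cell, name = "n_foci")
  out <- left_join(cells, counts, by = "cell")
  out$n_foci[is.na(out$n_foci)] <- 0L
  out
}

#' Per-strain intensity summary and concordance with reference copy numbers
#'
#' Sums focus intensities per cell, summarises each strain's per-cell total
#' intensity distribution, and — when reference copy numbers are supplied —
#' reports the Pearson and Spearman correlation of strain median intensity
#' with copy number.
#'
#' @param foci A tibble of foci across strains with columns `strain`,
#'   `cell`, `intensity`.
#' @param reference Optional tibble `strain`, `copies`.
#' @return A `strain_intensity_summary` tibble, one row per strain, with
#'   correlations (or `NA` when undefined) in attributes; `glance()` returns
#'   them.
#' @export
strain_intensity_summary <- function(foci, reference = NULL) {
  stopifnot(all(c("strain", "cell", "intensity") %in% names(foci)))
  per_cell <- foci %>%
    group_by(.data$strain, .data$cell) %>%
    summarise(
      total = sum(.data$intensity), n_foci = dplyr::n(), .groups = "drop"
    )
  out <- per_cell %>%
    group_by(.data$strain) %>%
    summarise(
      n_cells = dplyr::n(),
      mean_foci_per_cell = mean(.data$n_foci),
      median_intensity = median(.data$total),
      mean_intensity = mean(.data$total),
      sd_intensity = sd(.data$total),
      .groups = "drop"
    )
  pearson_r <- spearman_r <- NA_real_
  if (!is.null(reference)) {
    out <- left_join(out, reference, by = "strain")
    ok <- complete.cases(out[, c("median_intensity", "copies")])
    if (sum(ok) >= 3 &&
      sd(out$median_intensity[ok]) > 0 && sd(out$copies[ok]) > 0) {
      pearson_r <- cor(out$median_intensity[ok], out$copies[ok])
      spearman_r <- cor(out$median_intensity[ok], out$copies[ok],
        method = "spearman"
      )
    }
  }
  attr(out, "pearson") <- pearson_r
  attr(out, "spearman") <- spearman_r
  attr(out, "per_cell") <- per_cell
  class(out) <- c("strain_intensity_summary", class(out))
  out
}

#' @method glance strain_intensity_summary
#' @export
glance.strain_intensity_summary <- function(x, ...) {
  tibble(
    n_strains = nrow(x),
    pearson = attr(x, "pearson"),
    spearman = attr(x, "spearman"),
    mean_foci_per_cell = mean(x$mean_foci_per_cell)
  )
}

#' @rdname autoplot-repeatdepth
#' @method autoplot strain_intensity_summary
#' @export
autoplot.strain_intensity_summary <- function(object, ...) {
  per_cell <- attr(object, "per_cell")
  d <- left_join(per_cell,
    object[, c("strain", intersect("copies", names(object)))],
    by = "strain"
  )
  if ("copies" %in% names(d)) {
    ggplot2::ggplot(d, ggplot2::aes(
      x = factor(.data$copies), y = .data$total
    )) +
      ggplot2::geom_boxplot(outlier.alpha = 0.3) +
      ggplot2::labs(
        x = "reference copy number",
        y = "per-cell integrated FISH intensity (a.u.)"
      )
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$strain, y = .data$total)) +
      ggplot2::geom_boxplot(outlier.alpha = 0.3) +
      ggplot2::labs(x = NULL, y = "per-cell integrated FISH intensity (a.u.)")
  }
}
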