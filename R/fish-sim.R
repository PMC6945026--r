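# Synthetic two-channel 3-D FISH stacks: DAPI nuclei as filled ellipsoids,
# repeat-array foci as 3-D Gaussians whose integrated intensity is
# proportional to copy number.

#' Simulate a 3-D FISH image stack
#'
#' Cells are laid out on a grid; each cell's nucleus is a filled ellipsoid in
#' the DAPI channel. Each cell carries one or two foci (two with probability
#' `p_two_foci`); the cell's total focus intensity is
#' `intensity_per_copy * copy_number`, split randomly between foci when there
#' are two, and each focus is rendered as an isotropic 3-D Gaussian of width
#' `psf_sigma`. Additive Gaussian noise is applied to both channels.
#'
#' @param n_cells Number of cells.
#' @param copy_number Repeat copy number of the strain.
#' @param intensity_per_copy Integrated intensity contributed per repeat copy
#'   (arbitrary units).
#' @param p_two_foci Probability a cell shows two foci rather than one
#'   (default 0.76, giving a mean of 1.76 foci per cell).
#' @param psf_sigma Gaussian focus width in voxels.
#' @param noise_sd Additive noise SD (both channels).
#' @param seed Integer seed.
#' @param cell_box Per-cell sub-volume as `c(x, y, z)` voxels.
#' @return A list of class `fish_stack`: `fish` and `dapi` 3-D arrays and a
#'   `truth` tibble (one row per cell: `cell`, `n_foci`, `total_intensity`,
#'   nucleus center).
#' @export
simulate_fish_stack <- function(n_cells, copy_number, intensity_per_copy = 1,
                                p_two_foci = 0.76, psf_sigma = 1.5,
                                noise_sd = 0.05, seed = 1L,
                                cell_box = c(26, 26, 14)) {
  ncol_grid <- ceiling(sqrt(n_cells))
  nrow_grid <- ceiling(n_cells / ncol_grid)
  dims <- c(ncol_grid * cell_box[1], nrow_grid * cell_box[2], cell_box[3])
  fish <- array(0, dims)
  dapi <- array(0, dims)
  semi <- c(cell_box[1] * 0.33, cell_box[2] * 0.33, cell_box[3] * 0.30)

  withr::with_seed(seed, {
    truth <- purrr::map_dfr(seq_len(n_cells), function(i) {
      gx <- (i - 1) %% ncol_grid
      gy <- (i - 1) %/% ncol_grid
      center <- c(
        gx * cell_box[1] + cell_box[1] / 2 + runif(1, -1.5, 1.5),
        gy * cell_box[2] + cell_box[2] / 2 + runif(1, -1.5, 1.5),
        cell_box[3] / 2 + runif(1, -1, 1)
      )
      dapi <<- add_ellipsoid(dapi, center, semi, value = 1)

      k <- 1L + rbinom(1, 1, p_two_foci)
      total <- intensity_per_copy * copy_number
      if (k == 2) {
        f <- runif(1, 0.35, 0.65)
        split <- c(f, 1 - f) * total
        # two foci sit on opposite sides of the nucleus, as distinct
        # nucleolar organizers do; keeps them resolvable at the PSF scale
        ang <- runif(1, 0, 2 * pi)
        rad <- runif(1, 0.30, 0.45)
        off <- c(cos(ang), sin(ang)) * rad * semi[1:2]
        pos <- list(
          center + c(off, runif(1, -0.3, 0.3) * semi[3]),
          center + c(-off, runif(1, -0.3, 0.3) * semi[3])
        )
      } else {
        split <- total
        pos <- list(center + c(
          runif(2, -0.3, 0.3) * semi[1:2],
          runif(1, -0.3, 0.3) * semi[3]
        ))
      }
      for (j in seq_len(k)) {
        fish <<- add_gaussian_focus(fish, pos[[j]], psf_sigma, split[j])
      }
      tibble(
        cell = i, n_foci = k, total_intensity = total,
        cx = center[1], cy = center[2], cz = center[3]
      )
    })
    if (noise_sd > 0) {
      fish <- fish + array(rnorm(length(fish), 0, noise_sd), dims)
      dapi <- dapi + array(rnorm(length(dapi), 0, noise_sd), dims)
    }
  })
  structure(
    list(fish = fish, dapi = dapi, truth = truth, copy_number = copy_number),
    class = "fish_stack"
  )
}

add_ellipsoid <- function(a, center, semi, value = 1) {
  rng <- lapply(1:3, function(d) {
    max(1, floor(center[d] - semi[d])):min(dim(a)[d], ceiling(center[d] + semi[d]))
  })
  xs <- (rng[[1]] - center[1]) / semi[1]
  ys <- (rng[[2]] - center[2]) / semi[2]
  zs <- (rng[[3]] - center[3]) / semi[3]
  d2 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
  sub <- a[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  a[rng[[1]], rng[[2]], rng[[3]]] <- sub + value * (d2 <= 1)
  a
}

add_gaussian_focus <- function(a, center, sigma, total) {
  r <- ceiling(4 * sigma)
  rng <- lapply(1:3, function(d) {
    max(1, round(center[d]) - r):min(dim(a)[d], round(center[d]) + r)
  })
  gx <- exp(-(rng[[1]] - center[1])^2 / (2 * sigma^2))
  gy <- exp(-(rng[[2]] - center[2])^2 / (2 * sigma^2))
  gz <- exp(-(rng[[3]] - center[3])^2 / (2 * sigma^2))
  kern <- outer(outer(gx, gy), gz)
  kern <- kern * (total / (2 * pi * sigma^2)^1.5)
  sub <- a[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  a[rng[[1]], rng[[2]], rng[[3]]] <- sub + kern
  a
}
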