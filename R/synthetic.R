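# run code with a locally scoped RNG seed, restoring the caller's RNG state
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic frond outline with controlled asymmetry
#'
#' Produces an egg-shaped closed outline with one mirror axis (the x-axis),
#' pointier at one end, emulating the guitar-pick silhouette of a duckweed
#' frond. The base curve is the polar egg `r(t) = 1 + pointiness * cos(t)`,
#' compressed across the axis by `1/elongation`. For `asymmetry > 0` a smooth
#' one-sided S-shaped perturbation `asymmetry * sin(t)^2 * sin(2t)` (upper
#' side only, vanishing to second order at the axis) multiplies the radius,
#' pushing the upper-right lobe out and the upper-left lobe in; this breaks
#' bilateral symmetry by a known amount, and the resulting CSM grows strictly
#' with `asymmetry` over the documented box (`asymmetry <= 0.2`);
#' `asymmetry = 0` gives an exactly mirror-symmetric point set. The outline
#' is resampled to `n_points` equally spaced reference points starting on the
#' axis at the pointy tip, then centered on the reference-point centroid.
#' Deterministic: no RNG is consumed.
#'
#' @param scale Overall size in pixels (max centroid-to-tip distance before
#'   elongation compression), > 0.
#' @param elongation Length-to-width ratio along the symmetry axis, >= 1.
#' @param pointiness Egg skew in `[0, 1)`; 0 gives an ellipse/circle.
#' @param asymmetry Bump amplitude `>= 0` (relative to the local radius).
#' @param n_points Number of outline reference points.
#' @param dense Number of dense samples used before equal-arc resampling.
#' @return Tibble with `x`, `y` (pixel units), centered near the origin.
#' @examples
#' sym <- make_outline(asymmetry = 0)
#' csm(sym)$csm          # ~0
#' bent <- make_outline(asymmetry = 0.1)
#' csm(bent)$csm > 1e-4  # symmetry visibly broken
#' @export
make_outline <- function(scale = 100, elongation = 1.3, pointiness = 0.35,
                         asymmetry = 0, n_points = 200L, dense = 2000L) {
  stopifnot(scale > 0, elongation >= 1, pointiness >= 0, pointiness < 1,
            asymmetry >= 0)
  m <- as.integer(dense) %/% 2L
  t_up <- seq(0, pi, length.out = m + 1L)
  r_up <- (1 + pointiness * cos(t_up)) *
    (1 + asymmetry * sin(t_up)^2 * sin(2 * t_up))
  if (any(r_up <= 0)) stop("parameters produce a degenerate (non-positive) radius")
  xu <- r_up * cos(t_up)
  yu <- r_up * sin(t_up) / elongation
  # mirror the interior of the upper half so that asymmetry = 0 is symmetric
  # to the bit: the lower half reuses the upper half's coordinates at
  # asymmetry = 0
  t_lo <- t_up[m:2]
  r_lo <- (1 + pointiness * cos(t_lo))
  xl <- r_lo * cos(t_lo)
  yl <- -(r_lo * sin(t_lo)) / elongation
  xy <- cbind(c(xu, xl), c(yu, yl)) * scale
  out <- resample_outline(tibble::tibble(x = xy[, 1], y = xy[, 2]),
                          n_points = n_points)
  out$x <- out$x - mean(out$x)
  out$y <- out$y - mean(out$y)
  if (polygon_self_intersects(out)) {
    stop("parameters produce a self-intersecting outline")
  }
  out
}

# even-odd (crossing-number) point-in-polygon test, vectorised over points
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Render a synthetic frond photograph
#'
#' Paints an outline polygon as a green-ish frond (dark in the blue channel)
#' on a pale background (bright in blue), so that the inverse blue channel is
#' bimodal as the segmentation expects. Optional Gaussian pixel noise, small
#' foreground-coloured specks in the background and background-coloured holes
#' inside the frond exercise the mask-cleaning steps.
#'
#' @param outline Data frame with `x`, `y` (pixel units), centered near the
#'   origin; must fit the canvas with a 2-pixel margin.
#' @param width,height Canvas size in pixels.
#' @param noise_sd Gaussian intensity noise SD (0-255 scale).
#' @param n_specks Number of small (radius 1-2 px) foreground-coloured specks.
#' @param n_holes Number of small background-coloured interior holes.
#' @param seed RNG seed for noise/speck/hole placement (locally scoped).
#' @return `H x W x 3` numeric array, intensities in `[0, 255]`.
#' @export
render_frond_image <- function(outline, width = 256L, height = 256L,
                               noise_sd = 0, n_specks = 0L, n_holes = 0L,
                               seed = NULL) {
  cx <- width / 2; cy <- height / 2
  vx <- outline$x + cx
  vy <- cy - outline$y           # math y-up -> row-down
  if (min(vx) < 2 || max(vx) > width - 3 || min(vy) < 2 || max(vy) > height - 3) {
    stop("outline does not fit the canvas with a 2-pixel margin")
  }
  # pixel centers: 0-based (row, col); matrix entry [r, c] is center (r-1, c-1)
  cc <- rep(0:(width - 1L), each = height)
  rr <- rep(0:(height - 1L), times = width)
  fg <- matrix(points_in_polygon(cc, rr, vx, vy), height, width)

  local_seed(seed, {
    fg_col <- c(70, 140, 40)     # green-ish: low blue
    bg_col <- c(225, 225, 235)   # pale: high blue
    img <- array(0, dim = c(height, width, 3L))
    for (ch in 1:3) {
      img[, , ch] <- ifelse(fg, fg_col[ch], bg_col[ch])
    }
    paint_disk <- function(img, r0, c0, rad, col) {
      rs <- pmax(1L, r0 - rad):pmin(height, r0 + rad)
      cs <- pmax(1L, c0 - rad):pmin(width, c0 + rad)
      for (r in rs) for (c in cs) {
        if ((r - r0)^2 + (c - c0)^2 <= rad^2) img[r, c, ] <- col
      }
      img
    }
    if (n_specks > 0L) {
      placed <- 0L
      guard <- 0L
      while (placed < n_specks && guard < 1000L) {
        guard <- guard + 1L
        rad <- sample(1:2, 1L)
        r0 <- sample(seq_len(height), 1L); c0 <- sample(seq_len(width), 1L)
        box_r <- pmax(1L, r0 - rad - 2L):pmin(height, r0 + rad + 2L)
        box_c <- pmax(1L, c0 - rad - 2L):pmin(width, c0 + rad + 2L)
        if (any(fg[box_r, box_c])) next     # keep specks clear of the frond
        img <- paint_disk(img, r0, c0, rad, fg_col)
        placed <- placed + 1L
      }
    }
    if (n_holes > 0L) {
      fg_idx <- which(fg)
      placed <- 0L
      guard <- 0L
      while (placed < n_holes && guard < 1000L) {
        guard <- guard + 1L
        rad <- sample(1:2, 1L)
        k <- sample(fg_idx, 1L)
        r0 <- (k - 1L) %% height + 1L; c0 <- (k - 1L) %/% height + 1L
        box_r <- pmax(1L, r0 - rad - 2L):pmin(height, r0 + rad + 2L)
        box_c <- pmax(1L, c0 - rad - 2L):pmin(width, c0 + rad + 2L)
        if (!all(fg[box_r, box_c])) next    # hole must be strictly interior
        img <- paint_disk(img, r0, c0, rad, bg_col)
        placed <- placed + 1L
      }
    }
    if (noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, noise_sd)
    }
    pmin(pmax(img, 0), 255)
  })
}

#' Write an RGB array as a PNG file
#'
#' @param image `H x W x 3` array, intensities in `[0, 255]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frond_image <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}
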